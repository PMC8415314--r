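## pipeline: end-to-end train / call / eval entry points plus model
## serialization.  These are the functions the command-line wrapper
## (inst/cli/cnv-meann) dispatches to.

#' Serialize / load a trained model
#'
#' Plain-text JSON holding the topology, all weights and thresholds, the
#' learning rate and stopping error, the min-max normalization statistics
#' and the calling parameters (`bin_size`, `min_bins`), so that calling a
#' new sample reuses the training normalization exactly.
#'
#' @param net A trained `meann_net`.
#' @param path File path.
#' @return `read_meann_model()` returns the `meann_net`;
#'   `write_meann_model()` returns `path` invisibly.
#' @export
write_meann_model <- function(net, path) {
  stopifnot(inherits(net, "meann_net"))
  obj <- list(topology = unclass(net$topology),
              w_ih = as.vector(net$w_ih), w_ho = as.vector(net$w_ho),
              lam = net$lam, eta = net$eta, mu = net$mu, e0 = net$e0,
              stats = if (is.null(net$stats)) NULL else unclass(net$stats),
              bin_size = net$bin_size, min_bins = net$min_bins)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_meann_model
#' @export
read_meann_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  topo <- network_topology(obj$topology$n, obj$topology$m_out,
                           obj$topology$h)
  net <- decode_params(c(obj$w_ih, obj$w_ho, obj$lam, obj$eta), topo,
                       mu = obj$mu, e0 = obj$e0)
  if (!is.null(obj$stats)) {
    net$stats <- structure(obj$stats, class = "minmax_stats")
  }
  net$bin_size <- obj$bin_size
  net$min_bins <- obj$min_bins
  net
}

#' Train a CNV-calling model
#'
#' Fits the min-max normalization over all training tables, assembles the
#' labeled training set, searches for initial weights and thresholds with
#' the mind evolutionary algorithm, refines them by backpropagation, and
#' (optionally) serializes the model.  Training tables come from
#' [simulate_profile()] / [simulate_study()] or from
#' [compute_bin_features()] plus known per-bin labels.
#'
#' @param tables A labeled feature table, a list of them, or a vector of
#'   TSV paths readable by [read_feature_table()].
#' @param out_model Optional path for the serialized model (JSON).
#' @param bin_size Bin width (bp) the tables were computed with; stored in
#'   the model and enforced at calling time.
#' @param topology,mea_cfg,mu,e0,max_epochs Network and optimizer
#'   settings; see [network_topology()], [mea_config()], [init_network()]
#'   and [nn_train()].
#' @param use_mea If `FALSE`, skip the MEA and start backpropagation from
#'   random weights (for comparisons).
#' @param balance Downsample the majority (normal) class to the largest
#'   CNV class before training (pipeline default `TRUE`; the raw ~10:1
#'   imbalance otherwise dominates the squared-error objective).
#' @param min_bins Minimum run length for calls made with this model.
#' @param seed Integer seed controlling the MEA, initialization and epoch
#'   shuffling; a fixed seed reproduces the model bitwise.
#' @param trace_path Optional TSV path for the MEA convergence trace.
#' @param verbose Emit progress messages.
#' @return A list with `net` (the trained model, carrying the
#'   normalization statistics), `train` (epochs, convergence flag,
#'   final max error), `mea_score` (best MEA score, `NA` when
#'   `use_mea = FALSE`) and `dataset_size`.
#' @export
run_train <- function(tables, out_model = NULL, bin_size = 1000L,
                      topology = network_topology(),
                      mea_cfg = mea_config(), mu = 0.1, e0 = 0.1,
                      max_epochs = 100L, use_mea = TRUE, balance = TRUE,
                      min_bins = 3L, seed = NULL, trace_path = NULL,
                      verbose = FALSE) {
  if (is.character(tables)) tables <- lapply(tables, read_feature_table)
  if (is.data.frame(tables)) tables <- list(tables)
  if (!is.null(seed)) set.seed(seed)
  say <- function(...) if (verbose) message(...)

  dataset <- assemble_training_set(tables, balance = balance)
  say("training set: ", dataset$m, " bins (",
      paste(table(factor(dataset$L, levels = 0:3)), collapse = "/"),
      " per state)")

  mea_score <- NA_real_
  mea_trace <- NULL
  if (use_mea) {
    opt <- mea_optimize(dataset, topology, mea_cfg, trace_path = trace_path)
    net <- opt$net
    net$mu <- mu
    net$e0 <- e0
    mea_score <- opt$best$score
    mea_trace <- opt$trace
    say("MEA best score: ", format(mea_score))
  } else {
    net <- init_network(topology, mu = mu, e0 = e0)
  }

  fit <- nn_train(net, dataset, max_epochs = max_epochs)
  say("backpropagation: ", fit$epochs, " epochs, converged = ",
      fit$converged, ", max error = ", format(fit$max_error))

  net <- fit$net
  net$stats <- dataset$stats
  net$bin_size <- as.integer(bin_size)
  net$min_bins <- as.integer(min_bins)
  if (!is.null(out_model)) write_meann_model(net, out_model)
  list(net = net, train = fit[c("epochs", "converged", "max_error")],
       mea_score = mea_score, mea_trace = mea_trace,
       dataset_size = dataset$m)
}

#' Call CNVs on a sample
#'
#' Runs the calling half of the pipeline: features (computed from an
#' alignment or taken from a feature table), normalization with the
#' model's stored statistics, per-bin classification, and merging into
#' CNV calls.
#'
#' @param model A trained `meann_net` (from [run_train()]) or a path to a
#'   serialized model.
#' @param features A bin feature table or the path of a feature TSV.
#'   Ignored when `alignment` is given.
#' @param alignment,reference Paths to a SAM/BAM file and its reference
#'   FASTA; features are computed with the model's `bin_size`.
#' @param out Optional path for the BED-like call TSV.
#' @param min_bins Minimum call length in bins; defaults to the value
#'   stored in the model.
#' @return The call table (invisibly written to `out` when given).
#' @export
run_call <- function(model, features = NULL, alignment = NULL,
                     reference = NULL, out = NULL, min_bins = NULL) {
  net <- if (is.character(model)) read_meann_model(model) else model
  stopifnot(inherits(net, "meann_net"))
  if (is.null(net$stats)) {
    stop("model carries no normalization statistics; train it with ",
         "run_train()")
  }
  if (!is.null(alignment)) {
    if (is.null(reference)) stop("alignment input needs a reference FASTA")
    table <- compute_bin_features(alignment, reference,
                                  bin_size = net$bin_size)
  } else if (is.character(features)) {
    table <- read_feature_table(features)
  } else if (is.data.frame(features)) {
    table <- features
  } else {
    stop("supply either 'features' or 'alignment' + 'reference'")
  }
  widths <- table$end - table$start
  if (!is.null(net$bin_size) && length(widths) > 1 &&
      stats::median(widths) != net$bin_size) {
    stop("feature table bin size (", stats::median(widths),
         ") does not match the model's bin_size (", net$bin_size, ")")
  }
  norm <- apply_minmax(table, net$stats)
  classified <- classify_bins(net, norm)
  ## report raw (unnormalized) feature values alongside the calls' bins
  classified$rd <- table$rd
  classified$gc <- table$gc
  classified$mq <- table$mq
  if (is.null(min_bins)) min_bins <- if (is.null(net$min_bins)) 1L else
    net$min_bins
  calls <- merge_calls(classified, min_bins = min_bins)
  if (!is.null(out)) write_calls(calls, out)
  invisible(calls)
}

#' Evaluate a call set (or a batch of them) against ground truth
#'
#' @param calls Call table or path ([read_calls()]).
#' @param truth Truth table or path ([read_truth()]).
#' @param bin_size Bin width in bp.
#' @param out Optional path; the one-row evaluation report is written as
#'   TSV.
#' @param ... Passed to [evaluate_calls()] (e.g. `match_state`).
#' @return A `cnv_eval` object.
#' @export
run_eval <- function(calls, truth, bin_size = 1000L, out = NULL, ...) {
  if (is.character(calls)) calls <- read_calls(calls)
  if (is.character(truth)) truth <- read_truth(truth)
  ev <- evaluate_calls(calls, truth, bin_size = bin_size, ...)
  if (!is.null(out)) {
    write.table(data.frame(sensitivity = ev$sensitivity,
                           precision = ev$precision, f1 = ev$f1,
                           boundary_bias = ev$boundary_bias,
                           n_truth = ev$n_truth, n_calls = ev$n_calls),
                out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  ev
}
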