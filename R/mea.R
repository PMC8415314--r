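## mea: mind evolutionary algorithm over the flat weight/threshold vector.
## Superior and temporary subgroups evolve by similartaxis (local Gaussian
## search around each subgroup's best member until maturity) and compete
## by dissimilation (a temporary subgroup that out-scores the worst
## superior subgroup replaces it; vacated slots are re-seeded at random).
## Subgroup scores are published on a bulletin board whose best entry is
## non-decreasing across iterations.

#' MEA configuration
#'
#' Population structure and search-scale parameters.  The default
#' structure is 5 superior + 5 temporary subgroups of 20 individuals each
#' (population 200); `(n_superior + n_temporary) * subgroup_size` must
#' equal `population_size`.
#'
#' @param population_size Total number of individuals.
#' @param n_superior,n_temporary Numbers of superior / temporary subgroups.
#' @param subgroup_size Individuals per subgroup.
#' @param gene_bounds Search-space bounds `c(lo, hi)` for every gene.
#' @param similartaxis_sd Gaussian perturbation scale of the local search.
#' @param maturity_patience A subgroup is mature after this many
#'   consecutive similartaxis rounds without improvement of its best score.
#' @param max_iterations Outer similartaxis/dissimilation iterations.
#' @param stagnation_patience Stop early after this many outer iterations
#'   without improvement of the global best score.
#' @param seed Optional integer seed.
#' @return An object of class `mea_config`.
#' @export
mea_config <- function(population_size = 200L, n_superior = 5L,
                       n_temporary = 5L, subgroup_size = 20L,
                       gene_bounds = c(-1, 1), similartaxis_sd = 0.1,
                       maturity_patience = 3L, max_iterations = 8L,
                       stagnation_patience = 5L, seed = NULL) {
  stopifnot(population_size > 0, n_superior > 0, n_temporary > 0,
            subgroup_size > 1,
            (n_superior + n_temporary) * subgroup_size == population_size,
            length(gene_bounds) == 2L, gene_bounds[2] > gene_bounds[1],
            similartaxis_sd > 0, maturity_patience >= 1,
            max_iterations >= 0, stagnation_patience >= 1)
  structure(list(population_size = as.integer(population_size),
                 n_superior = as.integer(n_superior),
                 n_temporary = as.integer(n_temporary),
                 subgroup_size = as.integer(subgroup_size),
                 gene_bounds = gene_bounds,
                 similartaxis_sd = similartaxis_sd,
                 maturity_patience = as.integer(maturity_patience),
                 max_iterations = as.integer(max_iterations),
                 stagnation_patience = as.integer(stagnation_patience),
                 seed = seed),
            class = "mea_config")
}

#' Flatten network parameters to a gene vector and back
#'
#' The gene order is fixed and lossless: all input-to-hidden weights
#' (column-major), all hidden-to-output weights (column-major), the hidden
#' thresholds, then the output thresholds — 105 + 19 = 124 genes for the
#' default 3-15-4 topology.
#'
#' @param net A `meann_net`.
#' @return `encode_params()` returns the numeric gene vector;
#'   `decode_params()` returns a `meann_net`.
#' @export
encode_params <- function(net) {
  stopifnot(inherits(net, "meann_net"))
  c(as.vector(net$w_ih), as.vector(net$w_ho), net$lam, net$eta)
}

#' @rdname encode_params
#' @param genes Numeric gene vector of length
#'   `sum(n_params(topology))`.
#' @param topology An [network_topology()] object.
#' @param mu,e0 Learning rate and stopping error of the decoded network.
#' @export
decode_params <- function(genes, topology = network_topology(), mu = 0.1,
                          e0 = 0.1) {
  n <- topology$n; h <- topology$h; m <- topology$m_out
  expected <- n * h + h * m + h + m
  if (length(genes) != expected) {
    stop("gene vector has length ", length(genes), "; topology requires ",
         expected)
  }
  structure(list(topology = topology,
                 w_ih = matrix(genes[seq_len(n * h)], n, h),
                 w_ho = matrix(genes[n * h + seq_len(h * m)], h, m),
                 lam = genes[n * h + h * m + seq_len(h)],
                 eta = genes[n * h + h * m + h + seq_len(m)],
                 mu = mu, e0 = e0,
                 stats = NULL, bin_size = NULL, min_bins = NULL),
            class = "meann_net")
}

#' Score an individual on a training set
#'
#' The MEA objective: the reciprocal of the mean squared error of the
#' decoded network on the training data, `F = N / sum((E - P)^2)` with `N`
#' the total number of training outputs (`4 * m` for the standard
#' network).  Residuals are computed on the logistic-mapped outputs
#' against one-hot targets.  When the residual sum falls below `1e-12`
#' the score is capped at `1e12`.
#'
#' @param genes Gene vector (or a `meann_net`).
#' @param dataset A `cnv_dataset`.
#' @param topology Topology used to decode `genes`.
#' @return A single finite score (larger is better).
#' @export
score_individual <- function(genes, dataset, topology = network_topology()) {
  score_fn <- make_score_fn(dataset, topology)
  if (inherits(genes, "meann_net")) genes <- encode_params(genes)
  score_fn(genes)
}

#' Build a fast scoring closure for a dataset
#'
#' Precomputes the feature matrix and one-hot targets so repeated
#' individual scoring inside the MEA avoids per-call setup.
#'
#' @inheritParams score_individual
#' @return A function `f(genes) -> score`.
#' @export
make_score_fn <- function(dataset, topology = network_topology()) {
  stopifnot(inherits(dataset, "cnv_dataset"), dataset$m > 0)
  X <- .dataset_features(dataset)
  Tt <- .one_hot(dataset$L, topology$m_out)
  n <- topology$n; h <- topology$h; m <- topology$m_out
  if (ncol(X) != n) stop("dataset features do not match topology inputs")
  N <- nrow(X) * m
  iw <- seq_len(n * h)
  ih <- n * h + seq_len(h * m)
  il <- n * h + h * m + seq_len(h)
  ie <- n * h + h * m + h + seq_len(m)
  function(genes) {
    w_ih <- matrix(genes[iw], n, h)
    w_ho <- matrix(genes[ih], h, m)
    H <- nn_activation(sweep(X %*% w_ih, 2, genes[il], "-"))
    probs <- plogis(sweep(H %*% w_ho, 2, genes[ie], "-"))
    ss <- sum((Tt - probs)^2)
    if (ss < 1e-12) 1e12 else N / ss
  }
}

## internal: new subgroup around a center gene vector (center kept first)
.subgroup_around <- function(center, score_fn, config,
                             center_score = NULL) {
  k <- config$subgroup_size
  ng <- length(center)
  genes <- matrix(rep(center, each = k), k, ng)
  noise <- matrix(rnorm((k - 1L) * ng, 0, config$similartaxis_sd),
                  k - 1L, ng)
  genes[-1L, ] <- pmin(pmax(genes[-1L, , drop = FALSE] + noise,
                            config$gene_bounds[1]), config$gene_bounds[2])
  scores <- c(if (is.null(center_score)) score_fn(genes[1L, ]) else
    center_score,
    apply(genes[-1L, , drop = FALSE], 1, score_fn))
  list(genes = genes, scores = scores, fresh = FALSE)
}

## internal: fully random subgroup within the bounds
.subgroup_random <- function(score_fn, n_genes, config) {
  k <- config$subgroup_size
  genes <- matrix(runif(k * n_genes, config$gene_bounds[1],
                        config$gene_bounds[2]), k, n_genes)
  list(genes = genes, scores = apply(genes, 1, score_fn), fresh = TRUE)
}

.subgroup_score <- function(sg) max(sg$scores)

.subgroup_best <- function(sg) sg$genes[which.max(sg$scores), ]

#' Initialize the MEA population
#'
#' Draws `population_size` individuals uniformly within the gene bounds
#' and scores them; the `n_superior` best become centers of the superior
#' subgroups and the next `n_temporary` the centers of the temporary
#' subgroups.  Each subgroup is filled to `subgroup_size` with Gaussian
#' perturbations of its center.
#'
#' @param score_fn Scoring closure from [make_score_fn()] (or any
#'   `f(genes) -> score`).
#' @param n_genes Gene vector length.
#' @param config An [mea_config()].
#' @return An `mea_state`: a list with `superior`, `temporary` (lists of
#'   subgroups), `best` (`genes`, `score`) and `bulletin` (per-subgroup
#'   scores).
#' @export
mea_init_population <- function(score_fn, n_genes, config = mea_config()) {
  pop <- matrix(runif(config$population_size * n_genes,
                      config$gene_bounds[1], config$gene_bounds[2]),
                config$population_size, n_genes)
  scores <- apply(pop, 1, score_fn)
  ord <- order(scores, decreasing = TRUE)
  n_sup <- config$n_superior
  n_tmp <- config$n_temporary
  superior <- lapply(seq_len(n_sup), function(i) {
    .subgroup_around(pop[ord[i], ], score_fn, config,
                     center_score = scores[ord[i]])
  })
  temporary <- lapply(seq_len(n_tmp), function(i) {
    .subgroup_around(pop[ord[n_sup + i], ], score_fn, config,
                     center_score = scores[ord[n_sup + i]])
  })
  state <- list(superior = superior, temporary = temporary)
  state$bulletin <- .mea_bulletin(state)
  best_idx <- which.max(state$bulletin$score)
  all_sg <- c(state$superior, state$temporary)
  state$best <- list(genes = .subgroup_best(all_sg[[best_idx]]),
                     score = max(state$bulletin$score))
  class(state) <- "mea_state"
  state
}

## internal: bulletin board of subgroup scores
.mea_bulletin <- function(state) {
  data.frame(
    subgroup = c(paste0("superior", seq_along(state$superior)),
                 paste0("temporary", seq_along(state$temporary))),
    kind = rep(c("superior", "temporary"),
               c(length(state$superior), length(state$temporary))),
    score = c(vapply(state$superior, .subgroup_score, numeric(1)),
              vapply(state$temporary, .subgroup_score, numeric(1))),
    stringsAsFactors = FALSE)
}

#' Mature one subgroup by similartaxis
#'
#' Repeatedly re-samples the subgroup's members as Gaussian perturbations
#' of its current best individual, keeping the best ever found (elitism),
#' until the best score has failed to improve for `maturity_patience`
#' consecutive rounds.
#'
#' @param subgroup A subgroup (list with `genes` matrix and `scores`).
#' @param score_fn Scoring closure.
#' @param config An [mea_config()].
#' @return The matured subgroup; its score is its best member's score.
#' @export
mea_similartaxis <- function(subgroup, score_fn, config = mea_config()) {
  best <- .subgroup_best(subgroup)
  best_score <- .subgroup_score(subgroup)
  stall <- 0L
  while (stall < config$maturity_patience) {
    cand <- .subgroup_around(best, score_fn, config,
                             center_score = best_score)
    if (.subgroup_score(cand) > best_score) {
      best <- .subgroup_best(cand)
      best_score <- .subgroup_score(cand)
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    subgroup <- cand
  }
  ## elitist: ensure the best-ever individual sits in the subgroup
  subgroup$genes[1L, ] <- best
  subgroup$scores[1L] <- best_score
  subgroup$fresh <- FALSE
  subgroup
}

#' Compete subgroups by dissimilation
#'
#' Temporary subgroups that score higher than the worst superior subgroup
#' replace it (the displaced superior subgroup is discarded); each vacated
#' temporary slot is re-seeded with a fresh random subgroup.  After
#' dissimilation no surviving (non-fresh) temporary subgroup out-scores
#' any superior subgroup.
#'
#' @param state An `mea_state` with matured subgroups.
#' @param score_fn Scoring closure.
#' @param n_genes Gene vector length.
#' @param config An [mea_config()].
#' @return The updated `mea_state` (bulletin and best refreshed).
#' @export
mea_dissimilation <- function(state, score_fn, n_genes,
                              config = mea_config()) {
  sup_scores <- vapply(state$superior, .subgroup_score, numeric(1))
  tmp_scores <- vapply(state$temporary, .subgroup_score, numeric(1))
  for (j in order(tmp_scores, decreasing = TRUE)) {
    if (state$temporary[[j]]$fresh) next
    worst <- which.min(sup_scores)
    if (tmp_scores[j] > sup_scores[worst]) {
      state$superior[[worst]] <- state$temporary[[j]]
      sup_scores[worst] <- tmp_scores[j]
      state$temporary[[j]] <- .subgroup_random(score_fn, n_genes, config)
      tmp_scores[j] <- .subgroup_score(state$temporary[[j]])
    } else {
      break  # processed in descending order: no later one can qualify
    }
  }
  state$bulletin <- .mea_bulletin(state)
  cand_best <- max(state$bulletin$score)
  if (is.null(state$best) || cand_best > state$best$score) {
    all_sg <- c(state$superior, state$temporary)
    state$best <- list(
      genes = .subgroup_best(all_sg[[which.max(state$bulletin$score)]]),
      score = cand_best)
  }
  state
}

#' Run the full MEA search on an arbitrary objective
#'
#' Engine shared by [mea_optimize()] and usable with any scoring function
#' (e.g. a 1-D toy objective).  Runs initialization, then repeats
#' similartaxis over every subgroup followed by dissimilation, for
#' `max_iterations` outer iterations or until the bulletin best stagnates
#' for `stagnation_patience` iterations.  The best individual ever seen is
#' returned; its score is non-decreasing across iterations.
#'
#' @param score_fn Function `f(genes) -> score` (higher is better).
#' @param n_genes Gene vector length.
#' @param config An [mea_config()]; its `seed` makes the run reproducible.
#' @return A list with `best` (`genes`, `score`), `trace` (one row per
#'   iteration: iteration, best score, subgroup scores) and the final
#'   `state`.
#' @export
mea_run <- function(score_fn, n_genes, config = mea_config()) {
  stopifnot(is.function(score_fn), n_genes >= 1)
  if (!is.null(config$seed)) set.seed(config$seed)
  state <- mea_init_population(score_fn, n_genes, config)
  trace <- list(data.frame(iteration = 0L, best_score = state$best$score,
                           t(setNames(state$bulletin$score,
                                      state$bulletin$subgroup))))
  stall <- 0L
  iter <- 0L
  while (iter < config$max_iterations && stall < config$stagnation_patience) {
    iter <- iter + 1L
    prev_best <- state$best$score
    state$superior <- lapply(state$superior, mea_similartaxis, score_fn,
                             config)
    state$temporary <- lapply(state$temporary, mea_similartaxis, score_fn,
                              config)
    state <- mea_dissimilation(state, score_fn, n_genes, config)
    stall <- if (state$best$score > prev_best) 0L else stall + 1L
    trace[[length(trace) + 1L]] <-
      data.frame(iteration = iter, best_score = state$best$score,
                 t(setNames(state$bulletin$score,
                            state$bulletin$subgroup)))
  }
  list(best = state$best, trace = do.call(rbind, trace), state = state)
}

#' Optimize network weights and thresholds with the MEA
#'
#' Searches the flat 124-gene space (for the default topology) for the
#' individual with the highest reciprocal-MSE score on the training data;
#' the result is used as the initial weights and thresholds for
#' backpropagation.
#'
#' @param dataset A `cnv_dataset`.
#' @param topology An [network_topology()].
#' @param config An [mea_config()].
#' @param trace_path Optional path; when given, the optimizer trace
#'   (iteration, subgroup scores, best score) is written there as TSV.
#' @return A list with `net` (the decoded best network), `best`
#'   (`genes`, `score`) and `trace`.
#' @export
mea_optimize <- function(dataset, topology = network_topology(),
                         config = mea_config(), trace_path = NULL) {
  score_fn <- make_score_fn(dataset, topology)
  n_genes <- sum(n_params(topology))
  res <- mea_run(score_fn, n_genes, config)
  if (!is.null(trace_path)) {
    write.table(res$trace, trace_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  list(net = decode_params(res$best$genes, topology), best = res$best,
       trace = res$trace)
}
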