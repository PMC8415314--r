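## caller: per-bin classification -> merged CNV calls -> benchmark metrics.

#' Classify every bin of a normalized feature table
#'
#' Runs the trained network on each bin and assigns the copy-number label
#' with the largest predicted probability.  Exact ties are broken toward
#' normal, then toward the lower label index.  Flagged bins (`NA` in any
#' feature) are labeled normal with `NA` probabilities.
#'
#' @param net A trained `meann_net`.
#' @param table Bin feature table normalized with the model's stored
#'   min-max statistics (values must lie in `[0, 1]`).
#' @return The table with columns `label`, `p_normal`, `p_gain`,
#'   `p_hemi_loss`, `p_homo_loss` appended.
#' @export
classify_bins <- function(net, table) {
  stopifnot(inherits(net, "meann_net"))
  feats <- as.matrix(table[, c("gc", "mq", "rd")])  # network order (g,q,r)
  ok <- stats::complete.cases(feats)
  vals <- feats[ok, , drop = FALSE]
  if (length(vals) > 0 && (min(vals) < -1e-9 || max(vals) > 1 + 1e-9)) {
    stop("feature values outside [0, 1]; normalize the table with the ",
         "model's min-max statistics before classification")
  }
  m <- nrow(table)
  probs <- matrix(NA_real_, m, 4,
                  dimnames = list(NULL, paste0("p_", cnv_states())))
  label <- integer(m)
  if (any(ok)) {
    p <- predict_proba(net, vals)
    if (!is.matrix(p)) p <- matrix(p, nrow = 1)
    probs[ok, ] <- p
    ## argmax with ties to the lowest index (normal is index 1)
    label[ok] <- max.col(p, ties.method = "first") - 1L
  }
  cbind(table[, c("chrom", "start", "end", "rd", "gc", "mq")], label = label,
        as.data.frame(probs))
}

#' Merge consecutive same-state bins into CNV calls
#'
#' Maximal runs of consecutive bins sharing the same non-normal label
#' become one call spanning the union of the member bins; a change of
#' state breaks a run.  Runs shorter than `min_bins` are dropped.
#'
#' @param classified A classified bin table from [classify_bins()] (or any
#'   table with `chrom`, `start`, `end`, `label`, and optionally the four
#'   probability columns).
#' @param min_bins Minimum run length (in bins) to report a call.
#' @return Data frame of calls: `chrom`, `start`, `end` (bp, 0-based
#'   half-open), `state`, `n_bins`, and the per-class mean probabilities
#'   when available.  Zero rows when everything is normal.
#' @export
merge_calls <- function(classified, min_bins = 1L) {
  stopifnot(min_bins >= 1L)
  lab <- classified$label
  prob_cols <- paste0("p_", cnv_states())
  has_probs <- all(prob_cols %in% names(classified))
  runs <- rle(lab)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  keep <- runs$values != 0L & runs$lengths >= min_bins
  rows <- lapply(which(keep), function(i) {
    idx <- seq.int(run_start[i], run_end[i])
    out <- data.frame(chrom = classified$chrom[idx[1]],
                      start = classified$start[idx[1]],
                      end = classified$end[idx[length(idx)]],
                      state = .label_to_state(runs$values[i]),
                      n_bins = length(idx),
                      stringsAsFactors = FALSE)
    if (has_probs) {
      out <- cbind(out, as.list(colMeans(
        classified[idx, prob_cols, drop = FALSE])))
    }
    out
  })
  if (length(rows) == 0) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), state = character(0),
                      n_bins = integer(0), stringsAsFactors = FALSE)
    if (has_probs) for (pc in prob_cols) out[[pc]] <- numeric(0)
    return(out)
  }
  do.call(rbind, rows)
}

#' Benchmark calls against ground truth
#'
#' A ground-truth event counts as accurately identified when some call of
#' the same state (unless `match_state = FALSE`) overlaps it reciprocally:
#' the overlap covers at least `min_reciprocal` of the truth event *and*
#' of the call.  Sensitivity is the fraction of truth events identified;
#' precision the fraction of calls that identify some truth event; the
#' F1-score their harmonic mean.  Boundary bias is the mean, over matched
#' truth events and their best-overlapping call, of
#' `(|start_call - start_truth| + |end_call - end_truth|) / 2` in bp.
#'
#' @param calls Call table from [merge_calls()].
#' @param truth Ground-truth event table (`start_bin`, `end_bin`, `class`,
#'   0-based half-open bin indices).
#' @param bin_size Bin width in bp used to convert truth to bp.
#' @param min_reciprocal Reciprocal-overlap fraction required for a match.
#' @param match_state If `FALSE`, overlap alone (ignoring the state)
#'   qualifies as a match.
#' @return An object of class `cnv_eval`: a list with `sensitivity`,
#'   `precision`, `f1`, `boundary_bias` (bp; `NA` with no matches),
#'   `n_truth`, `n_calls`, and `per_class` detected/total counts.
#'   Sensitivity is `NA` when the truth set is empty, precision when the
#'   call set is empty.
#' @export
evaluate_calls <- function(calls, truth, bin_size, min_reciprocal = 0.5,
                           match_state = TRUE) {
  t_start <- truth$start_bin * bin_size
  t_end <- truth$end_bin * bin_size
  n_truth <- nrow(truth)
  n_calls <- nrow(calls)

  truth_hit <- logical(n_truth)
  call_hit <- logical(n_calls)
  bias <- rep(NA_real_, n_truth)
  if (n_truth > 0 && n_calls > 0) {
    tr <- IRanges::IRanges(start = t_start + 1L, end = t_end)
    cr <- IRanges::IRanges(start = calls$start + 1L, end = calls$end)
    ov <- IRanges::findOverlaps(tr, cr)
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    w <- IRanges::width(IRanges::pintersect(tr[qh], cr[sh]))
    good <- w >= min_reciprocal * IRanges::width(tr)[qh] &
      w >= min_reciprocal * IRanges::width(cr)[sh]
    if (match_state) {
      good <- good & truth$class[qh] == calls$state[sh]
    }
    truth_hit[unique(qh[good])] <- TRUE
    call_hit[unique(sh[good])] <- TRUE
    for (i in which(truth_hit)) {
      cand <- sh[good & qh == i]
      best <- cand[which.max(w[good & qh == i])]
      bias[i] <- (abs(calls$start[best] - t_start[i]) +
                    abs(calls$end[best] - t_end[i])) / 2
    }
  }
  sensitivity <- if (n_truth == 0) NA_real_ else sum(truth_hit) / n_truth
  precision <- if (n_calls == 0) NA_real_ else sum(call_hit) / n_calls
  f1 <- if (is.na(sensitivity) || is.na(precision)) {
    NA_real_
  } else if (sensitivity + precision > 0) {
    2 * sensitivity * precision / (sensitivity + precision)
  } else {
    0
  }
  per_class <- do.call(rbind, lapply(cnv_states()[-1], function(st) {
    in_class <- truth$class == st
    data.frame(class = st, total = sum(in_class),
               detected = sum(truth_hit[in_class]),
               stringsAsFactors = FALSE)
  }))
  structure(list(sensitivity = sensitivity, precision = precision, f1 = f1,
                 boundary_bias = if (any(truth_hit))
                   mean(bias[truth_hit]) else NA_real_,
                 n_truth = n_truth, n_calls = n_calls,
                 per_class = per_class),
            class = "cnv_eval")
}

#' @export
print.cnv_eval <- function(x, ...) {
  cat(sprintf("CNV evaluation: %d truth events, %d calls\n", x$n_truth,
              x$n_calls))
  cat(sprintf("  sensitivity   %.4f\n  precision     %.4f\n  F1-score      %.4f\n",
              x$sensitivity, x$precision, x$f1))
  cat(sprintf("  boundary bias %.1f bp\n", x$boundary_bias))
  for (i in seq_len(nrow(x$per_class))) {
    cat(sprintf("  %-10s %d / %d detected\n", x$per_class$class[i],
                x$per_class$detected[i], x$per_class$total[i]))
  }
  invisible(x)
}

#' Write / read a BED-like call table
#'
#' Tab-separated with header `chrom start end state n_bins p_normal p_gain
#' p_hemi_loss p_homo_loss` (coordinates 0-based half-open).
#'
#' @param calls Call table.
#' @param path File path.
#' @return `read_calls()` returns the data frame.
#' @export
write_calls <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  t <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "state", "n_bins")
  if (!all(need %in% names(t))) {
    stop("call table must have columns: ", paste(need, collapse = ", "))
  }
  t
}
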