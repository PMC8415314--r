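## features: alignments + reference -> per-bin (RD, GC, MQ) feature table,
## min-max normalization, training-set assembly.

#' Partition a chromosome into fixed-size bins
#'
#' Consecutive, non-overlapping bins covering `[0, chrom_length)`; the last
#' bin may be shorter.  Coordinates are 0-based half-open.
#'
#' @param chrom_length Chromosome length in bp.
#' @param bin_size Bin width in bp.
#' @return Data frame with columns `start`, `end`.
#' @export
#' @examples
#' bin_genome(2500, 1000)
bin_genome <- function(chrom_length, bin_size) {
  stopifnot(chrom_length > 0, bin_size > 0)
  start <- seq.int(0L, chrom_length - 1L, by = bin_size)
  data.frame(start = start, end = pmin(start + bin_size, chrom_length))
}

#' Compute per-bin read-depth, GC and mapping-quality features
#'
#' Divides each reference contig into fixed-size bins and computes, per
#' bin: `rd`, the number of reads whose leftmost aligned base falls in the
#' bin, scaled to reads per kb of bin (so a 1000-bp bin reports the count
#' directly); `gc`, the G+C fraction among non-N reference bases; and
#' `mq`, the mean MAPQ of the reads assigned to the bin.  Unmapped,
#' secondary, supplementary and duplicate-flagged alignments are excluded.
#' Bins with no reads get `mq = NA` (flagged; they are dropped from
#' training and calling), and bins whose reference sequence is more than
#' `max_n_frac` N get `gc = NA`.
#'
#' @param alignment Path to a SAM or BAM file.  SAM input is converted on
#'   the fly with [Rsamtools::asBam()].
#' @param reference Path to the matching reference FASTA.
#' @param bin_size Bin width in bp (default 1000).
#' @param max_n_frac Maximum tolerated fraction of N bases in a bin.
#' @return Data frame with columns `chrom`, `start`, `end`, `rd`, `gc`,
#'   `mq` (one row per bin, all contigs concatenated).
#' @export
compute_bin_features <- function(alignment, reference, bin_size = 1000L,
                                 max_n_frac = 0.5) {
  stopifnot(file.exists(alignment), file.exists(reference))
  ref <- Biostrings::readDNAStringSet(reference)
  names(ref) <- sub("\\s.*$", "", names(ref))

  if (grepl("\\.sam$", alignment, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(alignment,
                            destination = tempfile(fileext = ""),
                            overwrite = TRUE, indexDestination = FALSE)
  } else {
    bam <- alignment
  }
  targets <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  missing <- setdiff(names(targets), names(ref))
  if (length(missing) > 0) {
    stop("contig(s) in alignment header absent from reference FASTA: ",
         paste(missing, collapse = ", "))
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags,
                                   what = c("rname", "pos", "mapq"))
  aln <- Rsamtools::scanBam(bam, param = param)[[1]]

  per_contig <- lapply(names(targets), function(ctg) {
    len <- length(ref[[ctg]])
    bins <- bin_genome(len, bin_size)
    n_bins <- nrow(bins)

    sel <- !is.na(aln$pos) & as.character(aln$rname) == ctg
    bin_idx <- (aln$pos[sel] - 1L) %/% bin_size + 1L   # pos is 1-based
    counts <- tabulate(bin_idx, nbins = n_bins)
    mq_sum <- numeric(n_bins)
    if (any(sel)) {
      sums <- rowsum(as.numeric(aln$mapq[sel]), group = bin_idx)
      mq_sum[as.integer(rownames(sums))] <- sums[, 1]
    }
    mq <- ifelse(counts > 0, mq_sum / counts, NA_real_)

    views <- Biostrings::Views(ref[[ctg]], start = bins$start + 1L,
                               end = bins$end)
    freq <- Biostrings::letterFrequency(views, letters = c("G", "C", "N"))
    width <- bins$end - bins$start
    informative <- width - freq[, "N"]
    gc <- ifelse(informative > 0, (freq[, "G"] + freq[, "C"]) / informative,
                 NA_real_)
    gc[freq[, "N"] / width > max_n_frac] <- NA_real_

    data.frame(chrom = ctg, start = bins$start, end = bins$end,
               rd = counts / (bin_size / 1000), gc = gc, mq = mq,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, per_contig)
}

#' Fit global min-max normalization statistics
#'
#' Per-feature minimum and maximum taken over all bins of all supplied
#' feature tables (not per table), ignoring flagged (`NA`) bins.
#'
#' @param tables A bin feature table or a list of them.
#' @return An object of class `minmax_stats`: a list with elements `rd`,
#'   `gc`, `mq`, each `c(min, max)`.
#' @export
fit_minmax <- function(tables) {
  if (is.data.frame(tables)) tables <- list(tables)
  stopifnot(length(tables) > 0)
  one <- function(col) {
    v <- unlist(lapply(tables, function(t) t[[col]]), use.names = FALSE)
    v <- v[is.finite(v)]
    if (length(v) == 0) stop("no finite values for feature '", col, "'")
    c(min(v), max(v))
  }
  structure(list(rd = one("rd"), gc = one("gc"), mq = one("mq")),
            class = "minmax_stats")
}

#' Apply min-max normalization
#'
#' Maps each feature to `(x - min) / (max - min)` with the fitted global
#' extrema, clamping to `[0, 1]` when a new table exceeds the training
#' range.  A constant feature (`max == min`) maps to 0.
#'
#' @param table Bin feature table.
#' @param stats A `minmax_stats` object from [fit_minmax()].
#' @return The table with `rd`, `gc`, `mq` normalized; `NA`s are preserved.
#' @export
apply_minmax <- function(table, stats) {
  stopifnot(inherits(stats, "minmax_stats"))
  for (col in c("rd", "gc", "mq")) {
    rng <- stats[[col]]
    if (rng[2] > rng[1]) {
      table[[col]] <- pmin(pmax((table[[col]] - rng[1]) / (rng[2] - rng[1]),
                                0), 1)
    } else {
      table[[col]] <- ifelse(is.na(table[[col]]), NA_real_, 0)
    }
  }
  table
}

#' Assemble a labeled training set
#'
#' Pools one or more labeled feature tables into the training quadruple
#' `(g, q, r, L)`: normalized column vectors of GC, MQ and RD plus the
#' per-bin class label (0 = normal, 1 = gain, 2 = hemi_loss,
#' 3 = homo_loss).  Flagged bins (`NA` in any feature) are dropped.
#'
#' @param tables A labeled bin feature table (with a `label` column) or a
#'   list of them.
#' @param stats Optional pre-fitted [fit_minmax()] statistics; fitted from
#'   `tables` when `NULL`.
#' @param balance If `TRUE`, downsample the majority class to the size of
#'   the largest remaining class (off by default).
#' @param seed Optional seed for the balancing subsample.
#' @return An object of class `cnv_dataset`: a list with `m` (rows), `g`,
#'   `q`, `r`, `L` and the `stats` used for normalization.
#' @export
assemble_training_set <- function(tables, stats = NULL, balance = FALSE,
                                  seed = NULL) {
  if (is.data.frame(tables)) tables <- list(tables)
  for (t in tables) {
    if (!"label" %in% names(t)) stop("feature table has no 'label' column")
  }
  if (is.null(stats)) stats <- fit_minmax(tables)
  pooled <- do.call(rbind, lapply(tables, function(t) {
    apply_minmax(t[c("rd", "gc", "mq", "label")], stats)
  }))
  keep <- stats::complete.cases(pooled[c("rd", "gc", "mq")])
  pooled <- pooled[keep, , drop = FALSE]
  if (!all(pooled$label %in% 0:3)) {
    bad <- setdiff(unique(pooled$label), 0:3)
    stop("labels outside {0, 1, 2, 3}: ", paste(bad, collapse = ", "))
  }
  if (balance) {
    if (!is.null(seed)) set.seed(seed)
    counts <- table(factor(pooled$label, levels = 0:3))
    majority <- names(counts)[which.max(counts)]
    cap <- max(counts[names(counts) != majority])
    if (cap > 0 && counts[majority] > cap) {
      idx_maj <- which(pooled$label == as.integer(majority))
      drop_n <- length(idx_maj) - cap
      pooled <- pooled[-sample(idx_maj, drop_n), , drop = FALSE]
    }
  }
  structure(list(m = nrow(pooled), g = pooled$gc, q = pooled$mq,
                 r = pooled$rd, L = as.integer(pooled$label), stats = stats),
            class = "cnv_dataset")
}

## internal: feature matrix (columns g, q, r -- the network input order)
.dataset_features <- function(dataset) {
  cbind(g = dataset$g, q = dataset$q, r = dataset$r)
}

#' Write / read a bin feature table as TSV
#'
#' Tab-separated with header `chrom start end rd gc mq [label]`;
#' coordinates 0-based half-open.
#'
#' @param table Bin feature table.
#' @param path File path.
#' @return `read_feature_table()` returns the data frame;
#'   `write_feature_table()` returns `path` invisibly.
#' @export
write_feature_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  t <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "rd", "gc", "mq")
  if (!all(need %in% names(t))) {
    stop("feature table must have columns: ", paste(need, collapse = ", "))
  }
  t
}

#' Write / read a ground-truth event table as TSV
#'
#' Columns `start_bin`, `end_bin` (0-based half-open bin indices) and
#' `class`.
#'
#' @param truth Ground-truth data frame.
#' @param path File path.
#' @return `read_truth()` returns the data frame.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  t <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("start_bin", "end_bin", "class")
  if (!all(need %in% names(t))) {
    stop("truth table must have columns: ", paste(need, collapse = ", "))
  }
  t
}
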