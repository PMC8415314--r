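## simdata: feature-level simulator of tumor read-depth profiles with
## planted CNVs, plus tiny SAM/FASTA fixture generation.

#' Simulation configuration
#'
#' Parameters of the per-bin feature simulator.  The simulator emulates, at
#' the bin-feature level, a tumor sample sequenced at a given coverage and
#' tumor purity: a baseline read-depth (RD) track with Gaussian noise,
#' per-bin GC-content, and per-bin mean mapping quality (MQ), with
#' non-overlapping CNV events planted on top.
#'
#' Inside an event the RD mean is scaled by the two-genome mixture
#' multiplier for the event's copy number at tumor purity `p`:
#' `1 + p/2` for gain (3 copies), `1 - p/2` for hemi_loss (1 copy) and
#' `1 - p` for homo_loss (0 copies).  RD noise is Gaussian with standard
#' deviation `rd_noise_sd * baseline * sqrt(multiplier)`, i.e. the variance
#' scales with the local copy number as read-count noise does.  MQ is
#' depressed by `mq_drop_in_cnv` inside events (CNVs preferentially arise
#' in repeat-rich, poorly mappable sequence); GC is drawn independently of
#' class, so a classifier must learn to ignore it unless `gc_bias` couples
#' it to RD.
#'
#' @param n_bins Number of genome bins to simulate.
#' @param bin_size Bin width in bp (default 1000).
#' @param tumor_purity Fraction of tumor cells in the sample, in `[0, 1]`.
#' @param coverage_depth Mean sequencing coverage (e.g. 4, 6); baseline RD
#'   per bin is `coverage_depth * bin_size / read_length` reads.
#' @param n_events_per_class Number of planted events for each of the three
#'   CNV classes (gain, hemi_loss, homo_loss).
#' @param event_length_bins Integer range `c(min, max)` of event lengths in
#'   bins.
#' @param rd_noise_sd RD noise as a fraction of the baseline RD
#'   (coefficient of variation at copy-neutral bins).
#' @param gc_range Interval GC-content is drawn from, uniformly per bin.
#' @param mq_baseline Mean mapping quality (Phred scale) outside events.
#' @param mq_drop_in_cnv MQ decrease inside planted events.
#' @param mq_noise_sd Gaussian sd of per-bin MQ noise.
#' @param gc_bias Optional linear coupling of RD to GC: the RD mean is
#'   multiplied by `1 + gc_bias * (gc - mean(gc_range))`.  Default 0 (off).
#' @param read_length Read length in bp used to convert coverage to reads
#'   per bin (and by [write_sam_fixture()]).
#' @param chrom Chromosome name of the simulated contig.
#' @param seed Optional integer seed; the same seed reproduces the profile
#'   bitwise.
#' @return An object of class `sim_config` (a list of the above).
#' @seealso [simulate_profile()], [simulate_study()]
#' @export
sim_config <- function(n_bins = 5000L, bin_size = 1000L, tumor_purity = 0.3,
                       coverage_depth = 6, n_events_per_class = 15L,
                       event_length_bins = c(8L, 15L), rd_noise_sd = 0.05,
                       gc_range = c(0.3, 0.6), mq_baseline = 60,
                       mq_drop_in_cnv = 10, mq_noise_sd = 2, gc_bias = 0,
                       read_length = 100L, chrom = "chrS", seed = NULL) {
  n_bins <- as.integer(n_bins)
  bin_size <- as.integer(bin_size)
  stopifnot(n_bins > 0L, bin_size > 0L, read_length > 0L,
            tumor_purity >= 0, tumor_purity <= 1,
            coverage_depth > 0, n_events_per_class >= 0L,
            length(event_length_bins) == 2L,
            event_length_bins[1] >= 1L,
            event_length_bins[2] >= event_length_bins[1],
            rd_noise_sd >= 0, mq_noise_sd >= 0,
            length(gc_range) == 2L, gc_range[1] >= 0, gc_range[2] <= 1,
            gc_range[2] >= gc_range[1])
  structure(list(n_bins = n_bins, bin_size = bin_size,
                 tumor_purity = tumor_purity, coverage_depth = coverage_depth,
                 n_events_per_class = as.integer(n_events_per_class),
                 event_length_bins = as.integer(event_length_bins),
                 rd_noise_sd = rd_noise_sd, gc_range = gc_range,
                 mq_baseline = mq_baseline, mq_drop_in_cnv = mq_drop_in_cnv,
                 mq_noise_sd = mq_noise_sd, gc_bias = gc_bias,
                 read_length = as.integer(read_length), chrom = chrom,
                 seed = seed),
            class = "sim_config")
}

## internal: RD multiplier for each state at purity p (two-genome mixture)
.state_multiplier <- function(state, purity) {
  switch(state,
         normal    = 1,
         gain      = 1 + purity / 2,
         hemi_loss = 1 - purity / 2,
         homo_loss = 1 - purity,
         stop("unknown state: ", state))
}

## internal: place non-overlapping events (>= 1 normal bin between events)
.place_events <- function(n_bins, n_per_class, len_range, max_tries = 1000L) {
  classes <- rep(cnv_states()[-1], each = n_per_class)
  if (length(classes) == 0L) {
    return(data.frame(start_bin = integer(0), end_bin = integer(0),
                      class = character(0), stringsAsFactors = FALSE))
  }
  occupied <- logical(n_bins)  # TRUE = event bin or buffer bin
  starts <- ends <- integer(length(classes))
  for (i in seq_along(classes)) {
    len <- if (len_range[1] == len_range[2]) len_range[1] else
      sample(seq(len_range[1], len_range[2]), 1L)
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      s <- sample.int(n_bins - len + 1L, 1L) - 1L   # 0-based start bin
      span <- seq.int(s + 1L, s + len)              # 1-based indices
      buffer <- seq.int(max(1L, s), min(n_bins, s + len + 1L))
      if (!any(occupied[buffer])) {
        occupied[span] <- TRUE
        starts[i] <- s
        ends[i] <- s + len
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place ", length(classes), " non-overlapping events of ",
           "length ", len_range[1], "-", len_range[2], " bins in ", n_bins,
           " bins; reduce n_events_per_class or event length")
    }
  }
  out <- data.frame(start_bin = starts, end_bin = ends, class = classes,
                    stringsAsFactors = FALSE)
  out <- out[order(out$start_bin), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a per-bin feature profile with planted CNVs
#'
#' Generates one synthetic sample: a bin feature table with columns
#' `chrom`, `start`, `end` (bp, 0-based half-open), `rd`, `gc`, `mq` and
#' `label`, plus the ground-truth event table.  Events are sorted,
#' non-overlapping (with at least one normal bin between consecutive
#' events) and use 0-based half-open *bin* coordinates
#' `[start_bin, end_bin)`.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `profile` (data.frame of bin features with
#'   truth labels) and `truth` (data.frame with `start_bin`, `end_bin`,
#'   `class`).
#' @export
#' @examples
#' sim <- simulate_profile(sim_config(n_bins = 500, n_events_per_class = 2,
#'                                    seed = 1))
#' head(sim$profile)
#' sim$truth
simulate_profile <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_bins
  truth <- .place_events(n, config$n_events_per_class,
                         config$event_length_bins)
  label <- integer(n)
  for (i in seq_len(nrow(truth))) {
    idx <- seq.int(truth$start_bin[i] + 1L, truth$end_bin[i])
    label[idx] <- .state_to_label(truth$class[i])
  }
  mult <- vapply(cnv_states()[label + 1L], .state_multiplier, numeric(1),
                 purity = config$tumor_purity, USE.NAMES = FALSE)

  gc <- runif(n, config$gc_range[1], config$gc_range[2])
  baseline <- config$coverage_depth * config$bin_size / config$read_length
  rd_mean <- baseline * mult
  if (config$gc_bias != 0) {
    rd_mean <- rd_mean * (1 + config$gc_bias * (gc - mean(config$gc_range)))
  }
  rd <- rnorm(n, rd_mean, config$rd_noise_sd * baseline * sqrt(mult))
  rd <- pmax(rd, 0) / (config$bin_size / 1000)  # reads per kb of bin

  mq <- config$mq_baseline - config$mq_drop_in_cnv * (label != 0L) +
    rnorm(n, 0, config$mq_noise_sd)
  mq <- pmax(mq, 0)

  start <- (seq_len(n) - 1L) * config$bin_size
  profile <- data.frame(chrom = config$chrom, start = start,
                        end = start + config$bin_size,
                        rd = rd, gc = gc, mq = mq, label = label,
                        stringsAsFactors = FALSE)
  list(profile = profile, truth = truth)
}

#' Simulate a multi-configuration study
#'
#' Generates `length(purities) * length(coverages) * replicates` samples,
#' each tagged with its purity/coverage configuration and replicate index
#' (e.g. purities 0.2/0.3/0.4 x coverages 4x/6x x 50 replicates = 300
#' samples).
#'
#' @param purities Numeric vector of tumor purities.
#' @param coverages Numeric vector of coverage depths.
#' @param replicates Number of replicate samples per configuration.
#' @param base_config [sim_config()] supplying all other parameters; its
#'   `seed` (if any) seeds the whole study.
#' @return A list of samples; each element carries `profile`, `truth`,
#'   `purity`, `coverage` and `replicate`.
#' @export
simulate_study <- function(purities, coverages, replicates,
                           base_config = sim_config()) {
  stopifnot(length(purities) > 0, length(coverages) > 0, replicates >= 0)
  if (!is.null(base_config$seed)) set.seed(base_config$seed)
  out <- vector("list", length(purities) * length(coverages) * replicates)
  k <- 0L
  for (p in purities) {
    for (cov in coverages) {
      cfg <- base_config
      cfg$tumor_purity <- p
      cfg$coverage_depth <- cov
      cfg$seed <- NULL  # consume the study-level RNG stream
      for (r in seq_len(replicates)) {
        k <- k + 1L
        sim <- simulate_profile(cfg)
        sim$purity <- p
        sim$coverage <- cov
        sim$replicate <- r
        out[[k]] <- sim
      }
    }
  }
  out
}

#' Ground-truth labels for every bin
#'
#' Expands an event table into the per-bin label vector (0 = normal,
#' 1 = gain, 2 = hemi_loss, 3 = homo_loss).
#'
#' @param truth Data frame with `start_bin`, `end_bin` (0-based half-open)
#'   and `class`.
#' @param n_bins Total number of bins.
#' @return Integer vector of length `n_bins`.
#' @export
truth_labels <- function(truth, n_bins) {
  label <- integer(n_bins)
  for (i in seq_len(nrow(truth))) {
    label[seq.int(truth$start_bin[i] + 1L, truth$end_bin[i])] <-
      .state_to_label(truth$class[i])
  }
  label
}

#' Write a SAM/FASTA fixture reproducing a simulated profile
#'
#' Materialises a profile as a single-chromosome reference FASTA and a
#' coordinate-sorted plain-text SAM whose per-bin read-start counts and
#' MAPQ values reproduce the profile's RD and MQ to within rounding, so
#' that [compute_bin_features()] recovers the planted features.  Reads are
#' single-end, `read_length` bp, and lie fully within their bin.  Reference
#' bases are drawn per bin with `P(G or C)` equal to the bin's `gc` value.
#'
#' @param profile Bin feature table from [simulate_profile()].
#' @param fasta_path,sam_path Output paths.
#' @param read_length Read length in bp; must not exceed the bin size.
#' @param seed Optional seed for base/read-position sampling.
#' @return Invisibly, a list with the two paths.
#' @export
write_sam_fixture <- function(profile, fasta_path, sam_path,
                              read_length = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bin_size <- profile$end[1] - profile$start[1]
  if (read_length > bin_size) {
    stop("read_length (", read_length, ") exceeds bin size (", bin_size, ")")
  }
  chrom <- profile$chrom[1]
  chrom_len <- max(profile$end)

  ## reference: per-bin base sampling honouring the bin's GC fraction
  seq_chunks <- vapply(seq_len(nrow(profile)), function(i) {
    w <- profile$end[i] - profile$start[i]
    gc <- profile$gc[i]
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(names(p), w, replace = TRUE, prob = p), collapse = "")
  }, character(1))
  ref <- Biostrings::DNAStringSet(paste(seq_chunks, collapse = ""))
  names(ref) <- chrom
  Biostrings::writeXStringSet(ref, fasta_path)
  refseq <- ref[[1]]

  ## reads: round(rd * bin_kb) starts per bin, uniform, fully inside the bin
  lines <- c("@HD\tVN:1.6\tSO:coordinate",
             paste0("@SQ\tSN:", chrom, "\tLN:", chrom_len))
  read_id <- 0L
  for (i in seq_len(nrow(profile))) {
    n_reads <- as.integer(round(profile$rd[i] * (bin_size / 1000)))
    if (n_reads <= 0L) next
    lo <- profile$start[i] + 1L                       # 1-based leftmost
    hi <- profile$end[i] - read_length + 1L
    pos <- sort(lo + sample.int(hi - lo + 1L, n_reads, replace = TRUE) - 1L)
    mapq <- max(0L, min(254L, as.integer(round(profile$mq[i]))))
    seqs <- as.character(Biostrings::extractAt(
      refseq, IRanges::IRanges(start = pos, width = read_length)))
    recs <- paste(paste0("r", read_id + seq_len(n_reads)), 0L, chrom, pos,
                  mapq, paste0(read_length, "M"), "*", 0L, 0L, seqs, "*",
                  sep = "\t")
    read_id <- read_id + n_reads
    lines <- c(lines, recs)
  }
  writeLines(lines, sam_path)
  invisible(list(fasta = fasta_path, sam = sam_path))
}
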