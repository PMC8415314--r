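make_table <- function(labels, bin_size = 1000, chrom = "chrS") {
  n <- length(labels)
  data.frame(chrom = chrom, start = (0:(n - 1)) * bin_size,
             end = (1:n) * bin_size, rd = 0.5, gc = 0.5, mq = 0.5,
             label = as.integer(labels), stringsAsFactors = FALSE)
}

test_that("per-bin classification takes the argmax with ties broken toward normal", {
  topo <- network_topology()
  tab <- make_table(rep(0, 3))[, 1:6]
  # zero network: all four probabilities exactly 0.5 -> tie -> normal
  cls <- classify_bins(zero_net(topo), tab)
  expect_equal(cls$label, rep(0L, 3))
  expect_equal(cls$p_gain, rep(0.5, 3))

  # a biased output threshold moves the argmax to gain
  net <- zero_net(topo)
  net$eta <- c(0, -1, 0, 0)
  expect_equal(unique(classify_bins(net, tab)$label), 1L)

  # flagged bins keep the normal label with missing probabilities
  tab$mq[2] <- NA
  cls <- classify_bins(net, tab)
  expect_equal(cls$label[2], 0L)
  expect_true(is.na(cls$p_normal[2]))
  expect_equal(cls$label[-2], c(1L, 1L))

  # unnormalized input is rejected
  bad <- make_table(rep(0, 2))[, 1:6]
  bad$rd <- c(10, 20)
  expect_error(classify_bins(net, bad), "normalize")
})

test_that("merging produces one call per maximal same-state run", {
  cls <- make_table(c(0, 1, 1, 0, 2, 2, 2, 0))
  calls <- merge_calls(cls)
  expect_equal(nrow(calls), 2)
  expect_equal(calls$start, c(1000, 4000))
  expect_equal(calls$end, c(3000, 7000))
  expect_equal(calls$state, c("gain", "hemi_loss"))
  expect_equal(calls$n_bins, c(2, 3))

  # all-normal input yields an empty, well-formed table
  empty <- merge_calls(make_table(rep(0, 6)))
  expect_equal(nrow(empty), 0)
  expect_true(all(c("chrom", "start", "end", "state") %in% names(empty)))

  # a state change breaks the run even between adjacent CNV bins
  two <- merge_calls(make_table(c(1, 1, 2, 2)))
  expect_equal(two$state, c("gain", "hemi_loss"))
  expect_equal(two$end[1], two$start[2])

  # min_bins filters short runs
  filt <- merge_calls(make_table(c(1, 0, 2, 2, 0, 3, 3, 3)), min_bins = 2)
  expect_equal(filt$state, c("hemi_loss", "homo_loss"))
  expect_equal(nrow(merge_calls(make_table(c(1, 0, 2)), min_bins = 2)), 0)
})

test_that("merged calls are disjoint, sorted, and cover every surviving CNV bin", {
  set.seed(8)
  for (i in 1:5) {
    labels <- sample(0:3, 60, replace = TRUE, prob = c(0.6, rep(0.4 / 3, 3)))
    calls <- merge_calls(make_table(labels), min_bins = 2)
    if (nrow(calls) > 1) {
      expect_true(all(diff(calls$start) > 0))
      expect_true(all(calls$start[-1] >= calls$end[-nrow(calls)]))
    }
    runs <- rle(labels)
    survived <- sum(runs$lengths[runs$values != 0 & runs$lengths >= 2])
    expect_equal(sum(calls$n_bins), survived)
  }
})

test_that("evaluation computes sensitivity, precision, F1 and boundary bias", {
  truth <- data.frame(start_bin = c(10, 40), end_bin = c(20, 50),
                      class = c("gain", "hemi_loss"))
  calls <- data.frame(chrom = "chrS",
                      start = c(10e3, 40e3, 70e3),
                      end = c(20e3, 50e3, 75e3),
                      state = c("gain", "hemi_loss", "homo_loss"),
                      n_bins = c(10, 10, 5), stringsAsFactors = FALSE)
  ev <- evaluate_calls(calls, truth, bin_size = 1000)
  expect_equal(ev$sensitivity, 1.0)
  expect_equal(ev$precision, 2 / 3)
  expect_equal(ev$f1, 0.8)
  expect_equal(ev$boundary_bias, 0)
  expect_equal(ev$per_class$detected, c(1, 1, 0))

  # both endpoints shifted one bin -> boundary bias of one bin size
  shifted <- calls[1:2, ]
  shifted$start <- shifted$start + 1000
  shifted$end <- shifted$end + 1000
  ev2 <- evaluate_calls(shifted, truth, bin_size = 1000)
  expect_equal(ev2$sensitivity, 1.0)
  expect_equal(ev2$boundary_bias, 1000)

  # state agreement is required unless match_state = FALSE
  wrong <- calls[1, ]; wrong$state <- "homo_loss"
  expect_equal(evaluate_calls(wrong, truth[1, ], 1000)$sensitivity, 0)
  expect_equal(evaluate_calls(wrong, truth[1, ], 1000,
                              match_state = FALSE)$sensitivity, 1)

  # a call overlapping less than half the event reciprocally is no match
  short <- data.frame(chrom = "chrS", start = 10e3, end = 13e3,
                      state = "gain", n_bins = 3)
  expect_equal(evaluate_calls(short, truth[1, ], 1000)$sensitivity, 0)

  # empty truth: sensitivity undefined; empty calls: precision undefined
  expect_true(is.na(evaluate_calls(calls, truth[0, ], 1000)$sensitivity))
  expect_true(is.na(evaluate_calls(calls[0, ], truth, 1000)$precision))
})

test_that("evaluation is invariant under a genome-wide coordinate shift", {
  truth <- data.frame(start_bin = c(5, 30), end_bin = c(12, 38),
                      class = c("gain", "homo_loss"))
  calls <- data.frame(chrom = "chrS", start = c(5e3, 31e3),
                      end = c(12e3, 38e3),
                      state = c("gain", "homo_loss"), n_bins = c(7, 7))
  ev <- evaluate_calls(calls, truth, bin_size = 1000)
  shift_bins <- 100
  truth2 <- transform(truth, start_bin = start_bin + shift_bins,
                      end_bin = end_bin + shift_bins)
  calls2 <- transform(calls, start = start + shift_bins * 1000,
                      end = end + shift_bins * 1000)
  ev2 <- evaluate_calls(calls2, truth2, bin_size = 1000)
  expect_equal(ev2$sensitivity, ev$sensitivity)
  expect_equal(ev2$precision, ev$precision)
  expect_equal(ev2$boundary_bias, ev$boundary_bias)
})

test_that("calls round-trip through the BED-like TSV", {
  calls <- data.frame(chrom = "chrS", start = 1000L, end = 4000L,
                      state = "gain", n_bins = 3L, p_normal = 0.1,
                      p_gain = 0.7, p_hemi_loss = 0.1, p_homo_loss = 0.1,
                      stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".tsv")
  write_calls(calls, path)
  expect_equal(read_calls(path), calls)
})
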