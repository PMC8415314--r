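test_that("encode/decode is a lossless round trip over 124 genes", {
  topo <- network_topology()
  net <- init_network(topo, seed = 2)
  genes <- encode_params(net)
  expect_length(genes, 124)
  back <- decode_params(genes, topo, mu = net$mu, e0 = net$e0)
  expect_equal(back$w_ih, net$w_ih)
  expect_equal(back$w_ho, net$w_ho)
  expect_equal(back$lam, net$lam)
  expect_equal(back$eta, net$eta)
  expect_identical(encode_params(back), genes)

  z <- decode_params(rep(0, 124), topo)
  expect_true(all(z$w_ih == 0) && all(z$eta == 0))
  expect_error(decode_params(rep(0, 100), topo), "length")
})

test_that("the score is the reciprocal mean squared error, capped for perfect fits", {
  topo <- network_topology()
  ds <- toy_dataset(5, seed = 11)
  # zero genes -> every probability 0.5, every one-hot residual 0.5^2:
  # sum = m*4*0.25, N = m*4, so the score is exactly 4
  expect_equal(score_individual(rep(0, 124), ds, topo), 4)

  # a (numerically) perfect fit hits the 1e12 cap: zero weights with
  # saturating output thresholds drive the probabilities to the one-hot
  # target of an all-normal single-row dataset
  one <- structure(list(m = 1L, g = 0.5, q = 0.5, r = 0.5, L = 0L,
                        stats = NULL), class = "cnv_dataset")
  genes <- rep(0, 124)
  genes[121:124] <- c(-100, 100, 100, 100)   # eta; raw = -eta
  expect_equal(score_individual(genes, one, topo), 1e12)
  set.seed(1)
  expect_lt(score_individual(runif(124, -1, 1), ds, topo), 1e12)
})

test_that("score equals 1/MSE from an independent forward-pass oracle", {
  topo <- network_topology()
  for (i in 1:10) {
    ds <- toy_dataset(m_per_class = 3, noise = 0.1, seed = 100 + i)
    genes <- runif(124, -1, 1)
    X <- cbind(ds$g, ds$q, ds$r)
    probs <- oracle_probs(genes, X, topo)
    E <- t(vapply(ds$L, .one_hot_test, numeric(4)))
    expected <- (nrow(X) * 4) / sum((E - probs)^2)
    expect_equal(score_individual(genes, ds, topo), expected,
                 tolerance = 1e-9)
  }
})

test_that("population initialization builds the 5+5 x 20 subgroup structure", {
  score_fn <- function(g) 1 / (1 + sum(g^2))
  cfg <- mea_config(seed = 1)
  set.seed(1)
  st <- mea_init_population(score_fn, 124, cfg)
  expect_length(st$superior, 5)
  expect_length(st$temporary, 5)
  expect_true(all(vapply(c(st$superior, st$temporary),
                         function(s) nrow(s$genes), integer(1)) == 20))
  expect_equal(nrow(st$bulletin), 10)
  # superior centers outscore temporary centers (selection by rank)
  sup_centers <- vapply(st$superior, function(s) s$scores[1], numeric(1))
  tmp_centers <- vapply(st$temporary, function(s) s$scores[1], numeric(1))
  expect_gte(min(sup_centers), max(tmp_centers))
})

test_that("similartaxis matures toward a known 1-D optimum", {
  x_star <- 0.37
  score_fn <- function(g) 1 / (1 + (g - x_star)^2)
  cfg <- mea_config(population_size = 40, n_superior = 2, n_temporary = 2,
                    subgroup_size = 10, similartaxis_sd = 0.05,
                    maturity_patience = 5, seed = 3)
  set.seed(3)
  sg <- list(genes = matrix(runif(10, -1, 1), 10, 1), fresh = FALSE)
  sg$scores <- apply(sg$genes, 1, score_fn)
  before <- max(sg$scores)
  mat <- mea_similartaxis(sg, score_fn, cfg)
  expect_gte(max(mat$scores), before)          # elitist, never loses ground
  expect_lt(abs(mat$genes[which.max(mat$scores), ] - x_star), 0.05)
})

test_that("dissimilation swaps a winning temporary subgroup and refills the slot", {
  score_fn <- function(g) sum(g)   # deterministic, monotone toy score
  cfg <- mea_config(population_size = 20, n_superior = 2, n_temporary = 2,
                    subgroup_size = 5, seed = 4)
  mk <- function(vals) {
    g <- matrix(vals, length(vals), 1)
    list(genes = g, scores = vals, fresh = FALSE)
  }
  st <- structure(list(superior = list(mk(c(0.9, 0.1)), mk(c(0.3, 0.1))),
                       temporary = list(mk(c(0.6, 0.2)), mk(c(0.05, 0.01))),
                       best = list(genes = 0.9, score = 0.9)),
                  class = "mea_state")
  set.seed(4)
  out <- mea_dissimilation(st, score_fn, 1, cfg)
  expect_length(out$superior, 2)
  expect_length(out$temporary, 2)
  # the 0.6-scoring temporary replaced the 0.3-scoring superior
  sup_scores <- vapply(out$superior, max_score <- function(s) max(s$scores),
                       numeric(1))
  expect_true(0.6 %in% sup_scores)
  expect_false(0.3 %in% sup_scores)
  expect_true(out$temporary[[1]]$fresh)
  # surviving (non-fresh) temporaries never outscore any superior
  surv <- Filter(function(s) !s$fresh, out$temporary)
  if (length(surv) > 0) {
    expect_gte(min(sup_scores),
               max(vapply(surv, function(s) max(s$scores), numeric(1))))
  }

  # when all temporaries score lower, the superior set is unchanged
  st2 <- structure(list(superior = list(mk(c(0.9, 0.1)), mk(c(0.3, 0.1))),
                        temporary = list(mk(c(0.2, 0.1)), mk(c(0.05, 0.01))),
                        best = list(genes = 0.9, score = 0.9)),
                   class = "mea_state")
  out2 <- mea_dissimilation(st2, score_fn, 1, cfg)
  expect_equal(vapply(out2$superior, function(s) max(s$scores), numeric(1)),
               c(0.9, 0.3))
  expect_false(any(vapply(out2$temporary, `[[`, logical(1), "fresh")))
})

test_that("the full MEA run is elitist, reproducible and structure-preserving", {
  x_star <- -0.25
  score_fn <- function(g) 1 / (1 + sum((g - x_star)^2))
  cfg <- mea_config(max_iterations = 10, stagnation_patience = 10, seed = 6)
  res <- mea_run(score_fn, 3, cfg)
  # best score never decreases across iterations
  expect_true(all(diff(res$trace$best_score) >= 0))
  # 10 subgroup columns present and finite in every iteration
  sg_cols <- grep("^(superior|temporary)", names(res$trace))
  expect_length(sg_cols, 10)
  expect_true(all(is.finite(as.matrix(res$trace[, sg_cols]))))
  expect_lt(max(abs(res$best$genes - x_star)), 0.05)
  # reproducible under the same seed
  res2 <- mea_run(score_fn, 3, cfg)
  expect_identical(res$best, res2$best)

  # zero iterations returns the best of the initial population
  res0 <- mea_run(score_fn, 3, mea_config(max_iterations = 0, seed = 8))
  expect_equal(nrow(res0$trace), 1)
  expect_equal(res0$best$score, max(res0$trace[1, sg_cols]))
})

test_that("MEA-optimized weights give a better starting point than random ones", {
  ds <- toy_dataset(15, noise = 0.05, seed = 17)
  topo <- network_topology()
  cfg <- mea_config(max_iterations = 3, seed = 17)
  opt <- mea_optimize(ds, topo, cfg)
  set.seed(17)
  rand_scores <- replicate(20, score_individual(runif(124, -1, 1), ds, topo))
  expect_gt(opt$best$score, max(rand_scores))
  expect_equal(score_individual(opt$net, ds, topo), opt$best$score)
})
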