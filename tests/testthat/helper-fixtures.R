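# Shared in-code fixtures: tiny networks, datasets, and an independent
# loop-based forward-pass oracle used to cross-check the vectorized
# implementation.

zero_net <- function(topology = network_topology()) {
  decode_params(rep(0, sum(n_params(topology))), topology)
}

# Four well-separated Gaussian clusters in normalized (g, q, r) space:
# CNV classes share a depressed MQ, the classes differ in RD, GC is
# uninformative -- the geometry the simulator produces after min-max
# scaling.
toy_dataset <- function(m_per_class = 30, noise = 0.03, seed = 1,
                        classes = 0:3) {
  set.seed(seed)
  centers <- rbind(normal    = c(0.5, 0.9, 0.55),
                   gain      = c(0.5, 0.3, 0.85),
                   hemi_loss = c(0.5, 0.3, 0.35),
                   homo_loss = c(0.5, 0.3, 0.10))
  L <- rep(classes, each = m_per_class)
  xyz <- centers[L + 1L, , drop = FALSE] +
    matrix(rnorm(3 * length(L), 0, noise), ncol = 3)
  xyz[, 1] <- runif(length(L))          # GC carries no class signal
  xyz <- pmin(pmax(xyz, 0), 1)
  structure(list(m = length(L), g = xyz[, 1], q = xyz[, 2], r = xyz[, 3],
                 L = as.integer(L), stats = NULL),
            class = "cnv_dataset")
}

# Independent forward pass: plain loops, no code shared with the package
# internals beyond the mathematical definition.
oracle_probs <- function(genes, X, topology) {
  n <- topology$n; h <- topology$h; m <- topology$m_out
  w_ih <- matrix(genes[1:(n * h)], n, h)
  w_ho <- matrix(genes[n * h + 1:(h * m)], h, m)
  lam <- genes[n * h + h * m + 1:h]
  eta <- genes[n * h + h * m + h + 1:m]
  out <- matrix(NA_real_, nrow(X), m)
  for (i in seq_len(nrow(X))) {
    H <- numeric(h)
    for (j in seq_len(h)) {
      H[j] <- tanh(sum(w_ih[, j] * X[i, ]) - lam[j])
    }
    for (k in seq_len(m)) {
      out[i, k] <- 1 / (1 + exp(-(sum(H * w_ho[, k]) - eta[k])))
    }
  }
  out
}

.one_hot_test <- function(label, k = 4) {
  v <- numeric(k)
  v[label + 1] <- 1
  v
}

# Squared error of a single example on the raw (linear) outputs.
raw_sq_error <- function(net, b, target) {
  sum((target - nn_forward(net, b)$raw)^2)
}
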