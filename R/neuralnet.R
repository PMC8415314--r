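## neuralnet: the 3-15-4 feedforward classifier.  Hidden activation is
## f(x) = 2/(1+exp(-2x)) - 1 (identically tanh); the output layer is
## linear during training and logistic-mapped to (0,1) probabilities at
## prediction time.  Trained by per-example backpropagation.

#' Network topology
#'
#' Three input neurons (the normalized GC, MQ and RD of a bin), four
#' output neurons (one per copy-number state), and `h = n + 3 m` hidden
#' neurons by default (15 for the standard 3-input, 4-output network).
#'
#' @param n_input Number of input neurons.
#' @param n_output Number of output neurons.
#' @param n_hidden Number of hidden neurons; defaults to
#'   `n_input + 3 * n_output`.
#' @return An object of class `nn_topology` with fields `n`, `h`, `m_out`.
#' @export
#' @examples
#' network_topology()  # 3-15-4
network_topology <- function(n_input = 3L, n_output = 4L, n_hidden = NULL) {
  n <- as.integer(n_input)
  m <- as.integer(n_output)
  h <- if (is.null(n_hidden)) n + 3L * m else as.integer(n_hidden)
  stopifnot(n > 0L, m > 0L, h > 0L)
  structure(list(n = n, h = h, m_out = m), class = "nn_topology")
}

#' Number of free parameters of a topology
#'
#' @param topology An [network_topology()] object.
#' @return Named vector with `weights` (`n*h + h*m`) and `thresholds`
#'   (`h + m`) counts.
#' @export
n_params <- function(topology) {
  stopifnot(inherits(topology, "nn_topology"))
  c(weights = topology$n * topology$h + topology$h * topology$m_out,
    thresholds = topology$h + topology$m_out)
}

#' Initialize a network with random parameters
#'
#' All weights and thresholds are drawn uniformly in `[-1, 1]`.  In the
#' full pipeline these are overwritten by the mind evolutionary algorithm
#' before backpropagation.
#'
#' @param topology An [network_topology()] object.
#' @param seed Optional integer seed.
#' @param mu Learning rate (default 0.1).
#' @param e0 Maximum allowable per-output absolute error for the training
#'   stopping rule (default 0.1).
#' @return An object of class `meann_net`: a list with `topology`, `w_ih`
#'   (n x h input-to-hidden weights), `w_ho` (h x m hidden-to-output
#'   weights), `lam` (h hidden thresholds), `eta` (m output thresholds),
#'   `mu` and `e0`.
#' @export
init_network <- function(topology = network_topology(), seed = NULL,
                         mu = 0.1, e0 = 0.1) {
  stopifnot(inherits(topology, "nn_topology"), mu >= 0, e0 >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- topology$n; h <- topology$h; m <- topology$m_out
  structure(list(topology = topology,
                 w_ih = matrix(runif(n * h, -1, 1), n, h),
                 w_ho = matrix(runif(h * m, -1, 1), h, m),
                 lam = runif(h, -1, 1),
                 eta = runif(m, -1, 1),
                 mu = mu, e0 = e0,
                 stats = NULL, bin_size = NULL, min_bins = NULL),
            class = "meann_net")
}

#' Hidden-layer activation function
#'
#' `f(x) = 2 / (1 + exp(-2x)) - 1`, a sigmoid with range (-1, 1);
#' mathematically identical to `tanh(x)`.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length.
#' @export
#' @examples
#' nn_activation(c(-1, 0, 1))
nn_activation <- function(x) {
  2 / (1 + exp(-2 * x)) - 1
}

#' Forward pass
#'
#' Hidden activations `H_j = f(sum_i w_ij b_i - lambda_j)`, raw outputs
#' `P_k = sum_j H_j w_jk - eta_k`, and probabilities
#' `probs = logistic(P)` in (0, 1), one value per copy-number state.
#'
#' @param net A `meann_net`.
#' @param b A normalized input 3-vector (g, q, r), or an m x 3 matrix of
#'   inputs (one row per bin).
#' @return A list with `H` (hidden activations), `raw` (linear outputs)
#'   and `probs` (logistic-mapped outputs); matrices when `b` is a matrix.
#' @export
nn_forward <- function(net, b) {
  stopifnot(inherits(net, "meann_net"))
  B <- if (is.matrix(b)) b else matrix(b, nrow = 1)
  if (ncol(B) != net$topology$n) {
    stop("input has ", ncol(B), " features; network expects ",
         net$topology$n)
  }
  H <- nn_activation(sweep(B %*% net$w_ih, 2, net$lam, "-"))
  raw <- sweep(H %*% net$w_ho, 2, net$eta, "-")
  out <- list(H = H, raw = raw, probs = plogis(raw))
  if (!is.matrix(b)) out <- lapply(out, drop)
  out
}

## internal single-example update.  Residual e = E - raw output.
## rule "gradient": exact gradient descent on the raw-output squared error
##   (hidden derivative 1 - H^2; thresholds updated in the descent
##   direction, scaled by mu).
## rule "as_printed": the literal recursions -- hidden factor H(1-H),
##   lam += mu*H(1-H)*sum(w e), eta += e.
.nn_step <- function(net, b, target, rule) {
  a <- drop(b %*% net$w_ih) - net$lam
  H <- nn_activation(a)
  raw <- drop(H %*% net$w_ho) - net$eta
  e <- target - raw
  gfac <- if (rule == "gradient") 1 - H^2 else H * (1 - H)
  s <- drop(net$w_ho %*% e)              # sum_k w_jk e_k, per hidden j
  net$w_ih <- net$w_ih + net$mu * outer(b, gfac * s)
  net$w_ho <- net$w_ho + net$mu * outer(H, e)
  if (rule == "gradient") {
    net$lam <- net$lam - net$mu * gfac * s
    net$eta <- net$eta - net$mu * e
  } else {
    net$lam <- net$lam + net$mu * gfac * s
    net$eta <- net$eta + e
  }
  list(net = net, e = e)
}

#' One backpropagation step on a single example
#'
#' Applies the per-example update rules to all weights and thresholds with
#' the signed residuals `e_k = E_k - P_k` (raw outputs).  The default rule
#' performs exact gradient descent on the example's squared error; the
#' `"as_printed"` rule applies the literal textbook-style recursions with
#' the `H(1-H)` hidden factor and unscaled output-threshold step (kept for
#' comparison; it does not guarantee error descent).
#'
#' @param net A `meann_net`.
#' @param b Normalized input 3-vector.
#' @param target Expected output: one-hot 4-vector (or a label 0-3).
#' @param rule `"gradient"` (default) or `"as_printed"`.
#' @return A list with the updated `net`, the signed residuals `e`, and
#'   `abs_e = |e|` used by the stopping rule.
#' @export
train_step <- function(net, b, target, rule = c("gradient", "as_printed")) {
  rule <- match.arg(rule)
  stopifnot(inherits(net, "meann_net"))
  if (length(target) == 1) target <- drop(.one_hot(as.integer(target),
                                                   net$topology$m_out))
  stopifnot(length(b) == net$topology$n,
            length(target) == net$topology$m_out)
  res <- .nn_step(net, b, target, rule)
  list(net = res$net, e = res$e, abs_e = abs(res$e))
}

#' Train the network by per-example backpropagation
#'
#' Repeats [train_step()] over all training rows, in a freshly shuffled
#' order each epoch, until every row's maximum absolute output error is at
#' most `net$e0` or `max_epochs` is reached.  Non-convergence is not an
#' error; the result carries a `converged` flag.
#'
#' @param net A `meann_net` (random or MEA-initialized).
#' @param dataset A `cnv_dataset` from [assemble_training_set()].
#' @param max_epochs Maximum number of passes over the data.
#' @param rule Update rule, see [train_step()].
#' @param seed Optional seed for the per-epoch shuffling.
#' @return A list with `net` (trained), `epochs` (completed), `converged`,
#'   and `max_error` (final maximum absolute output error on the training
#'   rows).
#' @export
nn_train <- function(net, dataset, max_epochs = 100L, rule = "gradient",
                     seed = NULL) {
  stopifnot(inherits(net, "meann_net"), inherits(dataset, "cnv_dataset"),
            dataset$m > 0)
  if (!is.null(seed)) set.seed(seed)
  X <- .dataset_features(dataset)
  Tt <- .one_hot(dataset$L, net$topology$m_out)
  epoch_max_error <- function(nn) {
    raw <- sweep(nn_activation(sweep(X %*% nn$w_ih, 2, nn$lam, "-")) %*%
                   nn$w_ho, 2, nn$eta, "-")
    max(abs(Tt - raw))
  }
  max_err <- epoch_max_error(net)
  epochs <- 0L
  converged <- max_err <= net$e0
  while (!converged && epochs < max_epochs) {
    for (i in sample.int(dataset$m)) {
      net <- .nn_step(net, X[i, ], Tt[i, ], rule)$net
    }
    epochs <- epochs + 1L
    max_err <- epoch_max_error(net)
    converged <- max_err <= net$e0
  }
  list(net = net, epochs = epochs, converged = converged,
       max_error = max_err)
}

#' Class probabilities for normalized inputs
#'
#' @param net A trained `meann_net`.
#' @param b Normalized input 3-vector or m x 3 matrix (columns g, q, r).
#' @return A 4-vector (or m x 4 matrix) of values in (0, 1), one per
#'   copy-number state in the order normal, gain, hemi_loss, homo_loss.
#' @export
predict_proba <- function(net, b) {
  nn_forward(net, b)$probs
}
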