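# Independent oracles used across the suite.  Everything here is written as
# plainly as possible (enumeration, naive loops) and never calls the package
# code paths it is used to check.

# Exact Mann-Whitney null distribution of U (x-statistic) for group sizes
# n1, n2 over distinct values, by full enumeration of labelings.
enum_u_distribution <- function(n1, n2) {
  n <- n1 + n2
  splits <- utils::combn(n, n1)
  u <- apply(splits, 2L, function(ix) sum(ix) - n1 * (n1 + 1) / 2)
  table(factor(u, levels = 0:(n1 * n2))) / ncol(splits)
}

# Two-sided exact p for an observed U under the enumeration distribution
# (symmetric-tail definition).
enum_mw_p <- function(u_obs, n1, n2) {
  dist <- enum_u_distribution(n1, n2)
  u_vals <- as.numeric(names(dist))
  mu <- n1 * n2 / 2
  sum(dist[abs(u_vals - mu) >= abs(u_obs - mu) - 1e-12])
}

# Reference forward pass: explicit affine + tanh composition in R.
r_forward <- function(net, X) {
  A <- as.matrix(X)
  for (l in seq_along(net$weights))
    A <- tanh(sweep(A %*% net$weights[[l]], 2L, net$biases[[l]], "+"))
  A[, 1L]
}

# Reference MSE loss used for finite-difference gradient checks.
r_loss <- function(net, X, y) mean((r_forward(net, X) - y)^2)

# Central finite-difference gradient over every weight and bias of a net.
fd_gradient <- function(net, X, y, eps = 1e-5) {
  grads <- list(weights = list(), biases = list())
  for (l in seq_along(net$weights)) {
    gw <- net$weights[[l]] * 0
    for (i in seq_along(gw)) {
      np <- net; np$weights[[l]][i] <- np$weights[[l]][i] + eps
      nm <- net; nm$weights[[l]][i] <- nm$weights[[l]][i] - eps
      gw[i] <- (r_loss(np, X, y) - r_loss(nm, X, y)) / (2 * eps)
    }
    gb <- net$biases[[l]] * 0
    for (i in seq_along(gb)) {
      np <- net; np$biases[[l]][i] <- np$biases[[l]][i] + eps
      nm <- net; nm$biases[[l]][i] <- nm$biases[[l]][i] - eps
      gb[i] <- (r_loss(np, X, y) - r_loss(nm, X, y)) / (2 * eps)
    }
    grads$weights[[l]] <- gw
    grads$biases[[l]] <- gb
  }
  grads
}

# Hand-stepped iRPROP- on a single parameter with gradient function g(w):
# mirrors the published rule step by step, independent of the package.
hand_rprop <- function(w, gfun, steps, step0 = 0.1, eta_plus = 1.2,
                       eta_minus = 0.5, step_min = 1e-6, step_max = 50) {
  delta <- step0; prev <- 0; trace <- numeric(steps)
  for (t in seq_len(steps)) {
    g <- gfun(w)
    if (g * prev > 0) {
      delta <- min(delta * eta_plus, step_max)
      w <- w - sign(g) * delta
      prev <- g
    } else if (g * prev < 0) {
      delta <- max(delta * eta_minus, step_min)
      prev <- 0
    } else {
      w <- w - sign(g) * delta
      prev <- g
    }
    trace[t] <- w
  }
  trace
}

# Naive brute-force Tukey fence check for one vector.
brute_tukey_keep <- function(x) {
  s <- sort(x)
  q <- stats::quantile(s, c(0.25, 0.75), type = 7, names = FALSE)
  lo <- q[1] - 1.5 * (q[2] - q[1])
  hi <- q[2] + 1.5 * (q[2] - q[1])
  x >= lo & x <= hi
}

# AUC as the Mann-Whitney rank statistic with midranks.
rank_auc <- function(truth, scores) {
  r <- rank(scores)
  n1 <- sum(truth); n0 <- sum(!truth)
  (sum(r[as.logical(truth)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
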