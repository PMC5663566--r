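test_that("forward pass is the affine + symmetric-sigmoid composition", {
  # all-zero weights and biases: output 0
  net0 <- mlp_net(c(2, 3, 1), seed = 1)
  net0$weights <- lapply(net0$weights, function(w) w * 0)
  net0$biases <- lapply(net0$biases, function(b) b * 0)
  expect_equal(ann_forward(net0, matrix(c(1, -1), 1)), 0)
  # saturation: 1-1-1 net with weight +10
  nets <- mlp_net(c(1, 1, 1), seed = 1)
  nets$weights <- list(matrix(10), matrix(10))
  nets$biases <- list(0, 0)
  expect_gt(ann_forward(nets, matrix(1)), 0.9999)
  # random nets match the independent R composition to 1e-12
  set.seed(9)
  for (i in 1:10) {
    net <- mlp_net(c(3, 4, 5, 1), seed = i)
    X <- matrix(rnorm(30), 10, 3)
    expect_lt(max(abs(ann_forward(net, X) - r_forward(net, X))), 1e-12)
  }
  expect_error(ann_forward(mlp_net(c(3, 2, 1), seed = 1), matrix(1, 1, 2)),
               "feature count")
})

test_that("backpropagation matches central finite differences", {
  set.seed(10)
  for (i in 1:8) {
    sizes <- c(sample(2:4, 1), sample(1:5, sample(1:2, 1), replace = TRUE), 1)
    net <- mlp_net(sizes, seed = 100 + i)
    n <- 7
    X <- matrix(rnorm(n * sizes[1]), n, sizes[1])
    y <- sample(c(-1, 1), n, replace = TRUE)
    g <- ann_gradient(net, X, y)
    fd <- fd_gradient(net, X, y)
    ga <- unlist(c(g$grad_weights, g$grad_biases))
    gn <- unlist(c(fd$weights, fd$biases))
    expect_lt(sqrt(sum((ga - gn)^2)) / max(sqrt(sum(gn^2)), 1e-8), 1e-6)
  }
})

test_that("iRPROP- steps follow the sign-agreement rule", {
  # two consecutive positive gradients: step grows 0.1 -> 0.12
  s1 <- rprop_update(1, 2)            # first step, product 0: move by 0.1
  expect_equal(s1$par, 0.9)
  expect_equal(s1$state$step, 0.1)
  s2 <- rprop_update(s1$par, 1.8, s1$state)
  expect_equal(s2$state$step, 0.12)
  expect_equal(s2$par, 0.78)
  # sign flip: step halves, weight unchanged that epoch
  s3 <- rprop_update(s2$par, -1, s2$state)
  expect_equal(s3$state$step, 0.06)
  expect_equal(s3$par, s2$par)
  expect_equal(s3$state$prev_grad, 0)
})

test_that("ten iRPROP- steps on f(w) = w^2 match the hand-stepped trace", {
  expected <- hand_rprop(1, function(w) 2 * w, steps = 10)
  w <- 1; state <- NULL; got <- numeric(10)
  for (t in 1:10) {
    up <- rprop_update(w, 2 * w, state)
    w <- up$par; state <- up$state; got[t] <- w
  }
  expect_equal(got, expected, tolerance = 1e-15)
  # frozen values for the first and the post-flip steps
  expect_equal(got[1:3], c(0.9, 0.78, 0.636))
  expect_equal(got[7], got[8])   # the flip epoch does not move the weight
})

test_that("the compiled trainer reproduces an R-stepped epoch loop exactly", {
  set.seed(6)
  net <- mlp_net(c(2, 3, 1), seed = 42)
  X <- matrix(rnorm(16), 8, 2)
  y <- rep(c(-1, 1), 4)
  ctrl <- train_control(max_epochs = 5, patience = 5)
  fit <- train_early_stopping(net, X, y, X, y, ctrl)
  # R reference: same rule applied to the flattened parameter vector
  ref <- net
  state <- NULL
  flat <- function(n) unlist(c(n$weights, n$biases))
  best <- ref; best_err <- mean((r_forward(ref, X) - y)^2)
  for (e in 1:5) {
    g <- ann_gradient(ref, X, y)
    up <- rprop_update(flat(ref), unlist(c(g$grad_weights, g$grad_biases)), state)
    state <- up$state
    # unflatten
    idx <- 1
    for (l in seq_along(ref$weights)) {
      k <- length(ref$weights[[l]])
      ref$weights[[l]][] <- up$par[idx:(idx + k - 1)]; idx <- idx + k
    }
    for (l in seq_along(ref$biases)) {
      k <- length(ref$biases[[l]])
      ref$biases[[l]][] <- up$par[idx:(idx + k - 1)]; idx <- idx + k
    }
    err <- mean((r_forward(ref, X) - y)^2)
    if (err < best_err) { best_err <- err; best <- ref }
  }
  expect_equal(fit$val_error, best_err, tolerance = 1e-12)
  expect_equal(unlist(fit$net$weights), unlist(best$weights), tolerance = 1e-12)
  expect_equal(unlist(fit$net$biases), unlist(best$biases), tolerance = 1e-12)
})

test_that("early stopping trains a separable toy to zero error and is deterministic", {
  set.seed(2)
  X <- rbind(matrix(rnorm(20, -1, 0.2), 10, 2), matrix(rnorm(20, 1, 0.2), 10, 2))
  y <- rep(c(-1, 1), each = 10)
  net <- mlp_net(c(2, 4, 1), seed = 5)
  fit <- train_early_stopping(net, X, y, X, y, train_control(max_epochs = 500, patience = 500))
  pred <- ifelse(ann_forward(fit$net, X) > 0, 1, -1)
  expect_identical(pred, y)
  expect_lt(min(fit$train_trace), 0.05)
  fit2 <- train_early_stopping(net, X, y, X, y, train_control(max_epochs = 500, patience = 500))
  expect_equal(fit$net, fit2$net, tolerance = 1e-15)
  # patience 0 returns the initialization (degenerate but defined)
  fit0 <- train_early_stopping(net, X, y, X, y, train_control(patience = 0))
  expect_equal(fit0$net$weights, net$weights, tolerance = 1e-15)
  expect_equal(fit0$epochs_run, 0)
  # the returned weights never exceed the best validation error seen
  expect_equal(fit$val_error, min(fit$val_trace), tolerance = 1e-12)
  expect_error(train_early_stopping(net, X, rep(1, 20), X, y), "both classes")
})

test_that("stratified splits have the documented sizes and are deterministic", {
  labels <- factor(rep(c("malignant", "benign"), c(40, 20)))
  sp <- split_dataset(labels, seed = 3)
  expect_equal(lengths(sp), c(train = 36L, validation = 12L, test = 12L))
  expect_setequal(unlist(sp), 1:60)
  expect_equal(length(intersect(sp$train, sp$validation)), 0)
  # both classes present in every split
  for (s in sp) expect_equal(nlevels(droplevels(labels[s])), 2)
  # remainder-to-train rounding at n = 62
  labels62 <- factor(rep(c("malignant", "benign"), c(42, 20)))
  sp62 <- split_dataset(labels62, seed = 3)
  expect_equal(lengths(sp62), c(train = 38L, validation = 12L, test = 12L))
  expect_identical(sp, split_dataset(labels, seed = 3))
  expect_error(split_dataset(labels[1:4]), "at least 5")
  expect_error(split_dataset(factor(rep("a", 10))), "both classes")
})

test_that("the topology search is deterministic and selects by validation error", {
  co <- simulate_birads4_cohort(n = 40, malignant_fraction = 0.5, effects = 2.5,
                                noise_cv = 0.2, missing_rate = 0, seed = 8)
  dat <- as.data.frame(co$levels)
  names(dat) <- make.names(colnames(co$levels))
  dat$class <- co$labels
  m1 <- ann_fit(class ~ ., dat, iterations = 15, seed = 21)
  m2 <- ann_fit(class ~ ., dat, iterations = 15, seed = 21)
  expect_equal(m1$net, m2$net, tolerance = 1e-15)
  expect_identical(m1$topology, m2$topology)
  expect_equal(m1$val_error, min(m1$leaderboard$val_error, na.rm = TRUE))
  expect_equal(nrow(m1$leaderboard), 15)
  # iterations = 1 returns that single model
  m3 <- ann_fit(class ~ ., dat, iterations = 1, seed = 4)
  expect_equal(nrow(m3$leaderboard), 1)
})

test_that("preprocessing parameters come from the training split only (no leakage)", {
  co <- simulate_birads4_cohort(n = 50, malignant_fraction = 0.6, effects = 2.5,
                                noise_cv = 0.3, missing_rate = 0, seed = 12)
  dat <- as.data.frame(co$levels)
  names(dat) <- make.names(colnames(co$levels))
  dat$class <- co$labels
  m <- ann_fit(class ~ ., dat, iterations = 10, seed = 2)
  X <- m$data$X
  refit <- plasmiR:::preprocess_fit(X[m$split_idx$train, , drop = FALSE])
  expect_equal(m$preprocess$fences, refit$fences, tolerance = 1e-12)
  expect_equal(m$preprocess$minmax, refit$minmax, tolerance = 1e-12)
  # including test rows would change the fitted fences, proving they are unused
  with_test <- plasmiR:::preprocess_fit(X)
  expect_false(isTRUE(all.equal(refit$minmax, with_test$minmax, tolerance = 1e-12)))
})

test_that("prediction thresholds at zero, flags fence outliers, rejects missing features", {
  co <- simulate_birads4_cohort(n = 40, malignant_fraction = 0.5, effects = 2.5,
                                noise_cv = 0.2, missing_rate = 0, seed = 14)
  dat <- as.data.frame(co$levels)
  names(dat) <- make.names(colnames(co$levels))
  dat$class <- co$labels
  m <- ann_fit(class ~ ., dat, iterations = 8, seed = 7)
  pr <- predict(m, dat)
  expect_identical(pr$class[pr$score > 0],
                   rep("malignant", sum(pr$score > 0)))
  expect_identical(pr$class[pr$score <= 0],
                   rep("benign", sum(pr$score <= 0)))
  # negating the output layer flips every score's sign (tanh symmetry)
  mneg <- m
  L <- length(mneg$net$weights)
  mneg$net$weights[[L]] <- -mneg$net$weights[[L]]
  mneg$net$biases[[L]] <- -mneg$net$biases[[L]]
  expect_equal(predict(mneg, dat)$score, -pr$score, tolerance = 1e-12)
  # a wildly out-of-range sample is scored but flagged
  far <- dat[1, ]; far[1, 1] <- 1e3
  prf <- predict(m, far)
  expect_true(prf$out_of_fence[1])
  expect_match(prf$reason[1], "fence")
  # missing feature value: rejected with a reason
  miss <- dat[1, ]; miss[1, 2] <- NA
  prm <- predict(m, miss)
  expect_true(is.na(prm$class[1]))
  expect_match(prm$reason[1], "missing")
})

test_that("models round-trip through JSON and predict identically", {
  co <- simulate_birads4_cohort(n = 40, malignant_fraction = 0.5, effects = 2.5,
                                noise_cv = 0.2, missing_rate = 0, seed = 31)
  dat <- as.data.frame(co$levels)
  names(dat) <- make.names(colnames(co$levels))
  dat$class <- co$labels
  m <- ann_fit(class ~ ., dat, iterations = 5, seed = 9)
  path <- file.path(tempdir(), "model.json")
  write_ann_model(m, path)
  m2 <- read_ann_model(path)
  expect_equal(predict(m2, dat)$score, predict(m, dat)$score, tolerance = 1e-12)
  expect_identical(m2$topology, m$topology)
})
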