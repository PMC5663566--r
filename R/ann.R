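#' Create a multilayer perceptron with symmetric-sigmoid units
#'
#' Layer sizes run input -> hidden... -> output (output size 1 for the
#' binary lesion classifier).  Every layer, including the output, applies
#' the symmetric sigmoid (tanh), so raw scores lie in (-1, +1).  Weights and
#' biases are initialized uniformly in \[-0.5, +0.5\].
#'
#' @param sizes integer vector of layer sizes, e.g. `c(3, 4, 5, 1)`; at least
#'   one hidden layer, all sizes >= 1.
#' @param seed integer seed for the initialization.
#' @return list(sizes, weights, biases) of class `mlp_net`; `weights[[l]]` is
#'   `sizes[l] x sizes[l+1]`, `biases[[l]]` has length `sizes[l+1]`.
#' @export
mlp_net <- function(sizes, seed = 1L) {
  if (length(sizes) < 3L || any(sizes < 1L) || any(sizes != floor(sizes)))
    stop("sizes must give input, >=1 hidden and output layers, all >= 1", call. = FALSE)
  set.seed(check_count(seed, "seed"))
  L <- length(sizes) - 1L
  weights <- lapply(seq_len(L), function(l)
    matrix(runif(sizes[l] * sizes[l + 1L], -0.5, 0.5), sizes[l], sizes[l + 1L]))
  biases <- lapply(seq_len(L), function(l) runif(sizes[l + 1L], -0.5, 0.5))
  structure(list(sizes = as.integer(sizes), weights = weights, biases = biases),
            class = "mlp_net")
}

#' Forward pass through a network
#'
#' @param net an `mlp_net` (or any list with `weights`/`biases`).
#' @param X numeric matrix, one row per sample; column count must equal the
#'   input size.
#' @return Raw output score per row, in (-1, +1).
#' @export
ann_forward <- function(net, X) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(net$weights[[1L]]))
    stop(sprintf("feature count %d does not match input size %d",
                 ncol(X), nrow(net$weights[[1L]])), call. = FALSE)
  storage.mode(X) <- "double"
  as.numeric(mlp_forward_cpp(net$weights, net$biases, X))
}

#' Backpropagation gradient of the mean squared error
#'
#' @param net an `mlp_net`.
#' @param X feature matrix (rows = samples).
#' @param y numeric targets encoded benign = -1, malignant = +1.
#' @return list(grad_weights, grad_biases, error) where error is the MSE.
#' @export
ann_gradient <- function(net, X, y) {
  X <- as.matrix(X); storage.mode(X) <- "double"
  mlp_gradient_cpp(net$weights, net$biases, X, as.numeric(y))
}

#' One iRPROP- update step
#'
#' Per-parameter adaptive steps driven by gradient sign agreement: if the
#' gradient keeps its sign, the step grows by `eta_plus` (capped at
#' `step_max`) and the parameter moves by `-sign(g) * step`; on a sign flip
#' the step shrinks by `eta_minus` (floored at `step_min`), the gradient is
#' treated as zero and the parameter does not move this epoch.  A zero
#' product (first step, or the step after a flip) moves by the current step
#' without changing it.
#'
#' @param par numeric parameter vector.
#' @param grad gradient of the loss at `par`.
#' @param state NULL on the first call, else the state returned previously.
#' @param eta_plus,eta_minus,step0,step_min,step_max iRPROP- constants
#'   (defaults 1.2, 0.5, 0.1, 1e-6, 50 — the standard resilient
#'   backpropagation values).
#' @return list(par, state) with `state = list(step, prev_grad)`.
#' @export
rprop_update <- function(par, grad, state = NULL, eta_plus = 1.2,
                         eta_minus = 0.5, step0 = 0.1, step_min = 1e-6,
                         step_max = 50) {
  if (is.null(state))
    state <- list(step = rep(step0, length(par)), prev_grad = rep(0, length(par)))
  prod <- grad * state$prev_grad
  up <- prod > 0; down <- prod < 0; flat <- prod == 0
  state$step[up] <- pmin(state$step[up] * eta_plus, step_max)
  state$step[down] <- pmax(state$step[down] * eta_minus, step_min)
  move <- up | flat
  par[move] <- par[move] - sign(grad[move]) * state$step[move]
  state$prev_grad <- ifelse(down, 0, grad)
  list(par = par, state = state)
}

#' Training control for the lesion classifier
#'
#' @param max_epochs training budget per network.
#' @param patience early-stopping patience: training stops once the
#'   validation error has not improved for this many epochs (the best-so-far
#'   weights are always the ones returned).
#' @param eta_plus,eta_minus,step0,step_min,step_max iRPROP- constants.
#' @param fractions train/validation/test split fractions (must sum to 1).
#' @param hidden_layers range of hidden-layer counts sampled by the topology
#'   search.
#' @param hidden_width range of per-layer widths sampled by the search.
#' @return list of class `train_control`.
#' @export
train_control <- function(max_epochs = 5000L, patience = 50L, eta_plus = 1.2,
                          eta_minus = 0.5, step0 = 0.1, step_min = 1e-6,
                          step_max = 50, fractions = c(0.6, 0.2, 0.2),
                          hidden_layers = 1:3, hidden_width = 1:10) {
  if (abs(sum(fractions) - 1) > 1e-9 || length(fractions) != 3L)
    stop_field("fractions", "must be three fractions summing to 1")
  if (!(eta_plus > 1 && eta_minus < 1 && eta_minus > 0))
    stop_field("eta", "requires eta_plus > 1 > eta_minus > 0")
  structure(list(max_epochs = check_count(max_epochs, "max_epochs", 1L),
                 patience = check_count(patience, "patience", 0L),
                 eta_plus = eta_plus, eta_minus = eta_minus, step0 = step0,
                 step_min = step_min, step_max = step_max,
                 fractions = fractions, hidden_layers = hidden_layers,
                 hidden_width = hidden_width),
            class = "train_control")
}

#' Train a network with early stopping
#'
#' Full-batch iRPROP- on the mean squared error with targets benign = -1,
#' malignant = +1.  After each epoch the validation error is evaluated; the
#' best-so-far weights are retained and returned.  Training stops at
#' `max_epochs` or once the validation error has not improved for
#' `patience` epochs.  With `patience = 0` the initialization itself is
#' returned (degenerate but defined).
#'
#' @param net an `mlp_net`.
#' @param X_train,y_train,X_val,y_val scaled features and +/-1 targets; the
#'   training set must contain both classes.
#' @param control a [train_control()].
#' @return list: trained `net`, `val_error`, `best_epoch`, `epochs_run`,
#'   `train_trace`, `val_trace`.
#' @export
train_early_stopping <- function(net, X_train, y_train, X_val, y_val,
                                 control = train_control()) {
  if (length(y_train) == 0L || length(y_val) == 0L)
    stop("train and validation sets must be non-empty", call. = FALSE)
  if (length(unique(y_train)) < 2L)
    stop("training set must contain both classes", call. = FALSE)
  X_train <- as.matrix(X_train); storage.mode(X_train) <- "double"
  X_val <- as.matrix(X_val); storage.mode(X_val) <- "double"
  fit <- mlp_train_cpp(net$weights, net$biases, X_train, as.numeric(y_train),
                       X_val, as.numeric(y_val), control$max_epochs,
                       control$patience, control$eta_plus, control$eta_minus,
                       control$step0, control$step_min, control$step_max)
  net$weights <- fit$weights
  net$biases <- fit$biases
  list(net = net, val_error = fit$val_error, best_epoch = fit$best_epoch,
       epochs_run = fit$epochs_run, train_trace = fit$train_trace,
       val_trace = fit$val_trace)
}

#' Stratified train/validation/test split
#'
#' Within each class, `floor(fraction * n_class)` samples go to validation
#' and test; the remainder goes to training, so e.g. 60 samples at 60/20/20
#' split 36/12/12 and 62 split 38/12/12.  Each split holds both classes
#' where the class sizes permit.
#'
#' @param labels factor (or vector) of class labels, length n >= 5, both
#'   classes present.
#' @param fractions train/validation/test fractions summing to 1.
#' @param seed integer seed; identical seeds give identical memberships.
#' @return list(train, validation, test) of integer index vectors, disjoint
#'   and exhaustive.
#' @export
split_dataset <- function(labels, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  n <- length(labels)
  if (n < 5L) stop("need at least 5 samples to split", call. = FALSE)
  if (length(unique(labels)) < 2L) stop("both classes must be present", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-9) stop_field("fractions", "must sum to 1")
  set.seed(check_count(seed, "seed"))
  val <- test <- integer(0)
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    n_val <- floor(fractions[2] * length(idx))
    n_test <- floor(fractions[3] * length(idx))
    val <- c(val, idx[seq_len(n_val)])
    test <- c(test, idx[n_val + seq_len(n_test)])
  }
  train <- setdiff(seq_len(n), c(val, test))
  if (length(train) == 0L || length(val) == 0L || length(test) == 0L)
    stop("too few samples for three non-empty splits", call. = FALSE)
  list(train = sort(train), validation = sort(val), test = sort(test))
}

encode_labels <- function(labels, positive) {
  ifelse(labels == positive, 1, -1)
}

#' Fit the BI-RADS 4 lesion classifier by stochastic topology search
#'
#' The modelling core: repeatedly (i) draw a random topology (hidden-layer
#' count and widths from the ranges in `control`), (ii) draw a fresh
#' stratified 60/20/20 split, (iii) fit Tukey fences and min-max scaling on
#' the training rows only, (iv) train with iRPROP- under early stopping, and
#' (v) score by validation error.  The best-by-validation network is
#' returned; its test metrics are reported but never used for selection.
#'
#' @param formula model formula, e.g. `malignant ~ .` or
#'   `class ~ miR15a + miR101 + miR144`; the response must be a two-level
#'   factor (rows with missing features are dropped with a count).
#' @param data data.frame of relative miRNA levels plus the response.
#' @param iterations number of (topology, split) draws (>= 1).  10,000
#'   reproduces a full published-scale search; a few hundred suffice at desk
#'   scale.
#' @param seed master seed; (control, seed) fully determine the winner.
#' @param control a [train_control()].
#' @param positive label treated as the positive (malignant) class; default
#'   the second factor level, or `"malignant"` when present.
#' @return An object of class `birads_ann`: winning topology, weights,
#'   preprocessing parameters, split membership, error traces, the full
#'   leaderboard, and test/pooled diagnostic metrics.
#' @seealso [predict.birads_ann()], [summary.birads_ann()]
#' @export
ann_fit <- function(formula, data, iterations = 200L, seed = 1L,
                    control = train_control(), positive = NULL) {
  cl <- match.call()
  iterations <- check_count(iterations, "iterations", 1L)
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y_raw <- stats::model.response(mf)
  X <- as.matrix(mf[, -1L, drop = FALSE])
  storage.mode(X) <- "double"
  complete <- stats::complete.cases(X) & !is.na(y_raw)
  n_dropped <- sum(!complete)
  X <- X[complete, , drop = FALSE]
  y_raw <- y_raw[complete]
  y_fac <- as.factor(y_raw)
  if (nlevels(y_fac) != 2L)
    stop("the response must have exactly two classes", call. = FALSE)
  if (is.null(positive))
    positive <- if ("malignant" %in% levels(y_fac)) "malignant" else levels(y_fac)[2L]
  y <- encode_labels(as.character(y_fac), positive)

  best <- NULL
  leaderboard <- vector("list", iterations)
  for (i in seq_len(iterations)) {
    iter_seed <- child_seed(seed, "topology_search", i)
    set.seed(iter_seed)
    n_layers <- sample(control$hidden_layers, 1L)
    widths <- sample(control$hidden_width, n_layers, replace = TRUE)
    sizes <- c(ncol(X), widths, 1L)
    split <- split_dataset(y_fac, control$fractions,
                           seed = child_seed(iter_seed, "split"))
    fit <- tryCatch({
      prep <- preprocess_fit(X[split$train, , drop = FALSE])
      train_idx <- split$train[prep$keep_row]
      if (length(unique(y[train_idx])) < 2L)
        stop("single-class training set after outlier filtering")
      scale_all <- preprocess_apply(X, prep)
      net <- mlp_net(sizes, seed = child_seed(iter_seed, "init"))
      tr <- train_early_stopping(net,
                                 scale_all$scaled[train_idx, , drop = FALSE],
                                 y[train_idx],
                                 scale_all$scaled[split$validation, , drop = FALSE],
                                 y[split$validation], control)
      c(tr, list(prep = prep, split = split, train_idx = train_idx,
                 scaled = scale_all, sizes = sizes, iter_seed = iter_seed))
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      leaderboard[[i]] <- data.frame(iteration = i, topology = paste(sizes, collapse = "-"),
                                     seed = iter_seed, val_error = NA_real_,
                                     test_accuracy = NA_real_, epochs = NA_integer_,
                                     stringsAsFactors = FALSE)
      next
    }
    test_scores <- ann_forward(fit$net, fit$scaled$scaled[split$test, , drop = FALSE])
    test_pred <- ifelse(test_scores > 0, 1, -1)
    test_acc <- mean(test_pred == y[split$test])
    leaderboard[[i]] <- data.frame(iteration = i, topology = paste(sizes, collapse = "-"),
                                   seed = iter_seed, val_error = fit$val_error,
                                   test_accuracy = test_acc, epochs = fit$epochs_run,
                                   stringsAsFactors = FALSE)
    if (is.null(best) || fit$val_error < best$val_error) best <- fit
  }
  if (is.null(best)) stop("no topology-search iteration trained successfully", call. = FALSE)

  scores_all <- ann_forward(best$net, best$scaled$scaled)
  pred_all <- ifelse(scores_all > 0, positive,
                     setdiff(levels(y_fac), positive))
  truth_all <- as.character(y_fac)
  ids <- rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  structure(list(
    call = cl, topology = best$sizes, net = best$net,
    preprocess = best$prep, split = lapply(best$split, function(ix) ids[ix]),
    split_idx = best$split, train_idx_used = best$train_idx,
    val_error = best$val_error, best_epoch = best$best_epoch,
    train_trace = best$train_trace, val_trace = best$val_trace,
    leaderboard = do.call(rbind, leaderboard),
    positive = positive, levels = levels(y_fac),
    features = colnames(X), data = list(X = X, labels = truth_all, ids = ids),
    scores = scores_all, predicted = pred_all,
    n_dropped_missing = n_dropped,
    metrics_test = evaluate_subset(truth_all, pred_all, scores_all,
                                   best$split$test, positive),
    metrics_pooled = evaluate_subset(truth_all, pred_all, scores_all,
                                     seq_along(truth_all), positive),
    iterations = iterations, seed = seed, control = control),
    class = "birads_ann")
}

evaluate_subset <- function(truth, pred, scores, idx, positive) {
  cm <- confusion_matrix(truth[idx], pred[idx], positive = positive)
  m <- diagnostic_metrics(cm)
  m$auc <- if (length(unique(truth[idx])) == 2L)
    roc_auc(truth[idx] == positive, scores[idx])$auc else NA_real_
  m
}

#' @export
print.birads_ann <- function(x, ...) {
  cat("BI-RADS 4 lesion classifier (multilayer perceptron, iRPROP-)\n")
  cat(sprintf("topology: %s (symmetric sigmoid), selected from %d random draws\n",
              paste(x$topology, collapse = "-"), x$iterations))
  cat(sprintf("validation MSE %.4f (best epoch %d); test accuracy %.3f, pooled accuracy %.3f\n",
              x$val_error, x$best_epoch, x$metrics_test$accuracy,
              x$metrics_pooled$accuracy))
  invisible(x)
}

#' @export
summary.birads_ann <- function(object, ...) {
  x <- object
  cat("Call: "); print(x$call)
  print(x)
  cat(sprintf("splits: %d train (%d used after outlier filter) / %d validation / %d test; %d sample(s) dropped for missing features\n",
              length(x$split$train), length(x$train_idx_used),
              length(x$split$validation), length(x$split$test),
              x$n_dropped_missing))
  for (set in c("test", "pooled")) {
    m <- x[[paste0("metrics_", set)]]
    cat(sprintf("%s: accuracy %.4f, sensitivity %s, specificity %s, LR+ %s, LR- %s, AUC %s\n",
                set, m$accuracy, fmt_metric(m$sensitivity), fmt_metric(m$specificity),
                fmt_metric(m$lr_positive), fmt_metric(m$lr_negative), fmt_metric(m$auc)))
  }
  invisible(x)
}

fmt_metric <- function(v) if (is.null(v) || is.na(v)) "undefined" else sprintf("%.4f", v)

#' @export
coef.birads_ann <- function(object, ...) {
  w <- unlist(lapply(seq_along(object$net$weights), function(l)
    c(object$net$weights[[l]], object$net$biases[[l]])))
  names(w) <- NULL
  w
}

#' Predict lesion class for new samples
#'
#' Applies the stored Tukey fences and min-max scaling (fitted on the
#' training split — never refitted), runs the forward pass, and labels a
#' sample malignant iff its raw score is strictly positive (a score of
#' exactly 0 is benign).  Samples outside the training fences are still
#' scored but flagged; samples with a missing feature are rejected
#' (NA class, reason recorded).
#'
#' @param object a fitted `birads_ann`.
#' @param newdata data.frame or matrix holding the model's features; if
#'   omitted, the training-time cohort is scored.
#' @param ... unused.
#' @return data.frame: score, class, out_of_fence, reason.
#' @export
predict.birads_ann <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    X <- object$data$X
  } else {
    newdata <- as.data.frame(newdata)
    missing_feats <- setdiff(object$features, names(newdata))
    if (length(missing_feats) > 0L)
      stop(sprintf("missing feature(s): %s", paste(missing_feats, collapse = ", ")),
           call. = FALSE)
    X <- as.matrix(newdata[, object$features, drop = FALSE])
    storage.mode(X) <- "double"
  }
  n <- nrow(X)
  score <- rep(NA_real_, n)
  cls <- rep(NA_character_, n)
  reason <- rep("", n)
  oof <- rep(NA, n)
  ok <- stats::complete.cases(X)
  reason[!ok] <- "missing feature value"
  if (any(ok)) {
    sc <- preprocess_apply(X[ok, , drop = FALSE], object$preprocess)
    score[ok] <- ann_forward(object$net, sc$scaled)
    negative <- setdiff(object$levels, object$positive)
    cls[ok] <- ifelse(score[ok] > 0, object$positive, negative)
    oof[ok] <- sc$out_of_fence
    reason[which(ok)[sc$out_of_fence]] <- "outside training fences"
  }
  data.frame(score = score, class = cls, out_of_fence = oof,
             reason = reason, stringsAsFactors = FALSE)
}

#' @export
fitted.birads_ann <- function(object, ...) object$scores

#' Residuals of the fitted classifier
#'
#' Raw score minus the +/-1 encoded truth, over the full cohort.
#' @param object a `birads_ann`.
#' @param ... unused.
#' @export
residuals.birads_ann <- function(object, ...) {
  object$scores - encode_labels(object$data$labels, object$positive)
}

#' Plot the training history and search leaderboard
#'
#' Left: training and validation MSE traces of the winning network (the
#' vertical line marks the retained best-validation epoch).  Right:
#' validation error of every topology-search draw.
#'
#' @param x a `birads_ann`.
#' @param ... unused.
#' @export
plot.birads_ann <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  epochs <- seq_along(x$train_trace) - 1L
  graphics::plot(epochs, x$train_trace, type = "l", col = "grey40",
                 xlab = "epoch", ylab = "MSE", main = "winning network")
  graphics::lines(epochs, x$val_trace, col = "firebrick")
  graphics::abline(v = x$best_epoch, lty = 2)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  lb <- x$leaderboard
  graphics::plot(lb$iteration, lb$val_error, pch = 16, cex = 0.6,
                 xlab = "search iteration", ylab = "validation MSE",
                 main = "topology search")
  invisible(x)
}

#' Serialize / restore a fitted classifier as JSON
#'
#' Stores topology, weights (row-major), preprocessing parameters, split
#' membership and metrics, so the model can be reloaded and applied to new
#' samples without retraining.
#'
#' @param model a `birads_ann`.
#' @param path JSON file path.
#' @return `write_ann_model()`: the path, invisibly; `read_ann_model()`: a
#'   `birads_ann` usable with [predict.birads_ann()].
#' @export
write_ann_model <- function(model, path) {
  stopifnot(inherits(model, "birads_ann"))
  payload <- list(
    topology = model$topology,
    weights = lapply(model$net$weights, function(w) list(dim = dim(w), values = as.numeric(t(w)))),
    biases = model$net$biases,
    preprocess = list(fences = model$preprocess$fences,
                      minmax = model$preprocess$minmax,
                      feature_names = model$preprocess$feature_names),
    positive = model$positive, levels = model$levels,
    features = model$features, split = model$split,
    seed = model$seed, val_error = model$val_error,
    metrics_test = model$metrics_test, metrics_pooled = model$metrics_pooled)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ann_model
#' @export
read_ann_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- lapply(seq_len(nrow_or_len(p$weights)), function(l) {
    w <- if (is.data.frame(p$weights)) list(dim = p$weights$dim[[l]], values = p$weights$values[[l]]) else p$weights[[l]]
    matrix(w$values, nrow = w$dim[1], ncol = w$dim[2], byrow = TRUE)
  })
  biases <- if (is.list(p$biases)) p$biases else list(p$biases)
  net <- structure(list(sizes = p$topology, weights = weights,
                        biases = lapply(biases, as.numeric)), class = "mlp_net")
  prep <- list(fences = apply(p$preprocess$fences, 1L, as.list),
               minmax = apply(p$preprocess$minmax, 1L, as.list),
               feature_names = p$preprocess$feature_names)
  structure(list(topology = p$topology, net = net, preprocess = prep,
                 positive = p$positive, levels = p$levels,
                 features = p$features, split = p$split, seed = p$seed,
                 val_error = p$val_error, metrics_test = p$metrics_test,
                 metrics_pooled = p$metrics_pooled),
            class = "birads_ann")
}

nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
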