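#' Fit the oculomotor screening classifier
#'
#' Trains a small multilayer perceptron (one hidden layer of 64 rectified
#' linear units, softmax output, cross-entropy loss, Adam optimizer) on the
#' four trial-level oculomotor features: fixation count, mean fixation
#' duration, regression ratio and total reading time. The data are split by
#' stratified sampling into an 80% training and 20% held-out validation set;
#' features are z-score standardized with means and standard deviations
#' fitted on the training portion only, and the scaler is stored with the
#' weights so inference applies the identical transform. Held-out accuracy
#' and F1 (positive class = `"dyslexic"` when present, otherwise the last
#' factor level) are reported.
#'
#' All randomness — the split, weight initialization, and any optimizer
#' shuffling — is controlled by `seed`; refitting with the same inputs and
#' seed reproduces the model exactly.
#'
#' @param x Data frame or matrix with (at least) the columns
#'   `n_fix, mean_fix, regression_ratio, total_read_time`, one row per trial.
#' @param y Binary labels (factor or character), same length as `nrow(x)`;
#'   exactly two classes with at least two samples each.
#' @param seed Integer seed controlling all randomness.
#' @param hidden Hidden-layer width (default 64).
#' @param max_epochs Maximum full-batch epochs (default 500); training stops
#'   earlier when the loss plateaus.
#' @param learn_rate Adam step size (default 1e-3, the optimizer's
#'   conventional default).
#' @param train_frac Training fraction of the stratified split (default 0.8).
#' @param patience Epochs without loss improvement tolerated before early
#'   stop (default 25).
#' @param tol Minimum relative loss improvement counted as progress.
#' @return An object of class `"gaze_mlp"` with components `weights`,
#'   `scaler`, `feature_order`, `levels`, `metrics` (held-out accuracy and
#'   F1), `seed` and training bookkeeping.
#' @seealso [predict.gaze_mlp()], [save_gaze_model()], [gen_cohort()]
#' @export
#' @examples
#' cohort <- gen_cohort(cohort_spec(n_per_class = 30, seed = 1))
#' fit <- gaze_mlp(cohort, cohort$label, seed = 1)
#' fit
gaze_mlp <- function(x, y, seed = 1L, hidden = 64L, max_epochs = 500L,
                     learn_rate = 1e-3, train_frac = 0.8, patience = 25L,
                     tol = 1e-6) {
  feats <- gaze_feature_order()
  x <- as.data.frame(x)
  missing_cols <- setdiff(feats, names(x))
  if (length(missing_cols)) {
    lexi_abort(paste0("feature matrix is missing column(s): ",
                      paste(missing_cols, collapse = ", ")),
               class = "lexi_schema_error")
  }
  X <- as.matrix(x[, feats])
  storage.mode(X) <- "double"
  if (anyNA(X)) lexi_abort("feature matrix contains missing values")
  y <- factor(as.character(y), levels = gaze_label_levels(y))
  if (nlevels(y) != 2L) {
    lexi_abort(sprintf("need exactly 2 classes, got %d", nlevels(y)))
  }
  if (length(y) != nrow(X)) lexi_abort("length(y) must equal nrow(x)")
  class_n <- table(y)
  if (any(class_n < 2L)) {
    lexi_abort("need at least 2 samples per class")
  }
  n_test <- floor(as.numeric(class_n) * (1 - train_frac))
  if (any(n_test < 1L)) {
    lexi_abort("too few samples per class for a stratified split")
  }

  with_seed(seed, {
    # stratified split: held-out indices drawn per class
    test_idx <- unlist(lapply(levels(y), function(lv) {
      idx <- which(y == lv)
      sample(idx, floor(length(idx) * (1 - train_frac)))
    }))
    train_idx <- setdiff(seq_along(y), test_idx)

    mu <- colMeans(X[train_idx, , drop = FALSE])
    sdv <- apply(X[train_idx, , drop = FALSE], 2L, stats::sd)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    Xs <- scale_features(X, mu, sdv)

    net <- mlp_train(Xs[train_idx, , drop = FALSE],
                     as.integer(y[train_idx]) - 1L,
                     hidden = hidden, max_epochs = max_epochs,
                     learn_rate = learn_rate, patience = patience, tol = tol)

    model <- structure(list(
      weights = net$weights,
      scaler = list(mean = mu, sd = sdv),
      feature_order = feats,
      levels = levels(y),
      hidden = as.integer(hidden),
      seed = as.integer(seed),
      epochs_run = net$epochs,
      final_loss = net$loss
    ), class = "gaze_mlp")

    held <- predict(model, x[test_idx, , drop = FALSE])
    truth <- y[test_idx]
    model$metrics <- classification_metrics(truth, held$label,
                                            positive = levels(y)[2L])
    model
  })
}

scale_features <- function(X, mu, sdv) {
  sweep(sweep(X, 2L, mu, "-"), 2L, sdv, "/")
}

# ---- network internals -----------------------------------------------------
# Full-batch MLP: input -> hidden (ReLU) -> 2-way softmax, cross-entropy
# loss, Adam updates. Written out directly because no installed package
# offers this architecture; deliberately minimal.

mlp_init <- function(n_in, hidden) {
  list(
    W1 = matrix(stats::rnorm(n_in * hidden, sd = sqrt(2 / n_in)),
                n_in, hidden),
    b1 = numeric(hidden),
    W2 = matrix(stats::rnorm(hidden * 2L, sd = sqrt(2 / hidden)),
                hidden, 2L),
    b2 = numeric(2L)
  )
}

mlp_forward <- function(w, X) {
  H <- pmax(sweep(X %*% w$W1, 2L, w$b1, "+"), 0)
  Z <- sweep(H %*% w$W2, 2L, w$b2, "+")
  Z <- Z - apply(Z, 1L, max)               # stabilized softmax
  E <- exp(Z)
  P <- E / rowSums(E)
  list(H = H, P = P)
}

mlp_train <- function(X, y01, hidden, max_epochs, learn_rate, patience, tol) {
  n <- nrow(X)
  w <- mlp_init(ncol(X), hidden)
  Y <- cbind(1 - y01, y01)                 # one-hot, column 2 = positive
  m <- lapply(w, function(p) p * 0)        # Adam first moment
  v <- lapply(w, function(p) p * 0)        # Adam second moment
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  best <- Inf; stall <- 0L; loss <- NA_real_
  for (epoch in seq_len(max_epochs)) {
    fwd <- mlp_forward(w, X)
    loss <- -mean(log(rowSums(fwd$P * Y) + 1e-12))
    if (!is.finite(best) || best - loss > tol * max(1, abs(best))) {
      best <- loss; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
    dZ <- (fwd$P - Y) / n
    grad <- list(
      W1 = NULL, b1 = NULL,
      W2 = crossprod(fwd$H, dZ),
      b2 = colSums(dZ)
    )
    dH <- dZ %*% t(w$W2)
    dH[fwd$H <= 0] <- 0
    grad$W1 <- crossprod(X, dH)
    grad$b1 <- colSums(dH)
    for (nm in names(w)) {
      m[[nm]] <- b1 * m[[nm]] + (1 - b1) * grad[[nm]]
      v[[nm]] <- b2 * v[[nm]] + (1 - b2) * grad[[nm]]^2
      mhat <- m[[nm]] / (1 - b1^epoch)
      vhat <- v[[nm]] / (1 - b2^epoch)
      w[[nm]] <- w[[nm]] - learn_rate * mhat / (sqrt(vhat) + eps)
    }
  }
  list(weights = w, epochs = epoch, loss = loss)
}

classification_metrics <- function(truth, pred, positive) {
  truth <- as.character(truth); pred <- as.character(pred)
  acc <- mean(truth == pred)
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(accuracy = acc, f1 = f1, n_heldout = length(truth))
}

# ---- S3 interface ----------------------------------------------------------

#' Predict dyslexia risk from oculomotor features
#'
#' Applies the stored feature scaler and the trained network to new trials.
#' A probability of exactly 0.5 is resolved to the negative (typical) class —
#' the conservative screening default.
#'
#' @param object A fitted [gaze_mlp()] model.
#' @param newdata A `gaze_features` object, or a data frame with the model's
#'   feature columns.
#' @param type `"response"` (default) returns a data frame of labels and
#'   positive-class probabilities; `"prob"` returns the probability vector.
#' @param ... Unused.
#' @return Data frame with columns `label` (factor) and `probability`
#'   (probability of the positive, dyslexic class), one row per trial.
#' @export
predict.gaze_mlp <- function(object, newdata, type = c("response", "prob"),
                             ...) {
  type <- match.arg(type)
  if (inherits(newdata, "gaze_features")) {
    newdata <- as.data.frame(newdata[gaze_feature_order()])
  }
  newdata <- as.data.frame(newdata)
  missing_cols <- setdiff(object$feature_order, names(newdata))
  if (length(missing_cols)) {
    lexi_abort(paste0("missing feature column(s): ",
                      paste(missing_cols, collapse = ", ")),
               class = "lexi_schema_error")
  }
  X <- as.matrix(newdata[, object$feature_order, drop = FALSE])
  storage.mode(X) <- "double"
  if (anyNA(X) || any(!is.finite(X))) {
    lexi_abort("feature extraction failed")
  }
  Xs <- scale_features(X, object$scaler$mean, object$scaler$sd)
  p <- mlp_forward(object$weights, Xs)$P[, 2L]
  if (type == "prob") return(unname(p))
  label <- factor(ifelse(p > 0.5, object$levels[2L], object$levels[1L]),
                  levels = object$levels)
  out <- data.frame(label = label, probability = unname(p))
  rownames(out) <- NULL
  out
}

#' @export
print.gaze_mlp <- function(x, ...) {
  cat("Oculomotor screening MLP\n")
  cat(sprintf("  features : %s\n", paste(x$feature_order, collapse = ", ")))
  cat(sprintf("  network  : %d -> %d (ReLU) -> 2 (softmax)\n",
              length(x$feature_order), x$hidden))
  cat(sprintf("  classes  : %s (positive: %s)\n",
              paste(x$levels, collapse = " / "), x$levels[2L]))
  cat(sprintf("  held-out : accuracy %.3f, F1 %.3f (n = %d)\n",
              x$metrics$accuracy, x$metrics$f1, x$metrics$n_heldout))
  invisible(x)
}

#' @export
summary.gaze_mlp <- function(object, ...) {
  structure(list(model = object), class = "summary.gaze_mlp")
}

#' @export
print.summary.gaze_mlp <- function(x, ...) {
  m <- x$model
  print(m)
  cat(sprintf("  trained  : %d epoch(s), final loss %.5f, seed %d\n",
              m$epochs_run, m$final_loss, m$seed))
  cat("  scaler (training-split fit):\n")
  print(data.frame(mean = m$scaler$mean, sd = m$scaler$sd))
  invisible(x)
}

#' @export
coef.gaze_mlp <- function(object, ...) {
  object$weights
}

# ---- persistence -----------------------------------------------------------

#' Persist or restore a trained gaze model
#'
#' The model — weights, scaler, feature order, class levels and metadata —
#' is written as a single JSON artifact with full double precision, so a
#' reloaded model reproduces predictions bit-for-bit.
#'
#' @param model A fitted [gaze_mlp()] model.
#' @param path Output (input) file path, conventionally `*.json`.
#' @return `save_gaze_model()` returns `path` invisibly;
#'   `load_gaze_model()` returns the restored `gaze_mlp` object.
#' @export
save_gaze_model <- function(model, path) {
  stopifnot(inherits(model, "gaze_mlp"))
  payload <- list(
    format = "lexiscreen-gaze-mlp",
    version = 1L,
    feature_order = model$feature_order,
    levels = model$levels,
    hidden = model$hidden,
    seed = model$seed,
    epochs_run = model$epochs_run,
    final_loss = model$final_loss,
    metrics = model$metrics,
    scaler = list(mean = unname(model$scaler$mean),
                  sd = unname(model$scaler$sd)),
    weights = lapply(model$weights, function(w) {
      if (is.matrix(w)) list(dim = dim(w), data = as.numeric(w))
      else list(dim = NULL, data = as.numeric(w))
    })
  )
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname save_gaze_model
#' @export
load_gaze_model <- function(path) {
  if (!file.exists(path)) {
    lexi_abort(paste0("model file not found: ", path), class = "lexi_io_error")
  }
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "lexiscreen-gaze-mlp")) {
    lexi_abort("not a lexiscreen gaze model artifact",
               class = "lexi_schema_error")
  }
  weights <- lapply(p$weights, function(w) {
    if (!is.null(w$dim)) matrix(w$data, w$dim[1L], w$dim[2L]) else w$data
  })
  structure(list(
    weights = weights,
    scaler = list(mean = stats::setNames(p$scaler$mean, p$feature_order),
                  sd = stats::setNames(p$scaler$sd, p$feature_order)),
    feature_order = p$feature_order,
    levels = p$levels,
    hidden = as.integer(p$hidden),
    seed = as.integer(p$seed),
    epochs_run = p$epochs_run,
    final_loss = p$final_loss,
    metrics = p$metrics
  ), class = "gaze_mlp")
}
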