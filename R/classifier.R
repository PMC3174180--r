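# RBF-kernel SVM training, decision-value scoring, and hyperparameter
# selection on a held-out validation set. The decision value (signed
# distance-like output of the learned hyperplane) is the prediction score;
# predicted class is +1 iff the value is > 0 (an exact 0 is conservatively
# called -1).

#' SVM hyperparameters
#'
#' @param C penalty on the training error (> 0).
#' @param gamma RBF kernel width parameter (> 0).
#' @return list of class `svm_params`.
#' @export
svm_params <- function(C, gamma) {
  stopifnot(is.numeric(C), is.numeric(gamma), C > 0, gamma > 0)
  structure(list(C = C, gamma = gamma), class = "svm_params")
}

#' Default (C, gamma) search grid
#'
#' The classic libsvm-style exponential grid: C in 2^(-5, -3, ..., 15),
#' gamma in 2^(-15, -13, ..., 3).
#'
#' @return list of [svm_params()].
#' @export
default_grid <- function() {
  grid <- expand.grid(C = 2^seq(-5, 15, by = 2), gamma = 2^seq(-15, 3, by = 2))
  lapply(seq_len(nrow(grid)), function(i) svm_params(grid$C[i], grid$gamma[i]))
}

# Fit the min-max scaler on training columns: maps each column to [0,1];
# constant columns map to 0.
fit_scaler <- function(X) {
  mins <- apply(X, 2L, min)
  rngs <- apply(X, 2L, max) - mins
  list(min = mins, range = rngs)
}

apply_scaler <- function(scaler, X) {
  rng <- ifelse(scaler$range > 0, scaler$range, 1)
  Xs <- sweep(X, 2L, scaler$min, "-")
  Xs <- sweep(Xs, 2L, rng, "/")
  Xs[, scaler$range == 0] <- 0
  Xs
}

#' Train an RBF-SVM target/non-target classifier
#'
#' Columns named by `mask` are selected, min-max scaled to `[0,1]` (scaler
#' fitted on the training data only and stored in the model), and passed to
#' a C-classification SVM with RBF kernel (libsvm via e1071; fixed fit
#' tolerance 1e-3, shrinking on, deterministic).
#'
#' @param X numeric feature matrix (one row per pair, catalog column order).
#' @param y labels, +1 (target) / -1 (non-target); at least 2 of each class.
#' @param mask feature (column) indices to use; nonempty.
#' @param params an [svm_params()].
#' @param catalog_version string recorded in the model.
#' @return object of class `mirtar_model`.
#' @export
train_model <- function(X, y, mask = seq_len(ncol(X)),
                        params = svm_params(8, 1 / length(mask)),
                        catalog_version = "context90/v1") {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (!all(y %in% c(-1L, 1L))) stop("labels must be +1/-1", call. = FALSE)
  if (min(table(factor(y, levels = c(-1L, 1L)))) < 2L) {
    stop("need at least 2 examples of each class", call. = FALSE)
  }
  if (length(mask) == 0L) stop("empty feature mask", call. = FALSE)
  mask <- sort(unique(as.integer(mask)))
  if (any(mask < 1L | mask > ncol(X))) {
    stop("mask column missing from feature matrix", call. = FALSE)
  }
  Xm <- X[, mask, drop = FALSE]
  scaler <- fit_scaler(Xm)
  Xs <- apply_scaler(scaler, Xm)
  yf <- factor(y, levels = c(1L, -1L))  # +1 first => decision value sign
  fit <- e1071::svm(x = Xs, y = yf, type = "C-classification",
                    kernel = "radial", cost = params$C, gamma = params$gamma,
                    scale = FALSE, tolerance = 1e-3, shrinking = TRUE)
  # libsvm orients the hyperplane by order of appearance; record a sign so
  # that positive decision value always means the +1 class
  dv <- attr(predict(fit, Xs[1, , drop = FALSE], decision.values = TRUE),
             "decision.values")
  flip <- if (grepl("^1/", colnames(dv)[1L])) 1 else -1
  structure(list(params = params, mask = mask, scaler = scaler, fit = fit,
                 flip = flip, n_features = ncol(X),
                 catalog_version = catalog_version),
            class = "mirtar_model")
}

#' @export
print.mirtar_model <- function(x, ...) {
  cat("RBF-SVM target classifier (", x$catalog_version, ")\n", sep = "")
  cat("  features: ", length(x$mask), "/", x$n_features,
      "; C = ", format(x$params$C), ", gamma = ", format(x$params$gamma),
      "; SVs = ", x$fit$tot.nSV, "\n", sep = "")
  invisible(x)
}

#' Score pairs with a trained model
#'
#' @param model a `mirtar_model`.
#' @param X full-width feature vector (length = model's catalog width) or
#'   matrix; the model applies its own mask and scaler.
#' @return numeric decision values (the prediction scores); higher means a
#'   more reliable target call.
#' @export
score_pairs <- function(model, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (ncol(X) != model$n_features) {
    stop("feature vector of length ", ncol(X), "; model expects ",
         model$n_features, call. = FALSE)
  }
  Xs <- apply_scaler(model$scaler, X[, model$mask, drop = FALSE])
  dv <- attr(predict(model$fit, Xs, decision.values = TRUE),
             "decision.values")
  as.numeric(dv[, 1L]) * model$flip
}

#' Predicted class labels (+1/-1) for pairs
#'
#' @inheritParams score_pairs
#' @return integer vector of +1/-1; a decision value of exactly 0 is -1.
#' @export
predict_class <- function(model, X) {
  ifelse(score_pairs(model, X) > 0, 1L, -1L)
}

#' Select (C, gamma) on a held-out validation set
#'
#' Trains one model per grid point on the training set and keeps the
#' parameters maximizing validation accuracy; ties go to the smallest C,
#' then the smallest gamma.
#'
#' @param X_train,y_train training data.
#' @param X_val,y_val held-out validation data (disjoint from training).
#' @param mask feature indices.
#' @param grid nonempty list of [svm_params()].
#' @return the winning `svm_params`, with the validation accuracy attached
#'   as attribute `"accuracy"`.
#' @export
grid_select <- function(X_train, y_train, X_val, y_val,
                        mask = seq_len(ncol(X_train)), grid = default_grid()) {
  if (length(grid) == 0L) stop("empty parameter grid", call. = FALSE)
  acc <- vapply(grid, function(p) {
    m <- train_model(X_train, y_train, mask, p)
    mean(predict_class(m, X_val) == y_val)
  }, numeric(1L))
  Cs <- vapply(grid, `[[`, numeric(1L), "C")
  gs <- vapply(grid, `[[`, numeric(1L), "gamma")
  best <- order(-acc, Cs, gs)[1L]
  structure(grid[[best]], accuracy = acc[best])
}

#' Save / load a trained model
#'
#' Single-file container (RDS) holding parameters, feature mask, scaler,
#' support-vector representation and catalog version; round-trips exactly.
#'
#' @param model a `mirtar_model`.
#' @param path file path.
#' @return `path` (save) or the model (load).
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "mirtar_model")) stop("not a mirtar_model file",
                                             call. = FALSE)
  model
}
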