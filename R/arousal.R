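#' Assemble the 24-dimensional arousal feature matrix
#'
#' Combines the first- and second-order time series of alpha and theta power
#' over the six frontal channels into one feature vector per second:
#' 2 orders x 2 bands x 6 channels = 24 dimensions. The second-order series
#' is shorter than the first-order series by the formation window; features
#' are built on the overlapping support using the trailing (window-end)
#' convention, i.e. the second-order value formed from first-order samples
#' `[k, k+129]` is paired with first-order sample `k+129`.
#'
#' @param alpha_1st,theta_1st first-order `power_series` (6 channels).
#' @param alpha_2nd,theta_2nd second-order `power_series` (6 channels), as
#'   produced by [second_order_series()] from the first-order inputs.
#' @return A numeric matrix (time x 24) with fixed column order
#'   `<band><order>_<channel>`; row times (seconds into the series) in
#'   attribute `time_s`.
#' @export
build_features <- function(alpha_1st, theta_1st, alpha_2nd, theta_2nd) {
  ser <- list(alpha_1st, theta_1st, alpha_2nd, theta_2nd)
  stopifnot(all(vapply(ser, inherits, TRUE, "power_series")))
  n_ch <- vapply(ser, function(s) ncol(s$values), 0L)
  if (!all(n_ch == 6L))
    stop("all series must carry the 6-channel frontal montage; got ",
         paste(n_ch, collapse = "/"), " channels")
  L1 <- nrow(alpha_1st$values)
  L2 <- nrow(alpha_2nd$values)
  if (nrow(theta_1st$values) != L1 || nrow(theta_2nd$values) != L2)
    stop("alpha and theta series lengths disagree")
  offset <- L1 - L2                     # formation-window lag (129 at defaults)
  if (offset < 0) stop("second-order series longer than first-order series")
  if (L2 < 1) stop("empty overlap between first- and second-order series")
  keep1 <- (offset + 1):L1
  labels <- function(prefix, s) paste0(prefix, "_", colnames(s$values))
  X <- cbind(alpha_1st$values[keep1, , drop = FALSE],
             theta_1st$values[keep1, , drop = FALSE],
             alpha_2nd$values, theta_2nd$values)
  colnames(X) <- c(labels("alpha1", alpha_1st), labels("theta1", theta_1st),
                   labels("alpha2", alpha_2nd), labels("theta2", theta_2nd))
  attr(X, "time_s") <- alpha_1st$t0_s + (keep1 - 1) / alpha_1st$fs_series
  X
}

#' Z-transform features within a scope
#'
#' Standardizes each feature dimension to zero mean and unit variance within
#' each scope group (the protocol normalizes per participant and task, so group
#' by participant-task identifiers). Zero-variance dimensions are flagged
#' with a warning and passed through as zeros.
#'
#' @param X numeric feature matrix (rows = time points).
#' @param groups optional grouping vector (length `nrow(X)`); `NULL`
#'   standardizes globally.
#' @return The standardized matrix.
#' @export
z_normalize <- function(X, groups = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 vectors to standardize")
  zscale <- function(M) {
    mu <- colMeans(M)
    sdv <- apply(M, 2, sd)
    flat <- sdv < .Machine$double.eps
    if (any(flat)) {
      warning("zero-variance feature dimension(s): ",
              paste(colnames(M)[flat], collapse = ", "), "; set to 0")
      sdv[flat] <- 1
      M[, flat] <- mu[flat]              # becomes 0 after centering
    }
    sweep(sweep(M, 2, mu), 2, sdv, "/")
  }
  if (is.null(groups)) return(zscale(X))
  stopifnot(length(groups) == nrow(X))
  for (g in unique(groups)) {
    i <- which(groups == g)
    if (length(i) < 2) stop("scope group '", g, "' has fewer than 2 vectors")
    X[i, ] <- zscale(X[i, , drop = FALSE])
  }
  X
}

#' Train the arousal classifier with leave-one-person-out validation
#'
#' Gaussian-kernel support-vector machine on (z-normalized) feature vectors,
#' validated by leaving out all vectors of one participant per fold — the
#' guard against a model memorizing participant identity. The returned
#' bundle contains the final model refit on all participants plus the
#' per-fold held-out accuracies.
#'
#' @param X feature matrix (time points x dimensions), already z-normalized
#'   within the scope that will also be used at estimation time.
#' @param labels factor or character vector of `"high"`/`"low"` arousal.
#' @param participants participant identifier per row.
#' @param cost SVM cost parameter C (default 1).
#' @param gamma Gaussian kernel width (default `1 / ncol(X)`).
#' @return An `arousal_model`: `model` (final fit), `fold_accuracy` (named by
#'   participant), `mean_accuracy`, `folds` (held-out row indices).
#' @export
train_lopo <- function(X, labels, participants, cost = 1,
                       gamma = 1 / ncol(X)) {
  X <- as.matrix(X)
  labels <- factor(labels, levels = c("low", "high"))
  stopifnot(nrow(X) == length(labels), nrow(X) == length(participants))
  ids <- unique(participants)
  if (length(ids) < 3)
    stop("leave-one-person-out validation needs >= 3 participants")
  folds <- lapply(ids, function(id) which(participants == id))
  names(folds) <- ids
  acc <- vapply(ids, function(id) {
    test <- folds[[id]]
    train <- setdiff(seq_len(nrow(X)), test)
    if (nlevels(droplevels(labels[train])) < 2)
      stop("training fold for held-out participant '", id,
           "' contains a single class")
    fit <- e1071::svm(X[train, , drop = FALSE], labels[train],
                      kernel = "radial", cost = cost, gamma = gamma,
                      scale = FALSE)
    mean(predict(fit, X[test, , drop = FALSE]) == labels[test])
  }, numeric(1))
  final <- e1071::svm(X, labels, kernel = "radial", cost = cost,
                      gamma = gamma, scale = FALSE)
  structure(list(model = final, fold_accuracy = acc,
                 mean_accuracy = mean(acc), folds = folds,
                 cost = cost, gamma = gamma),
            class = "arousal_model")
}

#' @export
print.arousal_model <- function(x, ...) {
  cat(sprintf("<arousal_model> Gaussian-kernel SVM (C = %g, gamma = %g)\n",
              x$cost, x$gamma))
  cat(sprintf("  LOPO accuracy: mean %.3f over %d folds\n",
              x$mean_accuracy, length(x$fold_accuracy)))
  invisible(x)
}

#' Per-second arousal classification of a task run
#'
#' Applies a trained model to a feature matrix (z-normalized with the same
#' scope rule used in training) and reports the per-second decisions and the
#' high-arousal time portion — the fraction of classified seconds labelled
#' high.
#'
#' @param model an `arousal_model` from [train_lopo()].
#' @param X feature matrix.
#' @return An `arousal_trace`: `decisions` (factor per second),
#'   `high_portion`.
#' @export
estimate_trace <- function(model, X) {
  stopifnot(inherits(model, "arousal_model"))
  X <- as.matrix(X)
  if (ncol(X) != ncol(model$model$SV))
    stop("feature dimension (", ncol(X), ") does not match the model (",
         ncol(model$model$SV), ")")
  dec <- predict(model$model, X)
  structure(list(decisions = dec,
                 high_portion = mean(dec == "high")),
            class = "arousal_trace")
}

#' @export
print.arousal_trace <- function(x, ...) {
  cat(sprintf("<arousal_trace> %d s classified, high-arousal portion %.3f\n",
              length(x$decisions), x$high_portion))
  invisible(x)
}
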