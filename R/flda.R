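#' Fit Fisher's linear discriminant
#'
#' Two-class Fisher discriminant from scratch:
#' `w = (S_w + ridge * I)^{-1} (m_a - m_b)` with `S_w` the sum of the two
#' within-class scatter matrices and `m_a`, `m_b` the class means. The
#' decision threshold is the midpoint of the projected class means (equal
#' priors; the block design is balanced). Classification is by side of the
#' threshold.
#'
#' @param class_a matrix (n_a x d) of feature vectors for class A
#' @param class_b matrix (n_b x d) for class B
#' @param ridge ridge regularization added to the scatter diagonal
#'   (default 1e-8, a numerical guard)
#' @return object of class `flda_model` with `weights`, `threshold`,
#'   `class_order`, `ridge`
#' @export
flda_fit <- function(class_a, class_b, ridge = 1e-8) {
  class_a <- as.matrix(class_a)
  class_b <- as.matrix(class_b)
  stopifnot(ncol(class_a) == ncol(class_b))
  if (nrow(class_a) < 2 || nrow(class_b) < 2)
    stop("each class needs at least 2 samples")
  d <- ncol(class_a)
  ma <- colMeans(class_a)
  mb <- colMeans(class_b)
  Sw <- crossprod(sweep(class_a, 2, ma)) + crossprod(sweep(class_b, 2, mb))
  A <- Sw + diag(ridge, d)
  w <- tryCatch(solve(A, ma - mb), error = function(e) {
    if (ridge == 0)
      stop("singular within-class scatter; refit with a nonzero ridge")
    stop(e)
  })
  pa <- sum(w * ma)
  pb <- sum(w * mb)
  structure(list(weights = w, threshold = (pa + pb) / 2,
                 class_order = c(a = sign(pa - (pa + pb) / 2)),
                 proj_mean_a = pa, proj_mean_b = pb, ridge = ridge),
            class = "flda_model")
}

#' Classify feature vectors with a fitted discriminant
#'
#' @param object an `flda_model`
#' @param newdata matrix (n x d) of feature vectors
#' @param ... unused
#' @return character vector of `"a"` / `"b"` labels; ties on the threshold
#'   go to class A's side deterministically
#' @export
predict.flda_model <- function(object, newdata, ...) {
  proj <- as.matrix(newdata) %*% object$weights
  a_side <- sign(object$proj_mean_a - object$threshold)
  if (a_side == 0) a_side <- 1  # degenerate: identical projected means
  ifelse((proj - object$threshold) * a_side >= 0, "a", "b")
}

#' Leave-one-out cross-validated accuracy of the discriminant
#'
#' Each trial is classified by a model trained on all remaining trials;
#' accuracy is the fraction classified correctly, hence always an exact
#' multiple of `1/n`.
#'
#' @param X matrix (n x d) of feature vectors
#' @param y two-level label vector, length n, at least 2 trials per class
#' @param ridge passed to [flda_fit()]
#' @return accuracy fraction in \code{[0, 1]}
#' @export
loocv_accuracy <- function(X, y, ridge = 1e-8) {
  X <- as.matrix(X)
  y <- as.character(y)
  lev <- unique(y)
  stopifnot(length(lev) == 2)
  if (min(table(y)) < 2) stop("need at least 2 trials per class")
  n <- nrow(X)
  correct <- 0L
  for (i in seq_len(n)) {
    tr_a <- X[-i, , drop = FALSE][y[-i] == lev[1], , drop = FALSE]
    tr_b <- X[-i, , drop = FALSE][y[-i] == lev[2], , drop = FALSE]
    if (nrow(tr_a) == 0 || nrow(tr_b) == 0)
      stop("a leave-one-out fold has an empty class")
    fit <- flda_fit(tr_a, tr_b, ridge)
    pred <- predict(fit, X[i, , drop = FALSE])
    truth <- if (y[i] == lev[1]) "a" else "b"
    if (pred == truth) correct <- correct + 1L
  }
  correct / n
}

#' Enumerate non-empty feature subsets
#'
#' The 15 non-empty subsets of \{mean, variance, skewness, kurtosis\},
#' ordered by size then lexicographically by feature index — the order in
#' which ties are broken (smaller models first).
#'
#' @return list of integer vectors indexing the features in the order
#'   mean, variance, skewness, kurtosis
#' @export
feature_subsets <- function() {
  subs <- list()
  for (size in 1:4) {
    cmb <- utils::combn(4, size)
    for (j in seq_len(ncol(cmb))) subs[[length(subs) + 1]] <- cmb[, j]
  }
  subs
}

#' Exhaustive search over channel, window and feature subset
#'
#' Evaluates every combination of channel, analysis window and non-empty
#' feature subset by leave-one-out cross-validated Fisher discriminant
#' accuracy, and returns the best-performing combination. With the default
#' grids the space has `3 * 93 * 15 = 4185` combinations. Combinations
#' whose features are undefined for any trial (zero within-window spread)
#' are skipped and logged.
#'
#' Ties on accuracy are broken deterministically, preferring the simplest
#' model: fewer features, then shorter window, then earlier start, then
#' lower channel index.
#'
#' @param epochs a `trial_epochs` object
#' @param windows window grid (default [enumerate_windows()])
#' @param ridge ridge regularization (default 1e-8)
#' @param chromophore `"o2hb"` (default) or `"hhb"`
#' @param engine `"cpp"` (default, compiled) or `"r"` (reference path via
#'   [loocv_accuracy()]); both give identical results
#' @return object of class `search_result`: `best` (channel, start, end,
#'   features, accuracy), `accuracy`, `n_trials`, `tie_set`, and the full
#'   `per_combination` table
#' @export
exhaustive_search <- function(epochs, windows = enumerate_windows(),
                              ridge = 1e-8, chromophore = "o2hb",
                              engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  stopifnot(inherits(epochs, "trial_epochs"))
  y <- as.character(epochs$condition)
  lev <- sort(unique(y))
  stopifnot(length(lev) == 2)
  yi <- as.integer(y == lev[2])
  subs <- feature_subsets()
  n_trials <- length(y)
  rows <- vector("list", epochs$n_channels * nrow(windows))
  k <- 0L
  for (ch in seq_len(epochs$n_channels)) {
    for (w in seq_len(nrow(windows))) {
      fm <- feature_matrix(epochs, ch, windows[w, ], chromophore)
      acc <- if (engine == "cpp") {
        loocv_subsets_cpp(fm, yi, subs, ridge)
      } else {
        vapply(subs, function(sel) {
          Xs <- fm[, sel, drop = FALSE]
          if (any(!is.finite(Xs))) return(NA_real_)
          loocv_accuracy(Xs, y, ridge)
        }, numeric(1))
      }
      k <- k + 1L
      rows[[k]] <- data.frame(
        channel = ch, start_s = windows$start[w], end_s = windows$end[w],
        subset_id = seq_along(subs),
        n_features = vapply(subs, length, integer(1)),
        features = vapply(subs, function(s) paste(FEATURE_NAMES[s], collapse = ";"),
                          character(1)),
        accuracy = acc, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  skipped <- sum(is.na(tab$accuracy))
  ok <- tab[!is.na(tab$accuracy), ]
  if (nrow(ok) == 0) stop("all combinations were rejected (undefined features)")
  best_acc <- max(ok$accuracy)
  tie_set <- ok[ok$accuracy == best_acc, ]
  ord <- order(tie_set$n_features, tie_set$end_s - tie_set$start_s,
               tie_set$start_s, tie_set$channel, tie_set$subset_id)
  tie_set <- tie_set[ord, ]
  rownames(tie_set) <- NULL
  structure(list(best = tie_set[1, ], accuracy = best_acc,
                 n_trials = n_trials, tie_set = tie_set,
                 per_combination = tab, n_skipped = skipped,
                 class_levels = lev, ridge = ridge),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  b <- x$best
  cat("<search_result> best: channel ", b$channel, ", ", b$start_s, "-", b$end_s,
      " s, {", b$features, "}: accuracy ",
      sprintf("%.1f%%", 100 * x$accuracy),
      " (", round(x$accuracy * x$n_trials), "/", x$n_trials, "; ",
      nrow(x$tie_set), " tied)\n", sep = "")
  invisible(x)
}
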