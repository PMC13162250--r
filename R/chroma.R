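#' Silhouette statistics of labelled chromaticity points
#'
#' Standard silhouette values with Euclidean distance: for point i,
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` where `a(i)` is the mean
#' distance to the other points of its own class and `b(i)` the smallest
#' mean distance to another class (singleton clusters get `s = 0`).
#' Summaries per class (mean, median, interquartile range, fraction of
#' positive silhouettes, n), the size-weighted mean over all points, and a
#' 95% normal-approximation confidence interval for the weighted mean using
#' the pooled standard error `sd(s) / sqrt(n)`.
#'
#' @param points numeric matrix or data frame with two columns (r, g).
#' @param labels class labels, at least two distinct with >= 1 point each.
#' @return an object of class `silhouette_report`: list with `per_class`
#'   data frame, `weighted_mean`, `ci95` (length-2 vector), `n`, and the
#'   per-point values `s`.
#' @export
silhouette_stats <- function(points, labels) {
  pts <- as.matrix(points[, 1:2])
  labels <- as.character(labels)
  stopifnot(nrow(pts) == length(labels))
  classes <- unique(labels)
  if (length(classes) < 2)
    stop("silhouette requires at least two classes")
  n <- nrow(pts)
  D <- as.matrix(stats::dist(pts))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    n_own <- sum(own) - 1
    if (n_own == 0) { s[i] <- 0; next }
    a <- sum(D[i, own]) / n_own
    b <- min(vapply(classes[classes != labels[i]],
                    function(cl) mean(D[i, labels == cl]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    v <- s[labels == cl]
    data.frame(class = cl, n = length(v), mean = mean(v),
               median = stats::median(v), iqr = stats::IQR(v),
               frac_positive = mean(v > 0))
  }))
  wm <- sum(per_class$n * per_class$mean) / sum(per_class$n)
  se <- stats::sd(s) / sqrt(n)
  structure(list(per_class = per_class, weighted_mean = wm,
                 ci95 = wm + c(-1, 1) * 1.96 * se, n = n, s = s),
            class = "silhouette_report")
}

#' @export
print.silhouette_report <- function(x, ...) {
  cat(sprintf("Weighted mean silhouette: %.3f (95%% CI %.3f-%.3f, n = %d)\n",
              x$weighted_mean, x$ci95[1], x$ci95[2], x$n))
  print(transform(x$per_class, mean = round(mean, 3), median = round(median, 3),
                  iqr = round(iqr, 3), frac_positive = round(frac_positive, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Pairwise Mahalanobis distances between class centroids
#'
#' `D(i, j) = sqrt((mu_i - mu_j)' S^-1 (mu_i - mu_j))` with `S` the pooled
#' within-class covariance.  A near-singular `S` is ridge-regularised; a
#' still-singular one is rejected.
#'
#' @param points numeric matrix or data frame with two columns (r, g).
#' @param labels class labels.
#' @return symmetric distance matrix with zero diagonal, classes as
#'   dimnames.
#' @export
mahalanobis_distances <- function(points, labels) {
  pts <- as.matrix(points[, 1:2])
  labels <- as.character(labels)
  classes <- unique(labels)
  stopifnot(length(classes) >= 2)
  k <- length(classes)
  mu <- t(vapply(classes, function(cl) colMeans(pts[labels == cl, , drop = FALSE]),
                 numeric(ncol(pts))))
  S <- matrix(0, ncol(pts), ncol(pts))
  for (cl in classes) {
    xc <- sweep(pts[labels == cl, , drop = FALSE], 2, mu[match(cl, classes), ])
    S <- S + crossprod(xc)
  }
  S <- S / max(nrow(pts) - k, 1)
  if (rcond(S) < 1e-10)
    S <- S + diag(ncol(pts)) * 1e-8 * max(sum(diag(S)), 1e-12)
  if (rcond(S) < 1e-12) stop("pooled covariance is singular")
  Sinv <- solve(S)
  D <- matrix(0, k, k, dimnames = list(classes, classes))
  for (i in seq_len(k - 1))
    for (j in (i + 1):k) {
      d <- mu[i, ] - mu[j, ]
      D[i, j] <- D[j, i] <- sqrt(drop(t(d) %*% Sinv %*% d))
    }
  D
}
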