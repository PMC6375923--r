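#' Pearson correlation matrix of a composition matrix
#'
#' @param m Numeric matrix, samples x categories.
#' @return Symmetric correlation matrix with unit diagonal. Zero-variance
#'   categories yield \code{NA} correlations (with a warning).
#' @export
correlation_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 3) stop("need at least 3 samples")
  v <- apply(m, 2, stats::var)
  if (any(v == 0))
    warning("zero-variance categor", if (sum(v == 0) > 1) "ies" else "y",
            " (", paste(colnames(m)[v == 0], collapse = ", "),
            "): correlations reported as NA")
  suppressWarnings(stats::cor(m))
}

#' Principal component analysis of a composition matrix
#'
#' Columns are centred and, by default, scaled to unit variance before the
#' eigendecomposition (\code{stats::prcomp}). For reproducibility across
#' linear-algebra backends each loading vector is oriented so that its
#' largest-magnitude entry is positive.
#'
#' @param m Numeric matrix, samples x categories.
#' @param scaling \code{"unit"} (default; autoscaling, appropriate for
#'   concentration categories of very different magnitude) or
#'   \code{"none"} (covariance PCA).
#' @param n_components Number of components to keep; truncated with a
#'   warning if more are requested than \code{min(samples - 1,
#'   categories)}.
#' @return A \code{pca_result} list: \code{scores} (samples x components),
#'   \code{loadings} (categories x components, orthonormal),
#'   \code{explained} (variance fractions, non-increasing),
#'   \code{scaling}.
#' @export
composition_pca <- function(m, scaling = c("unit", "none"),
                            n_components = NULL) {
  scaling <- match.arg(scaling)
  m <- as.matrix(m)
  if (nrow(m) < 2) stop("need more than one sample")
  max_pc <- min(nrow(m) - 1, ncol(m))
  if (is.null(n_components)) n_components <- max_pc
  if (n_components > max_pc) {
    warning("only ", max_pc, " components are estimable; truncating")
    n_components <- max_pc
  }
  if (scaling == "unit") {
    v <- apply(m, 2, stats::var)
    if (any(v == 0))
      stop("zero-variance categories cannot be unit-variance scaled: ",
           paste(colnames(m)[v == 0], collapse = ", "))
  }
  p <- stats::prcomp(m, center = TRUE, scale. = scaling == "unit")
  keep <- seq_len(n_components)
  load <- p$rotation[, keep, drop = FALSE]
  scores <- p$x[, keep, drop = FALSE]
  ## sign convention: largest-|loading| entry of each component positive
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  expl <- p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = scores, loadings = load,
                 explained = expl[keep], scaling = scaling,
                 center = p$center,
                 scale = if (scaling == "unit") p$scale else NULL),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cum <- cumsum(x$explained)
  cat(sprintf("PCA (%s scaling): %d components\n", x$scaling,
              ncol(x$scores)))
  for (j in seq_along(x$explained))
    cat(sprintf("  PC%d: %.1f%% (cumulative %.1f%%)\n", j,
                100 * x$explained[j], 100 * cum[j]))
  invisible(x)
}
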