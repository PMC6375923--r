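## Full second-order model in coded units:
##   y = b0 + sum_i b_i X_i + sum_i b_ii X_i^2 + sum_{i<j} b_ij X_i X_j
## Coefficients are stored as one named vector in the fixed order
## (Intercept), X1..Xk, X1^2..Xk^2, X1:X2, X1:X3, ..., X(k-1):Xk.

quad_term_names <- function(k, fnames = paste0("X", seq_len(k))) {
  inter <- if (k >= 2)
    apply(utils::combn(fnames, 2), 2, paste, collapse = ":")
  else character(0)
  c("(Intercept)", fnames, paste0(fnames, "^2"), inter)
}

#' Construct a quadratic response-surface model from literal coefficients
#'
#' Use this to evaluate a published second-order polynomial without
#' refitting, e.g. \code{quadratic_model(1737.8, c(-106.1, 43.8),
#' c(-86.9, -6.8), 47.3)}.
#'
#' @param intercept Intercept \eqn{b_0}.
#' @param linear Length-\eqn{k} vector of linear coefficients \eqn{b_i}.
#' @param quadratic Length-\eqn{k} vector of pure quadratic coefficients
#'   \eqn{b_{ii}}.
#' @param interaction Vector of \eqn{k(k-1)/2} interaction coefficients
#'   \eqn{b_{ij}} in column-major pair order (for \eqn{k=2}: a single
#'   number).
#' @param factor_names Coded factor names; default \code{X1..Xk}.
#' @return An object of class \code{quadratic_model}.
#' @export
quadratic_model <- function(intercept, linear, quadratic,
                            interaction = numeric(0),
                            factor_names = paste0("X", seq_along(linear))) {
  k <- length(linear)
  stopifnot(length(quadratic) == k, length(interaction) == k * (k - 1) / 2)
  beta <- c(intercept, linear, quadratic, interaction)
  names(beta) <- quad_term_names(k, factor_names)
  structure(list(coefficients = beta, k = k, factor_names = factor_names,
                 se = NULL, p_values = NULL, sigma2 = NA_real_,
                 df_residual = NA_integer_, vcov = NULL),
            class = "quadratic_model")
}

#' Fit the full quadratic surface to a designed experiment
#'
#' Ordinary least squares on the coded design matrix with intercept,
#' linear, pure quadratic and two-factor interaction terms. Per-coefficient
#' standard errors and two-sided t p-values against zero are reported.
#'
#' @param design A \code{design_table} (typically a central composite
#'   design) with the response attached.
#' @param response_name Response column name.
#' @return A \code{quadratic_model} with standard errors, p-values,
#'   residual variance and degrees of freedom filled in.
#' @export
fit_quadratic <- function(design, response_name) {
  if (!response_name %in% names(design))
    stop("response '", response_name, "' not found in design")
  X <- coded_matrix(design)
  k <- ncol(X)
  y <- design[[response_name]]
  if (nrow(X) <= 1 + 2 * k + k * (k - 1) / 2)
    stop("more model parameters than runs: enlarge the design")

  M <- model_matrix_quad(X)
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    keep <- qrM$pivot[seq_len(qrM$rank)]
    stop("singular design matrix; deficient term(s): ",
         paste(colnames(M)[-keep], collapse = ", "))
  }
  fit <- stats::lm.fit(M, y)
  beta <- fit$coefficients
  dfres <- fit$df.residual
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / dfres
  XtXinv <- chol2inv(qr.R(qrM))
  se <- sqrt(diag(XtXinv) * sigma2)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), dfres)
  names(se) <- names(pval) <- names(beta)

  fnames <- colnames(X)
  structure(list(coefficients = beta, k = k, factor_names = fnames,
                 se = se, p_values = pval, sigma2 = sigma2,
                 df_residual = dfres, vcov = XtXinv * sigma2),
            class = "quadratic_model")
}

model_matrix_quad <- function(X) {
  k <- ncol(X)
  fnames <- colnames(X)
  if (is.null(fnames)) fnames <- paste0("X", seq_len(k))
  inter <- if (k >= 2) {
    cb <- utils::combn(k, 2)
    sapply(seq_len(ncol(cb)), function(j) X[, cb[1, j]] * X[, cb[2, j]])
  } else NULL
  M <- cbind(1, X, X^2, inter)
  colnames(M) <- quad_term_names(k, fnames)
  M
}

#' @export
print.quadratic_model <- function(x, ...) {
  cat(sprintf("Quadratic response-surface model in %d coded factor(s)\n",
              x$k))
  tab <- data.frame(coefficient = x$coefficients)
  if (!is.null(x$se)) {
    tab$std_error <- x$se
    tab$p_value <- signif(x$p_values, 3)
  }
  print(tab, ...)
  invisible(x)
}

#' Evaluate a quadratic surface
#'
#' @param model A \code{quadratic_model}.
#' @param points Numeric vector (one point), or matrix / data frame with
#'   one row per point, in coded units.
#' @param se Logical; also return the standard deviation of the predicted
#'   mean (needs a fitted model).
#' @return Numeric vector of predictions, or a data frame with columns
#'   \code{fit} and \code{se_fit} when \code{se = TRUE}.
#' @examples
#' m <- quadratic_model(1737.8, c(-106.1, 43.8), c(-86.9, -6.8), 47.3)
#' predict_surface(m, c(0, 0))   # 1737.8
#' @export
predict_surface <- function(model, points, se = FALSE) {
  stopifnot(inherits(model, "quadratic_model"))
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  points <- as.matrix(points)
  if (ncol(points) != model$k)
    stop("points have ", ncol(points), " coordinates; model expects ",
         model$k)
  colnames(points) <- model$factor_names
  M <- model_matrix_quad(points)
  fit <- unname(drop(M %*% model$coefficients))
  if (!se) return(fit)
  if (is.null(model$vcov))
    stop("standard errors unavailable: model was built from literal ",
         "coefficients, not fitted")
  se_fit <- sqrt(rowSums((M %*% model$vcov) * M))
  data.frame(fit = fit, se_fit = se_fit)
}

region_grid <- function(k, radius, shape, step) {
  ax <- seq(-radius, radius, by = step)
  if (abs(ax[length(ax)] - radius) > 1e-12) ax <- c(ax, radius)
  g <- as.matrix(expand.grid(rep(list(ax), k)))
  if (shape == "disk") g <- g[rowSums(g^2) <= radius^2 + 1e-12, , drop = FALSE]
  g
}

#' Maximize one or several responses over the design region
#'
#' Single mode maximizes one surface by grid search (coded step
#' \code{<= 0.01}) followed by local refinement. Desirability mode
#' maximizes the geometric mean of per-response linear scalings to [0, 1]
#' (Derringer-type, all responses maximized; the min/max of each surface
#' over the region grid define the scaling). Ties are broken toward the
#' lower second coordinate (temperature), then the lower first.
#'
#' @param models A \code{quadratic_model} or list of them (all on the same
#'   factors).
#' @param radius Half-width of the square region, or disk radius, in coded
#'   units; default 1.414 (the axial distance).
#' @param shape \code{"square"} (default) or \code{"disk"}.
#' @param mode \code{"single"} or \code{"desirability"}.
#' @param step Grid step in coded units.
#' @return An \code{optimum_result} list: \code{coded} optimum,
#'   \code{predicted} response(s) there, \code{desirability} (multi-response
#'   mode), \code{shape}, \code{radius}, and \code{natural} (NULL unless
#'   \code{specs} given).
#' @param specs Optional list of \code{\link{factor_spec}} to also report
#'   the optimum in natural units.
#' @examples
#' m <- quadratic_model(14.0, c(0.35, 0.33), c(-0.63, -0.27), -0.16)
#' optimize_response(m)$coded  # about (0.208, 0.549)
#' @export
optimize_response <- function(models, radius = 1.414,
                              shape = c("square", "disk"),
                              mode = c("single", "desirability"),
                              step = 0.01, specs = NULL) {
  shape <- match.arg(shape)
  mode <- match.arg(mode)
  if (inherits(models, "quadratic_model")) models <- list(models)
  stopifnot(all(vapply(models, inherits, logical(1), "quadratic_model")))
  k <- models[[1]]$k
  fnames <- models[[1]]$factor_names

  grid <- region_grid(k, radius, shape, step)
  preds <- vapply(models, predict_surface, numeric(nrow(grid)),
                  points = grid)
  preds <- matrix(preds, nrow = nrow(grid))

  if (mode == "single") {
    score <- preds[, 1]
    desir <- NULL
  } else {
    rng <- apply(preds, 2, range)
    span <- rng[2, ] - rng[1, ]
    if (all(span < 1e-12)) {
      warning("all responses constant over the region; returning origin")
      pt <- stats::setNames(rep(0, k), fnames)
      return(optimum_result(pt, models, 1, shape, radius, specs))
    }
    d <- sweep(sweep(preds, 2, rng[1, ]), 2, pmax(span, 1e-300), "/")
    score <- exp(rowMeans(log(pmax(d, 1e-300))))
    desir <- score
  }

  if (max(score) - min(score) < 1e-12 && mode == "single") {
    warning("response constant over the region; returning origin")
    pt <- stats::setNames(rep(0, k), fnames)
    return(optimum_result(pt, models, NULL, shape, radius, specs))
  }

  ## tie-break: among near-maximal grid points prefer low 2nd then 1st coord
  best <- max(score)
  cand <- which(score >= best - 1e-12)
  if (length(cand) > 1) {
    ordcols <- if (k >= 2) list(grid[cand, 2], grid[cand, 1])
               else list(grid[cand, 1])
    cand <- cand[do.call(order, ordcols)]
  }
  x0 <- grid[cand[1], ]

  obj <- function(x) {
    p <- vapply(models, predict_surface, numeric(1), points = x)
    if (mode == "single") p[1]
    else {
      rng <- apply(preds, 2, range)
      d <- (p - rng[1, ]) / pmax(rng[2, ] - rng[1, ], 1e-300)
      d <- pmin(pmax(d, 0), 1)
      exp(mean(log(pmax(d, 1e-300))))
    }
  }
  if (shape == "square") {
    ref <- stats::optim(x0, obj, method = "L-BFGS-B",
                        lower = rep(-radius, k), upper = rep(radius, k),
                        control = list(fnscale = -1))
    xopt <- if (ref$value >= obj(x0)) ref$par else x0
  } else {
    ## disk: refine on a fine local grid clipped to the disk (the box
    ## optimizer cannot respect the circular constraint)
    loc <- sweep(region_grid(k, 2 * step, "square", step / 20), 2, x0, "+")
    loc <- loc[rowSums(loc^2) <= radius^2 + 1e-12, , drop = FALSE]
    vals <- apply(loc, 1, obj)
    xopt <- loc[which.max(vals), ]
  }
  names(xopt) <- fnames
  dval <- if (mode == "desirability") obj(xopt) else NULL
  optimum_result(xopt, models, dval, shape, radius, specs)
}

optimum_result <- function(pt, models, desirability, shape, radius, specs) {
  pred <- vapply(models, predict_surface, numeric(1), points = pt)
  pred_sd <- vapply(models, function(m) {
    if (is.null(m$vcov)) NA_real_
    else predict_surface(m, pt, se = TRUE)$se_fit
  }, numeric(1))
  natural <- if (!is.null(specs)) decode_units(pt, specs) else NULL
  structure(list(coded = pt, natural = natural, predicted = pred,
                 predicted_sd = pred_sd, desirability = desirability,
                 region = list(shape = shape, radius = radius)),
            class = "optimum_result")
}

#' @export
print.optimum_result <- function(x, ...) {
  cat(sprintf("Optimum over %s region (radius %.3f coded units)\n",
              x$region$shape, x$region$radius))
  cat("  coded: ", paste(sprintf("%s = %.3f", names(x$coded), x$coded),
                         collapse = ", "), "\n")
  if (!is.null(x$natural))
    cat("  natural: ", paste(sprintf("%s = %.3f", names(x$natural),
                                     x$natural), collapse = ", "), "\n")
  cat("  predicted:", paste(sprintf("%.4g", x$predicted), collapse = ", "),
      "\n")
  if (!is.null(x$desirability))
    cat("  desirability:", sprintf("%.4f", x$desirability), "\n")
  invisible(x)
}

#' Closed-form stationary point of a quadratic surface
#'
#' Solves the gradient system of the second-order polynomial; useful as an
#' analytic cross-check of the numeric optimizer when the stationary point
#' is an interior maximum.
#'
#' @param model A \code{quadratic_model}.
#' @return Named coded coordinates of the stationary point.
#' @export
stationary_point <- function(model) {
  k <- model$k
  b <- model$coefficients
  lin <- b[1 + seq_len(k)]
  quad <- b[1 + k + seq_len(k)]
  B <- diag(quad, k, k)
  if (k >= 2) {
    cb <- utils::combn(k, 2)
    inter <- b[1 + 2 * k + seq_len(ncol(cb))]
    for (j in seq_len(ncol(cb))) {
      B[cb[1, j], cb[2, j]] <- inter[j] / 2
      B[cb[2, j], cb[1, j]] <- inter[j] / 2
    }
  }
  xs <- drop(solve(2 * B, -lin))
  stats::setNames(xs, model$factor_names)
}

#' Compare a predicted optimum with verification experiments
#'
#' Welch's two-sample t-test assembled from summary statistics, plus the
#' absolute percent difference \eqn{|pred - exp| / pred \times 100}.
#'
#' @param predicted_mean,predicted_sd Model prediction and its standard
#'   deviation.
#' @param experimental_mean,experimental_sd,n_experimental Verification
#'   replicate summary (\code{n_experimental >= 2}).
#' @param n_predicted Nominal n for the predicted side (default 3).
#' @return A \code{verification_result} list with \code{t}, \code{df},
#'   \code{p_value}, \code{percent_difference} and the inputs.
#' @examples
#' verify_optimum(356.6, 3.6, 354.4, 3.2, 3)
#' @export
verify_optimum <- function(predicted_mean, predicted_sd,
                           experimental_mean, experimental_sd,
                           n_experimental, n_predicted = 3) {
  stopifnot(predicted_sd >= 0, experimental_sd >= 0, n_experimental >= 2)
  v1 <- predicted_sd^2 / n_predicted
  v2 <- experimental_sd^2 / n_experimental
  if (v1 + v2 == 0) {
    tstat <- if (predicted_mean == experimental_mean) 0 else Inf
    df <- n_predicted + n_experimental - 2
    p <- if (tstat == 0) 1 else 0
  } else {
    tstat <- (predicted_mean - experimental_mean) / sqrt(v1 + v2)
    df <- (v1 + v2)^2 /
      (v1^2 / (n_predicted - 1) + v2^2 / (n_experimental - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  pct <- abs(predicted_mean - experimental_mean) / abs(predicted_mean) * 100
  structure(list(predicted_mean = predicted_mean,
                 predicted_sd = predicted_sd,
                 experimental_mean = experimental_mean,
                 experimental_sd = experimental_sd,
                 n_experimental = n_experimental,
                 n_predicted = n_predicted,
                 t = tstat, df = df, p_value = p,
                 percent_difference = pct),
            class = "verification_result")
}

#' @export
print.verification_result <- function(x, ...) {
  cat(sprintf("Predicted %.4g +/- %.3g vs experimental %.4g +/- %.3g (n=%d)\n",
              x$predicted_mean, x$predicted_sd, x$experimental_mean,
              x$experimental_sd, x$n_experimental))
  cat(sprintf("  Welch t = %.3f (df %.1f), p = %.4f; %%difference = %.2f%%\n",
              x$t, x$df, x$p_value, x$percent_difference))
  invisible(x)
}
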