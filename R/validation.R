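## exact lines are legitimate degenerate inputs here; keep stats::summary.lm
## from warning about them
quiet_perfect_fit <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

#' Fit a linear calibration curve
#'
#' Ordinary least squares of detector response (peak area) on
#' concentration, with the ICH-style linearity diagnostics: r-squared, 95%
#' confidence intervals and two-sided t-tests (alpha = 0.05, N - 2 dof) of
#' slope and intercept against zero, and per-level replicate %RSD screened
#' against 5%.
#'
#' @param data Data frame with columns \code{conc} (µg/mL) and \code{area};
#'   an optional \code{replicate} column is ignored (replicates are simply
#'   extra rows).
#' @param rsd_screen Per-level %RSD acceptance screen (default 5).
#' @return A \code{calibration_fit} list: \code{slope}, \code{intercept},
#'   their \code{se}, \code{ci} (95%), \code{p} values, \code{r_squared},
#'   \code{sigma_intercept}, per-level RSD table, \code{n}, residual dof.
#' @examples
#' d <- data.frame(conc = 1:5, area = 2 * (1:5) + 1)
#' fit_calibration(d)$slope  # 2
#' @export
fit_calibration <- function(data, rsd_screen = 5) {
  stopifnot(all(c("conc", "area") %in% names(data)))
  lev <- unique(data$conc)
  if (length(lev) < 2) stop("need at least 2 distinct concentration levels")
  if (stats::var(data$conc) == 0) stop("zero variance in concentration")
  if (length(lev) < 5)
    warning("fewer than 5 calibration levels; ICH recommends n >= 5")

  fit <- stats::lm(area ~ conc, data = data)
  sm <- quiet_perfect_fit(summary(fit))
  coefs <- sm$coefficients
  n <- nrow(data)
  dof <- fit$df.residual
  tcrit <- stats::qt(0.975, dof)
  ci <- cbind(coefs[, 1] - tcrit * coefs[, 2],
              coefs[, 1] + tcrit * coefs[, 2])

  level_rsd <- do.call(rbind, lapply(split(data$area, data$conc), function(a) {
    data.frame(n = length(a),
               rsd_pct = if (length(a) >= 2 && mean(a) != 0)
                 stats::sd(a) / abs(mean(a)) * 100 else NA_real_)
  }))
  level_rsd <- data.frame(conc = as.numeric(rownames(level_rsd)), level_rsd,
                          row.names = NULL)
  level_rsd$pass <- is.na(level_rsd$rsd_pct) | level_rsd$rsd_pct <= rsd_screen

  structure(list(slope = unname(coefs["conc", 1]),
                 intercept = unname(coefs["(Intercept)", 1]),
                 se_slope = unname(coefs["conc", 2]),
                 sigma_intercept = unname(coefs["(Intercept)", 2]),
                 ci_slope = unname(ci["conc", ]),
                 ci_intercept = unname(ci["(Intercept)", ]),
                 p_slope = unname(coefs["conc", 4]),
                 p_intercept = unname(coefs["(Intercept)", 4]),
                 r_squared = sm$r.squared,
                 residual_sd = sm$sigma,
                 level_rsd = level_rsd,
                 n = n, df_residual = dof),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Calibration: area = %.4g x conc %+.4g  (r^2 = %.5f, N = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  cat(sprintf("  intercept 95%% CI [%.4g, %.4g], p = %.3g%s\n",
              x$ci_intercept[1], x$ci_intercept[2], x$p_intercept,
              if (x$ci_intercept[1] <= 0 && x$ci_intercept[2] >= 0)
                " (includes 0)" else ""))
  invisible(x)
}

#' Mandel's fitting test for linearity
#'
#' Compares the residual standard deviations of first-order
#' (\eqn{s_{lin}}, N - 2 dof) and second-order (\eqn{s_{quad}}, N - 3 dof)
#' calibration fits through the variance difference
#' \eqn{DS^2 = (N-2)s_{lin}^2 - (N-3)s_{quad}^2} and the test statistic
#' \eqn{F = DS^2 / s_{quad}^2}, referred to \eqn{F(1-\alpha; 1, N-3)}.
#' The quadratic model is preferred iff \eqn{F} exceeds the critical value.
#'
#' @param data Data frame with columns \code{conc} and \code{area}.
#' @param alpha Significance level (default 0.01).
#' @return A \code{mandel_result} list: \code{s_lin}, \code{s_quad},
#'   \code{ds2}, \code{F}, \code{f_critical}, \code{decision}
#'   (\code{"linear"} or \code{"quadratic"}), \code{n}, \code{alpha}.
#' @export
mandel_test <- function(data, alpha = 0.01) {
  stopifnot(all(c("conc", "area") %in% names(data)))
  n <- nrow(data)
  if (n < 4) stop("Mandel's test needs at least 4 points")
  f1 <- stats::lm(area ~ conc, data = data)
  f2 <- stats::lm(area ~ conc + I(conc^2), data = data)
  s_lin <- quiet_perfect_fit(summary(f1)$sigma)
  s_quad <- quiet_perfect_fit(summary(f2)$sigma)
  ds2 <- (n - 2) * s_lin^2 - (n - 3) * s_quad^2
  fcrit <- stats::qf(1 - alpha, 1, n - 3)
  if (s_lin <= 1e-10 * max(1, stats::sd(data$area))) {
    ## numerically perfect first-order fit: linear by convention
    Fstat <- 0
    decision <- "linear"
  } else if (s_quad == 0) {
    if (ds2 > 1e-10 * max(1, s_lin^2)) {
      Fstat <- Inf
      decision <- "quadratic"
    } else {
      Fstat <- 0
      decision <- "linear"
    }
  } else {
    Fstat <- max(0, ds2 / s_quad^2)
    decision <- if (Fstat > fcrit) "quadratic" else "linear"
  }
  structure(list(s_lin = s_lin, s_quad = s_quad, ds2 = ds2, F = Fstat,
                 f_critical = fcrit, decision = decision, n = n,
                 alpha = alpha),
            class = "mandel_result")
}

#' @export
print.mandel_result <- function(x, ...) {
  cat(sprintf(
    "Mandel's fitting test (alpha %.3g): F = %.3f vs critical %.3f -> %s\n",
    x$alpha, x$F, x$f_critical, x$decision))
  invisible(x)
}

#' Cochran's C test for homogeneity of variances
#'
#' \eqn{C = s^2_{max} / \sum_j s^2_j} over \eqn{k} balanced groups of
#' \eqn{n} replicates. The critical value uses the exact closed form
#' \eqn{C_{crit} = [1 + (k-1)/F(1-\alpha/k;\, \nu, (k-1)\nu)]^{-1}} with
#' \eqn{\nu = n - 1}.
#'
#' @param group_variances Numeric vector of group variances (or a list /
#'   data frame of raw replicate vectors via \code{groups}).
#' @param n_per_group Replicates per group (equal replication required).
#' @param alpha Significance level (default 0.05).
#' @return A \code{cochran_result} list: \code{C}, \code{c_critical},
#'   \code{k}, \code{n_per_group}, \code{homogeneous}.
#' @examples
#' cochran_c(c(3, 1, 1, 1), n_per_group = 6)$C  # 0.5
#' @export
cochran_c <- function(group_variances, n_per_group, alpha = 0.05) {
  v <- as.numeric(group_variances)
  k <- length(v)
  if (k < 2) stop("need at least 2 groups")
  if (any(v < 0)) stop("variances must be non-negative")
  nu <- n_per_group - 1
  if (nu < 1) stop("need at least 2 replicates per group")
  ccrit <- 1 / (1 + (k - 1) / stats::qf(1 - alpha / k, nu, (k - 1) * nu))
  if (sum(v) == 0) {
    C <- NA_real_
    homog <- TRUE  # all-zero variances: trivially homogeneous
  } else {
    C <- max(v) / sum(v)
    homog <- C <= ccrit
  }
  structure(list(C = C, c_critical = ccrit, k = k,
                 n_per_group = n_per_group, alpha = alpha,
                 homogeneous = homog),
            class = "cochran_result")
}

#' @export
print.cochran_result <- function(x, ...) {
  cat(sprintf(
    "Cochran's C = %.4f vs critical %.4f (k=%d, n=%d): variances %s\n",
    x$C, x$c_critical, x$k, x$n_per_group,
    if (x$homogeneous) "homogeneous" else "NOT homogeneous"))
  invisible(x)
}

#' Repeatability and intermediate precision from a nested precision study
#'
#' Determinations are grouped into cells (by default day x level).
#' Repeatability is the pooled within-cell standard deviation;
#' intermediate precision adds the between-cell variance component from a
#' one-way random-effects decomposition:
#' \eqn{s_R^2 = s_r^2 + \max(0, (MS_{between} - MS_{within})/n)}.
#' Both are reported as %RSD on the grand mean, together with per-day and
#' per-level %RSDs.
#'
#' @param data Data frame with columns \code{day}, \code{level},
#'   \code{value} (one determination per row; a \code{replicate} column is
#'   allowed and ignored).
#' @return A \code{precision_result} list: \code{grand_mean}, \code{s_r2},
#'   \code{s_between2}, \code{rsd_r}, \code{rsd_R}, \code{per_day},
#'   \code{per_level}, \code{cells}.
#' @export
precision_summary <- function(data) {
  stopifnot(all(c("day", "level", "value") %in% names(data)))
  cell_id <- interaction(data$day, data$level, drop = TRUE)
  cells <- split(data$value, cell_id)
  sizes <- lengths(cells)
  if (any(sizes < 2))
    stop("every day x level cell needs at least 2 replicates ",
         "(repeatability undefined otherwise)")
  gm <- mean(data$value)
  if (gm == 0) stop("grand mean is zero; %RSD undefined")

  k <- length(cells)
  ## pooled within-cell variance (weights by cell dof; equals the mean of
  ## cell variances in the balanced case)
  s_r2 <- sum(vapply(cells, function(x) (length(x) - 1) * stats::var(x),
                     numeric(1))) / sum(sizes - 1)
  n_h <- mean(sizes)   # balanced designs: the common cell size
  means <- vapply(cells, mean, numeric(1))
  ms_between <- if (k > 1) n_h * stats::var(means) else 0
  s_b2 <- max(0, (ms_between - s_r2) / n_h)
  s_R2 <- s_r2 + s_b2

  grp_rsd <- function(g) {
    vapply(split(data$value, g), function(x)
      stats::sd(x) / abs(mean(x)) * 100, numeric(1))
  }
  structure(list(grand_mean = gm,
                 s_r2 = s_r2, s_between2 = s_b2,
                 rsd_r = sqrt(s_r2) / abs(gm) * 100,
                 rsd_R = sqrt(s_R2) / abs(gm) * 100,
                 per_day = grp_rsd(data$day),
                 per_level = grp_rsd(data$level),
                 cells = data.frame(cell = names(cells), n = as.integer(sizes),
                                    mean = unname(means),
                                    var = vapply(cells, stats::var,
                                                 numeric(1)),
                                    row.names = NULL)),
            class = "precision_result")
}

#' @export
print.precision_result <- function(x, ...) {
  cat(sprintf(
    "Precision: repeatability RSDr = %.3f%%, intermediate RSDR = %.3f%% (grand mean %.4g)\n",
    x$rsd_r, x$rsd_R, x$grand_mean))
  invisible(x)
}

#' Horwitz acceptability limits for precision
#'
#' The Horwitz function gives the maximum acceptable between-laboratory
#' %RSD as a function of the analyte mass fraction \eqn{C} (dimensionless,
#' m/m): \eqn{RSD_R = 2^{1 - 0.5 \log_{10} C}}. The repeatability limit is
#' two thirds of it.
#'
#' @param C Analyte concentration as a dimensionless mass fraction,
#'   \eqn{0 < C \le 1}.
#' @return A \code{horwitz_limits} list: \code{C}, \code{rsd_R_max},
#'   \code{rsd_r_max}.
#' @examples
#' horwitz_limits(1)         # RSD_R 2, RSD_r 4/3
#' rsd_r_from_rsd_R(5.68)    # 3.79 (2 d.p.)
#' @export
horwitz_limits <- function(C) {
  if (any(C <= 0)) stop("mass fraction C must be positive")
  if (any(C > 1)) stop("C is a mass fraction and cannot exceed 1")
  rsdR <- 2^(1 - 0.5 * log10(C))
  structure(list(C = C, rsd_R_max = rsdR, rsd_r_max = 2 / 3 * rsdR),
            class = "horwitz_limits")
}

#' @rdname horwitz_limits
#' @param rsd_R An intermediate-precision %RSD (observed or a Horwitz
#'   limit); returns the corresponding repeatability limit \eqn{2/3 \times
#'   RSD_R}.
#' @export
rsd_r_from_rsd_R <- function(rsd_R) 2 / 3 * rsd_R

#' Recovery-based accuracy summary
#'
#' Mean recovery is the unweighted mean of the spike-level recoveries when
#' one value per level is given, or of all raw replicates when replicates
#' are present. The 95% CI is t-based on the averaged values. Three
#' acceptance flags are reported: CI contains 100%, mean within
#' [98, 102]%, and %RSD at or below a repeatability reference (if given).
#'
#' @param data Data frame with columns \code{level} (spike level, e.g. 75 /
#'   100 / 125) and \code{recovery} (percent); multiple rows per level are
#'   treated as replicates.
#' @param rsd_r_reference Optional repeatability %RSD to screen the
#'   recovery %RSD against.
#' @return A \code{recovery_result} list: \code{per_level}, \code{mean},
#'   \code{rsd_pct}, \code{ci}, \code{pass} (named logical vector).
#' @examples
#' recovery_stats(data.frame(level = c(75, 100, 125),
#'                           recovery = c(101.41, 100.10, 99.96)))$mean
#' @export
recovery_stats <- function(data, rsd_r_reference = NULL) {
  stopifnot(all(c("level", "recovery") %in% names(data)))
  if (length(unique(data$level)) < 2) stop("need at least 2 spike levels")
  if (any(data$recovery <= 0)) stop("recoveries must be positive")
  per_level <- vapply(split(data$recovery, data$level), mean, numeric(1))
  vals <- if (anyDuplicated(data$level)) data$recovery else per_level
  m <- mean(vals)
  s <- stats::sd(vals)
  rsd <- s / m * 100
  ci <- m + c(-1, 1) * stats::qt(0.975, length(vals) - 1) *
    s / sqrt(length(vals))
  pass <- c(ci_contains_100 = ci[1] <= 100 && ci[2] >= 100,
            mean_in_98_102 = m >= 98 && m <= 102,
            rsd_within_reference = if (is.null(rsd_r_reference)) NA
                                   else rsd <= rsd_r_reference)
  structure(list(per_level = per_level, mean = m, rsd_pct = rsd, ci = ci,
                 n = length(vals), pass = pass),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("Mean recovery %.2f%% (RSD %.2f%%), 95%% CI [%.2f, %.2f]\n",
              x$mean, x$rsd_pct, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Detection and quantification limits
#'
#' Calibration method (ICH): \eqn{LoD = 3.3\sigma/b}, \eqn{LoQ =
#' 10\sigma/b} with \eqn{\sigma} the standard deviation of the intercept
#' and \eqn{b} the slope. Empirical method: the lowest concentration of a
#' measured dilution series whose signal-to-noise ratio exceeds
#' \code{sn_threshold} (LoD) and whose replicate %RSD is at most
#' \code{rsd_threshold} (LoQ).
#'
#' @param fit A \code{\link{fit_calibration}} result (calibration method).
#' @param series Data frame with columns \code{conc}, \code{sn},
#'   \code{rsd_pct} (empirical method). Supply exactly one of \code{fit} /
#'   \code{series}.
#' @param sn_threshold Minimum S/N for detection (default 3, within the
#'   conventional 2-3.5 band).
#' @param rsd_threshold Maximum %RSD for quantification (default 5).
#' @return A \code{detection_limits} list: \code{lod}, \code{loq} (in the
#'   concentration units of the input), \code{method}, inputs used.
#' @examples
#' d <- data.frame(conc = 1:6, area = 10 * (1:6))
#' # sigma of a perfect line is 0; use a synthetic sigma instead:
#' detection_limits(series = data.frame(conc = c(0.1, 0.2, 0.4),
#'                                      sn = c(2, 4, 9),
#'                                      rsd_pct = c(9, 6, 4)))
#' @export
detection_limits <- function(fit = NULL, series = NULL,
                             sn_threshold = 3, rsd_threshold = 5) {
  if (is.null(fit) == is.null(series))
    stop("supply exactly one of 'fit' or 'series'")
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "calibration_fit"))
    if (fit$slope <= 0) stop("calibration slope must be positive")
    lod <- 3.3 * fit$sigma_intercept / fit$slope
    loq <- 10 * fit$sigma_intercept / fit$slope
    return(structure(list(lod = lod, loq = loq, method = "calibration",
                          sigma = fit$sigma_intercept, slope = fit$slope),
                     class = "detection_limits"))
  }
  stopifnot(all(c("conc", "sn", "rsd_pct") %in% names(series)))
  series <- series[order(series$conc), ]
  det <- series$conc[series$sn > sn_threshold]
  qnt <- series$conc[series$rsd_pct <= rsd_threshold]
  if (!length(det)) stop("no level reaches the S/N detection threshold")
  if (!length(qnt)) stop("no level meets the %RSD quantification threshold")
  structure(list(lod = min(det), loq = min(qnt), method = "empirical",
                 sn_threshold = sn_threshold,
                 rsd_threshold = rsd_threshold),
            class = "detection_limits")
}

#' @export
print.detection_limits <- function(x, ...) {
  cat(sprintf("LoD = %.4g, LoQ = %.4g (%s method)\n", x$lod, x$loq,
              x$method))
  invisible(x)
}
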