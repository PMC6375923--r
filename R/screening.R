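#' Estimate two-level factorial effects
#'
#' The effect of a contrast is the mean response at its coded +1 runs minus
#' the mean at its -1 runs, over the factorial portion of the design only
#' (center replicates carry no contrast information and are excluded).
#' Interaction contrasts are written \code{"A:B"} and computed as the
#' elementwise product of the parent columns.
#'
#' @param design A \code{design_table} with the response attached.
#' @param response_name Name of the response column.
#' @param effects Character vector of contrasts to estimate. Default: all
#'   main effects, plus — for the 7-factor resolution-IV screening design —
#'   the seven estimable two-factor alias representatives
#'   (A:B, A:C, A:D, A:E, A:F, A:G, B:D).
#' @return An object of class \code{effect_table}: data frame with columns
#'   \code{effect} and \code{estimate}, response name and units carried as
#'   attributes.
#' @examples
#' d <- build_fractional_factorial(2, 0)
#' d <- set_response(d, "y", c(1, 3, 5, 7))
#' estimate_effects(d, "y")  # A: 2, B: 4
#' @export
estimate_effects <- function(design, response_name, effects = NULL) {
  fnames <- attr(design, "factor_names")
  if (!response_name %in% names(design))
    stop("response '", response_name, "' not found in design")
  if (is.null(effects)) {
    effects <- fnames
    if (length(fnames) == 7 && !is.null(attr(design, "generators")))
      effects <- c(fnames, "A:B", "A:C", "A:D", "A:E", "A:F", "A:G", "B:D")
  }
  fac <- design[!design$center, , drop = FALSE]
  y <- fac[[response_name]]
  X <- coded_matrix(fac)

  cols <- vapply(effects, function(e) {
    parts <- strsplit(e, ":", fixed = TRUE)[[1]]
    bad <- setdiff(parts, fnames)
    if (length(bad))
      stop("unknown factor(s) in contrast '", e, "': ",
           paste(bad, collapse = ", "))
    apply(X[, parts, drop = FALSE], 1, prod)
  }, numeric(nrow(fac)))

  ## confounding check: two requested contrasts with identical (+/-) columns
  n <- nrow(cols)
  g <- crossprod(cols) / n
  conf <- which(abs(abs(g) - 1) < 1e-12 & upper.tri(g), arr.ind = TRUE)
  if (nrow(conf)) {
    al <- attr(design, "aliases")
    pair <- paste(effects[conf[1, 1]], "and", effects[conf[1, 2]])
    chain <- if (!is.null(al) && effects[conf[1, 1]] %in% names(al))
      paste(" (alias chain: ",
            paste(al[[effects[conf[1, 1]]]], collapse = " = "), ")", sep = "")
    else ""
    stop("requested contrasts are confounded: ", pair, chain)
  }

  est <- vapply(seq_along(effects), function(j) {
    cj <- cols[, j]
    mean(y[cj > 0]) - mean(y[cj < 0])
  }, numeric(1))
  structure(data.frame(effect = effects, estimate = est,
                       stringsAsFactors = FALSE),
            class = c("effect_table", "data.frame"),
            response = response_name)
}

#' Build an effect table from literal estimates
#'
#' Convenience constructor for effect values that are already available
#' (e.g. a published screening table) rather than computed from a design.
#'
#' @param effects Named numeric vector of effect estimates.
#' @param response Response label.
#' @return An \code{effect_table}.
#' @export
effect_table <- function(effects, response = "y") {
  stopifnot(is.numeric(effects), !is.null(names(effects)))
  structure(data.frame(effect = names(effects),
                       estimate = as.numeric(effects),
                       stringsAsFactors = FALSE),
            class = c("effect_table", "data.frame"),
            response = response)
}

#' Dong's critical effect for unreplicated two-level designs
#'
#' Estimates the standard error of an effect from the small ("pseudo-noise")
#' effects and scales it by a one-sided Student t quantile into a
#' significance threshold, the critical effect.
#'
#' Two trimming rules are provided. \code{"lowest75"} retains the
#' \code{floor(0.75 m)} smallest absolute effects of the \code{m} estimated
#' effects and takes their root mean square as the effect standard error.
#' \code{"dong_classic"} starts from the initial estimate
#' \eqn{s_0 = 1.5 \times \mathrm{median}|E|}, retains effects with
#' \eqn{|E| \le 2.5 s_0}, and takes the RMS of those. In both variants
#' the critical effect is \eqn{t_{1-\alpha}(\mathrm{dof}) \times (SE)_e}
#' with \code{dof} defaulting to \code{m}.
#'
#' @param effects An \code{effect_table} (or named numeric vector).
#' @param alpha One-sided significance level (default 0.05).
#' @param variant \code{"lowest75"} (default) or \code{"dong_classic"}.
#' @param dof Degrees of freedom for the t quantile; default the number of
#'   effects \code{m}.
#' @return An object of class \code{dong_result} with fields \code{s0},
#'   \code{se_effect}, \code{critical_effect}, \code{retained_effects},
#'   \code{variant}, \code{alpha}, \code{dof}.
#' @examples
#' e <- effect_table(c(A = -92.9, B = 38.5, C = 77.0, D = 149.2,
#'                     E = 39.5, F = 12.7, G = -73.2, `A:B` = -22.6))
#' dong_critical(e, variant = "dong_classic")
#' @export
dong_critical <- function(effects, alpha = 0.05,
                          variant = c("lowest75", "dong_classic"),
                          dof = NULL) {
  variant <- match.arg(variant)
  if (is.numeric(effects)) effects <- effect_table(effects)
  e <- effects$estimate
  nm <- effects$effect
  m <- length(e)
  if (m < 4) stop("need at least 4 effects for a stable error estimate")
  if (is.null(dof)) dof <- m
  ae <- abs(e)

  if (all(ae == 0)) {
    warning("all effects are zero: degenerate error estimate, ",
            "critical effect set to 0")
    return(structure(list(s0 = 0, se_effect = 0, critical_effect = 0,
                          retained_effects = nm, variant = variant,
                          alpha = alpha, dof = dof),
                     class = "dong_result"))
  }

  if (variant == "lowest75") {
    keep_n <- floor(0.75 * m)
    keep <- order(ae)[seq_len(keep_n)]
    s0 <- sqrt(mean(ae[keep]^2))  # no separate initial stage for this rule
  } else {
    s0 <- 1.5 * stats::median(ae)
    keep <- which(ae <= 2.5 * s0)
  }
  se <- sqrt(mean(ae[keep]^2))
  crit <- stats::qt(1 - alpha, dof) * se
  structure(list(s0 = s0, se_effect = se, critical_effect = crit,
                 retained_effects = nm[keep], variant = variant,
                 alpha = alpha, dof = dof),
            class = "dong_result")
}

#' @export
print.dong_result <- function(x, ...) {
  cat(sprintf(
    "Dong critical effect (variant %s, alpha %.3g, dof %d)\n", x$variant,
    x$alpha, x$dof))
  cat(sprintf("  (SE)_e = %.4f, E_critical = %.4f (%d effects retained)\n",
              x$se_effect, x$critical_effect, length(x$retained_effects)))
  invisible(x)
}

#' Classify effects against a critical effect
#'
#' An effect is significant iff its absolute estimate exceeds the critical
#' effect. The report is sorted by absolute estimate, descending.
#'
#' @param effects An \code{effect_table}.
#' @param dong A \code{dong_result} (from \code{\link{dong_critical}}).
#' @return A \code{screening_report}: data frame with columns
#'   \code{effect}, \code{estimate}, \code{abs_estimate},
#'   \code{e_critical}, \code{significant}.
#' @export
classify_effects <- function(effects, dong) {
  stopifnot(inherits(dong, "dong_result"))
  if (is.numeric(effects)) effects <- effect_table(effects)
  out <- data.frame(effect = effects$effect,
                    estimate = effects$estimate,
                    abs_estimate = abs(effects$estimate),
                    e_critical = dong$critical_effect,
                    significant = abs(effects$estimate) > dong$critical_effect,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$abs_estimate), ]
  rownames(out) <- NULL
  structure(out, class = c("screening_report", "data.frame"),
            response = attr(effects, "response"), dong = dong)
}

#' One-call screening of a designed experiment
#'
#' Runs \code{\link{estimate_effects}}, \code{\link{dong_critical}} and
#' \code{\link{classify_effects}} for one response.
#'
#' @inheritParams estimate_effects
#' @inheritParams dong_critical
#' @return A \code{screening_report}.
#' @export
screen_design <- function(design, response_name, effects = NULL,
                          alpha = 0.05,
                          variant = c("lowest75", "dong_classic"),
                          dof = NULL) {
  et <- estimate_effects(design, response_name, effects)
  classify_effects(et, dong_critical(et, alpha, match.arg(variant), dof))
}

#' Write a screening report as CSV
#'
#' @param report A \code{screening_report}.
#' @param path File path.
#' @export
write_screening_csv <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
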