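## Seeded generators producing inputs with the statistical structure each
## pipeline stage assumes. All randomness is Gaussian: additive noise on
## responses and areas, variance components for the precision study. With
## zero noise every downstream stage recovers its truth exactly, which the
## test-suite exploits.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else if (exists(".Random.seed", globalenv()))
              rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
  }
  force(expr)
}

#' Simulate a two-level screening study
#'
#' Generates responses on a (fractional) factorial design as grand mean
#' plus half-effect contributions along each named contrast plus Gaussian
#' noise: \code{y = mu + sum(effect/2 * contrast) + N(0, sd)}. Center runs
#' receive the grand mean plus noise.
#'
#' @param true_effects Named numeric vector of true effects; names are
#'   factor letters or interactions like \code{"A:D"}.
#' @param noise_sd Response noise standard deviation.
#' @param grand_mean Baseline response level.
#' @param design A \code{design_table}; default the 7-factor, 16-run
#'   resolution-IV screening design with duplicate center points.
#' @param response_name Name for the generated response column.
#' @param seed Integer seed (optional but recommended).
#' @return The design with the simulated response attached.
#' @examples
#' d <- gen_screening_study(c(D = 150), noise_sd = 0, seed = 1)
#' subset(estimate_effects(d, "y"), effect == "D")$estimate  # 150
#' @export
gen_screening_study <- function(true_effects, noise_sd = 0,
                                grand_mean = 1000,
                                design = build_fractional_factorial(
                                  7, 3, n_center = 2),
                                response_name = "y", seed = NULL) {
  stopifnot(is.numeric(true_effects), !is.null(names(true_effects)))
  fnames <- attr(design, "factor_names")
  X <- coded_matrix(design)
  mu <- rep(grand_mean, nrow(design))
  for (nm in names(true_effects)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    bad <- setdiff(parts, fnames)
    if (length(bad))
      stop("unknown effect name '", nm, "' (no factor ",
           paste(bad, collapse = ", "), ")")
    contrast <- apply(X[, parts, drop = FALSE], 1, prod)
    mu <- mu + true_effects[[nm]] / 2 * contrast
  }
  y <- with_seed(seed, mu + stats::rnorm(length(mu), 0, noise_sd))
  set_response(design, response_name, y)
}

#' Simulate a central composite study from a true quadratic surface
#'
#' @param true_model A \code{\link{quadratic_model}} providing the truth.
#' @param noise_sd Response noise standard deviation.
#' @param design A \code{design_table}; default the 2-factor rotatable CCD
#'   with 3 center points.
#' @param response_name Name for the generated response column.
#' @param seed Integer seed.
#' @return The design with the simulated response attached.
#' @export
gen_ccd_study <- function(true_model, noise_sd = 0,
                          design = build_central_composite(
                            ccd_spec(2, alpha = sqrt(2), n_center = 3)),
                          response_name = "y", seed = NULL) {
  stopifnot(inherits(true_model, "quadratic_model"))
  X <- coded_matrix(design)
  if (ncol(X) != true_model$k)
    stop("model has ", true_model$k, " factors but design has ", ncol(X))
  mu <- predict_surface(true_model, X)
  y <- with_seed(seed, mu + stats::rnorm(length(mu), 0, noise_sd))
  set_response(design, response_name, y)
}

#' Simulate method-validation input tables
#'
#' Four kinds mirroring the validation workflows:
#' \describe{
#'   \item{calibration}{\code{y = intercept + slope x + N(0, sd)} at the
#'     given levels with \code{n_rep} replicates each. Default levels are
#'     the low end of the standard dilution series (0.02-50 µg/mL).}
#'   \item{precision}{Level means perturbed by a shared day effect
#'     \code{N(0, sd_day)} and residual \code{N(0, sd_r)}; defaults mirror
#'     a 4-day x 3-level x 6-replicate study.}
#'   \item{recovery}{\code{N(true_recovery, sd)} per replicate at spike
#'     levels 75/100/125%, \code{n_rep = 3}.}
#'   \item{dilution_series}{A serial dilution with signal-to-noise
#'     proportional to concentration (\code{sn = conc * sn_per_conc}) and
#'     replicate %RSD rising as concentration falls.}
#' }
#'
#' @param kind One of \code{"calibration"}, \code{"precision"},
#'   \code{"recovery"}, \code{"dilution_series"}.
#' @param ... Truth parameters overriding the defaults listed above:
#'   \code{slope}, \code{intercept}, \code{sd}, \code{levels},
#'   \code{n_rep}; \code{level_means}, \code{n_days}, \code{sd_day},
#'   \code{sd_r}; \code{true_recovery}; \code{sn_per_conc}.
#' @param seed Integer seed.
#' @return A data frame in the layout the corresponding validation
#'   function expects.
#' @export
gen_validation_data <- function(kind = c("calibration", "precision",
                                         "recovery", "dilution_series"),
                                ..., seed = NULL) {
  kind <- match.arg(kind)
  p <- list(...)
  getp <- function(name, default) if (!is.null(p[[name]])) p[[name]] else default
  sds <- unlist(p[names(p) %in% c("sd", "sd_day", "sd_r")])
  if (any(sds < 0)) stop("noise standard deviations must be non-negative")

  with_seed(seed, switch(kind,
    calibration = {
      levels <- getp("levels", c(0.02, 0.2, 1.6, 8.0, 20, 50))
      n_rep <- getp("n_rep", 3)
      slope <- getp("slope", 67.6)
      intercept <- getp("intercept", 0)
      sd <- getp("sd", 1)
      conc <- rep(levels, each = n_rep)
      data.frame(conc = conc,
                 replicate = rep(seq_len(n_rep), length(levels)),
                 area = intercept + slope * conc +
                   stats::rnorm(length(conc), 0, sd))
    },
    precision = {
      level_means <- getp("level_means", c(`50` = 50, `100` = 100,
                                           `150` = 150))
      n_days <- getp("n_days", 4)
      n_rep <- getp("n_rep", 6)
      sd_day <- getp("sd_day", 0)
      sd_r <- getp("sd_r", 1)
      grid <- expand.grid(replicate = seq_len(n_rep),
                          level = names(level_means), day = seq_len(n_days),
                          stringsAsFactors = FALSE)
      day_eff <- stats::rnorm(n_days, 0, sd_day)
      grid$value <- level_means[grid$level] + day_eff[grid$day] +
        stats::rnorm(nrow(grid), 0, sd_r)
      grid[, c("day", "level", "replicate", "value")]
    },
    recovery = {
      levels <- getp("levels", c(75, 100, 125))
      n_rep <- getp("n_rep", 3)
      true_recovery <- getp("true_recovery", 100)
      sd <- getp("sd", 0.5)
      grid <- expand.grid(replicate = seq_len(n_rep), level = levels)
      data.frame(level = grid$level, replicate = grid$replicate,
                 recovery = stats::rnorm(nrow(grid), true_recovery, sd))
    },
    dilution_series = {
      levels <- getp("levels", c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6))
      sn_per_conc <- getp("sn_per_conc", 10)
      sd <- getp("sd", 0.05)
      sn <- pmax(levels * sn_per_conc *
                   (1 + stats::rnorm(length(levels), 0, sd)), 0)
      rsd <- pmin(100, 2 / levels *
                    (1 + abs(stats::rnorm(length(levels), 0, sd))))
      data.frame(conc = levels, sn = sn, rsd_pct = rsd)
    }))
}

#' Simulate replicate peak tables from a composition table
#'
#' Inverts the quantification chain: each compound's mass fraction is
#' converted back to an injected concentration and then to a peak area via
#' its assigned external standard, and multiplicative Gaussian noise of
#' the given coefficient of variation is applied per replicate. Censored
#' compounds receive zero area. Quantifying the zero-noise output
#' reproduces the input table exactly.
#'
#' @param base A \code{quantified_samples} table (default the packaged
#'   composition fixture).
#' @param area_noise_cv Relative noise per replicate area (0.01 = 1\%).
#' @param n_rep Replicates per sample.
#' @param analytes,standards,prep Configuration shared with
#'   \code{\link{quantify_samples}}.
#' @param seed Integer seed.
#' @return A peak-table data frame: \code{sample_id}, \code{compound_id},
#'   \code{replicate}, \code{area}.
#' @export
gen_peak_tables <- function(base = load_composition_fixture(),
                            area_noise_cv = 0, n_rep = 3,
                            analytes = read_analytes(),
                            standards = default_standards(),
                            prep = sample_prep(), seed = NULL) {
  ai <- match(base$compound_id, analytes$compound_id)
  if (anyNA(ai)) stop("fixture compound(s) missing from the analyte table")
  si <- match(analytes$standard[ai], standards$standard)
  mf <- ifelse(base$censor == "none", base$mean_ug_g, 0)
  conc <- mf * prep$mass_g / (prep$volume_ml * prep$dilution)
  area <- conc / standards$conc_ug_ml[si] * standards$area[si]

  out <- base[rep(seq_len(nrow(base)), each = n_rep),
              c("sample_id", "compound_id")]
  out$replicate <- rep(seq_len(n_rep), nrow(base))
  base_area <- rep(area, each = n_rep)
  out$area <- with_seed(seed, pmax(0, base_area *
    (1 + stats::rnorm(length(base_area), 0, area_noise_cv))))
  rownames(out) <- NULL
  out
}
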