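#' Run pipeline stages headlessly from a configuration
#'
#' Executes the requested analysis stages in order from a single
#' configuration (a YAML file path or an equivalent nested list), writing
#' machine-readable CSV reports plus a flat key-value text summary to the
#' output directory. Every stage is runnable from the config alone; the
#' resolved configuration, package version and seed are logged alongside
#' the reports so any run is reproducible.
#'
#' Recognised stages and their options:
#' \describe{
#'   \item{simulate}{\code{kind} (ffd/ccd), \code{noise_sd},
#'     \code{true_effects} (named list), writes \code{design_table.csv}.}
#'   \item{screen}{\code{design} (CSV path; defaults to the simulated
#'     design), \code{response}, \code{variant}, \code{alpha}; writes
#'     \code{screening_report.csv}.}
#'   \item{optimize}{\code{models} = path to a coefficient CSV with
#'     columns response, intercept, x1, x2, x1_sq, x2_sq, x1_x2;
#'     \code{mode} (single/desirability), \code{shape}, \code{radius};
#'     writes \code{optimum.csv}.}
#'   \item{validate_accuracy}{\code{input} = recovery CSV (columns
#'     \code{level}/\code{level_pct}, \code{recovery}/\code{recovery_pct},
#'     optional \code{analyte}); writes \code{accuracy_report.csv}.}
#'   \item{validate_linearity}{\code{input} = calibration CSV (conc,
#'     area); writes \code{linearity_report.csv} including Mandel's test
#'     and calibration-based limits.}
#'   \item{validate_precision}{\code{input} = precision CSV (day, level,
#'     value); writes \code{precision_report.csv} with Cochran's C and
#'     Horwitz screening when \code{mass_fraction} is given.}
#'   \item{quantify}{\code{peaks} = peak-table CSV; writes
#'     \code{quantified.csv} and \code{totals.csv}.}
#'   \item{pca}{\code{matrix} = composition CSV (first column sample id)
#'     or \code{"fixture"}; writes \code{scores.csv}, \code{loadings.csv},
#'     \code{explained_variance.csv}.}
#' }
#'
#' @param config YAML file path or named list with elements \code{stages}
#'   (named list of stage options as above), optional \code{seed} and
#'   \code{out_dir}.
#' @param out_dir Output directory (overrides the config); created if
#'   missing.
#' @return Named list of stage results, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML path or a list")
  known <- c("stages", "seed", "out_dir")
  bad <- setdiff(names(config), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  stages <- config$stages
  if (is.null(stages) || !length(stages)) stop("config lists no stages")
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("no output directory given")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  results <- list()
  summary_lines <- c(
    sprintf("package_version=%s",
            as.character(utils::packageVersion("phenoval"))),
    sprintf("seed=%s", if (is.null(seed)) "none" else seed))
  state <- new.env(parent = emptyenv())

  for (stage in names(stages)) {
    opts <- stages[[stage]]
    if (is.null(opts)) opts <- list()
    res <- switch(stage,
      simulate = stage_simulate(opts, seed, out_dir, state),
      screen = stage_screen(opts, out_dir, state),
      optimize = stage_optimize(opts, out_dir),
      validate_accuracy = stage_accuracy(opts, out_dir),
      validate_linearity = stage_linearity(opts, out_dir),
      validate_precision = stage_precision(opts, out_dir),
      quantify = stage_quantify(opts, out_dir),
      pca = stage_pca(opts, out_dir),
      stop("unknown stage '", stage, "'"))
    results[[stage]] <- res$value
    summary_lines <- c(summary_lines, res$summary)
  }
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  yaml::write_yaml(config, file.path(out_dir, "config_resolved.yaml"))
  invisible(results)
}

read_table_checked <- function(path, required, what) {
  if (is.null(path) || !file.exists(path))
    stop(what, " input file not found: ", if (is.null(path)) "(missing)"
         else path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop("malformed CSV '", path, "': ", conditionMessage(e)))
  if (!nrow(df)) stop("empty input table: ", path)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(what, " CSV '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  df
}

stage_simulate <- function(opts, seed, out_dir, state) {
  kind <- if (is.null(opts$kind)) "ffd" else opts$kind
  d <- if (kind == "ffd") {
    eff <- unlist(opts$true_effects)
    if (is.null(eff)) eff <- c(A = -93, D = 150)
    gen_screening_study(eff,
                        noise_sd = if (is.null(opts$noise_sd)) 20
                                   else opts$noise_sd,
                        seed = seed)
  } else if (kind == "ccd") {
    mdl <- quadratic_model(14.0, c(0.35, 0.33), c(-0.63, -0.27), -0.16)
    gen_ccd_study(mdl, noise_sd = if (is.null(opts$noise_sd)) 0.3
                                  else opts$noise_sd, seed = seed)
  } else stop("unknown simulate kind '", kind, "'")
  path <- file.path(out_dir, "design_table.csv")
  write_design_csv(d, path)
  state$design <- d
  list(value = d, summary = sprintf("simulate.runs=%d", nrow(d)))
}

stage_screen <- function(opts, out_dir, state) {
  d <- if (!is.null(opts$design)) read_design_csv(opts$design)
       else if (!is.null(state$design)) state$design
       else stop("screen stage: no design available")
  rn <- if (is.null(opts$response)) attr(d, "response_names")[1]
        else opts$response
  rep <- screen_design(d, rn,
                       alpha = if (is.null(opts$alpha)) 0.05 else opts$alpha,
                       variant = if (is.null(opts$variant)) "lowest75"
                                 else opts$variant)
  write_screening_csv(rep, file.path(out_dir, "screening_report.csv"))
  list(value = rep,
       summary = sprintf("screen.e_critical=%.4f",
                         attr(rep, "dong")$critical_effect))
}

read_model_csv <- function(path) {
  df <- read_table_checked(path, c("response", "intercept", "x1", "x2",
                                   "x1_sq", "x2_sq", "x1_x2"), "model")
  models <- lapply(seq_len(nrow(df)), function(i)
    quadratic_model(df$intercept[i], c(df$x1[i], df$x2[i]),
                    c(df$x1_sq[i], df$x2_sq[i]), df$x1_x2[i]))
  names(models) <- df$response
  models
}

stage_optimize <- function(opts, out_dir) {
  models <- read_model_csv(opts$models)
  opt <- optimize_response(
    unname(models),
    mode = if (is.null(opts$mode)) "single" else opts$mode,
    shape = if (is.null(opts$shape)) "square" else opts$shape,
    radius = if (is.null(opts$radius)) 1.414 else opts$radius)
  out <- data.frame(t(c(opt$coded, predicted = opt$predicted)))
  utils::write.csv(out, file.path(out_dir, "optimum.csv"),
                   row.names = FALSE)
  list(value = opt,
       summary = sprintf("optimize.coded=%s",
                         paste(round(opt$coded, 3), collapse = ",")))
}

stage_accuracy <- function(opts, out_dir) {
  df <- read_table_checked(opts$input, character(0), "recovery")
  names(df)[names(df) == "level_pct"] <- "level"
  names(df)[names(df) == "recovery_pct"] <- "recovery"
  if (!all(c("level", "recovery") %in% names(df)))
    stop("recovery CSV needs columns level(_pct) and recovery(_pct)")
  groups <- if ("analyte" %in% names(df)) split(df, df$analyte)
            else list(all = df)
  rep <- do.call(rbind, lapply(names(groups), function(a) {
    r <- recovery_stats(groups[[a]])
    data.frame(analyte = a, mean_recovery = r$mean, rsd_pct = r$rsd_pct,
               ci_low = r$ci[1], ci_high = r$ci[2],
               ci_contains_100 = r$pass[["ci_contains_100"]],
               mean_in_98_102 = r$pass[["mean_in_98_102"]])
  }))
  utils::write.csv(rep, file.path(out_dir, "accuracy_report.csv"),
                   row.names = FALSE)
  list(value = rep,
       summary = sprintf("accuracy.mean=%s",
                         paste(round(rep$mean_recovery, 2),
                               collapse = ",")))
}

stage_linearity <- function(opts, out_dir) {
  df <- read_table_checked(opts$input, c("conc", "area"), "calibration")
  fit <- fit_calibration(df)
  man <- mandel_test(df)
  lim <- detection_limits(fit = fit)
  rep <- data.frame(slope = fit$slope, intercept = fit$intercept,
                    r_squared = fit$r_squared,
                    ci_intercept_low = fit$ci_intercept[1],
                    ci_intercept_high = fit$ci_intercept[2],
                    p_slope = fit$p_slope, p_intercept = fit$p_intercept,
                    mandel_F = man$F, mandel_decision = man$decision,
                    lod = lim$lod, loq = lim$loq)
  utils::write.csv(rep, file.path(out_dir, "linearity_report.csv"),
                   row.names = FALSE)
  list(value = list(fit = fit, mandel = man, limits = lim),
       summary = sprintf("linearity.r2=%.5f mandel=%s", fit$r_squared,
                         man$decision))
}

stage_precision <- function(opts, out_dir) {
  df <- read_table_checked(opts$input, c("day", "level", "value"),
                           "precision")
  pr <- precision_summary(df)
  cc <- cochran_c(pr$cells$var, n_per_group = round(mean(pr$cells$n)))
  rep <- data.frame(rsd_r = pr$rsd_r, rsd_R = pr$rsd_R,
                    cochran_C = cc$C, cochran_critical = cc$c_critical,
                    variances_homogeneous = cc$homogeneous)
  if (!is.null(opts$mass_fraction)) {
    hw <- horwitz_limits(opts$mass_fraction)
    rep$horwitz_rsd_R_max <- hw$rsd_R_max
    rep$horwitz_rsd_r_max <- hw$rsd_r_max
    rep$within_horwitz <- pr$rsd_r <= hw$rsd_r_max &&
      pr$rsd_R <= hw$rsd_R_max
  }
  utils::write.csv(rep, file.path(out_dir, "precision_report.csv"),
                   row.names = FALSE)
  list(value = list(precision = pr, cochran = cc),
       summary = sprintf("precision.rsd_r=%.3f rsd_R=%.3f", pr$rsd_r,
                         pr$rsd_R))
}

stage_quantify <- function(opts, out_dir) {
  peaks <- read_table_checked(opts$peaks,
                              c("sample_id", "compound_id", "replicate",
                                "area"), "peak table")
  q <- quantify_samples(peaks)
  tot <- aggregate_totals(q)
  utils::write.csv(as.data.frame(q), file.path(out_dir, "quantified.csv"),
                   row.names = FALSE)
  utils::write.csv(tot, file.path(out_dir, "totals.csv"),
                   row.names = FALSE)
  list(value = list(quantified = q, totals = tot),
       summary = sprintf("quantify.samples=%d",
                         length(unique(q$sample_id))))
}

stage_pca <- function(opts, out_dir) {
  m <- if (identical(opts$matrix, "fixture") || is.null(opts$matrix)) {
    rollup_categories(load_composition_fixture())
  } else {
    df <- read_table_checked(opts$matrix, character(0), "composition")
    mm <- as.matrix(df[, -1, drop = FALSE])
    rownames(mm) <- df[[1]]
    mm
  }
  p <- composition_pca(m, scaling = if (is.null(opts$scale)) "unit"
                                    else opts$scale)
  utils::write.csv(data.frame(sample = rownames(p$scores), p$scores),
                   file.path(out_dir, "scores.csv"), row.names = FALSE)
  utils::write.csv(data.frame(category = rownames(p$loadings), p$loadings),
                   file.path(out_dir, "loadings.csv"), row.names = FALSE)
  utils::write.csv(data.frame(component = seq_along(p$explained),
                              explained = p$explained),
                   file.path(out_dir, "explained_variance.csv"),
                   row.names = FALSE)
  list(value = p,
       summary = sprintf("pca.cum3=%.3f",
                         sum(p$explained[seq_len(min(3,
                           length(p$explained)))])))
}
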