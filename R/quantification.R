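#' Packaged analyte configuration
#'
#' The 36-compound leaf-phenolic panel: compound class (phenolic acid,
#' flavonoid, flavonolignan), the 8-category roll-up assignment (CA, LG,
#' AG, LMG, AMG, DG, QG, FL), the quantification standard (CA; VX1 =
#' vitexin at 340 nm; VX2 = vitexin at 390 nm; RU = rutin) and detection
#' wavelength. Flavone C-glycosides are quantified as vitexin equivalents,
#' quercetin O-glycosides as rutin equivalents, and flavonolignans as
#' vitexin equivalents at 390 nm.
#'
#' @param path Optional path to an alternative analyte CSV with the same
#'   columns.
#' @return Data frame with columns \code{compound_id}, \code{compound_name},
#'   \code{class}, \code{category}, \code{standard}, \code{wavelength_nm}.
#' @export
read_analytes <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "analytes.csv", package = "phenoval")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "class", "category", "standard")
  if (!all(need %in% names(df)))
    stop("analyte table must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(df$compound_id))
    stop("duplicated compound_id in analyte table")
  df
}

#' External-standard reference solutions
#'
#' Reference concentrations of the external standards used for
#' quantification (chlorogenic acid 20.12, vitexin 20.32, rutin
#' 18.69 µg/mL). The reference peak areas are synthetic: computed as
#' concentration times the corresponding calibration slope, they provide a
#' self-consistent area scale for simulation and round-trip testing; real
#' analyses should supply measured standard areas.
#'
#' @return Data frame with columns \code{standard}, \code{conc_ug_ml},
#'   \code{area}.
#' @export
default_standards <- function() {
  data.frame(standard = c("CA", "VX1", "VX2", "RU"),
             conc_ug_ml = c(20.12, 20.32, 20.32, 18.69),
             area = c(67.6 * 20.12, 74.4 * 20.32, 5.2 * 20.32,
                      41.4 * 18.69),
             stringsAsFactors = FALSE)
}

#' Sample preparation record
#'
#' @param mass_g Dry sample mass (g).
#' @param volume_ml Final volumetric-flask volume (mL); the reference
#'   workflow collects in a 50.0 mL flask.
#' @param dilution Dilution factor applied before injection (1:2 gives 2).
#' @return A \code{sample_prep} list.
#' @export
sample_prep <- function(mass_g = 1, volume_ml = 50, dilution = 2) {
  if (any(c(mass_g, volume_ml, dilution) <= 0))
    stop("sample mass, volume and dilution must all be positive")
  structure(list(mass_g = mass_g, volume_ml = volume_ml,
                 dilution = dilution), class = "sample_prep")
}

#' Back-calculate concentration from a peak area
#'
#' Single-point external-standard mode: \code{conc = area / area_std *
#' conc_std}. Curve mode: \code{conc = (area - intercept) / slope} from a
#' \code{\link{fit_calibration}} result. Negative back-calculated
#' concentrations are floored at zero with a warning.
#'
#' @param area Numeric vector of peak areas.
#' @param standard_area,standard_conc Reference peak area and concentration
#'   (single-point mode).
#' @param curve A \code{calibration_fit} (curve mode); supply either the
#'   standard pair or the curve.
#' @return Concentrations in the standard's units (µg/mL).
#' @export
concentration_from_area <- function(area, standard_area = NULL,
                                    standard_conc = NULL, curve = NULL) {
  if (!is.null(curve)) {
    stopifnot(inherits(curve, "calibration_fit"))
    conc <- (area - curve$intercept) / curve$slope
  } else {
    if (is.null(standard_area) || is.null(standard_conc))
      stop("single-point mode needs standard_area and standard_conc")
    if (standard_area <= 0) stop("standard area must be positive")
    conc <- area / standard_area * standard_conc
  }
  if (any(conc < 0)) {
    warning("negative back-calculated concentration floored at 0")
    conc[conc < 0] <- 0
  }
  conc
}

#' Convert solution concentration to dry-mass fraction
#'
#' \code{mass_fraction = conc * volume * dilution / mass}, giving µg of
#' analyte per g of dry leaf.
#'
#' @param conc_ug_ml Concentration in the injected solution (µg/mL).
#' @param prep A \code{\link{sample_prep}}.
#' @return Mass fraction in µg/g.
#' @examples
#' to_mass_fraction(10.06, sample_prep(0.5, 50, 2))  # 2012
#' @export
to_mass_fraction <- function(conc_ug_ml, prep) {
  stopifnot(inherits(prep, "sample_prep"))
  conc_ug_ml * prep$volume_ml * prep$dilution / prep$mass_g
}

#' Quantify samples from a replicate peak table
#'
#' Runs the full external-standard chain: area to concentration (via the
#' compound's assigned standard), concentration to µg/g dry mass, replicate
#' mean and sd, and LoQ/LoD censoring.
#'
#' @param peaks Data frame with columns \code{sample_id},
#'   \code{compound_id}, \code{replicate}, \code{area}.
#' @param analytes Analyte table (see \code{\link{read_analytes}}).
#' @param prep A \code{\link{sample_prep}} (shared) or a data frame with
#'   \code{sample_id}, \code{mass_g}, \code{volume_ml}, \code{dilution}.
#' @param standards Standards table (see \code{\link{default_standards}}).
#' @param loq,lod Quantification / detection limits in µg/g (single value
#'   or named by compound_id); values below \code{loq} are censored.
#' @return A \code{quantified_samples} data frame: \code{sample_id},
#'   \code{compound_id}, \code{mean_ug_g}, \code{sd_ug_g}, \code{n},
#'   \code{censor} (\code{"none"}, \code{"loq"} or \code{"lod"}).
#' @export
quantify_samples <- function(peaks, analytes = read_analytes(),
                             prep = sample_prep(),
                             standards = default_standards(),
                             loq = 20, lod = 5) {
  need <- c("sample_id", "compound_id", "replicate", "area")
  stopifnot(all(need %in% names(peaks)))
  if (any(peaks$area < 0)) stop("peak areas must be non-negative")
  unmapped <- setdiff(unique(peaks$compound_id), analytes$compound_id)
  if (length(unmapped))
    stop("compound(s) missing from the analyte table: ",
         paste(unmapped, collapse = ", "))

  ai <- match(peaks$compound_id, analytes$compound_id)
  si <- match(analytes$standard[ai], standards$standard)
  if (anyNA(si))
    stop("standard(s) missing from the standards table: ",
         paste(setdiff(analytes$standard[ai], standards$standard),
               collapse = ", "))
  conc <- peaks$area / standards$area[si] * standards$conc_ug_ml[si]

  if (inherits(prep, "sample_prep")) {
    mf <- to_mass_fraction(conc, prep)
  } else {
    pi <- match(peaks$sample_id, prep$sample_id)
    if (anyNA(pi)) stop("sample(s) missing from the prep table")
    mf <- conc * prep$volume_ml[pi] * prep$dilution[pi] / prep$mass_g[pi]
  }

  key <- interaction(peaks$sample_id, peaks$compound_id, drop = TRUE)
  agg <- do.call(rbind, lapply(split(seq_along(mf), key), function(ix) {
    data.frame(sample_id = peaks$sample_id[ix[1]],
               compound_id = peaks$compound_id[ix[1]],
               mean_ug_g = mean(mf[ix]),
               sd_ug_g = if (length(ix) > 1) stats::sd(mf[ix]) else NA_real_,
               n = length(ix), stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  get_lim <- function(lim, id) {
    if (!is.null(names(lim))) {
      out <- lim[id]
      out[is.na(out)] <- 0
      unname(out)
    } else rep(lim, length(id))
  }
  lo <- get_lim(lod, agg$compound_id)
  lq <- get_lim(loq, agg$compound_id)
  agg$censor <- ifelse(agg$mean_ug_g < lo, "lod",
                       ifelse(agg$mean_ug_g < lq, "loq", "none"))
  structure(agg, class = c("quantified_samples", "data.frame"))
}

#' Load the packaged leaf composition table
#'
#' Per-compound mass fractions (µg/g dry leaf, mean and sd of n = 3
#' preparations) for 19 leaf samples of four \emph{Cecropia} species and
#' three commercial products. Sample-compound pairs absent from the file
#' are below the limit of quantification and are expanded to censored rows
#' (\code{censor = "loq"}); one pair is below the detection limit.
#'
#' @param path Optional alternative CSV path.
#' @param expand Logical; expand censored pairs (default TRUE).
#' @return A \code{quantified_samples} data frame.
#' @export
load_composition_fixture <- function(path = NULL, expand = TRUE) {
  if (is.null(path))
    path <- system.file("extdata", "leaf_composition.csv",
                        package = "phenoval")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$n <- 3L
  if (expand) {
    analytes <- read_analytes()
    samples <- unique(df$sample_id)
    full <- expand.grid(compound_id = analytes$compound_id,
                        sample_id = samples, stringsAsFactors = FALSE)
    key <- paste(df$compound_id, df$sample_id)
    miss <- full[!paste(full$compound_id, full$sample_id) %in% key, ]
    if (nrow(miss)) {
      miss$mean_ug_g <- NA_real_
      miss$sd_ug_g <- NA_real_
      miss$censor <- "loq"
      miss$n <- 3L
      df <- rbind(df[, names(miss)], miss)
    }
  }
  structure(df, class = c("quantified_samples", "data.frame"))
}

#' Censoring-aware class totals
#'
#' Total flavonoids (TF) is the sum of quantified flavonoid rows; the
#' flavonolignan total sums the flavonolignan rows. Censored compounds
#' contribute zero; when every member of a class is censored the total
#' itself is reported censored (\code{NA} with \code{censor = "loq"}).
#'
#' @param quant A \code{quantified_samples} data frame.
#' @param analytes Analyte table.
#' @param impute \code{"zero"} (default) or \code{"half_loq"}; the latter
#'   replaces censored members by \code{loq/2} and needs \code{loq}.
#' @param loq LoQ in µg/g used by \code{"half_loq"} imputation.
#' @return Data frame with one row per sample and class:
#'   \code{sample_id}, \code{class}, \code{total_ug_g}, \code{n_quantified},
#'   \code{censor}.
#' @export
aggregate_totals <- function(quant, analytes = read_analytes(),
                             impute = c("zero", "half_loq"), loq = 20) {
  impute <- match.arg(impute)
  cls <- analytes$class[match(quant$compound_id, analytes$compound_id)]
  if (anyNA(cls))
    stop("compound(s) missing from the analyte table: ",
         paste(unique(quant$compound_id[is.na(cls)]), collapse = ", "))
  out <- do.call(rbind, lapply(
    split(seq_len(nrow(quant)), list(quant$sample_id, cls)), function(ix) {
      if (!length(ix)) return(NULL)
      cen <- quant$censor[ix] != "none"
      vals <- ifelse(cen,
                     if (impute == "zero") 0 else loq / 2,
                     quant$mean_ug_g[ix])
      all_cen <- all(cen)
      data.frame(sample_id = quant$sample_id[ix[1]],
                 class = cls[ix[1]],
                 total_ug_g = if (all_cen && impute == "zero") NA_real_
                              else sum(vals),
                 n_quantified = sum(!cen),
                 censor = if (all_cen) "loq" else "none",
                 stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  out
}

#' Sum quantified values into the 8-category composition matrix
#'
#' Categories: CA (chlorogenic acid), LG (luteolin C- and C,O-glycosides),
#' AG (apigenin C- and C,O-glycosides), LMG (luteolin malonyl-C-
#' glycosides), AMG (apigenin malonyl-C,O-glycosides), DG (diosmetin
#' C,O-glycosides), QG (quercetin O-glycosides), FL (flavonolignans).
#' Censored compounds contribute zero.
#'
#' @param quant A \code{quantified_samples} data frame.
#' @param analytes Analyte table supplying the category mapping.
#' @return Numeric matrix, samples x 8 categories (µg/g).
#' @export
rollup_categories <- function(quant, analytes = read_analytes()) {
  cat_of <- analytes$category[match(quant$compound_id,
                                    analytes$compound_id)]
  if (anyNA(cat_of))
    stop("compound(s) without a category mapping: ",
         paste(unique(quant$compound_id[is.na(cat_of)]), collapse = ", "))
  cats <- unique(analytes$category)
  samples <- unique(quant$sample_id)
  m <- matrix(0, length(samples), length(cats),
              dimnames = list(samples, cats))
  ok <- quant$censor == "none"
  for (i in which(ok))
    m[quant$sample_id[i], cat_of[i]] <-
      m[quant$sample_id[i], cat_of[i]] + quant$mean_ug_g[i]
  m
}
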