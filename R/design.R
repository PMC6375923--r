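#' Define a design factor
#'
#' A factor specification maps natural (laboratory) units to coded design
#' units: the factorial low/high levels code to -1/+1 and the centre to 0.
#'
#' @param name Factor name (single string).
#' @param low,high Natural-unit levels coded to -1 and +1. Must satisfy
#'   \code{low < high}.
#' @param center Natural-unit centre, coded to 0. Defaults to the midpoint.
#' @param units Unit label, e.g. \code{"\%, v/v"} or \code{"degC"}.
#' @param discrete Logical; discrete factors (e.g. a number of extractions)
#'   only take integer natural levels at the design points.
#' @return An object of class \code{factor_spec}.
#' @examples
#' factor_spec("methanol", 50, 90, units = "%, v/v")
#' @export
factor_spec <- function(name, low, high, center = (low + high) / 2,
                        units = "", discrete = FALSE) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(low), is.numeric(high), is.numeric(center))
  if (low >= high)
    stop("factor '", name, "': low level must be strictly below high level")
  if (center < low || center > high)
    stop("factor '", name, "': center must lie within [low, high]")
  if (discrete) {
    lv <- c(low, high, center)
    if (any(abs(lv - round(lv)) > 1e-8))
      stop("factor '", name, "': discrete factor levels must be integers")
  }
  structure(list(name = name, low = low, high = high, center = center,
                 units = units, discrete = discrete),
            class = "factor_spec")
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("Factor %s: low %g, center %g, high %g %s%s\n",
              x$name, x$low, x$center, x$high, x$units,
              if (x$discrete) " (discrete)" else ""))
  invisible(x)
}

half_range <- function(spec) (spec$high - spec$low) / 2

new_design_table <- function(coded, run_id, center, factor_names,
                             generators = NULL, aliases = NULL,
                             type = "custom") {
  coded <- as.matrix(coded)
  colnames(coded) <- factor_names
  df <- data.frame(run_id = run_id, center = center,
                   coded, check.names = FALSE,
                   stringsAsFactors = FALSE)
  structure(df,
            class = c("design_table", "data.frame"),
            factor_names = factor_names,
            response_names = character(0),
            generators = generators,
            aliases = aliases,
            design_type = type)
}

#' @export
print.design_table <- function(x, ...) {
  cat(sprintf("%s design: %d runs (%d center), factors: %s\n",
              attr(x, "design_type"), nrow(x), sum(x$center),
              paste(attr(x, "factor_names"), collapse = ", ")))
  rn <- attr(x, "response_names")
  if (length(rn)) cat("responses:", paste(rn, collapse = ", "), "\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Coded factor columns of a design
#'
#' @param design A \code{design_table}.
#' @return Numeric matrix of coded levels, runs x factors.
#' @export
coded_matrix <- function(design) {
  as.matrix(design[, attr(design, "factor_names"), drop = FALSE])
}

#' Attach a response vector to a design
#'
#' @param design A \code{design_table}.
#' @param name Response name.
#' @param values Numeric vector, one value per run.
#' @return The design with the response column added.
#' @export
set_response <- function(design, name, values) {
  if (length(values) != nrow(design))
    stop("response '", name, "' must have exactly one value per run (",
         nrow(design), ")")
  design[[name]] <- as.numeric(values)
  attr(design, "response_names") <-
    union(attr(design, "response_names"), name)
  design
}

## parse an alias word like "ABC" into base-factor letters
parse_word <- function(word, base_names) {
  letters_w <- strsplit(word, "")[[1]]
  bad <- setdiff(letters_w, base_names)
  if (length(bad))
    stop("invalid generator word '", word, "': unknown base factor(s) ",
         paste(bad, collapse = ", "))
  sort(letters_w)
}

## symmetric difference of two effect words (as sorted character vectors)
word_xor <- function(a, b) sort(c(setdiff(a, b), setdiff(b, a)))

word_label <- function(w) if (length(w) == 0L) "I" else paste(w, collapse = "")

#' Build a two-level (fractional) factorial design
#'
#' Constructs a regular \eqn{2^{k-p}} design in standard order: the first
#' \eqn{k-p} factors form a full factorial and each generated factor equals
#' the product of the base-factor columns named by its generator word. With
#' \code{n_generators = 0} the full \eqn{2^k} factorial is returned.
#'
#' The default generators for the 7-factor, 16-run screening design are
#' E = ABC, F = BCD, G = ACD, a resolution-IV choice under which no main
#' effect is aliased with another main effect.
#'
#' @param n_factors Total number of factors \eqn{k}.
#' @param n_generators Number of generated factors \eqn{p}.
#' @param generators Character vector of \eqn{p} generator words over the
#'   base factors, e.g. \code{c(E = "ABC", F = "BCD", G = "ACD")}. Names
#'   default to the letters following the base factors.
#' @param n_center Number of center-point replicates appended (all-zero
#'   coded rows).
#' @param factor_names Factor labels; defaults to \code{LETTERS}.
#' @param shuffle_seed Optional integer; if given the run order is shuffled
#'   reproducibly (standard Yates order otherwise).
#' @return A \code{design_table} with \eqn{2^{k-p}} factorial runs plus the
#'   center replicates, carrying the alias structure as an attribute
#'   (retrievable with \code{\link{alias_structure}}).
#' @examples
#' d <- build_fractional_factorial(7, 3, n_center = 2)
#' nrow(d)  # 18
#' @export
build_fractional_factorial <- function(n_factors, n_generators = 0,
                                       generators = NULL, n_center = 0,
                                       factor_names = LETTERS[seq_len(n_factors)],
                                       shuffle_seed = NULL) {
  stopifnot(n_factors >= 1, n_generators >= 0, n_center >= 0)
  if (n_factors < n_generators + 2 && n_generators > 0)
    stop("need n_factors >= n_generators + 2")
  k_base <- n_factors - n_generators
  base_names <- factor_names[seq_len(k_base)]
  gen_names <- factor_names[k_base + seq_len(n_generators)]

  if (is.null(generators)) {
    if (n_generators == 0) {
      generators <- character(0)
    } else if (n_factors == 7 && n_generators == 3) {
      generators <- c(E = "ABC", F = "BCD", G = "ACD")
      names(generators) <- gen_names
    } else {
      ## default: each generated factor is the product of all base factors
      ## except a distinct leading one (gives distinct words)
      generators <- vapply(seq_len(n_generators), function(i)
        paste(base_names[-i], collapse = ""), character(1))
      names(generators) <- gen_names
    }
  }
  if (length(generators) != n_generators)
    stop("need exactly ", n_generators, " generator words")
  if (is.null(names(generators)) || any(!nzchar(names(generators))))
    names(generators) <- gen_names

  words <- lapply(generators, parse_word, base_names = base_names)
  if (anyDuplicated(vapply(words, word_label, character(1))))
    stop("duplicated generated column: generator words must be distinct")

  ## full factorial on base factors, first column alternating fastest
  base <- as.matrix(expand.grid(rep(list(c(-1, 1)), k_base)))
  colnames(base) <- base_names
  gen_cols <- vapply(words, function(w)
    apply(base[, w, drop = FALSE], 1, prod), numeric(nrow(base)))
  coded <- cbind(base, gen_cols)
  colnames(coded) <- c(base_names, names(generators))
  coded <- coded[, factor_names, drop = FALSE]

  if (n_center > 0)
    coded <- rbind(coded, matrix(0, n_center, n_factors))
  center <- c(rep(FALSE, 2^k_base), rep(TRUE, n_center))
  run_id <- sprintf("R%02d", seq_len(nrow(coded)))

  aliases <- compute_aliases(generators, base_names, factor_names)
  d <- new_design_table(coded, run_id, center, factor_names,
                        generators = generators, aliases = aliases,
                        type = sprintf("2^(%d-%d) fractional factorial",
                                       n_factors, n_generators))
  if (!is.null(shuffle_seed)) {
    ord <- withr_seed_sample(shuffle_seed, nrow(d))
    d <- d[ord, , drop = FALSE]
  }
  d
}

withr_seed_sample <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(n)
}

## defining-contrast subgroup and alias chains for each main effect and
## two-factor interaction
compute_aliases <- function(generators, base_names, factor_names) {
  if (length(generators) == 0L) return(NULL)
  gen_words <- lapply(seq_along(generators), function(i)
    sort(c(names(generators)[i], parse_word(generators[[i]], base_names))))
  ## all non-empty products of generator defining words
  p <- length(gen_words)
  defining <- list()
  for (mask in seq_len(2^p - 1)) {
    w <- character(0)
    for (i in seq_len(p))
      if (bitwAnd(mask, bitwShiftL(1L, i - 1L))) w <- word_xor(w, gen_words[[i]])
    defining[[mask]] <- w
  }
  effects <- c(as.list(factor_names),
               combn(factor_names, 2, simplify = FALSE))
  names(effects) <- vapply(effects, function(e)
    paste(e, collapse = ":"), character(1))
  lapply(effects, function(e) {
    chains <- vapply(defining, function(w) word_label(word_xor(sort(e), w)),
                     character(1))
    sort(unique(chains))
  })
}

#' Alias structure of a fractional factorial design
#'
#' @param design A \code{design_table} built by
#'   \code{\link{build_fractional_factorial}}.
#' @return Named list: for each main effect and two-factor interaction, the
#'   effects it is aliased with (as compact words, e.g. \code{"BD"}).
#'   \code{NULL} for full factorials.
#' @export
alias_structure <- function(design) attr(design, "aliases")

#' Specify a central composite design
#'
#' @param factor_specs List of \code{\link{factor_spec}} objects (the
#'   number of factors \eqn{k} is taken from its length) or an integer
#'   number of factors for a purely coded design.
#' @param alpha Axial distance in coded units; default \code{sqrt(2)}
#'   (~1.414, rotatable for \eqn{k = 2}).
#' @param n_center Number of center replicates.
#' @return An object of class \code{ccd_spec}.
#' @export
ccd_spec <- function(factor_specs = 2, alpha = sqrt(2), n_center = 3) {
  if (is.numeric(factor_specs) && length(factor_specs) == 1L) {
    k <- as.integer(factor_specs)
    specs <- NULL
  } else {
    stopifnot(all(vapply(factor_specs, inherits, logical(1), "factor_spec")))
    k <- length(factor_specs)
    specs <- factor_specs
  }
  if (alpha <= 0) stop("axial distance alpha must be positive")
  stopifnot(k >= 1, n_center >= 0)
  structure(list(k = k, alpha = alpha, n_center = n_center, specs = specs),
            class = "ccd_spec")
}

#' Build a central composite design
#'
#' Returns the \eqn{2^k} factorial portion, \eqn{2k} axial runs at
#' \eqn{\pm\alpha} on one factor (0 elsewhere), and the requested center
#' replicates, in that order.
#'
#' @param spec A \code{\link{ccd_spec}} (or an integer, taken as the number
#'   of factors with default axial distance and 3 center points).
#' @return A \code{design_table}.
#' @examples
#' d <- build_central_composite(ccd_spec(2, alpha = 1.414, n_center = 3))
#' nrow(d)  # 11
#' @export
build_central_composite <- function(spec = ccd_spec()) {
  if (!inherits(spec, "ccd_spec")) spec <- ccd_spec(spec)
  k <- spec$k
  if (k != 2)
    warning("central composite construction is general, but downstream ",
            "surface optimization is tuned for k = 2")
  fnames <- if (!is.null(spec$specs))
    vapply(spec$specs, `[[`, character(1), "name")
  else paste0("X", seq_len(k))

  fact <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  axial <- matrix(0, 2 * k, k)
  for (i in seq_len(k)) {
    axial[2 * i - 1, i] <- -spec$alpha
    axial[2 * i, i] <- spec$alpha
  }
  coded <- rbind(fact, axial,
                 matrix(0, spec$n_center, k))
  center <- c(rep(FALSE, 2^k + 2 * k), rep(TRUE, spec$n_center))
  run_id <- sprintf("R%02d", seq_len(nrow(coded)))
  d <- new_design_table(coded, run_id, center, fnames,
                        type = sprintf("central composite (k=%d, alpha=%.3f)",
                                       k, spec$alpha))
  attr(d, "ccd_spec") <- spec
  d
}

#' Convert factor values between natural and coded units
#'
#' Coded value = (natural - center) / half-range, where the half-range is
#' \code{(high - low)/2}; decoding is the exact inverse.
#'
#' @param x Named numeric vector, or matrix/data frame with factor columns.
#' @param specs List of \code{\link{factor_spec}} covering every factor
#'   present in \code{x}.
#' @param direction \code{"code"} (natural to coded) or \code{"decode"}.
#' @return Object of the same shape as \code{x}.
#' @examples
#' sp <- list(factor_spec("MeOH", 50, 90))
#' code_units(c(MeOH = 90), sp)   # +1
#' @export
convert_units <- function(x, specs, direction = c("code", "decode")) {
  direction <- match.arg(direction)
  spec_names <- vapply(specs, `[[`, character(1), "name")
  one <- function(v, nm) {
    i <- match(nm, spec_names)
    if (is.na(i)) stop("no factor_spec for factor '", nm, "'")
    s <- specs[[i]]
    if (direction == "code") (v - s$center) / half_range(s)
    else s$center + v * half_range(s)
  }
  if (is.matrix(x) || is.data.frame(x)) {
    nm <- colnames(x)
    if (is.null(nm)) stop("factor columns must be named")
    out <- x
    for (j in seq_along(nm)) out[, j] <- one(x[, j], nm[j])
    out
  } else {
    nm <- names(x)
    if (is.null(nm)) stop("factor values must be named")
    vapply(seq_along(x), function(j) one(x[[j]], nm[j]), numeric(1)) |>
      stats::setNames(nm)
  }
}

#' @rdname convert_units
#' @export
code_units <- function(x, specs) convert_units(x, specs, "code")

#' @rdname convert_units
#' @export
decode_units <- function(x, specs) convert_units(x, specs, "decode")

#' Write / read a design table as CSV
#'
#' Plain UTF-8 comma-separated layout: \code{run_id}, \code{center_flag},
#' one column per coded factor, one column per response.
#'
#' @param design A \code{design_table}.
#' @param path File path.
#' @return \code{write_design_csv} returns \code{path} invisibly;
#'   \code{read_design_csv} returns a \code{design_table}.
#' @export
write_design_csv <- function(design, path) {
  df <- as.data.frame(design)
  names(df)[names(df) == "center"] <- "center_flag"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @param factor_names Factor columns in the file; by default every column
#'   between \code{center_flag} and the first response is treated as a
#'   factor, so pass this when reading files with responses.
#' @export
read_design_csv <- function(path, factor_names = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("run_id", "center_flag")
  if (!all(need %in% names(df)))
    stop("malformed design CSV '", path, "': need columns ",
         paste(need, collapse = ", "))
  other <- setdiff(names(df), need)
  if (is.null(factor_names)) factor_names <- other
  responses <- setdiff(other, factor_names)
  d <- new_design_table(df[, factor_names, drop = FALSE],
                        df$run_id, as.logical(df$center_flag),
                        factor_names, type = "imported")
  for (r in responses) d <- set_response(d, r, df[[r]])
  d
}
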