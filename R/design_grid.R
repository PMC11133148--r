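#' Simulation design: scenario families and levels
#'
#' The built-in design crosses four scenario families with the data and
#' analysis characteristics of the simulation:
#' \describe{
#'   \item{\code{dim_correct}}{one-factor population, one-factor analysis
#'     model (correctly specified factor dimensionality).}
#'   \item{\code{dim_misspec}}{correlated two-factor population analysed with
#'     a one-factor model; the population factor correlation (.70/.50/.30)
#'     indexes the magnitude of the dimensionality misspecification (lower
#'     correlation = larger misspecification).}
#'   \item{\code{cross_correct}}{two-factor population without cross-loadings,
#'     two-factor analysis model; factors uncorrelated (.00) or correlated
#'     (.30) in both population and analysis model.}
#'   \item{\code{cross_misspec}}{two-factor population with unmodeled
#'     cross-loadings of magnitude .20/.30 on a proportion .17/.33 of the
#'     indicators; the analysis model omits them.}
#' }
#' Every family additionally crosses estimator (ML, MLR, DWLS, WLSMV),
#' number of indicators (6, 12), response options (3, 5, 7), response
#' distribution (symmetric skew 0 / asymmetric skew 0.65, both with excess
#' kurtosis of about -0.80), primary loading magnitude (.40/.60/.80) and
#' sample size (200/500/2000).
#'
#' @return A named list of per-family level sets, suitable for
#'   [enumerate_scenarios()].
#' @export
default_design <- function() {
  base <- list(
    estimator    = c("ML", "MLR", "DWLS", "WLSMV"),
    n_indicators = c(6L, 12L),
    n_options    = c(3L, 5L, 7L),
    distribution = c("symmetric", "asymmetric"),
    loading      = c(0.40, 0.60, 0.80),
    sample_size  = c(200L, 500L, 2000L)
  )
  list(
    dim_correct   = base,
    dim_misspec   = c(base, list(factor_correlation = c(0.70, 0.50, 0.30))),
    cross_correct = c(base, list(factor_correlation = c(0.00, 0.30))),
    cross_misspec = c(base, list(
      factor_correlation = c(0.00, 0.30),
      misspec_magnitude  = c(0.20, 0.30),
      misspec_proportion = c(0.17, 0.33)
    ))
  )
}

.families   <- c("dim_correct", "dim_misspec", "cross_correct", "cross_misspec")
.estimators <- c("ML", "MLR", "DWLS", "WLSMV")

.design_levels <- list(
  estimator          = .estimators,
  n_indicators       = c(6, 12),
  n_options          = c(3, 5, 7),
  distribution       = c("symmetric", "asymmetric"),
  loading            = c(0.40, 0.60, 0.80),
  sample_size        = c(200, 500, 2000),
  factor_correlation = c(0.00, 0.30, 0.50, 0.70),
  misspec_magnitude  = c(0.20, 0.30),
  misspec_proportion = c(0.17, 0.33)
)

.validate_family_config <- function(family, levels, strict = TRUE) {
  needed <- c("estimator", "n_indicators", "n_options", "distribution",
              "loading", "sample_size")
  extra <- switch(family,
    dim_correct   = character(0),
    dim_misspec   = "factor_correlation",
    cross_correct = "factor_correlation",
    cross_misspec = c("factor_correlation", "misspec_magnitude",
                      "misspec_proportion")
  )
  needed <- c(needed, extra)
  missing <- setdiff(needed, names(levels))
  if (length(missing))
    stop(sprintf("family '%s': missing factor(s) %s", family,
                 paste(missing, collapse = ", ")), call. = FALSE)
  surplus <- setdiff(names(levels), needed)
  if (length(surplus))
    stop(sprintf("family '%s': factor(s) %s not part of this family", family,
                 paste(surplus, collapse = ", ")), call. = FALSE)
  for (f in needed) {
    vals <- levels[[f]]
    if (!length(vals))
      stop(sprintf("family '%s': factor '%s' has an empty level set",
                   family, f), call. = FALSE)
    known <- .design_levels[[f]]
    bad <- if (is.numeric(known)) {
      vals[!vapply(vals, function(v)
        any(abs(as.numeric(v) - known) < 1e-9), logical(1))]
    } else {
      vals[!vals %in% known]
    }
    if (length(bad)) {
      msg <- sprintf("family '%s': unknown level(s) %s for factor '%s'",
                     family, paste(bad, collapse = ", "), f)
      if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    }
  }
  if (family %in% c("cross_correct", "cross_misspec")) {
    bad <- setdiff(as.numeric(levels$factor_correlation), c(0, 0.30))
    if (length(bad) && strict)
      stop(sprintf("family '%s': factor_correlation must be in {0, .30}",
                   family), call. = FALSE)
  }
  levels[needed]
}

#' Enumerate the crossed simulation design
#'
#' Expands each family's level sets to the full Cartesian product and
#' concatenates the families in a fixed order
#' (dim_correct, dim_misspec, cross_correct, cross_misspec), each family
#' sorted lexicographically over (estimator, indicators, options,
#' distribution, loading, N, correlation, magnitude, proportion). The
#' ordering is deterministic, so the same configuration always yields the
#' same sequence and the same stable identifiers.
#'
#' @param config Named list of families, each a named list of level vectors;
#'   defaults to [default_design()] (the full built-in grid of 6048 cells).
#' @param strict If `TRUE` (default), reject levels outside the documented
#'   design; if `FALSE`, allow extensions with a warning.
#' @return A data frame with one row per scenario: the design fields plus a
#'   stable `id` column. Fields not applicable to a family are `NA`.
#' @examples
#' nrow(enumerate_scenarios())             # 6048
#' g <- enumerate_scenarios(list(dim_correct = default_design()$dim_correct))
#' nrow(g)                                 # 432
#' @export
enumerate_scenarios <- function(config = default_design(), strict = TRUE) {
  stopifnot(is.list(config), length(config) > 0)
  unknown <- setdiff(names(config), .families)
  if (length(unknown))
    stop("unknown scenario family: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  fams <- .families[.families %in% names(config)]
  out <- lapply(fams, function(fam) {
    lv <- .validate_family_config(fam, config[[fam]], strict = strict)
    # sort each factor's levels so enumeration order is canonical
    lv <- lapply(lv, function(v) sort(unique(v)))
    grid <- expand.grid(lv, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    # lexicographic order: last key varies slowest
    keys <- rev(names(lv))
    grid <- grid[do.call(order, grid[keys]), , drop = FALSE]
    grid$family <- fam
    grid
  })
  all_cols <- c("family", "estimator", "n_indicators", "n_options",
                "distribution", "loading", "sample_size",
                "factor_correlation", "misspec_magnitude",
                "misspec_proportion")
  out <- lapply(out, function(g) {
    for (col in setdiff(all_cols, names(g))) g[[col]] <- NA
    g[all_cols]
  })
  grid <- do.call(rbind, out)
  rownames(grid) <- NULL
  grid$n_indicators <- as.integer(grid$n_indicators)
  grid$n_options <- as.integer(grid$n_options)
  grid$sample_size <- as.integer(grid$sample_size)
  grid$id <- vapply(seq_len(nrow(grid)), function(i)
    scenario_id(as_scenario(grid[i, ])), character(1))
  grid
}

#' Construct a single scenario
#'
#' @param x A one-row data frame (e.g. a row of [enumerate_scenarios()]) or a
#'   named list with the scenario fields.
#' @return An object of class `scenario`.
#' @export
as_scenario <- function(x) {
  if (inherits(x, "scenario")) return(x)
  x <- as.list(x)
  s <- list(
    family             = as.character(x$family),
    estimator          = as.character(x$estimator),
    n_indicators       = as.integer(x$n_indicators),
    n_options          = as.integer(x$n_options),
    distribution       = as.character(x$distribution),
    loading            = as.numeric(x$loading),
    sample_size        = as.integer(x$sample_size),
    factor_correlation = if (is.null(x$factor_correlation)) NA_real_
                         else as.numeric(x$factor_correlation),
    misspec_magnitude  = if (is.null(x$misspec_magnitude)) NA_real_
                         else as.numeric(x$misspec_magnitude),
    misspec_proportion = if (is.null(x$misspec_proportion)) NA_real_
                         else as.numeric(x$misspec_proportion)
  )
  class(s) <- "scenario"
  validate_scenario(s)
  s
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario> ", scenario_id(x), "\n", sep = "")
  invisible(x)
}

validate_scenario <- function(s) {
  if (!s$family %in% .families)
    stop("unknown family '", s$family, "'", call. = FALSE)
  if (!s$estimator %in% .estimators)
    stop("unknown estimator '", s$estimator, "'", call. = FALSE)
  if (!s$distribution %in% c("symmetric", "asymmetric"))
    stop("unknown distribution '", s$distribution, "'", call. = FALSE)
  misspec_cross <- s$family == "cross_misspec"
  if (misspec_cross &&
      (is.na(s$misspec_magnitude) || is.na(s$misspec_proportion)))
    stop("cross_misspec scenarios need misspec_magnitude and ",
         "misspec_proportion", call. = FALSE)
  if (!misspec_cross &&
      (!is.na(s$misspec_magnitude) || !is.na(s$misspec_proportion)))
    stop("misspecification fields only apply to cross_misspec scenarios",
         call. = FALSE)
  if (s$family == "dim_correct" && !is.na(s$factor_correlation))
    stop("dim_correct scenarios have no factor correlation", call. = FALSE)
  if (s$family != "dim_correct" && is.na(s$factor_correlation))
    stop(s$family, " scenarios need a factor_correlation", call. = FALSE)
  invisible(s)
}

#' Stable scenario identifier
#'
#' Injective, filesystem-safe, and stable across runs; round-trips through
#' [parse_scenario_id()].
#'
#' @param s A `scenario` (or coercible via [as_scenario()]).
#' @return A single string.
#' @export
scenario_id <- function(s) {
  s <- as_scenario(s)
  num <- function(v) if (is.na(v)) "na" else sub("^0\\.", ".", format(v, nsmall = 0))
  paste(s$family, s$estimator,
        paste0("p", s$n_indicators), paste0("k", s$n_options),
        substr(s$distribution, 1, 3),
        paste0("l", num(s$loading)), paste0("n", s$sample_size),
        paste0("r", num(s$factor_correlation)),
        paste0("m", num(s$misspec_magnitude)),
        paste0("q", num(s$misspec_proportion)),
        sep = "_")
}

#' Parse a scenario identifier back into a scenario
#' @param id String produced by [scenario_id()].
#' @return A `scenario`.
#' @export
parse_scenario_id <- function(id) {
  toks <- strsplit(id, "_")[[1]]
  if (length(toks) != 11)
    stop("malformed scenario id: ", id, call. = FALSE)
  fam <- paste(toks[1:2], collapse = "_")
  rest <- toks[-(1:2)]
  unnum <- function(x) if (x == "na") NA_real_ else as.numeric(x)
  as_scenario(list(
    family = fam,
    estimator = rest[1],
    n_indicators = as.integer(sub("^p", "", rest[2])),
    n_options = as.integer(sub("^k", "", rest[3])),
    distribution = c(sym = "symmetric", asy = "asymmetric")[[rest[4]]],
    loading = unnum(sub("^l", "", rest[5])),
    sample_size = as.integer(sub("^n", "", rest[6])),
    factor_correlation = unnum(sub("^r", "", rest[7])),
    misspec_magnitude = unnum(sub("^m", "", rest[8])),
    misspec_proportion = unnum(sub("^q", "", rest[9]))
  ))
}

#' Number of cross-loaded indicators implied by a misspecification proportion
#'
#' Proportions .17/.33 map to counts by rounding proportion x indicators to
#' the nearest integer: 1 or 2 of 6 indicators, 2 or 4 of 12.
#'
#' @param proportion Fraction of indicators carrying a cross-loading.
#' @param n_indicators Total indicator count.
#' @return Integer count (at least 1 when `proportion > 0`).
#' @export
cross_loading_count <- function(proportion, n_indicators) {
  if (is.na(proportion) || proportion == 0) return(0L)
  max(1L, as.integer(round(proportion * n_indicators)))
}

#' Read a design configuration from YAML or JSON
#'
#' The file mirrors [default_design()]: top-level keys are family names, each
#' holding named level vectors.
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return A config list for [enumerate_scenarios()].
#' @export
read_design_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("reading JSON configs requires the 'jsonlite' package", call. = FALSE)
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be .yaml/.yml or .json", call. = FALSE)
}
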