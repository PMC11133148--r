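.gof_names <- c("chi2", "chi2_df", "cfi", "rmsea", "srmr")
# CFI is "higher is better": its tailored cutoff is a lower quantile and a
# model is rejected below it; the other four use upper quantiles.
.gof_lower <- c(chi2 = FALSE, chi2_df = FALSE, cfi = TRUE,
                rmsea = FALSE, srmr = FALSE)

#' Derive tailored cutoffs as Type-I-error-controlling quantiles
#'
#' Per scenario and index, the empirical `1 - alpha` quantile (the `alpha`
#' quantile for CFI) of the index distribution over converged replications
#' of a correctly specified model. Rejecting a model beyond these cutoffs
#' has probability `alpha` when the model is correctly specified.
#'
#' @param result A `gof_simulation` whose records all come from correctly
#'   specified scenarios (`dim_correct`, `cross_correct`); misspecified
#'   records are an error, since cutoffs are defined under correct
#'   specification.
#' @param alpha Nominal Type I error rate (default .05).
#' @param min_reps Warn when a cell has fewer converged replications.
#' @return Object of class `cutoff_table`: data frame with scenario id,
#'   per-index cutoffs, `alpha`, `n_effective`.
#' @export
derive_cutoffs <- function(result, alpha = 0.05, min_reps = 50) {
  records <- if (inherits(result, "gof_simulation")) result$records else result
  if (is.null(records) || !nrow(records)) stop("no records", call. = FALSE)
  if (any(!records$family %in% c("dim_correct", "cross_correct")))
    stop("cutoffs are defined on correctly specified scenarios only; ",
         "misspecified-family records present", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1)
  conv <- records[records$converged, , drop = FALSE]
  if (!nrow(conv)) stop("zero converged records", call. = FALSE)
  ids <- unique(records$scenario_id)
  rows <- lapply(ids, function(id) {
    sub <- conv[conv$scenario_id == id, , drop = FALSE]
    if (nrow(sub) < min_reps)
      warning(sprintf("scenario %s: only %d converged replications", id,
                      nrow(sub)), call. = FALSE)
    cuts <- vapply(.gof_names, function(g) {
      v <- sub[[g]][!is.na(sub[[g]])]
      if (!length(v)) return(NA_real_)
      stats::quantile(v, if (.gof_lower[[g]]) alpha else 1 - alpha,
                      names = FALSE, type = 7)
    }, numeric(1))
    data.frame(scenario_id = id, t(cuts), alpha = alpha,
               n_effective = nrow(sub))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cutoff_table", "data.frame")
  out
}

# map a misspecified scenario id to its correctly specified twin: same
# non-misspecification features; dim_misspec loses its population
# correlation (the dim_correct twin is the one-factor population)
.twin_correct_id <- function(id) {
  s <- parse_scenario_id(id)
  if (s$family == "dim_misspec") {
    s$family <- "dim_correct"
    s$factor_correlation <- NA_real_
  } else if (s$family == "cross_misspec") {
    s$family <- "cross_correct"
  } else {
    return(id)
  }
  s$misspec_magnitude <- NA_real_
  s$misspec_proportion <- NA_real_
  scenario_id(s)
}

#' Type I / Type II rates of a cutoff table
#'
#' Correct-specification records are scored against their own scenario's
#' cutoffs (rejection fraction = empirical Type I error); misspecified
#' records are scored against the cutoffs of their correctly specified twin
#' (the cell agreeing on all non-misspecification features), and the
#' acceptance fraction is the empirical Type II error.
#'
#' @param result A `gof_simulation`.
#' @param table A `cutoff_table` covering (the twins of) the scenarios in
#'   `result`.
#' @return Data frame with scenario id, `kind` (`"type1"`/`"type2"`), and a
#'   rate per index.
#' @export
rejection_rates <- function(result, table) {
  records <- if (inherits(result, "gof_simulation")) result$records else result
  conv <- records[records$converged, , drop = FALSE]
  if (!nrow(conv)) stop("zero converged records", call. = FALSE)
  ids <- unique(conv$scenario_id)
  rows <- lapply(ids, function(id) {
    sub <- conv[conv$scenario_id == id, , drop = FALSE]
    correct <- sub$family[1] %in% c("dim_correct", "cross_correct")
    cut_id <- if (correct) id else .twin_correct_id(id)
    cuts <- table[table$scenario_id == cut_id, , drop = FALSE]
    if (!nrow(cuts))
      stop("no cutoffs for scenario ", cut_id, call. = FALSE)
    rates <- vapply(.gof_names, function(g) {
      v <- sub[[g]][!is.na(sub[[g]])]
      if (!length(v) || is.na(cuts[[g]])) return(NA_real_)
      rej <- if (.gof_lower[[g]]) mean(v < cuts[[g]]) else mean(v > cuts[[g]])
      if (correct) rej else 1 - rej
    }, numeric(1))
    data.frame(scenario_id = id, kind = if (correct) "type1" else "type2",
               t(rates))
  })
  do.call(rbind, rows)
}

# ---- regression-formula predictor ----------------------------------------

.coef_cache <- new.env()

#' Shipped cutoff-regression coefficients
#'
#' The embedded coefficient set of the cutoff-prediction formulae: one
#' column per index, one row per term (estimator dummies against the ML
#' reference, main effects, quadratics for factors with more than two
#' levels, and all two-way interactions; sample size enters divided by
#' 1000). SRMR rows involving MLR or WLSMV are `NA` because SRMR is
#' identical under ML/MLR and under DWLS/WLSMV.
#'
#' @return Object of class `cutoff_regression`: `coefficients` (data
#'   frame), `r_squared`, `n_cells`.
#' @export
cutoff_regression_table <- function() {
  if (!is.null(.coef_cache$tab)) return(.coef_cache$tab)
  path <- system.file("extdata", "cutoff_regression_coefficients.csv",
                      package = "gofcutoffs")
  if (path == "") path <- file.path("inst", "extdata",
                                    "cutoff_regression_coefficients.csv")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- raw$term %in% c("r_squared", "n_cells")
  out <- structure(list(
    coefficients = raw[!meta, , drop = FALSE],
    r_squared = unlist(raw[raw$term == "r_squared", .gof_names]),
    n_cells = unlist(raw[raw$term == "n_cells", .gof_names])
  ), class = "cutoff_regression")
  rownames(out$coefficients) <- NULL
  .coef_cache$tab <- out
  out
}

#' @export
print.cutoff_regression <- function(x, ...) {
  cat(sprintf("<cutoff_regression> %d terms per index; R^2: %s\n",
              nrow(x$coefficients),
              paste(sprintf("%s=%.3f", .gof_names, x$r_squared),
                    collapse = " ")))
  invisible(x)
}

# feature vector named by coefficient terms, from analysis characteristics
.cutoff_features <- function(estimator, n_indicators, n_options, asymmetric,
                             loading, sample_size, n_factors, correlated) {
  sz <- sample_size / 1000
  e_mlr <- as.numeric(estimator == "MLR")
  e_dwls <- as.numeric(estimator == "DWLS")
  e_wlsmv <- as.numeric(estimator == "WLSMV")
  base <- c(
    intercept = 1, est_mlr = e_mlr, est_dwls = e_dwls, est_wlsmv = e_wlsmv,
    indicators = n_indicators, options = n_options, options_sq = n_options^2,
    asymmetric = asymmetric, loading = loading, loading_sq = loading^2,
    size = sz, size_sq = sz^2, factors = n_factors)
  inter <- c(
    indicators = n_indicators, options = n_options, options_sq = n_options^2,
    asymmetric = asymmetric, loading = loading, loading_sq = loading^2,
    size = sz, size_sq = sz^2, factors = n_factors)
  feats <- base
  for (est in c("mlr", "dwls", "wlsmv")) {
    dummy <- switch(est, mlr = e_mlr, dwls = e_dwls, wlsmv = e_wlsmv)
    v <- dummy * inter
    names(v) <- paste0("est_", est, "_x_", names(inter))
    feats <- c(feats, v)
  }
  pair <- function(a, aval, bnames) {
    v <- aval * inter[bnames]
    names(v) <- paste0(a, "_x_", bnames)
    v
  }
  feats <- c(feats,
    pair("indicators", n_indicators,
         c("options", "options_sq", "asymmetric", "loading", "loading_sq",
           "size", "size_sq", "factors")),
    pair("options", n_options,
         c("asymmetric", "loading", "loading_sq", "size", "size_sq",
           "factors")),
    pair("options_sq", n_options^2,
         c("asymmetric", "loading", "loading_sq", "size", "size_sq",
           "factors")),
    pair("asymmetric", asymmetric,
         c("loading", "loading_sq", "size", "size_sq", "factors")),
    pair("loading", loading, c("size", "size_sq", "factors")),
    pair("loading_sq", loading^2, c("size", "size_sq", "factors")),
    pair("size", sz, "factors"),
    pair("size_sq", sz^2, "factors"),
    c(factors_x_correlated = n_factors * correlated))
  feats
}

#' Predict tailored cutoffs from data and analysis characteristics
#'
#' Evaluates the cutoff-prediction regression formulae: the sum of the
#' coefficients times the (unstandardized, uncentered) characteristics, with
#' sample size divided by 1000. For SRMR the MLR formula is the ML one and
#' the WLSMV formula the DWLS one (SRMR is identical within those pairs).
#' The chi-square prediction depends on the degrees of freedom of the
#' simulated models and is emitted with a warning attribute: it is barely
#' useful for models different from the built-in grid.
#'
#' @param estimator `"ML"`, `"MLR"`, `"DWLS"` or `"WLSMV"`.
#' @param n_indicators Number of indicators.
#' @param n_options Number of response options.
#' @param distribution `"symmetric"` or `"asymmetric"`.
#' @param loading Standardized loading magnitude.
#' @param sample_size Sample size (raw; divided by 1000 internally).
#' @param n_factors 1 or 2.
#' @param correlated Logical: correlated factors (only meaningful with two
#'   factors).
#' @param reg A `cutoff_regression`; defaults to the shipped table.
#' @return Named numeric vector of predicted cutoffs for the five indices,
#'   with attribute `"chi2_warning"`.
#' @export
predict_cutoffs <- function(estimator, n_indicators, n_options,
                            distribution = c("symmetric", "asymmetric"),
                            loading, sample_size, n_factors = 1,
                            correlated = FALSE,
                            reg = cutoff_regression_table()) {
  distribution <- match.arg(distribution)
  if (!estimator %in% .estimators)
    stop("estimator must be one of ", paste(.estimators, collapse = ", "),
         call. = FALSE)
  if (!n_factors %in% c(1, 2))
    stop("the predictor supports 1 or 2 factors", call. = FALSE)
  rng_warn <- character(0)
  if (n_indicators < 6 || n_indicators > 12)
    rng_warn <- c(rng_warn, "n_indicators outside the simulated range 6-12")
  if (n_options < 3 || n_options > 7)
    rng_warn <- c(rng_warn, "n_options outside the simulated range 3-7")
  if (loading < 0.4 || loading > 0.8)
    rng_warn <- c(rng_warn, "loading outside the simulated range .40-.80")
  if (sample_size < 200 || sample_size > 2000)
    rng_warn <- c(rng_warn, "sample_size outside the simulated range 200-2000")
  if (length(rng_warn))
    warning("extrapolating beyond the simulated design: ",
            paste(rng_warn, collapse = "; "), call. = FALSE)
  asym <- as.numeric(distribution == "asymmetric")
  coefs <- reg$coefficients
  out <- vapply(.gof_names, function(g) {
    est_g <- estimator
    if (g == "srmr") {
      if (estimator == "MLR") est_g <- "ML"
      if (estimator == "WLSMV") est_g <- "DWLS"
    }
    feats <- .cutoff_features(est_g, n_indicators, n_options, asym, loading,
                              sample_size, n_factors, as.numeric(correlated))
    beta <- coefs[[g]]
    names(beta) <- coefs$term
    beta <- beta[!is.na(beta)]
    sum(beta * feats[names(beta)])
  }, numeric(1))
  attr(out, "chi2_warning") <-
    paste("the chi-square prediction depends on the simulated models'",
          "degrees of freedom and is barely useful for other models")
  out
}

#' Fit the cutoff-prediction regression to a cutoff table
#'
#' Ordinary least squares of each index's tailored cutoffs on the scenario
#' characteristics with the full term structure of the shipped coefficient
#' table (estimator dummies against ML, quadratics, all two-way
#' interactions; sample size divided by 1000; the correlated-factors
#' indicator entering only through its interaction with the number of
#' factors). SRMR cutoffs are fitted on the ML/DWLS cells only, without
#' MLR/WLSMV terms.
#'
#' @param table A `cutoff_table` (scenario ids provide the features).
#' @return A `cutoff_regression` with fitted `coefficients`, `r_squared`,
#'   `n_cells`.
#' @export
fit_cutoff_regression <- function(table) {
  if (nrow(table) < 2) stop("cutoff table is underdetermined", call. = FALSE)
  feats <- lapply(table$scenario_id, function(id) {
    s <- parse_scenario_id(id)
    nf <- if (startsWith(s$family, "dim")) 1 else 2
    corr <- if (nf == 2 && !is.na(s$factor_correlation) &&
                s$factor_correlation > 0) 1 else 0
    list(estimator = s$estimator,
         x = function(est) .cutoff_features(
           est, s$n_indicators, s$n_options,
           as.numeric(s$distribution == "asymmetric"), s$loading,
           s$sample_size, nf, corr))
  })
  template <- cutoff_regression_table()$coefficients
  coefs <- template
  r2 <- numeric(length(.gof_names)); names(r2) <- .gof_names
  ncells <- integer(length(.gof_names)); names(ncells) <- .gof_names
  for (g in .gof_names) {
    keep_terms <- template$term[!is.na(template[[g]])]
    rows <- seq_len(nrow(table))
    ests <- vapply(feats, `[[`, character(1), "estimator")
    if (g == "srmr") rows <- rows[ests %in% c("ML", "DWLS")]
    Xm <- t(vapply(rows, function(i)
      feats[[i]]$x(feats[[i]]$estimator)[keep_terms],
      numeric(length(keep_terms))))
    y <- table[[g]][rows]
    ok <- !is.na(y)
    Xm <- Xm[ok, , drop = FALSE]; y <- y[ok]
    qrX <- qr(Xm)
    if (qrX$rank < ncol(Xm)) {
      aliased <- keep_terms[qrX$pivot[(qrX$rank + 1):ncol(Xm)]]
      stop("rank-deficient cutoff regression for ", g, "; aliased terms: ",
           paste(aliased, collapse = ", "), call. = FALSE)
    }
    beta <- qr.coef(qrX, y)
    fittedv <- drop(Xm %*% beta)
    r2[g] <- 1 - sum((y - fittedv)^2) / sum((y - mean(y))^2)
    ncells[g] <- length(y)
    coefs[[g]] <- NA_real_
    coefs[[g]][match(keep_terms, coefs$term)] <- beta
  }
  structure(list(coefficients = coefs, r_squared = r2, n_cells = ncells),
            class = "cutoff_regression")
}
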