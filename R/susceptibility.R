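#' Kendall's tau-b rank correlation
#'
#' Tie-corrected in both margins (the `cor` "kendall" method); returns `NA`
#' when either margin is entirely tied.
#'
#' @param x,y Equal-length vectors (length at least 2).
#' @export
kendall_tau_b <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
  stats::cor(as.numeric(x), as.numeric(y), method = "kendall")
}

# recode indices so that lower = worse fit for every index (CFI already is);
# chi2, chi2/df, RMSEA and SRMR are multiplied by -1
.recode_gofs <- function(records) {
  for (g in c("chi2", "chi2_df", "rmsea", "srmr"))
    records[[g]] <- -records[[g]]
  records
}

# characteristics available in a record set, with >2-level numerics squared
.susceptibility_terms <- function(records) {
  cand <- list(
    est_mlr   = as.numeric(records$estimator == "MLR"),
    est_dwls  = as.numeric(records$estimator == "DWLS"),
    est_wlsmv = as.numeric(records$estimator == "WLSMV"),
    indicators = records$n_indicators,
    options = records$n_options,
    asymmetric = as.numeric(records$distribution == "asymmetric"),
    loading = records$loading,
    size = records$sample_size / 1000,
    correlation = records$factor_correlation,
    magnitude = records$misspec_magnitude,
    proportion = records$misspec_proportion
  )
  cand <- Filter(function(v) !all(is.na(v)) && length(unique(v)) > 1, cand)
  squares <- list(options_sq = cand$options^2, loading_sq = cand$loading^2,
                  size_sq = cand$size^2)
  if (!is.null(cand$correlation) && length(unique(cand$correlation)) > 2)
    squares$correlation_sq <- cand$correlation^2
  c(cand, Filter(Negate(is.null), squares))
}

#' Susceptibility regression of fit indices on design characteristics
#'
#' Per index, a least-squares fit of the recoded index (chi-square,
#' chi-square/df, RMSEA and SRMR multiplied by -1, so that lower always
#' means worse fit) on the characteristics varying in the record subset:
#' linear terms, quadratic terms for characteristics with more than two
#' levels, and all two-way interactions (no higher-order interactions).
#'
#' @param result A `gof_simulation` (typically one family).
#' @param family Optional family name to subset the records first.
#' @return Object of class `susceptibility_summary` with `coefficients`
#'   (list of named vectors per index) and `r_squared`.
#' @export
susceptibility_regression <- function(result, family = NULL) {
  records <- if (inherits(result, "gof_simulation")) result$records else result
  if (!is.null(family))
    records <- records[records$family == family, , drop = FALSE]
  records <- records[records$converged, , drop = FALSE]
  if (!nrow(records)) stop("no converged records", call. = FALSE)
  records <- .recode_gofs(records)
  terms <- .susceptibility_terms(records)
  base_names <- setdiff(names(terms),
                        c("options_sq", "loading_sq", "size_sq",
                          "correlation_sq"))
  X <- do.call(cbind, terms)
  # two-way interactions among the linear characteristics (estimator dummies
  # belong to one categorical characteristic, so they do not interact with
  # each other)
  est_d <- intersect(c("est_mlr", "est_dwls", "est_wlsmv"), base_names)
  pairs <- utils::combn(base_names, 2, simplify = FALSE)
  pairs <- Filter(function(pr) !(all(pr %in% est_d)), pairs)
  for (pr in pairs) {
    v <- terms[[pr[1]]] * terms[[pr[2]]]
    if (length(unique(v)) > 1) {
      X <- cbind(X, v)
      colnames(X)[ncol(X)] <- paste(pr, collapse = "_x_")
    }
  }
  coefs <- list(); r2 <- numeric(0)
  for (g in .gof_names) {
    y <- records[[g]]
    ok <- !is.na(y)
    if (!sum(ok)) next
    fit <- stats::lm.fit(cbind(intercept = 1, X[ok, , drop = FALSE]), y[ok])
    dropped <- names(fit$coefficients)[is.na(fit$coefficients)]
    if (length(dropped))
      warning("aliased terms dropped for ", g, ": ",
              paste(dropped, collapse = ", "), call. = FALSE)
    coefs[[g]] <- fit$coefficients
    r2[g] <- 1 - sum(fit$residuals^2) / sum((y[ok] - mean(y[ok]))^2)
  }
  structure(list(coefficients = coefs, r_squared = r2,
                 n_records = nrow(records)),
            class = "susceptibility_summary")
}

#' @export
print.susceptibility_summary <- function(x, ...) {
  cat("<susceptibility_summary>\n")
  if (length(x$r_squared))
    cat("  R^2:", paste(sprintf("%s=%.3f", names(x$r_squared), x$r_squared),
                        collapse = "  "), "\n")
  invisible(x)
}

#' Grouped medians of an index or parameter estimate
#'
#' The data behind conditional-median displays: medians of `response`
#' (a fit index or `"factor_cor"`) over converged replications, grouped by
#' the requested design factors.
#'
#' @param result A `gof_simulation`.
#' @param condition_on Character vector of record columns to group by.
#' @param response Column to take medians of.
#' @return Data frame of group levels, `median` and `n`; empty groups are
#'   absent.
#' @export
median_profiles <- function(result, condition_on, response = "cfi") {
  records <- if (inherits(result, "gof_simulation")) result$records else result
  records <- records[records$converged, , drop = FALSE]
  missing_cols <- setdiff(c(condition_on, response), names(records))
  if (length(missing_cols))
    stop("columns not present in records: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!nrow(records)) stop("no converged records", call. = FALSE)
  groups <- records[condition_on]
  agg <- stats::aggregate(records[[response]], by = groups,
                          FUN = function(v) stats::median(v, na.rm = TRUE))
  names(agg)[ncol(agg)] <- "median"
  cnt <- stats::aggregate(records[[response]], by = groups,
                          FUN = function(v) sum(!is.na(v)))
  agg$n <- cnt$x
  agg[!is.na(agg$median), , drop = FALSE]
}

#' Pooled Kendall association of a characteristic with a column
#'
#' Convenience wrapper: tau-b between a design characteristic and a record
#' column over converged replications.
#'
#' @inheritParams median_profiles
#' @param characteristic Record column holding the design characteristic.
#' @export
gof_tau_b <- function(result, characteristic, response) {
  records <- if (inherits(result, "gof_simulation")) result$records else result
  records <- records[records$converged, , drop = FALSE]
  ok <- !is.na(records[[characteristic]]) & !is.na(records[[response]])
  kendall_tau_b(records[[characteristic]][ok], records[[response]][ok])
}
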