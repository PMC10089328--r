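## Posterior summaries: odds-ratio tables, smooth-effect curves, spatial
## significance codes, and variance-component tables.

.cri <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  unname(quantile(x, c(a, 1 - a), type = 7))
}

#' Posterior odds-ratio table for the fixed effects
#'
#' Each stored fixed-effect draw is exponentiated; the table reports the
#' mean and central 95% credible interval of the odds-ratio draws, and
#' flags a term significant when the interval excludes 1.  (The point
#' estimate is the mean of the exponentiated draws, not the exponentiated
#' mean; both are recoverable from the stored draws.)
#'
#' @param fit A [star_fit()] result.
#' @param level Credible level (default 0.95).
#' @param include_intercept Include the intercept row (default `FALSE`).
#' @return Data frame with columns `term`, `or_mean`, `cri_low`,
#'   `cri_high`, `significant`.
#' @export
odds_ratio_table <- function(fit, level = 0.95, include_intercept = FALSE) {
  stopifnot(inherits(fit, "star_fit"))
  draws <- fit$samples$fixed
  if (!include_intercept)
    draws <- draws[, colnames(draws) != "(Intercept)", drop = FALSE]
  rows <- lapply(colnames(draws), function(term) {
    or <- exp(draws[, term])
    ci <- .cri(or, level)
    data.frame(term = term, or_mean = mean(or), cri_low = ci[1],
               cri_high = ci[2],
               significant = ci[1] > 1 || ci[2] < 1)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Posterior smooth-effect curve with credible band
#'
#' Evaluates the stored spline basis on a grid, multiplies by each stored
#' coefficient draw, and reports the pointwise posterior mean and central
#' credible band on the log-odds scale.  The sum-to-zero constraint built
#' into the fit centres the curve (mean zero over the observed covariate
#' values) for every draw.
#'
#' @param fit A [star_fit()] result.
#' @param term Smooth term name, e.g. `"s(child_age)"` (the bare
#'   covariate name is also accepted).
#' @param grid Evaluation points; default 100 equidistant points over the
#'   observed range.  Must lie inside the knot range.
#' @param level Credible level (default 0.95).
#' @return Data frame with columns `x`, `mean`, `cri_low`, `cri_high`.
#' @export
smooth_effect_curve <- function(fit, term, grid = NULL, level = 0.95) {
  stopifnot(inherits(fit, "star_fit"))
  if (!term %in% names(fit$samples$smooth))
    term <- paste0("s(", term, ")")
  if (!term %in% names(fit$samples$smooth))
    stop("no smooth term '", term, "' in fit", call. = FALSE)
  block <- fit$blocks[[term]]
  info <- block$info
  if (is.null(grid))
    grid <- seq(info$range[1], info$range[2], length.out = 100)
  if (any(grid < info$range[1] | grid > info$range[2]))
    stop("grid outside knot range", call. = FALSE)
  B <- .eval_bspline(info$knots, grid, info$degree, info$range[2])
  Xg <- B %*% info$Z                        # constrained parameterisation
  draws <- fit$samples$smooth[[term]]       # ndraws x r
  curves <- draws %*% t(Xg)                 # ndraws x ngrid
  a <- (1 - level) / 2
  data.frame(
    x = grid,
    mean = colMeans(curves),
    cri_low = apply(curves, 2, quantile, probs = a),
    cri_high = apply(curves, 2, quantile, probs = 1 - a)
  )
}

#' Spatial significance classification
#'
#' Summarises the per-region spatial effect draws and codes each region
#' `+1` when the credible interval lies above zero (significantly higher
#' odds), `-1` when below zero, and `0` otherwise.
#'
#' @param fit A [star_fit()] result with spatial effects.
#' @param component `"total"` (structured + unstructured, the full
#'   `f_spat` decomposition; default), `"structured"` or
#'   `"unstructured"`.
#' @param level Credible level (default 0.95).
#' @return Data frame with columns `region`, `mean_logodds`, `cri_low`,
#'   `cri_high`, `code`.
#' @export
spatial_significance <- function(fit,
                                 component = c("total", "structured",
                                               "unstructured"),
                                 level = 0.95) {
  stopifnot(inherits(fit, "star_fit"))
  component <- match.arg(component)
  draws <- switch(component,
    total = {
      if (is.null(fit$samples$str) && is.null(fit$samples$unstr))
        stop("fit has no spatial effects", call. = FALSE)
      s <- fit$samples$str
      u <- fit$samples$unstr
      if (is.null(s)) u else if (is.null(u)) s else s + u
    },
    structured = fit$samples$str,
    unstructured = fit$samples$unstr)
  if (is.null(draws))
    stop("fit has no ", component, " spatial effects", call. = FALSE)
  rows <- lapply(colnames(draws), function(r) {
    ci <- .cri(draws[, r], level)
    data.frame(region = r, mean_logodds = mean(draws[, r]),
               cri_low = ci[1], cri_high = ci[2],
               code = if (ci[1] > 0) 1L else if (ci[2] < 0) -1L else 0L)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Posterior summary of the variance components
#'
#' One row per penalised block (each smooth term, then the structured
#' and unstructured spatial components): posterior mean, SD and central
#' 95% credible interval of the variance draws.
#'
#' @param fit A [star_fit()] result.
#' @param level Credible level (default 0.95).
#' @return Data frame with columns `component`, `mean`, `sd`, `cri_low`,
#'   `cri_high`.
#' @export
variance_summary <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "star_fit"))
  v <- fit$variance_samples
  rows <- lapply(colnames(v), function(comp) {
    ci <- .cri(v[, comp], level)
    data.frame(component = comp, mean = mean(v[, comp]), sd = sd(v[, comp]),
               cri_low = ci[1], cri_high = ci[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write spatial significance codes as JSON
#'
#' @param summary Output of [spatial_significance()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spatial_codes <- function(summary, path) {
  codes <- setNames(as.list(summary$code), summary$region)
  jsonlite::write_json(codes, path, auto_unbox = TRUE)
  invisible(path)
}
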