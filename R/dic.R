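## Deviance information criterion and the nested M0-M3 model hierarchy.

#' DIC report from its components
#'
#' `pD = dbar - dhat` (effective number of parameters) and
#' `DIC = dbar + pD = dhat + 2 * pD`, with `dbar` the posterior mean
#' deviance and `dhat` the deviance at the posterior means of the
#' parameters (the classical plug-in definition).
#'
#' @param dbar Posterior mean deviance.
#' @param dhat Deviance at the posterior means.
#' @return Object of class `dic_report` with fields `dic`, `pd`, `dbar`,
#'   `dhat`.
#' @examples
#' dic_report(dbar = 12947.11 + 38.38, dhat = 12947.11)$dic  # 13023.87
#' @export
dic_report <- function(dbar, dhat) {
  pd <- dbar - dhat
  structure(list(dic = dbar + pd, pd = pd, dbar = dbar, dhat = dhat),
            class = "dic_report")
}

#' @export
print.dic_report <- function(x, ...) {
  cat(sprintf("DIC %.2f  (pD %.2f, mean deviance %.2f, plug-in %.2f)\n",
              x$dic, x$pd, x$dbar, x$dhat))
  invisible(x)
}

#' Compute the DIC of a fitted model
#'
#' `dbar` is the mean of the stored deviance trace; `dhat` evaluates the
#' Bernoulli deviance at the linear predictor built from the posterior
#' mean of every coefficient block.
#'
#' @param fit A [star_fit()] result.
#' @param data Unused (the fit retains its outcome and design); accepted
#'   for interface symmetry.
#' @return A [dic_report()].
#' @export
compute_dic <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "star_fit"))
  if (!length(fit$deviance_trace)) stop("empty deviance trace", call. = FALSE)
  dbar <- mean(fit$deviance_trace)
  dhat <- bernoulli_deviance(fit$y, .eta_at_posterior_means(fit))
  dic_report(dbar, dhat)
}

#' Fit the nested model hierarchy M0-M3 and compare by DIC
#'
#' * `M0`: linear fixed effects for all covariates (continuous ones as
#'   centred linear columns);
#' * `M1`: M0 with the continuous covariates replaced by P-spline smooths;
#' * `M2`: M0 plus structured + unstructured spatial effects;
#' * `M3`: the full geo-additive model (smooths and spatial effects).
#'
#' The selected model is the DIC argmin.
#'
#' @param data Data frame with outcome and covariates.
#' @param graph A [region_graph()].
#' @param config A [chain_config()] used for every model.
#' @param outcome Outcome column name (default `"outcome"`).
#' @param fixed Character vector of categorical covariates.
#' @param continuous Continuous covariates smoothed in M1/M3 (default
#'   `c("child_age", "mother_age")`).
#' @param region Region id column (default `"region"`).
#' @param smooth A [smooth_term()] applied to every continuous covariate.
#' @param keep_fits Keep the four `star_fit` objects (default `TRUE`).
#' @return Object of class `star_hierarchy`: list with `reports` (named
#'   [dic_report()]s), `table` (rows DIC, pD, Deviance; columns M0-M3),
#'   `selected`, and `fits` when kept.
#' @export
fit_hierarchy <- function(data, graph, config = chain_config(),
                          outcome = "outcome", fixed = character(),
                          continuous = c("child_age", "mother_age"),
                          region = "region", smooth = smooth_term(),
                          keep_fits = TRUE) {
  continuous <- intersect(continuous, names(data))
  smooths <- setNames(rep(list(smooth), length(continuous)), continuous)
  spat <- spatial_term(region)
  specs <- list(
    M0 = star_spec(outcome, fixed = c(fixed, continuous)),
    M1 = star_spec(outcome, fixed = fixed, smooth = smooths),
    M2 = star_spec(outcome, fixed = c(fixed, continuous), spatial = spat),
    M3 = star_spec(outcome, fixed = fixed, smooth = smooths, spatial = spat)
  )
  fits <- lapply(specs, function(sp)
    star_fit(sp, data, graph = graph, config = config))
  reports <- lapply(fits, compute_dic)
  tab <- base::matrix(
    c(vapply(reports, `[[`, 0, "dic"),
      vapply(reports, `[[`, 0, "pd"),
      vapply(reports, `[[`, 0, "dhat")),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("DIC", "pD", "Deviance"), names(specs)))
  structure(
    list(reports = reports, table = tab,
         selected = names(specs)[which.min(tab["DIC", ])],
         fits = if (keep_fits) fits),
    class = "star_hierarchy")
}

#' @export
print.star_hierarchy <- function(x, ...) {
  print(round(x$table, 2))
  cat("selected:", x$selected, "(smallest DIC)\n")
  invisible(x)
}
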