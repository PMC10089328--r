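## Synthetic survey-data generator: DHS-like child records on a region
## graph with known ground truth (fixed effects, smooth functions,
## structured/unstructured spatial fields), used for validation and
## parameter-recovery experiments.  All generators are pure functions of
## (arguments, seed).

#' Draw one intrinsic GMRF field on a region graph
#'
#' Samples a zero-sum Gaussian field with density proportional to
#' `exp(-f' K f / (2 * variance))`, `K` the neighbourhood matrix of
#' [gmrf_precision()].  Sampling uses the spectral decomposition of `K`
#' with the null (constant) eigenvector removed, so the sum-to-zero
#' constraint holds exactly and the field covariance is
#' `variance * pinv(K)`.
#'
#' @param graph A connected [region_graph()].
#' @param variance Structured spatial variance (> 0, log-odds^2 units).
#' @param seed Optional integer seed (sets the R RNG).
#' @param n Number of independent fields to draw (default 1).
#' @return If `n = 1` a named vector of per-region effects; otherwise an
#'   `n x n_regions` matrix.
#' @examples
#' f <- sample_structured_field(make_lattice_graph(2, 2), 0.3, seed = 1)
#' sum(f)  # 0 (up to rounding)
#' @export
sample_structured_field <- function(graph, variance, seed = NULL, n = 1) {
  stopifnot(inherits(graph, "region_graph"), variance >= 0)
  if (!is.null(seed)) set.seed(seed)
  S <- length(graph$ids)
  if (variance == 0) {
    out <- base::matrix(0, n, S, dimnames = list(NULL, graph$ids))
    return(if (n == 1) out[1, ] else out)
  }
  K <- gmrf_precision(graph)
  eig <- eigen(K, symmetric = TRUE)
  lam <- eig$values[seq_len(S - 1)]        # positive eigenvalues
  V <- eig$vectors[, seq_len(S - 1), drop = FALSE]
  if (any(lam < 1e-10)) stop("graph must be connected", call. = FALSE)
  Z <- base::matrix(rnorm(n * (S - 1)), S - 1, n)
  out <- t(V %*% (sqrt(variance / lam) * Z))
  colnames(out) <- graph$ids
  if (n == 1) out[1, ] else out
}

#' Default categorical covariate mix (survey-like variable set)
#'
#' Level sets and reference categories follow the standard DHS child
#' questionnaire variables (illness recall, vitamin A, birth order and
#' size, breastfeeding, maternal education / BMI / work, household
#' water / toilet / residence / wealth, media exposure).  The marginal
#' probabilities are plausible national survey frequencies; the source
#' data's marginals are not public, so these are the package's fixed
#' choices, documented in the methods vignette.
#'
#' @return Named list; each element has `levels` (reference first) and
#'   `p` (probabilities summing to 1).
#' @export
default_covariate_mix <- function() {
  list(
    gender      = list(levels = c("female", "male"), p = c(0.49, 0.51)),
    diarrhoea   = list(levels = c("no", "yes"), p = c(0.87, 0.13)),
    cough       = list(levels = c("no", "yes"), p = c(0.80, 0.20)),
    fever       = list(levels = c("no", "yes"), p = c(0.75, 0.25)),
    vitamin_a   = list(levels = c("no", "yes"), p = c(0.55, 0.45)),
    birth_order = list(levels = c("1st", "2nd-3rd", "4th+"),
                       p = c(0.20, 0.35, 0.45)),
    size_birth  = list(levels = c("very small", "small", "average/larger"),
                       p = c(0.05, 0.12, 0.83)),
    breastfeeding = list(levels = c("no", "yes"), p = c(0.55, 0.45)),
    education   = list(levels = c("none", "primary", "secondary+"),
                       p = c(0.45, 0.15, 0.40)),
    bmi         = list(levels = c("normal", "thin", "obese"),
                       p = c(0.70, 0.10, 0.20)),
    working     = list(levels = c("no", "yes"), p = c(0.35, 0.65)),
    toilet      = list(levels = c("unimproved", "improved"), p = c(0.45, 0.55)),
    water       = list(levels = c("unimproved", "improved"), p = c(0.35, 0.65)),
    residence   = list(levels = c("rural", "urban"), p = c(0.60, 0.40)),
    wealth      = list(levels = c("poorest", "poorer", "middle", "richer",
                                  "richest"),
                       p = c(0.25, 0.22, 0.19, 0.18, 0.16)),
    media       = list(levels = c("no", "yes"), p = c(0.45, 0.55))
  )
}

#' Simulate child-level covariates on a region graph
#'
#' Child age is discrete uniform on 0-59 months, mother age discrete
#' uniform on 15-49 years, region assignment multinomial over regions,
#' and each categorical variable multinomial with its `mix` probabilities
#' (reference level first in the factor levels).
#'
#' @param n Number of records.
#' @param graph A [region_graph()].
#' @param mix Named list of categorical variables as in
#'   [default_covariate_mix()]; may be a subset or empty list.
#' @param region_p Optional region assignment probabilities (default
#'   uniform).
#' @param seed Optional integer seed.
#' @return Data frame with `region`, `child_age`, `mother_age` and one
#'   factor column per `mix` entry.
#' @export
simulate_covariates <- function(n, graph, mix = default_covariate_mix(),
                                region_p = NULL, seed = NULL) {
  stopifnot(n >= 1, inherits(graph, "region_graph"))
  if (!is.null(seed)) set.seed(seed)
  for (v in names(mix)) {
    p <- mix[[v]]$p
    if (length(p) != length(mix[[v]]$levels) || any(p < 0) ||
        abs(sum(p) - 1) > 1e-8)
      stop("invalid probability vector for '", v, "'", call. = FALSE)
  }
  if (is.null(region_p)) region_p <- rep(1, length(graph$ids))
  region_p <- region_p / sum(region_p)
  out <- data.frame(
    region = factor(sample(graph$ids, n, replace = TRUE, prob = region_p),
                    levels = graph$ids),
    child_age = sample(0:59, n, replace = TRUE),
    mother_age = sample(15:49, n, replace = TRUE)
  )
  for (v in names(mix)) {
    lev <- mix[[v]]$levels
    out[[v]] <- factor(sample(lev, n, replace = TRUE, prob = mix[[v]]$p),
                       levels = lev)
  }
  out
}

#' Ground-truth parameter set for the outcome generator
#'
#' @param beta Named vector of fixed-effect log-odds, named
#'   `"(Intercept)"` and `"<variable>:<level>"` for each non-reference
#'   level (unnamed levels default to effect 0).
#' @param f_child_age,f_mother_age Functions of age (months / years)
#'   returning log-odds contributions; centred over the sampled covariate
#'   values at simulation time.
#' @param f_str,f_unstr Named per-region log-odds effects (structured
#'   field should sum to zero).
#' @param var_str,var_unstr The variances used to generate the fields
#'   (recorded for recovery checks).
#' @return Object of class `true_params`.
#' @export
true_params <- function(beta = c("(Intercept)" = 0),
                        f_child_age = function(a) rep(0, length(a)),
                        f_mother_age = function(a) rep(0, length(a)),
                        f_str = NULL, f_unstr = NULL,
                        var_str = 0, var_unstr = 0) {
  stopifnot(is.numeric(beta), !is.null(names(beta)))
  structure(list(beta = beta, f_child_age = f_child_age,
                 f_mother_age = f_mother_age, f_str = f_str,
                 f_unstr = f_unstr, var_str = var_str,
                 var_unstr = var_unstr),
            class = "true_params")
}

#' Default ground truth on a graph
#'
#' Fixed-effect log-odds taken as round values of plausible magnitude for
#' a handful of variables (male gender, diarrhoea, media exposure,
#' maternal BMI and education); the child-age smooth is a centred
#' concave shape rising to a peak near 30 months, dipping to 48 months
#' and rising again; the mother-age smooth is linear with a small
#' negative slope; the structured field is one intrinsic GMRF draw with
#' variance `var_str` and the unstructured field i.i.d. normal with
#' variance `var_unstr`.
#'
#' @param graph A [region_graph()].
#' @param var_str,var_unstr Spatial variances (defaults 0.3 and 0.01).
#' @param seed Integer seed for the spatial field draws.
#' @return A [true_params()] object.
#' @export
default_truth <- function(graph, var_str = 0.3, var_unstr = 0.01, seed = 1) {
  beta <- c("(Intercept)" = -0.45,
            "gender:male" = log(1.315),
            "diarrhoea:yes" = log(1.256),
            "media:yes" = log(0.858),
            "bmi:thin" = log(1.216), "bmi:obese" = log(0.691),
            "education:primary" = log(0.801),
            "education:secondary+" = log(0.622))
  f_child <- function(a) {
    y <- 0.6 * (1 - ((a - 30) / 30)^2)
    up <- a > 48
    y[up] <- 0.6 * (1 - (18 / 30)^2) + 0.02 * (a[up] - 48)
    y
  }
  f_mother <- function(a) -0.012 * (a - 32)
  if (!is.null(seed)) set.seed(seed)
  f_str <- if (var_str > 0) sample_structured_field(graph, var_str) else
    setNames(rep(0, length(graph$ids)), graph$ids)
  f_unstr <- setNames(
    if (var_unstr > 0) rnorm(length(graph$ids), 0, sqrt(var_unstr)) else
      rep(0, length(graph$ids)),
    graph$ids)
  true_params(beta = beta, f_child_age = f_child, f_mother_age = f_mother,
              f_str = f_str, f_unstr = f_unstr,
              var_str = var_str, var_unstr = var_unstr)
}

# Ground-truth linear predictor for a covariate table: intercept + dummy
# effects + centred smooths + spatial fields.
.truth_eta <- function(records, truth) {
  n <- nrow(records)
  int <- if ("(Intercept)" %in% names(truth$beta))
    truth$beta[["(Intercept)"]] else 0
  eta <- rep(int, n)
  for (nm in setdiff(names(truth$beta), "(Intercept)")) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    v <- parts[1]; lev <- paste(parts[-1], collapse = ":")
    if (!v %in% names(records))
      stop("truth references missing covariate '", v, "'", call. = FALSE)
    eta <- eta + truth$beta[[nm]] * (as.character(records[[v]]) == lev)
  }
  if ("child_age" %in% names(records)) {
    f <- truth$f_child_age(records$child_age)
    eta <- eta + (f - mean(f))
  }
  if ("mother_age" %in% names(records)) {
    f <- truth$f_mother_age(records$mother_age)
    eta <- eta + (f - mean(f))
  }
  reg <- as.character(records$region)
  if (!is.null(truth$f_str)) {
    if (any(!reg %in% names(truth$f_str)))
      stop("region missing from structured field", call. = FALSE)
    eta <- eta + truth$f_str[reg]
  }
  if (!is.null(truth$f_unstr)) eta <- eta + truth$f_unstr[reg]
  unname(eta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate binary outcomes through the geo-additive predictor
#'
#' For each record computes the log-odds
#' `eta = intercept + dummy effects + f_child(age) + f_mother(age) +
#' f_str(region) + f_unstr(region)` (smooth contributions centred over
#' the sample) and draws `outcome ~ Bernoulli(plogis(eta))`.
#'
#' @param records Covariate table from [simulate_covariates()].
#' @param truth A [true_params()] object.
#' @param seed Optional integer seed.
#' @return `records` with added `outcome` column; the truth, seed and the
#'   per-record true `eta` are attached as attributes `truth`, `seed`,
#'   `eta`.
#' @export
simulate_outcomes <- function(records, truth, seed = NULL) {
  stopifnot(inherits(truth, "true_params"))
  if (!is.null(seed)) set.seed(seed)
  eta <- .truth_eta(records, truth)
  records$outcome <- rbinom(nrow(records), 1, plogis(eta))
  attr(records, "truth") <- truth
  attr(records, "eta") <- eta
  attr(records, "seed") <- seed
  records
}

#' One-call synthetic dataset
#'
#' Covariates plus outcomes on a graph with the [default_truth()] (or a
#' supplied one).
#'
#' @inheritParams simulate_covariates
#' @param truth A [true_params()]; default [default_truth()] on `graph`.
#' @return Data frame with covariates and `outcome`, truth attached as an
#'   attribute (see [simulate_outcomes()]).
#' @export
simulate_ciaf_data <- function(n, graph, truth = NULL,
                               mix = default_covariate_mix(), seed = 1) {
  set.seed(seed)
  if (is.null(truth)) {
    truth <- default_truth(graph, seed = seed)
    # keep only effects whose covariate is simulated under this mix
    keep <- vapply(names(truth$beta), function(nm)
      nm == "(Intercept)" ||
        strsplit(nm, ":", fixed = TRUE)[[1]][1] %in% names(mix), TRUE)
    truth$beta <- truth$beta[keep]
  }
  rec <- simulate_covariates(n, graph, mix = mix)
  simulate_outcomes(rec, truth)
}

#' Simulate correlated anthropometric z-scores at a target CIAF prevalence
#'
#' Draws trivariate normal (HAZ, WHZ, WAZ) records with the given
#' correlation and a common mean shift calibrated by 1-D root finding so
#' that the empirical CIAF prevalence (any z-score strictly below -2)
#' matches `target_prevalence` on the generated sample.
#'
#' @param n Number of records.
#' @param target_prevalence Target fraction in (0, 1).
#' @param correlation 3x3 positive-definite correlation matrix; default
#'   has moderate positive dependence (HAZ-WAZ and WHZ-WAZ correlated,
#'   as underweight is a composite of the other two).
#' @param sd Common marginal standard deviation (default 1.1, slightly
#'   over-dispersed relative to the reference population).
#' @param seed Optional integer seed.
#' @return Data frame with columns `haz`, `whz`, `waz`.
#' @export
simulate_zscores <- function(n, target_prevalence = 0.413,
                             correlation = NULL, sd = 1.1, seed = NULL) {
  stopifnot(n >= 1, target_prevalence > 0, target_prevalence < 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(correlation))
    correlation <- base::matrix(c(1, 0.05, 0.55,
                                  0.05, 1, 0.6,
                                  0.55, 0.6, 1), 3, 3)
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("correlation not positive definite", call. = FALSE)
  L <- chol(correlation)
  Z0 <- base::matrix(rnorm(n * 3), n, 3) %*% L * sd
  prev <- function(m) mean(Z0[, 1] + m < -2 | Z0[, 2] + m < -2 |
                             Z0[, 3] + m < -2)
  if (prev(-8) < target_prevalence || prev(8) > target_prevalence)
    stop("target prevalence unattainable", call. = FALSE)
  # step function of m; bisect to the target on this fixed sample
  lo <- -8; hi <- 8
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (prev(mid) > target_prevalence) lo <- mid else hi <- mid
  }
  m <- if (abs(prev(lo) - target_prevalence) <
           abs(prev(hi) - target_prevalence)) lo else hi
  data.frame(haz = Z0[, 1] + m, whz = Z0[, 2] + m, waz = Z0[, 3] + m)
}
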