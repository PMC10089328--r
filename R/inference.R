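## MCMC for the Bayesian geo-additive logistic model.  Polya-Gamma data
## augmentation gives multivariate-Gaussian full conditionals for every
## coefficient block and conjugate inverse-gamma full conditionals for
## every variance component; the sampler sweeps fixed -> smooths ->
## structured -> unstructured -> variances.

#' Additive linear predictor over design blocks
#'
#' @param blocks Named list of [design_block()]s (e.g. from
#'   [build_design()]).
#' @param params Named list of coefficient vectors, one per block, on the
#'   block's (possibly constrained) parameterisation.
#' @return Numeric vector `eta`, the sum of all block contributions.
#' @export
linear_predictor <- function(blocks, params) {
  eta <- 0
  for (nm in names(blocks)) {
    th <- params[[nm]]
    if (is.null(th))
      stop("missing parameters for block '", nm, "'", call. = FALSE)
    X <- blocks[[nm]]$matrix
    if (length(th) != ncol(X))
      stop("dimension mismatch for block '", nm, "'", call. = FALSE)
    eta <- eta + as.numeric(X %*% th)
  }
  eta
}

#' Bernoulli deviance of a logistic predictor
#'
#' `-2 * sum(y * log(p) + (1 - y) * log(1 - p))` with
#' `p = plogis(eta)` clamped to `[1e-12, 1 - 1e-12]` so the deviance
#' stays finite under numerically saturated predictors.
#'
#' @param outcome Binary 0/1 vector.
#' @param eta Linear predictor (log-odds), same length.
#' @return Non-negative scalar deviance.
#' @examples
#' bernoulli_deviance(c(1, 0), c(0, 0))  # -2 * 2 * log(0.5)
#' @export
bernoulli_deviance <- function(outcome, eta) {
  stopifnot(length(outcome) == length(eta))
  p <- plogis(eta)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * sum(outcome * log(p) + (1 - outcome) * log(1 - p))
}

#' Full conditional of one region's structured effect
#'
#' Under the intrinsic GMRF prior, a region's effect given all others is
#' Gaussian with mean the average of its neighbours' effects and variance
#' `variance / N_s` (`N_s` the neighbour count).
#'
#' @param region Region label.
#' @param effects Named vector of current per-region effects.
#' @param graph A [region_graph()].
#' @param variance Structured spatial variance.
#' @return Named vector `c(mean, variance)`.
#' @examples
#' g <- make_lattice_graph(1, 3)
#' gmrf_conditional(g$ids[2], setNames(c(1, 0, 3), g$ids), g, variance = 2)
#' @export
gmrf_conditional <- function(region, effects, graph, variance) {
  nb <- region_neighbours(graph, region)
  if (!length(nb)) stop("region has no neighbours", call. = FALSE)
  if (any(!nb %in% names(effects)))
    stop("effects vector missing neighbour values", call. = FALSE)
  c(mean = mean(effects[nb]), variance = variance / length(nb))
}

#' Conjugate inverse-gamma draw for a variance component
#'
#' Full conditional of the variance behind a Gaussian penalty prior
#' `coef ~ N(0, variance * pinv(penalty))`:
#' `IG(a + rank/2, b + coef' K coef / 2)`.
#'
#' @param coef Coefficient vector of the block.
#' @param penalty Penalty matrix `K`.
#' @param a,b Inverse-gamma prior hyperparameters (default 0.001 each).
#' @param rank Rank of `K`; computed from its eigenvalues when missing.
#' @param seed Optional integer seed.
#' @return One draw of the variance.
#' @export
update_variance <- function(coef, penalty, a = 0.001, b = 0.001,
                            rank = NULL, seed = NULL) {
  stopifnot(a > 0, b > 0)
  if (!is.null(seed)) set.seed(seed)
  penalty <- as.matrix(penalty)
  if (is.null(rank)) {
    ev <- eigen(penalty, symmetric = TRUE, only.values = TRUE)$values
    rank <- sum(ev > 1e-10 * max(1, max(abs(ev))))
  }
  quad <- drop(crossprod(coef, penalty %*% coef))
  shape <- a + rank / 2
  scale <- b + quad / 2
  1 / rgamma(1, shape = shape, rate = scale)
}

# Crude quasi-separation check on dummy columns of the fixed block.
.warn_separation <- function(X, y) {
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    if (!all(x %in% c(0, 1)) || length(unique(x)) < 2) next
    y1 <- unique(y[x == 1]); y0 <- unique(y[x == 0])
    if (length(y1) == 1 && length(y0) == 1 && y1 != y0)
      warning("possible separation on column '", colnames(X)[j],
              "'; posterior remains proper through the priors",
              call. = FALSE)
  }
}

# One Gaussian block draw: precision = X' Omega X + prior precision,
# canonical mean vector bvec = X'(kappa - omega * eta_rest).
.draw_block <- function(X, omega, bvec, prior_prec) {
  P <- crossprod(X * sqrt(omega)) + prior_prec
  R <- tryCatch(chol(P),
                error = function(e) chol(P + diag(1e-8, ncol(P))))
  m <- backsolve(R, backsolve(R, bvec, transpose = TRUE))
  as.numeric(m + backsolve(R, rnorm(ncol(X))))
}

.data_digest <- function(data) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(data, f, version = 2)
  unname(tools::md5sum(f))
}

#' Fit the geo-additive logistic model by MCMC
#'
#' Gibbs sampler with Polya-Gamma augmentation: at each sweep latent
#' `omega_i ~ PG(1, eta_i)` are drawn, then every coefficient block
#' (fixed effects with diffuse `N(0, 1e8)` priors; P-spline blocks with
#' random-walk penalty priors; structured region effects with the
#' intrinsic GMRF prior; unstructured region effects with i.i.d. Gaussian
#' priors) is updated jointly from its Gaussian full conditional, and
#' every penalised block's variance from its conjugate inverse-gamma full
#' conditional.  Identical seeds give identical chains.
#'
#' @param spec A [star_spec()].
#' @param data Data frame with outcome and covariates.
#' @param graph A [region_graph()] (needed for spatial terms).
#' @param config A [chain_config()].
#' @param verbose Print progress every 1000 sweeps (default `FALSE`).
#' @return Object of class `star_fit` with elements:
#'   * `samples`: list with `fixed` (draws x p, named columns), `smooth`
#'     (per-term coefficient draws on the constrained basis), `str` and
#'     `unstr` (draws x regions, per-region effects);
#'   * `variance_samples`: draws x components (smooth terms,
#'     `Structured`, `Unstructured`);
#'   * `deviance_trace`: stored deviance values;
#'   * `blocks`, `spec`, `config`, `y`, `data_digest`.
#' @export
star_fit <- function(spec, data, graph = NULL, config = chain_config(),
                     verbose = FALSE) {
  stopifnot(inherits(spec, "star_spec"), inherits(config, "chain_config"))
  set.seed(config$seed)
  des <- build_design(spec, data, graph)
  y <- des$y
  blocks <- des$blocks
  bn <- names(blocks)
  n <- length(y)
  .warn_separation(blocks$fixed$matrix, y)

  penalized <- bn[vapply(blocks, function(b) any(b$penalty != 0), TRUE)]
  theta <- lapply(blocks, function(b) rep(0, ncol(b$matrix)))
  tau2 <- setNames(rep(0.1, length(penalized)), penalized)
  fix_cols <- colnames(blocks$fixed$matrix)
  if ("(Intercept)" %in% fix_cols) {
    p0 <- min(max(mean(y), 1e-3), 1 - 1e-3)
    theta$fixed[match("(Intercept)", fix_cols)] <- log(p0 / (1 - p0))
  }
  eta <- as.numeric(blocks$fixed$matrix %*% theta$fixed)
  kappa <- y - 0.5

  nstore <- (config$iterations - config$burnin) %/% config$thin
  if (nstore < 1) stop("chain stores no draws; lengthen it", call. = FALSE)
  smooth_names <- grep("^s\\(", bn, value = TRUE)
  out_fixed <- base::matrix(NA_real_, nstore, length(fix_cols),
                            dimnames = list(NULL, fix_cols))
  out_smooth <- lapply(blocks[smooth_names], function(b)
    base::matrix(NA_real_, nstore, ncol(b$matrix)))
  out_str <- out_unstr <- NULL
  if ("Structured" %in% bn)
    out_str <- base::matrix(NA_real_, nstore,
                            length(blocks$Structured$info$regions),
                            dimnames = list(NULL,
                                            blocks$Structured$info$regions))
  if ("Unstructured" %in% bn)
    out_unstr <- base::matrix(NA_real_, nstore,
                              length(blocks$Unstructured$info$regions),
                              dimnames = list(NULL,
                                              blocks$Unstructured$info$regions))
  out_tau2 <- base::matrix(NA_real_, nstore, length(penalized),
                           dimnames = list(NULL, penalized))
  out_dev <- numeric(nstore)

  fixed_prec <- diag(1e-8, length(fix_cols))
  k <- 0L
  for (it in seq_len(config$iterations)) {
    omega <- rpg_devroye(eta)
    for (j in seq_along(blocks)) {
      X <- blocks[[j]]$matrix
      etam <- eta - as.numeric(X %*% theta[[j]])
      prior_prec <- if (bn[j] == "fixed") fixed_prec else
        blocks[[j]]$penalty / tau2[[bn[j]]]
      bvec <- crossprod(X, kappa - omega * etam)
      theta[[j]] <- .draw_block(X, omega, bvec, prior_prec)
      eta <- etam + as.numeric(X %*% theta[[j]])
    }
    for (v in penalized) {
      b <- blocks[[v]]
      tau2[[v]] <- update_variance(theta[[v]], b$penalty,
                                   a = b$info$a, b = b$info$b,
                                   rank = b$penalty_rank)
    }
    if (it > config$burnin && (it - config$burnin) %% config$thin == 0) {
      k <- k + 1L
      out_fixed[k, ] <- theta$fixed
      for (s in smooth_names) out_smooth[[s]][k, ] <- theta[[s]]
      if (!is.null(out_str))
        out_str[k, ] <- as.numeric(blocks$Structured$info$Z %*%
                                     theta$Structured)
      if (!is.null(out_unstr)) out_unstr[k, ] <- theta$Unstructured
      out_tau2[k, ] <- tau2
      out_dev[k] <- bernoulli_deviance(y, eta)
    }
    if (verbose && it %% 1000 == 0)
      message("sweep ", it, "/", config$iterations)
  }

  structure(
    list(samples = list(fixed = out_fixed, smooth = out_smooth,
                        str = out_str, unstr = out_unstr),
         variance_samples = out_tau2, deviance_trace = out_dev,
         blocks = blocks, spec = spec, config = config, y = y, n = n,
         data_digest = .data_digest(data)),
    class = "star_fit")
}

#' @export
print.star_fit <- function(x, ...) {
  cat("star_fit:", x$n, "observations,",
      nrow(x$samples$fixed), "stored draws\n")
  cat("blocks:", paste(names(x$blocks), collapse = ", "), "\n")
  cat("posterior mean deviance:", round(mean(x$deviance_trace), 2), "\n")
  invisible(x)
}

# Linear predictor at the posterior mean of every block (plug-in).
.eta_at_posterior_means <- function(fit) {
  eta <- as.numeric(fit$blocks$fixed$matrix %*% colMeans(fit$samples$fixed))
  for (s in names(fit$samples$smooth))
    eta <- eta + as.numeric(fit$blocks[[s]]$matrix %*%
                              colMeans(fit$samples$smooth[[s]]))
  ri <- NULL
  if (!is.null(fit$samples$str)) {
    f <- colMeans(fit$samples$str)
    eta <- eta + as.numeric(fit$blocks$Structured$matrix %*%
                              (t(fit$blocks$Structured$info$Z) %*% f))
  }
  if (!is.null(fit$samples$unstr))
    eta <- eta + as.numeric(fit$blocks$Unstructured$matrix %*%
                              colMeans(fit$samples$unstr))
  eta
}

#' Export stored draws and a run manifest
#'
#' Writes one CSV with a column per stored parameter (fixed effects,
#' smooth coefficients, per-region spatial effects, variance components,
#' deviance) and a JSON manifest recording the specification, chain
#' configuration and input digest.
#'
#' @param fit A [star_fit()] result.
#' @param dir Output directory (created if needed).
#' @return Paths of the written files, invisibly.
#' @export
export_draws <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  draws <- cbind(fit$samples$fixed)
  for (s in names(fit$samples$smooth)) {
    m <- fit$samples$smooth[[s]]
    colnames(m) <- paste0(s, ".", seq_len(ncol(m)))
    draws <- cbind(draws, m)
  }
  if (!is.null(fit$samples$str)) {
    m <- fit$samples$str; colnames(m) <- paste0("str:", colnames(m))
    draws <- cbind(draws, m)
  }
  if (!is.null(fit$samples$unstr)) {
    m <- fit$samples$unstr; colnames(m) <- paste0("unstr:", colnames(m))
    draws <- cbind(draws, m)
  }
  tv <- fit$variance_samples
  colnames(tv) <- paste0("var:", colnames(tv))
  draws <- cbind(draws, tv, deviance = fit$deviance_trace)
  csv <- file.path(dir, "draws.csv")
  write.csv(as.data.frame(draws), csv, row.names = FALSE)
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(outcome = fit$spec$outcome, fixed = fit$spec$fixed,
         smooth = names(fit$spec$smooth),
         spatial = !is.null(fit$spec$spatial),
         iterations = fit$config$iterations, burnin = fit$config$burnin,
         thin = fit$config$thin, seed = fit$config$seed,
         n = fit$n, data_digest = fit$data_digest),
    manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(csv, manifest))
}
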