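# Shared fixtures, generated in code.

# Small covariate mix used by most model tests (3 binary covariates).
tiny_mix <- function() {
  default_covariate_mix()[c("gender", "diarrhoea", "media")]
}

# Fixed-effects-only ground truth on any graph.
linear_truth <- function(intercept = -0.4) {
  true_params(beta = c("(Intercept)" = intercept, "gender:male" = 0.5,
                       "diarrhoea:yes" = -0.4, "media:yes" = 0.3))
}

# Simulated dataset + short-chain fit shared by reporting/DIC tests;
# memoised so the sampler runs once per test session.
shared_fit_cache <- new.env(parent = emptyenv())
shared_small_fit <- function() {
  if (!is.null(shared_fit_cache$fit)) return(shared_fit_cache$fit)
  g <- make_lattice_graph(3, 4)
  truth <- default_truth(g, var_str = 0.5, var_unstr = 0, seed = 5)
  truth$beta <- c("(Intercept)" = -0.4, "gender:male" = 0.5,
                  "diarrhoea:yes" = -0.4, "media:yes" = 0.3)
  set.seed(11)
  dat <- simulate_covariates(2000, g, mix = tiny_mix())
  dat <- simulate_outcomes(dat, truth)
  spec <- star_spec("outcome", fixed = c("gender", "diarrhoea", "media"),
                    smooth = list(child_age = smooth_term()),
                    spatial = spatial_term("region"))
  fit <- star_fit(spec, dat, g, chain_config(1500, 500, 2, seed = 3))
  shared_fit_cache$fit <- fit
  shared_fit_cache$truth <- truth
  shared_fit_cache$data <- dat
  shared_fit_cache$graph <- g
  fit
}

# Minimal hand-made fit object for reporting-level tests.
fake_fit <- function(fixed_draws = NULL, str = NULL, unstr = NULL,
                     variance = NULL, smooth = list(), blocks = list()) {
  structure(
    list(samples = list(fixed = fixed_draws, smooth = smooth,
                        str = str, unstr = unstr),
         variance_samples = variance, deviance_trace = numeric(),
         blocks = blocks),
    class = "star_fit")
}
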