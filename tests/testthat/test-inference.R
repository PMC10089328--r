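test_that("linear predictor is additive over blocks", {
  X <- cbind(1, c(0, 1, 0))
  colnames(X) <- c("(Intercept)", "x")
  blocks <- list(fixed = design_block(X, label = "fixed"))
  eta <- linear_predictor(blocks, list(fixed = c(0.5, 1.0)))
  expect_equal(eta, c(0.5, 1.5, 0.5))
  expect_equal(linear_predictor(blocks, list(fixed = c(0, 0))), rep(0, 3))

  b2 <- design_block(matrix(c(1, 0, 2), 3, 1), label = "z")
  both <- linear_predictor(list(fixed = blocks$fixed, z = b2),
                           list(fixed = c(0.5, 1.0), z = 2))
  expect_equal(both, eta + c(2, 0, 4))
  expect_error(linear_predictor(blocks, list(fixed = 1)), "dimension")
  expect_error(linear_predictor(blocks, list()), "missing")
})

test_that("Bernoulli deviance matches the closed form and stays finite", {
  expect_equal(bernoulli_deviance(c(1, 0), c(0, 0)), -4 * log(0.5),
               tolerance = 1e-12)            # 2.772589
  expect_lt(bernoulli_deviance(1, 50), 1e-8) # saturated, near zero
  expect_true(is.finite(bernoulli_deviance(c(1, 0), c(-800, 800))))
  set.seed(12)
  for (i in 1:20)
    expect_gte(bernoulli_deviance(rbinom(10, 1, 0.5), rnorm(10, 0, 3)), 0)
})

test_that("GMRF full conditional has neighbour-average mean, var/N_s", {
  g <- make_lattice_graph(1, 3)
  eff <- setNames(c(1.0, 99, 3.0), g$ids)
  cond <- gmrf_conditional(g$ids[2], eff, g, variance = 2)
  expect_equal(unname(cond), c(2.0, 1.0))
  cond1 <- gmrf_conditional(g$ids[1], eff, g, variance = 2)
  expect_equal(unname(cond1), c(99, 2))  # single neighbour: mean v, var g2
})

test_that("conditionals are consistent with the joint GMRF density", {
  # Brook's lemma on a 3-region path: the telescoping conditional ratio
  # must equal the unnormalised joint density ratio exp(-(fKf - gKg)/2v)
  g <- make_lattice_graph(1, 3)
  K <- gmrf_precision(g)
  v <- 0.8
  set.seed(13)
  for (rep in 1:5) {
    f <- setNames(rnorm(3), g$ids)
    h <- setNames(rnorm(3), g$ids)
    logratio <- 0
    for (i in 1:3) {
      mixed <- c(f[seq_len(i - 1)], h[i:3])
      cm <- gmrf_conditional(g$ids[i], mixed[names(mixed) != g$ids[i]] ,
                             g, v)
      logratio <- logratio +
        dnorm(f[i], cm["mean"], sqrt(cm["variance"]), log = TRUE) -
        dnorm(h[i], cm["mean"], sqrt(cm["variance"]), log = TRUE)
    }
    target <- -(drop(f %*% K %*% f) - drop(h %*% K %*% h)) / (2 * v)
    expect_equal(unname(logratio), target, tolerance = 1e-8)
  }
})

test_that("variance update follows the conjugate inverse-gamma law", {
  # rank-1 identity case: beta = 2 gives IG(0.501, 2.001); its mean is
  # scale / (shape - 1) only when shape > 1, so use a larger rank here
  K <- diag(4)
  beta <- c(1, -1, 0.5, 2)
  a <- 2; b <- 0.5
  shape <- a + 4 / 2                    # rank 4
  scale <- b + sum(beta^2) / 2
  set.seed(14)
  draws <- replicate(20000, update_variance(beta, K, a = a, b = b, rank = 4))
  m <- scale / (shape - 1)
  expect_equal(mean(draws), m, tolerance = 0.05)
  # seeded draws reproduce
  expect_equal(update_variance(beta, K, a, b, rank = 4, seed = 5),
               update_variance(beta, K, a, b, rank = 5 - 1, seed = 5))
  # beta = 0 collapses the scale to b: draws are IG(a + rank/2, b)
  set.seed(15)
  d0 <- replicate(20000, update_variance(rep(0, 4), K, a = a, b = b))
  expect_equal(mean(d0), b / (a + 2 - 1), tolerance = 0.05)
})

test_that("chain storage arithmetic is exact and seeds reproduce chains", {
  g <- make_lattice_graph(2, 2)
  rec <- simulate_covariates(300, g, mix = tiny_mix(), seed = 16)
  dat <- simulate_outcomes(rec, linear_truth(), seed = 16)
  spec <- star_spec("outcome", fixed = c("gender", "diarrhoea"))
  cfg <- chain_config(iterations = 230, burnin = 55, thin = 7, seed = 4)
  fit <- star_fit(spec, dat, config = cfg)
  expect_equal(nrow(fit$samples$fixed), (230 - 55) %/% 7)
  fit2 <- star_fit(spec, dat, config = cfg)
  expect_identical(fit$samples$fixed, fit2$samples$fixed)
  expect_identical(fit$deviance_trace, fit2$deviance_trace)
  expect_error(chain_config(100, 100), "burnin")
  expect_error(star_fit(spec, dat, config = chain_config(10, 5, 20)),
               "no draws")
})

test_that("fixed effects are recovered on synthetic data", {
  g <- make_lattice_graph(2, 2)
  set.seed(17)
  rec <- simulate_covariates(1500, g, mix = tiny_mix())
  dat <- simulate_outcomes(rec, linear_truth())
  spec <- star_spec("outcome", fixed = c("gender", "diarrhoea", "media"))
  fit <- star_fit(spec, dat, config = chain_config(1200, 300, 2, seed = 6))
  truth <- c("(Intercept)" = -0.4, "gender:male" = 0.5,
             "diarrhoea:yes" = -0.4, "media:yes" = 0.3)
  pm <- colMeans(fit$samples$fixed)
  ps <- apply(fit$samples$fixed, 2, sd)
  expect_true(all(abs(pm - truth[names(pm)]) < 3 * ps))
})

test_that("outcome and schema violations are rejected", {
  g <- make_lattice_graph(2, 2)
  rec <- simulate_covariates(100, g, mix = tiny_mix(), seed = 18)
  rec$outcome <- rec$child_age  # not binary
  spec <- star_spec("outcome", fixed = "gender")
  expect_error(star_fit(spec, rec), "binary")
  rec$outcome <- rbinom(100, 1, 0.5)
  sp2 <- star_spec("outcome", fixed = "gender",
                   spatial = spatial_term("region"))
  expect_error(star_fit(sp2, rec), "graph")
  g2 <- make_lattice_graph(1, 2)  # graph missing observed regions
  expect_error(star_fit(sp2, rec, g2), "missing from graph")
})
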