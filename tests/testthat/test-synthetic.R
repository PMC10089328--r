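test_that("structured field draws are zero-sum and variance-scaled", {
  g <- make_lattice_graph(2, 2)
  f <- sample_structured_field(g, 0.3, seed = 1)
  expect_lt(abs(sum(f)), 1e-10)
  expect_equal(names(f), g$ids)
  expect_equal(unname(sample_structured_field(g, 0, seed = 1)), rep(0, 4))
  # reproducible under the seed
  expect_equal(sample_structured_field(g, 0.3, seed = 9),
               sample_structured_field(g, 0.3, seed = 9))
})

test_that("structured field covariance matches variance * pinv(K)", {
  g <- make_lattice_graph(2, 3)
  K <- gmrf_precision(g)
  eig <- eigen(K, symmetric = TRUE)
  idx <- seq_len(n_regions(g) - 1)
  Kplus <- eig$vectors[, idx] %*% diag(1 / eig$values[idx]) %*%
    t(eig$vectors[, idx])
  v <- 0.7
  draws <- sample_structured_field(g, v, seed = 2, n = 6000)
  C <- crossprod(draws) / nrow(draws)     # mean is 0 by construction
  target <- v * Kplus
  se <- sqrt((diag(target) %o% diag(target) + target^2) / nrow(draws))
  expect_true(all(abs(C - target) < 5 * se + 1e-9))
})

test_that("each region's conditional given the rest matches the GMRF law", {
  # empirical check on a path graph: regress middle on neighbour average
  g <- make_lattice_graph(1, 3)
  v <- 0.5
  draws <- sample_structured_field(g, v, seed = 3, n = 20000)
  mid <- draws[, 2]
  nbavg <- (draws[, 1] + draws[, 3]) / 2
  res <- mid - nbavg
  # conditional mean = neighbour average (slope 1, no intercept offset)
  expect_lt(abs(mean(res)), 0.02)
  expect_equal(var(res), v / 2, tolerance = 0.05)  # var = variance / N_s
})

test_that("covariate simulation honours supports, mixes and determinism", {
  g <- make_lattice_graph(3, 4)
  d1 <- simulate_covariates(1000, g, seed = 5)
  d2 <- simulate_covariates(1000, g, seed = 5)
  expect_identical(d1, d2)
  expect_true(all(d1$child_age %in% 0:59))
  expect_true(all(d1$mother_age %in% 15:49))
  expect_true(all(as.character(d1$region) %in% g$ids))
  # empirical frequencies within 3 binomial SEs of their targets
  mix <- default_covariate_mix()
  n <- nrow(d1)
  for (v in c("gender", "wealth", "bmi")) {
    p <- mix[[v]]$p
    emp <- as.numeric(table(d1[[v]])[mix[[v]]$levels]) / n
    expect_true(all(abs(emp - p) <= 3 * sqrt(p * (1 - p) / n) + 1e-9))
  }
  badmix <- list(gender = list(levels = c("female", "male"), p = c(0.7, 0.7)))
  expect_error(simulate_covariates(10, g, mix = badmix), "probability")
})

test_that("outcome generator follows the logistic predictor", {
  g <- make_lattice_graph(2, 2)
  rec <- simulate_covariates(4000, g, mix = tiny_mix(), seed = 6)
  # all effects zero -> mean 0.5 within 3 binomial SEs
  null_truth <- true_params(beta = c("(Intercept)" = 0))
  out <- simulate_outcomes(rec, null_truth, seed = 6)
  expect_lt(abs(mean(out$outcome) - 0.5), 3 * sqrt(0.25 / 4000))
  # saturated intercept
  sat <- simulate_outcomes(rec, true_params(beta = c("(Intercept)" = 10)),
                           seed = 6)
  expect_gt(mean(sat$outcome), 0.999)
  # mean of plogis(eta) agrees with the empirical outcome mean
  tr <- linear_truth()
  out <- simulate_outcomes(rec, tr, seed = 7)
  pbar <- mean(plogis(attr(out, "eta")))
  mc <- sqrt(pbar * (1 - pbar) / nrow(out))
  expect_lt(abs(mean(out$outcome) - pbar), 4 * mc)
})

test_that("a single log(2) effect is recovered from the contingency table", {
  g <- make_lattice_graph(1, 2)
  mix <- list(x = list(levels = c("lo", "hi"), p = c(0.5, 0.5)))
  rec <- simulate_covariates(50000, g, mix = mix, seed = 8)
  tr <- true_params(beta = c("(Intercept)" = -0.2, "x:hi" = log(2)))
  out <- simulate_outcomes(rec, tr, seed = 8)
  tab <- table(out$x, out$outcome)
  logodds <- log(tab["hi", "1"] / tab["hi", "0"]) -
    log(tab["lo", "1"] / tab["lo", "0"])
  # Monte-Carlo SE of a log odds ratio: sqrt(sum(1/cell counts))
  se <- sqrt(sum(1 / tab))
  expect_lt(abs(logodds - log(2)), 4 * se)
})

test_that("z-score generator hits the target prevalence and is seeded", {
  z <- simulate_zscores(20000, target_prevalence = 0.413, seed = 9)
  cl <- suppressWarnings(ciaf_classify(z))
  expect_lt(abs(mean(cl$ciaf) - 0.413), 0.02)
  expect_identical(simulate_zscores(500, 0.3, seed = 10),
                   simulate_zscores(500, 0.3, seed = 10))
  # independence: joint failure probability is the product of marginals
  zi <- simulate_zscores(200000, target_prevalence = 0.3,
                         correlation = diag(3), seed = 11)
  fl <- flag_failures(zi$haz, zi$whz, zi$waz)
  pj <- mean(fl$stunted & fl$wasted & fl$underweight)
  pprod <- mean(fl$stunted) * mean(fl$wasted) * mean(fl$underweight)
  expect_lt(abs(pj - pprod), 6 * sqrt(pprod / 200000) + 1e-4)
  expect_error(simulate_zscores(100, 0.5, correlation = matrix(1, 3, 3)),
               "positive definite")
})
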