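test_that("z-score validation applies the plausibility windows", {
  expect_false(validate_zscores(7.0, 0, 0))
  expect_false(validate_zscores(-6.5, 0, 0))
  expect_true(validate_zscores(0, 0, 0))
  # boundaries are inclusive; each index has its own window
  expect_equal(validate_zscores(c(6, -6, 0, 0, 0, 0),
                                c(0, 0, 5.2, -5, 0, 0),
                                c(0, 0, 0, 0, 5.5, -6)),
               c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_error(validate_zscores(NaN, 0, 0), "non-finite")
  expect_error(validate_zscores(Inf, 0, 0), "non-finite")
})

test_that("failure flags use a strict cut-off at -2", {
  f <- flag_failures(-2.5, -0.4, -1.0)
  expect_equal(unlist(f), c(stunted = TRUE, wasted = FALSE,
                            underweight = FALSE))
  expect_equal(unlist(flag_failures(0, 0, 0)),
               c(stunted = FALSE, wasted = FALSE, underweight = FALSE))
  # exactly at the cut-off is not failure
  expect_equal(unlist(flag_failures(-2, -2, -2)),
               c(stunted = FALSE, wasted = FALSE, underweight = FALSE))
  expect_true(all(unlist(flag_failures(-2.0001, -2.0001, -2.0001))))
})

test_that("group classification matches the seven-group table plus H", {
  expect_equal(as.character(classify_group(TRUE, FALSE, TRUE)), "C")
  expect_equal(as.character(classify_group(FALSE, FALSE, FALSE)), "A")
  expect_warning(g <- classify_group(TRUE, TRUE, FALSE), "H")
  expect_equal(as.character(g), "H")
  # full truth table
  tab <- expand.grid(s = c(FALSE, TRUE), w = c(FALSE, TRUE),
                     u = c(FALSE, TRUE))
  g <- suppressWarnings(classify_group(tab$s, tab$w, tab$u))
  expect_setequal(as.character(g), LETTERS[1:8])
})

test_that("indicator equals the any-failure oracle on all 8 combinations", {
  tab <- expand.grid(s = c(FALSE, TRUE), w = c(FALSE, TRUE),
                     u = c(FALSE, TRUE))
  g <- suppressWarnings(classify_group(tab$s, tab$w, tab$u))
  ind <- ciaf_indicator(g)
  oracle <- as.integer(tab$s | tab$w | tab$u)
  expect_equal(ind, oracle)
  expect_equal(sum(ind == 0), 1L)  # exactly one failure-free combination
  expect_error(ciaf_indicator("X"), "unknown")
})

test_that("ciaf is monotone: decreasing any z-score never removes failure", {
  set.seed(404)
  for (i in 1:200) {
    z <- runif(3, -4, 4)
    f0 <- flag_failures(z[1], z[2], z[3])
    c0 <- ciaf_indicator(suppressWarnings(
      classify_group(f0$stunted, f0$wasted, f0$underweight)))
    j <- sample(3, 1)
    z[j] <- z[j] - runif(1, 0, 3)
    f1 <- flag_failures(z[1], z[2], z[3])
    c1 <- ciaf_indicator(suppressWarnings(
      classify_group(f1$stunted, f1$wasted, f1$underweight)))
    expect_gte(c1, c0)
  }
})

test_that("Wald interval reproduces known values and clips at the bounds", {
  # half-width 1.96 * sqrt(0.25/100) = 0.098 at p = 0.5, n = 100
  ci <- wald_ci(0.5, 100)
  expect_equal(unname(ci[2] - ci[1]) / 2, qnorm(0.975) * sqrt(0.25 / 100),
               tolerance = 1e-12)
  expect_equal(unname(wald_ci(0, 100)), c(0, 0))
  expect_equal(unname(wald_ci(1, 100)), c(1, 1))
  # width is monotone decreasing in n at fixed p
  widths <- vapply(c(50, 200, 1000, 5000),
                   function(n) diff(wald_ci(0.3, n)), 0)
  expect_true(all(diff(widths) < 0))
})

test_that("prevalence_ci summarises a binary vector", {
  x <- c(rep(1, 40), rep(0, 60))
  est <- prevalence_ci(x)
  expect_equal(est$proportion, 0.4)
  expect_equal(est$n, 100)
  expect_true(est$ci_low <= est$proportion && est$proportion <= est$ci_high)
  expect_error(prevalence_ci(integer()), "empty")
  expect_error(prevalence_ci(c(0, 2)), "binary")
})

test_that("classification pipeline and prevalence table are coherent", {
  set.seed(7)
  z <- simulate_zscores(5000, target_prevalence = 0.4, seed = 7)
  cl <- suppressWarnings(ciaf_classify(z))
  expect_true(all(cl$ciaf %in% 0:1))
  expect_equal(cl$ciaf == 0, cl$group == "A")
  tab <- suppressWarnings(ciaf_prevalence_table(cl))
  expect_equal(tab$status[1], "CIAF")
  # exclusive group proportions (all rows but the CIAF one) sum to 1
  expect_equal(sum(tab$prevalence[-1]), 1, tolerance = 1e-12)
  expect_true(all(tab$ci_low <= tab$prevalence &
                  tab$prevalence <= tab$ci_high))
  # CIAF = 1 - No failure
  expect_equal(tab$prevalence[1] + tab$prevalence[2], 1, tolerance = 1e-12)
})

test_that("implausible records are dropped with a message", {
  z <- data.frame(haz = c(0, 7, -1), whz = c(0, 0, 0), waz = c(0, 0, 0))
  expect_message(out <- ciaf_classify(z), "dropped 1")
  expect_equal(nrow(out), 2)
  expect_error(ciaf_classify(z, drop_invalid = FALSE), "implausible")
})
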