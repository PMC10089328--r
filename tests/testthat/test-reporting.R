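test_that("odds-ratio table handles constant and symmetric chains", {
  draws <- cbind("(Intercept)" = rep(0.1, 50), "x:yes" = rep(log(2), 50))
  fit <- fake_fit(fixed_draws = draws)
  tab <- odds_ratio_table(fit)
  expect_equal(nrow(tab), 1)  # intercept excluded by default
  expect_equal(tab$or_mean, 2)
  expect_equal(c(tab$cri_low, tab$cri_high), c(2, 2))
  expect_true(tab$significant)

  sym <- cbind("x:yes" = c(seq(-1, 1, length.out = 101)))
  tab2 <- odds_ratio_table(fake_fit(fixed_draws = sym))
  expect_false(tab2$significant)
  expect_true(tab2$cri_low < 1 && tab2$cri_high > 1)
})

test_that("odds-ratio quantiles match a sorting-based oracle", {
  set.seed(21)
  d <- rnorm(1000, 0.3, 0.4)
  fit <- fake_fit(fixed_draws = cbind("x:yes" = d))
  tab <- odds_ratio_table(fit)
  or <- sort(exp(d))
  # type-7 quantile oracle, computed by hand from the sorted draws
  q_oracle <- function(p) {
    h <- (length(or) - 1) * p + 1
    lo <- floor(h)
    or[lo] + (h - lo) * (or[min(lo + 1, length(or))] - or[lo])
  }
  expect_equal(tab$cri_low, q_oracle(0.025), tolerance = 1e-10)
  expect_equal(tab$cri_high, q_oracle(0.975), tolerance = 1e-10)
  expect_equal(tab$or_mean, mean(exp(d)), tolerance = 1e-12)
  # Jensen: mean of exponentiated draws exceeds exp of mean draw
  expect_gt(tab$or_mean, exp(mean(d)))
})

test_that("smooth curves reduce correctly for degenerate chains", {
  x <- runif(60, 0, 10)
  b <- bspline_basis(x, segments = 6, degree = 3, range = c(0, 10),
                     label = "s(x)")
  b$penalty <- difference_penalty(2, ncol(b$matrix))
  b$penalty_rank <- ncol(b$matrix) - 2
  bc <- apply_sum_to_zero(b)
  r <- ncol(bc$matrix)

  zero <- fake_fit(smooth = list("s(x)" = matrix(0, 20, r)),
                   blocks = list("s(x)" = bc))
  cv <- smooth_effect_curve(zero, "x", grid = seq(0, 10, 1))
  expect_equal(cv$mean, rep(0, 11))
  expect_equal(cv$cri_high - cv$cri_low, rep(0, 11))

  set.seed(22)
  al <- rnorm(r)
  one <- fake_fit(smooth = list("s(x)" = matrix(al, 1, r)),
                  blocks = list("s(x)" = bc))
  cv1 <- smooth_effect_curve(one, "s(x)", grid = seq(0, 10, 2.5))
  # single draw: band collapses onto the curve, which equals the manual
  # basis %*% coefficient product
  manual <- as.numeric(
    geociaf:::.eval_bspline(bc$info$knots, seq(0, 10, 2.5), bc$info$degree,
                            10) %*% bc$info$Z %*% al)
  expect_equal(cv1$mean, manual, tolerance = 1e-10)
  expect_equal(cv1$cri_low, manual, tolerance = 1e-10)
  expect_equal(cv1$cri_high, manual, tolerance = 1e-10)
  expect_error(smooth_effect_curve(one, "s(x)", grid = c(-1, 5)), "outside")
  expect_error(smooth_effect_curve(one, "nope"), "no smooth term")
})

test_that("spatial significance codes match a quantile-sign oracle", {
  set.seed(23)
  regs <- paste0("R", 1:6)
  s <- matrix(rnorm(300 * 6, rep(c(2, -2, 0, 0.2, -0.1, 0), each = 300),
                    0.5), 300, 6, dimnames = list(NULL, regs))
  u <- matrix(0, 300, 6, dimnames = list(NULL, regs))
  fit <- fake_fit(str = s, unstr = u)
  out <- spatial_significance(fit)
  expect_equal(nrow(out), 6)  # every region classified
  for (i in seq_len(6)) {
    q <- quantile(s[, i], c(0.025, 0.975))
    expect_equal(out$code[i],
                 if (q[1] > 0) 1L else if (q[2] < 0) -1L else 0L)
  }
  expect_equal(out$code[1:2], c(1L, -1L))
  expect_equal(sum(out$code %in% c(-1L, 0L, 1L)), 6)
  # structured-only view uses the structured draws alone
  out_s <- spatial_significance(fit, "structured")
  expect_equal(out_s$code, out$code)  # unstructured draws are all zero
})

test_that("variance summaries match the sorting oracle", {
  set.seed(24)
  v <- cbind("s(x)" = rgamma(400, 2, 10), Structured = rep(0.3, 400))
  fit <- fake_fit(variance = v)
  out <- variance_summary(fit)
  expect_equal(out$component, c("s(x)", "Structured"))
  expect_equal(out$sd[2], 0)  # constant chain
  expect_equal(out$mean[1], mean(v[, 1]), tolerance = 1e-12)
  expect_equal(out$cri_low[1],
               unname(quantile(v[, 1], 0.025)), tolerance = 1e-10)
  expect_equal(out$cri_high[1],
               unname(quantile(v[, 1], 0.975)), tolerance = 1e-10)
})

test_that("report surfaces work end to end on a real fit", {
  fit <- shared_small_fit()
  tab <- odds_ratio_table(fit)
  expect_setequal(tab$term, c("gender:male", "diarrhoea:yes", "media:yes"))
  expect_true(all(tab$cri_low <= tab$or_mean | tab$cri_low <= tab$cri_high))
  vs <- variance_summary(fit)
  expect_setequal(vs$component,
                  c("s(child_age)", "Structured", "Unstructured"))
  expect_true(all(vs$mean > 0))
  ss <- spatial_significance(fit)
  expect_equal(nrow(ss), 12)
  expect_true(all(ss$code %in% c(-1L, 0L, 1L)))
  path <- tempfile(fileext = ".json")
  write_spatial_codes(ss, path)
  codes <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(unname(unlist(codes)), ss$code)
  unlink(path)
})
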