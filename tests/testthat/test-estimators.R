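test_that("gaussian fits return the sample mean and unbiased sd", {
  f <- fit_gaussian(work_set("b", "forward", c(1, 3)))
  expect_equal(f$mean, 2)
  expect_equal(f$sd, sqrt(2))
  expect_false(f$degenerate)

  g <- fit_gaussian(work_set("b", "forward", rep(5, 4)))
  expect_equal(g$mean, 5)
  expect_true(g$degenerate)

  expect_error(fit_gaussian(work_set("b", "forward", 1)), "at least 2")
})

test_that("gaussian fit recovers known moments at large n", {
  x <- withr::with_seed(7, rnorm(1e5, 30, 4))
  f <- fit_gaussian(work_set("b", "forward", x))
  expect_lt(abs(f$mean - 30), 0.05)
  expect_lt(abs(f$sd - 4), 0.05)
})

test_that("CGI equals the midpoint for equal variances", {
  wf <- work_set("b", "forward", exact_moment_sample(60, 10, 2, seed = 1))
  wb <- work_set("b", "backward", -exact_moment_sample(60, 6, 2, seed = 2))
  est <- cgi_estimate(wf, wb)
  expect_equal(est$dG, 8, tolerance = 1e-10)
  expect_false(est$diagnostics$cgi_warning)
})

test_that("CGI on identical forward and negated-backward samples gives the mean", {
  x <- withr::with_seed(3, rnorm(40, 25, 3))
  est <- cgi_estimate(work_set("b", "forward", x),
                      work_set("b", "backward", -x))
  expect_equal(est$dG, mean(x), tolerance = 1e-9)
})

test_that("CGI unequal-variance root matches the dense intersection oracle", {
  wf <- work_set("b", "forward", exact_moment_sample(80, 12, 2, seed = 4))
  wb <- work_set("b", "backward", -exact_moment_sample(80, 6, 3, seed = 5))
  est <- cgi_estimate(wf, wb)
  oracle <- dense_gaussian_intersection(12, 2, 6, 3)
  expect_equal(est$dG, oracle, tolerance = 1e-5)
})

test_that("CGI rejects degenerate work distributions", {
  expect_error(cgi_estimate(work_set("b", "forward", rep(5, 3)),
                            work_set("b", "backward", c(-4, -6))),
               "degenerate")
})

test_that("BAR solves symmetric configurations exactly", {
  est <- bar_estimate(work_set("b", "forward", c(9, 7)),
                      work_set("b", "backward", c(-7, -9)))
  expect_equal(est$dG, 8, tolerance = 1e-7)

  est2 <- bar_estimate(work_set("b", "forward", c(10, 10)),
                       work_set("b", "backward", c(-10, -10)))
  expect_equal(est2$dG, 10, tolerance = 1e-7)
})

test_that("BAR root matches the grid-scan oracle on a printed fixture", {
  wf <- c(27.1, 32.6, 29.9, 31.4, 30.2)
  wb <- c(-26.8, -29.3, -28.1, -30.9, -27.5)
  forward <- work_set("fix", "forward", wf)
  backward <- work_set("fix", "backward", wb)
  est <- bar_estimate(forward, backward)
  oracle <- grid_scan_root(function(x) bar_objective(x, forward, backward),
                           lo = 20, hi = 40)
  expect_equal(est$dG, oracle, tolerance = 1e-6)
})

test_that("the BAR objective is strictly monotone in dG", {
  withr::with_seed(11, {
    for (k in 1:5) {
      f <- work_set("b", "forward", rnorm(40, 30, 5))
      b <- work_set("b", "backward", -rnorm(40, 26, 5))
      g <- bar_objective(seq(10, 50, length.out = 200), f, b)
      expect_true(all(diff(g) > 0))
    }
  })
})

test_that("shifting works by +c/-c shifts both estimators by exactly +c", {
  p <- sample_cft_works(cft_model(30, 4, n_per_direction = 120, seed = 8))
  cc <- 5.25
  shift_f <- work_set("b", "forward", p$forward$works + cc)
  shift_b <- work_set("b", "backward", p$backward$works - cc)
  expect_equal(cgi_estimate(shift_f, shift_b)$dG,
               cgi_estimate(p$forward, p$backward)$dG + cc, tolerance = 1e-9)
  expect_equal(bar_estimate(shift_f, shift_b)$dG,
               bar_estimate(p$forward, p$backward)$dG + cc, tolerance = 1e-6)
})

test_that("bootstrap SE is deterministic given a seed and zero for degenerate data", {
  p <- sample_cft_works(cft_model(30, 4, n_per_direction = 80, seed = 21))
  s1 <- bootstrap_se(p$forward, p$backward, "bar", n_boot = 100, seed = 5)
  s2 <- bootstrap_se(p$forward, p$backward, "bar", n_boot = 100, seed = 5)
  expect_identical(s1, s2)
  expect_gt(s1, 0)

  degen <- bootstrap_se(work_set("b", "forward", rep(12, 10)),
                        work_set("b", "backward", rep(-12, 10)),
                        "bar", n_boot = 100, seed = 1)
  expect_identical(degen, 0)
})

test_that("bootstrap SE tracks the repeated-sampling spread of BAR", {
  # oracle: sd of BAR estimates over independently regenerated datasets
  n_rep <- 200
  ests <- vapply(seq_len(n_rep), function(i) {
    p <- sample_cft_works(cft_model(30, 4, n_per_direction = 500,
                                    seed = 1000 + i))
    bar_estimate(p$forward, p$backward)$dG
  }, numeric(1))
  truth_sd <- sd(ests)
  p <- sample_cft_works(cft_model(30, 4, n_per_direction = 500, seed = 77))
  se <- bootstrap_se(p$forward, p$backward, "bar", n_boot = 1000, seed = 78)
  expect_lt(abs(se - truth_sd), 0.3 * truth_sd)
})

test_that("Bhattacharyya coefficient matches closed form and quadrature", {
  expect_equal(bhattacharyya_coef(3, 1.5, 3, 1.5), 1)
  expect_lt(bhattacharyya_coef(0, 1, 100, 1), 1e-10)
  bc <- bhattacharyya_coef(0, 1, 2, 1)
  expect_equal(bc, exp(-0.5), tolerance = 1e-12)
  quad <- stats::integrate(function(x) sqrt(dnorm(x, 0, 1) * dnorm(x, 2, 1)),
                           -20, 20)$value
  expect_equal(bc, quad, tolerance = 1e-8)
})

test_that("overlap diagnostics summarise fitted distributions", {
  p <- sample_cft_works(cft_model(30, 4, n_per_direction = 300, seed = 9))
  rep <- overlap_diagnostics(p$forward, p$backward)
  expect_true(rep$bhattacharyya > 0 && rep$bhattacharyya <= 1)
  expect_true(rep$ks_p_forward >= 0 && rep$ks_p_forward <= 1)
  expect_true(rep$ks_p_backward >= 0 && rep$ks_p_backward <= 1)
  # mean gap estimates twice the dissipation beta*sigma^2/2
  beta <- beta_from_temperature(300)
  expect_equal(rep$mean_gap, beta * 16, tolerance = 1)
  expect_error(overlap_diagnostics(work_set("b", "forward", rep(1, 5)),
                                   work_set("b", "backward", c(-1, -2))),
               "degenerate")
})

test_that("CGI and BAR agree on equal-variance Gaussian data", {
  for (seed in 1:4) {
    p <- sample_cft_works(cft_model(30, 4, n_per_direction = 500,
                                    seed = 200 + seed))
    cgi <- cgi_estimate(p$forward, p$backward)$dG
    bar <- bar_estimate(p$forward, p$backward)$dG
    se_c <- bootstrap_se(p$forward, p$backward, "cgi", 200, seed = 300 + seed)
    se_b <- bootstrap_se(p$forward, p$backward, "bar", 200, seed = 400 + seed)
    expect_lt(abs(cgi - bar), 2 * sqrt(se_c^2 + se_b^2))
  }
})

test_that("estimators demand matching directions and temperatures", {
  f <- work_set("b", "forward", c(1, 2))
  b <- work_set("b", "backward", c(-1, -2), temperature = 310)
  expect_error(cgi_estimate(f, b), "temperature")
  expect_error(bar_estimate(f, f), "forward and one backward")
})
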