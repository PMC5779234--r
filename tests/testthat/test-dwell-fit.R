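test_that("censored density matches direct formula evaluation and normalizes", {
  m <- exp_mixture_model(0.5, 20, 165, censor_window(5, 1800))
  # frozen value computed by independent evaluation of the printed formula
  expect_equal(censored_pdf(5, m), 0.025626893496244158, tolerance = 1e-12)
  expect_error(censored_pdf(3, m), "outside")
  expect_error(censored_pdf(2000, m), "outside")

  # integrates to 1 for random valid parameters
  set.seed(71)
  for (i in 1:25) {
    tau1 <- stats::runif(1, 1, 100)
    mi <- exp_mixture_model(
      A1 = stats::runif(1), tau1 = tau1, tau2 = tau1 * stats::runif(1, 1, 20),
      window = censor_window(stats::runif(1, 0.5, 10), stats::runif(1, 500, 3000))
    )
    int <- stats::integrate(censored_pdf, mi$window$t_m, mi$window$t_max,
                            model = mi, rel.tol = 1e-10)$value
    expect_lt(abs(int - 1), 1e-6)
  }

  # the two-term density degenerates exactly to the one-term density at the
  # amplitude boundaries
  tt <- seq(5, 1800, length.out = 50)
  m_a1 <- exp_mixture_model(1, 20, 165, censor_window(5, 1800))
  m_1c <- exp_mixture_model(1, 20, window = censor_window(5, 1800))
  expect_equal(censored_pdf(tt, m_a1), censored_pdf(tt, m_1c), tolerance = 1e-12)
  m_a0 <- exp_mixture_model(0, 20, 165, censor_window(5, 1800))
  m_2c <- exp_mixture_model(1, 165, window = censor_window(5, 1800))
  expect_equal(censored_pdf(tt, m_a0), censored_pdf(tt, m_2c), tolerance = 1e-12)
})

test_that("maximum-likelihood fitting recovers known dwell models", {
  # untruncated single exponential: MLE is the sample mean exactly
  set.seed(81)
  t1 <- stats::rexp(500, 1 / 30)
  f1 <- fit_mle(t1, 1, censor_window(0, Inf))
  expect_equal(f1$model$tau1, mean(t1), tolerance = 1e-6)

  # biexponential recovery at the E-complex operating point
  m <- exp_mixture_model(0.5, 20, 165, censor_window(5, 1800))
  d <- sample_mixture_dwells(m, 3000, seed = 82)
  f2 <- fit_mle(d, 2, censor_window(5, 1800), seed = 83)
  expect_equal(f2$model$tau1, 20, tolerance = 0.15)
  expect_equal(f2$model$tau2, 165, tolerance = 0.15)
  expect_false(f2$boundary)

  # optimality: likelihood at the generator truth never beats the optimum
  for (s in 1:5) {
    ds <- sample_mixture_dwells(m, 500, seed = 100 + s)$duration_s
    fs <- fit_mle(ds, 2, censor_window(5, 1800), seed = s)
    ll_truth <- sum(censored_pdf(ds, m, log = TRUE))
    expect_lte(ll_truth, fs$loglik + 1e-6)
  }

  expect_error(fit_mle(c(1, 2, 3), 1, censor_window(0.5, 10)), "at least 10")
  expect_error(fit_mle(stats::runif(50, 10, 20), 1, censor_window(5, 15)),
               "inside")
  expect_warning(f_const <- fit_mle(rep(25, 50), 1, censor_window(5, 1800)),
                 "degenerate")
  expect_equal(f_const$model$tau1, 25)
})

test_that("bootstrap uncertainties behave like sampling error", {
  w <- censor_window(5, 1800)
  # constant data: zero spread
  suppressWarnings(fb0 <- bootstrap_fit(rep(25, 50), 1, w, n_boot = 50, seed = 1))
  expect_identical(unname(fb0$bootstrap_sd["tau1"]), 0)

  # doubling the sample size shrinks the bootstrap SD by about sqrt(2)
  m <- exp_mixture_model(1, 60, window = w)
  sds <- vapply(1:8, function(i) {
    dn <- sample_mixture_dwells(m, 600, seed = 200 + i)
    d2 <- sample_mixture_dwells(m, 1200, seed = 300 + i)
    c(bootstrap_fit(dn, 1, w, n_boot = 150, seed = i)$bootstrap_sd["tau1"],
      bootstrap_fit(d2, 1, w, n_boot = 150, seed = i)$bootstrap_sd["tau1"])
  }, numeric(2))
  ratio <- stats::median(sds[1, ] / sds[2, ])
  expect_equal(ratio, sqrt(2), tolerance = 0.2)

  # two-component bootstrap returns SDs for all three parameters
  d <- sample_mixture_dwells(exp_mixture_model(0.5, 20, 165, w), 1500, seed = 84)
  fb <- bootstrap_fit(d, 2, w, n_boot = 60, seed = 85)
  expect_named(fb$bootstrap_sd, c("A1", "tau1", "tau2"))
  expect_true(all(fb$bootstrap_sd > 0))
  expect_identical(fb$n_boot, 60L)
})

test_that("likelihood-ratio model selection separates one from two components", {
  w <- censor_window(5, 1800)
  # type-I control: single-exponential truth selects one component
  n_one <- sum(vapply(1:10, function(s) {
    d <- sample_mixture_dwells(exp_mixture_model(1, 60, window = w), 5000, seed = 400 + s)
    select_model(d, w, seed = s)$k_selected == 1L
  }, logical(1)))
  expect_gte(n_one, 9)

  # power: the well-separated E-complex mixture is always detected
  n_two <- sum(vapply(1:10, function(s) {
    d <- sample_mixture_dwells(exp_mixture_model(0.5, 20, 165, w), 5000, seed = 500 + s)
    select_model(d, w, seed = s)$k_selected == 2L
  }, logical(1)))
  expect_identical(n_two, 10L)
})

test_that("probability-density histograms implement the binomial error formula", {
  # all dwells in one bin: density 1/w, zero binomial error
  h1 <- density_histogram(rep(7, 40), bin_edges = c(5, 15))
  expect_equal(h1$density, 0.1)
  expect_equal(h1$error, 0)

  # direct formula check: N = 100, n = 25 in a 10 s bin
  t <- c(stats::runif(25, 0, 10), stats::runif(75, 10, 100))
  set.seed(91)
  h2 <- density_histogram(t, bin_edges = c(0, 10, 100))
  expect_equal(h2$count[1], 25)
  expect_equal(h2$density[1], 0.025)
  expect_equal(h2$error[1], sqrt(25 * 0.75) / 1000, tolerance = 1e-12)

  # total probability is 1 when the bins cover all data
  d <- sample_mixture_dwells(exp_mixture_model(0.5, 20, 165, censor_window(5, 1800)),
                             2000, seed = 92)
  h3 <- density_histogram(d, bin_edges = seq(5, 1800, length.out = 30))
  expect_equal(sum(h3$density * (h3$bin_right - h3$bin_left)), 1, tolerance = 1e-12)

  # the histogram overlays the generating censored density within 2 error bars
  m <- exp_mixture_model(0.5, 20, 165, censor_window(5, 1800))
  d4 <- sample_mixture_dwells(m, 10000, seed = 93)$duration_s
  edges <- stats::quantile(d4, seq(0, 1, length.out = 21), names = FALSE)
  edges[1] <- 5; edges[21] <- 1800
  h4 <- density_histogram(d4, edges)
  mid_dens <- vapply(seq_len(nrow(h4)), function(i) {
    stats::integrate(censored_pdf, h4$bin_left[i], h4$bin_right[i], model = m)$value /
      (h4$bin_right[i] - h4$bin_left[i])
  }, numeric(1))
  frac_ok <- mean(abs(h4$density - mid_dens) <= 2 * h4$error)
  expect_gte(frac_ok, 0.9)

  expect_error(density_histogram(c(1, 20), bin_edges = c(5, 30)), "cover")
})

test_that("mean lifetime reports mean with its standard error", {
  ml <- mean_lifetime(c(10, 20, 30))
  expect_equal(ml$mean, 20)
  expect_equal(ml$se, 10 / sqrt(3), tolerance = 1e-12)
  expect_error(mean_lifetime(42), "at least two")
})

test_that("photobleaching extrapolation recovers the zero-power dissociation rate", {
  # simulated truth: k_obs = k_off + c * P with k_off = 1/165, c = 2e-5
  k_off <- 1 / 165; cc <- 2e-5
  powers <- c(200, 350, 500)
  w <- censor_window(1, 5000)
  fits <- lapply(powers, function(P) {
    d <- sample_mixture_dwells(
      exp_mixture_model(1, 1 / (k_off + cc * P), window = w), 4000,
      seed = round(P)
    )
    list(power = P, fit = bootstrap_fit(d, 1, w, n_boot = 80, seed = round(P) + 1))
  })
  pb <- photobleach_extrapolate(fits)
  expect_equal(pb$k_off[pb$component == "tau1"], k_off, tolerance = 0.10)
  expect_false(pb$minimal_bleaching[pb$component == "tau1"])

  # no power dependence: slope ~ 0, flagged as minimal photobleaching
  tab0 <- data.frame(power = powers, component = "tau2", tau = 165, tau_sd = 5)
  pb0 <- photobleach_extrapolate(tab0)
  expect_equal(pb0$slope, 0, tolerance = 1e-12)
  expect_true(pb0$minimal_bleaching)

  # pure bleaching is linear in power: doubling power doubles k_obs
  tabb <- data.frame(power = c(powers, 2 * powers), component = "tau1",
                     tau = 1 / (cc * c(powers, 2 * powers)), tau_sd = NA_real_)
  pbb <- photobleach_extrapolate(tabb)
  expect_equal(pbb$slope, cc, tolerance = 1e-9)
  expect_equal(pbb$k_off, 0, tolerance = 1e-9)

  expect_error(photobleach_extrapolate(tab0[c(1, 1), ]), "distinct")
})
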