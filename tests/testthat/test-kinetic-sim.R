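test_that("kinetic scheme construction enforces its invariants", {
  expect_error(
    kinetic_scheme("bound", c("bound->bound" = 1), "bound"),
    "must include the dark state"
  )
  expect_error(
    kinetic_scheme(c("unbound", "b"), c("unbound->b" = -1, "b->unbound" = 1), "b"),
    "positive"
  )
  expect_error(
    kinetic_scheme(c("unbound", "b"), c("b->b" = 1), "b"),
    "self-transitions"
  )
  expect_error(
    kinetic_scheme(c("unbound", "b"), c("unbound->b" = 1), c("unbound", "b")),
    "exclude the dark state"
  )
  # a bound state that can never release the fluorophore is rejected
  expect_error(
    kinetic_scheme(
      c("unbound", "a", "b"),
      c("unbound->a" = 0.1, "a->b" = 0.1, "b->a" = 0.1),
      c("a", "b")
    ),
    "not reachable"
  )
  # zero rates are dropped rather than kept as zero-rate edges
  sc <- two_step_scheme(0.01, 0.05, k12 = 0, k_off2 = 0.01)
  expect_false(any(sc$rates$rate == 0))
})

test_that("closed-form dwell distribution matches the defining special cases", {
  # no interconversion between bound phases: single exponential 1/k_off
  m <- dwell_distribution_from_scheme(two_step_scheme(0.01, 0.05, k12 = 0, k_off2 = 0.01))
  expect_identical(m$A1, 1)
  expect_equal(m$tau1, 20)
  expect_null(m$tau2)

  m1 <- dwell_distribution_from_scheme(one_step_scheme(0.01, 0.05))
  expect_equal(m1$tau1, 20)

  # independent pathways: mixture (p, 1/k_a; 1-p, 1/k_b) exactly
  m2 <- dwell_distribution_from_scheme(
    independent_pathway_scheme(k_on_a = 0.01, k_off_a = 0.05,
                               k_on_b = 0.03, k_off_b = 0.005)
  )
  expect_equal(m2$A1, 0.25, tolerance = 1e-12)
  expect_equal(m2$tau1, 20, tolerance = 1e-12)
  expect_equal(m2$tau2, 200, tolerance = 1e-12)

  expect_error(
    dwell_distribution_from_scheme(kinetic_scheme(
      c("unbound", "a", "b", "c"),
      c("unbound->a" = 1, "a->unbound" = 1, "unbound->b" = 1,
        "b->unbound" = 1, "unbound->c" = 1, "c->unbound" = 1),
      c("a", "b", "c")
    )),
    "more than two bound states"
  )
})

test_that("eigen-derived dwell distribution agrees with brute-force Gillespie draws", {
  sc <- two_step_scheme(k_on = 0.01, k_off1 = 0.2, k12 = 0.05, k_off2 = 0.01)
  m <- dwell_distribution_from_scheme(sc)
  d <- sample_scheme_dwells(sc, 2e4, seed = 11)
  # chi-square goodness of fit against the analytic mixture on its own quantile bins
  probs <- seq(0.05, 0.95, by = 0.05)
  qs <- vapply(probs, function(p) {
    stats::uniroot(function(t) mixture_cdf(t, m$A1, m$tau1, m$tau2) - p,
                   c(1e-6, 1e5))$root
  }, numeric(1))
  edges <- c(0, qs, Inf)
  counts <- table(cut(d, edges))
  expect_gt(stats::chisq.test(counts, p = diff(c(0, probs, 1)))$p.value, 0.01)
  # and the mixture mean matches the sample mean
  mix_mean <- m$A1 * m$tau1 + (1 - m$A1) * m$tau2
  expect_equal(mean(d), mix_mean, tolerance = 3 * stats::sd(d) / sqrt(length(d)) / mix_mean)
})

test_that("Gillespie timelines have the right dwell statistics", {
  # one-state binder that never associates: empty interval set
  expect_identical(
    nrow(simulate_timeline(one_step_scheme(0, 0.05), frame_schedule(), seed = 1)),
    0L
  )
  # mean bound dwell = 1/k_off within 2%
  set.seed(21)
  dwells <- unlist(lapply(seq_len(3000), function(m) {
    iv <- simulate_timeline(one_step_scheme(0.01, 0.05), 1800)
    iv <- iv[iv$start_s > 0 & iv$end_s < 1800, , drop = FALSE]  # completed only
    iv$end_s - iv$start_s
  }))
  expect_gt(length(dwells), 2e4)
  expect_equal(mean(dwells), 20, tolerance = 0.02)
})

test_that("mixture dwell sampler matches its analytic truncated density", {
  # untruncated single exponential: sample mean ~ tau within 3 SE
  m <- exp_mixture_model(1, 20, window = censor_window(0, Inf))
  d <- sample_mixture_dwells(m, 1e5, seed = 5)$duration_s
  expect_lt(abs(mean(d) - 20), 3 * stats::sd(d) / sqrt(length(d)))

  # E-complex operating point: all samples inside the observable window
  me <- exp_mixture_model(0.5, 20, 165, censor_window(5, 1800))
  de <- sample_mixture_dwells(me, 2e4, seed = 6)$duration_s
  expect_true(all(de >= 5 & de <= 1800))
  expect_equal(mean(de), truncated_mixture_mean(0.5, 20, 165, 5, 1800),
               tolerance = 3 * stats::sd(de) / sqrt(length(de)) / mean(de))

  # degenerate mixture tau1 = tau2 is indistinguishable from one component
  md <- exp_mixture_model(0.5, 50, 50, censor_window(5, 1800))
  ms <- exp_mixture_model(1, 50, window = censor_window(5, 1800))
  dd <- sample_mixture_dwells(md, 5e3, seed = 7)$duration_s
  ds <- sample_mixture_dwells(ms, 5e3, seed = 8)$duration_s
  expect_gt(suppressWarnings(stats::ks.test(dd, ds)$p.value), 0.01)

  expect_error(exp_mixture_model(1.2, 20), "A1")
  expect_error(exp_mixture_model(0.5, -1, 10), "tau1")
  expect_error(censor_window(10, 10), "t_m < t_max")
})

test_that("frame sampling implements the acquisition geometry and detection floor", {
  fs <- frame_schedule()  # exposures [0,1), [5,6), [10,11), ...
  # an event between exposures is invisible
  tr <- frame_sample(data.frame(start_s = 7.2, end_s = 7.5), fs)
  expect_false(any(tr$present))
  # [4.5, 11.2) is seen in frames 1 and 2 only
  tr2 <- frame_sample(data.frame(start_s = 4.5, end_s = 11.2), fs)
  expect_identical(tr2$frame_index[tr2$present], c(1L, 2L))
  expect_error(frame_sample(data.frame(start_s = 1, end_s = 2), fs, bleach_rate = -1),
               "non-negative")
  # background adds spurious single-frame presences at the given rate
  tr3 <- frame_sample(data.frame(start_s = numeric(0), end_s = numeric(0)),
                      fs, background_rate = 0.2, seed = 9)
  expect_gt(sum(tr3$present), 0)
})

test_that("decoupled two-channel simulation has BBP-independent U1 dwells", {
  # quasi-static BBP occupancy so the with/without split does not
  # length-bias the classes (a rapidly cycling partner preferentially
  # tags long dwells even without coupling)
  cp <- coupling_spec(
    u1_scheme = one_step_scheme(1 / 100, 1 / 50),
    bbp_scheme = one_step_scheme(1e-6, 1e-6),
    stabilization_factor = 1
  )
  rec <- simulate_two_channel(cp, 800, frame_schedule(), seed = 31,
                              start_at_equilibrium = TRUE)
  cd <- conditional_dwells(rec)
  expect_gt(sum(cd$with_bbp), 100)
  expect_gt(sum(!cd$with_bbp), 100)
  expect_gt(
    suppressWarnings(
      stats::ks.test(cd$duration_s[cd$with_bbp], cd$duration_s[!cd$with_bbp])$p.value
    ),
    0.01
  )
})

test_that("stabilization lengthens U1 dwells only while BBP is bound", {
  cp <- coupling_spec(
    u1_scheme = one_step_scheme(1 / 100, 1 / 40),
    bbp_scheme = one_step_scheme(1 / 200, 1 / 300),
    stabilization_factor = 4
  )
  rec <- simulate_two_channel(cp, 600, frame_schedule(), seed = 32)
  cd <- conditional_dwells(rec)
  expect_gt(
    mean(cd$duration_s[cd$with_bbp]),
    mean(cd$duration_s[!cd$with_bbp])
  )
  # a partner that never binds yields no colocalized complexes
  cp0 <- coupling_spec(
    u1_scheme = one_step_scheme(1 / 100, 1 / 40),
    bbp_scheme = one_step_scheme(0, 1 / 300)
  )
  rec0 <- simulate_two_channel(cp0, 50, frame_schedule(), seed = 33)
  expect_identical(nrow(find_coloc(rec0)), 0L)
  expect_error(coupling_spec(one_step_scheme(1, 1), one_step_scheme(1, 1), 0.5),
               "stabilization_factor")
})
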