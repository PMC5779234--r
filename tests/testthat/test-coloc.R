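test_that("affine field-of-view registration recovers known maps", {
  pts <- cbind(stats::runif(40, 0, 512), stats::runif(40, 0, 512))
  id <- fit_affine(pts, pts)
  expect_equal(id$linear, diag(2), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(id$offset, c(0, 0), tolerance = 1e-9)
  expect_equal(id$rms_residual, 0, tolerance = 1e-9)

  shifted <- fit_affine(pts, sweep(pts, 2, c(-2.5, 1), "-"))
  expect_equal(shifted$offset, c(2.5, -1), tolerance = 1e-9)

  # rotation + scale with 0.1 px bead noise: parameters within 1%
  set.seed(101)
  th <- 10 * pi / 180
  A <- 1.2 * matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  b <- c(3, -2)
  dst <- t(A %*% t(pts) + b) + matrix(stats::rnorm(80, 0, 0.1), ncol = 2)
  got <- fit_affine(pts, dst)
  expect_equal(got$linear, A, tolerance = 0.01, ignore_attr = TRUE)
  expect_lt(got$rms_residual, 0.3)
  expect_equal(apply_affine(got, pts), dst, tolerance = 0.05, ignore_attr = TRUE)

  coll <- cbind(1:5, 2 * (1:5))
  expect_error(fit_affine(coll, coll), "collinear")
  expect_error(fit_affine(pts[1:2, ], pts[1:2, ]), "at least 3")
})

test_that("colocalized complexes are the channel overlaps with entry/exit labels", {
  rec <- data.frame(
    molecule_id = 1, channel = c("U1", "BBP"),
    start_s = c(0, 50), end_s = c(100, 150)
  )
  cx <- find_coloc(rec, record_length = 1800)
  expect_identical(nrow(cx), 1L)
  expect_equal(cx$start_s, 50)
  expect_equal(cx$end_s, 100)
  expect_identical(cx$entered_by, "U1-first")
  expect_identical(cx$exit_event, "U1-loss")

  disj <- data.frame(
    molecule_id = 1, channel = c("U1", "BBP"),
    start_s = c(0, 500), end_s = c(100, 600)
  )
  expect_identical(nrow(find_coloc(disj, record_length = 1800)), 0L)

  # channel-swap symmetry: intervals preserved, labels exchanged
  set.seed(111)
  mk_channel <- function(mid, ch) {
    s1 <- stats::runif(1, 0, 600); e1 <- s1 + stats::rexp(1, 1 / 120)
    s2 <- e1 + stats::runif(1, 30, 300); e2 <- s2 + stats::rexp(1, 1 / 120)
    out <- data.frame(molecule_id = mid, channel = ch,
                      start_s = c(s1, s2), end_s = c(e1, e2))
    out[out$end_s < 1800, , drop = FALSE]
  }
  rec2 <- do.call(rbind, lapply(1:5, function(m) {
    rbind(mk_channel(m, "U1"), mk_channel(m, "BBP"))
  }))
  swapped <- rec2
  swapped$channel <- ifelse(rec2$channel == "U1", "BBP", "U1")
  a <- find_coloc(rec2, record_length = 1800)
  b <- find_coloc(swapped, record_length = 1800)
  expect_equal(a$start_s, b$start_s)
  expect_equal(a$end_s, b$end_s)
  swap_lab <- function(x) {
    out <- x
    out[x == "U1-first"] <- "BBP-first"; out[x == "BBP-first"] <- "U1-first"
    out[x == "U1-loss"] <- "BBP-loss"; out[x == "BBP-loss"] <- "U1-loss"
    out
  }
  expect_identical(b$entered_by, swap_lab(a$entered_by))
  # exact departure ties break toward U1, the one asymmetric label
  ties <- a$u1_end_s == a$bbp_end_s
  expect_identical(b$exit_event[!ties], swap_lab(a$exit_event[!ties]))
})

test_that("conditional lifetimes separate and recover calibrated class means", {
  # with no BBP events every complete U1 dwell falls in the without class
  rec0 <- data.frame(
    molecule_id = 1:3, channel = "U1",
    start_s = c(10, 20, 30), end_s = c(50, 90, 200)
  )
  cd0 <- conditional_dwells(rec0, record_length = 1800)
  expect_identical(sum(cd0$with_bbp), 0L)
  expect_identical(nrow(cd0), 3L)

  # coupled simulation: stabilized class is significantly longer
  cp <- coupling_spec(
    u1_scheme = one_step_scheme(1 / 150, 1 / 50),
    bbp_scheme = one_step_scheme(1 / 400, 1 / 500),
    stabilization_factor = 3
  )
  rec <- simulate_two_channel(cp, 700, frame_schedule(), seed = 121)
  cd <- conditional_dwells(rec)
  expect_gt(sum(cd$with_bbp), 500)
  tt <- stats::t.test(cd$duration_s[cd$with_bbp], cd$duration_s[!cd$with_bbp])
  expect_lt(tt$p.value, 0.01)

  # calibrated to the published conditional means: recovery within 2 SE
  cpc <- calibrate_conditional_coupling(182.3, 73.6)
  recc <- simulate_two_channel(cpc, 1500, frame_schedule(), seed = 122,
                               start_at_equilibrium = TRUE)
  cdc <- conditional_dwells(recc)
  ml_w <- mean_lifetime(cdc$duration_s[cdc$with_bbp])
  ml_o <- mean_lifetime(cdc$duration_s[!cdc$with_bbp])
  expect_lt(abs(ml_w$mean - 182.3), 2 * ml_w$se)
  expect_lt(abs(ml_o$mean - 73.6), 2 * ml_o$se)
})

test_that("randomized pairing control abolishes the conditional difference", {
  cp <- calibrate_conditional_coupling(182.3, 73.6)
  rec <- simulate_two_channel(cp, 400, frame_schedule(), seed = 131,
                              start_at_equilibrium = TRUE)
  # derangement: no molecule keeps its own partner channel
  n_null <- 0L
  for (s in 1:10) {
    rc <- randomized_control(rec, seed = 600 + s)
    expect_false(any(rc$permutation == as.integer(names(rc$permutation))))
    # compare at the molecule level: dwells of one molecule share a class,
    # so molecule means are the independent sampling units
    p <- molecule_level_pvalue(rc$dwells)
    if (is.na(p) || p > 0.05) n_null <- n_null + 1L
  }
  expect_gte(n_null, 9L)
  expect_error(randomized_control(rec[rec$molecule_id == 1, ], seed = 1,
                                  record_length = 1800), "two molecules")
})

test_that("fate classification distinguishes redefinition from double loss", {
  # U1 lost, a new U1 binds while BBP persists: 5'SS redefinition
  r1 <- data.frame(
    molecule_id = 1, channel = c("U1", "U1", "BBP"),
    start_s = c(0, 120, 50), end_s = c(100, 300, 400)
  )
  f1 <- classify_fates(r1, record_length = 1800)
  expect_identical(f1$count[f1$route == "U1-lost_then_new-U1"], 1L)
  expect_identical(attr(f1, "n_total"), 1L)  # initial complex only
  # classifying every complex also sees the second episode's double loss
  f1_all <- classify_fates(r1, record_length = 1800, initial_only = FALSE)
  expect_identical(f1_all$count[f1_all$route == "U1-lost_then_BBP-lost"], 1L)
  expect_identical(attr(f1_all, "n_total"), 2L)

  # U1 lost and BBP follows with nothing rebinding: double loss
  r2 <- data.frame(
    molecule_id = 1, channel = c("U1", "BBP"),
    start_s = c(0, 50), end_s = c(100, 110)
  )
  f2 <- classify_fates(r2, record_length = 1800)
  expect_identical(f2$count[f2$route == "U1-lost_then_BBP-lost"], 1L)

  # complex running into the record end is censored
  r3 <- data.frame(
    molecule_id = 1, channel = c("U1", "BBP"),
    start_s = c(1000, 1100), end_s = c(1800, 1800)
  )
  f3 <- classify_fates(r3, record_length = 1800)
  expect_identical(f3$count[f3$route == "censored"], 1L)

  # generator with known route probability: tally matches within binomial error
  rec <- make_fate_records(1000, p_redef = 0.3, seed = 141)
  ft <- classify_fates(rec)
  expect_equal(sum(ft$fraction), 1)
  expect_identical(sum(ft$count), attr(ft, "n_total"))
  redef <- ft[ft$route == "U1-lost_then_new-U1", ]
  expect_lt(abs(redef$fraction - 0.3), 3 * sqrt(0.3 * 0.7 / 1000))
  expect_equal(redef$error, sqrt(redef$count * (1 - redef$count / 1000)) / 1000,
               tolerance = 1e-12)
})

test_that("assembly order tallies first binders and matches the arrival race", {
  # symmetric decoupled channels: U1-first and BBP-first are equally likely
  cp_sym <- coupling_spec(
    u1_scheme = one_step_scheme(1 / 300, 1 / 400),
    bbp_scheme = one_step_scheme(1 / 300, 1 / 400)
  )
  rec_s <- simulate_two_channel(cp_sym, 600, frame_schedule(), seed = 151)
  ao_s <- assembly_order(rec_s)
  n1 <- ao_s$count[ao_s$entered_by == "U1-first"]
  n2 <- ao_s$count[ao_s$entered_by == "BBP-first"]
  expect_lt(abs(n1 - n2), 3 * sqrt(n1 + n2))

  # 3:1 arrival-rate asymmetry: competing exponentials predict 3/4 U1-first
  # for each molecule's initial complex when dwells far outlast the waits
  cp_3 <- coupling_spec(
    u1_scheme = one_step_scheme(3 / 400, 1 / 6000),
    bbp_scheme = one_step_scheme(1 / 400, 1 / 6000)
  )
  rec_3 <- simulate_two_channel(cp_3, 800, frame_schedule(), seed = 152)
  ao_3 <- assembly_order(rec_3, initial_only = TRUE)
  nu <- ao_3$count[ao_3$entered_by == "U1-first"]
  nb <- ao_3$count[ao_3$entered_by == "BBP-first"]
  p_hat <- nu / (nu + nb)
  expect_lt(abs(p_hat - 0.75), 3 * sqrt(0.75 * 0.25 / (nu + nb)))
})

test_that("decoupled complex durations follow the minimum-of-exponentials law", {
  # complexes of two independent memoryless channels end at the first of two
  # exponential clocks: mean complete-complex duration = windowed mean of
  # Exp(1/(1/k_u + 1/k_b)^-1)
  k_u <- 1 / 40; k_b <- 1 / 50
  cp <- coupling_spec(
    u1_scheme = one_step_scheme(1 / 120, k_u),
    bbp_scheme = one_step_scheme(1 / 120, k_b)
  )
  rec <- simulate_two_channel(cp, 1200, frame_schedule(), seed = 161,
                              start_at_equilibrium = TRUE)
  cx <- find_coloc(rec)
  dur <- (cx$end_s - cx$start_s)[cx$exit_event != "record-end"]
  expected <- windowed_complete_mean(1 / (k_u + k_b), 1800)
  expect_gt(length(dur), 300)
  expect_lt(abs(mean(dur) - expected), 3 * stats::sd(dur) / sqrt(length(dur)))
})
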