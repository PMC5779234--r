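#' Simulate one molecule's binding timeline
#'
#' Exact-stochastic (Gillespie) realization of a kinetic scheme over one
#' recording window. Holding times in each state are exponential with rate
#' equal to the total outgoing rate; bound intervals are the maximal time
#' spans in bound states, clipped to the record.
#'
#' @param scheme A [kinetic_scheme()].
#' @param schedule A [frame_schedule()] (only its `record_length` is used)
#'   or a single number giving the record length in seconds.
#' @param seed Optional integer seed.
#' @param start_state Initial state (default the dark state).
#' @return Data frame of half-open bound intervals with columns `start_s`,
#'   `end_s`, inside `[0, record_length)`.
#' @examples
#' simulate_timeline(one_step_scheme(0.01, 0.05), frame_schedule(), seed = 1)
#' @export
simulate_timeline <- function(scheme, schedule = frame_schedule(), seed = NULL,
                              start_state = scheme$unbound) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  record_length <- if (inherits(schedule, "frame_schedule")) schedule$record_length else as.numeric(schedule)
  if (!is.null(seed)) set.seed(seed)
  .gillespie_bound_intervals(scheme$Q, scheme$states, scheme$bound_states,
                             start_state, record_length)
}

# core Gillespie loop over a (possibly time-homogeneous joint) generator
.gillespie_bound_intervals <- function(Q, states, bound_states, start_state,
                                       record_length) {
  exit_rate <- -diag(Q)
  s <- start_state
  t <- 0
  starts <- numeric(0); ends <- numeric(0)
  in_bound <- s %in% bound_states
  cur_start <- if (in_bound) 0 else NA_real_
  while (t < record_length) {
    r <- exit_rate[s]
    if (r <= 0) break  # absorbing state
    t_next <- t + stats::rexp(1, r)
    if (t_next >= record_length) break
    probs <- Q[s, ]
    probs[probs < 0] <- 0
    s_new <- states[sample.int(length(states), 1, prob = probs)]
    new_bound <- s_new %in% bound_states
    if (!in_bound && new_bound) cur_start <- t_next
    if (in_bound && !new_bound) {
      starts <- c(starts, cur_start); ends <- c(ends, t_next)
      cur_start <- NA_real_
    }
    s <- s_new; in_bound <- new_bound; t <- t_next
  }
  if (in_bound) {
    starts <- c(starts, cur_start); ends <- c(ends, record_length)
  }
  data.frame(start_s = starts, end_s = ends)
}

#' Coupling specification for a two-channel U1/BBP simulation
#'
#' Joint continuous-time Markov model over the product of a U1 scheme and a
#' BBP scheme, in which BBP occupancy stabilizes U1: while the BBP channel
#' is in a bound state, every U1 transition from a bound state to the dark
#' state is divided by `stabilization_factor`, and (optionally) every U1
#' bound-to-bound transition is multiplied by `transition_multiplier`
#' (initial-to-stable stimulation in the two-step scheme).
#' `stabilization_factor = 1` and `transition_multiplier = 1` recover two
#' independent channels.
#'
#' @param u1_scheme,bbp_scheme [kinetic_scheme()]s for the two channels.
#' @param stabilization_factor Divisor (>= 1) applied to U1 dissociation
#'   rates while BBP is bound.
#' @param transition_multiplier Multiplier (>= 1) applied to U1
#'   bound-to-bound rates while BBP is bound.
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(u1_scheme, bbp_scheme, stabilization_factor = 1,
                          transition_multiplier = 1) {
  stopifnot(inherits(u1_scheme, "kinetic_scheme"), inherits(bbp_scheme, "kinetic_scheme"))
  if (!is.numeric(stabilization_factor) || stabilization_factor < 1) {
    stop("stabilization_factor must be >= 1")
  }
  if (!is.numeric(transition_multiplier) || transition_multiplier < 1) {
    stop("transition_multiplier must be >= 1")
  }
  structure(
    list(
      u1_scheme = u1_scheme, bbp_scheme = bbp_scheme,
      stabilization_factor = stabilization_factor,
      transition_multiplier = transition_multiplier
    ),
    class = "coupling_spec"
  )
}

# U1 generator conditional on BBP occupancy
.u1_generator_given_bbp <- function(coupling, bbp_bound) {
  sc <- coupling$u1_scheme
  Q <- sc$Q
  if (bbp_bound) {
    for (b in sc$bound_states) {
      Q[b, sc$unbound] <- Q[b, sc$unbound] / coupling$stabilization_factor
      others <- setdiff(sc$bound_states, b)
      Q[b, others] <- Q[b, others] * coupling$transition_multiplier
    }
    diag(Q) <- 0
    diag(Q) <- -rowSums(Q)
  }
  Q
}

# full joint generator over product states (u x b), for equilibrium starts
.joint_generator <- function(coupling) {
  us <- coupling$u1_scheme$states
  bs <- coupling$bbp_scheme$states
  Qb <- coupling$bbp_scheme$Q
  joint <- as.vector(outer(us, bs, function(u, b) paste(u, b, sep = "|")))
  n <- length(joint)
  Q <- matrix(0, n, n, dimnames = list(joint, joint))
  for (b in bs) {
    bb <- b %in% coupling$bbp_scheme$bound_states
    Qu <- .u1_generator_given_bbp(coupling, bb)
    for (u in us) {
      from <- paste(u, b, sep = "|")
      for (u2 in us) if (u2 != u && Qu[u, u2] > 0) {
        Q[from, paste(u2, b, sep = "|")] <- Qu[u, u2]
      }
      for (b2 in bs) if (b2 != b && Qb[b, b2] > 0) {
        Q[from, paste(u, b2, sep = "|")] <- Qb[b, b2]
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# stationary distribution of a CTMC generator (solve pi Q = 0, sum pi = 1)
.stationary_distribution <- function(Q) {
  n <- nrow(Q)
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  pi_hat <- as.numeric(stats::coef(stats::lm.fit(A, b)))
  pi_hat[pi_hat < 0] <- 0
  pi_hat / sum(pi_hat)
}

#' Simulate coupled two-channel U1/BBP records
#'
#' Gillespie simulation of the joint U1 x BBP chain of a [coupling_spec()]
#' for `n_molecules` independent molecules over one recording window.
#'
#' @param coupling A [coupling_spec()].
#' @param n_molecules Number of molecules.
#' @param schedule A [frame_schedule()] or record length in seconds.
#' @param seed Optional integer seed.
#' @param start_at_equilibrium If `TRUE`, the initial joint state of each
#'   molecule is drawn from the stationary distribution of the joint chain
#'   (binding events in progress at t = 0 appear as left-truncated
#'   intervals); if `FALSE` (default) both channels start in their dark
#'   states.
#' @return Tidy data frame of bound intervals with columns `molecule_id`,
#'   `channel` (`"U1"`/`"BBP"`), `start_s`, `end_s`, with the record length
#'   attached as attribute `record_length`.
#' @export
simulate_two_channel <- function(coupling, n_molecules, schedule = frame_schedule(),
                                 seed = NULL, start_at_equilibrium = FALSE) {
  stopifnot(inherits(coupling, "coupling_spec"), n_molecules >= 1)
  record_length <- if (inherits(schedule, "frame_schedule")) schedule$record_length else as.numeric(schedule)
  if (!is.null(seed)) set.seed(seed)

  usc <- coupling$u1_scheme; bsc <- coupling$bbp_scheme
  Qu_free <- .u1_generator_given_bbp(coupling, FALSE)
  Qu_stab <- .u1_generator_given_bbp(coupling, TRUE)
  Qb <- bsc$Q
  us <- usc$states; bs <- bsc$states

  if (start_at_equilibrium) {
    Qj <- .joint_generator(coupling)
    pi_j <- .stationary_distribution(Qj)
    joint_names <- rownames(Qj)
  }

  res <- vector("list", n_molecules)
  for (m in seq_len(n_molecules)) {
    if (start_at_equilibrium) {
      st <- strsplit(joint_names[sample.int(length(pi_j), 1, prob = pi_j)], "|", fixed = TRUE)[[1]]
      u <- st[1]; b <- st[2]
    } else {
      u <- usc$unbound; b <- bsc$unbound
    }
    t <- 0
    u_bound <- u %in% usc$bound_states
    b_bound <- b %in% bsc$bound_states
    u_start <- if (u_bound) 0 else NA_real_
    b_start <- if (b_bound) 0 else NA_real_
    u_iv <- list(); b_iv <- list()
    repeat {
      Qu <- if (b_bound) Qu_stab else Qu_free
      ru <- Qu[u, ]; ru[ru < 0] <- 0
      rb <- Qb[b, ]; rb[rb < 0] <- 0
      total <- sum(ru) + sum(rb)
      if (total <= 0) { t <- record_length; break }
      t_next <- t + stats::rexp(1, total)
      if (t_next >= record_length) { t <- record_length; break }
      if (stats::runif(1) < sum(ru) / total) {
        u_new <- us[sample.int(length(us), 1, prob = ru)]
        nb <- u_new %in% usc$bound_states
        if (!u_bound && nb) u_start <- t_next
        if (u_bound && !nb) { u_iv[[length(u_iv) + 1]] <- c(u_start, t_next); u_start <- NA_real_ }
        u <- u_new; u_bound <- nb
      } else {
        b_new <- bs[sample.int(length(bs), 1, prob = rb)]
        nb <- b_new %in% bsc$bound_states
        if (!b_bound && nb) b_start <- t_next
        if (b_bound && !nb) { b_iv[[length(b_iv) + 1]] <- c(b_start, t_next); b_start <- NA_real_ }
        b <- b_new; b_bound <- nb
      }
      t <- t_next
    }
    if (u_bound) u_iv[[length(u_iv) + 1]] <- c(u_start, record_length)
    if (b_bound) b_iv[[length(b_iv) + 1]] <- c(b_start, record_length)
    n_u <- length(u_iv); n_b <- length(b_iv)
    if (n_u + n_b > 0) {
      mat <- do.call(rbind, c(u_iv, b_iv))
      res[[m]] <- data.frame(
        molecule_id = m,
        channel = rep(c("U1", "BBP"), c(n_u, n_b)),
        start_s = mat[, 1], end_s = mat[, 2],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(
      molecule_id = integer(0), channel = character(0),
      start_s = numeric(0), end_s = numeric(0)
    )
  }
  rownames(out) <- NULL
  attr(out, "record_length") <- record_length
  attr(out, "n_molecules") <- n_molecules
  out
}

#' Mean of a complete dwell inside a finite recording window
#'
#' For binding events whose start times occur at uniform (stationary) rate
#' over a record of length `R` and whose durations are exponential with
#' mean `tau`, only events that end before the record does are observed as
#' complete dwells. Their expected duration is
#' \deqn{m(\tau) = \tau - \frac{\tau^2\,(1 - e^{-R/\tau}(1 + R/\tau))}
#'   {R - \tau\,(1 - e^{-R/\tau})}}
#' which is below `tau` because long events are preferentially truncated by
#' the record end.
#'
#' @param tau True exponential mean dwell (s).
#' @param record_length Record length `R` (s).
#' @return Expected complete-dwell mean (s).
#' @seealso [calibrate_conditional_coupling()]
#' @export
windowed_complete_mean <- function(tau, record_length = 1800) {
  stopifnot(tau > 0, record_length > 0)
  R <- record_length
  e <- exp(-R / tau)
  D <- R - tau * (1 - e)
  tau - tau^2 * (1 - e * (1 + R / tau)) / D
}

#' Calibrate a coupled simulation to target conditional U1 mean lifetimes
#'
#' Builds a [coupling_spec()] whose conditional-lifetime analysis (complete
#' U1 dwells partitioned by BBP colocalization, inside a finite record)
#' reproduces target observed class means. The true exponential lifetimes
#' are obtained by inverting the record-window censoring bias
#' ([windowed_complete_mean()]) with `uniroot`, so the targets are matched
#' as *observed* (window-censored) means, which is what a finite recording
#' measures.
#'
#' BBP kinetics are made quasi-static (`k_on = k_off = 1e-6` s^-1): together
#' with an equilibrium start, each molecule is BBP-occupied or BBP-free for
#' essentially the whole record (occupancy 1/2), so the two U1 dwell classes
#' are clean single exponentials with the calibrated lifetimes.
#'
#' @param mean_with Target observed mean U1 dwell while colocalized with
#'   BBP (s).
#' @param mean_without Target observed mean U1 dwell in the absence of BBP
#'   (s); must be below `mean_with`.
#' @param record_length Record length (s).
#' @param k_on_u1 U1 association rate (s^-1).
#' @return A [coupling_spec()]; the calibrated true lifetimes are attached
#'   as attributes `tau_with` and `tau_without`.
#' @examples
#' cp <- calibrate_conditional_coupling(182.3, 73.6)
#' attr(cp, "tau_with")
#' @export
calibrate_conditional_coupling <- function(mean_with, mean_without,
                                           record_length = 1800,
                                           k_on_u1 = 1 / 300) {
  stopifnot(mean_with > mean_without, mean_without > 0)
  solve_tau <- function(target) {
    stats::uniroot(
      function(tau) windowed_complete_mean(tau, record_length) - target,
      interval = c(target, target * 50), tol = 1e-10
    )$root
  }
  tau_without <- solve_tau(mean_without)
  tau_with <- solve_tau(mean_with)
  cp <- coupling_spec(
    u1_scheme = one_step_scheme(k_on = k_on_u1, k_off = 1 / tau_without),
    bbp_scheme = one_step_scheme(k_on = 1e-6, k_off = 1e-6),
    stabilization_factor = tau_with / tau_without
  )
  attr(cp, "tau_with") <- tau_with
  attr(cp, "tau_without") <- tau_without
  cp
}

#' Sample dwell times from a window-censored exponential mixture
#'
#' Inverse-CDF sampling from the truncated one- or two-component density of
#' an [exp_mixture_model()]: a component is chosen with probability
#' proportional to its truncated mass, then a truncated exponential is
#' drawn on `[t_m, t_max]`.
#'
#' @param model An [exp_mixture_model()].
#' @param n Number of dwells.
#' @param seed Optional integer seed.
#' @return Data frame of dwell observations (columns `molecule_id`,
#'   `channel`, `start_s`, `duration_s`, `left_truncated`,
#'   `right_truncated`); durations lie inside the model's window.
#' @examples
#' d <- sample_mixture_dwells(exp_mixture_model(0.5, 20, 165), 100, seed = 1)
#' range(d$duration_s)
#' @export
sample_mixture_dwells <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "exp_mixture_model"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  w <- model$window
  taus <- c(model$tau1, model$tau2)
  amps <- if (is.null(model$tau2)) 1 else c(model$A1, 1 - model$A1)
  mass <- amps * (exp(-w$t_m / taus) - .exp_neg(w$t_max / taus))
  comp <- if (length(taus) == 1) rep(1L, n) else {
    sample.int(2L, n, replace = TRUE, prob = mass)
  }
  tau <- taus[comp]
  hi <- exp(-w$t_m / tau)
  lo <- .exp_neg(w$t_max / tau)
  u <- stats::runif(n)
  t <- -tau * log(hi - u * (hi - lo))
  data.frame(
    molecule_id = seq_len(n), channel = "U1", start_s = NA_real_,
    duration_s = t, left_truncated = FALSE, right_truncated = FALSE,
    stringsAsFactors = FALSE
  )
}

# exp(-x) that tolerates x = Inf
.exp_neg <- function(x) ifelse(is.infinite(x), 0, exp(-x))

#' Frame-sample a binding timeline
#'
#' Converts continuous bound intervals into the discrete per-frame record a
#' camera would produce: a frame reads "present" iff a bound interval
#' overlaps its exposure window, so events falling entirely between
#' exposures are invisible (the detection floor of the acquisition
#' schedule). Optional photobleaching truncates each interval with constant
#' hazard per illuminated (exposure) second; optional surface background
#' adds spurious single-frame presences.
#'
#' @param intervals Data frame with columns `start_s`, `end_s` (one
#'   molecule's bound intervals), all inside the record window.
#' @param schedule A [frame_schedule()].
#' @param bleach_rate Photobleaching hazard per exposure-second (>= 0).
#' @param background_rate Probability of a spurious single-frame presence
#'   per frame (>= 0).
#' @param noise_sd Gaussian intensity noise SD around the 0/1 fluorophore
#'   levels.
#' @param seed Optional integer seed.
#' @return Data frame with columns `frame_index` (0-based), `time_s` (frame
#'   start), `present` (logical) and `intensity`.
#' @examples
#' fs <- frame_schedule()
#' # an event falling between exposures is not detected
#' frame_sample(data.frame(start_s = 7.2, end_s = 7.5), fs)$present |> any()
#' @export
frame_sample <- function(intervals, schedule = frame_schedule(),
                         bleach_rate = 0, background_rate = 0,
                         noise_sd = 0, seed = NULL) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (bleach_rate < 0 || background_rate < 0 || noise_sd < 0) {
    stop("rates must be non-negative")
  }
  if (!is.null(seed)) set.seed(seed)
  if (nrow(intervals) > 0 &&
      (any(intervals$start_s < 0) || any(intervals$end_s > schedule$record_length))) {
    stop("intervals must lie inside the record window")
  }
  f0 <- (seq_len(schedule$n_frames) - 1) * schedule$interval  # exposure starts
  f1 <- f0 + schedule$exposure

  if (bleach_rate > 0 && nrow(intervals) > 0) {
    intervals$end_s <- vapply(seq_len(nrow(intervals)), function(i) {
      .bleach_truncate(intervals$start_s[i], intervals$end_s[i], f0, f1, bleach_rate)
    }, numeric(1))
    intervals <- intervals[intervals$end_s > intervals$start_s, , drop = FALSE]
  }

  present <- rep(FALSE, schedule$n_frames)
  for (i in seq_len(nrow(intervals))) {
    present <- present | (intervals$start_s[i] < f1 & intervals$end_s[i] > f0)
  }
  if (background_rate > 0) {
    present <- present | (stats::runif(schedule$n_frames) < background_rate)
  }
  intensity <- as.numeric(present)
  if (noise_sd > 0) intensity <- intensity + stats::rnorm(schedule$n_frames, 0, noise_sd)
  data.frame(
    frame_index = seq_len(schedule$n_frames) - 1L,
    time_s = f0, present = present, intensity = intensity
  )
}

# truncate one interval at the real time its cumulative illuminated time
# reaches an Exp(bleach_rate) draw; illumination accrues only during exposures
.bleach_truncate <- function(start, end, f0, f1, bleach_rate) {
  t_b <- stats::rexp(1, bleach_rate)  # budget in exposure-seconds
  keep <- f1 > start & f0 < end
  if (!any(keep)) return(end)
  seg0 <- pmax(f0[keep], start)
  seg1 <- pmin(f1[keep], end)
  durs <- seg1 - seg0
  cum <- cumsum(durs)
  k <- which(cum >= t_b)[1]
  if (is.na(k)) return(end)
  prev <- if (k == 1) 0 else cum[k - 1]
  seg0[k] + (t_b - prev)
}
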