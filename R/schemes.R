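#' Labeled-state kinetic scheme for single-molecule binding
#'
#' A continuous-time Markov chain over named states with strictly positive
#' transition rate constants. One state (by convention `"unbound"`) is the
#' dark state; `bound_states` are the states in which a fluorophore is
#' colocalized with the tethered RNA and therefore visible. Dwell times are
#' times spent in maximal runs of bound states.
#'
#' @param states Character vector of state names; must include `unbound`.
#' @param rates Named numeric vector of rate constants in s^-1. Names are
#'   `"from->to"` (e.g. `"unbound->bound"`). Rates must be finite and > 0;
#'   entries equal to 0 are dropped (no transition). Self-transitions are
#'   not allowed.
#' @param bound_states Character vector, non-empty subset of `states`
#'   excluding `unbound`.
#' @param unbound Name of the dark state (default `"unbound"`).
#'
#' @return An object of class `kinetic_scheme` with elements `states`,
#'   `rates` (data frame `from`, `to`, `rate`), `bound_states`, `unbound`,
#'   and the generator matrix `Q` (rows = from-states, diagonal = minus the
#'   total exit rate).
#'
#' @details The dark state must be reachable from every bound state so that
#'   every binding event can terminate; this is checked at construction.
#'
#' @examples
#' sc <- kinetic_scheme(
#'   states = c("unbound", "bound"),
#'   rates = c("unbound->bound" = 0.01, "bound->unbound" = 0.05),
#'   bound_states = "bound"
#' )
#' print(sc)
#' @seealso [two_step_scheme()], [one_step_scheme()],
#'   [independent_pathway_scheme()], [simulate_timeline()],
#'   [dwell_distribution_from_scheme()]
#' @export
kinetic_scheme <- function(states, rates, bound_states, unbound = "unbound") {
  states <- as.character(states)
  if (anyDuplicated(states)) stop("duplicate state names")
  if (!unbound %in% states) stop("states must include the dark state '", unbound, "'")
  if (length(bound_states) == 0) stop("bound_states must be non-empty")
  if (!all(bound_states %in% states)) stop("bound_states must be a subset of states")
  if (unbound %in% bound_states) stop("bound_states must exclude the dark state")

  if (is.null(names(rates)) || any(!nzchar(names(rates)))) {
    stop("rates must be a named vector with names of the form 'from->to'")
  }
  parts <- strsplit(names(rates), "->", fixed = TRUE)
  if (any(lengths(parts) != 2)) stop("rate names must be of the form 'from->to'")
  from <- vapply(parts, `[`, "", 1)
  to <- vapply(parts, `[`, "", 2)
  rate <- as.numeric(rates)
  keep <- rate != 0
  from <- from[keep]; to <- to[keep]; rate <- rate[keep]
  if (any(!is.finite(rate)) || any(rate < 0)) stop("rates must be finite and positive")
  if (!all(from %in% states) || !all(to %in% states)) stop("rate endpoints must be named states")
  if (any(from == to)) stop("self-transitions are not allowed")
  if (anyDuplicated(paste(from, to))) stop("duplicate transition")

  n <- length(states)
  Q <- matrix(0, n, n, dimnames = list(states, states))
  for (i in seq_along(rate)) Q[from[i], to[i]] <- rate[i]
  diag(Q) <- -rowSums(Q)

  sc <- structure(
    list(
      states = states,
      rates = data.frame(from = from, to = to, rate = rate, stringsAsFactors = FALSE),
      bound_states = as.character(bound_states),
      unbound = unbound,
      Q = Q
    ),
    class = "kinetic_scheme"
  )
  # every binding event must be able to end: unbound reachable from all bound states
  reach <- .reachable_set(Q)
  for (b in sc$bound_states) {
    if (!unbound %in% reach[[b]]) {
      stop("dark state not reachable from bound state '", b, "'")
    }
  }
  sc
}

# states reachable (transitively) from each state along positive-rate edges
.reachable_set <- function(Q) {
  states <- rownames(Q)
  adj <- Q > 0
  out <- list()
  for (s in states) {
    seen <- structure(logical(length(states)), names = states)
    frontier <- s
    while (length(frontier)) {
      nxt <- states[colSums(adj[frontier, , drop = FALSE]) > 0]
      nxt <- nxt[!seen[nxt]]
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    out[[s]] <- states[seen]
  }
  out
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Kinetic scheme:", length(x$states), "states (",
      paste(x$states, collapse = ", "), ")\n")
  cat("  bound:", paste(x$bound_states, collapse = ", "), "\n")
  for (i in seq_len(nrow(x$rates))) {
    cat(sprintf("  %s -> %s : %g /s\n", x$rates$from[i], x$rates$to[i], x$rates$rate[i]))
  }
  invisible(x)
}

#' One-step reversible binding scheme
#'
#' Unbound <-> bound with association rate `k_on` and dissociation rate
#' `k_off`; the bound dwell time is exponential with mean `1/k_off`.
#'
#' @param k_on,k_off Rate constants (s^-1). `k_on = 0` gives a binder that
#'   never associates (useful as a null channel).
#' @return A [kinetic_scheme()].
#' @export
one_step_scheme <- function(k_on, k_off) {
  kinetic_scheme(
    states = c("unbound", "bound"),
    rates = c("unbound->bound" = k_on, "bound->unbound" = k_off),
    bound_states = "bound"
  )
}

#' Two-step U1 binding scheme
#'
#' Sequential mechanism in which U1 first forms a short-lived initial
#' complex at the 5' splice site and can then transition into a long-lived
#' stabilized complex:
#' unbound -(k_on)-> initial -(k12)-> stable, with dissociation k_off1 from
#' the initial complex and k_off2 from the stable complex, and optional
#' reverse transition k21. The apparent bound dwell time is phase-type and,
#' for this linear two-state bound chain, a two-exponential mixture (see
#' [dwell_distribution_from_scheme()]).
#'
#' @param k_on Association rate (s^-1).
#' @param k_off1 Dissociation rate from the initial complex (s^-1).
#' @param k12 Forward stabilization rate initial -> stable (s^-1); 0 removes
#'   the transition (the stable state becomes unreachable).
#' @param k21 Reverse rate stable -> initial (s^-1), default 0.
#' @param k_off2 Dissociation rate from the stable complex (s^-1).
#' @return A [kinetic_scheme()] with bound states `initial`, `stable`.
#' @export
two_step_scheme <- function(k_on, k_off1, k12, k_off2, k21 = 0) {
  kinetic_scheme(
    states = c("unbound", "initial", "stable"),
    rates = c(
      "unbound->initial" = k_on,
      "initial->unbound" = k_off1,
      "initial->stable" = k12,
      "stable->initial" = k21,
      "stable->unbound" = k_off2
    ),
    bound_states = c("initial", "stable")
  )
}

#' Independent-pathway binding scheme
#'
#' Two non-interconverting bound complexes entered directly from the dark
#' state with rates `k_on_a`, `k_on_b` and left with rates `k_off_a`,
#' `k_off_b`. A binding event enters complex a with probability
#' `k_on_a / (k_on_a + k_on_b)`, so the dwell distribution is exactly the
#' mixture (p, 1/k_off_a; 1-p, 1/k_off_b).
#'
#' @param k_on_a,k_off_a,k_on_b,k_off_b Rate constants (s^-1).
#' @return A [kinetic_scheme()] with bound states `bound_a`, `bound_b`.
#' @export
independent_pathway_scheme <- function(k_on_a, k_off_a, k_on_b, k_off_b) {
  kinetic_scheme(
    states = c("unbound", "bound_a", "bound_b"),
    rates = c(
      "unbound->bound_a" = k_on_a,
      "bound_a->unbound" = k_off_a,
      "unbound->bound_b" = k_on_b,
      "bound_b->unbound" = k_off_b
    ),
    bound_states = c("bound_a", "bound_b")
  )
}

#' Camera frame schedule
#'
#' Acquisition timing for frame-sampled recordings: frames start every
#' `interval` seconds and the camera integrates for `exposure` seconds at
#' the start of each frame. Defaults are the standard CoSMoS schedule used
#' throughout this package: 1 s exposures at 5 s intervals for 30 min
#' (360 frames, 1800 s records).
#'
#' @param exposure Exposure duration per frame (s); `0 < exposure <= interval`.
#' @param interval Time between consecutive frame starts (s).
#' @param n_frames Number of frames in the record.
#' @return An object of class `frame_schedule` with fields `exposure`,
#'   `interval`, `n_frames` and derived `record_length = interval * n_frames`.
#' @examples
#' frame_schedule() # 1 s @ 5 s x 360 frames = 1800 s
#' @export
frame_schedule <- function(exposure = 1, interval = 5, n_frames = 360) {
  stopifnot(is.numeric(exposure), is.numeric(interval), is.numeric(n_frames))
  if (!(exposure > 0 && exposure <= interval)) stop("need 0 < exposure <= interval")
  if (n_frames < 1 || n_frames != round(n_frames)) stop("n_frames must be a positive integer")
  structure(
    list(
      exposure = exposure, interval = interval, n_frames = as.integer(n_frames),
      record_length = interval * n_frames
    ),
    class = "frame_schedule"
  )
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf(
    "Frame schedule: %g s exposure every %g s, %d frames (%g s record)\n",
    x$exposure, x$interval, x$n_frames, x$record_length
  ))
  invisible(x)
}

#' Observable dwell-time window
#'
#' Truncation window of the censored dwell-time densities: `t_m` is the
#' shortest observable dwell (one frame interval under the default
#' acquisition schedule) and `t_max` the longest (the record length).
#' Fitted densities are normalized on `[t_m, t_max]`.
#'
#' @param t_m Minimum observable dwell (s), > 0 (or 0 for the untruncated
#'   limit).
#' @param t_max Maximum observable dwell (s), may be `Inf` for the
#'   untruncated limit; must exceed `t_m`.
#' @return An object of class `censor_window`.
#' @export
censor_window <- function(t_m = 5, t_max = 1800) {
  stopifnot(is.numeric(t_m), is.numeric(t_max), length(t_m) == 1, length(t_max) == 1)
  if (t_m < 0 || !(t_m < t_max)) stop("need 0 <= t_m < t_max")
  structure(list(t_m = t_m, t_max = t_max), class = "censor_window")
}

#' @export
print.censor_window <- function(x, ...) {
  cat(sprintf("Censor window: [%g, %g] s\n", x$t_m, x$t_max))
  invisible(x)
}

#' Window-censored exponential mixture dwell-time model
#'
#' The one- or two-component exponential probability density of observed
#' dwell times, truncated and renormalized on the observable window
#' `[t_m, t_max]`. With amplitude `A1` of the fast component (`A2 = 1 - A1`
#' is always derived, never stored):
#'
#' \deqn{f(t) = \frac{(A_1/\tau_1) e^{-t/\tau_1} + (A_2/\tau_2) e^{-t/\tau_2}}
#'   {A_1 (e^{-t_m/\tau_1} - e^{-t_{max}/\tau_1}) +
#'    A_2 (e^{-t_m/\tau_2} - e^{-t_{max}/\tau_2})}}
#'
#' Setting `A1 = 1` (or omitting `tau2`) gives the single-exponential form.
#'
#' @param A1 Fast-component amplitude in \[0, 1\].
#' @param tau1 Fast time constant (s), > 0.
#' @param tau2 Slow time constant (s), `>= tau1`, or `NULL` for a
#'   single-component model.
#' @param window A [censor_window()].
#' @return An object of class `exp_mixture_model`.
#' @examples
#' exp_mixture_model(A1 = 0.5, tau1 = 20, tau2 = 165)
#' @export
exp_mixture_model <- function(A1 = 1, tau1, tau2 = NULL, window = censor_window()) {
  stopifnot(inherits(window, "censor_window"))
  if (!is.numeric(A1) || length(A1) != 1 || is.na(A1) || A1 < 0 || A1 > 1) {
    stop("A1 must be in [0, 1]")
  }
  if (!is.numeric(tau1) || length(tau1) != 1 || !is.finite(tau1) || tau1 <= 0) {
    stop("tau1 must be a positive number")
  }
  if (!is.null(tau2)) {
    if (!is.numeric(tau2) || length(tau2) != 1 || !is.finite(tau2) || tau2 <= 0) {
      stop("tau2 must be a positive number")
    }
    if (tau2 < tau1) stop("tau2 must be >= tau1 (components are ordered)")
  }
  if (is.null(tau2)) A1 <- 1
  structure(
    list(A1 = A1, tau1 = tau1, tau2 = tau2, window = window),
    class = "exp_mixture_model"
  )
}

#' @export
print.exp_mixture_model <- function(x, ...) {
  if (is.null(x$tau2)) {
    cat(sprintf("Censored exponential: tau = %.4g s", x$tau1))
  } else {
    cat(sprintf(
      "Censored biexponential: A1 = %.3f, tau1 = %.4g s, tau2 = %.4g s",
      x$A1, x$tau1, x$tau2
    ))
  }
  cat(sprintf("  [window %g-%g s]\n", x$window$t_m, x$window$t_max))
  invisible(x)
}

# number of free parameters of the mixture (used by model selection)
.n_par <- function(model) if (is.null(model$tau2)) 1L else 3L
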