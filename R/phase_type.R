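#' Closed-form dwell-time distribution of a binding scheme
#'
#' The bound-state dwell time of a kinetic scheme is the time to absorption
#' into the dark state of the sub-chain restricted to the bound states — a
#' phase-type distribution. For schemes whose bound sub-chain has one or two
#' states (one-step, two-step sequential, independent pathways) this is an
#' exponential or a two-exponential mixture, obtained here by
#' eigen-decomposition of the bound-state sub-generator.
#'
#' Entry probabilities into the bound states are proportional to the rates
#' out of the dark state, i.e. the distribution describes the dwell of a
#' typical binding event started from the dark state.
#'
#' @param scheme A [kinetic_scheme()] with at most two bound states.
#' @param window A [censor_window()] attached to the returned model (the
#'   analytic time constants themselves do not depend on it). Defaults to
#'   the untruncated limit.
#' @return An [exp_mixture_model()] with the exact amplitudes and time
#'   constants, fast component first.
#' @details For two bound states the survival function starting from the
#'   entry distribution is \eqn{S(t) = c_1 e^{\lambda_1 t} + c_2 e^{\lambda_2 t}}
#'   with \eqn{\lambda_i} the (real, negative) eigenvalues of the bound
#'   sub-generator; the density weights are the \eqn{c_i} and
#'   \eqn{\tau_i = -1/\lambda_i}. For strictly sequential schemes with a
#'   slow second step the weights are a genuine mixture (both in \[0,1\]);
#'   if a weight falls outside \[0,1\] the dwell law is not expressible as
#'   a probabilistic two-exponential mixture and an error is raised.
#' @examples
#' sc <- two_step_scheme(k_on = 0.01, k_off1 = 0.2, k12 = 0.05, k_off2 = 0.01)
#' dwell_distribution_from_scheme(sc)
#' @export
dwell_distribution_from_scheme <- function(scheme,
                                           window = censor_window(0, Inf)) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  bound <- scheme$bound_states
  if (length(bound) > 2) {
    stop("unsupported scheme: more than two bound states")
  }
  Q <- scheme$Q
  # entry distribution: direct transitions dark state -> bound states
  entry <- Q[scheme$unbound, bound]
  if (sum(entry) <= 0) {
    stop("no transition from the dark state into a bound state")
  }
  alpha <- entry / sum(entry)
  Qb <- Q[bound, bound, drop = FALSE]

  if (length(bound) == 1) {
    rate_out <- -Qb[1, 1]
    return(exp_mixture_model(A1 = 1, tau1 = 1 / rate_out, window = window))
  }

  eg <- eigen(Qb)
  lam <- Re(eg$values)  # 2x2 sub-generator with non-negative off-diagonals: real spectrum
  if (any(lam >= 0)) stop("bound sub-chain is not transient; cannot form dwell distribution")

  if (abs(lam[1] - lam[2]) < 1e-12 * max(abs(lam))) {
    # degenerate spectrum: only arises here when the two phases are
    # kinetically identical, in which case the dwell is single-exponential
    return(exp_mixture_model(A1 = 1, tau1 = -1 / lam[1], window = window))
  }

  V <- Re(eg$vectors)
  # S(t) = alpha' exp(Qb t) 1 = sum_i c_i exp(lam_i t); c = (alpha' V) * (V^{-1} 1)
  c_i <- as.numeric(alpha %*% V) * as.numeric(solve(V, rep(1, 2)))
  taus <- -1 / lam
  ord <- order(taus)
  taus <- taus[ord]; c_i <- c_i[ord]

  tol <- 1e-9
  if (any(c_i < -tol) || any(c_i > 1 + tol)) {
    stop(
      "dwell distribution of this scheme is not a two-exponential mixture ",
      "(weights ", paste(signif(c_i, 4), collapse = ", "), ")"
    )
  }
  c_i <- pmin(pmax(c_i, 0), 1)
  if (c_i[1] >= 1 - 1e-12) {
    return(exp_mixture_model(A1 = 1, tau1 = taus[1], window = window))
  }
  exp_mixture_model(A1 = c_i[1], tau1 = taus[1], tau2 = taus[2], window = window)
}

#' Draw bound dwell times directly from a scheme
#'
#' Gillespie realization of single binding events: each draw starts in a
#' bound state chosen with probability proportional to the dark-state entry
#' rates and runs the embedded chain until return to the dark state. This
#' is the brute-force sampler used to cross-check
#' [dwell_distribution_from_scheme()]; unlike [simulate_timeline()] it
#' imposes no recording window.
#'
#' @param scheme A [kinetic_scheme()].
#' @param n Number of dwells to draw.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` dwell times (s).
#' @export
sample_scheme_dwells <- function(scheme, n, seed = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  Q <- scheme$Q
  states <- scheme$states
  bound <- scheme$bound_states
  entry <- Q[scheme$unbound, bound]
  if (sum(entry) <= 0) stop("no transition from the dark state into a bound state")
  p_entry <- entry / sum(entry)

  exit_rate <- -diag(Q)
  jump_prob <- Q
  diag(jump_prob) <- 0
  for (s in states) if (exit_rate[s] > 0) jump_prob[s, ] <- jump_prob[s, ] / exit_rate[s]

  start_states <- bound[sample.int(length(bound), n, replace = TRUE, prob = p_entry)]
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- start_states[i]
    t <- 0
    while (s != scheme$unbound) {
      t <- t + stats::rexp(1, exit_rate[s])
      s <- states[sample.int(length(states), 1, prob = jump_prob[s, ])]
    }
    out[i] <- t
  }
  out
}
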