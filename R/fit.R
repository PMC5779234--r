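#' Window-censored exponential mixture density
#'
#' Probability density of observed dwell times under an
#' [exp_mixture_model()], truncated and renormalized on the observable
#' window `[t_m, t_max]` (see the model's help page for the formula). The
#' one-component density is the `A1 = 1` special case.
#'
#' @param t Vector of dwell times; every value must lie inside the window.
#' @param model An [exp_mixture_model()].
#' @param log If `TRUE`, return log-density.
#' @return Density values (s^-1).
#' @examples
#' m <- exp_mixture_model(0.5, 20, 165, censor_window(5, 1800))
#' censored_pdf(5, m)
#' integrate(censored_pdf, 5, 1800, model = m) # 1
#' @export
censored_pdf <- function(t, model, log = FALSE) {
  stopifnot(inherits(model, "exp_mixture_model"))
  w <- model$window
  if (any(t < w$t_m | t > w$t_max)) stop("t outside the censoring window")
  taus <- c(model$tau1, model$tau2)
  amps <- if (is.null(model$tau2)) 1 else c(model$A1, 1 - model$A1)
  Z <- sum(amps * (exp(-w$t_m / taus) - .exp_neg(w$t_max / taus)))
  dens <- 0
  for (i in seq_along(taus)) dens <- dens + amps[i] / taus[i] * exp(-t / taus[i])
  if (log) base::log(dens) - base::log(Z) else dens / Z
}

# negative log-likelihood on raw parameters (vectorized over data)
.nll_mixture <- function(A1, tau1, tau2, t, w) {
  Z <- A1 * (exp(-w$t_m / tau1) - .exp_neg(w$t_max / tau1)) +
    (1 - A1) * (exp(-w$t_m / tau2) - .exp_neg(w$t_max / tau2))
  dens <- A1 / tau1 * exp(-t / tau1) + (1 - A1) / tau2 * exp(-t / tau2)
  -sum(log(dens)) + length(t) * log(Z)
}

# one-component fit via the sufficient statistic (sum of dwells)
.fit1_suffstat <- function(S, n, w) {
  nll <- function(log_tau) {
    tau <- exp(log_tau)
    Z <- exp(-w$t_m / tau) - .exp_neg(w$t_max / tau)
    S / tau + n * log_tau + n * log(Z)
  }
  mean_t <- S / n
  opt <- stats::optimize(nll, interval = log(c(mean_t / 100, mean_t * 100)), tol = 1e-12)
  list(tau = exp(opt$minimum), nll = opt$objective)
}

#' Maximum-likelihood fit of the censored dwell-time density
#'
#' Fits the window-censored exponential (`k_components = 1`) or
#' biexponential (`k_components = 2`) density to completed dwell times by
#' unbinned maximum likelihood. The two-component likelihood is multimodal,
#' so optimization runs in unconstrained coordinates (logit amplitude, log
#' time constants with enforced ordering) from `n_starts` stratified random
#' initial values plus one moment-based start; the best optimum is
#' returned. Deterministic given `seed`.
#'
#' @param dwells Numeric vector of dwell durations (s), or a dwell data
#'   frame as produced by [extract_dwells()] / [sample_mixture_dwells()]
#'   (truncated observations are dropped).
#' @param k_components 1 or 2.
#' @param window A [censor_window()]; all dwells must lie inside it.
#' @param n_starts Number of random restarts for the two-component fit.
#' @param seed Optional integer seed (controls the restart draw only).
#' @return An object of class `dwell_fit`: `model` ([exp_mixture_model()]),
#'   `loglik`, `n_dwells`, `boundary` (`TRUE` when the amplitude ran to a
#'   boundary, i.e. no resolvable second component), `bootstrap_sd` and
#'   `n_boot` (filled by [bootstrap_fit()]).
#' @examples
#' d <- sample_mixture_dwells(exp_mixture_model(0.5, 20, 165), 2000, seed = 1)
#' fit_mle(d, 2)
#' @export
fit_mle <- function(dwells, k_components = 2, window = censor_window(),
                    n_starts = 10, seed = NULL) {
  stopifnot(k_components %in% c(1, 2), inherits(window, "censor_window"))
  t <- .fit_durations(dwells)
  if (length(t) < 10) stop("need at least 10 completed dwells")
  if (any(t < window$t_m | t > window$t_max)) {
    stop("all dwells must lie inside [t_m, t_max]")
  }
  if (!is.null(seed)) set.seed(seed)

  if (stats::sd(t) == 0) {
    warning("degenerate fit: all dwells identical; tau set to that value")
    model <- exp_mixture_model(A1 = 1, tau1 = t[1], window = window)
    ll <- sum(censored_pdf(t, model, log = TRUE))
    return(.new_dwell_fit(model, ll, length(t), boundary = TRUE))
  }

  if (k_components == 1) {
    f1 <- .fit1_suffstat(sum(t), length(t), window)
    model <- exp_mixture_model(A1 = 1, tau1 = f1$tau, window = window)
    return(.new_dwell_fit(model, -f1$nll, length(t), boundary = FALSE))
  }

  qs <- stats::quantile(t, c(0.1, 0.5, 0.9), names = FALSE)
  mean_t <- mean(t)
  starts <- list(c(stats::qlogis(0.6), log(qs[1]), log(max(qs[3] - qs[1], mean_t / 4))))
  for (i in seq_len(max(n_starts - 1, 0))) {
    A1 <- stats::runif(1, 0.2, 0.8)
    tau1 <- exp(stats::runif(1, log(max(qs[1] / 2, window$t_m / 2)), log(qs[2])))
    tau2 <- exp(stats::runif(1, log(qs[2]), log(qs[3] * 4)))
    starts[[length(starts) + 1]] <-
      c(stats::qlogis(A1), log(tau1), log(max(tau2 - tau1, tau1 * 0.1)))
  }
  obj <- function(theta) {
    A1 <- stats::plogis(theta[1])
    tau1 <- exp(theta[2])
    tau2 <- tau1 + exp(theta[3])
    v <- .nll_mixture(A1, tau1, tau2, t, window)
    if (!is.finite(v)) 1e10 else v
  }
  best <- NULL
  for (st in starts) {
    opt <- try(stats::optim(st, obj, method = "Nelder-Mead",
                            control = list(maxit = 2000, reltol = 1e-10)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("two-component fit failed from every start")
  A1 <- stats::plogis(best$par[1])
  tau1 <- exp(best$par[2])
  tau2 <- tau1 + exp(best$par[3])
  boundary <- A1 > 0.995 || A1 < 0.005 || tau2 / tau1 < 1.02
  model <- exp_mixture_model(A1 = A1, tau1 = tau1, tau2 = tau2, window = window)
  .new_dwell_fit(model, -best$value, length(t), boundary = boundary)
}

.new_dwell_fit <- function(model, loglik, n_dwells, boundary,
                           bootstrap_sd = NULL, n_boot = 0L) {
  structure(
    list(model = model, loglik = loglik, n_dwells = n_dwells,
         boundary = boundary, bootstrap_sd = bootstrap_sd, n_boot = n_boot),
    class = "dwell_fit"
  )
}

#' @export
print.dwell_fit <- function(x, ...) {
  print(x$model)
  cat(sprintf("  loglik %.2f on %d dwells", x$loglik, x$n_dwells))
  if (x$boundary) cat("  [boundary solution]")
  cat("\n")
  if (!is.null(x$bootstrap_sd)) {
    cat("  bootstrap SD (", x$n_boot, " resamples): ",
        paste(sprintf("%s %.4g", names(x$bootstrap_sd), x$bootstrap_sd),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Bootstrap standard deviations of fitted dwell parameters
#'
#' Case-resampling bootstrap of [fit_mle()]: `n_boot` random samples of the
#' dwells (with replacement, same size) are refit — warm-started from the
#' full-data optimum — and the standard deviation of each parameter over
#' replicates is reported. Replicates whose refit fails are dropped and
#' counted; more than 10% failures is an error.
#'
#' @param dwells Dwell durations (vector or dwell data frame).
#' @param k_components 1 or 2.
#' @param window A [censor_window()].
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Optional integer seed.
#' @param fit Optional full-data `dwell_fit` to reuse (otherwise fit here).
#' @return The `dwell_fit` for the full data with `bootstrap_sd` (named
#'   vector over `A1`, `tau1`, `tau2` as applicable), `n_boot`, and the
#'   replicate estimates in `boot_estimates`.
#' @examples
#' d <- sample_mixture_dwells(exp_mixture_model(1, 30, window = censor_window(5, 1800)), 500, seed = 2)
#' bootstrap_fit(d, 1, n_boot = 100, seed = 3)$bootstrap_sd
#' @export
bootstrap_fit <- function(dwells, k_components = 2, window = censor_window(),
                          n_boot = 1000, seed = NULL, fit = NULL) {
  t <- .fit_durations(dwells)
  if (is.null(fit)) fit <- fit_mle(t, k_components, window, seed = seed)
  if (!is.null(seed)) set.seed(seed)
  n <- length(t)

  if (stats::sd(t) == 0) {
    sd_out <- if (k_components == 1) c(tau1 = 0) else c(A1 = 0, tau1 = 0, tau2 = 0)
    fit$bootstrap_sd <- sd_out
    fit$n_boot <- as.integer(n_boot)
    return(fit)
  }

  if (k_components == 1 || is.null(fit$model$tau2)) {
    est <- matrix(NA_real_, n_boot, 1, dimnames = list(NULL, "tau1"))
    for (b in seq_len(n_boot)) {
      tb <- t[sample.int(n, n, replace = TRUE)]
      est[b, 1] <- .fit1_suffstat(sum(tb), n, window)$tau
    }
  } else {
    m <- fit$model
    theta0 <- c(stats::qlogis(min(max(m$A1, 1e-6), 1 - 1e-6)),
                log(m$tau1), log(max(m$tau2 - m$tau1, m$tau1 * 1e-3)))
    est <- matrix(NA_real_, n_boot, 3, dimnames = list(NULL, c("A1", "tau1", "tau2")))
    for (b in seq_len(n_boot)) {
      tb <- t[sample.int(n, n, replace = TRUE)]
      obj <- function(theta) {
        v <- .nll_mixture(stats::plogis(theta[1]), exp(theta[2]),
                          exp(theta[2]) + exp(theta[3]), tb, window)
        if (!is.finite(v)) 1e10 else v
      }
      opt <- try(stats::optim(theta0, obj, method = "Nelder-Mead",
                              control = list(maxit = 1000, reltol = 1e-9)),
                 silent = TRUE)
      if (inherits(opt, "try-error")) next
      est[b, ] <- c(stats::plogis(opt$par[1]), exp(opt$par[2]),
                    exp(opt$par[2]) + exp(opt$par[3]))
    }
  }
  ok <- stats::complete.cases(est)
  if (mean(!ok) > 0.1) {
    stop("bootstrap: more than 10% of replicate refits failed")
  }
  fit$bootstrap_sd <- apply(est[ok, , drop = FALSE], 2, stats::sd)
  fit$n_boot <- as.integer(sum(ok))
  fit$boot_estimates <- est[ok, , drop = FALSE]
  fit
}

#' Select one vs. two exponential components
#'
#' Likelihood-ratio comparison of the censored one- and two-component fits
#' with a boundary-corrected null: under the one-component truth the extra
#' amplitude sits on the parameter boundary, so the deviance null is
#' approximated by the 50:50 mixture of a point mass at zero and chi-square
#' with 2 degrees of freedom. Two components are selected when p < `alpha`;
#' on a tie (p exactly `alpha`) the simpler model is preferred.
#'
#' @inheritParams fit_mle
#' @param alpha Significance level (default 0.05).
#' @return List with `k_selected`, `p_value`, `deviance`, and both fits
#'   (`fit1`, `fit2`).
#' @export
select_model <- function(dwells, window = censor_window(), alpha = 0.05,
                         n_starts = 10, seed = NULL) {
  fit1 <- fit_mle(dwells, 1, window)
  fit2 <- fit_mle(dwells, 2, window, n_starts = n_starts, seed = seed)
  D <- max(0, 2 * (fit2$loglik - fit1$loglik))
  p <- if (D <= 0) 1 else 0.5 * stats::pchisq(D, df = 2, lower.tail = FALSE)
  list(
    k_selected = if (p < alpha) 2L else 1L,
    p_value = p, deviance = D, fit1 = fit1, fit2 = fit2
  )
}

#' Probability-density dwell histogram with binomial errors
#'
#' Bins dwell times and divides each bin count by the product of the bin
#' width and the total number of events, giving an empirical probability
#' density that overlays the fitted censored densities. Per-bin errors are
#' the counting-statistics error from the variance of a binomial
#' distribution: `sqrt(n_i (1 - n_i/N)) / (N w_i)`.
#'
#' @param dwells Dwell durations (vector or dwell data frame).
#' @param bin_edges Increasing vector of bin edges (s) covering the data.
#' @return Object of class `dwell_histogram`: data frame with `bin_left`,
#'   `bin_right`, `count`, `density`, `error` plus attribute `n_total`.
#' @examples
#' h <- density_histogram(c(2, 3, 7, 12), bin_edges = c(0, 5, 10, 15))
#' sum(h$density * (h$bin_right - h$bin_left)) # 1
#' @export
density_histogram <- function(dwells, bin_edges) {
  t <- .fit_durations(dwells)
  N <- length(t)
  if (N < 1) stop("need at least one dwell")
  if (is.unsorted(bin_edges, strictly = TRUE)) stop("bin_edges must be increasing")
  if (any(t < bin_edges[1] | t > bin_edges[length(bin_edges)])) {
    stop("bins must cover all dwells")
  }
  # [a, b) bins with the top edge closed so the maximum is counted
  idx <- findInterval(t, bin_edges, rightmost.closed = TRUE)
  cnt <- tabulate(idx, nbins = length(bin_edges) - 1)
  w <- diff(bin_edges)
  out <- data.frame(
    bin_left = bin_edges[-length(bin_edges)],
    bin_right = bin_edges[-1],
    count = cnt,
    density = cnt / (N * w),
    error = sqrt(cnt * (1 - cnt / N)) / (N * w)
  )
  structure(out, n_total = N, class = c("dwell_histogram", "data.frame"))
}

#' Mean lifetime with standard error
#'
#' Arithmetic mean of dwell durations with its standard error
#' (sample SD / sqrt(N)); the summary used for conditional-lifetime
#' comparisons.
#'
#' @param dwells Dwell durations (vector or dwell data frame).
#' @return List with `mean`, `se`, `n`.
#' @examples
#' mean_lifetime(c(10, 20, 30)) # 20 +/- 5.77
#' @export
mean_lifetime <- function(dwells) {
  t <- .fit_durations(dwells)
  if (length(t) < 2) stop("need at least two dwells for a standard error")
  list(mean = mean(t), se = stats::sd(t) / sqrt(length(t)), n = length(t))
}

#' Photobleaching extrapolation across laser powers
#'
#' Separates true dissociation from photobleaching by exploiting that the
#' photobleaching hazard scales with excitation power while dissociation
#' does not: the observed rate of each kinetic component,
#' `k_obs = 1/tau`, is regressed linearly on laser power
#' (`k_obs = k_off + c * P`, weighted by inverse bootstrap variances when
#' available) and the zero-power intercept is the bleach-corrected
#' dissociation rate. A component is flagged `minimal_bleaching` when the
#' slope is within two standard errors of zero.
#'
#' @param fits List of `list(power = , fit = )` pairs, where `fit` is a
#'   [fit_mle()] / [bootstrap_fit()] result measured at that laser power;
#'   or a data frame with columns `power`, `component`, `tau` and
#'   optionally `tau_sd`.
#' @return Data frame with one row per component: `component`, `k_off`
#'   (intercept, s^-1), `k_off_se`, `slope`, `slope_se`,
#'   `minimal_bleaching`.
#' @export
photobleach_extrapolate <- function(fits) {
  tab <- if (is.data.frame(fits)) {
    if (!all(c("power", "component", "tau") %in% names(fits))) {
      stop("data frame input needs columns power, component, tau")
    }
    if (!"tau_sd" %in% names(fits)) fits$tau_sd <- NA_real_
    fits
  } else {
    do.call(rbind, lapply(fits, function(pf) {
      m <- pf$fit$model
      sds <- pf$fit$bootstrap_sd
      rows <- data.frame(
        power = pf$power, component = "tau1", tau = m$tau1,
        tau_sd = if (!is.null(sds) && "tau1" %in% names(sds)) sds[["tau1"]] else NA_real_
      )
      if (!is.null(m$tau2)) {
        rows <- rbind(rows, data.frame(
          power = pf$power, component = "tau2", tau = m$tau2,
          tau_sd = if (!is.null(sds) && "tau2" %in% names(sds)) sds[["tau2"]] else NA_real_
        ))
      }
      rows
    }))
  }
  if (length(unique(tab$power)) < 2) stop("need at least two distinct laser powers")

  out <- lapply(split(tab, tab$component), function(d) {
    k_obs <- 1 / d$tau
    sd_k <- d$tau_sd / d$tau^2  # delta method
    w <- if (all(is.finite(sd_k)) && all(sd_k > 0)) 1 / sd_k^2 else NULL
    fit <- stats::lm(k_obs ~ power, data = data.frame(k_obs = k_obs, power = d$power),
                     weights = w)
    # noise-free inputs trigger summary.lm's perfect-fit warning; a zero
    # residual is a valid outcome here (slope SE 0)
    cf <- suppressWarnings(summary(fit)$coefficients)
    slope_se <- if (nrow(cf) > 1 && nrow(d) > 2) cf["power", "Std. Error"] else NA_real_
    data.frame(
      component = d$component[1],
      k_off = cf["(Intercept)", "Estimate"],
      k_off_se = if (nrow(d) > 2) cf["(Intercept)", "Std. Error"] else NA_real_,
      slope = cf["power", "Estimate"],
      slope_se = slope_se,
      minimal_bleaching = is.finite(slope_se) &&
        abs(cf["power", "Estimate"]) <= 2 * slope_se
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
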