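# Independent oracles used across tests: plain-formula implementations kept
# deliberately separate from the package's code paths.

# untruncated CDF of a two-exponential mixture
mixture_cdf <- function(t, A1, tau1, tau2) {
  A1 * (1 - exp(-t / tau1)) + (1 - A1) * (1 - exp(-t / tau2))
}

# truncated-mixture mean on [tm, tmax] by numerical integration of the
# printed density (normalizer written out directly)
truncated_mixture_mean <- function(A1, tau1, tau2, tm, tmax) {
  Z <- A1 * (exp(-tm / tau1) - exp(-tmax / tau1)) +
    (1 - A1) * (exp(-tm / tau2) - exp(-tmax / tau2))
  f <- function(t) {
    (A1 / tau1 * exp(-t / tau1) + (1 - A1) / tau2 * exp(-t / tau2)) / Z
  }
  stats::integrate(function(t) t * f(t), tm, tmax)$value
}

# brute-force best base-pairing register: direct double loop, no tie logic
brute_force_max_pairs <- function(region, u1, wobble = FALSE) {
  tr <- strsplit(region, "")[[1]]
  ur <- rev(strsplit(u1, "")[[1]])
  is_pair <- function(a, b) {
    wc <- (a == "A" & b == "U") | (a == "U" & b == "A") |
      (a == "G" & b == "C") | (a == "C" & b == "G")
    if (wobble) wc | (a == "G" & b == "U") | (a == "U" & b == "G") else wc
  }
  best <- 0L
  for (off in seq(-(length(ur) - 1), length(tr) - 1)) {
    n <- 0L
    for (i in seq_along(tr)) {
      j <- i - off
      if (j >= 1 && j <= length(ur) && is_pair(tr[i], ur[j])) n <- n + 1L
    }
    best <- max(best, n)
  }
  best
}

random_rna <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")

# Welch t-test between conditional classes using per-molecule class means as
# the independent units (dwells of one molecule are not independent)
molecule_level_pvalue <- function(dw) {
  agg <- stats::aggregate(duration_s ~ molecule_id + with_bbp, dw, mean)
  a <- agg$duration_s[agg$with_bbp]
  b <- agg$duration_s[!agg$with_bbp]
  if (length(a) < 5 || length(b) < 5) return(NA_real_)
  stats::t.test(a, b)$p.value
}

# constructed two-channel records where each molecule carries one complex
# whose disassembly route is drawn with known probabilities:
#   p_redef: U1 lost, then a new U1 binds while BBP persists
#   otherwise: U1 lost and BBP is subsequently lost with nothing rebinding
make_fate_records <- function(n, p_redef, seed, record_length = 1800) {
  set.seed(seed)
  rows <- list()
  for (m in seq_len(n)) {
    rows[[length(rows) + 1]] <- data.frame(
      molecule_id = m, channel = c("U1", "BBP"),
      start_s = c(10, 50), end_s = c(100, 400)
    )
    if (stats::runif(1) < p_redef) {
      rows[[length(rows) + 1]] <- data.frame(
        molecule_id = m, channel = "U1", start_s = 150, end_s = 300
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "record_length") <- record_length
  out
}
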