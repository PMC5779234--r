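#' Reference sequences for 5' splice-site / U1 snRNA pairing
#'
#' Small built-in RNA sequences used by the base-pairing worked examples.
#'
#' `u1_snrna_5prime()` is the 5'-terminal region of the yeast U1 snRNA that
#' base-pairs with the 5' splice site (the region targeted by RNase H
#' ablation with a complementary DNA oligo); the first `n` nucleotides are
#' returned, default 10 (5'-AUACUUACCU-3').
#'
#' `consensus_5ss_region()` is the yeast consensus 5' splice-site region of
#' the RP51A reporter: the terminal exonic G followed by the intronic
#' GU AUGU hexamer ("G/GUAUGU"), which forms 6 Watson-Crick pairs with the
#' U1 5' end. `weak_5ss_region()` is the SUS1 weak 5' splice-site hexamer
#' (GUAUGA, 4 pairs). `hyperstabilized_5ss_region()` is a 5' splice site
#' designed fully complementary to the first 10 nt of the U1 5' end
#' (10 pairs).
#'
#' @param n Number of 5'-terminal U1 nucleotides (default 10).
#' @return RNA string.
#' @name reference_sequences
NULL

#' @rdname reference_sequences
#' @export
u1_snrna_5prime <- function(n = 10) {
  seq <- "AUACUUACCU"
  if (n < 1 || n > nchar(seq)) stop("n must be between 1 and ", nchar(seq))
  substr(seq, 1, n)
}

#' @rdname reference_sequences
#' @export
consensus_5ss_region <- function() "GGUAUGU"

#' @rdname reference_sequences
#' @export
weak_5ss_region <- function() "GUAUGA"

#' @rdname reference_sequences
#' @export
hyperstabilized_5ss_region <- function() revcomp_rna(u1_snrna_5prime(10))

#' Reverse complement of an RNA string
#' @param x RNA string over A, C, G, U.
#' @return Reverse-complemented RNA string.
#' @export
revcomp_rna <- function(x) {
  .check_rna(x)
  paste(rev(strsplit(chartr("ACGU", "UGCA", x), "")[[1]]), collapse = "")
}

.check_rna <- function(x) {
  if (!is.character(x) || length(x) != 1 || nchar(x) == 0) {
    stop("sequence must be a single non-empty string")
  }
  if (grepl("[^ACGU]", x)) stop("invalid characters: RNA alphabet is A, C, G, U")
  invisible(x)
}

#' Count base pairs between a 5' splice-site region and the U1 snRNA 5' end
#'
#' Evaluates every ungapped antiparallel register of the transcript region
#' against the snRNA 5' end and returns the register maximizing the number
#' of paired positions (Watson-Crick A:U and G:C; G:U wobble counted only
#' when `count_wobble = TRUE`). Internal mismatches within the register are
#' allowed. Ties between registers are broken toward fewer internal
#' mismatches, then the smaller offset.
#'
#' @param transcript_region RNA string (5'->3'), the 5' splice-site region
#'   including any exonic positions adjacent to the splice site.
#' @param u1_5prime RNA string (5'->3'), the snRNA 5'-end region; default
#'   [u1_snrna_5prime()].
#' @param count_wobble Count G:U wobble pairs as paired (default `FALSE`:
#'   counts are of potential Watson-Crick pairs against the snRNA).
#' @return Object of class `pairing_result`: `n_pairs`, `register_offset`
#'   (transcript position, 1-based, aligned with the snRNA 3'-most
#'   nucleotide minus 1), `n_mismatches` (internal mismatches inside the
#'   paired span) and `pair_map`, a data frame with one row per aligned
#'   position (`transcript_pos`, `snrna_pos`, `transcript_base`,
#'   `snrna_base`, `pair` in `WC`/`GU-wobble`/`mismatch`).
#' @examples
#' count_basepairs(consensus_5ss_region())$n_pairs        # 6
#' count_basepairs(hyperstabilized_5ss_region())$n_pairs  # 10
#' @export
count_basepairs <- function(transcript_region, u1_5prime = u1_snrna_5prime(),
                            count_wobble = FALSE) {
  .check_rna(transcript_region)
  .check_rna(u1_5prime)
  tr <- strsplit(transcript_region, "")[[1]]
  u1 <- strsplit(u1_5prime, "")[[1]]
  nu <- length(u1)
  nt <- length(tr)
  # antiparallel: transcript 5'->3' against the snRNA 3'->5'
  u1r <- rev(u1)
  u1r_pos <- rev(seq_len(nu))  # original snRNA coordinates of u1r

  classify <- function(a, b) {
    if ((a == "A" && b == "U") || (a == "U" && b == "A") ||
        (a == "G" && b == "C") || (a == "C" && b == "G")) "WC"
    else if ((a == "G" && b == "U") || (a == "U" && b == "G")) "GU-wobble"
    else "mismatch"
  }

  best <- NULL
  for (off in seq(-(nu - 1), nt - 1)) {
    idx_t <- seq_len(nt)
    idx_u <- idx_t - off
    keep <- idx_u >= 1 & idx_u <= nu
    if (!any(keep)) next
    it <- idx_t[keep]; iu <- idx_u[keep]
    cls <- vapply(seq_along(it), function(k) classify(tr[it[k]], u1r[iu[k]]), "")
    paired <- cls == "WC" | (count_wobble & cls == "GU-wobble")
    n_pairs <- sum(paired)
    if (n_pairs == 0) next
    span <- range(which(paired))
    n_mm <- sum(!paired[span[1]:span[2]])
    cand <- list(
      n_pairs = n_pairs, n_mismatches = n_mm, offset = off,
      map = data.frame(
        transcript_pos = it,
        snrna_pos = u1r_pos[iu],
        transcript_base = tr[it],
        snrna_base = u1r[iu],
        pair = cls,
        stringsAsFactors = FALSE
      )
    )
    if (is.null(best) ||
        cand$n_pairs > best$n_pairs ||
        (cand$n_pairs == best$n_pairs && cand$n_mismatches < best$n_mismatches) ||
        (cand$n_pairs == best$n_pairs && cand$n_mismatches == best$n_mismatches &&
         cand$offset < best$offset)) {
      best <- cand
    }
  }
  if (is.null(best)) {
    best <- list(
      n_pairs = 0L, n_mismatches = 0L, offset = NA_integer_,
      map = data.frame(
        transcript_pos = integer(0), snrna_pos = integer(0),
        transcript_base = character(0), snrna_base = character(0),
        pair = character(0), stringsAsFactors = FALSE
      )
    )
  }
  structure(
    list(
      n_pairs = as.integer(best$n_pairs),
      register_offset = best$offset,
      n_mismatches = as.integer(best$n_mismatches),
      pair_map = best$map,
      transcript_region = transcript_region,
      u1_5prime = u1_5prime,
      count_wobble = count_wobble
    ),
    class = "pairing_result"
  )
}

#' @export
print.pairing_result <- function(x, ...) {
  cat(sprintf(
    "Base-pairing: %d pairs (%s wobble), offset %s, %d internal mismatch(es)\n",
    x$n_pairs, if (x$count_wobble) "with" else "without",
    as.character(x$register_offset), x$n_mismatches
  ))
  invisible(x)
}

#' Convert a dwell time constant to a rate constant
#'
#' Reciprocal of a fitted time constant, in s^-1 or min^-1. The companion
#' helper [round_rate()] rounds to one significant figure for headline
#' reporting (e.g. a 165 s time constant is a dissociation rate of
#' ~0.4 min^-1).
#'
#' @param tau Time constant (s), > 0.
#' @param out_unit `"per_second"` or `"per_minute"`.
#' @return Rate constant in the requested unit.
#' @examples
#' tau_to_rate(60, "per_minute")             # 1
#' round_rate(tau_to_rate(165, "per_minute")) # 0.4
#' @export
tau_to_rate <- function(tau, out_unit = c("per_second", "per_minute")) {
  out_unit <- match.arg(out_unit)
  if (!is.numeric(tau) || any(tau <= 0)) stop("tau must be positive")
  switch(out_unit, per_second = 1 / tau, per_minute = 60 / tau)
}

#' @rdname tau_to_rate
#' @param x Rate to round.
#' @export
round_rate <- function(x) signif(x, 1)
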