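#' Least-squares affine registration between two fields of view
#'
#' Fits the 2-D affine map (2x2 linear part plus offset) carrying matched
#' fiducial positions (e.g. multi-wavelength beads) from one camera field
#' of view onto the other, by ordinary least squares.
#'
#' @param src,dst Two-column matrices or data frames of matched (x, y)
#'   positions (pixels); at least 3 non-collinear pairs.
#' @return Object of class `affine_map2d` with `linear` (2x2), `offset`
#'   (length 2) and `rms_residual` (pixels).
#' @examples
#' pts <- cbind(c(0, 1, 0, 5), c(0, 0, 1, 3))
#' fit_affine(pts, pts + rep(c(2.5, -1), each = 4))$offset
#' @export
fit_affine <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (ncol(src) != 2 || ncol(dst) != 2 || nrow(src) != nrow(dst)) {
    stop("src and dst must be matched two-column point sets")
  }
  if (nrow(src) < 3) stop("need at least 3 point pairs")
  X <- cbind(1, src)
  if (qr(X)$rank < 3) stop("points are collinear; affine map is underdetermined")
  beta <- qr.solve(X, dst)  # rows: intercept, x, y; cols: x', y'
  pred <- X %*% beta
  rms <- sqrt(mean(rowSums((dst - pred)^2)))
  structure(
    list(linear = t(beta[2:3, , drop = FALSE]), offset = as.numeric(beta[1, ]),
         rms_residual = rms),
    class = "affine_map2d"
  )
}

#' Apply an affine field-of-view map to points
#' @param map An `affine_map2d` from [fit_affine()].
#' @param pts Two-column matrix of (x, y) positions.
#' @return Mapped positions, same shape.
#' @export
apply_affine <- function(map, pts) {
  pts <- as.matrix(pts)
  t(map$linear %*% t(pts) + map$offset)
}

#' @export
print.affine_map2d <- function(x, ...) {
  cat("Affine FOV map: offset (", paste(signif(x$offset, 6), collapse = ", "),
      "), RMS residual ", signif(x$rms_residual, 4), " px\n", sep = "")
  invisible(x)
}

.record_length_of <- function(records, record_length) {
  if (!is.null(record_length)) return(record_length)
  rl <- attr(records, "record_length")
  if (is.null(rl)) stop("supply record_length or a records table carrying it as an attribute")
  rl
}

.check_records <- function(records) {
  stopifnot(all(c("molecule_id", "channel", "start_s", "end_s") %in% names(records)))
  if (nrow(records) && !all(records$channel %in% c("U1", "BBP"))) {
    stop("channel must be 'U1' or 'BBP'")
  }
  invisible(records)
}

#' Detect colocalized U1/BBP complexes
#'
#' Finds the maximal overlaps between U1 and BBP bound intervals on each
#' molecule — the colocalized (E-complex) episodes — and labels how each was
#' entered and how it ended. Boundary comparisons use frame resolution:
#' arrivals within one frame interval of each other count as simultaneous;
#' exact ties in departure are attributed to U1 loss (deterministic
#' tie-break).
#'
#' @param records Tidy interval table (`molecule_id`, `channel` in
#'   `"U1"`/`"BBP"`, `start_s`, `end_s`), e.g. from
#'   [simulate_two_channel()].
#' @param tolerance_frames Number of frame intervals by which each interval
#'   is symmetrically expanded before overlap detection (default 0); after
#'   expansion, overlapping episodes are merged into maximal complexes.
#' @param frame_s Frame interval (s) defining temporal resolution.
#' @param record_length Record length (s); defaults to the table's
#'   `record_length` attribute.
#' @return Data frame of complexes: `molecule_id`, `start_s`, `end_s`,
#'   `entered_by` (`"U1-first"`, `"BBP-first"`, `"simultaneous"`),
#'   `exit_event` (`"U1-loss"`, `"BBP-loss"`, `"record-end"`), and the end
#'   times of the participating intervals (`u1_end_s`, `bbp_end_s`).
#' @examples
#' rec <- data.frame(
#'   molecule_id = 1, channel = c("U1", "BBP"),
#'   start_s = c(0, 50), end_s = c(100, 150)
#' )
#' find_coloc(rec, record_length = 1800)
#' @export
find_coloc <- function(records, tolerance_frames = 0, frame_s = 5,
                       record_length = NULL) {
  .check_records(records)
  record_length <- .record_length_of(records, record_length)
  tol <- tolerance_frames * frame_s
  rows <- list()
  for (mid in unique(records$molecule_id)) {
    mol <- records[records$molecule_id == mid, , drop = FALSE]
    u <- mol[mol$channel == "U1", , drop = FALSE]
    b <- mol[mol$channel == "BBP", , drop = FALSE]
    if (nrow(u) == 0 || nrow(b) == 0) next
    cand <- list()
    for (i in seq_len(nrow(u))) {
      for (j in seq_len(nrow(b))) {
        s <- max(u$start_s[i] - tol, b$start_s[j] - tol, 0)
        e <- min(u$end_s[i] + tol, b$end_s[j] + tol, record_length)
        if (e <= s) next
        cand[[length(cand) + 1]] <- list(
          start = s, end = e,
          u_start = u$start_s[i], u_end = u$end_s[i],
          b_start = b$start_s[j], b_end = b$end_s[j]
        )
      }
    }
    if (length(cand) == 0) next
    ord <- order(vapply(cand, `[[`, 0, "start"))
    cand <- cand[ord]
    merged <- list(cand[[1]])
    if (length(cand) > 1) {
      for (k in 2:length(cand)) {
        last <- merged[[length(merged)]]
        cur <- cand[[k]]
        if (cur$start < last$end) {
          # maximal complex: extend; entry labels come from the earliest
          # pair, exit labels from the latest
          last$end <- max(last$end, cur$end)
          last$u_end <- max(last$u_end, cur$u_end)
          last$b_end <- max(last$b_end, cur$b_end)
          merged[[length(merged)]] <- last
        } else {
          merged[[length(merged) + 1]] <- cur
        }
      }
    }
    for (cx in merged) {
      entered <- if (abs(cx$u_start - cx$b_start) <= frame_s) "simultaneous"
      else if (cx$u_start < cx$b_start) "U1-first" else "BBP-first"
      exit <- if (cx$end >= record_length - 1e-9) "record-end"
      else if (cx$u_end <= cx$b_end) "U1-loss" else "BBP-loss"
      rows[[length(rows) + 1]] <- data.frame(
        molecule_id = mid, start_s = cx$start, end_s = cx$end,
        entered_by = entered, exit_event = exit,
        u1_end_s = cx$u_end, bbp_end_s = cx$b_end,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    molecule_id = integer(0), start_s = numeric(0), end_s = numeric(0),
    entered_by = character(0), exit_event = character(0),
    u1_end_s = numeric(0), bbp_end_s = numeric(0), stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "record_length") <- record_length
  out
}

#' Partition U1 dwells by BBP colocalization
#'
#' Splits all completed U1 dwells (those not in contact with the record
#' boundaries) into those that overlap a BBP bound interval at any point
#' during the dwell and those that never do — the conditional-lifetime
#' comparison testing whether BBP occupancy stabilizes U1.
#'
#' @inheritParams find_coloc
#' @return Data frame with `molecule_id`, `start_s`, `duration_s`,
#'   `with_bbp` (logical); summarize each class with [mean_lifetime()].
#' @export
conditional_dwells <- function(records, record_length = NULL) {
  .check_records(records)
  record_length <- .record_length_of(records, record_length)
  rows <- list()
  for (mid in unique(records$molecule_id)) {
    mol <- records[records$molecule_id == mid, , drop = FALSE]
    u <- mol[mol$channel == "U1", , drop = FALSE]
    b <- mol[mol$channel == "BBP", , drop = FALSE]
    if (nrow(u) == 0) next
    complete <- u$start_s > 0 & u$end_s < record_length
    u <- u[complete, , drop = FALSE]
    if (nrow(u) == 0) next
    with_bbp <- vapply(seq_len(nrow(u)), function(i) {
      nrow(b) > 0 && any(b$start_s < u$end_s[i] & b$end_s > u$start_s[i])
    }, logical(1))
    rows[[length(rows) + 1]] <- data.frame(
      molecule_id = mid, start_s = u$start_s,
      duration_s = u$end_s - u$start_s, with_bbp = with_bbp
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    molecule_id = integer(0), start_s = numeric(0),
    duration_s = numeric(0), with_bbp = logical(0)
  )
  rownames(out) <- NULL
  out
}

#' Randomized-control conditional analysis
#'
#' Destroys any true U1/BBP coupling by reassigning each molecule's BBP
#' channel to a different molecule's U1 channel (a random derangement: no
#' molecule keeps its own partner), then reruns [conditional_dwells()]. In
#' the presence of genuine coupling the conditional-lifetime difference
#' vanishes under this control.
#'
#' @inheritParams find_coloc
#' @param seed Optional integer seed for the derangement.
#' @return List with `dwells` (as [conditional_dwells()]), `permutation`
#'   (named vector: BBP of molecule i assigned to U1 of `permutation[i]`),
#'   and the permuted `records`.
#' @export
randomized_control <- function(records, seed = NULL, record_length = NULL) {
  .check_records(records)
  record_length <- .record_length_of(records, record_length)
  if (!is.null(seed)) set.seed(seed)
  ids <- sort(unique(records$molecule_id))
  if (length(ids) < 2) stop("need at least two molecules to randomize pairings")
  repeat {
    perm <- sample(ids)
    if (!any(perm == ids)) break
  }
  names(perm) <- as.character(ids)
  permuted <- records
  is_bbp <- permuted$channel == "BBP"
  permuted$molecule_id[is_bbp] <- perm[as.character(permuted$molecule_id[is_bbp])]
  attr(permuted, "record_length") <- record_length
  list(
    dwells = conditional_dwells(permuted, record_length = record_length),
    permutation = perm,
    records = permuted
  )
}

.fate_routes <- c(
  "U1-lost_then_BBP-lost", "U1-lost_then_new-U1",
  "BBP-lost_then_U1-lost", "BBP-lost_then_new-BBP", "censored"
)

#' Classify E-complex disassembly fates
#'
#' For every colocalized complex, identifies which channel's fluorophore
#' was lost first at the complex end, then scans forward: if the lost
#' component rebinds while the partner is still present the splice site (or
#' branchsite) was redefined; if the partner is lost first the complex
#' decayed by double loss; complexes ongoing at the record end are
#' censored. The lookahead extends to the record end.
#'
#' @inheritParams find_coloc
#' @param initial_only If `TRUE` (default), only each molecule's first
#'   (initial) colocalized complex is classified, matching the convention
#'   of reporting fates of initial complexes; `FALSE` classifies every
#'   complex.
#' @return Object of class `fate_tally`: data frame with `route`, `count`,
#'   `fraction`, `error` (binomial counting error of each fraction,
#'   `sqrt(n_i (1 - n_i/N)) / N`), with attribute `n_total`. Routes:
#'   `U1-lost_then_BBP-lost`, `U1-lost_then_new-U1` (5'SS redefinition),
#'   `BBP-lost_then_U1-lost`, `BBP-lost_then_new-BBP` (BS redefinition),
#'   `censored`.
#' @export
classify_fates <- function(records, tolerance_frames = 0, frame_s = 5,
                           record_length = NULL, initial_only = TRUE) {
  .check_records(records)
  record_length <- .record_length_of(records, record_length)
  cx <- find_coloc(records, tolerance_frames, frame_s, record_length)
  if (initial_only && nrow(cx) > 1) {
    cx <- cx[!duplicated(cx$molecule_id), , drop = FALSE]
  }
  routes <- character(nrow(cx))
  for (i in seq_len(nrow(cx))) {
    if (cx$exit_event[i] == "record-end") {
      routes[i] <- "censored"
      next
    }
    lost <- if (cx$exit_event[i] == "U1-loss") "U1" else "BBP"
    partner_end <- if (lost == "U1") cx$bbp_end_s[i] else cx$u1_end_s[i]
    t_loss <- cx$end_s[i]
    mol <- records[records$molecule_id == cx$molecule_id[i] &
                     records$channel == lost, , drop = FALSE]
    rebind <- any(mol$start_s >= t_loss - 1e-9 & mol$start_s < partner_end)
    routes[i] <- if (lost == "U1") {
      if (rebind) "U1-lost_then_new-U1" else "U1-lost_then_BBP-lost"
    } else {
      if (rebind) "BBP-lost_then_new-BBP" else "BBP-lost_then_U1-lost"
    }
  }
  counts <- vapply(.fate_routes, function(r) sum(routes == r), integer(1))
  N <- length(routes)
  frac <- if (N > 0) counts / N else rep(NA_real_, length(counts))
  err <- if (N > 0) sqrt(counts * (1 - counts / N)) / N else rep(NA_real_, length(counts))
  out <- data.frame(
    route = .fate_routes, count = as.integer(counts),
    fraction = frac, error = err, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, n_total = N, class = c("fate_tally", "data.frame"))
}

#' @export
print.fate_tally <- function(x, ...) {
  cat("E-complex fates (N =", attr(x, "n_total"), "complexes)\n")
  print.data.frame(cbind(
    x["route"], count = x$count,
    percent = sprintf("%.1f +/- %.1f", 100 * x$fraction, 100 * x$error)
  ), row.names = FALSE)
  invisible(x)
}

#' Tally E-complex assembly order
#'
#' Counts, over all colocalized complexes, whether U1 or BBP arrived first
#' (or both within one frame), with binomial counting errors — the check
#' that E-complex assembly can proceed through either initial binder.
#'
#' @inheritParams find_coloc
#' @param initial_only If `TRUE`, tally only each molecule's first complex
#'   (the arrival race from the empty state); default `FALSE` tallies all.
#' @return Data frame with `entered_by`, `count`, `fraction`, `error`, and
#'   attribute `n_total`.
#' @export
assembly_order <- function(records, tolerance_frames = 0, frame_s = 5,
                           record_length = NULL, initial_only = FALSE) {
  cx <- find_coloc(records, tolerance_frames, frame_s, record_length)
  if (initial_only && nrow(cx) > 1) {
    cx <- cx[!duplicated(cx$molecule_id), , drop = FALSE]
  }
  lev <- c("U1-first", "BBP-first", "simultaneous")
  counts <- vapply(lev, function(l) sum(cx$entered_by == l), integer(1))
  N <- nrow(cx)
  out <- data.frame(
    entered_by = lev, count = as.integer(counts),
    fraction = if (N > 0) counts / N else NA_real_,
    error = if (N > 0) sqrt(counts * (1 - counts / N)) / N else NA_real_,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_total") <- N
  out
}
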