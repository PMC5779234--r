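#' Rastergram of per-molecule binding timelines
#'
#' Stacked time ribbons: one row per molecule with bound intervals drawn as
#' colored bands (U1 red, BBP green by the usual CoSMoS figure convention)
#' and, for two-channel input, the U1/BBP overlap — the colocalized
#' complex — as a third (blue) band on top. Ordering and colors are
#' deterministic so rendered figures are reproducible.
#'
#' @param records Tidy interval table (`molecule_id`, `channel`, `start_s`,
#'   `end_s`); a single-channel table may omit `channel`.
#' @param record_length Record length (s); defaults to the table's
#'   attribute.
#' @param order Row ordering: by `"molecule"` id (default) or by
#'   `"first_event"` time.
#' @param colors Named fill colors for `U1`, `BBP`, `overlap`.
#' @return A ggplot object.
#' @export
render_rastergram <- function(records, record_length = NULL,
                              order = c("molecule", "first_event"),
                              colors = c(U1 = "#d62728", BBP = "#2ca02c",
                                         overlap = "#1f77b4")) {
  order <- match.arg(order)
  if (!"channel" %in% names(records)) records$channel <- "U1"
  if (nrow(records) == 0) {
    warning("no intervals to draw; returning an empty canvas")
    return(ggplot2::ggplot() + ggplot2::theme_void())
  }
  record_length <- .record_length_of(records, record_length)

  ids <- unique(records$molecule_id)
  if (order == "first_event") {
    first_ev <- vapply(ids, function(i) {
      min(records$start_s[records$molecule_id == i])
    }, numeric(1))
    ids <- ids[order(first_ev)]
  } else {
    ids <- sort(ids)
  }
  row_of <- stats::setNames(seq_along(ids), as.character(ids))

  bands <- records[c("molecule_id", "channel", "start_s", "end_s")]
  # overlap bands for two-channel input
  if (all(c("U1", "BBP") %in% records$channel)) {
    cx <- find_coloc(records, record_length = record_length)
    if (nrow(cx) > 0) {
      bands <- rbind(bands, data.frame(
        molecule_id = cx$molecule_id, channel = "overlap",
        start_s = cx$start_s, end_s = cx$end_s
      ))
    }
  }
  bands$row <- row_of[as.character(bands$molecule_id)]
  bands$channel <- factor(bands$channel, levels = c("U1", "BBP", "overlap"))
  bands <- bands[order(bands$channel, bands$molecule_id, bands$start_s), ]

  ggplot2::ggplot(bands) +
    ggplot2::geom_rect(
      ggplot2::aes(
        xmin = start_s, xmax = end_s,
        ymin = row - 0.42, ymax = row + 0.42,
        fill = channel
      )
    ) +
    ggplot2::scale_fill_manual(values = colors, drop = FALSE) +
    ggplot2::scale_x_continuous(limits = c(0, record_length), expand = c(0, 0)) +
    ggplot2::scale_y_reverse(
      breaks = seq_along(ids), labels = as.character(ids),
      expand = ggplot2::expansion(add = 0.6)
    ) +
    ggplot2::labs(x = "time (s)", y = "molecule", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Relative binding-event frequencies across conditions
#'
#' Compares the number of binding events observed per molecule per unit
#' time across experimental conditions, normalized to a reference
#' condition, with binomial counting errors on each ratio (the two
#' conditions' event counts are treated as a binomial split of their
#' total; the error is propagated to the ratio by the delta method).
#'
#' @param counts Data frame with columns `condition`, `n_events`,
#'   `n_molecules`, `record_length_s`; or a named list of interval tables
#'   (each carrying `record_length` and `n_molecules` attributes) whose U1
#'   events are counted.
#' @param reference Condition used as denominator (default the first).
#' @return Data frame with `condition`, `n_events`, `rate` (events per
#'   molecule per second), `relative`, `error`; conditions with zero
#'   molecules are excluded with a warning.
#' @export
summarize_counts <- function(counts, reference = NULL) {
  if (is.list(counts) && !is.data.frame(counts)) {
    counts <- do.call(rbind, lapply(names(counts), function(nm) {
      rec <- counts[[nm]]
      data.frame(
        condition = nm,
        n_events = sum(rec$channel %in% "U1"),
        n_molecules = attr(rec, "n_molecules") %||% length(unique(rec$molecule_id)),
        record_length_s = .record_length_of(rec, NULL)
      )
    }))
  }
  stopifnot(all(c("condition", "n_events", "n_molecules", "record_length_s") %in% names(counts)))
  if (nrow(counts) < 1) stop("need at least one condition")
  empty <- counts$n_molecules == 0
  if (any(empty)) {
    warning("excluding condition(s) with zero molecules: ",
            paste(counts$condition[empty], collapse = ", "))
    counts <- counts[!empty, , drop = FALSE]
  }
  if (is.null(reference)) reference <- counts$condition[1]
  if (!reference %in% counts$condition) stop("reference condition not found")
  ref <- counts[counts$condition == reference, ][1, ]

  rate <- counts$n_events / (counts$n_molecules * counts$record_length_s)
  rate_ref <- ref$n_events / (ref$n_molecules * ref$record_length_s)
  norm <- (ref$n_molecules * ref$record_length_s) /
    (counts$n_molecules * counts$record_length_s)
  rel <- rate / rate_ref
  err <- vapply(seq_len(nrow(counts)), function(i) {
    n_i <- counts$n_events[i]; n_r <- ref$n_events
    tot <- n_i + n_r
    if (tot == 0) return(NA_real_)
    p <- n_i / tot
    sd_p <- sqrt(p * (1 - p) / tot)
    # ratio = norm * p/(1-p); delta method in p
    norm[i] * sd_p / (1 - p)^2
  }, numeric(1))
  out <- data.frame(
    condition = counts$condition, n_events = counts$n_events,
    rate = rate, relative = rel, error = err, stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
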