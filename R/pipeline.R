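#' Read and write the package's tidy tables
#'
#' Plain TSV readers/writers for the interval, per-frame trace and dwell
#' tables exchanged between pipeline stages. Interval tables carry the
#' record length in a `# record_length: <s>` header comment so round trips
#' preserve it.
#'
#' @param x Table to write.
#' @param path File path.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_intervals_tsv <- function(x, path) {
  rl <- attr(x, "record_length")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(rl)) writeLines(paste0("# record_length: ", format(rl, digits = 15)), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname table_io
#' @export
read_intervals_tsv <- function(path) {
  first <- readLines(path, n = 1)
  rl <- NULL
  if (startsWith(first, "# record_length:")) {
    rl <- as.numeric(sub("# record_length:", "", first))
  }
  out <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!is.null(rl)) attr(out, "record_length") <- rl
  out
}

#' @rdname table_io
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname table_io
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

.scheme_from_config <- function(cfg) {
  type <- cfg$type %||% "one_step"
  switch(
    type,
    one_step = one_step_scheme(cfg$k_on, cfg$k_off),
    two_step = two_step_scheme(cfg$k_on, cfg$k_off1, cfg$k12, cfg$k_off2,
                               k21 = cfg$k21 %||% 0),
    independent = independent_pathway_scheme(cfg$k_on_a, cfg$k_off_a,
                                             cfg$k_on_b, cfg$k_off_b),
    stop("unknown scheme type '", type, "'")
  )
}

.schedule_from_config <- function(cfg) {
  if (is.null(cfg)) return(frame_schedule())
  frame_schedule(
    exposure = cfg$exposure %||% 1,
    interval = cfg$interval %||% 5,
    n_frames = cfg$n_frames %||% 360
  )
}

.run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the simulate / extract / fit / coloc / report pipeline from a config
#'
#' Executes the selected stages of the analysis end to end, writing every
#' intermediate table as TSV/JSON under the configured output directory
#' together with a manifest (parameters, seeds, package version, outputs)
#' that allows bit-exact re-runs: the same config and seed reproduce every
#' tabular output byte-identically.
#'
#' The config is a YAML or JSON file (or an equivalent nested list) with
#' top-level fields `seed`, `out_dir`, `stages` (subset of `simulate`,
#' `extract`, `fit`, `coloc`, `report`), and one block per stage:
#' \describe{
#'   \item{simulate}{`n_molecules`, `schedule` (`exposure`, `interval`,
#'     `n_frames`), either `u1_scheme`/`bbp_scheme` (+
#'     `stabilization_factor`) for a two-channel run or `scheme` for a
#'     single channel; scheme blocks have `type` (`one_step`, `two_step`,
#'     `independent`) and rates. Optional `bleach_rate`, `background_rate`,
#'     `noise_sd` for frame sampling.}
#'   \item{extract}{`threshold`, `gap_merge`.}
#'   \item{fit}{`components` (1, 2 or `"auto"`), `t_min`, `t_max`,
#'     `n_boot`, `channel`.}
#'   \item{coloc}{`tolerance_frames`.}
#'   \item{report}{`rastergram_molecules` (rows drawn; 30 by default).}
#' }
#'
#' @param config Path to a YAML/JSON config file, or the equivalent list.
#' @param out_dir Output directory (overrides the config's `out_dir`).
#' @return Invisibly, the manifest list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  out_dir <- out_dir %||% config$out_dir %||% stop("config must name an out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  stages <- config$stages %||% c("simulate", "extract", "fit", "coloc", "report")
  schedule <- .schedule_from_config(config$simulate$schedule)

  manifest <- list(
    package = "smdwell",
    version = as.character(utils::packageVersion("smdwell")),
    seed = seed, stages = stages, config = config, outputs = list()
  )
  add_output <- function(stage, path) {
    manifest$outputs[[stage]] <<- c(manifest$outputs[[stage]], basename(path))
    path
  }
  intervals <- NULL
  traces <- NULL
  dwells <- NULL

  if ("simulate" %in% stages) {
    .run_stage("simulate", {
      sim <- config$simulate %||% stop("missing 'simulate' block")
      n_mol <- sim$n_molecules %||% 100
      if (!is.null(sim$u1_scheme)) {
        cp <- coupling_spec(
          u1_scheme = .scheme_from_config(sim$u1_scheme),
          bbp_scheme = .scheme_from_config(sim$bbp_scheme %||% stop("missing bbp_scheme")),
          stabilization_factor = sim$stabilization_factor %||% 1,
          transition_multiplier = sim$transition_multiplier %||% 1
        )
        intervals <- simulate_two_channel(
          cp, n_mol, schedule, seed = seed,
          start_at_equilibrium = isTRUE(sim$start_at_equilibrium)
        )
      } else {
        sc <- .scheme_from_config(sim$scheme %||% stop("missing 'scheme'"))
        set.seed(seed)
        per_mol <- lapply(seq_len(n_mol), function(m) {
          iv <- simulate_timeline(sc, schedule)
          if (nrow(iv) == 0) return(NULL)
          cbind(molecule_id = m, channel = "U1", iv)
        })
        intervals <- do.call(rbind, Filter(Negate(is.null), per_mol)) %||%
          data.frame(molecule_id = integer(0), channel = character(0),
                     start_s = numeric(0), end_s = numeric(0))
        attr(intervals, "record_length") <- schedule$record_length
        attr(intervals, "n_molecules") <- n_mol
      }
      write_intervals_tsv(intervals, add_output("simulate", file.path(out_dir, "intervals.tsv")))

      set.seed(seed + 1L)
      tr <- list()
      for (mid in unique(intervals$molecule_id)) {
        for (ch in unique(intervals$channel[intervals$molecule_id == mid])) {
          iv <- intervals[intervals$molecule_id == mid & intervals$channel == ch, ]
          fr <- frame_sample(iv, schedule,
                             bleach_rate = sim$bleach_rate %||% 0,
                             background_rate = sim$background_rate %||% 0,
                             noise_sd = sim$noise_sd %||% 0)
          tr[[length(tr) + 1]] <- cbind(molecule_id = mid, channel = ch, fr)
        }
      }
      traces <- do.call(rbind, tr)
      write_tsv_table(traces, add_output("simulate", file.path(out_dir, "traces.tsv")))
    })
  }

  if ("extract" %in% stages) {
    .run_stage("extract", {
      if (is.null(traces)) {
        p <- file.path(out_dir, "traces.tsv")
        if (!file.exists(p)) stop("no trace table available (run 'simulate' or provide traces.tsv)")
        traces <- read_tsv_table(p)
      }
      ex <- config$extract %||% list()
      dw <- list()
      key <- interaction(traces$molecule_id, traces$channel, drop = TRUE)
      for (grp in split(traces, key)) {
        iv <- binarize_trace(grp$intensity, schedule,
                             threshold = ex$threshold %||% 0.5,
                             gap_merge = ex$gap_merge %||% 0)
        if (nrow(iv) == 0) next
        iv$molecule_id <- grp$molecule_id[1]
        iv$channel <- grp$channel[1]
        dw[[length(dw) + 1]] <- extract_dwells(iv, schedule)
      }
      dwells <- do.call(rbind, dw) %||% data.frame(
        molecule_id = integer(0), channel = character(0), start_s = numeric(0),
        duration_s = numeric(0), left_truncated = logical(0),
        right_truncated = logical(0)
      )
      write_tsv_table(dwells, add_output("extract", file.path(out_dir, "dwells.tsv")))
    })
  }

  if ("fit" %in% stages) {
    .run_stage("fit", {
      if (is.null(dwells)) {
        p <- file.path(out_dir, "dwells.tsv")
        if (!file.exists(p)) stop("no dwell table available (run 'extract' or provide dwells.tsv)")
        dwells <- read_tsv_table(p)
      }
      ft <- config$fit %||% list()
      ch <- ft$channel %||% "U1"
      d <- dwells[dwells$channel == ch, , drop = FALSE]
      window <- censor_window(ft$t_min %||% schedule$interval,
                              ft$t_max %||% schedule$record_length)
      comp <- ft$components %||% "auto"
      report <- if (identical(comp, "auto")) {
        sel <- select_model(d, window, seed = seed + 2L)
        fit <- if (sel$k_selected == 2) sel$fit2 else sel$fit1
        list(selection = list(k_selected = sel$k_selected,
                              p_value = sel$p_value, deviance = sel$deviance),
             fit = fit)
      } else {
        list(selection = NULL,
             fit = fit_mle(d, as.integer(comp), window, seed = seed + 2L))
      }
      fit <- bootstrap_fit(d, .n_par(report$fit$model) %/% 2 + 1, window,
                           n_boot = ft$n_boot %||% 1000, seed = seed + 3L,
                           fit = report$fit)
      m <- fit$model
      out <- list(
        channel = ch,
        window = list(t_m = window$t_m, t_max = window$t_max),
        parameters = list(A1 = m$A1, tau1 = m$tau1, tau2 = m$tau2),
        bootstrap_sd = as.list(fit$bootstrap_sd),
        n_boot = fit$n_boot,
        loglik = fit$loglik, n_dwells = fit$n_dwells,
        boundary = fit$boundary, selection = report$selection
      )
      jsonlite::write_json(out, add_output("fit", file.path(out_dir, "fit.json")),
                           auto_unbox = TRUE, digits = NA, null = "null")
    })
  }

  if ("coloc" %in% stages) {
    .run_stage("coloc", {
      if (is.null(intervals)) {
        p <- file.path(out_dir, "intervals.tsv")
        if (!file.exists(p)) stop("no interval table available")
        intervals <- read_intervals_tsv(p)
      }
      if (!all(c("U1", "BBP") %in% intervals$channel)) {
        stop("coloc requires a two-channel interval table")
      }
      cl <- config$coloc %||% list()
      tolf <- cl$tolerance_frames %||% 0
      cx <- find_coloc(intervals, tolf, schedule$interval)
      write_tsv_table(cx, add_output("coloc", file.path(out_dir, "complexes.tsv")))
      cond <- conditional_dwells(intervals)
      fates <- classify_fates(intervals, tolf, schedule$interval)
      ord <- assembly_order(intervals, tolf, schedule$interval)
      summarize_class <- function(d) {
        if (length(d) < 2) list(mean = NA, se = NA, n = length(d))
        else mean_lifetime(d)
      }
      out <- list(
        n_complexes = nrow(cx),
        conditional_lifetimes = list(
          with_bbp = summarize_class(cond$duration_s[cond$with_bbp]),
          without_bbp = summarize_class(cond$duration_s[!cond$with_bbp])
        ),
        fates = as.list(stats::setNames(fates$count, fates$route)),
        fate_fractions = as.list(stats::setNames(fates$fraction, fates$route)),
        assembly_order = as.list(stats::setNames(ord$count, ord$entered_by))
      )
      jsonlite::write_json(out, add_output("coloc", file.path(out_dir, "coloc_summary.json")),
                           auto_unbox = TRUE, digits = NA, null = "null")
    })
  }

  if ("report" %in% stages) {
    .run_stage("report", {
      if (is.null(intervals)) {
        p <- file.path(out_dir, "intervals.tsv")
        if (!file.exists(p)) stop("no interval table available")
        intervals <- read_intervals_tsv(p)
      }
      n_draw <- config$report$rastergram_molecules %||% 30
      ids <- sort(unique(intervals$molecule_id))
      keep <- intervals$molecule_id %in% ids[seq_len(min(n_draw, length(ids)))]
      sub <- intervals[keep, , drop = FALSE]
      attr(sub, "record_length") <- attr(intervals, "record_length")
      gg <- render_rastergram(sub)
      path <- add_output("report", file.path(out_dir, "rastergram.png"))
      ggplot2::ggsave(path, gg, width = 8, height = 6, dpi = 150)
    })
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(manifest)
}
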