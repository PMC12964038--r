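#' Assemble a pipeline run configuration
#'
#' Collects every analysis constant in one validated list. Thresholds
#' default to the rule constants used throughout: framewise-displacement
#' exclusion at mean FD > 0.30 mm or > 20\% of FDs above 0.30 mm;
#' explained-variance inclusion at >= 0.10; display threshold PP > 0.99.
#'
#' @param data_dir directory holding \code{sub-XXX_bold.tsv} files and
#'   \code{participants.csv}.
#' @param out_dir output directory.
#' @param tr repetition time (s).
#' @param mar_order MAR order.
#' @param freqs analysis frequency grid (Hz).
#' @param ev_threshold explained-variance inclusion threshold.
#' @param pp_cutoff posterior-probability display threshold.
#' @param fd_mean_thresh,fd_prop_thresh,fd_large_thresh motion QC rules.
#' @param ppg_fs PPG sampling rate (Hz) when PPG traces are present.
#' @param max_iter,tol inversion options.
#' @param seed seed recorded in the report (the pipeline itself is
#'   deterministic given its inputs).
#' @return list of class \code{run_config}.
#' @export
run_config <- function(data_dir, out_dir = file.path(data_dir, "derived"),
                       tr = 0.961, mar_order = 8,
                       freqs = default_freq_grid(),
                       ev_threshold = 0.10, pp_cutoff = 0.99,
                       fd_mean_thresh = 0.30, fd_prop_thresh = 0.20,
                       fd_large_thresh = 0.30, ppg_fs = 500,
                       max_iter = 128, tol = 1e-2, seed = 1) {
  stopifnot(ev_threshold >= 0, ev_threshold <= 1,
            pp_cutoff >= 0, pp_cutoff <= 1,
            dir.exists(data_dir))
  structure(
    list(data_dir = data_dir, out_dir = out_dir, tr = tr,
         mar_order = mar_order, freqs = freqs,
         ev_threshold = ev_threshold, pp_cutoff = pp_cutoff,
         fd_mean_thresh = fd_mean_thresh, fd_prop_thresh = fd_prop_thresh,
         fd_large_thresh = fd_large_thresh, ppg_fs = ppg_fs,
         max_iter = max_iter, tol = tol, seed = seed),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file; keys as in [run_config()].
#' @return a \code{run_config}.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$freqs)) y$freqs <- as.numeric(y$freqs)
  do.call(run_config, y)
}

#' First-level pipeline: per-subject QC, spectra, inversion, screening
#'
#' For every subject listed in \code{participants.csv}: motion QC when a
#' motion table exists, heart-rate extraction when a PPG trace exists (and
#' the covariate table lacks an HR), MAR cross-spectra, model inversion, and
#' the explained-variance screen. Posteriors are written as JSON; a ledger
#' records every exclusion with exactly one primary reason. Failures in one
#' subject are isolated and logged, not fatal.
#'
#' @param config a \code{run_config}.
#' @param progress print per-subject progress lines.
#' @return list of class \code{first_level_result}: \code{posteriors}
#'   (named list, included subjects only), \code{ledger} (data frame: id,
#'   stage outcomes, primary exclusion reason), \code{covariates} (updated
#'   with extracted HR), \code{config}.
#' @export
run_first_level <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "run_config"))
  covars <- read_participants(file.path(config$data_dir,
                                        "participants.csv"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  posteriors <- list()
  rows <- list()
  for (i in seq_len(nrow(covars))) {
    id <- covars$id[i]
    mean_fd <- NA_real_
    ev <- NA_real_
    reason <- ""
    status <- "included"
    tryCatch({
      mfile <- file.path(config$data_dir, paste0(id, "_motion.tsv"))
      if (file.exists(mfile)) {
        motion <- as.matrix(utils::read.delim(mfile))
        qc <- qc_exclude(framewise_displacement(motion),
                         config$fd_mean_thresh, config$fd_prop_thresh,
                         config$fd_large_thresh)
        mean_fd <- qc$mean_fd
        if (qc$excluded) {
          reason <- paste0("motion_", qc$reason)
          status <- "excluded"
        }
      }
      pfile <- file.path(config$data_dir, paste0(id, "_ppg.tsv"))
      if (!is.finite(covars$hr_bpm[i]) && file.exists(pfile)) {
        ppg <- utils::read.delim(pfile)
        covars$hr_bpm[i] <- ppg_to_hr(ppg$amplitude, config$ppg_fs)$mean_hr
      }
      if (status == "included") {
        bold <- read_bold_tsv(file.path(config$data_dir,
                                        paste0(id, "_bold.tsv")))
        fit <- spdcm(bold, tr = config$tr, order = config$mar_order,
                     freqs = config$freqs, max_iter = config$max_iter,
                     tol = config$tol)
        ev <- fit$explained_variance
        if (!fit$converged) {
          reason <- "nonconvergence"
          status <- "excluded"
        } else if (ev < config$ev_threshold) {
          reason <- "explained_variance"
          status <- "excluded"
        } else {
          posteriors[[id]] <- fit
          write_posterior_json(fit, file.path(config$out_dir,
                                              paste0(id, "_post.json")))
        }
      }
    }, error = function(e) {
      reason <<- paste0("error: ", conditionMessage(e))
      status <<- "failed"
    })
    rows[[i]] <- data.frame(id = id, status = status, reason = reason,
                            mean_fd = mean_fd, explained_variance = ev,
                            stringsAsFactors = FALSE)
    if (progress) {
      message(sprintf("%s: %s %s", id, status,
                      if (nzchar(reason)) paste0("(", reason, ")") else ""))
    }
  }
  ledger <- do.call(rbind, rows)
  stopifnot(nrow(ledger) == sum(table(ledger$status)))
  write_participants(covars, file.path(config$out_dir,
                                       "participants_updated.csv"))
  utils::write.csv(ledger, file.path(config$out_dir, "ledger.csv"),
                   row.names = FALSE)
  structure(list(posteriors = posteriors, ledger = ledger,
                 covariates = covars, config = config),
            class = "first_level_result")
}

#' Second-level pipeline: group analyses and thresholded reports
#'
#' Runs the four-analysis PEB suite on the included subjects (those with
#' complete covariates), writes per-analysis TSV matrices in the display
#' convention "Ep (SD)" with blanks below the PP cutoff, and a JSON report
#' with the full numbers and provenance.
#'
#' @param first a \code{first_level_result} (or a directory of posterior
#'   JSONs via \code{posterior_dir} + \code{covariates}).
#' @param config optional \code{run_config}; defaults to the one in
#'   \code{first}.
#' @return list of class \code{analysis_report}: the \code{peb_suite},
#'   exclusion \code{ledger}, and output paths.
#' @export
run_second_level <- function(first, config = first$config) {
  stopifnot(inherits(first, "first_level_result"))
  posteriors <- first$posteriors
  covars <- first$covariates
  keep <- covars$id %in% names(posteriors)
  covars <- covars[keep, , drop = FALSE]
  no_hr <- !is.finite(covars$hr_bpm)
  ledger <- first$ledger
  if (any(no_hr)) {
    ledger$reason[ledger$id %in% covars$id[no_hr] &
                    ledger$reason == ""] <- "missing_hr"
    ledger$status[ledger$id %in% covars$id[no_hr]] <- "excluded_covariate"
    covars <- covars[!no_hr, , drop = FALSE]
  }
  posteriors <- posteriors[covars$id]
  groups <- table(covars$group)
  if (length(groups) == 2 && any(groups < 2)) {
    stop("run_second_level: need at least 2 subjects per group")
  }
  suite <- run_analysis_suite(posteriors, covars,
                              cutoff = config$pp_cutoff)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(suite$matrices)) {
    p <- file.path(config$out_dir, paste0("matrix_", nm, ".tsv"))
    write_matrix_tsv(suite$matrices[[nm]]$Ep, p)
    paths <- c(paths, p)
  }
  report <- list(
    thresholds = list(pp_cutoff = config$pp_cutoff,
                      ev_threshold = config$ev_threshold,
                      fd_mean_thresh = config$fd_mean_thresh,
                      fd_prop_thresh = config$fd_prop_thresh),
    seed = config$seed,
    n_analyzed = nrow(covars),
    exclusions = as.list(table(ledger$reason[nzchar(ledger$reason)])),
    analyses = lapply(suite$matrices, function(m) {
      list(Ep = m$Ep, SD = m$SD, PP = m$PP)
    })
  )
  rpath <- file.path(config$out_dir, "analysis_report.json")
  jsonlite::write_json(report, rpath, digits = NA, auto_unbox = TRUE)
  structure(list(suite = suite, ledger = ledger, covariates = covars,
                 report_path = rpath, matrix_paths = paths,
                 config = config),
            class = "analysis_report")
}

#' Run the full pipeline
#'
#' [run_first_level()] followed by [run_second_level()].
#'
#' @param config a \code{run_config}.
#' @param progress print progress.
#' @return an \code{analysis_report}.
#' @export
run_pipeline <- function(config, progress = FALSE) {
  run_second_level(run_first_level(config, progress = progress))
}

#' Figures for an analysis report
#'
#' Writes, per thresholded analysis matrix, a heatmap and a directed-graph
#' rendering (solid arrows = between-region connections, dashed loops =
#' self-connections), as PDF files. Deterministic node layout (circle).
#'
#' @param report an \code{analysis_report}.
#' @param dir output directory (default: the report's output directory).
#' @return character vector of files written, invisibly.
#' @export
make_figures <- function(report, dir = report$config$out_dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(report$suite$matrices)) {
    m <- report$suite$matrices[[nm]]
    f <- file.path(dir, paste0("figure_", nm, ".pdf"))
    grDevices::pdf(f, width = 9, height = 4.5)
    graphics::par(mfrow = c(1, 2), mar = c(2, 4, 3, 5))
    plot_matrix_heatmap(m, main = nm)
    plot_connectivity_graph(m, main = nm)
    grDevices::dev.off()
    files <- c(files, f)
  }
  invisible(files)
}

plot_matrix_heatmap <- function(m, main = "") {
  E <- m$Ep
  n <- nrow(E)
  z <- t(E)[, n:1, drop = FALSE]
  lim <- max(abs(E), 0.01, na.rm = TRUE)
  cols <- grDevices::hcl.colors(65, "Blue-Red 2")
  graphics::image(seq_len(n), seq_len(n), z, zlim = c(-lim, lim),
                  col = cols, axes = FALSE, xlab = "source (from)",
                  ylab = "", main = main)
  graphics::axis(1, seq_len(n), colnames(E), las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(n), rev(rownames(E)), las = 2, cex.axis = 0.8)
  graphics::mtext("target (to)", side = 2, line = 3)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    v <- E[i, j]
    if (!is.na(v)) {
      graphics::text(j, n - i + 1,
                     sprintf("%.2f\n(%.2f)", v, m$SD[i, j]), cex = 0.6)
    }
  }
}

plot_connectivity_graph <- function(m, main = "") {
  E <- m$Ep
  n <- nrow(E)
  ang <- pi / 2 - 2 * pi * (seq_len(n) - 1) / n
  xs <- cos(ang); ys <- sin(ang)
  graphics::plot(xs, ys, xlim = c(-1.45, 1.45), ylim = c(-1.45, 1.45),
                 pch = 21, bg = "grey90", cex = 4, axes = FALSE,
                 xlab = "", ylab = "", main = main, asp = 1)
  graphics::text(1.28 * xs, 1.28 * ys, rownames(E), cex = 0.8)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    v <- E[i, j]
    if (is.na(v)) next
    col <- if (v >= 0) "firebrick" else "steelblue4"
    if (i == j) {
      # dashed self-loop
      th <- seq(0, 2 * pi, length.out = 40)
      graphics::lines(xs[i] * 1.12 + 0.1 * cos(th),
                      ys[i] * 1.12 + 0.1 * sin(th), lty = 2, col = col,
                      lwd = 1 + 3 * min(abs(v), 1))
    } else {
      # solid arrow source j -> target i, shortened at both ends
      dx <- xs[i] - xs[j]; dy <- ys[i] - ys[j]
      len <- sqrt(dx^2 + dy^2)
      sh <- 0.14 / len
      graphics::arrows(xs[j] + dx * sh, ys[j] + dy * sh,
                       xs[i] - dx * sh, ys[i] - dy * sh,
                       length = 0.08, col = col,
                       lwd = 1 + 3 * min(abs(v), 1))
    }
  }
}
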