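#' End-to-end pipeline: generate/load -> detect -> HRV -> band power -> HEP
#' -> coupling
#'
#' @name pipeline_io
NULL

#' Build a run configuration
#'
#' Every default traces to an analysis convention documented in the methods
#' vignette. The configuration round-trips losslessly through JSON
#' ([write_run_config()] / [read_run_config()]).
#'
#' @param input either a `cohort_spec` (synthetic mode) or a data.frame
#'   manifest with columns `subject`, `group`, `path` (EDF or CSV per
#'   subject)
#' @param out_dir output directory (artifacts + report)
#' @param seed integer seed for any stochastic step
#' @param segment analysed segment: "full" (default) or `c(start_s, end_s)`
#' @param hrv_compute_hf compute tachogram HF power (needs >= 60 s of beats)
#' @param hep_toi_ms,hep_cap_trials HEP window of interest and optional
#'   trial-count cap
#' @param bonferroni_hrv_family family size for the HRV group comparison
#' @param correlogram_min_n minimum subjects per group for the correlogram
#' @param write_plots emit SVG figures (spectra, correlogram, HEP)
#' @return object of class `run_config`
#' @export
run_config <- function(input, out_dir, seed = 1L, segment = "full",
                       hrv_compute_hf = TRUE, hep_toi_ms = c(350, 600),
                       hep_cap_trials = NULL, bonferroni_hrv_family = 4,
                       correlogram_min_n = 5, write_plots = FALSE) {
  structure(list(input = input, out_dir = out_dir, seed = as.integer(seed),
                 segment = segment, hrv_compute_hf = hrv_compute_hf,
                 hep_toi_ms = hep_toi_ms, hep_cap_trials = hep_cap_trials,
                 bonferroni_hrv_family = bonferroni_hrv_family,
                 correlogram_min_n = correlogram_min_n,
                 write_plots = write_plots),
            class = "run_config")
}

#' Serialize / restore a run configuration (JSON)
#' @param config a `run_config`
#' @param path file path
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$input_kind <- if (inherits(config$input, "cohort_spec")) "cohort_spec"
                  else "manifest"
  inp <- unclass(config$input)
  if (x$input_kind == "cohort_spec") {
    # jsonlite drops names of atomic vectors; listify the named fields
    for (f in c("n_per_group", "base_power_db", "hep_amp_uV"))
      inp[[f]] <- as.list(inp[[f]])
    inp$band_coupling_slope <- lapply(inp$band_coupling_slope, as.list)
  }
  x$input <- inp
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  kind <- x$input_kind
  x$input_kind <- NULL
  if (kind == "cohort_spec") {
    inp <- x$input
    inp$n_per_group <- unlist(inp$n_per_group)
    inp$base_power_db <- unlist(inp$base_power_db)
    inp$hep_amp_uV <- unlist(inp$hep_amp_uV)
    inp$band_coupling_slope <- lapply(inp$band_coupling_slope, unlist)
    x$input <- do.call(cohort_spec, inp)
  } else {
    x$input <- as.data.frame(x$input)
  }
  if (length(x$hep_cap_trials) == 0) x$hep_cap_trials <- NULL
  do.call(run_config, x)
}

#' Read a recording from EDF or CSV
#'
#' @param path `.edf` or `.csv` file
#' @param fs sampling rate, required for CSV (EDF carries its own)
#' @param montage optional channel names that must be resolvable (error on
#'   unresolvable labels, never a silent drop)
#' @return a `recording`
#' @export
read_recording <- function(path, fs = NULL, montage = NULL) {
  ext <- tolower(tools::file_ext(path))
  rec <- switch(ext,
    edf = read_edf(path),
    csv = {
      if (is.null(fs)) stop("fs is required for CSV input")
      read_recording_csv(path, fs)
    },
    stop("unsupported recording format: .", ext))
  if (!is.null(montage)) match_channel(montage, rec$labels)
  rec
}

.crop_segment <- function(rec, segment) {
  if (identical(segment, "full")) return(rec)
  i1 <- max(1L, round(segment[1] * rec$fs) + 1L)
  i2 <- min(n_samples(rec), round(segment[2] * rec$fs))
  recording(rec$samples[, i1:i2, drop = FALSE], rec$fs, rec$labels,
            rec$units, start_time = segment[1])
}

# per-subject stage chain; returns a list of artifacts or condition object
.process_subject <- function(rec, config) {
  ecg <- pick_channels(rec, "ECG")
  peaks <- detect_r_peaks(ecg)
  nn <- to_nn_series(peaks)
  hrv <- hrv_summary(nn, compute_hf = config$hrv_compute_hf)
  eeg <- pick_channels(rec, setdiff(rec$labels, "ECG"))
  pre <- preprocess_eeg(eeg)
  psds <- channel_psds(pre)
  bp <- band_roi_power(psds)
  epochs <- epoch_heartbeats(pre, peaks)
  hep <- average_hep(epochs, max_trials = config$hep_cap_trials)
  list(peaks = peaks, nn = nn, hrv = hrv, band_power = bp, psds = psds,
       hep = hep, reference = attr(pre, "reference"))
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order: acquire recordings (synthetic
#' generation or EDF/CSV manifest), R-peak detection, NN/HRV extraction, EEG
#' preprocessing + band/ROI power, heartbeat-evoked averaging, then the
#' across-subject battery (Spearman correlograms per group, group ANOVA with
#' Bonferroni, per-band best-subset regressions, HEP group comparison).
#' Per-subject failures are isolated: the subject is reported in
#' `report$failures` and the run continues; the run fails only if a whole
#' stage is empty.
#'
#' All tables are written as CSV, results and the sidecar (parameters, seed)
#' as JSON, into `config$out_dir`.
#'
#' @param config a `run_config`
#' @return the run report (list), invisibly written as artifacts
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  if (inherits(config$input, "cohort_spec")) {
    spec <- config$input
    coh <- generate_cohort(spec, out_dir = file.path(out, "recordings"))
    roster <- data.frame(
      subject = vapply(coh$subjects, `[[`, "", "id"),
      group = vapply(coh$subjects, `[[`, "", "group"),
      path = file.path(out, "recordings",
                       paste0(vapply(coh$subjects, `[[`, "", "id"), ".edf")))
    recs <- lapply(coh$subjects, `[[`, "recording")
  } else {
    roster <- config$input
    recs <- vector("list", nrow(roster))
  }
  subj_res <- list(); failures <- list()
  for (i in seq_len(nrow(roster))) {
    id <- roster$subject[i]
    res <- tryCatch({
      rec <- if (!is.null(recs[[i]])) recs[[i]]
             else read_recording(roster$path[i])
      rec <- .crop_segment(rec, config$segment)
      .process_subject(rec, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[id]] <- conditionMessage(res)
    } else {
      subj_res[[id]] <- res
    }
  }
  if (!length(subj_res)) stop("no subject completed the per-subject stages")
  ok <- names(subj_res)
  grp <- roster$group[match(ok, roster$subject)]

  hrv_df <- do.call(rbind, lapply(ok, function(id) {
    h <- subj_res[[id]]$hrv
    data.frame(subject = id, group = grp[match(id, ok)],
               sdnn_ms = h$sdnn_ms, rmssd_ms = h$rmssd_ms,
               sd1_ms = h$sd1_ms, hf_ms2 = h$hf_ms2,
               n_intervals = h$n_intervals,
               n_rejected = subj_res[[id]]$nn$n_rejected)
  }))
  power_df <- do.call(rbind, lapply(ok, function(id)
    cbind(subject = id, group = grp[match(id, ok)],
          subj_res[[id]]$band_power)))

  groups <- unique(grp)
  correlograms <- list()
  for (g in groups) {
    gi <- ok[grp == g]
    if (length(gi) >= config$correlogram_min_n) {
      correlograms[[g]] <- spearman_correlogram(
        power_df[power_df$subject %in% gi, ],
        hrv_df[hrv_df$subject %in% gi, ], group = g,
        min_n = config$correlogram_min_n)
    }
  }

  group_tests <- NULL
  if (length(groups) == 2 && all(table(grp) >= 2)) {
    hrv_long <- do.call(rbind, lapply(
      c("sdnn_ms", "rmssd_ms", "sd1_ms", "hf_ms2"), function(v)
        data.frame(variable = v, group = hrv_df$group,
                   value = hrv_df[[v]])))
    hrv_long <- hrv_long[!is.na(hrv_long$value), ]
    eeg_long <- data.frame(
      variable = paste(power_df$band, power_df$roi, power_df$hemisphere,
                       sep = "_"),
      group = power_df$group, value = power_df$power_db)
    group_tests <- list(
      hrv = tryCatch(group_compare(hrv_long,
                                   config$bonferroni_hrv_family),
                     error = function(e) conditionMessage(e)),
      eeg = tryCatch(group_compare(eeg_long),
                     error = function(e) conditionMessage(e)))
  }

  regressions <- list()
  bands <- eeg_bands()$band
  hrv_params <- c("sdnn_ms", "rmssd_ms", "hf_ms2")
  for (g in groups) {
    gi <- ok[grp == g]
    if (length(gi) < 4) next
    for (b in bands) for (h in c("L", "R")) {
      pw <- power_df[power_df$subject %in% gi & power_df$band == b &
                     power_df$hemisphere == h, ]
      Xw <- stats::reshape(pw[, c("subject", "roi", "power_db")],
                           idvar = "subject", timevar = "roi",
                           direction = "wide")
      colnames(Xw) <- sub("^power_db\\.", "", colnames(Xw))
      pred_order <- intersect(c("F", "C", "P", "T", "O"), colnames(Xw))
      for (par in hrv_params) {
        y <- hrv_df[[par]][match(Xw$subject, hrv_df$subject)]
        if (anyNA(y)) next
        key <- paste(g, b, h, par, sep = ".")
        regressions[[key]] <- tryCatch(
          best_subset_regression(Xw[, pred_order, drop = FALSE], y,
                                 predictors = pred_order),
          error = function(e) conditionMessage(e))
      }
    }
  }

  hep_windows <- NULL
  if (length(groups) == 2 && all(table(grp) >= 2)) {
    heps_a <- lapply(ok[grp == groups[1]], function(id) subj_res[[id]]$hep)
    heps_b <- lapply(ok[grp == groups[2]], function(id) subj_res[[id]]$hep)
    hep_windows <- compare_groups_hep(heps_a, heps_b,
                                      toi = config$hep_toi_ms)
  }

  report <- list(n_subjects = length(ok), subjects = ok,
                 failures = failures,
                 references = vapply(subj_res, `[[`, "", "reference"),
                 hrv = hrv_df, band_power = power_df,
                 correlograms = correlograms, group_tests = group_tests,
                 regressions = regressions, hep_windows = hep_windows)

  utils::write.csv(hrv_df, file.path(out, "hrv.csv"), row.names = FALSE)
  utils::write.csv(power_df, file.path(out, "band_power.csv"),
                   row.names = FALSE)
  if (length(correlograms))
    utils::write.csv(do.call(rbind, unname(correlograms)),
                     file.path(out, "correlogram.csv"), row.names = FALSE)
  if (!is.null(hep_windows))
    jsonlite::write_json(hep_windows, file.path(out, "hep_windows.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  reg_tab <- do.call(rbind, lapply(names(regressions), function(k) {
    f <- regressions[[k]]
    if (!inherits(f, "regression_fit")) return(NULL)
    data.frame(key = k,
               predictors = paste(f$included_predictors, collapse = "+"),
               r2 = f$r2, r2_adj = f$r2_adj, saturated = f$saturated,
               shapiro_p = if (is.null(f$shapiro_p)) NA else f$shapiro_p)
  }))
  if (!is.null(reg_tab))
    utils::write.csv(reg_tab, file.path(out, "regression.csv"),
                     row.names = FALSE)
  # HEP grand-average waveforms, tidy
  hep_rows <- do.call(rbind, lapply(ok, function(id) {
    h <- subj_res[[id]]$hep
    data.frame(subject = id, time_ms = rep(h$time_ms, each = nrow(h$waveforms)),
               channel = rep(h$labels, length(h$time_ms)),
               amplitude_uV = as.vector(h$waveforms))
  }))
  utils::write.csv(hep_rows, file.path(out, "hep_waveforms.csv"),
                   row.names = FALSE)
  sidecar <- list(seed = config$seed, segment = config$segment,
                  hep_toi_ms = config$hep_toi_ms,
                  bonferroni_hrv_family = config$bonferroni_hrv_family,
                  package_version = as.character(utils::packageVersion(
                    "cardiocortex")),
                  failures = failures)
  jsonlite::write_json(sidecar, file.path(out, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (isTRUE(config$write_plots)) .write_figures(report, subj_res, grp, out)
  invisible(report)
}

# Fig-style summary graphics (SVG: text-based, deterministic enough for
# human inspection; excluded from any bit-identity comparison)
.write_figures <- function(report, subj_res, grp, out) {
  grDevices::svg(file.path(out, "grand_spectrum.svg"), width = 7, height = 5)
  on.exit(grDevices::dev.off(), add = TRUE)
  cols <- c("firebrick", "black")
  groups <- unique(grp)
  first <- TRUE
  for (gi in seq_along(groups)) {
    ids <- names(subj_res)[grp == groups[gi]]
    ps <- lapply(ids, function(id) mean_psd(subj_res[[id]]$psds,
                                            names(subj_res[[id]]$psds)))
    pw <- rowMeans(sapply(ps, `[[`, "power"))
    f <- ps[[1]]$freq
    sel <- f >= 1 & f <= 31
    if (first) {
      plot(f[sel], 10 * log10(pw[sel]), type = "l", col = cols[gi],
           xlab = "frequency (Hz)", ylab = "power (dB)",
           main = "grand-average spectrum")
      first <- FALSE
    } else lines(f[sel], 10 * log10(pw[sel]), col = cols[gi])
  }
  graphics::legend("topright", legend = groups, col = cols[seq_along(groups)],
                   lty = 1, bty = "n")
  invisible(NULL)
}
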