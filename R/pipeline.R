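# Orchestration: single-recording runs (ROI -> preprocess -> extract ->
# postprocess -> PRV), reference-PPG ingestion, and cohort-level
# agreement grids across subjects and methods.

#' Run the full pipeline on one recording
#'
#' Executes, in order: ROI extraction (when the input is a frame
#' sequence), preprocessing, pulse extraction by the chosen method,
#' postprocessing, peak detection and PRV feature computation.  Identical
#' inputs and configuration give identical outputs (stochastic methods
#' are seeded through `params`).
#'
#' @param input an [rgb_trace] (raw), a [frame_sequence], or a path to an
#'   RGB trace CSV (`t,r,g,b`).
#' @param method extraction method name (see `IPPG_METHODS`).
#' @param config a [filter_config].
#' @param params a [method_params].
#' @param out_dir optional directory; when given, features
#'   (`features_<method>.json` and `.csv`), the NN series
#'   (`nn_<method>.csv`) and a run manifest are written there.
#' @param dump_stages when `TRUE` (and `out_dir` is set) the raw trace,
#'   preprocessed trace and extracted signal are dumped as CSV.
#' @return list: `features` ([prv_features]), `nn` ([nn_series]),
#'   `signal` (postprocessed [ippg_signal]), `trace_raw`, `trace_pre`,
#'   `manifest`.
#' @export
run_single <- function(input, method = "POS", config = filter_config(),
                       params = method_params(), out_dir = NULL,
                       dump_stages = FALSE) {
  method <- toupper(method)
  if (!method %in% IPPG_METHODS)
    stop("unknown method '", method, "'; valid methods: ",
         paste(IPPG_METHODS, collapse = ", "))
  stage <- "input"
  res <- tryCatch({
    if (is.character(input)) input <- read_rgb_trace(input)
    if (inherits(input, "frame_sequence")) {
      stage <- "video_roi"
      input <- video_to_trace(input)$trace
    }
    stopifnot(inherits(input, "rgb_trace"))
    trace_raw <- input
    stage <- "preprocess"
    trace_pre <- preprocess_trace(trace_raw, config)
    stage <- "extract"
    sig <- extract_ippg(trace_pre, method, trace_raw = trace_raw,
                        params = params,
                        band = c(config$band_lo, config$band_hi))
    stage <- "postprocess"
    sig_pp <- postprocess_ippg(sig, config = config)
    stage <- "prv"
    pk <- detect_peaks(sig_pp)
    nn <- peaks_to_nn(pk)
    feats <- prv_features(nn)
    list(trace_raw = trace_raw, trace_pre = trace_pre, signal = sig_pp,
         nn = nn, features = feats)
  }, error = function(e) {
    stop("run_single[", method, "] failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  res$manifest <- list(method = method, config = unclass(config),
                       params = unclass(params),
                       package_version = as.character(
                         utils::packageVersion("ippg")),
                       n_samples = length(res$trace_raw),
                       fs = res$trace_raw$fs,
                       corrected_beats = res$nn$corrected_count)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_prv_features(res$features,
                       file.path(out_dir, paste0("features_", method, ".json")))
    write_prv_features(res$features,
                       file.path(out_dir, paste0("features_", method, ".csv")))
    write_nn_series(res$nn, file.path(out_dir, paste0("nn_", method, ".csv")))
    jsonlite::write_json(res$manifest,
                         file.path(out_dir, paste0("manifest_", method, ".json")),
                         auto_unbox = TRUE, digits = NA)
    if (dump_stages) {
      write_rgb_trace(res$trace_raw, file.path(out_dir, "trace_raw.csv"))
      write_rgb_trace(res$trace_pre, file.path(out_dir, "trace_pre.csv"))
      utils::write.csv(data.frame(t = res$trace_pre$t,
                                  value = res$signal$values),
                       file.path(out_dir, paste0("signal_", method, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
  }
  res
}

#' Read a contact-PPG reference file
#'
#' The expected dialect is three whitespace-separated numeric lines: the
#' PPG signal, the device pulse-rate trace, and the sample timestamps in
#' seconds.  The signal is resampled onto a uniform grid (cubic spline,
#' rate from the median timestamp spacing) so it can enter the same PRV
#' path as the contactless signals.
#'
#' @param path text file path.
#' @return list: `signal` (an [ippg_signal], method `"REF"`,
#'   polarity-oriented), `hr` (device pulse-rate samples),
#'   `timestamps` (original, seconds), `fs`.
#' @export
read_reference_ppg <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 3L)
    stop("reference PPG file must have exactly 3 numeric lines, got ",
         length(lines), ": ", path)
  parse_line <- function(l, what) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1L]]))
    if (anyNA(v)) stop("non-numeric token in ", what, " line: ", path)
    v
  }
  sig <- parse_line(lines[1L], "signal")
  hr <- parse_line(lines[2L], "pulse-rate")
  ts <- parse_line(lines[3L], "timestamp")
  if (length(sig) != length(ts))
    stop("signal and timestamp lines differ in length: ", path)
  if (any(diff(ts) <= 0))
    stop("non-monotone timestamps in reference file: ", path)
  fs <- 1 / stats::median(diff(ts))
  grid <- seq(ts[1L], ts[length(ts)], by = 1 / fs)
  v <- stats::spline(ts, sig, xout = grid, method = "fmm")$y
  list(signal = ippg_signal(v, fs, "REF", polarity_oriented = TRUE),
       hr = hr, timestamps = ts, fs = fs)
}

#' Cohort-level agreement analysis
#'
#' Computes agreement statistics per (feature, method) cell from
#' per-subject feature tables: Spearman rho and p, NRMSE, and
#' Bland-Altman bias with 95% limits of agreement.  Cells with fewer
#' than three complete pairs (or degenerate inputs) are reported as `NA`
#' with the reason kept alongside.
#'
#' @param est named list (one element per method) of per-subject feature
#'   data frames as produced by `as.data.frame.prv_features` (rows =
#'   subjects, columns = the 14 features).
#' @param ref per-subject reference feature data frame (same row order).
#' @param out_dir optional directory: grids are written as
#'   `spearman_rho.csv`, `spearman_pval.csv`, `nrmse.csv`, `bias.csv`,
#'   `loa_low.csv`, `loa_high.csv` (feature x method), and one
#'   Bland-Altman PNG per cell under `bland_altman/`.
#' @param plots whether to emit the per-cell plots when `out_dir` is set.
#' @return list of class `cohort_agreement`: `grids` (named list of
#'   feature x method matrices), `reports` (nested list of
#'   [agreement_report] or a character reason), `n_subjects`.
#' @export
run_cohort <- function(est, ref, out_dir = NULL, plots = FALSE) {
  stopifnot(is.list(est), length(est) >= 1L, is.data.frame(ref))
  methods <- names(est)
  feats <- intersect(PRV_FEATURE_NAMES, colnames(ref))
  grid <- function() matrix(NA_real_, length(feats), length(methods),
                            dimnames = list(feats, methods))
  grids <- list(rho = grid(), pval = grid(), nrmse = grid(),
                bias = grid(), loa_low = grid(), loa_high = grid())
  reports <- stats::setNames(vector("list", length(methods)), methods)
  for (m in methods) {
    reports[[m]] <- stats::setNames(vector("list", length(feats)), feats)
    for (f in feats) {
      rep_or_reason <- tryCatch({
        pf <- paired_features(est[[m]][[f]], ref[[f]], feature = f)
        agreement_report(pf)
      }, error = function(e) conditionMessage(e))
      reports[[m]][[f]] <- rep_or_reason
      if (inherits(rep_or_reason, "agreement_report")) {
        grids$rho[f, m] <- rep_or_reason$rho
        grids$pval[f, m] <- rep_or_reason$pval
        grids$nrmse[f, m] <- rep_or_reason$nrmse
        grids$bias[f, m] <- rep_or_reason$bias
        grids$loa_low[f, m] <- rep_or_reason$loa_low
        grids$loa_high[f, m] <- rep_or_reason$loa_high
      }
    }
  }
  out <- structure(list(grids = grids, reports = reports,
                        n_subjects = nrow(ref)),
                   class = "cohort_agreement")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    fn <- c(rho = "spearman_rho.csv", pval = "spearman_pval.csv",
            nrmse = "nrmse.csv", bias = "bias.csv",
            loa_low = "loa_low.csv", loa_high = "loa_high.csv")
    for (g in names(fn))
      utils::write.csv(grids[[g]], file.path(out_dir, fn[[g]]))
    if (plots) {
      pd <- file.path(out_dir, "bland_altman")
      dir.create(pd, showWarnings = FALSE)
      for (m in methods) for (f in feats) {
        r <- reports[[m]][[f]]
        if (inherits(r, "agreement_report"))
          plot_bland_altman(r, file.path(pd, paste0(f, "_", m, ".png")))
      }
    }
  }
  out
}

#' @export
print.cohort_agreement <- function(x, ...) {
  cat(sprintf("<cohort_agreement> %d subjects, %d methods x %d features\n",
              x$n_subjects, ncol(x$grids$rho), nrow(x$grids$rho)))
  cat("Spearman rho:\n")
  print(round(x$grids$rho, 3))
  invisible(x)
}
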