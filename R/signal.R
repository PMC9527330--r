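## ERG signal pipeline: baseline shift, resampling to the 0.5-ms standard
## grid, automated repeat selection and component detection.

#' Construct a raw ERG trace
#'
#' @param time_ms strictly increasing sample times in ms.
#' @param voltage_uV voltages in microvolts.
#' @param patient,eye,stimulus,repeat_ trace key.
#' @return object of class `erg_trace`.
#' @export
raw_trace <- function(time_ms, voltage_uV, patient = NA_character_,
                      eye = NA_character_, stimulus = NA_character_,
                      repeat_ = NA_integer_) {
  if (length(time_ms) != length(voltage_uV))
    stopf("time and voltage lengths differ")
  if (length(time_ms) < 2) stopf("a trace needs >= 2 samples")
  if (any(diff(time_ms) <= 0)) stopf("sample times must be strictly increasing")
  structure(list(time_ms = as.numeric(time_ms),
                 voltage_uV = as.numeric(voltage_uV),
                 patient = patient, eye = eye, stimulus = stimulus,
                 repeat_ = repeat_),
            class = "erg_trace")
}

#' Baseline-correct a trace
#'
#' Subtracts the mean of the five samples immediately after time zero
#' (0.5-2.5 ms on the standard grid), shifting the trace so its immediate
#' post-stimulus baseline is zero. Idempotent.
#'
#' @param trace an `erg_trace`.
#' @return baseline-corrected `erg_trace`.
#' @export
baseline_correct <- function(trace) {
  idx <- which(trace$time_ms > 0)
  if (length(idx) < 5) stopf("need >= 5 samples after t = 0 for baseline")
  trace$voltage_uV <- trace$voltage_uV - mean(trace$voltage_uV[idx[1:5]])
  trace
}

## matrix form used by the bulk pipeline: columns are traces already on the
## standard grid (time 0 at row 1)
baseline_correct_mat <- function(v) {
  sweep(v, 2, colMeans(v[2:6, , drop = FALSE]))
}

#' Resample a trace onto the standard grid
#'
#' Linear interpolation onto 0, 0.5, ..., 80 ms (161 samples). The native
#' samples must span the full grid; no extrapolation is performed.
#'
#' @param trace an `erg_trace`.
#' @param cfg configuration (grid spec).
#' @return `erg_trace` on the standard grid (class also `erg_stdtrace`).
#' @export
resample_std <- function(trace, cfg = default_config()) {
  grid <- std_grid(cfg)
  if (min(trace$time_ms) > grid[1] || max(trace$time_ms) < grid[length(grid)])
    stopf("trace spans [%g, %g] ms; cannot resample to [%g, %g] without extrapolation",
          min(trace$time_ms), max(trace$time_ms), grid[1], grid[length(grid)])
  trace$voltage_uV <- stats::approx(trace$time_ms, trace$voltage_uV,
                                    xout = grid, method = "linear")$y
  trace$time_ms <- grid
  class(trace) <- c("erg_stdtrace", "erg_trace")
  trace
}

## ---- trace selection -------------------------------------------------------

## mean squared difference between two equally sampled traces
pair_mse <- function(u, v) mean((u - v)^2)

#' Select repeats by minimum within-triple mean squared error
#'
#' For the flash stimuli (DA 10, LA 3) the most mutually consistent subset of
#' `k` repeats is chosen: the subset minimising the sum of pairwise mean
#' squared differences among its members, by exhaustive search over all
#' C(n, k) subsets. Ties are broken towards the earliest repeat indices.
#' With exactly two repeats both are returned and the quality flag is set.
#'
#' @param traces list of standard-grid traces (or a samples x repeats matrix).
#' @param k subset size (default 3).
#' @return list with `index` (selected repeat positions), `flag`
#'   (`"ok"` or `"two_repeats_only"`).
#' @export
select_traces_mse <- function(traces, k = 3L) {
  v <- traces_as_matrix(traces)
  n <- ncol(v)
  if (n < 2) stopf("need >= 2 repeats for selection")
  if (n == 2) return(list(index = 1:2, flag = "two_repeats_only"))
  if (n <= k) return(list(index = seq_len(n), flag = "ok"))
  ## pairwise MSE matrix, then exhaustive search over subsets
  d <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- pair_mse(v[, i], v[, j])
  }
  combos <- utils::combn(n, k)
  score <- apply(combos, 2, function(ix) sum(d[ix, ix]) / 2)
  best <- which.min(score)  # combn is lexicographic: first min = earliest ties
  list(index = combos[, best], flag = "ok")
}

## magnitude of the discrete Fourier component at `freq` Hz over the grid
flicker_signal <- function(voltage, time_ms, freq = 30) {
  w <- exp(-2i * pi * freq * time_ms / 1000)
  Mod(sum(voltage * w)) / length(voltage)
}

#' Select flicker repeats by maximum 30 Hz signal
#'
#' For the LA 30 Hz stimulus the `k` repeats with the largest 30 Hz Fourier
#' magnitude over the 0-80 ms window are selected; ties towards earliest
#' repeat indices.
#'
#' @inheritParams select_traces_mse
#' @param cfg configuration (grid spec).
#' @return list with `index` and `flag` as in [select_traces_mse()].
#' @export
select_traces_flicker <- function(traces, k = 3L, cfg = default_config()) {
  v <- traces_as_matrix(traces)
  n <- ncol(v)
  if (n < 2) stopf("need >= 2 repeats for selection")
  if (n == 2) return(list(index = 1:2, flag = "two_repeats_only"))
  grid <- std_grid(cfg)
  mag <- apply(v, 2, flicker_signal, time_ms = grid)
  ord <- order(-mag, seq_len(n))
  list(index = sort(ord[seq_len(min(k, n))]), flag = "ok")
}

traces_as_matrix <- function(traces) {
  if (is.matrix(traces)) return(traces)
  if (inherits(traces, "erg_trace")) traces <- list(traces)
  vapply(traces, function(tr) tr$voltage_uV, numeric(length(traces[[1]]$voltage_uV)))
}

## ---- component detection ---------------------------------------------------

## derivative sign-change positions on a filtered trace; returns, for each
## interior index i, the crossing type: -1 = neg-to-pos (trough), +1 =
## pos-to-neg (peak), 0 = none. The crossing is localised at whichever of the
## two samples has the derivative closer to zero.
derivative_crossings <- function(vf, dt) {
  n <- length(vf)
  d <- c(vf[2] - vf[1], (vf[3:n] - vf[1:(n - 2)]) / 2, vf[n] - vf[n - 1]) / dt
  s <- sign(d)
  idx <- which(s[-n] < 0 & s[-1] >= 0)   # trough candidates between i, i+1
  troughs <- ifelse(abs(d[idx]) <= abs(d[idx + 1]), idx, idx + 1)
  idx <- which(s[-n] > 0 & s[-1] <= 0)
  peaks <- ifelse(abs(d[idx]) <= abs(d[idx + 1]), idx, idx + 1)
  list(troughs = troughs, peaks = peaks)
}

#' Detect ERG components on a single standard-grid trace
#'
#' The trace is low-pass filtered with a zero-phase order-5 Butterworth
#' filter; extrema are located as the earliest zero crossings of the first
#' derivative of the filtered trace, subject to per-component minimum-time
#' cutoffs that suppress artifactual early deflections. Amplitudes are read
#' from the unfiltered trace at the detected times: the a-wave from baseline
#' to trough, the b-wave from a-trough to b-peak, and the flicker peak from
#' the preceding trough to the peak.
#'
#' @param trace standard-grid `erg_trace` (or bare numeric voltage vector).
#' @param stimulus one of `"DA10"`, `"LA3"`, `"LA30Hz"`.
#' @param cfg configuration (cutoffs).
#' @return one-row data frame with `a_amp_uV`, `a_time_ms`, `b_amp_uV`,
#'   `b_time_ms` (flash) or `peak_amp_uV`, `peak_time_ms` (flicker), and a
#'   `quality` flag (`"ok"` or `"unmeasurable"`). Unmeasurable components are
#'   flagged, not raised as errors.
#' @export
detect_components <- function(trace, stimulus, cfg = default_config()) {
  v <- if (inherits(trace, "erg_trace")) trace$voltage_uV else as.numeric(trace)
  grid <- std_grid(cfg)
  if (length(v) != length(grid))
    stopf("trace is not on the standard grid (%d samples)", length(grid))
  stimulus <- match.arg(stimulus, STIMULI)
  fs <- 1000 / cfg$grid$by
  fl <- butter_lowpass(cfg$filter_order, cfg$filter_cutoff_hz[[stimulus]], fs)
  vf <- filtfilt(fl$b, fl$a, v)
  cr <- derivative_crossings(vf, cfg$grid$by)
  if (stimulus == "LA30Hz") {
    detect_flicker(v, grid, cr, cfg$min_time_ms$LA30Hz[["trough"]])
  } else {
    detect_flash(v, grid, cr, cfg$min_time_ms[[stimulus]])
  }
}

detect_flash <- function(v, grid, cr, cutoffs) {
  na_row <- data.frame(a_amp_uV = NA_real_, a_time_ms = NA_real_,
                       b_amp_uV = NA_real_, b_time_ms = NA_real_,
                       quality = "unmeasurable", stringsAsFactors = FALSE)
  a_ok <- cr$troughs[grid[cr$troughs] >= cutoffs[["a"]]]
  if (!length(a_ok)) return(na_row)
  ia <- a_ok[1]
  b_ok <- cr$peaks[cr$peaks > ia & grid[cr$peaks] >= cutoffs[["b"]]]
  if (!length(b_ok)) return(na_row)
  ib <- b_ok[1]
  data.frame(a_amp_uV = abs(v[1] - v[ia]), a_time_ms = grid[ia],
             b_amp_uV = v[ib] - v[ia], b_time_ms = grid[ib],
             quality = "ok", stringsAsFactors = FALSE)
}

detect_flicker <- function(v, grid, cr, cutoff) {
  na_row <- data.frame(peak_amp_uV = NA_real_, peak_time_ms = NA_real_,
                       quality = "unmeasurable", stringsAsFactors = FALSE)
  t_ok <- cr$troughs[grid[cr$troughs] >= cutoff]
  if (!length(t_ok)) return(na_row)
  it <- t_ok[1]
  p_ok <- cr$peaks[cr$peaks > it]
  if (!length(p_ok)) return(na_row)
  ip <- p_ok[1]
  data.frame(peak_amp_uV = v[ip] - v[it], peak_time_ms = grid[ip],
             quality = "ok", stringsAsFactors = FALSE)
}

## ---- cohort-level orchestration -------------------------------------------

## Preprocess a long TraceTable into per-(patient, eye, stimulus) matrices of
## standard-grid, baseline-corrected repeats, with repeat selection applied.
## Returns a data frame index plus a samples x traces matrix of the selected
## traces, shared by measurement and classifier feature building.
process_traces <- function(trace_table, cfg = default_config(),
                           verbose = FALSE) {
  validate_trace_table(trace_table)
  grid <- std_grid(cfg)
  key <- interaction(trace_table$patient_id, trace_table$eye,
                     trace_table$stimulus, drop = TRUE)
  groups <- split(seq_len(nrow(trace_table)), key)
  idx_rows <- list()
  mats <- list()
  flags <- character()
  for (g in names(groups)) {
    rows <- groups[[g]]
    sub <- trace_table[rows, ]
    stim <- sub$stimulus[1]
    reps <- split(seq_len(nrow(sub)), sub$repeat_)
    m <- vapply(reps, function(r) {
      if (min(sub$time_ms[r]) > grid[1] ||
          max(sub$time_ms[r]) < grid[length(grid)])
        stopf("trace %s/%s/%s repeat %s does not span the standard grid",
              sub$patient_id[1], sub$eye[1], stim, sub$repeat_[r[1]])
      stats::approx(sub$time_ms[r], sub$voltage_uV[r], xout = grid,
                    method = "linear")$y
    }, numeric(length(grid)))
    m <- baseline_correct_mat(m)
    rep_ids <- as.integer(names(reps))
    if (ncol(m) >= 2) {
      sel <- if (stim == "LA30Hz") select_traces_flicker(m, cfg$select_k, cfg)
             else select_traces_mse(m, cfg$select_k)
    } else {
      sel <- list(index = 1L, flag = "single_repeat")
    }
    m <- m[, sel$index, drop = FALSE]
    idx_rows[[g]] <- data.frame(
      patient_id = sub$patient_id[1], eye = sub$eye[1], stimulus = stim,
      repeat_ = rep_ids[sel$index], flag = sel$flag,
      stringsAsFactors = FALSE)
    mats[[g]] <- m
  }
  index <- do.call(rbind, c(idx_rows, list(make.row.names = FALSE)))
  list(index = index, voltages = do.call(cbind, mats), grid = grid)
}

#' Measure ERG components for a whole cohort
#'
#' Full measurement pipeline: resample each repeat to the standard grid,
#' baseline-correct, select repeats (minimum mutual MSE for the flash
#' stimuli, maximum 30 Hz signal for flicker), detect components on each
#' selected trace, then average component values over selected traces within
#' each eye and finally across available eyes per patient.
#'
#' @param trace_table long-format trace table (see [read_trace_table()]).
#' @param cfg configuration.
#' @param verbose emit progress messages.
#' @return list with `eye` (per patient/eye/stimulus component averages),
#'   `patient` (per patient/stimulus, averaged over eyes), and `selected`
#'   (the processed trace structure used for classification features).
#' @export
measure_cohort <- function(trace_table, cfg = default_config(),
                           verbose = FALSE) {
  pr <- process_traces(trace_table, cfg, verbose)
  eye <- measure_selected(pr, cfg)
  patient <- summarize_patient(eye)
  list(eye = eye, patient = patient, selected = pr)
}

## component detection + per-eye averaging on a processed trace structure
measure_selected <- function(pr, cfg = default_config()) {
  idx <- pr$index
  key <- interaction(idx$patient_id, idx$eye, idx$stimulus, drop = TRUE)
  out <- list()
  for (g in levels(key)) {
    rows <- which(key == g)
    stim <- idx$stimulus[rows[1]]
    per <- lapply(rows, function(r)
      detect_components(pr$voltages[, r], stim, cfg))
    per <- do.call(rbind, per)
    ok <- per$quality == "ok"
    base <- data.frame(patient_id = idx$patient_id[rows[1]],
                       eye = idx$eye[rows[1]], stimulus = stim,
                       n_traces = sum(ok), stringsAsFactors = FALSE)
    vals <- per[, setdiff(names(per), "quality"), drop = FALSE]
    if (any(ok)) {
      avg <- as.data.frame(as.list(colMeans(vals[ok, , drop = FALSE])))
      flag <- if (any(idx$flag[rows] != "ok")) idx$flag[rows][idx$flag[rows] != "ok"][1]
              else if (!all(ok)) "partial" else "ok"
    } else {
      avg <- as.data.frame(as.list(colMeans(vals)))  # all NA
      flag <- "missing"
    }
    out[[g]] <- cbind(base, avg, quality = flag, stringsAsFactors = FALSE)
  }
  ## flash and flicker rows have different columns; bind within stimulus type
  flash <- out[vapply(out, function(d) "a_amp_uV" %in% names(d), logical(1))]
  flick <- out[vapply(out, function(d) "peak_amp_uV" %in% names(d), logical(1))]
  res <- list()
  if (length(flash)) res$flash <- do.call(rbind, c(flash, list(make.row.names = FALSE)))
  if (length(flick)) res$flicker <- do.call(rbind, c(flick, list(make.row.names = FALSE)))
  merge_component_frames(res)
}

## combine flash/flicker frames into one long frame with shared columns
merge_component_frames <- function(res) {
  cols <- c("patient_id", "eye", "stimulus", "n_traces",
            "a_amp_uV", "a_time_ms", "b_amp_uV", "b_time_ms",
            "peak_amp_uV", "peak_time_ms", "quality")
  fill <- function(d) {
    for (cn in setdiff(cols, names(d))) d[[cn]] <- NA_real_
    d[, cols]
  }
  out <- do.call(rbind, c(lapply(res, fill), list(make.row.names = FALSE)))
  out[order(out$patient_id, out$stimulus, out$eye), , drop = FALSE]
}

#' Average eye-level components per patient
#'
#' Component values are averaged across available eyes; patients with a
#' single recorded eye use that eye alone. Stimuli with no measurable trace
#' in either eye are flagged `"missing"`.
#'
#' @param eye eye-level component frame from [measure_cohort()].
#' @return per-(patient, stimulus) component frame.
#' @export
summarize_patient <- function(eye) {
  if (!nrow(eye)) stopf("no eye-level measurements")
  key <- interaction(eye$patient_id, eye$stimulus, drop = TRUE)
  vals <- c("a_amp_uV", "a_time_ms", "b_amp_uV", "b_time_ms",
            "peak_amp_uV", "peak_time_ms")
  rows <- lapply(levels(key), function(g) {
    sub <- eye[key == g, , drop = FALSE]
    ok <- sub$quality != "missing"
    base <- data.frame(patient_id = sub$patient_id[1],
                       stimulus = sub$stimulus[1],
                       n_eyes = sum(ok), stringsAsFactors = FALSE)
    if (any(ok)) {
      avg <- as.data.frame(lapply(sub[ok, vals, drop = FALSE], mean))
      qual <- if (all(sub$quality[ok] == "ok")) "ok" else "partial"
    } else {
      avg <- as.data.frame(lapply(sub[, vals, drop = FALSE], function(x) NA_real_))
      qual <- "missing"
    }
    cbind(base, avg, quality = qual, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$patient_id, out$stimulus), , drop = FALSE]
}
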