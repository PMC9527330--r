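## Synthetic ERG cohort generator. Stands in for the non-public clinical
## dataset: group-structured DA/LA waveform parameters, age-related
## amplitude decline, 3-8 repeats per eye with noise/drift/blink artifacts,
## high interocular symmetry, and a biallelic variant model in which disease
## severity is driven by the milder allele.

COMPONENTS <- c("da10_a", "da10_b", "la3_a", "la3_b", "la30hz_peak")
DA_COMPONENTS <- c("da10_a", "da10_b")
LA_COMPONENTS <- c("la3_a", "la3_b", "la30hz_peak")

#' Default per-stimulus waveform parameters
#'
#' Plausible ISCEV-range group-1 values: DA 10 a-wave 250 uV at 15 ms and
#' b-wave 400 uV at 48 ms; LA 3 a-wave 30 uV at 15 ms and b-wave 120 uV at
#' 30 ms; 30 Hz flicker fundamental 90 uV; Gaussian lobe widths 4 and 12 ms.
#' These are generator defaults, not clinical claims.
#'
#' @param ... named overrides (recursively merged).
#' @return nested list of class `wave_params`.
#' @export
default_wave_params <- function(...) {
  p <- list(
    DA10   = list(A_a = 250, t_a = 15, A_b = 400, t_b = 48,
                  sigma_a = 4, sigma_b = 12),
    ## narrower, later LA3 b-lobe than DA10: with sigma_b >= ~10 at t_b = 30
    ## the b-lobe's rising slope at t_a would exceed the small a-lobe's
    ## falling slope and the summed model would have no a-wave trough to
    ## detect at all; these values give a clear ~24-uV trough
    LA3    = list(A_a = 30, t_a = 15, A_b = 120, t_b = 32,
                  sigma_a = 3, sigma_b = 7),
    LA30Hz = list(A_f = 90, phase_ms = 0),
    noise_sd = 2.5, drift_amp = 5, blink_prob = 0.05, offset_sd = 15,
    n_repeats = c(3L, 8L)
  )
  p <- modify_list_deep(p, list(...))
  validate_wave_params(p)
  structure(p, class = "wave_params")
}

validate_wave_params <- function(p) {
  for (st in c("DA10", "LA3")) {
    s <- p[[st]]
    if (s$A_a < 0 || s$A_b < 0) stopf("%s amplitudes must be >= 0", st)
    if (s$t_a >= s$t_b) stopf("%s requires t_a < t_b", st)
  }
  if (p$LA30Hz$A_f < 0) stopf("flicker amplitude must be >= 0")
  if (max(p$n_repeats) < 2) stopf("need n_repeats >= 2")
  invisible(p)
}

## closed-form noiseless waveform on a time grid
wave_model <- function(p, stimulus, t) {
  if (stimulus == "LA30Hz") {
    s <- p$LA30Hz
    s$A_f * sin(2 * pi * 30 * (t - s$phase_ms) / 1000) +
      0.2 * s$A_f * sin(2 * pi * 60 * (t - s$phase_ms) / 1000)
  } else {
    s <- p[[stimulus]]
    -s$A_a * exp(-(t - s$t_a)^2 / (2 * s$sigma_a^2)) +
      s$A_b * exp(-(t - s$t_b)^2 / (2 * s$sigma_b^2))
  }
}

#' Simulate one raw ERG repeat
#'
#' Two-Gaussian-lobe model for the flash stimuli; 30 Hz fundamental plus a
#' 20% second harmonic for flicker. White noise, a slow sinusoidal drift, a
#' random DC offset and (with probability `blink_prob`) a 300-uV blink
#' transient of 20-ms width at a random time are added on top.
#'
#' @param params `wave_params` list.
#' @param stimulus `"DA10"`, `"LA3"` or `"LA30Hz"`.
#' @param time_ms native sampling grid (default 0-82 ms at 0.4-ms steps; must
#'   cover at least 0-80 ms).
#' @param patient,eye,repeat_ key fields for the returned trace.
#' @return an [raw_trace()] object.
#' @export
generate_trace <- function(params, stimulus, time_ms = seq(0, 82, by = 0.4),
                           patient = "sim", eye = "R", repeat_ = 1L) {
  stimulus <- match.arg(stimulus, STIMULI)
  v <- wave_model(params, stimulus, time_ms)
  v <- v + generate_artifacts(params, time_ms)
  raw_trace(time_ms, v, patient, eye, stimulus, repeat_)
}

generate_artifacts <- function(params, t) {
  n <- length(t)
  art <- stats::rnorm(1, 0, params$offset_sd) + stats::rnorm(n, 0, params$noise_sd)
  if (params$drift_amp > 0) {
    f <- stats::runif(1, 2, 8)
    art <- art + params$drift_amp * sin(2 * pi * f * t / 1000 +
                                          stats::runif(1, 0, 2 * pi))
  }
  if (stats::runif(1) < params$blink_prob) {
    ## 300-uV blink transient; 20-ms Gaussian width parameter (real blink
    ## artifacts are slow, ~50-300 ms events, with little 30-Hz content)
    ctr <- stats::runif(1, min(t), max(t))
    art <- art + 300 * exp(-(t - ctr)^2 / (2 * 20^2))
  }
  art
}

## ---- group assignment ------------------------------------------------------

#' Assign the functional phenotype group from component amplitudes
#'
#' Group 1: all five full-field amplitudes at or above their normative
#' limits (dysfunction confined to the macula). Group 2: any light-adapted
#' (cone-driven) amplitude below its limit while the dark-adapted amplitudes
#' remain normal. Group 3: any dark-adapted (rod-system) amplitude below its
#' limit, regardless of the LA components.
#'
#' @param amps named numeric vector (or matrix with named columns) with
#'   entries `da10_a, da10_b, la3_a, la3_b, la30hz_peak`.
#' @param limits normative lower limits, same names (vector or matrix).
#' @return integer group label(s) in 1:3.
#' @export
assign_group <- function(amps, limits) {
  if (is.null(dim(amps))) amps <- matrix(amps, 1, dimnames = list(NULL, names(amps)))
  if (is.null(dim(limits))) limits <- matrix(limits, nrow(amps), length(limits),
                                             byrow = TRUE,
                                             dimnames = list(NULL, names(limits)))
  below <- amps[, COMPONENTS, drop = FALSE] < limits[, COMPONENTS, drop = FALSE]
  da_low <- rowSums(below[, DA_COMPONENTS, drop = FALSE]) > 0
  la_low <- rowSums(below[, LA_COMPONENTS, drop = FALSE]) > 0
  out <- ifelse(da_low, 3L, ifelse(la_low, 2L, 1L))
  as.integer(out)
}

#' Default simulator settings
#'
#' Group mix defaults to the prevalence structure assumed throughout
#' (57.6 / 7.4 / 35.0 percent); age-related amplitude decline defaults to the
#' group-1 cross-sectional rates (uV/y); light-adapted amplitudes of groups
#' 2-3 are scaled by 0.35 with peak times delayed 6 ms, and dark-adapted
#' amplitudes additionally scaled by 0.35 in group 3, so that group 3 has the
#' lowest amplitudes and longest peak times.
#'
#' @param ... named overrides.
#' @return list of simulator settings.
#' @export
default_sim_params <- function(...) {
  p <- list(
    mode = "mix",                        # "mix" or "genotype"
    group_mix = c(0.576, 0.074, 0.35),
    age_range = c(8, 70),
    age_ref = 10,
    age_rates = c(da10_a = -1.46, da10_b = -1.72, la3_a = -0.20,
                  la3_b = -0.75, la30hz_peak = -0.41),
    la_scale = 0.35, da_scale = 0.35, la_delay_ms = 6,
    interocular_rho = 0.95,
    unilateral_frac = 5 / 597,
    norm_spread = 0.15,                  # relative sd defining normative limits
    time_jitter_ms = 0.3,
    amp_floor_uV = 1,
    pupil_small_frac = 0.2,
    severity_gain = 0.9                  # depth of genotype-driven loss
  )
  modify_list_deep(p, list(...))
}

## group-1 mean amplitude for each component at given ages (matrix n x 5)
base_amplitudes <- function(age, wave, sim) {
  base <- c(da10_a = wave$DA10$A_a, da10_b = wave$DA10$A_b,
            la3_a = wave$LA3$A_a, la3_b = wave$LA3$A_b,
            la30hz_peak = wave$LA30Hz$A_f)
  out <- outer(age - sim$age_ref, sim$age_rates[COMPONENTS]) +
    matrix(base[COMPONENTS], length(age), 5, byrow = TRUE)
  colnames(out) <- COMPONENTS
  pmax(out, sim$amp_floor_uV)
}

#' Normative amplitude limits
#'
#' Age-corrected lower limits of normal, taken as the 5th percentile of the
#' group-1 generative distribution: the group-1 mean amplitude at that age
#' times `exp(-1.6449 * norm_spread)`.
#'
#' @param age numeric vector of ages.
#' @param wave `wave_params`.
#' @param sim simulator settings.
#' @return matrix (length(age) x 5) of limits, columns `COMPONENTS`.
#' @export
normative_limits <- function(age, wave = default_wave_params(),
                             sim = default_sim_params()) {
  base_amplitudes(age, wave, sim) * exp(-stats::qnorm(0.95) * sim$norm_spread)
}

## ---- variant panel ---------------------------------------------------------

#' Construct a default synthetic variant panel
#'
#' A panel of HGVS-style labelled variants with allele severities spread over
#' [0, 1] and skewed population frequencies (a few common alleles, a long
#' rare tail), emulating the allelic architecture of a recessive
#' maculopathy: the commonest alleles are mild.
#'
#' @param n_variants panel size (default 30).
#' @return data frame with `variant_id`, `severity`, `freq` (sums to 1).
#' @export
default_variant_panel <- function(n_variants = 30L) {
  id <- sprintf("c.%dA>G", 100 + 137 * seq_len(n_variants))
  sev <- seq(0, 1, length.out = n_variants)
  ## mild variants common, severe rarer; Zipf-like tail
  w <- (1 / rank(sev, ties.method = "first"))^0.7
  data.frame(variant_id = id, severity = sev, freq = w / sum(w),
             stringsAsFactors = FALSE)
}

## severity multipliers from two allele severities: the milder allele
## dominates (min-weighted product); the dark-adapted (rod) system is less
## susceptible than the cone system, so intermediate genotypes lose LA
## amplitudes first
severity_multipliers <- function(s1, s2, gain = 0.9) {
  prod <- pmin(s1, s2) * pmax(s1, s2)
  list(la = 1 - gain * prod, da = 1 - gain * prod^1.5)
}

## ---- cohort generation -----------------------------------------------------

#' Generate a synthetic cohort with ground truth
#'
#' Per patient: demographics, two alleles drawn from the variant panel, and
#' per-component true amplitudes derived either from a directly sampled
#' group label (`mode = "mix"`; scalings in [default_sim_params()]) or from
#' the genotype (`mode = "genotype"`; multiplier `1 - 0.9 * min(s) * max(s)`
#' on the light-adapted amplitudes, so one mild allele keeps full-field
#' responses normal). Eyes share the patient's parameters with a small
#' independent perturbation calibrated so that the cohort-level interocular
#' correlation of each amplitude is approximately `interocular_rho`; a
#' configurable fraction of patients is unilateral. The expert group label
#' is assigned deterministically from the true patient-level amplitudes and
#' the age-corrected normative limits.
#'
#' @param n number of patients (>= 1).
#' @param wave `wave_params` waveform/noise settings.
#' @param sim simulator settings ([default_sim_params()]).
#' @param panel variant panel data frame (`variant_id`, `severity`, `freq`).
#' @param seed integer seed; the generator is fully reproducible.
#' @param with_traces simulate raw waveforms (default). `FALSE` skips trace
#'   synthesis and returns only metadata and ground truth, for fast
#'   parameter-recovery studies.
#' @return list with `traces` (long trace table), `cohort` (metadata table),
#'   `truth` (list: `patient` and `eye` true component tables, allele
#'   severities, multipliers), `panel`, `wave`, `sim`.
#' @export
generate_cohort <- function(n, wave = default_wave_params(),
                            sim = default_sim_params(),
                            panel = default_variant_panel(),
                            seed = 1L, with_traces = TRUE) {
  if (n < 1) stopf("n must be >= 1")
  if (!nrow(panel)) stopf("empty variant panel")
  with_seed(seed, {
    ids <- sprintf("P%04d", seq_len(n))
    age <- stats::runif(n, sim$age_range[1], sim$age_range[2])
    sex <- sample(c("M", "F"), n, replace = TRUE)
    pupil <- sample(c(">=7mm", "<7mm"), n, replace = TRUE,
                    prob = c(1 - sim$pupil_small_frac, sim$pupil_small_frac))
    compliance <- sample(1:5, n, replace = TRUE,
                         prob = c(0.02, 0.08, 0.2, 0.35, 0.35))
    a1 <- sample(panel$variant_id, n, replace = TRUE, prob = panel$freq)
    a2 <- sample(panel$variant_id, n, replace = TRUE, prob = panel$freq)
    s1 <- panel$severity[match(a1, panel$variant_id)]
    s2 <- panel$severity[match(a2, panel$variant_id)]

    base <- base_amplitudes(age, wave, sim)
    scale <- matrix(1, n, 5, dimnames = list(NULL, COMPONENTS))
    delay_la <- numeric(n)
    if (sim$mode == "mix") {
      g_int <- sample(1:3, n, replace = TRUE, prob = sim$group_mix)
      scale[g_int >= 2, LA_COMPONENTS] <- sim$la_scale
      scale[g_int == 3, DA_COMPONENTS] <- sim$da_scale
      delay_la[g_int >= 2] <- sim$la_delay_ms
    } else if (sim$mode == "genotype") {
      mult <- severity_multipliers(s1, s2, sim$severity_gain)
      scale[, LA_COMPONENTS] <- mult$la
      scale[, DA_COMPONENTS] <- mult$da
      delay_la <- sim$la_delay_ms * (1 - mult$la)
      g_int <- rep(NA_integer_, n)
    } else stopf("unknown simulator mode '%s'", sim$mode)

    amp_pat <- pmax(base * scale, sim$amp_floor_uV)
    limits <- normative_limits(age, wave, sim)
    group <- assign_group(amp_pat, limits)

    ## Eye-level asymmetry: a common multiplicative response-scale factor per
    ## eye (interocular asymmetry is predominantly global, and a shared
    ## factor keeps the overlapping-lobe amplitude readout coherent), with
    ## its sd calibrated so the DA10 b-wave interocular correlation is the
    ## target rho: Var_between / (Var_between + mean_amp^2 * sigma_f^2) = rho.
    rho <- sim$interocular_rho
    sigma_f <- if (rho >= 1) 0 else
      stats::sd(amp_pat[, "da10_b"]) * sqrt(1 / rho - 1) /
        mean(amp_pat[, "da10_b"])
    t_jit <- if (rho >= 1) 0 else sim$time_jitter_ms

    bilateral <- stats::runif(n) >= sim$unilateral_frac
    eye_rows <- list(); trace_chunks <- list(); ci <- 0L
    for (i in seq_len(n)) {
      eyes <- if (bilateral[i]) EYES else sample(EYES, 1)
      for (e in eyes) {
        amp_eye <- pmax(amp_pat[i, ] * (1 + stats::rnorm(1, 0, sigma_f)),
                        sim$amp_floor_uV)
        wp <- wave
        wp$DA10$A_a <- amp_eye[["da10_a"]]; wp$DA10$A_b <- amp_eye[["da10_b"]]
        wp$LA3$A_a <- amp_eye[["la3_a"]];  wp$LA3$A_b <- amp_eye[["la3_b"]]
        wp$LA30Hz$A_f <- amp_eye[["la30hz_peak"]]
        wp$LA3$t_a <- wave$LA3$t_a + delay_la[i] + stats::rnorm(1, 0, t_jit)
        wp$LA3$t_b <- wave$LA3$t_b + delay_la[i] + stats::rnorm(1, 0, t_jit)
        wp$LA30Hz$phase_ms <- wave$LA30Hz$phase_ms + delay_la[i] +
          stats::rnorm(1, 0, t_jit)
        wp$DA10$t_a <- wave$DA10$t_a + stats::rnorm(1, 0, t_jit)
        wp$DA10$t_b <- wave$DA10$t_b + stats::rnorm(1, 0, t_jit)
        if (with_traces) {
          n_rep <- if (length(wave$n_repeats) > 1)
            sample(seq(wave$n_repeats[1], wave$n_repeats[2]), 1)
          else wave$n_repeats
          for (st in STIMULI) {
            for (r in seq_len(n_rep)) {
              tr <- generate_trace(wp, st, patient = ids[i], eye = e,
                                   repeat_ = r)
              ci <- ci + 1L
              trace_chunks[[ci]] <- list(id = ids[i], eye = e, st = st, r = r,
                                         t = tr$time_ms, v = tr$voltage_uV)
            }
          }
        }
        eye_rows[[length(eye_rows) + 1L]] <- data.frame(
          patient_id = ids[i], eye = e, t(amp_eye), stringsAsFactors = FALSE)
      }
    }

    nsamp <- vapply(trace_chunks, function(x) length(x$t), integer(1))
    traces <- if (!with_traces) NULL else data.frame(
      patient_id = rep(vapply(trace_chunks, `[[`, character(1), "id"), nsamp),
      eye = rep(vapply(trace_chunks, `[[`, character(1), "eye"), nsamp),
      stimulus = rep(vapply(trace_chunks, `[[`, character(1), "st"), nsamp),
      repeat_ = rep(vapply(trace_chunks, `[[`, integer(1), "r"), nsamp),
      time_ms = unlist(lapply(trace_chunks, `[[`, "t")),
      voltage_uV = unlist(lapply(trace_chunks, `[[`, "v")),
      stringsAsFactors = FALSE)

    cohort <- data.frame(
      patient_id = ids, age_years = age, sex = sex, pupil_class = pupil,
      compliance = compliance, group_label = group,
      variant_a = a1, variant_b = a2, stringsAsFactors = FALSE)

    truth_pat <- data.frame(
      patient_id = ids, age_years = age, group = group,
      intended_group = g_int, severity_1 = s1, severity_2 = s2,
      amp_pat, stringsAsFactors = FALSE)
    truth_eye <- do.call(rbind, c(eye_rows, list(make.row.names = FALSE)))

    list(traces = traces, cohort = cohort,
         truth = list(patient = truth_pat, eye = truth_eye),
         panel = panel, wave = wave, sim = sim, seed = seed)
  })
}

#' Ground-truth component tables from a simulated cohort
#'
#' Builds eye- and patient-level component tables directly from the
#' generator's true amplitudes (bypassing trace measurement), in the same
#' layout as [measure_cohort()] output. Peak times are the generative means.
#' Useful for fast parameter-recovery studies.
#'
#' @param cohort_sim result of [generate_cohort()].
#' @return list with `eye` and `patient` component data frames.
#' @export
true_component_set <- function(cohort_sim) {
  te <- cohort_sim$truth$eye
  wave <- cohort_sim$wave
  mk <- function(d, with_eye) {
    rows <- list(
      data.frame(stimulus = "DA10", a_amp_uV = d$da10_a, a_time_ms = wave$DA10$t_a,
                 b_amp_uV = d$da10_b, b_time_ms = wave$DA10$t_b,
                 peak_amp_uV = NA_real_, peak_time_ms = NA_real_),
      data.frame(stimulus = "LA3", a_amp_uV = d$la3_a, a_time_ms = wave$LA3$t_a,
                 b_amp_uV = d$la3_b, b_time_ms = wave$LA3$t_b,
                 peak_amp_uV = NA_real_, peak_time_ms = NA_real_),
      data.frame(stimulus = "LA30Hz", a_amp_uV = NA_real_, a_time_ms = NA_real_,
                 b_amp_uV = NA_real_, b_time_ms = NA_real_,
                 peak_amp_uV = d$la30hz_peak, peak_time_ms = 10))
    out <- do.call(rbind, lapply(rows, function(r) {
      r <- cbind(patient_id = d$patient_id, r, stringsAsFactors = FALSE)
      if (with_eye) r$eye <- d$eye
      r$quality <- "ok"
      r
    }))
    out
  }
  eye <- mk(te, with_eye = TRUE)
  pat_amp <- stats::aggregate(te[, COMPONENTS], by = list(patient_id = te$patient_id),
                              FUN = mean)
  patient <- mk(pat_amp, with_eye = FALSE)
  list(eye = eye[order(eye$patient_id, eye$stimulus, eye$eye), ],
       patient = patient[order(patient$patient_id, patient$stimulus), ])
}
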