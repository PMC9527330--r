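## shared fixtures, all built in code

GRID <- seq(0, 80, by = 0.5)

## noiseless two-lobe flash model on the standard grid
flash_model <- function(A_a = 250, t_a = 15, A_b = 400, t_b = 45,
                        sigma_a = 4, sigma_b = 12, t = GRID) {
  -A_a * exp(-(t - t_a)^2 / (2 * sigma_a^2)) +
    A_b * exp(-(t - t_b)^2 / (2 * sigma_b^2))
}

std_trace <- function(v, patient = "T", eye = "R", stimulus = "DA10",
                      repeat_ = 1L) {
  tr <- raw_trace(GRID, v, patient, eye, stimulus, repeat_)
  class(tr) <- c("erg_stdtrace", "erg_trace")
  tr
}

## long-format trace table from a voltage matrix (columns = repeats)
trace_table_from_matrix <- function(v, patient = "P1", eye = "R",
                                    stimulus = "DA10") {
  n <- length(GRID)
  data.frame(patient_id = patient, eye = eye, stimulus = stimulus,
             repeat_ = rep(seq_len(ncol(v)), each = n),
             time_ms = rep(GRID, ncol(v)),
             voltage_uV = as.vector(v), stringsAsFactors = FALSE)
}

## independent exhaustive-search oracle for MSE triple selection
mse_oracle <- function(v, k = 3L) {
  n <- ncol(v)
  combos <- utils::combn(n, k)
  best <- NULL; best_score <- Inf
  for (ci in seq_len(ncol(combos))) {
    ix <- combos[, ci]
    s <- 0
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      s <- s + mean((v[, ix[a]] - v[, ix[b]])^2)
    }
    if (s < best_score - 1e-12) { best_score <- s; best <- ix }
  }
  best
}

## tiny cohort metadata table
make_cohort <- function(n, group = rep(1L, n), age = seq(10, 60, length.out = n),
                        va = NA, vb = NA) {
  data.frame(patient_id = sprintf("P%03d", seq_len(n)), age_years = age,
             sex = rep(c("M", "F"), length.out = n),
             pupil_class = rep(c(">=7mm", "<7mm"), length.out = n),
             compliance = rep(3:5, length.out = n), group_label = group,
             variant_a = va, variant_b = vb, stringsAsFactors = FALSE)
}

## Separable classifier fixture: the class label is a deterministic function
## of one underlying per-patient response-scale factor, which (as in real
## ERGs) is reflected across the whole waveform; traces add small noise.
separable_features <- function(n_per_class = 10, traces_per = 1L,
                               eyes = c("L", "R"), seed = 42,
                               noise_sd = 0.3) {
  withr::with_seed(seed, {
    n <- 3 * n_per_class
    ids <- sprintf("P%03d", seq_len(n))
    cl <- rep(1:3, each = n_per_class)
    scale_f <- c(1, 0.5, 0.15)[cl] + runif(n, -0.05, 0.05)
    age <- runif(n, 10, 70)
    shape <- flash_model(1, 15, 1.6, 45, 4, 12)   # unit waveform
    rows <- expand.grid(trace = seq_len(traces_per), eye = eyes,
                        stimulus = c("DA10", "LA3", "LA30Hz"), pid = ids,
                        stringsAsFactors = FALSE)
    meta <- data.frame(patient_id = rows$pid, eye = rows$eye,
                       stimulus = rows$stimulus, repeat_ = rows$trace,
                       flag = "ok", stringsAsFactors = FALSE)
    v <- outer(shape, scale_f[match(rows$pid, ids)]) +
      matrix(rnorm(161 * nrow(rows), sd = noise_sd), 161)
    x <- cbind(t(v), age_years = age[match(rows$pid, ids)], pupil_small = 0)
    colnames(x) <- c(sprintf("v%03d", 1:161), "age_years", "pupil_small")
    list(features = list(meta = meta, x = x),
         labels = stats::setNames(cl, ids))
  })
}

## small hyperparameter grids so CV tests stay within the time budget
tiny_cv_config <- function(repeats = 1L, final_C = 1, seed = 1L, ...) {
  default_config(cv = list(repeats = repeats),
                 grids = list(svm = list(C = 1, gamma = "scale"),
                              ada = list(depth = 1L, n_estimators = 25L),
                              lr = list(C = 1),
                              final_svm = list(C = final_C)),
                 seed = seed, ...)
}
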