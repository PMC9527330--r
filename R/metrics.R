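## Cohort-level descriptive statistics: prevalence, eye accounting,
## interocular symmetry, age trends, confusion-matrix summaries and
## per-variant group profiles.

#' Group prevalence
#'
#' Counts and percentages (half-up rounded to one decimal) per phenotype
#' group.
#'
#' @param labels vector of group labels in \{1, 2, 3\}.
#' @return data frame with `group`, `count`, `percent`.
#' @export
prevalence <- function(labels) {
  if (!length(labels)) stopf("empty label vector")
  labels <- as.integer(as.character(labels))
  if (any(!labels %in% 1:3)) stopf("labels must be in 1..3")
  cnt <- vapply(1:3, function(g) sum(labels == g), integer(1))
  data.frame(group = 1:3, count = cnt,
             percent = round_half_up(100 * cnt / length(labels), 1))
}

#' Eye accounting
#'
#' @param cohort cohort table.
#' @param traces trace table (eyes counted from recorded traces).
#' @return list with `patients`, `bilateral`, `unilateral`, `eyes`
#'   (`eyes = 2 * bilateral + unilateral`).
#' @export
eye_accounting <- function(cohort, traces) {
  extra <- setdiff(unique(traces$patient_id), cohort$patient_id)
  if (length(extra)) stopf("trace patient '%s' absent from cohort table",
                           extra[1])
  eye_per_pat <- tapply(traces$eye, traces$patient_id,
                        function(e) length(unique(e)))
  bilateral <- sum(eye_per_pat == 2)
  unilateral <- sum(eye_per_pat == 1)
  list(patients = length(eye_per_pat), bilateral = bilateral,
       unilateral = unilateral, eyes = 2L * bilateral + unilateral)
}

#' Interocular symmetry of component amplitudes
#'
#' Pearson correlation between left- and right-eye values over bilateral
#' patients, and the through-origin regression slope
#' `sum(L * R) / sum(L^2)` (right on left, intercept 0), per component.
#'
#' @param eye_components eye-level component table ([measure_cohort()]`$eye`).
#' @return data frame with `component`, `n`, `r`, `slope`.
#' @export
interocular_symmetry <- function(eye_components) {
  specs <- list(da10_a = c("DA10", "a_amp_uV"), da10_b = c("DA10", "b_amp_uV"),
                la3_a = c("LA3", "a_amp_uV"), la3_b = c("LA3", "b_amp_uV"),
                la30hz_peak = c("LA30Hz", "peak_amp_uV"))
  present <- Filter(function(cmp) any(eye_components$stimulus == specs[[cmp]][1]),
                    names(specs))
  rows <- lapply(present, function(cmp) {
    sub <- eye_components[eye_components$stimulus == specs[[cmp]][1], ]
    val <- sub[[specs[[cmp]][2]]]
    l <- val[sub$eye == "L"][match(unique(sub$patient_id),
                                   sub$patient_id[sub$eye == "L"])]
    r <- val[sub$eye == "R"][match(unique(sub$patient_id),
                                   sub$patient_id[sub$eye == "R"])]
    ok <- !is.na(l) & !is.na(r)
    if (sum(ok) < 3) stopf("fewer than 3 bilateral pairs for %s", cmp)
    l <- l[ok]; r <- r[ok]
    data.frame(component = cmp, n = sum(ok),
               r = stats::cor(l, r), slope = sum(l * r) / sum(l^2))
  })
  rbind_rows(rows)
}

#' Age trends of component values per group
#'
#' Ordinary least-squares slope of each component value on age within each
#' group, with the Pearson correlation test; the `nd` ("no decline
#' detected") flag is set when the correlation is not significant at
#' `alpha`.
#'
#' @param patient_components patient-level component table.
#' @param cohort cohort table providing `age_years` and `group_label`.
#' @param value one of `"amp"` (amplitudes) or `"time"` (peak times).
#' @param alpha significance gate (default 0.05).
#' @param min_n minimum patients per (group, component) cell.
#' @return data frame with `group`, `component`, `n`, `slope`, `intercept`,
#'   `r`, `p`, `nd`.
#' @export
age_trends <- function(patient_components, cohort, value = "amp",
                       alpha = 0.05, min_n = 5L) {
  amp <- component_amplitudes(patient_components)
  if (value == "time") {
    pc <- patient_components
    amp <- amp * NA
    pick <- list(da10_a = c("DA10", "a_time_ms"), da10_b = c("DA10", "b_time_ms"),
                 la3_a = c("LA3", "a_time_ms"), la3_b = c("LA3", "b_time_ms"),
                 la30hz_peak = c("LA30Hz", "peak_time_ms"))
    for (cmp in names(pick)) {
      sub <- pc[pc$stimulus == pick[[cmp]][1], ]
      amp[match(sub$patient_id, rownames(amp)), cmp] <- sub[[pick[[cmp]][2]]]
    }
  }
  age <- cohort$age_years[match(rownames(amp), cohort$patient_id)]
  grp <- cohort$group_label[match(rownames(amp), cohort$patient_id)]
  rows <- list()
  for (g in sort(unique(grp))) {
    for (cmp in colnames(amp)) {
      sel <- grp == g & !is.na(amp[, cmp]) & !is.na(age)
      if (sum(sel) < min_n) next
      x <- age[sel]; y <- amp[sel, cmp]
      if (stats::sd(x) < 1e-12) stopf("degenerate (constant) age in group %s", g)
      fit <- stats::lm.fit(cbind(1, x), y)
      if (stats::sd(y) < 1e-12) {
        ## constant response: no association, trivially "no decline"
        rows[[length(rows) + 1]] <- data.frame(
          group = g, component = cmp, n = sum(sel), slope = 0,
          intercept = mean(y), r = NA_real_, p = NA_real_, nd = TRUE)
        next
      }
      ct <- stats::cor.test(x, y)
      rows[[length(rows) + 1]] <- data.frame(
        group = g, component = cmp, n = sum(sel),
        slope = fit$coefficients[2], intercept = fit$coefficients[1],
        r = unname(ct$estimate), p = ct$p.value, nd = ct$p.value >= alpha)
    }
  }
  rbind_rows(rows)
}

#' Confusion matrix (counts and row-normalized)
#'
#' @param truth,predicted label vectors.
#' @param classes class order (default: sorted union).
#' @return list with `counts` and `normalized` (rows sum to 1).
#' @export
confusion_matrix <- function(truth, predicted,
                             classes = sort(unique(c(truth, predicted)))) {
  cm <- table(factor(truth, levels = classes),
              factor(predicted, levels = classes))
  counts <- matrix(as.integer(cm), length(classes),
                   dimnames = list(truth = classes, predicted = classes))
  rs <- rowSums(counts)
  norm <- counts / ifelse(rs == 0, 1, rs)
  list(counts = counts, normalized = norm)
}

#' Cohen's kappa from a confusion matrix
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with expected agreement `p_e` computed
#' from the marginals.
#'
#' @param cm square matrix of counts.
#' @return kappa (scalar); `NA` with a warning when `p_e = 1`.
#' @export
cohen_kappa <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stopf("confusion matrix must be square")
  n <- sum(cm)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (abs(1 - pe) < 1e-12) {
    warning("expected agreement is 1; kappa undefined")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' One-vs-rest AUC per class
#'
#' Rank-statistic (Mann-Whitney) AUC of each class's probability column
#' against all other classes, with midrank tie handling.
#'
#' @param labels true labels.
#' @param probs matrix of class probabilities, columns named by class.
#' @return named numeric vector of per-class AUCs (NA for classes absent
#'   from `labels`).
#' @export
ovr_auc <- function(labels, probs) {
  vapply(colnames(probs), function(cl) {
    pos <- labels == cl
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) return(NA_real_)
    r <- rank(probs[, cl])
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
}

#' Per-variant phenotype group profiles, expert vs model
#'
#' For each variant carried by at least `min_carriers` patients, the
#' percentage of its carriers falling in each group, according to the
#' expert labels and to the model predictions.
#'
#' @param cohort cohort table (expert labels in `group_label`).
#' @param predictions data frame with `patient_id` and `predicted` (1/2/3);
#'   multiple rows per patient (e.g. CV repeats) are reduced by majority.
#' @param min_carriers panel threshold (default 5).
#' @return list with `expert` and `model` data frames (`variant_id`, `n`,
#'   `pct_g1`, `pct_g2`, `pct_g3`; rows sum to 100 up to rounding).
#' @export
variant_group_profile <- function(cohort, predictions, min_carriers = 5L) {
  pred_pat <- tapply(as.character(predictions$predicted),
                     predictions$patient_id, function(v)
                       names(sort(table(v), decreasing = TRUE))[1])
  carriers <- data.frame(
    variant_id = c(cohort$variant_a, cohort$variant_b),
    patient_id = rep(cohort$patient_id, 2), stringsAsFactors = FALSE)
  carriers <- unique(carriers[!is.na(carriers$variant_id) &
                                carriers$variant_id != "", ])
  tab <- table(carriers$variant_id)
  panel <- names(tab)[tab >= min_carriers]
  prof <- function(lab_of) {
    rows <- lapply(panel, function(v) {
      pats <- carriers$patient_id[carriers$variant_id == v]
      labs <- lab_of(pats)
      labs <- labs[!is.na(labs)]
      pct <- vapply(1:3, function(g)
        round_half_up(100 * sum(labs == g) / length(labs), 1), numeric(1))
      data.frame(variant_id = v, n = length(labs), pct_g1 = pct[1],
                 pct_g2 = pct[2], pct_g3 = pct[3])
    })
    rbind_rows(rows)
  }
  list(expert = prof(function(p)
         cohort$group_label[match(p, cohort$patient_id)]),
       model = prof(function(p) as.integer(pred_pat[p])))
}
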