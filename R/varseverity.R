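## Elastic-net quantification of per-variant severity: genotype (allele
## counts) plus age/sex/pupil covariates regressed onto z-scored ERG
## component amplitudes, with LOOCV r-squared and cross-component
## concordance of the standardized coefficients.

AMP_COMPONENTS <- c(da10_a = "DA10.a_amp_uV", da10_b = "DA10.b_amp_uV",
                    la3_a = "LA3.a_amp_uV", la3_b = "LA3.b_amp_uV",
                    la30hz_peak = "LA30Hz.peak_amp_uV")
COVARIATES <- c("age_years", "sex_M", "pupil_small")

## default cis pairs: the hypomorphic c.5603A>T is treated as part of a
## complex allele when co-occurring with either known partner
DEFAULT_CIS_PAIRS <- list(c("c.2588G>C", "c.5603A>T"),
                          c("c.5461-10T>C", "c.5603A>T"))

## wide per-patient amplitude matrix from a patient-level component table
component_amplitudes <- function(patient_components) {
  pc <- patient_components
  ids <- sort(unique(pc$patient_id))
  out <- matrix(NA_real_, length(ids), 5,
                dimnames = list(ids, names(AMP_COMPONENTS)))
  pick <- list(da10_a = c("DA10", "a_amp_uV"), da10_b = c("DA10", "b_amp_uV"),
               la3_a = c("LA3", "a_amp_uV"), la3_b = c("LA3", "b_amp_uV"),
               la30hz_peak = c("LA30Hz", "peak_amp_uV"))
  for (cmp in names(pick)) {
    sub <- pc[pc$stimulus == pick[[cmp]][1], ]
    out[match(sub$patient_id, ids), cmp] <- sub[[pick[[cmp]][2]]]
  }
  out
}

#' Build elastic-net design matrices for each ERG component
#'
#' Predictors are allele counts (0/1/2) per panel variant plus age, sex and
#' pupil class; the response is one component amplitude, z-scored over the
#' retained patients. Known cis pairs are collapsed into a single
#' complex-allele column (the standalone column is incremented only when the
#' partner variant is absent). Patients without exactly two recognized
#' alleles after merging, or with a missing response, are excluded. Variants
#' carried by fewer than `m` patients are pooled into an `other` column
#' (configurable).
#'
#' @param cohort cohort table with `variant_a`, `variant_b` HGVS strings.
#' @param patient_components patient-level component table
#'   ([measure_cohort()]`$patient` or [true_component_set()]`$patient`).
#' @param cis_pairs list of length-2 character vectors of cis partners.
#' @param m minimum carrier count for a variant to get its own column.
#' @param pool_other pool sub-threshold variants into an `other` column
#'   (otherwise their carriers keep counts in no column and are dropped by
#'   the two-allele rule).
#' @return list of class `fferg_design`, one entry per component, each with
#'   `x` (design matrix), `y` (z-scored response), `y_raw`, `variants`
#'   (variant column names), `patients`, plus `excluded` attribute.
#' @export
build_design_matrix <- function(cohort, patient_components,
                                cis_pairs = DEFAULT_CIS_PAIRS, m = 2L,
                                pool_other = TRUE) {
  blank <- function(v) is.na(v) | v == ""
  has_geno <- !(blank(cohort$variant_a) & blank(cohort$variant_b))
  co <- cohort[has_geno, , drop = FALSE]
  alleles <- allele_lists(co$variant_a, co$variant_b, cis_pairs)
  n_alleles <- lengths(alleles)

  counts_tab <- table(unlist(lapply(alleles, unique)))
  panel <- names(counts_tab)[counts_tab >= m]
  panel <- sort(panel)
  cols <- c(panel, if (pool_other) "other")
  X <- matrix(0, nrow(co), length(cols), dimnames = list(co$patient_id, cols))
  for (i in seq_along(alleles)) {
    for (al in alleles[[i]]) {
      cn <- if (al %in% panel) al else if (pool_other) "other" else NA
      if (!is.na(cn)) X[i, cn] <- X[i, cn] + 1
    }
  }
  keep2 <- n_alleles == 2 & rowSums(X) == 2
  amp <- component_amplitudes(patient_components)

  cov <- cbind(age_years = co$age_years,
               sex_M = as.numeric(co$sex == "M"),
               pupil_small = as.numeric(co$pupil_class == "<7mm"))
  designs <- list()
  for (cmp in names(AMP_COMPONENTS)) {
    y_raw <- amp[match(co$patient_id, rownames(amp)), cmp]
    keep <- keep2 & !is.na(y_raw)
    y <- y_raw[keep]
    mu <- mean(y); sdv <- stats::sd(y)
    if (!is.finite(sdv) || sdv == 0) sdv <- 1
    designs[[cmp]] <- list(
      x = cbind(X[keep, , drop = FALSE], cov[keep, , drop = FALSE]),
      y = (y - mu) / sdv, y_raw = y, y_center = mu, y_scale = sdv,
      variants = cols, patients = co$patient_id[keep])
  }
  attr(designs, "excluded") <- co$patient_id[!keep2]
  attr(designs, "panel") <- panel
  attr(designs, "allele_counts") <- X   # pre-exclusion counts, all genotyped
  class(designs) <- "fferg_design"
  designs
}

## resolve each patient's genotype strings into a list of allele labels,
## applying cis merging: a known cis pair occurring across the two slots is
## one complex allele "partnerA;partnerB"; slots may themselves contain
## semicolon-joined complex alleles; missing second slot gives one allele;
## slots with ">2 variants" conventions are left as-is (they count as two
## listed alleles and are screened by the caller)
allele_lists <- function(va, vb, cis_pairs) {
  resolve_slot <- function(s) {
    vs <- strsplit(s, ";", fixed = TRUE)[[1]]
    if (length(vs) == 1) return(vs)
    for (cp in cis_pairs) {
      if (setequal(vs, cp)) return(paste(sort(cp), collapse = ";"))
    }
    vs  # unrecognized multi-variant slot: counts as >1 listed variant
  }
  lapply(seq_along(va), function(i) {
    slots <- c(va[i], vb[i])
    slots <- slots[!is.na(slots) & slots != ""]
    als <- unlist(lapply(slots, resolve_slot))
    ## two single-variant slots forming a known cis pair are one complex
    ## allele on the same chromosome; the second allele is then unknown
    if (length(als) == 2 && !any(grepl(";", als, fixed = TRUE))) {
      for (cp in cis_pairs) {
        if (setequal(als, cp)) return(paste(sort(cp), collapse = ";"))
      }
    }
    als
  })
}

## Explicit log-spaced penalty path down to 1e-4 * lambda_max. glmnet's
## default path stops early (fdev rule) when many individually small variant
## effects enter slowly, which would hide the informative low-lambda region
## from the internal cross-validation.
lambda_path <- function(x, y, alpha, length_out = 100L) {
  lmax <- max(abs(crossprod(x, y - mean(y)))) / (nrow(x) * max(alpha, 1e-3))
  exp(seq(log(lmax), log(lmax * 1e-4), length.out = length_out))
}

#' Fit an elastic net to one component design
#'
#' Mixing parameter `alpha` (default 0.5); penalty strength chosen by
#' internal k-fold cross-validation over glmnet's log-spaced path, with
#' deterministic folds derived from `seed`. Predictors stay on the
#' allele-count scale unless `standardize_predictors`; the response is
#' already z-scored, so coefficients are standardized betas.
#'
#' @param design one component entry of [build_design_matrix()].
#' @param cfg configuration (elastic-net settings).
#' @param seed integer seed for the internal CV folds.
#' @param lambda optional fixed penalty (skips internal CV).
#' @return list with `beta` (variant coefficients), `covariates` (age, sex,
#'   pupil coefficients), `intercept`, `lambda`, `fit`.
#' @export
fit_elastic_net <- function(design, cfg = default_config(), seed = 1L,
                            lambda = NULL) {
  x <- design$x; y <- design$y
  en <- cfg$elastic_net
  if (stats::sd(y) < 1e-12) {
    warning("constant response; returning all-zero coefficients")
    beta <- stats::setNames(numeric(ncol(x)), colnames(x))
    return(list(beta = beta[design$variants],
                covariates = beta[intersect(COVARIATES, names(beta))],
                intercept = mean(y), lambda = Inf, fit = NULL))
  }
  if (is.null(lambda)) {
    foldid <- with_seed(seed, sample(rep_len(seq_len(en$nfolds), nrow(x))))
    cvfit <- glmnet::cv.glmnet(x, y, alpha = en$alpha, foldid = foldid,
                               lambda = lambda_path(x, y, en$alpha),
                               standardize = en$standardize_predictors)
    lambda <- cvfit$lambda.min
  }
  fit <- glmnet::glmnet(x, y, alpha = en$alpha, lambda = lambda,
                        standardize = en$standardize_predictors,
                        thresh = 1e-12)
  cf <- as.numeric(stats::coef(fit, s = lambda))
  names(cf) <- c("(Intercept)", colnames(x))
  list(beta = cf[design$variants],
       covariates = cf[intersect(COVARIATES, names(cf))],
       intercept = cf[1], lambda = lambda, fit = fit)
}

#' Leave-one-out cross-validated r-squared
#'
#' Each patient is predicted by an elastic net fitted on the remaining
#' n - 1 patients (penalty fixed at the value chosen on the full data set,
#' for tractability); r-squared is computed on the pooled out-of-sample
#' predictions: `1 - SS_res / SS_tot`.
#'
#' @param design one component design.
#' @param cfg configuration.
#' @param seed seed for the penalty-selection folds.
#' @return list with `r2` and the pooled out-of-sample `predictions`.
#' @export
loocv_r2 <- function(design, cfg = default_config(), seed = 1L) {
  x <- design$x; y <- design$y
  n <- nrow(x)
  if (n < 10) stopf("need n >= 10 for LOOCV (got %d)", n)
  en <- cfg$elastic_net
  foldid <- with_seed(seed, sample(rep_len(seq_len(en$nfolds), n)))
  cvfit <- glmnet::cv.glmnet(x, y, alpha = en$alpha, foldid = foldid,
                             lambda = lambda_path(x, y, en$alpha),
                             standardize = en$standardize_predictors)
  lam <- cvfit$lambda.min
  pred <- vapply(seq_len(n), function(i) {
    f <- glmnet::glmnet(x[-i, , drop = FALSE], y[-i], alpha = en$alpha,
                        lambda = lam, standardize = en$standardize_predictors,
                        thresh = 1e-12)
    as.numeric(stats::predict(f, x[i, , drop = FALSE], s = lam))
  }, numeric(1))
  list(r2 = 1 - sum((y - pred)^2) / sum((y - mean(y))^2),
       predictions = pred, lambda = lam)
}

#' Full severity analysis over the five ERG components
#'
#' Builds the design matrices, fits the elastic net per component, and
#' assembles the severity table of standardized beta-coefficients with
#' per-component LOOCV r-squared.
#'
#' @param cohort cohort table.
#' @param patient_components patient-level component table.
#' @param cfg configuration.
#' @param seed integer seed.
#' @param loocv compute LOOCV r-squared per component (slower).
#' @return list of class `fferg_severity`: `beta` (variants x components
#'   data frame), `covariates`, `r2` (per component, if computed),
#'   `mean_r2`, `concordance`.
#' @export
severity_table <- function(cohort, patient_components,
                           cfg = default_config(), seed = 1L, loocv = TRUE) {
  designs <- build_design_matrix(cohort, patient_components,
                                 m = cfg$elastic_net$min_carriers,
                                 pool_other = cfg$elastic_net$pool_other)
  fits <- lapply(names(designs), function(cmp)
    fit_elastic_net(designs[[cmp]], cfg, seed = derive_seed(seed, match(cmp, names(designs)))))
  names(fits) <- names(designs)
  beta <- as.data.frame(lapply(fits, `[[`, "beta"))
  beta <- cbind(variant_id = designs[[1]]$variants, beta)
  rownames(beta) <- NULL
  covs <- as.data.frame(lapply(fits, `[[`, "covariates"))
  r2 <- NULL
  if (loocv) {
    r2 <- vapply(names(designs), function(cmp)
      loocv_r2(designs[[cmp]], cfg,
               seed = derive_seed(seed, match(cmp, names(designs))))$r2,
      numeric(1))
  }
  out <- list(beta = beta, covariates = covs, r2 = r2,
              mean_r2 = if (!is.null(r2)) mean(r2) else NULL,
              designs = designs)
  class(out) <- "fferg_severity"
  out$concordance <- coefficient_concordance(out)
  out
}

#' Cross-component concordance of severity coefficients
#'
#' Mean pairwise Pearson correlation between the per-component standardized
#' coefficient vectors over the panel variants. Pairs involving a constant
#' vector are skipped with a warning.
#'
#' @param severity `fferg_severity` object (or a data frame with a
#'   `variant_id` column and one column per component).
#' @return mean pairwise correlation (scalar).
#' @export
coefficient_concordance <- function(severity) {
  b <- if (inherits(severity, "fferg_severity")) severity$beta else severity
  mat <- as.matrix(b[, setdiff(colnames(b), "variant_id"), drop = FALSE])
  if (nrow(mat) < 3) stopf("need >= 3 variants for concordance")
  if (ncol(mat) < 2) stopf("need >= 2 components for concordance")
  cors <- c()
  for (i in 1:(ncol(mat) - 1)) for (j in (i + 1):ncol(mat)) {
    if (stats::sd(mat[, i]) < 1e-12 || stats::sd(mat[, j]) < 1e-12) {
      warning(sprintf("constant coefficient vector; skipping pair %s-%s",
                      colnames(mat)[i], colnames(mat)[j]))
      next
    }
    cors <- c(cors, stats::cor(mat[, i], mat[, j]))
  }
  mean(cors)
}

#' Rank variants from mild to severe
#'
#' Sorted by mean standardized beta, descending: higher coefficients mean
#' less amplitude loss per allele, i.e. milder variants. Ties keep input
#' order.
#'
#' @param severity `fferg_severity` object or beta data frame.
#' @return data frame with `variant_id`, per-component betas, `mean_beta`,
#'   ordered mild to severe.
#' @export
rank_variants <- function(severity) {
  b <- if (inherits(severity, "fferg_severity")) severity$beta else severity
  comp_cols <- setdiff(colnames(b), "variant_id")
  b$mean_beta <- rowMeans(as.matrix(b[, comp_cols, drop = FALSE]))
  b[order(-b$mean_beta), , drop = FALSE]
}
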