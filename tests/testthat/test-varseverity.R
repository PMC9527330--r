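## small hand-built design helper
toy_design <- function(n = 30, p = 4, seed = 2, beta = NULL, noise = 0.05) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, dimnames = list(NULL, sprintf("v%d", 1:p)))
    if (is.null(beta)) beta <- seq(1, -1, length.out = p)
    y <- drop(x %*% beta) + rnorm(n, sd = noise)
    y <- (y - mean(y)) / sd(y)
    list(x = x, y = y, y_raw = y, variants = colnames(x),
         patients = sprintf("P%d", 1:n))
  })
}

test_that("cis pairs collapse into one complex allele; exclusion rules apply", {
  co <- make_cohort(6,
    va = c("c.5603A>T", "c.5882G>A", "c.5882G>A", "c.100A>G;c.200A>G",
           "c.5882G>A", "c.5882G>A"),
    vb = c("c.2588G>C", "c.5603A>T", NA, "c.5882G>A", "c.5882G>A",
           "c.5461-10T>C"))
  comps <- true_component_set(generate_cohort(6, seed = 1, with_traces = FALSE))
  comps$patient$patient_id <- sprintf("P%03d", rep(1:6, each = 3))
  d <- build_design_matrix(co, comps$patient, m = 1L)
  X <- attr(d, "allele_counts")
  ## patient 1: known cis pair across slots -> complex allele only
  expect_equal(unname(X["P001", "c.2588G>C;c.5603A>T"]), 1)
  expect_equal(unname(X["P001", "c.5603A>T"]), 0)
  ## ... and is excluded (only one recognized allele)
  expect_true("P001" %in% attr(d, "excluded"))
  ## patient 2: c.5603A>T in trans with a non-partner stays standalone
  expect_equal(unname(X["P002", "c.5603A>T"]), 1)
  expect_equal(unname(X["P002", "c.5882G>A"]), 1)
  expect_false("P002" %in% attr(d, "excluded"))
  ## patient 3: one listed variant -> excluded
  expect_true("P003" %in% attr(d, "excluded"))
  ## patient 4: three variants (unrecognized complex slot) -> excluded
  expect_true("P004" %in% attr(d, "excluded"))
  ## patient 5: homozygous -> count 2, retained
  expect_equal(unname(X["P005", "c.5882G>A"]), 2)
  expect_true(all(rowSums(d$da10_b$x[, d$da10_b$variants]) == 2))
  ## z-scoring of the response over retained patients
  expect_lt(abs(mean(d$da10_b$y)), 1e-9)
  expect_equal(sd(d$da10_b$y), 1, tolerance = 1e-9)
})

test_that("sub-threshold variants pool into 'other'", {
  co <- make_cohort(4,
    va = c("c.1A>G", "c.1A>G", "c.1A>G", "c.9T>C"),
    vb = c("c.1A>G", "c.2A>G", "c.1A>G", "c.1A>G"))
  comps <- true_component_set(generate_cohort(4, seed = 2, with_traces = FALSE))
  comps$patient$patient_id <- sprintf("P%03d", rep(1:4, each = 3))
  d <- build_design_matrix(co, comps$patient, m = 2L)
  X <- attr(d, "allele_counts")
  expect_true("other" %in% colnames(X))
  expect_equal(unname(X["P002", "other"]), 1)  # c.2A>G seen once
  expect_equal(unname(X["P004", "other"]), 1)  # c.9T>C seen once
})

test_that("elastic net matches the OLS oracle in the zero-penalty limit", {
  d <- toy_design()
  fit <- fit_elastic_net(d, lambda = 1e-8)
  ols <- stats::lm(d$y ~ d$x)
  expect_equal(unname(fit$beta), unname(coef(ols)[-1]), tolerance = 1e-6)
  expect_equal(unname(fit$intercept), unname(coef(ols)[1]), tolerance = 1e-6)

  dz <- d; dz$y <- rep(0, length(d$y))
  expect_warning(f0 <- fit_elastic_net(dz), "constant response")
  expect_true(all(f0$beta == 0))
})

test_that("coefficients are invariant to row and column permutations", {
  d <- toy_design(n = 40)
  fit <- fit_elastic_net(d, seed = 5, lambda = 0.01)
  pr <- withr::with_seed(1, sample(nrow(d$x)))
  d_rows <- d; d_rows$x <- d$x[pr, ]; d_rows$y <- d$y[pr]
  expect_equal(fit_elastic_net(d_rows, seed = 5, lambda = 0.01)$beta,
               fit$beta, tolerance = 1e-8)
  pc <- c(3, 1, 4, 2)
  d_cols <- d; d_cols$x <- d$x[, pc]; d_cols$variants <- d$variants[pc]
  expect_equal(fit_elastic_net(d_cols, seed = 5, lambda = 0.01)$beta[d$variants],
               fit$beta, tolerance = 1e-8)
})

test_that("LOOCV r2 behaves at the limits and matches a manual loop oracle", {
  ## perfect-fit limit
  d <- toy_design(n = 25, noise = 1e-4)
  expect_gt(loocv_r2(d, seed = 1)$r2, 0.99)
  ## null limit: response independent of the design
  r2s <- vapply(1:3, function(s) {
    dn <- toy_design(n = 30, seed = 10 + s, beta = rep(0, 4), noise = 1)
    loocv_r2(dn, seed = s)$r2
  }, numeric(1))
  expect_true(all(r2s < 0.1))
  expect_lt(mean(r2s), 0)
  ## explicit leave-one-out loop oracle at a fixed penalty
  d20 <- toy_design(n = 20)
  got <- loocv_r2(d20, seed = 3)
  lam <- got$lambda
  pred <- vapply(seq_len(20), function(i) {
    f <- glmnet::glmnet(d20$x[-i, ], d20$y[-i], alpha = 0.5, lambda = lam,
                        standardize = FALSE, thresh = 1e-12)
    as.numeric(predict(f, d20$x[i, , drop = FALSE], s = lam))
  }, numeric(1))
  r2_oracle <- 1 - sum((d20$y - pred)^2) / sum((d20$y - mean(d20$y))^2)
  expect_equal(got$r2, r2_oracle, tolerance = 1e-9)
  expect_error(loocv_r2(toy_design(n = 8), seed = 1), "n >= 10")
  ## LOOCV r2 never beats the in-sample fit
  fit <- fit_elastic_net(d20, lambda = lam)
  in_r2 <- 1 - sum((d20$y - (d20$x %*% fit$beta + fit$intercept))^2) /
    sum((d20$y - mean(d20$y))^2)
  expect_lte(got$r2, in_r2 + 1e-9)
})

test_that("coefficient concordance matches closed-form Pearson", {
  b <- data.frame(variant_id = c("a", "b", "c"),
                  c1 = c(1, 2, 3), c2 = c(1, 2, 3))
  expect_equal(coefficient_concordance(b), 1)
  b$c2 <- c(3, 2, 1)
  expect_equal(coefficient_concordance(b), -1)
  b2 <- data.frame(variant_id = c("a", "b", "c"),
                   c1 = c(1, 2, 4), c2 = c(2, 1, 5))
  expect_equal(coefficient_concordance(b2), cor(c(1, 2, 4), c(2, 1, 5)))
  b2$c3 <- c(1, 1, 1)
  ## two constant pairs -> two warnings
  expect_warning(expect_warning(cc <- coefficient_concordance(b2),
                                "constant"), "constant")
  expect_equal(cc, cor(c(1, 2, 4), c(2, 1, 5)))  # constant pairs skipped
  expect_error(coefficient_concordance(b2[1:2, ]), ">= 3 variants")
})

test_that("variant ranking is mild-first with stable ties", {
  b <- data.frame(variant_id = c("v1", "v2", "v3", "v4"),
                  c1 = c(0.5, -0.5, 0.5, 0), c2 = c(0.5, -0.5, 0.5, 0))
  rk <- rank_variants(b)
  expect_equal(rk$variant_id[1:2], c("v1", "v3"))  # tie keeps input order
  expect_equal(rk$variant_id[4], "v2")
  expect_equal(rank_variants(b[1, ])$variant_id, "v1")
})

test_that("severity analysis recovers the simulated allele-severity spectrum", {
  sim <- generate_cohort(400, sim = default_sim_params(mode = "genotype"),
                         seed = 17, with_traces = FALSE)
  tc <- true_component_set(sim)
  sev <- severity_table(sim$cohort, tc$patient, seed = 17, loocv = FALSE)
  b <- rank_variants(sev)
  mi <- match(b$variant_id, sim$panel$variant_id)
  sv <- sim$panel$severity[mi]
  ## mild-to-severe ordering: mean beta anticorrelates with true severity
  expect_gt(cor(-b$mean_beta[!is.na(mi)], sv[!is.na(mi)],
                method = "spearman"), 0.8)
  ## the mildest simulated variant outranks the null-like one
  mild_id <- sim$panel$variant_id[which.min(sim$panel$severity)]
  null_id <- sim$panel$variant_id[which.max(sim$panel$severity)]
  expect_lt(which(b$variant_id == mild_id), which(b$variant_id == null_id))
  expect_gt(sev$concordance, 0.8)
})
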