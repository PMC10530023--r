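test_that("the two-phage streak assay logic is exact (all 4 genotypes)", {
  assay <- genotype_to_assay(c("S", "R", "C", "D"))
  expect_equal(assay$resistant_to_phage, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(assay$resistant_to_acr_phage, c(FALSE, TRUE, FALSE, TRUE))
  cls <- classify_phenotype(assay$resistant_to_phage,
                            assay$resistant_to_acr_phage)
  # D scores as sm: the Acr disables CRISPR but the receptor stays mutated
  expect_equal(cls, c("sensitive", "sm", "crispr", "sm"))
  expect_error(classify_phenotype(FALSE, TRUE), "inconsistent")
  expect_error(genotype_to_assay("X"), "genotype")
})

test_that("degenerate truths give degenerate clone tables", {
  truth <- data.frame(treatment = "t1", day = 1, f_S = 0, f_R = 0, f_C = 1,
                      f_D = 0)
  ct <- sample_clone_table(truth, n_clones = 24, n_replicates = 4, seed = 2)
  expect_true(all(ct$n_crispr == 24))
  expect_true(all(ct$n_sensitive == 0))
  expect_error(sample_clone_table(truth, n_clones = 0), "positive")
  expect_error(sample_clone_table(truth, overdispersion = 1), "\\[0, 1\\)")
})

test_that("clone sampling is multinomially unbiased at rho = 0", {
  truth <- data.frame(treatment = "t1", day = 1, f_S = 0.5, f_R = 0.25,
                      f_C = 0.25, f_D = 0)
  ct <- sample_clone_table(truth, n_clones = 24, n_replicates = 10000,
                           seed = 8)
  n <- nrow(ct)
  for (col_p in list(c("n_sensitive", 0.5), c("n_sm", 0.25),
                     c("n_crispr", 0.25))) {
    p <- as.numeric(col_p[2])
    m <- mean(ct[[col_p[1]]])
    se <- sqrt(24 * p * (1 - p) / n)
    expect_lt(abs(m - 24 * p), 3 * se)
  }
})

test_that("clone fractions are unbiased for (f_S, f_R+f_D, f_C) generally", {
  set.seed(21)
  for (i in 1:4) {
    f <- runif(4)
    f <- f / sum(f)
    truth <- data.frame(treatment = "t", day = 1, f_S = f[1], f_R = f[2],
                        f_C = f[3], f_D = f[4])
    ct <- sample_clone_table(truth, n_clones = 24, n_replicates = 3000,
                             seed = 100 + i)
    p_sm <- f[2] + f[4]
    se <- sqrt(24 * p_sm * (1 - p_sm) / nrow(ct))
    expect_lt(abs(mean(ct$n_sm) - 24 * p_sm), 4 * se)
  }
})

test_that("overdispersion inflates across-replicate variance", {
  truth <- data.frame(treatment = "t1", day = 1, f_S = 0.4, f_R = 0.3,
                      f_C = 0.3, f_D = 0)
  tight <- sample_clone_table(truth, n_replicates = 2000, seed = 5,
                              overdispersion = 0)
  wide <- sample_clone_table(truth, n_replicates = 2000, seed = 5,
                             overdispersion = 0.3)
  expect_gt(var(wide$n_crispr), var(tight$n_crispr))
  # beta-binomial inflation factor 1 + (n-1)*rho on the crispr counts
  n <- 24; p <- 0.3; rho <- 0.3
  expect_equal(var(wide$n_crispr),
               n * p * (1 - p) * (1 + (n - 1) * rho), tolerance = 0.15)
})

test_that("count noise is off at cv = 0 and datasets are reproducible", {
  des <- bundled_design("inoculum_sweep")
  ds <- generate_dataset(des, model_params(),
                         noise = list(count_cv = 0, overdispersion = 0),
                         seed = 4)
  idx <- rep(seq_len(nrow(ds$truth)), each = des$n_replicates)
  expect_identical(ds$counts$cfu_per_ml, ds$truth$N[idx])
  expect_identical(ds$counts$pfu_per_ml, ds$truth$V[idx])
  ds2 <- generate_dataset(des, model_params(),
                          noise = list(count_cv = 0, overdispersion = 0),
                          seed = 4)
  expect_identical(ds$clones, ds2$clones)
  expect_identical(ds$counts, ds2$counts)
  # schema contract
  expect_named(ds$clones, c("treatment", "replicate", "day", "n_sensitive",
                            "n_sm", "n_crispr"))
  expect_named(ds$counts, c("treatment", "replicate", "day", "cfu_per_ml",
                            "pfu_per_ml"))
  expect_true(all(ds$clones$n_sensitive + ds$clones$n_sm +
                    ds$clones$n_crispr == 24))
})

test_that("generated data reproduce the dose effect on early CRISPR", {
  des <- bundled_design("fig3_analogue")
  ds <- generate_dataset(des, model_params(), seed = 9)
  cl <- ds$clones
  top_K <- max(des$treatments$K)
  d1 <- merge(cl[cl$day == 1, ], des$treatments, by = "treatment")
  d1 <- d1[d1$K == top_K, ]
  mean_fC <- tapply(d1$n_crispr / 24, d1$V0, mean)
  v0 <- as.numeric(names(mean_fC))
  expect_true(all(diff(mean_fC[order(v0)]) > 0))
})
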