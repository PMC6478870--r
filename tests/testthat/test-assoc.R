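# Association networks: Spearman matrices, the bootstrap FDR threshold,
# the augmented TR-gene network, and tissue signatures.

test_that("Spearman matrices agree with cor.test on small instances", {
  set.seed(4)
  X <- matrix(rnorm(30), 3, dimnames = list(paste0("x", 1:3), NULL))
  Y <- matrix(rnorm(40), 4, dimnames = list(paste0("y", 1:4), NULL))
  sm <- spearman_matrix(X, Y)
  for (i in 1:3) for (j in 1:4) {
    ct <- cor.test(X[i, ], Y[j, ], method = "spearman", exact = FALSE)
    expect_equal(sm$R[i, j], unname(ct$estimate))
    expect_equal(sm$p[i, j], ct$p.value, tolerance = 1e-8)
  }
  # reciprocity
  sm2 <- spearman_matrix(Y, X)
  expect_equal(t(sm$R), sm2$R)
  expect_equal(t(sm$p), sm2$p)
})

test_that("activity-metabolite correlation is rank-invariant and exact", {
  act <- matrix(c(1, 3, 2, 5, 4, 6), 1,
                dimnames = list("tr1", paste0("l", 1:6)))
  z <- rbind(same = act[1, ], mono = exp(act[1, ]), anti = -act[1, ])
  colnames(z) <- colnames(act)
  am <- tr_metabolite_correlation(act, z, min_lines = 5)
  expect_equal(unname(am$R[1, ]), c(1, 1, -1))
  expect_s3_class(am, "assoc_matrix")
  expect_error(tr_metabolite_correlation(act[, 1:3, drop = FALSE],
                                         z[, 1:3]), "shared cell lines")
  # constant metabolite row flagged undefined
  z2 <- rbind(z, flat = rep(1, 6))
  am2 <- tr_metabolite_correlation(act, z2, min_lines = 5)
  expect_true(is.na(am2$R[1, "flat"]))
})

test_that("bootstrap FDR threshold behaves like a null quantile", {
  set.seed(5)
  act <- matrix(rnorm(8 * 20), 8,
                dimnames = list(paste0("t", 1:8), paste0("l", 1:20)))
  z <- matrix(rnorm(12 * 20), 12,
              dimnames = list(paste0("m", 1:12), paste0("l", 1:20)))
  thr_strict <- bootstrap_fdr_threshold(act, z, n_resamples = 50,
                                        fdr = 0.01, seed = 1)
  thr_loose <- bootstrap_fdr_threshold(act, z, n_resamples = 50,
                                       fdr = 0.2, seed = 1)
  expect_gt(thr_strict$threshold, thr_loose$threshold)
  expect_equal(bootstrap_fdr_threshold(act, z, n_resamples = 5,
                                       fdr = 1, seed = 1)$threshold, 0)
  expect_error(bootstrap_fdr_threshold(act, z, n_resamples = 1), ">= 2")
})

test_that("planted associations pass the 0.1% FDR threshold", {
  st <- default_study()
  ab <- filter_ions(fit_cell_regression(
    estimate_plate_factors(st$intensities)$corrected))
  z <- zscore_abundance(volume_correct(ab)$ab)
  zc <- z$z
  rownames(zc) <- st$truth$metabolites[
    match(rownames(zc), st$truth$ions)]
  zc <- zc[!is.na(rownames(zc)), ]
  act <- st$truth$tr_activity_true
  am <- tr_metabolite_correlation(act, zc)
  thr <- bootstrap_fdr_threshold(act, zc, n_resamples = 100,
                                 fdr = 0.001, seed = 2)
  cp <- st$truth$coupling
  cp <- cp[cp$metabolite %in% colnames(am$R), ]
  planted_R <- abs(am$R[cbind(cp$tr, cp$metabolite)])
  expect_gt(mean(planted_R >= thr$threshold), 0.8)
})

test_that("augmented network recovers planted TR-enzyme regulation", {
  # compendium without the growth confounder: regulation is the only
  # structured signal, as the operation assumes
  cfg <- tiny_config(seed = 24, growth_strength = 0)
  truth <- simulate_ground_truth(cfg)
  ts <- simulate_tr_system(cfg, truth)
  e <- truth$regulatory_edges
  enz <- unique(e$target)
  aug <- augmented_network(truth$tr_activity_true, ts$expression, enz,
                           r_threshold = 0.5)
  # exclusive targets of each TR appear as augmented edges
  excl <- e[!e$target %in% e$target[duplicated(e$target)], ]
  found <- paste(aug$tr, aug$enzyme)
  expect_gt(mean(paste(excl$tr, excl$target) %in% found), 0.9)
  # threshold 1 keeps only perfectly monotone pairs
  aug1 <- augmented_network(truth$tr_activity_true, ts$expression, enz,
                            r_threshold = 1 - 1e-12)
  expect_lt(nrow(aug1), nrow(aug))
})

test_that("tissue ANOVA detects planted effects and matches the t-test", {
  st <- tiny_study()
  ab <- filter_ions(fit_cell_regression(
    estimate_plate_factors(st$intensities)$corrected))
  z <- zscore_abundance(volume_correct(ab)$ab)
  res <- tissue_anova(z, st$truth$tissue)
  planted <- res$metabolite %in% st$truth$tissue_ions
  expect_lt(median(res$p[planted], na.rm = TRUE),
            median(res$p[!planted], na.rm = TRUE))
  # two groups: the ANOVA F-test equals the equal-variance t-test
  y <- matrix(rnorm(12), 1, dimnames = list("m", paste0("l", 1:12)))
  g <- setNames(rep(c("a", "b"), each = 6), colnames(y))
  suppressWarnings(p_f <- tissue_anova(y, g)$p)
  p_t <- t.test(y[1, 1:6], y[1, 7:12], var.equal = TRUE)$p.value
  expect_equal(p_f, p_t)
})

test_that("tissue similarity ROC separates clustered profiles", {
  set.seed(6)
  centers <- matrix(rnorm(20 * 3, sd = 3), 20)
  prof <- centers[, rep(1:3, each = 4)] + matrix(rnorm(240, sd = 0.3), 20)
  colnames(prof) <- paste0("l", 1:12)
  tiss <- setNames(rep(c("a", "b", "c"), each = 4), colnames(prof))
  roc <- tissue_similarity_roc(prof, tiss)
  expect_gt(roc$auc, 0.99)
  # agrees with an established ROC implementation
  skip_if_not_installed("pROC")
  ref <- suppressMessages(
    pROC::auc(pROC::roc(roc$same_tissue, roc$scores, quiet = TRUE)))
  expect_equal(roc$auc, as.numeric(ref))
  # label permutation gives chance-level AUC
  aucs <- vapply(1:10, function(i) {
    tissue_similarity_roc(prof, setNames(sample(tiss), colnames(prof)))$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
  # random profiles: chance level
  prof0 <- matrix(rnorm(240), 20, dimnames = list(NULL, colnames(prof)))
  expect_lt(abs(tissue_similarity_roc(prof0, tiss)$auc - 0.5), 0.15)
})
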