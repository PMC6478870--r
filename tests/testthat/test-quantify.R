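# Quantification: plate-factor estimation, cell-number regression, ion
# filtering, volume correction, Z-scoring and m/z annotation.

make_table <- function(inten, meta) {
  structure(list(intensity = inten, sample_meta = meta),
            class = "intensity_table")
}

test_that("confluence converts to cell number by the area ratio", {
  expect_equal(cells_from_confluence(0, 1600), 0)
  expect_equal(cells_from_confluence(100, 1000, well_area = 1000), 1)
  expect_equal(cells_from_confluence(50, 1600, well_area = 0.32e8), 10000)
  expect_equal(cells_from_confluence(25, 2000, well_area = 3.2e7), 4000)
  expect_error(cells_from_confluence(120, 1600), "within")
  expect_error(cells_from_confluence(50, -1), "positive")
})

test_that("plate factors are identified from pooled samples", {
  # two plates in one batch, identical pooled compositions -> gamma = 1
  M <- matrix(c(100, 200, 400, 800), 2)
  inten <- cbind(M, M)
  colnames(inten) <- paste0("s", 1:4)
  rownames(inten) <- c("i1", "i2")
  meta <- data.frame(sample_id = colnames(inten),
                     plate = c("p1", "p1", "p2", "p2"), batch = 1,
                     sample_type = "pooled", cell_line = NA,
                     stringsAsFactors = FALSE)
  pf <- estimate_plate_factors(make_table(inten, meta))
  expect_equal(unname(pf$gamma), c(1, 1))
  # scaling plate 2 by 2: gamma in the product-1 gauge, corrected table
  # matching the original up to one global scale
  inten2 <- inten
  inten2[, 3:4] <- 2 * inten2[, 3:4]
  pf2 <- estimate_plate_factors(make_table(inten2, meta))
  expect_equal(unname(pf2$gamma[2] / pf2$gamma[1]), 2)
  expect_equal(prod(pf2$gamma), 1)
  ratio <- pf2$corrected$intensity / inten
  expect_equal(max(ratio), min(ratio))
})

test_that("plate factors recover the generator truth exactly without noise", {
  cfg <- tiny_config(seed = 11, noise_cv = 0)
  truth <- simulate_ground_truth(cfg)
  it <- simulate_intensities(truth, simulate_growth(cfg, truth), cfg)
  pf <- estimate_plate_factors(it)
  expect_equal(pf$gamma, truth$plate_factor_true[names(pf$gamma)],
               tolerance = 1e-12)
  expect_length(pf$unidentifiable, 0)
})

test_that("cell regression fits an exact line and ignores sample order", {
  N <- c(100, 200, 300, 500)
  inten <- matrix(2 * N + 5, 1, dimnames = list("i1", paste0("s", 1:4)))
  meta <- data.frame(sample_id = paste0("s", 1:4), cell_line = "A",
                     plate = "p1", batch = 1, sample_type = "cell",
                     cell_count = N, stringsAsFactors = FALSE)
  ab <- fit_cell_regression(make_table(inten, meta))
  expect_equal(unname(ab$alpha["i1", "A"]), 2)
  expect_equal(unname(ab$beta[["i1"]]), 5)
  expect_equal(unname(ab$alpha_se["i1", "A"]), 0, tolerance = 1e-7)
  perm <- c(3, 1, 4, 2)
  ab2 <- fit_cell_regression(make_table(inten[, perm, drop = FALSE],
                                        meta[perm, ]))
  expect_equal(ab2$alpha, ab$alpha)
  expect_equal(ab2$alpha_p, ab$alpha_p)
  # design validation
  meta_bad <- meta
  meta_bad$cell_count <- rep(100, 4)
  expect_error(fit_cell_regression(make_table(inten, meta_bad)),
               "distinct cell counts")
})

test_that("alpha estimates are invariant to the sampled density window", {
  cfg <- tiny_config(seed = 12)
  truth <- simulate_ground_truth(cfg)
  samples <- simulate_growth(cfg, truth)
  it <- simulate_intensities(truth, samples, cfg)
  corr <- estimate_plate_factors(it)$corrected
  ab <- fit_cell_regression(corr)
  # refit on a subset spanning the count range: three of five time points
  keep <- is.na(corr$sample_meta$timepoint) |
    corr$sample_meta$timepoint %in% c(0, 48, 96)
  sub <- make_table(corr$intensity[, keep], corr$sample_meta[keep, ])
  ab_sub <- fit_cell_regression(sub)
  dev <- abs(ab_sub$alpha - ab$alpha) /
    sqrt(ab$alpha_se^2 + ab_sub$alpha_se^2)
  expect_lt(stats::quantile(dev, 0.99, na.rm = TRUE), 3)
})

test_that("ion filtering applies the dual Bonferroni criterion", {
  p <- rbind(alw = rep(1e-12, 10),
             one = c(1e-12, rep(0.5, 9)),
             none = rep(0.2, 10),
             most = c(1e-12, rep(0.01, 8), 0.5))
  ab <- structure(list(alpha_p = p, alpha = p, alpha_se = p),
                  class = "abundance_matrix")
  ab <- filter_ions(ab)
  expect_equal(unname(ab$retained), c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(attr(ab, "threshold"), 0.05 / (10 * 4))
  # the published scale: 54 lines x 2723 ions gives ~3.4e-7
  expect_equal(0.05 / (54 * 2723), 3.4e-7, tolerance = 0.01)
  # bonferroni mode for the fraction criterion is stricter
  ab2 <- filter_ions(ab, frac_mode = "bonferroni")
  expect_equal(unname(ab2$retained), c(TRUE, FALSE, FALSE, FALSE))
})

test_that("volume correction removes a rank-one volume component", {
  set.seed(1)
  s <- exp(rnorm(30)); v <- exp(rnorm(12, 0, 0.5))
  A <- outer(s, v)
  dimnames(A) <- list(paste0("i", 1:30), paste0("l", 1:12))
  ab <- structure(list(alpha = A, alpha_se = A * 0.01,
                       alpha_p = A * 0 + 1e-12,
                       retained = rep(TRUE, 30)),
                  class = "abundance_matrix")
  vc <- volume_correct(ab)
  # all between-line variance is gone
  expect_lt(max(apply(vc$ab$alpha, 1, sd) /
                  rowMeans(vc$ab$alpha)), 1e-10)
  expect_gt(cor(vc$volume_factor, v), 0.999)
  # equal volumes -> unit factors
  A2 <- outer(s, rep(2, 12))
  dimnames(A2) <- dimnames(A)
  ab2 <- ab; ab2$alpha <- A2
  vc2 <- volume_correct(ab2)
  expect_equal(unname(vc2$volume_factor), rep(1, 12))
  expect_error(volume_correct(structure(list(alpha = A, retained = NULL),
                                        class = "abundance_matrix")),
               "filter_ions")
})

test_that("volume factors recover simulated cell volumes up to scale", {
  cfg <- tiny_config(seed = 13)
  truth <- simulate_ground_truth(cfg)
  it <- simulate_intensities(truth, simulate_growth(cfg, truth), cfg)
  ab <- filter_ions(fit_cell_regression(estimate_plate_factors(it)$corrected))
  vc <- volume_correct(ab)
  expect_gt(cor(vc$volume_factor, truth$cell_volume), 0.95)
})

test_that("Z-scores use the population SD and flag degenerate ions", {
  z <- zscore_abundance(rbind(a = c(1, 2, 3), b = c(2, 2, 2)))
  expect_equal(unname(z$z["a", ]), c(-1.2247449, 0, 1.2247449),
               tolerance = 1e-6)
  expect_true(z$zero_variance[["b"]])
  expect_true(all(is.na(z$z["b", ])))
  set.seed(2)
  M <- matrix(rnorm(200), 10)
  zz <- zscore_abundance(M)$z
  expect_equal(unname(rowMeans(zz)), rep(0, 10))
  expect_equal(unname(sqrt(rowMeans(zz^2))), rep(1, 10))
})

test_that("Z-scored output is invariant to global intensity rescaling", {
  cfg <- tiny_config(seed = 14)
  truth <- simulate_ground_truth(cfg)
  it <- simulate_intensities(truth, simulate_growth(cfg, truth), cfg)
  run <- function(tbl) {
    ab <- filter_ions(fit_cell_regression(
      estimate_plate_factors(tbl)$corrected))
    zscore_abundance(volume_correct(ab)$ab)$z
  }
  z1 <- run(it)
  it2 <- it
  it2$intensity <- it$intensity * 7.3
  expect_equal(run(it2), z1, tolerance = 1e-9)
})

test_that("m/z annotation matches deprotonated and phenylhydrazone ions", {
  expect_equal(phenylhydrazone_shift(), 90.05818, tolerance = 1e-5)
  ref <- data.frame(compound_id = c("glucose", "pyruvate"),
                    formula = c("C6H12O6", "C3H4O3"),
                    monoisotopic_mass = c(180.06339, 88.01604),
                    is_alpha_keto = c(FALSE, TRUE),
                    stringsAsFactors = FALSE)
  hits <- annotate_ions(c(x1 = 179.0560), ref)
  expect_equal(hits$compound_id, "glucose")
  expect_equal(hits$adduct, "[M-H]-")
  expect_equal(hits$mz - hits$mass_error, 180.06339 - 1.007276)
  # tolerance boundary
  expect_equal(nrow(annotate_ions(c(x = 179.0560 + 0.004), ref)), 0)
  # phenylhydrazone derivative of the alpha-keto acid
  mz_ph <- 88.01604 + phenylhydrazone_shift() - 1.007276
  hits2 <- annotate_ions(c(x2 = mz_ph), ref)
  expect_true("[M+C6H8N2-H2O-H]-" %in% hits2$adduct)
  expect_equal(hits2$compound_id[hits2$adduct != "[M-H]-"], "pyruvate")
})
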