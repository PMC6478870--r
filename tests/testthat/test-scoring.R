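# TR scoring: flux association, in-vivo inference, knockdown ranking and
# drug regression.

test_that("flux correlation averages the two rank correlations", {
  z <- rbind(up = 1:6, anti = 6:1, mix = c(2, 1, 4, 3, 6, 5))
  colnames(z) <- paste0("l", 1:6)
  flux <- data.frame(cell_line = colnames(z), glucose_uptake = 1:6,
                     lactate_secretion = c(1, 3, 2, 5, 4, 6))
  fc <- metabolite_flux_correlation(z, flux)
  expect_equal(unname(fc["up"]),
               (1 + cor(1:6, flux$lactate_secretion,
                        method = "spearman")) / 2)
  # hand-computed average for the mixed row
  manual <- mean(c(cor(z["mix", ], 1:6, method = "spearman"),
                   cor(z["mix", ], flux$lactate_secretion,
                       method = "spearman")))
  expect_equal(unname(fc["mix"]), manual)
  expect_equal(unname(fc["anti"]), -unname(fc["up"]))
  flux$glucose_uptake <- 1
  expect_error(metabolite_flux_correlation(z, flux), "constant")
})

test_that("TR flux score is an L1-normalized dot product", {
  f <- c(m1 = 0.8, m2 = -0.4, m3 = 0.2)
  R <- rbind(aligned = f / 2,
             orth = c(-0.4 / 2, -0.8 / 2, 0),
             zero = c(0, 0, 0))
  colnames(R) <- names(f)
  s <- tr_flux_score(R, f)
  expect_equal(unname(s["aligned"]), sum(f^2) / sum(abs(f)))
  expect_equal(unname(s["orth"]), 0)
  expect_true(is.na(s["zero"]))
  # bound: |score| <= max |f| for random inputs
  set.seed(12)
  for (i in 1:20) {
    Rr <- matrix(rnorm(30), 5, dimnames = list(NULL, names(f)[c(1, 2, 3)][
      rep(1:3, 2)][1:6]))
    colnames(Rr) <- paste0("m", 1:6)
    fr <- setNames(runif(6, -1, 1), colnames(Rr))
    sr <- tr_flux_score(Rr, fr)
    expect_true(all(abs(sr) <= max(abs(fr)) + 1e-12))
  }
})

test_that("pathway TR scores flag planted high-score clusters", {
  set.seed(13)
  scores <- setNames(rnorm(60), paste0("t", 1:60))
  scores[1:6] <- scores[1:6] + 3
  paths <- list(hot = paste0("t", 1:6), cold = paste0("t", 31:36))
  res <- suppressWarnings(pathway_tr_score(scores, paths, n_perm = 2000, seed = 1))
  expect_lt(res$p[res$pathway == "hot"], 0.01)
  expect_gt(res$p[res$pathway == "cold"], 0.05)
  # constant scores: every pathway is typical
  res0 <- suppressWarnings(pathway_tr_score(
    setNames(rep(1, 60), names(scores)), paths, n_perm = 200, seed = 1))
  expect_true(all(res0$p == 1))
})

test_that("in-vivo scores follow Eq-style arithmetic and its bound", {
  C <- matrix(c(1, -1), 1, dimnames = list("tr1", c("m1", "m2")))
  FC <- matrix(c(2, -2), 2, dimnames = list(c("m1", "m2"), "p1"))
  sc <- suppressWarnings(invivo_tr_score(C, FC, n_perm = 100, seed = 1))
  expect_equal(unname(sc$S["tr1", "p1"]), 2)
  # all-zero fold-changes: degenerate null has p = 1
  sc0 <- suppressWarnings(invivo_tr_score(C, FC * 0, n_perm = 100, seed = 1))
  expect_equal(unname(sc0$S["tr1", "p1"]), 0)
  expect_equal(unname(sc0$p["tr1", "p1"]), 1)
  # L1 bound over random instances
  set.seed(14)
  Cr <- matrix(rnorm(5 * 12), 5,
               dimnames = list(paste0("t", 1:5), paste0("m", 1:12)))
  FCr <- matrix(rnorm(12 * 4), 12,
                dimnames = list(paste0("m", 1:12), paste0("p", 1:4)))
  scr <- suppressWarnings(invivo_tr_score(Cr, FCr, n_perm = 50, seed = 1))
  expect_true(all(abs(scr$S) <= max(abs(FCr)) + 1e-12))
  # invariance under joint relabeling of metabolites
  perm <- sample(12)
  scp <- suppressWarnings(invivo_tr_score(Cr[, perm], FCr[perm, ], n_perm = 500, seed = 1))
  expect_equal(scp$S, scr$S)
})

test_that("Monte-Carlo permutation p matches exhaustive enumeration at 5!", {
  set.seed(15)
  C <- matrix(rnorm(5), 1, dimnames = list("tr", paste0("m", 1:5)))
  FC <- matrix(rnorm(5), 5, dimnames = list(paste0("m", 1:5), "p1"))
  sc <- suppressWarnings(invivo_tr_score(C, FC, n_perm = 10000, seed = 2))
  perms <- gtools_permutations_5()
  s_obs <- sum(C[1, ] * FC[, 1]) / sum(abs(C[1, ]))
  s_null <- apply(perms, 1, function(ix)
    sum(C[1, ] * FC[ix, 1]) / sum(abs(C[1, ])))
  p_exact <- mean(s_null >= s_obs)
  se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(sc$p[1, 1] - p_exact), 4 * se + 1e-6)
})

test_that("metabolite filtering drops rows with many missing patients", {
  C <- matrix(rnorm(6), 1, dimnames = list("tr", paste0("m", 1:6)))
  FC <- matrix(rnorm(6 * 15), 6,
               dimnames = list(paste0("m", 1:6), paste0("p", 1:15)))
  FC["m6", 1:12] <- NA
  sc <- suppressWarnings(invivo_tr_score(C, FC, n_perm = 10, max_missing = 10, seed = 1))
  expect_false("m6" %in% sc$metabolites)
  expect_error(invivo_tr_score(C[, 1, drop = FALSE],
                               FC[1, , drop = FALSE], n_perm = 10),
               "fewer than 2")
})

test_that("knockdown ranking surfaces the silenced TR", {
  set.seed(16)
  C <- matrix(rnorm(20 * 30), 20,
              dimnames = list(paste0("t", 1:20), paste0("m", 1:30)))
  sig <- C["t7", ] / sd(C["t7", ])
  fc <- vapply(c(0.5, 1, 1.5), function(k) -k * sig + rnorm(30, 0, 0.3),
               numeric(30))
  dimnames(fc) <- list(names(sig), paste0("c", 1:3))
  kd <- knockdown_rank(C, fc)
  expect_equal(kd$ranking$tr[1], "t7")
  # identical concentrations: median equals each column
  fc_same <- fc[, c(1, 1, 1)]
  kd2 <- knockdown_rank(C, fc_same)
  expect_equal(kd2$median_score, kd2$scores[, 1])
  expect_error(knockdown_rank(C, fc[, 1, drop = FALSE]), ">= 2")
  # combined significance is the product across concentrations
  p3 <- matrix(runif(90), 30, dimnames = dimnames(fc))
  kd3 <- knockdown_rank(C, fc, p_by_conc = p3)
  expect_equal(unname(kd3$combined_p["m1"]), prod(p3["m1", ]))
})

test_that("drug regression estimates lambda with tissue covariates", {
  set.seed(17)
  act <- matrix(rnorm(3 * 24), 3,
                dimnames = list(paste0("t", 1:3), paste0("l", 1:24)))
  tissue <- setNames(rep(c("a", "b", "c"), each = 8), colnames(act))
  beta_t <- c(a = 1, b = -2, c = 0.5)
  panel <- rbind(d1 = 2 * act["t1", ] + beta_t[tissue],
                 d2 = rnorm(24))
  colnames(panel) <- colnames(act)
  reg <- drug_tr_regression(panel, act, tissue)
  r11 <- reg$results[reg$results$tr == "t1" & reg$results$drug == "d1", ]
  expect_equal(r11$lambda, 2, tolerance = 1e-6)
  expect_lt(r11$p, 1e-12)
  expect_equal(unname(reg$beta["t1", "d1", ]), unname(beta_t),
               tolerance = 1e-6)
  expect_equal(reg$threshold, 0.05 / (3 * 2))
  # small tissues pooled with a warning
  tissue2 <- tissue; tissue2[1] <- "rare"
  expect_warning(drug_tr_regression(panel, act, tissue2), "other")
})

test_that("null drug panels keep family-wise false positives controlled", {
  fp <- vapply(1:3, function(s) {
    set.seed(100 + s)
    act <- matrix(rnorm(5 * 30), 5,
                  dimnames = list(paste0("t", 1:5), paste0("l", 1:30)))
    tissue <- setNames(rep(c("a", "b", "c"), each = 10), colnames(act))
    panel <- matrix(rnorm(6 * 30), 6,
                    dimnames = list(paste0("d", 1:6), colnames(act)))
    sum(drug_tr_regression(panel, act, tissue)$results$significant)
  }, numeric(1))
  expect_lte(sum(fp), 1)
})

test_that("cluster-by-MoA enrichment finds concentrated associations", {
  res <- data.frame(
    tr = rep(paste0("t", 1:6), each = 4),
    drug = rep(paste0("d", 1:4), 6), stringsAsFactors = FALSE)
  res$significant <- res$tr %in% c("t1", "t2") & res$drug %in% c("d1", "d2")
  clusters <- setNames(rep(c("c1", "c2", "c3"), each = 2),
                       paste0("t", 1:6))
  moa <- setNames(rep(c("m1", "m2"), each = 2), paste0("d", 1:4))
  enr <- moa_cluster_enrichment(res, clusters, moa)
  expect_equal(unname(which.min(apply(enr$p, 1, min))), 1)
  expect_lt(enr$p["c1", "m1"], 0.01)
  expect_equal(enr$threshold, 0.05 / 6)
})
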