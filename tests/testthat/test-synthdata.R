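# The synthetic study generator: design structure, determinism, and the
# statistical structure downstream stages rely on.

test_that("config validation rejects degenerate designs", {
  expect_s3_class(tiny_config(), "sim_config")
  expect_error(tiny_config(noise_cv = -0.1), "noise_cv")
  expect_error(sim_config(n_ions = 0), "count")
  expect_error(sim_config(n_genes = 10, n_trs = 50, targets_per_tr = 8),
               "not enough genes")
})

test_that("identical seeds reproduce identical studies", {
  a <- simulate_study(tiny_config(seed = 5))
  b <- simulate_study(tiny_config(seed = 5))
  expect_identical(a$intensities$intensity, b$intensities$intensity)
  expect_identical(a$tr_system$expression, b$tr_system$expression)
  expect_identical(a$proteome_drugs$drug_panel, b$proteome_drugs$drug_panel)
  c <- simulate_study(tiny_config(seed = 6))
  expect_false(identical(a$intensities$intensity,
                         c$intensities$intensity))
})

test_that("growth design yields replicates x timepoints samples per line", {
  st <- tiny_study()
  cfg <- st$truth$config
  per_line <- table(st$samples$cell_line)
  expect_true(all(per_line ==
                    cfg$replicates_per_timepoint * cfg$n_timepoints))
  expect_true(all(st$samples$confluence >= 0 &
                    st$samples$confluence <= 100))
  # default design: 3 x 5 = 15 metabolome samples per line
  expect_equal(sim_config()$replicates_per_timepoint *
                 sim_config()$n_timepoints, 15)
})

test_that("plate factors multiply intensities and have per-batch product 1", {
  cfg <- tiny_config(seed = 2, noise_cv = 0)
  truth <- simulate_ground_truth(cfg)
  samples <- simulate_growth(cfg, truth)
  it <- simulate_intensities(truth, samples, cfg)
  # noiseless identity: I = gamma * (alpha N + beta) exactly
  j <- which(it$sample_meta$sample_type == "cell")[1]
  m <- it$sample_meta[j, ]
  expect_equal(
    it$intensity[, j],
    truth$plate_factor_true[[m$plate]] *
      (truth$alpha_true[, m$cell_line] * m$cell_count + truth$beta_true))
  # doubling one plate's gamma doubles exactly that plate's intensities
  truth2 <- truth
  p1 <- names(truth$plate_factor_true)[1]
  truth2$plate_factor_true[[p1]] <- 2 * truth$plate_factor_true[[p1]]
  it2 <- simulate_intensities(truth2, samples, cfg)
  on_p1 <- it$sample_meta$plate == p1
  expect_equal(it2$intensity[, on_p1], 2 * it$intensity[, on_p1])
  expect_equal(it2$intensity[, !on_p1], it$intensity[, !on_p1])
  # gauge
  batches <- sub("_t\\d+$", "", names(truth$plate_factor_true))
  prod_b <- tapply(truth$plate_factor_true, batches, prod)
  expect_equal(as.vector(prod_b), rep(1, length(prod_b)))
  expect_equal(prod(truth$plate_factor_true), 1)
})

test_that("pooled wells share one pre-noise composition per batch", {
  cfg <- tiny_config(seed = 3, noise_cv = 0)
  truth <- simulate_ground_truth(cfg)
  it <- simulate_intensities(truth, simulate_growth(cfg, truth), cfg)
  meta <- it$sample_meta
  pooled <- meta$sample_type == "pooled"
  descaled <- sweep(it$intensity[, pooled], 2,
                    truth$plate_factor_true[meta$plate[pooled]], "/")
  for (b in unique(meta$batch[pooled])) {
    cols <- descaled[, meta$batch[pooled] == b, drop = FALSE]
    expect_lt(max(abs(cols - cols[, 1])), 1e-9)
  }
  # blanks emit scaled background only
  blank <- which(meta$sample_type == "blank")[1]
  expect_equal(it$intensity[, blank],
               truth$plate_factor_true[[meta$plate[blank]]] *
                 truth$beta_true)
})

test_that("noiseless regression on simulated intensities recovers alpha", {
  cfg <- tiny_config(seed = 4, noise_cv = 0)
  truth <- simulate_ground_truth(cfg)
  samples <- simulate_growth(cfg, truth)
  it <- simulate_intensities(truth, samples, cfg)
  # least-squares oracle on one line, intensities already descaled
  l <- truth$cell_lines[1]
  rows <- it$sample_meta$cell_line == l & !is.na(it$sample_meta$cell_line)
  g <- truth$plate_factor_true[it$sample_meta$plate[rows]]
  y <- it$intensity[1, rows] / g
  N <- it$sample_meta$cell_count[rows]
  fit <- lm(y ~ N)
  expect_equal(unname(coef(fit)[["N"]]), truth$alpha_true[1, l],
               tolerance = 1e-9)
  expect_equal(unname(coef(fit)[[1]]), unname(truth$beta_true[1]),
               tolerance = 1e-6)
})

test_that("expression follows the low-rank TR model with growth confounder", {
  cfg0 <- tiny_config(seed = 5, expression_noise_sd = 0,
                      growth_strength = 0)
  truth0 <- simulate_ground_truth(cfg0)
  ts0 <- simulate_tr_system(cfg0, truth0)
  expect_lte(qr(ts0$expression)$rank, cfg0$n_trs)
  # sign propagation: an all-activation TR's exclusive targets track it
  e <- truth0$regulatory_edges
  counts <- table(e$tr, e$mode)
  allpos <- rownames(counts)[counts[, "Activation"] ==
                               rowSums(counts)][1]
  skip_if(is.na(allpos))
  tg <- e$target[e$tr == allpos]
  excl <- tg[!tg %in% e$target[e$tr != allpos]]
  for (g in excl)
    expect_gt(cor(ts0$expression[g, ],
                  truth0$tr_activity_true[allpos, ]), 0.99)
  # growth confounder dominates the first expression PC
  st <- tiny_study()
  pc1 <- prcomp(t(st$tr_system$expression), center = TRUE)$x[, 1]
  expect_gt(abs(cor(pc1, st$tr_system$growth_rate)), 0.5)
})

test_that("cohort generator plants the perturbed TR signature", {
  st <- tiny_study()
  C <- matrix(rnorm(15 * 40), 15,
              dimnames = list(st$truth$trs, paste0("met", 1:40)))
  cfg <- st$truth$config
  tr <- st$truth$perturbed_tr
  expect_error(simulate_cohort(C, cfg, "not_a_tr"), "unknown perturbed_tr")
  # noiseless, no missingness: FC proportional to the standardized signature
  co <- simulate_cohort(C, cfg, tr, effect_size = 1, noise_sd = 0,
                        missing_frac = 0, dropout_frac = 0)
  expect_equal(co$fc[, 1], C[tr, ] / sd(C[tr, ]), ignore_attr = TRUE)
  # null cohort carries no signature
  co0 <- simulate_cohort(C, cfg, tr, effect_size = 0, noise_sd = 1,
                         missing_frac = 0, dropout_frac = 0)
  expect_lt(abs(cor(rowMeans(co0$fc), C[tr, ])), 0.5)
  # heavy-dropout metabolites exceed the >10-missing filter
  co2 <- simulate_cohort(C, cfg, tr, dropout_frac = 0.2)
  expect_gt(sum(rowSums(is.na(co2$fc)) > 10), 0)
})

test_that("effector modulation has the stated saturable forms and limits", {
  x <- c(0.2, 1, 5)
  expect_equal(trmet:::effector_f(x, 1, "activating"), x / (1 + x))
  expect_equal(trmet:::effector_f(x, 1, "inhibiting"), 1 / (1 + x))
  # K -> 0 activating: f -> 1, activity proportional to protein
  expect_equal(trmet:::effector_f(x, 1e-12, "activating"), rep(1, 3),
               tolerance = 1e-10)
  st <- tiny_study()
  pd <- st$proteome_drugs
  expect_true(all(pd$proteome > 0))
  expect_setequal(unique(pd$protein_type), c("TR", "kinase"))
  # non-effector TRs keep their ground-truth activity
  other <- setdiff(st$truth$trs, st$truth$planted_effectors$tr)[1]
  expect_equal(pd$activity[other, ], st$truth$tr_activity_true[other, ])
})

test_that("flux proxies put about 70% of glucose carbon into lactate", {
  cfg <- sim_config(seed = 8)  # 54 lines
  truth <- simulate_ground_truth(cfg)
  fx <- simulate_flux(cfg, truth)
  carbon <- 3 * fx$lactate_secretion / (6 * fx$glucose_uptake)
  expect_equal(mean(carbon), 0.7, tolerance = 0.05)
  expect_true(all(fx$glucose_uptake > 0))
})
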