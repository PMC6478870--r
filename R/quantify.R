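# Quantification: from raw ion intensities and confluence to comparable,
# volume-corrected, Z-scored metabolite abundances per cell line.

#' Convert confluence to extracted cell number
#'
#' Cell count is confluence (fraction of the well covered) times well area
#' divided by the line's characteristic single-cell area.
#'
#' @param confluence percent confluence in \[0, 100\].
#' @param cell_area characteristic adherent cell area, square micrometres.
#' @param well_area well surface area, square micrometres (default: 96-well
#'   plate, 0.32 cm^2).
#' @return cell counts (same length as `confluence`).
#' @export
#' @examples
#' cells_from_confluence(50, cell_area = 1600)  # 10,000 cells
cells_from_confluence <- function(confluence, cell_area, well_area = 0.32e8) {
  if (any(confluence < 0 | confluence > 100, na.rm = TRUE))
    stop("cells_from_confluence: confluence must be within [0, 100]")
  if (any(cell_area <= 0) || any(well_area <= 0))
    stop("cells_from_confluence: areas must be positive")
  (confluence / 100) * well_area / cell_area
}

#' Estimate plate scaling factors from pooled samples
#'
#' Fits the two-factor log-linear model
#' `log(I[i,j,p]) = log(gamma[p]) + log(M[i,j])` over pooled QC samples,
#' where the pooled composition `M` is specific to an (ion, batch) pair.
#' Because pooled extracts only tie together plates of the same batch, the
#' gauge `prod(gamma) = 1` is imposed within each connected component of
#' the plate/pool design. All intensities on plate p are divided by
#' `gamma[p]`.
#'
#' @param table an `intensity_table` (see [simulate_intensities()]): list
#'   with `intensity` (ions x samples) and `sample_meta` carrying `plate`,
#'   `batch` and `sample_type` columns.
#' @param max_iter,tol backfitting control for unbalanced designs (balanced
#'   designs converge in one pass).
#' @return list with `gamma` (named per-plate factors; plates without
#'   pooled samples get 1 and are reported in `unidentifiable`), `corrected`
#'   (the intensity table divided by plate factors) and `unidentifiable`.
#' @export
estimate_plate_factors <- function(table, max_iter = 100, tol = 1e-10) {
  meta <- table$sample_meta
  inten <- table$intensity
  pooled <- meta$sample_type == "pooled"
  if (!any(pooled))
    stop("estimate_plate_factors: no pooled samples in the table")
  if (any(inten[, pooled] <= 0))
    stop("estimate_plate_factors: pooled intensities must be positive")
  plates <- unique(meta$plate)
  pm <- meta[pooled, ]
  li <- log(inten[, pooled, drop = FALSE])

  # long-format response indexed by plate and (ion, batch) composition
  n_ion <- nrow(inten)
  plate_of <- rep(pm$plate, each = n_ion)
  comp_of <- paste(rep(rownames(inten), times = nrow(pm)),
                   rep(pm$batch, each = n_ion), sep = "\r")
  y <- as.vector(li)
  pf <- factor(plate_of)
  cf <- factor(comp_of)
  lg <- stats::setNames(rep(0, nlevels(pf)), levels(pf))
  for (it in seq_len(max_iter)) {
    lm_comp <- tapply(y - lg[pf], cf, mean)
    lg_new <- tapply(y - lm_comp[cf], pf, mean)
    delta <- max(abs(lg_new - lg))
    lg <- lg_new
    if (delta < tol) break
  }
  # per-component gauge: plates are connected iff they share a batch
  plate_batch <- pm$batch[match(levels(pf), pm$plate)]
  for (b in unique(plate_batch)) {
    i <- plate_batch == b
    lg[i] <- lg[i] - mean(lg[i])
  }
  gamma <- stats::setNames(rep(1, length(plates)), plates)
  gamma[names(lg)] <- exp(lg)
  unident <- setdiff(plates, names(lg))
  if (length(unident))
    warning("estimate_plate_factors: no pooled samples on plate(s) ",
            paste(unident, collapse = ", "), "; factors set to 1")
  corrected <- table
  corrected$intensity <- sweep(inten, 2, gamma[meta$plate], "/")
  list(gamma = gamma, corrected = corrected, unidentifiable = unident)
}

#' Fit per-cell abundance slopes by multiple regression
#'
#' For each ion, one linear model over all cell samples of all lines: the
#' design has one slope `alpha[line]` multiplying that line's extracted
#' cell numbers and a single shared intercept `beta` (expected signal at
#' zero cells, i.e. MS background). Returns slopes, standard errors and
#' two-sided t-test p-values; estimates are invariant to sample ordering.
#'
#' @param table a (plate-corrected) `intensity_table`; cell samples must
#'   carry `cell_line` and `cell_count` in `sample_meta`.
#' @return an object of class `abundance_matrix`: list with `alpha`,
#'   `alpha_se`, `alpha_p` (ions x lines), `beta`, `beta_se` (per ion),
#'   `sigma`, `df`, and `retained` (NULL until [filter_ions()]).
#' @export
fit_cell_regression <- function(table) {
  meta <- table$sample_meta
  cell <- !is.na(meta$cell_line)
  meta <- meta[cell, ]
  y <- t(table$intensity[, cell, drop = FALSE])  # samples x ions
  lines <- sort(unique(meta$cell_line))
  for (l in lines) {
    n_l <- meta$cell_count[meta$cell_line == l]
    if (length(n_l) < 3 || length(unique(n_l)) < 2)
      stop("fit_cell_regression: cell line '", l,
           "' needs >= 3 samples spanning >= 2 distinct cell counts")
  }
  n <- nrow(meta)
  X <- matrix(0, n, length(lines) + 1L,
              dimnames = list(NULL, c(lines, ".beta")))
  X[cbind(seq_len(n), match(meta$cell_line, lines))] <- meta$cell_count
  X[, length(lines) + 1L] <- 1
  estimable <- c(vapply(lines, function(l)
    sum(X[, l]^2) > 0, logical(1)), TRUE)
  Xe <- X[, estimable, drop = FALSE]
  xtx_inv <- solve(crossprod(Xe))
  coef <- xtx_inv %*% crossprod(Xe, y)
  res <- y - Xe %*% coef
  df <- n - ncol(Xe)
  sigma2 <- colSums(res^2) / df
  d <- diag(xtx_inv)
  se <- sqrt(outer(d, sigma2))
  tt <- coef / se
  p <- 2 * stats::pt(-abs(tt), df)

  full <- function(m, fill = NA_real_) {
    out <- matrix(fill, length(lines) + 1L, ncol(y),
                  dimnames = list(c(lines, ".beta"), colnames(y)))
    out[rownames(m), ] <- m
    out
  }
  rownames(coef) <- rownames(se) <- rownames(tt) <- colnames(Xe)
  rownames(p) <- colnames(Xe)
  coef <- full(coef); se <- full(se); p <- full(p)
  # orientation: ions x lines
  ab <- list(
    alpha = t(coef[lines, , drop = FALSE]),
    alpha_se = t(se[lines, , drop = FALSE]),
    alpha_p = t(p[lines, , drop = FALSE]),
    beta = stats::setNames(coef[".beta", ], colnames(y)),
    beta_se = stats::setNames(se[".beta", ], colnames(y)),
    sigma = sqrt(sigma2), df = df, retained = NULL)
  class(ab) <- "abundance_matrix"
  ab
}

#' Retain ions with a robust cell-number dependency
#'
#' Dual criterion: the Bonferroni-adjusted regression p-value threshold
#' `alpha / (n_lines * n_ions)` must be met in at least one line, and the
#' nominal threshold (`nominal_alpha`, or the Bonferroni one when
#' `frac_mode = "bonferroni"`) in more than `frac_lines` of lines.
#'
#' @param ab an `abundance_matrix`.
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @param frac_lines required fraction of lines passing the per-line test.
#' @param nominal_alpha per-line threshold used for the fraction criterion.
#' @param frac_mode whether the fraction criterion uses the nominal or the
#'   Bonferroni threshold.
#' @return `ab` with a logical `retained` flag and attribute `threshold`.
#' @export
filter_ions <- function(ab, alpha = 0.05, frac_lines = 0.8,
                        nominal_alpha = 0.05,
                        frac_mode = c("nominal", "bonferroni")) {
  frac_mode <- match.arg(frac_mode)
  p <- ab$alpha_p
  thr <- alpha / (ncol(p) * nrow(p))
  line_thr <- if (frac_mode == "nominal") nominal_alpha else thr
  min_p <- apply(p, 1, min, na.rm = TRUE)
  frac <- rowMeans(p < line_thr, na.rm = TRUE)
  ab$retained <- is.finite(min_p) & min_p <= thr & frac > frac_lines
  attr(ab, "threshold") <- thr
  ab
}

#' Correct per-cell abundances for cell-volume differences
#'
#' PCA across retained ions (lines as observations) identifies the dominant
#' cell-volume trend; ions whose abundance profile correlates with the PC1
#' scores (Pearson r above `r_threshold`, p below `p_threshold`) are
#' rescaled to unit mean and averaged into a per-line consensus correction
#' factor, by which all abundance columns are divided. PC1 scores are
#' oriented so larger scores mean larger overall abundance.
#'
#' @param ab a filtered `abundance_matrix`.
#' @param r_threshold,p_threshold ion selection thresholds.
#' @param standardize scale ions to unit variance before PCA (default:
#'   centre only).
#' @return list with `ab` (corrected), `volume_factor` (per line),
#'   `selected` (ion names used for the consensus), `pc1` (scores).
#' @export
volume_correct <- function(ab, r_threshold = 0.8, p_threshold = 0.05,
                           standardize = FALSE) {
  if (is.null(ab$retained))
    stop("volume_correct: run filter_ions() first")
  A <- ab$alpha[ab$retained, , drop = FALSE]
  if (nrow(A) < 3)
    stop("volume_correct: need >= 3 retained ions")
  pc <- stats::prcomp(t(A), center = TRUE, scale. = standardize)
  s1 <- pc$x[, 1]
  if (stats::sd(s1) == 0) {
    # no between-line variance at all: nothing to correct
    return(list(ab = ab,
                volume_factor = stats::setNames(rep(1, ncol(A)),
                                                colnames(A)),
                selected = character(0), pc1 = s1))
  }
  if (stats::cor(s1, colMeans(A)) < 0) s1 <- -s1
  n <- length(s1)
  r <- as.vector(stats::cor(t(A), s1))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  pv <- 2 * stats::pt(-abs(tt), n - 2)
  sel <- which(r > r_threshold & pv < p_threshold)
  if (length(sel) == 0)
    stop("volume_correct: no ion passed the volume-reporter selection ",
         "(max Pearson r = ", round(max(r), 3), ")")
  scaled <- A[sel, , drop = FALSE] / rowMeans(A[sel, , drop = FALSE])
  vf <- colMeans(scaled)
  ab$alpha <- sweep(ab$alpha, 2, vf, "/")
  ab$alpha_se <- sweep(ab$alpha_se, 2, vf, "/")
  list(ab = ab, volume_factor = vf, selected = rownames(A)[sel], pc1 = s1)
}

#' Z-score normalize abundances across cell lines
#'
#' Per ion, `z = (alpha - mean(alpha)) / sd_pop(alpha)` with the population
#' (1/n) standard deviation. Missing values propagate (they reflect
#' abundances near background and can be treated as zero downstream);
#' zero-variance ions are flagged and set to NA.
#'
#' @param ab an `abundance_matrix`, or a plain ions x lines matrix.
#' @param retained_only restrict to retained ions when a filtered
#'   `abundance_matrix` is supplied.
#' @return list with `z` (ions x lines) and logical `zero_variance`.
#' @export
zscore_abundance <- function(ab, retained_only = TRUE) {
  A <- if (inherits(ab, "abundance_matrix")) {
    if (retained_only && !is.null(ab$retained))
      ab$alpha[ab$retained, , drop = FALSE]
    else ab$alpha
  } else ab
  if (ncol(A) < 2) stop("zscore_abundance: need >= 2 cell lines")
  mu <- rowMeans(A, na.rm = TRUE)
  n_obs <- rowSums(!is.na(A))
  sd_pop <- sqrt(rowSums((A - mu)^2, na.rm = TRUE) / n_obs)
  zero <- !is.na(sd_pop) & sd_pop == 0
  z <- (A - mu) / sd_pop
  z[zero, ] <- NA_real_
  list(z = z, zero_variance = zero)
}

#' Mass of a proton (amu), as subtracted for deprotonated ions
#' @return scalar mass in amu.
#' @export
proton_mass <- function() 1.007276

#' Phenylhydrazone derivatization mass shift (amu)
#'
#' Condensation of phenylhydrazine with an alpha-keto acid adds C6H8N2 and
#' eliminates water: +C6H8N2 - H2O, computed from standard atomic masses.
#' @return scalar mass shift in amu (about +90.05818).
#' @export
phenylhydrazone_shift <- function() {
  h <- 1.0078250319; c12 <- 12; n <- 14.0030740052; o <- 15.9949146221
  (6 * c12 + 8 * h + 2 * n) - (2 * h + o)
}

#' Annotate ions by m/z matching against a reference compound list
#'
#' An ion matches a compound if its m/z is within `tolerance` of the
#' deprotonated neutral mass `M - 1.007276`. Compounds flagged as
#' alpha-keto acids are additionally tested as deprotonated
#' phenylhydrazone derivatives (`M + 90.05818 - 1.007276`). All matches
#' are reported.
#'
#' @param mz named numeric vector of ion m/z values (amu).
#' @param reference data.frame with columns `compound_id`, `formula`,
#'   `monoisotopic_mass` and logical `is_alpha_keto`.
#' @param tolerance mass accuracy window (amu).
#' @return data.frame: ion, mz, compound_id, formula, adduct, mass_error.
#' @export
annotate_ions <- function(mz, reference, tolerance = 0.003) {
  stopifnot(all(c("compound_id", "monoisotopic_mass", "is_alpha_keto") %in%
                  names(reference)))
  if (is.null(names(mz))) names(mz) <- paste0("ion", seq_along(mz))
  targets <- data.frame(
    compound_id = reference$compound_id,
    formula = if ("formula" %in% names(reference)) reference$formula else NA,
    adduct = "[M-H]-",
    target = reference$monoisotopic_mass - proton_mass(),
    stringsAsFactors = FALSE)
  keto <- reference[reference$is_alpha_keto, , drop = FALSE]
  if (nrow(keto) > 0) {
    targets <- rbind(targets, data.frame(
      compound_id = keto$compound_id,
      formula = if ("formula" %in% names(keto)) keto$formula else NA,
      adduct = "[M+C6H8N2-H2O-H]-",
      target = keto$monoisotopic_mass + phenylhydrazone_shift() -
        proton_mass(),
      stringsAsFactors = FALSE))
  }
  out <- lapply(seq_along(mz), function(i) {
    err <- mz[i] - targets$target
    hit <- which(abs(err) <= tolerance)
    if (length(hit) == 0) return(NULL)
    data.frame(ion = names(mz)[i], mz = unname(mz[i]),
               compound_id = targets$compound_id[hit],
               formula = targets$formula[hit],
               adduct = targets$adduct[hit],
               mass_error = err[hit], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(ion = character(0), mz = numeric(0),
                      compound_id = character(0), formula = character(0),
                      adduct = character(0), mass_error = numeric(0))
  rownames(out) <- NULL
  out
}
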