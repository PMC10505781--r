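#' Back-solve age-specific SNP effects from breeding values
#'
#' The SNP effect vector at age t is obtained from the genotyped animals'
#' breeding values at that age as
#' `beta_t = q (1 - alpha) W' G^-1 GEBV_t`, with `W` the centred marker
#' matrix, `G` the blended genomic relationship matrix and `q` its marker
#' scaling factor. The `(1 - alpha)` factor carries the share of the blended
#' relationship matrix that the markers explain, making the back-solved
#' effects consistent with the prediction-error variance used for their
#' standard errors; with no blending (`alpha = 0`) it vanishes and
#' `W beta_t` reproduces `GEBV_t` exactly.
#'
#' @param rel A `relationship_set` with a genotyped block.
#' @param gebv_t Named vector of breeding values at age t for the genotyped
#'   animals, in panel order.
#' @return Per-SNP effect vector (trait units per allele).
#' @export
snp_effects_at_age <- function(rel, gebv_t) {
  if (is.null(rel$W)) stop("relationship set has no genotyped block")
  if (length(gebv_t) != nrow(rel$W)) {
    stop("gebv_t length ", length(gebv_t), " does not match the ",
         nrow(rel$W), " genotyped animals")
  }
  rel$q * (1 - rel$alpha) *
    drop(crossprod(rel$W, rel$G_adj_inv %*% gebv_t))
}

#' Sampling variances of the back-solved SNP effects at an age
#'
#' Collapses the coefficient-level prediction-error covariance `C22`
#' (3x3 blocks per animal pair) onto age t as
#' `Ct22 = Phi_t C22 Phi_t'` and evaluates
#' `var(beta_t) = diag[ q^2 (1 - alpha)^2 W' G^-1 (G sigma2_ut - Ct22)
#' G^-1 W ]`, where `sigma2_ut = phi_t' V_g phi_t` is the additive genetic
#' variance at age t. Entries within a numerical tolerance of zero are
#' clamped to zero; genuinely negative entries signal inconsistent inputs
#' and raise an error.
#'
#' @param rel A `relationship_set` with a genotyped block.
#' @param C22 From [pev_block_c22()], animal-major over the genotyped set.
#' @param basis Random-regression [legendre_basis()].
#' @param age Age in months.
#' @param comps [cov_components()].
#' @return Per-SNP sampling variance vector; attribute `"sigma2_ut"` holds
#'   the additive variance at `age`.
#' @export
snp_variance_at_age <- function(rel, C22, basis, age, comps) {
  phi <- legendre_design_row(basis, age, basis$order)
  k <- length(phi)
  n_g <- length(rel$genotyped_ids)
  stopifnot(nrow(C22) == k * n_g)
  sigma2_ut <- drop(phi %*% comps$V_g %*% phi)
  if (sigma2_ut <= 0) stop("additive genetic variance is zero at age ", age)
  Phi_t <- matrix(0, n_g, k * n_g)
  Phi_t[cbind(rep(seq_len(n_g), each = k),
              seq_len(k * n_g))] <- rep(phi, n_g)
  Ct22 <- Phi_t %*% C22 %*% t(Phi_t)
  Tm <- rel$G_adj_inv %*% rel$W
  mid <- rel$G_adj * sigma2_ut - Ct22
  v <- rel$q^2 * (1 - rel$alpha)^2 * colSums(Tm * (mid %*% Tm))
  # tolerance on the scale of the perfect-information variance, so exact
  # cancellations (zero-information inputs) round to zero rather than raise
  scale_v <- rel$q^2 * (1 - rel$alpha)^2 * sigma2_ut *
    max(colSums(Tm * (rel$G_adj %*% Tm)))
  floor_tol <- 1e-8 * scale_v
  if (any(v < -floor_tol)) {
    stop("negative SNP sampling variance detected; C22 and the covariance ",
         "components are inconsistent")
  }
  v <- pmax(v, 0)
  attr(v, "sigma2_ut") <- sigma2_ut
  v
}

#' Two-sided normal P-values for SNP effects
#'
#' `z = beta / sqrt(var)`; `p = 2 (1 - Phi_N(|z|))`. The `-log10(p)` column
#' is evaluated through the log survival function, so it stays finite for
#' arbitrarily large `|z|`.
#'
#' @param effects Per-SNP effects.
#' @param variances Per-SNP sampling variances (must be > 0).
#' @return `data.frame` with `effect`, `se`, `z`, `p`, `neg_log10_p`.
#' @export
snp_pvalues <- function(effects, variances) {
  if (any(variances <= 0)) {
    stop(sum(variances <= 0), " SNP have non-positive sampling variance")
  }
  se <- sqrt(variances)
  z <- effects / se
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  nlp <- -(stats::pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) +
             log(2)) / log(10)
  data.frame(effect = effects, se = se, z = z, p = p, neg_log10_p = nlp)
}

#' Percentage of additive genetic variance explained per SNP
#'
#' `100 * 2 p_o (1 - p_o) beta_o^2 / sigma2_ut`: the variance contributed
#' by one marker at Hardy-Weinberg proportions relative to the total
#' additive genetic variance at the age considered.
#'
#' @param effects Per-SNP effects at one age.
#' @param freq Per-SNP allele frequencies.
#' @param sigma2_ut Additive genetic variance at that age (> 0).
#' @return Per-SNP percentages.
#' @export
variance_explained <- function(effects, freq, sigma2_ut) {
  if (sigma2_ut <= 0) stop("sigma2_ut must be > 0")
  100 * 2 * freq * (1 - freq) * effects^2 / sigma2_ut
}

# Li-Ji effective-test count from one correlation matrix.
meff_from_corr <- function(R) {
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  snap <- abs(ev - round(ev)) < 1e-9
  ev[snap] <- round(ev[snap])
  sum((ev >= 1) + (ev - floor(ev)))
}

#' Effective number of independent SNP (Li-Ji)
#'
#' Eigen-decomposes the SNP Pearson correlation matrix and counts
#' `sum_i [ I(lambda_i >= 1) + (lambda_i - floor(lambda_i)) ]`. By default
#' the count is computed within each chromosome and summed (between-
#' chromosome correlation is sampling noise); `per_chromosome = FALSE`
#' uses the full panel-wide matrix.
#'
#' @param panel A filtered, imputed [genotype_panel()].
#' @param per_chromosome Sum per-chromosome counts (default) or use the
#'   full correlation matrix.
#' @return The effective number of SNP (not necessarily an integer).
#' @export
effective_num_snp <- function(panel, per_chromosome = TRUE) {
  dos <- panel$dosages
  if (ncol(dos) < 2L) stop("need at least 2 SNP")
  sds <- apply(dos, 2L, stats::sd)
  if (any(sds == 0)) {
    stop(sum(sds == 0), " SNP have constant genotypes; ",
         "their correlation is undefined")
  }
  if (per_chromosome) {
    sum(vapply(split(seq_len(ncol(dos)), panel$map$chrom), function(ix) {
      if (length(ix) == 1L) return(1)
      meff_from_corr(stats::cor(dos[, ix, drop = FALSE]))
    }, numeric(1)))
  } else {
    meff_from_corr(stats::cor(dos))
  }
}

#' Genome-wide significance threshold from the effective test count
#'
#' Sidak correction on the effective number of independent SNP:
#' `-log10[1 - (1 - alpha)^(1 / m_eff)]`.
#'
#' @param m_eff Effective number of SNP (>= 1).
#' @param alpha Genome-wide type-I error rate, in (0, 1).
#' @return Threshold on the `-log10(p)` scale.
#' @export
significance_threshold <- function(m_eff, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (m_eff < 1) stop("m_eff must be >= 1")
  -log10(-expm1(log1p(-alpha) / m_eff))
}

#' Run the longitudinal single-step GWAS
#'
#' End-to-end association stage: solves the single-step random-regression
#' MME, inverts the coefficient matrix for the prediction-error block of the
#' genotyped animals, and, for each requested age, back-solves SNP effects
#' from the age-collapsed breeding values, attaches prediction-error based
#' standard errors, two-sided P-values and the percentage of additive
#' genetic variance explained. SNP are classified as `persistent`
#' (significant at every requested age), `transient` (at some but not all)
#' or `null` against the Sidak threshold on the Li-Ji effective test count.
#'
#' @param phenos A filtered `phenotype_table`.
#' @param pedigree Pedigree `data.frame`.
#' @param panel A filtered, imputed [genotype_panel()].
#' @param comps [cov_components()] (fixed inputs or Gibbs posterior means).
#' @param ages Ages (months) at which effects are tested.
#' @param alpha_blend Blending weight for G (default 0.05).
#' @param tune,tune_order Tuning controls, see [blend_and_tune_G()].
#' @param sig_alpha Genome-wide type-I error rate (default 0.05).
#' @param random_order,fixed_order Legendre degrees of the random (2) and
#'   fixed (4) regressions.
#' @param tol,max_iter PCG controls, see [solve_pcg()].
#' @param meff_per_chromosome See [effective_num_snp()].
#' @param max_dense_dim See [pev_block_c22()].
#' @return A `gwas_result`: `tables` (one `data.frame` per age with columns
#'   `snp_id`, `chrom`, `pos`, `effect`, `se`, `p`, `neg_log10_p`,
#'   `pct_var`), `summary` (per-SNP persistence class and per-age
#'   significance), `m_eff`, `threshold_neglog10`, `sigma2_ut`, plus the
#'   fitted `solution`, `rel`, `basis` for downstream use.
#' @export
run_longitudinal_gwas <- function(phenos, pedigree, panel, comps,
                                  ages = c(10, 20, 30, 40, 50, 60),
                                  alpha_blend = 0.05, tune = TRUE,
                                  tune_order = "tune_then_blend",
                                  sig_alpha = 0.05,
                                  random_order = 2L, fixed_order = 4L,
                                  tol = 1e-14, max_iter = 20000L,
                                  meff_per_chromosome = TRUE,
                                  max_dense_dim = 8000L) {
  basis <- legendre_basis(random_order, 0, 60)
  rel <- build_relationships(pedigree, panel, alpha = alpha_blend,
                             tune = tune, tune_order = tune_order)
  system <- assemble_mme(phenos, basis, rel, comps,
                         fixed_order = fixed_order)
  solution <- solve_pcg(system, tol = tol, max_iter = max_iter)
  C22 <- pev_block_c22(system, max_dense_dim = max_dense_dim)
  m_eff <- effective_num_snp(panel, per_chromosome = meff_per_chromosome)
  thr <- significance_threshold(m_eff, sig_alpha)
  tables <- list()
  sigma2_ut <- numeric(0)
  sig_mat <- matrix(FALSE, nrow(panel$map), length(ages),
                    dimnames = list(panel$map$snp_id, ages))
  for (j in seq_along(ages)) {
    t_age <- ages[j]
    gebv_t <- gebv_at_age(solution, basis, t_age, rel$genotyped_ids)
    beta <- snp_effects_at_age(rel, gebv_t)
    v <- snp_variance_at_age(rel, C22, basis, t_age, comps)
    s2u <- attr(v, "sigma2_ut")
    pv <- snp_pvalues(beta, as.numeric(v))
    tab <- data.frame(snp_id = panel$map$snp_id, chrom = panel$map$chrom,
                      pos = panel$map$pos, effect = pv$effect, se = pv$se,
                      p = pv$p, neg_log10_p = pv$neg_log10_p,
                      pct_var = variance_explained(beta, panel$allele_freq,
                                                   s2u))
    tables[[as.character(t_age)]] <- tab
    sigma2_ut[as.character(t_age)] <- s2u
    sig_mat[, j] <- tab$neg_log10_p >= thr
  }
  n_sig <- rowSums(sig_mat)
  summary <- data.frame(snp_id = panel$map$snp_id, chrom = panel$map$chrom,
                        pos = panel$map$pos, n_ages_significant = n_sig,
                        class = ifelse(n_sig == length(ages), "persistent",
                                       ifelse(n_sig > 0, "transient",
                                              "null")))
  structure(list(tables = tables, summary = summary, m_eff = m_eff,
                 threshold_neglog10 = thr, sigma2_ut = sigma2_ut,
                 ages = ages, solution = solution, rel = rel,
                 basis = basis, comps = comps),
            class = "gwas_result")
}

#' @export
print.gwas_result <- function(x, ...) {
  cat("gwas_result:", nrow(x$summary), "SNP at ages",
      paste(x$ages, collapse = ", "), "months\n")
  cat("  m_eff =", round(x$m_eff, 1), "; -log10 threshold =",
      round(x$threshold_neglog10, 2), "\n")
  cat("  persistent:", sum(x$summary$class == "persistent"),
      "; transient:", sum(x$summary$class == "transient"), "\n")
  invisible(x)
}

#' Manhattan plot of one age's association results
#'
#' Simple base-graphics Manhattan plot with chromosome-alternating colours
#' and the genome-wide threshold line.
#'
#' @param result A `gwas_result`.
#' @param age One of the ages in `result$ages`.
#' @param ... Passed to [plot()].
#' @return Invisibly, the plotted table.
#' @export
plot_manhattan <- function(result, age = result$ages[1], ...) {
  tab <- result$tables[[as.character(age)]]
  if (is.null(tab)) stop("no results at age ", age)
  ord <- order(tab$chrom, tab$pos)
  tab <- tab[ord, ]
  xpos <- seq_len(nrow(tab))
  cols <- c("grey30", "steelblue")[tab$chrom %% 2 + 1]
  plot(xpos, tab$neg_log10_p, col = cols, pch = 20,
       xlab = "SNP (genome order)", ylab = expression(-log[10](p)),
       main = paste0("Age ", age, " mo"), ...)
  graphics::abline(h = result$threshold_neglog10, col = "blue")
  invisible(tab)
}
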