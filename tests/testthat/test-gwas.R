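test_that("zero breeding values back-solve to zero SNP effects", {
  d <- small_dataset()
  rel <- build_relationships(d$pedigree, d$panel_f)
  beta <- snp_effects_at_age(rel, rep(0, length(rel$genotyped_ids)))
  expect_equal(beta, rep(0, ncol(rel$W)), ignore_attr = TRUE)
  expect_error(snp_effects_at_age(rel, 1:3), "does not match")
})

test_that("back-solved effects match the explicit matrix product", {
  d <- small_dataset()
  rel <- build_relationships(d$pedigree, d$panel_f)
  set.seed(61)
  gebv <- stats::rnorm(length(rel$genotyped_ids))
  beta <- snp_effects_at_age(rel, gebv)
  oracle <- rel$q * (1 - rel$alpha) *
    as.numeric(t(rel$W) %*% solve(rel$G_adj) %*% gebv)
  expect_equal(beta, oracle, tolerance = 1e-10)
})

test_that("sampling variances obey the two information limits", {
  d <- small_dataset()
  rel <- build_relationships(d$pedigree, d$panel_f)
  basis <- d$basis
  ng <- length(rel$genotyped_ids)
  phi <- legendre_design_row(basis, 30)
  s2u <- drop(phi %*% d$comps$V_g %*% phi)
  # zero information: C22 = G (x) V_g collapses to G * sigma2_ut exactly
  C22_null <- kronecker(rel$G_adj, d$comps$V_g)
  v0 <- snp_variance_at_age(rel, C22_null, basis, 30, d$comps)
  expect_equal(as.numeric(v0), rep(0, ncol(rel$W)), tolerance = 1e-12)
  # perfect information: C22 = 0
  v1 <- snp_variance_at_age(rel, matrix(0, 3 * ng, 3 * ng), basis, 30,
                            d$comps)
  Ginv_W <- solve(rel$G_adj) %*% rel$W
  closed <- rel$q^2 * (1 - rel$alpha)^2 * s2u *
    colSums(rel$W * Ginv_W)
  expect_equal(as.numeric(v1), closed, tolerance = 1e-10)
  # inconsistent inputs (more PEV than prior variance) raise
  expect_error(snp_variance_at_age(rel, 3 * C22_null, basis, 30, d$comps),
               "negative")
})

test_that("the diagonal shortcut equals the full-matrix brute force", {
  d <- small_dataset()
  rel <- build_relationships(d$pedigree, d$panel_f)
  sys <- assemble_mme(d$phenos_f, d$basis, rel, d$comps)
  C22 <- pev_block_c22(sys)
  ng <- length(rel$genotyped_ids)
  for (age in c(10, 40)) {
    v <- snp_variance_at_age(rel, C22, d$basis, age, d$comps)
    phi <- legendre_design_row(d$basis, age)
    P <- kronecker(diag(ng), matrix(phi, 1, 3))
    Ct <- P %*% C22 %*% t(P)
    s2u <- drop(phi %*% d$comps$V_g %*% phi)
    Ginv <- solve(rel$G_adj)
    full <- rel$q^2 * (1 - rel$alpha)^2 *
      t(rel$W) %*% Ginv %*% (rel$G_adj * s2u - Ct) %*% Ginv %*% rel$W
    expect_equal(as.numeric(v), diag(full), tolerance = 1e-8)
    expect_true(all(v >= 0))
  }
})

test_that("P-values follow the two-sided normal and survive extreme z", {
  pv <- snp_pvalues(c(0, 1.959964, 3), c(1, 1, 1))
  expect_equal(pv$p[1], 1)
  expect_equal(pv$p[2], 0.05, tolerance = 1e-6)
  expect_equal(pv$neg_log10_p, -log10(pv$p), tolerance = 1e-10)
  # far tail: finite -log10(p) matching the Mills-ratio expansion
  z <- 50
  pv2 <- snp_pvalues(z, 1)
  expect_true(is.finite(pv2$neg_log10_p))
  mills <- (-z^2 / 2 - log(z) - 0.5 * log(2 * pi) +
              log1p(-1 / z^2 + 3 / z^4) + log(2)) / log(10)
  expect_equal(pv2$neg_log10_p, -mills, tolerance = 1e-4)
  expect_error(snp_pvalues(1, 0), "non-positive")
})

test_that("variance explained scales as 2pq beta^2", {
  expect_equal(variance_explained(0, 0.3, 5), 0)
  v1 <- variance_explained(2, 0.25, 10)
  expect_equal(v1, 100 * 2 * 0.25 * 0.75 * 4 / 10)
  expect_equal(variance_explained(4, 0.25, 10), 4 * v1)
  expect_error(variance_explained(1, 0.5, 0), "sigma2_ut")
})

test_that("Li-Ji count: orthogonal markers count fully, duplicates once", {
  # centred dosage columns are exactly orthogonal contrasts
  dos <- cbind(c(0, 0, 2, 2), c(0, 2, 0, 2), c(0, 2, 2, 0))
  map <- data.frame(snp_id = paste0("s", 1:3), chrom = 1, pos = 1:3)
  expect_equal(effective_num_snp(genotype_panel(1:4, dos, map)), 3)
  dup <- dos[, c(1, 1, 1, 1, 1)]
  map5 <- data.frame(snp_id = paste0("s", 1:5), chrom = 1, pos = 1:5)
  expect_equal(effective_num_snp(genotype_panel(1:4, dup, map5)), 1)
  cst <- cbind(dos, 1)
  map4 <- data.frame(snp_id = paste0("s", 1:4), chrom = 1, pos = 1:4)
  expect_error(effective_num_snp(genotype_panel(1:4, cst, map4)),
               "constant")
})

test_that("Li-Ji on an LD-structured panel sits between blocks and markers", {
  set.seed(62)
  n <- 200; blocks <- 10; per <- 8
  base <- matrix(stats::rbinom(n * blocks, 2, 0.5), n, blocks)
  dos <- matrix(0L, n, blocks * per)
  for (b in seq_len(blocks)) {
    for (j in seq_len(per)) {
      x <- base[, b]
      flip <- stats::runif(n) < 0.08   # weak within-block discordance
      x[flip] <- stats::rbinom(sum(flip), 2, 0.5)
      dos[, (b - 1) * per + j] <- x
    }
  }
  map <- data.frame(snp_id = sprintf("s%02d", seq_len(blocks * per)),
                    chrom = rep(seq_len(blocks), each = per),
                    pos = seq_len(blocks * per))
  panel <- genotype_panel(1:n, dos, map)
  m_eff <- effective_num_snp(panel, per_chromosome = FALSE)
  expect_gt(m_eff, blocks)
  expect_lt(m_eff, blocks * per)
  # brute-force oracle on the full correlation matrix
  ev <- pmax(eigen(stats::cor(dos), symmetric = TRUE,
                   only.values = TRUE)$values, 0)
  oracle <- sum((ev >= 1) + (ev - floor(ev)))
  expect_equal(m_eff, oracle, tolerance = 1e-6)
  # chromosome-wise evaluation is close for between-block independence
  m_chr <- effective_num_snp(panel, per_chromosome = TRUE)
  expect_lt(abs(m_chr - m_eff) / m_eff, 0.15)
})

test_that("significance threshold: limits, Bonferroni asymptotics, monotonicity", {
  expect_equal(significance_threshold(1, 0.05), -log10(0.05))
  # direct evaluation of the Sidak formula at moderate m
  expect_equal(significance_threshold(5000, 0.05),
               -log10(1 - 0.95^(1 / 5000)), tolerance = 1e-10)
  # for large m the threshold sits a constant -log10 offset of
  # log10(ln(1/(1-a))/a) ~ 0.011 below Bonferroni
  gap <- (-log10(0.05 / 1e6)) - significance_threshold(1e6, 0.05)
  expect_lt(abs(gap - log10(-log1p(-0.05) / 0.05)), 1e-6)
  ms <- c(1, 10, 100, 5000, 1e6)
  th <- vapply(ms, significance_threshold, numeric(1), alpha = 0.05)
  expect_true(all(diff(th) > 0))
  expect_gt(significance_threshold(100, 0.01),
            significance_threshold(100, 0.05))
  expect_error(significance_threshold(100, 1.2), "alpha")
  expect_error(significance_threshold(0.5), "m_eff")
})

test_that("a strong QTL is the top SNP at every age and classified persistent", {
  hits <- 0L
  persistent <- 0L
  b0 <- 2
  for (s in 1:5) {
    cfg <- sim_config(n_founders = 150, n_generations = 2,
                      offspring_per_mating = 2, n_snp = 300,
                      n_chromosomes = 5, maf_low = 0.4, maf_high = 0.4,
                      genotyping_rule = "all",
                      qtl_spec = list(list(snp = 150, beta = c(b0, 0, 0))),
                      records_per_animal_range = c(8, 14), seed = 70 + s)
    d <- simulate_dataset(cfg)
    pf <- filter_snps(d$panel)
    ph <- filter_phenotypes(d$phenotypes)
    comps <- cov_components(cfg$V_g, cfg$V_p, cfg$residual_variances)
    res <- run_longitudinal_gwas(ph, d$pedigree, pf, comps,
                                 ages = c(10, 30, 50))
    qtl_id <- d$panel$map$snp_id[150]
    top <- vapply(res$tables, function(tab) {
      tab$snp_id[which.max(abs(tab$effect / tab$se))]
    }, character(1))
    if (all(top == qtl_id)) {
      hits <- hits + 1L
      # its variance share tracks the generating share (shrinkage allows a
      # generous bracket) and is the largest in the panel
      p_true <- attr(d$panel, "founder_freq")[150]
      for (age in names(res$tables)) {
        tab <- res$tables[[age]]
        share <- 100 * 2 * p_true * (1 - p_true) * (b0 * sqrt(0.5))^2 /
          res$sigma2_ut[age]
        pct <- tab$pct_var[tab$snp_id == qtl_id]
        expect_equal(tab$snp_id[which.max(tab$pct_var)], qtl_id)
        # GBLUP shrinkage leaves the estimated share well below the
        # generating one; demand the right order of magnitude only
        expect_gt(pct, share / 10)
        expect_lt(pct, share * 1.5)
      }
    }
    if (res$summary$class[res$summary$snp_id == qtl_id] == "persistent") {
      persistent <- persistent + 1L
    }
  }
  expect_gte(hits, 4L)
  expect_gte(persistent, 4L)
})

test_that("requesting one age reproduces that slice of the multi-age run", {
  d <- small_dataset()
  res_all <- run_longitudinal_gwas(d$phenos_f, d$pedigree, d$panel_f,
                                   d$comps, ages = c(10, 30))
  res_one <- run_longitudinal_gwas(d$phenos_f, d$pedigree, d$panel_f,
                                   d$comps, ages = 30)
  expect_equal(res_one$tables[["30"]], res_all$tables[["30"]])
  expect_equal(res_one$m_eff, res_all$m_eff)
})

test_that("effect and variance-share rankings agree at equal allele frequencies", {
  cfg <- sim_config(n_founders = 40, n_generations = 2, n_snp = 100,
                    maf_low = 0.5, maf_high = 0.5,
                    genotyping_rule = "last_k_generations", genotype_k = 2,
                    records_per_animal_range = c(4, 8), seed = 63)
  d <- simulate_dataset(cfg)
  pf <- filter_snps(d$panel)
  ph <- filter_phenotypes(d$phenotypes)
  comps <- cov_components(cfg$V_g, cfg$V_p, cfg$residual_variances)
  res <- run_longitudinal_gwas(ph, d$pedigree, pf, comps, ages = 30)
  tab <- res$tables[["30"]]
  # with p(1-p) (nearly) equal, pct_var orders like beta^2 and the |z|
  # ordering only differs through mild SE variation
  expect_gt(stats::cor(rank(abs(tab$effect)), rank(tab$pct_var)), 0.98)
  expect_gt(stats::cor(rank(abs(tab$effect / tab$se)), rank(tab$pct_var)),
            0.9)
})
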