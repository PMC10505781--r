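# Shared small simulated data sets, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# ~30-animal pedigree with a genotyped subset; the workhorse instance for
# oracle comparisons.
small_dataset <- function() {
  if (is.null(fixture_env$small)) {
    cfg <- sim_config(n_founders = 10, n_generations = 2,
                      offspring_per_mating = 2, n_snp = 50,
                      n_chromosomes = 2, genotyping_rule = "random_fraction",
                      genotype_fraction = 0.65,
                      records_per_animal_range = c(4, 8), seed = 3)
    d <- simulate_dataset(cfg)
    d$panel_f <- filter_snps(d$panel)
    d$phenos_f <- filter_phenotypes(d$phenotypes)
    d$comps <- cov_components(cfg$V_g, cfg$V_p, cfg$residual_variances,
                              "true_simulated")
    d$basis <- legendre_basis(2)
    fixture_env$small <- d
  }
  fixture_env$small
}

# A hand-written 5-animal pedigree: two founder pairs and a full-sib pair.
toy_pedigree <- function() {
  data.frame(animal = 1:6,
             sire = c(0L, 0L, 0L, 0L, 1L, 1L),
             dam = c(0L, 0L, 0L, 0L, 2L, 2L),
             sex = c("M", "F", "M", "F", "M", "F"),
             generation = c(0L, 0L, 0L, 0L, 1L, 1L))
}

expect_symmetric <- function(M, tol = 1e-10) {
  expect_lt(max(abs(M - Matrix::t(M))), tol)
}
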