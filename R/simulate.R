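#' Configuration for the pedigree / genotype / phenotype simulator
#'
#' Bundles every knob of the generator: pedigree shape, marker panel,
#' random-regression covariance structure, fixed effects, record
#' schedules, and optional QTL. The defaults describe a moderate dairy-like
#' population: a multi-generation pedigree with a genotyped subset,
#' additive-genetic and permanent-environment regression coefficients on a
#' quadratic Legendre basis, heterogeneous residual variance in six
#' 10-month age classes between birth and 60 months, and height-like
#' records (an increasing mean curve around 110 trait units).
#'
#' @param n_founders Number of unrelated base animals (>= 2).
#' @param n_generations Number of discrete generations bred from the founders.
#' @param offspring_per_mating Offspring produced by each mating.
#' @param genotyping_rule Which animals enter the genotype panel: `"all"`,
#'   `"last_k_generations"` (see `genotype_k`) or `"random_fraction"`
#'   (see `genotype_fraction`).
#' @param genotype_k Number of most recent generations genotyped under
#'   `"last_k_generations"`.
#' @param genotype_fraction Fraction genotyped under `"random_fraction"`.
#' @param n_snp,n_chromosomes Marker panel size; SNP are assigned evenly to
#'   chromosomes.
#' @param maf_low,maf_high Founder allele-frequency range, in (0, 0.5].
#' @param V_g,V_p 3x3 covariance matrices of the additive-genetic and
#'   permanent-environment regression coefficients (trait units squared).
#' @param residual_variances Residual variance per age class; classes are
#'   equal-width bins spanning `[0, 60]` months.
#' @param n_herd_years Number of herd-year levels; effects drawn
#'   `N(0, herd_year_sd^2)`.
#' @param herd_year_sd,birth_month_sd Fixed-effect standard deviations
#'   (trait units).
#' @param age_grid Integer months at which records may be taken, within
#'   `[0, 60]`.
#' @param records_per_animal_range Min and max number of records per animal.
#' @param qtl_spec Optional list of QTL, each `list(snp = <index>,
#'   beta = <length-3 coefficient vector>)`; the polygenic component is
#'   rescaled so the total additive covariance stays `V_g`.
#' @param phenotyped_fraction Fraction of animals that receive records.
#' @param phenotyped_sex `"both"` or `"F"` (records on females only).
#' @param fixed_curve Length-5 coefficient vector of the fixed mean curve on
#'   the quartic Legendre basis.
#' @param linkage `"unlinked"` (independent Mendelian draws per locus) or
#'   `"block"` (one crossover per chromosome per meiosis, generating LD).
#' @param missing_rate Probability a panel dosage is masked missing; only
#'   used to exercise the call-rate filter.
#' @param edit_compliance Fraction of animals whose record schedule is forced
#'   to satisfy the standard data edits (>= 3 records, one before 10 and one
#'   after 30 months); the remainder is left unconstrained so the filters
#'   have work to do.
#' @param keep_transmission Store the per-meiosis gamete choices (memory
#'   heavy; intended for small verification runs).
#' @param seed Integer seed; every simulation stage derives its stream from
#'   it, so a fixed seed reproduces the data set exactly.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_founders = 100L,
                       n_generations = 4L,
                       offspring_per_mating = 2L,
                       genotyping_rule = c("last_k_generations", "all",
                                           "random_fraction"),
                       genotype_k = 2L,
                       genotype_fraction = 0.5,
                       n_snp = 1000L,
                       n_chromosomes = 10L,
                       maf_low = 0.1,
                       maf_high = 0.5,
                       V_g = diag(c(9, 1, 0.2)),
                       V_p = diag(c(4, 0.5, 0.1)),
                       residual_variances = c(16, 12, 10, 8, 7, 6),
                       n_herd_years = 8L,
                       herd_year_sd = 3,
                       birth_month_sd = 1,
                       age_grid = 0:60,
                       records_per_animal_range = c(10L, 25L),
                       qtl_spec = NULL,
                       phenotyped_fraction = 1,
                       phenotyped_sex = c("both", "F"),
                       fixed_curve = c(155.6, 24.5, 0, 0, 0),
                       linkage = c("unlinked", "block"),
                       missing_rate = 0,
                       edit_compliance = 0.9,
                       keep_transmission = FALSE,
                       seed = 1L) {
  genotyping_rule <- match.arg(genotyping_rule)
  phenotyped_sex <- match.arg(phenotyped_sex)
  linkage <- match.arg(linkage)
  if (n_founders < 2L) stop("n_founders must be >= 2 (cannot form a mating)")
  if (n_generations < 1L) stop("n_generations must be >= 1")
  if (maf_low <= 0 || maf_high > 0.5 || maf_low > maf_high) {
    stop("maf bounds must satisfy 0 < maf_low <= maf_high <= 0.5")
  }
  check_psd(V_g, "V_g")
  check_psd(V_p, "V_p")
  if (any(residual_variances < 0)) stop("residual variances must be >= 0")
  if (any(age_grid < 0 | age_grid > 60)) stop("age_grid must lie in [0, 60]")
  if (length(fixed_curve) != 5L) stop("fixed_curve must have length 5")
  if (!is.null(qtl_spec)) {
    ok <- vapply(qtl_spec, function(q) {
      is.list(q) && !is.null(q$snp) && length(q$beta) == 3L
    }, logical(1))
    if (!all(ok)) stop("each qtl_spec entry needs $snp and a length-3 $beta")
  }
  structure(as.list(environment()), class = "sim_config")
}

# sample() that never interprets a length-1 x as 1:x
resample <- function(x, size = 1L, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

check_psd <- function(M, name) {
  if (!isSymmetric(unname(M), tol = 1e-8)) stop(name, " must be symmetric")
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop(name, " must be positive semidefinite")
  }
  invisible(TRUE)
}

#' Simulate a multi-generation pedigree
#'
#' Breeds `n_generations` discrete generations from `n_founders` unrelated
#' base animals by random mating: every female of the previous generation is
#' mated once to a sire drawn at random (with replacement, so half-sib
#' families arise) from the previous generation's males, producing
#' `offspring_per_mating` offspring. Sexes are balanced within each
#' generation. There is no selection.
#'
#' @param config A [sim_config()].
#' @return A `data.frame` of class `pedigree` with columns `animal`, `sire`,
#'   `dam` (0 = unknown), `sex`, `generation`, topologically ordered
#'   (parents precede offspring).
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 11L)
  n0 <- config$n_founders
  sex <- sample(rep(c("M", "F"), length.out = n0))
  ped <- data.frame(animal = seq_len(n0), sire = 0L, dam = 0L,
                    sex = sex, generation = 0L)
  for (g in seq_len(config$n_generations)) {
    prev <- ped[ped$generation == g - 1L, ]
    sires <- prev$animal[prev$sex == "M"]
    dams <- prev$animal[prev$sex == "F"]
    if (length(sires) < 1L || length(dams) < 1L) {
      stop("generation ", g - 1L, " lacks animals of one sex; ",
           "increase n_founders or offspring_per_mating")
    }
    n_off <- length(dams) * config$offspring_per_mating
    sire_of <- rep(resample(sires, length(dams), replace = TRUE),
                   each = config$offspring_per_mating)
    dam_of <- rep(dams, each = config$offspring_per_mating)
    ids <- max(ped$animal) + seq_len(n_off)
    ped <- rbind(ped, data.frame(
      animal = ids, sire = sire_of, dam = dam_of,
      sex = sample(rep(c("M", "F"), length.out = n_off)),
      generation = g))
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# One gamete from parent haplotypes (0/1 vectors h1, h2) under the
# configured linkage model. `chrom` is the per-locus chromosome index.
make_gamete <- function(h1, h2, chrom, linkage) {
  m <- length(h1)
  if (linkage == "unlinked") {
    pick <- sample(c(0L, 1L), m, replace = TRUE)
  } else {
    pick <- integer(m)
    for (cc in unique(chrom)) {
      idx <- which(chrom == cc)
      k <- sample(length(idx), 1L)            # one crossover per chromosome
      start <- sample(c(0L, 1L), 1L)
      pick[idx] <- c(rep(start, k), rep(1L - start, length(idx) - k))
    }
  }
  ifelse(pick == 0L, h1, h2)
}

#' Gene-drop genotypes down a pedigree
#'
#' Founder haplotypes are drawn as independent Bernoulli(p_o) gametes with
#' per-locus allele frequencies uniform in `[maf_low, maf_high]`; descendants
#' inherit one gamete from each parent per the linkage model. Dosage is the
#' count of the coded allele, in `{0, 1, 2}`.
#'
#' @param pedigree From [simulate_pedigree()].
#' @param config A [sim_config()].
#' @return A `genotype_panel` (see [genotype_panel()]) for the genotyped
#'   subset selected by `genotyping_rule`, with attributes carrying the
#'   founder frequencies and the dosages of any QTL loci for *all* pedigree
#'   animals (needed to inject QTL effects).
#' @export
simulate_genotypes <- function(pedigree, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 22L)
  n <- nrow(pedigree)
  m <- config$n_snp
  chrom <- rep(seq_len(config$n_chromosomes),
               each = ceiling(m / config$n_chromosomes))[seq_len(m)]
  p0 <- stats::runif(m, config$maf_low, config$maf_high)
  hap1 <- matrix(0L, n, m)
  hap2 <- matrix(0L, n, m)
  founders <- which(pedigree$sire == 0L & pedigree$dam == 0L)
  hap1[founders, ] <- matrix(stats::rbinom(length(founders) * m, 1L,
                                           rep(p0, each = length(founders))),
                             length(founders), m)
  hap2[founders, ] <- matrix(stats::rbinom(length(founders) * m, 1L,
                                           rep(p0, each = length(founders))),
                             length(founders), m)
  transmission <- if (config$keep_transmission) vector("list", n) else NULL
  for (i in seq_len(n)) {
    s <- pedigree$sire[i]; d <- pedigree$dam[i]
    if (s == 0L && d == 0L) next
    if (s == 0L || d == 0L) stop("animal ", pedigree$animal[i],
                                 " has exactly one known parent")
    si <- match(s, pedigree$animal); di <- match(d, pedigree$animal)
    hap1[i, ] <- make_gamete(hap1[si, ], hap2[si, ], chrom, config$linkage)
    hap2[i, ] <- make_gamete(hap1[di, ], hap2[di, ], chrom, config$linkage)
    if (config$keep_transmission) {
      transmission[[i]] <- list(sire_hap1 = hap1[si, ], sire_hap2 = hap2[si, ],
                                dam_hap1 = hap1[di, ], dam_hap2 = hap2[di, ],
                                paternal = hap1[i, ], maternal = hap2[i, ])
    }
  }
  dosage_all <- hap1 + hap2
  geno_ids <- switch(config$genotyping_rule,
    all = pedigree$animal,
    last_k_generations = pedigree$animal[
      pedigree$generation > config$n_generations - config$genotype_k],
    random_fraction = sort(sample(pedigree$animal,
      round(config$genotype_fraction * n))))
  rows <- match(geno_ids, pedigree$animal)
  dos <- dosage_all[rows, , drop = FALSE]
  if (config$missing_rate > 0) {
    dos[matrix(stats::runif(length(dos)) < config$missing_rate,
               nrow(dos), ncol(dos))] <- NA_integer_
  }
  map <- data.frame(snp_id = sprintf("snp%05d", seq_len(m)),
                    chrom = chrom,
                    pos = stats::ave(seq_len(m), chrom, FUN = seq_along) * 1e5)
  panel <- genotype_panel(geno_ids, dos, map)
  attr(panel, "founder_freq") <- p0
  if (!is.null(config$qtl_spec)) {
    qtl_idx <- vapply(config$qtl_spec, `[[`, numeric(1), "snp")
    attr(panel, "qtl_dosages") <- dosage_all[, qtl_idx, drop = FALSE]
  }
  attr(panel, "transmission") <- transmission
  panel
}

#' Construct a genotype panel
#'
#' @param animal_ids Animal identifiers, one per dosage row.
#' @param dosages `n x m` matrix of allele counts in `{0, 1, 2}`, `NA` for
#'   missing.
#' @param map `data.frame` with columns `snp_id`, `chrom`, `pos`.
#' @return A `genotype_panel` list with `animal_ids`, `dosages`, `map` and
#'   `allele_freq` (observed, `mean(dosage)/2` over non-missing calls).
#' @export
genotype_panel <- function(animal_ids, dosages, map) {
  dosages <- as.matrix(dosages)
  stopifnot(length(animal_ids) == nrow(dosages), nrow(map) == ncol(dosages))
  structure(list(animal_ids = animal_ids,
                 dosages = dosages,
                 map = map,
                 allele_freq = colMeans(dosages, na.rm = TRUE) / 2),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", length(x$animal_ids), "animals x",
      nrow(x$map), "SNP on", length(unique(x$map$chrom)), "chromosome(s)\n")
  cat("  allele freq range:",
      paste(round(range(x$allele_freq, na.rm = TRUE), 3), collapse = " - "),
      "; missing:", sum(is.na(x$dosages)), "calls\n")
  invisible(x)
}

#' Draw the true random-regression effects
#'
#' Additive-genetic coefficient vectors `u_l` (length 3, one per pedigree
#' animal) are drawn jointly from `MVN(0, V_g (x) A)` using the Cholesky
#' factors of the numerator relationship matrix `A` and of the polygenic
#' coefficient covariance; permanent-environment vectors are i.i.d.
#' `MVN(0, V_p)` for phenotyped animals. If QTL are specified, each QTL adds
#' `w_lo * beta_o` (centred dosage times its coefficient vector) to `u_l`,
#' and the polygenic covariance is reduced by the expected QTL contribution
#' `sum_o 2 p_o (1 - p_o) beta_o beta_o'` so the total additive covariance
#' remains `V_g`.
#'
#' @param pedigree From [simulate_pedigree()].
#' @param config A [sim_config()].
#' @param genotypes The panel from [simulate_genotypes()]; required when
#'   `qtl_spec` is non-empty (supplies QTL dosages for all animals).
#' @return A `true_effects` list: `additive_coeffs` (`n_ped x 3`),
#'   `pe_coeffs` (`n_phen x 3`), `phenotyped` ids, `herd_year_effects`,
#'   `birth_month_effects`, `qtl` (the QTL list used, with centring
#'   frequencies).
#' @export
simulate_effects <- function(pedigree, config, genotypes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 33L)
  n <- nrow(pedigree)
  Vg_poly <- config$V_g
  qtl <- NULL
  if (!is.null(config$qtl_spec)) {
    if (is.null(genotypes) || is.null(attr(genotypes, "qtl_dosages"))) {
      stop("qtl_spec present: pass the simulated genotypes")
    }
    p0 <- attr(genotypes, "founder_freq")
    W_qtl <- attr(genotypes, "qtl_dosages")
    contrib <- matrix(0, 3, 3)
    for (j in seq_along(config$qtl_spec)) {
      q <- config$qtl_spec[[j]]
      contrib <- contrib + 2 * p0[q$snp] * (1 - p0[q$snp]) *
        tcrossprod(q$beta)
    }
    Vg_poly <- config$V_g - contrib
    ev <- eigen(Vg_poly, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) {
      stop("QTL effects imply more additive variance than V_g allows")
    }
    qtl <- list(spec = config$qtl_spec, centering_freq = p0)
  }
  A <- build_A(pedigree)
  L_A <- t(chol(A))
  L_g <- chol_psd(Vg_poly)
  U <- L_A %*% matrix(stats::rnorm(n * 3), n, 3) %*% t(L_g)
  if (!is.null(qtl)) {
    W_qtl <- attr(genotypes, "qtl_dosages")
    for (j in seq_along(config$qtl_spec)) {
      q <- config$qtl_spec[[j]]
      w <- W_qtl[, j] - 2 * qtl$centering_freq[q$snp]
      U <- U + outer(w, q$beta)
    }
  }
  rownames(U) <- pedigree$animal
  pool <- pedigree$animal
  if (config$phenotyped_sex == "F") pool <- pedigree$animal[pedigree$sex == "F"]
  phen <- sort(sample(pool, round(config$phenotyped_fraction * length(pool))))
  L_p <- chol_psd(config$V_p)
  PE <- matrix(stats::rnorm(length(phen) * 3), length(phen), 3) %*% t(L_p)
  rownames(PE) <- phen
  structure(list(
    additive_coeffs = U,
    pe_coeffs = PE,
    phenotyped = phen,
    herd_year_effects = stats::rnorm(config$n_herd_years,
                                     sd = config$herd_year_sd),
    birth_month_effects = stats::rnorm(12L, sd = config$birth_month_sd),
    qtl = qtl), class = "true_effects")
}

# Cholesky factor of a PSD matrix, tolerating zero eigenvalues.
chol_psd <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(M))
}

#' Simulate longitudinal phenotype records
#'
#' Each phenotyped animal gets a herd-year and birth-month code and an
#' irregular schedule of integer ages sampled from `age_grid`; most
#' schedules (fraction `edit_compliance`) are forced to satisfy the standard
#' data edits. A record at age t is
#' `HY + M + phi4(t)' b + phi2(t)' u_l + phi2(t)' pe_l + e`, with residual
#' variance taken from the age class of t.
#'
#' @param pedigree From [simulate_pedigree()].
#' @param effects From [simulate_effects()].
#' @param config A [sim_config()].
#' @return A `data.frame` of class `phenotype_table` with columns `animal`,
#'   `age`, `value`, `herd_year`, `birth_month`.
#' @export
simulate_phenotypes <- function(pedigree, effects, config) {
  stopifnot(inherits(config, "sim_config"), inherits(effects, "true_effects"))
  set.seed(config$seed + 44L)
  basis <- legendre_basis(4L, 0, 60)
  grid <- sort(unique(as.integer(config$age_grid)))
  early <- grid[grid < 10]; late <- grid[grid > 30]
  if (length(early) == 0L || length(late) == 0L) {
    stop("age_grid must contain ages below 10 and above 30 months")
  }
  rng <- config$records_per_animal_range
  rows <- vector("list", length(effects$phenotyped))
  for (ii in seq_along(effects$phenotyped)) {
    id <- effects$phenotyped[ii]
    n_rec <- resample(seq(rng[1], rng[2]))
    if (stats::runif(1) < config$edit_compliance) {
      n_rec <- max(n_rec, 3L)
      ages <- c(resample(early), resample(late))
      rest <- setdiff(grid, ages)
      ages <- c(ages, resample(rest, min(n_rec - 2L, length(rest))))
    } else {
      ages <- resample(grid, min(n_rec, length(grid)))
    }
    ages <- sort(ages)
    if (length(ages) == 0L) stop("empty record schedule for animal ", id)
    hy <- sample.int(config$n_herd_years, 1L)
    bm <- sample.int(12L, 1L)
    Phi4 <- legendre_design_row(basis, ages, 4L)
    if (length(ages) == 1L) Phi4 <- matrix(Phi4, 1L)
    Phi2 <- Phi4[, 1:3, drop = FALSE]
    cls <- age_class(ages, length(config$residual_variances))
    e <- stats::rnorm(length(ages),
                      sd = sqrt(config$residual_variances[cls]))
    y <- effects$herd_year_effects[hy] + effects$birth_month_effects[bm] +
      drop(Phi4 %*% config$fixed_curve) +
      drop(Phi2 %*% effects$additive_coeffs[as.character(id), ]) +
      drop(Phi2 %*% effects$pe_coeffs[as.character(id), ]) + e
    rows[[ii]] <- data.frame(animal = id, age = ages, value = y,
                             herd_year = hy, birth_month = bm)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Residual age class of an age
#'
#' Ages in `[0, 60]` months are binned into `n_classes` equal-width classes
#' (default 6 classes of 10 months, the last closed at 60).
#'
#' @param age Age(s) in months.
#' @param n_classes Number of residual classes.
#' @return Integer class index in `1..n_classes`.
#' @export
age_class <- function(age, n_classes = 6L) {
  pmin(as.integer(floor(age / (60 / n_classes))) + 1L, n_classes)
}

#' Simulate a complete data set
#'
#' Convenience wrapper running pedigree, genotype, effect and phenotype
#' simulation in order.
#'
#' @param config A [sim_config()].
#' @return List with `pedigree`, `panel`, `effects`, `phenotypes`, `config`.
#' @export
simulate_dataset <- function(config) {
  ped <- simulate_pedigree(config)
  panel <- simulate_genotypes(ped, config)
  eff <- simulate_effects(ped, config, panel)
  phen <- simulate_phenotypes(ped, eff, config)
  list(pedigree = ped, panel = panel, effects = eff, phenotypes = phen,
       config = config)
}
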