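#' Read and write the pipeline's plain-text formats
#'
#' Pedigree: CSV `animal,sire,dam` (0 = unknown), optional `sex`,
#' `generation`. Phenotypes: CSV `animal,age,value,herd_year,birth_month`.
#' Genotypes: dosage TSV (first column `animal`, one column per SNP) plus a
#' map TSV `snp_id,chrom,pos`; missing dosages are `NA`. A PLINK-style
#' `.ped`/`.map` writer is provided for interoperability.
#'
#' @param file,path File paths.
#' @param pedigree,phenos,panel Objects to write.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
read_pedigree <- function(file) {
  ped <- utils::read.csv(file)
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(ped))) {
    stop("pedigree file must have columns animal, sire, dam")
  }
  bad <- which(!(ped$sire %in% c(0, ped$animal)) |
                 !(ped$dam %in% c(0, ped$animal)))
  if (length(bad)) {
    stop("pedigree parent not listed as an animal (line ",
         bad[1] + 1L, " of ", file, ")")
  }
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' @rdname pipeline_io
#' @export
write_pedigree <- function(pedigree, file) {
  utils::write.csv(as.data.frame(pedigree), file, row.names = FALSE,
                   quote = FALSE)
  invisible(file)
}

#' @rdname pipeline_io
#' @export
read_phenotypes <- function(file) {
  tab <- utils::read.csv(file)
  need <- c("animal", "age", "value", "herd_year", "birth_month")
  if (!all(need %in% names(tab))) {
    stop("phenotype file must have columns ", paste(need, collapse = ", "))
  }
  if (any(tab$age < 0 | tab$age > 60)) {
    stop("phenotype ages outside [0, 60] months (line ",
         which(tab$age < 0 | tab$age > 60)[1] + 1L, ")")
  }
  class(tab) <- c("phenotype_table", "data.frame")
  tab
}

#' @rdname pipeline_io
#' @export
write_phenotypes <- function(phenos, file) {
  utils::write.csv(as.data.frame(phenos), file, row.names = FALSE,
                   quote = FALSE)
  invisible(file)
}

#' @rdname pipeline_io
#' @export
read_genotypes <- function(file, map_file) {
  dos <- utils::read.delim(file, check.names = FALSE)
  map <- utils::read.delim(map_file)
  if (names(dos)[1] != "animal") {
    stop("dosage file must have 'animal' as its first column")
  }
  ids <- dos$animal
  dos <- as.matrix(dos[, -1, drop = FALSE])
  if (ncol(dos) != nrow(map)) {
    stop("dosage columns (", ncol(dos), ") do not match map rows (",
         nrow(map), ")")
  }
  genotype_panel(ids, dos, map)
}

#' @rdname pipeline_io
#' @export
write_genotypes <- function(panel, file, map_file) {
  df <- data.frame(animal = panel$animal_ids, panel$dosages,
                   check.names = FALSE)
  names(df) <- c("animal", panel$map$snp_id)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(panel$map, map_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname pipeline_io
#' @export
write_plink <- function(panel, path) {
  alleles <- matrix("A A", nrow(panel$dosages), ncol(panel$dosages))
  alleles[panel$dosages == 1] <- "A B"
  alleles[panel$dosages == 2] <- "B B"
  alleles[is.na(panel$dosages)] <- "0 0"
  ped_lines <- paste(panel$animal_ids, panel$animal_ids, 0, 0, 0, -9,
                     apply(alleles, 1L, paste, collapse = " "))
  writeLines(ped_lines, paste0(path, ".ped"))
  map_df <- data.frame(panel$map$chrom, panel$map$snp_id, 0, panel$map$pos)
  utils::write.table(map_df, paste0(path, ".map"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write the simulation truth for test harnesses
#'
#' Stores the true regression coefficients, fixed effects, QTL list and the
#' generating covariance components as JSON.
#'
#' @param effects From [simulate_effects()].
#' @param config The [sim_config()] used.
#' @param file Output path.
#' @export
write_truth <- function(effects, config, file) {
  truth <- list(
    additive_coeffs = effects$additive_coeffs,
    pe_coeffs = effects$pe_coeffs,
    phenotyped = effects$phenotyped,
    herd_year_effects = effects$herd_year_effects,
    birth_month_effects = effects$birth_month_effects,
    qtl = effects$qtl,
    V_g = config$V_g, V_p = config$V_p,
    residual_variances = config$residual_variances,
    seed = config$seed)
  jsonlite::write_json(truth, file, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(file)
}

#' Default pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with the standard
#' settings as defaults: MAF >= 0.05, call rate >= 0.90, the 5-SD outlier
#' edit, at least 3 records with one before 10 and one after 30 months,
#' blending weight 0.05, quartic fixed and quadratic random regressions,
#' six residual age classes, tested ages 10..60 by 10.
#'
#' @param ... Named overrides of any default.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    pedigree_file = NULL, phenotype_file = NULL,
    genotype_file = NULL, map_file = NULL,
    maf_min = 0.05, call_rate_min = 0.90,
    sd_mult = 5, min_records = 3L, early_age = 10, late_age = 30,
    alpha = 0.05, tune = TRUE, tune_order = "tune_then_blend",
    fixed_order = 4L, random_order = 2L, n_residual_classes = 6L,
    variance_mode = "gibbs",
    gibbs = list(n_iter = 2000L, burn_in = 500L, thinning = 10L),
    fixed_components = NULL,
    ages = c(10, 20, 30, 40, 50, 60),
    sig_alpha = 0.05, meff_per_chromosome = TRUE,
    pcg_tol = 1e-14, pcg_max_iter = 20000L, max_dense_dim = 8000L,
    seed = 1L, out_dir = NULL)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown pipeline_config fields: ",
                        paste(bad, collapse = ", "))
  cfg <- modifyList(cfg, over)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Unknown keys raise; missing keys take the package defaults.
#'
#' @param file YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(file) {
  vals <- yaml::read_yaml(file)
  if (!is.null(vals$fixed_components)) {
    fc <- vals$fixed_components
    vals$fixed_components <- cov_components(
      matrix(unlist(fc$V_g), 3, 3, byrow = TRUE),
      matrix(unlist(fc$V_p), 3, 3, byrow = TRUE),
      unlist(fc$sigma_e2), provenance = "fixed_input")
  }
  do.call(pipeline_config, vals)
}

#' Run the full longitudinal single-step GWAS pipeline
#'
#' Preprocess (SNP and phenotype edits) -> relationship matrices ->
#' covariance components (Gibbs, or fixed inputs) -> MME solve -> GWAS.
#' When `config$out_dir` is set, writes one result TSV per age, a summary
#' TSV, the filter report, and a JSON run manifest (seed, settings,
#' per-stage record counts).
#'
#' @param config A `pipeline_config`.
#' @param pedigree,phenos,panel In-memory inputs; any that are `NULL` are
#'   read from the paths in `config`.
#' @return Invisibly, a list with the `gwas_result`, the components used,
#'   the filtered inputs and the manifest.
#' @export
run_pipeline <- function(config, pedigree = NULL, phenos = NULL,
                         panel = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage [", what, "] failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (is.null(pedigree)) {
    pedigree <- stage("read", read_pedigree(config$pedigree_file))
  }
  if (is.null(phenos)) {
    phenos <- stage("read", read_phenotypes(config$phenotype_file))
  }
  if (is.null(panel)) {
    panel <- stage("read", read_genotypes(config$genotype_file,
                                          config$map_file))
  }
  panel_f <- stage("preprocess",
                   filter_snps(panel, config$maf_min, config$call_rate_min))
  phenos_f <- stage("preprocess",
                    filter_phenotypes(phenos, config$sd_mult,
                                      config$min_records, config$early_age,
                                      config$late_age))
  basis <- legendre_basis(config$random_order, 0, 60)
  comps <- if (identical(config$variance_mode, "fixed")) {
    if (is.null(config$fixed_components)) {
      stop("variance_mode = 'fixed' needs fixed_components")
    }
    config$fixed_components
  } else {
    chain <- stage("varcomp", gibbs_rrm(
      phenos_f, pedigree, basis,
      n_iter = config$gibbs$n_iter, burn_in = config$gibbs$burn_in,
      thinning = config$gibbs$thinning,
      n_classes = config$n_residual_classes,
      fixed_order = config$fixed_order, seed = config$seed))
    chain$posterior_mean
  }
  result <- stage("gwas", run_longitudinal_gwas(
    phenos_f, pedigree, panel_f, comps,
    ages = config$ages, alpha_blend = config$alpha, tune = config$tune,
    tune_order = config$tune_order, sig_alpha = config$sig_alpha,
    random_order = config$random_order, fixed_order = config$fixed_order,
    tol = config$pcg_tol, max_iter = config$pcg_max_iter,
    meff_per_chromosome = config$meff_per_chromosome,
    max_dense_dim = config$max_dense_dim))
  manifest <- list(
    package_version = as.character(utils::packageVersion("rrgwas")),
    seed = config$seed,
    settings = config[!vapply(config, is.null, logical(1))],
    counts = list(
      pedigree_animals = nrow(pedigree),
      records_in = nrow(phenos), records_used = nrow(phenos_f),
      snp_in = ncol(panel$dosages), snp_used = ncol(panel_f$dosages),
      genotyped_animals = length(panel_f$animal_ids),
      phenotyped_animals = length(unique(phenos_f$animal))),
    filter_report = list(snp = as.list(attr(panel_f, "report")),
                         phenotypes = as.list(attr(phenos_f, "report"))),
    m_eff = result$m_eff,
    threshold_neglog10 = result$threshold_neglog10)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (age in names(result$tables)) {
      utils::write.table(result$tables[[age]],
                         file.path(config$out_dir,
                                   paste0("gwas_age_", age, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    utils::write.table(result$summary,
                       file.path(config$out_dir, "gwas_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_filter_report(snp = attr(panel_f, "report"),
                        phenotypes = attr(phenos_f, "report"),
                        file = file.path(config$out_dir,
                                         "filter_report.tsv"))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  invisible(list(result = result, comps = comps, pedigree = pedigree,
                 phenos = phenos_f, panel = panel_f, manifest = manifest))
}
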