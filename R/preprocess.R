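#' Filter a genotype panel on MAF and call rate
#'
#' Keeps SNP with minor allele frequency `min(p, 1-p) >= maf_min` (computed
#' from non-missing calls) and call rate `>= call_rate_min`. Allele
#' frequencies are recomputed on the retained set and remaining missing
#' dosages are mean-imputed as `2 p_o`.
#'
#' @param panel A [genotype_panel()].
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param call_rate_min Minimum fraction of non-missing calls (default 0.90).
#' @return The filtered panel; attribute `"report"` holds per-rule counts
#'   (`n_snp_in`, `removed_maf`, `removed_call_rate`, `n_snp_retained`,
#'   `imputed_calls`).
#' @export
filter_snps <- function(panel, maf_min = 0.05, call_rate_min = 0.90) {
  stopifnot(inherits(panel, "genotype_panel"))
  dos <- panel$dosages
  call_rate <- colMeans(!is.na(dos))
  p <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  fail_cr <- call_rate < call_rate_min
  fail_maf <- !fail_cr & (is.na(maf) | maf < maf_min)
  keep <- !fail_cr & !fail_maf
  if (!any(keep)) stop("all SNP removed by the MAF / call-rate filters")
  dos <- dos[, keep, drop = FALSE]
  p <- colMeans(dos, na.rm = TRUE) / 2
  n_imp <- sum(is.na(dos))
  if (n_imp > 0L) {
    miss <- which(is.na(dos), arr.ind = TRUE)
    dos[miss] <- 2 * p[miss[, 2L]]
  }
  out <- genotype_panel(panel$animal_ids, dos, panel$map[keep, , drop = FALSE])
  out$allele_freq <- p
  if (!is.null(attr(panel, "founder_freq"))) {
    attr(out, "founder_freq") <- attr(panel, "founder_freq")[keep]
  }
  attr(out, "report") <- c(n_snp_in = ncol(panel$dosages),
                           removed_call_rate = sum(fail_cr),
                           removed_maf = sum(fail_maf),
                           n_snp_retained = sum(keep),
                           imputed_calls = n_imp)
  out
}

#' Apply the standard longitudinal data edits
#'
#' Two steps, in order. (1) Outlier removal: within each integer age group,
#' records deviating from the age-group mean by more than `sd_mult` standard
#' deviations are dropped; age groups with fewer than 2 records are skipped
#' (no SD is estimable) and counted in the report. (2) Animal eligibility:
#' an animal is retained only if, after step 1, it has at least
#' `min_records` records, at least one record before `early_age` months and
#' at least one after `late_age` months.
#'
#' @param table A `phenotype_table` (columns `animal`, `age`, `value`,
#'   `herd_year`, `birth_month`); fractional ages are floored to integer
#'   months.
#' @param sd_mult Outlier threshold in SD units (default 5).
#' @param min_records Minimum records per animal (default 3).
#' @param early_age An eligible animal needs a record at an age strictly
#'   below this (default 10 months).
#' @param late_age ... and one strictly above this (default 30 months).
#' @return The filtered table; attribute `"report"` holds per-rule counts:
#'   records in/out, outlier records removed, age groups too small for the
#'   SD edit, and the number of animals violating each eligibility rule.
#' @export
filter_phenotypes <- function(table, sd_mult = 5, min_records = 3L,
                              early_age = 10, late_age = 30) {
  stopifnot(nrow(table) > 0L)
  tab <- as.data.frame(table)
  tab$age <- as.integer(floor(tab$age))
  mu <- stats::ave(tab$value, tab$age, FUN = mean)
  sdv <- stats::ave(tab$value, tab$age,
                    FUN = function(v) if (length(v) >= 2L) stats::sd(v) else NA)
  n_small <- length(unique(tab$age[is.na(sdv)]))
  out_flag <- !is.na(sdv) & abs(tab$value - mu) > sd_mult * sdv
  tab1 <- tab[!out_flag, , drop = FALSE]
  by_animal <- split(tab1$age, tab1$animal)
  n_rec <- lengths(by_animal)
  has_early <- vapply(by_animal, function(a) any(a < early_age), logical(1))
  has_late <- vapply(by_animal, function(a) any(a > late_age), logical(1))
  ok <- n_rec >= min_records & has_early & has_late
  keep_ids <- names(by_animal)[ok]
  out <- tab1[as.character(tab1$animal) %in% keep_ids, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("phenotype_table", "data.frame")
  attr(out, "report") <- c(
    records_in = nrow(tab),
    outlier_records_removed = sum(out_flag),
    age_groups_sd_skipped = n_small,
    animals_in = length(by_animal),
    animals_failing_min_records = sum(n_rec < min_records),
    animals_failing_early_age = sum(!has_early),
    animals_failing_late_age = sum(!has_late),
    animals_retained = sum(ok),
    records_retained = nrow(out))
  out
}

#' Write a filter report as TSV
#'
#' @param ... Named report vectors (attributes `"report"` of filtered
#'   objects), e.g. `snp = attr(panel, "report")`.
#' @param file Output path.
#' @return The combined report `data.frame`, invisibly.
#' @export
write_filter_report <- function(..., file) {
  reps <- list(...)
  df <- do.call(rbind, lapply(names(reps), function(nm) {
    data.frame(stage = nm, rule = names(reps[[nm]]),
               count = unname(reps[[nm]]))
  }))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
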