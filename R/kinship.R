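#' Tabular numerator relationship matrix A
#'
#' Dense recursive (tabular-method) computation of the pedigree relationship
#' matrix, suitable at desk scale; used for simulation, for the
#' genotyped-by-genotyped block `A22`, and as the oracle against which the
#' sparse A-inverse is verified.
#'
#' @param pedigree `data.frame` with columns `animal`, `sire`, `dam`
#'   (0 = unknown), parents listed before offspring.
#' @return Dense `n x n` matrix with `dimnames` the animal ids.
#' @export
build_A <- function(pedigree) {
  ped <- check_pedigree(pedigree)
  n <- ped$n
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- ped$si[i]; d <- ped$di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (s > 0L) A[j, s] else 0
      ad_ <- if (d > 0L) A[j, d] else 0
      A[j, i] <- A[i, j] <- 0.5 * (as_ + ad_)
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  dimnames(A) <- list(pedigree$animal, pedigree$animal)
  A
}

# Validate ordering and resolve parent ids to row indices.
check_pedigree <- function(pedigree) {
  stopifnot(all(c("animal", "sire", "dam") %in% names(pedigree)))
  n <- nrow(pedigree)
  si <- match(pedigree$sire, pedigree$animal, nomatch = 0L)
  di <- match(pedigree$dam, pedigree$animal, nomatch = 0L)
  if (any(pedigree$sire != 0L & si == 0L) ||
      any(pedigree$dam != 0L & di == 0L)) {
    stop("pedigree contains parent ids not listed as animals (and not 0)")
  }
  if (any(si >= seq_len(n)) || any(di >= seq_len(n))) {
    stop("pedigree is not topologically ordered (a parent follows its offspring)")
  }
  list(si = si, di = di, n = n)
}

# Inbreeding coefficients by the Meuwissen & Luo (1992) algorithm.
# Returns list(F, D) with D the Mendelian-sampling variance scalars.
ml_inbreeding <- function(si, di) {
  n <- length(si)
  F <- numeric(n)
  D <- numeric(n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    D[i] <- 1 - (if (s > 0L) 0.25 * (1 + F[s]) else 0) -
      (if (d > 0L) 0.25 * (1 + F[d]) else 0)
    if (s == 0L || d == 0L) { F[i] <- 0; next }
    L <- numeric(i)
    L[i] <- 1
    aii <- 0
    for (j in i:1) {
      if (L[j] == 0) next
      if (si[j] > 0L) L[si[j]] <- L[si[j]] + 0.5 * L[j]
      if (di[j] > 0L) L[di[j]] <- L[di[j]] + 0.5 * L[j]
      aii <- aii + L[j]^2 * D[j]
    }
    F[i] <- aii - 1
  }
  list(F = F, D = D)
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding accounted for via the Meuwissen-Luo
#' algorithm: the contribution of animal i is `1/D_i` on the animal, with the
#' usual -1/2 and 1/4 spread over its known parents, where `D_i` is the
#' Mendelian-sampling variance given parental inbreeding.
#'
#' @inheritParams build_A
#' @return Sparse symmetric `n x n` [Matrix::Matrix] with animal-id dimnames.
#' @export
build_A_inverse <- function(pedigree) {
  ped <- check_pedigree(pedigree)
  n <- ped$n
  fd <- ml_inbreeding(ped$si, ped$di)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  for (i in seq_len(n)) {
    m <- 1 / fd$D[i]
    s <- ped$si[i]; d <- ped$di[i]
    add(i, i, m)
    if (s > 0L) {
      add(i, s, -m / 2); add(s, i, -m / 2); add(s, s, m / 4)
    }
    if (d > 0L) {
      add(i, d, -m / 2); add(d, i, -m / 2); add(d, d, m / 4)
    }
    if (s > 0L && d > 0L) {
      add(s, d, m / 4); add(d, s, m / 4)
    }
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(pedigree$animal,
                                               pedigree$animal))
  Matrix::forceSymmetric(Ainv)
}

#' Pedigree relationship block of the genotyped animals
#'
#' @inheritParams build_A
#' @param genotyped_ids Animal ids present in the genotype panel.
#' @return Dense matrix `A22`, ordered as `genotyped_ids`.
#' @export
build_A22 <- function(pedigree, genotyped_ids) {
  if (!all(genotyped_ids %in% pedigree$animal)) {
    stop("genotyped animals missing from the pedigree: ",
         paste(setdiff(genotyped_ids, pedigree$animal), collapse = ", "))
  }
  A <- build_A(pedigree)
  idx <- match(genotyped_ids, pedigree$animal)
  A[idx, idx, drop = FALSE]
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' q` with `Z` the dosage matrix centred by twice the allele
#' frequency and `q = 1 / (2 sum_o p_o (1 - p_o))`.
#'
#' @param panel A filtered, imputed [genotype_panel()] (no missing dosages,
#'   no fixed alleles).
#' @param freq Allele frequencies used for centring and for `q`; defaults to
#'   the panel's observed frequencies.
#' @return List with `G` (dense, `n_g x n_g`, animal-id dimnames), `q`, and
#'   `W` (the centred marker matrix, reused by the back-solving step).
#' @export
build_G <- function(panel, freq = panel$allele_freq) {
  if (anyNA(panel$dosages)) {
    stop("panel has missing dosages; run filter_snps() first")
  }
  if (any(freq <= 0 | freq >= 1)) {
    stop("allele frequencies at 0 or 1; filter monomorphic SNP first")
  }
  W <- sweep(panel$dosages, 2L, 2 * freq, `-`)
  q <- 1 / (2 * sum(freq * (1 - freq)))
  G <- tcrossprod(W) * q
  dimnames(G) <- list(panel$animal_ids, panel$animal_ids)
  list(G = G, q = q, W = W)
}

#' Tune and blend G against A22
#'
#' Tuning rescales `G` so that the means of its diagonal and off-diagonal
#' elements match those of `A22` (solving a 2x2 linear system for an
#' intercept and a scale), aligning the genomic and pedigree base
#' populations. Blending then takes `(1 - alpha) G + alpha A22` to guarantee
#' invertibility. The default order is tune first, then blend (the
#' convention of the single-step evaluation toolchain); both steps can be
#' switched off.
#'
#' @param G_raw,A22 Matching `n_g x n_g` matrices.
#' @param alpha Blending weight on `A22` (default 0.05).
#' @param tune Apply the mean-matching adjustment first?
#' @param order `"tune_then_blend"` (default) or `"blend_then_tune"`.
#' @return List with `G_adj`, the tuning coefficients `a`, `b`, and `alpha`.
#' @export
blend_and_tune_G <- function(G_raw, A22, alpha = 0.05, tune = TRUE,
                             order = c("tune_then_blend", "blend_then_tune")) {
  order <- match.arg(order)
  stopifnot(all(dim(G_raw) == dim(A22)))
  a <- 0; b <- 1
  tune_step <- function(G) {
    n <- nrow(G)
    off <- row(G) != col(G)
    md_g <- mean(diag(G)); mo_g <- mean(G[off])
    md_a <- mean(diag(A22)); mo_a <- mean(A22[off])
    M <- rbind(c(1, md_g), c(1, mo_g))
    if (abs(det(M)) < 1e-12) {
      stop("tuning system singular: G has equal diagonal and off-diagonal means")
    }
    ab <- solve(M, c(md_a, mo_a))
    a <<- ab[1]; b <<- ab[2]
    a + b * G
  }
  G <- G_raw
  if (order == "tune_then_blend") {
    if (tune) G <- tune_step(G)
    G <- (1 - alpha) * G + alpha * A22
  } else {
    G <- (1 - alpha) * G + alpha * A22
    if (tune) G <- tune_step(G)
  }
  dimnames(G) <- dimnames(A22)
  list(G_adj = G, a = a, b = b, alpha = alpha)
}

# Dense symmetric positive-definite inverse via Cholesky.
chol_inverse <- function(M, what = "matrix") {
  ch <- tryCatch(chol(M), error = function(e) {
    stop(what, " is not positive definite: ", conditionMessage(e))
  })
  inv <- chol2inv(ch)
  dimnames(inv) <- dimnames(M)
  inv
}

#' Inverse of the unified relationship matrix H
#'
#' `H^-1 = A^-1 + [0 0; 0 G^-1 - A22^-1]`, with the correction added into the
#' rows/columns of the genotyped animals.
#'
#' @param A_inv Sparse `A^-1` from [build_A_inverse()].
#' @param G_adj_inv,A22_inv Dense inverses over the genotyped animals, in
#'   `genotyped_ids` order.
#' @param genotyped_ids Animal ids mapping the dense block into `A_inv`.
#' @return Sparse symmetric [Matrix::Matrix] `H^-1`.
#' @export
build_H_inverse <- function(A_inv, G_adj_inv, A22_inv, genotyped_ids) {
  idx <- match(as.character(genotyped_ids), rownames(A_inv))
  if (anyNA(idx)) stop("genotyped animals not found in A_inv")
  if (length(idx) > 0L &&
      !all(dim(G_adj_inv) == length(idx) & dim(A22_inv) == length(idx))) {
    stop("dimension mismatch between genotyped block and index")
  }
  H_inv <- methods::as(A_inv, "CsparseMatrix")
  if (length(idx) > 0L) {
    corr <- Matrix::sparseMatrix(
      i = rep(idx, each = length(idx)),
      j = rep(idx, times = length(idx)),
      x = as.vector(t(G_adj_inv - A22_inv)),
      dims = dim(A_inv), dimnames = dimnames(A_inv))
    H_inv <- H_inv + corr
  }
  Matrix::forceSymmetric((H_inv + Matrix::t(H_inv)) / 2)
}

#' Build the full relationship set for single-step evaluation
#'
#' Convenience constructor computing `A^-1`, `A22`, the (tuned, blended)
#' genomic relationship matrix and all inverses needed downstream.
#'
#' @inheritParams build_A
#' @param panel A filtered, imputed [genotype_panel()]; `NULL` for a
#'   pedigree-only (no genomics) set.
#' @param alpha Blending weight (see [blend_and_tune_G()]).
#' @param tune,tune_order Tuning controls (see [blend_and_tune_G()]).
#' @param centering_freq Optional externally supplied allele frequencies for
#'   centring; default uses frequencies observed in the genotyped set.
#' @return A `relationship_set` list with components `A_inv`, `A22`,
#'   `A22_inv`, `G_raw`, `G_adj`, `G_adj_inv`, `W`, `q`, `alpha`,
#'   `genotyped_ids`.
#' @export
build_relationships <- function(pedigree, panel = NULL, alpha = 0.05,
                                tune = TRUE,
                                tune_order = "tune_then_blend",
                                centering_freq = NULL) {
  A_inv <- build_A_inverse(pedigree)
  if (is.null(panel) || length(panel$animal_ids) == 0L) {
    return(structure(list(A_inv = A_inv, H_inv = A_inv, A22 = NULL,
                          A22_inv = NULL, G_raw = NULL, G_adj = NULL,
                          G_adj_inv = NULL, W = NULL, q = NA_real_,
                          alpha = alpha, genotyped_ids = integer(0)),
                     class = "relationship_set"))
  }
  A22 <- build_A22(pedigree, panel$animal_ids)
  freq <- if (is.null(centering_freq)) panel$allele_freq else centering_freq
  g <- build_G(panel, freq)
  bl <- blend_and_tune_G(g$G, A22, alpha = alpha, tune = tune,
                         order = tune_order)
  A22_inv <- chol_inverse(A22, "A22")
  G_adj_inv <- chol_inverse(bl$G_adj, "blended G")
  structure(list(A_inv = A_inv,
                 H_inv = build_H_inverse(A_inv, G_adj_inv, A22_inv,
                                         panel$animal_ids),
                 A22 = A22,
                 A22_inv = A22_inv,
                 G_raw = g$G,
                 G_adj = bl$G_adj,
                 G_adj_inv = G_adj_inv,
                 W = g$W,
                 q = g$q,
                 alpha = alpha,
                 genotyped_ids = panel$animal_ids),
            class = "relationship_set")
}

#' @export
print.relationship_set <- function(x, ...) {
  cat("relationship_set:", nrow(x$A_inv), "pedigree animals,",
      length(x$genotyped_ids), "genotyped\n")
  if (length(x$genotyped_ids)) {
    cat("  q =", signif(x$q, 4), "; alpha =", x$alpha, "\n")
  }
  invisible(x)
}
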