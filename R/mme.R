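#' Covariance components of the random regression model
#'
#' @param V_g 3x3 covariance of the additive-genetic regression coefficients.
#' @param V_p 3x3 covariance of the permanent-environment coefficients.
#' @param sigma_e2 Residual variance per age class (equal-width classes over
#'   `[0, 60]` months).
#' @param provenance One of `"true_simulated"`, `"gibbs_posterior_mean"`,
#'   `"fixed_input"`.
#' @return A `cov_components` list.
#' @export
cov_components <- function(V_g, V_p, sigma_e2,
                           provenance = c("fixed_input", "true_simulated",
                                          "gibbs_posterior_mean")) {
  provenance <- match.arg(provenance)
  check_psd(V_g, "V_g")
  check_psd(V_p, "V_p")
  if (any(sigma_e2 <= 0)) stop("sigma_e2 must be > 0")
  structure(list(V_g = unname(V_g), V_p = unname(V_p),
                 sigma_e2 = unname(sigma_e2), provenance = provenance),
            class = "cov_components")
}

# Dummy columns for a factor, first level dropped (identifiability datum).
drop_first_dummies <- function(f, prefix) {
  f <- factor(f)
  lv <- levels(f)
  if (length(lv) <= 1L) {
    return(Matrix::Matrix(0, length(f), 0, sparse = TRUE))
  }
  j <- as.integer(f) - 1L
  keep <- j >= 1L
  out <- Matrix::sparseMatrix(i = which(keep), j = j[keep], x = 1,
                              dims = c(length(f), length(lv) - 1L))
  colnames(out) <- paste0(prefix, lv[-1L])
  out
}

# Shared design builder for the random regression model.
# Returns X (fixed: herd-year and birth-month dummies, first level dropped,
# plus the quartic fixed-regression covariates), Z1 (additive, quadratic
# basis, animal-major 3-blocks over all pedigree animals), Z2 (permanent
# environment over phenotyped animals), y, and the residual class of each
# record.
rrm_design <- function(phenos, basis, ped_ids, n_classes,
                       fixed_order = 4L) {
  stopifnot(all(phenos$animal %in% ped_ids))
  phen_ids <- sort(unique(phenos$animal))
  n_rec <- nrow(phenos)
  fb <- legendre_basis(fixed_order, basis$t_min, basis$t_max)
  Phi_f <- legendre_design_row(fb, phenos$age, fixed_order)
  if (n_rec == 1L) Phi_f <- matrix(Phi_f, 1L)
  X <- cbind(drop_first_dummies(phenos$herd_year, "hy"),
             drop_first_dummies(phenos$birth_month, "bm"),
             Matrix::Matrix(Phi_f, sparse = TRUE))
  k1 <- basis$order + 1L
  Phi_r <- Phi_f[, seq_len(k1), drop = FALSE]
  ai <- match(phenos$animal, ped_ids)
  Z1 <- Matrix::sparseMatrix(
    i = rep(seq_len(n_rec), each = k1),
    j = as.vector(t((ai - 1L) * k1 + matrix(seq_len(k1), n_rec, k1,
                                            byrow = TRUE))),
    x = as.vector(t(Phi_r)),
    dims = c(n_rec, k1 * length(ped_ids)))
  pi <- match(phenos$animal, phen_ids)
  Z2 <- Matrix::sparseMatrix(
    i = rep(seq_len(n_rec), each = k1),
    j = as.vector(t((pi - 1L) * k1 + matrix(seq_len(k1), n_rec, k1,
                                            byrow = TRUE))),
    x = as.vector(t(Phi_r)),
    dims = c(n_rec, k1 * length(phen_ids)))
  list(X = X, Z1 = Z1, Z2 = Z2, y = phenos$value,
       cls = age_class(phenos$age, n_classes),
       ped_ids = ped_ids, phen_ids = phen_ids, k = k1,
       fixed_names = colnames(X))
}

#' Assemble the single-step random-regression mixed model equations
#'
#' Builds the full Henderson system for the model
#' `y = X b + Z1 a + Z2 p + e` with `a ~ N(0, H (x) V_g)` (animal-major
#' ordering), `p ~ N(0, I (x) V_p)` and heterogeneous diagonal residuals by
#' age class. The covariance matrices enter the left-hand side inverted, as
#' `H^-1 (x) V_g^-1` and `I (x) V_p^-1`. Identifiability: the first level of
#' the herd-year factor and of the birth-month factor are dropped (the
#' fixed regression's intercept basis function carries the datum); breeding
#' values are invariant to this choice.
#'
#' @param phenos A filtered `phenotype_table`.
#' @param basis [legendre_basis()] for the random regressions (order 2).
#' @param rel A `relationship_set` from [build_relationships()].
#' @param comps [cov_components()].
#' @param fixed_order Degree of the fixed-regression basis (default 4).
#' @return An `mme_system` list: sparse `LHS`, `RHS`, the design pieces, and
#'   bookkeeping (`n_fixed`, `ped_ids`, `phen_ids`, `rel`, `comps`, `basis`).
#' @export
assemble_mme <- function(phenos, basis, rel, comps, fixed_order = 4L) {
  stopifnot(inherits(rel, "relationship_set"), inherits(comps, "cov_components"))
  ped_ids <- as.integer(rownames(rel$A_inv))
  n_classes <- length(comps$sigma_e2)
  d <- rrm_design(phenos, basis, ped_ids, n_classes, fixed_order)
  rinv <- 1 / comps$sigma_e2[d$cls]
  W <- cbind(d$X, d$Z1, d$Z2)
  Wr <- W * sqrt(rinv)
  LHS <- Matrix::crossprod(Wr)
  RHS <- Matrix::crossprod(W, rinv * d$y)
  n_fixed <- ncol(d$X)
  Vg_inv <- chol_inverse(comps$V_g, "V_g")
  Vp_inv <- chol_inverse(comps$V_p, "V_p")
  Gpart <- Matrix::kronecker(rel$H_inv, Vg_inv)
  Ppart <- Matrix::kronecker(Matrix::Diagonal(length(d$phen_ids)), Vp_inv)
  prior <- Matrix::bdiag(Matrix::Matrix(0, n_fixed, n_fixed, sparse = TRUE),
                         Gpart, Ppart)
  LHS <- methods::as(LHS + prior, "CsparseMatrix")
  structure(list(LHS = Matrix::forceSymmetric(LHS), RHS = as.numeric(RHS),
                 design = W, y = d$y, cls = d$cls, rinv = rinv,
                 n_fixed = n_fixed, fixed_names = d$fixed_names,
                 ped_ids = ped_ids, phen_ids = d$phen_ids, k = d$k,
                 basis = basis, comps = comps, rel = rel),
            class = "mme_system")
}

#' Solve the mixed model equations by preconditioned conjugate gradient
#'
#' Jacobi (diagonal) preconditioning; convergence is declared when the
#' squared ratio of residual to right-hand-side norms,
#' `||RHS - LHS x||^2 / ||RHS||^2`, falls at or below `tol`.
#'
#' @param system An `mme_system` from [assemble_mme()].
#' @param tol Convergence criterion on the squared norm ratio (default
#'   1e-14).
#' @param max_iter Iteration cap.
#' @param precondition Use the Jacobi preconditioner (default TRUE).
#' @return An `mme_solution`: `b_hat` (named), `a_hat` and `pe_hat`
#'   (`n x 3` matrices, animal ids as rownames), the raw solution vector
#'   `x`, and `convergence_history`.
#' @export
solve_pcg <- function(system, tol = 1e-14, max_iter = 10000L,
                      precondition = TRUE) {
  A <- system$LHS
  b <- system$RHS
  bb <- sum(b^2)
  x <- numeric(length(b))
  if (bb == 0) {
    return(pack_solution(system, x, numeric(0), 0L, TRUE))
  }
  Minv <- if (precondition) {
    dg <- Matrix::diag(A)
    1 / ifelse(dg > 0, dg, 1)
  } else rep(1, length(b))
  r <- b
  z <- Minv * r
  p <- z
  rz <- sum(r * z)
  hist <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    crit <- sum(r^2) / bb
    hist <- c(hist, crit)
    if (crit <= tol) { converged <- TRUE; break }
    z <- Minv * r
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  if (!converged) {
    stop("PCG did not converge in ", max_iter, " iterations (criterion ",
         signif(hist[length(hist)], 3), ")")
  }
  pack_solution(system, x, hist, it, converged)
}

pack_solution <- function(system, x, hist, iters, converged) {
  k <- system$k
  nf <- system$n_fixed
  np <- length(system$ped_ids)
  nq <- length(system$phen_ids)
  b_hat <- x[seq_len(nf)]
  names(b_hat) <- system$fixed_names
  a_hat <- matrix(x[nf + seq_len(k * np)], np, k, byrow = TRUE,
                  dimnames = list(system$ped_ids, NULL))
  pe_hat <- matrix(x[nf + k * np + seq_len(k * nq)], nq, k, byrow = TRUE,
                   dimnames = list(system$phen_ids, NULL))
  structure(list(b_hat = b_hat, a_hat = a_hat, pe_hat = pe_hat, x = x,
                 convergence_history = hist, iterations = iters,
                 converged = converged),
            class = "mme_solution")
}

#' Genomic breeding value at an age
#'
#' `GEBV_l(t) = phi(t)' a_l`: the additive regression coefficients collapsed
#' onto one age through the Legendre covariates.
#'
#' @param solution An `mme_solution`.
#' @param basis The random-regression [legendre_basis()].
#' @param age Age in months.
#' @param animals Animal ids (default: all animals in the solution).
#' @return Named numeric vector of breeding values at `age`.
#' @export
gebv_at_age <- function(solution, basis, age, animals = NULL) {
  if (is.null(animals)) animals <- rownames(solution$a_hat)
  idx <- match(as.character(animals), rownames(solution$a_hat))
  if (anyNA(idx)) {
    stop("animals absent from the solution: ",
         paste(animals[is.na(idx)], collapse = ", "))
  }
  phi <- legendre_design_row(basis, age, basis$order)
  out <- drop(solution$a_hat[idx, , drop = FALSE] %*% phi)
  names(out) <- animals
  out
}

#' Prediction-error (co)variance block of the genotyped animals
#'
#' Inverts the full (constrained) left-hand side densely and returns the
#' rows/columns of the additive regression coefficients of the genotyped
#' animals, in animal-major order. Intended for desk-scale systems; a size
#' guard refuses dimensions where dense inversion is unreasonable.
#'
#' @param system An `mme_system`.
#' @param genotyped_ids Animal ids (default: the relationship set's).
#' @param max_dense_dim Refuse dense inversion above this dimension.
#' @return Dense `3 n_g x 3 n_g` matrix `C22`.
#' @export
pev_block_c22 <- function(system, genotyped_ids = system$rel$genotyped_ids,
                          max_dense_dim = 8000L) {
  n <- nrow(system$LHS)
  if (n > max_dense_dim) {
    stop("LHS dimension ", n, " exceeds max_dense_dim = ", max_dense_dim,
         "; dense inversion refused")
  }
  Cfull <- tryCatch(chol2inv(chol(as.matrix(system$LHS))),
                    error = function(e) {
                      stop("LHS is singular after constraints: ",
                           conditionMessage(e))
                    })
  k <- system$k
  ai <- match(as.integer(genotyped_ids), system$ped_ids)
  if (anyNA(ai)) stop("genotyped animals absent from the pedigree block")
  idx <- system$n_fixed + rep((ai - 1L) * k, each = k) + seq_len(k)
  Cfull[idx, idx, drop = FALSE]
}
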