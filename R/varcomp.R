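#' Gibbs sampler for the pedigree random regression model
#'
#' Estimates the additive-genetic coefficient covariance `V_g`, the
#' permanent-environment covariance `V_p` and the age-class residual
#' variances of the random regression model from pedigree and phenotypes
#' only (no genomic information enters the estimation). One iteration
#' samples (1) all location effects jointly from their Gaussian full
#' conditional via a sparse Cholesky factorization of the pedigree MME,
#' (2) `V_g` from its inverse-Wishart full conditional with scale
#' `S0_g + U' A^-1 U`, (3) `V_p` likewise with scale `S0_p + P'P`, and
#' (4) each residual class variance from its scaled inverse chi-square
#' full conditional.
#'
#' @param phenos A filtered `phenotype_table`.
#' @param pedigree Pedigree `data.frame` (topologically ordered).
#' @param basis Random-regression [legendre_basis()] (order 2).
#' @param priors List with inverse-Wishart scale/df for the covariance
#'   matrices (`S0_g`, `nu_g`, `S0_p`, `nu_p`) and scaled-inverse-chi-square
#'   scale/df for the residuals (`s0_e`, `nu_e`). Defaults are weak but
#'   proper: identity scales with df = dim + 2 for the matrices, df = 2 for
#'   the residuals.
#' @param n_iter,burn_in,thinning Chain controls.
#' @param n_classes Number of residual age classes (default 6).
#' @param fixed_order Degree of the fixed-regression basis (default 4).
#' @param seed Integer seed; fixed seed gives an identical chain.
#' @param start Optional [cov_components()] with starting values.
#' @param verbose Print progress every 100 iterations.
#' @return A `posterior_chain`: kept `samples` (`V_g`, `V_p` as 3x3xK
#'   arrays, `sigma_e2` as K x n_classes), chain metadata, and
#'   `posterior_mean` as a [cov_components()] with provenance
#'   `"gibbs_posterior_mean"`.
#' @export
gibbs_rrm <- function(phenos, pedigree, basis, priors = NULL,
                      n_iter = 2000L, burn_in = 500L, thinning = 10L,
                      n_classes = 6L, fixed_order = 4L, seed = 1L,
                      start = NULL, verbose = FALSE) {
  stopifnot(n_iter > burn_in, thinning >= 1L)
  set.seed(seed)
  pr <- modifyList(list(S0_g = diag(3), nu_g = 5, S0_p = diag(3), nu_p = 5,
                        s0_e = 1, nu_e = 2), priors %||% list())
  A_inv <- build_A_inverse(pedigree)
  ped_ids <- as.integer(rownames(A_inv))
  d <- rrm_design(phenos, basis, ped_ids, n_classes, fixed_order)
  k <- d$k
  Wd <- cbind(d$X, d$Z1, d$Z2)
  nf <- ncol(d$X)
  np <- length(d$ped_ids)
  nq <- length(d$phen_ids)
  ntot <- ncol(Wd)
  cls_idx <- split(seq_along(d$y), d$cls)
  if (any(!as.character(seq_len(n_classes)) %in% names(cls_idx))) {
    stop("some residual age classes have no records; reduce n_classes")
  }
  Mc <- lapply(cls_idx, function(ix)
    Matrix::crossprod(Wd[ix, , drop = FALSE]))
  rc <- lapply(cls_idx, function(ix)
    as.numeric(Matrix::crossprod(Wd[ix, , drop = FALSE], d$y[ix])))
  nc <- lengths(cls_idx)
  # Fixed-pattern machinery: the left-hand side's sparsity never changes
  # across iterations, so build the combined pattern once and refresh only
  # the numeric values each round.
  J3 <- matrix(1, k, k)
  K3 <- matrix(seq_len(k * k), k, k)
  A_pat <- A_inv; A_pat@x[] <- 1
  kronA_val <- Matrix::kronecker(A_inv, J3)   # carries the A^-1 values
  kronA_idx <- Matrix::kronecker(A_pat, K3)   # carries the Vg^-1 cell index
  I_pat <- Matrix::Diagonal(nq)
  kronI_idx <- Matrix::kronecker(I_pat, K3)
  shift_rand <- function(M, off) {
    T <- methods::as(methods::as(M, "generalMatrix"), "TsparseMatrix")
    keep <- T@i <= T@j
    list(i = T@i[keep] + off, j = T@j[keep] + off, x = T@x[keep])
  }
  trip_a_val <- shift_rand(kronA_val, nf)
  trip_a_idx <- shift_rand(kronA_idx, nf)
  ord <- match(as.numeric(trip_a_val$j) * ntot + trip_a_val$i,
               as.numeric(trip_a_idx$j) * ntot + trip_a_idx$i)
  trip_a_idx$x <- trip_a_idx$x[ord]
  trip_p_idx <- shift_rand(kronI_idx, nf + k * np)
  trip_m <- lapply(Mc, function(M) shift_rand(M, 0L))
  all_i <- c(unlist(lapply(trip_m, `[[`, "i")), trip_a_val$i, trip_p_idx$i)
  all_j <- c(unlist(lapply(trip_m, `[[`, "j")), trip_a_val$j, trip_p_idx$j)
  C_tmpl <- Matrix::sparseMatrix(i = all_i + 1L, j = all_j + 1L,
                                 x = 1, dims = c(ntot, ntot),
                                 symmetric = TRUE)
  tmpl_cols <- rep(seq_len(ntot) - 1L, diff(C_tmpl@p))
  tmpl_key <- as.numeric(tmpl_cols) * ntot + C_tmpl@i
  pos_of <- function(tr) match(as.numeric(tr$j) * ntot + tr$i, tmpl_key)
  map_m <- lapply(trip_m, pos_of)
  map_a <- pos_of(trip_a_val)
  map_p <- pos_of(trip_p_idx)
  nnzC <- length(C_tmpl@x)
  # moment-based starting values: split the between-animal variance of
  # age-detrended records evenly between the additive and permanent
  # environment intercepts (higher orders start small), and start the
  # residuals at the within-animal variance
  dev <- d$y - stats::ave(d$y, phenos$age, FUN = mean)
  an_mean <- stats::ave(dev, phenos$animal, FUN = mean)
  vb <- max(stats::var(an_mean), 0.01 * stats::var(d$y))
  vw <- max(stats::var(dev - an_mean), 0.01 * stats::var(d$y))
  Vg <- if (is.null(start)) diag(c(vb, vb / 10, vb / 50)) else start$V_g
  Vp <- if (is.null(start)) diag(c(vb, vb / 10, vb / 50)) else start$V_p
  s2 <- if (is.null(start)) rep(vw, n_classes) else start$sigma_e2
  n_keep <- floor((n_iter - burn_in) / thinning)
  keep_Vg <- array(NA_real_, c(3, 3, n_keep))
  keep_Vp <- array(NA_real_, c(3, 3, n_keep))
  keep_s2 <- matrix(NA_real_, n_keep, n_classes)
  kk <- 0L
  ch <- NULL
  a_rows <- nf + seq_len(k * np)
  p_rows <- nf + k * np + seq_len(k * nq)
  for (it in seq_len(n_iter)) {
    Vg_inv <- chol_inverse(Vg, "V_g sample")
    Vp_inv <- chol_inverse(Vp, "V_p sample")
    xC <- numeric(nnzC)
    for (cnm in names(trip_m)) {
      mp <- map_m[[cnm]]
      xC[mp] <- xC[mp] + trip_m[[cnm]]$x / s2[as.integer(cnm)]
    }
    xC[map_a] <- xC[map_a] + trip_a_val$x * Vg_inv[trip_a_idx$x]
    xC[map_p] <- xC[map_p] + Vp_inv[trip_p_idx$x]
    C <- C_tmpl
    C@x <- xC
    r <- Reduce(`+`, Map(function(v, s) v / s, rc, s2[as.integer(names(rc))]))
    ch <- if (is.null(ch)) {
      Matrix::Cholesky(C, LDL = FALSE, perm = TRUE, super = TRUE)
    } else {
      Matrix::.updateCHMfactor(ch, C, mult = 0)  # reuse the symbolic analysis
    }
    mu <- as.numeric(Matrix::solve(ch, r, system = "A"))
    z <- stats::rnorm(ntot)
    u <- Matrix::solve(ch, z, system = "Lt")
    theta <- mu + as.numeric(Matrix::solve(ch, u, system = "Pt"))
    U <- matrix(theta[a_rows], np, k, byrow = TRUE)
    P <- matrix(theta[p_rows], nq, k, byrow = TRUE)
    Sa <- as.matrix(Matrix::crossprod(U, A_inv %*% U))
    Sa <- (Sa + t(Sa)) / 2
    Vg <- solve(stats::rWishart(1, np + pr$nu_g,
                                solve(pr$S0_g + Sa))[, , 1])
    Sp <- crossprod(P)
    Vp <- solve(stats::rWishart(1, nq + pr$nu_p,
                                solve(pr$S0_p + Sp))[, , 1])
    e <- d$y - as.numeric(Wd %*% theta)
    for (cnm in names(cls_idx)) {
      ci <- as.integer(cnm)
      ss <- sum(e[cls_idx[[cnm]]]^2)
      s2[ci] <- (ss + pr$nu_e * pr$s0_e) /
        stats::rchisq(1, nc[[cnm]] + pr$nu_e)
    }
    if (it > burn_in && (it - burn_in) %% thinning == 0L) {
      kk <- kk + 1L
      keep_Vg[, , kk] <- (Vg + t(Vg)) / 2
      keep_Vp[, , kk] <- (Vp + t(Vp)) / 2
      keep_s2[kk, ] <- s2
    }
    if (verbose && it %% 100L == 0L) {
      message("iter ", it, "  diag(Vg) = ",
              paste(signif(diag(Vg), 3), collapse = " "))
    }
  }
  pm <- cov_components(apply(keep_Vg, c(1, 2), mean),
                       apply(keep_Vp, c(1, 2), mean),
                       colMeans(keep_s2),
                       provenance = "gibbs_posterior_mean")
  structure(list(samples = list(V_g = keep_Vg, V_p = keep_Vp,
                                sigma_e2 = keep_s2),
                 n_iter = n_iter, burn_in = burn_in, thinning = thinning,
                 seed = seed, priors = pr, posterior_mean = pm),
            class = "posterior_chain")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.posterior_chain <- function(x, ...) {
  cat("posterior_chain:", dim(x$samples$V_g)[3], "kept samples",
      sprintf("(%d iterations, %d burn-in, thin %d)\n",
              x$n_iter, x$burn_in, x$thinning))
  cat("posterior mean diag(V_g):",
      paste(signif(diag(x$posterior_mean$V_g), 4), collapse = ", "), "\n")
  cat("posterior mean diag(V_p):",
      paste(signif(diag(x$posterior_mean$V_p), 4), collapse = ", "), "\n")
  cat("posterior mean sigma_e2:",
      paste(signif(x$posterior_mean$sigma_e2, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Heritability at an age
#'
#' `h2(t) = phi_t' V_g phi_t / (phi_t' V_g phi_t + phi_t' V_p phi_t +
#' sigma_e2(class(t)))`, the standard random-regression decomposition at a
#' single age.
#'
#' @param comps [cov_components()].
#' @param basis Random-regression [legendre_basis()].
#' @param age Age(s) in months.
#' @return Heritability value(s) in `[0, 1]`.
#' @export
heritability_at_age <- function(comps, basis, age) {
  vapply(age, function(t) {
    phi <- legendre_design_row(basis, t, basis$order)
    vg <- drop(phi %*% comps$V_g %*% phi)
    vp <- drop(phi %*% comps$V_p %*% phi)
    ve <- comps$sigma_e2[age_class(t, length(comps$sigma_e2))]
    vg / (vg + vp + ve)
  }, numeric(1))
}

#' Genetic correlation between two ages
#'
#' `r_g(t1, t2) = phi_t1' V_g phi_t2 / sqrt(phi_t1' V_g phi_t1 *
#' phi_t2' V_g phi_t2)`.
#'
#' @inheritParams heritability_at_age
#' @param age1,age2 The two ages in months.
#' @return Correlation in `[-1, 1]`.
#' @export
genetic_correlation <- function(comps, basis, age1, age2) {
  p1 <- legendre_design_row(basis, age1, basis$order)
  p2 <- legendre_design_row(basis, age2, basis$order)
  v1 <- drop(p1 %*% comps$V_g %*% p1)
  v2 <- drop(p2 %*% comps$V_g %*% p2)
  if (v1 <= 0 || v2 <= 0) {
    stop("genetic variance is zero at one of the requested ages")
  }
  drop(p1 %*% comps$V_g %*% p2) / sqrt(v1 * v2)
}
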