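test_that("one animal, one record: blocks match the hand-assembled system", {
  ped <- data.frame(animal = 1L, sire = 0L, dam = 0L)
  phen <- data.frame(animal = 1L, age = 20, value = 5,
                     herd_year = 1L, birth_month = 1L)
  basis <- legendre_basis(2)
  Vg <- diag(c(2, 1, 0.5)); Vp <- diag(c(1, 0.5, 0.25))
  comps <- cov_components(Vg, Vp, rep(4, 6))
  rel <- build_relationships(ped, NULL)
  sys <- assemble_mme(phen, basis, rel, comps)
  # single-level factors contribute no columns; fixed part is phi_0..phi_4
  expect_equal(sys$n_fixed, 5L)
  phi <- legendre_design_row(basis, 20)
  LHS <- as.matrix(sys$LHS)
  add_block <- LHS[6:8, 6:8]
  expect_equal(add_block, tcrossprod(phi) / 4 + solve(Vg),
               ignore_attr = TRUE)
  pe_block <- LHS[9:11, 9:11]
  expect_equal(pe_block, tcrossprod(phi) / 4 + solve(Vp),
               ignore_attr = TRUE)
  expect_equal(LHS[6:8, 9:11], tcrossprod(phi) / 4, ignore_attr = TRUE)
  expect_equal(sys$RHS[6:8], phi * 5 / 4, ignore_attr = TRUE)
})

test_that("the system is invariant to record order", {
  d <- small_dataset()
  rel <- build_relationships(d$pedigree, d$panel_f)
  sys1 <- assemble_mme(d$phenos_f, d$basis, rel, d$comps)
  set.seed(41)
  perm <- sample(nrow(d$phenos_f))
  sys2 <- assemble_mme(d$phenos_f[perm, ], d$basis, rel, d$comps)
  expect_lt(max(abs(sys1$LHS - sys2$LHS)), 1e-10)
  expect_lt(max(abs(sys1$RHS - sys2$RHS)), 1e-10)
})

test_that("PCG solves the system to the dense-solver oracle", {
  d <- small_dataset()
  rel <- build_relationships(d$pedigree, d$panel_f)
  sys <- assemble_mme(d$phenos_f, d$basis, rel, d$comps)
  sol <- solve_pcg(sys, tol = 1e-20, max_iter = 50000L)
  xd <- solve(as.matrix(sys$LHS), sys$RHS)
  expect_lt(sqrt(sum((sol$x - xd)^2) / sum(xd^2)), 1e-6)
  crit <- sol$convergence_history[sol$iterations]
  expect_lte(crit, 1e-14)
})

test_that("zero right-hand side gives the zero solution", {
  d <- small_dataset()
  rel <- build_relationships(d$pedigree, d$panel_f)
  phen0 <- d$phenos_f
  phen0$value <- 0
  sys <- assemble_mme(phen0, d$basis, rel, d$comps)
  sol <- solve_pcg(sys)
  expect_equal(sol$x, numeric(length(sys$RHS)))
})

test_that("preconditioning changes the path, not the solution", {
  d <- small_dataset()
  rel <- build_relationships(d$pedigree, d$panel_f)
  sys <- assemble_mme(d$phenos_f, d$basis, rel, d$comps)
  sol_p <- solve_pcg(sys, precondition = TRUE)
  sol_n <- solve_pcg(sys, precondition = FALSE, max_iter = 50000L)
  expect_lt(max(abs(sol_p$x - sol_n$x)) / max(abs(sol_p$x)), 1e-5)
  expect_lte(sol_p$iterations, sol_n$iterations)
})

test_that("breeding values at an age follow the basis algebra", {
  d <- small_dataset()
  rel <- build_relationships(d$pedigree, d$panel_f)
  sys <- assemble_mme(d$phenos_f, d$basis, rel, d$comps)
  sol <- solve_pcg(sys)
  # intercept-only coefficients give a flat trajectory c * sqrt(1/2)
  sol2 <- sol
  sol2$a_hat[1, ] <- c(3, 0, 0)
  for (age in c(0, 17, 42, 60)) {
    expect_equal(unname(gebv_at_age(sol2, d$basis, age, 1)), 3 * sqrt(0.5))
  }
  # the linear basis function vanishes at the midpoint age 30
  sol2$a_hat[1, ] <- c(0, 1, 0)
  expect_equal(unname(gebv_at_age(sol2, d$basis, 30, 1)), 0)
  # full trajectory equals the matrix product with independently evaluated
  # Legendre polynomials (Bonnet recurrence re-derived here)
  ages <- seq(0, 60, 5)
  x <- 2 * ages / 60 - 1
  P0 <- rep(1, length(x)); P1 <- x; P2 <- (3 * x^2 - 1) / 2
  Phi <- cbind(P0 * sqrt(1 / 2), P1 * sqrt(3 / 2), P2 * sqrt(5 / 2))
  a5 <- sol$a_hat[5, ]
  traj <- vapply(ages, function(t) gebv_at_age(sol, d$basis, t,
                                               rownames(sol$a_hat)[5]),
                 numeric(1))
  expect_equal(unname(traj), as.numeric(Phi %*% a5), tolerance = 1e-10)
  expect_error(gebv_at_age(sol, d$basis, 30, 99999), "absent")
})

test_that("C22 equals the subset of the dense full inverse", {
  d <- small_dataset()
  rel <- build_relationships(d$pedigree, d$panel_f)
  sys <- assemble_mme(d$phenos_f, d$basis, rel, d$comps)
  C22 <- pev_block_c22(sys)
  Cfull <- solve(as.matrix(sys$LHS))
  ai <- match(rel$genotyped_ids, sys$ped_ids)
  idx <- sys$n_fixed + rep((ai - 1L) * 3L, each = 3L) + 1:3
  expect_lt(max(abs(C22 - Cfull[idx, idx])), 1e-8)
  expect_error(pev_block_c22(sys, max_dense_dim = 10L), "max_dense_dim")
})

test_that("adding records for an animal shrinks its prediction-error variance", {
  d <- small_dataset()
  rel <- build_relationships(d$pedigree, d$panel_f)
  sys1 <- assemble_mme(d$phenos_f, d$basis, rel, d$comps)
  C1 <- pev_block_c22(sys1)
  target <- rel$genotyped_ids[1]
  extra <- d$phenos_f[d$phenos_f$animal == target, ][rep(1, 40), ]
  sys2 <- assemble_mme(rbind(d$phenos_f, extra), d$basis, rel, d$comps)
  C2 <- pev_block_c22(sys2)
  k <- which(rel$genotyped_ids == target)
  blk <- (k - 1) * 3 + 1:3
  expect_true(all(diag(C2)[blk] < diag(C1)[blk]))
})

test_that("prediction error never exceeds the prior genetic variance", {
  d <- small_dataset()
  rel <- build_relationships(d$pedigree, d$panel_f)
  sys <- assemble_mme(d$phenos_f, d$basis, rel, d$comps)
  C22 <- pev_block_c22(sys)
  for (age in c(10, 30, 50)) {
    phi <- legendre_design_row(d$basis, age)
    s2u <- drop(phi %*% d$comps$V_g %*% phi)
    for (k in seq_along(rel$genotyped_ids)) {
      blk <- (k - 1) * 3 + 1:3
      pev_t <- drop(phi %*% C22[blk, blk] %*% phi)
      gii <- rel$G_adj[k, k]
      expect_gt(pev_t, 0)
      expect_lte(pev_t, s2u * gii + 1e-8)
    }
  }
})

test_that("breeding values are invariant to which factor level is dropped", {
  d <- small_dataset()
  rel <- build_relationships(d$pedigree, d$panel_f)
  sol1 <- solve_pcg(assemble_mme(d$phenos_f, d$basis, rel, d$comps),
                    tol = 1e-20, max_iter = 50000L)
  relab <- d$phenos_f
  # swap herd-year labels 1 and 2: a different level becomes the datum
  hy <- relab$herd_year
  relab$herd_year[hy == 1] <- 2L
  relab$herd_year[hy == 2] <- 1L
  sol2 <- solve_pcg(assemble_mme(relab, d$basis, rel, d$comps),
                    tol = 1e-20, max_iter = 50000L)
  expect_equal(sol1$a_hat, sol2$a_hat, tolerance = 1e-6)
})

test_that("with no genomics the solver matches an independent dense pedigree RRM", {
  cfg <- sim_config(n_founders = 8, n_generations = 2, n_snp = 10,
                    records_per_animal_range = c(4, 6), seed = 43)
  d <- simulate_dataset(cfg)
  ph <- filter_phenotypes(d$phenotypes)
  basis <- legendre_basis(2)
  comps <- cov_components(cfg$V_g, cfg$V_p, cfg$residual_variances)
  rel <- build_relationships(d$pedigree, NULL)
  sol <- solve_pcg(assemble_mme(ph, basis, rel, comps), tol = 1e-20,
                   max_iter = 50000L)
  # independent dense construction of the same pedigree RRM
  A <- build_A(d$pedigree)
  ped_ids <- d$pedigree$animal
  phen_ids <- sort(unique(ph$animal))
  hy <- factor(ph$herd_year); bm <- factor(ph$birth_month)
  Xf <- cbind(stats::model.matrix(~ hy)[, -1, drop = FALSE],
              stats::model.matrix(~ bm)[, -1, drop = FALSE],
              legendre_design_row(legendre_basis(4), ph$age))
  Phi2 <- legendre_design_row(basis, ph$age)
  Z1 <- matrix(0, nrow(ph), 3 * length(ped_ids))
  Z2 <- matrix(0, nrow(ph), 3 * length(phen_ids))
  for (r in seq_len(nrow(ph))) {
    ia <- match(ph$animal[r], ped_ids)
    ip <- match(ph$animal[r], phen_ids)
    Z1[r, (ia - 1) * 3 + 1:3] <- Phi2[r, ]
    Z2[r, (ip - 1) * 3 + 1:3] <- Phi2[r, ]
  }
  Rinv <- diag(1 / cfg$residual_variances[age_class(ph$age)])
  Wd <- cbind(Xf, Z1, Z2)
  LHS <- t(Wd) %*% Rinv %*% Wd
  ridx <- ncol(Xf) + seq_len(3 * length(ped_ids))
  pidx <- ncol(Xf) + 3 * length(ped_ids) + seq_len(3 * length(phen_ids))
  LHS[ridx, ridx] <- LHS[ridx, ridx] + kronecker(solve(A), solve(cfg$V_g))
  LHS[pidx, pidx] <- LHS[pidx, pidx] +
    kronecker(diag(length(phen_ids)), solve(cfg$V_p))
  xd <- solve(LHS, t(Wd) %*% Rinv %*% ph$value)
  a_dense <- matrix(xd[ridx], ncol = 3, byrow = TRUE)
  expect_equal(unname(sol$a_hat), a_dense, tolerance = 1e-5)
})
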