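#' Normalized Legendre polynomial basis over an age range
#'
#' Constructs the orthonormal Legendre covariate basis used for both the
#' fixed and the random regressions of the model. Ages in months on
#' `[t_min, t_max]` are mapped to the standardized scale
#' `x = 2 (t - t_min) / (t_max - t_min) - 1` in `[-1, 1]`, and the k-th
#' basis function is the normalized Legendre polynomial
#' `phi_k(x) = sqrt((2k + 1) / 2) * P_k(x)`, with `P_k` the ordinary
#' Legendre polynomial. This normalization makes the basis orthonormal
#' under the uniform weight on `[-1, 1]`.
#'
#' @param order Highest polynomial degree kept in the basis (`k_max`).
#' @param t_min,t_max Age range in months covered by the basis.
#' @return An object of class `legendre_basis` with elements `order`,
#'   `t_min`, `t_max`.
#' @examples
#' b <- legendre_basis(2)
#' legendre_design_row(b, 30)  # x = 0 at the midpoint
#' @export
legendre_basis <- function(order = 2L, t_min = 0, t_max = 60) {
  stopifnot(order >= 0L, t_max > t_min)
  structure(list(order = as.integer(order), t_min = t_min, t_max = t_max),
            class = "legendre_basis")
}

# Ordinary Legendre polynomials P_0..P_kmax at x, by the Bonnet recurrence.
# Returns a length(x) x (kmax + 1) matrix.
legendre_P <- function(x, kmax) {
  out <- matrix(0, length(x), kmax + 1L)
  out[, 1L] <- 1
  if (kmax >= 1L) out[, 2L] <- x
  if (kmax >= 2L) {
    for (k in 2:kmax) {
      out[, k + 1L] <- ((2 * k - 1) * x * out[, k] - (k - 1) * out[, k - 1L]) / k
    }
  }
  out
}

#' Evaluate the basis at one or more ages
#'
#' Returns the row(s) of Legendre covariates `(phi_0(x), ..., phi_kmax(x))`
#' entering the design matrices at the given age(s).
#'
#' @param basis A [legendre_basis()].
#' @param age Age(s) in months, inside `[t_min, t_max]`.
#' @param k_max Highest degree to evaluate; defaults to the basis order.
#' @return If `age` has length 1, a numeric vector of length `k_max + 1`;
#'   otherwise a `length(age) x (k_max + 1)` matrix.
#' @export
legendre_design_row <- function(basis, age, k_max = basis$order) {
  stopifnot(inherits(basis, "legendre_basis"))
  if (any(age < basis$t_min | age > basis$t_max)) {
    stop("age outside the basis range [", basis$t_min, ", ", basis$t_max, "]")
  }
  x <- 2 * (age - basis$t_min) / (basis$t_max - basis$t_min) - 1
  P <- legendre_P(x, k_max)
  norm <- sqrt((2 * (0:k_max) + 1) / 2)
  Phi <- sweep(P, 2L, norm, `*`)
  colnames(Phi) <- paste0("phi", 0:k_max)
  if (length(age) == 1L) drop(Phi) else Phi
}
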