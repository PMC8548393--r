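#' Lotka-Volterra intrinsic growth rate from annual-plant vital rates
#'
#' Maps the Ricker intrinsic fecundity to the growth rate of the equivalent
#' Lotka-Volterra system, accounting for the seed bank: a rare invader with
#' germination g, seed survival s and per-germinant fecundity lambda grows
#' when `g * lambda + (1 - g) * s > 1`, i.e. when
#' `r = log(lambda) - log((1 - (1 - g) * s) / g) > 0`.
#' With no seed bank (g = 1) this reduces to `r = log(lambda)`. Setting
#' `printed_sign = TRUE` flips the sign of the seed-bank term
#' (`r = log(lambda) + log((1 - (1 - g) * s) / g)`), an alternative
#' convention retained for comparison; it is not invasion-consistent.
#'
#' @param log_lambda Log intrinsic fecundity (base e), scalar or vector.
#' @param g Germination probability in (0, 1].
#' @param s Seed survival probability in [0, 1).
#' @param printed_sign Flip the sign of the seed-bank term.
#' @return Intrinsic growth rate(s) r.
#' @export
lv_growth_rate <- function(log_lambda, g, s, printed_sign = FALSE) {
  if (any(g <= 0) || any(g > 1)) {
    stop("g must lie in (0, 1]", call. = FALSE)
  }
  if (any(s < 0) || any(s >= 1)) {
    stop("s must lie in [0, 1)", call. = FALSE)
  }
  bank <- log((1 - (1 - g) * s) / g)
  if (printed_sign) log_lambda + bank else log_lambda - bank
}

#' Construct a Lotka-Volterra community
#'
#' @param species Character vector of species codes.
#' @param r Named (or positional) vector of intrinsic growth rates.
#' @param A Square interaction matrix; `A[i, j]` is the per-capita effect of
#'   species j on species i, positive = competition.
#' @return Object of class `lv_community`.
#' @export
lv_community <- function(species, r, A) {
  species <- as.character(species)
  S <- length(species)
  stopifnot(is.matrix(A), nrow(A) == S, ncol(A) == S, length(r) == S)
  r <- setNames(as.numeric(r), species)
  dimnames(A) <- list(species, species)
  structure(list(species = species, r = r, A = A), class = "lv_community")
}

#' @export
print.lv_community <- function(x, ...) {
  cat("Lotka-Volterra community of", length(x$species), "species\n")
  invisible(x)
}

#' Convert fitted Ricker parameters to the Lotka-Volterra frame
#'
#' Growth rates come from [lv_growth_rate()]; the interaction matrix is
#' carried over unchanged.
#'
#' @param params A [community_params()].
#' @param subset Optional character vector of species to keep.
#' @param printed_sign Passed to [lv_growth_rate()].
#' @return An [lv_community()].
#' @export
params_to_lv <- function(params, subset = NULL, printed_sign = FALSE) {
  stopifnot(inherits(params, "community_params"))
  sp <- params$species
  if (!is.null(subset)) {
    missing <- setdiff(subset, sp)
    if (length(missing)) {
      stop("species not in params: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    sp <- sort(subset)
  }
  r <- lv_growth_rate(params$log_lambda[sp], params$g[sp], params$s[sp],
                      printed_sign = printed_sign)
  lv_community(sp, r, params$alpha[sp, sp, drop = FALSE])
}

feasibility_result <- function(subset, equilibrium, feasible, singular,
                               omega = NULL, stable = NULL) {
  structure(
    list(subset = subset, equilibrium = equilibrium, feasible = feasible,
         singular = singular, omega = omega, stable = stable),
    class = "feasibility_result"
  )
}

#' @export
print.feasibility_result <- function(x, ...) {
  cat("Subset {", paste(x$subset, collapse = ", "), "}: ",
      if (x$singular) "singular" else if (x$feasible) "feasible"
      else "not feasible", "\n", sep = "")
  invisible(x)
}

#' Interior equilibrium of a species subset
#'
#' Solves `A[subset, subset] %*% N = r[subset]` and flags the subset
#' feasible when every component of N exceeds a positivity tolerance. A
#' singleton is feasible when its growth rate and self-limitation are both
#' positive (monoculture equilibrium `r / alpha_ii`). Near-singular
#' submatrices (reciprocal condition number below `rcond_tol`) are flagged
#' singular and not feasible.
#'
#' @param comm An [lv_community()].
#' @param subset Nonempty character vector of species in `comm`.
#' @param tol Positivity tolerance on equilibrium abundances.
#' @param rcond_tol Reciprocal-condition-number threshold for singularity.
#' @return A `feasibility_result`.
#' @export
equilibrium_abundances <- function(comm, subset, tol = 1e-10,
                                   rcond_tol = 1e-12) {
  stopifnot(inherits(comm, "lv_community"))
  subset <- sort(as.character(subset))
  if (length(subset) == 0) stop("subset must be nonempty", call. = FALSE)
  missing <- setdiff(subset, comm$species)
  if (length(missing)) {
    stop("species not in community: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  A <- comm$A[subset, subset, drop = FALSE]
  r <- comm$r[subset]
  m <- length(subset)
  if (m == 1) {
    if (A[1, 1] == 0) {
      return(feasibility_result(subset, setNames(NA_real_, subset),
                                feasible = FALSE, singular = TRUE))
    }
    eq <- setNames(r / A[1, 1], subset)
    feas <- r[[1]] > tol && A[1, 1] > 0
    return(feasibility_result(subset, eq, feasible = feas, singular = FALSE))
  }
  if (rcond(A) < rcond_tol) {
    return(feasibility_result(subset, setNames(rep(NA_real_, m), subset),
                              feasible = FALSE, singular = TRUE))
  }
  eq <- setNames(drop(solve(A, r)), subset)
  feasibility_result(subset, eq, feasible = all(eq > tol), singular = FALSE)
}

#' Relative volume of the feasibility domain
#'
#' Fraction of growth-rate directions (unit sphere) for which the community
#' has a componentwise-positive equilibrium, i.e. the normalized solid angle
#' of the cone spanned by the columns of A. Closed forms are used in
#' dimensions 1 (1/2) and 2 (angle between the normalized columns divided
#' by 2 pi); higher dimensions use Monte-Carlo sampling of isotropic
#' directions.
#'
#' @param A Square nonsingular interaction matrix.
#' @param n_samples Monte-Carlo sample count (dimension 3 and above).
#' @param seed Integer seed for the Monte-Carlo estimate.
#' @return Estimated relative volume in [0, 1].
#' @export
feasibility_domain_volume <- function(A, n_samples = 1e5, seed = 1) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  d <- nrow(A)
  if (d > 1 && rcond(A) < 1e-12 || d == 1 && A[1, 1] == 0) {
    stop("interaction matrix is singular", call. = FALSE)
  }
  if (d == 1) return(0.5)
  if (d == 2) {
    c1 <- A[, 1] / sqrt(sum(A[, 1]^2))
    c2 <- A[, 2] / sqrt(sum(A[, 2]^2))
    return(acos(max(-1, min(1, sum(c1 * c2)))) / (2 * pi))
  }
  B <- solve(A)
  withr::with_seed(as.integer(seed), {
    Z <- matrix(rnorm(n_samples * d), n_samples, d)
    N <- Z %*% t(B)
    mean(rowSums(N > 0) == d)
  })
}

#' Local asymptotic stability of a feasible equilibrium
#'
#' Evaluates the Jacobian of `dN_i/dt = N_i (r_i - sum_j A_ij N_j)` at the
#' interior equilibrium, `-diag(N*) %*% A`, and reports whether every
#' eigenvalue has negative real part.
#'
#' @param res A feasible [equilibrium_abundances()] result.
#' @param comm The [lv_community()] it came from.
#' @return Logical.
#' @export
local_stability <- function(res, comm) {
  stopifnot(inherits(res, "feasibility_result"), inherits(comm, "lv_community"))
  if (!isTRUE(res$feasible)) {
    stop("local stability is defined only for feasible equilibria",
         call. = FALSE)
  }
  sub <- res$subset
  J <- -diag(res$equilibrium, nrow = length(sub)) %*%
    comm$A[sub, sub, drop = FALSE]
  all(Re(eigen(J, only.values = TRUE)$values) < 0)
}
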