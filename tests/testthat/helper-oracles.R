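# Independent oracles and small fixtures used across test files.

# negative-binomial log-pmf from the factorial (gamma-function) form,
# written directly from the density definition (independent of dnbinom)
nb_logpmf_oracle <- function(x, mu, k) {
  lgamma(x + k) - lgamma(k) - lfactorial(x) +
    k * log(k / (k + mu)) + x * log(mu / (k + mu))
}

# brute-force subset feasibility in plain R: base solve() per subset
brute_force_subsets <- function(A, r, tol = 1e-10) {
  S <- nrow(A)
  sp <- rownames(A)
  out <- list()
  for (m in seq_len(S)) {
    combos <- combn(S, m)
    for (ci in seq_len(ncol(combos))) {
      idx <- combos[, ci]
      if (m == 1) {
        feas <- A[idx, idx] > 0 && r[idx] > tol
        eq <- r[idx] / A[idx, idx]
      } else {
        eq <- tryCatch(solve(A[idx, idx], r[idx]), error = function(e) NULL)
        feas <- !is.null(eq) && all(eq > tol)
      }
      out[[paste(sp[idx], collapse = ";")]] <-
        list(feasible = feas, equilibrium = eq)
    }
  }
  out
}

# integrate Lotka-Volterra dynamics and report the final state
lv_ode_final <- function(A, r, N0, t_end = 2000) {
  deriv <- function(t, N, p) {
    list(N * (r - drop(A %*% N)))
  }
  out <- deSolve::ode(y = N0, times = c(0, t_end / 2, t_end), func = deriv,
                      parms = NULL)
  out[nrow(out), -1]
}

# random small community that is feasible and locally stable: diagonally
# dominant competition with positive growth rates
random_stable_community <- function(n, seed) {
  withr::with_seed(seed, {
    repeat {
      A <- matrix(runif(n * n, 0, 0.3), n, n)
      diag(A) <- runif(n, 0.8, 1.5)
      r <- runif(n, 0.5, 1.5)
      sp <- LETTERS[seq_len(n)]
      dimnames(A) <- list(sp, sp)
      comm <- lv_community(sp, r, A)
      res <- equilibrium_abundances(comm, sp)
      if (res$feasible && local_stability(res, comm)) {
        return(list(comm = comm, res = res))
      }
    }
  })
}

# rock-paper-scissors community: singletons and the triplet are feasible,
# no pair is
rps_community <- function() {
  A <- matrix(c(1, 0.2, 1.5,
                1.5, 1, 0.2,
                0.2, 1.5, 1), 3, 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  lv_community(c("A", "B", "C"), c(1, 1, 1), A)
}

# quick ground truth with every parameter overridable
make_truth <- function(design, scenario = "homogeneous",
                       heterogeneity_sd = 0, seed = 1,
                       occupancy = NULL, alpha = NULL, density = NULL,
                       dispersion = NULL, log_lambda = NULL) {
  tr <- generate_ground_truth(design, scenario,
                              heterogeneity_sd = heterogeneity_sd,
                              seed = seed)
  if (!is.null(occupancy)) tr$occupancy[] <- occupancy
  if (!is.null(density)) tr$density[] <- density
  if (!is.null(dispersion)) tr$dispersion[] <- dispersion
  if (!is.null(log_lambda)) {
    tr$log_lambda[] <- log_lambda
  }
  if (!is.null(alpha)) {
    tr$alpha[] <- alpha
    tr$alpha_plot[] <- rep(as.vector(tr$alpha), design$n_plots)
  }
  tr
}

small_design <- function(n_species = 4, n_years = 1, n_plots = 1, ...) {
  study_design(n_years = n_years, n_plots = n_plots,
               species_names = default_species_codes()[seq_len(n_species)],
               ...)
}
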