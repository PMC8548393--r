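#' Draw ground-truth community parameters
#'
#' Generates a complete parameter set for a synthetic annual-plant community:
#' intrinsic fecundities (log lambda), a sparse and mostly weak interaction
#' matrix with occasional facilitation, seed germination and survival rates,
#' negative-binomial dispersions, and gradient-structured plot occupancies.
#' Occupancy follows a logistic response to a one-dimensional plot covariate
#' standing in for a soil-salinity gradient: each species has a preferred
#' position along the gradient and occurs with high probability only near it.
#'
#' Under `scenario = "heterogeneous"`, per-plot deviations are added to
#' log lambda (standard deviation `heterogeneity_sd`) and to each interaction
#' coefficient (standard deviation `heterogeneity_sd * alpha_dev_scale`,
#' scaled down because interaction coefficients live on a much smaller scale
#' than log fecundities).
#'
#' @param design A [study_design()].
#' @param scenario `"homogeneous"` (identical parameters in every plot) or
#'   `"heterogeneous"` (plot-varying log lambda and alpha).
#' @param heterogeneity_sd Standard deviation of per-plot deviations of
#'   log lambda. Must be 0 when `scenario = "homogeneous"`.
#' @param seed Integer seed; the same seed always returns the same truth.
#' @param alpha_dev_scale Multiplier applied to `heterogeneity_sd` for the
#'   per-plot deviations of interaction coefficients.
#'
#' @return An object of class `ground_truth`: a list with elements
#'   `species`, `log_lambda` (species x plot matrix), `alpha` (base
#'   species x species matrix, entry \[i, j\] = per-capita effect of j on i,
#'   positive = competition), `alpha_plot` (species x species x plot array),
#'   `g`, `s`, `dispersion` (named vectors), `occupancy` and `density`
#'   (species x plot matrices), `scenario`, and `design`.
#' @export
generate_ground_truth <- function(design,
                                  scenario = c("homogeneous", "heterogeneous"),
                                  heterogeneity_sd = 0,
                                  seed,
                                  alpha_dev_scale = 0.05) {
  stopifnot(inherits(design, "study_design"))
  scenario <- match.arg(scenario)
  if (scenario == "homogeneous" && heterogeneity_sd != 0) {
    stop("homogeneous scenario requires heterogeneity_sd = 0", call. = FALSE)
  }
  if (heterogeneity_sd < 0) {
    stop("heterogeneity_sd must be nonnegative", call. = FALSE)
  }
  sp <- design$species_names
  S <- length(sp)
  P <- design$n_plots

  withr::with_seed(as.integer(seed), {
    # fecundity spans the range typical of annual-plant neighborhood data
    # (median ~20 viable seeds, 95% range ~1-380); the low tail sits near
    # the seed-bank replacement threshold, so some species are local sinks
    log_lambda_base <- setNames(rnorm(S, mean = log(20), sd = 1.5), sp)

    # interactions: positive diagonal; off-diagonal sparse, weak, mostly
    # competitive with occasional facilitation
    alpha <- matrix(0, S, S, dimnames = list(sp, sp))
    diag(alpha) <- runif(S, 0.03, 0.10)
    off <- which(row(alpha) != col(alpha))
    type <- runif(length(off))
    a_off <- numeric(length(off))
    comp <- type >= 0.25
    fac <- type < 0.10                        # 10% facilitative
    a_off[comp] <- rexp(sum(comp), rate = 25) # mean 0.04, competitive
    a_off[fac] <- -rexp(sum(fac), rate = 100) # mean -0.01, facilitative
    # remaining 15% exactly zero (no detectable interaction)
    alpha[off] <- a_off

    g <- setNames(runif(S, 0.2, 0.9), sp)
    s <- setNames(runif(S, 0.1, 0.7), sp)
    dispersion <- setNames(runif(S, 0.8, 3), sp)

    # gradient-structured occupancy: plots ordered along a covariate
    grad <- if (P > 1) seq(-1.5, 1.5, length.out = P) else 0
    optimum <- runif(S, -2, 2)
    breadth <- runif(S, 0.8, 1.6)
    occupancy <- matrix(0, S, P, dimnames = list(sp, seq_len(P)))
    for (p in seq_len(P)) {
      occupancy[, p] <- plogis(2 - 2 * ((grad[p] - optimum) / breadth)^2)
    }

    base_density <- rlnorm(S, meanlog = log(2.5), sdlog = 0.4)
    density <- occupancy * base_density

    log_lambda <- matrix(log_lambda_base, S, P,
                         dimnames = list(sp, seq_len(P)))
    alpha_plot <- array(alpha, dim = c(S, S, P),
                        dimnames = list(sp, sp, seq_len(P)))
    if (scenario == "heterogeneous" && heterogeneity_sd > 0) {
      log_lambda <- log_lambda +
        matrix(rnorm(S * P, sd = heterogeneity_sd), S, P)
      alpha_plot <- alpha_plot +
        array(rnorm(S * S * P, sd = heterogeneity_sd * alpha_dev_scale),
              dim = c(S, S, P))
    }
  })

  structure(
    list(
      species = sp,
      log_lambda = log_lambda,
      alpha = alpha,
      alpha_plot = alpha_plot,
      g = g,
      s = s,
      dispersion = dispersion,
      occupancy = occupancy,
      density = density,
      scenario = scenario,
      heterogeneity_sd = heterogeneity_sd,
      design = design
    ),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth:", length(x$species), "species,",
      x$design$n_plots, "plots,", x$scenario, "scenario")
  if (x$scenario == "heterogeneous") {
    cat(" (sd =", x$heterogeneity_sd, ")")
  }
  cat("\n  mean lambda:", format(mean(exp(x$log_lambda)), digits = 3),
      " mean occupancy:", format(mean(x$occupancy), digits = 3), "\n")
  invisible(x)
}

#' Column names holding neighbor counts in an observation table
#' @param species Character vector of species codes.
#' @return Character vector `n_<code>`.
#' @export
neighbor_columns <- function(species) paste0("n_", species)

#' Simulate a focal-individual observation table
#'
#' Draws, for every year and plot, which species occur (Bernoulli occupancy
#' draws), then for each occurring species a fixed number of focal
#' individuals. Each focal individual gets independent Poisson neighbor
#' counts for every co-occurring species (mean = that species' plot density)
#' and a viable-seed count drawn from a negative binomial whose mean follows
#' the Ricker fecundity model
#' `lambda_i * exp(-sum_j alpha_ij * N_j)`.
#' Species absent from a plot in a year contribute no rows and no neighbors
#' there.
#'
#' @param truth A `ground_truth`.
#' @param design The matching [study_design()].
#' @param n_focal_per_species_plot Focal individuals per occurring species
#'   per plot per year.
#' @param seed Integer seed.
#'
#' @return A tibble with columns `year`, `plot`, `subplot`, `focal`,
#'   `seeds`, and one `n_<code>` neighbor-count column per species.
#' @export
generate_observations <- function(truth, design, n_focal_per_species_plot = 10,
                                  seed) {
  stopifnot(inherits(truth, "ground_truth"), inherits(design, "study_design"))
  if (!identical(truth$species, design$species_names)) {
    stop("species in truth and design do not match", call. = FALSE)
  }
  if (n_focal_per_species_plot < 1) {
    stop("n_focal_per_species_plot must be >= 1", call. = FALSE)
  }
  sp <- truth$species
  S <- length(sp)
  years <- design_years(design)
  n_sub <- design$n_subplots_per_plot

  rows <- withr::with_seed(as.integer(seed), {
    out <- vector("list", length(years) * design$n_plots)
    k <- 0L
    for (y in years) {
      for (p in seq_len(design$n_plots)) {
        present <- runif(S) < truth$occupancy[, p]
        if (!any(present)) next
        pres_idx <- which(present)
        n_focal_tot <- length(pres_idx) * n_focal_per_species_plot
        # neighbor counts: independent Poisson per focal and present species
        nb <- matrix(0L, n_focal_tot, S, dimnames = list(NULL, sp))
        for (j in pres_idx) {
          nb[, j] <- rpois(n_focal_tot, truth$density[j, p])
        }
        focal <- rep(sp[pres_idx], each = n_focal_per_species_plot)
        mu <- numeric(n_focal_tot)
        for (i in pres_idx) {
          r_idx <- which(focal == sp[i])
          eta <- truth$log_lambda[i, p] -
            nb[r_idx, , drop = FALSE] %*% truth$alpha_plot[i, , p]
          mu[r_idx] <- exp(eta)
        }
        if (any(!is.finite(mu))) {
          stop("nonfinite simulated fecundity mean; check alpha scale",
               call. = FALSE)
        }
        disp <- truth$dispersion[focal]
        seeds <- integer(n_focal_tot)
        fin <- is.finite(disp)
        seeds[fin] <- rnbinom(sum(fin), size = disp[fin], mu = mu[fin])
        if (any(!fin)) {  # dispersion = Inf is the Poisson limit
          seeds[!fin] <- rpois(sum(!fin), mu[!fin])
        }
        k <- k + 1L
        out[[k]] <- tibble::tibble(
          year = as.integer(y),
          plot = as.integer(p),
          subplot = sample.int(n_sub, n_focal_tot, replace = TRUE),
          focal = focal,
          seeds = as.integer(seeds),
          tibble::as_tibble(nb, .name_repair = ~ neighbor_columns(sp))
        )
      }
    }
    out[seq_len(k)]
  })
  obs <- dplyr::bind_rows(rows)
  dplyr::arrange(obs, .data$year, .data$plot, .data$focal, .data$subplot)
}

#' Presence of each species in each plot and year
#'
#' A species is taken to be present in a plot-year if it appears there as a
#' focal individual.
#'
#' @param obs An observation table from [generate_observations()] or
#'   [read_observations()].
#' @return Tibble with columns `year`, `plot`, `species`.
#' @export
presence_table <- function(obs) {
  obs |>
    dplyr::distinct(.data$year, .data$plot, species = .data$focal) |>
    dplyr::arrange(.data$year, .data$plot, .data$species)
}
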