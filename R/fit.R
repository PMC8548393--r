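#' Construct a community parameter set
#'
#' Container for per-year (and optionally per-plot) fitted or true
#' parameters of the Ricker fecundity model: log intrinsic fecundities,
#' interaction matrix, vital rates, negative-binomial dispersions, and
#' per-coefficient standard errors and status flags.
#'
#' @param year Year identifier.
#' @param plot Plot identifier, or `"ALL"` for a pooled (homogeneous) fit.
#' @param species Character vector of species codes (stored sorted).
#' @param log_lambda Named numeric vector of log intrinsic fecundities.
#' @param alpha Square numeric matrix, `alpha[i, j]` = per-capita effect of
#'   species j on the fecundity of species i (positive = competition,
#'   negative = facilitation).
#' @param g,s Named vectors of germination and seed-survival probabilities.
#' @param dispersion Named vector of negative-binomial dispersions (size
#'   parameters).
#' @param standard_errors List with elements `log_lambda`, `alpha`,
#'   `dispersion` matching the estimate shapes; entries are 0 for
#'   coefficients fixed at zero.
#' @param fit_flags List with elements `log_lambda` (character vector) and
#'   `alpha` (character matrix); each entry one of `"estimated"`,
#'   `"fixed_zero_unobserved"`, `"boundary"`.
#' @param convergence Named logical vector, per focal species.
#' @param loglik Named numeric vector of per-species log-likelihoods at the
#'   fitted optimum (unpenalized).
#'
#' @return An object of class `community_params`.
#' @export
community_params <- function(year, plot, species, log_lambda, alpha, g, s,
                             dispersion, standard_errors = NULL,
                             fit_flags = NULL, convergence = NULL,
                             loglik = NULL) {
  species <- sort(as.character(species))
  S <- length(species)
  stopifnot(
    is.matrix(alpha), nrow(alpha) == S, ncol(alpha) == S,
    length(log_lambda) == S
  )
  log_lambda <- log_lambda[species]
  alpha <- alpha[species, species, drop = FALSE]
  g <- g[species]
  s <- s[species]
  dispersion <- dispersion[species]
  if (any(g <= 0 | g > 1)) stop("g must lie in (0, 1]", call. = FALSE)
  if (any(s < 0 | s >= 1)) stop("s must lie in [0, 1)", call. = FALSE)
  if (any(dispersion <= 0)) stop("dispersion must be > 0", call. = FALSE)
  if (!is.null(standard_errors)) {
    bad <- unlist(lapply(standard_errors, function(x) any(x[!is.na(x)] < 0)))
    if (any(bad)) stop("standard errors must be nonnegative", call. = FALSE)
  }
  structure(
    list(
      year = year, plot = plot, species = species,
      log_lambda = log_lambda, alpha = alpha,
      g = g, s = s, dispersion = dispersion,
      standard_errors = standard_errors, fit_flags = fit_flags,
      convergence = convergence, loglik = loglik
    ),
    class = "community_params"
  )
}

#' @export
print.community_params <- function(x, ...) {
  cat("Community parameters, year", x$year, "plot", x$plot, ":",
      length(x$species), "species\n")
  cat("  log lambda range:",
      paste(format(range(x$log_lambda), digits = 3), collapse = " .. "), "\n")
  invisible(x)
}

# neighbor-count matrix for one focal species' rows, ordered as `species`
obs_neighbor_matrix <- function(obs, species) {
  cols <- neighbor_columns(species)
  missing <- setdiff(cols, names(obs))
  if (length(missing)) {
    stop("observation table lacks neighbor columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(obs[cols])
  colnames(X) <- species
  X
}

#' Negative-binomial Ricker log-likelihood of an observation table
#'
#' Sums, over rows of `obs`, the log-probability of the observed seed count
#' under a negative binomial with mean
#' `lambda_i * exp(-sum_j alpha_ij * N_j)` and the focal species'
#' dispersion, where i is the row's focal species.
#'
#' @param params A [community_params()].
#' @param obs Observation table; every focal species must be in
#'   `params$species`.
#' @return Total log-likelihood (numeric scalar).
#' @export
neg_binomial_ricker_loglik <- function(params, obs) {
  stopifnot(inherits(params, "community_params"))
  unknown <- setdiff(unique(obs$focal), params$species)
  if (length(unknown)) {
    stop("focal species absent from params: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  X <- obs_neighbor_matrix(obs, params$species)
  eta <- params$log_lambda[obs$focal] -
    rowSums(X * params$alpha[obs$focal, , drop = FALSE])
  mu <- exp(eta)
  if (any(!is.finite(mu))) {
    stop("nonfinite fecundity mean at row(s) ",
         paste(head(which(!is.finite(mu)), 5), collapse = ", "),
         call. = FALSE)
  }
  sum(dnbinom(obs$seeds, size = params$dispersion[obs$focal], mu = mu,
              log = TRUE))
}

# ---- internal ML machinery ------------------------------------------------

# negative log-likelihood of one focal species' rows; theta = (log lambda,
# alpha over free columns); dispersion k fixed
nb_negll <- function(theta, y, X, k) {
  eta <- pmin(theta[1] - drop(X %*% theta[-1]), 50)
  -sum(dnbinom(y, size = k, mu = exp(eta), log = TRUE))
}

nb_negll_grad <- function(theta, y, X, k) {
  eta <- pmin(theta[1] - drop(X %*% theta[-1]), 50)
  mu <- exp(eta)
  w <- y - mu * (y + k) / (mu + k)
  -c(sum(w), -colSums(X * w))
}

# observed-information Hessian of nb_negll at theta
nb_negll_hess <- function(theta, y, X, k) {
  eta <- pmin(theta[1] - drop(X %*% theta[-1]), 50)
  mu <- exp(eta)
  h <- mu * k * (y + k) / (mu + k)^2
  Z <- cbind(1, -X)
  crossprod(Z, Z * h)
}

# fallback joint ML over (theta, log k) when glm.nb does not converge
nb_fit_ml <- function(y, X) {
  p <- ncol(X)
  start <- c(log(mean(y) + 0.5), rep(0, p), 0)
  fn <- function(par) nb_negll(par[1:(p + 1)], y, X, exp(min(par[p + 2], 25)))
  opt <- nlminb(start, fn, control = list(iter.max = 500))
  k <- exp(min(opt$par[p + 2], 25))
  H <- try(nb_negll_hess(opt$par[1:(p + 1)], y, X, k), silent = TRUE)
  se <- rep(NA_real_, p + 1)
  if (!inherits(H, "try-error")) {
    V <- try(solve(H), silent = TRUE)
    if (!inherits(V, "try-error") &&
        isTRUE(all(is.finite(diag(V)) & diag(V) > 0))) {
      se <- sqrt(diag(V))
    }
  }
  list(coef = opt$par[1:(p + 1)], se = se, theta = k, se_theta = NA_real_,
       loglik = -opt$objective, converged = opt$convergence == 0)
}

#' Fit the pooled (homogeneous-environment) Ricker model for one year
#'
#' For each focal species, fits a negative-binomial regression of viable
#' seed count on the neighbor-count columns with log link, pooling
#' observations from all plots: `log(mean) = log lambda_i - sum_j alpha_ij
#' N_j`. Interaction coefficients toward neighbor species never observed
#' next to a focal species are not identifiable; they are fixed at zero and
#' flagged `"fixed_zero_unobserved"`. Fitting goes through
#' [MASS::glm.nb()]; if it fails to converge, a direct maximum-likelihood
#' fall-back is used and the species is flagged as non-converged.
#'
#' @param obs Observation table.
#' @param g,s Named vectors of germination and seed-survival probabilities
#'   covering every focal species.
#' @param year Year to fit (must be present in `obs`).
#'
#' @return A [community_params()] with `plot = "ALL"`.
#' @export
fit_homogeneous <- function(obs, g, s, year) {
  obs_y <- dplyr::filter(obs, .data$year == !!year)
  if (nrow(obs_y) == 0) stop("no observations for year ", year, call. = FALSE)
  species <- sort(unique(obs_y$focal))
  zero_sp <- vapply(species, function(f) {
    all(obs_y$seeds[obs_y$focal == f] == 0)
  }, logical(1))
  if (any(zero_sp)) {
    warning("dropping species with all-zero seed counts: ",
            paste(species[zero_sp], collapse = ", "), call. = FALSE)
    species <- species[!zero_sp]
  }
  if (length(species) == 0) {
    stop("no species with nonzero seed counts in year ", year, call. = FALSE)
  }
  miss <- setdiff(species, intersect(names(g), names(s)))
  if (length(miss)) {
    stop("vital rates missing for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  S <- length(species)
  log_lambda <- setNames(rep(NA_real_, S), species)
  alpha <- matrix(0, S, S, dimnames = list(species, species))
  se_ll <- setNames(rep(NA_real_, S), species)
  se_alpha <- matrix(0, S, S, dimnames = list(species, species))
  dispersion <- setNames(rep(NA_real_, S), species)
  se_disp <- setNames(rep(NA_real_, S), species)
  flags_ll <- setNames(rep("estimated", S), species)
  flags_alpha <- matrix("fixed_zero_unobserved", S, S,
                        dimnames = list(species, species))
  convergence <- setNames(rep(TRUE, S), species)
  loglik <- setNames(rep(NA_real_, S), species)

  for (f in species) {
    rows <- obs_y$focal == f
    y <- obs_y$seeds[rows]
    X_all <- obs_neighbor_matrix(obs_y[rows, ], species)
    observed <- colSums(X_all) > 0
    X <- X_all[, observed, drop = FALSE]
    kept <- species[observed]

    fit <- NULL
    ok <- TRUE
    withCallingHandlers(
      fit <- tryCatch(
        MASS::glm.nb(y ~ ., data = data.frame(y = y, X, check.names = FALSE)),
        error = function(e) NULL
      ),
      warning = function(w) {
        ok <<- FALSE
        invokeRestart("muffleWarning")
      }
    )
    if (!is.null(fit) && ok && fit$converged) {
      cf <- coef(fit)
      # aliased (collinear) columns come back NA and are absent from vcov;
      # like never-observed pairs, the likelihood cannot identify them
      se_fit <- sqrt(diag(vcov(fit)))
      se <- setNames(rep(0, length(cf)), names(cf))
      se[names(se_fit)] <- se_fit
      aliased <- is.na(cf)
      cf[aliased] <- 0
      log_lambda[f] <- cf[1]
      se_ll[f] <- se[1]
      alpha[f, kept] <- -cf[-1]
      se_alpha[f, kept] <- se[-1]
      dispersion[f] <- fit$theta
      se_disp[f] <- fit$SE.theta
      loglik[f] <- as.numeric(stats::logLik(fit))
      aliased_cols <- kept[aliased[-1]]
    } else {
      aliased_cols <- character(0)
      mf <- nb_fit_ml(y, X)
      log_lambda[f] <- mf$coef[1]
      se_ll[f] <- mf$se[1]
      alpha[f, kept] <- -mf$coef[-1]
      se_alpha[f, kept] <- mf$se[-1]
      dispersion[f] <- max(mf$theta, 1e-3)
      se_disp[f] <- mf$se_theta
      loglik[f] <- mf$loglik
      convergence[f] <- mf$converged
      if (!mf$converged) {
        warning("fit for focal species ", f, " in year ", year,
                " did not converge", call. = FALSE)
      }
    }
    flags_alpha[f, kept] <- "estimated"
    if (length(aliased_cols)) {
      flags_alpha[f, aliased_cols] <- "fixed_zero_unobserved"
    }
  }
  community_params(
    year = year, plot = "ALL", species = species,
    log_lambda = log_lambda, alpha = alpha,
    g = g[species], s = s[species], dispersion = dispersion,
    standard_errors = list(log_lambda = se_ll, alpha = se_alpha,
                           dispersion = se_disp),
    fit_flags = list(log_lambda = flags_ll, alpha = flags_alpha),
    convergence = convergence, loglik = loglik
  )
}

#' Fit the plot-heterogeneous Ricker model for one year
#'
#' Partial-pooling analogue of a plot random effect: per plot and focal
#' species, log lambda and the interaction coefficients are re-estimated by
#' penalized maximum likelihood, with a Gaussian penalty of scale
#' `shrinkage_sd` on deviations from the pooled ([fit_homogeneous()])
#' estimates. As `shrinkage_sd` approaches 0 every plot collapses onto the
#' pooled fit; large values approach independent per-plot fits. The
#' negative-binomial dispersion is held at its pooled per-species estimate.
#' Plots where a focal species was never observed carry no estimate for it.
#'
#' @inheritParams fit_homogeneous
#' @param shrinkage_sd Positive scale of the Gaussian penalty on per-plot
#'   deviations (log-fecundity units for the intercept; the same scale is
#'   applied to interaction coefficients).
#' @param pooled Optionally, a precomputed pooled fit for this year.
#'
#' @return Named list of [community_params()], one per plot (names are plot
#'   identifiers); each is restricted to the species observed in that plot.
#' @export
fit_heterogeneous <- function(obs, g, s, year, shrinkage_sd = 0.2,
                              pooled = NULL) {
  if (shrinkage_sd <= 0) stop("shrinkage_sd must be > 0", call. = FALSE)
  if (is.null(pooled)) pooled <- fit_homogeneous(obs, g, s, year)
  obs_y <- dplyr::filter(obs, .data$year == !!year,
                         .data$focal %in% pooled$species)
  plots <- sort(unique(obs_y$plot))
  inv_var <- 1 / shrinkage_sd^2
  out <- vector("list", length(plots))
  names(out) <- plots

  for (pi in seq_along(plots)) {
    p <- plots[pi]
    obs_p <- dplyr::filter(obs_y, .data$plot == !!p)
    sp_p <- sort(unique(obs_p$focal))
    Sp <- length(sp_p)
    log_lambda <- setNames(rep(NA_real_, Sp), sp_p)
    alpha_full <- matrix(0, Sp, length(pooled$species),
                         dimnames = list(sp_p, pooled$species))
    se_ll <- setNames(rep(NA_real_, Sp), sp_p)
    se_alpha_full <- matrix(0, Sp, length(pooled$species),
                            dimnames = list(sp_p, pooled$species))
    loglik <- setNames(rep(NA_real_, Sp), sp_p)
    convergence <- setNames(rep(TRUE, Sp), sp_p)

    for (f in sp_p) {
      rows <- obs_p$focal == f
      y <- obs_p$seeds[rows]
      X_all <- obs_neighbor_matrix(obs_p[rows, ], pooled$species)
      free <- pooled$fit_flags$alpha[f, ] == "estimated"
      X <- X_all[, free, drop = FALSE]
      theta0 <- c(pooled$log_lambda[f], pooled$alpha[f, free])
      k <- pooled$dispersion[f]
      fn <- function(th) {
        nb_negll(th, y, X, k) + 0.5 * inv_var * sum((th - theta0)^2)
      }
      gr <- function(th) {
        nb_negll_grad(th, y, X, k) + inv_var * (th - theta0)
      }
      opt <- optim(theta0, fn, gr, method = "BFGS",
                   control = list(maxit = 500))
      convergence[f] <- opt$convergence == 0
      th <- opt$par
      H <- nb_negll_hess(th, y, X, k) + diag(inv_var, length(th))
      V <- try(solve(H), silent = TRUE)
      se <- rep(NA_real_, length(th))
      if (!inherits(V, "try-error") &&
          isTRUE(all(is.finite(diag(V)) & diag(V) > 0))) {
        se <- sqrt(diag(V))
      }
      log_lambda[f] <- th[1]
      alpha_full[f, free] <- th[-1]
      se_ll[f] <- se[1]
      se_alpha_full[f, free] <- se[-1]
      loglik[f] <- -nb_negll(th, y, X, k)
    }
    out[[pi]] <- community_params(
      year = year, plot = p, species = sp_p,
      log_lambda = log_lambda,
      alpha = alpha_full[, sp_p, drop = FALSE],
      g = g[sp_p], s = s[sp_p],
      dispersion = pooled$dispersion[sp_p],
      standard_errors = list(
        log_lambda = se_ll,
        alpha = se_alpha_full[, sp_p, drop = FALSE],
        dispersion = pooled$standard_errors$dispersion[sp_p]
      ),
      fit_flags = list(
        log_lambda = setNames(rep("estimated", Sp), sp_p),
        alpha = pooled$fit_flags$alpha[sp_p, sp_p, drop = FALSE]
      ),
      convergence = convergence, loglik = loglik
    )
  }
  out
}

#' Draw sampling-distribution replicates of a fitted parameter set
#'
#' Each coefficient (log lambda, alpha, dispersion) is drawn independently
#' from a Gaussian centered on its estimate with its standard error;
#' coefficients fixed at zero (unobserved pairs) stay exactly zero, and
#' dispersion draws are floored at a small positive value. Used to check
#' robustness of downstream persistence and curve results to parameter
#' uncertainty.
#'
#' @param fit A [community_params()] with standard errors.
#' @param n_draws Number of replicate parameter sets.
#' @param seed Integer seed.
#' @return List of `n_draws` [community_params()] objects.
#' @export
draw_parameter_replicates <- function(fit, n_draws, seed) {
  stopifnot(inherits(fit, "community_params"))
  se <- fit$standard_errors
  if (is.null(se) || any(is.na(se$log_lambda)) || any(is.na(se$alpha))) {
    stop("fit has missing standard errors; cannot draw replicates",
         call. = FALSE)
  }
  S <- length(fit$species)
  se_disp <- se$dispersion
  se_disp[is.na(se_disp)] <- 0
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_draws), function(d) {
      rep_fit <- fit
      rep_fit$log_lambda <- fit$log_lambda + rnorm(S) * se$log_lambda
      rep_fit$alpha <- fit$alpha + matrix(rnorm(S * S), S, S) * se$alpha
      rep_fit$dispersion <- pmax(fit$dispersion + rnorm(S) * se_disp, 1e-3)
      rep_fit
    })
  })
}
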