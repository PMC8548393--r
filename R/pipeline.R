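#' Configuration for a full pipeline run
#'
#' Collects every tunable of the pipeline in one validated list. All
#' stochastic stages derive their seeds from `seed`, so a run is a pure
#' function of (inputs, config).
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Master integer seed (mandatory).
#' @param design A [study_design()].
#' @param simulate Generate synthetic inputs (`TRUE`) or read observation
#'   and vitals files (`FALSE`).
#' @param scenario Simulation scenario, `"homogeneous"` or
#'   `"heterogeneous"`.
#' @param heterogeneity_sd Plot-level sd of log lambda in the simulation.
#' @param n_focal_per_species_plot Focal individuals per species, plot and
#'   year in the simulation.
#' @param observations_file,vitals_file Input CSVs used when
#'   `simulate = FALSE`.
#' @param shrinkage_sd Partial-pooling scale of [fit_heterogeneous()].
#' @param n_null_replicates Replicates per null model.
#' @param null_models Null models to run (subset of `"shuffle_all"`,
#'   `"shuffle_offdiag"`).
#' @param n_parameter_draws Reserved for robustness re-runs with
#'   [draw_parameter_replicates()].
#' @param omega_samples Monte-Carlo samples for
#'   [feasibility_domain_volume()].
#' @param precedence Persistence-category precedence.
#' @param het_denominator Denominator of [heterogeneity_contribution()].
#' @param printed_sign Growth-rate sign convention switch (see
#'   [lv_growth_rate()]).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed,
                            design = study_design(),
                            simulate = TRUE,
                            scenario = "heterogeneous",
                            heterogeneity_sd = if (scenario ==
                              "homogeneous") 0 else 0.4,
                            n_focal_per_species_plot = 10,
                            observations_file = NULL,
                            vitals_file = NULL,
                            shrinkage_sd = 0.2,
                            n_null_replicates = 100,
                            null_models = c("shuffle_all",
                                            "shuffle_offdiag"),
                            n_parameter_draws = 100,
                            omega_samples = 1e5,
                            precedence = c("pair", "multispecies",
                                           "dominant"),
                            het_denominator = "het",
                            printed_sign = FALSE) {
  stopifnot(
    inherits(design, "study_design"),
    n_focal_per_species_plot >= 1, shrinkage_sd > 0,
    n_null_replicates >= 1, n_parameter_draws >= 1, omega_samples >= 1
  )
  if (missing(seed)) stop("a master seed is mandatory", call. = FALSE)
  null_models <- match.arg(null_models, several.ok = TRUE)
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), design = design,
         simulate = simulate, scenario = scenario,
         heterogeneity_sd = heterogeneity_sd,
         n_focal_per_species_plot = n_focal_per_species_plot,
         observations_file = observations_file, vitals_file = vitals_file,
         shrinkage_sd = shrinkage_sd,
         n_null_replicates = n_null_replicates, null_models = null_models,
         n_parameter_draws = n_parameter_draws,
         omega_samples = omega_samples, precedence = precedence,
         het_denominator = het_denominator, printed_sign = printed_sign),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [pipeline_config()]; design sub-keys
#' (`n_years`, `n_plots`, ...) go under a `design:` block. Unknown keys are
#' an error.
#'
#' @param path YAML file.
#' @param ... Overrides applied after reading (e.g. `seed = 42`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  overrides <- list(...)
  raw[names(overrides)] <- overrides
  if (!is.null(raw$design)) {
    raw$design <- do.call(study_design, raw$design)
  }
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> fit (homogeneous + heterogeneous) ->
#' classify -> curves -> null models, writing all artifact files into
#' `config$out_dir`: `observations.csv`, per-year `alpha_*.csv` /
#' `vitals_*.csv` fits, `fit_report.json`, `persistence.csv`,
#' `curves.csv`, `powerlaw.csv`, `nulls.csv`, `nulls_summary.csv`,
#' `summary.json` and a `manifest.json` recording the configuration, seed
#' and package version. Files are written atomically; if any stage fails,
#' files already written by this run are removed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`truth`, `obs`,
#'   `fits_hom`, `fits_het`, `records`, `curves`, `powerlaw`,
#'   `null_summary`, `heterogeneity_contribution`, `transient_fraction`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)
  emit <- function(fname, writer) {
    path <- file.path(config$out_dir, fname)
    writer(path)
    written <<- c(written, path)
    path
  }

  # -- simulate or load ----------------------------------------------------
  truth <- NULL
  sim <- stage("simulate", {
    if (config$simulate) {
      truth <- generate_ground_truth(
        config$design, scenario = config$scenario,
        heterogeneity_sd = config$heterogeneity_sd, seed = config$seed
      )
      obs <- generate_observations(
        truth, config$design,
        n_focal_per_species_plot = config$n_focal_per_species_plot,
        seed = config$seed + 1L
      )
      emit("observations.csv", function(p) write_observations(obs, p))
      emit("truth_alpha.csv", function(p) write_alpha(truth$alpha, p))
      emit("truth_vitals.csv",
           function(p) write_vitals(params_to_vitals(truth), p))
      list(obs = obs, g = truth$g, s = truth$s)
    } else {
      if (is.null(config$observations_file) || is.null(config$vitals_file)) {
        stop("simulate = FALSE needs observations_file and vitals_file")
      }
      obs <- read_observations(config$observations_file)
      vit <- read_vitals(config$vitals_file)
      list(obs = obs, g = setNames(vit$g, vit$species),
           s = setNames(vit$s, vit$species))
    }
  })
  obs <- sim$obs
  years <- sort(unique(obs$year))
  presence <- presence_table(obs)
  plots <- sort(unique(obs$plot))

  # -- fit -----------------------------------------------------------------
  fits <- stage("fit", {
    fits_hom <- list()
    fits_het <- list()
    for (y in years) {
      yk <- as.character(y)
      fits_hom[[yk]] <- fit_homogeneous(obs, sim$g, sim$s, year = y)
      fits_het[[yk]] <- fit_heterogeneous(obs, sim$g, sim$s, year = y,
                                          shrinkage_sd = config$shrinkage_sd,
                                          pooled = fits_hom[[yk]])
      emit(paste0("alpha_hom_", y, ".csv"),
           function(p) write_alpha(fits_hom[[yk]]$alpha, p))
      emit(paste0("vitals_hom_", y, ".csv"),
           function(p) write_vitals(params_to_vitals(fits_hom[[yk]]), p))
      for (pk in names(fits_het[[yk]])) {
        emit(paste0("alpha_het_", y, "_plot", pk, ".csv"),
             function(p) write_alpha(fits_het[[yk]][[pk]]$alpha, p))
        emit(paste0("vitals_het_", y, "_plot", pk, ".csv"),
             function(p) write_vitals(params_to_vitals(fits_het[[yk]][[pk]]),
                                      p))
      }
    }
    report <- lapply(fits_hom, function(f) {
      list(converged = as.list(f$convergence), loglik = as.list(f$loglik))
    })
    emit("fit_report.json", function(p) {
      atomic_write(p, function(tmp) {
        jsonlite::write_json(report, tmp, auto_unbox = TRUE, digits = NA)
      })
    })
    list(hom = fits_hom, het = fits_het)
  })

  # -- classify ------------------------------------------------------------
  records <- stage("classify", {
    recs <- lapply(years, function(y) {
      yk <- as.character(y)
      dplyr::bind_rows(
        classify_year(fits$hom[[yk]], presence, "hom",
                      printed_sign = config$printed_sign,
                      precedence = config$precedence),
        classify_year(fits$het[[yk]], presence, "het",
                      printed_sign = config$printed_sign,
                      precedence = config$precedence)
      )
    })
    recs <- dplyr::bind_rows(recs)
    emit("persistence.csv", function(p) write_persistence(recs, p))
    recs
  })

  # -- curves --------------------------------------------------------------
  curve_out <- stage("curves", {
    rec_hom <- dplyr::filter(records, .data$parameterization == "hom")
    rec_het <- dplyr::filter(records, .data$parameterization == "het")
    curves <- build_curve_table(
      presence, rec_hom, rec_het, plots = plots,
      plot_area_m2 = plot_area_m2(config$design)
    )
    emit("curves.csv", function(p) write_curves(curves, p))
    pl <- lapply(years, function(y) {
      cy <- dplyr::filter(curves, .data$year == !!y)
      fits_pl <- list(sar = power_law_fit(cy$area_m2, cy$sar_mean),
                      car_hom = power_law_fit(cy$area_m2, cy$car_hom_mean),
                      car_het = power_law_fit(cy$area_m2, cy$car_het_mean))
      tibble::tibble(
        year = y, curve = names(fits_pl),
        c = vapply(fits_pl, `[[`, numeric(1), "c"),
        z = vapply(fits_pl, `[[`, numeric(1), "z"),
        rss = vapply(fits_pl, `[[`, numeric(1), "residual_sum_squares")
      )
    })
    pl <- dplyr::bind_rows(pl)
    emit("powerlaw.csv", function(p) {
      atomic_write(p, function(tmp) readr::write_csv(pl, tmp,
                                                     progress = FALSE))
    })
    het_contrib <- heterogeneity_contribution(
      curves, denominator = config$het_denominator)
    trans_frac <- transient_fraction(rec_het, presence, plots = plots)
    emit("summary.json", function(p) {
      atomic_write(p, function(tmp) {
        jsonlite::write_json(
          list(heterogeneity_contribution_pct = het_contrib,
               transient_fraction_pct = trans_frac),
          tmp, auto_unbox = TRUE, digits = NA
        )
      })
    })
    list(curves = curves, powerlaw = pl, het_contrib = het_contrib,
         trans_frac = trans_frac)
  })

  # -- null models ---------------------------------------------------------
  nulls <- stage("nulls", {
    rows <- list()
    summaries <- list()
    i <- 0L
    for (y in years) {
      yk <- as.character(y)
      for (m in config$null_models) {
        i <- i + 1L
        ens <- null_car_ensemble(
          fits$hom[[yk]], presence, model = m,
          n_replicates = config$n_null_replicates,
          seed = config$seed + 100L + i,
          plots = plots, plot_area_m2 = plot_area_m2(config$design),
          printed_sign = config$printed_sign,
          precedence = config$precedence
        )
        rows[[i]] <- dplyr::bind_rows(lapply(
          seq_along(ens$replicate_curves), function(b) {
            tibble::tibble(year = y, model = m, replicate = b,
                           k = ens$replicate_curves[[b]]$k,
                           car_mean = ens$replicate_curves[[b]]$car_mean)
          }))
        summaries[[i]] <- tibble::tibble(
          year = y, model = m, k = ens$mean_curve$k,
          car_mean = ens$mean_curve$car_mean,
          car_se = ens$mean_curve$car_se
        )
      }
    }
    rows <- dplyr::bind_rows(rows)
    summaries <- dplyr::bind_rows(summaries)
    emit("nulls.csv", function(p) {
      atomic_write(p, function(tmp) readr::write_csv(rows, tmp,
                                                     progress = FALSE))
    })
    emit("nulls_summary.csv", function(p) {
      atomic_write(p, function(tmp) readr::write_csv(summaries, tmp,
                                                     progress = FALSE))
    })
    summaries
  })

  # -- manifest ------------------------------------------------------------
  stage("manifest", {
    cfg <- config
    cfg$design <- unclass(cfg$design)
    emit("manifest.json", function(p) {
      atomic_write(p, function(tmp) {
        jsonlite::write_json(
          list(config = unclass(cfg), seed = config$seed,
               package_version =
                 as.character(utils::packageVersion("coexar"))),
          tmp, auto_unbox = TRUE, digits = NA
        )
      })
    })
  })

  ok <- TRUE
  invisible(list(
    truth = truth, obs = obs, presence = presence,
    fits_hom = fits$hom, fits_het = fits$het, records = records,
    curves = curve_out$curves, powerlaw = curve_out$powerlaw,
    null_summary = nulls,
    heterogeneity_contribution = curve_out$het_contrib,
    transient_fraction = curve_out$trans_frac
  ))
}
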