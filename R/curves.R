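# mean/SE of union sizes over all k-combinations of plots
combo_union_stats <- function(sets_by_plot, plots) {
  P <- length(plots)
  out <- lapply(seq_len(P), function(k) {
    combos <- combn(P, k)
    sizes <- apply(combos, 2, function(ix) {
      length(unique(unlist(sets_by_plot[as.character(plots[ix])])))
    })
    n <- ncol(combos)
    tibble::tibble(
      k = k,
      n_combinations = n,
      mean = mean(sizes),
      se = if (n > 1) sd(sizes) / sqrt(n) else 0
    )
  })
  dplyr::bind_rows(out)
}

sets_from_presence <- function(presence_y, plots) {
  sets <- split(presence_y$species, presence_y$plot)
  out <- setNames(vector("list", length(plots)), as.character(plots))
  out[names(sets)] <- sets
  out
}

#' Species-area relationship by combination averaging
#'
#' For each year and each number of plots k, averages the union richness
#' over all `choose(P, k)` combinations of plots (a "Type B", non-contiguous
#' SAR); the standard error is the sample standard deviation across
#' combinations divided by the square root of the number of combinations.
#'
#' @param presence Presence tibble (`year`, `plot`, `species`).
#' @param plots Plot identifiers to use (defaults to every plot in
#'   `presence`; pass explicitly if some plots are empty).
#' @param plot_area_m2 Area of one plot in square meters.
#' @return Tibble: `year`, `k`, `area_m2`, `n_combinations`, `sar_mean`,
#'   `sar_se`.
#' @export
sar_curve <- function(presence, plots = NULL, plot_area_m2 = 8.5^2) {
  if (is.null(plots)) plots <- sort(unique(presence$plot))
  if (length(plots) < 1) stop("at least one plot is required", call. = FALSE)
  presence |>
    dplyr::group_by(.data$year) |>
    dplyr::group_modify(function(d, g) {
      combo_union_stats(sets_from_presence(d, plots), plots)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(area_m2 = .data$k * plot_area_m2) |>
    dplyr::select("year", "k", "area_m2", "n_combinations",
                  sar_mean = "mean", sar_se = "se")
}

#' Coexistence-area relationship by combination averaging
#'
#' Same construction as [sar_curve()], but the per-plot species set is the
#' set of species predicted to persist there (any category but transient);
#' the union over a combination of plots counts a species as coexisting in
#' that area if it persists in at least one of its plots.
#'
#' @param records Persistence records (from [classify_year()]), a single
#'   parameterization.
#' @param plots Plot identifiers (defaults to every plot in `records`).
#' @param plot_area_m2 Area of one plot in square meters.
#' @param prefix Column-name prefix for the output mean/SE.
#' @return Tibble: `year`, `k`, `area_m2`, `n_combinations`,
#'   `<prefix>_mean`, `<prefix>_se`.
#' @export
car_curve <- function(records, plots = NULL, plot_area_m2 = 8.5^2,
                      prefix = "car") {
  if (length(unique(records$parameterization)) > 1) {
    stop("records mix parameterizations; filter to one first", call. = FALSE)
  }
  if (is.null(plots)) plots <- sort(unique(records$plot))
  if (length(plots) < 1) stop("no plots in records", call. = FALSE)
  out <- records |>
    dplyr::group_by(.data$year) |>
    dplyr::group_modify(function(d, g) {
      sets <- lapply(split(d, d$plot), persistent_set)
      all_sets <- setNames(vector("list", length(plots)),
                           as.character(plots))
      all_sets[names(sets)] <- sets
      combo_union_stats(all_sets, plots)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(area_m2 = .data$k * plot_area_m2)
  out <- dplyr::select(out, "year", "k", "area_m2", "n_combinations",
                       "mean", "se")
  names(out)[names(out) == "mean"] <- paste0(prefix, "_mean")
  names(out)[names(out) == "se"] <- paste0(prefix, "_se")
  out
}

#' Combined SAR/CAR curve table
#'
#' Joins the observed SAR with the coexistence curves from the homogeneous
#' and heterogeneous parameterizations on (`year`, `k`).
#'
#' @param presence Presence tibble.
#' @param records_hom,records_het Persistence records for the two
#'   parameterizations (either may be `NULL`).
#' @param plots Plot identifiers; defaults to every plot in `presence`.
#' @param plot_area_m2 Area of one plot in square meters.
#' @return Tibble with columns `year`, `k`, `area_m2`, `n_combinations`,
#'   `sar_mean`, `sar_se`, and `car_hom_*` / `car_het_*` where available.
#' @export
build_curve_table <- function(presence, records_hom = NULL,
                              records_het = NULL, plots = NULL,
                              plot_area_m2 = 8.5^2) {
  if (is.null(plots)) plots <- sort(unique(presence$plot))
  tab <- sar_curve(presence, plots = plots, plot_area_m2 = plot_area_m2)
  if (!is.null(records_hom)) {
    tab <- dplyr::left_join(
      tab,
      car_curve(records_hom, plots = plots, plot_area_m2 = plot_area_m2,
                prefix = "car_hom") |>
        dplyr::select(-"area_m2", -"n_combinations"),
      by = c("year", "k")
    )
  }
  if (!is.null(records_het)) {
    tab <- dplyr::left_join(
      tab,
      car_curve(records_het, plots = plots, plot_area_m2 = plot_area_m2,
                prefix = "car_het") |>
        dplyr::select(-"area_m2", -"n_combinations"),
      by = c("year", "k")
    )
  }
  tab
}

#' Fit a power law S = c * A^z to a richness-area curve
#'
#' Nonlinear least squares on the untransformed values, initialized from
#' the log-log linear regression. Zero (or negative) richness values are
#' dropped with a warning before taking logs.
#'
#' @param area Vector of areas (positive).
#' @param value Vector of mean richness values, same length.
#' @return Object of class `power_law_fit`: list with `c`, `z`,
#'   `residual_sum_squares`, and `fitted`.
#' @export
power_law_fit <- function(area, value) {
  stopifnot(length(area) == length(value))
  if (any(area <= 0)) stop("areas must be positive", call. = FALSE)
  keep <- value > 0
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " non-positive richness value(s) ",
            "before fitting", call. = FALSE)
    area <- area[keep]
    value <- value[keep]
  }
  if (length(area) < 3) {
    stop("need at least 3 positive points to fit a power law", call. = FALSE)
  }
  start_fit <- lm(log(value) ~ log(area))
  start <- list(c = exp(coef(start_fit)[[1]]), z = coef(start_fit)[[2]])
  est <- tryCatch({
    fit <- minpack.lm::nlsLM(value ~ c * area^z, start = start,
                             control = minpack.lm::nls.lm.control(
                               maxiter = 200))
    coef(fit)
  }, error = function(e) {
    # zero-residual curves can drive z to a denormal where the gradient
    # degenerates; the log-log start is exact there, so keep it
    c(c = start$c, z = start$z)
  })
  fitted <- est[["c"]] * area^est[["z"]]
  structure(
    list(c = est[["c"]], z = est[["z"]],
         residual_sum_squares = sum((value - fitted)^2),
         fitted = fitted),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("Power law S = %.4g * A^%.4g (RSS %.3g)\n",
              x$c, x$z, x$residual_sum_squares))
  invisible(x)
}

#' Average contribution of spatial heterogeneity to coexistence
#'
#' Percentage by which the heterogeneous-parameterization CAR exceeds the
#' homogeneous one, averaged over all (year, k) rows:
#' `100 * mean((car_het - car_hom) / denominator)`. Rows with a zero
#' denominator are excluded.
#'
#' @param curves A [build_curve_table()] result containing both CAR
#'   parameterizations.
#' @param denominator Which curve normalizes the difference.
#' @return Percentage (can be negative if the homogeneous CAR is larger).
#' @export
heterogeneity_contribution <- function(curves,
                                       denominator = c("het", "hom")) {
  denominator <- match.arg(denominator)
  if (!all(c("car_hom_mean", "car_het_mean") %in% names(curves))) {
    stop("curves must contain car_hom_mean and car_het_mean", call. = FALSE)
  }
  den <- if (denominator == "het") curves$car_het_mean else curves$car_hom_mean
  keep <- !is.na(den) & !is.na(curves$car_hom_mean) &
    !is.na(curves$car_het_mean) & den > 0
  if (!any(keep)) stop("all rows have zero denominator", call. = FALSE)
  100 * mean((curves$car_het_mean[keep] - curves$car_hom_mean[keep]) /
               den[keep])
}

#' Average fraction of transient species across areas
#'
#' For every year, number of plots k and plot combination, counts the
#' species of the combination that are classified transient in every plot
#' of the combination where they occur, divides by the union richness of
#' the combination, and returns 100 times the grand mean over all
#' combinations. Combinations with no species present are skipped.
#'
#' @param records Persistence records (one parameterization).
#' @param presence Presence tibble covering the same plot-years.
#' @param plots Plot identifiers; defaults to every plot in `presence`.
#' @return Percentage of the community that is transient, on average.
#' @export
transient_fraction <- function(records, presence, plots = NULL) {
  if (length(unique(records$parameterization)) > 1) {
    stop("records mix parameterizations; filter to one first", call. = FALSE)
  }
  if (is.null(plots)) plots <- sort(unique(presence$plot))
  years <- sort(unique(presence$year))
  fracs <- c()
  for (y in years) {
    pres_y <- presence[presence$year == y, ]
    rec_y <- records[records$year == y, ]
    pres_sets <- sets_from_presence(pres_y, plots)
    trans_sets <- lapply(as.character(plots), function(p) {
      rp <- rec_y[rec_y$plot == p, ]
      rp$species[rp$category == "transient"]
    })
    names(trans_sets) <- as.character(plots)
    P <- length(plots)
    for (k in seq_len(P)) {
      combos <- combn(P, k)
      for (ci in seq_len(ncol(combos))) {
        ix <- as.character(plots[combos[, ci]])
        union_sp <- unique(unlist(pres_sets[ix]))
        if (length(union_sp) == 0) next
        n_trans <- sum(vapply(union_sp, function(spp) {
          in_plots <- ix[vapply(ix, function(p) spp %in% pres_sets[[p]],
                                logical(1))]
          length(in_plots) > 0 &&
            all(vapply(in_plots, function(p) spp %in% trans_sets[[p]],
                       logical(1)))
        }, logical(1)))
        fracs <- c(fracs, n_trans / length(union_sp))
      }
    }
  }
  if (length(fracs) == 0) stop("no non-empty combinations", call. = FALSE)
  100 * mean(fracs)
}
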