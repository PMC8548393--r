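#' Species codes used by the default study design
#'
#' Four-letter codes in the style used for Mediterranean annual grassland
#' surveys (first two letters of genus and species epithet). The default
#' community has 19 species, matching the richness of the field system the
#' synthetic generator emulates.
#'
#' @return Character vector of 19 species codes.
#' @export
default_species_codes <- function() {
  c("BEMA", "CETE", "CHFU", "CHMI", "HOMA", "LEMA", "LYTR", "MEEL",
    "MEPO", "MESU", "PAIN", "PLCO", "POMA", "POMO", "PUPA", "SASO",
    "SCLA", "SOAS", "SUSP")
}

#' Define the spatial and temporal layout of a study
#'
#' The defaults mirror a five-year survey of nine 8.5 m x 8.5 m plots, each
#' divided into 36 subplots of 1 m x 1 m, with focal-individual neighborhoods
#' recorded within a 7.5 cm radius.
#'
#' @param n_years Number of annual censuses.
#' @param n_plots Number of plots.
#' @param n_subplots_per_plot Subplots per plot.
#' @param plot_side_m Side length of a (square) plot, in meters.
#' @param interaction_radius_cm Neighborhood radius around each focal
#'   individual, in centimeters. Recorded for provenance; neighbor counts are
#'   modeled directly.
#' @param species_names Character vector of species codes.
#' @param first_year Calendar year of the first census.
#'
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_years = 5,
                         n_plots = 9,
                         n_subplots_per_plot = 36,
                         plot_side_m = 8.5,
                         interaction_radius_cm = 7.5,
                         species_names = default_species_codes(),
                         first_year = 2015L) {
  stopifnot(
    n_years >= 1, n_plots >= 1, n_subplots_per_plot >= 1,
    plot_side_m > 0, interaction_radius_cm > 0
  )
  if (length(species_names) < 1) {
    stop("study_design: at least one species is required", call. = FALSE)
  }
  if (anyDuplicated(species_names)) {
    stop("study_design: species codes must be unique", call. = FALSE)
  }
  structure(
    list(
      n_years = as.integer(n_years),
      n_plots = as.integer(n_plots),
      n_subplots_per_plot = as.integer(n_subplots_per_plot),
      plot_side_m = plot_side_m,
      interaction_radius_cm = interaction_radius_cm,
      species_names = sort(as.character(species_names)),
      first_year = as.integer(first_year)
    ),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("Study design:", x$n_years, "years,", x$n_plots, "plots x",
      x$n_subplots_per_plot, "subplots,", length(x$species_names),
      "species\n")
  cat("  plot:", x$plot_side_m, "m side (", format(plot_area_m2(x)),
      "m2 ); neighborhood radius:", x$interaction_radius_cm, "cm\n")
  invisible(x)
}

#' Area of a single plot in square meters
#'
#' @param design A `study_design`.
#' @return Numeric scalar, `plot_side_m^2`.
#' @export
plot_area_m2 <- function(design) {
  stopifnot(inherits(design, "study_design"))
  design$plot_side_m^2
}

#' Census years of a design
#' @param design A `study_design`.
#' @return Integer vector of calendar years.
#' @export
design_years <- function(design) {
  stopifnot(inherits(design, "study_design"))
  design$first_year + seq_len(design$n_years) - 1L
}
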