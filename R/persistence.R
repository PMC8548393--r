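#' Feasibility of every species subset of a community
#'
#' Exhaustively solves the interior equilibrium of every subset of size 1 to
#' `max_size` (singletons follow the monoculture rule: feasible when the
#' growth rate and self-limitation are both positive). Enumeration is
#' exhaustive by design; communities larger than `hard_cap` species are
#' rejected unless `allow_large = TRUE`, since the subset count doubles per
#' added species (about 10^6 linear solves at 20 species).
#'
#' @param comm An [lv_community()].
#' @param max_size Largest subset size to evaluate.
#' @param tol Positivity tolerance on equilibrium abundances.
#' @param rcond_tol Singularity threshold (reciprocal condition number).
#' @param hard_cap Refuse communities above this richness.
#' @param allow_large Override the cap explicitly.
#'
#' @return A tibble with one row per subset: `key` (semicolon-joined sorted
#'   species codes), `size`, `feasible`, `singular`, `subset` (list-column
#'   of species codes) and `equilibrium` (list-column of named abundances;
#'   `NULL` for singular subsets). A logical membership matrix
#'   (subsets x species) is attached as attribute `"membership"`.
#' @export
enumerate_feasible_subsets <- function(comm, max_size = length(comm$species),
                                       tol = 1e-10, rcond_tol = 1e-12,
                                       hard_cap = 20, allow_large = FALSE) {
  stopifnot(inherits(comm, "lv_community"))
  S <- length(comm$species)
  if (max_size > S) stop("max_size exceeds community richness", call. = FALSE)
  if (max_size < 1) stop("max_size must be >= 1", call. = FALSE)
  if (S > hard_cap && !allow_large) {
    stop("community of ", S, " species exceeds the enumeration cap (",
         hard_cap, "); pass allow_large = TRUE to force", call. = FALSE)
  }
  ord <- order(comm$species)
  sp <- comm$species[ord]
  A <- comm$A[ord, ord, drop = FALSE]
  r <- comm$r[ord]
  res <- enumerate_subsets_cpp(A, r, as.integer(max_size), tol, rcond_tol)

  membership <- outer(res$mask, 2^(seq_len(S) - 1),
                      function(m, b) floor(m / b) %% 2 == 1)
  colnames(membership) <- sp
  subset <- lapply(seq_along(res$mask), function(i) sp[membership[i, ]])
  equilibrium <- lapply(seq_along(res$mask), function(i) {
    eq <- res$equilibrium[[i]]
    if (is.null(eq)) NULL else setNames(eq, sp[membership[i, ]])
  })
  out <- tibble::tibble(
    key = vapply(subset, paste, character(1), collapse = ";"),
    size = res$size,
    feasible = res$feasible,
    singular = res$singular,
    subset = subset,
    equilibrium = equilibrium
  )
  attr(out, "membership") <- membership
  out
}

#' Assign each species its persistence category
#'
#' Categories follow the simplest-configuration rule: a species is
#' `"pair"` if it belongs to at least one feasible two-species subset,
#' otherwise `"multispecies"` if it belongs to a feasible subset of three
#' or more species, otherwise `"dominant"` if it persists alone while no
#' multi-species subset containing it is feasible, and `"transient"` if no
#' feasible subset contains it at all. The order of the first three checks
#' is configurable through `precedence`; transient is always the fallback.
#' The recorded witness is the lexicographically smallest feasible subset
#' of the qualifying size.
#'
#' @param feasible_subsets Output of [enumerate_feasible_subsets()] at full
#'   `max_size`.
#' @param comm The [lv_community()] that was enumerated.
#' @param precedence Order in which the `pair`, `multispecies` and
#'   `dominant` rules are tried.
#' @return A tibble with columns `species`, `category`,
#'   `witness_subset` (semicolon-joined codes; empty string for transient).
#' @export
classify_species <- function(feasible_subsets, comm,
                             precedence = c("pair", "multispecies",
                                            "dominant")) {
  stopifnot(inherits(comm, "lv_community"))
  precedence <- match.arg(precedence, several.ok = TRUE)
  if (anyDuplicated(precedence)) {
    stop("precedence must not repeat categories", call. = FALSE)
  }
  M <- attr(feasible_subsets, "membership")
  if (is.null(M)) {
    stop("feasible_subsets must come from enumerate_feasible_subsets()",
         call. = FALSE)
  }
  sp <- sort(comm$species)
  feas <- feasible_subsets$feasible
  size <- feasible_subsets$size
  key <- feasible_subsets$key

  witness_for <- function(rows) {
    if (!any(rows)) NA_character_ else min(key[rows])
  }
  out <- lapply(sp, function(f) {
    inset <- M[, f]
    tests <- list(
      pair = feas & inset & size == 2,
      multispecies = feas & inset & size >= 3,
      dominant = feas & inset & size == 1
    )
    for (cat in precedence) {
      if (any(tests[[cat]])) {
        return(tibble::tibble(species = f, category = cat,
                              witness_subset = witness_for(tests[[cat]])))
      }
    }
    tibble::tibble(species = f, category = "transient", witness_subset = "")
  })
  dplyr::bind_rows(out)
}

#' Species predicted to persist
#'
#' A species persists in a plot (or an aggregation of plots) if it was
#' assigned any category other than transient, i.e. it persists alone or as
#' part of at least one feasible community.
#'
#' @param records Persistence records for one plot-year (tibble with
#'   `species` and `category` columns).
#' @return Sorted character vector of persistent species.
#' @export
persistent_set <- function(records) {
  sort(unique(records$species[records$category != "transient"]))
}

#' Classify persistence for every plot of one year
#'
#' Builds, for each plot, the Lotka-Volterra community of the species
#' present there and classifies each of them. Under the homogeneous
#' parameterization, `params` is the single pooled [community_params()] of
#' the year and each plot community is the submatrix over the species
#' present in that plot. Under the heterogeneous parameterization, `params`
#' is the per-plot list returned by [fit_heterogeneous()].
#'
#' @param params A [community_params()] (pooled) or a named list of them
#'   (per plot).
#' @param presence Presence tibble (`year`, `plot`, `species`) for the same
#'   year, as from [presence_table()].
#' @param parameterization Label stored in the records, e.g. `"hom"` or
#'   `"het"`.
#' @param printed_sign,precedence Passed to [params_to_lv()] and
#'   [classify_species()].
#' @param ... Further arguments for [enumerate_feasible_subsets()].
#' @return Tibble of persistence records: `year`, `plot`,
#'   `parameterization`, `species`, `category`, `witness_subset`.
#' @export
classify_year <- function(params, presence, parameterization,
                          printed_sign = FALSE,
                          precedence = c("pair", "multispecies", "dominant"),
                          ...) {
  per_plot <- inherits(params, "community_params")
  year <- if (per_plot) params$year else params[[1]]$year
  presence <- dplyr::filter(presence, .data$year == !!year)
  if (nrow(presence) == 0) {
    stop("presence table has no rows for year ", year, call. = FALSE)
  }
  plots <- sort(unique(presence$plot))
  recs <- lapply(plots, function(p) {
    sp_p <- presence$species[presence$plot == p]
    if (per_plot) {
      sp_p <- intersect(sp_p, params$species)
      if (length(sp_p) == 0) return(NULL)
      comm <- params_to_lv(params, subset = sp_p,
                           printed_sign = printed_sign)
    } else {
      pp <- params[[as.character(p)]]
      if (is.null(pp)) return(NULL)
      sp_p <- intersect(sp_p, pp$species)
      if (length(sp_p) == 0) return(NULL)
      comm <- params_to_lv(pp, subset = sp_p, printed_sign = printed_sign)
    }
    subsets <- enumerate_feasible_subsets(comm, ...)
    cls <- classify_species(subsets, comm, precedence = precedence)
    tibble::tibble(year = year, plot = p, parameterization = parameterization,
                   cls)
  })
  dplyr::bind_rows(recs)
}
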