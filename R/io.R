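# write a data frame (or matrix writer callback) atomically: temp file in
# the same directory, then rename over the target
atomic_write <- function(path, writer) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

#' Write / read an observation table
#'
#' Wide CSV dialect: columns `year, plot, subplot, focal, seeds`, then one
#' `n_<CODE>` neighbor-count column per species code, UTF-8, `.` decimal
#' separator, header mandatory. Reading validates the header, checks that
#' seed and neighbor counts are nonnegative integers and that every focal
#' code has a matching neighbor column.
#'
#' @param obs Observation tibble.
#' @param path File path.
#' @return `read_observations()` returns the validated tibble;
#'   `write_observations()` returns `path` invisibly.
#' @export
write_observations <- function(obs, path) {
  atomic_write(path, function(p) readr::write_csv(obs, p, progress = FALSE))
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  obs <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("year", "plot", "subplot", "focal", "seeds")
  missing <- setdiff(need, names(obs))
  if (length(missing)) {
    stop("malformed observation header; missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ncols <- grep("^n_", names(obs), value = TRUE)
  if (length(ncols) == 0) {
    stop("malformed observation header: no n_<SPECIES> columns",
         call. = FALSE)
  }
  if (any(obs$seeds < 0)) {
    stop("validation error: negative seed counts", call. = FALSE)
  }
  nb <- as.matrix(obs[ncols])
  if (any(nb < 0)) {
    stop("validation error: negative neighbor counts", call. = FALSE)
  }
  species <- sub("^n_", "", ncols)
  unknown <- setdiff(unique(obs$focal), species)
  if (length(unknown)) {
    stop("unknown species code(s) in focal column: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  obs
}

#' Write / read an interaction matrix
#'
#' Square CSV dialect: header row of species codes, one index column
#' `species` of the same codes (row = focal species i, column = neighbor
#' j). Reading enforces squareness and matching row/column codes.
#'
#' @param alpha Square named matrix.
#' @param path File path.
#' @return `read_alpha()` returns the matrix; the writer returns `path`
#'   invisibly.
#' @export
write_alpha <- function(alpha, path) {
  stopifnot(is.matrix(alpha), nrow(alpha) == ncol(alpha))
  df <- tibble::as_tibble(alpha, rownames = "species")
  atomic_write(path, function(p) readr::write_csv(df, p, progress = FALSE))
}

#' @rdname write_alpha
#' @export
read_alpha <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (names(df)[1] != "species") {
    stop("malformed alpha header: first column must be 'species'",
         call. = FALSE)
  }
  m <- as.matrix(df[, -1])
  if (nrow(m) != ncol(m)) {
    stop("alpha matrix is not square (", nrow(m), " rows, ", ncol(m),
         " columns)", call. = FALSE)
  }
  rownames(m) <- df$species
  if (!identical(rownames(m), colnames(m))) {
    stop("alpha row and column species codes differ", call. = FALSE)
  }
  m
}

#' Write / read per-species vital rates and fecundities
#'
#' CSV dialect: columns `species, log_lambda, g, s, dispersion` (the last
#' three may be NA when unknown, e.g. for intermediate fits).
#'
#' @param vitals Tibble with the columns above.
#' @param path File path.
#' @return `read_vitals()` returns the validated tibble.
#' @export
write_vitals <- function(vitals, path) {
  atomic_write(path, function(p) readr::write_csv(vitals, p, progress = FALSE))
}

#' @rdname write_vitals
#' @export
read_vitals <- function(path) {
  v <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("species", "log_lambda", "g", "s", "dispersion")
  missing <- setdiff(need, names(v))
  if (length(missing)) {
    stop("malformed vitals header; missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ok_g <- is.na(v$g) | (v$g > 0 & v$g <= 1)
  ok_s <- is.na(v$s) | (v$s >= 0 & v$s < 1)
  if (!all(ok_g)) stop("validation error: g outside (0, 1]", call. = FALSE)
  if (!all(ok_s)) stop("validation error: s outside [0, 1)", call. = FALSE)
  v
}

# vitals tibble for a community_params or ground_truth (per-plot means for
# heterogeneous truths)
params_to_vitals <- function(params) {
  if (inherits(params, "ground_truth")) {
    return(tibble::tibble(
      species = params$species,
      log_lambda = rowMeans(params$log_lambda),
      g = as.numeric(params$g), s = as.numeric(params$s),
      dispersion = as.numeric(params$dispersion)
    ))
  }
  tibble::tibble(
    species = params$species,
    log_lambda = as.numeric(params$log_lambda),
    g = as.numeric(params$g), s = as.numeric(params$s),
    dispersion = as.numeric(params$dispersion)
  )
}

#' Write / read persistence records
#'
#' CSV columns: `year, plot, parameterization, species, category,
#' witness_subset` (semicolon-joined species codes).
#'
#' @param records Records tibble from [classify_year()].
#' @param path File path.
#' @return `read_persistence()` returns the validated tibble.
#' @export
write_persistence <- function(records, path) {
  atomic_write(path, function(p) readr::write_csv(records, p,
                                                  progress = FALSE))
}

#' @rdname write_persistence
#' @export
read_persistence <- function(path) {
  rec <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("year", "plot", "parameterization", "species", "category",
            "witness_subset")
  missing <- setdiff(need, names(rec))
  if (length(missing)) {
    stop("malformed persistence header; missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(rec$category),
                 c("dominant", "pair", "multispecies", "transient"))
  if (length(bad)) {
    stop("unknown persistence category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  rec$witness_subset[is.na(rec$witness_subset)] <- ""
  rec
}

#' Write / read a curve table
#'
#' @param curves Curve tibble from [build_curve_table()].
#' @param path File path.
#' @return `read_curves()` returns the tibble.
#' @export
write_curves <- function(curves, path) {
  atomic_write(path, function(p) readr::write_csv(curves, p,
                                                  progress = FALSE))
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  cv <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("year", "k", "area_m2", "n_combinations", "sar_mean", "sar_se")
  missing <- setdiff(need, names(cv))
  if (length(missing)) {
    stop("malformed curves header; missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cv
}
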