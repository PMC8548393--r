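#' Reshuffle all interaction coefficients
#'
#' Returns a matrix of the same dimensions whose entries are a uniformly
#' random permutation of all entries of `alpha`, diagonal included.
#'
#' @param alpha Square interaction matrix.
#' @param seed Integer seed.
#' @return Reshuffled matrix with the same dimnames.
#' @export
shuffle_all <- function(alpha, seed) {
  stopifnot(is.matrix(alpha), nrow(alpha) == ncol(alpha))
  out <- alpha
  withr::with_seed(as.integer(seed), {
    out[] <- sample(as.vector(alpha))
  })
  out
}

#' Reshuffle interspecific coefficients, keeping self-limitation fixed
#'
#' The diagonal (intraspecific terms) is preserved exactly; the
#' off-diagonal entries are a uniformly random permutation of the original
#' off-diagonal multiset.
#'
#' @inheritParams shuffle_all
#' @return Reshuffled matrix with the same dimnames and diagonal.
#' @export
shuffle_offdiag <- function(alpha, seed) {
  stopifnot(is.matrix(alpha), nrow(alpha) == ncol(alpha))
  out <- alpha
  off <- which(row(alpha) != col(alpha))
  if (length(off) > 1) {
    withr::with_seed(as.integer(seed), {
      out[off] <- sample(alpha[off])
    })
  }
  out
}

#' Null ensemble of coexistence-area curves
#'
#' Takes the pooled (homogeneous) parameterization of one year as baseline
#' and, per replicate, reshuffles the interaction submatrix of every plot
#' community (restricted to the species present in that plot), re-runs the
#' persistence classification and rebuilds the CAR. Replicate seeds are
#' drawn upfront from the master seed (one `sample.int()` call under
#' `seed`), so replicates are individually reproducible; within a
#' replicate, plot matrices are reshuffled sequentially under that
#' replicate's seed.
#'
#' @param params Pooled [community_params()] for one year
#'   (from [fit_homogeneous()]).
#' @param presence Presence tibble covering that year.
#' @param model `"shuffle_all"` or `"shuffle_offdiag"`.
#' @param n_replicates Number of reshuffled replicates.
#' @param seed Master seed.
#' @param plots Plot identifiers; defaults to every plot in `presence`.
#' @param plot_area_m2 Area of one plot in square meters.
#' @param printed_sign,precedence Passed through to the classifier.
#'
#' @return Object of class `null_ensemble`: list with `model`,
#'   `n_replicates`, `replicate_curves` (list of per-replicate CAR
#'   tibbles), and `mean_curve` (element-wise mean CAR across replicates,
#'   with the between-replicate standard error in `car_se`).
#' @export
null_car_ensemble <- function(params, presence,
                              model = c("shuffle_all", "shuffle_offdiag"),
                              n_replicates = 100, seed,
                              plots = NULL, plot_area_m2 = 8.5^2,
                              printed_sign = FALSE,
                              precedence = c("pair", "multispecies",
                                             "dominant")) {
  stopifnot(inherits(params, "community_params"))
  model <- match.arg(model)
  shuffler <- switch(model, shuffle_all = shuffle_all,
                     shuffle_offdiag = shuffle_offdiag)
  year <- params$year
  presence <- dplyr::filter(presence, .data$year == !!year)
  if (is.null(plots)) plots <- sort(unique(presence$plot))
  # headroom below 2^31 so per-plot offsets stay valid integer seeds
  rep_seeds <- withr::with_seed(as.integer(seed), {
    sample.int(2147400000L, n_replicates)
  })

  plot_species <- lapply(plots, function(p) {
    sort(intersect(presence$species[presence$plot == p], params$species))
  })
  names(plot_species) <- as.character(plots)
  r_full <- lv_growth_rate(params$log_lambda, params$g, params$s,
                           printed_sign = printed_sign)

  replicate_curves <- vector("list", n_replicates)
  failed <- 0L
  for (b in seq_len(n_replicates)) {
    recs <- try({
      rows <- lapply(seq_along(plots), function(pi) {
        sp_p <- plot_species[[pi]]
        if (length(sp_p) == 0) return(NULL)
        A_p <- params$alpha[sp_p, sp_p, drop = FALSE]
        A_shuf <- shuffler(A_p, seed = rep_seeds[b] + pi - 1L)
        comm <- lv_community(sp_p, r_full[sp_p], A_shuf)
        subsets <- enumerate_feasible_subsets(comm)
        cls <- classify_species(subsets, comm, precedence = precedence)
        tibble::tibble(year = year, plot = plots[pi],
                       parameterization = paste0("null_", model), cls)
      })
      dplyr::bind_rows(rows)
    }, silent = TRUE)
    if (inherits(recs, "try-error")) {
      failed <- failed + 1L
      warning("null replicate ", b, " failed: ",
              attr(recs, "condition")$message, call. = FALSE)
      next
    }
    replicate_curves[[b]] <- car_curve(recs, plots = plots,
                                       plot_area_m2 = plot_area_m2)
  }
  replicate_curves <- Filter(Negate(is.null), replicate_curves)
  if (length(replicate_curves) == 0) {
    stop("all null replicates failed", call. = FALSE)
  }
  means <- vapply(replicate_curves, function(x) x$car_mean,
                  numeric(nrow(replicate_curves[[1]])))
  means <- matrix(means, nrow = nrow(replicate_curves[[1]]))
  mean_curve <- replicate_curves[[1]]
  mean_curve$car_mean <- rowMeans(means)
  mean_curve$car_se <- apply(means, 1, function(v) {
    if (length(v) > 1) sd(v) / sqrt(length(v)) else 0
  })
  structure(
    list(model = model, n_replicates = length(replicate_curves),
         n_failed = failed, replicate_curves = replicate_curves,
         mean_curve = mean_curve),
    class = "null_ensemble"
  )
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat("Null CAR ensemble (", x$model, "): ", x$n_replicates,
      " replicates\n", sep = "")
  invisible(x)
}
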