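presence_from_sets <- function(sets, year = 2015) {
  dplyr::bind_rows(lapply(names(sets), function(p) {
    if (length(sets[[p]]) == 0) return(NULL)
    tibble::tibble(year = year, plot = as.integer(p), species = sets[[p]])
  }))
}

records_from_sets <- function(persist, present, year = 2015,
                              parameterization = "hom") {
  dplyr::bind_rows(lapply(names(present), function(p) {
    if (length(present[[p]]) == 0) return(NULL)
    tibble::tibble(
      year = year, plot = as.integer(p), parameterization = parameterization,
      species = present[[p]],
      category = ifelse(present[[p]] %in% persist[[p]], "pair", "transient"),
      witness_subset = ""
    )
  }))
}

test_that("nine-plot combination counts match the binomial coefficients", {
  sets <- setNames(lapply(1:9, function(p) c("X", LETTERS[p])),
                   as.character(1:9))
  sar <- sar_curve(presence_from_sets(sets), plots = 1:9)
  expect_equal(sar$n_combinations, choose(9, 1:9))
  expect_equal(sar$n_combinations, c(9, 36, 84, 126, 126, 84, 36, 9, 1))
  expect_equal(sar$area_m2, (1:9) * 72.25)
})

test_that("SAR handles flat and fully-nested compositions exactly", {
  # identical composition everywhere: flat curve, zero SE
  sets <- setNames(rep(list(c("A", "B", "C")), 4), as.character(1:4))
  sar <- sar_curve(presence_from_sets(sets), plots = 1:4)
  expect_equal(sar$sar_mean, rep(3, 4))
  expect_equal(sar$sar_se, rep(0, 4))

  # one unique species per plot: SAR = k, enumerated over all combinations
  sets2 <- list(`1` = "A", `2` = "B", `3` = "C")
  sar2 <- sar_curve(presence_from_sets(sets2), plots = 1:3)
  expect_equal(sar2$sar_mean, c(1, 2, 3))
  expect_equal(sar2$n_combinations, c(3, 3, 1))
  expect_equal(sar2$sar_se, c(0, 0, 0))

  # SAR at k = P equals total richness with zero SE
  sets3 <- list(`1` = c("A", "B"), `2` = c("B", "C"), `3` = "D")
  sar3 <- sar_curve(presence_from_sets(sets3), plots = 1:3)
  expect_equal(sar3$sar_mean[3], 4)
  expect_equal(sar3$sar_se[3], 0)
  # monotone non-decreasing in k
  expect_true(all(diff(sar3$sar_mean) >= 0))
})

test_that("CAR equals SAR when everyone persists and zero when nobody does", {
  present <- list(`1` = c("A", "B"), `2` = c("B", "C"))
  pres <- presence_from_sets(present)

  rec_all <- records_from_sets(present, present)
  car <- car_curve(rec_all, plots = 1:2)
  sar <- sar_curve(pres, plots = 1:2)
  expect_equal(car$car_mean, sar$sar_mean)

  rec_none <- records_from_sets(list(`1` = character(), `2` = character()),
                                present)
  car0 <- car_curve(rec_none, plots = 1:2)
  expect_equal(car0$car_mean, c(0, 0))

  # disjoint persistent sets: union grows from 1 to 2
  rec_mix <- records_from_sets(list(`1` = "A", `2` = "C"), present)
  car2 <- car_curve(rec_mix, plots = 1:2)
  expect_equal(car2$car_mean, c(1, 2))

  expect_error(car_curve(dplyr::bind_rows(
    rec_all, dplyr::mutate(rec_none, parameterization = "het"))),
    "mix")
})

test_that("power-law fits recover exact curves and flat curves", {
  area <- (1:9) * 72.25
  fit <- power_law_fit(area, 2 * area^0.3)
  expect_equal(fit$c, 2, tolerance = 1e-6)
  expect_equal(fit$z, 0.3, tolerance = 1e-6)
  expect_lt(fit$residual_sum_squares, 1e-10)

  flat <- power_law_fit(area, rep(5, 9))
  expect_equal(flat$z, 0, tolerance = 1e-6)
  expect_equal(flat$c, 5, tolerance = 1e-5)

  expect_warning(fitz <- power_law_fit(area, c(0, 2 * area[-1]^0.3)),
                 "non-positive")
  expect_equal(fitz$z, 0.3, tolerance = 1e-6)
  expect_error(power_law_fit(area[1:2], c(1, 2)), "3 positive points")
  expect_error(power_law_fit(-area, rep(1, 9)), "positive")
})

test_that("heterogeneity contribution reproduces direct formulas", {
  curves <- tibble::tibble(
    year = 2015, k = 1:3, area_m2 = (1:3) * 72.25,
    n_combinations = c(3, 3, 1),
    sar_mean = c(10, 11, 12), sar_se = 0,
    car_hom_mean = c(9, 9, 9), car_hom_se = 0,
    car_het_mean = c(10, 10, 10), car_het_se = 0
  )
  expect_equal(heterogeneity_contribution(curves), 10)
  expect_equal(heterogeneity_contribution(curves, denominator = "hom"),
               100 * mean((10 - 9) / 9))

  same <- dplyr::mutate(curves, car_het_mean = car_hom_mean)
  expect_equal(heterogeneity_contribution(same), 0)

  zero <- dplyr::mutate(curves, car_het_mean = 0, car_hom_mean = 0)
  expect_error(heterogeneity_contribution(zero), "zero denominator")
})

test_that("transient fraction matches direct enumeration", {
  # 10 species everywhere, the same single transient in every plot: 10%
  sp <- paste0("S", sprintf("%02d", 1:10))
  present <- setNames(rep(list(sp), 3), as.character(1:3))
  persist <- setNames(rep(list(sp[-1]), 3), as.character(1:3))
  pres <- presence_from_sets(present)
  rec <- records_from_sets(persist, present)
  expect_equal(transient_fraction(rec, pres, plots = 1:3), 10)

  # no transients -> 0%; all transients -> 100%
  rec_all <- records_from_sets(present, present)
  expect_equal(transient_fraction(rec_all, pres, plots = 1:3), 0)
  rec_none <- records_from_sets(setNames(rep(list(character()), 3),
                                         as.character(1:3)), present)
  expect_equal(transient_fraction(rec_none, pres, plots = 1:3), 100)

  # a species transient in one plot but persistent in another is not
  # transient for combinations containing both
  present2 <- list(`1` = c("A", "B"), `2` = c("A", "B"))
  persist2 <- list(`1` = c("A", "B"), `2` = "B")
  rec2 <- records_from_sets(persist2, present2)
  pres2 <- presence_from_sets(present2)
  # k=1: plot1 0/2, plot2 1/2; k=2: A persists in plot 1 -> 0/2
  expect_equal(transient_fraction(rec2, pres2, plots = 1:2),
               100 * mean(c(0, 0.5, 0)))
})
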