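test_that("rock-paper-scissors: only singletons and the full triplet are feasible", {
  comm <- rps_community()
  subs <- enumerate_feasible_subsets(comm)
  expect_equal(nrow(subs), 2^3 - 1)

  singles <- subs[subs$size == 1, ]
  expect_true(all(singles$feasible))
  pairs <- subs[subs$size == 2, ]
  expect_false(any(pairs$feasible))
  triple <- subs[subs$size == 3, ]
  expect_true(triple$feasible)
  expect_equal(unname(triple$equilibrium[[1]]), rep(1 / 2.7, 3),
               tolerance = 1e-10)

  # cyclic coexistence: everything is classified multispecies
  cls <- classify_species(subs, comm)
  expect_equal(cls$category, rep("multispecies", 3))
  expect_equal(unique(cls$witness_subset), "A;B;C")
})

test_that("subset enumeration agrees with a plain-R brute force", {
  set.seed(123)
  for (i in 1:8) {
    n <- sample(2:5, 1)
    sp <- sort(replicate(n, paste(sample(LETTERS, 4), collapse = "")))
    A <- matrix(runif(n * n, -0.3, 0.6), n, n, dimnames = list(sp, sp))
    diag(A) <- runif(n, 0.3, 1.2)
    r <- runif(n, -0.5, 1.5)
    comm <- lv_community(sp, r, A)
    subs <- enumerate_feasible_subsets(comm)
    oracle <- brute_force_subsets(A, r)
    expect_equal(nrow(subs), length(oracle))
    for (j in seq_len(nrow(subs))) {
      o <- oracle[[subs$key[j]]]
      expect_equal(subs$feasible[j], o$feasible)
      if (!subs$singular[j] && !is.null(o$equilibrium)) {
        expect_equal(unname(subs$equilibrium[[j]]), unname(o$equilibrium),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("decoupled species yield all-feasible subsets; counts are 2^S - 1", {
  sp <- c("A", "B", "C", "D")
  comm <- lv_community(sp, rep(1, 4), diag(4))
  subs <- enumerate_feasible_subsets(comm)
  expect_equal(nrow(subs), 15)
  expect_true(all(subs$feasible))
  cls <- classify_species(subs, comm)
  expect_equal(cls$category, rep("pair", 4))   # simplest multi-species config
  expect_equal(persistent_set(cls), sp)

  expect_error(enumerate_feasible_subsets(comm, max_size = 5), "max_size")
  big <- lv_community(as.character(1:25), rep(1, 25), diag(25))
  expect_error(enumerate_feasible_subsets(big), "cap")
})

test_that("facilitation rescue and dominance classify as specified", {
  sp <- c("A", "B")
  # facilitation rescue: the pair is feasible, so both are 'pair'
  comm_f <- lv_community(sp, c(-0.2, 1),
                         matrix(c(1, -0.5, 0.1, 1), 2, 2, byrow = TRUE))
  cls_f <- classify_species(enumerate_feasible_subsets(comm_f), comm_f)
  expect_equal(cls_f$category, c("pair", "pair"))

  # competition: A cannot persist anywhere, B persists alone
  comm_c <- lv_community(sp, c(-0.2, 1),
                         matrix(c(1, 0.5, 0.1, 1), 2, 2, byrow = TRUE))
  cls_c <- classify_species(enumerate_feasible_subsets(comm_c), comm_c)
  expect_equal(cls_c$category[cls_c$species == "A"], "transient")
  expect_equal(cls_c$witness_subset[cls_c$species == "A"], "")
  expect_equal(cls_c$category[cls_c$species == "B"], "dominant")
  expect_equal(cls_c$witness_subset[cls_c$species == "B"], "B")
  expect_equal(persistent_set(cls_c), "B")

  expect_equal(persistent_set(cls_c[cls_c$category == "transient", ]),
               character(0))
})

test_that("category precedence is configurable", {
  # both species persist alone AND as a pair
  sp <- c("A", "B")
  comm <- lv_community(sp, c(1, 1), matrix(c(1, 0.2, 0.2, 1), 2, 2))
  subs <- enumerate_feasible_subsets(comm)
  expect_equal(classify_species(subs, comm)$category, c("pair", "pair"))
  dom_first <- classify_species(subs, comm,
                                precedence = c("dominant", "pair",
                                               "multispecies"))
  expect_equal(dom_first$category, c("dominant", "dominant"))
})

test_that("adding a species never changes verdicts of unrelated subsets", {
  set.seed(31)
  sp <- c("A", "B", "C", "D")
  A <- matrix(runif(16, -0.2, 0.5), 4, 4, dimnames = list(sp, sp))
  diag(A) <- runif(4, 0.5, 1.2)
  r <- runif(4, -0.2, 1)
  comm4 <- lv_community(sp, r, A)
  comm3 <- lv_community(sp[1:3], r[1:3], A[1:3, 1:3])
  subs4 <- enumerate_feasible_subsets(comm4)
  subs3 <- enumerate_feasible_subsets(comm3)
  for (j in seq_len(nrow(subs3))) {
    row4 <- subs4[subs4$key == subs3$key[j], ]
    expect_equal(row4$feasible, subs3$feasible[j])
  }
})

test_that("every species gets exactly one category and self-limited growers never go transient", {
  set.seed(57)
  for (i in 1:10) {
    n <- sample(3:6, 1)
    sp <- LETTERS[1:n]
    A <- matrix(runif(n * n, -0.3, 0.6), n, n, dimnames = list(sp, sp))
    diag(A) <- runif(n, 0.3, 1)
    r <- runif(n, -0.5, 1.5)
    comm <- lv_community(sp, r, A)
    cls <- classify_species(enumerate_feasible_subsets(comm), comm)
    expect_equal(sort(cls$species), sp)            # one record per species
    expect_equal(nrow(cls), n)
    can_alone <- sp[r > 0]
    expect_false(any(cls$category[cls$species %in% can_alone] == "transient"))
    # witness size matches category
    wit_n <- lengths(strsplit(cls$witness_subset, ";"))
    expect_true(all(wit_n[cls$category == "pair"] == 2))
    expect_true(all(wit_n[cls$category == "multispecies"] >= 3))
    expect_true(all(wit_n[cls$category == "dominant"] == 1))
  }
})

test_that("classification agrees with an ODE-integration oracle on small communities", {
  set.seed(73)
  n_checked <- 0
  for (i in 1:12) {
    n <- sample(2:4, 1)
    sp <- LETTERS[1:n]
    A <- matrix(runif(n * n, 0, 0.4), n, n, dimnames = list(sp, sp))
    diag(A) <- runif(n, 0.6, 1.4)
    r <- runif(n, 0.2, 1.2)
    comm <- lv_community(sp, r, A)
    res <- equilibrium_abundances(comm, sp)
    if (!res$feasible || !local_stability(res, comm)) next
    final <- lv_ode_final(A, r, setNames(rep(0.05, n), sp))
    expect_equal(unname(final), unname(res$equilibrium), tolerance = 1e-3)
    # a feasible+stable full community means nobody is transient
    cls <- classify_species(enumerate_feasible_subsets(comm), comm)
    expect_false(any(cls$category == "transient"))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 4)
})
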