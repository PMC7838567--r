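test_that("generalized Jaccard evaluates the min/max formula", {
  a <- make_kv(c(1, 2), c(2, 1), id = "a")
  b <- make_kv(c(1, 3), c(1, 4), id = "b")
  expect_equal(generalized_jaccard(a, b), 1 / 7)
  expect_equal(generalized_jaccard(a, a), 1.0)
  expect_equal(generalized_jaccard(a, make_kv(c(7, 8), c(1, 1), id = "c")), 0)
  expect_error(generalized_jaccard(make_kv(numeric(0), integer(0)),
                                   make_kv(numeric(0), integer(0))),
               "empty")
})

test_that("modified generalized Jaccard divides by min(sum max, max N)", {
  a <- make_kv(c(1, 2), c(2, 1), id = "a")  # N = 3
  b <- make_kv(c(1, 3), c(1, 4), id = "b")  # N = 5
  expect_equal(modified_generalized_jaccard(a, b), 1 / 5)
  expect_equal(modified_generalized_jaccard(a, a), 1.0)
  # distinct-count mode: N_a = N_b = 2 -> 1 / min(7, 2)
  expect_equal(modified_generalized_jaccard(a, b, n_mode = "distinct"), 1 / 2)
  # subset case: never below the generalized measure
  sub <- make_kv(1, 2, id = "s")
  sup <- make_kv(c(1, 2, 3), c(2, 3, 1), id = "S")
  expect_gte(modified_generalized_jaccard(sub, sup),
             generalized_jaccard(sub, sup))
})

test_that("both measures agree with the brute-force multiset oracle", {
  for (seed in 1:60) {
    a <- random_kv(seed, id = "a")
    b <- random_kv(seed + 500, id = "b")
    j <- generalized_jaccard(a, b)
    expect_equal(j, jaccard_oracle(a, b))
    expect_gte(j, 0); expect_lte(j, 1)
    expect_equal(generalized_jaccard(b, a), j)
    expect_gte(modified_generalized_jaccard(a, b), j)
  }
})

test_that("mirror-signed keys compare as distinct keys", {
  a <- make_kv(c(-5, 3), c(1, 1), id = "a", mirror = TRUE)
  b <- make_kv(c(5, 3), c(1, 1), id = "b", mirror = TRUE)
  expect_equal(generalized_jaccard(a, b), 1 / 3)
})

test_that("similarity matrices are symmetric with unit diagonal", {
  vs <- list(a = random_kv(1, id = "a"), b = random_kv(2, id = "b"),
             c = random_kv(3, id = "c"))
  sim <- tsr_similarity(vs)
  expect_equal(diag(unclass(sim)), c(a = 1, b = 1, c = 1))
  expect_equal(unclass(sim), t(unclass(sim)))
  # element-wise brute-force recomputation
  for (i in 1:3) for (j in 1:3) {
    expect_equal(sim[i, j], jaccard_oracle(vs[[i]], vs[[j]]))
  }
  # identical vectors give an all-ones matrix
  same <- list(x = vs$a, y = vs$a, z = vs$a)
  attr(same$y, "protein_id") <- "y"; attr(same$z, "protein_id") <- "z"
  expect_equal(unclass(tsr_similarity(same)),
               matrix(1, 3, 3, dimnames = list(c("x", "y", "z"),
                                               c("x", "y", "z"))),
               ignore_attr = TRUE)
  # permuting input order permutes rows/columns consistently
  sim2 <- tsr_similarity(vs[c(3, 1, 2)])
  expect_equal(unclass(sim2), unclass(sim)[c("c", "a", "b"), c("c", "a", "b")],
               ignore_attr = TRUE)
  expect_error(tsr_similarity(list(a = vs$a, a = vs$a)), "unique")
})

test_that("distance is one minus similarity", {
  vs <- list(a = random_kv(4, id = "a"), b = random_kv(5, id = "b"))
  sim <- tsr_similarity(vs)
  d <- tsr_distance(sim)
  expect_equal(unclass(d), 1 - unclass(sim), ignore_attr = TRUE)
  expect_equal(diag(unclass(d)), c(a = 0, b = 0))
  expect_equal(unclass(d), t(unclass(d)))
})

test_that("key-space grouping and nested bin coarsening never decrease similarity", {
  sc <- default_bin_scheme()
  # nested coarsening: keep every other theta cut so coarse bins are unions
  coarse <- bin_scheme(sc$theta_breaks[seq(2, 27, by = 2)],
                       sc$maxdist_breaks, m = sc$m)
  g <- default_grouping()
  for (seed in 1:15) {
    s1 <- make_coil(12, seed = seed)
    s2 <- perturb(make_coil(12, seed = seed), 1.0, seed = seed + 30)
    a <- tsr_keys(s1, sc); b <- tsr_keys(s2, sc)
    j0 <- generalized_jaccard(a, b)
    expect_gte(generalized_jaccard(group_keys(a, g, sc),
                                   group_keys(b, g, sc)), j0)
    expect_gte(generalized_jaccard(coarsen_keys(a, sc, coarse),
                                   coarsen_keys(b, sc, coarse)), j0)
    # geometric regeneration under the nested coarse scheme agrees with the
    # key-space coarsening exactly (labels unchanged, bins are unions)
    expect_equal(as.data.frame(tsr_keys(s1, coarse)),
                 as.data.frame(coarsen_keys(a, sc, coarse)))
  }
})

test_that("generation-time grouping collapses label detail", {
  # applied before vertex ordering (new ties break geometrically), this is
  # the label-assignment semantics; it typically raises similarity but is
  # not an exact key merge
  sc <- default_bin_scheme()
  g <- default_grouping()
  s1 <- make_coil(12, seed = 101)
  kv <- tsr_keys(s1, sc, grouping = g)
  dec <- decode_key(kv$key, sc)
  grouped_away <- c(20, 10, 9, 15, 14, 23, 22, 21)  # THR GLU GLN LYS LEU VAL TYR TRP
  expect_false(any(unlist(dec[, c("l1", "l2", "l3")]) %in% grouped_away))
})

test_that("similarity to a noisy copy decreases with the noise level", {
  sc <- default_bin_scheme()
  sims <- vapply(c(0.01, 0.1, 0.5, 2.0), function(sigma) {
    mean(vapply(1:5, function(seed) {
      s <- make_coil(15, seed = seed)
      generalized_jaccard(tsr_keys(s, sc),
                          tsr_keys(perturb(s, sigma, seed + 10), sc))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(sims) < 0))
})

test_that("matrix TSV files round-trip", {
  vs <- list(a = random_kv(8, id = "a"), b = random_kv(9, id = "b"))
  sim <- tsr_similarity(vs)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(sim, f)
  m2 <- read_matrix_tsv(f, "sim")
  expect_equal(unclass(m2), unclass(sim), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(attr(m2, "measure"), "generalized")
})
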