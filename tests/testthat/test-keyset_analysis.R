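test_that("key-set report computes common, specific and Venn regions", {
  vs <- list(p1 = make_kv(c(1, 2, 3), c(1, 1, 1), id = "p1"),
             p2 = make_kv(c(3, 4), c(1, 1), id = "p2"))
  rep <- build_keyset_report(vs, c(p1 = "A", p2 = "B"))
  expect_equal(rep$common_all_classes, 3)
  expect_equal(rep$specific$A, c(1, 2))
  expect_equal(rep$specific$B, 4)
  expect_equal(sum(rep$venn_counts$n), 4)  # |union|
  # one class only: specific = distinct = union
  rep1 <- build_keyset_report(vs, c(p1 = "A", p2 = "A"))
  expect_equal(rep1$specific$A, 1:4)
  expect_equal(rep1$common_all_classes, 1:4)
  expect_error(build_keyset_report(vs, c(p1 = "A")), "missing")
})

test_that("Venn region counts match the exhaustive set oracle", {
  for (seed in 1:10) {
    vs <- lapply(1:9, function(i) random_kv(seed * 20 + i, id = paste0("q", i),
                                            pool = 1:60, n_keys = 15))
    names(vs) <- paste0("q", 1:9)
    cmap <- stats::setNames(rep(c("A", "B", "C"), each = 3), names(vs))
    rep <- build_keyset_report(vs, cmap)
    oracle <- venn_oracle(rep$distinct_keys)
    expect_equal(dplyr::arrange(rep$venn_counts, region),
                 dplyr::arrange(oracle, region))
    # invariants: specific sets pairwise disjoint, disjoint from common
    expect_length(intersect(rep$specific$A, rep$specific$B), 0)
    expect_length(intersect(unlist(rep$specific), rep$common_all_classes), 0)
    for (cl in c("A", "B", "C")) {
      expect_true(all(rep$common_every_protein[[cl]] %in%
                        rep$distinct_keys[[cl]]))
      for (other in setdiff(c("A", "B", "C"), cl)) {
        expect_length(intersect(rep$specific[[cl]],
                                rep$distinct_keys[[other]]), 0)
      }
    }
  }
})

test_that("Common keys are the intersection over class members", {
  v <- random_kv(5, id = "v")
  same <- list(a = v, b = v, c = v)
  res <- common_keys_every_protein(same)
  expect_equal(res$keys, v$key)
  expect_equal(res$coverage$frac_distinct, rep(1, 3))
  expect_equal(res$coverage$frac_weighted, rep(1, 3))
  # a disjoint member empties the intersection
  disj <- make_kv(1000 + 1:5, rep(1, 5), id = "d")
  expect_length(common_keys_every_protein(list(v, disj))$keys, 0)
  # planted shared core recovered exactly
  core <- 1:10
  vs <- lapply(1:5, function(i) {
    extra <- 100 + (i * 20):(i * 20 + 8)   # disjoint per-protein extras
    make_kv(c(core, extra), rep(1, length(core) + length(extra)),
            id = paste0("m", i))
  })
  expect_equal(common_keys_every_protein(vs)$keys, core)
})

test_that("key feature statistics use raw values or bin midpoints", {
  sc <- default_bin_scheme()
  k <- encode_key(5, 4, 4, 2, 5, sc)
  st <- key_feature_stats(k, sc)
  tb <- c(0, sc$theta_breaks, 90)
  db <- c(0, sc$maxdist_breaks)
  expect_equal(st$mean_theta, (tb[5] + tb[6]) / 2)
  expect_equal(st$mean_maxdist, (db[2] + db[3]) / 2)
  # stats over all keys equal the size-weighted mean over a partition
  keys <- withr::with_seed(11, encode_key(
    sample(4:23, 30, TRUE), sample(4:23, 30, TRUE), sample(4:23, 30, TRUE),
    sample(1:35, 30, TRUE), sample(1:29, 30, TRUE), sc))
  keys <- unique(keys)
  half <- seq_len(length(keys) %/% 2)
  all_st <- key_feature_stats(keys, sc)
  s1 <- key_feature_stats(keys[half], sc)
  s2 <- key_feature_stats(keys[-half], sc)
  w <- length(half) / length(keys)
  expect_equal(all_st$mean_theta,
               w * s1$mean_theta + (1 - w) * s2$mean_theta)
  expect_error(key_feature_stats(numeric(0), sc), "empty")
  # raw per-triangle values override midpoints, and the constructed
  # ordering (common keys built with larger theta) is reflected
  s <- make_coil(10, seed = 2)
  tr <- tsr_triangles(s, sc)
  top <- tr$key[tr$theta > stats::median(tr$theta)]
  bot <- tr$key[tr$theta <= stats::median(tr$theta)]
  st_top <- key_feature_stats(top, sc, triangles = tr)
  st_bot <- key_feature_stats(bot, sc, triangles = tr)
  expect_gt(st_top$mean_theta, st_bot$mean_theta)
  # mean frequency from a key vector
  kv <- make_kv(c(1, 2), c(4, 2), id = "f")
  expect_equal(key_feature_stats(c(1, 2), sc, counts = kv)$mean_frequency, 3)
})

test_that("motif matching tolerates +-1 Theta bins without digit wrap", {
  sc <- default_bin_scheme()
  kv <- make_kv(1683886, 1, id = "x")  # (4,4,4,1,2)
  hit <- match_motif(kv, 1683885, tolerance = 1, scheme = sc)
  expect_true(hit$matched)
  expect_true(attr(hit, "all_present"))
  # same labels and MaxDist, Theta two bins away: no match at tolerance 1
  kv3 <- make_kv(encode_key(4, 4, 4, 1, 3, sc), 1, id = "y")
  expect_false(match_motif(kv3, 1683885, tolerance = 1, scheme = sc)$matched)
  # tolerance 0 is exact membership
  expect_true(match_motif(kv, 1683886, tolerance = 0, scheme = sc)$matched)
  expect_false(match_motif(kv, 1683885, tolerance = 0, scheme = sc)$matched)
  # signs must agree
  kvm <- make_kv(-1683886, 1, id = "m", mirror = TRUE)
  expect_false(match_motif(kvm, 1683886, tolerance = 1, scheme = sc)$matched)
  expect_true(match_motif(kvm, -1683885, tolerance = 1, scheme = sc)$matched)
})

test_that("raw +-1 matching agrees with decoded mode except at Theta digit wrap", {
  tiny <- structure(list(theta_breaks = c(30, 60), maxdist_breaks = 10,
                         theta_bins = 3L, maxdist_bins = 2L, m = 2L),
                    class = "bin_scheme")
  space <- 3 * 2 * 2^3 - 1
  mismatch <- 0
  for (vk in 0:space) {
    kv <- make_kv(vk, 1, id = "v")
    for (qk in 0:space) {
      raw <- match_motif(kv, qk, tolerance = 1, scheme = tiny,
                         mode = "raw")$matched
      dec <- match_motif(kv, qk, tolerance = 1, scheme = tiny,
                         mode = "theta_bin")$matched
      if (raw != dec) {
        mismatch <- mismatch + 1
        # disagreement only where the raw +-1 step crosses a digit boundary,
        # i.e. one of the two keys sits at theta_bin 1 or theta_bins
        tb <- decode_key(c(vk, qk), tiny)$theta_bin
        expect_true(any(tb %in% c(1L, tiny$theta_bins)))
      }
    }
  }
  expect_gt(mismatch, 0)  # the wrap cases exist and are the only differences
})

test_that("mirror pair analysis flags sign-separated classes", {
  va1 <- make_kv(c(10, 20), c(1, 1), id = "a1", mirror = TRUE)
  va2 <- make_kv(c(10, 30), c(1, 1), id = "a2", mirror = TRUE)
  vb1 <- make_kv(c(-10, 20), c(1, 1), id = "b1", mirror = TRUE)
  vb2 <- make_kv(c(-10, -30), c(2, 1), id = "b2", mirror = TRUE)
  res <- mirror_pair_analysis(list(a1 = va1, a2 = va2, b1 = vb1, b2 = vb2),
                              c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  expect_true(10 %in% res$flagged)    # +10 in A, -10 in B
  expect_false(20 %in% res$flagged)   # +20 in both classes
  expect_true(30 %in% res$flagged)
  # a key carried with both signs inside one class is never flagged
  vmix <- make_kv(c(10, -10), c(1, 1), id = "mix", mirror = TRUE)
  res2 <- mirror_pair_analysis(list(a1 = va1, mix = vmix, b1 = vb1),
                               c(a1 = "A", mix = "A", b1 = "B"))
  expect_false(10 %in% res2$flagged)
  expect_error(mirror_pair_analysis(list(a1 = make_kv(1, 1, id = "x")),
                                    c(x = "A")), "mirror")
})

test_that("planted mirror-image motifs are flagged across classes", {
  sc <- default_bin_scheme()
  motif <- stable_motif()
  th <- triangle_geometry(motif$coords)$theta1
  build <- function(seed, theta) {
    s <- make_coil(10, seed = seed)
    tri <- make_motif_triangle(theta, motif$maxdist, motif$maxdist / 3)
    s <- plant_motif(s, tri, motif$aa3, 1:3, seed = seed + 5)
    tsr_keys(s, sc, mirror = TRUE)
  }
  vs <- c(lapply(1:3, build, theta = th),
          lapply(4:6, build, theta = 180 - th))
  names(vs) <- paste0("s", 1:6)
  res <- mirror_pair_analysis(vs, stats::setNames(rep(c("A", "B"), each = 3),
                                                  names(vs)))
  mk <- motif_key()
  expect_true(abs(mk) %in% res$flagged)
})
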