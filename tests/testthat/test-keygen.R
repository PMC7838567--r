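sc <- default_bin_scheme()

test_that("vertex ordering follows the rule-based label determination", {
  # distinct labels: descending label order
  o <- order_vertices(c(7, 19, 12), rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)),
                      0:2)
  expect_equal(o$labels, c(19, 12, 7))
  # two tied labels: greater distance to the remaining vertex goes first
  o <- order_vertices(c(12, 12, 7),
                      rbind(c(-6, 0, 0), c(4, 0, 0), c(0, 0, 0)), 0:2)
  expect_equal(o$order, c(1L, 2L, 3L))
  o <- order_vertices(c(12, 12, 7),
                      rbind(c(4, 0, 0), c(-6, 0, 0), c(0, 0, 0)), 0:2)
  expect_equal(o$order, c(2L, 1L, 3L))
  # all labels equal on an equilateral triangle: ascending seq_index
  eq <- rbind(c(0, 0, 0), c(2, 0, 0), c(1, sqrt(3), 0))
  o <- order_vertices(c(9, 9, 9), eq, c(5L, 2L, 7L))
  expect_equal(o$order, c(2L, 1L, 3L))
  expect_error(order_vertices(c(1, 2, 3), rbind(c(0, 0, 0), c(0, 0, 0),
                                                c(1, 0, 0)), 0:2),
               "degenerate")
})

test_that("vertex ordering is frame-independent", {
  for (seed in 1:25) {
    coords <- withr::with_seed(seed, matrix(stats::rnorm(9, sd = 5), 3))
    labels <- withr::with_seed(seed + 50, sample(4:23, 3, replace = TRUE))
    o1 <- order_vertices(labels, coords, 0:2)
    s <- ca_structure(tibble::tibble(aa3 = "ALA", label = labels,
                                     x = coords[, 1], y = coords[, 2],
                                     z = coords[, 3]), id = "x")
    s2 <- rigid_move(s, seed = seed + 99)
    o2 <- order_vertices(labels, ca_coords(s2), 0:2)
    expect_equal(o1$order, o2$order)
  }
})

test_that("triangle geometry matches the closed-form cases", {
  g <- triangle_geometry(rbind(c(0, 0, 0), c(2, 0, 0), c(1, sqrt(3), 0)))
  expect_equal(g$theta1, 90, tolerance = 1e-12)
  expect_equal(g$theta, 90, tolerance = 1e-12)
  expect_equal(g$maxdist, 2)
  expect_equal(g$d3, sqrt(3), tolerance = 1e-12)
  g <- triangle_geometry(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 1, 0)))
  expect_equal(g$theta1, 135, tolerance = 1e-12)
  expect_equal(g$theta, 45, tolerance = 1e-12)
  expect_equal(g$maxdist, sqrt(5))  # longest edge is the l2-l3 one here
  expect_error(triangle_geometry(rbind(c(0, 0, 0), c(2, 0, 0), c(1, 0, 0))),
               "degenerate")
})

test_that("theta agrees with an independent vector-angle oracle", {
  worst <- 0
  for (seed in 1:500) {
    coords <- withr::with_seed(seed, matrix(stats::rnorm(9, sd = 8), 3))
    g <- triangle_geometry(coords)
    worst <- max(worst, abs(g$theta - theta_oracle(coords)))
  }
  expect_lt(worst, 1e-9)
})

test_that("key encoding matches the positional formula and decodes exactly", {
  expect_equal(encode_key(4, 4, 4, 1, 1, sc), 1683885)
  expect_equal(encode_key(4, 4, 4, 1, 2, sc), 1683886)
  expect_equal(encode_key(1, 1, 1, 1, 1, sc), 0)
  expect_equal(decode_key(0, sc)[, -(1:2)],
               tibble::tibble(l1 = 1L, l2 = 1L, l3 = 1L, d_bin = 1L,
                              theta_bin = 1L))
  d <- decode_key(1683885, sc)
  expect_equal(unlist(d[, c("l1", "l2", "l3", "d_bin", "theta_bin")],
                      use.names = FALSE), c(4L, 4L, 4L, 1L, 1L))
  expect_error(encode_key(24, 1, 1, 1, 1, sc), "labels")
  expect_error(encode_key(4, 4, 4, 36, 1, sc), "d_bin")
  expect_error(decode_key(sc$theta_bins * sc$maxdist_bins * sc$m^3, sc),
               "range")
})

test_that("encode/decode round-trips on a random sample of the digit space", {
  n <- 20000
  dig <- withr::with_seed(7, tibble::tibble(
    l1 = sample.int(23, n, TRUE), l2 = sample.int(23, n, TRUE),
    l3 = sample.int(23, n, TRUE), d_bin = sample.int(35, n, TRUE),
    theta_bin = sample.int(29, n, TRUE)))
  k <- encode_key(dig$l1, dig$l2, dig$l3, dig$d_bin, dig$theta_bin, sc)
  dec <- decode_key(k, sc)
  expect_equal(dec[, c("l1", "l2", "l3", "d_bin", "theta_bin")],
               dig, ignore_attr = TRUE)
  expect_equal(encode_key(dec$l1, dec$l2, dec$l3, dec$d_bin, dec$theta_bin,
                          sc), k)
})

test_that("all triangles are enumerated and degenerate ones counted", {
  s <- make_coil(5, seed = 3)
  kv <- tsr_keys(s, sc)
  expect_equal(sum(kv$count), 10L)
  expect_equal(attr(kv, "skipped_degenerate"), 0L)
  # three equally spaced collinear residues with the smallest label in the
  # middle: after ordering, l3 sits at the midpoint of l1-l2, so d3 = 0
  col3 <- ca_structure(tibble::tibble(aa3 = c("SER", "ALA", "GLY"),
                                      x = c(0, 3.8, 7.6), y = 0, z = 0),
                       id = "col")
  kv <- tsr_keys(col3, sc)
  expect_equal(nrow(kv), 0L)
  expect_equal(attr(kv, "skipped_degenerate"), 1L)
  expect_error(tsr_keys(trim_structure(col3, 0, 1), sc), "at least 3")
  # conservation across sizes
  for (n in c(3, 7, 12, 20)) {
    kvn <- tsr_keys(make_coil(n, seed = n), sc)
    expect_equal(sum(kvn$count) + attr(kvn, "skipped_degenerate"),
                 choose(n, 3))
  }
})

test_that("keys are invariant under rigid motion and residue reordering", {
  for (seed in 1:10) {
    s <- make_coil(12, seed = seed)
    kv <- tsr_keys(s, sc)
    expect_equal(as.data.frame(tsr_keys(rigid_move(s, seed + 77), sc)),
                 as.data.frame(kv))
    cut <- 1 + (seed %% 10)
    expect_equal(as.data.frame(tsr_keys(rearrange(s, cut), sc)),
                 as.data.frame(kv))
  }
})

test_that("reflection leaves keys invariant; apex-mirrored triangles flip sign", {
  # reflection is an isometry: theta1 depends only on distances, so even
  # mirror-signed key multisets are unchanged
  s <- make_coil(12, seed = 21)
  expect_equal(as.data.frame(tsr_keys(reflect(s), sc, mirror = TRUE)),
               as.data.frame(tsr_keys(s, sc, mirror = TRUE)))
  # the mirror-image pair of one triangle: theta1 and 180 - theta1 share the
  # folded Theta bin but take opposite signs
  for (th in c(25, 40, 62, 89)) {
    t1 <- plant_motif(make_coil(3, seed = 2), make_motif_triangle(th, 9),
                      c("SER", "HIS", "ASP"), 1:3, place = FALSE)
    t2 <- plant_motif(make_coil(3, seed = 2), make_motif_triangle(180 - th, 9),
                      c("SER", "HIS", "ASP"), 1:3, place = FALSE)
    k1 <- tsr_triangles(t1, sc, mirror = TRUE)
    k2 <- tsr_triangles(t2, sc, mirror = TRUE)
    expect_equal(k1$theta, k2$theta, tolerance = 1e-9)
    expect_equal(k1$key, -k2$key)
    expect_gt(k1$key, 0)
  }
  # theta1 of exactly 90 degrees keeps the positive sign
  t90 <- plant_motif(make_coil(3, seed = 2), make_motif_triangle(90, 9),
                     c("SER", "HIS", "ASP"), 1:3, place = FALSE)
  expect_gt(tsr_triangles(t90, sc, mirror = TRUE)$key, 0)
})

test_that("scaling changes MaxDist bins but not Theta", {
  s <- make_coil(10, seed = 8)
  t1 <- tsr_triangles(s, sc)
  s2 <- s
  s2$x <- s$x * 2; s2$y <- s$y * 2; s2$z <- s$z * 2
  t2 <- tsr_triangles(s2, sc)
  expect_equal(t2$theta, t1$theta, tolerance = 1e-9)
  expect_equal(t2$theta_bin, t1$theta_bin)
  expect_equal(t2$maxdist, 2 * t1$maxdist, tolerance = 1e-9)
  expect_false(all(t2$d_bin == t1$d_bin))
  expect_false(all(t2$key == t1$key))
})

test_that("key files round-trip with their metadata", {
  kv <- tsr_keys(make_helix(8, seed = 1), sc, mirror = TRUE)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_keys(kv, f)
  kv2 <- read_keys(f)
  expect_equal(as.data.frame(kv2), as.data.frame(kv))
  expect_equal(attr(kv2, "protein_id"), attr(kv, "protein_id"))
  expect_true(attr(kv2, "mirror"))
  expect_equal(attr(kv2, "theta_bins"), 29L)
  expect_equal(attr(kv2, "m"), 23L)
})
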