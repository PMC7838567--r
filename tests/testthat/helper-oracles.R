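# Shared fixtures and independent oracles for the test suite.

# construct a key vector directly (bypasses key generation)
make_kv <- function(keys, counts, id = "p", mirror = FALSE) {
  df <- tibble::tibble(key = as.numeric(keys), count = as.integer(counts))
  attr(df, "protein_id") <- id
  attr(df, "n_triangles") <- sum(df$count)
  attr(df, "skipped_degenerate") <- 0L
  attr(df, "mirror") <- mirror
  class(df) <- c("tsr_keyvec", class(tibble::tibble()))
  df
}

random_kv <- function(seed, id = paste0("p", seed), pool = 1:120,
                      n_keys = 25, max_count = 6) {
  withr::with_seed(seed, {
    keys <- sample(pool, min(n_keys, length(pool)))
    make_kv(sort(keys), sample.int(max_count, length(keys), replace = TRUE),
            id = id)
  })
}

# brute-force multiset Jaccard: expand to explicit multisets and count
# per-key occurrences by direct comparison
jaccard_oracle <- function(a, b) {
  xa <- rep(a$key, a$count)
  xb <- rep(b$key, b$count)
  keys <- unique(c(xa, xb))
  inter <- sum(vapply(keys, function(k) min(sum(xa == k), sum(xb == k)),
                      numeric(1)))
  uni <- sum(vapply(keys, function(k) max(sum(xa == k), sum(xb == k)),
                    numeric(1)))
  inter / uni
}

# independent vector-angle oracle: angle at the midpoint of the l1-l2 edge
# between the directions to l2 and to l3, folded into (0, 90]
theta_oracle <- function(coords) {
  m <- (coords[1, ] + coords[2, ]) / 2
  u <- coords[2, ] - m
  v <- coords[3, ] - m
  ang <- acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
  if (ang > 90) 180 - ang else ang
}

# exhaustive Venn region oracle over explicit key sets
venn_oracle <- function(key_sets) {
  all_keys <- sort(unique(unlist(key_sets)))
  pat <- vapply(all_keys, function(k) {
    paste(names(key_sets)[vapply(key_sets, function(s) k %in% s, logical(1))],
          collapse = "+")
  }, character(1))
  tab <- table(pat)
  tibble::tibble(region = names(tab), n = as.integer(tab))
}

# a motif triangle centred in wide default-scheme bins, so that small
# coordinate jitter cannot move it across a Theta or MaxDist boundary
stable_motif <- function(scheme = default_bin_scheme()) {
  widest_mid <- function(breaks, lo_cap, hi_cap) {
    edges <- c(lo_cap, breaks, hi_cap)
    w <- diff(edges)
    i <- which.max(w)
    (edges[i] + edges[i + 1]) / 2
  }
  theta <- widest_mid(scheme$theta_breaks, 0, 90)
  # interior MaxDist bin (skip the open-ended last bin)
  me <- c(0, scheme$maxdist_breaks)
  w <- diff(me)
  i <- which.max(w)
  maxdist <- (me[i] + me[i + 1]) / 2
  list(coords = make_motif_triangle(theta, maxdist, d3 = maxdist / 3),
       theta = theta, maxdist = maxdist,
       aa3 = c("SER", "HIS", "ASP"))  # labels 19 > 12 > 7: base l1, l2, apex
}

# plant the stable motif into a random coil at random positions with
# per-coordinate jitter <= jit
planted_structure <- function(seed, n = 20, jit = 0.05, motif = stable_motif()) {
  s <- make_coil(n, seed = seed)
  pos <- withr::with_seed(seed + 1000L, sort(sample.int(n, 3)))
  coords <- motif$coords +
    withr::with_seed(seed + 2000L, matrix(stats::runif(9, -jit, jit), 3))
  plant_motif(s, coords, motif$aa3, pos, seed = seed + 3000L)
}

motif_key <- function(motif = stable_motif(), scheme = default_bin_scheme()) {
  s <- plant_motif(make_coil(3, seed = 1), motif$coords, motif$aa3, 1:3,
                   place = FALSE)
  tsr_triangles(s, scheme)$key
}
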