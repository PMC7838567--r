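#' Encode and decode triangle keys
#'
#' A triangle is reduced to five digits: its three ordered amino-acid labels
#' `l1 >= l2 >= l3` (ordering by [order_vertices()]), the MaxDist bin `d_bin`
#' and the Theta bin `theta_bin`. The key treats these as digits of a mixed
#' positional number system with Theta as the lowest-order digit:
#'
#' \deqn{k = \theta_T d_T (l_1 - 1) m^2 + \theta_T d_T (l_2 - 1) m +
#'       \theta_T d_T (l_3 - 1) + \theta_T (d - 1) + (\theta - 1)}
#'
#' where `m` is the label-alphabet size and `theta_T`, `d_T` the bin counts.
#' The map is one-to-one and onto `0 .. theta_T * d_T * m^3 - 1`, so
#' `decode_key()` recovers the digits exactly by successive quotient and
#' remainder. Keys differing only by one Theta bin differ by exactly 1.
#'
#' @param l1,l2,l3 Integer labels in `1..m` (vectorized).
#' @param d_bin MaxDist bin in `1..maxdist_bins`.
#' @param theta_bin Theta bin in `1..theta_bins`.
#' @param scheme A [bin_scheme].
#' @return `encode_key()`: non-negative numeric keys (exact integers).
#'   `decode_key()`: a tibble with columns `key`, `sign`, `l1`, `l2`, `l3`,
#'   `d_bin`, `theta_bin`; signed (mirror-mode) keys are decoded from their
#'   magnitude with the sign reported separately.
#' @examples
#' sc <- default_bin_scheme()
#' k <- encode_key(4, 4, 4, 1, 1, sc)
#' decode_key(k, sc)
#' @export
encode_key <- function(l1, l2, l3, d_bin, theta_bin, scheme) {
  m <- scheme$m; tT <- scheme$theta_bins; dT <- scheme$maxdist_bins
  if (any(l1 < 1 | l1 > m) || any(l2 < 1 | l2 > m) || any(l3 < 1 | l3 > m)) {
    abort("labels out of 1..m.")
  }
  if (any(d_bin < 1 | d_bin > dT)) abort("d_bin out of range.")
  if (any(theta_bin < 1 | theta_bin > tT)) abort("theta_bin out of range.")
  tT * dT * ((l1 - 1) * m^2 + (l2 - 1) * m + (l3 - 1)) +
    tT * (d_bin - 1) + (theta_bin - 1)
}

#' @rdname encode_key
#' @param key Numeric key vector (signed keys allowed).
#' @export
decode_key <- function(key, scheme) {
  m <- scheme$m; tT <- scheme$theta_bins; dT <- scheme$maxdist_bins
  a <- abs(key)
  if (any(a >= tT * dT * m^3) || any(a != floor(a))) {
    abort("key outside the encodable range.")
  }
  theta_bin <- a %% tT + 1
  q <- a %/% tT
  d_bin <- q %% dT + 1
  q <- q %/% dT
  l3 <- q %% m + 1
  q <- q %/% m
  l2 <- q %% m + 1
  l1 <- q %/% m + 1
  tibble(key = key, sign = ifelse(key < 0, -1L, 1L),
         l1 = as.integer(l1), l2 = as.integer(l2), l3 = as.integer(l3),
         d_bin = as.integer(d_bin), theta_bin = as.integer(theta_bin))
}

#' Canonical vertex ordering for one triangle
#'
#' Deterministic rule-based label determination, so identical triangles get
#' identical keys in any protein and any coordinate frame: (a) if all three
#' labels are distinct, `l1` is the largest and `l3` the smallest; (b) if
#' exactly two labels tie, the tied pair is ranked by distance to the
#' remaining vertex (greater distance earlier); (c) if all three tie, the
#' vertices are ranked by their longest incident edge, then their shortest,
#' descending. Any residual exact tie falls back to ascending sequence
#' index; at that point the tied vertices are geometrically interchangeable
#' (the triangle has an internal symmetry), so the fallback never affects
#' the resulting descriptor. The ordering
#' depends only on labels and pairwise distances (plus `seq_index` for exact
#' ties), never on the coordinate frame.
#'
#' @param labels Integer vector of length 3.
#' @param coords 3 x 3 matrix of vertex coordinates (rows are vertices).
#' @param seq_indices Integer vector of length 3 (distinct).
#' @return A list with `order` (permutation putting the vertices into
#'   positions l1, l2, l3) and `labels` (the ordered labels).
#' @export
order_vertices <- function(labels, coords, seq_indices) {
  d <- as.matrix(dist(coords))
  if (min(d[upper.tri(d)]) < 1e-9) {
    abort("degenerate triangle: coincident vertices.")
  }
  o <- order_vertices_vec(labels[1], labels[2], labels[3],
                          d[1, 2], d[1, 3], d[2, 3],
                          seq_indices[1], seq_indices[2], seq_indices[3])
  ord <- c(o$o1, o$o2, o$o3)
  list(order = ord, labels = labels[ord])
}

# Vectorized canonical ordering over triangles with vertices A, B, C.
# Returns positions o1,o2,o3 as 1/2/3 selecting among (A,B,C).
order_vertices_vec <- function(la, lb, lc, dab, dac, dbc, sa, sb, sc) {
  eAB <- la == lb; eAC <- la == lc; eBC <- lb == lc
  all_eq <- eAB & eAC
  two_ab <- eAB & !all_eq
  two_ac <- eAC & !all_eq
  two_bc <- eBC & !all_eq
  # secondary score: tied pair -> distance to the remaining vertex;
  # three-way tie -> longest incident edge; otherwise 0
  SA <- ifelse(all_eq, pmax(dab, dac), ifelse(two_ab, dac, ifelse(two_ac, dab, 0)))
  SB <- ifelse(all_eq, pmax(dab, dbc), ifelse(two_ab, dbc, ifelse(two_bc, dab, 0)))
  SC <- ifelse(all_eq, pmax(dac, dbc), ifelse(two_ac, dbc, ifelse(two_bc, dac, 0)))
  # tertiary score (three-way ties only): shortest incident edge. After this,
  # any residual tie is a genuinely symmetric triangle whose descriptor is
  # invariant under the swap, so the seq_index fallback cannot change the key
  TA <- ifelse(all_eq, pmin(dab, dac), 0)
  TB <- ifelse(all_eq, pmin(dab, dbc), 0)
  TC <- ifelse(all_eq, pmin(dac, dbc), 0)
  better <- function(Lu, Lv, Su, Sv, Tu, Tv, su, sv) {
    Lu > Lv | (Lu == Lv & (Su > Sv | (Su == Sv &
      (Tu > Tv | (Tu == Tv & su < sv)))))
  }
  bAB <- better(la, lb, SA, SB, TA, TB, sa, sb)
  bAC <- better(la, lc, SA, SC, TA, TC, sa, sc)
  bBC <- better(lb, lc, SB, SC, TB, TC, sb, sc)
  scoreA <- bAB + bAC
  scoreB <- (!bAB) + bBC
  scoreC <- (!bAC) + (!bBC)
  pick <- function(score_target) {
    ifelse(scoreA == score_target, 1L, ifelse(scoreB == score_target, 2L, 3L))
  }
  list(o1 = pick(2L), o2 = pick(1L), o3 = pick(0L))
}

#' Geometry of an ordered triangle
#'
#' Given the vertices already in canonical order (positions l1, l2, l3),
#' computes the edge lengths, `d3` (distance from the l3 vertex to the
#' midpoint of the l1-l2 edge), MaxDist (the longest edge) and the angles:
#'
#' \deqn{\theta_1 = \arccos\left(\frac{d_{13}^2 - (d_{12}/2)^2 - d_3^2}
#'       {2 (d_{12}/2) d_3}\right)}
#'
#' with the arccos argument clamped to \[-1, 1\] against floating-point
#' error, and `theta` the fold of `theta1` into (0, 90]
#' (`180 - theta1` when `theta1 > 90`). `theta1` equals the angle at the
#' midpoint of the l1-l2 edge between the directions to l2 and to l3.
#'
#' @param coords 3 x 3 matrix of ordered vertex coordinates.
#' @return A named list: `d12`, `d13`, `d23`, `d3`, `maxdist`, `theta1`,
#'   `theta` (degrees).
#' @export
triangle_geometry <- function(coords) {
  p1 <- coords[1, ]; p2 <- coords[2, ]; p3 <- coords[3, ]
  d12 <- sqrt(sum((p1 - p2)^2))
  d13 <- sqrt(sum((p1 - p3)^2))
  d23 <- sqrt(sum((p2 - p3)^2))
  d3 <- sqrt(sum((p3 - (p1 + p2) / 2)^2))
  if (d12 < 1e-9 || d3 < 1e-9) abort("degenerate triangle.")
  arg <- (d13^2 - (d12 / 2)^2 - d3^2) / (2 * (d12 / 2) * d3)
  theta1 <- acos(pmin(1, pmax(-1, arg))) * 180 / pi
  list(d12 = d12, d13 = d13, d23 = d23, d3 = d3,
       maxdist = max(d12, d13, d23),
       theta1 = theta1,
       theta = if (theta1 > 90 + 1e-9) 180 - theta1 else theta1)
}

#' Per-triangle descriptors of a structure
#'
#' Enumerates all `choose(n, 3)` C-alpha triples, orders each triple's
#' vertices canonically, computes geometry, assigns Theta/MaxDist bins and
#' encodes the key. With `mirror = TRUE`, keys of triangles with
#' `theta1 > 90` degrees get a negative sign, distinguishing a triangle from
#' its mirror image; `theta1` within 1e-9 degrees of 90 counts as 90 and
#' stays positive, so exactly right-angled triangles (common in idealized
#' geometry) cannot flip branch under floating-point jitter. Degenerate triangles
#' (coincident vertices, or `d12`/`d3` below 1e-9 A) are skipped and
#' counted, not keyed.
#'
#' @param s A [ca_structure] with at least 3 residues.
#' @param scheme A [bin_scheme].
#' @param mirror Sign keys by chirality?
#' @param grouping Optional amino-acid grouping (data frame `aa3`, `group`
#'   or named vector old label -> group label) applied to the labels before
#'   vertex ordering.
#' @param ss_filter `"none"`, `"iess"` (all three residues in helix or
#'   strand segments, possibly different ones) or `"iass"` (see
#'   `iass_mode`). Filtering happens before geometry, so filtered triangles
#'   are neither keyed nor counted as degenerate.
#' @param iass_mode `"segment"`: all three residues in one single
#'   secondary-structure segment (the default, strictly intra-segment);
#'   `"type"`: all three share one secondary-structure type across any
#'   segments. Both give key sets contained in the IESS set.
#' @return A tibble with one row per kept triangle: 0-based residue indices
#'   `pos0`, `pos1`, `pos2` (canonical positions l1, l2, l3), labels,
#'   edge lengths, `d3`, `maxdist`, `theta1`, `theta`, bins and `key`.
#'   Attributes: `skipped_degenerate`, `n_candidates`.
#' @examples
#' s <- make_helix(6, seed = 1)
#' tsr_triangles(s, default_bin_scheme())
#' @export
tsr_triangles <- function(s, scheme, mirror = FALSE, grouping = NULL,
                          ss_filter = c("none", "iess", "iass"),
                          iass_mode = c("segment", "type")) {
  ss_filter <- match.arg(ss_filter)
  iass_mode <- match.arg(iass_mode)
  n <- nrow(s)
  if (n < 3) abort("need at least 3 residues.")
  labels <- apply_grouping_labels(s, grouping)
  if (any(labels > scheme$m)) abort("labels exceed scheme m.")

  tri <- t(combn(n, 3L))
  A <- tri[, 1L]; B <- tri[, 2L]; C <- tri[, 3L]

  if (ss_filter != "none") {
    keep <- ss_triple_keep(s, A, B, C, ss_filter, iass_mode)
    A <- A[keep]; B <- B[keep]; C <- C[keep]
  }
  n_cand <- length(A)
  empty <- tibble(pos0 = integer(), pos1 = integer(), pos2 = integer(),
                  l1 = integer(), l2 = integer(), l3 = integer(),
                  d12 = numeric(), d13 = numeric(), d23 = numeric(),
                  d3 = numeric(), maxdist = numeric(),
                  theta1 = numeric(), theta = numeric(),
                  d_bin = integer(), theta_bin = integer(), key = numeric())
  if (n_cand == 0) {
    attr(empty, "skipped_degenerate") <- 0L
    attr(empty, "n_candidates") <- 0L
    return(empty)
  }

  cm <- ca_coords(s)
  D <- as.matrix(dist(cm))
  dab <- D[cbind(A, B)]; dac <- D[cbind(A, C)]; dbc <- D[cbind(B, C)]

  o <- order_vertices_vec(labels[A], labels[B], labels[C],
                          dab, dac, dbc,
                          s$seq_index[A], s$seq_index[B], s$seq_index[C])
  vert <- cbind(A, B, C)
  o1 <- vert[cbind(seq_len(n_cand), o$o1)]
  o2 <- vert[cbind(seq_len(n_cand), o$o2)]
  o3 <- vert[cbind(seq_len(n_cand), o$o3)]

  d12 <- D[cbind(o1, o2)]
  d13 <- D[cbind(o1, o3)]
  d23 <- D[cbind(o2, o3)]
  mid <- (cm[o1, , drop = FALSE] + cm[o2, , drop = FALSE]) / 2
  d3 <- sqrt(rowSums((cm[o3, , drop = FALSE] - mid)^2))

  degenerate <- pmin(dab, dac, dbc) < 1e-9 | d12 < 1e-9 | d3 < 1e-9
  n_skip <- sum(degenerate)
  if (n_skip > 0) {
    ok <- !degenerate
    o1 <- o1[ok]; o2 <- o2[ok]; o3 <- o3[ok]
    d12 <- d12[ok]; d13 <- d13[ok]; d23 <- d23[ok]; d3 <- d3[ok]
  }
  if (length(o1) == 0) {
    attr(empty, "skipped_degenerate") <- n_skip
    attr(empty, "n_candidates") <- n_cand
    return(empty)
  }

  arg <- (d13^2 - (d12 / 2)^2 - d3^2) / (2 * (d12 / 2) * d3)
  theta1 <- acos(pmin(1, pmax(-1, arg))) * 180 / pi
  # 1e-9 degree band at 90: exactly right-angled (isoceles d13 = d23)
  # triangles must not flip branch under floating-point jitter
  obtuse <- theta1 > 90 + 1e-9
  theta <- ifelse(obtuse, 180 - theta1, theta1)
  maxdist <- pmax(d12, d13, d23)
  d_bin <- assign_bin(maxdist, scheme$maxdist_breaks)
  theta_bin <- assign_bin(theta, scheme$theta_breaks)
  key <- encode_key(labels[o1], labels[o2], labels[o3], d_bin, theta_bin, scheme)
  if (mirror) key <- ifelse(obtuse, -key, key)

  out <- tibble(
    pos0 = s$seq_index[o1], pos1 = s$seq_index[o2], pos2 = s$seq_index[o3],
    l1 = as.integer(labels[o1]), l2 = as.integer(labels[o2]),
    l3 = as.integer(labels[o3]),
    d12 = d12, d13 = d13, d23 = d23, d3 = d3, maxdist = maxdist,
    theta1 = theta1, theta = theta,
    d_bin = as.integer(d_bin), theta_bin = as.integer(theta_bin), key = key)
  attr(out, "skipped_degenerate") <- n_skip
  attr(out, "n_candidates") <- n_cand
  out
}

apply_grouping_labels <- function(s, grouping) {
  labels <- s$label
  if (is.null(grouping)) return(labels)
  if (is.data.frame(grouping)) {
    idx <- match(s$aa3, toupper(grouping$aa3))
    hit <- !is.na(idx)
    labels[hit] <- as.integer(grouping$group[idx[hit]])
  } else {
    idx <- match(as.character(labels), names(grouping))
    hit <- !is.na(idx)
    labels[hit] <- as.integer(grouping[idx[hit]])
  }
  labels
}

#' Key-frequency vector of a structure
#'
#' Runs [tsr_triangles()] and tallies key occurrence counts: the multiset of
#' keys that represents the structure for similarity computation. Without a
#' secondary-structure filter, `sum(count) + skipped_degenerate` equals
#' `choose(n, 3)`.
#'
#' @inheritParams tsr_triangles
#' @param id Protein identifier stored on the vector; defaults to the
#'   structure id.
#' @return A tibble of class `tsr_keyvec` with columns `key` and `count`,
#'   sorted by key. Attributes: `protein_id`, `n_triangles` (sum of counts),
#'   `skipped_degenerate`, `mirror`, and the scheme digit sizes
#'   (`theta_bins`, `maxdist_bins`, `m`) for later decoding.
#' @examples
#' kv <- tsr_keys(make_helix(8, seed = 1), default_bin_scheme())
#' sum(kv$count)  # choose(8, 3) = 56
#' @export
tsr_keys <- function(s, scheme, mirror = FALSE, grouping = NULL,
                     ss_filter = c("none", "iess", "iass"),
                     iass_mode = c("segment", "type"),
                     id = structure_id(s)) {
  tr <- tsr_triangles(s, scheme, mirror = mirror, grouping = grouping,
                      ss_filter = ss_filter, iass_mode = iass_mode)
  out <- tr %>% count(.data$key, name = "count") %>% arrange(.data$key)
  new_keyvec(out, id = id,
             skipped = attr(tr, "skipped_degenerate"),
             mirror = mirror, scheme = scheme)
}

new_keyvec <- function(df, id, skipped = 0L, mirror = FALSE, scheme = NULL) {
  df <- tibble(key = as.numeric(df$key), count = as.integer(df$count))
  attr(df, "protein_id") <- id
  attr(df, "n_triangles") <- sum(df$count)
  attr(df, "skipped_degenerate") <- as.integer(skipped)
  attr(df, "mirror") <- mirror
  if (!is.null(scheme)) {
    attr(df, "theta_bins") <- scheme$theta_bins
    attr(df, "maxdist_bins") <- scheme$maxdist_bins
    attr(df, "m") <- scheme$m
  }
  class(df) <- c("tsr_keyvec", class(tibble()))
  df
}

#' @export
print.tsr_keyvec <- function(x, ...) {
  cat("<tsr_keyvec>", attr(x, "protein_id"), "-", nrow(x), "distinct keys,",
      attr(x, "n_triangles"), "triangles",
      if (isTRUE(attr(x, "mirror"))) "(mirror-signed)" else "", "\n")
  NextMethod()
}

#' @export
glance.tsr_keyvec <- function(x, ...) {
  tibble(protein_id = attr(x, "protein_id"),
         n_distinct_keys = nrow(x),
         n_triangles = attr(x, "n_triangles"),
         skipped_degenerate = attr(x, "skipped_degenerate"),
         mirror = isTRUE(attr(x, "mirror")))
}

#' Read and write key files
#'
#' Key files are TSV with comment header lines starting with `#` (carrying
#' the protein id and run configuration) and columns `key`, `count`.
#' `write_keys()` with `verbose = TRUE` additionally writes a
#' `<path>.triangles.tsv` companion with per-triangle rows (decoded digits,
#' canonical vertex positions, theta, maxdist) when given the triangle
#' table.
#'
#' @param kv A `tsr_keyvec`.
#' @param path Output path.
#' @param extra_header Additional `#` header lines (provenance).
#' @param triangles Optional [tsr_triangles()] tibble for verbose output.
#' @export
write_keys <- function(kv, path, extra_header = character(0), triangles = NULL) {
  hdr <- c(paste0("# protein_id=", attr(kv, "protein_id")),
           paste0("# n_triangles=", attr(kv, "n_triangles")),
           paste0("# skipped_degenerate=", attr(kv, "skipped_degenerate")),
           paste0("# mirror=", isTRUE(attr(kv, "mirror"))),
           paste0("# theta_bins=", attr(kv, "theta_bins"),
                  " maxdist_bins=", attr(kv, "maxdist_bins"),
                  " m=", attr(kv, "m")),
           extra_header)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("key\tcount", con)
  writeLines(sprintf("%s\t%d", format(kv$key, scientific = FALSE, trim = TRUE),
                     kv$count), con)
  if (!is.null(triangles)) {
    tp <- paste0(path, ".triangles.tsv")
    utils::write.table(triangles, tp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_keys
#' @export
read_keys <- function(path) {
  ln <- readLines(path)
  hdr <- ln[grepl("^#", ln)]
  get <- function(name, default = NA) {
    hit <- grep(paste0("^# ", name, "="), hdr, value = TRUE)
    if (length(hit) == 0) return(default)
    sub(paste0("^# ", name, "="), "", hit[1])
  }
  body <- ln[!grepl("^#", ln)]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t")
  scheme_line <- grep("^# theta_bins=", hdr, value = TRUE)
  sc <- NULL
  kv <- new_keyvec(df, id = get("protein_id", "unknown"),
                   skipped = as.integer(get("skipped_degenerate", 0)),
                   mirror = identical(get("mirror", "FALSE"), "TRUE"))
  if (length(scheme_line) == 1) {
    nums <- as.integer(regmatches(scheme_line,
                                  gregexpr("[0-9]+", scheme_line))[[1]])
    attr(kv, "theta_bins") <- nums[1]
    attr(kv, "maxdist_bins") <- nums[2]
    attr(kv, "m") <- nums[3]
  }
  kv
}

#' Key-frequency spectrum plot
#'
#' @param object A `tsr_keyvec`.
#' @param ... Ignored.
#' @return A ggplot: histogram of key occurrence counts.
#' @export
autoplot.tsr_keyvec <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$count)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "key occurrence count", y = "number of distinct keys",
                  title = attr(object, "protein_id"))
}
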