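#' Synthetic C-alpha trace generators
#'
#' Deterministic generators of idealized protein backbones so that every
#' operation in the package can be exercised without downloading structures.
#' Geometry follows textbook C-alpha parameters:
#' an ideal alpha helix (1.5 A rise, 100 degrees twist, 2.3 A radius, giving
#' consecutive C-alpha distances of about 3.8 A), an ideal extended strand
#' (3.3 A axial step with an alternating 0.94 A zigzag, again a 3.8 A
#' virtual bond), and a self-avoiding random-walk coil with fixed 3.8 A
#' virtual bonds and a 3.0 A clash cutoff. Sequences are drawn uniformly
#' from the 20 standard residues under the given seed. These fixtures
#' emulate realistic Theta/MaxDist distributions but not real packing,
#' side-chain effects or solvent structure.
#'
#' @param n Number of residues (at least 3).
#' @param seed Integer seed; the output is a pure function of the arguments.
#' @param sequence Optional character vector of three-letter codes, length
#'   `n`; random if omitted.
#' @param id Structure identifier.
#' @return A [ca_structure].
#' @examples
#' h <- make_helix(10, seed = 1)
#' range(sqrt(rowSums(diff(ca_coords(h))^2)))  # ~3.8 A virtual bonds
#' @export
make_helix <- function(n, seed = 1L, sequence = NULL, id = "helix") {
  if (n < 3) abort("n must be >= 3.")
  i <- seq_len(n) - 1L
  ang <- i * 100 * pi / 180
  df <- tibble(aa3 = fixture_sequence(n, seed, sequence),
               x = 2.3 * cos(ang), y = 2.3 * sin(ang), z = 1.5 * i,
               ss = "helix")
  ca_structure(df, id = id)
}

#' @rdname make_helix
#' @export
make_strand <- function(n, seed = 1L, sequence = NULL, id = "strand") {
  if (n < 3) abort("n must be >= 3.")
  i <- seq_len(n) - 1L
  df <- tibble(aa3 = fixture_sequence(n, seed, sequence),
               x = 3.3 * i, y = 0.943 * (-1)^i, z = 0,
               ss = "strand")
  ca_structure(df, id = id)
}

#' @rdname make_helix
#' @param max_tries Resampling attempts per step of the self-avoiding walk.
#' @export
make_coil <- function(n, seed = 1L, sequence = NULL, id = "coil",
                      max_tries = 200L) {
  if (n < 3) abort("n must be >= 3.")
  coords <- withr::with_seed(seed, {
    cm <- matrix(0, n, 3)
    for (i in 2:n) {
      for (t in seq_len(max_tries)) {
        u <- stats::rnorm(3)
        p <- cm[i - 1, ] + 3.8 * u / sqrt(sum(u^2))
        if (i == 2 || min(sqrt(rowSums(sweep(cm[seq_len(i - 2), , drop = FALSE],
                                             2, p)^2))) >= 3.0) break
      }
      cm[i, ] <- p
    }
    cm
  })
  df <- tibble(aa3 = fixture_sequence(n, seed + 1L, sequence),
               x = coords[, 1], y = coords[, 2], z = coords[, 3],
               ss = "none")
  ca_structure(df, id = id)
}

#' @rdname make_helix
#' @param n_helices Number of helices in the bundle.
#' @param helix_len Residues per helix.
#' @export
make_bundle <- function(n_helices = 3L, helix_len = 10L, seed = 1L,
                        id = "bundle") {
  parts <- purrr::map(seq_len(n_helices), function(h) {
    s <- make_helix(helix_len, seed = seed + h)
    ang <- 2 * pi * (h - 1) / n_helices
    tibble(aa3 = s$aa3,
           x = s$x + 9 * cos(ang), y = s$y + 9 * sin(ang),
           z = if (h %% 2 == 0) max(s$z) - s$z else s$z,
           ss = "helix")
  })
  df <- bind_rows(parts)
  ca <- ca_structure(df, id = id)
  # the helices are distinct segments even though the ss run is contiguous
  seg <- rep(seq_len(n_helices), each = helix_len)
  ca$ss_segment <- seg
  ca
}

#' @rdname make_helix
#' @param helix_len,linker_len,strand_len Segment lengths of the composite
#'   helix-coil-strand fixture.
#' @export
make_composite <- function(seed = 1L, helix_len = 8L, linker_len = 4L,
                           strand_len = 8L, id = "composite") {
  h <- make_helix(helix_len, seed = seed)
  c0 <- make_coil(linker_len + 2L, seed = seed + 1L)
  st <- make_strand(strand_len, seed = seed + 2L)
  hx <- tibble(aa3 = h$aa3, x = h$x, y = h$y, z = h$z, ss = "helix")
  lx <- tibble(aa3 = c0$aa3[seq_len(linker_len)],
               x = c0$x[seq_len(linker_len)] + max(h$x) + 4,
               y = c0$y[seq_len(linker_len)],
               z = c0$z[seq_len(linker_len)] + max(h$z), ss = "none")
  sx <- tibble(aa3 = st$aa3, x = st$x + max(lx$x) + 4, y = st$y,
               z = st$z + max(lx$z) + 4, ss = "strand")
  ca_structure(bind_rows(hx, lx, sx), id = id)
}

fixture_sequence <- function(n, seed, sequence = NULL) {
  if (!is.null(sequence)) {
    if (length(sequence) != n) abort("sequence length must equal n.")
    return(toupper(sequence))
  }
  withr::with_seed(seed, sample(default_label_table()$aa3, n, replace = TRUE))
}

#' Structure transformations for testing invariances
#'
#' `perturb()` adds i.i.d. Gaussian noise (sd `sigma` A) to every
#' coordinate; `reflect()` negates x (a mirror image; distances preserved,
#' chirality reversed); `rigid_move()` applies a random rotation plus
#' translation (keys must be invariant); `rearrange()` moves residues
#' `[0, cut)` to the end without touching coordinates (keys must be
#' invariant, sequence order is not part of the representation);
#' `plant_motif()` overwrites three residues with given coordinates and
#' residue types, optionally after a random rigid placement of the motif.
#'
#' @param s A [ca_structure].
#' @param sigma Noise standard deviation in Angstrom.
#' @param seed Integer seed.
#' @return A transformed [ca_structure].
#' @export
perturb <- function(s, sigma, seed = 1L) {
  if (sigma < 0) abort("sigma must be >= 0.")
  if (sigma == 0) return(s)
  noise <- withr::with_seed(seed, matrix(stats::rnorm(3 * nrow(s), 0, sigma),
                                         ncol = 3))
  s$x <- s$x + noise[, 1]; s$y <- s$y + noise[, 2]; s$z <- s$z + noise[, 3]
  s
}

#' @rdname perturb
#' @export
reflect <- function(s) {
  s$x <- -s$x
  s
}

#' @rdname perturb
#' @export
rigid_move <- function(s, seed = 1L) {
  tr <- withr::with_seed(seed, {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    list(R = quat_to_rot(q), t = stats::runif(3, -50, 50))
  })
  cm <- ca_coords(s) %*% t(tr$R)
  s$x <- cm[, 1] + tr$t[1]; s$y <- cm[, 2] + tr$t[2]; s$z <- cm[, 3] + tr$t[3]
  s
}

quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
}

#' @rdname perturb
#' @param cut Residues `[0, cut)` (seq_index terms) are moved to the end.
#' @export
rearrange <- function(s, cut) {
  n <- nrow(s)
  if (cut < 1 || cut >= n) abort("cut must be in 1..(n-1).")
  df <- as_tibble(s)[c((cut + 1):n, 1:cut),
                     c("aa3", "label", "x", "y", "z", "ss")]
  ca_structure(df, id = structure_id(s))
}

#' @rdname perturb
#' @param coords3 3 x 3 coordinate matrix of the motif vertices.
#' @param aa3_3 Character vector of the three motif residue types.
#' @param positions 1-based row indices of the residues to overwrite.
#' @param place Apply a seeded random rigid placement to the motif before
#'   planting (so the planted copy is in a generic orientation)?
#' @export
plant_motif <- function(s, coords3, aa3_3, positions, seed = 1L,
                        place = TRUE) {
  if (length(positions) != 3 || any(positions < 1 | positions > nrow(s))) {
    abort("positions must be three valid residue rows.")
  }
  if (place) {
    tr <- withr::with_seed(seed, {
      q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
      list(R = quat_to_rot(q), t = stats::runif(3, -30, 30))
    })
    coords3 <- coords3 %*% t(tr$R)
    coords3 <- sweep(coords3, 2, -tr$t)
  }
  lt <- default_label_table()
  s$aa3[positions] <- toupper(aa3_3)
  s$label[positions] <- as.integer(label_of(lt, aa3_3))
  s$x[positions] <- coords3[, 1]
  s$y[positions] <- coords3[, 2]
  s$z[positions] <- coords3[, 3]
  s
}

#' Construct a triangle with prescribed Theta and MaxDist
#'
#' Builds vertex coordinates whose canonical descriptor has exactly the
#' requested angle and longest edge, useful for planting motifs whose key is
#' known by construction. The two base vertices sit `maxdist` apart (the
#' longest edge), the apex at distance `d3` from the base midpoint at angle
#' `theta` degrees from the midpoint-to-second-base-vertex direction. With
#' `d3 <= maxdist / 2` the base is guaranteed to stay the longest edge.
#' A `theta` above 90 degrees builds the mirror-image form of the
#' `180 - theta` triangle: same labels, same folded Theta, opposite key sign
#' under mirror mode (provided the base vertices carry the two largest
#' labels, so they remain the l1-l2 edge after canonical ordering).
#'
#' @param theta The theta1 angle in degrees, in (0, 180).
#' @param maxdist Longest edge length in Angstrom.
#' @param d3 Distance from apex to base midpoint.
#' @return A 3 x 3 coordinate matrix (rows: base vertex l1, base vertex l2,
#'   apex l3).
#' @export
make_motif_triangle <- function(theta, maxdist, d3 = maxdist / 3) {
  if (theta <= 0 || theta >= 180) abort("theta must be in (0, 180).")
  if (d3 > maxdist / 2) abort("d3 must be <= maxdist / 2.")
  th <- theta * pi / 180
  rbind(c(-maxdist / 2, 0, 0),
        c(maxdist / 2, 0, 0),
        c(d3 * cos(th), d3 * sin(th), 0))
}
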