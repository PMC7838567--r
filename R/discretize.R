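#' Bin schemes for Theta and MaxDist
#'
#' A bin scheme holds the discretization used by the key encoder: interior
#' cut-points for Theta (degrees, bins covering (0, 90]) and MaxDist
#' (Angstrom, last bin open-ended), together with the implied bin counts and
#' the label-alphabet size `m`. Values are assigned to bins with the
#' right-closed convention `boundaries[i-1] < value <= boundaries[i]`;
#' values above the last cut-point fall in the last bin.
#'
#' The shipped presets expose bin counts Theta in \{7, 15, 21, 29\} and
#' MaxDist in \{12, 26, 35\} (12 candidate combinations), with 29/35 as the
#' default. Their boundaries were fitted with [fit_bin_boundaries()] on a
#' packaged synthetic C-alpha sample (see `data-raw/boundaries.R`); users
#' with their own calibrated boundaries can load them with
#' [read_boundaries()] and build a scheme directly.
#'
#' @param theta_breaks Ascending interior cut-points for Theta (degrees).
#' @param maxdist_breaks Ascending interior cut-points for MaxDist (A).
#' @param m Label-alphabet size (from the [label_table]).
#' @return An object of class `bin_scheme`.
#' @examples
#' sc <- default_bin_scheme()
#' sc$theta_bins
#' @export
bin_scheme <- function(theta_breaks, maxdist_breaks, m = 23L) {
  theta_breaks <- as.numeric(theta_breaks)
  maxdist_breaks <- as.numeric(maxdist_breaks)
  if (is.unsorted(theta_breaks, strictly = TRUE) ||
      is.unsorted(maxdist_breaks, strictly = TRUE)) {
    abort("boundaries must be strictly increasing.")
  }
  if (any(theta_breaks <= 0) || any(theta_breaks >= 90)) {
    abort("theta cut-points must lie strictly inside (0, 90).")
  }
  if (any(maxdist_breaks <= 0)) abort("maxdist cut-points must be positive.")
  structure(
    list(theta_breaks = theta_breaks,
         maxdist_breaks = maxdist_breaks,
         theta_bins = length(theta_breaks) + 1L,
         maxdist_bins = length(maxdist_breaks) + 1L,
         m = as.integer(m)),
    class = "bin_scheme")
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat(sprintf("<bin_scheme> Theta %d bins, MaxDist %d bins, m = %d\n",
              x$theta_bins, x$maxdist_bins, x$m))
  invisible(x)
}

#' @rdname bin_scheme
#' @param theta_bins,maxdist_bins Preset bin counts; Theta one of 7, 15, 21,
#'   29 and MaxDist one of 12, 26, 35.
#' @export
default_bin_scheme <- function(theta_bins = 29L, maxdist_bins = 35L, m = 23L) {
  tb <- read_boundaries(preset_boundary_path("theta", theta_bins))
  db <- read_boundaries(preset_boundary_path("maxdist", maxdist_bins))
  bin_scheme(tb, db, m = m)
}

preset_boundary_path <- function(which, n_bins) {
  fn <- sprintf("%s_%02d.txt", which, as.integer(n_bins))
  p <- system.file("extdata", "boundaries", fn, package = "tsrkeys")
  if (!nzchar(p)) {
    abort(sprintf("no shipped %s preset with %d bins.", which, n_bins))
  }
  p
}

#' @rdname bin_scheme
#' @param path Boundary file: one ascending cut-point per line, `#` comments.
#' @export
read_boundaries <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*(#|$)", ln)]
  as.numeric(ln)
}

#' @rdname bin_scheme
#' @param boundaries Numeric cut-points to write.
#' @param comment Optional header comment.
#' @export
write_boundaries <- function(boundaries, path, comment = NULL) {
  out <- character(0)
  if (!is.null(comment)) out <- paste0("# ", comment)
  writeLines(c(out, format(boundaries, digits = 15, trim = TRUE)), path)
  invisible(path)
}

#' Assign values to bins
#'
#' Right-closed assignment: value `v` goes to bin `i` with
#' `boundaries[i-1] < v <= boundaries[i]` (1-based); values above the last
#' cut-point are clamped into the last bin, so the final bin is open-ended.
#'
#' @param values Non-negative finite numeric vector.
#' @param boundaries Ascending interior cut-points (`n_bins - 1` of them).
#' @return Integer bin indices in `1..(length(boundaries) + 1)`.
#' @examples
#' assign_bin(c(10, 30, 45, 1e6), c(30, 60))
#' @export
assign_bin <- function(values, boundaries) {
  if (any(!is.finite(values)) || any(values < 0)) {
    abort("values must be finite and non-negative.")
  }
  n_bins <- length(boundaries) + 1L
  idx <- findInterval(values, boundaries, left.open = TRUE) + 1L
  pmin(idx, n_bins)
}

#' Total within-bin variance
#'
#' Sum over bins of the population variance of the values falling in each
#' bin; empty bins contribute zero. This is the objective the boundary
#' fitter minimizes and the statistic scanned when choosing bin counts.
#'
#' @inheritParams assign_bin
#' @return A single non-negative number.
#' @export
within_bin_variance <- function(values, boundaries) {
  n_bins <- length(boundaries) + 1L
  b <- pmin(findInterval(values, boundaries, left.open = TRUE) + 1L, n_bins)
  pop_var <- function(v) if (length(v) < 2) 0 else mean((v - mean(v))^2)
  sum(vapply(split(values, b), pop_var, numeric(1)))
}

#' Fit bin boundaries by adaptive unsupervised iterative discretization
#'
#' Fits `n_bins - 1` interior cut-points so that (a) bins hold as close to
#' equal numbers of values as achievable and (b) all occurrences of a tied
#' value land in the same bin (cut-points only sit in gaps between distinct
#' values). Cut-points are seeded at the equal-frequency positions and then
#' iteratively relocated: each cut may move to a nearby gap (one whose
#' cumulative count deviates from the ideal equal-frequency count by at most
#' `max(0.5, minimal achievable deviation)`) if that lowers the total
#' within-bin variance; passes repeat until no cut moves or `max_iter`
#' passes. The returned cut-points are midpoints of the chosen gaps.
#'
#' @param values Non-empty numeric vector.
#' @param n_bins Number of bins; at most the number of distinct values.
#' @param max_iter Maximum relocation passes.
#' @return Ascending numeric vector of `n_bins - 1` cut-points
#'   (`numeric(0)` for one bin).
#' @examples
#' fit_bin_boundaries(c(5, 5, 5, 5, 5, 5, 10, 20), 2)
#' @export
fit_bin_boundaries <- function(values, n_bins, max_iter = 100L) {
  if (length(values) == 0) abort("`values` must be non-empty.")
  n_bins <- as.integer(n_bins)
  u <- sort(unique(values))
  if (n_bins < 1L) abort("`n_bins` must be >= 1.")
  if (n_bins > length(u)) {
    abort(sprintf("n_bins (%d) exceeds number of distinct values (%d).",
                  n_bins, length(u)))
  }
  if (n_bins == 1L) return(numeric(0))

  counts <- as.integer(table(factor(values, levels = u)))
  cum <- cumsum(counts)              # cumulative count left of each gap
  g <- length(u) - 1L                # gaps between distinct values
  n <- length(values)
  cumg <- cum[seq_len(g)]

  # equal-frequency seeding under feasibility (cuts strictly increasing)
  cuts <- integer(n_bins - 1L)       # gap indices
  prev <- 0L
  for (j in seq_len(n_bins - 1L)) {
    lo <- prev + 1L
    hi <- g - (n_bins - 1L - j)
    ideal <- j * n / n_bins
    cand <- lo:hi
    cuts[j] <- cand[which.min(abs(cumg[cand] - ideal))]
    prev <- cuts[j]
  }

  gap_sorted <- u                    # values sorted; bin of gap index gp = values <= u[gp]
  sorted_vals <- sort(values)
  # variance of the run of sorted values in (a, b] gap terms
  run_var <- function(gp_lo, gp_hi) {
    # values strictly after gap gp_lo up to gap gp_hi (cum counts)
    i1 <- if (gp_lo == 0L) 1L else cum[gp_lo] + 1L
    i2 <- if (gp_hi > g) n else cum[gp_hi]
    v <- sorted_vals[i1:i2]
    if (length(v) < 2) 0 else mean((v - mean(v))^2)
  }

  for (pass in seq_len(max_iter)) {
    moved <- FALSE
    for (j in seq_len(n_bins - 1L)) {
      lo <- if (j == 1L) 1L else cuts[j - 1L] + 1L
      hi <- if (j == n_bins - 1L) g else cuts[j + 1L] - 1L
      cand <- lo:hi
      ideal <- j * n / n_bins
      dev <- abs(cumg[cand] - ideal)
      # stay as close to equal frequency as achievable: on all-distinct data
      # this keeps every cumulative count within 0.5 of its ideal, bounding
      # each bin's deviation from n/n_bins by 1 element
      cand <- cand[dev <= max(0.5, min(dev)) + 1e-9]
      left_gap <- if (j == 1L) 0L else cuts[j - 1L]
      right_gap <- if (j == n_bins - 1L) g + 1L else cuts[j + 1L]
      obj <- vapply(cand, function(cp) {
        run_var(left_gap, cp) + run_var(cp, right_gap)
      }, numeric(1))
      best <- cand[which.min(obj)]
      if (best != cuts[j]) {
        cuts[j] <- best
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  (u[cuts] + u[cuts + 1L]) / 2
}

#' Scan candidate bin counts by within-bin variance
#'
#' For each sample set and each candidate bin count, fits boundaries with
#' [fit_bin_boundaries()] and records the total within-bin variance. Per
#' sample set the five candidates with the smallest variance are kept
#' (variance ties broken toward the larger bin count, which favors finer
#' discretization), and of those five the two with the greatest bin counts
#' are selected. Across sample sets the minimum, median, maximum and modal
#' selected bin counts are reported.
#'
#' @param sample_sets List of numeric vectors (one per sample set).
#' @param candidates Integer vector of candidate bin counts.
#' @return A list of class `bin_count_scan` with elements `scan` (tibble:
#'   sample, n_bins, variance, top5, selected) and `summary` (tibble with
#'   min/median/max/mode of the selected counts).
#' @export
select_bin_counts <- function(sample_sets, candidates) {
  if (length(sample_sets) == 0) abort("need at least one sample set.")
  if (length(candidates) == 0) abort("empty candidate range.")
  candidates <- sort(unique(as.integer(candidates)))
  scan <- purrr::map_dfr(seq_along(sample_sets), function(si) {
    vals <- sample_sets[[si]]
    ok <- candidates[candidates <= length(unique(vals))]
    v <- vapply(ok, function(nb) {
      within_bin_variance(vals, fit_bin_boundaries(vals, nb))
    }, numeric(1))
    d <- tibble(sample = si, n_bins = ok, variance = v)
    # five smallest variances; ties toward larger bin counts
    ord <- order(d$variance, -d$n_bins)
    d$top5 <- seq_len(nrow(d)) %in% ord[seq_len(min(5L, nrow(d)))]
    top <- d$n_bins[d$top5]
    sel <- sort(top, decreasing = TRUE)[seq_len(min(2L, length(top)))]
    d$selected <- d$top5 & d$n_bins %in% sel
    d
  })
  sel <- scan$n_bins[scan$selected]
  mode_count <- as.integer(names(which.max(rev(table(sel)))))
  summary <- tibble(min = min(sel), median = stats::median(sel),
                    max = max(sel), mode = mode_count)
  structure(list(scan = scan, summary = summary), class = "bin_count_scan")
}

#' @export
print.bin_count_scan <- function(x, ...) {
  cat("<bin_count_scan>", length(unique(x$scan$sample)), "sample set(s)\n")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.bin_count_scan <- function(x, ...) x$scan

#' @export
glance.bin_count_scan <- function(x, ...) x$summary
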