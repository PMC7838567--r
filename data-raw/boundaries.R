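# Fit the shipped Theta / MaxDist boundary presets on a synthetic C-alpha
# sample (mixed ideal helices, strands and self-avoiding coils), pooling the
# raw triangle descriptors of 12 sample sets. Deterministic: fixed seeds.
# Run from the repository root: Rscript data-raw/boundaries.R
devtools::load_all(".", quiet = TRUE)

# crude equal-width scheme; only the raw theta/maxdist values are used here
crude <- bin_scheme(seq(3, 87, by = 3), seq(2, 68, by = 2), m = 23L)

sample_values <- function(set_seed) {
  structs <- c(
    lapply(1:3, function(i) make_helix(30 + 2 * i, seed = set_seed * 100 + i)),
    lapply(1:3, function(i) make_strand(28 + 2 * i, seed = set_seed * 100 + 10 + i)),
    lapply(1:3, function(i) make_coil(32 + 2 * i, seed = set_seed * 100 + 20 + i))
  )
  tr <- lapply(structs, tsr_triangles, scheme = crude)
  list(theta = unlist(lapply(tr, `[[`, "theta")),
       maxdist = unlist(lapply(tr, `[[`, "maxdist")))
}

sets <- lapply(1:12, sample_values)
theta_pool <- unlist(lapply(sets, `[[`, "theta"))
maxdist_pool <- unlist(lapply(sets, `[[`, "maxdist"))
cat("pooled:", length(theta_pool), "triangles\n")

dir.create("inst/extdata/boundaries", showWarnings = FALSE, recursive = TRUE)
for (nb in c(7, 15, 21, 29)) {
  b <- fit_bin_boundaries(round(theta_pool, 3), nb)
  write_boundaries(b, sprintf("inst/extdata/boundaries/theta_%02d.txt", nb),
                   comment = sprintf(
                     "Theta cut-points (degrees), %d bins; fitted on the packaged synthetic sample", nb))
}
for (nb in c(12, 26, 35)) {
  b <- fit_bin_boundaries(round(maxdist_pool, 3), nb)
  write_boundaries(b, sprintf("inst/extdata/boundaries/maxdist_%02d.txt", nb),
                   comment = sprintf(
                     "MaxDist cut-points (Angstrom), %d bins; fitted on the packaged synthetic sample", nb))
}
cat("done\n")
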