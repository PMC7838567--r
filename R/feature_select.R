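#' Secondary-structure key filters (IASS / IESS)
#'
#' Feature selection restricts key generation to triangles of residues in
#' secondary-structure elements. IESS (inter-secondary-structure) keeps a
#' triangle iff all three residues are tagged helix or strand, in any
#' segments and of any mix of types; IASS (intra-secondary-structure)
#' additionally requires, in the default `"segment"` mode, that all three
#' residues lie within one single segment, or in the alternate `"type"`
#' mode that they share one secondary-structure type across any segments.
#' In both modes IASS keys are a subset of IESS keys, which are a subset of
#' the unfiltered keys. Filters are applied through the `ss_filter`
#' argument of [tsr_triangles()] / [tsr_keys()].
#'
#' `ss_triple_pass()` exposes the predicate directly for residue index
#' triples (1-based row indices into the structure).
#'
#' @param s A [ca_structure] with secondary-structure tags.
#' @param i,j,k Integer vectors of 1-based residue row indices.
#' @param ss_filter `"iess"` or `"iass"`.
#' @param iass_mode `"segment"` or `"type"`.
#' @return Logical vector: does each triple pass the filter?
#' @examples
#' s <- make_composite(seed = 1)
#' k_all <- tsr_keys(s, default_bin_scheme())
#' k_iess <- tsr_keys(s, default_bin_scheme(), ss_filter = "iess")
#' @export
ss_triple_pass <- function(s, i, j, k, ss_filter = c("iess", "iass"),
                           iass_mode = c("segment", "type")) {
  ss_filter <- match.arg(ss_filter)
  iass_mode <- match.arg(iass_mode)
  if (all(s$ss == "none")) abort("structure has no secondary-structure annotation.")
  ss_triple_keep(s, i, j, k, ss_filter, iass_mode)
}

ss_triple_keep <- function(s, i, j, k, ss_filter, iass_mode) {
  tags <- s$ss
  tagged <- tags[i] != "none" & tags[j] != "none" & tags[k] != "none"
  if (ss_filter == "iess") return(tagged)
  if (iass_mode == "segment") {
    seg <- s$ss_segment
    tagged & !is.na(seg[i]) & seg[i] == seg[j] & seg[j] == seg[k]
  } else {
    tagged & tags[i] == tags[j] & tags[j] == tags[k]
  }
}

#' User-supplied secondary-structure annotation
#'
#' Replaces the secondary-structure tags of a structure with an annotation
#' table, for cases where the tags should come from an external assignment
#' rather than the PDB HELIX/SHEET records. The annotation file is TSV with
#' columns `seq_index` (0-based), `tag` (`helix`, `strand` or `none`);
#' residues absent from the table get `none`.
#'
#' @param s A [ca_structure].
#' @param annotation Data frame with columns `seq_index` and `tag`.
#' @return The structure with new `ss` and recomputed `ss_segment`.
#' @export
set_ss <- function(s, annotation) {
  if (!all(annotation$tag %in% c("helix", "strand", "none"))) {
    abort("tags must be helix, strand or none.")
  }
  if (!all(annotation$seq_index %in% s$seq_index)) {
    abort("annotation references residues not in the structure.")
  }
  ss <- rep("none", nrow(s))
  ss[match(annotation$seq_index, s$seq_index)] <- annotation$tag
  s$ss <- ss
  s$ss_segment <- ss_segment_ids(ss)
  s
}

#' @rdname set_ss
#' @param path TSV path (`seq_index`, `tag`), `#` comment lines allowed.
#' @export
read_ss_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  as_tibble(df)
}

#' Key-space merge transforms: grouping and bin coarsening
#'
#' These operate on an existing key vector, merging keys without
#' regenerating triangles. `group_keys()` decodes every key, maps its three
#' labels through an amino-acid grouping and re-sorts them descending before
#' re-encoding; `coarsen_keys()` re-maps the Theta and MaxDist digits onto a
#' coarser scheme whose cut-points are a subset of the original ones (nested
#' bins). Both are many-to-one maps on the key space, so counts of merged
#' keys add and -- by min/max superadditivity -- pairwise generalized Jaccard
#' similarity never decreases under either transform.
#'
#' `group_keys()` differs from generation-time grouping
#' (`tsr_keys(..., grouping = )`): the latter replaces labels before vertex
#' ordering, so new label ties are broken geometrically and a triangle's
#' grouped key is not a function of its ungrouped key. Generation-time
#' grouping matches how labels would be assigned in the first place;
#' `group_keys()` is the exact merge with the guaranteed monotonicity.
#'
#' @param kv A `tsr_keyvec`.
#' @param grouping Named integer vector (old label -> group label) or data
#'   frame (`aa3`, `group`), resolved against [default_label_table()].
#' @param scheme The [bin_scheme] the keys were generated with.
#' @return A merged `tsr_keyvec` under the same scheme (for `group_keys`) or
#'   the coarse scheme (for `coarsen_keys`).
#' @export
group_keys <- function(kv, grouping, scheme) {
  map <- grouping_label_map(grouping, scheme$m)
  dec <- decode_key(kv$key, scheme)
  relab <- function(l) ifelse(is.na(map[as.character(l)]), l,
                              map[as.character(l)])
  lab <- cbind(relab(dec$l1), relab(dec$l2), relab(dec$l3))
  lab <- t(apply(lab, 1, sort, decreasing = TRUE))
  newk <- dec$sign * encode_key(lab[, 1], lab[, 2], lab[, 3],
                                dec$d_bin, dec$theta_bin, scheme)
  merged <- tibble(key = newk, count = kv$count) %>%
    group_by(.data$key) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    arrange(.data$key)
  new_keyvec(merged, id = attr(kv, "protein_id"),
             skipped = attr(kv, "skipped_degenerate"),
             mirror = isTRUE(attr(kv, "mirror")), scheme = scheme)
}

grouping_label_map <- function(grouping, m) {
  if (is.data.frame(grouping)) {
    lt <- default_label_table()
    old <- label_of(lt, grouping$aa3)
    map <- stats::setNames(as.integer(grouping$group), as.character(old))
  } else {
    map <- stats::setNames(as.integer(grouping), names(grouping))
  }
  if (any(map < 1L | map > m)) abort("group labels must lie in 1..m.")
  map
}

#' @rdname group_keys
#' @param fine_scheme,coarse_scheme Bin schemes; every coarse cut-point must
#'   be one of the fine cut-points (nested bins), and `m` must agree.
#' @export
coarsen_keys <- function(kv, fine_scheme, coarse_scheme) {
  ok <- function(coarse, fine) {
    all(vapply(coarse, function(b) any(abs(fine - b) < 1e-9), logical(1)))
  }
  if (!ok(coarse_scheme$theta_breaks, fine_scheme$theta_breaks) ||
      !ok(coarse_scheme$maxdist_breaks, fine_scheme$maxdist_breaks)) {
    abort("coarse cut-points must be a subset of the fine ones.")
  }
  if (coarse_scheme$m != fine_scheme$m) abort("schemes disagree on m.")
  # map each fine bin to the coarse bin containing it, via its upper edge
  map_bins <- function(fine_breaks, coarse_breaks) {
    upper <- c(fine_breaks, Inf)
    pmin(findInterval(upper, coarse_breaks, left.open = TRUE) + 1L,
         length(coarse_breaks) + 1L)
  }
  tmap <- map_bins(fine_scheme$theta_breaks, coarse_scheme$theta_breaks)
  dmap <- map_bins(fine_scheme$maxdist_breaks, coarse_scheme$maxdist_breaks)
  dec <- decode_key(kv$key, fine_scheme)
  newk <- dec$sign * encode_key(dec$l1, dec$l2, dec$l3,
                                dmap[dec$d_bin], tmap[dec$theta_bin],
                                coarse_scheme)
  merged <- tibble(key = newk, count = kv$count) %>%
    group_by(.data$key) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    arrange(.data$key)
  new_keyvec(merged, id = attr(kv, "protein_id"),
             skipped = attr(kv, "skipped_degenerate"),
             mirror = isTRUE(attr(kv, "mirror")), scheme = coarse_scheme)
}
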