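#' C-alpha structure objects
#'
#' A `ca_structure` is a tibble with one row per residue carrying the
#' C-alpha trace of a single protein chain: `seq_index` (0-based internal
#' index), `auth_pos` (author residue number), `ins` (insertion code, "" if
#' none), `aa3`, integer `label`, coordinates `x`, `y`, `z` in Angstrom, and
#' secondary-structure annotation `ss` ("helix", "strand" or "none") with a
#' per-segment id `ss_segment` (NA outside segments). The structure id is
#' kept in the `id` attribute.
#'
#' @param residues Data frame with at least `aa3`, `x`, `y`, `z`; optional
#'   `auth_pos`, `ins`, `label`, `ss`.
#' @param id Structure identifier.
#' @param label_table [label_table] used to fill `label` when missing.
#' @return A `ca_structure` tibble.
#' @export
ca_structure <- function(residues, id = "structure",
                         label_table = default_label_table()) {
  df <- as_tibble(residues)
  n <- nrow(df)
  if (n == 0) abort("a ca_structure needs at least one residue.")
  if (!"auth_pos" %in% names(df)) df$auth_pos <- seq_len(n)
  if (!"ins" %in% names(df)) df$ins <- ""
  if (!"label" %in% names(df)) {
    df$label <- as.integer(label_of(label_table, df$aa3))
  }
  if (anyNA(df$label)) abort("unmapped residues; supply labels or a table that covers them.")
  if (!"ss" %in% names(df)) df$ss <- "none"
  if (!all(is.finite(df$x)) || !all(is.finite(df$y)) || !all(is.finite(df$z))) {
    abort("coordinates must be finite.")
  }
  key <- paste(df$auth_pos, df$ins)
  if (anyDuplicated(key)) abort("residues must be unique by (position, insertion code).")
  df$seq_index <- seq_len(n) - 1L
  df <- df[, c("seq_index", "auth_pos", "ins", "aa3", "label", "x", "y", "z", "ss")]
  df$ss_segment <- ss_segment_ids(df$ss)
  attr(df, "id") <- id
  class(df) <- c("ca_structure", class(tibble()))
  df
}

# maximal runs of one tag get consecutive segment ids; "none" -> NA
ss_segment_ids <- function(ss) {
  n <- length(ss)
  seg <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (ss[i] == "none") next
    if (i > 1 && ss[i - 1] == ss[i]) seg[i] <- seg[i - 1] else {
      cur <- cur + 1L
      seg[i] <- cur
    }
  }
  seg
}

#' @export
print.ca_structure <- function(x, ...) {
  cat("<ca_structure>", attr(x, "id"), "-", nrow(x), "residues,",
      sum(!is.na(x$ss_segment) & !duplicated(x$ss_segment)), "SS segments\n")
  NextMethod()
}

#' @rdname ca_structure
#' @param s A `ca_structure`.
#' @return `ca_coords()` returns the n x 3 coordinate matrix;
#'   `structure_id()` the id; `ss_segments()` a tibble
#'   (`type`, `start`, `end`, `segment`) in `seq_index` coordinates.
#' @export
ca_coords <- function(s) {
  as.matrix(s[, c("x", "y", "z")])
}

#' @rdname ca_structure
#' @export
structure_id <- function(s) attr(s, "id")

#' @rdname ca_structure
#' @export
ss_segments <- function(s) {
  seg <- s[!is.na(s$ss_segment), ]
  if (nrow(seg) == 0) {
    return(tibble(type = character(), start = integer(),
                  end = integer(), segment = integer()))
  }
  seg %>%
    group_by(segment = .data$ss_segment) %>%
    summarise(type = .data$ss[1],
              start = min(.data$seq_index),
              end = max(.data$seq_index), .groups = "drop") %>%
    select("type", "start", "end", "segment")
}

#' Read the C-alpha trace of one chain from a PDB file
#'
#' Selects C-alpha ATOM/HETATM records of one chain and model, resolves
#' alternate locations (highest occupancy wins; ties go to the first record
#' in the file), maps residue names to integer labels through an alias
#' table plus a [label_table], and parses HELIX/SHEET records into
#' per-residue secondary-structure tags. Residues whose name has neither a
#' direct mapping nor an alias are skipped with a warning; the count is kept
#' in the `n_skipped` attribute.
#'
#' @param path PDB file path.
#' @param chain Chain identifier, or `"first"` for the first chain with a
#'   C-alpha atom.
#' @param model Model index for multi-model (e.g. NMR) files; default 1.
#' @param label_table A [label_table].
#' @param aliases Data frame (`alias`, `aa3`) for non-standard residues.
#' @return A [ca_structure].
#' @examples
#' s <- make_helix(8, seed = 1)
#' f <- tempfile(fileext = ".pdb")
#' write_pdb_ca(s, f)
#' read_pdb_ca(f)
#' @export
read_pdb_ca <- function(path, chain = "first", model = 1L,
                        label_table = default_label_table(),
                        aliases = default_residue_aliases()) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  atoms <- pdb$atom
  nmod <- nrow(pdb$xyz)
  if (model < 1 || model > nmod) {
    abort(sprintf("model %d not present (file has %d).", model, nmod))
  }
  ca <- which(atoms$elety == "CA" & atoms$type %in% c("ATOM", "HETATM"))
  if (length(ca) == 0) abort("no C-alpha atoms in file.")
  chains <- atoms$chain[ca]
  chains[is.na(chains)] <- " "
  if (identical(chain, "first")) chain <- chains[1]
  keep <- ca[chains == chain]
  if (length(keep) == 0) abort(paste0("no C-alpha atoms in chain '", chain, "'."))

  a <- atoms[keep, ]
  a$.row <- keep
  # altloc resolution: per residue keep max occupancy, tie -> first in file
  rid <- paste(a$resno, ifelse(is.na(a$insert), "", a$insert))
  occ <- ifelse(is.na(a$o), 1, a$o)
  ord <- order(match(rid, unique(rid)), -occ, seq_along(rid))
  a <- a[ord, ]
  rid <- rid[ord]
  a <- a[!duplicated(rid), ]

  # residue name -> label, via alias table for modified residues
  aa3 <- toupper(a$resid)
  ali <- match(aa3, toupper(aliases$alias))
  aa3[!is.na(ali)] <- toupper(aliases$aa3[ali[!is.na(ali)]])
  lab <- label_of(label_table, aa3)
  skipped <- sum(is.na(lab))
  if (skipped > 0) {
    warn(sprintf("skipping %d residue(s) with unmapped names: %s",
                 skipped, paste(unique(a$resid[is.na(lab)]), collapse = ", ")))
    a <- a[!is.na(lab), ]
    aa3 <- aa3[!is.na(lab)]
    lab <- lab[!is.na(lab)]
  }
  if (nrow(a) == 0) abort("no mappable residues in chain.")

  xyz <- pdb$xyz[model, ]
  ix <- 3L * (a$.row - 1L)
  df <- tibble(
    auth_pos = as.integer(a$resno),
    ins = ifelse(is.na(a$insert), "", a$insert),
    aa3 = aa3,
    label = as.integer(lab),
    x = xyz[ix + 1L], y = xyz[ix + 2L], z = xyz[ix + 3L],
    ss = "none"
  )

  # HELIX / SHEET records -> per-residue tags (helix wins on overlap)
  tag_span <- function(df, start, end, chains_rec, type) {
    for (i in seq_along(start)) {
      ch <- chains_rec[i]
      if (!is.na(ch) && ch != chain) next
      hit <- df$auth_pos >= as.integer(start[i]) & df$auth_pos <= as.integer(end[i])
      df$ss[hit & df$ss == "none"] <- type
    }
    df
  }
  if (!is.null(pdb$sheet) && length(pdb$sheet$start) > 0) {
    df <- tag_span(df, pdb$sheet$start, pdb$sheet$end, pdb$sheet$chain, "strand")
  }
  if (!is.null(pdb$helix) && length(pdb$helix$start) > 0) {
    for (i in seq_along(pdb$helix$start)) {
      ch <- pdb$helix$chain[i]
      if (!is.na(ch) && ch != chain) next
      hit <- df$auth_pos >= as.integer(pdb$helix$start[i]) &
        df$auth_pos <= as.integer(pdb$helix$end[i])
      df$ss[hit] <- "helix"
    }
  }

  id <- paste0(sub("\\.(pdb|ent)(\\.gz)?$", "", basename(path)), "_",
               ifelse(chain == " ", "A", chain))
  out <- ca_structure(df, id = id, label_table = label_table)
  attr(out, "n_skipped") <- skipped
  out
}

#' Trim a structure to a residue window
#'
#' Keeps residues with `seq_index` in the closed interval `[start, end]`
#' (0-based), re-indexes them from 0 and clips secondary-structure segments
#' to the window. Mirrors the common preprocessing step of trimming chains
#' from either terminus so that compared structures cover the same span.
#'
#' @param s A [ca_structure].
#' @param start,end 0-based first and last `seq_index` to keep.
#' @return A [ca_structure] with `end - start + 1` residues.
#' @export
trim_structure <- function(s, start, end) {
  n <- nrow(s)
  if (start < 0 || end >= n || start > end) {
    abort(sprintf("invalid window [%d, %d] for %d residues.", start, end, n))
  }
  df <- s[s$seq_index >= start & s$seq_index <= end, ]
  out <- ca_structure(as_tibble(df)[, c("auth_pos", "ins", "aa3", "label",
                                        "x", "y", "z", "ss")],
                      id = structure_id(s))
  out
}

#' Write a minimal C-alpha PDB file
#'
#' Writes one ATOM record per residue plus HELIX/SHEET records derived from
#' the structure's secondary-structure tags. Intended for fixtures and
#' round-trip tests, not as a general-purpose PDB writer: coordinates are
#' written at the standard 3-decimal PDB precision.
#'
#' @param s A [ca_structure].
#' @param path Output file path.
#' @param chain Chain identifier to write (single character).
#' @return `path`, invisibly.
#' @export
write_pdb_ca <- function(s, path, chain = "A") {
  segs <- ss_segments(s)
  lines <- character(0)
  hn <- 0L; sn <- 0L
  for (i in seq_len(nrow(segs))) {
    a1 <- s$auth_pos[s$seq_index == segs$start[i]]
    a2 <- s$auth_pos[s$seq_index == segs$end[i]]
    r1 <- s$aa3[s$seq_index == segs$start[i]]
    r2 <- s$aa3[s$seq_index == segs$end[i]]
    if (segs$type[i] == "helix") {
      hn <- hn + 1L
      lines <- c(lines, sprintf(
        "HELIX  %3d %3d %3s %1s %4d%1s %3s %1s %4d%1s%2d%30s %5d",
        hn, hn, r1, chain, a1, " ", r2, chain, a2, " ", 1L, "",
        segs$end[i] - segs$start[i] + 1L))
    } else {
      sn <- sn + 1L
      lines <- c(lines, sprintf(
        "SHEET  %3d %3s%2d %3s %1s%4d%1s %3s %1s%4d%1s%2d",
        sn, "A", 1L, r1, chain, a1, " ", r2, chain, a2, " ", 0L))
    }
  }
  lines <- c(lines, sprintf(
    "ATOM  %5d  CA  %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(nrow(s)), s$aa3, chain, s$auth_pos, ifelse(s$ins == "", " ", s$ins),
    s$x, s$y, s$z, 1, 0))
  lines <- c(lines, "TER", "END")
  writeLines(lines, path)
  invisible(path)
}
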