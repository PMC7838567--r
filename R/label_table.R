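#' Amino-acid label tables
#'
#' A label table maps three-letter residue codes to the integer labels used
#' as triangle vertex digits in key encoding. The default table assigns the
#' 20 standard amino acids, in alphabetical order of their three-letter
#' codes, the integers 4..23, and fixes the label-alphabet size `m = 23`
#' (the largest label), so that every `label - 1 < m` and the key encoding
#' stays bijective. Absolute key integers depend on this mapping: two key
#' files are only comparable if they were generated with the same table,
#' bin boundaries and bin counts.
#'
#' @param mapping A data frame with columns `aa3` (three-letter code,
#'   uppercase) and `label` (positive integer).
#' @param m Label-alphabet size; must be at least `max(mapping$label)`.
#' @return A tibble of class `label_table` with columns `aa3`, `label` and
#'   attribute `m`.
#' @examples
#' lt <- default_label_table()
#' label_of(lt, c("ALA", "TRP"))
#' @export
label_table <- function(mapping, m = max(mapping$label)) {
  mapping <- as_tibble(mapping)
  if (!all(c("aa3", "label") %in% names(mapping))) {
    abort("`mapping` needs columns `aa3` and `label`.")
  }
  mapping$aa3 <- toupper(as.character(mapping$aa3))
  mapping$label <- as.integer(mapping$label)
  if (anyDuplicated(mapping$aa3)) abort("duplicate residue codes in mapping.")
  if (any(mapping$label < 1L)) abort("labels must be >= 1.")
  if (m < max(mapping$label)) abort("`m` must be >= max(label).")
  out <- mapping[, c("aa3", "label")]
  attr(out, "m") <- as.integer(m)
  class(out) <- c("label_table", class(tibble()))
  out
}

#' @rdname label_table
#' @export
default_label_table <- function() {
  path <- system.file("extdata", "config", "label_table.tsv",
                      package = "tsrkeys", mustWork = TRUE)
  read_label_table(path)
}

#' @rdname label_table
#' @param path Path to a TSV file with columns `aa3` and `label`
#'   (`#` lines are comments).
#' @export
read_label_table <- function(path, m = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  label_table(df, m = if (is.null(m)) max(df$label) else m)
}

#' @rdname label_table
#' @param table A `label_table`.
#' @param aa3 Character vector of three-letter codes.
#' @return `label_of()` returns the integer labels (NA for unmapped codes).
#' @export
label_of <- function(table, aa3) {
  table$label[match(toupper(aa3), table$aa3)]
}

#' @export
print.label_table <- function(x, ...) {
  cat("<label_table> m =", attr(x, "m"), "\n")
  NextMethod()
}

#' Residue alias table for modified residues
#'
#' Non-standard residues (phosphothreonine TPO, selenomethionine MSE,
#' nitrotyrosine TYN, phosphotyrosine PTR, ...) are resolved to a parent
#' standard residue before label lookup. The treatment of modified residues
#' is a configurable convention of this package: residues with no alias and
#' no direct mapping are skipped (with a warning) during structure reading.
#'
#' @return A tibble with columns `alias` and `aa3`.
#' @export
default_residue_aliases <- function() {
  path <- system.file("extdata", "config", "residue_aliases.tsv",
                      package = "tsrkeys", mustWork = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  as_tibble(df)
}

#' Amino-acid grouping
#'
#' Grouping maps structurally similar residues to one shared label,
#' coarsening the key space (e.g. Ser and Thr collapse, so triangles that
#' differ only by an S/T swap get the same key). `apply_grouping()` composes
#' a grouping into a label table; key generation with the grouped table can
#' only merge keys, never split them, so pairwise generalized Jaccard
#' similarity never decreases.
#'
#' The default grouping pools \{S,T\}, \{D,E\}, \{N,Q\}, \{K,R\}, \{I,L,V\}
#' and \{F,Y,W\}, leaving the rest as singletons; each group label is the
#' smallest member label so it stays within `1..m`.
#'
#' @param table A [label_table].
#' @param groups A data frame with columns `aa3` and `group` (integer group
#'   label), or a named integer vector mapping old labels to group labels.
#'   Residues absent from `groups` keep their label.
#' @return A new `label_table` with the same `m`.
#' @examples
#' gt <- apply_grouping(default_label_table(), default_grouping())
#' label_of(gt, c("SER", "THR"))
#' @export
apply_grouping <- function(table, groups) {
  stopifnot(inherits(table, "label_table"))
  m <- attr(table, "m")
  new_label <- table$label
  if (is.data.frame(groups)) {
    idx <- match(table$aa3, toupper(groups$aa3))
    hit <- !is.na(idx)
    new_label[hit] <- as.integer(groups$group[idx[hit]])
  } else {
    idx <- match(as.character(table$label), names(groups))
    hit <- !is.na(idx)
    new_label[hit] <- as.integer(groups[idx[hit]])
  }
  if (any(new_label < 1L | new_label > m)) {
    abort("group labels must lie in 1..m.")
  }
  out <- table
  out$label <- new_label
  out
}

#' @rdname apply_grouping
#' @export
default_grouping <- function() {
  path <- system.file("extdata", "config", "grouping_default.tsv",
                      package = "tsrkeys", mustWork = TRUE)
  read_grouping(path)
}

#' @rdname apply_grouping
#' @param path Path to a TSV file with columns `aa3` and `group`.
#' @export
read_grouping <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE)
  as_tibble(df)
}
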