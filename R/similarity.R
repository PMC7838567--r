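#' Generalized Jaccard similarity between key vectors
#'
#' For two key-frequency vectors the generalized Jaccard coefficient is
#' \deqn{J = \sum_i \min(c_a(k_i), c_b(k_i)) / \sum_i \max(c_a(k_i), c_b(k_i))}
#' over the union of their keys (an absent key counts 0). The modified
#' variant divides by `min(sum max, max(N_a, N_b))` instead, where `N_p` is
#' a protein's total key count -- by default with multiplicity (equal to the
#' number of keyed triangles), or the distinct-key count with
#' `n_mode = "distinct"`. Mirror-signed keys compare as distinct keys: a key
#' and its negative never match. Distance is `1 - similarity`.
#'
#' @param a,b `tsr_keyvec` objects (non-empty).
#' @return A number in \[0, 1\].
#' @examples
#' sc <- default_bin_scheme()
#' k1 <- tsr_keys(make_helix(8, seed = 1), sc)
#' generalized_jaccard(k1, k1)  # 1
#' @export
generalized_jaccard <- function(a, b) {
  cc <- match_counts(a, b)
  sum(pmin(cc$ca, cc$cb)) / sum(pmax(cc$ca, cc$cb))
}

#' @rdname generalized_jaccard
#' @param n_mode How `N_p` is counted in the modified measure:
#'   `"multiset"` (total occurrences) or `"distinct"` (distinct keys).
#' @export
modified_generalized_jaccard <- function(a, b,
                                         n_mode = c("multiset", "distinct")) {
  n_mode <- match.arg(n_mode)
  cc <- match_counts(a, b)
  na <- if (n_mode == "multiset") sum(a$count) else nrow(a)
  nb <- if (n_mode == "multiset") sum(b$count) else nrow(b)
  sum(pmin(cc$ca, cc$cb)) / min(sum(pmax(cc$ca, cc$cb)), max(na, nb))
}

match_counts <- function(a, b) {
  if (nrow(a) == 0 && nrow(b) == 0) {
    abort("cannot compare two empty key vectors.")
  }
  keys <- union(a$key, b$key)
  ca <- a$count[match(keys, a$key)]
  cb <- b$count[match(keys, b$key)]
  ca[is.na(ca)] <- 0L
  cb[is.na(cb)] <- 0L
  list(ca = ca, cb = cb)
}

#' Pairwise similarity and distance matrices
#'
#' Computes all pairwise similarities between a list of key vectors. Both
#' measures are symmetric with unit self-similarity, so only the upper
#' triangle is computed.
#'
#' @param vectors List of `tsr_keyvec` objects (at least 2); names default
#'   to each vector's `protein_id`, and ids must be unique.
#' @param measure `"generalized"` or `"modified"`.
#' @param n_mode Passed to [modified_generalized_jaccard()].
#' @return A symmetric matrix of class `tsr_simmat` with unit diagonal and
#'   the measure kept in the `measure` attribute.
#' @export
tsr_similarity <- function(vectors, measure = c("generalized", "modified"),
                           n_mode = c("multiset", "distinct")) {
  measure <- match.arg(measure)
  n_mode <- match.arg(n_mode)
  if (length(vectors) < 2) abort("need at least 2 key vectors.")
  ids <- names(vectors)
  if (is.null(ids)) {
    ids <- purrr::map_chr(vectors, ~ attr(.x, "protein_id") %||% NA_character_)
  }
  if (anyNA(ids) || anyDuplicated(ids)) abort("vectors need unique ids.")
  p <- length(vectors)
  f <- if (measure == "generalized") generalized_jaccard else
    function(x, y) modified_generalized_jaccard(x, y, n_mode = n_mode)
  mat <- diag(1, p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      mat[i, j] <- mat[j, i] <- f(vectors[[i]], vectors[[j]])
    }
  }
  dimnames(mat) <- list(ids, ids)
  attr(mat, "measure") <- measure
  class(mat) <- c("tsr_simmat", "matrix")
  mat
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname tsr_similarity
#' @param sim A `tsr_simmat`.
#' @return `tsr_distance()`: the element-wise `1 - similarity` matrix
#'   (class `tsr_distmat`), zero diagonal.
#' @export
tsr_distance <- function(sim) {
  d <- 1 - unclass(sim)
  attr(d, "measure") <- attr(sim, "measure")
  class(d) <- c("tsr_distmat", "matrix")
  d
}

#' @export
print.tsr_simmat <- function(x, ...) {
  cat("<tsr_simmat>", nrow(x), "proteins, measure:", attr(x, "measure"), "\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' @export
print.tsr_distmat <- function(x, ...) {
  cat("<tsr_distmat>", nrow(x), "proteins\n")
  print(round(unclass(x), 4))
  invisible(x)
}

#' @export
tidy.tsr_simmat <- function(x, ...) {
  m <- unclass(x)
  as_tibble(as.data.frame.table(m, responseName = "similarity",
                                stringsAsFactors = FALSE)) %>%
    rename(id1 = "Var1", id2 = "Var2")
}

#' @export
tidy.tsr_distmat <- function(x, ...) {
  m <- unclass(x)
  as_tibble(as.data.frame.table(m, responseName = "distance",
                                stringsAsFactors = FALSE)) %>%
    rename(id1 = "Var1", id2 = "Var2")
}

#' @export
autoplot.tsr_simmat <- function(object, ...) {
  df <- tidy(object)
  ord <- rownames(object)[stats::hclust(stats::as.dist(1 - unclass(object)),
                                        "average")$order]
  df$id1 <- factor(df$id1, levels = ord)
  df$id2 <- factor(df$id2, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(.data$id1, .data$id2,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Write a similarity or distance matrix
#'
#' TSV with an `id` header column/row; `#` provenance lines first.
#'
#' @param mat A `tsr_simmat` or `tsr_distmat`.
#' @param path Output path.
#' @param extra_header Additional `#` header lines.
#' @export
write_matrix_tsv <- function(mat, path, extra_header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# measure=", attr(mat, "measure") %||% "unknown"),
               extra_header), con)
  writeLines(paste(c("id", colnames(mat)), collapse = "\t"), con)
  for (i in seq_len(nrow(mat))) {
    writeLines(paste(c(rownames(mat)[i],
                       format(mat[i, ], digits = 10, trim = TRUE)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @param class_out Matrix class to restore: `"sim"` or `"dist"`.
#' @export
read_matrix_tsv <- function(path, class_out = c("sim", "dist")) {
  class_out <- match.arg(class_out)
  ln <- readLines(path)
  body <- ln[!grepl("^#", ln)]
  df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  hdr <- grep("^# measure=", ln, value = TRUE)
  attr(m, "measure") <- if (length(hdr)) sub("^# measure=", "", hdr[1]) else NULL
  class(m) <- c(if (class_out == "sim") "tsr_simmat" else "tsr_distmat",
                "matrix")
  m
}
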