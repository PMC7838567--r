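#' Class-level key-set report
#'
#' Computes the key-set algebra underlying Venn-diagram analyses of labeled
#' protein classes, on distinct keys (frequencies ignored): per-class unions
#' of member key sets, the keys common to all class unions, the keys
#' specific to exactly one class, the per-class "Common" keys present in
#' every member protein of that class, and the count of keys in every
#' non-empty region of the class Venn lattice. Venn regions are enumerated
#' for up to 6 classes.
#'
#' @param vectors Named list of `tsr_keyvec` objects (names default to each
#'   vector's `protein_id`).
#' @param class_map Data frame (`id`, `class`) or named character vector
#'   mapping every protein id to exactly one class.
#' @return A list of class `keyset_report`: `classes` (tibble id/class),
#'   `distinct_keys` (list class -> key vector), `common_all_classes`,
#'   `specific` (list class -> keys), `common_every_protein` (list class ->
#'   keys), `venn_counts` (tibble `region`, `n`; region names are
#'   `+`-joined class subsets).
#' @examples
#' sc <- default_bin_scheme()
#' vs <- list(p1 = tsr_keys(make_helix(8, 1), sc),
#'            p2 = tsr_keys(make_strand(8, 2), sc))
#' build_keyset_report(vs, c(p1 = "A", p2 = "B"))
#' @export
build_keyset_report <- function(vectors, class_map) {
  ids <- names(vectors)
  if (is.null(ids)) ids <- purrr::map_chr(vectors, attr, "protein_id")
  names(vectors) <- ids
  cm <- normalize_class_map(class_map)
  missing <- setdiff(ids, cm$id)
  if (length(missing)) {
    abort(paste0("ids missing from class_map: ", paste(missing, collapse = ", ")))
  }
  cm <- cm[cm$id %in% ids, ]
  classes <- sort(unique(cm$class))
  if (length(classes) > 6) {
    warn("more than 6 classes: Venn regions restricted to pairwise + all-common.")
  }

  member_keys <- purrr::map(vectors, ~ .x$key)
  distinct_keys <- purrr::map(setNames(classes, classes), function(cl) {
    sort(unique(unlist(member_keys[cm$id[cm$class == cl]], use.names = FALSE)))
  })
  common_all <- Reduce(intersect, distinct_keys)
  specific <- purrr::imap(distinct_keys, function(ks, cl) {
    others <- unlist(distinct_keys[setdiff(classes, cl)], use.names = FALSE)
    setdiff(ks, others)
  })
  common_every <- purrr::map(setNames(classes, classes), function(cl) {
    Reduce(intersect, member_keys[cm$id[cm$class == cl]])
  })

  venn <- venn_counts(distinct_keys)
  structure(list(classes = cm,
                 distinct_keys = distinct_keys,
                 common_all_classes = common_all,
                 specific = specific,
                 common_every_protein = common_every,
                 venn_counts = venn),
            class = "keyset_report")
}

normalize_class_map <- function(class_map) {
  if (is.data.frame(class_map)) {
    as_tibble(class_map)[, c("id", "class")]
  } else {
    tibble(id = names(class_map), class = unname(as.character(class_map)))
  }
}

venn_counts <- function(key_sets) {
  classes <- names(key_sets)
  k <- length(classes)
  all_keys <- sort(unique(unlist(key_sets, use.names = FALSE)))
  if (k > 6) {
    # pairwise intersections + all-common only
    out <- purrr::map_dfr(utils::combn(classes, 2, simplify = FALSE),
                          function(pr) {
      tibble(region = paste(pr, collapse = "+"),
             n = length(intersect(key_sets[[pr[1]]], key_sets[[pr[2]]])))
    })
    return(bind_rows(out, tibble(region = paste(classes, collapse = "+"),
                                 n = length(Reduce(intersect, key_sets)))))
  }
  membership <- vapply(key_sets, function(ks) all_keys %in% ks,
                       logical(length(all_keys)))
  if (length(all_keys) == 1) membership <- matrix(membership, nrow = 1)
  pattern <- apply(membership, 1, function(r) paste(classes[r], collapse = "+"))
  tab <- table(pattern)
  tibble(region = names(tab), n = as.integer(tab)) %>% arrange(.data$region)
}

#' @export
print.keyset_report <- function(x, ...) {
  cat("<keyset_report>", length(x$distinct_keys), "classes,",
      length(x$common_all_classes), "keys common to all class unions\n")
  print(x$venn_counts)
  invisible(x)
}

#' @export
glance.keyset_report <- function(x, ...) {
  tibble(n_classes = length(x$distinct_keys),
         n_union = sum(x$venn_counts$n),
         n_common_all = length(x$common_all_classes),
         n_specific = sum(lengths(x$specific)))
}

#' @export
tidy.keyset_report <- function(x, ...) x$venn_counts

#' Common keys present in every protein of a class
#'
#' Intersects the key sets of all member proteins and reports what fraction
#' of each protein's keys the Common set covers, both on distinct keys and
#' weighted by occurrence frequency.
#'
#' @param vectors List of `tsr_keyvec` objects from one class (>= 1).
#' @return A list: `keys` (the Common key vector) and `coverage` (tibble
#'   `id`, `frac_distinct`, `frac_weighted`).
#' @export
common_keys_every_protein <- function(vectors) {
  if (length(vectors) == 0) abort("need at least one vector.")
  common <- Reduce(intersect, purrr::map(vectors, ~ .x$key))
  ids <- names(vectors)
  if (is.null(ids)) ids <- purrr::map_chr(vectors, attr, "protein_id")
  coverage <- purrr::map_dfr(seq_along(vectors), function(i) {
    v <- vectors[[i]]
    hit <- v$key %in% common
    tibble(id = ids[i],
           frac_distinct = mean(hit),
           frac_weighted = sum(v$count[hit]) / sum(v$count))
  })
  list(keys = common, coverage = coverage)
}

#' Feature statistics of a key set
#'
#' Mean Theta, mean MaxDist and mean occurrence frequency of a set of keys,
#' the summary used to contrast Common against Uncommon keys. When a
#' per-triangle table from [tsr_triangles()] is available the raw theta and
#' maxdist values are averaged; otherwise the keys are decoded and bin
#' midpoints are used as representatives (the open-ended last MaxDist bin is
#' represented by the last cut plus half the previous bin's width).
#'
#' @param keys Numeric key vector (non-empty).
#' @param scheme The [bin_scheme] the keys were generated with.
#' @param triangles Optional [tsr_triangles()] tibble for raw-value means.
#' @param counts Optional `tsr_keyvec` supplying occurrence frequencies.
#' @return A one-row tibble: `n_keys`, `mean_theta`, `mean_maxdist`,
#'   `mean_frequency`.
#' @export
key_feature_stats <- function(keys, scheme, triangles = NULL, counts = NULL) {
  if (length(keys) == 0) abort("empty key set.")
  if (!is.null(triangles)) {
    rows <- triangles[triangles$key %in% keys, ]
    mt <- mean(rows$theta)
    md <- mean(rows$maxdist)
  } else {
    dec <- decode_key(keys, scheme)
    mt <- mean(bin_midpoints(scheme$theta_breaks, 90)[dec$theta_bin])
    md <- mean(bin_midpoints(scheme$maxdist_breaks, NA)[dec$d_bin])
  }
  mf <- NA_real_
  if (!is.null(counts)) {
    mf <- mean(counts$count[counts$key %in% keys])
  }
  tibble(n_keys = length(keys), mean_theta = mt, mean_maxdist = md,
         mean_frequency = mf)
}

bin_midpoints <- function(breaks, upper) {
  last_width <- diff(utils::tail(c(0, breaks), 2))
  lo <- c(0, breaks)
  hi <- c(breaks,
          if (is.na(upper)) breaks[length(breaks)] + last_width else upper)
  (lo + hi) / 2
}

#' Tolerant motif matching
#'
#' Tests whether a key vector contains each key of a motif query, allowing
#' the Theta bin to differ by up to `tolerance` (the "key +-1" flexibility
#' rule: adjacent Theta bins count as the same substructure). In the default
#' `"theta_bin"` mode the tolerance applies to the decoded Theta digit, so
#' it never wraps across the MaxDist digit at bins 1 and theta_bins; the
#' `"raw"` mode reproduces the literal integer `key +- tolerance`
#' comparison. Signs must match exactly (a mirror image is a different
#' substructure).
#'
#' @param v A `tsr_keyvec`.
#' @param query Numeric vector of (signed) query keys.
#' @param tolerance Non-negative integer; 0 means exact membership.
#' @param scheme The [bin_scheme] of the keys.
#' @param mode `"theta_bin"` or `"raw"`.
#' @return A tibble (`query_key`, `n_hits`, `matched`) with attribute
#'   `all_present` (TRUE iff every query key matched).
#' @examples
#' sc <- default_bin_scheme()
#' kv <- tsr_keys(make_helix(8, 1), sc)
#' match_motif(kv, kv$key[1] + 1, tolerance = 1, scheme = sc)
#' @export
match_motif <- function(v, query, tolerance = 1L, scheme,
                        mode = c("theta_bin", "raw")) {
  mode <- match.arg(mode)
  if (tolerance < 0) abort("tolerance must be >= 0.")
  if (mode == "raw") {
    hits <- vapply(query, function(q) {
      sum(sign(v$key) == sign(q) & abs(abs(v$key) - abs(q)) <= tolerance)
    }, numeric(1))
  } else {
    dv <- decode_key(v$key, scheme)
    dq <- decode_key(query, scheme)
    hits <- vapply(seq_along(query), function(i) {
      sum(dv$sign == dq$sign[i] & dv$l1 == dq$l1[i] & dv$l2 == dq$l2[i] &
            dv$l3 == dq$l3[i] & dv$d_bin == dq$d_bin[i] &
            abs(dv$theta_bin - dq$theta_bin[i]) <= tolerance)
    }, numeric(1))
  }
  out <- tibble(query_key = query, n_hits = as.integer(hits),
                matched = hits > 0)
  attr(out, "all_present") <- all(out$matched)
  out
}

#' Mirror-image key analysis across classes
#'
#' For mirror-signed key vectors, reports for each key magnitude which
#' classes carry the positive and which the negative form, and flags
#' magnitudes whose sign perfectly partitions classes: no class mixes both
#' signs, and at least one class carries each sign. Such keys mark
#' chirality differences between classes (a triangle in one class whose
#' mirror image characterizes another).
#'
#' @inheritParams build_keyset_report
#' @return A list: `by_class` (tibble `key`, `class`, `n_pos`, `n_neg`) and
#'   `flagged` (vector of flagged key magnitudes).
#' @export
mirror_pair_analysis <- function(vectors, class_map) {
  ids <- names(vectors)
  if (is.null(ids)) ids <- purrr::map_chr(vectors, attr, "protein_id")
  names(vectors) <- ids
  if (!any(purrr::map_lgl(vectors, ~ any(.x$key < 0)))) {
    if (!all(purrr::map_lgl(vectors, ~ isTRUE(attr(.x, "mirror"))))) {
      abort("vectors must be computed with mirror mode on.")
    }
  }
  cm <- normalize_class_map(class_map)
  per <- purrr::map_dfr(ids, function(id) {
    v <- vectors[[id]]
    tibble(id = id, class = cm$class[match(id, cm$id)],
           key = abs(v$key), sign = ifelse(v$key < 0, -1L, 1L))
  })
  by_class <- per %>%
    distinct(.data$id, .data$class, .data$key, .data$sign) %>%
    group_by(.data$key, .data$class) %>%
    summarise(n_pos = sum(.data$sign > 0), n_neg = sum(.data$sign < 0),
              .groups = "drop")
  flag_tbl <- by_class %>%
    group_by(.data$key) %>%
    summarise(mixed = any(.data$n_pos > 0 & .data$n_neg > 0),
              has_pos = any(.data$n_pos > 0 & .data$n_neg == 0),
              has_neg = any(.data$n_neg > 0 & .data$n_pos == 0),
              .groups = "drop")
  flagged <- flag_tbl$key[!flag_tbl$mixed & flag_tbl$has_pos & flag_tbl$has_neg]
  list(by_class = by_class, flagged = flagged)
}
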