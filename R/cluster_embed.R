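#' Cluster proteins from a distance matrix
#'
#' Thin, reproducible wrappers around standard algorithms: average-linkage
#' hierarchical clustering (cut at a cluster count `k` or height `h`) and
#' k-means. Because k-means needs coordinates, the distance matrix is first
#' embedded by classical MDS into `min(10, n - 1)` dimensions; the k-means
#' run is seeded and uses 10 restarts. The wrappers add determinism and
#' input validation only.
#'
#' @param d A `tsr_distmat`, `dist` or symmetric numeric matrix.
#' @param method `"average"` (average-linkage) or `"kmeans"`.
#' @param k Number of clusters (required for k-means).
#' @param h Cut height for average linkage (alternative to `k`).
#' @param seed Integer seed (k-means initialization).
#' @return A tibble of class `tsr_clust` (`id`, `cluster`) with the fitted
#'   `hclust` object (average linkage) in the `hclust` attribute.
#' @examples
#' sc <- default_bin_scheme()
#' vs <- list(a = tsr_keys(make_helix(8, 1), sc),
#'            b = tsr_keys(make_helix(8, 1, id = "b"), sc),
#'            c = tsr_keys(make_strand(8, 2), sc))
#' tsr_cluster(tsr_distance(tsr_similarity(vs)), k = 2)
#' @export
tsr_cluster <- function(d, method = c("average", "kmeans"), k = NULL,
                        h = NULL, seed = 1L) {
  method <- match.arg(method)
  dm <- as_dist_matrix(d)
  ids <- rownames(dm)
  n <- nrow(dm)
  if (!is.null(k) && k > n) abort("k exceeds number of items.")
  if (method == "average") {
    hc <- hclust(stats::as.dist(dm), method = "average")
    if (is.null(k) && is.null(h)) abort("supply k or h for average linkage.")
    cl <- cutree(hc, k = k, h = h)
    out <- tibble(id = ids, cluster = as.integer(cl))
    attr(out, "hclust") <- hc
  } else {
    if (is.null(k)) abort("k-means requires k.")
    emb <- tsr_embed(dm, method = "mds", dims = min(10L, n - 1L))
    km <- withr::with_seed(seed,
      kmeans(as.matrix(emb[, -1]), centers = k, nstart = 10L))
    out <- tibble(id = ids, cluster = as.integer(km$cluster))
    attr(out, "withinss") <- km$tot.withinss
  }
  attr(out, "method") <- method
  attr(out, "k") <- if (is.null(k)) length(unique(out$cluster)) else k
  class(out) <- c("tsr_clust", class(tibble()))
  out
}

as_dist_matrix <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  dm <- unclass(as.matrix(d))
  if (nrow(dm) != ncol(dm) || max(abs(dm - t(dm))) > 1e-8) {
    abort("need a symmetric distance matrix.")
  }
  if (is.null(rownames(dm))) {
    rownames(dm) <- colnames(dm) <- paste0("p", seq_len(nrow(dm)))
  }
  dm
}

#' @export
print.tsr_clust <- function(x, ...) {
  cat("<tsr_clust>", attr(x, "method"), "-", attr(x, "k"), "clusters,",
      nrow(x), "items\n")
  NextMethod()
}

#' @export
tidy.tsr_clust <- function(x, ...) as_tibble(x)

#' @export
glance.tsr_clust <- function(x, ...) {
  tibble(method = attr(x, "method"), k = attr(x, "k"), n = nrow(x))
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between two clusterings over the same ids;
#' 1 for identical partitions, about 0 for independent ones. Accepts
#' `tsr_clust` tibbles or named vectors; assignments are aligned by id when
#' names or `id` columns are present.
#'
#' @param a,b Partitions (`tsr_clust`, named vector, or bare vector of equal
#'   length).
#' @return A single number.
#' @export
ari <- function(a, b) {
  va <- partition_vector(a)
  vb <- partition_vector(b)
  if (!is.null(names(va)) && !is.null(names(vb))) {
    if (!setequal(names(va), names(vb))) abort("partitions cover different ids.")
    vb <- vb[names(va)]
  } else if (length(va) != length(vb)) {
    abort("partitions have different lengths and no ids to align on.")
  }
  mclust::adjustedRandIndex(va, vb)
}

partition_vector <- function(x) {
  if (inherits(x, "tsr_clust") || (is.data.frame(x) &&
                                   all(c("id", "cluster") %in% names(x)))) {
    return(setNames(x$cluster, x$id))
  }
  x
}

#' Scan average-linkage cutoffs for the ARI-maximizing cut
#'
#' Normalizes dendrogram heights to \[0, 1\] and scans cutoffs on a fixed
#' grid, scoring each resulting partition against a reference partition by
#' ARI. When `n_clusters` is given the scan is restricted to cutoffs that
#' produce exactly that many clusters, falling back to the full scan (with a
#' warning) if no cutoff attains it. Ties go to the smallest cutoff.
#'
#' @param d Distance matrix.
#' @param truth Reference partition (named vector or `tsr_clust`).
#' @param n_clusters Optional required cluster count.
#' @param step Cutoff grid step on the normalized scale.
#' @return A list: `best_cutoff`, `best_ari`, and `scan` (tibble `cutoff`,
#'   `n_clusters`, `ari`).
#' @export
sweep_cutoff <- function(d, truth, n_clusters = NULL, step = 0.01) {
  dm <- as_dist_matrix(d)
  hc <- hclust(stats::as.dist(dm), method = "average")
  hmax <- max(hc$height)
  tv <- partition_vector(truth)
  grid <- seq(0, 1, by = step)
  scan <- purrr::map_dfr(grid, function(cf) {
    cl <- cutree(hc, h = cf * hmax)
    tibble(cutoff = cf, n_clusters = length(unique(cl)),
           ari = ari(setNames(cl, rownames(dm)), tv))
  })
  pool <- scan
  if (!is.null(n_clusters)) {
    hit <- scan[scan$n_clusters == n_clusters, ]
    if (nrow(hit) == 0) {
      warn("no cutoff yields the requested cluster count; using full scan.")
    } else {
      pool <- hit
    }
  }
  best <- pool[which.max(pool$ari), ]
  list(best_cutoff = best$cutoff, best_ari = best$ari, scan = scan)
}

#' Embed a distance matrix
#'
#' Classical multidimensional scaling (`"mds"`, via [stats::cmdscale()]) or
#' principal components of the distance matrix rows (`"pca"`, via
#' [stats::prcomp()]). Axis signs are fixed deterministically (the
#' largest-magnitude coordinate of every axis is made positive), so repeated
#' runs are bitwise identical.
#'
#' @param d Distance matrix.
#' @param method `"mds"` or `"pca"`.
#' @param dims Number of embedding dimensions (`< n`).
#' @return A tibble of class `tsr_embedding` (`id`, `dim1`, ...) with the
#'   per-axis explained-variance fractions in the `explained` attribute and
#'   the method in `method`.
#' @export
tsr_embed <- function(d, method = c("mds", "pca"), dims = 2L) {
  method <- match.arg(method)
  dm <- as_dist_matrix(d)
  n <- nrow(dm)
  if (dims >= n) abort("dims must be < number of items.")
  if (method == "mds") {
    fit <- cmdscale(stats::as.dist(dm), k = dims, eig = TRUE)
    coords <- fit$points
    pos <- fit$eig[fit$eig > 0]
    explained <- (fit$eig[seq_len(dims)] / sum(pos))[seq_len(dims)]
  } else {
    fit <- prcomp(dm, rank. = dims)
    coords <- fit$x[, seq_len(dims), drop = FALSE]
    explained <- (fit$sdev^2 / sum(fit$sdev^2))[seq_len(dims)]
  }
  # deterministic sign convention per axis
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  out <- as_tibble(coords, .name_repair = ~ paste0("dim", seq_len(dims)))
  out <- dplyr::bind_cols(tibble(id = rownames(dm)), out)
  attr(out, "explained") <- explained
  attr(out, "method") <- method
  class(out) <- c("tsr_embedding", class(tibble()))
  out
}

#' @export
print.tsr_embedding <- function(x, ...) {
  cat("<tsr_embedding>", attr(x, "method"), "-", ncol(x) - 1, "dims\n")
  NextMethod()
}

#' @export
glance.tsr_embedding <- function(x, ...) {
  tibble(method = attr(x, "method"), dims = ncol(x) - 1,
         explained_total = sum(attr(x, "explained")))
}

#' @export
autoplot.tsr_embedding <- function(object, colour = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$dim1, .data$dim2)) +
    ggplot2::labs(x = "dimension 1", y = "dimension 2")
  if (!is.null(colour)) {
    df <- object
    df$group <- colour[match(df$id, names(colour))]
    p <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
                                          colour = .data$group))
  }
  p + ggplot2::geom_point()
}

#' Write an average-linkage dendrogram as Newick text
#'
#' @param x A `tsr_clust` fitted with `method = "average"`.
#' @param path Output path.
#' @export
write_dendrogram <- function(x, path) {
  hc <- attr(x, "hclust")
  if (is.null(hc)) abort("no dendrogram: cluster with method = 'average'.")
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
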