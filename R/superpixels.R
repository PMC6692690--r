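# Superpixel partitions: lattice and SLIC backends, majority tissue labels,
# and the superpixel adjacency graph.

#' Superpixel partition of an ROI
#'
#' A partition assigns every pixel to exactly one superpixel, with ids
#' contiguous in `1..K`.  Components:
#' \describe{
#'   \item{assignment}{integer matrix of superpixel ids, same shape as the
#'     image}
#'   \item{n}{number of superpixels K}
#'   \item{sizes}{pixel count per id}
#'   \item{majority_label}{per-id tissue code 0..7, after
#'     [assign_majority_labels()]; `NULL` before}
#'   \item{edges}{two-column matrix of undirected adjacency edges
#'     (`a < b`), after [build_adjacency()]; `NULL` before}
#' }
#'
#' @param assignment Integer matrix of positive superpixel ids; relabelled
#'   to contiguous `1..K` in row-major order of first appearance.
#' @return An object of class `superpixel_partition`.
#' @export
superpixel_partition <- function(assignment) {
  if (!is.matrix(assignment)) stop("`assignment` must be a matrix")
  a <- assignment
  storage.mode(a) <- "integer"
  if (any(is.na(a) | a < 1L)) stop("superpixel ids must be positive integers")
  # contiguous relabelling, stable in row-major scan order
  first <- unique(as.vector(t(a)))
  map <- integer(max(a))
  map[first] <- seq_along(first)
  a[] <- map[a]
  structure(list(assignment = a, n = max(a),
                 sizes = tabulate(a, nbins = max(a)),
                 majority_label = NULL, edges = NULL),
            class = "superpixel_partition")
}

#' @export
print.superpixel_partition <- function(x, ...) {
  cat(sprintf("<superpixel_partition> K = %d over %d x %d pixels (sizes %d..%d)\n",
              x$n, nrow(x$assignment), ncol(x$assignment),
              min(x$sizes), max(x$sizes)))
  if (!is.null(x$majority_label)) cat("  majority labels assigned\n")
  if (!is.null(x$edges))
    cat(sprintf("  adjacency: %d edges\n", nrow(x$edges)))
  invisible(x)
}

#' Deterministic lattice superpixels for label-only input
#'
#' Partitions the image into axis-aligned square tiles of side
#' `floor(sqrt(target_area))` (edge tiles may be smaller).  This is the
#' deterministic stand-in for colour-based superpixels when only a tissue
#' label map is available (synthetic fixtures have no meaningful colour).
#'
#' @param img A [tissue_label_image()] (or integer matrix).
#' @param target_area Desired superpixel area in pixels; default 3000, the
#'   scale at which one superpixel covers at least one epithelial cell on a
#'   full-resolution biopsy scan.
#' @return A [superpixel_partition()].
#' @export
lattice_superpixels <- function(img, target_area = 3000) {
  g <- if (inherits(img, "tissue_label_image")) img$grid else img
  if (target_area < 1) stop("`target_area` must be >= 1")
  h <- nrow(g); w <- ncol(g)
  if (target_area > h * w) {
    warning("target_area exceeds the image area; returning a single superpixel")
    return(superpixel_partition(matrix(1L, h, w)))
  }
  side <- max(1L, floor(sqrt(target_area)))
  rband <- (seq_len(h) - 1L) %/% side
  cband <- (seq_len(w) - 1L) %/% side
  ncb <- max(cband) + 1L
  a <- outer(rband, cband, function(r, c) r * ncb + c + 1L)
  superpixel_partition(matrix(as.integer(a), h, w))
}

#' SLIC superpixels from an RGB raster
#'
#' Simple linear iterative clustering: k-means in joint (colour, position)
#' space with a spatially windowed search, followed by connectivity
#' enforcement (fragments smaller than `target_area / 4` are merged into
#' their largest neighbouring segment).
#'
#' @param rgb An `H x W x 3` array with values in `[0, 1]` (as returned by
#'   `png::readPNG`).
#' @param target_area Desired superpixel area in pixels (default 3000).
#' @param compactness Weight of the spatial term relative to colour
#'   distance (default 10; larger gives more regular tiles).
#' @param iters Number of assignment/update sweeps (default 10).
#' @param label_image Optional [tissue_label_image()] the partition will be
#'   paired with; a dimension mismatch is an error.
#' @return A [superpixel_partition()].
#' @export
slic_superpixels <- function(rgb, target_area = 3000, compactness = 10,
                             iters = 10, label_image = NULL) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3L] < 3L)
    stop("`rgb` must be an H x W x 3 array")
  if (target_area < 1) stop("`target_area` must be >= 1")
  h <- dim(rgb)[1L]; w <- dim(rgb)[2L]
  if (!is.null(label_image)) {
    g <- if (inherits(label_image, "tissue_label_image")) label_image$grid else label_image
    if (nrow(g) != h || ncol(g) != w)
      stop(sprintf("RGB raster (%d x %d) does not match label image (%d x %d)",
                   h, w, nrow(g), ncol(g)))
  }
  if (target_area >= h * w)
    return(superpixel_partition(matrix(1L, h, w)))
  step <- sqrt(target_area)
  raw <- slic_assign(rgb[, , 1L], rgb[, , 2L], rgb[, , 3L],
                     step, compactness, as.integer(iters))
  cc <- cc_label_values(raw)
  merged <- .merge_small_segments(cc, min_size = ceiling(target_area / 4))
  superpixel_partition(merged)
}

# Merge segments smaller than min_size into their largest neighbouring
# segment (union-find); used to enforce SLIC connectivity.
.merge_small_segments <- function(cc, min_size) {
  k <- max(cc)
  if (k == 1L) return(cc)
  sizes <- tabulate(cc, nbins = k)
  e <- .grid_edges(cc)
  parent <- seq_len(k)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (id in order(sizes)) {
    ri <- find(id)
    if (sizes[ri] >= min_size) next
    nb <- c(e[e[, 1L] == id, 2L], e[e[, 2L] == id, 1L])
    nb <- unique(vapply(nb, find, integer(1L)))
    nb <- setdiff(nb, ri)
    if (!length(nb)) next
    tgt <- nb[which.max(sizes[nb])]
    parent[ri] <- tgt
    sizes[tgt] <- sizes[tgt] + sizes[ri]
  }
  root <- vapply(seq_len(k), find, integer(1L))
  m <- cc
  m[] <- root[cc]
  m
}

# undirected edges (a < b) between distinct ids of 4-connected neighbouring
# pixels in an id matrix
.grid_edges <- function(a) {
  h <- nrow(a); w <- ncol(a)
  p1 <- c(if (w > 1L) a[, -w], if (h > 1L) a[-h, ])
  p2 <- c(if (w > 1L) a[, -1L], if (h > 1L) a[-1L, ])
  keep <- p1 != p2
  if (!any(keep)) return(matrix(integer(0), 0L, 2L))
  e <- cbind(pmin(p1[keep], p2[keep]), pmax(p1[keep], p2[keep]))
  unique(e)
}

#' Assign majority tissue labels to superpixels
#'
#' Each superpixel receives the tissue code held by most of its pixels;
#' ties break toward the lowest code.
#'
#' @param part A [superpixel_partition()].
#' @param img The paired [tissue_label_image()] (same shape).
#' @return The partition with `majority_label` filled in.
#' @export
assign_majority_labels <- function(part, img) {
  g <- if (inherits(img, "tissue_label_image")) img$grid else img
  if (!identical(dim(part$assignment), dim(g)))
    stop(sprintf("partition (%d x %d) and label image (%d x %d) differ in shape",
                 nrow(part$assignment), ncol(part$assignment), nrow(g), ncol(g)))
  # K x 8 pixel counts; max.col with ties.method = "first" implements the
  # lowest-code tie-break because columns are in ascending code order
  counts <- matrix(0L, part$n, 8L)
  idx <- cbind(as.vector(part$assignment), as.vector(g) + 1L)
  tab <- table(factor(idx[, 1L], levels = seq_len(part$n)),
               factor(idx[, 2L], levels = 1:8))
  counts[] <- as.integer(tab)
  part$majority_label <- max.col(counts, ties.method = "first") - 1L
  part
}

#' Build the superpixel adjacency graph
#'
#' Two superpixels are adjacent when some pixel of one is 4-connected to a
#' pixel of the other.  The graph is undirected and loop-free.
#'
#' @param part A [superpixel_partition()].
#' @return The partition with `edges` filled in (two-column matrix,
#'   `a < b`, lexicographically ordered).
#' @export
build_adjacency <- function(part) {
  e <- .grid_edges(part$assignment)
  part$edges <- e[order(e[, 1L], e[, 2L]), , drop = FALSE]
  part
}

# adjacency list (list of integer neighbour vectors) from stored edges
.adjacency_list <- function(part) {
  if (is.null(part$edges))
    stop("adjacency not built; call build_adjacency() first")
  nbr <- vector("list", part$n)
  if (nrow(part$edges)) {
    spl1 <- split(part$edges[, 2L], factor(part$edges[, 1L], seq_len(part$n)))
    spl2 <- split(part$edges[, 1L], factor(part$edges[, 2L], seq_len(part$n)))
    nbr <- Map(c, spl1, spl2)
  }
  lapply(nbr, as.integer)
}
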