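# Tissue distribution feature: label frequency histogram plus label
# co-occurrence histogram over adjacent superpixels.

#' Tissue frequency histogram over superpixels
#'
#' @param part A [superpixel_partition()] with majority labels assigned.
#' @return Numeric 8-vector summing to 1; entry `c` is the fraction of
#'   superpixels with majority tissue code `c`.
#' @export
tissue_frequency <- function(part) {
  if (is.null(part$majority_label))
    stop("majority labels not assigned; call assign_majority_labels() first")
  if (part$n < 1L) stop("empty partition")
  f <- tabulate(part$majority_label + 1L, nbins = 8L) / part$n
  names(f) <- paste0("freq_label", 0:7)
  f
}

#' Tissue co-occurrence histogram over adjacent superpixels
#'
#' Every adjacency edge contributes one count to the unordered pair of the
#' majority labels at its endpoints (the diagonal pairs included); counts
#' are normalized by the number of edges.  The symmetric 36-bin form loses
#' nothing for an undirected graph; `directed = TRUE` gives the full
#' 64-bin ordered variant (each edge counted in both directions).
#'
#' @param part Partition with majority labels and adjacency built.
#' @param directed Use ordered label pairs (64 bins) instead of unordered
#'   (36 bins).
#' @return Named numeric vector (`cooc_{a}_{b}`) summing to 1, or all-zero
#'   when the graph has no edges.
#' @export
tissue_cooccurrence <- function(part, directed = FALSE) {
  if (is.null(part$majority_label))
    stop("majority labels not assigned; call assign_majority_labels() first")
  if (is.null(part$edges))
    stop("adjacency not built; call build_adjacency() first")
  la <- part$majority_label[part$edges[, 1L]]
  lb <- part$majority_label[part$edges[, 2L]]
  if (directed) {
    nm <- as.vector(t(outer(0:7, 0:7, function(a, b)
      sprintf("cooc_%d_%d", a, b))))
    v <- numeric(64L)
    names(v) <- nm
    if (length(la)) {
      idx <- c(la * 8L + lb, lb * 8L + la) + 1L
      tab <- tabulate(idx, nbins = 64L)
      v[] <- tab / (2L * length(la))
    }
    return(v)
  }
  pairs <- which(upper.tri(matrix(0, 8, 8), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), ]
  nm <- sprintf("cooc_%d_%d", pairs[, 1L] - 1L, pairs[, 2L] - 1L)
  v <- numeric(36L)
  names(v) <- nm
  if (length(la)) {
    a <- pmin(la, lb); b <- pmax(la, lb)
    key <- sprintf("cooc_%d_%d", a, b)
    tab <- table(factor(key, levels = nm))
    v[] <- as.numeric(tab) / length(la)
  }
  v
}

#' Tissue distribution feature for one ROI
#'
#' Concatenation of [tissue_frequency()] (8 entries) and
#' [tissue_cooccurrence()] (36 entries), capturing the amounts of each
#' tissue and their simple spatial relationships.
#'
#' @inheritParams tissue_cooccurrence
#' @param roi_id Optional identifier attached as an attribute.
#' @return Named numeric vector of length 44 (or 72 when `directed`).
#' @export
roi_distribution_feature <- function(part, roi_id = NULL, directed = FALSE) {
  feat <- c(tissue_frequency(part), tissue_cooccurrence(part, directed))
  attr(feat, "roi_id") <- roi_id
  feat
}
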