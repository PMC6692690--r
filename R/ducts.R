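# Duct detection: connected components of epithelium/secretion/necrosis
# superpixels on the adjacency graph.

# tissue codes forming the duct mask: malignant epithelium, benign
# epithelium, secretion, necrosis
.DUCT_MASK_CODES <- c(2L, 4L, 5L, 7L)

#' Superpixels belonging to ductal structures
#'
#' Breast ducts are epithelial rings, but involved ducts may be filled with
#' secretion or necrotic debris, so the binary mask unions epithelium (both
#' benign and malignant), secretion and necrosis majority labels.
#'
#' @param part A [superpixel_partition()] with majority labels assigned.
#' @return Integer vector of superpixel ids in the mask.
#' @export
duct_mask <- function(part) {
  if (is.null(part$majority_label))
    stop("majority labels not assigned; call assign_majority_labels() first")
  which(part$majority_label %in% .DUCT_MASK_CODES)
}

#' Detect ducts as connected components of the duct mask
#'
#' Connected components of the subgraph induced by `mask` on the superpixel
#' adjacency graph.  Components smaller than `min_size` superpixels are
#' discarded ("cleaning").  Components are ordered by decreasing size, ties
#' by smallest member id, and numbered `1..n` in that order.
#'
#' @param part A [superpixel_partition()] with adjacency built and majority
#'   labels assigned.
#' @param mask Integer vector of superpixel ids; defaults to
#'   [duct_mask()] of `part`.
#' @param min_size Minimum component size in superpixels (default 3).
#' @return A list of duct objects, each a list with `duct_id`,
#'   `member_ids` (sorted) and `size`.
#' @export
find_ducts <- function(part, mask = duct_mask(part), min_size = 3) {
  if (min_size < 1) stop("`min_size` must be >= 1")
  if (!length(mask)) return(list())
  if (any(mask < 1L | mask > part$n))
    stop("mask contains ids outside the partition")
  nbr <- .adjacency_list(part)
  in_mask <- logical(part$n)
  in_mask[mask] <- TRUE
  seen <- logical(part$n)
  comps <- list()
  for (s in sort(mask)) {
    if (seen[s]) next
    # BFS over the induced subgraph
    queue <- s
    seen[s] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      members <- c(members, v)
      nb <- nbr[[v]]
      nb <- nb[in_mask[nb] & !seen[nb]]
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    if (length(members) >= min_size)
      comps[[length(comps) + 1L]] <- sort(members)
  }
  if (!length(comps)) return(list())
  sizes <- lengths(comps)
  firsts <- vapply(comps, min, integer(1L))
  ord <- order(-sizes, firsts)
  lapply(seq_along(ord), function(i) {
    m <- comps[[ord[i]]]
    structure(list(duct_id = i, member_ids = m, size = length(m)),
              class = "duct_object")
  })
}

#' @export
print.duct_object <- function(x, ...) {
  cat(sprintf("<duct_object> id %d, %d superpixels\n", x$duct_id, x$size))
  invisible(x)
}

#' Summarise detected ducts as a data frame
#'
#' @param ducts A list of duct objects from [find_ducts()].
#' @param part The partition they were detected on (for bounding boxes).
#' @return Data frame with `duct_id`, `size_superpixels`, `size_pixels` and
#'   the pixel bounding box of each duct.
#' @export
duct_table <- function(ducts, part) {
  if (!length(ducts))
    return(data.frame(duct_id = integer(0), size_superpixels = integer(0),
                      size_pixels = integer(0), row_min = integer(0),
                      row_max = integer(0), col_min = integer(0),
                      col_max = integer(0)))
  do.call(rbind, lapply(ducts, function(d) {
    px <- which(matrix(part$assignment %in% d$member_ids,
                       nrow(part$assignment)), arr.ind = TRUE)
    data.frame(duct_id = d$duct_id, size_superpixels = d$size,
               size_pixels = sum(part$sizes[d$member_ids]),
               row_min = min(px[, 1L]), row_max = max(px[, 1L]),
               col_min = min(px[, 2L]), col_max = max(px[, 2L]))
  }))
}
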