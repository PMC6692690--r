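# The structure feature: one-superpixel-thick layers peeled inward and
# outward from each duct, per-layer tissue histograms, and the 80-dim ROI
# aggregate.

#' Layer names of the structure feature
#'
#' Rows of the layer histogram stack, ordered `inner5 ... inner1,
#' outer1 ... outer5` (deepest inside first).  This order is fixed and
#' bit-stable across versions.
#'
#' @param n_inner,n_outer Number of inner/outer layers (default 5 each).
#' @return Character vector of layer names.
#' @export
layer_names <- function(n_inner = 5, n_outer = 5) {
  c(paste0("inner", rev(seq_len(n_inner))), paste0("outer", seq_len(n_outer)))
}

#' Peel one-superpixel-thick layers around a duct
#'
#' Inner layer k holds the duct members at erosion depth k: layer 1 is the
#' duct boundary (members adjacent to at least one non-member), and deeper
#' layers follow by iteratively removing the current boundary — equivalent
#' to the graph distance from the complement.  Outer layer k holds the
#' non-members at graph distance k from the member set.  Members deeper
#' than `n_inner` and non-members farther than `n_outer` are unassigned.
#'
#' @param duct A duct object from [find_ducts()] (or a bare integer vector
#'   of member superpixel ids).
#' @param part A [superpixel_partition()] with adjacency built.
#' @param n_inner,n_outer Number of layers peeled in each direction
#'   (default 5, matching the structure feature).
#' @return A named list of class `layer_assignment`: one integer vector of
#'   superpixel ids per layer, named as in [layer_names()].
#' @export
peel_layers <- function(duct, part, n_inner = 5, n_outer = 5) {
  members <- if (inherits(duct, "duct_object")) duct$member_ids else as.integer(duct)
  if (any(members < 1L | members > part$n))
    stop("duct members outside the partition")
  nbr <- .adjacency_list(part)
  is_member <- logical(part$n)
  is_member[members] <- TRUE

  # inner layers: multi-source BFS from the complement, restricted to members
  inner <- vector("list", n_inner)
  frontier <- members[vapply(members, function(v) {
    nb <- nbr[[v]]
    length(nb) == 0L || any(!is_member[nb])
  }, logical(1L))]
  # isolated members (no neighbours at all) are boundary by convention
  remaining <- is_member
  for (k in seq_len(n_inner)) {
    inner[[k]] <- sort(frontier)
    remaining[frontier] <- FALSE
    if (!any(remaining)) {
      frontier <- integer(0)
    } else {
      nxt <- unique(unlist(nbr[frontier], use.names = FALSE))
      frontier <- nxt[remaining[nxt]]
    }
    if (!length(frontier)) {
      for (kk in seq_len(n_inner)[-seq_len(k)]) inner[[kk]] <- integer(0)
      break
    }
  }

  # outer layers: multi-source BFS from the member set over non-members
  outer <- vector("list", n_outer)
  visited <- is_member
  frontier <- members
  for (k in seq_len(n_outer)) {
    nxt <- unique(unlist(nbr[frontier], use.names = FALSE))
    nxt <- nxt[!visited[nxt]]
    outer[[k]] <- sort(nxt)
    visited[nxt] <- TRUE
    frontier <- nxt
    if (!length(frontier)) {
      for (kk in seq_len(n_outer)[-seq_len(k)]) outer[[kk]] <- integer(0)
      break
    }
  }

  out <- c(rev(inner), outer)
  names(out) <- layer_names(n_inner, n_outer)
  structure(out, class = "layer_assignment")
}

#' Per-layer tissue histograms for one duct
#'
#' Counts the superpixels of each layer by majority tissue label and
#' normalizes each layer row to sum to 1 (empty layers stay all-zero).
#'
#' @param layers A `layer_assignment` from [peel_layers()].
#' @param part The partition with majority labels assigned.
#' @return An object of class `layer_histogram_stack` with `counts` and
#'   `proportions`, both `n_layers x 8` matrices (rows = layers in stack
#'   order, columns = tissue codes 0..7).
#' @export
layer_histograms <- function(layers, part) {
  if (is.null(part$majority_label))
    stop("majority labels not assigned; call assign_majority_labels() first")
  counts <- t(vapply(layers, function(ids) {
    tabulate(part$majority_label[ids] + 1L, nbins = 8L)
  }, integer(8L)))
  dimnames(counts) <- list(names(layers), .TISSUE_NAMES)
  rs <- rowSums(counts)
  props <- counts / ifelse(rs > 0, rs, 1)
  structure(list(counts = counts, proportions = props),
            class = "layer_histogram_stack")
}

#' @export
print.layer_histogram_stack <- function(x, digits = 2, ...) {
  cat("<layer_histogram_stack>\n")
  print(round(x$proportions, digits))
  invisible(x)
}

#' Aggregate duct layer histograms into the ROI structure feature
#'
#' Diagnostic classes attach to ROIs, not ducts, so the per-duct stacks are
#' combined into a single vector: layer by layer, the raw superpixel counts
#' of all ducts are summed and then L1-normalized (zero rows stay zero),
#' and the resulting `n_layers x 8` matrix is flattened row-major into an
#' 80-entry vector.  Summing raw counts (rather than per-duct proportions)
#' makes the feature dominated by the largest structures in the ROI;
#' `per_duct_normalized = TRUE` switches to summing the per-duct normalized
#' histograms instead.
#'
#' @param stacks List of `layer_histogram_stack` objects (possibly empty).
#' @param roi_id Optional ROI identifier attached as an attribute.
#' @param per_duct_normalized Sum per-duct proportions instead of raw
#'   counts (default `FALSE`).
#' @return Named numeric vector of length `n_layers * 8` (80 by default),
#'   names `layer{-5..-1,+1..+5}_label{0..7}`, with attribute `roi_id`.
#' @export
roi_structure_feature <- function(stacks, roi_id = NULL,
                                  per_duct_normalized = FALSE) {
  if (length(stacks)) {
    mats <- lapply(stacks, function(s)
      if (per_duct_normalized) s$proportions else s$counts)
    total <- Reduce(`+`, mats)
  } else {
    warning("no ducts in ROI", if (!is.null(roi_id)) paste0(" ", roi_id),
            "; structure feature is all-zero")
    nm <- layer_names()
    total <- matrix(0, length(nm), 8L, dimnames = list(nm, .TISSUE_NAMES))
  }
  rs <- rowSums(total)
  norm <- total / ifelse(rs > 0, rs, 1)
  feat <- as.vector(t(norm))
  names(feat) <- structure_feature_names(nrow(norm) / 2, nrow(norm) / 2)
  attr(feat, "roi_id") <- roi_id
  feat
}

#' Column names of the flattened structure feature
#'
#' @param n_inner,n_outer Layer counts (default 5 each).
#' @return Character vector, `layer{-5..-1,+1..+5}_label{0..7}` by default:
#'   negative layer indices are inner (deepest first), positive are outer.
#' @export
structure_feature_names <- function(n_inner = 5, n_outer = 5) {
  lay <- c(-rev(seq_len(n_inner)), seq_len(n_outer))
  as.vector(t(outer(lay, 0:7, function(l, c)
    sprintf("layer%+d_label%d", l, c))))
}

#' Full structure-feature extraction for one ROI
#'
#' Convenience wrapper: detect ducts, peel layers, build histograms and
#' aggregate.
#'
#' @param part Partition with majority labels and adjacency.
#' @param min_duct_size Cleaning threshold passed to [find_ducts()].
#' @param roi_id Optional identifier.
#' @inheritParams roi_structure_feature
#' @return The 80-entry structure feature vector.
#' @export
structure_feature <- function(part, min_duct_size = 3, roi_id = NULL,
                              per_duct_normalized = FALSE) {
  ducts <- find_ducts(part, min_size = min_duct_size)
  stacks <- lapply(ducts, function(d)
    layer_histograms(peel_layers(d, part), part))
  roi_structure_feature(stacks, roi_id = roi_id,
                        per_duct_normalized = per_duct_normalized)
}
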