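# Shared fixtures and independent oracles.

# random valid label grid
random_grid <- function(h, w) matrix(sample(0:7, h * w, replace = TRUE), h, w)

# partition in which every pixel is one superpixel, id = (r-1)*w + c
# (row-major), with adjacency built: the unit lattice used by the layer
# oracle tests
unit_lattice <- function(h, w) {
  a <- matrix(rep(seq_len(h), each = w) * 0L, h, w)
  a[] <- (row(a) - 1L) * w + col(a)
  build_adjacency(superpixel_partition(a))
}

# superpixel ids of TRUE cells of a h x w logical matrix on the unit lattice
px_ids <- function(m) {
  w <- ncol(m)
  sort((row(m)[m] - 1L) * w + col(m)[m])
}

# grow a random 4-connected blob of n_target cells on an h x w grid
random_blob <- function(h, w, n_target) {
  m <- matrix(FALSE, h, w)
  r <- sample(h, 1L); c <- sample(w, 1L)
  m[r, c] <- TRUE
  frontier <- matrix(c(r, c), 1L)
  while (sum(m) < n_target) {
    i <- sample(nrow(frontier), 1L)
    rc <- frontier[i, ]
    moves <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
    rc2 <- rc + moves[sample(4L, 1L), ]
    if (rc2[1L] >= 1 && rc2[1L] <= h && rc2[2L] >= 1 && rc2[2L] <= w) {
      if (!m[rc2[1L], rc2[2L]]) {
        m[rc2[1L], rc2[2L]] <- TRUE
        frontier <- rbind(frontier, rc2)
      } else frontier[i, ] <- rc2
    }
  }
  m
}

# --- independent layer-peeling oracle: one-step set erosion/dilation on the
# pixel grid (matrix shifting), fully separate from the graph-BFS code path

shift_mat <- function(m, dr, dc, pad) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(pad, h, w)
  rs <- seq_len(h) - dr; cs <- seq_len(w) - dc
  ok_r <- rs >= 1 & rs <= h; ok_c <- cs >= 1 & cs <= w
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# out-of-grid counts as "member" so that only true complement cells erode
erode1 <- function(m)
  m & shift_mat(m, 1, 0, TRUE) & shift_mat(m, -1, 0, TRUE) &
    shift_mat(m, 0, 1, TRUE) & shift_mat(m, 0, -1, TRUE)

dilate1 <- function(m)
  m | shift_mat(m, 1, 0, FALSE) | shift_mat(m, -1, 0, FALSE) |
    shift_mat(m, 0, 1, FALSE) | shift_mat(m, 0, -1, FALSE)

oracle_peel <- function(member, n_inner = 5, n_outer = 5) {
  inner <- vector("list", n_inner)
  e <- member
  for (k in seq_len(n_inner)) {
    boundary <- e & !erode1(e)
    inner[[k]] <- px_ids(boundary)
    e <- e & !boundary
  }
  outer <- vector("list", n_outer)
  d <- member
  for (k in seq_len(n_outer)) {
    d2 <- dilate1(d)
    outer[[k]] <- px_ids(d2 & !d)
    d <- d2
  }
  out <- c(rev(inner), outer)
  names(out) <- layer_names(n_inner, n_outer)
  out
}

# label image whose unit-lattice majority labels equal the matrix itself
labeled_unit_lattice <- function(labels) {
  part <- unit_lattice(nrow(labels), ncol(labels))
  assign_majority_labels(part, tissue_label_image(labels))
}
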