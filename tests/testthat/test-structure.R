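test_that("single-superpixel duct peels to inner1 plus its neighbours", {
  part <- unit_lattice(3, 3)
  lay <- peel_layers(5L, part)  # centre cell of the 3x3 lattice
  expect_identical(lay$inner1, 5L)
  expect_length(lay$inner2, 0)
  expect_identical(lay$outer1, sort(c(2L, 4L, 6L, 8L)))
  expect_identical(lay$outer2, sort(c(1L, 3L, 7L, 9L)))
})

test_that("4x4 block in a 6x6 lattice gives the hand-derived layer sizes", {
  part <- unit_lattice(6, 6)
  m <- matrix(FALSE, 6, 6); m[2:5, 2:5] <- TRUE
  lay <- peel_layers(px_ids(m), part)
  expect_identical(lengths(lay)[layer_names()],
                   c(inner5 = 0L, inner4 = 0L, inner3 = 0L, inner2 = 4L,
                     inner1 = 12L, outer1 = 16L, outer2 = 4L, outer3 = 0L,
                     outer4 = 0L, outer5 = 0L))
  # exact sets, not just sizes
  oracle <- oracle_peel(m)
  expect_identical(unclass(lay)[layer_names()], oracle[layer_names()])
})

test_that("peeling equals the erosion/dilation oracle on random blobs", {
  set.seed(6)
  for (i in 1:40) {
    h <- sample(5:20, 1); w <- sample(5:20, 1)
    m <- random_blob(h, w, sample(seq_len(ceiling(h * w / 2)), 1))
    part <- unit_lattice(h, w)
    lay <- peel_layers(px_ids(m), part)
    oracle <- oracle_peel(m)
    expect_identical(unclass(lay)[layer_names()], oracle[layer_names()])
    # disjointness and containment invariants
    all_ids <- unlist(lay)
    expect_identical(anyDuplicated(all_ids), 0L)
    member <- px_ids(m)
    for (k in paste0("inner", 1:5)) expect_true(all(lay[[k]] %in% member))
    for (k in paste0("outer", 1:5)) expect_false(any(lay[[k]] %in% member))
  }
})

test_that("layer histograms count majority labels and normalize rows", {
  # filled 3x3 epithelial duct in stroma: inner1 one-hot at code 2,
  # outer1 one-hot at code 1
  labs <- matrix(1L, 5, 5); labs[2:4, 2:4] <- 2L
  part <- labeled_unit_lattice(labs)
  d <- find_ducts(part)
  expect_length(d, 1)
  hs <- layer_histograms(peel_layers(d[[1]], part), part)
  expect_equal(unname(hs$proportions["inner1", ]), c(0, 0, 1, 0, 0, 0, 0, 0))
  expect_equal(unname(hs$proportions["outer1", ]), c(0, 1, 0, 0, 0, 0, 0, 0))
  # empty layer: all-zero row
  expect_true(all(hs$proportions["inner3", ] == 0))
  expect_equal(unname(hs$counts["inner1", 3]), 8)
})

test_that("every non-empty layer row sums to one on random fixtures", {
  set.seed(7)
  for (i in 1:20) {
    labs <- random_grid(10, 10)
    part <- labeled_unit_lattice(labs)
    m <- random_blob(10, 10, sample(5:40, 1))
    hs <- layer_histograms(peel_layers(px_ids(m), part), part)
    rs <- rowSums(hs$proportions)
    expect_true(all(abs(rs[rs > 0] - 1) < 1e-12))
    expect_true(all(hs$counts >= 0))
  }
})

test_that("ROI aggregation sums counts, so large ducts dominate", {
  labs <- matrix(1L, 12, 20)
  labs[2:9, 2:11] <- 2L     # large 8x10 malignant duct
  labs[10:11, 14:16] <- 4L  # small 2x3 benign duct
  part <- labeled_unit_lattice(labs)
  ducts <- find_ducts(part)
  expect_length(ducts, 2)
  stacks <- lapply(ducts, function(d)
    layer_histograms(peel_layers(d, part), part))
  feat <- roi_structure_feature(stacks)
  expect_length(feat, 80)
  expect_true(all(feat >= 0 & feat <= 1))
  # each 8-entry layer block sums to 1 or 0
  blocks <- matrix(feat, 10, 8, byrow = TRUE)
  bs <- rowSums(blocks)
  expect_true(all(abs(bs[bs > 0] - 1) < 1e-12))
  # dominance: closer in L1 to the large duct's normalized stack
  norm_flat <- function(s) as.vector(t(s$proportions))
  d_large <- sum(abs(feat - norm_flat(stacks[[1]])))
  d_small <- sum(abs(feat - norm_flat(stacks[[2]])))
  expect_lt(d_large, d_small)
  # duplication and ordering invariance
  expect_equal(unname(roi_structure_feature(stacks[c(1, 1, 2, 2)])),
               unname(roi_structure_feature(rev(stacks))))
  expect_equal(unname(roi_structure_feature(stacks[c(1, 1)])),
               unname(roi_structure_feature(stacks[1])))
  # per-duct-normalized variant weights the two ducts equally
  f2 <- roi_structure_feature(stacks, per_duct_normalized = TRUE)
  expect_false(isTRUE(all.equal(unname(f2), unname(feat))))
  # empty ROI: all-zero with a warning
  expect_warning(f0 <- roi_structure_feature(list()), "no ducts")
  expect_identical(unname(f0), rep(0, 80))
})
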