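test_that("lattice superpixels tile exactly and conserve pixels", {
  img <- tissue_label_image(matrix(1L, 10, 10))
  p <- lattice_superpixels(img, 25)
  expect_equal(p$n, 4)
  expect_true(all(p$sizes == 25))
  # default target area is 3000 px
  expect_equal(formals(lattice_superpixels)$target_area, 3000)
  # property: sizes sum to the image area on random shapes
  set.seed(2)
  for (i in 1:20) {
    h <- sample(5:40, 1); w <- sample(5:40, 1)
    ta <- sample(1:30, 1)
    pp <- lattice_superpixels(matrix(0L, h, w), ta)
    expect_equal(sum(pp$sizes), h * w)
    expect_identical(sort(unique(as.vector(pp$assignment))), seq_len(pp$n))
  }
  expect_warning(lattice_superpixels(matrix(0L, 4, 4), 100),
                 "single superpixel")
})

test_that("majority labels follow the modal rule with lowest-code ties", {
  part <- superpixel_partition(matrix(c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L), 2))
  img <- tissue_label_image(matrix(c(2L, 2L, 2L, 5L, 1L, 1L, 4L, 4L), 2))
  part <- assign_majority_labels(part, img)
  expect_identical(part$majority_label, c(2L, 1L))  # {2,2,2,5} -> 2; tie {1,1,4,4} -> 1
  # uniform superpixel keeps its only label
  u <- assign_majority_labels(superpixel_partition(matrix(1L, 3, 3)),
                              tissue_label_image(matrix(6L, 3, 3)))
  expect_identical(u$majority_label, 6L)
  expect_error(assign_majority_labels(part, tissue_label_image(matrix(0L, 3, 3))),
               "shape")
  # permutation invariance of the pixel order within a superpixel
  set.seed(3)
  g <- random_grid(12, 12)
  p1 <- assign_majority_labels(lattice_superpixels(g, 16), g)
  p2 <- assign_majority_labels(lattice_superpixels(g[12:1, ], 16), g[12:1, ])
  expect_setequal(p1$majority_label, p2$majority_label)
})

test_that("adjacency matches the lattice closed form and is loop-free", {
  # two side-by-side tiles: one edge
  p <- build_adjacency(superpixel_partition(matrix(c(1L, 1L, 2L, 2L), 2)))
  expect_identical(p$edges, matrix(c(1L, 2L), 1))
  # m x n lattice: m(n-1) + n(m-1) edges
  for (mn in list(c(3, 4), c(5, 5), c(2, 7))) {
    m <- mn[1]; n <- mn[2]
    pp <- unit_lattice(m, n)
    expect_equal(nrow(pp$edges), m * (n - 1) + n * (m - 1))
    expect_true(all(pp$edges[, 1] < pp$edges[, 2]))
  }
  # single superpixel: no edges
  expect_equal(nrow(build_adjacency(superpixel_partition(matrix(1L, 3, 3)))$edges), 0)
})

test_that("SLIC partitions satisfy the invariants", {
  # uniform colour, target area equal to the image: one superpixel
  u <- array(0.5, c(8, 8, 3))
  expect_equal(slic_superpixels(u, 64)$n, 1)
  # uniform colour: near-regular tiles within 2x of the target area
  u <- array(0.5, c(60, 48, 3))
  p <- slic_superpixels(u, 144)
  expect_true(all(p$sizes >= 72) && all(p$sizes <= 288))
  expect_equal(sum(p$sizes), 60 * 48)
  # noisy colour: coverage and contiguity invariants still hold
  set.seed(4)
  arr <- array(runif(40 * 40 * 3), c(40, 40, 3))
  p2 <- slic_superpixels(arr, 100)
  expect_equal(sum(p2$sizes), 1600)
  expect_identical(sort(unique(as.vector(p2$assignment))), seq_len(p2$n))
  # every superpixel is 4-connected (one component of constant id)
  cc <- ductlayers:::cc_label_values(p2$assignment)
  expect_equal(max(cc), p2$n)
  expect_error(slic_superpixels(arr, 100, label_image = matrix(0L, 10, 10)),
               "does not match")
})
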