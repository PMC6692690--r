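test_that("duct mask selects epithelium, secretion and necrosis", {
  labs <- matrix(c(1L, 4L, 5L, 3L), 1)  # stroma, benign epi, secretion, blood
  part <- labeled_unit_lattice(labs)
  expect_identical(duct_mask(part), c(2L, 3L))
  # all-stroma: empty
  expect_length(duct_mask(labeled_unit_lattice(matrix(1L, 3, 3))), 0)
  # necrosis-only superpixel is included
  expect_identical(duct_mask(labeled_unit_lattice(matrix(7L, 1, 1))), 1L)
  expect_error(duct_mask(unit_lattice(2, 2)), "majority labels")
})

test_that("connected components with cleaning and deterministic order", {
  # two 2x2 epithelium blobs separated by stroma
  labs <- matrix(1L, 4, 7)
  labs[1:2, 1:2] <- 4L
  labs[3:4, 5:7] <- 2L
  part <- labeled_unit_lattice(labs)
  d <- find_ducts(part, min_size = 3)
  expect_length(d, 2)
  # ordering: decreasing size (6 then 4), ids renumbered 1..n
  expect_identical(sapply(d, `[[`, "size"), c(6L, 4L))
  expect_identical(sapply(d, `[[`, "duct_id"), 1:2)
  expect_identical(d[[1]]$member_ids, px_ids(labs == 2L))
  # 1-superpixel blob removed by cleaning at min_size 3
  labs2 <- matrix(1L, 3, 3); labs2[2, 2] <- 4L
  expect_length(find_ducts(labeled_unit_lattice(labs2), min_size = 3), 0)
  expect_length(find_ducts(labeled_unit_lattice(labs2), min_size = 1), 1)
})

test_that("components equal the igraph oracle on random instances", {
  skip_if_not_installed("igraph")
  set.seed(5)
  for (i in 1:25) {
    h <- sample(4:12, 1); w <- sample(4:12, 1)
    labs <- matrix(sample(0:7, h * w, replace = TRUE, prob = c(2, 3, 2, 1, 2, 1, 1, 1)), h, w)
    part <- labeled_unit_lattice(labs)
    mask <- duct_mask(part)
    d <- find_ducts(part, min_size = 1)
    # oracle: igraph components of the induced subgraph
    e <- part$edges
    keep <- e[, 1] %in% mask & e[, 2] %in% mask
    g <- igraph::graph_from_data_frame(
      as.data.frame(matrix(as.character(e[keep, ]), ncol = 2)),
      directed = FALSE,
      vertices = data.frame(name = as.character(mask)))
    comp <- igraph::components(g)
    oracle <- unname(split(as.integer(names(comp$membership)), comp$membership))
    oracle <- lapply(oracle, sort)
    mine <- lapply(d, `[[`, "member_ids")
    # same set of components (ordering checked separately)
    expect_setequal(lapply(mine, paste, collapse = ","),
                    lapply(oracle, paste, collapse = ","))
    # ordering rule: decreasing size, ties by smallest member
    sz <- lengths(mine)
    expect_true(all(diff(sz) <= 0))
    firsts <- vapply(mine, min, integer(1))
    ties <- which(diff(sz) == 0)
    expect_true(all(firsts[ties] < firsts[ties + 1]))
    # partition property: union of members = mask
    expect_setequal(unlist(mine), mask)
  }
})
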