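test_that("tissue vocabulary is closed and bijective", {
  tl <- tissue_labels()
  expect_identical(tl$code, 0:7)
  expect_identical(tl$name[1], "background")
  expect_identical(tl$name[8], "necrosis")
  expect_identical(tissue_code(tl$name), tl$code)
  expect_identical(tissue_name(tl$code), tl$name)
  expect_error(tissue_code("adh"), "unknown tissue name")
  expect_error(tissue_name(8), "0..7")
})

test_that("label image construction validates codes and shape", {
  img <- tissue_label_image(matrix(0L, 2, 2))
  expect_identical(dim(img$grid), c(2L, 2L))
  bad <- matrix(0L, 3, 3); bad[2, 3] <- 9L
  expect_error(tissue_label_image(bad), "value 9 .*row 2, col 3")
  expect_error(tissue_label_image(matrix(integer(0), 0, 0)), "height")
})

test_that("write/read round-trips grids bit-identically", {
  tmp <- withr::local_tempdir()
  # all-necrosis 4x4
  img <- tissue_label_image(matrix(7L, 4, 4))
  p <- file.path(tmp, "necrosis.png")
  write_label_image(img, p)
  expect_identical(read_label_image(p)$grid, img$grid)
  # property: random 32x32 grids
  set.seed(1)
  for (i in 1:10) {
    g <- random_grid(32, 32)
    p <- file.path(tmp, sprintf("g%d.png", i))
    write_label_image(tissue_label_image(g), p)
    expect_identical(read_label_image(p)$grid, g)
  }
  expect_error(write_label_image(matrix(8L, 2, 2), file.path(tmp, "x.png")),
               "value 8")
})

test_that("reading rejects rasters outside the vocabulary", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "bad.png")
  png::writePNG(matrix(9 / 255, 2, 2), p)   # grayscale value 9
  expect_error(read_label_image(p), "value 9")
  expect_error(read_label_image(file.path(tmp, "missing.png")), "not found")
  # RGB raster through the documented palette round-trips
  g <- random_grid(8, 8)
  pal <- t(grDevices::col2rgb(tissue_labels()$color) / 255)
  arr <- array(0, c(8, 8, 3))
  for (ch in 1:3) arr[, , ch] <- matrix(pal[g + 1, ch], 8, 8)
  p2 <- file.path(tmp, "rgb.png")
  png::writePNG(arr, p2)
  expect_identical(read_label_image(p2)$grid, g)
})

test_that("manifest reading normalizes and validates diagnoses", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "m.csv")
  write.csv(data.frame(roi_id = c("a", "b", "c"),
                       label_image_path = c("a.png", "b.png", "c.png"),
                       diagnosis = c("benign", "DCIS ", "invasive")),
            p, row.names = FALSE)
  m <- read_roi_manifest(p)
  expect_equal(nrow(m), 3)
  expect_identical(m$diagnosis, c("benign", "dcis", "invasive"))
  expect_true(all(startsWith(m$label_image_path, tmp)))

  write.csv(data.frame(roi_id = "x", label_image_path = "x.png",
                       diagnosis = "adh"), p, row.names = FALSE)
  expect_error(read_roi_manifest(p), "allowed: benign, atypia, dcis, invasive")
  write.csv(data.frame(roi_id = "x", diagnosis = "benign"), p,
            row.names = FALSE)
  expect_error(read_roi_manifest(p), "missing column")
})
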