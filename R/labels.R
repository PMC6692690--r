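# Tissue-label vocabulary, label images and ROI manifests.

.TISSUE_NAMES <- c("background", "normal_stroma", "malignant_epithelium",
                   "blood", "benign_epithelium", "secretion",
                   "desmoplastic_stroma", "necrosis")

# fixed 8-colour palette used when reading/writing RGB label rasters;
# documented bit-exactly in the README
.TISSUE_PALETTE <- c(background = "#FFFFFF", normal_stroma = "#F8C8DC",
                     malignant_epithelium = "#5E2D79", blood = "#C0181D",
                     benign_epithelium = "#2C7FB8", secretion = "#F2E33B",
                     desmoplastic_stroma = "#F58231", necrosis = "#1A1A1A")

.DIAGNOSES <- c("benign", "atypia", "dcis", "invasive")

#' The eight-class tissue vocabulary
#'
#' Tissue codes are 0-based: 0 = background, 1 = normal stroma,
#' 2 = malignant epithelium, 3 = blood, 4 = benign epithelium,
#' 5 = secretion, 6 = desmoplastic stroma, 7 = necrosis.
#'
#' @return A data frame with columns `code` (integer 0..7), `name` and
#'   `color` (hex, the palette used for RGB label rasters).
#' @examples
#' tissue_labels()
#' @export
tissue_labels <- function() {
  data.frame(code = 0:7, name = .TISSUE_NAMES,
             color = unname(.TISSUE_PALETTE), stringsAsFactors = FALSE)
}

#' Convert between tissue codes and names
#'
#' @param name Tissue name(s) from the vocabulary of [tissue_labels()].
#' @param code Integer tissue code(s) in 0..7.
#' @return `tissue_code()` returns integer codes; `tissue_name()` returns
#'   character names.
#' @examples
#' tissue_code("necrosis")
#' tissue_name(0:7)
#' @export
tissue_code <- function(name) {
  i <- match(name, .TISSUE_NAMES)
  if (anyNA(i))
    stop("unknown tissue name(s): ",
         paste(name[is.na(i)], collapse = ", "),
         "; allowed: ", paste(.TISSUE_NAMES, collapse = ", "))
  i - 1L
}

#' @rdname tissue_code
#' @export
tissue_name <- function(code) {
  code <- as.integer(code)
  if (any(is.na(code) | code < 0L | code > 7L))
    stop("tissue codes must be integers in 0..7")
  .TISSUE_NAMES[code + 1L]
}

#' Construct a tissue label image
#'
#' A tissue label image is an integer matrix (rows = image rows, origin
#' top-left) whose cells are tissue codes 0..7.
#'
#' @param grid An integer matrix with values in 0..7.
#' @return An object of class `tissue_label_image` with element `grid`.
#' @examples
#' img <- tissue_label_image(matrix(0L, 4, 4))
#' @export
tissue_label_image <- function(grid) {
  if (!is.matrix(grid)) stop("`grid` must be a matrix")
  if (nrow(grid) < 1L || ncol(grid) < 1L)
    stop("label image must have height >= 1 and width >= 1")
  g <- grid
  storage.mode(g) <- "integer"
  .check_codes(g)
  structure(list(grid = g), class = "tissue_label_image")
}

# validation shared by constructors and readers; reports the first offending
# value and its (row, col) location
.check_codes <- function(g, what = "label image") {
  bad <- which(is.na(g) | g < 0L | g > 7L)
  if (length(bad)) {
    i <- bad[1L]
    rc <- arrayInd(i, dim(g))
    stop(sprintf(
      "%s contains value %s outside the tissue vocabulary 0..7 at (row %d, col %d); %d offending pixel(s) in total",
      what, format(g[i]), rc[1L], rc[2L], length(bad)))
  }
  invisible(g)
}

#' @export
print.tissue_label_image <- function(x, ...) {
  tab <- tabulate(x$grid + 1L, nbins = 8L)
  cat(sprintf("<tissue_label_image> %d x %d pixels\n",
              nrow(x$grid), ncol(x$grid)))
  present <- which(tab > 0L)
  cat("  labels:",
      paste(sprintf("%s (%d px)", .TISSUE_NAMES[present], tab[present]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Read a tissue label image from a PNG file
#'
#' Accepts single-channel (grayscale) PNGs whose 8-bit pixel values are the
#' tissue codes 0..7, and RGB(A) PNGs whose colours are the documented
#' 8-colour palette (see [tissue_labels()]).
#'
#' @param path Path to a PNG file.
#' @return A [tissue_label_image()].
#' @export
read_label_image <- function(path) {
  if (!file.exists(path)) stop("label image file not found: ", path)
  a <- png::readPNG(path)
  if (is.matrix(a)) {
    g <- round(a * 255)
  } else if (length(dim(a)) == 3L) {
    hex <- grDevices::rgb(a[, , 1L], a[, , 2L], a[, , 3L])
    code <- match(toupper(hex), toupper(.TISSUE_PALETTE)) - 1L
    g <- matrix(code, nrow = dim(a)[1L], ncol = dim(a)[2L])
    if (anyNA(g)) {
      i <- which(is.na(g))[1L]
      rc <- arrayInd(i, dim(g))
      stop(sprintf(
        "RGB label image %s contains colour %s at (row %d, col %d) outside the 8-colour tissue palette",
        path, hex[i], rc[1L], rc[2L]))
    }
  } else {
    stop("unsupported PNG layout in ", path)
  }
  storage.mode(g) <- "integer"
  .check_codes(g, what = paste0("label image ", path))
  tissue_label_image(g)
}

#' Write a tissue label image to a PNG file
#'
#' Stores the grid as a single-channel 8-bit PNG with pixel value = tissue
#' code, so that [read_label_image()] round-trips bit-identically.
#'
#' @param img A [tissue_label_image()] (or a bare 0..7 integer matrix).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_label_image <- function(img, path) {
  if (!inherits(img, "tissue_label_image")) img <- tissue_label_image(img)
  png::writePNG(img$grid / 255, target = path)
  invisible(path)
}

#' Read an ROI manifest
#'
#' The manifest is a CSV with columns `roi_id`, `label_image_path` and
#' `diagnosis` (one of benign, atypia, dcis, invasive; matched
#' case-insensitively).  Relative image paths are resolved against the
#' manifest's directory.
#'
#' @param path Path to the manifest CSV.
#' @return A data frame with one row per ROI and normalized `diagnosis`.
#' @export
read_roi_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("roi_id", "label_image_path", "diagnosis")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "))
  m$diagnosis <- tolower(trimws(m$diagnosis))
  bad <- setdiff(unique(m$diagnosis), .DIAGNOSES)
  if (length(bad))
    stop("unknown diagnosis value(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(.DIAGNOSES, collapse = ", "))
  rel <- !grepl("^(/|[A-Za-z]:)", m$label_image_path)
  m$label_image_path[rel] <- file.path(dirname(path), m$label_image_path[rel])
  m[need]
}

#' The four consensus diagnostic categories
#'
#' @return Character vector `c("benign", "atypia", "dcis", "invasive")`.
#' @export
diagnosis_categories <- function() .DIAGNOSES
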