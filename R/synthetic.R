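# Synthetic tissue-label maps with category-specific ductal morphology.
# The generator renders the layered signatures that distinguish the four
# diagnostic categories: benign ducts are thin epithelial rings around an
# open (background) lumen, atypia thickens the rim and partially fills the
# lumen with secretion, DCIS fills the duct with malignant epithelium
# (often with central necrosis), and invasive cancer shows irregular
# malignant nests in desmoplastic stroma with no closed rims.

#' Specification of a synthetic ROI
#'
#' Category presets (all lengths in pixels; `tile_px` is the side of the
#' downstream lattice superpixel, default 8, i.e. `target_area = 64`):
#' \describe{
#'   \item{benign}{3 ducts, radius 22–36, benign-epithelium rim 1.25
#'     superpixels thick, background lumen, normal stroma}
#'   \item{atypia}{3 ducts, radius 24–38, rim thickened to 2.5
#'     superpixels, secretion filling the outer half of the lumen}
#'   \item{dcis}{3 ducts, radius 26–40, filled with malignant epithelium,
#'     central necrosis core (70% of ducts), normal stroma}
#'   \item{invasive}{12 irregular malignant nests, radius 6–14, in
#'     desmoplastic stroma, no closed rims}
#' }
#'
#' @param category One of `benign`, `atypia`, `dcis`, `invasive`.
#' @param size Image side in pixels (square ROI, default 256).
#' @param n_ducts Number of ducts / nests; `NULL` for the preset.
#' @param radius_range Length-2 pixel range of duct radii; `NULL` for the
#'   preset.
#' @param rim_thickness Epithelial rim thickness in superpixels; `NULL`
#'   for the preset (ignored for filled categories).
#' @param noise_rate Per-pixel probability of flipping to a uniformly
#'   random other label, in `[0, 0.2]` (default 0.02).
#' @param tile_px Side of one superpixel tile in pixels (default 8).
#' @param seed RNG seed making the ROI fully deterministic.
#' @return An object of class `synthetic_roi_spec`.
#' @export
synthetic_roi_spec <- function(category, size = 256, n_ducts = NULL,
                               radius_range = NULL, rim_thickness = NULL,
                               noise_rate = 0.02, tile_px = 8, seed = 1) {
  category <- match.arg(category, .DIAGNOSES)
  if (noise_rate < 0 || noise_rate > 0.2)
    stop("`noise_rate` must be in [0, 0.2]")
  preset <- switch(category,
    benign = list(n_ducts = 3, radius_range = c(22, 36), rim_thickness = 1.25,
                  rim_label = 4L, fill_label = 0L, stroma_label = 1L),
    atypia = list(n_ducts = 3, radius_range = c(24, 38), rim_thickness = 2.5,
                  rim_label = 4L, fill_label = 5L, stroma_label = 1L),
    dcis = list(n_ducts = 3, radius_range = c(26, 40), rim_thickness = NA,
                rim_label = 2L, fill_label = 2L, stroma_label = 1L),
    invasive = list(n_ducts = 12, radius_range = c(6, 14), rim_thickness = NA,
                    rim_label = 2L, fill_label = 2L, stroma_label = 6L))
  if (!is.null(n_ducts)) preset$n_ducts <- n_ducts
  if (!is.null(radius_range)) preset$radius_range <- radius_range
  if (!is.null(rim_thickness)) preset$rim_thickness <- rim_thickness
  structure(c(list(category = category, size = as.integer(size),
                   noise_rate = noise_rate, tile_px = tile_px,
                   seed = as.integer(seed)), preset),
            class = "synthetic_roi_spec")
}

# pixel membership of a rotated ellipse
.ellipse_mask <- function(size, cy, cx, a, b, theta) {
  y <- matrix(seq_len(size), size, size) - cy
  x <- matrix(seq_len(size), size, size, byrow = TRUE) - cx
  u <- x * cos(theta) + y * sin(theta)
  v <- -x * sin(theta) + y * cos(theta)
  if (a < 0.5) a <- 0.5
  if (b < 0.5) b <- 0.5
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate one synthetic ROI
#'
#' Deterministic given `spec$seed`.  Ducts are ellipses with randomized
#' size, eccentricity and orientation, placed without overlap; label noise
#' (uniform flips) is applied after rendering.  The returned `duct_mask`
#' marks the noise-free pixels whose labels fall in the duct-mask
#' vocabulary (epithelium, secretion, necrosis).
#'
#' @param spec A [synthetic_roi_spec()].
#' @return List with `image` (a [tissue_label_image()]), `duct_mask`
#'   (logical matrix, ground truth before noise) and `spec`.
#' @export
generate_roi <- function(spec) {
  stopifnot(inherits(spec, "synthetic_roi_spec"))
  set.seed(spec$seed)
  size <- spec$size
  g <- matrix(spec$stroma_label, size, size)
  rim_px <- if (is.na(spec$rim_thickness)) 0 else spec$rim_thickness * spec$tile_px

  # rejection-sample non-overlapping centres
  centres <- matrix(numeric(0), 0L, 3L) # cy, cx, r
  sep <- if (spec$category == "invasive") 6 else 8
  for (d in seq_len(spec$n_ducts)) {
    r <- runif(1, spec$radius_range[1L], spec$radius_range[2L])
    margin <- r + 4
    placed <- FALSE
    for (try in seq_len(400L)) {
      cy <- runif(1, margin, size - margin)
      cx <- runif(1, margin, size - margin)
      if (nrow(centres) == 0L ||
          all(sqrt((centres[, 1L] - cy)^2 + (centres[, 2L] - cx)^2) >
              centres[, 3L] + r + sep)) {
        centres <- rbind(centres, c(cy, cx, r))
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop(sprintf(
        "could not place %d non-overlapping ducts of radius %g..%g in a %d px image; use fewer or smaller ducts",
        spec$n_ducts, spec$radius_range[1L], spec$radius_range[2L], size))
  }

  for (d in seq_len(nrow(centres))) {
    cy <- centres[d, 1L]; cx <- centres[d, 2L]; r <- centres[d, 3L]
    ecc <- runif(1, 0.7, 1)
    theta <- runif(1, 0, pi)
    a <- r; b <- r * ecc
    if (spec$category == "invasive") {
      # irregular nest: union of the ellipse and 3 satellite bumps
      m <- .ellipse_mask(size, cy, cx, a, b, theta)
      for (s in seq_len(3L)) {
        off <- runif(2, -r * 0.7, r * 0.7)
        m <- m | .ellipse_mask(size, cy + off[1L], cx + off[2L],
                               r * runif(1, 0.3, 0.6), r * runif(1, 0.3, 0.6),
                               runif(1, 0, pi))
      }
      g[m] <- spec$fill_label
    } else if (spec$category == "dcis") {
      m <- .ellipse_mask(size, cy, cx, a, b, theta)
      g[m] <- spec$fill_label
      if (runif(1) < 0.7) {
        core <- .ellipse_mask(size, cy, cx, a * 0.35, b * 0.35, theta)
        g[core] <- 7L # central necrosis
      }
    } else {
      outer_m <- .ellipse_mask(size, cy, cx, a, b, theta)
      lumen <- .ellipse_mask(size, cy, cx, a - rim_px, b - rim_px, theta)
      g[outer_m & !lumen] <- spec$rim_label
      if (spec$category == "benign") {
        g[lumen] <- 0L # open lumen appears as background
      } else {
        # atypia: secretion fills the outer half of the lumen, the very
        # centre stays open
        la <- max(a - rim_px, 0.5); lb <- max(b - rim_px, 0.5)
        centre_m <- .ellipse_mask(size, cy, cx, la * 0.5, lb * 0.5, theta)
        g[lumen & !centre_m] <- spec$fill_label
        g[centre_m] <- 0L
      }
    }
  }

  # occasional blood specks in the stroma (nuisance variation)
  for (s in seq_len(2L)) {
    sy <- runif(1, 8, size - 8); sx <- runif(1, 8, size - 8)
    sp <- .ellipse_mask(size, sy, sx, runif(1, 2, 4), runif(1, 2, 4), 0)
    sp <- sp & (g == spec$stroma_label)
    g[sp] <- 3L
  }

  duct_mask <- matrix(g %in% .DUCT_MASK_CODES, size, size)

  if (spec$noise_rate > 0) {
    flip <- which(runif(length(g)) < spec$noise_rate)
    if (length(flip)) {
      old <- g[flip]
      shift <- sample(7L, length(flip), replace = TRUE)
      g[flip] <- (old + shift) %% 8L
    }
  }

  list(image = tissue_label_image(g), duct_mask = duct_mask, spec = spec)
}

#' Generate a labelled synthetic dataset on disk
#'
#' Writes `n_per_category` label images per diagnostic category plus a
#' manifest CSV compatible with [read_roi_manifest()].  Per-ROI seeds are
#' derived deterministically from `seed`.
#'
#' @param n_per_category ROIs per category (>= 1).
#' @param dir Output directory (created if needed).
#' @param seed Base seed.
#' @param categories Categories to generate (default all four).
#' @param ... Overrides passed to [synthetic_roi_spec()] (e.g.
#'   `noise_rate`, `size`).
#' @return The manifest data frame (with paths resolved), invisibly.
#' @export
generate_dataset <- function(n_per_category, dir, seed = 1,
                             categories = diagnosis_categories(), ...) {
  if (n_per_category < 1) stop("`n_per_category` must be >= 1")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  counter <- 0L
  for (cat in categories) {
    for (i in seq_len(n_per_category)) {
      counter <- counter + 1L
      roi_seed <- (abs(seed) %% 100000L) * 10000L + counter
      spec <- synthetic_roi_spec(cat, seed = roi_seed, ...)
      roi <- generate_roi(spec)
      fname <- sprintf("%s_%03d.png", cat, i)
      write_label_image(roi$image, file.path(dir, fname))
      rows[[counter]] <- data.frame(roi_id = sprintf("%s_%03d", cat, i),
                                    label_image_path = fname,
                                    diagnosis = cat,
                                    stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(read_roi_manifest(file.path(dir, "manifest.csv")))
}
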