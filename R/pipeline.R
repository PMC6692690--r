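# Pipeline orchestration: manifest -> superpixels -> ducts -> features ->
# evaluation, with reproducible seeds and structured outputs.
# A command-line front end lives in inst/scripts/ductlayers.

#' Extract ROI features from one label image
#'
#' Runs the superpixel, duct and feature stages on a single tissue label
#' map.
#'
#' @param img A [tissue_label_image()] (or path to one).
#' @param feature `"structure"`, `"distribution"` or `"both"`.
#' @param target_area Superpixel area in pixels (default 3000; use
#'   `tile_px^2` = 64 for the synthetic fixtures).
#' @param min_duct_size Duct cleaning threshold in superpixels.
#' @param rgb Optional RGB array for the SLIC backend; the lattice backend
#'   is used when absent.
#' @param compactness SLIC compactness (ignored by the lattice backend).
#' @return Named numeric feature vector (80, 44 or 124 entries).
#' @export
extract_features <- function(img, feature = c("both", "structure", "distribution"),
                             target_area = 3000, min_duct_size = 3,
                             rgb = NULL, compactness = 10) {
  feature <- match.arg(feature)
  if (is.character(img)) img <- read_label_image(img)
  part <- if (is.null(rgb)) {
    lattice_superpixels(img, target_area)
  } else {
    slic_superpixels(rgb, target_area, compactness, label_image = img)
  }
  part <- assign_majority_labels(part, img)
  part <- build_adjacency(part)
  out <- numeric(0)
  if (feature %in% c("both", "structure"))
    out <- c(out, structure_feature(part, min_duct_size = min_duct_size))
  if (feature %in% c("both", "distribution"))
    out <- c(out, roi_distribution_feature(part))
  out
}

#' Read a pipeline run configuration
#'
#' YAML (or JSON) file with fields `manifest`, `feature`, `target_area`,
#' `min_duct_size`, `out_dir`, `seed` and an optional `eval` block
#' mirroring [eval_config()].  Missing fields take the defaults below.
#'
#' @param path Path to a YAML/JSON config file, or a named list.
#' @return A validated config list of class `run_config`.
#' @export
run_config <- function(path) {
  cfg <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
  } else as.list(path)
  defaults <- list(feature = "both", target_area = 3000, min_duct_size = 3,
                   out_dir = ".", seed = 1, eval = list())
  cfg <- utils::modifyList(defaults, cfg)
  cfg$feature <- match.arg(cfg$feature, c("both", "structure", "distribution"))
  if (is.null(cfg$manifest)) stop("config must name a `manifest`")
  if (!file.exists(cfg$manifest)) stop("manifest not found: ", cfg$manifest)
  cfg$eval <- do.call(eval_config, utils::modifyList(
    list(base_seed = cfg$seed), cfg$eval))
  structure(cfg, class = "run_config")
}

#' Extract features for every ROI in a manifest
#'
#' Writes `features.csv` (one row per ROI: `roi_id`, `diagnosis`, feature
#' columns) and a sidecar `features_meta.json` with the seed, package
#' version and config hash.  Per-ROI failures are logged and skipped; the
#' number of failures is returned in the summary.
#'
#' @param config A [run_config()] (or path / named list accepted by it).
#' @return Invisibly, a list with the feature `table`, output `path` and
#'   `n_failed`.
#' @export
run_extract <- function(config) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  manifest <- read_roi_manifest(cfg$manifest)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  failed <- character(0)
  for (i in seq_len(nrow(manifest))) {
    rec <- manifest[i, ]
    feat <- tryCatch(
      extract_features(rec$label_image_path, feature = cfg$feature,
                       target_area = cfg$target_area,
                       min_duct_size = cfg$min_duct_size),
      error = function(e) {
        message("ROI ", rec$roi_id, " failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(feat)) {
      failed <- c(failed, rec$roi_id)
      next
    }
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(roi_id = rec$roi_id, diagnosis = rec$diagnosis,
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(feat), check.names = FALSE))
  }
  if (!length(rows)) stop("no ROI could be processed")
  tab <- do.call(rbind, rows)
  out_csv <- file.path(cfg$out_dir, "features.csv")
  write.csv(tab, out_csv, row.names = FALSE)
  meta <- list(seed = cfg$seed, feature = cfg$feature,
               target_area = cfg$target_area,
               min_duct_size = cfg$min_duct_size,
               package_version = as.character(packageVersion("ductlayers")),
               config_hash = .config_hash(cfg), n_failed = length(failed),
               failed_rois = failed)
  jsonlite::write_json(meta, file.path(cfg$out_dir, "features_meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(table = tab, path = out_csv, n_failed = length(failed)))
}

.config_hash <- function(cfg) {
  plain <- cfg
  class(plain) <- NULL
  plain$eval <- unclass(plain$eval)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(plain, auto_unbox = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Evaluate the three diagnostic tasks on an extracted feature table
#'
#' Runs [evaluate_task()] for each hierarchical task and writes a JSON
#' report (three tasks x accuracy/sensitivity/specificity, both per-repeat
#' means and pooled-contingency versions, plus the per-repeat values).
#'
#' @param config A [run_config()] (or path / named list).
#' @param features Feature table from [run_extract()] (data frame or path
#'   to `features.csv`); defaults to `features.csv` under the config's
#'   `out_dir`.
#' @return Invisibly, the report list (also written to `report.json`).
#' @export
run_evaluate <- function(config, features = NULL) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  if (is.null(features)) features <- file.path(cfg$out_dir, "features.csv")
  tab <- if (is.character(features)) {
    read.csv(features, stringsAsFactors = FALSE, check.names = FALSE)
  } else features
  if (!all(c("roi_id", "diagnosis") %in% names(tab)))
    stop("feature table must have roi_id and diagnosis columns")
  if (any(is.na(tab$diagnosis) | !nzchar(tab$diagnosis)))
    stop("missing diagnosis for ROI(s): ",
         paste(tab$roi_id[is.na(tab$diagnosis) | !nzchar(tab$diagnosis)],
               collapse = ", "))
  x <- as.matrix(tab[, setdiff(names(tab), c("roi_id", "diagnosis")),
                     drop = FALSE])
  report <- lapply(diagnosis_tasks(), function(task) {
    res <- evaluate_task(x, tab$diagnosis, task, cfg$eval)
    list(task = task$name, n = res$n,
         mean = res$means, pooled = res$pooled,
         per_repeat = res$repeats[c("repeat_id", "accuracy", "sensitivity",
                                    "specificity", "TP", "TN", "FP", "FN")])
  })
  out <- list(config = list(seed = cfg$seed, feature = cfg$feature,
                            n_repeats = cfg$eval$n_repeats,
                            pca_components = cfg$eval$pca_components,
                            config_hash = .config_hash(cfg)),
              tasks = report)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(out, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(out)
}
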