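#' Read a 4D DWI volume with its b-value/NEX sidecars
#'
#' NIfTI image plus FSL-style `.bval` sidecar and a parallel `.nex` file
#' (whitespace-separated; NEX defaults to 1 when the file is absent). The
#' voxel-to-world affine is retained and propagated to written maps.
#'
#' @param image_path Path to a 4D NIfTI file.
#' @param bval_path,nex_path Sidecar paths; default: `image_path` with its
#'   extension replaced.
#' @return A [dwi_volume].
#' @export
read_dwi <- function(image_path,
                     bval_path = sub("\\.nii(\\.gz)?$", ".bval", image_path),
                     nex_path = sub("\\.nii(\\.gz)?$", ".nex", image_path)) {
  img <- RNifti::readNifti(image_path)
  d <- dim(img)
  if (length(d) != 4) stop("expected a 4D NIfTI image")
  scheme <- read_scheme(bval_path, nex_path)
  if (length(scheme$b) != d[4]) {
    stop(sprintf("sidecar mismatch: image has %d frames but sidecar has %d b-values",
                 d[4], length(scheme$b)))
  }
  dwi_volume(array(as.numeric(img), dim = d), scheme,
             affine = structure(RNifti::xform(img), class = NULL))
}

#' Write a phantom (or any DWI volume) as NIfTI + sidecars
#'
#' @param volume A [dwi_volume] or [make_phantom] result.
#' @param path Output NIfTI path (`.nii` or `.nii.gz`).
#' @return Invisibly, the image path.
#' @export
write_dwi <- function(volume, path) {
  if (inherits(volume, "dwi_phantom")) {
    volume <- dwi_volume(volume$data, volume$scheme)
  }
  RNifti::writeNifti(RNifti::asNifti(volume$data), path)
  write_scheme(volume$scheme,
               sub("\\.nii(\\.gz)?$", ".bval", path),
               sub("\\.nii(\\.gz)?$", ".nex", path))
  invisible(path)
}

#' Write parameter maps as one float32 NIfTI per quantity
#'
#' @param maps A `param_maps` object from [fit_mad_volume].
#' @param dir Output directory (created if needed).
#' @param prefix Filename prefix.
#' @return Invisibly, the written paths.
#' @export
write_param_maps <- function(maps, dir, prefix = "mad") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  qty <- c(mad_param_names(), "ADC", "rss", "converged")
  paths <- vapply(qty, function(q) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, q))
    img <- RNifti::asNifti(maps[[q]], datatype = "float")
    RNifti::writeNifti(img, p)
    p
  }, character(1))
  invisible(paths)
}

#' Read parameter maps written by [write_param_maps]
#'
#' @param dir Directory holding the map files.
#' @param prefix Filename prefix used when writing.
#' @return A `param_maps` list (without fit metadata).
#' @export
read_param_maps <- function(dir, prefix = "mad") {
  qty <- c(mad_param_names(), "ADC", "rss", "converged")
  maps <- stats::setNames(lapply(qty, function(q) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, q))
    img <- RNifti::readNifti(p)
    d <- dim(img)
    if (length(d) < 3) d <- c(d, rep(1L, 3 - length(d)))  # NIfTI drops trailing 1s
    array(as.numeric(img), dim = d)
  }), qty)
  structure(c(maps, list(n_fit = sum(is.finite(maps$rss)), scheme = NULL,
                         affine = NULL)),
            class = "param_maps")
}

# stable numeric formatting for reproducible CSVs
write_csv_stable <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
}

#' Write analysis results as CSV tables with a run manifest
#'
#' Emits the comparison and ROC tables of a [run_full_analysis] result as
#' CSVs mirroring the study's table layouts, the run log as plain text, and
#' a JSON manifest carrying the package version, seed and configuration
#' hash so every artifact is reproducible from config + seed alone.
#'
#' @param analysis A `mad_analysis` object.
#' @param dir Output directory.
#' @param seed Seed recorded in the manifest.
#' @param config Optional configuration list recorded (hashed) in the
#'   manifest.
#' @return Invisibly, the output directory.
#' @export
write_results <- function(analysis, dir, seed = NA_integer_, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, mode = 2) != 0) stop("output directory is not writable")
  write_csv_stable(analysis$comparison_malignancy,
                   file.path(dir, "comparison_malignancy.csv"))
  write_csv_stable(analysis$comparison_ki67,
                   file.path(dir, "comparison_ki67.csv"))
  if (!is.null(analysis$roc_malignancy$table)) {
    write_csv_stable(analysis$roc_malignancy$table,
                     file.path(dir, "roc_malignancy.csv"))
  }
  if (!is.null(analysis$roc_ki67$table)) {
    write_csv_stable(analysis$roc_ki67$table, file.path(dir, "roc_ki67.csv"))
  }
  writeLines(analysis$log, file.path(dir, "run_log.txt"))
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest <- list(package = "maddwi",
                   version = as.character(utils::packageVersion("maddwi")),
                   seed = seed,
                   config_hash = unname(tools::md5sum(tf)))
  unlink(tf)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
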