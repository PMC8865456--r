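#' Read a parcel label volume (NIfTI)
#'
#' @param path NIfTI-1/2 file with nonnegative integer labels (0 =
#'   background).
#' @return Integer array of labels (the NIfTI image attributes are kept on
#'   the array).
#' @export
read_label_volume <- function(path) {
  if (!file.exists(path)) stop("label volume not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  v <- as.array(img)
  if (any(!is.finite(v)) || any(v != round(v)) || any(v < 0))
    stop("read_label_volume: labels must be nonnegative integers", call. = FALSE)
  storage.mode(v) <- "integer"
  v
}

#' Read an intensity volume (NIfTI)
#' @param path NIfTI-1/2 file.
#' @return Numeric array of voxel intensities.
#' @export
read_intensity_volume <- function(path) {
  if (!file.exists(path)) stop("intensity volume not found: ", path, call. = FALSE)
  as.array(RNifti::readNifti(path))
}

#' Write a volume as NIfTI
#' @param x Numeric or integer array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(x, path) {
  RNifti::writeNifti(RNifti::asNifti(x), path)
  invisible(path)
}

#' Read/write the parcel-to-network table (TSV)
#'
#' Columns: `parcel_id`, `parcel_name`, `network`.
#' @param path TSV file.
#' @export
read_parcel_table <- function(path) {
  if (!file.exists(path)) stop("parcel table not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("parcel_id", "parcel_name", "network")
  if (!all(need %in% names(df)))
    stop("parcel table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname read_parcel_table
#' @param parcels Parcel table data frame.
#' @export
write_parcel_table <- function(parcels, path) {
  utils::write.table(parcels, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write a connectivity (or PDF) matrix as CSV
#'
#' The first column holds the row ids; remaining columns are the matrix.
#' @param m Matrix with rownames.
#' @param path CSV file.
#' @export
write_matrix_csv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline; the configuration (with a content
#' hash) is serialized as a JSON sidecar next to every output for
#' provenance, and downstream stages refuse inputs whose sidecar hash
#' differs from the active configuration.
#'
#' @param out_dir Output directory.
#' @param simulate Generate a phantom cohort instead of reading volumes.
#' @param n_subjects,age_min,age_max,seed Cohort simulation parameters.
#' @param grid_min,grid_max,bins Standardized histogram grid.
#' @param min_voxels Minimum parcel size retained.
#' @param epsilon Density floor for the divergence.
#' @param bandwidth `"botev"` or `"silverman"`.
#' @param top_fraction,alpha,viz_threshold Metric/report parameters.
#' @param atlas_path,networks_path,cohort_path,volumes_dir Input locations
#'   when `simulate = FALSE`.
#' @param include_pairs Analyze between-network pairs.
#' @return List of class `run_config` including a `config_hash`.
#' @export
run_config <- function(out_dir, simulate = TRUE, n_subjects = 12L,
                       age_min = 20, age_max = 82, seed = 1L,
                       grid_min = 0, grid_max = 3, bins = 256L,
                       min_voxels = 800L, epsilon = 1e-12,
                       bandwidth = c("botev", "silverman"),
                       top_fraction = 0.20, alpha = 0.05,
                       viz_threshold = 0.80,
                       atlas_path = NULL, networks_path = NULL,
                       cohort_path = NULL, volumes_dir = NULL,
                       include_pairs = TRUE) {
  cfg <- list(out_dir = out_dir, simulate = simulate,
              n_subjects = as.integer(n_subjects),
              age_min = age_min, age_max = age_max, seed = as.integer(seed),
              grid_min = grid_min, grid_max = grid_max,
              bins = as.integer(bins), min_voxels = as.integer(min_voxels),
              epsilon = epsilon, bandwidth = match.arg(bandwidth),
              top_fraction = top_fraction, alpha = alpha,
              viz_threshold = viz_threshold,
              atlas_path = atlas_path, networks_path = networks_path,
              cohort_path = cohort_path, volumes_dir = volumes_dir,
              include_pairs = include_pairs)
  cfg$config_hash <- config_hash(cfg)
  structure(cfg, class = "run_config")
}

# polynomial rolling hash of the serialized configuration (provenance stamp)
config_hash <- function(cfg) {
  cfg$config_hash <- NULL
  cfg$out_dir <- NULL  # the same analysis in another directory is the same run
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

write_sidecar <- function(info, path) {
  jsonlite::write_json(info, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
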