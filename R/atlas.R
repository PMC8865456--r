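#' Functional network sizes of the default 100-parcel atlas
#'
#' Parcel counts per intrinsic functional network for a 100-parcel
#' Schaefer-style cortical parcellation: frontoparietal (4), visual (13),
#' somatomotor (14), dorsal attention (13), ventral attention (14), limbic
#' (5), control (16) and default mode (21).
#'
#' @return Named integer vector of parcel counts summing to 100.
#' @export
default_network_sizes <- function() {
  c(frontoparietal = 4L, visual = 13L, somatomotor = 14L,
    dorsal_attention = 13L, ventral_attention = 14L,
    limbic = 5L, control = 16L, default_mode = 21L)
}

#' Specification of a phantom atlas and its uptake statistics
#'
#' Describes the synthetic parcellation used to validate the pipeline without
#' real data: a rectangular label volume holding `parcel_voxels` voxels per
#' parcel, grouped into functional networks, with per-parcel baseline offsets
#' `delta` (the deviation of the parcel's mean normalized uptake from 1) and
#' within-parcel standard deviations `sigma`. Parcels are laid out as
#' contiguous voxel blocks; no anatomical geometry is emulated because the
#' connectivity computation never uses spatial adjacency.
#'
#' @param volume_shape Integer triple, voxel dimensions of the label volume.
#' @param parcel_voxels Voxels per parcel (default 800, the minimum parcel
#'   size retained by the density stage).
#' @param network_sizes Named integer vector of parcels per network.
#' @param delta Per-parcel mean offsets; `NULL` draws them from
#'   `N(0, delta_sd)` under `seed`.
#' @param delta_sd Standard deviation of drawn offsets (default 0.05); this
#'   sets the baseline inter-parcel dispersion of mean uptake.
#' @param sigma Per-parcel within-parcel standard deviation(s), recycled
#'   (default 0.1).
#' @param seed Integer seed used for drawing `delta`.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(volume_shape = c(48L, 42L, 40L),
                         parcel_voxels = 800L,
                         network_sizes = default_network_sizes(),
                         delta = NULL, delta_sd = 0.05,
                         sigma = 0.1, seed = 1L) {
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3L || any(volume_shape < 1L))
    stop("phantom_spec: volume_shape must be three positive integers", call. = FALSE)
  if (is.null(names(network_sizes)) || any(!nzchar(names(network_sizes))))
    stop("phantom_spec: network_sizes must be named", call. = FALSE)
  n_parcels <- sum(as.integer(network_sizes))
  if (is.null(delta)) {
    delta <- with_seed(seed, rnorm(n_parcels, 0, delta_sd))
  }
  if (length(delta) != n_parcels)
    stop("phantom_spec: need one delta per parcel", call. = FALSE)
  sigma <- rep_len(sigma, n_parcels)
  if (any(sigma <= 0))
    stop("phantom_spec: sigma must be positive", call. = FALSE)
  structure(
    list(volume_shape = volume_shape,
         parcel_voxels = as.integer(parcel_voxels),
         network_sizes = setNames(as.integer(network_sizes), names(network_sizes)),
         delta = delta, sigma = sigma, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Construct a parcellation atlas object
#'
#' @param labels Integer array of parcel labels; 0 is background, labels
#'   `1..N` identify parcels.
#' @param parcels Data frame with at least columns `parcel_id`, `parcel_name`
#'   and `network`; every nonzero label in `labels` must appear in
#'   `parcel_id`.
#' @return Object of class `parcellation_atlas` with elements `labels` and
#'   `parcels` (the parcel table, augmented with an `n_voxels` column).
#' @export
parcellation_atlas <- function(labels, parcels) {
  storage.mode(labels) <- "integer"
  if (any(labels < 0L, na.rm = TRUE))
    stop("parcellation_atlas: labels must be nonnegative", call. = FALSE)
  present <- sort(unique(labels[labels > 0L]))
  if (!all(present %in% parcels$parcel_id))
    stop("parcellation_atlas: labels present in the volume but missing from the parcel table",
         call. = FALSE)
  counts <- tabulate(labels, nbins = max(parcels$parcel_id))
  parcels$n_voxels <- counts[parcels$parcel_id]
  structure(list(labels = labels, parcels = parcels),
            class = "parcellation_atlas")
}

#' @export
print.parcellation_atlas <- function(x, ...) {
  cat(sprintf("<parcellation_atlas> %d parcels, %d networks, volume %s\n",
              nrow(x$parcels), length(unique(x$parcels$network)),
              paste(dim(x$labels), collapse = "x")))
  invisible(x)
}

#' Build a phantom parcellation atlas
#'
#' Lays the parcels of a [phantom_spec()] out as contiguous blocks of voxels
#' in a rectangular volume. Every parcel occupies exactly
#' `spec$parcel_voxels` voxels; remaining voxels are background (label 0).
#'
#' @param spec A [phantom_spec()].
#' @return A [parcellation_atlas()] whose parcel table additionally carries
#'   the generative `delta` and `sigma` columns used by [simulate_subject()].
#' @examples
#' atlas <- build_phantom_atlas(phantom_spec())
#' nrow(atlas$parcels)
#' @export
build_phantom_atlas <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n_parcels <- sum(spec$network_sizes)
  n_vox <- prod(spec$volume_shape)
  need <- n_parcels * spec$parcel_voxels
  if (need > n_vox)
    stop(sprintf("build_phantom_atlas: volume holds %d voxels but %d are required",
                 n_vox, need), call. = FALSE)
  lab <- integer(n_vox)
  lab[seq_len(need)] <- rep(seq_len(n_parcels), each = spec$parcel_voxels)
  labels <- array(lab, dim = spec$volume_shape)
  network <- rep(names(spec$network_sizes), times = spec$network_sizes)
  parcels <- data.frame(
    parcel_id = seq_len(n_parcels),
    parcel_name = sprintf("%s_%02d", network,
                          unlist(lapply(spec$network_sizes, seq_len), use.names = FALSE)),
    network = network,
    delta = spec$delta,
    sigma = spec$sigma,
    stringsAsFactors = FALSE
  )
  parcellation_atlas(labels, parcels)
}
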