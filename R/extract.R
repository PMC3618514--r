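# Probability-weighted regional extraction.
#
# Regions are defined by probabilistic label volumes. Before extraction
# each region is delineated at p > 0.25 and overlaps are resolved by
# assigning each voxel to the region with the highest probability there
# (ties go to the lower region index, a documented convention). The
# surviving probabilities then serve as weights for regional means of a
# functional 4-D series or of a scalar (e.g. fractional-anisotropy)
# volume.

#' Probabilistic label volume set
#'
#' @param probabilities 4-D array `[x, y, z, region]` of voxelwise region
#'   probabilities in `[0, 1]`.
#' @param region_names character vector, one name per region (4th
#'   dimension).
#' @return object of class `label_volume_set`: list with `probabilities`,
#'   `grid_shape`, `region_names`, and `resolved` (logical flag).
#' @export
label_volume_set <- function(probabilities, region_names = NULL) {
  stopifnot(is.array(probabilities), length(dim(probabilities)) == 4L)
  if (any(probabilities < 0) || any(probabilities > 1)) {
    stop_invalid("label probabilities must lie in [0, 1]")
  }
  nr <- dim(probabilities)[4]
  if (is.null(region_names)) region_names <- default_region_names(nr)
  stopifnot(length(region_names) == nr)
  structure(
    list(
      probabilities = probabilities,
      grid_shape = dim(probabilities)[1:3],
      region_names = region_names,
      resolved = FALSE
    ),
    class = "label_volume_set"
  )
}

#' Threshold labels and resolve regional overlaps
#'
#' Zeroes probabilities at or below `p_threshold`, then assigns each
#' voxel claimed by several regions to the single region with the
#' highest probability (ties broken towards the lower region index).
#'
#' @param labels a `label_volume_set`.
#' @param p_threshold probability threshold (default 0.25; a voxel
#'   survives for a region only if `p > p_threshold`).
#' @return a resolved `label_volume_set` (at most one nonzero
#'   probability per voxel).
#' @export
resolve_labels <- function(labels, p_threshold = 0.25) {
  stopifnot(inherits(labels, "label_volume_set"))
  p <- labels$probabilities
  d <- dim(p)
  pm <- matrix(p, prod(d[1:3]), d[4]) # voxels x regions
  pm[pm <= p_threshold] <- 0
  multi <- rowSums(pm > 0) > 1L
  if (any(multi)) {
    winner <- max.col(pm[multi, , drop = FALSE], ties.method = "first")
    kept <- pm[multi, , drop = FALSE][cbind(seq_along(winner), winner)]
    pm[multi, ] <- 0
    pm[cbind(which(multi), winner)] <- kept
  }
  out <- labels
  out$probabilities <- array(pm, dim = d)
  out$resolved <- TRUE
  out
}

# Shared weighted-mean engine: values_matrix is voxels x columns.
.regional_weighted_means <- function(labels, values_matrix, p_threshold) {
  if (!labels$resolved) labels <- resolve_labels(labels, p_threshold)
  d <- dim(labels$probabilities)
  pm <- matrix(labels$probabilities, prod(d[1:3]), d[4])
  wsum <- colSums(pm)
  empty <- wsum == 0
  if (any(empty)) {
    stop_invalid(
      "no voxels survive the p > ", p_threshold,
      " threshold for region(s): ",
      paste(labels$region_names[empty], collapse = ", ")
    )
  }
  sweep(crossprod(pm, values_matrix), 1L, wsum, "/")
}

#' Probability-weighted regional mean BOLD time series
#'
#' For each region, the weighted mean of the 4-D series over the region's
#' surviving voxels, with the post-threshold label probabilities as
#' weights.
#'
#' @param volume_series 4-D numeric array `[x, y, z, time]`.
#' @param labels a `label_volume_set` on the same spatial grid.
#' @param p_threshold label probability threshold (default 0.25).
#' @return numeric matrix, regions x timepoints, with region row names.
#' @export
regional_mean_timeseries <- function(volume_series, labels,
                                     p_threshold = 0.25) {
  stopifnot(inherits(labels, "label_volume_set"))
  d <- dim(volume_series)
  if (length(d) != 4L || !all(d[1:3] == labels$grid_shape)) {
    stop_invalid("volume_series grid does not match the label grid")
  }
  vals <- matrix(volume_series, prod(d[1:3]), d[4])
  out <- .regional_weighted_means(labels, vals, p_threshold)
  rownames(out) <- labels$region_names
  out
}

#' Probability-weighted regional fractional anisotropy
#'
#' Mean FA per region: `sum_v p_v FA_v / sum_v p_v` over the region's
#' surviving voxels (post-threshold probabilities as weights).
#'
#' @param fa_volume 3-D numeric array of FA values in `[0, 1]`.
#' @param labels a `label_volume_set` on the same grid.
#' @param p_threshold label probability threshold (default 0.25).
#' @param subject_id optional id stored with the result.
#' @return object of class `regional_fa_table`: list with `subject_id`
#'   and `fa_by_region` (named numeric vector).
#' @export
regional_fa <- function(fa_volume, labels, p_threshold = 0.25,
                        subject_id = NA_character_) {
  stopifnot(inherits(labels, "label_volume_set"))
  d <- dim(fa_volume)
  if (length(d) != 3L || !all(d == labels$grid_shape)) {
    stop_invalid("fa_volume grid does not match the label grid")
  }
  vals <- matrix(as.vector(fa_volume), ncol = 1L)
  fa <- drop(.regional_weighted_means(labels, vals, p_threshold))
  names(fa) <- labels$region_names
  structure(
    list(subject_id = subject_id, fa_by_region = fa),
    class = "regional_fa_table"
  )
}
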