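# Mean statistical parametric network (SPN).
#
# Individual correlation matrices differ in their grand mean and spread,
# so raw correlation thresholds are not comparable across groups. The
# mean SPN standardises each edge's across-subject mean correlation
# against the grand distribution of all correlations in the population:
# z^e = (rbar^e - rbar) / sd(r), where rbar and sd(r) pool every
# upper-triangle edge of every subject.

#' Population mean statistical parametric network
#'
#' @param corr_stack list of per-subject correlation matrices (plain
#'   symmetric matrices or `correlation_matrix` objects from
#'   [build_connectivity()]), all with identical dimension and region
#'   order.
#' @return object of class `mean_spn`: list with `z` (edge z-score
#'   matrix, zero diagonal), `mean_edge_corr` (per-edge mean `rbar^e`),
#'   `grand_mean`, `grand_sd`, `n_subjects`, `region_names`.
#' @export
mean_spn <- function(corr_stack) {
  mats <- lapply(corr_stack, function(x) {
    if (inherits(x, "correlation_matrix")) x$r else as.matrix(x)
  })
  if (length(mats) < 2L) stop_invalid("need at least 2 subjects")
  n <- nrow(mats[[1]])
  region_names <- rownames(mats[[1]])
  if (is.null(region_names)) region_names <- default_region_names(n)
  for (m in mats) {
    if (nrow(m) != n || ncol(m) != n) {
      stop_invalid("correlation matrices must share dimensions")
    }
  }
  ut <- upper.tri(mats[[1]])
  edge_vals <- vapply(mats, function(m) m[ut], numeric(sum(ut)))
  grand_mean <- mean(edge_vals)
  grand_sd <- sd(as.vector(edge_vals))
  if (!is.finite(grand_sd) || grand_sd == 0) {
    stop_invalid("grand standard deviation of correlations is zero; ",
                 "the SPN z-scores are undefined")
  }
  rbar_e <- rowMeans(edge_vals)
  mean_mat <- matrix(0, n, n)
  mean_mat[ut] <- rbar_e
  mean_mat <- mean_mat + t(mean_mat)
  z <- (mean_mat - grand_mean) / grand_sd
  diag(z) <- 0
  diag(mean_mat) <- 0
  dimnames(z) <- dimnames(mean_mat) <- list(region_names, region_names)
  structure(
    list(
      z = z, mean_edge_corr = mean_mat, grand_mean = grand_mean,
      grand_sd = grand_sd, n_subjects = length(mats),
      region_names = region_names
    ),
    class = "mean_spn"
  )
}

#' First-degree connection profile of a seed region
#'
#' Lists the regions whose edge to the seed exceeds a threshold, in
#' descending order of strength. With `kind = "correlation"` the matrix
#' entries are compared with `threshold` directly; with `kind =
#' "z_p_value"` the matrix is interpreted as SPN z-scores and `threshold`
#' as a p-value mapped to a standard-normal quantile (one-sided
#' upper-tail by default, e.g. z > 2.576 for p = 0.005).
#'
#' @param matrix square symmetric matrix (mean correlations or SPN
#'   z-scores) with region dimnames, or a `mean_spn` object (its `z` used
#'   for `kind = "z_p_value"`, `mean_edge_corr` otherwise).
#' @param seed seed region name (or index).
#' @param threshold correlation cut-off, or p-value for the z kind.
#' @param kind `"correlation"` (default) or `"z_p_value"`.
#' @param two_sided for the z kind, use the two-sided quantile
#'   (default `FALSE`).
#' @return object of class `connection_profile`: list with `seed_region`,
#'   `connected_regions` (data.frame `region`, `strength`, descending),
#'   `threshold_used` (the value actually compared against),
#'   `threshold_kind`.
#' @export
first_degree_connections <- function(matrix, seed, threshold,
                                     kind = c("correlation", "z_p_value"),
                                     two_sided = FALSE) {
  kind <- match.arg(kind)
  if (inherits(matrix, "mean_spn")) {
    matrix <- if (kind == "z_p_value") matrix$z else matrix$mean_edge_corr
  }
  m <- as.matrix(matrix)
  nm <- rownames(m)
  if (is.null(nm)) nm <- default_region_names(nrow(m))
  if (is.character(seed)) {
    si <- match(seed, nm)
    if (is.na(si)) stop_invalid("seed region '", seed, "' not found")
  } else {
    si <- as.integer(seed)
    stopifnot(si >= 1, si <= nrow(m))
  }
  cut <- if (kind == "correlation") {
    threshold
  } else {
    if (threshold <= 0 || threshold >= 1) {
      stop_invalid("p-value threshold must lie in (0, 1)")
    }
    qnorm(1 - if (two_sided) threshold / 2 else threshold)
  }
  strengths <- m[si, -si]
  labels <- nm[-si]
  keep <- which(strengths > cut)
  ord <- keep[order(strengths[keep], decreasing = TRUE)]
  structure(
    list(
      seed_region = nm[si],
      connected_regions = data.frame(
        region = labels[ord], strength = unname(strengths[ord]),
        stringsAsFactors = FALSE
      ),
      threshold_used = cut,
      threshold_kind = kind
    ),
    class = "connection_profile"
  )
}

#' Percentile threshold of a seed region's edge strengths
#'
#' Quantile (type 7, linear interpolation) of the seed's edges to all
#' other regions; e.g. `percentile = 95` gives the cut above which the
#' strongest ~5% of the seed's connections lie.
#'
#' @inheritParams first_degree_connections
#' @param percentile percentile in `[0, 100]`.
#' @return scalar threshold.
#' @export
percentile_threshold <- function(matrix, seed, percentile) {
  if (inherits(matrix, "mean_spn")) matrix <- matrix$mean_edge_corr
  m <- as.matrix(matrix)
  nm <- rownames(m)
  if (is.null(nm)) nm <- default_region_names(nrow(m))
  si <- if (is.character(seed)) match(seed, nm) else as.integer(seed)
  if (is.na(si)) stop_invalid("seed region not found")
  stopifnot(percentile >= 0, percentile <= 100)
  unname(quantile(m[si, -si], percentile / 100, type = 7))
}
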