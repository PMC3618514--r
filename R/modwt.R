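# Maximum-overlap discrete wavelet transform (MODWT) and wavelet
# correlation networks.
#
# The MODWT is the undecimated, shift-covariant variant of the DWT: every
# level keeps one coefficient per timepoint, so correlations between two
# signals' level-k coefficients estimate their association restricted to
# the level-k frequency band. We implement the standard pyramid algorithm
# with filters rescaled by 1/sqrt(2) per level and circular (periodic)
# boundary treatment, which preserves the exact energy decomposition
# ||x||^2 = sum_j ||W_j||^2 + ||V_J||^2.

# Daubechies least-asymmetric length-8 ("LA(8)") scaling filter,
# normalised so sum(g) = sqrt(2), sum(g^2) = 1.
.la8_scaling <- c(
  -0.0757657147892733, -0.0296355276459985, 0.4976186676320155,
   0.8037387518059161,  0.2978577956052774, -0.0992195435768472,
  -0.0126039672620378,  0.0322231006040427
)

wavelet_filters <- function(family = c("la8", "haar")) {
  family <- match.arg(family)
  g <- switch(family,
    la8  = .la8_scaling,
    haar = c(1, 1) / sqrt(2)
  )
  L <- length(g)
  # quadrature-mirror relation: h_l = (-1)^l g_{L-1-l}
  h <- rev(g) * (-1)^(seq_len(L) - 1L)
  list(g = g, h = h, length = L, family = family)
}

# Length of the equivalent filter at level j (number of boundary-affected
# coefficients is L_j - 1).
modwt_filter_span <- function(level, filter_length) {
  (2^level - 1L) * (filter_length - 1L) + 1L
}

#' Frequency band of a MODWT level
#'
#' Level k of a wavelet decomposition of a series sampled every `tr`
#' seconds captures the octave band `[1 / (2^(k+1) tr), 1 / (2^k tr)]` Hz.
#' For `tr = 2.5` the first four levels are 0.1-0.2, 0.05-0.1,
#' 0.025-0.05 and 0.0125-0.025 Hz; level 3 is the band conventionally
#' analysed in resting-state BOLD studies.
#'
#' @param tr sampling interval (repetition time) in seconds; `> 0`.
#' @param k decomposition level; integer `>= 1`.
#' @return numeric vector `c(low_hz, high_hz)`.
#' @examples
#' band_bounds(2.5, 3) # 0.025 - 0.05 Hz
#' @export
band_bounds <- function(tr, k) {
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0) {
    stop_invalid("tr must be a positive scalar")
  }
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k)) {
    stop_invalid("k must be a positive integer level index")
  }
  c(low_hz = 1 / (2^(k + 1) * tr), high_hz = 1 / (2^k * tr))
}

#' Maximum-overlap discrete wavelet transform
#'
#' Computes the MODWT of one series (or of every column of a matrix) with
#' periodic boundary handling. Each level has as many coefficients as the
#' input; the transform is covariant under circular shifts of the input.
#'
#' @param x numeric vector, or a matrix with one series per column.
#' @param levels number of decomposition levels (default 4).
#' @param family wavelet family: `"la8"` (Daubechies least-asymmetric,
#'   length 8; default) or `"haar"`.
#' @param tr sampling interval in seconds, stored for band bookkeeping.
#' @return an object of class `modwt_decomp`: list with `W` (list of
#'   per-level detail coefficient vectors/matrices), `V` (level-`levels`
#'   smooth), `levels`, `family`, `tr`, `n`.
#' @export
modwt <- function(x, levels = 4L, family = "la8", tr = 2.5) {
  f <- wavelet_filters(family)
  x <- as.matrix(x)
  n <- nrow(x)
  if (!is.numeric(levels) || levels < 1 || levels != round(levels)) {
    stop_invalid("levels must be a positive integer")
  }
  span <- modwt_filter_span(levels, f$length)
  if (n < span) {
    stop_invalid(
      "series too short for a ", levels, "-level MODWT with the ",
      f$family, " filter: need at least ", span, " points, got ", n
    )
  }
  ht <- f$h / sqrt(2)
  gt <- f$g / sqrt(2)
  W <- vector("list", levels)
  V <- x
  t0 <- seq_len(n) - 1L
  for (j in seq_len(levels)) {
    stride <- 2^(j - 1L)
    Wj <- matrix(0, n, ncol(x))
    Vj <- matrix(0, n, ncol(x))
    for (l in seq_along(ht)) {
      idx <- ((t0 - stride * (l - 1L)) %% n) + 1L
      Wj <- Wj + ht[l] * V[idx, , drop = FALSE]
      Vj <- Vj + gt[l] * V[idx, , drop = FALSE]
    }
    W[[j]] <- if (ncol(x) == 1L) drop(Wj) else Wj
    V <- Vj
  }
  structure(
    list(
      W = W,
      V = if (ncol(x) == 1L) drop(V) else V,
      levels = as.integer(levels),
      family = f$family,
      tr = tr,
      n = n
    ),
    class = "modwt_decomp"
  )
}

#' Wavelet correlation between two decompositions at one level
#'
#' Pearson correlation of the two series' level-`k` MODWT detail
#' coefficients, i.e. their association restricted to the level-`k`
#' frequency band.
#'
#' @param dec_a,dec_b `modwt_decomp` objects of equal length, levels and
#'   family (each built from a single series).
#' @param k level index.
#' @param exclude_boundary drop the `L_k - 1` boundary-affected
#'   coefficients at the start of the series before correlating
#'   (default `FALSE`: all coefficients are used).
#' @return correlation in `[-1, 1]`.
#' @export
wavelet_correlation <- function(dec_a, dec_b, k, exclude_boundary = FALSE) {
  stopifnot(inherits(dec_a, "modwt_decomp"), inherits(dec_b, "modwt_decomp"))
  if (dec_a$n != dec_b$n || dec_a$levels != dec_b$levels ||
      dec_a$family != dec_b$family) {
    stop_invalid("decompositions must share length, levels and family")
  }
  if (k < 1 || k > dec_a$levels) {
    stop_invalid("k must lie in 1..levels")
  }
  a <- dec_a$W[[k]]
  b <- dec_b$W[[k]]
  if (!is.null(dim(a)) || !is.null(dim(b))) {
    stop_invalid("wavelet_correlation expects single-series decompositions")
  }
  if (exclude_boundary) {
    drop_n <- min(
      modwt_filter_span(k, wavelet_filters(dec_a$family)$length) - 1L,
      dec_a$n - 3L
    )
    if (drop_n > 0) {
      a <- a[-seq_len(drop_n)]
      b <- b[-seq_len(drop_n)]
    }
  }
  if (sd(a) == 0 || sd(b) == 0) {
    stop_invalid("wavelet correlation undefined for a constant coefficient series")
  }
  cor(a, b)
}

#' Build a wavelet correlation matrix and soft-thresholded weight network
#'
#' For a regions-by-time BOLD matrix, computes the MODWT of every regional
#' series, correlates each pair's level-`level` coefficients, and maps the
#' correlations to edge weights by the soft threshold `w = r^2` (the
#' square of the absolute correlation; squaring emphasises strong and
#' penalises weak correlations without binarising).
#'
#' @param bold numeric matrix, regions x timepoints. Row names, when
#'   present, are used as region names.
#' @param tr repetition time in seconds (default 2.5).
#' @param level wavelet level whose band is analysed (default 3, the
#'   0.025-0.05 Hz band at `tr = 2.5`).
#' @param levels total decomposition depth (default 4).
#' @param family wavelet family (default `"la8"`).
#' @param exclude_boundary see [wavelet_correlation()].
#' @return list with components `correlation` (class
#'   `correlation_matrix`: fields `r`, `band_index`, `region_names`) and
#'   `network` (class `weighted_network`, see [weighted_network()]).
#' @export
build_connectivity <- function(bold, tr = 2.5, level = 3L, levels = 4L,
                               family = "la8", exclude_boundary = FALSE) {
  bold <- as.matrix(bold)
  if (nrow(bold) < 2L) stop_invalid("need at least 2 regions")
  region_names <- rownames(bold)
  if (is.null(region_names)) region_names <- default_region_names(nrow(bold))
  sds <- apply(bold, 1L, sd)
  if (any(sds == 0)) {
    stop_invalid(
      "constant BOLD signal in region(s): ",
      paste(region_names[sds == 0], collapse = ", "),
      "; wavelet correlation is undefined"
    )
  }
  dec <- modwt(t(bold), levels = levels, family = family, tr = tr)
  coefs <- dec$W[[level]] # timepoints x regions
  if (exclude_boundary) {
    drop_n <- min(
      modwt_filter_span(level, wavelet_filters(family)$length) - 1L,
      nrow(coefs) - 3L
    )
    if (drop_n > 0) coefs <- coefs[-seq_len(drop_n), , drop = FALSE]
  }
  r <- cor(coefs)
  dimnames(r) <- list(region_names, region_names)
  w <- abs(r)^2
  diag(w) <- 0
  list(
    correlation = structure(
      list(r = r, band_index = as.integer(level), region_names = region_names),
      class = "correlation_matrix"
    ),
    network = weighted_network(w, region_names)
  )
}
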