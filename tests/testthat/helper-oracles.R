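# Independent oracles used across the suite. These deliberately take
# different computational routes from the package implementation.

# --- MODWT oracle: frequency-domain computation -------------------------
# The level-j MODWT detail coefficients equal the circular convolution of
# the input with the level-j equivalent filter, whose DFT is
# H(2^(j-1) f) * prod_{l=0}^{j-2} G(2^l f), with H, G the DFTs of the
# 1/sqrt(2)-rescaled wavelet/scaling filters. The package uses the
# time-domain pyramid; this oracle goes through the FFT.
fft_modwt_oracle <- function(x, levels, family = "la8") {
  f <- costnet:::wavelet_filters(family)
  n <- length(x)
  ht <- f$h / sqrt(2)
  gt <- f$g / sqrt(2)
  filt_dft <- function(coefs, stride) {
    l <- seq_along(coefs) - 1
    vapply(0:(n - 1), function(k) {
      sum(coefs * exp(-2i * pi * l * stride * k / n))
    }, complex(1))
  }
  xf <- fft(x)
  out <- vector("list", levels)
  gprod <- rep(1 + 0i, n)
  for (j in seq_len(levels)) {
    hj <- filt_dft(ht, 2^(j - 1)) * gprod
    out[[j]] <- Re(fft(xf * hj, inverse = TRUE)) / n
    gprod <- gprod * filt_dft(gt, 2^(j - 1))
  }
  out
}

# --- Graph oracles: Floyd-Warshall and direct formula evaluation --------
fw_distances <- function(a) {
  n <- nrow(a)
  d <- ifelse(a == 1, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_nodal_eff <- function(a) {
  d <- fw_distances(a)
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    inv <- 1 / d[i, -i]
    sum(inv[is.finite(inv)]) / (n - 1)
  }, numeric(1))
}

oracle_global_eff <- function(a) mean(oracle_nodal_eff(a))

oracle_local_eff <- function(a) {
  n <- nrow(a)
  per_node <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1)
    if (length(nb) < 2) return(0)
    oracle_global_eff(a[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(per_node)
}

random_binary_adj <- function(n, p = 0.4) {
  a <- matrix(0L, n, n)
  ut <- which(upper.tri(a))
  a[sample(ut, rbinom(1, length(ut), p))] <- 1L
  a + t(a)
}

# All 2-graphs on 4 nodes: one adjacency per subset of the 6 edges.
all_graphs_n4 <- function() {
  ut <- which(upper.tri(matrix(0, 4, 4)))
  lapply(0:63, function(bits) {
    a <- matrix(0L, 4, 4)
    a[ut[bitwAnd(bits, 2^(0:5)) > 0]] <- 1L
    a + t(a)
  })
}

# --- BH step-up, straight from the definition ---------------------------
bh_stepup_oracle <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k_ok <- which(ps <= (seq_len(m) / m) * alpha)
  reject <- logical(m)
  if (length(k_ok)) reject[ord[seq_len(max(k_ok))]] <- TRUE
  reject
}

# Small weighted network with distinct weights for thresholding tests.
toy_weighted_net <- function(n, seed = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- runif(n * (n - 1) / 2)
  w <- w + t(w)
  weighted_network(w)
}

# Miniature cohort settings shared by several tests (keeps runtimes low).
tiny_cohort <- function(seed = 11, n_subjects = 12L, n_regions = 20L,
                        n_timepoints = 120L, n_communities = 4L, ...) {
  cohort_config(
    n_subjects = n_subjects, n_regions = n_regions,
    n_timepoints = n_timepoints, n_communities = n_communities,
    seed = seed, ...
  )
}
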