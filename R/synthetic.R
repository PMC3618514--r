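# Synthetic cohort generator.
#
# Generates phenotypes, regional BOLD series, probabilistic label
# volumes and regional fractional anisotropy with the statistical
# structure the downstream analysis assumes, so the full pipeline is
# testable without any imaging download. Defaults emulate the working
# cohort scale: 127 subjects, 149 regions, 260 timepoints at TR = 2.5 s,
# inter-regional coupling concentrated in the 0.025-0.05 Hz band.

#' Synthetic cohort configuration
#'
#' @param n_subjects number of subjects (default 127).
#' @param n_regions number of regions (default 149).
#' @param n_timepoints BOLD series length (default 260).
#' @param tr repetition time in seconds (default 2.5).
#' @param n_communities number of signal communities the regions are
#'   partitioned into (default 8, roughly equal sizes).
#' @param module_partition optional integer vector assigning each region
#'   to a community; overrides `n_communities`. Must cover all regions.
#' @param hub_region index of the designated hub node (default 1, a
#'   member of community 1); its community coupling carries the
#'   trait-degree effect.
#' @param fa_effect_regions indices of regions whose FA carries the
#'   trait effect (default `c(2, 3)`).
#' @param effect_sizes named list of standardised slopes per trait SD:
#'   `hub_degree` (scales the hub's community coupling; default -0.5),
#'   `local_efficiency` (scales every region's community coupling;
#'   default -0.1), `fa` (shifts FA in effect regions in units of the
#'   FA residual SD; default -0.3). Set all to 0 for a null cohort.
#' @param noise_sd white-noise SD added to each regional series
#'   (default 1; community/global signals have unit variance).
#' @param global_strength multiplier on the global-signal loadings
#'   (default 1; 0 removes the shared global component entirely).
#' @param band_level wavelet level whose frequency band carries the
#'   shared signals (default 3: 0.025-0.05 Hz at `tr = 2.5`).
#' @param assq_srs_corr latent correlation between the two trait scores
#'   (not printed for the emulated cohort; default 0.6).
#' @param seed master integer seed; all stage seeds derive from it.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 127L, n_regions = 149L,
                          n_timepoints = 260L, tr = 2.5,
                          n_communities = 8L, module_partition = NULL,
                          hub_region = 1L, fa_effect_regions = c(2L, 3L),
                          effect_sizes = list(hub_degree = -0.5,
                                              local_efficiency = -0.1,
                                              fa = -0.3),
                          noise_sd = 1, global_strength = 1,
                          band_level = 3L,
                          assq_srs_corr = 0.6, seed = 1L) {
  if (n_subjects < 1 || n_regions < 2 || n_timepoints < 1) {
    stop_invalid("all cohort counts must be positive (>= 2 regions)")
  }
  if (is.null(module_partition)) {
    module_partition <- sort(rep_len(seq_len(n_communities), n_regions))
  }
  if (length(module_partition) != n_regions ||
      anyNA(module_partition)) {
    stop_invalid("module_partition must assign every region exactly once")
  }
  es <- list(hub_degree = -0.5, local_efficiency = -0.1, fa = -0.3)
  es[names(effect_sizes)] <- effect_sizes
  if (hub_region < 1 || hub_region > n_regions ||
      any(fa_effect_regions < 1) || any(fa_effect_regions > n_regions)) {
    stop_invalid("effect regions must be valid region indices")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_regions = as.integer(n_regions),
      n_timepoints = as.integer(n_timepoints),
      tr = tr,
      module_partition = as.integer(module_partition),
      hub_region = as.integer(hub_region),
      fa_effect_regions = as.integer(fa_effect_regions),
      effect_sizes = es,
      noise_sd = noise_sd,
      global_strength = global_strength,
      band_level = as.integer(band_level),
      assq_srs_corr = assq_srs_corr,
      seed = as.integer(seed),
      region_names = default_region_names(n_regions)
    ),
    class = "cohort_config"
  )
}

# Marginal transforms from standard-normal latents. ASSQ is right-skewed
# (exponentiated Gaussian, clipped to integers 0-39); SRS approximately
# normal (rounded, clipped to 0-195). Constants target the emulated
# cohort's printed mean/SD/range.
.assq_from_z <- function(z) pmin(39, pmax(0, round(exp(1.34 + 0.98 * z) - 1)))
.srs_from_z <- function(z) pmin(195, pmax(0, round(27.2 + 19.4 * z)))
.viq_from_z <- function(z) round(106.9 + 13 * z)
.piq_from_z <- function(z) round(108.5 + 14 * z)

# Pearson attenuation of a monotone marginal transform: for bivariate
# normal (X, Z) with latent correlation rho, cor(X, f(Z)) =
# rho * cor(Z, f(Z)). The factor cor(Z, f(Z)) is computed by fixed-grid
# Gauss quadrature, so latent correlations can be inflated to hit the
# observed-scale targets.
.attenuation <- function(f) {
  z <- seq(-6, 6, by = 0.001)
  w <- dnorm(z)
  w <- w / sum(w)
  fz <- f(z)
  mz <- sum(w * z)
  mf <- sum(w * fz)
  cov_zf <- sum(w * (z - mz) * (fz - mf))
  cov_zf / sqrt(sum(w * (z - mz)^2) * sum(w * (fz - mf)^2))
}

# Latent 4x4 correlation matrix over (VIQ, PIQ, ASSQ, SRS) that maps to
# the observed-scale targets after marginal attenuation. Off-diagonals
# are shrunk uniformly if the matrix is not positive definite.
.latent_sigma <- function(assq_srs_corr) {
  a <- c(
    viq = .attenuation(.viq_from_z), piq = .attenuation(.piq_from_z),
    assq = .attenuation(.assq_from_z), srs = .attenuation(.srs_from_z)
  )
  target <- diag(4)
  dimnames(target) <- list(names(a), names(a))
  target["viq", "piq"] <- target["piq", "viq"] <- 0.55
  target["viq", "assq"] <- target["assq", "viq"] <- -0.393
  target["viq", "srs"] <- target["srs", "viq"] <- -0.343
  # PIQ shares the trait correlations through its association with VIQ.
  target["piq", "assq"] <- target["assq", "piq"] <- 0.55 * -0.393
  target["piq", "srs"] <- target["srs", "piq"] <- 0.55 * -0.343
  sigma <- target / outer(a, a)
  sigma["assq", "srs"] <- sigma["srs", "assq"] <- assq_srs_corr
  diag(sigma) <- 1
  while (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) <
         1e-6) {
    off <- sigma - diag(diag(sigma))
    sigma <- diag(diag(sigma)) + off * 0.98
  }
  sigma
}

#' Generate a synthetic phenotype table
#'
#' Draws a latent Gaussian copula over (verbal IQ, performance IQ, ASSQ,
#' SRS) whose latent correlations are calibrated so the observed-scale
#' Pearson correlations approach the targets (VIQ-PIQ 0.55, VIQ-ASSQ
#' -0.393, VIQ-SRS -0.343), then applies the marginal transforms. Age
#' (18-65, truncated normal) and gender (female/male, P(male) = 78/127)
#' are independent of the trait scores.
#'
#' @param config a [cohort_config()].
#' @return data.frame with columns `subject_id`, `age`, `gender`,
#'   `verbal_iq`, `performance_iq`, `full_iq`, `assq`, `srs`.
#' @export
generate_phenotypes <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  if (n < 10) stop_invalid("need n_subjects >= 10 for a phenotype cohort")
  sigma <- .latent_sigma(config$assq_srs_corr)
  with_seed(derive_seed(config$seed, 1L), {
    z <- matrix(rnorm(n * 4), n, 4) %*% chol(sigma)
    age <- round(rnorm(n, 35.8, 12.8))
    while (any(bad <- age < 18 | age > 65)) {
      age[bad] <- round(rnorm(sum(bad), 35.8, 12.8))
    }
    gender <- ifelse(runif(n) < 78 / 127, "male", "female")
    viq <- .viq_from_z(z[, 1])
    piq <- .piq_from_z(z[, 2])
    data.frame(
      subject_id = sprintf("sub-%04d", seq_len(n)),
      age = as.integer(age),
      gender = factor(gender, levels = c("female", "male")),
      verbal_iq = viq,
      performance_iq = piq,
      full_iq = round((viq + piq) / 2),
      assq = as.integer(.assq_from_z(z[, 3])),
      srs = as.integer(.srs_from_z(z[, 4])),
      stringsAsFactors = FALSE
    )
  })
}

#' Combined standardised trait score
#'
#' Mean of the within-cohort z-scores of ASSQ and SRS; the single
#' dimensional trait axis that drives the injected effects.
#'
#' @param phenotypes data.frame from [generate_phenotypes()] (needs
#'   `assq` and `srs` columns).
#' @return numeric vector, one score per subject.
#' @export
combined_trait_score <- function(phenotypes) {
  z1 <- (phenotypes$assq - mean(phenotypes$assq)) / sd(phenotypes$assq)
  z2 <- (phenotypes$srs - mean(phenotypes$srs)) / sd(phenotypes$srs)
  (z1 + z2) / 2
}

# Unit-variance signal band-limited to [low, high] Hz: white noise
# brick-wall filtered in the frequency domain.
.bandlimited_signal <- function(n, tr, low, high) {
  x <- rnorm(n)
  freqs <- (seq_len(n) - 1) / (n * tr)
  freqs <- pmin(freqs, 1 / tr - freqs) # two-sided spectrum
  keep <- freqs >= low & freqs <= high
  if (!any(keep)) stop_invalid("series too short to carry the band")
  xf <- fft(x)
  xf[!keep] <- 0
  y <- Re(fft(xf, inverse = TRUE)) / n
  (y - mean(y)) / sd(y)
}

#' Generate per-subject regional BOLD matrices
#'
#' Each region's series is `coupling * s_community + g * s_global +
#' noise_sd * white noise`, where the community and global signals are
#' unit-variance and band-limited to the level-`band_level` wavelet band
#' (0.025-0.05 Hz by default). Community couplings and global loadings
#' vary across regions (drawn once per cohort), giving the thresholded
#' graphs modular but connected, brain-like structure. The hub region's
#' community coupling is scaled by `1 + hub_degree * trait_z`, and every
#' region's community coupling by `1 + local_efficiency * trait_z`
#' (multipliers floored at 0), so higher-trait subjects have a weaker
#' hub and slightly weaker within-community synchrony.
#'
#' @param config a [cohort_config()].
#' @param phenotypes data.frame from [generate_phenotypes()]; row count
#'   must equal `config$n_subjects`.
#' @return named list (one entry per subject) of regions x timepoints
#'   matrices with region row names.
#' @export
generate_bold <- function(config, phenotypes) {
  stopifnot(inherits(config, "cohort_config"))
  if (nrow(phenotypes) != config$n_subjects) {
    stop_invalid("phenotype table has ", nrow(phenotypes),
                 " rows but config expects ", config$n_subjects)
  }
  nt <- config$n_timepoints
  nr <- config$n_regions
  part <- config$module_partition
  band <- band_bounds(config$tr, config$band_level)
  trait <- combined_trait_score(phenotypes)
  # Region-level couplings: fixed across subjects (region identity).
  # Heterogeneous loadings. Each region couples to its own community,
  # more weakly to a second (random) community, and to a global signal.
  # The secondary memberships emulate overlapping resting-state networks:
  # they put strong between-community bridges among the top-ranked edges,
  # so low-cost thresholded graphs stay connected (as real connectomes
  # do) while the primary modular structure still dominates clustering.
  n_comm <- max(part)
  loadings <- with_seed(derive_seed(config$seed, 2L), {
    list(
      community = runif(nr, 0.5, 1.2),
      secondary = if (n_comm > 1) runif(nr, 0, 0.9) else numeric(nr),
      sec_comm = if (n_comm > 1) {
        vapply(part, function(p) {
          sample(setdiff(seq_len(n_comm), p), 1L)
        }, integer(1))
      } else {
        part
      },
      global = runif(nr, 0.2, 1.0) * config$global_strength
    )
  })
  es <- config$effect_sizes
  out <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    out[[s]] <- with_seed(derive_seed(config$seed, c(3L, s)), {
      s_comm <- vapply(
        seq_len(max(part)),
        function(cc) .bandlimited_signal(nt, config$tr, band[1], band[2]),
        numeric(nt)
      )
      s_glob <- .bandlimited_signal(nt, config$tr, band[1], band[2])
      all_mult <- max(0, 1 + es$local_efficiency * trait[s])
      hub_mult <- max(0, 1 + es$hub_degree * trait[s])
      # The hub effect scales the hub's participation in every shared
      # signal (community, secondary, global): scaling only one source
      # would shrink the hub's total variance and mechanically inflate
      # its remaining correlations instead of weakening them.
      coup <- loadings$community * all_mult
      sec <- loadings$secondary * all_mult
      glob <- loadings$global
      coup[config$hub_region] <- coup[config$hub_region] * hub_mult
      sec[config$hub_region] <- sec[config$hub_region] * hub_mult
      glob[config$hub_region] <- glob[config$hub_region] * hub_mult
      x <- t(s_comm[, part, drop = FALSE]) * coup +
        t(s_comm[, loadings$sec_comm, drop = FALSE]) * sec +
        outer(glob, s_glob) +
        config$noise_sd * matrix(rnorm(nr * nt), nr, nt)
      rownames(x) <- config$region_names
      x
    })
  }
  names(out) <- phenotypes$subject_id
  out
}

#' Generate probabilistic label volumes
#'
#' Places region centres on a 3-D lattice and gives each region a
#' Gaussian probability blob (peak 0.9) around its centre. Neighbouring
#' blobs deliberately overlap so the p > 0.25 threshold and
#' highest-probability overlap resolution are genuinely exercised.
#'
#' @param config a [cohort_config()].
#' @param grid_shape optional 3-vector of voxel dimensions; defaults to
#'   the smallest lattice-aligned grid that holds all regions.
#' @param spacing lattice spacing between region centres in voxels
#'   (default 3).
#' @param blob_sd Gaussian blob SD in voxels (default 1.5, at which
#'   voxels adjacent to two centres carry p > 0.25 for both regions).
#' @return a `label_volume_set`.
#' @export
generate_label_volumes <- function(config, grid_shape = NULL, spacing = 3,
                                   blob_sd = 1.5) {
  stopifnot(inherits(config, "cohort_config"))
  nr <- config$n_regions
  a <- ceiling(nr^(1 / 3))
  b <- ceiling(sqrt(nr / a))
  cc <- ceiling(nr / (a * b))
  lattice_dims <- c(a, b, cc)
  if (is.null(grid_shape)) {
    grid_shape <- lattice_dims * spacing
  }
  if (prod(floor(grid_shape / spacing)) < nr) {
    stop_invalid("grid_shape too small to hold ", nr,
                 " region centres at spacing ", spacing)
  }
  avail <- floor(grid_shape / spacing)
  centres <- arrayInd(seq_len(nr), avail)
  centres <- (centres - 0.5) * spacing + 0.5
  coords <- as.matrix(expand.grid(
    x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]),
    z = seq_len(grid_shape[3])
  ))
  p <- array(0, dim = c(grid_shape, nr))
  pv <- matrix(0, nrow(coords), nr)
  for (r in seq_len(nr)) {
    d2 <- rowSums(sweep(coords, 2L, centres[r, ])^2)
    pv[, r] <- 0.9 * exp(-d2 / (2 * blob_sd^2))
  }
  p <- array(pv, dim = c(grid_shape, nr))
  labels <- label_volume_set(p, config$region_names)
  resolved <- resolve_labels(labels)
  owned <- colSums(matrix(resolved$probabilities,
                          ncol = nr) > 0)
  if (any(owned == 0)) {
    stop_invalid("grid too small: region(s) own no voxel after overlap ",
                 "resolution: ",
                 paste(config$region_names[owned == 0], collapse = ", "))
  }
  labels
}

#' Generate per-subject regional fractional anisotropy
#'
#' Region FA baselines are drawn once per cohort from U(0.35, 0.55);
#' subject values add N(0, 0.03) residual noise. In the designated
#' effect regions FA additionally shifts by `fa * trait_z * 0.03`
#' (standardised slope times residual SD), i.e. decreases linearly in
#' the trait for a negative slope. Values are clipped to (0.01, 0.99).
#'
#' @param config a [cohort_config()].
#' @param phenotypes phenotype data.frame of matching size.
#' @param labels optional `label_volume_set`; when supplied, per-subject
#'   FA volumes are also returned (voxel FA = FA of the owning region),
#'   exercising the volume-extraction path.
#' @return list with `fa` (subjects x regions matrix, dimnames set) and
#'   `volumes` (list of 3-D arrays, or `NULL`).
#' @export
generate_fa <- function(config, phenotypes, labels = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (nrow(phenotypes) != config$n_subjects) {
    stop_invalid("phenotype table size mismatch")
  }
  nr <- config$n_regions
  fa_sd <- 0.03
  trait <- combined_trait_score(phenotypes)
  base <- with_seed(derive_seed(config$seed, 4L), runif(nr, 0.35, 0.55))
  fa <- with_seed(derive_seed(config$seed, 5L), {
    m <- matrix(rnorm(config$n_subjects * nr, 0, fa_sd),
                config$n_subjects, nr)
    m <- sweep(m, 2L, base, "+")
    m[, config$fa_effect_regions] <- m[, config$fa_effect_regions] +
      config$effect_sizes$fa * trait * fa_sd
    pmin(pmax(m, 0.01), 0.99) # m first so the matrix shape is kept
  })
  dimnames(fa) <- list(phenotypes$subject_id, config$region_names)
  volumes <- NULL
  if (!is.null(labels)) {
    resolved <- resolve_labels(labels)
    d <- dim(resolved$probabilities)
    pm <- matrix(resolved$probabilities, prod(d[1:3]), d[4])
    owner <- max.col(pm, ties.method = "first")
    owner[rowSums(pm) == 0] <- NA
    volumes <- lapply(seq_len(config$n_subjects), function(s) {
      v <- ifelse(is.na(owner), 0, fa[s, owner])
      array(v, dim = d[1:3])
    })
    names(volumes) <- phenotypes$subject_id
  }
  list(fa = fa, volumes = volumes)
}
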