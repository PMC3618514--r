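# Bundled reference connection profiles.

#' Reference seed-connection profiles of the right posterior cingulate
#'
#' A bundled table of first-degree connection strengths (mean wavelet
#' correlation coefficients) between a right posterior cingulate seed
#' and other brain regions, reported for two subgroups of a neurotypical
#' adult cohort defined by ASSQ cut-off scores (`cutoff2`: ASSQ <= 2;
#' `cutoff24`: ASSQ >= 24). Strengths are printed to two decimals. Used
#' in examples and in validation of the profile-counting logic.
#'
#' @return data.frame with columns `group`, `region`, `correlation`.
#' @export
reference_seed_profiles <- function() {
  read.csv(
    system.file("extdata", "pcc_seed_profiles.csv", package = "costnet"),
    stringsAsFactors = FALSE
  )
}

#' Build a seed-centred correlation matrix from a reference profile
#'
#' Embeds one subgroup's profile into a small symmetric matrix whose
#' first row/column is the seed region (`r-CingGyP`), suitable for
#' [first_degree_connections()].
#'
#' @param group `"cutoff2"` or `"cutoff24"`.
#' @return symmetric matrix with a zero diagonal; entries outside the
#'   seed's row/column are zero.
#' @export
reference_profile_matrix <- function(group = c("cutoff2", "cutoff24")) {
  group <- match.arg(group)
  tab <- reference_seed_profiles()
  tab <- tab[tab$group == group, ]
  nm <- c("r-CingGyP", tab$region)
  n <- length(nm)
  m <- matrix(0, n, n, dimnames = list(nm, nm))
  m[1, -1] <- tab$correlation
  m[-1, 1] <- tab$correlation
  m
}
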