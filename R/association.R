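# GLM association of topology / FA with dimensional trait scores.
#
# Each regional (or global) measure is regressed on the trait terms plus
# nuisance covariates by ordinary least squares; the trait effect is an
# F-contrast on the trait term(s), its effect size the partial eta
# squared F*dfh / (F*dfh + dfe). With one observation per subject and
# region, a per-subject random effect is not identifiable and is
# absorbed into the residual. Families of per-region p-values are
# corrected by Benjamini-Hochberg FDR.

#' GLM design specification
#'
#' Design 1 regresses the response on the trait term(s) plus age and
#' gender; design 2 additionally controls for verbal IQ. The trait
#' contrast is, by default, the joint 2-df F-test on the ASSQ and SRS
#' slopes; `trait` selects single-score alternatives, including a 1-df
#' combined standardised score.
#'
#' @param design_id 1 (age + gender covariates) or 2 (+ verbal IQ).
#' @param trait one of `"assq_srs"` (joint 2-df contrast, default),
#'   `"assq"`, `"srs"`, `"combined"` (1-df mean of standardised ASSQ and
#'   SRS).
#' @return list of class `glm_design` with `design_id`, `trait`,
#'   `trait_terms`, `covariates`.
#' @export
glm_design <- function(design_id = 1L,
                       trait = c("assq_srs", "assq", "srs", "combined")) {
  trait <- match.arg(trait)
  if (!design_id %in% c(1L, 2L)) stop_invalid("design_id must be 1 or 2")
  trait_terms <- switch(trait,
    assq_srs = c("assq", "srs"),
    assq = "assq", srs = "srs", combined = "trait_score"
  )
  covariates <- c("age", "gender", if (design_id == 2L) "verbal_iq")
  structure(
    list(
      design_id = as.integer(design_id), trait = trait,
      trait_terms = trait_terms, covariates = covariates
    ),
    class = "glm_design"
  )
}

# Build the design matrix. Gender is coded 0 = female, 1 = male.
.design_matrix <- function(phenotypes, design) {
  n <- nrow(phenotypes)
  cols <- list("(Intercept)" = rep(1, n))
  for (term in c(design$trait_terms, design$covariates)) {
    cols[[term]] <- switch(term,
      gender = as.numeric(phenotypes$gender == "male"),
      trait_score = combined_trait_score(phenotypes),
      assq = as.numeric(phenotypes$assq),
      srs = as.numeric(phenotypes$srs),
      age = as.numeric(phenotypes$age),
      verbal_iq = as.numeric(phenotypes$verbal_iq)
    )
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  X
}

# Vectorised OLS for a matrix of responses sharing one design.
.ols_family <- function(Y, X, trait_terms) {
  n <- nrow(X)
  p <- ncol(X)
  if (qr(X)$rank < p) {
    stop_invalid("design matrix is rank deficient (collinear predictors)")
  }
  if (n <= p) stop_invalid("need more subjects than predictors")
  xtx_inv <- solve(crossprod(X))
  coefs <- xtx_inv %*% crossprod(X, Y) # p x m
  res <- Y - X %*% coefs
  rss1 <- colSums(res^2)
  dfe <- n - p
  keep <- setdiff(colnames(X), trait_terms)
  X0 <- X[, keep, drop = FALSE]
  coef0 <- solve(crossprod(X0), crossprod(X0, Y))
  rss0 <- colSums((Y - X0 %*% coef0)^2)
  dfh <- length(trait_terms)
  f <- pmax(0, (rss0 - rss1) / dfh) / (rss1 / dfe)
  sigma2 <- rss1 / dfe
  se <- sqrt(outer(diag(xtx_inv), sigma2)) # p x m
  tstat <- coefs / se
  list(
    coefficients = coefs,
    f_stat = f,
    p_value = pf(f, dfh, dfe, lower.tail = FALSE),
    partial_eta_sq = partial_eta_squared(f, dfh, dfe),
    slope_p = 2 * pt(-abs(tstat), dfe),
    slope_eta_sq = partial_eta_squared(tstat^2, 1, dfe),
    dfh = dfh, dfe = dfe, residuals = res
  )
}

#' Fit the trait-association GLM for one response
#'
#' @param response numeric vector, one value per subject.
#' @param phenotypes phenotype data.frame (columns `assq`, `srs`, `age`,
#'   `gender`, and `verbal_iq` for design 2).
#' @param design a [glm_design()].
#' @param region label stored with the result (default `"global"`).
#' @return object of class `association_result`: list with `region`,
#'   `f_stat`, `p_value`, `partial_eta_sq`, `dfh`, `dfe`, and `slopes`
#'   (data.frame: `term`, `B`, `partial_eta_sq`, `p`).
#' @export
fit_glm <- function(response, phenotypes, design = glm_design(),
                    region = "global") {
  stopifnot(inherits(design, "glm_design"))
  if (anyNA(response) || length(response) != nrow(phenotypes)) {
    stop_invalid("response must be complete and match the phenotype table")
  }
  X <- .design_matrix(phenotypes, design)
  fit <- .ols_family(cbind(response), X, design$trait_terms)
  slopes <- data.frame(
    term = colnames(X),
    B = fit$coefficients[, 1],
    partial_eta_sq = fit$slope_eta_sq[, 1],
    p = fit$slope_p[, 1],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(
      region = region,
      f_stat = unname(fit$f_stat),
      p_value = unname(fit$p_value),
      partial_eta_sq = unname(fit$partial_eta_sq),
      dfh = fit$dfh, dfe = fit$dfe,
      slopes = slopes,
      residuals = fit$residuals[, 1]
    ),
    class = "association_result"
  )
}

#' Partial eta squared from an F statistic
#'
#' `eta_p^2 = F * dfh / (F * dfh + dfe)`; 0 for F = 0 and approaching 1
#' as F grows.
#'
#' @param f F statistic(s), `>= 0`.
#' @param dfh hypothesis degrees of freedom, `>= 1`.
#' @param dfe error degrees of freedom, `>= 1`.
#' @return value(s) in `[0, 1]`.
#' @export
partial_eta_squared <- function(f, dfh, dfe) {
  if (any(f < 0) || any(dfh < 1) || any(dfe < 1)) {
    stop_invalid("need f >= 0, dfh >= 1, dfe >= 1")
  }
  (f * dfh) / (f * dfh + dfe)
}

#' Benjamini-Hochberg FDR rejection flags
#'
#' Step-up procedure: with ordered p-values `p_(1) <= ... <= p_(m)`,
#' reject all hypotheses up to the largest `k` with
#' `p_(k) <= (k / m) * alpha`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return logical rejection flags aligned with `p_values`.
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop_invalid("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH") <= alpha
}

#' Per-region trait association with FDR control
#'
#' Fits the design to every region of one metric family (degree,
#' efficiency or FA) and applies Benjamini-Hochberg FDR across the
#' family's regions.
#'
#' @param metrics numeric matrix, subjects x regions (column names are
#'   region labels).
#' @param phenotypes phenotype data.frame aligned with the rows.
#' @param design a [glm_design()].
#' @param alpha FDR level (default 0.05).
#' @return data.frame, one row per region: `region`, `f_stat`,
#'   `p_value`, `partial_eta_sq`, `dfh`, `dfe`, one `b_<term>` /
#'   `p_<term>` pair per trait term, and `fdr_significant`.
#' @export
run_regional_association <- function(metrics, phenotypes,
                                     design = glm_design(), alpha = 0.05) {
  metrics <- as.matrix(metrics)
  if (nrow(metrics) != nrow(phenotypes)) {
    stop_invalid("metrics rows must align with the phenotype table")
  }
  regions <- colnames(metrics)
  if (is.null(regions)) regions <- default_region_names(ncol(metrics))
  X <- .design_matrix(phenotypes, design)
  fit <- .ols_family(metrics, X, design$trait_terms)
  out <- data.frame(
    region = regions,
    f_stat = unname(fit$f_stat),
    p_value = unname(fit$p_value),
    partial_eta_sq = unname(fit$partial_eta_sq),
    dfh = fit$dfh, dfe = fit$dfe,
    stringsAsFactors = FALSE
  )
  for (term in design$trait_terms) {
    out[[paste0("b_", term)]] <- unname(fit$coefficients[term, ])
    out[[paste0("p_", term)]] <- unname(fit$slope_p[term, ])
  }
  out$fdr_significant <- bh_fdr(out$p_value, alpha)
  out
}
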