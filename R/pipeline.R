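# End-to-end pipeline: (synthetic or supplied) data -> wavelet
# connectivity -> cost-integrated topology -> mean SPN -> GLM
# association, with optional CSV/JSON output and a reproducibility
# manifest.

#' Pipeline configuration
#'
#' @param cohort a [cohort_config()]; also supplies the master seed.
#' @param level wavelet band analysed (default 3).
#' @param cost a [cost_config()] for the topology stage. Its seed, when
#'   `NULL`, is derived per subject from the master seed.
#' @param design a [glm_design()] for the association stage.
#' @param alpha FDR level (default 0.05).
#' @param spn_percentile percentile used for seed-profile thresholds
#'   (default 95).
#' @param output_dir optional directory; when set, [run_pipeline()]
#'   writes per-subject matrices, metric tables, association tables and
#'   a run manifest there.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), level = 3L,
                            cost = cost_config(), design = glm_design(),
                            alpha = 0.05, spn_percentile = 95,
                            output_dir = NULL) {
  stopifnot(inherits(cohort, "cohort_config"), inherits(cost, "cost_config"),
            inherits(design, "glm_design"))
  structure(
    list(
      cohort = cohort, level = as.integer(level), cost = cost,
      design = design, alpha = alpha, spn_percentile = spn_percentile,
      output_dir = output_dir
    ),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Chains the stages: phenotype + BOLD (+ FA) generation (or user-given
#' inputs), per-subject wavelet connectivity, per-subject Monte-Carlo
#' cost-integrated topology, the population mean SPN, and the per-region
#' GLM association with FDR control for the degree, efficiency and FA
#' families plus the two global efficiencies. Identical configuration
#' and seed reproduce identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param bold optional named list of regions x time matrices; defaults
#'   to synthetic data from the cohort config.
#' @param phenotypes optional phenotype data.frame with `subject_id`;
#'   required when `bold` is supplied.
#' @param fa optional subjects x regions FA matrix; synthetic by
#'   default.
#' @return list of class `pipeline_result` with `phenotypes`, `networks`
#'   (per-subject weighted networks), `correlations`, `metrics` (list of
#'   subjects x regions matrices `degree_star`, `efficiency_star`, and
#'   vectors `eg_star`, `el_star`), `spn`, `fa`, `associations` (list of
#'   data.frames `degree`, `efficiency`, `fa` and `global`), and
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), bold = NULL,
                         phenotypes = NULL, fa = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cc <- config$cohort
  if (is.null(phenotypes)) {
    phenotypes <- generate_phenotypes(cc)
  }
  if (is.null(bold)) {
    bold <- generate_bold(cc, phenotypes)
  } else {
    missing_ph <- setdiff(names(bold), phenotypes$subject_id)
    missing_bold <- setdiff(phenotypes$subject_id, names(bold))
    if (length(missing_ph) || length(missing_bold)) {
      stop_invalid(
        "subject mismatch between BOLD and phenotypes; ",
        if (length(missing_ph)) {
          paste0("no phenotype for: ",
                 paste(missing_ph, collapse = ", "), ". ")
        } else "",
        if (length(missing_bold)) {
          paste0("no BOLD for: ", paste(missing_bold, collapse = ", "))
        } else ""
      )
    }
    bold <- bold[phenotypes$subject_id]
  }
  if (is.null(fa)) {
    fa <- generate_fa(cc, phenotypes)$fa
  }

  n_sub <- length(bold)
  conn <- lapply(bold, build_connectivity,
                 tr = cc$tr, level = config$level)
  networks <- lapply(conn, `[[`, "network")
  correlations <- lapply(conn, `[[`, "correlation")

  want_global <- any(c("global_efficiency", "local_efficiency") %in%
                       config$cost$metric_set)
  metrics <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    cfg_s <- config$cost
    if (is.null(cfg_s$seed)) {
      cfg_s$seed <- derive_seed(cc$seed, c(6L, s))
    }
    metrics[[s]] <- cost_integrate(networks[[s]], cfg_s)
  }
  region_names <- networks[[1]]$region_names
  collect <- function(field) {
    if (is.null(metrics[[1]][[field]])) return(NULL)
    m <- t(vapply(metrics, `[[`, numeric(length(region_names)), field))
    dimnames(m) <- list(phenotypes$subject_id, region_names)
    m
  }
  metric_tables <- list(
    degree_star = collect("degree_star"),
    efficiency_star = collect("efficiency_star"),
    eg_star = vapply(metrics, `[[`, numeric(1), "eg_star"),
    el_star = vapply(metrics, `[[`, numeric(1), "el_star")
  )

  spn <- mean_spn(correlations)

  associations <- list()
  if (!is.null(metric_tables$degree_star)) {
    associations$degree <- run_regional_association(
      metric_tables$degree_star, phenotypes, config$design, config$alpha
    )
  }
  if (!is.null(metric_tables$efficiency_star)) {
    associations$efficiency <- run_regional_association(
      metric_tables$efficiency_star, phenotypes, config$design, config$alpha
    )
  }
  if (!is.null(fa)) {
    associations$fa <- run_regional_association(
      fa, phenotypes, config$design, config$alpha
    )
  }
  if (want_global && !anyNA(metric_tables$eg_star)) {
    glob <- rbind(
      as.data.frame(unclass(fit_glm(metric_tables$eg_star, phenotypes,
                                    config$design, "E_g*"))[
        c("region", "f_stat", "p_value", "partial_eta_sq", "dfh", "dfe")
      ]),
      if (!anyNA(metric_tables$el_star)) {
        as.data.frame(unclass(fit_glm(metric_tables$el_star, phenotypes,
                                      config$design, "E_l*"))[
          c("region", "f_stat", "p_value", "partial_eta_sq", "dfh", "dfe")
        ])
      }
    )
    associations$global <- glob
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("costnet")),
    seed = cc$seed,
    n_subjects = cc$n_subjects, n_regions = cc$n_regions,
    n_timepoints = cc$n_timepoints, tr = cc$tr,
    wavelet_level = config$level,
    cost_range = config$cost$cost_range,
    cost_samples = config$cost$n_samples,
    design_id = config$design$design_id, trait = config$design$trait,
    alpha = config$alpha,
    config_hash = config_hash(config),
    timestamp = format(Sys.time(), tz = "UTC")
  )

  result <- structure(
    list(
      phenotypes = phenotypes, networks = networks,
      correlations = correlations, metrics = metric_tables,
      spn = spn, fa = fa, associations = associations,
      manifest = manifest
    ),
    class = "pipeline_result"
  )
  if (!is.null(config$output_dir)) {
    write_pipeline_outputs(result, config$output_dir)
  }
  result
}

#' Deterministic configuration fingerprint
#'
#' Serialises the configuration (timestamps excluded) to canonical JSON
#' and hashes it with a 64-bit FNV-1a digest, so a manifest records
#' exactly which configuration produced a run.
#'
#' @param config any serialisable configuration object.
#' @return hexadecimal string.
#' @export
config_hash <- function(config) {
  json <- jsonlite::toJSON(unclass_recursive(config), auto_unbox = TRUE,
                           digits = NA, null = "null")
  bytes <- utf8ToInt(as.character(json))
  # FNV-1a, 64-bit arithmetic emulated on doubles via two 32-bit halves
  # is overkill here; a 2^53-safe variant is enough for a fingerprint.
  h <- 1469598103
  for (b in bytes) {
    h <- ((bitwXor(h, b)) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

unclass_recursive <- function(x) {
  if (is.list(x)) {
    lapply(unclass(x), unclass_recursive)
  } else if (is.function(x)) {
    NULL
  } else {
    unclass(x)
  }
}

#' Write pipeline outputs to a directory
#'
#' Per-subject correlation and weight matrices, metric tables, the SPN
#' z-matrix, association tables and the JSON manifest, all as plain
#' text.
#'
#' @param result a `pipeline_result`.
#' @param dir output directory (created if absent).
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sub_dir <- file.path(dir, "subjects")
  dir.create(sub_dir, showWarnings = FALSE)
  for (id in names(result$networks)) {
    write_matrix_csv(result$correlations[[id]]$r,
                     file.path(sub_dir, paste0(id, "_correlation.csv")))
    write_matrix_csv(result$networks[[id]]$w,
                     file.path(sub_dir, paste0(id, "_weights.csv")))
  }
  write.csv(result$phenotypes, file.path(dir, "phenotypes.csv"),
            row.names = FALSE)
  for (fld in c("degree_star", "efficiency_star")) {
    if (!is.null(result$metrics[[fld]])) {
      write_matrix_csv(result$metrics[[fld]],
                       file.path(dir, paste0(fld, ".csv")))
    }
  }
  write.csv(
    data.frame(
      subject_id = result$phenotypes$subject_id,
      eg_star = result$metrics$eg_star, el_star = result$metrics$el_star
    ),
    file.path(dir, "global_metrics.csv"), row.names = FALSE
  )
  write_matrix_csv(result$spn$z, file.path(dir, "spn_z.csv"))
  if (!is.null(result$fa)) {
    write_matrix_csv(result$fa, file.path(dir, "fa.csv"))
  }
  for (fam in names(result$associations)) {
    write.csv(result$associations[[fam]],
              file.path(dir, paste0("association_", fam, ".csv")),
              row.names = FALSE)
  }
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
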