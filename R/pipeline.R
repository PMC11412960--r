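#' Pipeline configuration
#'
#' One object holding every tunable of the simulation-analysis chain, so a
#' full run is reproducible from the configuration plus its seed. Defaults
#' are the reference-cohort conditions: 50 subjects per group, a single
#' shell at b = 1000 s/mm^2 with 32 directions plus one b = 0, SNR 30
#' Rician noise, and a 40 x 40 x 20 voxel phantom at 2 mm.
#'
#' @param seed master integer seed; all per-subject seeds derive from it.
#' @param n_tinnitus,n_hc group sizes.
#' @param geom a [phantom_geometry()].
#' @param gtab a [gradient_table()].
#' @param s0 non-weighted signal amplitude.
#' @param snr signal-to-noise ratio s0/sigma; 0 or Inf disables noise.
#' @param coupling a [coupling_spec()].
#' @param params_tinnitus,params_hc [group_params()] for each group.
#' @param welch,alpha,alpha_normality statistics options (see
#'   [compare_groups()]).
#' @param write_dwi write per-subject DWI NIfTI files when an output
#'   directory is given.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, n_tinnitus = 50L, n_hc = 50L,
                            geom = phantom_geometry(),
                            gtab = default_gradient_table(),
                            s0 = 1000, snr = 30,
                            coupling = coupling_spec(),
                            params_tinnitus = group_params("tinnitus",
                                                           n_subjects = n_tinnitus),
                            params_hc = group_params("HC", n_subjects = n_hc),
                            welch = FALSE, alpha = 0.05,
                            alpha_normality = 0.05, write_dwi = TRUE) {
  stopifnot(is.numeric(seed), length(seed) == 1L, s0 > 0, snr >= 0)
  structure(list(schema_version = 1L, seed = as.integer(seed),
                 geom = geom, gtab = gtab, s0 = s0, snr = snr,
                 coupling = coupling, params_tinnitus = params_tinnitus,
                 params_hc = params_hc, welch = welch, alpha = alpha,
                 alpha_normality = alpha_normality, write_dwi = write_dwi),
            class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration (lossless JSON round trip)
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return `write_config` returns the path invisibly; `read_config` the
#'   restored `pipeline_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- list(
    schema_version = config$schema_version, seed = config$seed,
    geom = list(dim = config$geom$dim, voxel_mm = config$geom$voxel_mm,
                background_diffusivity = config$geom$background_diffusivity,
                roi_blocks = lapply(config$geom$roi_blocks,
                                    function(b) as.vector(t(b)))),
    gtab = list(bvals = config$gtab$bvals,
                bvecs = as.vector(config$gtab$bvecs)),
    s0 = config$s0, snr = config$snr,
    coupling = unclass(config$coupling),
    groups = lapply(list(tinnitus = config$params_tinnitus,
                         HC = config$params_hc), function(p)
      list(group_label = p$group_label, n_subjects = p$n_subjects,
           diffusivity_mean = as.list(p$diffusivity_mean),
           diffusivity_sd = as.list(p$diffusivity_sd),
           score_mean = as.list(p$score_mean),
           score_sd = as.list(p$score_sd),
           male_prob = p$male_prob)),
    welch = config$welch, alpha = config$alpha,
    alpha_normality = config$alpha_normality, write_dwi = config$write_dwi)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- phantom_geometry(
    dim = x$geom$dim, voxel_mm = x$geom$voxel_mm,
    background_diffusivity = x$geom$background_diffusivity,
    roi_blocks = lapply(x$geom$roi_blocks,
                        function(v) matrix(v, 3L, 2L, byrow = TRUE)))
  gtab <- gradient_table(x$gtab$bvals,
                         matrix(x$gtab$bvecs, ncol = 3L))
  mk_params <- function(g) {
    unl <- function(l) vapply(l, function(e)
      if (is.null(e)) NA_real_ else as.numeric(e), 1)
    group_params(g$group_label, n_subjects = g$n_subjects,
                 diffusivity_mean = unlist(g$diffusivity_mean),
                 diffusivity_sd = unlist(g$diffusivity_sd),
                 score_mean = unl(g$score_mean),
                 score_sd = unl(g$score_sd),
                 male_prob = g$male_prob)
  }
  pipeline_config(seed = x$seed, geom = geom, gtab = gtab, s0 = x$s0,
                  snr = x$snr,
                  coupling = coupling_spec(x$coupling$target_r_alps_tmtb,
                                           x$coupling$target_r_dyyproj_avlt),
                  params_tinnitus = mk_params(x$groups$tinnitus),
                  params_hc = mk_params(x$groups$HC),
                  welch = x$welch, alpha = x$alpha,
                  alpha_normality = x$alpha_normality,
                  write_dwi = x$write_dwi)
}

#' Run the full simulation-analysis chain
#'
#' Simulates a cohort, builds each subject's tensor phantom, simulates the
#' DWI signal with Rician noise, fits the tensor per ROI voxel, extracts
#' the nine ROI diffusivities and the ALPS index, and assembles the three
#' group-comparison reports (demographics, cognition, diffusivities) and
#' the covariate-adjusted correlation battery within the tinnitus group.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; when given, cohort, measured
#'   profile, report CSVs and a JSON results bundle are written (DWI
#'   volumes too when `config$write_dwi`).
#' @return list with `cohort`, `truth`, `measured` (per-subject profile +
#'   ALPS + orientation pass flags), `reports` (list of comparison tables),
#'   `correlations`, and `paths`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- simulate_cohort(config, out_dir = if (isTRUE(config$write_dwi))
    out_dir else NULL)
  geom <- config$geom
  roi <- roi_mask(geom)
  sigma <- if (config$snr > 0 && is.finite(config$snr))
    config$s0 / config$snr else 0
  seeds <- sim$seeds
  measured <- vector("list", nrow(sim$truth))
  for (i in seq_len(nrow(sim$truth))) {
    truth <- as.list(sim$truth[i, ])
    field <- build_tensor_field(truth, geom)
    dwi <- simulate_dwi(field, config$gtab, s0 = config$s0, sigma = sigma,
                        seed = seeds[i, 3L])
    res <- subject_alps(dwi, config$gtab, roi,
                        subject_id = truth$subject_id)
    measured[[i]] <- data.frame(
      subject_id = truth$subject_id, group = truth$group,
      t(unlist(res$profile[diffusivity_names()])),
      alps_index = res$alps$alps_index,
      orientation_ok = all(res$orientation$pass),
      stringsAsFactors = FALSE)
  }
  measured <- do.call(rbind, measured)
  demo_vars <- c("age", "gender", "education_years", "hearing_left",
                 "hearing_right", "hearing_avg", "gm_pct_tiv", "wm_pct_tiv")
  cog_vars <- c("mmse", "moca", "avlt", "cft", "cft_delay", "dst", "tmt_a",
                "tmt_b", "cdt", "vft", "dsst", "sas", "sds")
  merged <- merge(sim$cohort, measured[, c("subject_id", diffusivity_names(),
                                           "alps_index")], by = "subject_id")
  reports <- list(
    demographics = compare_groups(sim$cohort, demo_vars,
                                  alpha = config$alpha,
                                  alpha_normality = config$alpha_normality,
                                  welch = config$welch),
    cognition = compare_groups(sim$cohort, cog_vars, alpha = config$alpha,
                               alpha_normality = config$alpha_normality,
                               welch = config$welch),
    diffusivity = compare_groups(merged, c(diffusivity_names(), "alps_index"),
                                 alpha = config$alpha,
                                 alpha_normality = config$alpha_normality,
                                 welch = config$welch))
  tin <- merged[merged$group == "tinnitus", ]
  correlations <- tryCatch(
    correlation_battery(tin, imaging_vars = c("alps_index", "Dyyproj"),
                        score_vars = cog_vars, method = "pearson"),
    error = function(e) {
      warning("correlation battery skipped: ", conditionMessage(e))
      NULL
    })
  paths <- sim$paths
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (is.null(paths)) {
      paths <- list(cohort = file.path(out_dir, "cohort.csv"),
                    truth = file.path(out_dir, "ground_truth.csv"))
      utils::write.csv(sim$cohort, paths$cohort, row.names = FALSE)
      utils::write.csv(sim$truth, paths$truth, row.names = FALSE)
    }
    paths$measured <- file.path(out_dir, "alps_measured.csv")
    utils::write.csv(measured, paths$measured, row.names = FALSE)
    for (nm in names(reports)) {
      paths[[paste0("report_", nm)]] <-
        file.path(out_dir, paste0("report_", nm, ".csv"))
      utils::write.csv(reports[[nm]], paths[[paste0("report_", nm)]],
                       row.names = FALSE)
    }
    if (!is.null(correlations)) {
      paths$correlations <- file.path(out_dir, "correlations.csv")
      utils::write.csv(correlations, paths$correlations, row.names = FALSE)
    }
    paths$results_json <- file.path(out_dir, "results.json")
    write_results_json(list(reports = reports, correlations = correlations),
                       paths$results_json)
  }
  list(cohort = sim$cohort, truth = sim$truth, measured = measured,
       reports = reports, correlations = correlations, paths = paths)
}
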