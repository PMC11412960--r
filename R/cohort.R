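#' Names of the nine fiber-type ROI diffusivities
#'
#' Diagonal diffusivities (x, y, z) read in each of the projection,
#' association and subcortical fiber ROIs.
#'
#' @return character vector of length 9.
#' @export
diffusivity_names <- function() {
  c("Dxxproj", "Dyyproj", "Dzzproj",
    "Dxxassoc", "Dyyassoc", "Dzzassoc",
    "Dxxsub", "Dyysub", "Dzzsub")
}

#' Names of the demographic / clinical / cognitive score columns
#' @return character vector.
#' @export
score_names <- function() {
  c("age", "education_years", "thq", "hearing_left", "hearing_right",
    "gm_pct_tiv", "wm_pct_tiv",
    "mmse", "moca", "avlt", "cft", "cft_delay", "dst", "tmt_a", "tmt_b",
    "cdt", "vft", "dsst", "sas", "sds")
}

#' Group-level simulation parameters
#'
#' Marginal mean and SD for each of the nine ROI diffusivities and each
#' demographic/cognitive score, plus the male proportion and group size.
#' Defaults reproduce the summary statistics of a published chronic-tinnitus
#' versus healthy-control cohort (n = 50 per group): lower ALPS index and
#' higher Dyyproj in the tinnitus group, worse AVLT and TMT-B performance,
#' matched age, sex, education and hearing thresholds.
#'
#' @param group `"tinnitus"` or `"HC"`.
#' @param n_subjects group size (default 50).
#' @param diffusivity_mean,diffusivity_sd named numeric vectors over
#'   [diffusivity_names()], mm^2/s. Means must lie in the physiological
#'   range \[1e-5, 5e-3\] mm^2/s; SDs must be non-negative.
#' @param score_mean,score_sd named numeric vectors over [score_names()].
#'   NA entries mark scores not administered to the group (e.g. the tinnitus
#'   handicap questionnaire in controls).
#' @param male_prob probability a subject is male (default 23/50).
#' @return object of class `group_params`.
#' @export
group_params <- function(group = c("tinnitus", "HC"), n_subjects = 50L,
                         diffusivity_mean = NULL, diffusivity_sd = NULL,
                         score_mean = NULL, score_sd = NULL,
                         male_prob = 23 / 50) {
  group <- match.arg(group)
  def <- cohort_reference_params()[[group]]
  if (is.null(diffusivity_mean)) diffusivity_mean <- def$diffusivity_mean
  if (is.null(diffusivity_sd)) diffusivity_sd <- def$diffusivity_sd
  if (is.null(score_mean)) score_mean <- def$score_mean
  if (is.null(score_sd)) score_sd <- def$score_sd
  dm <- diffusivity_mean[diffusivity_names()]
  ds <- diffusivity_sd[diffusivity_names()]
  for (nm in diffusivity_names()) {
    if (!is.finite(dm[[nm]]))
      stop("non-finite diffusivity mean for ", nm)
    if (!is.finite(ds[[nm]]) || ds[[nm]] < 0)
      stop("invalid diffusivity SD for ", nm)
    if (dm[[nm]] < 1e-5 || dm[[nm]] > 5e-3)
      stop(sprintf("diffusivity mean for %s (%g mm^2/s) outside the physiological range [1e-5, 5e-3]",
                   nm, dm[[nm]]))
  }
  sm <- score_mean[score_names()]
  ss <- score_sd[score_names()]
  bad <- names(sm)[!is.na(sm) & !is.finite(sm)]
  if (length(bad)) stop("non-finite score mean for ", bad[1])
  if (any(!is.na(ss) & ss < 0)) stop("negative score SD")
  stopifnot(n_subjects >= 1, male_prob >= 0, male_prob <= 1)
  structure(list(group_label = group, n_subjects = as.integer(n_subjects),
                 diffusivity_mean = dm, diffusivity_sd = ds,
                 score_mean = sm, score_sd = ss, male_prob = male_prob),
            class = "group_params")
}

#' Reference summary statistics for the two study groups
#'
#' The published per-group means and SDs used as simulation defaults:
#' demographics and clinical measures, thirteen neuropsychological scores,
#' and the nine ROI diffusivities (mm^2/s).
#'
#' @return named list with elements `tinnitus` and `HC`, each holding
#'   `diffusivity_mean`, `diffusivity_sd`, `score_mean`, `score_sd`.
#' @export
cohort_reference_params <- function() {
  dn <- diffusivity_names()
  tin_dm <- c(0.00060, 0.00042, 0.00111, 0.00063, 0.00111, 0.00038,
              0.00110, 0.00051, 0.00089)
  tin_ds <- c(0.00005, 0.00006, 0.00006, 0.00007, 0.00007, 0.00007,
              0.00010, 0.00011, 0.00033)
  hc_dm  <- c(0.00059, 0.00039, 0.00110, 0.00062, 0.00110, 0.00036,
              0.00108, 0.00058, 0.00098)
  hc_ds  <- c(0.00004, 0.00005, 0.00006, 0.00008, 0.00005, 0.00006,
              0.00013, 0.00027, 0.00030)
  names(tin_dm) <- names(tin_ds) <- names(hc_dm) <- names(hc_ds) <- dn
  sn <- score_names()
  tin_sm <- c(age = 50.38, education_years = 10.78, thq = 51.51,
              hearing_left = 16.60, hearing_right = 16.85,
              gm_pct_tiv = 32.16, wm_pct_tiv = 29.58,
              mmse = 28.88, moca = 25.74, avlt = 32.68, cft = 34.40,
              cft_delay = 16.83, dst = 11.16, tmt_a = 69.34, tmt_b = 183.10,
              cdt = 3.48, vft = 14.39, dsst = 69.78, sas = 36.52, sds = 38.58)
  tin_ss <- c(age = 13.56, education_years = 1.81, thq = 15.64,
              hearing_left = 2.68, hearing_right = 3.03,
              gm_pct_tiv = 2.05, wm_pct_tiv = 1.45,
              mmse = 1.27, moca = 1.72, avlt = 7.13, cft = 1.76,
              cft_delay = 3.40, dst = 1.60, tmt_a = 20.44, tmt_b = 51.57,
              cdt = 0.54, vft = 3.90, dsst = 7.72, sas = 5.96, sds = 9.08)
  hc_sm <- c(age = 48.76, education_years = 10.94, thq = NA,
             hearing_left = 17.68, hearing_right = 17.10,
             gm_pct_tiv = 32.75, wm_pct_tiv = 29.50,
             mmse = 28.82, moca = 26.20, avlt = 35.78, cft = 34.71,
             cft_delay = 17.32, dst = 11.80, tmt_a = 69.44, tmt_b = 152.36,
             cdt = 3.54, vft = 14.96, dsst = 69.04, sas = 36.02, sds = 38.00)
  hc_ss <- c(age = 15.21, education_years = 1.87, thq = NA,
             hearing_left = 3.81, hearing_right = 3.48,
             gm_pct_tiv = 1.92, wm_pct_tiv = 1.67,
             mmse = 1.24, moca = 1.76, avlt = 7.19, cft = 1.53,
             cft_delay = 3.69, dst = 2.14, tmt_a = 21.13, tmt_b = 48.65,
             cdt = 0.54, vft = 3.68, dsst = 10.16, sas = 6.45, sds = 9.14)
  list(tinnitus = list(diffusivity_mean = tin_dm, diffusivity_sd = tin_ds,
                       score_mean = tin_sm[sn], score_sd = tin_ss[sn]),
       HC = list(diffusivity_mean = hc_dm, diffusivity_sd = hc_ds,
                 score_mean = hc_sm[sn], score_sd = hc_ss[sn]))
}

#' Imaging-cognition coupling targets
#'
#' Population correlations injected into the tinnitus group: ALPS index
#' with TMT-B (set shifting; higher = worse, so a lower ALPS pairs with a
#' higher TMT-B at the default -0.309) and Dyyproj with AVLT (auditory
#' verbal memory, default -0.413).
#'
#' @param target_r_alps_tmtb,target_r_dyyproj_avlt correlation coefficients,
#'   each strictly inside (-1, 1).
#' @return object of class `coupling_spec`.
#' @export
coupling_spec <- function(target_r_alps_tmtb = -0.309,
                          target_r_dyyproj_avlt = -0.413) {
  for (r in c(target_r_alps_tmtb, target_r_dyyproj_avlt))
    if (!is.finite(r) || abs(r) >= 1)
      stop("coupling correlation must be finite with |r| < 1")
  structure(list(target_r_alps_tmtb = target_r_alps_tmtb,
                 target_r_dyyproj_avlt = target_r_dyyproj_avlt),
            class = "coupling_spec")
}

# truncated-normal draw with a hard floor (floor is >= 6 SD below every
# reference diffusivity mean, so the truncation bias is negligible)
rnorm_floor <- function(n, mean, sd, floor = 1e-5) {
  pmax(floor, stats::rnorm(n, mean, sd))
}

#' Draw one subject's ground-truth ROI diffusivities
#'
#' Each of the nine diffusivities is drawn independently from a normal with
#' the group's marginal mean/SD, truncated below at 1e-5 mm^2/s; the true
#' ALPS index is computed from the four constituent draws.
#'
#' @param params a [group_params()].
#' @param seed non-negative integer seed.
#' @return object of class `subject_truth`: the nine named diffusivities
#'   plus `alps_true` and `group_label`.
#' @export
draw_subject_truth <- function(params, seed) {
  stopifnot(inherits(params, "group_params"), is.numeric(seed), seed >= 0)
  set.seed(as.integer(seed))
  d <- rnorm_floor(9L, params$diffusivity_mean, params$diffusivity_sd)
  names(d) <- diffusivity_names()
  out <- as.list(d)
  out$alps_true <- alps_ratio(d[["Dxxproj"]], d[["Dxxassoc"]],
                              d[["Dyyproj"]], d[["Dzzassoc"]])
  out$group_label <- params$group_label
  structure(out, class = "subject_truth")
}

#' Population mean and SD of the true ALPS index under a group's parameters
#'
#' Under independent normal diffusivity draws the ALPS index is a ratio of
#' two independent normals N = (Dxxproj + Dxxassoc)/2 and
#' M = (Dyyproj + Dzzassoc)/2. Its first two moments follow from
#' E\[N/M\] = E\[N\] E\[1/M\] and E\[(N/M)^2\] = E\[N^2\] E\[1/M^2\]; the
#' reciprocal moments of the denominator are evaluated by numerical
#' integration against its normal density (the denominator mean sits more
#' than 8 SDs above zero for the reference parameters, so the integrals are
#' well defined to numerical precision and the 1e-5 mm^2/s truncation is
#' negligible).
#'
#' @param params a [group_params()].
#' @return list with `mean` and `sd` of the true ALPS index.
#' @export
alps_population_moments <- function(params) {
  stopifnot(inherits(params, "group_params"))
  dm <- params$diffusivity_mean; ds <- params$diffusivity_sd
  mu_n <- (dm[["Dxxproj"]] + dm[["Dxxassoc"]]) / 2
  sd_n <- sqrt(ds[["Dxxproj"]]^2 + ds[["Dxxassoc"]]^2) / 2
  mu_m <- (dm[["Dyyproj"]] + dm[["Dzzassoc"]]) / 2
  sd_m <- sqrt(ds[["Dyyproj"]]^2 + ds[["Dzzassoc"]]^2) / 2
  if (sd_m == 0) {
    e1 <- 1 / mu_m; e2 <- 1 / mu_m^2
  } else {
    lo <- mu_m - 8 * sd_m
    hi <- mu_m + 8 * sd_m
    if (lo <= 0)
      stop("denominator distribution too close to zero for ratio moments")
    e1 <- stats::integrate(function(x) stats::dnorm(x, mu_m, sd_m) / x,
                           lo, hi, rel.tol = 1e-10)$value
    e2 <- stats::integrate(function(x) stats::dnorm(x, mu_m, sd_m) / x^2,
                           lo, hi, rel.tol = 1e-10)$value
  }
  m1 <- mu_n * e1
  m2 <- (mu_n^2 + sd_n^2) * e2
  list(mean = m1, sd = sqrt(max(0, m2 - m1^2)))
}

#' Generate one subject's demographic and cognitive record
#'
#' Scores are drawn from the group's marginal normals. Within the tinnitus
#' group, TMT-B is generated as a linear function of the subject's true ALPS
#' index plus independent noise, with slope and residual SD solved in closed
#' form so that the population correlation equals the coupling target while
#' the marginal mean/SD stay at the group values; AVLT is coupled to the
#' true Dyyproj the same way. Covariates (age, gender, education, hearing,
#' volumes) are drawn independently of the imaging truths, so marginal and
#' covariate-adjusted correlations coincide in expectation. Gender is
#' Bernoulli with the group's male proportion, coded 1 = male; the average
#' hearing threshold is the per-subject mean of left and right.
#'
#' @param truth a `subject_truth` from [draw_subject_truth()].
#' @param params a [group_params()].
#' @param coupling a [coupling_spec()].
#' @param seed non-negative integer seed.
#' @return one-row data.frame (a subject record).
#' @export
generate_cognitive_scores <- function(truth, params, coupling, seed) {
  stopifnot(inherits(truth, "subject_truth"), inherits(params, "group_params"),
            inherits(coupling, "coupling_spec"))
  set.seed(as.integer(seed))
  sm <- params$score_mean; ss <- params$score_sd
  vals <- rep(NA_real_, length(sm))
  names(vals) <- names(sm)
  ok <- !is.na(sm)
  vals[ok] <- stats::rnorm(sum(ok), sm[ok], ifelse(is.na(ss[ok]), 0, ss[ok]))
  gender <- stats::rbinom(1L, 1L, params$male_prob)
  if (params$group_label == "tinnitus") {
    am <- alps_population_moments(params)
    z_alps <- if (am$sd > 0) (truth$alps_true - am$mean) / am$sd else 0
    vals[["tmt_b"]] <- coupled_score(sm[["tmt_b"]], ss[["tmt_b"]],
                                     coupling$target_r_alps_tmtb, z_alps)
    mu_d <- params$diffusivity_mean[["Dyyproj"]]
    sd_d <- params$diffusivity_sd[["Dyyproj"]]
    z_dyy <- if (sd_d > 0) (truth$Dyyproj - mu_d) / sd_d else 0
    vals[["avlt"]] <- coupled_score(sm[["avlt"]], ss[["avlt"]],
                                    coupling$target_r_dyyproj_avlt, z_dyy)
  }
  rec <- data.frame(group = params$group_label, gender = gender,
                    t(vals), stringsAsFactors = FALSE)
  rec$hearing_avg <- (rec$hearing_left + rec$hearing_right) / 2
  rec
}

# y = mu + r*sd*z + sqrt(1-r^2)*sd*eps keeps the marginal at (mu, sd) and
# the population correlation with the standardized driver z at r
coupled_score <- function(mu, sd, r, z) {
  mu + r * sd * z + sqrt(1 - r^2) * sd * stats::rnorm(1L)
}

#' Simulate a full cohort
#'
#' Draws ground-truth diffusivities and subject records for both groups
#' under deterministic per-subject seeds derived from the master seed, and
#' (optionally, when `out_dir` is given) writes per-subject DWI volumes with
#' bval/bvec files, the ROI label mask, the cohort table and the
#' ground-truth table to disk.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory, or NULL for an in-memory cohort only.
#' @return list with `cohort` (data.frame, one row per subject), `truth`
#'   (data.frame of true diffusivities and ALPS), `geom`, `gtab`, and
#'   `paths` (named list of files written, or NULL).
#' @export
simulate_cohort <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  groups <- list(config$params_tinnitus, config$params_hc)
  n_tot <- sum(vapply(groups, function(p) p$n_subjects, 1L))
  set.seed(config$seed)
  sub_seeds <- matrix(sample.int(.Machine$integer.max - 1L, 3L * n_tot),
                      ncol = 3L)  # truth, scores, noise
  geom <- config$geom
  gtab <- config$gtab
  sigma <- if (config$snr > 0) config$s0 / config$snr else 0
  write_files <- !is.null(out_dir)
  if (write_files) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  }
  rows <- vector("list", n_tot)
  truths <- vector("list", n_tot)
  i <- 0L
  paths <- list(dwi = character(0))
  for (params in groups) {
    for (j in seq_len(params$n_subjects)) {
      i <- i + 1L
      id <- sprintf("sub-%03d", i)
      truth <- draw_subject_truth(params, sub_seeds[i, 1L])
      rec <- generate_cognitive_scores(truth, params, config$coupling,
                                       sub_seeds[i, 2L])
      rec <- cbind(data.frame(subject_id = id, stringsAsFactors = FALSE), rec)
      rows[[i]] <- rec
      truths[[i]] <- data.frame(subject_id = id, group = params$group_label,
                                t(unlist(truth[diffusivity_names()])),
                                alps_true = truth$alps_true,
                                stringsAsFactors = FALSE)
      if (write_files && config$write_dwi) {
        field <- build_tensor_field(truth, geom)
        dwi <- simulate_dwi(field, gtab, s0 = config$s0, sigma = sigma,
                            seed = sub_seeds[i, 3L])
        p <- file.path(out_dir, paste0(id, "_dwi.nii.gz"))
        write_dwi(dwi, gtab, p)
        paths$dwi <- c(paths$dwi, p)
      }
    }
  }
  cohort <- do.call(rbind, rows)
  cohort <- cohort[, cohort_columns()]
  truth_df <- do.call(rbind, truths)
  out_paths <- NULL
  if (write_files) {
    out_paths <- list(
      cohort = file.path(out_dir, "cohort.csv"),
      truth = file.path(out_dir, "ground_truth.csv"),
      roi_mask = file.path(out_dir, "roi_mask.nii.gz"),
      dwi = paths$dwi
    )
    utils::write.csv(cohort, out_paths$cohort, row.names = FALSE)
    utils::write.csv(truth_df, out_paths$truth, row.names = FALSE)
    RNifti::writeNifti(RNifti::asNifti(roi_mask(geom) + 0,
                                       pixdim = rep(geom$voxel_mm, 3)),
                       out_paths$roi_mask)
  }
  list(cohort = cohort, truth = truth_df, geom = geom, gtab = gtab,
       seeds = sub_seeds, paths = out_paths)
}

#' Column schema of the cohort table
#' @return character vector of required column names, in order.
#' @export
cohort_columns <- function() {
  c("subject_id", "group", "age", "gender", "education_years", "thq",
    "hearing_left", "hearing_right", "hearing_avg", "gm_pct_tiv",
    "wm_pct_tiv", "mmse", "moca", "avlt", "cft", "cft_delay", "dst",
    "tmt_a", "tmt_b", "cdt", "vft", "dsst", "sas", "sds")
}
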