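#' Published ALPS-index group summary
#'
#' Per-group mean and SD of the per-subject ALPS index in the reference
#' cohort, used to recompute the group-difference p-value from summary
#' data. Kept separate from [cohort_reference_params()] because the
#' per-subject index is a derived quantity, not a simulation marginal: its
#' SD reflects the (unpublished) covariance between its four constituent
#' diffusivities.
#'
#' @return list with `tinnitus` and `HC`, each c(mean, sd, n).
#' @export
reference_alps_summary <- function() {
  list(tinnitus = c(mean = 1.51839, sd = 0.11933, n = 50),
       HC = c(mean = 1.61730, sd = 0.14277, n = 50))
}

#' Recompute group-comparison p-values from published summary statistics
#'
#' Applies the pooled t-test to each variable's published per-group
#' mean +/- SD (n = 50 per group), and the chi-square test to the sex
#' split, reproducing the reference tables' p-value column for every
#' variable whose comparison was t-routed. Variables routed to
#' Mann-Whitney in the original analysis (identifiable because their
#' printed p disagrees with the pooled-t recomputation) cannot be
#' reproduced from summaries alone.
#'
#' @param variables character vector of variables to recompute; default all
#'   score and diffusivity variables plus `alps_index` and `gender`.
#' @return data.frame: variable, method, statistic, df, p, p_rounded.
#' @export
recompute_summary_pvalues <- function(variables = NULL) {
  ref <- cohort_reference_params()
  alps <- reference_alps_summary()
  all_vars <- c(score_names(), diffusivity_names(), "alps_index", "gender")
  if (is.null(variables)) variables <- all_vars
  rows <- lapply(variables, function(v) {
    if (v == "gender") {
      tr <- chi_square_2x2(matrix(c(23, 27, 23, 27), 2L), variable = "gender")
    } else if (v == "alps_index") {
      tr <- pooled_t_from_summary(alps$tinnitus[["mean"]], alps$tinnitus[["sd"]],
                                  alps$tinnitus[["n"]],
                                  alps$HC[["mean"]], alps$HC[["sd"]],
                                  alps$HC[["n"]], variable = v)
    } else if (v %in% diffusivity_names()) {
      tr <- pooled_t_from_summary(
        ref$tinnitus$diffusivity_mean[[v]], ref$tinnitus$diffusivity_sd[[v]], 50,
        ref$HC$diffusivity_mean[[v]], ref$HC$diffusivity_sd[[v]], 50,
        variable = v)
    } else if (v %in% score_names()) {
      if (is.na(ref$HC$score_mean[[v]])) return(NULL)  # tinnitus-only measure
      tr <- pooled_t_from_summary(
        ref$tinnitus$score_mean[[v]], ref$tinnitus$score_sd[[v]], 50,
        ref$HC$score_mean[[v]], ref$HC$score_sd[[v]], 50, variable = v)
    } else stop("unknown variable: ", v)
    data.frame(variable = tr$variable, method = tr$method,
               statistic = tr$statistic, df = tr$df, p = tr$p,
               p_rounded = round_half_up(tr$p, 3L), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

#' Group-comparison report over a cohort table
#'
#' For each requested variable: per-group mean +/- SD (or counts for
#' gender), a normality-routed two-sample test ([route_two_sample()];
#' chi-square for gender), the raw and rounded p, a two-tailed
#' significance flag at `alpha`, and — for variables named in
#' `bonferroni_family` — the Bonferroni-adjusted p over that family.
#'
#' @param cohort cohort data.frame with a `group` column (two levels).
#' @param variables character vector of cohort columns to compare.
#' @param alpha two-tailed significance level (default 0.05).
#' @param alpha_normality Shapiro-Wilk routing level (default 0.05).
#' @param welch use Welch's t on the parametric branch.
#' @param bonferroni_family variables forming one multiple-comparison
#'   family (default: those of `variables` that are diffusivity or
#'   ALPS-index columns, the family of the diffusivity table).
#' @return data.frame, one row per variable.
#' @export
compare_groups <- function(cohort, variables, alpha = 0.05,
                           alpha_normality = 0.05, welch = FALSE,
                           bonferroni_family = NULL) {
  missing_cols <- setdiff(c("group", variables), names(cohort))
  if (length(missing_cols))
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "))
  g <- unique(cohort$group)
  if (length(g) != 2L) stop("cohort must contain exactly two groups")
  g <- sort(g, decreasing = TRUE)  # "tinnitus" before "HC" when present
  if ("tinnitus" %in% g) g <- c("tinnitus", setdiff(g, "tinnitus"))
  if (is.null(bonferroni_family))
    bonferroni_family <- intersect(variables,
                                   c(diffusivity_names(), "alps_index"))
  rows <- lapply(variables, function(v) {
    x <- cohort[[v]][cohort$group == g[1]]
    y <- cohort[[v]][cohort$group == g[2]]
    if (v == "gender") {
      counts <- rbind(c(sum(x == 1), sum(x == 0)),
                      c(sum(y == 1), sum(y == 0)))
      tr <- chi_square_2x2(t(counts), variable = v)
      s1 <- sprintf("%d/%d", counts[1, 1], counts[1, 2])
      s2 <- sprintf("%d/%d", counts[2, 1], counts[2, 2])
    } else {
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      s1 <- sprintf("%.5g ± %.5g", mean(x), stats::sd(x))
      s2 <- sprintf("%.5g ± %.5g", mean(y), stats::sd(y))
      if (length(x) < 2 || length(y) < 2) {
        warning("variable ", v, ": a group has < 2 observations; no test run")
        return(data.frame(variable = v, summary_1 = s1, summary_2 = s2,
                          method = NA_character_, statistic = NA_real_,
                          p = NA_real_, p_rounded = NA_real_,
                          significant = NA, stringsAsFactors = FALSE))
      }
      tr <- route_two_sample(x, y, alpha_normality = alpha_normality,
                             variable = v, welch = welch)
    }
    data.frame(variable = v, summary_1 = s1, summary_2 = s2,
               method = tr$method, statistic = tr$statistic, p = tr$p,
               p_rounded = round_half_up(tr$p, 3L),
               significant = !is.na(tr$p) && tr$p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- g
  out$p_bonferroni <- NA_real_
  fam <- out$variable %in% bonferroni_family & !is.na(out$p)
  if (any(fam)) out$p_bonferroni[fam] <- bonferroni_adjust(out$p[fam])
  out
}

#' Covariate-adjusted correlation battery
#'
#' Partial correlation of each imaging variable with each cognitive score
#' within one data.frame (typically the tinnitus subset of a cohort merged
#' with its measured ALPS results), adjusted for the standard covariate
#' set, with a Bonferroni column over all tested pairs.
#'
#' @param data data.frame holding imaging, score and covariate columns.
#' @param imaging_vars,score_vars character vectors of column names.
#' @param covariates character vector of covariate columns (default: age,
#'   gender, education, mean hearing threshold, gray-matter volume).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame: imaging, score, method, r, n, k, df, p, p_bonferroni.
#' @export
correlation_battery <- function(data, imaging_vars, score_vars,
                                covariates = c("age", "gender",
                                               "education_years",
                                               "hearing_avg", "gm_pct_tiv"),
                                method = "pearson") {
  missing_cols <- setdiff(c(imaging_vars, score_vars, covariates), names(data))
  if (length(missing_cols))
    stop("data is missing column(s): ", paste(missing_cols, collapse = ", "))
  Z <- if (length(covariates)) as.matrix(data[covariates]) else NULL
  rows <- list()
  for (iv in imaging_vars) for (sv in score_vars) {
    cr <- partial_correlation(data[[iv]], data[[sv]], Z, method = method,
                              pair = paste(iv, sv, sep = " ~ "))
    rows[[length(rows) + 1L]] <-
      data.frame(imaging = iv, score = sv, method = cr$method, r = cr$r,
                 n = cr$n, k = cr$k, df = cr$df, p = cr$p,
                 stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- bonferroni_adjust(out$p)
  out
}
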