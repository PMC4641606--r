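#' Effect configuration for the synthetic cohort
#'
#' Controls how a patient's latent severity maps to the clinical scores
#' and how much noise blurs the mapping. ALSFRS-R (0–48, falling with
#' physical impairment) and ECAS (0–136, falling with cognitive decline)
#' both decrease in severity.
#'
#' @param alsfrs_base,alsfrs_slope ALSFRS-R at severity 0 and its drop
#'   per unit severity.
#' @param ecas_base,ecas_slope Same for ECAS.
#' @param score_noise_sd SD of Gaussian noise added to both scores
#'   (0 makes the severity-score mapping strictly monotone).
#' @param bulbar_fraction Fraction of patients labelled bulbar onset.
#' @return A list of class `vog_effect_config`.
#' @export
cohort_effect_config <- function(alsfrs_base = 45, alsfrs_slope = 22,
                                 ecas_base = 122, ecas_slope = 40,
                                 score_noise_sd = 2, bulbar_fraction = 0.26) {
  structure(list(alsfrs_base = alsfrs_base, alsfrs_slope = alsfrs_slope,
                 ecas_base = ecas_base, ecas_slope = ecas_slope,
                 score_noise_sd = score_noise_sd,
                 bulbar_fraction = bulbar_fraction),
            class = "vog_effect_config")
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  pmin(hi, pmax(lo, rnorm(n, mean, sd)))
}

# Control phenotypes: narrow distributions around healthy medians so
# that the Tukey fences are tight and staged deficits (>= 3 control SD)
# separate cleanly.
draw_control_phenotype <- function() {
  phenotype(
    spem_gain_true = rnorm_trunc(1, 0.92, 0.03, 0.75, 1.05),
    pursuit_error_mode = "anticipatory",
    n_anticipatory = rpois(1, 1.5),
    anticipatory_amplitude = 3.5,
    ms_vmax = rnorm_trunc(1, 470, 25, 380, 560),
    saccade_gain_true = rnorm_trunc(1, 0.90, 0.02, 0.8, 1),
    latency_mean = rnorm_trunc(1, 0.235, 0.015, 0.18, 0.30),
    anti_error_prob = rnorm_trunc(1, 0.17, 0.06, 0, 0.45),
    delayed_error_prob = rnorm_trunc(1, 0.08, 0.04, 0, 0.25),
    shift_rate = rnorm_trunc(1, 1.9, 0.22, 1.0, 3.2),
    intrusion_rate_true = rnorm_trunc(1, 1.2, 0.30, 0.3, 2.4)
  )
}

#' Build a synthetic cohort with known stage labels
#'
#' Generates a cohort of control, stage-1 (executive deficit) and
#' stage-2 (executive plus brainstem deficit) subjects. A latent
#' severity per patient drives both the oculomotor phenotype parameters
#' (through [phenotype_stage1()] / [phenotype_stage2()]) and the
#' clinical scores, so clinical-oculomotor rank correlations have a
#' controllable ground truth. With `extract = TRUE` (the default) the
#' full simulate–preprocess–extract pipeline is run per subject and the
#' fourteen profile parameters are appended as columns.
#'
#' @param n_control,n_stage1,n_stage2 Group sizes.
#' @param effect A [cohort_effect_config()].
#' @param seed Integer seed; every subject derives its own stream.
#' @param extract Run the recording pipeline and append profiles?
#' @param protocols Protocol battery shared by all subjects.
#' @return A tibble with `id`, `group` (control / als_spinal /
#'   als_bulbar), `stage_true`, `severity`, `alsfrs_r`, `ecas`, a
#'   `phenotype` list-column and (if `extract`) the profile columns.
#' @export
build_synthetic_cohort <- function(n_control = 31, n_stage1 = 20,
                                   n_stage2 = 10,
                                   effect = cohort_effect_config(),
                                   seed = 1L, extract = TRUE,
                                   protocols = make_protocols(seed)) {
  stopifnot(n_control >= 0, n_stage1 >= 0, n_stage2 >= 0)
  n <- n_control + n_stage1 + n_stage2
  cohort <- withr::with_seed(seed, {
    stage_true <- rep(c("stage0", "stage1", "stage2"),
                      c(n_control, n_stage1, n_stage2))
    severity <- c(rep(0, n_control),
                  runif(n_stage1, 0.05, 1),
                  runif(n_stage2, 0.3, 1))
    is_patient <- stage_true != "stage0"
    group <- ifelse(!is_patient, "control",
                    ifelse(runif(n) < effect$bulbar_fraction,
                           "als_bulbar", "als_spinal"))
    phen <- purrr::map(seq_len(n), function(i) {
      switch(stage_true[i],
             stage0 = draw_control_phenotype(),
             stage1 = phenotype_stage1(severity[i]),
             stage2 = phenotype_stage2(severity[i],
                                       slowed = runif(1) < 0.5))
    })
    noise <- function(n) {
      if (effect$score_noise_sd > 0) rnorm(n, 0, effect$score_noise_sd)
      else rep(0, n)
    }
    alsfrs <- round(pmin(48, pmax(
      0, effect$alsfrs_base - effect$alsfrs_slope * severity + noise(n))))
    ecas <- round(pmin(136, pmax(
      0, effect$ecas_base - effect$ecas_slope * severity + noise(n))))
    tibble(
      id = sprintf("S%03d", seq_len(n)),
      group = factor(group, levels = c("control", "als_spinal",
                                       "als_bulbar")),
      stage_true = stage_true, severity = severity,
      alsfrs_r = alsfrs, ecas = ecas, phenotype = phen
    )
  })
  if (extract && n > 0) {
    profiles <- purrr::map_dfr(seq_len(n), function(i) {
      simulate_and_extract(cohort$phenotype[[i]], protocols,
                           seed = seed + 7919L * i)
    })
    cohort <- dplyr::bind_cols(cohort, profiles)
  }
  cohort
}

#' Nonparametric group comparison of one parameter
#'
#' Two-sided Wilcoxon-Mann-Whitney U test between controls and all
#' patients, Kruskal-Wallis rank ANOVA across the three groups
#' (controls, spinal onset, bulbar onset), and — only when the omnibus
#' test is significant at `alpha` — post hoc pairwise Mann-Whitney
#' tests.
#'
#' @param cohort Cohort tibble with a `group` column and the parameter
#'   column.
#' @param parameter Parameter column name.
#' @param alpha Omnibus significance gate for the post hoc tests.
#' @return A list of class `vog_group_test`: `parameter`, `p_two_group`,
#'   `p_omnibus`, `posthoc` (tibble or `NULL`), group sizes.
#' @export
compare_groups <- function(cohort, parameter, alpha = 0.05) {
  x <- cohort[[parameter]]
  grp <- cohort$group
  ok <- is.finite(x) & !is.na(grp)
  x <- x[ok]; grp <- droplevels(factor(grp[ok]))
  sizes <- table(grp)
  if (length(sizes) < 2 || any(sizes < 3)) {
    abort("Each group needs at least 3 subjects.",
          class = "vog_group_error")
  }
  is_ctrl <- grp == "control"
  p2 <- wilcox.test(x[is_ctrl], x[!is_ctrl], exact = FALSE,
                    correct = TRUE)$p.value
  pk <- if (length(sizes) > 2) kruskal.test(x, grp)$p.value else NA_real_
  posthoc <- NULL
  if (!is.na(pk) && pk < alpha) {
    prs <- utils::combn(levels(grp), 2, simplify = FALSE)
    posthoc <- purrr::map_dfr(prs, function(pr) {
      tibble(group1 = pr[1], group2 = pr[2],
             p = wilcox.test(x[grp == pr[1]], x[grp == pr[2]],
                             exact = FALSE, correct = TRUE)$p.value)
    })
  }
  structure(list(parameter = parameter, p_two_group = p2, p_omnibus = pk,
                 posthoc = posthoc, n = as.list(sizes)),
            class = "vog_group_test")
}

#' @export
print.vog_group_test <- function(x, ...) {
  cat(sprintf("<vog_group_test> %s: MWU p = %.4g, KW p = %.4g\n",
              x$parameter, x$p_two_group, x$p_omnibus))
  if (!is.null(x$posthoc)) print(x$posthoc)
  invisible(x)
}

#' @rdname compare_groups
#' @param x A `vog_group_test`.
#' @param ... Unused.
#' @export
tidy.vog_group_test <- function(x, ...) {
  tibble(parameter = x$parameter, test = c("mann_whitney", "kruskal_wallis"),
         p_value = c(x$p_two_group, x$p_omnibus))
}

#' Spearman correlations of oculomotor parameters with clinical scores
#'
#' Spearman rank correlations between each parameter and each clinical
#' score, computed on patients only, with Holm step-down family-wise
#' error correction over the whole parameter-by-score family.
#'
#' @param cohort Cohort tibble (needs `group` plus the parameter and
#'   score columns).
#' @param parameters Parameter columns to correlate.
#' @param scores Clinical score columns.
#' @param min_pairs Minimum complete pairs per test.
#' @return Tibble: `parameter`, `score`, `n`, `rho`, `p_value`,
#'   `p_holm`. Constant inputs yield missing `rho`.
#' @export
correlate_clinical <- function(cohort,
                               parameters = intersect(profile_parameters(),
                                                      names(cohort)),
                               scores = c("alsfrs_r", "ecas"),
                               min_pairs = 10) {
  patients <- dplyr::filter(cohort, .data$group != "control")
  grid <- tidyr::expand_grid(parameter = parameters, score = scores)
  out <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    x <- patients[[grid$parameter[i]]]
    y <- patients[[grid$score[i]]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < min_pairs) {
      abort(sprintf("Fewer than %d complete pairs for %s vs %s.",
                    min_pairs, grid$parameter[i], grid$score[i]),
            class = "vog_correlation_error")
    }
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      return(tibble(parameter = grid$parameter[i], score = grid$score[i],
                    n = sum(ok), rho = NA_real_, p_value = NA_real_))
    }
    ct <- suppressWarnings(
      cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
    tibble(parameter = grid$parameter[i], score = grid$score[i],
           n = sum(ok), rho = unname(ct$estimate), p_value = ct$p.value)
  })
  out$p_holm <- p.adjust(out$p_value, method = "holm")
  out
}

#' Median (IQR), min–max cohort description of the profile parameters
#'
#' @param cohort Cohort tibble with `group` and profile columns.
#' @param parameters Parameters to summarise.
#' @return Long tibble: `parameter`, `group`, `n`, `median`, `q1`, `q3`,
#'   `min`, `max`.
#' @export
summarize_cohort <- function(cohort,
                             parameters = intersect(profile_parameters(),
                                                    names(cohort))) {
  cohort %>%
    select(all_of(c("group", parameters))) %>%
    tidyr::pivot_longer(all_of(parameters), names_to = "parameter") %>%
    filter(is.finite(.data$value)) %>%
    group_by(.data$parameter, .data$group) %>%
    summarise(n = dplyr::n(), median = median(.data$value),
              q1 = unname(quantile(.data$value, 0.25, type = 7)),
              q3 = unname(quantile(.data$value, 0.75, type = 7)),
              min = min(.data$value), max = max(.data$value),
              .groups = "drop")
}

#' Serialize cohort statistics to a JSON report
#'
#' Group descriptions, two- and three-group tests and (when present)
#' post hoc markers for every profile parameter, mirroring the usual
#' clinical-table layout.
#'
#' @param cohort Cohort tibble.
#' @param path Output JSON path.
#' @param parameters Parameters to include.
#' @return `path`, invisibly.
#' @export
write_stats_report <- function(cohort, path,
                               parameters = intersect(profile_parameters(),
                                                      names(cohort))) {
  desc <- summarize_cohort(cohort, parameters)
  tests <- lapply(parameters, function(p) {
    gt <- compare_groups(cohort, p)
    list(parameter = p, p_two_group = gt$p_two_group,
         p_omnibus = gt$p_omnibus,
         posthoc = if (is.null(gt$posthoc)) NULL else gt$posthoc)
  })
  jsonlite::write_json(list(description = desc, tests = tests), path,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
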