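#' Parameters entering the staging decision and their abnormal direction
#'
#' Executive parameters flag when abnormal in the listed direction
#' (error rates, intrusions and the anticipatory saccade sum high;
#' voluntary shift counts low); brainstem parameters are the three peak
#' velocities (low) and the catch-up pursuit pattern (saccade sum below
#' the lower fence *and* negative, together with a pursuit gain below
#' its lower fence). Saccade latencies and the reactive-saccade gains
#' are described per group but do not enter the staging decision.
#'
#' @return Tibble with `parameter`, `abnormal_direction`, `role`, `flag`.
#' @export
staging_parameters <- function() {
  tibble(
    parameter = c("delayed_error_rate", "anti_error_rate",
                  "n_voluntary_shifts", "intrusion_rate",
                  "spem_saccade_sum",
                  "vgrs_h_pv", "vgrs_up_pv", "vgrs_down_pv"),
    abnormal_direction = c("high", "high", "low", "high", "high",
                           "low", "low", "low"),
    role = c(rep("executive", 5), rep("brainstem", 3)),
    flag = c("delayed_error", "anti_error", "voluntary_shifts",
             "intrusion_rate", "anticipatory_spem",
             "pv_horizontal", "pv_up", "pv_down")
  )
}

#' Control-derived Tukey fences
#'
#' For every profile parameter, computes the lower and upper Tukey
#' fences from the control cohort: `Q1 - 1.5 * IQR` and
#' `Q3 + 1.5 * IQR`, with quartiles by linear interpolation between
#' order statistics. Values outside the fence in a parameter's abnormal
#' direction are classified as pathological.
#'
#' @param controls Data frame of control profiles (one row per subject,
#'   columns as in [extract_profile()]).
#' @param parameters Parameters to derive fences for.
#' @param min_controls Minimum number of non-missing control values per
#'   parameter.
#' @return A `vog_reference` object whose `table` has one row per
#'   parameter: `q1`, `q3`, `iqr`, `lower_fence`, `upper_fence`,
#'   `abnormal_direction`, `n_controls`.
#' @examples
#' ctrl <- tibble::tibble(anti_error_rate = c(1:8) * 5)
#' compute_reference(ctrl, parameters = "anti_error_rate",
#'                   min_controls = 8)
#' @export
compute_reference <- function(controls,
                              parameters = intersect(profile_parameters(),
                                                     names(controls)),
                              min_controls = 10) {
  dirs <- staging_parameters()
  tab <- purrr::map_dfr(parameters, function(p) {
    x <- controls[[p]]
    x <- x[is.finite(x)]
    if (length(x) < min_controls) {
      abort(sprintf(
        "Only %d non-missing control values for '%s' (need >= %d).",
        length(x), p, min_controls), class = "vog_reference_error")
    }
    q <- unname(quantile(x, c(0.25, 0.75), type = 7))
    iqr <- q[2] - q[1]
    dirn <- dirs$abnormal_direction[match(p, dirs$parameter)]
    tibble(parameter = p, q1 = q[1], q3 = q[2], iqr = iqr,
           lower_fence = q[1] - 1.5 * iqr, upper_fence = q[2] + 1.5 * iqr,
           abnormal_direction = ifelse(is.na(dirn), "both", dirn),
           n_controls = length(x))
  })
  structure(list(table = tab), class = "vog_reference")
}

#' @export
print.vog_reference <- function(x, ...) {
  cat("<vog_reference> Tukey fences from", x$table$n_controls[1],
      "controls\n")
  print(x$table)
  invisible(x)
}

#' @rdname compute_reference
#' @param x A `vog_reference`.
#' @param ... Unused.
#' @export
tidy.vog_reference <- function(x, ...) x$table

fence_row <- function(reference, parameter) {
  dplyr::filter(reference$table, .data$parameter == !!parameter)
}

#' Flag abnormal parameters of one subject profile
#'
#' Compares a subject's profile against the control fences and returns
#' the executive and brainstem flag sets that drive staging:
#'
#' * executive — `delayed_error` / `anti_error` / `intrusion_rate` above
#'   the upper fence; `voluntary_shifts` below the lower fence;
#'   `anticipatory_spem` when the pursuit saccade sum exceeds the upper
#'   fence.
#' * brainstem — `pv_horizontal` / `pv_up` / `pv_down` below their
#'   lower fences; `catchup_spem` when the pursuit saccade sum is below
#'   the lower fence *and* negative *and* the pursuit gain is below its
#'   lower fence (the conjunction of reduced gain and a negative sum is
#'   what identifies a deficient ponto-cerebellar pursuit component).
#'
#' Missing endpoints never flag.
#'
#' @param profile One-row profile (data frame or list).
#' @param reference A `vog_reference`.
#' @return List with character vectors `executive` and `brainstem`.
#' @export
flag_abnormal <- function(profile, reference) {
  prof <- as.list(profile)
  above <- function(p) {
    f <- fence_row(reference, p)
    nrow(f) == 1 && is.finite(prof[[p]] %||% NA_real_) &&
      prof[[p]] > f$upper_fence
  }
  below <- function(p) {
    f <- fence_row(reference, p)
    nrow(f) == 1 && is.finite(prof[[p]] %||% NA_real_) &&
      prof[[p]] < f$lower_fence
  }
  executive <- c(
    if (above("delayed_error_rate")) "delayed_error",
    if (above("anti_error_rate")) "anti_error",
    if (below("n_voluntary_shifts")) "voluntary_shifts",
    if (above("intrusion_rate")) "intrusion_rate",
    if (above("spem_saccade_sum")) "anticipatory_spem"
  )
  brainstem <- c(
    if (below("vgrs_h_pv")) "pv_horizontal",
    if (below("vgrs_up_pv")) "pv_up",
    if (below("vgrs_down_pv")) "pv_down",
    if (below("spem_saccade_sum") &&
        isTRUE(prof$spem_saccade_sum < 0) &&
        below("spem_gain")) "catchup_spem"
  )
  list(executive = executive %||% character(0),
       brainstem = brainstem %||% character(0))
}

#' Assign the two-stage oculomotor stage from the flag sets
#'
#' Deterministic mapping: no flags at all is stage 0; executive flags
#' only is stage 1; executive plus brainstem flags is stage 2 (stage 2
#' requires at least one executive deficit by construction); brainstem
#' flags without any executive flag do not conform to the staging
#' scheme.
#'
#' @param flags List with `executive` and `brainstem` character vectors
#'   (from [flag_abnormal()]).
#' @return One of `"stage0"`, `"stage1"`, `"stage2"`, `"nonconforming"`.
#' @export
assign_stage <- function(flags) {
  has_ex <- length(flags$executive) > 0
  has_bs <- length(flags$brainstem) > 0
  if (!has_ex && !has_bs) "stage0"
  else if (has_ex && !has_bs) "stage1"
  else if (has_ex && has_bs) "stage2"
  else "nonconforming"
}

#' Stage every subject of a profile table
#'
#' @param profiles Data frame of subject profiles (one row each).
#' @param reference A `vog_reference` from the control cohort.
#' @return `profiles` with added columns `executive_flags`,
#'   `brainstem_flags` (list-columns) and `stage` (factor with levels
#'   stage0 < stage1 < stage2, plus nonconforming).
#' @export
stage_cohort <- function(profiles, reference) {
  fl <- purrr::map(seq_len(nrow(profiles)),
                   function(i) flag_abnormal(profiles[i, ], reference))
  profiles$executive_flags <- purrr::map(fl, "executive")
  profiles$brainstem_flags <- purrr::map(fl, "brainstem")
  profiles$stage <- factor(purrr::map_chr(fl, assign_stage),
                           levels = c("stage0", "stage1", "stage2",
                                      "nonconforming"))
  profiles
}

#' Write / read a staging report as JSON
#'
#' Serializes the control reference fences and the per-subject stage
#' assignments (flags included) to a JSON report.
#'
#' @param staged Output of [stage_cohort()].
#' @param reference The `vog_reference` used.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_staging_report <- function(staged, reference, path) {
  report <- list(
    reference = reference$table,
    subjects = lapply(seq_len(nrow(staged)), function(i) {
      list(
        id = if ("id" %in% names(staged)) staged$id[i] else i,
        stage = as.character(staged$stage[i]),
        executive_flags = staged$executive_flags[[i]],
        brainstem_flags = staged$brainstem_flags[[i]]
      )
    })
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
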