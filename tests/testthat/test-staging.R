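test_that("Tukey fences match the hand-computed order-statistic example", {
  ctrl <- tibble::tibble(anti_error_rate = 1:8)
  ref <- compute_reference(ctrl, parameters = "anti_error_rate",
                           min_controls = 8)
  tab <- tidy(ref)
  expect_equal(tab$q1, 2.75)
  expect_equal(tab$q3, 6.25)
  expect_equal(tab$iqr, 3.5)
  expect_equal(tab$lower_fence, -2.5)
  expect_equal(tab$upper_fence, 11.5)
})

test_that("identical control values collapse both fences onto that value", {
  ctrl <- tibble::tibble(intrusion_rate = rep(1.3, 12))
  tab <- tidy(compute_reference(ctrl, parameters = "intrusion_rate"))
  expect_equal(tab$lower_fence, 1.3)
  expect_equal(tab$upper_fence, 1.3)
})

test_that("fences agree exactly with a brute-force oracle on random samples", {
  withr::with_seed(99, {
    for (i in 1:25) {
      n <- sample(10:60, 1)
      x <- switch(sample(3, 1),
                  rnorm(n, 50, 12),
                  rexp(n, 0.1),
                  sample(0:100, n, replace = TRUE))
      ctrl <- tibble::tibble(delayed_error_rate = x)
      tab <- tidy(compute_reference(ctrl, parameters = "delayed_error_rate"))
      oracle <- oracle_fences(x)
      expect_equal(tab$lower_fence, unname(oracle["lower"]))
      expect_equal(tab$upper_fence, unname(oracle["upper"]))
      # adding an interior point: still exactly the oracle
      x2 <- c(x, median(x))
      tab2 <- tidy(compute_reference(
        tibble::tibble(delayed_error_rate = x2),
        parameters = "delayed_error_rate"))
      oracle2 <- oracle_fences(x2)
      expect_equal(tab2$lower_fence, unname(oracle2["lower"]))
      expect_equal(tab2$upper_fence, unname(oracle2["upper"]))
    }
  })
})

test_that("too few controls abort the reference computation", {
  expect_error(compute_reference(tibble::tibble(spem_gain = rnorm(5))),
               class = "vog_reference_error")
})

make_ref <- function() {
  withr::with_seed(7, tibble::tibble(
    spem_gain = rnorm(31, 90, 4),
    spem_saccade_sum = rnorm(31, 8, 6),
    vgrs_h_pv = rnorm(31, 430, 25),
    vgrs_up_pv = rnorm(31, 430, 25),
    vgrs_down_pv = rnorm(31, 400, 25),
    intrusion_rate = rnorm(31, 1.2, 0.3),
    delayed_error_rate = rnorm(31, 8, 4),
    anti_error_rate = rnorm(31, 18, 6),
    n_voluntary_shifts = rnorm(31, 58, 8)
  )) |> compute_reference()
}

test_that("flagging follows the per-parameter abnormal directions", {
  ref <- make_ref()
  medians <- purrr::map(tidy(ref)$parameter,
                        ~ (tidy(ref)$q1[tidy(ref)$parameter == .x] +
                             tidy(ref)$q3[tidy(ref)$parameter == .x]) / 2)
  names(medians) <- tidy(ref)$parameter
  fl0 <- flag_abnormal(medians, ref)
  expect_length(fl0$executive, 0)
  expect_length(fl0$brainstem, 0)

  hi_anti <- medians
  hi_anti$anti_error_rate <- tidy(ref)$upper_fence[
    tidy(ref)$parameter == "anti_error_rate"] + 5
  fl1 <- flag_abnormal(hi_anti, ref)
  expect_equal(fl1$executive, "anti_error")
  expect_length(fl1$brainstem, 0)

  # catch-up conjunction: very negative sum AND low gain
  catchup <- medians
  catchup$spem_saccade_sum <- -150
  catchup$spem_gain <- 40
  fl2 <- flag_abnormal(catchup, ref)
  expect_true("catchup_spem" %in% fl2$brainstem)

  # a low-but-positive sum never flags catch-up
  lowpos <- medians
  lowpos$spem_saccade_sum <- max(0, tidy(ref)$lower_fence[
    tidy(ref)$parameter == "spem_saccade_sum"] - 1)
  lowpos$spem_gain <- 40
  fl3 <- flag_abnormal(lowpos, ref)
  expect_false("catchup_spem" %in% fl3$brainstem)

  # missing endpoints never flag
  missing <- medians
  missing$anti_error_rate <- NA_real_
  missing$vgrs_h_pv <- NA_real_
  fl4 <- flag_abnormal(missing, ref)
  expect_length(fl4$executive, 0)
  expect_length(fl4$brainstem, 0)
})

test_that("stage assignment is exhaustive, exclusive and monotone over all flag sets", {
  exec_all <- c("delayed_error", "anti_error", "voluntary_shifts",
                "intrusion_rate", "anticipatory_spem")
  brain_all <- c("pv_horizontal", "pv_up", "pv_down", "catchup_spem")
  subsets <- function(v) {
    purrr::map(0:(2^length(v) - 1), function(m) v[bitwAnd(m, 2^(seq_along(v) - 1)) > 0])
  }
  combos <- tidyr::expand_grid(e = subsets(exec_all), b = subsets(brain_all))
  expect_equal(nrow(combos), 2^9)
  stage_of <- purrr::map_chr(seq_len(nrow(combos)), function(i) {
    assign_stage(list(executive = combos$e[[i]], brainstem = combos$b[[i]]))
  })
  expect_true(all(stage_of %in% c("stage0", "stage1", "stage2",
                                  "nonconforming")))
  # the four canonical cases
  expect_equal(assign_stage(list(executive = character(0),
                                 brainstem = character(0))), "stage0")
  expect_equal(assign_stage(list(executive = "delayed_error",
                                 brainstem = character(0))), "stage1")
  expect_equal(assign_stage(list(executive = "anti_error",
                                 brainstem = "pv_horizontal")), "stage2")
  expect_equal(assign_stage(list(executive = character(0),
                                 brainstem = "catchup_spem")),
               "nonconforming")
  # deterministic mapping from set sizes only
  expect_true(all((stage_of == "stage0") ==
                    (lengths(combos$e) == 0 & lengths(combos$b) == 0)))
  expect_true(all((stage_of == "stage1") ==
                    (lengths(combos$e) > 0 & lengths(combos$b) == 0)))
  expect_true(all((stage_of == "stage2") ==
                    (lengths(combos$e) > 0 & lengths(combos$b) > 0)))
  # monotone: adding any flag never lowers the stage
  rank <- c(stage0 = 0, stage1 = 1, nonconforming = 1, stage2 = 2)
  for (i in sample(seq_len(nrow(combos)), 50)) {
    e <- combos$e[[i]]; b <- combos$b[[i]]
    for (extra in setdiff(exec_all, e)) {
      expect_gte(rank[assign_stage(list(executive = c(e, extra),
                                        brainstem = b))],
                 rank[assign_stage(list(executive = e, brainstem = b))])
    }
    for (extra in setdiff(brain_all, b)) {
      expect_gte(rank[assign_stage(list(executive = e,
                                        brainstem = c(b, extra)))],
                 rank[assign_stage(list(executive = e, brainstem = b))])
    }
  }
})

test_that("staging a profile table adds flags and a stage factor", {
  ref <- make_ref()
  profs <- withr::with_seed(5, tibble::tibble(
    spem_gain = rnorm(6, 90, 4), spem_saccade_sum = rnorm(6, 8, 6),
    vgrs_h_pv = c(rnorm(5, 430, 10), 250),
    vgrs_up_pv = rnorm(6, 430, 10), vgrs_down_pv = rnorm(6, 400, 10),
    intrusion_rate = rnorm(6, 1.2, 0.1),
    delayed_error_rate = c(60, rnorm(5, 8, 2)),
    anti_error_rate = rnorm(6, 18, 3),
    n_voluntary_shifts = rnorm(6, 58, 4)
  ))
  st <- stage_cohort(profs, ref)
  expect_s3_class(st$stage, "factor")
  expect_equal(as.character(st$stage[1]), "stage1")
  expect_true(as.character(st$stage[6]) %in% c("nonconforming", "stage2"))
  expect_equal(st$executive_flags[[1]], "delayed_error")
})

test_that("fences applied back to the simulated control cohort flag few controls", {
  cohort <- staging_cohort()
  controls <- dplyr::filter(cohort, group == "control")
  ref <- compute_reference(controls)
  for (p in staging_parameters()$parameter) {
    f <- tidy(ref)[tidy(ref)$parameter == p, ]
    dirn <- f$abnormal_direction
    frac <- if (dirn == "high") mean(controls[[p]] > f$upper_fence)
    else mean(controls[[p]] < f$lower_fence)
    expect_lte(frac, 0.25)
  }
})
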