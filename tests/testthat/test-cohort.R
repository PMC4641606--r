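test_that("cohort builder is seed-stable and maps severity monotonically", {
  co1 <- build_synthetic_cohort(8, 5, 3, seed = 77, extract = FALSE)
  co2 <- build_synthetic_cohort(8, 5, 3, seed = 77, extract = FALSE)
  expect_identical(dplyr::select(co1, -phenotype),
                   dplyr::select(co2, -phenotype))
  expect_equal(nrow(co1), 16)
  expect_equal(sum(co1$group == "control"), 8)
  expect_true(all(co1$alsfrs_r >= 0 & co1$alsfrs_r <= 48))
  expect_true(all(co1$ecas >= 0 & co1$ecas <= 136))

  # noiseless monotone severity map: perfect rank correlation with the
  # generative error probability
  co <- build_synthetic_cohort(0, 30, 0, seed = 5, extract = FALSE,
                               effect = cohort_effect_config(score_noise_sd = 0))
  p_err <- purrr::map_dbl(co$phenotype, "anti_error_prob")
  expect_equal(unname(cor(co$severity, p_err, method = "spearman")), 1)
  # clinical scores fall with severity
  expect_lt(cor(co$severity, co$alsfrs_r, method = "spearman"), -0.95)
  expect_lt(cor(co$severity, co$ecas, method = "spearman"), -0.95)
})

test_that("group comparison follows the two- and three-group nonparametric scheme", {
  withr::with_seed(3, {
    same <- tibble::tibble(
      group = factor(rep(c("control", "als_spinal"), each = 20),
                     levels = c("control", "als_spinal", "als_bulbar")),
      x = rep(rnorm(20), 2)
    )
  })
  gt <- compare_groups(same, "x")
  expect_equal(gt$p_two_group, 1, tolerance = 0.05)

  withr::with_seed(4, {
    sep <- tibble::tibble(
      group = factor(c(rep("control", 30), rep("als_spinal", 15),
                       rep("als_bulbar", 15)),
                     levels = c("control", "als_spinal", "als_bulbar")),
      x = c(rnorm(30), rnorm(30) + 10)  # shifted by 10 SDs
    )
  })
  gt2 <- compare_groups(sep, "x")
  expect_lt(gt2$p_two_group, 0.001)
  expect_lt(gt2$p_omnibus, 0.001)
  expect_s3_class(gt2$posthoc, "tbl_df")
  expect_equal(nrow(gt2$posthoc), 3)

  # no post hoc tests when the omnibus test is not significant
  withr::with_seed(5, {
    null3 <- tibble::tibble(
      group = factor(rep(c("control", "als_spinal", "als_bulbar"), each = 12),
                     levels = c("control", "als_spinal", "als_bulbar")),
      x = rnorm(36)
    )
  })
  gt3 <- compare_groups(null3, "x")
  if (gt3$p_omnibus >= 0.05) expect_null(gt3$posthoc)

  expect_error(compare_groups(same[1:22, ], "x"), class = "vog_group_error")
})

test_that("clinical correlations use patients only with Holm correction", {
  n <- 40
  co <- tibble::tibble(
    group = factor(rep("als_spinal", n),
                   levels = c("control", "als_spinal", "als_bulbar")),
    anti_error_rate = seq_len(n),
    delayed_error_rate = withr::with_seed(8, rnorm(n)),
    alsfrs_r = 48 - seq_len(n), ecas = rep(100, n)
  )
  res <- correlate_clinical(co, parameters = c("anti_error_rate",
                                               "delayed_error_rate"))
  mono <- dplyr::filter(res, parameter == "anti_error_rate",
                        score == "alsfrs_r")
  expect_equal(mono$rho, -1)
  # constant score yields missing correlation
  const <- dplyr::filter(res, score == "ecas")
  expect_true(all(is.na(const$rho)))
  # Holm: corrected p never below raw p, ranking preserved
  ok <- dplyr::filter(res, !is.na(p_value))
  expect_true(all(ok$p_holm >= ok$p_value))
  expect_equal(order(ok$p_holm), order(ok$p_value))
})

test_that("independent draws show near-zero rank correlation at large n", {
  n <- 1000
  co <- withr::with_seed(11, tibble::tibble(
    group = factor(rep("als_spinal", n),
                   levels = c("control", "als_spinal", "als_bulbar")),
    anti_error_rate = rnorm(n),
    alsfrs_r = rnorm(n), ecas = rnorm(n)
  ))
  res <- correlate_clinical(co, parameters = "anti_error_rate")
  expect_true(all(abs(res$rho) < 0.1))
})

test_that("cohort summaries report median, quartiles and range per group", {
  co <- tibble::tibble(
    group = factor(rep(c("control", "als_spinal"), each = 8),
                   levels = c("control", "als_spinal", "als_bulbar")),
    anti_error_rate = c(1:8, 11:18)
  )
  s <- summarize_cohort(co, "anti_error_rate")
  ctrl <- dplyr::filter(s, group == "control")
  expect_equal(ctrl$median, 4.5)
  expect_equal(ctrl$q1, 2.75)
  expect_equal(ctrl$q3, 6.25)
  expect_equal(ctrl$min, 1)
  expect_equal(ctrl$max, 8)
})

test_that("stats and staging reports serialize deterministically to JSON", {
  co <- tibble::tibble(
    group = factor(c(rep("control", 12), rep("als_spinal", 8),
                     rep("als_bulbar", 6)),
                   levels = c("control", "als_spinal", "als_bulbar")),
    anti_error_rate = withr::with_seed(2, c(rnorm(12, 15, 4),
                                            rnorm(14, 50, 10)))
  )
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_stats_report(co, f1, parameters = "anti_error_rate")
  write_stats_report(co, f2, parameters = "anti_error_rate")
  expect_identical(readLines(f1), readLines(f2))
  expect_true(jsonlite::validate(paste(readLines(f1), collapse = "")))
})
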