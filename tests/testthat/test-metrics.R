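mk_dup <- function(values_by_group) {
  # values_by_group: list of numeric vectors (one per duplicate group)
  n <- sum(lengths(values_by_group))
  ids <- sprintf("D%03d", seq_len(n))
  g <- rep(seq_along(values_by_group), lengths(values_by_group))
  list(
    data = tibble(sample_id = ids, bm = unlist(values_by_group)),
    dup = tibble(group_id = paste0("G", g), sample_id = ids,
                 release = !duplicated(g))
  )
}

test_that("duplicate CV% follows the root-mean-square formula", {
  all_same <- mk_dup(list(c(4, 4), c(7, 7, 7)))
  expect_equal(duplicate_cv(all_same$data, all_same$dup)$cv_pct, 0)

  one_pair <- mk_dup(list(c(3, 5)))
  expect_equal(round(duplicate_cv(one_pair$data, one_pair$dup)$cv_pct, 2),
               35.36) # sd sqrt(2) over mean 4

  two_pairs <- mk_dup(list(c(3, 5), c(4, 4)))
  expect_equal(duplicate_cv(two_pairs$data, two_pairs$dup)$cv_pct,
               100 * sqrt((0.125 + 0) / 2)) # = 25.00
})

test_that("the 4xIQR exclusion and zero offset are applied before CV", {
  # an extreme member lands outside 4 IQR of the duplicate-sample median
  groups <- c(list(c(1000, 3)), replicate(12, c(4, 5), simplify = FALSE))
  fix <- mk_dup(groups)
  res <- duplicate_cv(fix$data, fix$dup)
  expect_equal(res$n_excluded, 1L)
  expect_equal(res$n_groups, 12L) # the outlier's group drops to one member
  expect_equal(res$cv_pct, 100 * sqrt(mean(rep((sd(c(4, 5)) / 4.5)^2, 12))))

  # zeros: the biomarker's half-min-non-zero offset keeps means positive
  zero_pair <- mk_dup(list(c(0, 2), c(2, 2)))
  res0 <- duplicate_cv(zero_pair$data, zero_pair$dup)
  offset <- 1 # half the minimum non-zero (2)
  cv1 <- sd(c(1, 3)) / mean(c(1, 3))
  expect_equal(res0$cv_pct, 100 * sqrt((cv1^2 + 0) / 2))
})

test_that("duplicate R2 regresses the released member on its partner", {
  set.seed(23)
  n <- 2000
  rho <- 0.9
  a <- rnorm(n)
  x <- a * sqrt(rho) + rnorm(n, 0, sqrt(1 - rho))
  y <- a * sqrt(rho) + rnorm(n, 0, sqrt(1 - rho))
  fix <- mk_dup(Map(c, y, x)) # release member first
  res <- duplicate_r2(fix$data, fix$dup)
  # under a bivariate normal with intraclass correlation rho, R2 -> rho^2
  expect_lt(abs(res$r2 - rho^2), 0.03)

  perfect <- mk_dup(list(c(1, 1), c(2, 2), c(5, 5)))
  expect_equal(duplicate_r2(perfect$data, perfect$dup)$r2, 1)

  flat <- mk_dup(list(c(1, 2), c(3, 2), c(5, 2)))
  expect_warning(res_flat <- duplicate_r2(flat$data, flat$dup), "degenerate")
  expect_true(is.na(res_flat$r2))
})

test_that("triplets contribute the release member paired with each other member", {
  fix <- mk_dup(list(c(10, 11, 9), c(1, 1), c(5, 6), c(2, 2)))
  res <- duplicate_r2(fix$data, fix$dup)
  expect_equal(res$n_pairs, 5L) # 2 from the triplet + 3 singleton pairs
})

test_that("variance explained matches closed forms and an ANOVA oracle", {
  set.seed(29)
  n <- 500
  meta <- tibble(
    sample_id = sprintf("S%04d", 1:n),
    plate_id = rep(sprintf("P%02d", 1:25), each = 20),
    well_row = sample(LETTERS[1:8], n, replace = TRUE),
    well_col = sample(1:12, n, replace = TRUE),
    spectrometer_id = sample(c("S1", "S2"), n, replace = TRUE),
    measurement_timestamp = as.POSIXct("2021-01-01", tz = "UTC") +
      rep(1:25, each = 20) * 86400,
    prep_timestamp = as.POSIXct("2021-01-01", tz = "UTC") +
      rep(1:25, each = 20) * 86400 - rlnorm(n, 3, 0.3) * 3600
  )
  hours <- degradation_hours(meta)$degradation_hours
  g3 <- sample(c("A", "B", "C"), n, replace = TRUE)
  dat <- tibble(
    sample_id = meta$sample_id,
    exact_linear = 2 + 3 * hours,            # r2 = 1 on its driver
    noise = rnorm(n),                        # r2 ~ 0
    grouped = rnorm(n, mean = c(A = 0, B = 1, C = 3)[g3], sd = 0.5)
  )
  meta$g3 <- g3
  ve <- variance_explained(
    dat, meta,
    spec = tibble(covariate = c("degradation_time", "g3"),
                  encoding = c("duration_linear", "categorical")))
  expect_equal(ve$r2[ve$biomarker == "exact_linear" &
                       ve$covariate == "degradation_time"], 1)
  expect_lt(ve$r2[ve$biomarker == "noise" & ve$covariate == "g3"], 0.02)

  # between/total sum-of-squares oracle for the categorical covariate
  y <- dat$grouped
  gm <- tapply(y, g3, mean)
  ss_between <- sum((gm[g3] - mean(y))^2)
  ss_total <- sum((y - mean(y))^2)
  expect_equal(ve$r2[ve$biomarker == "grouped" & ve$covariate == "g3"],
               ss_between / ss_total, tolerance = 1e-12)

  # identity with squared Pearson correlation for a linear covariate
  ve_lin <- variance_explained(
    dat["sample_id"] |> mutate(y = dat$grouped), meta,
    spec = tibble(covariate = "degradation_time",
                  encoding = "duration_linear"))
  expect_lt(abs(ve_lin$r2 - cor(hours, dat$grouped)^2), 1e-12)
})

test_that("missing covariate levels form their own non-reference group", {
  set.seed(33)
  n <- 200
  meta <- tibble(sample_id = as.character(1:n),
                 tip = sample(c("t1", "t2", NA), n, replace = TRUE,
                              prob = c(0.6, 0.3, 0.1)))
  dat <- tibble(sample_id = meta$sample_id,
                y = ifelse(is.na(meta$tip), 5, 0) + rnorm(n, 0, 0.1))
  ve <- variance_explained(dat, meta,
                           spec = tibble(covariate = "tip",
                                         encoding = "categorical"))
  # the missing group carries all the signal; r2 is high only if it is
  # modelled as its own group
  expect_gt(ve$r2, 0.9)
})

test_that("QC improves duplicate reproducibility on simulated data", {
  # at this deliberately small size the technical effects are boosted so
  # they dominate coefficient-estimation noise; the full-scale direction
  # check runs in the acceptance suite at generator defaults
  sim <- simulate_nmr_dataset(n_plates = 16, samples_per_plate = 48,
                              n_spectrometers = 2, seed = 77,
                              duplicate_rate = 0.25,
                              spect_offset_sd = 0.2, row_effect_sd = 0.05,
                              drift_amp_sd = 0.05)
  qc <- remove_technical_variation(sim$biomarkers, sim$metadata,
                                   rederive = FALSE)
  pre <- duplicate_cv(sim$biomarkers[c("sample_id", non_derived_names)],
                      sim$duplicates)
  post <- duplicate_cv(qc$postqc, sim$duplicates)
  d <- inner_join(pre, post, by = "biomarker", suffix = c("_pre", "_post"))
  improved <- mean(d$cv_pct_post <= d$cv_pct_pre, na.rm = TRUE)
  expect_gt(improved, 0.9)
})
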