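test_that("the generator is bit-reproducible given a seed", {
  a <- simulate_nmr_dataset(n_plates = 4, samples_per_plate = 10,
                            n_spectrometers = 2, seed = 101)
  b <- simulate_nmr_dataset(n_plates = 4, samples_per_plate = 10,
                            n_spectrometers = 2, seed = 101)
  expect_identical(a$biomarkers, b$biomarkers)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$duplicates, b$duplicates)
  c_ <- simulate_nmr_dataset(n_plates = 4, samples_per_plate = 10,
                             n_spectrometers = 2, seed = 102)
  expect_false(identical(a$biomarkers, c_$biomarkers))
})

test_that("generated data respect the plate layout contract", {
  sim <- small_sim()
  m <- sim$metadata
  expect_true(all(m$well_row %in% LETTERS[1:8]))
  expect_true(all(m$well_col %in% 1:12))
  # control wells are exactly A01 and H12 on every plate
  ctrl <- m[m$is_control_well, ]
  expect_equal(nrow(ctrl), 2 * length(unique(m$plate_id)))
  expect_true(all(paste0(ctrl$well_row, ctrl$well_col) %in% c("A1", "H12")))
  expect_false(anyDuplicated(paste(m$plate_id, m$well_row, m$well_col)) > 0)
  expect_true(all(m$measurement_timestamp > m$prep_timestamp))
  # truth covers every injected effect family
  expect_setequal(
    c("deg_slope", "row_offsets", "col_slope", "spect_offsets",
      "plate_shift", "outlier_plates", "duplicates") ,
    intersect(names(sim$truth),
              c("deg_slope", "row_offsets", "col_slope", "spect_offsets",
                "plate_shift", "outlier_plates", "duplicates")))
})

test_that("zeros are injected by left-censoring and stay non-negative", {
  sim <- simulate_nmr_dataset(n_plates = 8, samples_per_plate = 40,
                              n_spectrometers = 2, seed = 5, zero_rate = 0.05)
  vals <- sim$biomarkers$Acetone
  expect_gt(sum(vals == 0), 0)
  expect_true(all(vals >= 0))
  # censoring removes the left tail: every zero replaced a small value
  expect_gt(min(vals[vals > 0]), 0)
})

test_that("a null generator produces no recoverable structure", {
  sim <- simulate_nmr_dataset(
    n_plates = 20, samples_per_plate = 60, n_spectrometers = 2, seed = 9,
    deg_slope_sd = 0, row_effect_sd = 0, col_slope_sd = 0,
    spect_offset_sd = 0, drift_amp_sd = 0, plate_sd = 0,
    strong_effects = FALSE, outlier_plate_rate = 0, zero_rate = 0)
  study <- sim$metadata[!sim$metadata$is_control_well, ]
  ve <- variance_explained(
    sim$biomarkers[c("sample_id", non_derived_names[c(1, 30, 80)])], study)
  expect_lt(max(ve$r2), 0.02)
  # the pipeline output tracks the input up to coefficient-estimation
  # noise, which shrinks with sample size
  qc <- remove_technical_variation(sim$biomarkers, sim$metadata,
                                   remove_outlier_plates = FALSE,
                                   rederive = FALSE)
  for (bm in c("Ala", "Glucose", "S_HDL_TG")) {
    x <- sim$biomarkers[[bm]][match(qc$postqc$sample_id,
                                    sim$biomarkers$sample_id)]
    rel <- abs(qc$postqc[[bm]] - x) / x
    expect_lt(median(rel), 0.05)
    expect_gt(cor(qc$postqc[[bm]], x), 0.97)
  }
})

test_that("infeasible configurations are rejected", {
  expect_error(simulate_nmr_dataset(n_plates = 2, seed = 1,
                                    duplicate_rate = 1.5), "rates")
  expect_error(simulate_nmr_dataset(n_plates = 2, samples_per_plate = 95,
                                    seed = 1))
  expect_error(simulate_nmr_dataset(n_plates = 2, samples_per_plate = 10),
               "seed")
})

test_that("injected effects are recovered by the pipeline fits", {
  sim <- simulate_nmr_dataset(n_plates = 30, samples_per_plate = 60,
                              n_spectrometers = 2, seed = 42,
                              outlier_plate_rate = 0)
  qc <- remove_technical_variation(sim$biomarkers, sim$metadata,
                                   remove_outlier_plates = FALSE,
                                   rederive = FALSE)
  rec <- truth_recovery_report(qc, sim)
  eff <- rec$effects
  # the strong histidine-like degradation slope is recovered tightly
  his <- eff[eff$biomarker == "His" & eff$effect == "degradation", ]
  expect_lt(abs(his$estimate - his$truth), 3 * his$std.error)
  expect_lt(abs(his$estimate - (-0.12)), 0.02)
  # glycine-like column trend and row dip
  gly_col <- eff[eff$biomarker == "Gly" & eff$effect == "well_col", ]
  expect_true(all(abs(gly_col$estimate - gly_col$truth) <=
                    3.5 * gly_col$std.error))
  # coverage across all biomarkers and effects is near-nominal for a
  # 3 SE band (expected miss rate ~0.3%)
  expect_gt(mean(eff$covered[!isTRUE(eff$outlier_contaminated)]), 0.97)
})

test_that("recovery report refuses a mismatched dataset", {
  sim <- small_sim()
  other <- simulate_nmr_dataset(n_plates = 3, samples_per_plate = 8,
                                n_spectrometers = 2, seed = 1)
  qc <- remove_technical_variation(other$biomarkers, other$metadata,
                                   rederive = FALSE)
  expect_error(truth_recovery_report(qc, sim), "different datasets")
})

test_that("injected outlier plates are detected with high sensitivity", {
  sim <- simulate_nmr_dataset(n_plates = 60, samples_per_plate = 40,
                              n_spectrometers = 2, seed = 13,
                              outlier_plate_rate = 0.02, outlier_shift_sd = 6)
  # detection-level sensitivity on the raw simulated concentrations,
  # where the injected 6 SD shifts are intact
  inj <- sim$truth$outlier_plates
  study <- !sim$metadata$is_control_well
  affected <- unique(inj$biomarker)
  det <- detect_outlier_plates(sim$biomarkers[study, affected],
                               sim$metadata$plate_id[study])
  hits <- inner_join(inj, det$report, by = c("biomarker", "plate_id"))
  expect_gt(nrow(hits) / nrow(inj), 0.9)

  # through the whole pipeline an outlier plate occupies a third of its
  # drift bin at this scale, so the bin fit absorbs part of the shift;
  # sensitivity degrades but detection remains well above chance
  qc <- remove_technical_variation(sim$biomarkers, sim$metadata,
                                   rederive = FALSE)
  rec <- truth_recovery_report(qc, sim)
  cm <- rec$outlier_confusion
  expect_gt(cm$sensitivity, 0.5)
  # false flags stay near the one-per-biomarker design rate
  expect_lt(cm$FP, 2 * 107)
})
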