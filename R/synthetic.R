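#' Simulate a plate-structured NMR biomarker dataset with known truth
#'
#' Generates the 107 non-derived biomarkers for a study laid out like a
#' biobank NMR metabolomics run: 96-well plates carrying up to 94 study
#' samples plus two control wells (A01/H12), plates allocated across
#' spectrometers and measured over calendar time, log-normal sample
#' degradation times, and blind duplicate samples. Technical effects are
#' injected additively on the log scale:
#'
#' * a per-biomarker slope on log degradation hours,
#' * per-biomarker well-row offsets (8-vector, centred),
#' * a per-biomarker linear trend across well columns 1-12,
#' * per-biomarker spectrometer offsets (centred),
#' * smooth within-spectrometer drift across the plate sequence
#'   (sinusoidal in plate index with random amplitude and phase),
#' * independent per-plate intercepts, and
#' * occasional outlier plates whose samples are shifted by a multiple
#'   of the between-plate median SD.
#'
#' Lipoprotein subclass lipids are generated bottom-up from correlated
#' log-normals (shared class and subclass factors) so that every
#' composite biomarker closure holds by construction after
#' [nmr_rederive()]. With `strong_effects = TRUE` three biomarkers mimic
#' the archetypal strong effects seen in real data: histidine-like decay
#' with degradation time (slope -0.12 per log-hour), alanine-like
#' within-spectrometer drift (amplitude 0.15), and a glycine-like
#' column trend (-0.02 per column) with a row-G dip. Duplicate members
#' share the subject-level biological value but occupy their own wells
#' and receive their own technical effects and residuals.
#'
#' @param n_plates Number of plates.
#' @param samples_per_plate Study samples per plate (max 94).
#' @param n_spectrometers Number of spectrometers.
#' @param seed Integer seed; every random choice derives from it.
#' @param start_date First measurement date.
#' @param max_plates_per_day Plates measured per spectrometer-day are
#'   drawn uniformly from 1..this.
#' @param two_day_plate_frac Fraction of plates whose measurement spills
#'   into a second day (a minority of wells, so the plate date is the
#'   first day).
#' @param degradation_meanlog,degradation_sdlog Log-normal parameters of
#'   preparation-to-measurement hours.
#' @param bio_sd Between-subject biological SD on the log scale for
#'   unstructured biomarkers (lipoprotein lipids use shared factors of
#'   comparable total magnitude).
#' @param residual_sd Within-sample technical residual SD (log scale).
#' @param plate_sd SD of per-plate random intercepts (log scale).
#' @param deg_slope_sd SD of per-biomarker degradation slopes.
#' @param row_effect_sd SD of per-biomarker row offsets.
#' @param col_slope_sd SD of per-biomarker per-column linear trends.
#' @param spect_offset_sd SD of per-biomarker spectrometer offsets.
#' @param drift_amp_sd Scale of within-spectrometer drift amplitudes.
#' @param strong_effects Inject the three archetypal strong effects.
#' @param outlier_plate_rate Per-biomarker probability that a given
#'   plate is an outlier plate.
#' @param outlier_shift_sd Outlier plate shift, in SDs of that
#'   biomarker's plate medians.
#' @param zero_rate Left-censoring rate for the ketone biomarkers
#'   (values below this quantile become exact zeros).
#' @param duplicate_rate Fraction of study samples that are blind
#'   duplicate members.
#' @param n_triplets Number of triplet groups among the duplicates.
#' @return A list of class `nmr_simulation`: `biomarkers` (tibble,
#'   `sample_id` + 107 columns, controls included), `metadata`,
#'   `duplicates` (`group_id`, `sample_id`, `release`), and `truth`
#'   (injected coefficients, per-plate shifts, outlier-plate labels,
#'   duplicate linkage, and the configuration).
#' @export
simulate_nmr_dataset <- function(n_plates = 100L,
                                 samples_per_plate = 94L,
                                 n_spectrometers = 6L,
                                 seed,
                                 start_date = as.Date("2021-01-04"),
                                 max_plates_per_day = 3L,
                                 two_day_plate_frac = 0.3,
                                 degradation_meanlog = log(24),
                                 degradation_sdlog = 0.6,
                                 bio_sd = 0.25,
                                 residual_sd = 0.05,
                                 plate_sd = 0.015,
                                 deg_slope_sd = 0.01,
                                 row_effect_sd = 0.015,
                                 col_slope_sd = 0.003,
                                 spect_offset_sd = 0.05,
                                 drift_amp_sd = 0.02,
                                 strong_effects = TRUE,
                                 outlier_plate_rate = 0.01,
                                 outlier_shift_sd = 6,
                                 zero_rate = 0.01,
                                 duplicate_rate = 0.025,
                                 n_triplets = 2L) {
  if (missing(seed)) abort("simulate_nmr_dataset: a seed is required")
  stopifnot(samples_per_plate >= 1, samples_per_plate <= 94,
            n_plates >= 1, n_spectrometers >= 1)
  rates <- c(two_day_plate_frac, outlier_plate_rate, zero_rate, duplicate_rate)
  if (any(rates < 0 | rates > 1)) abort("rates must be in [0, 1]")
  catalog <- nmr_catalog()
  non_derived <- catalog$name[catalog$tier == "non_derived"]
  B <- length(non_derived)
  n_samples <- n_plates * samples_per_plate
  n_controls <- 2L * n_plates

  ## ---- phase A: layout, timestamps, duplicates -------------------------
  set.seed(seed)
  plate_id <- sprintf("P%04d", seq_len(n_plates))
  spectrometer <- sample(rep_len(sprintf("S%d", seq_len(n_spectrometers)),
                                 n_plates))
  plates <- tibble(plate_id = plate_id, spectrometer_id = spectrometer) |>
    group_by(.data$spectrometer_id) |>
    mutate(date = start_date + assign_days(dplyr::n(), max_plates_per_day)) |>
    ungroup()

  study_wells <- expand.grid(well_row = LETTERS[1:8], well_col = 1:12,
                             stringsAsFactors = FALSE) |>
    filter(!(.data$well_row == "A" & .data$well_col == 1),
           !(.data$well_row == "H" & .data$well_col == 12))

  meta_list <- vector("list", n_plates)
  for (p in seq_len(n_plates)) {
    pick <- study_wells[sample.int(94L, samples_per_plate), , drop = FALSE]
    wells <- bind_rows(
      tibble(well_row = pick$well_row, well_col = pick$well_col,
             is_control_well = FALSE),
      tibble(well_row = c("A", "H"), well_col = c(1L, 12L),
             is_control_well = TRUE)
    )
    nw <- nrow(wells)
    meas_order <- sample.int(nw)
    two_day <- stats::runif(1) < two_day_plate_frac && nw >= 5
    day2_n <- if (two_day) sample.int(floor((nw - 1) / 2), 1) else 0L
    day_offset <- rep(0, nw)
    if (day2_n > 0) day_offset[meas_order > (nw - day2_n)] <- 1
    base <- as.POSIXct(paste(plates$date[p], "08:00:00"), tz = "UTC")
    meas <- base + day_offset * 86400 + (meas_order - 1) * 480
    meta_list[[p]] <- tibble(
      plate_id = plates$plate_id[p],
      spectrometer_id = plates$spectrometer_id[p],
      well_row = wells$well_row,
      well_col = wells$well_col,
      is_control_well = wells$is_control_well,
      measurement_timestamp = meas
    )
  }
  meta <- list_rbind(meta_list)
  meta$sample_id <- ifelse(
    meta$is_control_well,
    paste0("CTRL_", meta$plate_id, "_", meta$well_row,
           sprintf("%02d", meta$well_col)),
    sprintf("SMP%06d", cumsum(!meta$is_control_well))
  )
  hours <- rlnorm(nrow(meta), degradation_meanlog, degradation_sdlog)
  meta$prep_timestamp <- meta$measurement_timestamp - hours * 3600
  meta <- meta |>
    select("sample_id", "plate_id", "well_row", "well_col",
           "spectrometer_id", "prep_timestamp", "measurement_timestamp",
           "is_control_well")

  study_ids <- meta$sample_id[!meta$is_control_well]
  n_members <- round(duplicate_rate * n_samples)
  n_triplets <- min(n_triplets, floor(n_members / 3))
  n_pairs <- max(0L, floor((n_members - 3L * n_triplets) / 2))
  need <- 2L * n_pairs + 3L * n_triplets
  if (need > n_samples) {
    abort("simulate_nmr_dataset: more duplicate members than samples")
  }
  dup_groups <- tibble(group_id = character(), sample_id = character(),
                       release = logical())
  subject_of <- set_names(study_ids, study_ids)
  if (need >= 2) {
    members <- sample(study_ids, need)
    sizes <- c(rep(3L, n_triplets), rep(2L, n_pairs))
    gid <- rep(seq_along(sizes), sizes)
    dup_groups <- tibble(
      group_id = sprintf("DUP%04d", gid),
      sample_id = members,
      release = !duplicated(gid)
    )
    first_member <- dup_groups |>
      group_by(.data$group_id) |>
      summarise(first = .data$sample_id[1], .groups = "drop")
    j <- match(dup_groups$group_id, first_member$group_id)
    subject_of[dup_groups$sample_id] <- first_member$first[j]
  }

  ## ---- phase B: injected technical effects -----------------------------
  set.seed(seed + 1L)
  specs <- sort(unique(meta$spectrometer_id))
  S <- length(specs)
  deg_slope <- set_names(rnorm(B, 0, deg_slope_sd), non_derived)
  row_offsets <- matrix(rnorm(B * 8, 0, row_effect_sd), nrow = B,
                        dimnames = list(non_derived, LETTERS[1:8]))
  col_slope <- set_names(rnorm(B, 0, col_slope_sd), non_derived)
  spect_offsets <- matrix(rnorm(B * S, 0, spect_offset_sd), nrow = B,
                          dimnames = list(non_derived, specs))
  drift_amp <- matrix(abs(rnorm(B * S, 0, drift_amp_sd)), nrow = B,
                      dimnames = list(non_derived, specs))
  drift_phase <- matrix(runif(B * S), nrow = B,
                        dimnames = list(non_derived, specs))
  if (strong_effects) {
    deg_slope["His"] <- -0.12
    drift_amp["Ala", ] <- 0.15
    col_slope["Gly"] <- -0.02
    row_offsets["Gly", ] <- c(rep(0.01, 6), -0.07, 0.01)
  }
  row_offsets <- row_offsets - rowMeans(row_offsets)
  spect_offsets <- spect_offsets - rowMeans(spect_offsets)

  plate_int <- matrix(rnorm(B * n_plates, 0, plate_sd), nrow = B,
                      dimnames = list(non_derived, plate_id))
  drift_plate <- matrix(0, nrow = B, ncol = n_plates,
                        dimnames = list(non_derived, plate_id))
  for (sp in specs) {
    in_sp <- plates |> filter(.data$spectrometer_id == sp) |>
      arrange(.data$date, .data$plate_id)
    ns <- nrow(in_sp)
    x <- if (ns > 1) (seq_len(ns) - 1) / (ns - 1) else 0.5
    for (i in seq_len(ns)) {
      drift_plate[, in_sp$plate_id[i]] <-
        drift_amp[, sp] * sin(2 * pi * (x[i] + drift_phase[, sp]))
    }
  }
  plate_shift <- drift_plate + plate_int

  outlier_draw <- matrix(rbinom(B * n_plates, 1, outlier_plate_rate) == 1,
                         nrow = B, dimnames = list(non_derived, plate_id))
  outlier_dir <- matrix(sample(c(-1, 1), B * n_plates, replace = TRUE),
                        nrow = B, dimnames = list(non_derived, plate_id))

  ## ---- phase C: biology -------------------------------------------------
  set.seed(seed + 2L)
  subjects <- unique(c(subject_of, paste0("CTRLSUBJ", 1:8)))
  bio <- subject_biology(subjects, non_derived, bio_sd)
  # control wells: four pairs of control materials, one pair per plate;
  # A01 carries the first member, H12 the second
  pair_of_plate <- ((match(meta$plate_id, plate_id) - 1) %% 4) + 1
  ctrl_subject <- paste0("CTRLSUBJ", 2 * (pair_of_plate - 1) +
                           ifelse(meta$well_row == "A", 1, 2))
  sample_subject <- ifelse(meta$is_control_well, ctrl_subject,
                           subject_of[meta$sample_id])
  log_values <- bio[sample_subject, , drop = FALSE]
  dimnames(log_values) <- list(meta$sample_id, non_derived)

  ## ---- phase D: technical effects, residuals, zeros --------------------
  set.seed(seed + 3L)
  lnh <- log(hours)
  lnh_c <- lnh - mean(lnh[!meta$is_control_well])
  row_idx <- match(meta$well_row, LETTERS[1:8])
  sp_idx <- match(meta$spectrometer_id, specs)
  pl_idx <- match(meta$plate_id, plate_id)
  tech <- outer(lnh_c, deg_slope) +
    t(row_offsets)[row_idx, , drop = FALSE] +
    outer(meta$well_col - 6.5, col_slope) +
    t(spect_offsets)[sp_idx, , drop = FALSE] +
    t(plate_shift)[pl_idx, , drop = FALSE]
  log_values <- log_values + tech +
    matrix(rnorm(length(log_values), 0, residual_sd), nrow = nrow(log_values))

  # outlier plates: shift all study samples on the plate by a multiple of
  # the between-plate median SD of that biomarker
  outlier_tbl <- list()
  study_rows <- which(!meta$is_control_well)
  plate_f <- factor(meta$plate_id[study_rows], levels = plate_id)
  for (b in which(rowSums(outlier_draw) > 0)) {
    med <- tapply(log_values[study_rows, b], plate_f, median)
    sig <- sd(med, na.rm = TRUE)
    hit <- plate_id[outlier_draw[b, ]]
    for (pl in hit) {
      rows <- study_rows[meta$plate_id[study_rows] == pl]
      shift <- outlier_dir[b, pl] * outlier_shift_sd * sig
      log_values[rows, b] <- log_values[rows, b] + shift
      outlier_tbl[[length(outlier_tbl) + 1]] <- tibble(
        biomarker = non_derived[b], plate_id = pl,
        direction = outlier_dir[b, pl], shift_log = shift)
    }
  }
  outlier_tbl <- if (length(outlier_tbl)) list_rbind(outlier_tbl) else
    tibble(biomarker = character(), plate_id = character(),
           direction = double(), shift_log = double())

  conc <- exp(log_values)
  zero_bms <- intersect(c("bOHbutyrate", "Acetoacetate", "Acetone", "Acetate"),
                        non_derived)
  if (zero_rate > 0) {
    for (bm in zero_bms) {
      thr <- quantile(conc[, bm], zero_rate)
      conc[conc[, bm] <= thr, bm] <- 0
    }
  }

  biomarkers <- bind_cols(tibble(sample_id = meta$sample_id),
                          as_tibble(conc))
  truth <- list(
    deg_slope = deg_slope,
    row_offsets = row_offsets,
    col_slope = col_slope,
    spect_offsets = spect_offsets,
    plate_shift = plate_shift,
    drift = drift_plate,
    plate_intercepts = plate_int,
    outlier_plates = outlier_tbl,
    duplicates = dup_groups,
    sample_ids = study_ids,
    mean_log_hours = mean(lnh[!meta$is_control_well]),
    zero_biomarkers = if (zero_rate > 0) zero_bms else character(),
    config = list(n_plates = n_plates, samples_per_plate = samples_per_plate,
                  n_spectrometers = n_spectrometers, seed = seed,
                  bio_sd = bio_sd, residual_sd = residual_sd,
                  plate_sd = plate_sd, outlier_shift_sd = outlier_shift_sd,
                  outlier_plate_rate = outlier_plate_rate)
  )
  structure(list(biomarkers = biomarkers, metadata = meta,
                 duplicates = dup_groups, truth = truth),
            class = "nmr_simulation")
}

# days elapsed for each of n plates when 1..max_per_day plates share a day
assign_days <- function(n, max_per_day) {
  days <- integer(0)
  day <- 0L
  while (length(days) < n) {
    k <- sample.int(max_per_day, 1)
    days <- c(days, rep(day, k))
    day <- day + 1L
  }
  days[seq_len(n)]
}

# Subject-level biology on the log scale. Lipoprotein subclass components
# share class- and subclass-level factors so lipid panels are correlated;
# everything else is an independent log-normal around a plausible
# concentration.
subject_biology <- function(subjects, non_derived, bio_sd) {
  n <- length(subjects)
  mu <- biology_logmeans(non_derived)
  out <- matrix(0, nrow = n, ncol = length(non_derived),
                dimnames = list(subjects, non_derived))
  class_of <- function(sc) {
    if (grepl("VLDL$", sc)) "VLDL" else if (grepl("LDL$", sc)) "LDL" else "HDL"
  }
  subclasses <- c("XXL_VLDL", "XL_VLDL", "L_VLDL", "M_VLDL", "S_VLDL",
                  "XS_VLDL", "IDL", "L_LDL", "M_LDL", "S_LDL",
                  "XL_HDL", "L_HDL", "M_HDL", "S_HDL")
  class_factor <- matrix(rnorm(n * 3, 0, 0.6 * bio_sd), nrow = n,
                         dimnames = list(NULL, c("VLDL", "LDL", "HDL")))
  assigned <- character()
  for (sc in subclasses) {
    sub_factor <- rnorm(n, 0, 0.4 * bio_sd)
    shared <- class_factor[, class_of(sc)] + sub_factor
    for (m in c("P", "PL", "FC", "CE", "TG")) {
      nm <- paste0(sc, "_", m)
      out[, nm] <- mu[nm] + shared + rnorm(n, 0, 0.6 * bio_sd)
      assigned <- c(assigned, nm)
    }
  }
  rest <- setdiff(non_derived, assigned)
  for (nm in rest) {
    sdv <- if (grepl("_size$", nm) || nm == "Unsaturation") 0.1 * bio_sd else bio_sd
    out[, nm] <- mu[nm] + rnorm(n, 0, sdv)
  }
  out
}

biology_logmeans <- function(non_derived) {
  base_L <- c(XXL_VLDL = 0.01, XL_VLDL = 0.03, L_VLDL = 0.1, M_VLDL = 0.3,
              S_VLDL = 0.5, XS_VLDL = 0.5, IDL = 1.0, L_LDL = 1.4,
              M_LDL = 0.9, S_LDL = 0.6, XL_HDL = 0.25, L_HDL = 0.7,
              M_HDL = 1.0, S_HDL = 1.2)
  frac <- list(
    VLDL = c(PL = 0.22, FC = 0.08, CE = 0.18, TG = 0.52),
    LDL  = c(PL = 0.28, FC = 0.12, CE = 0.50, TG = 0.10),
    HDL  = c(PL = 0.45, FC = 0.05, CE = 0.40, TG = 0.10)
  )
  mu <- c(
    VLDL_size = log(36.8), LDL_size = log(23.6), HDL_size = log(9.8),
    Clinical_LDL_C = log(2.2), Phosphoglyc = log(2.0), Cholines = log(2.2),
    Phosphatidylc = log(2.0), Sphingomyelins = log(0.4),
    ApoA1 = log(1.5), ApoB = log(1.0),
    Omega_3 = log(0.5), Omega_6 = log(4.4), MUFA = log(3.3),
    SFA = log(4.5), LA = log(3.5), DHA = log(0.2),
    Unsaturation = log(1.25),
    Ala = log(0.35), Gln = log(0.6), Gly = log(0.25), His = log(0.08),
    Ile = log(0.06), Leu = log(0.09), Val = log(0.2), Phe = log(0.08),
    Tyr = log(0.06),
    Glucose = log(5), Lactate = log(1.5), Pyruvate = log(0.1),
    Citrate = log(0.1),
    bOHbutyrate = log(0.1), Acetate = log(0.05), Acetoacetate = log(0.03),
    Acetone = log(0.02),
    Creatinine = log(0.07), Albumin = log(45), GlycA = log(1.3)
  )
  for (sc in names(base_L)) {
    cls <- if (grepl("VLDL$", sc)) "VLDL" else if (grepl("LDL$", sc)) "LDL"
           else "HDL"
    fr <- frac[[cls]]
    for (m in names(fr)) mu[paste0(sc, "_", m)] <- log(base_L[[sc]] * fr[[m]])
    mu[paste0(sc, "_P")] <- log(base_L[[sc]] / 500)
  }
  missing_mu <- setdiff(non_derived, names(mu))
  if (length(missing_mu)) {
    abort(paste0("no simulated concentration scale for: ",
                 paste(missing_mu, collapse = ", ")))
  }
  mu[non_derived]
}

#' Compare pipeline estimates against simulation ground truth
#'
#' For a QC result produced from a matching simulated dataset, tabulates
#' every fitted adjustment coefficient against the injected effect it
#' estimates: degradation slope against the injected slope, well-row and
#' well-column contrasts against injected offsets and trends relative to
#' the fitted reference level, and drift-bin contrasts against the
#' sample-weighted mean of the injected per-plate shift (smooth drift
#' plus plate intercepts) in each bin. Drift rows whose bin (or
#' reference bin) contains an injected outlier plate are marked
#' `outlier_contaminated`. Also returns the outlier-plate confusion
#' matrix (flagged versus injected, over all biomarker-plate pairs).
#'
#' @param qc An `nmr_qc` result from [remove_technical_variation()].
#' @param truth The `truth` element of [simulate_nmr_dataset()] output
#'   (or the simulation object itself).
#' @return A list with `effects` (tibble: biomarker, effect, term,
#'   estimate, truth, std.error, z, covered) and `outlier_confusion`
#'   (one-row tibble with TP/FP/FN/TN and sensitivity).
#' @export
truth_recovery_report <- function(qc, truth) {
  if (inherits(truth, "nmr_simulation")) truth <- truth$truth
  if (!setequal(qc$sample_ids, truth$sample_ids)) {
    abort("truth_recovery_report: QC result and truth describe different datasets")
  }
  cf <- qc$coefficients
  refs <- qc$references
  eff <- list()

  slope <- cf |> filter(.data$term == "log_hours")
  if (nrow(slope)) {
    eff$deg <- slope |>
      transmute(.data$biomarker, effect = "degradation", term = .data$term,
                estimate = .data$estimate,
                truth = unname(truth$deg_slope[.data$biomarker]),
                std.error = .data$std.error)
  }
  rows <- cf |> filter(startsWith(.data$term, "well_row"))
  if (nrow(rows)) {
    ref_row <- refs$reference[refs$term == "well_row"][1]
    lv <- sub("^well_row", "", rows$term)
    eff$row <- rows |>
      mutate(level = lv) |>
      transmute(.data$biomarker, effect = "well_row", term = .data$term,
                estimate = .data$estimate,
                truth = truth$row_offsets[cbind(.data$biomarker, .data$level)] -
                  truth$row_offsets[cbind(.data$biomarker, ref_row)],
                std.error = .data$std.error)
  }
  cols <- cf |> filter(startsWith(.data$term, "well_col"))
  if (nrow(cols)) {
    ref_col <- as.numeric(refs$reference[refs$term == "well_col"][1])
    lv <- as.numeric(sub("^well_col", "", cols$term))
    eff$col <- cols |>
      mutate(level = lv) |>
      transmute(.data$biomarker, effect = "well_col", term = .data$term,
                estimate = .data$estimate,
                truth = unname(truth$col_slope[.data$biomarker]) *
                  (.data$level - ref_col),
                std.error = .data$std.error)
  }
  drift <- cf |> filter(startsWith(.data$term, "drift_bin"))
  if (nrow(drift)) {
    bm_names <- rownames(truth$plate_shift)
    bin_map <- qc$bin_map
    bin_shift <- bin_map |>
      group_by(.data$spectrometer_id, .data$drift_bin) |>
      summarise(plates = list(.data$plate_id), w = list(.data$n_samples),
                .groups = "drop")
    contaminated_bins <- bin_map |>
      left_join(truth$outlier_plates, by = "plate_id",
                relationship = "many-to-many") |>
      filter(!is.na(.data$biomarker)) |>
      distinct(.data$biomarker, .data$spectrometer_id, .data$drift_bin)
    mean_shift <- function(bm, sp, bin) {
      row <- bin_shift |> filter(.data$spectrometer_id == sp,
                                 .data$drift_bin == bin)
      if (!nrow(row)) return(NA_real_)
      pl <- row$plates[[1]]; w <- row$w[[1]]
      sum(truth$plate_shift[bm, pl] * w) / sum(w)
    }
    ref_bins <- refs |> filter(.data$term == "drift_bin")
    drift_rows <- drift |>
      mutate(bin = as.integer(sub("^drift_bin", "", .data$term)))
    est_truth <- map_dbl(seq_len(nrow(drift_rows)), function(i) {
      bm <- drift_rows$biomarker[i]
      sp <- drift_rows$spectrometer[i]
      ref_bin <- as.integer(ref_bins$reference[ref_bins$spectrometer == sp][1])
      mean_shift(bm, sp, drift_rows$bin[i]) - mean_shift(bm, sp, ref_bin)
    })
    contam <- map_lgl(seq_len(nrow(drift_rows)), function(i) {
      sp <- drift_rows$spectrometer[i]
      ref_bin <- as.integer(ref_bins$reference[ref_bins$spectrometer == sp][1])
      any(contaminated_bins$biomarker == drift_rows$biomarker[i] &
            contaminated_bins$spectrometer_id == sp &
            contaminated_bins$drift_bin %in% c(drift_rows$bin[i], ref_bin))
    })
    eff$drift <- drift_rows |>
      transmute(.data$biomarker, effect = "drift", term = .data$term,
                spectrometer = .data$spectrometer,
                estimate = .data$estimate, truth = est_truth,
                std.error = .data$std.error,
                outlier_contaminated = contam)
  }
  effects <- bind_rows(eff) |>
    mutate(z = (.data$estimate - .data$truth) / .data$std.error,
           covered = abs(.data$estimate - .data$truth) <= 3 * .data$std.error)

  flagged <- if (!is.null(qc$outlier_report)) {
    qc$outlier_report |> distinct(.data$biomarker, .data$plate_id)
  } else tibble(biomarker = character(), plate_id = character())
  injected <- truth$outlier_plates |> distinct(.data$biomarker, .data$plate_id)
  n_bm <- length(unique(qc$offsets$biomarker))
  n_pl <- nrow(qc$bin_map)
  key <- function(d) paste(d$biomarker, d$plate_id)
  tp <- sum(key(flagged) %in% key(injected))
  fp <- nrow(flagged) - tp
  fn <- nrow(injected) - tp
  tn <- n_bm * n_pl - tp - fp - fn
  confusion <- tibble(TP = tp, FP = fp, FN = fn, TN = tn,
                      sensitivity = ifelse(tp + fn > 0, tp / (tp + fn), NA))
  list(effects = effects, outlier_confusion = confusion)
}
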