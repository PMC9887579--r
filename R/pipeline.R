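#' Hours between sample preparation and measurement
#'
#' Sample degradation time: the decimal hours separating sample
#' preparation from spectrometer measurement. Ongoing metabolism in the
#' prepared sample alters some biomarker concentrations during this
#' interval, so it is the first technical covariate removed by the
#' pipeline (on the log scale, since the decay pattern is exponential
#' rather than linear).
#'
#' @param meta A data frame with `sample_id`, `prep_timestamp` and
#'   `measurement_timestamp` (POSIXct or parseable date-time strings).
#' @return A tibble with `sample_id`, `degradation_hours` (`NA` when a
#'   timestamp is missing or the duration is not positive) and `flagged`.
#' @export
degradation_hours <- function(meta) {
  prep <- to_posix(meta$prep_timestamp)
  meas <- to_posix(meta$measurement_timestamp)
  hours <- as.numeric(difftime(meas, prep, units = "hours"))
  bad <- is.na(hours) | hours <= 0
  hours[bad] <- NA_real_
  tibble(sample_id = meta$sample_id, degradation_hours = hours, flagged = bad)
}

to_posix <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  if (is.character(x)) {
    # ISO 8601 (with or without T/Z) and "YYYY-MM-DD HH:MM:SS"
    return(readr::parse_datetime(x))
  }
  as.POSIXct(x, tz = "UTC")
}

#' Assign plates to within-spectrometer drift bins
#'
#' Reproduces the binning used to remove within-spectrometer drift over
#' time: each plate's measurement date is the date on which most of its
#' samples were measured (ties broken by the earliest date); plates
#' within a spectrometer are ordered by (date, plate id) and split into
#' `n_bins` date-contiguous groups of approximately equal sample counts,
#' never splitting plates that share a date across bins. The partition
#' minimises the maximum absolute deviation of group sample counts from
#' n/`n_bins` (found by dynamic programming over date boundaries, which
#' is exactly optimal among contiguous partitions). A spectrometer with
#' fewer distinct dates than `n_bins` gets one bin per date.
#'
#' @param meta Sample-level metadata with `sample_id`, `plate_id`,
#'   `spectrometer_id` and `measurement_timestamp`.
#' @param n_bins Number of drift bins per spectrometer (default 10).
#' @return A tibble with one row per plate: `plate_id`,
#'   `spectrometer_id`, `plate_date`, `drift_bin`, `n_samples`.
#' @export
assign_drift_bins <- function(meta, n_bins = 10L) {
  stopifnot(n_bins >= 1)
  spec_per_plate <- meta |>
    distinct(.data$plate_id, .data$spectrometer_id)
  if (anyDuplicated(spec_per_plate$plate_id)) {
    dup <- spec_per_plate$plate_id[duplicated(spec_per_plate$plate_id)]
    abort(paste0("plate(s) mapped to more than one spectrometer: ",
                 paste(unique(dup), collapse = ", ")))
  }
  dates <- as.Date(to_posix(meta$measurement_timestamp))
  per_plate <- tibble(plate_id = meta$plate_id, date = dates) |>
    count(.data$plate_id, .data$date) |>
    group_by(.data$plate_id) |>
    summarise(
      plate_date = .data$date[order(-.data$n, .data$date)][1],
      n_samples = sum(.data$n),
      .groups = "drop"
    ) |>
    left_join(spec_per_plate, by = "plate_id")

  out <- per_plate |>
    group_by(.data$spectrometer_id) |>
    group_modify(function(d, key) {
      d <- arrange(d, .data$plate_date, .data$plate_id)
      date_counts <- d |>
        group_by(.data$plate_date) |>
        summarise(n = sum(.data$n_samples), .groups = "drop") |>
        arrange(.data$plate_date)
      g <- min(n_bins, nrow(date_counts))
      grp <- balanced_contiguous_partition(date_counts$n, g,
                                           target = sum(date_counts$n) / n_bins)
      bin_of_date <- set_names(grp, as.character(date_counts$plate_date))
      d$drift_bin <- as.integer(bin_of_date[as.character(d$plate_date)])
      d
    }) |>
    ungroup() |>
    select("plate_id", "spectrometer_id", "plate_date", "drift_bin",
           "n_samples")
  out
}

# Optimal contiguous partition of `sizes` into `g` groups minimising the
# maximum |group sum - target|; returns a group index per element.
balanced_contiguous_partition <- function(sizes, g, target = sum(sizes) / g) {
  m <- length(sizes)
  if (g >= m) return(seq_len(m))
  cs <- c(0, cumsum(sizes))
  seg <- function(i, j) abs(cs[j + 1] - cs[i] - target) # cost of block i..j
  # f[j, b]: best (minimal max-deviation) for first j dates in b groups
  f <- matrix(Inf, nrow = m + 1, ncol = g)
  choice <- matrix(NA_integer_, nrow = m + 1, ncol = g)
  for (j in seq_len(m)) f[j + 1, 1] <- seg(1, j)
  for (b in 2:g) {
    for (j in b:m) {
      best <- Inf; arg <- NA_integer_
      for (i in (b - 1):(j - 1)) {
        v <- max(f[i + 1, b - 1], seg(i + 1, j))
        if (v < best) { best <- v; arg <- i }
      }
      f[j + 1, b] <- best
      choice[j + 1, b] <- arg
    }
  }
  bounds <- integer(g)
  j <- m
  for (b in g:2) {
    bounds[b] <- j
    j <- choice[j + 1, b]
  }
  bounds[1] <- j
  grp <- integer(m)
  prev <- 0
  for (b in seq_len(g)) {
    grp[(prev + 1):bounds[b]] <- b
    prev <- bounds[b]
  }
  grp
}

#' Normal-theory outlier limit for plate medians
#'
#' The number of standard deviations beyond which a plate median is
#' flagged as an outlier, chosen so that a sample of `n_plates` draws
#' from a normal distribution is expected to produce about one flag:
#' the standard normal quantile at probability `1 - 1/(2 * n_plates)`.
#' At 1,352 plates this evaluates to 3.3744.
#'
#' @param n_plates Number of plates (`>= 2`).
#' @return The SD multiple (strictly increasing in `n_plates`).
#' @examples
#' round(outlier_plate_limit(1352), 4) # 3.3744
#' @export
outlier_plate_limit <- function(n_plates) {
  if (!is.numeric(n_plates) || any(is.na(n_plates)) || any(n_plates < 2)) {
    abort("outlier_plate_limit: n_plates must be >= 2")
  }
  qnorm(1 - 1 / (2 * n_plates))
}

#' Detect and remove outlier plates
#'
#' For each biomarker, models the distribution of per-plate medians as
#' normal: plates whose median lies strictly more than
#' [outlier_plate_limit()] standard deviations from the mean of plate
#' medians are flagged, and all samples on a flagged plate are set
#' missing for that biomarker only. Surviving values are never altered.
#' A biomarker whose plate medians have zero spread yields no flags.
#'
#' @param data A data frame of biomarker columns (numeric), one row per
#'   sample.
#' @param plate Plate identifier per row of `data`.
#' @param limit_sd Optional fixed SD multiple; by default computed from
#'   the number of plates with a defined median for each biomarker.
#' @return A list with `values` (the data with flagged plates set
#'   missing) and `report` (a tibble with one row per flagged
#'   biomarker-plate pair: plate median, mean and SD of medians, the
#'   limit used, and the number of plates).
#' @export
detect_outlier_plates <- function(data, plate, limit_sd = NULL) {
  plate <- as.character(plate)
  stopifnot(length(plate) == nrow(data))
  biomarkers <- names(data)[vapply(data, is.numeric, logical(1))]
  plate_f <- factor(plate)
  report <- list()
  values <- data
  for (bm in biomarkers) {
    x <- as.numeric(data[[bm]])
    med <- tapply(x, plate_f, median, na.rm = TRUE)
    med <- med[!is.na(med)]
    n_pl <- length(med)
    if (n_pl < 2) {
      abort(paste0("detect_outlier_plates: fewer than 2 plates with a ",
                   "defined median for ", bm))
    }
    mu <- mean(med)
    sigma <- sd(med)
    if (sigma == 0) next # no spread: nothing can be called an outlier
    lim <- limit_sd %||% outlier_plate_limit(n_pl)
    flagged <- names(med)[abs(med - mu) > lim * sigma]
    if (length(flagged)) {
      values[[bm]][plate %in% flagged] <- NA_real_
      report[[bm]] <- tibble(
        biomarker = bm, plate_id = flagged,
        plate_median = as.numeric(med[flagged]),
        mean_medians = mu, sd_medians = sigma,
        limit = lim, n_plates = n_pl
      )
    }
  }
  report <- if (length(report)) list_rbind(unname(report)) else
    tibble(biomarker = character(), plate_id = character(),
           plate_median = double(), mean_medians = double(),
           sd_medians = double(), limit = double(), n_plates = integer())
  list(values = values, report = report)
}

#' Return adjustment residuals to absolute concentrations
#'
#' Residuals from the technical-covariate regressions are centred on
#' zero; adding back the robust mean of the original log-scale values
#' restores their location, exponentiation inverts the log transform,
#' and the forward offset (applied to biomarkers with zeros) is
#' removed. If removing the offset leaves any negative concentrations
#' (possible only for biomarkers that contained zeros), a small offset
#' is added to the whole column and recorded: the smallest power of ten
#' at least as large as the most negative value, or — when that rounding
#' would not stay an order of magnitude below the smallest non-zero
#' original concentration — the most negative value rounded up to the
#' fewest significant digits that do. If even the unrounded magnitude
#' reaches a tenth of the smallest non-zero concentration the fit is
#' considered pathological and an error is raised.
#'
#' @param residuals Residuals on the log scale (`NA` allowed).
#' @param log_original The log-transformed original values the
#'   regressions started from.
#' @param offset Forward offset recorded by [log_offset_transform()].
#' @return A list with `values` (absolute concentrations),
#'   `postqc_offset` and `location` (the robust mean added back).
#' @export
rescale_residuals <- function(residuals, log_original, offset = 0) {
  m <- robust_mean(log_original, tol = 1e-11)
  out <- exp(residuals + m) - offset
  postqc_offset <- 0
  if (any(out < 0, na.rm = TRUE)) {
    worst <- max(-out, na.rm = TRUE)
    original <- exp(log_original) - offset
    # round-trip dust: exact zeros reconstruct as ~1e-16 * offset
    if (offset > 0) original[abs(original) < offset * 1e-9] <- 0
    min_nonzero <- min(original[!is.na(original) & original > 0])
    bound <- 0.1 * min_nonzero
    if (worst >= bound) {
      abort(paste0("rescale_residuals: negative post-QC value ", -worst,
                   " cannot be offset an order of magnitude below the ",
                   "smallest non-zero original concentration ", min_nonzero,
                   " (pathological fit)"))
    }
    postqc_offset <- ceil_signif(worst, bound)
    out <- out + postqc_offset
  }
  list(values = out, postqc_offset = postqc_offset, location = m)
}

# smallest "round" number >= worst that stays strictly below `bound`:
# a power of ten where possible, else the fewest significant digits
ceil_signif <- function(worst, bound) {
  e <- floor(log10(worst))
  for (digits in 0:15) {
    unit <- 10^(e - digits + 1)
    cand <- ceiling(worst / unit) * unit
    if (cand < bound) return(cand)
  }
  worst * (1 + 1e-12)
}

well_row_levels <- LETTERS[1:8]

check_meta <- function(meta) {
  required <- c("sample_id", "plate_id", "well_row", "well_col",
                "spectrometer_id", "prep_timestamp", "measurement_timestamp")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    abort(paste0("metadata is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad_row <- !is.na(meta$well_row) & !(meta$well_row %in% well_row_levels)
  if (any(bad_row)) {
    abort(paste0("unknown well row label(s): ",
                 paste(unique(meta$well_row[bad_row]), collapse = ", ")))
  }
  wc <- suppressWarnings(as.integer(meta$well_col))
  bad_col <- !is.na(meta$well_col) & (is.na(wc) | wc < 1 | wc > 12)
  if (any(bad_col)) {
    abort(paste0("well column labels outside 1-12: ",
                 paste(unique(meta$well_col[bad_col]), collapse = ", ")))
  }
  key <- paste(meta$plate_id, meta$well_row, wc)
  if (anyDuplicated(key)) {
    abort("duplicated (plate, well row, well column) positions in metadata")
  }
  invisible(meta)
}

#' Remove technical variation from non-derived biomarker concentrations
#'
#' The full quality-control pipeline. Each of the 107 non-derived
#' biomarkers is log transformed (with a half-minimum-non-zero offset
#' for biomarkers containing zeros) and adjusted for technical
#' covariates by Huber robust regression, in one of three equivalent
#' arrangements:
#'
#' * `multi_step` (the default): four sequential regressions — (1) on
#'   log degradation hours, (2) residuals on well row (A-H,
#'   categorical), (3) residuals on well column (1-12, categorical),
#'   (4) residuals on within-spectrometer measurement-date bin
#'   (categorical, fit separately per spectrometer).
#' * `two_step`: one joint regression on log degradation hours, row and
#'   column, followed by the per-spectrometer drift-bin regression.
#' * `one_step`: a single joint regression on all four terms, fit
#'   separately within each spectrometer.
#'
#' Residuals are returned to absolute concentrations by adding back the
#' robust mean of the original log values and inverting the transform
#' ([rescale_residuals()]); outlier plates are then detected and removed
#' per biomarker ([detect_outlier_plates()]); finally all composite
#' biomarkers and ratios are re-derived from the adjusted non-derived
#' values ([nmr_rederive()]).
#'
#' Control wells (A01/H12) are dropped before fitting and never
#' influence the adjustment. Samples with a missing or non-positive
#' degradation time are excluded from the first regression and receive
#' no degradation adjustment (covariates are centred, so their fitted
#' value falls back to the intercept); they are flagged in the log.
#'
#' @param data Data frame with `sample_id` and at least the 107
#'   non-derived biomarker columns. Derived columns, if present, are
#'   ignored and recomputed.
#' @param meta Sample technical metadata: `sample_id`, `plate_id`,
#'   `well_row` (A-H), `well_col` (1-12), `spectrometer_id`,
#'   `prep_timestamp`, `measurement_timestamp`, optionally
#'   `is_control_well`.
#' @param variant One of `"multi_step"`, `"two_step"`, `"one_step"`.
#' @param remove_outlier_plates Set `FALSE` to skip outlier-plate
#'   removal.
#' @param rederive Set `FALSE` to return only the 107 adjusted
#'   non-derived biomarkers.
#' @param catalog An [nmr_catalog()]; defaults to the shipped one.
#' @param n_bins Drift bins per spectrometer (default 10).
#' @param k,tol,max_iter Passed to the robust fitter. The default
#'   tolerance here is tighter than [robust_fit()]'s so that the
#'   sequential centring steps compose to the identity on structure-free
#'   data.
#' @return An object of class `nmr_qc`: a list with `postqc` (tibble of
#'   adjusted absolute concentrations), `offsets` (per-biomarker offset
#'   ledger and restored location), `coefficients` (every fitted term of
#'   every step), `bin_map`, `outlier_report`, `samples_set_missing`,
#'   `plate_medians` (per plate, before and after adjustment),
#'   `variant`, and a message `log`. Methods: [tidy()], [glance()],
#'   [autoplot.nmr_qc()], `print()`.
#' @export
remove_technical_variation <- function(data, meta,
                                       variant = c("multi_step", "two_step",
                                                   "one_step"),
                                       remove_outlier_plates = TRUE,
                                       rederive = TRUE,
                                       catalog = NULL,
                                       n_bins = 10L,
                                       k = 1.345, tol = 1e-11,
                                       max_iter = 200L) {
  variant <- match.arg(variant)
  catalog <- catalog %||% nmr_catalog()
  check_meta(meta)
  log_msgs <- character()

  non_derived <- catalog$name[catalog$tier == "non_derived"]
  missing_nd <- setdiff(non_derived, names(data))
  if (length(missing_nd)) {
    abort(paste0("input is missing non-derived biomarker column(s): ",
                 paste(missing_nd, collapse = ", ")))
  }
  if (!"sample_id" %in% names(data)) {
    abort("input data must have a sample_id column")
  }

  meta <- as_tibble(meta)
  if ("is_control_well" %in% names(meta)) {
    controls <- meta$sample_id[as.logical(meta$is_control_well) %in% TRUE]
  } else {
    controls <- meta$sample_id[meta$well_row == "A" & as.integer(meta$well_col) == 1 |
                               meta$well_row == "H" & as.integer(meta$well_col) == 12]
  }
  if (length(controls)) {
    log_msgs <- qc_log(log_msgs, paste0("excluded ", sum(data$sample_id %in% controls),
                                        " control-well samples from the input"))
    data <- data[!data$sample_id %in% controls, , drop = FALSE]
    meta <- meta[!meta$sample_id %in% controls, , drop = FALSE]
  }
  no_meta <- setdiff(data$sample_id, meta$sample_id)
  if (length(no_meta)) {
    abort(paste0("metadata does not cover sample(s): ",
                 paste(head(no_meta, 5), collapse = ", "),
                 if (length(no_meta) > 5) ", ..."))
  }
  meta <- meta[match(data$sample_id, meta$sample_id), , drop = FALSE]

  deg <- degradation_hours(meta)
  if (any(deg$flagged)) {
    log_msgs <- qc_log(log_msgs, paste0(
      sum(deg$flagged), " sample(s) with missing or non-positive degradation ",
      "time: excluded from the degradation fit, no degradation adjustment"))
  }
  bin_map <- assign_drift_bins(meta, n_bins = n_bins)
  plate_bins <- bin_map[match(meta$plate_id, bin_map$plate_id), , drop = FALSE]

  covars <- tibble(
    log_hours = log(deg$degradation_hours),
    well_row = as.character(meta$well_row),
    well_col = as.character(as.integer(meta$well_col)),
    spectrometer = as.character(meta$spectrometer_id),
    drift_bin = as.character(plate_bins$drift_bin)
  )

  n <- nrow(data)
  spec_split <- split(seq_len(n), covars$spectrometer)

  # Pre-build every design once; each biomarker reuses them.
  d_deg <- build_design(covars["log_hours"])
  d_row <- build_design(covars["well_row"])
  d_col <- build_design(covars["well_col"])
  d_joint <- build_design(covars[c("log_hours", "well_row", "well_col")])
  d_bins <- lapply(spec_split, function(idx) {
    build_design(covars[idx, "drift_bin", drop = FALSE])
  })
  d_one <- lapply(spec_split, function(idx) {
    build_design(covars[idx, c("log_hours", "well_row", "well_col",
                               "drift_bin"), drop = FALSE])
  })
  ref_rows <- list()
  add_ref <- function(design, terms, spectrometer = NA_character_) {
    for (tm in intersect(terms, names(design$reference_levels))) {
      ref_rows[[length(ref_rows) + 1]] <<- tibble(
        term = tm, spectrometer = spectrometer,
        reference = unname(design$reference_levels[tm]))
    }
  }
  if (variant == "multi_step") {
    add_ref(d_row, "well_row"); add_ref(d_col, "well_col")
    for (sp in names(d_bins)) add_ref(d_bins[[sp]], "drift_bin", sp)
  } else if (variant == "two_step") {
    add_ref(d_joint, c("well_row", "well_col"))
    for (sp in names(d_bins)) add_ref(d_bins[[sp]], "drift_bin", sp)
  } else {
    for (sp in names(d_one)) {
      add_ref(d_one[[sp]], c("well_row", "well_col", "drift_bin"), sp)
    }
  }
  references <- if (length(ref_rows)) list_rbind(ref_rows) else
    tibble(term = character(), spectrometer = character(),
           reference = character())

  dropped <- unique(c(d_deg$dropped, d_row$dropped, d_col$dropped,
                      unlist(lapply(d_bins, `[[`, "dropped"))))
  if (length(dropped)) {
    log_msgs <- qc_log(log_msgs, paste0("degenerate covariate(s) dropped ",
      "from one or more fits: ", paste(dropped, collapse = ", ")))
  }

  run_fit <- function(design, y, rows = NULL, step, spectrometer = NA) {
    # rows: index into full data this design covers (NULL = all)
    idx <- rows %||% seq_len(n)
    yy <- y[idx]
    fit_rows <- !is.na(yy) & design$complete
    if (sum(fit_rows) < 2) {
      abort(paste0("step '", step, "': fewer than 2 usable observations"))
    }
    fit <- huber_irls(design$X[fit_rows, , drop = FALSE], yy[fit_rows],
                      k = k, tol = tol, max_iter = max_iter)
    se <- huber_se(design$X[fit_rows, , drop = FALSE], fit, k = k)
    resid <- yy - drop(design$X %*% fit$coefficients)
    list(residuals = resid, idx = idx,
         coefs = tibble(step = step, spectrometer = as.character(spectrometer),
                        term = names(fit$coefficients),
                        estimate = unname(fit$coefficients),
                        std.error = unname(se),
                        n = sum(fit_rows), converged = fit$converged,
                        iterations = fit$iterations))
  }

  postqc107 <- matrix(NA_real_, nrow = n, ncol = length(non_derived),
                      dimnames = list(NULL, non_derived))
  offsets <- vector("list", length(non_derived))
  coefs <- list()
  skipped <- character()

  for (bi in seq_along(non_derived)) {
    bm <- non_derived[bi]
    x <- as.numeric(data[[bm]])
    if (all(is.na(x)) || all(is.na(x) | x == 0)) {
      skipped <- c(skipped, bm)
      next
    }
    lt <- log_offset_transform(x)
    y <- lt$values
    bm_coefs <- list()
    if (variant == "multi_step") {
      s1 <- run_fit(d_deg, y, step = "degradation")
      r <- s1$residuals
      s2 <- run_fit(d_row, r, step = "well_row")
      r <- s2$residuals
      s3 <- run_fit(d_col, r, step = "well_col")
      r <- s3$residuals
      r4 <- r
      s4c <- list()
      for (sp in names(spec_split)) {
        idx <- spec_split[[sp]]
        s4 <- run_fit(d_bins[[sp]], r, rows = idx, step = "drift",
                      spectrometer = sp)
        r4[idx] <- s4$residuals
        s4c[[sp]] <- s4$coefs
      }
      r <- r4
      bm_coefs <- c(list(s1$coefs, s2$coefs, s3$coefs), s4c)
    } else if (variant == "two_step") {
      s1 <- run_fit(d_joint, y, step = "degradation+row+col")
      r <- s1$residuals
      r4 <- r
      s4c <- list()
      for (sp in names(spec_split)) {
        idx <- spec_split[[sp]]
        s4 <- run_fit(d_bins[[sp]], r, rows = idx, step = "drift",
                      spectrometer = sp)
        r4[idx] <- s4$residuals
        s4c[[sp]] <- s4$coefs
      }
      r <- r4
      bm_coefs <- c(list(s1$coefs), s4c)
    } else { # one_step
      r <- rep(NA_real_, n)
      for (sp in names(spec_split)) {
        idx <- spec_split[[sp]]
        s1 <- run_fit(d_one[[sp]], y, rows = idx, step = "joint",
                      spectrometer = sp)
        r[idx] <- s1$residuals
        bm_coefs[[sp]] <- s1$coefs
      }
    }
    rs <- rescale_residuals(r, y, lt$offset)
    postqc107[, bi] <- rs$values
    offsets[[bi]] <- tibble(biomarker = bm, forward_offset = lt$offset,
                            postqc_offset = rs$postqc_offset,
                            log_location = rs$location)
    coefs[[bm]] <- bind_rows(bm_coefs) |> mutate(biomarker = bm, .before = 1)
  }
  if (length(skipped)) {
    log_msgs <- qc_log(log_msgs, paste0("biomarker(s) with no usable values ",
      "skipped (left missing): ", paste(skipped, collapse = ", ")))
  }

  plate_med_pre <- plate_medians_of(data[non_derived], meta$plate_id)
  pq <- as_tibble(postqc107)

  outlier_report <- NULL
  samples_missing <- tibble(biomarker = character(), n_flagged_plates = integer(),
                            n_samples_set_missing = integer())
  if (remove_outlier_plates) {
    det <- detect_outlier_plates(pq, meta$plate_id)
    n_before <- vapply(pq, function(v) sum(is.na(v)), integer(1))
    pq <- det$values
    n_after <- vapply(pq, function(v) sum(is.na(v)), integer(1))
    outlier_report <- det$report
    if (nrow(det$report)) {
      samples_missing <- det$report |>
        count(.data$biomarker, name = "n_flagged_plates") |>
        left_join(tibble(biomarker = names(n_after),
                         n_samples_set_missing = unname(n_after - n_before)),
                  by = "biomarker")
    }
  }
  plate_med_post <- plate_medians_of(pq, meta$plate_id)

  postqc <- bind_cols(tibble(sample_id = data$sample_id), pq)
  if (rederive) postqc <- nmr_rederive(postqc, catalog)

  structure(list(
    postqc = postqc,
    offsets = list_rbind(offsets[!vapply(offsets, is.null, logical(1))]),
    coefficients = list_rbind(unname(coefs)),
    bin_map = bin_map,
    references = references,
    outlier_report = outlier_report,
    samples_set_missing = samples_missing,
    plate_medians = left_join(
      rename(plate_med_pre, median_original = "plate_median"),
      rename(plate_med_post, median_postqc = "plate_median"),
      by = c("biomarker", "plate_id")) |>
      left_join(bin_map, by = "plate_id"),
    variant = variant,
    sample_ids = data$sample_id,
    log = log_msgs
  ), class = "nmr_qc")
}

plate_medians_of <- function(df, plate) {
  plate_f <- factor(plate)
  out <- lapply(names(df), function(bm) {
    med <- tapply(as.numeric(df[[bm]]), plate_f, median, na.rm = TRUE)
    tibble(biomarker = bm, plate_id = names(med), plate_median = as.numeric(med))
  })
  list_rbind(out)
}

#' @export
print.nmr_qc <- function(x, ...) {
  cat("NMR plate QC result (variant: ", x$variant, ")\n", sep = "")
  cat("  samples:    ", nrow(x$postqc), "\n", sep = "")
  cat("  biomarkers: ", ncol(x$postqc) - 1, "\n", sep = "")
  cat("  plates:     ", nrow(x$bin_map), " on ",
      length(unique(x$bin_map$spectrometer_id)), " spectrometer(s)\n", sep = "")
  if (!is.null(x$outlier_report)) {
    cat("  outlier plate flags: ", nrow(x$outlier_report), " (",
        length(unique(x$outlier_report$biomarker)), " biomarker(s))\n", sep = "")
  }
  for (m in x$log) cat("  - ", m, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.nmr_qc <- function(x, ...) x$coefficients

#' @export
glance.nmr_qc <- function(x, ...) {
  tibble(
    variant = x$variant,
    n_samples = nrow(x$postqc),
    n_biomarkers = ncol(x$postqc) - 1L,
    n_plates = nrow(x$bin_map),
    n_spectrometers = length(unique(x$bin_map$spectrometer_id)),
    n_outlier_flags = if (is.null(x$outlier_report)) NA_integer_ else
      nrow(x$outlier_report)
  )
}

#' Adjust for biological covariates and re-derive
#'
#' Direct adjustment of a composite biomarker or ratio gives different
#' values than recomputing it from its adjusted parts, because
#' covariates have different effect sizes on the components. This
#' function therefore always filters to the 107 non-derived biomarkers,
#' adjusts them (log scale, Huber robust regression on the supplied
#' model terms, residuals rescaled to absolute concentrations), and
#' re-derives all 218 derived biomarkers from the adjusted values.
#' Requesting direct adjustment of a derived biomarker is refused.
#'
#' @param data Post-QC (or original) concentrations with `sample_id`
#'   and at least the 107 non-derived biomarker columns.
#' @param covariates Data frame aligned to `data` by `sample_id`,
#'   holding the model terms (e.g. age, sex, log BMI).
#' @param formula Right-hand-side formula naming columns of
#'   `covariates`, e.g. `~ age + sex + log_bmi`.
#' @param biomarkers Optional subset of non-derived biomarkers to
#'   adjust (the rest are carried through unadjusted). Naming a derived
#'   biomarker is an error: adjust its parts and re-derive instead.
#' @param catalog An [nmr_catalog()].
#' @param k,tol,max_iter Passed to the robust fitter.
#' @return A tibble like `data` with all 325 biomarker columns
#'   re-derived from the adjusted non-derived values.
#' @export
adjust_and_rederive <- function(data, covariates, formula,
                                biomarkers = NULL, catalog = NULL,
                                k = 1.345, tol = 1e-11, max_iter = 200L) {
  catalog <- catalog %||% nmr_catalog()
  non_derived <- catalog$name[catalog$tier == "non_derived"]
  if (!is.null(biomarkers)) {
    derived_req <- intersect(biomarkers,
                             catalog$name[catalog$tier != "non_derived"])
    if (length(derived_req)) {
      abort(paste0(
        "refusing to directly adjust derived biomarker(s): ",
        paste(derived_req, collapse = ", "),
        ". Covariates can affect the components of a composite or ratio ",
        "differently; adjust the non-derived components and re-derive ",
        "(this function does that automatically when `biomarkers` names ",
        "only non-derived biomarkers)."))
    }
  }
  targets <- biomarkers %||% non_derived
  missing_nd <- setdiff(non_derived, names(data))
  if (length(missing_nd)) {
    abort(paste0("input is missing non-derived biomarker column(s): ",
                 paste(missing_nd, collapse = ", ")))
  }
  if (!"sample_id" %in% names(data)) abort("data must have a sample_id column")
  if ("sample_id" %in% names(covariates)) {
    covariates <- covariates[match(data$sample_id, covariates$sample_id), ,
                             drop = FALSE]
  } else if (nrow(covariates) != nrow(data)) {
    abort("covariates must align with data (same rows or a sample_id key)")
  }
  terms <- all.vars(formula)
  design <- build_design(as.data.frame(covariates)[terms])
  adjusted <- data
  for (bm in targets) {
    x <- as.numeric(data[[bm]])
    if (all(is.na(x) | x == 0)) next
    lt <- log_offset_transform(x)
    y <- lt$values
    fit_rows <- !is.na(y) & design$complete
    fit <- huber_irls(design$X[fit_rows, , drop = FALSE], y[fit_rows],
                      k = k, tol = tol, max_iter = max_iter)
    r <- y - drop(design$X %*% fit$coefficients)
    adjusted[[bm]] <- rescale_residuals(r, y, lt$offset)$values
  }
  nmr_rederive(adjusted, catalog)
}

#' Directly adjust biomarker columns (for comparison only)
#'
#' Adjusts the named biomarker columns for covariates without
#' re-deriving anything: percentages are logit transformed, everything
#' else log transformed, a Huber robust regression is fit on the model
#' terms, and residuals are rescaled back. Directly adjusting composite
#' biomarkers or ratios is exactly the practice the QC pipeline warns
#' against — after direct adjustment a composite no longer equals the
#' sum of its adjusted parts. This function exists to demonstrate that
#' discrepancy; use [adjust_and_rederive()] for real adjustment.
#'
#' @inheritParams adjust_and_rederive
#' @param biomarkers Columns to adjust (any tier).
#' @return `data` with the named columns replaced by their directly
#'   adjusted values.
#' @export
adjust_direct <- function(data, covariates, formula, biomarkers,
                          catalog = NULL, k = 1.345, tol = 1e-11,
                          max_iter = 200L) {
  catalog <- catalog %||% nmr_catalog()
  units <- set_names(catalog$units, catalog$name)
  if ("sample_id" %in% names(covariates)) {
    covariates <- covariates[match(data$sample_id, covariates$sample_id), ,
                             drop = FALSE]
  }
  terms <- all.vars(formula)
  design <- build_design(as.data.frame(covariates)[terms])
  out <- data
  for (bm in biomarkers) {
    x <- as.numeric(data[[bm]])
    is_pct <- !is.na(units[bm]) && units[bm] == "%"
    if (is_pct) {
      lt <- logit_offset_transform(x)
    } else {
      lt <- log_offset_transform(x)
    }
    y <- lt$values
    fit_rows <- !is.na(y) & design$complete
    fit <- huber_irls(design$X[fit_rows, , drop = FALSE], y[fit_rows],
                      k = k, tol = tol, max_iter = max_iter)
    r <- y - drop(design$X %*% fit$coefficients)
    m <- robust_mean(y, tol = 1e-11)
    if (is_pct) {
      out[[bm]] <- inverse_logit_offset(r + m, lt$lower_offset,
                                        lt$upper_offset)
    } else {
      out[[bm]] <- rescale_residuals(r, y, lt$offset)$values
    }
  }
  out
}
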