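#' Variance explained by technical covariates
#'
#' For each biomarker and covariate separately, fits ordinary least
#' squares and reports the model r-squared. Encodings follow the
#' diagnostic conventions of the pipeline:
#'
#' * `categorical` — one group per level, largest level as reference;
#'   missing values form their own (non-reference) group.
#' * `duration_linear` — a duration in decimal hours, linear effect.
#' * `event_time_binned` — a date-time covariate split into 10 bins of
#'   equal duration, treated categorically (non-linear drift over time).
#' * `plate_binned` — plates encoded as spectrometer x date-bin groups
#'   via [assign_drift_bins()] (fitting plate itself as a categorical
#'   with over a thousand levels is impractical).
#'
#' @param data Data frame with `sample_id` and biomarker columns.
#' @param meta Sample technical metadata (see
#'   [remove_technical_variation()]).
#' @param spec A tibble with columns `covariate` and `encoding` choosing
#'   what to test. `covariate` is a column of `meta`, or one of the
#'   specials `"plate"` (plate_binned), `"degradation_time"`
#'   (duration_linear on prep-to-measurement hours). The default tests
#'   degradation time, well row, well column, spectrometer, measurement
#'   date and plate.
#' @param n_bins Bins for `event_time_binned` and `plate_binned`.
#' @return A tibble: `biomarker`, `covariate`, `encoding`, `r2`,
#'   `n_used`.
#' @export
variance_explained <- function(data, meta, spec = NULL, n_bins = 10L) {
  spec <- spec %||% tibble(
    covariate = c("degradation_time", "well_row", "well_col",
                  "spectrometer_id", "measurement_timestamp", "plate"),
    encoding = c("duration_linear", "categorical", "categorical",
                 "categorical", "event_time_binned", "plate_binned")
  )
  if (!"sample_id" %in% names(data)) abort("data must have a sample_id column")
  meta <- as_tibble(meta)[match(data$sample_id, meta$sample_id), , drop = FALSE]
  biomarkers <- setdiff(names(data), "sample_id")
  out <- list()
  for (i in seq_len(nrow(spec))) {
    cv <- spec$covariate[i]
    enc <- spec$encoding[i]
    x <- covariate_vector(cv, enc, meta, n_bins)
    for (bm in biomarkers) {
      y <- as.numeric(data[[bm]])
      out[[length(out) + 1]] <- tibble(
        biomarker = bm, covariate = cv, encoding = enc,
        r2 = ols_r2(x, y, enc), n_used = sum(!is.na(y) & !is_na_cov(x, enc))
      )
    }
  }
  list_rbind(out)
}

is_na_cov <- function(x, enc) {
  if (enc %in% c("categorical", "event_time_binned", "plate_binned")) {
    rep(FALSE, length(x)) # missing levels form their own group
  } else {
    is.na(x)
  }
}

covariate_vector <- function(cv, enc, meta, n_bins) {
  if (cv == "degradation_time") {
    return(degradation_hours(meta)$degradation_hours)
  }
  if (cv == "plate") {
    bins <- assign_drift_bins(meta, n_bins = n_bins)
    j <- match(meta$plate_id, bins$plate_id)
    return(paste0(bins$spectrometer_id[j], ":", bins$drift_bin[j]))
  }
  if (!cv %in% names(meta)) {
    abort(paste0("variance_explained: covariate '", cv, "' not in metadata"))
  }
  v <- meta[[cv]]
  if (enc == "event_time_binned") {
    tt <- as.numeric(to_posix(v))
    br <- seq(min(tt, na.rm = TRUE), max(tt, na.rm = TRUE), length.out = n_bins + 1)
    return(as.character(cut(tt, breaks = br, include.lowest = TRUE,
                            labels = FALSE)))
  }
  if (enc == "duration_linear") return(as.numeric(v))
  as.character(v)
}

# r2 of y ~ x under the requested encoding, via least squares
ols_r2 <- function(x, y, enc) {
  if (enc %in% c("categorical", "event_time_binned", "plate_binned")) {
    f <- as.character(x)
    f[is.na(f)] <- "(missing)"
    ok <- !is.na(y)
    f <- factor(f[ok])
    y <- y[ok]
    if (nlevels(f) < 2) {
      warn("covariate with a single level: r2 = 0")
      return(0)
    }
    gm <- tapply(y, f, mean)
    fitted <- gm[as.integer(f)]
    rss <- sum((y - fitted)^2)
  } else {
    ok <- !is.na(y) & !is.na(x)
    x <- x[ok]; y <- y[ok]
    if (length(unique(x)) < 2) {
      warn("covariate with no variation: r2 = 0")
      return(0)
    }
    X <- cbind(1, x)
    fit <- stats::.lm.fit(X, y)
    rss <- sum(fit$residuals^2)
  }
  tss <- sum((y - mean(y))^2)
  if (tss == 0) return(0)
  max(0, min(1, 1 - rss / tss))
}

#' Blind-duplicate coefficient of variation
#'
#' Within-sample CV% across blind duplicate groups, computed with the
#' root-mean-square approach: per group i with at least two surviving
#' members, `cv_i = sd_i / mean_i`, and `CV% = 100 * sqrt(mean(cv_i^2))`.
#' Before computation, outlier samples more than four times the
#' interquartile range from the median (per biomarker, across all
#' duplicate samples) are excluded, and the biomarker's zero offset
#' (half the minimum non-zero value, when zeros are present) is added
#' so that group means are positive.
#'
#' @param data Data frame with `sample_id` and biomarker columns.
#' @param duplicates A tibble with `group_id` and `sample_id` (2-3
#'   members per group), optionally `release` (used by
#'   [duplicate_r2()]).
#' @return A tibble: `biomarker`, `cv_pct`, `n_groups`, `n_excluded`.
#' @export
duplicate_cv <- function(data, duplicates) {
  dup <- check_duplicates(duplicates)
  biomarkers <- setdiff(names(data), "sample_id")
  idx <- match(dup$sample_id, data$sample_id)
  if (anyNA(idx)) abort("duplicates reference sample(s) absent from data")
  out <- list()
  for (bm in biomarkers) {
    full_col <- as.numeric(data[[bm]])
    x <- full_col[idx]
    keep <- iqr_keep(x)
    offset <- zero_offset(full_col)
    xx <- x + offset
    g <- dup$group_id
    usable <- keep & !is.na(xx)
    cvs <- tapply(seq_along(xx)[usable], g[usable], function(ii) {
      if (length(ii) < 2) return(NA_real_)
      sd(xx[ii]) / mean(xx[ii])
    })
    cvs <- cvs[!is.na(cvs)]
    if (!length(cvs)) {
      warn(paste0("duplicate_cv: no surviving duplicate groups for ", bm))
      cv <- NA_real_
    } else {
      cv <- 100 * sqrt(mean(cvs^2))
    }
    out[[bm]] <- tibble(biomarker = bm, cv_pct = cv,
                        n_groups = length(cvs),
                        n_excluded = sum(!keep, na.rm = TRUE))
  }
  list_rbind(unname(out))
}

#' Blind-duplicate coefficient of determination
#'
#' Per biomarker, regresses the released member's value on its
#' duplicate's value across groups by ordinary least squares and
#' reports the coefficient of determination. Triplets contribute the
#' release member paired with each of the other two members. The same
#' four-times-IQR outlier exclusion as [duplicate_cv()] is applied.
#'
#' @inheritParams duplicate_cv
#' @return A tibble: `biomarker`, `r2`, `n_pairs`.
#' @export
duplicate_r2 <- function(data, duplicates) {
  dup <- check_duplicates(duplicates)
  if (!"release" %in% names(dup)) {
    abort("duplicate_r2 needs a logical 'release' column marking the released member")
  }
  biomarkers <- setdiff(names(data), "sample_id")
  idx <- match(dup$sample_id, data$sample_id)
  if (anyNA(idx)) abort("duplicates reference sample(s) absent from data")
  # expand each group into (release, other) pairs
  pairs <- dup |>
    group_by(.data$group_id) |>
    group_modify(function(d, key) {
      rel <- d$sample_id[as.logical(d$release)]
      oth <- d$sample_id[!as.logical(d$release)]
      if (length(rel) != 1 || !length(oth)) {
        abort(paste0("duplicate group without exactly one released member"))
      }
      tibble(release_id = rel, other_id = oth)
    }) |>
    ungroup()
  out <- list()
  for (bm in biomarkers) {
    x <- as.numeric(data[[bm]])
    keep <- set_names(iqr_keep(x[idx]), dup$sample_id)
    yv <- x[match(pairs$release_id, data$sample_id)]
    xv <- x[match(pairs$other_id, data$sample_id)]
    ok <- !is.na(yv) & !is.na(xv) &
      keep[pairs$release_id] & keep[pairs$other_id]
    yy <- yv[ok]; xx <- xv[ok]
    if (length(yy) < 3 || length(unique(xx)) < 2) {
      warn(paste0("duplicate_r2: degenerate or insufficient pairs for ", bm))
      r2 <- NA_real_
    } else {
      fit <- stats::.lm.fit(cbind(1, xx), yy)
      tss <- sum((yy - mean(yy))^2)
      r2 <- if (tss == 0) NA_real_ else max(0, 1 - sum(fit$residuals^2) / tss)
    }
    out[[bm]] <- tibble(biomarker = bm, r2 = r2, n_pairs = sum(ok))
  }
  list_rbind(unname(out))
}

check_duplicates <- function(duplicates) {
  dup <- as_tibble(duplicates)
  if (!all(c("group_id", "sample_id") %in% names(dup))) {
    abort("duplicates must have group_id and sample_id columns")
  }
  sizes <- table(dup$group_id)
  if (any(sizes < 2 | sizes > 3)) {
    abort("duplicate groups must have 2 or 3 members")
  }
  dup
}

# TRUE for samples within 4 IQR of the median (NA treated as keep so that
# missingness is handled downstream)
iqr_keep <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(rep(TRUE, length(x)))
  med <- median(x[ok])
  iqr <- stats::IQR(x[ok])
  keep <- rep(TRUE, length(x))
  keep[ok] <- abs(x[ok] - med) <= 4 * iqr
  keep
}

zero_offset <- function(x) {
  if (!any(x == 0, na.rm = TRUE)) return(0)
  nz <- x[!is.na(x) & x > 0]
  if (!length(nz)) return(0)
  min(nz) / 2
}
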