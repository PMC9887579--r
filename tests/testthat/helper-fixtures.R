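# Shared fixtures: all data built in code at test time.

the_catalog <- nmr_catalog()
non_derived_names <- the_catalog$name[the_catalog$tier == "non_derived"]

# a constant-valued 107-column input (plus ids)
constant_input <- function(n = 3, value = 2) {
  dplyr::bind_cols(
    tibble::tibble(sample_id = sprintf("S%03d", seq_len(n))),
    tibble::as_tibble(setNames(as.list(rep(value, length(non_derived_names))),
                               non_derived_names))
  )
}

# small simulated dataset reused across tests (cached)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_nmr_dataset(n_plates = 12, samples_per_plate = 24,
                                     n_spectrometers = 2, seed = 42)
    }
    cache
  }
})

# metadata with fully degenerate covariates: constant degradation time,
# one row, one column, one spectrometer, one date
degenerate_meta <- function(n) {
  base <- as.POSIXct("2021-03-01 12:00:00", tz = "UTC")
  tibble::tibble(
    sample_id = sprintf("S%03d", seq_len(n)),
    plate_id = paste0("P", seq_len(n)), # one sample per plate keeps
    # (plate, row, column) unique while every covariate stays constant
    well_row = "B",
    well_col = 2L,
    spectrometer_id = "S1",
    prep_timestamp = base - 24 * 3600,
    measurement_timestamp = base
  )
}

# independent, deliberately naive Huber IRLS oracle (intercept only)
oracle_huber_mean <- function(x, k = 1.345, iters = 5000) {
  m <- median(x)
  for (i in seq_len(iters)) {
    r <- x - m
    s <- median(abs(r)) / 0.6745
    if (s == 0) return(m)
    w <- ifelse(abs(r) <= k * s, 1, k * s / abs(r))
    m_new <- sum(w * x) / sum(w)
    if (abs(m_new - m) < 1e-12) return(m_new)
    m <- m_new
  }
  m
}

# exhaustive search over contiguous partitions of date sizes into g groups,
# minimising max |group sum - target|
oracle_partition_cost <- function(sizes, g, target) {
  m <- length(sizes)
  cuts <- utils::combn(m - 1, g - 1, simplify = FALSE)
  best <- Inf
  for (cu in cuts) {
    bounds <- c(0, cu, m)
    cost <- max(vapply(seq_len(g), function(b) {
      abs(sum(sizes[(bounds[b] + 1):bounds[b + 1]]) - target)
    }, numeric(1)))
    best <- min(best, cost)
  }
  best
}
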