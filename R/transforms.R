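#' Offset-aware log transform
#'
#' Log transforms non-negative concentrations. If the vector contains
#' exact zeros, an offset of half the minimum non-zero value is added to
#' every value before taking logs, so that zeros map to a finite value
#' and the transform is exactly invertible given the recorded offset.
#'
#' @param x Numeric vector of concentrations (`>= 0` or `NA`).
#' @return A list with `values` (natural-log scale, `NA` propagated) and
#'   `offset` (0 when `x` has no zeros).
#' @examples
#' log_offset_transform(c(0, 2, 4)) # offset 1, values log(1), log(3), log(5)
#' @export
log_offset_transform <- function(x) {
  x <- as.numeric(x)
  if (any(x < 0, na.rm = TRUE)) {
    abort("log_offset_transform: negative values are not allowed")
  }
  nonzero <- x[!is.na(x) & x > 0]
  if (!length(nonzero)) {
    abort("log_offset_transform: no non-zero, non-missing values")
  }
  offset <- if (any(x == 0, na.rm = TRUE)) min(nonzero) / 2 else 0
  list(values = log(x + offset), offset = offset)
}

#' Invert the offset-aware log transform
#'
#' @param values Log-scale values.
#' @param offset The offset recorded by [log_offset_transform()].
#' @return Concentrations on the original scale.
#' @export
inverse_log_offset <- function(values, offset = 0) {
  exp(values) - offset
}

#' Offset-aware logit transform for percentage biomarkers
#'
#' Maps percentages in \[0, 100\] strictly into the real line. Exact 0
#' values are replaced by half the minimum non-zero percentage (the
#' lower offset) and exact 100 values by 100 minus half the gap to the
#' largest value below 100 (the upper offset) before applying
#' `qlogis(p/100)`. Both offsets are returned so the transform can be
#' inverted exactly.
#'
#' @param x Numeric vector of percentages in \[0, 100\] (or `NA`).
#' @return A list with `values`, `lower_offset` and `upper_offset`.
#' @export
logit_offset_transform <- function(x) {
  x <- as.numeric(x)
  if (any(x < 0 | x > 100, na.rm = TRUE)) {
    abort("logit_offset_transform: values outside [0, 100]")
  }
  ok <- !is.na(x)
  if (!any(ok)) abort("logit_offset_transform: all values missing")
  interior_low <- x[ok & x > 0]
  interior_high <- x[ok & x < 100]
  if (!length(interior_low) || !length(interior_high)) {
    abort("logit_offset_transform: column is constant at a boundary value")
  }
  lower <- if (any(x[ok] == 0)) min(interior_low) / 2 else 0
  upper <- if (any(x[ok] == 100)) (100 - max(interior_high)) / 2 else 0
  adj <- x
  if (lower > 0) adj[ok & x == 0] <- lower
  if (upper > 0) adj[ok & x == 100] <- 100 - upper
  list(values = qlogis(adj / 100), lower_offset = lower, upper_offset = upper)
}

#' Invert the offset-aware logit transform
#'
#' Values that map back (within floating-point round-off) to the
#' recorded boundary offsets are restored to exact 0 or 100.
#'
#' @param values Logit-scale values.
#' @param lower_offset,upper_offset Offsets recorded by
#'   [logit_offset_transform()].
#' @return Percentages on the original \[0, 100\] scale.
#' @export
inverse_logit_offset <- function(values, lower_offset = 0, upper_offset = 0) {
  v <- 100 * plogis(values)
  if (lower_offset > 0) {
    v[abs(v - lower_offset) < lower_offset * 1e-6] <- 0
  }
  if (upper_offset > 0) {
    v[abs(v - (100 - upper_offset)) < upper_offset * 1e-6] <- 100
  }
  v
}

# Core Huber M-estimation by iteratively reweighted least squares.
# X: full-rank design matrix (no NAs), y: response (no NAs).
# Scale is re-estimated each iteration as median(|r|)/0.6745; convergence
# when the largest absolute coefficient change drops below `tol`.
huber_irls <- function(X, y, k = 1.345, tol = 1e-8, max_iter = 200L) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    collinear <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    abort(paste0("rank-deficient design; collinear term(s): ",
                 paste(collinear, collapse = ", ")))
  }
  beta <- qr.coef(qrX, y)
  converged <- FALSE
  iter <- 0L
  scale <- NA_real_
  r <- y - drop(X %*% beta)
  for (iter in seq_len(max_iter)) {
    scale <- median(abs(r)) / 0.6745
    if (scale <= 0 || !is.finite(scale)) {
      # more than half the residuals are exactly zero: the fit
      # interpolates the majority and cannot be improved further
      converged <- TRUE
      break
    }
    w <- pmin(1, (k * scale) / abs(r))
    w[r == 0] <- 1
    wX <- X * w
    beta_new <- tryCatch(
      drop(solve(crossprod(wX, X), crossprod(wX, y))),
      error = function(e) qr.coef(qr(X * sqrt(w)), y * sqrt(w))
    )
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    r <- y - drop(X %*% beta)
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  fitted <- drop(X %*% beta)
  list(coefficients = set_names(as.numeric(beta), colnames(X)),
       fitted = fitted, residuals = y - fitted, scale = scale,
       weights = if (is.na(scale) || scale <= 0) rep(1, length(y))
                 else pmin(1, (k * scale) / pmax(abs(r), .Machine$double.xmin)),
       iterations = iter, converged = converged)
}

# Huber-type asymptotic standard errors for huber_irls coefficients
huber_se <- function(X, fit, k = 1.345) {
  r <- fit$residuals
  s <- fit$scale
  n <- length(r)
  p <- ncol(X)
  if (is.na(s) || s <= 0) return(set_names(rep(0, p), colnames(X)))
  u <- r / s
  psi <- pmax(-k, pmin(k, u))
  dpsi <- as.numeric(abs(u) <= k)
  num <- sum(psi^2) / (n - p)
  den <- (mean(dpsi))^2
  XtX_inv <- chol2inv(chol(crossprod(X)))
  set_names(sqrt(pmax(0, diag(XtX_inv)) * s^2 * num / den), colnames(X))
}

# Build a design matrix from a covariate data frame.
# Factors/characters are one-hot encoded against the largest level
# (ties broken lexicographically); numeric terms are centred on the mean
# of the rows used for fitting so that rows with a missing numeric
# covariate can still receive a fitted value through the intercept.
# Rows with missing covariate levels get 0 in all columns of that term.
build_design <- function(covariates, center_numeric = TRUE) {
  n <- nrow(covariates)
  cols <- list(`(Intercept)` = rep(1, n))
  reference_levels <- character()
  dropped <- character()
  centers <- numeric()
  for (term in names(covariates)) {
    v <- covariates[[term]]
    if (is.numeric(v)) {
      if (var(v, na.rm = TRUE) %in% c(0, NA) || all(is.na(v))) {
        dropped <- c(dropped, term)
        next
      }
      ctr <- if (center_numeric) mean(v, na.rm = TRUE) else 0
      centers[term] <- ctr
      vv <- v - ctr
      vv[is.na(vv)] <- 0
      cols[[term]] <- vv
    } else {
      f <- as.character(v)
      counts <- sort(table(f), decreasing = TRUE)
      # largest level is the reference; ties broken by label order
      top <- names(counts)[counts == max(counts)]
      ref <- sort(top)[1]
      lev <- setdiff(sort(unique(f[!is.na(f)])), ref)
      if (!length(lev)) {
        dropped <- c(dropped, term)
        next
      }
      reference_levels[term] <- ref
      for (l in lev) {
        cols[[paste0(term, l)]] <- as.numeric(!is.na(f) & f == l)
      }
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  used <- setdiff(names(covariates), dropped)
  complete <- if (length(used)) complete.cases(covariates[used]) else rep(TRUE, n)
  list(X = X, reference_levels = reference_levels, dropped = dropped,
       centers = centers, complete = complete)
}

#' Robust linear regression by Huber M-estimation
#'
#' Fits a linear model by iteratively reweighted least squares with the
#' Huber loss (tuning constant `k` on the standardised residual) and a
#' robust residual scale re-estimated each iteration as
#' `median(|r|)/0.6745`. Categorical covariates are one-hot encoded with
#' the largest level as the reference (ties broken by label order);
#' degenerate terms (a single observed level, or zero variance) are
#' dropped with a warning. Rows with a missing response or missing
#' covariates are excluded from fitting; rows with covariates present
#' still receive fitted values and residuals from the final
#' coefficients.
#'
#' @param data A data frame holding the response and covariates.
#' @param formula A formula `response ~ term1 + term2 + ...`. Terms must
#'   be column names of `data` (no expressions).
#' @param k Huber tuning constant (default 1.345).
#' @param tol Convergence tolerance on the largest absolute coefficient
#'   change (default 1e-8).
#' @param max_iter Iteration cap (default 200).
#' @return An object of class `nmr_robust_fit` with elements
#'   `coefficients`, `se`, `scale`, `residuals`, `fitted` (both full
#'   length, `NA` where not computable), `reference_levels`,
#'   `dropped_terms`, `converged`, `n_iterations`, `nobs`.
#' @examples
#' d <- data.frame(x = 1:10, y = 2 * (1:10) + 1)
#' fit <- robust_fit(d, y ~ x)
#' coef(fit) # (Intercept) ~ 11 at the centred x, slope 2
#' @export
robust_fit <- function(data, formula, k = 1.345, tol = 1e-8, max_iter = 200L) {
  vars <- all.vars(formula)
  response <- vars[1]
  terms <- vars[-1]
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols)) {
    abort(paste0("robust_fit: column(s) not in data: ",
                 paste(missing_cols, collapse = ", ")))
  }
  y <- as.numeric(data[[response]])
  design <- build_design(as.data.frame(data)[terms])
  if (length(design$dropped)) {
    warn(paste0("robust_fit: dropped degenerate term(s): ",
                paste(design$dropped, collapse = ", ")))
  }
  fit_rows <- !is.na(y) & design$complete
  if (sum(fit_rows) < 2) {
    abort("robust_fit: fewer than 2 usable observations")
  }
  fit <- huber_irls(design$X[fit_rows, , drop = FALSE], y[fit_rows],
                    k = k, tol = tol, max_iter = max_iter)
  se <- huber_se(design$X[fit_rows, , drop = FALSE], fit, k = k)
  fitted_all <- drop(design$X %*% fit$coefficients)
  residuals_all <- y - fitted_all
  structure(list(
    coefficients = fit$coefficients,
    se = se,
    scale = fit$scale,
    fitted = fitted_all,
    residuals = residuals_all,
    reference_levels = design$reference_levels,
    dropped_terms = design$dropped,
    centers = design$centers,
    converged = fit$converged,
    n_iterations = fit$iterations,
    nobs = sum(fit_rows),
    formula = formula
  ), class = "nmr_robust_fit")
}

#' @export
coef.nmr_robust_fit <- function(object, ...) object$coefficients

#' @export
residuals.nmr_robust_fit <- function(object, ...) object$residuals

#' @export
print.nmr_robust_fit <- function(x, ...) {
  cat("Huber robust linear fit (", x$nobs, " obs, ",
      x$n_iterations, " iterations, ",
      if (x$converged) "converged" else "NOT converged", ")\n", sep = "")
  print(round(x$coefficients, 6))
  invisible(x)
}

#' @export
tidy.nmr_robust_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std.error = unname(x$se))
}

#' @export
glance.nmr_robust_fit <- function(x, ...) {
  tibble(scale = x$scale, converged = x$converged,
         n_iterations = x$n_iterations, nobs = x$nobs)
}

#' Robust mean (intercept-only Huber fit)
#'
#' The Huber M-estimate of location with MAD scale: the intercept of a
#' robust regression with no covariates. Equals the arithmetic mean for
#' symmetric data and lies between the median and the mean under
#' one-sided contamination.
#'
#' @param x Numeric vector (missing values dropped).
#' @inheritParams robust_fit
#' @return A single number.
#' @export
robust_mean <- function(x, k = 1.345, tol = 1e-8, max_iter = 200L) {
  x <- x[!is.na(x)]
  if (length(x) < 1) abort("robust_mean: no non-missing values")
  if (length(x) == 1) return(x)
  m <- mean(x)
  for (iter in seq_len(max_iter)) {
    r <- x - m
    s <- median(abs(r)) / 0.6745
    if (s <= 0) break
    w <- pmin(1, (k * s) / abs(r))
    w[r == 0] <- 1
    m_new <- sum(w * x) / sum(w)
    if (abs(m_new - m) < tol) {
      m <- m_new
      break
    }
    m <- m_new
  }
  m
}
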