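# Model-quality statistics for a series of observed vs. calculated endpoint
# values: R^2, Lin's concordance correlation coefficient (CCC), the index of
# ideality of correlation (IIC), the correlation intensity index (CII), the
# coefficient of conformism of correlation prediction (CCCP), leave-one-out
# Q^2, RMSE, MAE and the Fisher F-ratio.
#
# Residuals are always observed - calculated.

.check_series <- function(observed, calculated, min_n = 1L) {
  if (length(observed) != length(calculated)) {
    stop("observed and calculated must have equal length", call. = FALSE)
  }
  if (length(observed) < min_n) {
    stop("need at least ", min_n, " paired values", call. = FALSE)
  }
  if (!all(is.finite(observed)) || !all(is.finite(calculated))) {
    stop("observed and calculated must be finite", call. = FALSE)
  }
  invisible(TRUE)
}

#' Determination coefficient R^2
#'
#' Squared Pearson correlation between observed and calculated values.
#'
#' @param observed,calculated Numeric vectors of equal length.
#' @return R^2 in `[0, 1]`.
#' @export
r_squared <- function(observed, calculated) {
  .check_series(observed, calculated, min_n = 3L)
  if (stats::sd(observed) == 0 || stats::sd(calculated) == 0) {
    stop("undefined statistic: constant series", call. = FALSE)
  }
  stats::cor(observed, calculated)^2
}

#' Lin's concordance correlation coefficient
#'
#' `2 * cov / (var_obs + var_calc + (mean_obs - mean_calc)^2)` with
#' population (1/n) moments.  Unlike Pearson's r it penalizes location and
#' scale shifts, so a systematically biased predictor scores below its
#' correlation.
#'
#' @inheritParams r_squared
#' @return CCC in `[-1, 1]`.
#' @export
ccc <- function(observed, calculated) {
  .check_series(observed, calculated, min_n = 3L)
  n <- length(observed)
  mo <- mean(observed); mc <- mean(calculated)
  vo <- mean((observed - mo)^2)
  vc <- mean((calculated - mc)^2)
  cv <- mean((observed - mo) * (calculated - mc))
  denom <- vo + vc + (mo - mc)^2
  if (denom == 0) {
    return(1)  # both series constant and identical
  }
  if (vo == 0 || vc == 0) {
    stop("undefined statistic: constant series", call. = FALSE)
  }
  2 * cv / denom
}

#' Index of ideality of correlation (IIC)
#'
#' Combines correlation with the balance of the two signed residual classes:
#' `IIC = r * min(MAEneg, MAEpos) / max(MAEneg, MAEpos)`, where `MAEneg` is
#' the mean absolute residual over points with `observed - calculated < 0`
#' and `MAEpos` over points with `observed - calculated >= 0`, and `r` is the
#' Pearson correlation.  A model whose errors all fall on one side of the
#' regression (including an exact fit, whose residuals are all zero and land
#' in the `>= 0` class) has one class empty and `IIC = 0` by convention.
#' Intended for the calibration set, where it rewards models whose residual
#' distribution is symmetric rather than merely small.
#'
#' @inheritParams r_squared
#' @return IIC in `[-1, 1]`.
#' @export
iic <- function(observed, calculated) {
  .check_series(observed, calculated, min_n = 3L)
  if (stats::sd(observed) == 0 || stats::sd(calculated) == 0) {
    stop("undefined statistic: constant series", call. = FALSE)
  }
  res <- observed - calculated
  neg <- res < 0
  if (!any(neg) || all(neg)) {
    return(0)
  }
  mae_neg <- mean(abs(res[neg]))
  mae_pos <- mean(abs(res[!neg]))
  hi <- max(mae_neg, mae_pos)
  if (hi == 0) return(0)
  stats::cor(observed, calculated) * min(mae_neg, mae_pos) / hi
}

# Leave-one-out R^2 vector: element k is the squared Pearson correlation of
# the series with point k removed, computed by downdating the five sums.
# NA where the removal leaves a constant series.
.loo_r2 <- function(observed, calculated) {
  x <- observed; y <- calculated
  n <- length(x)
  m <- n - 1
  sx <- sum(x) - x
  sy <- sum(y) - y
  sxx <- sum(x * x) - x * x
  syy <- sum(y * y) - y * y
  sxy <- sum(x * y) - x * y
  dx <- m * sxx - sx^2
  dy <- m * syy - sy^2
  num <- m * sxy - sx * sy
  out <- num^2 / (dx * dy)
  out[dx <= 0 | dy <= 0] <- NA_real_
  out
}

#' Correlation intensity index (CII)
#'
#' `CII = 1 - sum_k protest_k` with `protest_k = max(0, R2_minus_k - R2)`,
#' where `R2_minus_k` is the determination coefficient with point `k`
#' removed.  A point whose removal *raises* R^2 is an opponent of the
#' correlation and protests by the amount of that increase; supporters
#' (whose removal lowers R^2) contribute nothing, so only opponents pull the
#' index below 1.  Points whose removal leaves a constant series contribute
#' zero.
#'
#' @inheritParams r_squared
#' @return CII, at most 1.
#' @export
cii <- function(observed, calculated) {
  .check_series(observed, calculated, min_n = 4L)
  r2 <- r_squared(observed, calculated)
  loo <- .loo_r2(observed, calculated)
  protest <- pmax(0, loo - r2)
  protest[is.na(protest)] <- 0
  1 - sum(protest)
}

#' Coefficient of conformism of correlation prediction (CCCP)
#'
#' The normalized balance of supporters against opponents:
#' `CCCP = (n_supporters - n_opponents) / n`, where point `k` is a supporter
#' if `R2_minus_k < R2` (its presence strengthens the correlation) and an
#' opponent if `R2_minus_k > R2`.  Exact ties, and points whose removal
#' degenerates the series, count to neither side.
#'
#' @inheritParams r_squared
#' @return CCCP in `[-1, 1]`.
#' @export
cccp <- function(observed, calculated) {
  .check_series(observed, calculated, min_n = 4L)
  r2 <- r_squared(observed, calculated)
  loo <- .loo_r2(observed, calculated)
  sup <- sum(loo < r2, na.rm = TRUE)
  opp <- sum(loo > r2, na.rm = TRUE)
  (sup - opp) / length(observed)
}

#' Leave-one-out cross-validated Q^2
#'
#' `Q2 = 1 - PRESS / SS_tot` for leave-one-out refits of the one-variable
#' regression of observed on calculated.  PRESS is evaluated through the
#' standard hat-value identity `e_(i) = e_i / (1 - h_ii)`, which is exactly
#' equivalent to refitting without each point.
#'
#' @inheritParams r_squared
#' @return Q^2 (at most R^2; can be negative for a useless predictor).
#' @export
q2_loo <- function(observed, calculated) {
  .check_series(observed, calculated, min_n = 4L)
  x <- calculated; y <- observed
  n <- length(x)
  mx <- mean(x)
  sxx <- sum((x - mx)^2)
  if (sxx == 0) stop("undefined statistic: constant calculated series", call. = FALSE)
  b1 <- sum((x - mx) * (y - mean(y))) / sxx
  b0 <- mean(y) - b1 * mx
  e <- y - (b0 + b1 * x)
  h <- 1 / n + (x - mx)^2 / sxx
  if (any(1 - h <= .Machine$double.eps)) {
    stop("undefined statistic: degenerate leave-one-out refit", call. = FALSE)
  }
  press <- sum((e / (1 - h))^2)
  1 - press / sum((y - mean(y))^2)
}

#' Root mean squared error and mean absolute error
#'
#' Standard definitions over the residuals `observed - calculated`.
#'
#' @inheritParams r_squared
#' @return A non-negative number.
#' @export
rmse <- function(observed, calculated) {
  .check_series(observed, calculated, min_n = 1L)
  sqrt(mean((observed - calculated)^2))
}

#' @rdname rmse
#' @export
mae <- function(observed, calculated) {
  .check_series(observed, calculated, min_n = 1L)
  mean(abs(observed - calculated))
}

#' Fisher F-ratio of the one-descriptor regression
#'
#' `F = R2 * (n - 2) / (1 - R2)`.  A perfect correlation gives `Inf` with a
#' warning.
#'
#' @inheritParams r_squared
#' @return F statistic (possibly `Inf`).
#' @export
f_ratio <- function(observed, calculated) {
  .check_series(observed, calculated, min_n = 3L)
  r2 <- r_squared(observed, calculated)
  n <- length(observed)
  if (1 - r2 <= 0) {
    warning("perfect correlation: F is infinite", call. = FALSE)
    return(Inf)
  }
  r2 * (n - 2) / (1 - r2)
}

#' All per-subset statistics in one row
#'
#' Computes the full statistics block for a subset: n, R^2, CCC, IIC, CII,
#' Q^2, CCCP, RMSE, MAE, F, and the number of active attributes `N_A` when
#' supplied.  Statistics whose preconditions fail on the series (too few
#' points, degenerate refits) are reported as `NA`.
#'
#' @inheritParams r_squared
#' @param n_active Optional N_A count (see [count_active_attributes()]).
#' @return One-row data.frame with columns `n`, `R2`, `CCC`, `IIC`, `CII`,
#'   `Q2`, `CCCP`, `RMSE`, `MAE`, `F`, `N_A`.
#' @export
stat_block <- function(observed, calculated, n_active = NA_integer_) {
  .check_series(observed, calculated, min_n = 3L)
  safe <- function(f) {
    tryCatch(suppressWarnings(f(observed, calculated)),
             error = function(e) NA_real_)
  }
  data.frame(
    n = length(observed),
    R2 = safe(r_squared),
    CCC = safe(ccc),
    IIC = safe(iic),
    CII = safe(cii),
    Q2 = safe(q2_loo),
    CCCP = safe(cccp),
    RMSE = safe(rmse),
    MAE = safe(mae),
    F = safe(f_ratio),
    N_A = as.integer(n_active),
    stringsAsFactors = FALSE
  )
}
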