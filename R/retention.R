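#' Dual-point retention-time correction
#'
#' Run-to-run drift of an isocratic system is removed by aligning each run
#' on two anchor compounds of known reference retention time.  The unique
#' affine map sending the observed anchor times to their reference times is
#' applied to the analyte time; the correction is exact at both anchors by
#' construction.
#'
#' @param tR Observed retention time(s), minutes.
#' @param ref Length-2 numeric: reference retention times of the two anchors.
#' @param obs Length-2 numeric: observed retention times of the same anchors
#'   in this run.  Must be distinct.
#' @return Corrected retention time(s), minutes.
#' @examples
#' correct_time(7, ref = c(2, 12), obs = c(2, 10))  # 6 min after correction...
#' @export
correct_time <- function(tR, ref, obs) {
  if (length(ref) != 2 || length(obs) != 2) {
    stop("`ref` and `obs` must each hold two anchor times", call. = FALSE)
  }
  if (any(!is.finite(c(ref, obs)))) {
    stop("anchor times must be finite", call. = FALSE)
  }
  if (obs[1] == obs[2]) {
    stop("degenerate anchors: the two observed anchor times are identical (",
         obs[1], " min)", call. = FALSE)
  }
  a <- (ref[2] - ref[1]) / (obs[2] - obs[1])
  ref[1] + a * (tR - obs[1])
}

#' Retention factor from retention time and dead time
#'
#' The standard dimensionless retention measure `k = (tR - t0) / t0`, with
#' the dead time `t0` determined from an unretained marker (uracil).
#'
#' @param tR Retention time(s), minutes. Must exceed `t0`.
#' @param t0 Column dead time, minutes (> 0).
#' @return Retention factor(s), strictly positive.
#' @export
retention_factor <- function(tR, t0) {
  if (any(!is.finite(tR)) || any(!is.finite(t0))) {
    stop("`tR` and `t0` must be finite", call. = FALSE)
  }
  if (any(t0 <= 0)) stop("dead time t0 must be positive", call. = FALSE)
  if (any(tR <= t0)) {
    stop("non-retained solute: tR (", paste(signif(tR[tR <= t0], 4), collapse = ", "),
         " min) does not exceed the dead time t0", call. = FALSE)
  }
  (tR - t0) / t0
}

#' Fit the linear solvent strength model for one retention series
#'
#' Under the linear solvent strength (LSS) model the isocratic retention of
#' a solute obeys `log10 k = logkw - S * phi`, where `phi` is the organic
#' modifier volume fraction, `logkw` the extrapolated retention factor in a
#' fully aqueous mobile phase and `S` the (positive) solvent-strength slope.
#' The series is one compound at one pH, measured at >= 4 distinct `phi`
#' levels.  Replicate injections at the same `phi` are averaged after the
#' dual-point time correction, and the line is fitted by ordinary least
#' squares.  A coefficient of determination below 0.99 raises a warning
#' (poor LSS linearity) but does not reject the fit.
#'
#' @param series Data frame for a single (compound, pH): columns `phi`
#'   (volume fraction, strictly in (0,1)), `tR` (minutes) and `t0`
#'   (minutes), plus optionally `anchor1_ref`, `anchor1_obs`, `anchor2_ref`,
#'   `anchor2_obs` for per-row DP-RTC, and optionally `compound_id`, `pH`
#'   carried into the result.
#' @return Object of class `lss_fit`: list with `compound_id`, `pH`,
#'   `logkw`, `S`, `r2`, `n_points`, `se_logkw`, `se_S`, `rss`.
#' @examples
#' phi <- seq(0.1, 0.5, 0.1)
#' ser <- data.frame(phi = phi, tR = 2.5 * (1 + 10^(2 - 3 * phi)), t0 = 2.5)
#' fit_lss(ser)  # recovers logkw = 2, S = 3 exactly
#' @export
fit_lss <- function(series) {
  stopifnot(is.data.frame(series))
  need <- c("phi", "tR", "t0")
  miss <- setdiff(need, names(series))
  if (length(miss) > 0) {
    stop("retention series lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(series$phi <= 0 | series$phi >= 1)) {
    stop("phi must lie strictly within (0, 1)", call. = FALSE)
  }
  tR <- series$tR
  if (all(c("anchor1_ref", "anchor1_obs", "anchor2_ref", "anchor2_obs")
          %in% names(series))) {
    has_anchor <- !is.na(series$anchor1_obs) & !is.na(series$anchor2_obs)
    if (any(has_anchor)) {
      tR[has_anchor] <- vapply(which(has_anchor), function(i) {
        correct_time(series$tR[i],
                     ref = c(series$anchor1_ref[i], series$anchor2_ref[i]),
                     obs = c(series$anchor1_obs[i], series$anchor2_obs[i]))
      }, numeric(1))
    }
  }
  t0 <- unique(series$t0)
  if (length(t0) != 1) {
    stop("a retention series must have a single dead time t0", call. = FALSE)
  }
  ## average replicate injections at each phi level before fitting
  logk <- log10(retention_factor(tR, t0))
  agg <- stats::aggregate(logk, by = list(phi = series$phi), FUN = mean)
  phi <- agg$phi
  y <- agg$x
  n <- length(phi)
  if (n < 4) {
    stop("insufficient data: ", n, " distinct phi level(s), need at least 4",
         call. = FALSE)
  }
  if (stats::var(phi) == 0) {
    stop("degenerate design: no variation in phi", call. = FALSE)
  }
  fit <- stats::lm(y ~ phi)
  sm <- summary_quiet(fit)
  r2 <- sm$r.squared
  if (is.finite(r2) && r2 < 0.99) {
    warning("LSS fit", if (!is.null(series$compound_id))
      paste0(" for ", series$compound_id[1]), ": R2 = ", round(r2, 4),
      " below 0.99", call. = FALSE)
  }
  structure(list(
    compound_id = if ("compound_id" %in% names(series)) series$compound_id[1] else NA_character_,
    pH = if ("pH" %in% names(series)) series$pH[1] else NA_real_,
    logkw = unname(stats::coef(fit)[1]),
    S = -unname(stats::coef(fit)[2]),
    r2 = r2,
    n_points = n,
    se_logkw = sm$coefficients[1, 2],
    se_S = sm$coefficients[2, 2],
    rss = sum(stats::residuals(fit)^2)
  ), class = "lss_fit")
}

#' @export
print.lss_fit <- function(x, ...) {
  cat(sprintf("LSS fit%s%s: logkw = %.4f (se %.4f), S = %.4f (se %.4f), R2 = %.5f, n = %d\n",
              if (is.na(x$compound_id)) "" else paste0(" ", x$compound_id),
              if (is.na(x$pH)) "" else paste0(" @ pH ", x$pH),
              x$logkw, x$se_logkw, x$S, x$se_S, x$r2, x$n_points))
  invisible(x)
}

#' Extrapolated logkw for every compound and pH
#'
#' Splits a long-format retention table into per-(compound, pH) series,
#' fits each with [fit_lss()] and assembles the extrapolated `logkw`
#' intercepts into a compound-by-pH table.  Cells without measurements are
#' left `NA` with a message.
#'
#' @param retention Long-format data frame with columns `compound_id`, `pH`,
#'   `phi`, `tR`, `t0` and optional anchor columns (see [fit_lss()]).
#' @param ph Optional pH grid; defaults to the sorted unique pH values
#'   present.
#' @return Data frame with `compound_id` and one `logkw` column per pH,
#'   plus attribute `"fits"` holding the underlying `lss_fit` objects.
#' @export
build_logkw_matrix <- function(retention, ph = NULL) {
  if (nrow(retention) == 0) {
    out <- data.frame(compound_id = character(0))
    for (p in ph) out[[format_ph(p)]] <- numeric(0)
    return(out)
  }
  if (is.null(ph)) ph <- sort(unique(retention$pH))
  ph <- check_ph_grid(ph)
  ids <- unique(retention$compound_id)
  out <- data.frame(compound_id = as.character(ids), stringsAsFactors = FALSE)
  fits <- list()
  for (p in ph) {
    col <- rep(NA_real_, length(ids))
    for (i in seq_along(ids)) {
      ser <- retention[retention$compound_id == ids[i] & retention$pH == p, ,
                       drop = FALSE]
      if (nrow(ser) == 0) next
      fit <- fit_lss(ser)
      col[i] <- fit$logkw
      fits[[paste(ids[i], format_ph(p), sep = "@")]] <- fit
    }
    if (anyNA(col)) {
      message("build_logkw_matrix: no measurements for ",
              sum(is.na(col)), " compound(s) at pH ", format_ph(p))
    }
    out[[format_ph(p)]] <- col
  }
  attr(out, "fits") <- fits
  out
}

#' Read a long-format retention CSV
#'
#' Columns: `compound_id,pH,phi,tR,t0` and optionally
#' `anchor1_ref,anchor1_obs,anchor2_ref,anchor2_obs`.  One row per
#' injection; replicate injections appear as repeated (compound, pH, phi)
#' rows and are averaged during fitting.
#'
#' @param path CSV path.
#' @return Data frame ready for [build_logkw_matrix()].
#' @export
read_retention <- function(path) {
  df <- read_csv_ascii(path)
  need <- c("compound_id", "pH", "phi", "tR", "t0")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("retention CSV ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df$compound_id <- as.character(df$compound_id)
  for (col in setdiff(names(df), "compound_id")) {
    df[[col]] <- parse_numeric(df[[col]], col, path)
  }
  df
}

#' Read a precomputed logkw matrix
#'
#' Alternative entry point when extrapolated `logkw` values are already
#' available (e.g. published tables): a CSV with `compound_id` and one
#' column per pH value.
#'
#' @param path CSV path.
#' @return Data frame shaped like the output of [build_logkw_matrix()].
#' @export
read_logkw_matrix <- function(path) {
  df <- read_csv_ascii(path)
  if (!"compound_id" %in% names(df)) {
    stop("logkw matrix ", path, " lacks a compound_id column", call. = FALSE)
  }
  df$compound_id <- as.character(df$compound_id)
  for (col in setdiff(names(df), "compound_id")) {
    df[[col]] <- parse_numeric(df[[col]], col, path)
  }
  df
}
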