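#' Fraction of a basic site that is protonated at a given pH
#'
#' For a base B with conjugate acid BH+ of dissociation constant `pKa`, the
#' protonated (cationic) fraction at mobile-phase `pH` follows the
#' Henderson-Hasselbalch relation `1 / (1 + 10^(pH - pKa))`.  At `pH == pKa`
#' exactly half the molecules are charged; two pH units above the pKa the
#' charge is suppressed to below 1%.
#'
#' @param pKa Dissociation constant of the conjugate acid (dimensionless).
#' @param pH Mobile-phase pH. Vectorised; recycled against `pKa`.
#' @return Numeric vector of fractions in `[0, 1]`.
#' @examples
#' ionized_fraction(9.35, 7)   # benzylamine at neutral pH: almost fully charged
#' ionized_fraction(4.45, 7)   # 2-methylaniline: essentially neutral
#' @export
ionized_fraction <- function(pKa, pH) {
  if (!is.numeric(pKa) || !is.numeric(pH)) {
    stop("`pKa` and `pH` must be numeric", call. = FALSE)
  }
  if (any(!is.finite(pKa)) || any(!is.finite(pH))) {
    stop("`pKa` and `pH` must be finite", call. = FALSE)
  }
  1 / (1 + 10^(pH - pKa))
}

#' Apparent distribution coefficient of a base from logP, pKa and pH
#'
#' Corrects the intrinsic partition coefficient of the neutral species
#' (`logP`) for ionization at the working pH.  For a monoprotic base,
#' \deqn{\log D = \log P - \log_{10}(1 + 10^{pK_{a1}-pH}).}
#' When a second, weaker basic site is present (`pKa2 < pKa1`) the
#' denominator gains the doubly protonated species:
#' \deqn{\log D = \log P - \log_{10}(1 + 10^{pK_{a1}-pH} +
#'   10^{pK_{a1}+pK_{a2}-2\,pH}).}
#' `logD` never exceeds `logP` and converges to it once the pH is well above
#' `pKa1` (dissociation fully suppressed).
#'
#' @param logP log10 octanol/water partition coefficient of the neutral form.
#' @param pKa1 pKa of the most basic site.
#' @param pH Mobile-phase pH.
#' @param pKa2 Optional pKa of a second basic site (`NA` when absent).
#' @return Numeric vector of logD values.
#' @examples
#' logd_base(1.09, 9.35, 7)          # benzylamine, mostly ionized: -1.26
#' logd_base(-0.30, 6.31, 7, 2.97)   # 1,4-benzenediamine (diprotic): -0.38
#' @export
logd_base <- function(logP, pKa1, pH, pKa2 = NA_real_) {
  n <- max(length(logP), length(pKa1), length(pH), length(pKa2))
  logP <- rep_len(logP, n)
  pKa1 <- rep_len(pKa1, n)
  pH <- rep_len(pH, n)
  pKa2 <- rep_len(pKa2, n)
  if (any(is.na(logP))) {
    stop("logD is not computable without logP (missing for ",
         sum(is.na(logP)), " value(s))", call. = FALSE)
  }
  if (any(!is.finite(pKa1)) || any(!is.finite(pH))) {
    stop("`pKa1` and `pH` must be finite", call. = FALSE)
  }
  extra <- ifelse(is.na(pKa2), 0, 10^(pKa1 + pKa2 - 2 * pH))
  logP - log10(1 + 10^(pKa1 - pH) + extra)
}

#' Tabulate logD for a set of compounds over a pH grid
#'
#' Applies [logd_base()] to every (compound, pH) pair.  Sample compounds
#' without a literature logP cannot be ionization-corrected; they are
#' dropped with a message rather than an error.
#'
#' @param compounds Compound table as returned by [read_compounds()] (needs
#'   columns `id`, `logP`, `pKa1`, `pKa2`).
#' @param ph Numeric vector of pH values (strictly increasing, within 0-14).
#' @return Data frame with `compound_id` and one column per pH value (named
#'   by the pH, e.g. `"7"`), full floating precision.  Rounding to the
#'   2-decimal presentation convention is left to report writers.
#' @export
logd_table <- function(compounds, ph) {
  ph <- check_ph_grid(ph)
  if (nrow(compounds) == 0) {
    out <- data.frame(compound_id = character(0))
    for (p in ph) out[[format_ph(p)]] <- numeric(0)
    return(out)
  }
  missing_logp <- is.na(compounds$logP)
  if (any(missing_logp)) {
    message("logd_table: skipping ", sum(missing_logp),
            " compound(s) without logP: ",
            paste(compounds$id[missing_logp], collapse = ", "))
    compounds <- compounds[!missing_logp, , drop = FALSE]
  }
  pKa2 <- if ("pKa2" %in% names(compounds)) compounds$pKa2 else NA_real_
  out <- data.frame(compound_id = compounds$id, stringsAsFactors = FALSE)
  for (p in ph) {
    out[[format_ph(p)]] <- logd_base(compounds$logP, compounds$pKa1, p, pKa2)
  }
  rownames(out) <- NULL
  out
}

#' Expected positive charge of a base at a given pH
#'
#' Fallback electrostatic-charge descriptor used when a curated per-pH `n_e`
#' value is not supplied with the compound table: the expected number of
#' protonated sites, i.e. the sum of the Henderson-Hasselbalch protonated
#' fractions over the one or two basic sites.
#'
#' @inheritParams logd_base
#' @return Numeric vector of charges in `[0, 2]`.
#' @seealso [ionized_fraction()]
#' @export
default_ne <- function(pKa1, pH, pKa2 = NA_real_) {
  if (any(!is.finite(pKa1))) stop("`pKa1` must be finite", call. = FALSE)
  n <- max(length(pKa1), length(pH), length(pKa2))
  pKa1 <- rep_len(pKa1, n)
  pH <- rep_len(pH, n)
  pKa2 <- rep_len(pKa2, n)
  second <- numeric(n)
  has2 <- !is.na(pKa2)
  second[has2] <- 1 / (1 + 10^(pH[has2] - pKa2[has2]))
  ionized_fraction(pKa1, pH) + second
}

## pH grids are small and user-facing: validate early, fail with context.
check_ph_grid <- function(ph) {
  if (length(ph) == 0 || !is.numeric(ph)) {
    stop("pH grid must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(ph)) || any(ph < 0) || any(ph > 14)) {
    stop("pH values must be finite and within [0, 14]", call. = FALSE)
  }
  if (is.unsorted(ph, strictly = TRUE)) {
    stop("pH grid must be strictly increasing", call. = FALSE)
  }
  ph
}

## Canonical column label for a pH value ("7", "7.5", ...).
format_ph <- function(ph) {
  format(ph, trim = TRUE, drop0trailing = TRUE, scientific = FALSE)
}
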