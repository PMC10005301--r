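#' Configuration for the synthetic-study generator
#'
#' Collects every knob of the simulated chromatographic study in one
#' validated list.  The defaults emulate the real study design this package
#' targets: 23 model + 4 verification + 15 sample compounds, mobile-phase
#' pH grid {7, 8, 9, 10}, five methanol fractions 0.1-0.5, literature logP
#' spanning roughly -0.3 to 4.6 and pKa 2.97-9.35, per-pH true QSRR models
#' whose coefficient sets mirror the published multi-parameter models
#' (electrostatic-charge-only at pH 7-8, full descriptor set at pH 9-10),
#' 0.01 min retention-time noise and 0.1 equation error on the logD
#' channel.
#'
#' The ground truth is ionization-consistent: each compound's true logD at
#' every pH follows exactly from its logP/pKa, and the true logkw is placed
#' by inverting the pH's true QSRR model, with the logD-channel noise
#' entering as equation error in that inversion.  Solvent-strength slopes
#' are coupled linearly to logkw (more hydrophobic solutes respond more
#' steeply to modifier), as observed in reversed-phase practice.
#'
#' @param n_model,n_verification,n_sample Compounds per role.
#' @param ph pH grid (strictly increasing).
#' @param phi Organic-modifier volume fractions, >= 4 levels in (0, 1).
#' @param true_models Named list (by pH label) of true coefficient vectors
#'   with entries `(Intercept)`, `logkw` and optionally `ne`, `A`, `B`.
#' @param logp_range,pka_range Uniform sampling ranges for logP and pKa1.
#' @param p_diprotic Probability that a compound carries a second basic
#'   site (pKa2 drawn 1.5-4 units below pKa1).
#' @param p_acidic_A Probability that a compound has a non-zero
#'   hydrogen-bond acidity A (primary/secondary amines, anilines); when
#'   non-zero, A ~ U(0.1, 0.35).  B ~ U(0.3, 1.0) always.
#' @param s_slope,s_intercept,s_jitter,s_min Linear logkw-to-S coupling
#'   `S = s_slope * logkw + s_intercept + N(0, s_jitter)`, clamped at
#'   `s_min`.
#' @param t0 Column dead time, minutes.
#' @param n_replicates Injections averaged per (compound, pH, phi).
#' @param retention_sd Gaussian noise sd on retention times, minutes.
#' @param logd_sd Equation-error sd on the logD channel (dimensionless).
#' @param rtc_drift Simulate an affine run-to-run time drift (removed by
#'   the dual-point correction) with anchor reference times `anchor_ref`.
#' @param anchor_ref Reference retention times of the two anchors, minutes.
#' @param seed Integer seed fixing all randomness, or `NULL` to use the
#'   current RNG state.
#' @return Validated list of class `generator_config`.
#' @export
generator_config <- function(n_model = 23, n_verification = 4, n_sample = 15,
                             ph = c(7, 8, 9, 10),
                             phi = seq(0.1, 0.5, by = 0.1),
                             true_models = default_true_models(),
                             logp_range = c(-0.3, 4.6),
                             pka_range = c(2.97, 9.35),
                             p_diprotic = 0.1,
                             p_acidic_A = 0.5,
                             s_slope = 0.9, s_intercept = 2.0,
                             s_jitter = 0.2, s_min = 0.5,
                             t0 = 1.5, n_replicates = 3,
                             retention_sd = 0.01, logd_sd = 0.1,
                             rtc_drift = TRUE, anchor_ref = c(4, 12),
                             seed = NULL) {
  cfg <- list(n_model = n_model, n_verification = n_verification,
              n_sample = n_sample, ph = check_ph_grid(ph), phi = phi,
              true_models = true_models, logp_range = logp_range,
              pka_range = pka_range, p_diprotic = p_diprotic,
              p_acidic_A = p_acidic_A, s_slope = s_slope,
              s_intercept = s_intercept, s_jitter = s_jitter, s_min = s_min,
              t0 = t0, n_replicates = n_replicates,
              retention_sd = retention_sd, logd_sd = logd_sd,
              rtc_drift = rtc_drift, anchor_ref = anchor_ref, seed = seed)
  if (n_model < 1) stop("invalid config: n_model must be >= 1", call. = FALSE)
  if (min(n_verification, n_sample) < 0) {
    stop("invalid config: negative compound counts", call. = FALSE)
  }
  if (length(phi) < 4 || any(phi <= 0 | phi >= 1)) {
    stop("invalid config: phi grid needs >= 4 levels strictly in (0, 1)",
         call. = FALSE)
  }
  if (retention_sd < 0 || logd_sd < 0 || s_jitter < 0) {
    stop("invalid config: noise sds must be non-negative", call. = FALSE)
  }
  for (p in ph) {
    tm <- true_models[[format_ph(p)]]
    if (is.null(tm) || !all(c("(Intercept)", "logkw") %in% names(tm))) {
      stop("invalid config: true model for pH ", format_ph(p),
           " must define (Intercept) and logkw coefficients", call. = FALSE)
    }
  }
  structure(cfg, class = "generator_config")
}

#' Default true QSRR coefficient sets of the generator
#'
#' One coefficient vector per pH of the default grid, patterned on the
#' published multi-parameter models: at pH 7 and 8 retention plus
#' electrostatic charge carry the signal; at pH 9 and 10 the hydrogen-bond
#' terms enter with small effects (the weakness of those terms relative to
#' their standard errors is a property of the real models, deliberately
#' preserved).
#'
#' @return Named list of named numeric vectors.
#' @export
default_true_models <- function() {
  list(
    "7" = c("(Intercept)" = -0.12, logkw = 1.02, ne = -0.85),
    "8" = c("(Intercept)" = -0.09, logkw = 0.96, ne = -0.54),
    "9" = c("(Intercept)" = 0.21, logkw = 0.93, ne = -0.29, A = 0.21,
            B = -0.49),
    "10" = c("(Intercept)" = 0.26, logkw = 0.92, ne = -0.67, A = -0.30,
             B = -0.62)
  )
}

#' Draw a synthetic compound set with known ground truth
#'
#' @param config A [generator_config()].
#' @return Compound table (columns `id`, `name`, `logP`, `pKa1`, `pKa2`,
#'   `role`, `A`, `B`) with every field populated; role-dependent blinding
#'   (samples losing their literature values) happens in
#'   [generate_study()], not here.
#' @export
generate_compounds <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_model + config$n_verification + config$n_sample
  roles <- rep(c("model", "verification", "sample"),
               times = c(config$n_model, config$n_verification,
                         config$n_sample))
  logP <- stats::runif(n, config$logp_range[1], config$logp_range[2])
  pKa1 <- stats::runif(n, config$pka_range[1], config$pka_range[2])
  diprotic <- stats::runif(n) < config$p_diprotic
  pKa2 <- rep(NA_real_, n)
  pKa2[diprotic] <- pmax(0.5, pKa1[diprotic] -
                           stats::runif(sum(diprotic), 1.5, 4))
  A <- ifelse(stats::runif(n) < config$p_acidic_A,
              stats::runif(n, 0.1, 0.35), 0)
  B <- stats::runif(n, 0.3, 1.0)
  data.frame(id = sprintf("syn%02d", seq_len(n)),
             name = sprintf("synthetic compound %d", seq_len(n)),
             logP = logP, pKa1 = pKa1, pKa2 = pKa2, role = roles,
             A = A, B = B, stringsAsFactors = FALSE)
}

#' Simulate one isocratic retention series
#'
#' Inverts the linear solvent strength relation to produce retention times
#' `tR = t0 * (1 + 10^(logkw - S * phi))` at every modifier fraction of the
#' config grid, adds Gaussian measurement noise, and (optionally) applies
#' an affine run drift recorded through the two anchor compounds so that
#' the dual-point correction can remove it downstream.  Draws that would
#' fall at or below the dead time are re-drawn (at most 100 times each)
#' with a message.
#'
#' @param logkw,S True LSS parameters of the series.
#' @param config A [generator_config()] (supplies phi grid, t0, noise,
#'   replicate count, drift policy).
#' @param compound_id,ph Labels carried into the output.
#' @return Long-format retention data frame compatible with [fit_lss()].
#' @export
simulate_retention <- function(logkw, S, config = generator_config(),
                               compound_id = "syn01", ph = NA_real_) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  drift <- if (config$rtc_drift) {
    c(offset = stats::runif(1, -0.05, 0.05), scale = stats::runif(1, 0.98, 1.02))
  } else c(offset = 0, scale = 1)
  simulate_series(logkw, S, config, compound_id, ph, drift)
}

simulate_series <- function(logkw, S, config, compound_id, ph, drift) {
  phi <- rep(config$phi, each = config$n_replicates)
  t0 <- config$t0
  true_t <- t0 * (1 + 10^(logkw - S * phi))
  tR <- numeric(length(phi))
  for (i in seq_along(phi)) {
    for (try in seq_len(100)) {
      cand <- true_t[i] + stats::rnorm(1, 0, config$retention_sd)
      if (cand > t0) break
      if (try == 100) {
        stop("simulate_retention: could not draw tR > t0 at phi = ",
             phi[i], call. = FALSE)
      }
      message("simulate_retention: re-drawing tR <= t0 at phi = ", phi[i])
    }
    tR[i] <- cand
  }
  g <- function(t) drift[["offset"]] + drift[["scale"]] * t
  data.frame(compound_id = compound_id, pH = ph, phi = phi, tR = g(tR),
             t0 = t0,
             anchor1_ref = config$anchor_ref[1],
             anchor1_obs = g(config$anchor_ref[1]),
             anchor2_ref = config$anchor_ref[2],
             anchor2_obs = g(config$anchor_ref[2]),
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic study
#'
#' Produces the full input bundle for an end-to-end pipeline run with known
#' ground truth: a compound table (samples blinded as in a real study:
#' literature logP/pKa withheld), supplied per-pH `ne` descriptor columns,
#' a long-format retention table, and a `truth` record holding every latent
#' quantity (true logkw, S, logD, the generating coefficient vectors and
#' the config).
#'
#' Construction per compound and pH: true logD follows exactly from
#' logP/pKa by ionization correction; the true logkw is the value that the
#' pH's generating QSRR model maps to that logD given the compound's
#' descriptors, plus `logd_sd` equation error; retention times then follow
#' the LSS relation with `retention_sd` measurement noise.  With both sds
#' at zero the whole pipeline reproduces the generating coefficients to
#' numerical precision.
#'
#' @param config A [generator_config()].
#' @return List of class `synthetic_study`: `compounds`, `retention`,
#'   `truth`.
#' @export
generate_study <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  truth_compounds <- local({
    cfg <- config
    cfg$seed <- NULL
    generate_compounds(cfg)
  })
  n <- nrow(truth_compounds)
  ph_labels <- vapply(config$ph, format_ph, character(1))
  logkw_true <- ne_true <- logd_true <- s_true <-
    matrix(NA_real_, n, length(ph_labels),
           dimnames = list(truth_compounds$id, ph_labels))
  retention <- list()
  for (j in seq_along(config$ph)) {
    p <- config$ph[j]
    beta <- config$true_models[[ph_labels[j]]]
    ne <- default_ne(truth_compounds$pKa1, p, truth_compounds$pKa2)
    logd <- logd_base(truth_compounds$logP, truth_compounds$pKa1, p,
                      truth_compounds$pKa2)
    eps <- stats::rnorm(n, 0, config$logd_sd)
    covar <- beta[["(Intercept)"]] +
      coef_or_zero(beta, "ne") * ne +
      coef_or_zero(beta, "A") * truth_compounds$A +
      coef_or_zero(beta, "B") * truth_compounds$B
    logkw <- (logd - eps - covar) / beta[["logkw"]]
    S <- pmax(config$s_min,
              config$s_slope * logkw + config$s_intercept +
                stats::rnorm(n, 0, config$s_jitter))
    ne_true[, j] <- ne
    logd_true[, j] <- logd
    logkw_true[, j] <- logkw
    s_true[, j] <- S
    for (i in seq_len(n)) {
      drift <- if (config$rtc_drift) {
        c(offset = stats::runif(1, -0.05, 0.05),
          scale = stats::runif(1, 0.98, 1.02))
      } else c(offset = 0, scale = 1)
      retention[[paste(i, j)]] <- simulate_series(
        logkw[i], S[i], config, truth_compounds$id[i], p, drift)
    }
  }
  compounds <- truth_compounds
  blind <- compounds$role == "sample"
  compounds$logP[blind] <- NA_real_
  compounds$pKa1[blind] <- NA_real_
  compounds$pKa2[blind] <- NA_real_
  for (j in seq_along(ph_labels)) {
    compounds[[paste0("ne_", ph_labels[j])]] <- ne_true[, j]
  }
  structure(list(
    compounds = compounds,
    retention = do.call(rbind, c(retention, list(make.row.names = FALSE))),
    truth = list(compounds = truth_compounds, logkw = logkw_true,
                 S = s_true, ne = ne_true, logD = logd_true,
                 models = config$true_models, config = config)
  ), class = "synthetic_study")
}

#' Write a synthetic study to disk
#'
#' Emits exactly the CSV dialects the pipeline readers consume
#' (`compounds.csv`, `retention.csv`) plus `truth.json` for test harnesses.
#'
#' @param study A `synthetic_study` from [generate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_compounds(study$compounds, file.path(dir, "compounds.csv"))
  utils::write.csv(study$retention, file.path(dir, "retention.csv"),
                   row.names = FALSE, na = "")
  truth <- study$truth
  truth$config$true_models <- lapply(truth$config$true_models, as.list)
  truth$config <- unclass(truth$config)
  truth$models <- lapply(truth$models, as.list)
  for (f in c("logkw", "S", "ne", "logD")) {
    truth[[f]] <- as.data.frame(truth[[f]])
  }
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", digits = NA, auto_unbox = TRUE,
                       na = "null")
  invisible(dir)
}

coef_or_zero <- function(beta, term) {
  if (term %in% names(beta)) beta[[term]] else 0
}
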