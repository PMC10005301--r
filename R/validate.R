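#' Signed relative error of a determined logD against literature
#'
#' `100 * (determined - literature) / literature`; negative values indicate
#' under-prediction relative to the literature reference.
#'
#' @param determined Chromatographically determined logD.
#' @param literature Literature logD (non-zero).
#' @return Signed percent error.
#' @examples
#' relative_error(1.79, 1.74)  # 2.87 %
#' @export
relative_error <- function(determined, literature) {
  if (any(literature == 0)) {
    stop("relative error undefined for literature logD = 0", call. = FALSE)
  }
  100 * (determined - literature) / literature
}

#' External validation of QSRR models on held-out compounds
#'
#' For each verification compound and pH: the literature logD is computed
#' from the compound's logP/pKa by ionization correction ([logd_base()]),
#' the determined logD is predicted from the fitted model for that pH and
#' the compound's `logkw` and descriptors, and the signed relative error is
#' flagged against the conventional 20% acceptance band.  The flag is
#' descriptive; failing records are still returned.
#'
#' @param models Named list of `qsrr_model` objects keyed by pH label
#'   (as produced by [run_pipeline()] or built by hand).
#' @param compounds Compound table; rows with `role == "verification"` are
#'   used (pass a pre-filtered table to override).
#' @param logkw logkw matrix (`compound_id` + one column per pH).
#' @param threshold Acceptance band on `|error_pct|`, percent.
#' @param ne_fallback Use [default_ne()] when no supplied `ne_<pH>` column
#'   covers a compound (logged per substitution).
#' @return Data frame of validation records: `compound_id`, `pH`,
#'   `literature_logD`, `determined_logD`, `error_pct`, `pass`.
#' @export
validate_models <- function(models, compounds, logkw, threshold = 20,
                            ne_fallback = TRUE) {
  verif <- compounds[compounds$role == "verification", , drop = FALSE]
  if (nrow(verif) == 0 && nrow(compounds) > 0) verif <- compounds
  recs <- predict_logd(models, verif, logkw, ne_fallback = ne_fallback,
                       require_logP = TRUE)
  if (nrow(recs) == 0) {
    return(data.frame(compound_id = character(0), pH = numeric(0),
                      literature_logD = numeric(0),
                      determined_logD = numeric(0),
                      error_pct = numeric(0), pass = logical(0)))
  }
  idx <- match(recs$compound_id, verif$id)
  lit <- logd_base(verif$logP[idx], verif$pKa1[idx], recs$pH,
                   verif$pKa2[idx])
  err <- relative_error(recs$logD, lit)
  data.frame(compound_id = recs$compound_id, pH = recs$pH,
             literature_logD = lit, determined_logD = recs$logD,
             error_pct = err, pass = abs(err) <= threshold,
             stringsAsFactors = FALSE)
}

#' Predict logD for compounds from per-pH QSRR models
#'
#' Applies each pH's fitted model to the compound's extrapolated `logkw`
#' and descriptors.  Cells without a `logkw` value, or without a required
#' descriptor when the fallback is disabled, are skipped with a message.
#'
#' @inheritParams validate_models
#' @param compounds Compound table; rows with `role == "sample"` are used
#'   when present, otherwise all rows.
#' @param require_logP Internal: restrict to compounds with logP (used by
#'   [validate_models()]).
#' @return Data frame with `compound_id`, `pH`, `logD` (full precision;
#'   round to 2 decimals for presentation).
#' @export
predict_logd <- function(models, compounds, logkw, ne_fallback = TRUE,
                         require_logP = FALSE) {
  stopifnot(is.list(models))
  targets <- if (any(compounds$role == "sample") && !require_logP) {
    compounds[compounds$role == "sample", , drop = FALSE]
  } else compounds
  out <- list()
  for (ph_label in names(models)) {
    model <- models[[ph_label]]
    ph <- as.numeric(ph_label)
    kw_col <- logkw[[ph_label]]
    if (is.null(kw_col)) {
      message("predict_logd: no logkw column for pH ", ph_label, "; skipped")
      next
    }
    kw <- kw_col[match(targets$id, logkw$compound_id)]
    desc <- descriptor_frame(targets, ph, model$subset, ne_fallback)
    newdata <- cbind(data.frame(logkw = kw), desc)
    usable <- stats::complete.cases(newdata)
    if (any(!usable)) {
      message("predict_logd: skipping ", sum(!usable), " compound(s) at pH ",
              ph_label, " with missing logkw or descriptors: ",
              paste(targets$id[!usable], collapse = ", "))
    }
    if (!any(usable)) next
    pred <- predict(model, newdata[usable, , drop = FALSE])
    out[[ph_label]] <- data.frame(compound_id = targets$id[usable],
                                  pH = ph, logD = unname(pred),
                                  stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(compound_id = character(0), pH = numeric(0),
                      logD = numeric(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(match(res$compound_id, compounds$id), res$pH), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

## Assemble the descriptor columns a model needs, honouring supplied per-pH
## ne_<pH> columns and falling back to the expected protonation charge.
descriptor_frame <- function(compounds, ph, subset, ne_fallback) {
  desc <- data.frame(row.names = seq_len(nrow(compounds)))
  for (d in subset) {
    if (d == "ne") {
      col <- paste0("ne_", format_ph(ph))
      if (col %in% names(compounds) && !anyNA(compounds[[col]])) {
        desc$ne <- compounds[[col]]
      } else if (ne_fallback) {
        supplied <- if (col %in% names(compounds)) compounds[[col]] else
          rep(NA_real_, nrow(compounds))
        fb <- is.na(supplied) & !is.na(compounds$pKa1)
        if (any(fb)) {
          message("descriptor fallback: ne at pH ", format_ph(ph),
                  " computed from pKa for ",
                  paste(compounds$id[fb], collapse = ", "))
          supplied[fb] <- default_ne(compounds$pKa1[fb], ph,
                                     compounds$pKa2[fb])
        }
        desc$ne <- supplied
      } else {
        desc$ne <- if (col %in% names(compounds)) compounds[[col]] else
          rep(NA_real_, nrow(compounds))
      }
    } else {
      desc[[d]] <- if (d %in% names(compounds)) compounds[[d]] else
        rep(NA_real_, nrow(compounds))
    }
  }
  desc
}
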