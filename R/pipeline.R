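#' Run the full logD-estimation workflow
#'
#' Chains the stages of the chromatographic logD study: read and validate
#' the compound table; obtain the logkw matrix (either by LSS extrapolation
#' of raw retention measurements or from a precomputed matrix); compute
#' literature logD of the model compounds by ionization correction; per pH,
#' fit QSRR models of logD on logkw and descriptors with subset selection;
#' externally validate on the verification compounds; and predict logD for
#' the sample compounds.  Every stage reports compound counts and
#' substitutions through messages, which are collected into the run log.
#'
#' @param compounds Compound table: a path to a CSV (see
#'   [read_compounds()]) or an already-validated data frame.
#' @param retention Long-format retention measurements (path or data
#'   frame); mutually exclusive with `logkw`.
#' @param logkw Precomputed logkw matrix (path or data frame).
#' @param ph pH grid; defaults to the numeric columns of the logkw matrix.
#' @param candidates Descriptor candidates for subset selection; use
#'   `character(0)` for the univariate logD-logkw model.
#' @param descriptor_policy `"supplied"` (use the table's descriptor
#'   columns, skip cells that lack them), `"fallback_ne"` (additionally
#'   derive a missing `ne` from pKa; the default) or `"fail"` (abort on any
#'   missing descriptor).
#' @param alpha Parsimony significance level, see [select_model()].
#' @param threshold External-validation acceptance band, percent.
#' @param out_dir Optional directory; when given, writes `models.json`,
#'   `ranking.csv`, `validation.csv`, `predictions.csv` and `run.log`.
#' @return List of class `chromlogd_run` with elements `models` (named by
#'   pH label), `selections`, `logkw`, `logd_model` (literature logD of the
#'   model compounds), `validation`, `predictions`, `log`.
#' @examples
#' run <- run_pipeline(
#'   compounds = chromlogd_example("study_compounds.csv"),
#'   logkw = chromlogd_example("study_logkw.csv"),
#'   candidates = character(0))
#' run$models[["9"]]
#' @export
run_pipeline <- function(compounds, retention = NULL, logkw = NULL,
                         ph = NULL, candidates = c("ne", "A", "B"),
                         descriptor_policy = c("fallback_ne", "supplied",
                                               "fail"),
                         alpha = 0.05, threshold = 20, out_dir = NULL) {
  descriptor_policy <- match.arg(descriptor_policy)
  log_lines <- character(0)
  note <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  collect <- function(expr) {
    withCallingHandlers(expr, message = function(m) {
      log_lines <<- c(log_lines, sub("\n$", "", conditionMessage(m)))
      invokeRestart("muffleMessage")
    })
  }

  if (is.character(compounds)) compounds <- read_compounds(compounds)
  else compounds <- validate_compounds(compounds)
  note("compounds: ", nrow(compounds), " total (",
       sum(compounds$role == "model"), " model, ",
       sum(compounds$role == "verification"), " verification, ",
       sum(compounds$role == "sample"), " sample)")

  if (is.null(retention) == is.null(logkw)) {
    stop("supply exactly one of `retention` or `logkw`", call. = FALSE)
  }
  if (!is.null(retention)) {
    if (is.character(retention)) retention <- read_retention(retention)
    kw <- collect(build_logkw_matrix(retention, ph))
    note("retention: fitted LSS series for ", nrow(kw), " compound(s)")
  } else {
    kw <- if (is.character(logkw)) read_logkw_matrix(logkw) else logkw
    note("logkw: precomputed matrix for ", nrow(kw), " compound(s)")
  }
  if (is.null(ph)) {
    ph <- suppressWarnings(as.numeric(setdiff(names(kw), "compound_id")))
    ph <- sort(ph[!is.na(ph)])
  }
  ph <- check_ph_grid(ph)
  ne_fallback <- descriptor_policy == "fallback_ne"

  model_comp <- compounds[compounds$role == "model", , drop = FALSE]
  logd_model <- collect(logd_table(model_comp, ph))

  selections <- list()
  models <- list()
  for (p in ph) {
    lab <- format_ph(p)
    dat <- data.frame(
      compound_id = model_comp$id,
      logD = logd_model[[lab]],
      logkw = kw[[lab]][match(model_comp$id, kw$compound_id)],
      stringsAsFactors = FALSE)
    desc <- collect(descriptor_frame(model_comp, p, candidates, ne_fallback))
    unavailable <- vapply(desc, function(x) all(is.na(x)), logical(1))
    if (any(unavailable) && descriptor_policy == "fail") {
      stop("qsrr stage: descriptor(s) ",
           paste(names(desc)[unavailable], collapse = ", "),
           " missing at pH ", lab, call. = FALSE)
    }
    if (any(unavailable)) {
      note("pH ", lab, ": descriptor(s) ",
           paste(names(desc)[unavailable], collapse = ", "),
           " unavailable for every model compound; dropped from candidates")
      desc <- desc[, !unavailable, drop = FALSE]
    }
    cand_p <- intersect(candidates, names(desc))
    dat <- cbind(dat, desc)
    complete <- stats::complete.cases(dat)
    if (any(!complete)) {
      if (descriptor_policy == "fail") {
        stop("qsrr stage: missing logkw or descriptors at pH ", lab,
             " for ", paste(dat$compound_id[!complete], collapse = ", "),
             call. = FALSE)
      }
      note("qsrr stage pH ", lab, ": dropping ", sum(!complete),
           " compound(s) with missing cells")
      dat <- dat[complete, , drop = FALSE]
    }
    sel <- collect(select_model(dat, candidates = cand_p,
                                alpha = alpha, ph = p))
    selections[[lab]] <- sel
    models[[lab]] <- sel$model
    note("pH ", lab, ": selected subset {", subset_label(sel$model$subset),
         "}, N = ", sel$model$N, ", R2 = ", signif(sel$model$r2, 4))
  }

  validation <- collect(validate_models(models, compounds, kw,
                                        threshold = threshold,
                                        ne_fallback = ne_fallback))
  note("validation: ", nrow(validation), " record(s), ",
       sum(validation$pass), " within ", threshold, "%")
  predictions <- collect(predict_logd(models, compounds, kw,
                                      ne_fallback = ne_fallback))
  note("prediction: ", nrow(predictions), " (compound, pH) cell(s)")

  run <- structure(list(models = models, selections = selections,
                        logkw = kw, logd_model = logd_model,
                        validation = validation, predictions = predictions,
                        log = log_lines),
                   class = "chromlogd_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.chromlogd_run <- function(x, ...) {
  cat("chromlogd pipeline run\n")
  for (lab in names(x$models)) {
    cat(sprintf("  pH %-4s %s  [R2 %.4f, N %d]\n", lab,
                model_report(x$models[[lab]]), x$models[[lab]]$r2,
                x$models[[lab]]$N))
  }
  cat("  validation records: ", nrow(x$validation), "; predictions: ",
      nrow(x$predictions), "\n", sep = "")
  invisible(x)
}

#' Write the artifact bundle of a pipeline run
#'
#' @param run A `chromlogd_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_models(run$models, file.path(dir, "models.json"))
  ranking <- do.call(rbind, lapply(names(run$selections), function(lab) {
    cbind(pH = lab, run$selections[[lab]]$ranking)
  }))
  utils::write.csv(ranking, file.path(dir, "ranking.csv"), row.names = FALSE)
  val <- run$validation
  val$literature_logD <- round(val$literature_logD, 2)
  val$determined_logD <- round(val$determined_logD, 2)
  val$error_pct <- round(val$error_pct, 2)
  utils::write.csv(val, file.path(dir, "validation.csv"), row.names = FALSE)
  pred <- run$predictions
  pred$logD <- round(pred$logD, 2)
  utils::write.csv(pred, file.path(dir, "predictions.csv"),
                   row.names = FALSE)
  writeLines(run$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' Serialize fitted QSRR models to JSON
#'
#' Full precision; one record per pH with the coefficient map, standard
#' errors, r2 statistics, N and the compound ids used.
#'
#' @param models Named list of `qsrr_model` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_models <- function(models, path) {
  payload <- lapply(models, function(m) {
    list(pH = m$pH, subset = as.list(m$subset), coef = as.list(m$coef),
         se = as.list(m$se), r2 = m$r2, r2_adj = m$r2_adj,
         sigma = m$sigma, N = m$N,
         compound_ids = as.list(m$compound_ids))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read QSRR models back from JSON
#'
#' @param path JSON file written by [write_models()].
#' @return Named list of `qsrr_model` objects.
#' @export
read_models <- function(path) {
  payload <- jsonlite::read_json(path)
  lapply(payload, function(m) {
    structure(list(
      pH = m$pH,
      subset = as.character(unlist(m$subset)),
      terms = names(m$coef),
      coef = unlist(m$coef),
      se = unlist(m$se),
      r2 = m$r2, r2_adj = m$r2_adj, sigma = m$sigma, N = m$N,
      compound_ids = as.character(unlist(m$compound_ids))
    ), class = "qsrr_model")
  })
}
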