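#' Fit a QSRR model of logD on logkw and selected descriptors
#'
#' Ordinary least squares with intercept of `logD` on the extrapolated
#' retention factor `logkw` plus any chosen molecular descriptors:
#' `ne` (electrostatic charge at the working pH), `A` (hydrogen-bond
#' acidity) and `B` (hydrogen-bond basicity).  The reported uncertainties
#' are the classical OLS standard errors.  Both the raw coefficient of
#' determination (`r2`) and its degrees-of-freedom-adjusted form (`r2_adj`)
#' are kept: regression software customarily prints the adjusted value,
#' so published model tables are compared against `r2_adj`, while subset
#' selection ranks on the raw `r2`.
#'
#' @param data Data frame with columns `logD`, `logkw`, any descriptors
#'   named in `descriptors`, and optionally `compound_id`.
#' @param descriptors Character vector, a subset of `c("ne", "A", "B")`
#'   (empty for the univariate logD-logkw model).
#' @param ph Optional pH label stored with the model.
#' @return Object of class `qsrr_model`: coefficients, standard errors,
#'   `r2`, `r2_adj`, residual sd `sigma`, `N` and the compound ids used.
#' @examples
#' d <- data.frame(logkw = 1:6 / 2, logD = 0.9 * (1:6 / 2) - 0.2)
#' fit_mlr(d)   # exact line, r2 = 1
#' @export
fit_mlr <- function(data, descriptors = character(), ph = NA_real_) {
  stopifnot(is.data.frame(data))
  descriptors <- as.character(descriptors)
  bad <- setdiff(descriptors, c("ne", "A", "B"))
  if (length(bad) > 0) {
    stop("unknown descriptor(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  terms <- c("logkw", descriptors)
  miss <- setdiff(c("logD", terms), names(data))
  if (length(miss) > 0) {
    stop("model data lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  used <- data[, c("logD", terms), drop = FALSE]
  if (anyNA(used)) {
    stop("model data contains missing cells in: ",
         paste(names(used)[vapply(used, anyNA, logical(1))], collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(used)
  p <- length(terms) + 1L
  if (n < p) {
    stop("need at least ", p, " compounds to fit ", p,
         " coefficients, got ", n, call. = FALSE)
  }
  fml <- stats::as.formula(paste("logD ~", paste(terms, collapse = " + ")))
  fit <- stats::lm(fml, data = used)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("collinear design: term(s) ",
         paste(names(cf)[is.na(cf)], collapse = ", "),
         " are linearly dependent on the others", call. = FALSE)
  }
  sm <- summary_quiet(fit)
  structure(list(
    pH = ph,
    subset = descriptors,
    terms = names(cf),
    coef = cf,
    se = sm$coefficients[, 2],
    r2 = sm$r.squared,
    r2_adj = sm$adj.r.squared,
    sigma = sm$sigma,
    rss = sum(stats::residuals(fit)^2),
    tss = sum((used$logD - mean(used$logD))^2),
    N = n,
    compound_ids = if ("compound_id" %in% names(data)) data$compound_id else NULL
  ), class = "qsrr_model")
}

#' Predict logD from a fitted QSRR model
#'
#' @param object A `qsrr_model`.
#' @param newdata Data frame with `logkw` and the model's descriptors.
#' @param ... Unused.
#' @return Numeric vector of predicted logD (full precision).
#' @export
predict.qsrr_model <- function(object, newdata, ...) {
  terms <- c("logkw", object$subset)
  miss <- setdiff(terms, names(newdata))
  if (length(miss) > 0) {
    stop("newdata lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(newdata[, terms, drop = FALSE]))
  drop(X %*% object$coef[colnames(X)])
}

#' @export
print.qsrr_model <- function(x, ...) {
  cat(model_report(x), "\n")
  cat(sprintf("  N = %d, R2 = %.4f (adj. %.4f)%s\n", x$N, x$r2, x$r2_adj,
              if (is.na(x$pH)) "" else paste0(", pH ", x$pH)))
  invisible(x)
}

#' Exhaustive descriptor-subset selection for the QSRR model
#'
#' Fits all subsets of the candidate descriptors (`logkw` and the intercept
#' are always included; with the default three candidates that is 8
#' models) and ranks them by raw r2.  Because r2 can only grow as terms are
#' added, the raw maximum is always the full subset, so the selection pairs
#' the r2 ranking with a parsimony guard: starting from the smallest
#' subsets (within a size, in decreasing r2), the first model that is not
#' significantly worse than the top-r2 model by a partial F test at level
#' `alpha` is selected.  Terms that genuinely carry signal make every model
#' omitting them significantly worse and are therefore retained (with
#' noise-free data any true term is retained exactly), while descriptors
#' that only chase noise fail the F test and are dropped.  Subsets whose
#' design is collinear are excluded with a message.
#'
#' @inheritParams fit_mlr
#' @param candidates Descriptors to search over (default `c("ne","A","B")`).
#' @param alpha Significance level of the parsimony F test.
#' @return List of class `qsrr_selection`: `model` (the selected
#'   `qsrr_model`), `ranking` (data frame, one row per subset with
#'   `subset`, `n_terms`, `r2`, `r2_adj`, sorted by decreasing r2), and
#'   `models` (all fitted `qsrr_model`s, keyed by subset label).
#' @export
select_model <- function(data, candidates = c("ne", "A", "B"),
                         alpha = 0.05, ph = NA_real_) {
  subsets <- descriptor_subsets(candidates)
  models <- list()
  rows <- list()
  for (s in subsets) {
    label <- subset_label(s)
    m <- tryCatch(fit_mlr(data, descriptors = s, ph = ph),
                  error = function(e) e)
    if (inherits(m, "error")) {
      message("select_model: subset {", label, "} excluded: ",
              conditionMessage(m))
      next
    }
    models[[label]] <- m
    rows[[label]] <- data.frame(subset = label, n_terms = length(s),
                                r2 = m$r2, r2_adj = m$r2_adj,
                                stringsAsFactors = FALSE)
  }
  if (length(models) == 0) stop("no descriptor subset could be fitted",
                                call. = FALSE)
  ranking <- do.call(rbind, rows)
  ranking <- ranking[order(-ranking$r2, ranking$n_terms), , drop = FALSE]
  rownames(ranking) <- NULL
  best <- models[[ranking$subset[1]]]
  order_try <- ranking[order(ranking$n_terms, -ranking$r2), , drop = FALSE]
  chosen <- ranking$subset[1]
  for (i in seq_len(nrow(order_try))) {
    cand <- models[[order_try$subset[i]]]
    if (!all(cand$subset %in% best$subset)) next
    if (!nested_model_worse(cand, best, alpha)) {
      chosen <- order_try$subset[i]
      break
    }
  }
  structure(list(model = models[[chosen]], ranking = ranking,
                 models = models),
            class = "qsrr_selection")
}

## Partial F test of a nested `small` model against `big`; TRUE when the
## extra terms of `big` improve the fit significantly at level alpha.
## Numerically exact fits (both residual sums ~ 0) count as equivalent.
nested_model_worse <- function(small, big, alpha) {
  if (length(small$subset) >= length(big$subset)) return(FALSE)
  ## the small model already fits to numerical precision: nothing to gain
  if (small$rss <= 1e-16 * max(small$tss, 1)) return(FALSE)
  if (small$rss <= big$rss) return(FALSE)
  df_extra <- length(big$terms) - length(small$terms)
  df_resid <- big$N - length(big$terms)
  if (df_resid <= 0) return(FALSE)
  if (big$rss <= 1e-16 * max(big$tss, 1)) return(TRUE)
  f <- ((small$rss - big$rss) / df_extra) / (big$rss / df_resid)
  stats::pf(f, df_extra, df_resid, lower.tail = FALSE) < alpha
}

#' @export
print.qsrr_selection <- function(x, ...) {
  cat("QSRR subset selection (", nrow(x$ranking), " candidate models)\n",
      sep = "")
  print(x$ranking, row.names = FALSE)
  cat("selected: {", subset_label(x$model$subset), "}\n", sep = "")
  print(x$model)
  invisible(x)
}

#' Render a fitted QSRR model as an equation string
#'
#' Produces the conventional `logD = (est ± se) term ...` presentation with
#' estimates and standard errors rounded to 2 decimals and sign-aware
#' joining (a negative coefficient appears as `- (|est| ± se)`).
#'
#' @param model A `qsrr_model`.
#' @return Single character string.
#' @examples
#' d <- data.frame(logkw = c(0.2, 0.8, 1.4, 2.2, 3.0),
#'                 logD = c(0.0, 0.6, 1.1, 2.0, 2.8))
#' model_report(fit_mlr(d))
#' @export
model_report <- function(model) {
  stopifnot(inherits(model, "qsrr_model"))
  ord <- c("logkw", model$subset, "(Intercept)")
  pieces <- character(0)
  for (i in seq_along(ord)) {
    term <- ord[i]
    est <- model$coef[[term]]
    se <- model$se[[term]]
    body <- sprintf("(%.2f \u00b1 %.2f)", abs(est), se)
    name <- switch(term, "(Intercept)" = "", "ne" = " ne", paste0(" ", term))
    sign <- if (est < 0) "-" else "+"
    piece <- paste0(body, name)
    pieces <- c(pieces,
                if (i == 1) paste0(if (est < 0) "-" else "", piece)
                else paste(sign, piece))
  }
  paste("logD =", paste(pieces, collapse = " "))
}

## Inverse of model_report for round-trip checks: recovers estimates and
## standard errors (2-decimal precision) from the rendered equation.
parse_model_report <- function(text) {
  text <- gsub("\u2212", "-", text)
  body <- sub("^logD = ", "", text)
  pat <- "([+-]?) ?\\(([0-9.]+) \u00b1 ([0-9.]+)\\) ?([A-Za-z]*)"
  m <- gregexpr(pat, body, perl = TRUE)
  parts <- regmatches(body, m)[[1]]
  est <- se <- numeric(0)
  nm <- character(0)
  for (p in parts) {
    g <- regmatches(p, regexec(pat, p, perl = TRUE))[[1]]
    s <- if (g[2] == "-") -1 else 1
    est <- c(est, s * as.numeric(g[3]))
    se <- c(se, as.numeric(g[4]))
    nm <- c(nm, if (g[5] == "") "(Intercept)" else g[5])
  }
  list(coef = stats::setNames(est, nm), se = stats::setNames(se, nm))
}

## All subsets of the candidate descriptors, smallest first, stable order.
## summary.lm warns on residuals at numerical zero; exact fits are a
## legitimate state here (noise-free simulated studies, saturated designs),
## so that one warning is muffled while everything else propagates.
summary_quiet <- function(fit) {
  withCallingHandlers(summary(fit), warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

descriptor_subsets <- function(candidates) {
  out <- list(character(0))
  for (k in seq_along(candidates)) {
    combos <- utils::combn(candidates, k, simplify = FALSE)
    out <- c(out, combos)
  }
  out
}

subset_label <- function(s) {
  if (length(s) == 0) "(none)" else paste(s, collapse = "+")
}
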