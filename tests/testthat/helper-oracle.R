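## Closed-form OLS oracle, independent of the lm() path used by the package:
## coefficients by the normal equations, standard errors from the classical
## covariance, r2 from sums of squares.
ols_oracle <- function(X, y) {
  X <- cbind(1, as.matrix(X))
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  n <- nrow(X)
  p <- ncol(X)
  sigma2 <- sum(res^2) / (n - p)
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - sum(res^2) / tss
  list(coef = drop(beta), se = se, r2 = r2,
       r2_adj = 1 - (1 - r2) * (n - 1) / (n - p))
}

## Packaged study fixtures
study_compounds <- function() {
  read_compounds(chromlogd_example("study_compounds.csv"))
}
study_logkw <- function() {
  read_logkw_matrix(chromlogd_example("study_logkw.csv"))
}
study_logd_published <- function() {
  read_logkw_matrix(chromlogd_example("study_logd_published.csv"))
}
validation_published <- function() {
  utils::read.csv(chromlogd_example("study_validation_published.csv"),
                  check.names = FALSE, stringsAsFactors = FALSE)
}

## Model-compound regression frame at one pH from the packaged fixtures:
## logD recomputed from logP/pKa (full precision), logkw from the published
## matrix.  `ids` restricts to a subset of compound ids.
study_frame <- function(ph, ids = NULL) {
  comp <- study_compounds()
  comp <- comp[comp$role == "model", ]
  if (!is.null(ids)) comp <- comp[comp$id %in% as.character(ids), ]
  kw <- study_logkw()
  data.frame(
    compound_id = comp$id,
    logD = logd_base(comp$logP, comp$pKa1, ph, comp$pKa2),
    logkw = kw[[as.character(ph)]][match(comp$id, kw$compound_id)],
    stringsAsFactors = FALSE)
}
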