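# Cell-composition correction: per-probe OLS of beta on five of the six
# Houseman cell-type proportions (the sixth is the complement of the
# others, so it is excluded; NK by default, having the highest variance
# relative to abundance).  The corrected value is intercept + residual.

#' Fit the per-probe cell-proportion model
#'
#' Ordinary least squares of each probe's betas on an intercept and five
#' cell-type proportions, for all probes at once (multi-response
#' `lm.fit`).
#'
#' @param betas probe-by-sample matrix (no missing values).
#' @param sheet sample sheet covering the matrix's samples, with the six
#'   proportion columns.
#' @param exclude the proportion left out of the design (default "NK").
#' @return a `cell_model_fit` list: `coefficients` (probes x 6),
#'   `residuals` and `fitted` (probes x samples), `exclude`, `design`.
#' @export
fit_cell_model <- function(betas, sheet, exclude = "NK") {
  stopifnot(exclude %in% CELL_TYPES)
  if (anyNA(betas)) stop("cell model requires a complete beta matrix")
  sheet <- sheet[match(colnames(betas), sheet$sample_id), , drop = FALSE]
  if (anyNA(sheet$sample_id))
    stop("sample sheet does not cover all beta matrix samples")
  used <- setdiff(CELL_TYPES, exclude)
  X <- cbind(intercept = 1, as.matrix(sheet[, used]))
  if (nrow(X) <= ncol(X))
    stop("need more samples than model coefficients")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    deficient <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("collinear design; deficient column(s): ",
         paste(deficient, collapse = ", "))
  }
  fit <- lm.fit(X, t(betas))
  coefs <- t(fit$coefficients)            # probes x 6
  resid <- t(fit$residuals)               # probes x samples
  fitted <- betas - resid
  structure(list(coefficients = coefs, residuals = resid, fitted = fitted,
                 exclude = exclude, design = X,
                 sample_ids = colnames(betas)),
            class = "cell_model_fit")
}

#' Cell-composition-corrected betas
#'
#' Corrected value = per-probe intercept + per-probe-and-sample residual.
#' Values are deliberately not clipped to \[0, 1\]; the out-of-range rate
#' is attached as attribute `out_of_range_rate`.
#'
#' @param fit a `cell_model_fit`.
#' @return probe-by-sample matrix of corrected betas.
#' @export
corrected_betas <- function(fit) {
  stopifnot(inherits(fit, "cell_model_fit"))
  out <- fit$coefficients[, "intercept"] + fit$residuals
  dimnames(out) <- dimnames(fit$residuals)
  attr(out, "out_of_range_rate") <- mean(out < 0 | out > 1)
  out
}

#' Calls lost and gained after cell correction
#'
#' Compares a catalogue built from raw betas with one built from
#' cell-corrected betas over the same probes: which VMP/SMP calls
#' disappear once cell composition is regressed out (and which appear).
#'
#' @param catalog_raw,catalog_adjusted `variability_catalog` objects over
#'   the same probe universe.
#' @return list with `lost_vmp`, `gained_vmp`, `lost_smp`, `gained_smp`
#'   (probe id vectors) and `fractions` (lost / |raw set|).
#' @export
cell_sensitivity_report <- function(catalog_raw, catalog_adjusted) {
  if (!setequal(catalog_raw$probe_id, catalog_adjusted$probe_id))
    stop("catalogues cover different probe universes")
  vr <- vmp_ids(catalog_raw); va <- vmp_ids(catalog_adjusted)
  sr <- smp_ids(catalog_raw); sa <- smp_ids(catalog_adjusted)
  list(lost_vmp = setdiff(vr, va), gained_vmp = setdiff(va, vr),
       lost_smp = setdiff(sr, sa), gained_smp = setdiff(sa, sr),
       fractions = c(
         lost_vmp = if (length(vr)) length(setdiff(vr, va)) / length(vr) else NA_real_,
         lost_smp = if (length(sr)) length(setdiff(sr, sa)) / length(sr) else NA_real_))
}
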