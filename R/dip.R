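# Hartigan's dip test for unimodality, implemented from scratch.
#
# The dip of a sample is the smallest sup-norm distance between its
# empirical CDF and any unimodal CDF (convex below the mode, concave
# above, a jump allowed only at the mode).  It is bounded below by
# 1/(2n) and above by 1/4, the maximum being attained by two equal point
# masses.  Large dips indicate multimodality.  P-values are calibrated by
# Monte Carlo against the standard uniform, the canonical least
# favourable unimodal null.

#' Dip statistic
#'
#' Computed in C++ by iterative narrowing of the modal interval over
#' greatest-convex-minorant / least-concave-majorant hulls of the
#' empirical CDF.  The statistic is invariant to permutation of the input
#' and to affine maps `x -> a x + b` (a != 0); it is *not* invariant to
#' general monotone transforms, which change which CDFs are unimodal.
#'
#' @param values numeric sample, n >= 4, finite.
#' @param sorted set TRUE if `values` is already sorted ascending.
#' @return the dip, in (0, 0.25\]; for a degenerate (all-equal) sample the
#'   minimal dip 1/(2n) is returned with attribute `degenerate = TRUE`.
#' @export
dip_statistic <- function(values, sorted = FALSE) {
  if (length(values) < 4L) stop("dip statistic requires n >= 4")
  out <- .dip_stat_cpp(as.numeric(values), sorted)
  if (length(unique(values)) == 1L) attr(out, "degenerate") <- TRUE
  out
}

#' Monte-Carlo dip p-value
#'
#' Draws `B` samples of size `n` from the standard uniform, computes their
#' dips, and returns the add-one p-value
#' `(1 + #{null dips >= dip_stat}) / (B + 1)`, always inside
#' \[1/(B+1), 1\].
#'
#' @param dip_stat observed dip.
#' @param n sample size the dip was computed on.
#' @param B Monte-Carlo replicates.
#' @param rng_seed optional seed (uses the current RNG state when NULL).
#' @param null_dips optional pre-computed vector of null dips for this
#'   `n` (e.g. from [dip_null_distribution()]); when supplied, `B` and
#'   `rng_seed` are ignored.
#' @return p-value.
#' @export
dip_pvalue <- function(dip_stat, n, B = 2000L, rng_seed = NULL,
                       null_dips = NULL) {
  if (is.null(null_dips)) {
    if (B < 1L) stop("B must be >= 1")
    if (!is.null(rng_seed)) set.seed(rng_seed)
    null_dips <- .dip_null_cpp(as.integer(n), as.integer(B))
  }
  (1 + sum(null_dips >= as.numeric(dip_stat))) / (length(null_dips) + 1)
}

#' Null distribution of the dip under the uniform
#'
#' @param n sample size.
#' @param B number of draws.
#' @param rng_seed optional seed.
#' @return numeric vector of `B` null dips.
#' @export
dip_null_distribution <- function(n, B = 2000L, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  .dip_null_cpp(as.integer(n), as.integer(B))
}
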