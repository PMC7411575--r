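#' Composite log-likelihood of an observed SFS
#'
#' Multinomial composite log-likelihood treating sites as independent:
#' `lnL = sum over polymorphic cells of m_e * ln(max(p_e, min_p))`, with
#' `m_e` the observed (possibly real-valued, after projection) cell counts
#' and `p_e` the model's expected cell probabilities. Monomorphic cells are
#' excluded. Natural log throughout. The floor `min_p` guards cells whose
#' Monte-Carlo probability estimate is zero; its default,
#' `1 / (10 * n_sims * n_cells)`, sits below the resolution of the
#' simulation-based estimate.
#'
#' @param observed an [sfs_counts()].
#' @param expected an [expected_sfs()] with matching sizes and folding.
#' @param min_p probability floor (> 0).
#' @return the composite log-likelihood (scalar).
#' @export
composite_log_likelihood <- function(observed, expected, min_p = NULL) {
  stopifnot(inherits(observed, "sfs_counts"), inherits(expected, "expected_sfs"))
  if (!identical(as.integer(observed$n), as.integer(expected$n)))
    stop("shape mismatch: observed n = ", paste(observed$n, collapse = "x"),
         ", expected n = ", paste(expected$n, collapse = "x"))
  if (!identical(observed$folded, expected$folded))
    stop("folding mismatch between observed and expected SFS")
  mask <- polymorphic_mask(observed$n, observed$folded)
  if (is.null(min_p)) min_p <- 1 / (10 * expected$n_sims * sum(mask))
  stopifnot(min_p > 0)
  m <- observed$counts[mask]
  p <- pmax(expected$probs[mask], min_p)
  sum(m * log(p))
}

#' Maximum observed (saturated) log-likelihood
#'
#' The composite log-likelihood with cell probabilities set to the observed
#' proportions -- its maximum over any probability vector (Gibbs'
#' inequality): `lnL_obs = sum m_e * ln(m_e / S)` over polymorphic cells
#' with `m_e > 0`, `S` the total polymorphic count. The gap between this and
#' a fitted model's likelihood is the "delta likelihood" used for model
#' ranking.
#'
#' @param observed an [sfs_counts()].
#' @return the saturated log-likelihood (scalar, <= 0).
#' @export
max_observed_log_likelihood <- function(observed) {
  stopifnot(inherits(observed, "sfs_counts"))
  m <- observed$counts[polymorphic_mask(observed$n, observed$folded)]
  S <- sum(m)
  if (S <= 0) stop("all-zero spectrum: no polymorphic sites")
  m <- m[m > 0]
  sum(m * log(m / S))
}
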