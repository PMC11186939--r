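#' Estimate systolic pulmonary artery pressure
#'
#' The modified Bernoulli screening estimate from the tricuspid
#' regurgitation jet velocity and the right atrial pressure:
#' `sPAP = 4 * TRV^2 + RAP`. Vectorized; outputs are real-valued mmHg.
#'
#' @param trv tricuspid regurgitation velocity, m/s, nonnegative.
#' @param rap right atrial pressure, mmHg, nonnegative (clinically
#'   estimated from the inferior vena cava).
#' @return sPAP in mmHg; always at least `rap`.
#' @export
estimate_spap <- function(trv, rap) {
  if (any(trv < 0)) stop("TRV must be nonnegative", call. = FALSE)
  if (any(rap < 0)) stop("RAP must be nonnegative", call. = FALSE)
  4 * trv^2 + rap
}

#' Estimate mean pulmonary artery pressure
#'
#' Linear regression of mPAP on sPAP: `mPAP = 0.61 * sPAP + 2` mmHg.
#' Vectorized.
#'
#' @param spap systolic pulmonary artery pressure, mmHg, nonnegative.
#' @return mPAP in mmHg; at least 2.
#' @export
estimate_mpap <- function(spap) {
  if (any(spap < 0)) stop("sPAP must be nonnegative", call. = FALSE)
  0.61 * spap + 2
}
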