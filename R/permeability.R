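#' Classify cyclic-hexapeptide permeability from the mean SAPSA
#'
#' Empirical thresholds for this scaffold class: a time-averaged SAPSA
#' below 80 Å² indicates high passive permeability, above 150 Å² low
#' permeability; the band in between (boundaries included) is
#' intermediate.
#'
#' @param sapsa_mean Ensemble-mean SAPSA in Å² (>= 0); vectorized.
#' @param low,high Class boundaries in Å² (defaults 80 and 150).
#' @return Character vector: `"high"`, `"intermediate"` or `"low"`.
#' @examples
#' classify_permeability(66)   # "high"
#' classify_permeability(160)  # "low"
#' @export
classify_permeability <- function(sapsa_mean, low = 80, high = 150) {
  if (low >= high) stop("low threshold must be below high", call. = FALSE)
  if (any(!is.finite(sapsa_mean)) || any(sapsa_mean < 0)) {
    stop("sapsa_mean must be finite and >= 0", call. = FALSE)
  }
  ifelse(sapsa_mean < low, "high",
         ifelse(sapsa_mean > high, "low", "intermediate"))
}
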