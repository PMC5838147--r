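#' Time-averaged SAPSA of a conformational ensemble with block statistics
#'
#' Applies [conformer_surface()] to every frame and aggregates: the
#' ensemble mean and population standard deviation (divisor n) of the
#' per-frame SAPSA, plus means/SDs over consecutive non-overlapping
#' blocks of `block_size` frames (the last block may be short).  For a
#' 20 ns trajectory stored as 20,000 frames, `block_size = 1000`
#' corresponds to 1 ns block averages.
#'
#' @param ens An [ensemble()] with radii and polarity assigned.
#' @param config A [surface_config()].
#' @param block_size Frames per block (>= 1); default 1000.
#' @return Object of class `"ensemble_sapsa"` with fields `per_frame`,
#'   `mean`, `sd`, `block_size`, `block_means`, `block_sds` (all areas
#'   in Å²).
#' @export
ensemble_sapsa <- function(ens, config = surface_config(), block_size = 1000L) {
  stopifnot(inherits(ens, "ensemble"))
  if (block_size < 1L) stop("block_size must be >= 1", call. = FALSE)
  nf <- n_frames(ens)
  per_frame <- vapply(seq_len(nf), function(f) {
    conformer_surface(get_frame(ens, f), config)$sapsa
  }, numeric(1))
  new_ensemble_sapsa(per_frame, block_size)
}

# aggregation split out so precomputed per-frame series can be reused
new_ensemble_sapsa <- function(per_frame, block_size) {
  nf <- length(per_frame)
  blk <- rep(seq_len(ceiling(nf / block_size)), each = block_size)[seq_len(nf)]
  structure(list(
    per_frame = per_frame,
    mean = mean(per_frame),
    sd = pop_sd(per_frame),
    block_size = as.integer(block_size),
    block_means = as.numeric(tapply(per_frame, blk, mean)),
    block_sds = as.numeric(tapply(per_frame, blk, pop_sd))
  ), class = "ensemble_sapsa")
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' @export
print.ensemble_sapsa <- function(x, ...) {
  cat(sprintf(
    "ensemble_sapsa: %d frames, mean %.2f +/- %.2f A^2 (frame sd); %d block(s) of %d\n",
    length(x$per_frame), x$mean, x$sd, length(x$block_means), x$block_size))
  invisible(x)
}

#' Block series of an ensemble SAPSA as a data frame
#'
#' One row per block (`block_index`, `mean`, `sd`) — the series behind
#' block-average trajectory plots.
#'
#' @param es An `"ensemble_sapsa"` object.
#' @return `data.frame`.
#' @export
sapsa_block_series <- function(es) {
  stopifnot(inherits(es, "ensemble_sapsa"))
  data.frame(block_index = seq_along(es$block_means),
             mean = es$block_means, sd = es$block_sds)
}
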