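# internal helpers shared across modules

# round to nearest integer, ties away from zero (base round() uses banker's
# rounding; printed percentages like 59 = round(100*73/124) need ties-up)
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

# single-chromosome convenience: pull the Rle for a window, clipped to bounds
.trackSlice <- function(track, chrom, from, to) {
  r <- track@density[[chrom]]
  if (is.null(r)) stop("chromosome '", chrom, "' not in track")
  n <- length(r)
  from <- max(1L, as.integer(from)); to <- min(n, as.integer(to))
  if (from > to) stop("window empty after clipping to chromosome bounds")
  r[from:to]
}

# derive a 32-bit sub-seed from a base seed and a stream label
.subSeed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 2011L + sum(utf8ToInt(stream)) %% 104729L
}

# Post-PH selection rule shared by the generator truth channel and the
# estimator: low at 0 h (at or below the given quantile of detected-gene 0 h
# levels) and elevated at some later PH time (fold change over 0 h + eps)
.postPhRule <- function(mean0, maxPost, detected, lowQuantile, fold, eps) {
  thr <- quantile(mean0[detected], lowQuantile, names = FALSE, na.rm = TRUE)
  detected & (mean0 <= thr) & (maxPost >= fold * (mean0 + eps))
}
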