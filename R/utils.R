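# Small shared helpers.

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# PSNR between two equal-shaped real arrays on a known peak, in dB.
psnr_pair <- function(a, b, peak = 1) {
  stopifnot(all(dim(a) == dim(b)) || length(a) == length(b))
  rms <- sqrt(mean((a - b)^2))
  if (rms == 0) Inf else 20 * log10(peak / rms)
}
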