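# Independent oracles, written as explicit step-by-step procedures so they
# share no code path with the package implementations they check.

# two-stage adaptive linear step-up, spelled out loop by loop
oracle_two_stage_fdr <- function(p, q = 0.05) {
  m <- length(p)
  q1 <- q / (1 + q)
  stepup <- function(pv, level) {
    o <- order(pv)
    k <- 0L
    for (i in m:1) {
      if (pv[o[i]] <= i * level / m) { k <- i; break }
    }
    mask <- rep(FALSE, m)
    if (k > 0) mask[o[seq_len(k)]] <- TRUE
    mask
  }
  r1 <- sum(stepup(p, q1))
  if (r1 == 0) return(rep(FALSE, m))
  if (r1 == m) return(rep(TRUE, m))
  stepup(p, q1 * m / (m - r1))
}

# band power of a signal around f0 via the periodogram
band_power_at <- function(x, fs, f0, half_width = 2) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2 / n
  fr <- (seq_len(n) - 1) * fs / n
  sel <- fr >= f0 - half_width & fr <= f0 + half_width
  sum(sp[sel])
}
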