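# small fixtures shared across test files

# a tiny ADCP configuration for oracle-scale tests
tiny_config <- function(n_bins = 10L, n_samples = 50L, n_beams = 2L,
                        rmax_bins = 4L) {
  adcp_config(n_beams = n_beams, n_bins = n_bins, burst_samples = n_samples,
              rmax_bins = rmax_bins)
}

# a burst with prescribed velocity field (clean correlation/echo)
make_burst <- function(velocity, config) {
  adcp_burst(velocity, config = config)
}

# brute-force structure function: double loop over samples and separations,
# independent of the vectorised implementation
brute_force_dll <- function(burst, config) {
  v <- burst$velocity
  v[burst$qc_mask] <- NA_real_
  step <- config$separation_step
  kmax <- config$rmax_bins
  nb <- config$n_bins
  lapply(seq_len(config$n_beams), function(b) {
    dll <- matrix(NA_real_, nb, kmax)
    for (k in seq_len(kmax)) {
      off <- k * step
      if (off >= nb) break
      for (i in seq_len(nb)) {
        lo <- i - off / 2; hi <- i + off / 2
        if (lo < 1 || hi > nb) next
        acc <- c()
        for (s in seq_len(config$burst_samples)) {
          d <- v[b, hi, s] - v[b, lo, s]
          if (is.finite(d)) acc <- c(acc, d^2)
        }
        if (length(acc) >= 2) dll[i, k] <- mean(acc)
      }
    }
    dll
  })
}
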