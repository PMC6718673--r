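# Independent oracles used to cross-check the package implementations.
# Each one takes a deliberately different computational route from the code
# it checks.

# --- stationary wavelet transform via explicit equivalent filters --------
# Builds the level-j equivalent filters by convolving upsampled Haar
# filters and applies them by direct circular convolution, instead of the
# recursive pyramid the package uses.

oracle_upsample <- function(f, s) {
  out <- numeric((length(f) - 1) * s + 1)
  out[seq(1, length(out), by = s)] <- f
  out
}

oracle_conv <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1)] <- out[i:(i + length(b) - 1)] + a[i] * b
  }
  out
}

oracle_circ_filter <- function(x, f) {
  n <- length(x)
  vapply(seq_len(n), function(t) {
    idx <- ((t - seq_along(f)) %% n) + 1
    sum(f * x[idx])
  }, numeric(1))
}

# details (list) and smooth for a Haar stationary transform to `level`
oracle_modwt <- function(x, level) {
  g <- c(1 / 2, 1 / 2)
  h <- c(1 / 2, -1 / 2)
  details <- vector("list", level)
  for (j in seq_len(level)) {
    f <- oracle_upsample(h, 2^(j - 1))
    for (m in rev(seq_len(j - 1))) {
      f <- oracle_conv(oracle_upsample(g, 2^(m - 1)), f)
    }
    details[[j]] <- oracle_circ_filter(x, f)
  }
  f <- oracle_upsample(g, 2^(level - 1))
  for (m in rev(seq_len(level - 1))) {
    f <- oracle_conv(oracle_upsample(g, 2^(m - 1)), f)
  }
  list(details = details, smooth = oracle_circ_filter(x, f))
}

# --- two-sided Fisher p by hypergeometric enumeration --------------------
# P-value = sum of P(X = x) over all tables at the observed margins whose
# probability does not exceed the observed one.
oracle_fisher_two_sided <- function(k, m, K, N) {
  lo <- max(0, m - (N - K))
  hi <- min(m, K)
  support <- lo:hi
  probs <- stats::dhyper(support, K, N - K, m)
  p_obs <- stats::dhyper(k, K, N - K, m)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- Venn region counts by brute-force membership enumeration ------------
oracle_venn <- function(sets) {
  genes <- unique(unlist(sets))
  counts <- list()
  for (g in genes) {
    inset <- names(sets)[vapply(sets, function(s) g %in% s, logical(1))]
    key <- paste(inset, collapse = "&")
    counts[[key]] <- (counts[[key]] %||% 0L) + 1L
  }
  counts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- misc shared fixtures ------------------------------------------------

noiseless_cfg <- function(amplitudes = c(KCl = 1, GABA = 0.5,
                                         GluGlyNoMg = 0.8, ionomycin = 2),
                          ...) {
  trace_sim_config(noise_sd = 0, duration = 740, neuron_fraction = 1,
                   stimulus_amplitudes = amplitudes, ...)
}

# schedule with a long flat pre-roll: most wavelet detail coefficients are
# exactly zero, so the universal threshold vanishes and denoising is exact
flat_schedule <- function() default_stimulus_schedule(first_onset = 460)
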