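# Independent reference implementations used as oracles. These are kept
# deliberately naive (literal double loops over the defining formulas)
# and must never call into the package's optimized paths.

# O(N^2) brute-force approximate entropy: self-match included, Chebyshev
# template distance, shared comparison range j in 1..N-m for both lengths
apen_bruteforce <- function(x, m, r) {
  N <- length(x)
  M <- N - m
  total <- 0
  for (i in seq_len(M)) {
    cm <- 0L
    cm1 <- 0L
    for (j in seq_len(M)) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        cm <- cm + 1L
        if (abs(x[i + m] - x[j + m]) <= r) cm1 <- cm1 + 1L
      }
    }
    total <- total + log(cm1 / cm)
  }
  -total / M
}

# small ellipse helper for compact studies in unit tests
tiny_roi <- function() make_lv_roi(c(24, 24), c(12, 12), c(5, 7))

tiny_study <- function(preset = "normal", seed = 1, noise = "poisson",
                       total_counts = 1e6) {
  roi <- tiny_roi()
  pm <- preset_phase_image(preset, roi, seed = seed)
  make_gated_study(pm, roi, total_counts = total_counts, noise = noise,
                   seed = seed + 7L, patient_id = paste0("T-", preset))
}
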