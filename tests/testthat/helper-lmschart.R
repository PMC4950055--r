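# Shared test helpers: random-but-reproducible LMS triples and small
# synthetic registers.

# Random valid triples spanning the chart-relevant parameter ranges.
random_triples <- function(n, seed = 1) {
  set.seed(seed)
  lms_triple(
    L = runif(n, -0.5, 1.5),
    M = runif(n, 500, 4000),
    S = runif(n, 0.05, 0.3)
  )
}

triple_at <- function(tri, i) lms_triple(tri$L[i], tri$M[i], tri$S[i])

# A register at 1/10th of the reference counts (~880 records).
small_config <- function(seed, ...) {
  ref <- ds_reference()
  cnt <- ref$counts
  cnt$n <- pmax(1L, round(cnt$n / 10))
  simulation_config(count_table = cnt, seed = seed, ...)
}

# Records that exactly replicate the reference per-week counts (no
# randomness), weight at the median so z-scores are zero.
median_records <- function() {
  ref <- ds_reference()
  cnt <- ref$counts
  idx <- rep(seq_len(nrow(cnt)), cnt$n)
  key <- match(paste(cnt$week, cnt$sex)[idx],
               paste(ref$lms$week, ref$lms$sex))
  data.frame(
    sex = cnt$sex[idx],
    gest_weeks = cnt$week[idx],
    weight_g = ref$lms$M[key],
    year = rep_len(1989:2011, length(idx)),
    outcome = "live_birth",
    karyotype = "free_trisomy_21",
    stringsAsFactors = FALSE
  )
}
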