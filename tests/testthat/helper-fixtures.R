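# shared small fixtures built in code

# survival records with an optional single driving covariate
makeRecords <- function(n, lp = rep(0, n), censor = 0.2, seed = 1) {
  set.seed(seed)
  tEvent <- rexp(n) / exp(lp)
  if (censor > 0) {
    cens <- runif(n, 0, quantile(tEvent, 0.9) * 2)
    event <- as.integer(tEvent <= cens)
    time <- pmin(tEvent, cens)
  } else {
    time <- tEvent; event <- rep(1L, n)
  }
  data.frame(patient_id = sprintf("P%04d", seq_len(n)),
             time = time, event = event)
}

# a deterministic single-blob config
fixedBlobConfig <- function(radius, map = 32L, ...) {
  syntheticCohortConfig(
    n_patients = 1L, map_rows = map, map_cols = map,
    tumor_blobs = list(list(row = map %/% 2L, col = map %/% 2L,
                            radius = as.integer(radius))),
    ...)
}
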