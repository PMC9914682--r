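# small builders shared across tests

toy_meta <- function(n, sample = "s", session = "1A", mode = "A",
                     instrument = "demo") {
  data.frame(sample_id = sample, session_id = session,
             background_mode = mode, replicate_index = seq_len(n),
             instrument_id = instrument)
}

toy_dataset <- function(X, wl = NULL, ...) {
  X <- as.matrix(X)
  if (is.null(wl)) wl <- 1000 + 10 * seq_len(ncol(X))
  suppressWarnings(spectra_dataset(X, wl, toy_meta(nrow(X), ...)))
}

# dataset drawn from the full generative design, small unless asked
sim_small <- function(seed = 42, samples = "sugar_lump", replicates = 15L,
                      noise = noise_model(), sessions = 3L) {
  simulate_dataset(
    design_spec(samples = samples, sessions_per_mode = sessions,
                replicates = replicates, instrument = neospectra_like()),
    noise, seed = seed)
}

random_psd <- function(p, rank = p, seed = 1) {
  set.seed(seed)
  A <- matrix(rnorm(p * rank), p, rank)
  tcrossprod(A)
}
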