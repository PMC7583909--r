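# Shared helpers: everything is generated in code at test time.

# the worked CTD example sequence (20 nt, 5 of each base)
toy_ctd_seq <- "ATACGTACTGCTGACGTAGC"

random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# hand-constructable feature bundle for fusion tests
make_bundle <- function(phase_vals, graph = NULL, id = "x1") {
  structure(list(rna_id = id, kind = "lncRNA", phases = phase_vals,
                 graph = graph),
            class = "feature_bundle")
}

# independent brute-force 2-D histogram: per-point interval membership by
# explicit enumeration over bins (right edge of last bin inclusive)
brute_bin <- function(v, bins) {
  for (b in seq_len(bins)) {
    lo <- (b - 1) / bins; hi <- b / bins
    if (v >= lo && (v < hi || (b == bins && v <= hi))) return(b)
  }
  stop("value outside [0, 1]")
}

brute_channel <- function(vs, bins) {
  H <- matrix(0, bins, bins)
  for (pp in list(c(1, 2), c(1, 3), c(2, 3)))
    for (i in seq_along(vs[[1]])) {
      bx <- brute_bin(vs[[pp[1]]][i], bins)
      by <- brute_bin(vs[[pp[2]]][i], bins)
      H[bx, by] <- H[bx, by] + 1
    }
  H
}

# small corpora / fast settings used across tests
tiny_fixture <- function(seed = 42L, n_lnc = 8L, n_mir = 5L, n_pos = 10L,
                         signal = "seed_complement") {
  generate_fixture(fixture_spec(n_lnc = n_lnc, n_mir = n_mir, n_pos = n_pos,
                                signal = signal, seed = seed))
}

fast_encoder_opts <- list(walk_len = 10L, n_walks = 4L, r2v_epochs = 2L)

fast_cnn <- function(seed = 1L, epochs = 4L) {
  cnn_config(conv_filters = c(4L, 8L), dense_units = 16L, batch_size = 16L,
             epochs = epochs, val_frac = 0, patience = Inf, seed = seed)
}

# fixture-scale settings for the end-to-end evaluations: small enough to run
# many seeds on one CPU, large enough to learn a separable signal (verified
# in the classifier tests)
e2e_cnn <- function(seed) {
  cnn_config(conv_filters = c(8L, 16L), dense_units = 32L, batch_size = 32L,
             epochs = 25L, seed = seed)
}

e2e_cv <- function(fx, seed, ...) {
  suppressWarnings(run_cv(
    fx$lncs, fx$mirs, fx$positives, beta = 1, k = 2L, cnn = e2e_cnn(seed),
    d2v_epochs = 10L,
    encoder = list(walk_len = 20L, r2v_epochs = 5L, d2v_infer_epochs = 15L),
    seed = seed, ...))
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a * a) * sum(b * b))
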