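#' Specification of a synthetic lncRNA-miRNA corpus
#'
#' Desk-scale stand-in for a curated interaction corpus: uniform-composition
#' random sequences with miRNA lengths of 20-25 nt and lncRNA lengths of at
#' least 200 nt, plus a set of positive pairs. With
#' `signal = "seed_complement"` every positive pair carries a learnable cue:
#' the reverse complement of the miRNA seed (positions 2-8) is spliced into
#' its partner lncRNA at a uniformly random offset, so interaction is
#' predictable from sequence alone. `signal = "none"` is the matched null
#' corpus with no association between sequence and label.
#'
#' @param n_lnc,n_mir Numbers of lncRNAs and miRNAs (defaults 50 and 20).
#' @param lnc_len Length range of lncRNAs, min >= 200 (default `c(200, 300)`).
#' @param mir_len Length range of miRNAs within 20-25 (default `c(20, 25)`).
#' @param n_pos Number of positive pairs (default 100).
#' @param signal `"seed_complement"` or `"none"`.
#' @param seed Integer seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_lnc = 50L, n_mir = 20L, lnc_len = c(200L, 300L),
                         mir_len = c(20L, 25L), n_pos = 100L,
                         signal = c("seed_complement", "none"), seed = 1L) {
  signal <- match.arg(signal)
  if (lnc_len[1] < 200L) stop_input("lncRNAs are defined as > 200 nt; min length %d too short", lnc_len[1])
  if (mir_len[1] < 20L || mir_len[2] > 25L)
    stop_input("miRNA lengths must lie within 20-25 nt")
  if (n_pos > n_lnc * n_mir)
    stop_input("n_pos = %d exceeds the %d possible pairs", n_pos, n_lnc * n_mir)
  structure(list(n_lnc = as.integer(n_lnc), n_mir = as.integer(n_mir),
                 lnc_len = as.integer(lnc_len), mir_len = as.integer(mir_len),
                 n_pos = as.integer(n_pos), signal = signal,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Reverse complement of a DNA-alphabet sequence
#'
#' @param seq Canonical A/C/G/T sequence.
#' @return Reverse-complemented sequence.
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Generate a synthetic corpus
#'
#' Draws i.i.d. uniform A/C/G/T sequences at the lengths in the spec, samples
#' `n_pos` distinct positive pairs uniformly, and (for
#' `signal = "seed_complement"`) overwrites a random 7-nt window of each
#' positive pair's lncRNA with the reverse complement of the partner miRNA's
#' seed. A lncRNA with several positive partners receives one planted motif
#' per partner, at non-overlapping offsets so no plant destroys an earlier
#' one. Deterministic per seed.
#'
#' @param spec A [fixture_spec()].
#' @return List with `lncs` and `mirs` record data frames and `positives`
#'   (pair data frame with `label = 1`, `source = "curated"`).
#' @export
generate_fixture <- function(spec) {
  if (!inherits(spec, "fixture_spec")) stop_input("not a fixture_spec")
  with_seed(spec$seed, {
    lnc_seqs <- vapply(seq_len(spec$n_lnc), function(i)
      random_seq(sample(spec$lnc_len[1]:spec$lnc_len[2], 1L)), character(1))
    mir_seqs <- vapply(seq_len(spec$n_mir), function(i)
      random_seq(sample(spec$mir_len[1]:spec$mir_len[2], 1L)), character(1))
    lnc_ids <- sprintf("lnc%03d", seq_len(spec$n_lnc))
    mir_ids <- sprintf("mir%03d", seq_len(spec$n_mir))

    pair_idx <- sample.int(spec$n_lnc * spec$n_mir, spec$n_pos)
    li <- (pair_idx - 1L) %% spec$n_lnc + 1L
    mi <- (pair_idx - 1L) %/% spec$n_lnc + 1L

    if (spec$signal == "seed_complement") {
      planted <- vector("list", spec$n_lnc)  # occupied windows per lncRNA
      for (p in seq_len(spec$n_pos)) {
        motif <- reverse_complement(substr(mir_seqs[mi[p]], 2L, 8L))
        L <- nchar(lnc_seqs[li[p]])
        # uniform offset, resampled so plants on the same lncRNA never
        # overlap (an overlap would destroy a previously planted motif)
        for (try in 1:200) {
          off <- sample.int(L - 7L + 1L, 1L)
          clash <- any(vapply(planted[[li[p]]], function(w)
            off <= w + 6L && w <= off + 6L, logical(1)))
          if (!clash) break
        }
        planted[[li[p]]] <- c(planted[[li[p]]], off)
        substr(lnc_seqs[li[p]], off, off + 6L) <- motif
      }
    }
    list(lncs = rna_records(lnc_ids, lnc_seqs, "lncRNA"),
         mirs = rna_records(mir_ids, mir_seqs, "miRNA"),
         positives = data.frame(lnc_id = lnc_ids[li], mir_id = mir_ids[mi],
                                label = 1L, source = "curated",
                                stringsAsFactors = FALSE))
  })
}
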