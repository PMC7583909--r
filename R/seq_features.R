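#' Phase sub-sequences of an RNA
#'
#' Decomposes a sequence into the three reading-frame suffixes starting at
#' offsets 0, 1 and 2 (`seq`, `seq[2:]`, `seq[3:]` in 1-based terms). Every
#' feature encoder is applied to each of the three phases, which is what later
#' feeds the per-category histogram fusion.
#'
#' @param seq Canonical A/C/G/T sequence of length >= 3.
#' @return Character vector of the three phase sub-sequences.
#' @examples
#' phase_subsequences("ACGTA")  # "ACGTA" "CGTA" "GTA"
#' @export
phase_subsequences <- function(seq) {
  n <- nchar(seq)
  if (n < 3L) stop_input("sequence must have length >= 3 for phase decomposition (got %d)", n)
  c(seq, substr(seq, 2L, n), substr(seq, 3L, n))
}

#' k-mer spectrum of a sequence
#'
#' Concatenates, over `ks` in ascending order, the frequencies of all 4^k
#' overlapping k-mers (window step 1), each k-block divided by its window
#' count `L - k + 1` so that every block sums to 1. Mer order within a block
#' is lexicographic with A < C < G < T. The conventional choices are
#' `ks = 1:4` for lncRNAs (340 dimensions) and `ks = 1:3` for miRNAs
#' (84 dimensions), where 4-mers are dropped because they are sparse on
#' 20-25 nt sequences; see [kmer_ks()].
#'
#' @param seq Canonical A/C/G/T sequence.
#' @param ks Integer vector of k values; `seq` must be at least `max(ks)` long.
#' @return Named numeric vector of length `sum(4^ks)`.
#' @export
kmer_vector <- function(seq, ks) {
  ks <- sort(unique(as.integer(ks)))
  if (any(ks < 1L)) stop_input("k values must be >= 1")
  L <- nchar(seq)
  if (L < max(ks))
    stop_input("sequence length %d is shorter than k = %d", L, max(ks))
  dna <- Biostrings::DNAString(seq)
  blocks <- lapply(ks, function(k) {
    counts <- Biostrings::oligonucleotideFrequency(dna, width = k)
    freq <- counts / (L - k + 1L)
    names(freq) <- paste0("k", k, "_", names(counts))
    freq
  })
  unlist(blocks)
}

#' Default k-mer sizes per RNA kind
#'
#' @param kind `"lncRNA"` (k = 1..4, 340 dims) or `"miRNA"` (k = 1..3, 84 dims).
#' @return Integer vector of k values.
#' @export
kmer_ks <- function(kind = c("lncRNA", "miRNA")) {
  switch(match.arg(kind), lncRNA = 1:4, miRNA = 1:3)
}

CTD_BASES <- c("A", "T", "G", "C")
CTD_PAIRS <- c("AT", "AC", "AG", "TG", "TC", "GC")

#' Composition/Transition/Distribution (CTD) descriptor
#'
#' Computes the 30-dimensional global sequence descriptor:
#' \itemize{
#'   \item Composition (4): `count(x)/L` for x in A, T, G, C.
#'   \item Transition (6): for the unordered pairs AT, AC, AG, TG, TC, GC, the
#'     number of adjacent positions whose two nucleotides form that pair in
#'     either orientation, divided by `L - 1`.
#'   \item Distribution (20): for each of A, T, G, C with `n` occurrences, the
#'     1-based positions of the occurrence ranks `1`, `ceiling(0.25 n)`,
#'     `ceiling(0.5 n)`, `ceiling(0.75 n)`, `n`, each divided by `L`. A
#'     nucleotide absent from the sequence contributes five zeros.
#' }
#'
#' @param seq Canonical A/C/G/T sequence of length >= 2.
#' @return Named numeric vector of length 30, components in `[0, 1]`.
#' @examples
#' v <- ctd_vector("ATACGTACTGCTGACGTAGC")
#' v[["comp_A"]]       # 0.25
#' v[["trans_AC"]]     # 3/19
#' v[["dist_A_50"]]    # 7/20
#' @export
ctd_vector <- function(seq) {
  L <- nchar(seq)
  if (L < 2L) stop_input("CTD requires length >= 2 (transition undefined), got %d", L)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (any(!chars %in% CTD_BASES)) {
    bad <- which(!chars %in% CTD_BASES)[1]
    stop_input("invalid character '%s' at position %d", chars[bad], bad)
  }

  comp <- vapply(CTD_BASES, function(x) sum(chars == x) / L, numeric(1))
  names(comp) <- paste0("comp_", CTD_BASES)

  adj <- paste0(chars[-L], chars[-1])
  trans <- vapply(CTD_PAIRS, function(p) {
    a <- substr(p, 1, 1); b <- substr(p, 2, 2)
    sum(adj == paste0(a, b) | adj == paste0(b, a)) / (L - 1L)
  }, numeric(1))
  names(trans) <- paste0("trans_", CTD_PAIRS)

  quart <- c(0, 0.25, 0.5, 0.75, 1)
  dist <- unlist(lapply(CTD_BASES, function(x) {
    pos <- which(chars == x)
    n <- length(pos)
    vals <- if (n == 0L) rep(0, 5) else {
      ranks <- pmax(1L, ceiling(quart * n))  # rank 1 forced at the 0% point
      pos[ranks] / L
    }
    names(vals) <- paste0("dist_", x, "_", c("0", "25", "50", "75", "100"))
    vals
  }))

  c(comp, trans, dist)
}

#' Tokenize a sequence into overlapping k-mer words
#'
#' Segments the sequence with a sliding window of width `k` and step 1,
#' yielding `L - k + 1` tokens in order. Used to turn an RNA into a
#' "document" for the PV-DM embedder.
#'
#' @param seq Canonical A/C/G/T sequence with `nchar(seq) >= k`.
#' @param k Window width (default 3).
#' @return Character vector of tokens.
#' @examples
#' tokenize_kmers("ACGTA")  # "ACG" "CGT" "GTA"
#' @export
tokenize_kmers <- function(seq, k = 3L) {
  L <- nchar(seq)
  if (L < k) stop_input("sequence length %d is shorter than token width %d", L, k)
  substring(seq, 1:(L - k + 1L), k:L)
}
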