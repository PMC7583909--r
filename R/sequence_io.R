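#' Canonicalize a nucleotide sequence
#'
#' Uppercases the sequence and maps uracil (U) to thymine (T), so both RNA and
#' DNA alphabets collapse onto \{A, C, G, T\}. Any other letter (including
#' IUPAC ambiguity codes such as N, R, Y) is rejected: every downstream encoder
#' assumes a strict 4-letter alphabet.
#'
#' @param seq Character scalar, nucleotide sequence.
#' @param id Optional identifier used in error messages.
#' @return Canonicalized sequence (character scalar over A/C/G/T).
#' @examples
#' canonicalize_seq("ugaGGuag")  # "TGAGGTAG"
#' @export
canonicalize_seq <- function(seq, id = NULL) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop_input("sequence must be a single character string")
  s <- chartr("u", "T", toupper(seq))
  s <- chartr("U", "T", s)
  bad <- regexpr("[^ACGT]", s)
  if (bad > 0L) {
    stop_input(
      "invalid character '%s' at position %d%s: only A, C, G, T/U are allowed",
      substr(s, bad, bad), bad,
      if (is.null(id)) "" else sprintf(" in sequence '%s'", id)
    )
  }
  if (nchar(s) < 1L) stop_input("empty sequence%s",
                                if (is.null(id)) "" else sprintf(" for '%s'", id))
  s
}

#' Read RNA sequences from a FASTA file
#'
#' Parses a FASTA file into a data frame of records of one RNA kind. Sequences
#' are canonicalized with [canonicalize_seq()] (uppercase, U mapped to T) and
#' the record identifier is the first whitespace-delimited token of the header,
#' matching common GENCODE/miRBase header practice. miRNA records longer than
#' 30 nt are flagged (column `flagged`), not rejected.
#'
#' @param path Path to a FASTA file.
#' @param kind `"lncRNA"` or `"miRNA"`.
#' @return A data frame with columns `id`, `seq`, `kind`, `flagged`; input
#'   order is preserved.
#' @export
read_rna_fasta <- function(path, kind = c("lncRNA", "miRNA")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_input("FASTA file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) stop_input("empty FASTA file: %s", path)
  if (!startsWith(trimws(lines[nonempty[1]]), ">"))
    stop_input("malformed FASTA (%s): line %d does not start with '>'",
               path, nonempty[1])
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop_input("empty FASTA file: %s", path)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop_input("duplicate FASTA id(s): %s", paste(unique(dup), collapse = ", "))
  seqs <- as.character(set)
  seqs <- mapply(canonicalize_seq, seqs, ids, USE.NAMES = FALSE)
  rna_records(ids, seqs, kind)
}

#' Build a record table from ids and sequences
#'
#' @param ids Character vector of identifiers.
#' @param seqs Character vector of canonical A/C/G/T sequences.
#' @param kind `"lncRNA"` or `"miRNA"`.
#' @return Data frame with columns `id`, `seq`, `kind`, `flagged`.
#' @export
rna_records <- function(ids, seqs, kind = c("lncRNA", "miRNA")) {
  kind <- match.arg(kind)
  stopifnot(length(ids) == length(seqs))
  seqs <- mapply(canonicalize_seq, seqs, ids, USE.NAMES = FALSE)
  flagged <- kind == "miRNA" & nchar(seqs) > 30L
  if (any(flagged))
    warning(sprintf("%d miRNA record(s) longer than 30 nt flagged: %s",
                    sum(flagged), paste(ids[flagged], collapse = ", ")),
            call. = FALSE)
  data.frame(id = as.character(ids), seq = seqs, kind = kind,
             flagged = flagged, stringsAsFactors = FALSE)
}

#' Write records back to FASTA
#'
#' @param records Record data frame from [read_rna_fasta()] / [rna_records()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rna_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a table of known interacting pairs
#'
#' Reads a tab-separated table with two columns (`lnc_id`, `mir_id`), one pair
#' per line, and resolves every identifier against the loaded record tables.
#' An optional header line is auto-detected: if the first row resolves against
#' neither record set it is treated as a header. Duplicate pairs are collapsed
#' and the number removed is reported via a message.
#'
#' @param path Path to the TSV file.
#' @param lncs lncRNA record data frame.
#' @param mirs miRNA record data frame.
#' @return Data frame with columns `lnc_id`, `mir_id`, `label` (1), `source`
#'   (`"curated"`).
#' @export
read_pair_table <- function(path, lncs, mirs) {
  if (!file.exists(path)) stop_input("pair table not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop_input("empty pair table: %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L))
    stop_input("pair table line %d has %d column(s), expected 2 (lnc_id TAB mir_id)",
               which(nf < 2L)[1], nf[nf < 2L][1])
  lnc_id <- vapply(fields, `[`, character(1), 1L)
  mir_id <- vapply(fields, `[`, character(1), 2L)
  # header detection: first row resolving against neither record set
  if (length(lnc_id) >= 1L &&
      !(lnc_id[1] %in% lncs$id) && !(mir_id[1] %in% mirs$id)) {
    lnc_id <- lnc_id[-1]; mir_id <- mir_id[-1]
    if (length(lnc_id) == 0L) stop_input("pair table %s contains only a header", path)
  }
  unknown_l <- setdiff(lnc_id, lncs$id)
  if (length(unknown_l) > 0L) stop_input("unknown lncRNA id %s", unknown_l[1])
  unknown_m <- setdiff(mir_id, mirs$id)
  if (length(unknown_m) > 0L) stop_input("unknown miRNA id %s", unknown_m[1])
  key <- paste(lnc_id, mir_id, sep = "\r")
  dups <- duplicated(key)
  if (any(dups))
    message(sprintf("collapsed %d duplicate pair(s)", sum(dups)))
  data.frame(lnc_id = lnc_id[!dups], mir_id = mir_id[!dups],
             label = 1L, source = "curated", stringsAsFactors = FALSE)
}

#' Write a pair dataset to TSV
#'
#' Writes pairs with whatever of the columns `lnc_id`, `mir_id`, `label`,
#' `source`, `fold` are present, with a header line.
#'
#' @param pairs Pair data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_table <- function(pairs, path) {
  cols <- intersect(c("lnc_id", "mir_id", "label", "source", "fold"),
                    names(pairs))
  utils::write.table(pairs[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
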