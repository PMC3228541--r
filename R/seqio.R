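#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

DNA_CHARS <- c("A", "C", "G", "T", "N")
PROTEIN_CHARS <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V", "X"
)

alphabet_chars <- function(alphabet) {
  switch(alphabet,
    dna = DNA_CHARS,
    protein = PROTEIN_CHARS,
    abort(sprintf("unknown alphabet '%s' (use 'dna' or 'protein')", alphabet))
  )
}

#' Construct a sequence-record tibble
#'
#' The package's canonical in-memory representation of a multi-FASTA file:
#' one row per sequence with columns `id` (header token up to the first
#' whitespace), `desc` (full header line), `seq` (uppercased residues) and
#' `alphabet` (`"dna"` or `"protein"`).
#'
#' @param id character vector of non-empty identifiers.
#' @param seq character vector of sequences (case-insensitive on input).
#' @param alphabet `"dna"` (residues ACGTN) or `"protein"` (20 amino acids
#'   plus X).
#' @param desc optional full header lines; defaults to `id`.
#' @return A tibble of class `seq_records`.
#' @export
seq_records <- function(id, seq, alphabet = c("dna", "protein"), desc = id) {
  alphabet <- match.arg(alphabet)
  records <- tibble(
    id = as.character(id),
    desc = as.character(desc),
    seq = toupper(as.character(seq)),
    alphabet = alphabet
  )
  validate_records(records)
  class(records) <- c("seq_records", class(records))
  records
}

#' Validate a sequence-record tibble
#'
#' Checks the `seq_records` invariants: non-empty ids and sequences drawn
#' entirely from the declared alphabet. Called by every reader/constructor so
#' malformed input fails with the offending record named.
#'
#' @param records a tibble with columns `id`, `seq`, `alphabet`.
#' @return `records`, invisibly, if valid.
#' @export
validate_records <- function(records) {
  stopifnot(all(c("id", "seq", "alphabet") %in% names(records)))
  if (any(!nzchar(records$id))) {
    abort(sprintf("record %d has an empty id", which(!nzchar(records$id))[1]))
  }
  for (alpha in unique(records$alphabet)) {
    chars <- alphabet_chars(alpha)
    idx <- which(records$alphabet == alpha)
    bad <- grepl(sprintf("[^%s]", paste(chars, collapse = "")), records$seq[idx])
    if (any(bad)) {
      i <- idx[which(bad)[1]]
      abort(sprintf(
        "record '%s' contains residues outside the %s alphabet", records$id[i], alpha
      ))
    }
  }
  invisible(records)
}

#' Read a multi-FASTA file
#'
#' Reads with maximal tolerance (multi-line bodies, CRLF line endings) and
#' validates every record against the declared alphabet. Only FASTA is
#' supported; FASTQ/SFF/QUAL inputs are rejected with a clear message.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"dna"` or `"protein"`.
#' @return a `seq_records` tibble in file order.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) abort(sprintf("empty file: %s", path))
  if (startsWith(first, "@")) {
    abort(sprintf("%s looks like FASTQ; only FASTA input is supported", path))
  }
  if (!startsWith(first, ">")) {
    abort(sprintf("%s is not FASTA: first line does not start with '>'", path))
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(sprintf("no records in %s", path))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  seq_records(
    id = ids, seq = as.character(set), alphabet = alphabet, desc = headers
  )
}

#' Write records to a canonical FASTA file
#'
#' Deterministic output: LF line endings, bodies wrapped at `wrap` columns.
#' Headers are the stored `desc` so `read_fasta(write_fasta(x))` preserves
#' ids, descriptions, order and sequences exactly.
#'
#' @param records a `seq_records` tibble.
#' @param path output path.
#' @param wrap line width for sequence bodies (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, wrap = 60L) {
  validate_records(records)
  if (nrow(records) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- records$desc
  Biostrings::writeXStringSet(set, path, width = as.integer(wrap))
  invisible(path)
}

#' Generate a synthetic multi-FASTA record set
#'
#' Pure function of its arguments: the same specification (including seed)
#' yields byte-identical records. Lengths are uniform on
#' `[min_len, max_len]`; residues are uniform draws over the unambiguous
#' alphabet (no N/X, so profiles of synthetic data are N-free by
#' construction).
#'
#' @param n_records number of records (>= 0).
#' @param min_len,max_len inclusive uniform length bounds in residues.
#' @param alphabet `"dna"` or `"protein"`.
#' @param seed integer seed.
#' @param prefix id prefix; ids are `<prefix>_<index>`.
#' @return a `seq_records` tibble.
#' @export
generate_synthetic <- function(n_records, min_len = 100L, max_len = 500L,
                               alphabet = c("dna", "protein"), seed = 1L,
                               prefix = "synth") {
  alphabet <- match.arg(alphabet)
  if (n_records < 0) abort("n_records must be >= 0")
  if (min_len > max_len || min_len < 1) abort("need 1 <= min_len <= max_len")
  if (n_records == 0L) {
    return(seq_records(character(0), character(0), alphabet))
  }
  chars <- setdiff(alphabet_chars(alphabet), c("N", "X"))
  seqs <- with_seed(as.integer(seed), {
    lens <- sample.int(max_len - min_len + 1L, n_records, replace = TRUE) +
      min_len - 1L
    vapply(
      lens,
      function(l) paste(sample(chars, l, replace = TRUE), collapse = ""),
      character(1)
    )
  })
  seq_records(sprintf("%s_%04d", prefix, seq_len(n_records)), seqs, alphabet)
}

#' Reverse-complement DNA sequences
#'
#' Vectorised involution over the DNA alphabet: A<->T, C<->G, N<->N, order
#' reversed. Length is preserved and `reverse_complement(reverse_complement(s))`
#' is `s`.
#'
#' @param seq character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  seq <- toupper(seq)
  if (any(grepl("[^ACGTN]", seq))) {
    abort("reverse_complement is defined for dna sequences only (ACGTN)")
  }
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(
    strsplit(comp, "", fixed = TRUE),
    function(x) paste(rev(x), collapse = ""),
    character(1)
  )
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
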