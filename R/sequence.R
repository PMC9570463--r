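#' Normalize a raw nucleotide string to the RNA alphabet
#'
#' Uppercases the input and maps thymine to uracil, yielding a validated
#' RNA string over \{A, C, G, U\}. Ambiguity codes (including N) are
#' rejected rather than imputed: no imputation rule is defensible for
#' single-nucleotide site prediction, so windows containing them should be
#' dropped upstream.
#'
#' @param raw a single character string over \{A,C,G,U,T\} (any case).
#' @return a single uppercase RNA character string.
#' @examples
#' normalize_sequence("acgt")  # "ACGU"
#' @export
normalize_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(raw)) {
    stop("`raw` must be a single non-empty character string", call. = FALSE)
  }
  up <- chartr("acgut", "ACGUT", raw)
  up <- chartr("T", "U", up)
  bad <- regexpr("[^ACGU]", up)
  if (bad > 0L) {
    stop(sprintf("invalid nucleotide '%s' at position %d (alphabet is A/C/G/U/T)",
                 substr(raw, bad, bad), bad), call. = FALSE)
  }
  up
}

# Vectorized normalization for many windows at once.
normalize_sequences <- function(raw) {
  vapply(raw, normalize_sequence, character(1), USE.NAMES = FALSE)
}

#' Reverse complement
#'
#' Complements and reverses a nucleotide string. DNA input (with T) gives a
#' DNA reverse complement; RNA input (with U) gives an RNA one.
#'
#' @param x single character string.
#' @return reverse-complemented string, same case/alphabet conventions.
#' @export
reverse_complement <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  comp <- chartr("ACGTUacgtu", "TGCAAtgcaa", x)
  if (grepl("[Uu]", x)) comp <- chartr("Tt", "Uu", comp)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

seq_to_int <- function(seq) {
  m <- match(strsplit(seq, "", fixed = TRUE)[[1]], RNA_BASES)
  stopifnot(!anyNA(m))
  m
}

# n x L integer matrix for a vector of equal-length normalized windows.
seqs_to_int_matrix <- function(seqs) {
  L <- nchar(seqs[1])
  stopifnot(all(nchar(seqs) == L))
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(seqs), ncol = L, byrow = TRUE)
  m <- match(chars, RNA_BASES)
  stopifnot(!anyNA(m))
  matrix(m, nrow = length(seqs), ncol = L)
}

#' Read sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()]; sequences may use
#' the DNA or RNA alphabet and are normalized (T to U, uppercase) on read.
#'
#' @param path FASTA file path.
#' @return named character vector of normalized RNA sequences.
#' @export
read_fasta_sequences <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
  }
  ss <- Biostrings::readBStringSet(path)
  out <- as.character(ss)
  if (length(out)) out <- normalize_sequences(out)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of RNA sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta_sequences <- function(seqs, path) {
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, filepath = path, width = 80L)
  invisible(path)
}
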