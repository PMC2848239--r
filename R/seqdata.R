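#' DNA alphabet
#'
#' The ordered symbol set over which sequences are encoded. The canonical
#' DNA alphabet is `c("A", "C", "G", "T")`; the index of a symbol is its
#' position in this vector. All model code is generic in the alphabet size
#' `K`, but the defaults throughout the package assume DNA.
#'
#' @param symbols Character vector of unique single-character symbols.
#' @return A character vector of class `"mb_alphabet"`.
#' @export
#' @examples
#' dna_alphabet()
dna_alphabet <- function(symbols = c("A", "C", "G", "T")) {
  symbols <- toupper(as.character(symbols))
  if (anyDuplicated(symbols)) stop("alphabet symbols must be unique")
  if (length(symbols) < 2) stop("alphabet needs at least 2 symbols")
  if (any(nchar(symbols) != 1)) stop("alphabet symbols must be single characters")
  structure(symbols, class = "mb_alphabet")
}

#' Read sequences from a FASTA file
#'
#' Reads a (possibly multi-line) FASTA file into a tibble with one row per
#' record, in file order. Lowercase residues are normalized to uppercase and
#' record ids are taken up to the first whitespace character.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  tibble::tibble(id = ids, seq = toupper(as.character(x, use.names = FALSE)))
}

#' Write sequences to a FASTA file
#'
#' @param seqs Tibble with columns `id` and `seq`.
#' @param path Output path.
#' @param width Line width for sequence wrapping (default 60 columns).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  x <- Biostrings::BStringSet(seqs$seq)
  names(x) <- seqs$id
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Split sequences into consecutive chunks
#'
#' Splits each sequence left to right into non-overlapping pieces of at most
#' `max_len` residues; the final piece of a sequence may be shorter. The
#' total residue count is conserved. Chunking long background sequences into
#' pieces of at most 100 bp mirrors the standard preparation of genomic
#' background sets before window extraction, and the chunk is the unit used
#' by the hold-out split so that overlapping windows never straddle the
#' train/test boundary.
#'
#' @param seqs Tibble with columns `id` and `seq`.
#' @param max_len Maximum chunk length in bp (default 100).
#' @return A tibble with columns `id` (original id plus `/1`, `/2`, ...
#'   suffix when a sequence was split), `source_id`, and `seq`.
#' @export
chunk_sequences <- function(seqs, max_len = 100L) {
  max_len <- as.integer(max_len)
  if (max_len < 1L) stop("max_len must be >= 1")
  n <- nchar(seqs$seq)
  npieces <- pmax(1L, ceiling(n / max_len))
  piece <- sequence(npieces)
  src <- rep.int(seqs$id, npieces)
  starts <- (piece - 1L) * max_len + 1L
  tibble::tibble(
    id = ifelse(rep.int(npieces, npieces) > 1L, paste0(src, "/", piece), src),
    source_id = src,
    seq = substring(rep.int(seqs$seq, npieces), starts,
                    pmin(starts + max_len - 1L, rep.int(n, npieces)))
  )
}

#' Extract fixed-length overlapping windows
#'
#' Enumerates every overlapping window of length `L` on the forward strand
#' of each input sequence, in order. Windows containing symbols outside the
#' alphabet (e.g. `N` or IUPAC ambiguity codes) are discarded and the number
#' discarded is reported as a message. Sequences shorter than `L` contribute
#' no windows.
#'
#' @param seqs Tibble with columns `id` and `seq`.
#' @param L Window length (default 16).
#' @param alphabet An [dna_alphabet()] object.
#' @return A tibble with columns `id` (`<source>:<start>`, 1-based start),
#'   `source_id`, and `seq`.
#' @export
extract_windows <- function(seqs, L = 16L, alphabet = dna_alphabet()) {
  L <- as.integer(L)
  if (L < 1L) stop("L must be >= 1")
  nwin <- pmax(0L, nchar(seqs$seq) - L + 1L)
  starts <- sequence(nwin)
  src <- rep.int(seqs$id, nwin)
  out <- tibble::tibble(
    id = paste0(src, ":", starts),
    source_id = src,
    seq = substring(rep.int(seqs$seq, nwin), starts, starts + L - 1L)
  )
  if (nrow(out) == 0L) return(tibble::tibble(id = character(), source_id = character(), seq = character()))
  ok <- valid_sequences(out$seq, alphabet)
  if (any(!ok)) {
    rlang::inform(paste0("extract_windows: discarded ", sum(!ok),
                         " window(s) containing non-alphabet symbols"))
  }
  out[ok, ]
}

# TRUE for sequences composed only of alphabet symbols
valid_sequences <- function(seq, alphabet = dna_alphabet()) {
  !grepl(paste0("[^", paste(alphabet, collapse = ""), "]"), seq)
}

#' Assemble a labeled training set from foreground and background sequences
#'
#' Foreground sequences (binding sites) must all have length `L` after
#' filtering out those with non-alphabet symbols; background sequences are
#' chunked (at most `chunk_len` bp) and every overlapping window of length
#' `L` is used as a negative example.
#'
#' @param fg Tibble of foreground sequences (columns `id`, `seq`).
#' @param bg Tibble of background sequences (columns `id`, `seq`).
#' @param L Motif length (default 16).
#' @param chunk_len Background chunk length (default 100).
#' @param alphabet An [dna_alphabet()] object.
#' @return A tibble with columns `id`, `seq`, `label` (integer; 1 =
#'   foreground, 0 = background).
#' @export
labeled_data <- function(fg, bg, L = 16L, chunk_len = 100L,
                         alphabet = dna_alphabet()) {
  ok <- valid_sequences(fg$seq, alphabet) & nchar(fg$seq) == L
  if (any(!ok)) {
    rlang::inform(paste0("labeled_data: dropped ", sum(!ok),
                         " foreground sequence(s) (wrong length or non-alphabet symbols)"))
  }
  fg <- fg[ok, c("id", "seq")]
  bgw <- extract_windows(chunk_sequences(bg, chunk_len), L, alphabet)
  dplyr::bind_rows(
    tibble::tibble(id = fg$id, seq = fg$seq, label = 1L),
    tibble::tibble(id = bgw$id, seq = bgw$seq, label = 0L)
  )
}

# Encode equal-length sequences into an N x L integer matrix of
# 1-based alphabet indices. Stops on symbols outside the alphabet.
encode_sequences <- function(seq, alphabet = dna_alphabet()) {
  n <- length(seq)
  if (n == 0L) return(matrix(integer(), 0L, 0L))
  L <- nchar(seq[1])
  if (any(nchar(seq) != L)) stop("sequences must all have equal length")
  idx <- match(strsplit(paste(seq, collapse = ""), "", fixed = TRUE)[[1]],
               unclass(alphabet))
  if (anyNA(idx)) stop("sequence contains symbols outside the alphabet")
  matrix(idx, nrow = n, ncol = L, byrow = TRUE)
}

# Decode an integer matrix back into character sequences.
decode_sequences <- function(X, alphabet = dna_alphabet()) {
  if (nrow(X) == 0L) return(character())
  apply(X, 1L, function(r) paste(unclass(alphabet)[r], collapse = ""))
}
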