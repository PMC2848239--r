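#' Construct a motif PWM with a fixed consensus strength
#'
#' A simple informative motif: position `l` places probability
#' `consensus_prob` on a consensus symbol (cycling through the alphabet)
#' and spreads the remainder uniformly over the other symbols. With the
#' defaults (`L = 16`, consensus probability 0.7 over DNA) the motif
#' carries about 10 bits of information, a realistic figure for a
#' transcription factor binding site.
#'
#' @param L Motif length.
#' @param consensus_prob Probability of the consensus symbol per position.
#' @param alphabet An [dna_alphabet()] object.
#' @return `L x K` probability matrix.
#' @export
motif_pwm <- function(L = 16L, consensus_prob = 0.7,
                      alphabet = dna_alphabet()) {
  K <- length(alphabet)
  if (consensus_prob <= 0 || consensus_prob >= 1) stop("consensus_prob must lie in (0, 1)")
  th <- matrix((1 - consensus_prob) / (K - 1), L, K,
               dimnames = list(NULL, unclass(alphabet)))
  cons <- ((seq_len(L) - 1L) %% K) + 1L
  th[cbind(seq_len(L), cons)] <- consensus_prob
  th
}

#' Sample a PWM with Dirichlet-distributed columns
#'
#' Each position's symbol distribution is drawn independently from a
#' symmetric Dirichlet; small `concentration` gives sharp (informative)
#' columns, large values give near-uniform ones.
#'
#' @param L Motif length.
#' @param concentration Symmetric Dirichlet concentration per symbol.
#' @param seed Optional integer seed.
#' @param alphabet An [dna_alphabet()] object.
#' @return `L x K` probability matrix.
#' @export
random_pwm <- function(L = 16L, concentration = 0.5, seed = NULL,
                       alphabet = dna_alphabet()) {
  if (!is.null(seed)) set.seed(seed)
  K <- length(alphabet)
  g <- matrix(stats::rgamma(L * K, shape = concentration), L, K)
  th <- g / rowSums(g)
  colnames(th) <- unclass(alphabet)
  th
}

#' Sample fixed-length sequences from a PWM
#'
#' Draws `n` independent sequences; the symbol at position `l` is drawn
#' from column `l` of the PWM. Reproducible given `seed`.
#'
#' @param theta `L x K` probability matrix.
#' @param n Number of sequences.
#' @param seed Optional integer seed.
#' @param prefix Id prefix (`<prefix>_1`, ...).
#' @param alphabet An [dna_alphabet()] object.
#' @return Tibble with columns `id`, `seq`.
#' @export
sample_pwm_dataset <- function(theta, n, seed = NULL, prefix = "site",
                               alphabet = dna_alphabet()) {
  if (n < 0) stop("n must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (n == 0L) return(tibble::tibble(id = character(), seq = character()))
  L <- nrow(theta); K <- ncol(theta)
  X <- vapply(seq_len(L),
              function(l) sample.int(K, n, replace = TRUE, prob = theta[l, ]),
              integer(n))
  X <- matrix(X, nrow = n)
  tibble::tibble(id = paste0(prefix, "_", seq_len(n)),
                 seq = decode_sequences(X, alphabet))
}

#' Sample background sequence emitted as chunks
#'
#' Draws `total_bp` i.i.d. symbols from an order-0 background
#' distribution and emits them as consecutive chunks of at most
#' `chunk_len` bp (the last chunk may be shorter), emulating a chunked
#' genomic background set.
#'
#' @param bg_probs Length-`K` symbol distribution (uniform by default).
#' @param total_bp Total number of residues.
#' @param chunk_len Chunk length (default 100).
#' @param seed Optional integer seed.
#' @param prefix Id prefix.
#' @param alphabet An [dna_alphabet()] object.
#' @return Tibble with columns `id`, `source_id`, `seq`.
#' @export
sample_background <- function(bg_probs = NULL, total_bp = 68141L,
                              chunk_len = 100L, seed = NULL, prefix = "bg",
                              alphabet = dna_alphabet()) {
  if (total_bp < 0) stop("total_bp must be >= 0")
  K <- length(alphabet)
  if (is.null(bg_probs)) bg_probs <- rep(1 / K, K)
  if (length(bg_probs) != K) stop("bg_probs must have length K")
  if (!is.null(seed)) set.seed(seed)
  if (total_bp == 0L) {
    return(tibble::tibble(id = character(), source_id = character(),
                          seq = character()))
  }
  x <- sample.int(K, total_bp, replace = TRUE, prob = bg_probs)
  long <- paste(unclass(alphabet)[x], collapse = "")
  chunk_sequences(tibble::tibble(id = prefix, seq = long), chunk_len)
}

#' Generate a synthetic binding-site benchmark
#'
#' Emulates the classical binding-site classification setup: `n_fg`
#' motif instances of length `L` sampled from a foreground PWM, plus a
#' genomic-style background of `bg_total_bp` i.i.d. residues chunked
#' into pieces of at most `chunk_len` bp from which every overlapping
#' `L`-mer serves as a negative example. The default scale (about 100
#' sites against about 68 kb of background) mirrors a typical curated
#' binding-site collection evaluated against a standard exonic
#' background set.
#'
#' @param theta_fg Foreground PWM (`L x K`); defaults to
#'   [motif_pwm()]`(L)`.
#' @param bg_probs Background symbol distribution (uniform by default).
#' @param n_fg Number of foreground sites (default 104).
#' @param bg_total_bp Total background residues (default 68141).
#' @param chunk_len Background chunk length (default 100).
#' @param L Motif length (default 16).
#' @param seed Integer seed (default 1).
#' @param alphabet An [dna_alphabet()] object.
#' @return An object of class `"blend_benchmark"`: a list with `fg`
#'   (site tibble), `bg_chunks` (chunk tibble), `data` (assembled
#'   labeled tibble of sites and background windows), and `truth` (the
#'   generating quantities, for parameter-recovery checks).
#' @export
make_benchmark <- function(theta_fg = NULL, bg_probs = NULL, n_fg = 104L,
                           bg_total_bp = 68141L, chunk_len = 100L, L = 16L,
                           seed = 1L, alphabet = dna_alphabet()) {
  K <- length(alphabet)
  if (is.null(theta_fg)) theta_fg <- motif_pwm(L, alphabet = alphabet)
  if (nrow(theta_fg) != L || ncol(theta_fg) != K) stop("theta_fg must be L x K")
  if (is.null(bg_probs)) bg_probs <- rep(1 / K, K)
  set.seed(seed)
  fg <- sample_pwm_dataset(theta_fg, n_fg, seed = NULL, alphabet = alphabet)
  bg_chunks <- sample_background(bg_probs, bg_total_bp, chunk_len,
                                 seed = NULL, alphabet = alphabet)
  data <- labeled_data(fg, bg_chunks[, c("id", "seq")], L, chunk_len, alphabet)
  structure(
    list(fg = fg, bg_chunks = bg_chunks, data = data,
         truth = list(theta_fg = theta_fg, bg_probs = bg_probs,
                      n_fg = n_fg, bg_total_bp = bg_total_bp,
                      chunk_len = chunk_len, L = L, seed = seed)),
    class = "blend_benchmark"
  )
}

#' @export
print.blend_benchmark <- function(x, ...) {
  cat("<blend_benchmark>", nrow(x$fg), "foreground sites (L =", x$truth$L,
      "),", nrow(x$bg_chunks), "background chunks,",
      sum(x$data$label == 0L), "background windows\n")
  invisible(x)
}
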