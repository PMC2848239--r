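#' Log joint-ratio score of fixed-length sequences
#'
#' `[log P(fg) + log P(x|fg)] - [log P(bg) + log P(x|bg)]`, a monotone
#' transform of the posterior class probability: `P(fg|x) = plogis(score)`.
#' A sequence is called a binding site when the score is strictly positive.
#' Positions at which both classes assign probability zero (possible only
#' at pure maximum-likelihood boundary fits) contribute zero to the score.
#'
#' @param params An `"mb_params"` object or fitted `"blend_fit"`.
#' @param x Character vector of length-`L` sequences.
#' @param alphabet An [dna_alphabet()] object.
#' @return Numeric vector of scores (possibly `-Inf`/`Inf` at boundary
#'   fits).
#' @export
llr_score <- function(params, x, alphabet = dna_alphabet()) {
  params <- as_params(params)
  if (length(x) == 0L) return(numeric())
  if (any(nchar(x) != params$L)) {
    bad <- which(nchar(x) != params$L)[1]
    stop("sequence ", bad, " has length ", nchar(x[bad]),
         " but the model expects L = ", params$L)
  }
  X <- encode_sequences(x, alphabet)
  score_matrix_core(params, linear_index(X, params$L), nrow(X))
}

# scores from precomputed linear indices (shared with the hold-out loop)
score_matrix_core <- function(params, IDX, n) {
  lp_class <- log_softmax(params$z_class)
  d <- log_softmax(params$z_fg) - log_softmax(params$z_bg)
  d[is.nan(d)] <- 0    # both classes impossible at this position/symbol
  (lp_class[2] - lp_class[1]) + rowSums(matrix(d[as.vector(IDX)], n))
}

#' Class decision for fixed-length sequences
#'
#' The maximum-posterior decision: foreground (1) when the score is
#' strictly positive, background (0) otherwise. Ties at score exactly 0
#' go to the background class — the conservative call for a rare-positive
#' detection task.
#'
#' @inheritParams llr_score
#' @return Integer vector of class indices (0 = background, 1 =
#'   foreground).
#' @export
decide <- function(params, x, alphabet = dna_alphabet()) {
  as.integer(llr_score(params, x, alphabet) > 0)
}

#' Score and classify a set of sequences
#'
#' @param params An `"mb_params"` object or fitted `"blend_fit"`.
#' @param seqs Tibble with columns `id` and `seq`.
#' @param alphabet An [dna_alphabet()] object.
#' @return A tibble with columns `id`, `score`, `predicted_class`, in
#'   input order.
#' @export
classify_set <- function(params, seqs, alphabet = dna_alphabet()) {
  params <- as_params(params)
  if (nrow(seqs) == 0L) {
    return(tibble::tibble(id = character(), score = numeric(),
                          predicted_class = integer()))
  }
  bad <- which(nchar(seqs$seq) != params$L)
  if (length(bad) > 0L) {
    stop("sequence '", seqs$id[bad[1]], "' has length ",
         nchar(seqs$seq[bad[1]]), " but the model expects L = ", params$L)
  }
  s <- llr_score(params, seqs$seq, alphabet)
  tibble::tibble(id = seqs$id, score = s, predicted_class = as.integer(s > 0))
}

#' Predict method for fitted blend classifiers
#'
#' @param object A `"blend_fit"` object.
#' @param newdata Tibble with columns `id` and `seq`.
#' @param ... Unused.
#' @return See [classify_set()].
#' @export
predict.blend_fit <- function(object, newdata, ...) {
  classify_set(object, newdata, object$alphabet)
}
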