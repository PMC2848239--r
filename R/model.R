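#' Softmax transform of an unconstrained parameter group
#'
#' Maps a vector of unconstrained reals `z` to a probability vector via
#' normalized exponentials, computed with a max-shift so that `|z|` up to
#' several hundred cannot overflow. Adding a constant to every component of
#' `z` leaves the result unchanged (the gauge direction of the
#' over-parameterized simplex group); `-Inf` components map to probability 0.
#'
#' @param z Numeric vector (or matrix: the transform is applied row-wise).
#' @return Probability vector (or matrix with rows summing to 1).
#' @export
to_probabilities <- function(z) {
  if (is.matrix(z)) return(t(apply(z, 1L, to_probabilities)))
  if (any(is.nan(z)) || any(z == Inf)) stop("non-finite z in simplex group")
  e <- exp(z - max(z))
  e / sum(e)
}

# log-softmax, row-wise for matrices; -Inf entries give log-probability -Inf
log_softmax <- function(z) {
  if (is.matrix(z)) return(t(apply(z, 1L, log_softmax)))
  if (any(is.nan(z)) || any(z == Inf)) stop("non-finite z in simplex group")
  m <- max(z)
  z - (m + log(sum(exp(z - m))))
}

#' Two-class PWM classifier parameters
#'
#' Bundles the full parameter vector of the naive Bayes classifier built
#' from one position weight matrix (PWM) per class plus a class probability
#' group. All groups are stored in the unconstrained normalized-exponential
#' parameterization: a group of `K` reals `z` represents the probability
#' vector `exp(z)/sum(exp(z))`, which numerical optimization can traverse
#' without simplex constraints.
#'
#' @param z_class Length-2 numeric vector (background, foreground).
#' @param z_bg,z_fg `L x K` numeric matrices: row `l` is the unconstrained
#'   group for PWM column `l` of the background / foreground class.
#' @param alphabet An [dna_alphabet()] object.
#' @return An object of class `"mb_params"` with derived probability
#'   accessors available via [class_probs()] and [pwm_probs()].
#' @export
classifier_params <- function(z_class, z_bg, z_fg, alphabet = dna_alphabet()) {
  K <- length(alphabet)
  stopifnot(length(z_class) == 2L, ncol(z_bg) == K, ncol(z_fg) == K,
            nrow(z_bg) == nrow(z_fg))
  structure(
    list(z_class = as.numeric(z_class), z_bg = z_bg, z_fg = z_fg,
         L = nrow(z_fg), K = K, alphabet = alphabet),
    class = "mb_params"
  )
}

#' @export
print.mb_params <- function(x, ...) {
  cat("<mb_params> two-class PWM classifier, L =", x$L, ", K =", x$K, "\n")
  p <- class_probs(x)
  cat("  P(bg) =", signif(p[1], 4), " P(fg) =", signif(p[2], 4), "\n")
  invisible(x)
}

#' Class probabilities of a parameter object
#' @param params An `"mb_params"` object (or a fitted model).
#' @return Named numeric vector `c(bg = , fg = )`.
#' @export
class_probs <- function(params) {
  params <- as_params(params)
  stats::setNames(to_probabilities(params$z_class), c("bg", "fg"))
}

#' PWM probability matrix of one class
#' @param params An `"mb_params"` object (or a fitted model).
#' @param class `"fg"` or `"bg"`.
#' @return `L x K` matrix of per-position symbol probabilities (rows sum to 1).
#' @export
pwm_probs <- function(params, class = c("fg", "bg")) {
  params <- as_params(params)
  class <- match.arg(class)
  z <- if (class == "fg") params$z_fg else params$z_bg
  p <- to_probabilities(z)
  colnames(p) <- unclass(params$alphabet)
  p
}

# Accept either mb_params or a fitted model holding $params
as_params <- function(x) {
  if (inherits(x, "mb_params")) return(x)
  if (!is.null(x$params) && inherits(x$params, "mb_params")) return(x$params)
  stop("expected an 'mb_params' object or a fitted classifier")
}

#' Log-probability of a fixed-length sequence under a PWM
#'
#' Computes `sum_l log theta[l, x_l]`, the log of the product of the
#' per-position symbol probabilities.
#'
#' @param pwm `L x K` matrix of per-position probabilities (rows sum to 1).
#' @param x A character string of length-`L` sequence(s), or an integer
#'   vector of 1-based alphabet indices.
#' @param alphabet An [dna_alphabet()] object (used when `x` is character).
#' @return Numeric vector of log-probabilities, one per input sequence.
#' @export
pwm_log_prob <- function(pwm, x, alphabet = dna_alphabet()) {
  L <- nrow(pwm)
  if (is.character(x)) {
    if (any(nchar(x) != L)) stop("sequence length does not match PWM length")
    X <- encode_sequences(x, alphabet)
  } else {
    X <- matrix(as.integer(x), ncol = L, byrow = TRUE)
  }
  lt <- log(pwm)
  idx <- sweep((X - 1L) * L, 2L, seq_len(L), `+`)
  rowSums(matrix(lt[as.vector(idx)], nrow = nrow(X)))
}

#' Sufficient statistics of a labeled data set
#'
#' Per-class symbol counts per PWM position, the sufficient statistics that
#' the conjugate pseudo-count update combines with the prior. For class `c`,
#' `n[l, a]` counts class-`c` sequences carrying symbol `a` at position `l`;
#' every position's counts sum to the class size `N_c`.
#'
#' @param data Labeled tibble with columns `seq` and `label` (0 = background,
#'   1 = foreground), all sequences of equal length `L`.
#' @param L Expected sequence length; checked against the data.
#' @param alphabet An [dna_alphabet()] object.
#' @return A list of class `"mb_counts"` with elements `n_class` (named
#'   length-2 vector), `n_bg` and `n_fg` (`L x K` matrices), `L`, `K`.
#' @export
sufficient_counts <- function(data, L = NULL, alphabet = dna_alphabet()) {
  K <- length(alphabet)
  if (nrow(data) == 0L) {
    if (is.null(L)) stop("L must be given for an empty data set")
    z <- matrix(0, L, K, dimnames = list(NULL, unclass(alphabet)))
    return(structure(list(n_class = c(bg = 0, fg = 0), n_bg = z, n_fg = z,
                          L = L, K = K), class = "mb_counts"))
  }
  if (is.null(L)) L <- nchar(data$seq[1])
  if (any(nchar(data$seq) != L)) stop("all sequences must have length L = ", L)
  X <- encode_sequences(data$seq, alphabet)
  count_class <- function(rows) {
    if (length(rows) == 0L) return(matrix(0, L, K))
    t(vapply(seq_len(L), function(l) tabulate(X[rows, l], nbins = K),
             numeric(K)))
  }
  fg_rows <- which(data$label == 1L)
  bg_rows <- which(data$label == 0L)
  n_bg <- count_class(bg_rows)
  n_fg <- count_class(fg_rows)
  colnames(n_bg) <- colnames(n_fg) <- unclass(alphabet)
  structure(
    list(n_class = c(bg = length(bg_rows), fg = length(fg_rows)),
         n_bg = n_bg, n_fg = n_fg, L = L, K = K),
    class = "mb_counts"
  )
}

# --- packed parameter vector <-> mb_params -------------------------------
# Layout: [z_class (2), z_bg (L*K, column-major), z_fg (L*K, column-major)]

pack_params <- function(params) {
  c(params$z_class, as.vector(params$z_bg), as.vector(params$z_fg))
}

unpack_params <- function(v, L, K, alphabet = dna_alphabet()) {
  classifier_params(
    z_class = v[1:2],
    z_bg = matrix(v[2L + seq_len(L * K)], L, K),
    z_fg = matrix(v[2L + L * K + seq_len(L * K)], L, K),
    alphabet = alphabet
  )
}
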