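#' Weight vector on the learning-principle simplex
#'
#' The blend objective maximizes
#' `b0 * log P(C|D, lambda) + b1 * log P(C, D|lambda) + b2 * log Q(lambda|alpha)`:
#' a weighted combination of conditional log-likelihood (discriminative
#' term), joint log-likelihood (generative term), and log prior. The three
#' nonnegative weights are renormalized to sum to 1; exact zeros are
#' preserved so that limiting cases stay exact.
#'
#' @param b0,b1,b2 Nonnegative weights for the conditional likelihood,
#'   joint likelihood, and prior.
#' @return A named numeric vector of class `"mb_beta"`.
#' @seealso [beta_for_principle()] for the classical corner cases.
#' @export
beta_weights <- function(b0, b1, b2) {
  b <- c(b0 = b0, b1 = b1, b2 = b2)
  if (any(!is.finite(b)) || any(b < 0)) stop("beta weights must be finite and nonnegative")
  s <- sum(b)
  if (s <= 0) stop("beta weights must not all be zero")
  structure(b / s, class = "mb_beta")
}

#' @export
print.mb_beta <- function(x, ...) {
  cat(sprintf("<mb_beta> (b0 = %g, b1 = %g, b2 = %g)\n", x[1], x[2], x[3]))
  invisible(x)
}

#' Weight vectors of the classical learning principles
#'
#' Maps a learning-principle name to its point on the weight simplex:
#' maximum likelihood `ML = (0, 1, 0)`, maximum a posteriori
#' `MAP = (0, 0.5, 0.5)`, maximum conditional likelihood `MCL = (1, 0, 0)`,
#' and maximum supervised posterior `MSP = (0.5, 0, 0.5)`. The two hybrid
#' families are exposed as [gdt_beta()] (prior-free trade-off along
#' `b2 = 0`) and [pgdt_beta()] (penalized trade-off along `b2 = 0.5`).
#'
#' @param name One of `"ML"`, `"MAP"`, `"MCL"`, `"MSP"`.
#' @return A [beta_weights()] vector.
#' @export
beta_for_principle <- function(name) {
  switch(toupper(name),
    ML = beta_weights(0, 1, 0),
    MAP = beta_weights(0, 0.5, 0.5),
    MCL = beta_weights(1, 0, 0),
    MSP = beta_weights(0.5, 0, 0.5),
    stop("unknown learning principle: ", name,
         " (expected ML, MAP, MCL or MSP)")
  )
}

#' @rdname beta_for_principle
#' @param gamma Trade-off weight in `[0, 1]`; `gamma = 1` gives the
#'   generative end (ML, or MAP for the penalized family) and `gamma = 0`
#'   the discriminative end (MCL, or MSP).
#' @export
gdt_beta <- function(gamma) {
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  beta_weights(1 - gamma, gamma, 0)
}

#' @rdname beta_for_principle
#' @export
pgdt_beta <- function(gamma) {
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  beta_weights((1 - gamma) / 2, gamma / 2, 0.5)
}

# --- internal model-data container ---------------------------------------
# md: X (N x L integer matrix), y (0/1 labels), IDX (N x L linear indices
# into an L x K matrix, column-major), per-class sufficient counts.

linear_index <- function(X, L) sweep((X - 1L) * L, 2L, seq_len(L), `+`)

counts_from_matrix <- function(X, y, L, K) {
  count_class <- function(rows) {
    if (length(rows) == 0L) return(matrix(0, L, K))
    t(vapply(seq_len(L), function(l) tabulate(X[rows, l], nbins = K), numeric(K)))
  }
  fg_rows <- which(y == 1L)
  bg_rows <- which(y == 0L)
  structure(
    list(n_class = c(bg = length(bg_rows), fg = length(fg_rows)),
         n_bg = count_class(bg_rows), n_fg = count_class(fg_rows),
         L = L, K = K),
    class = "mb_counts"
  )
}

md_from_matrix <- function(X, y, L, K) {
  cnt <- counts_from_matrix(X, y, L, K)
  list(X = X, y = as.integer(y), IDX = linear_index(X, L), N = nrow(X),
       L = L, K = K, counts = cnt)
}

prep_model_data <- function(data, alphabet = dna_alphabet()) {
  if (nrow(data) == 0L) stop("data set is empty")
  L <- nchar(data$seq[1])
  X <- encode_sequences(data$seq, alphabet)
  md_from_matrix(X, data$label, L, length(alphabet))
}

# per-sequence log P(x | c) for both classes
seq_class_logprobs <- function(params, md) {
  lt_bg <- log_softmax(params$z_bg)
  lt_fg <- log_softmax(params$z_fg)
  list(bg = rowSums(matrix(lt_bg[as.vector(md$IDX)], md$N)),
       fg = rowSums(matrix(lt_fg[as.vector(md$IDX)], md$N)))
}

joint_core <- function(params, counts) {
  param_kernel(params, counts$n_class, counts$n_bg, counts$n_fg)
}

cond_core <- function(params, md) {
  lp_class <- log_softmax(params$z_class)
  lpx <- seq_class_logprobs(params, md)
  t_bg <- lp_class[1] + lpx$bg
  t_fg <- lp_class[2] + lpx$fg
  m <- pmax(t_bg, t_fg)
  lse <- m + log(exp(t_bg - m) + exp(t_fg - m))
  picked <- ifelse(md$y == 1L, t_fg, t_bg)
  sum(picked - lse)
}

obj_core <- function(params, md, beta, hyper) {
  b <- as.numeric(beta)
  v <- 0
  if (b[1] > 0) v <- v + b[1] * cond_core(params, md)
  if (b[2] > 0) v <- v + b[2] * joint_core(params, md$counts)
  if (b[3] > 0) v <- v + b[3] * prior_log_density(params, hyper)
  v
}

# weighted per-position symbol sums: W[l, a] = sum_i coef_i * [X_{i,l} = a]
weighted_counts <- function(coef, IDX, L, K) {
  g <- rowsum(rep(coef, ncol(IDX)), as.vector(IDX))
  W <- numeric(L * K)
  W[as.integer(rownames(g))] <- g
  matrix(W, L, K)
}

grad_core <- function(params, md, beta, hyper) {
  b <- as.numeric(beta)
  L <- md$L; K <- md$K
  w_class <- numeric(2)
  w_bg <- matrix(0, L, K)
  w_fg <- matrix(0, L, K)
  if (b[2] > 0) {
    w_class <- w_class + b[2] * md$counts$n_class
    w_bg <- w_bg + b[2] * md$counts$n_bg
    w_fg <- w_fg + b[2] * md$counts$n_fg
  }
  if (b[3] > 0) {
    w_class <- w_class + b[3] * hyper$alpha_class
    w_bg <- w_bg + b[3] * hyper$alpha_bg
    w_fg <- w_fg + b[3] * hyper$alpha_fg
  }
  p_class <- to_probabilities(params$z_class)
  th_bg <- to_probabilities(params$z_bg)
  th_fg <- to_probabilities(params$z_fg)
  g_class <- w_class - p_class * sum(w_class)
  g_bg <- w_bg - th_bg * rowSums(w_bg)
  g_fg <- w_fg - th_fg * rowSums(w_fg)
  if (b[1] > 0) {
    lp_class <- log(p_class)
    lpx <- seq_class_logprobs(params, md)
    t_bg <- lp_class[1] + lpx$bg
    t_fg <- lp_class[2] + lpx$fg
    post_fg <- stats::plogis(t_fg - t_bg)
    coef <- (md$y == 1L) - post_fg       # d(cond)/d t_fg(i); d/d t_bg = -coef
    cw_fg <- weighted_counts(coef, md$IDX, L, K)  # row sums all equal sum(coef)
    sc <- sum(coef)
    g_class <- g_class + b[1] * c(-sc, sc)  # group weights sum to 0 already
    g_fg <- g_fg + b[1] * (cw_fg - th_fg * sc)
    g_bg <- g_bg + b[1] * (-cw_fg + th_bg * sc)
  }
  c(g_class, as.vector(g_bg), as.vector(g_fg))
}

#' Joint log-likelihood of a labeled data set
#'
#' `sum_i [log P(c_i | lambda) + log P(x_i | c_i, lambda)]`, the generative
#' term of the blend objective.
#'
#' @param params An `"mb_params"` object (or fitted model).
#' @param data Labeled tibble with columns `seq` and `label`.
#' @param alphabet An [dna_alphabet()] object.
#' @return A single number (may be `-Inf` at boundary parameters).
#' @export
joint_log_likelihood <- function(params, data, alphabet = dna_alphabet()) {
  params <- as_params(params)
  cnt <- sufficient_counts(data, params$L, alphabet)
  joint_core(params, cnt)
}

#' Conditional log-likelihood of the labels given the sequences
#'
#' `sum_i log P(c_i | x_i, lambda)`, the discriminative term of the blend
#' objective, evaluated in log space with log-sum-exp over the two classes.
#'
#' @inheritParams joint_log_likelihood
#' @return A single number.
#' @export
conditional_log_likelihood <- function(params, data, alphabet = dna_alphabet()) {
  params <- as_params(params)
  md <- prep_model_data(data, alphabet)
  if (md$L != params$L) stop("sequence length does not match model L")
  cond_core(params, md)
}

#' The blended training objective
#'
#' `b0 * conditional + b1 * joint + b2 * log prior`, the single objective
#' whose corners and edges reproduce the classical learning principles
#' (see [beta_for_principle()]).
#'
#' @inheritParams joint_log_likelihood
#' @param beta A [beta_weights()] vector.
#' @param hyper An `"mb_hyper"` prior (required when `b2 > 0`).
#' @return A single number.
#' @export
unified_objective <- function(params, data, beta, hyper = NULL,
                              alphabet = dna_alphabet()) {
  params <- as_params(params)
  if (beta[[3]] > 0 && is.null(hyper)) stop("hyper is required when b2 > 0")
  md <- prep_model_data(data, alphabet)
  if (md$L != params$L) stop("sequence length does not match model L")
  obj_core(params, md, beta, hyper)
}

#' Analytic gradient of the blend objective
#'
#' Gradient with respect to the full unconstrained parameter vector, in the
#' packed layout `c(z_class, z_bg, z_fg)` (matrices column-major). Because
#' the softmax parameterization is over-parameterized, the components of
#' every group sum to zero (the gauge direction).
#'
#' @inheritParams unified_objective
#' @return Numeric vector of length `2 + 2 * L * K`.
#' @export
objective_gradient <- function(params, data, beta, hyper = NULL,
                               alphabet = dna_alphabet()) {
  params <- as_params(params)
  if (beta[[3]] > 0 && is.null(hyper)) stop("hyper is required when b2 > 0")
  md <- prep_model_data(data, alphabet)
  if (md$L != params$L) stop("sequence length does not match model L")
  grad_core(params, md, beta, hyper)
}

#' Closed-form estimator on the generative edge of the simplex
#'
#' For `b0 = 0` the objective decouples over simplex groups and its exact
#' maximizer is the weighted pseudo-count estimator
#' `theta_a = (b1 * n_a + b2 * alpha_a) / (b1 * N + b2 * ESS)` per group
#' (class probabilities use the class sizes analogously). `b1 = 1` gives
#' relative frequencies (maximum likelihood), `b1 = b2` the classical
#' posterior-mean pseudo-count estimator (maximum a posteriori).
#'
#' @param counts An `"mb_counts"` object from [sufficient_counts()].
#' @param beta A [beta_weights()] vector with `b0 = 0`.
#' @param hyper An `"mb_hyper"` prior (required when `b2 > 0`).
#' @param alphabet An [dna_alphabet()] object.
#' @return An `"mb_params"` object at the exact optimum.
#' @export
closed_form_generative <- function(counts, beta, hyper = NULL,
                                   alphabet = dna_alphabet()) {
  b <- as.numeric(beta)
  if (b[1] != 0) stop("closed form requires b0 = 0 (no conditional-likelihood term)")
  if (b[3] > 0 && is.null(hyper)) stop("hyper is required when b2 > 0")
  if (is.null(hyper)) {
    # b2 = 0: the prior never enters; zero pseudo-counts keep the algebra uniform
    hyper <- list(alpha_class = c(bg = 0, fg = 0),
                  alpha_bg = matrix(0, counts$L, counts$K),
                  alpha_fg = matrix(0, counts$L, counts$K))
  }
  blend_theta <- function(n, a) {
    w <- b[2] * n + b[3] * a
    w / sum(w)
  }
  blend_rows <- function(n, a) {
    w <- b[2] * n + b[3] * a
    w / rowSums(w)
  }
  classifier_params(
    z_class = log(blend_theta(counts$n_class, hyper$alpha_class)),
    z_bg = log(blend_rows(counts$n_bg, hyper$alpha_bg)),
    z_fg = log(blend_rows(counts$n_fg, hyper$alpha_fg)),
    alphabet = alphabet
  )
}

#' Canonical penalized trade-off form of a simplex point
#'
#' Every weight vector with `b0 + b1 > 0` is, after dividing by
#' `b0 + b1`, a penalized generative-discriminative trade-off with
#' trade-off weight `gamma = b1 / (b0 + b1)` and the prior raised to the
#' power `xi = b2 / (b0 + b1)`: the objective equals
#' `(b0 + b1) * [(1 - gamma) * cond + gamma * joint + xi * log Q]`, so the
#' optima coincide.
#'
#' @param beta A [beta_weights()] vector with `b0 + b1 > 0`.
#' @return Named numeric vector `c(gamma = , xi = )`.
#' @export
#' @examples
#' pgdt_canonical(beta_weights(0.3, 0.2, 0.5))  # gamma 0.4, xi 1
pgdt_canonical <- function(beta) {
  s <- beta[[1]] + beta[[2]]
  if (s <= 0) stop("pure-prior point (b0 + b1 = 0) has no trade-off form")
  c(gamma = beta[[2]] / s, xi = beta[[3]] / s)
}

#' Weighted-posterior hyperparameters of a simplex point
#'
#' The generative and prior terms of the blend objective together form the
#' kernel of a product-Dirichlet with pseudo-counts
#' `alpha~ = b1 * n + b2 * alpha` per group (class group:
#' `b1 * N_c + b2 * ESS_c`). Any simplex point is therefore supervised-
#' posterior estimation under this data-informed prior; the composition is
#' computed for every `beta`, though the probabilistic reading assumes
#' strictly positive weights.
#'
#' @param beta A [beta_weights()] vector.
#' @param counts An `"mb_counts"` object from [sufficient_counts()].
#' @param hyper An `"mb_hyper"` prior.
#' @return An `"mb_hyper"` object with the composed pseudo-counts.
#' @export
effective_posterior_hyperparams <- function(beta, counts, hyper) {
  b <- as.numeric(beta)
  hyper$alpha_class <- b[2] * counts$n_class + b[3] * hyper$alpha_class
  hyper$alpha_bg <- b[2] * counts$n_bg + b[3] * hyper$alpha_bg
  hyper$alpha_fg <- b[2] * counts$n_fg + b[3] * hyper$alpha_fg
  hyper$ess <- b[2] * counts$n_class[c("bg", "fg")] + b[3] * hyper$ess
  hyper
}
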