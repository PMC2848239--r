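#' Dirichlet-type prior hyperparameters from equivalent sample sizes
#'
#' Builds the per-group pseudo-count vectors of the product-Dirichlet prior
#' over all simplex groups of the two-PWM classifier. Each PWM column of
#' class `c` receives the pseudo-count vector `ESS_c * q` with `q` the base
#' distribution (uniform by default, i.e. "uniform pseudo data"), so the
#' column's pseudo-counts sum to the class's equivalent sample size (ESS).
#' The class-probability group receives `(ESS_bg, ESS_fg)`. The defaults
#' (foreground ESS 4, background ESS 1024) reflect the very different
#' amounts of foreground and background data in binding-site classification.
#'
#' @param ess_fg,ess_bg Positive equivalent sample sizes per class.
#' @param L Motif length.
#' @param alphabet An [dna_alphabet()] object.
#' @param q_fg,q_bg Optional base distributions (length-`K` probability
#'   vectors); uniform when `NULL`.
#' @return An object of class `"mb_hyper"` with elements `alpha_class`,
#'   `alpha_bg`, `alpha_fg` (same shapes as the corresponding count
#'   statistics), `ess`, `L`, `K`.
#' @export
hyperparams_from_ess <- function(ess_fg = 4, ess_bg = 1024, L = 16L,
                                 alphabet = dna_alphabet(),
                                 q_fg = NULL, q_bg = NULL) {
  if (ess_fg <= 0 || ess_bg <= 0) stop("ESS values must be positive")
  K <- length(alphabet)
  base <- function(q) {
    if (is.null(q)) return(rep(1 / K, K))
    if (length(q) != K || any(q <= 0)) stop("base distribution must be positive of length K")
    q / sum(q)
  }
  a_fg <- matrix(ess_fg * base(q_fg), L, K, byrow = TRUE,
                 dimnames = list(NULL, unclass(alphabet)))
  a_bg <- matrix(ess_bg * base(q_bg), L, K, byrow = TRUE,
                 dimnames = list(NULL, unclass(alphabet)))
  structure(
    list(alpha_class = c(bg = ess_bg, fg = ess_fg),
         alpha_bg = a_bg, alpha_fg = a_fg,
         ess = c(bg = ess_bg, fg = ess_fg), L = L, K = K),
    class = "mb_hyper"
  )
}

#' @export
print.mb_hyper <- function(x, ...) {
  cat("<mb_hyper> product-Dirichlet prior, L =", x$L, ", K =", x$K,
      "; ESS fg =", x$ess["fg"], ", bg =", x$ess["bg"], "\n")
  invisible(x)
}

# Sum over all groups of sum_a w_a * log theta_a, for any set of
# nonnegative per-group weight vectors shaped like the hyperparameters or
# the sufficient counts. This unnormalized "kernel" is shared by the joint
# likelihood (weights = counts) and the prior (weights = alpha).
param_kernel <- function(params, w_class, w_bg, w_fg) {
  lp_class <- log_softmax(params$z_class)
  lt_bg <- log_softmax(params$z_bg)
  lt_fg <- log_softmax(params$z_fg)
  dot0 <- function(w, lt) {       # with the 0 * -Inf = 0 convention
    s <- w * lt
    sum(s[w != 0])
  }
  dot0(w_class, lp_class) + dot0(w_bg, lt_bg) + dot0(w_fg, lt_fg)
}

# log normalizer of one prior group with pseudo-count vector alpha:
# the multivariate Beta function evaluated at (alpha + 1), matching the
# transformed density on unconstrained parameters whose kernel exponent is
# alpha (not alpha - 1).
log_group_normalizer <- function(alpha) {
  sum(lgamma(alpha + 1)) - lgamma(sum(alpha) + length(alpha))
}

hyper_log_normalizer <- function(hyper) {
  log_group_normalizer(hyper$alpha_class) +
    sum(apply(hyper$alpha_bg, 1L, log_group_normalizer)) +
    sum(apply(hyper$alpha_fg, 1L, log_group_normalizer))
}

#' Log density of the transformed Dirichlet prior
#'
#' Evaluates the prior on the unconstrained parameterization: per group the
#' term `sum_a alpha_a log theta_a - log Z(alpha)` with
#' `Z(alpha) = prod_a Gamma(alpha_a + 1) / Gamma(sum_a alpha_a + K)`.
#' Using kernel exponent `alpha_a` (rather than `alpha_a - 1`) absorbs the
#' change-of-variables correction of the softmax map, so that raising the
#' prior to a power `xi` is exactly the same prior with hyperparameters
#' `xi * alpha` (up to a parameter-independent constant), and the
#' generative closed form becomes the familiar pseudo-count estimator
#' `(n + alpha) / (N + ESS)`.
#'
#' @param params An `"mb_params"` object (or fitted model).
#' @param hyper An `"mb_hyper"` object with matching `L` and `K`.
#' @return The log prior density (`-Inf` when some `theta_a = 0` with
#'   `alpha_a > 0`).
#' @export
prior_log_density <- function(params, hyper) {
  params <- as_params(params)
  stopifnot(params$L == hyper$L, params$K == hyper$K)
  param_kernel(params, hyper$alpha_class, hyper$alpha_bg, hyper$alpha_fg) -
    hyper_log_normalizer(hyper)
}

#' Raise the prior to a power
#'
#' The product-Dirichlet prior is closed under powering: the `xi`-th power
#' of the prior with hyperparameters `alpha` is (up to normalization) the
#' prior with hyperparameters `xi * alpha`, so every group's ESS is scaled
#' by `xi`. This closure is what lets points on the simplex axes be read as
#' MAP or MSP estimation with a re-weighted prior.
#'
#' @param hyper An `"mb_hyper"` object.
#' @param xi Positive scaling factor.
#' @return A new `"mb_hyper"` object with all pseudo-counts scaled by `xi`.
#' @export
power_prior <- function(hyper, xi) {
  if (!is.numeric(xi) || length(xi) != 1L || xi <= 0) stop("xi must be a positive number")
  hyper$alpha_class <- xi * hyper$alpha_class
  hyper$alpha_bg <- xi * hyper$alpha_bg
  hyper$alpha_fg <- xi * hyper$alpha_fg
  hyper$ess <- xi * hyper$ess
  hyper
}

#' Virtual equivalent sample size of an axis point
#'
#' A point on the `b0`-axis of the weight simplex (`b1 = 0`) is maximum
#' supervised posterior estimation with the prior raised to `xi = b2/b0`;
#' a point on the `b1`-axis (`b0 = 0`) is maximum a posteriori estimation
#' with `xi = b2/b1`. The "virtual" ESS of that re-weighted prior is
#' `xi * ess`.
#'
#' @param beta A [beta_weights()] vector.
#' @param ess The original equivalent sample size.
#' @param axis `"b0"` (MSP axis) or `"b1"` (MAP axis).
#' @return The virtual ESS, a single number.
#' @export
#' @examples
#' virtual_ess(beta_weights(0.05, 0, 0.95), 4, "b0")  # 76
virtual_ess <- function(beta, ess, axis = c("b0", "b1")) {
  axis <- match.arg(axis)
  w <- if (axis == "b0") beta[[1]] else beta[[2]]
  if (w == 0) stop("axis weight is zero: virtual ESS undefined on this axis")
  (beta[[3]] / w) * ess
}
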