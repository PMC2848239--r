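#' Train the two-PWM classifier under a blended objective
#'
#' Maximizes the blend objective (see [unified_objective()]) over the full
#' unconstrained parameter vector. On the generative edge of the simplex
#' (`b0 = 0`) the exact optimum is available in closed form (the weighted
#' pseudo-count estimator, [closed_form_generative()]) and is used by
#' default; elsewhere a limited-memory quasi-Newton ascent (L-BFGS-B) is
#' run from a smoothed generative warm start. Training is deterministic
#' given the data, weights, prior, and configuration.
#'
#' @param data Labeled tibble with columns `seq` and `label` (1 =
#'   foreground, 0 = background); both classes must be present and all
#'   sequences must share one length `L`.
#' @param beta A [beta_weights()] vector (default: maximum a posteriori).
#' @param hyper An `"mb_hyper"` prior; built from `ess_fg`/`ess_bg` when
#'   `NULL`.
#' @param ess_fg,ess_bg Per-class equivalent sample sizes used when
#'   `hyper` is `NULL` (defaults 4 and 1024).
#' @param tol Convergence tolerance on the gradient max-norm (default 1e-6).
#' @param max_iter Iteration cap for the quasi-Newton ascent (default 1000).
#' @param init Optional `"mb_params"` starting point. When `NULL`, the
#'   closed form at `(0, max(b1, 1e-3), max(b2, 1e-3))` is used: a smoothed
#'   generative start that is strictly interior even for pure maximum
#'   likelihood.
#' @param method `"auto"` (closed form when `b0 = 0`, numeric otherwise),
#'   `"numeric"`, or `"closed_form"`.
#' @param alphabet An [dna_alphabet()] object.
#' @return An object of class `"blend_fit"`: the fitted parameters plus
#'   `objective_value`, `gradient_norm`, `iterations`, `converged`,
#'   `method`, and the training configuration. Supports [tidy()],
#'   [glance()], [predict()][predict.blend_fit], and [autoplot()].
#' @export
#' @examples
#' bench <- make_benchmark(n_fg = 40, bg_total_bp = 2000, L = 8, seed = 1)
#' fit <- train_classifier(bench$data, beta_for_principle("MAP"), L_ess(8))
#' glance(fit)
train_classifier <- function(data, beta = beta_for_principle("MAP"),
                             hyper = NULL, ess_fg = 4, ess_bg = 1024,
                             tol = 1e-6, max_iter = 1000L, init = NULL,
                             method = c("auto", "numeric", "closed_form"),
                             alphabet = dna_alphabet()) {
  method <- match.arg(method)
  md <- prep_model_data(data, alphabet)
  if (any(md$counts$n_class == 0)) stop("training data must contain both classes")
  if (is.null(hyper)) hyper <- hyperparams_from_ess(ess_fg, ess_bg, md$L, alphabet)
  if (hyper$L != md$L) stop("prior L does not match data L")
  train_core(md, beta, hyper, tol = tol, max_iter = max_iter, init = init,
             method = method, alphabet = alphabet)
}

# Shorthand used in examples/tests: default prior at a given motif length.
#' Default prior at a given motif length
#' @param L Motif length.
#' @param ess_fg,ess_bg Per-class equivalent sample sizes.
#' @return An `"mb_hyper"` object.
#' @export
L_ess <- function(L, ess_fg = 4, ess_bg = 1024) {
  hyperparams_from_ess(ess_fg, ess_bg, L)
}

train_core <- function(md, beta, hyper, tol = 1e-6, max_iter = 1000L,
                       init = NULL, method = "auto",
                       alphabet = dna_alphabet()) {
  b <- as.numeric(beta)
  if (method == "auto") method <- if (b[1] == 0) "closed_form" else "numeric"
  if (method == "closed_form") {
    if (b[1] != 0) stop("closed-form training requires b0 = 0")
    params <- closed_form_generative(md$counts, beta, hyper, alphabet)
    value <- obj_core(params, md, beta, hyper)
    gnorm <- if (all(is.finite(pack_params(params)))) {
      max(abs(grad_core(params, md, beta, hyper)))
    } else NA_real_  # exact boundary optimum (some theta = 0)
    return(new_blend_fit(params, beta, hyper, value, gnorm, 0L, TRUE,
                         "closed_form"))
  }
  if (is.null(init)) {
    eps <- 1e-3
    binit <- beta_weights(0, max(b[2], eps), max(b[3], eps))
    hinit <- if (binit[[3]] > 0 && is.null(hyper)) {
      hyperparams_from_ess(4, 1024, md$L, alphabet)
    } else hyper
    init <- closed_form_generative(md$counts, binit, hinit, alphabet)
  }
  z0 <- pack_params(init)
  fn <- function(z) -obj_core(unpack_params(z, md$L, md$K, alphabet), md, beta, hyper)
  gr <- function(z) -grad_core(unpack_params(z, md$L, md$K, alphabet), md, beta, hyper)
  res <- stats::optim(z0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = max_iter, pgtol = tol,
                                     factr = 1e-9 / .Machine$double.eps))
  params <- unpack_params(res$par, md$L, md$K, alphabet)
  gnorm <- max(abs(grad_core(params, md, beta, hyper)))
  converged <- gnorm <= tol || res$convergence == 0L
  new_blend_fit(params, beta, hyper, -res$value, gnorm,
                as.integer(res$counts[["function"]]), converged, "numeric")
}

new_blend_fit <- function(params, beta, hyper, value, gnorm, iterations,
                          converged, method) {
  structure(
    list(params = params, beta = beta, hyper = hyper,
         objective_value = value, gradient_norm = gnorm,
         iterations = iterations, converged = converged, method = method,
         L = params$L, K = params$K, alphabet = params$alphabet),
    class = "blend_fit"
  )
}

#' @export
print.blend_fit <- function(x, ...) {
  cat("<blend_fit> two-PWM classifier, L =", x$L, "\n")
  cat(sprintf("  beta = (%g, %g, %g), method = %s\n",
              x$beta[1], x$beta[2], x$beta[3], x$method))
  cat(sprintf("  objective = %.6g, grad max-norm = %s, converged = %s\n",
              x$objective_value,
              ifelse(is.na(x$gradient_norm), "NA (boundary)",
                     format(x$gradient_norm, digits = 3)),
              x$converged))
  invisible(x)
}

#' Tidy a fitted classifier into per-position probabilities
#'
#' @param x A `"blend_fit"` object.
#' @param ... Unused.
#' @return A tibble with columns `class` (`"fg"`/`"bg"`), `position`,
#'   `symbol`, `estimate` (the PWM probability).
#' @method tidy blend_fit
#' @export
tidy.blend_fit <- function(x, ...) {
  one <- function(cl) {
    th <- pwm_probs(x, cl)
    tibble::tibble(
      class = cl,
      position = rep(seq_len(nrow(th)), times = ncol(th)),
      symbol = rep(colnames(th), each = nrow(th)),
      estimate = as.vector(th)
    )
  }
  dplyr::arrange(dplyr::bind_rows(one("fg"), one("bg")),
                 .data$class, .data$position, .data$symbol)
}

#' One-row summary of a fitted classifier
#'
#' @param x A `"blend_fit"` object.
#' @param ... Unused.
#' @return A one-row tibble with the weights, objective value, gradient
#'   norm, iteration count, convergence flag, and class probabilities.
#' @method glance blend_fit
#' @export
glance.blend_fit <- function(x, ...) {
  p <- class_probs(x)
  tibble::tibble(
    b0 = x$beta[[1]], b1 = x$beta[[2]], b2 = x$beta[[3]],
    objective = x$objective_value, gradient_norm = x$gradient_norm,
    iterations = x$iterations, converged = x$converged, method = x$method,
    L = x$L, p_fg = p[["fg"]], p_bg = p[["bg"]]
  )
}

#' Serialize a fitted classifier to JSON
#'
#' Writes motif length, per-class probability matrices, class
#' probabilities, prior hyperparameters, and the training weights to a
#' JSON document with 17 significant digits, so that
#' `read_model(write_model(fit))` round-trips the probabilities exactly.
#'
#' @param fit A `"blend_fit"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(fit, path) {
  doc <- list(
    package = "motifblend", format_version = 1L,
    L = fit$L, alphabet = unclass(fit$alphabet),
    beta = as.numeric(fit$beta),
    class_probs = as.numeric(class_probs(fit)),
    theta_fg = unname(pwm_probs(fit, "fg")),
    theta_bg = unname(pwm_probs(fit, "bg")),
    ess = as.numeric(fit$hyper$ess),
    objective_value = fit$objective_value,
    converged = fit$converged, method = fit$method
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a serialized classifier
#'
#' @param path Path to a JSON model written by [write_model()].
#' @return A `"blend_fit"` object (boundary probabilities are restored as
#'   `-Inf` unconstrained parameters).
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  alphabet <- dna_alphabet(doc$alphabet)
  params <- classifier_params(
    z_class = log(doc$class_probs),
    z_bg = log(doc$theta_bg),
    z_fg = log(doc$theta_fg),
    alphabet = alphabet
  )
  hyper <- hyperparams_from_ess(doc$ess[2], doc$ess[1], doc$L, alphabet)
  beta <- beta_weights(doc$beta[1], doc$beta[2], doc$beta[3])
  new_blend_fit(params, beta, hyper, doc$objective_value, NA_real_, 0L,
                isTRUE(doc$converged), doc$method %||% "deserialized")
}
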