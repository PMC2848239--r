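#' Stratified train/test split of a labeled data set
#'
#' Within each class, a uniform random subset of `floor(train_fraction *
#' n_c)` items goes to the training side and the remainder to the test
#' side. The split is reproducible given `seed`.
#'
#' @param data Labeled tibble with a `label` column.
#' @param train_fraction Fraction of each class assigned to training
#'   (default 0.9).
#' @param seed Integer seed.
#' @return A list with tibbles `train` and `test` (disjoint, union =
#'   `data`).
#' @export
stratified_holdout_split <- function(data, train_fraction = 0.9, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1")
  }
  classes <- sort(unique(data$label))
  sizes <- table(data$label)
  if (any(sizes < 2L)) stop("every class needs at least 2 items to split")
  set.seed(seed)
  tr <- unlist(lapply(classes, function(cl) {
    rows <- which(data$label == cl)
    rows[sample.int(length(rows), floor(train_fraction * length(rows)))]
  }))
  list(train = data[sort(tr), ], test = data[-sort(tr), ])
}

# uniform subset of floor(frac * n) indices out of n (shared split rule)
split_train_indices <- function(n, frac) {
  sample.int(n, floor(frac * n))
}

#' Sensitivity at a fixed specificity
#'
#' The score threshold is set from the background (negative) scores: with
#' `m` negatives, at most `k = floor((1 - specificity) * m)` false
#' positives are allowed, so the threshold is the `(k+1)`-th largest
#' negative score (or `-Inf` when `k >= m`), and a sequence is called
#' positive when its score is strictly greater than the threshold. Returns
#' the fraction of foreground (positive) scores called positive.
#'
#' @param pos_scores,neg_scores Nonempty numeric score vectors.
#' @param specificity Target specificity in `(0, 1]` (default 0.999).
#' @return Sensitivity in `[0, 1]`.
#' @export
#' @examples
#' sensitivity_at_specificity(c(999.5, 1000.5), 1:1000, 1.0)    # 0.5
#' sensitivity_at_specificity(c(999.5, 1000.5), 1:1000, 0.999)  # 1.0
sensitivity_at_specificity <- function(pos_scores, neg_scores,
                                       specificity = 0.999) {
  if (length(pos_scores) == 0L || length(neg_scores) == 0L) {
    stop("score vectors must be nonempty")
  }
  if (specificity <= 0 || specificity > 1) stop("specificity must lie in (0, 1]")
  m <- length(neg_scores)
  k <- floor((1 - specificity) * m + 1e-9)
  t <- if (k >= m) -Inf else sort(neg_scores, decreasing = TRUE)[k + 1]
  mean(pos_scores > t)
}

#' Auxiliary performance measures
#'
#' ROC-AUC (the probability that a positive outscores a negative, ties
#' counting one half, computed from ranks), the area under the full
#' precision-recall curve by trapezoid (anchored at recall 0 with
#' precision 1), and the classification rate at the natural threshold 0.
#'
#' @inheritParams sensitivity_at_specificity
#' @return Named list with `roc_auc`, `pr_auc`, `classification_rate`.
#' @export
auxiliary_measures <- function(pos_scores, neg_scores) {
  np <- length(pos_scores); nn <- length(neg_scores)
  if (np == 0L || nn == 0L) stop("score vectors must be nonempty")
  r <- rank(c(pos_scores, neg_scores), ties.method = "average")
  roc_auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)

  sc <- c(pos_scores, neg_scores)
  is_pos <- rep(c(TRUE, FALSE), c(np, nn))
  o <- order(sc, decreasing = TRUE)
  tp <- cumsum(is_pos[o])
  n_called <- seq_along(sc)
  # collapse tied scores: the curve only has a point after each distinct value
  last_of_tie <- c(sc[o][-1] != sc[o][-length(sc)], TRUE)
  recall <- c(0, tp[last_of_tie] / np)
  precision <- c(1, tp[last_of_tie] / n_called[last_of_tie])
  pr_auc <- sum(diff(recall) * (precision[-1] + precision[-length(precision)]) / 2)

  classification_rate <- (sum(pos_scores > 0) + sum(neg_scores <= 0)) / (np + nn)
  list(roc_auc = roc_auc, pr_auc = pr_auc,
       classification_rate = classification_rate)
}

# --- repeated hold-out core ----------------------------------------------

draw_repeat_seeds <- function(seed, repeats) {
  set.seed(seed)
  sample.int(2147483646L, repeats)
}

# Precompute encodings once: foreground sites (rows) and background
# windows grouped by chunk (the split unit for the background class).
prep_holdout_data <- function(fg, bg_chunks, L, alphabet = dna_alphabet()) {
  ok <- valid_sequences(fg$seq, alphabet) & nchar(fg$seq) == L
  if (any(!ok)) {
    rlang::inform(paste0("holdout: dropped ", sum(!ok), " foreground sequence(s)"))
  }
  fg <- fg[ok, ]
  if (nrow(fg) < 2L) stop("need at least 2 usable foreground sequences")
  win <- extract_windows(bg_chunks, L, alphabet)
  if (nrow(win) < 2L) stop("background yields fewer than 2 windows of length L")
  chunk_ids <- unique(win$source_id)
  if (length(chunk_ids) < 2L) stop("need at least 2 background chunks to split")
  fgX <- encode_sequences(fg$seq, alphabet)
  wX <- encode_sequences(win$seq, alphabet)
  list(
    fgX = fgX, fgIDX = linear_index(fgX, L),
    wX = wX, wIDX = linear_index(wX, L),
    chunk_of = match(win$source_id, chunk_ids),
    n_chunks = length(chunk_ids),
    L = L, K = length(alphabet), alphabet = alphabet
  )
}

holdout_one_repeat <- function(hd, beta, hyper, rseed, train_fraction,
                               specificity, tol, max_iter) {
  set.seed(rseed)
  n_fg <- nrow(hd$fgX)
  tr_fg <- split_train_indices(n_fg, train_fraction)
  tr_chunks <- split_train_indices(hd$n_chunks, train_fraction)
  w_train <- hd$chunk_of %in% tr_chunks
  Xtr <- rbind(hd$fgX[tr_fg, , drop = FALSE], hd$wX[w_train, , drop = FALSE])
  y <- rep(c(1L, 0L), c(length(tr_fg), sum(w_train)))
  b <- as.numeric(beta)
  converged <- TRUE
  if (b[1] == 0) {
    cnt <- counts_from_matrix(Xtr, y, hd$L, hd$K)
    params <- closed_form_generative(cnt, beta, hyper, hd$alphabet)
  } else {
    md <- md_from_matrix(Xtr, y, hd$L, hd$K)
    fit <- train_core(md, beta, hyper, tol = tol, max_iter = max_iter,
                      alphabet = hd$alphabet)
    if (!fit$converged) {
      rlang::inform(paste0("holdout repeat (seed ", rseed, "): optimizer did not converge"))
    }
    converged <- fit$converged
    params <- fit$params
  }
  te_fg <- setdiff(seq_len(n_fg), tr_fg)
  w_test <- which(!w_train)
  pos <- score_matrix_core(params, hd$fgIDX[te_fg, , drop = FALSE], length(te_fg))
  neg <- score_matrix_core(params, hd$wIDX[w_test, , drop = FALSE], length(w_test))
  aux <- auxiliary_measures(pos, neg)
  tibble::tibble(
    sensitivity = sensitivity_at_specificity(pos, neg, specificity),
    roc_auc = aux$roc_auc, pr_auc = aux$pr_auc,
    classification_rate = aux$classification_rate,
    n_test_fg = length(te_fg), n_test_bg = length(w_test),
    converged = converged
  )
}

holdout_core <- function(hd, beta, hyper, rseeds, train_fraction,
                         specificity, tol, max_iter) {
  res <- purrr::map(seq_along(rseeds), function(r) {
    holdout_one_repeat(hd, beta, hyper, rseeds[r], train_fraction,
                       specificity, tol, max_iter)
  })
  dplyr::bind_rows(res, .id = NULL) |>
    dplyr::mutate(repeat_id = dplyr::row_number(), seed = rseeds,
                  .before = 1L)
}

summarize_holdout <- function(results) {
  measures <- c("sensitivity", "roc_auc", "pr_auc", "classification_rate")
  purrr::map(measures, function(m) {
    v <- results[[m]]
    tibble::tibble(measure = m, mean = mean(v),
                   se = stats::sd(v) / sqrt(length(v)))
  }) |> dplyr::bind_rows()
}

#' Repeated stratified hold-out evaluation of one simplex point
#'
#' For each repeat: stratified split (foreground sites and background
#' chunks are the split units, so overlapping background windows never
#' straddle the train/test boundary), training on the training side,
#' scoring of the held-out side, and computation of sensitivity at fixed
#' specificity plus the auxiliary measures. Repeats are summarized by
#' mean and standard error (`sd / sqrt(repeats)`). Fully reproducible
#' given `seed`: repeat `r` uses the `r`-th of a pre-drawn seed sequence.
#'
#' @param fg Tibble of foreground binding sites (columns `id`, `seq`),
#'   all of length `L`.
#' @param bg_chunks Tibble of background sequence chunks (columns `id`,
#'   `seq`); windows of length `L` are extracted within each side of the
#'   split.
#' @param beta A [beta_weights()] vector.
#' @param hyper An `"mb_hyper"` prior; built from `ess_fg`/`ess_bg` when
#'   `NULL`.
#' @param repeats Number of hold-out repetitions (default 1000, the
#'   standard protocol; tests and examples use far fewer).
#' @param train_fraction Per-class training fraction (default 0.9).
#' @param specificity Specificity at which sensitivity is read off
#'   (default 0.999).
#' @param seed Integer seed governing all repeats.
#' @param L Motif length (default 16).
#' @param ess_fg,ess_bg Equivalent sample sizes when `hyper` is `NULL`.
#' @param tol,max_iter Optimizer controls for interior simplex points.
#' @param alphabet An [dna_alphabet()] object.
#' @return An object of class `"blend_holdout"` with elements `results`
#'   (per-repeat tibble), `summary` (per-measure mean and standard
#'   error), `beta`, and the configuration. Supports [tidy()],
#'   [glance()], and [autoplot()].
#' @export
holdout_evaluate <- function(fg, bg_chunks, beta, hyper = NULL,
                             repeats = 1000L, train_fraction = 0.9,
                             specificity = 0.999, seed = 1L, L = 16L,
                             ess_fg = 4, ess_bg = 1024, tol = 1e-6,
                             max_iter = 1000L, alphabet = dna_alphabet()) {
  if (repeats < 1L) stop("repeats must be >= 1")
  hd <- prep_holdout_data(fg, bg_chunks, L, alphabet)
  if (is.null(hyper)) hyper <- hyperparams_from_ess(ess_fg, ess_bg, L, alphabet)
  rseeds <- draw_repeat_seeds(seed, repeats)
  results <- holdout_core(hd, beta, hyper, rseeds, train_fraction,
                          specificity, tol, max_iter)
  structure(
    list(results = results, summary = summarize_holdout(results),
         beta = beta,
         config = list(repeats = repeats, train_fraction = train_fraction,
                       specificity = specificity, seed = seed, L = L,
                       ess = hyper$ess)),
    class = "blend_holdout"
  )
}

#' @export
print.blend_holdout <- function(x, ...) {
  cat("<blend_holdout>", x$config$repeats, "stratified hold-out repeats,",
      sprintf("beta = (%g, %g, %g)\n", x$beta[1], x$beta[2], x$beta[3]))
  s <- x$summary[x$summary$measure == "sensitivity", ]
  cat(sprintf("  mean sensitivity at specificity %.4g: %.4f (se %.4f)\n",
              x$config$specificity, s$mean, s$se))
  invisible(x)
}

#' Per-repeat hold-out results
#' @param x A `"blend_holdout"` object.
#' @param ... Unused.
#' @return Tibble with one row per repeat.
#' @method tidy blend_holdout
#' @export
tidy.blend_holdout <- function(x, ...) x$results

#' One-row hold-out summary
#' @param x A `"blend_holdout"` object.
#' @param ... Unused.
#' @return One-row tibble with means and standard errors of all measures.
#' @method glance blend_holdout
#' @export
glance.blend_holdout <- function(x, ...) {
  s <- x$summary
  out <- tibble::tibble(
    b0 = x$beta[[1]], b1 = x$beta[[2]], b2 = x$beta[[3]],
    repeats = x$config$repeats, specificity = x$config$specificity
  )
  for (i in seq_len(nrow(s))) {
    out[[paste0("mean_", s$measure[i])]] <- s$mean[i]
    out[[paste0("se_", s$measure[i])]] <- s$se[i]
  }
  out
}

#' Grid of weight vectors on the simplex
#'
#' All points `(b0, b1, 1 - b0 - b1)` with `b0, b1` nonnegative multiples
#' of `step` and `b0 + b1 <= 1`. A step of 0.05 gives 231 points.
#'
#' @param step Grid step; must divide 1 (within 1e-9).
#' @return Tibble with columns `b0`, `b1`, `b2`.
#' @export
simplex_grid <- function(step = 0.05) {
  n <- round(1 / step)
  if (abs(n * step - 1) > 1e-9) stop("step must divide 1")
  pts <- purrr::map(0:n, function(j) {
    i <- 0:(n - j)
    tibble::tibble(b0 = i * step, b1 = j * step)
  })
  dplyr::bind_rows(pts) |>
    dplyr::mutate(b2 = pmax(0, 1 - .data$b0 - .data$b1))
}

#' Hold-out evaluation over the whole weight simplex
#'
#' Runs [holdout_evaluate()] at every point of the simplex grid, reusing
#' the identical sequence of repeat seeds (hence identical train/test
#' partitions) at every grid point, so that comparisons between weight
#' vectors are paired.
#'
#' @inheritParams holdout_evaluate
#' @param step Grid step width (default 0.05, i.e. 231 points).
#' @return A tibble of class `"blend_scan"` with columns `b0`, `b1`,
#'   `b2`, `mean_sensitivity`, `se_sensitivity`, and means of the
#'   auxiliary measures; one row per grid point. Supports [autoplot()].
#' @export
simplex_scan <- function(fg, bg_chunks, hyper = NULL, step = 0.05,
                         repeats = 1000L, train_fraction = 0.9,
                         specificity = 0.999, seed = 1L, L = 16L,
                         ess_fg = 4, ess_bg = 1024, tol = 1e-6,
                         max_iter = 1000L, alphabet = dna_alphabet()) {
  grid <- simplex_grid(step)
  hd <- prep_holdout_data(fg, bg_chunks, L, alphabet)
  if (is.null(hyper)) hyper <- hyperparams_from_ess(ess_fg, ess_bg, L, alphabet)
  rseeds <- draw_repeat_seeds(seed, repeats)
  rows <- purrr::map(seq_len(nrow(grid)), function(i) {
    beta <- beta_weights(grid$b0[i], grid$b1[i], grid$b2[i])
    res <- holdout_core(hd, beta, hyper, rseeds, train_fraction,
                        specificity, tol, max_iter)
    s <- summarize_holdout(res)
    tibble::tibble(
      b0 = grid$b0[i], b1 = grid$b1[i], b2 = grid$b2[i],
      mean_sensitivity = s$mean[s$measure == "sensitivity"],
      se_sensitivity = s$se[s$measure == "sensitivity"],
      mean_roc_auc = s$mean[s$measure == "roc_auc"],
      mean_pr_auc = s$mean[s$measure == "pr_auc"],
      mean_classification_rate = s$mean[s$measure == "classification_rate"]
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("blend_scan", class(out))
  attr(out, "step") <- step
  attr(out, "repeats") <- repeats
  attr(out, "specificity") <- specificity
  out
}
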