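test_that("softmax groups are normalized, shift-invariant, overflow-safe", {
  expect_equal(to_probabilities(c(0, 0, 0, 0)), rep(0.25, 4))
  expect_equal(to_probabilities(c(log(2), 0, 0, 0)), c(0.4, 0.2, 0.2, 0.2))
  set.seed(2)
  for (i in 1:20) {
    z <- rnorm(4, sd = 200)  # |z| up to ~700 must not overflow
    p <- to_probabilities(z)
    expect_lt(abs(sum(p) - 1), 1e-12)
    expect_equal(p, to_probabilities(z + 123.4), tolerance = 1e-12)
  }
  expect_equal(to_probabilities(c(700, 0, -700, 0))[1], 1, tolerance = 1e-12)
  expect_error(to_probabilities(c(NaN, 0, 0, 0)))
})

test_that("pwm_log_prob is the sum of per-position log probabilities", {
  unif <- matrix(0.25, 16, 4)
  expect_equal(pwm_log_prob(unif, strrep("A", 16)), 16 * log(0.25))
  pwm2 <- rbind(c(0.7, 0.1, 0.1, 0.1), rep(0.25, 4))
  expect_equal(pwm_log_prob(pwm2, "AC"), log(0.7 * 0.25))
  # normalization: probabilities over all K^L sequences sum to 1 at L = 2
  all2 <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T")), 1,
                paste, collapse = "")
  th <- random_pwm(2, seed = 9)
  expect_lt(abs(sum(exp(pwm_log_prob(th, all2))) - 1), 1e-10)
})

test_that("sufficient counts match a brute-force recount", {
  d <- tibble::tibble(id = c("1","2"), seq = c("AA", "AC"), label = c(1L, 1L))
  cnt <- sufficient_counts(d, 2)
  expect_equal(unname(cnt$n_class), c(0, 2))
  expect_equal(unname(cnt$n_fg[1, ]), c(2, 0, 0, 0))
  expect_equal(unname(cnt$n_fg[2, ]), c(1, 1, 0, 0))
  expect_equal(unname(cnt$n_bg), matrix(0, 2, 4), ignore_attr = TRUE)

  set.seed(11)
  L <- 5; n <- 40
  seqs <- apply(matrix(sample(c("A","C","G","T"), n * L, TRUE), n), 1,
                paste, collapse = "")
  lab <- sample(0:1, n, TRUE)
  cnt <- sufficient_counts(tibble::tibble(id = as.character(1:n),
                                          seq = seqs, label = lab), L)
  chars <- do.call(rbind, strsplit(seqs, ""))
  for (cl in 0:1) {
    nm <- if (cl == 1) "n_fg" else "n_bg"
    for (l in 1:L) for (a in 1:4) {
      expect_equal(unname(cnt[[nm]][l, a]),
                   sum(chars[lab == cl, l] == c("A","C","G","T")[a]))
    }
    expect_true(all(rowSums(cnt[[nm]]) == sum(lab == cl)))
  }
})

test_that("hyperparameters from ESS spread uniform pseudo-counts", {
  hy <- hyperparams_from_ess(4, 1024, L = 16)
  expect_true(all(hy$alpha_fg == 1))
  expect_true(all(hy$alpha_bg == 256))
  expect_equal(unname(hy$alpha_class), c(1024, 4))
  expect_equal(unname(rowSums(hy$alpha_fg)), rep(4, 16))
  expect_error(hyperparams_from_ess(0, 1024), "positive")
})

test_that("prior log density matches the stated transformed-Dirichlet form", {
  # single effective group: make all but the class group carry alpha -> the
  # full density is the sum of independent group terms, so check one group
  # against an independent evaluation of the formula
  hy <- hyperparams_from_ess(4, 4, L = 1)
  p <- classifier_params(z_class = c(0, 0),
                         z_bg = matrix(0, 1, 4), z_fg = matrix(0, 1, 4))
  # groups: class alpha (4,4); one fg column alpha (1,1,1,1); one bg column
  logZ <- function(a) sum(lgamma(a + 1)) - lgamma(sum(a) + length(a))
  expected <- (sum(c(4, 4) * log(0.5)) - logZ(c(4, 4))) +
    2 * (sum(rep(1, 4) * log(0.25)) - logZ(c(1, 1, 1, 1)))
  expect_equal(prior_log_density(p, hy), expected, tolerance = 1e-12)
  # the documented single-group worked value: K = 4, alpha = 1, theta uniform
  expect_equal(sum(rep(1, 4) * log(0.25)) - logZ(c(1, 1, 1, 1)),
               4 * log(0.25) - log(gamma(2)^4 / gamma(8)))

  # gauge invariance: density depends on z only through theta
  p2 <- classifier_params(z_class = c(5, 5),
                          z_bg = matrix(-3, 1, 4), z_fg = matrix(7, 1, 4))
  expect_equal(prior_log_density(p2, hy), prior_log_density(p, hy),
               tolerance = 1e-10)

  # theta = alpha / sum(alpha) maximizes each group term
  set.seed(3)
  hyr <- hyperparams_from_ess(3.7, 12.2, L = 2)
  popt <- classifier_params(
    z_class = log(hyr$alpha_class / sum(hyr$alpha_class)),
    z_bg = log(hyr$alpha_bg / rowSums(hyr$alpha_bg)),
    z_fg = log(hyr$alpha_fg / rowSums(hyr$alpha_fg))
  )
  best <- prior_log_density(popt, hyr)
  for (i in 1:20) {
    expect_lte(prior_log_density(random_params(2, seed = i), hyr), best)
  }

  # theta_a = 0 gives -Inf, not an error
  pz <- classifier_params(z_class = c(0, 0), z_bg = matrix(0, 1, 4),
                          z_fg = matrix(c(-Inf, 0, 0, 0), 1, 4))
  expect_equal(prior_log_density(pz, hy), -Inf)
})

test_that("powering the prior scales every pseudo-count and the ESS", {
  hy <- hyperparams_from_ess(4, 1024, L = 3)
  hy2 <- power_prior(hy, 2)
  expect_true(all(hy2$alpha_fg == 2))
  expect_equal(unname(hy2$ess), c(2048, 8))
  expect_equal(power_prior(hy, 1), hy)
  expect_error(power_prior(hy, 0), "positive")
  expect_error(power_prior(hy, -1), "positive")
})

test_that("prior power-closure: density with xi*alpha is xi*density plus a constant", {
  hy <- hyperparams_from_ess(4, 1024, L = 4)
  for (xi in c(0.3, 2.5, 19)) {
    hx <- power_prior(hy, xi)
    d <- vapply(1:50, function(i) {
      p <- random_params(4, seed = 100 + i)
      prior_log_density(p, hx) - xi * prior_log_density(p, hy)
    }, numeric(1))
    expect_lt(stats::var(d), 1e-16)
  }
})

test_that("virtual ESS follows the axis algebra", {
  expect_equal(virtual_ess(beta_weights(0.05, 0, 0.95), 4, "b0"), 76)
  expect_equal(virtual_ess(beta_weights(0.5, 0, 0.5), 4, "b0"), 4)
  expect_equal(virtual_ess(beta_weights(0, 0.5, 0.5), 4, "b1"), 4)
  expect_error(virtual_ess(beta_weights(0, 0.5, 0.5), 4, "b0"), "zero")
})

test_that("model JSON serialization round-trips probabilities exactly", {
  bench <- make_benchmark(n_fg = 25, bg_total_bp = 1200, L = 6, seed = 2)
  fit <- train_classifier(bench$data, beta_for_principle("MAP"), L_ess(6))
  f <- withr::local_tempfile(fileext = ".json")
  write_model(fit, f)
  back <- read_model(f)
  # 17-digit JSON round-trips the doubles; re-normalization through the
  # softmax touches at most the last ulp
  expect_equal(pwm_probs(back, "fg"), pwm_probs(fit, "fg"), tolerance = 1e-12)
  expect_equal(pwm_probs(back, "bg"), pwm_probs(fit, "bg"), tolerance = 1e-12)
  expect_equal(class_probs(back), class_probs(fit), tolerance = 1e-12)
  expect_equal(back$L, fit$L)
})
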