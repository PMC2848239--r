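hy6 <- hyperparams_from_ess(4, 1024, L = 6)
bench6 <- make_benchmark(n_fg = 40, bg_total_bp = 2500, L = 6, seed = 21)
md6 <- motifblend:::prep_model_data(bench6$data)

test_that("beta weights renormalize, preserve zeros, and name principles", {
  expect_equal(unname(unclass(beta_weights(2, 0, 2))), c(0.5, 0, 0.5))
  expect_identical(beta_weights(2, 0, 2)[[2]], 0)
  expect_error(beta_weights(-0.1, 0.6, 0.5), "nonnegative")
  expect_error(beta_weights(0, 0, 0), "all be zero")
  expect_equal(unname(unclass(beta_for_principle("ML"))), c(0, 1, 0))
  expect_equal(unname(unclass(beta_for_principle("MAP"))), c(0, 0.5, 0.5))
  expect_equal(unname(unclass(beta_for_principle("MCL"))), c(1, 0, 0))
  expect_equal(unname(unclass(beta_for_principle("MSP"))), c(0.5, 0, 0.5))
  expect_error(beta_for_principle("GDT"), "unknown")
  expect_equal(unname(unclass(gdt_beta(1))), c(0, 1, 0))      # -> ML
  expect_equal(unname(unclass(gdt_beta(0))), c(1, 0, 0))      # -> MCL
  expect_equal(unname(unclass(pgdt_beta(1))), c(0, 0.5, 0.5)) # -> MAP
  expect_equal(unname(unclass(pgdt_beta(0))), c(0.5, 0, 0.5)) # -> MSP
})

test_that("joint and conditional likelihoods satisfy the worked identities", {
  # one fg sequence, P(fg) = 0.5, P(x|fg) = 0.2
  p <- classifier_params(z_class = log(c(0.5, 0.5)),
                         z_bg = matrix(log(c(0.1, 0.3, 0.3, 0.3)), 1, 4, byrow = TRUE),
                         z_fg = matrix(log(c(0.2, 0.4, 0.2, 0.2)), 1, 4, byrow = TRUE))
  d_fg <- tibble::tibble(id = "1", seq = "A", label = 1L)
  d_bg <- tibble::tibble(id = "1", seq = "A", label = 0L)
  expect_equal(joint_log_likelihood(p, d_fg), log(0.5 * 0.2))
  expect_equal(conditional_log_likelihood(p, d_fg), log(2 / 3))
  expect_equal(conditional_log_likelihood(p, d_bg), log(1 / 3))

  # identical class models and equal priors: conditional = N log(1/2)
  pu <- classifier_params(z_class = c(0, 0), z_bg = matrix(0, 6, 4),
                          z_fg = matrix(0, 6, 4))
  expect_equal(conditional_log_likelihood(pu, bench6$data),
               nrow(bench6$data) * log(0.5))

  # joint additivity over concatenated data sets
  pr <- random_params(6, seed = 31)
  half <- bench6$data[seq_len(200), ]
  rest <- bench6$data[-seq_len(200), ]
  expect_equal(joint_log_likelihood(pr, bench6$data),
               joint_log_likelihood(pr, half) + joint_log_likelihood(pr, rest))

  # joint = conditional + marginal evidence
  lpx <- motifblend:::seq_class_logprobs(pr, md6)
  lp <- log(class_probs(pr))
  evid <- sum(log(exp(lp[1] + lpx$bg) + exp(lp[2] + lpx$fg)))
  expect_equal(joint_log_likelihood(pr, bench6$data),
               conditional_log_likelihood(pr, bench6$data) + evid,
               tolerance = 1e-10)
})

test_that("the blend objective reduces to its limiting cases exactly", {
  p <- random_params(6, seed = 41)
  cond <- conditional_log_likelihood(p, bench6$data)
  joint <- joint_log_likelihood(p, bench6$data)
  prior <- prior_log_density(p, hy6)
  expect_identical(unified_objective(p, bench6$data, beta_for_principle("ML"), hy6), joint)
  expect_identical(unified_objective(p, bench6$data, beta_for_principle("MCL"), hy6), cond)
  expect_identical(unified_objective(p, bench6$data, beta_for_principle("MAP"), hy6),
                   0.5 * joint + 0.5 * prior)
  expect_identical(unified_objective(p, bench6$data, beta_for_principle("MSP"), hy6),
                   0.5 * cond + 0.5 * prior)
  b <- beta_weights(0.2, 0.3, 0.5)
  expect_equal(unified_objective(p, bench6$data, b, hy6),
               0.2 * cond + 0.3 * joint + 0.5 * prior, tolerance = 1e-12)
})

test_that("analytic gradient matches central differences and is gauge-null", {
  # small set keeps the finite-difference cancellation error below 1e-6
  # moderate objective magnitudes, so |f| * eps / (2h) stays well under 1e-6
  dsmall <- make_benchmark(n_fg = 30, bg_total_bp = 150, L = 4, seed = 61)$data
  mds <- motifblend:::prep_model_data(dsmall)
  betas <- list(beta_weights(1, 0, 0), beta_weights(0, 0.5, 0.5),
                beta_weights(0.2, 0.3, 0.5))
  hy4 <- hyperparams_from_ess(4, 16, L = 4)
  for (b in betas) {
    for (i in 1:4) {
      p <- random_params(4, sd = 0.8, seed = 500 + i)
      z <- motifblend:::pack_params(p)
      g <- motifblend:::grad_core(p, mds, b, hy4)
      expect_lt(max(abs(g - fd_gradient(z, mds, b, hy4))), 1e-6)
      # per-group components sum to zero (the flat gauge direction)
      expect_lt(abs(sum(g[1:2])), 1e-10)
      expect_lt(max(abs(rowSums(matrix(g[3:18], 4)))), 1e-10)
      expect_lt(max(abs(rowSums(matrix(g[19:34], 4)))), 1e-10)
    }
  }
})

test_that("objective is invariant under a constant shift of any group's z", {
  p <- random_params(6, seed = 77)
  b <- beta_weights(0.3, 0.3, 0.4)
  v0 <- motifblend:::obj_core(p, md6, b, hy6)
  p$z_class <- p$z_class + 3.21
  p$z_bg[2, ] <- p$z_bg[2, ] - 11.5
  p$z_fg[5, ] <- p$z_fg[5, ] + 0.77
  expect_equal(motifblend:::obj_core(p, md6, b, hy6), v0, tolerance = 1e-10)
})

test_that("closed-form generative estimates are the weighted pseudo-counts", {
  cnt <- structure(list(n_class = c(bg = 1, fg = 4),
                        n_bg = matrix(c(1, 0, 0, 0), 1),
                        n_fg = matrix(c(3, 1, 0, 0), 1),
                        L = 1L, K = 4L), class = "mb_counts")
  p_ml <- closed_form_generative(cnt, beta_weights(0, 1, 0))
  expect_equal(unname(pwm_probs(p_ml, "fg")[1, ]), c(0.75, 0.25, 0, 0))
  hy1 <- hyperparams_from_ess(4, 4, L = 1)
  p_map <- closed_form_generative(cnt, beta_weights(0, 0.5, 0.5), hy1)
  expect_equal(unname(pwm_probs(p_map, "fg")[1, ]), c(0.5, 0.25, 0.125, 0.125))
  p_prior <- closed_form_generative(cnt, beta_weights(0, 0, 1), hy1)
  expect_equal(unname(pwm_probs(p_prior, "fg")[1, ]), rep(0.25, 4))
  expect_error(closed_form_generative(cnt, beta_weights(0.5, 0.5, 0), hy1), "b0")
})

test_that("numeric training agrees with the closed form on the generative edge", {
  d <- make_benchmark(n_fg = 100, bg_total_bp = 900, L = 6, seed = 51,
                      theta_fg = motif_pwm(6, 0.55))$data  # 200 sequences
  cnt <- sufficient_counts(d, 6)
  hy <- hyperparams_from_ess(4, 1024, 6)
  for (nm in c("ML", "MAP")) {
    b <- beta_for_principle(nm)
    num <- train_classifier(d, b, hy, method = "numeric")
    cf <- closed_form_generative(cnt, b, hy)
    expect_lt(max(abs(pwm_probs(num, "fg") - pwm_probs(cf, "fg"))), 1e-4)
    expect_lt(max(abs(pwm_probs(num, "bg") - pwm_probs(cf, "bg"))), 1e-4)
    expect_lt(max(abs(class_probs(num) - class_probs(cf))), 1e-4)
    expect_true(num$converged)
  }
  # at the generative optimum the gradient vanishes
  b_map <- beta_for_principle("MAP")
  cf <- closed_form_generative(cnt, b_map, hy)
  md <- motifblend:::prep_model_data(d)
  expect_lt(max(abs(motifblend:::grad_core(cf, md, b_map, hy))), 1e-8)
})

test_that("quasi-Newton ascent never ends below its starting objective", {
  b <- beta_weights(0.4, 0.2, 0.4)
  init <- random_params(6, sd = 0.5, seed = 99)
  v0 <- motifblend:::obj_core(init, md6, b, hy6)
  fit <- train_classifier(bench6$data, b, hy6, init = init, method = "numeric")
  expect_gte(fit$objective_value, v0)
  # stops on either the gradient max-norm or the relative-change rule
  expect_true(fit$converged)
})

test_that("canonical penalized trade-off coordinates follow the line algebra", {
  expect_equal(pgdt_canonical(beta_weights(0, 0.5, 0.5)), c(gamma = 1, xi = 1))
  expect_equal(pgdt_canonical(beta_weights(1, 0, 0)), c(gamma = 0, xi = 0))
  expect_equal(pgdt_canonical(beta_weights(0.5, 0, 0.5)), c(gamma = 0, xi = 1))
  expect_equal(pgdt_canonical(beta_weights(0.3, 0.2, 0.5)), c(gamma = 0.4, xi = 1))
  expect_error(pgdt_canonical(beta_weights(0, 0, 1)), "pure-prior")
})

test_that("weighted-posterior composition absorbs data and prior exactly", {
  cnt <- structure(list(n_class = c(bg = 0, fg = 3),
                        n_fg = matrix(c(3, 0, 0, 0), 1),
                        n_bg = matrix(0, 1, 4), L = 1L, K = 4L),
                   class = "mb_counts")
  hy1 <- hyperparams_from_ess(4, 4, L = 1)
  h_msp <- effective_posterior_hyperparams(beta_weights(0.5, 0, 0.5), cnt, hy1)
  expect_equal(h_msp$alpha_fg, 0.5 * hy1$alpha_fg)
  h_mix <- effective_posterior_hyperparams(beta_weights(1/3, 1/3, 1/3), cnt, hy1)
  expect_equal(unname(h_mix$alpha_fg[1, ]), c(4/3, 1/3, 1/3, 1/3))

  # objective minus b0*cond minus the composed kernel is constant in lambda
  b <- beta_weights(0.25, 0.35, 0.4)
  cnt6 <- sufficient_counts(bench6$data, 6)
  ht <- effective_posterior_hyperparams(b, cnt6, hy6)
  d <- vapply(1:50, function(i) {
    p <- random_params(6, seed = 700 + i)
    motifblend:::obj_core(p, md6, b, hy6) -
      b[[1]] * motifblend:::cond_core(p, md6) -
      motifblend:::param_kernel(p, ht$alpha_class, ht$alpha_bg, ht$alpha_fg)
  }, numeric(1))
  expect_lt(stats::var(d), 1e-16)
})

test_that("maximum-likelihood training recovers the generating PWM", {
  th <- random_pwm(8, concentration = 1, seed = 13)
  set.seed(14)
  fg <- sample_pwm_dataset(th, 10000)
  bg <- sample_pwm_dataset(matrix(0.25, 8, 4), 500, prefix = "bg")
  d <- tibble::tibble(id = c(fg$id, bg$id), seq = c(fg$seq, bg$seq),
                      label = rep(c(1L, 0L), c(10000, 500)))
  fit <- train_classifier(d, beta_for_principle("ML"))
  mae <- mean(abs(pwm_probs(fit, "fg") - th))
  expect_lt(mae, 0.02)
})
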