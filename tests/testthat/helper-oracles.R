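# Independent oracles and small fixture builders used across the suite.

# Brute-force sensitivity at fixed specificity: scan every candidate
# threshold, keep those whose false-positive COUNT does not exceed the
# allowed floor((1 - specificity) * m), and maximize sensitivity.
sens_brute <- function(pos, neg, specificity) {
  m <- length(neg)
  allowed <- floor((1 - specificity) * m + 1e-9)
  cand <- c(-Inf, sort(unique(c(pos, neg))))
  best <- 0
  for (t in cand) {
    if (sum(neg > t) <= allowed) best <- max(best, mean(pos > t))
  }
  best
}

# Exhaustive O(n^2) pair-counting ROC-AUC with half credit for ties.
roc_pairs <- function(pos, neg) {
  s <- outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n))
  mean(s)
}

# A random interior parameter point in the unconstrained parameterization.
random_params <- function(L, K = 4L, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  motifblend:::unpack_params(stats::rnorm(2L + 2L * L * K, sd = sd), L, K)
}

# Small two-class labeled set with overlapping classes (never separable
# for moderate n at L = 4): foreground from a weak motif, background
# uniform.
small_overlap_data <- function(n_per_class = 150L, L = 4L, seed = 1L) {
  set.seed(seed)
  fg <- sample_pwm_dataset(motif_pwm(L, consensus_prob = 0.5), n_per_class,
                           prefix = "fg")
  bg <- sample_pwm_dataset(matrix(0.25, L, 4), n_per_class, prefix = "bg")
  tibble::tibble(
    id = c(fg$id, bg$id), seq = c(fg$seq, bg$seq),
    label = rep(c(1L, 0L), each = n_per_class)
  )
}

# Central finite-difference gradient of the blend objective at z.
fd_gradient <- function(z, md, beta, hyper, h = 1e-6) {
  L <- md$L; K <- md$K
  vapply(seq_along(z), function(i) {
    zp <- z; zm <- z
    zp[i] <- zp[i] + h
    zm[i] <- zm[i] - h
    (motifblend:::obj_core(motifblend:::unpack_params(zp, L, K), md, beta, hyper) -
       motifblend:::obj_core(motifblend:::unpack_params(zm, L, K), md, beta, hyper)) / (2 * h)
  }, numeric(1))
}
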