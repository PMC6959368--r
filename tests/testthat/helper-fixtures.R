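# shared fixtures for the test suite; everything is generated in code

# a clean 4-parameter logistic trace
make_logistic_trace <- function(t = seq(0, 200, 2), base = 0, plateau = 1,
                                t_mid = 100, w = 10, noise_sd = 0, seed = 1,
                                m0 = NA_real_, direction = "rising") {
  y <- base + (plateau - base) / (1 + exp(-(t - t_mid) / w))
  if (noise_sd > 0) {
    set.seed(seed)
    y <- y + rnorm(length(t), 0, noise_sd)
  }
  aggregation_trace(t, y, m0 = m0, direction = direction)
}

# deterministic random parameter draws in the secondary-dominated regime,
# kappa fixed near 1 (arbitrary time unit), kappa/lambda log-uniform in
# [ratio_min, ratio_max]; multi-step draws have m0^n2/K_M log-uniform in
# [0.1, 10]
draw_kinetic_params <- function(n, seed, ratio_min, ratio_max, m0 = 3,
                                single_only = FALSE) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    kappa <- 10^runif(1, -0.3, 0.3)
    ratio <- 10^runif(1, log10(ratio_min), log10(ratio_max))
    multi <- !single_only && i %% 2L == 0L
    KM <- if (multi) m0^2 / 10^runif(1, -1, 1) else Inf
    sat <- 1 + m0^2 / KM
    kp_k2 <- kappa^2 * sat / (2 * m0^3)
    lambda <- kappa / ratio
    kp_kn <- lambda^2 / (2 * m0^2)
    list(params = kinetic_params(kp_kn = kp_kn, kp_k2 = kp_k2, K_M = KM),
         m0 = m0, kappa = kappa)
  })
}

# additive distance matrix from a random unrooted tree (ape), with the tree
# returned for topology comparison
random_additive_matrix <- function(n_taxa, seed) {
  set.seed(seed)
  tree <- ape::rtree(n_taxa, rooted = FALSE,
                     br = function(k) runif(k, 0.05, 1))
  list(tree = tree, d = ape::cophenetic.phylo(tree))
}

# averaged, normalized per-concentration traces from a generated dataset
averaged_series <- function(ds) {
  m0s <- vapply(ds$traces, function(x) x$m0, numeric(1))
  lapply(sort(unique(m0s)), function(cc)
    average_replicates(lapply(ds$traces[m0s == cc], normalize_trace)))
}
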