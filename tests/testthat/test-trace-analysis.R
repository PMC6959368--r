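test_that("normalization maps any affine image of a logistic to the unit logistic", {
  tr <- make_logistic_trace(base = 350, plateau = 2350)
  ntr <- normalize_trace(tr)
  ref <- make_logistic_trace()
  expect_equal(ntr$signal, ref$signal, tolerance = 1e-6)
  expect_identical(attr(ntr, "orig_direction"), "rising")
  # declining traces are flipped to aggregation extent
  dec <- make_logistic_trace(base = 1000, plateau = 200, direction = "declining")
  ndec <- normalize_trace(dec)
  expect_identical(ndec$direction, "rising")
  expect_identical(attr(ndec, "orig_direction"), "declining")
  expect_equal(ndec$signal, ref$signal, tolerance = 1e-6)
  # idempotence
  expect_equal(normalize_trace(ntr)$signal, ntr$signal, tolerance = 1e-6)
})

test_that("normalization rejects traces without a transition", {
  flat <- aggregation_trace(seq(0, 100, 5), rep(7, 21), replicate_id = "w3")
  expect_error(normalize_trace(flat), "w3")
})

test_that("a noisy normalized trace plateaus at one", {
  tr <- make_logistic_trace(base = 100, plateau = 3100, noise_sd = 60,
                            seed = 4)  # 2% of amplitude
  ntr <- normalize_trace(tr)
  n <- length(ntr$signal)
  tail_mean <- mean(ntr$signal[seq.int(floor(0.9 * n) + 1L, n)])
  expect_gt(tail_mean, 0.98); expect_lt(tail_mean, 1.02)
})

test_that("replicate averaging is idempotent and cancels mirrored noise", {
  tr <- make_logistic_trace(m0 = 3)
  avg <- average_replicates(list(tr, tr, tr))
  expect_equal(avg$signal, tr$signal)
  expect_identical(attr(avg, "n_replicates"), 3L)
  set.seed(9)
  noise <- rnorm(length(tr$time), 0, 0.05)
  up <- aggregation_trace(tr$time, tr$signal + noise, m0 = 3)
  dn <- aggregation_trace(tr$time, tr$signal - noise, m0 = 3)
  expect_equal(average_replicates(list(up, dn))$signal, tr$signal,
               tolerance = 1e-12)
})

test_that("averaging six replicates shrinks noise about sqrt(6)-fold", {
  truth <- make_logistic_trace()
  reps <- lapply(1:6, function(i)
    make_logistic_trace(noise_sd = 0.05, seed = 100 + i, m0 = 3))
  avg <- average_replicates(reps)
  rms <- function(x) sqrt(mean(x^2))
  r1 <- rms(reps[[1]]$signal - truth$signal)
  r6 <- rms(avg$signal - truth$signal)
  expect_gt(r1 / r6, sqrt(6) * 0.7)
  expect_lt(r1 / r6, sqrt(6) * 1.4)
})

test_that("averaging refuses mixed concentrations or modalities", {
  a <- make_logistic_trace(m0 = 3)
  b <- make_logistic_trace(m0 = 5)
  expect_error(average_replicates(list(a, b)), "mixed monomer")
})

test_that("the sigmoid fit recovers its own parameters in both directions", {
  up <- make_logistic_trace()
  est <- fit_sigmoid(up)
  expect_equal(est$tau_half, 100, tolerance = 1e-6)
  expect_equal(est$width, 10, tolerance = 1e-4)
  expect_identical(est$direction, "rising")
  dn <- make_logistic_trace(base = 1, plateau = 0, direction = "declining")
  estd <- fit_sigmoid(dn)
  expect_equal(estd$tau_half, 100, tolerance = 1e-6)
  expect_identical(estd$direction, "declining")
  flat <- aggregation_trace(seq(0, 100, 5), rep(2, 21))
  expect_error(fit_sigmoid(flat), "midpoint")
})

test_that("sigmoid half times track the model half time on noiseless curves", {
  p <- default_tht_params()
  tg <- seq(0, 25, length.out = 301)
  for (m0 in c(1, 2, 3, 5, 9)) {
    tr <- aggregation_trace(tg, mass_fraction_closed(p, tg, m0), m0 = m0)
    est <- fit_sigmoid(tr)
    expect_equal(est$tau_half, model_halftime(p, m0), tolerance = 0.02)
  }
})

test_that("the scaling exponent reproduces exact power laws and units do not matter", {
  m0 <- c(1, 3, 9)
  sf <- scaling_exponent(m0, 100 / m0)
  expect_equal(sf$gamma, -1)
  expect_equal(sf$gamma_se, 0, tolerance = 1e-10)
  expect_equal(sf$r_squared, 1)
  flat <- scaling_exponent(m0, rep(50, 3))
  expect_equal(flat$gamma, 0, tolerance = 1e-12)
  expect_error(scaling_exponent(c(1, 3), c(10, 5)), "3 distinct")
  # rescaling time or all concentrations shifts the intercept, not the slope
  taus <- c(400, 160, 90, 55)
  m0s <- c(1, 2, 3, 4)
  base <- scaling_exponent(m0s, taus)
  expect_equal(scaling_exponent(m0s, taus * 60)$gamma, base$gamma)
  expect_equal(scaling_exponent(m0s * 2.5, taus)$gamma, base$gamma)
})

test_that("plateau linearity flags perfect proportionality and degeneracy", {
  m0 <- 1:6
  fit <- plateau_linearity(m0, 500 * m0)
  expect_equal(fit$slope, 500)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1)
  finals <- 500 * m0
  finals[3] <- finals[3] * 2
  expect_lt(plateau_linearity(m0, finals)$r_squared, 1)
  expect_error(plateau_linearity(rep(2, 5), 1:5), "degenerate")
})

test_that("trace CSV + JSON metadata round-trips through read/write", {
  tr1 <- make_logistic_trace(m0 = 2)
  tr2 <- make_logistic_trace(m0 = 5, base = 10, plateau = 400)
  tmp <- withr::local_tempdir()
  csv <- file.path(tmp, "traces.csv"); meta <- file.path(tmp, "meta.json")
  write_traces(list(w1 = tr1, w2 = tr2), csv, meta)
  back <- read_traces(csv, meta)
  expect_named(back, c("w1", "w2"))
  expect_equal(back$w2$signal, tr2$signal)
  expect_equal(back$w2$m0, 5)
})
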