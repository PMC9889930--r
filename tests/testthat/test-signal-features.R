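test_that("linear moment features match hand-computed values", {
  expect_equal(feat_max(c(1, 5, -3)), 5)
  expect_equal(feat_max(rep(2.5, 10)), 2.5)
  expect_equal(feat_variance(c(1, -1)), 2)
  expect_equal(feat_variance(rep(3, 5)), 0)
  # (1/3) * 4 / (4/3)^2 - 3
  expect_equal(feat_kurtosis(c(1, -1, 1, -1)), -2.25)
  expect_equal(feat_skewness(c(-2, -1, 0, 1, 2)), 0)
  expect_equal(feat_skewness(c(0, 0, 0, 1)), 2 / sqrt(3))
  expect_error(feat_kurtosis(rep(1, 10)), "constant")
  expect_error(feat_skewness(rep(0, 10)), "constant")
  expect_error(feat_max(numeric(0)))
})

test_that("maximum equals a brute-force linear scan on noise", {
  x <- gen_white_noise(1e4, seed = 1)
  scan <- x[1]
  for (v in x) if (v > scan) scan <- v
  expect_identical(feat_max(x), scan)
})

test_that("sample variance of standard normal draws approaches 1", {
  x <- gen_white_noise(1e5, seed = 2)
  expect_lt(abs(feat_variance(x) - 1), 0.05)
})

test_that("skewness vanishes for any sequence symmetric about its mean", {
  for (s in 1:5) {
    half <- withr::with_seed(s, stats::rnorm(50))
    x <- c(half, -half) + 3  # exactly symmetric about 3
    expect_lt(abs(feat_skewness(x)), 1e-12)
  }
})

test_that("features are translation- and scale-equivariant as expected", {
  for (s in 1:5) {
    x <- gen_white_noise(1024, seed = s)
    shift <- 7.5; scale <- 3.2
    expect_equal(feat_max(x + shift), feat_max(x) + shift)
    expect_equal(feat_variance(x + shift), feat_variance(x), tolerance = 1e-9)
    expect_equal(feat_variance(scale * x), scale^2 * feat_variance(x), tolerance = 1e-9)
    expect_equal(feat_kurtosis(x + shift), feat_kurtosis(x), tolerance = 1e-9)
    expect_equal(feat_kurtosis(scale * x), feat_kurtosis(x), tolerance = 1e-9)
    expect_equal(feat_skewness(x + shift), feat_skewness(x), tolerance = 1e-9)
    expect_equal(feat_skewness(scale * x), feat_skewness(x), tolerance = 1e-9)
    expect_equal(dfa(x + shift)$alpha, dfa(x)$alpha, tolerance = 1e-9)
    expect_equal(dfa(scale * x)$alpha, dfa(x)$alpha, tolerance = 1e-9)
    expect_equal(higuchi_fd(x + shift)$dimension_raw, higuchi_fd(x)$dimension_raw,
                 tolerance = 1e-9)
    expect_equal(higuchi_fd(scale * x)$dimension_raw, higuchi_fd(x)$dimension_raw,
                 tolerance = 1e-9)
    expect_equal(spectral_entropy(x + shift, 250)$entropy,
                 spectral_entropy(x, 250)$entropy, tolerance = 1e-6)
    expect_equal(spectral_entropy(scale * x, 250)$entropy,
                 spectral_entropy(x, 250)$entropy, tolerance = 1e-9)
  }
})

test_that("DFA recovers known exponents for white noise and Brownian motion", {
  a_white <- mean(vapply(1:10, function(s) dfa(gen_white_noise(4096, s))$alpha,
                         numeric(1)))
  expect_lt(abs(a_white - 0.5), 0.08)
  a_brown <- mean(vapply(1:10, function(s) {
    dfa(cumsum(gen_white_noise(2048, s)))$alpha
  }, numeric(1)))
  expect_lt(abs(a_brown - 1.5), 0.12)
})

test_that("DFA fluctuations grow with box size for white noise on average", {
  incr <- vapply(1:10, function(s) {
    f <- dfa(gen_white_noise(4096, s))$fluctuations
    mean(diff(f) > 0)
  }, numeric(1))
  expect_gt(mean(incr), 0.9)
})

test_that("DFA validates its box-size contract", {
  x <- gen_white_noise(256, seed = 1)
  expect_error(dfa(x[1:32]), "at least")
  expect_error(dfa(x, box_sizes = c(2, 4, 8, 16)), "box_sizes")
  expect_error(dfa(x, box_sizes = c(4, 8, 16)), "box_sizes")       # too few
  expect_error(dfa(x, box_sizes = c(4, 8, 16, 200)), "box_sizes")  # > N/2
  res <- dfa(x, box_sizes = c(4, 8, 16, 32, 64))
  expect_length(res$fluctuations, 5)
  expect_true(all(res$fluctuations > 0))
})

test_that("vectorized DFA matches the literal-equation reference", {
  for (s in 1:5) {
    x <- gen_white_noise(512 + 128 * s, seed = s)
    bs <- unique(round(exp(seq(log(4), log(length(x) / 4), length.out = 10))))
    expect_equal(dfa(x, bs)$alpha, dfa_reference(x, bs)$alpha, tolerance = 1e-10)
  }
})

test_that("Higuchi dimension separates smooth from noise-like signals", {
  smooth <- sin(2 * pi * (0:1999) / 50)  # densely sampled sinusoid
  expect_lt(abs(higuchi_fd(smooth)$dimension - 1), 0.1)
  noisy <- higuchi_fd(gen_white_noise(4096, seed = 3))$dimension
  expect_lt(abs(noisy - 2), 0.15)
  expect_error(higuchi_fd(gen_white_noise(64, 1), k_max = 10), "too short")
})

test_that("vectorized Higuchi matches the triple-loop reference", {
  for (s in 1:5) {
    x <- gen_white_noise(1000, seed = 10 + s)
    expect_equal(higuchi_fd(x, k_max = 8)$dimension_raw,
                 higuchi_reference(x, 8)$dimension, tolerance = 1e-10)
  }
})

test_that("spectral entropy is high for white noise, low for a tone", {
  se_w <- spectral_entropy(gen_white_noise(8192, seed = 1), 250)
  expect_gt(se_w$entropy, 0.95)
  expect_equal(sum(se_w$normalized_power), 1, tolerance = 1e-9)
  tone <- sin(2 * pi * 10 * (0:8191) / 250)
  se_t <- spectral_entropy(tone, 250)
  expect_lt(se_t$entropy, 0.3)
  # agreement in regime with the raw-periodogram oracle
  expect_gt(periodogram_entropy(gen_white_noise(8192, seed = 1)), 0.9)
  expect_lt(periodogram_entropy(tone), 0.3)
  expect_error(spectral_entropy(rep(0, 256), 250), "degenerate|zero")
})

test_that("extract_features fills all seven features with provenance", {
  rec <- eeg_recording(list(cz = gen_white_noise(2000, 5)), sampling_rate = 250,
                       subject_id = "s1")
  ep <- epoch_signal(rec, window_seconds = 4)[[1]]
  fv <- extract_features(ep)
  expect_true(all(feature_names() %in% names(fv)))
  expect_true(all(is.finite(as.numeric(fv[feature_names()]))))
  expect_identical(fv$subject_id, "s1")
  expect_lt(abs(fv$dfa_alpha - 0.5), 0.25)
  # determinism
  expect_identical(fv, extract_features(ep))
  # degenerate epoch names the epoch and the failing feature family
  ep_const <- ep; ep_const$samples <- rep(1, length(ep$samples))
  expect_error(extract_features(ep_const), "s1.*constant")
})

test_that("per-subject aggregation averages epochs channel by channel", {
  rec <- eeg_recording(list(a = gen_white_noise(2000, 1), b = gen_white_noise(2000, 2)),
                       sampling_rate = 250, subject_id = "s1")
  eps <- epoch_signal(rec, window_seconds = 4)
  long <- features_table(eps)
  agg <- aggregate_features(long)
  expect_equal(dim(agg), c(1, 14))
  v <- long$value[long$channel == "a" & long$feature == "variance"]
  expect_equal(agg[["a.variance"]], mean(v))
})
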