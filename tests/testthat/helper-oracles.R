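# Independent reference implementations used as oracles. These follow the
# defining equations literally, loop by loop, and share no code with the
# package's vectorized implementations.

# DFA, step by step: integrate the mean-centered series, then for each box
# size fit a straight line per box by lm(), accumulate squared residuals,
# and take the RMS; alpha is the lm() slope of log F on log n.
dfa_reference <- function(x, box_sizes) {
  n_tot <- length(x)
  y <- cumsum(x - mean(x))
  fl <- numeric(length(box_sizes))
  for (bi in seq_along(box_sizes)) {
    bs <- box_sizes[bi]
    nb <- floor(n_tot / bs)
    total <- 0
    for (b in seq_len(nb)) {
      idx <- ((b - 1) * bs + 1):(b * bs)
      seg <- y[idx]
      t_ax <- seq_len(bs)
      fit <- stats::lm(seg ~ t_ax)
      total <- total + sum(stats::residuals(fit)^2)
    }
    fl[bi] <- sqrt(total / (nb * bs))
  }
  fit <- stats::lm(log(fl) ~ log(box_sizes))
  list(alpha = unname(stats::coef(fit)[2]), fluctuations = fl)
}

# Higuchi, with the explicit double loop over lag k and offset m.
higuchi_reference <- function(x, k_max) {
  n <- length(x)
  lk <- numeric(k_max)
  for (k in seq_len(k_max)) {
    lm_sum <- 0
    for (m in seq_len(k)) {
      n_seg <- floor((n - m) / k)
      s <- 0
      for (i in seq_len(n_seg)) {
        s <- s + abs(x[m + i * k] - x[m + (i - 1) * k])
      }
      lm_sum <- lm_sum + s * (n - 1) / (n_seg * k) / k
    }
    lk[k] <- lm_sum / k
  }
  fit <- stats::lm(log(lk) ~ log(seq_len(k_max)))
  list(dimension = -unname(stats::coef(fit)[2]), curve_lengths = lk)
}

# Raw-periodogram normalized spectral entropy (no Welch averaging): the
# independent check that the estimator is in the right regime.
periodogram_entropy <- function(x) {
  n <- length(x)
  p <- (Mod(stats::fft(x - mean(x)))^2)[2:(n %/% 2 + 1)]
  p <- p / sum(p)
  nz <- p > 0
  -sum(p[nz] * log(p[nz])) / log(length(p))
}

# Small labeled feature matrix with `n_info` informative columns (mean shift
# `delta`) among `n_noise` pure-noise columns.
make_planted_matrix <- function(n_per_class = 30, n_info = 3, n_noise = 50,
                                delta = 3, seed = 1, sd_noise = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    p <- n_info + n_noise
    x <- matrix(stats::rnorm(n * p, sd = sd_noise), n, p)
    lab <- rep(c("depressed", "control"), each = n_per_class)
    for (j in seq_len(n_info)) {
      x[lab == "depressed", j] <- x[lab == "depressed", j] + delta
    }
    colnames(x) <- c(sprintf("ch01.info%d", seq_len(n_info)),
                     sprintf("ch02.noise%02d", seq_len(n_noise)))
    rownames(x) <- sprintf("s%03d", seq_len(n))
    assemble_matrix(x, stats::setNames(lab, rownames(x)))
  })
}
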