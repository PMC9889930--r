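# Per-epoch EEG features: linear moments, long-range correlation (DFA),
# Higuchi fractal dimension, and normalized spectral entropy.

#' Maximum value of a signal
#'
#' @param x Numeric vector, non-empty and finite.
#' @return The largest sample value.
#' @export
feat_max <- function(x) {
  x <- check_numeric_vector(x, "x", min_len = 1L)
  max(x)
}

#' Sample variance of a signal
#'
#' Uses the unbiased 1/(n-1) denominator; its square root is the SD entering
#' the excess-kurtosis formula.
#'
#' @param x Numeric vector of length >= 2.
#' @return Sample variance.
#' @export
feat_variance <- function(x) {
  x <- check_numeric_vector(x, "x", min_len = 2L)
  stats::var(x)
}

#' Excess kurtosis of a signal
#'
#' Computed as \eqn{\frac{1}{n-1}\sum_i (x_i-\bar x)^4 / SD^4 - 3} with
#' \eqn{SD^2} the 1/(n-1) sample variance, so a Gaussian series scores about 0.
#' This hybrid estimator (1/(n-1) fourth moment over the squared sample
#' variance) is used deliberately, not the unbiased G2 form.
#'
#' @param x Numeric vector of length >= 4 with positive variance.
#' @return Excess kurtosis.
#' @export
feat_kurtosis <- function(x) {
  x <- check_numeric_vector(x, "x", min_len = 4L)
  n <- length(x)
  v <- stats::var(x)
  if (v <= 0) stop("kurtosis is undefined for a constant (zero-variance) signal", call. = FALSE)
  sum((x - mean(x))^4) / (n - 1) / v^2 - 3
}

#' Skewness of a signal
#'
#' Moment estimator \eqn{m_3 / m_2^{3/2}} with population (1/n) central
#' moments. Zero for any sequence symmetric about its mean; positive when the
#' right tail is heavier (the standard sign convention).
#'
#' @param x Numeric vector of length >= 3 with positive variance.
#' @return Skewness coefficient.
#' @export
feat_skewness <- function(x) {
  x <- check_numeric_vector(x, "x", min_len = 3L)
  n <- length(x)
  d <- x - mean(x)
  m2 <- sum(d^2) / n
  if (m2 <= 0) stop("skewness is undefined for a constant (zero-variance) signal", call. = FALSE)
  (sum(d^3) / n) / m2^1.5
}

# Default DFA box sizes: ~12 log-spaced integers from 4 to N/4, so the largest
# box still leaves >= 4 boxes.
default_box_sizes <- function(n, n_sizes = 12L) {
  upper <- floor(n / 4)
  sizes <- unique(round(exp(seq(log(4), log(upper), length.out = n_sizes))))
  sizes[sizes >= 4 & sizes <= upper]
}

#' Detrended fluctuation analysis (DFA)
#'
#' Estimates the scaling exponent alpha of long-range temporal correlation:
#' the mean-centered series is integrated, partitioned at each box size n into
#' floor(N/n) non-overlapping boxes, linearly detrended per box, and the
#' root-mean-square residual F(n) over all covered points is regressed
#' (natural log-log) on n. White noise gives alpha ~ 0.5, 1/f noise ~ 1.0,
#' Brownian motion ~ 1.5.
#'
#' @param x Numeric vector, length >= 64.
#' @param box_sizes Optional strictly increasing integer box sizes, each in
#'   \[4, N/2\], at least 4 values. Default: ~12 log-spaced sizes from 4 to N/4.
#' @return An object of class `dfa_result`: list with `alpha`, `box_sizes`,
#'   `fluctuations`, `fit_intercept`, `r_squared`.
#' @export
dfa <- function(x, box_sizes = NULL) {
  x <- check_numeric_vector(x, "x", min_len = 64L)
  n_tot <- length(x)
  if (is.null(box_sizes)) {
    box_sizes <- default_box_sizes(n_tot)
  } else {
    box_sizes <- as.integer(box_sizes)
    if (length(box_sizes) < 4L || is.unsorted(box_sizes, strictly = TRUE) ||
        any(box_sizes < 4L) || any(box_sizes > n_tot %/% 2L)) {
      stop("box_sizes must be >= 4 strictly increasing integers in [4, N/2]", call. = FALSE)
    }
  }
  y <- cumsum(x - mean(x))

  keep <- box_sizes[n_tot %/% box_sizes >= 2L]
  if (length(keep) < length(box_sizes)) {
    warning(sprintf("dropping %d box size(s) allowing fewer than 2 boxes",
                    length(box_sizes) - length(keep)))
  }
  fluct <- vapply(keep, function(bs) {
    nb <- n_tot %/% bs
    seg <- matrix(y[seq_len(nb * bs)], nrow = bs)
    # Residual-maker for regression on (1, t), applied to all boxes at once.
    t_ax <- seq_len(bs)
    xm <- cbind(1, t_ax)
    res <- seg - xm %*% solve(crossprod(xm), crossprod(xm, seg))
    sqrt(mean(res^2))
  }, numeric(1))

  ok <- fluct > 0
  if (sum(ok) < 4L) stop("fewer than 4 usable box sizes; cannot estimate alpha", call. = FALSE)
  lx <- log(keep[ok]); ly <- log(fluct[ok])
  slope <- ls_slope(lx, ly)
  intercept <- mean(ly) - slope * mean(lx)
  ss_res <- sum((ly - intercept - slope * lx)^2)
  ss_tot <- sum((ly - mean(ly))^2)
  structure(list(alpha = slope,
                 box_sizes = keep[ok],
                 fluctuations = fluct[ok],
                 fit_intercept = intercept,
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_),
            class = "dfa_result")
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("DFA: alpha = %.4f over %d box sizes [%d..%d], R^2 = %.4f\n",
              x$alpha, length(x$box_sizes), min(x$box_sizes), max(x$box_sizes),
              x$r_squared))
  invisible(x)
}

#' Higuchi fractal dimension
#'
#' Curve-length estimate of signal irregularity. For each lag k and offset m
#' in 1..k, the normalized curve length is
#' \deqn{L_m(k) = \Big[\sum_i |S(m+ik) - S(m+(i-1)k)|\Big]
#'   \frac{N-1}{\lfloor (N-m)/k \rfloor \, k} \frac{1}{k},}
#' L(k) is the mean over m, and the dimension is minus the slope of
#' ln L(k) on ln k. Values near 1 indicate a smooth curve, near 2 a
#' noise-like, space-filling one; estimates are clipped to \[1, 2\] with a flag.
#'
#' @param x Numeric vector, length >= 10 * k_max.
#' @param k_max Largest lag (>= 2). Default 10.
#' @return Object of class `hfd_result`: list with `dimension` (clipped to
#'   \[1, 2\]), `dimension_raw` (unclipped slope estimate), `k_values`,
#'   `curve_lengths`, `clipped`.
#' @export
higuchi_fd <- function(x, k_max = 10L) {
  k_max <- check_count(k_max, "k_max", min = 2L)
  x <- check_numeric_vector(x, "x", min_len = 1L)
  n <- length(x)
  if (n < 10L * k_max) {
    stop(sprintf("series too short for k_max=%d: need length >= %d, got %d",
                 k_max, 10L * k_max, n), call. = FALSE)
  }
  lk <- vapply(seq_len(k_max), function(k) {
    lm_k <- vapply(seq_len(k), function(m) {
      idx <- seq.int(m, n, by = k)
      nseg <- length(idx) - 1L
      sum(abs(diff(x[idx]))) * (n - 1) / (nseg * k) / k
    }, numeric(1))
    mean(lm_k)
  }, numeric(1))
  if (any(lk <= 0)) stop("degenerate (constant) signal: curve length is zero", call. = FALSE)
  dim_raw <- -ls_slope(log(seq_len(k_max)), log(lk))
  clipped <- dim_raw < 1 || dim_raw > 2
  structure(list(dimension = min(max(dim_raw, 1), 2),
                 dimension_raw = dim_raw,
                 k_values = seq_len(k_max),
                 curve_lengths = lk,
                 clipped = clipped),
            class = "hfd_result")
}

#' @export
print.hfd_result <- function(x, ...) {
  cat(sprintf("Higuchi FD: dimension = %.4f (k_max = %d%s)\n",
              x$dimension, max(x$k_values), if (x$clipped) ", clipped" else ""))
  invisible(x)
}

# Welch power spectral density: Hann taper, 50% overlap, one-sided.
welch_psd <- function(x, sampling_rate, segment_length = min(length(x), 256L),
                      overlap = 0.5) {
  n <- length(x)
  L <- as.integer(segment_length)
  step <- max(1L, as.integer(round(L * (1 - overlap))))
  starts <- seq.int(1L, n - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq.int(0L, L - 1L) / (L - 1L))  # Hann
  u <- sum(w^2)
  acc <- numeric(L)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w   # constant detrend per segment
    acc <- acc + Mod(stats::fft(seg))^2
  }
  psd <- acc / (length(starts) * u * sampling_rate)
  nf <- L %/% 2L + 1L
  one_sided <- psd[seq_len(nf)]
  # double interior bins to conserve total power in the one-sided form
  if (nf > 2L) one_sided[2:(nf - 1L)] <- 2 * one_sided[2:(nf - 1L)]
  list(frequencies = (seq_len(nf) - 1L) * sampling_rate / L, psd = one_sided)
}

#' Normalized spectral entropy
#'
#' Shannon entropy of the Welch power-spectral-density estimate, normalized by
#' ln(number of bins) to \[0, 1\]. Each Welch segment is mean-removed before
#' tapering (so the estimate is invariant under constant offsets), the DC bin
#' is discarded, and the remaining
#' spectrum treated as a probability distribution over frequency: a flat
#' (white) spectrum scores near 1, a single spectral line near 0.
#'
#' @param x Numeric vector, length >= 128, not all zero.
#' @param sampling_rate Sampling rate in Hz.
#' @param segment_length Welch segment length; default min(N, 256).
#' @return Object of class `spectral_entropy_result`: list with `entropy`,
#'   `frequencies`, `normalized_power`.
#' @export
spectral_entropy <- function(x, sampling_rate,
                             segment_length = min(length(x), 256L)) {
  x <- check_numeric_vector(x, "x", min_len = 128L)
  sampling_rate <- check_scalar(sampling_rate, "sampling_rate", lower = 1e-12)
  if (all(x == 0)) stop("degenerate input: all-zero signal has no spectrum", call. = FALSE)
  sp <- welch_psd(x, sampling_rate, segment_length = segment_length)
  p <- sp$psd[-1L]            # drop DC
  freqs <- sp$frequencies[-1L]
  tot <- sum(p)
  if (tot <= 0) stop("degenerate input: zero total spectral power", call. = FALSE)
  p <- p / tot
  nz <- p > 0
  h <- -sum(p[nz] * log(p[nz])) / log(length(p))
  structure(list(entropy = h, frequencies = freqs, normalized_power = p),
            class = "spectral_entropy_result")
}

#' @export
print.spectral_entropy_result <- function(x, ...) {
  cat(sprintf("Spectral entropy: %.4f over %d frequency bins\n",
              x$entropy, length(x$normalized_power)))
  invisible(x)
}

#' Names of the seven per-epoch features
#' @return Character vector of feature names in canonical order.
#' @export
feature_names <- function() {
  c("max", "variance", "kurtosis", "skewness", "dfa_alpha", "hfd", "spectral_entropy")
}

#' Extract the seven-feature vector from one epoch
#'
#' Computes maximum, variance, excess kurtosis, skewness, DFA exponent,
#' Higuchi fractal dimension and normalized spectral entropy with module
#' defaults, carrying the epoch's provenance.
#'
#' @param epoch An `eeg_epoch` (see [epoch_signal()]).
#' @param k_max Higuchi lag bound, default 10.
#' @param box_sizes Optional DFA box sizes (default log-spaced 4..N/4).
#' @return One-row data.frame: subject_id, channel, epoch plus the seven
#'   feature columns.
#' @export
extract_features <- function(epoch, k_max = 10L, box_sizes = NULL) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  x <- epoch$samples
  vals <- tryCatch(
    c(max = feat_max(x),
      variance = feat_variance(x),
      kurtosis = feat_kurtosis(x),
      skewness = feat_skewness(x),
      dfa_alpha = dfa(x, box_sizes = box_sizes)$alpha,
      hfd = higuchi_fd(x, k_max = k_max)$dimension,
      spectral_entropy = spectral_entropy(x, epoch$sampling_rate)$entropy),
    error = function(e) {
      stop(sprintf("feature extraction failed for subject '%s' channel '%s' epoch %d: %s",
                   epoch$subject_id, epoch$channel, epoch$index, conditionMessage(e)),
           call. = FALSE)
    })
  data.frame(subject_id = epoch$subject_id, channel = epoch$channel,
             epoch = epoch$index, t(vals), stringsAsFactors = FALSE)
}

#' Tidy per-epoch feature table for a set of epochs
#'
#' @param epochs List of `eeg_epoch` objects.
#' @inheritParams extract_features
#' @return Long data.frame: subject_id, channel, epoch, feature, value.
#' @export
features_table <- function(epochs, k_max = 10L, box_sizes = NULL) {
  wide <- do.call(rbind, lapply(epochs, extract_features,
                                k_max = k_max, box_sizes = box_sizes))
  long <- stats::reshape(wide, direction = "long",
                         varying = feature_names(), v.names = "value",
                         times = feature_names(), timevar = "feature",
                         idvar = c("subject_id", "channel", "epoch"))
  rownames(long) <- NULL
  long[order(long$subject_id, long$channel, long$epoch, long$feature), ]
}

#' Per-subject aggregate feature table
#'
#' Averages each channel-by-feature value over a subject's epochs, producing
#' one wide row per subject with columns named `<channel>.<feature>`
#' (channel-major, feature-minor order).
#'
#' @param feature_long Long table from [features_table()].
#' @return Wide data.frame, one row per subject, rownames = subject ids.
#' @export
aggregate_features <- function(feature_long) {
  stopifnot(all(c("subject_id", "channel", "feature", "value") %in% names(feature_long)))
  agg <- stats::aggregate(value ~ subject_id + channel + feature,
                          data = feature_long, FUN = mean)
  agg$col <- paste(agg$channel, agg$feature, sep = ".")
  subjects <- sort(unique(agg$subject_id))
  channels <- sort(unique(agg$channel))
  cols <- as.vector(t(outer(channels, feature_names(), paste, sep = ".")))
  out <- matrix(NA_real_, nrow = length(subjects), ncol = length(cols),
                dimnames = list(subjects, cols))
  out[cbind(match(agg$subject_id, subjects), match(agg$col, cols))] <- agg$value
  as.data.frame(out)
}
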