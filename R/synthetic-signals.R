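# Seeded synthetic-data generators: noise classes with known scaling
# structure, two-group EEG cohorts with injected band-power effects,
# scale-response cohorts with target group means, and hormone cohorts with an
# exact fraction of rhythm-disordered profiles. Every generator is a pure
# function of its arguments including the seed.

#' Gaussian white noise
#'
#' @param n Series length (>= 16).
#' @param seed Integer seed.
#' @return Numeric vector of i.i.d. standard normal samples. Its DFA scaling
#'   exponent is 0.5 in expectation.
#' @export
gen_white_noise <- function(n, seed) {
  n <- check_count(n, "n", min = 16L)
  withr::with_seed(seed, stats::rnorm(n))
}

#' Colored (1/f^beta) Gaussian noise via spectral shaping
#'
#' White Gaussian noise is shaped in the frequency domain by f^(-beta/2)
#' (Hermitian-symmetric, DC removed) and transformed back, giving an exact
#' target spectral slope in O(n log n). beta = 0 returns the white noise
#' untouched; beta = 1 is pink noise (DFA alpha ~ 1.0); beta = 2 is
#' Brownian-like (alpha ~ 1.5). Output is normalized to unit standard
#' deviation.
#'
#' @param n Series length (>= 64).
#' @param exponent Spectral slope beta in \[0, 2\].
#' @param seed Integer seed.
#' @return Numeric vector of length n.
#' @export
gen_colored_noise <- function(n, exponent, seed) {
  n <- check_count(n, "n", min = 64L)
  exponent <- check_scalar(exponent, "exponent", lower = 0, upper = 2)
  w <- withr::with_seed(seed, stats::rnorm(n))
  if (exponent == 0) return(w)
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k) / n           # symmetric frequency magnitude
  scale <- c(0, f[-1L]^(-exponent / 2))
  shaped <- Re(stats::fft(stats::fft(w) * scale, inverse = TRUE)) / n
  shaped / stats::sd(shaped)
}

# Band-limited Gaussian noise: white noise restricted to [f_lo, f_hi] Hz,
# unit SD. Used to inject band-power effects.
gen_bandlimited_noise <- function(n, sampling_rate, band, seed) {
  w <- withr::with_seed(seed, stats::rnorm(n))
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k) * sampling_rate / n
  keep <- f >= band[1L] & f <= band[2L]
  if (!any(keep)) stop("frequency band contains no spectral bins", call. = FALSE)
  shaped <- Re(stats::fft(stats::fft(w) * keep, inverse = TRUE)) / n
  shaped / stats::sd(shaped)
}

#' Specification of a synthetic two-group cohort
#'
#' Bundles the sample size, recording geometry, effect descriptor and seed
#' that define a simulated study. Defaults describe the emulated acquisition:
#' 250 Hz sampling, 16 channels, 60-s recordings, and an additive alpha-band
#' (8-13 Hz) power effect of 1 SD amplitude on the first half of the channels
#' in the depressed group.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param n_channels Number of EEG channels.
#' @param sampling_rate Sampling rate in Hz.
#' @param duration Recording length in seconds.
#' @param effect Named list: `type` ("band_power" or "none"), `band` (Hz),
#'   `magnitude` (SD of the injected band-limited component relative to the
#'   unit-SD pink background), `channels` (labels; NULL = first half).
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = 30L, n_channels = 16L,
                        sampling_rate = 250, duration = 60,
                        effect = list(type = "band_power", band = c(8, 13),
                                      magnitude = 1.0, channels = NULL),
                        seed = 1L) {
  n_per_group <- check_count(n_per_group, "n_per_group", min = 2L)
  n_channels <- check_count(n_channels, "n_channels")
  sampling_rate <- check_scalar(sampling_rate, "sampling_rate", lower = 1e-9)
  duration <- check_scalar(duration, "duration", lower = 1e-9)
  if (!is.list(effect) || is.null(effect$type)) {
    stop("effect must be a named list with a 'type'", call. = FALSE)
  }
  if (effect$type == "band_power") {
    if (is.null(effect$magnitude) || !is.finite(effect$magnitude)) {
      stop("band_power effect needs a finite 'magnitude'", call. = FALSE)
    }
    stopifnot(length(effect$band) == 2L, effect$band[1L] < effect$band[2L])
  }
  structure(list(n_per_group = n_per_group, n_channels = n_channels,
                 sampling_rate = sampling_rate, duration = duration,
                 effect = effect, seed = check_count(seed, "seed", min = 0L)),
            class = "cohort_spec")
}

#' Generate a two-group EEG cohort
#'
#' Each subject gets `n_channels` of unit-SD pink-noise (1/f) background;
#' subjects in the depressed group additionally receive an additive
#' band-limited component in the effect band on the designated channels,
#' scaled by the effect magnitude and a per-subject gain (N(1, 0.2),
#' truncated at 0.2) that emulates between-subject variability.
#'
#' @param spec A `cohort_spec`.
#' @return List of class `eeg_cohort`: `recordings` (list of
#'   `eeg_recording`), `labels` (named factor, "depressed"/"control"),
#'   `spec`, `metadata` (incl. a low-power warning flag for null effects with
#'   tiny groups).
#' @export
gen_eeg_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_samp <- as.integer(round(spec$duration * spec$sampling_rate))
  ch_labels <- sprintf("ch%02d", seq_len(spec$n_channels))
  eff <- spec$effect
  null_effect <- eff$type == "none" ||
    (eff$type == "band_power" && isTRUE(eff$magnitude == 0))
  eff_channels <- if (!null_effect) {
    if (is.null(eff$channels)) ch_labels[seq_len(max(1L, spec$n_channels %/% 2L))]
    else eff$channels
  } else character(0)

  recordings <- list()
  labels <- character(0)
  for (g in 1:2) {
    grp_label <- if (g == 1L) "depressed" else "control"
    for (s in seq_len(spec$n_per_group)) {
      sid <- sprintf("%s_%02d", if (g == 1L) "dep" else "ctl", s)
      gain <- max(0.2, withr::with_seed(derive_seed(spec$seed, g, s, 0L),
                                        stats::rnorm(1, mean = 1, sd = 0.2)))
      data <- stats::setNames(vector("list", spec$n_channels), ch_labels)
      for (ci in seq_len(spec$n_channels)) {
        ch_seed <- derive_seed(spec$seed, g, s, ci)
        bg <- gen_colored_noise(n_samp, exponent = 1, seed = ch_seed)
        if (g == 1L && ch_labels[ci] %in% eff_channels) {
          bl <- gen_bandlimited_noise(n_samp, spec$sampling_rate, eff$band,
                                      seed = derive_seed(spec$seed, g, s, ci, 7L))
          bg <- bg + gain * eff$magnitude * bl
        }
        data[[ci]] <- bg
      }
      recordings[[sid]] <- eeg_recording(data, spec$sampling_rate, subject_id = sid)
      labels[sid] <- grp_label
    }
  }
  warn <- NULL
  if (null_effect && spec$n_per_group < 4L) {
    warn <- "null effect with n_per_group < 4: downstream estimates will be unstable"
  }
  structure(list(recordings = recordings,
                 labels = factor(labels, levels = c("control", "depressed")),
                 spec = spec,
                 metadata = list(seed = spec$seed, warning = warn,
                                 effect_channels = eff_channels)),
            class = "eeg_cohort")
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat(sprintf("Synthetic EEG cohort: %d + %d subjects, %d channels, %.0f s at %g Hz\n",
              sum(x$labels == "depressed"), sum(x$labels == "control"),
              x$spec$n_channels, x$spec$duration, x$spec$sampling_rate))
  invisible(x)
}

# Draw one subject's item vector whose (possibly reverse-scored) total equals
# the integer target exactly: start at the per-item floor and distribute the
# remaining points uniformly over items with headroom.
allocate_items <- function(target, item_min, item_max) {
  items <- item_min
  pts <- target - sum(item_min)
  while (pts > 0L) {
    room <- which(items < item_max)
    i <- room[sample.int(length(room), 1L)]
    items[i] <- items[i] + 1L
    pts <- pts - 1L
  }
  items
}

#' Generate a two-group scale-response cohort
#'
#' Draws each subject's target total from a normal distribution truncated to
#' the instrument's admissible range, then fills item-level responses that
#' sum to that total exactly. Defaults emulate the study's subtype groups:
#' HAMD-24 totals 31.81 +/- 5.39 (A-MDD) vs 25.25 +/- 5.02 (NA-MDD), n = 21
#' per group.
#'
#' @param n_per_group Subjects per group.
#' @param means,sds Length-2 target total mean/SD per group.
#' @param instrument "hamd" or "tas".
#' @param group_names Labels for the two groups.
#' @param seed Integer seed.
#' @param config Optional instrument configuration override.
#' @return data.frame: subject_id, group, item_1..item_N.
#' @export
gen_scale_cohort <- function(n_per_group = 21L, means = c(31.81, 25.25),
                             sds = c(5.39, 5.02),
                             instrument = c("hamd", "tas"),
                             group_names = c("A-MDD", "NA-MDD"),
                             seed = 1L, config = NULL) {
  n_per_group <- check_count(n_per_group, "n_per_group", min = 2L)
  instrument <- match.arg(instrument)
  cfg <- config %||% if (instrument == "hamd") hamd_config() else tas_config()
  lo <- sum(cfg$item_min); hi <- sum(cfg$item_max)
  if (any(means < lo) || any(means > hi)) {
    stop(sprintf("target means must lie in the achievable total range [%d, %d]",
                 lo, hi), call. = FALSE)
  }
  stopifnot(length(means) == 2L, length(sds) == 2L, all(sds > 0))
  withr::with_seed(seed, {
    rows <- list()
    for (g in 1:2) {
      for (s in seq_len(n_per_group)) {
        target <- NA_integer_
        repeat {  # truncated-normal draw of the subject's total
          cand <- round(stats::rnorm(1, means[g], sds[g]))
          if (cand >= lo && cand <= hi) { target <- as.integer(cand); break }
        }
        items <- allocate_items(target, cfg$item_min, cfg$item_max)
        row <- data.frame(subject_id = sprintf("%s_%02d", group_names[g], s),
                          group = group_names[g], stringsAsFactors = FALSE)
        for (i in seq_along(items)) row[[sprintf("item_%d", i)]] <- items[i]
        rows[[length(rows) + 1L]] <- row
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate a hormone cohort with an exact fraction of disturbed profiles
#'
#' Profiles are built by direct construction: the 08:00 concentration is
#' drawn log-normally around a physiological baseline, and the 16:00/24:00
#' values are set as fractions of the earlier draws on the appropriate side
#' of the 50% decline thresholds — so rhythm-disorder status is exact by
#' construction (and re-verified against [classify_rhythm()]). Exactly
#' `round(n * crd_fraction)` profiles violate a decline rule.
#'
#' @param n Number of profiles (>= 1).
#' @param crd_fraction Fraction of rhythm-disordered profiles in \[0, 1\].
#' @param seed Integer seed.
#' @param analyte "COR" (baseline ~450 nmol/L) or "ACTH" (~40 pg/mL).
#' @param group Optional group label attached to every profile.
#' @return data.frame: subject_id, analyte, c8, c16, c24, crd_true (and
#'   `group` when given).
#' @export
gen_hormone_cohort <- function(n, crd_fraction, seed, analyte = c("COR", "ACTH"),
                               group = NULL) {
  n <- check_count(n, "n", min = 1L)
  crd_fraction <- check_scalar(crd_fraction, "crd_fraction", lower = 0, upper = 1)
  analyte <- match.arg(analyte)
  baseline <- if (analyte == "COR") 450 else 40
  n_crd <- round(n * crd_fraction)
  out <- withr::with_seed(seed, {
    status <- sample(c(rep(TRUE, n_crd), rep(FALSE, n - n_crd)))
    c8 <- baseline * exp(stats::rnorm(n, 0, 0.25))
    r1 <- numeric(n); r2 <- numeric(n)
    normal <- !status
    r1[normal] <- stats::runif(sum(normal), 0.20, 0.45)
    r2[normal] <- stats::runif(sum(normal), 0.20, 0.45)
    # disturbed: violate exactly one decline rule, alternating which
    which_rule <- sample(c("16v8", "24v16"), n, replace = TRUE)
    i1 <- status & which_rule == "16v8"
    r1[i1] <- stats::runif(sum(i1), 0.50, 0.95)
    r2[i1] <- stats::runif(sum(i1), 0.20, 0.45)
    i2 <- status & which_rule == "24v16"
    r1[i2] <- stats::runif(sum(i2), 0.20, 0.45)
    r2[i2] <- stats::runif(sum(i2), 0.50, 0.95)
    data.frame(subject_id = sprintf("s%03d", seq_len(n)),
               analyte = analyte,
               c8 = c8, c16 = r1 * c8, c24 = r2 * r1 * c8,
               crd_true = status, stringsAsFactors = FALSE)
  })
  verdict <- classify_rhythm(out$c8, out$c16, out$c24)
  stopifnot(identical(verdict$disturbed, out$crd_true))
  if (!is.null(group)) out$group <- group
  out
}

#' Write a cohort's recordings and labels to a directory
#'
#' Recordings go to `<subject_id>.csv` (or `.edf`), labels to `labels.csv`,
#' and the generating spec/seed to a `metadata.json` sidecar.
#'
#' @param cohort An `eeg_cohort`.
#' @param dir Output directory (created if missing).
#' @param format "csv" or "edf".
#' @return `dir`, invisibly.
#' @export
write_eeg_cohort <- function(cohort, dir, format = c("csv", "edf")) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  format <- match.arg(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (sid in names(cohort$recordings)) {
    write_recording(cohort$recordings[[sid]],
                    file.path(dir, paste0(sid, ".", format)), format = format)
  }
  utils::write.csv(data.frame(subject_id = names(cohort$labels),
                              label = as.character(cohort$labels)),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  meta <- cohort$spec
  class(meta) <- NULL
  jsonlite::write_json(c(meta, list(warning = cohort$metadata$warning)),
                       file.path(dir, "metadata.json"), auto_unbox = TRUE,
                       null = "null")
  invisible(dir)
}
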