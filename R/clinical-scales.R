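# Deterministic scoring and severity banding for HAMD-24 and TAS-20,
# including the anxious-depression subtype gate on the HAMD
# anxiety/somatization factor.

#' Default HAMD-24 instrument configuration
#'
#' Per-item admissible ranges and the 7-factor structure of the 24-item
#' Hamilton Depression Rating Scale. Most items score 0-4; the insomnia,
#' somatic, genital, weight, insight, diurnal-variation and obsessional items
#' score 0-2. The factor map is the standard 7-factor HAMD-24 structure
#' widely used with the Chinese version (anxiety/somatization 10,11,12,13,15,17;
#' body weight 16; cognitive impairment 2,3,9,19,20,21; diurnal variation 18;
#' retardation 1,7,8,14; sleep disturbance 4,5,6; hopelessness 22,23,24) —
#' sourced from common clinical practice, not fixed by the instrument itself,
#' and therefore editable. Severity bands on the total score: > 35 severe,
#' 20-35 definite, 8-19 possible, < 8 normal (the 20-point boundary is
#' resolved upward into "definite").
#'
#' @return A list with `item_min`, `item_max` (length-24 integer vectors),
#'   `factor_map` (named list of item indices), and `bands`.
#' @export
hamd_config <- function() {
  item_max <- rep(4L, 24L)
  item_max[c(4L, 5L, 6L, 12L, 13L, 14L, 16L, 17L, 18L, 21L)] <- 2L
  cfg <- list(
    n_items = 24L,
    item_min = rep(0L, 24L),
    item_max = item_max,
    factor_map = list(
      anxiety_somatization = c(10L, 11L, 12L, 13L, 15L, 17L),
      body_weight = 16L,
      cognitive_impairment = c(2L, 3L, 9L, 19L, 20L, 21L),
      diurnal_variation = 18L,
      retardation = c(1L, 7L, 8L, 14L),
      sleep_disturbance = c(4L, 5L, 6L),
      hopelessness = c(22L, 23L, 24L)),
    bands = list(severe = 36L, definite = 20L, possible = 8L))
  validate_factor_partition(cfg$factor_map, 24L, "HAMD-24")
  cfg
}

#' Default TAS-20 instrument configuration
#'
#' 20 items scored 1-5; items 4, 5, 10, 18 and 19 are reverse-scored
#' (v -> 6 - v). Factors: DIF (difficulty identifying feelings) = items
#' 1,3,6,7,9,13,14; DDF (difficulty describing feelings) = 2,4,11,12,17;
#' EOT (externally oriented thinking) = 5,8,10,15,16,18,19,20. Bands on the
#' total (range 20-100): <= 51 non-alexithymia, 52-60 moderate, >= 61 severe.
#'
#' @return A list with `item_min`, `item_max`, `reverse_items`, `factor_map`,
#'   `bands`.
#' @export
tas_config <- function() {
  cfg <- list(
    n_items = 20L,
    item_min = rep(1L, 20L),
    item_max = rep(5L, 20L),
    reverse_items = c(4L, 5L, 10L, 18L, 19L),
    factor_map = list(
      DIF = c(1L, 3L, 6L, 7L, 9L, 13L, 14L),
      DDF = c(2L, 4L, 11L, 12L, 17L),
      EOT = c(5L, 8L, 10L, 15L, 16L, 18L, 19L, 20L)),
    bands = list(severe = 61L, moderate = 52L))
  validate_factor_partition(cfg$factor_map, 20L, "TAS-20")
  cfg
}

# Factors must partition the items exactly: no overlap, no gaps.
validate_factor_partition <- function(factor_map, n_items, label) {
  all_items <- sort(unlist(factor_map, use.names = FALSE))
  if (!identical(all_items, seq_len(n_items))) {
    stop(sprintf("%s factor map must partition items 1..%d exactly", label, n_items),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Load an instrument configuration from YAML or JSON
#'
#' @param path File path ending in .yaml/.yml or .json.
#' @return Configuration list in the shape of [hamd_config()] / [tas_config()].
#' @export
read_scale_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg$factor_map <- lapply(cfg$factor_map, as.integer)
  validate_factor_partition(cfg$factor_map, cfg$n_items, basename(path))
  cfg
}

validate_items <- function(items, cfg, label) {
  if (length(items) != cfg$n_items) {
    stop(sprintf("%s requires exactly %d item scores (got %d)",
                 label, cfg$n_items, length(items)), call. = FALSE)
  }
  if (anyNA(items) || !is.numeric(items) || any(items != round(items))) {
    bad <- which(is.na(items) | items != round(items))
    stop(sprintf("%s items must be integers; offending item(s): %s",
                 label, paste(bad, collapse = ", ")), call. = FALSE)
  }
  oob <- which(items < cfg$item_min | items > cfg$item_max)
  if (length(oob) > 0L) {
    stop(sprintf("%s item(s) out of admissible range: %s",
                 label, paste(oob, collapse = ", ")), call. = FALSE)
  }
  as.integer(items)
}

#' Score a HAMD-24 response
#'
#' Total = sum of the 24 items; factor scores are per-factor sums; severity
#' band: total > 35 severe, 20-35 definite, 8-19 possible, < 8 normal.
#'
#' @param items Integer vector of 24 item scores within per-item ranges.
#' @param config Instrument configuration (default [hamd_config()]).
#' @return A `scale_result`: list with `total`, `factor_scores`, `band`.
#' @export
score_hamd <- function(items, config = hamd_config()) {
  items <- validate_items(items, config, "HAMD-24")
  total <- sum(items)
  fs <- vapply(config$factor_map, function(ix) sum(items[ix]), numeric(1))
  b <- config$bands
  band <- if (total >= b$severe) "severe"
          else if (total >= b$definite) "definite"
          else if (total >= b$possible) "possible"
          else "normal"
  structure(list(instrument = "HAMD-24", total = total,
                 factor_scores = fs, band = band),
            class = "scale_result")
}

#' Anxious-depression subtype gate
#'
#' Classifies a depressed patient by the HAMD anxiety/somatization factor:
#' score >= 7 is A-MDD (with anxiety), <= 2 is NA-MDD (without), 3-6 is
#' indeterminate (such patients fall outside both study groups).
#'
#' @param items 24 HAMD item scores, or a `scale_result` from [score_hamd()].
#' @param config Instrument configuration; must include an
#'   `anxiety_somatization` factor.
#' @return "A-MDD", "NA-MDD", or "indeterminate".
#' @export
classify_anxiety_subtype <- function(items, config = hamd_config()) {
  if (inherits(items, "scale_result")) {
    fs <- items$factor_scores
  } else {
    fs <- score_hamd(items, config)$factor_scores
  }
  if (!"anxiety_somatization" %in% names(fs)) {
    stop("configuration error: factor map lacks 'anxiety_somatization'", call. = FALSE)
  }
  s <- fs[["anxiety_somatization"]]
  if (s >= 7) "A-MDD" else if (s <= 2) "NA-MDD" else "indeterminate"
}

#' Score a TAS-20 response
#'
#' Reverse-scores items 4, 5, 10, 18, 19 (v -> 6 - v), sums to a total in
#' \[20, 100\], computes the DIF/DDF/EOT factor scores from the scored items,
#' and bands: <= 51 non-alexithymia, 52-60 moderate, >= 61 severe.
#'
#' @param items Integer vector of 20 item scores in 1..5.
#' @param config Instrument configuration (default [tas_config()]).
#' @return A `scale_result`: list with `total`, `factor_scores`, `band`.
#' @export
score_tas <- function(items, config = tas_config()) {
  items <- validate_items(items, config, "TAS-20")
  scored <- items
  scored[config$reverse_items] <- 6L - scored[config$reverse_items]
  total <- sum(scored)
  fs <- vapply(config$factor_map, function(ix) sum(scored[ix]), numeric(1))
  b <- config$bands
  band <- if (total >= b$severe) "severe_alexithymia"
          else if (total >= b$moderate) "moderate_alexithymia"
          else "non_alexithymia"
  structure(list(instrument = "TAS-20", total = total,
                 factor_scores = fs, band = band),
            class = "scale_result")
}

#' @export
print.scale_result <- function(x, ...) {
  cat(sprintf("%s: total %d (%s); factors: %s\n", x$instrument, x$total, x$band,
              paste(sprintf("%s=%g", names(x$factor_scores), x$factor_scores),
                    collapse = ", ")))
  invisible(x)
}

#' Batch-score a table of item responses
#'
#' Scores one row per subject. Malformed rows are reported with their row
#' number and error message but do not prevent valid rows from being scored.
#'
#' @param responses CSV path or data.frame with a `subject_id` column (or
#'   rownames) plus item columns `item_1` .. `item_N` in order.
#' @param instrument "hamd" or "tas".
#' @param config Optional instrument configuration override.
#' @return data.frame: subject_id, valid, error, total, band, one column per
#'   factor score.
#' @export
batch_score <- function(responses, instrument = c("hamd", "tas"), config = NULL) {
  instrument <- match.arg(instrument)
  if (is.character(responses) && length(responses) == 1L) {
    responses <- utils::read.csv(responses, check.names = FALSE)
  }
  cfg <- config %||% if (instrument == "hamd") hamd_config() else tas_config()
  scorer <- if (instrument == "hamd") score_hamd else score_tas
  item_cols <- grep("^item_[0-9]+$", names(responses), value = TRUE)
  item_cols <- item_cols[order(as.integer(sub("item_", "", item_cols)))]
  ids <- if (!is.null(responses[["subject_id"]])) as.character(responses$subject_id)
         else rownames(responses)
  fac_names <- names(cfg$factor_map)
  rows <- lapply(seq_len(nrow(responses)), function(i) {
    base <- data.frame(subject_id = ids[i], valid = FALSE, error = NA_character_,
                       total = NA_integer_, band = NA_character_,
                       stringsAsFactors = FALSE)
    for (fn in fac_names) base[[fn]] <- NA_real_
    res <- tryCatch(scorer(as.numeric(responses[i, item_cols]), cfg),
                    error = function(e) e)
    if (inherits(res, "error")) {
      base$error <- sprintf("row %d: %s", i, conditionMessage(res))
    } else {
      base$valid <- TRUE
      base$total <- res$total
      base$band <- res$band
      for (fn in fac_names) base[[fn]] <- res$factor_scores[[fn]]
    }
    base
  })
  do.call(rbind, rows)
}
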