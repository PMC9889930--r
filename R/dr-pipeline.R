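# Depression-recognition pipeline: feature-matrix assembly, SMOTE class
# balancing, leakage-safe z-score normalization, four feature-selection
# routes, classification, and repeated stratified cross-validation.

# glmnet and ranger must be loaded (not just ::-referenced) so their S3
# predict methods are registered when models are restored from disk.
#' @importFrom glmnet glmnet
#' @importFrom ranger ranger
NULL

#' Assemble a labeled feature matrix
#'
#' Binds per-subject feature records into a wide numeric matrix with a binary
#' label vector. Column order is canonical (channel-major, feature-minor when
#' columns are named `<channel>.<feature>`; lexicographic otherwise) and rows
#' are sorted by subject id, so permuted input yields an identical matrix.
#'
#' @param features Wide data.frame/matrix of per-subject features (rownames or
#'   a `subject_id` column identify subjects), or a list of one-row
#'   per-subject records with identical feature names.
#' @param labels Named vector/factor of class labels covering every subject.
#' @param positive_class Label treated as positive for recall/precision.
#'   Default: "depressed" or "A-MDD" if present, else the first level.
#' @return A `feature_matrix`: list with `x` (numeric matrix), `labels`
#'   (factor), `positive_class`.
#' @export
assemble_matrix <- function(features, labels, positive_class = NULL) {
  if (is.list(features) && !is.data.frame(features)) {
    name_sets <- lapply(features, function(r) sort(colnames(r)))
    if (length(unique(name_sets)) != 1L) {
      all_names <- unique(unlist(name_sets))
      diffs <- vapply(name_sets, function(s) paste(setdiff(all_names, s), collapse = ","),
                      character(1))
      stop(sprintf("mismatched feature sets across subjects; missing: %s",
                   paste(unique(diffs[diffs != ""]), collapse = " | ")), call. = FALSE)
    }
    features <- do.call(rbind, features)
  }
  if (is.data.frame(features) && !is.null(features[["subject_id"]])) {
    rownames(features) <- features$subject_id
    features <- features[, setdiff(colnames(features), "subject_id"), drop = FALSE]
  }
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("feature matrix contains missing values", call. = FALSE)
  if (anyDuplicated(colnames(x))) stop("duplicate feature names", call. = FALSE)
  subjects <- rownames(x)
  if (is.null(subjects)) subjects <- as.character(seq_len(nrow(x)))
  if (is.null(names(labels))) {
    if (length(labels) != nrow(x)) stop("labels must cover all subjects", call. = FALSE)
    names(labels) <- subjects
  }
  missing_lab <- setdiff(subjects, names(labels))
  if (length(missing_lab) > 0L) {
    stop(sprintf("missing label for subject(s): %s", paste(missing_lab, collapse = ", ")),
         call. = FALSE)
  }
  ord_row <- order(subjects)
  x <- x[ord_row, , drop = FALSE]
  # canonical channel-major, feature-minor column order
  cn <- colnames(x)
  parts <- regmatches(cn, regexec("^(.*)\\.([^.]+)$", cn))
  if (all(lengths(parts) == 3L)) {
    ch <- vapply(parts, `[`, character(1), 2L)
    ft <- vapply(parts, `[`, character(1), 3L)
    fo <- match(ft, feature_names())
    fo[is.na(fo)] <- length(feature_names()) + 1L
    x <- x[, order(ch, fo, ft), drop = FALSE]
  } else {
    x <- x[, order(cn), drop = FALSE]
  }
  lab <- factor(unname(labels[rownames(x)]))
  if (nlevels(lab) != 2L) stop("labels must have exactly two classes", call. = FALSE)
  if (any(table(lab) < 2L)) stop("need at least 2 subjects per class", call. = FALSE)
  if (is.null(positive_class)) {
    hit <- intersect(c("depressed", "A-MDD"), levels(lab))
    positive_class <- if (length(hit) > 0L) hit[1L] else levels(lab)[1L]
  }
  if (!positive_class %in% levels(lab)) stop("positive_class not among labels", call. = FALSE)
  structure(list(x = x, labels = lab, positive_class = positive_class),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("Feature matrix: %d subjects x %d features (%s; positive = %s)\n",
              nrow(x$x), ncol(x$x),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              x$positive_class))
  invisible(x)
}

#' SMOTE minority oversampling
#'
#' Grows the minority class to the majority size by interpolating new rows
#' uniformly on the segment between a randomly chosen minority row and one of
#' its `k_neighbors` nearest minority neighbors (Euclidean distance).
#' Original rows are preserved unchanged; an already balanced matrix is
#' returned as-is.
#'
#' @param m A `feature_matrix`.
#' @param k_neighbors Number of nearest minority neighbors (default 5).
#' @param seed Integer seed controlling base/neighbor/gap draws.
#' @return A balanced `feature_matrix`; synthetic rows are named
#'   `smote_<i>` and flagged in attribute `synthetic`.
#' @export
smote_oversample <- function(m, k_neighbors = 5L, seed = 1L) {
  stopifnot(inherits(m, "feature_matrix"))
  k_neighbors <- check_count(k_neighbors, "k_neighbors")
  tab <- table(m$labels)
  if (tab[1L] == tab[2L]) return(m)
  minority <- names(tab)[which.min(tab)]
  n_min <- min(tab); n_new <- max(tab) - n_min
  if (n_min < k_neighbors + 1L) {
    stop(sprintf(paste0("minority class has %d rows, too few for k_neighbors=%d; ",
                        "use k_neighbors <= %d"), n_min, k_neighbors, n_min - 1L),
         call. = FALSE)
  }
  xm <- m$x[m$labels == minority, , drop = FALSE]
  d <- as.matrix(stats::dist(xm))
  diag(d) <- Inf
  nn <- t(apply(d, 1L, function(r) order(r)[seq_len(k_neighbors)]))
  synth <- withr::with_seed(seed, {
    base <- sample.int(n_min, n_new, replace = TRUE)
    pick <- nn[cbind(base, sample.int(k_neighbors, n_new, replace = TRUE))]
    gap <- stats::runif(n_new)
    xm[base, , drop = FALSE] + gap * (xm[pick, , drop = FALSE] - xm[base, , drop = FALSE])
  })
  rownames(synth) <- sprintf("smote_%d", seq_len(n_new))
  out <- m
  out$x <- rbind(m$x, synth)
  out$labels <- factor(c(as.character(m$labels), rep(minority, n_new)),
                       levels = levels(m$labels))
  attr(out, "synthetic") <- rownames(synth)
  out
}

#' Fit / apply a per-feature z-score normalizer
#'
#' Parameters (mean, sd) are estimated from the training rows only; applying
#' them to held-out rows never re-estimates anything, which is the no-leakage
#' contract of the cross-validation loop. Constant features (sd = 0) are
#' dropped with a warning.
#'
#' @param train A `feature_matrix` (or numeric matrix) of training rows.
#' @return A `dr_normalizer`: list with `mean`, `sd`, `features`.
#' @export
fit_normalizer <- function(train) {
  x <- if (inherits(train, "feature_matrix")) train$x else as.matrix(train)
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  keep <- sdv > 1e-12
  if (!all(keep)) {
    warning(sprintf("dropping constant feature(s): %s",
                    paste(colnames(x)[!keep], collapse = ", ")))
  }
  structure(list(mean = mu[keep], sd = sdv[keep], features = colnames(x)[keep]),
            class = "dr_normalizer")
}

#' @rdname fit_normalizer
#' @param params A fitted `dr_normalizer`.
#' @param m A `feature_matrix` (or numeric matrix) to transform.
#' @return The z-scored object, restricted to the normalizer's features.
#' @export
apply_normalizer <- function(params, m) {
  stopifnot(inherits(params, "dr_normalizer"))
  x <- if (inherits(m, "feature_matrix")) m$x else as.matrix(m)
  missing_f <- setdiff(params$features, colnames(x))
  if (length(missing_f) > 0L) {
    stop(sprintf("feature name mismatch; absent from input: %s",
                 paste(missing_f, collapse = ", ")), call. = FALSE)
  }
  z <- sweep(sweep(x[, params$features, drop = FALSE], 2L, params$mean, "-"),
             2L, params$sd, "/")
  if (inherits(m, "feature_matrix")) { m$x <- z; m } else z
}

new_selection_result <- function(method, selected, scores) {
  structure(list(method = method, selected = selected, scores = scores),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("Selection (%s): %d feature(s) kept\n", x$method, length(x$selected)))
  invisible(x)
}

#' L1-penalized (lasso) feature selection
#'
#' Fits an L1-penalized logistic model and keeps features with non-zero
#' coefficients at the given penalty; scores are absolute coefficients.
#'
#' @param m A normalized `feature_matrix`.
#' @param penalty_strength Lasso penalty lambda (default 0.01).
#' @param seed Unused (the coordinate-descent fit is deterministic); kept for
#'   interface symmetry with the other routes.
#' @return A `selection_result` with features ordered by |coefficient|.
#' @export
select_l1 <- function(m, penalty_strength = 0.01, seed = 1L) {
  stopifnot(inherits(m, "feature_matrix"))
  fit <- glmnet::glmnet(m$x, m$labels, family = "binomial", alpha = 1,
                        standardize = FALSE)
  # exact refit at the requested penalty (the default path does not extend
  # below its own lambda_min, which matters for penalty -> 0)
  cf <- as.numeric(glmnet::coef.glmnet(fit, s = penalty_strength, exact = TRUE,
                                       x = m$x, y = m$labels))[-1L]
  names(cf) <- colnames(m$x)
  scores <- abs(cf)
  selected <- names(scores)[scores > 0]
  if (length(selected) == 0L) {
    warning("L1 penalty shrank all coefficients to zero; empty selection")
  }
  selected <- selected[order(-scores[selected], match(selected, colnames(m$x)))]
  new_selection_result("l1", selected, scores)
}

#' Tree-ensemble (impurity importance) feature selection
#'
#' Fits a seeded random forest and keeps features whose normalized impurity
#' importance exceeds the threshold rule. Importances are normalized to sum
#' to 1; ties are broken by canonical column order.
#'
#' @param m A normalized `feature_matrix`.
#' @param importance_threshold "mean", "median", or a numeric cutoff on the
#'   normalized importances.
#' @param seed Integer seed for the forest.
#' @param num_trees Number of trees (default 500).
#' @return A `selection_result` with features ordered by importance.
#' @export
select_tree <- function(m, importance_threshold = "mean", seed = 1L,
                        num_trees = 500L) {
  stopifnot(inherits(m, "feature_matrix"))
  df <- data.frame(m$x, check.names = FALSE)
  df$.label <- m$labels
  fit <- ranger::ranger(dependent.variable.name = ".label", data = df,
                        importance = "impurity", num.trees = num_trees,
                        seed = seed, respect.unordered.factors = TRUE)
  imp <- fit$variable.importance[colnames(m$x)]
  imp[imp < 0] <- 0
  scores <- if (sum(imp) > 0) imp / sum(imp) else imp
  cutoff <- switch(as.character(importance_threshold),
                   mean = mean(scores), median = stats::median(scores),
                   check_scalar(importance_threshold, "importance_threshold", 0, 1))
  selected <- names(scores)[scores > cutoff |
                              (!is.character(importance_threshold) & scores >= cutoff)]
  selected <- selected[order(-scores[selected], match(selected, colnames(m$x)))]
  new_selection_result("tree", selected, scores)
}

# Vectorized two-sample Welch t-test across matrix columns.
welch_t_columns <- function(x, g) {
  g <- as.factor(g)
  i1 <- g == levels(g)[1L]
  n1 <- sum(i1); n2 <- sum(!i1)
  m1 <- colMeans(x[i1, , drop = FALSE]); m2 <- colMeans(x[!i1, , drop = FALSE])
  v1 <- apply(x[i1, , drop = FALSE], 2L, stats::var)
  v2 <- apply(x[!i1, , drop = FALSE], 2L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(t = tstat, df = df, p = p, degenerate = se2 <= 0)
}

#' FDR-corrected univariate feature selection
#'
#' Per-feature two-sample Welch t-test between the classes with
#' Benjamini-Hochberg adjustment; keeps features with adjusted p below
#' `alpha_level`. Features with zero variance in both classes are skipped
#' (listed in attribute `skipped`).
#'
#' @param m A `feature_matrix` with >= 2 samples per class.
#' @param alpha_level FDR level (default 0.05).
#' @return A `selection_result`; scores are BH-adjusted p-values.
#' @export
select_fdr <- function(m, alpha_level = 0.05) {
  stopifnot(inherits(m, "feature_matrix"))
  wt <- welch_t_columns(m$x, m$labels)
  usable <- !wt$degenerate & is.finite(wt$p)
  p_adj <- rep(NA_real_, ncol(m$x))
  names(p_adj) <- colnames(m$x)
  p_adj[usable] <- stats::p.adjust(wt$p[usable], method = "BH")
  selected <- names(p_adj)[usable & p_adj < alpha_level]
  selected <- selected[order(p_adj[selected], match(selected, colnames(m$x)))]
  res <- new_selection_result("fdr", selected, p_adj)
  attr(res, "skipped") <- colnames(m$x)[!usable]
  res
}

#' Run one of the four feature-selection routes
#'
#' @param m A normalized `feature_matrix`.
#' @param method "all", "l1", "tree", or "fdr".
#' @param seed Integer seed (used by the stochastic routes).
#' @param ... Passed to the route-specific function.
#' @return A `selection_result`.
#' @export
select_features <- function(m, method = c("all", "l1", "tree", "fdr"),
                            seed = 1L, ...) {
  method <- match.arg(method)
  switch(method,
         all = new_selection_result("all", colnames(m$x),
                                    stats::setNames(rep(1, ncol(m$x)), colnames(m$x))),
         l1 = select_l1(m, seed = seed, ...),
         tree = select_tree(m, seed = seed, ...),
         fdr = select_fdr(m, ...))
}

# Fit the configured classifier on selected, normalized features.
# Returns a closure-free fit object with its own predict helper.
fit_classifier <- function(x, y, config, positive_class) {
  type <- config$type %||% "ridge"
  lev <- levels(y)
  if (ncol(x) == 0L) {
    # empty selection: fall back to the training prior of the second level
    return(list(type = "prior", p2 = mean(y == lev[2L]), levels = lev))
  }
  if (type == "ridge") {
    lambda <- config$lambda %||% 0.01
    if (ncol(x) >= 2L) {
      fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                            standardize = FALSE)
      list(type = "ridge", fit = fit, lambda = lambda, levels = lev)
    } else {
      df <- data.frame(f1 = x[, 1L], .y = as.integer(y == lev[2L]))
      fit <- suppressWarnings(stats::glm(.y ~ f1, data = df, family = stats::binomial()))
      list(type = "glm1", fit = fit, feature = colnames(x)[1L], levels = lev)
    }
  } else if (type == "tree") {
    df <- data.frame(x, check.names = FALSE)
    df$.label <- y
    fit <- ranger::ranger(dependent.variable.name = ".label", data = df,
                          probability = TRUE,
                          num.trees = config$num_trees %||% 500L,
                          seed = config$seed %||% 1L)
    list(type = "tree", fit = fit, levels = lev)
  } else {
    stop(sprintf("unknown classifier type '%s'", type), call. = FALSE)
  }
}

# Probability of the second factor level for each row of x.
predict_classifier <- function(cl, x) {
  if (cl$type == "prior") return(rep(cl$p2, nrow(x)))
  if (cl$type == "ridge") {
    as.numeric(stats::predict(cl$fit, newx = x, s = cl$lambda, type = "response"))
  } else if (cl$type == "glm1") {
    as.numeric(stats::predict(cl$fit,
                              newdata = data.frame(f1 = x[, 1L]),
                              type = "response"))
  } else {
    pr <- stats::predict(cl$fit, data = data.frame(x, check.names = FALSE))$predictions
    as.numeric(pr[, cl$levels[2L]])
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the full depression-recognition pipeline
#'
#' On the complete training matrix: SMOTE balancing, z-score normalization,
#' feature selection, classifier fit — in that fixed order.
#'
#' @param m A `feature_matrix`.
#' @param selection_method One of "all", "l1", "tree", "fdr".
#' @param classifier_config List: `type` ("ridge" or "tree") plus
#'   type-specific settings (`lambda` for ridge, `num_trees` for tree).
#' @param smote_k SMOTE neighbor count.
#' @param seed Integer seed.
#' @param selection_args Extra arguments for the selection route.
#' @return A fitted `dr_model`.
#' @export
fit_dr_model <- function(m, selection_method = "all",
                         classifier_config = list(type = "ridge", lambda = 0.01),
                         smote_k = 5L, seed = 1L, selection_args = list()) {
  stopifnot(inherits(m, "feature_matrix"))
  bal <- smote_oversample(m, k_neighbors = smote_k, seed = seed)
  norm <- suppressWarnings(fit_normalizer(bal))
  baln <- apply_normalizer(norm, bal)
  sel <- do.call(select_features,
                 c(list(m = baln, method = selection_method, seed = seed),
                   selection_args))
  cc <- classifier_config
  cc$seed <- cc$seed %||% seed
  cl <- fit_classifier(baln$x[, sel$selected, drop = FALSE], baln$labels, cc,
                       m$positive_class)
  structure(list(normalizer = norm, selection = sel, classifier = cl,
                 classifier_config = cc, levels = levels(m$labels),
                 positive_class = m$positive_class,
                 feature_names = colnames(m$x)),
            class = "dr_model")
}

#' Predict depression status for new data
#'
#' @param object A fitted `dr_model`.
#' @param newdata A `feature_matrix`, a numeric matrix/data.frame of feature
#'   rows with matching names, or a single `eeg_recording` (features are then
#'   extracted with module defaults: 4-s non-overlapping epochs, per-subject
#'   mean aggregation).
#' @param ... Ignored.
#' @return data.frame with `label` and `probability` (of the positive class)
#'   per row; probabilities of the two classes sum to 1.
#' @export
predict.dr_model <- function(object, newdata, ...) {
  if (inherits(newdata, "eeg_recording")) {
    eps <- epoch_signal(newdata)
    newdata <- aggregate_features(features_table(eps))
  }
  x <- if (inherits(newdata, "feature_matrix")) newdata$x else {
    xx <- as.matrix(newdata); storage.mode(xx) <- "double"; xx
  }
  z <- apply_normalizer(object$normalizer, x)
  zsel <- z[, intersect(object$selection$selected, colnames(z)), drop = FALSE]
  if (ncol(zsel) < length(object$selection$selected)) {
    stop("feature name mismatch: selected features missing from input", call. = FALSE)
  }
  p2 <- predict_classifier(object$classifier, zsel)
  pos <- object$positive_class
  p_pos <- if (object$levels[2L] == pos) p2 else 1 - p2
  lab <- ifelse(p_pos > 0.5, pos, setdiff(object$levels, pos))
  data.frame(label = lab, probability = p_pos, row.names = rownames(x))
}

#' Repeated stratified cross-validation of the DR pipeline
#'
#' Runs `repeats` independent stratified `folds`-fold splits. Inside every
#' training fold — and only there — the pipeline applies SMOTE, fits the
#' normalizer, selects features, and fits the classifier; the untouched test
#' fold is then scored. Accuracy = (TP+TN)/all, Recall = TP/(TP+FN),
#' Precision = TP/(TP+FP), with the positive class taken from the matrix.
#'
#' @inheritParams fit_dr_model
#' @param folds Number of folds (default 5).
#' @param repeats Number of repetitions (default 10).
#' @return A `cv_report`: pooled and per-repeat metrics, per-fold selected
#'   features and normalizer parameters, pooled confusion matrix, seed.
#' @export
cross_validate <- function(m, selection_method = "all",
                           classifier_config = list(type = "ridge", lambda = 0.01),
                           folds = 5L, repeats = 10L, seed = 1L, smote_k = 5L,
                           selection_args = list()) {
  stopifnot(inherits(m, "feature_matrix"))
  folds <- check_count(folds, "folds", min = 2L)
  repeats <- check_count(repeats, "repeats")
  tab <- table(m$labels)
  if (any(tab < folds)) {
    stop(sprintf("each class needs >= %d samples for %d-fold stratification",
                 folds, folds), call. = FALSE)
  }
  n <- nrow(m$x)
  pos <- m$positive_class
  per_repeat <- vector("list", repeats)
  fold_details <- vector("list", repeats)
  conf_total <- c(TP = 0, TN = 0, FP = 0, FN = 0)

  for (r in seq_len(repeats)) {
    # Stratified fold assignment: depends only on labels and the seed, never
    # on feature values (required for the leakage check to be meaningful).
    assign_vec <- integer(n)
    withr::with_seed(derive_seed(seed, r, 0L), {
      for (cls in levels(m$labels)) {
        idx <- which(m$labels == cls)
        assign_vec[sample(idx)] <- rep_len(seq_len(folds), length(idx))
      }
    })
    conf_rep <- c(TP = 0, TN = 0, FP = 0, FN = 0)
    fold_details[[r]] <- vector("list", folds)
    for (f in seq_len(folds)) {
      test_idx <- which(assign_vec == f)
      train_idx <- setdiff(seq_len(n), test_idx)
      fold_seed <- derive_seed(seed, r, f)
      tr <- m
      tr$x <- m$x[train_idx, , drop = FALSE]
      tr$labels <- droplevels(m$labels[train_idx])
      if (nlevels(tr$labels) < 2L) stop("class absent from a training fold", call. = FALSE)
      tr$labels <- factor(as.character(tr$labels), levels = levels(m$labels))

      bal <- smote_oversample(tr, k_neighbors = smote_k, seed = fold_seed)
      norm <- suppressWarnings(fit_normalizer(bal))
      baln <- apply_normalizer(norm, bal)
      sel <- do.call(select_features,
                     c(list(m = baln, method = selection_method, seed = fold_seed),
                       selection_args))
      cc <- classifier_config
      cc$seed <- fold_seed
      cl <- fit_classifier(baln$x[, sel$selected, drop = FALSE], baln$labels, cc, pos)

      zte <- apply_normalizer(norm, m$x[test_idx, , drop = FALSE])
      p2 <- predict_classifier(cl, zte[, sel$selected, drop = FALSE])
      p_pos <- if (levels(m$labels)[2L] == pos) p2 else 1 - p2
      pred_pos <- p_pos > 0.5
      true_pos <- m$labels[test_idx] == pos
      cm <- c(TP = sum(pred_pos & true_pos), TN = sum(!pred_pos & !true_pos),
              FP = sum(pred_pos & !true_pos), FN = sum(!pred_pos & true_pos))
      conf_rep <- conf_rep + cm
      fold_details[[r]][[f]] <- list(test_idx = test_idx,
                                     normalizer = norm,
                                     selected = sel$selected,
                                     confusion = cm)
    }
    conf_total <- conf_total + conf_rep
    per_repeat[[r]] <- data.frame(repeat_ = r,
                                  accuracy = unname((conf_rep["TP"] + conf_rep["TN"]) / sum(conf_rep)),
                                  recall = unname(conf_rep["TP"] / (conf_rep["TP"] + conf_rep["FN"])),
                                  precision = unname(conf_rep["TP"] / (conf_rep["TP"] + conf_rep["FP"])))
  }
  per_repeat <- do.call(rbind, per_repeat)
  pooled <- c(accuracy = unname((conf_total["TP"] + conf_total["TN"]) / sum(conf_total)),
              recall = unname(conf_total["TP"] / (conf_total["TP"] + conf_total["FN"])),
              precision = unname(conf_total["TP"] / (conf_total["TP"] + conf_total["FP"])))
  structure(list(folds = folds, repeats = repeats,
                 selection_method = selection_method,
                 per_repeat = per_repeat,
                 mean_over_repeats = colMeans(per_repeat[, -1L], na.rm = TRUE),
                 pooled = pooled,
                 confusion = conf_total,
                 fold_details = fold_details,
                 positive_class = pos,
                 seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d x %d-fold stratified CV (selection: %s, positive class: %s)\n",
              x$repeats, x$folds, x$selection_method, x$positive_class))
  cat(sprintf("  pooled:  accuracy %.3f, recall %.3f, precision %.3f\n",
              x$pooled["accuracy"], x$pooled["recall"], x$pooled["precision"]))
  cat(sprintf("  repeats: accuracy %.3f, recall %.3f, precision %.3f (means)\n",
              x$mean_over_repeats["accuracy"], x$mean_over_repeats["recall"],
              x$mean_over_repeats["precision"]))
  invisible(x)
}

#' Compare the four feature-selection routes under identical CV splits
#'
#' Reproduces the selection-route comparison experiment: one table of
#' accuracy, recall, precision (pooled and per-repeat mean) for the routes
#' "all", "l1", "tree" and "fdr".
#'
#' @inheritParams cross_validate
#' @param methods Selection routes to compare.
#' @return data.frame with one row per route; the individual `cv_report`s
#'   are in attribute `reports`.
#' @export
compare_selection_methods <- function(m, methods = c("all", "l1", "tree", "fdr"),
                                      classifier_config = list(type = "ridge", lambda = 0.01),
                                      folds = 5L, repeats = 10L, seed = 1L,
                                      smote_k = 5L) {
  reports <- lapply(methods, function(meth) {
    cross_validate(m, selection_method = meth,
                   classifier_config = classifier_config,
                   folds = folds, repeats = repeats, seed = seed,
                   smote_k = smote_k)
  })
  names(reports) <- methods
  out <- do.call(rbind, lapply(methods, function(meth) {
    rp <- reports[[meth]]
    data.frame(method = meth,
               accuracy = rp$pooled["accuracy"],
               recall = rp$pooled["recall"],
               precision = rp$pooled["precision"],
               accuracy_repeat_mean = rp$mean_over_repeats["accuracy"],
               recall_repeat_mean = rp$mean_over_repeats["recall"],
               precision_repeat_mean = rp$mean_over_repeats["precision"],
               row.names = NULL)
  }))
  attr(out, "reports") <- reports
  out
}
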