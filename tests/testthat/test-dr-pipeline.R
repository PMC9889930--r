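test_that("matrix assembly is canonical and validates its schema", {
  x <- matrix(seq_len(20), 4, 5,
              dimnames = list(c("s2", "s1", "s4", "s3"),
                              c("ch02.max", "ch01.variance", "ch01.max",
                                "ch02.variance", "ch01.hfd")))
  labels <- c(s1 = "depressed", s2 = "control", s3 = "depressed", s4 = "control")
  fm <- assemble_matrix(x, labels)
  expect_identical(rownames(fm$x), c("s1", "s2", "s3", "s4"))
  expect_identical(colnames(fm$x),
                   c("ch01.max", "ch01.variance", "ch01.hfd",
                     "ch02.max", "ch02.variance"))
  expect_identical(fm$positive_class, "depressed")
  # permuted rows give the identical matrix
  fm2 <- assemble_matrix(x[c(3, 1, 4, 2), c(5, 1, 2, 3, 4)], labels)
  expect_identical(fm$x, fm2$x)
  expect_error(assemble_matrix(x, labels[1:3]), "missing label.*s")
  xna <- x; xna[1, 1] <- NA
  expect_error(assemble_matrix(xna, labels), "missing values")
  expect_error(assemble_matrix(list(data.frame(a = 1), data.frame(b = 2)),
                               labels), "mismatched feature sets")
})

test_that("a 10-subject, 16-channel, 7-feature table gives 112 columns", {
  subj <- sprintf("s%02d", 1:10)
  long <- expand.grid(subject_id = subj, channel = sprintf("ch%02d", 1:16),
                      feature = feature_names(), epoch = 1:2,
                      stringsAsFactors = FALSE)
  long$value <- seq_len(nrow(long)) / 7
  agg <- aggregate_features(long)
  fm <- assemble_matrix(agg, stats::setNames(rep(c("depressed", "control"), 5), subj))
  expect_equal(ncol(fm$x), 112)
})

test_that("SMOTE balances classes with synthetic rows on minority segments", {
  fm <- make_planted_matrix(n_per_class = 10, n_info = 1, n_noise = 4, seed = 2)
  expect_identical(smote_oversample(fm, 3, 1), fm)  # already balanced

  unb <- fm
  keep <- c(which(unb$labels == "depressed")[1:5], which(unb$labels == "control"))
  unb$x <- unb$x[keep, , drop = FALSE]
  unb$labels <- unb$labels[keep]
  bal <- smote_oversample(unb, k_neighbors = 3, seed = 5)
  expect_equal(as.vector(table(bal$labels)), c(10, 10))
  syn <- attr(bal, "synthetic")
  expect_length(syn, 5)
  # originals preserved unchanged
  expect_identical(bal$x[rownames(unb$x), ], unb$x)
  # each synthetic row is a convex combination of two minority originals
  minority <- unb$x[unb$labels == "depressed", , drop = FALSE]
  for (srow in syn) {
    s <- bal$x[srow, ]
    found <- FALSE
    for (i in 1:(nrow(minority) - 1)) {
      for (j in (i + 1):nrow(minority)) {
        d <- minority[j, ] - minority[i, ]
        lam <- sum((s - minority[i, ]) * d) / sum(d * d)
        if (lam >= -1e-9 && lam <= 1 + 1e-9 &&
            max(abs(s - minority[i, ] - lam * d)) < 1e-9) found <- TRUE
      }
    }
    expect_true(found, label = sprintf("%s lies on a minority segment", srow))
  }
  expect_identical(smote_oversample(unb, 3, 5)$x, bal$x)
  expect_error(smote_oversample(unb, k_neighbors = 6, seed = 1), "k_neighbors <= 4")
})

test_that("normalizer fits on training rows only and drops constants", {
  fm <- make_planted_matrix(n_per_class = 10, n_info = 1, n_noise = 3, seed = 3)
  norm <- fit_normalizer(fm)
  z <- apply_normalizer(norm, fm)
  expect_lt(max(abs(colMeans(z$x))), 1e-9)
  expect_lt(max(abs(apply(z$x, 2, stats::sd) - 1)), 1e-9)
  cfm <- fm
  cfm$x <- cbind(cfm$x, flat = 1)
  expect_warning(norm2 <- fit_normalizer(cfm), "constant.*flat")
  expect_false("flat" %in% norm2$features)
  # train params applied to held-out rows do not recenter them
  tr <- fm; tr$x <- fm$x[1:10, ]; tr$labels <- fm$labels[1:10]
  nt <- fit_normalizer(tr)
  zte <- apply_normalizer(nt, fm$x[11:20, ])
  expect_gt(max(abs(colMeans(zte))), 0.01)
  expect_error(apply_normalizer(nt, fm$x[, 1:2]), "mismatch")
})

test_that("L1 selection shrinks to empty and expands to all at the extremes", {
  fm <- make_planted_matrix(n_per_class = 20, n_info = 2, n_noise = 6, seed = 4)
  z <- apply_normalizer(fit_normalizer(fm), fm)
  expect_warning(hi <- select_l1(z, penalty_strength = 1e6), "empty")
  expect_length(hi$selected, 0)
  # vanishing penalty keeps every feature (on non-separable data, where the
  # unpenalized optimum exists and is generically dense)
  null_fm <- make_planted_matrix(n_per_class = 20, n_info = 0, n_noise = 8,
                                 delta = 0, seed = 5)
  zn <- apply_normalizer(fit_normalizer(null_fm), null_fm)
  lo <- select_l1(zn, penalty_strength = 1e-8)
  expect_setequal(lo$selected, colnames(zn$x))
})

test_that("L1 and tree routes recover planted informative features", {
  hit_l1 <- 0; hit_tree <- 0
  n_runs <- 10
  for (s in seq_len(n_runs)) {
    fm <- make_planted_matrix(n_per_class = 30, n_info = 3, n_noise = 50,
                              delta = 3, seed = 100 + s)
    z <- apply_normalizer(fit_normalizer(fm), fm)
    planted <- grep("info", colnames(z$x), value = TRUE)
    sl1 <- select_l1(z, penalty_strength = 0.01)
    if (all(planted %in% sl1$selected)) hit_l1 <- hit_l1 + 1
    str <- select_tree(z, seed = s)
    expect_equal(sum(str$scores), 1, tolerance = 1e-9)
    if (all(planted %in% str$selected[1:10])) hit_tree <- hit_tree + 1
    expect_identical(select_tree(z, seed = s)$selected, str$selected)
  }
  expect_gte(hit_l1 / n_runs, 0.9)
  expect_gte(hit_tree / n_runs, 0.9)
})

test_that("FDR selection matches t.test/p.adjust and keeps obvious signals", {
  fm <- make_planted_matrix(n_per_class = 15, n_info = 2, n_noise = 10,
                            delta = 4, seed = 6)
  sel <- select_fdr(fm, alpha_level = 0.05)
  expect_true(all(c("ch01.info1", "ch01.info2") %in% sel$selected))
  # cross-check every adjusted p against the stats::t.test oracle
  p_raw <- vapply(colnames(fm$x), function(cn) {
    stats::t.test(fm$x[fm$labels == levels(fm$labels)[1], cn],
                  fm$x[fm$labels == levels(fm$labels)[2], cn])$p.value
  }, numeric(1))
  expect_equal(unname(sel$scores[names(p_raw)]),
               unname(stats::p.adjust(p_raw, "BH")), tolerance = 1e-9)
  # identical class distributions: nothing (or almost nothing) survives
  null_fm <- make_planted_matrix(n_per_class = 20, n_info = 0, n_noise = 30,
                                 delta = 0, seed = 7)
  expect_lte(length(select_fdr(null_fm)$selected), 1)
  # a degenerate feature is skipped with a note
  dfm <- fm; dfm$x[, 3] <- 5
  sel2 <- select_fdr(dfm)
  expect_true(colnames(dfm$x)[3] %in% attr(sel2, "skipped"))
})

test_that("stratified folds preserve class proportions within one sample", {
  fm <- make_planted_matrix(n_per_class = 13, n_info = 1, n_noise = 4, seed = 8)
  cv <- cross_validate(fm, folds = 5, repeats = 2, seed = 3)
  for (r in 1:2) {
    for (f in 1:5) {
      idx <- cv$fold_details[[r]][[f]]$test_idx
      counts <- table(fm$labels[idx])
      expect_true(all(abs(counts - 13 / 5) <= 1))
    }
  }
  expect_error(cross_validate(make_planted_matrix(4, 1, 2, seed = 1),
                              folds = 5, repeats = 1), ">= 5 samples")
})

test_that("cross-validation is chance-level without signal, perfect with it", {
  null_fm <- make_planted_matrix(n_per_class = 20, n_info = 0, n_noise = 12,
                                 delta = 0, seed = 9)
  cv0 <- cross_validate(null_fm, folds = 5, repeats = 10, seed = 5)
  expect_gte(cv0$pooled["accuracy"], 0.35)
  expect_lte(cv0$pooled["accuracy"], 0.65)
  sep <- make_planted_matrix(n_per_class = 15, n_info = 2, n_noise = 8,
                             delta = 10, sd_noise = 1, seed = 10)
  cv1 <- cross_validate(sep, folds = 5, repeats = 3, seed = 6)
  expect_equal(unname(cv1$pooled), c(1, 1, 1))
  # bit-reproducible from (matrix, config, seed)
  expect_identical(cross_validate(sep, folds = 5, repeats = 2, seed = 7),
                   cross_validate(sep, folds = 5, repeats = 2, seed = 7))
})

test_that("test-fold rows never influence fold-fitted parameters", {
  fm <- make_planted_matrix(n_per_class = 12, n_info = 1, n_noise = 6, seed = 11)
  cv1 <- cross_validate(fm, selection_method = "fdr", folds = 4, repeats = 1,
                        seed = 13)
  for (f in 1:4) {
    mutated <- fm
    idx <- cv1$fold_details[[1]][[f]]$test_idx
    mutated$x[idx, ] <- mutated$x[idx, ] * 10 + 100
    cv2 <- cross_validate(mutated, selection_method = "fdr", folds = 4,
                          repeats = 1, seed = 13)
    expect_identical(cv2$fold_details[[1]][[f]]$normalizer,
                     cv1$fold_details[[1]][[f]]$normalizer)
    expect_identical(cv2$fold_details[[1]][[f]]$selected,
                     cv1$fold_details[[1]][[f]]$selected)
  }
})

test_that("predictions carry calibrated two-class probabilities", {
  sep <- make_planted_matrix(n_per_class = 15, n_info = 2, n_noise = 8,
                             delta = 8, seed = 12)
  mod <- fit_dr_model(sep, selection_method = "l1", seed = 1)
  pr <- predict(mod, sep)
  expect_identical(pr$label, as.character(sep$labels))
  expect_true(all(pr$probability >= 0 & pr$probability <= 1))
  expect_true(all(pr$probability[sep$labels == "depressed"] > 0.5))
  # two-class probabilities sum to one by construction
  expect_equal(pr$probability + (1 - pr$probability), rep(1, nrow(pr)))
  expect_identical(pr, predict(mod, sep))
  expect_error(predict(mod, sep$x[, 1:3]), "mismatch")
})

test_that("the selection-route comparison harness returns the 4 x 3 table", {
  fm <- make_planted_matrix(n_per_class = 12, n_info = 2, n_noise = 10,
                            delta = 4, seed = 14)
  tab <- compare_selection_methods(fm, folds = 4, repeats = 2, seed = 2)
  expect_identical(tab$method, c("all", "l1", "tree", "fdr"))
  expect_true(all(c("accuracy", "recall", "precision") %in% names(tab)))
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 1))
  expect_length(attr(tab, "reports"), 4)
})
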