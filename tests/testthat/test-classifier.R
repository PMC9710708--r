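test_that("enumerate_grid counts follow the configured ranges", {
  g <- enumerate_grid(grid_config())
  expect_equal(sum(g$kernel == "polynomial"), 9 * 21)
  expect_equal(sum(g$kernel == "rbf"), 19 * 21)
  expect_equal(nrow(g), 588)
  # polynomial pairs come first, in ascending (d, C) order
  expect_equal(g$d[1:21], rep(1L, 21))
  expect_equal(g$C[1:3], 10^c(-7, -6, -5))

  single <- enumerate_grid(grid_config(poly_d = 1L, poly_C_exponents = 0L,
                                       rbf_g_exponents = integer(),
                                       rbf_C_exponents = integer()))
  expect_equal(nrow(single), 1)
  expect_equal(single$kernel, "polynomial")
  expect_equal(single$d, 1L)
  expect_equal(single$C, 1)
})

test_that("mcc matches the closed form, including marginal-zero cases", {
  expect_equal(mcc(5, 0, 5, 0), 1.0)
  expect_equal(mcc(0, 5, 0, 5), -1.0)
  expect_equal(mcc(4, 1, 3, 2), 10 / sqrt(600))
  # all four marginal-zero cases are defined as 0
  expect_equal(mcc(0, 0, 5, 5), 0)  # TP+FP = 0
  expect_equal(mcc(0, 5, 5, 0), 0)  # TP+FN = 0
  expect_equal(mcc(0, 0, 0, 5), 0)
  expect_equal(mcc(5, 5, 0, 0), 0)
  expect_equal(mcc(0, 0, 0, 0), 0)

  set.seed(77)
  for (i in 1:100) {
    cm <- sample(0:40, 4, replace = TRUE)
    tp <- cm[1]; fp <- cm[2]; tn <- cm[3]; fn <- cm[4]
    denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    want <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
    expect_equal(mcc(tp, fp, tn, fn), want, tolerance = 1e-12)
    expect_gte(mcc(tp, fp, tn, fn), -1)
    expect_lte(mcc(tp, fp, tn, fn), 1)
  }
})

test_that("stratified folds balance sizes and class ratios deterministically", {
  y <- rep(c(TRUE, FALSE), each = 50)
  f <- stratified_kfold(y, 5, seed = 1)
  expect_equal(as.vector(table(f)), rep(20L, 5))
  for (k in 1:5) expect_equal(sum(y[f == k]), 10)
  expect_identical(f, stratified_kfold(y, 5, seed = 1))
  expect_false(identical(f, stratified_kfold(y, 5, seed = 2)))

  y2 <- c(rep(TRUE, 52), rep(FALSE, 20))
  f2 <- stratified_kfold(y2, 5, seed = 3)
  pos_counts <- vapply(1:5, function(k) sum(y2[f2 == k]), integer(1))
  expect_true(all(pos_counts %in% c(10L, 11L)))
  expect_equal(sum(pos_counts), 52)
  # folds are disjoint and exhaustive by construction
  expect_equal(sort(unique(f2)), 1:5)
  expect_length(f2, 72)

  expect_error(stratified_kfold(c(TRUE, rep(FALSE, 20)), 5, 1), "stratum")
})

test_that("train_binary separates a linearly separable toy and is deterministic", {
  x <- rbind(c(1, 0), c(1, 0.1), c(-1, 0), c(-1, 0.1))
  y <- c(TRUE, TRUE, FALSE, FALSE)
  params <- list(kernel = "polynomial", d = 1L, C = 1, g = NA)
  m <- train_binary(x, y, params)
  dv <- decision_values(m, x)
  expect_true(all(dv[1:2] > 0))
  expect_true(all(dv[3:4] < 0))

  m2 <- train_binary(x, y, params)
  expect_equal(decision_values(m2, x), dv, tolerance = 1e-8)
  expect_error(train_binary(x, rep(TRUE, 4), params), "positive and negative")
})

test_that("decision values agree in sign with an independent SVM solver", {
  skip_if_not_installed("kernlab")
  set.seed(13)
  synth <- generate_training_set(15, 40, seed = 13)
  enc <- encode_matrix(synth$records, encoding_config())
  y <- synth$truth$true_class == "TNL"
  m <- train_binary(enc$features, y,
                    list(kernel = "polynomial", d = 1L, C = 1, g = NA))
  dv <- decision_values(m, enc$features)
  ref <- kernlab::ksvm(enc$features, factor(ifelse(y, "pos", "neg")),
                       kernel = "polydot",
                       kpar = list(degree = 1, scale = 1, offset = 1),
                       C = 1, scaled = FALSE)
  ref_pred <- kernlab::predict(ref, enc$features)
  expect_gt(mean((dv > 0) == (ref_pred == "pos")), 0.98)
})

test_that("cross_validate reports no signal on identical vectors and stays internally consistent", {
  x <- matrix(rep(0.5, 40 * 10), 40, 10)
  y <- rep(c(TRUE, FALSE), 20)
  cv <- cross_validate(x, y, list(kernel = "polynomial", d = 1L, C = 1, g = NA),
                       folds = 5, seed = 1)
  expect_lt(abs(cv$mean_mcc), 0.2)
  # accuracy recomputable from the stored fold confusions
  with(cv$confusions, {
    expect_equal(cv$mean_accuracy,
                 mean((TP + TN) / (TP + TN + FP + FN)))
    expect_equal(sum(TP + TN + FP + FN), 40)
  })
})

test_that("cross-validation reaches perfect MCC on a separable synthetic class", {
  synth <- generate_training_set(15, 40, seed = 42)
  enc <- encode_matrix(synth$records, encoding_config())
  y <- synth$truth$true_class == "CNL"
  cv <- cross_validate(enc$features, y,
                       list(kernel = "polynomial", d = 1L, C = 100, g = NA),
                       folds = 5, seed = 42)
  expect_equal(cv$mean_mcc, 1.0)
})

test_that("grid_search ranks by MCC with the documented tie-breaks", {
  synth <- generate_training_set(10, 25, seed = 3)
  enc <- encode_matrix(synth$records, encoding_config())
  y <- synth$truth$true_class == "RLK"
  gs <- grid_search(enc$features, y, tiny_grid(folds = 3, seed = 5))
  expect_equal(nrow(gs$results), 1)
  expect_equal(gs$results$rank, 1)
  expect_s3_class(gs$model, "binary_svm")

  # tie-break: equal MCC resolved by accuracy, then poly < rbf, then smaller C
  res <- data.frame(kernel = c("rbf", "polynomial", "polynomial"),
                    d = c(NA, 2, 1), C = c(1, 10, 10), g = c(0.1, NA, NA),
                    mean_mcc = c(0.9, 0.9, 0.9),
                    mean_accuracy = c(0.95, 0.95, 0.90))
  ord <- order(-res$mean_mcc, -res$mean_accuracy, res$kernel != "polynomial",
               ifelse(is.na(res$d), Inf, res$d), res$C,
               ifelse(is.na(res$g), Inf, res$g))
  expect_equal(ord[1], 2L)  # polynomial d=2 acc .95 beats rbf and the .90
})

test_that("prediction is deterministic, order-invariant, and flags degenerate input", {
  synth <- generate_training_set(12, 30, seed = 8)
  model <- rgene_svm(as_training_dataset(synth), grid = tiny_grid(seed = 8))
  held <- generate_training_set(5, 10, seed = 99)
  pred <- predict(model, held$records)
  expect_equal(nrow(pred), nrow(held$records))
  expect_identical(pred, predict(model, held$records))

  perm <- sample(nrow(held$records))
  pred_perm <- predict(model, subset_seq_set_for_test(held$records, perm))
  reord <- pred_perm[match(pred$seq_id, pred_perm$seq_id), ]
  rownames(reord) <- NULL
  expect_equal(reord, pred)

  # all-X protein: near-zero encoding, deterministic, flagged
  degen <- seq_set("allx", strrep("X", 100))
  p <- predict(model, degen)
  expect_true(p$low_information)
  expect_identical(p, predict(model, degen))

  empty <- predict(model, seq_set(character(), character()))
  expect_equal(nrow(empty), 0)
})

test_that("a held-out synthetic sequence is recovered as its true class", {
  synth <- generate_training_set(15, 40, seed = 42)
  model <- rgene_svm(as_training_dataset(synth), grid = tiny_grid(seed = 42))
  held <- generate_training_set(3, 3, seed = 4242)
  tnl <- subset_seq_set_for_test(held$records,
                                 which(held$truth$true_class == "TNL"))
  pred <- predict(model, tnl)
  expect_true(all(pred$primary == "TNL"))
})

test_that("bundle save/load preserves decision values and guards integrity", {
  synth <- generate_training_set(10, 25, seed = 6)
  model <- rgene_svm(as_training_dataset(synth), grid = tiny_grid(seed = 6))
  held <- generate_training_set(5, 5, seed = 66)
  before <- predict(model, held$records)

  path <- withr::local_tempfile(fileext = ".rds")
  write_rgene_svm(model, path)
  back <- read_rgene_svm(path)
  after <- predict(back, held$records)
  for (cl in model$classes) {
    col <- paste0("decision_", cl)
    expect_equal(after[[col]], before[[col]], tolerance = 1e-10)
  }

  expect_error(read_rgene_svm(path, encoding_config(min_length = 75)),
               "fingerprint")
  bad <- withr::local_tempfile(fileext = ".rds")
  writeLines("this is not a bundle", bad)
  expect_error(read_rgene_svm(bad), "parse|bundle")
  expect_error(read_rgene_svm("no/such/file.rds"), "not found")
})
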