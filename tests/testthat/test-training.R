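manifest_105 <- function() {
  tibble::tibble(
    sequence_id = sprintf("s%03d", 1:105),
    case_id = rep(sprintf("c%02d", 1:21), each = 5),
    label = rep(rep(c("high", "low"), length.out = 21), each = 5)
  )
}

test_that("split sizes follow round(train_fraction * N)", {
  sp <- make_splits(manifest_105(), 0.743, n_splits = 3, seed = 1,
                    grouping = "sequence")
  for (s in sp) {
    expect_length(s$train, 78)
    expect_length(s$test, 27)
    expect_length(intersect(s$train, s$test), 0)
    expect_setequal(c(s$train, s$test), manifest_105()$sequence_id)
  }
  mf10 <- manifest_105()[1:10, ]
  mf10$label <- rep(c("high", "low"), 5)
  s10 <- make_splits(mf10, 0.7, 1, seed = 2, grouping = "sequence")[[1]]
  expect_length(s10$train, 7)
  expect_length(s10$test, 3)
})

test_that("splits are reproducible from the seed and differ across splits", {
  a <- make_splits(manifest_105(), 0.743, 3, seed = 9, grouping = "sequence")
  b <- make_splits(manifest_105(), 0.743, 3, seed = 9, grouping = "sequence")
  expect_identical(lapply(a, `[[`, "train"), lapply(b, `[[`, "train"))
  expect_false(identical(sort(a[[1]]$train), sort(a[[2]]$train)))
})

test_that("case grouping keeps all sequences of a case on one side", {
  mf <- manifest_105()
  for (strat in c(TRUE, FALSE)) {
    sp <- make_splits(mf, 0.75, 2, seed = 4, grouping = "case",
                      stratify = strat)
    for (s in sp) {
      train_cases <- unique(mf$case_id[mf$sequence_id %in% s$train])
      test_cases <- unique(mf$case_id[mf$sequence_id %in% s$test])
      expect_length(intersect(train_cases, test_cases), 0)
    }
  }
})

test_that("stratified splits retain both classes on both sides", {
  sp <- make_splits(manifest_105(), 0.75, 3, seed = 5, grouping = "case",
                    stratify = TRUE)
  mf <- manifest_105()
  for (s in sp) {
    expect_setequal(unique(mf$label[mf$sequence_id %in% s$train]),
                    c("high", "low"))
    expect_setequal(unique(mf$label[mf$sequence_id %in% s$test]),
                    c("high", "low"))
  }
})

test_that("a split that strands one class errors out", {
  mf <- manifest_105()
  mf$label <- "high"
  expect_error(make_splits(mf, 0.7, 1, seed = 1, grouping = "sequence"),
               "without one of the classes")
})

test_that("cross-entropy matches its closed forms and clamps at zero", {
  expect_equal(cross_entropy_loss(c(1, 0), "high"), 0)
  expect_equal(cross_entropy_loss(c(0.5, 0.5), "low"), log(2), tolerance = 1e-12)
  expect_equal(cross_entropy_loss(c(0.25, 0.75), "high"), log(4), tolerance = 1e-12)
  big <- cross_entropy_loss(c(0, 1), "high")
  expect_true(is.finite(big))
  expect_equal(big, -log(1e-12))
  expect_error(cross_entropy_loss(c(0.7, 0.7), "high"), "probability")
})

test_that("the sequence model overfits a tiny well-separated training set", {
  ds <- tiny_dataset(n_cases = 4, spc = 1, preset = "separated", seed = 19)
  split <- structure(list(split_id = 1,
                          train = ds$manifest$sequence_id,
                          test = character(0), seed = 1),
                     class = "cle_split")
  bb <- tiny_backbone()
  fit <- train_model(ds, split, tiny_model_config(model_dim = 16, n_heads = 2),
                     train_config(learning_rate = 3e-3, batch_size = 4,
                                  max_epochs = 200, patience = Inf, seed = 2),
                     bb)
  expect_equal(max(fit$history$accuracy), 1)
  expect_lt(min(fit$history$loss), 0.1)
})

test_that("zero learning rate leaves parameters and loss unchanged", {
  ds <- tiny_dataset(n_cases = 2, spc = 2, seed = 23)
  split <- structure(list(split_id = 1, train = ds$manifest$sequence_id,
                          test = character(0), seed = 1),
                     class = "cle_split")
  bb <- tiny_backbone()
  m0 <- init_temporal_model(tiny_model_config(), bb, seed = 3)
  fit <- train_model(ds, split, tiny_model_config(),
                     train_config(learning_rate = 0, batch_size = 2,
                                  max_epochs = 5, seed = 3), bb)
  expect_equal(fit$model$params, m0$params, tolerance = 1e-12)
  expect_true(all(abs(diff(fit$history$loss)) < 1e-10))
})

test_that("training is deterministic under a fixed seed", {
  ds <- tiny_dataset(n_cases = 2, spc = 2, seed = 29)
  split <- structure(list(split_id = 1, train = ds$manifest$sequence_id,
                          test = character(0), seed = 1),
                     class = "cle_split")
  bb <- tiny_backbone()
  cfgm <- tiny_model_config(dropout = 0.1)
  tc <- train_config(learning_rate = 1e-3, batch_size = 2, max_epochs = 8,
                     seed = 11)
  f1 <- train_model(ds, split, cfgm, tc, bb)
  f2 <- train_model(ds, split, cfgm, tc, bb)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
})

test_that("train/test disjointness is asserted before fitting", {
  ds <- tiny_dataset(n_cases = 2, spc = 2, seed = 31)
  bad <- structure(list(split_id = 1, train = ds$manifest$sequence_id,
                        test = ds$manifest$sequence_id[1], seed = 1),
                   class = "cle_split")
  expect_error(train_model(ds, bad, tiny_model_config(), train_config(),
                           tiny_backbone()), "overlap")
  expect_error(train_frame_baseline(ds, bad, train_config(), tiny_backbone()),
               "overlap")
})

test_that("frame baseline fits separable per-frame features", {
  ds <- tiny_dataset(n_cases = 4, spc = 2, preset = "separated", seed = 37)
  split <- structure(list(split_id = 1,
                          train = ds$manifest$sequence_id[1:6],
                          test = ds$manifest$sequence_id[7:8], seed = 1),
                     class = "cle_split")
  fit <- train_frame_baseline(ds, split,
                              train_config(learning_rate = 1e-2,
                                           max_epochs = 200, seed = 5),
                              tiny_backbone())
  expect_s3_class(fit$model, "cle_frame_model")
  expect_gte(utils::tail(fit$history$accuracy, 1), 0.9)
  preds <- predict_dataset(fit, ds, ids = split$test)
  expect_equal(nrow(preds), 2)
  expect_true(all(preds$prediction %in% c("high", "low")))
})

test_that("fit summaries expose history through broom-style methods", {
  ds <- tiny_dataset(n_cases = 2, spc = 1, seed = 41)
  split <- structure(list(split_id = 1, train = ds$manifest$sequence_id,
                          test = character(0), seed = 1),
                     class = "cle_split")
  fit <- train_model(ds, split, tiny_model_config(),
                     train_config(max_epochs = 3, seed = 1), tiny_backbone())
  g <- glance(fit)
  expect_equal(g$epochs, 3)
  expect_named(tidy(fit), c("epoch", "loss", "accuracy"))
})
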