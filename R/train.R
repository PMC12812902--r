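#' Training configuration
#'
#' Hyperparameters for fitting the temporal classifier (and the frame-based
#' baseline head) by minimizing cross-entropy with the Adam optimizer.
#'
#' @param learning_rate Adam step size (> 0, or 0 for a null update used in
#'   testing).
#' @param batch_size Sequences per optimization step.
#' @param max_epochs Maximum passes over the training set (>= 1).
#' @param patience Early-stopping patience: stop when the training loss has
#'   not improved for this many consecutive epochs. `Inf` disables.
#' @param seed Seed controlling weight initialization, shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 4L,
                         max_epochs = 100L, patience = Inf, seed = 1L) {
  assert_that(is.numeric(learning_rate) && learning_rate >= 0,
              "learning_rate must be >= 0")
  assert_that(is_count(batch_size, min = 1), "batch_size must be >= 1")
  assert_that(is_count(max_epochs, min = 1), "max_epochs must be >= 1")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = patience, seed = as.integer(seed)),
            class = "train_config")
}

#' Random train/test splits of a sequence manifest
#'
#' Divides the dataset into a training and testing set at `train_fraction`
#' (training size = `round(train_fraction * N)` sequences), repeated
#' `n_splits` times under seeds derived deterministically from `seed`.
#' `grouping = "sequence"` randomizes at the sequence level (the original
#' study protocol, which can place sequences of one patient on both sides);
#' `grouping = "case"` keeps all sequences of a case on one side, cutting at
#' the case boundary closest to the target size. `stratify = TRUE` performs
#' the randomization within each grade so both sides retain both classes by
#' construction. A split leaving either side without one of the classes is
#' an error.
#'
#' @param manifest Tibble with columns `sequence_id`, `case_id`, `label`.
#' @param train_fraction Fraction of sequences for training, in (0, 1).
#' @param n_splits Number of independent random splits.
#' @param seed Master seed.
#' @param grouping `"case"` (default; leakage-safe) or `"sequence"`.
#' @param stratify Randomize within grade strata.
#' @return List of `cle_split` objects (fields `split_id`, `train`, `test`,
#'   `seed`), each with disjoint, exhaustive id sets.
#' @examples
#' mf <- tibble::tibble(sequence_id = sprintf("s%03d", 1:105),
#'                      case_id = rep(sprintf("c%02d", 1:21), each = 5),
#'                      label = rep(c("high", "low"), c(55, 50)))
#' sp <- make_splits(mf, 0.743, n_splits = 1, seed = 1,
#'                   grouping = "sequence")
#' length(sp[[1]]$train)
#' @export
make_splits <- function(manifest, train_fraction = 0.743, n_splits = 3L,
                        seed = 1L, grouping = c("case", "sequence"),
                        stratify = FALSE) {
  grouping <- match.arg(grouping)
  assert_that(train_fraction > 0 && train_fraction < 1,
              "train_fraction must lie strictly between 0 and 1")
  assert_that(is_count(n_splits, min = 1), "n_splits must be >= 1")
  n <- nrow(manifest)
  target <- round(train_fraction * n)
  lapply(seq_len(n_splits), function(k) {
    with_seed(derive_seed(seed, k), {
      train_ids <- if (grouping == "sequence") {
        split_sequences(manifest, target, stratify)
      } else {
        split_cases(manifest, target, stratify)
      }
      test_ids <- setdiff(manifest$sequence_id, train_ids)
      for (side in list(train = train_ids, test = test_ids)) {
        lbl <- manifest$label[manifest$sequence_id %in% side]
        assert_that(length(unique(lbl)) == 2,
                    "split leaves one side without one of the classes")
      }
      structure(list(split_id = k, train = train_ids, test = test_ids,
                     seed = derive_seed(seed, k)),
                class = "cle_split")
    })
  })
}

split_sequences <- function(manifest, target, stratify) {
  if (!stratify) {
    return(sample(manifest$sequence_id, target))
  }
  ids <- character(0)
  frac <- target / nrow(manifest)
  for (lbl in unique(manifest$label)) {
    pool <- manifest$sequence_id[manifest$label == lbl]
    ids <- c(ids, sample(pool, round(frac * length(pool))))
  }
  ids
}

split_cases <- function(manifest, target, stratify) {
  case_tbl <- manifest[!duplicated(manifest$case_id),
                       c("case_id", "label")]
  counts <- table(manifest$case_id)[case_tbl$case_id]
  pick_prefix <- function(cases, sizes, tgt) {
    ord <- sample(length(cases))
    cum <- cumsum(sizes[ord])
    k <- which.min(abs(cum - tgt))
    cases[ord[seq_len(k)]]
  }
  train_cases <- if (!stratify) {
    pick_prefix(case_tbl$case_id, as.integer(counts), target)
  } else {
    frac <- target / nrow(manifest)
    out <- character(0)
    for (lbl in unique(case_tbl$label)) {
      sel <- case_tbl$label == lbl
      out <- c(out, pick_prefix(case_tbl$case_id[sel],
                                as.integer(counts[sel]),
                                frac * sum(counts[sel])))
    }
    out
  }
  manifest$sequence_id[manifest$case_id %in% train_cases]
}

#' Cross-entropy loss of a grade prediction
#'
#' Negative log probability assigned to the true class; the probability is
#' clamped at 1e-12 before the logarithm so a (numerically) zero probability
#' yields a large finite loss rather than infinity.
#'
#' @param prediction A `grade_prediction`, or a numeric vector
#'   `c(p_high, p_low)`.
#' @param label `"high"` or `"low"`.
#' @return Nonnegative scalar.
#' @examples
#' cross_entropy_loss(c(0.5, 0.5), "high") # log(2)
#' @export
cross_entropy_loss <- function(prediction, label) {
  probs <- if (inherits(prediction, "grade_prediction")) {
    c(prediction$prob_high, prediction$prob_low)
  } else {
    as.numeric(prediction)
  }
  assert_that(length(probs) == 2 && all(is.finite(probs)) &&
                all(probs >= 0) && abs(sum(probs) - 1) < 1e-6,
              "prediction must be a valid two-class probability vector")
  idx <- label_to_index(label)
  -log(max(probs[idx], 1e-12))
}

# Numerically stable cross-entropy straight from logits.
ce_from_logits <- function(logits, label_idx) {
  m <- max(logits)
  (m + log(sum(exp(logits - m)))) - logits[label_idx]
}

#' Extract backbone features for every sequence of a dataset
#'
#' Convenience cache: since the backbone is frozen, per-frame embeddings can
#' be computed once and shared between the sequence model, the frame-based
#' baseline, and repeated training runs.
#'
#' @param dataset A `cle_dataset`.
#' @param backbone A [backbone_spec()].
#' @return Named list of `T x D` feature matrices keyed by `sequence_id`.
#' @export
extract_dataset_features <- function(dataset, backbone = backbone_spec()) {
  stopifnot(inherits(dataset, "cle_dataset"))
  feats <- lapply(dataset$sequences, extract_features, spec = backbone)
  names(feats) <- names(dataset$sequences)
  feats
}

#' Train the sequence-based temporal classifier
#'
#' Fits the temporal model on the training side of a split by minimizing the
#' cross-entropy between the softmax output and the examination label, using
#' Adam with mini-batches of sequences. The visual backbone stays frozen;
#' only the temporal classifier's parameters are updated. Training is fully
#' deterministic given `train_cfg$seed`. Train/test disjointness is asserted
#' before fitting; non-finite loss aborts with a diagnostic.
#'
#' @param dataset A `cle_dataset`.
#' @param split A `cle_split` from [make_splits()].
#' @param model_config A [temporal_model_config()].
#' @param train_cfg A [train_config()].
#' @param backbone A [backbone_spec()].
#' @param features Optional precomputed feature list from
#'   [extract_dataset_features()].
#' @return A `cle_fit`: list with `model` (a `cle_temporal_model`), `history`
#'   (tibble of per-epoch training loss and accuracy) and `split_id`.
#' @export
train_model <- function(dataset, split,
                        model_config = temporal_model_config(),
                        train_cfg = train_config(),
                        backbone = backbone_spec(),
                        features = NULL) {
  stopifnot(inherits(dataset, "cle_dataset"), inherits(split, "cle_split"))
  assert_that(length(intersect(split$train, split$test)) == 0,
              "train and test sets overlap")
  features <- features %||% extract_dataset_features(dataset, backbone)
  labels <- stats::setNames(dataset$manifest$label,
                            dataset$manifest$sequence_id)
  train_ids <- split$train
  assert_that(length(unique(labels[train_ids])) == 2,
              "training set must contain both classes")

  model <- init_temporal_model(model_config, backbone, seed = train_cfg$seed)
  model$scaling <- fit_feature_scaling(features[train_ids])
  scaled <- lapply(features, function(f) {
    apply_feature_scaling(unclass_features(f), model$scaling)
  })
  state <- adam_init(model$params)
  history <- vector("list", train_cfg$max_epochs)
  best_loss <- Inf; stall <- 0L; n_done <- 0L

  with_seed(derive_seed(train_cfg$seed, 104729L), {
    for (epoch in seq_len(train_cfg$max_epochs)) {
      order_ids <- sample(train_ids)
      epoch_loss <- 0
      for (start in seq(1, length(order_ids), by = train_cfg$batch_size)) {
        batch <- order_ids[start:min(start + train_cfg$batch_size - 1,
                                     length(order_ids))]
        total <- NULL
        for (sid in batch) {
          x <- scaled[[sid]]
          yi <- label_to_index(labels[[sid]])
          fwd <- temporal_forward(model$params, model$config, x,
                                  train = TRUE, need_cache = TRUE)
          loss_i <- ce_from_logits(fwd$logits, yi)
          if (!is.finite(loss_i)) {
            stop(sprintf("training diverged at epoch %d (non-finite loss)",
                         epoch), call. = FALSE)
          }
          epoch_loss <- epoch_loss + loss_i
          dlogits <- fwd$probs
          dlogits[yi] <- dlogits[yi] - 1
          bwd <- temporal_backward(model$params, model$config, fwd$cache,
                                   dlogits)
          total <- accumulate_grads(total, bwd$grads)
        }
        upd <- adam_step(model$params, scale_grads(total, 1 / length(batch)),
                         state, train_cfg$learning_rate)
        model$params <- upd$params
        state <- upd$state
      }
      epoch_loss <- epoch_loss / length(train_ids)
      acc <- mean(vapply(train_ids, function(sid) {
        p <- temporal_forward(model$params, model$config, scaled[[sid]])
        label_levels[which.max(p$probs)] == labels[[sid]]
      }, logical(1)))
      n_done <- epoch
      history[[epoch]] <- tibble::tibble(epoch = epoch, loss = epoch_loss,
                                         accuracy = acc)
      if (epoch_loss < best_loss - 1e-5) {
        best_loss <- epoch_loss
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= train_cfg$patience) break
      }
    }
  })
  structure(list(model = model,
                 history = dplyr::bind_rows(history[seq_len(n_done)]),
                 split_id = split$split_id, train_cfg = train_cfg),
            class = "cle_fit")
}

#' Train the frame-based baseline classifier
#'
#' Fits a per-frame softmax head on the frozen backbone embeddings, each
#' frame inheriting its examination's label — the conventional frame-based
#' approach with no temporal modeling. Optimized full-batch with Adam under
#' the same cross-entropy loss.
#'
#' @inheritParams train_model
#' @return A `cle_fit` whose `model` is a `cle_frame_model`.
#' @export
train_frame_baseline <- function(dataset, split,
                                 train_cfg = train_config(),
                                 backbone = backbone_spec(),
                                 features = NULL) {
  stopifnot(inherits(dataset, "cle_dataset"), inherits(split, "cle_split"))
  assert_that(length(intersect(split$train, split$test)) == 0,
              "train and test sets overlap")
  features <- features %||% extract_dataset_features(dataset, backbone)
  labels <- stats::setNames(dataset$manifest$label,
                            dataset$manifest$sequence_id)
  scaling <- fit_feature_scaling(features[split$train])
  X <- do.call(rbind, lapply(split$train, function(sid) {
    apply_feature_scaling(unclass_features(features[[sid]]), scaling)
  }))
  y <- unlist(lapply(split$train, function(sid) {
    rep(label_to_index(labels[[sid]]), nrow(features[[sid]]))
  }))
  d <- ncol(X)
  with_seed(train_cfg$seed, {
    params <- list(W = matrix(stats::rnorm(d * 2, 0, 0.01), d, 2),
                   b = rep(0, 2))
    state <- adam_init(params)
    history <- vector("list", train_cfg$max_epochs)
    Y <- matrix(0, length(y), 2)
    Y[cbind(seq_along(y), y)] <- 1
    for (epoch in seq_len(train_cfg$max_epochs)) {
      logits <- sweep(X %*% params$W, 2, params$b, "+")
      P <- softmax_rows(logits)
      loss <- mean(-log(pmax(P[cbind(seq_along(y), y)], 1e-12)))
      if (!is.finite(loss)) {
        stop("baseline training diverged (non-finite loss)", call. = FALSE)
      }
      dlogits <- (P - Y) / length(y)
      grads <- list(W = t(X) %*% dlogits, b = colSums(dlogits))
      upd <- adam_step(params, grads, state, train_cfg$learning_rate)
      params <- upd$params; state <- upd$state
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, loss = loss,
        accuracy = mean(max.col(P, ties.method = "first") == y))
    }
    structure(list(model = new_frame_model(params$W, params$b, backbone,
                                           scaling = scaling),
                   history = dplyr::bind_rows(history),
                   split_id = split$split_id, train_cfg = train_cfg),
              class = "cle_fit")
  })
}

#' Per-examination predictions over a dataset
#'
#' @param fit A `cle_fit` (sequence model or frame baseline).
#' @param dataset A `cle_dataset`.
#' @param ids Sequence ids to predict (default: all).
#' @param features Optional precomputed feature cache.
#' @param aggregation Frame-baseline aggregation rule (ignored for the
#'   sequence model).
#' @return Tibble with `sequence_id`, `label`, `prediction`, `prob_high`.
#' @export
predict_dataset <- function(fit, dataset, ids = NULL, features = NULL,
                            aggregation = "majority") {
  stopifnot(inherits(fit, "cle_fit"))
  ids <- ids %||% dataset$manifest$sequence_id
  labels <- stats::setNames(dataset$manifest$label,
                            dataset$manifest$sequence_id)
  backbone <- fit$model$backbone
  features <- features %||%
    lapply(dataset$sequences[ids], extract_features, spec = backbone)
  rows <- lapply(ids, function(sid) {
    pred <- if (inherits(fit$model, "cle_temporal_model")) {
      predict_sequence(features[[sid]], fit$model)
    } else {
      predict_frame_baseline(features[[sid]], fit$model,
                             aggregation = aggregation)
    }
    tibble::tibble(sequence_id = sid, label = labels[[sid]],
                   prediction = pred$label, prob_high = pred$prob_high)
  })
  dplyr::bind_rows(rows)
}

#' @export
print.cle_fit <- function(x, ...) {
  last <- utils::tail(x$history, 1)
  cat(sprintf("<cle_fit> %s | %d epoch(s), final loss %.4f, train accuracy %.3f\n",
              class(x$model)[1], nrow(x$history), last$loss, last$accuracy))
  invisible(x)
}

#' Glance at a fitted model
#'
#' One-row summary in the broom style.
#'
#' @param x A `cle_fit`.
#' @param ... Unused.
#' @return One-row tibble with `epochs`, `final_loss`, `train_accuracy`.
#' @export
glance.cle_fit <- function(x, ...) {
  last <- utils::tail(x$history, 1)
  tibble::tibble(epochs = nrow(x$history), final_loss = last$loss,
                 train_accuracy = last$accuracy)
}

#' Tidy the training history of a fit
#'
#' @param x A `cle_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble.
#' @export
tidy.cle_fit <- function(x, ...) x$history

#' Run one simulated grading experiment end to end
#'
#' Orchestrates the full protocol on synthetic data: generate a labeled
#' dataset of cases, split it into train/test sets, fit both the
#' sequence-based temporal classifier and the frame-based baseline on the
#' training side, and score per-examination top-1 accuracy of both models on
#' the held-out test side. All randomness (simulation, splitting, weight
#' initialization, shuffling, dropout) derives from `seed`.
#'
#' @param n_cases,sequences_per_case Corpus size (default 16 cases of 5
#'   sequences: 80 examinations, split 60/20 at the default fraction).
#' @param config Base [simulator_config()] (the per-sequence seed is derived
#'   internally).
#' @param profiles Grade-profile pair from [cle_profiles()].
#' @param train_fraction Fraction of sequences used for training.
#' @param seed Master seed for the whole experiment.
#' @param backbone A [backbone_spec()].
#' @param model_config A [temporal_model_config()].
#' @param seq_train,frame_train [train_config()]s for the two models (their
#'   `seed` field is overridden by `seed`).
#' @param grouping,stratify Split policy, see [make_splits()].
#' @param aggregation Frame-baseline aggregation rule.
#' @return One-row tibble: `seed`, `n_train`, `n_test`,
#'   `sequence_accuracy`, `frame_accuracy` (percent, per examination).
#' @export
run_grading_experiment <- function(n_cases = 16, sequences_per_case = 5,
                                   config = simulator_config(frame_size = 64,
                                                             n_frames = 12),
                                   profiles = cle_profiles("separated"),
                                   train_fraction = 0.75,
                                   seed = 1L,
                                   backbone = backbone_spec(),
                                   model_config = temporal_model_config(),
                                   seq_train = train_config(
                                     learning_rate = 1e-3, batch_size = 8,
                                     max_epochs = 60),
                                   frame_train = train_config(
                                     learning_rate = 1e-2, max_epochs = 200),
                                   grouping = "case", stratify = TRUE,
                                   aggregation = "majority") {
  ds <- generate_dataset(n_cases, sequences_per_case, config = config,
                         profiles = profiles, seed = seed)
  feats <- extract_dataset_features(ds, backbone)
  split <- make_splits(ds$manifest, train_fraction, n_splits = 1, seed = seed,
                       grouping = grouping, stratify = stratify)[[1]]
  seq_train$seed <- as.integer(seed)
  frame_train$seed <- as.integer(seed)
  fit <- train_model(ds, split, model_config, seq_train, backbone,
                     features = feats)
  seq_pred <- predict_dataset(fit, ds, ids = split$test, features = feats)
  bfit <- train_frame_baseline(ds, split, frame_train, backbone,
                               features = feats)
  frame_pred <- predict_dataset(bfit, ds, ids = split$test, features = feats,
                                aggregation = aggregation)
  tibble::tibble(
    seed = as.integer(seed),
    n_train = length(split$train), n_test = length(split$test),
    sequence_accuracy = 100 * mean(seq_pred$prediction == seq_pred$label),
    frame_accuracy = 100 * mean(frame_pred$prediction == frame_pred$label)
  )
}
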