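# Training protocol and evaluation harness: Adam, early stopping on
# validation loss with restoration of the best state, accuracy / specificity /
# sensitivity, ROC/AUC, and the multi-seed experiment runner.

#' Training configuration
#'
#' Defaults follow the clinical protocol: Adam with initial learning rate
#' 1e-4, batch size 128, at most 100 epochs, early stopping after 10
#' non-improving validation epochs, five independent runs.
#'
#' @param lr learning rate.
#' @param batch_size optimizer minibatch size.
#' @param micro_batch how many windows are forwarded at once; gradients of a
#'   minibatch are accumulated over micro-batches of this size (a memory
#'   bound, not a protocol parameter).
#' @param max_epochs maximum number of epochs.
#' @param clip_norm global L2 gradient-norm ceiling per optimizer step
#'   (`Inf` disables clipping; the desk preset clips at 1 to stabilize the
#'   small-batch regime).
#' @param patience early-stopping patience (must be < `max_epochs`).
#' @param n_runs number of independent runs for mean +/- sd reporting.
#' @param seed_base seed of the first run; run r uses `seed_base + r - 1`.
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 1e-4, batch_size = 128, micro_batch = 32,
                         max_epochs = 100, clip_norm = Inf, patience = 10,
                         n_runs = 5, seed_base = 1L) {
  stopifnot(lr > 0, batch_size > 0, micro_batch > 0, max_epochs > 0,
            clip_norm > 0, n_runs > 0, patience > 0, patience < max_epochs)
  structure(list(lr = lr, batch_size = batch_size,
                 micro_batch = min(micro_batch, batch_size),
                 max_epochs = max_epochs, clip_norm = clip_norm,
                 patience = patience, n_runs = n_runs,
                 seed_base = as.integer(seed_base)),
            class = "train_config")
}

#' Desk-scale training preset
#'
#' The reduced protocol used for the synthetic end-to-end experiments: the
#' desk cohort has roughly a hundred times fewer optimizer steps than the
#' clinical protocol, so the step budget is shortened and the learning rate
#' raised tenfold to keep the total parameter displacement comparable.
#'
#' @param ... overrides passed to [train_config()].
#' @return a `train_config`.
#' @export
train_preset_desk <- function(n_runs = 5, ...) {
  train_config(lr = 2e-3, batch_size = 64, micro_batch = 32, max_epochs = 3,
               patience = 2, n_runs = n_runs, ...)
}

# Accumulate the gradient of the mean loss over one optimizer batch by
# forwarding micro-batches; mathematically the full-batch gradient (up to the
# per-micro-batch normalization statistics of BN).
batch_grad <- function(model, feats, take, micro) {
  nb <- length(take)
  gacc <- NULL
  lacc <- 0
  i <- 1
  while (i <= nb) {
    j <- min(i + micro - 1, nb)
    sub <- take[i:j]
    w <- length(sub) / nb
    fw <- model_forward(model,
                        feats$eeg[, , , sub, drop = FALSE],
                        feats$emg[, , , sub, drop = FALSE], train = TRUE)
    if (!is.null(fw$cache$buffers)) model$buffers <- fw$cache$buffers
    lo <- ce_loss_batch(fw$logits, feats$labels[sub])
    g <- model_backward(model, fw$cache, lo$dlogits)
    gv <- tree_flatten(g) * w
    gacc <- if (is.null(gacc)) gv else gacc + gv
    lacc <- lacc + w * lo$loss
    i <- j + 1
  }
  list(grads = tree_fill(model$params, gacc), loss = lacc,
       buffers = model$buffers)
}

# Rescale a gradient tree so its global L2 norm is at most `max_norm`.
clip_global_norm <- function(grads, max_norm) {
  if (!is.finite(max_norm)) return(grads)
  g <- tree_flatten(grads)
  nrm <- sqrt(sum(g^2))
  if (nrm <= max_norm) return(grads)
  tree_fill(grads, g * (max_norm / nrm))
}

# Early-stopping rule as a pure function of the validation-loss trace:
# improvement = strictly lower loss; training halts at the first epoch whose
# distance from the best epoch exceeds the patience.
early_stop_trace <- function(val_losses, patience) {
  best_epoch <- 1L
  best <- val_losses[1]
  stop_epoch <- length(val_losses)
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]
      best_epoch <- e
    }
    if (e - best_epoch > patience) {
      stop_epoch <- e
      break
    }
  }
  list(stop_epoch = as.integer(stop_epoch), best_epoch = best_epoch)
}

val_loss_of <- function(model, feats, batch_size = 32) {
  logits <- model_predict(model, feats, batch_size)
  ce_loss_batch(logits, feats$labels)$loss
}

#' Train a detector with early stopping
#'
#' Minibatch Adam with per-epoch validation; training terminates once the
#' validation loss has not improved for `patience` consecutive epochs and the
#' returned model is the state with the lowest validation loss. Training and
#' validation sets must not share subjects.
#'
#' @param model a `spasm_model` from [build_model()].
#' @param train_feats,val_feats prepared feature sets from
#'   [prepare_features()].
#' @param config a [train_config()].
#' @param seed seed for minibatch shuffling (defaults to the model seed).
#' @param verbose print per-epoch losses.
#' @return a `spasm_fit`: list with the restored `model`, per-epoch `history`
#'   tibble, `best_epoch` and `stopped_epoch`.
#' @export
train <- function(model, train_feats, val_feats, config = train_config(),
                  seed = NULL, verbose = FALSE) {
  n <- length(train_feats$labels)
  if (n == 0 || length(val_feats$labels) == 0) stop("empty dataset")
  shared <- intersect(unique(train_feats$meta$subject_id),
                      unique(val_feats$meta$subject_id))
  if (length(shared) > 0) {
    stop("subject leakage between train and validation: ",
         paste(shared, collapse = ", "))
  }
  if (is.null(seed)) seed <- derive_seed(model$seed, "shuffle")
  opt <- adam_init(model$params)
  history <- list()
  best <- list(val = Inf, epoch = 0L, params = model$params,
               buffers = model$buffers)
  for (epoch in seq_len(config$max_epochs)) {
    idx <- with_seed(derive_seed(seed, epoch), sample.int(n))
    batch_losses <- c()
    i <- 1
    while (i <= n) {
      j <- min(i + config$batch_size - 1, n)
      bg <- batch_grad(model, train_feats, idx[i:j], config$micro_batch)
      model$buffers <- bg$buffers
      grads <- clip_global_norm(bg$grads, config$clip_norm)
      st <- adam_step(model$params, grads, opt, lr = config$lr)
      model$params <- st$params
      opt <- st$state
      batch_losses <- c(batch_losses, bg$loss)
      i <- j + 1
    }
    vl <- val_loss_of(model, val_feats, config$micro_batch)
    history[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = mean(batch_losses), val_loss = vl
    )
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      mean(batch_losses), vl))
    }
    if (vl < best$val) {
      best <- list(val = vl, epoch = epoch, params = model$params,
                   buffers = model$buffers)
    }
    if (epoch - best$epoch > config$patience) break
  }
  model$params <- best$params
  model$buffers <- best$buffers
  structure(
    list(model = model, history = dplyr::bind_rows(history),
         best_epoch = best$epoch, stopped_epoch = epoch,
         best_val_loss = best$val, config = config),
    class = "spasm_fit"
  )
}

#' @export
print.spasm_fit <- function(x, ...) {
  cat(sprintf(
    "<spasm_fit: %d epochs (best %d, val loss %.4f)>\n",
    x$stopped_epoch, x$best_epoch, x$best_val_loss
  ))
  invisible(x)
}

#' @rdname train
#' @param x a `spasm_fit`.
#' @param ... unused.
#' @export
tidy.spasm_fit <- function(x, ...) x$history

#' @rdname train
#' @export
glance.spasm_fit <- function(x, ...) {
  tibble::tibble(
    epochs_trained = x$stopped_epoch,
    best_epoch = x$best_epoch,
    best_val_loss = x$best_val_loss,
    n_params = tree_count(x$model$params)
  )
}

#' Posterior spasm probability for each window
#'
#' @param model a `spasm_model`.
#' @param feats a prepared feature set.
#' @param batch_size forward batch size.
#' @return numeric vector of P(spasm) per window.
#' @export
model_scores <- function(model, feats, batch_size = 32) {
  logits <- model_predict(model, feats, batch_size)
  1 / (1 + exp(logits[1, ] - logits[2, ]))
}

#' Classification metrics from binary labels and predictions
#'
#' Exact contingency formulas: accuracy `(TP+TN)/(TP+TN+FP+FN)`, specificity
#' `TN/(TN+FP)`, sensitivity `TP/(TP+FN)`, reported as percentages. A metric
#' whose denominator is zero is returned as `NA` (undefined), never as 0.
#'
#' @param labels true classes (0/1).
#' @param predictions predicted classes (0/1).
#' @return one-row tibble of class `metrics_report` with counts and
#'   percentage metrics.
#' @export
evaluate_metrics <- function(labels, predictions) {
  if (length(labels) == 0) stop("empty input")
  if (length(labels) != length(predictions)) stop("length mismatch")
  if (!all(labels %in% c(0, 1)) || !all(predictions %in% c(0, 1))) {
    stop("labels and predictions must be binary (0/1)")
  }
  tp <- sum(labels == 1 & predictions == 1)
  tn <- sum(labels == 0 & predictions == 0)
  fp <- sum(labels == 0 & predictions == 1)
  fn <- sum(labels == 1 & predictions == 0)
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  out <- tibble::tibble(
    tp = tp, tn = tn, fp = fp, fn = fn,
    acc = pct(tp + tn, tp + tn + fp + fn),
    spe = pct(tn, tn + fp),
    sen = pct(tp, tp + fn)
  )
  class(out) <- c("metrics_report", class(out))
  out
}

#' ROC curve and AUC
#'
#' The curve sweeps all score thresholds; the AUC is the rank statistic
#' (probability that a random positive outscores a random negative, ties
#' counted half), which equals the trapezoidal area under the curve.
#'
#' @param labels true classes (0/1), both present.
#' @param scores real-valued scores, larger = more spasm-like.
#' @return list of class `roc_result` with `curve` (tibble: threshold, fpr,
#'   tpr) and `auc`.
#' @export
roc_auc <- function(labels, scores) {
  if (length(unique(labels)) < 2) {
    stop("both classes must be present for a ROC curve")
  }
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
  ord <- order(scores, decreasing = TRUE)
  thr <- scores[ord]
  tpr <- cumsum(labels[ord] == 1) / P
  fpr <- cumsum(labels[ord] == 0) / N
  keep <- !duplicated(thr, fromLast = TRUE)
  curve <- tibble::tibble(
    threshold = c(Inf, thr[keep]),
    fpr = c(0, fpr[keep]),
    tpr = c(0, tpr[keep])
  )
  structure(list(curve = curve, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result: AUC = %.4f over %d thresholds>\n", x$auc,
              nrow(x$curve) - 1))
  invisible(x)
}

#' Evaluate a model on a prepared feature set
#'
#' Class decisions are the argmax of the two logits; scores are softmax
#' spasm probabilities.
#'
#' @param model a `spasm_model`.
#' @param feats a prepared feature set.
#' @param batch_size forward batch size.
#' @return one-row tibble: counts, acc/spe/sen (percent) and `auc`.
#' @export
evaluate_model <- function(model, feats, batch_size = 32) {
  logits <- model_predict(model, feats, batch_size)
  pred <- as.integer(logits[2, ] > logits[1, ])
  m <- evaluate_metrics(feats$labels, pred)
  scores <- 1 / (1 + exp(logits[1, ] - logits[2, ]))
  m$auc <- if (length(unique(feats$labels)) == 2) {
    roc_auc(feats$labels, scores)$auc
  } else {
    NA_real_
  }
  m
}

#' Full desk pipeline: cohort -> preprocessed, balanced, split feature sets
#'
#' Simulates (or accepts) a cohort, applies the preprocessing chain
#' (EEG band-pass + notch + average reference, EMG band-pass, per-recording
#' z-scoring), extracts and balances windows, splits by subject and computes
#' model input features for each split.
#'
#' Windows are balanced per recording (so every subject-wise split is itself
#' class-balanced), then split by subject. Band-magnitude features are
#' standardized per (band, channel) with statistics fitted on the training
#' subjects only: raw scalogram magnitudes span orders of magnitude across
#' bands under 1/f backgrounds, which ill-conditions short training runs.
#'
#' @param synth_cfg a [synth_config()]; ignored when `cohort` is given.
#' @param model_cfg a [model_config()].
#' @param cohort optional pre-simulated cohort from [simulate_cohort()].
#' @param balance_seed,split_seed seeds for balancing and the subject split.
#' @param emg_high upper EMG band edge; `NULL` picks 500 Hz when the rate
#'   allows, otherwise 100 Hz.
#' @param standardize standardize features with train-split statistics.
#' @return list with `train`, `val`, `test` feature sets, the `split` and
#'   the fitted `scaler`.
#' @export
prepare_experiment_data <- function(synth_cfg, model_cfg, cohort = NULL,
                                    balance_seed = 11L, split_seed = 7L,
                                    emg_high = NULL, standardize = TRUE) {
  if (is.null(cohort)) cohort <- simulate_cohort(synth_cfg)
  fs <- cohort$recordings[[1]]$fs
  if (is.null(emg_high)) emg_high <- if (fs > 1000) 500 else 100
  wins <- lapply(cohort$recordings, function(rec) {
    rec <- preprocess_eeg(rec)
    rec <- preprocess_emg(rec, high = emg_high)
    rec <- zscore_recording(rec)
    ws <- extract_windows(rec, cohort$annotations)
    balance_classes(ws, seed = derive_seed(balance_seed, rec$recording_id))
  })
  ws <- bind_windows(wins)
  split <- subject_split(ws, seed = split_seed)
  parts <- split_windows(ws, split)
  out <- list(
    train = prepare_features(parts$train, model_cfg),
    val = prepare_features(parts$val, model_cfg),
    test = prepare_features(parts$test, model_cfg),
    split = split
  )
  if (standardize) {
    scaler <- list(eeg = fit_feature_scaler(out$train$eeg),
                   emg = fit_feature_scaler(out$train$emg))
    for (part in c("train", "val", "test")) {
      out[[part]]$eeg <- apply_feature_scaler(out[[part]]$eeg, scaler$eeg)
      out[[part]]$emg <- apply_feature_scaler(out[[part]]$emg, scaler$emg)
    }
    out$scaler <- scaler
  }
  out
}

# Per-(band, channel) location/scale over all time points and windows.
fit_feature_scaler <- function(x) {
  list(m = apply(x, c(1, 2), mean), s = pmax(apply(x, c(1, 2), sd), 1e-8))
}

apply_feature_scaler <- function(x, scaler) {
  d <- dim(x)
  (x - array(scaler$m, d)) / array(scaler$s, d)
}

#' Multi-seed experiment over model variants
#'
#' Trains `n_runs` models per variant with seeds `seed_base .. seed_base +
#' n_runs - 1` on one fixed subject split and reports test metrics per run
#' plus mean +/- sd per variant, mirroring the five-independent-experiments
#' protocol.
#'
#' @param data prepared splits from [prepare_experiment_data()].
#' @param model_cfgs named list of [model_config()] variants.
#' @param tr_cfg a [train_config()].
#' @param verbose print progress.
#' @return list with per-run tibble `runs` and aggregated `summary`
#'   (mean and sd of acc/spe/sen/auc per variant).
#' @export
run_experiment <- function(data, model_cfgs, tr_cfg = train_config(),
                           verbose = FALSE) {
  runs <- list()
  for (vn in names(model_cfgs)) {
    for (r in seq_len(tr_cfg$n_runs)) {
      seed <- tr_cfg$seed_base + r - 1L
      model <- build_model(model_cfgs[[vn]], seed = seed)
      fit <- train(model, data$train, data$val, tr_cfg, verbose = FALSE)
      m <- evaluate_model(fit$model, data$test, tr_cfg$micro_batch)
      runs[[length(runs) + 1]] <- dplyr::mutate(
        tibble::as_tibble(m), variant = vn, run = r, seed = seed,
        best_epoch = fit$best_epoch, epochs = fit$stopped_epoch,
        .before = 1
      )
      if (verbose) {
        message(sprintf("%s run %d: acc %.1f%% auc %.3f (epochs %d)",
                        vn, r, m$acc, m$auc, fit$stopped_epoch))
      }
    }
  }
  runs <- dplyr::bind_rows(runs)
  summary <- runs |>
    dplyr::group_by(.data$variant) |>
    dplyr::summarise(dplyr::across(c("acc", "spe", "sen", "auc"),
                                   list(mean = mean, sd = sd)),
                     .groups = "drop")
  list(runs = runs, summary = summary)
}
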