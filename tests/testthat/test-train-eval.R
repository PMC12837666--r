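ns <- asNamespace("spasmfusion")

test_that("contingency metrics follow the exact printed formulas", {
  perfect <- evaluate_metrics(rep(c(1, 0), each = 50), rep(c(1, 0), each = 50))
  expect_equal(perfect$acc, 100)
  expect_equal(perfect$spe, 100)
  expect_equal(perfect$sen, 100)
  labels <- c(rep(1, 50), rep(0, 50))
  preds <- c(rep(1, 40), rep(0, 10), rep(0, 45), rep(1, 5))
  m <- evaluate_metrics(labels, preds)
  expect_equal(c(m$tp, m$fn, m$tn, m$fp), c(40, 10, 45, 5))
  expect_equal(m$sen, 80)
  expect_equal(m$spe, 90)
  expect_equal(m$acc, 85)
  all_neg <- evaluate_metrics(rep(c(1, 0), 25), rep(0, 50))
  expect_equal(all_neg$sen, 0)
  expect_equal(all_neg$spe, 100)
  expect_equal(all_neg$acc, 50)
})

test_that("empty inputs and zero denominators are flagged, not silently 0", {
  expect_error(evaluate_metrics(numeric(0), numeric(0)), "empty")
  expect_error(evaluate_metrics(c(0, 1), c(0.5, 1)), "binary")
  m <- evaluate_metrics(c(1, 1, 1), c(1, 0, 1)) # no negatives
  expect_true(is.na(m$spe))
  expect_false(is.na(m$sen))
})

test_that("acc equals the prevalence-weighted mix of sen and spe", {
  set.seed(13)
  for (i in 1:20) {
    n <- 60
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    preds <- rbinom(n, 1, 0.5)
    m <- evaluate_metrics(labels, preds)
    P <- sum(labels == 1)
    N <- sum(labels == 0)
    expect_equal(m$acc, (m$sen * P + m$spe * N) / (P + N), tolerance = 1e-9)
  }
})

test_that("ROC/AUC: separation, the 4-point worked example, invariance", {
  sep <- roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(sep$auc, 1.0)
  toy <- roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1))
  expect_equal(toy$auc, 0.75) # 3 of 4 correctly ordered pairs
  # invariance under strictly monotone transforms
  set.seed(14)
  labels <- rbinom(40, 1, 0.5)
  labels[1:2] <- c(0, 1)
  scores <- rnorm(40)
  a1 <- roc_auc(labels, scores)$auc
  expect_equal(roc_auc(labels, exp(scores))$auc, a1)
  expect_equal(roc_auc(labels, 5 * scores - 2)$auc, a1)
  expect_error(roc_auc(rep(1, 5), rnorm(5)), "both classes")
  # curve endpoints
  expect_equal(sep$curve$fpr[1], 0)
  expect_equal(tail(sep$curve$tpr, 1), 1)
})

test_that("AUC agrees with an independent implementation and ties average", {
  set.seed(15)
  labels <- rbinom(100, 1, 0.5)
  labels[1:2] <- c(0, 1)
  scores <- round(rnorm(100), 1) # induce ties
  ours <- roc_auc(labels, scores)$auc
  ref <- suppressMessages(as.numeric(pROC::auc(labels, scores,
                                               direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("shuffled scores give AUC near 1/2 (permutation null)", {
  set.seed(16)
  n <- 400
  labels <- rep(c(0, 1), n / 2)
  aucs <- replicate(30, roc_auc(labels, sample(rnorm(n)))$auc)
  null_sd <- sqrt((n / 2 + 1) / (3 * n)) / sqrt(n / 2) * sqrt(n / 2)
  # Wilcoxon null sd for equal groups: sqrt((n1+n2+1)/(12 n1 n2))
  sd0 <- sqrt((n + 1) / (12 * (n / 2)^2))
  expect_lt(abs(mean(aucs) - 0.5), 3 * sd0)
})

test_that("early stopping follows the non-improvement trace rule", {
  # flat trace: best at epoch 1, stop once 10 epochs exceed the patience
  tr <- ns$early_stop_trace(rep(1.0, 12), patience = 10)
  expect_equal(tr$stop_epoch, 12L)
  expect_equal(tr$best_epoch, 1L)
  # strictly decreasing: never stops early, best is the last epoch
  tr2 <- ns$early_stop_trace(seq(1, 0.01, length.out = 100), patience = 10)
  expect_equal(tr2$stop_epoch, 100L)
  expect_equal(tr2$best_epoch, 100L)
})

test_that("training restores the lowest-validation state, deterministically", {
  cfg <- tiny_model_config()
  set.seed(17)
  n <- 24
  Tn <- 32
  mk <- function(n, subj) {
    labels <- rep(c(0L, 1L), length.out = n)
    eeg <- array(rnorm(4 * 3 * Tn * n), c(4, 3, Tn, n))
    emg <- array(rnorm(4 * 2 * Tn * n), c(4, 2, Tn, n))
    for (i in which(labels == 1)) eeg[1, , , i] <- eeg[1, , , i] + 2
    list(eeg = eeg, emg = emg, labels = labels,
         meta = tibble::tibble(subject_id = subj))
  }
  trf <- mk(n, "s1")
  vaf <- mk(12, "s2")
  tc <- train_config(lr = 1e-3, batch_size = 12, micro_batch = 12,
                     max_epochs = 4, patience = 2, n_runs = 1)
  fit1 <- train(build_model(cfg, seed = 21), trf, vaf, tc)
  fit2 <- train(build_model(cfg, seed = 21), trf, vaf, tc)
  expect_identical(fit1$history, fit2$history) # fixed seed, identical run
  expect_equal(fit1$best_val_loss, min(fit1$history$val_loss))
  expect_equal(fit1$best_epoch, which.min(fit1$history$val_loss))
  # restored model reproduces the best validation loss
  vl <- ns$val_loss_of(fit1$model, vaf)
  expect_equal(vl, fit1$best_val_loss, tolerance = 1e-9)
  expect_s3_class(tidy(fit1), "tbl_df")
  expect_equal(glance(fit1)$best_epoch, fit1$best_epoch)
  # subject leakage and empty sets are rejected
  expect_error(train(build_model(cfg, seed = 1), trf, trf, tc), "leakage")
  empty <- mk(0, character(0))
  expect_error(train(build_model(cfg, seed = 1), empty, vaf, tc), "empty")
})
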