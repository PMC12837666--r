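ns <- asNamespace("spasmfusion")

rand_feats <- function(cfg, n, Tn = 32, seed = 1) {
  set.seed(seed)
  list(
    eeg = array(rnorm(4 * cfg$eeg_channels * Tn * n),
                c(4, cfg$eeg_channels, Tn, n)),
    emg = array(rnorm(4 * cfg$emg_channels * Tn * n),
                c(4, cfg$emg_channels, Tn, n)),
    labels = rep(c(0L, 1L), length.out = n),
    meta = tibble::tibble(subject_id = rep("sX", n))
  )
}

test_that("branch widths follow D = F x C (100 EEG / 16 EMG by default)", {
  cfg <- model_config(fs = 256)
  expect_equal(cfg$d_eeg, 100)
  expect_equal(cfg$d_emg, 16)
  expect_equal(cfg$mamba_eeg$e, 200) # E = 2D
  expect_equal(cfg$mamba_eeg$n, 32)
})

test_that("forward yields one logit pair per window, deterministically", {
  cfg <- tiny_model_config()
  model <- build_model(cfg, seed = 3)
  f <- rand_feats(cfg, 4)
  out1 <- ns$model_forward(model, f$eeg, f$emg, train = FALSE)
  expect_equal(dim(out1$logits), c(2, 4))
  model2 <- build_model(cfg, seed = 3)
  out2 <- ns$model_forward(model2, f$eeg, f$emg, train = FALSE)
  expect_identical(out1$logits, out2$logits) # seeded init is bit-identical
  model3 <- build_model(cfg, seed = 4)
  out3 <- ns$model_forward(model3, f$eeg, f$emg, train = FALSE)
  expect_false(identical(out1$logits, out3$logits))
})

test_that("classifier head: pooling identity and constant fallback", {
  head <- list(W1 = matrix(rnorm(8 * 16), 8, 16), b1 = rnorm(8),
               W2 = matrix(rnorm(16), 2, 8), b2 = c(0.3, -0.2))
  fused <- matrix(rep(rnorm(16), each = 10), 10, 16) # constant in time
  z <- classify(fused, head)
  pooled <- fused[1, ]
  h <- pmax(head$W1 %*% pooled + head$b1, 0.01 * (head$W1 %*% pooled + head$b1))
  expect_lt(relerr(z, as.numeric(head$W2 %*% h + head$b2)), 1e-12)
  head0 <- head
  head0$W2[] <- 0
  expect_equal(classify(matrix(rnorm(160), 10, 16), head0), head0$b2)
})

test_that("cross-entropy matches softmax NLL and its limits", {
  expect_equal(cross_entropy(c(1, 1), 0), log(2))
  expect_lt(cross_entropy(c(-20, 20), 1), 1e-8)
  set.seed(5)
  z <- rnorm(2)
  p <- exp(z) / sum(exp(z))
  expect_equal(cross_entropy(z, 1), -log(p[2]), tolerance = 1e-12)
  expect_error(cross_entropy(z, 2), "label")
})

test_that("parameter accounting matches the architecture budgets", {
  model <- build_model(model_config(fs = 256), seed = 1)
  pc <- count_parameters(model)
  get <- function(m) pc$params[pc$module == m]
  expect_equal(get("cwt"), 0)
  expect_equal(get("stconv_eeg") + get("stconv_emg"), 4384)
  expect_equal(get("cross_time_mixing"), 230400)
  expect_equal(get("total"), sum(pc$params[pc$module != "total"]))
})

test_that("disabling a stage removes exactly its parameters", {
  full <- build_model(model_config(fs = 256), seed = 1)
  pc_full <- count_parameters(full)
  no_st <- build_model(model_config(fs = 256, use_stconv = FALSE), seed = 1)
  pc_no <- count_parameters(no_st)
  st_params <- sum(pc_full$params[pc_full$module %in%
                                    c("stconv_eeg", "stconv_emg")])
  expect_equal(pc_full$params[pc_full$module == "total"] - st_params,
               pc_no$params[pc_no$module == "total"])
  emg_only <- build_model(model_config(fs = 256, fusion = "none_emg_only"),
                          seed = 1)
  pc_emg <- count_parameters(emg_only)
  expect_false(any(grepl("eeg", pc_emg$module)))
})

test_that("ablated forward paths keep shapes compatible", {
  for (flags in list(list(use_cwt = FALSE), list(use_stconv = FALSE),
                     list(use_bimamba = FALSE))) {
    cfg <- do.call(tiny_model_config, flags)
    model <- build_model(cfg, seed = 2)
    f <- rand_feats(cfg, 3)
    out <- ns$model_forward(model, f$eeg, f$emg, train = FALSE)
    expect_equal(dim(out$logits), c(2, 3))
  }
  for (fus in c("concat", "average", "none_eeg_only", "none_emg_only")) {
    cfg <- tiny_model_config(fusion = fus)
    model <- build_model(cfg, seed = 2)
    f <- rand_feats(cfg, 3)
    out <- ns$model_forward(model, f$eeg, f$emg, train = FALSE)
    expect_equal(dim(out$logits), c(2, 3))
  }
})

test_that("FLOP estimates double with T and follow the MAC=2 convention", {
  model <- build_model(model_config(fs = 256), seed = 1)
  f256 <- estimate_flops(model, 256)
  f512 <- estimate_flops(model, 512)
  for (m in c("bimamba_eeg", "cross_time_mixing")) {
    expect_equal(f512$flops[f512$module == m] /
                   f256$flops[f256$module == m], 2)
  }
  # a single linear map D_in -> D_out over T steps costs 2 T D_in D_out
  expect_equal(f256$flops[f256$module == "proj_eeg"], 2 * 256 * 100 * 128)
})

test_that("one Adam step at lr 1e-4 strictly decreases the batch loss", {
  cfg <- tiny_model_config()
  model <- build_model(cfg, seed = 7)
  f <- rand_feats(cfg, 8, seed = 7)
  fw <- ns$model_forward(model, f$eeg, f$emg, train = TRUE)
  lo <- ns$ce_loss_batch(fw$logits, f$labels)
  gr <- ns$model_backward(model, fw$cache, lo$dlogits)
  st <- ns$adam_step(model$params, gr, ns$adam_init(model$params), lr = 1e-4)
  model$params <- st$params
  fw2 <- ns$model_forward(model, f$eeg, f$emg, train = TRUE)
  lo2 <- ns$ce_loss_batch(fw2$logits, f$labels)
  expect_lt(lo2$loss, lo$loss)
})

test_that("full-model analytic gradients match finite differences", {
  cfg <- tiny_model_config()
  model <- build_model(cfg, seed = 9)
  f <- rand_feats(cfg, 4, Tn = 16, seed = 9)
  fw <- ns$model_forward(model, f$eeg, f$emg, train = TRUE)
  lo <- ns$ce_loss_batch(fw$logits, f$labels)
  gr <- ns$model_backward(model, fw$cache, lo$dlogits)
  g <- ns$tree_flatten(gr)
  v0 <- ns$tree_flatten(model$params)
  loss_at <- function(v) {
    m <- model
    m$params <- ns$tree_fill(model$params, v)
    ns$ce_loss_batch(ns$model_forward(m, f$eeg, f$emg, train = TRUE)$logits,
                     f$labels)$loss
  }
  pick <- order(abs(g), decreasing = TRUE)[1:20]
  gn <- vapply(pick, function(i) {
    e <- 1e-4
    v1 <- v0
    v2 <- v0
    v1[i] <- v1[i] + e
    v2[i] <- v2[i] - e
    (loss_at(v1) - loss_at(v2)) / (2 * e)
  }, numeric(1))
  expect_lt(max(abs(g[pick] - gn)) / max(abs(gn)), 1e-4)
})
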