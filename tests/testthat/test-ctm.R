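ns <- asNamespace("spasmfusion")

test_that("rmsnorm: unit output for constants, scale invariance, formula", {
  x <- matrix(2, 4, 3) # constant vectors, gain 1
  expect_equal(rmsnorm(t(x)), t(matrix(1, 4, 3)), tolerance = 1e-6)
  xc <- matrix(-0.5, 4, 2)
  expect_equal(unique(as.numeric(rmsnorm(t(xc)))), -1, tolerance = 1e-6)
  set.seed(1)
  y <- matrix(rnorm(5 * 4), 5, 4)
  expect_lt(relerr(rmsnorm(7 * y), rmsnorm(y)), 1e-6)
  g <- runif(4)
  direct <- t(apply(y, 1, function(r) r * g / sqrt(mean(r^2) + 1e-8)))
  expect_lt(relerr(rmsnorm(y, g), direct), 1e-12)
})

test_that("token shift blends current and previous steps as specified", {
  set.seed(2)
  Tn <- 6
  D <- 3
  x <- matrix(rnorm(Tn * D), Tn, D)
  W <- matrix(rnorm(D * D), D, D)
  # M = I: no history
  expect_lt(relerr(token_shift_mix(x, diag(D), W), x %*% t(W)), 1e-12)
  # M = 0: pure previous step, first row zero
  shifted <- rbind(0, x[1:(Tn - 1), ])
  expect_lt(relerr(token_shift_mix(x, matrix(0, D, D), W), shifted %*% t(W)),
            1e-12)
  # random matrix mode equals an explicit loop
  M <- matrix(rnorm(D * D, sd = 0.5), D, D)
  out <- token_shift_mix(x, M, W)
  manual <- x * 0
  prev <- rep(0, D)
  for (t in seq_len(Tn)) {
    blend <- M %*% x[t, ] + (diag(D) - M) %*% prev
    manual[t, ] <- W %*% blend
    prev <- x[t, ]
  }
  expect_lt(relerr(out, manual), 1e-12)
  # vector mode equals the elementwise loop
  mu <- runif(D)
  outv <- token_shift_mix(x, mu, W)
  manual <- x * 0
  prev <- rep(0, D)
  for (t in seq_len(Tn)) {
    manual[t, ] <- W %*% (mu * x[t, ] + (1 - mu) * prev)
    prev <- x[t, ]
  }
  expect_lt(relerr(outv, manual), 1e-12)
})

test_that("wkv: constant values are a fixed point in both orders", {
  set.seed(3)
  Tn <- 9
  D <- 4
  k <- matrix(rnorm(Tn * D), Tn)
  v <- matrix(rep(c(2, -1, 0.5, 3), each = Tn), Tn)
  for (ord in c("rwkv", "literal")) {
    out <- wkv_scan(k, v, runif(D, 0.1, 2), rnorm(D), order = ord)
    expect_lt(relerr(out, v), 1e-12)
  }
})

test_that("wkv with infinite decay reduces to the two-term closed form", {
  k <- matrix(c(0.3, -0.8, 1.1, 0.2), 2, 2)
  v <- matrix(c(1.5, -2, 0.7, 0.1), 2, 2)
  u <- c(0.4, -0.3)
  out <- wkv_scan(k, v, omega = c(1e4, 1e4), u = u, order = "rwkv")
  for (d in 1:2) {
    w1 <- exp(k[1, d])
    w2 <- exp(u[d] + k[2, d])
    expect_equal(out[2, d], (w1 * v[1, d] + w2 * v[2, d]) / (w1 + w2),
                 tolerance = 1e-10)
  }
})

test_that("wkv equals the O(T^2) direct sum on 100 random instances", {
  set.seed(4)
  worst <- 0
  for (i in 1:100) {
    Tn <- sample(2:32, 1)
    D <- sample(1:8, 1)
    k <- matrix(rnorm(Tn * D, sd = 2), Tn)
    v <- matrix(rnorm(Tn * D), Tn)
    om <- runif(D, 0.01, 3)
    u <- rnorm(D)
    ord <- sample(c("rwkv", "literal"), 1)
    worst <- max(worst, relerr(wkv_scan(k, v, om, u, ord),
                               wkv_direct_sum(k, v, om, u, ord)))
  }
  expect_lt(worst, 1e-10)
})

test_that("stabilized recurrence matches the naive one where it is finite", {
  set.seed(5)
  Tn <- 24
  D <- 6
  k <- matrix(rnorm(Tn * D, sd = 5), Tn)
  v <- matrix(rnorm(Tn * D), Tn)
  om <- runif(D, 0.05, 1)
  u <- rnorm(D, sd = 2)
  for (ord in c("rwkv", "literal")) {
    naive <- wkv_naive_recurrence(k, v, om, u, ord)
    expect_true(all(is.finite(naive)))
    expect_lt(relerr(wkv_scan(k, v, om, u, ord), naive), 1e-10)
  }
})

test_that("overflow regime stays finite and convexity bounds hold", {
  set.seed(6)
  Tn <- 16
  D <- 4
  k <- matrix(sample(c(-200, 200), Tn * D, TRUE), Tn)
  v <- matrix(rnorm(Tn * D), Tn)
  om <- runif(D, 0.1, 1)
  u <- rnorm(D)
  for (ord in c("rwkv", "literal")) {
    out <- wkv_scan(k, v, om, u, ord)
    expect_true(all(is.finite(out)))
    for (t in seq_len(Tn)) {
      for (d in seq_len(D)) {
        expect_gte(out[t, d], min(v[1:t, d]) - 1e-9)
        expect_lte(out[t, d], max(v[1:t, d]) + 1e-9)
      }
    }
  }
})

test_that("faster decay monotonically reduces the influence of v_1", {
  set.seed(7)
  Tn <- 20
  k <- matrix(rnorm(Tn), Tn, 1)
  v <- matrix(rnorm(Tn), Tn, 1)
  u <- 0.2
  influence <- vapply(c(0.05, 0.3, 1, 3), function(om) {
    v2 <- v
    v2[1, 1] <- v2[1, 1] + 1
    abs(wkv_scan(k, v2, om, u)[Tn, 1] - wkv_scan(k, v, om, u)[Tn, 1])
  }, numeric(1))
  expect_true(all(diff(influence) <= 1e-12))
})

test_that("direction forward: zero projection or closed gate silence output", {
  cfg <- ctm_config(d = 4)
  par <- ns$with_seed(8, ns$ctm_direction_init(cfg))
  set.seed(8)
  q <- matrix(rnorm(24), 6, 4)
  ctx <- matrix(rnorm(24), 6, 4)
  par0 <- par
  par0$Wo[] <- 0
  expect_true(all(ctm_direction_forward(q, ctx, par0, cfg) == 0))
  par_neg <- par
  par_neg$Wr[] <- 0
  par_neg$Mr[] <- 0 # receptance pre-activation forced to 0 -> sigmoid 0.5
  o_half <- ctm_direction_forward(q, ctx, par_neg, cfg)
  # closed-form check of composition: o = Wo (0.5 * wkv)
  kk <- token_shift_mix(ctx, par$Mk, par$Wk)
  vv <- token_shift_mix(ctx, par$Mv, par$Wv)
  wk <- wkv_scan(kk, vv, par$omega, par$u)
  expect_lt(relerr(o_half, (0.5 * wk) %*% t(par$Wo)), 1e-10)
  expect_error(ctm_direction_forward(q, ctx[1:3, ], par, cfg), "equal shape")
})

test_that("random direction output equals the sub-operation composition", {
  cfg <- ctm_config(d = 5)
  par <- ns$with_seed(9, ns$ctm_direction_init(cfg))
  set.seed(9)
  q <- matrix(rnorm(40), 8, 5)
  ctx <- matrix(rnorm(40), 8, 5)
  o <- ctm_direction_forward(q, ctx, par, cfg)
  r <- token_shift_mix(q, par$Mr, par$Wr)
  kk <- token_shift_mix(ctx, par$Mk, par$Wk)
  vv <- token_shift_mix(ctx, par$Mv, par$Wv)
  wk <- wkv_scan(kk, vv, par$omega, par$u)
  manual <- (1 / (1 + exp(-r)) * wk) %*% t(par$Wo)
  expect_lt(relerr(o, manual), 1e-10)
})

test_that("fusion degenerates to summed RMSNorms when projections vanish", {
  cfg <- ctm_config(d = 4)
  par <- ns$with_seed(10, ns$ctm_init(cfg))
  par$dir_eeg$Wo[] <- 0
  par$dir_emg$Wo[] <- 0
  set.seed(10)
  xe <- matrix(rnorm(24), 6, 4)
  xm <- matrix(rnorm(24), 6, 4)
  out <- ctm_fuse(xe, xm, par, cfg)
  expect_lt(relerr(out, rmsnorm(xe, par$g_out_eeg) +
                     rmsnorm(xm, par$g_out_emg)), 1e-10)
})

test_that("swapping modalities together with direction parameters is exact", {
  cfg <- ctm_config(d = 4)
  par <- ns$with_seed(11, ns$ctm_init(cfg))
  set.seed(11)
  xe <- matrix(rnorm(24), 6, 4)
  xm <- matrix(rnorm(24), 6, 4)
  par_sw <- par
  par_sw$dir_eeg <- par$dir_emg
  par_sw$dir_emg <- par$dir_eeg
  par_sw$g_in_eeg <- par$g_in_emg
  par_sw$g_in_emg <- par$g_in_eeg
  par_sw$g_out_eeg <- par$g_out_emg
  par_sw$g_out_emg <- par$g_out_eeg
  expect_lt(relerr(ctm_fuse(xm, xe, par_sw, cfg), ctm_fuse(xe, xm, par, cfg)),
            1e-12)
})

test_that("fused module at width 128 counts exactly 230400 parameters", {
  cfg <- ctm_config(d = 128, mix_mode = "matrix")
  par <- ns$with_seed(1, ns$ctm_init(cfg))
  expect_equal(ns$tree_count(par), 230400)
  expect_equal(round(ns$tree_count(par) / 1e6, 2), 0.23)
})

test_that("analytic WKV cost is linear in T, quadratic attention is not", {
  cfg <- ctm_config(d = 64)
  f <- vapply(c(256, 512, 1024), function(T) ns$flops_ctm(cfg, T), numeric(1))
  expect_equal(f[2] / f[1], 2)
  expect_equal(f[3] / f[2], 2)
  q <- vapply(c(256, 512, 1024), function(T) flops_quadratic_attention(T, 64),
              numeric(1))
  expect_gt(q[3] / q[2], 2 * 0.99)
  expect_gt((q[3] - q[2]) / (q[2] - q[1]), 2) # super-linear growth
})

test_that("fusion gradients agree with finite differences (both orders)", {
  for (ord in c("rwkv", "literal")) {
    cfg <- ctm_config(d = 4, wkv_order = ord)
    par <- ns$with_seed(12, ns$ctm_init(cfg))
    set.seed(12)
    Tn <- 5
    B <- 2
    xe <- matrix(rnorm(4 * Tn * B), 4)
    xm <- matrix(rnorm(4 * Tn * B), 4)
    wts <- matrix(rnorm(4 * Tn * B), 4)
    fw <- ns$ctm_fuse_fwd(xe, xm, par, cfg, Tn, B)
    bw <- ns$ctm_fuse_bwd(wts, xe, xm, par, cfg, Tn, B, fw$cache)
    f <- function(v) sum(ns$ctm_fuse_fwd(xe, xm, ns$tree_fill(par, v), cfg,
                                         Tn, B)$y * wts)
    gn <- num_grad(f, ns$tree_flatten(par), 1e-6)
    expect_lt(relerr(ns$tree_flatten(bw$grads), gn), 1e-6)
  }
})
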