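test_that("scaled dot-product attention has the softmax limit behaviours", {
  withr::with_seed(1, {
    # a single key: output equals the single value row for any query
    Q <- matrix(rnorm(6), 3, 2)
    K <- matrix(c(0.3, -1), 1, 2)
    V <- matrix(c(5, -2, 7), 1, 3)
    out <- scaled_dot_attention(Q, K, V)
    for (i in 1:3) expect_equal(unname(out$output[i, ]), c(5, -2, 7))
    expect_true(all(out$weights == 1))

    # all logits equal (zero query): output is the column mean of V
    Q0 <- matrix(0, 2, 3)
    K2 <- matrix(rnorm(12), 4, 3)
    V2 <- matrix(rnorm(8), 4, 2)
    out2 <- scaled_dot_attention(Q0, K2, V2)
    expect_equal(out2$output[1, ], colMeans(V2))
    expect_close(rowSums(out2$weights), 1, 1e-12)
  })
})

test_that("the two-key worked example reproduces the hand-computed softmax", {
  out <- scaled_dot_attention(matrix(c(1, 0), 1, 2), diag(2), diag(2))
  # logits (1/sqrt(2), 0); softmax = exp(l)/sum -> (0.66984, 0.33016)
  w_oracle <- exp(c(1 / sqrt(2), 0)) / sum(exp(c(1 / sqrt(2), 0)))
  expect_equal(drop(out$weights), w_oracle, tolerance = 1e-12)
  expect_equal(drop(out$output), w_oracle, tolerance = 1e-12)
  expect_equal(round(drop(out$weights), 4), c(0.6698, 0.3302))
})

test_that("per-head projections reduce to identity and match a loop oracle", {
  p <- manual_mhca_params(C = 4, d_model = 4, n_heads = 1, identity_adapters = TRUE)
  p$Wq[[1]] <- diag(4)
  x <- withr::with_seed(2, matrix(rnorm(12), 3, 4))
  heads <- project_qkv(x, x, x, p)
  expect_equal(heads[[1]]$Q, x %*% diag(4))
  expect_equal(project_qkv(x * 0, x * 0, x * 0, p)[[1]]$K, matrix(0, 3, 4))

  withr::with_seed(3, {
    xq <- matrix(rnorm(12), 3, 4)
    W <- matrix(rnorm(8), 4, 2)
    p2 <- manual_mhca_params(C = 4, d_model = 4, n_heads = 2)
    p2$Wq[[1]] <- W
    got <- project_qkv(xq, xq, xq, p2)[[1]]$Q
    oracle <- matrix(0, 3, 2)
    for (i in 1:3) for (j in 1:2) oracle[i, j] <- sum(xq[i, ] * W[, j])
    expect_equal(got, oracle, tolerance = 1e-12)
  })
})

test_that("fused cross-attention equals the loop-based brute force on random instances", {
  withr::with_seed(11, {
    for (trial in 1:20) {
      S <- sample(1:4, 1); C <- sample(1:4, 1)
      h <- sample(1:2, 1); dm <- h * sample(1:2, 1)
      mode <- sample(c("concat_project", "head_mean"), 1)
      p <- manual_mhca_params(C, dm, h, seed = trial, fusion_mode = mode)
      xq <- matrix(rnorm(S * C), S, C)
      xk <- matrix(rnorm(S * C), S, C)
      xv <- matrix(rnorm(S * C), S, C)
      got <- multi_head_cross_attention(xq, xk, xv, p)
      expect_lt(max(abs(got$x_fusion - naive_mhca(xq, xk, xv, p))), 1e-5)
      sums <- apply(got$attention, c(1, 2), sum)
      expect_close(sums, 1, 1e-5)
    }
  })
})

test_that("attention output stays in the convex hull of value rows and is key-permutation symmetric", {
  withr::with_seed(21, {
    for (trial in 1:10) {
      Q <- matrix(rnorm(8), 2, 4)
      K <- matrix(rnorm(20), 5, 4)
      V <- matrix(rnorm(15), 5, 3)
      out <- scaled_dot_attention(Q, K, V)$output
      for (j in 1:3) {
        expect_true(all(out[, j] >= min(V[, j]) - 1e-12))
        expect_true(all(out[, j] <= max(V[, j]) + 1e-12))
      }
      perm <- sample(5)
      out_p <- scaled_dot_attention(Q, K[perm, ], V[perm, ])$output
      expect_equal(out, out_p, tolerance = 1e-12)
    }
  })
})

test_that("identical value tokens pass through regardless of query/key content", {
  v <- c(1, 2, 0.5, 3)
  p <- manual_mhca_params(C = 4, d_model = 4, n_heads = 1, identity_adapters = TRUE)
  p$Wv[[1]] <- diag(4)
  xv <- matrix(rep(v, each = 3), 3, byrow = FALSE) # 3 identical non-negative rows
  for (seed in 1:3) {
    xq <- withr::with_seed(seed, matrix(abs(rnorm(12)), 3, 4))
    xk <- withr::with_seed(seed + 10, matrix(abs(rnorm(12)), 3, 4))
    fr <- multi_head_cross_attention(xq, xk, xv, p)
    expect_equal(fr$x_fusion, drop(v %*% p$Wo), tolerance = 1e-10)
  }
})

test_that("single-head fusion with identity output projection reduces to plain attention", {
  p <- manual_mhca_params(C = 3, d_model = 3, n_heads = 1, identity_adapters = TRUE)
  p$Wo <- diag(3)
  withr::with_seed(4, {
    xq <- matrix(abs(rnorm(9)), 3, 3)
    xk <- matrix(abs(rnorm(9)), 3, 3)
    xv <- matrix(abs(rnorm(9)), 3, 3)
  })
  fr <- multi_head_cross_attention(xq, xk, xv, p)
  direct <- scaled_dot_attention(xq %*% p$Wq[[1]], xk %*% p$Wk[[1]], xv %*% p$Wv[[1]])
  expect_equal(fr$fused_tokens, direct$output, tolerance = 1e-12)
})

test_that("the regression head is affine with the stated degenerate cases", {
  head0 <- list(W_bp = matrix(0, 2, 4), b_bp = c(120, 80))
  est <- regress_bp(c(1, 2, 3, 4), head0, "w1")
  expect_equal(c(est$sbp_hat, est$dbp_hat), c(120, 80))
  headr <- withr::with_seed(6, list(W_bp = matrix(rnorm(8), 2, 4), b_bp = c(1, -1)))
  expect_equal(unname(unlist(regress_bp(rep(0, 4), headr)[, c("sbp_hat", "dbp_hat")])),
               headr$b_bp)
  x <- c(0.5, -1, 2, 0.25)
  got <- regress_bp(x, headr)
  oracle <- c(sum(headr$W_bp[1, ] * x) + 1, sum(headr$W_bp[2, ] * x) - 1)
  expect_equal(unname(unlist(got[, c("sbp_hat", "dbp_hat")])), oracle, tolerance = 1e-12)
})

test_that("full forward is deterministic and identical inputs give identical estimates", {
  m <- toy_model()
  win <- make_toy_windows(2, len = 60)
  win$ppg[[2]] <- win$ppg[[1]]; win$vppg[[2]] <- win$vppg[[1]]; win$appg[[2]] <- win$appg[[1]]
  p1 <- predict(m, win)
  p2 <- predict(m, win)
  expect_identical(p1$sbp_hat, p2$sbp_hat)
  expect_equal(p1$sbp_hat[1], p1$sbp_hat[2])
  expect_equal(p1$dbp_hat[1], p1$dbp_hat[2])
})

test_that("analytic gradients match central finite differences", {
  m <- toy_model(d_model = 8, n_heads = 2, img = 32)
  win <- make_toy_windows(1, len = 50)
  tok <- ppgbp:::window_tokens(m, win[1, ])
  y <- c(0.4, -0.2)
  res <- ppgbp:::window_loss_grads(m, tok, y)
  flat <- ppgbp:::collect_params(m)
  check_group <- function(nm, k = 6, tol = 1e-4) {
    p <- flat[[nm]]
    for (j in withr::with_seed(9, sample(length(p), min(k, length(p))))) {
      eps <- 1e-5
      up <- flat; up[[nm]][j] <- up[[nm]][j] + eps
      dn <- flat; dn[[nm]][j] <- dn[[nm]][j] - eps
      lp <- ppgbp:::window_loss_grads(ppgbp:::set_params(m, up), tok, y)$loss
      lm <- ppgbp:::window_loss_grads(ppgbp:::set_params(m, dn), tok, y)$loss
      fd <- (lp - lm) / (2 * eps)
      an <- res$grads[[nm]][j]
      expect_lt(abs(fd - an) / max(1e-8, abs(fd), abs(an)), tol)
    }
  }
  check_group("head.W_bp")
  check_group("head.b_bp")
  check_group("mhca.Wo")
  check_group("mhca.Aq")
  check_group("mhca.Wq.1")
  check_group("mhca.Wk.2")
  check_group("mhca.Wv.1")
})

test_that("invalid attention inputs and configurations are rejected", {
  expect_error(scaled_dot_attention(matrix(1, 1, 2), matrix(numeric(0), 0, 2), matrix(1, 1, 2)),
               class = "ppgbp_input_error")
  expect_error(mhca_config(d_model = 10, n_heads = 3), class = "ppgbp_config_error")
  expect_error(mhca_config(roles = c(q = "ppg", k = "ppg", v = "appg")),
               class = "ppgbp_config_error")
})
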