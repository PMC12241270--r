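# Shared fixtures and independent oracles used across test files.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small window tibble with arbitrary signals (not from the simulator).
make_toy_windows <- function(n = 8, len = 40, sbp = NULL, dbp = NULL, seed = 7) {
  withr::with_seed(seed, {
    tibble::tibble(
      window_id = sprintf("toy_w%03d", seq_len(n)),
      record_id = sprintf("toy_r%03d", seq_len(n)),
      subject_id = sprintf("toy_s%03d", ((seq_len(n) - 1) %% 4) + 1),
      sampling_rate = 50,
      start_time = 0,
      sbp = sbp %||% runif(n, 100, 160),
      dbp = dbp %||% runif(n, 60, 90),
      ppg = purrr::map(seq_len(n), ~ rnorm(len)),
      vppg = purrr::map(seq_len(n), ~ rnorm(len)),
      appg = purrr::map(seq_len(n), ~ rnorm(len))
    )
  })
}

# A small, fast model configuration for training tests.
toy_model <- function(freeze = TRUE, d_model = 16, n_heads = 2, img = 32, seed = 3) {
  bp_model(
    backbone_config("tiny", freeze = freeze, seed = seed),
    mhca_config(d_model = d_model, n_heads = n_heads, seed = seed),
    render_spec(img, img, margin = 2),
    seed = seed
  )
}

# Straight-line reimplementation of the fused cross-attention with explicit
# loops: adapters, per-head projections, softmax attention, head combination
# and the mean over query tokens. Kept deliberately naive and independent of
# the package's vectorized path.
naive_mhca <- function(x_q, x_k, x_v, params) {
  cfg <- params$config
  relu <- function(m) pmax(m, 0)
  lin <- function(x, A, b) {
    out <- matrix(0, nrow(x), ncol(A))
    for (i in seq_len(nrow(x))) {
      for (j in seq_len(ncol(A))) {
        acc <- b[j]
        for (c in seq_len(ncol(x))) acc <- acc + x[i, c] * A[c, j]
        out[i, j] <- acc
      }
    }
    out
  }
  aq <- relu(lin(x_q, params$Aq, params$bq))
  ak <- relu(lin(x_k, params$Ak, params$bk))
  av <- relu(lin(x_v, params$Av, params$bv))
  heads <- list()
  for (h in seq_len(cfg$n_heads)) {
    Q <- lin(aq, params$Wq[[h]], numeric(cfg$d_k))
    K <- lin(ak, params$Wk[[h]], numeric(cfg$d_k))
    V <- lin(av, params$Wv[[h]], numeric(cfg$d_k))
    O <- matrix(0, nrow(Q), cfg$d_k)
    for (i in seq_len(nrow(Q))) {
      logits <- numeric(nrow(K))
      for (j in seq_len(nrow(K))) logits[j] <- sum(Q[i, ] * K[j, ]) / sqrt(ncol(K))
      w <- exp(logits - max(logits))
      w <- w / sum(w)
      for (j in seq_len(nrow(K))) O[i, ] <- O[i, ] + w[j] * V[j, ]
    }
    heads[[h]] <- O
  }
  if (cfg$fusion_mode == "concat_project") {
    concat <- do.call(cbind, heads)
    fused <- lin(concat, params$Wo, numeric(cfg$d_model))
  } else {
    avg <- Reduce(`+`, heads) / cfg$n_heads
    fused <- lin(avg, params$Wo[seq_len(cfg$d_k), , drop = FALSE], numeric(cfg$d_model))
  }
  colMeans(fused)
}

# Hand-constructed MHCA parameters with explicit dimensions (bypasses the
# seeded initializer so tests control every matrix).
manual_mhca_params <- function(C, d_model, n_heads, seed = 1,
                               fusion_mode = "concat_project",
                               identity_adapters = FALSE) {
  cfg <- mhca_config(d_model = d_model, n_heads = n_heads,
                     fusion_mode = fusion_mode, seed = seed)
  withr::with_seed(seed, {
    rnd <- function(a, b) matrix(rnorm(a * b, sd = 0.5), a, b)
    p <- list(
      config = cfg,
      Aq = if (identity_adapters) diag(C) else rnd(C, d_model),
      bq = numeric(d_model),
      Ak = if (identity_adapters) diag(C) else rnd(C, d_model),
      bk = numeric(d_model),
      Av = if (identity_adapters) diag(C) else rnd(C, d_model),
      bv = numeric(d_model),
      Wq = lapply(seq_len(n_heads), function(i) rnd(d_model, cfg$d_k)),
      Wk = lapply(seq_len(n_heads), function(i) rnd(d_model, cfg$d_k)),
      Wv = lapply(seq_len(n_heads), function(i) rnd(d_model, cfg$d_k)),
      Wo = rnd(n_heads * cfg$d_k, d_model)
    )
    class(p) <- "mhca_params"
    p
  })
}

# Enumeration oracle for the sliding-window count.
count_windows_naive <- function(n, w, s) {
  count <- 0L
  start <- 0L
  while (start + w <= n) {
    count <- count + 1L
    start <- start + s
  }
  count
}

expect_close <- function(x, y, tol) expect_true(all(abs(x - y) <= tol))
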