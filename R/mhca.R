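#' Multi-head cross-attention configuration
#'
#' Fuses the three modality token grids with PPG as query, vPPG as key and
#' aPPG as value. Input adapters (linear + ReLU) map the backbone's token
#' channels to the model width `d_model`; per-head projections map `d_model`
#' to the head width `d_k = d_model / n_heads`.
#'
#' Two fusion readings are provided. `"concat_project"` (default, canonical):
#' per-query head outputs are concatenated and projected with `W^O`, then
#' averaged over query tokens into one `d_model` fusion vector.
#' `"head_mean"`: head outputs are averaged over heads first and then
#' projected; this is the literal per-head-average reading and is retained as
#' an alternative. `attend_over = "vector"` collapses every modality to its
#' pooled embedding before attention, in which case the softmax over a single
#' key degenerates to a pass-through of the value modality; `"tokens"`
#' (default) attends over the spatial token sequence.
#'
#' @param d_model Fusion width (divisible by `n_heads`).
#' @param n_heads Number of attention heads.
#' @param fusion_mode `"concat_project"` or `"head_mean"`.
#' @param attend_over `"tokens"` or `"vector"`.
#' @param roles Named character vector assigning modalities to query/key/value.
#' @param seed Seed for parameter initialization.
#' @return An object of class `mhca_config`.
#' @export
mhca_config <- function(d_model = 256L, n_heads = 4L,
                        fusion_mode = c("concat_project", "head_mean"),
                        attend_over = c("tokens", "vector"),
                        roles = c(q = "ppg", k = "vppg", v = "appg"),
                        seed = 0L) {
  fusion_mode <- match.arg(fusion_mode)
  attend_over <- match.arg(attend_over)
  if (!is_count(d_model) || !is_count(n_heads) || d_model %% n_heads != 0) {
    abort_config("`d_model` must be a positive multiple of `n_heads`.")
  }
  if (!setequal(names(roles), c("q", "k", "v")) ||
      !setequal(unname(roles), c("ppg", "vppg", "appg"))) {
    abort_config("`roles` must assign ppg/vppg/appg to q/k/v.")
  }
  structure(
    list(d_model = as.integer(d_model), n_heads = as.integer(n_heads),
         d_k = as.integer(d_model / n_heads), fusion_mode = fusion_mode,
         attend_over = attend_over, roles = roles, seed = as.integer(seed)),
    class = "mhca_config"
  )
}

# Scaled uniform (fan-in) initialization for a linear map.
lin_init <- function(nin, nout) he_uniform(nin, nout, nin)

#' Initialize MHCA parameters
#'
#' @param config An [mhca_config()].
#' @param token_channels Channel count `C` of the backbone token grids.
#' @return A parameter list of class `mhca_params`: adapters `Aq/Ak/Av` with
#'   biases, per-head projection lists `Wq/Wk/Wv`, output projection `Wo`, and
#'   the configuration.
#' @export
init_mhca <- function(config = mhca_config(), token_channels = 32L) {
  with_local_seed(config$seed, {
    p <- list(
      config = config,
      Aq = lin_init(token_channels, config$d_model), bq = numeric(config$d_model),
      Ak = lin_init(token_channels, config$d_model), bk = numeric(config$d_model),
      Av = lin_init(token_channels, config$d_model), bv = numeric(config$d_model),
      Wq = lapply(seq_len(config$n_heads), function(i) lin_init(config$d_model, config$d_k)),
      Wk = lapply(seq_len(config$n_heads), function(i) lin_init(config$d_model, config$d_k)),
      Wv = lapply(seq_len(config$n_heads), function(i) lin_init(config$d_model, config$d_k)),
      Wo = lin_init(config$n_heads * config$d_k, config$d_model)
    )
    class(p) <- "mhca_params"
    p
  })
}

#' Row-wise softmax with max subtraction
#'
#' @param x Numeric matrix of logits.
#' @return Matrix of the same shape; every row sums to 1.
#' @export
softmax_rows <- function(x) {
  m <- apply(x, 1, max)
  e <- exp(x - m)
  e / rowSums(e)
}

#' Scaled dot-product attention
#'
#' Computes `softmax(Q K' / sqrt(d_k)) V` with the softmax taken over the key
#' axis and max-subtraction for overflow safety. Every output row is a convex
#' combination of the rows of `V`.
#'
#' @param Q Query matrix (`S_q x d_k`).
#' @param K Key matrix (`S_k x d_k`).
#' @param V Value matrix (`S_k x d_v`).
#' @return List with `output` (`S_q x d_v`) and `weights` (`S_q x S_k`, rows
#'   summing to 1).
#' @export
scaled_dot_attention <- function(Q, K, V) {
  if (is.null(dim(K)) || nrow(K) == 0) abort_input("`K` must contain at least one key row.")
  if (ncol(Q) != ncol(K)) abort_input("Q and K must share the inner dimension.")
  if (nrow(K) != nrow(V)) abort_input("K and V must have the same number of rows.")
  logits <- tcrossprod(Q, K) / sqrt(ncol(K))
  w <- softmax_rows(logits)
  list(output = w %*% V, weights = w)
}

# Adapter: linear + ReLU mapping token channels to d_model.
adapt_tokens <- function(x, A, b) {
  pre <- sweep(x %*% A, 2, b, "+")
  list(out = pre * (pre > 0), mask = pre > 0)
}

#' Per-head query/key/value projections
#'
#' Applies the learned per-head projections `Q_i = X_q W_i^Q`,
#' `K_i = X_k W_i^K`, `V_i = X_v W_i^V` to (already channel-adapted) token
#' matrices. Row counts are preserved: queries keep `S_q` rows from the query
#' modality, keys/values keep `S_k` rows.
#'
#' @param x_q,x_k,x_v Token matrices for the query/key/value modalities.
#' @param params An `mhca_params` list (only the `Wq`/`Wk`/`Wv` entries are
#'   used here).
#' @return A list with one element per head, each holding `Q`, `K`, `V`.
#' @export
project_qkv <- function(x_q, x_k, x_v, params) {
  h <- params$config$n_heads
  if (ncol(x_q) != nrow(params$Wq[[1]])) abort_config("query channel count does not match W^Q.")
  if (ncol(x_k) != nrow(params$Wk[[1]])) abort_config("key channel count does not match W^K.")
  if (ncol(x_v) != nrow(params$Wv[[1]])) abort_config("value channel count does not match W^V.")
  lapply(seq_len(h), function(i) {
    list(Q = x_q %*% params$Wq[[i]], K = x_k %*% params$Wk[[i]], V = x_v %*% params$Wv[[i]])
  })
}

#' Multi-head cross-attention fusion
#'
#' Runs the full fusion: channel adapters, per-head projections, scaled
#' dot-product attention per head, head combination (see [mhca_config()] for
#' the two fusion modes) and averaging over query tokens into a single
#' `d_model` fusion vector.
#'
#' @param x_q,x_k,x_v Raw token matrices (`S x C`) for the query, key and
#'   value modalities.
#' @param params An `mhca_params` from [init_mhca()].
#' @param keep_cache Keep intermediate activations for backpropagation.
#' @return List of class `fused_repr`: `x_fusion` (length `d_model`),
#'   `fused_tokens` (`S_q x d_model`), `attention` (`h x S_q x S_k` array of
#'   weights, rows summing to 1), and (optionally) `cache`.
#' @export
multi_head_cross_attention <- function(x_q, x_k, x_v, params, keep_cache = FALSE) {
  cfg <- params$config
  if (cfg$attend_over == "vector") {
    x_q <- matrix(colMeans(x_q), 1); x_k <- matrix(colMeans(x_k), 1)
    x_v <- matrix(colMeans(x_v), 1)
  }
  aq <- adapt_tokens(x_q, params$Aq, params$bq)
  ak <- adapt_tokens(x_k, params$Ak, params$bk)
  av <- adapt_tokens(x_v, params$Av, params$bv)
  heads <- project_qkv(aq$out, ak$out, av$out, params)
  att <- lapply(heads, function(hd) scaled_dot_attention(hd$Q, hd$K, hd$V))
  s_q <- nrow(x_q); s_k <- nrow(x_k)
  attention <- array(0, dim = c(cfg$n_heads, s_q, s_k))
  for (i in seq_len(cfg$n_heads)) attention[i, , ] <- att[[i]]$weights
  if (cfg$fusion_mode == "concat_project") {
    concat <- do.call(cbind, lapply(att, `[[`, "output")) # S_q x (h*d_k)
    fused <- concat %*% params$Wo
  } else { # head_mean: average head outputs, project with the leading d_k rows
    concat <- Reduce(`+`, lapply(att, `[[`, "output")) / cfg$n_heads
    fused <- concat %*% params$Wo[seq_len(cfg$d_k), , drop = FALSE]
  }
  out <- list(
    x_fusion = colMeans(fused),
    fused_tokens = fused,
    attention = attention
  )
  if (keep_cache) {
    out$cache <- list(x_q = x_q, x_k = x_k, x_v = x_v, aq = aq, ak = ak, av = av,
                      heads = heads, att = att, concat = concat)
  }
  class(out) <- "fused_repr"
  out
}

#' Linear regression head mapping the fusion vector to (SBP, DBP)
#'
#' @param fused A `fused_repr` (or a bare `d_model` numeric vector).
#' @param head List with `W_bp` (`2 x d_model`) and `b_bp` (length-2 mmHg
#'   offsets, order SBP then DBP).
#' @param window_id Optional window identifier carried through.
#' @return A one-row tibble with `window_id`, `sbp_hat`, `dbp_hat` (mmHg).
#' @export
regress_bp <- function(fused, head, window_id = NA_character_) {
  x <- if (inherits(fused, "fused_repr")) fused$x_fusion else fused
  if (ncol(head$W_bp) != length(x)) abort_config("regression head width does not match d_model.")
  y <- drop(head$W_bp %*% x) + head$b_bp
  tibble::tibble(window_id = window_id, sbp_hat = y[1], dbp_hat = y[2])
}

# Backward pass through multi_head_cross_attention + mean-over-queries.
# `dfusion` is the gradient w.r.t. x_fusion (length d_model). Returns
# parameter gradients and gradients w.r.t. the raw token matrices.
mhca_backward <- function(dfusion, params, cache) {
  cfg <- params$config
  s_q <- nrow(cache$aq$out)
  dk <- cfg$d_k
  dfused <- matrix(rep(dfusion / s_q, each = s_q), nrow = s_q) # mean over queries
  if (cfg$fusion_mode == "concat_project") {
    dWo <- crossprod(cache$concat, dfused)
    dconcat <- tcrossprod(dfused, params$Wo)
    dheads <- lapply(seq_len(cfg$n_heads), function(i) {
      dconcat[, (i - 1L) * dk + seq_len(dk), drop = FALSE]
    })
  } else {
    wo_hm <- params$Wo[seq_len(dk), , drop = FALSE]
    dWo <- matrix(0, nrow(params$Wo), ncol(params$Wo))
    dWo[seq_len(dk), ] <- crossprod(cache$concat, dfused)
    dmean <- tcrossprod(dfused, wo_hm)
    dheads <- lapply(seq_len(cfg$n_heads), function(i) dmean / cfg$n_heads)
  }
  dXq_ad <- matrix(0, nrow(cache$aq$out), cfg$d_model)
  dXk_ad <- matrix(0, nrow(cache$ak$out), cfg$d_model)
  dXv_ad <- matrix(0, nrow(cache$av$out), cfg$d_model)
  gWq <- vector("list", cfg$n_heads); gWk <- gWq; gWv <- gWq
  for (i in seq_len(cfg$n_heads)) {
    hd <- cache$heads[[i]]; at <- cache$att[[i]]
    dO <- dheads[[i]]
    dV <- crossprod(at$weights, dO)
    dA <- tcrossprod(dO, hd$V)
    dL <- at$weights * (dA - rowSums(dA * at$weights))
    dL <- dL / sqrt(ncol(hd$K))
    dQ <- dL %*% hd$K
    dK <- crossprod(dL, hd$Q)
    gWq[[i]] <- crossprod(cache$aq$out, dQ)
    gWk[[i]] <- crossprod(cache$ak$out, dK)
    gWv[[i]] <- crossprod(cache$av$out, dV)
    dXq_ad <- dXq_ad + tcrossprod(dQ, params$Wq[[i]])
    dXk_ad <- dXk_ad + tcrossprod(dK, params$Wk[[i]])
    dXv_ad <- dXv_ad + tcrossprod(dV, params$Wv[[i]])
  }
  adapter_back <- function(dout, ad, x_raw, A) {
    dpre <- dout * ad$mask
    list(dA = crossprod(x_raw, dpre), db = colSums(dpre), dx = tcrossprod(dpre, A))
  }
  bq <- adapter_back(dXq_ad, cache$aq, cache$x_q, params$Aq)
  bk <- adapter_back(dXk_ad, cache$ak, cache$x_k, params$Ak)
  bv <- adapter_back(dXv_ad, cache$av, cache$x_v, params$Av)
  list(
    Aq = bq$dA, bq = bq$db, Ak = bk$dA, bk = bk$db, Av = bv$dA, bv = bv$db,
    Wq = gWq, Wk = gWk, Wv = gWv, Wo = dWo,
    dx_q = bq$dx, dx_k = bk$dx, dx_v = bv$dx
  )
}
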