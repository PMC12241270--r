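#' Assemble the end-to-end blood-pressure model
#'
#' Combines rendering, backbone, cross-attention fusion and the linear
#' regression head into one object. The forward path for a window is:
#' render the three modality images, extract token grids, fuse with
#' multi-head cross-attention, regress (SBP, DBP).
#'
#' @param backbone A [backbone_config()].
#' @param fusion An [mhca_config()].
#' @param render A [render_spec()].
#' @param seed Seed for head initialization (backbone/fusion carry their own).
#' @return An object of class `bp_model`.
#' @export
bp_model <- function(backbone = backbone_config(), fusion = mhca_config(),
                     render = render_spec(), seed = 0L) {
  bb <- init_backbone(backbone)
  mh <- init_mhca(fusion, token_channels = backbone$token_channels)
  head <- with_local_seed(derive_seed(seed, 7L), {
    list(W_bp = t(lin_init(fusion$d_model, 2L)), b_bp = c(0, 0))
  })
  structure(
    list(backbone = bb, mhca = mh, head = head, render = render,
         target_scale = NULL, feature_norm = NULL, seed = as.integer(seed)),
    class = "bp_model"
  )
}

# Render one window and extract the (q, k, v) raw token triplet according to
# the configured modality roles.
window_tokens <- function(model, window, keep_cache = FALSE) {
  trip <- render_triplet(window, model$render)
  imgs <- list(ppg = trip$ppg_img, vppg = trip$vppg_img, appg = trip$appg_img)
  roles <- model$mhca$config$roles
  fw <- lapply(imgs, function(img) {
    x <- normalize_image(img, model$backbone$config)
    if (model$backbone$config$kind == "tiny") {
      tiny_forward(x, model$backbone$params, keep_cache = keep_cache)
    } else {
      resnet50_forward(x, model$backbone$params)
    }
  })
  list(q = fw[[roles[["q"]]]], k = fw[[roles[["k"]]]], v = fw[[roles[["v"]]]])
}

# Per-channel standardization of token features, with statistics estimated
# from the training windows at train time (see train_bp_model). Conditions
# the adapter inputs so short optimization schedules converge.
apply_feature_norm <- function(tokens, fn) {
  if (is.null(fn)) return(tokens)
  for (role in c("q", "k", "v")) {
    tk <- tokens[[role]]$tokens
    tokens[[role]]$tokens <- sweep(sweep(tk, 2, fn[[role]]$mu, "-"), 2, fn[[role]]$sd, "/")
  }
  tokens
}

compute_feature_norm <- function(token_list) {
  out <- list()
  for (role in c("q", "k", "v")) {
    stacked <- do.call(rbind, lapply(token_list, function(t) t[[role]]$tokens))
    mu <- colMeans(stacked)
    sdv <- apply(stacked, 2, sd)
    sdv[!is.finite(sdv) | sdv < 1e-6] <- 1
    out[[role]] <- list(mu = mu, sd = sdv)
  }
  out
}

# Forward pass from a raw token triplet (list with q/k/v token matrices).
model_forward <- function(model, tokens, keep_cache = FALSE) {
  tokens <- apply_feature_norm(tokens, model$feature_norm)
  fused <- multi_head_cross_attention(tokens$q$tokens, tokens$k$tokens, tokens$v$tokens,
                                      model$mhca, keep_cache = keep_cache)
  pred <- drop(model$head$W_bp %*% fused$x_fusion) + model$head$b_bp
  list(pred = pred, fused = fused)
}

unscale_pred <- function(pred, scale) {
  if (is.null(scale)) return(pred)
  pred * scale$sigma + scale$mu
}

#' Predict blood pressure for analysis windows
#'
#' @param object A `bp_model` (typically the trained model inside a
#'   [train_bp_model()] fit).
#' @param windows Tibble from [make_windows()].
#' @param ... Unused.
#' @return Tibble with `window_id`, `sbp_hat`, `dbp_hat` (mmHg), one row per
#'   window; deterministic for a fixed model.
#' @export
predict.bp_model <- function(object, windows, ...) {
  rows <- purrr::map(seq_len(nrow(windows)), function(i) {
    tok <- window_tokens(object, windows[i, ])
    fw <- model_forward(object, tok)
    y <- unscale_pred(fw$pred, object$target_scale)
    tibble::tibble(window_id = windows$window_id[i], sbp_hat = y[1], dbp_hat = y[2])
  })
  dplyr::bind_rows(rows)
}

#' Single-window forward pass
#'
#' Runs the full pipeline (render, tokens, fusion, regression) for one window
#' and also returns the fused representation with its attention weights.
#'
#' @param model A `bp_model`.
#' @param window One row of a windows tibble.
#' @return List with `estimate` (one-row tibble: `window_id`, `sbp_hat`,
#'   `dbp_hat`) and `fused` (a `fused_repr`).
#' @export
forward_bp <- function(model, window) {
  tok <- window_tokens(model, window)
  fw <- model_forward(model, tok)
  y <- unscale_pred(fw$pred, model$target_scale)
  list(
    estimate = tibble::tibble(window_id = window$window_id[[1]],
                              sbp_hat = y[1], dbp_hat = y[2]),
    fused = fw$fused
  )
}

#' Parameter counts of a model
#'
#' @param model A `bp_model`.
#' @return Named integer vector of parameter counts per component.
#' @export
count_params <- function(model) {
  n <- function(x) sum(vapply(x, function(p) length(unlist(p)), numeric(1)))
  c(
    backbone = n(model$backbone$params),
    fusion = length(unlist(model$mhca[setdiff(names(model$mhca), "config")])),
    head = length(model$head$W_bp) + length(model$head$b_bp)
  )
}

# ---- flat parameter handling for the optimizer ----------------------------

# Collect trainable arrays into a flat named list. Backbone parameters are
# included only when the backbone is trainable (tiny kind, freeze = FALSE).
collect_params <- function(model) {
  out <- list(head.W_bp = model$head$W_bp, head.b_bp = model$head$b_bp)
  mh <- model$mhca
  for (nm in c("Aq", "bq", "Ak", "bk", "Av", "bv", "Wo")) {
    out[[paste0("mhca.", nm)]] <- mh[[nm]]
  }
  for (i in seq_len(mh$config$n_heads)) {
    out[[paste0("mhca.Wq.", i)]] <- mh$Wq[[i]]
    out[[paste0("mhca.Wk.", i)]] <- mh$Wk[[i]]
    out[[paste0("mhca.Wv.", i)]] <- mh$Wv[[i]]
  }
  if (!model$backbone$config$freeze) {
    if (model$backbone$config$kind != "tiny") {
      abort_config("only the tiny backbone supports gradient training (freeze = FALSE).")
    }
    for (i in seq_along(model$backbone$params)) {
      out[[paste0("bb.", i, ".w")]] <- model$backbone$params[[i]]$w
      out[[paste0("bb.", i, ".b")]] <- model$backbone$params[[i]]$b
    }
  }
  out
}

set_params <- function(model, flat) {
  model$head$W_bp <- flat$head.W_bp
  model$head$b_bp <- flat$head.b_bp
  for (nm in c("Aq", "bq", "Ak", "bk", "Av", "bv", "Wo")) {
    model$mhca[[nm]] <- flat[[paste0("mhca.", nm)]]
  }
  for (i in seq_len(model$mhca$config$n_heads)) {
    model$mhca$Wq[[i]] <- flat[[paste0("mhca.Wq.", i)]]
    model$mhca$Wk[[i]] <- flat[[paste0("mhca.Wk.", i)]]
    model$mhca$Wv[[i]] <- flat[[paste0("mhca.Wv.", i)]]
  }
  if (!model$backbone$config$freeze) {
    for (i in seq_along(model$backbone$params)) {
      model$backbone$params[[i]]$w <- flat[[paste0("bb.", i, ".w")]]
      model$backbone$params[[i]]$b <- flat[[paste0("bb.", i, ".b")]]
    }
  }
  model
}

# Loss and gradients for one window. `y` is the (scaled) length-2 target.
# Returns loss, flat gradient list matching collect_params(), and prediction.
window_loss_grads <- function(model, tokens, y) {
  fw <- model_forward(model, tokens, keep_cache = TRUE)
  err <- unname(fw$pred - y)
  loss <- mean(err^2)
  dpred <- err # d/dpred of mean over the 2 targets of err^2 = 2*err/2
  g <- list(
    head.W_bp = dpred %o% fw$fused$x_fusion,
    head.b_bp = dpred
  )
  dfusion <- drop(crossprod(model$head$W_bp, dpred))
  mb <- mhca_backward(dfusion, model$mhca, fw$fused$cache)
  for (nm in c("Aq", "bq", "Ak", "bk", "Av", "bv", "Wo")) {
    g[[paste0("mhca.", nm)]] <- mb[[nm]]
  }
  for (i in seq_len(model$mhca$config$n_heads)) {
    g[[paste0("mhca.Wq.", i)]] <- mb$Wq[[i]]
    g[[paste0("mhca.Wk.", i)]] <- mb$Wk[[i]]
    g[[paste0("mhca.Wv.", i)]] <- mb$Wv[[i]]
  }
  if (!model$backbone$config$freeze) {
    if (model$mhca$config$attend_over != "tokens") {
      abort_config("backbone training requires attend_over = \"tokens\".")
    }
    dts <- list(q = mb$dx_q, k = mb$dx_k, v = mb$dx_v)
    acc <- NULL
    for (role in c("q", "k", "v")) {
      if (!is.null(model$feature_norm)) {
        dts[[role]] <- sweep(dts[[role]], 2, model$feature_norm[[role]]$sd, "/")
      }
      gb <- tiny_backward(dts[[role]], tokens[[role]]$caches)
      if (is.null(acc)) acc <- gb else {
        for (i in seq_along(acc)) {
          acc[[i]]$w <- acc[[i]]$w + gb[[i]]$w
          acc[[i]]$b <- acc[[i]]$b + gb[[i]]$b
        }
      }
    }
    for (i in seq_along(acc)) {
      g[[paste0("bb.", i, ".w")]] <- acc[[i]]$w
      g[[paste0("bb.", i, ".b")]] <- acc[[i]]$b
    }
  }
  list(loss = loss, grads = g, pred = fw$pred)
}
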