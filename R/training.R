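#' Training configuration
#'
#' Defaults mirror a long-horizon training setup (adaptive-moment optimizer at
#' learning rate 1e-4, batch size 16, up to 200 epochs, 10% validation split,
#' 5-fold cross-validation, early stopping and step-down learning-rate
#' scheduling). Short CPU-scale runs should raise `learning_rate` and lower
#' `max_epochs`; see the package vignette for the rationale.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Windows per gradient step.
#' @param max_epochs Maximum number of epochs.
#' @param val_split Fraction of the training windows held out for early
#'   stopping, in (0, 1).
#' @param k_folds Folds for [kfold_evaluate()] (>= 2).
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping.
#' @param lr_factor,lr_patience Multiply the learning rate by `lr_factor`
#'   after `lr_patience` epochs without validation improvement.
#' @param loss Loss name; `"mse"` (mean squared error over SBP and DBP
#'   jointly, equal weights) is the only supported loss.
#' @param seed Seed controlling splits, shuffling and initialization order.
#' @param split_by `"window"` or `"subject"`: fold/validation grouping unit.
#'   Window-level splitting of overlapping windows leaks near-duplicate data
#'   between train and test; subject-level splitting avoids this and is
#'   recommended whenever multiple records per subject exist.
#' @param scale_targets Standardize (SBP, DBP) to zero mean / unit variance
#'   for optimization (predictions are always returned in mmHg).
#' @param feature_norm Standardize each backbone token channel (per modality)
#'   using training-split statistics before the fusion adapters. Purely a
#'   conditioning device for the optimizer; the statistics are stored in the
#'   model and applied identically at prediction time.
#' @param trainable Optional character vector restricting updates to matching
#'   parameter names (prefix match, e.g. `"head.b_bp"`); `NULL` trains all.
#' @param verbose Print per-epoch log lines.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 16L, max_epochs = 200L,
                         val_split = 0.1, k_folds = 5L, early_stop_patience = 10L,
                         lr_factor = 0.5, lr_patience = 5L, loss = "mse",
                         seed = 0L, split_by = c("window", "subject"),
                         scale_targets = TRUE, feature_norm = TRUE,
                         trainable = NULL, verbose = FALSE) {
  split_by <- match.arg(split_by)
  if (!is.numeric(learning_rate) || learning_rate < 0) abort_config("`learning_rate` must be >= 0.")
  if (!is_count(batch_size) || !is_count(max_epochs)) {
    abort_config("`batch_size` and `max_epochs` must be positive integers.")
  }
  if (!is.numeric(val_split) || val_split <= 0 || val_split >= 1) {
    abort_config("`val_split` must lie in (0, 1).")
  }
  if (!is_count(k_folds) || k_folds < 2) abort_config("`k_folds` must be >= 2.")
  if (!is_count(early_stop_patience) || !is_count(lr_patience)) {
    abort_config("patience values must be positive integers.")
  }
  if (!identical(loss, "mse")) abort_config("only loss = \"mse\" is supported.")
  structure(
    list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
         max_epochs = as.integer(max_epochs), val_split = val_split,
         k_folds = as.integer(k_folds),
         early_stop_patience = as.integer(early_stop_patience),
         lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
         loss = loss, seed = as.integer(seed), split_by = split_by,
         scale_targets = isTRUE(scale_targets), feature_norm = isTRUE(feature_norm),
         trainable = trainable, verbose = isTRUE(verbose)),
    class = "train_config"
  )
}

adam_init <- function(flat) {
  list(m = lapply(flat, function(p) p * 0), v = lapply(flat, function(p) p * 0), t = 0L)
}

adam_step <- function(flat, grads, state, lr, trainable = NULL,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(flat)) {
    if (!is.null(trainable) && !any(startsWith(nm, trainable))) next
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    flat[[nm]] <- flat[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(flat = flat, state = state)
}

targets_matrix <- function(windows) cbind(sbp = windows$sbp, dbp = windows$dbp)

precompute_tokens <- function(model, windows, keep_cache = FALSE) {
  purrr::map(seq_len(nrow(windows)), function(i) {
    window_tokens(model, windows[i, ], keep_cache = keep_cache)
  })
}

#' Train the blood-pressure model
#'
#' Optimizes all trainable parameters with the adaptive-moment (Adam)
#' optimizer on the mean-squared error over (SBP, DBP). A validation fraction
#' is held out before training for early stopping and learning-rate
#' scheduling; the weights of the best validation epoch are restored. The run
#' is fully seeded and deterministic.
#'
#' When the backbone is frozen, each window's token triplet is computed once
#' and cached for all epochs; with `freeze = FALSE` (tiny backbone only) the
#' convolution stack is part of every gradient step.
#'
#' @param model A [bp_model()].
#' @param windows Tibble from [make_windows()] (needs at least
#'   `2 * batch_size` rows).
#' @param config A [train_config()].
#' @param tokens Optional precomputed token triplets (internal use by
#'   [kfold_evaluate()]); only valid for a frozen backbone.
#' @return An object of class `bp_fit`: the trained `model`, a `history`
#'   tibble (epoch, train_loss, val_loss, lr), `best_epoch` and
#'   `stopped_early`.
#' @export
train_bp_model <- function(model, windows, config = train_config(), tokens = NULL) {
  n <- nrow(windows)
  if (n < 2 * config$batch_size) {
    abort_input(sprintf("need at least %d windows, got %d.", 2 * config$batch_size, n))
  }
  y <- targets_matrix(windows)
  if (any(!is.finite(y))) abort_input("window labels must be finite.")
  frozen <- model$backbone$config$freeze

  # validation split (grouped by subject when requested), before training
  ids <- if (config$split_by == "subject") windows$subject_id else windows$window_id
  val_idx <- with_local_seed(derive_seed(config$seed, 1L), {
    groups <- unique(ids)
    n_val_groups <- max(1L, round(config$val_split * length(groups)))
    val_groups <- sample(groups, n_val_groups)
    which(ids %in% val_groups)
  })
  train_idx <- setdiff(seq_len(n), val_idx)
  if (length(train_idx) < config$batch_size) abort_input("validation split leaves too few training windows.")

  # target standardization from the training portion only
  if (config$scale_targets) {
    mu <- colMeans(y[train_idx, , drop = FALSE])
    sigma <- apply(y[train_idx, , drop = FALSE], 2, sd)
    sigma[!is.finite(sigma) | sigma < 1e-8] <- 1
  } else {
    mu <- c(0, 0); sigma <- c(1, 1)
  }
  model$target_scale <- list(mu = mu, sigma = sigma)
  y_scaled <- sweep(sweep(y, 2, mu, "-"), 2, sigma, "/")

  if (is.null(tokens) && frozen) {
    tokens <- precompute_tokens(model, windows)
  }
  token_of <- function(i, keep_cache = FALSE) {
    if (frozen) tokens[[i]] else window_tokens(model, windows[i, ], keep_cache = keep_cache)
  }
  if (config$feature_norm) {
    # channel statistics frozen at the (initial) backbone state, training split only
    model$feature_norm <- compute_feature_norm(lapply(train_idx, token_of))
  }

  flat <- collect_params(model)
  state <- adam_init(flat)
  lr <- config$learning_rate
  best_val <- Inf; best_flat <- flat; best_epoch <- 0L
  since_improve <- 0L; since_lr <- 0L; stopped_early <- FALSE
  history <- vector("list", config$max_epochs)

  for (epoch in seq_len(config$max_epochs)) {
    order_idx <- with_local_seed(derive_seed(config$seed, 1000L + epoch), sample(train_idx))
    batches <- split(order_idx, ceiling(seq_along(order_idx) / config$batch_size))
    epoch_loss <- 0
    for (batch in batches) {
      acc <- NULL; bloss <- 0
      for (i in batch) {
        wl <- window_loss_grads(model, token_of(i, keep_cache = TRUE), y_scaled[i, ])
        if (!is.finite(wl$loss)) abort_train("non-finite training loss; check inputs and learning rate.")
        bloss <- bloss + wl$loss
        if (is.null(acc)) {
          acc <- wl$grads
        } else {
          for (nm in names(acc)) acc[[nm]] <- acc[[nm]] + wl$grads[[nm]]
        }
      }
      for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / length(batch)
      epoch_loss <- epoch_loss + bloss
      upd <- adam_step(flat, acc, state, lr, config$trainable)
      flat <- upd$flat; state <- upd$state
      model <- set_params(model, flat)
    }
    train_loss <- epoch_loss / length(train_idx)
    val_loss <- mean(vapply(val_idx, function(i) {
      fw <- model_forward(model, token_of(i))
      mean((fw$pred - y_scaled[i, ])^2)
    }, numeric(1)))
    history[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = train_loss,
                                       val_loss = val_loss, lr = lr)
    if (config$verbose) {
      inform(sprintf("epoch %3d  train %.5f  val %.5f  lr %.2e", epoch, train_loss, val_loss, lr))
    }
    if (val_loss < best_val - 1e-12) {
      best_val <- val_loss; best_flat <- flat; best_epoch <- epoch
      since_improve <- 0L; since_lr <- 0L
    } else {
      since_improve <- since_improve + 1L
      since_lr <- since_lr + 1L
      if (since_lr >= config$lr_patience) { lr <- lr * config$lr_factor; since_lr <- 0L }
      if (since_improve >= config$early_stop_patience) { stopped_early <- TRUE; break }
    }
  }
  model <- set_params(model, best_flat)
  structure(
    list(model = model, history = dplyr::bind_rows(history),
         best_epoch = best_epoch, stopped_early = stopped_early, config = config),
    class = "bp_fit"
  )
}

#' K-fold cross-validated training and prediction
#'
#' Partitions windows into `k_folds` folds (grouped by subject when
#' `split_by = "subject"`, so no subject spans folds), trains one model per
#' fold on the remaining windows (with the usual validation split for early
#' stopping inside the training portion) and predicts the held-out fold.
#' Pooled out-of-fold predictions cover every window exactly once.
#'
#' @param windows Tibble from [make_windows()].
#' @param backbone,fusion,render Model component configurations.
#' @param config A [train_config()].
#' @return An object of class `bp_cv`: `predictions` (tibble: `window_id`,
#'   `fold`, `sbp`, `dbp`, `sbp_hat`, `dbp_hat`), `fold_metrics` (per fold and
#'   target), and `fits` (list of `bp_fit`).
#' @export
kfold_evaluate <- function(windows, backbone = backbone_config(),
                           fusion = mhca_config(), render = render_spec(),
                           config = train_config()) {
  n <- nrow(windows)
  if (n < config$k_folds * config$batch_size) {
    abort_input("too few windows for the requested number of folds and batch size.")
  }
  ids <- if (config$split_by == "subject") windows$subject_id else windows$window_id
  groups <- unique(ids)
  if (config$split_by == "subject" && length(groups) < config$k_folds) {
    abort_config("fewer subjects than folds with split_by = \"subject\".")
  }
  fold_of_group <- with_local_seed(derive_seed(config$seed, 2L), {
    g <- sample(rep_len(seq_len(config$k_folds), length(groups)))
    stats::setNames(g, groups)
  })
  fold <- unname(fold_of_group[ids])

  # with a frozen backbone all folds share the same deterministic token grids
  proto <- bp_model(backbone, fusion, render, seed = config$seed)
  shared_tokens <- if (backbone$freeze) precompute_tokens(proto, windows) else NULL

  fits <- vector("list", config$k_folds)
  preds <- vector("list", config$k_folds)
  for (f in seq_len(config$k_folds)) {
    test_idx <- which(fold == f)
    train_wins <- windows[fold != f, , drop = FALSE]
    model <- bp_model(backbone, fusion, render, seed = derive_seed(config$seed, 100L + f))
    fit <- train_bp_model(model, train_wins, config,
                          tokens = if (!is.null(shared_tokens)) shared_tokens[fold != f] else NULL)
    fits[[f]] <- fit
    pred <- if (!is.null(shared_tokens)) {
      # reuse cached tokens for the held-out windows
      dplyr::bind_rows(purrr::map(test_idx, function(i) {
        fw <- model_forward(fit$model, shared_tokens[[i]])
        yhat <- unscale_pred(fw$pred, fit$model$target_scale)
        tibble::tibble(window_id = windows$window_id[i], sbp_hat = yhat[1], dbp_hat = yhat[2])
      }))
    } else {
      predict(fit$model, windows[test_idx, , drop = FALSE])
    }
    pred$fold <- f
    pred$sbp <- windows$sbp[test_idx]
    pred$dbp <- windows$dbp[test_idx]
    preds[[f]] <- pred
  }
  predictions <- dplyr::bind_rows(preds)[, c("window_id", "fold", "sbp", "dbp", "sbp_hat", "dbp_hat")]
  fold_metrics <- dplyr::bind_rows(purrr::map(seq_len(config$k_folds), function(f) {
    p <- predictions[predictions$fold == f, ]
    dplyr::bind_rows(
      dplyr::mutate(regression_metrics(p$sbp_hat, p$sbp), fold = f, target = "sbp"),
      dplyr::mutate(regression_metrics(p$dbp_hat, p$dbp), fold = f, target = "dbp")
    )
  }))
  structure(list(predictions = predictions, fold_metrics = fold_metrics, fits = fits),
            class = "bp_cv")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history of a fit
#'
#' @param x A `bp_fit`.
#' @param ... Unused.
#' @return The history tibble (epoch, train_loss, val_loss, lr).
#' @export
tidy.bp_fit <- function(x, ...) x$history

#' One-row summary of a fit
#'
#' @param x A `bp_fit`.
#' @param ... Unused.
#' @return Tibble with `n_epochs`, `best_epoch`, `best_val_loss`,
#'   `stopped_early`, `final_lr`.
#' @export
glance.bp_fit <- function(x, ...) {
  tibble::tibble(
    n_epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    best_val_loss = min(x$history$val_loss),
    stopped_early = x$stopped_early,
    final_lr = x$history$lr[nrow(x$history)]
  )
}

#' Pooled out-of-fold predictions of a cross-validated run
#'
#' @param x A `bp_cv`.
#' @param ... Unused.
#' @return The pooled predictions tibble.
#' @export
tidy.bp_cv <- function(x, ...) x$predictions

#' Per-fold metric summary of a cross-validated run
#'
#' @param x A `bp_cv`.
#' @param ... Unused.
#' @return The fold-by-target metrics tibble.
#' @export
glance.bp_cv <- function(x, ...) x$fold_metrics

#' Plot the training history
#'
#' @param object A `bp_fit`.
#' @param ... Unused.
#' @return A ggplot of train/validation loss per epoch.
#' @export
autoplot.bp_fit <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                            names_to = "series", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss, colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "epoch", y = "loss (scaled target space)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot
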