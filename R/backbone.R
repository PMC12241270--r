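#' Backbone configuration
#'
#' The backbone maps a rendered modality image to a grid of spatial feature
#' tokens. Two kinds are provided:
#'
#' * `"tiny"`: three stride-2 3x3 convolution blocks (3 -> 8 -> 16 -> 32
#'   channels) with ReLU, giving a 28x28 token grid with 32 channels for a
#'   224x224 input (12x12 for 96x96). Fully trainable and fast enough for
#'   CPU-scale experiments; this is the default.
#' * `"resnet50"`: the standard bottleneck residual architecture (stages of
#'   3/4/6/3 blocks, 2048 output channels, 7x7 grid for 224x224 input) with
#'   the classifier head removed, forward-only. Batch normalization is
#'   represented as a per-channel affine transform (identity at
#'   initialization; trained scale/shift can be supplied via `weights_file`).
#'   `pretrained = TRUE` requires such a weights file: no pretrained weights
#'   ship with the package.
#'
#' @param kind `"tiny"` or `"resnet50"`.
#' @param pretrained Use pretrained weights (resnet50 only, needs
#'   `weights_file`).
#' @param freeze If `TRUE` the backbone is excluded from gradient updates and
#'   its token grids may be cached during training.
#' @param weights_file Optional path to a plain-text weights file written by
#'   [save_backbone_weights()].
#' @param seed Seed for random initialization.
#' @return An object of class `backbone_config`.
#' @export
backbone_config <- function(kind = c("tiny", "resnet50"), pretrained = FALSE,
                            freeze = TRUE, weights_file = NULL, seed = 0L) {
  kind <- match.arg(kind)
  if (pretrained && kind != "resnet50") {
    abort_config("`pretrained` is only meaningful for kind = \"resnet50\".")
  }
  if (pretrained && is.null(weights_file)) {
    abort_config(paste0(
      "pretrained resnet50 weights are not bundled with this package; ",
      "supply `weights_file` (see save_backbone_weights()) or use pretrained = FALSE."))
  }
  structure(
    list(kind = kind, pretrained = pretrained, freeze = isTRUE(freeze),
         weights_file = weights_file, seed = as.integer(seed),
         token_channels = if (kind == "resnet50") 2048L else 32L),
    class = "backbone_config"
  )
}

# ---- im2col convolution machinery -----------------------------------------
# Layout conventions (all column-major, R native):
#   * images are H x W x C arrays;
#   * the patch matrix `cols` is P x (k^2 * Cin) with P = Hout*Wout output
#     positions ordered column-major over (row, col), and columns grouped by
#     input channel, kernel offsets column-major within each channel;
#   * weights are (k^2 * Cin) x Cout matrices matching that layout.

.im2col_cache <- new.env(parent = emptyenv())

im2col_meta <- function(h, w, k, stride, pad) {
  key <- paste(h, w, k, stride, pad, sep = "_")
  got <- .im2col_cache[[key]]
  if (!is.null(got)) return(got)
  hp <- h + 2L * pad; wp <- w + 2L * pad
  hout <- (hp - k) %/% stride + 1L
  wout <- (wp - k) %/% stride + 1L
  i <- rep(seq_len(hout), times = wout)
  j <- rep(seq_len(wout), each = hout)
  base_r <- (i - 1L) * stride # top-left (0-based) of each patch
  base_c <- (j - 1L) * stride
  idx <- matrix(0L, nrow = hout * wout, ncol = k * k)
  q <- 0L
  for (dc in seq_len(k)) {
    for (dr in seq_len(k)) {
      q <- q + 1L
      idx[, q] <- (base_c + dc - 1L) * hp + (base_r + dr)
    }
  }
  meta <- list(hp = hp, wp = wp, hout = hout, wout = wout, idx = idx, k = k, pad = pad)
  .im2col_cache[[key]] <- meta
  meta
}

pad_image <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  out
}

im2col <- function(x, meta) {
  cin <- dim(x)[3]
  k2 <- ncol(meta$idx)
  cols <- matrix(0, nrow = nrow(meta$idx), ncol = k2 * cin)
  xp <- pad_image(x, meta$pad)
  for (c in seq_len(cin)) {
    plane <- xp[, , c]
    cols[, (c - 1L) * k2 + seq_len(k2)] <- matrix(plane[meta$idx], nrow(meta$idx), k2)
  }
  cols
}

conv_forward <- function(x, wmat, bias, k, stride, pad, keep_cache = FALSE) {
  d <- dim(x)
  meta <- im2col_meta(d[1], d[2], k, stride, pad)
  cols <- im2col(x, meta)
  out <- cols %*% wmat
  out <- sweep(out, 2, bias, "+")
  res <- list(out = array(out, dim = c(meta$hout, meta$wout, ncol(wmat))))
  if (keep_cache) res$cache <- list(cols = cols, meta = meta, wmat = wmat, in_dim = d)
  res
}

conv_backward <- function(dout, cache) {
  # dout: P x Cout (or array reshaped to it)
  meta <- cache$meta
  p <- nrow(meta$idx)
  dout <- matrix(dout, nrow = p)
  dw <- crossprod(cache$cols, dout)
  db <- colSums(dout)
  dcols <- tcrossprod(dout, cache$wmat) # P x (k2*Cin)
  d <- cache$in_dim
  k2 <- ncol(meta$idx)
  cin <- d[3]
  dxp <- array(0, dim = c(meta$hp, meta$wp, cin))
  for (c in seq_len(cin)) {
    plane <- numeric(meta$hp * meta$wp)
    for (q in seq_len(k2)) {
      ii <- meta$idx[, q]
      plane[ii] <- plane[ii] + dcols[, (c - 1L) * k2 + q]
    }
    dxp[, , c] <- plane
  }
  pad <- meta$pad
  dx <- dxp[pad + seq_len(d[1]), pad + seq_len(d[2]), , drop = FALSE]
  list(dw = dw, db = db, dx = dx)
}

maxpool_forward <- function(x, k = 3L, stride = 2L, pad = 1L) {
  d <- dim(x)
  meta <- im2col_meta(d[1], d[2], k, stride, pad)
  xp <- pad_image(x, pad)
  # padded with 0; fine for post-ReLU activations (non-negative)
  out <- array(0, dim = c(meta$hout, meta$wout, d[3]))
  for (c in seq_len(d[3])) {
    plane <- xp[, , c]
    m <- matrix(plane[meta$idx], nrow(meta$idx))
    out[, , c] <- matrixStats_rowMax(m)
  }
  out
}

matrixStats_rowMax <- function(m) do.call(pmax, as.data.frame(m))

he_uniform <- function(nrow, ncol, fan_in) {
  lim <- sqrt(6 / fan_in)
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

# ---- tiny backbone ---------------------------------------------------------

tiny_plan <- list(
  list(k = 3L, stride = 2L, pad = 1L, cin = 3L, cout = 8L),
  list(k = 3L, stride = 2L, pad = 1L, cin = 8L, cout = 16L),
  list(k = 3L, stride = 2L, pad = 1L, cin = 16L, cout = 32L)
)

init_tiny <- function(seed) {
  with_local_seed(seed, lapply(tiny_plan, function(l) {
    list(w = he_uniform(l$k^2 * l$cin, l$cout, l$k^2 * l$cin), b = numeric(l$cout),
         k = l$k, stride = l$stride, pad = l$pad)
  }))
}

tiny_forward <- function(x, layers, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(layers)) else NULL
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    cf <- conv_forward(x, l$w, l$b, l$k, l$stride, l$pad, keep_cache = keep_cache)
    pre <- cf$out
    x <- pre * (pre > 0) # ReLU
    if (keep_cache) caches[[i]] <- list(conv = cf$cache, mask = pre > 0)
  }
  d <- dim(x)
  list(tokens = matrix(x, nrow = d[1] * d[2], ncol = d[3]),
       grid_shape = c(d[1], d[2]), caches = caches)
}

tiny_backward <- function(dtokens, caches) {
  grads <- vector("list", length(caches))
  dout <- dtokens # P x C of the last layer
  for (i in rev(seq_along(caches))) {
    mask <- caches[[i]]$mask
    dout <- matrix(dout, nrow = length(mask) / dim(mask)[3])
    dout <- dout * matrix(mask, nrow = nrow(dout))
    cb <- conv_backward(dout, caches[[i]]$conv)
    grads[[i]] <- list(w = cb$dw, b = cb$db)
    dout <- cb$dx
  }
  grads
}

# ---- resnet-50 (forward only) ---------------------------------------------

resnet50_spec <- function() {
  stage <- function(blocks, cin, mid, cout, first_stride) {
    lapply(seq_len(blocks), function(b) {
      list(cin = if (b == 1) cin else cout, mid = mid, cout = cout,
           stride = if (b == 1) first_stride else 1L,
           project = b == 1)
    })
  }
  list(
    stem = list(k = 7L, stride = 2L, pad = 3L, cin = 3L, cout = 64L),
    stages = c(
      stage(3, 64L, 64L, 256L, 1L),
      stage(4, 256L, 128L, 512L, 2L),
      stage(6, 512L, 256L, 1024L, 2L),
      stage(3, 1024L, 512L, 2048L, 2L)
    )
  )
}

init_conv_bn <- function(k, cin, cout) {
  list(w = he_uniform(k^2 * cin, cout, k^2 * cin), b = numeric(cout),
       gamma = rep(1, cout), beta = numeric(cout), k = k)
}

init_resnet50 <- function(seed) {
  spec <- resnet50_spec()
  with_local_seed(seed, {
    params <- list(stem = init_conv_bn(spec$stem$k, spec$stem$cin, spec$stem$cout))
    params$blocks <- lapply(spec$stages, function(bl) {
      p <- list(
        conv1 = init_conv_bn(1L, bl$cin, bl$mid),
        conv2 = init_conv_bn(3L, bl$mid, bl$mid),
        conv3 = init_conv_bn(1L, bl$mid, bl$cout),
        stride = bl$stride
      )
      if (bl$project) p$proj <- init_conv_bn(1L, bl$cin, bl$cout)
      p
    })
    params
  })
}

bn_affine <- function(x, gamma, beta) {
  d <- dim(x)
  sweep(sweep(x, 3, gamma, "*"), 3, beta, "+")
}

conv_bn_relu <- function(x, p, stride, pad, relu = TRUE) {
  out <- conv_forward(x, p$w, p$b, p$k, stride, pad)$out
  out <- bn_affine(out, p$gamma, p$beta)
  if (relu) out <- out * (out > 0)
  out
}

resnet50_forward <- function(x, params) {
  x <- conv_bn_relu(x, params$stem, stride = 2L, pad = 3L)
  x <- maxpool_forward(x, k = 3L, stride = 2L, pad = 1L)
  for (bp in params$blocks) {
    identity_in <- x
    y <- conv_bn_relu(x, bp$conv1, stride = 1L, pad = 0L)
    y <- conv_bn_relu(y, bp$conv2, stride = bp$stride, pad = 1L)
    y <- conv_bn_relu(y, bp$conv3, stride = 1L, pad = 0L, relu = FALSE)
    if (!is.null(bp$proj)) {
      identity_in <- conv_bn_relu(x, bp$proj, stride = bp$stride, pad = 0L, relu = FALSE)
    }
    x <- y + identity_in
    x <- x * (x > 0)
  }
  d <- dim(x)
  list(tokens = matrix(x, nrow = d[1] * d[2], ncol = d[3]), grid_shape = c(d[1], d[2]))
}

# ---- public surface --------------------------------------------------------

#' Initialize a backbone
#'
#' @param config A [backbone_config()].
#' @return An object of class `ppg_backbone` holding the configuration and
#'   parameters.
#' @export
init_backbone <- function(config = backbone_config()) {
  if (!inherits(config, "backbone_config")) abort_config("`config` must be a `backbone_config`.")
  params <- if (config$kind == "tiny") init_tiny(config$seed) else init_resnet50(config$seed)
  bb <- structure(list(config = config, params = params), class = "ppg_backbone")
  if (!is.null(config$weights_file)) bb <- load_backbone_weights(bb, config$weights_file)
  bb
}

# Normalization applied before the convolution stack: images come in on the
# [0, 255] intensity scale and are rescaled to [0, 1]; when pretrained
# weights are in use, the pretraining channel statistics are applied.
normalize_image <- function(img, config) {
  x <- unclass(img) / 255
  if (isTRUE(config$pretrained)) {
    mean <- c(0.485, 0.456, 0.406); sd <- c(0.229, 0.224, 0.225)
    x <- sweep(sweep(x, 3, mean, "-"), 3, sd, "/")
  }
  x
}

#' Extract spatial feature tokens from modality images
#'
#' @param images One image (`height x width x channels` array) or a list of
#'   them, pixel values in `[0, 255]`.
#' @param backbone A `ppg_backbone` from [init_backbone()].
#' @param modality Optional modality tag attached to each token grid.
#' @return For a single image, an `S x C` token matrix with attributes
#'   `grid_shape` (rows, cols with `rows * cols == S`) and `modality`; for a
#'   list, a list of such matrices (order preserved).
#' @export
extract_tokens <- function(images, backbone, modality = NULL) {
  if (!inherits(backbone, "ppg_backbone")) abort_config("`backbone` must come from init_backbone().")
  single <- !is.list(images)
  if (single) images <- list(images)
  out <- purrr::map(images, function(img) {
    if (length(dim(img)) != 3 || dim(img)[3] != 3) {
      abort_input("each image must be a height x width x 3 array.")
    }
    x <- normalize_image(img, backbone$config)
    fw <- if (backbone$config$kind == "tiny") {
      tiny_forward(x, backbone$params)
    } else {
      resnet50_forward(x, backbone$params)
    }
    tokens <- fw$tokens
    attr(tokens, "grid_shape") <- fw$grid_shape
    attr(tokens, "modality") <- modality
    tokens
  })
  if (single) out[[1]] else out
}

#' Global average pooling of a token grid
#'
#' @param tokens An `S x C` token matrix.
#' @return The length-`C` channel-wise mean vector.
#' @export
pool_embedding <- function(tokens) {
  if (!is.matrix(tokens) || nrow(tokens) < 1) abort_input("`tokens` must be a non-empty matrix.")
  colMeans(tokens)
}

#' Save / load backbone weights as plain text
#'
#' Weights are flattened to a single numeric vector and stored alongside the
#' backbone kind and seed, full precision, one value per line.
#'
#' @param backbone A `ppg_backbone`.
#' @param path File path.
#' @return `path` / the updated backbone.
#' @export
save_backbone_weights <- function(backbone, path) {
  flat <- unlist(backbone$params, use.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("#kind", backbone$config$kind), format(flat, digits = 17, trim = TRUE)), con)
  invisible(path)
}

#' @rdname save_backbone_weights
#' @export
load_backbone_weights <- function(backbone, path) {
  lines <- readLines(path)
  kind <- strsplit(lines[1], " ")[[1]][2]
  if (!identical(kind, backbone$config$kind)) {
    abort_config(sprintf("weights file is for kind '%s', backbone is '%s'.", kind, backbone$config$kind))
  }
  flat <- as.numeric(lines[-1])
  rel <- utils::relist(flat, skeleton = backbone$params)
  # relist drops matrix dims; restore them from the existing skeleton
  backbone$params <- restore_dims(rel, backbone$params)
  backbone
}

restore_dims <- function(new, old) {
  if (is.list(old)) {
    for (nm in seq_along(old)) new[[nm]] <- restore_dims(new[[nm]], old[[nm]])
    new
  } else {
    if (!is.null(dim(old))) dim(new) <- dim(old)
    new
  }
}
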