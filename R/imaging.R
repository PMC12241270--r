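#' Rendering specification for signal-to-image conversion
#'
#' Each window is drawn as a black polyline on a white background with
#' per-window min--max amplitude normalization, no axes and no text, so the
#' image is a pure deterministic function of the samples. Per-window
#' normalization makes the rendering invariant to sensor gain and offset;
#' constant signals map to a horizontal line at the vertical center.
#'
#' @param height,width Image size in pixels (>= 32).
#' @param line_value,background_value Intensities in `[0, 255]` for the trace
#'   and the background.
#' @param margin Vertical margin in pixels kept free above and below the trace.
#' @param line_thickness Trace thickness in pixels.
#' @param channels Number of output channels (the grayscale trace is
#'   replicated; 3 matches standard vision backbones).
#' @return An object of class `render_spec`.
#' @export
render_spec <- function(height = 224L, width = 224L, line_value = 0L,
                        background_value = 255L, margin = 8L,
                        line_thickness = 2L, channels = 3L) {
  if (height < 32 || width < 32) abort_config("image size must be at least 32x32.")
  if (margin >= height / 4) abort_config("`margin` must be below height/4.")
  if (line_thickness < 1) abort_config("`line_thickness` must be >= 1.")
  structure(
    list(height = as.integer(height), width = as.integer(width),
         line_value = line_value, background_value = background_value,
         margin = as.integer(margin), line_thickness = as.integer(line_thickness),
         channels = as.integer(channels)),
    class = "render_spec"
  )
}

# Integer line rasterization between two pixel centers: step along the longer
# axis, rounding the other coordinate (Bresenham-like, deterministic).
line_pixels <- function(r0, c0, r1, c1) {
  n <- max(abs(r1 - r0), abs(c1 - c0)) + 1L
  if (n == 1L) return(cbind(r0, c0))
  tt <- seq(0, 1, length.out = n)
  cbind(as.integer(round(r0 + tt * (r1 - r0))), as.integer(round(c0 + tt * (c1 - c0))))
}

#' Rasterize one signal trace into an image
#'
#' @param samples Finite numeric signal (length >= 2).
#' @param spec A [render_spec()].
#' @return A `height x width x channels` numeric array with values in
#'   `[0, 255]` (class `ppg_image`).
#' @examples
#' img <- render_window(sin(seq(0, 6 * pi, length.out = 500)), render_spec(64, 64))
#' dim(img)
#' @export
render_window <- function(samples, spec = render_spec()) {
  if (length(samples) < 2) abort_input("need at least 2 samples to render.")
  if (any(!is.finite(samples))) abort_input("`samples` must be finite.")
  h <- spec$height; w <- spec$width; m <- spec$margin
  rng <- range(samples)
  if (rng[2] > rng[1]) {
    z <- (samples - rng[1]) / (rng[2] - rng[1]) # in [0, 1]
  } else {
    z <- rep(0.5, length(samples)) # constant trace -> vertical center
  }
  # row 1 is the image top; larger amplitude is drawn higher; the tiny epsilon
  # keeps ties stable under floating-point jitter from affine rescaling
  rows <- as.integer(floor((1 - z) * (h - 1 - 2 * m) + 0.5 + 1e-9)) + m + 1L
  cols <- as.integer(floor((seq_along(samples) - 1) / (length(samples) - 1) * (w - 1) + 0.5)) + 1L
  img <- matrix(spec$background_value, nrow = h, ncol = w)
  th <- spec$line_thickness
  off <- seq_len(th) - 1L - (th - 1L) %/% 2L # thickness offsets around the line
  for (i in seq_len(length(samples) - 1L)) {
    px <- line_pixels(rows[i], cols[i], rows[i + 1L], cols[i + 1L])
    for (d in off) {
      rr <- pmin(pmax(px[, 1] + d, 1L), h)
      img[cbind(rr, px[, 2])] <- spec$line_value
    }
  }
  out <- array(img, dim = c(h, w, spec$channels))
  class(out) <- c("ppg_image", class(out))
  out
}

#' Render the three modality images for one window
#'
#' @param window One row of the tibble produced by [make_windows()] (or any
#'   list with elements `ppg`, `vppg`, `appg`, `window_id`, `sbp`, `dbp`).
#' @param spec A [render_spec()].
#' @return A list of class `modality_triplet` with elements `ppg_img`,
#'   `vppg_img`, `appg_img`, `window_id`, `sbp`, `dbp`.
#' @export
render_triplet <- function(window, spec = render_spec()) {
  grab <- function(x) if (is.list(x)) x[[1]] else x
  out <- list(
    ppg_img = render_window(grab(window$ppg), spec),
    vppg_img = render_window(grab(window$vppg), spec),
    appg_img = render_window(grab(window$appg), spec),
    window_id = grab(window$window_id),
    sbp = grab(window$sbp), dbp = grab(window$dbp)
  )
  class(out) <- "modality_triplet"
  out
}

#' Write / read a rendered image as 8-bit PNG
#'
#' @param img Array from [render_window()] (values in `[0, 255]`).
#' @param path Output path.
#' @return `path` (write) or a `height x width x channels` array in
#'   `[0, 255]` (read), invisibly for the writer.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(unclass(img) / 255, path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2) x <- array(x, dim = c(dim(x), 1))
  x * 255
}

#' Write all three modality images of a triplet
#'
#' Files are named `<window_id>_<modality>.png` under `dir`.
#'
#' @param triplet A `modality_triplet` from [render_triplet()].
#' @param dir Output directory.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_triplet_png <- function(triplet, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    ppg = file.path(dir, paste0(triplet$window_id, "_ppg.png")),
    vppg = file.path(dir, paste0(triplet$window_id, "_vppg.png")),
    appg = file.path(dir, paste0(triplet$window_id, "_appg.png"))
  )
  write_image_png(triplet$ppg_img, paths["ppg"])
  write_image_png(triplet$vppg_img, paths["vppg"])
  write_image_png(triplet$appg_img, paths["appg"])
  invisible(paths)
}
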