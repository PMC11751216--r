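#' Configuration for gaze preprocessing
#'
#' @param window_s,overlap segmentation window length (s) and overlap.
#' @param canvas gaze-plot raster size in pixels, `c(width, height)`.
#' @param idt_dispersion I-DT dispersion threshold in pixels
#'   (`(max - min of x) + (max - min of y)` within a candidate fixation).
#' @param idt_min_duration minimum fixation duration in ms.
#' @param max_gap_interp longest invalid run (ms) that linear interpolation
#'   will bridge; longer gaps remain invalid. `Inf` bridges everything.
#' @param accumulate if `TRUE`, gaze plots accumulate visit counts (min-max
#'   scaled to 0-255) instead of the default binary 255-at-visited-pixel
#'   rendering.
#' @return A list of class `gaze_config`.
#' @export
gaze_config <- function(window_s = 1, overlap = 0.5, canvas = c(64, 64),
                        idt_dispersion = 50, idt_min_duration = 100,
                        max_gap_interp = 300, accumulate = FALSE) {
  if (any(canvas <= 0)) stop("canvas dimensions must be positive")
  if (idt_min_duration <= 0) stop("idt_min_duration must be positive")
  structure(list(window_s = window_s, overlap = overlap, canvas = canvas,
                 idt_dispersion = idt_dispersion,
                 idt_min_duration = idt_min_duration,
                 max_gap_interp = max_gap_interp, accumulate = accumulate),
            class = "gaze_config")
}

#' Linearly interpolate blink gaps in a gaze recording
#'
#' Invalid runs no longer than `max_gap_interp` ms are replaced by the
#' straight line between the bracketing valid samples (x and y
#' independently) and marked valid; longer runs are left untouched. Leading
#' and trailing invalid runs are filled by holding the nearest valid sample.
#'
#' @param rec an `et_recording`.
#' @param cfg a [gaze_config()].
#' @return The interpolated `et_recording`.
#' @export
interpolate_gaps <- function(rec, cfg = gaze_config()) {
  v <- rec$valid
  if (!any(v)) stop("recording has no valid samples to interpolate from")
  if (sum(v) < 2) stop("need at least two valid samples")
  n <- length(v)
  max_run <- cfg$max_gap_interp / 1000 * rec$fs
  r <- rle(!v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  x <- rec$gaze_x; y <- rec$gaze_y
  for (i in seq_along(r$lengths)) {
    if (!r$values[i]) next
    a <- starts[i]; b <- ends[i]
    if (a == 1L) {            # leading run: hold next valid sample
      x[a:b] <- x[b + 1L]; y[a:b] <- y[b + 1L]; v[a:b] <- TRUE
    } else if (b == n) {      # trailing run: hold last valid sample
      x[a:b] <- x[a - 1L]; y[a:b] <- y[a - 1L]; v[a:b] <- TRUE
    } else if (r$lengths[i] <= max_run) {
      w <- seq_len(r$lengths[i]) / (r$lengths[i] + 1)
      x[a:b] <- x[a - 1L] + w * (x[b + 1L] - x[a - 1L])
      y[a:b] <- y[a - 1L] + w * (y[b + 1L] - y[a - 1L])
      v[a:b] <- TRUE
    }
  }
  rec$gaze_x <- x; rec$gaze_y <- y; rec$valid <- v
  rec
}

#' Segment an ET recording into overlapping windows
#'
#' Same hop rule as the EEG [segment()] (1-s windows, 50% overlap by
#' default), yielding `window_s * fs` x 2 gaze matrices.
#'
#' @param rec an `et_recording` with trials.
#' @param cfg a [gaze_config()].
#' @return An `nc_windows` object whose windows are samples x 2 matrices.
#' @export
segment_et <- function(rec, cfg = gaze_config()) {
  segment(rec, cfg)
}

#' Rasterize a gaze window onto the canvas
#'
#' Screen coordinates map to canvas pixels by `floor(x / W * cw)` (clipped to
#' the canvas); visited pixels are set to 255 on a black (0) background.
#' Repeated visits are idempotent in the default binary mode.
#'
#' @param window samples x 2 gaze matrix (columns x, y; rows with missing
#'   coordinates are skipped).
#' @param screen_size screen `c(width, height)` in pixels.
#' @param cfg a [gaze_config()].
#' @return A canvas-height x canvas-width numeric matrix with values in
#'   0..255 (rows = y).
#' @export
render_gaze_plot <- function(window, screen_size, cfg = gaze_config()) {
  if (any(screen_size <= 0)) stop("screen_size must be positive")
  cw <- cfg$canvas[1]; chh <- cfg$canvas[2]
  img <- matrix(0, nrow = chh, ncol = cw)
  ok <- stats::complete.cases(window)
  if (!any(ok)) return(img)
  px <- pmin(pmax(floor(window[ok, 1] / screen_size[1] * cw), 0), cw - 1)
  py <- pmin(pmax(floor(window[ok, 2] / screen_size[2] * chh), 0), chh - 1)
  if (cfg$accumulate) {
    for (i in seq_along(px)) img[py[i] + 1, px[i] + 1] <- img[py[i] + 1, px[i] + 1] + 1
    mx <- max(img)
    if (mx > 0) img <- img / mx * 255
  } else {
    img[cbind(py + 1, px + 1)] <- 255
  }
  img
}

#' Detect fixations with the I-DT dispersion algorithm
#'
#' Grows a sample window while the dispersion
#' `(max - min of x) + (max - min of y)` stays within `idt_dispersion` px and
#' emits a fixation when the window lasts at least `idt_min_duration` ms.
#' Fixations are non-overlapping and time-ordered. Expects interpolated gaze;
#' samples still invalid (long gaps) break candidate windows.
#'
#' @param rec an `et_recording`, or a samples x 2 gaze matrix (then `fs` must
#'   be given).
#' @param cfg a [gaze_config()].
#' @param fs sampling rate when `rec` is a plain matrix.
#' @return Data frame with one row per fixation: `start_ms`, `end_ms`,
#'   `duration_ms`, `x`, `y` (centroid), `n_samples`.
#' @export
detect_fixations <- function(rec, cfg = gaze_config(), fs = NULL) {
  if (inherits(rec, "et_recording")) {
    x <- rec$gaze_x; y <- rec$gaze_y; ok <- rec$valid
    fs <- rec$fs
  } else {
    x <- rec[, 1]; y <- rec[, 2]; ok <- stats::complete.cases(rec)
    if (is.null(fs)) stop("fs is required when passing a plain gaze matrix")
  }
  n <- length(x)
  minlen <- max(2L, ceiling(cfg$idt_min_duration / 1000 * fs))
  fix <- list()
  i <- 1L
  while (i + minlen - 1L <= n) {
    j <- i + minlen - 1L
    if (!all(ok[i:j]) || dispersion(x[i:j], y[i:j]) > cfg$idt_dispersion) {
      i <- i + 1L
      next
    }
    while (j + 1L <= n && ok[j + 1L] &&
           dispersion(x[i:(j + 1L)], y[i:(j + 1L)]) <= cfg$idt_dispersion)
      j <- j + 1L
    fix[[length(fix) + 1L]] <- data.frame(
      start_ms = (i - 1L) / fs * 1000,
      end_ms = j / fs * 1000,
      duration_ms = (j - i + 1L) / fs * 1000,
      x = mean(x[i:j]), y = mean(y[i:j]), n_samples = j - i + 1L)
    i <- j + 1L
  }
  if (!length(fix))
    return(data.frame(start_ms = numeric(), end_ms = numeric(),
                      duration_ms = numeric(), x = numeric(), y = numeric(),
                      n_samples = integer()))
  do.call(rbind, fix)
}

dispersion <- function(x, y) (max(x) - min(x)) + (max(y) - min(y))

#' Full ET preprocessing chain
#'
#' Gap interpolation, segmentation, per-window gaze-plot rasterization and
#' per-window fixation detection.
#'
#' @param rec an `et_recording` with trials.
#' @param cfg a [gaze_config()].
#' @return An `nc_windows` object with extra elements `gaze_plots` (list of
#'   canvas matrices) and `fixations` (list of per-window fixation frames).
#' @export
preprocess_et <- function(rec, cfg = gaze_config()) {
  rec <- interpolate_gaps(rec, cfg)
  ws <- segment_et(rec, cfg)
  ws$gaze_plots <- lapply(ws$windows, render_gaze_plot,
                          screen_size = rec$screen_size, cfg = cfg)
  ws$fixations <- lapply(ws$windows, detect_fixations, cfg = cfg, fs = rec$fs)
  ws
}

#' Write a gaze plot as a grayscale PNG
#'
#' @param img a [render_gaze_plot()] matrix (0-255).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gaze_png <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the png package is required to export gaze plots")
  png::writePNG(img / 255, path)
  invisible(path)
}
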