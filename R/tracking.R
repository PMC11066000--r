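#' Track a dark marker through a grayscale frame stack
#'
#' Minimal marker tracker for the open-field ear-marker protocol: in each
#' frame the marker is located as the centroid of dark pixels (intensity
#' below `threshold`) within `radius` pixels of the position in the
#' previous frame, starting from `init_position` in frame 1. This mirrors
#' what point-tracking video software computes for a high-contrast
#' marker; it is deliberately simple and is exercised on synthetic frame
#' stacks (see [make_track_fixture()]), not on real video.
#'
#' @param frames 3-d numeric array `[rows, cols, n_frames]` of intensities
#'   in `[0, 1]` (0 = black).
#' @param init_position Numeric `c(x, y)` near the marker in frame 1
#'   (x = column, y = row, 1-based).
#' @param threshold Intensity below which a pixel counts as marker
#'   (default 0.5).
#' @param radius Search radius in pixels around the previous position
#'   (default 20).
#' @param fps Frame rate attached to the output track (default 30).
#' @return Tibble with columns `frame` (0-based), `x`, `y`; attribute
#'   `fps`.
#' @export
track_marker <- function(frames, init_position, threshold = 0.5,
                         radius = 20, fps = 30) {
  if (!is.array(frames) || length(dim(frames)) != 3 || dim(frames)[3] < 1)
    stop_robscore("frames must be a non-empty [rows, cols, n] array")
  if (length(init_position) != 2 || any(!is.finite(init_position)))
    stop_robscore("init_position must be finite c(x, y)")
  n <- dim(frames)[3]
  nr <- dim(frames)[1]
  nc <- dim(frames)[2]
  pos <- matrix(NA_real_, nrow = n, ncol = 2)
  prev <- c(init_position[1], init_position[2])
  # Pixel center coordinates: x along columns, y along rows.
  col_x <- seq_len(nc)
  row_y <- seq_len(nr)
  for (k in seq_len(n)) {
    img <- frames[, , k]
    dark <- which(img < threshold, arr.ind = TRUE)
    if (nrow(dark) > 0) {
      dx <- col_x[dark[, 2]] - prev[1]
      dy <- row_y[dark[, 1]] - prev[2]
      keep <- (dx * dx + dy * dy) <= radius * radius
      dark <- dark[keep, , drop = FALSE]
    }
    if (nrow(dark) == 0)
      stop_robscore(sprintf(
        "marker lost at frame %d: no pixel below %.2f within %g px", k - 1,
        threshold, radius))
    prev <- c(mean(col_x[dark[, 2]]), mean(row_y[dark[, 1]]))
    pos[k, ] <- prev
  }
  out <- tibble(frame = 0:(n - 1), x = pos[, 1], y = pos[, 2])
  attr(out, "fps") <- fps
  out
}

#' Render a synthetic frame stack from a track
#'
#' Draws a dark disk at each tracked position on a white background,
#' producing the kind of stack [track_marker()] consumes. Used to test
#' the tracker against known ground truth.
#'
#' @param track Data frame with columns `frame`, `x`, `y` (pixel
#'   coordinates, 1-based).
#' @param width,height Frame size in pixels.
#' @param blob_radius Marker disk radius in pixels (default 3).
#' @return 3-d array `[height, width, n_frames]`, intensities in `[0, 1]`.
#' @export
render_track_frames <- function(track, width = 64, height = 64,
                                blob_radius = 3) {
  track <- as_track(track)
  if (any(track$x < 1 + blob_radius | track$x > width - blob_radius |
          track$y < 1 + blob_radius | track$y > height - blob_radius))
    stop_robscore("track leaves the frame (allowing for the blob radius)")
  frames <- array(1, dim = c(height, width, nrow(track)))
  for (k in seq_len(nrow(track))) {
    cx <- track$x[k]
    cy <- track$y[k]
    rows <- max(1, floor(cy - blob_radius)):min(height, ceiling(cy + blob_radius))
    cols <- max(1, floor(cx - blob_radius)):min(width, ceiling(cx + blob_radius))
    for (r in rows) for (cc in cols) {
      if ((cc - cx)^2 + (r - cy)^2 <= blob_radius^2) frames[r, cc, k] <- 0
    }
  }
  frames
}
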