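#' Extract detections from a response map
#'
#' Strict 8-neighbor local maxima above `t3` times the map's global
#' maximum, non-maximum-suppressed so no two detections lie closer than
#' `min_separation`, ranked by descending score.  If `x` is the result
#' of [invariant_response()], each detection is annotated with the
#' winning transform (`psi`, `upsilon`, `reflected`).
#'
#' @param x Response matrix, or the list returned by
#'   [invariant_response()].
#' @param t3 Score threshold fraction in `[0, 1]`.
#' @param top_k Keep only the `top_k` best detections (optional).
#' @param min_separation Minimum distance between detections, pixels.
#' @param height Image height used to also report raster `row`/`col`
#'   coordinates; defaults to the map height.
#' @return Data frame with columns `x`, `y` (math frame, y up), `row`,
#'   `col` (raster frame, row 1 at top), `score`, `rank` and, when
#'   transform labels are available, `psi`, `upsilon`, `reflected`.
#'   Zero rows when nothing clears the threshold.
#' @export
local_maxima <- function(x, t3 = 0, top_k = NULL, min_separation = 0,
                         height = NULL) {
  labels <- NULL
  if (is.list(x) && !is.null(x$response)) {
    labels <- x$labels
    x <- x$response
  }
  if (t3 < 0 || t3 > 1) stop("t3 must be in [0, 1]")
  if (is.null(height)) height <- ncol(x)
  mx <- max(x)
  det <- data.frame(x = integer(), y = integer(), row = integer(),
                    col = integer(), score = numeric(), rank = integer())
  if (mx > 0) {
    lm <- which(strict_local_maxima(x) & x >= t3 * mx & x > 0,
                arr.ind = TRUE)
    if (nrow(lm) > 0) {
      pts <- data.frame(x = lm[, 1], y = lm[, 2], value = x[lm])
      pts <- suppress_close(pts, min_separation)
      if (!is.null(top_k)) pts <- head(pts, top_k)
      det <- data.frame(x = pts$x, y = pts$y,
                        row = height - pts$y + 1, col = pts$x,
                        score = pts$value, rank = seq_len(nrow(pts)))
      if (!is.null(labels)) {
        idx <- cbind(pts$x, pts$y)
        det$psi <- labels$psi[idx]
        det$upsilon <- labels$upsilon[idx]
        det$reflected <- labels$reflected[idx]
      }
    }
  }
  det
}
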