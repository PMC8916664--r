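#' Channel layout of an insole recording
#'
#' A recording has 28 channels in a fixed order: 16 pressure sensors
#' (8 left, 8 right), 6 accelerometer axes and 6 gyroscope axes.
#' All matrices in the package are time-by-channel in this order.
#'
#' @return A list with `channels` (28 channel names), and integer index
#'   vectors `pre`, `acc`, `rot` for the pressure, acceleration and rotation
#'   blocks, plus `n_channels = 28`.
#' @examples
#' lay <- modality_layout()
#' lay$channels[lay$acc]
#' @export
modality_layout <- function() {
  pre <- c(paste0("pl", 1:8), paste0("pr", 1:8))
  acc <- c("alx", "aly", "alz", "arx", "ary", "arz")
  rot <- c("rlx", "rly", "rlz", "rrx", "rry", "rrz")
  list(
    channels   = c(pre, acc, rot),
    pre        = 1:16,
    acc        = 17:22,
    rot        = 23:28,
    n_channels = 28L
  )
}

#' @keywords internal
.check_channels <- function(x, what = "matrix") {
  if (!is.matrix(x) || ncol(x) != 28L)
    stop(what, " must be a numeric matrix with 28 channel columns", call. = FALSE)
  invisible(x)
}

#' Split a time-by-channel matrix into modality blocks
#'
#' @param x numeric matrix with 28 columns.
#' @return List with elements `pre` (T x 16), `acc` (T x 6), `rot` (T x 6).
#' @export
split_modalities <- function(x) {
  .check_channels(x)
  lay <- modality_layout()
  list(pre = x[, lay$pre, drop = FALSE],
       acc = x[, lay$acc, drop = FALSE],
       rot = x[, lay$rot, drop = FALSE])
}
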