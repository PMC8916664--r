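#' Gaussian smoothing of the pressure channels
#'
#' The raw pressure sensors report three discrete levels; smoothing removes
#' spurious single-sample transitions before stance/swing detection.
#' Only the 16 pressure channels are filtered; acceleration and rotation
#' channels pass through untouched.
#'
#' @param recording numeric matrix, time by 28 channels.
#' @param sigma kernel standard deviation in samples (> 0). The kernel is
#'   truncated at +/- 4 sigma; boundaries are handled by reflection.
#' @return Matrix of the same shape with smoothed pressure channels.
#' @export
smooth_pressure <- function(recording, sigma = 3) {
  .check_channels(recording, "recording")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a positive number", call. = FALSE)
  lay <- modality_layout()
  out <- recording
  out[, lay$pre] <- apply(recording[, lay$pre, drop = FALSE], 2,
                          gaussian_smooth, sigma = sigma)
  out
}

#' Gaussian smoothing of a single series (reflected boundaries)
#'
#' @param x numeric vector.
#' @param sigma kernel standard deviation in samples (> 0).
#' @return Smoothed vector of the same length.
#' @export
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  n <- length(x)
  # reflected padding (mirror about the end points, end point not repeated)
  idx <- c(rev(seq_len(r)) + 1L, seq_len(n), n - seq_len(r))
  xp <- x[pmin(pmax(idx, 1L), n)]
  as.numeric(stats::filter(xp, k, sides = 2))[(r + 1):(r + n)]
}

#' Segment a continuous recording into unit steps
#'
#' A unit step is one full walking cycle: a stance phase (foot on ground,
#' non-zero pressure) followed by the swing phase (foot in the air, zero
#' pressure). Stance onsets are the rising edges of `sum(pressure) >
#' swing_threshold` computed over all 16 (smoothed) pressure channels; each
#' cycle spans the half-open interval from one onset to the next and is
#' linearly resampled along time to exactly `T_len` rows. Incomplete leading
#' and trailing cycles are dropped.
#'
#' @param recording numeric matrix, time by 28 channels, already smoothed.
#' @param T_len number of rows of each resampled unit step (>= 2).
#' @param swing_threshold summed-pressure level below which the foot is
#'   considered in swing.
#' @return List of `T_len` x 28 unit-step matrices (possibly empty).
#' @export
segment_unit_steps <- function(recording, T_len = 100, swing_threshold = 0.5) {
  .check_channels(recording, "recording")
  if (!is.numeric(T_len) || length(T_len) != 1L || T_len < 2)
    stop("T_len must be an integer >= 2", call. = FALSE)
  if (swing_threshold < 0)
    stop("swing_threshold must be non-negative", call. = FALSE)
  T_len <- as.integer(T_len)
  lay <- modality_layout()
  p <- rowSums(recording[, lay$pre, drop = FALSE])
  stance <- p > swing_threshold
  # rising edges: FALSE -> TRUE transitions (a stance at sample 1 has no
  # observed onset, so the leading partial cycle is dropped automatically)
  onsets <- which(diff(c(FALSE, stance)) == 1L)
  if (length(onsets) < 2L) return(list())
  lapply(seq_len(length(onsets) - 1L), function(i) {
    seg <- recording[onsets[i]:(onsets[i + 1L] - 1L), , drop = FALSE]
    resample_rows(seg, T_len)
  })
}

#' Linearly resample the rows of a matrix to a fixed count
#'
#' @param x numeric matrix (n x k), n >= 1.
#' @param T_len target number of rows (>= 2).
#' @return `T_len` x k matrix, each column linearly interpolated in time.
#' @export
resample_rows <- function(x, T_len) {
  n <- nrow(x)
  if (n == 1L) return(x[rep(1L, T_len), , drop = FALSE])
  ti <- seq(1, n, length.out = T_len)
  apply(x, 2, function(col) stats::approx(seq_len(n), col, xout = ti)$y)
}

#' Replace zero pressure values by a small positive floor
#'
#' Zero pressure marks the swing phase; substituting a small delta keeps
#' live samples distinguishable from occluded entries, which are set to
#' exactly zero. Only pressure channels are touched; the operation is
#' idempotent.
#'
#' @param step unit-step matrix (T x 28).
#' @param delta positive floor value (default 0.01).
#' @return The floored unit step.
#' @export
apply_pressure_floor <- function(step, delta = 0.01) {
  .check_channels(step, "step")
  if (delta <= 0) stop("delta must be positive", call. = FALSE)
  lay <- modality_layout()
  p <- step[, lay$pre, drop = FALSE]
  p[p == 0] <- delta
  step[, lay$pre] <- p
  step
}

#' Per-subject prototype of a set of unit steps
#'
#' The prototype is the element-wise arithmetic mean of a subject's unit
#' steps: for each channel m, the mean of the q aligned length-T traces.
#'
#' @param steps non-empty list of T x 28 unit-step matrices of one subject.
#' @param subject optional subject id recorded on the result.
#' @return T x 28 matrix of class `gait_prototype` with attributes
#'   `subject` and `q` (number of averaged steps).
#' @export
compute_prototype <- function(steps, subject = NA) {
  if (!is.list(steps) || length(steps) == 0L)
    stop("steps must be a non-empty list of unit steps", call. = FALSE)
  d <- dim(steps[[1L]])
  for (s in steps) {
    .check_channels(s, "each step")
    if (!identical(dim(s), d))
      stop("all unit steps must share the same T x 28 shape", call. = FALSE)
  }
  ids <- unique(unlist(lapply(steps, attr, "subject")))
  if (length(ids) > 1L)
    stop("unit steps come from different subjects: ",
         paste(ids, collapse = ", "), call. = FALSE)
  if (is.na(subject) && length(ids) == 1L) subject <- ids
  proto <- Reduce(`+`, steps) / length(steps)
  structure(proto, class = c("gait_prototype", class(proto)),
            subject = subject, q = length(steps))
}

#' Normalize a matrix (or vector) to unit L2 norm
#'
#' The norm is taken over all entries (flattened). Direction is preserved;
#' an all-zero input cannot be normalized and raises an error.
#'
#' @param x numeric matrix or vector with non-zero norm.
#' @return `x / ||x||_2`.
#' @export
l2_normalize <- function(x) {
  nrm <- sqrt(sum(x^2))
  if (nrm == 0)
    stop("cannot L2-normalize an all-zero input (division by zero)",
         call. = FALSE)
  x / nrm
}

#' Normalize each channel column of a unit step to unit L2 norm
#'
#' @param x T x k matrix; every column must have non-zero norm.
#' @return Matrix whose columns each have L2 norm 1.
#' @export
normalize_channels <- function(x) {
  nrm <- sqrt(colSums(x^2))
  if (any(nrm == 0))
    stop("cannot normalize a zero-norm channel (division by zero)",
         call. = FALSE)
  sweep(x, 2, nrm, "/")
}
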