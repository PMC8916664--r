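#' Build a synthetic subject template
#'
#' A template is a smooth per-channel signature of one gait cycle: pressure
#' channels are clipped sums of 2--4 random-phase sinusoids, exactly zero on
#' the swing window (the final `swing_frac` of the cycle); acceleration and
#' rotation channels are random low-order harmonic series of unit scale.
#' Distinct seeds give distinct harmonic coefficients, so templates differ
#' across subjects by construction.
#'
#' @param seed integer seed; the template is deterministic given it.
#' @param T_len number of rows (>= 2), default 100 (one cycle at 100 Hz).
#' @param swing_frac fraction of the cycle spent in swing, in (0, 1).
#' @return List of class `subject_template` with `signal` (T x 28 matrix),
#'   `swing` (row indices of the swing window), `swing_frac` and `T_len`.
#' @export
make_subject_template <- function(seed, T_len = 100, swing_frac = 0.4) {
  if (T_len < 2) stop("T_len must be >= 2", call. = FALSE)
  if (swing_frac <= 0 || swing_frac >= 1)
    stop("swing_frac must be in (0, 1)", call. = FALSE)
  T_len <- as.integer(T_len)
  lay <- modality_layout()
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  swing_start <- floor(T_len * (1 - swing_frac)) + 1L
  swing <- swing_start:T_len
  stance_len <- swing_start - 1L
  u <- seq(0, 1, length.out = stance_len)       # normalized stance time

  sig <- matrix(0, T_len, lay$n_channels, dimnames = list(NULL, lay$channels))
  for (j in lay$pre) {
    nh <- sample(2:4, 1L)
    w <- numeric(stance_len)
    for (h in seq_len(nh))
      w <- w + stats::runif(1, 0.4, 1) * sin(pi * u * h + stats::runif(1, 0, 2 * pi))
    w <- pmax(w, 0) * sin(pi * u)               # force 0 at stance edges
    sig[seq_len(stance_len), j] <- w
  }
  t_full <- seq(0, 1, length.out = T_len)
  for (j in c(lay$acc, lay$rot)) {
    w <- numeric(T_len)
    for (h in 1:4)
      w <- w + stats::rnorm(1, 0, 1 / h) * sin(2 * pi * h * t_full + stats::runif(1, 0, 2 * pi))
    sig[, j] <- w
  }
  structure(list(signal = sig, swing = swing, swing_frac = swing_frac,
                 T_len = T_len),
            class = "subject_template")
}

# save/restore the global RNG state so generators are pure given their seed
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Generate one noisy unit step from a subject template
#'
#' The template is warped in time by a smooth monotone warp of amplitude up
#' to `jitter * T`, Gaussian noise of sd `noise_sd` is added on all
#' channels, pressure is clipped at zero, re-zeroed on the swing window and
#' floored at `delta`.
#'
#' @param template a `subject_template`.
#' @param noise_sd additive noise standard deviation (>= 0).
#' @param jitter timing-jitter fraction in `[0, 0.2]`.
#' @param delta pressure floor (default 0.01).
#' @param quantize if `TRUE`, pressure is snapped to the three discrete
#'   sensor levels (0, 0.5, 1 on the unit amplitude scale) before the
#'   floor is applied, mimicking raw three-level sensors. Off by default:
#'   downstream processing treats pressure as continuous after smoothing.
#' @return T x 28 unit-step matrix.
#' @export
generate_unit_step <- function(template, noise_sd = 0.1, jitter = 0.05,
                               delta = 0.01, quantize = FALSE) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (jitter < 0 || jitter > 0.2)
    stop("jitter must be in [0, 0.2]", call. = FALSE)
  lay <- modality_layout()
  sig <- template$signal
  T_len <- template$T_len
  if (jitter > 0) {
    # smooth monotone warp: t -> t + a*T*sin(2*pi*t/T + phase), |a| <= jitter;
    # |d warp/dt| = 2*pi*a <= 2*pi*0.2 < 1 keeps it monotone
    a <- stats::runif(1, -jitter, jitter)
    ph <- stats::runif(1, 0, 2 * pi)
    tt <- seq_len(T_len)
    src <- tt + a * T_len * sin(2 * pi * tt / T_len + ph)
    src <- pmin(pmax(src, 1), T_len)
    sig <- apply(sig, 2, function(col)
      stats::approx(seq_len(T_len), col, xout = src)$y)
  }
  if (noise_sd > 0)
    sig <- sig + matrix(stats::rnorm(length(sig), 0, noise_sd), nrow(sig))
  p <- sig[, lay$pre, drop = FALSE]
  p <- pmax(p, 0)
  if (quantize) p <- round(pmin(p, 1) * 2) / 2
  p[template$swing, ] <- 0
  sig[, lay$pre] <- p
  colnames(sig) <- lay$channels
  apply_pressure_floor(sig, delta)
}

#' Configuration of a synthetic gait dataset
#'
#' Defaults mirror the study conditions of the real cohort the generator
#' stands in for: 40 subjects, 158 unit steps per subject, 100-row unit
#' steps, unit-scale signals with noise sd 0.1 and 5% timing jitter.
#'
#' @param n_subjects number of subjects.
#' @param steps_per_subject unit steps per subject.
#' @param T_len unit-step length in rows.
#' @param noise_sd additive noise sd.
#' @param jitter timing-jitter fraction in `[0, 0.2]`.
#' @param delta pressure floor.
#' @param swing_frac swing fraction of the cycle.
#' @param quantize snap pressure to three discrete levels (default off).
#' @param seed integer seed governing all randomness.
#' @return List of class `generation_config`.
#' @export
generation_config <- function(n_subjects = 40, steps_per_subject = 158,
                              T_len = 100, noise_sd = 0.1, jitter = 0.05,
                              delta = 0.01, swing_frac = 0.4,
                              quantize = FALSE, seed = 1) {
  stopifnot(n_subjects >= 1, steps_per_subject >= 1, T_len >= 2,
            noise_sd >= 0, jitter >= 0, jitter <= 0.2, delta > 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 steps_per_subject = as.integer(steps_per_subject),
                 T_len = as.integer(T_len), noise_sd = noise_sd,
                 jitter = jitter, delta = delta, swing_frac = swing_frac,
                 quantize = isTRUE(quantize), seed = as.integer(seed)),
            class = "generation_config")
}

#' Generate a synthetic multi-subject unit-step dataset
#'
#' Subject templates are drawn deterministically from the config seed; unit
#' steps are generated i.i.d. around each template. The result is the
#' in-memory dataset bundle consumed by the rest of the pipeline; see
#' [write_gait_bundle()] for the on-disk layout.
#'
#' @param config a [generation_config()].
#' @return List of class `gait_dataset` with `steps` (named list: subject id
#'   -> list of T x 28 matrices), `templates`, and the config fields.
#' @export
generate_dataset <- function(config = generation_config()) {
  stopifnot(inherits(config, "generation_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  subj_seeds <- sample.int(.Machine$integer.max, config$n_subjects)
  ids <- sprintf("S%02d", seq_len(config$n_subjects))
  templates <- stats::setNames(lapply(subj_seeds, make_subject_template,
                                      T_len = config$T_len,
                                      swing_frac = config$swing_frac), ids)
  steps <- stats::setNames(vector("list", config$n_subjects), ids)
  for (a in ids) {
    steps[[a]] <- replicate(config$steps_per_subject,
                            generate_unit_step(templates[[a]],
                                               noise_sd = config$noise_sd,
                                               jitter = config$jitter,
                                               delta = config$delta,
                                               quantize = config$quantize),
                            simplify = FALSE)
  }
  structure(list(steps = steps, templates = templates,
                 T_len = config$T_len, delta = config$delta,
                 config = config),
            class = "gait_dataset")
}

#' Render a continuous synthetic recording of several gait cycles
#'
#' Concatenates noisy cycles of varying duration from one template, giving
#' a raw recording suitable for [smooth_pressure()] and
#' [segment_unit_steps()].
#'
#' @param template a `subject_template`.
#' @param n_cycles number of full cycles.
#' @param noise_sd,jitter,delta as in [generate_unit_step()]; the floor is
#'   not applied here (raw recordings keep true zeros during swing).
#' @param cycle_sd relative sd of the per-cycle duration.
#' @return N x 28 matrix of class `raw_recording`.
#' @export
generate_recording <- function(template, n_cycles = 5, noise_sd = 0.05,
                               jitter = 0.05, delta = 0.01, cycle_sd = 0.05) {
  T_len <- template$T_len
  cycles <- lapply(seq_len(n_cycles), function(i) {
    s <- generate_unit_step(template, noise_sd = noise_sd, jitter = jitter,
                            delta = delta)
    lay <- modality_layout()
    p <- s[, lay$pre, drop = FALSE]
    p[p == delta] <- 0                       # undo the floor: raw zeros
    s[, lay$pre] <- p
    len <- max(4L, round(T_len * stats::rnorm(1, 1, cycle_sd)))
    resample_rows(s, len)
  })
  out <- do.call(rbind, cycles)
  class(out) <- c("raw_recording", class(out))
  out
}
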