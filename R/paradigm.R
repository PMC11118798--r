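#' Build the stimulation paradigm for one imaging run
#'
#' Runs last 270 s at TR 6.75 s (40 volumes).  At the 1-min mark a cue
#' informs the participant of the run condition.  In Pain runs a 30-s
#' stimulation block starts at 120 s: 10 noxious heat contacts of 1.5 s
#' each, with onsets every 3 s (temporal-summation paradigm).  No-Pain
#' runs have identical timing but no contacts.
#'
#' @param condition `"Pain"` or `"No-Pain"`.
#' @return a `sapm_paradigm` list with fields `condition`, `duration_s`,
#'   `tr_s`, `n_volumes`, `cue_onset_s`, `cue_duration_s`,
#'   `stim_onsets_s`, `contact_duration_s`.
#' @export
build_paradigm <- function(condition = c("Pain", "No-Pain")) {
  condition <- match.arg(condition)
  stim <- if (condition == "Pain") 120 + 3 * (0:9) else numeric()
  structure(list(condition = condition, duration_s = 270, tr_s = 6.75,
                 n_volumes = 40L, n_runs = 5L, cue_onset_s = 60,
                 cue_duration_s = 3, stim_onsets_s = stim,
                 contact_duration_s = 1.5),
            class = "sapm_paradigm")
}

#' The stimulus temperature protocol
#'
#' One calibrated temperature per Pain run; default 46, 50, 44, 48 degC.
#'
#' @param temperatures_C numeric vector of temperatures.
#' @return list with field `temperatures_C`.
#' @export
stimulus_protocol <- function(temperatures_C = c(46, 50, 44, 48)) {
  stopifnot(is.numeric(temperatures_C), all(temperatures_C > 0))
  structure(list(temperatures_C = temperatures_C), class = "sapm_protocol")
}

#' Canonical hemodynamic response function
#'
#' Double-gamma kernel (difference of gamma densities with shapes 6 and
#' 16, undershoot ratio 1/6), rescaled to unit peak amplitude.  The peak
#' lies near 5 s, within the physiological 4-7 s window.
#'
#' @param t time in seconds (vectorized, `t >= 0`; negative times return 0).
#' @return dimensionless response values.
#' @export
hrf <- function(t) {
  h <- stats::dgamma(t, shape = 6, rate = 1) -
       stats::dgamma(t, shape = 16, rate = 1) / 6
  h[t < 0] <- 0
  # unit-peak normalization; kernel maximum (near t = 5 s) on a dense grid
  h / 0.1754412012
}

#' Latent neural design for one run
#'
#' Builds the three neural component series that drive the network's
#' latent inputs, at second-scale resolution `dt`:
#' \describe{
#'   \item{stimulation}{boxcars over the 10 heat contacts (identically
#'     zero in No-Pain runs); drives the spinal dorsal horn (int1).}
#'   \item{cue}{a short boxcar at the 60-s cue (condition announcement);
#'     drives arousal circuitry (int2).}
#'   \item{drift}{a tonic half-cosine over the run standing in for slow
#'     baseline/state fluctuations; drives the thalamus (int3).}
#' }
#' All components are mean-centered over the run.
#'
#' @param p a `sapm_paradigm`.
#' @param dt sampling interval in seconds (default 0.25, which divides
#'   the 6.75-s TR exactly so volume sampling needs no interpolation).
#' @return matrix `3 x T` with rownames `stimulation`, `cue`, `drift`
#'   and attribute `times` (seconds).
#' @export
neural_design <- function(p, dt = 0.25) {
  stopifnot(inherits(p, "sapm_paradigm"))
  times <- seq(0, p$duration_s - dt, by = dt)
  stim <- numeric(length(times))
  for (on in p$stim_onsets_s)
    stim[times >= on & times < on + p$contact_duration_s] <- 1
  cue <- as.numeric(times >= p$cue_onset_s &
                    times < p$cue_onset_s + p$cue_duration_s)
  drift <- cos(pi * times / p$duration_s)
  out <- rbind(stimulation = stim - mean(stim),
               cue = cue - mean(cue),
               drift = drift - mean(drift))
  attr(out, "times") <- times
  attr(out, "dt") <- dt
  out
}

#' Convolve neural series with the HRF and sample at volume times
#'
#' Each second-resolution neural series is convolved with the canonical
#' [hrf()], sampled at volume acquisition times `0, tr_s, 2*tr_s, ...`,
#' then mean-centered and scaled to unit variance (an identically-zero
#' series stays zero).
#'
#' @param neural numeric vector or matrix (series in rows) with a `dt`
#'   attribute, as produced by [neural_design()], or a plain vector with
#'   `dt` supplied.
#' @param tr_s repetition time, seconds per volume.
#' @param dt neural sampling interval (taken from `neural` if present).
#' @return volume-sampled matrix (series in rows) or vector.
#' @export
bold_from_neural <- function(neural, tr_s, dt = attr(neural, "dt")) {
  if (is.null(dt)) stop("dt must be supplied", call. = FALSE)
  vec_in <- is.null(dim(neural))
  x <- if (vec_in) matrix(neural, nrow = 1) else neural
  n_t <- ncol(x)
  duration <- n_t * dt
  if (duration < tr_s) stop("series shorter than one TR", call. = FALSE)
  kern <- hrf(seq(0, min(48, duration), by = dt))
  n_vol <- floor(duration / tr_s)
  vol_idx <- pmin(n_t, round((0:(n_vol - 1)) * tr_s / dt) + 1L)
  out <- matrix(0, nrow(x), n_vol, dimnames = list(rownames(x), NULL))
  for (i in seq_len(nrow(x))) {
    conv <- stats::convolve(x[i, ], rev(kern), type = "open")[seq_len(n_t)] * dt
    v <- conv[vol_idx]
    v <- v - mean(v)
    s <- stats::sd(v)
    out[i, ] <- if (s > 0) v / s else v
  }
  if (vec_in) drop(out) else out
}

#' Normalized pain score
#'
#' A participant's mean pain rating divided by the mean stimulus
#' temperature used to elicit it; higher values indicate higher pain
#' sensitivity.
#'
#' @param ratings numeric vector of pain ratings (0-100 scale).
#' @param temperatures_C numeric vector of stimulus temperatures (> 0).
#' @return dimensionless score.
#' @export
normalized_pain_score <- function(ratings, temperatures_C) {
  if (!length(ratings) || !length(temperatures_C))
    stop("ratings and temperatures must be non-empty", call. = FALSE)
  stopifnot(all(temperatures_C > 0))
  mean(ratings) / mean(temperatures_C)
}

#' Phase-randomized surrogate of a time series
#'
#' Fourier-transform the series, randomize the phases (respecting
#' Hermitian symmetry so the output is real), and invert.  The amplitude
#' spectrum — hence the autocovariance and variance — is preserved, while
#' any locking to the stimulation paradigm is destroyed.  This is the
#' null-data construction used for connectivity reference distributions.
#'
#' @param series numeric vector, length >= 4.
#' @param seed integer seed (surrogate is deterministic given the seed).
#' @return surrogate numeric vector of the same length.
#' @export
phase_randomize <- function(series, seed) {
  n <- length(series)
  if (n < 4) stop("series must have length >= 4", call. = FALSE)
  if (!missing(seed) && !is.null(seed)) set.seed(seed)
  X <- stats::fft(series)
  half <- floor((n - 1) / 2)                 # indices 2..half+1 are free
  ph <- stats::runif(half, 0, 2 * pi)
  Xs <- X
  if (half > 0) {
    k <- 2:(half + 1)
    Xs[k] <- Mod(X[k]) * exp(1i * ph)
    Xs[n + 2 - k] <- Conj(Xs[k])
  }
  if (n %% 2 == 0) {                          # Nyquist bin stays real
    s <- sample(c(-1, 1), 1)
    Xs[n / 2 + 1] <- Mod(X[n / 2 + 1]) * s
  }
  Re(stats::fft(Xs, inverse = TRUE)) / n
}
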