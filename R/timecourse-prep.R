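#' Component time-course container
#'
#' @param data T x C numeric matrix (rows = TRs, columns = components);
#'   column names are the component ids.
#' @param tr_seconds repetition time in seconds.
#' @param subject_id subject identifier.
#' @return object of class `timecourse_set`.
#' @export
timecourse_set <- function(data, tr_seconds, subject_id = "sub-01") {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), nrow(data) >= 2, tr_seconds > 0)
  if (anyNA(data)) stop("time courses contain missing values")
  if (is.null(colnames(data))) {
    colnames(data) <- sprintf("IC%02d", seq_len(ncol(data)))
  }
  structure(list(subject_id = subject_id, data = data,
                 tr_seconds = tr_seconds,
                 component_ids = colnames(data)),
            class = "timecourse_set")
}

#' @export
print.timecourse_set <- function(x, ...) {
  cat("<timecourse_set> ", x$subject_id, ": ", nrow(x$data), " TRs x ",
      ncol(x$data), " components, TR = ", x$tr_seconds, " s\n", sep = "")
  invisible(x)
}

#' Remove per-component linear trends
#'
#' Least-squares linear trend (intercept + slope) removed per component, so
#' every column has zero mean afterwards. A constant column becomes all
#' zeros.
#'
#' @param ts a [timecourse_set()].
#' @return detrended [timecourse_set()].
#' @export
tc_detrend <- function(ts) {
  x <- ts$data
  stopifnot(nrow(x) >= 3)
  t_ <- seq_len(nrow(x))
  X <- cbind(1, t_ - mean(t_))
  ts$data <- x - X %*% qr.coef(qr(X), x)
  ts
}

#' Replace motion/artifact spikes by local interpolation
#'
#' Per component, samples whose robust z-score `|x - median| / (1.4826 MAD)`
#' exceeds `robust_z` are replaced by linear interpolation between the
#' nearest non-spike neighbours (edge spikes take the nearest valid value).
#' When the MAD degenerates to zero (more than half the samples identical,
#' as with an isolated spike on a flat background) the scale falls back to
#' 1.4826 times the mean absolute deviation from the median; a component
#' that is exactly constant is passed through untouched.
#'
#' @param ts a [timecourse_set()].
#' @param robust_z spike threshold in robust z units.
#' @return despiked [timecourse_set()].
#' @export
tc_despike <- function(ts, robust_z = 4) {
  x <- ts$data
  stopifnot(nrow(x) >= 5, robust_z > 0)
  ts$data <- apply(x, 2, function(col) {
    m <- median(col)
    s <- mad(col)   # 1.4826 * MAD
    if (s == 0) s <- 1.4826 * mean(abs(col - m))  # degenerate-MAD fallback
    if (s == 0) return(col)
    spike <- abs(col - m) / s > robust_z
    if (!any(spike) || all(spike)) return(col)
    idx <- seq_along(col)
    col[spike] <- approx(idx[!spike], col[!spike], xout = idx[spike],
                         rule = 2)$y
    col
  })
  ts
}

#' Zero-phase low-pass filtering
#'
#' 5th-order Butterworth low-pass applied forward and backward
#' (zero-phase), per component. The default 0.15 Hz cutoff suppresses
#' high-frequency content while leaving the slow fluctuations that carry
#' functional connectivity.
#'
#' @param ts a [timecourse_set()].
#' @param cutoff_hz cutoff frequency; must be below Nyquist
#'   (`1 / (2 tr_seconds)`).
#' @param order filter order (before the forward-backward pass).
#' @return filtered [timecourse_set()].
#' @export
tc_lowpass <- function(ts, cutoff_hz = 0.15, order = 5) {
  nyquist <- 1 / (2 * ts$tr_seconds)
  if (cutoff_hz >= nyquist) {
    stop("cutoff_hz (", cutoff_hz, ") must be below the Nyquist frequency (",
         nyquist, " Hz)")
  }
  bf <- signal::butter(order, cutoff_hz / nyquist, type = "low")
  ts$data <- apply(ts$data, 2, function(col) {
    mu <- mean(col)
    signal::filtfilt(bf, col - mu) + mu
  })
  ts
}

#' Low-band to high-band spectral power ratio
#'
#' Welch periodogram (Hann-windowed segments of length `min(T, 64)`, 50%
#' overlap, per-segment demeaning); returns integrated power in `low_band`
#' divided by integrated power in `high_band`. Components dominated by slow
#' fluctuations (ratio above ~4 with the default 0-0.10 / 0.15-0.25 Hz
#' bands) are the ones worth keeping for connectivity analysis.
#'
#' @param x numeric vector, one component's time course.
#' @param tr_seconds sampling interval in seconds.
#' @param low_band,high_band frequency bands in Hz, within `[0, Nyquist]`.
#' @return the power ratio; `Inf` if the high band carries no power.
#' @export
power_ratio <- function(x, tr_seconds, low_band = c(0, 0.10),
                        high_band = c(0.15, 0.25)) {
  fs <- 1 / tr_seconds
  nyquist <- fs / 2
  stopifnot(low_band[1] >= 0, high_band[2] <= nyquist + 1e-12,
            low_band[2] > low_band[1], high_band[2] > high_band[1])
  w <- welch_psd(x, fs)
  band_power <- function(band) {
    sum(w$psd[w$freq >= band[1] & w$freq <= band[2]])
  }
  hi <- band_power(high_band)
  lo <- band_power(low_band)
  if (hi == 0) return(Inf)
  lo / hi
}

# Welch power spectral density: Hann segments, 50% overlap, demeaned.
welch_psd <- function(x, fs, seg_len = min(length(x), 64L)) {
  n <- length(x)
  seg_len <- as.integer(seg_len)
  step <- max(1L, seg_len %/% 2L)
  starts <- seq(1L, n - seg_len + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, seg_len - 1) / (seg_len - 1))
  scale <- sum(win^2) * fs
  acc <- numeric(seg_len %/% 2L + 1L)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * win
    p <- abs(fft(seg))^2 / scale
    acc <- acc + p[seq_len(seg_len %/% 2L + 1L)]
  }
  psd <- acc / length(starts)
  # fold the negative frequencies into the one-sided spectrum
  if (seg_len %% 2L == 0L) {
    psd[2:(length(psd) - 1L)] <- 2 * psd[2:(length(psd) - 1L)]
  } else {
    psd[2:length(psd)] <- 2 * psd[2:length(psd)]
  }
  list(freq = (seq_along(psd) - 1) * fs / seg_len, psd = psd)
}

#' Head-motion quality control for one subject
#'
#' Fails a subject whose mean frame-wise displacement exceeds
#' `mean_fd_max` (default 0.2 mm), or whose maximum translation or rotation
#' exceeds the displacement bounds (defaults 3 mm / 3 degrees).
#'
#' @param fd_trace per-volume frame-wise displacement in mm (non-negative).
#' @param translations optional T x 3 matrix of absolute translations (mm).
#' @param rotations optional T x 3 matrix of absolute rotations (degrees).
#' @param mean_fd_max,max_disp_mm,max_rot_deg exclusion bounds.
#' @return list with `pass` (logical) and `reasons` (character vector of
#'   fired rules, empty on pass).
#' @export
qc_subject <- function(fd_trace, translations = NULL, rotations = NULL,
                       mean_fd_max = 0.2, max_disp_mm = 3,
                       max_rot_deg = 3) {
  stopifnot(length(fd_trace) >= 1)
  if (any(fd_trace < 0)) stop("frame-wise displacement must be non-negative")
  reasons <- character()
  if (mean(fd_trace) > mean_fd_max) {
    reasons <- c(reasons, sprintf("mean FD %.3f mm > %.3f mm",
                                  mean(fd_trace), mean_fd_max))
  }
  if (!is.null(translations) && max(abs(translations)) > max_disp_mm) {
    reasons <- c(reasons, sprintf("max displacement %.2f mm > %.1f mm",
                                  max(abs(translations)), max_disp_mm))
  }
  if (!is.null(rotations) && max(abs(rotations)) > max_rot_deg) {
    reasons <- c(reasons, sprintf("max rotation %.2f deg > %.1f deg",
                                  max(abs(rotations)), max_rot_deg))
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Full time-course conditioning chain
#'
#' Discards the first `discard_volumes` TRs (signal stabilization), then
#' applies, in this fixed order: linear detrend, robust-z despiking,
#' zero-phase low-pass. The order is recorded in the `conditioning`
#' attribute for provenance.
#'
#' @param ts a [timecourse_set()].
#' @param discard_volumes leading volumes to drop before conditioning.
#' @param robust_z despike threshold.
#' @param cutoff_hz low-pass cutoff in Hz.
#' @return conditioned [timecourse_set()].
#' @export
condition_timecourses <- function(ts, discard_volumes = 0L, robust_z = 4,
                                  cutoff_hz = 0.15) {
  if (discard_volumes > 0L) {
    stopifnot(nrow(ts$data) > discard_volumes + 2L)
    ts$data <- ts$data[-seq_len(discard_volumes), , drop = FALSE]
  }
  ts <- tc_lowpass(tc_despike(tc_detrend(ts), robust_z), cutoff_hz)
  attr(ts, "conditioning") <- list(
    steps = c("discard", "detrend", "despike", "lowpass"),
    discard_volumes = discard_volumes, robust_z = robust_z,
    cutoff_hz = cutoff_hz)
  ts
}

#' Number of volumes collected in a scan of given duration
#'
#' @param duration_seconds total acquisition time in seconds.
#' @param tr_seconds repetition time in seconds.
#' @return integer volume count.
#' @export
n_volumes <- function(duration_seconds, tr_seconds) {
  stopifnot(duration_seconds > 0, tr_seconds > 0)
  as.integer(floor(duration_seconds / tr_seconds))
}
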