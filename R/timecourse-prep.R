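#' Discard initial volumes of a run
#'
#' Removes the first `nDiscard` rows of the time series (signal
#' stabilization discard); node metadata is untouched.
#'
#' @param ts a [ComponentTimeSeries-class].
#' @param nDiscard number of leading volumes to drop (default 4).
#' @return the shortened [ComponentTimeSeries-class], flagged "discarded".
#' @export
discardInitialVolumes <- function(ts, nDiscard = 4L) {
  stopifnot(is(ts, "ComponentTimeSeries"))
  nDiscard <- as.integer(nDiscard)
  if (nDiscard < 0) stop("nDiscard must be >= 0")
  if (nDiscard >= nrow(ts@data))
    stop("nDiscard (", nDiscard, ") must be smaller than the volume count (",
         nrow(ts@data), ")")
  if (nDiscard > 0)
    ts@data <- ts@data[-seq_len(nDiscard), , drop = FALSE]
  ts@prepState <- union(ts@prepState, "discarded")
  validObject(ts)
  ts
}

#' Remove per-node linear trend and mean
#'
#' Least-squares projection of each column onto \{constant, linear ramp\};
#' the residual has zero mean and zero slope. Applying it twice is a
#' no-op (idempotent).
#'
#' @param ts a [ComponentTimeSeries-class] with >= 3 volumes.
#' @return the detrended series, flagged "detrended".
#' @export
detrendTimeSeries <- function(ts) {
  stopifnot(is(ts, "ComponentTimeSeries"))
  n <- nrow(ts@data)
  if (n < 3) stop("detrending needs >= 3 volumes")
  tt <- seq_len(n)
  X <- cbind(1, tt - mean(tt))
  ts@data <- ts@data - X %*% qr.solve(X, ts@data)
  ts@prepState <- union(ts@prepState, "detrended")
  ts
}

#' Zero-phase low-pass filter
#'
#' Order-5 Butterworth applied forward and backward
#' ([signal::filtfilt()]), so the passband is flat, attenuation at
#' 1.5x the cutoff exceeds 20 dB, and features are not shifted in time.
#' The filter may be applied only once per series (enforced by the
#' processing-state flag).
#'
#' @param ts a [ComponentTimeSeries-class].
#' @param cutoffHz cutoff frequency in Hz (default 0.15); must be below
#'   the Nyquist frequency `1/(2*trSeconds)`.
#' @param order Butterworth order (default 5).
#' @return the filtered series, flagged "filtered".
#' @export
lowpassFilter <- function(ts, cutoffHz = 0.15, order = 5L) {
  stopifnot(is(ts, "ComponentTimeSeries"))
  nyquist <- 1 / (2 * ts@trSeconds)
  if (cutoffHz >= nyquist)
    stop("cutoffHz (", cutoffHz, ") must be below the Nyquist frequency (",
         nyquist, " Hz)")
  if (cutoffHz <= 0) stop("cutoffHz must be positive")
  if ("filtered" %in% ts@prepState)
    stop("series is already low-pass filtered; the filter is applied once")
  bf <- signal::butter(order, cutoffHz / nyquist, type = "low")
  ts@data <- apply(ts@data, 2, function(col)
    signal::filtfilt(bf, col))
  ts@prepState <- union(ts@prepState, "filtered")
  ts
}

#' Standard preparation pipeline
#'
#' Fixed order: initial-volume discard, detrend, zero-phase low-pass.
#'
#' @param ts a [ComponentTimeSeries-class].
#' @param nDiscard leading volumes to drop (default 4).
#' @param cutoffHz low-pass cutoff in Hz (default 0.15).
#' @return the prepared [ComponentTimeSeries-class].
#' @export
prepTimeSeries <- function(ts, nDiscard = 4L, cutoffHz = 0.15) {
  ts <- discardInitialVolumes(ts, nDiscard)
  ts <- detrendTimeSeries(ts)
  lowpassFilter(ts, cutoffHz)
}

## Welch-style averaged periodogram: Hann-windowed overlapping segments.
## Returns freq (Hz) and power density per node column.
welchPsd <- function(X, fs, segLength = 64L, overlap = 0.5) {
  n <- nrow(X)
  segLength <- min(as.integer(segLength), n)
  stepLen <- max(1L, as.integer(segLength * (1 - overlap)))
  starts <- seq(1L, n - segLength + 1L, by = stepLen)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(segLength) / (segLength + 1))
  nf <- segLength %/% 2L
  psd <- matrix(0, nf, ncol(X))
  for (s in starts) {
    seg <- X[s:(s + segLength - 1L), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg))
    segW <- seg * w
    ft <- stats::mvfft(segW)
    psd <- psd + (Mod(ft[2:(nf + 1L), , drop = FALSE])^2) /
      (fs * sum(w^2))
  }
  list(freq = (seq_len(nf)) * fs / segLength, psd = psd / length(starts))
}

#' Component quality-control spectra
#'
#' Computes, per node, the dynamic range of the power spectral density
#' (peak minus minimum of the Welch PSD) and the ratio of integrated
#' spectral power below `splitHz` to power above it. Components whose
#' time courses are dominated by low-frequency fluctuations (high ratio)
#' are the ones retained as network nodes in ICA-based parcellations.
#'
#' @param ts a [ComponentTimeSeries-class] with >= 32 volumes.
#' @param splitHz frequency (Hz) separating "low" from "high" power
#'   (default 0.10).
#' @param segLength Welch segment length in volumes (default 64).
#' @return data.frame with columns `node`, `dynamic_range`,
#'   `low_high_ratio`. Constant nodes yield `NA` with a warning.
#' @export
componentQC <- function(ts, splitHz = 0.10, segLength = 64L) {
  stopifnot(is(ts, "ComponentTimeSeries"))
  if (nrow(ts@data) < 32) stop("component QC needs >= 32 volumes")
  fs <- 1 / ts@trSeconds
  if (splitHz <= 0 || splitHz >= fs / 2)
    stop("splitHz must lie in (0, Nyquist)")
  const <- apply(ts@data, 2, function(col) diff(range(col)) == 0)
  W <- welchPsd(ts@data, fs, segLength = segLength)
  low <- W$freq <= splitHz
  dynRange <- apply(W$psd, 2, function(p) max(p) - min(p))
  ratio <- colSums(W$psd[low, , drop = FALSE]) /
    colSums(W$psd[!low, , drop = FALSE])
  if (any(const)) {
    warning(sum(const), " constant node(s): QC ratio undefined, set to NA")
    dynRange[const] <- NA_real_
    ratio[const] <- NA_real_
  }
  nodes <- if (nrow(ts@nodeMeta)) ts@nodeMeta$node else
    sprintf("N%02d", seq_len(ncol(ts@data)))
  data.frame(node = nodes, dynamic_range = as.numeric(dynRange),
             low_high_ratio = as.numeric(ratio), stringsAsFactors = FALSE)
}
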