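#' Canonical BOLD frequency bands
#'
#' Returns the canonical slow-band decomposition of resting-state BOLD
#' signal: slow5 (0.01--0.027 Hz), slow4 (0.027--0.073 Hz), slow3
#' (0.073--0.198 Hz), slow2 (0.198--0.25 Hz), and the full band
#' (0.01--0.25 Hz). At the default repetition time of 2 s the upper edge
#' of slow2 (and of the full band) coincides with the Nyquist frequency;
#' [bandpass()] then degrades gracefully to a high-pass filter.
#'
#' @param include_full logical; include the full 0.01--0.25 Hz band.
#'   The full band participates only in single-layer analyses; the
#'   multilayer model uses the four slow bands.
#' @return A data.frame with columns `name`, `low_hz`, `high_hz`,
#'   ordered from the lowest band (slow5) upward.
#' @export
#' @examples
#' canonical_bands()
canonical_bands <- function(include_full = TRUE) {
  bands <- data.frame(
    name = c("slow5", "slow4", "slow3", "slow2", "full"),
    low_hz = c(0.010, 0.027, 0.073, 0.198, 0.010),
    high_hz = c(0.027, 0.073, 0.198, 0.250, 0.250),
    stringsAsFactors = FALSE
  )
  if (!include_full) bands <- bands[bands$name != "full", , drop = FALSE]
  bands
}

#' Multiplex-layer bands
#'
#' The four slow bands (slow5, slow4, slow3, slow2) that form the layers
#' of the multilayer network; the full band is excluded.
#'
#' @return A data.frame as in [canonical_bands()].
#' @export
multiplex_bands <- function() canonical_bands(include_full = FALSE)

#' Zero-phase band-pass filter
#'
#' Filters each region's time series into a frequency band using a
#' forward-backward (zero-phase) Butterworth filter, so that group delay
#' cannot desynchronize regions before correlation. When the upper edge
#' reaches the Nyquist frequency the band is realized as a high-pass
#' filter (the upper transition is clamped at Nyquist); an upper edge
#' strictly above Nyquist is an error.
#'
#' The filter is applied twice (forward and backward), so the effective
#' attenuation is the squared magnitude response of the design. Each
#' series is demeaned before filtering: no band passes DC, and removing
#' the mean first suppresses the start-up transients of the recursive
#' filter. No samples are discarded, but the first and last few filter
#' lengths remain attenuated by the edge treatment; tests of the
#' frequency response use interior windows.
#'
#' @param x numeric vector, or a regions x timepoints matrix (rows are
#'   filtered independently).
#' @param low_hz,high_hz band edges in Hz, `0 < low_hz < high_hz`.
#' @param tr_seconds sampling interval (repetition time) in seconds.
#' @param order Butterworth design order per skirt (default 2).
#' @return An object of the same shape as `x`.
#' @export
#' @examples
#' t <- seq(0, by = 2, length.out = 256)
#' x <- sin(2 * pi * 0.05 * t)
#' y <- bandpass(x, 0.027, 0.073, tr_seconds = 2)
bandpass <- function(x, low_hz, high_hz, tr_seconds, order = 2L) {
  stopifnot(is.numeric(low_hz), is.numeric(high_hz), is.numeric(tr_seconds),
            tr_seconds > 0, order >= 1)
  nyq <- 1 / (2 * tr_seconds)
  if (low_hz <= 0) stop("low_hz must be positive")
  if (high_hz <= low_hz) stop("high_hz must exceed low_hz")
  if (high_hz > nyq * (1 + 1e-9)) {
    stop(sprintf("high_hz = %g exceeds the Nyquist frequency %g Hz", high_hz, nyq))
  }
  filt <- design_bandpass(low_hz, high_hz, tr_seconds, order)
  if (is.matrix(x)) {
    out <- x
    for (i in seq_len(nrow(x))) {
      out[i, ] <- signal::filtfilt(filt, x[i, ] - mean(x[i, ]))
    }
    out
  } else {
    x <- as.numeric(x)
    signal::filtfilt(filt, x - mean(x))
  }
}

# Butterworth design, clamping the upper transition at Nyquist: a band
# whose upper edge sits on Nyquist is a high-pass filter.
design_bandpass <- function(low_hz, high_hz, tr_seconds, order) {
  nyq <- 1 / (2 * tr_seconds)
  if (high_hz >= nyq * (1 - 1e-9)) {
    signal::butter(order, low_hz / nyq, type = "high")
  } else {
    signal::butter(order, c(low_hz / nyq, high_hz / nyq), type = "pass")
  }
}

#' Apply a set of band-pass filters
#'
#' Convenience wrapper filtering one regions x timepoints matrix into
#' every band of a band table.
#'
#' @param x regions x timepoints numeric matrix.
#' @param bands data.frame with columns `name`, `low_hz`, `high_hz`.
#' @inheritParams bandpass
#' @return Named list of filtered matrices, one per band.
#' @export
bandpass_all <- function(x, bands, tr_seconds, order = 2L) {
  stopifnot(is.matrix(x), all(c("name", "low_hz", "high_hz") %in% names(bands)))
  out <- lapply(seq_len(nrow(bands)), function(b) {
    bandpass(x, bands$low_hz[b], bands$high_hz[b], tr_seconds, order)
  })
  names(out) <- bands$name
  out
}

#' Pearson functional connectivity
#'
#' Pairwise Pearson correlation between region time series. The diagonal
#' is stored as zero: self-connections are excluded from all downstream
#' network construction and metrics.
#'
#' @param x regions x timepoints numeric matrix; every region must have
#'   nonzero variance.
#' @return N x N symmetric matrix of correlations with a zero diagonal,
#'   carrying the row names of `x`.
#' @export
#' @examples
#' x <- rbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4))
#' pearson_connectivity(x)["a", "b"]  # 0.8
pearson_connectivity <- function(x) {
  stopifnot(is.matrix(x), ncol(x) >= 2)
  if (any(!is.finite(x))) stop("time series contain non-finite values")
  v <- apply(x, 1, stats::var)
  if (any(v == 0)) {
    bad <- rownames(x)[v == 0]
    if (is.null(bad)) bad <- which(v == 0)
    stop("zero-variance region(s): ", paste(bad, collapse = ", "))
  }
  r <- stats::cor(t(x))
  diag(r) <- 0
  r
}
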