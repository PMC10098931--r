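#' @name features
#' @title Time- and frequency-domain waveform descriptors
#'
#' @description
#' Each trajectory or joint-angle channel of a motion cycle is summarized
#' by 13 descriptors: ten time-domain statistics (maximum, minimum, mean,
#' peak-to-peak, standard deviation, kurtosis, skewness, root mean
#' square, shape factor, crest factor) and three spectral moments of the
#' periodogram (centroid frequency FC, mean square frequency MSF,
#' frequency variance VF). The standard deviation uses the 1/n
#' (population) form, kurtosis divides by (n-1) * st^4 and skewness by
#' n * st^3 -- these exact forms, not the unbiased textbook variants, are
#' the feature definitions. VF satisfies the identity VF = MSF - FC^2.
NULL

time_feature_names <- c("Max", "Min", "mean", "pk", "st", "ku", "sk",
                        "rm", "S", "C")
freq_feature_names <- c("FC", "MSF", "VF")

#' Ten time-domain descriptors of a series
#'
#' Degenerate inputs do not abort: for a constant series (st = 0) the
#' kurtosis and skewness are returned as 0, and when the RMS is 0 the
#' shape and crest factors are returned as 0; the `degenerate` attribute
#' flags either case. This keeps near-static downhill-tuck channels in
#' the pipeline.
#'
#' @param x numeric series, length >= 2.
#' @return named numeric vector `Max, Min, mean, pk, st, ku, sk, rm, S, C`
#'   with a logical `degenerate` attribute.
#' @export
time_features <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2) stop("time_features needs at least 2 samples")
  if (any(!is.finite(x))) stop("series must be finite")
  mx <- max(x); mn <- min(x); mu <- mean(x)
  pk <- mx - mn
  st <- sqrt(mean((x - mu)^2))
  rm_ <- sqrt(mean(abs(x)^2))
  degen <- FALSE
  if (st > 0) {
    ku <- sum((x - mu)^4) / ((n - 1) * st^4)
    sk <- sum((x - mu)^3) / (n * st^3)
  } else {
    ku <- 0; sk <- 0; degen <- TRUE
  }
  if (rm_ > 0) {
    S <- rm_ / mean(abs(x))
    C <- pk / rm_
  } else {
    S <- 0; C <- 0; degen <- TRUE
  }
  out <- c(Max = mx, Min = mn, mean = mu, pk = pk, st = st,
           ku = ku, sk = sk, rm = rm_, S = S, C = C)
  attr(out, "degenerate") <- degen
  out
}

#' One-sided periodogram power spectral density
#'
#' FFT-based periodogram of the mean-removed series on the even grid
#' 0, fs/n, ..., fs/2. Scaled so the total one-sided power equals the
#' population variance of the series (discrete Parseval). A rectangular
#' window is the default; a Hann window is available for leakage-critical
#' uses (the Parseval identity then holds for the windowed series).
#'
#' @param x numeric series, length >= 16.
#' @param fs sampling rate in Hz.
#' @param window `"rectangular"` or `"hann"`.
#' @return list with `freq` (Hz) and `power`.
#' @export
psd <- function(x, fs, window = c("rectangular", "hann")) {
  window <- match.arg(window)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 16) stop("psd needs at least 16 samples")
  xc <- x - mean(x)
  if (window == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
    xc <- xc * w / sqrt(mean(w^2))
  }
  X <- stats::fft(xc)
  nh <- n %/% 2
  p_full <- Mod(X)^2 / n^2
  idx <- seq_len(nh + 1)            # bins 0 .. floor(n/2)
  power <- p_full[idx]
  # fold the negative-frequency half in: double every bin that has a
  # conjugate twin (not DC; not Nyquist when n is even)
  interior <- 2:(nh + 1 - (n %% 2 == 0))
  power[interior] <- 2 * power[interior]
  list(freq = (idx - 1) * fs / n, power = power)
}

#' Spectral moment features
#'
#' Discrete-sum realizations of the three spectral integrals over the
#' periodogram: the centroid frequency `FC = sum(f P) / sum(P)`, the mean
#' square frequency `MSF = sum(f^2 P) / sum(P)` and the frequency
#' variance `VF = sum((f - FC)^2 P) / sum(P)`. A zero-power series
#' returns all three as 0 with a `degenerate` flag.
#'
#' @param x numeric series (length >= 16) or a list as returned by [psd()].
#' @param fs sampling rate in Hz (ignored when `x` is already a PSD).
#' @return named numeric vector `FC, MSF, VF` with a `degenerate` attribute.
#' @export
freq_features <- function(x, fs = NULL) {
  sp <- if (is.list(x) && !is.null(x$power)) x else psd(x, fs)
  tot <- sum(sp$power)
  if (tot <= 0) {
    out <- c(FC = 0, MSF = 0, VF = 0)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  fc <- sum(sp$freq * sp$power) / tot
  msf <- sum(sp$freq^2 * sp$power) / tot
  vf <- sum((sp$freq - fc)^2 * sp$power) / tot
  out <- c(FC = fc, MSF = msf, VF = vf)
  attr(out, "degenerate") <- FALSE
  out
}

#' Channel set for one analysis window
#'
#' A named collection of equal-length scalar series sampled at `fs`,
#' typically the left/right ankle forward coordinates, left/right
#' pole-tip vertical coordinates, left/right elbow and knee angle series
#' of one motion cycle, optionally augmented with bilateral difference
#' channels (see [extract_channels()]).
#'
#' @param channels named list of equal-length numeric series.
#' @param fs sampling rate in Hz.
#' @return list of class `channel_set`.
#' @export
channel_set <- function(channels, fs) {
  if (is.null(names(channels)) || any(!nzchar(names(channels)))) {
    stop("channels must be named")
  }
  len <- unique(lengths(channels))
  if (length(len) != 1) stop("all channels must have the same length")
  structure(list(channels = channels, fs = fs, length = len),
            class = "channel_set")
}

#' Build the per-cycle feature vector
#'
#' Concatenates the 13 descriptors of every channel, in the channel
#' set's order, named `<channel>_<descriptor>`. The ordering is frozen by
#' that naming so feature matrices and trained models stay compatible
#' across sessions. 8 channels give a 104-dimensional vector.
#'
#' @param cs a [channel_set()] with channel length >= 16 (spectral
#'   features need resolvable frequencies).
#' @return named numeric feature vector of length `13 * n_channels`.
#' @export
build_feature_vector <- function(cs) {
  stopifnot(inherits(cs, "channel_set"))
  out <- numeric(0)
  for (nm in names(cs$channels)) {
    ch <- cs$channels[[nm]]
    if (length(ch) < 16) {
      stop("feature error: channel '", nm, "' too short (", length(ch),
           " < 16 samples)")
    }
    tf <- time_features(ch)
    ff <- freq_features(ch, cs$fs)
    v <- c(tf, ff)
    names(v) <- paste(nm, c(time_feature_names, freq_feature_names),
                      sep = "_")
    out <- c(out, v)
  }
  out
}

#' Center standardization (z-scoring) of a feature matrix
#'
#' `fit = TRUE` learns per-feature means and standard deviations and
#' returns the standardized matrix with the parameters attached;
#' `fit = FALSE` applies previously learned parameters (pass them as
#' `params`), which is how test data must be standardized to avoid
#' leakage. Zero-variance features map to 0.
#'
#' @param x numeric matrix (rows = cycles, columns = features).
#' @param fit learn parameters from `x`?
#' @param params a `standardizer` object (required when `fit = FALSE`).
#' @return standardized matrix with attribute `standardizer`
#'   (list `mean`, `sd`, class `standardizer`).
#' @export
center_standardize <- function(x, fit = TRUE, params = NULL) {
  x <- as.matrix(x)
  if (fit) {
    if (nrow(x) < 2) stop("fitting a standardizer needs >= 2 rows")
    mu <- colMeans(x)
    sd_ <- apply(x, 2, stats::sd)
    params <- structure(list(mean = mu, sd = sd_), class = "standardizer")
  } else {
    if (!inherits(params, "standardizer")) {
      stop("state error: apply requires a fitted standardizer")
    }
  }
  sd_safe <- ifelse(params$sd > 0, params$sd, 1)
  z <- sweep(sweep(x, 2, params$mean, "-"), 2, sd_safe, "/")
  z[, params$sd == 0] <- 0
  attr(z, "standardizer") <- params
  z
}
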