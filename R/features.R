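#' Canonical EEG frequency bands
#'
#' Clinical band edges in Hz: delta `[0.5, 4)`, theta `[4, 8)`, alpha
#' `[8, 13)`, beta `[13, 30)`, gamma `[30, fs/2)`. The feature extractors use
#' the four-band set alpha, beta, gamma, delta; with 4 Hz high-passed input
#' the delta block effectively captures low-theta content, and a
#' `delta_theta` variant merging the two lowest bands can be requested.
#'
#' @param fs Sampling rate in Hz (caps the gamma band at Nyquist).
#' @param merge_delta_theta If `TRUE`, delta spans `[0.5, 8)`.
#' @return Named list of `c(lower, upper)` intervals.
#' @export
spectral_bands <- function(fs = 128, merge_delta_theta = FALSE) {
  stopifnot(fs > 60)
  b <- list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13),
            beta = c(13, 30), gamma = c(30, fs / 2))
  if (merge_delta_theta) {
    b$delta <- c(0.5, 8)
    b$theta <- NULL
  }
  b
}

#' Welch analysis configuration
#'
#' Segment length defaults to one second of samples (`L = fs`), so each
#' segment covers at least one full period of the lowest analyzed frequency
#' (4 Hz floor); overlap 50%; Hamming taper.
#'
#' @param fs Sampling rate (Hz).
#' @param L Segment length in samples (>= 2).
#' @param overlap_frac Fractional overlap between consecutive segments,
#'   in `[0, 1)`.
#' @param window Taper weights of length `L`; default Hamming.
#' @return List of class `welch_config`.
#' @export
welch_config <- function(fs = 128, L = fs, overlap_frac = 0.5,
                         window = NULL) {
  if (L < 2) stop("L must be >= 2")
  if (overlap_frac < 0 || overlap_frac >= 1) stop("overlap_frac in [0, 1)")
  if (is.null(window)) {
    i <- seq_len(L) - 1
    window <- 0.54 - 0.46 * cos(2 * pi * i / (L - 1))
  }
  if (length(window) != L) stop("window length must equal L")
  nu <- mean(window^2)
  if (nu <= 0) stop("window energy must be positive")
  structure(list(fs = fs, L = L, overlap_frac = overlap_frac,
                 window = window, nu = nu),
            class = "welch_config")
}

## split y into overlapping segments (columns), dropping a ragged tail
.segment <- function(y, L, overlap_frac) {
  step <- max(1L, round(L * (1 - overlap_frac)))
  starts <- seq(1L, length(y) - L + 1L, by = step)
  vapply(starts, function(s) y[s:(s + L - 1L)], numeric(L))
}

#' Welch power spectral density
#'
#' Averaged modified periodogram: the signal is split into overlapping
#' segments of length `L`, each tapered by the window, and the squared DFT
#' magnitudes are summed across segments and normalized by the number of
#' segments `M` and the window energy `nu = mean(window^2)`, then scaled to a
#' one-sided spectral density in units^2/Hz (interior bins carry the factor
#' 2 from folding negative frequencies).
#'
#' @param y Numeric signal of length `T >= L`.
#' @param cfg A `welch_config`.
#' @return List of class `welch_psd`: `s` (density per bin), `freq` (Hz,
#'   `0 .. fs/2`), `n_segments`.
#' @export
welch_psd <- function(y, cfg = welch_config()) {
  L <- cfg$L
  if (length(y) < L) stop("signal shorter than segment length L")
  V <- .segment(y, L, cfg$overlap_frac)
  M <- ncol(V)
  Vw <- V * cfg$window
  n_keep <- floor(L / 2) + 1
  U <- stats::mvfft(Vw)
  u <- rowSums(Mod(U[seq_len(n_keep), , drop = FALSE])^2)
  s <- u / (M * cfg$nu * L * cfg$fs)
  one_sided <- rep(2, n_keep)
  one_sided[1] <- 1
  if (L %% 2 == 0) one_sided[n_keep] <- 1
  s <- s * one_sided
  structure(list(s = s, freq = (seq_len(n_keep) - 1) * cfg$fs / L,
                 n_segments = M),
            class = "welch_psd")
}

.band_stats <- function(x, prefix, band) {
  stats_v <- c(max(x), mean(x), stats::var(x))
  if (length(x) == 1) stats_v[3] <- 0
  names(stats_v) <- paste(prefix, band, c("max", "mean", "var"), sep = "_")
  stats_v
}

#' PSD band statistics
#'
#' For each of the alpha, beta, gamma and delta bands (in that order):
#' maximum, mean and variance of the PSD bins whose frequency lies in the
#' band, giving 12 values.
#'
#' @param psd A `welch_psd` (or list with `s` and `freq`).
#' @param bands Band list from [spectral_bands()].
#' @return Named numeric vector of length 12.
#' @export
psd_band_features <- function(psd, bands = spectral_bands()) {
  out <- numeric(0)
  for (b in c("alpha", "beta", "gamma", "delta")) {
    rng <- bands[[b]]
    sel <- psd$freq >= rng[1] & psd$freq < rng[2]
    if (!any(sel)) stop("no PSD bins fall in band ", b)
    out <- c(out, .band_stats(psd$s[sel], "psd", b))
  }
  out
}

## Hjorth parameters of one segment; derivative = first difference * fs
.hjorth_one <- function(v, fs) {
  act <- stats::var(v)
  d1 <- diff(v) * fs
  d2 <- diff(d1) * fs
  mob <- sqrt(stats::var(d1) / act)
  mob_d <- sqrt(stats::var(d2) / stats::var(d1))
  c(activity = act, mobility = mob, complexity = mob_d / mob)
}

#' Hjorth parameters over short-time segments
#'
#' Computes activity (variance), mobility (root ratio of derivative variance
#' to signal variance, a dominant-frequency proxy in rad/s) and complexity
#' (mobility of the derivative over mobility of the signal, a bandwidth
#' proxy) on each short-time segment, using the same segmentation as the
#' Welch analysis but without the taper, then summarizes each parameter by
#' max, mean and variance across segments: 9 values. Segments with zero
#' variance are dropped with a warning; derivative = first difference
#' scaled by `fs`.
#'
#' @param y Numeric signal.
#' @param cfg A `welch_config` (supplies `fs`, `L`, overlap).
#' @return Named numeric vector of length 9 (activity, mobility, complexity
#'   blocks, each max/mean/var).
#' @export
hjorth_features <- function(y, cfg = welch_config()) {
  if (length(y) < cfg$L) stop("signal shorter than segment length L")
  V <- .segment(y, cfg$L, cfg$overlap_frac)
  vars <- apply(V, 2, stats::var)
  keep <- vars > 0
  if (!any(keep)) stop("all segments are constant; Hjorth undefined")
  if (!all(keep)) {
    warning(sum(!keep), " constant segment(s) dropped in Hjorth analysis")
    V <- V[, keep, drop = FALSE]
  }
  H <- apply(V, 2, .hjorth_one, fs = cfg$fs)  # 3 x M
  out <- numeric(0)
  for (p in c("activity", "mobility", "complexity")) {
    out <- c(out, .band_stats(H[p, ], "hjorth", p))
  }
  out
}

#' Wavelet analysis configuration
#'
#' Complex Morlet continuous transform evaluated at fixed center frequencies
#' (2 Hz for the delta band, 10 Hz alpha, 20 Hz beta, 50 Hz gamma) with
#' `eta` cycles per wavelet, plus a Daubechies db4 discrete transform whose
#' dyadic detail levels are mapped to the bands.
#'
#' @param fs Sampling rate (Hz).
#' @param cwt_centers_hz Named centers; defaults `alpha = 10, beta = 20,
#'   gamma = 50, delta = 2`. Centers at or above Nyquist are dropped with a
#'   warning.
#' @param eta Morlet width in cycles (default 6).
#' @param dwt_levels Decomposition depth (default 6).
#' @param level_band_map Named list band -> detail levels; default derived
#'   from `fs` by assigning each dyadic detail band
#'   `[fs/2^(j+1), fs/2^j)` to the named band containing its geometric
#'   center, with all levels centered below 4 Hz aggregated into delta.
#' @return List of class `wavelet_config`.
#' @export
wavelet_config <- function(fs = 128,
                           cwt_centers_hz = c(alpha = 10, beta = 20,
                                              gamma = 50, delta = 2),
                           eta = 6, dwt_levels = 6, level_band_map = NULL) {
  drop <- cwt_centers_hz >= fs / 2
  if (any(drop)) {
    warning("dropping CWT centers at/above Nyquist: ",
            paste(names(cwt_centers_hz)[drop], collapse = ", "))
    cwt_centers_hz <- cwt_centers_hz[!drop]
  }
  if (dwt_levels < 1) stop("dwt_levels must be >= 1")
  if (is.null(level_band_map)) {
    bands <- spectral_bands(fs)
    level_band_map <- list(alpha = integer(0), beta = integer(0),
                           gamma = integer(0), delta = integer(0))
    for (j in seq_len(dwt_levels)) {
      ctr <- sqrt((fs / 2^(j + 1)) * (fs / 2^j))  # geometric center
      band <- if (ctr < 4) "delta"
        else if (ctr < 8) "theta"
        else names(which(vapply(bands[c("alpha", "beta", "gamma")],
                                function(r) ctr >= r[1] && ctr < r[2],
                                logical(1))))[1]
      if (!is.na(band) && band %in% names(level_band_map)) {
        level_band_map[[band]] <- c(level_band_map[[band]], j)
      }
    }
  }
  structure(list(fs = fs, cwt_centers_hz = cwt_centers_hz, eta = eta,
                 dwt_levels = dwt_levels, level_band_map = level_band_map),
            class = "wavelet_config")
}

## complex Morlet kernel at center frequency f0 (Hz); unit response to a
## unit-amplitude sinusoid at f0
.morlet_kernel <- function(f0, fs, eta) {
  sigma_t <- eta / (2 * pi * f0)
  K <- ceiling(4 * sigma_t * fs)
  tk <- (-K:K) / fs
  env <- exp(-tk^2 / (2 * sigma_t^2))
  kern <- env * exp(1i * 2 * pi * f0 * tk)
  kern / (sum(env) / 2)
}

## linear convolution via FFT, central ("same") part
.conv_same <- function(z, kern) {
  n <- length(z); m <- length(kern)
  nfft <- stats::nextn(n + m - 1, 2)
  full <- stats::fft(stats::fft(c(z, rep(0, nfft - n))) *
                     stats::fft(c(kern, rep(0, nfft - m))),
                     inverse = TRUE) / nfft
  half <- (m - 1) / 2
  full[(half + 1):(half + n)]
}

#' Continuous wavelet amplitude features
#'
#' Convolves the signal with complex Morlet wavelets centered at the
#' configured band frequencies and summarizes the instantaneous amplitude
#' `|CWT|` of each center by max, mean and variance, in band order alpha,
#' beta, gamma, delta: 12 values. A center dropped at configuration time
#' (at/above Nyquist) yields `NA` features.
#'
#' @param z Numeric signal.
#' @param cfg A `wavelet_config`.
#' @return Named numeric vector of length 12.
#' @export
cwt_features <- function(z, cfg = wavelet_config()) {
  out <- numeric(0)
  for (b in c("alpha", "beta", "gamma", "delta")) {
    if (!b %in% names(cfg$cwt_centers_hz)) {
      nav <- rep(NA_real_, 3)
      names(nav) <- paste("cwt", b, c("max", "mean", "var"), sep = "_")
      out <- c(out, nav)
      next
    }
    kern <- .morlet_kernel(cfg$cwt_centers_hz[[b]], cfg$fs, cfg$eta)
    amp <- Mod(.conv_same(as.complex(z), kern))
    out <- c(out, .band_stats(amp, "cwt", b))
  }
  out
}

## Daubechies db4 (8-tap) analysis lowpass filter
.db4_lo <- c(0.23037781330885523, 0.7148465705525415, 0.6308807679295904,
             -0.02798376941698385, -0.18703481171888114,
             0.030841381835986965, 0.032883011666982945,
             -0.010597401784997278)

## one level of the periodic decimated DWT: returns approx and detail
.dwt_step <- function(a) {
  h <- .db4_lo
  g <- rev(h) * (-1)^(seq_along(h) - 1)  # quadrature mirror highpass
  n <- length(a)
  L <- length(h)
  idx <- outer(seq(1, n, by = 2), 0:(L - 1), `+`)
  idx <- ((idx - 1) %% n) + 1
  A <- matrix(a[idx], ncol = L)
  list(approx = as.numeric(A %*% h), detail = as.numeric(A %*% g))
}

## periodic fold of a filter into length n
.fold <- function(h, n) {
  out <- numeric(n)
  for (l in seq_along(h)) {
    j <- ((l - 1) %% n) + 1
    out[j] <- out[j] + h[l]
  }
  out
}

## inverse of .dwt_step (periodic adjoint, via circular convolution)
.idwt_step <- function(approx, detail) {
  h <- .db4_lo
  g <- rev(h) * (-1)^(seq_along(h) - 1)
  n2 <- length(approx) * 2
  ua <- numeric(n2); ud <- numeric(n2)
  ua[seq(1, n2, by = 2)] <- approx
  ud[seq(1, n2, by = 2)] <- detail
  spec <- stats::fft(ua) * stats::fft(.fold(h, n2)) +
          stats::fft(ud) * stats::fft(.fold(g, n2))
  Re(stats::fft(spec, inverse = TRUE)) / n2
}

#' Discrete wavelet decomposition (periodic db4)
#'
#' Multilevel decimated discrete wavelet transform with Daubechies db4
#' filters and periodic boundary handling, plus the reconstructed detail
#' signal at each level (the contribution of that level alone, upsampled back
#' to full length). The reconstruction is perfect: the detail signals plus
#' the final approximation sum back to the input.
#'
#' @param z Signal whose length is divisible by `2^levels`.
#' @param levels Decomposition depth.
#' @return List: `details` (list of full-length detail signals, level 1 =
#'   finest), `approx` (full-length final approximation signal),
#'   `coefficients` (per-level detail coefficients).
#' @export
dwt_decompose <- function(z, levels) {
  n <- length(z)
  if (n < 2^levels || n %% 2^levels != 0) {
    stop("signal length must be a multiple of 2^levels (got ", n, ")")
  }
  coeffs <- vector("list", levels)
  a <- z
  for (j in seq_len(levels)) {
    st <- .dwt_step(a)
    coeffs[[j]] <- st$detail
    a <- st$approx
  }
  upsample <- function(vec, from_level, with_detail = NULL) {
    # reconstruct a signal that has `vec` at level `from_level` and zeros
    # elsewhere
    cur <- vec
    for (j in rev(seq_len(from_level))) {
      if (j == from_level && !is.null(with_detail)) {
        cur <- .idwt_step(numeric(length(vec)), with_detail)
      } else {
        cur <- .idwt_step(cur, numeric(length(cur)))
      }
    }
    cur
  }
  details <- lapply(seq_len(levels), function(j) {
    upsample(coeffs[[j]], j, with_detail = coeffs[[j]])
  })
  approx_sig <- {
    cur <- a
    for (j in rev(seq_len(levels))) cur <- .idwt_step(cur, numeric(length(cur)))
    cur
  }
  list(details = details, approx = approx_sig, coefficients = coeffs)
}

#' Discrete wavelet band features
#'
#' Runs the db4 multilevel transform, maps detail levels to the alpha, beta,
#' gamma and delta bands (at `fs = 128`: level 1 -> gamma 32-64 Hz, level 2
#' -> beta 16-32 Hz, level 3 -> alpha 8-16 Hz, levels with centers below
#' 4 Hz aggregated -> delta), sums the detail signals mapped to each band,
#' and summarizes `|b_j|` by max, mean and variance per band: 12 values.
#'
#' @param z Signal; length must be a multiple of `2^dwt_levels`.
#' @param cfg A `wavelet_config`.
#' @return Named numeric vector of length 12.
#' @export
dwt_features <- function(z, cfg = wavelet_config()) {
  dec <- dwt_decompose(z, cfg$dwt_levels)
  out <- numeric(0)
  for (b in c("alpha", "beta", "gamma", "delta")) {
    lv <- cfg$level_band_map[[b]]
    if (length(lv) == 0) {
      nav <- rep(NA_real_, 3)
      names(nav) <- paste("dwt", b, c("max", "mean", "var"), sep = "_")
      out <- c(out, nav)
      next
    }
    sig <- Reduce(`+`, dec$details[lv])
    out <- c(out, .band_stats(abs(sig), "dwt", b))
  }
  out
}

#' Full 45-statistic feature vector for one signal
#'
#' Concatenates the four feature families in fixed order: PSD band statistics
#' (12), Hjorth parameters (9), continuous wavelet amplitudes (12) and
#' discrete wavelet amplitudes (12) - exactly 45 named values per signal.
#'
#' @param y Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param welch A `welch_config`; default `welch_config(fs)`.
#' @param wavelet A `wavelet_config`; default `wavelet_config(fs)`.
#' @param bands Band list; default `spectral_bands(fs)`.
#' @return Named numeric vector of length 45.
#' @export
extract_signal_features <- function(y, fs = 128, welch = welch_config(fs),
                                    wavelet = wavelet_config(fs),
                                    bands = spectral_bands(fs)) {
  run <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("feature stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  psd <- run("welch_psd", welch_psd(y, welch))
  out <- c(
    run("psd_band_features", psd_band_features(psd, bands)),
    run("hjorth_features", hjorth_features(y, welch)),
    run("cwt_features", cwt_features(y, wavelet)),
    run("dwt_features", dwt_features(y, wavelet))
  )
  stopifnot(length(out) == 45)
  out
}

#' Trial-by-feature matrix
#'
#' Builds the classification input: one row per trial, columns are the
#' concatenation over signals (channels or ROIs) of the 45 per-signal
#' features, named `signal::feature`.
#'
#' @param trials List of signal-by-time matrices, one per trial; all trials
#'   must have the same number of signals.
#' @param fs Sampling rate (Hz).
#' @param signal_names Optional character vector naming the signals; defaults
#'   to the row names of the first trial or `s01, s02, ...`.
#' @param ... Passed to [extract_signal_features()].
#' @return N_tr x (n_signals * 45) numeric matrix with unique column names.
#' @export
build_feature_matrix <- function(trials, fs = 128, signal_names = NULL, ...) {
  n_sig <- vapply(trials, nrow, integer(1))
  if (length(unique(n_sig)) != 1) {
    stop("all trials must have the same signal count (got ",
         paste(unique(n_sig), collapse = ", "), ")")
  }
  if (is.null(signal_names)) {
    signal_names <- rownames(trials[[1]])
    if (is.null(signal_names)) {
      signal_names <- sprintf("s%02d", seq_len(n_sig[1]))
    }
  }
  rows <- lapply(trials, function(tr) {
    fv <- lapply(seq_len(nrow(tr)), function(i) {
      v <- extract_signal_features(tr[i, ], fs = fs, ...)
      names(v) <- paste(signal_names[i], names(v), sep = "::")
      v
    })
    unlist(fv)
  })
  Xi <- do.call(rbind, rows)
  rownames(Xi) <- sprintf("trial%03d", seq_along(trials))
  if (anyDuplicated(colnames(Xi))) stop("internal error: duplicate columns")
  Xi
}
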