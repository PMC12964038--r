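#' Cross-spectral density container
#'
#' Holds a complex cross-spectral density over a frequency grid. Values are a
#' \code{n_freq x N x N} complex array; each frequency slice is Hermitian with
#' real non-negative diagonal. The density convention is two-sided and in
#' units of signal-variance per Hz, so integrating a diagonal entry over
#' (-Nyquist, Nyquist) recovers the channel variance.
#'
#' @param freqs strictly increasing frequency vector in Hz.
#' @param values complex array \code{length(freqs) x N x N}.
#' @param labels optional channel names.
#' @param validate check the Hermitian/diagonal invariants.
#' @return object of class \code{cross_spectrum}.
#' @export
cross_spectrum <- function(freqs, values, labels = NULL, validate = TRUE) {
  stopifnot(is.numeric(freqs), all(diff(freqs) > 0))
  dims <- dim(values)
  stopifnot(length(dims) == 3, dims[1] == length(freqs), dims[2] == dims[3])
  n <- dims[2]
  if (is.null(labels)) labels <- paste0("R", seq_len(n))
  obj <- structure(list(freqs = freqs, values = values, labels = labels),
                   class = "cross_spectrum")
  if (validate) {
    stopifnot(is_hermitian_csd(obj))
  }
  obj
}

#' @rdname cross_spectrum
#' @param x a \code{cross_spectrum}.
#' @param tol numerical tolerance.
#' @export
is_hermitian_csd <- function(x, tol = 1e-8) {
  scale <- max(Mod(x$values), 1e-12)
  for (k in seq_along(x$freqs)) {
    S <- x$values[k, , , drop = TRUE]
    S <- matrix(S, dim(x$values)[2])
    if (max(Mod(S - Conj(t(S)))) > tol * scale) return(FALSE)
    d <- diag(S)
    if (any(abs(Im(d)) > tol * scale) || any(Re(d) < -tol * scale)) {
      return(FALSE)
    }
  }
  TRUE
}

#' @export
print.cross_spectrum <- function(x, ...) {
  cat("Cross-spectral density: ", length(x$labels), " channels, ",
      length(x$freqs), " frequencies (",
      signif(min(x$freqs), 3), "-", signif(max(x$freqs), 3), " Hz)\n",
      sep = "")
  invisible(x)
}

#' Fit a multivariate autoregressive (MAR) model by least squares
#'
#' Columns are de-meaned and linearly detrended, then a VAR(p) is estimated by
#' ordinary least squares. The innovation covariance is the residual
#' covariance with degrees-of-freedom correction. The fitted model is flagged
#' (not rejected) if its companion matrix is non-stationary.
#'
#' @param bold time-by-regions numeric matrix.
#' @param order MAR order p (default 8).
#' @param tr sampling interval in seconds.
#' @return object of class \code{mar_model} with fields \code{coeffs} (list of
#'   p N-by-N matrices, entry (i,j) = effect of channel j on channel i),
#'   \code{innovation_cov}, \code{order}, \code{sample_interval},
#'   \code{stationary}.
#' @export
fit_mar <- function(bold, order = 8, tr = 1) {
  bold <- as.matrix(bold)
  n <- ncol(bold)
  T_len <- nrow(bold)
  p <- as.integer(order)
  stopifnot(p >= 1, T_len > p * n + n)
  time_idx <- seq_len(T_len)
  Yd <- apply(bold, 2, function(y) stats::lsfit(time_idx, y)$residuals)
  Y <- Yd[(p + 1):T_len, , drop = FALSE]
  X <- do.call(cbind, lapply(seq_len(p), function(k) {
    Yd[(p + 1 - k):(T_len - k), , drop = FALSE]
  }))
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    bad <- setdiff(seq_len(ncol(X)), qr_X$pivot[seq_len(qr_X$rank)])
    stop("fit_mar: rank-deficient lag regression (columns ",
         paste(bad, collapse = ", "), ")")
  }
  B <- qr.coef(qr_X, Y)                       # (n*p) x n
  resid <- Y - X %*% B
  dof <- nrow(Y) - ncol(X)
  sigma <- symm(crossprod(resid) / dof)
  coeffs <- lapply(seq_len(p), function(k) {
    t(B[((k - 1) * n + 1):(k * n), , drop = FALSE])
  })
  # companion-matrix stationarity check
  comp <- matrix(0, n * p, n * p)
  for (k in seq_len(p)) comp[1:n, ((k - 1) * n + 1):(k * n)] <- coeffs[[k]]
  if (p > 1) {
    comp[(n + 1):(n * p), 1:(n * (p - 1))] <- diag(n * (p - 1))
  }
  rho <- max(Mod(eigen(comp, only.values = TRUE)$values))
  if (rho >= 1) warning("fit_mar: fitted MAR model is non-stationary")
  structure(
    list(order = p, coeffs = coeffs, innovation_cov = sigma,
         sample_interval = tr, stationary = rho < 1,
         labels = colnames(bold) %||% paste0("R", seq_len(n))),
    class = "mar_model"
  )
}

#' @export
print.mar_model <- function(x, ...) {
  cat("MAR(", x$order, ") model, ", nrow(x$innovation_cov), " channels, ",
      "sample interval ", x$sample_interval, " s",
      if (!x$stationary) " [non-stationary]", "\n", sep = "")
  invisible(x)
}

#' Cross-spectral density of a fitted MAR model
#'
#' Evaluates \eqn{S(f) = \Delta H(f) \Sigma H(f)^\dagger} with transfer
#' function \eqn{H(f) = (I - \sum_k A_k e^{-i 2\pi f k \Delta})^{-1}}, where
#' \eqn{\Delta} is the sample interval. Hermitian by construction.
#'
#' @param mar a \code{mar_model}.
#' @param freqs frequency grid in Hz, strictly below Nyquist.
#' @return a \code{cross_spectrum}.
#' @export
mar_to_csd <- function(mar, freqs) {
  stopifnot(inherits(mar, "mar_model"))
  delta <- mar$sample_interval
  nyq <- 1 / (2 * delta)
  stopifnot(all(freqs > 0), all(freqs < nyq))
  n <- nrow(mar$innovation_cov)
  vals <- array(complex(real = 0), c(length(freqs), n, n))
  I_n <- diag(n)
  for (fi in seq_along(freqs)) {
    M <- I_n
    for (k in seq_len(mar$order)) {
      M <- M - mar$coeffs[[k]] * exp(-2i * pi * freqs[fi] * k * delta)
    }
    H <- tryCatch(solve(M), error = function(e) {
      stop("mar_to_csd: singular transfer function at f = ", freqs[fi],
           " Hz")
    })
    S <- delta * H %*% mar$innovation_cov %*% Conj(t(H))
    vals[fi, , ] <- (S + Conj(t(S))) / 2
  }
  cross_spectrum(freqs, vals, mar$labels)
}

#' Welch averaged-periodogram cross-spectral estimate
#'
#' Nonparametric cross-spectral density via Hann-windowed overlapping
#' segments, on the same two-sided density convention as [mar_to_csd()]. It
#' serves as the model-free counterpart of the MAR-based estimate.
#'
#' @param bold time-by-regions matrix.
#' @param tr sample interval in seconds.
#' @param window segment length in seconds.
#' @param overlap segment overlap fraction in [0, 1).
#' @return a \code{cross_spectrum} on the FFT bin grid (excluding DC and
#'   Nyquist).
#' @export
welch_csd <- function(bold, tr, window, overlap = 0.5) {
  bold <- as.matrix(bold)
  n <- ncol(bold)
  T_len <- nrow(bold)
  L <- floor(window / tr)
  stopifnot(L >= 8, overlap >= 0, overlap < 1)
  step <- max(1, floor(L * (1 - overlap)))
  starts <- seq(1, T_len - L + 1, by = step)
  if (length(starts) < 2) stop("welch_csd: fewer than 2 segments")
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1))   # Hann
  U <- sum(w^2)
  n_freq <- floor((L - 1) / 2)
  freqs <- seq_len(n_freq) / (L * tr)
  acc <- array(complex(real = 0), c(n_freq, n, n))
  bold <- scale(bold, center = TRUE, scale = FALSE)
  for (s in starts) {
    seg <- bold[s:(s + L - 1), , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg))
    Xf <- stats::mvfft(seg * w)[2:(n_freq + 1), , drop = FALSE]
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        acc[, i, j] <- acc[, i, j] + Xf[, i] * Conj(Xf[, j])
      }
    }
  }
  vals <- acc * (tr / (U * length(starts)))
  for (fi in seq_len(n_freq)) {
    S <- matrix(vals[fi, , ], n)
    vals[fi, , ] <- (S + Conj(t(S))) / 2
  }
  cross_spectrum(freqs, vals, colnames(bold) %||% NULL)
}

#' Default analysis frequency grid
#'
#' 32 linearly spaced frequencies from 1/128 Hz to 0.25 Hz, covering the
#' resting-state band below the Nyquist frequency of a 0.961-s repetition
#' time.
#'
#' @param n_freq number of grid points.
#' @param f_min,f_max band edges in Hz.
#' @return numeric vector.
#' @export
default_freq_grid <- function(n_freq = 32, f_min = 1 / 128, f_max = 0.25) {
  seq(f_min, f_max, length.out = n_freq)
}
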