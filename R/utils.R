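# Internal numerical helpers shared across modules.

## log-determinant of a symmetric positive-definite matrix via Cholesky
logdet <- function(M) {
  2 * sum(log(diag(chol(M))))
}

## symmetrise (guards tiny asymmetries from floating point)
symm <- function(M) (M + t(M)) / 2

## largest real part among eigenvalues of a square matrix
max_re_eig <- function(A) max(Re(eigen(A, only.values = TRUE)$values))

## discrete-cosine high-pass basis (SPM convention): columns are the DCT
## regressors with period longer than `cutoff_s`, excluding the constant.
dct_basis <- function(n_frames, tr, cutoff_s = 128) {
  k_max <- floor(2 * n_frames * tr / cutoff_s)
  if (k_max < 1) {
    return(matrix(numeric(0), nrow = n_frames, ncol = 0))
  }
  t_idx <- seq_len(n_frames) - 1
  X <- sapply(seq_len(k_max), function(k) {
    cos(pi * k * (2 * t_idx + 1) / (2 * n_frames))
  })
  matrix(X, nrow = n_frames)
}

## residuals of y after projecting out the column space of X (QR based)
project_out <- function(y, X) {
  if (is.null(X) || ncol(X) == 0) return(y)
  qr_X <- qr(X)
  y - qr.fitted(qr_X, y)
}

## draw a derived 32-bit seed for a sub-stream, reproducibly
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 2654435 + as.numeric(k) * 97) %%
               2147483647)
}

## band-limited power of a univariate series via the periodogram
band_power <- function(x, dt, f_lo, f_hi) {
  n <- length(x)
  x <- x - mean(x)
  X <- stats::fft(x)
  freqs <- (seq_len(n) - 1) / (n * dt)
  keep <- freqs >= f_lo & freqs <= f_hi
  sum(Mod(X[keep])^2) / n^2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
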