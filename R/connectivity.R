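#' Construct a ground-truth effective-connectivity object
#'
#' The coupling matrix of the neuronal state equation dx/dt = A x + v is split
#' into off-diagonal couplings (Hz) and unitless self-connection log-scalings:
#' the effective matrix has \code{A[i,j] = theta_offdiag[i,j]} for i != j and
#' \code{A[i,i] = -0.5 * exp(theta_self[i])}, so self-connections are
#' inhibitory by construction. Throughout the package, entry (i, j) is the
#' influence of region j (source, column) on region i (target, row).
#'
#' @param theta_offdiag square numeric matrix of couplings in Hz; the diagonal
#'   is ignored.
#' @param theta_self numeric vector of self-connection log-scalings (unitless),
#'   one per region; 0 maps to the nominal -0.5 Hz self-decay.
#' @param labels optional character vector of region names.
#' @return an object of class \code{dcm_connectivity}.
#' @seealso [effective_matrix()], [make_connectivity()]
#' @export
dcm_connectivity <- function(theta_offdiag, theta_self = NULL,
                             labels = NULL) {
  theta_offdiag <- as.matrix(theta_offdiag)
  n <- nrow(theta_offdiag)
  stopifnot(ncol(theta_offdiag) == n)
  if (is.null(theta_self)) theta_self <- numeric(n)
  stopifnot(length(theta_self) == n, all(is.finite(theta_offdiag)),
            all(is.finite(theta_self)))
  if (is.null(labels)) labels <- paste0("R", seq_len(n))
  stopifnot(length(labels) == n)
  diag(theta_offdiag) <- 0
  dimnames(theta_offdiag) <- list(labels, labels)
  structure(
    list(theta_offdiag = theta_offdiag,
         theta_self = stats::setNames(as.numeric(theta_self), labels),
         labels = labels),
    class = "dcm_connectivity"
  )
}

#' Effective coupling matrix in Hz
#'
#' Assembles the matrix A with off-diagonal couplings as given and diagonal
#' \code{-0.5 * exp(theta_self)}.
#'
#' @param conn a \code{dcm_connectivity} object.
#' @return numeric matrix (Hz) with strictly negative diagonal.
#' @export
effective_matrix <- function(conn) {
  stopifnot(inherits(conn, "dcm_connectivity"))
  A <- conn$theta_offdiag
  diag(A) <- -0.5 * exp(conn$theta_self)
  A
}

#' Test dynamical stability of a coupling matrix
#'
#' @param A square numeric matrix.
#' @param margin stability margin; all eigenvalue real parts must be below
#'   \code{-margin}.
#' @return logical.
#' @export
is_stable <- function(A, margin = 0) {
  max_re_eig(A) < -margin
}

#' Draw a random stable fully-connected coupling matrix
#'
#' Off-diagonal couplings are drawn i.i.d. from N(0, coupling_sd^2); the
#' self-connection log-scalings start at 0 (diagonal -0.5 Hz). Draws are
#' rejection-resampled until the effective matrix is stable (all eigenvalues
#' with negative real part).
#'
#' @param n_regions number of network nodes (>= 2); the central autonomic
#'   network model uses 6.
#' @param coupling_sd spread of off-diagonal couplings in Hz.
#' @param seed integer RNG seed; a fixed seed gives a deterministic matrix.
#' @param labels optional region names.
#' @param max_attempts resampling budget before giving up.
#' @return a \code{dcm_connectivity} object whose effective matrix is stable.
#' @export
make_connectivity <- function(n_regions, coupling_sd = 0.2, seed = 1,
                              labels = NULL, max_attempts = 100) {
  stopifnot(n_regions >= 2, coupling_sd >= 0)
  rng <- local({
    set.seed(seed)
    NULL
  })
  for (attempt in seq_len(max_attempts)) {
    theta <- matrix(stats::rnorm(n_regions^2, 0, coupling_sd), n_regions)
    diag(theta) <- 0
    conn <- dcm_connectivity(theta, numeric(n_regions), labels)
    if (is_stable(effective_matrix(conn))) return(conn)
  }
  stop("make_connectivity: no stable matrix in ", max_attempts,
       " draws; coupling_sd = ", coupling_sd, " is too large for n = ",
       n_regions)
}

#' @export
print.dcm_connectivity <- function(x, ...) {
  cat("Effective connectivity (", length(x$labels), " regions)\n", sep = "")
  cat("Couplings in Hz; diagonal = -0.5*exp(theta_self); row = target,",
      "column = source\n")
  print(round(effective_matrix(x), 3))
  invisible(x)
}

## Perturb a base connectivity by additive off-diagonal effects, resampling the
## perturbation noise until the effective matrix stays stable.
perturb_connectivity <- function(base, delta_offdiag, noise_sd = 0,
                                 max_attempts = 100) {
  stopifnot(inherits(base, "dcm_connectivity"))
  n <- length(base$labels)
  for (attempt in seq_len(max_attempts)) {
    noise <- if (noise_sd > 0) {
      matrix(stats::rnorm(n^2, 0, noise_sd), n)
    } else {
      matrix(0, n, n)
    }
    diag(noise) <- 0
    theta <- base$theta_offdiag + delta_offdiag + noise
    conn <- dcm_connectivity(theta, base$theta_self, base$labels)
    if (is_stable(effective_matrix(conn))) {
      attr(conn, "noise") <- noise
      return(conn)
    }
  }
  stop("perturb_connectivity: perturbed matrix never stable after ",
       max_attempts, " resamples")
}
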