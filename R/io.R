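#' Read and write region-by-time BOLD tables
#'
#' Tab-separated, one column per region with region labels as header, one
#' row per frame. Round-trips exactly at full double precision.
#'
#' @param bold time-by-regions matrix with column names.
#' @param path file path.
#' @return \code{read_bold_tsv}: numeric matrix with region labels as column
#'   names.
#' @export
write_bold_tsv <- function(bold, path) {
  bold <- as.matrix(bold)
  if (is.null(colnames(bold))) colnames(bold) <- paste0("R", seq_len(ncol(bold)))
  df <- as.data.frame(bold)
  df[] <- lapply(df, function(v) sprintf("%.17g", v))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bold_tsv
#' @export
read_bold_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "numeric")
  if (ncol(df) < 1 || nrow(df) < 1) {
    stop("read_bold_tsv: ", path, " is empty or malformed")
  }
  as.matrix(df)
}

#' Read and write participant covariate tables
#'
#' CSV with columns \code{id}, \code{group}, \code{hr_bpm} (missing heart
#' rates allowed and flagged). Subjects with missing covariates are reported
#' so they can be dropped from covariate analyses downstream.
#'
#' @param participants data frame.
#' @param path file path.
#' @return \code{read_participants}: the data frame, with attribute
#'   \code{missing_hr} listing subject ids lacking a heart rate.
#' @export
write_participants <- function(participants, path) {
  utils::write.csv(participants, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_participants
#' @export
read_participants <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "group")
  if (!all(need %in% names(df))) {
    stop("read_participants: ", path, " must have columns id, group")
  }
  if (!"hr_bpm" %in% names(df)) df$hr_bpm <- NA_real_
  missing_hr <- df$id[!is.finite(df$hr_bpm)]
  attr(df, "missing_hr") <- missing_hr
  df
}

#' Write / read a subject posterior as JSON
#'
#' Serializes the posterior expectations (named by \code{source->target} for
#' couplings), the flattened posterior covariance, free energy, explained
#' variance and convergence metadata.
#'
#' @param fit an \code{spdcm_posterior}.
#' @param path file path.
#' @return \code{read_posterior_json}: a list with the same fields, Cp
#'   restored to a matrix. Numeric content round-trips to full precision.
#' @export
write_posterior_json <- function(fit, path) {
  out <- list(
    Ep = as.list(fit$Ep),
    Cp = as.numeric(fit$Cp),
    parameter_names = names(fit$Ep),
    free_energy = fit$free_energy,
    explained_variance = fit$explained_variance,
    explained_variance_time = fit$explained_variance_time,
    converged = fit$converged,
    n_iter = fit$n_iter,
    scale = fit$scale,
    labels = fit$priors$labels
  )
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_posterior_json
#' @export
read_posterior_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- length(x$parameter_names)
  x$Ep <- stats::setNames(as.numeric(x$Ep), x$parameter_names)
  x$Cp <- matrix(x$Cp, p, p,
                 dimnames = list(x$parameter_names, x$parameter_names))
  x
}

#' Write / read a thresholded connectivity matrix as TSV
#'
#' Below-threshold entries are written as empty cells and restored as
#' \code{NA} (never 0) on re-read.
#'
#' @param mat numeric matrix with NA for blanked entries.
#' @param path file path.
#' @return \code{read_matrix_tsv}: numeric matrix with NAs preserved.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- as.data.frame(mat)
  df[] <- lapply(df, function(v) ifelse(is.na(v), "", sprintf("%.17g", v)))
  df <- cbind(region = rownames(mat) %||% paste0("R", seq_len(nrow(mat))), df)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  rn <- df[[1]]
  m <- as.matrix(df[, -1, drop = FALSE])
  m[m == ""] <- NA
  storage.mode(m) <- "double"
  rownames(m) <- rn
  m
}

#' The six central-autonomic-network volumes of interest
#'
#' Sphere definitions (MNI mm center and radius) of the left-lateralized
#' 6-node network: ventromedial prefrontal cortex, anterior cingulate,
#' anterior insula, amygdala, hypothalamus, and brainstem (nucleus of the
#' solitary tract).
#'
#' @return data.frame with columns label, x, y, z (mm), radius (mm).
#' @export
can_atlas <- function() {
  data.frame(
    label = c("vmPFC", "ACC", "INS", "AMY", "HYPO", "BS"),
    x = c(0, 0, -41, -24, -2, -3),
    y = c(44, 47, 3, -4, -4, -43),
    z = c(-14, 11, 6, -18, -10, -55),
    radius = c(8, 8, 8, 5, 5, 3),
    stringsAsFactors = FALSE
  )
}

#' Extract a volume-of-interest time series from a 4D image
#'
#' Voxels whose world-space (mm) center lies within \code{radius} of the
#' sphere center (inclusive) are summarized per frame, either by their mean
#' or by the first principal component scaled to the mean voxel amplitude
#' (eigenvariate).
#'
#' @param img4d 4D numeric array (x, y, z, time).
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices).
#' @param center length-3 world coordinate (mm).
#' @param radius sphere radius (mm).
#' @param summary "mean" or "eigenvariate".
#' @return numeric time series with attribute \code{n_voxels}.
#' @export
extract_voi <- function(img4d, affine, center, radius,
                        summary = c("mean", "eigenvariate")) {
  summary <- match.arg(summary)
  stopifnot(length(dim(img4d)) == 4, all(dim(affine) == c(4, 4)),
            length(center) == 3, radius > 0)
  dims <- dim(img4d)[1:3]
  vox <- as.matrix(expand.grid(i = seq_len(dims[1]) - 1,
                               j = seq_len(dims[2]) - 1,
                               k = seq_len(dims[3]) - 1))
  world <- t(affine %*% rbind(t(vox), 1))[, 1:3, drop = FALSE]
  d2 <- rowSums(sweep(world, 2, center)^2)
  inside <- which(d2 <= radius^2)
  if (length(inside) == 0) {
    stop("extract_voi: sphere at (", paste(center, collapse = ", "),
         ") radius ", radius, " mm contains 0 voxels")
  }
  n_t <- dim(img4d)[4]
  mat <- matrix(img4d, prod(dims), n_t)[inside, , drop = FALSE]
  out <- if (summary == "mean" || length(inside) == 1) {
    colMeans(mat)
  } else {
    centered <- mat - rowMeans(mat)
    sv <- svd(t(centered), nu = 1, nv = 0)
    pc <- sv$u[, 1] * sv$d[1] / sqrt(nrow(mat))
    # orient with the mean signal and restore mean amplitude
    ms <- colMeans(mat)
    if (stats::sd(ms) > 0 && stats::cor(pc, ms) < 0) pc <- -pc
    pc + mean(mat)
  }
  attr(out, "n_voxels") <- length(inside)
  out
}

#' Regress confounds and low-frequency drift out of VOI time series
#'
#' Projects out the supplied confound columns together with a discrete-cosine
#' high-pass basis (cutoff period \code{highpass_s}) and the constant.
#' Residuals are orthogonal to every regressor; applying the operation twice
#' equals applying it once.
#'
#' @param roi time-by-regions matrix.
#' @param confounds optional frame-aligned confound matrix (e.g. 6 motion
#'   parameters, white-matter and CSF signals).
#' @param tr repetition time in seconds.
#' @param highpass_s high-pass cutoff period in seconds.
#' @return residual matrix of the same shape.
#' @export
nuisance_regress <- function(roi, confounds = NULL, tr = 0.961,
                             highpass_s = 128) {
  roi <- as.matrix(roi)
  n_t <- nrow(roi)
  X <- cbind(1, dct_basis(n_t, tr, highpass_s))
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    stopifnot(nrow(confounds) == n_t)
    keep <- apply(confounds, 2, function(v) stats::sd(v) > 0)
    X <- cbind(X, confounds[, keep, drop = FALSE])
    kappa <- kappa(qr.R(qr(scale(X[, -1, drop = FALSE]))))
    if (is.finite(kappa) && kappa > 1e6) {
      warning("nuisance_regress: confounds nearly collinear (condition ",
              "number ", format(kappa, digits = 3), ")")
    }
  }
  out <- apply(roi, 2, function(y) project_out(y, X))
  dimnames(out) <- dimnames(roi)
  out
}
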