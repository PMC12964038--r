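#' Build a second-level design matrix
#'
#' First column is the constant; every following regressor is mean-centered.
#' Group membership is coded +1 for the first (patient) group and -1 for
#' controls before centering; heart rate is centered; the group-by-HR
#' interaction is the elementwise product of the two centered columns,
#' itself re-centered.
#'
#' @param covariates data frame with one row per included subject; columns
#'   \code{id}, \code{group}, and \code{hr_bpm} as needed.
#' @param regressors character subset of \code{c("group", "hr",
#'   "group_x_hr")}; order is preserved.
#' @param patient_label which \code{group} level is coded +1 (default: the
#'   first level encountered).
#' @return matrix of class \code{peb_design} with subjects in rows; attribute
#'   \code{raw_coding} keeps the un-centered columns.
#' @export
build_design <- function(covariates, regressors = character(0),
                         patient_label = NULL) {
  stopifnot(is.data.frame(covariates), nrow(covariates) >= 1)
  n <- nrow(covariates)
  X <- matrix(1, n, 1)
  names_x <- "mean"
  raw <- list()
  for (r in regressors) {
    col <- switch(
      r,
      group = {
        stopifnot("group" %in% names(covariates))
        if (is.null(patient_label)) patient_label <- covariates$group[1]
        ifelse(covariates$group == patient_label, 1, -1)
      },
      hr = {
        if (!"hr_bpm" %in% names(covariates) ||
            any(!is.finite(covariates$hr_bpm))) {
          bad <- covariates$id[!is.finite(covariates$hr_bpm %||% NA)]
          stop("build_design: missing heart rate for subject(s) ",
               paste(bad, collapse = ", "))
        }
        covariates$hr_bpm
      },
      group_x_hr = {
        gc <- X[, match("group", names_x)]
        hc <- X[, match("hr", names_x)]
        if (anyNA(c(gc, hc))) stop("build_design: interaction needs group and hr")
        gc * hc
      },
      stop("build_design: unknown regressor ", r)
    )
    raw[[r]] <- col
    X <- cbind(X, col - mean(col))
    names_x <- c(names_x, r)
  }
  colnames(X) <- names_x
  if (qr(X)$rank < ncol(X)) {
    stop("build_design: design matrix is rank deficient")
  }
  structure(X, raw_coding = raw, class = c("peb_design", "matrix", "array"))
}

## Collate the connectivity sub-vector (couplings + self log-scalings) and
## its covariance from a subject posterior (spdcm_posterior or the list
## restored from JSON).
connectivity_field <- function(post) {
  nm <- names(post$Ep)
  keep <- grepl("->", nm, fixed = TRUE) | startsWith(nm, "self_")
  list(Ep = post$Ep[keep], Cp = post$Cp[keep, keep, drop = FALSE])
}

#' Parametric empirical Bayes over subject posteriors
#'
#' Hierarchical model: each subject's posterior connectivity vector is
#' treated as data for a group-level GLM, theta_i = (x_i' kron I) beta +
#' eps_i. The between-subject covariance of eps is a single scaled
#' component, exp(-gamma) V with V = 1/16 of the first-level prior variance
#' per parameter; the log-scaling gamma is set by maximizing the
#' second-level free energy under a N(0, 1) hyperprior. Subjects enter precision-weighted: a subject
#' with larger posterior covariance moves the group estimate less. The prior
#' on each group-effect coefficient is zero-mean with the first-level prior
#' variance of the corresponding parameter.
#'
#' @param posteriors list of subject posteriors (\code{spdcm_posterior} or
#'   lists from [read_posterior_json()]), one per design row.
#' @param design a \code{peb_design} (or plain matrix, first column
#'   constant).
#' @param field which parameters enter the hierarchy: "connectivity"
#'   (couplings + self, the default) or "couplings" (off-diagonal only).
#' @param prior_var optional named prior variances per parameter; defaults
#'   to the usual shrinkage values (1/64 couplings, 1/256 self).
#' @param gamma_range search interval for the between-subject log-precision.
#' @return object of class \code{peb}: \code{Ep} (regressors-by-parameters
#'   matrix), \code{Cp} (full posterior covariance over vec(beta)),
#'   \code{SD} (posterior standard deviations, same shape as \code{Ep}),
#'   \code{PP} (posterior probabilities from Bayesian model reduction),
#'   \code{free_energy}, \code{gamma}, \code{design}, \code{param_names}.
#' @export
peb_fit <- function(posteriors, design, field = c("connectivity",
                                                  "couplings"),
                    prior_var = NULL, gamma_range = c(-8, 8)) {
  field <- match.arg(field)
  X <- unclass(design)
  n_sub <- length(posteriors)
  stopifnot(nrow(X) == n_sub, n_sub >= 1)
  fields <- lapply(posteriors, connectivity_field)
  pn <- names(fields[[1]]$Ep)
  if (field == "couplings") pn <- pn[grepl("->", pn, fixed = TRUE)]
  P <- length(pn)
  K <- ncol(X)
  theta <- t(vapply(fields, function(f) f$Ep[pn], numeric(P)))
  Cps <- lapply(fields, function(f) f$Cp[pn, pn, drop = FALSE])
  if (is.null(prior_var)) {
    prior_var <- ifelse(grepl("->", pn, fixed = TRUE), 1 / 64, 1 / 256)
    names(prior_var) <- pn
  }
  # second-level prior over vec(beta): per regressor, the first-level prior
  # variance of the corresponding parameter
  Sb <- rep(prior_var[pn], each = K)
  # between-subject covariance: exp(-gamma) times a baseline of 1/16 of the
  # first-level prior variance per parameter
  Vb <- prior_var[pn] / 16

  neg_F <- function(gamma) -peb_free_energy(theta, X, Cps, Sb, gamma, Vb)$F
  opt <- stats::optimize(neg_F, gamma_range)
  gamma <- opt$minimum
  sol <- peb_free_energy(theta, X, Cps, Sb, gamma, Vb)

  Ep <- matrix(sol$m, K, P, dimnames = list(colnames(X), pn))
  SD <- matrix(sqrt(diag(sol$C)), K, P, dimnames = list(colnames(X), pn))
  PP <- matrix(NA_real_, K, P, dimnames = list(colnames(X), pn))
  Pq <- solve(symm(sol$C))
  ld_Pq <- logdet(symm(Pq))
  for (k in seq_len(K)) {
    for (j in seq_len(P)) {
      idx <- (j - 1) * K + k
      PP[k, j] <- bmr_pp(sol$m, Pq, ld_Pq, Sb, idx)
    }
  }
  structure(
    list(Ep = Ep, Cp = sol$C, SD = SD, PP = PP,
         free_energy = sol$F, gamma = gamma,
         design = design, param_names = pn, n_subjects = n_sub,
         labels = attr_labels(posteriors[[1]])),
    class = "peb"
  )
}

attr_labels <- function(post) {
  if (!is.null(post$priors)) return(post$priors$labels)
  post$labels %||% NULL
}

## Second-level free energy and posterior for a given between-subject
## log-precision gamma. beta ordering: vec with parameter-major blocks,
## index (j - 1) * K + k for parameter j, regressor k.
peb_free_energy <- function(theta, X, Cps, Sb, gamma, Vb) {
  n_sub <- nrow(theta)
  P <- ncol(theta)
  K <- ncol(X)
  Pi_beta <- diag(1 / Sb, length(Sb))
  Hmat <- Pi_beta
  gvec <- numeric(length(Sb))
  ll <- 0
  for (i in seq_len(n_sub)) {
    Si <- Cps[[i]] + diag(exp(-gamma) * Vb, P)
    R <- chol(symm(Si))
    wi <- backsolve(R, forwardsolve(t(R), theta[i, ]))
    # X_i kron I_P structure: rows of the big design for subject i
    # contribution to precision: (x_i x_i') kron Si^{-1}, but beta ordering
    # is parameter-major, so blocks are Si^{-1}[j,j'] * x_i x_i'
    Si_inv <- chol2inv(R)
    xxt <- tcrossprod(X[i, ])
    Hmat <- Hmat + kronecker(Si_inv, xxt)
    gvec <- gvec + as.numeric(outer(X[i, ], wi))
    ll <- ll - sum(log(diag(R))) - 0.5 * sum(wi * theta[i, ]) -
      0.5 * P * log(2 * pi)
  }
  C <- solve(symm(Hmat))
  m <- C %*% gvec
  # marginal likelihood with beta integrated out (Gaussian identity)
  F_val <- ll - 0.5 * sum(log(Sb)) - 0.5 * logdet(symm(Hmat)) +
    0.5 * sum(m * gvec) +
    stats::dnorm(gamma, 0, 1, log = TRUE)   # hyperprior on log-precision
  list(F = F_val, m = as.numeric(m), C = symm(C))
}

## Posterior probability that one coefficient is nonzero, by Bayesian model
## reduction: free-energy difference between the full model and the model
## with that coefficient's prior variance collapsed (precision inflated by
## 1e8), mapped through the logistic function.
bmr_pp <- function(m, Pq, ld_Pq, Sb, idx, shrink = 1e8) {
  P0r_d <- 1 / Sb
  P0r_d[idx] <- P0r_d[idx] * shrink
  Pr <- Pq
  diag(Pr) <- diag(Pr) + (P0r_d - 1 / Sb)
  mq <- Pq %*% m
  mr <- solve(Pr, mq)
  dF_reduced <- 0.5 * (sum(mr * (Pr %*% mr)) - sum(m * mq)) +
    0.5 * (ld_Pq - logdet(symm(Pr))) +
    0.5 * sum(log(P0r_d) - log(1 / Sb))
  # dF_reduced = F_reduced - F_full; evidence for the effect is -dF
  1 / (1 + exp(dF_reduced))
}

#' @export
print.peb <- function(x, ...) {
  cat("PEB group model: ", x$n_subjects, " subjects, ",
      nrow(x$Ep), " regressor(s), ", ncol(x$Ep), " parameters\n", sep = "")
  cat(sprintf("  between-subject log-precision %.2f, free energy %.2f\n",
              x$gamma, x$free_energy))
  for (k in seq_len(nrow(x$Ep))) {
    n_rel <- sum(x$PP[k, ] > 0.99)
    cat(sprintf("  %-10s: %d parameter(s) with PP > 0.99\n",
                rownames(x$Ep)[k], n_rel))
  }
  invisible(x)
}

#' @export
summary.peb <- function(object, cutoff = 0.99, ...) {
  print(object)
  for (k in seq_len(nrow(object$Ep))) {
    rel <- which(object$PP[k, ] > cutoff)
    if (length(rel)) {
      cat("\n", rownames(object$Ep)[k], ":\n", sep = "")
      df <- data.frame(parameter = object$param_names[rel],
                       Ep = round(object$Ep[k, rel], 3),
                       SD = round(object$SD[k, rel], 3),
                       PP = round(object$PP[k, rel], 4))
      print(df, row.names = FALSE)
    }
  }
  invisible(object)
}

#' @export
coef.peb <- function(object, ...) object$Ep

#' Posterior probability of one group-level effect
#'
#' @param peb a fitted \code{peb} object.
#' @param regressor regressor name or index.
#' @param parameter parameter name (e.g. \code{"R1->R2"}) or index.
#' @return probability that the effect is nonzero.
#' @export
posterior_probability <- function(peb, regressor, parameter) {
  stopifnot(inherits(peb, "peb"))
  peb$PP[regressor, parameter]
}

#' Threshold a group-effect row into a display matrix
#'
#' Entries whose posterior probability does not exceed the cutoff are
#' blanked (NA). Off-diagonal survivors carry the effect size in Hz;
#' diagonal (self-connection) entries are on the unitless log-scaling scale
#' and are flagged as such.
#'
#' @param peb a fitted \code{peb}.
#' @param regressor regressor name or index.
#' @param cutoff posterior-probability display threshold (strict).
#' @return list of class \code{peb_matrix}: \code{Ep}, \code{SD}, \code{PP}
#'   N-by-N matrices (NA = below threshold), \code{regressor},
#'   \code{cutoff}, \code{diagonal_scale = "log-scaling"}.
#' @export
threshold_matrix <- function(peb, regressor, cutoff = 0.99) {
  stopifnot(inherits(peb, "peb"))
  labels <- peb$labels %||% infer_labels(peb$param_names)
  n <- length(labels)
  Ep <- SD <- PP <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  for (j in seq_along(peb$param_names)) {
    nm <- peb$param_names[j]
    if (grepl("->", nm, fixed = TRUE)) {
      parts <- strsplit(nm, "->", fixed = TRUE)[[1]]
      tgt <- match(parts[2], labels); src <- match(parts[1], labels)
    } else {
      tgt <- src <- match(sub("^self_", "", nm), labels)
    }
    if (peb$PP[regressor, j] > cutoff) {
      Ep[tgt, src] <- peb$Ep[regressor, j]
      SD[tgt, src] <- peb$SD[regressor, j]
      PP[tgt, src] <- peb$PP[regressor, j]
    }
  }
  structure(list(Ep = Ep, SD = SD, PP = PP, regressor = regressor,
                 cutoff = cutoff, diagonal_scale = "log-scaling"),
            class = "peb_matrix")
}

infer_labels <- function(param_names) {
  selfs <- grep("^self_", param_names, value = TRUE)
  sub("^self_", "", selfs)
}

#' @export
print.peb_matrix <- function(x, digits = 2, ...) {
  cat("Thresholded effects (PP > ", x$cutoff, "), regressor: ",
      x$regressor, "\n", sep = "")
  cat("Ep with posterior SD in parentheses; blank = below threshold;\n")
  cat("diagonal on the self-connection log-scaling scale\n")
  n <- nrow(x$Ep)
  disp <- matrix("", n, n, dimnames = dimnames(x$Ep))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (!is.na(x$Ep[i, j])) {
      disp[i, j] <- sprintf("%.*f (%.*f)", digits, x$Ep[i, j], digits,
                            x$SD[i, j])
    }
  }
  print(disp, quote = FALSE)
  invisible(x)
}

#' Run the four-group-analysis suite
#'
#' The complete second level: (1) per-group mean-only models (group
#' commonalities), (2) pooled model with the group regressor (group
#' differences), (3) per-group models with heart rate as the regressor of
#' interest (centered within group), and (4) the pooled model with group,
#' heart rate, and their interaction.
#'
#' @param posteriors named list of subject posteriors.
#' @param covariates data frame (\code{id}, \code{group}, \code{hr_bpm})
#'   aligned with \code{posteriors} by \code{id}.
#' @param patient_label group level coded +1 (default first level in the
#'   table).
#' @param cutoff display threshold on posterior probability.
#' @param hr_centering "within" (default) centers HR within group for the
#'   per-group HR analyses; "grand" centers across all subjects.
#' @return list of class \code{peb_suite} with elements \code{commonalities}
#'   (one \code{peb} per group), \code{group_difference}, \code{hr_within}
#'   (one per group), \code{interaction}, and thresholded display matrices
#'   under \code{matrices}.
#' @export
run_analysis_suite <- function(posteriors, covariates,
                               patient_label = NULL, cutoff = 0.99,
                               hr_centering = c("within", "grand")) {
  hr_centering <- match.arg(hr_centering)
  stopifnot(length(posteriors) == nrow(covariates))
  if (!is.null(names(posteriors))) {
    stopifnot(all(names(posteriors) == covariates$id))
  }
  if (is.null(patient_label)) patient_label <- covariates$group[1]
  groups <- unique(covariates$group)
  commonalities <- list()
  hr_within <- list()
  for (g in groups) {
    sel <- which(covariates$group == g)
    Xg <- build_design(covariates[sel, , drop = FALSE])
    commonalities[[g]] <- peb_fit(posteriors[sel], Xg)
    has_hr <- all(is.finite(covariates$hr_bpm[sel]))
    if (has_hr) {
      cov_g <- covariates[sel, , drop = FALSE]
      if (hr_centering == "grand") {
        cov_g$hr_bpm <- cov_g$hr_bpm -
          mean(covariates$hr_bpm[is.finite(covariates$hr_bpm)])
      }
      Xh <- build_design(cov_g, "hr")
      hr_within[[g]] <- peb_fit(posteriors[sel], Xh)
    }
  }
  ok_hr <- is.finite(covariates$hr_bpm)
  Xd <- build_design(covariates, "group", patient_label = patient_label)
  group_difference <- peb_fit(posteriors, Xd)
  interaction <- NULL
  if (sum(ok_hr) >= 4) {
    Xi <- build_design(covariates[ok_hr, , drop = FALSE],
                       c("group", "hr", "group_x_hr"),
                       patient_label = patient_label)
    interaction <- peb_fit(posteriors[ok_hr], Xi)
  }
  matrices <- list()
  for (g in groups) {
    matrices[[paste0("mean_", g)]] <-
      threshold_matrix(commonalities[[g]], "mean", cutoff)
    if (!is.null(hr_within[[g]])) {
      matrices[[paste0("hr_", g)]] <-
        threshold_matrix(hr_within[[g]], "hr", cutoff)
    }
  }
  matrices$group_difference <- threshold_matrix(group_difference, "group",
                                                cutoff)
  if (!is.null(interaction)) {
    matrices$interaction <- threshold_matrix(interaction, "group_x_hr",
                                             cutoff)
  }
  structure(
    list(commonalities = commonalities, group_difference = group_difference,
         hr_within = hr_within, interaction = interaction,
         matrices = matrices, cutoff = cutoff,
         patient_label = patient_label),
    class = "peb_suite"
  )
}

#' @export
print.peb_suite <- function(x, ...) {
  cat("PEB analysis suite (display threshold PP > ", x$cutoff, ")\n",
      sep = "")
  for (nm in names(x$matrices)) {
    n_sig <- sum(!is.na(x$matrices[[nm]]$Ep))
    cat(sprintf("  %-20s: %d connection(s) above threshold\n", nm, n_sig))
  }
  invisible(x)
}
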