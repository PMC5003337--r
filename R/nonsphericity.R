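#' ReML estimation of error non-sphericity
#'
#' Models the error covariance over observations as a sum of covariance
#' components: one variance component per design cell (uneven variances
#' between factor levels) plus one dependence component linking the two
#' hemisphere observations of the same trial. The component weights are
#' estimated by restricted maximum likelihood (ReML), pooling pixels inside
#' the analysis mask as replicates of a single covariance (the one-V-for-all
#' -pixels convention of mass-univariate imaging GLMs). The block-diagonal
#' (2 x 2 per trial) structure is exploited, so estimation is fast at
#' trial-level stacks.
#'
#' @param Y Numeric matrix, observations x pixels (in-mask values), or a
#'   `tf_stack` whose maps are used.
#' @param design A [build_design()] object aligned with the rows of `Y`.
#' @param n_pixels Number of (evenly subsampled) pixels pooled for
#'   estimation. Default 256.
#' @param max_iter,tol Optimizer budget and relative convergence tolerance.
#' @return A `nonsphericity` object: per-cell variances `lambda`,
#'   cross-hemisphere covariance `rho`, effective degrees of freedom
#'   (Satterthwaite, equal to the nominal trial-level df once the data are
#'   whitened with the estimated covariance), log-restricted-likelihood and
#'   convergence flag.
#' @export
estimate_nonsphericity <- function(Y, design, n_pixels = 256L,
                                   max_iter = 200L, tol = 1e-8) {
  if (inherits(Y, "tf_stack")) Y <- stack_matrix(Y)
  stopifnot(is.matrix(Y), nrow(Y) == nrow(design$X))
  if (min(design$n_per_cell) < 2L)
    stop_cfg("need >= 2 observations per cell for covariance estimation")
  P <- ncol(Y)
  if (P > n_pixels)
    Y <- Y[, round(seq(1L, P, length.out = n_pixels)), drop = FALSE]
  P <- ncol(Y)
  X <- design$X
  cell <- design$cell_of
  pair <- design$pair
  pi1 <- which(!is.na(pair) & !duplicated(pair))
  pi2 <- integer(length(pi1))
  if (length(pi1)) {
    second <- which(!is.na(pair) & duplicated(pair))
    pi2[match(pair[second], pair[pi1])] <- second
  }
  single <- which(is.na(pair))
  # sufficient statistics of the pooled pixel sample
  Sd <- rowSums(Y^2) / P
  So <- if (length(pi1)) rowSums(Y[pi1, , drop = FALSE] *
                                   Y[pi2, , drop = FALSE]) / P else numeric(0)
  n <- nrow(Y)
  p <- ncol(X)

  neg_restricted_ll <- function(theta) {
    lam <- exp(theta[seq_len(p)])
    rho <- theta[p + 1L]
    l1 <- lam[cell[pi1]]; l2 <- lam[cell[pi2]]
    det2 <- l1 * l2 - rho^2
    if (any(det2 <= 1e-10 * l1 * l2)) return(1e10)
    # blockwise V^-1
    vi11 <- l2 / det2; vi22 <- l1 / det2; vi12 <- -rho / det2
    vis <- 1 / lam[cell[single]]
    ldV <- sum(log(det2)) + sum(log(lam[cell[single]]))
    # U = V^-1 X (rows), A = X' V^-1 X
    U <- matrix(0, n, p)
    if (length(pi1)) {
      U[cbind(pi1, cell[pi1])] <- vi11
      U[cbind(pi1, cell[pi2])] <- U[cbind(pi1, cell[pi2])] + vi12
      U[cbind(pi2, cell[pi2])] <- U[cbind(pi2, cell[pi2])] + vi22
      U[cbind(pi2, cell[pi1])] <- U[cbind(pi2, cell[pi1])] + vi12
    }
    if (length(single)) U[cbind(single, cell[single])] <-
      U[cbind(single, cell[single])] + vis
    A <- crossprod(X, U)
    cA <- tryCatch(chol((A + t(A)) / 2), error = function(e) NULL)
    if (is.null(cA)) return(1e10)
    trVS <- sum(vi11 * Sd[pi1]) + sum(vi22 * Sd[pi2]) + 2 * sum(vi12 * So) +
      sum(vis * Sd[single])
    C <- crossprod(Y, U)                     # P x p
    G <- crossprod(C) / P                    # U' S U
    trAG <- sum(diag(backsolve(cA, forwardsolve(t(cA), G))))
    0.5 * P * (ldV + 2 * sum(log(diag(cA))) + trVS - trAG)
  }

  # start from per-cell OLS residual variances
  cmean <- rowsum(Y, cell) / as.vector(design$n_per_cell)
  R <- Y - cmean[cell, , drop = FALSE]
  v0 <- rowSums(rowsum(R^2, cell)) / (pmax(design$n_per_cell - 1L, 1L) * P)
  theta0 <- c(log(pmax(v0, 1e-12)), 0)
  opt <- optim(theta0, neg_restricted_ll, method = "L-BFGS-B",
               lower = c(rep(log(1e-12), p), -Inf),
               control = list(maxit = max_iter, factr = tol / .Machine$double.eps))
  if (opt$convergence != 0 && opt$convergence != 52)
    stop_cfg("ReML did not converge (code ", opt$convergence, "): ",
             opt$message %||% "")
  lam <- exp(opt$par[seq_len(p)]); names(lam) <- design$cells$label
  structure(list(lambda = lam, rho = opt$par[p + 1L],
                 logLik = -opt$value, converged = opt$convergence == 0,
                 df_effective = n - p, n_obs = n, n_pixels = P),
            class = "nonsphericity")
}

#' @export
print.nonsphericity <- function(x, ...) {
  cat("nonsphericity (ReML):\n  per-cell variances:\n")
  print(round(x$lambda, 4))
  cat(sprintf("  cross-hemisphere covariance: %.4f\n  effective df: %.1f\n",
              x$rho, x$df_effective))
  invisible(x)
}

# Blockwise whitening transform W = V^-1/2 applied to a matrix with
# observations in rows. Identity when nonsph is NULL.
whiten_rows <- function(M, design, nonsph) {
  if (is.null(nonsph)) return(M)
  lam <- nonsph$lambda
  rho <- nonsph$rho
  cell <- design$cell_of
  pair <- design$pair
  pi1 <- which(!is.na(pair) & !duplicated(pair))
  second <- which(!is.na(pair) & duplicated(pair))
  pi2 <- integer(length(pi1))
  if (length(pi1)) pi2[match(pair[second], pair[pi1])] <- second
  single <- which(is.na(pair))
  out <- M
  if (length(single))
    out[single, ] <- M[single, , drop = FALSE] / sqrt(lam[cell[single]])
  if (length(pi1)) {
    a <- lam[cell[pi1]]; b <- lam[cell[pi2]]
    # inverse square root of [[a, rho], [rho, b]] per pair
    det2 <- a * b - rho^2
    tr2 <- a + b
    s <- sqrt(det2)
    tq <- sqrt(tr2 + 2 * s)
    # (V + s I) / (tq * s) is V^1/2 inverse... use closed form for 2x2
    w11 <- (b + s) / (tq * s)
    w22 <- (a + s) / (tq * s)
    w12 <- -rho / (tq * s)
    out[pi1, ] <- w11 * M[pi1, , drop = FALSE] + w12 * M[pi2, , drop = FALSE]
    out[pi2, ] <- w12 * M[pi1, , drop = FALSE] + w22 * M[pi2, , drop = FALSE]
  }
  out
}

#' Satterthwaite effective degrees of freedom under a known covariance
#'
#' For an ordinary (unwhitened) least-squares fit with error covariance `V`,
#' the effective degrees of freedom of the residual variance estimate are
#' `tr(RV)^2 / tr(RVRV)` with `R` the residual-forming matrix. Equals the
#' nominal `n - p` when `V` is spherical and shrinks as variance
#' heterogeneity or dependence grows.
#'
#' @param design A [build_design()] object.
#' @param nonsph A `nonsphericity` object (or NULL for sphericity).
#' @return Effective degrees of freedom (scalar).
#' @export
satterthwaite_df <- function(design, nonsph = NULL) {
  n <- nrow(design$X)
  p <- ncol(design$X)
  if (is.null(nonsph)) return(n - p)
  if (n > 4000L)
    stop_cfg("dense Satterthwaite computation limited to 4000 observations")
  V <- assemble_V(design, nonsph)
  # normalize scale so trace terms are well-conditioned (df is scale-free)
  V <- V * (n / sum(diag(V)))
  Xp <- design$X %*% solve(crossprod(design$X), t(design$X))
  RV <- V - Xp %*% V
  sum(diag(RV))^2 / sum(RV * t(RV))
}

# Dense error covariance from the block representation (small n only).
assemble_V <- function(design, nonsph) {
  n <- nrow(design$X)
  V <- diag(nonsph$lambda[design$cell_of], n)
  pair <- design$pair
  pi1 <- which(!is.na(pair) & !duplicated(pair))
  second <- which(!is.na(pair) & duplicated(pair))
  if (length(pi1)) {
    pi2 <- integer(length(pi1))
    pi2[match(pair[second], pair[pi1])] <- second
    V[cbind(pi1, pi2)] <- nonsph$rho
    V[cbind(pi2, pi1)] <- nonsph$rho
  }
  V
}
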