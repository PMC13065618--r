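#' Principal component analysis with varimax rotation
#'
#' Correlation-matrix PCA of a standardized descriptor table, retaining
#' components with eigenvalue above 1 (Kaiser criterion) and applying a
#' normalized varimax rotation to the retained loadings for
#' interpretability. Constant columns are dropped with a warning before the
#' correlation matrix is formed.
#'
#' The rotation is the classic iterative scheme: loadings are row-normalized
#' by their communalities, every pair of retained components is rotated in
#' its plane by the angle maximizing the varimax criterion, and sweeps
#' repeat until the largest rotation angle falls below \code{tol}.
#'
#' @param X Observations x variables (>= 3 rows, >= 2 usable columns).
#' @param tol Convergence tolerance on the rotation angle (default 1e-6).
#' @param max_sweeps Safety bound on rotation sweeps.
#' @return An object of class \code{pca_result}: \code{eigenvalues},
#'   \code{percent_variance}, \code{loadings} (all components),
#'   \code{rotated_loadings} (retained, varimax), \code{retained} (logical
#'   mask), \code{scores} (standardized observations on all components) and
#'   \code{dropped} (constant columns removed).
#' @export
pca_varimax <- function(X, tol = 1e-6, max_sweeps = 1000) {
  X <- as.data.frame(X)
  num <- vapply(X, is.numeric, TRUE)
  X <- as.matrix(X[, num, drop = FALSE])
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[!is.finite(sds) | sds == 0]
  if (length(dropped)) {
    warning("dropping constant column(s): ", paste(dropped, collapse = ", "),
            call. = FALSE)
    X <- X[, !(colnames(X) %in% dropped), drop = FALSE]
  }
  p <- ncol(X)
  if (p < 2 || nrow(X) < 3)
    stop("need >= 2 non-constant variables and >= 3 observations", call. = FALSE)

  Z <- scale(X)
  R <- stats::cor(X)
  eig <- eigen(R, symmetric = TRUE)
  values <- pmax(eig$values, 0)
  loadings <- eig$vectors %*% diag(sqrt(values), p)
  dimnames(loadings) <- list(colnames(X), paste0("PC", seq_len(p)))
  retained <- values > 1
  rotated <- if (sum(retained) >= 2) {
    .varimax_rotate(loadings[, retained, drop = FALSE], tol, max_sweeps)
  } else loadings[, retained, drop = FALSE]

  structure(list(eigenvalues = values,
                 percent_variance = 100 * values / p,
                 loadings = loadings,
                 rotated_loadings = rotated,
                 retained = retained,
                 scores = Z %*% eig$vectors,
                 dropped = dropped),
            class = "pca_result")
}

# normalized varimax by pairwise planar rotations
.varimax_rotate <- function(L, tol = 1e-6, max_sweeps = 1000) {
  h <- sqrt(rowSums(L^2))
  h[h == 0] <- 1
  A <- L / h
  n <- nrow(A); m <- ncol(A)
  for (sweep in seq_len(max_sweeps)) {
    max_phi <- 0
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        x <- A[, i]; y <- A[, j]
        u <- x^2 - y^2
        v <- 2 * x * y
        num <- 2 * (n * sum(u * v) - sum(u) * sum(v))
        den <- n * sum(u^2 - v^2) - (sum(u)^2 - sum(v)^2)
        phi <- atan2(num, den) / 4
        if (abs(phi) > tol) {
          c_ <- cos(phi); s_ <- sin(phi)
          A[, i] <- c_ * x + s_ * y
          A[, j] <- -s_ * x + c_ * y
        }
        max_phi <- max(max_phi, abs(phi))
      }
    }
    if (max_phi <= tol) break
  }
  out <- A * h
  dimnames(out) <- dimnames(L)
  out
}

#' @export
print.pca_result <- function(x, ...) {
  k <- sum(x$retained)
  cat(sprintf("<pca_result> %d variables, %d component(s) with eigenvalue > 1 (%.1f%% variance)\n",
              nrow(x$loadings), k, sum(x$percent_variance[x$retained])))
  invisible(x)
}
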