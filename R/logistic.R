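#' Binary logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit with an intercept. Columns are
#' standardized internally for numerical stability and the coefficients
#' are returned on the original scale. Convergence is declared when the
#' maximum absolute score (gradient of the log-likelihood) falls below
#' `tol`. Perfect separation is detected as a diverging standardized
#' coefficient and raised as an error rather than silently returning
#' huge estimates.
#'
#' @param X Numeric n x k predictor matrix (no intercept column).
#' @param y Binary response: 0/1, logical, or `"case"`/`"control"` labels
#'   (case = 1).
#' @param max_iter Maximum IRLS iterations (default 100).
#' @param tol Score convergence tolerance (default 1e-8).
#' @return List with `beta` (named, original scale), `intercept`, `se`
#'   (standard errors, intercept first, from the inverse observed
#'   information), `loglik`, `iterations`, and `fitted` probabilities.
#' @export
fit_logistic <- function(X, y, max_iter = 100, tol = 1e-8) {
  X <- as.matrix(X)
  if (is.character(y)) y <- y == "case"
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary", call. = FALSE)
  n <- nrow(X); k <- ncol(X)
  if (length(y) != n) stop("X and y sizes disagree", call. = FALSE)
  if (n <= k + 1) stop("need more observations than parameters", call. = FALSE)
  if (sum(y) == 0 || sum(y) == n) {
    stop("both classes must be present", call. = FALSE)
  }
  sds <- apply(X, 2, sd)
  if (k > 0 && any(sds == 0)) {
    stop(sprintf("constant predictor column(s): %s",
                 paste(colnames(X)[sds == 0], collapse = ", ")), call. = FALSE)
  }
  mus <- if (k > 0) colMeans(X) else numeric()
  Z <- if (k > 0) scale(X, center = mus, scale = sds) else X
  Z1 <- cbind(1, Z)
  beta <- c(log(mean(y) / (1 - mean(y))), rep(0, k))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(Z1 %*% beta)
    p <- 1 / (1 + exp(-eta))
    score <- drop(crossprod(Z1, y - p))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    w <- pmax(p * (1 - p), 1e-12)
    info <- crossprod(Z1 * w, Z1)
    step <- tryCatch(solve(info, score), error = function(e) {
      stop("singular information matrix during IRLS", call. = FALSE)
    })
    beta <- beta + step
    if (max(abs(beta[-1])) > 20) {
      stop("perfect separation detected (diverging standardized coefficient)",
           call. = FALSE)
    }
  }
  if (!converged) {
    eta <- drop(Z1 %*% beta)
    p <- 1 / (1 + exp(-eta))
    score <- drop(crossprod(Z1, y - p))
    if (max(abs(score)) >= tol) {
      stop(sprintf("IRLS did not converge in %d iterations (max |score| = %.3g)",
                   max_iter, max(abs(score))), call. = FALSE)
    }
  }
  # back-transform to the original predictor scale
  b <- if (k > 0) unname(beta[-1] / sds) else numeric()
  b0 <- unname(beta[1] - if (k > 0) sum(beta[-1] * mus / sds) else 0)
  X1 <- cbind(1, X)
  eta <- drop(X1 %*% c(b0, b))
  p <- 1 / (1 + exp(-eta))
  w <- pmax(p * (1 - p), 1e-12)
  info <- crossprod(X1 * w, X1)
  se <- sqrt(diag(solve(info)))
  loglik <- sum(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300)))
  names(b) <- colnames(X)
  names(se) <- c("(Intercept)", colnames(X))
  list(beta = b, intercept = b0, se = se, loglik = loglik,
       iterations = it, fitted = p)
}
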