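#' Logistic generalized estimating equations
#'
#' Binomial-logit GEE with an exchangeable or independence working
#' correlation and robust (sandwich) variance, for repeated binary outcomes
#' within patients. The exchangeable correlation parameter is estimated by
#' the usual Pearson-residual moment estimator; under independence the
#' point estimates coincide with an ordinary logistic fit and only the
#' variance differs (clustered sandwich).
#'
#' @param formula model formula for the binary outcome.
#' @param data data.frame with one row per observation.
#' @param id cluster (patient) identifier, length `nrow(data)`.
#' @param corstr working correlation structure.
#' @param maxit,tol Fisher-scoring iteration controls.
#' @return object of class `gee_logit`: list with `coefficients`, robust
#'   `vcov`, `alpha` (working correlation), `converged`, `n_clusters`.
#' @export
gee_logit <- function(formula, data, id,
                      corstr = c("exchangeable", "independence"),
                      maxit = 50L, tol = 1e-8) {
  corstr <- match.arg(corstr)
  mf <- stats::model.frame(formula, data)
  y <- as.numeric(stats::model.response(mf))
  X <- stats::model.matrix(formula, mf)
  stopifnot(length(id) == length(y), all(y %in% c(0, 1)))
  cl <- split(seq_along(y), factor(id, levels = unique(id)))
  p <- ncol(X)
  if (qr(X)$rank < p)
    stopf("design matrix is rank-deficient (aliased or constant covariate)")

  # start from the intercept-only model: a separated covariate would place
  # the full-model MLE start in a numerically degenerate region
  beta <- numeric(p)
  ybar <- min(max(mean(y), 1e-3), 1 - 1e-3)
  if ("(Intercept)" %in% colnames(X)) beta[1] <- stats::qlogis(ybar)
  alpha <- 0
  converged <- FALSE
  ridge_solve <- function(H, U) {
    solve(H + diag(1e-10 * max(diag(H)) + 1e-300, nrow(H)), U)
  }
  for (it in seq_len(maxit)) {
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    mu <- stats::plogis(eta)
    a <- mu * (1 - mu)
    r <- (y - mu) / sqrt(a)
    if (corstr == "exchangeable") {
      num <- 0; npairs <- 0
      for (ix in cl) {
        ni <- length(ix)
        if (ni < 2L) next
        ri <- r[ix]
        num <- num + (sum(ri)^2 - sum(ri^2)) / 2
        npairs <- npairs + ni * (ni - 1) / 2
      }
      alpha <- if (npairs > p) num / (npairs - p) else 0
      nmax <- max(lengths(cl))
      alpha <- max(min(alpha, 0.95), -0.95 / max(nmax - 1, 1))
    }
    # standardized form: D'V^{-1}D = (A^{1/2}X)' R^{-1} (A^{1/2}X), so
    # near-degenerate variances downweight rows instead of inflating them
    H <- matrix(0, p, p); U <- numeric(p)
    for (ix in cl) {
      ni <- length(ix)
      Zi <- X[ix, , drop = FALSE] * sqrt(a[ix])
      Ri <- diag(ni) * (1 - alpha) + alpha
      RZ <- solve(Ri, Zi)
      H <- H + crossprod(Zi, RZ)
      U <- U + drop(crossprod(RZ, r[ix]))
    }
    delta <- ridge_solve(H, U)
    if (any(!is.finite(delta)))
      stopf("GEE update is not finite; check for separation or degenerate data")
    # damp large Fisher-scoring steps: sparse outcome cells can otherwise
    # overshoot into a numerically singular region
    step <- max(abs(delta))
    if (step > 2) delta <- delta * (2 / step)
    beta <- beta + delta
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }

  eta <- pmin(pmax(drop(X %*% beta), -30), 30)
  mu <- stats::plogis(eta); a <- mu * (1 - mu)
  r <- (y - mu) / sqrt(a)
  H <- matrix(0, p, p); M <- matrix(0, p, p)
  for (ix in cl) {
    ni <- length(ix)
    Zi <- X[ix, , drop = FALSE] * sqrt(a[ix])
    Ri <- diag(ni) * (1 - alpha) + alpha
    RZ <- solve(Ri, Zi)
    H <- H + crossprod(Zi, RZ)
    ui <- drop(crossprod(RZ, r[ix]))
    M <- M + tcrossprod(ui)
  }
  Hinv <- solve(H + diag(1e-10 * max(diag(H)) + 1e-300, p))
  V <- Hinv %*% M %*% Hinv
  dimnames(V) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  out <- list(coefficients = beta, vcov = V, alpha = alpha,
              corstr = corstr, converged = converged,
              n_clusters = length(cl), n_obs = length(y))
  class(out) <- "gee_logit"
  out
}

#' @export
print.gee_logit <- function(x, ...) {
  cat(sprintf("GEE logistic model (%s working correlation, alpha = %.3f)\n",
              x$corstr, x$alpha))
  se <- sqrt(diag(x$vcov))
  print(data.frame(estimate = x$coefficients, robust_se = se,
                   z = x$coefficients / se))
  invisible(x)
}
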