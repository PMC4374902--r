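#' Confirmatory factor analysis model specification
#'
#' Congeneric CFA: each item loads on exactly one factor, factor variances
#' are fixed to 1 for identification, inter-factor correlations are free.
#' Nested comparisons follow from the factor structure itself: a 1-factor
#' model is the 2-factor model with the inter-factor correlation fixed at 1,
#' and the 2-factor model is the 3-factor model with the psychological-
#' social correlation fixed at 1, so chi-square differences have 1 and 2
#' degrees of freedom respectively.
#'
#' @param items Character vector of item names.
#' @param factors Named character vector or list mapping each item to its
#'   factor.
#' @return A `cfa_model` object.
#' @export
cfa_model <- function(items, factors) {
  factors <- unlist(factors)
  if (!setequal(names(factors), items)) {
    stop("every item must be assigned to exactly one factor")
  }
  factors <- factors[items]
  structure(list(items = items, assignment = factors,
                 factor_names = unique(unname(factors))),
            class = "cfa_model")
}

#' MHC-SF factor structures used in nested comparisons
#'
#' @param n_factors 1 (single well-being factor), 2 (hedonic + eudaimonic)
#'   or 3 (hedonic + psychological + social).
#' @param item_map An [mhcsf_item_map()]; pass the Brown variant for the
#'   alternative 3-d allocation.
#' @export
cfa_mhcsf_model <- function(n_factors = c(3, 2, 1), item_map = mhcsf_item_map()) {
  n_factors <- n_factors[1]
  fac <- switch(as.character(n_factors),
                "3" = item_map$scale,
                "2" = ifelse(item_map$scale == "hedonic", "hedonic", "eudaimonic"),
                "1" = rep("wellbeing", nrow(item_map)),
                stop("n_factors must be 1, 2 or 3"))
  cfa_model(item_map$item, stats::setNames(fac, item_map$item))
}

cfa_implied_sigma <- function(Lambda, Phi, Psi) {
  Lambda %*% Phi %*% t(Lambda) + diag(Psi, nrow = length(Psi))
}

# F_ML = log|Sigma| + tr(S Sigma^-1) - log|S| - p, with analytic gradient
# dF = tr(Omega dSigma), Omega = Sigma^-1 (Sigma - S) Sigma^-1
cfa_objective <- function(theta, S, pattern, logdetS) {
  p <- nrow(S); q <- ncol(pattern$L0)
  lam <- theta[pattern$i_lam]
  psi <- exp(theta[pattern$i_psi])
  # correlations enter unconstrained: the implied-covariance family stays
  # well-defined slightly past |phi| = 1 (chol() guards non-PD Sigma), and an
  # interior parameterization keeps nested chi-square tests at the phi = 1
  # restriction on their standard asymptotics
  phi <- theta[pattern$i_phi]
  Lambda <- pattern$L0
  Lambda[pattern$lam_cells] <- lam
  Phi <- diag(q)
  if (length(phi)) {
    Phi[pattern$phi_cells] <- phi
    Phi[pattern$phi_cells[, c(2, 1), drop = FALSE]] <- phi
  }
  Sigma <- cfa_implied_sigma(Lambda, Phi, psi)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(list(value = 1e10, grad = NULL))
  logdet <- 2 * sum(log(diag(ch)))
  Sinv <- chol2inv(ch)
  value <- logdet + sum(Sinv * S) - logdetS - p
  Omega <- Sinv - Sinv %*% S %*% Sinv
  g_lam <- 2 * (Omega %*% Lambda %*% Phi)[pattern$lam_cells]
  g_psi <- diag(Omega) * psi
  g <- c(g_lam, g_psi)
  if (length(phi)) {
    LOL <- t(Lambda) %*% Omega %*% Lambda
    g_phi <- 2 * LOL[pattern$phi_cells]
    g <- c(g, g_phi)
  }
  list(value = value, grad = g, Lambda = Lambda, Phi = Phi, Psi = psi)
}

cfa_pattern <- function(spec) {
  p <- length(spec$items); q <- length(spec$factor_names)
  L0 <- matrix(0, p, q, dimnames = list(spec$items, spec$factor_names))
  lam_cells <- cbind(seq_len(p), match(spec$assignment, spec$factor_names))
  phi_cells <- if (q > 1) t(utils::combn(q, 2))[, c(2, 1), drop = FALSE] else
    matrix(integer(), 0, 2)
  # phi_cells rows are (row > col) lower-triangle cells
  phi_cells <- phi_cells[order(phi_cells[, 1], phi_cells[, 2]), , drop = FALSE]
  n_lam <- p; n_psi <- p; n_phi <- nrow(phi_cells)
  list(L0 = L0, lam_cells = lam_cells, phi_cells = phi_cells,
       i_lam = seq_len(n_lam), i_psi = n_lam + seq_len(n_psi),
       i_phi = n_lam + n_psi + seq_len(n_phi),
       n_free = n_lam + n_psi + n_phi)
}

#' Fit a CFA by maximum likelihood
#'
#' Minimizes the ML discrepancy
#' `F = log|Sigma(theta)| + tr(S Sigma(theta)^-1) - log|S| - p`
#' over loadings, uniquenesses (log-parameterized) and factor correlations
#' (tanh-parameterized), by quasi-Newton optimization with analytic
#' gradients and multiple jittered starts. The test statistic is
#' `T = (n - 1) * F_min` with `df = p(p+1)/2 - #free parameters`.
#'
#' @param data Either a subjects-x-items data matrix or a sample covariance
#'   matrix (in which case `n` is required).
#' @param spec A [cfa_model()].
#' @param n Sample size when `data` is a covariance matrix.
#' @param n_starts Number of optimization starts (best solution kept).
#' @param seed Seed for start jitter.
#' @param grad_tol Gradient-norm tolerance declaring convergence.
#' @return A `cfa_fit` list: `loadings`, `uniquenesses`, `factor_cor`,
#'   `F_ml`, `statistic` (T), `df`, `n`, `converged`, `heywood`.
#' @export
fit_cfa_ml <- function(data, spec, n = NULL, n_starts = 5, seed = 1L,
                       grad_tol = 1e-6) {
  stopifnot(inherits(spec, "cfa_model"))
  if (is.matrix(data) && isSymmetric(unname(data), tol = 1e-8) &&
      nrow(data) == length(spec$items) &&
      all(spec$items %in% rownames(data))) {
    S <- data[spec$items, spec$items]
    if (is.null(n)) stop("n is required when supplying a covariance matrix")
  } else {
    X <- as.matrix(if (inherits(data, "item_matrix")) data$responses else data)
    X <- X[stats::complete.cases(X), spec$items, drop = FALSE]
    n <- nrow(X)
    S <- stats::cov(X)
  }
  p <- nrow(S)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("sample covariance is not positive definite")
  pattern <- cfa_pattern(spec)
  if (n <= pattern$n_free) stop("n must exceed the number of free parameters")
  logdetS <- determinant(S, logarithm = TRUE)$modulus[1]
  sdit <- sqrt(diag(S))
  rbar <- max(mean(stats::cov2cor(S)[lower.tri(S)]), 0.05)
  th0 <- c(sqrt(rbar) * sdit, log(pmax((1 - rbar), 0.1) * diag(S)),
           rep(0.5, length(pattern$i_phi)))
  fn <- function(th) cfa_objective(th, S, pattern, logdetS)$value
  gr <- function(th) {
    o <- cfa_objective(th, S, pattern, logdetS)
    if (is.null(o$grad)) numeric(length(th)) else o$grad
  }
  best <- NULL
  with_seed(seed, {
    for (s in seq_len(n_starts)) {
      th <- if (s == 1) th0 else th0 + stats::rnorm(length(th0), 0, 0.2)
      opt <- tryCatch(
        stats::optim(th, fn, gr, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-14)),
        error = function(e) NULL)
      if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
    }
  })
  if (is.null(best)) stop("CFA optimization failed from every start")
  sol <- cfa_objective(best$par, S, pattern, logdetS)
  gnorm <- max(abs(sol$grad))
  converged <- is.finite(sol$value) && gnorm < grad_tol
  heywood <- any(sol$Psi < 1e-4 * diag(S))
  if (heywood) warning("Heywood case: uniqueness at or below zero")
  if (!converged) warning(sprintf("CFA may not have converged (max |grad| = %.2e)", gnorm))
  df <- p * (p + 1) / 2 - pattern$n_free
  loadings <- sol$Lambda
  # sign convention: factors oriented so loading sums are positive
  flip <- colSums(loadings) < 0
  loadings[, flip] <- -loadings[, flip]
  sol$Phi[flip, ] <- -sol$Phi[flip, ]
  sol$Phi[, flip] <- -sol$Phi[, flip]
  diag(sol$Phi) <- 1
  dimnames(sol$Phi) <- list(spec$factor_names, spec$factor_names)
  structure(list(loadings = loadings,
                 uniquenesses = stats::setNames(sol$Psi, spec$items),
                 factor_cor = sol$Phi, F_ml = sol$value,
                 statistic = (n - 1) * sol$value, df = df, n = n,
                 logLik = -((n - 1) / 2) * (sol$value + logdetS + p),
                 converged = converged, heywood = heywood,
                 grad_norm = gnorm, spec = spec),
            class = "cfa_fit")
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat(sprintf("CFA fit: %d items, %d factor(s); T = %.3f on %d df (n = %d)\n",
              nrow(x$loadings), ncol(x$loadings), x$statistic, x$df, x$n))
  if (!x$converged) cat("  [convergence not attained]\n")
  invisible(x)
}

#' Nested chi-square difference test
#'
#' Compares a restricted model (fewer factors) against a more general model
#' fit to the same items: `dX2 = T_restricted - T_general`, `ddf =
#' df_restricted - df_general`, p from the chi-square distribution.
#'
#' @param fit_restricted,fit_general Two [fit_cfa_ml()] fits on the same
#'   items and sample.
#' @return List: `delta_chisq`, `delta_df`, `p`.
#' @export
nested_chisq_test <- function(fit_restricted, fit_general) {
  if (!setequal(rownames(fit_restricted$loadings),
                rownames(fit_general$loadings))) {
    stop("models are fit to different item sets; not nested")
  }
  if (fit_restricted$n != fit_general$n) stop("fits use different sample sizes")
  ddf <- fit_restricted$df - fit_general$df
  if (ddf < 0) stop("restricted model must have more df than the general model")
  dx2 <- fit_restricted$statistic - fit_general$statistic
  if (dx2 < -1e-6 * max(1, fit_general$statistic)) {
    warning("restricted fit better than general fit beyond numerical tolerance")
  }
  dx2 <- max(dx2, 0)
  p <- if (ddf == 0) NA_real_ else stats::pchisq(dx2, ddf, lower.tail = FALSE)
  list(delta_chisq = dx2, delta_df = ddf, p = p)
}
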