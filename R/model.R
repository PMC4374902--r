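#' Pooled CTRA association model
#'
#' Maximum-likelihood repeated-measures linear model relating sign-adjusted
#' CTRA indicator expression to subject-level predictors. For subject i with
#' response vector `y_i` over the G panel genes,
#' `y_i = mu + (x_i' b) 1_G + e_i`, `e_i ~ N(0, Sigma)`:
#' gene-specific fixed intercepts `mu`, common subject-level slopes `b`, and
#' a structured within-subject covariance `Sigma` —
#' heterogeneous compound symmetry (`"hcs"`: gene-specific SDs `sigma_g`,
#' one common cross-gene correlation `rho`), compound symmetry (`"cs"`:
#' shared SD), or unstructured (`"un"`: full G x G matrix).
#'
#' Estimation profiles the fixed effects out by generalized least squares
#' and maximizes the profile log-likelihood over the covariance parameters
#' (`log sigma_g` and a scaled-logit transform of `rho` keeping `Sigma`
#' positive definite) by quasi-Newton iteration with analytic gradients and
#' multiple starts. The unstructured fit iterates GLS and the closed-form
#' covariance update `Sigma = S/n` (with ridge stabilization when G
#' approaches n). Inference uses model-based standard errors from
#' `(X' V^-1 X)^-1` and the between-within denominator df convention
#' `df = n - p - 1` for subject-level terms (`p` = number of subject-level
#' predictor columns), which reproduces the df bookkeeping of balanced
#' repeated-measures designs.
#'
#' @param long Long-format data (see [to_long_format()]): columns
#'   `subject_id`, `gene`, `value`, plus predictor columns; every subject
#'   must have a complete gene panel.
#' @param predictors Character vector of predictor column names (subject
#'   level).
#' @param structure `"hcs"`, `"cs"` or `"un"`.
#' @param standardize_predictors Standardize predictors to mean 0 / SD 1 on
#'   the analyzed sample (the reporting convention for standardized
#'   association coefficients)?
#' @param method `"reml"` (default) or `"ml"`. REML corrects the downward
#'   bias of the covariance-parameter estimates induced by the many fixed
#'   effects (G gene intercepts plus the subject-level terms); with panels of
#'   50+ genes and around 120 subjects the ML standard errors are small
#'   enough to inflate the type-I error of the Wald tests well beyond
#'   nominal, while REML restores approximate calibration. Slope estimates
#'   are essentially identical under the two methods.
#' @param n_starts Optimization starts for the structured fits.
#' @param seed Seed for start jitter.
#' @param ridge Ridge factor for the unstructured covariance update.
#' @param adjust_vcov Apply the Kenward-Roger-type correction that
#'   propagates covariance-parameter uncertainty into the slope covariance
#'   (structured fits only)? Without it, Wald tests are anti-conservative
#'   when the panel size is an appreciable fraction of the sample size.
#' @return A `ctra_fit` object: `coefficients` table (b, SE, t, df, p, VIF),
#'   `gene_effects`, `sigma`, `rho` (or `Sigma`), `logLik`, `vcov`,
#'   `converged`, plus bookkeeping fields.
#' @export
fit_ctra_model <- function(long, predictors, structure = c("hcs", "cs", "un"),
                           standardize_predictors = TRUE,
                           method = c("reml", "ml"), n_starts = 3,
                           seed = 1L, ridge = 1e-6, adjust_vcov = TRUE) {
  structure <- match.arg(structure)
  method <- match.arg(method)
  miss <- setdiff(c("subject_id", "gene", "value", predictors), names(long))
  if (length(miss)) stop("missing columns in long data: ", paste(miss, collapse = ", "))
  genes <- unique(long$gene)
  subs <- unique(long$subject_id)
  G <- length(genes); n <- length(subs)
  if (nrow(long) != G * n) stop("unbalanced panel: need one row per subject x gene")
  Y <- matrix(NA_real_, G, n, dimnames = list(genes, subs))
  Y[cbind(match(long$gene, genes), match(long$subject_id, subs))] <- long$value
  if (anyNA(Y)) stop("unbalanced panel: missing subject x gene cells")
  first <- long[!duplicated(long$subject_id), , drop = FALSE]
  first <- first[match(subs, first$subject_id), , drop = FALSE]
  X <- as.matrix(first[predictors])
  if (anyNA(X)) stop("predictors contain NA; drop incomplete subjects first")
  storage.mode(X) <- "double"
  const <- apply(X, 2L, stats::sd) == 0
  if (any(const)) {
    message("dropping constant predictor(s): ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
    predictors <- predictors[!const]
  }
  if (standardize_predictors) X <- scale(X)[, , drop = FALSE]
  p <- ncol(X)
  if (n <= p + 2) stop("need n_subjects > predictors + 2")
  df_bw <- n - p - 1L

  reml <- method == "reml"
  fit <- switch(structure,
                hcs = fit_structured(Y, X, heterogeneous = TRUE,
                                     n_starts = n_starts, seed = seed,
                                     reml = reml, adjust_vcov = adjust_vcov),
                cs = fit_structured(Y, X, heterogeneous = FALSE,
                                    n_starts = n_starts, seed = seed,
                                    reml = reml, adjust_vcov = adjust_vcov),
                un = fit_unstructured(Y, X, ridge = ridge, reml = reml))
  b <- fit$beta
  Vb <- fit$vcov_beta
  se <- sqrt(diag(Vb))
  tval <- b / se
  pval <- 2 * stats::pt(-abs(tval), df_bw)
  vifs <- if (p > 1) vapply(predictors, function(tm) vif(X, tm), 0) else
    stats::setNames(rep(1, p), predictors)
  coefs <- data.frame(term = predictors, b = b, se = se, t = tval,
                      df = df_bw, p = pval, vif = unname(vifs),
                      row.names = NULL, stringsAsFactors = FALSE)
  structure(list(coefficients = coefs, gene_effects = fit$mu,
                 sigma = fit$sigma, rho = fit$rho, Sigma = fit$Sigma,
                 logLik = fit$logLik, vcov = Vb, df = df_bw,
                 n_subjects = n, n_genes = G, structure = structure,
                 method = method,
                 converged = fit$converged,
                 predictors = predictors, X = X, Y = Y),
            class = "ctra_fit")
}

#' @export
print.ctra_fit <- function(x, ...) {
  cat(sprintf("CTRA repeated-measures fit (%s): %d genes x %d subjects, logLik %.2f\n",
              toupper(x$structure), x$n_genes, x$n_subjects, x$logLik))
  tab <- x$coefficients
  tab[c("b", "se", "t", "p", "vif")] <- lapply(tab[c("b", "se", "t", "p", "vif")],
                                               signif, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

# ---- internal machinery ----------------------------------------------------

# closed-form pieces for Sigma = D M D, M = (1-rho) I + rho J
hcs_sigma_inv <- function(sigma, rho) {
  G <- length(sigma)
  a <- 1 / (1 - rho)
  bq <- -rho / ((1 - rho) * (1 + (G - 1) * rho))
  Minv <- matrix(bq, G, G); diag(Minv) <- a + bq
  Dinv <- 1 / sigma
  Sinv <- Minv * tcrossprod(Dinv)
  logdet <- 2 * sum(log(sigma)) + (G - 1) * log1p(-rho) + log1p((G - 1) * rho)
  list(Sinv = Sinv, logdet = logdet)
}

# profile GLS given Sigma^-1: returns beta-hat, mu-hat, residual cross-product
gls_profile <- function(Y, X, Sinv) {
  G <- nrow(Y); n <- ncol(Y); p <- ncol(X)
  one <- rep(1, G)
  Si1 <- Sinv %*% one
  s11 <- sum(Si1)
  sx <- colSums(X)
  M <- rbind(cbind(n * Sinv, Si1 %*% t(sx)),
             cbind(sx %*% t(Si1), s11 * crossprod(X)))
  SiY <- Sinv %*% Y
  rhs <- c(rowSums(SiY), as.vector(t(X) %*% colSums(SiY)))
  est <- solve(M, rhs)
  mu <- est[seq_len(G)]
  beta <- est[G + seq_len(p)]
  R <- Y - mu - matrix(X %*% beta, G, n, byrow = TRUE)
  list(mu = mu, beta = beta, R = R, M = M)
}

neg_profile_loglik_hcs <- function(theta, Y, X, heterogeneous, reml = FALSE,
                                   XtX = crossprod(X)) {
  G <- nrow(Y); n <- ncol(Y)
  bad <- function(sigma, z) list(value = 1e10, grad = rep(0, length(theta)),
                                 fit = NULL, sigma = sigma, rho = NA_real_,
                                 Sinv = NULL)
  if (!all(is.finite(theta))) return(bad(NULL, NULL))
  if (heterogeneous) {
    sigma <- exp(theta[seq_len(G)])
    z <- theta[G + 1]
  } else {
    sigma <- rep(exp(theta[1]), G)
    z <- theta[2]
  }
  if (!all(is.finite(sigma)) || any(sigma <= 0)) return(bad(sigma, z))
  # with a single response the correlation is vacuous; pin it at 0
  lo <- if (G > 1) -1 / (G - 1) + 1e-6 else -0.5
  hi <- 1 - 1e-5
  if (G == 1) z <- 0
  rho <- lo + (hi - lo) / (1 + exp(-z))
  si <- hcs_sigma_inv(sigma, rho)
  g <- tryCatch(gls_profile(Y, X, si$Sinv), error = function(e) NULL)
  if (is.null(g)) {
    return(list(value = 1e10, grad = rep(0, length(theta)), fit = NULL,
                sigma = sigma, rho = rho, Sinv = si$Sinv))
  }
  S <- tcrossprod(g$R)
  ll <- -0.5 * (n * G * log(2 * pi) + n * si$logdet + sum(si$Sinv * S))
  if (!is.finite(ll)) return(bad(sigma, z))
  if (reml) {
    ldM <- determinant(g$M, logarithm = TRUE)
    if (ldM$sign <= 0) return(bad(sigma, z))
    ll <- ll - 0.5 * ldM$modulus[1]
  }
  # gradient (envelope theorem: beta-hat partials vanish)
  Sigma <- tcrossprod(sigma) * ((1 - rho) * diag(G) + rho)
  Astar <- n * si$Sinv - si$Sinv %*% S %*% si$Sinv
  AS <- Astar %*% Sigma
  g_logsig <- -diag(AS)   # dl/dlog sigma_g
  W <- Astar * tcrossprod(sigma)
  g_rho <- -0.5 * (sum(W) - sum(diag(W)))
  if (reml) {
    # d(-0.5 log|M|)/dtheta = -0.5 tr(M^-1 dM/dtheta); dM blocks are linear
    # in dSigma^-1, so each parameter costs O(1) after O(G^3) precomputation
    p <- ncol(X)
    Minv <- tryCatch(solve(g$M), error = function(e) NULL)
    if (is.null(Minv)) return(bad(sigma, z))
    A11 <- Minv[seq_len(G), seq_len(G), drop = FALSE]
    A12 <- Minv[seq_len(G), G + seq_len(p), drop = FALSE]
    A22 <- Minv[G + seq_len(p), G + seq_len(p), drop = FALSE]
    Sinv <- si$Sinv
    Si1 <- rowSums(Sinv)
    sx <- colSums(X)
    P <- A11 %*% Sinv
    v <- as.vector(A12 %*% sx)
    Sv <- as.vector(Sinv %*% v)
    c22 <- sum(A22 * XtX)
    tr_sig <- -2 * (n * diag(P) + Sv + Si1 * v + Si1 * c22)
    w <- as.vector(Sinv %*% sigma)
    Q <- Sinv %*% A11 %*% Sinv
    trA11K <- -(as.numeric(t(sigma) %*% Q %*% sigma) -
                  sum(diag(Q) * sigma^2))
    K1 <- -(w * sum(sigma * Si1) - as.vector(Sinv %*% (sigma^2 * Si1)))
    tr_rho <- n * trA11K + 2 * sum(K1 * v) + sum(K1) * c22
    g_logsig <- g_logsig - 0.5 * tr_sig
    g_rho <- g_rho - 0.5 * tr_rho
  }
  drho_dz <- (hi - lo) * exp(-z) / (1 + exp(-z))^2
  grad <- if (heterogeneous) c(g_logsig, g_rho * drho_dz) else
    c(sum(g_logsig), g_rho * drho_dz)
  list(value = -ll, grad = -grad, fit = g, sigma = sigma, rho = rho,
       Sinv = si$Sinv)
}

fit_structured <- function(Y, X, heterogeneous, n_starts = 3, seed = 1L,
                           reml = FALSE, adjust_vcov = TRUE) {
  G <- nrow(Y); n <- ncol(Y)
  XtX <- crossprod(X)
  ols <- gls_profile(Y, X, diag(G))
  s0 <- sqrt(rowSums(ols$R^2) / n)
  if (G > 1) {
    Rs <- ols$R / s0
    cs <- crossprod(colSums(Rs)) / n   # 1' C 1 with C = cor estimate * G
    rho0 <- max(min((as.numeric(cs) - G) / (G * (G - 1)), 0.9), -0.5 / (G - 1))
    lo <- -1 / (G - 1) + 1e-6
    z0 <- stats::qlogis((rho0 - lo) / (1 - 1e-5 - lo))
  } else {
    z0 <- 0
  }
  th0 <- if (heterogeneous) c(log(s0), z0) else c(mean(log(s0)), z0)
  fn <- function(th) neg_profile_loglik_hcs(th, Y, X, heterogeneous, reml, XtX)$value
  gr <- function(th) neg_profile_loglik_hcs(th, Y, X, heterogeneous, reml, XtX)$grad
  best <- NULL
  with_seed(seed, {
    for (s in seq_len(n_starts)) {
      th <- if (s == 1) th0 else th0 + stats::rnorm(length(th0), 0, 0.3)
      opt <- tryCatch(
        stats::optim(th, fn, gr, method = "BFGS",
                     control = list(maxit = 300, reltol = 1e-13)),
        error = function(e) NULL)
      if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
    }
  })
  if (is.null(best)) stop("covariance optimization failed to converge")
  sol <- neg_profile_loglik_hcs(best$par, Y, X, heterogeneous, reml, XtX)
  if (is.null(sol$fit)) {
    stop("covariance optimization ended at a degenerate point (rho near boundary?)")
  }
  p <- ncol(X)
  Minv <- solve(sol$fit$M)
  vcov_beta <- Minv[G + seq_len(p), G + seq_len(p), drop = FALSE]
  if (adjust_vcov) {
    vcov_beta <- vcov_beta +
      kr_adjust(Y, X, best$par, heterogeneous, reml, Minv, XtX)
  }
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  list(mu = stats::setNames(sol$fit$mu, rownames(Y)),
       beta = stats::setNames(sol$fit$beta, colnames(X)),
       vcov_beta = vcov_beta, sigma = stats::setNames(sol$sigma, rownames(Y)),
       rho = if (G > 1) sol$rho else NA_real_, Sigma = NULL,
       logLik = unname(-sol$value),
       converged = best$convergence == 0)
}

fit_unstructured <- function(Y, X, ridge = 1e-6, max_iter = 200, tol = 1e-10,
                             reml = FALSE) {
  G <- nrow(Y); n <- ncol(Y); p <- ncol(X)
  if (G * (G + 1) / 2 >= n * G) {
    warning("unstructured covariance has as many parameters as observations")
  }
  if (G >= n) warning("G >= n: unstructured estimate stabilized by ridge")
  XtX <- crossprod(X)
  sx <- colSums(X)
  Sigma <- diag(G)
  ll_old <- -Inf; converged <- FALSE; g <- NULL
  for (it in seq_len(max_iter)) {
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) {
      Sigma <- Sigma + (ridge + 1e-8) * mean(diag(Sigma)) * diag(G)
      ch <- chol(Sigma)
    }
    Sinv <- chol2inv(ch)
    g <- gls_profile(Y, X, Sinv)
    S <- tcrossprod(g$R) / n
    if (reml) {
      # add back the hat-matrix correction sum_i X_i (X'V^-1 X)^-1 X_i' / n,
      # the REML fixed-point update accounting for the fitted fixed effects
      Minv <- solve(g$M)
      A11 <- Minv[seq_len(G), seq_len(G), drop = FALSE]
      A12 <- Minv[seq_len(G), G + seq_len(p), drop = FALSE]
      A22 <- Minv[G + seq_len(p), G + seq_len(p), drop = FALSE]
      v <- as.vector(A12 %*% sx)
      hat <- n * A11 + outer(v, rep(1, G)) + outer(rep(1, G), v) +
        sum(A22 * XtX)
      S <- S + hat / n
    }
    Sigma_new <- S + ridge * mean(diag(S)) * diag(G)
    ll <- -0.5 * (n * G * log(2 * pi) +
                    n * 2 * sum(log(diag(chol(Sigma_new)))) +
                    n * G)  # tr(Sigma^-1 S) = G at the ML update
    if (abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      Sigma <- Sigma_new; converged <- TRUE; ll_old <- ll; break
    }
    Sigma <- Sigma_new; ll_old <- ll
  }
  Sinv <- chol2inv(chol(Sigma))
  g <- gls_profile(Y, X, Sinv)
  Minv <- solve(g$M)
  vcov_beta <- Minv[G + seq_len(p), G + seq_len(p), drop = FALSE]
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  dimnames(Sigma) <- list(rownames(Y), rownames(Y))
  list(mu = stats::setNames(g$mu, rownames(Y)),
       beta = stats::setNames(g$beta, colnames(X)),
       vcov_beta = vcov_beta, sigma = sqrt(diag(Sigma)), rho = NULL,
       Sigma = Sigma, logLik = ll_old, converged = converged)
}

# Adjusted slope covariance after Kenward & Roger: the model-based
# (X'V^-1 X)^-1 ignores that Sigma was estimated. With W the sampling
# covariance of the covariance parameters (inverse observed information),
# T_j = Sigma^-1 (dSigma/dtheta_j) Sigma^-1, P_j = -M(T_j) and
# Q_jk = M(T_j Sigma T_k) (M(.) builds the fixed-design cross-product with
# the given G x G kernel), the adjustment is
#   Var(b) += 2 A { sum_jk W_jk (Q_jk - P_j A P_k) } A,  A = M^-1,
# omitting the second-derivative term. Sums over parameter pairs collapse
# through a square root of W, keeping the cost at O(n_par G^3).
kr_adjust <- function(Y, X, theta, heterogeneous, reml, Minv, XtX) {
  G <- nrow(Y); n <- ncol(Y); p <- ncol(X)
  obj <- function(th) neg_profile_loglik_hcs(th, Y, X, heterogeneous, reml, XtX)
  sol <- obj(theta)
  Sinv <- sol$Sinv
  sigma <- sol$sigma
  rho <- sol$rho
  Sigma <- tcrossprod(sigma) * ((1 - rho) * diag(G) + rho)
  lo <- if (G > 1) -1 / (G - 1) + 1e-6 else -0.5
  hi <- 1 - 1e-5
  z <- theta[length(theta)]
  drho_dz <- (hi - lo) * exp(-z) / (1 + exp(-z))^2
  n_th <- length(theta)
  sx <- colSums(X)
  # observed information of the covariance parameters by forward differences
  H <- matrix(0, n_th, n_th)
  h <- 1e-5 * pmax(abs(theta), 1)
  for (j in seq_len(n_th)) {
    thj <- theta; thj[j] <- thj[j] + h[j]
    H[, j] <- (obj(thj)$grad - sol$grad) / h[j]
  }
  H <- (H + t(H)) / 2
  W <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(W)) return(matrix(0, p, p))
  ew <- eigen(W, symmetric = TRUE)
  ew$values <- pmax(ew$values, 0)
  Lhalf <- ew$vectors %*% diag(sqrt(ew$values), n_th)
  # T_rho (chain through the scaled-logit transform)
  w <- as.vector(Sinv %*% sigma)
  T_rho <- (tcrossprod(w) - Sinv %*% (sigma^2 * Sinv)) * drho_dz
  build_M <- function(C) {
    C1 <- rowSums(C)
    rbind(cbind(n * C, C1 %*% t(sx)),
          cbind(sx %*% t(C1), sum(C1) * XtX))
  }
  acc <- matrix(0, G + p, G + p)
  for (a in seq_len(n_th)) {
    coef <- Lhalf[, a]
    if (heterogeneous) {
      d <- coef[seq_len(G)]
      # sum_g d_g T_g = Sinv D + D Sinv with D = diag(d), since
      # T_g = Sinv[,g] e_g' + e_g Sinv[g,]
      Ca <- Sinv * rep(d, each = G) + Sinv * rep(d, times = G)
      dim(Ca) <- c(G, G)
      Ca <- Ca + coef[G + 1] * T_rho
    } else {
      Ca <- 2 * coef[1] * Sinv + coef[2] * T_rho
    }
    MU <- build_M(Ca %*% Sigma %*% Ca)
    MC <- build_M(Ca)
    acc <- acc + MU - MC %*% Minv %*% MC
  }
  adj <- 2 * (Minv %*% acc %*% Minv)
  adj[G + seq_len(p), G + seq_len(p), drop = FALSE]
}

# ---- tests and diagnostics -------------------------------------------------

#' Wald t test for one model term
#'
#' `t = b / SE` with the between-within denominator df
#' (`n_subjects - p - 1`) and a two-sided p-value.
#'
#' @param fit A [fit_ctra_model()] fit.
#' @param term Predictor name.
#' @return List: `b`, `se`, `t`, `df`, `p`.
#' @export
wald_t <- function(fit, term) {
  row <- fit$coefficients[fit$coefficients$term == term, ]
  if (nrow(row) != 1L) stop("term not in fit: ", term)
  list(b = row$b, se = row$se, t = row$t, df = row$df, p = row$p)
}

#' Omnibus Wald F test for a group of terms
#'
#' `F = b_C' V_C^-1 b_C / q` for the joint null that all `q` group
#' coefficients are zero, on `(q, n - p - 1)` df.
#'
#' @param fit A [fit_ctra_model()] fit.
#' @param terms Character vector of predictor names (>= 1).
#' @return List: `F`, `df1`, `df2`, `p`.
#' @export
omnibus_f <- function(fit, terms) {
  if (!length(terms)) stop("need at least one term")
  if (!all(terms %in% fit$coefficients$term)) stop("terms not all in fit")
  b <- fit$coefficients$b[match(terms, fit$coefficients$term)]
  V <- fit$vcov[terms, terms, drop = FALSE]
  q <- length(terms)
  Fstat <- as.numeric(t(b) %*% solve(V, b)) / q
  df2 <- fit$df
  list(F = Fstat, df1 = q, df2 = df2,
       p = stats::pf(Fstat, q, df2, lower.tail = FALSE))
}

#' Contrast of two coefficients
#'
#' Tests `b_A - b_B = 0` using the estimated coefficient covariance; with
#' standardized predictors this is the "eudaimonic predominance" contrast
#' comparing association magnitudes.
#'
#' @param fit A [fit_ctra_model()] fit.
#' @param term_a,term_b Predictor names.
#' @return List: `estimate`, `se`, `t`, `df`, `p`.
#' @export
contrast_test <- function(fit, term_a, term_b) {
  tms <- fit$coefficients$term
  if (!all(c(term_a, term_b) %in% tms)) stop("terms not in fit")
  ba <- fit$coefficients$b[tms == term_a]
  bb <- fit$coefficients$b[tms == term_b]
  if (term_a == term_b) {
    return(list(estimate = 0, se = NA_real_, t = 0, df = fit$df, p = 1))
  }
  v <- fit$vcov[term_a, term_a] + fit$vcov[term_b, term_b] -
    2 * fit$vcov[term_a, term_b]
  est <- ba - bb
  tval <- est / sqrt(v)
  list(estimate = est, se = sqrt(v), t = tval, df = fit$df,
       p = 2 * stats::pt(-abs(tval), fit$df))
}

#' Variance inflation factor
#'
#' `VIF = 1 / (1 - R^2)` from regressing one predictor on all the others
#' (intercept included). Values above 10 indicate problematic
#' multicollinearity.
#'
#' @param design Numeric matrix of predictor columns (subject level).
#' @param term Column to diagnose.
#' @return Scalar VIF (>= 1).
#' @export
vif <- function(design, term) {
  design <- as.matrix(design)
  if (!term %in% colnames(design)) stop("term not in design: ", term)
  y <- design[, term]
  others <- design[, setdiff(colnames(design), term), drop = FALSE]
  if (ncol(others) == 0L) return(1)
  fit <- stats::lm.fit(cbind(1, others), y)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  if (r2 >= 1) stop("design is rank deficient; VIF undefined for ", term)
  1 / (1 - r2)
}

#' Percent-difference effect transform
#'
#' Converts an unstandardized association coefficient `b` (log2 expression
#' per SD of predictor) to the percent difference in average transcript
#' abundance across a range-spanning -2 SD to +2 SD contrast:
#' `100 * (2^(4 b) - 1)`.
#'
#' @param b Coefficient on the log2 scale per predictor SD.
#' @return Percent difference (vectorized).
#' @export
percent_difference_effect <- function(b) {
  100 * (2^(4 * b) - 1)
}
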