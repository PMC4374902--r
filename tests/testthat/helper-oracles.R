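# Independent oracles used by the tests. These deliberately share no code
# with the package internals: dense likelihoods, generic optimizers, closed
# forms and enumeration.

# Dense multivariate-normal log-likelihood for the repeated-measures model
# y_i = mu + (x_i' beta) 1 + e_i, e_i ~ N(0, Sigma), evaluated from scratch.
oracle_dense_loglik <- function(mu, beta, Sigma, Y, X) {
  G <- nrow(Y); n <- ncol(Y)
  R <- Y - mu - matrix(X %*% beta, G, n, byrow = TRUE)
  ld <- determinant(Sigma, logarithm = TRUE)$modulus[1]
  Si <- solve(Sigma)
  -0.5 * (n * G * log(2 * pi) + n * ld + sum(Si * (R %*% t(R))))
}

# Brute-force ML fit by generic optimization over ALL parameters
# (gene means, slopes, covariance), no profiling, numerical gradients.
# structure "hcs": Sigma = D[(1-rho)I + rho J]D; "un": Sigma = L L' (Cholesky).
oracle_fit_dense <- function(Y, X, structure = c("hcs", "un")) {
  structure <- match.arg(structure)
  G <- nrow(Y); n <- ncol(Y); p <- ncol(X)
  comp <- colMeans(Y)
  b0 <- stats::coef(stats::lm(comp ~ X))
  mu0 <- rowMeans(Y) - mean(X %*% b0[-1])
  R0 <- Y - mu0 - matrix(X %*% b0[-1], G, n, byrow = TRUE)
  s0 <- sqrt(rowSums(R0^2) / n)
  make_sigma <- function(th) {
    if (structure == "hcs") {
      s <- exp(th[seq_len(G)])
      rho <- tanh(th[G + 1])
      M <- matrix(rho, G, G); diag(M) <- 1
      diag(s) %*% M %*% diag(s)
    } else {
      L <- matrix(0, G, G)
      L[lower.tri(L, diag = TRUE)] <- th
      diag(L) <- exp(diag(L))
      tcrossprod(L)
    }
  }
  th_cov0 <- if (structure == "hcs") c(log(s0), atanh(0.1)) else {
    L <- t(chol(tcrossprod(R0) / n))
    diag(L) <- log(diag(L))
    L[lower.tri(L, diag = TRUE)]
  }
  par0 <- c(mu0, b0[-1], th_cov0)
  nll <- function(par) {
    mu <- par[seq_len(G)]
    beta <- par[G + seq_len(p)]
    Sigma <- make_sigma(par[-(seq_len(G + p))])
    val <- tryCatch(-oracle_dense_loglik(mu, beta, Sigma, Y, X),
                    error = function(e) 1e12)
    if (!is.finite(val)) 1e12 else val
  }
  opt <- stats::optim(par0, nll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
  opt <- stats::optim(opt$par, nll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-15))
  list(logLik = -opt$value,
       mu = opt$par[seq_len(G)],
       beta = opt$par[G + seq_len(p)],
       Sigma = make_sigma(opt$par[-(seq_len(G + p))]))
}

# Closed-form scale-score correlation implied by a congeneric 2-factor model
# with uniform loading lam, factor correlation phi and k1/k2 items per scale
# (continuous items; discretization attenuates slightly).
oracle_scale_cor <- function(lam, phi, k1, k2) {
  v1 <- (1 + (k1 - 1) * lam^2) / k1
  v2 <- (1 + (k2 - 1) * lam^2) / k2
  lam^2 * phi / sqrt(v1 * v2)
}

# Exact two-sided binomial sign-test p-value by enumeration.
oracle_sign_p <- function(k, n) {
  probs <- stats::dbinom(0:n, n, 0.5)
  sum(probs[probs <= stats::dbinom(k, n, 0.5) + 1e-12])
}

# Generic-optimizer CFA oracle: minimizes the same ML discrepancy by
# Nelder-Mead/BFGS over a raw parameterization, no analytic gradients.
oracle_cfa_fml <- function(S, assignment) {
  p <- nrow(S)
  factors <- unique(assignment)
  q <- length(factors)
  idx <- match(assignment, factors)
  nphi <- q * (q - 1) / 2
  fml <- function(th) {
    lam <- th[seq_len(p)]
    psi <- th[p + seq_len(p)]
    if (any(psi <= 1e-8)) return(1e12)
    Phi <- diag(q)
    if (nphi) {
      ph <- th[2 * p + seq_len(nphi)]
      if (any(abs(ph) >= 1)) return(1e12)
      Phi[lower.tri(Phi)] <- ph
      Phi <- Phi + t(Phi) - diag(q)
      diag(Phi) <- 1
    }
    L <- matrix(0, p, q)
    L[cbind(seq_len(p), idx)] <- lam
    Sig <- L %*% Phi %*% t(L) + diag(psi)
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(1e12)
    val <- 2 * sum(log(diag(ch))) + sum(chol2inv(ch) * S) -
      determinant(S, logarithm = TRUE)$modulus[1] - p
    if (!is.finite(val)) 1e12 else val
  }
  th0 <- c(sqrt(diag(S)) * 0.7, diag(S) * 0.5, rep(0.4, nphi))
  opt <- stats::optim(th0, fml, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
  opt <- stats::optim(opt$par, fml, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  opt$value
}

# Small balanced long-format dataset with known structure, for model tests.
make_toy_long <- function(G = 4, n = 30, beta = c(wb = -0.4), rho = 0.3,
                          sigma = NULL, seed = 11) {
  set.seed(seed)
  if (is.null(sigma)) sigma <- seq(0.8, 1.4, length.out = G)
  x <- stats::rnorm(n)
  M <- matrix(rho, G, G); diag(M) <- 1
  E <- t(chol(M)) %*% matrix(stats::rnorm(G * n), G, n)
  Y <- (seq_len(G)) + sigma * E
  Y <- Y + matrix(x * beta[1], G, n, byrow = TRUE)
  dimnames(Y) <- list(paste0("g", seq_len(G)), paste0("s", seq_len(n)))
  long <- data.frame(
    subject_id = rep(colnames(Y), each = G),
    gene = rep(rownames(Y), n),
    value = as.vector(Y),
    wb = rep(x, each = G)
  )
  list(long = long, Y = Y, x = x, X = matrix(x, ncol = 1,
                                             dimnames = list(NULL, "wb")))
}
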