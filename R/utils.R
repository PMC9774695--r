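#' @importFrom stats rnorm runif quantile sd qt pf rWishart rgamma rexp
#'   uniroot lm anova aggregate setNames median pnorm dnorm
#' @importFrom utils read.csv write.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw from a multivariate normal distribution
#'
#' Cholesky-based sampler used throughout the simulator and the MCMC engine.
#' Accepts a positive semi-definite covariance (zero-variance directions give
#' exactly zero draws).
#'
#' @param n number of draws
#' @param mu mean vector
#' @param Sigma covariance matrix (symmetric PSD)
#' @return `n` x `length(mu)` matrix of draws
#' @keywords internal
rmvn <- function(n, mu, Sigma) {
  q <- length(mu)
  Sigma <- (Sigma + t(Sigma)) / 2
  if (all(Sigma == 0)) {
    return(matrix(rep(mu, each = n), nrow = n))
  }
  ch <- tryCatch(chol(Sigma), error = function(e) {
    ev <- eigen(Sigma, symmetric = TRUE)
    if (min(ev$values) < -1e-8 * max(abs(ev$values)))
      stop("covariance matrix is not positive semi-definite", call. = FALSE)
    ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), q) %*% t(ev$vectors)
  })
  z <- matrix(rnorm(n * q), n, q)
  sweep(z %*% ch, 2, mu, `+`)
}

# Inverse-Wishart draw via stats::rWishart: X ~ IW(nu, S) <=> X^-1 ~ W(nu, S^-1)
rinvwishart <- function(nu, S) {
  W <- rWishart(1, nu, chol2inv(chol(S)))[, , 1]
  chol2inv(chol(W))
}

# Gauss-Legendre nodes/weights on [a, b]
gauss_legendre <- function(n, a, b) {
  gl <- pracma::gaussLegendre(n, a, b)
  list(nodes = gl$x, weights = gl$w)
}

# split-Rhat (Gelman et al.) for a vector of draws from `chains` chains laid
# out consecutively; each chain is split in half.
split_rhat <- function(x, chains = 1L) {
  m <- length(x) %/% chains
  if (m < 4) return(NA_real_)
  halves <- list()
  for (c in seq_len(chains)) {
    xc <- x[((c - 1) * m + 1):(c * m)]
    h <- length(xc) %/% 2
    halves <- c(halves, list(xc[1:h], xc[(h + 1):(2 * h)]))
  }
  nh <- length(halves)
  hlen <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  B <- hlen * stats::var(means)
  Wv <- mean(vars)
  if (Wv <= 0) return(1)
  sqrt(((hlen - 1) / hlen * Wv + B / hlen) / Wv)
}

# deterministic child seeds below 2^31 derived from a master seed
derive_seed <- function(seed, index) {
  (as.integer(seed) %% 1000003L) * 1009L + 7L * as.integer(index) + 13L
}
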