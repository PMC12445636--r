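# Dense-matrix oracles, independent of the package's MME/REML code paths.

# restricted log-likelihood from the V-matrix definition
dense_reml_loglik <- function(X, V, y) {
  n <- length(y)
  X <- as.matrix(X)
  Vi <- solve(V)
  XVX <- crossprod(X, Vi %*% X)
  b <- solve(XVX, crossprod(X, Vi %*% y))
  r <- y - X %*% b
  as.numeric(-0.5 * ((n - ncol(X)) * log(2 * pi) +
                       determinant(V, logarithm = TRUE)$modulus +
                       determinant(XVX, logarithm = TRUE)$modulus +
                       crossprod(r, Vi %*% r)))
}

# GLS fixed effects and conditional-mean random effects
dense_gls_blup <- function(X, Zlist, Glist, Rvec, y) {
  n <- length(y)
  V <- diag(Rvec, n)
  for (i in seq_along(Zlist)) {
    Zi <- as.matrix(Zlist[[i]])
    V <- V + Zi %*% Glist[[i]] %*% t(Zi)
  }
  Vi <- solve(V)
  X <- as.matrix(X)
  XVX <- crossprod(X, Vi %*% X)
  b <- solve(XVX, crossprod(X, Vi %*% y))
  r <- Vi %*% (y - X %*% b)
  u <- lapply(seq_along(Zlist), function(i) {
    as.numeric(Glist[[i]] %*% crossprod(as.matrix(Zlist[[i]]), r))
  })
  list(beta = as.numeric(b), u = u, V = V)
}

# V matrix implied by a design bundle and covariance structure
dense_V <- function(design, cov, A) {
  n <- design$n
  V <- diag(cov$sigma_e2[design$cls], n)
  if (!is.null(cov$Sigma_a)) {
    Za <- as.matrix(design$Za)
    V <- V + Za %*% kronecker(A, as.matrix(cov$Sigma_a)) %*% t(Za)
  }
  if (!is.null(cov$Sigma_pe)) {
    Zp <- as.matrix(design$Zpe)
    V <- V + Zp %*% kronecker(diag(design$m), as.matrix(cov$Sigma_pe)) %*% t(Zp)
  }
  if (!is.null(cov$sigma_hys2)) {
    Zh <- as.matrix(design$Zhys)
    V <- V + Zh %*% diag(rep(cov$sigma_hys2, design$q_hys),
                         design$q_hys * design$d) %*% t(Zh)
  }
  if (!is.null(cov$sigma_clt2)) {
    Zc <- as.matrix(design$Zclt)
    V <- V + Zc %*% diag(rep(cov$sigma_clt2, design$q_clt),
                         design$q_clt * design$d) %*% t(Zc)
  }
  V
}

# random pedigree generator for property tests: founders plus random
# later animals with randomly known/unknown parents
random_pedigree <- function(n, p_known = 0.8, n_founders = max(3L, n %/% 5L)) {
  id <- paste0("A", seq_len(n))
  sire <- dam <- rep("0", n)
  for (i in (n_founders + 1L):n) {
    if (stats::runif(1) < p_known) sire[i] <- id[sample(i - 1L, 1L)]
    if (stats::runif(1) < p_known) {
      cand <- setdiff(seq_len(i - 1L), match(sire[i], id))
      if (length(cand)) dam[i] <- id[sample(cand, 1L)]
    }
  }
  as_pedigree(data.frame(animal = id, sire = sire, dam = dam), quiet = TRUE)
}
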