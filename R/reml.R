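# REML estimation for the repeatability animal model and the constrained
# trivariate age-class model.
#
# Criterion (restricted log-likelihood), evaluated through the mixed-model
# equations:
#   -2 l = (n-p) log 2pi + log|R| + log|G| + log|M| + y'Py
# with M the full MME coefficient matrix and y'Py = y'R^-1 y - sol'rhs.
# Optimisation: component-wise EM warm start (monotone), then
# average-information (AI) Newton steps with step halving. Both updates
# need the prediction-error covariance C = M^-1, computed densely once per
# iteration; every trace the updates need is a sparse-weighted sum over C.

#' REML optimiser settings
#'
#' @param max_iter iteration cap (EM + AI together).
#' @param tol_loglik relative log-likelihood change declaring convergence.
#' @param tol_param maximum relative parameter change declaring convergence.
#' @param em_iters number of pure EM warm-up iterations before switching to
#'   average-information steps.
#' @param tol_flat absolute log-likelihood change below which an iteration
#'   counts as likelihood-flat (well under any meaningful likelihood-ratio
#'   difference).
#' @param flat_iters consecutive flat iterations after which the fit is
#'   declared converged even if parameters still drift along a flat ridge.
#' @param verbose print the iteration trace.
#' @export
reml_control <- function(max_iter = 200L, tol_loglik = 1e-8,
                         tol_param = 1e-6, em_iters = 5L,
                         tol_flat = 3e-3, flat_iters = 3L, verbose = FALSE) {
  list(max_iter = as.integer(max_iter), tol_loglik = tol_loglik,
       tol_param = tol_param, em_iters = as.integer(em_iters),
       tol_flat = tol_flat, flat_iters = as.integer(flat_iters),
       verbose = isTRUE(verbose))
}

# ---- parameter vector <-> cov_structure -----------------------------------

.vech <- function(M) M[lower.tri(M, diag = TRUE)]

.unvech <- function(v, d) {
  M <- matrix(0, d, d)
  M[lower.tri(M, diag = TRUE)] <- v
  M <- M + t(M)
  diag(M) <- diag(M) / 2
  M
}

.vech_pairs <- function(d) {
  kl <- which(lower.tri(diag(d), diag = TRUE), arr.ind = TRUE)
  kl[, c(2L, 1L), drop = FALSE]   # (k = col, l = row) -> pairs (k <= l)
}

.param_layout <- function(design) {
  d <- design$d
  terms <- design$random
  types <- character(0); ks <- integer(0); ls <- integer(0); nm <- character(0)
  addmat <- function(type) {
    pr <- .vech_pairs(d)
    types <<- c(types, rep(type, nrow(pr)))
    ks <<- c(ks, pr[, 1L]); ls <<- c(ls, pr[, 2L])
    nm <<- c(nm, sprintf("%s:T%dT%d", type, pr[, 1L], pr[, 2L]))
  }
  addvec <- function(type) {
    types <<- c(types, rep(type, d))
    ks <<- c(ks, seq_len(d)); ls <<- c(ls, seq_len(d))
    nm <<- c(nm, sprintf("%s:T%d", type, seq_len(d)))
  }
  if ("animal" %in% terms) addmat("a")
  if ("pe" %in% terms) addmat("pe")
  if ("hys" %in% terms) addvec("hys")
  if ("clt" %in% terms) addvec("clt")
  addvec("e")
  list(type = types, k = ks, l = ls, names = nm, n = length(types), d = d)
}

.theta_to_cov <- function(theta, pl) {
  d <- pl$d
  g <- function(tp) theta[pl$type == tp]
  Sa <- if (any(pl$type == "a")) .unvech(g("a"), d) else NULL
  Spe <- if (any(pl$type == "pe")) .unvech(g("pe"), d) else NULL
  cov_structure(Sigma_a = Sa, Sigma_pe = Spe,
                sigma_hys2 = if (any(pl$type == "hys")) g("hys") else NULL,
                sigma_clt2 = if (any(pl$type == "clt")) g("clt") else NULL,
                sigma_e2 = g("e"))
}

.cov_to_theta <- function(cov, pl) {
  th <- numeric(pl$n)
  if (any(pl$type == "a")) th[pl$type == "a"] <- .vech(as.matrix(cov$Sigma_a))
  if (any(pl$type == "pe")) th[pl$type == "pe"] <- .vech(as.matrix(cov$Sigma_pe))
  if (any(pl$type == "hys")) th[pl$type == "hys"] <- cov$sigma_hys2
  if (any(pl$type == "clt")) th[pl$type == "clt"] <- cov$sigma_clt2
  th[pl$type == "e"] <- cov$sigma_e2
  stats::setNames(th, pl$names)
}

# symmetric eigenvalue clipping keeping matrices safely positive definite
.psd_clip <- function(M, floor_v) {
  M <- (M + t(M)) / 2
  ev <- eigen(M, symmetric = TRUE)
  lo <- max(1e-8 * sum(pmax(diag(M), 0)), floor_v)
  if (min(ev$values) >= lo) return(M)
  ev$vectors %*% (pmax(ev$values, lo) * t(ev$vectors))
}

# map an unconstrained proposal back into the feasible set
.project_theta <- function(theta, pl, floor_v) {
  for (tp in c("a", "pe")) {
    if (any(pl$type == tp)) {
      M <- .psd_clip(.unvech(theta[pl$type == tp], pl$d), floor_v)
      theta[pl$type == tp] <- .vech(M)
    }
  }
  for (tp in c("hys", "clt", "e")) {
    if (any(pl$type == tp)) theta[pl$type == tp] <- pmax(theta[pl$type == tp], floor_v)
  }
  theta
}

#' Restricted log-likelihood at given variance components
#'
#' Evaluates the REML criterion through the sparse mixed-model equations:
#' `-2l = (n-p) log(2 pi) + log|R| + log|G| + log|M| + y'Py`, identical to
#' the dense definition based on `log|V|`, `log|X'V^-1 X|` and the
#' residual quadratic form.
#'
#' @inheritParams assemble_and_solve
#' @return Scalar restricted log-likelihood.
#' @export
reml_loglik <- function(cov, design, Ainv, y = design$y) {
  .mme_solve_sparse(design, cov, Ainv, y)$loglik
}

# sum over the sparse pattern of Q of Q * C, with C given densely and the
# pattern's rows/columns living at an offset
.trace_QC <- function(qi, qj, qx, C, off_r, off_c) {
  sum(qx * C[cbind(off_r + qi, off_c + qj)])
}

# ---- the engine -----------------------------------------------------------

.reml_engine <- function(design, Ainv, init, opts, y = design$y) {
  pl <- .param_layout(design)
  d <- pl$d
  n <- design$n
  cls <- design$cls
  layout <- .mme_layout(design, init)
  W <- layout$W
  blocks <- layout$blocks
  ntot <- layout$ntot
  has <- function(tp) !is.null(blocks[[tp]])
  off <- vapply(c("fixed", "animal", "pe", "hys", "clt"),
                function(b) if (!is.null(blocks[[b]])) blocks[[b]][1L] - 1L else NA_integer_,
                0L)
  vscale <- stats::var(y)
  floor_v <- 1e-8 * vscale
  logdet_A <- if (has("animal")) .logdet_A_from_inv(Ainv) else NULL

  ai_full <- as(as(Ainv, "generalMatrix"), "TsparseMatrix")
  ai_i <- ai_full@i + 1L; ai_j <- ai_full@j + 1L; ai_x <- ai_full@x
  n_c <- tabulate(cls, d)

  # ---- cached sparse scaffolding: the MME coefficient matrix is
  # reassembled from fixed triplet patterns at every parameter value ------
  wtw <- lapply(seq_len(d), function(c3) {
    Q <- as(as(Matrix::crossprod(W[cls == c3, , drop = FALSE]),
               "generalMatrix"), "TsparseMatrix")
    list(i = Q@i + 1L, j = Q@j + 1L, x = Q@x)
  })
  wty <- lapply(seq_len(d), function(c3) {
    as.numeric(Matrix::crossprod(W[cls == c3, , drop = FALSE], y[cls == c3]))
  })
  y2_c <- vapply(seq_len(d), function(c3) sum(y[cls == c3]^2), 0)

  tri_i <- unlist(lapply(wtw, `[[`, "i"))
  tri_j <- unlist(lapply(wtw, `[[`, "j"))
  kl_grid <- expand.grid(k = seq_len(d), l = seq_len(d))
  if (has("animal")) {
    ga_i <- integer(0); ga_j <- integer(0); ga_k <- integer(0); ga_l <- integer(0)
    for (g in seq_len(nrow(kl_grid))) {
      k <- kl_grid$k[g]; l <- kl_grid$l[g]
      ga_i <- c(ga_i, off["animal"] + (ai_i - 1L) * d + k)
      ga_j <- c(ga_j, off["animal"] + (ai_j - 1L) * d + l)
      ga_k <- c(ga_k, rep(k, length(ai_x))); ga_l <- c(ga_l, rep(l, length(ai_x)))
    }
    tri_i <- c(tri_i, ga_i); tri_j <- c(tri_j, ga_j)
  }
  if (has("pe")) {
    ib <- rep(seq_len(design$m), each = d * d)
    gp_k <- rep(kl_grid$k, design$m); gp_l <- rep(kl_grid$l, design$m)
    gp_i <- off["pe"] + (ib - 1L) * d + gp_k
    gp_j <- off["pe"] + (ib - 1L) * d + gp_l
    tri_i <- c(tri_i, gp_i); tri_j <- c(tri_j, gp_j)
  }
  iid_cls <- list()
  for (tp in c("hys", "clt")) {
    if (!has(tp)) next
    q <- design[[paste0("q_", tp)]]
    cols <- off[tp] + seq_len(q * d)
    iid_cls[[tp]] <- rep(seq_len(d), q)
    tri_i <- c(tri_i, cols); tri_j <- c(tri_j, cols)
  }

  mme_x <- function(cov, Sai, Spi) {
    xs <- unlist(lapply(seq_len(d), function(c3) wtw[[c3]]$x / cov$sigma_e2[c3]))
    if (has("animal")) xs <- c(xs, rep(ai_x, d * d) * Sai[cbind(ga_k, ga_l)])
    if (has("pe")) xs <- c(xs, Spi[cbind(gp_k, gp_l)])
    for (tp in c("hys", "clt")) {
      if (!has(tp)) next
      s2 <- if (tp == "hys") cov$sigma_hys2 else cov$sigma_clt2
      xs <- c(xs, 1 / s2[iid_cls[[tp]]])
    }
    xs
  }
  logdetG_R <- function(cov) {
    lg <- 0
    if (has("animal")) {
      lg <- lg + d * logdet_A +
        design$n_a * as.numeric(determinant(as.matrix(cov$Sigma_a), TRUE)$modulus)
    }
    if (has("pe")) {
      lg <- lg + design$m *
        as.numeric(determinant(as.matrix(cov$Sigma_pe), TRUE)$modulus)
    }
    for (tp in c("hys", "clt")) {
      if (!has(tp)) next
      s2 <- if (tp == "hys") cov$sigma_hys2 else cov$sigma_clt2
      lg <- lg + design[[paste0("q_", tp)]] * sum(log(s2))
    }
    list(logdetG = lg, logdetR = sum(n_c * log(cov$sigma_e2)))
  }
  mme_rhs <- function(cov) {
    Reduce(`+`, lapply(seq_len(d), function(c3) wty[[c3]] / cov$sigma_e2[c3]))
  }
  const_ll <- -0.5 * (n - design$p) * log(2 * pi)
  # cheap likelihood-only evaluation via sparse Cholesky
  fast_ll <- function(theta_try) {
    cov <- tryCatch(.theta_to_cov(theta_try, pl), error = function(e) NULL)
    if (is.null(cov)) return(-Inf)
    Sai <- if (has("animal")) tryCatch(.psolve(cov$Sigma_a), error = function(e) NULL) else NULL
    Spi <- if (has("pe")) tryCatch(.psolve(cov$Sigma_pe), error = function(e) NULL) else NULL
    if ((has("animal") && is.null(Sai)) || (has("pe") && is.null(Spi))) return(-Inf)
    M <- Matrix::sparseMatrix(i = tri_i, j = tri_j, x = mme_x(cov, Sai, Spi),
                              dims = c(ntot, ntot))
    fac <- tryCatch(Matrix::Cholesky(Matrix::forceSymmetric(M), LDL = FALSE,
                                     perm = TRUE),
                    error = function(e) NULL)
    if (is.null(fac)) return(-Inf)
    rhs <- mme_rhs(cov)
    sol <- as.numeric(Matrix::solve(fac, rhs))
    ld <- logdetG_R(cov)
    yPy <- sum(y2_c / cov$sigma_e2) - sum(sol * rhs)
    logdetM <- 2 * as.numeric(Matrix::determinant(fac, sqrt = TRUE)$modulus)
    const_ll - 0.5 * (ld$logdetR + ld$logdetG + logdetM + yPy)
  }

  theta <- .project_theta(.cov_to_theta(init, pl), pl, floor_v)
  prev_ll <- -Inf
  prev_theta <- theta
  tracedf <- data.frame()
  converged <- FALSE
  flat_count <- 0L
  final <- NULL

  for (it in seq_len(opts$max_iter)) {
    cov <- .theta_to_cov(theta, pl)
    Sai <- if (has("animal")) .psolve(cov$Sigma_a) else NULL
    Spi <- if (has("pe")) .psolve(cov$Sigma_pe) else NULL
    M <- Matrix::sparseMatrix(i = tri_i, j = tri_j, x = mme_x(cov, Sai, Spi),
                              dims = c(ntot, ntot))
    Md <- as.matrix(M)
    ch <- chol(Md)
    logdetM <- 2 * sum(log(diag(ch)))
    rhs <- mme_rhs(cov)
    sol <- backsolve(ch, backsolve(ch, rhs, transpose = TRUE))
    C <- chol2inv(ch)
    ld <- logdetG_R(cov)
    yPy <- sum(y2_c / cov$sigma_e2) - sum(sol * rhs)
    ll <- const_ll - 0.5 * (ld$logdetR + ld$logdetG + logdetM + yPy)
    rvec <- cov$sigma_e2[cls]
    ehat <- y - as.numeric(W %*% sol)
    r <- ehat / rvec

    # ---- traces and BLUP quadratics --------------------------------------
    U <- P <- T_a <- T_pe <- Quad_a <- Quad_pe <- NULL
    if (has("animal")) {
      U <- matrix(sol[blocks$animal], nrow = d)       # class x animal
      Quad_a <- tcrossprod(as.matrix(U %*% Ainv), U)
      T_a <- matrix(0, d, d)
      for (k in seq_len(d)) for (l in seq_len(d)) {
        T_a[k, l] <- .trace_QC(
          (ai_i - 1L) * d + k, (ai_j - 1L) * d + l, ai_x, C,
          off["animal"], off["animal"])
      }
    }
    if (has("pe")) {
      P <- matrix(sol[blocks$pe], nrow = d)
      Quad_pe <- tcrossprod(P)
      T_pe <- matrix(0, d, d)
      ip <- seq_len(design$m)
      for (k in seq_len(d)) for (l in seq_len(d)) {
        T_pe[k, l] <- sum(C[cbind(off["pe"] + (ip - 1L) * d + k,
                                  off["pe"] + (ip - 1L) * d + l)])
      }
    }
    tr_iid <- list(); quad_iid <- list(); Um_iid <- list()
    for (tp in c("hys", "clt")) {
      if (!has(tp)) next
      q <- design[[paste0("q_", tp)]]
      Hm <- matrix(sol[blocks[[tp]]], nrow = d)
      iq <- seq_len(q)
      tr_iid[[tp]] <- vapply(seq_len(d), function(c3) {
        sum(C[cbind(off[tp] + (iq - 1L) * d + c3, off[tp] + (iq - 1L) * d + c3)])
      }, 0)
      quad_iid[[tp]] <- rowSums(Hm^2)
      Um_iid[[tp]] <- Hm
    }
    ss_e <- vapply(seq_len(d), function(c3) sum(ehat[cls == c3]^2), 0)
    tr_e <- vapply(seq_len(d), function(c3) {
      .trace_QC(wtw[[c3]]$i, wtw[[c3]]$j, wtw[[c3]]$x, C, 0L, 0L)
    }, 0)

    tracedf <- rbind(tracedf, data.frame(iter = it, loglik = ll))
    if (opts$verbose) {
      message(sprintf("it %3d  logL %.6f  %s", it, ll,
                      paste(signif(theta, 4), collapse = " ")))
    }

    # ---- gradient and AI matrix (needed for SEs even at convergence) -----
    grad <- numeric(pl$n)
    Fm <- matrix(0, n, pl$n)
    for (ip in seq_len(pl$n)) {
      tp <- pl$type[ip]; k <- pl$k[ip]; l <- pl$l[ip]
      if (tp %in% c("a", "pe")) {
        Sinv <- if (tp == "a") Sai else Spi
        Tm <- if (tp == "a") T_a else T_pe
        nlev <- if (tp == "a") design$n_a else design$m
        map <- if (tp == "a") design$rec_animal else design$rec_boar
        V1 <- Sinv %*% (if (tp == "a") U else P)
        B <- matrix(0, d, d); B[k, l] <- B[l, k] <- 1
        if (k == l) B[k, k] <- 1
        S1 <- Sinv %*% B %*% Sinv
        trPV <- nlev * sum(B * Sinv) - sum(S1 * Tm)
        wv <- B %*% V1
        Fm[, ip] <- wv[cbind(cls, map)]
      } else if (tp %in% c("hys", "clt")) {
        s2 <- if (tp == "hys") cov$sigma_hys2[k] else cov$sigma_clt2[k]
        q <- design[[paste0("q_", tp)]]
        trPV <- (q - tr_iid[[tp]][k] / s2) / s2
        f <- numeric(n)
        sel <- cls == k
        f[sel] <- Um_iid[[tp]][k, design[[paste0("rec_", tp)]][sel]] / s2
        Fm[, ip] <- f
      } else {             # residual class k
        s2 <- cov$sigma_e2[k]
        trPV <- n_c[k] / s2 - tr_e[k] / s2^2
        Fm[, ip] <- r * (cls == k)
      }
      grad[ip] <- -0.5 * (trPV - sum(r * Fm[, ip]))
    }
    St <- as.matrix(Matrix::crossprod(W, Fm / rvec))
    Z2 <- backsolve(ch, backsolve(ch, St, transpose = TRUE))
    PF <- (Fm - as.matrix(W %*% Z2)) / rvec
    AI <- 0.5 * crossprod(Fm, PF)
    AI <- (AI + t(AI)) / 2

    # ---- convergence ------------------------------------------------------
    # Besides the joint (loglik, parameter) criterion, accept convergence
    # when the likelihood has been flat for several consecutive iterations:
    # with a near-singular Sigma the optimum lies on a likelihood-flat
    # ridge along which EM keeps drifting without changing the fit.
    rel_ll <- abs(ll - prev_ll) / (abs(ll) + 1e-10)
    rel_par <- max(abs(theta - prev_theta) / (abs(prev_theta) + floor_v + 1e-12))
    is_flat <- it > 1L && (rel_ll < opts$tol_loglik || abs(ll - prev_ll) < opts$tol_flat)
    flat_count <- if (is_flat) flat_count + 1L else 0L
    final <- list(cov = cov, theta = theta, loglik = ll, sol = sol, C = C,
                  grad = grad, AI = AI, it = it)
    if ((it > 1L && rel_ll < opts$tol_loglik && rel_par < opts$tol_param) ||
        (it > opts$em_iters + 1L && flat_count >= opts$flat_iters)) {
      converged <- TRUE
      break
    }

    # ---- update -----------------------------------------------------------
    em_update <- function() {
      th <- theta
      if (has("animal")) th[pl$type == "a"] <- .vech((Quad_a + T_a) / design$n_a)
      if (has("pe")) th[pl$type == "pe"] <- .vech((Quad_pe + T_pe) / design$m)
      for (tp in c("hys", "clt")) {
        if (has(tp)) {
          th[pl$type == tp] <- (quad_iid[[tp]] + tr_iid[[tp]]) / design[[paste0("q_", tp)]]
        }
      }
      th[pl$type == "e"] <- (ss_e + tr_e) / n_c
      th
    }
    prev_ll <- ll
    prev_theta <- theta
    th_em1 <- .project_theta(em_update(), pl, floor_v)
    if (it <= opts$em_iters) {
      theta <- th_em1
      next
    }
    # over-relaxed EM (Aitken-style extrapolation along the EM direction)
    th_em <- th_em1
    ll_em <- fast_ll(th_em)
    for (alpha in c(2, 4, 8, 16)) {
      th_x <- .project_theta(theta + alpha * (th_em1 - theta), pl, floor_v)
      ll_x <- fast_ll(th_x)
      if (is.finite(ll_x) && ll_x > ll_em) {
        th_em <- th_x
        ll_em <- ll_x
      } else break
    }
    # AI Newton step, taken in the Cholesky factor of Sigma_a / Sigma_pe so
    # that positive semidefiniteness cannot be violated; Levenberg-Marquardt
    # damping ladder for ill-conditioned systems near a singular Sigma ridge
    J <- diag(pl$n)
    Lmat <- list()
    for (tp in c("a", "pe")) {
      if (!any(pl$type == tp)) next
      idx <- which(pl$type == tp)
      S <- .unvech(theta[idx], d)
      L <- t(chol(.psd_clip(S, floor_v)))
      Lmat[[tp]] <- L
      pr <- .vech_pairs(d)                 # (k, l) with k <= l: entry (row l, col k)
      Jm <- matrix(0, length(idx), length(idx))
      for (i in seq_len(nrow(pr))) {
        ri <- pr[i, 2L]; ci <- pr[i, 1L]
        for (j in seq_len(nrow(pr))) {
          rj <- pr[j, 2L]; cj <- pr[j, 1L]
          Jm[i, j] <- (ri == rj) * L[ci, cj] + (ci == rj) * L[ri, cj]
        }
      }
      J[idx, idx] <- Jm
    }
    g_phi <- as.numeric(crossprod(J, grad))
    A_phi <- crossprod(J, AI %*% J)
    A_phi <- (A_phi + t(A_phi)) / 2
    phi_step <- function(delta, step) {
      cand <- theta
      for (tp in c("a", "pe")) {
        if (!any(pl$type == tp)) next
        idx <- which(pl$type == tp)
        Lc <- Lmat[[tp]]
        Lc[lower.tri(Lc, diag = TRUE)] <-
          Lc[lower.tri(Lc, diag = TRUE)] + step * delta[idx]
        cand[idx] <- .vech(tcrossprod(Lc))
      }
      sc <- which(!pl$type %in% c("a", "pe"))
      cand[sc] <- cand[sc] + step * delta[sc]
      .project_theta(cand, pl, floor_v)
    }
    best_th <- th_em
    best_ll <- ll_em
    dA <- diag(A_phi)
    dA[dA <= 0] <- max(dA, 1e-12)
    for (lambda in c(0, 1e-4, 1e-2, 1, 100)) {
      delta <- tryCatch(solve(A_phi + lambda * diag(dA, length(dA)), g_phi),
                        error = function(e) NULL)
      if (is.null(delta) || !all(is.finite(delta))) next
      improved <- FALSE
      for (step in c(1, 0.5, 0.25, 0.1)) {
        cand <- phi_step(delta, step)
        ll_try <- fast_ll(cand)
        if (is.finite(ll_try) && ll_try > best_ll) {
          best_th <- cand
          best_ll <- ll_try
          improved <- TRUE
          break
        }
      }
      if (improved) break
    }
    if (opts$verbose) {
      message(sprintf("   EM +%.3e  best +%.3e (%s)", ll_em - ll, best_ll - ll,
                      if (identical(best_th, th_em)) "EM" else "AI"))
    }
    if (best_ll > -Inf && best_ll >= ll - 1e-8) {
      theta <- best_th
    } else {
      theta <- th_em1    # plain EM never decreases the likelihood
    }
  }

  if (!converged) {
    warning("REML did not converge in ", opts$max_iter,
            " iterations; returning best iterate")
  }

  # SE machinery: invert AI, excluding parameters pinned at the boundary
  theta <- final$theta
  pinned <- theta <= floor_v * 1.01 & pl$type %in% c("hys", "clt", "e") |
    (pl$type %in% c("a", "pe") & pl$k == pl$l & theta <= floor_v * 1.01)
  ai_inv <- matrix(NA_real_, pl$n, pl$n, dimnames = list(pl$names, pl$names))
  free <- which(!pinned)
  if (length(free)) {
    inv <- tryCatch(solve(final$AI[free, free, drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(inv)) {
      ev <- eigen(final$AI[free, free, drop = FALSE], symmetric = TRUE)
      pos <- ev$values > max(ev$values) * 1e-12
      inv <- ev$vectors[, pos, drop = FALSE] %*%
        (t(ev$vectors[, pos, drop = FALSE]) / ev$values[pos])
    }
    ai_inv[free, free] <- inv
  }

  sol_un <- .unpack_solution(design, layout, final$sol)
  sol_un$C_xx <- final$C[blocks$fixed, blocks$fixed, drop = FALSE]
  sol_un$fitted <- as.numeric(W %*% final$sol)
  sol_un$residuals <- y - sol_un$fitted
  sol_un$design <- design
  sol_un$cov <- final$cov
  class(sol_un) <- "solution_set"

  structure(list(
    estimates = final$cov, theta = stats::setNames(theta, pl$names),
    param = pl, loglik = final$loglik, ai = final$AI, ai_inv = ai_inv,
    gradient = final$grad, pinned = stats::setNames(pinned, pl$names),
    trace = tracedf, converged = converged, iterations = final$it,
    sol = sol_un, n_records = n, n_per_class = n_c, vscale = vscale),
    class = "reml_fit")
}

# index of a per-class component in the parameter vector
.pindex <- function(fit, type, k, l = k) {
  pl <- fit$param
  which(pl$type == type & ((pl$k == k & pl$l == l) | (pl$k == l & pl$l == k)))
}

# default starting values: equal split of the per-class phenotypic variance
.default_init <- function(design, y) {
  d <- design$d
  terms <- design$random
  v <- vapply(seq_len(d), function(c3) stats::var(y[design$cls == c3]), 0)
  ncomp <- length(terms) + 1L
  share <- v / ncomp
  mk <- function() {
    S <- diag(share, d)
    if (d > 1L) {
      for (k in 1:(d - 1)) for (l in (k + 1):d) {
        S[k, l] <- S[l, k] <- 0.5 * sqrt(share[k] * share[l])
      }
    }
    S
  }
  cov_structure(
    Sigma_a = if ("animal" %in% terms) mk() else NULL,
    Sigma_pe = if ("pe" %in% terms) mk() else NULL,
    sigma_hys2 = if ("hys" %in% terms) share else NULL,
    sigma_clt2 = if ("clt" %in% terms) share else NULL,
    sigma_e2 = share)
}

#' Univariate REML for the repeatability animal model
#'
#' Estimates the variance components of
#' `y = Xb + Za + Wp (+ Hh + Cc) + e` with `a ~ N(0, A sigma_a2)` by
#' EM-REML warm-up followed by average-information Newton steps with step
#' halving; negative proposals are truncated toward the boundary.
#'
#' @param design a [build_design()] bundle with `class_structure = "off"`.
#' @param y response (defaults to the design's stored response).
#' @param Ainv sparse A-inverse from [a_inverse()].
#' @param init starting [cov_structure()]; default splits the phenotypic
#'   variance equally across the included components.
#' @param opts a [reml_control()].
#' @return A `reml_fit`: `estimates` (cov_structure), `theta` (named
#'   parameter vector), `loglik`, `ai` / `ai_inv` (average-information
#'   matrix and sampling covariance of the estimates), `trace`
#'   (iteration log), `converged`, and `sol` (solutions at convergence).
#' @export
fit_univariate <- function(design, y = design$y, Ainv, init = NULL,
                           opts = reml_control()) {
  stopifnot(inherits(design, "design_bundle"))
  if (design$d != 1L) stop("design has a trivariate structure; use fit_trivariate()")
  if ("pe" %in% design$random && max(tabulate(design$rec_boar)) < 2L) {
    stop("permanent environment unidentifiable: no boar has repeated records")
  }
  if (is.null(init)) init <- .default_init(design, y)
  .reml_engine(design, Ainv, init, opts, y)
}

#' Trivariate age-class REML with constrained covariances
#'
#' Estimates unstructured 3 x 3 additive-genetic and permanent-
#' environment covariance matrices across the age classes together with
#' per-class herd-year-season, technician and residual variances, with
#' all cross-class covariances of the latter fixed to zero. Positive
#' semidefiniteness of the matrices is maintained by symmetric
#' eigenvalue clipping. Including the (unselected) early class in a
#' joint analysis is what corrects the variance components of the later
#' classes for phenotype-based culling.
#'
#' @inheritParams fit_univariate
#' @param design a [build_design()] bundle with
#'   `class_structure = "trivariate"`.
#' @return A `reml_fit` (see [fit_univariate()]); the cross-class
#'   covariances of class pairs no boar spans are flagged in
#'   `$unidentifiable_pairs`.
#' @export
fit_trivariate <- function(design, y = design$y, Ainv, init = NULL,
                           opts = reml_control()) {
  stopifnot(inherits(design, "design_bundle"))
  if (design$d != 3L) stop("design does not carry the trivariate class structure")
  seen <- table(design$rec_boar, design$cls) > 0
  bad <- list()
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    if (!any(seen[, pair[1]] & seen[, pair[2]])) bad <- c(bad, list(pair))
  }
  if (length(bad)) {
    warning("no boar spans class pair(s) ",
            paste(vapply(bad, function(p) paste0("T", p[1], "-T", p[2]), ""),
                  collapse = ", "), "; those covariances are unidentifiable")
  }
  if (is.null(init)) init <- .default_init(design, y)
  fit <- .reml_engine(design, Ainv, init, opts, y)
  fit$unidentifiable_pairs <- bad
  fit
}

#' Sampling standard errors of variance-component estimates
#'
#' Standard errors from the inverse average-information matrix; functions
#' of components (ratios, correlations, differences) get first-order
#' delta-method errors via [delta_se()].
#'
#' @param fit a `reml_fit`.
#' @return Named vector of standard errors (NA for parameters pinned at
#'   the boundary, which are excluded from the AI system).
#' @export
vc_se <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  stats::setNames(sqrt(pmax(diag(fit$ai_inv), 0)), fit$param$names)
}

#' Delta-method standard error of a function of variance components
#'
#' @param fit a `reml_fit`.
#' @param grad gradient of the function with respect to the full
#'   parameter vector (`fit$theta` order); entries for pinned boundary
#'   parameters are ignored.
#' @return Scalar standard error (NA if the needed AI block is singular).
#' @export
delta_se <- function(fit, grad) {
  stopifnot(inherits(fit, "reml_fit"), length(grad) == fit$param$n)
  use <- which(grad != 0)
  V <- fit$ai_inv[use, use, drop = FALSE]
  if (anyNA(V)) return(NA_real_)
  sqrt(max(0, grad[use] %*% V %*% grad[use]))
}
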