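#' Heritability, repeatability and phenotypic variance
#'
#' `sigma_p2` is the sum of the five variance components
#' (`a + pe + hys + clt + e`; absent terms contribute zero),
#' `h2 = sigma_a2 / sigma_p2` and `rep = (sigma_a2 + sigma_pe2) /
#' sigma_p2`. Standard errors are first-order delta-method errors from
#' the inverse average-information matrix when a `reml_fit` is supplied.
#'
#' @param fit a `reml_fit`, or a [cov_structure()] (then no SEs).
#' @return data.frame with one row per age class: `class`, `sigma_p2`,
#'   `h2`, `rep` and their standard errors.
#' @examples
#' gp <- genetic_ratios(cov_structure(Sigma_a = 47.4, Sigma_pe = 45.9,
#'                                    sigma_e2 = 59.6))
#' round(c(gp$sigma_p2, gp$h2, gp$rep), 2)  # 152.9 0.31 0.61
#' @export
genetic_ratios <- function(fit) {
  cov <- if (inherits(fit, "reml_fit")) fit$estimates else fit
  stopifnot(inherits(cov, "cov_structure"))
  d <- cov$d
  comp <- function(what, c3) {
    switch(what,
           a = if (is.null(cov$Sigma_a)) 0 else cov$Sigma_a[c3, c3],
           pe = if (is.null(cov$Sigma_pe)) 0 else cov$Sigma_pe[c3, c3],
           hys = if (is.null(cov$sigma_hys2)) 0 else cov$sigma_hys2[c3],
           clt = if (is.null(cov$sigma_clt2)) 0 else cov$sigma_clt2[c3],
           e = cov$sigma_e2[c3])
  }
  out <- data.frame(class = paste0("T", seq_len(d)),
                    sigma_p2 = NA_real_, h2 = NA_real_, rep = NA_real_,
                    se_sigma_p2 = NA_real_, se_h2 = NA_real_, se_rep = NA_real_)
  for (c3 in seq_len(d)) {
    va <- comp("a", c3); vpe <- comp("pe", c3)
    vp <- va + vpe + comp("hys", c3) + comp("clt", c3) + comp("e", c3)
    if (vp <= 0) stop("phenotypic variance must be > 0")
    out$sigma_p2[c3] <- vp
    out$h2[c3] <- va / vp
    out$rep[c3] <- (va + vpe) / vp
    if (inherits(fit, "reml_fit")) {
      pl <- fit$param
      idx <- function(tp) .pindex(fit, tp, c3)
      g_p <- numeric(pl$n)
      for (tp in intersect(unique(pl$type), c("a", "pe", "hys", "clt", "e"))) {
        i <- idx(tp); if (length(i)) g_p[i] <- 1
      }
      out$se_sigma_p2[c3] <- delta_se(fit, g_p)
      # d h2 / d sigma_a = (vp - va)/vp^2 ; d h2 / d other = -va/vp^2
      g_h <- g_p * (-va / vp^2)
      ia <- idx("a"); if (length(ia)) g_h[ia] <- (vp - va) / vp^2
      out$se_h2[c3] <- delta_se(fit, g_h)
      g_r <- g_p * (-(va + vpe) / vp^2)
      w <- (vp - va - vpe) / vp^2
      if (length(ia)) g_r[ia] <- w
      ipe <- idx("pe"); if (length(ipe)) g_r[ipe] <- w
      out$se_rep[c3] <- delta_se(fit, g_r)
    }
  }
  out
}

#' Correlation from a covariance and two variances
#'
#' `r = cov / sqrt(var_i * var_j)`. Values exceeding 1 in absolute value
#' by numerical noise (< 1e-6) are clipped and flagged with an attribute;
#' larger excursions are reported as-is with a warning.
#'
#' @param cov covariance between the two classes.
#' @param var_i,var_j the two variances (must be `> 0`).
#' @return Correlation (possibly with attribute `clipped = TRUE`).
#' @export
vc_correlation <- function(cov, var_i, var_j) {
  if (var_i <= 0 || var_j <= 0) stop("variances must be > 0")
  r <- cov / sqrt(var_i * var_j)
  if (abs(r) > 1) {
    if (abs(r) - 1 < 1e-6) {
      r <- sign(r)
      attr(r, "clipped") <- TRUE
    } else {
      warning("correlation outside [-1, 1]: ", format(r))
    }
  }
  r
}

#' Cross-class correlations of a trivariate fit
#'
#' Additive-genetic, permanent-environment and phenotypic correlations
#' for each class pair, with delta-method standard errors. The phenotypic
#' covariance between classes is `cov_a + cov_pe` (herd-year-season,
#' technician and residual cross-class covariances are structurally
#' zero).
#'
#' @param fit a trivariate `reml_fit`.
#' @return data.frame with `pair`, `r_a`, `se_r_a`, `r_pe`, `se_r_pe`,
#'   `r_p`, `se_r_p`.
#' @export
correlation_set <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  cov <- fit$estimates
  d <- cov$d
  if (d < 2L) stop("correlations need the trivariate structure")
  gp <- genetic_ratios(fit)
  pairs <- utils::combn(d, 2L)
  out <- data.frame(pair = apply(pairs, 2L, function(p) sprintf("T%d-T%d", p[1], p[2])),
                    r_a = NA_real_, se_r_a = NA_real_,
                    r_pe = NA_real_, se_r_pe = NA_real_,
                    r_p = NA_real_, se_r_p = NA_real_)
  corr_se <- function(tp, i, j, S) {
    # gradient of cov/sqrt(vi vj) wrt (cov, vi, vj)
    cv <- S[i, j]; vi <- S[i, i]; vj <- S[j, j]
    g <- numeric(fit$param$n)
    g[.pindex(fit, tp, i, j)] <- 1 / sqrt(vi * vj)
    g[.pindex(fit, tp, i)] <- -cv / (2 * vi * sqrt(vi * vj))
    g[.pindex(fit, tp, j)] <- -cv / (2 * vj * sqrt(vi * vj))
    delta_se(fit, g)
  }
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    if (!is.null(cov$Sigma_a)) {
      out$r_a[p] <- as.numeric(vc_correlation(cov$Sigma_a[i, j],
                                              cov$Sigma_a[i, i], cov$Sigma_a[j, j]))
      out$se_r_a[p] <- corr_se("a", i, j, cov$Sigma_a)
    }
    if (!is.null(cov$Sigma_pe)) {
      out$r_pe[p] <- as.numeric(vc_correlation(cov$Sigma_pe[i, j],
                                               cov$Sigma_pe[i, i], cov$Sigma_pe[j, j]))
      out$se_r_pe[p] <- corr_se("pe", i, j, cov$Sigma_pe)
    }
    cp <- (if (is.null(cov$Sigma_a)) 0 else cov$Sigma_a[i, j]) +
      (if (is.null(cov$Sigma_pe)) 0 else cov$Sigma_pe[i, j])
    out$r_p[p] <- as.numeric(vc_correlation(cp, gp$sigma_p2[i], gp$sigma_p2[j]))
  }
  out
}

#' Z-test for the difference of two variance components
#'
#' Assumes the difference of the two estimates is approximately normal:
#' `Z = (est_i - est_j) / se_diff`, two-sided
#' `p = 2 (1 - Phi(|Z|))`.
#'
#' @param est_i,est_j the two estimates.
#' @param se_diff standard error of the difference (`> 0`); with a joint
#'   fit use `sqrt(V_ii + V_jj - 2 V_ij)` from the AI-inverse.
#' @return list with `Z`, `p` and `minus_log10_p`.
#' @export
variance_diff_test <- function(est_i, est_j, se_diff) {
  if (se_diff <= 0) stop("se_diff must be > 0")
  Z <- (est_i - est_j) / se_diff
  p <- 2 * stats::pnorm(-abs(Z))
  list(Z = Z, p = p, minus_log10_p = -log10(p))
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha nominal level (0 < alpha < 1).
#' @param m number of tests (>= 1).
#' @return list with `threshold = alpha/m` and its `minus_log10`.
#' @examples
#' bonferroni_threshold(0.05, 144)   # 3.5e-4
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 1L) {
  if (m < 1L) stop("m must be >= 1")
  stopifnot(alpha > 0, alpha < 1)
  thr <- alpha / m
  list(threshold = thr, minus_log10 = -log10(thr))
}

#' Pairwise variance-difference tests across age classes
#'
#' Enumerates, for each trait fit, the pairwise cross-class differences
#' of the chosen components (default additive genetic, permanent
#' environment, residual and phenotypic: 4 components x 3 class pairs
#' per trait) and tests each with [variance_diff_test()], using the joint
#' sampling covariance of the two estimates. With the study's 12 traits
#' this enumeration yields 144 tests.
#'
#' @param fits named list of trivariate `reml_fit`s (one per trait).
#' @param components subset of `c("a", "pe", "e", "p")`.
#' @param alpha nominal level for the Bonferroni threshold.
#' @return data.frame with one row per test: trait, component, pair,
#'   estimates, `se_diff`, `Z`, `p`, `minus_log10_p`, `significant`.
#' @export
variance_test_table <- function(fits, components = c("a", "pe", "e", "p"),
                                alpha = 0.05) {
  components <- match.arg(components, c("a", "pe", "e", "p"), several.ok = TRUE)
  rows <- list()
  for (tr in names(fits)) {
    fit <- fits[[tr]]
    d <- fit$estimates$d
    pairs <- utils::combn(d, 2L)
    gp <- genetic_ratios(fit)
    for (comp in components) {
      for (pc in seq_len(ncol(pairs))) {
        i <- pairs[1L, pc]; j <- pairs[2L, pc]
        if (comp == "p") {
          est <- gp$sigma_p2
          g_i <- numeric(fit$param$n); g_j <- numeric(fit$param$n)
          for (tp in intersect(unique(fit$param$type), c("a", "pe", "hys", "clt", "e"))) {
            g_i[.pindex(fit, tp, i)] <- 1
            g_j[.pindex(fit, tp, j)] <- 1
          }
          sed <- delta_se(fit, g_i - g_j)
          ei <- est[i]; ej <- est[j]
        } else {
          idx_i <- .pindex(fit, comp, i); idx_j <- .pindex(fit, comp, j)
          if (!length(idx_i)) next
          g <- numeric(fit$param$n); g[idx_i] <- 1; g[idx_j] <- g[idx_j] - 1
          sed <- delta_se(fit, g)
          ei <- fit$theta[idx_i]; ej <- fit$theta[idx_j]
        }
        tst <- variance_diff_test(ei, ej, sed)
        rows[[length(rows) + 1L]] <-
          data.frame(trait = tr, component = comp,
                     pair = sprintf("T%d-T%d", i, j),
                     est_i = unname(ei), est_j = unname(ej), se_diff = sed,
                     Z = tst$Z, p = tst$p, minus_log10_p = tst$minus_log10_p)
      }
    }
  }
  out <- do.call(rbind, rows)
  thr <- bonferroni_threshold(alpha, nrow(out))
  out$significant <- out$p < thr$threshold
  attr(out, "threshold") <- thr
  out
}

#' Genetic-parameter report table
#'
#' One row per trait x age class with the phenotypic variance (annotated
#' with its ratio to the first class), heritability and repeatability
#' with standard errors — the layout of the study's variance-component
#' summary.
#'
#' @param fits named list of `reml_fit`s.
#' @return data.frame.
#' @export
report_genetic_parameters <- function(fits) {
  rows <- lapply(names(fits), function(tr) {
    gp <- genetic_ratios(fits[[tr]])
    gp$ratio_to_T1 <- gp$sigma_p2 / gp$sigma_p2[1L]
    cbind(trait = tr, gp)
  })
  do.call(rbind, rows)
}

#' Genetic-correlation report table
#'
#' One row per trait with the additive-genetic correlation (and SE) per
#' class pair.
#'
#' @param fits named list of trivariate `reml_fit`s.
#' @return data.frame.
#' @export
report_genetic_correlations <- function(fits) {
  rows <- lapply(names(fits), function(tr) {
    cs <- correlation_set(fits[[tr]])
    cbind(trait = tr, cs[, c("pair", "r_a", "se_r_a")])
  })
  do.call(rbind, rows)
}
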