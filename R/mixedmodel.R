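#' Model specification for the repeatability animal model
#'
#' Describes which response, fixed factors and random terms enter the
#' model `y = Xb + Za + Wp + Hh + Cc + e`. The fixed factor `"age"` is
#' derived from `age_month` (54 monthly classes in the full model) or,
#' with `class_structure = "trivariate"`, from the within-class month so
#' that each age class carries its own age factors (7, 10 and 37 levels
#' when all months are present). `"rest_class"` (15 one-day classes) and
#' `"month_of_year"` (12 classes) are taken from the record table.
#'
#' @param trait response column name.
#' @param fixed character vector of fixed factors; `"age"` is derived,
#'   anything else must be a column of the record table.
#' @param random subset of `c("animal", "pe", "hys", "clt")`.
#' @param class_structure `"off"` for the single-trait repeatability
#'   model, `"trivariate"` for the age-class model in which the animal,
#'   permanent-environment, herd-year-season, technician and residual
#'   terms are all class-specific.
#' @export
model_spec <- function(trait,
                       fixed = c("age", "rest_class", "month_of_year"),
                       random = c("animal", "pe", "hys", "clt"),
                       class_structure = c("off", "trivariate")) {
  class_structure <- match.arg(class_structure)
  random <- match.arg(random, c("animal", "pe", "hys", "clt"), several.ok = TRUE)
  structure(list(trait = trait, fixed = fixed, random = random,
                 class_structure = class_structure), class = "model_spec")
}

#' Build the design bundle for a record table
#'
#' Constructs sparse incidence matrices for the fixed factors (one
#' reference level dropped per factor, intercept retained) and for each
#' random term. Animal columns cover all pedigree animals, phenotyped or
#' not; in the trivariate structure every animal (and boar, herd-year-
#' season level, technician) has one column per age class.
#'
#' @param records record table; needs `boar`, `age_month` and the columns
#'   named in the spec (plus `age_class` when trivariate).
#' @param spec a [model_spec()].
#' @param ped the [as_pedigree()] the animal effect is structured by.
#' @return A `design_bundle` list holding the response `y`, the fixed
#'   block `X` with its level maps, the random incidence blocks and the
#'   record-to-level index vectors.
#' @export
build_design <- function(records, spec, ped) {
  stopifnot(inherits(spec, "model_spec"), inherits(ped, "pedigree"))
  if (nrow(records) == 0L) stop("empty record table")
  n <- nrow(records)
  trivar <- spec$class_structure == "trivariate"
  d <- if (trivar) 3L else 1L

  if (trivar) {
    if (!"age_class" %in% names(records)) {
      records$age_class <- assign_age_class(records$age_month)
    }
    cls <- as.integer(factor(records$age_class, levels = c("T1", "T2", "T3")))
    if (anyNA(cls)) stop("records with unassigned age class")
    if (length(unique(cls)) < 3L) stop("each age class must be non-empty")
  } else {
    cls <- rep(1L, n)
  }

  # fixed block: intercept + treatment-coded factors
  fixed_data <- list()
  for (f in spec$fixed) {
    fixed_data[[f]] <- if (f == "age") {
      if (trivar) {
        factor(sprintf("%s:%02d", records$age_class, records$age_month))
      } else {
        factor(records$age_month)
      }
    } else {
      if (!f %in% names(records)) stop("record column not found: ", f)
      if (anyNA(records[[f]])) stop("record with unmapped level in ", f)
      factor(records[[f]])
    }
  }
  xi <- rep(seq_len(n), 1L)
  xj <- rep(1L, n)
  colnames_x <- "(Intercept)"
  fixed_cols <- list()
  fixed_levels <- list()
  p <- 1L
  for (f in names(fixed_data)) {
    fac <- fixed_data[[f]]
    levs <- levels(fac)
    fixed_levels[[f]] <- levs
    if (length(levs) < 2L) { fixed_cols[[f]] <- integer(0); next }
    cols <- p + seq_len(length(levs) - 1L)
    fixed_cols[[f]] <- cols
    colnames_x <- c(colnames_x, paste0(f, "=", levs[-1L]))
    nonref <- which(as.integer(fac) > 1L)
    xi <- c(xi, nonref)
    xj <- c(xj, cols[as.integer(fac)[nonref] - 1L])
    p <- p + length(levs) - 1L
  }
  X <- Matrix::sparseMatrix(i = xi, j = xj, x = 1, dims = c(n, p),
                            dimnames = list(NULL, colnames_x))

  n_a <- nrow(ped)
  rec_animal <- unname(attr(ped, "id_map")[as.character(records$boar)])
  if (anyNA(rec_animal)) {
    stop("boar(s) not in pedigree: ",
         paste(utils::head(setdiff(records$boar, ped$id), 5L), collapse = ", "))
  }
  Za <- Matrix::sparseMatrix(i = seq_len(n), j = (rec_animal - 1L) * d + cls,
                             x = 1, dims = c(n, n_a * d))

  boar_ids <- ped$id[sort(unique(rec_animal))]
  m <- length(boar_ids)
  rec_boar <- match(records$boar, boar_ids)
  Zpe <- Matrix::sparseMatrix(i = seq_len(n), j = (rec_boar - 1L) * d + cls,
                              x = 1, dims = c(n, m * d))

  des <- list(y = as.numeric(records[[spec$trait]]),
              n = n, d = d, cls = cls, p = p,
              X = X, fixed_cols = fixed_cols, fixed_levels = fixed_levels,
              fixed_data = fixed_data,
              Za = Za, n_a = n_a, animal_ids = ped$id, rec_animal = rec_animal,
              Zpe = Zpe, m = m, boar_ids = boar_ids, rec_boar = rec_boar,
              random = intersect(c("animal", "pe", "hys", "clt"), spec$random),
              spec = spec)
  for (term in c("hys", "clt")) {
    if (term %in% spec$random) {
      if (!term %in% names(records)) stop("record column not found: ", term)
      fac <- factor(records[[term]])
      q <- nlevels(fac)
      des[[paste0("Z", term)]] <-
        Matrix::sparseMatrix(i = seq_len(n),
                             j = (as.integer(fac) - 1L) * d + cls,
                             x = 1, dims = c(n, q * d))
      des[[paste0("q_", term)]] <- q
      des[[paste0("rec_", term)]] <- as.integer(fac)
      des[[paste0(term, "_levels")]] <- levels(fac)
    }
  }
  if (anyNA(des$y)) stop("missing response values")
  class(des) <- "design_bundle"
  des
}

#' Variance-component structure
#'
#' Container for the (co)variance parameters of the model: `d x d`
#' additive-genetic and permanent-environment matrices (scalars in the
#' univariate model) and per-class herd-year-season, technician and
#' residual variances. Cross-class covariances of hys, clt and residual
#' are structurally zero.
#'
#' @param Sigma_a,Sigma_pe scalars (univariate) or 3 x 3 symmetric PSD
#'   matrices; `NULL` if the term is absent.
#' @param sigma_hys2,sigma_clt2 per-class variances (`NULL` if absent).
#' @param sigma_e2 per-class residual variances (required, `> 0`).
#' @export
cov_structure <- function(Sigma_a = NULL, Sigma_pe = NULL,
                          sigma_hys2 = NULL, sigma_clt2 = NULL,
                          sigma_e2) {
  d <- length(sigma_e2)
  asmat <- function(x) {
    if (is.null(x)) return(NULL)
    x <- as.matrix(x)
    if (length(x) == 1L && d > 1L) stop("class dimension mismatch")
    stopifnot(nrow(x) == d, ncol(x) == d)
    (x + t(x)) / 2
  }
  if (any(sigma_e2 <= 0)) stop("residual variances must be > 0")
  structure(list(Sigma_a = asmat(Sigma_a), Sigma_pe = asmat(Sigma_pe),
                 sigma_hys2 = sigma_hys2, sigma_clt2 = sigma_clt2,
                 sigma_e2 = as.numeric(sigma_e2), d = d),
            class = "cov_structure")
}

# ---- internal MME assembly ------------------------------------------------

# column layout: [fixed | animal | pe | hys? | clt?], animal-major within
# random blocks (class runs fastest)
.mme_layout <- function(design, cov) {
  d <- design$d
  terms <- design$random
  if (!is.null(cov)) {
    if (("animal" %in% terms) != !is.null(cov$Sigma_a) ||
        ("pe" %in% terms) != !is.null(cov$Sigma_pe) ||
        ("hys" %in% terms) != !is.null(cov$sigma_hys2) ||
        ("clt" %in% terms) != !is.null(cov$sigma_clt2)) {
      stop("cov_structure terms do not match the design's random terms")
    }
  }
  blocks <- list(fixed = seq_len(design$p))
  off <- design$p
  W <- design$X
  if ("animal" %in% terms) {
    blocks$animal <- off + seq_len(design$n_a * d); off <- off + design$n_a * d
    W <- cbind(W, design$Za)
  }
  if ("pe" %in% terms) {
    blocks$pe <- off + seq_len(design$m * d); off <- off + design$m * d
    W <- cbind(W, design$Zpe)
  }
  if ("hys" %in% terms) {
    blocks$hys <- off + seq_len(design$q_hys * d); off <- off + design$q_hys * d
    W <- cbind(W, design$Zhys)
  }
  if ("clt" %in% terms) {
    blocks$clt <- off + seq_len(design$q_clt * d); off <- off + design$q_clt * d
    W <- cbind(W, design$Zclt)
  }
  list(W = W, blocks = blocks, ntot = off)
}

.psolve <- function(S) {
  S <- as.matrix(S)
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) <= 0) stop("covariance matrix not positive definite")
  ev$vectors %*% (t(ev$vectors) / ev$values)
}

# G-inverse (without fixed rows), rvec and the log-determinants of G and R
.mme_ginv <- function(design, cov, Ainv, logdet_A = NULL) {
  d <- design$d
  pieces <- list(Matrix::Diagonal(design$p, 0))
  logdetG <- 0
  if (!is.null(cov$Sigma_a)) {
    Sai <- .psolve(cov$Sigma_a)
    pieces <- c(pieces, list(Matrix::kronecker(Ainv, Sai)))
    if (is.null(logdet_A)) logdet_A <- .logdet_A_from_inv(Ainv)
    logdetG <- logdetG + d * logdet_A +
      design$n_a * as.numeric(determinant(as.matrix(cov$Sigma_a), TRUE)$modulus)
  }
  if (!is.null(cov$Sigma_pe)) {
    Spi <- .psolve(cov$Sigma_pe)
    pieces <- c(pieces, list(Matrix::kronecker(Matrix::Diagonal(design$m), Spi)))
    logdetG <- logdetG +
      design$m * as.numeric(determinant(as.matrix(cov$Sigma_pe), TRUE)$modulus)
  }
  if (!is.null(cov$sigma_hys2)) {
    pieces <- c(pieces, list(Matrix::Diagonal(design$q_hys * d,
                                              rep(1 / cov$sigma_hys2, design$q_hys))))
    logdetG <- logdetG + design$q_hys * sum(log(cov$sigma_hys2))
  }
  if (!is.null(cov$sigma_clt2)) {
    pieces <- c(pieces, list(Matrix::Diagonal(design$q_clt * d,
                                              rep(1 / cov$sigma_clt2, design$q_clt))))
    logdetG <- logdetG + design$q_clt * sum(log(cov$sigma_clt2))
  }
  rvec <- cov$sigma_e2[design$cls]
  list(Ginv = Matrix::bdiag(pieces), rvec = rvec,
       logdetG = logdetG, logdetR = sum(log(rvec)), logdet_A = logdet_A)
}

# sparse factorization of the MME; returns solutions and the restricted
# log-likelihood (full constant included)
.mme_solve_sparse <- function(design, cov, Ainv, y = design$y, layout = NULL,
                              logdet_A = NULL) {
  if (is.null(layout)) layout <- .mme_layout(design, cov)
  gi <- .mme_ginv(design, cov, Ainv, logdet_A)
  W <- layout$W
  Ws <- W / sqrt(gi$rvec)
  M <- Matrix::forceSymmetric(Matrix::crossprod(Ws) + gi$Ginv)
  rhs <- Matrix::crossprod(W, y / gi$rvec)
  fac <- Matrix::Cholesky(M, LDL = FALSE, perm = TRUE)
  sol <- as.numeric(Matrix::solve(fac, rhs))
  logdetM <- 2 * as.numeric(Matrix::determinant(fac, sqrt = TRUE)$modulus)
  yRy <- sum(y^2 / gi$rvec)
  yPy <- yRy - sum(sol * as.numeric(rhs))
  npar <- design$n - design$p
  loglik <- -0.5 * (npar * log(2 * pi) + gi$logdetR + gi$logdetG + logdetM + yPy)
  list(sol = sol, fac = fac, loglik = loglik, yPy = yPy, layout = layout,
       gi = gi, M = M, rhs = as.numeric(rhs))
}

# unpack a stacked solution vector into named effect blocks
.unpack_solution <- function(design, layout, sol) {
  d <- design$d
  b <- layout$blocks
  out <- list(beta = stats::setNames(sol[b$fixed], colnames(design$X)))
  if (!is.null(b$animal)) {
    out$a <- matrix(sol[b$animal], ncol = d, byrow = TRUE,
                    dimnames = list(design$animal_ids, paste0("T", seq_len(d))))
  }
  if (!is.null(b$pe)) {
    out$pe <- matrix(sol[b$pe], ncol = d, byrow = TRUE,
                     dimnames = list(design$boar_ids, paste0("T", seq_len(d))))
  }
  if (!is.null(b$hys)) {
    out$hys <- matrix(sol[b$hys], ncol = d, byrow = TRUE,
                      dimnames = list(design$hys_levels, paste0("T", seq_len(d))))
  }
  if (!is.null(b$clt)) {
    out$clt <- matrix(sol[b$clt], ncol = d, byrow = TRUE,
                      dimnames = list(design$clt_levels, paste0("T", seq_len(d))))
  }
  out
}

#' Solve Henderson's mixed-model equations at given variance components
#'
#' Assembles the MME for the design at the supplied covariance structure
#' and solves them by sparse Cholesky factorization. The solutions are
#' the generalized-least-squares fixed effects and the conditional-mean
#' (BLUP) random effects.
#'
#' @param design a [build_design()] bundle.
#' @param cov a [cov_structure()] matching the design's random terms.
#' @param Ainv sparse A-inverse from [a_inverse()] (same pedigree).
#' @param y response; defaults to the one stored in the design.
#' @return A `solution_set`: `beta` (named), `a`, `pe`, `hys`, `clt`
#'   (matrices, one column per class), `fitted`, `residuals`, the REML
#'   log-likelihood at `cov`, and `C_xx`, the prediction covariance of
#'   the fixed effects.
#' @export
assemble_and_solve <- function(design, cov, Ainv, y = design$y) {
  stopifnot(inherits(design, "design_bundle"), inherits(cov, "cov_structure"))
  ms <- .mme_solve_sparse(design, cov, Ainv, y)
  out <- .unpack_solution(design, ms$layout, ms$sol)
  fitted <- as.numeric(ms$layout$W %*% ms$sol)
  # covariance of the fixed-effect solutions: first p columns of M^-1
  Ip <- Matrix::sparseMatrix(i = seq_len(design$p), j = seq_len(design$p),
                             x = 1, dims = c(ms$layout$ntot, design$p))
  Cp <- as.matrix(Matrix::solve(ms$fac, Ip))
  out$C_xx <- Cp[seq_len(design$p), , drop = FALSE]
  out$fitted <- fitted
  out$residuals <- y - fitted
  out$loglik <- ms$loglik
  out$design <- design
  out$cov <- cov
  class(out) <- "solution_set"
  out
}

#' Predicted marginal means of a fixed factor
#'
#' Predicts the phenotype per level of the target factor by averaging
#' over the effects of all other terms in the model: intercept + the
#' level's own effect + the average of each other fixed factor's effects
#' (equal weights by default, observed level frequencies optionally);
#' random effects contribute zero. Standard errors come from the
#' covariance of the corresponding linear combination of fixed-effect
#' solutions.
#'
#' @param sol a [assemble_and_solve()] solution (or `$sol` of a REML fit).
#' @param target fixed factor to predict over (default `"age"`).
#' @param weights `"equal"` or `"observed"` averaging over the other
#'   factors' levels.
#' @return data.frame with `level`, `predicted` and `se`.
#' @export
predict_factor_means <- function(sol, target = "age",
                                 weights = c("equal", "observed")) {
  weights <- match.arg(weights)
  design <- sol$design
  if (!target %in% names(design$fixed_levels)) stop("target factor not in model: ", target)
  beta <- sol$beta
  p <- design$p
  base <- numeric(p)
  base[1L] <- 1
  for (f in names(design$fixed_levels)) {
    if (f == target) next
    levs <- design$fixed_levels[[f]]
    cols <- design$fixed_cols[[f]]
    if (!length(cols)) next
    wts <- if (weights == "equal") {
      rep(1 / length(levs), length(levs))
    } else {
      as.numeric(table(design$fixed_data[[f]])) / design$n
    }
    base[cols] <- wts[-1L]          # reference level contributes 0
  }
  levs <- design$fixed_levels[[target]]
  cols <- design$fixed_cols[[target]]
  out <- data.frame(level = levs, predicted = NA_real_, se = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(levs)) {
    x <- base
    if (k > 1L) x[cols[k - 1L]] <- 1
    out$predicted[k] <- sum(x * beta)
    if (!is.null(sol$C_xx)) out$se[k] <- sqrt(max(0, x %*% sol$C_xx %*% x))
  }
  out
}

#' Unadjusted means per factor level
#'
#' Arithmetic mean with a 95% normal-approximation confidence interval
#' per level of a grouping column. Levels with a single record get an
#' undefined (NA) interval and are flagged.
#'
#' @param records record table.
#' @param trait trait column.
#' @param by grouping column (e.g. `age_month`).
#' @return data.frame with `level`, `n`, `mean`, `se`, `lower`, `upper`,
#'   `flag_single`.
#' @export
unadjusted_means <- function(records, trait, by = "age_month") {
  g <- records[[by]]
  y <- records[[trait]]
  levs <- sort(unique(g))
  out <- data.frame(level = levs, n = NA_integer_, mean = NA_real_,
                    se = NA_real_, lower = NA_real_, upper = NA_real_,
                    flag_single = FALSE)
  for (k in seq_along(levs)) {
    yy <- y[g == levs[k]]
    out$n[k] <- length(yy)
    out$mean[k] <- mean(yy)
    if (length(yy) > 1L) {
      out$se[k] <- stats::sd(yy) / sqrt(length(yy))
      out$lower[k] <- out$mean[k] - 1.96 * out$se[k]
      out$upper[k] <- out$mean[k] + 1.96 * out$se[k]
    } else {
      out$flag_single[k] <- TRUE
    }
  }
  out
}
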