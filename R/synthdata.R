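#' Specification of one simulated semen trait
#'
#' Describes the generative model of a single trait on the analysis scale:
#' an overall mean, fixed monthly age / rest-day / month-of-year effect
#' curves, variance components per age class, and cross-class correlation
#' matrices for the additive-genetic and permanent-environment effects.
#'
#' @param name trait name (becomes the record-table column).
#' @param mean overall mean on the analysis scale.
#' @param age_effect numeric vector of length 54, the fixed effect of each
#'   age month 7..60 relative to the mean.
#' @param rest_effect numeric vector of length 15 (rest-day classes).
#' @param month_effect numeric vector of length 12 (months of the year).
#' @param components 3 x 5 numeric matrix (rows = age classes T1..T3,
#'   columns `a`, `pe`, `hys`, `clt`, `e`) of variance components.
#' @param cor_a,cor_pe 3 x 3 cross-class correlation matrices (unit
#'   diagonal, symmetric positive semidefinite) for the additive-genetic
#'   and permanent-environment effects.
#' @return A `trait_spec` list.
#' @export
trait_spec <- function(name, mean = 0,
                       age_effect = numeric(54),
                       rest_effect = numeric(15),
                       month_effect = numeric(12),
                       components,
                       cor_a = diag(3), cor_pe = diag(3)) {
  stopifnot(length(age_effect) == 54L, length(rest_effect) == 15L,
            length(month_effect) == 12L)
  components <- as.matrix(components)
  if (nrow(components) == 1L) components <- components[rep(1L, 3L), , drop = FALSE]
  stopifnot(nrow(components) == 3L, ncol(components) == 5L)
  colnames(components) <- c("a", "pe", "hys", "clt", "e")
  rownames(components) <- c("T1", "T2", "T3")
  if (any(components < 0)) stop("variance components must be >= 0")
  for (R in list(cor_a, cor_pe)) {
    stopifnot(all(dim(R) == c(3L, 3L)))
    if (max(abs(R - t(R))) > 1e-10 || max(abs(diag(R) - 1)) > 1e-10) {
      stop("correlation matrices must be symmetric with unit diagonal")
    }
    if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stop("correlation matrix is not positive semidefinite")
    }
  }
  structure(list(name = name, mean = mean, age_effect = age_effect,
                 rest_effect = rest_effect, month_effect = month_effect,
                 components = components, cor_a = cor_a, cor_pe = cor_pe),
            class = "trait_spec")
}

# covariance matrix for component 'what' ("a" or "pe") across the 3 classes
.class_cov <- function(spec, what = c("a", "pe")) {
  what <- match.arg(what)
  v <- spec$components[, what]
  R <- if (what == "a") spec$cor_a else spec$cor_pe
  R * tcrossprod(sqrt(v))
}

#' Phenotype-based culling rule
#'
#' Boars whose running mean of `trait` over their last `k` records falls
#' below the population `quantile` of that trait are culled with
#' probability `prob` at each monthly evaluation; all their later records
#' are dropped.
#'
#' @param trait trait name the rule watches.
#' @param k window size (number of most recent records), `k >= 1`.
#' @param quantile population quantile defining "poor quality" (0..1).
#' @param prob per-month probability of actually culling a flagged boar.
#' @export
culling_rule <- function(trait = "motility", k = 5L, quantile = 0.10, prob = 0.3) {
  if (k < 1L) stop("window k must be >= 1")
  stopifnot(quantile >= 0, quantile <= 1, prob >= 0, prob <= 1)
  structure(list(trait = trait, k = as.integer(k),
                 quantile = quantile, prob = prob), class = "culling_rule")
}

#' Simulation configuration
#'
#' Bundles everything [simulate_dataset()] needs: pedigree structure,
#' collection schedule, trait specifications, factor assignment rules,
#' an optional culling rule and the seed.
#'
#' The default schedule collects from every boar of the final pedigree
#' generation, monthly from 7 to 60 months with on average 1.5 ejaculates
#' per month, mirroring routine AI-station practice. Defaults for the
#' traits are the reference configurations of [default_traits()].
#'
#' @param pedigree list with `n_founders`, `n_matings` (vector, one per
#'   offspring generation) and `progeny` (progeny per mating, recycled).
#' @param schedule data.frame with columns `age_month` and `n_per_month`.
#' @param traits list of [trait_spec()] objects.
#' @param n_clt number of collector-lab technicians in the pool.
#' @param rest_probs sampling weights of the 15 rest-day classes.
#' @param culling `NULL` or a [culling_rule()].
#' @param phenotyped which animals enter collection: `"nonfounders"`
#'   (all non-founder generations, the default — AI boars span
#'   generations) or `"last"` (final generation only).
#' @param seed integer seed; mandatory for reproducible runs.
#' @export
sim_config <- function(pedigree = list(n_founders = 24L, n_matings = c(24L, 40L),
                                       progeny = c(4L, 10L)),
                       schedule = data.frame(age_month = 7:60,
                                             n_per_month = rep(c(1L, 2L), 27L)),
                       traits = default_traits(),
                       n_clt = 20L,
                       rest_probs = stats::dgeom(0:14, 0.25) + 0.01,
                       culling = NULL,
                       phenotyped = c("nonfounders", "last"),
                       seed = 1L) {
  phenotyped <- match.arg(phenotyped)
  stopifnot(all(schedule$age_month >= 7L), all(schedule$age_month <= 60L))
  if (inherits(traits, "trait_spec")) traits <- list(traits)
  names(traits) <- vapply(traits, `[[`, "", "name")
  structure(list(pedigree = pedigree, schedule = schedule, traits = traits,
                 n_clt = as.integer(n_clt), rest_probs = rest_probs,
                 culling = culling, phenotyped = phenotyped,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Reference trait configurations
#'
#' Two built-in traits: `motility` (a semen quality trait on its
#' variance-stabilised analysis scale, age curve peaking at 13 months and
#' declining after) and `sperm_cells` (a semen quantity trait on the
#' observed scale, rising to a plateau at 18 months). Variance components
#' per age class follow the reference estimates for a commercial boar
#' line; herd-year-season and technician variances default to a small
#' share of the phenotypic variance.
#'
#' @param hys_frac,clt_frac fraction of the phenotypic variance assigned
#'   to the herd-year-season and collector-technician components (taken
#'   out of the residual).
#' @return Named list of [trait_spec()] objects.
#' @export
default_traits <- function(hys_frac = 0.02, clt_frac = 0.02) {
  ages <- 7:60
  # motility: rises to a peak at 13 mo, then gradual decline
  mot_curve <- ifelse(ages <= 13, (ages - 7) * 1.0, 6 - (ages - 13) * 0.25)
  # quantity: steep rise to 18 mo, plateau, slight decline after 39 mo
  qty_curve <- ifelse(ages <= 18, (ages - 7) * 2.0,
                      22 - pmax(0, ages - 39) * 0.1)
  comp <- function(sp2, h2, rep) {
    e <- (1 - rep) * sp2
    hys <- hys_frac * sp2
    clt <- clt_frac * sp2
    cbind(a = h2 * sp2, pe = (rep - h2) * sp2, hys = hys, clt = clt,
          e = e - hys - clt)
  }
  cor3 <- function(r12, r13, r23) {
    matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3L, 3L)
  }
  list(
    motility = trait_spec(
      name = "motility", mean = 70,
      age_effect = mot_curve,
      rest_effect = seq(-1.5, 1.5, length.out = 15),
      month_effect = 1.0 * sin(2 * pi * (1:12) / 12),
      components = comp(c(152.9, 158.2, 171.0), c(0.31, 0.29, 0.28),
                        c(0.61, 0.64, 0.63)),
      cor_a = cor3(0.97, 0.91, 0.98),
      cor_pe = cor3(0.85, 0.85, 0.85)),
    sperm_cells = trait_spec(
      name = "sperm_cells", mean = 55,
      age_effect = qty_curve,
      rest_effect = seq(-4, 4, length.out = 15),
      month_effect = 2.0 * sin(2 * pi * (1:12) / 12),
      components = comp(c(408.7, 606.7, 722.4), c(0.22, 0.23, 0.20),
                        c(0.44, 0.46, 0.46)),
      cor_a = cor3(0.93, 0.89, 0.96),
      cor_pe = cor3(0.85, 0.85, 0.85))
  )
}

#' Simulate a discrete-generation pedigree
#'
#' Founders are split into equal numbers of males and females; each
#' offspring generation is produced by random non-self sire x dam matings
#' among the previous generation, with a fixed number of progeny per
#' mating. Sex is assigned alternately at birth. Uses the R random number
#' stream (seed with [set.seed()]).
#'
#' @param n_founders number of founders (>= 2).
#' @param n_matings matings per offspring generation (vector).
#' @param progeny progeny per mating (recycled over generations).
#' @return A [as_pedigree()] object with extra columns `generation` and
#'   `sex`.
#' @export
simulate_pedigree <- function(n_founders = 24L, n_matings = c(24L, 40L),
                              progeny = c(4L, 10L)) {
  if (n_founders < 2L) stop("need at least 2 founders")
  n_gen <- length(n_matings)
  progeny <- rep_len(progeny, max(n_gen, 1L))
  id <- sprintf("F%03d", seq_len(n_founders))
  sire <- dam <- rep("0", n_founders)
  sex <- rep(c("M", "F"), length.out = n_founders)
  gen <- rep(0L, n_founders)
  prev <- seq_len(n_founders)
  for (g in seq_len(n_gen)) {
    males <- prev[sex[prev] == "M"]
    females <- prev[sex[prev] == "F"]
    if (!length(males) || !length(females)) stop("infeasible mating config: a sex died out")
    ns <- n_matings[g]
    sires <- sample(males, ns, replace = TRUE)
    dams <- sample(females, ns, replace = TRUE)
    kid_s <- rep(sires, each = progeny[g])
    kid_d <- rep(dams, each = progeny[g])
    nk <- length(kid_s)
    kid_id <- sprintf("G%d_%04d", g, seq_len(nk))
    id <- c(id, kid_id)
    sire <- c(sire, id[kid_s])
    dam <- c(dam, id[kid_d])
    sex <- c(sex, rep(c("M", "F"), length.out = nk))
    gen <- c(gen, rep(g, nk))
    prev <- seq.int(length(id) - nk + 1L, length(id))
  }
  ped <- as_pedigree(data.frame(animal = id, sire = sire, dam = dam),
                     quiet = TRUE)
  ped$generation <- gen[match(ped$id, id)]
  ped$sex <- sex[match(ped$id, id)]
  ped
}

#' Sample breeding values down a pedigree
#'
#' Draws per-animal breeding-value vectors whose joint covariance is
#' `A %x% Sigma_a` by the Mendelian-sampling recursion: founders are
#' `N(0, Sigma_a)`, non-founders are the mean of their known parents'
#' vectors plus `N(0, d_i * Sigma_a)` where `d_i` is the
#' Mendelian-sampling variance from the inbreeding rules.
#'
#' @param ped a [as_pedigree()] object.
#' @param Sigma_a `d x d` positive semidefinite covariance matrix (use a
#'   `1 x 1` matrix or scalar for a single class).
#' @return `n x d` matrix of breeding values, rows named by original ids.
#' @export
sample_breeding_values <- function(ped, Sigma_a) {
  stopifnot(inherits(ped, "pedigree"))
  Sigma_a <- as.matrix(Sigma_a)
  d <- nrow(Sigma_a)
  ev <- eigen(Sigma_a, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values), 1)) {
    stop("Sigma_a is not positive semidefinite")
  }
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), d)
  n <- nrow(ped)
  a <- matrix(0, n, d)
  z <- matrix(stats::rnorm(n * d), n, d) %*% t(L)
  sire <- ped$sire; dam <- ped$dam; dms <- ped$d
  for (i in seq_len(n)) {
    mu <- numeric(d)
    if (sire[i] > 0L) mu <- mu + 0.5 * a[sire[i], ]
    if (dam[i] > 0L) mu <- mu + 0.5 * a[dam[i], ]
    a[i, ] <- mu + sqrt(dms[i]) * z[i, ]
  }
  rownames(a) <- ped$id
  a
}

#' Simulate longitudinal semen records
#'
#' Generates one row per ejaculate for every phenotyped boar following the
#' repeatability model: trait value = mean + age effect + rest-day effect +
#' month-of-year effect + class-specific breeding value + class-specific
#' permanent environment + herd-year-season of birth + collector-lab
#' technician + residual. Age classes are `7-13`, `14-23` and `24-60`
#' months; the herd-year-season level is one per generation x birth
#' quarter, the technician is drawn per record from a pool. Uses the R
#' random number stream.
#'
#' @param ped pedigree from [simulate_pedigree()] (needs `generation`).
#' @param cfg a [sim_config()].
#' @param boars ids of phenotyped boars; default all animals of the last
#'   generation.
#' @return List with `records` (data.frame: `boar`, `age_month`,
#'   `age_class`, `rest_class`, `month_of_year`, `hys`, `clt`, one column
#'   per trait) and `truth` (per-trait true effects: `bv`, `pe`, `hys`,
#'   `clt` matrices and the fixed curves).
#' @export
simulate_records <- function(ped, cfg, boars = NULL) {
  stopifnot(inherits(ped, "pedigree"), inherits(cfg, "sim_config"))
  if (is.null(boars)) {
    if (is.null(ped$generation)) stop("pedigree has no generation column; pass boars=")
    boars <- ped$id[ped$generation == max(ped$generation)]
  }
  if (!all(boars %in% ped$id)) stop("pedigree does not cover all scheduled boars")
  nb <- length(boars)
  bidx <- match(boars, ped$id)

  sched <- cfg$schedule
  ages <- rep(sched$age_month, sched$n_per_month)
  nrec_b <- length(ages)

  birth_month <- sample(1:12, nb, replace = TRUE)
  gen <- if (is.null(ped$generation)) rep(1L, nb) else ped$generation[bidx]
  hys_lab <- paste0("g", gen, "q", (birth_month - 1L) %/% 3L + 1L)
  hys_lev <- factor(hys_lab)
  q_h <- nlevels(hys_lev)

  rec <- data.frame(
    boar = rep(boars, each = nrec_b),
    age_month = rep(ages, nb),
    rest_class = sample(1:15, nb * nrec_b, replace = TRUE, prob = cfg$rest_probs),
    month_of_year = ((rep(birth_month, each = nrec_b) + rep(ages, nb) - 1L) %% 12L) + 1L,
    hys = rep(as.integer(hys_lev), each = nrec_b),
    clt = sample(seq_len(cfg$n_clt), nb * nrec_b, replace = TRUE),
    stringsAsFactors = FALSE)
  rec$age_class <- assign_age_class(rec$age_month)
  cls <- as.integer(factor(rec$age_class, levels = c("T1", "T2", "T3")))

  truth <- list()
  for (tr in cfg$traits) {
    Sa <- .class_cov(tr, "a")
    Spe <- .class_cov(tr, "pe")
    bv <- sample_breeding_values(ped, Sa)
    pe <- .rmvnorm(nb, Spe); rownames(pe) <- boars
    hys_eff <- vapply(1:3, function(c3) stats::rnorm(q_h, 0, sqrt(tr$components[c3, "hys"])),
                      numeric(q_h))
    clt_eff <- vapply(1:3, function(c3) stats::rnorm(cfg$n_clt, 0, sqrt(tr$components[c3, "clt"])),
                      numeric(cfg$n_clt))
    res <- stats::rnorm(nrow(rec), 0, sqrt(tr$components[cls, "e"]))
    brow <- match(rec$boar, boars)
    y <- tr$mean +
      tr$age_effect[rec$age_month - 6L] +
      tr$rest_effect[rec$rest_class] +
      tr$month_effect[rec$month_of_year] +
      bv[cbind(bidx[brow], cls)] +
      pe[cbind(brow, cls)] +
      hys_eff[cbind(rec$hys, cls)] +
      clt_eff[cbind(rec$clt, cls)] +
      res
    rec[[tr$name]] <- y
    truth[[tr$name]] <- list(bv = bv, pe = pe, hys = hys_eff, clt = clt_eff,
                             residual = res, mean = tr$mean,
                             age_effect = tr$age_effect,
                             rest_effect = tr$rest_effect,
                             month_effect = tr$month_effect,
                             Sigma_a = Sa, Sigma_pe = Spe,
                             components = tr$components)
  }
  list(records = rec, truth = truth)
}

.rmvnorm <- function(n, Sigma) {
  Sigma <- as.matrix(Sigma)
  d <- nrow(Sigma)
  ev <- eigen(Sigma, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), d)
  matrix(stats::rnorm(n * d), n, d) %*% t(L)
}

#' Apply phenotype-based culling to a record table
#'
#' Walks through collection months in order; a boar whose running mean of
#' the rule trait over its last `k` records lies strictly below the
#' population quantile threshold is culled with the configured
#' probability, and all its records in later months are dropped. The
#' threshold is the `quantile` of all (uncensored) values of the trait.
#' Uses the R random number stream.
#'
#' @param records record table (see [simulate_records()]).
#' @param rule a [culling_rule()].
#' @return List with `records` (censored table) and `log` (data.frame:
#'   `boar`, `cull_age`, `trigger`, one row per culled boar).
#' @export
apply_culling <- function(records, rule) {
  stopifnot(inherits(rule, "culling_rule"))
  if (!rule$trait %in% names(records)) stop("rule trait not in records: ", rule$trait)
  y <- records[[rule$trait]]
  threshold <- stats::quantile(y, rule$quantile, names = FALSE, type = 7)
  ord <- order(records$boar, records$age_month)
  keep <- rep(TRUE, nrow(records))
  log_boar <- character(0); log_age <- integer(0); log_val <- numeric(0)
  for (b in unique(records$boar)) {
    ib <- ord[records$boar[ord] == b]
    ages_b <- records$age_month[ib]
    yb <- y[ib]
    culled_after <- NA_integer_
    for (m in unique(ages_b)) {
      upto <- which(ages_b <= m)
      if (length(upto) < rule$k) next
      rm <- mean(yb[upto[(length(upto) - rule$k + 1L):length(upto)]])
      if (rm < threshold && stats::runif(1) < rule$prob) {
        culled_after <- m
        log_boar <- c(log_boar, b); log_age <- c(log_age, m); log_val <- c(log_val, rm)
        break
      }
    }
    if (!is.na(culled_after)) keep[ib[ages_b > culled_after]] <- FALSE
  }
  list(records = records[keep, , drop = FALSE],
       log = data.frame(boar = log_boar, cull_age = log_age, trigger = log_val,
                        stringsAsFactors = FALSE))
}
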