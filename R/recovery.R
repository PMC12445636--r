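# Parameter-recovery experiments: simulate replicate datasets whose true
# variance components are constructed from published genetic-parameter
# rows (phenotypic variance, heritability, repeatability per age class),
# fit them with the package's REML machinery and average the estimates.
# These are the package's primary self-verification instruments.

#' Variance components from (phenotypic variance, h2, rep) rows
#'
#' `sigma_a2 = h2 * sigma_p2`, `sigma_pe2 = (rep - h2) * sigma_p2`,
#' herd-year-season and technician variances zero, residual the
#' remainder.
#'
#' @param sigma_p2,h2,rep numeric vectors (one entry per age class).
#' @return matrix with columns `a`, `pe`, `hys`, `clt`, `e`.
#' @export
components_from_ratios <- function(sigma_p2, h2, rep) {
  stopifnot(length(h2) == length(sigma_p2), length(rep) == length(sigma_p2),
            all(h2 >= 0), all(rep >= h2), all(rep <= 1))
  cbind(a = h2 * sigma_p2, pe = (rep - h2) * sigma_p2,
        hys = 0 * sigma_p2, clt = 0 * sigma_p2, e = (1 - rep) * sigma_p2)
}

#' Heritability/repeatability recovery experiment (univariate)
#'
#' Simulates replicate single-age-class datasets under the repeatability
#' animal model with true components built by [components_from_ratios()],
#' fits each with [fit_univariate()] and returns the per-replicate
#' heritability and repeatability estimates.
#'
#' The default design: 800 phenotyped boars spanning three pedigree
#' generations bred from 40 founders, 12 ejaculates each collected at
#' 8-13 months (two per month), age / rest-day / month-of-year fixed
#' effects included in simulation and fit.
#'
#' @param sigma_p2,h2,rep the true ratios of the emulated class.
#' @param n_reps number of replicate datasets.
#' @param seed base seed; replicate r uses `seed + r`.
#' @param pedigree pedigree configuration (see [sim_config()]).
#' @param ages collection ages (months, one class).
#' @param n_per_month ejaculates per month.
#' @param opts a [reml_control()].
#' @return data.frame with one row per replicate: `h2_hat`, `rep_hat`,
#'   `sigma_p2_hat`, `converged`.
#' @export
recovery_univariate <- function(sigma_p2, h2, rep, n_reps = 30L, seed = 1L,
                                pedigree = list(n_founders = 40L,
                                                n_matings = c(40L, 60L, 100L),
                                                progeny = 4L),
                                ages = 8:13, n_per_month = 2L,
                                opts = reml_control()) {
  comp <- components_from_ratios(sigma_p2, h2, rep)[base::rep(1L, 3L), , drop = FALSE]
  tr <- trait_spec("y", mean = 10 * sqrt(sigma_p2),
                   age_effect = .default_curve(54, 0.05 * sqrt(sigma_p2)),
                   rest_effect = seq(-0.1, 0.1, length.out = 15) * sqrt(sigma_p2),
                   month_effect = 0.1 * sqrt(sigma_p2) * sin(2 * pi * (1:12) / 12),
                   components = comp)
  out <- lapply(seq_len(n_reps), function(r) {
    cfg <- sim_config(pedigree = pedigree,
                      schedule = data.frame(age_month = ages,
                                            n_per_month = n_per_month),
                      traits = list(tr), phenotyped = "nonfounders",
                      seed = seed + r)
    dat <- simulate_dataset(cfg)
    des <- build_design(dat$records,
                        model_spec("y", random = c("animal", "pe"),
                                   class_structure = "off"), dat$ped)
    fit <- fit_univariate(des, Ainv = a_inverse(dat$ped), opts = opts)
    gp <- genetic_ratios(fit)
    data.frame(rep = r, h2_hat = gp$h2, rep_hat = gp$rep,
               sigma_p2_hat = gp$sigma_p2, converged = fit$converged)
  })
  do.call(rbind, out)
}

#' Genetic-correlation recovery experiment (trivariate)
#'
#' Simulates replicate datasets with records in all three age classes,
#' per-class true components from [components_from_ratios()] and the
#' given cross-class genetic correlation matrix, fits the constrained
#' trivariate model and returns the estimated genetic correlations per
#' replicate.
#'
#' Default design: 400 phenotyped boars over three generations from 40
#' founders, six ejaculates in each age class (collection schedules of AI
#' boars are dense; a sparse schedule leaves the cross-class genetic
#' correlation weakly identified for low-heritability configurations).
#'
#' @param sigma_p2,h2,rep per-class true ratios (length 3).
#' @param cor_a 3 x 3 true genetic correlation matrix.
#' @param cor_pe 3 x 3 true permanent-environment correlation matrix.
#' @param n_reps,seed replicates and base seed.
#' @param pedigree pedigree configuration.
#' @param class_ages list of collection ages per class.
#' @param opts a [reml_control()].
#' @return data.frame with per-replicate `r_a12`, `r_a13`, `r_a23`,
#'   per-class `h2_hat`, and `converged`.
#' @export
recovery_trivariate <- function(sigma_p2, h2, rep, cor_a,
                                cor_pe = matrix(0.85, 3, 3) + diag(3) * 0.15,
                                n_reps = 20L, seed = 1L,
                                pedigree = list(n_founders = 40L,
                                                n_matings = c(20L, 30L, 50L),
                                                progeny = 4L),
                                class_ages = list(c(8L, 9L, 10L, 11L, 12L, 13L),
                                                  c(15L, 16L, 18L, 19L, 20L, 22L),
                                                  c(26L, 28L, 32L, 36L, 40L, 48L)),
                                opts = reml_control()) {
  comp <- components_from_ratios(sigma_p2, h2, rep)
  sc <- sqrt(mean(sigma_p2))
  tr <- trait_spec("y", mean = 10 * sc,
                   age_effect = .default_curve(54, 0.05 * sc),
                   rest_effect = seq(-0.1, 0.1, length.out = 15) * sc,
                   month_effect = 0.1 * sc * sin(2 * pi * (1:12) / 12),
                   components = comp, cor_a = cor_a, cor_pe = cor_pe)
  sched <- data.frame(age_month = unlist(class_ages), n_per_month = 1L)
  out <- lapply(seq_len(n_reps), function(r) {
    cfg <- sim_config(pedigree = pedigree, schedule = sched,
                      traits = list(tr), phenotyped = "nonfounders",
                      seed = seed + r)
    dat <- simulate_dataset(cfg)
    rec <- dat$records
    rec$age_class <- assign_age_class(rec$age_month)
    des <- build_design(rec, model_spec("y", random = c("animal", "pe"),
                                        class_structure = "trivariate"),
                        dat$ped)
    fit <- fit_trivariate(des, Ainv = a_inverse(dat$ped), opts = opts)
    cs <- correlation_set(fit)
    gp <- genetic_ratios(fit)
    data.frame(rep = r, r_a12 = cs$r_a[1], r_a13 = cs$r_a[2],
               r_a23 = cs$r_a[3], h2_T1 = gp$h2[1], h2_T2 = gp$h2[2],
               h2_T3 = gp$h2[3], converged = fit$converged)
  })
  do.call(rbind, out)
}

# mildly curved default age-effect profile for recovery runs
.default_curve <- function(len, scale) {
  x <- seq_len(len)
  scale * (6 * (1 - exp(-(x - 1) / 6)) - 0.05 * x)
}
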