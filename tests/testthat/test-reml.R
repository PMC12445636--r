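tiny_univ <- function(seed = 9) {
  dat <- small_dataset(seed = seed, n_founders = 4L, n_matings = c(3L, 3L),
                       progeny = c(2L, 1L), ages = c(8L, 10L))
  des <- build_design(dat$records,
                      model_spec("y", fixed = "age", random = c("animal", "pe"),
                                 class_structure = "off"), dat$ped)
  list(dat = dat, des = des, Ainv = a_inverse(dat$ped),
       A = relationship_matrix(dat$ped))
}

test_that("the MME-based REML log-likelihood equals the dense definition", {
  m <- tiny_univ()
  stopifnot(m$des$n <= 25)
  for (p in list(c(4, 3, 5), c(1, 6, 2), c(10, 0.5, 7))) {
    cov <- cov_structure(Sigma_a = p[1], Sigma_pe = p[2], sigma_e2 = p[3])
    mine <- reml_loglik(cov, m$des, m$Ainv)
    orac <- dense_reml_loglik(m$des$X, dense_V(m$des, cov, m$A), m$des$y)
    expect_equal(mine, orac, tolerance = 1e-8)
  }
})

test_that("the trivariate log-likelihood with all five terms matches the dense oracle", {
  tr <- flat_trait(a = 4, pe = 3, hys = 2, clt = 1, e = 5,
                   cor_a = cor3(.6, .4, .5), cor_pe = cor3(.3, .2, .4))
  dat <- small_dataset(seed = 14, n_founders = 4L, n_matings = c(2L, 2L),
                       progeny = c(2L, 2L),
                       ages = c(8L, 15L, 26L), trait = tr)
  rec <- dat$records
  rec$age_class <- assign_age_class(rec$age_month)
  des <- build_design(rec, model_spec("y", fixed = "age",
                                      random = c("animal", "pe", "hys", "clt"),
                                      class_structure = "trivariate"), dat$ped)
  A <- relationship_matrix(dat$ped)
  cov <- cov_structure(
    Sigma_a = cor3(.6, .4, .5) * tcrossprod(sqrt(c(4, 5, 6))),
    Sigma_pe = cor3(.3, .2, .4) * tcrossprod(sqrt(c(3, 3, 4))),
    sigma_hys2 = c(2, 2.5, 2), sigma_clt2 = c(1, 1, 1.5),
    sigma_e2 = c(5, 6, 7))
  mine <- reml_loglik(cov, des, a_inverse(dat$ped))
  orac <- dense_reml_loglik(des$X, dense_V(des, cov, A), des$y)
  expect_equal(mine, orac, tolerance = 1e-8)
})

test_that("REML criterion is invariant to reparameterizing the fixed effects", {
  m <- tiny_univ(seed = 17)
  rec <- m$dat$records
  cov <- cov_structure(Sigma_a = 4, Sigma_pe = 3, sigma_e2 = 5)
  ll1 <- reml_loglik(cov, m$des, m$Ainv)
  rec2 <- rec
  rec2$age_month <- factor(rec2$age_month,
                           levels = rev(sort(unique(rec2$age_month))))
  des2 <- build_design(rec2, model_spec("y", fixed = "age",
                                        random = c("animal", "pe"),
                                        class_structure = "off"), m$dat$ped)
  expect_equal(reml_loglik(cov, des2, m$Ainv), ll1, tolerance = 1e-10)
})

test_that("scaling the data and components shifts the criterion by the analytic constant", {
  m <- tiny_univ(seed = 23)
  cov <- cov_structure(Sigma_a = 4, Sigma_pe = 3, sigma_e2 = 5)
  ll1 <- reml_loglik(cov, m$des, m$Ainv)
  cc <- 2.5
  cov2 <- cov_structure(Sigma_a = 4 * cc^2, Sigma_pe = 3 * cc^2,
                        sigma_e2 = 5 * cc^2)
  ll2 <- reml_loglik(cov2, m$des, m$Ainv, y = cc * m$des$y)
  expect_equal(ll2, ll1 - (m$des$n - m$des$p) * log(cc), tolerance = 1e-8)
})

test_that("balanced one-way data with unrelated animals reproduces the ANOVA estimators", {
  set.seed(31)
  q <- 40L; r <- 5L
  ped <- as_pedigree(data.frame(animal = paste0("b", 1:q), sire = "0", dam = "0"))
  u <- rnorm(q, 0, 2)
  y <- rep(u, each = r) + rnorm(q * r, 0, sqrt(5))
  rec <- data.frame(boar = rep(paste0("b", 1:q), each = r), age_month = 8L, y = y)
  des <- build_design(rec, model_spec("y", fixed = "age", random = "animal",
                                      class_structure = "off"), ped)
  # exactness check: run the optimiser to the strict joint criterion
  fit <- fit_univariate(des, Ainv = a_inverse(ped),
                        opts = reml_control(tol_flat = 1e-12))
  gm <- ave(y, rec$boar)
  msb <- r * var(gm[seq(1, q * r, by = r)])
  msw <- sum((y - gm)^2) / (q * (r - 1))
  expect_equal(unname(fit$theta["e:T1"]), msw, tolerance = 1e-6)
  expect_equal(unname(fit$theta["a:T1T1"]), (msb - msw) / r, tolerance = 1e-6)
})

test_that("pure EM iterations never decrease the restricted log-likelihood", {
  m <- tiny_univ(seed = 41)
  fit <- suppressWarnings(
    fit_univariate(m$des, Ainv = m$Ainv,
                   opts = reml_control(max_iter = 25, em_iters = 25)))
  expect_true(all(diff(fit$trace$loglik) > -1e-8))

  # and in the trivariate model
  tr <- flat_trait(a = 4, pe = 3, e = 5, cor_a = cor3(.5, .5, .5),
                   cor_pe = cor3(.4, .4, .4))
  dat <- small_dataset(seed = 42, ages = c(8L, 10L, 15L, 18L, 26L, 32L),
                       trait = tr)
  rec <- dat$records
  rec$age_class <- assign_age_class(rec$age_month)
  des3 <- build_design(rec, model_spec("y", random = c("animal", "pe"),
                                       class_structure = "trivariate"), dat$ped)
  fit3 <- suppressWarnings(
    fit_trivariate(des3, Ainv = a_inverse(dat$ped),
                   opts = reml_control(max_iter = 15, em_iters = 15)))
  expect_true(all(diff(fit3$trace$loglik) > -1e-8))
})

test_that("a zero-variance additive component is driven to the boundary", {
  set.seed(55)
  tr <- flat_trait(a = 0, pe = 5, e = 5)
  dat <- small_dataset(seed = 55, n_founders = 12L, n_matings = c(10L, 15L),
                       progeny = c(3L, 3L), ages = c(8L, 9L, 10L, 11L, 12L),
                       trait = tr)
  des <- build_design(dat$records,
                      model_spec("y", fixed = "age", random = c("animal", "pe"),
                                 class_structure = "off"), dat$ped)
  fit <- fit_univariate(des, Ainv = a_inverse(dat$ped))
  expect_lt(unname(fit$theta["a:T1T1"]), 0.5)
})

test_that("estimates are invariant to record order", {
  m <- tiny_univ(seed = 61)
  fit1 <- fit_univariate(m$des, Ainv = m$Ainv)
  rec2 <- m$dat$records[sample(nrow(m$dat$records)), ]
  des2 <- build_design(rec2, model_spec("y", fixed = "age",
                                        random = c("animal", "pe"),
                                        class_structure = "off"), m$dat$ped)
  fit2 <- fit_univariate(des2, Ainv = m$Ainv)
  expect_equal(fit1$theta, fit2$theta, tolerance = 1e-6)
})

test_that("sampling covariance: component SEs come from the AI inverse and scale linearly", {
  m <- tiny_univ(seed = 71)
  fit <- fit_univariate(m$des, Ainv = m$Ainv)
  se <- vc_se(fit)
  expect_equal(unname(se["a:T1T1"]), sqrt(fit$ai_inv["a:T1T1", "a:T1T1"]))
  # delta method on c * component scales the SE by |c|
  g <- numeric(fit$param$n); g[1] <- 3
  expect_equal(delta_se(fit, g), 3 * unname(se[1]), tolerance = 1e-12)
})

test_that("trivariate recovery: degenerate unit-correlation truth gives near-unit estimates", {
  tr <- trait_spec("y", mean = 10,
                   components = cbind(a = 40, pe = 30, hys = 0, clt = 0, e = 40)[rep(1, 3), ],
                   cor_a = cor3(1, 1, 1) * 0.999 + diag(3) * 0.001,
                   cor_pe = cor3(.6, .6, .6))
  r12 <- vapply(1:3, function(i) {
    cfg <- sim_config(pedigree = list(n_founders = 30L, n_matings = c(25L, 40L),
                                      progeny = c(3L, 3L)),
                      schedule = data.frame(age_month = c(8L, 10L, 12L, 15L, 18L,
                                                          20L, 26L, 32L, 40L),
                                            n_per_month = 1L),
                      traits = list(tr), seed = 700L + i)
    dat <- simulate_dataset(cfg)
    rec <- dat$records
    rec$age_class <- assign_age_class(rec$age_month)
    des <- build_design(rec, model_spec("y", random = c("animal", "pe"),
                                        class_structure = "trivariate"), dat$ped)
    fit <- fit_trivariate(des, Ainv = a_inverse(dat$ped))
    correlation_set(fit)$r_a[1]
  }, 0)
  expect_lt(abs(mean(r12) - 1), 0.02)
})

test_that("a missing class or absent class overlap is caught", {
  tr <- flat_trait()
  dat <- small_dataset(seed = 81, ages = c(8L, 10L, 15L, 18L))  # no T3 records
  rec <- dat$records
  rec$age_class <- assign_age_class(rec$age_month)
  expect_error(build_design(rec, model_spec("y", random = c("animal", "pe"),
                                            class_structure = "trivariate"),
                            dat$ped), "non-empty")
})

test_that("fits including herd-year-season and technician terms reach a REML optimum", {
  tr <- flat_trait(a = 6, pe = 4, hys = 3, clt = 2, e = 6)
  cfg <- sim_config(pedigree = list(n_founders = 16L, n_matings = c(12L, 20L),
                                    progeny = 3L),
                    schedule = data.frame(age_month = 8:13, n_per_month = 2L),
                    traits = list(tr), n_clt = 10L, seed = 83L)
  dat <- simulate_dataset(cfg)
  des <- build_design(dat$records,
                      model_spec("y", random = c("animal", "pe", "hys", "clt"),
                                 class_structure = "off"), dat$ped)
  Ainv <- a_inverse(dat$ped)
  fit <- fit_univariate(des, Ainv = Ainv)
  expect_true(fit$converged)
  expect_length(fit$theta, 5L)
  expect_true(all(is.finite(fit$theta)))
  # the estimate cannot have lower restricted likelihood than the truth
  truth <- cov_structure(Sigma_a = 6, Sigma_pe = 4, sigma_hys2 = 3,
                         sigma_clt2 = 2, sigma_e2 = 6)
  expect_gte(fit$loglik, reml_loglik(truth, des, Ainv) - 1e-6)
  # residual and technician variances are well-identified at this size
  expect_lt(abs(fit$theta["e:T1"] - 6) / 6, 0.5)
})
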