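make_univ <- function(seed = 3, ages = c(8L, 10L, 12L), n_founders = 6L,
                      n_matings = c(4L, 4L), progeny = c(2L, 2L),
                      trait = flat_trait()) {
  dat <- small_dataset(seed = seed, n_founders = n_founders,
                       n_matings = n_matings, progeny = progeny,
                       ages = ages, trait = trait)
  des <- build_design(dat$records,
                      model_spec("y", fixed = "age", random = c("animal", "pe"),
                                 class_structure = "off"), dat$ped)
  list(dat = dat, des = des, Ainv = a_inverse(dat$ped))
}

test_that("design bundles have the declared incidence structure", {
  m <- make_univ()
  des <- m$des
  n <- des$n
  # fixed block: intercept + age dummies; adding the reference restores row sums
  expect_equal(unname(as.numeric(des$X[, 1])), rep(1, n))
  age_fac <- des$fixed_data$age
  row_tot <- Matrix::rowSums(des$X[, des$fixed_cols$age, drop = FALSE]) +
    (as.integer(age_fac) == 1L)
  expect_equal(unname(as.numeric(row_tot)), rep(1, n))
  # random blocks: one 1 per row
  expect_true(all(Matrix::rowSums(des$Za) == 1))
  expect_true(all(Matrix::rowSums(des$Zpe) == 1))
  expect_equal(ncol(des$Za), nrow(m$dat$ped))

  # trivariate: 3 columns per animal
  tr3 <- flat_trait(cor_a = cor3(.5, .5, .5), cor_pe = cor3(.5, .5, .5))
  dat3 <- small_dataset(seed = 4, ages = c(8L, 10L, 15L, 18L, 26L, 32L), trait = tr3)
  rec3 <- dat3$records
  rec3$age_class <- assign_age_class(rec3$age_month)
  des3 <- build_design(rec3, model_spec("y", random = c("animal", "pe"),
                                        class_structure = "trivariate"), dat3$ped)
  expect_equal(des3$d, 3L)
  expect_equal(ncol(des3$Za), 3L * nrow(dat3$ped))

  expect_error(build_design(dat3$records[0, ],
                            model_spec("y", random = "animal"), dat3$ped),
               "empty")
})

test_that("MME solutions match dense GLS and conditional means on tiny data", {
  m <- make_univ(seed = 9, n_founders = 4L, n_matings = c(3L, 3L),
                 progeny = c(2L, 1L), ages = c(8L, 10L, 12L))
  des <- m$des
  stopifnot(des$n <= 30)
  cov <- cov_structure(Sigma_a = 4, Sigma_pe = 3, sigma_e2 = 5)
  sol <- assemble_and_solve(des, cov, m$Ainv)
  A <- relationship_matrix(m$dat$ped)
  or <- dense_gls_blup(des$X,
                       list(des$Za, des$Zpe),
                       list(4 * A, 3 * diag(des$m)),
                       rep(5, des$n), des$y)
  expect_lt(max(abs(unname(sol$beta) - or$beta)), 1e-8)
  expect_lt(max(abs(as.numeric(t(sol$a)) - or$u[[1]])), 1e-8)
  expect_lt(max(abs(as.numeric(t(sol$pe)) - or$u[[2]])), 1e-8)
})

test_that("record duplication acts as residual reweighting and OLS limit holds", {
  m <- make_univ(seed = 12)
  des <- m$des
  # duplicating every record carries the same information as halving the
  # residual variance on the originals: all solutions must coincide
  sol1 <- assemble_and_solve(des, cov_structure(Sigma_a = 4, Sigma_pe = 3,
                                                sigma_e2 = 2.5), m$Ainv)
  rec2 <- rbind(m$dat$records, m$dat$records)
  des2 <- build_design(rec2, model_spec("y", fixed = "age",
                                        random = c("animal", "pe"),
                                        class_structure = "off"), m$dat$ped)
  sol2 <- assemble_and_solve(des2, cov_structure(Sigma_a = 4, Sigma_pe = 3,
                                                 sigma_e2 = 5), m$Ainv)
  expect_equal(unname(sol1$beta), unname(sol2$beta), tolerance = 1e-8)
  expect_equal(sol1$a, sol2$a, tolerance = 1e-8)

  # huge random variances penalise nothing: fixed solutions -> OLS = level means
  rec <- m$dat$records
  des_f <- build_design(rec, model_spec("y", fixed = "age", random = "animal",
                                        class_structure = "off"), m$dat$ped)
  cov_f <- cov_structure(Sigma_a = 1e-8, sigma_e2 = 1)
  sol_f <- assemble_and_solve(des_f, cov_f, m$Ainv)
  mns <- tapply(rec$y, rec$age_month, mean)
  pred <- predict_factor_means(sol_f, "age")
  expect_equal(unname(pred$predicted), unname(as.numeric(mns)), tolerance = 1e-4)
})

test_that("predicted marginal means equal raw/marginal means in balanced designs", {
  # two orthogonal balanced factors, no random variation
  set.seed(5)
  grid <- expand.grid(f1 = 1:3, f2 = 1:4, rep = 1:5)
  eff1 <- c(0, 2, 4)[grid$f1]
  eff2 <- c(0, 1, 2, 3)[grid$f2]
  y <- 10 + eff1 + eff2 + rnorm(nrow(grid), 0, 0.3)
  ped <- as_pedigree(data.frame(animal = paste0("b", 1:6), sire = "0", dam = "0"))
  rec <- data.frame(boar = rep(paste0("b", 1:6), length.out = nrow(grid)),
                    age_month = 8L, f1 = grid$f1, f2 = grid$f2, y = y)
  des <- build_design(rec, model_spec("y", fixed = c("f1", "f2"),
                                      random = c("animal", "pe"),
                                      class_structure = "off"), ped)
  cov <- cov_structure(Sigma_a = 1e-6, Sigma_pe = 1e-6, sigma_e2 = 0.09)
  sol <- assemble_and_solve(des, cov, a_inverse(ped))
  pm1 <- predict_factor_means(sol, "f1")
  marg1 <- tapply(y, grid$f1, mean)
  expect_equal(unname(pm1$predicted), unname(as.numeric(marg1)), tolerance = 1e-3)
  expect_true(all(pm1$se > 0))
})

test_that("predicted means are invariant to the reference-level choice", {
  m <- make_univ(seed = 21)
  rec <- m$dat$records
  cov <- cov_structure(Sigma_a = 4, Sigma_pe = 3, sigma_e2 = 5)
  des_a <- build_design(rec, model_spec("y", fixed = c("age", "month_of_year"),
                                        random = c("animal", "pe"),
                                        class_structure = "off"), m$dat$ped)
  pm_a <- predict_factor_means(assemble_and_solve(des_a, cov, m$Ainv), "age")

  # relabel month levels so a different one becomes the reference
  rec2 <- rec
  rec2$month_of_year <- factor(rec2$month_of_year,
                               levels = rev(sort(unique(rec2$month_of_year))))
  des_b <- build_design(rec2, model_spec("y", fixed = c("age", "month_of_year"),
                                         random = c("animal", "pe"),
                                         class_structure = "off"), m$dat$ped)
  pm_b <- predict_factor_means(assemble_and_solve(des_b, cov, m$Ainv), "age")
  expect_equal(pm_a$predicted, pm_b$predicted, tolerance = 1e-8)
})

test_that("unadjusted means agree with direct recomputation and flag singletons", {
  rec <- data.frame(age_month = c(rep(8L, 10), rep(9L, 9), 10L),
                    y = c(rnorm(19), 5))
  um <- unadjusted_means(rec, "y", "age_month")
  y8 <- rec$y[rec$age_month == 8]
  expect_equal(um$mean[1], mean(y8))
  expect_equal(um$se[1], sd(y8) / sqrt(10))
  expect_equal(um$upper[1] - um$lower[1], 2 * 1.96 * um$se[1])
  expect_true(um$flag_single[3])
  expect_true(is.na(um$se[3]))

  # constant trait: zero-width interval
  recc <- data.frame(age_month = rep(8L, 5), y = rep(3, 5))
  umc <- unadjusted_means(recc, "y", "age_month")
  expect_equal(umc$mean, 3)
  expect_equal(umc$upper - umc$lower, 0)
})

test_that("observed-frequency weighting matches equal weighting in balanced data only", {
  m <- make_univ(seed = 33)
  cov <- cov_structure(Sigma_a = 4, Sigma_pe = 3, sigma_e2 = 5)
  sol <- assemble_and_solve(m$des, cov, m$Ainv)
  pm_eq <- predict_factor_means(sol, "age", weights = "equal")
  pm_ob <- predict_factor_means(sol, "age", weights = "observed")
  # this design is balanced over rest/month only by sampling; with a single
  # extra fixed factor absent the two weightings coincide exactly because
  # only the age factor is in the model
  expect_equal(pm_eq$predicted, pm_ob$predicted, tolerance = 1e-10)

  # with an unbalanced second factor they differ
  rec <- m$dat$records
  des2 <- build_design(rec, model_spec("y", fixed = c("age", "month_of_year"),
                                       random = c("animal", "pe"),
                                       class_structure = "off"), m$dat$ped)
  sol2 <- assemble_and_solve(des2, cov, m$Ainv)
  pm2_eq <- predict_factor_means(sol2, "age", weights = "equal")
  pm2_ob <- predict_factor_means(sol2, "age", weights = "observed")
  expect_false(isTRUE(all.equal(pm2_eq$predicted, pm2_ob$predicted,
                                tolerance = 1e-10)))
})
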