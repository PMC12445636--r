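test_that("pedigree simulation respects the mating configuration and the seed", {
  set.seed(1)
  ped1 <- simulate_pedigree(10L, integer(0), integer(0))
  expect_equal(nrow(ped1), 10L)          # founders only
  expect_true(all(ped1$sire == 0L))

  set.seed(2)
  ped2 <- simulate_pedigree(10L, 5L, 2L)
  expect_equal(nrow(ped2), 20L)          # 10 founders + 5 x 2 progeny
  expect_equal(sum(ped2$generation == 1L), 10L)

  set.seed(3); a <- simulate_pedigree(12L, c(6L, 4L), 3L)
  set.seed(3); b <- simulate_pedigree(12L, c(6L, 4L), 3L)
  expect_identical(a, b)

  expect_error(simulate_pedigree(1L), "at least 2")
})

test_that("breeding values follow A x Sigma: founder variance and full-sib covariance", {
  # zero covariance -> all zero
  set.seed(1)
  ped <- simulate_pedigree(10L, 5L, 2L)
  bv0 <- sample_breeding_values(ped, matrix(0, 3, 3))
  expect_true(all(bv0 == 0))

  # 2,000 founders, Sigma = diag(100): per-class sample variance within 100 +/- 10
  set.seed(11)
  pedf <- as_pedigree(data.frame(animal = paste0("f", 1:2000),
                                 sire = "0", dam = "0"))
  bv <- sample_breeding_values(pedf, diag(100, 3))
  expect_true(all(abs(apply(bv, 2, var) - 100) < 10))

  # full-sib pairs: cov between sibs ~ 0.5 * Sigma
  set.seed(13)
  n_fam <- 2000L
  df <- data.frame(
    animal = c(paste0("s", 1:n_fam), paste0("d", 1:n_fam),
               paste0("x", 1:n_fam), paste0("y", 1:n_fam)),
    sire = c(rep("0", 2 * n_fam), paste0("s", 1:n_fam), paste0("s", 1:n_fam)),
    dam = c(rep("0", 2 * n_fam), paste0("d", 1:n_fam), paste0("d", 1:n_fam)))
  pedfs <- as_pedigree(df)
  Sig <- matrix(c(100, 50, 0, 50, 100, 0, 0, 0, 100), 3)
  bv <- sample_breeding_values(pedfs, Sig)
  x <- bv[paste0("x", 1:n_fam), ]
  y <- bv[paste0("y", 1:n_fam), ]
  cc <- cov(x, y)
  expect_true(all(abs(cc - 0.5 * Sig) < 10))

  expect_error(sample_breeding_values(ped, matrix(c(1, 2, 2, 1), 2)),
               "positive semidefinite")
})

test_that("records reproduce the configured mean exactly when all variances are zero", {
  tr <- flat_trait(a = 0, pe = 0, e = 0, mean = 42)
  dat <- small_dataset(seed = 5, trait = tr)
  expect_true(all(dat$records$y == 42))
})

test_that("record variance and intra-boar correlation match the generative components", {
  # single class, many boars x 10 records
  tr <- flat_trait(a = 30, pe = 20, hys = 0, clt = 0, e = 50, mean = 0)
  cfg <- sim_config(pedigree = list(n_founders = 100L, n_matings = 500L, progeny = 2L),
                    schedule = data.frame(age_month = 8:12, n_per_month = 2L),
                    traits = list(tr), seed = 21L)
  dat <- simulate_dataset(cfg)
  y <- dat$records$y
  sp2 <- 30 + 20 + 50
  expect_lt(abs(var(y) - sp2) / sp2, 0.05)
  # intra-boar correlation ~ repeatability = (a + pe) / p
  wide <- split(y, dat$records$boar)
  grand <- mean(y)
  between <- mean(vapply(wide, function(v) (mean(v) - grand)^2, 0)) -
    mean(vapply(wide, var, 0)) / 10
  icc <- between / var(y)
  expect_lt(abs(icc - 50 / sp2), 0.06)
})

test_that("simulated datasets are reproducible bit-for-bit from the config seed", {
  cfg <- sim_config(schedule = data.frame(age_month = c(8L, 15L, 30L),
                                          n_per_month = 2L),
                    traits = list(flat_trait()), seed = 33L,
                    culling = culling_rule("y", k = 2L, quantile = 0.3, prob = 0.5))
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  expect_identical(a$cull_log, b$cull_log)
})

test_that("culling boundary cases: zero quantile culls nobody, certain culling keeps k records", {
  tr <- flat_trait(a = 4, pe = 3, e = 5)
  dat <- small_dataset(seed = 8, ages = c(8L, 9L, 10L, 11L, 12L), trait = tr)
  set.seed(1)
  none <- apply_culling(dat$records, culling_rule("y", k = 2L, quantile = 0, prob = 1))
  expect_identical(none$records, dat$records)
  expect_equal(nrow(none$log), 0L)

  set.seed(1)
  all_cull <- apply_culling(dat$records, culling_rule("y", k = 2L, quantile = 1, prob = 1))
  kept <- table(all_cull$records$boar)
  expect_true(all(kept == 2L))           # every boar keeps exactly its first k records
  expect_error(culling_rule("y", k = 0L), ">= 1")
})

test_that("culling on low values raises the surviving mean at later ages", {
  # declining trait with boar-level variation; selection against low values
  # must leave survivors above the uncensored mean at old ages
  ages <- 7:60
  curve <- -0.3 * (ages - 7)
  tr <- trait_spec("q", mean = 50, age_effect = curve,
                   components = cbind(a = 30, pe = 20, hys = 0, clt = 0, e = 20)[rep(1, 3), ],
                   cor_a = cor3(1, 1, 1) * 0.999 + diag(3) * 0.001,
                   cor_pe = cor3(1, 1, 1) * 0.999 + diag(3) * 0.001)
  wins <- 0L
  n_rep <- 50L
  for (i in seq_len(n_rep)) {
    cfg <- sim_config(pedigree = list(n_founders = 20L, n_matings = 20L, progeny = 3L),
                      schedule = data.frame(age_month = seq(7L, 59L, by = 4L),
                                            n_per_month = 1L),
                      traits = list(tr), seed = 400L + i)
    dat <- simulate_dataset(cfg)
    set.seed(4000L + i)
    culled <- apply_culling(dat$records,
                            culling_rule("q", k = 3L, quantile = 0.35, prob = 0.7))
    old_c <- culled$records$age_month >= 24
    old_u <- dat$records$age_month >= 24
    if (mean(culled$records$q[old_c]) > mean(dat$records$q[old_u])) wins <- wins + 1L
  }
  expect_gte(wins, 45L)
})
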