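# Config-driven orchestration: simulate -> prepare -> fit -> report, and
# the selection demonstration. These functions are the package's
# work-flow surface; they only chain the module functions together.

#' Simulate a complete dataset
#'
#' Runs pedigree simulation, record generation and (optionally) culling
#' under the seed stored in the configuration, and writes the pedigree,
#' record table, true effects, culling log and configuration to `dir`
#' when given. Reruns with the same configuration are reproducible
#' bit-for-bit.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (`NULL` = nothing written).
#' @return List: `ped`, `records` (after culling), `records_uncensored`,
#'   `truth`, `cull_log`.
#' @export
simulate_dataset <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  ped <- simulate_pedigree(cfg$pedigree$n_founders, cfg$pedigree$n_matings,
                           cfg$pedigree$progeny)
  boars <- if (identical(cfg$phenotyped, "last")) {
    ped$id[ped$generation == max(ped$generation)]
  } else {
    ped$id[ped$generation > 0L]
  }
  sim <- simulate_records(ped, cfg, boars = boars)
  out <- list(ped = ped, records = sim$records,
              records_uncensored = sim$records, truth = sim$truth,
              cull_log = NULL)
  if (!is.null(cfg$culling)) {
    cl <- apply_culling(sim$records, cfg$culling)
    out$records <- cl$records
    out$cull_log <- cl$log
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    lab <- c("0", ped$id)   # index 0 = unknown parent
    utils::write.csv(data.frame(animal = ped$id,
                                sire = lab[ped$sire + 1L],
                                dam = lab[ped$dam + 1L]),
                     file.path(dir, "pedigree.csv"), row.names = FALSE)
    utils::write.csv(out$records, file.path(dir, "records.csv"), row.names = FALSE)
    if (!is.null(out$cull_log)) {
      utils::write.csv(out$cull_log, file.path(dir, "culling_log.csv"),
                       row.names = FALSE)
    }
    for (tr in names(out$truth)) {
      utils::write.csv(data.frame(animal = rownames(out$truth[[tr]]$bv),
                                  out$truth[[tr]]$bv),
                       file.path(dir, paste0("true_bv_", tr, ".csv")),
                       row.names = FALSE)
    }
    yaml::write_yaml(.cfg_as_list(cfg), file.path(dir, "sim_config.yaml"))
    writeLines(jsonlite::toJSON(list(seed = cfg$seed,
                                     n_records = nrow(out$records),
                                     n_animals = nrow(ped),
                                     r_version = as.character(getRversion())),
                                auto_unbox = TRUE, pretty = TRUE),
               file.path(dir, "manifest.json"))
  }
  out
}

.cfg_as_list <- function(cfg) {
  list(pedigree = cfg$pedigree,
       schedule = as.list(cfg$schedule),
       n_clt = cfg$n_clt, seed = cfg$seed,
       traits = lapply(cfg$traits, function(tr) {
         list(name = tr$name, mean = tr$mean,
              components = apply(tr$components, 1L, as.list),
              cor_a = as.list(as.data.frame(tr$cor_a)),
              cor_pe = as.list(as.data.frame(tr$cor_pe)))
       }),
       culling = if (is.null(cfg$culling)) NULL else unclass(cfg$culling))
}

#' Fit the repeatability and trivariate models to a dataset
#'
#' Applies the minimum-ejaculate filter, fits the trivariate age-class
#' model and, optionally, a univariate model per age class on that
#' class's records alone (the contrast that exposes selection bias), and
#' assembles the genetic-parameter and correlation report tables.
#'
#' @param data a [simulate_dataset()] result, or any list with `ped` and
#'   `records`.
#' @param trait trait column to analyse.
#' @param random random terms to include (terms simulated with zero
#'   variance can be omitted).
#' @param univariate_per_class also fit each class univariately.
#' @param min_per_class minimum-ejaculate filter threshold.
#' @param opts a [reml_control()].
#' @return List: `trivariate` (reml_fit), `univariate` (list per class or
#'   NULL), `params`, `correlations`, `filter_log`.
#' @export
fit_dataset <- function(data, trait,
                        random = c("animal", "pe", "hys", "clt"),
                        univariate_per_class = FALSE,
                        min_per_class = 3L,
                        opts = reml_control()) {
  rec <- data$records
  if (!"age_class" %in% names(rec)) rec$age_class <- assign_age_class(rec$age_month)
  fl <- filter_min_records(rec, min_per_class)
  rec <- fl$records
  Ainv <- a_inverse(data$ped)
  des3 <- build_design(rec, model_spec(trait, random = random,
                                       class_structure = "trivariate"), data$ped)
  fit3 <- fit_trivariate(des3, Ainv = Ainv, opts = opts)
  uni <- NULL
  if (univariate_per_class) {
    uni <- lapply(c("T1", "T2", "T3"), function(cl) {
      rc <- rec[rec$age_class == cl, , drop = FALSE]
      des1 <- build_design(rc, model_spec(trait, random = random,
                                          class_structure = "off"), data$ped)
      fit_univariate(des1, Ainv = Ainv, opts = opts)
    })
    names(uni) <- c("T1", "T2", "T3")
  }
  fits <- stats::setNames(list(fit3), trait)
  list(trivariate = fit3, univariate = uni,
       params = report_genetic_parameters(fits),
       correlations = report_genetic_correlations(fits),
       filter_log = fl$removed_boars)
}

#' Demonstrate the effect of culling on age-effect and variance estimates
#'
#' Simulates replicate datasets with the configured culling rule and
#' reports, per replicate: (i) the mean squared error of the predicted
#' and of the unadjusted age-effect curves against the true curve
#' (predicted means come from the repeatability model, which uses records
#' of culled boars and so corrects the age trend), and (ii) univariate
#' versus trivariate estimates of the post-peak additive-genetic variance
#' against the simulated truth (the univariate fit cannot account for
#' selection; the trivariate fit, which includes the unselected early
#' class, can).
#'
#' @param cfg a [sim_config()] with a culling rule.
#' @param trait trait under culling.
#' @param n_reps number of replicates.
#' @param random random terms to fit.
#' @param fit_variances also run the univariate/trivariate REML contrast
#'   (slower); otherwise only the age-curve comparison is produced.
#' @param ages_for_mse ages (months) over which curve MSEs are compared;
#'   default the post-peak class 24-60.
#' @param opts a [reml_control()].
#' @return data.frame with one row per replicate: `mse_predicted`,
#'   `mse_unadjusted` and, if requested, `sa2_T3_true`, `sa2_T3_uni`,
#'   `sa2_T3_tri`.
#' @export
selection_demo <- function(cfg, trait = "motility", n_reps = 10L,
                           random = c("animal", "pe"),
                           fit_variances = FALSE,
                           ages_for_mse = 24:60,
                           opts = reml_control()) {
  stopifnot(inherits(cfg, "sim_config"), !is.null(cfg$culling))
  rows <- lapply(seq_len(n_reps), function(rp) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + rp
    dat <- simulate_dataset(cfg_r)
    rec <- dat$records
    rec$age_class <- assign_age_class(rec$age_month)
    tru <- dat$truth[[trait]]
    spec1 <- model_spec(trait, random = random, class_structure = "off")
    des1 <- build_design(rec, spec1, dat$ped)
    Ainv <- a_inverse(dat$ped)
    # true components of the record's class mix, for the BLUP solve
    cls_tab <- table(factor(rec$age_class, c("T1", "T2", "T3")))
    wcl <- as.numeric(cls_tab) / sum(cls_tab)
    cmp <- tru$components
    cov1 <- cov_structure(
      Sigma_a = sum(wcl * cmp[, "a"]),
      Sigma_pe = if ("pe" %in% random) sum(wcl * cmp[, "pe"]) else NULL,
      sigma_hys2 = if ("hys" %in% random) sum(wcl * cmp[, "hys"]) else NULL,
      sigma_clt2 = if ("clt" %in% random) sum(wcl * cmp[, "clt"]) else NULL,
      sigma_e2 = sum(wcl * cmp[, "e"]))
    sol <- assemble_and_solve(des1, cov1, Ainv)
    pm <- predict_factor_means(sol, "age")
    um <- unadjusted_means(rec, trait, "age_month")
    ages <- intersect(ages_for_mse, as.integer(as.character(pm$level)))
    truth_curve <- tru$mean + tru$age_effect[ages - 6L] +
      mean(tru$rest_effect) + mean(tru$month_effect)
    pred <- pm$predicted[match(ages, as.integer(as.character(pm$level)))]
    unadj <- um$mean[match(ages, um$level)]
    out <- data.frame(rep = rp,
                      mse_predicted = mean((pred - truth_curve)^2, na.rm = TRUE),
                      mse_unadjusted = mean((unadj - truth_curve)^2, na.rm = TRUE))
    if (fit_variances) {
      fl <- filter_min_records(rec, 3L)
      rec3 <- fl$records
      des3 <- build_design(rec3, model_spec(trait, random = random,
                                            class_structure = "trivariate"),
                           dat$ped)
      fit3 <- fit_trivariate(des3, Ainv = Ainv, opts = opts)
      recT3 <- rec3[rec3$age_class == "T3", , drop = FALSE]
      desu <- build_design(recT3, spec1, dat$ped)
      fitu <- fit_univariate(desu, Ainv = Ainv, opts = opts)
      out$sa2_T3_true <- cmp["T3", "a"]
      out$sa2_T3_uni <- as.numeric(fitu$estimates$Sigma_a)
      out$sa2_T3_tri <- fit3$estimates$Sigma_a[3L, 3L]
    }
    out
  })
  do.call(rbind, rows)
}

#' Serialize a REML fit
#'
#' Writes the estimates, standard errors, log-likelihood and iteration
#' trace as JSON (plus the genetic-parameter table as CSV alongside).
#'
#' @param fit a `reml_fit`.
#' @param path output path for the JSON file.
#' @export
write_reml_fit <- function(fit, path) {
  stopifnot(inherits(fit, "reml_fit"))
  est <- fit$estimates
  obj <- list(
    theta = as.list(fit$theta),
    se = as.list(vc_se(fit)),
    Sigma_a = if (!is.null(est$Sigma_a)) unclass(as.matrix(est$Sigma_a)) else NULL,
    Sigma_pe = if (!is.null(est$Sigma_pe)) unclass(as.matrix(est$Sigma_pe)) else NULL,
    sigma_e2 = est$sigma_e2,
    loglik = fit$loglik, converged = fit$converged,
    iterations = fit$iterations,
    trace = fit$trace)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, null = "null"), path)
  csv <- sub("\\.json$", "_params.csv", path)
  utils::write.csv(genetic_ratios(fit), csv, row.names = FALSE)
  invisible(path)
}
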