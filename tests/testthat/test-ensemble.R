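test_that("an equality-determined system yields a constant ensemble", {
  toy <- toy_chain_model(reversible = TRUE)
  lim <- build_lim(toy, fixed_fluxes = c(R1 = 1),
                   measured_fluxes = data.frame(reaction = "R3", value = 1, sd = 0.1))
  ## with R1 fixed the whole chain is determined: polytope is one point
  ens <- sample_ensemble(lim, sampler_config(n_burnin = 10, n_iter = 100,
                                             thin = 10, seed = 1))
  expect_true(all(abs(sweep(ens$samples, 2, c(1, 1, 1))) < 1e-9))
  expect_gt(nrow(ens$samples), 1)
})

test_that("sampling reproduces truncated-normal moments in one dimension", {
  for (case in list(c(b = 1.0, sd = 0.1), c(b = 0.05, sd = 0.1))) {
    lim <- one_dof_lim(case[["b"]], case[["sd"]])
    ens <- sample_ensemble(lim, sampler_config(n_burnin = 2e3, n_iter = 5e4,
                                               thin = 5, jump = 0.5, seed = 42))
    v <- ens$samples[, "v"]
    expect_gte(min(v), -1e-12)   # truncation respected
    mom <- truncnorm_moments(case[["b"]], case[["sd"]])
    se <- mc_se(v)
    expect_lt(abs(mean(v) - mom[["mean"]]), 3 * se + 1e-4)
    expect_lt(abs(stats::sd(v) - mom[["sd"]]), 3 * se + 2e-3)
  }
})

test_that("kept samples always satisfy the constraints", {
  lim <- one_dof_lim(0.05, 0.1)  # truncation strongly active
  ens <- sample_ensemble(lim, sampler_config(n_burnin = 1e3, n_iter = 1e4,
                                             thin = 2, jump = 0.5, seed = 9))
  expect_true(all(lim$G %*% t(ens$samples) >= -1e-9))
})

test_that("identical seed and configuration give identical ensembles", {
  lim <- two_dof_lim(1, 0.2, 0.5, 0.1)
  cfg <- sampler_config(n_burnin = 500, n_iter = 2000, thin = 2, seed = 77)
  e1 <- sample_ensemble(lim, cfg)
  e2 <- sample_ensemble(lim, cfg)
  expect_identical(e1$samples, e2$samples)
  e3 <- sample_ensemble(lim, sampler_config(n_burnin = 500, n_iter = 2000,
                                            thin = 2, seed = 78))
  expect_false(identical(e1$samples, e3$samples))
})

test_that("independent dimensions factorize into independent truncated normals", {
  lim <- two_dof_lim(1.0, 0.15, 0.08, 0.1)
  ens <- sample_ensemble(lim, sampler_config(n_burnin = 2e3, n_iter = 5e4,
                                             thin = 5, jump = 0.5, seed = 5))
  for (j in 1:2) {
    v <- ens$samples[, j]
    mom <- truncnorm_moments(lim$b[j], lim$sd[j])
    se <- mc_se(v)
    expect_lt(abs(mean(v) - mom[["mean"]]), 3 * se + 1e-4)
    expect_lt(abs(stats::sd(v) - mom[["sd"]]), 3 * se + 2e-3)
  }
  ## near-zero cross-correlation
  expect_lt(abs(stats::cor(ens$samples[, 1], ens$samples[, 2])), 0.1)
})

test_that("autocorrelation is normalized and flags constant traces", {
  ens <- structure(list(
    samples = matrix(stats::rnorm(4000), 2000, 2,
                     dimnames = list(NULL, c("ra", "rb"))),
    reaction_labels = c("ra", "rb"),
    config = sampler_config(n_burnin = 0, n_iter = 2000, thin = 1),
    acceptance_rate = 1), class = "flux_ensemble")
  ac <- autocorrelation(ens, "ra", max_lag = 10)
  expect_equal(ac[1], 1)
  ## white-noise band for an i.i.d. column
  expect_true(all(abs(ac[-1]) <= 3 / sqrt(2000)))

  const <- ens; const$samples[, "rb"] <- 2
  acc <- autocorrelation(const, "rb", max_lag = 5)
  expect_equal(as.numeric(acc), c(1, 0, 0, 0, 0, 0))
  expect_true(attr(acc, "constant"))
})

test_that("autocorrelation recovers the AR(1) coefficient", {
  set.seed(31)
  n <- 20000; rho <- 0.5
  x <- as.numeric(stats::arima.sim(list(ar = rho), n))
  ens <- structure(list(
    samples = matrix(x, ncol = 1, dimnames = list(NULL, "r")),
    reaction_labels = "r",
    config = sampler_config(n_burnin = 0, n_iter = n, thin = 1),
    acceptance_rate = 1), class = "flux_ensemble")
  ac <- autocorrelation(ens, "r", max_lag = 3)
  ## 3 Monte-Carlo standard errors of acf(1) at this chain length ~ 0.02
  expect_equal(ac[2], rho, tolerance = 0.03)
})

test_that("ensemble summaries report means, sds and quantiles", {
  samples <- matrix(c(0, 1, 0, 1, 2, 2, 2, 2), 4, 2,
                    dimnames = list(NULL, c("a", "b")))
  ens <- structure(list(samples = samples, reaction_labels = c("a", "b"),
                        config = sampler_config(n_burnin = 0, n_iter = 4, thin = 1),
                        acceptance_rate = 1), class = "flux_ensemble")
  s <- ensemble_summary(ens)
  expect_equal(s$mean, c(0.5, 2))
  expect_equal(s$sd[2], 0)
  expect_named(s, c("reaction", "mean", "sd", "q2.5", "q50", "q97.5"))
})

test_that("ensembles persist as CSV with a JSON sidecar", {
  lim <- one_dof_lim(1, 0.2)
  ens <- sample_ensemble(lim, sampler_config(n_burnin = 100, n_iter = 1000,
                                             thin = 10, seed = 3))
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_ensemble(ens, csv, js)
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), nrow(ens$samples))
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(meta$seed, 3)
  expect_true(meta$acceptance_rate >= 0 && meta$acceptance_rate <= 1)
})

test_that("sampling requires measured fluxes and a feasible start", {
  toy <- toy_chain_model()
  expect_error(sample_ensemble(build_lim(toy), sampler_config()),
               "measured")
  lim_bad <- build_lim(toy, fixed_fluxes = c(R1 = -1),
                       measured_fluxes = data.frame(reaction = "R3",
                                                    value = 1, sd = 0.1))
  expect_error(sample_ensemble(lim_bad, sampler_config(n_burnin = 10,
                                                       n_iter = 100, thin = 1)),
               "feasible|infeasible")
})
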