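test_that("build_lim assembles balance rows, fixed fluxes and irreversibility", {
  toy <- toy_chain_model()
  lim <- build_lim(toy, fixed_fluxes = c(R1 = 1))
  expect_equal(nrow(lim$E), 3)          # 2 balances + 1 fixed
  expect_equal(lim$f, c(0, 0, 1))
  expect_equal(nrow(lim$G), 3)          # all three irreversible
  expect_true(all(rowSums(lim$G != 0) == 1))
  expect_equal(lim$h, c(0, 0, 0))
  expect_null(lim$A)

  ## all-reversible model: no inequality rows
  lim_rev <- build_lim(toy_chain_model(reversible = TRUE))
  expect_equal(nrow(lim_rev$G), 0)

  expect_error(build_lim(toy, fixed_fluxes = c(Rx = 1)), "unknown")

  ## brain fixture bookkeeping: E rows = internal metabolites + 5 fixes
  ref <- brain_reference_fit()
  n_internal <- nrow(stoichiometric_matrix(ref$model))
  expect_equal(nrow(ref$lim$E), n_internal + 5)
  expect_null(ref$lim$A)
})

test_that("steady state forces all chain fluxes equal to the fixed input", {
  lim <- build_lim(toy_chain_model(), fixed_fluxes = c(R1 = 1))
  fit <- solve_fba(lim, objective_spec(c(R3 = 1)))
  expect_equal(unname(fit$values), c(1, 1, 1), tolerance = 1e-9)
  expect_equal(fit$objective_value, 1, tolerance = 1e-9)
  ## feasibility post-conditions
  expect_lt(max(abs(lim$E %*% fit$values - lim$f)), 1e-9)
  expect_gt(min(lim$G %*% fit$values - lim$h), -1e-9)
})

test_that("a parallel-branch optimum reports the total but not the split", {
  m <- branched_model()
  lim <- build_lim(m, fixed_fluxes = c(R_in = 1))
  fit <- solve_fba(lim, objective_spec(c(R_out = 1)))
  expect_equal(fit$objective_value, 1, tolerance = 1e-9)
  fv <- flux_variability(lim, objective_spec(c(R_out = 1)), 1.0)
  branch <- fv[fv$reaction %in% c("R_1", "R_2"), ]
  expect_equal(branch$min, c(0, 0), tolerance = 1e-8)
  expect_equal(branch$max, c(1, 1), tolerance = 1e-8)
  fixed_rows <- fv[fv$reaction %in% c("R_in", "R_out"), ]
  expect_lt(max(fixed_rows$width), 1e-8)
})

test_that("infeasible and unbounded problems raise informative errors", {
  toy <- toy_chain_model()
  ## R1 forced negative against irreversibility -> infeasible
  lim_bad <- build_lim(toy, fixed_fluxes = c(R1 = -1))
  expect_error(solve_fba(lim_bad, objective_spec(c(R3 = 1))), "infeasible")

  ## reversible chain with no fixed flux: objective unbounded
  lim_unb <- build_lim(toy_chain_model(reversible = TRUE))
  expect_error(solve_fba(lim_unb, objective_spec(c(R3 = 1))),
               "unbounded.*R[123]")
})

test_that("solve_fba agrees with a vertex-enumeration oracle on random models", {
  for (seed in 1:25) {
    inst <- random_instance(seed)
    lim <- structure(list(E = inst$E, f = inst$f, G = inst$G, h = inst$h,
                          A = NULL, b = NULL, sd = NULL,
                          reaction_labels = paste0("v", seq_len(inst$n))),
                     class = "lim")
    obj <- objective_spec(stats::setNames(inst$cvec, lim$reaction_labels))
    fit <- solve_fba(lim, obj)
    orc <- oracle_lp_vertex(inst, "maximize")
    expect_equal(fit$objective_value, orc$objective, tolerance = 1e-8,
                 info = paste("seed", seed))
  }
})

test_that("the optimum is invariant under reaction reordering", {
  for (seed in c(3, 11)) {
    inst <- random_instance(seed)
    labels <- paste0("v", seq_len(inst$n))
    lim <- structure(list(E = inst$E, f = inst$f, G = inst$G, h = inst$h,
                          A = NULL, b = NULL, sd = NULL,
                          reaction_labels = labels), class = "lim")
    obj <- objective_spec(stats::setNames(inst$cvec, labels))
    set.seed(seed + 1000)
    p <- sample(inst$n)
    limp <- structure(list(E = inst$E[, p], f = inst$f,
                           G = inst$G[, p], h = inst$h,
                           A = NULL, b = NULL, sd = NULL,
                           reaction_labels = labels[p]), class = "lim")
    f1 <- solve_fba(lim, obj)
    f2 <- solve_fba(limp, obj)
    expect_equal(f1$objective_value, f2$objective_value, tolerance = 1e-8)
    expect_equal(f1$values[labels], f2$values[labels], tolerance = 1e-6)
  }
})

test_that("scaling the right-hand sides scales the optimum linearly", {
  toy <- toy_chain_model()
  for (cc in c(0.5, 3)) {
    lim1 <- build_lim(toy, fixed_fluxes = c(R1 = 1))
    lim2 <- build_lim(toy, fixed_fluxes = c(R1 = cc))
    f1 <- solve_fba(lim1, objective_spec(c(R3 = 1)))
    f2 <- solve_fba(lim2, objective_spec(c(R3 = 1)))
    expect_equal(cc * f1$values, f2$values, tolerance = 1e-9)
  }
})

test_that("flux variability brackets the FBA solution with nonnegative widths", {
  inst <- random_instance(42)
  lim <- structure(list(E = inst$E, f = inst$f, G = inst$G, h = inst$h,
                        A = NULL, b = NULL, sd = NULL,
                        reaction_labels = paste0("v", seq_len(inst$n))),
                   class = "lim")
  obj <- objective_spec(stats::setNames(inst$cvec, lim$reaction_labels))
  fv <- flux_variability(lim, obj, optimum_fraction = 0.9)
  expect_true(all(fv$width >= -1e-9))
  expect_true(all(fv$min <= fv$fba + 1e-7))
  expect_true(all(fv$max >= fv$fba - 1e-7))
})

test_that("fully determined chains have zero flux variability", {
  lim <- build_lim(toy_chain_model(), fixed_fluxes = c(R1 = 1))
  fv <- flux_variability(lim, objective_spec(c(R3 = 1)), 1.0)
  expect_lt(max(fv$width), 1e-9)
})

test_that("flux CSV export includes the objective row", {
  lim <- build_lim(toy_chain_model(), fixed_fluxes = c(R1 = 1))
  fit <- solve_fba(lim, objective_spec(c(R3 = 1)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_flux_csv(fit, path)
  df <- read_flux_csv(path)
  expect_equal(df$value[df$reaction_id == "objective"], 1, tolerance = 1e-9)
  expect_setequal(setdiff(df$reaction_id, "objective"), c("R1", "R2", "R3"))
})
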