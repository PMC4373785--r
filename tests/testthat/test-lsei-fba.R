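test_that("fold-change tables validate and convert scales", {
  fc <- fold_change_table(c(g1 = 1, g2 = -1), scale = "log2")
  expect_equal(unclass(fc), c(g1 = 2, g2 = 0.5))
  expect_error(fold_change_table(c(g1 = -0.5), scale = "linear"), "positive")
  expect_error(fold_change_table(c(1, 2)), "named")
})

test_that("aggregation policies combine multi-gene reactions as specified", {
  assoc <- list(R = c("g1", "g2"))
  expect_equal(aggregate_fold_changes(assoc, fold_change_table(c(g1 = 1.2, g2 = 0.8)))[["R"]], 1.0)
  expect_equal(aggregate_fold_changes(assoc, fold_change_table(c(g1 = 4, g2 = 1)),
                                      policy = "geometric_mean")[["R"]], 2.0)
  expect_equal(aggregate_fold_changes(assoc, fold_change_table(c(g1 = 4, g2 = 1)),
                                      policy = "minimum")[["R"]], 1.0)
  ## single gene: identical under any policy
  assoc1 <- list(R = "g1")
  fc1 <- fold_change_table(c(g1 = 0.5))
  for (p in c("average", "minimum", "geometric_mean"))
    expect_equal(aggregate_fold_changes(assoc1, fc1, policy = p)[["R"]], 0.5)
  ## genes absent from the table are skipped; all-absent reactions omitted
  assoc2 <- list(Ra = c("g1", "gX"), Rb = "gY")
  agg <- aggregate_fold_changes(assoc2, fold_change_table(c(g1 = 2)))
  expect_identical(names(agg), "Ra")
  expect_equal(agg[["Ra"]], 2)
  expect_warning(aggregate_fold_changes(list(R = "gZ"), fold_change_table(c(g1 = 2))),
                 "no reaction")
})

test_that("the structured policy takes minima over AND complexes", {
  assoc <- list(R = c("g1", "g2", "g3"))
  attr(assoc, "expression") <- c(R = "(g1 and g2) or g3")
  fc <- fold_change_table(c(g1 = 0.2, g2 = 1.0, g3 = 0.8))
  ## AND group -> min(0.2, 1.0) = 0.2; OR branches averaged with 0.8
  expect_equal(aggregate_fold_changes(assoc, fc, structured = TRUE)[["R"]], 0.5)
  ## flattened default: mean of all three
  expect_equal(aggregate_fold_changes(assoc, fc)[["R"]], mean(c(0.2, 1, 0.8)))
})

test_that("rough estimates scale signed reference fluxes", {
  expect_equal(rough_estimate(c(R = 2), c(R = 0.5))[["R"]], 1.0)
  ## a release flux stays a release flux under up-regulation
  expect_equal(rough_estimate(c(R = -0.013), c(R = 2))[["R"]], -0.026)
  expect_length(rough_estimate(c(R = 1), numeric(0)), 0)
  expect_error(rough_estimate(c(R = 1), c(Q = 1)), "undefined")
})

test_that("unit fold changes return the reference flux exactly", {
  ref <- brain_reference_fit()
  fc1 <- synthetic_fold_changes(ref$model, noise_sd = 0, seed = 1)
  expect_true(all(unclass(fc1) == 1))
  fit <- lsei_fba(ref$model, ref$fit, fc1)
  expect_lt(max(abs(fit$values - ref$fit$values)), 1e-8)
  expect_lt(fit$residual_ss, 1e-16)
})

test_that("halving one branch's expression shifts flux to the sibling", {
  m <- branched_model()
  ref <- c(R_in = 1, R_1 = 0.5, R_2 = 0.5, R_out = 1)
  fit <- lsei_fba(m, ref, fold_change_table(c(g0 = 1, g1 = 0.5, g2 = 1, g3 = 1)))
  ## frozen from the brute-force QP oracle on this 2-D polytope:
  ## minimize 2(t+u-1)^2 + (t-1/4)^2 + (u-1/2)^2 => t = 0.35, u = 0.6
  expect_equal(unname(fit$values["R_1"]), 0.35, tolerance = 1e-8)
  expect_equal(unname(fit$values["R_2"]), 0.60, tolerance = 1e-8)
  expect_equal(unname(fit$values["R_in"]), 0.95, tolerance = 1e-8)
  ## and the oracle agrees
  lim <- build_lim(m)
  inst <- list(E = lim$E, f = lim$f, G = lim$G, h = lim$h, d = 2)
  A <- diag(4); b <- c(1, 0.25, 0.5, 1)
  orc <- oracle_lsei_active_set(inst, A, b)
  expect_equal(unname(fit$values), orc$x, tolerance = 1e-7)
})

test_that("the attained objective never exceeds the reference objective", {
  ref <- brain_reference_fit()
  for (seed in 1:3) {
    fc <- synthetic_fold_changes(ref$model,
      pathway_effects = c(oxphos = -0.6, glycolysis = -0.3, ppp = 0.7),
      noise_sd = 0.15, seed = seed)
    fit <- lsei_fba(ref$model, ref$fit, fc)
    ## reference is feasible, so its sum of squares bounds the optimum
    ref_ss <- sum((fit$report$reference * fit$report$fold_change -
                   fit$report$reference)^2)
    expect_lte(fit$residual_ss, ref_ss + 1e-10)
    ## predictions satisfy steady state and irreversibility
    E <- stoichiometric_matrix(ref$model)
    expect_lt(max(abs(E %*% fit$values)), 1e-8)
    irrev <- names(Filter(function(r) !r$reversible, ref$model$reactions))
    expect_gte(min(fit$values[irrev]), -1e-9)
  }
})

test_that("down-regulating oxidative phosphorylation lowers ATP synthase flux", {
  ref <- brain_reference_fit()
  fc <- synthetic_fold_changes(ref$model,
    pathway_effects = c(oxphos = -0.9, tca = -0.75), noise_sd = 0, seed = 1)
  fit <- lsei_fba(ref$model, ref$fit, fc)
  expect_lt(fit$values[["R_ATPS4m"]], ref$fit$values[["R_ATPS4m"]])
})

test_that("Lsei-FBA output scales with the reference scale", {
  m <- branched_model()
  ref <- c(R_in = 1, R_1 = 0.5, R_2 = 0.5, R_out = 1)
  fc <- fold_change_table(c(g0 = 1.2, g1 = 0.5, g2 = 1.4, g3 = 0.9))
  f1 <- lsei_fba(m, ref, fc)
  f2 <- lsei_fba(m, 10 * ref, fc)
  expect_equal(10 * f1$values, f2$values, tolerance = 1e-8)
})

test_that("fold-change CSV files round-trip including the log2 header flag", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# scale: log2", "gene_id,fold_change", "g1,1", "g2,-2"), path)
  fc <- read_fold_changes(path)
  expect_equal(unclass(fc), c(g1 = 2, g2 = 0.25))
})
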