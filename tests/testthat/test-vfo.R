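test_that("day folding averages the two days and interpolates through them", {
  pr <- generate_harmonic_profile(tissue_presets()$liver, seed = 1, noise = 0)
  cy <- fold_average_days(pr)
  # noiseless harmonic data: both days identical, fold returns day 1
  expect_equal(unname(cy$values), unname(pr$values[, 1:12]), tolerance = 1e-9)
  for (gi in seq_len(5))
    expect_equal(cy$interp[[gi]](cy$times), unname(cy$values[gi, ]),
                 tolerance = 1e-9)
  # pointwise average of two different days
  pr2 <- pr
  pr2$values[, 1:12] <- 0.8
  pr2$values[, 13:24] <- 1.2
  cy2 <- fold_average_days(pr2)
  expect_true(all(abs(cy2$values - 1) < 1e-12))
  bad <- pr; bad$times <- seq(0, 69, by = 3)
  expect_error(fold_average_days(bad), "2-h spacing|expects 24")
})

test_that("periodic central differences match the cosine derivative", {
  times <- seq(0, 46, by = 2)
  genes <- clock_genes()
  A <- 0.5
  vals <- matrix(rep(1 + A * cos(2 * pi * times / 24), each = 5), 5,
                 dimnames = list(genes, times), byrow = FALSE)
  for (g in genes) vals[g, ] <- 1 + A * cos(2 * pi * times / 24)
  pr <- normalize_profile(vals, times)
  cy <- fold_average_days(pr)
  dv <- estimate_derivatives(cy)
  truth <- -(2 * pi * A / 24) * sin(2 * pi * cy$times / 24)
  # central differences at 2-h spacing attenuate the fundamental by
  # sin(wh)/(wh) = 0.955, so agreement is to ~5%
  expect_equal(unname(dv[1, ]), truth, tolerance = 0.05)
  expect_lt(abs(sum(dv[1, ])), 1e-10)
  # constant gene: zero derivative
  vals["Dbp", ] <- 2
  dv2 <- estimate_derivatives(fold_average_days(normalize_profile(vals, times)))
  expect_true(all(dv2["Dbp", ] == 0))
})

test_that("gradient-matching residual is zero when derivatives come from the model itself", {
  pr <- generate_model_profile(rep_fixture()$params, noise = 0)
  cy <- fold_average_days(pr)
  p <- rep_fixture()$params
  topo <- default_topology()
  sp <- clockloops:::split_params(p, topo)
  genes <- topo$genes
  rhs <- matrix(0, 5, 12, dimnames = list(genes, NULL))
  for (gi in seq_len(5)) {
    prod <- rep(1, 12)
    for (i in which(topo$edges$target == genes[gi])) {
      si <- match(topo$edges$source[i], genes)
      y <- pmax(cy$interp[[si]](cy$times - sp$tau[si]), 0)
      prod <- prod * if (topo$edges$mode[i] == "activation")
        activation_factor(y, sp$a[i], sp$K[i], topo$edges$n[i])
      else inhibition_factor(y, sp$r[i], topo$edges$n[i])
    }
    rhs[gi, ] <- prod - sp$d[gi] * cy$values[genes[gi], ]
  }
  expect_equal(vfo_objective(p, cy, rhs, topo), 0, tolerance = 1e-20)
})

test_that("analytic gradient matches finite differences", {
  pr <- generate_model_profile(rep_fixture()$params, seed = 2, noise = 0.1)
  cy <- fold_average_days(pr)
  dv <- estimate_derivatives(cy)
  b <- parameter_bounds()
  set.seed(3)
  for (k in 1:3) {
    p <- runif(34, b$lower, b$upper)
    ga <- vfo_gradient(p, cy, dv)
    gn <- vapply(seq_along(p), function(i) {
      h <- 1e-5 * max(abs(p[i]), 1)
      pp <- p; pp[i] <- p[i] + h
      pm <- p; pm[i] <- p[i] - h
      (vfo_objective(pp, cy, dv) - vfo_objective(pm, cy, dv)) / (2 * h)
    }, numeric(1))
    expect_equal(ga, gn, tolerance = 1e-4)
  }
})

test_that("true parameters beat nearly all random draws on the folded objective", {
  p <- rep_fixture()$params
  pr <- generate_model_profile(p, noise = 0)
  cy <- fold_average_days(pr)
  dv <- estimate_derivatives(cy)
  truth <- vfo_objective(p, cy, dv)
  b <- parameter_bounds()
  set.seed(101)
  draws <- vapply(1:200, function(i)
    vfo_objective(runif(34, b$lower, b$upper), cy, dv), numeric(1))
  expect_gte(mean(draws > truth), 0.95)
})

test_that("antiphase Bmal1/RevErbA data drive the Bmal1 delay into the upper half of [0, 6]", {
  # Bmal1 peaks at 0, RevErbA at 12 h: the activation Bmal1 -> RevErbA needs
  # a delay near half a cycle, capped at 6 h
  preset <- list(name = "antiphase",
                 phase = stats::setNames(c(0, 11, 13, 16, 12), clock_genes()),
                 fold_change = stats::setNames(c(4, 6, 5, 3, 10),
                                               clock_genes()),
                 noise = 0)
  pr <- generate_harmonic_profile(preset, seed = 1, noise = 0)
  v <- run_vfo(pr, n_starts = 10, seed = 4)
  expect_gt(unname(unclass(v$params)["tau_Bmal1"]), 3)
})

test_that("vector field optimization respects bounds, improves its starts and never integrates", {
  pr <- generate_model_profile(br_fixture()$params, seed = 5, noise = 0.1)
  simulation_count(reset = TRUE)
  v <- run_vfo(pr, n_starts = 6, seed = 9)
  expect_equal(simulation_count(), 0L)
  b <- parameter_bounds()
  expect_true(all(as.numeric(v$params) >= b$lower - 1e-12))
  expect_true(all(as.numeric(v$params) <= b$upper + 1e-12))
  expect_lte(v$residual, min(v$start_residuals))
  # seeded runs are reproducible
  v2 <- run_vfo(pr, n_starts = 6, seed = 9)
  expect_identical(as.numeric(v$params), as.numeric(v2$params))
})
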