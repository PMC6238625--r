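make_stub_ensemble <- function() {
  fams <- c("Per2_loop", "Cry1_loop", "Bmal1_RevErbA", "Repressilator")
  fits <- list(); reports <- list()
  set.seed(21)
  k <- 0
  for (ts in c("liver", "SCN")) {
    for (i in 1:6) {
      k <- k + 1
      ess <- sample(fams, sample(0:3, 1))
      fits[[k]] <- stub_fit(runif(1, 0, 15), ts,
                            params = clock_params(runif(34, 0.5, 2)))
      reports[[k]] <- stub_report(ess, if (length(ess)) list(ess)
                                       else list())
    }
  }
  clock_ensemble(fits, reports)
}

test_that("loop frequencies match brute-force counting and stay in [0, 1]", {
  ens <- make_stub_ensemble()
  tab <- loop_frequency_table(ens, threshold = 10)
  expect_true(all(tab >= 0 & tab <= 1, na.rm = TRUE))
  # counting oracle for one cell
  keep <- ens$scores < 10 & ens$tissues == "liver"
  oracle <- mean(vapply(which(keep), function(i)
    "Repressilator" %in% ens$reports[[i]]$essential_families, logical(1)))
  expect_equal(unname(tab["Repressilator", "liver"]), oracle)
})

test_that("oscillator composition counts partition the fit set", {
  ens <- make_stub_ensemble()
  v <- oscillator_venn(ens, "SCN")
  expect_equal(sum(v), sum(ens$tissues == "SCN"))
  # all-identical reports collapse to a single cell
  fits <- lapply(1:4, function(i) stub_fit(1, "x"))
  reports <- lapply(1:4, function(i)
    stub_report("Repressilator", list("Repressilator")))
  v2 <- oscillator_venn(clock_ensemble(fits, reports))
  expect_equal(unname(v2), 4L)
  expect_equal(names(v2), "Repressilator")
})

test_that("principal-component projection matches a singular-value oracle", {
  ens <- make_stub_ensemble()
  pj <- pca_project(ens)
  expect_equal(dim(pj$loadings), c(34, 2))
  expect_equal(unname(colMeans(pj$coordinates)), c(0, 0), tolerance = 1e-10)
  X <- clockloops:::ensemble_param_matrix(ens)
  sv <- svd(X)
  expect_equal(abs(pj$coordinates[, 1]),
               abs(sv$u[, 1] * sv$d[1]), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(pj$explained[1], sv$d[1]^2 / sum(sv$d^2), tolerance = 1e-8)
  # near-collinear data: first component owns almost all variance
  base <- clock_params(seq(0.5, 2, length.out = 34))
  fits <- lapply(1:6, function(i)
    stub_fit(1, "t", params = clock_params(as.numeric(base) * (1 + 0.1 * i) +
                                             rnorm(34, 0, 1e-7))))
  reports <- lapply(1:6, function(i) stub_report(character(0), list()))
  pj2 <- pca_project(clock_ensemble(fits, reports))
  expect_gt(pj2$explained[1], 0.999)
})

test_that("discriminant projection separates constructed tissue clusters", {
  set.seed(5)
  mk <- function(center, ts, n = 8) lapply(1:n, function(i)
    stub_fit(1, ts, params = clock_params(center + rnorm(34, 0, 0.05))))
  fits <- c(mk(rep(1, 34), "liver"), mk(rep(1.6, 34), "SCN"))
  reports <- lapply(fits, function(f) stub_report(character(0), list()))
  ens <- clock_ensemble(fits, reports)
  pj <- lda_project(ens)
  d1 <- pj$coordinates[, 1]
  m_liver <- mean(d1[ens$tissues == "liver"])
  m_scn <- mean(d1[ens$tissues == "SCN"])
  spread <- max(tapply(d1, ens$tissues, stats::sd))
  expect_gt(abs(m_liver - m_scn), 3 * spread)
  expect_length(pj$top4, 4)
  # permuting fit order leaves the axis invariant up to sign
  ord <- sample(seq_along(fits))
  ens2 <- clock_ensemble(fits[ord], reports[ord])
  pj2 <- lda_project(ens2)
  back <- pj2$coordinates[match(seq_along(fits), ord), 1]
  expect_gt(abs(stats::cor(pj$coordinates[, 1], back)), 0.999)
})

test_that("discriminant directions solve the scatter generalized eigenproblem", {
  set.seed(6)
  mk <- function(center, ts, n = 10) lapply(1:n, function(i)
    stub_fit(1, ts, params = clock_params(center + rnorm(34, 0, 0.2))))
  shift <- c(rep(2, 10), rep(0, 24))
  fits <- c(mk(rep(1, 34), "a"), mk(rep(1, 34) + shift, "b"),
            mk(rep(1, 34) - shift, "c"))
  reports <- lapply(fits, function(f) stub_report(character(0), list()))
  ens <- clock_ensemble(fits, reports)
  pj <- lda_project(ens, ridge = 1e-8)
  X <- clockloops:::ensemble_param_matrix(ens)
  # oracle: explicit scatter matrices and eigen decomposition
  mu <- colMeans(X); Sw <- matrix(0, 34, 34); Sb <- matrix(0, 34, 34)
  for (ts in unique(ens$tissues)) {
    Xi <- X[ens$tissues == ts, ]
    mi <- colMeans(Xi)
    Sw <- Sw + crossprod(sweep(Xi, 2, mi))
    Sb <- Sb + nrow(Xi) * tcrossprod(mi - mu)
  }
  eg <- eigen(solve(Sw + 1e-8 * diag(34), Sb))
  w1 <- Re(eg$vectors[, 1]); w1 <- w1 / sqrt(sum(w1^2))
  expect_gt(abs(sum(w1 * pj$loadings[, 1])), 0.9999)
})

test_that("rank-sum test is exact for small samples and rank-based", {
  rs <- ranksum(c(1, 2), c(3, 4))
  expect_equal(rs$p_value, 1 / 3)
  expect_equal(rs$method, "exact")
  expect_gt(ranksum(c(1, 2, 3), c(1, 2, 3))$p_value, 0.99)
  # invariance under common monotone transforms
  set.seed(31)
  x <- rnorm(7); y <- rnorm(9, 1)
  expect_equal(ranksum(x, y)$p_value, ranksum(exp(x), exp(y))$p_value)
  # large-sample normal approximation tracks the reference implementation
  x2 <- rnorm(30); y2 <- rnorm(30, 0.7)
  ours <- ranksum(x2, y2)
  ref <- stats::wilcox.test(x2, y2, exact = FALSE, correct = FALSE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-8)
})

test_that("circular mean handles wraparound and degenerate antipodes", {
  expect_equal(circular_mean(c(23, 1), 24), 0)
  expect_equal(circular_mean(c(6, 6, 6), 24), 6)
  cm <- circular_mean(c(0, 12), 24)
  expect_true(is.na(cm))
  expect_true(attr(cm, "degenerate"))
})

test_that("repressor phases invert by half a cycle and activators stay put", {
  ph <- c(a = 8, r = 20)
  roles <- c("activator", "repressor")
  out <- invert_repressor_phases(ph, roles)
  expect_equal(unname(out), c(8, 8))
  # double application is the identity
  expect_equal(invert_repressor_phases(out, roles), ph,
               ignore_attr = TRUE)
})

test_that("score/loop-count association detects a constructed signal", {
  fams <- c("Per2_loop", "Cry1_loop", "Bmal1_RevErbA", "Repressilator")
  # low-score fits carry strictly more essential loops
  fits <- c(lapply(1:10, function(i) stub_fit(1 + i / 100, "t")),
            lapply(1:10, function(i) stub_fit(20 + i, "t")))
  reports <- c(lapply(1:10, function(i) stub_report(fams[1:3])),
               lapply(1:10, function(i) stub_report(fams[1])))
  ens <- clock_ensemble(fits, reports)
  assoc <- score_loop_association(ens, family = "Cry1_loop",
                                  alternative = "less")
  expect_lt(assoc$ranksum$p_value, 0.05)
  expect_equal(assoc$mean_loops_low, 3)
  expect_equal(assoc$mean_loops_high, 1)
  # with/without-family mean scores match a direct computation
  has <- vapply(reports, function(r)
    "Cry1_loop" %in% r$essential_families, logical(1))
  expect_equal(assoc$mean_score_with, mean(ens$scores[has]))
  expect_equal(assoc$mean_score_without, mean(ens$scores[!has]))
  # identical ensembles show no association
  same <- clock_ensemble(lapply(1:6, function(i) stub_fit(2, "t")),
                         lapply(1:6, function(i) stub_report(fams[1:2])))
  expect_gt(score_loop_association(same)$ranksum$p_value, 0.99)
})
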