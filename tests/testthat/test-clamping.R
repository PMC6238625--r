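test_that("cycle enumeration finds the repressilator and signs cycles by parity", {
  topo <- default_topology()
  loops <- enumerate_loops(topo)
  desc <- vapply(loops, function(l) paste(sort(l$genes), collapse = "+"),
                 character(1))
  # the serial-inhibition triangle Per2 -| RevErbA -| Cry1 -| Per2
  rep_i <- which(vapply(loops, function(l)
    l$length == 3 && setequal(l$genes, c("Per2", "RevErbA", "Cry1")) &&
      all(topo$edges$mode[l$edges] == "inhibition"), logical(1)))
  expect_length(rep_i, 1)
  expect_equal(loops[[rep_i]]$sign, "negative")
  # Bmal1 -> RevErbA -| Bmal1: one inhibition, negative 2-cycle
  br_i <- which(vapply(loops, function(l)
    l$length == 2 && setequal(l$genes, c("Bmal1", "RevErbA")), logical(1)))
  expect_length(br_i, 1)
  expect_equal(loops[[br_i]]$sign, "negative")
  # RevErbA -| Cry1 -| RevErbA: two inhibitions, positive 2-cycle
  rc_i <- which(vapply(loops, function(l)
    l$length == 2 && setequal(l$genes, c("Cry1", "RevErbA")), logical(1)))
  expect_length(rc_i, 1)
  expect_equal(loops[[rc_i]]$sign, "positive")
})

test_that("cycle count matches a brute-force path enumeration oracle", {
  topo <- default_topology()
  genes <- topo$genes
  adj <- matrix(FALSE, 5, 5, dimnames = list(genes, genes))
  for (i in seq_len(nrow(topo$edges)))
    adj[topo$edges$source[i], topo$edges$target[i]] <- TRUE
  # brute force: for every k, count ordered k-tuples of distinct genes that
  # form a closed walk, then divide by k (each cycle appears once per
  # rotation of its starting point)
  oracle2 <- 0
  for (k in 1:5) {
    cnt <- 0
    idx <- utils::combn(5, k, simplify = FALSE)
    for (set in idx) {
      perms <- if (k == 1) list(set) else {
        p <- list()
        gen <- function(pre, rest) {
          if (!length(rest)) p[[length(p) + 1]] <<- pre
          else for (i in seq_along(rest)) gen(c(pre, rest[i]), rest[-i])
        }
        gen(integer(0), set)
        p
      }
      for (pm in perms)
        if (all(vapply(seq_len(k), function(i)
          adj[pm[i], pm[i %% k + 1]], logical(1)))) cnt <- cnt + 1
    }
    oracle2 <- oracle2 + cnt / k
  }
  expect_equal(length(enumerate_loops(topo)), oracle2)
})

test_that("core catalog has four all-negative families with Dbp extensions", {
  cat4 <- core_loop_catalog()
  expect_setequal(names(cat4), c("Per2_loop", "Cry1_loop", "Bmal1_RevErbA",
                                 "Repressilator"))
  expect_length(cat4$Per2_loop, 2)   # direct auto-inhibition + Dbp detour
  expect_length(cat4$Cry1_loop, 2)
  expect_length(cat4$Bmal1_RevErbA, 1)
  expect_length(cat4$Repressilator, 1)
  for (fam in cat4) for (l in fam) expect_equal(l$sign, "negative")
})

test_that("edge-clamp constants equal an independent quadrature of the factor", {
  fx <- rep_fixture()
  traj <- rep_traj()
  const <- clamp_constants(traj, fx$params)
  topo <- default_topology()
  # oracle: integrate the factor over the final period with a spline
  keep <- traj$times >= max(traj$times) - const$period
  for (i in c(4, 9, 17)) {
    series <- clockloops:::edge_factor_series(traj, i, fx$params, topo)
    f <- stats::splinefun(traj$times[keep], series[keep])
    o <- stats::integrate(f, min(traj$times[keep]), max(traj$times[keep]),
                          subdivisions = 500L)$value / const$period
    # the period estimate itself is only accurate to ~0.01 h, which caps
    # the achievable agreement between the two averages
    expect_equal(const$edge_means[i], o, tolerance = 5e-3)
  }
})

test_that("clamping all regulations abolishes rhythms by fixed-point collapse", {
  fx <- rep_fixture()
  traj <- rep_traj()
  const <- clamp_constants(traj, fx$params)
  topo <- default_topology()
  tr <- clamp_simulate(fx$params, topo, const, edges = 1:17,
                       duration = 300, step = 0.05)
  expect_false(is_rhythmic(tr, transient = 200))
  # converges to the product-over-incoming / degradation fixed point
  d <- as.numeric(fx$params)[25:29]
  expected <- vapply(seq_len(5), function(g)
    prod(const$edge_means[topo$edges$target == topo$genes[g]]) / d[g],
    numeric(1))
  expect_equal(unname(tr$values[nrow(tr$values), ]), expected,
               tolerance = 1e-4)
})

test_that("loop dissection recovers each fixture's built-in mechanism", {
  cases <- list(
    list(fx = rep_fixture(), fam = "Repressilator"),
    list(fx = br_fixture(), fam = "Bmal1_RevErbA"),
    list(fx = per2_fixture(), fam = "Per2_loop"),
    list(fx = cry1_fixture(), fam = "Cry1_loop"))
  for (cs in cases) {
    rep <- loop_report(cs$fx$params)
    expect_equal(rep$essential_families, cs$fam)
    expect_length(rep$minimal_oscillators, 1)
    expect_equal(rep$minimal_oscillators[[1]], cs$fam)
    # bookkeeping: an essential loop's every edge clamp kills rhythms
    cat4 <- core_loop_catalog()
    for (l in cat4[[cs$fam]])
      if (all(!rep$edge_rhythmic[l$edges]))
        expect_true(any(rep$essential_members[[cs$fam]]))
    # no loop with a rhythm-preserving edge clamp is reported
    for (fam in names(cat4)) {
      for (k in seq_along(cat4[[fam]])) {
        l <- cat4[[fam]][[k]]
        if (any(rep$edge_rhythmic[l$edges]))
          expect_false(rep$essential_members[[fam]][k])
      }
    }
  }
})

test_that("targeted single-edge clamps behave as designed in the fixtures", {
  # repressilator: clamping RevErbA -| Cry1 abolishes rhythms
  fxr <- rep_fixture()
  topo <- default_topology()
  e_rc <- which(topo$edges$source == "RevErbA" & topo$edges$target == "Cry1")
  const <- clamp_constants(rep_traj(), fxr$params)
  trc <- clamp_simulate(fxr$params, topo, const, edges = e_rc,
                        duration = 600, step = 0.05)
  expect_false(is_rhythmic(trc))
  # Bmal1/RevErbA fixture: clamping RevErbA -| Bmal1 kills rhythms,
  # clamping Cry1 -| Cry1 does not
  fxb <- br_fixture()
  trb <- simulate_clock(fxb$params)
  constb <- clamp_constants(trb, fxb$params)
  e_rb <- which(topo$edges$source == "RevErbA" & topo$edges$target == "Bmal1")
  e_cc <- which(topo$edges$source == "Cry1" & topo$edges$target == "Cry1")
  expect_false(is_rhythmic(clamp_simulate(fxb$params, topo, constb,
                                          edges = e_rb, duration = 600,
                                          step = 0.05)))
  expect_true(is_rhythmic(clamp_simulate(fxb$params, topo, constb,
                                         edges = e_cc, duration = 600,
                                         step = 0.05)))
})

test_that("synergy classification separates dependent from independent loop pairs", {
  dep <- synergy_fixture("dependent")
  rdep <- loop_report(dep$params)
  expect_length(rdep$minimal_oscillators, 1)
  expect_setequal(rdep$minimal_oscillators[[1]], dep$expected$oscillator)
  expect_equal(unname(rdep$synergy[1]), "dependent")
  ind <- synergy_fixture("independent")
  rind <- loop_report(ind$params)
  singles <- vapply(rind$minimal_oscillators, length, integer(1))
  expect_true(all(singles == 1))
  expect_equal(classify_synergy(rind, ind$expected$oscillator),
               "independent")
  expect_error(classify_synergy(rind, "Per2_loop"), "single")
})

test_that("gene clamping freezes the gene and is re-verifiable", {
  fx <- rep_fixture()
  topo <- default_topology()
  traj <- rep_traj()
  const <- clamp_constants(traj, fx$params)
  tr <- clamp_simulate(fx$params, topo, const, genes = "Per2",
                       duration = 200, step = 0.05)
  expect_true(all(abs(tr$values[, "Per2"] - const$gene_means["Per2"]) < 1e-12))
  rep <- loop_report(fx$params, duration = tb$duration, step = tb$step,
                     transient = tb$transient, criterion = tb_criterion)
  expect_true(verify_loop_report(rep, fx$params))
  # determinism: identical inputs give identical reports
  rep2 <- loop_report(fx$params, duration = tb$duration, step = tb$step,
                      transient = tb$transient, criterion = tb_criterion)
  expect_identical(rep$edge_rhythmic, rep2$edge_rhythmic)
  expect_identical(rep$minimal_oscillators, rep2$minimal_oscillators)
})
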