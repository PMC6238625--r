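# Shared fixtures, computed once per test run.

.cache <- new.env(parent = emptyenv())

cached <- function(name, fn) {
  if (!exists(name, envir = .cache)) assign(name, fn(), envir = .cache)
  get(name, envir = .cache)
}

# reduced-span simulation controls used by the heavier tests
tb <- list(duration = 360, step = 0.1, transient = 240)
tb_criterion <- list(transient = 240, epsilon = 0.01, decay_min = 0.95)

rep_fixture <- function() cached("rep_fix", function()
  ground_truth_fixture("Repressilator", verify = FALSE))
br_fixture <- function() cached("br_fix", function()
  ground_truth_fixture("Bmal1_RevErbA", verify = FALSE))
per2_fixture <- function() cached("per2_fix", function()
  ground_truth_fixture("Per2_loop", verify = FALSE))
cry1_fixture <- function() cached("cry1_fix", function()
  ground_truth_fixture("Cry1_loop", verify = FALSE))

rep_traj <- function() cached("rep_traj", function()
  simulate_clock(rep_fixture()$params))

# a synthetic trajectory with pure cosine gene curves
make_cosine_traj <- function(phases, amps, period = 24, mean_level = 1,
                             duration = 200, step = 0.05) {
  genes <- clock_genes()
  times <- seq(0, duration, by = step)
  values <- vapply(seq_along(genes), function(i)
    mean_level * (1 + amps[i] * cos(2 * pi * (times - phases[i]) / period)),
    numeric(length(times)))
  colnames(values) <- genes
  structure(list(times = times, values = values, derivs = NULL,
                 step = step, genes = genes), class = "clock_trajectory")
}

# minimal hand-built fit/report pair for ensemble bookkeeping tests
stub_fit <- function(score, tissue, params = NULL, seed = 1) {
  if (is.null(params)) params <- clock_params(rep(1, 34) + seq_len(34) / 100)
  structure(list(params = params,
                 score = structure(list(total = score,
                                        breakdown = c(total = score),
                                        nonrhythmic = FALSE),
                                   class = "clock_score"),
                 trace = score, tissue = tissue, seed = seed,
                 vfo_used = FALSE), class = "clock_fit")
}

stub_report <- function(essential, oscillators = list(essential)) {
  structure(list(essential_families = essential,
                 minimal_oscillators = oscillators,
                 sufficient_sets = oscillators,
                 synergy = rep(NA_character_, length(oscillators))),
            class = "clock_loop_report")
}
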