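test_that("every generator is deterministic in its config", {
  cfg <- sim_config(123)
  a <- gen_sted_field(cfg, 4, punctum_offsets = c(-60, 0, 60, 120))
  b <- gen_sted_field(cfg, 4, punctum_offsets = c(-60, 0, 60, 120))
  expect_identical(a$field$reference, b$field$reference)
  expect_identical(a$field$query, b$field$query)
  expect_identical(a$truth, b$truth)

  expect_identical(gen_phluorin_traces(cfg, 3)$traces,
                   gen_phluorin_traces(cfg, 3)$traces)

  counts <- data.frame(condition = "wt", time = "100ms", n_profiles = 2,
                       pits = 1, svs = 1, levs = 1, endosomes = 0)
  expect_identical(gen_em_profiles(cfg, counts)$profiles,
                   gen_em_profiles(cfg, counts)$profiles)

  expect_identical(gen_titration_series(cfg, 1:10, c(3, 4))$tables,
                   gen_titration_series(cfg, 1:10, c(3, 4))$tables)
  expect_identical(gen_binding_curve(cfg, 44, 2, noise_sd = 0.05)$curve,
                   gen_binding_curve(cfg, 44, 2, noise_sd = 0.05)$curve)
  expect_identical(gen_srm_table(cfg, c(A = 10))$transitions,
                   gen_srm_table(cfg, c(A = 10))$transitions)
})

test_that("generators leave the session RNG stream untouched", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(gen_phluorin_traces(sim_config(5), 2))
  expect_identical(runif(1), before)
})

test_that("sted field photon expectation matches the object-model integral", {
  sim <- gen_sted_field(sim_config(1), n_synapses = 1, punctum_offsets = 0,
                        photon_budget = Inf, background = 0, tile = 61)
  # nominal zero-noise budget is 1e6 photons per object
  expect_equal(sum(sim$field$reference), 1e6, tolerance = 1e-3)
  expect_equal(sum(sim$field$query), 1e6, tolerance = 1e-3)
})

test_that("sted generator rejects puncta placed outside the field", {
  expect_error(
    gen_sted_field(sim_config(1), 1, punctum_offsets = -1000),
    "synapse 1"
  )
  expect_error(
    gen_sted_field(sim_config(1), 1, punctum_offsets = 5000, tile = 31),
    "synapse 1"
  )
})

test_that("noiseless pHluorin traces equal the stated model exactly", {
  sim <- gen_phluorin_traces(sim_config(2), 1, tau = 15, plateau = 0.3,
                             bleach_K = 0, noise_sd = 0)
  tr <- sim$traces[[1]]
  t <- (seq_along(tr$values) - 1) / tr$frame_rate
  t_stim <- t[tr$stimulus_frame]
  model <- ifelse(t < t_stim, 1,
                  1 + (0.7 * exp(-(t - t_stim) / 15) + 0.3))
  expect_equal(tr$values, model)
  expect_error(gen_phluorin_traces(sim_config(1), 1, noise_sd = -1),
               "noise_sd")
})

test_that("titration series: non-site residues never shift without noise", {
  sim <- gen_titration_series(sim_config(3), residues = 1:20,
                              site_residues = c(4, 5), noise_sd = 0)
  first <- sim$tables[[1]]
  for (tab in sim$tables) {
    idx <- !(tab$residue %in% c(4, 5))
    expect_equal(tab$delta_H[idx], first$delta_H[idx])
    expect_equal(tab$delta_N[idx], first$delta_N[idx])
  }
  expect_error(gen_titration_series(sim_config(1), c(1, 1, 2), 1),
               "duplicate")
})

test_that("binding curve model identity and input validation", {
  sim <- gen_binding_curve(sim_config(1), kd = 50, bmax = 3,
                           concentrations = c(10, 50, 100, 400))
  at_kd <- sim$curve$signal[sim$curve$concentration == 50]
  expect_equal(at_kd, 1.5)
  expect_error(gen_binding_curve(sim_config(1), kd = -1, bmax = 1), "kd")
})

test_that("SRM split conserves each protein total exactly", {
  sim <- gen_srm_table(sim_config(4), c(A = 300, B = 30))
  sums <- tapply(sim$transitions$area, sim$transitions$protein, sum)
  expect_identical(as.numeric(sums[["A"]]), 300)
  expect_identical(as.numeric(sums[["B"]]), 30)
  expect_equal(length(unique(sim$transitions$peptide)), 6L)
})
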