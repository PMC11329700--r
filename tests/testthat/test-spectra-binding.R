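test_that("CSP formula: direct evaluation, nitrogen scaling, sign symmetry", {
  free <- data.frame(residue = 1:3, delta_H = c(8.0, 8.2, 7.9),
                     delta_N = c(120, 118, 125))
  bound <- free
  expect_equal(compute_csp(free, bound)$delta_delta, rep(0, 3))

  bound2 <- free; bound2$delta_N[1] <- 120.5
  expect_equal(compute_csp(free, bound2)$delta_delta[1], 0.1)

  bound3 <- free
  bound3$delta_H[2] <- free$delta_H[2] + 0.03
  bound3$delta_N[2] <- free$delta_N[2] + 0.25
  expect_equal(compute_csp(free, bound3)$delta_delta[2],
               sqrt(0.0009 + 0.0025), tolerance = 1e-9)
  expect_equal(sqrt(0.0009 + 0.0025), 0.05831, tolerance = 1e-4)

  # negating every shift difference leaves the CSP unchanged
  bound4 <- free
  bound4$delta_H <- free$delta_H - (bound3$delta_H - free$delta_H)
  bound4$delta_N <- free$delta_N - (bound3$delta_N - free$delta_N)
  expect_equal(compute_csp(free, bound4)$delta_delta,
               compute_csp(free, bound3)$delta_delta)
})

test_that("CSP reports unmatched and undetectable residues as missing", {
  free <- data.frame(residue = c(1, 2, 3), delta_H = 8, delta_N = 120,
                     detectable = c(TRUE, TRUE, FALSE))
  bound <- data.frame(residue = c(1, 2, 4), delta_H = 8.1, delta_N = 121)
  prof <- compute_csp(free, bound)
  expect_equal(prof$residue, c(1, 2))
  expect_equal(attr(prof, "missing"), c(3, 4))
  expect_error(compute_csp(free[c(1, 1), ], bound), "duplicate")
})

test_that("perturbed-residue calling uses the strict profile mean", {
  uniform <- data.frame(residue = 1:5, delta_delta = 0.05)
  expect_length(call_perturbed_residues(uniform), 0)

  prof <- data.frame(residue = 1:10,
                     delta_delta = c(rep(0.01, 9), 0.2))
  called <- call_perturbed_residues(prof)
  expect_equal(as.integer(called), 10L)
  expect_equal(attr(called, "threshold"), mean(prof$delta_delta))
})

test_that("site calling round-trips the titration generator", {
  sites <- c(5, 6, 12, 13, 17)
  sim <- gen_titration_series(sim_config(21), residues = 1:30,
                              site_residues = sites,
                              prolines = c(7, 20), noise_sd = 0)
  prof <- compute_csp(sim$tables[[1]], sim$tables[[length(sim$tables)]])
  expect_false(any(c(7, 20) %in% prof$residue))
  expect_equal(as.integer(call_perturbed_residues(prof)), sites)

  # 10:1 shift-to-noise: recall of planted sites stays >= 95%
  sites2 <- seq(5, 100, by = 5)
  recall <- vapply(1:10, function(s) {
    sim2 <- gen_titration_series(sim_config(s), residues = 1:100,
                                 site_residues = sites2,
                                 max_shifts = 0.2, noise_sd = 0.02)
    prof2 <- compute_csp(sim2$tables[[1]],
                         sim2$tables[[length(sim2$tables)]])
    called <- call_perturbed_residues(prof2)
    length(intersect(called, sites2)) / length(sites2)
  }, numeric(1))
  expect_gte(mean(recall), 0.95)
})

test_that("binding fit: model identity, scale equivariance, validation", {
  conc <- 2^(0:7) * 5
  curve <- data.frame(concentration = conc,
                      signal = 2 * conc / (44 + conc))
  fit <- fit_binding_curve(curve)
  expect_equal(fit$kd, 44, tolerance = 1e-6)
  expect_equal(fit$bmax, 2, tolerance = 1e-6)
  # at L = Kd the fitted model passes through Bmax / 2
  expect_equal(fit$bmax * 44 / (fit$kd + 44), fit$bmax / 2,
               tolerance = 1e-6)

  scaled <- curve; scaled$signal <- 100 * curve$signal
  fit2 <- fit_binding_curve(scaled)
  expect_equal(fit2$kd, fit$kd, tolerance = 1e-6)
  expect_equal(fit2$bmax, 100 * fit$bmax, tolerance = 1e-6)

  expect_error(fit_binding_curve(curve[1:3, ]), "4 distinct")
})

test_that("Kd recovery: exact when noiseless, within 10% under plate noise", {
  sim <- gen_binding_curve(sim_config(33), kd = 44, bmax = 2)
  expect_lt(abs(fit_binding_curve(sim$curve)$kd - 44) / 44, 0.001)

  errs <- vapply(1:40, function(s) {
    noisy <- gen_binding_curve(sim_config(s), kd = 44, bmax = 2,
                               noise_sd = 0.02 * 2, replicates = 4)
    abs(fit_binding_curve(noisy$curve)$kd - 44) / 44
  }, numeric(1))
  expect_lt(mean(errs), 0.10)
  expect_gte(mean(errs <= 0.10), 0.95)
})

test_that("SRM aggregation conserves areas and is order-invariant", {
  tab <- data.frame(
    protein = c("A", "A", "A", "B"),
    peptide = c("A_p1", "A_p1", "A_p2", "B_p1"),
    transition = c("y4", "y5", "y4", "y4"),
    area = c(100, 50, 150, 30)
  )
  res <- srm_protein_abundance(tab)
  expect_equal(res$grand_total, 330)
  expect_equal(res$proteins$total[res$proteins$protein == "A"], 300)
  expect_equal(res$proteins$ratio[res$proteins$protein == "B"], 0.1)

  perm <- tab[c(3, 1, 4, 2), ]
  res2 <- srm_protein_abundance(perm)
  expect_equal(res2$proteins, res$proteins)

  single <- srm_protein_abundance(tab[4, ])
  expect_equal(single$proteins$total, 30)

  tab$area[1] <- -1
  expect_error(srm_protein_abundance(tab), "negative")

  zero <- data.frame(protein = c("A", "B"), peptide = c("a", "b"),
                     transition = "y4", area = c(10, 0))
  expect_true(is.na(srm_protein_abundance(zero)$proteins$ratio[2]))
})

test_that("SRM generator round-trips planted fold ratios", {
  sim <- gen_srm_table(sim_config(3), c(A = 300, B = 30, C = 3))
  res <- srm_protein_abundance(sim$transitions)
  expect_equal(res$grand_total, 333)
  ratios <- setNames(res$proteins$ratio, res$proteins$protein)
  expect_equal(unname(ratios["A"] / ratios["B"]), 10, tolerance = 1e-12)
  expect_equal(unname(ratios["A"] / ratios["C"]), 100, tolerance = 1e-12)
})
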