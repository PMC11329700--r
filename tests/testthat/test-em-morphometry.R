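test_that("annotation JSON round-trips exactly and rejects bad vocabulary", {
  counts <- data.frame(condition = "wt", time = "100ms", n_profiles = 1,
                       pits = 2, svs = 1, levs = 1, endosomes = 1)
  sim <- gen_em_profiles(sim_config(7), counts)
  p <- sim$profiles[[1]]
  f <- withr::local_tempfile(fileext = ".json")
  write_annotation(p, f)
  back <- parse_annotation(f)
  expect_equal(back$scale, p$scale)
  ord <- function(d) d[order(d$feature, d$object, d$x, d$y), ]
  expect_equal(ord(back$features)$x, ord(p$features)$x, tolerance = 1e-9)
  expect_equal(ord(back$features)$y, ord(p$features)$y, tolerance = 1e-9)

  bad <- p$features
  bad$feature[1] <- "mitochondria"
  expect_error(profile_annotation("x", 1, bad), "mitochondria")
  expect_error(parse_annotation("{not json"), "malformed")
})

test_that("vesicle classification applies the 60-100 nm rule inclusively", {
  expect_equal(classify_vesicle(40), "synaptic_vesicle")
  expect_equal(classify_vesicle(80), "large_vesicle")
  expect_equal(classify_vesicle(c(60, 100)), rep("large_vesicle", 2))
  expect_equal(classify_vesicle(120, TRUE), "endosome")
  expect_equal(classify_vesicle(59.999), "synaptic_vesicle")
  expect_equal(classify_vesicle(100.001, TRUE), "endosome")
  expect_error(classify_vesicle(-5))
})

test_that("pit geometry: semicircle, exhaustive depth oracle, degenerate base", {
  theta <- seq(0, pi, length.out = 41)
  semi <- cbind(40 * cos(theta), 40 * sin(theta))
  g <- pit_geometry(semi)
  expect_equal(g$width, 80)
  expect_equal(g$depth, 40)

  # depth equals the brute-force maximum over point-to-chord distances
  set.seed(5)
  trace <- cbind(seq(-50, 50, length.out = 30),
                 runif(30, 0, 60))
  g2 <- pit_geometry(trace)
  a <- trace[1, ]; b <- trace[nrow(trace), ]
  chord_angle <- atan2(b[2] - a[2], b[1] - a[1])
  dists <- apply(trace, 1, function(p) {
    v <- p - a
    abs(-sin(chord_angle) * v[1] + cos(chord_angle) * v[2])
  })
  expect_equal(g2$depth, max(dists), tolerance = 1e-12)

  expect_error(pit_geometry(rbind(c(0, 0), c(1, 5), c(0, 0))),
               "coincident")
  expect_error(pit_geometry(rbind(c(0, 0), c(1, 1))), "3 points")
})

test_that("pit geometry is invariant under rigid motion", {
  counts <- data.frame(condition = "wt", time = "100ms", n_profiles = 1,
                       pits = 1, svs = 0, levs = 0, endosomes = 0)
  sim <- gen_em_profiles(sim_config(8), counts,
                         pit_shapes = list(c(80, 55)))
  tr <- subset(sim$profiles[[1]]$features, feature == "pits")
  xy <- cbind(tr$x, tr$y)
  g0 <- pit_geometry(xy)
  expect_equal(g0$width, 80, tolerance = 1e-9)
  expect_equal(g0$depth, 55, tolerance = 1e-9)
  for (ang in c(0.3, 1.7, 4.4)) {
    rot <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    moved <- sweep(xy %*% rot, 2, c(123.4, -56.7), "+")
    g <- pit_geometry(moved)
    expect_equal(g$width, g0$width, tolerance = 1e-9)
    expect_equal(g$depth, g0$depth, tolerance = 1e-9)
  }
})

test_that("structure counts round-trip the generator exactly", {
  counts <- data.frame(
    condition = c("wt", "wt"), time = c("no_stim", "100ms"),
    n_profiles = c(3, 3),
    pits = c(0, 2), svs = c(1, 2), levs = c(0, 1), endosomes = c(0, 1)
  )
  sim <- gen_em_profiles(sim_config(9), counts)
  got <- count_structures(sim$profiles)
  expect_equal(got$pits, sim$truth$counts$pits)
  expect_equal(got$svs_ferritin, sim$truth$counts$svs)
  expect_equal(got$levs_ferritin, sim$truth$counts$levs)
  expect_equal(got$endosomes_ferritin, sim$truth$counts$endosomes)
})

test_that("counts classify by measured diameter across rule boundaries", {
  mk <- function(d, feature) endoquant:::circle_feature(1L, feature, d,
                                                        ferritin = TRUE)
  p <- profile_annotation("t", 1, rbind(
    endoquant:::membrane_features(),
    mk(40, "synaptic_vesicles"),
    transform(mk(70, "large_vesicles"), object = 2L),
    transform(mk(130, "endosomes"), object = 3L)
  ))
  got <- count_structures(p)
  expect_equal(got$svs_ferritin, 1L)
  expect_equal(got$levs_ferritin, 1L)
  expect_equal(got$endosomes_ferritin, 1L)
  expect_equal(got$pits, 0L)
})

test_that("time-course summary: mean, SEM, increase, and edge conventions", {
  counts <- data.frame(
    profile_id = sprintf("p%d", 1:9),
    condition = "wt",
    time = c(rep("no_stim", 4), rep("100ms", 4), "1s"),
    pits = c(0, 1, 1, 2, 1, 2, 2, 3, 2),
    svs_ferritin = 0, levs_ferritin = 0, endosomes_ferritin = 0
  )
  s <- summarize_time_course(counts)
  base <- s[s$time == "no_stim" & s$class == "pits", ]
  expect_equal(base$mean, 1.0)
  expect_equal(base$sem, sd(c(0, 1, 1, 2)) / 2)
  stim <- s[s$time == "100ms" & s$class == "pits", ]
  expect_equal(stim$increase, 2.0 - 1.0)
  one <- s[s$time == "1s" & s$class == "pits", ]
  expect_true(is.na(one$sem))
  expect_equal(one$n, 1L)

  no_base <- counts[counts$time != "no_stim", ]
  expect_error(summarize_time_course(no_base), "no_stim")
})
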