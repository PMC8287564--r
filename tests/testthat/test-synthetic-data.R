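# Synthetic-data generators: determinism, planted margins, closed-form and
# round-trip ground truths.

test_that("generators are bit-reproducible under a fixed seed", {
  sp <- fluid_spec(20, 50, 5, "ideal", n_frames = 3, seed = 42)
  expect_identical(gen_ideal_gas(sp)$frames, gen_ideal_gas(sp)$frames)

  sp2 <- fluid_spec(10, 80, 5, "exponential_excess", amplitude = 0.4,
                    decay_length = 0.3, n_frames = 2, seed = 7)
  expect_identical(gen_structured_fluid(sp2)$frames,
                   gen_structured_fluid(sp2)$frames)

  expect_identical(gen_hbond_fixture(4, 4, seed = 5),
                   gen_hbond_fixture(4, 4, seed = 5))
  expect_identical(gen_inclusion_fixture(2, 3, 4, seed = 5),
                   gen_inclusion_fixture(2, 3, 4, seed = 5))
  expect_identical(gen_gamma_series(1, 2, 1:6, 0.5, seed = 9),
                   gen_gamma_series(1, 2, 1:6, 0.5, seed = 9))
  # and the session RNG is left untouched
  set.seed(123); before <- .Random.seed
  invisible(gen_ideal_gas(sp))
  expect_identical(.Random.seed, before)
})

test_that("fluid spec validation rejects unphysical inputs", {
  expect_error(fluid_spec(0, 10, 5), "n_centers")
  expect_error(fluid_spec(10, 10, -1), "box_edge")
  expect_error(fluid_spec(10, 10, 5, "exponential_excess",
                          amplitude = -1.2, decay_length = 0.3),
               "amplitude")
  expect_error(fluid_spec(10, 10, 5, "exponential_excess",
                          amplitude = 0.5, decay_length = 2),
               "minimum image")
  expect_error(gen_ideal_gas(fluid_spec(5, 5, 5, "exponential_excess",
                                        amplitude = 0.1,
                                        decay_length = 0.3)),
               "ideal")
})

test_that("ideal gas is uniform: long-range g near 1, corrected KBI near 0", {
  traj <- gen_ideal_gas(fluid_spec(100, 1000, 8, "ideal", n_frames = 5,
                                   seed = 1))
  rdf <- compute_rdf(traj, "I", "J", dr = 0.1, r_max = 3.9)
  expect_lt(abs(mean(rdf$g[rdf$r > 1]) - 1), 0.01)

  # single center, many partners, many frames: corrected KBI within 3 SE of 0
  tr <- gen_ideal_gas(fluid_spec(1, 2000, 10, "ideal", n_frames = 50,
                                 seed = 7))
  run <- block_running_kbis(tr, "I", "J", dr = 0.1, r_max = 4.5, blocks = 5)
  est <- estimate_kbi(run, c(2.5, 4.0), flatness_tol = Inf)
  expect_lt(abs(est$G), 3 * est$stderr)
})

test_that("structured fluid realises g = 1 + A exp(-r/lambda) binwise", {
  A <- 0.5; lam <- 0.3
  sp <- fluid_spec(100, 400, 8, "exponential_excess", amplitude = A,
                   decay_length = lam, n_frames = 20, seed = 3)
  traj <- gen_structured_fluid(sp)
  expect_equal(attr(traj, "G_analytic"), 8 * pi * A * lam^3)
  # per-block g curves give binwise standard errors
  nf <- length(traj$frames)
  gmat <- sapply(split(seq_len(nf), rep(1:5, each = nf / 5)), function(ix) {
    sub <- kb_trajectory(traj$frames[ix])
    compute_rdf(sub, "I", "J", dr = 0.1, r_max = 2.5)$g
  })
  r <- compute_rdf(traj, "I", "J", dr = 0.1, r_max = 2.5)$r
  gbar <- rowMeans(gmat)
  se <- apply(gmat, 1, sd) / sqrt(ncol(gmat))
  target <- 1 + A * exp(-r / lam)
  expect_true(all(abs(gbar - target) < 3.5 * se + 0.01))
})

test_that("closed-form KBI matches quadrature and carries the sign of A", {
  expect_equal(8 * pi * 0.5 * 0.3^3,
               oracle_kbi_quadrature(function(r) 1 + 0.5 * exp(-r / 0.3)),
               tolerance = 1e-8)
  expect_equal(8 * pi * 0.5 * 0.3^3, 0.339292, tolerance = 1e-6)
  sp <- fluid_spec(10, 100, 6, "exponential_excess", amplitude = -0.2,
                   decay_length = 0.2, n_frames = 1, seed = 1)
  expect_lt(attr(gen_structured_fluid(sp), "G_analytic"), 0)
})

test_that("amplitude zero degenerates to an ideal fluid", {
  sp <- fluid_spec(50, 300, 6, "exponential_excess", amplitude = 0,
                   decay_length = 0.3, n_frames = 10, seed = 13)
  traj <- gen_structured_fluid(sp)
  expect_equal(attr(traj, "G_analytic"), 0)
  rdf <- compute_rdf(traj, "I", "J", dr = 0.15, r_max = 2.9)
  expect_lt(abs(mean(rdf$g) - 1), 0.02)
})

test_that("planted hydrogen-bond fixtures respect boundary margins", {
  for (seed in 1:5) {
    fx <- gen_hbond_fixture(6, 9, seed = seed)
    expect_identical(detect_hbonds(fx), 6L)
    # margin safety: every donor-acceptor distance is >= 5 pm away from the
    # cutoff and every true angle >= 2 degrees inside it
    pos <- fx$config$positions
    d <- sqrt(rowSums((pos[fx$donors, , drop = FALSE] -
                       pos[fx$acceptors, , drop = FALSE])^2))
    expect_true(all(abs(d - 0.35) >= 0.005 - 1e-12))
  }
  expect_identical(detect_hbonds(gen_hbond_fixture(0, 10, seed = 3)), 0L)
})

test_that("planted inclusion fixtures respect the 0.5 nm margin", {
  for (seed in 1:4) {
    fx <- gen_inclusion_fixture(3, 7, 6, seed = seed)
    res <- inclusion_fraction(fx)
    expect_equal(res$per_frame_counts, 3L)
    expect_equal(res$percent_cds_including, 3 / 6 * 100)
    cd <- fx$traj$frames[[1]]$positions[unlist(fx$cd_groups), , drop = FALSE]
    gu <- fx$traj$frames[[1]]$positions[unlist(fx$guest_groups), ,
                                        drop = FALSE]
    d <- kbsolv:::pair_distances(cd, gu, fx$traj$frames[[1]]$box)
    expect_true(all(abs(d - 0.5) >= 0.02 - 1e-12))
  }
  expect_equal(inclusion_fraction(
    gen_inclusion_fixture(0, 0, 5, seed = 1))$percent_cds_including, 0)
  expect_error(gen_inclusion_fixture(6, 0, 5, seed = 1), "n_cds")
})

test_that("gamma series generator produces the planted line", {
  s <- gen_gamma_series(0, 1.20, 1:6, noise_sd = 0, seed = 1)
  expect_equal(s$gamma, 1.20 * (1:6))
  expect_equal(diff(s$gamma), rep(1.20, 5))
  expect_error(gen_gamma_series(0, 1, c(3, 2, 1)), "increasing")
  expect_error(gen_gamma_series(0, 1, 1:3, noise_sd = -1), "noise_sd")
})

test_that("forward thermo generation round-trips through the inversion", {
  grid <- seq(0.0008, 0.004, length.out = 12)
  ds <- gen_binary_thermo_dataset(test_kbi_profile, grid)
  tru <- attr(ds, "kbi_true")
  inv <- invert_thermo_to_kbi(ds)
  rel <- abs(as.matrix(inv[, c("G11", "G13", "G33")]) -
             as.matrix(tru[, c("G11", "G13", "G33")])) /
         abs(as.matrix(tru[, c("G11", "G13", "G33")]))
  expect_lt(max(rel), 1e-6)

  # betaT-closure mode: G11 derived from the supplied compressibility
  prof <- function(x3) c(NA, -600 - 500 * x3, -3000 + 4000 * x3)
  ds2 <- gen_binary_thermo_dataset(prof, grid)
  expect_true(all(ds2$betaT == 4.52e-10))
  tru2 <- attr(ds2, "kbi_true")
  inv2 <- invert_thermo_to_kbi(ds2)
  rel2 <- abs(as.matrix(inv2[, 2:4]) - as.matrix(tru2[, 2:4])) /
          abs(as.matrix(tru2[, 2:4]))
  expect_lt(max(rel2), 1e-6)
})

test_that("quasi-ideal profile yields an ideal dataset inverting to zeros", {
  ds <- gen_binary_thermo_dataset(function(x3) c(0, 0, 0),
                                  c(0.005, 0.01, 0.02, 0.04))
  expect_equal(ds$f3, rep(1, 4), tolerance = 1e-10)
  inv <- invert_thermo_to_kbi(ds)
  expect_lt(max(abs(as.matrix(inv[, 2:4]))), 1e-8)
  # density pinned by the water partial molar volume
  expect_equal(ds$rho[1], 1 / 18.07 * 1000, tolerance = 1e-6)
})

test_that("thermo generator rejects out-of-regime or degenerate inputs", {
  expect_error(gen_binary_thermo_dataset(function(x) c(0, 0, 0), c(0.1)),
               "dilute")
  expect_error(gen_binary_thermo_dataset(function(x) c(0, 0), c(0.01)),
               "G11")
  # a wildly negative G33 drives the compressibility intermediate negative
  expect_error(
    gen_binary_thermo_dataset(function(x) c(-16, -600, -3e5), c(0.01)),
    "x3 = 0.01")
})

test_that("thermo CSV round trip preserves the dataset", {
  ds <- gen_binary_thermo_dataset(test_kbi_profile,
                                  seq(0.001, 0.003, length.out = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_thermo_csv(ds, path)
  back <- read_thermo_csv(path)
  expect_equal(back$rho, ds$rho, tolerance = 1e-12)
  expect_equal(back$dmu3_dx3, ds$dmu3_dx3, tolerance = 1e-12)
})
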