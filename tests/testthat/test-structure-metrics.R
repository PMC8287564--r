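# Hydrogen-bond detection, chi percentage, cavity inclusion and
# orientation metrics.

test_that("hydrogen-bond detector matches the brute-force oracle", {
  for (seed in 1:4) {
    fx <- gen_hbond_fixture(5, 7, seed = seed)
    expect_identical(
      detect_hbonds(fx),
      as.integer(oracle_hbonds(fx$config, fx$donors, fx$hydrogens,
                               fx$acceptors)))
  }
  # random small configuration (not planted): counts must still agree
  set.seed(31)
  pos <- matrix(runif(45, 0, 1.5), 15, 3)
  cfg <- kb_config(pos, c(10, 10, 10))
  donors <- 1:5; hydrogens <- 6:10; acceptors <- 11:15
  expect_identical(
    detect_hbonds(cfg, donors, hydrogens, acceptors),
    as.integer(oracle_hbonds(cfg, donors, hydrogens, acceptors)))
})

test_that("hydrogen-bond cutoffs are strict inequalities", {
  # donor at origin, acceptor along x, hydrogen exactly on the D->A line
  mk <- function(d_da, angle_deg) {
    h <- 0.1 * c(cos(angle_deg * pi / 180), sin(angle_deg * pi / 180), 0)
    kb_config(rbind(c(0, 0, 0), h, c(d_da, 0, 0)), c(20, 20, 20),
              species = c("D", "H", "A"))
  }
  crit <- hbond_criterion()
  # at 0.34 nm / 10 degrees: bond; at exactly 0.35 nm: no bond
  expect_identical(detect_hbonds(mk(0.34, 10), 1L, 2L, 3L, crit), 1L)
  expect_identical(detect_hbonds(mk(0.35, 10), 1L, 2L, 3L, crit), 0L)
  expect_identical(detect_hbonds(mk(0.36, 10), 1L, 2L, 3L, crit), 0L)
  # just past 30 degrees: no bond; just inside: bond
  expect_identical(detect_hbonds(mk(0.30, 30.001), 1L, 2L, 3L, crit), 0L)
  expect_identical(detect_hbonds(mk(0.30, 29.9), 1L, 2L, 3L, crit), 1L)
})

test_that("hydrogen mapping and criterion validation", {
  cfg <- kb_config(matrix(runif(9), 3, 3), c(5, 5, 5))
  expect_error(detect_hbonds(cfg, 1:2, 1L, 3L), "exactly one donor")
  expect_error(hbond_criterion(angle_max = 95), "90")
  expect_error(hbond_criterion(d_max = -1), "d_max")
})

test_that("chi percentage is monotone with the documented edge cases", {
  expect_warning(z <- chi_parameter(c(0, 0), c(0, 0)), "zero")
  expect_equal(z$chi, 0)
  expect_equal(chi_parameter(c(0, 0, 0), c(5, 4, 6))$chi, 0)
  base <- chi_parameter(c(2, 3), c(10, 10))
  expect_equal(base$chi, 25)
  doubled <- chi_parameter(c(4, 6), c(10, 10))
  expect_equal(doubled$chi, 2 * base$chi)
  # hand-computed value on a planted constant-count trajectory
  expect_equal(chi_parameter(rep(3, 8), rep(12, 8))$chi, 100 * 3 / 12)
  expect_warning(capped <- chi_parameter(12, 10), "capped")
  expect_equal(capped$chi, 100)
  expect_error(chi_parameter(c(-1), c(2)), "non-negative")
})

test_that("inclusion fraction matches planted truth and brute force", {
  fx <- gen_inclusion_fixture(2, 8, 5, seed = 4)
  res <- inclusion_fraction(fx)
  expect_equal(res$percent_cds_including, 40)
  expect_equal(res$per_frame_counts, 2L)
  cd_idx <- unlist(fx$cd_groups)
  guest_idx <- unlist(fx$guest_groups)
  expect_equal(res$percent_cds_including,
               oracle_inclusion(fx$traj, cd_idx, guest_idx))
  # all guests far away -> 0%
  fx0 <- gen_inclusion_fixture(0, 10, 4, seed = 2)
  expect_equal(inclusion_fraction(fx0)$percent_cds_including, 0)
})

test_that("a CD with several guests inside still counts once", {
  cd <- c(2, 2, 2)
  cfg <- kb_config(rbind(cd, cd + c(0.3, 0, 0), cd + c(0, 0.3, 0)),
                   c(10, 10, 10), species = c("CD", "G", "G"))
  res <- inclusion_fraction(kb_trajectory(cfg), list(1L), list(2L, 3L))
  expect_equal(res$per_frame_counts, 1L)
  expect_equal(res$percent_cds_including, 100)
})

test_that("inclusion cutoff is strict and frame averaging is linear", {
  mk <- function(d) kb_config(rbind(c(1, 1, 1), c(1 + d, 1, 1)),
                              c(10, 10, 10), species = c("CD", "G"))
  at_cut <- inclusion_fraction(kb_trajectory(mk(0.5)), list(1L), list(2L))
  expect_equal(at_cut$percent_cds_including, 0)   # exactly 0.5 nm excluded
  inside <- inclusion_fraction(kb_trajectory(mk(0.499)), list(1L), list(2L))
  expect_equal(inside$percent_cds_including, 100)
  # concatenation: percentage is the frame-count-weighted mean of the parts
  t1 <- kb_trajectory(list(mk(0.3), mk(0.3), mk(0.9)))
  t2 <- kb_trajectory(list(mk(0.9)))
  tall <- kb_trajectory(c(t1$frames, t2$frames))
  p1 <- inclusion_fraction(t1, list(1L), list(2L))$percent_cds_including
  p2 <- inclusion_fraction(t2, list(1L), list(2L))$percent_cds_including
  pall <- inclusion_fraction(tall, list(1L), list(2L))$percent_cds_including
  expect_equal(pall, (3 * p1 + 1 * p2) / 4)
})

test_that("centre-of-mass helper respects masses and periodic wrapping", {
  cfg <- kb_config(rbind(c(0.1, 1, 1), c(9.9, 1, 1)), c(10, 10, 10),
                   masses = c(1, 3))
  com <- kbsolv:::group_com(cfg, 1:2)
  # heavier atom across the boundary pulls the COM to its unwrapped side
  expect_equal(com[1], 0.1 + 0.75 * (-0.2), tolerance = 1e-12)
})

test_that("rim orientation: enriched rim shows the larger RDF maximum", {
  # build a fluid where 'secondary rim' particles are enriched around the
  # targets (A = 1) while 'primary rim' particles are ideal (A = 0)
  sp_enriched <- fluid_spec(30, 300, 8, "exponential_excess",
                            amplitude = 1, decay_length = 0.3,
                            n_frames = 10, seed = 41)
  tr_en <- gen_structured_fluid(sp_enriched)
  sp_ideal <- fluid_spec(30, 300, 8, "ideal", n_frames = 10, seed = 42)
  tr_id <- gen_ideal_gas(sp_ideal)
  # merge: centers of the enriched fluid are the targets; its partners are
  # the secondary rim; the ideal partners are the primary rim
  frames <- mapply(function(a, b) {
    kb_config(rbind(a$positions, b$positions[b$species == "J", ,
                                             drop = FALSE]),
              a$box,
              species = c(ifelse(a$species == "I", "TGT", "SEC"),
                          rep("PRI", sum(b$species == "J"))))
  }, tr_en$frames, tr_id$frames, SIMPLIFY = FALSE)
  traj <- kb_trajectory(frames)
  targets <- as.list(select_atoms(traj, "TGT"))
  res <- rim_orientation_rdf_max(traj, "PRI", "SEC", targets,
                                 dr = 0.1, r_max = 2)
  expect_gt(res$secondary$max_g, res$primary$max_g)
  expect_gt(res$secondary$max_g, 1.5)
  # the ideal rim is flat away from the noisy first bins
  prim <- res$primary$rdf
  expect_lt(abs(mean(prim$g[prim$r > 0.5]) - 1), 0.1)
})

test_that("rim orientation handles delta geometry and bad selections", {
  cfg <- kb_config(rbind(c(1, 1, 1), c(1, 1, 2.13), c(3, 3, 3)),
                   c(10, 10, 10), species = c("TGT", "RIM1", "RIM2"))
  traj <- kb_trajectory(cfg)
  res <- rim_orientation_rdf_max(traj, "RIM1", "RIM2", list(1L),
                                 dr = 0.1, r_max = 4)
  expect_equal(res$primary$r_at_max, 1.15)   # bin [1.1, 1.2) holds 1.13
  expect_error(rim_orientation_rdf_max(traj, "RIM1", "RIM1", list(1L),
                                       dr = 0.1, r_max = 4), "disjoint")
})

test_that("backbone vs side-chain maxima and the glycine degenerate case", {
  sp <- fluid_spec(25, 250, 8, "exponential_excess", amplitude = 1,
                   decay_length = 0.3, n_frames = 8, seed = 51)
  tr <- gen_structured_fluid(sp)
  # one center acts as the rim COM reference; enriched partners = backbone
  frames <- lapply(tr$frames, function(f) {
    kb_config(f$positions, f$box,
              species = ifelse(f$species == "I", "RIM", "BB"))
  })
  traj <- kb_trajectory(frames)
  rim_atom <- select_atoms(traj, "RIM")[1]
  res <- backbone_sidechain_rdf_max(traj, "BB", NULL, rim_atom,
                                    dr = 0.1, r_max = 2)
  expect_gt(res$backbone$max_g, 1.3)
  expect_true(isTRUE(res$sidechain$absent))
  # identical selections give identical maxima
  res2 <- backbone_sidechain_rdf_max(traj, "BB", "BB", rim_atom,
                                     dr = 0.1, r_max = 2)
  expect_equal(res2$backbone$max_g, res2$sidechain$max_g)
})
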