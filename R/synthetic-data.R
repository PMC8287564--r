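# Synthetic-data generators with known ground truth.
#
# Everything downstream (RDF/KBI numerics, the thermodynamic inversion, the
# structural counters, the backbone decomposition) is exercised against these
# generators, whose outputs come with closed-form or planted truths: an ideal
# gas (KBI = 0), an exponential-excess fluid (KBI = 8 pi A lambda^3),
# hydrogen-bond and cavity-inclusion fixtures planted with safety margins
# around the 0.35 nm / 30 degree / 0.5 nm decision boundaries, linear
# gamma-vs-chain-length series, and binary-solution thermodynamic datasets
# generated forward from chosen Kirkwood-Buff integrals.

#' Specification of a synthetic pair fluid
#'
#' @param n_centers number of reference particles (species `"I"`).
#' @param n_partners number of observed particles (species `"J"`).
#' @param box_edge cubic box edge, nm.
#' @param rdf_form `"ideal"` or `"exponential_excess"` (target
#'   `g(r) = 1 + A exp(-r/lambda)`).
#' @param amplitude excess amplitude A (dimensionless, > -1).
#' @param decay_length decay length lambda, nm (required for
#'   `exponential_excess`; must satisfy `lambda < box_edge / 4`).
#' @param n_frames number of independent frames.
#' @param seed integer RNG seed.
#' @return an object of class `kb_fluid_spec`.
#' @export
fluid_spec <- function(n_centers, n_partners, box_edge,
                       rdf_form = c("ideal", "exponential_excess"),
                       amplitude = 0, decay_length = NA_real_,
                       n_frames = 1L, seed = 1L) {
  rdf_form <- match.arg(rdf_form)
  n_centers <- stop_if_not_count(n_centers, "n_centers", min = 1L)
  n_partners <- stop_if_not_count(n_partners, "n_partners", min = 1L)
  n_frames <- stop_if_not_count(n_frames, "n_frames", min = 1L)
  stop_if_not_scalar_positive(box_edge, "box_edge")
  if (rdf_form == "exponential_excess") {
    if (!is.finite(amplitude) || amplitude <= -1) {
      stop("`amplitude` must be finite and > -1 (density must stay non-negative)",
           call. = FALSE)
    }
    stop_if_not_scalar_positive(decay_length, "decay_length")
    if (decay_length >= box_edge / 4) {
      stop("`decay_length` must be < box_edge / 4 (target not realizable inside the minimum image)",
           call. = FALSE)
    }
  }
  structure(
    list(n_centers = n_centers, n_partners = n_partners,
         box_edge = box_edge, rdf_form = rdf_form, amplitude = amplitude,
         decay_length = decay_length, n_frames = n_frames,
         seed = as.integer(seed)),
    class = "kb_fluid_spec"
  )
}

#' Generate an ideal-gas trajectory (uncorrelated uniform particles)
#'
#' Centers and partners are placed i.i.d. uniformly in the periodic box, so
#' every pair correlation is absent and all Kirkwood-Buff integrals are zero
#' by construction. Bit-reproducible under the spec's seed.
#'
#' @param spec a `kb_fluid_spec` with `rdf_form = "ideal"`.
#' @return a `kb_trajectory`; species `"I"` are centers, `"J"` partners.
#' @export
gen_ideal_gas <- function(spec) {
  stopifnot(inherits(spec, "kb_fluid_spec"))
  if (spec$rdf_form != "ideal") {
    stop("spec$rdf_form must be \"ideal\" for gen_ideal_gas", call. = FALSE)
  }
  box <- rep(spec$box_edge, 3L)
  with_seed(spec$seed, {
    frames <- lapply(seq_len(spec$n_frames), function(f) {
      n <- spec$n_centers + spec$n_partners
      pos <- matrix(stats::runif(3L * n, 0, spec$box_edge), n, 3L)
      kb_config(pos, box,
                species = rep(c("I", "J"),
                              c(spec$n_centers, spec$n_partners)))
    })
    kb_trajectory(frames)
  })
}

#' Generate a structured pair fluid with a known Kirkwood-Buff integral
#'
#' Partner particles are placed so that the ensemble pair density around the
#' centers follows \eqn{g(r) = 1 + A e^{-r/\lambda}}. For A >= 0, a uniform
#' background is combined with a fixed total number of excess partners
#' (multinomially assigned to centers, radial density
#' \eqn{\propto r^2 e^{-r/\lambda}}); for A < 0, all partners are drawn
#' i.i.d. from the normalised target density field by exact rejection
#' sampling. Either way every frame carries exactly `n_partners` partner
#' particles, and the planted amplitude is rescaled so the target holds
#' under the realised total partner density (the residual baseline bias is
#' below one part in `n_partners`). The analytic KBI,
#' \deqn{G = 4\pi \int_0^\infty A e^{-r/\lambda} r^2 dr = 8\pi A \lambda^3,}
#' is recorded as attribute `"G_analytic"` (nm^3).
#'
#' @param spec a `kb_fluid_spec` with `rdf_form = "exponential_excess"`.
#' @return a `kb_trajectory` with attributes `G_analytic`, `amplitude`,
#'   `decay_length`.
#' @export
gen_structured_fluid <- function(spec) {
  stopifnot(inherits(spec, "kb_fluid_spec"))
  if (spec$rdf_form != "exponential_excess") {
    stop("spec$rdf_form must be \"exponential_excess\"", call. = FALSE)
  }
  A <- spec$amplitude
  lam <- spec$decay_length
  L <- spec$box_edge
  box <- rep(L, 3L)
  v <- L^3
  n_c <- spec$n_centers
  n_p <- spec$n_partners
  traj <- with_seed(spec$seed, {
    frames <- lapply(seq_len(spec$n_frames), function(f) {
      centers <- matrix(stats::runif(3L * n_c, 0, L), n_c, 3L)
      if (A >= 0) {
        # fixed total excess count against the total density n_p / V
        k_total <- round(n_c * (n_p / v) * A * 8 * pi * lam^3)
        if (k_total >= n_p) {
          stop("amplitude too large: excess would exhaust the partners",
               call. = FALSE)
        }
        background <- matrix(stats::runif(3L * (n_p - k_total), 0, L),
                             ncol = 3L)
        partners <- background
        if (k_total > 0L) {
          owner <- sample.int(n_c, k_total, replace = TRUE)
          r <- stats::rgamma(k_total, shape = 3, scale = lam) # ~ r^2 e^(-r/lam)
          u <- matrix(stats::rnorm(3L * k_total), k_total, 3L)
          u <- u / sqrt(rowSums(u^2))
          partners <- rbind(background, centers[owner, , drop = FALSE] + u * r)
        }
      } else {
        # exact i.i.d. rejection sampling from the (clamped) target field
        # w(x) = 1 + A_p sum_c exp(-r_c/lam), envelope 1 since A_p < 0
        beta <- 8 * pi * lam^3 * n_c / v
        a_plant <- A / (1 - beta * A)
        partners <- matrix(numeric(0), 0L, 3L)
        while (nrow(partners) < n_p) {
          m <- 2L * (n_p - nrow(partners)) + 16L
          cand <- matrix(stats::runif(3L * m, 0, L), m, 3L)
          d <- pair_distances(cand, centers, box)
          w <- pmax(0, 1 + a_plant * rowSums(exp(-d / lam)))
          keep <- stats::runif(m) < w
          partners <- rbind(partners, cand[keep, , drop = FALSE])
        }
        partners <- partners[seq_len(n_p), , drop = FALSE]
      }
      partners <- partners %% L   # wrap into the box
      kb_config(rbind(centers, partners), box,
                species = rep(c("I", "J"), c(n_c, nrow(partners))))
    })
    kb_trajectory(frames)
  })
  attr(traj, "G_analytic") <- 8 * pi * A * lam^3
  attr(traj, "amplitude") <- A
  attr(traj, "decay_length") <- lam
  traj
}

#' Generate a planted hydrogen-bond fixture
#'
#' Builds `n_true` donor/hydrogen/acceptor triples that satisfy the geometric
#' hydrogen-bond criterion with a safety margin (distance <= d_max - 0.005
#' nm, angle <= angle_max - 2 degrees) and `n_false` triples that violate at
#' least one condition with the same margins, so histogram binning can never
#' flip a planted label. Triples are spaced >= 2 nm apart so no cross-triple
#' pair can qualify.
#'
#' @param n_true,n_false planted counts (>= 0).
#' @param seed integer RNG seed.
#' @param crit an [hbond_criterion()].
#' @return an object of class `kb_hbond_fixture` with fields `config`
#'   (a `kb_config`), `donors`, `hydrogens`, `acceptors` (index vectors) and
#'   `planted_true_count`.
#' @export
gen_hbond_fixture <- function(n_true, n_false, seed = 1L,
                              crit = hbond_criterion()) {
  n_true <- stop_if_not_count(n_true, "n_true")
  n_false <- stop_if_not_count(n_false, "n_false")
  n <- n_true + n_false
  d_margin <- 0.005
  a_margin <- 2
  with_seed(seed, {
    # lay triples on a coarse jittered grid, >= 2 nm apart
    per_side <- max(2L, ceiling(max(1L, n)^(1 / 3)))
    spacing <- 3
    box_l <- per_side * spacing + 4
    cells <- as.matrix(expand.grid(seq_len(per_side), seq_len(per_side),
                                   seq_len(per_side)))[seq_len(max(1L, n)), ,
                                                       drop = FALSE]
    base <- (cells - 0.5) * spacing +
      matrix(stats::runif(3 * max(1L, n), -0.3, 0.3), ncol = 3L)
    make_triple <- function(origin, true_bond) {
      u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))  # donor -> acceptor axis
      if (true_bond) {
        d_da <- stats::runif(1, 0.25, crit$d_max - d_margin)
        theta <- stats::runif(1, 0, crit$angle_max - a_margin) * pi / 180
      } else if (stats::runif(1) < 0.5) {
        d_da <- stats::runif(1, crit$d_max + d_margin, 0.8)  # too far
        theta <- stats::runif(1, 0, 80) * pi / 180
      } else {
        d_da <- stats::runif(1, 0.25, crit$d_max - d_margin)  # bad angle
        theta <- stats::runif(1, crit$angle_max + a_margin, 85) * pi / 180
      }
      # perpendicular direction for the off-axis component of D -> H
      w <- stats::rnorm(3); w <- w - sum(w * u) * u; w <- w / sqrt(sum(w^2))
      h_dir <- cos(theta) * u + sin(theta) * w
      list(d = origin, h = origin + 0.1 * h_dir, a = origin + d_da * u)
    }
    labels <- rep(c(TRUE, FALSE), c(n_true, n_false))
    if (n > 0L) labels <- sample(labels)
    triples <- lapply(seq_len(n), function(i) make_triple(base[i, ],
                                                          labels[i]))
    dpos <- do.call(rbind, lapply(triples, `[[`, "d"))
    hpos <- do.call(rbind, lapply(triples, `[[`, "h"))
    apos <- do.call(rbind, lapply(triples, `[[`, "a"))
    if (n == 0L) dpos <- hpos <- apos <- matrix(numeric(0), 0L, 3L)
    pos <- rbind(dpos, hpos, apos)
    if (nrow(pos) == 0L) pos <- matrix(box_l / 2, 1L, 3L)
    cfg <- kb_config(pos, rep(box_l, 3L),
                     species = if (n > 0L) rep(c("D", "H", "A"), each = n)
                               else "X")
    structure(
      list(config = cfg,
           donors = if (n > 0L) seq_len(n) else integer(0),
           hydrogens = if (n > 0L) n + seq_len(n) else integer(0),
           acceptors = if (n > 0L) 2L * n + seq_len(n) else integer(0),
           planted_true_count = n_true, criterion = crit),
      class = "kb_hbond_fixture"
    )
  })
}

#' Generate a planted cavity-inclusion fixture
#'
#' Places `n_cds` cyclodextrin centre-of-mass sites on a spaced grid and
#' plants `n_in` guest centres within 0.48 nm of distinct CDs and `n_out`
#' guests farther than 0.52 nm from every CD (0.02 nm margins around the 0.5
#' nm cutoff).
#'
#' @param n_in number of included guests (<= `n_cds`, each in a distinct CD).
#' @param n_out number of excluded guests.
#' @param n_cds number of cyclodextrins (>= 1).
#' @param seed integer RNG seed.
#' @param crit an [inclusion_criterion()].
#' @return an object of class `kb_inclusion_fixture` with fields `traj`
#'   (one-frame `kb_trajectory`), `cd_groups`, `guest_groups` (lists of index
#'   vectors) and `planted_included_count`.
#' @export
gen_inclusion_fixture <- function(n_in, n_out, n_cds, seed = 1L,
                                  crit = inclusion_criterion()) {
  n_in <- stop_if_not_count(n_in, "n_in")
  n_out <- stop_if_not_count(n_out, "n_out")
  n_cds <- stop_if_not_count(n_cds, "n_cds", min = 1L)
  if (n_in > n_cds) {
    stop("`n_in` must not exceed `n_cds` (one included guest per CD)",
         call. = FALSE)
  }
  margin <- 0.02
  with_seed(seed, {
    per_side <- max(2L, ceiling(n_cds^(1 / 3)))
    spacing <- 3
    box_l <- per_side * spacing + 2
    cells <- as.matrix(expand.grid(seq_len(per_side), seq_len(per_side),
                                   seq_len(per_side)))[seq_len(n_cds), ,
                                                       drop = FALSE]
    cd_pos <- (cells - 0.5) * spacing +
      matrix(stats::runif(3 * n_cds, -0.2, 0.2), ncol = 3L)
    included_cds <- if (n_in > 0L) sample(n_cds, n_in) else integer(0)
    guest_in <- if (n_in > 0L) {
      t(vapply(included_cds, function(ic) {
        u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
        cd_pos[ic, ] + stats::runif(1, 0.1, crit$com_cutoff - margin) * u
      }, numeric(3)))
    } else matrix(numeric(0), 0L, 3L)
    guest_out <- matrix(numeric(0), 0L, 3L)
    while (nrow(guest_out) < n_out) {
      cand <- matrix(stats::runif(3 * n_out, 0, box_l), ncol = 3L)
      dmin <- apply(pair_distances(cand, cd_pos, rep(box_l, 3L)), 1L, min)
      ok <- cand[dmin > crit$com_cutoff + margin + 0.05, , drop = FALSE]
      guest_out <- rbind(guest_out, ok)
    }
    guest_out <- guest_out[seq_len(n_out), , drop = FALSE]
    pos <- rbind(cd_pos, guest_in, guest_out)
    n_guests <- n_in + n_out
    cfg <- kb_config(pos, rep(box_l, 3L),
                     species = rep(c("CD", "G"), c(n_cds, n_guests)))
    structure(
      list(traj = kb_trajectory(cfg),
           cd_groups = lapply(seq_len(n_cds), identity),
           guest_groups = if (n_guests > 0L)
             lapply(n_cds + seq_len(n_guests), identity) else list(),
           planted_included_count = n_in, criterion = crit),
      class = "kb_inclusion_fixture"
    )
  })
}

#' Generate a noisy linear gamma-vs-chain-length series
#'
#' Emulates preferential-interaction coefficients of an
#' N-acetyl-(glycine)_x-amide series:
#' \eqn{\gamma(x) = \gamma^{eg} + \gamma^{bb} x + N(0, \sigma)}.
#'
#' @param gamma_eg_true end-group (intercept) truth, nm^3.
#' @param gamma_bb_true backbone (slope) truth, nm^3 per internal glycine.
#' @param x_values internal glycine counts (strictly increasing integers
#'   >= 1); default 1:6.
#' @param noise_sd Gaussian noise SD, nm^3 (>= 0).
#' @param seed integer RNG seed.
#' @return data.frame with columns `x`, `gamma`.
#' @export
gen_gamma_series <- function(gamma_eg_true, gamma_bb_true, x_values = 1:6,
                             noise_sd = 0, seed = 1L) {
  if (!length(x_values) || any(x_values < 1) ||
      any(x_values != round(x_values)) || is.unsorted(x_values, strictly = TRUE)) {
    stop("`x_values` must be strictly increasing integers >= 1",
         call. = FALSE)
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be >= 0", call. = FALSE)
  }
  with_seed(seed, {
    gamma <- gamma_eg_true + gamma_bb_true * x_values +
      if (noise_sd > 0) stats::rnorm(length(x_values), 0, noise_sd) else 0
    data.frame(x = as.integer(x_values), gamma = gamma)
  })
}

# Solve the Kirkwood-Buff volume relation for the total molar density rho
# (SI units) given a full KBI triple and the water partial molar volume:
#   V1 * (rho + rho^2 x1 x3 Delta) = 1 + rho x3 (G33 - G13)
solve_rho_full_triple <- function(x3, g11, g13, g33, v1) {
  x1 <- 1 - x3
  b <- g33 - g13
  delta <- (g11 - g13) + b
  qa <- v1 * x1 * x3 * delta
  qb <- v1 - x3 * b
  qc <- -1
  if (abs(qa) < 1e-300) {
    rho <- -qc / qb
  } else {
    disc <- qb^2 - 4 * qa * qc
    if (disc < 0) {
      stop(sprintf("no physical density for x3 = %g (discriminant < 0); KBI profile too extreme",
                   x3), call. = FALSE)
    }
    roots <- c((-qb + sqrt(disc)) / (2 * qa), (-qb - sqrt(disc)) / (2 * qa))
    roots <- roots[roots > 0]
    if (!length(roots)) {
      stop(sprintf("no positive density root at x3 = %g", x3), call. = FALSE)
    }
    rho <- min(roots)   # branch continuous with the Delta -> 0 limit 1/(V1 ...)
  }
  if (!is.finite(rho) || rho <= 0) {
    stop(sprintf("density solve failed at x3 = %g", x3), call. = FALSE)
  }
  rho
}

# Full per-composition forward state from a KBI triple (SI units in, SI out).
forward_state_si <- function(x3, g11, g13, g33, v1, betaT, temperature) {
  x1 <- 1 - x3
  a <- g11 - g13
  b <- g33 - g13
  rt <- R_GAS * temperature
  if (is.na(g11)) {
    # physical mode: the supplied compressibility closes the system, G11 is
    # derived.  From the compressibility relation, rho1 * a = (RT betaT -
    # G13)/V1 - 1 is composition-independent.
    cc <- (rt * betaT - g13) / v1 - 1
    qa <- v1 * x1 * x3 * b
    qb <- v1 * (1 + x3 * cc) - x3 * b
    if (abs(qa) < 1e-300) {
      rho <- 1 / qb
    } else {
      disc <- qb^2 + 4 * qa
      if (disc < 0) stop(sprintf("no density root at x3 = %g", x3),
                         call. = FALSE)
      roots <- c((-qb + sqrt(disc)) / (2 * qa), (-qb - sqrt(disc)) / (2 * qa))
      roots <- roots[roots > 0]
      if (!length(roots)) stop(sprintf("no positive density root at x3 = %g",
                                       x3), call. = FALSE)
      rho <- min(roots)
    }
    rho1 <- rho * x1
    a <- cc / rho1
    g11 <- g13 + a
    betaT_state <- betaT
  } else {
    rho <- solve_rho_full_triple(x3, g11, g13, g33, v1)
    rho1 <- rho * x1
    betaT_state <- NA_real_  # filled below from the exact relation
  }
  rho3 <- rho * x3
  delta <- a + b
  eta <- rho1 + rho3 + rho1 * rho3 * delta
  if (!is.finite(eta) || eta <= 0) {
    stop(sprintf("intermediate eta vanishes at x3 = %g", x3), call. = FALSE)
  }
  v3 <- (1 + rho1 * a) / eta
  if (v3 <= 0) {
    stop(sprintf("negative partial molar volume V3 at x3 = %g", x3),
         call. = FALSE)
  }
  dd <- rho / eta                     # = x3 dmu3/dx3 / RT, dimensionless
  if (is.na(betaT_state)) {
    zeta <- 1 + rho1 * g11 + rho3 * g33 +
      rho1 * rho3 * (g11 * g33 - g13^2)
    if (zeta <= 0) {
      stop(sprintf("compressibility intermediate vanishes at x3 = %g", x3),
           call. = FALSE)
    }
    betaT_state <- zeta / (eta * rt)
  }
  list(x3 = x3, rho = rho, rho1 = rho1, rho3 = rho3, v1 = v1, v3 = v3,
       betaT = betaT_state, dmu3_dx3 = rt * dd / x3, f33 = dd - 1,
       g11 = g11, g13 = g13, g33 = g33)
}

#' Forward-generate a binary-solution thermodynamic dataset from chosen KBIs
#'
#' Inverts the Kirkwood-Buff relations algebraically: given a profile of
#' KBIs for a dilute water(1)-cosolvent(3) mixture it produces, per
#' composition, the total/species molar densities, partial molar volumes,
#' isothermal compressibility, chemical-potential derivative and activity
#' coefficients that are exactly consistent with those KBIs, so that
#' [invert_thermo_to_kbi()] round-trips to the input.
#'
#' Two modes are supported. If the profile returns all three of
#' `c(G11, G13, G33)` (cm^3/mol), the water partial molar volume `V1`
#' anchors the density scale and the state's compressibility is derived from
#' the exact compressibility relation. If the profile returns `G11 = NA`,
#' the supplied `betaT` closes the system instead and G11 is derived (the
#' realised triple is recorded in the output attributes).
#'
#' @param kbi_profile function `x3 -> c(G11, G13, G33)` in cm^3/mol
#'   (`G11` may be `NA`, see above); must be smooth on the grid.
#' @param x3_grid cosolvent mole fractions, all in (0, 0.05] (dilute regime).
#' @param V1 water partial molar volume, cm^3/mol (default 18.07).
#' @param betaT isothermal compressibility, 1/Pa (default 4.52e-10); used
#'   only in the `G11 = NA` mode.
#' @param temperature temperature, K (default 298).
#' @return a data.frame of class `kb_thermo_dataset` with columns `x3`,
#'   `rho`, `rho1`, `rho3` (mol/L), `V1`, `V3` (cm^3/mol), `betaT` (1/Pa),
#'   `dmu3_dx3` (J/mol), `f3`, `f3m`, `T` (K); the realised KBI triples are
#'   in `attr(, "kbi_true")` (cm^3/mol).
#' @export
gen_binary_thermo_dataset <- function(kbi_profile, x3_grid, V1 = 18.07,
                                      betaT = 4.52e-10, temperature = 298) {
  if (!is.function(kbi_profile)) stop("`kbi_profile` must be a function",
                                      call. = FALSE)
  x3_grid <- as.numeric(x3_grid)
  if (!length(x3_grid) || any(x3_grid <= 0) || any(x3_grid > 0.05)) {
    stop("`x3_grid` values must lie in (0, 0.05] (dilute regime)",
         call. = FALSE)
  }
  stop_if_not_scalar_positive(V1, "V1")
  stop_if_not_scalar_positive(temperature, "temperature")
  v1_si <- V1 * 1e-6
  prof_si <- function(x3) {
    g <- as.numeric(kbi_profile(x3))
    if (length(g) != 3L) stop("kbi_profile must return c(G11, G13, G33)",
                              call. = FALSE)
    g * 1e-6
  }
  states <- lapply(x3_grid, function(x3) {
    g <- prof_si(x3)
    forward_state_si(x3, g[1L], g[2L], g[3L], v1_si, betaT, temperature)
  })
  # ln f3(x3) by quadrature of the closed-form derivative from x3 -> 0
  dlnf3 <- function(s) {
    vapply(s, function(si) {
      g <- prof_si(si)
      st <- forward_state_si(si, g[1L], g[2L], g[3L], v1_si, betaT,
                             temperature)
      st$f33 / si
    }, numeric(1))
  }
  lnf3 <- vapply(x3_grid, function(x3) {
    stats::integrate(dlnf3, 0, x3, rel.tol = 1e-9,
                     subdivisions = 400L)$value
  }, numeric(1))
  out <- data.frame(
    x3 = x3_grid,
    rho = vapply(states, function(s) s$rho / 1e3, numeric(1)),
    rho1 = vapply(states, function(s) s$rho1 / 1e3, numeric(1)),
    rho3 = vapply(states, function(s) s$rho3 / 1e3, numeric(1)),
    V1 = V1,
    V3 = vapply(states, function(s) s$v3 * 1e6, numeric(1)),
    betaT = vapply(states, function(s) s$betaT, numeric(1)),
    dmu3_dx3 = vapply(states, function(s) s$dmu3_dx3, numeric(1)),
    f3 = exp(lnf3),
    f3m = x3_grid * exp(lnf3),
    T = temperature
  )
  attr(out, "kbi_true") <- data.frame(
    x3 = x3_grid,
    G11 = vapply(states, function(s) s$g11 * 1e6, numeric(1)),
    G13 = vapply(states, function(s) s$g13 * 1e6, numeric(1)),
    G33 = vapply(states, function(s) s$g33 * 1e6, numeric(1))
  )
  attr(out, "f33_true") <- vapply(states, function(s) s$f33, numeric(1))
  class(out) <- c("kb_thermo_dataset", "data.frame")
  out
}

#' Write a thermodynamic dataset as CSV
#'
#' @param dataset a `kb_thermo_dataset` (or compatible data.frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_thermo_csv <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}

#' Read a thermodynamic dataset CSV written by [write_thermo_csv()]
#'
#' @param path input file path.
#' @return a `kb_thermo_dataset` data.frame.
#' @export
read_thermo_csv <- function(path) {
  out <- utils::read.csv(path)
  class(out) <- c("kb_thermo_dataset", "data.frame")
  out
}
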