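# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package internals: plain loops,
# explicit minimum image, same binning conventions.

oracle_min_image <- function(a, b, box) {
  d <- a - b
  for (k in 1:3) d[k] <- d[k] - box[k] * round(d[k] / box[k])
  d
}

# Brute-force RDF on one or more frames: half-open bins [r, r+dr), density
# N_j / V, self-pairs excluded when the index sets are identical.
oracle_rdf <- function(traj, idx_i, idx_j, dr, r_max) {
  nbins <- ceiling(r_max / dr - 1e-9)
  counts <- numeric(nbins)
  ideal <- numeric(nbins)
  self_pair <- identical(sort(idx_i), sort(idx_j))
  for (cfg in traj$frames) {
    v <- prod(cfg$box)
    for (i in idx_i) {
      for (j in idx_j) {
        if (self_pair && i == j) next
        r <- sqrt(sum(oracle_min_image(cfg$positions[i, ],
                                       cfg$positions[j, ], cfg$box)^2))
        b <- floor(r / dr) + 1
        if (b <= nbins) counts[b] <- counts[b] + 1
      }
    }
    for (b in seq_len(nbins)) {
      shell <- (4 / 3) * pi * ((b * dr)^3 - ((b - 1) * dr)^3)
      ideal[b] <- ideal[b] + length(idx_i) * length(idx_j) / v * shell
    }
  }
  list(r = (seq_len(nbins) - 0.5) * dr, g = counts / ideal)
}

# Brute-force excess counts Delta N_ij(r): mean over frames and centers of
# (j within r, self excluded) minus (N_j/V) * 4 pi r^3 / 3.
oracle_excess <- function(traj, idx_i, idx_j, r_grid) {
  self_pair <- identical(sort(idx_i), sort(idx_j))
  acc <- numeric(length(r_grid))
  for (cfg in traj$frames) {
    v <- prod(cfg$box)
    for (ri in seq_along(r_grid)) {
      r0 <- r_grid[ri]
      tot <- 0
      for (i in idx_i) {
        for (j in idx_j) {
          if (self_pair && i == j) next
          r <- sqrt(sum(oracle_min_image(cfg$positions[i, ],
                                         cfg$positions[j, ], cfg$box)^2))
          if (r <= r0) tot <- tot + 1
        }
      }
      acc[ri] <- acc[ri] + tot / length(idx_i) -
        length(idx_j) / v * (4 / 3) * pi * r0^3
    }
  }
  acc / length(traj$frames)
}

# Brute-force geometric hydrogen-bond counter (angle at the donor).
oracle_hbonds <- function(config, donors, hydrogens, acceptors,
                          d_max = 0.35, angle_max = 30) {
  count <- 0
  for (k in seq_along(donors)) {
    for (a in acceptors) {
      if (a == donors[k]) next
      da <- oracle_min_image(config$positions[a, ],
                             config$positions[donors[k], ], config$box)
      if (sqrt(sum(da^2)) >= d_max) next
      dh <- oracle_min_image(config$positions[hydrogens[k], ],
                             config$positions[donors[k], ], config$box)
      cosang <- sum(dh * da) / sqrt(sum(dh^2) * sum(da^2))
      ang <- acos(max(-1, min(1, cosang))) * 180 / pi
      if (ang < angle_max) count <- count + 1
    }
  }
  count
}

# Brute-force inclusion percentage for single-atom groups.
oracle_inclusion <- function(traj, cd_idx, guest_idx, cutoff = 0.5) {
  counts <- vapply(traj$frames, function(cfg) {
    n <- 0
    for (c_i in cd_idx) {
      hit <- FALSE
      for (g_i in guest_idx) {
        d <- sqrt(sum(oracle_min_image(cfg$positions[c_i, ],
                                       cfg$positions[g_i, ], cfg$box)^2))
        if (d < cutoff) { hit <- TRUE; break }
      }
      if (hit) n <- n + 1
    }
    n
  }, numeric(1))
  mean(counts) / length(cd_idx) * 100
}

# Numerical quadrature of 4 pi int (g(r)-1) r^2 dr for analytic g.
oracle_kbi_quadrature <- function(gfun, upper = Inf) {
  stats::integrate(function(r) 4 * pi * (gfun(r) - 1) * r^2, 0, upper,
                   rel.tol = 1e-10)$value
}

# A mild, physically admissible KBI profile (cm^3/mol) for thermo tests:
# stays inside the positive-compressibility region over x3 <= 0.005.
test_kbi_profile <- function(x3) {
  c(G11 = -16 + 20 * x3, G13 = -60 - 200 * x3, G33 = -200 + 1000 * x3)
}
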