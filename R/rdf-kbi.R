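# Radial distribution functions, the closed-system finite-size correction,
# and Kirkwood-Buff integrals.
#
# The pipeline is g_ij(r) -> (optional finite-size correction) ->
# G_ij(R) = 4 pi int_0^R (g-1) r^2 dr -> window-averaged estimate with a
# block-averaged standard error. Distances use the minimum-image convention
# in orthorhombic boxes; bins are uniform and half-open [r, r + dr), reported
# at bin centres. The pair density used for normalisation is N_j / V (with
# self-pairs excluded from the counts when the selections coincide), which is
# the convention the closed-system correction assumes.

#' Construct an RDF curve directly from values
#'
#' Mainly useful for injecting analytic g(r) curves into [running_kbi()] and
#' [correct_rdf_finite_size()]; [compute_rdf()] builds these from
#' trajectories.
#'
#' @param r bin centres, nm (strictly increasing, uniform width).
#' @param g dimensionless RDF values (non-negative).
#' @param n_i,n_j particle counts of the reference and observed selections.
#' @param volume mean box volume, nm^3.
#' @param self_pair logical: do the two selections coincide?
#' @param frame_count number of frames averaged.
#' @param pair character pair label, e.g. `c("I", "J")`.
#' @param corrected logical: has the finite-size correction been applied?
#' @return an object of class `kb_rdf`.
#' @export
rdf_curve <- function(r, g, n_i = 1L, n_j = 1L, volume = Inf,
                      self_pair = FALSE, frame_count = 1L,
                      pair = c("i", "j"), corrected = FALSE) {
  r <- as.numeric(r)
  g <- as.numeric(g)
  if (length(r) != length(g) || length(r) < 2L) {
    stop("`r` and `g` must be equal-length vectors (>= 2 points)",
         call. = FALSE)
  }
  dr <- diff(r)
  if (any(dr <= 0) || max(abs(dr - dr[1L])) > 1e-8 * dr[1L]) {
    stop("`r` must be strictly increasing with uniform spacing",
         call. = FALSE)
  }
  if (any(g < 0)) stop("g(r) must be non-negative", call. = FALSE)
  structure(
    list(r = r, g = g, dr = dr[1L], n_i = as.integer(n_i),
         n_j = as.integer(n_j), volume = volume, self_pair = self_pair,
         frame_count = as.integer(frame_count), pair = pair,
         corrected = corrected),
    class = "kb_rdf"
  )
}

#' @export
print.kb_rdf <- function(x, ...) {
  cat(sprintf(
    "kb_rdf %s-%s: %d bins, dr = %g nm, r in [%g, %g] nm%s\n",
    x$pair[1], x$pair[2], length(x$r), x$dr, min(x$r), max(x$r),
    if (x$corrected) " (finite-size corrected)" else ""))
  invisible(x)
}

#' Compute a radial distribution function from a trajectory
#'
#' Histogram of minimum-image pair distances between two selections,
#' normalised per frame by the ideal-gas expectation `N_i * (N_j/V) * Vshell`
#' from the instantaneous box volume. When the selections coincide,
#' self-pairs are excluded from the counts but the density is still `N_j/V`
#' (closed-system convention; see [correct_rdf_finite_size()]).
#'
#' @param traj a `kb_trajectory`.
#' @param sel_i,sel_j selections (see [select_atoms()]).
#' @param dr bin width, nm.
#' @param r_max histogram range, nm; must not exceed half the smallest box
#'   edge (minimum-image validity).
#' @return a `kb_rdf` object.
#' @export
compute_rdf <- function(traj, sel_i, sel_j, dr, r_max) {
  stop_if_not_scalar_positive(dr, "dr")
  stop_if_not_scalar_positive(r_max, "r_max")
  idx_i <- select_atoms(traj, sel_i)
  idx_j <- select_atoms(traj, sel_j)
  self_pair <- identical(idx_i, idx_j)
  min_edge <- min(vapply(traj$frames, function(f) min(f$box), numeric(1)))
  if (r_max > min_edge / 2 + 1e-12) {
    stop(sprintf(
      "r_max = %g nm exceeds half the smallest box edge (%g nm)",
      r_max, min_edge / 2), call. = FALSE)
  }
  nbins <- ceiling(r_max / dr - 1e-9)
  edges <- (0:nbins) * dr
  counts <- numeric(nbins)
  ideal <- numeric(nbins)
  vsum <- 0
  shell_vol <- (4 / 3) * pi * diff(edges^3)
  for (cfg in traj$frames) {
    d <- pair_distances(cfg$positions[idx_i, , drop = FALSE],
                        cfg$positions[idx_j, , drop = FALSE], cfg$box)
    if (self_pair) diag(d) <- Inf
    d <- d[d < nbins * dr]
    if (length(d)) {
      bins <- pmin(floor(d / dr) + 1L, nbins)
      counts <- counts + tabulate(bins, nbins)
    }
    v <- prod(cfg$box)
    vsum <- vsum + v
    ideal <- ideal + length(idx_i) * (length(idx_j) / v) * shell_vol
  }
  g <- counts / ideal
  rdf_curve(r = edges[-1L] - dr / 2, g = g, n_i = length(idx_i),
            n_j = length(idx_j), volume = vsum / n_frames(traj),
            self_pair = self_pair, frame_count = n_frames(traj),
            pair = c(deparse(substitute(sel_i))[1L],
                     deparse(substitute(sel_j))[1L]))
}

#' Excess number of j particles within a sphere around i
#'
#' For each radius in `r_grid`, the mean over frames and reference particles
#' of the minimum-image count of j particles within r (self-pairs excluded
#' when the selections coincide) minus the ideal-gas expectation
#' `(N_j/V) * 4 pi r^3 / 3`. This is the Delta N_ij(r) curve the
#' finite-size correction consumes.
#'
#' @inheritParams compute_rdf
#' @param r_grid radii at which to evaluate, nm (typically `rdf$r`).
#' @return numeric vector of excess counts with attribute `"r"`.
#' @export
excess_counts <- function(traj, sel_i, sel_j, r_grid) {
  idx_i <- select_atoms(traj, sel_i)
  idx_j <- select_atoms(traj, sel_j)
  self_pair <- identical(idx_i, idx_j)
  r_grid <- as.numeric(r_grid)
  if (any(r_grid < 0)) stop("radii must be non-negative", call. = FALSE)
  min_edge <- min(vapply(traj$frames, function(f) min(f$box), numeric(1)))
  if (max(r_grid) > min_edge / 2 + 1e-12) {
    stop("r_grid extends beyond minimum-image validity", call. = FALSE)
  }
  acc <- numeric(length(r_grid))
  for (cfg in traj$frames) {
    d <- pair_distances(cfg$positions[idx_i, , drop = FALSE],
                        cfg$positions[idx_j, , drop = FALSE], cfg$box)
    if (self_pair) diag(d) <- Inf
    ds <- sort(as.numeric(d))
    cum <- findInterval(r_grid, ds)            # pairs with distance <= r
    rho_j <- length(idx_j) / prod(cfg$box)
    acc <- acc + cum / length(idx_i) - rho_j * (4 / 3) * pi * r_grid^3
  }
  out <- acc / n_frames(traj)
  attr(out, "r") <- r_grid
  out
}

#' Apply the closed-system finite-size correction to an RDF
#'
#' Rescales a closed-system (NVT/NpT, fixed particle number) RDF so that its
#' Kirkwood-Buff integral approximates open-system behaviour:
#' \deqn{g^{cor}_{ij}(r) = g_{ij}(r)\,
#'   \frac{N_j\,(1 - V(r)/V)}{N_j\,(1 - V(r)/V) - \Delta N_{ij}(r) -
#'   \delta_{ij}}}
#' with \eqn{V(r) = 4\pi r^3/3}, \eqn{\Delta N_{ij}(r)} the excess count
#' curve from [excess_counts()], and \eqn{\delta_{ij}} the Kronecker delta
#' for identical selections. The factor tends to 1 as r tends to 0 for
#' unlike pairs in large systems, and already-corrected curves are refused.
#'
#' @param rdf a `kb_rdf` from [compute_rdf()] (not yet corrected).
#' @param excess Delta N_ij(r) evaluated on `rdf$r` (see [excess_counts()]).
#' @return the corrected `kb_rdf`, flagged `corrected = TRUE`.
#' @export
correct_rdf_finite_size <- function(rdf, excess) {
  stopifnot(inherits(rdf, "kb_rdf"))
  if (isTRUE(rdf$corrected)) {
    stop("RDF is already finite-size corrected; refusing to correct twice",
         call. = FALSE)
  }
  rg <- attr(excess, "r")
  if (!is.null(rg) &&
      (length(rg) != length(rdf$r) || max(abs(rg - rdf$r)) > 1e-9)) {
    stop("excess-count grid does not match the RDF grid", call. = FALSE)
  }
  if (length(excess) != length(rdf$r)) {
    stop("excess-count curve must have one value per RDF bin", call. = FALSE)
  }
  if (!is.finite(rdf$volume)) {
    stop("RDF carries no box volume; cannot correct", call. = FALSE)
  }
  delta_ij <- as.numeric(isTRUE(rdf$self_pair))
  vr <- (4 / 3) * pi * rdf$r^3
  bulk <- rdf$n_j * (1 - vr / rdf$volume)
  denom <- bulk - as.numeric(excess) - delta_ij
  if (any(denom <= 0)) {
    stop("correction denominator vanishes; r range too large for this system",
         call. = FALSE)
  }
  out <- rdf
  out$g <- rdf$g * bulk / denom
  out$corrected <- TRUE
  out
}

#' Running Kirkwood-Buff integral of an RDF
#'
#' Cumulative trapezoidal evaluation of
#' \deqn{G(R) = 4\pi \int_0^R (g(r) - 1)\, r^2\, dr}
#' on the bin grid, with the exact value G(0) = 0 prepended (the integrand
#' vanishes at r = 0).
#'
#' @param rdf a `kb_rdf`.
#' @return an object of class `kb_running` with fields `R` (nm) and `G`
#'   (nm^3); quadrature recorded in `$quadrature`.
#' @export
running_kbi <- function(rdf) {
  stopifnot(inherits(rdf, "kb_rdf"))
  r <- c(0, rdf$r)
  integrand <- c(0, 4 * pi * (rdf$g - 1) * rdf$r^2)
  widths <- diff(r)
  areas <- widths * (integrand[-1L] + integrand[-length(integrand)]) / 2
  structure(
    list(R = r, G = c(0, cumsum(areas)), quadrature = "trapezoid",
         corrected = rdf$corrected),
    class = "kb_running"
  )
}

#' Estimate a converged KBI from running integrals
#'
#' The estimate is the mean of G(R) over a window `[R_lo, R_hi]` where the
#' running integral has flattened. When a list of per-block running curves is
#' supplied (see [block_running_kbis()]), the standard error is the standard
#' deviation of the per-block window means divided by sqrt(blocks); a single
#' curve yields stderr 0. A warning is attached when the mean slope of G(R)
#' across the window exceeds `flatness_tol` (nm^3 per nm).
#'
#' @param running a `kb_running` or a list of them (one per frame block).
#' @param window numeric `c(R_lo, R_hi)` in nm; default `c(1.5, 2.5)`.
#' @param flatness_tol maximum |dG/dR| (nm^2) regarded as converged.
#' @return an object of class `kb_estimate` with fields `G`, `stderr`,
#'   `window`, `blocks`, `corrected`.
#' @export
estimate_kbi <- function(running, window = c(1.5, 2.5), flatness_tol = 0.5) {
  if (inherits(running, "kb_running")) running <- list(running)
  if (!length(running) ||
      !all(vapply(running, inherits, logical(1), "kb_running"))) {
    stop("`running` must be a kb_running or a list of them", call. = FALSE)
  }
  if (length(window) != 2L || window[1L] >= window[2L]) {
    stop("`window` must be c(R_lo, R_hi) with R_lo < R_hi", call. = FALSE)
  }
  rmax <- min(vapply(running, function(x) max(x$R), numeric(1)))
  if (window[2L] > rmax + 1e-9 || window[1L] < 0) {
    stop(sprintf("window [%g, %g] nm lies outside the R grid (max %g nm)",
                 window[1L], window[2L], rmax), call. = FALSE)
  }
  win_mean <- vapply(running, function(x) {
    keep <- x$R >= window[1L] - 1e-9 & x$R <= window[2L] + 1e-9
    if (!any(keep)) stop("window contains no grid points", call. = FALSE)
    mean(x$G[keep])
  }, numeric(1))
  nb <- length(win_mean)
  g_hat <- mean(win_mean)
  se <- if (nb >= 2L) stats::sd(win_mean) / sqrt(nb) else 0
  # flatness check on the pooled curve
  pooled_g <- rowMeans(vapply(running, function(x) x$G,
                              numeric(length(running[[1L]]$R))))
  pooled_r <- running[[1L]]$R
  at <- function(r0) pooled_g[which.min(abs(pooled_r - r0))]
  slope <- abs(at(window[2L]) - at(window[1L])) / diff(window)
  est <- structure(
    list(G = g_hat, stderr = se, window = window, blocks = nb,
         corrected = isTRUE(running[[1L]]$corrected)),
    class = "kb_estimate"
  )
  if (is.finite(flatness_tol) && slope > flatness_tol) {
    warning(sprintf(
      "running KBI not flat on window [%g, %g] nm (|dG/dR| ~ %.3g nm^2)",
      window[1L], window[2L], slope), call. = FALSE)
  }
  est
}

#' @export
print.kb_estimate <- function(x, ...) {
  cat(sprintf(
    "KBI estimate: G = %.4g +/- %.3g nm^3 (window %g-%g nm, %d block(s)%s)\n",
    x$G, x$stderr, x$window[1], x$window[2], x$blocks,
    if (x$corrected) ", finite-size corrected" else ""))
  invisible(x)
}

#' Per-block running KBIs from a trajectory
#'
#' Splits the frames into `blocks` contiguous blocks and computes the
#' (optionally finite-size-corrected) running KBI for each, for use with
#' [estimate_kbi()].
#'
#' @inheritParams compute_rdf
#' @param blocks number of frame blocks (>= 2 for a standard error).
#' @param correct logical: apply [correct_rdf_finite_size()] per block.
#' @return list of `kb_running` objects.
#' @export
block_running_kbis <- function(traj, sel_i, sel_j, dr, r_max, blocks = 5L,
                               correct = TRUE) {
  blocks <- stop_if_not_count(blocks, "blocks", min = 1L)
  nf <- n_frames(traj)
  if (blocks > nf) stop("more blocks than frames", call. = FALSE)
  cut_idx <- split(seq_len(nf), ceiling(seq_len(nf) / (nf / blocks)))
  lapply(cut_idx, function(ix) {
    sub <- kb_trajectory(traj$frames[ix], traj$times[ix])
    rdf <- compute_rdf(sub, sel_i, sel_j, dr, r_max)
    if (correct) {
      rdf <- correct_rdf_finite_size(
        rdf, excess_counts(sub, sel_i, sel_j, rdf$r))
    }
    running_kbi(rdf)
  })
}

#' Convert a KBI between nm^3 per molecule and cm^3 per mole
#'
#' `1 nm^3 = N_A * 1e-21 cm^3/mol = 602.214... cm^3/mol`.
#'
#' @param x numeric value(s).
#' @return converted value(s).
#' @export
kbi_nm3_to_cm3mol <- function(x) {
  if (any(!is.finite(x))) stop("input must be finite", call. = FALSE)
  x * AVOGADRO * 1e-21
}

#' @rdname kbi_nm3_to_cm3mol
#' @export
kbi_cm3mol_to_nm3 <- function(x) {
  if (any(!is.finite(x))) stop("input must be finite", call. = FALSE)
  x / (AVOGADRO * 1e-21)
}

#' Write an RDF or running-KBI curve as two-column CSV
#'
#' Metadata (pair labels, counts, volume, correction flag) is written as
#' comment lines prefixed with `#`.
#'
#' @param x a `kb_rdf` or `kb_running` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "kb_rdf")) {
    writeLines(c(
      sprintf("# kbsolv rdf pair=%s-%s", x$pair[1], x$pair[2]),
      sprintf("# n_i=%d n_j=%d volume_nm3=%g frames=%d corrected=%s",
              x$n_i, x$n_j, x$volume, x$frame_count, x$corrected),
      "r_nm,g"), con)
    utils::write.table(data.frame(x$r, x$g), con, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  } else if (inherits(x, "kb_running")) {
    writeLines(c(sprintf("# kbsolv running-kbi quadrature=%s corrected=%s",
                         x$quadrature, x$corrected),
                 "R_nm,G_nm3"), con)
    utils::write.table(data.frame(x$R, x$G), con, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  } else {
    stop("`x` must be a kb_rdf or kb_running object", call. = FALSE)
  }
  invisible(path)
}
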