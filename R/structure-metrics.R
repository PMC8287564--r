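# Per-trajectory structural metrics: geometric hydrogen bonds and the chi
# percentage, cavity inclusion of guests, and rim / backbone-vs-side-chain
# orientation via RDF maxima.
#
# All cutoffs are strict inequalities, as in the geometric criteria they
# implement: donor-acceptor distance < 0.35 nm AND proton deviation angle
# < 30 degrees for a hydrogen bond; guest centre of mass < 0.5 nm from the
# cyclodextrin centre of mass for an inclusion.

#' Geometric hydrogen-bond criterion
#'
#' @param d_max maximum donor-acceptor distance, nm (strict; default 0.35).
#' @param angle_max maximum angle, degrees (strict; default 30). The angle
#'   is measured at the donor, between the donor-to-hydrogen vector and the
#'   donor-to-acceptor line (the standard proton-deviation convention; see
#'   `vertex`).
#' @param vertex where the angle is measured: `"donor"` (default) or
#'   `"hydrogen"` (angle at H between H-to-donor and H-to-acceptor).
#' @return an object of class `kb_hbond_criterion`.
#' @export
hbond_criterion <- function(d_max = 0.35, angle_max = 30,
                            vertex = c("donor", "hydrogen")) {
  stop_if_not_scalar_positive(d_max, "d_max")
  if (!is.finite(angle_max) || angle_max <= 0 || angle_max >= 90) {
    stop("`angle_max` must lie in (0, 90) degrees", call. = FALSE)
  }
  structure(list(d_max = d_max, angle_max = angle_max,
                 vertex = match.arg(vertex)),
            class = "kb_hbond_criterion")
}

#' Cavity-inclusion criterion
#'
#' @param com_cutoff maximum guest-to-host centre-of-mass distance, nm
#'   (strict; default 0.5).
#' @return an object of class `kb_inclusion_criterion`.
#' @export
inclusion_criterion <- function(com_cutoff = 0.5) {
  stop_if_not_scalar_positive(com_cutoff, "com_cutoff")
  structure(list(com_cutoff = com_cutoff),
            class = "kb_inclusion_criterion")
}

#' Count geometric hydrogen bonds in a configuration
#'
#' A donor-acceptor pair is counted when the minimum-image donor-acceptor
#' distance is strictly below `crit$d_max` and the angle (at the donor, by
#' default) between the donor-to-hydrogen vector and the donor-to-acceptor
#' line is strictly below `crit$angle_max`. Each hydrogen is mapped to
#' exactly one donor by position: `hydrogens[k]` is bonded to `donors[k]`.
#' Pairs where the acceptor atom is the donor itself are skipped.
#'
#' @param config a `kb_config` (or a fixture from [gen_hbond_fixture()], in
#'   which case the selections default to the fixture's own).
#' @param donors,hydrogens integer index vectors of equal length.
#' @param acceptors integer index vector.
#' @param crit an [hbond_criterion()].
#' @return integer count of hydrogen bonds.
#' @export
detect_hbonds <- function(config, donors = NULL, hydrogens = NULL,
                          acceptors = NULL, crit = hbond_criterion()) {
  if (inherits(config, "kb_hbond_fixture")) {
    fixture <- config
    config <- fixture$config
    if (is.null(donors)) donors <- fixture$donors
    if (is.null(hydrogens)) hydrogens <- fixture$hydrogens
    if (is.null(acceptors)) acceptors <- fixture$acceptors
  }
  stopifnot(inherits(config, "kb_config"))
  if (length(donors) == 0L || length(acceptors) == 0L) return(0L)
  if (length(hydrogens) != length(donors)) {
    stop("every hydrogen must be mapped to exactly one donor (equal-length vectors)",
         call. = FALSE)
  }
  box <- config$box
  pos <- config$positions
  count <- 0L
  for (k in seq_along(donors)) {
    dpos <- pos[donors[k], ]
    hpos <- pos[hydrogens[k], ]
    dh <- min_image(matrix(hpos - dpos, 1L), box)[1L, ]
    for (ai in acceptors) {
      if (ai == donors[k]) next
      da <- min_image(matrix(pos[ai, ] - dpos, 1L), box)[1L, ]
      r <- sqrt(sum(da^2))
      if (r >= crit$d_max) next
      if (crit$vertex == "donor") {
        v1 <- dh; v2 <- da
      } else {
        v1 <- -dh
        v2 <- min_image(matrix(pos[ai, ] - hpos, 1L), box)[1L, ]
      }
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      if (ang < crit$angle_max) count <- count + 1L
    }
  }
  count
}

#' Hydrogen-bonding chi percentage
#'
#' The percentage of hydrogen bonds formed by the cosolvent that involve the
#' solute, pooled over frames:
#' \deqn{\chi = 100 \times \frac{\sum_f n^{2-3}_f}{\sum_f n^{tot}_f},}
#' where `n23` counts solute-cosolvent hydrogen bonds in frame f and
#' `n_total` counts all hydrogen bonds the cosolvent forms in that frame
#' (with solute and water alike). A zero denominator yields chi = 0 with a
#' warning; chi is monotone nondecreasing in `n23` at fixed normalization.
#'
#' @param n23 per-frame solute-cosolvent hydrogen-bond counts.
#' @param n_total per-frame total cosolvent hydrogen-bond counts (same
#'   length); must be >= `n23` frame-wise.
#' @return an object of class `kb_chi` with fields `chi` (percent),
#'   `n23_mean`, `n_total_mean`.
#' @export
chi_parameter <- function(n23, n_total) {
  if (length(n23) != length(n_total) || !length(n23)) {
    stop("`n23` and `n_total` must be non-empty and of equal length",
         call. = FALSE)
  }
  if (any(n23 < 0) || any(n_total < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  tot <- sum(n_total)
  if (tot == 0) {
    warning("total hydrogen-bond count is zero; chi defined as 0",
            call. = FALSE)
    chi <- 0
  } else {
    chi <- 100 * sum(n23) / tot
    if (chi > 100) {
      warning("solute-cosolvent bonds exceed the total count; chi capped at 100",
              call. = FALSE)
      chi <- 100
    }
  }
  structure(list(chi = chi, n23_mean = mean(n23),
                 n_total_mean = mean(n_total)),
            class = "kb_chi")
}

#' Fraction of hosts including a guest, averaged over frames
#'
#' Per frame, a cyclodextrin counts as "including" when at least one guest
#' centre of mass lies strictly closer than `crit$com_cutoff` to the CD
#' centre of mass (multiple guests in one cavity still count the CD once).
#' The per-frame counts are averaged over frames and normalised by the
#' number of CDs, times 100.
#'
#' @param traj a `kb_trajectory` (or a fixture from
#'   [gen_inclusion_fixture()], in which case groups default to the
#'   fixture's own).
#' @param cd_groups list of atom-index vectors, one per cyclodextrin.
#' @param guest_groups list of atom-index vectors, one per guest molecule.
#' @param crit an [inclusion_criterion()].
#' @return an object of class `kb_inclusion` with fields
#'   `percent_cds_including`, `per_frame_counts`, `n_cds`.
#' @export
inclusion_fraction <- function(traj, cd_groups = NULL, guest_groups = NULL,
                               crit = inclusion_criterion()) {
  if (inherits(traj, "kb_inclusion_fixture")) {
    fixture <- traj
    traj <- fixture$traj
    if (is.null(cd_groups)) cd_groups <- fixture$cd_groups
    if (is.null(guest_groups)) guest_groups <- fixture$guest_groups
  }
  stopifnot(inherits(traj, "kb_trajectory"))
  if (!length(cd_groups)) stop("need at least one CD group", call. = FALSE)
  n_cds <- length(cd_groups)
  counts <- vapply(traj$frames, function(cfg) {
    if (!length(guest_groups)) return(0L)
    cd_com <- t(vapply(cd_groups, function(g) group_com(cfg, g), numeric(3)))
    guest_com <- t(vapply(guest_groups, function(g) group_com(cfg, g),
                          numeric(3)))
    d <- pair_distances(cd_com, guest_com, cfg$box)
    sum(apply(d, 1L, function(row) any(row < crit$com_cutoff)))
  }, integer(1))
  structure(
    list(percent_cds_including = mean(counts) / n_cds * 100,
         per_frame_counts = counts, n_cds = n_cds),
    class = "kb_inclusion"
  )
}

# Build a one-point-per-group centre-of-mass pseudo-trajectory alongside a
# set of atoms kept as-is, for COM-based RDFs. Returns a kb_trajectory whose
# species are "ATOM" (kept atoms, in order) then "COM" (group centres).
com_pseudo_trajectory <- function(traj, keep_atoms, com_groups) {
  frames <- lapply(traj$frames, function(cfg) {
    atoms <- cfg$positions[keep_atoms, , drop = FALSE]
    coms <- t(vapply(com_groups, function(g) group_com(cfg, g), numeric(3)))
    kb_config(rbind(atoms, coms), cfg$box,
              species = rep(c("ATOM", "COM"),
                            c(length(keep_atoms), length(com_groups))))
  })
  kb_trajectory(frames, traj$times)
}

#' Rim-orientation analysis via RDF maxima
#'
#' Computes the RDFs of the primary- and secondary-rim atoms around the
#' centres of mass of the target molecules (e.g. amino acids) and returns
#' the maximum g value of each with its location; a larger secondary-rim
#' maximum indicates that the host presents its secondary rim to the target.
#'
#' @param traj a `kb_trajectory`.
#' @param primary_rim,secondary_rim disjoint, non-empty atom selections.
#' @param target_groups list of atom-index vectors whose mass-weighted
#'   centres of mass are the RDF reference points.
#' @param dr,r_max RDF binning, nm (see [compute_rdf()]).
#' @return list with elements `primary` and `secondary`, each
#'   `list(max_g, r_at_max, rdf)`.
#' @export
rim_orientation_rdf_max <- function(traj, primary_rim, secondary_rim,
                                    target_groups, dr, r_max) {
  idx_p <- select_atoms(traj, primary_rim)
  idx_s <- select_atoms(traj, secondary_rim)
  if (length(intersect(idx_p, idx_s))) {
    stop("primary and secondary rim selections must be disjoint",
         call. = FALSE)
  }
  if (!length(target_groups)) stop("no target groups", call. = FALSE)
  one_rim <- function(idx_rim) {
    pseudo <- com_pseudo_trajectory(traj, idx_rim, target_groups)
    rdf <- compute_rdf(pseudo, "COM", "ATOM", dr, r_max)
    i_max <- which.max(rdf$g)
    list(max_g = rdf$g[i_max], r_at_max = rdf$r[i_max], rdf = rdf)
  }
  list(primary = one_rim(idx_p), secondary = one_rim(idx_s))
}

#' Backbone-vs-side-chain orientation via RDF maxima
#'
#' Computes the RDFs of backbone and side-chain atoms around the centre of
#' mass of the host's secondary rim and returns the maximum of each. An
#' empty side-chain selection (glycine) yields a result flagged absent
#' rather than zero.
#'
#' @param traj a `kb_trajectory`.
#' @param backbone_sel atom selection for the backbone.
#' @param sidechain_sel atom selection for the side chain; may be `NULL` or
#'   empty (glycine).
#' @param rim_group atom-index vector whose centre of mass is the secondary
#'   rim reference point.
#' @param dr,r_max RDF binning, nm.
#' @return list with elements `backbone` and `sidechain`
#'   (`list(max_g, r_at_max, rdf)`; `sidechain` is
#'   `list(absent = TRUE)` when the selection is empty).
#' @export
backbone_sidechain_rdf_max <- function(traj, backbone_sel, sidechain_sel,
                                       rim_group, dr, r_max) {
  idx_bb <- select_atoms(traj, backbone_sel)
  one <- function(idx) {
    pseudo <- com_pseudo_trajectory(traj, idx, list(rim_group))
    rdf <- compute_rdf(pseudo, "COM", "ATOM", dr, r_max)
    i_max <- which.max(rdf$g)
    list(max_g = rdf$g[i_max], r_at_max = rdf$r[i_max], rdf = rdf)
  }
  sc <- if (is.null(sidechain_sel) ||
            (is.numeric(sidechain_sel) && length(sidechain_sel) == 0L)) {
    list(absent = TRUE)
  } else {
    one(select_atoms(traj, sidechain_sel))
  }
  list(backbone = one(idx_bb), sidechain = sc)
}
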