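# Kirkwood-Buff inversion of binary-solution thermodynamics, and the
# activity-coefficient derivative predicted from KBIs.
#
# Components: water (1) and cosolvent (3), matching the ternary labelling
# used elsewhere in the package (an amino acid or peptide would be 2). All
# algebra is done in SI units; the user-facing convention is mol/L for
# densities, cm^3/mol for partial molar volumes and KBIs, 1/Pa for the
# compressibility and J/mol for the chemical-potential derivative.
#
# The inversion route, per composition point:
#   D   = (x3 / RT) (dmu3/dx3)_{p,T}          (dimensionless)
#   eta = rho / D
#   G13 = RT betaT - rho V1 V3 / D
#   G33 = G13 + (eta V1 - 1) / rho3
#   G11 = G13 + (eta V3 - 1) / rho1
# and the activity-coefficient derivative predicted back from the KBIs:
#   f33 = (d ln f3 / d ln x3)_{p,T}
#       = -rho1 x3 Delta / (1 + rho1 x3 Delta),  Delta = G11 + G33 - 2 G13.
# These are the exact Kirkwood-Buff fluctuation relations for a binary
# mixture; the two routes close on each other identically.

#' Construct a binary thermodynamic state
#'
#' One composition point of a water(1)-cosolvent(3) mixture. `rho1`/`rho3`
#' default to `rho * x1` / `rho * x3` and are checked for consistency if
#' given.
#'
#' @param x3 cosolvent mole fraction, in (0, 1).
#' @param rho total molar density, mol/L.
#' @param V1,V3 partial molar volumes, cm^3/mol.
#' @param betaT isothermal compressibility, 1/Pa.
#' @param dmu3_dx3 (dmu3/dx3)_{p,T}, J/mol.
#' @param temperature temperature, K.
#' @param rho1,rho3 optional species molar densities, mol/L.
#' @param f3,f3m optional mole-fraction / molal-scale activity coefficients.
#' @param p pressure, Pa (metadata only).
#' @return an object of class `kb_thermo_state`.
#' @export
thermo_state <- function(x3, rho, V1, V3, betaT, dmu3_dx3,
                         temperature = 298, rho1 = NULL, rho3 = NULL,
                         f3 = NA_real_, f3m = NA_real_, p = 101325) {
  if (!is.finite(x3) || x3 <= 0 || x3 >= 1) {
    stop("`x3` must lie in (0, 1)", call. = FALSE)
  }
  stop_if_not_scalar_positive(rho, "rho")
  stop_if_not_scalar_positive(V1, "V1")
  stop_if_not_scalar_positive(V3, "V3")
  stop_if_not_scalar_positive(betaT, "betaT")
  stop_if_not_scalar_positive(temperature, "temperature")
  if (!is.finite(dmu3_dx3)) stop("`dmu3_dx3` must be finite", call. = FALSE)
  x1 <- 1 - x3
  if (is.null(rho1)) rho1 <- rho * x1
  if (is.null(rho3)) rho3 <- rho * x3
  if (abs(rho1 - rho * x1) > 1e-6 * rho || abs(rho3 - rho * x3) > 1e-6 * rho) {
    stop("rho1/rho3 inconsistent with rho and the mole fractions",
         call. = FALSE)
  }
  structure(
    list(x1 = x1, x3 = x3, rho = rho, rho1 = rho1, rho3 = rho3,
         V1 = V1, V3 = V3, betaT = betaT, dmu3_dx3 = dmu3_dx3,
         temperature = temperature, f3 = f3, f3m = f3m, p = p),
    class = "kb_thermo_state"
  )
}

# Accept a kb_thermo_state or one row of a kb_thermo_dataset.
as_thermo_state <- function(state) {
  if (inherits(state, "kb_thermo_state")) return(state)
  if (is.data.frame(state)) {
    if (nrow(state) != 1L) {
      stop("pass a single row (use invert_thermo_to_kbi on a dataset for all rows)",
           call. = FALSE)
    }
    return(thermo_state(
      x3 = state$x3, rho = state$rho, V1 = state$V1, V3 = state$V3,
      betaT = state$betaT, dmu3_dx3 = state$dmu3_dx3,
      temperature = if ("T" %in% names(state)) state$T else 298,
      f3 = if ("f3" %in% names(state)) state$f3 else NA_real_,
      f3m = if ("f3m" %in% names(state)) state$f3m else NA_real_))
  }
  stop("`state` must be a kb_thermo_state or a one-row data.frame",
       call. = FALSE)
}

#' Convert a molal-scale activity coefficient to the mole-fraction scale
#'
#' Uses the dilute-solution relation `f3m = x3 * f3`, i.e. `f3 = f3m / x3`.
#'
#' @param f3m molal-scale activity coefficient(s), > 0.
#' @param x3 mole fraction(s) in (0, 1).
#' @return mole-fraction-scale activity coefficient(s) `f3`.
#' @export
molal_to_molefraction_activity <- function(f3m, x3) {
  if (any(!is.finite(f3m)) || any(f3m <= 0)) {
    stop("`f3m` must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(x3)) || any(x3 <= 0) || any(x3 >= 1)) {
    stop("`x3` must lie in (0, 1)", call. = FALSE)
  }
  f3m / x3
}

#' Chemical-potential derivative from an activity-coefficient curve
#'
#' Differentiates `ln f3` with respect to `x3` by a cubic smoothing spline
#' (generalized cross-validation by default; an interpolating spline is used
#' when fewer than 4 points are supplied) and assembles
#' \deqn{(\partial\mu_3/\partial x_3)_{p,T} =
#'   RT\,[(\partial \ln f_3/\partial x_3) + 1/x_3].}
#'
#' @param f3_curve data.frame with columns `x3` (strictly increasing, >= 3
#'   points) and `f3` (> 0).
#' @param temperature temperature, K.
#' @param spar optional smoothing parameter passed to
#'   [stats::smooth.spline()]; `NULL` selects it by GCV.
#' @return data.frame with columns `x3`, `dlnf3_dx3`, `dmu3_dx3` (J/mol);
#'   the differentiation method is recorded in `attr(, "method")`.
#' @export
chem_potential_derivative <- function(f3_curve, temperature = 298,
                                      spar = NULL) {
  if (!is.data.frame(f3_curve) || !all(c("x3", "f3") %in% names(f3_curve))) {
    stop("`f3_curve` needs columns x3 and f3", call. = FALSE)
  }
  x <- f3_curve$x3
  y <- f3_curve$f3
  if (length(x) < 3L) stop("need at least 3 composition points",
                           call. = FALSE)
  if (anyDuplicated(x) || is.unsorted(x, strictly = TRUE)) {
    stop("`x3` must be strictly increasing (no duplicates)", call. = FALSE)
  }
  if (any(y <= 0)) stop("`f3` must be positive", call. = FALSE)
  lny <- log(y)
  if (length(x) >= 4L) {
    fit <- if (is.null(spar)) {
      stats::smooth.spline(x, lny, cv = FALSE, all.knots = TRUE)
    } else {
      stats::smooth.spline(x, lny, spar = spar, all.knots = TRUE)
    }
    dln <- stats::predict(fit, x, deriv = 1L)$y
    method <- "smoothing spline (GCV)"
  } else {
    sf <- stats::splinefun(x, lny, method = "natural")
    dln <- sf(x, deriv = 1L)
    method <- "natural interpolating spline"
  }
  out <- data.frame(
    x3 = x, dlnf3_dx3 = dln,
    dmu3_dx3 = R_GAS * temperature * (dln + 1 / x)
  )
  attr(out, "method") <- method
  out
}

#' Invert binary-solution thermodynamics to Kirkwood-Buff integrals
#'
#' Computes the intermediates `D = (x3/RT) dmu3/dx3` and `eta = rho / D`
#' and then the three independent binary KBIs (see the file header for the
#' route). Accepts a single state or a whole `kb_thermo_dataset`.
#'
#' @param state a [thermo_state()], a one-row data.frame, or a
#'   `kb_thermo_dataset` (all rows inverted).
#' @return for a single state, an object of class `kb_kbi_triple` (fields
#'   `G11`, `G13`, `G33` in cm^3/mol, plus `intermediates`); for a dataset,
#'   a data.frame with columns `x3`, `G11`, `G13`, `G33`.
#' @export
invert_thermo_to_kbi <- function(state) {
  if (is.data.frame(state) && nrow(state) > 1L) {
    rows <- lapply(seq_len(nrow(state)), function(i) {
      tri <- invert_thermo_to_kbi(state[i, , drop = FALSE])
      data.frame(x3 = state$x3[i], G11 = tri$G11, G13 = tri$G13,
                 G33 = tri$G33)
    })
    return(do.call(rbind, rows))
  }
  st <- as_thermo_state(state)
  rt <- R_GAS * st$temperature
  rho <- st$rho * 1e3      # mol/m^3
  rho1 <- st$rho1 * 1e3
  rho3 <- st$rho3 * 1e3
  v1 <- st$V1 * 1e-6       # m^3/mol
  v3 <- st$V3 * 1e-6
  dd <- st$x3 * st$dmu3_dx3 / rt
  if (!is.finite(dd) || abs(dd) < 1e-14) {
    stop("intermediate D = (x3/RT) dmu3/dx3 vanishes; cannot invert",
         call. = FALSE)
  }
  eta <- rho / dd
  g13 <- rt * st$betaT - rho * v1 * v3 / dd
  g33 <- g13 + (eta * v1 - 1) / rho3
  g11 <- g13 + (eta * v3 - 1) / rho1
  structure(
    list(G11 = g11 * 1e6, G13 = g13 * 1e6, G33 = g33 * 1e6,
         units = "cm3/mol",
         intermediates = list(D = dd, eta = eta / 1e3,
                              eta_units = "mol/L")),
    class = "kb_kbi_triple"
  )
}

#' @export
print.kb_kbi_triple <- function(x, ...) {
  cat(sprintf("KBI triple (cm^3/mol): G11 = %.4g, G13 = %.4g, G33 = %.4g\n",
              x$G11, x$G13, x$G33))
  invisible(x)
}

#' Activity-coefficient derivative predicted from Kirkwood-Buff integrals
#'
#' Evaluates
#' \deqn{f_{33} = (\partial \ln f_3/\partial \ln x_3)_{p,T} =
#'   \frac{-\rho_1 x_3 \Delta}{1 + \rho_1 x_3 \Delta}, \quad
#'   \Delta = G_{11} + G_{33} - 2 G_{13}.}
#' Ideal-solution KBIs (Delta = 0) give f33 = 0.
#'
#' @param kbi a `kb_kbi_triple` or a numeric `c(G11, G13, G33)` in cm^3/mol.
#' @param state the [thermo_state()] (or one-row data.frame) supplying the
#'   composition; must match the composition the KBIs refer to.
#' @return a list of class `kb_f33` with fields `f33` and `x3`.
#' @export
f33_from_kbi <- function(kbi, state) {
  st <- as_thermo_state(state)
  if (inherits(kbi, "kb_kbi_triple")) {
    g <- c(kbi$G11, kbi$G13, kbi$G33)
  } else {
    g <- as.numeric(kbi)
    if (length(g) != 3L) stop("`kbi` must supply c(G11, G13, G33)",
                              call. = FALSE)
  }
  delta <- (g[1L] + g[3L] - 2 * g[2L]) * 1e-6   # m^3/mol
  rho1 <- st$rho1 * 1e3
  q <- rho1 * st$x3 * delta
  if (abs(1 + q) < 1e-14) {
    stop("denominator 1 + rho1 x3 Delta vanishes", call. = FALSE)
  }
  structure(list(f33 = -q / (1 + q), x3 = st$x3), class = "kb_f33")
}

#' Root-mean-square error between a simulated and an experimental curve
#'
#' The simulated curve is linearly interpolated onto the experimental
#' compositions; points outside the simulated range are dropped.
#'
#' @param sim data.frame with columns `x3` and `value` (simulation).
#' @param exp data.frame with columns `x3` and `value` (experiment).
#' @return RMSE over the shared compositions (scalar).
#' @export
compare_curves <- function(sim, exp) {
  for (nm in list(sim, exp)) {
    if (!is.data.frame(nm) || !all(c("x3", "value") %in% names(nm))) {
      stop("curves need columns x3 and value", call. = FALSE)
    }
  }
  interp <- stats::approx(sim$x3, sim$value, xout = exp$x3, rule = 1)$y
  keep <- !is.na(interp)
  if (!any(keep)) {
    stop("no overlap between simulated and experimental compositions",
         call. = FALSE)
  }
  sqrt(mean((interp[keep] - exp$value[keep])^2))
}
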