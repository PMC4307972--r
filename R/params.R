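#' Interaction parameters of the clustering model
#'
#' Bundles the three energy scales of the membrane clustering model, all
#' expressed in units of \eqn{k_B T} (room temperature is absorbed into this
#' convention): the binding energy of one protein to the membrane, the
#' short-range nearest-neighbour attraction per bond within a cluster, and the
#' long-range pairwise repulsion acting between every pair of proteins in a
#' cluster.
#'
#' @param eps_b Binding energy per protein (\eqn{k_B T}; positive favours
#'   membrane binding).
#' @param eps_nn Nearest-neighbour attraction per bond (\eqn{k_B T}).
#' @param e_r Repulsion strength per protein pair (\eqn{k_B T}).  The
#'   adsorption series converges for every bulk concentration iff `e_r > 0`.
#' @return An object of class `"interaction_params"`.
#' @examples
#' interaction_params(eps_b = 2, eps_nn = 1, e_r = 0.5)
#' @export
interaction_params <- function(eps_b = 0, eps_nn = 0, e_r = 1) {
  for (v in list(eps_b, eps_nn, e_r)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop_domain("interaction parameters must be finite scalars")
    }
  }
  structure(list(eps_b = eps_b, eps_nn = eps_nn, e_r = e_r),
            class = "interaction_params")
}

#' @export
print.interaction_params <- function(x, ...) {
  cat(sprintf(
    "Interaction parameters (kB*T): eps_b = %g, eps_nn = %g, e_r = %g\n",
    x$eps_b, x$eps_nn, x$e_r))
  invisible(x)
}

#' Radius- or range-dependent repulsion laws
#'
#' Constructs one of the four repulsion laws used throughout the package.
#' `"constant"` is a radius-independent strength `c1`.  `"curvature"` is the
#' linear-in-curvature expansion `e_r(r) = c1 - c2 / r` (its zero crossing at
#' `r = c2/c1` is the divergence radius below which the adsorption series
#' diverges).  `"tension"` is the linear-in-tension form `e_r(r) = c1 + c2 * r`
#' (the tension of an osmotically pressurised spherical vesicle scales as its
#' radius, so the tension-proportionality constant is absorbed into `c2`).
#' `"step"` is the finite-interaction-range law in which cluster repulsive
#' energy grows quadratically up to `k_max` proteins and linearly beyond; it
#' has no radius dependence and is evaluated through [repulsion_energy()].
#'
#' @param kind One of `"constant"`, `"curvature"`, `"tension"`, `"step"`.
#' @param c1 Offset (\eqn{k_B T}).
#' @param c2 Slope; units \eqn{k_B T \mu m} for the curvature law and
#'   \eqn{k_B T \mu m^{-1}} for the tension law.
#' @param e_r0 Base pairwise strength for the step law (\eqn{k_B T}).
#' @param k_max Interaction-range cutoff in proteins (step law only,
#'   integer \eqn{\ge 1}).
#' @return An object of class `"repulsion_law"`.
#' @examples
#' repulsion_law("curvature", c1 = 2.67, c2 = 1.1649)
#' repulsion_law("tension", c1 = 0.7, c2 = 0.61)
#' repulsion_law("step", e_r0 = 0.2, k_max = 10)
#' @export
repulsion_law <- function(kind = c("constant", "curvature", "tension", "step"),
                          c1 = NULL, c2 = NULL, e_r0 = NULL, k_max = NULL) {
  kind <- match.arg(kind)
  if (kind == "step") {
    if (is.null(e_r0)) stop_domain("step law requires e_r0")
    if (is.null(k_max) || k_max < 1 || k_max != round(k_max)) {
      stop_domain("step law requires integer k_max >= 1")
    }
    law <- list(kind = kind, e_r0 = e_r0, k_max = as.integer(k_max))
  } else {
    if (is.null(c1)) stop_domain(sprintf("%s law requires c1", kind))
    if (kind != "constant" && is.null(c2)) {
      stop_domain(sprintf("%s law requires c2", kind))
    }
    law <- list(kind = kind, c1 = c1, c2 = if (kind == "constant") 0 else c2)
  }
  structure(law, class = "repulsion_law")
}

#' @export
print.repulsion_law <- function(x, ...) {
  desc <- switch(x$kind,
    constant  = sprintf("e_r = %g", x$c1),
    curvature = sprintf("e_r(r) = %g - %g / r", x$c1, x$c2),
    tension   = sprintf("e_r(r) = %g + %g * r", x$c1, x$c2),
    step      = sprintf("step repulsion, e_r0 = %g, k_max = %d",
                        x$e_r0, x$k_max))
  cat("Repulsion law [", x$kind, "]: ", desc, "\n", sep = "")
  invisible(x)
}

#' Evaluate a repulsion law at a vesicle radius
#'
#' Returns the pairwise repulsion strength \eqn{e_r} (in \eqn{k_B T}) at
#' radius `r` (in micrometres).  The curvature law may legitimately return
#' zero or negative values at small radii; downstream series evaluations then
#' raise a divergence error rather than clipping, because that divergence is
#' itself the physically telling diagnostic of the curvature law.
#'
#' @param r Vesicle radius in micrometres; must be positive.  Vectorised.
#' @param law A [repulsion_law()] of kind constant, curvature, or tension.
#' @return Numeric vector of repulsion strengths (\eqn{k_B T}).
#' @examples
#' e_r_of_radius(0.75, repulsion_law("curvature", c1 = 2.67, c2 = 1.1649))
#' @export
e_r_of_radius <- function(r, law) {
  stopifnot(inherits(law, "repulsion_law"))
  if (law$kind == "step") {
    stop_unsupported("step law has no radius dependence; use repulsion_energy()")
  }
  if (!is.numeric(r) || any(!is.finite(r)) || any(r <= 0)) {
    stop_domain("radius must be positive and finite")
  }
  switch(law$kind,
         constant  = rep_len(law$c1, length(r)),
         curvature = law$c1 - law$c2 / r,
         tension   = law$c1 + law$c2 * r)
}

#' Repulsive energy of a cluster of k proteins
#'
#' For the infinite-range (default) form every pair in a cluster repels with
#' strength \eqn{e_r}, giving energy \eqn{e_r k(k-1)/2}.  For the step law the
#' interaction has finite range: energy grows quadratically,
#' \eqn{e_{r0} k(k-1)/2}, up to `k_max` proteins, and linearly,
#' \eqn{e_{r0}[k_{max}(k_{max}-1) + (k-k_{max})(k_{max}-1)]/2}, beyond.  The
#' two branches agree at `k = k_max`.
#'
#' @param k Cluster size(s); positive integer(s).
#' @param law Either a scalar repulsion strength \eqn{e_r} (\eqn{k_B T}) or a
#'   [repulsion_law()] of kind `"step"` or `"constant"`.
#' @return Repulsive energy in \eqn{k_B T} (vectorised over `k`).
#' @examples
#' repulsion_energy(6, repulsion_law("step", e_r0 = 0.2, k_max = 4))
#' @export
repulsion_energy <- function(k, law) {
  if (!is.numeric(k) || any(!is.finite(k)) || any(k < 1) ||
      any(k != round(k))) {
    stop_domain("cluster size k must be an integer >= 1")
  }
  if (is.numeric(law) && length(law) == 1L) {
    return(law * k * (k - 1) / 2)
  }
  stopifnot(inherits(law, "repulsion_law"))
  if (law$kind == "constant") {
    return(law$c1 * k * (k - 1) / 2)
  }
  if (law$kind != "step") {
    stop_unsupported(
      "radius-dependent laws must be evaluated with e_r_of_radius() first")
  }
  km <- law$k_max
  e <- ifelse(k <= km,
              k * (k - 1),
              km * (km - 1) + (k - km) * (km - 1))
  law$e_r0 * e / 2
}

#' Lattice geometry of a spherical vesicle surface
#'
#' The vesicle surface is treated as a lattice of `L_v` binding sites with
#' `L_v = round(4 r^2 / a^2)` where `r` is the vesicle radius and `a` an
#' effective protein footprint length.  Note the convention deliberately
#' carries no factor of \eqn{\pi}: it is an order-of-magnitude site count, and
#' only enters through the dilute-limit normalisation.
#'
#' @param r Vesicle radius in micrometres (> 0).
#' @param a Effective protein footprint length in nanometres (> 0),
#'   default 4 nm (the length of the SpoVM amphipathic helix).
#' @return An object of class `"membrane_geometry"` with fields `r`, `a`, and
#'   the site count `L_v`.
#' @examples
#' membrane_geometry(r = 1, a = 4)
#' @export
membrane_geometry <- function(r, a = 4) {
  if (!is.numeric(r) || r <= 0 || !is.numeric(a) || a <= 0) {
    stop_domain("radius and footprint must be positive")
  }
  r_nm <- r * 1e3
  L_v <- max(1, round(4 * r_nm^2 / a^2))
  structure(list(r = r, a = a, L_v = L_v), class = "membrane_geometry")
}

#' Bath (solution) state and concentration normalisation
#'
#' Links the site-occupancy fraction of protein in solution,
#' `ns_star = n_s / L_s`, to the measured bulk concentration
#' `c_s = alpha * ns_star` and to the model's normalised concentration
#' `C_s = c_s / c_0` with reference scale
#' `c_0 = exp(-(eps_nn + eps_b)) * alpha`.  Equivalently
#' `C_s = ns_star * exp(eps_nn + eps_b)`.
#'
#' @param ns_star Site-occupancy fraction of protein in solution (>= 0).
#' @param params [interaction_params()] supplying `eps_b` and `eps_nn`.
#' @param alpha Concentration conversion constant (concentration units per
#'   unit occupancy), default 1.
#' @return An object of class `"bath_state"` with fields `ns_star`, `alpha`,
#'   `c_s`, `c_0`, `C_s`, and a logical `dilute` flag (`ns_star <= 0.1`).
#' @export
bath_state <- function(ns_star, params, alpha = 1) {
  stopifnot(inherits(params, "interaction_params"))
  if (!is.numeric(ns_star) || any(ns_star < 0)) {
    stop_domain("ns_star must be nonnegative")
  }
  c_0 <- exp(-(params$eps_nn + params$eps_b)) * alpha
  dilute <- all(ns_star <= 0.1)
  if (!dilute) {
    warning("ns_star > 0.1: dilute-limit formulas are unreliable",
            call. = FALSE)
  }
  structure(list(ns_star = ns_star, alpha = alpha,
                 c_s = alpha * ns_star, c_0 = c_0,
                 C_s = ns_star * exp(params$eps_nn + params$eps_b),
                 dilute = dilute),
            class = "bath_state")
}

#' Maximum gap between a straight rod and a sphere it touches
#'
#' For a rigid rod of length `l` tangent to a sphere of radius `R` at one
#' end, the far end sits a distance \eqn{\sqrt{R^2 + l^2} - R} above the
#' surface.  For a 4 nm amphipathic helix on a 0.5 micrometre-radius vesicle
#' this gap is only 0.016 nm (0.16 angstrom) -- the geometric argument that a
#' single protein cannot plausibly sense micron-scale curvature, motivating
#' cluster-based sensing.
#'
#' @param rod_length Rod length in nm (> 0).
#' @param sphere_radius Sphere radius in nm (> 0).
#' @return Gap in nm.
#' @examples
#' rod_sphere_gap(4, 500)      # 0.015999... nm
#' @export
rod_sphere_gap <- function(rod_length, sphere_radius) {
  if (!is.numeric(rod_length) || any(rod_length <= 0) ||
      !is.numeric(sphere_radius) || any(sphere_radius <= 0)) {
    stop_domain("rod length and sphere radius must be positive")
  }
  # sqrt(R^2 + l^2) - R, in a cancellation-safe form
  rod_length^2 / (sqrt(sphere_radius^2 + rod_length^2) + sphere_radius)
}

# -- condition helpers ---------------------------------------------------

stop_domain <- function(msg) {
  stop(structure(class = c("spovm_domain_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_divergence <- function(msg) {
  stop(structure(class = c("spovm_divergence_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_unsupported <- function(msg) {
  stop(structure(class = c("spovm_unsupported_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
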