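# Finite-range (step-function) repulsion and two-region curvature
# localization.  With a step repulsion the cluster energy grows only linearly
# beyond k_max proteins, so above a critical concentration the largest
# admissible cluster dominates -- a condensation ("giant cluster") transition
# that amplifies a tiny per-protein binding-energy difference into near-total
# localization.

#' Two membrane regions competing for one protein bath
#'
#' Region 1 is the higher-curvature region; helix insertion is slightly
#' easier there, giving it a per-protein binding-energy advantage `delta_b`
#' (in \eqn{k_B T}).  Both regions share the step repulsion
#' (`e_r0`, `k_max`) and a finite per-region site budget `K_cap` that caps
#' cluster size.  `delta_b` may be given directly, or as a relative fraction
#' `rel_delta` of an absolute binding energy `eps_b` (e.g. a 1 percent
#' advantage needs `eps_b` to be pinned down, since only the product enters).
#'
#' @param delta_b Binding-energy advantage of region 1 (\eqn{k_B T},
#'   `>= 0`).  Supply either this or both `eps_b` and `rel_delta`.
#' @param eps_b,rel_delta Alternative specification:
#'   `delta_b = eps_b * rel_delta`.
#' @param e_r0 Step-repulsion base strength (\eqn{k_B T}).
#' @param k_max Repulsion range cutoff in proteins (integer >= 1).
#' @param K_cap Maximum cluster size = per-region site budget
#'   (integer >= `k_max`); required because the linear-energy tail makes the
#'   untruncated series divergent at high concentration.
#' @param area_ratio Area of region 1 over area of region 2 (default 1,
#'   equal areas).
#' @return An object of class `"two_region_system"`.
#' @examples
#' two_region_system(eps_b = 2, rel_delta = 0.01, e_r0 = 0.2,
#'                   k_max = 10, K_cap = 1000)
#' @export
two_region_system <- function(delta_b = NULL, eps_b = NULL, rel_delta = NULL,
                              e_r0 = 0.2, k_max = 10L, K_cap = 1000L,
                              area_ratio = 1) {
  if (is.null(delta_b)) {
    if (is.null(eps_b) || is.null(rel_delta)) {
      stop_domain(
        "supply delta_b, or both eps_b and rel_delta (delta_b = eps_b * rel_delta)")
    }
    delta_b <- eps_b * rel_delta
  }
  if (delta_b < 0) stop_domain("delta_b must be >= 0 (region 1 is favoured)")
  if (k_max < 1 || k_max != round(k_max)) {
    stop_domain("k_max must be an integer >= 1")
  }
  if (!is.finite(K_cap) || K_cap < k_max || K_cap != round(K_cap)) {
    stop_domain("K_cap must be a finite integer >= k_max")
  }
  if (area_ratio <= 0) stop_domain("area_ratio must be positive")
  structure(list(delta_b = delta_b, e_r0 = e_r0,
                 k_max = as.integer(k_max), K_cap = as.integer(K_cap),
                 area_ratio = area_ratio),
            class = "two_region_system")
}

# log summands of the step-repulsion series, k = 1..K_cap
.step_log_weights <- function(C_s_eff, e_r0, k_max, K_cap) {
  k <- seq_len(K_cap)
  law <- repulsion_law("step", e_r0 = e_r0, k_max = k_max)
  log(k) - repulsion_energy(k, law) + k * log(C_s_eff)
}

#' Adsorption of one region under step (finite-range) repulsion
#'
#' Evaluates \eqn{C_v = \sum_{k=1}^{K_{cap}} k e^{-E_{rep}(k)} C_s^k} with
#' the piecewise (quadratic-then-linear) cluster repulsive energy of
#' [repulsion_energy()].  Because the energy grows only linearly in `k`
#' beyond `k_max`, the series must be truncated at the finite site budget
#' `K_cap`; when the `k = K_cap` term is the largest summand the region is in
#' the giant-cluster (condensation) regime and the result is reported with
#' `giant = TRUE`.
#'
#' @param C_s_eff Effective normalised bulk concentration seen by the region
#'   (>= 0); a binding-energy advantage `delta_b` enters as
#'   `C_s * exp(delta_b)`.
#' @param e_r0 Step-repulsion base strength (\eqn{k_B T}).
#' @param k_max Interaction-range cutoff (proteins).
#' @param K_cap Maximum cluster size (finite integer; required).
#' @return A list with `C_v`, `log_C_v` (always finite even when `C_v`
#'   overflows), `mean_size` (number-weighted), `dominant_size`, and the
#'   logical `giant`.
#' @examples
#' region_adsorption_step(2, e_r0 = 0.2, k_max = 5, K_cap = 200)
#' @export
region_adsorption_step <- function(C_s_eff, e_r0, k_max, K_cap) {
  if (missing(K_cap) || is.null(K_cap) || !is.finite(K_cap)) {
    stop_domain("K_cap must be finite: the linear-tail series needs a site budget")
  }
  if (!is.numeric(C_s_eff) || C_s_eff < 0) stop_domain("C_s_eff must be >= 0")
  if (C_s_eff == 0) {
    return(list(C_v = 0, log_C_v = -Inf, mean_size = 1,
                dominant_size = 1L, giant = FALSE))
  }
  lw <- .step_log_weights(C_s_eff, e_r0, k_max, K_cap)
  k <- seq_along(lw)
  lse <- logsumexp(lw)
  k_star <- which.max(lw)
  list(C_v = exp(lse),
       log_C_v = lse,
       mean_size = exp(lse - logsumexp(lw - log(k))),
       dominant_size = as.integer(k_star),
       giant = k_star == K_cap)
}

#' Fraction of adsorbed protein in the high-curvature region
#'
#' Both regions see the same bath at normalised concentration `C_s`; region 1
#' is evaluated at the effective concentration `C_s * exp(delta_b)` (the
#' per-protein binding advantage multiplies the size-`k` summand by
#' `exp(k * delta_b)`).  The localization fraction is
#' \eqn{A_1 C_{v,1} / (A_1 C_{v,1} + A_2 C_{v,2})}, computed from log-scale
#' adsorptions so that the giant-cluster regime (astronomically large
#' summands) is handled exactly.  It equals 1/2 iff `delta_b = 0` (for equal
#' areas) and exceeds 1/2 whenever `delta_b > 0`, because every region-1
#' summand beats its region-2 counterpart by `exp(k * delta_b) > 1`.
#'
#' @param C_s Normalised bulk concentration (> 0 for a defined fraction).
#' @param system A [two_region_system()].
#' @return The fraction in (0, 1).
#' @examples
#' sys <- two_region_system(delta_b = 0.1, e_r0 = 0.2, k_max = 10,
#'                          K_cap = 500)
#' localization_fraction(1e-6, sys)    # ~ exp(0.1)/(1 + exp(0.1))
#' @export
localization_fraction <- function(C_s, system) {
  stopifnot(inherits(system, "two_region_system"))
  if (!is.numeric(C_s) || C_s < 0) stop_domain("C_s must be >= 0")
  if (C_s == 0) {
    stop_domain("total adsorption is zero at C_s = 0; fraction undefined")
  }
  r1 <- region_adsorption_step(C_s * exp(system$delta_b),
                               system$e_r0, system$k_max, system$K_cap)
  r2 <- region_adsorption_step(C_s, system$e_r0, system$k_max, system$K_cap)
  # fraction = sigmoid(log(A1 Cv1) - log(A2 Cv2))
  stats::plogis(log(system$area_ratio) + r1$log_C_v - r2$log_C_v)
}

#' Localization curve over a concentration grid
#'
#' Sweeps the bath concentration and tabulates, per grid point, the
#' normalised adsorption of each region, the (area-weighted) total
#' adsorption, the localization fraction, and the mean cluster size in each
#' region.  Because clusters in region 1 are uniformly favoured, its mean
#' cluster size is at least that of region 2 at every concentration.
#'
#' @param system A [two_region_system()].
#' @param Cs_grid Positive, strictly increasing concentration grid.
#' @return A data frame of class `"localization_curve"` with columns
#'   `C_s`, `adsorption_1`, `adsorption_2`, `total_adsorption`, `fraction_1`,
#'   `mean_size_1`, `mean_size_2`, plus logical columns `giant_1`, `giant_2`
#'   flagging the giant-cluster regime (the seven model columns are what
#'   [write_localization_curve()] emits).
#' @examples
#' sys <- two_region_system(delta_b = 0.02, e_r0 = 0.2, k_max = 10,
#'                          K_cap = 200)
#' head(localization_curve(sys, c(0.5, 1, 2)))
#' @export
localization_curve <- function(system, Cs_grid) {
  stopifnot(inherits(system, "two_region_system"))
  if (any(Cs_grid <= 0) || is.unsorted(Cs_grid, strictly = TRUE)) {
    stop_domain("Cs_grid must be positive and strictly increasing")
  }
  A1 <- system$area_ratio
  rows <- lapply(Cs_grid, function(cs) {
    r1 <- region_adsorption_step(cs * exp(system$delta_b),
                                 system$e_r0, system$k_max, system$K_cap)
    r2 <- region_adsorption_step(cs, system$e_r0, system$k_max, system$K_cap)
    data.frame(
      C_s = cs,
      adsorption_1 = r1$C_v,
      adsorption_2 = r2$C_v,
      total_adsorption = (A1 * r1$C_v + r2$C_v) / (A1 + 1),
      fraction_1 = stats::plogis(log(A1) + r1$log_C_v - r2$log_C_v),
      mean_size_1 = r1$mean_size,
      mean_size_2 = r2$mean_size,
      giant_1 = r1$giant,
      giant_2 = r2$giant)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("localization_curve", "data.frame")
  out
}

#' Adsorption under fixed-stoichiometry clustering
#'
#' Alternative clustering scenario: monomers in equilibrium with clusters of
#' one fixed size `q` (e.g. trimers), with formation constant `K_q`, giving
#' \eqn{C_v = C_s + q K_q C_s^q}.  At low concentration this is linear in
#' `C_s` just like the open-size-distribution model; the two differ in the
#' sharpness and order of the cooperative rise.
#'
#' @param C_s Normalised bulk concentration (>= 0, vectorised).
#' @param q Fixed cluster size (integer >= 2).
#' @param K_q Cluster formation constant (>= 0).
#' @return Normalised adsorption.
#' @examples
#' stoichiometric_adsorption(0.5, q = 3, K_q = 1)   # 0.875
#' @export
stoichiometric_adsorption <- function(C_s, q, K_q) {
  if (q < 2 || q != round(q)) stop_domain("q must be an integer >= 2")
  if (K_q < 0) stop_domain("K_q must be >= 0")
  if (any(C_s < 0)) stop_domain("C_s must be >= 0")
  C_s + q * K_q * C_s^q
}
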