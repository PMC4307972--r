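# Synthetic vesicle-adsorption datasets.  The in vitro measurements the
# model was built against are not publicly deposited, so the generator
# emulates their design: vesicle radii spanning 0.75-30 um, a bulk
# concentration sweep, positive intensity readouts with multiplicative
# noise, and amplitudes in arbitrary units.

#' Specification of a synthetic adsorption experiment
#'
#' Defaults reflect the emulated experimental design: radii from 0.75 to
#' 30 micrometres (including the 0.75, 1.75 and 3.25 um radii used for
#' reference isotherms), a tension-law repulsion with the wild-type
#' best-fit coefficients `c1 = 0.7`, `c2 = 0.61`, and 5 percent
#' multiplicative measurement noise.
#'
#' @param law A [repulsion_law()] (constant, curvature, or tension).
#' @param A Signal amplitude in adsorption units.
#' @param c_0 Concentration scale (measurement units per normalised unit).
#' @param radii Radius grid in micrometres.
#' @param concentrations Bulk-concentration grid in measurement units.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0; 0 gives the deterministic model surface).
#' @param replicates Replicate measurements per (radius, concentration) cell.
#' @param seed Integer RNG seed; identical seeds give identical datasets.
#' @return An object of class `"generator_spec"`.
#' @export
generator_spec <- function(law = repulsion_law("tension", c1 = 0.7,
                                               c2 = 0.61),
                           A = 1, c_0 = 1,
                           radii = c(0.75, 1, 1.75, 3.25, 7.5, 15, 30),
                           concentrations = seq(0.1, 2.5, length.out = 10),
                           noise_cv = 0.05, replicates = 1L, seed = 1L) {
  stopifnot(inherits(law, "repulsion_law"))
  if (noise_cv < 0) stop_domain("noise_cv must be >= 0")
  if (any(radii <= 0) || any(concentrations < 0)) {
    stop_domain("grids must be positive")
  }
  if (replicates < 1 || replicates != round(replicates)) {
    stop_domain("replicates must be a positive integer")
  }
  structure(list(law = law, A = A, c_0 = c_0, radii = radii,
                 concentrations = concentrations, noise_cv = noise_cv,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' Generate a synthetic adsorption dataset
#'
#' Evaluates the deterministic model surface
#' `A * C_v(c / c_0, e_r(r))` on the radius-by-concentration grid and
#' applies mean-one multiplicative lognormal noise:
#' `adsorption = surface * exp(eps)` with
#' `eps ~ Normal(-noise_cv^2 / 2, noise_cv)`, so replicate means converge to
#' the deterministic surface.  The `sigma` column carries the implied
#' per-point measurement scale `noise_cv * surface`.  Any grid point with a
#' divergent `(C_s, e_r)` combination aborts generation with a message
#' listing the offending points.
#'
#' @param spec A [generator_spec()].
#' @return A data frame with columns `radius_um`, `concentration`,
#'   `adsorption`, `sigma`, `label` (the law kind), one row per grid cell
#'   and replicate; fully reproducible from `spec$seed`.
#' @examples
#' d <- generate_dataset(generator_spec(noise_cv = 0, replicates = 1))
#' head(d)
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  grid <- expand.grid(radius_um = spec$radii,
                      concentration = spec$concentrations,
                      KEEP.OUT.ATTRS = FALSE)
  er <- e_r_of_radius(grid$radius_um, spec$law)
  Cs <- grid$concentration / spec$c_0
  bad <- er < 0 | (er == 0 & Cs >= 1)
  if (any(bad)) {
    pts <- unique(grid[bad, c("radius_um", "concentration")])
    stop_divergence(paste0(
      "divergent (C_s, e_r) at grid point(s): ",
      paste(sprintf("(r=%g, c=%g)", pts$radius_um, pts$concentration),
            collapse = ", ")))
  }
  surface <- spec$A *
    vapply(seq_len(nrow(grid)), function(i) adsorption(Cs[i], er[i]), 0)
  n_cells <- nrow(grid)
  out <- grid[rep(seq_len(n_cells), times = spec$replicates), , drop = FALSE]
  mu <- rep(surface, times = spec$replicates)
  noise <- if (spec$noise_cv > 0) {
    .with_seed(spec$seed,
               exp(stats::rnorm(nrow(out), -spec$noise_cv^2 / 2,
                                spec$noise_cv)))
  } else {
    rep(1, nrow(out))
  }
  out$adsorption <- mu * noise
  out$sigma <- spec$noise_cv * mu
  out$label <- spec$law$kind
  rownames(out) <- NULL
  out
}

#' Generate a localization configuration + expected-output bundle
#'
#' Produces, for a [two_region_system()] and a concentration grid, both the
#' serializable configuration block and the model-computed
#' [localization_curve()], optionally writing them to disk (JSON config,
#' CSV curve).  Intended as a regression fixture: re-running the
#' localization pipeline on the config must reproduce the bundled curve.
#'
#' @param system A [two_region_system()].
#' @param Cs_grid Positive increasing concentration grid.
#' @param dir Optional directory; when given, writes `localization_config.json`
#'   and `localization_curve.csv` there.
#' @return A list with `config` (plain list) and `curve` (data frame), plus
#'   `paths` when files were written.
#' @export
generate_localization_inputs <- function(system, Cs_grid, dir = NULL) {
  stopifnot(inherits(system, "two_region_system"))
  curve <- localization_curve(system, Cs_grid)
  config <- list(delta_b = system$delta_b, e_r0 = system$e_r0,
                 k_max = system$k_max, K_cap = system$K_cap,
                 area_ratio = system$area_ratio, Cs_grid = Cs_grid)
  out <- list(config = config, curve = curve)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    cfg_path <- file.path(dir, "localization_config.json")
    crv_path <- file.path(dir, "localization_curve.csv")
    jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA)
    write_localization_curve(curve, crv_path)
    out$paths <- c(config = cfg_path, curve = crv_path)
  }
  out
}
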