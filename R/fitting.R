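# Fitting the adsorption model with competing radius-dependent repulsion
# laws.  Both measurement axes are in arbitrary units, so an amplitude A
# (and, for concentration fits, a concentration scale c_0) are always free
# nuisance parameters.  A is linear in the model and is profiled out of the
# nonlinear search analytically.

# run expr with a local, restored RNG stream
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

.check_dataset <- function(data) {
  need <- c("radius_um", "concentration", "adsorption")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop_domain(paste0("dataset is missing column(s): ",
                       paste(miss, collapse = ", ")))
  }
  if (any(data$radius_um <= 0)) stop_domain("radii must be positive")
  if (any(data$adsorption < 0)) stop_domain("adsorption must be >= 0")
  data
}

.weights_from_sigma <- function(data) {
  if (!is.null(data$sigma) && all(is.finite(data$sigma)) &&
      all(data$sigma > 0)) 1 / data$sigma^2 else rep(1, nrow(data))
}

#' Predicted adsorption signal for one measurement
#'
#' Composes the adsorption series with a radius-dependent repulsion law and
#' the two nuisance scales:
#' `A * adsorption(concentration / c_0, e_r_of_radius(r, law))`.
#'
#' @param r Vesicle radius in micrometres.
#' @param concentration Bulk concentration in measurement units.
#' @param law A [repulsion_law()] (constant, curvature, or tension).
#' @param A Signal amplitude (adsorption units per normalised adsorption).
#' @param c_0 Concentration scale mapping measurement units to the
#'   normalised concentration.
#' @return Predicted adsorption signal (vectorised over `r` and
#'   `concentration` jointly).
#' @export
predict_adsorption <- function(r, concentration, law, A = 1, c_0 = 1) {
  er <- e_r_of_radius(r, law)
  n <- max(length(er), length(concentration))
  er <- rep_len(er, n)
  Cs <- rep_len(concentration / c_0, n)
  A * vapply(seq_len(n), function(i) adsorption(Cs[i], er[i]), 0)
}

# model C_v surface for a parameter proposal; returns NULL on any divergent
# (C_s, e_r) combination so callers can apply a penalty.  Points sharing an
# e_r value (one vesicle radius) are evaluated together: the summand matrix
# over k is built once per radius and reduced by a column sum, which keeps
# the optimizer's many objective evaluations cheap.
.cv_surface <- function(Cs, er, tol = 1e-12) {
  if (any(!is.finite(er)) || any(!is.finite(Cs)) || any(Cs < 0) ||
      any(er <= 0)) {
    return(NULL)
  }
  out <- numeric(length(Cs))
  for (e in unique(er)) {
    idx <- which(er == e)
    cs <- Cs[idx]
    pos <- cs > 0
    if (!any(pos)) next
    lcs_max <- log(max(cs[pos]))
    K <- max(16L, ceiling(2 * max(1, lcs_max / e)) + 16L)
    repeat {
      lratio <- log((K + 1) / K) - K * e + lcs_max
      if (lratio < 0) {
        lwK <- log(K) - 0.5 * K * (K - 1) * e + K * lcs_max
        # the k = 1 term lower-bounds the sum, so this is conservative
        if (lwK + lratio - log1p(-exp(lratio)) - lcs_max < log(tol)) break
      }
      # a proposal needing more than ~2e4 terms sits at the divergence
      # boundary (e_r effectively zero); reject it like a divergent one
      if (K > 2e4) return(NULL)
      K <- K * 2L
    }
    k <- seq_len(K)
    base <- log(k) - 0.5 * k * (k - 1) * e
    lw <- base + outer(k, log(cs[pos]))
    m <- apply(lw, 2, max)
    out[idx[pos]] <- exp(m) * colSums(exp(sweep(lw, 2, m)))
  }
  out
}

# weighted SSR with amplitude profiled out; log_space uses residuals of logs
.profiled_objective <- function(Cv, y, w, log_space) {
  if (is.null(Cv)) return(list(obj = 1e12, A = NA_real_))
  if (log_space) {
    ok <- Cv > 0 & y > 0
    if (!any(ok)) return(list(obj = 1e12, A = NA_real_))
    lA <- sum(w[ok] * (log(y[ok]) - log(Cv[ok]))) / sum(w[ok])
    list(obj = sum(w[ok] * (lA + log(Cv[ok]) - log(y[ok]))^2), A = exp(lA))
  } else {
    den <- sum(w * Cv^2)
    A <- if (den > 0) sum(w * y * Cv) / den else 0
    list(obj = sum(w * (A * Cv - y)^2), A = A)
  }
}

.penalized_er <- function(kind, theta, r) {
  law <- repulsion_law(kind, c1 = theta[1], c2 = theta[2])
  er <- switch(kind,
               constant  = rep_len(theta[1], length(r)),
               curvature = theta[1] - theta[2] / r,
               tension   = theta[1] + theta[2] * r)
  er
}

# multi-start + Nelder-Mead + BFGS polish over the reduced parameters
.optimize_reduced <- function(fn, lower, upper, n_starts, seed) {
  starts <- .with_seed(seed, {
    p <- length(lower)
    t(replicate(n_starts, stats::runif(p, lower, upper)))
  })
  if (is.null(dim(starts))) starts <- matrix(starts, ncol = length(lower))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(starts[i, ], fn, method = "Nelder-Mead",
                   control = list(reltol = 1e-12, maxit = 2000L)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) stop("all optimization starts failed", call. = FALSE)
  for (nd in c(1e-5, 1e-7)) {
    polish <- tryCatch(
      stats::optim(best$par, fn, method = "BFGS",
                   control = list(reltol = 1e-15, maxit = 1000L,
                                  ndeps = rep(nd, length(best$par)))),
      error = function(e) NULL)
    if (!is.null(polish) && polish$value <= best$value) best <- polish
  }
  best
}

# numerical Jacobian of a residual vector function
.num_jacobian <- function(resfn, par, eps = 1e-6) {
  r0 <- resfn(par)
  J <- matrix(0, length(r0), length(par))
  for (j in seq_along(par)) {
    h <- eps * max(1, abs(par[j]))
    pp <- par; pp[j] <- pp[j] + h
    pm <- par; pm[j] <- pm[j] - h
    J[, j] <- (resfn(pp) - resfn(pm)) / (2 * h)
  }
  J
}

.fit_result <- function(kind, theta, A, c_0, Cs, objective, cov, converged,
                        warnings, n) {
  law <- repulsion_law(kind, c1 = theta[1],
                       c2 = if (kind == "constant") NULL else theta[2])
  structure(list(
    kind = kind, law = law,
    c1 = theta[1], c2 = if (kind == "constant") 0 else theta[2],
    A = A, c_0 = c_0, Cs = Cs,
    objective = objective, cov = cov, converged = converged,
    divergence_radius = divergence_radius(law),
    warnings = warnings, n = n),
    class = "spovm_fit")
}

#' @export
print.spovm_fit <- function(x, ...) {
  cat(sprintf("Adsorption-model fit [%s law], n = %d\n", x$kind, x$n))
  cat(sprintf("  c1 = %.6g, c2 = %.6g, A = %.6g", x$c1, x$c2, x$A))
  if (!is.null(x$c_0) && !is.na(x$c_0)) cat(sprintf(", c_0 = %.6g", x$c_0))
  cat(sprintf("\n  objective (weighted SSR) = %.6g, converged: %s\n",
              x$objective, x$converged))
  if (!is.null(x$divergence_radius)) {
    cat(sprintf("  divergence radius = %.4g um (e_r < 0 below this radius)\n",
                x$divergence_radius))
  }
  if (length(x$warnings)) {
    cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Radius at which a curvature-law repulsion vanishes
#'
#' For the curvature law `e_r(r) = c1 - c2 / r` with positive coefficients,
#' the repulsion crosses zero at `r = c2 / c1`; below that radius the
#' adsorption series diverges, which is the physical implausibility
#' diagnostic weighing against the curvature law.  Other laws (and
#' nonpositive coefficients) have no such radius and return `NULL`.
#'
#' @param law A [repulsion_law()].
#' @return The divergence radius in micrometres, or `NULL`.
#' @examples
#' divergence_radius(repulsion_law("curvature", c1 = 2.67, c2 = 1.1649))
#' @export
divergence_radius <- function(law) {
  stopifnot(inherits(law, "repulsion_law"))
  if (law$kind == "curvature" && law$c1 > 0 && law$c2 > 0) {
    law$c2 / law$c1
  } else {
    NULL
  }
}

#' Fit a repulsion law to an adsorption-versus-radius profile
#'
#' Weighted least squares over `(c1, c2, A)` on a fixed-concentration slice
#' (all rows share one bulk concentration), with the normalised concentration
#' `Cs` either held fixed (default 1, absorbing the unknown `c_0` into the
#' slice) or fitted jointly (`fit_Cs = TRUE`).  The amplitude is profiled out
#' analytically; the `(c1, c2)` search is multi-started from a seeded uniform
#' box and polished.  Parameter proposals implying a divergent series at any
#' data radius are rejected with a large penalty rather than an error, so
#' curvature-law fits can approach their divergence boundary.
#'
#' @param data Data frame with columns `radius_um`, `concentration`,
#'   `adsorption`, and optionally `sigma` (weights `1/sigma^2`; unit weights
#'   when absent).
#' @param kind `"curvature"` or `"tension"` (or `"constant"`).
#' @param Cs Fixed normalised concentration of the slice (default 1).
#' @param fit_Cs If `TRUE`, fit `Cs` jointly with the law parameters.
#' @param log_space If `TRUE`, minimize squared residuals of log adsorption.
#' @param n_starts Number of multi-start points.
#' @param seed Seed making the multi-start (and hence the fit) deterministic.
#' @param box Named list with `c1` and `c2` ranges for the start box.
#' @return A `"spovm_fit"` object; see [divergence_radius()] for the
#'   curvature-law diagnostic it carries.
#' @export
fit_radius_profile <- function(data, kind = c("curvature", "tension"),
                               Cs = 1, fit_Cs = FALSE, log_space = FALSE,
                               n_starts = 8L, seed = 1L,
                               box = list(c1 = c(0.05, 5), c2 = c(0.01, 5))) {
  kind <- match.arg(kind)
  data <- .check_dataset(data)
  warnings <- character(0)
  r <- data$radius_um
  y <- data$adsorption
  w <- .weights_from_sigma(data)
  if (length(unique(r)) < 3L) {
    warnings <- c(warnings, "fewer than 3 distinct radii: fit not identifiable")
  }
  if (isTRUE(stats::sd(y) == 0)) {
    warnings <- c(warnings,
                  "constant adsorption across radii: c2 unconstrained")
  }

  fn <- function(theta) {
    cs <- if (fit_Cs) exp(theta[3]) else Cs
    er <- .penalized_er(kind, theta[1:2], r)
    if (any(er <= 0) || (cs >= 1 && any(er <= 0))) {
      return(1e10 * (1 + sum(pmax(0, -er))))
    }
    Cv <- .cv_surface(rep_len(cs, length(r)), er)
    .profiled_objective(Cv, y, w, log_space)$obj
  }

  lower <- c(box$c1[1], box$c2[1])
  upper <- c(box$c1[2], box$c2[2])
  if (fit_Cs) { lower <- c(lower, log(0.01)); upper <- c(upper, log(10)) }
  best <- .optimize_reduced(fn, lower, upper, n_starts, seed)

  theta <- best$par
  cs_hat <- if (fit_Cs) exp(theta[3]) else Cs
  er <- .penalized_er(kind, theta[1:2], r)
  Cv <- .cv_surface(rep_len(cs_hat, length(r)), er)
  prof <- .profiled_objective(Cv, y, w, log_space)

  # covariance of (c1, c2, A) from the residual Jacobian at the optimum
  cov <- tryCatch({
    resfn <- function(p) {
      er <- .penalized_er(kind, p[1:2], r)
      Cv <- .cv_surface(rep_len(cs_hat, length(r)), er)
      if (is.null(Cv)) return(rep(1e5, length(y)))
      sqrt(w) * (p[3] * Cv - y)
    }
    p_hat <- c(theta[1:2], prof$A)
    J <- .num_jacobian(resfn, p_hat)
    dof <- max(1L, length(y) - length(p_hat))
    s2 <- best$value / dof
    V <- s2 * solve(crossprod(J))
    dimnames(V) <- list(c("c1", "c2", "A"), c("c1", "c2", "A"))
    V
  }, error = function(e) NULL)

  .fit_result(kind, theta[1:2], prof$A, c_0 = NA_real_, Cs = cs_hat,
              objective = best$value, cov = cov,
              converged = is.finite(best$value) && best$value < 1e9,
              warnings = warnings, n = length(y))
}

#' Fit a repulsion law to adsorption-versus-concentration profiles
#'
#' Joint weighted least squares of `(c1, c2, A, c_0)` across concentration
#' sweeps measured at two or more radii, sharing all four parameters.  The
#' amplitude is profiled out; `(c1, c2, log c_0)` are searched by seeded
#' multi-start.  The cooperative steepening of the isotherm at radii with
#' lower `e_r(r)` is what identifies the law parameters; a dataset confined
#' to the linear low-concentration regime carries no repulsion information
#' and is flagged as weakly identified.
#'
#' @inheritParams fit_radius_profile
#' @param data Data frame with `radius_um`, `concentration`, `adsorption`,
#'   and optionally `sigma`; needs >= 2 distinct radii and >= 4
#'   concentrations per radius.
#' @param c0_box Range (in units of the median concentration) for the `c_0`
#'   start box.
#' @return A `"spovm_fit"` object with `c_0` populated.
#' @export
fit_concentration_profiles <- function(data,
                                       kind = c("curvature", "tension"),
                                       log_space = FALSE, n_starts = 8L,
                                       seed = 1L,
                                       box = list(c1 = c(0.05, 5),
                                                  c2 = c(0.01, 5)),
                                       c0_box = c(0.05, 20)) {
  kind <- match.arg(kind)
  data <- .check_dataset(data)
  warnings <- character(0)
  r <- data$radius_um
  cc <- data$concentration
  y <- data$adsorption
  w <- .weights_from_sigma(data)
  if (length(unique(r)) < 2L) {
    warnings <- c(warnings, "needs >= 2 distinct radii to separate c1 and c2")
  }
  if (min(table(r)) < 4L) {
    warnings <- c(warnings, "fewer than 4 concentrations at some radius")
  }

  cmed <- stats::median(cc[cc > 0])

  fn <- function(theta) {
    c0 <- exp(theta[3])
    er <- .penalized_er(kind, theta[1:2], r)
    Cs <- cc / c0
    if (any(er <= 0)) return(1e10 * (1 + sum(pmax(0, -er))))
    Cv <- .cv_surface(Cs, er)
    .profiled_objective(Cv, y, w, log_space)$obj
  }

  lower <- c(box$c1[1], box$c2[1], log(c0_box[1] * cmed))
  upper <- c(box$c1[2], box$c2[2], log(c0_box[2] * cmed))
  best <- .optimize_reduced(fn, lower, upper, n_starts, seed)

  theta <- best$par
  c0_hat <- exp(theta[3])
  er <- .penalized_er(kind, theta[1:2], r)
  Cv <- .cv_surface(cc / c0_hat, er)
  prof <- .profiled_objective(Cv, y, w, log_space)

  if (max(cc / c0_hat, na.rm = TRUE) < 0.1) {
    warnings <- c(warnings, paste(
      "data confined to the linear low-concentration regime:",
      "(c1, c2) weakly identified, only A/c_0 is pinned down"))
  }

  cov <- tryCatch({
    resfn <- function(p) {
      er <- .penalized_er(kind, p[1:2], r)
      Cv <- .cv_surface(cc / exp(p[4]), er)
      if (is.null(Cv)) return(rep(1e5, length(y)))
      sqrt(w) * (p[3] * Cv - y)
    }
    p_hat <- c(theta[1:2], prof$A, log(c0_hat))
    J <- .num_jacobian(resfn, p_hat)
    dof <- max(1L, length(y) - length(p_hat))
    V <- (best$value / dof) * solve(crossprod(J))
    nm <- c("c1", "c2", "A", "log_c0")
    dimnames(V) <- list(nm, nm)
    V
  }, error = function(e) NULL)

  .fit_result(kind, theta[1:2], prof$A, c_0 = c0_hat, Cs = NA_real_,
              objective = best$value, cov = cov,
              converged = is.finite(best$value) && best$value < 1e9,
              warnings = warnings, n = length(y))
}

#' Compare curvature- and tension-law fits on one dataset
#'
#' Fits both radius-dependent laws to the same radius profile from identical
#' multi-start boxes and seeds, and ranks them by weighted SSR.  For the
#' curvature law the divergence-radius diagnostic is reported alongside: a
#' competitive curvature fit whose divergence radius sits just below the
#' measured radii is the model's warning sign that the law is being pushed
#' toward an unphysical regime.
#'
#' @inheritParams fit_radius_profile
#' @return An object of class `"spovm_model_comparison"`: list with `fits`
#'   (named list of `"spovm_fit"`), `ranking` (law kinds, best first),
#'   `objective_ratio` (curvature SSR / tension SSR), and
#'   `non_identifiable` (`TRUE` for single-radius data, where the laws
#'   cannot be distinguished).
#' @export
compare_models <- function(data, Cs = 1, fit_Cs = FALSE, log_space = FALSE,
                           n_starts = 8L, seed = 1L) {
  data <- .check_dataset(data)
  non_id <- length(unique(data$radius_um)) < 2L
  fits <- list(
    curvature = fit_radius_profile(data, "curvature", Cs = Cs,
                                   fit_Cs = fit_Cs, log_space = log_space,
                                   n_starts = n_starts, seed = seed),
    tension = fit_radius_profile(data, "tension", Cs = Cs, fit_Cs = fit_Cs,
                                 log_space = log_space,
                                 n_starts = n_starts, seed = seed))
  objs <- vapply(fits, `[[`, 0, "objective")
  structure(list(
    fits = fits,
    ranking = names(sort(objs)),
    objective_ratio = objs[["curvature"]] / objs[["tension"]],
    non_identifiable = non_id),
    class = "spovm_model_comparison")
}

#' @export
print.spovm_model_comparison <- function(x, ...) {
  cat("Model comparison (weighted SSR):\n")
  for (k in x$ranking) {
    cat(sprintf("  %-9s %.6g\n", k, x$fits[[k]]$objective))
  }
  if (x$non_identifiable) {
    cat("  NOTE: single-radius data; laws are not distinguishable\n")
  }
  dr <- x$fits$curvature$divergence_radius
  if (!is.null(dr)) {
    cat(sprintf("  curvature-law divergence radius: %.4g um\n", dr))
  }
  invisible(x)
}
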