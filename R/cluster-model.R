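# Core cluster-sum machinery.  All series are evaluated in log space so that
# normalised concentrations up to exp(100) remain representable; sums use
# a log-sum-exp reduction.

logsumexp <- function(lx) {
  lx <- lx[is.finite(lx) | lx == -Inf]
  if (length(lx) == 0L) return(-Inf)
  m <- max(lx)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(lx - m)))
}

# log of the k-th adsorption summand: log[k exp(-k(k-1) e_r/2) C_s^k]
.log_weight <- function(k, log_Cs, e_r) {
  log(k) - 0.5 * k * (k - 1) * e_r + k * log_Cs
}

.check_convergent <- function(C_s, e_r) {
  if (!is.finite(C_s) || C_s < 0) stop_domain("C_s must be finite and >= 0")
  if (!is.finite(e_r)) stop_domain("e_r must be finite")
  if (e_r < 0 || (e_r == 0 && C_s >= 1)) {
    stop_divergence(sprintf(
      "adsorption series diverges for C_s = %g, e_r = %g", C_s, e_r))
  }
  invisible(TRUE)
}

# Adaptive truncation: starting from a guess past the dominant term
# k* ~ ln(C_s)/e_r, double K until (a) the dominant term lies strictly inside
# the window and (b) the geometric tail bound beyond K is below tol times the
# partial sum.  Returns the vector of log weights.
.log_weights_adaptive <- function(C_s, e_r, tol = 1e-12, k_cap = 1e6) {
  log_Cs <- log(C_s)
  k_star <- if (e_r > 0) max(1, ceiling(log_Cs / e_r)) else
    max(1, ceiling(-1 / log_Cs))
  K <- max(16L, as.integer(2L * k_star + 16L))
  repeat {
    k <- seq_len(K)
    lw <- .log_weight(k, log_Cs, e_r)
    lse <- logsumexp(lw)
    # ratio of the (K+1)-th to the K-th term; beyond the peak the ratio keeps
    # shrinking, so a geometric bound on the tail is valid once ratio < 1
    lratio <- log((K + 1) / K) - K * e_r + log_Cs
    if (which.max(lw) < K && lratio < 0) {
      ltail <- lw[K] + lratio - log1p(-exp(lratio))  # bound on sum_{k>K}
      if (ltail - lse < log(tol)) return(lw)
    }
    if (K >= k_cap) {
      stop_divergence(sprintf(
        "series for C_s = %g, e_r = %g not converged within %d terms",
        C_s, e_r, k_cap))
    }
    K <- min(k_cap, K * 2L)
  }
}

#' Summands of the adsorption series
#'
#' Returns the first `K` terms \eqn{w_k = k e^{-k(k-1) e_r / 2} C_s^k} of the
#' dilute-limit adsorption series.  The per-site cluster count of size-`k`
#' clusters is recoverable as \eqn{(w_k / k) e^{-\epsilon_{nn}}}.
#'
#' @param C_s Normalised bulk concentration (dimensionless, >= 0).
#' @param e_r Pairwise repulsion strength (\eqn{k_B T}).
#' @param K Truncation: number of terms returned (integer >= 1).
#' @return Numeric vector of length `K` with the summands for `k = 1..K`.
#' @examples
#' cluster_weights(0.5, e_r = 0, K = 3)   # 0.5, 0.5, 0.375
#' @export
cluster_weights <- function(C_s, e_r, K) {
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K != round(K)) {
    stop_domain("K must be an integer >= 1")
  }
  if (!is.finite(C_s) || C_s < 0) stop_domain("C_s must be finite and >= 0")
  if (!is.finite(e_r)) stop_domain("e_r must be finite")
  if (e_r <= 0 && C_s >= 1) {
    stop_divergence(sprintf(
      "series diverges for C_s = %g with e_r = %g", C_s, e_r))
  }
  if (C_s == 0) return(numeric(K))
  exp(.log_weight(seq_len(K), log(C_s), e_r))
}

#' Normalised membrane adsorption
#'
#' Evaluates the dilute-limit adsorption
#' \eqn{C_v = \sum_{k \ge 1} k e^{-k(k-1) e_r / 2} C_s^k}, the normalised
#' concentration of membrane-bound protein as a function of the normalised
#' bulk concentration \eqn{C_s} and the pairwise repulsion \eqn{e_r}.  The
#' series is truncated adaptively: summation stops when a geometric bound on
#' the remaining tail falls below `tol` times the partial sum.  It converges
#' for any \eqn{C_s \ge 0} when \eqn{e_r > 0} and for \eqn{C_s < 1} when
#' \eqn{e_r = 0}; other combinations raise a divergence error.
#'
#' @inheritParams cluster_weights
#' @param tol Relative tail tolerance for adaptive truncation.
#' @param log If `TRUE`, return \eqn{\ln C_v} (needed when \eqn{C_v}
#'   overflows double precision, e.g. deep in the asymptotic regime).
#' @return `C_v` (or `log(C_v)`), a nonnegative scalar.
#' @examples
#' adsorption(0.5, e_r = 0)       # = 0.5 / (1 - 0.5)^2 = 2
#' adsorption(1, e_r = 2)         # 1.278131...
#' @export
adsorption <- function(C_s, e_r, tol = 1e-12, log = FALSE) {
  .check_convergent(C_s, e_r)
  if (C_s == 0) return(if (log) -Inf else 0)
  lw <- .log_weights_adaptive(C_s, e_r, tol)
  lse <- logsumexp(lw)
  if (log) lse else exp(lse)
}

#' Mean cluster size on the membrane
#'
#' The number-weighted mean cluster size
#' \eqn{\sum_k k m_k / \sum_k m_k} with per-site cluster counts
#' \eqn{m_k \propto e^{-k(k-1) e_r/2} C_s^k}; it tends to 1 as
#' \eqn{C_s \to 0} (monomers only).  The mass-weighted alternative
#' \eqn{\sum_k k^2 m_k / \sum_k k m_k} (the mean size of the cluster a
#' randomly chosen *bound protein* belongs to) is available via
#' `weighting = "mass"`.
#'
#' @inheritParams adsorption
#' @param weighting `"number"` (default) or `"mass"`.
#' @return Mean cluster size in proteins (>= 1).
#' @examples
#' mean_cluster_size(0.5, e_r = 0)   # 1 / (1 - 0.5) = 2
#' @export
mean_cluster_size <- function(C_s, e_r, tol = 1e-12,
                              weighting = c("number", "mass")) {
  weighting <- match.arg(weighting)
  .check_convergent(C_s, e_r)
  if (C_s == 0) return(1)
  lw <- .log_weights_adaptive(C_s, e_r, tol)
  k <- seq_along(lw)
  if (weighting == "number") {
    exp(logsumexp(lw) - logsumexp(lw - log(k)))
  } else {
    exp(logsumexp(lw + log(k)) - logsumexp(lw))
  }
}

#' Dominant (modal) cluster size
#'
#' The cluster size whose term maximises the adsorption series, found by an
#' exact scan, together with the asymptotic estimate
#' \eqn{k^* \approx \ln(C_s) / e_r} valid for large \eqn{C_s}.
#'
#' @inheritParams adsorption
#' @return A list with `k_star` (integer argmax), `estimate`
#'   (\eqn{\ln(C_s)/e_r}), and `weight` (the maximal summand, on the log scale
#'   as `log_weight`).
#' @examples
#' dominant_cluster_size(exp(10), e_r = 1)   # k_star = 11, estimate = 10
#' @export
dominant_cluster_size <- function(C_s, e_r, tol = 1e-12) {
  if (!is.finite(C_s) || C_s <= 0) stop_domain("C_s must be positive")
  if (!is.finite(e_r) || e_r <= 0) stop_domain("e_r must be positive")
  lw <- .log_weights_adaptive(C_s, e_r, tol)
  k_star <- which.max(lw)
  list(k_star = as.integer(k_star),
       estimate = log(C_s) / e_r,
       log_weight = lw[k_star])
}

#' Asymptotic log-adsorption at large concentration
#'
#' In the large-concentration regime (while still dilute on the membrane) the
#' adsorption series is dominated by terms near \eqn{k^* = \ln(C_s)/e_r},
#' giving \eqn{\ln C_v \approx (\ln C_s)^2 / (2 e_r)}.
#'
#' @inheritParams adsorption
#' @return The approximation to \eqn{\ln C_v}.
#' @examples
#' asymptotic_log_adsorption(exp(10), e_r = 1)   # 50
#' @export
asymptotic_log_adsorption <- function(C_s, e_r) {
  if (!is.numeric(C_s) || any(C_s <= 1)) {
    stop_domain("asymptotic regime requires C_s > 1")
  }
  if (!is.numeric(e_r) || any(e_r <= 0)) stop_domain("e_r must be positive")
  log(C_s)^2 / (2 * e_r)
}

#' Convert normalised adsorption to a bound-protein count
#'
#' Undoes the dilute-limit normalisation:
#' \eqn{n_v = C_v L_v e^{-\epsilon_{nn}}}.  A warning is raised when the
#' implied coverage `n_v / L_v` exceeds 0.1, where the dilute assumption
#' (\eqn{n_v \ll L_v}) underlying the whole series breaks down.
#'
#' @param C_v Normalised adsorption (>= 0).
#' @param geometry A [membrane_geometry()] supplying the site count `L_v`.
#' @param params An [interaction_params()] supplying `eps_nn`.
#' @return Expected number of membrane-bound proteins.
#' @export
denormalize <- function(C_v, geometry, params) {
  stopifnot(inherits(geometry, "membrane_geometry"),
            inherits(params, "interaction_params"))
  if (!is.numeric(C_v) || any(C_v < 0)) stop_domain("C_v must be >= 0")
  n_v <- C_v * geometry$L_v * exp(-params$eps_nn)
  if (any(n_v / geometry$L_v > 0.1)) {
    warning("coverage n_v / L_v > 0.1: dilute assumption violated",
            call. = FALSE)
  }
  n_v
}

#' Full cluster-size distribution and summary statistics
#'
#' Convenience wrapper returning the adaptive series evaluation as one
#' object: per-site cluster densities `m_k / L_v` (including the
#' \eqn{e^{-\epsilon_{nn}}} prefactor), the normalised adsorption, and the
#' mean and dominant cluster sizes.
#'
#' @inheritParams adsorption
#' @param eps_nn Nearest-neighbour attraction (\eqn{k_B T}) entering the
#'   per-site prefactor; defaults to 0 (pure normalised units).
#' @return An object of class `"cluster_distribution"`: a list with `weights`
#'   (per-site densities over `k = 1..K`), `C_v`, `mean_size`,
#'   `dominant_size`, and `truncation_K`.
#' @examples
#' cluster_distribution(0.8, e_r = 0.5)
#' @export
cluster_distribution <- function(C_s, e_r, tol = 1e-12, eps_nn = 0) {
  .check_convergent(C_s, e_r)
  if (C_s == 0) {
    return(structure(list(weights = 0, C_v = 0, mean_size = 1,
                          dominant_size = 1L, truncation_K = 1L),
                     class = "cluster_distribution"))
  }
  lw <- .log_weights_adaptive(C_s, e_r, tol)
  k <- seq_along(lw)
  structure(list(
    weights = exp(lw - log(k) - eps_nn),
    C_v = exp(logsumexp(lw)),
    mean_size = exp(logsumexp(lw) - logsumexp(lw - log(k))),
    dominant_size = as.integer(which.max(lw)),
    truncation_K = length(lw)),
    class = "cluster_distribution")
}

#' @export
print.cluster_distribution <- function(x, ...) {
  cat(sprintf(
    "Cluster distribution: C_v = %.6g, mean size = %.4g, modal size = %d (K = %d)\n",
    x$C_v, x$mean_size, x$dominant_size, x$truncation_K))
  invisible(x)
}
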