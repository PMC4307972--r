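# Dataset, configuration and result I/O.  Datasets are plain CSV (comma
# separated, header row, '.' decimal) with columns
# radius_um, concentration, adsorption[, sigma][, label]; configs are JSON
# or YAML key-value files; fit results serialize to JSON.

#' Read an adsorption dataset from CSV
#'
#' Validates required columns (`radius_um`, `concentration`, `adsorption`)
#' and row-level sanity (positive radii, nonnegative adsorption), reporting
#' offending rows with their file line numbers (header is line 1).
#'
#' @param path Path to a CSV file.
#' @return A data frame with the dataset columns.
#' @export
read_adsorption_dataset <- function(path) {
  if (!file.exists(path)) stop_domain(paste0("no such file: ", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("radius_um", "concentration", "adsorption")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop_domain(paste0(path, ": missing required column(s): ",
                       paste(miss, collapse = ", ")))
  }
  for (col in need) {
    if (!is.numeric(d[[col]])) {
      stop_domain(paste0(path, ": column ", col, " is not numeric"))
    }
  }
  bad <- which(!is.finite(d$radius_um) | d$radius_um <= 0)
  if (length(bad)) {
    stop_domain(paste0(path, ": nonpositive radius_um at line(s) ",
                       paste(bad + 1L, collapse = ", ")))
  }
  bad <- which(!is.finite(d$adsorption) | d$adsorption < 0)
  if (length(bad)) {
    stop_domain(paste0(path, ": negative adsorption at line(s) ",
                       paste(bad + 1L, collapse = ", ")))
  }
  d
}

#' Write an adsorption dataset to CSV
#'
#' @param data Data frame with at least `radius_um`, `concentration`,
#'   `adsorption`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_adsorption_dataset <- function(data, path) {
  .check_dataset(data)
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a localization curve as delimited text
#'
#' Emits the seven model columns (`C_s`, `adsorption_1`, `adsorption_2`,
#' `total_adsorption`, `fraction_1`, `mean_size_1`, `mean_size_2`).
#'
#' @param curve A [localization_curve()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_localization_curve <- function(curve, path) {
  cols <- c("C_s", "adsorption_1", "adsorption_2", "total_adsorption",
            "fraction_1", "mean_size_1", "mean_size_2")
  miss <- setdiff(cols, names(curve))
  if (length(miss)) {
    stop_domain(paste0("curve is missing column(s): ",
                       paste(miss, collapse = ", ")))
  }
  utils::write.csv(curve[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.config_keys <- c("law.kind", "law.c1", "law.c2", "law.e_r0", "law.k_max",
                  "eps_b", "eps_nn", "a_nm", "tol")

#' Read a model configuration file
#'
#' Flat key-value configuration in JSON (`.json`) or YAML
#' (`.yml`/`.yaml`), with the keys
#' `law.kind`, `law.c1`, `law.c2`, `law.e_r0`, `law.k_max`,
#' `eps_b`, `eps_nn`, `a_nm`, `tol` (all optional except `law.kind`
#' when a law block is present; unknown keys are rejected).  Nested
#' `law: {kind: ...}` blocks are also accepted and flattened.
#'
#' @param path Path to the configuration file.
#' @return A list with `law` (a [repulsion_law()] or `NULL`), `params`
#'   (an [interaction_params()]), `a_nm`, and `tol`.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop_domain(paste0("no such file: ", path))
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  # flatten a nested law block into dotted keys
  if (!is.null(raw$law) && is.list(raw$law)) {
    for (nm in names(raw$law)) raw[[paste0("law.", nm)]] <- raw$law[[nm]]
    raw$law <- NULL
  }
  unknown <- setdiff(names(raw), .config_keys)
  if (length(unknown)) {
    stop_domain(paste0("unknown configuration key(s): ",
                       paste(unknown, collapse = ", ")))
  }
  law <- NULL
  if (!is.null(raw[["law.kind"]])) {
    law <- repulsion_law(raw[["law.kind"]],
                         c1 = raw[["law.c1"]], c2 = raw[["law.c2"]],
                         e_r0 = raw[["law.e_r0"]],
                         k_max = raw[["law.k_max"]])
  }
  params <- interaction_params(
    eps_b = if (is.null(raw$eps_b)) 0 else raw$eps_b,
    eps_nn = if (is.null(raw$eps_nn)) 0 else raw$eps_nn,
    e_r = if (!is.null(law) && law$kind == "constant") law$c1 else 1)
  list(law = law, params = params,
       a_nm = if (is.null(raw$a_nm)) 4 else raw$a_nm,
       tol = if (is.null(raw$tol)) 1e-12 else raw$tol)
}

#' Serialize a fit result to JSON
#'
#' @param fit A `"spovm_fit"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "spovm_fit"))
  out <- list(kind = fit$kind, c1 = fit$c1, c2 = fit$c2, A = fit$A,
              c_0 = fit$c_0, Cs = fit$Cs, objective = fit$objective,
              converged = fit$converged,
              divergence_radius = if (is.null(fit$divergence_radius))
                NULL else fit$divergence_radius,
              covariance = if (is.null(fit$cov)) NULL else
                as.data.frame(fit$cov),
              warnings = fit$warnings, n = fit$n)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a fit result back from JSON
#'
#' @param path Path written by [write_fit_result()].
#' @return A list mirroring the serialized fields.
#' @export
read_fit_result <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
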