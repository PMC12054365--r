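#' Ev11 error-model parameters
#'
#' The three global coefficients of the classic calibration: `s_fac`
#' rescales intensities' counting-statistics uncertainty (detector-gain
#' error), `s_add` adds error whose variance scales with the squared mean
#' intensity, and `s_B` is an intensity-linear term with no assigned
#' physical meaning.
#'
#' @param s_fac Dimensionless scale, > 0.
#' @param s_B Intensity-linear coefficient (units of intensity), any sign.
#' @param s_add Fractional additional error, >= 0.
#' @return Object of class `ev11_params`.
#' @export
ev11_params <- function(s_fac = 1, s_B = 0, s_add = 0) {
  stopifnot(is.finite(s_fac), s_fac > 0, is.finite(s_B), is.finite(s_add), s_add >= 0)
  structure(list(s_fac = s_fac, s_B = s_B, s_add = s_add), class = "ev11_params")
}

#' @export
print.ev11_params <- function(x, ...) {
  cat(sprintf("<ev11_params> s_fac=%.6g  s_B=%.6g  s_add=%.6g\n", x$s_fac, x$s_B, x$s_add))
  invisible(x)
}

#' MM24 error-model parameters
#'
#' `s_fac` is the global rescale; the per-lattice additional error is an
#' exponential decay of the lattice correlation,
#' `s_add(cc) = s_add_0 + s_add_1 * exp(-s_add_2 * cc)`, so poorly
#' correlated lattices receive more error. `nu` is the degrees of freedom
#' of the half-t likelihood (ignored for the half-normal kernel); it tunes
#' tail weight (1 = Cauchy, large = normal).
#'
#' @param s_fac Dimensionless scale, > 0.
#' @param s_add_0,s_add_1,s_add_2 Coefficients of the exponential decay;
#'   `s_add(cc)` must stay positive on cc in \[-1, 1\].
#' @param nu Degrees of freedom, > 1 (required when `likelihood = "half_t"`).
#' @param likelihood `"half_normal"` or `"half_t"`.
#' @return Object of class `mm24_params`.
#' @export
mm24_params <- function(s_fac = 1, s_add_0 = 0, s_add_1 = 0, s_add_2 = 0,
                        nu = NULL, likelihood = c("half_t", "half_normal")) {
  likelihood <- match.arg(likelihood)
  stopifnot(is.finite(s_fac), s_fac > 0,
            is.finite(s_add_0), s_add_0 >= 0,
            is.finite(s_add_1), s_add_1 >= 0,
            is.finite(s_add_2))
  if (likelihood == "half_t") {
    if (is.null(nu)) stop("nu is required for the half_t likelihood")
    stopifnot(is.finite(nu), nu > 1)
  }
  structure(list(s_fac = s_fac, s_add_0 = s_add_0, s_add_1 = s_add_1,
                 s_add_2 = s_add_2, nu = nu, likelihood = likelihood),
            class = "mm24_params")
}

#' @export
print.mm24_params <- function(x, ...) {
  cat(sprintf("<mm24_params> s_fac=%.6g  s_add_0=%.6g  s_add_1=%.6g  s_add_2=%.6g  likelihood=%s%s\n",
              x$s_fac, x$s_add_0, x$s_add_1, x$s_add_2, x$likelihood,
              if (!is.null(x$nu)) sprintf("  nu=%.4g", x$nu) else ""))
  invisible(x)
}

#' Ev11 uncertainty transform
#'
#' `sigma' = s_fac * sqrt(sigma^2 + s_B * <I_h> + s_add^2 * <I_h>^2)`.
#' The bracket can go non-positive for negative `s_B * <I_h>`; that is a
#' domain error naming the first offending element.
#'
#' @param sigma_counting Counting-statistics sigma(s), > 0.
#' @param mean_intensity All-in mean intensity `<I_h>` of the Miller group
#'   each observation belongs to.
#' @param params An [ev11_params()].
#' @return Calibrated sigma(s), > 0.
#' @export
ev11_sigma <- function(sigma_counting, mean_intensity, params) {
  stopifnot(inherits(params, "ev11_params"))
  if (any(sigma_counting <= 0)) stop("sigma_counting must be > 0")
  bracket <- sigma_counting^2 + params$s_B * mean_intensity +
    params$s_add^2 * mean_intensity^2
  if (any(bracket <= 0)) {
    i <- which(bracket <= 0)[1]
    stop(sprintf("non-positive variance bracket at element %d (sigma=%g, <I>=%g)",
                 i, sigma_counting[min(i, length(sigma_counting))],
                 mean_intensity[min(i, length(mean_intensity))]))
  }
  params$s_fac * sqrt(bracket)
}

#' Per-lattice additional error from the lattice correlation
#'
#' `s_add(cc) = s_add_0 + s_add_1 * exp(-s_add_2 * cc)`: always positive
#' for the fitted parameter ranges, constant when `s_add_1 = 0`, and
#' monotonically decreasing in cc when `s_add_1, s_add_2 > 0`.
#'
#' @param cc_l Lattice correlation(s) in \[-1, 1\].
#' @param params An [mm24_params()].
#' @return `s_add` value(s).
#' @export
s_add_of_cc <- function(cc_l, params) {
  stopifnot(inherits(params, "mm24_params"))
  if (any(!is.finite(cc_l)) || any(abs(cc_l) > 1))
    stop("cc_l must be finite and in [-1, 1]")
  params$s_add_0 + params$s_add_1 * exp(-params$s_add_2 * cc_l)
}

#' MM24 uncertainty transform
#'
#' `sigma' = s_fac * sqrt(sigma^2 + s_add(cc_l)^2 * <I_h>^2)`: the Ev11
#' form with the intensity-linear term removed and the additional error
#' made lattice-specific through the correlation coefficient.
#'
#' @inheritParams ev11_sigma
#' @param cc_l Correlation of the observation's lattice to the scaling
#'   reference.
#' @param params An [mm24_params()].
#' @return Calibrated sigma(s), > 0.
#' @export
mm24_sigma <- function(sigma_counting, mean_intensity, cc_l, params) {
  stopifnot(inherits(params, "mm24_params"))
  if (any(sigma_counting <= 0)) stop("sigma_counting must be > 0")
  s_add <- s_add_of_cc(cc_l, params)
  if (any(s_add < 0)) stop("s_add(cc) must be non-negative on [-1, 1]")
  params$s_fac * sqrt(sigma_counting^2 + s_add^2 * mean_intensity^2)
}

# Dispatch: per-observation calibrated sigma for an annotated obs table.
calibrated_sigma_obs <- function(obs, params) {
  if (is.null(params)) return(obs$sigma)
  if (inherits(params, "ev11_params"))
    return(ev11_sigma(obs$sigma, obs$mean_intensity, params))
  if (inherits(params, "mm24_params")) {
    if (any(is.na(obs$cc)))
      stop("MM24 sigmas require a cc value for every lattice")
    return(mm24_sigma(obs$sigma, obs$mean_intensity, obs$cc, params))
  }
  stop("params must be ev11_params, mm24_params or NULL")
}

#' Apply calibrated uncertainties to a table
#'
#' Returns a copy of the table whose `sigma` column has been replaced by
#' the calibrated `sigma'` under the given parameter set. Intensities are
#' never modified: calibration is purely an error transform.
#'
#' @param table A [refl_table()].
#' @param params [ev11_params()] or [mm24_params()].
#' @return A new `refl_table`.
#' @export
apply_error_model <- function(table, params) {
  obs <- annotate_groups(table)
  new_obs <- copy(table$observations)
  new_obs[, sigma := calibrated_sigma_obs(obs, params)]
  out <- list(observations = new_obs, lattices = copy(table$lattices))
  class(out) <- "refl_table"
  out
}

#' Half-normal log-density
#'
#' `p(w) = sqrt(2/pi) * exp(-w^2/2)` on w >= 0: the distribution of the
#' normalized pairwise differences when uncertainties are exactly
#' calibrated and errors are normal.
#'
#' @param omega Non-negative value(s).
#' @return Log-density value(s).
#' @export
half_normal_log_pdf <- function(omega) {
  if (any(omega < 0)) stop("omega must be >= 0")
  0.5 * log(2 / pi) - omega^2 / 2
}

#' Half-t log-density
#'
#' Folded Student-t on \[0, Inf):
#' `p(w; nu) = 2 * Gamma((nu+1)/2) / (sqrt(nu*pi) * Gamma(nu/2)) *
#' (1 + w^2/nu)^(-(nu+1)/2)`. Computed in log space via `lgamma` for
#' numerical stability. nu = 1 is the half-Cauchy; nu -> Inf converges to
#' the half-normal.
#'
#' @param omega Non-negative value(s).
#' @param nu Degrees of freedom, > 0.
#' @return Log-density value(s).
#' @export
half_t_log_pdf <- function(omega, nu) {
  if (any(omega < 0)) stop("omega must be >= 0")
  if (!is.finite(nu) || nu <= 0) stop("nu must be > 0")
  log(2) + lgamma((nu + 1) / 2) - 0.5 * log(nu * pi) - lgamma(nu / 2) -
    (nu + 1) / 2 * log1p(omega^2 / nu)
}

#' Serialize an error-model parameter set to JSON
#'
#' Flat key-value document with keys `model, s_fac, s_B, s_add_0, s_add_1,
#' s_add_2, nu, likelihood_kind` (only the keys that apply to the model
#' are written).
#'
#' @param params [ev11_params()] or [mm24_params()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_params_json <- function(params, path) {
  if (inherits(params, "ev11_params")) {
    doc <- list(model = "ev11", s_fac = params$s_fac, s_B = params$s_B,
                s_add_0 = params$s_add, s_add_1 = 0, s_add_2 = 0)
  } else if (inherits(params, "mm24_params")) {
    doc <- list(model = "mm24", s_fac = params$s_fac,
                s_add_0 = params$s_add_0, s_add_1 = params$s_add_1,
                s_add_2 = params$s_add_2,
                likelihood_kind = params$likelihood)
    if (!is.null(params$nu)) doc$nu <- params$nu
  } else stop("unknown parameter class")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an error-model parameter set from JSON
#'
#' @param path Path to a document written by [write_params_json()].
#' @return [ev11_params()] or [mm24_params()] according to the `model` key.
#' @export
read_params_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(doc$model, "ev11"))
    return(ev11_params(s_fac = doc$s_fac, s_B = doc$s_B, s_add = doc$s_add_0))
  if (identical(doc$model, "mm24"))
    return(mm24_params(s_fac = doc$s_fac, s_add_0 = doc$s_add_0,
                       s_add_1 = doc$s_add_1, s_add_2 = doc$s_add_2,
                       nu = doc$nu,
                       likelihood = doc$likelihood_kind))
  stop("unknown model in ", path)
}
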