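#' Observed second moment of merged intensities per resolution shell
#'
#' The dispersion statistic `<Z^2>/<Z>^2` with `Z = I/Sigma`, `Sigma` the
#' mean merged intensity of the shell. For untwinned acentric data drawn
#' from the Wilson distribution it equals 2 in the absence of measurement
#' error; measurement noise inflates it. Centric reflections are out of
#' scope: the statistic assumes an acentric population.
#'
#' @param merged Output of [merge_reflections()] with finite d-spacings.
#' @param resolution_bins Result of [make_resolution_bins()].
#' @param min_per_bin Minimum reflections for a shell to be reported
#'   (default 10; thinner shells give `NA`).
#' @return data.table: `bin, d_max, d_min, n_refl, sigma_big` (the shell
#'   mean intensity), `second_moment`.
#' @export
observed_second_moment <- function(merged, resolution_bins, min_per_bin = 10) {
  m <- as.data.table(merged)[is.finite(d_spacing)]
  if (!nrow(m)) stop("merged table has no finite d-spacings")
  m[, bin := resolution_bins$assign(d_spacing)]
  out <- m[, {
    Sig <- mean(intensity)
    z <- intensity / Sig
    .(n_refl = .N, sigma_big = Sig,
      second_moment = if (.N >= min_per_bin && Sig != 0)
        mean(z^2) / mean(z)^2 else NA_real_)
  }, keyby = bin]
  out <- merge(data.table(bin = seq_len(resolution_bins$n_bins),
                          d_max = resolution_bins$d_max,
                          d_min = resolution_bins$d_min),
               out, by = "bin", all.x = TRUE)
  out[is.na(n_refl), n_refl := 0L]
  out[]
}

#' Expected second moment from merged uncertainties
#'
#' Under the Wilson model the normalized true intensity Z is unit
#' exponential; adding Gaussian measurement error of SD `sigma_Z = sigma /
#' Sigma` gives an exponentially modified Gaussian marginal with mean 1
#' and variance `1 + sigma_Z^2`, hence a second moment of
#' `2 + <sigma_Z^2>` per shell (the shell aggregate uses the mean of the
#' squared normalized sigmas, the variance-consistent choice). Equals 2
#' exactly when all sigmas vanish.
#'
#' @inheritParams observed_second_moment
#' @return data.table: `bin, d_max, d_min, n_refl, mean_sigma_z2,
#'   expected_second_moment`.
#' @export
expected_second_moment <- function(merged, resolution_bins, min_per_bin = 10) {
  m <- as.data.table(merged)[is.finite(d_spacing)]
  if (!nrow(m)) stop("merged table has no finite d-spacings")
  m[, bin := resolution_bins$assign(d_spacing)]
  out <- m[, {
    Sig <- mean(intensity)
    sz2 <- (sigma / Sig)^2
    .(n_refl = .N, mean_sigma_z2 = mean(sz2),
      expected_second_moment = if (.N >= min_per_bin && Sig != 0)
        2 + mean(sz2) else NA_real_)
  }, keyby = bin]
  out <- merge(data.table(bin = seq_len(resolution_bins$n_bins),
                          d_max = resolution_bins$d_max,
                          d_min = resolution_bins$d_min),
               out, by = "bin", all.x = TRUE)
  out[is.na(n_refl), n_refl := 0L]
  out[]
}

#' Second-moment diagnostic curves
#'
#' Observed and expected second moments side by side per resolution
#' shell: agreement indicates uncertainties consistent with the intensity
#' dispersion; observed above expected indicates under-estimated sigmas
#' (and vice versa).
#'
#' @inheritParams observed_second_moment
#' @return data.table joining [observed_second_moment()] and
#'   [expected_second_moment()].
#' @export
second_moment_profile <- function(merged, resolution_bins, min_per_bin = 10) {
  obs <- observed_second_moment(merged, resolution_bins, min_per_bin)
  exp_ <- expected_second_moment(merged, resolution_bins, min_per_bin)
  merge(obs, exp_[, .(bin, mean_sigma_z2, expected_second_moment)], by = "bin")
}

half_ref_quantile <- function(p, reference, nu = NULL) {
  switch(reference,
         half_normal = qnorm((1 + p) / 2),
         half_t = {
           if (is.null(nu)) stop("half_t reference needs nu")
           qt((1 + p) / 2, df = nu)
         },
         stop("unknown reference distribution: ", reference))
}

#' Rankit (normal-probability) profile
#'
#' Sorts the statistic values and pairs them with the expected order
#' statistics (rankits) of a half-normal or half-t reference, using Blom
#' plotting positions `(i - 0.375)/(n + 0.25)`. Correctly calibrated
#' statistics fall on a straight line through the origin with slope one;
#' the least-squares slope and intercept are returned for that check.
#'
#' @param values Non-negative statistic values (omega or |delta|), length
#'   >= 10.
#' @param reference `"half_normal"` or `"half_t"`.
#' @param nu Degrees of freedom (required for `"half_t"`).
#' @return List of class `rankit_profile`: `sorted` (ascending data),
#'   `rankits`, `slope`, `intercept`, `reference`, `nu`.
#' @export
rankit_profile <- function(values, reference = c("half_normal", "half_t"),
                           nu = NULL) {
  reference <- match.arg(reference)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 10) stop("need at least 10 values for a rankit profile")
  srt <- sort(values)
  p <- (seq_len(n) - 0.375) / (n + 0.25)
  rk <- half_ref_quantile(p, reference, nu)
  fit <- stats::lm.fit(cbind(1, rk), srt)
  structure(list(sorted = srt, rankits = rk,
                 slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 reference = reference, nu = nu),
            class = "rankit_profile")
}

#' @export
print.rankit_profile <- function(x, ...) {
  cat(sprintf("<rankit_profile> n=%d  reference=%s%s  slope=%.4f  intercept=%.4f\n",
              length(x$sorted), x$reference,
              if (!is.null(x$nu)) sprintf("(nu=%.3g)", x$nu) else "",
              x$slope, x$intercept))
  invisible(x)
}

#' Histogram of calibration statistics with reference overlays
#'
#' Histogram of omega (or |delta|) values together with the half-normal
#' density and, when `nu` is given, the half-t density evaluated at the
#' bin centers — the standard visual check that calibrated statistics
#' match their target distribution.
#'
#' @param values Non-negative statistic values.
#' @param n_bins Number of histogram bins (default 50).
#' @param upper Upper edge of the histogram support (default the data
#'   maximum).
#' @param nu Optional degrees of freedom for the half-t overlay.
#' @return List with `table` (data.table: `lower, upper, center, count,
#'   density, half_normal` and optionally `half_t`) and `n`.
#' @export
statistic_histograms <- function(values, n_bins = 50, upper = NULL, nu = NULL) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values")
  if (is.null(upper)) upper <- max(values)
  edges <- seq(0, upper, length.out = n_bins + 1)
  idx <- pmin(pmax(findInterval(values, edges, rightmost.closed = TRUE), 1L), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  width <- diff(edges)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  out <- data.table(lower = edges[-length(edges)], upper = edges[-1],
                    center = centers, count = counts,
                    density = counts / (sum(counts) * width),
                    half_normal = exp(half_normal_log_pdf(centers)))
  if (!is.null(nu)) out[, half_t := exp(half_t_log_pdf(center, nu))]
  list(table = out[], n = length(values))
}
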