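#' Normalized deviations
#'
#' Leave-one-out residual of each observation divided by its modeled
#' uncertainty:
#' `delta_hk = (I_hk - <I_h>_(-k)) / sqrt(sigma'_hk^2 + sum_{j!=k} sigma'_hj^2 / (n-1)^2)`,
#' where `<I_h>_(-k)` is the mean of the other n-1 observations of the
#' Miller index. When the error model is correct the deltas have unit RMS.
#' Groups with a single observation contribute nothing. Note that the
#' `<I_h>` entering the sigma transform is the all-in mean; only the
#' residual numerator is leave-one-out.
#'
#' @param table A [refl_table()].
#' @param params An [ev11_params()].
#' @return data.table (one row per observation in a group with n >= 2):
#'   Miller index, `lattice_id`, `intensity`, `sigma`, `mean_intensity`,
#'   `n`, `sigma_prime`, the residual variance `res_var`, `delta`, and
#'   `group_id` / `group_sp2` back-references used by the target gradient.
#' @export
normalized_deviations <- function(table, params) {
  stopifnot(inherits(params, "ev11_params"))
  obs <- annotate_groups(table)
  obs <- obs[n >= 2L]
  if (!nrow(obs)) stop("no Miller group has 2 or more observations")
  obs[, sigma_prime := ev11_sigma(sigma, mean_intensity, params)]
  obs[, sp2 := sigma_prime^2]
  obs[, group_sp2 := sum(sp2), by = group_id]
  loo_mean <- (obs$n * obs$mean_intensity - obs$intensity) / (obs$n - 1)
  obs[, res_var := sp2 + (group_sp2 - sp2) / (n - 1)^2]
  obs[, delta := (intensity - loo_mean) / sqrt(res_var)]
  obs[]
}

#' Even intensity binning of Miller groups
#'
#' `n_bins` bins evenly spaced in mean intensity from the minimum to the
#' maximum `<I_h>`; every observation of a Miller index falls in the single
#' bin its `<I_h>` belongs to. Assignment is half-open `[edge_b, edge_b+1)`
#' with the last bin closed, so the maximum lands in the last bin. `m_b`
#' counts observations (not groups); empty bins are retained with
#' `m_b = 0` and skipped downstream. Bin weight `w_b = sqrt(m_b)`.
#'
#' @param groups Output of [group_by_miller()] (optionally pre-filtered,
#'   e.g. to groups with n >= 2).
#' @param n_bins Number of bins (default 100).
#' @return List with `edges` (length `n_bins + 1`), per-bin data.table
#'   `bins` (`bin, m_b, w_b`), and `assignment`: the bin index of each row
#'   of `groups`.
#' @export
make_intensity_bins <- function(groups, n_bins = 100) {
  groups <- as.data.table(groups)
  mi <- groups$mean_intensity
  if (length(unique(mi)) < 2)
    stop("all mean intensities are equal; intensity binning is degenerate")
  edges <- seq(min(mi), max(mi), length.out = n_bins + 1)
  assignment <- pmin(findInterval(mi, edges, rightmost.closed = TRUE), n_bins)
  counts <- tapply(groups$n, factor(assignment, levels = seq_len(n_bins)), sum)
  counts[is.na(counts)] <- 0
  bins <- data.table(bin = seq_len(n_bins), m_b = as.numeric(counts))
  bins[, w_b := sqrt(m_b)]
  list(edges = edges, bins = bins[], assignment = assignment)
}

# Shared scaffold for the Ev11 target: per-observation static quantities
# plus the bin id of each observation.
ev11_prepare <- function(table, n_bins = 100) {
  obs <- annotate_groups(table)
  obs <- obs[n >= 2L]
  if (!nrow(obs)) stop("no Miller group has 2 or more observations")
  groups <- obs[, .(n = .N, mean_intensity = mean_intensity[1]), by = group_id]
  binning <- make_intensity_bins(groups, n_bins)
  obs[, bin := binning$assignment[match(group_id, groups$group_id)]]
  loo_mean <- (obs$n * obs$mean_intensity - obs$intensity) / (obs$n - 1)
  obs[, resid := intensity - loo_mean]
  list(obs = obs[], binning = binning)
}

# Loss and analytic gradient at a parameter point, on a prepared scaffold.
ev11_objective <- function(par, prep, gradient = TRUE) {
  s_fac <- par[1]; s_B <- par[2]; s_add <- par[3]
  obs <- prep$obs
  bracket <- obs$sigma^2 + s_B * obs$mean_intensity + s_add^2 * obs$mean_intensity^2
  if (any(bracket <= 0)) {
    # smooth, finite penalty steering the optimizer back into the domain
    # (L-BFGS-B cannot digest Inf)
    viol <- pmax(-bracket, 0)
    bad <- viol > 0
    loss <- 1e10 * (1 + sum(viol))
    if (!gradient) return(list(loss = loss))
    g <- c(0,
           -1e10 * sum(obs$mean_intensity[bad]),
           -1e10 * sum(2 * s_add * obs$mean_intensity[bad]^2))
    return(list(loss = loss, gradient = g))
  }
  sp2 <- s_fac^2 * bracket
  S_h <- ave_sum(sp2, obs$group_id)
  V <- sp2 + (S_h - sp2) / (obs$n - 1)^2
  delta2 <- obs$resid^2 / V

  sum_d2 <- tapply(delta2, factor(obs$bin, levels = prep$binning$bins$bin), sum)
  sum_d2[is.na(sum_d2)] <- 0
  m_b <- prep$binning$bins$m_b
  w_b <- prep$binning$bins$w_b
  nz <- m_b > 0
  rms_b <- sqrt(ifelse(nz, sum_d2 / pmax(m_b, 1), 0))
  loss <- sum(w_b[nz] * (rms_b[nz] - 1)^2)
  if (!gradient) return(list(loss = loss))

  # d(loss)/d(theta) = sum_obs coeff_obs * d(delta2_obs)/d(theta) with
  # coeff from the bin the observation sits in; d(delta2)/d(theta) =
  # -delta2/V * dV/dtheta.
  coeff_bin <- numeric(length(m_b))
  pos <- nz & rms_b > 0
  coeff_bin[pos] <- w_b[pos] * (rms_b[pos] - 1) / (rms_b[pos] * m_b[pos])
  cf <- coeff_bin[obs$bin] * (-delta2 / V)

  grad <- vapply(list(
    s_fac = 2 * s_fac * bracket,
    s_B   = s_fac^2 * obs$mean_intensity,
    s_add = 2 * s_fac^2 * s_add * obs$mean_intensity^2
  ), function(dsp2) {
    dS_h <- ave_sum(dsp2, obs$group_id)
    dV <- dsp2 + (dS_h - dsp2) / (obs$n - 1)^2
    sum(cf * dV)
  }, numeric(1))
  list(loss = loss, gradient = unname(grad))
}

# Group-wise sum broadcast back to each element (fast ave()).
ave_sum <- function(x, g) {
  s <- rowsum(x, g, reorder = FALSE)
  s[match(g, unique(g))]
}

#' Ev11 target function
#'
#' The binned weighted RMS-to-one loss,
#' `L = sum_b sqrt(m_b) * (RMS(delta in b) - 1)^2`, with its analytic
#' gradient with respect to `(s_fac, s_B, s_add)`. Empty bins are skipped.
#'
#' @param table A [refl_table()].
#' @param params An [ev11_params()].
#' @param n_bins Number of intensity bins (default 100).
#' @return List with `loss` and `gradient` (length 3).
#' @export
ev11_target <- function(table, params, n_bins = 100) {
  stopifnot(inherits(params, "ev11_params"))
  prep <- ev11_prepare(table, n_bins)
  ev11_objective(c(params$s_fac, params$s_B, params$s_add), prep)
}

#' Fit the Ev11 error model
#'
#' Bounded quasi-Newton (L-BFGS-B) minimization of [ev11_target()] with
#' analytic first derivatives. `s_fac` is initialized to the overall RMS of
#' the normalized deviations at the identity transform, `s_B` to 0 and
#' `s_add` to 0.01.
#'
#' @param table A [refl_table()] with redundant observations.
#' @param n_bins Number of intensity bins (default 100).
#' @param bounds Named list overriding the default box constraints
#'   `s_fac` in \[1e-3, 1e3\], `s_B` in \[-1e3, 1e3\], `s_add` in \[0, 10\].
#' @param control Passed to [stats::optim()] (`maxit` defaults to 500).
#' @return An [ev11_params()] with attribute `"fit"`: list with
#'   `initial_loss`, `final_loss`, `counts`, `convergence`, `message`.
#' @export
fit_ev11 <- function(table, n_bins = 100, bounds = list(), control = list()) {
  prep <- ev11_prepare(table, n_bins)
  dev0 <- normalized_deviations(table, ev11_params(1, 0, 0))
  par0 <- c(sqrt(mean(dev0$delta^2)), 0, 0.01)
  lower <- c(s_fac = 1e-3, s_B = -1e3, s_add = 0)
  upper <- c(s_fac = 1e3, s_B = 1e3, s_add = 10)
  for (nmi in names(bounds)) {
    lower[nmi] <- bounds[[nmi]][1]; upper[nmi] <- bounds[[nmi]][2]
  }
  par0 <- pmin(pmax(par0, lower), upper)
  control <- utils::modifyList(list(maxit = 500), control)
  init <- ev11_objective(par0, prep, gradient = FALSE)
  fit <- optim(par0,
               fn = function(p) ev11_objective(p, prep, gradient = FALSE)$loss,
               gr = function(p) ev11_objective(p, prep)$gradient,
               method = "L-BFGS-B", lower = lower, upper = upper,
               control = control)
  if (!fit$convergence %in% c(0L, 1L))
    stop("Ev11 optimization failed to converge: ", fit$message)
  out <- ev11_params(s_fac = fit$par[1], s_B = fit$par[2], s_add = max(fit$par[3], 0))
  attr(out, "fit") <- list(initial_par = par0, initial_loss = init$loss,
                           final_loss = fit$value, counts = fit$counts,
                           convergence = fit$convergence, message = fit$message)
  out
}
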