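#' Cantor pairing function
#'
#' `pi(k1, k2) = (k1 + k2)(k1 + k2 + 1)/2 + k2`: a bijection from pairs of
#' natural numbers to the naturals, used to build one deterministic seed
#' per Miller index. Exact in double arithmetic for the index magnitudes
#' involved (|k| <= 1e4).
#'
#' @param k1,k2 Non-negative integers (vectorized).
#' @return The paired natural number(s), as doubles.
#' @export
cantor_pair <- function(k1, k2) {
  if (any(k1 < 0) || any(k2 < 0) || any(k1 != floor(k1)) || any(k2 != floor(k2)))
    stop("cantor_pair requires non-negative integers")
  s <- k1 + k2
  s * (s + 1) / 2 + k2
}

#' Deterministic seed from a Miller index
#'
#' Each index component is shifted by +1000 to make it positive, then the
#' Cantor pairing function is applied iteratively:
#' `seed = pi(pi(h + 1000, k + 1000), l + 1000) + extra_offset`. The seed
#' is identical across runs, platforms and any partitioning of the data,
#' which makes per-group random subsampling reproducible in distributed
#' settings. An optional integer offset yields alternative draws.
#'
#' @param h,k,l Miller index components, each with |.| < 1000 (vectorized).
#' @param extra_offset Integer added to the seed (default 0).
#' @return Seed value(s), as doubles.
#' @export
miller_seed <- function(h, k, l, extra_offset = 0) {
  if (any(abs(h) >= 1000) || any(abs(k) >= 1000) || any(abs(l) >= 1000))
    stop("miller_seed requires |h|, |k|, |l| < 1000")
  cantor_pair(cantor_pair(h + 1000, k + 1000), l + 1000) + extra_offset
}

# Map linear pair index p in 1..n(n-1)/2 to (j, k), j < k, enumerating
# lexicographically: (1,2), (1,3), ..., (1,n), (2,3), ...
pair_from_linear <- function(p, n) {
  # cumulative pairs having first member <= j: C(j) = j*n - j(j+1)/2
  cum <- function(j) j * n - j * (j + 1) / 2
  j <- ceiling(n - 0.5 - sqrt((n - 0.5)^2 - 2 * p))
  # guard against sqrt rounding at exact block boundaries
  j <- j - (cum(j - 1) >= p)
  j <- j + (cum(j) < p)
  k <- p - cum(j - 1) + j
  cbind(j, k)
}

#' Deterministic pair subsampling per Miller group
#'
#' Enumerates the unordered pairs of observations within each Miller group
#' (in canonical table order, so lexicographic over sorted observations).
#' When a group has more than `cap` candidate pairs, exactly `cap` are
#' drawn without replacement using a fresh generator seeded from
#' [miller_seed()], so the result is identical for identical inputs no
#' matter how the table was produced or partitioned. Groups with a single
#' observation yield no pairs.
#'
#' @param table A [refl_table()].
#' @param cap Maximum number of pairs per Miller index (default 100).
#' @param extra_offset Seed offset forwarded to [miller_seed()].
#' @return data.table with one row per pair: `h, k, l, group_id, i_row,
#'   j_row` (row numbers of the two members in the canonical observation
#'   table, i_row < j_row), `intensity_i/j`, `sigma_i/j`, `cc_i/j`,
#'   `mean_intensity`, `abs_diff`.
#' @export
subsample_pairs <- function(table, cap = 100, extra_offset = 0) {
  stopifnot(cap >= 1)
  obs <- annotate_groups(table)
  obs[, row_id := .I]
  grp <- obs[n >= 2L, .(h = h[1], k = k[1], l = l[1], n = .N,
                        first_row = min(row_id)), by = group_id]
  if (!nrow(grp))
    return(data.table(h = integer(), k = integer(), l = integer(),
                      group_id = integer(), i_row = integer(), j_row = integer(),
                      intensity_i = numeric(), intensity_j = numeric(),
                      sigma_i = numeric(), sigma_j = numeric(),
                      cc_i = numeric(), cc_j = numeric(),
                      mean_intensity = numeric(), abs_diff = numeric()))
  grp[, npairs := n * (n - 1) / 2]

  full <- grp[npairs <= cap]
  picks <- vector("list", 2L)
  if (nrow(full)) {
    # all pairs, vectorized
    reps <- full$npairs
    gidx <- rep(seq_len(nrow(full)), reps)
    p <- sequence(reps)
    jk <- pair_from_linear(p, full$n[gidx])
    picks[[1L]] <- data.table(gi = full$group_id[gidx],
                              i_loc = jk[, 1], j_loc = jk[, 2],
                              first_row = full$first_row[gidx])
  }
  need <- grp[npairs > cap]
  if (nrow(need)) {
    sampled <- with_preserved_rng({
      lapply(seq_len(nrow(need)), function(i) {
        set_pinned_seed(miller_seed(need$h[i], need$k[i], need$l[i], extra_offset))
        sort(sample.int(need$npairs[i], cap))
      })
    })
    gidx <- rep(seq_len(nrow(need)), each = cap)
    p <- unlist(sampled)
    jk <- pair_from_linear(p, need$n[gidx])
    picks[[2L]] <- data.table(gi = need$group_id[gidx],
                              i_loc = jk[, 1], j_loc = jk[, 2],
                              first_row = need$first_row[gidx])
  }
  sel <- rbindlist(picks)
  sel[, `:=`(i_row = first_row + i_loc - 1L, j_row = first_row + j_loc - 1L)]
  pairs <- data.table(
    h = obs$h[sel$i_row], k = obs$k[sel$i_row], l = obs$l[sel$i_row],
    group_id = sel$gi, i_row = as.integer(sel$i_row), j_row = as.integer(sel$j_row),
    intensity_i = obs$intensity[sel$i_row], intensity_j = obs$intensity[sel$j_row],
    sigma_i = obs$sigma[sel$i_row], sigma_j = obs$sigma[sel$j_row],
    cc_i = obs$cc[sel$i_row], cc_j = obs$cc[sel$j_row],
    mean_intensity = obs$mean_intensity[sel$i_row]
  )
  pairs[, abs_diff := abs(intensity_i - intensity_j)]
  setorder(pairs, group_id, i_row, j_row)
  pairs[]
}

#' Normalized pairwise differences
#'
#' `omega_hjk = |I_hj - I_hk| / sqrt(sigma'_hj^2 + sigma'_hk^2)`: the
#' absolute intensity difference of two symmetry-equivalent observations
#' over the quadrature sum of their calibrated uncertainties. Half-normal
#' with unit scale when the error model is exact and errors are normal.
#'
#' @param pairs Output of [subsample_pairs()].
#' @param params An [mm24_params()].
#' @return The `pairs` table with columns `sp_i`, `sp_j` (calibrated
#'   sigmas) and `omega` added.
#' @export
normalized_pairwise_differences <- function(pairs, params) {
  stopifnot(inherits(params, "mm24_params"))
  out <- copy(as.data.table(pairs))
  out[, sp_i := mm24_sigma(sigma_i, mean_intensity, cc_i, params)]
  out[, sp_j := mm24_sigma(sigma_j, mean_intensity, cc_j, params)]
  out[, omega := abs_diff / sqrt(sp_i^2 + sp_j^2)]
  out[]
}

#' MM24 initialization from binned mean pairwise differences
#'
#' If two observations share true intensity and error SD `sigma_err`, their
#' difference is normal with SD `sqrt(2) * sigma_err` and its absolute
#' value is half-normal with mean `(2/sqrt(pi)) * sigma_err`. The mean raw
#' pairwise difference is therefore computed in 100 even intensity bins
#' spanning `[0, 0.1 * max(<I_h>)]` (Miller indices outside the range are
#' excluded) and `(s_fac, s_add_1)` are fitted by least squares of the bin
#' means against `(2/sqrt(pi)) * s_fac * sqrt(<sigma^2>_b + s_add_1^2 *
#' I_b^2)`, with `I_b` the bin-center intensity and `<sigma^2>_b` the mean
#' squared counting sigma in the bin. The optimizer is started from the
#' anchor given by the first non-empty bin, whose mean difference
#' represents the expected nonzero error of low-intensity reflections and
#' pins the starting `s_fac` at `I ~ 0`. `s_add_0` and `s_add_2` are
#' initialized to 0.001.
#'
#' @param table A [refl_table()].
#' @param pairs Optional pre-computed [subsample_pairs()] result (computed
#'   at `cap`/`extra_offset` defaults otherwise).
#' @param n_bins Number of initialization bins (default 100).
#' @return List with `s_fac`, `s_add_0`, `s_add_1`, `s_add_2`, `upper`
#'   (the binning upper edge, exactly one tenth of the maximum biased
#'   mean) and the diagnostic table `bins`.
#' @export
initialize_mm24 <- function(table, pairs = NULL, n_bins = 100) {
  if (is.null(pairs)) pairs <- subsample_pairs(table)
  if (!nrow(pairs)) stop("no pairwise differences available for initialization")
  obs <- annotate_groups(table)
  upper <- 0.1 * max(obs$mean_intensity)
  if (upper <= 0) stop("maximum biased mean is non-positive; cannot initialize")
  edges <- seq(0, upper, length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-length(edges)]) / 2

  keep <- pairs$mean_intensity >= 0 & pairs$mean_intensity <= upper
  pb <- pmin(findInterval(pairs$mean_intensity[keep], edges, rightmost.closed = TRUE), n_bins)
  okeep <- obs$mean_intensity >= 0 & obs$mean_intensity <= upper
  ob <- pmin(findInterval(obs$mean_intensity[okeep], edges, rightmost.closed = TRUE), n_bins)

  mean_absdiff <- tapply(pairs$abs_diff[keep], factor(pb, levels = seq_len(n_bins)), mean)
  mean_sig2 <- tapply(obs$sigma[okeep]^2, factor(ob, levels = seq_len(n_bins)), mean)
  bins <- data.table(bin = seq_len(n_bins), center = centers,
                     mean_abs_diff = as.numeric(mean_absdiff),
                     mean_sigma2 = as.numeric(mean_sig2))
  usable <- bins[is.finite(mean_abs_diff) & is.finite(mean_sigma2)]
  if (nrow(usable) < 3) {
    warning("fewer than 3 usable initialization bins; falling back to (1.0, 0.05)")
    return(list(s_fac = 1.0, s_add_0 = 0.001, s_add_1 = 0.05, s_add_2 = 0.001,
                upper = upper, bins = bins[]))
  }
  # anchor: expected nonzero error of low-intensity reflections
  anchor <- usable[1]
  s_fac0 <- max(anchor$mean_abs_diff * sqrt(pi) / 2 / sqrt(anchor$mean_sigma2), 1e-3)
  model <- function(p) 2 / sqrt(pi) * p[1] * sqrt(usable$mean_sigma2 + p[2]^2 * usable$center^2)
  fit <- optim(c(s_fac0, 0.05),
               fn = function(p) sum((usable$mean_abs_diff - model(p))^2),
               method = "L-BFGS-B", lower = c(1e-3, 0), upper = c(1e3, 10))
  list(s_fac = fit$par[1], s_add_0 = 0.001, s_add_1 = fit$par[2],
       s_add_2 = 0.001, upper = upper, bins = bins[])
}

# Internal: NLL and analytic gradient for a pair table at a parameter
# vector th = (s_fac, s_add_0, s_add_1, s_add_2 [, log nu]).
mm24_objective <- function(th, pairs, likelihood, fit_nu = FALSE, nu_fixed = NULL,
                           gradient = TRUE) {
  s_fac <- th[1]; a0 <- th[2]; a1 <- th[3]; a2 <- th[4]
  nu <- if (fit_nu) exp(th[5]) else nu_fixed
  e_i <- exp(-a2 * pairs$cc_i); e_j <- exp(-a2 * pairs$cc_j)
  sa_i <- a0 + a1 * e_i;        sa_j <- a0 + a1 * e_j
  I2 <- pairs$mean_intensity^2
  b_i <- pairs$sigma_i^2 + sa_i^2 * I2   # bracket of sigma'^2 / s_fac^2
  b_j <- pairs$sigma_j^2 + sa_j^2 * I2
  D <- s_fac^2 * (b_i + b_j)
  omega <- pairs$abs_diff / sqrt(D)

  # likelihood of the pairwise differences themselves: the kernel density
  # of omega carries a 1/sqrt(D) change-of-variable factor, hence the
  # 0.5 log D term (without it the loss would be unbounded in s_fac).
  if (likelihood == "half_normal") {
    nll <- sum(-half_normal_log_pdf(omega)) + 0.5 * sum(log(D))
    dnll_domega <- omega
  } else {
    nll <- sum(-half_t_log_pdf(omega, nu)) + 0.5 * sum(log(D))
    dnll_domega <- (nu + 1) * omega / (nu + omega^2)
  }
  if (!is.finite(nll)) {
    bad <- which(!is.finite(omega))[1]
    stop("non-finite likelihood (first offending pair index: ",
         if (length(bad)) bad else "unknown", ")")
  }
  if (!gradient) return(list(loss = nll, omega = omega))

  # d omega / d theta = -(omega / (2 D)) dD/dtheta; the log D term adds
  # 1/(2 D) dD/dtheta
  w <- dnll_domega * (-omega / (2 * D)) + 1 / (2 * D)
  dD <- cbind(
    s_fac = 2 * s_fac * (b_i + b_j),
    a0 = s_fac^2 * 2 * I2 * (sa_i + sa_j),
    a1 = s_fac^2 * 2 * I2 * (sa_i * e_i + sa_j * e_j),
    a2 = s_fac^2 * 2 * I2 * (-a1) * (sa_i * pairs$cc_i * e_i + sa_j * pairs$cc_j * e_j)
  )
  grad <- colSums(w * dD)
  if (fit_nu && likelihood == "half_t") {
    u <- omega^2 / nu
    dnll_dnu <- 0.5 * (digamma(nu / 2) - digamma((nu + 1) / 2) + 1 / nu +
                         log1p(u) - (nu + 1) * u / (nu * (1 + u)))
    grad <- c(grad, sum(dnll_dnu) * nu)  # chain rule through log nu
  }
  list(loss = nll, gradient = unname(grad), omega = omega)
}

#' MM24 negative log-likelihood and gradient
#'
#' The negative log-likelihood of the pairwise intensity differences:
#' `NLL = -sum [log p(omega; .) - 0.5 log(sigma'_j^2 + sigma'_k^2)]`
#' under the half-normal or half-t kernel. The second term is the
#' change-of-variable factor from the normalized statistic back to the
#' measured difference; it is what makes the target a proper likelihood
#' with a finite minimizer (it reduces to a constant when the quadrature
#' sigma is one). The analytic gradient is over `(s_fac, s_add_0,
#' s_add_1, s_add_2)` and, for the half-t kernel, `nu` (as d/d nu).
#'
#' @param pairs Output of [subsample_pairs()].
#' @param params An [mm24_params()].
#' @return List with `loss`, `gradient` (named), and the `omega` vector at
#'   these parameters.
#' @export
mm24_loss_and_gradient <- function(pairs, params) {
  stopifnot(inherits(params, "mm24_params"))
  fit_nu <- params$likelihood == "half_t"
  th <- c(params$s_fac, params$s_add_0, params$s_add_1, params$s_add_2,
          if (fit_nu) log(params$nu))
  res <- mm24_objective(th, pairs, params$likelihood, fit_nu = fit_nu,
                        nu_fixed = params$nu)
  nms <- c("s_fac", "s_add_0", "s_add_1", "s_add_2")
  if (fit_nu) {
    res$gradient[5] <- res$gradient[5] / params$nu  # back to d/d nu
    nms <- c(nms, "nu")
  }
  names(res$gradient) <- nms
  res
}

#' Fit the MM24 error model
#'
#' Full calibration pipeline: deterministic pair subsampling, binned
#' mean-difference initialization, and bounded L-BFGS-B minimization of
#' the negative log-likelihood with analytic first derivatives. The
#' degrees of freedom `nu` of the half-t kernel are optimized on a log
#' scale within \[1.5, 200\] unless fixed. Bit-reproducible for identical
#' inputs and `extra_offset`, however the table was assembled.
#'
#' @param table A [refl_table()] whose lattices carry `cc` values.
#' @param likelihood `"half_t"` (default) or `"half_normal"`.
#' @param fix_nu Optional fixed degrees of freedom (half-t only).
#' @param cap Pair cap per Miller index (default 100).
#' @param extra_offset Seed offset for the subsampling (default 0).
#' @param nu_init Starting degrees of freedom (default 10).
#' @param bounds Named list overriding box constraints: `s_fac` in
#'   \[1e-3, 1e3\], `s_add_0` and `s_add_1` in \[0, 10\], `s_add_2` in
#'   \[0, 50\], `nu` in \[1.5, 200\].
#' @param control Passed to [stats::optim()] (`maxit` defaults to 1000).
#' @return An [mm24_params()] with attribute `"fit"`: list with
#'   `initial_par`, `initial_nll`, `final_nll`, `n_pairs`, `counts`,
#'   `convergence`, `message`.
#' @export
fit_mm24 <- function(table, likelihood = c("half_t", "half_normal"),
                     fix_nu = NULL, cap = 100, extra_offset = 0,
                     nu_init = 10, bounds = list(), control = list()) {
  likelihood <- match.arg(likelihood)
  if (any(is.na(table$lattices$cc)))
    stop("every lattice needs a cc value; see lattice_correlations()")
  pairs <- subsample_pairs(table, cap = cap, extra_offset = extra_offset)
  if (!nrow(pairs)) stop("no Miller group has 2 or more observations")
  init <- initialize_mm24(table, pairs = pairs)

  fit_nu <- likelihood == "half_t" && is.null(fix_nu)
  nu_fixed <- if (likelihood == "half_t" && !is.null(fix_nu)) fix_nu else NULL
  lower <- c(s_fac = 1e-3, s_add_0 = 0, s_add_1 = 0, s_add_2 = 0)
  upper <- c(s_fac = 1e3, s_add_0 = 10, s_add_1 = 10, s_add_2 = 50)
  nu_bounds <- if (!is.null(bounds$nu)) bounds$nu else c(1.5, 200)
  for (nmi in intersect(names(bounds), names(lower))) {
    lower[nmi] <- bounds[[nmi]][1]; upper[nmi] <- bounds[[nmi]][2]
  }
  th0 <- c(init$s_fac, init$s_add_0, init$s_add_1, init$s_add_2)
  th0 <- pmin(pmax(th0, lower), upper)
  if (fit_nu) {
    th0 <- c(th0, log(min(max(nu_init, nu_bounds[1]), nu_bounds[2])))
    lower <- c(lower, log_nu = log(nu_bounds[1]))
    upper <- c(upper, log_nu = log(nu_bounds[2]))
  }
  control <- utils::modifyList(list(maxit = 1000), control)
  obj0 <- mm24_objective(th0, pairs, likelihood, fit_nu, nu_fixed, gradient = FALSE)
  fit <- optim(th0,
               fn = function(p) mm24_objective(p, pairs, likelihood, fit_nu,
                                               nu_fixed, gradient = FALSE)$loss,
               gr = function(p) mm24_objective(p, pairs, likelihood, fit_nu,
                                               nu_fixed)$gradient,
               method = "L-BFGS-B", lower = lower, upper = upper,
               control = control)
  if (!fit$convergence %in% c(0L, 1L))
    stop("MM24 optimization failed to converge: ", fit$message)
  nu_out <- if (likelihood == "half_normal") NULL
            else if (fit_nu) exp(fit$par[5]) else fix_nu
  out <- mm24_params(s_fac = fit$par[1], s_add_0 = fit$par[2],
                     s_add_1 = fit$par[3], s_add_2 = fit$par[4],
                     nu = nu_out, likelihood = likelihood)
  attr(out, "fit") <- list(initial_par = th0, initial_nll = obj0$loss,
                           final_nll = fit$value, n_pairs = nrow(pairs),
                           counts = fit$counts, convergence = fit$convergence,
                           message = fit$message)
  out
}
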