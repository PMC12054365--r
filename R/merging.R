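#' Per-lattice correlations to a scaling reference
#'
#' Pearson correlation between each lattice's observed intensities and the
#' reference intensities of the same Miller indices. Lattices sharing
#' fewer than 3 Miller indices with the reference cannot be scored; they
#' are assigned `cc = 0` and flagged with a warning.
#'
#' @param table A [refl_table()].
#' @param reference data.frame with columns `h, k, l, intensity` (merged
#'   reference intensities keyed by Miller index).
#' @return A new `refl_table` with updated lattice `cc` values; the
#'   `"flagged"` attribute lists lattices that could not be scored.
#' @export
lattice_correlations <- function(table, reference) {
  ref <- as.data.table(reference)
  if (!nrow(ref)) stop("empty reference")
  if (!all(c("h", "k", "l", "intensity") %in% names(ref)))
    stop("reference needs columns h, k, l, intensity")
  setnames(ref, "intensity", "ref_intensity")
  obs <- merge(table$observations, ref[, .(h, k, l, ref_intensity)],
               by = c("h", "k", "l"), all.x = TRUE)
  scored <- obs[is.finite(ref_intensity),
                .(cc = if (.N >= 3 && sd(intensity) > 0 && sd(ref_intensity) > 0)
                        cor(intensity, ref_intensity) else NA_real_,
                  n_shared = .N),
                by = lattice_id]
  lat <- copy(table$lattices)
  lat[, cc := scored$cc[match(lattice_id, scored$lattice_id)]]
  flagged <- lat$lattice_id[!is.finite(lat$cc)]
  if (length(flagged)) {
    warning(length(flagged),
            " lattice(s) share fewer than 3 usable reflections with the reference; cc set to 0")
    lat[!is.finite(cc), cc := 0]
  }
  out <- list(observations = copy(table$observations), lattices = lat[])
  class(out) <- "refl_table"
  attr(out, "flagged") <- flagged
  out
}

#' Correlation outlier filter
#'
#' Removes every lattice whose correlation to the scaling reference falls
#' below `threshold`, together with all of its observations. The
#' conventional threshold when data are suspect is 0.1; `threshold = -1`
#' disables filtering (nothing can fall below it).
#'
#' @param table A [refl_table()] with `cc` populated.
#' @param threshold Minimum `cc` to keep a lattice.
#' @return List with `table` (the filtered `refl_table`) and `removed`
#'   (data.table of removed lattices: `lattice_id, cc, n_obs`).
#' @export
correlation_filter <- function(table, threshold) {
  lat <- table$lattices
  if (any(is.na(lat$cc))) stop("cc is not populated for every lattice")
  removed <- lat[cc < threshold]
  kept <- lat[cc >= threshold]
  obs <- table$observations[lattice_id %in% kept$lattice_id]
  out <- list(observations = copy(obs), lattices = copy(kept))
  class(out) <- "refl_table"
  list(table = out, removed = removed[])
}

#' Merge symmetry-equivalent observations
#'
#' Inverse-variance weighting (`w = 1/sigma'^2`) is the maximum-likelihood
#' estimate of the mean: `I_h = sum(w I)/sum(w)` with merged sigma
#' `1/sqrt(sum w)`. The unweighted alternative takes the arithmetic mean
#' with the standard error of the mean from the residuals (falling back to
#' the observation's own sigma for singletons). When `params` is supplied
#' the weights use calibrated sigmas; otherwise the table's sigma column
#' is used as-is.
#'
#' @param table A [refl_table()].
#' @param params Optional [ev11_params()] or [mm24_params()] used to
#'   calibrate sigmas before weighting.
#' @param weighting `"inverse_variance"` (default) or `"unweighted"`.
#' @return data.table with one row per Miller index: `h, k, l, intensity,
#'   sigma, multiplicity, d_spacing`.
#' @export
merge_reflections <- function(table, params = NULL,
                              weighting = c("inverse_variance", "unweighted")) {
  weighting <- match.arg(weighting)
  obs <- annotate_groups(table)
  obs[, sigma_prime := calibrated_sigma_obs(obs, params)]
  if (weighting == "inverse_variance") {
    merged <- obs[, {
      w <- 1 / sigma_prime^2
      .(intensity = sum(w * intensity) / sum(w),
        sigma = 1 / sqrt(sum(w)),
        multiplicity = .N,
        d_spacing = d_spacing[which(is.finite(d_spacing))[1]])
    }, by = .(h, k, l)]
  } else {
    merged <- obs[, {
      m <- mean(intensity)
      s <- if (.N >= 2) sd(intensity) / sqrt(.N) else sigma_prime[1]
      .(intensity = m, sigma = s, multiplicity = .N,
        d_spacing = d_spacing[which(is.finite(d_spacing))[1]])
    }, by = .(h, k, l)]
  }
  merged[]
}

#' Resolution shells with equal reciprocal volume
#'
#' Bin edges evenly spaced in 1/d^3, the standard crystallographic
#' convention giving each shell roughly equal reciprocal-space volume and
#' hence comparable reflection counts.
#'
#' @param d d-spacings (Angstrom) of the reflections to be binned.
#' @param n_bins Number of shells (default 10).
#' @return List with `edges_inv_d3` (increasing, length `n_bins + 1`),
#'   `d_max`/`d_min` per shell, and `assign(d)`: a function mapping
#'   d-spacings to shell indices (1 = lowest resolution).
#' @export
make_resolution_bins <- function(d, n_bins = 10) {
  d <- d[is.finite(d) & d > 0]
  if (!length(d)) stop("no finite positive d-spacings")
  s3 <- 1 / d^3
  edges <- seq(min(s3), max(s3), length.out = n_bins + 1)
  if (diff(range(s3)) == 0) edges <- c(s3[1] - 0.5, s3[1] + 0.5)
  assign_fun <- function(dd) {
    v <- 1 / dd^3
    pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
         length(edges) - 1L)
  }
  list(edges_inv_d3 = edges,
       d_max = 1 / edges[-length(edges)]^(1 / 3),
       d_min = 1 / edges[-1]^(1 / 3),
       n_bins = length(edges) - 1L,
       assign = assign_fun)
}

#' Half-dataset correlation CC1/2
#'
#' Observations of each Miller group are split into two random halves by
#' a per-group generator seeded deterministically from the Miller index
#' ([miller_seed()] with `seed` as the offset), each half is merged, and
#' CC1/2 is the Pearson correlation of the two half-set merged intensities
#' over groups represented in both halves. Reported overall and per
#' resolution shell; shells with fewer than 3 usable groups are undefined
#' (`NA`).
#'
#' @param table A [refl_table()] with d-spacings (for the binned variant).
#' @param resolution_bins Optional result of [make_resolution_bins()]; if
#'   `NULL`, only the overall value is computed.
#' @param seed Integer offset entering every per-group seed (default 0).
#' @param params Optional error-model parameters for inverse-variance
#'   merging of the halves.
#' @param weighting Half-merging rule, as in [merge_reflections()];
#'   default `"unweighted"`.
#' @return List with `overall` (CC1/2 over all usable groups), `bins`
#'   (data.table: `bin, d_max, d_min, n_groups, cc_half`), and `halves`
#'   (per-group half means).
#' @export
cc_half <- function(table, resolution_bins = NULL, seed = 0, params = NULL,
                    weighting = c("unweighted", "inverse_variance")) {
  weighting <- match.arg(weighting)
  obs <- annotate_groups(table)
  obs[, sigma_prime := calibrated_sigma_obs(obs, params)]
  obs <- obs[n >= 2L]
  if (!nrow(obs)) stop("no Miller group has 2 or more observations")

  grp_keys <- obs[, .(h = h[1], k = k[1], l = l[1], n = .N), by = group_id]
  halves_idx <- with_preserved_rng({
    lapply(seq_len(nrow(grp_keys)), function(i) {
      n_i <- grp_keys$n[i]
      set_pinned_seed(miller_seed(grp_keys$h[i], grp_keys$k[i], grp_keys$l[i], seed))
      perm <- sample.int(n_i)
      k1 <- n_i %/% 2L
      if (n_i %% 2L == 1L) k1 <- k1 + rbinom(1, 1, 0.5)  # odd: extra obs placed by RNG
      half <- integer(n_i)
      half[perm <= k1] <- 1L
      half[perm > k1] <- 2L
      half
    })
  })
  obs[, half := unlist(halves_idx)]

  half_merge <- function(I, s, hh, which_half) {
    sel <- hh == which_half
    if (!any(sel)) return(NA_real_)
    if (weighting == "inverse_variance") {
      w <- 1 / s[sel]^2
      sum(w * I[sel]) / sum(w)
    } else mean(I[sel])
  }
  halves <- obs[, .(
    d_spacing = d_spacing[which(is.finite(d_spacing))[1]],
    i1 = half_merge(intensity, sigma_prime, half, 1L),
    i2 = half_merge(intensity, sigma_prime, half, 2L)
  ), by = .(h, k, l)]
  usable <- halves[is.finite(i1) & is.finite(i2)]
  overall <- if (nrow(usable) >= 3) cor(usable$i1, usable$i2) else NA_real_

  bins_out <- NULL
  if (!is.null(resolution_bins)) {
    ub <- usable[is.finite(d_spacing)]
    ub[, bin := resolution_bins$assign(d_spacing)]
    bins_out <- ub[, .(n_groups = .N,
                       cc_half = if (.N >= 3) cor(i1, i2) else NA_real_),
                   keyby = bin]
    bins_out <- merge(data.table(bin = seq_len(resolution_bins$n_bins),
                                 d_max = resolution_bins$d_max,
                                 d_min = resolution_bins$d_min),
                      bins_out, by = "bin", all.x = TRUE)
    bins_out[is.na(n_groups), n_groups := 0L]
  }
  list(overall = overall, bins = bins_out, halves = usable[])
}

#' Mean merged I/sigma per resolution shell
#'
#' @param merged Output of [merge_reflections()] (needs finite
#'   d-spacings).
#' @param resolution_bins Result of [make_resolution_bins()].
#' @return data.table: `bin, d_max, d_min, n_refl, i_over_sigma` (NA for
#'   empty shells).
#' @export
binned_i_over_sigma <- function(merged, resolution_bins) {
  m <- as.data.table(merged)[is.finite(d_spacing)]
  if (!nrow(m)) stop("merged table has no finite d-spacings")
  m[, bin := resolution_bins$assign(d_spacing)]
  out <- m[, .(n_refl = .N, i_over_sigma = mean(intensity / sigma)), keyby = bin]
  out <- merge(data.table(bin = seq_len(resolution_bins$n_bins),
                          d_max = resolution_bins$d_max,
                          d_min = resolution_bins$d_min),
               out, by = "bin", all.x = TRUE)
  out[is.na(n_refl), n_refl := 0L]
  out[]
}

#' Merging statistics per resolution shell
#'
#' Convenience wrapper assembling observation counts, unique reflection
#' counts, mean I/sigma and CC1/2 per shell, in the layout of a standard
#' merging table.
#'
#' @param table A [refl_table()] with d-spacings.
#' @param params Optional error-model parameters for weighting.
#' @param n_bins Number of resolution shells (default 10).
#' @param seed Seed offset for the CC1/2 half split.
#' @return data.table: `bin, d_max, d_min, n_obs, n_unique, multiplicity,
#'   i_over_sigma, cc_half`.
#' @export
merging_stats <- function(table, params = NULL, n_bins = 10, seed = 0) {
  obs <- table$observations[is.finite(d_spacing)]
  if (!nrow(obs)) stop("table has no finite d-spacings")
  rb <- make_resolution_bins(obs$d_spacing, n_bins)
  merged <- merge_reflections(table, params = params)
  ios <- binned_i_over_sigma(merged, rb)
  cch <- cc_half(table, rb, seed = seed, params = params,
                 weighting = if (is.null(params)) "unweighted" else "inverse_variance")
  obs2 <- copy(obs)[, bin := rb$assign(d_spacing)]
  counts <- obs2[, .(n_obs = .N, n_unique = uniqueN(paste(h, k, l))), keyby = bin]
  out <- merge(ios[, .(bin, d_max, d_min, i_over_sigma)], counts, by = "bin", all.x = TRUE)
  out <- merge(out, cch$bins[, .(bin, cc_half)], by = "bin", all.x = TRUE)
  out[is.na(n_obs), `:=`(n_obs = 0L, n_unique = 0L)]
  out[, multiplicity := ifelse(n_unique > 0, n_obs / n_unique, NA_real_)]
  setcolorder(out, c("bin", "d_max", "d_min", "n_obs", "n_unique",
                     "multiplicity", "i_over_sigma", "cc_half"))
  out[]
}
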