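#' Simulation configuration
#'
#' Describes a synthetic serial-crystallography experiment whose
#' statistical structure matches the calibration model exactly: Wilson
#' (exponential) acentric true intensities with resolution falloff
#' `Sigma(d) = scale * exp(-B / (2 d^2))`, Poisson-motivated counting
#' sigmas with an intensity floor, per-lattice quality expressed as a
#' correlation coefficient, and additional error whose SD is
#' `s_fac * sqrt(sigma^2 + s_add(cc)^2 * I^2)` with the same exponential
#' `s_add(cc)` law the calibrator fits (or a mis-specified power law for
#' robustness studies).
#'
#' @param n_miller Number of unique Miller indices.
#' @param multiplicity_mean Mean observations per Miller index (Poisson,
#'   floored at 1).
#' @param cell A [unit_cell()] (default cubic, a = 79 Angstrom).
#' @param d_range Resolution range (Angstrom), `c(d_min, d_max)`.
#' @param wilson_scale,wilson_b Wilson scale and B factor (Angstrom^2) of
#'   `Sigma(d)`.
#' @param n_lattices Number of lattices.
#' @param cc_range Range of per-lattice correlation coefficients, drawn
#'   uniformly from the latent quality.
#' @param cc_map `"exponential"` (model-conforming: the fitted law) or
#'   `"power"` (mis-specified: `s_add = s_add_0 + s_add_1 (1 - cc)^2`).
#' @param intensity_floor,background Counting-noise model: `sigma_hk =
#'   sqrt(max(I_h, floor) + background) / gain`.
#' @param gain Counting-noise scale divisor.
#' @param s_fac,s_add_0,s_add_1,s_add_2 True error-model coefficients
#'   (defaults are the calibration study conditions; `s_fac = 0` gives
#'   noise-free data).
#' @param noise `"normal"` or `"t"` (heavy-tailed additional error).
#' @param nu_true Degrees of freedom of the t noise (SD-standardized;
#'   requires `nu_true > 2`).
#' @param outlier_fraction Fraction of observations replaced by gross
#'   outliers (intensity x `outlier_magnitude`); in \[0, 0.5\].
#' @param outlier_magnitude Outlier inflation factor (default 100).
#' @param seed Mandatory integer seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_miller = 2000, multiplicity_mean = 6,
                       cell = unit_cell(79, 79, 79), d_range = c(1.8, 20),
                       wilson_scale = 1000, wilson_b = 20,
                       n_lattices = 200, cc_range = c(0.2, 0.95),
                       cc_map = c("exponential", "power"),
                       intensity_floor = 1, background = 50, gain = 1,
                       s_fac = 1.2, s_add_0 = 0.01, s_add_1 = 0.15,
                       s_add_2 = 2.0, noise = c("normal", "t"), nu_true = 5,
                       outlier_fraction = 0, outlier_magnitude = 100,
                       seed) {
  if (missing(seed)) stop("seed is mandatory")
  noise <- match.arg(noise)
  cc_map <- match.arg(cc_map)
  stopifnot(n_miller >= 1, multiplicity_mean >= 1, n_lattices >= 1,
            inherits(cell, "unit_cell"), length(d_range) == 2,
            d_range[1] > 0, d_range[2] > d_range[1],
            wilson_scale > 0, s_fac >= 0, s_add_0 >= 0, s_add_1 >= 0,
            outlier_fraction >= 0, outlier_fraction <= 0.5,
            outlier_magnitude > 0,
            cc_range[1] >= -1, cc_range[2] <= 1, cc_range[1] <= cc_range[2])
  if (noise == "t" && nu_true <= 2)
    stop("nu_true must be > 2 so the t noise has a finite SD")
  structure(as.list(environment()), class = "sim_config")
}

s_add_true <- function(cc, config) {
  if (config$cc_map == "exponential")
    config$s_add_0 + config$s_add_1 * exp(-config$s_add_2 * cc)
  else
    config$s_add_0 + config$s_add_1 * (1 - cc)^2
}

# Candidate Miller indices inside the resolution window, on a positive
# grid large enough to cover n_miller picks.
miller_candidates <- function(config) {
  hmax <- min(ceiling(max(config$cell$a, config$cell$b, config$cell$c) /
                        config$d_range[1]) + 1L, 999L)
  grid <- as.data.table(expand.grid(h = 0:hmax, k = 0:hmax, l = 0:hmax))
  grid <- grid[h + k + l > 0]
  grid[, d := compute_d_spacing(config$cell, cbind(h, k, l))]
  grid <- grid[d >= config$d_range[1] & d <= config$d_range[2]]
  if (nrow(grid) < config$n_miller)
    stop("resolution window holds only ", nrow(grid),
         " Miller indices; reduce n_miller or widen d_range")
  grid
}

#' Simulate a synthetic serial-crystallography experiment
#'
#' Draws true intensities from the Wilson distribution with resolution
#' falloff, assigns each observation to a lattice, applies counting noise
#' plus intensity-proportional additional error at the lattice's quality
#' level, and returns both the observable table and the full ground
#' truth. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return List with `table` (a [refl_table()]; lattice records carry the
#'   generating cc) and `truth`: `miller` (true intensities and
#'   d-spacings), `observations` (per-row true error SD and outlier
#'   flag), `lattices` (latent quality, generating cc, realized cc
#'   against the true intensities), and `params` (the true parameter
#'   values).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_preserved_rng({
    set_pinned_seed(config$seed)
    cand <- miller_candidates(config)
    pick <- cand[sample.int(nrow(cand), config$n_miller)]
    Sigma <- config$wilson_scale * exp(-config$wilson_b / (2 * pick$d^2))
    pick[, I_true := rexp(.N) * Sigma]

    mult <- pmax(1L, rpois(config$n_miller, config$multiplicity_mean))
    gi <- rep(seq_len(config$n_miller), mult)
    n_obs <- length(gi)

    lat_ids <- sprintf("lat%04d", seq_len(config$n_lattices))
    q <- runif(config$n_lattices)
    cc_gen <- config$cc_range[1] + diff(config$cc_range) * q
    lat_of_obs <- sample.int(config$n_lattices, n_obs, replace = TRUE)

    I_h <- pick$I_true[gi]
    sigma_count <- sqrt(pmax(I_h, config$intensity_floor) + config$background) /
      config$gain
    sadd <- s_add_true(cc_gen[lat_of_obs], config)
    sigma_err <- config$s_fac * sqrt(sigma_count^2 + sadd^2 * I_h^2)
    eps <- if (config$noise == "normal") rnorm(n_obs, 0, 1)
           else rt(n_obs, df = config$nu_true) / sqrt(config$nu_true / (config$nu_true - 2))
    I_obs <- I_h + sigma_err * eps

    is_outlier <- rep(FALSE, n_obs)
    n_out <- round(config$outlier_fraction * n_obs)
    if (n_out > 0) {
      idx <- sample.int(n_obs, n_out)
      I_obs[idx] <- I_obs[idx] * config$outlier_magnitude
      is_outlier[idx] <- TRUE
    }

    obs <- data.table(h = pick$h[gi], k = pick$k[gi], l = pick$l[gi],
                      lattice_id = lat_ids[lat_of_obs],
                      intensity = I_obs, sigma = sigma_count,
                      d_spacing = pick$d[gi])
    # realized correlation of each lattice against the true intensities
    cc_real <- vapply(seq_len(config$n_lattices), function(i) {
      sel <- lat_of_obs == i
      if (sum(sel) >= 3 && sd(I_h[sel]) > 0) cor(I_obs[sel], I_h[sel]) else NA_real_
    }, numeric(1))

    table <- refl_table(obs,
                        data.table(lattice_id = lat_ids, cc = cc_gen))
    truth <- list(
      miller = pick[, .(h, k, l, d, I_true)],
      observations = data.table(h = pick$h[gi], k = pick$k[gi], l = pick$l[gi],
                                lattice_id = lat_ids[lat_of_obs],
                                I_true = I_h, sigma_error = sigma_err,
                                outlier = is_outlier),
      lattices = data.table(lattice_id = lat_ids, q = q, cc_gen = cc_gen,
                            cc_realized = cc_real),
      params = list(s_fac = config$s_fac, s_add_0 = config$s_add_0,
                    s_add_1 = config$s_add_1, s_add_2 = config$s_add_2,
                    noise = config$noise, nu_true = config$nu_true),
      config = config
    )
    list(table = table, truth = truth)
  })
}

fixture_configs <- list(
  tiny = function() sim_config(n_miller = 20, multiplicity_mean = 4,
                               n_lattices = 5, seed = 101),
  calibration = function() sim_config(n_miller = 20000, multiplicity_mean = 5,
                                      n_lattices = 500, seed = 202),
  robustness = function() sim_config(n_miller = 20000, multiplicity_mean = 5,
                                     n_lattices = 500,
                                     outlier_fraction = 0.01, seed = 303)
)

#' Write a canned synthetic fixture to disk
#'
#' Three named configurations used throughout the test suite: `tiny`
#' (20 Miller indices, ~4 observations each), `calibration` (20000
#' groups) and `robustness` (`calibration` plus 1% gross outliers).
#' Outputs the native TSV tables, ground-truth tables and a JSON manifest
#' echoing the configuration; byte-stable across runs.
#'
#' @param name One of `"tiny"`, `"calibration"`, `"robustness"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the file paths written.
#' @export
make_fixture <- function(name = c("tiny", "calibration", "robustness"), dir) {
  name <- match.arg(name)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  config <- fixture_configs[[name]]()
  sim <- simulate_experiment(config)
  paths <- list(
    reflections = file.path(dir, paste0(name, "_reflections.tsv")),
    lattices = file.path(dir, paste0(name, "_lattices.tsv")),
    truth_miller = file.path(dir, paste0(name, "_truth_miller.tsv")),
    truth_lattices = file.path(dir, paste0(name, "_truth_lattices.tsv")),
    manifest = file.path(dir, paste0(name, "_manifest.json"))
  )
  write_unmerged_table(sim$table, paths$reflections, paths$lattices)
  fwrite(sim$truth$miller, paths$truth_miller, sep = "\t")
  fwrite(sim$truth$lattices, paths$truth_lattices, sep = "\t")
  cfg <- config
  cfg$cell <- unclass(cfg$cell)
  cfg <- cfg[!vapply(cfg, is.function, logical(1))]
  manifest <- list(
    fixture = name,
    config = cfg,
    seed = config$seed,
    n_observations = n_observations(sim$table),
    n_outliers = sum(sim$truth$observations$outlier),
    files = lapply(paths[c("reflections", "lattices", "truth_miller",
                           "truth_lattices")], basename)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
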