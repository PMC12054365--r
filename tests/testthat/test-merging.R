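make_ref_from_truth <- function(sim) {
  tr <- sim$truth$miller
  data.frame(h = tr$h, k = tr$k, l = tr$l, intensity = tr$I_true)
}

test_that("lattice correlations match affine, negated and brute-force cases", {
  set.seed(31)
  n <- 20
  ref <- data.frame(h = 1:n, k = 0, l = 0, intensity = rexp(n, 1 / 100))
  aff <- data.frame(h = 1:n, k = 0, l = 0, lattice_id = "aff",
                    intensity = 3 * ref$intensity + 7, sigma = 1)
  neg <- data.frame(h = 1:n, k = 0, l = 0, lattice_id = "neg",
                    intensity = -ref$intensity, sigma = 1)
  rnd_i <- ref$intensity + rnorm(n, 0, 50)
  rnd <- data.frame(h = 1:n, k = 0, l = 0, lattice_id = "rnd",
                    intensity = rnd_i, sigma = 1)
  tab <- refl_table(rbind(aff, neg, rnd))
  out <- lattice_correlations(tab, ref)
  lat <- out$lattices
  expect_equal(lat$cc[lat$lattice_id == "aff"], 1)
  expect_equal(lat$cc[lat$lattice_id == "neg"], -1)
  # brute-force Pearson, coded independently of cor()
  x <- rnd_i; y <- ref$intensity
  cc_bf <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(lat$cc[lat$lattice_id == "rnd"], cc_bf, tolerance = 1e-12)
  expect_error(lattice_correlations(tab, ref[0, ]), "empty")
})

test_that("lattices sharing too few reflections are flagged with cc = 0", {
  obs <- data.frame(h = c(1, 2, 3, 4, 9), k = 0, l = 0,
                    lattice_id = c("a", "a", "a", "a", "b"),
                    intensity = c(5, 9, 2, 7, 1), sigma = 1)
  ref <- data.frame(h = 1:4, k = 0, l = 0, intensity = c(4, 10, 1, 8))
  expect_warning(out <- lattice_correlations(refl_table(obs), ref), "fewer than 3")
  expect_equal(out$lattices$cc[out$lattices$lattice_id == "b"], 0)
  expect_equal(attr(out, "flagged"), "b")
})

test_that("the correlation filter removes exactly the sub-threshold lattices", {
  obs <- data.frame(h = rep(1:4, 3), k = 0, l = 0,
                    lattice_id = rep(c("a", "b", "c"), each = 4),
                    intensity = rnorm(12, 100, 5), sigma = 1)
  lat <- data.frame(lattice_id = c("a", "b", "c"), cc = c(0.05, 0.3, 0.9))
  tab <- refl_table(obs, lat)
  f <- correlation_filter(tab, 0.1)
  expect_equal(f$removed$lattice_id, "a")
  expect_equal(n_observations(f$table), 8)
  # threshold -1 is the identity
  f0 <- correlation_filter(tab, -1)
  expect_equal(nrow(f0$removed), 0)
  expect_equal(f0$table$observations, tab$observations)
  # a threshold above 1 removes everything
  fall <- correlation_filter(tab, 1 + 1e-9)
  expect_equal(nrow(fall$removed), 3)
  expect_equal(n_observations(fall$table), 0)
})

test_that("weighted merging matches hand case and brute-force minimizer", {
  tab <- refl_table(data.frame(h = 1, k = 2, l = 3,
                               lattice_id = c("a", "b"),
                               intensity = c(10, 20), sigma = c(1, 2)))
  m <- merge_reflections(tab)
  expect_equal(m$intensity, 12)
  expect_equal(m$sigma, 0.894427190999916, tolerance = 1e-12)
  expect_equal(m$multiplicity, 2)
  # weighted mean minimizes sum w (I - x)^2 (independent 1-d optimizer)
  set.seed(77)
  I <- rnorm(9, 50, 10); s <- runif(9, 0.5, 3)
  tab2 <- refl_table(data.frame(h = 5, k = 5, l = 5,
                                lattice_id = sprintf("L%d", 1:9),
                                intensity = I, sigma = s))
  m2 <- merge_reflections(tab2)
  opt <- optimize(function(x) sum((I - x)^2 / s^2), range(I))
  expect_equal(m2$intensity, opt$minimum, tolerance = 1e-6)
  # equal sigmas: weighted equals unweighted arithmetic mean
  tab3 <- refl_table(data.frame(h = 1, k = 1, l = 1,
                                lattice_id = c("a", "b", "c"),
                                intensity = c(4, 5, 9), sigma = 2))
  expect_equal(merge_reflections(tab3)$intensity,
               merge_reflections(tab3, weighting = "unweighted")$intensity,
               tolerance = 1e-12)
})

test_that("filter-then-merge equals merge of the surviving lattices", {
  sim <- sim_default()
  tab <- sim$table
  f <- correlation_filter(tab, 0.5)
  m1 <- merge_reflections(f$table)
  keep <- tab$lattices$lattice_id[tab$lattices$cc >= 0.5]
  obs2 <- tab$observations[tab$observations$lattice_id %in% keep]
  m2 <- merge_reflections(refl_table(obs2, tab$lattices[tab$lattices$lattice_id %in% keep]))
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("merged sigmas predict the empirical spread of merged intensities", {
  sim <- cached("zscore", {
    simulate_experiment(sim_config(n_miller = 2500, multiplicity_mean = 6,
                                   n_lattices = 300, seed = 7006))
  })
  truth <- sim$truth$params
  params <- mm24_params(truth$s_fac, truth$s_add_0, truth$s_add_1,
                        truth$s_add_2, likelihood = "half_normal")
  merged <- merge_reflections(sim$table, params = params)
  key <- paste(merged$h, merged$k, merged$l)
  tr <- sim$truth$miller
  itrue <- tr$I_true[match(key, paste(tr$h, tr$k, tr$l))]
  z <- (merged$intensity - itrue) / merged$sigma
  expect_gt(sd(z), 0.93)
  expect_lt(sd(z), 1.07)
})

test_that("CC1/2 is exactly 1 on duplicated observations and deterministic", {
  set.seed(13)
  n <- 400
  I <- rexp(n, 1 / 200)
  obs <- data.frame(h = rep(1:n, each = 2), k = 1, l = 1,
                    lattice_id = rep(c("a", "b"), n),
                    intensity = rep(I, each = 2), sigma = 1,
                    d_spacing = rep(runif(n, 1.5, 10), each = 2))
  tab <- refl_table(obs)
  cc <- cc_half(tab)
  expect_equal(cc$overall, 1)
  # pure noise: no signal variance across Miller indices
  obs$intensity <- rnorm(2 * n, 100, 10)
  cc0 <- cc_half(refl_table(obs))
  expect_lt(abs(cc0$overall), 3 / sqrt(n))
  # fixed seed: bit-identical repeats; different seed changes the split
  cc1 <- cc_half(refl_table(obs), seed = 0)
  cc2 <- cc_half(refl_table(obs), seed = 0)
  expect_identical(cc1$overall, cc2$overall)
  cc3 <- cc_half(refl_table(obs), seed = 1)
  expect_false(identical(cc1$overall, cc3$overall))
})

test_that("binned I/sigma matches a group-by oracle and is homogeneous", {
  sim <- sim_default()
  merged <- merge_reflections(sim$table)
  rb <- make_resolution_bins(merged$d_spacing, 8)
  ios <- binned_i_over_sigma(merged, rb)
  # independent group-by mean
  bin_of <- rb$assign(merged$d_spacing)
  oracle <- tapply(merged$intensity / merged$sigma, bin_of, mean)
  expect_equal(ios$i_over_sigma[as.integer(names(oracle))],
               as.numeric(oracle), tolerance = 1e-12)
  # halving every sigma doubles every bin mean
  merged2 <- data.table::copy(merged)[, sigma := sigma / 2]
  ios2 <- binned_i_over_sigma(merged2, rb)
  expect_equal(ios2$i_over_sigma, 2 * ios$i_over_sigma, tolerance = 1e-12)
  # single reflection alone in a bin
  single <- data.frame(h = 1, k = 0, l = 0, intensity = 12, sigma = 2,
                       multiplicity = 1, d_spacing = 3)
  rb1 <- make_resolution_bins(3, 1)
  expect_equal(binned_i_over_sigma(single, rb1)$i_over_sigma, 6)
})

test_that("merging_stats assembles a coherent shell table", {
  sim <- sim_default()
  st <- merging_stats(sim$table, n_bins = 8)
  expect_equal(nrow(st), 8)
  expect_equal(sum(st$n_obs), n_observations(sim$table))
  expect_true(all(st$cc_half >= -1 & st$cc_half <= 1, na.rm = TRUE))
  expect_true(all(st$d_max >= st$d_min))
})
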