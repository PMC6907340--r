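# Experiment grid, summary statistics and result I/O.

make_traj <- function(breeding, passive = NULL) {
  tr <- data.frame(year = seq_along(breeding), pop = "breeding", n = 100,
                   mean_m = 0, mean_d = 0, mean_total = breeding,
                   sd_total = 1, mean_F = 0)
  if (!is.null(passive))
    tr <- rbind(tr, data.frame(year = seq_along(passive), pop = "passive",
                               n = 100, mean_m = 0, mean_d = 0,
                               mean_total = passive, sd_total = 1,
                               mean_F = 0))
  tr
}

test_that("the full parameter grid enumerates exactly 408 settings", {
  g <- enumerate_grid()
  expect_equal(nrow(g), 408L)
  # no q > 0 with absent or infinite passive population
  expect_false(any((g$N_p == 0 | is.infinite(g$N_p)) & g$q > 0))
  # restricted grid: 1 x 2 x 4 x 1 x 2 = 16
  g2 <- enumerate_grid(N_b = 500, N_p = c(0, Inf), q = 0)
  expect_equal(nrow(g2), 16L)
})

test_that("genetic gain and its decomposition are plain cohort arithmetic", {
  tr <- make_traj(seq(0, 1.9, by = 0.1))   # slope 0.1/year
  expect_equal(genetic_gain(tr, 5, 20), 1.5)
  expect_equal(genetic_gain(tr, 5, 5), 0)
  expect_error(genetic_gain(tr, 5, 25), "cover")
  tr2 <- make_traj(rep(1, 20))
  expect_equal(genetic_gain(tr2), 0)
  # decomposition
  tr3 <- make_traj(seq(0, 1.9, by = 0.1))
  tr3$mean_m <- seq(0, 1.9, by = 0.1) / 4
  tr3$mean_d <- 3 * seq(0, 1.9, by = 0.1) / 4
  d <- decompose_gain(tr3)
  expect_equal(d$ratio, 3)
  expect_equal(d$larger, "direct")
  tr4 <- make_traj(seq(0, 1.9, by = 0.1))
  tr4$mean_m <- seq(0, 1.9, by = 0.1); tr4$mean_d <- 0 * tr4$mean_m
  expect_true(is.na(decompose_gain(tr4)$ratio))
})

test_that("genetic lag is gap over slope on matching linear ramps", {
  b <- 0.2 * (1:20)
  expect_equal(genetic_lag(make_traj(b, b)), 0)
  # passive = breeding shifted right by 3 years
  p <- 0.2 * pmax(1:20 - 3, 0)
  expect_equal(genetic_lag(make_traj(b, p)), 3)
  expect_warning(l <- genetic_lag(make_traj(rep(0, 20), rep(0, 20))),
                 "slope")
  expect_true(is.na(l))
})

test_that("gain-p correlation handles linear and degenerate inputs", {
  d <- data.frame(p = c(0, 0.25, 0.5, 1), gain = c(0.1, 0.6, 1.1, 2.1))
  expect_equal(gain_p_correlation(d), 1)
  expect_warning(r <- gain_p_correlation(data.frame(p = c(0, .5, 1),
                                                    gain = rep(1, 3))),
                 "undefined")
  expect_true(is.na(r))
  expect_error(gain_p_correlation(data.frame(p = 0, gain = 1)), "3 settings")
})

test_that("run_grid produces replicate and aggregate rows deterministically", {
  g <- data.frame(N_b = 50, N_p = 0, N_s = 2, q = 0, sigma_Amd = -0.75)
  out <- run_grid(g, replicates = 2, seed = 3, years = 6,
                  dam_fraction = 0.2)
  expect_equal(nrow(out$replicates), 2L)
  expect_equal(nrow(out$summary), 1L)
  expect_equal(out$summary$gain_5_20, mean(out$replicates$gain_5_20))
  out2 <- run_grid(g, replicates = 2, seed = 3, years = 6,
                   dam_fraction = 0.2)
  expect_identical(out$replicates, out2$replicates)
})

test_that("results round-trip through CSV and the manifest stores the seed", {
  g <- data.frame(N_b = 50, N_p = 0, N_s = 2, q = 0, sigma_Amd = -0.75)
  out <- run_grid(g, replicates = 1, seed = 11, years = 6,
                  dam_fraction = 0.2)
  dir <- tempfile("results")
  files <- write_results(out, dir, manifest = list(seed = 11, grid = g))
  reps <- read.csv(file.path(dir, "beebreedsim_replicates.csv"))
  expect_equal(reps$gain_5_20, out$replicates$gain_5_20)
  man <- jsonlite::read_json(file.path(dir, "beebreedsim_manifest.json"))
  expect_equal(man$seed, 11L)
  # empty results still give a header-only file
  empty <- list(replicates = out$replicates[0, ])
  write_results(empty, dir, prefix = "empty")
  e <- read.csv(file.path(dir, "empty_replicates.csv"))
  expect_equal(nrow(e), 0L)
  expect_equal(names(e), names(out$replicates))
  unlink(dir, recursive = TRUE)
})

test_that("finite-locus replicates run and agree with the infinitesimal model at small scale", {
  cfg_fl <- scheme_config(N_b = 50, N_p = 0, N_s = 2, q = 0, years = 8,
                          dam_fraction = 0.2, model = "finite_locus",
                          n_loci = 200)
  res <- run_replicate(cfg_fl, 21)
  tr <- res$trajectory
  expect_true(all(is.na(tr$mean_F)))
  expect_equal(sort(unique(tr$year)), 1:8)
  # positive response under selection
  expect_gt(genetic_gain(tr, 2, 8), 0)
})

test_that("long-term runner reports response and SD loss per scheme", {
  out <- run_long_term(years = 10, replicates = 1, seed = 2, N_b = 50,
                       N_p = 20, q = 0.5, n_loci = 100,
                       schemes = c("uncontrolled", "controlled_relaxed"))
  expect_equal(nrow(out$summary), 2L)
  expect_true(all(is.finite(out$summary$response)))
  expect_true(all(out$summary$sd_loss_pct <= 100))
})
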