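# Yearly population dynamics of the breeding scheme.

small_cfg <- function(...) {
  scheme_config(N_b = 50, N_p = 20, N_s = 3, q = 0.5, years = 8,
                dam_fraction = 0.2, ...)
}

test_that("configuration constraints are enforced", {
  expect_error(scheme_config(N_p = 0, q = 0.5), "q must be 0")
  expect_error(scheme_config(N_p = Inf, q = 0.25), "q must be 0")
  expect_error(scheme_config(N_b = 100, N_s = 200), "stations")
  expect_warning(scheme_config(N_b = 56, N_p = 0, q = 0,
                               dam_fraction = 0.2, daughters_per_dam = 5),
                 "cyclically")
})

test_that("initialization fills two base cohorts with zero-mean TBVs", {
  set.seed(61)
  cfg <- scheme_config(N_b = 500, N_p = 0, N_s = 5, q = 0, years = 6)
  st <- initialize_population(cfg)
  tr <- st$traj
  tr <- do.call(rbind, tr)
  expect_equal(tr$n, rep(500, 2))
  se <- sqrt(3 / 500)  # total TBV variance is 2.25 at the base
  expect_true(all(abs(tr$mean_total) < 4 * se))
  expect_true(all(tr$mean_F == 0))
  # no PQ instantiated when N_p = 0; none either for infinite N_p
  expect_equal(sum(st$cat[seq_len(st$nq)] == 3L), 0)
  cfg_inf <- scheme_config(N_b = 50, N_p = Inf, N_s = 0, q = 0, years = 6)
  st_inf <- initialize_population(cfg_inf)
  expect_equal(sum(st_inf$cat[seq_len(st_inf$nq)] == 3L), 0)
})

test_that("replicates are bit-reproducible", {
  cfg <- small_cfg()
  r1 <- run_replicate(cfg, 7)
  r2 <- run_replicate(cfg, 7)
  expect_identical(r1$trajectory, r2$trajectory)
  r3 <- run_replicate(cfg, 8)
  expect_false(identical(r3$trajectory, r1$trajectory))
})

test_that("cohort sizes are conserved every year", {
  res <- run_replicate(small_cfg(), 3)
  tr <- res$trajectory
  expect_true(all(tr$n[tr$pop == "breeding"] == 50))
  expect_true(all(tr$n[tr$pop == "passive"] == 20))
  expect_equal(sort(unique(tr$year)), 1:8)
})

test_that("controlled matings use a single station's DPQs per queen", {
  res <- run_replicate(small_cfg(), 4, keep_state = TRUE)
  st <- res$state
  bq <- which(st$cat[seq_len(st$nq)] == 1L & st$byear[seq_len(st$nq)] >= 3L)
  for (i in bq[1:20]) {
    dd <- st$mate_dd[i, ]
    expect_true(all(st$cat[dd] == 2L))          # DPQ dams only
    expect_equal(length(unique(st$byear[dd])), 1L)
    # all drone dams belong to the same sister group (same dam)
    expect_equal(length(unique(st$dam[dd])), 1L)
  }
})

test_that("drone dams are drawn uniformly among a station's DPQs", {
  set.seed(62)
  cfg <- scheme_config(N_b = 100, N_p = 0, N_s = 1, q = 0, years = 4,
                       dam_fraction = 0.2)
  res <- run_replicate(cfg, 5, keep_state = TRUE)
  st <- res$state
  bq4 <- which(st$cat[seq_len(st$nq)] == 1L & st$byear[seq_len(st$nq)] == 4L)
  dd <- as.vector(st$mate_dd[bq4, ])
  counts <- table(dd)
  expect_equal(length(counts), 8L)
  n <- length(dd)
  expect_true(all(abs(counts / n - 1 / 8) < 3 * sqrt(1 / 8 * 7 / 8 / n)))
})

test_that("uncontrolled drone dams hit BQ with probability N_b/(N_b+N_p)", {
  set.seed(63)
  cfg <- scheme_config(N_b = 200, N_p = 200, N_s = 0, q = 0, years = 5)
  res <- run_replicate(cfg, 6, keep_state = TRUE)
  st <- res$state
  bq5 <- which(st$cat[seq_len(st$nq)] == 1L & st$byear[seq_len(st$nq)] == 5L)
  dd <- as.vector(st$mate_dd[bq5, ])
  p_hat <- mean(st$cat[dd] == 1L)
  n <- length(dd)
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / n))
  # drone dams are aged 1-3 relative to the mating year
  expect_true(all(st$byear[dd] %in% 2:4))
})

test_that("infinite passive population drones look like base drones", {
  set.seed(64)
  cfg <- scheme_config(N_b = 300, N_p = Inf, N_s = 0, q = 0, years = 4)
  res <- run_replicate(cfg, 7, keep_state = TRUE)
  st <- res$state
  bq <- which(st$cat[seq_len(st$nq)] == 1L & st$byear[seq_len(st$nq)] == 4L)
  tot <- as.vector(st$mate_m[bq, ] + st$mate_d[bq, ])
  # Var(m + d) under 2 Sigma_A = 2 * (1 + 2 - 1.5) = 3
  n <- length(tot)
  expect_lt(abs(var(tot) - 3), 4 * 3 * sqrt(2 / n))
  expect_true(all(st$mate_dd[bq, ] == 0L))
})

test_that("passive cohorts respect the q dam-source split exactly", {
  set.seed(65)
  cfg <- scheme_config(N_b = 60, N_p = 40, N_s = 2, q = 0.5, years = 5,
                       dam_fraction = 0.2)
  res <- run_replicate(cfg, 8, keep_state = TRUE)
  st <- res$state
  pq5 <- which(st$cat[seq_len(st$nq)] == 3L & st$byear[seq_len(st$nq)] == 5L)
  dam_cat <- st$cat[st$dam[pq5]]
  expect_equal(sum(dam_cat == 1L), 20L)   # round(0.5 * 40)
  expect_equal(sum(dam_cat == 3L), 20L)
  # q = 1: all PQ have BQ dams
  cfg1 <- scheme_config(N_b = 60, N_p = 40, N_s = 2, q = 1, years = 5,
                        dam_fraction = 0.2)
  res1 <- run_replicate(cfg1, 9, keep_state = TRUE)
  st1 <- res1$state
  pq <- which(st1$cat[seq_len(st1$nq)] == 3L & st1$byear[seq_len(st1$nq)] == 5L)
  expect_true(all(st1$cat[st1$dam[pq]] == 1L))
})

test_that("dam selection picks the criterion top fraction with id tie-breaks", {
  res <- run_replicate(small_cfg(), 10, keep_state = TRUE)
  st <- res$state
  st$year <- st$year + 1L
  cohort <- which(st$cat[seq_len(st$nq)] == 1L &
                    st$byear[seq_len(st$nq)] == st$year - 2L)
  crit <- rep(NA_real_, st$nq)
  crit[cohort] <- rnorm(length(cohort))
  dams <- select_dams(st, crit)
  expect_equal(sort(dams),
               sort(cohort[order(-crit[cohort])[seq_len(st$cfg$n_dams)]]))
  # exact ties resolve by ascending queen index
  crit[cohort] <- 1
  dams_tie <- select_dams(st, crit)
  expect_equal(dams_tie, sort(cohort)[seq_len(st$cfg$n_dams)])
})

test_that("uncontrolled runs record all sires as unknown", {
  res <- run_replicate(scheme_config(N_b = 50, N_p = 0, N_s = 0, q = 0,
                                     years = 6, dam_fraction = 0.2), 11,
                       keep_state = TRUE)
  st <- res$state
  ped <- as_bee_pedigree(st)
  expect_true(all(ped$records$sire_ref == 0L))
  expect_equal(length(ped$stations), 0L)
})

test_that("incremental engines agree with the standalone pedigree machinery", {
  res <- run_replicate(small_cfg(), 12, keep_state = TRUE)
  st <- res$state
  # true inbreeding: incremental window vs full-pedigree recursion
  fp <- as_full_pedigree(st)
  K <- kinship_matrix(fp$ped)
  Ftrue <- vapply(seq_len(st$nq), function(i) {
    qid <- fp$queen_id[i]
    d <- fp$ped$dam_id[qid]
    if (d == 0) 0 else K[d, fp$ped$sire_id[qid]]
  }, 0)
  expect_equal(st$Fq[seq_len(st$nq)], Ftrue, tolerance = 1e-12)
  # observed model: incremental A^-1 vs dense oracle on the exported pedigree
  op <- as_bee_pedigree(st)
  Ad <- build_relationship_dense(op, cap = 5000)
  A1 <- as.matrix(current_a_inverse(st))
  expect_lt(max(abs(A1 %*% Ad - diag(nrow(Ad)))), 1e-8)
})

test_that("breeding-cohort inbreeding accumulates under controlled mating", {
  cfg <- scheme_config(N_b = 100, N_p = 0, N_s = 2, q = 0, years = 12,
                       dam_fraction = 0.2)
  res <- run_replicate(cfg, 13)
  tr <- res$trajectory
  f <- tr$mean_F[tr$pop == "breeding"]
  # accumulation with Monte-Carlo wiggle: clear upward trend, no big drops
  expect_gt(coef(lm(f ~ seq_along(f)))[[2]], 0)
  expect_gt(mean(f[9:12]), mean(f[3:6]))
  expect_gt(f[12], 0)
})
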