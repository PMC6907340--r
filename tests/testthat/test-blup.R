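# Mixed-model evaluation of maternal and direct effects.

vc <- variance_components()

# small observed pedigree: b base queens, each with a worker group, and a
# record per colony
base_colonies <- function(b) {
  rec <- data.frame(id = seq_len(2 * b),
                    kind = rep(c("queen", "worker"), each = b),
                    dam_id = c(rep(0L, b), seq_len(b)),
                    sire_ref = 0L, birth_year = 1L)
  bee_pedigree(rec)
}

test_that("no phenotypes give all-zero EBVs", {
  ped <- base_colonies(3)
  Ainv <- build_a_inverse(ped)
  ph <- data.frame(queen = integer(), worker = integer(), y = numeric())
  ebv <- solve_mme(assemble_mme(ph, Ainv, vc))
  expect_equal(ebv$ebv_m, rep(0, 6))
  expect_equal(ebv$ebv_d, rep(0, 6))
})

test_that("equations are symmetric and reject dangling references", {
  ped <- base_colonies(3)
  Ainv <- build_a_inverse(ped)
  ph <- data.frame(queen = 1:3, worker = 4:6, y = c(1, -1, 0.5))
  mme <- assemble_mme(ph, Ainv, vc)
  expect_lt(max(abs(mme$C - Matrix::t(mme$C))), 1e-10)
  expect_error(assemble_mme(data.frame(queen = 9, worker = 4, y = 1),
                            Ainv, vc), "outside")
})

test_that("sparse solution matches a dense solve and shrinks records", {
  ped <- base_colonies(2)
  Ainv <- build_a_inverse(ped)
  ph <- data.frame(queen = 1:2, worker = 3:4, y = c(1, -1))
  mme <- assemble_mme(ph, Ainv, vc)
  sol_dense <- solve(as.matrix(mme$C), mme$rhs)
  ebv <- solve_mme(mme)
  expect_equal(ebv$ebv_m, sol_dense[2:5], tolerance = 1e-10)
  expect_equal(ebv$ebv_d, sol_dense[6:9], tolerance = 1e-10)
  # shrinkage: worker-group criterion has the record's sign, smaller size
  expect_gt(ebv$criterion[3], 0)
  expect_lt(ebv$criterion[3], 1)
  expect_equal(ebv$criterion[3], -ebv$criterion[4], tolerance = 1e-10)
})

test_that("a 20-colony system matches the dense oracle elementwise", {
  set.seed(31)
  ped <- random_observed_pedigree(n_base = 6, n_stations = 2, n_g2 = 10,
                                  n_g3 = 4, dpq = 4)
  r <- ped$records
  Ainv <- build_a_inverse(ped)
  queens <- which(r$kind == "worker")
  ph <- data.frame(queen = r$dam_id[queens], worker = queens,
                   y = rnorm(length(queens)))
  mme <- assemble_mme(ph, Ainv, vc)
  sol_dense <- solve(as.matrix(mme$C), mme$rhs)
  ebv <- solve_mme(mme)
  E <- nrow(r)
  expect_lt(max(abs(c(ebv$ebv_m, ebv$ebv_d) - sol_dense[-1])), 1e-6)
})

test_that("EBVs are linear in the phenotypes and invariant to record order", {
  set.seed(32)
  ped <- base_colonies(5)
  Ainv <- build_a_inverse(ped)
  ph <- data.frame(queen = 1:5, worker = 6:10, y = rnorm(5))
  ebv1 <- solve_mme(assemble_mme(ph, Ainv, vc))
  ph2 <- ph; ph2$y <- 3 * ph$y
  ebv2 <- solve_mme(assemble_mme(ph2, Ainv, vc))
  expect_equal(ebv2$ebv_m, 3 * ebv1$ebv_m, tolerance = 1e-9)
  ph3 <- ph[sample.int(5), ]
  ebv3 <- solve_mme(assemble_mme(ph3, Ainv, vc))
  expect_equal(ebv3$criterion, ebv1$criterion, tolerance = 1e-10)
})

test_that("the simulator's evaluation path matches the reference MME solve", {
  res <- run_replicate(scheme_config(N_b = 50, N_p = 20, N_s = 3, q = 0.5,
                                     years = 7, dam_fraction = 0.2), 17,
                       keep_state = TRUE)
  st <- res$state
  crit_fast <- beebreedsim:::blup_criteria(st)
  ph <- data.frame(queen = st$ph_q[seq_len(st$pn)],
                   worker = st$ph_w[seq_len(st$pn)],
                   y = st$ph_y[seq_len(st$pn)])
  ebv <- solve_mme(assemble_mme(ph, current_a_inverse(st), st$vc))
  tested <- which(st$went[seq_len(st$nq)] > 0L)
  expect_equal(crit_fast[tested], ebv$criterion[st$went[tested]],
               tolerance = 1e-7)
})

test_that("known sires make the selection criterion more accurate than free mating", {
  # accuracy = correlation between the criterion and the true worker-group
  # total TBV of the current two-year-old cohort
  accuracy <- function(cfg, seeds) {
    vapply(seeds, function(s) {
      res <- run_replicate(cfg, s, keep_state = TRUE)
      st <- res$state
      crit <- beebreedsim:::blup_criteria(st)
      cohort <- which(st$cat[seq_len(st$nq)] == 1L &
                        st$byear[seq_len(st$nq)] == st$year - 2L)
      wm <- 0.5 * (st$bvm[cohort] +
                     rowMeans(st$mate_m[cohort, , drop = FALSE]))
      wd <- 0.5 * (st$bvd[cohort] +
                     rowMeans(st$mate_d[cohort, , drop = FALSE]))
      cor(crit[cohort], wm + wd)
    }, 0)
  }
  seeds <- 1:6
  a_c <- accuracy(scheme_config(200, 0, 3, 0, years = 8,
                                dam_fraction = 0.2), seeds)
  a_u <- accuracy(scheme_config(200, 200, 0, 0, years = 8,
                                dam_fraction = 0.2), seeds)
  expect_true(all(a_c > 0))
  expect_gt(mean(a_c), mean(a_u))
})

test_that("selection criterion is the worker-group EBV sum", {
  expect_equal(selection_criterion(0, 0), 0)
  expect_equal(selection_criterion(0.4, 0.6), 1.0)
  m <- rnorm(10); d <- rnorm(10)
  expect_equal(order(selection_criterion(m, d)), order(m + d))
})
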