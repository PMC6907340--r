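# Bivariate maternal/direct infinitesimal model: inheritance operators.

vc53 <- variance_components()                      # sigma_Amd = -0.75
vc88 <- variance_components(sigma_Amd = -1.25)     # r_md about -0.88
vc0 <- variance_components(sigma2_Am = 0, sigma2_Ad = 0, sigma_Amd = 0,
                           sigma2_E = 0)

test_that("variance components validate their inputs", {
  expect_error(variance_components(sigma_Amd = -2), "semi-definite")
  expect_error(variance_components(sigma2_E = -1), "residual")
  expect_equal(vc53$r_md, -0.75 / sqrt(2))
  expect_equal(vc88$r_md, -1.25 / sqrt(2))
})

test_that("degenerate variance collapses all samplers to exact values", {
  expect_equal(sample_base_queens(3, vc0), matrix(0, 3, 2,
               dimnames = list(NULL, c("m", "d"))))
  expect_equal(drop(make_drone_tbv(c(0, 0), 0, vc0)), c(m = 0, d = 0))
  expect_equal(drop(make_queen_offspring_tbv(c(2, 0), c(0, 2), 0, vc0)),
               c(m = 1, d = 1))
})

test_that("fully inbred dams transmit without Mendelian noise", {
  expect_equal(drop(make_drone_tbv(c(1.5, -0.5), 1, vc53)),
               c(m = 1.5, d = -0.5))
  expect_equal(drop(make_queen_offspring_tbv(c(1, 1), c(3, -1), 1, vc53)),
               c(m = 2, d = 0))
  expect_error(make_drone_tbv(c(0, 0), 1.2, vc53), "\\[0, 1\\]")
  expect_error(make_queen_offspring_tbv(c(0, 0), c(0, 0), -0.1, vc53),
               "\\[0, 1\\]")
})

test_that("base sampling has the configured moments", {
  set.seed(101)
  n <- 1e5
  for (vc in list(vc53, vc88)) {
    bv <- sample_base_queens(n, vc)
    emp <- cov(bv)
    # 3 SE: SE of a covariance of bivariate normals is O(sigma^2 / sqrt(n))
    se <- 3 * sqrt(2) * max(abs(vc$Sigma)) / sqrt(n)
    expect_true(all(abs(emp - vc$Sigma) < 3 * se))
    expect_lt(abs(cor(bv)[1, 2] - vc$r_md), 3 / sqrt(n) * 3)
  }
})

test_that("drone TBVs have variance 2 Sigma_A on the diploid scale", {
  set.seed(102)
  n <- 1e5
  queens <- sample_base_queens(n, vc53)
  drones <- make_drone_tbv(queens, 0, vc53)
  emp <- cov(drones)
  se <- 3 * sqrt(2) * 2 * max(abs(vc53$Sigma)) / sqrt(n)
  expect_true(all(abs(emp - 2 * vc53$Sigma) < 3 * se))
})

test_that("offspring are midparent plus shrinking Mendelian noise", {
  set.seed(103)
  n <- 4e4
  q <- matrix(rep(c(0.7, -0.2), each = n), n)
  d <- matrix(rep(c(-0.3, 0.4), each = n), n)
  for (Fq in c(0, 0.25, 0.6)) {
    off <- make_queen_offspring_tbv(q, d, Fq, vc53)
    dev <- off - 0.5 * (q + d)
    expect_true(all(abs(colMeans(dev)) < 4 * sqrt(2 / n)))
    emp <- cov(dev)
    expected <- 0.25 * (1 - Fq) * vc53$Sigma
    se <- 3 * sqrt(2) * max(abs(expected), 0.25 / n) / sqrt(n)
    expect_true(all(abs(emp - expected) < 4 * se))
  }
})

test_that("worker-group TBV is the queen/drone-mean average", {
  expect_equal(worker_group_tbv(c(0, 0), matrix(0, 12, 2)), c(m = 0, d = 0))
  expect_equal(worker_group_tbv(c(2, 2), matrix(0, 12, 2)), c(m = 1, d = 1))
  drones <- rbind(matrix(rep(c(2, 0), each = 6), 6),
                  matrix(rep(c(0, 2), each = 6), 6))
  expect_equal(worker_group_tbv(c(1, -1), drones), c(m = 1, d = 0))
  expect_error(worker_group_tbv(c(0, 0), matrix(0, 0, 2)), "at least one")
})

test_that("total breeding value sums the two effects", {
  expect_equal(total_breeding_value(c(0, 0)), 0)
  expect_equal(total_breeding_value(c(1.2, -0.4)), 0.8)
  expect_equal(total_breeding_value(rbind(c(-1, 1), c(2, 3))), c(0, 5))
})

test_that("colony phenotypes combine worker direct and queen maternal effects", {
  expect_equal(colony_phenotype(c(0.5, 1.0), c(0.2, 0.9), vc0), 1.2)
  set.seed(104)
  n <- 1e5
  q <- sample_base_queens(n, vc53)
  w <- 0.5 * (q + make_drone_tbv(sample_base_queens(n, vc53), 0, vc53))
  y <- colony_phenotype(w, q, vc53)
  expect_lt(abs(mean(y)), 3 * sd(y) / sqrt(n))
  resid <- y - (w[, "d"] + q[, "m"])
  expect_lt(abs(var(resid) - 1), 3 * sqrt(2 / n))
})

test_that("unselected random mating keeps queen TBV covariance stationary", {
  # 10 generations of random mating in a large population with negligible
  # inbreeding: cohort covariance should stay at Sigma_A throughout
  set.seed(105)
  n <- 4000
  vc <- vc53
  queens <- sample_base_queens(n, vc)
  for (gen in 1:10) {
    dams <- queens[sample.int(n, n, replace = TRUE), , drop = FALSE]
    drone_dams <- queens[sample.int(n, n, replace = TRUE), , drop = FALSE]
    drones <- make_drone_tbv(drone_dams, 0, vc)
    queens <- make_queen_offspring_tbv(dams, drones, 0, vc)
  }
  emp <- cov(queens)
  se <- 3 * sqrt(2) * max(abs(vc$Sigma)) / sqrt(n)
  expect_true(all(abs(emp - vc$Sigma) < 4 * se))
})
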