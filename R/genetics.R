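#' Sample base-population queens
#'
#' Draws true breeding values (TBV) for unrelated, non-inbred base queens.
#' Each queen receives a bivariate-normal (maternal, direct) TBV with mean
#' zero and covariance `Sigma_A`.
#'
#' @param n Number of queens.
#' @param vc A [variance_components()] object.
#' @return An `n` x 2 matrix with columns `m` and `d` (trait units).
#' @examples
#' vc <- variance_components()
#' bv <- sample_base_queens(1000, vc)
#' colMeans(bv)
#' @export
sample_base_queens <- function(n, vc) {
  stopifnot(inherits(vc, "bee_vc"), n >= 0)
  rmvn2(n, vc$Sigma)
}

# coerce a breeding value (length-2 vector or n x 2 matrix) to a matrix
as_bv_matrix <- function(bv) {
  if (is.null(dim(bv))) bv <- matrix(bv, ncol = 2)
  stopifnot(ncol(bv) == 2)
  colnames(bv) <- c("m", "d")
  bv
}

#' Drone true breeding value from his dam
#'
#' Haplodiploid inheritance: a drone develops from a single (unfertilised)
#' gamete of his dam. On the diploid-equivalent scale used throughout
#' (a drone's TBV counts his one haplotype twice) this is
#' \deqn{TBV_D = TBV_Q + \sqrt{1 - F_Q}\,\Phi, \qquad \Phi \sim N(0, \Sigma_A),}
#' where \eqn{F_Q} is the inbreeding coefficient of the dam: inbreeding
#' shrinks the Mendelian sampling variance of her gametes.
#'
#' @param queen_bv Dam TBV: length-2 vector `(m, d)` or an `n` x 2 matrix.
#' @param F_Q Dam inbreeding coefficient(s) in `[0, 1]`, recycled to `n`.
#' @param vc A [variance_components()] object.
#' @return TBV matrix of the drones, same shape as `queen_bv`.
#' @export
make_drone_tbv <- function(queen_bv, F_Q, vc) {
  stopifnot(inherits(vc, "bee_vc"))
  qb <- as_bv_matrix(queen_bv)
  n <- nrow(qb)
  F_Q <- rep_len(F_Q, n)
  if (any(!is.finite(F_Q)) || any(F_Q < 0) || any(F_Q > 1))
    stop("inbreeding coefficient must lie in [0, 1]", call. = FALSE)
  qb + sqrt(1 - F_Q) * rmvn2(n, vc$Sigma)
}

#' Offspring queen true breeding value from dam and drone
#'
#' Midparent inheritance with dam-side Mendelian sampling:
#' \deqn{TBV_R = \tfrac12\left(TBV_D + TBV_Q + \sqrt{1 - F_Q}\,\Phi\right),
#'   \qquad \Phi \sim N(0, \Sigma_A).}
#' The drone contributes his gamete deterministically (he is a clonal
#' gamete of his own dam), so the only Mendelian noise is the dam's,
#' scaled by her inbreeding coefficient. In an unselected random-mating
#' base population this rule keeps the queen TBV covariance stationary at
#' `Sigma_A`.
#'
#' @param queen_bv Dam TBV (vector or `n` x 2 matrix).
#' @param drone_bv Sire drone TBV on the diploid-equivalent scale.
#' @param F_Q Dam inbreeding coefficient(s) in `[0, 1]`.
#' @param vc A [variance_components()] object.
#' @return TBV matrix of the offspring queens.
#' @export
make_queen_offspring_tbv <- function(queen_bv, drone_bv, F_Q, vc) {
  stopifnot(inherits(vc, "bee_vc"))
  qb <- as_bv_matrix(queen_bv)
  db <- as_bv_matrix(drone_bv)
  stopifnot(nrow(qb) == nrow(db))
  n <- nrow(qb)
  F_Q <- rep_len(F_Q, n)
  if (any(!is.finite(F_Q)) || any(F_Q < 0) || any(F_Q > 1))
    stop("inbreeding coefficient must lie in [0, 1]", call. = FALSE)
  0.5 * (db + qb + sqrt(1 - F_Q) * rmvn2(n, vc$Sigma))
}

#' Worker-group true breeding value
#'
#' The worker group of a colony is the collective of the queen's worker
#' offspring. Its TBV is the mean of the queen's TBV and the average TBV of
#' her mates:
#' \deqn{TBV_W = \tfrac12\left(TBV_Q + \overline{TBV}_D\right).}
#'
#' @param queen_bv Queen TBV, length-2 vector `(m, d)`.
#' @param drone_bvs TBVs of her mates: a matrix with 2 columns (one row per
#'   drone, typically 12).
#' @return Length-2 worker-group TBV `(m, d)`.
#' @export
worker_group_tbv <- function(queen_bv, drone_bvs) {
  drone_bvs <- as_bv_matrix(drone_bvs)
  if (nrow(drone_bvs) == 0)
    stop("a mated queen must have at least one drone", call. = FALSE)
  qb <- as_bv_matrix(queen_bv)
  stopifnot(nrow(qb) == 1)
  drop(0.5 * (qb[1, ] + colMeans(drone_bvs)))
}

#' Total breeding value
#'
#' The sum of the maternal and direct components, the scalar used to
#' report genetic progress of queens.
#'
#' @param bv Length-2 vector or `n` x 2 matrix of breeding values.
#' @return Numeric scalar or vector of totals.
#' @export
total_breeding_value <- function(bv) {
  unname(rowSums(as_bv_matrix(bv)))
}

#' Simulate a colony phenotype
#'
#' One performance record per tested colony:
#' \deqn{y = d_W + m_Q + e, \qquad e \sim N(0, \sigma^2_E),}
#' i.e. the direct effect of the worker group plus the maternal effect of
#' the queen plus residual noise. No fixed effects beyond an overall mean
#' (which is zero in simulation) and no repeated records.
#'
#' @param worker_bv Worker-group TBV (vector or `n` x 2 matrix).
#' @param queen_bv Queen TBV (same shape).
#' @param vc A [variance_components()] object.
#' @return Numeric phenotype(s).
#' @export
colony_phenotype <- function(worker_bv, queen_bv, vc) {
  stopifnot(inherits(vc, "bee_vc"))
  wb <- as_bv_matrix(worker_bv)
  qb <- as_bv_matrix(queen_bv)
  stopifnot(nrow(wb) == nrow(qb))
  unname(wb[, "d"] + qb[, "m"]) + rnorm(nrow(wb), 0, sqrt(vc$sigma2_E))
}
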