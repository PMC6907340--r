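#' Assemble the mixed-model equations for the maternal/direct evaluation
#'
#' Animal-model equations for the bivariate (maternal, direct) genetic
#' effect with an overall mean as the only fixed effect. Each colony
#' record links the maternal effect of its queen and the direct effect of
#' its worker group:
#' \deqn{y = \mu + m_{Q} + d_{W} + e.}
#' The genetic covariance enters through the Kronecker structure
#' `Sigma_A^{-1} (x) A^{-1}` scaled by the residual variance, with `A^{-1}`
#' the sparse inverse relationship matrix over all observed-pedigree
#' entities (see [build_a_inverse()]). Unknowns are ordered
#' `(mu, m_1..m_E, d_1..d_E)`.
#'
#' @param phenotypes A `data.frame` with columns `queen` (entity id of the
#'   tested queen), `worker` (entity id of her worker group) and `y`.
#' @param a_inverse Sparse inverse relationship matrix (entities x
#'   entities).
#' @param vc A [variance_components()] object (`Sigma_A` must be positive
#'   definite and `sigma2_E > 0`).
#' @return An object of class `bee_mme`: list with the sparse symmetric
#'   coefficient matrix `C`, right-hand side `rhs`, and `n_entities`.
#' @export
assemble_mme <- function(phenotypes, a_inverse, vc) {
  stopifnot(inherits(vc, "bee_vc"))
  E <- nrow(a_inverse)
  n <- nrow(phenotypes)
  if (n > 0 &&
      (any(phenotypes$queen < 1) || any(phenotypes$queen > E) ||
       any(phenotypes$worker < 1) || any(phenotypes$worker > E)))
    stop("phenotype refers to an entity outside the pedigree", call. = FALSE)
  if (vc$sigma2_E <= 0)
    stop("BLUP requires a positive residual variance", call. = FALSE)
  if (rcond(vc$Sigma) < 1e-12)
    stop("BLUP requires a positive-definite Sigma_A", call. = FALSE)
  Sinv <- solve(vc$Sigma)
  # design: column 1 = mu, then maternal effects, then direct effects
  W <- Matrix::sparseMatrix(
    i = rep(seq_len(n), 3),
    j = c(rep(1L, n), 1L + phenotypes$queen, 1L + E + phenotypes$worker),
    x = 1, dims = c(n, 1L + 2L * E))
  C <- Matrix::crossprod(W)
  Ginv <- Matrix::kronecker(Sinv, a_inverse) * vc$sigma2_E
  C <- C + Matrix::bdiag(Matrix::Matrix(0, 1, 1), Ginv)
  rhs <- as.numeric(Matrix::crossprod(W, phenotypes$y))
  structure(list(C = Matrix::forceSymmetric(C), rhs = rhs, n_entities = E,
                 n_records = n),
            class = "bee_mme")
}

#' Solve the mixed-model equations
#'
#' Sparse symmetric factorisation (CHOLMOD Cholesky) of the coefficient
#' matrix; the solution is checked against `tolerance` on the relative
#' residual. Deterministic given its inputs.
#'
#' @param mme A [assemble_mme()] result.
#' @param tolerance Relative-residual bound (default `1e-8`).
#' @return An `ebv_table`: `data.frame` with one row per pedigree entity:
#'   `id`, `ebv_m`, `ebv_d`, and `criterion = ebv_m + ebv_d` (the
#'   selection criterion when read off a worker-group row); the fitted
#'   overall mean is attached as attribute `mu`.
#' @export
solve_mme <- function(mme, tolerance = 1e-8) {
  stopifnot(inherits(mme, "bee_mme"))
  if (mme$n_records == 0) {
    # no data: the mean is not estimable and all EBVs shrink to zero
    sol <- numeric(1L + 2L * mme$n_entities)
  } else {
    # supernodal Cholesky with fill-reducing permutation
    ch <- Matrix::Cholesky(mme$C, LDL = FALSE, super = TRUE, perm = TRUE)
    sol <- as.numeric(Matrix::solve(ch, mme$rhs))
  }
  res <- as.numeric(mme$C %*% sol) - mme$rhs
  denom <- max(sqrt(sum(mme$rhs^2)), 1e-12)
  if (sqrt(sum(res^2)) / denom > tolerance)
    stop(sprintf("mixed-model solve did not reach tolerance %g (residual %g)",
                 tolerance, sqrt(sum(res^2)) / denom), call. = FALSE)
  E <- mme$n_entities
  ebv_m <- sol[1L + seq_len(E)]
  ebv_d <- sol[1L + E + seq_len(E)]
  out <- data.frame(id = seq_len(E), ebv_m = ebv_m, ebv_d = ebv_d,
                    criterion = ebv_m + ebv_d)
  attr(out, "mu") <- sol[1L]
  class(out) <- c("ebv_table", "data.frame")
  out
}

#' Selection criterion from worker-group EBVs
#'
#' The criterion used to rank breeding queens is the sum of the maternal
#' and direct estimated breeding values of the queen's worker group -- the
#' expected genetic merit of an unmated daughter of the colony.
#'
#' @param ebv_m,ebv_d Maternal and direct EBVs (vectors of equal length),
#'   or a two-column matrix in `ebv_m` with `ebv_d` missing.
#' @return Numeric criterion values.
#' @export
selection_criterion <- function(ebv_m, ebv_d) {
  if (missing(ebv_d)) {
    ebv_m <- as_bv_matrix(ebv_m)
    return(unname(ebv_m[, 1] + ebv_m[, 2]))
  }
  unname(ebv_m + ebv_d)
}

#' Write an EBV table to CSV
#'
#' @param ebv An `ebv_table` from [solve_mme()].
#' @param path Output file.
#' @param year Optional evaluation year recorded in the file.
#' @return `path`, invisibly.
#' @export
write_ebv_csv <- function(ebv, path, year = NA_integer_) {
  df <- cbind(ebv, year = year)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
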