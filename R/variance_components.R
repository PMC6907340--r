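#' Variance components of the maternal/direct trait model
#'
#' Bundles the additive (co)variances of the bivariate maternal/direct trait
#' and the residual variance of the colony phenotype. The additive covariance
#' matrix is
#' \deqn{\Sigma_A = \begin{pmatrix} \sigma^2_{A,m} & \sigma_{A,md} \\
#'   \sigma_{A,md} & \sigma^2_{A,d} \end{pmatrix},}
#' which must be symmetric positive semi-definite.
#'
#' The defaults are the parameters used throughout the simulation study:
#' maternal variance 1, direct variance 2, residual variance 1, and a
#' maternal-direct covariance of -0.75 (correlation about -0.53). The
#' alternative covariance -1.25 corresponds to a correlation of about -0.88.
#'
#' @param sigma2_Am Additive maternal genetic variance (trait units squared).
#' @param sigma2_Ad Additive direct genetic variance (trait units squared).
#' @param sigma_Amd Additive maternal-direct covariance (trait units squared).
#' @param sigma2_E Residual variance of the colony phenotype.
#' @return An object of class `bee_vc`: a list with the four components,
#'   the 2x2 matrix `Sigma` (maternal first), and the implied correlation
#'   `r_md`.
#' @examples
#' vc <- variance_components()
#' vc$r_md
#' @export
variance_components <- function(sigma2_Am = 1, sigma2_Ad = 2,
                                sigma_Amd = -0.75, sigma2_E = 1) {
  stopifnot(is.numeric(sigma2_Am), is.numeric(sigma2_Ad),
            is.numeric(sigma_Amd), is.numeric(sigma2_E))
  if (sigma2_Am < 0 || sigma2_Ad < 0)
    stop("additive variances must be non-negative", call. = FALSE)
  if (sigma2_E < 0)
    stop("residual variance must be non-negative", call. = FALSE)
  Sigma <- matrix(c(sigma2_Am, sigma_Amd, sigma_Amd, sigma2_Ad), 2, 2,
                  dimnames = list(c("m", "d"), c("m", "d")))
  # PSD check: eigenvalues of a symmetric 2x2
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1))
    stop("Sigma_A is not positive semi-definite (sigma_Amd too large ",
         "in magnitude)", call. = FALSE)
  denom <- sqrt(sigma2_Am * sigma2_Ad)
  r_md <- if (denom > 0) sigma_Amd / denom else 0
  structure(list(sigma2_Am = sigma2_Am, sigma2_Ad = sigma2_Ad,
                 sigma_Amd = sigma_Amd, sigma2_E = sigma2_E,
                 Sigma = Sigma, r_md = r_md),
            class = "bee_vc")
}

#' @export
print.bee_vc <- function(x, ...) {
  cat("Maternal/direct variance components\n")
  cat(sprintf("  sigma2_Am = %g, sigma2_Ad = %g, sigma_Amd = %g (r_md = %.3f)\n",
              x$sigma2_Am, x$sigma2_Ad, x$sigma_Amd, x$r_md))
  cat(sprintf("  sigma2_E  = %g\n", x$sigma2_E))
  invisible(x)
}

# Lower-triangular square root of a PSD 2x2 matrix; falls back to an
# eigendecomposition when the matrix is singular (chol() would fail).
sigma_sqrt <- function(Sigma) {
  ch <- tryCatch(t(chol(Sigma)), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  es <- eigen(Sigma, symmetric = TRUE)
  es$vectors %*% diag(sqrt(pmax(es$values, 0)), nrow = 2)
}

# n draws from N(0, Sigma) as an n x 2 matrix (columns m, d)
rmvn2 <- function(n, Sigma) {
  L <- sigma_sqrt(Sigma)
  z <- matrix(rnorm(2 * n), n, 2)
  out <- z %*% t(L)
  colnames(out) <- c("m", "d")
  out
}
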