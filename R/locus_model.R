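#' Initialise a finite-locus genetic model
#'
#' Builds a biallelic finite-locus model whose base population (linkage
#' equilibrium, all allele frequencies `init_freq`) has additive genetic
#' covariance exactly `Sigma_A`. Per-locus bivariate effects are drawn
#' bivariate-normal and then linearly rescaled so that
#' \deqn{\sum_l 2 p_l (1 - p_l)\, \alpha_l \alpha_l' = \Sigma_A}
#' holds to machine precision. Loci are unlinked (free recombination), with
#' no mutation and no dominance.
#'
#' @param vc A [variance_components()] object.
#' @param n_loci Number of loci (default 400).
#' @param init_freq Initial frequency of the "1" allele at every locus.
#' @return An object of class `bee_locus_model`: list with `n_loci`,
#'   `effects` (`n_loci` x 2 matrix, columns `m`, `d`) and `init_freq`
#'   (length `n_loci`).
#' @export
init_locus_model <- function(vc, n_loci = 400, init_freq = 0.5) {
  stopifnot(inherits(vc, "bee_vc"), n_loci > 0)
  init_freq <- rep_len(init_freq, n_loci)
  if (any(init_freq <= 0) || any(init_freq >= 1))
    stop("initial allele frequencies must lie in (0, 1)", call. = FALSE)
  w <- 2 * init_freq * (1 - init_freq)
  if (all(vc$Sigma == 0)) {
    eff <- matrix(0, n_loci, 2)
  } else {
    a <- rmvn2(n_loci, vc$Sigma / sum(w))
    # exact rescale: find T with T C T' = Sigma where C = sum_l w_l a_l a_l'
    C <- crossprod(a * sqrt(w))
    if (n_loci >= 2 && rcond(C) > 1e-12) {
      LC <- sigma_sqrt(C)
      LS <- sigma_sqrt(vc$Sigma)
      Tm <- LS %*% solve(LC)
      eff <- a %*% t(Tm)
    } else {
      # a single locus (or degenerate draw) spans a rank-1 covariance and
      # can only be scaled to match the total variance
      eff <- a * sqrt(sum(diag(vc$Sigma)) / sum(diag(C)))
    }
  }
  colnames(eff) <- c("m", "d")
  structure(list(n_loci = n_loci, effects = eff, init_freq = init_freq),
            class = "bee_locus_model")
}

#' @export
print.bee_locus_model <- function(x, ...) {
  cat(sprintf("Finite-locus model: %d unlinked biallelic loci\n", x$n_loci))
  v <- base_locus_covariance(x)
  cat(sprintf("  base genetic covariance: Var_m = %.4f, Var_d = %.4f, Cov = %.4f\n",
              v[1, 1], v[2, 2], v[1, 2]))
  invisible(x)
}

# genetic covariance of the base population implied by the locus model
base_locus_covariance <- function(model) {
  w <- 2 * model$init_freq * (1 - model$init_freq)
  crossprod(model$effects * sqrt(w))
}

#' Construct a genotype
#'
#' Queens are diploid (two haplotypes); drones are haploid (one). A
#' haplotype is a 0/1 allele indicator vector over the model's loci.
#'
#' @param maternal_haplotype 0/1 integer vector.
#' @param paternal_haplotype 0/1 integer vector for queens; `NULL` for drones.
#' @return An object of class `bee_genotype` with fields `mat`, `pat`, and
#'   `ploidy` (2 for queens, 1 for drones).
#' @export
new_genotype <- function(maternal_haplotype, paternal_haplotype = NULL) {
  mat <- as.integer(maternal_haplotype)
  stopifnot(all(mat %in% c(0L, 1L)))
  if (is.null(paternal_haplotype)) {
    structure(list(mat = mat, pat = NULL, ploidy = 1L), class = "bee_genotype")
  } else {
    pat <- as.integer(paternal_haplotype)
    stopifnot(length(pat) == length(mat), all(pat %in% c(0L, 1L)))
    structure(list(mat = mat, pat = pat, ploidy = 2L), class = "bee_genotype")
  }
}

#' Sample a gamete from a queen genotype
#'
#' Meiosis with free recombination: an independent choice of one of the two
#' alleles at every locus. Drones do not undergo meiosis -- a drone
#' reproduces his single haplotype clonally -- so calling this on a haploid
#' genotype is an error.
#'
#' @param genotype A diploid `bee_genotype`.
#' @return 0/1 integer haplotype vector.
#' @export
sample_gamete <- function(genotype) {
  stopifnot(inherits(genotype, "bee_genotype"))
  if (genotype$ploidy != 2L)
    stop("gamete sampling requires a diploid (queen) genotype; ",
         "a drone passes his haplotype on unchanged", call. = FALSE)
  pick <- rbinom(length(genotype$mat), 1L, 0.5)
  ifelse(pick == 1L, genotype$pat, genotype$mat)
}

#' True breeding value of a genotype under a locus model
#'
#' Sums allele-effect contributions, centred at the base allele frequency.
#' Drone haplotypes are counted twice so that drone TBVs are on the same
#' diploid-equivalent scale as queen TBVs:
#' \deqn{TBV = \sum_l (x_l - 2 p_l)\, \alpha_l,}
#' with \eqn{x_l} the (diploid-equivalent) allele count at locus `l`.
#'
#' @param genotype A `bee_genotype`.
#' @param model A `bee_locus_model`.
#' @return Length-2 breeding value `(m, d)`.
#' @export
genotype_tbv <- function(genotype, model) {
  stopifnot(inherits(genotype, "bee_genotype"),
            inherits(model, "bee_locus_model"))
  if (length(genotype$mat) != model$n_loci)
    stop("genotype and locus model disagree on the number of loci",
         call. = FALSE)
  x <- if (genotype$ploidy == 2L) genotype$mat + genotype$pat
       else 2L * genotype$mat
  drop(crossprod(x - 2 * model$init_freq, model$effects))
}

# --- vectorised internals used by the population simulator ---------------

# n base haplotypes as an n x L 0/1 matrix
sample_base_haplotypes <- function(n, model) {
  L <- model$n_loci
  matrix(rbinom(n * L, 1L, rep(model$init_freq, each = n)), n, L)
}

# row-wise meiosis on paired haplotype matrices
gamete_rows <- function(mat, pat) {
  pick <- matrix(rbinom(length(mat), 1L, 0.5), nrow(mat), ncol(mat))
  mat + pick * (pat - mat)
}

# TBVs for diploid rows (mat, pat) or haploid rows (hap counted twice)
tbv_rows <- function(model, mat, pat = NULL) {
  x <- if (is.null(pat)) 2 * mat else mat + pat
  out <- (x - rep(2 * model$init_freq, each = nrow(x))) %*% model$effects
  colnames(out) <- c("m", "d")
  out
}
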