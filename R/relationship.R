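#' Dense additive relationship matrix of an observed pedigree
#'
#' Tabular construction of the relationship matrix implied by the
#' simulation's own mating mechanics, used as the oracle against which the
#' sparse inverse is checked. All values are on the diploid-equivalent
#' scale on which queen TBVs have variance `(1 + F) * Sigma_A` and drone
#' TBVs have variance `2 * Sigma_A`.
#'
#' A mating is a queen `Q` plus the actual dozen drones she mated with,
#' and every product of the mating is expressed through the colony's
#' worker group `W = (Q + T) / 2`, where `T` is the mean of the `n_d`
#' drones:
#' \itemize{
#' \item worker groups regress on the dam (1/2) and, under station mating,
#'   on the station's `k` DPQs (1/(2k) each; a drone's dam is a uniform
#'   draw among them). Writing `s` for the mean of the DPQ relationship
#'   block (the relationship between random drones of the station, 0 for
#'   unknown sires), the worker Mendelian term has variance
#'   `eps = (2 - s) / (4 n_d)`;
#' \item daughters of the mating regress on `W` with coefficient 1 --
#'   sharing the actual dozen makes the worker group, not the station
#'   average, the daughters' common parent -- with Mendelian variance
#'   `(1 - 1/n_d)(2 - s) / 4 + (1 - Fhat_Q) / 4`;
#' \item daughter diagonals are `1 + Fhat` with
#'   `Fhat = mean_j A(dpq_j, Q) / 2`.
#' }
#' With this structure every Mendelian residual is uncorrelated with
#' everything older, so the tabular matrix and the sparse inverse of
#' [build_a_inverse()] are exact inverses of one another.
#'
#' @param ped A [bee_pedigree()]. Daughters must be preceded by their
#'   dam's worker group (enforced by the constructor used here).
#' @param cap Maximum pedigree size (dense storage); larger input errors.
#' @return Dense symmetric relationship matrix.
#' @export
build_relationship_dense <- function(ped, cap = 2000) {
  stopifnot(inherits(ped, "bee_pedigree"))
  r <- ped$records
  n <- nrow(r)
  if (n > cap)
    stop("pedigree larger than the dense cap (", cap, ")", call. = FALSE)
  nd <- ped$n_drones
  worker_of <- worker_index(r)
  A <- matrix(0, n, n)
  scache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    dam <- r$dam_id[i]
    if (dam == 0L) { A[i, i] <- 1; next }
    st <- r$sire_ref[i]
    if (r$kind[i] == "worker") {
      if (st > 0L) {
        dpq <- ped$stations[[as.character(st)]]
        srow <- colMeans(A[dpq, , drop = FALSE])
        skey <- as.character(st)
        if (is.null(scache[[skey]])) scache[[skey]] <- mean(A[dpq, dpq])
        s <- scache[[skey]]
        vQ <- srow[dam]
      } else {
        srow <- numeric(n); s <- 0; vQ <- 0
      }
      row <- 0.5 * A[dam, ] + 0.5 * srow
      A[i, ] <- row
      A[, i] <- row
      varT <- 2 / nd + (1 - 1 / nd) * s
      A[i, i] <- 0.25 * (A[dam, dam] + varT + 2 * vQ)
    } else {
      w <- worker_of[dam]
      if (is.na(w) || w > i)
        stop("daughter before her dam's worker group", call. = FALSE)
      Fhat <- A[w, dam] - 0.5 * A[dam, dam]
      row <- A[w, ]
      A[i, ] <- row
      A[, i] <- row
      A[i, i] <- 1 + Fhat
    }
  }
  A
}

# position of each queen's worker-group entity (NA if untested)
worker_index <- function(records) {
  out <- rep(NA_integer_, nrow(records))
  w <- which(records$kind == "worker")
  out[records$dam_id[w]] <- w
  out
}

# Fhat (expected inbreeding under the observed model) for every queen and
# the drone-relationship scalar s for every station, from the dense matrix.
observed_fs <- function(ped, cap = 2000) {
  A <- build_relationship_dense(ped, cap = cap)
  r <- ped$records
  Fhat <- ifelse(r$kind == "queen", diag(A) - 1, NA_real_)
  s <- vapply(ped$stations, function(dpq) mean(A[dpq, dpq]), 0)
  list(Fhat = Fhat, s = s)
}

# Henderson single-entity contribution: given parent indices p, regression
# coefficients b and Mendelian variance d for entity i, A^-1 gains
# (1/d) * c(-b, 1) %o% c(-b, 1) at indices c(p, i).
henderson_triplet <- function(i, p, b, d) {
  v <- c(-b, 1)
  idx <- c(p, i)
  m <- length(idx)
  list(i = rep(idx, m), j = rep(idx, each = m),
       x = as.vector(outer(v, v)) / d)
}

#' Sparse inverse relationship matrix of an observed pedigree
#'
#' Henderson-style direct construction of the inverse of the matrix built
#' by [build_relationship_dense()]. Because every entity of the honeybee
#' pedigree -- worker groups regressing on dam and station DPQs, daughters
#' regressing on their colony's worker group -- has a Mendelian residual
#' that is uncorrelated with everything else, the inverse assembles from
#' per-entity scalar contributions, exactly as in the classical
#' construction for diploid pedigrees. Unknown sires are base drones and
#' contribute nothing; base queens contribute 1 on the diagonal.
#'
#' @param ped A [bee_pedigree()].
#' @param Fhat Optional numeric vector of expected inbreeding per entity
#'   (queens; from the incremental simulator). Computed from the dense
#'   recursion when `NULL`.
#' @param s_stations Optional named numeric vector/list of the station
#'   drone-relationship scalar `s`. Computed when `NULL`.
#' @param cap Dense-recursion size cap used when `Fhat`/`s_stations` must
#'   be computed here.
#' @return A sparse symmetric matrix (class `dsCMatrix`) with one
#'   row/column per pedigree entity, in id order.
#' @export
build_a_inverse <- function(ped, Fhat = NULL, s_stations = NULL,
                            cap = 2000) {
  stopifnot(inherits(ped, "bee_pedigree"))
  r <- ped$records
  n <- nrow(r)
  nd <- ped$n_drones
  if (is.null(Fhat) || (length(ped$stations) && is.null(s_stations))) {
    fs <- observed_fs(ped, cap = cap)
    if (is.null(Fhat)) Fhat <- fs$Fhat
    if (is.null(s_stations)) s_stations <- fs$s
  }
  worker_of <- worker_index(r)
  ti <- tj <- tx <- vector("list", n)
  for (i in seq_len(n)) {
    dam <- r$dam_id[i]
    if (dam == 0L) {
      tr <- list(i = i, j = i, x = 1)
    } else if (r$kind[i] == "worker") {
      st <- r$sire_ref[i]
      if (st > 0L) {
        dpq <- ped$stations[[as.character(st)]]
        s <- s_stations[[as.character(st)]]
        k <- length(dpq)
        tr <- henderson_triplet(i, c(dam, dpq), c(0.5, rep(0.5 / k, k)),
                                (2 - s) / (4 * nd))
      } else {
        tr <- henderson_triplet(i, dam, 0.5, 2 / (4 * nd))
      }
    } else {
      st <- r$sire_ref[i]
      s <- if (st > 0L) s_stations[[as.character(st)]] else 0
      w <- worker_of[dam]
      d <- 0.25 * ((1 - 1 / nd) * (2 - s) + 1 - Fhat[dam])
      tr <- henderson_triplet(i, w, 1, d)
    }
    ti[[i]] <- tr$i; tj[[i]] <- tr$j; tx[[i]] <- tr$x
  }
  Ainv <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj),
                               x = unlist(tx), dims = c(n, n))
  Matrix::forceSymmetric(Ainv)
}
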