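#' Configure a breeding scheme
#'
#' Bundles the population and scheme parameters of one simulation setting:
#' `N_b` breeding queens (BQ) and `N_p` passive queens (PQ) born per year,
#' `N_s` isolated mating stations (0 = uncontrolled, free mating), and the
#' fraction `q` of each passive cohort whose dams are breeding queens.
#' `N_p` may be `Inf`: the infinite passive population is never simulated
#' explicitly -- under free mating its drones are drawn as if from the
#' base population.
#'
#' The yearly cycle selects the best `dam_fraction` of 2-year-old BQ as
#' dams (`daughters_per_dam` each) and, under controlled mating, the `N_s`
#' best 3-year-old BQ as sources of the stations' sister groups of
#' `dpq_per_station` drone-producing queens (DPQ). Every queen mates with
#' `drones_per_mating` drones.
#'
#' @param N_b Breeding queens born per year (must allow
#'   `round(dam_fraction * N_b) * daughters_per_dam == N_b`).
#' @param N_p Passive queens born per year (finite, 0 or `Inf`).
#' @param N_s Mating stations per year; 0 means uncontrolled mating.
#' @param q Fraction of each passive cohort with BQ dams (0 unless the
#'   passive population is finite and positive).
#' @param vc A [variance_components()] object.
#' @param years Number of simulated years (birth cohorts).
#' @param dam_fraction Selected fraction of 2-year-old BQ.
#' @param daughters_per_dam Daughter queens per selected dam.
#' @param drones_per_mating Drones per mating (polyandry level).
#' @param dpq_per_station DPQ sisters per station.
#' @param model `"infinitesimal"` or `"finite_locus"`.
#' @param n_loci Locus count for the finite-locus model.
#' @param selection `"blup"` (criterion = worker-group EBV sum) or
#'   `"random"` (no selection; drift control runs).
#' @return A `bee_scheme_config` list.
#' @export
scheme_config <- function(N_b = 1000, N_p = 0, N_s = 10, q = 0,
                          vc = variance_components(), years = 20,
                          dam_fraction = 0.2, daughters_per_dam = 5,
                          drones_per_mating = 12, dpq_per_station = 8,
                          model = c("infinitesimal", "finite_locus"),
                          n_loci = 400,
                          selection = c("blup", "random")) {
  model <- match.arg(model)
  selection <- match.arg(selection)
  stopifnot(inherits(vc, "bee_vc"), N_b >= 5, years >= 2, N_s >= 0,
            drones_per_mating >= 1, dpq_per_station >= 1,
            daughters_per_dam >= 1)
  infinite_passive <- is.infinite(N_p)
  if (!infinite_passive) stopifnot(N_p >= 0, N_p == round(N_p))
  if (q < 0 || q > 1) stop("q must lie in [0, 1]", call. = FALSE)
  if ((infinite_passive || N_p == 0) && q != 0)
    stop("q must be 0 when the passive population is empty or infinite",
         call. = FALSE)
  n_dams <- round_half_up(dam_fraction * N_b)
  if (n_dams < 1) stop("dam_fraction selects no dams", call. = FALSE)
  if (n_dams * daughters_per_dam != N_b)
    warning("round(dam_fraction * N_b) * daughters_per_dam != N_b; ",
            "daughters are assigned to the top dams cyclically")
  if (N_s > N_b) stop("more stations than breeding queens", call. = FALSE)
  structure(list(N_b = as.integer(N_b),
                 N_p = if (infinite_passive) Inf else as.integer(N_p),
                 N_s = as.integer(N_s), q = q, vc = vc,
                 years = as.integer(years), dam_fraction = dam_fraction,
                 n_dams = as.integer(n_dams),
                 daughters_per_dam = as.integer(daughters_per_dam),
                 n_drones = as.integer(drones_per_mating),
                 dpq_per_station = as.integer(dpq_per_station),
                 model = model, n_loci = as.integer(n_loci),
                 selection = selection,
                 controlled = N_s > 0,
                 infinite_passive = infinite_passive),
            class = "bee_scheme_config")
}

#' @export
print.bee_scheme_config <- function(x, ...) {
  cat(sprintf(paste0("Breeding scheme: N_b=%d, N_p=%s, N_s=%d (%s mating), ",
                     "q=%g, %d years, %s model\n"),
              x$N_b, ifelse(is.finite(x$N_p), x$N_p, "Inf"), x$N_s,
              ifelse(x$controlled, "controlled", "uncontrolled"),
              x$q, x$years, x$model))
  invisible(x)
}

round_half_up <- function(x) floor(x + 0.5)

# queen categories
CAT_BQ <- 1L
CAT_DPQ <- 2L
CAT_PQ <- 3L

# ---------------------------------------------------------------------------
# Population state: one environment holding flat arrays over queens and
# observed-pedigree entities, the sliding-window kinship matrices, the
# incremental A^-1 triplets and the phenotype records.
# ---------------------------------------------------------------------------

#' Initialise a population state
#'
#' Creates the state for one replicate and fills years 1-2 with base
#' cohorts: unrelated, non-inbred queens with TBVs drawn from the base
#' distribution, mated to base drones. Breeding queens receive worker
#' groups and phenotype records; passive queens are never tested.
#'
#' @param config A [scheme_config()].
#' @return A `bee_population` (environment) positioned at the end of
#'   year 2.
#' @export
initialize_population <- function(config) {
  stopifnot(inherits(config, "bee_scheme_config"))
  cfg <- config
  st <- new.env(parent = emptyenv())
  st$cfg <- cfg
  st$vc <- cfg$vc
  st$finite <- cfg$model == "finite_locus"
  st$lm <- if (st$finite) init_locus_model(cfg$vc, cfg$n_loci) else NULL
  Npf <- if (cfg$infinite_passive) 0L else cfg$N_p
  st$Npf <- Npf
  per_year <- cfg$N_b + Npf + cfg$N_s * cfg$dpq_per_station
  ntot <- 2L * (cfg$N_b + Npf) + (cfg$years - 2L) * per_year + 8L
  st$nq <- 0L
  for (nm in c("bvm", "bvd", "Fq", "Fhat", "mate_s"))
    st[[nm]] <- numeric(ntot)
  for (nm in c("cat", "byear", "dam", "fdam", "fslot", "kinloc", "qent",
               "went", "mate_stgid"))
    st[[nm]] <- integer(ntot)
  nd <- cfg$n_drones
  st$mate_dd <- matrix(NA_integer_, ntot, nd)
  if (!st$finite) {
    st$mate_m <- matrix(NA_real_, ntot, nd)
    st$mate_d <- matrix(NA_real_, ntot, nd)
  } else {
    st$hap_mat <- matrix(NA_integer_, ntot, cfg$n_loci)
    st$hap_pat <- matrix(NA_integer_, ntot, cfg$n_loci)
    st$dronehap <- vector("list", cfg$years)  # per year: (n*nd) x L + index
    st$mate_m <- matrix(NA_real_, ntot, nd)   # drone TBVs (for worker means)
    st$mate_d <- matrix(NA_real_, ntot, nd)
  }
  # observed entities
  st$E <- 0L
  st$etype <- integer(0)
  st$equeen <- integer(0)
  st$ebyear <- integer(0)
  st$edam_ent <- integer(0)
  st$esire_gid <- integer(0)
  st$obsloc <- integer(0)
  grow_e <- 2L * cfg$N_b * cfg$years + cfg$N_s * cfg$dpq_per_station *
    cfg$years + 16L
  for (nm in c("etype", "equeen", "ebyear", "edam_ent", "esire_gid",
               "obsloc"))
    st[[nm]] <- integer(grow_e)
  # A^-1 triplets, accumulated as a list of per-batch chunks (appending
  # chunks avoids copying large buffers), plus an incrementally cached
  # genetic coefficient block Sigma^-1 (x) A^-1 * sigma2_E in interleaved
  # unknown order (m_i -> 2i-1, d_i -> 2i)
  st$trip <- list()
  st$Gscale <- solve(cfg$vc$Sigma) * cfg$vc$sigma2_E
  st$G_cache <- NULL
  st$trip_done <- 0L
  # phenotypes
  st$pn <- 0L
  st$ph_q <- integer(grow_e); st$ph_w <- integer(grow_e)
  st$ph_y <- numeric(grow_e)
  # true-kinship window (infinitesimal model only): the window must cover
  # every queen still reachable as a dam or stored drone dam. Without a
  # passive population the maximal birth-year lag shrinks (controlled:
  # station DPQs are contemporaries of the dam; uncontrolled: drone dams
  # at most three years older than the mated queen).
  if (!st$finite) {
    st$kinA_slots <- if (Npf > 0L) 7L else if (cfg$controlled) 4L else 6L
    st$strideA <- per_year
    st$K_true <- matrix(0, st$kinA_slots * per_year,
                        st$kinA_slots * per_year)
    st$kinA_slot_year <- rep(-1L, st$kinA_slots)
    st$kinA_used <- integer(st$kinA_slots)
    st$father_use <- new.env(parent = emptyenv())
  }
  # observed-relationship window (controlled mating only)
  if (cfg$controlled) {
    st$kinB_slots <- 4L
    st$strideB <- 2L * cfg$N_b + cfg$N_s * cfg$dpq_per_station
    st$K_obs <- matrix(0, st$kinB_slots * st$strideB,
                       st$kinB_slots * st$strideB)
    st$kinB_slot_year <- rep(-1L, st$kinB_slots)
    st$kinB_used <- integer(st$kinB_slots)
  }
  st$station_gid <- 0L
  st$station_dpq_ents <- list()
  st$stations_cur <- NULL
  # trajectory accumulators
  st$traj <- list()
  st$sel <- list()
  st$year <- 0L
  class(st) <- c("bee_population", "environment")

  # base cohorts, years 1 and 2
  for (t in 1:2) {
    st$year <- t
    bq <- add_base_queens(st, cfg$N_b, CAT_BQ, t)
    mate_base(st, bq)
    add_bq_entities_and_tests(st, bq)
    if (Npf > 0) {
      pq <- add_base_queens(st, Npf, CAT_PQ, t)
      mate_base(st, pq)
    }
    record_cohorts(st, t)
  }
  st
}

#' @export
print.bee_population <- function(x, ...) {
  cat(sprintf("Honeybee population after year %d: %d queens, %d evaluated entities\n",
              x$year, x$nq, x$E))
  invisible(x)
}

# --- low-level queen bookkeeping -------------------------------------------

new_queen_rows <- function(st, n) {
  idx <- st$nq + seq_len(n)
  if (max(idx) > length(st$cat))
    stop("internal: queen storage exhausted", call. = FALSE)
  st$nq <- st$nq + n
  idx
}

add_base_queens <- function(st, n, cat, t) {
  idx <- new_queen_rows(st, n)
  st$cat[idx] <- cat
  st$byear[idx] <- t
  if (st$finite) {
    st$hap_mat[idx, ] <- sample_base_haplotypes(n, st$lm)
    st$hap_pat[idx, ] <- sample_base_haplotypes(n, st$lm)
    bv <- tbv_rows(st$lm, st$hap_mat[idx, , drop = FALSE],
                   st$hap_pat[idx, , drop = FALSE])
  } else {
    bv <- sample_base_queens(n, st$vc)
  }
  st$bvm[idx] <- bv[, 1]; st$bvd[idx] <- bv[, 2]
  st$dam[idx] <- 0L; st$fdam[idx] <- 0L; st$fslot[idx] <- 0L
  st$Fq[idx] <- 0; st$Fhat[idx] <- 0
  if (!st$finite) kinA_add(st, idx)
  idx
}

# sliding-window slot allocation: returns the new (contiguous) local
# column indices plus the live column ranges as of before the insertion
window_alloc <- function(st, prefix, t, n) {
  slots <- st[[paste0(prefix, "_slots")]]
  stride <- st[[paste0("stride", toupper(substr(prefix, 4, 4)))]]
  sy <- st[[paste0(prefix, "_slot_year")]]
  used <- st[[paste0(prefix, "_used")]]
  slot <- (t - 1L) %% slots + 1L
  if (sy[slot] != t) { sy[slot] <- t; used[slot] <- 0L }
  live <- which(used > 0L)
  start <- (live - 1L) * stride + 1L
  len <- used[live]
  k0 <- used[slot]
  if (k0 + n > stride) stop("internal: window stride exhausted", call. = FALSE)
  locs <- (slot - 1L) * stride + k0 + seq_len(n)
  used[slot] <- k0 + n
  st[[paste0(prefix, "_slot_year")]] <- sy
  st[[paste0(prefix, "_used")]] <- used
  list(locs = as.integer(locs), start = as.integer(start),
       len = as.integer(len))
}

# true-kinship rows for newly created queens (infinitesimal model)
kinA_add <- function(st, idx) {
  t <- st$byear[idx[1]]
  n <- length(idx)
  al <- window_alloc(st, "kinA", t, n)
  locs <- al$locs
  st$kinloc[idx] <- locs
  dam <- st$dam[idx]
  fdam <- st$fdam[idx]
  damloc <- fdamloc <- integer(n)
  damloc[dam > 0L] <- st$kinloc[dam[dam > 0L]]
  fdamloc[fdam > 0L] <- st$kinloc[fdam[fdam > 0L]]
  Fq <- numeric(n)
  both <- damloc > 0L & fdamloc > 0L
  if (any(both))
    Fq[both] <- st$K_true[cbind(damloc[both], fdamloc[both])]
  st$Fq[idx] <- Fq
  row_update_block(st$K_true, cbind(damloc, fdamloc),
                   matrix(0.5, n, 2), locs[1], al$start, al$len,
                   0.5 * (1 + Fq))
  # same-father corrections: siblings sharing the dam's stored drone
  off <- which(dam > 0L)
  if (length(off)) {
    ci <- cj <- integer(0); cx <- numeric(0)
    for (o in off) {
      key <- paste0(dam[o], "_", st$fslot[idx[o]])
      prev <- st$father_use[[key]]
      if (!is.null(prev)) {
        fl <- fdamloc[o]
        fdd <- if (fl > 0L) st$K_true[fl, fl] else 0
        ci <- c(ci, rep(locs[o], length(prev)))
        cj <- c(cj, prev)
        cx <- c(cx, rep(0.25 * (1 - fdd), length(prev)))
      }
      st$father_use[[key]] <- c(prev, locs[o])
    }
    if (length(ci))
      add_pairs_sym(st$K_true, as.integer(ci), as.integer(cj), cx)
  }
  invisible(idx)
}

# --- observed entities and incremental A^-1 --------------------------------

new_entities <- function(st, n) {
  e <- st$E + seq_len(n)
  if (max(e) > length(st$etype)) {
    grow <- function(v) c(v, vector(typeof(v), length(v) + n))
    for (nm in c("etype", "equeen", "ebyear", "edam_ent", "esire_gid",
                 "obsloc"))
      st[[nm]] <- grow(st[[nm]])
  }
  st$E <- st$E + n
  e
}

push_triplets <- function(st, i, j, x) {
  st$trip[[length(st$trip) + 1L]] <- list(i = i, j = j, x = x)
}

# scalar Henderson contributions for a batch of entities with one parent
# each (coefficient b) and Mendelian variances d
push_one_parent <- function(st, ent, parent, b, d) {
  inv <- 1 / d
  push_triplets(st,
                i = c(parent, parent, ent, ent),
                j = c(parent, ent, parent, ent),
                x = c(b * b * inv, -b * inv, -b * inv, inv))
}

# worker-group contributions under station mating: parents are the queen
# (1/2) and the station's k DPQ entities (1/(2k) each)
push_worker_station <- function(st, went, qent, dpq_ents, d) {
  k <- ncol(dpq_ents)
  v <- c(-0.5, rep(-0.5 / k, k), 1)
  m <- length(v)
  pat <- as.vector(outer(v, v))
  idx <- cbind(qent, dpq_ents, went)            # n x m
  n <- length(went)
  ii <- idx[, rep(seq_len(m), each = m), drop = FALSE]
  jj <- idx[, rep(seq_len(m), m), drop = FALSE]
  xx <- rep(pat, each = n) / d
  push_triplets(st, as.vector(ii), as.vector(jj), as.vector(xx))
}

# observed-window rows for new entities (controlled mating only).
# mode: 0 base queen, 1 worker, 2 daughter queen. Returns Fhat (daughters;
# zero otherwise).
kinB_add <- function(st, ents, mode, damloc = NULL, wparloc = NULL,
                     dpqloc = NULL, svec = NULL) {
  t <- st$ebyear[ents[1]]
  n <- length(ents)
  al <- window_alloc(st, "kinB", t, n)
  locs <- al$locs
  st$obsloc[ents] <- locs
  nd <- st$cfg$n_drones
  K <- st$K_obs
  Fh <- numeric(n)
  if (mode == 0L) {
    par <- matrix(0L, n, 1L)
    coefs <- matrix(0, n, 1L)
    dv <- rep(1, n)
  } else if (mode == 1L) {
    if (is.null(dpqloc) || ncol(dpqloc) == 0L)
      dpqloc <- matrix(0L, n, 0L)
    k <- ncol(dpqloc)
    par <- cbind(as.integer(damloc), dpqloc)
    coefs <- cbind(rep(0.5, n),
                   matrix(if (k) 0.5 / k else numeric(0), n, k))
    vQ <- if (k) rowMeans(matrix(K[cbind(as.vector(dpqloc),
                                         rep(damloc, k))], n, k))
          else numeric(n)
    varT <- 2 / nd + (1 - 1 / nd) * svec
    dv <- 0.25 * (K[cbind(damloc, damloc)] + varT + 2 * vQ)
  } else {
    par <- matrix(as.integer(wparloc), n, 1L)
    coefs <- matrix(1, n, 1L)
    Fh <- K[cbind(wparloc, damloc)] - 0.5 * K[cbind(damloc, damloc)]
    dv <- 1 + Fh
  }
  storage.mode(par) <- "integer"
  row_update_block(K, par, coefs, locs[1], al$start, al$len, dv)
  Fh
}

# --- base matings, worker groups and phenotypes ----------------------------

# mate queens to unrelated base drones (used for the base cohorts and for
# the infinite passive population)
mate_base <- function(st, idx) {
  n <- length(idx)
  nd <- st$cfg$n_drones
  st$mate_dd[idx, ] <- 0L
  if (st$finite) {
    hap <- sample_base_haplotypes(n * nd, st$lm)
    st$dronehap[[st$year]] <- store_drone_haps(st, idx, hap)
    bv <- tbv_rows(st$lm, hap)
  } else {
    bv <- rmvn2(n * nd, 2 * st$vc$Sigma)
  }
  st$mate_m[idx, ] <- bv[, 1]
  st$mate_d[idx, ] <- bv[, 2]
  st$mate_s[idx] <- 0
  st$mate_stgid[idx] <- 0L
  invisible(idx)
}

# store freshly sampled drone haplotypes (given in slot-major order, the
# order of as.vector(ddam)) in queen-major layout for later lookup
store_drone_haps <- function(st, idx, hap_slotmajor) {
  n <- length(idx)
  nd <- st$cfg$n_drones
  i <- rep(seq_len(n), each = nd)
  j <- rep(seq_len(nd), times = n)
  hap <- hap_slotmajor[(j - 1L) * n + i, , drop = FALSE]
  prev <- st$dronehap[[st$year]]
  if (is.null(prev)) prev <- list(queen = integer(0),
                                  hap = matrix(0L, 0, st$cfg$n_loci))
  list(queen = c(prev$queen, idx), hap = rbind(prev$hap, hap))
}

# look up stored drone haplotypes for (queen, slot) pairs
drone_hap_rows <- function(st, qidx, slot) {
  out <- matrix(0L, length(qidx), st$cfg$n_loci)
  byy <- st$byear[qidx]
  nd <- st$cfg$n_drones
  for (t in unique(byy)) {
    rows <- which(byy == t)
    rec <- st$dronehap[[t]]
    pos <- match(qidx[rows], rec$queen)
    out[rows, ] <- rec$hap[(pos - 1L) * nd + slot[rows], , drop = FALSE]
  }
  out
}

# create worker groups + phenotype records for a BQ cohort, and their
# observed-pedigree entities (queen + worker) with A^-1 contributions
add_bq_entities_and_tests <- function(st, idx, dpq_ent_rows = NULL,
                                      svec = NULL) {
  cfg <- st$cfg
  n <- length(idx)
  t <- st$byear[idx[1]]
  nd <- cfg$n_drones
  # queen entities
  qe <- new_entities(st, n)
  st$etype[qe] <- 1L
  st$equeen[qe] <- idx
  st$ebyear[qe] <- t
  st$qent[idx] <- qe
  dam <- st$dam[idx]
  base <- dam == 0L
  st$edam_ent[qe] <- ifelse(base, 0L, st$qent[pmax(dam, 1L)])
  st$esire_gid[qe] <- ifelse(base, 0L, st$mate_stgid[pmax(dam, 1L)])
  if (cfg$controlled) {
    damloc <- ifelse(base, 0L, st$obsloc[st$qent[pmax(dam, 1L)]])
    wparloc <- ifelse(base, 0L, st$obsloc[st$went[pmax(dam, 1L)]])
    if (any(base)) {
      kinB_add(st, qe[base], 0L)
      st$Fhat[idx[base]] <- 0
    }
    if (any(!base)) {
      st$Fhat[idx[!base]] <- kinB_add(st, qe[!base], 2L,
                                      damloc = damloc[!base],
                                      wparloc = wparloc[!base])
    }
  } else {
    st$Fhat[idx] <- 0
  }
  # A^-1: base queens contribute 1 on the diagonal; daughters regress on
  # their dam's worker group
  if (any(base))
    push_triplets(st, qe[base], qe[base], rep(1, sum(base)))
  if (any(!base)) {
    dd <- dam[!base]
    d_mend <- 0.25 * ((1 - 1 / nd) * (2 - st$mate_s[dd]) + 1 - st$Fhat[dd])
    push_one_parent(st, qe[!base], st$went[dd], 1, d_mend)
  }
  # worker groups
  we <- new_entities(st, n)
  st$etype[we] <- 2L
  st$equeen[we] <- idx
  st$ebyear[we] <- t
  st$edam_ent[we] <- qe
  st$esire_gid[we] <- st$mate_stgid[idx]
  st$went[idx] <- we
  if (cfg$controlled) {
    if (is.null(dpq_ent_rows)) {        # base cohorts: base-drone matings
      kinB_add(st, we, 1L, damloc = st$obsloc[qe],
               dpqloc = matrix(0L, n, 0), svec = numeric(n))
    } else {
      kinB_add(st, we, 1L, damloc = st$obsloc[qe],
               dpqloc = matrix(st$obsloc[dpq_ent_rows],
                               nrow(dpq_ent_rows)),
               svec = svec)
    }
  }
  if (is.null(dpq_ent_rows)) {
    push_one_parent(st, we, qe, 0.5, rep(2 / (4 * nd), n))
  } else {
    dpq_loc_ent <- dpq_ent_rows
    push_worker_station(st, we, qe, dpq_loc_ent, (2 - svec) / (4 * nd))
  }
  # worker TBV and phenotype
  wbm <- 0.5 * (st$bvm[idx] + rowMeans(st$mate_m[idx, , drop = FALSE]))
  wbd <- 0.5 * (st$bvd[idx] + rowMeans(st$mate_d[idx, , drop = FALSE]))
  y <- wbd + st$bvm[idx] + rnorm(n, 0, sqrt(st$vc$sigma2_E))
  sel <- st$pn + seq_len(n)
  st$ph_q[sel] <- qe; st$ph_w[sel] <- we; st$ph_y[sel] <- y
  st$pn <- st$pn + n
  invisible(list(qe = qe, we = we))
}

# A^-1 as a sparse matrix over the entities created so far
current_a_inverse <- function(st) {
  i <- unlist(lapply(st$trip, `[[`, "i"), use.names = FALSE)
  j <- unlist(lapply(st$trip, `[[`, "j"), use.names = FALSE)
  x <- unlist(lapply(st$trip, `[[`, "x"), use.names = FALSE)
  Ainv <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(st$E, st$E))
  Matrix::forceSymmetric(Ainv)
}

# run the yearly BLUP evaluation; returns per-queen criterion values.
# Fast path equivalent to assemble_mme() + solve_mme() (checked by the
# test suite): interleaved unknown order with the overall mean as the
# last unknown, incrementally cached genetic block, supernodal Cholesky.
blup_criteria <- function(st) {
  E <- st$E
  dimG <- 2L * E
  if (st$trip_done < length(st$trip)) {
    chunks <- st$trip[(st$trip_done + 1L):length(st$trip)]
    i <- unlist(lapply(chunks, `[[`, "i"), use.names = FALSE)
    j <- unlist(lapply(chunks, `[[`, "j"), use.names = FALSE)
    x <- unlist(lapply(chunks, `[[`, "x"), use.names = FALSE)
    S <- st$Gscale
    Gnew <- Matrix::sparseMatrix(
      i = c(2 * i - 1, 2 * i - 1, 2 * i, 2 * i),
      j = c(2 * j - 1, 2 * j, 2 * j - 1, 2 * j),
      x = c(x * S[1, 1], x * S[1, 2], x * S[2, 1], x * S[2, 2]),
      dims = c(dimG, dimG))
    if (!is.null(st$G_cache)) {
      pad <- dimG - nrow(st$G_cache)
      G <- Matrix::bdiag(st$G_cache, Matrix::Matrix(0, pad, pad,
                                                    sparse = TRUE)) + Gnew
    } else G <- Gnew
    st$G_cache <- G
    st$trip_done <- length(st$trip)
  }
  n <- st$pn
  qe <- st$ph_q[seq_len(n)]; we <- st$ph_w[seq_len(n)]
  W <- Matrix::sparseMatrix(
    i = rep(seq_len(n), 3),
    j = c(2L * qe - 1L, 2L * we, rep(dimG + 1L, n)),
    x = 1, dims = c(n, dimG + 1L))
  C <- Matrix::forceSymmetric(
    Matrix::crossprod(W) +
      Matrix::bdiag(st$G_cache, Matrix::Matrix(0, 1, 1, sparse = TRUE)))
  rhs <- as.numeric(Matrix::crossprod(W, st$ph_y[seq_len(n)]))
  ch <- Matrix::Cholesky(C, LDL = FALSE, super = TRUE, perm = TRUE)
  sol <- as.numeric(Matrix::solve(ch, rhs))
  crit <- rep(NA_real_, st$nq)
  tested <- which(st$went[seq_len(st$nq)] > 0L)
  went <- st$went[tested]
  crit[tested] <- sol[2L * went - 1L] + sol[2L * went]
  crit
}

# --- mating ----------------------------------------------------------------

#' Set up the year's mating stations
#'
#' The `N_s` best three-year-old breeding queens (by the current selection
#' criterion) each produce a sister group of DPQs that stocks one isolated
#' station. During the start-up years of the scheme, while the only
#' queens old enough are unselected base queens, the stations are stocked
#' from randomly chosen queens of the oldest available cohort: the
#' paternal selection path only opens once the first selected generation
#' reaches age three. DPQs are unmated -- drones arise from unfertilised
#' eggs -- and serve only in their birth year.
#'
#' @param state A `bee_population`.
#' @param criteria Per-queen criterion values from the current evaluation.
#' @return Invisibly, the station table of the year.
#' @export
setup_mating_stations <- function(state, criteria) {
  st <- state
  cfg <- st$cfg
  t <- st$year
  src_pool <- which(st$cat[seq_len(st$nq)] == CAT_BQ & st$byear[seq_len(st$nq)] == t - 3L)
  if (!length(src_pool))  # bootstrap: oldest available cohort
    src_pool <- which(st$cat[seq_len(st$nq)] == CAT_BQ &
                        st$byear[seq_len(st$nq)] == t - 2L)
  if (length(src_pool) < cfg$N_s)
    stop("not enough queens to stock the mating stations", call. = FALSE)
  base_pool <- all(st$byear[src_pool] <= 2L)
  if (cfg$selection == "random" || base_pool) {
    src <- sort(src_pool[sample.int(length(src_pool), cfg$N_s)])
  } else {
    ord <- order(-criteria[src_pool], src_pool)
    src <- src_pool[ord[seq_len(cfg$N_s)]]
  }
  k <- cfg$dpq_per_station
  n <- cfg$N_s * k
  dams <- rep(src, each = k)
  idx <- make_offspring(st, dams, CAT_DPQ)
  dpq_q <- matrix(idx, cfg$N_s, k, byrow = TRUE)
  # observed entities for the DPQs
  qe <- new_entities(st, n)
  st$etype[qe] <- 1L
  st$equeen[qe] <- idx
  st$ebyear[qe] <- t
  st$edam_ent[qe] <- st$qent[dams]
  st$esire_gid[qe] <- st$mate_stgid[dams]
  st$qent[idx] <- qe
  st$Fhat[idx] <- kinB_add(st, qe, 2L, damloc = st$obsloc[st$qent[dams]],
                           wparloc = st$obsloc[st$went[dams]])
  nd <- cfg$n_drones
  d_mend <- 0.25 * ((1 - 1 / nd) * (2 - st$mate_s[dams]) + 1 -
                      st$Fhat[dams])
  push_one_parent(st, qe, st$went[dams], 1, d_mend)
  dpq_ent <- matrix(qe, cfg$N_s, k, byrow = TRUE)
  # station drone-relationship scalar s from the observed window
  svec <- numeric(cfg$N_s)
  for (j in seq_len(cfg$N_s)) {
    loc <- st$obsloc[dpq_ent[j, ]]
    svec[j] <- mean(st$K_obs[loc, loc])
  }
  gids <- st$station_gid + seq_len(cfg$N_s)
  st$station_gid <- st$station_gid + cfg$N_s
  for (j in seq_len(cfg$N_s))
    st$station_dpq_ents[[gids[j]]] <- dpq_ent[j, ]
  st$stations_cur <- list(year = t, dpq_q = dpq_q, dpq_ent = dpq_ent,
                          s = svec, gid = gids, source = src)
  invisible(st$stations_cur)
}

#' Mate a cohort on the year's stations
#'
#' Each queen is assigned one station uniformly at random and mates with
#' `drones_per_mating` drones; each drone's dam is drawn uniformly (with
#' replacement) among the station's DPQs, and the drone receives his dam's
#' TBV plus unshrunken-by-`F` Mendelian noise (haplodiploid inheritance,
#' diploid-equivalent scale).
#'
#' @param state A `bee_population` with stations set up for the year.
#' @param qidx Global queen indices of the cohort to mate.
#' @return Invisibly, the station assignment of each queen.
#' @export
mate_controlled <- function(state, qidx) {
  st <- state
  cfg <- st$cfg
  stc <- st$stations_cur
  if (is.null(stc) || stc$year != st$year)
    stop("no mating stations set up for this year", call. = FALSE)
  n <- length(qidx)
  nd <- cfg$n_drones
  k <- cfg$dpq_per_station
  stn <- sample.int(cfg$N_s, n, replace = TRUE)
  pick <- matrix(sample.int(k, n * nd, replace = TRUE), n, nd)
  ddam <- matrix(stc$dpq_q[cbind(rep(stn, nd), as.vector(pick))], n, nd)
  st$mate_dd[qidx, ] <- ddam
  if (st$finite) {
    hap <- gamete_rows(st$hap_mat[as.vector(ddam), , drop = FALSE],
                       st$hap_pat[as.vector(ddam), , drop = FALSE])
    st$dronehap[[st$year]] <- store_drone_haps(st, qidx, hap)
    bv <- tbv_rows(st$lm, hap)
  } else {
    phi <- rmvn2(n * nd, st$vc$Sigma)
    shrink <- sqrt(1 - st$Fq[as.vector(ddam)])
    bv <- cbind(st$bvm[as.vector(ddam)], st$bvd[as.vector(ddam)]) +
      shrink * phi
  }
  st$mate_m[qidx, ] <- bv[, 1]
  st$mate_d[qidx, ] <- bv[, 2]
  st$mate_s[qidx] <- stc$s[stn]
  st$mate_stgid[qidx] <- stc$gid[stn]
  invisible(stn)
}

#' Mate a cohort by free (uncontrolled) mating
#'
#' Every drone's dam is drawn uniformly with replacement from all living
#' queens one to three years old, breeding and passive population pooled,
#' so a drone's dam is a BQ with probability `N_b / (N_b + N_p)`. With an
#' infinite passive population every drone is created as if from the base
#' population. Sires are unknown to the genetic evaluation.
#'
#' @param state A `bee_population`.
#' @param qidx Global queen indices of the cohort to mate.
#' @return Invisibly, `qidx`.
#' @export
mate_uncontrolled <- function(state, qidx) {
  st <- state
  cfg <- st$cfg
  if (cfg$infinite_passive) return(mate_base(st, qidx))
  t <- st$year
  nq <- st$nq
  pool <- which((st$cat[seq_len(nq)] == CAT_BQ |
                   st$cat[seq_len(nq)] == CAT_PQ) &
                  st$byear[seq_len(nq)] >= t - 3L &
                  st$byear[seq_len(nq)] <= t - 1L)
  if (!length(pool))
    stop("no queens aged 1-3 available as drone dams", call. = FALSE)
  n <- length(qidx)
  nd <- cfg$n_drones
  ddam <- matrix(pool[sample.int(length(pool), n * nd, replace = TRUE)],
                 n, nd)
  st$mate_dd[qidx, ] <- ddam
  if (st$finite) {
    hap <- gamete_rows(st$hap_mat[as.vector(ddam), , drop = FALSE],
                       st$hap_pat[as.vector(ddam), , drop = FALSE])
    st$dronehap[[st$year]] <- store_drone_haps(st, qidx, hap)
    bv <- tbv_rows(st$lm, hap)
  } else {
    phi <- rmvn2(n * nd, st$vc$Sigma)
    shrink <- sqrt(1 - st$Fq[as.vector(ddam)])
    bv <- cbind(st$bvm[as.vector(ddam)], st$bvd[as.vector(ddam)]) +
      shrink * phi
  }
  st$mate_m[qidx, ] <- bv[, 1]
  st$mate_d[qidx, ] <- bv[, 2]
  st$mate_s[qidx] <- 0
  st$mate_stgid[qidx] <- 0L
  invisible(qidx)
}

# --- offspring -------------------------------------------------------------

#' Produce offspring queens from mated dams
#'
#' Each offspring's father is drawn uniformly with replacement from her
#' dam's stored drones; the TBV follows the midparent rule with the dam's
#' Mendelian noise shrunk by her inbreeding, and the offspring inbreeding
#' coefficient is the kinship between dam and father drone on the full
#' pedigree.
#'
#' @param state A `bee_population`.
#' @param dams Global queen indices (one entry per offspring; repeat a dam
#'   to give her several daughters).
#' @param category `1` = BQ, `2` = DPQ, `3` = PQ.
#' @return Global queen indices of the offspring.
#' @export
make_offspring <- function(state, dams, category) {
  st <- state
  cfg <- st$cfg
  n <- length(dams)
  nd <- cfg$n_drones
  slot <- sample.int(nd, n, replace = TRUE)
  idx <- new_queen_rows(st, n)
  st$cat[idx] <- category
  st$byear[idx] <- st$year
  st$dam[idx] <- dams
  st$fdam[idx] <- st$mate_dd[cbind(dams, slot)]
  st$fslot[idx] <- slot
  if (st$finite) {
    gam <- gamete_rows(st$hap_mat[dams, , drop = FALSE],
                       st$hap_pat[dams, , drop = FALSE])
    fhap <- drone_hap_rows(st, dams, slot)
    st$hap_mat[idx, ] <- gam
    st$hap_pat[idx, ] <- fhap
    bv <- tbv_rows(st$lm, gam, fhap)
    st$Fq[idx] <- 0
  } else {
    drone_bv <- cbind(st$mate_m[cbind(dams, slot)],
                      st$mate_d[cbind(dams, slot)])
    phi <- rmvn2(n, st$vc$Sigma)
    bv <- 0.5 * (cbind(st$bvm[dams], st$bvd[dams]) + drone_bv +
                   sqrt(1 - st$Fq[dams]) * phi)
  }
  st$bvm[idx] <- bv[, 1]; st$bvd[idx] <- bv[, 2]
  if (!st$finite) kinA_add(st, idx)
  idx
}

#' Select the year's dams
#'
#' The best `dam_fraction` of two-year-old breeding queens by the
#' selection criterion (worker-group EBV sum); ties break by ascending
#' queen id. Under `selection = "random"` the dams are drawn uniformly.
#'
#' @param state A `bee_population`.
#' @param criteria Per-queen criterion values (NA for untested queens).
#' @return Integer vector of dam queen indices (length `n_dams`).
#' @export
select_dams <- function(state, criteria) {
  st <- state
  cfg <- st$cfg
  t <- st$year
  cohort <- which(st$cat[seq_len(st$nq)] == CAT_BQ &
                    st$byear[seq_len(st$nq)] == t - 2L)
  if (!length(cohort)) stop("no two-year-old breeding queens", call. = FALSE)
  if (cfg$selection == "random") {
    dams <- sort(cohort[sample.int(length(cohort), cfg$n_dams)])
    s_crit <- s_true <- NA_real_
  } else {
    crit <- criteria[cohort]
    ord <- order(-crit, cohort)
    dams <- cohort[ord[seq_len(cfg$n_dams)]]
    s_crit <- mean(crit[ord[seq_len(cfg$n_dams)]]) - mean(crit)
    tot <- st$bvm + st$bvd
    s_true <- mean(tot[dams]) - mean(tot[cohort])
  }
  st$sel[[length(st$sel) + 1L]] <-
    data.frame(year = t, S_crit = s_crit, S_true = s_true)
  dams
}

#' Breed the passive cohort of the year
#'
#' A fraction `q` of the `N_p` new passive queens (rounded half-up) has a
#' dam drawn uniformly among breeding queens aged one to three; the rest
#' have passive dams of the same ages. The new passive queens then mate
#' uncontrolled. Passive queens inherit and pass on true breeding values
#' but are never performance tested and never enter the evaluation.
#'
#' @param state A `bee_population`.
#' @return Global queen indices of the new PQ cohort.
#' @export
breed_passive_cohort <- function(state) {
  st <- state
  cfg <- st$cfg
  if (st$Npf == 0L) return(integer(0))
  t <- st$year
  nq <- st$nq
  n_bq <- round_half_up(cfg$q * st$Npf)
  bq_pool <- which(st$cat[seq_len(nq)] == CAT_BQ &
                     st$byear[seq_len(nq)] >= t - 3L &
                     st$byear[seq_len(nq)] <= t - 1L)
  pq_pool <- which(st$cat[seq_len(nq)] == CAT_PQ &
                     st$byear[seq_len(nq)] >= t - 3L &
                     st$byear[seq_len(nq)] <= t - 1L)
  if (n_bq > 0L && !length(bq_pool))
    stop("q > 0 but no living breeding queens", call. = FALSE)
  dams <- c(bq_pool[sample.int(length(bq_pool), n_bq, replace = TRUE)],
            pq_pool[sample.int(length(pq_pool), st$Npf - n_bq,
                               replace = TRUE)])
  idx <- make_offspring(st, dams, CAT_PQ)
  mate_uncontrolled(st, idx)
  idx
}

# --- yearly cycle ----------------------------------------------------------

record_cohorts <- function(st, t) {
  for (pop in c("breeding", "passive")) {
    cat_want <- if (pop == "breeding") CAT_BQ else CAT_PQ
    cohort <- which(st$cat[seq_len(st$nq)] == cat_want &
                      st$byear[seq_len(st$nq)] == t)
    if (!length(cohort)) next
    tot <- st$bvm[cohort] + st$bvd[cohort]
    st$traj[[length(st$traj) + 1L]] <- data.frame(
      year = t, pop = pop, n = length(cohort),
      mean_m = mean(st$bvm[cohort]), mean_d = mean(st$bvd[cohort]),
      mean_total = mean(tot), sd_total = sd(tot),
      mean_F = if (st$finite) NA_real_ else mean(st$Fq[cohort]))
  }
}

#' Advance the population by one year
#'
#' Runs one cycle of the breeding scheme: genetic evaluation of all
#' records to date, dam selection among two-year-old BQ, station set-up
#' from three-year-old BQ (controlled mating), creation and mating of the
#' new BQ cohort, creation and free mating of the new PQ cohort, and
#' performance testing of the new BQ colonies. Queens older than three
#' years leave the pool of potential dam and drone sources implicitly
#' through the age window.
#'
#' @param state A `bee_population`.
#' @return The state, invisibly.
#' @export
advance_year <- function(state) {
  st <- state
  cfg <- st$cfg
  t <- st$year + 1L
  st$year <- t
  criteria <- if (cfg$selection == "blup") blup_criteria(st) else NULL
  dams <- select_dams(st, criteria)
  if (cfg$controlled) setup_mating_stations(st, criteria)
  # new breeding cohort: daughters of the selected dams
  dam_vec <- rep(dams, each = cfg$daughters_per_dam)
  if (length(dam_vec) > cfg$N_b) dam_vec <- dam_vec[seq_len(cfg$N_b)]
  if (length(dam_vec) < cfg$N_b)
    dam_vec <- rep(dams, length.out = cfg$N_b)
  bq <- make_offspring(st, dam_vec, CAT_BQ)
  if (cfg$controlled) {
    stn <- mate_controlled(st, bq)
    add_bq_entities_and_tests(st, bq,
                              dpq_ent_rows = st$stations_cur$dpq_ent[stn, ,
                                                                     drop = FALSE],
                              svec = st$stations_cur$s[stn])
  } else {
    mate_uncontrolled(st, bq)
    add_bq_entities_and_tests(st, bq)
  }
  breed_passive_cohort(st)
  record_cohorts(st, t)
  invisible(st)
}
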