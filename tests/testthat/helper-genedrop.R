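# Gene-dropping oracles: Monte-Carlo identity-by-descent simulation used as
# the independent check of the recursive kinship / relationship machinery.
# Alleles are integers; every base allele is globally unique.

# Drop alleles through a full haplodiploid pedigree. Returns a list with,
# per individual, an ndrops x 2 (queens) or ndrops x 1 (drones) matrix of
# allele ids.
gene_drop_full <- function(ped, ndrops = 10000) {
  n <- nrow(ped)
  alleles <- vector("list", n)
  counter <- 0L
  for (i in seq_len(n)) {
    dam <- ped$dam_id[i]
    if (ped$kind[i] == "drone") {
      if (dam == 0L) {
        alleles[[i]] <- matrix(counter + seq_len(ndrops), ncol = 1)
        counter <- counter + ndrops
      } else {
        pick <- sample.int(2L, ndrops, replace = TRUE)
        alleles[[i]] <- matrix(alleles[[dam]][cbind(seq_len(ndrops), pick)],
                               ncol = 1)
      }
    } else if (dam == 0L) {
      alleles[[i]] <- matrix(counter + seq_len(2L * ndrops), ncol = 2)
      counter <- counter + 2L * ndrops
    } else {
      sire <- ped$sire_id[i]
      pick <- sample.int(2L, ndrops, replace = TRUE)
      mat <- alleles[[dam]][cbind(seq_len(ndrops), pick)]
      alleles[[i]] <- cbind(mat, alleles[[sire]][, 1])
    }
  }
  alleles
}

# Monte-Carlo kinship estimate from dropped alleles: probability that a
# random allele of a is IBD to a random allele of b.
gd_kinship <- function(alleles, a, b) {
  A <- alleles[[a]]; B <- alleles[[b]]
  if (a == b) {
    if (ncol(A) == 1) return(1)
    return(mean(0.5 * (1 + (A[, 1] == A[, 2]))))
  }
  tot <- 0
  for (i in seq_len(ncol(A))) for (j in seq_len(ncol(B)))
    tot <- tot + mean(A[, i] == B[, j])
  tot / (ncol(A) * ncol(B))
}

gd_inbreeding <- function(alleles, a) {
  A <- alleles[[a]]
  stopifnot(ncol(A) == 2)
  mean(A[, 1] == A[, 2])
}

# Gene dropping through an *observed* pedigree (bee_pedigree): follows the
# observed model's mechanics exactly. Each mating realises its dozen
# drones once per drop (shared by the worker group and all daughters);
# station drones take a dam uniformly among the station's DPQs; unknown
# sires yield fresh base drones. Worker groups are allele *distributions*:
# two independent draws per drop (1/2 dam allele, 1/2 random drone allele).
# Returns the estimated relationship matrix on the 2*kinship scale used by
# build_relationship_dense().
gene_drop_observed <- function(ped, ndrops = 10000) {
  r <- ped$records
  n <- nrow(r)
  nd <- ped$n_drones
  alleles <- vector("list", n)   # queens: ndrops x 2; workers: ndrops x 2 draws
  counter <- 0L
  rows <- seq_len(ndrops)
  # realise each mating's drones lazily, keyed by dam id
  drones <- new.env(parent = emptyenv())  # dam -> ndrops x nd allele matrix
  mating_drones <- function(dam, st) {
    key <- as.character(dam)
    if (!is.null(drones[[key]])) return(drones[[key]])
    if (st > 0L) {
      dpq <- ped$stations[[as.character(st)]]
      dmat <- matrix(dpq[sample.int(length(dpq), ndrops * nd, replace = TRUE)],
                     ndrops, nd)
      out <- matrix(0L, ndrops, nd)
      for (k in seq_len(nd)) {
        pick <- sample.int(2L, ndrops, replace = TRUE)
        dmk <- dmat[, k]
        for (q in unique(dmk)) {
          sel <- dmk == q
          out[sel, k] <- alleles[[q]][cbind(which(sel), pick[sel])]
        }
      }
    } else {
      out <- matrix(counter + seq_len(ndrops * nd), ndrops, nd)
      counter <<- counter + ndrops * nd
    }
    drones[[key]] <- out
    out
  }
  draw_of <- function(i) {
    # one random-allele draw per drop for entity i (queens: pick of 2)
    A <- alleles[[i]]
    A[cbind(rows, sample.int(2L, ndrops, replace = TRUE))]
  }
  for (i in seq_len(n)) {
    dam <- r$dam_id[i]
    if (dam == 0L) {
      alleles[[i]] <- matrix(counter + seq_len(2L * ndrops), ncol = 2)
      counter <- counter + 2L * ndrops
      next
    }
    dz <- mating_drones(dam, r$sire_ref[i])
    if (r$kind[i] == "queen") {
      father <- sample.int(nd, ndrops, replace = TRUE)
      alleles[[i]] <- cbind(draw_of(dam), dz[cbind(rows, father)])
    } else {
      # two independent worker-group draws
      one_draw <- function() {
        use_dam <- sample.int(2L, ndrops, replace = TRUE) == 1L
        out <- integer(ndrops)
        out[use_dam] <- draw_of(dam)[use_dam]
        k <- sample.int(nd, ndrops, replace = TRUE)
        out[!use_dam] <- dz[cbind(rows, k)][!use_dam]
        out
      }
      alleles[[i]] <- cbind(one_draw(), one_draw())
    }
  }
  # relationship estimate: A = 2 * f, with exact-draw averaging for queens
  Ahat <- matrix(0, n, n)
  for (a in seq_len(n)) {
    for (b in seq_len(a)) {
      if (a == b) {
        f <- if (r$kind[a] == "queen")
          mean(0.5 * (1 + (alleles[[a]][, 1] == alleles[[a]][, 2])))
        else mean(alleles[[a]][, 1] == alleles[[a]][, 2])
      } else {
        f <- 0.25 * (mean(alleles[[a]][, 1] == alleles[[b]][, 1]) +
                     mean(alleles[[a]][, 1] == alleles[[b]][, 2]) +
                     mean(alleles[[a]][, 2] == alleles[[b]][, 1]) +
                     mean(alleles[[a]][, 2] == alleles[[b]][, 2]))
      }
      Ahat[a, b] <- Ahat[b, a] <- 2 * f
    }
  }
  Ahat
}

# Random observed pedigree with stations, for property tests.
random_observed_pedigree <- function(n_base = 8, n_stations = 2,
                                     n_g2 = 10, n_g3 = 6, dpq = 4,
                                     n_drones = 12, p_station = 0.6) {
  rec <- data.frame(id = integer(), kind = character(), dam_id = integer(),
                    sire_ref = integer(), birth_year = integer())
  add <- function(kind, dam, sire, yr) {
    rec <<- rbind(rec, data.frame(id = nrow(rec) + 1L, kind = kind,
                                  dam_id = dam, sire_ref = sire,
                                  birth_year = yr))
    nrow(rec)
  }
  for (i in seq_len(n_base)) add("queen", 0L, 0L, 1L)
  # base queens are mated to base drones (sire 0); give each a worker group
  for (q in seq_len(n_base)) add("worker", q, 0L, 1L)
  stations <- list()
  for (st in seq_len(n_stations)) {
    src <- sample.int(n_base, 1L)
    stations[[as.character(st)]] <-
      vapply(seq_len(dpq), function(k) add("queen", src, 0L, 2L), 1L)
  }
  mating <- integer(0)  # per queen id: her mating's sire_ref
  mating[seq_len(n_base)] <- 0L
  g2 <- integer(0)
  for (i in seq_len(n_g2)) {
    dam <- sample.int(n_base, 1L)
    q <- add("queen", dam, mating[dam], 2L)
    mating[q] <- if (n_stations > 0 && runif(1) < p_station)
      sample.int(n_stations, 1L) else 0L
    add("worker", q, mating[q], 2L)
    g2 <- c(g2, q)
  }
  for (i in seq_len(n_g3)) {
    dam <- sample(g2, 1L)
    q <- add("queen", dam, mating[dam], 3L)
    mating[q] <- if (n_stations > 0 && runif(1) < p_station)
      sample.int(n_stations, 1L) else 0L
    add("worker", q, mating[q], 3L)
  }
  bee_pedigree(rec, stations, n_drones = n_drones)
}

# Random full haplodiploid pedigree (queens + drones), for kinship tests.
random_full_pedigree <- function(n_base = 6, n_extra = 30, p_drone = 0.4) {
  id <- integer(); kind <- character(); dam <- integer(); sire <- integer()
  add <- function(k, d, s) {
    id <<- c(id, length(id) + 1L); kind <<- c(kind, k)
    dam <<- c(dam, d); sire <<- c(sire, s)
    length(id)
  }
  pick1 <- function(v) v[sample.int(length(v), 1L)]
  for (i in seq_len(n_base)) add("queen", 0L, 0L)
  for (i in seq_len(n_extra)) {
    queens <- which(kind == "queen")
    if (runif(1) < p_drone || !any(kind == "drone")) {
      add("drone", pick1(queens), 0L)
    } else {
      add("queen", pick1(queens), pick1(which(kind == "drone")))
    }
  }
  full_pedigree(id, kind, dam, sire)
}
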