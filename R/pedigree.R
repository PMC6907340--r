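#' Full (simulation-truth) pedigree
#'
#' The full pedigree records every queen's dam and her actual father drone,
#' and every drone's dam. It is the basis for exact inbreeding and kinship
#' under haplodiploid rules: a drone is a single gamete of his dam and
#' reproduces it clonally, so two offspring of the same drone share their
#' paternal allele with certainty.
#'
#' @param id Integer ids, strictly increasing; parents must precede
#'   offspring.
#' @param kind `"queen"` or `"drone"`.
#' @param dam_id Dam id (a queen) or 0 for base individuals.
#' @param sire_id For queens: the father drone's id, or 0 (base). Drones
#'   have no sire (0).
#' @param birth_year Optional integer year (used only for validation).
#' @return A `data.frame` of class `bee_full_pedigree`.
#' @export
full_pedigree <- function(id, kind, dam_id, sire_id,
                          birth_year = rep(NA_integer_, length(id))) {
  ped <- data.frame(id = as.integer(id), kind = as.character(kind),
                    dam_id = as.integer(dam_id),
                    sire_id = as.integer(sire_id),
                    birth_year = as.integer(birth_year))
  n <- nrow(ped)
  if (n && any(ped$id != seq_len(n)))
    stop("ids must be 1..n in order", call. = FALSE)
  if (!all(ped$kind %in% c("queen", "drone")))
    stop("kind must be 'queen' or 'drone'", call. = FALSE)
  if (any(ped$dam_id >= ped$id) || any(ped$sire_id >= ped$id))
    stop("parents must precede offspring", call. = FALSE)
  if (any(ped$dam_id > 0 & ped$kind[pmax(ped$dam_id, 1)] != "queen"))
    stop("dams must be queens", call. = FALSE)
  drone_rows <- ped$kind == "drone"
  if (any(ped$sire_id[drone_rows] != 0))
    stop("drones have no sire", call. = FALSE)
  sires <- ped$sire_id[!drone_rows]
  sires <- sires[sires > 0]
  if (length(sires) && !all(ped$kind[sires] == "drone"))
    stop("sires of queens must be drones", call. = FALSE)
  if (any((ped$dam_id == 0) != (ped$sire_id == 0) & !drone_rows))
    stop("queens are either base (no parents) or have both a dam and a ",
         "father drone", call. = FALSE)
  class(ped) <- c("bee_full_pedigree", "data.frame")
  ped
}

#' Kinship matrix of a full haplodiploid pedigree
#'
#' Tabular recursion adapted to haplodiploidy. For a queen `i` with dam `Q`
#' and father drone `D`: `f(i, j) = (f(Q, j) + f(D, j)) / 2` for earlier
#' `j`, and `f(i, i) = (1 + f(Q, D)) / 2`, so `F_i = f(Q, D)`. For a drone
#' `D` of dam `Q`: `f(D, j) = f(Q, j)` and `f(D, D) = 1` (a drone carries a
#' single allele per locus). Base individuals are unrelated and non-inbred.
#'
#' Intended for exact computation on pedigrees of moderate size (the
#' population simulator tracks kinship incrementally instead).
#'
#' @param ped A [full_pedigree()].
#' @return Dense symmetric matrix of kinship coefficients.
#' @export
kinship_matrix <- function(ped) {
  stopifnot(inherits(ped, "bee_full_pedigree"))
  n <- nrow(ped)
  K <- matrix(0, n, n)
  drone <- ped$kind == "drone"
  for (i in seq_len(n)) {
    dam <- ped$dam_id[i]
    if (drone[i]) {
      if (dam > 0) {
        K[i, seq_len(i - 1L)] <- K[dam, seq_len(i - 1L)]
        K[seq_len(i - 1L), i] <- K[i, seq_len(i - 1L)]
      }
      K[i, i] <- 1
    } else if (dam == 0L) {
      K[i, i] <- 0.5
    } else {
      sire <- ped$sire_id[i]
      j <- seq_len(i - 1L)
      K[i, j] <- 0.5 * (K[dam, j] + K[sire, j])
      K[j, i] <- K[i, j]
      K[i, i] <- 0.5 * (1 + K[dam, sire])
    }
  }
  K
}

#' Pairwise kinship coefficient
#'
#' Probability that a random allele from `id_a` is identical by descent to
#' a random allele from `id_b`. Self-kinship of a queen is `(1 + F) / 2`.
#'
#' @param ped A [full_pedigree()].
#' @param id_a,id_b Individual ids.
#' @return Kinship coefficient.
#' @export
kinship <- function(ped, id_a, id_b) {
  stopifnot(inherits(ped, "bee_full_pedigree"))
  n <- nrow(ped)
  if (any(c(id_a, id_b) < 1) || any(c(id_a, id_b) > n))
    stop("unknown individual id", call. = FALSE)
  K <- kinship_matrix(ped)
  K[id_a, id_b]
}

#' True inbreeding coefficient of a queen
#'
#' `F` is the probability that the queen's two alleles at a locus are
#' identical by descent, i.e. the kinship between her dam and her actual
#' father drone. Base queens have `F = 0`.
#'
#' @param ped A [full_pedigree()].
#' @param queen_id Id of a queen in `ped`.
#' @return Inbreeding coefficient in `[0, 1)`.
#' @export
true_inbreeding <- function(ped, queen_id) {
  stopifnot(inherits(ped, "bee_full_pedigree"))
  if (queen_id < 1 || queen_id > nrow(ped))
    stop("unknown individual id", call. = FALSE)
  if (ped$kind[queen_id] != "queen")
    stop("inbreeding is defined for queens (drones are haploid)",
         call. = FALSE)
  dam <- ped$dam_id[queen_id]
  if (dam == 0L) return(0)
  K <- kinship_matrix(ped)
  K[dam, ped$sire_id[queen_id]]
}

# ---------------------------------------------------------------------------
# Observed pedigree: what the breeder (and BLUP) can see.
# ---------------------------------------------------------------------------

#' Observed pedigree with mating stations as pseudo-sires
#'
#' The observed pedigree contains the entities that enter the genetic
#' evaluation: queens (breeding queens and drone-producing queens) and
#' worker groups. Sires are recorded as mating stations (a sister group of
#' drone-producing queens, DPQ) when mating was controlled, and as unknown
#' otherwise; unknown sires are treated as random draws from the base
#' population. Passive queens never appear here.
#'
#' All offspring of one queen (her worker group and all her daughters)
#' stem from the same mating -- the same set of stored drones -- which the
#' relationship machinery accounts for.
#'
#' @param records A `data.frame` with columns `id` (1..n, parents precede
#'   offspring), `kind` (`"queen"` or `"worker"`), `dam_id` (0 for base
#'   queens), `sire_ref` (station id, or 0 for unknown/base) and
#'   `birth_year`.
#' @param stations Named list mapping station id (as character) to the
#'   integer ids of the station's DPQs (daughters of one source queen,
#'   normally 8 sisters).
#' @param n_drones Number of drones per mating (default 12).
#' @return An object of class `bee_pedigree`.
#' @export
bee_pedigree <- function(records, stations = list(), n_drones = 12) {
  records <- data.frame(id = as.integer(records$id),
                        kind = as.character(records$kind),
                        dam_id = as.integer(records$dam_id),
                        sire_ref = as.integer(records$sire_ref),
                        birth_year = as.integer(records$birth_year))
  n <- nrow(records)
  if (n && any(records$id != seq_len(n)))
    stop("ids must be 1..n in order", call. = FALSE)
  if (!all(records$kind %in% c("queen", "worker")))
    stop("kind must be 'queen' or 'worker'", call. = FALSE)
  if (any(records$dam_id >= records$id))
    stop("dams must precede their offspring", call. = FALSE)
  if (any(records$kind == "worker" & records$dam_id == 0L))
    stop("worker groups must have a queen (dam)", call. = FALSE)
  base <- records$kind == "queen" & records$dam_id == 0L
  if (any(records$sire_ref[base] != 0L))
    stop("base queens have no sire", call. = FALSE)
  if (length(stations)) {
    ids <- suppressWarnings(as.integer(names(stations)))
    if (any(is.na(ids))) stop("station names must be integer ids",
                              call. = FALSE)
    for (st in stations) {
      st <- as.integer(st)
      if (!length(st) || any(st < 1) || any(st > n) ||
          !all(records$kind[st] == "queen"))
        stop("station DPQs must be queens in the pedigree", call. = FALSE)
    }
  }
  used <- unique(records$sire_ref[records$sire_ref > 0L])
  if (!all(as.character(used) %in% names(stations)))
    stop("sire_ref refers to an undefined station", call. = FALSE)
  # one mating per queen: all offspring of a dam share one sire_ref
  off <- records[records$dam_id > 0L, ]
  if (nrow(off)) {
    sp <- split(off$sire_ref, off$dam_id)
    if (any(vapply(sp, function(x) length(unique(x)), 1L) > 1L))
      stop("all offspring of one queen must share her single mating",
           call. = FALSE)
  }
  w <- which(records$kind == "worker")
  if (anyDuplicated(records$dam_id[w]))
    stop("a queen has at most one worker group", call. = FALSE)
  # daughters are modelled through their colony's worker group, so a
  # queen's worker group must precede all her daughter entities
  dtr <- which(records$kind == "queen" & records$dam_id > 0L)
  if (length(dtr)) {
    widx <- rep(NA_integer_, n)
    widx[records$dam_id[w]] <- w
    bad <- is.na(widx[records$dam_id[dtr]]) |
      widx[records$dam_id[dtr]] > dtr
    if (any(bad))
      stop("every daughter must be preceded by her dam's worker group",
           call. = FALSE)
  }
  structure(list(records = records, stations = stations,
                 n_drones = as.integer(n_drones)),
            class = "bee_pedigree")
}

#' @export
print.bee_pedigree <- function(x, ...) {
  r <- x$records
  cat(sprintf(paste0("Observed honeybee pedigree: %d entities ",
                     "(%d queens, %d worker groups), %d mating stations\n"),
              nrow(r), sum(r$kind == "queen"), sum(r$kind == "worker"),
              length(x$stations)))
  invisible(x)
}

#' Read / write the observed-pedigree CSV dialect
#'
#' The pedigree is written to `<path>` with columns `id`, `kind`,
#' `dam_id`, `sire_ref`, `birth_year` (0 or empty meaning unknown/base).
#' Station membership is written to a companion file
#' `<path base>_stations.csv` with columns `station_id`, `dpq_id`.
#'
#' @param ped A [bee_pedigree()].
#' @param path CSV file path.
#' @return `read_pedigree_csv` returns a [bee_pedigree()];
#'   `write_pedigree_csv` returns `path` invisibly.
#' @export
write_pedigree_csv <- function(ped, path) {
  stopifnot(inherits(ped, "bee_pedigree"))
  write.csv(ped$records, path, row.names = FALSE, quote = FALSE)
  st <- ped$stations
  sdf <- if (length(st)) {
    data.frame(station_id = rep(as.integer(names(st)), lengths(st)),
               dpq_id = unlist(st, use.names = FALSE))
  } else data.frame(station_id = integer(), dpq_id = integer())
  write.csv(sdf, station_companion_path(path), row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' @rdname write_pedigree_csv
#' @export
read_pedigree_csv <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("dam_id", "sire_ref"))
    rec[[col]][is.na(rec[[col]])] <- 0L
  spath <- station_companion_path(path)
  stations <- list()
  if (file.exists(spath)) {
    sdf <- read.csv(spath, stringsAsFactors = FALSE)
    if (nrow(sdf))
      stations <- lapply(split(sdf$dpq_id, sdf$station_id), as.integer)
  }
  bee_pedigree(rec, stations)
}

station_companion_path <- function(path) {
  sub("(\\.[^.]*)?$", "_stations\\1", path)
}
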