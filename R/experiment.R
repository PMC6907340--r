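#' Run one replicate of a breeding scheme
#'
#' Simulates the configured number of years and returns the per-year,
#' per-population trajectory of cohort statistics together with the
#' yearly selection differentials. Bit-reproducible for a given
#' `(config, seed)` pair.
#'
#' @param config A [scheme_config()].
#' @param seed Integer seed for the replicate's random stream.
#' @param keep_state Keep the full population state (for diagnostics and
#'   pedigree export)? Default `FALSE`.
#' @return A `bee_replicate`: list with `trajectory` (`data.frame`: year,
#'   pop, n, mean_m, mean_d, mean_total, sd_total, mean_F), `selection`
#'   (year, S_crit, S_true), `config`, `seed`, and optionally `state`.
#' @export
run_replicate <- function(config, seed, keep_state = FALSE) {
  stopifnot(inherits(config, "bee_scheme_config"))
  set.seed(as.integer(seed))
  st <- initialize_population(config)
  if (config$years >= 3)
    for (t in 3:config$years) advance_year(st)
  out <- list(trajectory = do.call(rbind, st$traj),
              selection = if (length(st$sel)) do.call(rbind, st$sel) else
                data.frame(year = integer(), S_crit = numeric(),
                           S_true = numeric()),
              config = config, seed = as.integer(seed))
  if (keep_state) out$state <- st
  class(out) <- "bee_replicate"
  out
}

#' @export
print.bee_replicate <- function(x, ...) {
  g <- tryCatch(genetic_gain(x$trajectory), error = function(e) NA)
  cat(sprintf("Replicate (seed %d): %d years; gain year 5 to %d = %s\n",
              x$seed, x$config$years, x$config$years,
              ifelse(is.na(g), "NA", sprintf("%.3f", g))))
  invisible(x)
}

traj_of <- function(x) {
  if (inherits(x, "bee_replicate")) x$trajectory else x
}

cohort_means <- function(traj, pop) {
  tr <- traj[traj$pop == pop, ]
  tr[order(tr$year), ]
}

#' Genetic gain between two birth cohorts
#'
#' Difference of the cohort-mean total true breeding value of queens
#' between `to_year` and `from_year` (birth cohorts of the chosen
#' population).
#'
#' @param x A `bee_replicate` or its trajectory `data.frame`.
#' @param from_year,to_year Birth cohorts compared (defaults 5 and 20).
#' @param pop `"breeding"` or `"passive"`.
#' @return Genetic gain in trait units.
#' @export
genetic_gain <- function(x, from_year = 5, to_year = 20,
                         pop = "breeding") {
  tr <- cohort_means(traj_of(x), pop)
  a <- tr$mean_total[tr$year == from_year]
  b <- tr$mean_total[tr$year == to_year]
  if (!length(a) || !length(b))
    stop("trajectory does not cover the requested years", call. = FALSE)
  b - a
}

#' Decompose genetic gain into maternal and direct components
#'
#' Component gains over the same window as [genetic_gain()], and the
#' ratio of the larger to the smaller component in absolute value (the
#' direct:maternal ratio when the direct gain dominates).
#'
#' @inheritParams genetic_gain
#' @return List with `maternal`, `direct`, `ratio` (larger over smaller,
#'   `NA` with a flag when a component is zero) and `larger`
#'   (`"direct"`/`"maternal"`).
#' @export
decompose_gain <- function(x, from_year = 5, to_year = 20,
                           pop = "breeding") {
  tr <- cohort_means(traj_of(x), pop)
  a <- tr[tr$year == from_year, ]
  b <- tr[tr$year == to_year, ]
  if (!nrow(a) || !nrow(b))
    stop("trajectory does not cover the requested years", call. = FALSE)
  gm <- b$mean_m - a$mean_m
  gd <- b$mean_d - a$mean_d
  larger <- if (abs(gd) >= abs(gm)) "direct" else "maternal"
  ratio <- if (min(abs(gm), abs(gd)) == 0) NA_real_
           else max(abs(gm), abs(gd)) / min(abs(gm), abs(gd))
  list(maternal = gm, direct = gd, ratio = ratio, larger = larger)
}

#' Genetic lag of the passive behind the breeding population
#'
#' The mean breeding-minus-passive gap in cohort-mean total TBV over a
#' steady-state window, divided by the breeding population's fitted
#' linear rate of gain over the same window: the horizontal displacement,
#' in years, between the two parallel trajectories.
#'
#' @param x A `bee_replicate` or trajectory `data.frame` containing both
#'   populations.
#' @param window Years of the steady-state window (default 10:20).
#' @return Lag in years (`NA` with a warning if the breeding slope is not
#'   positive).
#' @export
genetic_lag <- function(x, window = 10:20) {
  traj <- traj_of(x)
  b <- cohort_means(traj, "breeding")
  p <- cohort_means(traj, "passive")
  b <- b[b$year %in% window, ]
  p <- p[p$year %in% window, ]
  if (!nrow(b) || !nrow(p) || nrow(b) != nrow(p))
    stop("both populations must cover the lag window", call. = FALSE)
  slope <- coef(lm(mean_total ~ year, data = b))[["year"]]
  if (slope <= 0) {
    warning("non-positive breeding-population slope; lag undefined")
    return(NA_real_)
  }
  mean(b$mean_total - p$mean_total) / slope
}

#' Correlation between breeding-population share and genetic gain
#'
#' Pearson correlation between `p = N_b / (N_b + N_p)` (0 for an infinite
#' passive population) and the genetic gain across uncontrolled `q = 0`
#' settings.
#'
#' @param results A `data.frame` with columns `p` and `gain`.
#' @return Correlation coefficient (`NA` with a warning if either
#'   variable is constant).
#' @export
gain_p_correlation <- function(results) {
  stopifnot(all(c("p", "gain") %in% names(results)))
  if (nrow(results) < 3)
    stop("need at least 3 settings", call. = FALSE)
  if (sd(results$p) == 0 || sd(results$gain) == 0) {
    warning("constant gains or proportions; correlation undefined")
    return(NA_real_)
  }
  cor(results$p, results$gain)
}

#' Enumerate the full simulation grid
#'
#' All combinations of `N_b` in \{500, 1000, 2000\}, `N_p` in \{0, 500,
#' 1000, 2000, Inf\}, `N_s` in \{0, 5, 10, 20\}, `q` in \{0, 0.25, 0.5,
#' 0.75, 1\} and the two maternal-direct covariances, with `N_p` in
#' \{0, Inf\} restricted to `q = 0`: 408 settings.
#'
#' @param N_b,N_p,N_s,q,sigma_Amd Optional restrictions of each axis.
#' @return A `data.frame` with one row per setting.
#' @export
enumerate_grid <- function(N_b = c(500, 1000, 2000),
                           N_p = c(0, 500, 1000, 2000, Inf),
                           N_s = c(0, 5, 10, 20),
                           q = c(0, 0.25, 0.5, 0.75, 1),
                           sigma_Amd = c(-0.75, -1.25)) {
  g <- expand.grid(N_b = N_b, N_p = N_p, N_s = N_s, q = q,
                   sigma_Amd = sigma_Amd, KEEP.OUT.ATTRS = FALSE)
  keep <- !((g$N_p == 0 | is.infinite(g$N_p)) & g$q != 0)
  g <- g[keep, ]
  rownames(g) <- NULL
  g
}

#' Run a grid of settings
#'
#' Executes `replicates` replicates of each setting row and returns
#' per-replicate summary rows plus aggregated means. Replicate seeds are
#' derived deterministically from `seed` and the row/replicate indices.
#'
#' @param grid A `data.frame` as from [enumerate_grid()] (columns `N_b`,
#'   `N_p`, `N_s`, `q`, `sigma_Amd`).
#' @param replicates Replicates per setting.
#' @param seed Root seed.
#' @param years Simulated years per replicate.
#' @param vc_template Base [variance_components()]; `sigma_Amd` is taken
#'   from the grid.
#' @param ... Further arguments passed to [scheme_config()].
#' @return List with `replicates` (one row per setting x replicate) and
#'   `summary` (one row per setting with mean gain and its SE).
#' @export
run_grid <- function(grid, replicates = 5, seed = 1, years = 20,
                     vc_template = variance_components(), ...) {
  rows <- list()
  for (r in seq_len(nrow(grid))) {
    gr <- grid[r, ]
    vc <- variance_components(vc_template$sigma2_Am, vc_template$sigma2_Ad,
                              gr$sigma_Amd, vc_template$sigma2_E)
    cfg <- scheme_config(N_b = gr$N_b, N_p = gr$N_p, N_s = gr$N_s,
                         q = gr$q, vc = vc, years = years, ...)
    for (rep in seq_len(replicates)) {
      rs <- replicate_seed(seed, r, rep)
      res <- run_replicate(cfg, rs)
      to <- min(years, 20)
      rows[[length(rows) + 1L]] <- data.frame(
        setting = r, N_b = gr$N_b, N_p = gr$N_p, N_s = gr$N_s, q = gr$q,
        sigma_Amd = gr$sigma_Amd, replicate = rep, seed = rs,
        gain_5_20 = genetic_gain(res, 5, to),
        gain_year5 = genetic_gain(res, 2, 5))
    }
  }
  reps <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(reps, reps$setting), function(d) {
    data.frame(d[1, c("setting", "N_b", "N_p", "N_s", "q", "sigma_Amd")],
               replicates = nrow(d), gain_5_20 = mean(d$gain_5_20),
               se_gain = sd(d$gain_5_20) / sqrt(nrow(d)))
  }))
  rownames(agg) <- NULL
  list(replicates = reps, summary = agg)
}

# deterministic per-replicate seed below 2^31
replicate_seed <- function(seed, setting, rep) {
  as.integer((as.numeric(seed) * 7919 + setting * 1009 + rep * 101) %%
               .Machine$integer.max)
}

#' Long-term (100-year) comparison under the finite-locus model
#'
#' Runs the three schemes compared in the long-horizon analysis --
#' uncontrolled mating; controlled mating with 20 stations and 20 % of BQ
#' selected as dams; and a relaxed controlled scheme with 50 stations and
#' 50 % of BQ as dams (2 daughters each) -- under the finite-locus model,
#' and reports the genetic response and the loss of the initial genetic
#' standard deviation of queens' total TBV.
#'
#' @param years Simulated years (default 100).
#' @param replicates Replicates per scheme.
#' @param seed Root seed.
#' @param N_b,N_p Population sizes (defaults 500 and 1000).
#' @param q Passive coupling (default 0.5).
#' @param vc Variance components (moderate negative covariance default).
#' @param n_loci Locus count (default 400).
#' @param schemes Subset of `c("uncontrolled", "controlled",
#'   "controlled_relaxed")` to run.
#' @return List with `summary` (per scheme: mean response, mean SD-loss
#'   percent) and `trajectories` (per scheme x replicate).
#' @export
run_long_term <- function(years = 100, replicates = 20, seed = 1,
                          N_b = 500, N_p = 1000, q = 0.5,
                          vc = variance_components(), n_loci = 400,
                          schemes = c("uncontrolled", "controlled",
                                      "controlled_relaxed")) {
  schemes <- match.arg(schemes, several.ok = TRUE)
  defs <- list(
    uncontrolled = list(N_s = 0, dam_fraction = 0.2, dpd = 5),
    controlled = list(N_s = 20, dam_fraction = 0.2, dpd = 5),
    controlled_relaxed = list(N_s = 50, dam_fraction = 0.5, dpd = 2))
  trajs <- list(); rows <- list()
  for (sc in schemes) {
    d <- defs[[sc]]
    cfg <- scheme_config(N_b = N_b, N_p = N_p, N_s = d$N_s, q = q, vc = vc,
                         years = years, dam_fraction = d$dam_fraction,
                         daughters_per_dam = d$dpd, model = "finite_locus",
                         n_loci = n_loci)
    for (rep in seq_len(replicates)) {
      rs <- replicate_seed(seed, match(sc, names(defs)), rep)
      res <- run_replicate(cfg, rs)
      tr <- cohort_means(res$trajectory, "breeding")
      sd0 <- mean(tr$sd_total[tr$year <= 2])
      sdT <- tr$sd_total[tr$year == years]
      rows[[length(rows) + 1L]] <- data.frame(
        scheme = sc, replicate = rep, seed = rs,
        response = tr$mean_total[tr$year == years] -
          mean(tr$mean_total[tr$year <= 2]),
        sd_loss_pct = 100 * (1 - sdT / sd0))
      trajs[[length(trajs) + 1L]] <- cbind(scheme = sc, replicate = rep,
                                           res$trajectory)
    }
  }
  reps <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(reps, reps$scheme), function(d) {
    data.frame(scheme = d$scheme[1], replicates = nrow(d),
               response = mean(d$response),
               sd_loss_pct = mean(d$sd_loss_pct))
  }))
  rownames(summ) <- NULL
  list(summary = summ, replicates = reps,
       trajectories = do.call(rbind, trajs))
}

#' Write simulation results to CSV with a JSON run manifest
#'
#' @param results A list as returned by [run_grid()] (or any list of
#'   `data.frame`s) to write; each element becomes `<prefix>_<name>.csv`.
#' @param path Output directory (created if missing).
#' @param prefix File-name prefix.
#' @param manifest Optional list (config, seeds, notes) written to
#'   `<prefix>_manifest.json`.
#' @return Character vector of the files written, invisibly.
#' @export
write_results <- function(results, path, prefix = "beebreedsim",
                          manifest = NULL) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  files <- character(0)
  for (nm in names(results)) {
    if (!is.data.frame(results[[nm]])) next
    f <- file.path(path, paste0(prefix, "_", nm, ".csv"))
    write.csv(results[[nm]], f, row.names = FALSE, quote = FALSE)
    files <- c(files, f)
  }
  if (!is.null(manifest)) {
    f <- file.path(path, paste0(prefix, "_manifest.json"))
    jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <- c(files, f)
  }
  invisible(files)
}

# ---------------------------------------------------------------------------
# Pedigree exports (diagnostics and cross-validation of the incremental
# engines against the standalone pedigree machinery).
# ---------------------------------------------------------------------------

#' Export the observed pedigree of a population state
#'
#' @param state A `bee_population` (from [run_replicate()] with
#'   `keep_state = TRUE`, or built directly).
#' @return A [bee_pedigree()] over all evaluated entities, in creation
#'   order.
#' @export
as_bee_pedigree <- function(state) {
  st <- state
  E <- st$E
  rec <- data.frame(id = seq_len(E),
                    kind = ifelse(st$etype[seq_len(E)] == 1L, "queen",
                                  "worker"),
                    dam_id = st$edam_ent[seq_len(E)],
                    sire_ref = st$esire_gid[seq_len(E)],
                    birth_year = st$ebyear[seq_len(E)])
  stations <- st$station_dpq_ents
  if (length(stations)) names(stations) <- as.character(seq_along(stations))
  bee_pedigree(rec, stations, n_drones = st$cfg$n_drones)
}

#' Export the full (truth) pedigree of a population state
#'
#' Queens plus the father drones actually used, as a [full_pedigree()];
#' intended for small runs (exact kinship validation).
#'
#' @param state A `bee_population`.
#' @return List with `ped` (the [full_pedigree()]) and `queen_id` mapping
#'   each simulated queen index to its pedigree id.
#' @export
as_full_pedigree <- function(state) {
  st <- state
  nq <- st$nq
  id <- integer(0); kind <- character(0); dam <- integer(0)
  sire <- integer(0); by <- integer(0)
  queen_id <- integer(nq)
  drone_id <- new.env(parent = emptyenv())
  add <- function(k, d, s, y) {
    id <<- c(id, length(id) + 1L); kind <<- c(kind, k)
    dam <<- c(dam, d); sire <<- c(sire, s); by <<- c(by, y)
    length(id)
  }
  for (i in seq_len(nq)) {
    s <- 0L
    if (st$dam[i] > 0L) {
      key <- paste0(st$dam[i], "_", st$fslot[i])
      s <- drone_id[[key]]
      if (is.null(s)) {
        ddam <- st$fdam[i]
        s <- add("drone", if (ddam > 0L) queen_id[ddam] else 0L,
                 0L, st$byear[st$dam[i]])
        drone_id[[key]] <- s
      }
    }
    queen_id[i] <- add("queen", if (st$dam[i] > 0L) queen_id[st$dam[i]]
                       else 0L, s, st$byear[i])
  }
  list(ped = full_pedigree(id, kind, dam, sire, by), queen_id = queen_id)
}
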