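# Stochastic digestion: continuous-time Markov (Gillespie) simulation of a
# chain pool under endolytic and exolytic activities. Each cleavable bond of
# each chain carries propensity u_endo * k(a, b); each chain NRE carries
# propensity u_exo * r(dp). Activities are in mU and are mapped to
# propensity scale by one calibration constant (`activity_scale`, per mU per
# minute per relative-rate unit), frozen at 0.002.

.default_activity_scale <- 0.002

# Per-sequence event bookkeeping, memoized across the trajectory.
species_info <- function(seq, endo, exo, cache) {
  if (!is.null(cache[[seq]])) return(cache[[seq]])
  ch <- parse_sequence(seq)
  n_let <- length(ch$residues)
  n_rings <- dp(ch)
  info <- list(dp = n_rings)

  bonds <- integer(0L); rates <- numeric(0L); up <- character(0L); down <- character(0L)
  if (!is.null(endo) && n_let >= 2L) {
    for (i in seq_len(n_let - 1L)) {
      up_dp <- i + as.integer(ch$unsaturated)
      down_dp <- n_let - i
      if (up_dp < endo$min_nre_frag || down_dp < endo$min_re_frag) next
      kk <- endo_k(endo, ch$residues[i], ch$residues[i + 1L])
      if (kk <= 0) next
      pr <- endo_cleave(ch, i)
      bonds <- c(bonds, i); rates <- c(rates, kk)
      up <- c(up, format(pr$upstream))
      down <- c(down, if (is_monomer(pr$downstream)) paste0("monomer:", pr$downstream$species)
                      else format(pr$downstream))
    }
  }
  info$endo_rates <- rates
  info$endo_up <- up
  info$endo_down <- down
  info$endo_total <- sum(rates)

  info$exo_ok <- !is.null(exo) && n_rings >= 2L && !(ch$label_2ab && n_rings <= 2L)
  if (info$exo_ok) {
    info$exo_r <- exo_rate(exo, n_rings)
    st <- exo_step(ch)
    info$exo_released <- st$released$species
    info$exo_remainder <- if (is_monomer(st$remainder))
      paste0("monomer:", st$remainder$species) else format(st$remainder)
    if (info$exo_r <= 0) info$exo_ok <- FALSE
  } else {
    info$exo_r <- 0
  }
  cache[[seq]] <- info
  info
}

normalize_pool <- function(pool) {
  if (is.data.frame(pool)) {
    counts <- pool$count
    names(counts) <- pool$sequence
  } else if (is.numeric(pool) && !is.null(names(pool))) {
    counts <- pool
  } else if (is.character(pool)) {
    counts <- table(pool)
    counts <- stats::setNames(as.numeric(counts), names(counts))
  } else {
    stop("pool must be a named count vector, a data.frame(sequence, count), or a character vector of sequences",
         call. = FALSE)
  }
  canon <- vapply(names(counts), function(s) format(parse_sequence(s)), character(1L))
  agg <- tapply(as.numeric(counts), canon, sum)
  stats::setNames(as.numeric(agg), names(agg))
}

#' Simulate endo/exolytic digestion of a chain pool
#'
#' Continuous-time Markov (Gillespie) trajectory of a pool of chains under
#' an endolytic rate table and/or an exolytic size profile. Released
#' unsaturated monomers are tracked as a single `UDP1` pool (their
#' spontaneous conversion to DEH/TPC is a relabelling, see
#' [monomer_speciation()]); saturated monomers are tracked as `M` and `G`.
#' Total ring count is conserved along the whole trajectory.
#'
#' @param pool initial chains: a named count vector
#'   (`c("ΔGGMM" = 10, ...)`), a `data.frame(sequence, count)`, or a
#'   character vector of sequences (counted with multiplicity).
#' @param endo an [endo_rate_table()] or `NULL`.
#' @param exo an [exo_rate_profile()] or `NULL`.
#' @param endo_mU,exo_mU enzyme activities (mU).
#' @param t_end end time in minutes; `Inf` runs to absorption.
#' @param seed integer RNG seed; fixing it fixes the trajectory exactly.
#' @param activity_scale propensity per mU per minute per relative-rate
#'   unit; single calibration constant.
#' @param record_times optional numeric vector of snapshot times; the
#'   initial and final states are always recorded.
#' @param max_events hard cap on the number of reaction events.
#' @return Object of class `digest_trajectory`: list with `times` (snapshot
#'   times), `states` (list of `list(chains, monomers)` count vectors),
#'   `n_events`, `seed` and the configuration.
#' @export
simulate_digest <- function(pool, endo = NULL, exo = NULL,
                            endo_mU = 0, exo_mU = 0,
                            t_end = 60, seed = 1L,
                            activity_scale = .default_activity_scale,
                            record_times = NULL, max_events = 1e6) {
  stopifnot(endo_mU >= 0, exo_mU >= 0, t_end >= 0)
  chains <- normalize_pool(pool)
  if (!length(chains) || sum(chains) <= 0) stop("pool is empty", call. = FALSE)
  monomers <- c(UDP1 = 0, M = 0, G = 0)
  u1 <- endo_mU * activity_scale
  u2 <- exo_mU * activity_scale
  cache <- new.env(parent = emptyenv())
  set.seed(as.integer(seed))

  t <- 0
  n_events <- 0L
  record_times <- sort(unique(record_times))
  snaps_t <- 0
  snaps <- list(list(chains = chains, monomers = monomers))
  next_rec <- 1L

  record_up_to <- function(time) {
    while (next_rec <= length(record_times) && record_times[next_rec] <= time) {
      snaps_t <<- c(snaps_t, record_times[next_rec])
      snaps[[length(snaps) + 1L]] <<- list(chains = chains, monomers = monomers)
      next_rec <<- next_rec + 1L
    }
  }

  add_species <- function(name, k = 1) {
    if (startsWith(name, "monomer:")) {
      sp <- sub("^monomer:", "", name)
      key <- if (sp %in% c("UDP1", "DEH", "TPC")) "UDP1" else sp
      monomers[key] <<- monomers[key] + k
    } else {
      chains[name] <<- (if (is.na(chains[name])) 0 else chains[name]) + k
    }
  }

  repeat {
    live <- names(chains)[chains > 0]
    infos <- lapply(live, species_info, endo = endo, exo = exo, cache = cache)
    per <- vapply(seq_along(live), function(j) {
      inf <- infos[[j]]
      chains[live[j]] * (u1 * inf$endo_total + if (inf$exo_ok) u2 * inf$exo_r else 0)
    }, numeric(1L))
    A <- sum(per)
    if (A <= 0) {
      if (n_events == 0L && t_end > 0)
        warning("all propensities are zero; returning the initial state", call. = FALSE)
      break
    }
    dt <- stats::rexp(1L, A)
    if (t + dt > t_end) { t <- t_end; break }
    t <- t + dt
    record_up_to(t)
    j <- sample.int(length(live), 1L, prob = per)
    seqj <- live[j]; inf <- infos[[j]]
    endo_w <- u1 * inf$endo_rates
    exo_w <- if (inf$exo_ok) u2 * inf$exo_r else 0
    pick <- sample.int(length(endo_w) + 1L, 1L, prob = c(endo_w, exo_w))
    chains[seqj] <- chains[seqj] - 1
    if (pick <= length(endo_w)) {
      add_species(inf$endo_up[pick])
      add_species(inf$endo_down[pick])
    } else {
      add_species(paste0("monomer:", inf$exo_released))
      add_species(inf$exo_remainder)
    }
    n_events <- n_events + 1L
    if (n_events >= max_events) {
      warning("max_events reached before t_end", call. = FALSE)
      break
    }
  }
  record_up_to(t_end)
  snaps_t <- c(snaps_t, min(t_end, t))
  snaps[[length(snaps) + 1L]] <- list(chains = chains, monomers = monomers)

  structure(list(times = snaps_t, states = snaps, n_events = n_events,
                 seed = as.integer(seed),
                 config = list(endo = endo, exo = exo, endo_mU = endo_mU,
                               exo_mU = exo_mU, t_end = t_end,
                               activity_scale = activity_scale)),
            class = "digest_trajectory")
}

#' @export
print.digest_trajectory <- function(x, ...) {
  fin <- x$states[[length(x$states)]]
  cat(sprintf("<digest_trajectory> %d events to t = %.3g min; %d chain species, monomers UDP1=%g M=%g G=%g\n",
              x$n_events, x$times[length(x$times)],
              sum(fin$chains > 0), fin$monomers["UDP1"],
              fin$monomers["M"], fin$monomers["G"]))
  invisible(x)
}

#' Final state of a trajectory
#' @param traj a `digest_trajectory`.
#' @return list with `chains` (named counts) and `monomers`.
#' @export
final_state <- function(traj) traj$states[[length(traj$states)]]

#' Total ring count of a digest state
#'
#' Conserved quantity: every chain contributes its DP and every monomer one
#' ring.
#' @param state a `list(chains, monomers)` as stored in a trajectory.
#' @return numeric ring count.
#' @export
residue_count <- function(state) {
  ch <- state$chains[state$chains > 0]
  rings <- if (length(ch)) sum(ch * dp(names(ch))) else 0
  rings + sum(state$monomers)
}

#' Expected UDP1 / DEH / TPC split of the unsaturated monomer pool
#'
#' The unsaturated monomer converts spontaneously (non-enzymatically) to
#' DEH and then to its cyclized hydrate TPC; the package treats this as an
#' instantaneous relabelling of the pool with configurable expected
#' fractions rather than modelling kinetics.
#'
#' @param udp1_count size of the released unsaturated monomer pool.
#' @param fractions expected split, named `UDP1`, `DEH`, `TPC`, summing to 1.
#' @return Named numeric vector of expected counts.
#' @export
monomer_speciation <- function(udp1_count,
                               fractions = c(UDP1 = 0.05, DEH = 0.35, TPC = 0.60)) {
  stopifnot(all(c("UDP1", "DEH", "TPC") %in% names(fractions)),
            abs(sum(fractions) - 1) < 1e-9, all(fractions >= 0))
  udp1_count * fractions[c("UDP1", "DEH", "TPC")]
}

#' Write a trajectory as long-format TSV
#'
#' Columns `time`, `species`, `count`; chain species in canonical notation,
#' the unsaturated monomer pool split into UDP1/DEH/TPC expected counts via
#' [monomer_speciation()], saturated monomers as `M`/`G`. The header embeds
#' package version, seed and config hash.
#'
#' @param traj a `digest_trajectory`.
#' @param path output path.
#' @param speciation_fractions passed to [monomer_speciation()].
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(traj, path,
                                 speciation_fractions = c(UDP1 = 0.05, DEH = 0.35, TPC = 0.60)) {
  rows <- lapply(seq_along(traj$times), function(i) {
    st <- traj$states[[i]]
    ch <- st$chains[st$chains > 0]
    mono <- c(monomer_speciation(st$monomers[["UDP1"]], speciation_fractions),
              M = st$monomers[["M"]], G = st$monomers[["G"]])
    mono <- mono[mono > 0]
    data.frame(time = traj$times[i],
               species = c(names(ch), names(mono)),
               count = c(unname(ch), unname(mono)),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  write_tsv_with_header(df, path, seed = traj$seed, config = traj$config)
}

#' Exhaustive endolytic digestion: product size classes and compositions
#'
#' Runs [simulate_digest()] with endolytic activity to absorption and
#' summarizes the molar proportion of each product size class (UDP1..UDPn)
#' and the sequence composition within each class, averaged over replicates
#' with a Monte-Carlo standard error.
#'
#' @param pool initial chains (see [simulate_digest()]).
#' @param endo an [endo_rate_table()].
#' @param endo_mU activity (mU).
#' @param seed integer seed; replicate `i` uses `seed + i - 1`.
#' @param replicates number of independent trajectories (>= 1).
#' @return list with `size_summary` (data.frame `dp`, `proportion`, `se`)
#'   and `composition` (named list: per DP, a data.frame of sequences and
#'   mean molar fractions within the class).
#' @export
final_products <- function(pool, endo, endo_mU = 100, seed = 1L, replicates = 1L) {
  stopifnot(replicates >= 1L)
  if (all(endo$k == 0)) stop("non-absorbing rate table: all k are zero", call. = FALSE)
  per_rep_prop <- list(); per_rep_comp <- list()
  for (r in seq_len(replicates)) {
    traj <- simulate_digest(pool, endo = endo, endo_mU = endo_mU,
                            t_end = Inf, seed = as.integer(seed) + r - 1L)
    st <- final_state(traj)
    ch <- st$chains[st$chains > 0]
    species <- c(names(ch), if (st$monomers[["UDP1"]] > 0) "UDP1",
                 if (st$monomers[["M"]] > 0) "M", if (st$monomers[["G"]] > 0) "G")
    counts <- c(unname(ch), st$monomers[st$monomers > 0])
    dps <- ifelse(species %in% c("UDP1", "M", "G"), 1L, NA)
    dps[is.na(dps)] <- dp(species[is.na(dps)])
    tot <- sum(counts)
    per_rep_prop[[r]] <- tapply(counts / tot, dps, sum)
    per_rep_comp[[r]] <- data.frame(sequence = species, dp = dps,
                                    count = counts, stringsAsFactors = FALSE)
  }
  all_dp <- sort(unique(as.integer(unlist(lapply(per_rep_prop, names)))))
  prop_mat <- vapply(per_rep_prop, function(p) {
    v <- stats::setNames(numeric(length(all_dp)), all_dp)
    v[names(p)] <- p
    v
  }, numeric(length(all_dp)))
  prop_mat <- matrix(prop_mat, nrow = length(all_dp))
  size_summary <- data.frame(
    dp = all_dp,
    proportion = rowMeans(prop_mat),
    se = apply(prop_mat, 1L, stats::sd) / sqrt(replicates))
  comp_all <- do.call(rbind, per_rep_comp)
  composition <- lapply(stats::setNames(all_dp, paste0("UDP", all_dp)), function(n) {
    sub <- comp_all[comp_all$dp == n, , drop = FALSE]
    agg <- tapply(sub$count, sub$sequence, sum)
    data.frame(sequence = names(agg),
               fraction = as.numeric(agg) / sum(agg),
               stringsAsFactors = FALSE)
  })
  list(size_summary = size_summary, composition = composition)
}
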