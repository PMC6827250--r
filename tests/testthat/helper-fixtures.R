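# Shared fixtures (built in code) and an independent brute-force oracle for
# the stochastic digestion model.

# Final size-class compositions of the endolytic digest, as published for
# the four sequenced fractions.
table2_udp5 <- function() {
  oligo_mixture(c("ΔGGMM", "ΔMGMM", "ΔGMMM", "ΔMMMM"),
                c(0.467, 0.133, 0.311, 0.089))
}
table2_udp4 <- function() {
  oligo_mixture(c("ΔMMM", "ΔGMM"), c(0.76, 0.24))
}

delta <- "Δ"

random_sequence <- function(max_len = 8L) {
  n <- sample.int(max_len, 1L)
  paste0(if (stats::runif(1) < 0.5) delta else "",
         paste(sample(c("M", "G"), n, replace = TRUE), collapse = ""),
         if (stats::runif(1) < 0.2) "-2AB" else "")
}

# ---- independent digestion oracle -----------------------------------------
# String-level reimplementation of the cleavage rules plus exact enumeration
# of the absorbing-state distribution of the digestion Markov chain. Kept
# deliberately separate from the package implementation.

oracle_dp <- function(s) nchar(gsub("Δ", "", s)) + grepl("^Δ", s)

oracle_endo_events <- function(s, k, min_nre = 2L, min_re = 2L) {
  unsat <- grepl("^Δ", s)
  letters <- strsplit(sub("^Δ", "", s), "")[[1L]]
  n <- length(letters)
  ev <- list()
  if (n >= 2L) for (i in seq_len(n - 1L)) {
    up_dp <- i + as.integer(unsat)
    down_dp <- n - i
    if (up_dp < min_nre || down_dp < min_re) next
    rate <- k[[paste0(letters[i], letters[i + 1L])]]
    if (rate <= 0) next
    up <- paste0(if (unsat) delta else "", paste(letters[1:i], collapse = ""))
    down <- paste0(delta, paste(letters[(i + 2L):n], collapse = ""))
    ev[[length(ev) + 1L]] <- list(rate = rate, products = c(up, down))
  }
  ev
}

oracle_exo_event <- function(s, r_of_dp) {
  n_rings <- oracle_dp(s)
  if (n_rings < 2L) return(NULL)
  unsat <- grepl("^Δ", s)
  letters <- strsplit(sub("^Δ", "", s), "")[[1L]]
  released <- if (unsat) "UDP1" else letters[1L]
  rest <- if (unsat) letters else letters[-1L]
  remainder <- if (length(rest) == 1L) rest[1L]
               else paste0(delta, paste(rest[-1L], collapse = ""))
  list(rate = r_of_dp(n_rings),
       products = c(paste0("mono:", released),
                    if (nchar(gsub("Δ", "", remainder)) == 1L && !grepl(delta, remainder))
                      paste0("mono:", remainder) else remainder))
}

state_key <- function(species) paste(sort(species), collapse = "+")

# Exact absorbing-state distribution: recursion over every event order with
# propensity-proportional branching. `species` is a character multiset;
# monomers are "mono:UDP1" / "mono:M" / "mono:G".
oracle_final_distribution <- function(species, k = NULL, r_of_dp = NULL,
                                      u1 = 1, u2 = 1) {
  acc <- new.env(parent = emptyenv())
  recurse <- function(species, prob) {
    events <- list()
    for (idx in seq_along(species)) {
      s <- species[idx]
      if (startsWith(s, "mono:")) next
      if (!is.null(k)) for (e in oracle_endo_events(s, k)) {
        events[[length(events) + 1L]] <-
          list(rate = u1 * e$rate, next_species = c(species[-idx], e$products))
      }
      if (!is.null(r_of_dp)) {
        e <- oracle_exo_event(s, r_of_dp)
        if (!is.null(e) && e$rate > 0)
          events[[length(events) + 1L]] <-
            list(rate = u2 * e$rate, next_species = c(species[-idx], e$products))
      }
    }
    if (!length(events)) {
      key <- state_key(species)
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + prob
      return(invisible())
    }
    total <- sum(vapply(events, `[[`, numeric(1L), "rate"))
    for (e in events) recurse(e$next_species, prob * e$rate / total)
  }
  recurse(species, 1)
  as.list(acc)
}

# Canonical state key of a simulator final state, matching the oracle's.
sim_state_key <- function(state) {
  ch <- state$chains[state$chains > 0]
  mono <- state$monomers[state$monomers > 0]
  mono_names <- if (length(mono)) paste0("mono:", names(mono)) else character(0)
  species <- c(rep(names(ch), times = as.integer(unname(ch))),
               rep(mono_names, times = as.integer(unname(mono))))
  state_key(species)
}

default_k <- c(GG = 1.0, GM = 0.1, MG = 0.25, MM = 0.01)
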