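# Shared fixtures and independent oracles.

# Exhaustive path-enumeration oracle for cohort occupancy: sums the
# probability of every full state sequence (feasible only for short
# horizons). Independent of the engine's matrix recursion.
oracle_occupancy <- function(mats) {
  H <- length(mats)
  n <- nrow(mats[[1]])
  occ <- matrix(0, H + 1L, n)
  occ[1L, 1L] <- 1
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), H)))
  for (i in seq_len(nrow(seqs))) {
    path <- c(1L, seqs[i, ])
    p <- 1
    for (t in seq_len(H)) p <- p * mats[[t]][path[t], path[t + 1L]]
    if (p > 0) {
      for (t in seq_len(H)) {
        occ[t + 1L, path[t + 1L]] <- occ[t + 1L, path[t + 1L]] + p
      }
    }
  }
  occ
}

# Base case with a short horizon (keeps toy/oracle tests fast).
short_horizon_params <- function(params, horizon) {
  param_set(params, "economics.horizon", as.integer(horizon))
}

# A scenario in which RZV has the higher NMB than ZVL at the base ZVL price
# (cheap recombinant vaccine), so the price-threshold precondition holds.
threshold_scenario <- function(params = default_parameters()) {
  param_set(params, "costs.price_rzv_dose", 60)
}

# A constant-efficacy curve (no waning) at a given level.
flat_curve <- function(ve, t_end = 10) {
  fit_linear_waning(cbind(c(0, t_end), c(ve, ve)))
}
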