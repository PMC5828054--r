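# Shared fixtures; sphere meshes are memoized inside the package so these
# are cheap after first use.

fix_mesh <- function(n = 724) even_sphere(n)

fix_phantoms <- function() fiber_phantoms()

fix_truth <- function(ph) {
  do.call(rbind, lapply(ph$compartments, `[[`, "principal"))
}

# fast settings for unit tests that only exercise plumbing, not accuracy
fix_quick_params <- function(seed = 1) {
  hybrid_params(n_particles = 40, t_max = 60, m_rounds = 8, seed = seed)
}

# independent exhaustive matcher used as oracle for match_peaks: recursive
# enumeration of all injections, no shared code with the implementation
oracle_match <- function(found, truth) {
  k <- nrow(found)
  m <- nrow(truth)
  cost <- matrix(0, k, m)
  for (i in seq_len(k)) {
    for (j in seq_len(m)) cost[i, j] <- arc_angle(found[i, ], truth[j, ])
  }
  best <- Inf
  recurse <- function(i, used, acc) {
    if (acc >= best) return()
    if (i > min(k, m)) {
      best <<- acc
      return()
    }
    for (j in seq_len(m)) {
      if (!used[j]) {
        used[j] <- TRUE
        recurse(i + 1L, used, acc + cost[i, j])
        used[j] <- FALSE
      }
    }
  }
  if (k <= m) {
    recurse(1L, logical(m), 0)
  } else {
    # swap roles
    return(oracle_match(truth, found))
  }
  best
}
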