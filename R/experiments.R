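# Replica and parameter-scan drivers.  Every run inside a scan receives a
# seed derived deterministically from the scan seed and the cell/replica
# indices, so scans are reproducible cell by cell and embarrassingly
# parallel in principle (cells are independent given their seeds).

#' Derive a child RNG seed from a base seed and integer indices
#'
#' Simple LCG-style folding kept below 2^31 so results are valid R seeds.
#'
#' @param base Integer base seed.
#' @param ... Integer indices (cell, replica, ...).
#' @return A single integer seed.
#' @export
derive_seed <- function(base, ...) {
  x <- as.double(base) %% 2147483647
  for (k in c(...)) {
    x <- (x * 69069 + as.double(k) + 1) %% 2147483647
  }
  as.integer(x)
}

# Copy a compiled table with a new coupling (entries are reused).
with_epsilon <- function(rt, epsilon) {
  rt$epsilon <- epsilon
  attr(rt, "lookup_cache") <- NULL
  rt
}
with_lambda <- function(nt, lam) {
  nt$lam <- lam
  attr(nt, "lookup_cache") <- NULL
  nt
}

#' Scan the (epsilon, mu, lambda) parameter space
#'
#' Runs every grid cell with `replicas` independent realizations, starting
#' from the complete first structure as the initial seed (unless
#' `seed_side` is given), and records per replica the final assembly error,
#' density, energy, number of detected shifts and regime label.
#'
#' @param patterns A `target_patterns`.
#' @param eps_values,mu_values,lam_values Grid axes.
#' @param replicas Realizations per cell.
#' @param sweeps Run duration in sweeps.
#' @param seed_side Initial seed block side (default: full structure).
#' @param sample_every Observable cadence in sweeps.
#' @param rng_seed Scan seed; per-run seeds are derived from it.
#' @return A list of class `scan_result`: `cells` (one row per cell and
#'   replica) and `summary` (per-cell means, majority label and shift
#'   fraction).
#' @export
phase_scan <- function(patterns, eps_values, mu_values, lam_values,
                       replicas = 5L, sweeps = 2e5, seed_side = NULL,
                       sample_every = 200L, rng_seed = 1L) {
  stopifnot(replicas >= 1L)
  rt0 <- build_reciprocal_table(patterns, 1)
  nt0 <- build_nonreciprocal_table(patterns, 1)
  grid <- expand.grid(epsilon = eps_values, mu = mu_values,
                      lam = lam_values, KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(grid) * replicas)
  k <- 0L
  for (g in seq_len(nrow(grid))) {
    rt <- with_epsilon(rt0, grid$epsilon[g])
    nt <- with_lambda(nt0, grid$lam[g])
    for (r in seq_len(replicas)) {
      pars <- sim_params(
        epsilon = grid$epsilon[g], mu = grid$mu[g], lam = grid$lam[g],
        sweeps = sweeps, seed_side = seed_side,
        sample_every = sample_every,
        rng_seed = derive_seed(rng_seed, g, r)
      )
      res <- tryCatch({
        state <- init_state(patterns, pars)
        run <- run_simulation(state, rt, nt, pars, patterns)
        cls <- classify_run(run, patterns, rt)
        data.frame(
          epsilon = grid$epsilon[g], mu = grid$mu[g], lam = grid$lam[g],
          replicate = r, error = cls$measurements$error,
          density = cls$measurements$density,
          energy = cls$measurements$energy,
          n_shifts = cls$shifts$n_shifts, shifted = cls$shifted,
          label = cls$label, failed = FALSE
        )
      }, error = function(e) {
        data.frame(epsilon = grid$epsilon[g], mu = grid$mu[g],
                   lam = grid$lam[g], replicate = r, error = NA_real_,
                   density = NA_real_, energy = NA_real_,
                   n_shifts = NA_integer_, shifted = NA,
                   label = NA_character_, failed = TRUE)
      })
      k <- k + 1L
      rows[[k]] <- res
    }
  }
  cells <- do.call(rbind, rows)
  summary <- stats::aggregate(
    cbind(error, density, energy, n_shifts) ~ epsilon + mu + lam,
    data = cells, FUN = mean, na.action = stats::na.pass
  )
  lab <- stats::aggregate(
    label ~ epsilon + mu + lam, data = cells,
    FUN = function(x) names(sort(table(x), decreasing = TRUE))[1],
    na.action = stats::na.pass
  )
  shifted <- stats::aggregate(
    shifted ~ epsilon + mu + lam, data = cells,
    FUN = function(x) mean(x), na.action = stats::na.pass
  )
  names(shifted)[4] <- "shift_fraction"
  summary <- merge(merge(summary, lab), shifted)
  structure(list(cells = cells, summary = summary, replicas = replicas),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> %d cells x %d replicas\n",
              nrow(x$summary), x$replicas))
  print(utils::head(x$summary, 10))
  invisible(x)
}

#' Locate a boundary along a scanned axis
#'
#' Returns the midpoint between the last grid value for which `stable` is
#' `TRUE` and the first following value for which it is `FALSE` (values are
#' sorted first).  `NA` if the scan never crosses.
#'
#' @param values Scanned axis values.
#' @param stable Logical, same length.
#' @return The midpoint, or `NA`.
#' @export
boundary_midpoint <- function(values, stable) {
  o <- order(values)
  values <- values[o]; stable <- stable[o]
  last_ok <- if (any(stable)) max(which(stable)) else 0L
  if (last_ok == 0L || last_ok == length(values)) return(NA_real_)
  (values[last_ok] + values[last_ok + 1L]) / 2
}

#' Terminal-structure frequency over independent realizations
#'
#' Runs `n_realizations` independent realizations of the shifting protocol
#' for a fixed duration and assigns each terminal configuration to the
#' sequence structure against which its error is at most 0.1 (taking the
#' best-matching structure), or to the erroneous band otherwise.
#'
#' @param patterns A `target_patterns`.
#' @param params A `sim_params` template; per-realization seeds are derived
#'   from `params$rng_seed`.
#' @param n_realizations Number of realizations.
#' @param error_band Error threshold for a valid terminal structure.
#' @return A list with `fraction` (named vector over the sequence structures
#'   and `"erroneous"`, summing to 1) and `outcomes` (per-realization label).
#' @export
shift_frequency <- function(patterns, params, n_realizations = 10L,
                            error_band = 0.1) {
  stopifnot(n_realizations >= 1L)
  rt <- build_reciprocal_table(patterns, params$epsilon)
  nt <- build_nonreciprocal_table(patterns, params$lam)
  seqn <- patterns$sequence
  outcomes <- character(n_realizations)
  for (r in seq_len(n_realizations)) {
    pars <- params
    pars$rng_seed <- derive_seed(params$rng_seed, r)
    state <- init_state(patterns, pars)
    run <- run_simulation(state, rt, nt, pars, patterns)
    ov <- vapply(seqn, function(l) {
      overlap(run$final_state, patterns$patterns[[l]], rt)
    }, numeric(1))
    best <- which.max(ov)
    outcomes[r] <- if (1 - ov[best] <= error_band) {
      paste0("S", seqn[best])
    } else {
      "erroneous"
    }
  }
  lv <- c(paste0("S", seqn), "erroneous")
  frac <- table(factor(outcomes, levels = lv)) / n_realizations
  list(fraction = c(frac), outcomes = outcomes)
}

#' Classify the transitions of replica runs as correct, premature or waiting
#'
#' For every transition `l -> l+1` of the sequence and every replica:
#' * `premature` if the overlap with structure `l+1` rose persistently (two
#'   consecutive samples above `onset`) while the running maximum of the
#'   overlap with structure `l` was still below `threshold`;
#' * otherwise `correct` if structure `l+1` reached `threshold` (the shift
#'   completed after the current structure had assembled);
#' * otherwise `waiting` (the run ended before the transition).
#'
#' @param patterns A `target_patterns` with a sequence of length >= 2.
#' @param params A `sim_params` template.
#' @param replicas Number of replica runs.
#' @param threshold Completion threshold (default 0.95).
#' @param onset Premature-onset threshold on the next structure's overlap.
#' @return A list with `counts` (named: correct, premature, waiting; their
#'   sum is `(sequence length - 1) * replicas`) and `per_transition`
#'   (data.frame of per-replica classifications).
#' @export
shift_yield <- function(patterns, params, replicas = 5L, threshold = 0.95,
                        onset = 0.2) {
  seqn <- patterns$sequence
  stopifnot(length(seqn) >= 2L)
  rt <- build_reciprocal_table(patterns, params$epsilon)
  nt <- build_nonreciprocal_table(patterns, params$lam)
  rows <- list()
  for (r in seq_len(replicas)) {
    pars <- params
    pars$rng_seed <- derive_seed(params$rng_seed, r)
    state <- init_state(patterns, pars)
    run <- run_simulation(state, rt, nt, pars, patterns)
    ser <- run$series
    for (step in seq_len(length(seqn) - 1L)) {
      o_cur <- ser[[paste0("overlap_", seqn[step])]]
      o_nxt <- ser[[paste0("overlap_", seqn[step + 1L])]]
      cur_done <- cummax(o_cur) >= threshold
      rising <- o_nxt > onset & c(o_nxt[-1] > onset, FALSE)
      cls <- if (any(rising & !cur_done)) {
        "premature"
      } else if (any(o_nxt >= threshold)) {
        "correct"
      } else {
        "waiting"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, from = seqn[step], to = seqn[step + 1L],
        class = cls)
    }
  }
  per <- do.call(rbind, rows)
  counts <- table(factor(per$class,
                         levels = c("correct", "premature", "waiting")))
  list(counts = c(counts), per_transition = per)
}

#' Scaling of retrieval and shift timescales with pattern size
#'
#' For each pattern side length, measures `tau_retrieval` with the retrieval
#' protocol (a quarter-area seed, `side/2 x side/2`, equilibrium dynamics)
#' and `tau_shift` with the shifting protocol (complete first structure as
#' seed, non-reciprocal drive on), averaging over replicas.  Defaults follow
#' the shifting parameter conventions `epsilon = 11.5`, `mu = -20` with
#' `lam = 0` for retrieval and `lam = 8` for shifts.
#'
#' @param sides Pattern side lengths (each defines `M = side^2`).
#' @param replicas Replicas per size.
#' @param sweeps Run duration per realization.
#' @param m Number of stored structures (sequence uses all of them).
#' @param epsilon,mu,lam_shift Simulation parameters.
#' @param sample_every Observable cadence.
#' @param rng_seed Base seed.
#' @return A data.frame with one row per side: mean/sd of both timescales
#'   and the number of replicas in which each was observed.
#' @export
timescale_scaling <- function(sides, replicas = 5L, sweeps = 2e5, m = 4L,
                              epsilon = 11.5, mu = -20, lam_shift = 8,
                              sample_every = 100L, rng_seed = 1L) {
  rows <- lapply(seq_along(sides), function(si) {
    side <- sides[si]
    tp <- generate_patterns(m, side^2,
                            rng_seed = derive_seed(rng_seed, si))
    rt <- build_reciprocal_table(tp, epsilon)
    nt0 <- build_nonreciprocal_table(tp, 0)
    nt <- build_nonreciprocal_table(tp, lam_shift)
    taus_r <- taus_s <- numeric(0)
    for (r in seq_len(replicas)) {
      pr <- sim_params(epsilon, mu, 0, sweeps, seed_side = side %/% 2L,
                       sample_every = sample_every,
                       rng_seed = derive_seed(rng_seed, si, r, 1L))
      run_r <- run_simulation(init_state(tp, pr), rt, nt0, pr, tp)
      dr <- detect_shifts(run_r)
      if (!is.na(dr$tau_retrieval)) taus_r <- c(taus_r, dr$tau_retrieval)
      ps <- sim_params(epsilon, mu, lam_shift, sweeps, seed_side = side,
                       sample_every = sample_every,
                       rng_seed = derive_seed(rng_seed, si, r, 2L))
      run_s <- run_simulation(init_state(tp, ps), rt, nt, ps, tp)
      ds <- detect_shifts(run_s)
      if (ds$n_shifts >= 1L) taus_s <- c(taus_s, ds$shifts$tau_shift)
    }
    data.frame(
      side = side,
      tau_retrieval_mean = if (length(taus_r)) mean(taus_r) else NA_real_,
      tau_retrieval_sd = if (length(taus_r) > 1) stats::sd(taus_r)
                         else NA_real_,
      n_retrieved = length(taus_r),
      tau_shift_mean = if (length(taus_s)) mean(taus_s) else NA_real_,
      tau_shift_sd = if (length(taus_s) > 1) stats::sd(taus_s)
                     else NA_real_,
      n_shifts_observed = length(taus_s)
    )
  })
  do.call(rbind, rows)
}
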