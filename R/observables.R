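#' Largest specifically connected cluster
#'
#' Finds the largest connected component among occupied sites, where two
#' 4-adjacent occupied sites are connected only if their oriented species
#' pair is a stored specific bond.  Mere occupancy adjacency does not
#' connect: this is what separates a liquid (many tiles, few specific bonds)
#' from a chimera (one large specifically bonded composite).  Ties are broken
#' in favour of the component containing the smallest site in row-major
#' order.
#'
#' @param state A `lattice_state`.
#' @param rt A `recip_table`.
#' @return Integer matrix with columns `i`, `j` (1-based lattice coordinates
#'   of cluster sites); zero rows for an empty lattice.
#' @export
largest_specific_cluster <- function(state, rt) {
  comp <- specific_components(state, rt)
  if (is.null(comp)) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  }
  sizes <- tabulate(comp$membership)
  best_size <- max(sizes)
  cand <- which(sizes == best_size)
  if (length(cand) > 1L) {
    # row-major rank of each component's smallest site
    rm_rank <- (comp$sites[, 1] - 1L) * state$L + comp$sites[, 2]
    first <- vapply(cand, function(k) min(rm_rank[comp$membership == k]),
                    numeric(1))
    cand <- cand[which.min(first)]
  }
  sel <- comp$membership == cand[1]
  comp$sites[sel, , drop = FALSE]
}

# Occupied-site graph under specific-bond adjacency, via igraph.
specific_components <- function(state, rt) {
  occ <- which(state$sigma != 0L, arr.ind = TRUE)
  if (nrow(occ) == 0L) return(NULL)
  L <- state$L
  sig <- state$sigma
  lk <- recip_lookup(rt)
  id <- matrix(0L, L, L)
  id[occ] <- seq_len(nrow(occ))
  edges <- list()
  # horizontal bonds a -> right neighbour (periodic)
  right <- cbind(occ[, 1], ifelse(occ[, 2] == L, 1L, occ[, 2] + 1L))
  s <- sig[occ]; sr <- sig[right]
  okh <- sr != 0L & lk$H[cbind(s + 1L, sr + 1L)]
  edges[[1]] <- cbind(id[occ][okh], id[right][okh])
  down <- cbind(ifelse(occ[, 1] == L, 1L, occ[, 1] + 1L), occ[, 2])
  sd <- sig[down]
  okv <- sd != 0L & lk$V[cbind(s + 1L, sd + 1L)]
  edges[[2]] <- cbind(id[occ][okv], id[down][okv])
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(occ) - igraph::vcount(g)))
  comp <- igraph::components(g)
  list(sites = unname(occ), membership = comp$membership)
}

#' Overlap of the largest specific cluster with a stored structure
#'
#' Treats the cluster and the structure, placed on its centred lattice
#' footprint, as sets of (site, species) assignments and returns their
#' Jaccard index `|L intersect S| / |L union S|`.  This penalizes both extra
#' tiles attached to the structure and tiles missing from it, and equals 1
#' exactly when the cluster reproduces the structure.
#'
#' @param state A `lattice_state`.
#' @param pattern A `side x side` integer matrix (one stored structure).
#' @param rt A `recip_table` (defines specific-bond connectivity).
#' @param anchor 1-based lattice coordinates of the footprint's top-left
#'   corner; defaults to the centred placement used throughout.
#' @return Overlap in `[0, 1]`.
#' @export
overlap <- function(state, pattern, rt, anchor = state$anchor) {
  cl <- largest_specific_cluster(state, rt)
  side <- nrow(pattern)
  M <- side * side
  if (nrow(cl) == 0L) return(0)
  ic <- cl[, 1] - anchor[1] + 1L
  jc <- cl[, 2] - anchor[2] + 1L
  inside <- ic >= 1L & ic <= side & jc >= 1L & jc <= side
  inter <- 0L
  if (any(inside)) {
    sp <- state$sigma[cl[inside, , drop = FALSE]]
    inter <- sum(pattern[cbind(ic[inside], jc[inside])] == sp)
  }
  inter / (nrow(cl) + M - inter)
}

#' Assembly error of a configuration
#'
#' Per-structure error is `e_i = 1 - O_i`; the configuration's error is the
#' minimum of `e_i` over the structures of the shifting sequence (a
#' single-structure run reduces to `e_1`).
#'
#' @param state A `lattice_state`.
#' @param patterns A `target_patterns`.
#' @param rt A `recip_table`.
#' @param sequence Structure indices to minimize over (default: the stored
#'   shifting sequence).
#' @return Error in `[0, 1]`.
#' @export
assembly_error <- function(state, patterns, rt,
                           sequence = patterns$sequence) {
  ov <- vapply(sequence,
               function(l) overlap(state, patterns$patterns[[l]], rt),
               numeric(1))
  min(1 - ov)
}

#' Cumulative entropy production from move records
#'
#' `Sigma(t) = sum over accepted moves <= t of log(p_fwd / p_rev)` in units
#' of `k_B`, with `p_rev` the acceptance probability of the exact inverse
#' replacement in the post-move state.  At `lam = 0` the per-move log-ratio
#' telescopes to `-dH`, so the cumulative sum equals
#' `H(initial) - H(final)` and vanishes over closed cycles.
#'
#' @param move_records List of move records from [attempt_move()].
#' @return Numeric vector: cumulative entropy production after each record
#'   (rejected moves contribute 0).
#' @export
entropy_production <- function(move_records) {
  step <- vapply(move_records, function(r) {
    if (isTRUE(r$accepted)) log(r$p_fwd) - log(r$p_rev) else 0
  }, numeric(1))
  cumsum(step)
}

#' Detect structure-to-structure shifts in an overlap time series
#'
#' Retrieval is complete when the overlap with the first sequence structure
#' reaches `threshold`; a shift `i -> i+1` is recorded when the overlap with
#' structure `i+1` reaches `threshold` after structure `i` did.
#' `tau_retrieval` is the first crossing time of the seed structure;
#' `tau_shift` of a transition is the time between the consecutive
#' crossings.  Times are reported at the sampling resolution.
#'
#' @param series An `observable_series` (or its `series` data.frame plus a
#'   `sequence` attribute via the `sequence` argument).
#' @param threshold Overlap threshold (default 0.95).
#' @param sequence Structure indices of the shifting sequence.
#' @return A list: `tau_retrieval` (NA if never retrieved), `shifts`
#'   (data.frame with `from`, `to`, `sweep`, `tau_shift`), `n_shifts`.
#' @export
detect_shifts <- function(series, threshold = 0.95, sequence = NULL) {
  if (inherits(series, "observable_series")) {
    if (is.null(sequence)) sequence <- series$sequence
    series <- series$series
  }
  if (is.null(sequence)) stop("sequence must be given", call. = FALSE)
  sweeps <- series$sweep
  if (is.unsorted(sweeps, strictly = TRUE)) {
    stop("sampling grid must be strictly increasing", call. = FALSE)
  }
  ov <- as.matrix(series[paste0("overlap_", sequence)])
  shifts <- data.frame(from = integer(0), to = integer(0),
                       sweep = numeric(0), tau_shift = numeric(0))
  first_cross <- function(col, from_idx) {
    k <- which(ov[, col] >= threshold & seq_along(sweeps) >= from_idx)
    if (length(k)) k[1] else NA_integer_
  }
  k <- first_cross(1L, 1L)
  tau_retrieval <- if (is.na(k)) NA_real_ else sweeps[k]
  last <- k
  if (!is.na(k) && length(sequence) >= 2L) {
    for (step in seq_len(length(sequence) - 1L)) {
      nxt <- first_cross(step + 1L, last)
      if (is.na(nxt)) break
      shifts <- rbind(shifts, data.frame(
        from = sequence[step], to = sequence[step + 1L],
        sweep = sweeps[nxt], tau_shift = sweeps[nxt] - sweeps[last]))
      last <- nxt
    }
  }
  list(tau_retrieval = tau_retrieval, shifts = shifts,
       n_shifts = nrow(shifts))
}

#' Classify the final configuration into a self-assembly regime
#'
#' Decision tree over measurements of the final configuration:
#' * `error <= 0.05` with at least one detected shift: `shape_shifter`;
#' * `error <= 0.05` without shifts: `multifarious`;
#' * largest-cluster fraction `< 0.1` of `M` and density below the dilute
#'   threshold `0.5 * M / L^2`: `dispersion`;
#' * density at or above that threshold with fewer than 1 specific bond per
#'   occupied site: `liquid`;
#' * a substantial specific cluster otherwise: `chimera`;
#' * anything else (necessarily `error > 0.05`): `erroneous`.
#'
#' @param meas Measurement list from [state_measurements()] (fields `error`,
#'   `density`, `energy`, `cluster_frac`, `bonds_per_site`).
#' @param n_shifts Number of detected shifts for the run.
#' @param M,L Tiles per structure and lattice side (taken from `meas` if
#'   present).
#' @return One of `"multifarious"`, `"shape_shifter"`, `"chimera"`,
#'   `"liquid"`, `"dispersion"`, `"erroneous"`.
#' @export
classify_regime <- function(meas, n_shifts = 0L, M = meas$M, L = meas$L) {
  dilute <- 0.5 * M / L^2
  if (meas$error <= 0.05) {
    return(if (n_shifts >= 1L) "shape_shifter" else "multifarious")
  }
  if (meas$cluster_frac < 0.1 && meas$density < dilute) return("dispersion")
  if (meas$density >= dilute && meas$bonds_per_site < 1) return("liquid")
  if (meas$cluster_frac >= 0.1) return("chimera")
  "erroneous"
}

#' Measure the quantities used for regime classification
#'
#' @param state A `lattice_state`.
#' @param patterns A `target_patterns`.
#' @param rt A `recip_table`.
#' @param mu Chemical potential (for the energy readout).
#' @return A list with `error`, `density`, `energy`, `cluster_frac` (largest
#'   specific cluster size over `M`), `bonds_per_site` (specific bonds per
#'   occupied site, each bond counted once), `M` and `L`.
#' @export
state_measurements <- function(state, patterns, rt, mu) {
  cl <- largest_specific_cluster(state, rt)
  n_occ <- state$n
  bonds <- if (n_occ > 0) {
    e0 <- cpp_total_energy(state$sigma, state$M, table_entries(rt),
                           1.0, 0.0)
    -e0   # with eps = 1 and mu = 0 the energy is minus the bond count
  } else {
    0
  }
  list(
    error = assembly_error(state, patterns, rt),
    density = n_occ / state$L^2,
    energy = total_energy(state, rt, mu),
    cluster_frac = nrow(cl) / state$M,
    bonds_per_site = if (n_occ > 0) bonds / n_occ else 0,
    M = state$M,
    L = state$L
  )
}

#' Classify a finished run
#'
#' Convenience wrapper: measures the final state of an [run_simulation()]
#' result, detects shifts in its overlap series, and applies
#' [classify_regime()].
#'
#' A run counts as having shifted if either the strict overlap-crossing
#' detector fires ([detect_shifts()], threshold 0.95), or the terminal
#' configuration matches (error <= 0.05) a sequence structure *later* than
#' the seed structure.  The second clause matters for small patterns, where
#' transitions often begin before the current structure fully completes and
#' intermediate overlaps peak below the strict threshold even though the
#' programmed sequence is executed.
#'
#' @param result An `observable_series`.
#' @param patterns A `target_patterns`.
#' @param rt A `recip_table`.
#' @return A list with `label`, `measurements`, `shifts` (strict detector
#'   output), `terminal` (index into the sequence of the best-matching
#'   structure, or `NA`), and `shifted` (logical).
#' @export
classify_run <- function(result, patterns, rt) {
  meas <- state_measurements(result$final_state, patterns, rt,
                             result$params$mu)
  sh <- detect_shifts(result)
  seqn <- patterns$sequence
  ov <- vapply(seqn, function(l) {
    overlap(result$final_state, patterns$patterns[[l]], rt)
  }, numeric(1))
  best <- which.max(ov)
  terminal <- if (1 - ov[best] <= 0.05) best else NA_integer_
  shifted <- sh$n_shifts >= 1L || (!is.na(terminal) && terminal > 1L)
  list(label = classify_regime(meas, as.integer(shifted)),
       measurements = meas, shifts = sh, terminal = terminal,
       shifted = shifted)
}

#' Colour a configuration by contributing structure
#'
#' Empty sites are 0 (white).  Every tile takes the colour (index) of the
#' stored structure contributing the largest number of its specific bonds
#' with its current neighbours; ties are broken uniformly at random among
#' the competing structures, and tiles with no specific bond inherit a
#' uniformly random structure colour.  The random choices are reproducible
#' under `rng_seed`.
#'
#' @param state A `lattice_state`.
#' @param rt A `recip_table` (used for its bond set; per-structure
#'   attribution is recomputed from `patterns`).
#' @param patterns A `target_patterns`.
#' @param rng_seed Integer seed for tie-breaking.
#' @return An `L x L` integer matrix of colours in `0..m`.
#' @export
colour_configuration <- function(state, rt, patterns, rng_seed = 1L) {
  validate_patterns(patterns)
  m <- patterns$m
  L <- state$L
  sig <- state$sigma
  # per-structure oriented bond lookups
  per <- lapply(seq_len(m), function(l) {
    tp1 <- patterns
    tp1$patterns <- patterns$patterns[l]
    tp1$m <- 1L
    tp1$sequence <- 1L
    rt1 <- build_reciprocal_table(tp1, rt$epsilon)
    recip_lookup(rt1)
  })
  colours <- matrix(0L, L, L)
  with_local_seed(rng_seed, {
    occ <- which(sig != 0L, arr.ind = TRUE)
    for (k in seq_len(nrow(occ))) {
      i <- occ[k, 1]; j <- occ[k, 2]
      s <- sig[i, j]
      nb <- neighbour_species(state, c(i, j))
      score <- vapply(per, function(lk) {
        cnt <- 0L
        if (nb[["left"]] != 0L && lk$H[nb[["left"]] + 1L, s + 1L])
          cnt <- cnt + 1L
        if (nb[["right"]] != 0L && lk$H[s + 1L, nb[["right"]] + 1L])
          cnt <- cnt + 1L
        if (nb[["up"]] != 0L && lk$V[nb[["up"]] + 1L, s + 1L])
          cnt <- cnt + 1L
        if (nb[["down"]] != 0L && lk$V[s + 1L, nb[["down"]] + 1L])
          cnt <- cnt + 1L
        cnt
      }, integer(1))
      if (all(score == 0L)) {
        colours[i, j] <- sample.int(m, 1L)
      } else {
        winners <- which(score == max(score))
        colours[i, j] <- if (length(winners) == 1L) winners else
          winners[sample.int(length(winners), 1L)]
      }
    }
  })
  colours
}
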