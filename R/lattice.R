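#' Simulation parameters
#'
#' Bundles the scalar parameters of a grand-canonical kinetic Monte Carlo
#' run.  All energies are in units of the thermal energy `kT`; time is
#' measured in lattice sweeps (`tau_s`), one sweep being `L^2` single-site
#' replacement proposals on the `L x L` lattice (`L = 2 * sqrt(M)`).
#'
#' @param epsilon Specific bond energy (>= 0).
#' @param mu Chemical potential of the tiles; the Hamiltonian contains
#'   `-mu * n`, so typical assembly conditions use negative `mu`.
#' @param lam Non-reciprocal interaction strength lambda (>= 0); 0 recovers
#'   the equilibrium multifarious assembly model.
#' @param sweeps Run duration in sweeps.
#' @param seed_side Side length of the initial square seed block copied from
#'   the first structure of the sequence.
#' @param sample_every Sweeps between observable samples.
#' @param rng_seed Integer seed of the dynamics stream (independent from the
#'   pattern stream).
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(epsilon, mu, lam = 0, sweeps = 1e5, seed_side = NULL,
                       sample_every = 100L, rng_seed = 1L) {
  stopifnot(epsilon >= 0, lam >= 0, sweeps >= 0, sample_every >= 1)
  structure(
    list(epsilon = epsilon, mu = mu, lam = lam, sweeps = sweeps,
         seed_side = seed_side, sample_every = as.integer(sample_every),
         rng_seed = as.integer(rng_seed)),
    class = "sim_params"
  )
}

#' Initialize the lattice state
#'
#' Builds the `L x L` lattice (`L = 2 * side`) holding species `0..M` (0 =
#' empty) and places a centred `seed_side x seed_side` block copied from the
#' centre of the chosen structure.  `seed_side = side` places the complete
#' structure; `seed_side = 0` gives an empty lattice.
#'
#' @param patterns A `target_patterns` object.
#' @param params A `sim_params` object; `params$seed_side` defaults to the
#'   full structure when `NULL`.
#' @param seed_pattern Index of the structure providing the seed (default:
#'   first structure of the sequence).
#' @return An object of class `lattice_state` with fields `L`, `sigma`
#'   (`L x L` integer matrix), `n`, `anchor` (1-based lattice row/column of
#'   the centred pattern footprint's top-left corner), `side` and `M`.
#' @export
init_state <- function(patterns, params, seed_pattern = patterns$sequence[1]) {
  validate_patterns(patterns)
  side <- patterns$side
  seed_side <- params$seed_side
  if (is.null(seed_side)) seed_side <- side
  if (seed_side > side) stop("seed_side exceeds the pattern side",
                             call. = FALSE)
  L <- 2L * side
  sigma <- matrix(0L, L, L)
  anchor <- side %/% 2L + 1L
  if (seed_side > 0L) {
    off <- (side - seed_side) %/% 2L
    rows <- off + seq_len(seed_side)
    block <- patterns$patterns[[seed_pattern]][rows, rows, drop = FALSE]
    sigma[anchor + off + seq_len(seed_side) - 1L,
          anchor + off + seq_len(seed_side) - 1L] <- block
  }
  structure(
    list(L = L, sigma = sigma, n = sum(sigma != 0L),
         anchor = c(anchor, anchor), side = side, M = patterns$M),
    class = "lattice_state"
  )
}

#' @export
print.lattice_state <- function(x, ...) {
  cat(sprintf("<lattice_state> %d x %d lattice, %d / %d sites occupied\n",
              x$L, x$L, x$n, x$L^2))
  invisible(x)
}

# Periodic neighbour species (left, right, up, down) of a 1-based site.
neighbour_species <- function(state, site) {
  L <- state$L
  i <- site[1]; j <- site[2]
  c(
    left  = state$sigma[i, if (j == 1L) L else j - 1L],
    right = state$sigma[i, if (j == L) 1L else j + 1L],
    up    = state$sigma[if (i == 1L) L else i - 1L, j],
    down  = state$sigma[if (i == L) 1L else i + 1L, j]
  )
}

# Reciprocal bond energy of species s against the four neighbour species.
local_bond_energy <- function(s, nb, rt) {
  if (s == 0L) return(0)
  lkH <- recip_lookup(rt)$H
  lkV <- recip_lookup(rt)$V
  cnt <- 0L
  if (nb[["left"]] != 0L && lkH[nb[["left"]] + 1L, s + 1L]) cnt <- cnt + 1L
  if (nb[["right"]] != 0L && lkH[s + 1L, nb[["right"]] + 1L]) cnt <- cnt + 1L
  if (nb[["up"]] != 0L && lkV[nb[["up"]] + 1L, s + 1L]) cnt <- cnt + 1L
  if (nb[["down"]] != 0L && lkV[s + 1L, nb[["down"]] + 1L]) cnt <- cnt + 1L
  -rt$epsilon * cnt
}

# Cached dense lookups, memoised on the table object via an environment.
recip_lookup <- function(rt) {
  cache <- attr(rt, "lookup_cache")
  if (is.null(cache)) {
    # no reference to store the cache on; build afresh
    return(list(H = dir_lookup(rt, DIR_RECIP[["H"]]),
                V = dir_lookup(rt, DIR_RECIP[["V"]])))
  }
  if (is.null(cache$lk)) {
    cache$lk <- list(H = dir_lookup(rt, DIR_RECIP[["H"]]),
                     V = dir_lookup(rt, DIR_RECIP[["V"]]))
  }
  cache$lk
}

nonrecip_lookup <- function(nt) {
  cache <- attr(nt, "lookup_cache")
  build <- function() {
    list(NE = dir_lookup(nt, DIR_NONRECIP[["NE"]]),
         SW = dir_lookup(nt, DIR_NONRECIP[["SW"]]),
         SE = dir_lookup(nt, DIR_NONRECIP[["SE"]]),
         NW = dir_lookup(nt, DIR_NONRECIP[["NW"]]))
  }
  if (is.null(cache)) return(build())
  if (is.null(cache$lk)) cache$lk <- build()
  cache$lk
}

#' Attach a memoisation cache to an interaction table
#'
#' Dense lookup matrices are rebuilt on every energy evaluation unless the
#' table carries a cache environment; `cache_table()` attaches one.  The
#' compiled engine builds its own maps, so this only matters for the
#' R-level reference functions when called in a loop.
#'
#' @param tab A `recip_table` or `nonrecip_table`.
#' @return The table with a cache attached.
#' @export
cache_table <- function(tab) {
  attr(tab, "lookup_cache") <- new.env(parent = emptyenv())
  tab
}

#' Local energy change of a single-site replacement
#'
#' Returns `dH` for replacing the species at `site` by `new_species`,
#' evaluated over the (at most) four incident bonds plus the chemical
#' potential term `-mu * dn`.  This is the R reference implementation; the
#' compiled engine repeats the same arithmetic.
#'
#' @param state A `lattice_state`.
#' @param site Integer vector `c(i, j)`, 1-based.
#' @param new_species Proposed species (0 = removal).
#' @param rt A `recip_table`.
#' @param mu Chemical potential.
#' @return The energy change in `kT`.
#' @export
delta_hamiltonian <- function(state, site, new_species, rt, mu) {
  check_site(state, site)
  nb <- neighbour_species(state, site)
  old <- state$sigma[site[1], site[2]]
  dn <- (new_species != 0L) - (old != 0L)
  local_bond_energy(new_species, nb, rt) - local_bond_energy(old, nb, rt) -
    mu * dn
}

#' Non-reciprocal weight of an arriving tile
#'
#' Returns `Lambda` for the arrival of `new_species` at `site`: the sum of
#' `lam` over the directed approach entries matched by the four neighbours —
#' (left neighbour SW arriving), (arriving NE right neighbour), (arriving SE
#' neighbour below), (neighbour above NW arriving).  Removal
#' (`new_species = 0`) and empty neighbours contribute nothing.
#'
#' @param state A `lattice_state`.
#' @param site Integer vector `c(i, j)`, 1-based.
#' @param new_species Proposed species.
#' @param nt A `nonrecip_table`.
#' @return The weight in `kT` (a multiple of `lam`).
#' @export
nonreciprocal_weight <- function(state, site, new_species, nt) {
  check_site(state, site)
  if (new_species == 0L || nt$lam == 0) return(0)
  nb <- neighbour_species(state, site)
  lk <- nonrecip_lookup(nt)
  s1 <- new_species + 1L
  cnt <- 0L
  if (nb[["left"]] != 0L && lk$SW[nb[["left"]] + 1L, s1]) cnt <- cnt + 1L
  if (nb[["right"]] != 0L && lk$NE[s1, nb[["right"]] + 1L]) cnt <- cnt + 1L
  if (nb[["down"]] != 0L && lk$SE[s1, nb[["down"]] + 1L]) cnt <- cnt + 1L
  if (nb[["up"]] != 0L && lk$NW[nb[["up"]] + 1L, s1]) cnt <- cnt + 1L
  nt$lam * cnt
}

check_site <- function(state, site) {
  if (length(site) != 2L || any(site < 1L) || any(site > state$L)) {
    stop("site out of bounds", call. = FALSE)
  }
  invisible(site)
}

#' Propose and (possibly) apply one Monte Carlo move
#'
#' Draws a uniform random site and a uniform random replacement species
#' `sigma' != sigma` from `{0..M}`, computes the energy change and the
#' non-reciprocal weight, and accepts with probability
#' `p = min(1, exp(Lambda - dH))`.  The returned record carries the
#' quantities of both the forward move and its exact inverse (evaluated in
#' the post-move state), as needed for entropy-production accounting.
#'
#' Randomness is drawn from R's RNG (three variates per call: site, species,
#' acceptance), so sequences of moves are reproducible under `set.seed()`.
#' This reference implementation mirrors the compiled engine move for move;
#' the engine uses its own generator and is the one to use for long runs.
#'
#' @param state A `lattice_state`.
#' @param rt,nt Interaction tables.
#' @param mu Chemical potential.
#' @return A list with `state` (new state) and `record`, the move record
#'   (`site`, `old_species`, `new_species`, `dH`, `Lambda_fwd`, `Lambda_rev`,
#'   `p_fwd`, `p_rev`, `accepted`).
#' @export
attempt_move <- function(state, rt, nt, mu) {
  L <- state$L
  M <- state$M
  idx <- min(floor(stats::runif(1) * L * L), L * L - 1)
  i <- (idx %% L) + 1L
  j <- (idx %/% L) + 1L
  old <- state$sigma[i, j]
  prop <- min(floor(stats::runif(1) * M), M - 1)
  if (prop >= old) prop <- prop + 1L
  prop <- as.integer(prop)
  dh <- delta_hamiltonian(state, c(i, j), prop, rt, mu)
  lam_f <- nonreciprocal_weight(state, c(i, j), prop, nt)
  p_fwd <- min(1, exp(lam_f - dh))
  u <- stats::runif(1)
  accepted <- u < p_fwd
  # reverse replacement (prop -> old) in the post-move state; neighbours are
  # unchanged by the move, so it can be evaluated from the same surroundings
  lam_r <- nonreciprocal_weight(state, c(i, j), old, nt)
  p_rev <- min(1, exp(lam_r + dh))
  if (accepted) {
    state$sigma[i, j] <- prop
    state$n <- state$n + (prop != 0L) - (old != 0L)
  }
  list(
    state = state,
    record = list(site = c(i, j), old_species = old, new_species = prop,
                  dH = dh, Lambda_fwd = lam_f, Lambda_rev = lam_r,
                  p_fwd = p_fwd, p_rev = p_rev, accepted = accepted)
  )
}

#' Total lattice energy (brute force)
#'
#' Evaluates `H = sum_bonds U^r - mu * n` over all lattice bonds (periodic,
#' each bond counted once).  Serves as the from-scratch oracle against which
#' incremental energy tracking is checked.
#'
#' @param state A `lattice_state`.
#' @param rt A `recip_table`.
#' @param mu Chemical potential.
#' @return The total energy in `kT`.
#' @export
total_energy <- function(state, rt, mu) {
  cpp_total_energy(state$sigma, state$M, table_entries(rt), rt$epsilon, mu)
}

# R-only fallback oracle, independent of the compiled path; used in tests.
total_energy_r <- function(state, rt, mu) {
  L <- state$L
  sig <- state$sigma
  lk <- recip_lookup(rt)
  right <- as.vector(sig[, c(2:L, 1L)])
  down <- as.vector(sig[c(2:L, 1L), ])
  s <- as.vector(sig)
  hb <- s != 0L & right != 0L & lk$H[cbind(s + 1L, right + 1L)]
  vb <- s != 0L & down != 0L & lk$V[cbind(s + 1L, down + 1L)]
  -rt$epsilon * (sum(hb) + sum(vb)) - mu * sum(s != 0L)
}

table_entries <- function(tab) {
  e <- tab$entries
  storage.mode(e) <- "integer"
  e
}

#' Run the kinetic Monte Carlo simulation
#'
#' Executes `params$sweeps` lattice sweeps (`L^2` proposals each) with the
#' compiled engine and samples observables every `params$sample_every`
#' sweeps: density, energy (tracked incrementally from the initial
#' brute-force value), cumulative entropy production, and the overlap of the
#' largest specifically connected cluster with every stored structure.
#'
#' @param state Initial `lattice_state` (see [init_state()]).
#' @param rt,nt Interaction tables compiled from the same patterns.  Only
#'   their entry sets are used here; the couplings `epsilon` and `lam` of
#'   the run are taken from `params`, which is the single source of truth
#'   for all scalar parameters.
#' @param params A `sim_params`; `params$rng_seed` fully determines the
#'   trajectory.
#' @param patterns The `target_patterns` the tables were built from (used for
#'   overlap measurement); set `track_overlap = FALSE` to skip it.
#' @param track_overlap Sample overlaps (default `TRUE`).
#' @param record_codes Also record the whole configuration per sample as a
#'   base-`(M+1)` code; only for tiny systems (exact-distribution checks).
#' @return An object of class `observable_series`: list with `series` (a
#'   data.frame with columns `sweep`, `density`, `energy`, `entropy`,
#'   `overlap_1..overlap_m`), `final_state`, `accepted`, `params`, and
#'   `sequence`.
#' @export
run_simulation <- function(state, rt, nt, params, patterns = NULL,
                           track_overlap = !is.null(patterns),
                           record_codes = FALSE) {
  stopifnot(inherits(state, "lattice_state"), inherits(params, "sim_params"))
  if (track_overlap && is.null(patterns)) {
    stop("patterns are required to track overlaps", call. = FALSE)
  }
  pats_flat <- if (!is.null(patterns)) {
    matrix(unlist(lapply(patterns$patterns, as.integer)),
           ncol = patterns$m)
  } else {
    matrix(integer(0), nrow = 0, ncol = 0)
  }
  res <- cpp_run(
    state$sigma, state$M, table_entries(rt), table_entries(nt),
    params$epsilon, params$mu, params$lam, params$sweeps,
    params$sample_every,
    pats_flat, state$side, track_overlap, record_codes,
    as.double(params$rng_seed)
  )
  series <- data.frame(sweep = res$sweep, density = res$density,
                       energy = res$energy, entropy = res$entropy)
  if (track_overlap) {
    ov <- res$overlap
    colnames(ov) <- paste0("overlap_", seq_len(ncol(ov)))
    series <- cbind(series, as.data.frame(ov))
  }
  final_state <- state
  final_state$sigma <- res$sigma
  final_state$n <- as.integer(res$n)
  out <- list(
    series = series,
    final_state = final_state,
    final_energy = res$final_energy,
    accepted = res$accepted,
    params = params,
    sequence = if (!is.null(patterns)) patterns$sequence else NULL
  )
  if (record_codes) out$codes <- res$codes
  class(out) <- "observable_series"
  out
}

#' @export
print.observable_series <- function(x, ...) {
  ns <- nrow(x$series)
  cat(sprintf(
    "<observable_series> %d samples over %g sweeps; final density %.3f, energy %.1f, entropy %.1f\n",
    ns, max(x$series$sweep), x$series$density[ns], x$series$energy[ns],
    x$series$entropy[ns]))
  invisible(x)
}
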