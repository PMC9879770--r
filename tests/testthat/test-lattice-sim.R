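test_that("init_state places the centred seed block", {
  tp <- generate_patterns(4, 1600, rng_seed = 7)
  # full first structure
  pf <- sim_params(10, -19, 0, sweeps = 0, seed_side = 40)
  st <- init_state(tp, pf)
  expect_equal(st$L, 80L)
  expect_equal(st$n, 1600L)
  expect_equal(st$sigma[21:60, 21:60], tp$patterns[[1]])
  expect_equal(st$anchor, c(21L, 21L))

  # empty lattice
  p0 <- sim_params(10, -19, 0, sweeps = 0, seed_side = 0)
  expect_equal(init_state(tp, p0)$n, 0L)

  # 16 x 16 seed from the pattern centre
  p16 <- sim_params(10, -19, 0, sweeps = 0, seed_side = 16)
  st16 <- init_state(tp, p16)
  expect_equal(st16$n, 256L)
  expect_equal(st16$sigma[33:48, 33:48], tp$patterns[[1]][13:28, 13:28])

  expect_error(init_state(tp, sim_params(10, -19, 0, seed_side = 41)),
               "seed_side")
})

test_that("delta_hamiltonian matches hand-computed local changes", {
  tp <- generate_patterns(2, 400, rng_seed = 3)
  eps <- 11; mu <- -19
  rt <- cache_table(build_reciprocal_table(tp, eps))
  st <- init_state(tp, sim_params(eps, mu, 0, seed_side = 20))
  a <- st$anchor[1]

  # insertion into empty surroundings costs -mu
  far <- c(2L, 2L)
  expect_equal(delta_hamiltonian(st, far, 5L, rt, mu), 19)

  # removing an interior tile of the perfect structure: lose 4 bonds + one tile
  site <- c(a + 10L, a + 10L)
  expect_equal(delta_hamiltonian(st, site, 0L, rt, mu), 4 * eps + mu)

  # re-completing a hole whose 4 neighbours match the pattern: -4*eps + 19
  hole <- st
  sp <- hole$sigma[site[1], site[2]]
  hole$sigma[site[1], site[2]] <- 0L
  hole$n <- hole$n - 1L
  expect_equal(delta_hamiltonian(hole, site, sp, rt, mu), -4 * eps + 19)

  # identity replacement is free
  expect_equal(delta_hamiltonian(st, site, sp, rt, mu), 0)

  expect_error(delta_hamiltonian(st, c(0L, 1L), 1L, rt, mu), "out of bounds")
})

test_that("nonreciprocal_weight counts matched approach arrows", {
  tp <- generate_patterns(2, 9, rng_seed = 2)
  lam <- 3
  nt <- cache_table(build_nonreciprocal_table(tp, lam))
  st <- init_state(tp, sim_params(5, -8, lam, seed_side = 3))
  a <- st$anchor[1]

  # incoming next-structure tile over a complete current structure: 4 arrows
  s2 <- tp$patterns[[2]][2, 2]
  expect_equal(nonreciprocal_weight(st, c(a + 1L, a + 1L), s2, nt), 4 * lam)
  # corner site: only 2 neighbours inside the footprint
  expect_equal(nonreciprocal_weight(st, c(a, a), tp$patterns[[2]][1, 1], nt),
               2 * lam)
  # removal never collects non-reciprocal weight
  expect_equal(nonreciprocal_weight(st, c(a + 1L, a + 1L), 0L, nt), 0)
  # lam = 0 recovers the equilibrium model
  nt0 <- build_nonreciprocal_table(tp, 0)
  expect_equal(nonreciprocal_weight(st, c(a + 1L, a + 1L), s2, nt0), 0)
})

test_that("R and compiled local energies agree on random states", {
  tp <- generate_patterns(3, 36, rng_seed = 13)
  rt <- cache_table(build_reciprocal_table(tp, 2.5))
  nt <- cache_table(build_nonreciprocal_table(tp, 1.25))
  mu <- -3.5
  set.seed(42)
  st <- init_state(tp, sim_params(2.5, mu, 1.25, seed_side = 6))
  # scatter extra random tiles to create boundaries, vacancies, clashes
  extra <- sample(st$L^2, 40)
  st$sigma[extra] <- sample(0:36, 40, replace = TRUE)
  st$n <- sum(st$sigma != 0L)
  for (k in 1:60) {
    site <- c(sample(st$L, 1), sample(st$L, 1))
    sp <- sample(0:36, 1)
    expect_equal(
      delta_hamiltonian(st, site, sp, rt, mu),
      multishift:::cpp_delta_h(st$sigma, st$M, rt$entries, 2.5, mu,
                               site[1], site[2], sp))
    expect_equal(
      nonreciprocal_weight(st, site, sp, nt),
      multishift:::cpp_lambda(st$sigma, st$M, nt$entries, 1.25,
                              site[1], site[2], sp))
  }
})

test_that("incremental dH agrees with brute-force total energy over moves", {
  # 12 x 12 lattice (side-6 patterns), mixed dynamics
  tp <- generate_patterns(2, 36, rng_seed = 8)
  eps <- 2; mu <- -3; lam <- 1.5
  rt <- cache_table(build_reciprocal_table(tp, eps))
  nt <- cache_table(build_nonreciprocal_table(tp, lam))
  st <- init_state(tp, sim_params(eps, mu, lam, seed_side = 6))
  set.seed(101)
  h <- total_energy(st, rt, mu)
  expect_equal(h, multishift:::total_energy_r(st, rt, mu))
  n_acc <- 0L
  p_ok <- TRUE        # p in (0, 1], and p = 1 whenever Lambda - dH >= 0
  max_drift <- 0      # worst incremental-vs-brute-force discrepancy
  for (k in seq_len(10000)) {
    mv <- attempt_move(st, rt, nt, mu)
    st <- mv$state
    rec <- mv$record
    p_ok <- p_ok && rec$p_fwd > 0 && rec$p_fwd <= 1 &&
      (rec$Lambda_fwd - rec$dH < 0 || rec$p_fwd == 1)
    if (rec$accepted) {
      h <- h + rec$dH
      n_acc <- n_acc + 1L
    }
    if (k %% 500 == 0) {
      max_drift <- max(max_drift, abs(h - total_energy(st, rt, mu)))
    }
  }
  expect_true(p_ok)
  expect_lt(max_drift, 1e-9)
  expect_equal(h, multishift:::total_energy_r(st, rt, mu), tolerance = 1e-9)
  expect_gt(n_acc, 100L)  # the chain actually moved
})

test_that("acceptance probability follows the generalized Metropolis rule", {
  tp <- generate_patterns(2, 36, rng_seed = 8)
  rt <- build_reciprocal_table(tp, 2)
  nt0 <- build_nonreciprocal_table(tp, 0)
  st <- init_state(tp, sim_params(2, -3, 0, seed_side = 6))
  set.seed(7)
  ok <- TRUE
  for (k in 1:300) {
    mv <- attempt_move(st, rt, nt0, -3)
    rec <- mv$record
    st <- mv$state
    # lam = 0: plain Metropolis in both directions
    ok <- ok && rec$Lambda_fwd == 0 &&
      isTRUE(all.equal(rec$p_fwd, min(1, exp(-rec$dH)))) &&
      isTRUE(all.equal(rec$p_rev, min(1, exp(rec$dH))))
  }
  expect_true(ok)
  # direct evaluations of the acceptance formula at spec magnitudes
  expect_equal(min(1, exp(32 - 23)), 1)
  expect_equal(min(1, exp(8 - 23)), exp(-15))
})

test_that("total_energy matches closed forms", {
  tp <- generate_patterns(1, 400, rng_seed = 5)
  eps <- 7; mu <- -13
  rt <- build_reciprocal_table(tp, eps)
  # empty lattice
  st0 <- init_state(tp, sim_params(eps, mu, 0, seed_side = 0))
  expect_equal(total_energy(st0, rt, mu), 0)
  # isolated complete structure: 2*20*19 bonds, 400 tiles
  stf <- init_state(tp, sim_params(eps, mu, 0, seed_side = 20))
  expect_equal(total_energy(stf, rt, mu), -760 * eps - 400 * mu)
  # single isolated tile
  st1 <- st0
  st1$sigma[3, 3] <- 17L
  st1$n <- 1L
  expect_equal(total_energy(st1, rt, mu), -mu)
})

test_that("the engine is deterministic in the seed and tracks energy exactly", {
  tp <- generate_patterns(3, 100, rng_seed = 31)
  rt <- build_reciprocal_table(tp, 6)
  nt <- build_nonreciprocal_table(tp, 4)
  pars <- sim_params(6, -10, 4, sweeps = 300, sample_every = 50,
                     rng_seed = 77)
  st <- init_state(tp, pars)
  r1 <- run_simulation(st, rt, nt, pars, tp)
  r2 <- run_simulation(st, rt, nt, pars, tp)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$final_state$sigma, r2$final_state$sigma)
  pars2 <- pars; pars2$rng_seed <- 78L
  r3 <- run_simulation(st, rt, nt, pars2, tp)
  expect_false(identical(r1$final_state$sigma, r3$final_state$sigma))

  # tracked energy equals the brute-force oracle on the final state
  expect_equal(r1$final_energy, total_energy(r1$final_state, rt, -10),
               tolerance = 1e-9)
  expect_equal(r1$final_energy,
               multishift:::total_energy_r(r1$final_state, rt, -10),
               tolerance = 1e-9)
  # sweeps = 0: only the initial sample
  pars0 <- sim_params(6, -10, 4, sweeps = 0, rng_seed = 1)
  r0 <- run_simulation(st, rt, nt, pars0, tp)
  expect_equal(nrow(r0$series), 1L)
  expect_equal(r0$series$density[1], st$n / st$L^2)
})

test_that("lam = 0 sampling reproduces the exact Boltzmann distribution", {
  # tiny toy: 2 x 2 periodic lattice, 2 species, hand-made bond table;
  # all 81 configurations enumerable exactly
  rt <- manual_recip(list(list(1L, "H", 2L), list(2L, "V", 1L)), M = 2,
                     epsilon = 1.2)
  nt <- empty_nonrecip(2)
  mu <- -0.4
  states <- as.matrix(expand.grid(0:2, 0:2, 0:2, 0:2))
  energies <- apply(states, 1, function(s) {
    multishift:::total_energy_r(manual_state(matrix(s, 2, 2), M = 2), rt, mu)
  })
  p_exact <- exp(-energies) / sum(exp(-energies))

  st <- manual_state(matrix(0L, 2, 2), M = 2)
  pars <- sim_params(1.2, mu, 0, sweeps = 6e5, sample_every = 20,
                     rng_seed = 5)
  res <- run_simulation(st, rt, nt, pars, track_overlap = FALSE,
                        record_codes = TRUE)
  codes <- res$codes[-1]
  # code of each enumerated state, in R's column-major order (base 3)
  code_of <- states %*% 3^(0:3)
  counts <- tabulate(match(codes, code_of), nbins = 81)
  chi <- suppressWarnings(stats::chisq.test(counts, p = p_exact))
  expect_gt(chi$p.value, 1e-3)
})
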