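# Shared fixtures: hand-built miniature designs with known geometry.

# target_patterns from explicit matrices (bypasses the random generator)
manual_patterns <- function(mats, sequence = seq_along(mats)) {
  side <- nrow(mats[[1]])
  structure(
    list(m = length(mats), M = side^2, side = side,
         patterns = lapply(mats, function(m) {
           storage.mode(m) <- "integer"
           m
         }),
         sequence = as.integer(sequence), rng_seed = 0L),
    class = "target_patterns"
  )
}

# lattice_state from an explicit sigma matrix (for states not reachable via
# init_state, e.g. hand-placed clusters or toy systems without patterns)
manual_state <- function(sigma, M, side = nrow(sigma) %/% 2L,
                         anchor = rep(side %/% 2L + 1L, 2)) {
  storage.mode(sigma) <- "integer"
  structure(
    list(L = nrow(sigma), sigma = sigma, n = sum(sigma != 0L),
         anchor = anchor, side = side, M = as.integer(M)),
    class = "lattice_state"
  )
}

# recip_table from explicit (a, dir-letter, b) triples
manual_recip <- function(triples, M, epsilon = 1) {
  e <- do.call(rbind, lapply(triples, function(tr) {
    c(a = tr[[1]], dir = c(H = 1L, V = 2L)[[tr[[2]]]], b = tr[[3]])
  }))
  storage.mode(e) <- "integer"
  colnames(e) <- c("a", "dir", "b")
  structure(list(epsilon = epsilon, M = as.integer(M),
                 entries = e[order(e[, "dir"], e[, "a"], e[, "b"]), ,
                             drop = FALSE]),
            class = "recip_table")
}

empty_nonrecip <- function(M, lam = 0) {
  structure(
    list(lam = lam, M = as.integer(M),
         entries = matrix(integer(0), ncol = 3,
                          dimnames = list(NULL, c("a", "dir", "b")))),
    class = "nonrecip_table"
  )
}

# entries matrix -> set of "a dir b" strings for order-free comparison
entry_set <- function(tab) {
  e <- tab$entries
  sort(paste(e[, "a"], e[, "dir"], e[, "b"]))
}
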