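#' Generate target structures for multifarious self-assembly
#'
#' Draws `m` target structures, each a uniformly random permutation of the
#' `M` tile species arranged on a `sqrt(M) x sqrt(M)` grid (fully
#' heterogeneous, zero-sparsity structures: every species appears exactly
#' once per structure).  The first `sequence_length` structures form the
#' programmed shifting sequence `S1 -> S2 -> ...`.
#'
#' @param m Number of stored structures.
#' @param M Tiles per structure; must be a perfect square.
#' @param sequence_length Length of the shifting sequence (number of
#'   structures in the queue, `1 <= sequence_length <= m`).  The default uses
#'   all `m` structures.
#' @param rng_seed Integer seed for the pattern stream.  Pattern generation
#'   uses its own, locally restored RNG state so that patterns can be
#'   regenerated without disturbing (or replaying) the dynamics stream.
#' @return An object of class `target_patterns`: a list with fields `m`, `M`,
#'   `side`, `patterns` (list of `side x side` integer matrices), `sequence`
#'   (integer vector of pattern indices) and `rng_seed`.
#' @examples
#' tp <- generate_patterns(m = 2, M = 9, rng_seed = 1)
#' sort(tp$patterns[[1]])  # 1..9, each species once
#' @export
generate_patterns <- function(m, M, sequence_length = m, rng_seed = 1L) {
  side <- as.integer(round(sqrt(M)))
  if (side * side != M) {
    stop("M = ", M, " is not a perfect square", call. = FALSE)
  }
  if (m < 1L) stop("m must be >= 1", call. = FALSE)
  if (sequence_length < 1L || sequence_length > m) {
    stop("sequence_length must be in 1..m", call. = FALSE)
  }
  patterns <- with_local_seed(rng_seed, {
    lapply(seq_len(m), function(i) {
      matrix(sample.int(M), nrow = side, ncol = side)
    })
  })
  structure(
    list(
      m = as.integer(m), M = as.integer(M), side = side,
      patterns = patterns,
      sequence = seq_len(sequence_length),
      rng_seed = as.integer(rng_seed)
    ),
    class = "target_patterns"
  )
}

#' @export
print.target_patterns <- function(x, ...) {
  cat(sprintf(
    "<target_patterns> m = %d structures of %d x %d tiles (M = %d)\n",
    x$m, x$side, x$side, x$M
  ))
  cat("  sequence: S", paste(x$sequence, collapse = " -> S"), "\n", sep = "")
  invisible(x)
}

# Validate the target_patterns invariants; used by constructors/readers.
validate_patterns <- function(tp) {
  stopifnot(inherits(tp, "target_patterns"))
  if (tp$side^2 != tp$M) stop("side^2 != M", call. = FALSE)
  for (p in tp$patterns) {
    if (!identical(dim(p), c(tp$side, tp$side))) {
      stop("pattern of wrong shape", call. = FALSE)
    }
    if (!identical(sort(as.integer(p)), seq_len(tp$M))) {
      stop("pattern is not a permutation of 1..M", call. = FALSE)
    }
  }
  if (anyDuplicated(tp$sequence) ||
      any(tp$sequence < 1L) || any(tp$sequence > tp$m)) {
    stop("sequence entries must be distinct valid pattern indices",
         call. = FALSE)
  }
  invisible(tp)
}

# Run `code` under a temporary seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Orientation codes for reciprocal bonds and arrow codes for non-reciprocal
# approach interactions.  H: A immediately left of B.  V: A immediately above
# B.  Arrows name the role of the *arriving* tile relative to an existing
# neighbour; they are the polarized versions of H and V.
DIR_RECIP <- c(H = 1L, V = 2L)
DIR_NONRECIP <- c(NE = 1L, SW = 2L, SE = 3L, NW = 4L)

#' Compile the reciprocal interaction table
#'
#' Collects, over all stored structures, every oriented nearest-neighbour
#' species pair and assigns it the specific bond energy `-epsilon`.  A pair
#' favoured by several structures appears once (set semantics): two species
#' interact specifically if at least one structure places them next to each
#' other in that orientation.
#'
#' @param patterns A `target_patterns` object.
#' @param epsilon Specific bond energy in units of `kT` (`>= 0`; bonds
#'   contribute `-epsilon` to the Hamiltonian).
#' @return An object of class `recip_table` with fields `epsilon`, `M` and
#'   `entries`, an integer matrix with columns `a`, `dir`, `b` where `dir` is
#'   1 (`H`, a left of b) or 2 (`V`, a above b).  Rows are sorted
#'   canonically, so rebuilding from the same patterns is bit-identical.
#' @export
build_reciprocal_table <- function(patterns, epsilon) {
  validate_patterns(patterns)
  stopifnot(epsilon >= 0)
  s <- patterns$side
  rows <- vector("list", 2L * patterns$m)
  k <- 0L
  for (p in patterns$patterns) {
    if (s > 1L) {
      k <- k + 1L
      rows[[k]] <- cbind(
        a = as.integer(p[, -s]), dir = DIR_RECIP[["H"]],
        b = as.integer(p[, -1L])
      )
      k <- k + 1L
      rows[[k]] <- cbind(
        a = as.integer(p[-s, ]), dir = DIR_RECIP[["V"]],
        b = as.integer(p[-1L, ])
      )
    }
  }
  entries <- if (k > 0L) {
    canonical_entries(do.call(rbind, rows[seq_len(k)]))
  } else {
    matrix(integer(0), ncol = 3L, dimnames = list(NULL, c("a", "dir", "b")))
  }
  structure(
    list(epsilon = epsilon, M = patterns$M, entries = entries),
    class = "recip_table"
  )
}

#' Compile the non-reciprocal interaction table
#'
#' For every consecutive transition `S(l) -> S(l+1)` of the shifting sequence
#' and every pattern site, emits the four directed approach interactions that
#' favour the arrival of the incoming tile `S(l+1)[i, j]` next to the four
#' current-structure neighbours `S(l)` of that site (neighbours outside the
#' pattern footprint are skipped).  Entries are unioned over all transitions
#' with set semantics and carry weight `+lam` in the move acceptance rate.
#'
#' The arrow codes polarize the two lattice axes by which tile is arriving:
#' `SW` (left neighbour, arriving tile), `NE` (arriving tile, right
#' neighbour), `SE` (arriving tile, neighbour below), `NW` (neighbour above,
#' arriving tile).
#'
#' @param patterns A `target_patterns` object; a sequence with fewer than two
#'   structures yields an empty table.
#' @param lam Non-reciprocal interaction strength `lambda` in units of `kT`
#'   (`>= 0`).  With `lam = 0` the model reduces to the equilibrium
#'   multifarious self-assembly model.
#' @return An object of class `nonrecip_table` with fields `lam`, `M` and
#'   `entries`, an integer matrix with columns `a`, `dir`, `b` where `dir` is
#'   1 = `NE`, 2 = `SW`, 3 = `SE`, 4 = `NW`.
#' @export
build_nonreciprocal_table <- function(patterns, lam) {
  validate_patterns(patterns)
  stopifnot(lam >= 0)
  s <- patterns$side
  seqn <- patterns$sequence
  rows <- list()
  if (length(seqn) >= 2L && s > 1L) {
    for (t in seq_len(length(seqn) - 1L)) {
      cur <- patterns$patterns[[seqn[t]]]
      nxt <- patterns$patterns[[seqn[t + 1L]]]
      # left neighbour SW incoming  (incoming arrives to the right of cur tile)
      rows[[length(rows) + 1L]] <- cbind(
        a = as.integer(cur[, -s]), dir = DIR_NONRECIP[["SW"]],
        b = as.integer(nxt[, -1L])
      )
      # incoming NE right neighbour
      rows[[length(rows) + 1L]] <- cbind(
        a = as.integer(nxt[, -s]), dir = DIR_NONRECIP[["NE"]],
        b = as.integer(cur[, -1L])
      )
      # incoming SE neighbour below
      rows[[length(rows) + 1L]] <- cbind(
        a = as.integer(nxt[-s, ]), dir = DIR_NONRECIP[["SE"]],
        b = as.integer(cur[-1L, ])
      )
      # neighbour above NW incoming
      rows[[length(rows) + 1L]] <- cbind(
        a = as.integer(cur[-s, ]), dir = DIR_NONRECIP[["NW"]],
        b = as.integer(nxt[-1L, ])
      )
    }
  }
  entries <- if (length(rows)) {
    canonical_entries(do.call(rbind, rows))
  } else {
    matrix(integer(0), ncol = 3L, dimnames = list(NULL, c("a", "dir", "b")))
  }
  structure(
    list(lam = lam, M = patterns$M, entries = entries),
    class = "nonrecip_table"
  )
}

# Deduplicate and sort (dir, a, b) entry rows so tables are canonical.
canonical_entries <- function(x) {
  colnames(x) <- c("a", "dir", "b")
  x <- unique(x)
  x[order(x[, "dir"], x[, "a"], x[, "b"]), , drop = FALSE]
}

#' @export
print.recip_table <- function(x, ...) {
  cat(sprintf(
    "<recip_table> %d oriented specific bonds, epsilon = %g kT, M = %d\n",
    nrow(x$entries), x$epsilon, x$M
  ))
  invisible(x)
}

#' @export
print.nonrecip_table <- function(x, ...) {
  cat(sprintf(
    "<nonrecip_table> %d directed approach entries, lambda = %g kT, M = %d\n",
    nrow(x$entries), x$lam, x$M
  ))
  invisible(x)
}

# Dense logical lookup (M+1)x(M+1) for one direction code; row = a, col = b,
# both offset by one so species 0 is representable (never present in tables).
dir_lookup <- function(table, dir_code) {
  M <- table$M
  lk <- matrix(FALSE, M + 1L, M + 1L)
  e <- table$entries
  sel <- e[, "dir"] == dir_code
  if (any(sel)) {
    lk[cbind(e[sel, "a"] + 1L, e[sel, "b"] + 1L)] <- TRUE
  }
  lk
}

#' Diagnostic summary of the compiled interaction tables
#'
#' Reports entry counts, per-face promiscuity (for each species and each of
#' the four faces, how many distinct specific partners the reciprocal table
#' allows) and how many non-reciprocal entries project onto a stored
#' reciprocal bond when their polarity is dropped.
#'
#' @param rt A `recip_table`.
#' @param nt A `nonrecip_table` built from the same patterns.
#' @return A list with `n_recip`, `n_nonrecip`, `promiscuity` (matrix `M x 4`,
#'   faces right/left/down/up) and `nr_overlap_recip` (count of non-reciprocal
#'   entries whose depolarized oriented pair is also a reciprocal bond).
#' @export
interaction_summary <- function(rt, nt) {
  stopifnot(inherits(rt, "recip_table"), inherits(nt, "nonrecip_table"))
  if (rt$M != nt$M) stop("tables built from different pattern sets",
                         call. = FALSE)
  M <- rt$M
  e <- rt$entries
  prom <- matrix(0L, nrow = M, ncol = 4L,
                 dimnames = list(NULL, c("right", "left", "down", "up")))
  h <- e[e[, "dir"] == DIR_RECIP[["H"]], , drop = FALSE]
  v <- e[e[, "dir"] == DIR_RECIP[["V"]], , drop = FALSE]
  if (nrow(h)) {
    tr <- table(factor(h[, "a"], levels = seq_len(M)))
    tl <- table(factor(h[, "b"], levels = seq_len(M)))
    prom[, "right"] <- as.integer(tr)
    prom[, "left"] <- as.integer(tl)
  }
  if (nrow(v)) {
    td <- table(factor(v[, "a"], levels = seq_len(M)))
    tu <- table(factor(v[, "b"], levels = seq_len(M)))
    prom[, "down"] <- as.integer(td)
    prom[, "up"] <- as.integer(tu)
  }
  # Depolarize arrows onto oriented pairs: SW(a, b): a left of arriving b -> H;
  # NE(a, b): arriving a left of neighbour b -> H; SE(a, b): arriving a above
  # b -> V; NW(a, b): neighbour a above arriving b -> V.
  ne <- nt$entries
  n_overlap <- 0L
  if (nrow(ne)) {
    hset <- paste(h[, "a"], h[, "b"])
    vset <- paste(v[, "a"], v[, "b"])
    proj_h <- ne[, "dir"] %in% DIR_NONRECIP[c("NE", "SW")]
    n_overlap <- sum(paste(ne[proj_h, "a"], ne[proj_h, "b"]) %in% hset) +
      sum(paste(ne[!proj_h, "a"], ne[!proj_h, "b"]) %in% vset)
  }
  list(
    n_recip = nrow(e),
    n_nonrecip = nrow(ne),
    promiscuity = prom,
    nr_overlap_recip = n_overlap
  )
}
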