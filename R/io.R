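ARROW_CODES <- c("H", "V")          # reciprocal orientation codes
NR_CODES <- c("NE", "SW", "SE", "NW")  # non-reciprocal arrow codes

#' Write a design (patterns + tables) to JSON
#'
#' The layout is plain and diffable: pattern grids as nested integer arrays
#' (row by row), interaction tables as lists of `[A, code, B]` triples with
#' orientation codes `"H"`/`"V"` and arrow codes `"NE"/"SW"/"SE"/"NW"`.
#'
#' @param patterns A `target_patterns`.
#' @param rt,nt Interaction tables built from `patterns`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_design <- function(patterns, rt, nt, path) {
  validate_patterns(patterns)
  obj <- list(
    schema = "multishift-design/1",
    m = patterns$m, M = patterns$M, side = patterns$side,
    sequence = patterns$sequence, rng_seed = patterns$rng_seed,
    patterns = lapply(patterns$patterns, function(p) {
      lapply(seq_len(nrow(p)), function(i) as.integer(p[i, ]))
    }),
    epsilon = rt$epsilon,
    lambda = nt$lam,
    reciprocal = entries_to_triples(rt$entries, ARROW_CODES),
    nonreciprocal = entries_to_triples(nt$entries, NR_CODES)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

entries_to_triples <- function(entries, codes) {
  lapply(seq_len(nrow(entries)), function(r) {
    list(entries[r, "a"], codes[entries[r, "dir"]], entries[r, "b"])
  })
}

triples_to_entries <- function(triples, codes) {
  if (length(triples) == 0L) {
    return(matrix(integer(0), ncol = 3,
                  dimnames = list(NULL, c("a", "dir", "b"))))
  }
  m <- t(vapply(triples, function(tr) {
    c(as.integer(tr[[1]]), match(tr[[2]], codes), as.integer(tr[[3]]))
  }, integer(3)))
  colnames(m) <- c("a", "dir", "b")
  canonical_entries(m)
}

#' Read a design written by [write_design()]
#'
#' @param path JSON file.
#' @return A list with `patterns` (`target_patterns`), `rt` (`recip_table`)
#'   and `nt` (`nonrecip_table`); tables are read verbatim, not rebuilt.
#' @export
read_design <- function(path) {
  obj <- jsonlite::read_json(path)
  side <- obj$side
  patterns <- structure(
    list(
      m = as.integer(obj$m), M = as.integer(obj$M), side = as.integer(side),
      patterns = lapply(obj$patterns, function(p) {
        do.call(rbind, lapply(p, function(row) as.integer(unlist(row))))
      }),
      sequence = as.integer(unlist(obj$sequence)),
      rng_seed = as.integer(obj$rng_seed)
    ),
    class = "target_patterns"
  )
  validate_patterns(patterns)
  rt <- structure(
    list(epsilon = obj$epsilon, M = patterns$M,
         entries = triples_to_entries(obj$reciprocal, ARROW_CODES)),
    class = "recip_table"
  )
  nt <- structure(
    list(lam = obj$lambda, M = patterns$M,
         entries = triples_to_entries(obj$nonreciprocal, NR_CODES)),
    class = "nonrecip_table"
  )
  list(patterns = patterns, rt = rt, nt = nt)
}

config_defaults <- list(
  design = list(m = 4L, M = 400L, q = 4L, pattern_seed = 1L),
  simulation = list(epsilon = 11.5, mu = -20, lambda = 8, sweeps = 2e5,
                    seed_side = NULL, sample_every = 100L, rng_seed = 1L),
  experiment = list(eps_values = NULL, mu_values = NULL, lam_values = NULL,
                    replicas = 5L),
  output = list(dir = "runs")
)

#' Load and validate a run configuration
#'
#' Reads a YAML configuration with blocks `design`, `simulation`,
#' `experiment` and `output`, fills defaults for absent keys and rejects
#' unknown ones.
#'
#' @param path YAML file.
#' @return A validated list of class `run_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  unknown_blocks <- setdiff(names(raw), names(config_defaults))
  if (length(unknown_blocks)) {
    stop("unknown config block(s): ", paste(unknown_blocks, collapse = ", "),
         call. = FALSE)
  }
  cfg <- config_defaults
  for (blk in names(raw)) {
    unknown <- setdiff(names(raw[[blk]]), names(config_defaults[[blk]]))
    if (length(unknown)) {
      stop("unknown key(s) in '", blk, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    cfg[[blk]][names(raw[[blk]])] <- raw[[blk]]
  }
  d <- cfg$design
  if (round(sqrt(d$M))^2 != d$M) {
    stop("design$M must be a perfect square", call. = FALSE)
  }
  if (d$q < 1 || d$q > d$m) stop("design$q must be in 1..m", call. = FALSE)
  s <- cfg$simulation
  if (s$sweeps < 0) stop("simulation$sweeps must be >= 0", call. = FALSE)
  if (s$epsilon < 0 || s$lambda < 0) {
    stop("epsilon and lambda must be >= 0", call. = FALSE)
  }
  if (!is.null(s$seed_side) && s$seed_side > round(sqrt(d$M))) {
    stop("seed_side exceeds the pattern side", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Write the outputs of a finished run
#'
#' Writes into `outdir`: the trajectory CSV, the final lattice snapshot and
#' its structure colouring as integer-matrix text, the resolved
#' configuration as JSON and a manifest with MD5 content hashes.  Rerunning
#' the same configuration and seed reproduces the files byte for byte.
#'
#' @param result An `observable_series` from [run_simulation()].
#' @param patterns,rt The design objects (for colouring).
#' @param config The resolved configuration to archive (any list).
#' @param outdir Output directory, created if needed.
#' @return The manifest (named list of file MD5 hashes), invisibly.
#' @export
write_outputs <- function(result, patterns, rt, config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    trajectory = file.path(outdir, "trajectory.csv"),
    snapshot = file.path(outdir, "snapshot.txt"),
    colours = file.path(outdir, "colours.txt"),
    config = file.path(outdir, "config.json")
  )
  utils::write.csv(result$series, paths[["trajectory"]], row.names = FALSE)
  utils::write.table(result$final_state$sigma, paths[["snapshot"]],
                     row.names = FALSE, col.names = FALSE)
  cols <- colour_configuration(result$final_state, rt, patterns,
                               rng_seed = result$params$rng_seed)
  utils::write.table(cols, paths[["colours"]],
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(config, paths[["config"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  hashes <- tools::md5sum(paths)
  manifest <- as.list(stats::setNames(unname(hashes), names(paths)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Deterministic miniature designs with precomputed expectations
#'
#' Fixtures used across the test suite:
#' * `toy_2x2`: one 2 x 2 structure (4 oriented reciprocal bonds);
#' * `toy_3x3_shift`: two 3 x 3 structures with one transition (24 directed
#'   non-reciprocal entries);
#' * `mid_20x20`: two 20 x 20 structures (760 reciprocal bonds per
#'   structure before union).
#'
#' @param kind One of `"toy_2x2"`, `"toy_3x3_shift"`, `"mid_20x20"`.
#' @param seed Pattern seed.
#' @param epsilon,lam Couplings for the compiled tables.
#' @return A list with `patterns`, `rt`, `nt` and `expected` (entry-count
#'   expectations and, for the toys, the brute-force energy of the complete
#'   first structure placed centred on an otherwise empty lattice).
#' @export
make_fixture <- function(kind, seed = 1L, epsilon = 1, lam = 1) {
  spec <- switch(kind,
    toy_2x2 = list(m = 1L, M = 4L, q = 1L),
    toy_3x3_shift = list(m = 2L, M = 9L, q = 2L),
    mid_20x20 = list(m = 2L, M = 400L, q = 2L),
    stop("unknown fixture kind: ", kind, call. = FALSE)
  )
  tp <- generate_patterns(spec$m, spec$M, spec$q, rng_seed = seed)
  rt <- build_reciprocal_table(tp, epsilon)
  nt <- build_nonreciprocal_table(tp, lam)
  side <- tp$side
  expected <- list(
    recip_per_pattern = 2L * side * (side - 1L),
    nonrecip_per_transition = if (spec$q >= 2L) 4L * side * (side - 1L)
                              else 0L
  )
  pars <- sim_params(epsilon, mu = -1, lam = lam, sweeps = 0,
                     seed_side = side)
  st <- init_state(tp, pars)
  expected$full_seed_energy <- total_energy(st, rt, -1)
  list(patterns = tp, rt = rt, nt = nt, expected = expected)
}
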