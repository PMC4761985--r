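# End-to-end pipeline: a declarative run configuration tying together
# structure input (real chain lists + PDB directory, or the synthetic
# generator), pair extraction, polar conversion, density maps, counts and
# a JSON run report. All defaults mirror the survey's printed parameters
# (5 A extraction cutoff, 6 A closest-atom cutoff, first-4000 subsample),
# so a bare run on real data reproduces the published protocol.

#' Build a run configuration
#'
#' @param mode `"real"` (chain list + directory of PDB files) or
#'   `"synthetic"` (a [population_spec()]).
#' @param chain_list Path to (or text of) a Pisces-style chain list
#'   (real mode).
#' @param pdb_dir Directory containing `<pdbid>.pdb` files (real mode).
#' @param population A [population_spec()] (synthetic mode).
#' @param cutoff Pair-extraction cutoff in Angstrom (default 5).
#' @param polar_cutoff Closest-atom polar cutoff in Angstrom (default 6).
#' @param shells Named list of shell definitions, each
#'   `list(selector, d_min, d_max)`.
#' @param frames Frame registry (default [default_frames()]).
#' @param subsample_max,subsample_policy Subsampling of pairs entering the
#'   polar/density stages (defaults: 4000, `"first"`).
#' @param seed Seed for any randomised stage (random subsampling).
#' @param out_dir Output directory (`NULL` = keep results in memory only).
#' @param symmetrize_nh,exclude_seq_window,distance_mode Passed to
#'   [extract_pairs()].
#' @param psi_bin,theta_bin,solid_angle_weighting Passed to
#'   [build_density()].
#' @return Object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "real"), chain_list = NULL,
                       pdb_dir = NULL, population = NULL, cutoff = 5,
                       polar_cutoff = 6, shells = NULL,
                       frames = default_frames(), subsample_max = 4000,
                       subsample_policy = "first", seed = 1L,
                       out_dir = NULL, symmetrize_nh = FALSE,
                       exclude_seq_window = 0,
                       distance_mode = "defining", psi_bin = 5,
                       theta_bin = 5, solid_angle_weighting = FALSE) {
  mode <- match.arg(mode)
  if (cutoff <= 0 || polar_cutoff <= 0)
    stop("cutoffs must be positive", call. = FALSE)
  if (subsample_max <= 0) stop("subsample_max must be positive", call. = FALSE)
  if (mode == "real" && (is.null(chain_list) || is.null(pdb_dir)))
    stop("real mode needs chain_list and pdb_dir", call. = FALSE)
  if (mode == "synthetic" && !inherits(population, "population_spec"))
    stop("synthetic mode needs a population_spec", call. = FALSE)
  structure(list(mode = mode, chain_list = chain_list, pdb_dir = pdb_dir,
                 population = population, cutoff = cutoff,
                 polar_cutoff = polar_cutoff, shells = shells,
                 frames = frames, subsample_max = subsample_max,
                 subsample_policy = subsample_policy, seed = as.integer(seed),
                 out_dir = out_dir, symmetrize_nh = symmetrize_nh,
                 exclude_seq_window = exclude_seq_window,
                 distance_mode = distance_mode, psi_bin = psi_bin,
                 theta_bin = theta_bin,
                 solid_angle_weighting = solid_angle_weighting),
            class = "run_config")
}

# Resolve the input structures of a config to a list of
# list(pdb_id, chain_id, residues).
resolve_structures <- function(config) {
  if (config$mode == "synthetic") {
    pop <- generate_population(config$population)
    # in-memory residues: full double precision, not limited by the
    # 3-decimal fixed-width coordinates of the PDB text fixtures
    structs <- lapply(seq_along(pop$residues), function(i)
      list(pdb_id = sprintf("sy%04d", i), chain_id = "A",
           residues = pop$residues[[i]]))
    attr(structs, "ledger") <- pop$ledger
    return(structs)
  }
  recs <- parse_chain_list(config$chain_list)
  structs <- list()
  failures <- character(0)
  for (i in seq_len(nrow(recs))) {
    id <- recs$pdb_id[i]; ch <- recs$chain_id[i]
    path <- c(file.path(config$pdb_dir, paste0(id, ".pdb")),
              file.path(config$pdb_dir, paste0("pdb", id, ".ent")))
    path <- path[file.exists(path)][1]
    if (is.na(path)) {
      failures <- c(failures, sprintf("%s%s:file_not_found", id, ch))
      next
    }
    res <- tryCatch(load_chain(path, ch), error = function(e) {
      failures <<- c(failures, sprintf("%s%s:%s", id, ch,
                                       conditionMessage(e)))
      NULL
    })
    if (!is.null(res))
      structs[[length(structs) + 1L]] <- list(pdb_id = id, chain_id = ch,
                                              residues = res)
  }
  attr(structs, "failures") <- failures
  structs
}

#' Run the pair-extraction stage
#'
#' Loads every input structure, extracts canonical-frame interaction pairs,
#' writes per-pair files and the count table when an output directory is
#' configured, and assembles a run report accounting for every structure
#' and skipped residue.
#'
#' @param config A [run_config()].
#' @return List with `pairs` (list of `sc_pair`), `counts`
#'   ([count_interactions()] table), `report` (list; written as
#'   `run_report.json` when `out_dir` is set) and, in synthetic mode,
#'   `ledger` (the generator's ground truth).
#' @export
run_extract <- function(config) {
  stopifnot(inherits(config, "run_config"))
  structs <- resolve_structures(config)
  pairs <- list()
  per_struct <- list()
  for (s in structs) {
    ps <- extract_pairs(s$residues, frames = config$frames,
                        cutoff = config$cutoff,
                        distance_mode = config$distance_mode,
                        exclude_seq_window = config$exclude_seq_window,
                        symmetrize_nh = config$symmetrize_nh,
                        pdb_id = s$pdb_id, chain_id = s$chain_id)
    rep <- attr(ps, "report")
    per_struct[[length(per_struct) + 1L]] <-
      c(list(pdb_id = s$pdb_id, chain_id = s$chain_id), rep)
    pairs <- c(pairs, ps)
  }
  counts <- count_interactions(pairs)
  report <- list(
    mode = config$mode,
    n_structures = length(structs),
    n_structures_failed = length(attr(structs, "failures")),
    failures = attr(structs, "failures"),
    n_central = sum(vapply(per_struct, `[[`, 0L, "n_central")),
    n_skipped = sum(lengths(lapply(per_struct, `[[`, "skipped"))),
    n_pairs = length(pairs),
    cutoff = config$cutoff,
    per_structure = per_struct
  )
  if (!is.null(config$out_dir)) {
    dir.create(file.path(config$out_dir, "pairs"), showWarnings = FALSE,
               recursive = TRUE)
    for (p in pairs)
      write_pair_file(p, file.path(config$out_dir, "pairs",
                                   pair_file_name(p)))
    utils::write.table(counts, file.path(config$out_dir, "counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report,
                         file.path(config$out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out <- list(pairs = pairs, counts = counts, report = report)
  if (config$mode == "synthetic") out$ledger <- attr(structs, "ledger")
  out
}

#' Run the polar stage
#'
#' Subsamples the extracted pairs per the configured policy and applies the
#' closest-atom rule to each.
#'
#' @param config A [run_config()].
#' @param extraction Optional result of [run_extract()] to reuse.
#' @return List with `points` (polar-point table, written to
#'   `polar_points.csv` under `out_dir`), `subsample` record and the
#'   extraction result.
#' @export
run_polar <- function(config, extraction = NULL) {
  if (is.null(extraction)) extraction <- run_extract(config)
  kept <- subsample_pairs(extraction$pairs, max_n = config$subsample_max,
                          policy = config$subsample_policy,
                          seed = config$seed)
  pts <- polar_points(kept, cutoff = config$polar_cutoff,
                      frames = config$frames)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(pts, file.path(config$out_dir, "polar_points.csv"),
                     row.names = FALSE)
  }
  list(points = pts, subsample = attr(kept, "subsample"),
       extraction = extraction)
}

#' Run the density stage
#'
#' @param config A [run_config()].
#' @param polar Optional result of [run_polar()] to reuse.
#' @return List with `map` (a [build_density()] grid, written to
#'   `density.csv` under `out_dir`) and the polar result.
#' @export
run_density <- function(config, polar = NULL) {
  if (is.null(polar)) polar <- run_polar(config)
  map <- build_density(polar$points, psi_bin = config$psi_bin,
                       theta_bin = config$theta_bin,
                       solid_angle_weighting = config$solid_angle_weighting)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(map),
                     file.path(config$out_dir, "density.csv"),
                     row.names = FALSE)
  }
  list(map = map, polar = polar)
}

#' Run the counts stage
#'
#' @param config A [run_config()].
#' @param extraction Optional result of [run_extract()] to reuse.
#' @return The count table (written to `counts.tsv` under `out_dir`).
#' @export
run_counts <- function(config, extraction = NULL) {
  if (is.null(extraction)) extraction <- run_extract(config)
  counts <- extraction$counts
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(counts, file.path(config$out_dir, "counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  counts
}

#' Generate synthetic fixtures from a configuration
#'
#' @param config A [run_config()] in synthetic mode.
#' @return The [generate_population()] result; files, ledger and spec echo
#'   are written when `out_dir` is set.
#' @export
run_synth <- function(config) {
  stopifnot(inherits(config, "run_config"), config$mode == "synthetic")
  generate_population(config$population,
                      out_dir = if (is.null(config$out_dir)) NULL
                                else file.path(config$out_dir, "synth"))
}
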