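# Pair extraction: every central Arg/Lys against every neighbouring
# non-glycine residue whose side chain comes within the cutoff of the
# central defining-atom set, both returned in the canonical frame.

#' Construct an interaction pair
#'
#' @param central,neighbor Canonical-frame `sc_residue` objects.
#' @param min_dist Minimum distance (Angstrom) between the neighbour's
#'   side-chain heavy atoms and the central defining-atom set.
#' @param pdb_id,chain_id Provenance.
#' @return Object of class `sc_pair`.
#' @export
interaction_pair <- function(central, neighbor, min_dist,
                             pdb_id = "xxxx", chain_id = "A") {
  structure(list(central = central, neighbor = neighbor,
                 min_dist = min_dist, pdb_id = pdb_id, chain_id = chain_id),
            class = "sc_pair")
}

#' @export
print.sc_pair <- function(x, ...) {
  cat(sprintf("<pair %s_%s %s%d - %s%d  min_dist %.3f A>\n", x$pdb_id,
              x$chain_id, x$central$res_type, x$central$seq_num,
              x$neighbor$res_type, x$neighbor$seq_num, x$min_dist))
  invisible(x)
}

# Defining-atom coordinates of a residue under a frame (present atoms only).
defining_xyz <- function(res, frame) {
  residue_xyz(res, frame$defining_atoms, partial = TRUE)
}

#' Extract canonical-frame interaction pairs from one chain
#'
#' For every central residue with a registered frame (by default Arg and
#' Lys), finds all other standard non-glycine residues whose side-chain
#' heavy atoms come within `cutoff` of the central defining-atom set (Arg:
#' NE, CZ, NH1, NH2; Lys: CD, CE, NZ), and returns one canonical-frame pair
#' per (central, neighbour) combination. Centrals missing an anchor atom
#' and neighbours without side-chain heavy atoms are skipped; skip reasons
#' are tallied in the `"report"` attribute.
#'
#' @param residues List of `sc_residue` (one chain, e.g. from
#'   [load_chain()]).
#' @param frames Named list of [frame_definition()] keyed by residue type.
#' @param cutoff Contact cutoff in Angstrom (default 5).
#' @param distance_mode `"defining"` measures neighbour distances to the
#'   defining-atom set (default); `"all_sidechain"` to every central
#'   side-chain heavy atom.
#' @param exclude_seq_window Exclude neighbours with `|seq_num difference|
#'   <= k` (default 0: sequence-adjacent residues are included).
#' @param symmetrize_nh For Arg centrals, additionally emit each pair
#'   rotated half a turn about the CZ-NE axis (equivalent to exchanging the
#'   NH1/NH2 labels), for label-free densities. Off by default because
#'   NH1-specific signal is part of the analysis.
#' @param method Kabsch variant passed to [to_canonical_frame()].
#' @param pdb_id,chain_id Provenance stored on each pair.
#' @return List of `sc_pair`, with attribute `"report"` (centrals seen,
#'   centrals skipped with reasons, neighbours considered).
#' @export
extract_pairs <- function(residues, frames = default_frames(), cutoff = 5,
                          distance_mode = c("defining", "all_sidechain"),
                          exclude_seq_window = 0, symmetrize_nh = FALSE,
                          method = "pinned",
                          pdb_id = "xxxx", chain_id = "A") {
  distance_mode <- match.arg(distance_mode)
  stopifnot(cutoff > 0)
  pairs <- list()
  skips <- character(0)
  n_central <- 0L
  # bounding spheres over side-chain atoms for cheap residue-level pruning
  sc_list <- lapply(residues, function(r) residue_xyz(sidechain(r)))
  centers <- t(vapply(sc_list, function(m)
    if (nrow(m)) colMeans(m) else c(NA_real_, NA_real_, NA_real_),
    numeric(3)))
  radii <- vapply(seq_along(sc_list), function(i) {
    m <- sc_list[[i]]
    if (!nrow(m)) return(0)
    sqrt(max(rowSums(sweep(m, 2, centers[i, ])^2)))
  }, numeric(1))
  for (i in seq_along(residues)) {
    central <- residues[[i]]
    frame <- frames[[central$res_type]]
    if (is.null(frame)) next
    n_central <- n_central + 1L
    D <- if (distance_mode == "defining") defining_xyz(central, frame)
         else sc_list[[i]]
    need <- if (distance_mode == "defining") frame$defining_atoms
            else frame$anchor_atoms
    if (nrow(D) < length(frame$defining_atoms) && distance_mode == "defining" ||
        !all(frame$anchor_atoms %in% central$atoms$name)) {
      skips <- c(skips, sprintf("%s%d:missing_anchor_or_defining_atom",
                                central$res_type, central$seq_num))
      next
    }
    Dc <- colMeans(D)
    Dr <- sqrt(max(rowSums(sweep(D, 2, Dc)^2)))
    hits <- list()
    for (j in seq_along(residues)) {
      if (j == i) next
      nb <- residues[[j]]
      if (nb$res_type == "GLY") next
      if (exclude_seq_window > 0 &&
          abs(nb$seq_num - central$seq_num) <= exclude_seq_window) next
      S <- sc_list[[j]]
      if (!nrow(S)) next
      # bounding-sphere prune, then exact distances
      if (sqrt(sum((centers[j, ] - Dc)^2)) - radii[j] - Dr > cutoff) next
      d <- min_dist(S, D)
      if (d <= cutoff) hits[[length(hits) + 1L]] <- list(res = nb, d = d)
    }
    if (!length(hits)) next
    can <- tryCatch(
      to_canonical_frame(central, lapply(hits, `[[`, "res"), frame,
                         method = method),
      scpolar_missing_anchor = function(e) {
        skips <<- c(skips, sprintf("%s%d:missing_anchor", central$res_type,
                                   central$seq_num))
        NULL
      })
    if (is.null(can)) next
    for (k in seq_along(hits)) {
      p <- interaction_pair(can$central, can$neighbors[[k]], hits[[k]]$d,
                            pdb_id = pdb_id, chain_id = chain_id)
      pairs[[length(pairs) + 1L]] <- p
      if (symmetrize_nh && central$res_type == "ARG")
        pairs[[length(pairs) + 1L]] <- swap_nh_labels(p)
    }
  }
  attr(pairs, "report") <- list(n_residues = length(residues),
                                n_central = n_central,
                                n_pairs = length(pairs),
                                skipped = skips)
  pairs
}

# Rotate a pair half a turn about x (y -> -y, z -> -z) and exchange the
# NH1/NH2 labels: the canonical pose that would result from aligning the
# anchors (CZ, NH2, NH1) instead.
swap_nh_labels <- function(pair) {
  flip <- function(res) {
    res$atoms$y <- -res$atoms$y
    res$atoms$z <- -res$atoms$z
    nm <- res$atoms$name
    res$atoms$name[nm == "NH1"] <- "NH2_"
    res$atoms$name[nm == "NH2"] <- "NH1"
    res$atoms$name[res$atoms$name == "NH2_"] <- "NH2"
    res
  }
  pair$central <- flip(pair$central)
  pair$neighbor$atoms$y <- -pair$neighbor$atoms$y
  pair$neighbor$atoms$z <- -pair$neighbor$atoms$z
  pair
}

#' Tally interaction counts by residue-type pair
#'
#' @param pairs List of `sc_pair` from one run.
#' @return `data.frame` with columns `central_type`, `neighbor_type`,
#'   `n_pairs`, covering every (ARG/LYS x 19 non-glycine) cell (zeros
#'   included); marginal totals per central type are in the `"totals"`
#'   attribute and the grand total in `"total"`.
#' @export
count_interactions <- function(pairs) {
  tab <- expand.grid(central_type = c("ARG", "LYS"),
                     neighbor_type = NONGLY_AA,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab <- tab[order(tab$central_type, tab$neighbor_type), ]
  rownames(tab) <- NULL
  key <- paste(tab$central_type, tab$neighbor_type)
  cnt <- setNames(integer(length(key)), key)
  for (p in pairs) {
    k <- paste(p$central$res_type, p$neighbor$res_type)
    if (!k %in% key)
      stop("unexpected residue-type pair: ", k, call. = FALSE)
    cnt[k] <- cnt[k] + 1L
  }
  tab$n_pairs <- as.integer(cnt)
  attr(tab, "totals") <- tapply(tab$n_pairs, tab$central_type, sum)
  attr(tab, "total") <- sum(tab$n_pairs)
  tab
}
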