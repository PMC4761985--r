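# Independent oracles and fixture builders used across the suite.

# Brute-force all-pairs scan: plain double loops over atoms, no pruning,
# no shared code with extract_pairs. Returns central seq, neighbour seq
# and the minimum neighbour-side-chain-to-defining-set distance.
brute_force_pairs <- function(residues, cutoff = 5,
                              frames = default_frames()) {
  out <- list()
  for (i in seq_along(residues)) {
    central <- residues[[i]]
    frame <- frames[[central$res_type]]
    if (is.null(frame)) next
    if (!all(frame$anchor_atoms %in% central$atoms$name)) next
    if (!all(frame$defining_atoms %in% central$atoms$name)) next
    D <- residue_xyz(central, frame$defining_atoms)
    for (j in seq_along(residues)) {
      if (i == j) next
      nb <- residues[[j]]
      if (nb$res_type == "GLY") next
      S <- residue_xyz(sidechain(nb))
      if (!nrow(S)) next
      best <- Inf
      for (a in seq_len(nrow(S))) for (b in seq_len(nrow(D))) {
        d <- sqrt(sum((S[a, ] - D[b, ])^2))
        if (d < best) best <- d
      }
      if (best <= cutoff)
        out[[length(out) + 1L]] <- data.frame(
          central_seq = central$seq_num, neighbor_seq = nb$seq_num,
          min_dist = best)
    }
  }
  if (!length(out))
    return(data.frame(central_seq = integer(0), neighbor_seq = integer(0),
                      min_dist = numeric(0)))
  df <- do.call(rbind, out)
  df[order(df$central_seq, df$neighbor_seq), ]
}

# Pair list -> comparable data frame, same ordering as the oracle.
pairs_to_df <- function(pairs) {
  if (!length(pairs))
    return(data.frame(central_seq = integer(0), neighbor_seq = integer(0),
                      min_dist = numeric(0)))
  df <- do.call(rbind, lapply(pairs, function(p) data.frame(
    central_seq = p$central$seq_num, neighbor_seq = p$neighbor$seq_num,
    min_dist = p$min_dist)))
  df <- df[order(df$central_seq, df$neighbor_seq), ]
  rownames(df) <- NULL
  df
}

# Random multi-residue structure with one Arg or Lys central and `n_nb`
# neighbour residues whose side-chain atoms are scattered at random in a
# shell around the origin (some inside, some outside the cutoff). Built
# directly from new_residue so it shares nothing with the generator's
# planted-placement logic.
random_structure <- function(seed, n_nb = 8) {
  set.seed(seed)
  central_type <- sample(c("ARG", "LYS"), 1)
  central <- build_ideal_residue(central_type, seq_num = 1L)
  types <- sample(setdiff(names(SIDECHAIN_ATOM_NAMES),
                          c("GLY", "ALA")), n_nb, replace = TRUE)
  res <- list(central)
  for (k in seq_len(n_nb)) {
    nms <- SIDECHAIN_ATOM_NAMES[[types[k]]]
    n_at <- sample(seq_along(nms), 1)
    nms <- nms[seq_len(n_at)]
    centre <- stats::runif(3, -8, 8)
    xyz <- sweep(matrix(stats::rnorm(3 * n_at, 0, 0.8), ncol = 3), 2,
                 centre, "+")
    res[[k + 1]] <- new_residue(types[k],
      data.frame(name = nms, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 stringsAsFactors = FALSE),
      seq_num = k + 2L)
  }
  # random overall pose so structures are not axis-aligned
  tr <- random_rigid_transform(seed + 7919L)
  lapply(res, function(r) apply_transform(tr, r))
}

# Minimal hand-written PDB text: a single arginine with full backbone,
# used for reader tests (independent of the package's writer).
single_arg_pdb <- function() {
  atoms <- list(
    list("N",   c(27.340, 24.430, 2.614)),
    list("CA",  c(26.266, 25.413, 2.842)),
    list("C",   c(26.913, 26.639, 3.531)),
    list("O",   c(27.886, 26.463, 4.263)),
    list("CB",  c(25.112, 24.880, 3.649)),
    list("CG",  c(23.856, 25.737, 3.404)),
    list("CD",  c(22.654, 25.112, 4.059)),
    list("NE",  c(21.422, 25.809, 3.702)),
    list("CZ",  c(20.211, 25.472, 4.108)),
    list("NH1", c(19.995, 24.412, 4.871)),
    list("NH2", c(19.182, 26.219, 3.745)))
  c(
    "HEADER    TEST STRUCTURE",
    vapply(seq_along(atoms), function(i)
      sprintf("ATOM  %5d %s ARG A   2    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
              i,
              if (nchar(atoms[[i]][[1]]) < 4)
                sprintf(" %-3s", atoms[[i]][[1]])
              else sprintf("%-4s", atoms[[i]][[1]]),
              atoms[[i]][[2]][1], atoms[[i]][[2]][2], atoms[[i]][[2]][3],
              1, 0, substr(atoms[[i]][[1]], 1, 1)), character(1)),
    "TER", "END")
}
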