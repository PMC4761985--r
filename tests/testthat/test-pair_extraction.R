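test_that("single planted neighbours are found exactly at the cutoff rule", {
  # Leu CD1 4.0 A from CZ (psi toward +x keeps it 4.0 from the defining set
  # minimum as verified by the brute-force oracle)
  pp <- plant_pair("ARG", "LEU", "CD1", r = 4, theta = 0, psi = 0,
                   pose_seed = 2L)
  pairs <- extract_pairs(pp$residues)
  oracle <- brute_force_pairs(pp$residues)
  expect_length(pairs, 1L)
  expect_equal(pairs_to_df(pairs), oracle, tolerance = 1e-12)
  expect_equal(pairs[[1]]$min_dist, 4, tolerance = 1e-9)

  # closest side-chain atom beyond the cutoff -> no pair
  far <- plant_pair("ARG", "LEU", "CD1", r = 5.5, theta = 0, psi = 0,
                    pose_seed = 2L)
  expect_length(extract_pairs(far$residues), 0L)
  expect_equal(nrow(brute_force_pairs(far$residues)), 0L)
})

test_that("glycine is never a neighbour", {
  pp <- plant_pair("ARG", "LEU", "CD1", r = 6.5, theta = 0, psi = 0,
                   pose_seed = 4L)
  central <- pp$residues[[1]]
  gly <- new_residue("GLY", data.frame(
    name = c("N", "CA", "C", "O"),
    x = c(3, 3.8, 4.5, 5.5), y = c(0, 0.8, 0, 0.5), z = c(0, 0, 0, 0)),
    seq_num = 9L)
  gly <- apply_transform(random_rigid_transform(1L), gly)
  central2 <- apply_transform(random_rigid_transform(1L), central)
  expect_length(extract_pairs(list(central2, gly)), 0L)
})

test_that("extract_pairs matches the brute-force oracle on random structures", {
  for (seed in 1:20) {
    res <- random_structure(seed)
    got <- pairs_to_df(extract_pairs(res))
    want <- brute_force_pairs(res)
    expect_equal(got$central_seq, want$central_seq)
    expect_equal(got$neighbor_seq, want$neighbor_seq)
    expect_equal(got$min_dist, want$min_dist, tolerance = 1e-9)
  }
})

test_that("pair sets are monotone in the cutoff", {
  res <- random_structure(77)
  key <- function(ps) vapply(ps, function(p)
    paste(p$central$seq_num, p$neighbor$seq_num), character(1))
  p4 <- key(extract_pairs(res, cutoff = 4))
  p5 <- key(extract_pairs(res, cutoff = 5))
  p8 <- key(extract_pairs(res, cutoff = 8))
  expect_true(all(p4 %in% p5))
  expect_true(all(p5 %in% p8))
})

test_that("extraction is pose invariant", {
  res <- random_structure(31)
  base <- extract_pairs(res)
  tr <- random_rigid_transform(404L)
  moved <- extract_pairs(lapply(res, function(r) apply_transform(tr, r)))
  expect_length(moved, length(base))
  for (k in seq_along(base)) {
    expect_equal(moved[[k]]$min_dist, base[[k]]$min_dist, tolerance = 1e-6)
    expect_lt(max(abs(residue_xyz(moved[[k]]$neighbor) -
                        residue_xyz(base[[k]]$neighbor))), 1e-6)
  }
})

test_that("sequence-window exclusion and NH symmetrization are optional", {
  pp <- plant_pair("ARG", "LEU", "CD1", r = 4, theta = 30, psi = 10,
                   pose_seed = 6L)
  # neighbour is seq 3, central seq 1: |delta| = 2
  expect_length(extract_pairs(pp$residues, exclude_seq_window = 2), 0L)
  expect_length(extract_pairs(pp$residues, exclude_seq_window = 1), 1L)

  sym <- extract_pairs(pp$residues, symmetrize_nh = TRUE)
  expect_length(sym, 2L)
  a <- closest_atom_polar(sym[[1]])
  b <- closest_atom_polar(sym[[2]])
  expect_equal(b$theta, 180 - a$theta, tolerance = 1e-9)
  expect_equal(b$psi, -a$psi, tolerance = 1e-9)
  # mirrored central still has NH1 at +y
  expect_gt(residue_xyz(sym[[2]]$central, "NH1")[1, 2], 0)
})

test_that("count tables tally exhaustively with marginals", {
  empty <- count_interactions(list())
  expect_equal(nrow(empty), 2 * 19)
  expect_true(all(empty$n_pairs == 0))
  expect_equal(attr(empty, "total"), 0L)

  mk <- function(ct, nt) {
    pp <- plant_pair(ct, nt, SIDECHAIN_ATOM_NAMES[[nt]][2], r = 4,
                     theta = 45, psi = 90, pose_seed = 1L)
    extract_pairs(pp$residues)[[1]]
  }
  pairs <- c(replicate(3, mk("ARG", "LEU"), simplify = FALSE),
             replicate(2, mk("LYS", "ASP"), simplify = FALSE))
  tab <- count_interactions(pairs)
  expect_equal(tab$n_pairs[tab$central_type == "ARG" &
                             tab$neighbor_type == "LEU"], 3L)
  expect_equal(tab$n_pairs[tab$central_type == "LYS" &
                             tab$neighbor_type == "ASP"], 2L)
  expect_equal(attr(tab, "total"), 5L)
  expect_equal(unname(attr(tab, "totals")["ARG"]), 3L)
})

test_that("counts on a seeded population equal the generator ledger", {
  spec <- population_spec(60, seed = 5L, mixture = list(
    list(weight = 0.5, type = "axial", neighbor_type = "LEU",
         contact_atom = "CD1"),
    list(weight = 0.3, type = "uniform", neighbor_type = "TRP",
         contact_atom = "NE1"),
    list(weight = 0.2, type = "equatorial", neighbor_type = "ASP",
         contact_atom = "OD1")))
  ex <- run_extract(run_config(mode = "synthetic", population = spec))
  tab <- ex$counts
  led <- table(ex$ledger$neighbor_type)
  for (nt in names(led))
    expect_equal(tab$n_pairs[tab$central_type == "ARG" &
                               tab$neighbor_type == nt],
                 as.integer(led[[nt]]))
  expect_equal(attr(tab, "total"), 60L)
})
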