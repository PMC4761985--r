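# Synthetic structure generator: ideal central residues under random rigid
# poses with neighbour side chains planted at controlled (r, theta, psi) in
# the canonical frame, so every pipeline stage is testable against a known
# ground truth without downloading structures.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Seeded random rigid-body transform
#'
#' Rotation uniform over SO(3) (normalized quaternion of four standard
#' normals) and translation uniform in a cube of half-width `box` Angstrom.
#'
#' @param seed Integer seed.
#' @param box Translation half-width in Angstrom (default 10, i.e. a 20
#'   Angstrom box).
#' @return A [rigid_transform()].
#' @export
random_rigid_transform <- function(seed, box = 10) {
  with_seed(seed, {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    R <- rbind(
      c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
      c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
      c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
    rigid_transform(R, stats::runif(3, -box, box))
  })
}

# Idealized planar templates for the two central residue types. The anchor
# atoms sit exactly at reference_coords * bond_scale; the remaining side
# chain and backbone follow a fixed idealized (planar, z = 0) geometry that
# only needs to be rigid and sterically sane - rotamer realism is not the
# point of the generator.
ideal_template <- function(res_type, bond_scale) {
  if (res_type == "ARG") {
    s <- if (is.null(bond_scale)) 1.33 else bond_scale
    anchors <- rbind(CZ = c(0, 0, 0), NH1 = c(0.5, 0.87, 0),
                     NH2 = c(0.5, -0.87, 0)) * s
    rest <- rbind(NE = c(-1.33, 0, 0), CD = c(-2.20, 1.20, 0),
                  CG = c(-3.70, 1.20, 0), CB = c(-4.57, 2.40, 0),
                  CA = c(-6.07, 2.40, 0), N = c(-6.94, 3.60, 0),
                  C = c(-6.94, 1.20, 0), O = c(-8.17, 1.20, 0))
  } else if (res_type == "LYS") {
    s <- if (is.null(bond_scale)) 1.0 else bond_scale
    anchors <- rbind(NZ = c(0, 0, 0), CE = c(-1, 0, 0),
                     CD = c(-1.34, 0.94, 0)) * s
    rest <- rbind(CG = c(-2.84, 0.94, 0), CB = c(-3.71, 2.14, 0),
                  CA = c(-5.21, 2.14, 0), N = c(-6.08, 3.34, 0),
                  C = c(-6.08, 0.94, 0), O = c(-7.31, 0.94, 0))
  } else {
    stop("no ideal template for residue type: ", res_type, call. = FALSE)
  }
  rbind(anchors, rest)
}

#' Build an idealized central residue in canonical pose
#'
#' The anchor atoms equal the frame's reference coordinates scaled by
#' `bond_scale` (default 1.33 for Arg, giving guanidinium C-N bonds of
#' ~1.33 Angstrom; 1.0 for Lys, the printed reference scale); the remaining
#' atoms follow a fixed idealized planar geometry. By construction,
#' [to_canonical_frame()] of the result is the identity transform.
#'
#' @param res_type `"ARG"` or `"LYS"`.
#' @param bond_scale Anchor scale factor (`NULL` for the per-type default).
#' @param chain_id,seq_num Identity given to the residue.
#' @param include_backbone Include idealized N, CA, C, O atoms.
#' @return An `sc_residue` in canonical pose.
#' @export
build_ideal_residue <- function(res_type, bond_scale = NULL, chain_id = "A",
                                seq_num = 1L, include_backbone = TRUE) {
  res_type <- toupper(res_type)
  m <- ideal_template(res_type, bond_scale)
  if (!include_backbone) m <- m[!rownames(m) %in% BACKBONE_ATOMS, , drop = FALSE]
  new_residue(res_type,
              data.frame(name = rownames(m), x = m[, 1], y = m[, 2],
                         z = m[, 3], stringsAsFactors = FALSE),
              chain_id = chain_id, seq_num = seq_num)
}

# Place a neighbour residue whose `contact_atom` sits at canonical point
# `c0`, remaining atoms strung outward (away from the defining-set
# centroid) at 1.55 A spacing so the contact atom is strictly the closest.
place_neighbor <- function(neighbor_type, contact_atom, c0, defining,
                           chain_id = "A", seq_num = 3L) {
  names_sc <- SIDECHAIN_ATOM_NAMES[[neighbor_type]]
  if (is.null(names_sc) || !length(names_sc))
    stop("neighbour type has no side-chain atoms: ", neighbor_type,
         call. = FALSE)
  if (!contact_atom %in% names_sc)
    stop("contact atom ", contact_atom, " is not a side-chain atom of ",
         neighbor_type, call. = FALSE)
  g <- colMeans(defining)
  u <- c0 - g
  u <- u / sqrt(sum(u^2))
  others <- c(setdiff(names_sc, contact_atom), "CA", "N", "C", "O")
  coords <- matrix(NA_real_, length(others) + 1, 3,
                   dimnames = list(c(contact_atom, others), NULL))
  coords[1, ] <- c0
  for (k in seq_along(others))
    coords[k + 1, ] <- c0 + 1.55 * k * u
  new_residue(neighbor_type,
              data.frame(name = rownames(coords), x = coords[, 1],
                         y = coords[, 2], z = coords[, 3],
                         stringsAsFactors = FALSE),
              chain_id = chain_id, seq_num = seq_num)
}

#' Plant a single interaction pair with known ground truth
#'
#' Builds an ideal central residue, places a neighbour whose contact atom
#' sits at the requested canonical-frame spherical-polar position (all its
#' other atoms strictly farther from the defining set), optionally adds
#' isotropic Gaussian coordinate noise, and finally moves the whole
#' assembly by a seeded random rigid pose. The returned ground truth
#' records both the planted values and the realized (post-jitter)
#' closest-atom geometry.
#'
#' @param central_type `"ARG"` or `"LYS"`.
#' @param neighbor_type Neighbour residue type (non-glycine).
#' @param contact_atom Neighbour side-chain atom planted at the target.
#' @param r,theta,psi Target canonical polar coordinates (Angstrom,
#'   degrees); `r` must place the contact atom at least 1.5 Angstrom from
#'   every central atom or a steric error is raised.
#' @param pose_seed Seed for the random rigid pose.
#' @param jitter_sd Isotropic Gaussian noise SD in Angstrom (default 0).
#' @param frames Frame registry.
#' @param pdb_id Identifier written into the ground truth.
#' @return List with `pdb` (PDB-format text lines, coordinates at the
#'   format's 3-decimal precision), `residues` (the posed central and
#'   neighbour residues at full double precision) and `truth` (one-row
#'   `data.frame`: planted r/theta/psi, realized r/theta/psi of the contact
#'   atom, realized `min_dist`, types, atom, pose seed).
#' @export
plant_pair <- function(central_type = "ARG", neighbor_type = "LEU",
                       contact_atom = "CD1", r = 4, theta = 90, psi = 0,
                       pose_seed = 1L, jitter_sd = 0,
                       frames = default_frames(), pdb_id = "synt") {
  geo <- plant_geometry(central_type, neighbor_type, contact_atom,
                        r, theta, psi, frames)
  frame <- frames[[toupper(central_type)]]
  central <- geo$central
  nb <- geo$neighbor
  if (jitter_sd > 0) {
    jit <- function(res, seed_off) with_seed(pose_seed + seed_off, {
      xyz <- residue_xyz(res)
      set_xyz(res, xyz + matrix(stats::rnorm(length(xyz), 0, jitter_sd),
                                ncol = 3))
    })
    central <- jit(central, 100003L)
    nb <- jit(nb, 200003L)
  }
  # realized (post-jitter, pre-pose) ground truth in the ideal frame
  D <- defining_xyz(central, frame)
  S <- residue_xyz(sidechain(nb))
  dmin <- per_row_min_dist(S, D)
  best <- order(dmin, rownames(S))[1]
  pol <- spherical_polar(S[best, ])
  pose <- random_rigid_transform(pose_seed)
  central_p <- apply_transform(pose, central)
  nb_p <- apply_transform(pose, nb)
  truth <- data.frame(
    pdb_id = pdb_id, central_type = toupper(central_type),
    neighbor_type = toupper(neighbor_type), contact_atom = contact_atom,
    r = r, theta = theta, psi = psi,
    realized_atom = rownames(S)[best],
    realized_r = pol[["r"]], realized_theta = pol[["theta"]],
    realized_psi = pol[["psi"]], realized_min_dist = dmin[best],
    pose_seed = pose_seed, jitter_sd = jitter_sd, stringsAsFactors = FALSE)
  list(pdb = c(sprintf("REMARK  98 SYNTHETIC PLANTED PAIR %s", pdb_id),
               residues_to_pdb(list(central_p, nb_p)), "END"),
       residues = list(central_p, nb_p),
       truth = truth)
}

# Build the pre-pose, pre-jitter planted geometry; errors on steric
# infeasibility (contact atom or any neighbour atom within 1.5 A of the
# central residue).
plant_geometry <- function(central_type, neighbor_type, contact_atom,
                           r, theta, psi, frames = default_frames()) {
  stopifnot(r > 0, theta >= 0, theta <= 180, psi > -180, psi <= 180)
  frame <- frames[[toupper(central_type)]]
  if (is.null(frame)) stop("no frame for central type: ", central_type,
                           call. = FALSE)
  central <- build_ideal_residue(central_type, seq_num = 1L)
  c0 <- drop(polar_to_cartesian(r, theta, psi))
  if (min_dist(matrix(c0, 1), residue_xyz(central)) < 1.5)
    stop("steric clash: contact atom within 1.5 A of the central residue",
         call. = FALSE)
  nb <- place_neighbor(toupper(neighbor_type), contact_atom, c0,
                       defining_xyz(central, frame), seq_num = 3L)
  check_steric(list(central, nb))
  list(central = central, neighbor = nb)
}

# Inter-residue steric sanity: no atom of one residue within 1.5 A of an
# atom of another (covalently bonded atoms inside one residue are exempt).
check_steric <- function(residues) {
  n <- length(residues)
  if (n < 2) return(invisible(TRUE))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (min_dist(residue_xyz(residues[[i]]),
                 residue_xyz(residues[[j]])) < 1.5)
      stop("steric clash between residues ", i, " and ", j, call. = FALSE)
  }
  invisible(TRUE)
}

#' Specify a synthetic interaction population
#'
#' A mixture of angular components for the planted contact atom:
#' \describe{
#'   \item{axial}{spherical caps `theta < cap` or `theta > 180 - cap`
#'     (solid-angle uniform within the caps), `psi` uniform — the
#'     above/below-plane population seen for non-polar contacts of
#'     arginine.}
#'   \item{equatorial}{`theta` uniform in `90 +/- band`, `psi` drawn around
#'     configurable mode angles (Gaussian, SD `psi_sd`, wrapped) — the
#'     in-plane hydrogen-bonding population; the default modes +/-60 deg
#'     point along the CZ->NH1 and CZ->NH2 directions.}
#'   \item{uniform}{solid-angle uniform over the whole sphere — the
#'     orientation-free population seen around the lysine terminus.}
#' }
#'
#' @param n_pairs Number of planted pairs.
#' @param mixture List of components; each a list with `weight`, `type`
#'   (`"axial"`, `"equatorial"`, `"uniform"`), optional `cap` (default 45),
#'   `band` (default 15), `psi_modes` (default `c(60, -60)`), `psi_sd`
#'   (default 10), `neighbor_type` (default `"LEU"`), `contact_atom`
#'   (default first side-chain atom beyond CB, e.g. Leu CD1). Weights must
#'   sum to 1.
#' @param central_type `"ARG"` or `"LYS"`.
#' @param r_range Contact-distance range, uniform (default 3.2-4.5
#'   Angstrom, the close-contact shells of the density figures).
#' @param jitter_sd Coordinate noise SD in Angstrom.
#' @param seed Population seed.
#' @return Object of class `population_spec`.
#' @export
population_spec <- function(n_pairs, mixture, central_type = "ARG",
                            r_range = c(3.2, 4.5), jitter_sd = 0,
                            seed = 1L) {
  stopifnot(n_pairs > 0, length(r_range) == 2, r_range[1] > 0,
            r_range[1] <= r_range[2])
  w <- vapply(mixture, function(m) m$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-9)
    stop("mixture weights must sum to 1", call. = FALSE)
  defaults <- list(cap = 45, band = 15, psi_modes = c(60, -60), psi_sd = 10,
                   neighbor_type = "LEU", contact_atom = NULL)
  mixture <- lapply(mixture, function(m) {
    m <- utils::modifyList(defaults, m)
    if (is.null(m$contact_atom)) {
      sc <- SIDECHAIN_ATOM_NAMES[[m$neighbor_type]]
      m$contact_atom <- if (length(sc) > 1) sc[length(sc) - 1] else sc[1]
    }
    m
  })
  structure(list(n_pairs = as.integer(n_pairs), mixture = mixture,
                 central_type = toupper(central_type), r_range = r_range,
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "population_spec")
}

# Draw (theta, psi) from one mixture component.
draw_angles <- function(comp) {
  if (comp$type == "axial") {
    u <- stats::runif(1, cos(comp$cap * pi / 180), 1)
    th <- acos(u) * 180 / pi
    if (stats::runif(1) < 0.5) th <- 180 - th
    ps <- stats::runif(1, -180, 180)
  } else if (comp$type == "equatorial") {
    th <- 90 + stats::runif(1, -comp$band, comp$band)
    mode <- comp$psi_modes[sample.int(length(comp$psi_modes), 1)]
    ps <- mode + stats::rnorm(1, 0, comp$psi_sd)
    ps <- ((ps + 180) %% 360) - 180
    if (ps == -180) ps <- 180
  } else if (comp$type == "uniform") {
    th <- acos(stats::runif(1, -1, 1)) * 180 / pi
    ps <- stats::runif(1, -180, 180)
  } else stop("unknown mixture component type: ", comp$type, call. = FALSE)
  c(theta = th, psi = ps)
}

#' Generate a synthetic interaction population
#'
#' Draws `n_pairs` planted pairs from a [population_spec()] mixture under
#' its seed. The ground-truth ledger records, for every pair, the component
#' label, planted and realized (r, theta, psi), contact atom and pose seed;
#' the same seed reproduces the ledger and PDB text byte-identically.
#'
#' @param spec A [population_spec()].
#' @param out_dir Optional directory: when given, each structure is written
#'   to `synth_<i>.pdb`, the ledger to `ledger.csv` and the spec echo to
#'   `population_spec.json`.
#' @return List with `pdb` (list of character vectors, one per structure),
#'   `residues` (list of full-precision residue lists, one per structure)
#'   and `ledger` (`data.frame`, one row per pair, column `component` plus
#'   the [plant_pair()] truth columns).
#' @export
generate_population <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  w <- vapply(spec$mixture, function(m) m$weight, numeric(1))
  draws <- with_seed(spec$seed, {
    comp_idx <- sample.int(length(w), spec$n_pairs, replace = TRUE, prob = w)
    lapply(seq_len(spec$n_pairs), function(i) {
      comp <- spec$mixture[[comp_idx[i]]]
      # rejection-sample sterically feasible placements: directions that
      # would bury the contact in the central side chain are redrawn
      for (try in 1:100) {
        ang <- draw_angles(comp)
        rr <- stats::runif(1, spec$r_range[1], spec$r_range[2])
        ok <- tryCatch({
          plant_geometry(spec$central_type, comp$neighbor_type,
                         comp$contact_atom, rr, ang[["theta"]],
                         ang[["psi"]])
          TRUE
        }, error = function(e) FALSE)
        if (ok) break
      }
      if (!ok) stop("could not place a sterically valid pair for component ",
                    comp_idx[i], call. = FALSE)
      list(component = comp_idx[i], r = rr,
           theta = ang[["theta"]], psi = ang[["psi"]],
           neighbor_type = comp$neighbor_type,
           contact_atom = comp$contact_atom,
           pose_seed = sample.int(2147483646L, 1))
    })
  })
  pdb <- vector("list", spec$n_pairs)
  residues <- vector("list", spec$n_pairs)
  rows <- vector("list", spec$n_pairs)
  for (i in seq_len(spec$n_pairs)) {
    d <- draws[[i]]
    pp <- plant_pair(spec$central_type, d$neighbor_type, d$contact_atom,
                     r = d$r, theta = d$theta, psi = d$psi,
                     pose_seed = d$pose_seed, jitter_sd = spec$jitter_sd,
                     pdb_id = sprintf("sy%02d", i %% 100))
    pdb[[i]] <- pp$pdb
    residues[[i]] <- pp$residues
    row <- pp$truth
    row$component <- d$component
    row$structure <- i
    rows[[i]] <- row
  }
  ledger <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(spec$n_pairs))
      writeLines(pdb[[i]], file.path(out_dir, sprintf("synth_%04d.pdb", i)))
    utils::write.csv(ledger, file.path(out_dir, "ledger.csv"),
                     row.names = FALSE)
    jsonlite::write_json(unclass(spec),
                         file.path(out_dir, "population_spec.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(pdb = pdb, residues = residues, ledger = ledger)
}

#' Preset populations mimicking the observed Arg and Lys contact regimes
#'
#' `arg_like_population()` plants non-polar (Leu carbon) contacts in the
#' axial caps and polar (Asp carboxylate-oxygen) contacts in the equatorial
#' band, the segregation characteristic of the arginine guanidinium.
#' `lys_like_population()` plants both contact classes spherically
#' uniformly, the orientation-free regime around the lysine terminus.
#'
#' @param n_pairs Population size.
#' @param seed Population seed.
#' @return A [population_spec()].
#' @export
arg_like_population <- function(n_pairs = 1000, seed = 1L) {
  population_spec(n_pairs, central_type = "ARG", seed = seed, mixture = list(
    list(weight = 0.5, type = "axial", cap = 45,
         neighbor_type = "LEU", contact_atom = "CD1"),
    list(weight = 0.5, type = "equatorial", band = 15,
         neighbor_type = "ASP", contact_atom = "OD1")))
}

#' @rdname arg_like_population
#' @export
lys_like_population <- function(n_pairs = 1000, seed = 1L) {
  population_spec(n_pairs, central_type = "LYS", seed = seed, mixture = list(
    list(weight = 0.5, type = "uniform",
         neighbor_type = "LEU", contact_atom = "CD1"),
    list(weight = 0.5, type = "uniform",
         neighbor_type = "ASP", contact_atom = "OD1")))
}
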