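# Spherical-polar analysis of canonical-frame neighbour atoms: closest-atom
# rule, distance shells, angular density grids, axial/equatorial summaries.

#' Cartesian to spherical-polar coordinates
#'
#' In the canonical frame: `r` is the Euclidean distance from the origin
#' atom (CZ for Arg, NZ for Lys), `theta` the angle from the positive z
#' axis in degrees (90 = in the guanidinium / Cd-Ce-Nz plane, 180 = along
#' -z), and `psi` the rotation about z measured from the positive x axis,
#' in (-180, 180]. On the z axis (and at the origin) `psi` is defined as 0;
#' at the origin `theta` is also 0.
#'
#' @param xyz Length-3 vector or Nx3 matrix of canonical-frame coordinates.
#' @return Named vector `(r, theta, psi)` or an Nx3 matrix of the same.
#' @examples
#' spherical_polar(c(1, 0, 0))   # r 1, theta 90, psi 0
#' spherical_polar(c(0, 0, -1))  # theta 180
#' @export
spherical_polar <- function(xyz) {
  if (is.null(dim(xyz))) return(spherical_polar(matrix(xyz, 1))[1, ])
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, all(is.finite(xyz)))
  r <- sqrt(rowSums(xyz^2))
  theta <- ifelse(r == 0, 0, acos(pmin(1, pmax(-1, xyz[, 3] / ifelse(r == 0, 1, r)))) * 180 / pi)
  on_axis <- xyz[, 1] == 0 & xyz[, 2] == 0
  psi <- ifelse(on_axis, 0, atan2(xyz[, 2], xyz[, 1]) * 180 / pi)
  psi[psi <= -180] <- 180
  cbind(r = r, theta = theta, psi = psi)
}

#' Spherical-polar to Cartesian coordinates
#'
#' Inverse of [spherical_polar()] (angles in degrees).
#'
#' @param r,theta,psi Numeric vectors (recycled).
#' @return Nx3 matrix of Cartesian coordinates.
#' @export
polar_to_cartesian <- function(r, theta, psi) {
  th <- theta * pi / 180
  ps <- psi * pi / 180
  cbind(x = r * sin(th) * cos(ps),
        y = r * sin(th) * sin(ps),
        z = r * cos(th))
}

#' Closest neighbour atom of a pair in polar coordinates
#'
#' Applies the closest-atom rule: among the neighbour's side-chain heavy
#' atoms, the one with the minimum distance to the central defining-atom
#' set is selected (ties broken deterministically by atom-name order) and
#' its position expressed in spherical-polar coordinates about the frame
#' origin atom. Note the two reference points differ by construction: the
#' cutoff is measured to the defining set while `r`/`theta`/`psi` are
#' measured from the origin atom.
#'
#' @param pair Canonical-frame `sc_pair`.
#' @param cutoff Maximum defining-set distance in Angstrom (default 6);
#'   `NULL` for no cutoff.
#' @param frames Frame registry (for the defining-atom set).
#' @return One-row `data.frame` (pdb_id, chain_id, central_type,
#'   central_seq, neighbor_type, neighbor_seq, atom, r, theta, psi,
#'   min_dist) or `NULL` when every atom is beyond the cutoff.
#' @export
closest_atom_polar <- function(pair, cutoff = 6, frames = default_frames()) {
  frame <- frames[[pair$central$res_type]]
  D <- defining_xyz(pair$central, frame)
  nb <- sidechain(pair$neighbor)
  S <- residue_xyz(nb)
  if (!nrow(S)) return(NULL)
  d <- per_row_min_dist(S, D)
  ord <- order(d, rownames(S))
  best <- ord[1]
  if (!is.null(cutoff) && d[best] > cutoff) return(NULL)
  pol <- spherical_polar(S[best, ])
  data.frame(pdb_id = pair$pdb_id, chain_id = pair$chain_id,
             central_type = pair$central$res_type,
             central_seq = pair$central$seq_num,
             neighbor_type = pair$neighbor$res_type,
             neighbor_seq = pair$neighbor$seq_num,
             atom = rownames(S)[best],
             r = pol[["r"]], theta = pol[["theta"]], psi = pol[["psi"]],
             min_dist = d[best], stringsAsFactors = FALSE)
}

#' Polar-point table for a set of pairs
#'
#' Applies [closest_atom_polar()] to every pair and binds the rows.
#'
#' @param pairs List of `sc_pair`.
#' @inheritParams closest_atom_polar
#' @return `data.frame` of polar points (possibly zero rows).
#' @export
polar_points <- function(pairs, cutoff = 6, frames = default_frames()) {
  rows <- lapply(pairs, closest_atom_polar, cutoff = cutoff, frames = frames)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(pdb_id = character(0), chain_id = character(0),
                      central_type = character(0), central_seq = integer(0),
                      neighbor_type = character(0), neighbor_seq = integer(0),
                      atom = character(0), r = numeric(0), theta = numeric(0),
                      psi = numeric(0), min_dist = numeric(0)))
  do.call(rbind, rows)
}

#' Neighbour atoms of a pair within a distance shell
#'
#' Selects neighbour side-chain atoms matching an atom-class selector whose
#' minimum distance to the central defining set lies in the half-open
#' interval `(d_min, d_max]` — the convention under which the nested figure
#' cutoffs (3.5, 3.75, 4.0, 4.5 Angstrom) partition atoms exactly once.
#'
#' @param pair Canonical-frame `sc_pair`.
#' @param selector Selector name (see [atom_selectors()]), an element class
#'   (`"carbon"`, `"oxygen"`, ...), `"heavy"`, or explicit atom names.
#' @param d_min,d_max Shell bounds in Angstrom, `0 <= d_min < d_max`.
#' @param frames Frame registry.
#' @return `data.frame` with one row per selected atom: `atom`, `element`,
#'   `dist` (to the defining set), and polar `r`, `theta`, `psi`.
#' @export
shell_filter <- function(pair, selector = "heavy", d_min = 0, d_max = 4.5,
                         frames = default_frames()) {
  stopifnot(d_min >= 0, d_min < d_max)
  frame <- frames[[pair$central$res_type]]
  D <- defining_xyz(pair$central, frame)
  nb <- sidechain(pair$neighbor)
  keep_names <- resolve_selector(selector, nb$res_type)
  tab <- nb$atoms[nb$atoms$name %in% keep_names, , drop = FALSE]
  if (!nrow(tab))
    return(data.frame(atom = character(0), element = character(0),
                      dist = numeric(0), r = numeric(0), theta = numeric(0),
                      psi = numeric(0)))
  S <- as.matrix(tab[, c("x", "y", "z")])
  d <- per_row_min_dist(S, D)
  inside <- d > d_min & d <= d_max
  pol <- spherical_polar(S[inside, , drop = FALSE])
  data.frame(atom = tab$name[inside], element = tab$element[inside],
             dist = d[inside], r = pol[, "r"], theta = pol[, "theta"],
             psi = pol[, "psi"], stringsAsFactors = FALSE, row.names = NULL)
}

#' Angular density map over psi x theta
#'
#' Two-dimensional histogram of polar points on a regular psi x theta grid.
#' Bins are half-open `(lo, hi]` with the first theta bin closed at 0. When
#' solid-angle weighting is enabled each bin count is divided by
#' `sin(theta_centre)` (guarded below by the sine of half a bin width) to
#' compensate for the smaller Cartesian volume near the poles; the raw
#' counts are always retained.
#'
#' @param points `data.frame` with columns `theta` and `psi` (degrees), e.g.
#'   from [polar_points()].
#' @param psi_bin,theta_bin Bin widths in degrees; must divide 360 and 180.
#' @param solid_angle_weighting Compute the weighted density layer.
#' @return Object of class `density_map`: list with `psi_edges`,
#'   `theta_edges`, `counts` (theta rows x psi columns, integer), `density`
#'   (weighted, or `NULL`), `weighted` flag and `n_points`.
#' @export
build_density <- function(points, psi_bin = 5, theta_bin = 5,
                          solid_angle_weighting = FALSE) {
  if (360 %% psi_bin != 0 || 180 %% theta_bin != 0)
    stop("bin widths must divide 360 (psi) and 180 (theta)", call. = FALSE)
  psi_edges <- seq(-180, 180, by = psi_bin)
  theta_edges <- seq(0, 180, by = theta_bin)
  nt <- length(theta_edges) - 1L
  np <- length(psi_edges) - 1L
  counts <- matrix(0L, nt, np,
                   dimnames = list(theta = sprintf("(%g,%g]",
                                                   theta_edges[-(nt + 1)],
                                                   theta_edges[-1]),
                                   psi = sprintf("(%g,%g]",
                                                 psi_edges[-(np + 1)],
                                                 psi_edges[-1])))
  n <- if (is.data.frame(points)) nrow(points) else length(points$theta)
  if (n > 0) {
    ti <- pmin(pmax(ceiling(points$theta / theta_bin), 1L), nt)
    pi_ <- pmin(pmax(ceiling((points$psi + 180) / psi_bin), 1L), np)
    counts[] <- tabulate((pi_ - 1L) * nt + ti, nbins = nt * np)
  }
  density <- NULL
  if (solid_angle_weighting) {
    centres <- (theta_edges[-(nt + 1)] + theta_edges[-1]) / 2
    w <- pmax(sin(centres * pi / 180), sin(theta_bin / 2 * pi / 180))
    density <- counts / w
  }
  structure(list(psi_edges = psi_edges, theta_edges = theta_edges,
                 counts = counts, density = density,
                 weighted = solid_angle_weighting, n_points = n),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density map %dx%d (theta x psi), %d points%s>\n",
              nrow(x$counts), ncol(x$counts), x$n_points,
              if (x$weighted) ", solid-angle weighted" else ""))
  invisible(x)
}

#' Plot an angular density map
#'
#' @param x A `density_map`.
#' @param weighted Plot the solid-angle-weighted layer if available.
#' @param ... Passed to [graphics::image()].
#' @export
plot.density_map <- function(x, weighted = x$weighted, ...) {
  z <- if (weighted && !is.null(x$density)) x$density else x$counts
  graphics::image(x = x$psi_edges, y = x$theta_edges, z = t(z),
                  xlab = expression(psi ~ "(deg)"),
                  ylab = expression(theta ~ "(deg)"), ...)
  invisible(x)
}

#' Convert a density map to a long data frame
#'
#' @param x A `density_map`.
#' @param ... Unused.
#' @return `data.frame` with `psi_lo`, `psi_hi`, `theta_lo`, `theta_hi`,
#'   `count` and (when weighted) `density`.
#' @export
as.data.frame.density_map <- function(x, ...) {
  nt <- nrow(x$counts); np <- ncol(x$counts)
  out <- data.frame(
    psi_lo = rep(x$psi_edges[-(np + 1)], each = nt),
    psi_hi = rep(x$psi_edges[-1], each = nt),
    theta_lo = rep(x$theta_edges[-(nt + 1)], np),
    theta_hi = rep(x$theta_edges[-1], np),
    count = as.vector(x$counts)
  )
  if (!is.null(x$density)) out$density <- as.vector(x$density)
  out
}

#' Fraction of points in the axial caps
#'
#' Fraction of polar points lying above or below the central plane:
#' `theta < theta_cap` or `theta > 180 - theta_cap`. Quantifies the
#' axial-versus-equatorial segregation of contact atoms (non-polar contacts
#' of arginine are predominantly axial; in-plane hydrogen-bonding contacts
#' are equatorial).
#'
#' @param points `data.frame` with a `theta` column (degrees), or a numeric
#'   vector of theta values.
#' @param theta_cap Cap half-angle in degrees, `0 < theta_cap < 90`
#'   (default 45).
#' @return Fraction in `[0, 1]`. Empty input is an error.
#' @export
axial_fraction <- function(points, theta_cap = 45) {
  stopifnot(theta_cap > 0, theta_cap < 90)
  theta <- if (is.data.frame(points)) points$theta else points
  if (!length(theta))
    stop("axial_fraction is undefined for an empty point set", call. = FALSE)
  mean(theta < theta_cap | theta > 180 - theta_cap)
}

#' Subsample a pair list
#'
#' Caps the number of pairs carried into the visual/density stages. The
#' `"first"` policy keeps the first `max_n` pairs in extraction order; the
#' `"random"` policy draws a seeded uniform subsample.
#'
#' @param pairs List of `sc_pair`.
#' @param max_n Maximum number kept (default 4000).
#' @param policy `"first"` or `"random"`.
#' @param seed Integer seed for the random policy.
#' @return Subsampled list with a `"subsample"` attribute recording
#'   `n_before`, `n_after`, `policy`, `seed`.
#' @export
subsample_pairs <- function(pairs, max_n = 4000,
                            policy = c("first", "random"), seed = 1L) {
  policy <- match.arg(policy)
  stopifnot(max_n > 0)
  n <- length(pairs)
  out <- if (n <= max_n) {
    pairs
  } else if (policy == "first") {
    pairs[seq_len(max_n)]
  } else {
    idx <- with_seed(seed, sort(sample.int(n, max_n)))
    pairs[idx]
  }
  attr(out, "subsample") <- list(n_before = n, n_after = length(out),
                                    policy = policy,
                                    seed = if (policy == "random") seed else NA)
  out
}
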