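# Canonical residue frames: the terminal (origin) atom is translated to the
# origin and the anchor triple rotated onto fixed reference coordinates by a
# pinned-origin Kabsch rotation, so interaction populations superpose.

#' Define a canonical residue frame
#'
#' A frame names the origin atom (pinned to (0,0,0)), an ordered anchor
#' triple beginning with the origin atom, printed reference coordinates for
#' the anchors (first row must be the origin), and the defining-atom set
#' against which neighbour contact distances are measured.
#'
#' @param res_type Three-letter residue code.
#' @param origin_atom Atom placed at the origin (first anchor).
#' @param anchor_atoms Ordered character triple of anchor atom names.
#' @param reference_coords 3x3 numeric matrix of anchor reference positions
#'   (rows in `anchor_atoms` order; first row `(0,0,0)`).
#' @param defining_atoms Atoms used for contact-distance cutoffs.
#' @return Object of class `frame_definition`.
#' @export
frame_definition <- function(res_type, origin_atom, anchor_atoms,
                             reference_coords, defining_atoms) {
  reference_coords <- as.matrix(reference_coords)
  stopifnot(length(anchor_atoms) == 3,
            identical(dim(reference_coords), c(3L, 3L)))
  if (anchor_atoms[1] != origin_atom)
    stop("origin atom must be the first anchor", call. = FALSE)
  if (any(reference_coords[1, ] != 0))
    stop("first reference coordinate must be the origin", call. = FALSE)
  v1 <- reference_coords[2, ]; v2 <- reference_coords[3, ]
  if (sqrt(sum(crossprod3(v1, v2)^2)) < 1e-9)
    stop("reference anchors are collinear", call. = FALSE)
  structure(list(res_type = toupper(res_type), origin_atom = origin_atom,
                 anchor_atoms = anchor_atoms,
                 reference_coords = unname(reference_coords),
                 defining_atoms = defining_atoms),
            class = "frame_definition")
}

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Built-in canonical frames for arginine and lysine
#'
#' Arginine: CZ at the origin with (CZ, NH1, NH2) aligned onto
#' ((0,0,0), (0.5, 0.87, 0), (0.5, -0.87, 0)), so the guanidinium lies in
#' the xy-plane with NH1 at positive y. Lysine: NZ at the origin with
#' (NZ, CE, CD) aligned onto ((0,0,0), (-1, 0, 0), (-1.34, 0.94, 0)), so the
#' Cd-Ce-Nz plane is the xy-plane with the aliphatic tail along -x.
#' Contact distances are measured to the defining sets NE/CZ/NH1/NH2 (Arg)
#' and CD/CE/NZ (Lys).
#'
#' Additional frames (e.g. for amide groups) can be added to the returned
#' list; the transform machinery is frame-agnostic.
#'
#' @return Named list of [frame_definition()] objects.
#' @export
default_frames <- function() {
  list(
    ARG = frame_definition("ARG", "CZ", c("CZ", "NH1", "NH2"),
                           rbind(c(0, 0, 0), c(0.5, 0.87, 0),
                                 c(0.5, -0.87, 0)),
                           c("NE", "CZ", "NH1", "NH2")),
    LYS = frame_definition("LYS", "NZ", c("NZ", "CE", "CD"),
                           rbind(c(0, 0, 0), c(-1, 0, 0),
                                 c(-1.34, 0.94, 0)),
                           c("CD", "CE", "NZ"))
  )
}

#' Optimal proper rotation between paired point sets (Kabsch)
#'
#' Computes the rotation `R` minimizing `sum(|R p_i - q_i|^2)` over proper
#' rotations, by SVD of the covariance `t(P) %*% Q` with the reflection
#' branch corrected to `det(R) = +1`. No centroid subtraction is performed:
#' callers that want the classical centered superposition must centre `P`
#' and `Q` themselves. This is what allows the pinned-origin variant used by
#' the canonical-frame transform.
#'
#' @param P,Q Nx3 matrices of paired source and target points (N >= 3, each
#'   spanning at least a plane).
#' @return 3x3 proper orthogonal matrix `R`; apply as `xyz %*% t(R)`.
#' @export
kabsch_rotation <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(ncol(P) == 3, ncol(Q) == 3, nrow(P) == nrow(Q))
  if (nrow(P) < 3)
    stop("degenerate geometry: need at least 3 points", call. = FALSE)
  rank2 <- function(M) {
    s <- svd(scale(M, center = TRUE, scale = FALSE))$d
    s[2] > 1e-8 * max(s[1], 1e-12)
  }
  if (!rank2(P) || !rank2(Q))
    stop("degenerate geometry: points are collinear", call. = FALSE)
  s <- svd(t(P) %*% Q)
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

#' Rigid-body transform
#'
#' @param rotation 3x3 proper orthogonal matrix.
#' @param translation Length-3 vector; the transform acts as
#'   `x' = rotation %*% x + translation`.
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  stopifnot(identical(dim(rotation), c(3L, 3L)), length(translation) == 3)
  if (max(abs(t(rotation) %*% rotation - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation is not proper orthogonal", call. = FALSE)
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates or residues
#'
#' @param tr A `rigid_transform`.
#' @param x Nx3 coordinate matrix, a single `sc_residue`, or a list of them.
#' @return Transformed object of the same shape.
#' @export
apply_transform <- function(tr, x) {
  if (inherits(x, "sc_residue"))
    return(set_xyz(x, apply_transform(tr, residue_xyz(x))))
  if (is.list(x)) return(lapply(x, apply_transform, tr = tr))
  sweep(as.matrix(x) %*% t(tr$rotation), 2, tr$translation, "+")
}

# Compose: apply `a` after `b` (x -> a(b(x))).
compose_transforms <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Transform a central residue and its neighbours into the canonical frame
#'
#' The transform translates the frame's origin atom to (0,0,0) and then
#' applies the Kabsch rotation taking the translated anchor triple onto the
#' printed reference coordinates. The rotation is computed about the pinned
#' origin (no centroid re-centering), so the origin atom lands exactly at
#' the origin; a classical centroid-centered variant is available for
#' sensitivity checks (`method = "centroid"`, in which case the origin atom
#' lands near but not exactly at the origin). The same rigid transform is
#' applied to every atom of the central residue and of all neighbours, so
#' all internal distances are preserved.
#'
#' @param central `sc_residue` whose type matches `frame$res_type` and which
#'   contains all three anchor atoms (otherwise an error of class
#'   `scpolar_missing_anchor` is raised).
#' @param neighbors List of `sc_residue` objects moved along with the
#'   central residue (may be empty).
#' @param frame A [frame_definition()].
#' @param method `"pinned"` (default) or `"centroid"`.
#' @return List with elements `central`, `neighbors`, `transform`.
#' @export
to_canonical_frame <- function(central, neighbors = list(),
                               frame = default_frames()[[central$res_type]],
                               method = c("pinned", "centroid")) {
  method <- match.arg(method)
  if (central$res_type != frame$res_type)
    stop("residue type ", central$res_type, " does not match frame ",
         frame$res_type, call. = FALSE)
  missing <- setdiff(frame$anchor_atoms, central$atoms$name)
  if (length(missing))
    stop(structure(class = c("scpolar_missing_anchor", "error", "condition"),
                   list(message = paste0("missing anchor atom(s) in ",
                                         central$res_type, " ",
                                         central$seq_num, ": ",
                                         paste(missing, collapse = ",")),
                        call = NULL)))
  A <- residue_xyz(central, frame$anchor_atoms)
  Q <- frame$reference_coords
  if (method == "pinned") {
    o <- A[1, ]
    R <- kabsch_rotation(sweep(A, 2, o), Q)
    tr <- rigid_transform(R, -as.numeric(R %*% o))
  } else {
    pc <- colMeans(A); qc <- colMeans(Q)
    R <- kabsch_rotation(sweep(A, 2, pc), sweep(Q, 2, qc))
    tr <- rigid_transform(R, qc - as.numeric(R %*% pc))
  }
  list(central = apply_transform(tr, central),
       neighbors = apply_transform(tr, neighbors),
       transform = tr)
}
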