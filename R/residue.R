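# The residue container: a typed collection of heavy atoms with chain and
# sequence identity. Deliberately light-weight (a list with an atom table)
# so thousands of small synthetic structures stay cheap.

#' Construct a residue
#'
#' @param res_type Three-letter amino-acid code (upper case).
#' @param atoms `data.frame` with columns `name`, `element`, `x`, `y`, `z`,
#'   `occ`, `altloc`. Missing `element` is inferred from `name`; missing
#'   `occ`/`altloc` default to 1 and "".
#' @param chain_id Chain identifier.
#' @param seq_num Author residue number (integer).
#' @param icode Insertion code ("" if none).
#' @return Object of class `sc_residue`.
#' @export
new_residue <- function(res_type, atoms, chain_id = "A", seq_num = 1L,
                        icode = "") {
  res_type <- toupper(res_type)
  if (!res_type %in% STANDARD_AA)
    stop("not a standard amino acid: ", res_type, call. = FALSE)
  if (is.null(atoms$element)) atoms$element <- element_from_name(atoms$name)
  if (is.null(atoms$occ)) atoms$occ <- 1
  if (is.null(atoms$altloc)) atoms$altloc <- ""
  if (anyDuplicated(atoms$name))
    stop("duplicate atom names in residue: ",
         paste(atoms$name[duplicated(atoms$name)], collapse = ","),
         call. = FALSE)
  stopifnot(all(is.finite(atoms$x)), all(is.finite(atoms$y)),
            all(is.finite(atoms$z)))
  structure(
    list(res_type = res_type, chain_id = chain_id,
         seq_num = as.integer(seq_num), icode = icode,
         atoms = atoms[, c("name", "element", "x", "y", "z", "occ", "altloc")]),
    class = "sc_residue"
  )
}

#' @export
print.sc_residue <- function(x, ...) {
  cat(sprintf("<residue %s %s%d%s, %d atoms: %s>\n", x$res_type, x$chain_id,
              x$seq_num, x$icode, nrow(x$atoms),
              paste(x$atoms$name, collapse = " ")))
  invisible(x)
}

#' Atom coordinates of a residue
#'
#' @param res An `sc_residue`.
#' @param atoms Optional atom names to extract, in the given order; an error
#'   is raised if any is absent unless `partial = TRUE`.
#' @param partial Return only the atoms present instead of erroring.
#' @return Numeric matrix with one row per atom, rownames = atom names.
#' @export
residue_xyz <- function(res, atoms = NULL, partial = FALSE) {
  tab <- res$atoms
  if (!is.null(atoms)) {
    idx <- match(atoms, tab$name)
    if (anyNA(idx)) {
      if (!partial)
        stop("missing atom(s) in ", res$res_type, " ", res$seq_num, ": ",
             paste(atoms[is.na(idx)], collapse = ","), call. = FALSE)
      idx <- idx[!is.na(idx)]
    }
    tab <- tab[idx, , drop = FALSE]
  }
  m <- as.matrix(tab[, c("x", "y", "z")])
  rownames(m) <- tab$name
  m
}

#' Side-chain heavy atoms of a residue
#'
#' Everything except the backbone N, CA, C, O and terminal OXT; CB counts as
#' side chain, so alanine has one side-chain atom and glycine none.
#'
#' @param res An `sc_residue`.
#' @return `sc_residue` restricted to side-chain heavy atoms (hydrogens are
#'   already absent after [load_chain()]).
#' @export
sidechain <- function(res) {
  keep <- !(res$atoms$name %in% BACKBONE_ATOMS) &
    !(res$atoms$element %in% c("H", "D"))
  out <- res
  out$atoms <- res$atoms[keep, , drop = FALSE]
  out
}

# Replace residue coordinates with a same-shape matrix.
set_xyz <- function(res, xyz) {
  stopifnot(nrow(xyz) == nrow(res$atoms))
  res$atoms$x <- xyz[, 1]
  res$atoms$y <- xyz[, 2]
  res$atoms$z <- xyz[, 3]
  res
}

# Minimum distance and per-row minimum between two coordinate sets.
cross_dist2 <- function(A, B) {
  # squared distances, rows of A x rows of B
  outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
}

min_dist <- function(A, B) {
  if (nrow(A) == 0 || nrow(B) == 0) return(Inf)
  sqrt(max(0, min(cross_dist2(A, B))))
}

per_row_min_dist <- function(A, B) {
  if (nrow(A) == 0 || nrow(B) == 0) return(rep(Inf, nrow(A)))
  sqrt(pmax(0, apply(cross_dist2(A, B), 1, min)))
}
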