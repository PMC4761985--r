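# Reading culled chain lists and PDB-format coordinates, and writing /
# re-reading the per-pair side-chain files the pipeline produces.

#' Parse a culled chain list
#'
#' Reads a Pisces-style culled chain list: one whitespace-delimited record
#' per line whose first token is a 4-character PDB identifier followed by a
#' chain label (e.g. "1ABCA"). A header line (first token not matching the
#' identifier pattern, e.g. "PDBchain") is skipped.
#'
#' @param text Chain-list content as a single string or character vector of
#'   lines, or the path of an existing file.
#' @return `data.frame` with columns `pdb_id` (lower case) and `chain_id`,
#'   one row per data line in file order. Malformed data tokens (fewer than
#'   5 characters) are collected in the `"errors"` attribute rather than
#'   aborting the parse.
#' @examples
#' parse_chain_list(c("PDBchain length", "1ABCA 120", "2XYZB 300"))
#' @export
parse_chain_list <- function(text) {
  lines <- read_text_lines(text)
  tok <- vapply(strsplit(trimws(lines), "\\s+"), function(x)
    if (length(x)) x[[1]] else "", character(1))
  keep <- nzchar(tok)
  tok <- tok[keep]
  is_id <- grepl("^[0-9][0-9A-Za-z]{3}[0-9A-Za-z]+$", tok)
  bad <- !is_id & grepl("^[0-9]", tok)   # starts like an ID but malformed
  recs <- tok[is_id]
  out <- data.frame(
    pdb_id = tolower(substr(recs, 1, 4)),
    chain_id = substring(recs, 5),
    stringsAsFactors = FALSE
  )
  attr(out, "errors") <- tok[bad]
  if (any(bad))
    warning(sum(bad), " malformed chain-list record(s) skipped", call. = FALSE)
  out
}

# Accept raw text (contains newline or multiple elements) or a file path.
read_text_lines <- function(text) {
  if (length(text) == 1 && !grepl("\n", text) && file.exists(text))
    return(readLines(text, warn = FALSE))
  unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
}

# Fixed-width parse of ATOM/HETATM records (PDB v3 columns). Model 1 only.
parse_pdb_atoms <- function(lines) {
  if (any(grepl("^MODEL", lines))) {
    first <- which(grepl("^MODEL", lines))[1]
    end <- which(grepl("^ENDMDL", lines))
    end <- if (length(end)) end[1] else length(lines) + 1L
    lines <- c(lines[seq_len(first - 1L)],
               lines[seq(first, end - 1L)])
    lines <- lines[!grepl("^MODEL", lines)]
  }
  rec <- lines[grepl("^(ATOM  |HETATM)", lines)]
  rec <- rec[nchar(rec) >= 54]
  n <- length(rec)
  if (n == 0) {
    return(data.frame(type = character(0), name = character(0),
                      altloc = character(0), resid = character(0),
                      chain = character(0), resno = integer(0),
                      icode = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), occ = numeric(0),
                      element = character(0), stringsAsFactors = FALSE))
  }
  num <- function(s) suppressWarnings(as.numeric(s))
  occ <- num(substr(rec, 55, 60))
  occ[is.na(occ)] <- 1
  elem <- toupper(trimws(substr(rec, 77, 78)))
  name <- trimws(substr(rec, 13, 16))
  elem[!nzchar(elem)] <- element_from_name(name[!nzchar(elem)])
  out <- data.frame(
    type = trimws(substr(rec, 1, 6)),
    name = name,
    altloc = trimws(substr(rec, 17, 17)),
    resid = trimws(substr(rec, 18, 20)),
    chain = trimws(substr(rec, 22, 22)),
    resno = suppressWarnings(as.integer(trimws(substr(rec, 23, 26)))),
    icode = trimws(substr(rec, 27, 27)),
    x = num(substr(rec, 31, 38)),
    y = num(substr(rec, 39, 46)),
    z = num(substr(rec, 47, 54)),
    occ = occ,
    element = elem,
    stringsAsFactors = FALSE
  )
  bad <- is.na(out$x) | is.na(out$y) | is.na(out$z) | is.na(out$resno)
  if (any(bad)) {
    warning(sum(bad), " unreadable ATOM record(s) skipped", call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  out
}

# Keep the highest-occupancy conformer per atom name; ties broken by
# alphabetical altloc code.
resolve_altlocs <- function(df) {
  if (all(!nzchar(df$altloc)) || !anyDuplicated(df$name)) return(df)
  ord <- order(df$name, -df$occ, df$altloc)
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(df$name), , drop = FALSE]
  df[order(match(df$name, unique(df$name))), , drop = FALSE]
}

#' Load one chain of a PDB-format structure
#'
#' Returns the standard amino-acid residues of the named chain: model 1
#' only, hydrogens and deuteriums dropped, alternate locations resolved to
#' the highest-occupancy conformer (ties by altloc code), HETATM records
#' (waters, ligands, modified residues such as MSE) excluded.
#'
#' @param pdb PDB-format content as a string / character vector of lines, or
#'   a file path.
#' @param chain_id Chain to extract.
#' @return List of [new_residue()] objects in order of appearance.
#' @export
load_chain <- function(pdb, chain_id) {
  at <- parse_pdb_atoms(read_text_lines(pdb))
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!any(at$chain == chain_id))
    stop("chain not found: ", chain_id, call. = FALSE)
  at <- at[at$chain == chain_id, , drop = FALSE]
  at <- at[at$resid %in% STANDARD_AA, , drop = FALSE]
  at <- at[!at$element %in% c("H", "D"), , drop = FALSE]
  key <- paste(at$resno, at$icode, at$resid)
  res <- lapply(split(seq_len(nrow(at)), factor(key, levels = unique(key))),
    function(i) {
      sub <- resolve_altlocs(at[i, , drop = FALSE])
      new_residue(sub$resid[1],
                  data.frame(name = sub$name, element = sub$element,
                             x = sub$x, y = sub$y, z = sub$z,
                             occ = sub$occ, altloc = sub$altloc,
                             stringsAsFactors = FALSE),
                  chain_id = chain_id, seq_num = sub$resno[1],
                  icode = sub$icode[1])
    })
  names(res) <- NULL
  res
}

# One fixed-width ATOM line. Names of up to 3 characters are indented one
# column (standard PDB alignment for C/N/O/S atoms).
format_atom_line <- function(serial, name, resid, chain, resno, xyz,
                             occ = 1, element = NULL) {
  if (is.null(element)) element <- element_from_name(name)
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else sprintf("%-4s", name)
  sprintf("ATOM  %5d %s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, nm, resid, chain, resno, xyz[1], xyz[2], xyz[3],
          occ, 0, element)
}

# Serialize a list of residues (optionally side-chain only) to ATOM lines.
residues_to_pdb <- function(residues, sidechain_only = FALSE) {
  serial <- 0L
  out <- character(0)
  for (res in residues) {
    r <- if (sidechain_only) sidechain(res) else res
    tab <- r$atoms[!r$atoms$element %in% c("H", "D"), , drop = FALSE]
    for (i in seq_len(nrow(tab))) {
      serial <- serial + 1L
      out <- c(out, format_atom_line(serial, tab$name[i], r$res_type,
                                     r$chain_id, r$seq_num,
                                     c(tab$x[i], tab$y[i], tab$z[i]),
                                     tab$occ[i], tab$element[i]))
    }
  }
  out
}

#' Write an interaction pair to a PDB-like file
#'
#' Serializes a canonical-frame [interaction_pair()]: side-chain heavy atoms
#' of the central and neighbour residues only (no backbone, no hydrogens),
#' standard fixed-width ATOM formatting with coordinates to 3 decimals, and
#' REMARK 99 lines carrying provenance and the minimum contact distance so
#' that [read_pair_file()] can round-trip the pair.
#'
#' @param pair An `sc_pair` object.
#' @param path Optional output path; when given the text is also written.
#' @return The file content as a character vector of lines (invisibly when
#'   `path` is given).
#' @export
write_pair_file <- function(pair, path = NULL) {
  stopifnot(inherits(pair, "sc_pair"))
  hdr <- c(
    sprintf("REMARK  99 PAIR %s %s %s %d %s %d", pair$pdb_id, pair$chain_id,
            pair$central$res_type, pair$central$seq_num,
            pair$neighbor$res_type, pair$neighbor$seq_num),
    sprintf("REMARK  99 MINDIST %.6f", pair$min_dist)
  )
  body <- residues_to_pdb(list(pair$central, pair$neighbor),
                          sidechain_only = TRUE)
  txt <- c(hdr, body, "END")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Re-read a pair file written by [write_pair_file()]
#'
#' @param text File content (string or lines) or a path.
#' @return An `sc_pair` with the stored provenance and minimum distance.
#' @export
read_pair_file <- function(text) {
  lines <- read_text_lines(text)
  meta <- lines[grepl("^REMARK  99 PAIR", lines)]
  if (!length(meta)) stop("not a pair file: REMARK 99 PAIR missing",
                          call. = FALSE)
  f <- strsplit(trimws(meta[1]), "\\s+")[[1]]
  md <- lines[grepl("^REMARK  99 MINDIST", lines)]
  mind <- if (length(md)) as.numeric(strsplit(trimws(md[1]), "\\s+")[[1]][4])
          else NA_real_
  at <- parse_pdb_atoms(lines)
  key <- paste(at$resno, at$icode, at$resid)
  res <- lapply(split(seq_len(nrow(at)), factor(key, levels = unique(key))),
    function(i) {
      sub <- at[i, , drop = FALSE]
      new_residue(sub$resid[1],
                  data.frame(name = sub$name, element = sub$element,
                             x = sub$x, y = sub$y, z = sub$z,
                             occ = sub$occ, altloc = sub$altloc,
                             stringsAsFactors = FALSE),
                  chain_id = sub$chain[1], seq_num = sub$resno[1],
                  icode = sub$icode[1])
    })
  names(res) <- NULL
  ctype <- f[6]; cseq <- as.integer(f[7])
  is_central <- vapply(res, function(r)
    r$res_type == ctype && r$seq_num == cseq, logical(1))
  if (sum(is_central) != 1) stop("pair file central residue not identifiable",
                                 call. = FALSE)
  interaction_pair(central = res[[which(is_central)]],
                   neighbor = res[[which(!is_central)[1]]],
                   min_dist = mind, pdb_id = f[4], chain_id = f[5])
}

#' File name for a pair file
#'
#' `<pdbid>_<chain>_<centraltype><seqnum>_<neighbortype><seqnum>.pdb`
#'
#' @param pair An `sc_pair`.
#' @return File name (no directory).
#' @export
pair_file_name <- function(pair) {
  sprintf("%s_%s_%s%d_%s%d.pdb", pair$pdb_id, pair$chain_id,
          pair$central$res_type, pair$central$seq_num,
          pair$neighbor$res_type, pair$neighbor$seq_num)
}
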