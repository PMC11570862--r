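# Structure model and IO.
#
# A structure is an S3 object of class "allo_structure": a list with
#   id            character scalar (PDB code or synthetic label)
#   atoms         data.frame, one row per atom (first NMR model, single
#                 highest-occupancy altloc conformer), columns:
#                 serial, name, altloc, res_name, chain, res_seq, icode,
#                 x, y, z, occupancy, element, is_hetero, vdw
#   ligand_groups character vector of group keys (hetero residues that are
#                 candidate modulators; never water, never buffer compounds)
# Residues are addressed by identity strings
#   "<id>_<chain>_<res_seq><icode>_<res_name>"  (author numbering, 1-based).

new_structure <- function(id, atoms, buffer_exclude = default_buffer_exclude()) {
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0)
  atoms$element <- toupper(atoms$element)
  atoms$res_name <- toupper(atoms$res_name)
  if (is.null(atoms$vdw)) atoms$vdw <- .vdw_for_element(atoms$element)
  s <- structure(list(id = id, atoms = atoms), class = "allo_structure")
  s$ligand_groups <- .find_ligand_groups(s, buffer_exclude)
  s
}

#' @export
print.allo_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf(
    "<allo_structure> %s: %d atoms, %d chains, %d polymer residues, %d ligand group(s)\n",
    x$id, nrow(a), length(unique(a$chain[!a$is_hetero])),
    nrow(unique(a[!a$is_hetero, c("chain", "res_seq", "icode")])),
    length(x$ligand_groups)))
  invisible(x)
}

.residue_identity <- function(id, chain, res_seq, icode, res_name) {
  icode <- ifelse(is.na(icode) | icode == " ", "", icode)
  sprintf("%s_%s_%d%s_%s", id, chain, res_seq, icode, res_name)
}

#' Residue identity strings for every atom row
#' @param structure An `allo_structure`.
#' @return Character vector, one identity per atom row.
#' @keywords internal
atom_identities <- function(structure) {
  a <- structure$atoms
  .residue_identity(structure$id, a$chain, a$res_seq, a$icode, a$res_name)
}

.find_ligand_groups <- function(structure, buffer_exclude) {
  a <- structure$atoms
  het <- a[a$is_hetero & !.is_water(a$res_name), , drop = FALSE]
  if (nrow(het) == 0) return(character(0))
  het <- het[!(het$res_name %in% toupper(buffer_exclude)), , drop = FALSE]
  if (nrow(het) == 0) return(character(0))
  unique(.residue_identity(structure$id, het$chain, het$res_seq,
                           het$icode, het$res_name))
}

#' Pick the default modulator group of a holo structure
#'
#' A hetero group qualifies as a candidate allosteric modulator if it has at
#' least `min_heavy` heavy atoms and is not a water or buffer compound.  The
#' largest qualifying group wins (ties: first in file order).  The cutoff
#' exists because typical buffer leftovers are small; real modulators are
#' multi-atom organic molecules.
#'
#' @param structure An `allo_structure`.
#' @param min_heavy Minimum heavy-atom count (default 6).
#' @return Group key (residue identity string) or `NA_character_` if none.
#' @export
pick_modulator <- function(structure, min_heavy = 6L) {
  if (length(structure$ligand_groups) == 0) return(NA_character_)
  ids <- atom_identities(structure)
  heavy <- !(structure$atoms$element %in% c("H", "D"))
  n <- vapply(structure$ligand_groups,
              function(g) sum(ids == g & heavy), integer(1))
  ok <- n >= min_heavy
  if (!any(ok)) return(NA_character_)
  structure$ligand_groups[ok][which.max(n[ok])]
}

# ---- PDB ----

.parse_pdb <- function(lines, id) {
  # first model only
  m_start <- grep("^MODEL ", lines)
  if (length(m_start) > 0) {
    m_end <- grep("^ENDMDL", lines)
    if (length(m_end) > 0) lines <- lines[seq_len(m_end[1])]
  }
  rec <- substr(lines, 1, 6)
  keep <- rec %in% c("ATOM  ", "HETATM")
  lines <- lines[keep]
  if (length(lines) == 0)
    stop("PDB parse error in '", id, "': no ATOM/HETATM records found")
  bad <- nchar(lines) < 54
  if (any(bad))
    stop("PDB parse error in '", id, "': truncated ATOM record at line ",
         which(bad)[1])
  f <- function(a, b) substr(lines, a, b)
  serial <- suppressWarnings(as.integer(f(7, 11)))
  res_seq <- suppressWarnings(as.integer(f(23, 26)))
  if (anyNA(res_seq))
    stop("PDB parse error in '", id, "': unreadable residue number at record ",
         which(is.na(res_seq))[1])
  element <- toupper(trimws(f(77, 78)))
  name <- trimws(f(13, 16))
  # infer element from the atom name when columns 77-78 are absent
  guess <- toupper(substr(gsub("^[0-9']+", "", name), 1, 1))
  element <- ifelse(nzchar(element), element, guess)
  occ <- suppressWarnings(as.numeric(f(55, 60)))
  occ[is.na(occ)] <- 1.0
  atoms <- data.frame(
    serial = ifelse(is.na(serial), seq_along(lines), serial),
    name = name,
    altloc = f(17, 17),
    res_name = toupper(trimws(f(18, 20))),
    chain = trimws(f(22, 22)),
    res_seq = res_seq,
    icode = trimws(f(27, 27)),
    x = as.numeric(f(31, 38)),
    y = as.numeric(f(39, 46)),
    z = as.numeric(f(47, 54)),
    occupancy = occ,
    element = element,
    is_hetero = substr(lines, 1, 6) == "HETATM",
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z))
    stop("PDB parse error in '", id, "': unreadable coordinates")
  atoms
}

.parse_mmcif <- function(lines, id) {
  # minimal reader for the atom_site loop of an mmCIF file
  loop_idx <- grep("^loop_", lines)
  items <- grep("^_atom_site\\.", lines)
  if (length(items) == 0)
    stop("mmCIF parse error in '", id, "': no _atom_site category found")
  fields <- sub("^_atom_site\\.", "", trimws(lines[items]))
  body_start <- max(items) + 1
  body <- character(0)
  for (i in body_start:length(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || grepl("^(#|loop_|_)", ln)) break
    body <- c(body, ln)
  }
  if (length(body) == 0)
    stop("mmCIF parse error in '", id, "': empty atom_site loop")
  toks <- strsplit(body, "[[:space:]]+")
  nbad <- which(lengths(toks) != length(fields))
  if (length(nbad) > 0)
    stop("mmCIF parse error in '", id, "': token count mismatch at atom_site row ",
         nbad[1])
  tab <- as.data.frame(do.call(rbind, toks), stringsAsFactors = FALSE)
  names(tab) <- fields
  g <- function(nm, alt = NULL) {
    if (nm %in% fields) tab[[nm]]
    else if (!is.null(alt) && alt %in% fields) tab[[alt]]
    else rep(NA_character_, nrow(tab))
  }
  dot_na <- function(x) ifelse(x %in% c(".", "?"), "", x)
  model <- g("pdbx_PDB_model_num")
  if (!all(is.na(model))) tab <- tab[model == model[1], , drop = FALSE]
  g2 <- function(nm, alt = NULL) dot_na(if (nm %in% fields) tab[[nm]]
                                        else if (!is.null(alt) && alt %in% fields) tab[[alt]]
                                        else rep("", nrow(tab)))
  res_seq <- suppressWarnings(as.integer(g2("auth_seq_id", "label_seq_id")))
  atoms <- data.frame(
    serial = suppressWarnings(as.integer(g2("id"))),
    name = g2("auth_atom_id", "label_atom_id"),
    altloc = g2("label_alt_id"),
    res_name = toupper(g2("auth_comp_id", "label_comp_id")),
    chain = g2("auth_asym_id", "label_asym_id"),
    res_seq = res_seq,
    icode = g2("pdbx_PDB_ins_code"),
    x = as.numeric(g2("Cartn_x")),
    y = as.numeric(g2("Cartn_y")),
    z = as.numeric(g2("Cartn_z")),
    occupancy = {
      o <- suppressWarnings(as.numeric(g2("occupancy"))); o[is.na(o)] <- 1; o
    },
    element = toupper(g2("type_symbol")),
    is_hetero = g2("group_PDB") == "HETATM",
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$x) || anyNA(atoms$res_seq))
    stop("mmCIF parse error in '", id, "': unreadable atom_site values")
  atoms$name[!nzchar(atoms$name)] <- atoms$element[!nzchar(atoms$name)]
  atoms
}

.collapse_altlocs <- function(atoms) {
  alt <- ifelse(is.na(atoms$altloc) | atoms$altloc %in% c("", ".", " "),
                "", atoms$altloc)
  if (!any(nzchar(alt))) return(atoms)
  key <- paste(atoms$chain, atoms$res_seq, atoms$icode, atoms$res_name,
               atoms$name, sep = "\r")
  # keep highest occupancy; ties broken by first altloc letter alphabetically
  ord <- order(key, -atoms$occupancy, alt)
  atoms <- atoms[ord, , drop = FALSE]
  atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
  atoms[order(atoms$serial), , drop = FALSE]
}

#' Read a macromolecular structure from PDB or mmCIF
#'
#' Keeps the first NMR model and, per atom, the highest-occupancy alternate
#' conformer.  Hydrogens are retained in the atom table but ignored by all
#' heavy-atom geometry downstream.  Hetero groups other than water and buffer
#' compounds are registered as candidate modulator groups.
#'
#' @param path File path.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (by extension, falling back
#'   to content sniffing).
#' @param id Structure identifier; defaults to the file base name.
#' @param buffer_exclude Character vector of hetero residue names never
#'   considered modulators (see [default_buffer_exclude()]).
#' @return An `allo_structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           id = NULL,
                           buffer_exclude = default_buffer_exclude()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(id))
    id <- sub("\\.(pdb|ent|cif|mmcif)$", "", basename(path), ignore.case = TRUE)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif"
              else if (ext %in% c("pdb", "ent")) "pdb"
              else if (any(grepl("^_atom_site\\.", lines))) "mmcif"
              else "pdb"
  }
  atoms <- switch(format, pdb = .parse_pdb(lines, id),
                          mmcif = .parse_mmcif(lines, id))
  atoms <- .collapse_altlocs(atoms)
  new_structure(id, atoms, buffer_exclude)
}

#' Write a structure in PDB format
#'
#' @param structure An `allo_structure`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  a <- structure$atoms
  nm <- a$name
  # PDB atom-name column convention: 1-letter elements start in column 14
  pad <- ifelse(nchar(nm) >= 4, nm,
                ifelse(nchar(a$element) == 1,
                       sprintf(" %-3s", nm), sprintf("%-4s", nm)))
  lines <- sprintf("%-6s%5d %s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                   ifelse(a$is_hetero, "HETATM", "ATOM"),
                   a$serial %% 100000L, pad,
                   ifelse(nzchar(a$altloc), a$altloc, " "),
                   a$res_name, a$chain, a$res_seq,
                   ifelse(nzchar(a$icode), a$icode, " "),
                   a$x, a$y, a$z, a$occupancy, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# ---- geometry & group operations ----

#' Remove one hetero group from a structure
#'
#' Used to derive an apo form from a holo complex when no experimental apo
#' structure is available (rigid approximation: all other atoms untouched).
#'
#' @param structure An `allo_structure`.
#' @param group_key Residue identity string of a group in `ligand_groups`.
#' @return The structure without that group.
#' @export
strip_group <- function(structure, group_key) {
  if (!group_key %in% structure$ligand_groups)
    stop("group '", group_key, "' is not a ligand group of structure '",
         structure$id, "'")
  keep <- atom_identities(structure) != group_key
  new_structure(structure$id, structure$atoms[keep, , drop = FALSE])
}

#' Coordinate matrix of the heavy atoms in an atom table
#' @param atoms Atom data.frame (rows of `structure$atoms`).
#' @return Numeric matrix n x 3.
#' @keywords internal
heavy_coords <- function(atoms) {
  h <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  cbind(h$x, h$y, h$z)
}

#' Minimum heavy-atom distance between two atom sets
#'
#' @param atoms_a,atoms_b Atom data.frames.
#' @return Minimum pairwise Euclidean distance over heavy atoms (Angstrom).
#' @export
min_heavy_distance <- function(atoms_a, atoms_b) {
  A <- heavy_coords(atoms_a)
  B <- heavy_coords(atoms_b)
  if (nrow(A) == 0 || nrow(B) == 0)
    stop("min_heavy_distance: empty heavy-atom set")
  # |a-b|^2 = |a|^2 + |b|^2 - 2 a.b, computed as a full cross matrix
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  sqrt(max(0, min(d2)))
}

#' Geometric centroid of an atom set
#'
#' @param atoms Atom data.frame.
#' @param weighting Only `"geometric"` (unweighted mean) is supported: the
#'   centre of geometry, matching the DCC definition.
#' @param heavy_only Drop hydrogens first (default TRUE).
#' @return Numeric length-3 vector (Angstrom).
#' @export
centroid <- function(atoms, weighting = "geometric", heavy_only = TRUE) {
  weighting <- match.arg(weighting, "geometric")
  X <- if (heavy_only) heavy_coords(atoms) else cbind(atoms$x, atoms$y, atoms$z)
  if (nrow(X) == 0) stop("centroid: empty atom set")
  colMeans(X)
}

#' Split a structure's polymer atoms by residue
#'
#' @param structure An `allo_structure`.
#' @param chain Optional chain id filter.
#' @return Named list of atom data.frames, names are residue identities,
#'   in file order.
#' @export
polymer_residues <- function(structure, chain = NULL) {
  a <- structure$atoms[!structure$atoms$is_hetero, , drop = FALSE]
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  if (nrow(a) == 0) return(list())
  ids <- .residue_identity(structure$id, a$chain, a$res_seq, a$icode, a$res_name)
  split(a, factor(ids, levels = unique(ids)))
}

#' Atom rows of one hetero group
#' @param structure An `allo_structure`.
#' @param group_key Residue identity string.
#' @return Atom data.frame.
#' @export
group_atoms <- function(structure, group_key) {
  rows <- atom_identities(structure) == group_key
  if (!any(rows)) stop("no atoms for group '", group_key, "'")
  structure$atoms[rows, , drop = FALSE]
}
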