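# Internal-nanoenvironment descriptor panel.
#
# Each descriptor is an explicit, documented operationalization of a named
# nanoenvironment property: void "sponge" fraction, distance to the chain
# centre of geometry, neighbourhood hydrophobicity, Coulomb electrostatic
# potential with distance-dependent dielectric, Kabsch-Sander backbone
# hydrogen-bond energies, and contact-graph eccentricity / betweenness.
# All constants are captured in the table's provenance snapshot.

#' Distance from a residue to the chain centre of geometry
#'
#' @param residue Atom data.frame of one residue.
#' @param chain_atoms Atom data.frame of the whole chain (heavy atoms used).
#' @return Euclidean distance, Angstrom.
#' @export
distance_to_cg <- function(residue, chain_atoms) {
  sqrt(sum((centroid(residue) - centroid(chain_atoms))^2))
}

#' Residue contact graph of a chain
#'
#' Nodes are residues; an undirected edge joins residues whose minimum
#' heavy-atom distance is at most `cutoff` (default 5 Angstrom, the
#' non-bonded interaction range used throughout).
#'
#' @param residues Named list of residue atom data.frames (see
#'   [polymer_residues()]).
#' @param cutoff Edge distance threshold, Angstrom.
#' @return List with `nodes` (identity vector), `edges` (data.frame i, j,
#'   distance with i < j as node indices), and `graph` (an igraph object).
#' @export
build_contact_graph <- function(residues, cutoff = 5.0) {
  stopifnot(length(residues) >= 1)
  n <- length(residues)
  ids <- names(residues)
  coords <- lapply(residues, heavy_coords)
  # residue bounding info to skip far pairs cheaply
  cent <- t(vapply(coords, colMeans, numeric(3)))
  rad <- vapply(seq_len(n), function(i)
    sqrt(max(rowSums((coords[[i]] - rep(cent[i, ], each = nrow(coords[[i]])))^2))),
    numeric(1))
  ii <- jj <- integer(0); dd <- numeric(0)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      lb <- sqrt(sum((cent[i, ] - cent[j, ])^2)) - rad[i] - rad[j]
      if (lb > cutoff) next
      A <- coords[[i]]; B <- coords[[j]]
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
      d <- sqrt(max(0, min(d2)))
      if (d <= cutoff) { ii <- c(ii, i); jj <- c(jj, j); dd <- c(dd, d) }
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- ids
  if (length(ii) > 0)
    g <- igraph::add_edges(g, rbind(ii, jj), distance = dd)
  list(nodes = ids,
       edges = data.frame(i = ii, j = jj, distance = dd),
       graph = g)
}

#' Graph eccentricity of a residue node
#'
#' Maximum shortest-path hop count from the node to any node in its
#' connected component (0 for an isolated node).
#'
#' @param contact_graph Result of [build_contact_graph()].
#' @param node Residue identity.
#' @return Integer hop count.
#' @export
graph_eccentricity <- function(contact_graph, node) {
  g <- contact_graph$graph
  if (!node %in% igraph::V(g)$name) stop("unknown node: ", node)
  d <- igraph::distances(g, v = node, weights = NA)
  as.integer(max(d[is.finite(d)]))
}

#' Betweenness ("bottleneck") centrality of a residue node
#'
#' Fraction of shortest paths between ordered node pairs passing through the
#' node, normalised by (n-1)(n-2).
#'
#' @param contact_graph Result of [build_contact_graph()].
#' @param node Residue identity.
#' @return Centrality in \[0, 1\].
#' @export
graph_bottleneck <- function(contact_graph, node) {
  g <- contact_graph$graph
  if (!node %in% igraph::V(g)$name) stop("unknown node: ", node)
  n <- igraph::vcount(g)
  if (n < 3) return(0)
  b <- igraph::betweenness(g, v = node, directed = FALSE, weights = NA)
  as.numeric(2 * b / ((n - 1) * (n - 2)))
}

#' Void ("sponge") fraction around a residue
#'
#' Fraction of grid points within `radius` of the residue centroid lying
#' outside every atom's van der Waals sphere.  The grid is anchored at the
#' residue centroid, making the value deterministic and (up to grid
#' discretisation) rigid-motion invariant.
#'
#' @param structure An `allo_structure` (all atoms, including any bound
#'   hetero group, count as occupied volume).
#' @param residue Atom data.frame of the residue of interest.
#' @param radius Ball radius, Angstrom.
#' @param grid Grid spacing, Angstrom.
#' @return Void fraction in \[0, 1\].
#' @export
sponge_fraction <- function(structure, residue, radius = 10.0, grid = 1.0) {
  stopifnot(radius > grid, grid > 0)
  ctr <- centroid(residue)
  ax <- seq(-radius, radius, by = grid)
  G <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  G <- G[rowSums(G^2) <= radius^2, , drop = FALSE]
  G <- sweep(G, 2, ctr, "+")
  a <- structure$atoms
  a <- a[!(a$element %in% c("H", "D")), , drop = FALSE]
  near <- sqrt((a$x - ctr[1])^2 + (a$y - ctr[2])^2 + (a$z - ctr[3])^2) <=
    radius + max(a$vdw)
  a <- a[near, , drop = FALSE]
  void <- rep(TRUE, nrow(G))
  for (j in seq_len(nrow(a))) {
    p <- void
    if (!any(p)) break
    dx <- G[p, 1] - a$x[j]; dy <- G[p, 2] - a$y[j]; dz <- G[p, 3] - a$z[j]
    void[p] <- dx * dx + dy * dy + dz * dz > a$vdw[j]^2
  }
  mean(void)
}

#' Neighbourhood hydrophobicity
#'
#' Mean Kyte-Doolittle index over the residue itself and all chain residues
#' whose minimum heavy-atom distance is within `cutoff`.
#'
#' @param residues Named list of chain residue atom tables.
#' @param identity Identity of the residue of interest (must be in
#'   `names(residues)`).
#' @param cutoff Neighbourhood radius, Angstrom.
#' @return Mean hydropathy (unitless); non-standard residues contribute 0.
#' @export
hydrophobicity_env <- function(residues, identity, cutoff = 6.5) {
  if (!identity %in% names(residues)) stop("residue not in chain: ", identity)
  self <- residues[[identity]]
  kd <- function(rn) { v <- .kd_index[rn]; ifelse(is.na(v), 0, v) }
  vals <- numeric(0)
  for (nm in names(residues)) {
    d <- if (nm == identity) 0 else min_heavy_distance(self, residues[[nm]])
    if (d <= cutoff) vals <- c(vals, kd(residues[[nm]]$res_name[1]))
  }
  mean(vals)
}

#' Coulomb electrostatic potential at a residue
#'
#' Formal charges sit on side-chain reference atoms (Lys NZ +1, Arg CZ +1,
#' Asp CG -1, Glu CD -1, His CE1 +0.5) and on chain termini when the atoms
#' exist (first-residue N +1; last-residue OXT, else O, -1).  The potential
#' at the residue's reference atom (CA, else first heavy atom) is
#' V = sum 332.0636 q / (eps(r) r) with a distance-dependent dielectric
#' eps(r) = 4r and r floored at 2 Angstrom; the residue's own charges are
#' excluded.
#'
#' @param structure An `allo_structure`.
#' @param residue Atom data.frame of the residue of interest.
#' @return Potential in kcal mol^-1 e^-1 (0 when no charges exist).
#' @export
electrostatic_potential <- function(structure, residue) {
  ref <- residue[residue$name == "CA", , drop = FALSE]
  if (nrow(ref) == 0)
    ref <- residue[!(residue$element %in% c("H", "D")), , drop = FALSE]
  if (nrow(ref) == 0) stop("electrostatic_potential: residue has no heavy atom")
  r0 <- c(ref$x[1], ref$y[1], ref$z[1])
  ch <- .charge_sites(structure)
  if (nrow(ch) == 0) return(0)
  self_id <- .residue_identity(structure$id, residue$chain[1],
                               residue$res_seq[1], residue$icode[1],
                               residue$res_name[1])
  ch <- ch[ch$identity != self_id, , drop = FALSE]
  if (nrow(ch) == 0) return(0)
  r <- pmax(2, sqrt((ch$x - r0[1])^2 + (ch$y - r0[2])^2 + (ch$z - r0[3])^2))
  sum(.coulomb_k * ch$q / (4 * r * r))
}

.charge_sites <- function(structure) {
  a <- structure$atoms[!structure$atoms$is_hetero, , drop = FALSE]
  ids <- .residue_identity(structure$id, a$chain, a$res_seq, a$icode, a$res_name)
  out <- list()
  for (rn in names(.charge_atoms)) {
    spec <- .charge_atoms[[rn]]
    sel <- a$res_name == rn & a$name == spec[["atom"]]
    if (any(sel))
      out[[length(out) + 1]] <- data.frame(
        identity = ids[sel], x = a$x[sel], y = a$y[sel], z = a$z[sel],
        q = as.numeric(spec[["q"]]), stringsAsFactors = FALSE)
  }
  # termini, per chain, when the anchor atoms are present
  for (ch in unique(a$chain)) {
    b <- a[a$chain == ch, , drop = FALSE]
    first <- b[b$res_seq == min(b$res_seq), , drop = FALSE]
    nt <- first[first$name == "N", , drop = FALSE]
    if (nrow(nt) > 0)
      out[[length(out) + 1]] <- data.frame(
        identity = .residue_identity(structure$id, ch, nt$res_seq[1],
                                     nt$icode[1], nt$res_name[1]),
        x = nt$x[1], y = nt$y[1], z = nt$z[1], q = 1, stringsAsFactors = FALSE)
    last <- b[b$res_seq == max(b$res_seq), , drop = FALSE]
    ct <- last[last$name == "OXT", , drop = FALSE]
    if (nrow(ct) == 0) ct <- last[last$name == "O", , drop = FALSE]
    if (nrow(ct) > 0)
      out[[length(out) + 1]] <- data.frame(
        identity = .residue_identity(structure$id, ch, ct$res_seq[1],
                                     ct$icode[1], ct$res_name[1]),
        x = ct$x[1], y = ct$y[1], z = ct$z[1], q = -1, stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(identity = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), q = numeric(0)))
  do.call(rbind, out)
}

#' Backbone hydrogen-bond energies (Kabsch-Sander)
#'
#' Amide hydrogens are rebuilt geometrically (H = N + unit(C_prev - O_prev),
#' 1.0 Angstrom bond).  For donor residue i and acceptor residue j
#' (|i - j| >= 2) the electrostatic H-bond energy is
#' E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) kcal/mol,
#' floored at -9.9.  A residue's donor (acceptor) energy is its most
#' negative donated (accepted) E if below -0.5 kcal/mol, else 0.
#'
#' @param residues Named list of chain residue atom tables, in chain order.
#' @return data.frame with columns identity, donor_energy, acceptor_energy
#'   (kcal/mol) and partner indices (NA when none).
#' @export
hbond_energies <- function(residues) {
  n <- length(residues)
  get_atom <- function(r, nm) {
    s <- r[r$name == nm, , drop = FALSE]
    if (nrow(s) == 0) NULL else c(s$x[1], s$y[1], s$z[1])
  }
  N <- lapply(residues, get_atom, "N")
  C <- lapply(residues, get_atom, "C")
  O <- lapply(residues, get_atom, "O")
  H <- vector("list", n)
  for (i in 2:max(2, n)) {
    if (i > n) break
    if (!is.null(N[[i]]) && !is.null(C[[i - 1]]) && !is.null(O[[i - 1]])) {
      v <- C[[i - 1]] - O[[i - 1]]
      H[[i]] <- N[[i]] + v / sqrt(sum(v^2))
    }
  }
  is_pro <- vapply(residues, function(r) r$res_name[1] == "PRO", logical(1))
  E <- matrix(0, n, n) # E[i, j] = energy of donor i -> acceptor j
  dist1 <- function(a, b) sqrt(sum((a - b)^2))
  for (i in seq_len(n)) {
    if (is.null(N[[i]]) || is.null(H[[i]]) || is_pro[i]) next
    for (j in seq_len(n)) {
      if (abs(i - j) < 2) next
      if (is.null(C[[j]]) || is.null(O[[j]])) next
      rON <- dist1(O[[j]], N[[i]]); rCH <- dist1(C[[j]], H[[i]])
      rOH <- dist1(O[[j]], H[[i]]); rCN <- dist1(C[[j]], N[[i]])
      if (min(rON, rCH, rOH, rCN) < 0.5) { E[i, j] <- -9.9; next }
      e <- 0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      E[i, j] <- max(e, -9.9)
    }
  }
  donor <- apply(E, 1, min); donor_p <- apply(E, 1, which.min)
  accept <- apply(E, 2, min); accept_p <- apply(E, 2, which.min)
  missing_bb <- vapply(seq_len(n), function(i)
    is.null(N[[i]]) || is.null(C[[i]]) || is.null(O[[i]]), logical(1))
  if (any(missing_bb))
    warning("hbond_energies: ", sum(missing_bb),
            " residue(s) lack backbone N/C/O; energies set to 0")
  data.frame(
    identity = names(residues),
    donor_energy = ifelse(donor < -0.5, donor, 0),
    donor_partner = ifelse(donor < -0.5, donor_p, NA_integer_),
    acceptor_energy = ifelse(accept < -0.5, accept, 0),
    acceptor_partner = ifelse(accept < -0.5, accept_p, NA_integer_),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Compute the full per-residue descriptor table
#'
#' One row per labelled residue; columns are the descriptor panel (LASA and
#' modulator distance are deliberately excluded: label leakage).  ASA and
#' sponge are computed on the full complex (hetero atoms occlude), matching
#' descriptor extraction from deposited holo structures.  Non-finite
#' descriptor values are replaced by 0 and flagged in a companion
#' `<name>_missing` column (added only when at least one value was missing).
#'
#' @param structures List of `allo_structure` objects (or a single one).
#' @param labels Label table from [label_residues()] / [build_dataset()]
#'   covering the residues of `structures`.
#' @param config Named list overriding defaults: `probe_radius` (1.4),
#'   `n_points` (960), `contact_cutoff` (5), `hydro_cutoff` (6.5),
#'   `sponge_radius` (10), `sponge_grid` (1).
#' @return data.frame of class `allo_descriptor_table`: identity, chain,
#'   chain_key, res_name, label, then descriptor columns; provenance in
#'   `attr(, "provenance")`.
#' @export
compute_descriptor_table <- function(structures, labels, config = list()) {
  if (inherits(structures, "allo_structure")) structures <- list(structures)
  cfg <- utils::modifyList(list(probe_radius = 1.4, n_points = 960L,
                                contact_cutoff = 5.0, hydro_cutoff = 6.5,
                                sponge_radius = 10.0, sponge_grid = 1.0),
                           config)
  out <- list()
  for (s in structures) {
    asa <- compute_asa(s, cfg$probe_radius, cfg$n_points, include_hetero = TRUE)
    for (ch in unique(s$atoms$chain[!s$atoms$is_hetero])) {
      res <- polymer_residues(s, chain = ch)
      if (length(res) == 0) next
      cg <- build_contact_graph(res, cfg$contact_cutoff)
      hb <- hbond_energies(res)
      chain_atoms <- do.call(rbind, res)
      rn <- vapply(res, function(r) r$res_name[1], character(1))
      ra <- suppressWarnings(ifelse(rn %in% names(.max_asa),
        pmin(pmax(asa$per_residue[names(res)] / .max_asa[rn], 0), 1.2),
        NA_real_))
      rows <- data.frame(
        identity = names(res),
        chain = ch,
        chain_key = paste0(s$id, "_", ch),
        res_name = rn,
        rel_asa = as.numeric(ra),
        dist_cg = vapply(res, distance_to_cg, numeric(1),
                         chain_atoms = chain_atoms),
        sponge = vapply(res, function(r)
          sponge_fraction(s, r, cfg$sponge_radius, cfg$sponge_grid), numeric(1)),
        hydrophob_env = vapply(names(res), function(nm)
          hydrophobicity_env(res, nm, cfg$hydro_cutoff), numeric(1)),
        elec_pot = vapply(res, function(r)
          electrostatic_potential(s, r), numeric(1)),
        donor_energy = hb$donor_energy,
        acceptor_energy = hb$acceptor_energy,
        eccentricity = vapply(names(res), function(nm)
          as.numeric(graph_eccentricity(cg, nm)), numeric(1)),
        bottleneck = vapply(names(res), function(nm)
          graph_bottleneck(cg, nm), numeric(1)),
        stringsAsFactors = FALSE, row.names = NULL)
      out[[length(out) + 1]] <- rows
    }
  }
  tab <- do.call(rbind, out)
  m <- match(tab$identity, labels$identity)
  if (anyNA(m))
    stop("compute_descriptor_table: labels missing for ",
         sum(is.na(m)), " residue(s), e.g. ", tab$identity[is.na(m)][1])
  tab$label <- labels$label[m]
  # sentinel policy: non-finite -> 0 plus indicator column
  desc_cols <- descriptor_columns(tab)
  n_missing <- 0L
  for (cc in desc_cols) {
    bad <- !is.finite(tab[[cc]])
    if (any(bad)) {
      tab[[cc]][bad] <- 0
      tab[[paste0(cc, "_missing")]] <- as.numeric(bad)
      n_missing <- n_missing + sum(bad)
    }
  }
  tab <- tab[, c("identity", "chain", "chain_key", "res_name", "label",
                 setdiff(names(tab), c("identity", "chain", "chain_key",
                                       "res_name", "label")))]
  attr(tab, "provenance") <- c(cfg, list(
    vdw_radii = as.list(.vdw_radii), vdw_default = .vdw_default,
    coulomb_k = .coulomb_k, dielectric = "4r, r floored at 2 A",
    hbond = "Kabsch-Sander, accept if E < -0.5 kcal/mol, floor -9.9",
    max_asa_table = "Tien2013-theoretical",
    n_missing_values = n_missing))
  class(tab) <- c("allo_descriptor_table", "data.frame")
  tab
}

#' Names of the numeric descriptor columns of a table
#' @param table Descriptor table (or any data.frame following its schema).
#' @return Character vector of descriptor column names.
#' @export
descriptor_columns <- function(table) {
  setdiff(names(table)[vapply(table, is.numeric, logical(1))],
          c("lasa", "min_dist_modulator"))
}

#' Write a descriptor table with its provenance sidecar
#' @param table Descriptor table.
#' @param path TSV output path; provenance JSON goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  prov <- attr(table, "provenance")
  if (!is.null(prov))
    jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                         pretty = TRUE)
  invisible(path)
}
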