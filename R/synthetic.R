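# Synthetic fixtures with known ground truth: ideal alpha-helix chains, a
# planted multi-atom modulator at a controlled distance, and residue x
# descriptor tables with a configurable class-separating mean shift.

# NeRF atom placement: position D given A-B-C, bond |C-D|, angle B-C-D (deg)
# and torsion A-B-C-D (deg).
.place_atom <- function(A, B, C, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
         bond * sin(ang) * sin(tor))
  C + d[1] * bc + d[2] * m + d[3] * n
}

#' Build an ideal alpha-helix structure
#'
#' Backbone (N, CA, C, O) plus CB (except glycine) built from ideal peptide
#' internal coordinates with phi = -57, psi = -47, omega = 180 degrees,
#' giving ~1.5 Angstrom rise and ~100 degree turn per residue and
#' consecutive CA-CA distances of ~3.8 Angstrom.  Deterministic: a given
#' spec always yields identical coordinates.
#'
#' @param n_res Number of residues (>= 4).
#' @param sequence 1-letter sequence of length `n_res`, or `"poly-A"`.
#' @param id Structure id.
#' @param chain Chain id.
#' @return `allo_structure` with one chain and no hetero groups.
#' @export
make_helix_structure <- function(n_res, sequence = "poly-A", id = "synth",
                                 chain = "A") {
  if (n_res < 4) stop("make_helix_structure: n_res must be >= 4")
  if (identical(sequence, "poly-A")) sequence <- strrep("A", n_res)
  seq1 <- strsplit(sequence, "")[[1]]
  if (length(seq1) != n_res)
    stop("make_helix_structure: sequence length != n_res")
  res3 <- .aa_one_to_three[toupper(seq1)]
  if (anyNA(res3)) stop("make_helix_structure: invalid 1-letter code(s): ",
                        paste(unique(seq1[is.na(res3)]), collapse = ", "))
  phi <- -57; psi <- -47; omega <- 180
  # seed atoms of residue 1
  N <- list(c(0, 0, 0))
  CA <- list(c(1.458, 0, 0))
  C <- list(.place_atom(c(0, -1, 0), N[[1]], CA[[1]], 1.525, 111.2, 140))
  O <- list(); CB <- list()
  for (i in seq_len(n_res)) {
    if (i > 1) {
      N[[i]] <- .place_atom(N[[i - 1]], CA[[i - 1]], C[[i - 1]],
                            1.329, 116.2, psi)
      CA[[i]] <- .place_atom(CA[[i - 1]], C[[i - 1]], N[[i]],
                             1.458, 121.7, omega)
      C[[i]] <- .place_atom(C[[i - 1]], N[[i]], CA[[i]], 1.525, 111.2, phi)
    }
    O[[i]] <- .place_atom(N[[i]], CA[[i]], C[[i]], 1.231, 120.8, psi + 180)
    CB[[i]] <- .place_atom(C[[i]], N[[i]], CA[[i]], 1.521, 110.4, -122.5)
  }
  rows <- list(); serial <- 0L
  for (i in seq_len(n_res)) {
    at <- list(N = N[[i]], CA = CA[[i]], C = C[[i]], O = O[[i]])
    if (res3[i] != "GLY") at$CB <- CB[[i]]
    for (nm in names(at)) {
      serial <- serial + 1L
      rows[[serial]] <- data.frame(
        serial = serial, name = nm, altloc = "", res_name = res3[i],
        chain = chain, res_seq = i, icode = "",
        x = at[[nm]][1], y = at[[nm]][2], z = at[[nm]][3],
        occupancy = 1, element = substr(nm, 1, 1), is_hetero = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  new_structure(id, do.call(rbind, rows))
}

#' Plant an 8-atom modulator next to chosen residues
#'
#' Builds an 8-carbon ligand by placing one "anchor" atom per site residue
#' at distance `gap` along the residue's outward direction (iteratively
#' refined so the minimum heavy-atom distance hits `gap` exactly) and
#' stacking the remaining atoms 1.5 Angstrom further out.  The construction
#' is deterministic.  Residues outside the requested site that nevertheless
#' end up within the labelling cutoff are reported in the returned
#' ground-truth site (attribute `"site"`), keeping generator and labeller
#' consistent.
#'
#' @param structure `allo_structure` (typically [make_helix_structure()]).
#' @param site_residues Integer vector of residue numbers (1 to 8 of them)
#'   to form the site.
#' @param gap Target minimum distance, Angstrom.
#' @param tol Allowed deviation per site residue (default 0.3).
#' @param label_cutoff Distance rule used for the reported ground truth
#'   (default 5).
#' @return Holo `allo_structure` with the modulator as hetero group "LIG";
#'   attributes: `site` (ground-truth identities), `site_requested`.
#' @export
plant_modulator <- function(structure, site_residues, gap = 3.5, tol = 0.3,
                            label_cutoff = 5.0) {
  res <- polymer_residues(structure)
  seqs <- vapply(res, function(r) r$res_seq[1], numeric(1))
  if (!all(site_residues %in% seqs))
    stop("plant_modulator: site residue(s) not in structure")
  if (length(site_residues) > 8)
    stop("plant_modulator: at most 8 site residues (one anchor atom each)")
  site_idx <- match(site_residues, seqs)
  site_coords <- lapply(res[site_idx], heavy_coords)
  poly <- heavy_coords(structure$atoms[!structure$atoms$is_hetero, ,
                                       drop = FALSE])
  prot_ctr <- colMeans(poly)
  # radial outward direction: component orthogonal to the chain's principal
  # axis, so anchors sit on the barrel surface instead of drifting axially
  ax <- stats::prcomp(poly)$rotation[, 1]
  md <- function(p, X) sqrt(max(0, min(rowSums(
    sweep(X, 2, p, "-")^2))))
  anchors <- matrix(0, length(site_idx), 3)
  for (k in seq_along(site_idx)) {
    X <- site_coords[[k]]
    u <- colMeans(X) - prot_ctr
    u <- u - sum(u * ax) * ax
    nu <- sqrt(sum(u^2)); u <- if (nu < 1e-6) c(1, 0, 0) else u / nu
    # most exposed atom along u, then walk out until min distance == gap
    a <- X[which.max(X %*% u), ]
    p <- a + gap * u
    for (it in 1:20) {
      d <- md(p, X)
      if (abs(d - gap) < 1e-6) break
      p <- p + (gap - d) * u
    }
    anchors[k, ] <- p
  }
  extra <- 8 - nrow(anchors)
  if (extra > 0) {
    ctr_u <- colMeans(anchors) - prot_ctr
    ctr_u <- ctr_u - sum(ctr_u * ax) * ax
    ctr_u <- ctr_u / sqrt(sum(ctr_u^2))
    outer_atoms <- sweep(anchors[rep_len(seq_len(nrow(anchors)), extra), ,
                                 drop = FALSE], 2, 1.5 * ctr_u, "+")
    Q <- rbind(anchors, outer_atoms)
  } else Q <- anchors
  dev <- vapply(seq_along(site_coords), function(i) {
    d2 <- outer(rowSums(Q^2), rowSums(site_coords[[i]]^2), "+") -
      2 * Q %*% t(site_coords[[i]])
    sqrt(max(0, min(d2))) - gap
  }, numeric(1))
  if (max(abs(dev)) > tol)
    stop(sprintf(paste0("plant_modulator: infeasible placement (worst ",
                        "deviation %.2f A > %.2f); try a smaller or more ",
                        "surface-exposed site"), max(abs(dev)), tol))
  lig <- data.frame(
    serial = max(structure$atoms$serial) + seq_len(nrow(Q)),
    name = paste0("C", seq_len(nrow(Q))), altloc = "", res_name = "LIG",
    chain = structure$atoms$chain[1], res_seq = max(seqs) + 1L, icode = "",
    x = Q[, 1], y = Q[, 2], z = Q[, 3], occupancy = 1, element = "C",
    is_hetero = TRUE, stringsAsFactors = FALSE)
  holo <- new_structure(structure$id,
                        rbind(structure$atoms[, names(lig)], lig))
  lig_atoms <- group_atoms(holo, holo$ligand_groups[1])
  d_all <- vapply(res, function(r) min_heavy_distance(r, lig_atoms),
                  numeric(1))
  attr(holo, "site") <- names(res)[d_all <= label_cutoff]
  attr(holo, "site_requested") <- names(res)[site_idx]
  holo
}

#' Synthetic labelled helix fixture
#'
#' Convenience wrapper: a helix with a random small-alphabet sequence and a
#' contiguous planted site, reproducible by seed.
#'
#' @param n_res Residues in the helix.
#' @param site_size Contiguous site length.
#' @param gap Modulator gap, Angstrom.
#' @param seed Integer seed.
#' @param id Structure id.
#' @param alphabet 1-letter codes to draw the sequence from.  The default
#'   5-letter alphabet keeps per-residue-type training subsets populated at
#'   desk scale.
#' @return Holo `allo_structure` with attributes `site`, `site_requested`.
#' @export
make_labelled_fixture <- function(n_res = 32L, site_size = 4L, gap = 3.5,
                                  seed = 1L, id = sprintf("fx%03d", seed),
                                  alphabet = c("A", "L", "S", "K", "E")) {
  # helical-face offsets: residues on the same side of the helix barrel
  face <- c(0L, 1L, 3L, 4L, 7L, 8L, 10L, 11L)
  if (site_size > length(face))
    stop("make_labelled_fixture: site_size too large")
  offs <- face[seq_len(site_size)]
  .with_seed(seed, {
    seq1 <- paste(sample(alphabet, n_res, replace = TRUE), collapse = "")
    start <- sample(seq(4L, n_res - max(offs) - 3L), 1)
    helix <- make_helix_structure(n_res, seq1, id = id)
    plant_modulator(helix, start + offs, gap = gap)
  })
}

#' Synthetic residue x descriptor table with a planted class shift
#'
#' AFR rows are Normal(shift, 1) on the informative columns and Normal(0,1)
#' elsewhere; FR rows are Normal(0,1) everywhere.  Residue types are drawn
#' from `residue_mix`.
#'
#' @param n_pos,n_neg AFR and FR row counts.
#' @param n_features Total descriptor columns.
#' @param n_informative Number of shifted columns (first columns).
#' @param shift Standardised mean difference delta (>= 0).
#' @param residue_mix Named probability vector over 3-letter residue types,
#'   or NULL for uniform over the 20 standard types.
#' @param seed Integer seed.
#' @return `allo_descriptor_table`-style data.frame (identity, chain,
#'   chain_key, res_name, label, f1..fK).  Informative column names in
#'   `attr(, "informative")`.
#' @export
synth_feature_table <- function(n_pos, n_neg, n_features = 10L,
                                n_informative = 4L, shift = 1.0,
                                residue_mix = NULL, seed = 1L) {
  stopifnot(n_pos > 0, n_neg > 0, shift >= 0, n_informative <= n_features)
  .with_seed(seed, {
    n <- n_pos + n_neg
    lab <- c(rep("AFR", n_pos), rep("FR", n_neg))
    types <- if (is.null(residue_mix)) sample(.aa_three, n, replace = TRUE)
             else sample(names(residue_mix), n, replace = TRUE,
                         prob = residue_mix)
    X <- matrix(rnorm(n * n_features), n, n_features)
    if (n_informative > 0 && n_pos > 0)
      X[seq_len(n_pos), seq_len(n_informative)] <-
        X[seq_len(n_pos), seq_len(n_informative)] + shift
    colnames(X) <- sprintf("f%02d", seq_len(n_features))
    tab <- data.frame(identity = sprintf("synth_T_%d_%s", seq_len(n), types),
                      chain = "T", chain_key = "synth_T", res_name = types,
                      label = lab, stringsAsFactors = FALSE)
    tab <- cbind(tab, as.data.frame(X))
    attr(tab, "informative") <- colnames(X)[seq_len(n_informative)]
    attr(tab, "provenance") <- list(n_pos = n_pos, n_neg = n_neg,
                                    shift = shift, seed = seed)
    class(tab) <- c("allo_descriptor_table", "data.frame")
    tab
  })
}

#' Bayes ROC-AUC of the planted Gaussian shift
#'
#' For `k` independent informative features shifted by delta, the optimal
#' score is their sum and AUC = Phi(delta * sqrt(k) / sqrt(2)).
#'
#' @param shift Per-feature shift delta.
#' @param k Number of informative features.
#' @return AUC in \[0.5, 1\].
#' @export
bayes_auc <- function(shift, k) stats::pnorm(shift * sqrt(k) / sqrt(2))
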