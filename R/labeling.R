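# LASA computation and AFR/FR labeling.
#
# LASA = ASA_apo - ASA_complex per residue; the AFR label itself uses the
# operational distance rule: a residue is an AFR iff its minimum heavy-atom
# distance to the modulator group is <= 5 Angstrom.  LASA is computed and
# stored alongside (and may optionally be required to be positive).

#' Per-residue loss of accessible surface area (LASA)
#'
#' LASA = ASA_apo - ASA_complex, both sides computed with identical probe
#' radius and point count.  When `apo` is NULL the apo form is derived from
#' the holo structure by deleting the modulator group (rigid approximation).
#'
#' @param holo Holo `allo_structure` (modulator bound).
#' @param apo Apo `allo_structure` or NULL.
#' @param modulator Group key of the modulator in `holo`.
#' @param probe_radius,n_points ASA parameters, see [compute_asa()].
#' @return Named numeric vector, residue identity -> LASA (Angstrom^2),
#'   negative round-off clamped to zero.
#' @export
compute_lasa <- function(holo, apo = NULL, modulator = pick_modulator(holo),
                         probe_radius = 1.4, n_points = 960L) {
  derived_apo <- is.null(apo)
  if (derived_apo) {
    if (is.na(modulator)) stop("compute_lasa: no modulator group in '",
                               holo$id, "' and no apo structure given")
    apo <- strip_group(holo, modulator)
  }
  asa_c <- compute_asa(holo, probe_radius, n_points, include_hetero = TRUE)
  asa_a <- compute_asa(apo, probe_radius, n_points, include_hetero = TRUE)
  # apo residues are keyed by the apo structure id; align on chain/res part
  strip_id <- function(x, id) substring(x, nchar(id) + 2)
  kc <- strip_id(names(asa_c$per_residue), holo$id)
  ka <- strip_id(names(asa_a$per_residue), apo$id)
  if (!setequal(kc, ka)) {
    off <- c(setdiff(kc, ka), setdiff(ka, kc))
    stop("compute_lasa: holo/apo residue sets differ: ",
         paste(head(off, 10), collapse = ", "))
  }
  lasa <- asa_a$per_residue[match(kc, ka)] - asa_c$per_residue
  lasa[lasa < 1e-6] <- 0
  setNames(as.numeric(lasa), names(asa_c$per_residue))
}

#' Label every polymer residue as AFR or FR
#'
#' AFR iff the residue's minimum heavy-atom distance to the modulator group
#' is at most `distance_cutoff` (default 5 Angstrom).  LASA values are
#' attached from [compute_lasa()].
#'
#' @param holo Holo `allo_structure`.
#' @param modulator Group key; default picks the largest qualifying hetero
#'   group.
#' @param distance_cutoff AFR distance criterion, Angstrom.
#' @param apo Optional apo structure for the LASA term.
#' @param require_lasa If TRUE, additionally require LASA > 0 for AFR status.
#' @param compute_lasa_values Set FALSE to skip the (costlier) ASA pass and
#'   fill `lasa` with NA; labels are unaffected.
#' @param probe_radius,n_points ASA parameters.
#' @return data.frame with columns identity, chain, res_name, lasa,
#'   min_dist_modulator, label ("AFR"/"FR").
#' @export
label_residues <- function(holo, modulator = pick_modulator(holo),
                           distance_cutoff = 5.0, apo = NULL,
                           require_lasa = FALSE,
                           compute_lasa_values = TRUE,
                           probe_radius = 1.4, n_points = 960L) {
  res <- polymer_residues(holo)
  if (length(res) == 0) stop("label_residues: no polymer residues")
  has_mod <- !is.na(modulator) && length(modulator) == 1
  if (!has_mod && (require_lasa || is.null(apo)) && length(holo$ligand_groups) > 0)
    stop("label_residues: could not pick a modulator for '", holo$id,
         "'; pass one explicitly via `modulator`")
  dists <- rep(NA_real_, length(res))
  if (has_mod) {
    mod_atoms <- group_atoms(holo, modulator)
    dists <- vapply(res, function(r) min_heavy_distance(r, mod_atoms),
                    numeric(1))
  }
  lasa <- rep(NA_real_, length(res))
  if (compute_lasa_values && has_mod)
    lasa <- compute_lasa(holo, apo, modulator, probe_radius, n_points)[names(res)]
  lab <- if (has_mod) ifelse(dists <= distance_cutoff, "AFR", "FR")
         else rep("FR", length(res))
  if (require_lasa && has_mod)
    lab[lab == "AFR" & !(lasa > 0)] <- "FR"
  first <- vapply(res, function(r) r$chain[1], character(1))
  rn <- vapply(res, function(r) r$res_name[1], character(1))
  data.frame(identity = names(res), chain = first, res_name = rn,
             lasa = as.numeric(lasa), min_dist_modulator = as.numeric(dists),
             label = lab, stringsAsFactors = FALSE, row.names = NULL)
}

#' Assemble a labelled residue table from many structures
#'
#' Each entry is a holo structure (path or `allo_structure`), optionally with
#' an apo counterpart and an explicit modulator key.  Failures are recorded
#' and skipped; the run only errors if no rows at all survive.
#'
#' @param entries List; each element a list with `holo` (path or structure)
#'   and optional `apo`, `modulator`.
#' @param distance_cutoff AFR distance rule, Angstrom.
#' @param compute_lasa_values Forwarded to [label_residues()].
#' @param ... Further arguments to [label_residues()].
#' @return data.frame of stacked [label_residues()] rows plus a
#'   `chain_key` column ("<structure id>_<chain>"); failed entries in
#'   `attr(, "errors")`.
#' @export
build_dataset <- function(entries, distance_cutoff = 5.0,
                          compute_lasa_values = TRUE, ...) {
  rows <- list(); errs <- list()
  for (k in seq_along(entries)) {
    e <- entries[[k]]
    tab <- tryCatch({
      holo <- if (is.character(e$holo)) read_structure(e$holo) else e$holo
      apo <- if (is.null(e$apo)) NULL
             else if (is.character(e$apo)) read_structure(e$apo) else e$apo
      mod <- if (is.null(e$modulator)) pick_modulator(holo) else e$modulator
      tb <- label_residues(holo, modulator = mod,
                           distance_cutoff = distance_cutoff, apo = apo,
                           compute_lasa_values = compute_lasa_values, ...)
      tb$chain_key <- paste0(holo$id, "_", tb$chain)
      tb
    }, error = function(err) err)
    if (inherits(tab, "error")) errs[[length(errs) + 1]] <-
        list(entry = k, message = conditionMessage(tab))
    else rows[[length(rows) + 1]] <- tab
  }
  if (length(rows) == 0) stop("build_dataset: no labelled rows produced (",
                              length(errs), " failures)")
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$identity))
    stop("build_dataset: duplicate residue identities (same chain listed twice?): ",
         out$identity[duplicated(out$identity)][1])
  rownames(out) <- NULL
  attr(out, "errors") <- errs
  out
}
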