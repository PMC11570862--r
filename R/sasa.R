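# Shrake-Rupley accessible surface area with a deterministic golden-spiral
# point set.  Determinism matters: LASA = ASA_apo - ASA_complex must be
# exactly reproducible, so no RNG is involved anywhere.

.golden_spiral <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Accessible surface area (Shrake-Rupley)
#'
#' Rolls a probe sphere over the van der Waals surface by testing, for every
#' heavy atom, which of `n_points` quasi-uniform sphere points at radius
#' `r_vdw + probe_radius` fall inside any neighbouring atom's expanded
#' sphere.  Hydrogens are ignored.  Hetero atoms (e.g. a bound modulator)
#' occlude protein atoms when `include_hetero = TRUE`; their own ASA is
#' reported in `per_atom` but never summed into protein `per_residue` values.
#'
#' @param structure An `allo_structure`.
#' @param probe_radius Probe radius in Angstrom (water: 1.4).
#' @param n_points Number of sphere sample points per atom (>= 92).
#' @param include_hetero Should hetero atoms participate (as occluders and
#'   in `per_atom`)? Default TRUE.
#' @return An object of class `allo_asa`: list with `per_atom` (named by
#'   atom row index within the computed set), `per_residue` (named by
#'   polymer residue identity), `probe_radius`, `n_points`.
#' @export
compute_asa <- function(structure, probe_radius = 1.4, n_points = 960L,
                        include_hetero = TRUE) {
  stopifnot(n_points >= 92L, probe_radius >= 0)
  a <- structure$atoms
  a <- a[!(a$element %in% c("H", "D")), , drop = FALSE]
  if (!include_hetero) a <- a[!a$is_hetero, , drop = FALSE]
  n <- nrow(a)
  if (n == 0) stop("compute_asa: structure has no heavy atoms")
  X <- cbind(a$x, a$y, a$z)
  R <- a$vdw + probe_radius
  S <- .golden_spiral(n_points)
  # neighbour lists via a single cross-distance pass (fixture-scale n)
  d2 <- outer(rowSums(X^2), rowSums(X^2), "+") - 2 * X %*% t(X)
  area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (R[i] + R)^2 & seq_len(n) != i)
    P <- sweep(S * R[i], 2, X[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      pj <- free
      if (!any(pj)) break
      dx <- P[pj, 1] - X[j, 1]; dy <- P[pj, 2] - X[j, 2]; dz <- P[pj, 3] - X[j, 3]
      free[pj] <- dx * dx + dy * dy + dz * dz > R[j]^2
    }
    area[i] <- sum(free) / n_points * 4 * pi * R[i]^2
  }
  ids <- .residue_identity(structure$id, a$chain, a$res_seq, a$icode, a$res_name)
  poly <- !a$is_hetero
  per_res <- tapply(area[poly], factor(ids[poly], levels = unique(ids[poly])), sum)
  structure(list(per_atom = setNames(area, ids),
                 per_residue = setNames(as.numeric(per_res), names(per_res)),
                 probe_radius = probe_radius, n_points = as.integer(n_points)),
            class = "allo_asa")
}

#' Relative accessibility of a residue
#'
#' Residue ASA divided by the theoretical maximum ASA of its type
#' (Tien et al. values), clipped to \[0, 1.2\].
#'
#' @param residue_asa Residue ASA in Angstrom^2.
#' @param res_name 3-letter residue code (one of the 20 standard types).
#' @return Fraction in \[0, 1.2\].
#' @export
relative_asa <- function(residue_asa, res_name) {
  res_name <- toupper(res_name)
  bad <- !(res_name %in% names(.max_asa))
  if (any(bad))
    stop("relative_asa: unknown residue type(s) ",
         paste(unique(res_name[bad]), collapse = ", "),
         "; valid codes: ", paste(names(.max_asa), collapse = ", "))
  pmin(pmax(residue_asa / unname(.max_asa[res_name]), 0), 1.2)
}
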