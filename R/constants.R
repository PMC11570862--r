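# Physico-chemical lookup tables used across modules.  All values are
# recorded in the provenance snapshot of every descriptor table.

# Bondi-style van der Waals radii (Angstrom); unknown elements fall back to
# the carbon value with a warning at parse time.
.vdw_radii <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  H = 1.20, D = 1.20, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98,
  SE = 1.90
)
.vdw_default <- 1.70

# Theoretical maximum accessible surface areas (Tien et al. 2013), Angstrom^2.
.max_asa <- c(
  ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
  GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
  LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
  SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0
)

# Kyte-Doolittle hydropathy index.
.kd_index <- c(
  ALA =  1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5, CYS =  2.5,
  GLN = -3.5, GLU = -3.5, GLY = -0.4, HIS = -3.2, ILE =  4.5,
  LEU =  3.8, LYS = -3.9, MET =  1.9, PHE =  2.8, PRO = -1.6,
  SER = -0.8, THR = -0.7, TRP = -0.9, TYR = -1.3, VAL =  4.2
)

.aa_three <- names(.max_asa)

.aa_one_to_three <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
  Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
  L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
  S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL"
)

# Formal charges placed on side-chain reference atoms for the Coulomb
# descriptor; His carries a half charge on CE1 as a crude protonation average.
.charge_atoms <- list(
  LYS = c(atom = "NZ",  q =  1.0),
  ARG = c(atom = "CZ",  q =  1.0),
  ASP = c(atom = "CG",  q = -1.0),
  GLU = c(atom = "CD",  q = -1.0),
  HIS = c(atom = "CE1", q =  0.5)
)

.coulomb_k <- 332.0636 # kcal mol^-1 A e^-2

#' Default crystallisation-buffer / ion exclusion list
#'
#' Hetero groups whose residue names appear in this list are never treated as
#' candidate allosteric modulators (waters are excluded unconditionally).
#' The list ships as a plain-text config file and can be replaced by the user.
#'
#' @return Character vector of 3-letter (or shorter) hetero residue codes.
#' @export
default_buffer_exclude <- function() {
  path <- system.file("extdata", "buffer_exclude.txt", package = "alloscan")
  if (nzchar(path)) {
    x <- readLines(path, warn = FALSE)
    x <- toupper(trimws(sub("#.*", "", x)))
    x[nzchar(x)]
  } else {
    c("HOH", "WAT", "SO4", "PO4", "GOL", "EDO", "PEG", "ACT", "DMS",
      "CL", "NA", "MG", "ZN", "CA", "K", "MN", "FE", "NI", "CU", "BR", "IOD")
  }
}

.is_water <- function(res_name) toupper(res_name) %in% c("HOH", "WAT", "DOD")

.vdw_for_element <- function(element) {
  el <- toupper(element)
  r <- unname(.vdw_radii[el])
  miss <- is.na(r)
  if (any(miss)) {
    warning("unknown element(s) ", paste(unique(el[miss]), collapse = ", "),
            ": using fallback vdW radius ", .vdw_default, " A")
    r[miss] <- .vdw_default
  }
  r
}
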