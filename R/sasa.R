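# Solvent-accessible surface area.
#
# An in-package Shrake-Rupley engine (probe 1.4 A, 960 test points per atom,
# golden-section spiral) with NACCESS-compatible van der Waals radii and
# extended Ala-X-Ala tripeptide reference areas, so that per-residue
# *relative* all-atom SASA can be computed on the ligand-free protein.

# NACCESS-style van der Waals radii (A) by element; default 1.80
.VDW_RADII <- c(C = 1.87, N = 1.65, O = 1.40, S = 1.85, P = 1.90,
                SE = 1.90, H = 1.00, D = 1.00)
.VDW_DEFAULT <- 1.80

# Reference all-atom accessible areas (A^2) of residue X in an extended
# Ala-X-Ala tripeptide (Hubbard & Thornton reference set, as used for
# relative accessibility).
.SASA_REF <- c(
  ALA = 107.95, ARG = 238.76, ASN = 143.94, ASP = 140.39, CYS = 134.28,
  GLN = 178.50, GLU = 172.25, GLY =  80.10, HIS = 182.88, ILE = 175.12,
  LEU = 178.63, LYS = 200.78, MET = 194.15, PHE = 199.48, PRO = 136.13,
  SER = 116.50, THR = 139.27, TRP = 249.36, TYR = 187.05, VAL = 151.44)

# deterministic golden-section spiral on the unit sphere
.sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.vdw_radius <- function(elesy) {
  r <- .VDW_RADII[toupper(elesy)]
  r[is.na(r)] <- .VDW_DEFAULT
  unname(r)
}

#' Shrake-Rupley accessible surface area per atom
#'
#' @param xyz n x 3 coordinate matrix (A).
#' @param radii van der Waals radii per atom (A).
#' @param probe probe radius (A), default 1.4.
#' @param n_points number of test points per atom sphere, default 960.
#' @return numeric vector of per-atom accessible areas (A^2).
#' @export
sasa_atoms <- function(xyz, radii, probe = 1.4, n_points = 960L) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  stopifnot(length(radii) == n)
  if (n == 0) return(numeric(0))
  sp <- .sphere_points(n_points)
  rs <- radii + probe
  out <- numeric(n)
  dd <- .cross_dist(xyz, xyz)
  for (i in seq_len(n)) {
    nb <- which(dd[i, ] < rs[i] + rs & seq_len(n) != i)
    pts <- sweep(sp * rs[i], 2, xyz[i, ], "+")
    if (length(nb) > 0) {
      acc <- rep(TRUE, n_points)
      for (j in nb) {
        dj <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
              (pts[, 3] - xyz[j, 3])^2
        acc <- acc & (dj >= rs[j]^2)
        if (!any(acc)) break
      }
      frac <- sum(acc) / n_points
    } else frac <- 1
    out[i] <- 4 * pi * rs[i]^2 * frac
  }
  out
}

#' Per-residue relative solvent-accessible surface area
#'
#' Computes all-atom Shrake-Rupley SASA on the ligand-free protein: all
#' heteroatoms, all hydrogens and any short polymer-ligand chain (at most
#' \code{max_polymer_length} residues) are stripped before the calculation,
#' so the accessibility corresponds to the apo structure. Each residue's
#' area is expressed as a percentage of its extended-tripeptide reference
#' area and clamped to [0, 100].
#'
#' @param structure a \code{cpass_structure}.
#' @param probe probe radius (A).
#' @param n_points test points per atom.
#' @param max_polymer_length chains with at most this many residues are
#'   treated as bound polymer ligands and removed first.
#' @return data frame with one row per protein residue: \code{res_key},
#'   \code{resid}, \code{chain}, \code{resno}, \code{insert}, \code{area}
#'   (A^2) and \code{rel_sasa} (percent, clamped to [0, 100]; \code{NA} for
#'   residues without a reference area).
#' @export
compute_relative_sasa <- function(structure, probe = 1.4, n_points = 960L,
                                  max_polymer_length = 13L) {
  at <- structure$atom
  prot <- at[at$type == "ATOM" & !at$is_hydrogen, , drop = FALSE]
  if (nrow(prot) == 0) stop("structure has no protein atoms")

  # strip short polymer chains (bound peptide/nucleotide ligands)
  keep_chain <- vapply(unique(prot$chain), function(ch) {
    sum(!duplicated(prot$res_key[prot$chain == ch])) > max_polymer_length
  }, logical(1))
  chains <- unique(prot$chain)[keep_chain]
  if (length(chains) == 0) chains <- unique(prot$chain)  # lone short chain: keep
  prot <- prot[prot$chain %in% chains, , drop = FALSE]

  area <- sasa_atoms(as.matrix(prot[, c("x", "y", "z")]),
                     .vdw_radius(prot$elesy), probe = probe,
                     n_points = n_points)
  agg <- tapply(area, prot$res_key, sum)

  first <- prot[!duplicated(prot$res_key), , drop = FALSE]
  res_area <- as.numeric(agg[first$res_key])
  ref <- .SASA_REF[toupper(first$resid)]
  rel <- pmin(100, pmax(0, 100 * res_area / ref))
  data.frame(res_key = first$res_key, resid = first$resid,
             chain = first$chain, resno = first$resno,
             insert = first$insert, area = res_area,
             rel_sasa = as.numeric(rel), stringsAsFactors = FALSE)
}
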