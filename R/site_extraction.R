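# Binding-site construction.
#
# A ligand-defined binding site is the set of amino acids with at least one
# heavy atom within a distance cutoff (default 6 A) of any ligand heavy
# atom. A manually defined site is a user-supplied residue list whose
# reference point is the residues' heavy-atom center of mass. Each site
# residue carries its Calpha/Cbeta coordinates, relative SASA and shortest
# heavy-atom distance d_i to the ligand (or reference point); the site
# stores d_min = min(d_i), the anchor of the d_min/d_i distance weighting.

.new_binding_site <- function(source_id, ligand, reference_point, residues,
                              mode) {
  stopifnot(nrow(residues) > 0)
  structure(list(
    source_id = source_id,
    ligand = ligand,
    reference_point = reference_point,
    residues = residues,
    d_min = min(residues$d_i),
    mode = mode
  ), class = "cpass_site")
}

#' @export
print.cpass_site <- function(x, ...) {
  cat("<cpass_site>", x$source_id,
      if (x$mode == "ligand_defined") paste0("[", x$ligand$code, "]")
      else "[manual]",
      nrow(x$residues), "residues, d_min =", round(x$d_min, 3), "A\n")
  invisible(x)
}

#' Number of residues in a binding site
#' @param site a \code{cpass_site}
#' @return integer residue count
#' @export
site_size <- function(site) nrow(site$residues)

# build the per-residue site table for a set of residue keys
.site_residue_table <- function(structure, res_keys, ref_xyz, sasa_tab) {
  at <- structure$atom
  rows <- vector("list", length(res_keys))
  for (k in seq_along(res_keys)) {
    key <- res_keys[k]
    g <- at[at$res_key == key & at$type == "ATOM", , drop = FALSE]
    heavy <- g[!g$is_hydrogen, , drop = FALSE]
    aa <- toupper(g$resid[1])
    ca <- heavy[heavy$elety == "CA", , drop = FALSE]
    if (nrow(ca) == 0)
      stop("residue ", aa, " ", key, " lacks a CA atom")
    cb <- heavy[heavy$elety == "CB", , drop = FALSE]
    d_i <- min(.cross_dist(as.matrix(heavy[, c("x", "y", "z")]), ref_xyz))
    d_i <- max(d_i, 1e-6)   # d_i > 0 by contract
    rel <- if (is.null(sasa_tab)) NA_real_ else {
      m <- sasa_tab$rel_sasa[match(key, sasa_tab$res_key)]
      if (length(m) == 0) NA_real_ else m
    }
    rows[[k]] <- data.frame(
      aa = aa, chain = g$chain[1], resno = g$resno[1],
      insert = g$insert[1], res_key = key,
      ca_x = ca$x[1], ca_y = ca$y[1], ca_z = ca$z[1],
      cb_x = if (nrow(cb) > 0) cb$x[1] else NA_real_,
      cb_y = if (nrow(cb) > 0) cb$y[1] else NA_real_,
      cb_z = if (nrow(cb) > 0) cb$z[1] else NA_real_,
      rel_sasa = rel, d_i = d_i, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Extract a ligand-defined binding site
#'
#' All amino acids with at least one heavy atom within \code{cutoff} of at
#' least one ligand heavy atom form the site. \code{d_i} is each residue's
#' minimum heavy-atom distance to the ligand.
#'
#' @param structure a \code{cpass_structure}.
#' @param ligand a \code{cpass_ligand} belonging to \code{structure}.
#' @param cutoff inclusion distance in Angstrom (default 6).
#' @param rel_sasa optional precomputed relative-SASA table as returned by
#'   \code{\link{compute_relative_sasa}} (or a compatible data frame, e.g.
#'   injected values for synthetic fixtures). Computed on demand when
#'   \code{NULL}.
#' @return a \code{cpass_site} with \code{mode = "ligand_defined"}.
#' @export
extract_site <- function(structure, ligand, cutoff = 6.0, rel_sasa = NULL) {
  lig_xyz <- .ligand_heavy_xyz(ligand)
  if (nrow(lig_xyz) == 0) stop("ligand has no heavy atoms")
  at <- structure$atom
  prot <- at[at$type == "ATOM" & !at$is_hydrogen &
             toupper(at$resid) %in% .AA3, , drop = FALSE]
  # the ligand's own residues (polymer ligands) are never site residues
  if (isTRUE(ligand$is_polymer)) {
    lig_keys <- unique(.res_key(ligand$atoms$chain, ligand$atoms$resno,
                                ligand$atoms$insert))
    prot <- prot[!(prot$res_key %in% lig_keys), , drop = FALSE]
  }
  if (nrow(prot) == 0) stop("empty binding site: no protein residues")
  dmat <- .cross_dist(as.matrix(prot[, c("x", "y", "z")]), lig_xyz)
  near <- apply(dmat, 1, min) <= cutoff
  keys <- unique(prot$res_key[near])
  if (length(keys) == 0)
    stop("empty binding site: no residue within ", cutoff,
         " A of ligand ", ligand$code)
  if (is.null(rel_sasa)) rel_sasa <- compute_relative_sasa(structure)
  res <- .site_residue_table(structure, keys, lig_xyz, rel_sasa)
  .new_binding_site(source_id = structure$id, ligand = ligand,
                    reference_point = colMeans(lig_xyz),
                    residues = res, mode = "ligand_defined")
}

#' Parse a manually defined binding site
#'
#' Reads a plain-text residue list (one residue per line: three-letter code,
#' residue number, chain identifier; whitespace- or comma-separated, with
#' \code{#} comments) and builds a site whose reference point is the listed
#' residues' heavy-atom center of mass. The ligand-RMSD factor is disabled
#' for manual sites when scoring.
#'
#' @param site_file path to the residue list.
#' @param structure the \code{cpass_structure} the residues refer to.
#' @param rel_sasa optional precomputed relative-SASA table.
#' @return a \code{cpass_site} with \code{mode = "manual"} and no ligand.
#' @export
parse_manual_site <- function(site_file, structure, rel_sasa = NULL) {
  lines <- readLines(site_file, warn = FALSE)
  at <- structure$atom
  keys <- character(0)
  for (i in seq_along(lines)) {
    raw <- sub("#.*", "", lines[i])
    if (!nzchar(trimws(raw))) next
    tok <- strsplit(trimws(raw), "[,[:space:]]+")[[1]]
    if (length(tok) < 3)
      stop("manual site line ", i, " ('", trimws(raw),
           "'): expected 'AA NUMBER CHAIN'")
    aa <- toupper(tok[1]); resno <- suppressWarnings(as.integer(tok[2]))
    chain <- tok[3]
    if (is.na(resno))
      stop("manual site line ", i, ": residue number '", tok[2],
           "' is not an integer")
    hit <- at[at$type == "ATOM" & at$chain == chain & at$resno == resno, ,
              drop = FALSE]
    if (nrow(hit) == 0)
      stop("manual site line ", i, ": residue ", resno, " chain ", chain,
           " not found in structure")
    found <- toupper(hit$resid[1])
    if (found != aa)
      stop("manual site line ", i, ": residue ", resno, " chain ", chain,
           " is ", found, ", not ", aa)
    keys <- c(keys, hit$res_key[1])
  }
  keys <- unique(keys)
  if (length(keys) == 0) stop("manual site file lists no residues")

  heavy <- at[at$res_key %in% keys & at$type == "ATOM" & !at$is_hydrogen, ,
              drop = FALSE]
  com <- colMeans(as.matrix(heavy[, c("x", "y", "z")]))
  ref <- matrix(com, nrow = 1)
  if (is.null(rel_sasa)) rel_sasa <- compute_relative_sasa(structure)
  res <- .site_residue_table(structure, keys, ref, rel_sasa)
  .new_binding_site(source_id = structure$id, ligand = NULL,
                    reference_point = com, residues = res, mode = "manual")
}
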