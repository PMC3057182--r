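# Structure I/O: PDB reading/writing and ligand identification.
# Parsing is delegated to bio3d; this module normalizes the atom table
# (alternate locations resolved, hydrogens flagged, one model selected)
# and identifies candidate ligands under the database inclusion rules.

#' Read a PDB-format structure
#'
#' Parses a PDB file into a uniform atom table. Alternate locations are
#' resolved by keeping the highest-occupancy conformer (ties broken in favour
#' of conformer "A"), hydrogens are retained but flagged, and for multi-model
#' (NMR) files a single model is selected.
#'
#' @param path path to a PDB-format file.
#' @param model model number to keep for multi-model files (default 1).
#' @return an object of class \code{cpass_structure}: a list with elements
#'   \code{id} (file stem), \code{atom} (data frame with one row per atom:
#'   \code{type}, \code{eleno}, \code{elety}, \code{resid}, \code{chain},
#'   \code{resno}, \code{insert}, \code{x}, \code{y}, \code{z}, \code{o},
#'   \code{elesy}, \code{is_hydrogen}).
#' @export
read_structure <- function(path, model = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) stop("cannot parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("empty structure: ", path)

  # model selection: bio3d stores per-model coordinates in the xyz matrix
  nmod <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model > nmod) stop("model ", model, " requested but file has ", nmod)
  if (is.matrix(pdb$xyz) && nmod > 1L) {
    xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }

  at <- .resolve_altloc(at)
  if (!all(is.finite(at$x)) || !all(is.finite(at$y)) || !all(is.finite(at$z)))
    stop("non-finite coordinates in ", path)

  elesy <- at$elesy
  bad <- is.na(elesy) | elesy == ""
  if (any(bad)) elesy[bad] <- .element_from_elety(at$elety[bad])
  at$elesy <- toupper(elesy)
  at$is_hydrogen <- at$elesy %in% c("H", "D")
  at$insert[is.na(at$insert)] <- ""
  at$chain[is.na(at$chain)] <- " "
  if (is.null(at$o)) at$o <- 1
  at$o[is.na(at$o)] <- 1

  .new_structure(id = tools::file_path_sans_ext(basename(path)), atom = at)
}

# keep highest-occupancy alternate conformer per atom; ties -> conformer "A"
.resolve_altloc <- function(at) {
  alt <- at$alt
  alt[is.na(alt)] <- ""
  if (all(alt == "")) return(at)
  key <- paste(at$chain, at$resno, at$insert, at$resid, at$elety, sep = "|")
  occ <- at$o
  occ[is.na(occ)] <- 1
  # order so the preferred conformer comes first within each key
  pref <- order(key, -occ, ifelse(alt == "", "0", alt))
  at <- at[pref, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$insert, at$resid,
                             at$elety, sep = "|")), , drop = FALSE]
  at[order(at$eleno), , drop = FALSE]
}

.element_from_elety <- function(elety) {
  e <- gsub("[0-9' ]", "", elety)
  two <- toupper(substr(e, 1, 2))
  one <- toupper(substr(e, 1, 1))
  ifelse(two %in% c("FE", "ZN", "MG", "MN", "CL", "BR", "NA", "CU", "CO",
                    "NI", "CA", "SE", "CD"), two, one)
}

.new_structure <- function(id, atom) {
  atom$res_key <- .res_key(atom$chain, atom$resno, atom$insert)
  structure(list(id = id, atom = atom), class = "cpass_structure")
}

#' @export
print.cpass_structure <- function(x, ...) {
  prot <- x$atom[x$atom$type == "ATOM", ]
  cat("<cpass_structure>", x$id, "\n")
  cat("  chains:", paste(unique(prot$chain), collapse = " "),
      " protein residues:", length(unique(prot$res_key)),
      " heteroatoms:", sum(x$atom$type == "HETATM"), "\n")
  invisible(x)
}

#' Write a structure back to PDB format
#'
#' @param structure a \code{cpass_structure}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_structure <- function(structure, path) {
  at <- structure$atom
  bio3d::write.pdb(pdb = NULL, file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   type = at$type, resno = at$resno, resid = at$resid,
                   eleno = at$eleno, elety = at$elety, chain = at$chain,
                   insert = ifelse(at$insert == "", NA, at$insert),
                   o = at$o, b = if (is.null(at$b)) rep(0, nrow(at)) else at$b,
                   elesy = at$elesy)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Ligand identification

#' Default ligand exclusion list
#'
#' HET codes for water, common buffers, cryoprotectants, detergents and lone
#' ions that never define a binding site. Shipped as an editable text
#' resource (one code per line, '#' comments).
#'
#' @param path optional path to an alternative exclusion list.
#' @return character vector of excluded HET codes.
#' @export
default_ligand_exclusions <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "ligand_exclusion.txt", package = "cpassr")
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- toupper(trimws(lines))
  lines[nzchar(lines)]
}

#' Identify candidate ligands in a structure
#'
#' A ligand is any heteroatom group not on the exclusion list, or a short
#' polymer chain (peptide or nucleic acid) of at most thirteen residues.
#' Water is always excluded. The result is deterministic and order-stable:
#' ligands are sorted by code, chain and residue number.
#'
#' @param structure a \code{cpass_structure}.
#' @param exclusion_list character vector of HET codes to skip
#'   (default \code{\link{default_ligand_exclusions}()}).
#' @param max_polymer_length maximum residue count for a polymer ligand.
#' @return list of \code{cpass_ligand} objects. May be empty.
#' @export
identify_ligands <- function(structure,
                             exclusion_list = default_ligand_exclusions(),
                             max_polymer_length = 13L) {
  at <- structure$atom
  excl <- unique(c(toupper(exclusion_list), .WATER_CODES))
  out <- list()

  het <- at[at$type == "HETATM" & !(toupper(at$resid) %in% excl), ,
            drop = FALSE]
  if (nrow(het) > 0) {
    for (k in unique(het$res_key)) {
      g <- het[het$res_key == k, , drop = FALSE]
      out[[length(out) + 1L]] <-
        .new_ligand(code = toupper(g$resid[1]),
                    instance = paste0(g$chain[1], g$resno[1], g$insert[1]),
                    atoms = g, is_polymer = FALSE)
    }
  }

  # a short chain is a bound polymer ligand only when a longer (receptor)
  # chain is present; a lone short chain is the protein itself
  prot <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(prot) > 0) {
    chain_len <- vapply(unique(prot$chain), function(ch)
      sum(!duplicated(prot$res_key[prot$chain == ch])), 1L)
    if (any(chain_len > max_polymer_length)) {
      for (ch in unique(prot$chain)[chain_len <= max_polymer_length]) {
        ca <- prot[prot$chain == ch, , drop = FALSE]
        resids <- toupper(ca$resid[!duplicated(ca$res_key)])
        if (all(resids %in% c(.AA3, .NUC_CODES))) {
          out[[length(out) + 1L]] <-
            .new_ligand(code = paste0("CHAIN_", ch), instance = ch,
                        atoms = ca, is_polymer = TRUE,
                        polymer_length = length(resids))
        }
      }
    }
  }

  if (length(out) == 0) return(out)
  ord <- order(vapply(out, function(l) l$code, ""),
               vapply(out, function(l) l$instance, ""))
  out[ord]
}

.new_ligand <- function(code, instance, atoms, is_polymer,
                        polymer_length = NA_integer_) {
  heavy <- atoms[!atoms$is_hydrogen, , drop = FALSE]
  structure(list(
    code = code,
    instance = instance,
    atoms = atoms[, c("elety", "elesy", "resid", "chain", "resno", "insert",
                      "x", "y", "z", "is_hydrogen")],
    heavy_atom_count = nrow(heavy),
    is_polymer = is_polymer,
    polymer_length = if (is_polymer) as.integer(polymer_length) else NA_integer_
  ), class = "cpass_ligand")
}

#' @export
print.cpass_ligand <- function(x, ...) {
  cat("<cpass_ligand>", x$code, "(", x$instance, ")",
      x$heavy_atom_count, "heavy atoms",
      if (x$is_polymer) paste0("polymer[", x$polymer_length, "]") else "",
      "\n")
  invisible(x)
}

# heavy-atom coordinate matrix of a ligand
.ligand_heavy_xyz <- function(ligand) {
  h <- ligand$atoms[!ligand$atoms$is_hydrogen, , drop = FALSE]
  as.matrix(h[, c("x", "y", "z")])
}
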