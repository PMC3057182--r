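# Reference benchmark over user-supplied experimental structures.
#
# Compares one query protein's ligand-defined site against a set of other
# structures binding the same cofactor, reporting percent similarity for
# each — the classic check being an aspartate aminotransferase PLP site
# against other PLP-dependent enzymes. The PDB files must already be on
# disk; nothing is downloaded.

#' Compare one ligand-defined site against other structures
#'
#' Reads each structure, extracts the binding site of the first ligand
#' matching \code{ligand_code} (relative SASA computed on the ligand-free
#' protein), aligns the query site onto each target site and reports
#' percent similarity, sorted best-first.
#'
#' @param query_path PDB file of the query protein.
#' @param target_paths PDB files of the comparison proteins.
#' @param ligand_code HET code of the site-defining ligand (e.g.
#'   \code{"PLP"}).
#' @param options scoring options.
#' @param cutoff site extraction cutoff (A).
#' @return data frame: \code{target}, \code{percent}, \code{s_ab},
#'   \code{s_query}, \code{ligand_rmsd}, \code{n_matched}.
#' @export
cpass_benchmark <- function(query_path, target_paths, ligand_code = "PLP",
                            options = score_options(), cutoff = 6.0) {
  site_of <- function(path) {
    st <- read_structure(path)
    ligs <- identify_ligands(st)
    hit <- Filter(function(l) l$code == toupper(ligand_code), ligs)
    if (length(hit) == 0)
      stop("no ", ligand_code, " ligand found in ", path)
    extract_site(st, hit[[1]], cutoff = cutoff)
  }
  query <- site_of(query_path)
  rows <- lapply(target_paths, function(p) {
    target <- site_of(p)
    al <- find_best_alignment(query, target, options = options)
    sim <- score_alignment(query, target, al, options = options)
    data.frame(target = tools::file_path_sans_ext(basename(p)),
               percent = sim$percent, s_ab = sim$s_ab,
               s_query = sim$s_aa, ligand_rmsd = sim$ligand_rmsd_raw,
               n_matched = sim$n_pairs, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$percent), , drop = FALSE]
}
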