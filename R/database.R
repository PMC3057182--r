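# Binding-site database: record construction, uniqueness filtering and a
# diff-able plain-text serialization (one self-describing file per site,
# plus a manifest).
#
# Two sites are duplicates only when they share the same ligand AND at
# least 90% global sequence identity AND at least 80% residue identity in
# the aligned binding site; a different ligand, or falling under either
# threshold, marks a unique site.

.new_site_record <- function(cpass_id, site, ligand_code, source_sequence,
                             function_note = NA_character_) {
  stopifnot(site$mode == "ligand_defined")
  structure(list(cpass_id = cpass_id, site = site,
                 ligand_code = toupper(ligand_code),
                 source_sequence = source_sequence,
                 function_note = function_note),
            class = "cpass_record")
}

#' @export
print.cpass_record <- function(x, ...) {
  cat("<cpass_record>", x$cpass_id, "ligand", x$ligand_code,
      site_size(x$site), "residues\n")
  invisible(x)
}

# one-letter sequence of the chains contributing residues to a site
.chain_sequence <- function(structure, chains) {
  at <- structure$atom
  prot <- at[at$type == "ATOM" & toupper(at$resid) %in% .AA3 &
             at$chain %in% chains, , drop = FALSE]
  first <- prot[!duplicated(prot$res_key), , drop = FALSE]
  first <- first[order(first$chain, first$resno, first$insert), ,
                 drop = FALSE]
  paste(aa3to1(first$resid), collapse = "")
}

#' Build a deduplicated site database from structures
#'
#' Extracts one candidate record per (structure, identified ligand) pair,
#' skipping ligands with empty sites (a message is logged), then removes
#' duplicates. The first-seen record survives, so the result is stable for
#' a fixed input order; shuffling the input changes which representative
#' survives but not the record count.
#'
#' @param structures list of \code{cpass_structure} objects.
#' @param exclusion_list HET codes that never define a site.
#' @param cutoff site extraction cutoff (A).
#' @param rel_sasa optional list of precomputed relative-SASA tables,
#'   parallel to \code{structures} (computed on demand when \code{NULL}).
#' @param deduplicate apply \code{\link{is_duplicate}} filtering.
#' @return named list of \code{cpass_record} objects.
#' @export
build_database <- function(structures,
                           exclusion_list = default_ligand_exclusions(),
                           cutoff = 6.0, rel_sasa = NULL,
                           deduplicate = TRUE) {
  records <- list()
  for (s in seq_along(structures)) {
    st <- structures[[s]]
    sasa <- if (!is.null(rel_sasa)) rel_sasa[[s]] else
      attr(st, "rel_sasa") %||% NULL
    ligs <- tryCatch(identify_ligands(st, exclusion_list),
                     error = function(e) {
                       message("skipping ", st$id, ": ",
                               conditionMessage(e))
                       list()
                     })
    counts <- list()
    for (lig in ligs) {
      site <- tryCatch(
        extract_site(st, lig, cutoff = cutoff, rel_sasa = sasa),
        error = function(e) {
          message("skipping ", st$id, "/", lig$code, ": ",
                  conditionMessage(e))
          NULL
        })
      if (is.null(site)) next
      chain <- site$residues$chain[1]
      key <- paste(st$id, chain, lig$code, sep = "_")
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      id <- paste(key, counts[[key]], sep = "_")
      records[[id]] <- .new_site_record(
        cpass_id = id, site = site, ligand_code = lig$code,
        source_sequence = .chain_sequence(st, unique(site$residues$chain)))
    }
  }
  if (!deduplicate || length(records) < 2) return(records)
  kept <- records[1]
  for (k in seq_along(records)[-1]) {
    dup <- any(vapply(kept, function(r) is_duplicate(records[[k]], r),
                      logical(1)))
    if (!dup) kept[[records[[k]]$cpass_id]] <- records[[k]]
  }
  kept
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Global sequence identity (percent)
#'
#' Needleman-Wunsch global alignment under BLOSUM62 log-odds scores (gap
#' open 10, extend 0.5); identity is matches over alignment length.
#'
#' @param seq_a,seq_b character strings of one-letter residue codes.
#' @return percent identity in [0, 100].
#' @export
global_sequence_identity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  Biostrings::pid(pa, type = "PID1")
}

#' Binding-site sequence similarity (percent)
#'
#' Percent of residues identical among the pairs matched by the best site
#' alignment, relative to the smaller site's residue count.
#'
#' @param site_a,site_b \code{cpass_site} objects.
#' @param options,model passed to \code{\link{find_best_alignment}}.
#' @return percent in [0, 100].
#' @export
site_sequence_similarity <- function(site_a, site_b,
                                     options = score_options(),
                                     model = cpass_substitution()) {
  al <- find_best_alignment(site_a, site_b, options = options,
                            model = model)
  if (al$n_pairs == 0) return(0)
  same <- sum(site_a$residues$aa[al$pairs[, 1]] ==
              site_b$residues$aa[al$pairs[, 2]])
  100 * same / min(site_size(site_a), site_size(site_b))
}

#' Are two site records duplicates?
#'
#' TRUE only when the ligand codes agree, global sequence identity is at
#' least 90% and binding-site sequence similarity is at least 80%.
#' Symmetric in its arguments.
#'
#' @param rec_a,rec_b \code{cpass_record} objects.
#' @return logical.
#' @export
is_duplicate <- function(rec_a, rec_b) {
  if (rec_a$ligand_code != rec_b$ligand_code) return(FALSE)
  if (global_sequence_identity(rec_a$source_sequence,
                               rec_b$source_sequence) < 90) return(FALSE)
  s1 <- site_sequence_similarity(rec_a$site, rec_b$site)
  s2 <- site_sequence_similarity(rec_b$site, rec_a$site)
  max(s1, s2) >= 80
}

# ---------------------------------------------------------------------------
# serialization: one plain-text file per record + a manifest

.fmt <- function(x) sprintf("%.17g", x)

.write_one_record <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste(..., sep = "\t"), con)
  site <- rec$site
  w("cpass_site_record", "1")
  w("cpass_id", rec$cpass_id)
  w("source_id", site$source_id)
  w("ligand_code", rec$ligand_code)
  w("mode", site$mode)
  w("sequence", rec$source_sequence)
  w("function_note",
    if (is.na(rec$function_note)) "" else rec$function_note)
  w("reference_point", paste(.fmt(site$reference_point), collapse = " "))
  w("[residues]")
  r <- site$residues
  w(paste(c("aa", "chain", "resno", "insert", "ca_x", "ca_y", "ca_z",
            "cb_x", "cb_y", "cb_z", "rel_sasa", "d_i"), collapse = "\t"))
  for (k in seq_len(nrow(r)))
    w(paste(c(r$aa[k], r$chain[k], r$resno[k],
              if (r$insert[k] == "") "." else r$insert[k],
              .fmt(c(r$ca_x[k], r$ca_y[k], r$ca_z[k],
                     r$cb_x[k], r$cb_y[k], r$cb_z[k],
                     r$rel_sasa[k], r$d_i[k]))), collapse = "\t"))
  lig <- site$ligand
  w("[ligand]")
  w("code", lig$code)
  w("instance", lig$instance)
  w("is_polymer", as.character(lig$is_polymer))
  w("polymer_length", as.character(lig$polymer_length))
  w("[ligand_atoms]")
  w(paste(c("elety", "elesy", "resid", "chain", "resno", "insert",
            "x", "y", "z", "is_hydrogen"), collapse = "\t"))
  a <- lig$atoms
  for (k in seq_len(nrow(a)))
    w(paste(c(a$elety[k], a$elesy[k], a$resid[k], a$chain[k], a$resno[k],
              if (is.na(a$insert[k]) || a$insert[k] == "") "." else
                a$insert[k],
              .fmt(c(a$x[k], a$y[k], a$z[k])),
              as.character(a$is_hydrogen[k])), collapse = "\t"))
  invisible(path)
}

#' Write site records to a directory
#'
#' One self-describing text file per record plus a \code{manifest.tsv}
#' listing every stored identifier.
#'
#' @param records named list of \code{cpass_record}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_records <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(records, function(r) r$cpass_id, "")
  files <- paste0(gsub("[^A-Za-z0-9_.-]", "_", ids), ".site")
  for (k in seq_along(records))
    .write_one_record(records[[k]], file.path(dir, files[k]))
  utils::write.table(
    data.frame(cpass_id = ids, file = files,
               ligand_code = vapply(records, function(r) r$ligand_code, ""),
               n_residues = vapply(records,
                                   function(r) site_size(r$site), 1L)),
    file.path(dir, "manifest.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

.read_one_record <- function(path) {
  lines <- readLines(path, warn = FALSE)
  need <- function(field) {
    hit <- grep(paste0("^", field, "\t"), lines)
    if (length(hit) == 0)
      stop("malformed site record ", basename(path),
           ": missing field '", field, "'")
    sub(paste0("^", field, "\t"), "", lines[hit[1]])
  }
  if (!grepl("^cpass_site_record", lines[1]))
    stop("malformed site record ", basename(path),
         ": missing field 'cpass_site_record'")
  cpass_id <- need("cpass_id")
  source_id <- need("source_id")
  ligand_code <- need("ligand_code")
  mode <- need("mode")
  seqs <- need("sequence")
  fnote <- sub("^function_note\t?", "",
               lines[grep("^function_note", lines)[1]])
  if (identical(fnote, "")) fnote <- NA_character_
  refp <- as.numeric(strsplit(need("reference_point"), " ")[[1]])

  sec <- function(name) {
    i <- which(lines == paste0("[", name, "]"))
    if (length(i) == 0)
      stop("malformed site record ", basename(path),
           ": missing field '[", name, "]'")
    i[1]
  }
  i_res <- sec("residues"); i_lig <- sec("ligand")
  i_la <- sec("ligand_atoms")
  res <- utils::read.table(text = lines[(i_res + 1):(i_lig - 1)],
                           header = TRUE, sep = "\t",
                           colClasses = c("character", "character",
                                          "integer", "character",
                                          rep("numeric", 8)))
  res$insert[res$insert == "."] <- ""
  res$res_key <- .res_key(res$chain, res$resno, res$insert)
  la <- utils::read.table(text = lines[(i_la + 1):length(lines)],
                          header = TRUE, sep = "\t",
                          colClasses = c(rep("character", 4), "integer",
                                         "character", rep("numeric", 3),
                                         "logical"))
  la$insert[la$insert == "."] <- ""
  lig <- structure(list(
    code = need("code"), instance = need("instance"),
    is_polymer = as.logical(need("is_polymer")),
    polymer_length = suppressWarnings(
      as.integer(need("polymer_length"))),
    atoms = la, heavy_atom_count = sum(!la$is_hydrogen)),
    class = "cpass_ligand")
  site <- .new_binding_site(source_id = source_id, ligand = lig,
                            reference_point = refp, residues = res,
                            mode = mode)
  .new_site_record(cpass_id = cpass_id, site = site,
                   ligand_code = ligand_code, source_sequence = seqs,
                   function_note = fnote)
}

#' Read site records from a directory
#'
#' @param dir directory written by \code{\link{write_records}}.
#' @return named list of \code{cpass_record}.
#' @export
read_records <- function(dir) {
  man_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(man_path)) stop("no manifest.tsv under ", dir)
  man <- utils::read.table(man_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  out <- lapply(file.path(dir, man$file), .read_one_record)
  stats::setNames(out, vapply(out, function(r) r$cpass_id, ""))
}
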