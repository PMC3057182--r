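# Search runner: the four comparison modes (one vs all, single pair, one
# vs list, list vs list) with optional ligand filtering, local parallel
# chunking and a ranked result table. Scoring is deterministic, so chunked
# and serial runs produce identical tables; the percent threshold is a
# reporting filter, never applied at scoring time.

#' Describe a search job
#'
#' @param query a \code{cpass_site} (uploaded query) for modes
#'   \code{full_db}, \code{single_id} and \code{id_list}; ignored for
#'   \code{id_list_pairwise}, which compares database records directly.
#' @param mode one of \code{"full_db"}, \code{"single_id"},
#'   \code{"id_list"}, \code{"id_list_pairwise"}.
#' @param target_ids record identifiers to compare against (one for
#'   \code{single_id}; all records for \code{full_db}).
#' @param query_ids record identifiers used as queries
#'   (\code{id_list_pairwise} only).
#' @param ligand_filter restrict targets to records with this ligand code.
#' @param options scoring options (\code{\link{score_options}}).
#' @param workers number of parallel workers (forked processes).
#' @param min_percent reporting threshold on percent similarity (default
#'   30; set 0 to report everything).
#' @return a \code{cpass_job} list.
#' @export
search_job <- function(query = NULL,
                       mode = c("full_db", "single_id", "id_list",
                                "id_list_pairwise"),
                       target_ids = NULL, query_ids = NULL,
                       ligand_filter = NULL, options = score_options(),
                       workers = 1L, min_percent = 30) {
  mode <- match.arg(mode)
  if (mode == "id_list_pairwise") {
    if (is.null(query_ids) || is.null(target_ids))
      stop("id_list_pairwise mode needs query_ids and target_ids")
    if (!is.null(query))
      stop("id_list_pairwise mode compares database records; ",
           "no uploaded query site is allowed")
  } else {
    if (is.null(query) || !inherits(query, "cpass_site"))
      stop("mode '", mode, "' needs a cpass_site query")
    if (mode == "single_id" && length(target_ids) != 1)
      stop("single_id mode needs exactly one target id")
    if (mode == "id_list" && is.null(target_ids))
      stop("id_list mode needs target_ids")
  }
  structure(list(query = query, mode = mode, target_ids = target_ids,
                 query_ids = query_ids, ligand_filter = ligand_filter,
                 options = options, workers = as.integer(workers),
                 min_percent = min_percent),
            class = "cpass_job")
}

.check_ids <- function(ids, db) {
  missing <- setdiff(ids, names(db))
  if (length(missing) > 0)
    stop("unknown cpass_id(s): ", paste(missing, collapse = ", "))
}

# resolve a job into the (query_id, target_id) task table
.job_tasks <- function(job, db) {
  if (length(db) == 0) stop("empty database")
  targets <- switch(job$mode,
    full_db = names(db),
    single_id = ,
    id_list = ,
    id_list_pairwise = job$target_ids)
  .check_ids(targets, db)
  if (!is.null(job$ligand_filter)) {
    keep <- vapply(db[targets], function(r)
      r$ligand_code == toupper(job$ligand_filter), logical(1))
    targets <- targets[keep]
  }
  if (job$mode == "id_list_pairwise") {
    .check_ids(job$query_ids, db)
    expand.grid(query_id = job$query_ids, target_id = targets,
                stringsAsFactors = FALSE)
  } else {
    qid <- paste0(job$query$source_id, ":query")
    if (length(targets) == 0)
      data.frame(query_id = character(0), target_id = character(0))
    else data.frame(query_id = qid, target_id = targets,
                    stringsAsFactors = FALSE)
  }
}

.score_task_rows <- function(tasks, job, db, model) {
  rows <- vector("list", nrow(tasks))
  for (k in seq_len(nrow(tasks))) {
    qid <- tasks$query_id[k]; tid <- tasks$target_id[k]
    qsite <- if (job$mode == "id_list_pairwise") db[[qid]]$site
             else job$query
    tsite <- db[[tid]]$site
    al <- find_best_alignment(qsite, tsite, options = job$options)
    sim <- score_alignment(qsite, tsite, al, options = job$options)
    rows[[k]] <- data.frame(
      query_id = qid, target_id = tid,
      s_query = sim$s_aa, s_ab = sim$s_ab, percent = sim$percent,
      ligand_rmsd = sim$ligand_rmsd_raw, n_matched = sim$n_pairs,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

.sort_results <- function(tab) {
  tab[order(-tab$percent, tab$target_id, tab$query_id), , drop = FALSE]
}

#' Run a search job
#'
#' One row per comparison: query id, target id, the query self-score
#' S_query, the comparison score S_ab, percent similarity, the raw
#' inter-ligand RMSD and the number of matched residues; sorted by percent
#' (descending; ties by target id). Rows below \code{min_percent} are
#' dropped at reporting time.
#'
#' @param job a \code{cpass_job}.
#' @param db named list of \code{cpass_record} (see
#'   \code{\link{build_database}}, \code{\link{read_records}}).
#' @param model substitution model.
#' @return data frame of ranked results.
#' @export
run_search <- function(job, db, model = cpass_substitution()) {
  tasks <- .job_tasks(job, db)
  if (nrow(tasks) == 0)
    return(data.frame(query_id = character(0), target_id = character(0),
                      s_query = numeric(0), s_ab = numeric(0),
                      percent = numeric(0), ligand_rmsd = numeric(0),
                      n_matched = integer(0)))
  if (job$workers > 1 && nrow(tasks) > 1) {
    idx <- sort(rep_len(seq_len(job$workers), nrow(tasks)))
    parts <- parallel::mclapply(
      split(seq_len(nrow(tasks)), idx),
      function(sel) .score_task_rows(tasks[sel, , drop = FALSE], job, db,
                                     model),
      mc.cores = job$workers)
    tab <- do.call(rbind, parts)
  } else {
    tab <- .score_task_rows(tasks, job, db, model)
  }
  rownames(tab) <- NULL
  tab <- tab[tab$percent >= job$min_percent, , drop = FALSE]
  out <- .sort_results(tab)
  rownames(out) <- NULL
  out
}

#' Split a job into independent sub-jobs
#'
#' Partitions the target identifiers into \code{n_chunks} contiguous
#' blocks. Running every sub-job and merging (\code{\link{merge_results}})
#' reproduces the unchunked result exactly.
#'
#' @param job a \code{cpass_job}.
#' @param n_chunks number of sub-jobs (>= 1).
#' @param db the database the job will run against (needed to enumerate
#'   \code{full_db} targets).
#' @return list of \code{cpass_job} objects.
#' @export
chunk_jobs <- function(job, n_chunks, db) {
  stopifnot(n_chunks >= 1)
  tasks <- .job_tasks(job, db)
  targets <- unique(tasks$target_id)
  n_chunks <- min(n_chunks, max(1L, length(targets)))
  idx <- sort(rep_len(seq_len(n_chunks), length(targets)))
  lapply(split(targets, idx), function(ids) {
    sub <- job
    sub$mode <- if (job$mode == "id_list_pairwise") "id_list_pairwise"
                else "id_list"
    sub$target_ids <- ids
    sub$ligand_filter <- NULL   # already applied when enumerating tasks
    sub
  })
}

#' Merge sub-job result tables
#'
#' @param parts list of result tables from \code{\link{run_search}}.
#' @return single table, sorted like an unchunked run.
#' @export
merge_results <- function(parts) {
  out <- .sort_results(do.call(rbind, parts))
  rownames(out) <- NULL
  out
}

#' Write a result table as TSV
#'
#' @param results data frame from \code{\link{run_search}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
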