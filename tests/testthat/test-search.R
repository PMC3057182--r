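# Search modes, filtering, chunking and determinism.

local_db <- local({
  lib <- NULL
  function() {
    if (is.null(lib)) lib <<- make_decoy_library(n = 10, seed = 71,
                                                 n_positives = 2)
    lib
  }
})

test_that("a query finds its own record at exactly 100 percent", {
  lib <- local_db()
  db <- lib$records
  self_rec <- cpassr:::.new_site_record("self_A_ATP_1", lib$query, "ATP",
                                        "ACDEFGHIKLMNPQRSTVWY")
  db[["self_A_ATP_1"]] <- self_rec
  res <- run_search(search_job(query = lib$query, mode = "full_db",
                               min_percent = 0), db)
  expect_equal(res$target_id[1], "self_A_ATP_1")
  expect_equal(res$percent[1], 100, tolerance = 1e-9)
  expect_true(all(diff(res$percent) <= 0))
})

test_that("the ligand filter restricts the rows reported", {
  lib <- local_db()
  res <- run_search(search_job(query = lib$query, mode = "full_db",
                               ligand_filter = "PLP", min_percent = 0),
                    lib$records)
  lig <- vapply(lib$records[res$target_id], function(r) r$ligand_code, "")
  expect_true(all(lig == "PLP"))
  expect_gt(nrow(res), 0)
})

test_that("single_id and id_list modes check their identifiers", {
  lib <- local_db()
  ids <- names(lib$records)
  one <- run_search(search_job(query = lib$query, mode = "single_id",
                               target_ids = ids[1], min_percent = 0),
                    lib$records)
  expect_equal(nrow(one), 1L)
  some <- run_search(search_job(query = lib$query, mode = "id_list",
                                target_ids = ids[2:4], min_percent = 0),
                     lib$records)
  expect_setequal(some$target_id, ids[2:4])
  expect_error(run_search(search_job(query = lib$query, mode = "single_id",
                                     target_ids = "nope", min_percent = 0),
                          lib$records), "unknown cpass_id")
  expect_error(run_search(search_job(query = lib$query, mode = "full_db"),
                          list()), "empty database")
})

test_that("list-vs-list mode compares records without an uploaded site", {
  lib <- local_db()
  ids <- names(lib$records)
  expect_error(search_job(query = lib$query, mode = "id_list_pairwise",
                          query_ids = ids[1], target_ids = ids[2]),
               "no uploaded query")
  res <- run_search(search_job(mode = "id_list_pairwise",
                               query_ids = ids[1:2], target_ids = ids[3:5],
                               min_percent = 0), lib$records)
  expect_equal(nrow(res), 6L)
  expect_setequal(unique(res$query_id), ids[1:2])
})

test_that("the report threshold trims rows but never rescores", {
  lib <- local_db()
  all_rows <- run_search(search_job(query = lib$query, mode = "full_db",
                                    min_percent = 0), lib$records)
  trimmed <- run_search(search_job(query = lib$query, mode = "full_db",
                                   min_percent = 30), lib$records)
  expect_equal(trimmed, all_rows[all_rows$percent >= 30, ],
               ignore_attr = TRUE)
})

test_that("chunked and parallel runs reproduce the serial table exactly", {
  lib <- local_db()
  job <- search_job(query = lib$query, mode = "full_db", min_percent = 0)
  serial <- run_search(job, lib$records)

  par_job <- job; par_job$workers <- 2L
  expect_identical(run_search(par_job, lib$records), serial)

  for (n_chunks in c(1L, 3L, length(lib$records))) {
    subs <- chunk_jobs(job, n_chunks, lib$records)
    expect_equal(length(subs), n_chunks)
    merged <- merge_results(lapply(subs, run_search, db = lib$records))
    expect_identical(merged, serial)
  }

  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_results_tsv(serial, f1)
  write_results_tsv(merge_results(
    lapply(chunk_jobs(job, 3L, lib$records), run_search,
           db = lib$records)), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("every reported score is reproducible from the stored sites", {
  lib <- local_db()
  res <- run_search(search_job(query = lib$query, mode = "full_db",
                               min_percent = 0), lib$records)
  for (k in seq_len(min(4, nrow(res)))) {
    site <- lib$records[[res$target_id[k]]]$site
    al <- find_best_alignment(lib$query, site)
    sim <- score_alignment(lib$query, site, al)
    expect_equal(sim$s_ab, res$s_ab[k], tolerance = 1e-9)
    expect_equal(sim$percent, res$percent[k], tolerance = 1e-9)
  }
})
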