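# PDB reading/writing and ligand identification.

test_that("structures round-trip through PDB within coordinate precision", {
  st <- make_site_structure(fixture_spec(n_site_residues = 4, seed = 2))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(st, path)
  back <- read_structure(path)
  expect_equal(nrow(back$atom), nrow(st$atom))
  expect_equal(back$atom$resid, st$atom$resid)
  expect_equal(back$atom$res_key, st$atom$res_key)
  expect_lt(max(abs(back$atom$x - st$atom$x)), 1e-3)
  expect_lt(max(abs(back$atom$y - st$atom$y)), 1e-3)
  expect_lt(max(abs(back$atom$z - st$atom$z)), 1e-3)
})

test_that("unreadable and empty inputs fail loudly", {
  expect_error(read_structure(file.path(tempdir(), "absent.pdb")),
               "not found")
  empty <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", empty)
  expect_error(read_structure(empty))
})

pdb_line <- function(type, eleno, elety, resid, chain, resno, x, y, z,
                     occ = 1, alt = " ", elesy = " C") {
  sprintf("%-6s%5d %-4s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, eleno, elety, alt, resid, chain, resno, x, y, z, occ, 0,
          elesy)
}

test_that("multi-model files yield the selected model only", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    pdb_line("ATOM", 1, "CA", "ALA", "A", 1, 1, 0, 0),
    pdb_line("ATOM", 2, "CA", "GLY", "A", 2, 4, 0, 0),
    pdb_line("ATOM", 3, "CA", "SER", "A", 3, 8, 0, 0),
    "ENDMDL",
    "MODEL        2",
    pdb_line("ATOM", 1, "CA", "ALA", "A", 1, 100, 0, 0),
    pdb_line("ATOM", 2, "CA", "GLY", "A", 2, 104, 0, 0),
    pdb_line("ATOM", 3, "CA", "SER", "A", 3, 108, 0, 0),
    "ENDMDL", "END"), path)
  m1 <- read_structure(path, model = 1)
  m2 <- read_structure(path, model = 2)
  expect_equal(length(unique(m1$atom$res_key)), 3L)
  expect_equal(m1$atom$x[1], 1)
  expect_equal(m2$atom$x[1], 100)
  expect_error(read_structure(path, model = 3), "model")
})

test_that("alternate locations keep the highest-occupancy conformer", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.4, alt = "A"),
    pdb_line("ATOM", 2, "CA", "ALA", "A", 1, 9, 0, 0, occ = 0.6, alt = "B"),
    pdb_line("ATOM", 3, "CA", "GLY", "A", 2, 4, 0, 0, occ = 0.5, alt = "A"),
    pdb_line("ATOM", 4, "CA", "GLY", "A", 2, 5, 0, 0, occ = 0.5, alt = "B"),
    "END"), path)
  st <- read_structure(path)
  ca1 <- st$atom[st$atom$resno == 1 & st$atom$elety == "CA", ]
  expect_equal(nrow(ca1), 1L)
  expect_equal(ca1$x, 9)          # occupancy 0.6 wins
  ca2 <- st$atom[st$atom$resno == 2 & st$atom$elety == "CA", ]
  expect_equal(ca2$x, 4)          # tie broken toward conformer A
})

test_that("ligand identification follows the inclusion rules", {
  st <- make_site_structure(fixture_spec(n_site_residues = 4, seed = 7,
                                         ligand_code = "ATP"))
  # waters and an excluded buffer next to the real ligand
  extra <- st$atom[rep(nrow(st$atom), 6), ]
  extra$resid <- c(rep("HOH", 5), "SO4")
  extra$resno <- 950:955
  extra$eleno <- max(st$atom$eleno) + 1:6
  extra$elety <- "O"; extra$elesy <- "O"; extra$is_hydrogen <- FALSE
  st2 <- cpassr:::.new_structure(st$id, rbind(st$atom, extra))

  ligs <- identify_ligands(st2)
  expect_equal(vapply(ligs, function(l) l$code, ""), "ATP")
  # water survives nowhere even with an empty exclusion list
  ligs2 <- identify_ligands(st2, exclusion_list = character(0))
  expect_true(all(vapply(ligs2, function(l) l$code, "") %in%
                  c("ATP", "SO4")))
  # determinism / order stability
  expect_identical(identify_ligands(st2), identify_ligands(st2))
})

test_that("short polymer chains are ligands, longer ones are not", {
  mk_chain <- function(chain, n, offset) {
    do.call(rbind, lapply(seq_len(n), function(i)
      data.frame(type = "ATOM", eleno = offset + i, elety = "CA", alt = "",
                 resid = "ALA", chain = chain, resno = i, insert = "",
                 x = offset + 3 * i, y = 0, z = 0, o = 1, b = 0,
                 elesy = "C", is_hydrogen = FALSE,
                 stringsAsFactors = FALSE)))
  }
  at <- rbind(mk_chain("A", 20, 0), mk_chain("B", 13, 100),
              mk_chain("C", 14, 200))
  st <- cpassr:::.new_structure("poly", at)
  ligs <- identify_ligands(st)
  polys <- Filter(function(l) l$is_polymer, ligs)
  expect_equal(vapply(polys, function(l) l$instance, ""), "B")
  expect_equal(polys[[1]]$polymer_length, 13L)
})
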