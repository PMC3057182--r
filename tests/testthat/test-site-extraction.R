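# Ligand-defined and manual binding-site construction.

# hand-built structure: ligand atom at the origin, residues whose nearest
# heavy atom sits at exact distances
exact_structure <- function(dists, aa = NULL) {
  n <- length(dists)
  if (is.null(aa)) aa <- rep("ALA", n)
  rows <- list()
  eleno <- 0L
  add <- function(type, elety, elesy, resid, resno, x, y, z) {
    eleno <<- eleno + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      type = type, eleno = eleno, elety = elety, alt = "", resid = resid,
      chain = "A", resno = resno, insert = "", x = x, y = y, z = z,
      o = 1, b = 0, elesy = elesy, is_hydrogen = FALSE,
      stringsAsFactors = FALSE)
  }
  for (k in seq_len(n)) {
    # CA farther out than the contact atom CB along +x-ish directions
    ang <- 2 * pi * (k - 1) / n
    u <- c(cos(ang), sin(ang), 0)
    add("ATOM", "CA", "C", aa[k], k,
        u[1] * (dists[k] + 2), u[2] * (dists[k] + 2), 0)
    if (aa[k] != "GLY")
      add("ATOM", "CB", "C", aa[k], k,
          u[1] * dists[k], u[2] * dists[k], 0)
  }
  add("HETATM", "C1", "C", "LIG", 900L, 0, 0, 0)
  cpassr:::.new_structure("exact", do.call(rbind, rows))
}

sasa_for <- function(st, value = 50) {
  prot <- st$atom[st$atom$type == "ATOM", ]
  first <- prot[!duplicated(prot$res_key), ]
  data.frame(res_key = first$res_key, resid = first$resid,
             chain = first$chain, resno = first$resno,
             insert = first$insert, area = NA_real_,
             rel_sasa = rep_len(value, nrow(first)),
             stringsAsFactors = FALSE)
}

test_that("the 6 A cutoff is a hard threshold on heavy-atom distance", {
  st <- exact_structure(c(5.9, 6.1))
  lig <- identify_ligands(st, character(0))[[1]]
  site <- extract_site(st, lig, rel_sasa = sasa_for(st))
  expect_equal(site$residues$resno, 1L)
  # enlarging the cutoff only adds residues
  site2 <- extract_site(st, lig, cutoff = 7, rel_sasa = sasa_for(st))
  expect_true(all(site$residues$res_key %in% site2$residues$res_key))
  expect_equal(site_size(site2), 2L)
})

test_that("d_i, d_min and the distance weights follow the geometry", {
  st <- exact_structure(c(2, 4))
  lig <- identify_ligands(st, character(0))[[1]]
  site <- extract_site(st, lig, rel_sasa = sasa_for(st))
  expect_equal(sort(site$residues$d_i), c(2, 4), tolerance = 1e-9)
  expect_equal(site$d_min, 2, tolerance = 1e-9)
  expect_equal(sort(site$d_min / site$residues$d_i, decreasing = TRUE),
               c(1.0, 0.5), tolerance = 1e-9)
})

test_that("an out-of-range ligand produces an empty-site error", {
  st <- exact_structure(c(8, 9))
  lig <- identify_ligands(st, character(0))[[1]]
  expect_error(extract_site(st, lig, rel_sasa = sasa_for(st)),
               "empty binding site")
})

test_that("extraction is invariant under a joint rigid transform", {
  spec <- fixture_spec(n_site_residues = 5, seed = 21, decoy_shell = TRUE)
  st <- make_site_structure(spec)
  ang <- 1.1; R <- matrix(c(cos(ang), -sin(ang), 0,
                            sin(ang), cos(ang), 0, 0, 0, 1), 3, 3,
                          byrow = TRUE)
  at <- st$atom
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(R)
  at$x <- xyz[, 1] + 7; at$y <- xyz[, 2] - 3; at$z <- xyz[, 3] + 2
  st2 <- cpassr:::.new_structure(st$id, at)
  attr(st2, "rel_sasa") <- attr(st, "rel_sasa")
  s1 <- fixture_site(st); s2 <- fixture_site(st2)
  expect_equal(s1$residues$res_key, s2$residues$res_key)
  expect_equal(s1$residues$d_i, s2$residues$d_i, tolerance = 1e-9)
})

test_that("manual sites use the residue list and the center of mass", {
  st <- exact_structure(c(2, 4, 3), aa = c("ALA", "LEU", "GLY"))
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# manual site", "ALA 1 A", "LEU, 2, A", "GLY 3 A"), f)
  site <- parse_manual_site(f, st, rel_sasa = sasa_for(st))
  expect_equal(site$mode, "manual")
  expect_null(site$ligand)
  expect_equal(site_size(site), 3L)
  expect_equal(site$d_min, min(site$residues$d_i))

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines("ALA 2 A", bad)   # residue 2 is LEU
  expect_error(parse_manual_site(bad, st, rel_sasa = sasa_for(st)),
               "line 1.*LEU")
  missing <- withr::local_tempfile(fileext = ".txt")
  writeLines("ALA 9 A", missing)
  expect_error(parse_manual_site(missing, st, rel_sasa = sasa_for(st)),
               "not found")
})

test_that("a symmetric two-residue manual site has equal weights", {
  st <- exact_structure(c(3, 3), aa = c("ALA", "ALA"))
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("ALA 1 A", "ALA 2 A"), f)
  site <- parse_manual_site(f, st, rel_sasa = sasa_for(st))
  expect_equal(site$residues$d_i[1], site$residues$d_i[2], tolerance = 1e-9)
  expect_equal(site$d_min / site$residues$d_i, c(1, 1), tolerance = 1e-9)
})
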