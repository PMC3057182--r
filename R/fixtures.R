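# Synthetic protein-ligand structures.
#
# Generates PDB-writable structures with a planted ligand and a binding
# shell of residues at controlled distances, so site extraction, alignment,
# scoring, database and evaluation code are all testable without any
# downloaded structure. Geometry is minimal but chemically plausible:
# N-CA-C backbone stubs, a CB at 1.53 A from CA pointing at the ligand, and
# a side-chain contact pseudo-atom at the intended ligand distance (the
# generator does not attempt full rotamers). All output is deterministic
# for a fixed seed.

#' Fixture specification
#'
#' @param n_site_residues number of residues in the planted site (>= 3).
#' @param residue_types three-letter codes for the site residues (recycled);
#'   random draw from the 20 standard residues when \code{NULL}.
#' @param ligand_atoms number of ligand heavy atoms.
#' @param site_radius length-2 range (A) for the residues' closest-atom
#'   distance to the ligand; must stay below the 6 A extraction cutoff.
#' @param decoy_shell also place residues strictly beyond 6.5 A that must
#'   never be extracted.
#' @param noise_sigma Gaussian coordinate noise (A) applied to every atom.
#' @param seed integer seed; fixed seed gives identical output.
#' @param ligand_code HET code given to the planted ligand.
#' @param site_sasa relative-SASA values (percent) to inject for the site
#'   residues (recycled); random in [20, 90] when \code{NULL}.
#' @return a \code{fixture_spec} list.
#' @export
fixture_spec <- function(n_site_residues = 5L, residue_types = NULL,
                         ligand_atoms = 4L, site_radius = c(3.2, 5.0),
                         decoy_shell = FALSE, noise_sigma = 0,
                         seed = 1L, ligand_code = "LIG", site_sasa = NULL) {
  stopifnot(n_site_residues >= 3, ligand_atoms >= 1,
            length(site_radius) == 2, site_radius[1] > 1,
            site_radius[2] < 6, noise_sigma >= 0)
  structure(list(n_site_residues = as.integer(n_site_residues),
                 residue_types = residue_types,
                 ligand_atoms = as.integer(ligand_atoms),
                 site_radius = site_radius, decoy_shell = decoy_shell,
                 noise_sigma = noise_sigma, seed = as.integer(seed),
                 ligand_code = toupper(ligand_code),
                 site_sasa = site_sasa),
            class = "fixture_spec")
}

# run code under a local RNG stream without disturbing the caller's seed
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# quasi-uniform directions with a minimum mutual angle, sampled with retry
.spread_directions <- function(n, min_angle_deg = 25) {
  dirs <- matrix(numeric(0), ncol = 3)
  cmin <- cos(min_angle_deg * pi / 180)
  tries <- 0
  while (nrow(dirs) < n && tries < 5000) {
    v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
    if (nrow(dirs) == 0 || all(dirs %*% v < cmin))
      dirs <- rbind(dirs, v)
    tries <- tries + 1
  }
  if (nrow(dirs) < n)
    stop("infeasible geometry request: cannot place ", n,
         " residues with ", min_angle_deg, " degree separation")
  dirs
}

.fixture_atom_row <- function(eleno, type, elety, elesy, resid, chain,
                              resno, x, y, z) {
  data.frame(type = type, eleno = eleno, elety = elety, alt = "",
             resid = resid, chain = chain, resno = resno, insert = "",
             x = x, y = y, z = z, o = 1, b = 0, elesy = elesy,
             is_hydrogen = elesy %in% c("H", "D"),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic protein-ligand structure
#'
#' Places a compact ligand at the origin and \code{n_site_residues} residues
#' whose closest heavy atom sits at a controlled distance inside the 6 A
#' extraction cutoff (plus, optionally, a decoy shell beyond 6.5 A). The
#' result round-trips through \code{\link{write_structure}} /
#' \code{\link{read_structure}}.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @return a \code{cpass_structure}; the intended site residue numbers are
#'   attached as \code{attr(, "site_resno")} and the injected relative SASA
#'   table as \code{attr(, "rel_sasa")}.
#' @export
make_site_structure <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  .with_seed(spec$seed, {
    n <- spec$n_site_residues
    types <- if (is.null(spec$residue_types))
      sample(.AA3, n, replace = TRUE)
    else rep_len(toupper(spec$residue_types), n)

    # ligand: first heavy atom at the origin, the rest within ~1.4 A
    lig_el <- rep_len(c("C", "N", "O", "C"), spec$ligand_atoms)
    lig_xyz <- rbind(c(0, 0, 0))
    while (nrow(lig_xyz) < spec$ligand_atoms) {
      v <- stats::rnorm(3); v <- 1.4 * v / sqrt(sum(v^2))
      cand <- lig_xyz[nrow(lig_xyz), ] + v
      if (nrow(lig_xyz) == 1 ||
          min(.cross_dist(rbind(cand), lig_xyz)) > 1.1)
        lig_xyz <- rbind(lig_xyz, cand)
    }

    n_extra <- if (spec$decoy_shell) max(2L, n %/% 2L) else 0L
    dirs <- .spread_directions(n + n_extra)
    rows <- list(); eleno <- 0L
    add <- function(type, elety, elesy, resid, resno, p) {
      eleno <<- eleno + 1L
      rows[[length(rows) + 1L]] <<-
        .fixture_atom_row(eleno, type, elety, elesy, resid, "A", resno,
                          p[1], p[2], p[3])
    }

    place_residue <- function(resno, aa, u, contact_r) {
      # contact pseudo-atom at the intended closest distance to the ligand
      is_gly <- aa == "GLY"
      if (is_gly) {
        ca <- u * contact_r
      } else {
        contact <- u * contact_r
        ca <- u * (contact_r + 2.4)
      }
      # local frame for backbone stubs
      a1 <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      e1 <- a1 - sum(a1 * u) * u; e1 <- e1 / sqrt(sum(e1^2))
      e2 <- c(u[2] * e1[3] - u[3] * e1[2],
              u[3] * e1[1] - u[1] * e1[3],
              u[1] * e1[2] - u[2] * e1[1])
      add("ATOM", "N", "N", aa, resno, ca + 1.46 * e1)
      add("ATOM", "CA", "C", aa, resno, ca)
      add("ATOM", "C", "C", aa, resno, ca + 1.52 * e2)
      if (!is_gly) {
        cb <- ca - 1.53 * u   # points back toward the ligand
        add("ATOM", "CB", "C", aa, resno, cb)
        add("ATOM", "CG", "C", aa, resno, contact)
      }
      invisible(NULL)
    }

    radii <- stats::runif(n, spec$site_radius[1], spec$site_radius[2])
    for (k in seq_len(n)) place_residue(k, types[k], dirs[k, ], radii[k])
    if (n_extra > 0) {
      extra_types <- sample(.AA3, n_extra, replace = TRUE)
      for (k in seq_len(n_extra))
        place_residue(n + k, extra_types[k], dirs[n + k, ],
                      stats::runif(1, 8.5, 10.5))
    }
    for (k in seq_len(spec$ligand_atoms))
      add("HETATM", paste0(lig_el[k], k), lig_el[k], spec$ligand_code,
          900L, lig_xyz[k, ])

    at <- do.call(rbind, rows)
    if (spec$noise_sigma > 0) {
      at$x <- at$x + stats::rnorm(nrow(at), 0, spec$noise_sigma)
      at$y <- at$y + stats::rnorm(nrow(at), 0, spec$noise_sigma)
      at$z <- at$z + stats::rnorm(nrow(at), 0, spec$noise_sigma)
    }
    st <- .new_structure(id = paste0("fix", spec$seed), atom = at)

    sas <- if (is.null(spec$site_sasa)) stats::runif(n + n_extra, 20, 90)
           else rep_len(spec$site_sasa, n + n_extra)
    prot <- st$atom[st$atom$type == "ATOM", ]
    first <- prot[!duplicated(prot$res_key), ]
    attr(st, "rel_sasa") <- data.frame(
      res_key = first$res_key, resid = first$resid, chain = first$chain,
      resno = first$resno, insert = first$insert, area = NA_real_,
      rel_sasa = sas[seq_len(nrow(first))], stringsAsFactors = FALSE)
    attr(st, "site_resno") <- seq_len(n)
    st
  })
}

#' Extract the planted binding site of a fixture structure
#'
#' Convenience wrapper: identifies the planted ligand and extracts its site
#' with the fixture's injected relative SASA values.
#'
#' @param structure output of \code{\link{make_site_structure}} (or
#'   \code{\link{perturb_structure}} thereof).
#' @param cutoff extraction cutoff (A).
#' @return a \code{cpass_site}.
#' @export
fixture_site <- function(structure, cutoff = 6.0) {
  ligs <- identify_ligands(structure, exclusion_list = character(0))
  het <- Filter(function(l) !l$is_polymer, ligs)
  if (length(het) == 0) stop("fixture has no heteroatom ligand")
  extract_site(structure, het[[1]], cutoff = cutoff,
               rel_sasa = attr(structure, "rel_sasa"))
}

#' Perturb every atom with Gaussian noise
#'
#' @param structure a \code{cpass_structure}.
#' @param sigma displacement standard deviation (A); 0 returns the input
#'   unchanged.
#' @param seed integer seed.
#' @return the perturbed structure (injected SASA attributes are carried
#'   over unchanged).
#' @export
perturb_structure <- function(structure, sigma, seed = 1L) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(structure)
  .with_seed(seed, {
    at <- structure$atom
    at$x <- at$x + stats::rnorm(nrow(at), 0, sigma)
    at$y <- at$y + stats::rnorm(nrow(at), 0, sigma)
    at$z <- at$z + stats::rnorm(nrow(at), 0, sigma)
    out <- .new_structure(structure$id, at)
    attr(out, "rel_sasa") <- attr(structure, "rel_sasa")
    attr(out, "site_resno") <- attr(structure, "site_resno")
    out
  })
}

#' Generate a synthetic site library with planted positives
#'
#' Builds a decoy library for evaluation tests: near-copies of a query site
#' at graded noise (the planted true positives, sharing the query's ligand,
#' residue identities and accessibility pattern) plus unrelated random
#' sites (fresh residue compositions and geometries, random accessibility,
#' mixed ligand codes). Truth labels and E.C. annotations are attached.
#'
#' @param n total number of records (>= 2).
#' @param seed integer seed.
#' @param n_positives number of planted near-copies.
#' @param query_seed seed of the query fixture.
#' @param site_size residue count of the query (decoys vary around it).
#' @return list with \code{query} (a \code{cpass_site}), \code{records}
#'   (list of \code{cpass_record}), \code{truth} (data frame:
#'   \code{cpass_id}, \code{is_positive}, \code{ec}, \code{ligand_code}),
#'   and \code{query_ec}.
#' @export
make_decoy_library <- function(n = 50L, seed = 1L, n_positives = 5L,
                               query_seed = 100L, site_size = 6L) {
  stopifnot(n >= 2, n_positives >= 0, n_positives <= n)
  qspec <- fixture_spec(n_site_residues = site_size, ligand_atoms = 5L,
                        seed = query_seed, ligand_code = "ATP")
  qstruct <- make_site_structure(qspec)
  query <- fixture_site(qstruct)

  records <- vector("list", n)
  truth <- data.frame(cpass_id = character(n), is_positive = logical(n),
                      ec = character(n), ligand_code = character(n),
                      stringsAsFactors = FALSE)
  decoy_ligs <- c("ATP", "PLP", "NAD", "GTP")
  decoy_ecs <- c("3.2.1.4", "2.7.1.40", "4.1.1.49", "6.1.1.18", "1.1.1.1")

  .with_seed(seed, {
    for (k in seq_len(n)) {
      if (k <= n_positives) {
        # graded noise within the experimental-error scale that the
        # score's non-penalty regions (0.5 A ligand, 1 A residue) absorb:
        # positives emulate independently redetermined similar sites
        sigma <- 0.1 + 0.2 * (k - 1) / max(1, n_positives - 1)
        st <- perturb_structure(qstruct, sigma, seed = seed + 1000L + k)
        # accessibility pattern preserved up to small measurement noise
        sas <- attr(qstruct, "rel_sasa")
        sas$rel_sasa <- pmin(100, pmax(0, sas$rel_sasa +
                                         stats::runif(nrow(sas), -2, 2)))
        attr(st, "rel_sasa") <- sas
        site <- fixture_site(st)
        id <- sprintf("pos%03d_A_ATP_1", k)
        ec <- "2.6.1.1"; pos <- TRUE; lig <- "ATP"
      } else {
        spec <- fixture_spec(
          n_site_residues = sample(max(4L, site_size - 2L):(site_size + 1L), 1),
          ligand_atoms = sample(4:6, 1),
          seed = seed + 2000L + k,
          ligand_code = sample(decoy_ligs, 1))
        st <- make_site_structure(spec)
        site <- fixture_site(st)
        id <- sprintf("neg%03d_A_%s_1", k, spec$ligand_code)
        ec <- sample(decoy_ecs, 1); pos <- FALSE; lig <- spec$ligand_code
      }
      seqs <- paste(sample(.AA1, 40, replace = TRUE), collapse = "")
      records[[k]] <- .new_site_record(
        cpass_id = id, site = site, ligand_code = lig,
        source_sequence = seqs, function_note = NA_character_)
      truth$cpass_id[k] <- id; truth$is_positive[k] <- pos
      truth$ec[k] <- ec; truth$ligand_code[k] <- lig
    }
  })
  list(query = query, records = stats::setNames(records, truth$cpass_id),
       truth = truth, query_ec = "2.6.1.1")
}
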