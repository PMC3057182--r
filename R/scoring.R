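# The CPASS similarity function.
#
# v.1:  S_ab = sum_ij (d_min/d_i) f_dist(RMSD_ij) p_ij
# v.2:  S_ab = f_lig(RMSD_lig) sum_ij (d_min/d_i) f_sasa(dSASA_ij)
#              f_dist(RMSD_ij) p_ij
#
# with corrected arguments: the per-residue distance penalty is free below
# 1 A and the ligand penalty free below 0.5 A, absorbing typical
# experimental coordinate error. All penalty factors live in [0, 1]. The
# distance weight d_min/d_i is taken from the QUERY site (site a), so
# S_ab is deliberately asymmetric; percent similarity is normalized by the
# query self-score S_aa.

#' Scoring options
#'
#' @param use_ligand_rmsd apply the global bound-ligand alignment factor
#'   (disabled automatically when either site is manually defined).
#' @param use_sasa apply the per-pair solvent-accessibility penalty.
#' @param use_cbeta include Cbeta positions in per-residue RMSDs (Calpha
#'   only for pairs involving glycine or residues without a Cbeta record).
#' @param version \code{"v2"} (default) or \code{"v1"}; v1 is the original
#'   Calpha-distance-weighted function and forces all three flags off.
#' @param residue_penalty form of the per-residue distance decay:
#'   \code{"gaussian"} (default) reads the squared exponential as
#'   exp(-dRMSD^2); \code{"double_exp"} uses (exp(-dRMSD))^2 = exp(-2 dRMSD)
#'   for comparison.
#' @param percent_norm self-score used to normalize percent similarity:
#'   \code{"query"} (default) uses S_aa; \code{"max"} uses max(S_aa, S_bb).
#' @return a \code{cpass_options} list.
#' @export
score_options <- function(use_ligand_rmsd = TRUE, use_sasa = TRUE,
                          use_cbeta = TRUE, version = c("v2", "v1"),
                          residue_penalty = c("gaussian", "double_exp"),
                          percent_norm = c("query", "max")) {
  version <- match.arg(version)
  if (version == "v1") {
    use_ligand_rmsd <- FALSE; use_sasa <- FALSE; use_cbeta <- FALSE
  }
  structure(list(use_ligand_rmsd = isTRUE(use_ligand_rmsd),
                 use_sasa = isTRUE(use_sasa),
                 use_cbeta = isTRUE(use_cbeta),
                 version = version,
                 residue_penalty = match.arg(residue_penalty),
                 percent_norm = match.arg(percent_norm)),
            class = "cpass_options")
}

#' Per-residue distance penalty factor
#'
#' No penalty within 1 A; beyond that the corrected RMSD enters a squared
#' exponential, so the factor drops below 0.11 by 2.5 A (an alignment that
#' far off contributes essentially nothing).
#'
#' @param rmsd_raw raw per-residue RMSD in Angstrom (vectorized).
#' @param form \code{"gaussian"} or \code{"double_exp"} (see
#'   \code{\link{score_options}}).
#' @return penalty factor in (0, 1].
#' @export
residue_distance_penalty <- function(rmsd_raw, form = "gaussian") {
  if (any(rmsd_raw < 0)) stop("rmsd_raw must be non-negative")
  d <- pmax(0, rmsd_raw - 1)
  if (form == "double_exp") exp(-2 * d) else exp(-d^2)
}

#' Solvent-accessibility penalty factor
#'
#' \code{max(0, log10(100 - dSASA) - 1)}: unity at no difference, steeply
#' penalizing differences of 60 percentage points or more (the
#' surface-vs-buried distinction), zero at 90 and above.
#'
#' @param delta_sasa absolute relative-SASA difference in percentage points,
#'   within [0, 100] (vectorized).
#' @return penalty factor in [0, 1].
#' @export
sasa_penalty <- function(delta_sasa) {
  if (any(delta_sasa < 0 | delta_sasa > 100))
    stop("delta_sasa must lie in [0, 100]")
  out <- ifelse(delta_sasa >= 100, 0,
                pmax(0, log10(100 - delta_sasa) - 1))
  pmin(out, 1)
}

#' Global bound-ligand alignment factor
#'
#' The raw inter-ligand RMSD is reduced by 0.5 A (non-penalty region for
#' experimental error) and enters log5(5 - dRMSD_lig), clamped to [0, 1]:
#' unity up to 0.5 A raw RMSD, zero from 4.5 A on.
#'
#' @param rmsd_raw raw inter-ligand RMSD in Angstrom (vectorized).
#' @return factor in [0, 1].
#' @export
ligand_alignment_factor <- function(rmsd_raw) {
  if (any(rmsd_raw < 0)) stop("rmsd_raw must be non-negative")
  d <- pmax(0, rmsd_raw - 0.5)
  out <- numeric(length(d))
  out[d < 4] <- log(5 - d[d < 4], base = 5)
  pmin(pmax(out, 0), 1)
}

#' Per-residue-pair RMSD under a site alignment
#'
#' RMSD over the Calpha positions, plus the Cbeta positions when
#' \code{use_cbeta} is on and neither residue is glycine (or lacks a Cbeta
#' record in an incomplete model).
#'
#' @param res_a,res_b one-row residue tables from \code{cpass_site$residues}.
#' @param transform rigid transform (list with \code{rotation},
#'   \code{translation}) applied to \code{res_b}'s coordinates.
#' @param use_cbeta logical.
#' @return RMSD in Angstrom.
#' @export
pair_rmsd <- function(res_a, res_b, transform, use_cbeta = TRUE) {
  pa <- rbind(c(res_a$ca_x, res_a$ca_y, res_a$ca_z))
  pb <- rbind(c(res_b$ca_x, res_b$ca_y, res_b$ca_z))
  if (any(!is.finite(pa)) || any(!is.finite(pb)))
    stop("residue lacks CA coordinates")
  use_cb <- use_cbeta && res_a$aa != "GLY" && res_b$aa != "GLY" &&
    is.finite(res_a$cb_x) && is.finite(res_b$cb_x)
  if (use_cb) {
    pa <- rbind(pa, c(res_a$cb_x, res_a$cb_y, res_a$cb_z))
    pb <- rbind(pb, c(res_b$cb_x, res_b$cb_y, res_b$cb_z))
  }
  pbt <- apply_transform(pb, transform)
  sqrt(mean(rowSums((pa - pbt)^2)))
}

#' RMSD between two bound ligands under a site alignment
#'
#' The smaller ligand (fewer heavy atoms; ties favour \code{ligand_a}) is
#' mapped onto the larger: each of its heavy atoms takes the distance to
#' the nearest heavy atom of the other ligand after the site transform, and
#' the root mean square of those distances is returned. Extra atoms of the
#' larger ligand are ignored, so chemically different ligands compare
#' through their best-overlapping substructure.
#'
#' @param ligand_a query-site ligand (\code{cpass_ligand}).
#' @param ligand_b target-site ligand; the transform is applied to its
#'   coordinates.
#' @param transform rigid transform mapping site-b coordinates into the
#'   site-a frame.
#' @return RMSD in Angstrom.
#' @export
ligand_rmsd <- function(ligand_a, ligand_b, transform) {
  xa <- .ligand_heavy_xyz(ligand_a)
  xb <- apply_transform(.ligand_heavy_xyz(ligand_b), transform)
  if (nrow(xa) == 0 || nrow(xb) == 0) stop("ligand has no heavy atoms")
  if (nrow(xa) <= nrow(xb)) {
    d <- apply(.cross_dist(xa, xb), 1, min)
  } else {
    d <- apply(.cross_dist(xb, xa), 1, min)
  }
  sqrt(mean(d^2))
}

#' Percent similarity
#'
#' @param s_ab comparison score.
#' @param s_aa reference (query self-comparison) score; must be positive.
#' @return \code{100 * s_ab / s_aa}.
#' @export
percent_similarity <- function(s_ab, s_aa) {
  if (any(s_aa <= 0)) stop("self-score must be positive")
  100 * s_ab / s_aa
}

#' Self-comparison score of a site
#'
#' Under a self-alignment every penalty factor is 1, so the score reduces
#' to \code{sum((d_min/d_i) * p(aa, aa))}.
#'
#' @param site a \code{cpass_site}.
#' @param model substitution model.
#' @return numeric self-score.
#' @export
self_score <- function(site, model = cpass_substitution()) {
  r <- site$residues
  sum((site$d_min / r$d_i) * substitution_prob(model, r$aa, r$aa))
}

#' Score a site alignment
#'
#' Evaluates the similarity function on an explicit residue correspondence
#' and rigid transform. The global ligand factor is applied only when
#' enabled and both sites are ligand-defined; the per-pair breakdown is
#' returned so every reported score can be reproduced term by term.
#'
#' @param site_a query site (its \code{d_min/d_i} weights are used).
#' @param site_b target site.
#' @param alignment a \code{cpass_alignment} (see
#'   \code{\link{find_best_alignment}}) or any list with \code{pairs},
#'   \code{rotation}, \code{translation}.
#' @param model substitution model (default embedded BLOSUM62 target
#'   frequencies).
#' @param options a \code{cpass_options} list.
#' @return a \code{cpass_similarity}: list with \code{s_ab}, \code{s_aa},
#'   \code{percent}, \code{ligand_rmsd_raw} (NA unless both sites are
#'   ligand-defined), \code{ligand_factor}, \code{n_pairs} and
#'   \code{pair_breakdown} (data frame: indices, residues, blosum term,
#'   distance weight, distance/SASA penalties, contribution; \code{s_ab}
#'   equals \code{ligand_factor * sum(contribution)}).
#' @export
score_alignment <- function(site_a, site_b, alignment,
                            model = cpass_substitution(),
                            options = score_options()) {
  pairs <- alignment$pairs
  tr <- list(rotation = alignment$rotation,
             translation = alignment$translation)
  ra <- site_a$residues; rb <- site_b$residues
  s_aa <- self_score(site_a, model)

  both_lig <- site_a$mode == "ligand_defined" && site_b$mode == "ligand_defined"
  lig_raw <- NA_real_
  lig_factor <- 1
  if (both_lig) {
    lig_raw <- ligand_rmsd(site_a$ligand, site_b$ligand, tr)
    if (options$use_ligand_rmsd)
      lig_factor <- ligand_alignment_factor(lig_raw)
  }

  if (is.null(pairs) || NROW(pairs) == 0) {
    res <- list(s_ab = 0, s_aa = s_aa,
                percent = 0, ligand_rmsd_raw = lig_raw,
                ligand_factor = lig_factor, n_pairs = 0L,
                pair_breakdown = NULL, options = options)
    class(res) <- "cpass_similarity"
    return(res)
  }
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (any(pairs[, 1] < 1 | pairs[, 1] > nrow(ra)) ||
      any(pairs[, 2] < 1 | pairs[, 2] > nrow(rb)))
    stop("alignment references residues absent from the sites")

  k <- nrow(pairs)
  bl <- dw <- dp <- sp <- numeric(k)
  for (q in seq_len(k)) {
    i <- pairs[q, 1]; j <- pairs[q, 2]
    bl[q] <- substitution_prob(model, ra$aa[i], rb$aa[j])
    dw[q] <- site_a$d_min / ra$d_i[i]
    rr <- pair_rmsd(ra[i, ], rb[j, ], tr, use_cbeta = options$use_cbeta)
    dp[q] <- residue_distance_penalty(rr, form = options$residue_penalty)
    if (options$use_sasa && is.finite(ra$rel_sasa[i]) &&
        is.finite(rb$rel_sasa[j])) {
      ds <- min(100, abs(ra$rel_sasa[i] - rb$rel_sasa[j]))
      sp[q] <- sasa_penalty(ds)
    } else sp[q] <- 1
  }
  contrib <- dw * sp * dp * bl
  s_ab <- lig_factor * sum(contrib)

  norm <- if (options$percent_norm == "max")
    max(s_aa, self_score(site_b, model)) else s_aa

  res <- list(
    s_ab = s_ab, s_aa = s_aa,
    percent = percent_similarity(s_ab, norm),
    ligand_rmsd_raw = lig_raw, ligand_factor = lig_factor,
    n_pairs = k,
    pair_breakdown = data.frame(
      ia = pairs[, 1], ib = pairs[, 2],
      aa_a = ra$aa[pairs[, 1]], aa_b = rb$aa[pairs[, 2]],
      blosum = bl, dist_weight = dw, dist_penalty = dp,
      sasa_penalty = sp, contribution = contrib,
      stringsAsFactors = FALSE),
    options = options)
  class(res) <- "cpass_similarity"
  res
}

#' @export
print.cpass_similarity <- function(x, ...) {
  cat("<cpass_similarity> S_ab =", signif(x$s_ab, 6),
      " S_aa =", signif(x$s_aa, 6),
      " percent =", round(x$percent, 2), "\n")
  if (is.finite(x$ligand_rmsd_raw))
    cat("  ligand RMSD =", round(x$ligand_rmsd_raw, 3),
        "A (factor", round(x$ligand_factor, 4), ")\n")
  cat(" ", x$n_pairs, "matched residue pairs\n")
  invisible(x)
}
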