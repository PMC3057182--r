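# Sequence-order-independent binding-site alignment.
#
# The search maximizes the similarity score itself, not a geometric proxy:
# (1) candidate seeds are triplets of residue correspondences with mutually
#     compatible Calpha-Calpha distances (tolerance dist_tol) and, where
#     possible, replacement-favourable identities;
# (2) each seed is Kabsch-superposed, then a maximum-weight bipartite
#     assignment on the per-pair score-contribution matrix proposes a full
#     correspondence, which is re-superposed and iterated to convergence;
# (3) every candidate correspondence evaluated along the way (including a
#     prune ladder that drops the weakest pair down to size 3) is scored
#     with its own refitted transform, and the best-scoring one wins.
# Ties are broken by the lexicographically smallest pair list, so the
# search is deterministic. An exhaustive enumeration oracle
# (brute_force_alignment) is provided for small sites.

#' Apply a rigid transform to coordinates
#' @param xyz n x 3 matrix.
#' @param transform list with \code{rotation} (3x3) and \code{translation}.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, transform) {
  xyz <- matrix(xyz, ncol = 3)
  sweep(xyz %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation mapping \code{points_b} onto
#' \code{points_a} with minimal RMSD.
#'
#' @param points_a,points_b n x 3 coordinate matrices, n >= 3.
#' @return list with \code{rotation}, \code{translation}, \code{rmsd}.
#' @export
superpose <- function(points_a, points_b) {
  pa <- matrix(points_a, ncol = 3); pb <- matrix(points_b, ncol = 3)
  n <- nrow(pa)
  if (n < 3 || nrow(pb) != n)
    stop("superposition needs two equal-length point sets of >= 3 points")
  ca <- colMeans(pa); cb <- colMeans(pb)
  ac <- sweep(pa, 2, ca); bc <- sweep(pb, 2, cb)
  if (svd(bc)$d[2] < 1e-8 || svd(ac)$d[2] < 1e-8)
    stop("degenerate (collinear) point set: rotation is underdetermined")
  h <- crossprod(bc, ac)           # 3x3 covariance
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tra <- ca - as.numeric(rot %*% cb)
  fit <- sweep(bc %*% t(rot), 2, ca, "+")
  list(rotation = rot, translation = tra,
       rmsd = sqrt(mean(rowSums((pa - fit)^2))))
}

# ---------------------------------------------------------------------------
# internal fast scoring machinery shared by the heuristic and the oracle

.identity_transform <- function()
  list(rotation = diag(3), translation = c(0, 0, 0))

# fast rigid transform (no dimension checks, no sweep)
.tx <- function(xyz, tr) {
  p <- xyz %*% t(tr$rotation)
  p[, 1] <- p[, 1] + tr$translation[1]
  p[, 2] <- p[, 2] + tr$translation[2]
  p[, 3] <- p[, 3] + tr$translation[3]
  p
}

# minimal Kabsch for inner-loop fits; NULL on failure
.kabsch <- function(pa, pb) {
  n <- nrow(pa)
  if (n < 3) return(NULL)
  ca <- colMeans(pa); cb <- colMeans(pb)
  h <- crossprod(sweep(pb, 2, cb), sweep(pa, 2, ca))
  s <- tryCatch(svd(h), error = function(e) NULL)
  if (is.null(s)) return(NULL)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) return(NULL)
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = rot, translation = ca - as.numeric(rot %*% cb))
}

.empty_alignment <- function() {
  structure(list(pairs = matrix(integer(0), ncol = 2,
                                dimnames = list(NULL, c("ia", "ib"))),
                 rotation = diag(3), translation = c(0, 0, 0),
                 rmsd = NA_real_, score = 0, n_pairs = 0L),
            class = "cpass_alignment")
}

#' @export
print.cpass_alignment <- function(x, ...) {
  cat("<cpass_alignment>", x$n_pairs, "pairs, score =",
      signif(x$score, 6), "\n")
  invisible(x)
}

# precomputed arrays reused across candidate evaluations of one site pair
.align_precomp <- function(site_a, site_b, model, options) {
  ra <- site_a$residues; rb <- site_b$residues
  aCA <- as.matrix(ra[, c("ca_x", "ca_y", "ca_z")])
  bCA <- as.matrix(rb[, c("ca_x", "ca_y", "ca_z")])
  aCB <- as.matrix(ra[, c("cb_x", "cb_y", "cb_z")])
  bCB <- as.matrix(rb[, c("cb_x", "cb_y", "cb_z")])
  hasCB_a <- ra$aa != "GLY" & is.finite(aCB[, 1])
  hasCB_b <- rb$aa != "GLY" & is.finite(bCB[, 1])
  pmat <- outer(seq_len(nrow(ra)), seq_len(nrow(rb)),
                function(i, j) substitution_prob(model, ra$aa[i], rb$aa[j]))
  if (options$use_sasa && all(is.finite(ra$rel_sasa)) &&
      all(is.finite(rb$rel_sasa))) {
    dsasa <- pmin(abs(outer(ra$rel_sasa, rb$rel_sasa, "-")), 100)
    smat <- matrix(sasa_penalty(as.numeric(dsasa)), nrow = nrow(ra))
  } else smat <- matrix(1, nrow(ra), nrow(rb))
  both_lig <- site_a$mode == "ligand_defined" &&
    site_b$mode == "ligand_defined"
  list(aCA = aCA, bCA = bCA, aCB = aCB, bCB = bCB,
       hasCB_a = hasCB_a, hasCB_b = hasCB_b,
       w = site_a$d_min / ra$d_i, pmat = pmat, smat = smat,
       lig_a = if (both_lig) site_a$ligand else NULL,
       lig_b = if (both_lig) site_b$ligand else NULL,
       lig_b_xyz = if (both_lig) .ligand_heavy_xyz(site_b$ligand) else NULL,
       lig_a_xyz = if (both_lig) .ligand_heavy_xyz(site_a$ligand) else NULL,
       use_lig = options$use_ligand_rmsd && both_lig,
       n = nrow(ra), m = nrow(rb))
}

# per-pair contribution matrix under a transform
.contribution_matrix <- function(pc, tr, options) {
  bCA <- .tx(pc$bCA, tr)
  dca <- .cross_dist(pc$aCA, bCA)
  if (options$use_cbeta && any(pc$hasCB_a) && any(pc$hasCB_b)) {
    bCB <- pc$bCB
    bCB[pc$hasCB_b, ] <- .tx(pc$bCB[pc$hasCB_b, , drop = FALSE], tr)
    rmsd <- dca
    mask <- outer(pc$hasCB_a, pc$hasCB_b, "&")
    if (any(mask)) {
      aCBf <- pc$aCB; aCBf[!pc$hasCB_a, ] <- 0
      bCBf <- bCB;    bCBf[!pc$hasCB_b, ] <- 0
      dcb <- .cross_dist(aCBf, bCBf)
      rmsd[mask] <- sqrt((dca[mask]^2 + dcb[mask]^2) / 2)
    }
  } else rmsd <- dca
  d <- rmsd - 1
  d[d < 0] <- 0
  dp <- if (options$residue_penalty == "double_exp") exp(-2 * d)
        else exp(-d * d)
  pc$w * pc$smat * dp * pc$pmat
}

# ligand alignment factor under a transform (1 when disabled)
.ligand_factor_for <- function(pc, tr) {
  if (!pc$use_lig) return(1)
  xb <- .tx(pc$lig_b_xyz, tr)
  xa <- pc$lig_a_xyz
  d <- if (nrow(xa) <= nrow(xb)) .row_mins(.cross_dist(xa, xb))
       else .row_mins(.cross_dist(xb, xa))
  ligand_alignment_factor(sqrt(mean(d^2)))
}

# Kabsch refit on the matched residues (CA, plus CB where available on both
# sides and enabled). Returns NULL for degenerate point sets.
.fit_on_pairs <- function(pc, pairs, options) {
  ia <- pairs[, 1]; ib <- pairs[, 2]
  pa <- pc$aCA[ia, , drop = FALSE]; pb <- pc$bCA[ib, , drop = FALSE]
  if (options$use_cbeta) {
    cb <- pc$hasCB_a[ia] & pc$hasCB_b[ib]
    if (any(cb)) {
      pa <- rbind(pa, pc$aCB[ia[cb], , drop = FALSE])
      pb <- rbind(pb, pc$bCB[ib[cb], , drop = FALSE])
    }
  }
  .kabsch(pa, pb)
}

# score a candidate matching with its own refitted transform
.eval_candidate <- function(pc, pairs, options) {
  tr <- .fit_on_pairs(pc, pairs, options)
  if (is.null(tr)) return(NULL)
  cm <- .contribution_matrix(pc, tr, options)
  s <- .ligand_factor_for(pc, tr) * sum(cm[pairs])
  list(pairs = pairs, transform = tr, score = s, contrib = cm[pairs])
}

# canonical form + lexicographic comparison for deterministic tie-breaks
.canon_pairs <- function(pairs) {
  pairs <- matrix(as.integer(pairs), ncol = 2,
                  dimnames = list(NULL, c("ia", "ib")))
  pairs[order(pairs[, 1]), , drop = FALSE]
}

.pairs_less <- function(p1, p2) {
  v1 <- as.integer(t(p1)); v2 <- as.integer(t(p2))
  n <- min(length(v1), length(v2))
  for (k in seq_len(n)) {
    if (v1[k] < v2[k]) return(TRUE)
    if (v1[k] > v2[k]) return(FALSE)
  }
  length(v1) < length(v2)
}

# maximum-weight bipartite assignment on positive contributions
.best_assignment <- function(cm) {
  pos <- which(cm > 0, arr.ind = TRUE)
  if (nrow(pos) == 0) return(NULL)
  n <- nrow(cm); m <- ncol(cm)
  g <- igraph::make_bipartite_graph(c(rep(0, n), rep(1, m)),
                                    edges = as.numeric(t(cbind(pos[, 1],
                                                               n + pos[, 2]))))
  igraph::E(g)$weight <- cm[pos]
  mt <- igraph::max_bipartite_match(g, types = igraph::V(g)$type,
                                    weights = igraph::E(g)$weight)
  ia <- seq_len(n)
  ib <- mt$matching[seq_len(n)] - n
  keep <- !is.na(ib) & ib >= 1
  if (!any(keep)) return(NULL)
  cbind(ia = ia[keep], ib = as.integer(ib[keep]))
}

# ---------------------------------------------------------------------------
# seed generation

# candidate residue correspondences (i in a, j in b)
.seed_correspondences <- function(site_a, site_b, model) {
  ra <- site_a$residues; rb <- site_b$residues
  n <- nrow(ra); m <- nrow(rb)
  grid <- expand.grid(i = seq_len(n), j = seq_len(m))
  grid$fav <- .favorable_pair(model, ra$aa[grid$i], rb$aa[grid$j])
  # large sites: keep only favourable correspondences when enough exist
  if (n * m > 49 && sum(grid$fav) >= 20) grid <- grid[grid$fav, , drop = FALSE]
  grid
}

# triplets of correspondences used as alignment seeds, ranked by mutual
# Calpha-distance compatibility and replacement-favourable identities.
# Small problems are seeded exhaustively (every triplet pair); larger ones
# are pruned by the distance tolerance before ranking.
.seed_triplets <- function(site_a, site_b, model, dist_tol, max_seeds) {
  corr <- .seed_correspondences(site_a, site_b, model)
  f <- nrow(corr)
  if (f < 3) return(list())
  aCA <- as.matrix(site_a$residues[, c("ca_x", "ca_y", "ca_z")])
  bCA <- as.matrix(site_b$residues[, c("ca_x", "ca_y", "ca_z")])
  dA <- .cross_dist(aCA, aCA); dB <- .cross_dist(bCA, bCA)
  ddiff <- abs(dA[corr$i, corr$i] - dB[corr$j, corr$j])
  distinct <- outer(corr$i, corr$i, "!=") & outer(corr$j, corr$j, "!=")
  exhaustive <- choose(f, 3) <= max_seeds * 6L
  compat <- if (exhaustive) distinct else distinct & ddiff <= dist_tol

  seeds <- list(); disc <- numeric(0); favn <- integer(0)
  raw_cap <- max_seeds * 20L
  for (u in seq_len(f - 2)) {
    vs <- which(compat[u, ] & seq_len(f) > u)
    for (v in vs) {
      ws <- which(compat[u, ] & compat[v, ] & seq_len(f) > v)
      for (w in ws) {
        seeds[[length(seeds) + 1L]] <- c(u, v, w)
        disc <- c(disc, max(ddiff[u, v], ddiff[u, w], ddiff[v, w]))
        favn <- c(favn, sum(corr$fav[c(u, v, w)]))
      }
      if (length(seeds) >= raw_cap) break
    }
    if (length(seeds) >= raw_cap) break
  }
  if (length(seeds) == 0) return(list())
  keep <- order(-favn, disc)
  if (!exhaustive) keep <- keep[seq_len(min(length(keep), max_seeds))]
  lapply(seeds[keep], function(s) cbind(ia = corr$i[s], ib = corr$j[s]))
}

# ---------------------------------------------------------------------------

#' Find the best-scoring alignment between two binding sites
#'
#' Deterministic heuristic search for the residue correspondence and rigid
#' transform maximizing the similarity score (ignoring sequential
#' connectivity; one-to-one matching of at least 3 residues). See the
#' package vignette for the algorithm. Sites with no geometrically
#' compatible seed yield an empty matching with score 0.
#'
#' @param site_a query site (its distance weights drive the score).
#' @param site_b target site.
#' @param options scoring options (\code{\link{score_options}}).
#' @param model substitution model.
#' @param max_seeds cap on the number of seed triplets explored.
#' @param dist_tol Calpha-Calpha distance compatibility tolerance (A) for
#'   seeding.
#' @param max_iter assignment/superposition refinement iterations per seed.
#' @param ladder_prune skip the refinement ladders for seeds scoring below
#'   this fraction of the best candidate found so far (0 disables pruning).
#' @return a \code{cpass_alignment}: \code{pairs} (k x 2 index matrix into
#'   the two sites' residue tables, sorted by query index), \code{rotation},
#'   \code{translation}, \code{rmsd} (of the matched backbone points),
#'   \code{score} (S_ab under \code{options}), \code{n_pairs}.
#' @export
find_best_alignment <- function(site_a, site_b, options = score_options(),
                                model = cpass_substitution(),
                                max_seeds = 500L, dist_tol = 1.5,
                                max_iter = 20L, ladder_prune = 0.25) {
  pc <- .align_precomp(site_a, site_b, model, options)
  if (min(pc$n, pc$m) < 3) return(.empty_alignment())
  seeds <- .seed_triplets(site_a, site_b, model, dist_tol, max_seeds)
  if (length(seeds) == 0) return(.empty_alignment())

  best <- NULL
  seen <- new.env(parent = emptyenv())

  consider <- function(cand) {
    if (is.null(cand)) return()
    cand$pairs <- .canon_pairs(cand$pairs)
    if (is.null(best) || cand$score > best$score + 1e-12 ||
        (abs(cand$score - best$score) <= 1e-12 &&
         .pairs_less(cand$pairs, best$pairs)))
      best <<- cand
  }

  evaluate <- function(pairs) {
    pairs <- .canon_pairs(pairs)
    key <- paste(t(pairs), collapse = ",")
    if (!is.null(seen[[key]])) return(seen[[key]])
    cand <- .eval_candidate(pc, pairs, options)
    seen[[key]] <- if (is.null(cand)) list(NULL) else cand
    if (!is.null(cand)) consider(cand)
    cand
  }

  ok <- function(x) is.list(x) && !is.null(x$score)
  subset_of_best <- function(pairs) {
    !is.null(best) &&
      all(paste(pairs[, 1], pairs[, 2]) %in%
            paste(best$pairs[, 1], best$pairs[, 2]))
  }

  for (seed in seeds) {
    if (subset_of_best(seed)) next
    cand0 <- evaluate(seed)
    if (!ok(cand0)) next
    # a seed far below the incumbent cannot seed the optimum; skip ladders
    if (!is.null(best) && best$score > 0 &&
        cand0$score < ladder_prune * best$score) next
    tr <- cand0$transform

    # growth ladder: extend the seed one pair at a time, always taking the
    # largest contribution under the current refitted transform
    gr <- cand0
    repeat {
      if (nrow(gr$pairs) >= min(pc$n, pc$m)) break
      cm <- .contribution_matrix(pc, gr$transform, options)
      cm[gr$pairs[, 1], ] <- -Inf
      cm[, gr$pairs[, 2]] <- -Inf
      mx <- max(cm)
      if (!is.finite(mx) || mx <= 0) break
      add <- which(cm == mx, arr.ind = TRUE)
      nxt <- evaluate(rbind(gr$pairs,
                            c(add[1, 1], add[1, 2])))
      if (!ok(nxt)) break
      gr <- nxt
    }

    # assignment iteration with prune ladder
    prev_key <- ""
    for (it in seq_len(max_iter)) {
      cm <- .contribution_matrix(pc, tr, options)
      pairs <- .best_assignment(cm)
      if (is.null(pairs) || nrow(pairs) < 3) break
      pairs <- .canon_pairs(pairs)
      key <- paste(t(pairs), collapse = ",")
      cand <- evaluate(pairs)
      if (!ok(cand)) break
      pr <- cand
      while (nrow(pr$pairs) > 3) {
        drop <- which.min(pr$contrib)
        nxt <- evaluate(pr$pairs[-drop, , drop = FALSE])
        if (!ok(nxt)) break
        pr <- nxt
      }
      if (key == prev_key) break
      prev_key <- key
      tr <- cand$transform
    }
  }

  if (is.null(best) || best$score <= 0) return(.empty_alignment())
  .finalize_alignment(pc, best, site_a, site_b, model, options)
}

.finalize_alignment <- function(pc, cand, site_a, site_b, model, options) {
  tr <- cand$transform
  al <- structure(list(pairs = cand$pairs, rotation = tr$rotation,
                       translation = tr$translation,
                       rmsd = NA_real_, score = NA_real_,
                       n_pairs = nrow(cand$pairs)),
                  class = "cpass_alignment")
  fit <- .fit_on_pairs(pc, cand$pairs, options)
  al$rmsd <- if (is.null(fit)) NA_real_ else fit$rmsd
  al$score <- score_alignment(site_a, site_b, al, model, options)$s_ab
  al
}

#' Exhaustive alignment oracle for small sites
#'
#' Enumerates every partial one-to-one matching of size >= 3 between the two
#' sites, superposes and scores each with its own least-squares transform,
#' and returns the maximum. Intended as a test oracle; refuses sites with
#' more than \code{max_size} residues on the smaller side.
#'
#' @inheritParams find_best_alignment
#' @param max_size largest allowed min(site size) (default 6).
#' @return a \code{cpass_alignment} (see \code{\link{find_best_alignment}}).
#' @export
brute_force_alignment <- function(site_a, site_b, options = score_options(),
                                  model = cpass_substitution(),
                                  max_size = 6L) {
  pc <- .align_precomp(site_a, site_b, model, options)
  n <- pc$n; m <- pc$m
  if (min(n, m) > max_size)
    stop("site too large for exhaustive enumeration; use find_best_alignment")
  if (min(n, m) < 3) return(.empty_alignment())

  best <- NULL
  consider <- function(cand) {
    if (is.null(cand)) return()
    cand$pairs <- .canon_pairs(cand$pairs)
    if (is.null(best) || cand$score > best$score + 1e-12 ||
        (abs(cand$score - best$score) <= 1e-12 &&
         .pairs_less(cand$pairs, best$pairs)))
      best <<- cand
  }

  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (k in seq_along(v))
      for (p in perms(v[-k])) out[[length(out) + 1L]] <- c(v[k], p)
    out
  }

  for (k in 3:min(n, m)) {
    subs_a <- utils::combn(n, k, simplify = FALSE)
    subs_b <- utils::combn(m, k, simplify = FALSE)
    for (sa in subs_a) {
      for (sb in subs_b) {
        for (pb in perms(sb)) {
          cand <- .eval_candidate(pc, cbind(ia = sa, ib = pb), options)
          consider(cand)
        }
      }
    }
  }
  if (is.null(best) || best$score <= 0) return(.empty_alignment())
  .finalize_alignment(pc, best, site_a, site_b, model, options)
}

#' Write an alignment as a TSV of matched residue pairs
#'
#' @param alignment a \code{cpass_alignment}.
#' @param site_a,site_b the aligned sites.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_alignment_tsv <- function(alignment, site_a, site_b, path) {
  ra <- site_a$residues; rb <- site_b$residues
  p <- alignment$pairs
  df <- data.frame(
    aa_a = ra$aa[p[, 1]], chain_a = ra$chain[p[, 1]],
    resno_a = ra$resno[p[, 1]],
    aa_b = rb$aa[p[, 2]], chain_b = rb$chain[p[, 2]],
    resno_b = rb$resno[p[, 2]], stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
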