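# Amino-acid replacement probabilities.
#
# The similarity function weighs each aligned residue pair by p_ij, the
# BLOSUM62 probability of replacing residue i with residue j. The embedded
# default is the published BLOSUM62 target (joint) frequency table q_ij of
# Henikoff & Henikoff, NOT the integer log-odds matrix: probabilities must
# be positive and on a common scale so that penalty factors multiply
# meaningfully. Custom 20x20 matrices can be loaded from file.

.QIJ_LOWER <- list(
  A = c(0.0215),
  R = c(0.0023, 0.0178),
  N = c(0.0019, 0.0020, 0.0141),
  D = c(0.0022, 0.0016, 0.0037, 0.0213),
  C = c(0.0016, 0.0004, 0.0004, 0.0004, 0.0119),
  Q = c(0.0019, 0.0025, 0.0015, 0.0016, 0.0003, 0.0073),
  E = c(0.0030, 0.0027, 0.0022, 0.0049, 0.0004, 0.0035, 0.0161),
  G = c(0.0058, 0.0017, 0.0029, 0.0025, 0.0008, 0.0014, 0.0019, 0.0378),
  H = c(0.0011, 0.0012, 0.0014, 0.0010, 0.0002, 0.0010, 0.0014, 0.0010,
        0.0093),
  I = c(0.0032, 0.0012, 0.0010, 0.0012, 0.0011, 0.0009, 0.0012, 0.0014,
        0.0006, 0.0184),
  L = c(0.0044, 0.0024, 0.0014, 0.0015, 0.0016, 0.0016, 0.0020, 0.0021,
        0.0010, 0.0114, 0.0371),
  K = c(0.0033, 0.0062, 0.0024, 0.0024, 0.0005, 0.0031, 0.0041, 0.0025,
        0.0012, 0.0016, 0.0025, 0.0161),
  M = c(0.0013, 0.0008, 0.0005, 0.0005, 0.0004, 0.0007, 0.0007, 0.0007,
        0.0004, 0.0025, 0.0049, 0.0009, 0.0040),
  F = c(0.0016, 0.0009, 0.0008, 0.0008, 0.0005, 0.0005, 0.0009, 0.0012,
        0.0008, 0.0030, 0.0054, 0.0009, 0.0012, 0.0183),
  P = c(0.0022, 0.0010, 0.0009, 0.0012, 0.0004, 0.0008, 0.0014, 0.0014,
        0.0005, 0.0010, 0.0014, 0.0016, 0.0004, 0.0005, 0.0191),
  S = c(0.0063, 0.0023, 0.0031, 0.0028, 0.0010, 0.0019, 0.0030, 0.0038,
        0.0011, 0.0017, 0.0024, 0.0031, 0.0009, 0.0012, 0.0017, 0.0126),
  T = c(0.0037, 0.0018, 0.0022, 0.0019, 0.0009, 0.0014, 0.0020, 0.0022,
        0.0007, 0.0027, 0.0033, 0.0023, 0.0010, 0.0012, 0.0014, 0.0047,
        0.0125),
  W = c(0.0004, 0.0003, 0.0002, 0.0002, 0.0001, 0.0002, 0.0003, 0.0004,
        0.0002, 0.0004, 0.0007, 0.0003, 0.0002, 0.0008, 0.0001, 0.0003,
        0.0003, 0.0065),
  Y = c(0.0013, 0.0009, 0.0007, 0.0006, 0.0003, 0.0007, 0.0009, 0.0008,
        0.0015, 0.0014, 0.0022, 0.0010, 0.0006, 0.0042, 0.0005, 0.0010,
        0.0009, 0.0009, 0.0102),
  V = c(0.0051, 0.0016, 0.0012, 0.0013, 0.0014, 0.0012, 0.0017, 0.0018,
        0.0006, 0.0120, 0.0095, 0.0019, 0.0023, 0.0026, 0.0012, 0.0024,
        0.0036, 0.0004, 0.0015, 0.0196))

.build_qij <- function() {
  aa <- names(.QIJ_LOWER)
  q <- matrix(0, 20, 20, dimnames = list(aa, aa))
  for (i in seq_along(aa)) for (j in seq_len(i)) {
    q[i, j] <- .QIJ_LOWER[[i]][j]
    q[j, i] <- .QIJ_LOWER[[i]][j]
  }
  q
}

.QIJ <- .build_qij()

#' BLOSUM62 replacement-probability model
#'
#' Returns the substitution model used by the similarity function: a
#' symmetric, strictly positive 20x20 matrix of replacement probabilities
#' indexed by one-letter amino-acid code. The default is the published
#' BLOSUM62 target (joint) frequency table.
#'
#' @param path optional path to a whitespace-delimited 20x20 matrix file
#'   with one-letter amino-acid row/column headers.
#' @return an object of class \code{cpass_submodel} (a probability matrix).
#' @export
cpass_substitution <- function(path = NULL) {
  if (is.null(path)) {
    q <- .QIJ
  } else {
    q <- as.matrix(utils::read.table(path, header = TRUE, row.names = 1,
                                     check.names = FALSE))
    if (!all(dim(q) == c(20, 20)))
      stop("substitution matrix file must be 20x20 with residue headers")
    q <- q[colnames(q), , drop = FALSE]  # enforce consistent ordering
  }
  if (!isSymmetric(unname(q), tol = 1e-12))
    stop("substitution matrix must be symmetric")
  if (any(q <= 0)) stop("replacement probabilities must be positive")
  class(q) <- c("cpass_submodel", class(q))
  q
}

#' Replacement probability for a residue pair
#'
#' @param model a \code{cpass_submodel}.
#' @param aa_i,aa_j three-letter residue codes (vectorized).
#' @return numeric probabilities.
#' @export
substitution_prob <- function(model, aa_i, aa_j) {
  a <- aa3to1(aa_i); b <- aa3to1(aa_j)
  if (any(a == "X") || any(b == "X"))
    stop("unknown residue code: ",
         paste(unique(c(aa_i[a == "X"], aa_j[b == "X"])), collapse = ", "))
  model[cbind(a, b)]
}

# marginal residue frequencies implied by the joint table
.submodel_marginals <- function(model) rowSums(unclass(model))

# TRUE when a replacement is favourable (enriched over chance): q_ij above
# the product of marginals, i.e. positive log-odds. Used to rank alignment
# seeds.
.favorable_pair <- function(model, aa_i, aa_j) {
  p <- .submodel_marginals(model)
  a <- aa3to1(aa_i); b <- aa3to1(aa_j)
  model[cbind(a, b)] > p[a] * p[b]
}
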