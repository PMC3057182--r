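# Builders for hand-specified toy sites and ligands, used where tests need
# exact geometry (penalty arithmetic, manual score checks).

toy_ligand <- function(xyz, code = "LIG", elesy = NULL) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  if (is.null(elesy)) elesy <- rep("C", n)
  atoms <- data.frame(
    elety = paste0(elesy, seq_len(n)), elesy = elesy, resid = code,
    chain = "A", resno = 900L, insert = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    is_hydrogen = elesy %in% c("H", "D"), stringsAsFactors = FALSE)
  structure(list(code = code, instance = "A900", atoms = atoms,
                 heavy_atom_count = sum(!atoms$is_hydrogen),
                 is_polymer = FALSE, polymer_length = NA_integer_),
            class = "cpass_ligand")
}

# residues: data.frame(aa, ca_x.., cb_x.. (NA for GLY), rel_sasa, d_i)
toy_site <- function(aa, ca, cb = NULL, rel_sasa, d_i, ligand = NULL,
                     id = "toy") {
  n <- length(aa)
  ca <- matrix(ca, ncol = 3)
  if (is.null(cb)) cb <- matrix(NA_real_, n, 3) else cb <- matrix(cb, ncol = 3)
  res <- data.frame(
    aa = aa, chain = "A", resno = seq_len(n), insert = "",
    res_key = paste0("A|", seq_len(n), "|"),
    ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
    cb_x = cb[, 1], cb_y = cb[, 2], cb_z = cb[, 3],
    rel_sasa = rep_len(rel_sasa, n), d_i = rep_len(d_i, n),
    stringsAsFactors = FALSE)
  ref <- if (is.null(ligand)) colMeans(ca)
         else colMeans(cpassr:::.ligand_heavy_xyz(ligand))
  cpassr:::.new_binding_site(
    source_id = id, ligand = ligand, reference_point = ref,
    residues = res,
    mode = if (is.null(ligand)) "manual" else "ligand_defined")
}

identity_alignment <- function(n) {
  list(pairs = cbind(ia = seq_len(n), ib = seq_len(n)),
       rotation = diag(3), translation = c(0, 0, 0))
}

rigid_rotate_site <- function(site, angle = 0.7, axis = c(0, 0, 1),
                              shift = c(3, -2, 5)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  tx <- function(m) sweep(as.matrix(m) %*% t(R), 2, shift, "+")
  r <- site$residues
  r[, c("ca_x", "ca_y", "ca_z")] <- tx(r[, c("ca_x", "ca_y", "ca_z")])
  has_cb <- is.finite(r$cb_x)
  if (any(has_cb))
    r[has_cb, c("cb_x", "cb_y", "cb_z")] <-
      tx(r[has_cb, c("cb_x", "cb_y", "cb_z")])
  site$residues <- r
  if (!is.null(site$ligand)) {
    site$ligand$atoms[, c("x", "y", "z")] <-
      tx(site$ligand$atoms[, c("x", "y", "z")])
  }
  site
}

random_fixture_pair <- function(k, n_range = 3:5) {
  list(
    a = fixture_site(make_site_structure(
      fixture_spec(n_site_residues = sample(n_range, 1), seed = 1000 + k))),
    b = fixture_site(make_site_structure(
      fixture_spec(n_site_residues = sample(n_range, 1), seed = 2000 + k))))
}
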