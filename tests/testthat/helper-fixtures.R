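# Programmatic fixtures used across tests.

# a tiny atom-table builder: make_atoms("GLY", 1, N = c(0,0,0), ...) rows
res_atoms <- function(resid, resno, chain = "A", ...) {
  coords <- list(...)
  do.call(rbind, lapply(names(coords), function(el) {
    data.frame(chain = chain, resno = resno, insert = "", resid = resid,
               elety = el, element = protrin:::.element_from_name(el),
               x = coords[[el]][1], y = coords[[el]][2], z = coords[[el]][3],
               o = 1, alt = "", stringsAsFactors = FALSE)
  }))
}

make_structure <- function(..., id = "test") {
  new_structure(do.call(rbind, list(...)), id = id)
}

# idealized benzene-geometry PHE ring centred at `centre`
phe_ring_atoms <- function(resno, centre = c(0, 0, 0), chain = "A") {
  ang <- pi / 2 + (0:5) * pi / 3
  ring <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  data.frame(chain = chain, resno = resno, insert = "", resid = "PHE",
             elety = ring, element = "C",
             x = centre[1], y = centre[2] + 1.39 * cos(ang),
             z = centre[3] + 1.39 * sin(ang),
             o = 1, alt = "", stringsAsFactors = FALSE)
}

# dense random structure for oracle-equivalence tests: residues drawn from
# the package's idealized templates, random positions and rotations in a box
random_structure <- function(n_res = 50, seed = 1, box = 28) {
  set.seed(seed)
  tmpl <- protrin:::.fixture_templates
  rows <- lapply(seq_len(n_res), function(i) {
    tm <- tmpl[[sample(length(tmpl), 1)]]
    rot <- protrin:::.random_rotation()
    xyz <- as.matrix(tm[, c("x", "y", "z")]) %*% t(rot)
    pos <- runif(3, 0, box)
    data.frame(chain = "A", resno = i, insert = "", resid = tm$resid,
               elety = tm$elety,
               element = protrin:::.element_from_name(tm$elety),
               x = xyz[, 1] + pos[1], y = xyz[, 2] + pos[2],
               z = xyz[, 3] + pos[3],
               o = 1, alt = "", stringsAsFactors = FALSE)
  })
  new_structure(do.call(rbind, rows), id = paste0("random", seed))
}

random_rigid_transform <- function() {
  r <- protrin:::.random_rotation()
  t <- runif(3, -50, 50)
  list(R = r, t = t)
}

apply_rigid <- function(structure, tf) {
  at <- structure$atoms
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% t(tf$R)
  at$x <- xyz[, 1] + tf$t[1]
  at$y <- xyz[, 2] + tf$t[2]
  at$z <- xyz[, 3] + tf$t[3]
  at$resi <- NULL
  new_structure(at, id = structure$id)
}

# minimal hand-written two-residue PDB text
two_residue_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1       2.000  -0.760  -1.210  1.00  0.00           C",
    "ATOM      6  N   GLY A   2       3.332   1.540   0.000  1.00  0.00           N",
    "ATOM      7  CA  GLY A   2       3.970   2.850   0.000  1.00  0.00           C",
    "ATOM      8  C   GLY A   2       5.480   2.700   0.000  1.00  0.00           C",
    "ATOM      9  O   GLY A   2       6.030   1.600   0.000  1.00  0.00           O",
    "END"), path)
  path
}
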