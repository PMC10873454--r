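# Seeded generators for fixtures with planted ground truth: structures whose
# residue pairs realize each interaction type at a controlled distance,
# alignments with planted group-A/B columns, charge-composition sequences,
# and trees with clade rate contrasts.

# Residue templates in local coordinates. The "contact" atom (or ring
# centroid) sits at the origin and the rest of the residue extends into the
# x <= 0 half-space (the aromatic template lies in the x = 0 plane), so two
# templates facing each other across the x axis realize their interaction at
# exactly the requested contact distance while every other cross-pair stays
# at least that far apart. Idealized bond geometry; realism beyond what the
# detectors require is a non-goal.
.fixture_templates <- local({
  df <- function(resid, ...) {
    m <- matrix(c(...), ncol = 4, byrow = TRUE)
    data.frame(resid = resid, elety = m[, 1],
               x = as.numeric(m[, 2]), y = as.numeric(m[, 3]),
               z = as.numeric(m[, 4]), stringsAsFactors = FALSE)
  }
  phe <- local({
    ang <- pi / 2 + (0:5) * pi / 3
    ring <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
    rbind(
      data.frame(resid = "PHE", elety = ring, x = 0,
                 y = 1.39 * cos(ang), z = 1.39 * sin(ang),
                 stringsAsFactors = FALSE),
      df("PHE",
         "CB", 0, 2.90, 0,
         "CA", 0, 4.43, 0,
         "N", 0, 5.10, 1.29,
         "C", 0, 5.50, -1.10,
         "O", 0, 6.70, -1.30)
    )
  })
  list(
    gly_acceptor = df("GLY",
                      "O", 0, 0, 0,
                      "C", -1.23, 0, 0,
                      "CA", -2.03, 1.19, 0,
                      "N", -3.45, 1.05, 0),
    gly_donor = df("GLY",
                   "N", 0, 0, 0,
                   "CA", -1.46, 0, 0,
                   "C", -2.23, -1.26, 0,
                   "O", -1.65, -2.36, 0),
    ala_vdw = df("ALA",
                 "CB", 0, 0, 0,
                 "CA", -1.53, 0, 0,
                 "N", -2.22, -1.29, 0,
                 "C", -2.30, 1.24, 0,
                 "O", -1.78, 2.34, 0),
    cys_ss = df("CYS",
                "SG", 0, 0, 0,
                "CB", -1.81, 0, 0,
                "CA", -2.55, 1.34, 0,
                "N", -2.90, 2.70, 0,
                "C", -4.05, 1.40, 0,
                "O", -4.65, 2.45, 0),
    asp_neg = df("ASP",
                 "OD2", 0, 0, 0,
                 "CG", -1.25, 0, 0,
                 "OD1", -1.87, 1.08, 0,
                 "CB", -2.03, -1.21, 0,
                 "CA", -3.55, -1.10, 0,
                 "N", -4.12, -2.44, 0,
                 "C", -4.20, 0.20, 0,
                 "O", -3.70, 1.30, 0),
    lys_pos = df("LYS",
                 "NZ", 0, 0, 0,
                 "CE", -1.49, 0, 0,
                 "CD", -2.23, -1.29, 0,
                 "CG", -3.72, -1.29, 0,
                 "CB", -4.46, -2.58, 0,
                 "CA", -5.95, -2.58, 0,
                 "N", -6.65, -3.86, 0,
                 "C", -6.65, -1.29, 0,
                 "O", -6.05, -0.21, 0),
    phe_ring = phe
  )
})

.fixture_roles <- list(
  HBOND = c("gly_acceptor", "gly_donor"),
  VDW = c("ala_vdw", "ala_vdw"),
  SSBOND = c("cys_ss", "cys_ss"),
  IONIC = c("asp_neg", "lys_pos"),
  PIPI = c("phe_ring", "phe_ring"),
  PICATION = c("lys_pos", "phe_ring")
)

.planted_distance <- function(itype, config, margin) {
  switch(itype,
    HBOND = config$hbond_cutoff - margin,
    VDW = 2 * config$vdw_radii[["C"]] + config$vdw_slack - margin,
    SSBOND = config$disulfide_cutoff - margin,
    IONIC = config$ionic_cutoff - margin,
    PIPI = config$pipi_cutoff - margin,
    PICATION = config$pication_cutoff - margin
  )
}

.random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a structure fixture with planted interactions
#'
#' Places isolated residue pairs on a coarse grid (slots 40 A apart, so
#' units cannot interact with each other), each pair realizing one
#' interaction type at `cutoff - margin`; decoy pairs use the same geometry
#' at `cutoff + margin` and must not be detected. Each unit receives a
#' seeded random rigid rotation. Output is writable as a legal PDB file and
#' byte-identical across runs with the same seed.
#'
#' @param planted named integer vector: planted pair count per interaction
#'   type (names among HBOND, VDW, SSBOND, IONIC, PIPI, PICATION).
#' @param decoys named integer vector: decoy pair count per type.
#' @param margin distance margin in Angstrom, in (0, 0.4]; larger margins
#'   would push some planted geometries inside another type's cutoff (e.g. a
#'   salt bridge planted closer than 3.6 A also becomes a Van der Waals
#'   contact).
#' @param seed RNG seed.
#' @param config an [interaction_config()]; cutoffs define the planted
#'   distances.
#' @param box_size optional edge length (A) of the allowed placement cube;
#'   an error is raised if the units do not fit.
#' @param id structure label.
#' @return List with `structure` (a `protein_structure`) and `truth`, a data
#'   frame of the planted edges (resno_a, resno_b, itype, pair_label).
#' @export
make_structure_fixture <- function(planted = c(HBOND = 1, VDW = 1,
                                               SSBOND = 1, IONIC = 1,
                                               PIPI = 1, PICATION = 1),
                                   decoys = integer(),
                                   margin = 0.3,
                                   seed = 1L,
                                   config = interaction_config(),
                                   box_size = NULL,
                                   id = NULL) {
  stopifnot(all(names(planted) %in% .itypes),
            all(names(decoys) %in% .itypes))
  if (margin <= 0 || margin > 0.4) stop("margin must be in (0, 0.4]")
  set.seed(seed)

  units <- list()
  for (itype in names(planted)) {
    for (k in seq_len(planted[[itype]])) {
      units[[length(units) + 1L]] <- list(itype = itype, real = TRUE)
    }
  }
  for (itype in names(decoys)) {
    for (k in seq_len(decoys[[itype]])) {
      units[[length(units) + 1L]] <- list(itype = itype, real = FALSE)
    }
  }
  if (!length(units)) stop("no units requested")

  spacing <- 40
  m <- ceiling(length(units)^(1 / 3))
  if (!is.null(box_size) && (m - 1) * spacing + 30 > box_size) {
    stop("infeasible packing: ", length(units), " units need a box of ",
         (m - 1) * spacing + 30, " A, box_size is ", box_size)
  }

  atom_rows <- list()
  truth <- list()
  for (u in seq_along(units)) {
    itype <- units[[u]]$itype
    d <- if (units[[u]]$real) {
      .planted_distance(itype, config, margin)
    } else if (itype == "SSBOND") {
      # a cysteine pair just outside the disulfide cutoff still sits inside
      # the S-S Van der Waals contact range; decoys must miss every type
      2 * config$vdw_radii[["S"]] + config$vdw_slack + margin
    } else {
      .planted_distance(itype, config, margin) + 2 * margin
    }
    roles <- .fixture_roles[[itype]]
    ta <- .fixture_templates[[roles[1]]]
    tb <- .fixture_templates[[roles[2]]]
    # partner faces back along x: proper rotation by pi about the z axis
    # through (d/2, 0, 0)
    tb2 <- tb
    tb2$x <- d - tb$x
    tb2$y <- -tb$y
    both <- rbind(cbind(ta, part = 1L), cbind(tb2, part = 2L))
    rot <- .random_rotation()
    xyz <- as.matrix(both[, c("x", "y", "z")]) %*% t(rot)
    gx <- ((u - 1) %% m) * spacing
    gy <- (((u - 1) %/% m) %% m) * spacing
    gz <- ((u - 1) %/% (m * m)) * spacing
    resno_a <- 10L * u
    resno_b <- 10L * u + 3L
    atom_rows[[u]] <- data.frame(
      chain = "A",
      resno = ifelse(both$part == 1L, resno_a, resno_b),
      insert = "", resid = both$resid, elety = both$elety,
      element = .element_from_name(both$elety),
      x = xyz[, 1] + gx, y = xyz[, 2] + gy, z = xyz[, 3] + gz,
      o = 1, alt = "", stringsAsFactors = FALSE
    )
    if (units[[u]]$real) {
      lab <- if (itype == "PIPI") "F-F" else NA_character_
      truth[[length(truth) + 1L]] <- data.frame(
        resno_a = resno_a, resno_b = resno_b, itype = itype,
        pair_label = lab, stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, atom_rows)
  atoms$x <- round(atoms$x, 3)
  atoms$y <- round(atoms$y, 3)
  atoms$z <- round(atoms$z, 3)
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(resno_a = integer(), resno_b = integer(),
               itype = character(), pair_label = character())
  list(structure = new_structure(atoms,
                                 id = if (is.null(id))
                                   paste0("fixture_seed", seed) else id,
                                 source_path = "synthetic"),
       truth = truth_df)
}

#' Generate an alignment fixture with planted group A/B columns
#'
#' Builds a reference row plus `n_cluster` cluster rows (the first cluster
#' row is the query). Planted A columns differ from the reference in every
#' cluster row; planted B columns differ in the query plus a uniform-random
#' 0..n_cluster-2 other members (so 1..n_cluster-1 in total, a proper
#' subset); all remaining columns are identical across rows.
#'
#' @param n_cluster number of cluster rows (>= 2).
#' @param length alignment length in columns.
#' @param n_groupA,n_groupB planted column counts.
#' @param n_identical minimum number of identical columns (the remainder of
#'   the alignment is identical as well); used only to validate feasibility.
#' @param seed RNG seed.
#' @return List with `alignment` (named character vector: `REF`, `M1..Mk`),
#'   `truth` (list with per-column `groups` of "A"/"B"/"none", `ref_id`,
#'   `query_id`, `cluster_ids`).
#' @export
make_msa_fixture <- function(n_cluster = 5L, length = 60L,
                             n_groupA = 8L, n_groupB = 6L,
                             n_identical = 0L, seed = 1L) {
  if (n_cluster < 2) stop("n_cluster must be >= 2")
  if (n_groupA + n_groupB + n_identical > length) {
    stop("n_groupA + n_groupB + n_identical exceeds alignment length")
  }
  set.seed(seed)
  aa <- unname(.aa3to1)
  ref <- sample(aa, length, replace = TRUE)
  rows <- matrix(rep(ref, each = n_cluster), nrow = n_cluster)
  groups <- rep("none", length)
  special <- sample.int(length, n_groupA + n_groupB)
  a_cols <- special[seq_len(n_groupA)]
  b_cols <- special[setdiff(seq_along(special), seq_len(n_groupA))]
  groups[a_cols] <- "A"
  groups[b_cols] <- "B"
  alt <- function(r) sample(setdiff(aa, r), 1)
  for (j in a_cols) {
    rows[, j] <- vapply(seq_len(n_cluster), function(i) alt(ref[j]),
                        character(1))
  }
  for (j in b_cols) {
    rows[1, j] <- alt(ref[j])
    n_others <- sample.int(n_cluster - 1L, 1) - 1L # 0 .. n_cluster-2
    if (n_others > 0) {
      for (i in 1L + sample.int(n_cluster - 1L, n_others)) {
        rows[i, j] <- alt(ref[j])
      }
    }
  }
  ids <- c("REF", paste0("M", seq_len(n_cluster)))
  aln <- stats::setNames(
    c(paste(ref, collapse = ""),
      apply(rows, 1, paste, collapse = "")),
    ids)
  list(alignment = aln,
       truth = list(groups = groups, ref_id = "REF", query_id = "M1",
                    cluster_ids = ids[-1]))
}

#' Generate a sequence with a known charge composition
#'
#' @param n_acidic number of acidic residues (drawn from D, E).
#' @param n_basic number of basic residues (drawn from R, K, H).
#' @param n_neutral number of neutral residues.
#' @param seed RNG seed.
#' @return Character scalar: a shuffled sequence with exactly the requested
#'   composition.
#' @export
make_charge_fixture <- function(n_acidic, n_basic, n_neutral, seed = 1L) {
  stopifnot(n_acidic >= 0, n_basic >= 0, n_neutral >= 0)
  set.seed(seed)
  neutral_aa <- setdiff(unname(.aa3to1), c("D", "E", "R", "K", "H"))
  pool <- c(sample(c("D", "E"), n_acidic, replace = TRUE),
            sample(c("R", "K", "H"), n_basic, replace = TRUE),
            sample(neutral_aa, n_neutral, replace = TRUE))
  paste(sample(pool), collapse = "")
}

#' Generate a tree fixture with a fast-evolving clade
#'
#' Random per-clade topologies joined on a ladder backbone; edge lengths are
#' exponential with mean `base_rate`, multiplied by `fast_clade_multiplier`
#' inside the fast clade. Defaults emulate a four-cluster phylogeny whose
#' fourth cluster evolves about 4.5 times faster (mean edge length ~0.57
#' versus ~0.13).
#'
#' @param clade_sizes integer vector of leaves per clade (each >= 2).
#' @param base_rate mean edge length of ordinary clades.
#' @param fast_clade_multiplier rate multiplier of the fast clade.
#' @param fast_clade index of the fast clade.
#' @param seed RNG seed.
#' @return List with `tree` (`phylo`), `truth` (list: `clades` named leaf
#'   sets, `generating_mean` per clade, `fast_clade`).
#' @export
make_tree_fixture <- function(clade_sizes = c(10L, 10L, 10L, 10L),
                              base_rate = 0.13,
                              fast_clade_multiplier = 4.5,
                              fast_clade = length(clade_sizes),
                              seed = 1L) {
  if (length(clade_sizes) < 2) stop("need at least 2 clades")
  if (any(clade_sizes < 2)) stop("every clade needs >= 2 leaves")
  set.seed(seed)
  k <- length(clade_sizes)
  subs <- character(k)
  clades <- list()
  gen_mean <- numeric(k)
  for (i in seq_len(k)) {
    n <- clade_sizes[i]
    mult <- if (i == fast_clade) fast_clade_multiplier else 1
    gen_mean[i] <- base_rate * mult
    phy <- ape::rtree(n, br = NULL,
                      tip.label = paste0("cl", i, "_t", seq_len(n)))
    phy$edge.length <- stats::rexp(nrow(phy$edge), rate = 1 / gen_mean[i])
    txt <- ape::write.tree(phy)
    subs[i] <- sub(";$", "", txt)
    clades[[paste0("clade", i)]] <- phy$tip.label
  }
  # ladder backbone with fixed spine lengths
  spine <- format(base_rate, scientific = FALSE)
  node <- paste0(subs[k], ":", spine)
  for (i in rev(seq_len(k - 1L))) {
    node <- paste0("(", subs[i], ":", spine, ",", node, ")",
                   if (i > 1) paste0(":", spine) else "")
  }
  tree <- ape::read.tree(text = paste0(node, ";"))
  names(gen_mean) <- names(clades)
  list(tree = tree,
       truth = list(clades = clades, generating_mean = gen_mean,
                    fast_clade = fast_clade))
}
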