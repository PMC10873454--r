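# Unit tests of the six interaction detectors on hand-built geometries.

test_that("hydrogen bonds respect the donor-acceptor distance cutoff", {
  # backbone N of residue 5 placed 2.9 A from backbone O of residue 1
  st <- make_structure(
    res_atoms("GLY", 1, N = c(-3.45, 1.05, 0), CA = c(-2.03, 1.19, 0),
              C = c(-1.23, 0, 0), O = c(0, 0, 0)),
    res_atoms("GLY", 5, N = c(2.9, 0, 0), CA = c(4.36, 0, 0),
              C = c(5.13, -1.26, 0), O = c(4.55, -2.36, 0))
  )
  e <- detect_hbonds(st)
  expect_equal(nrow(e), 1L)
  expect_equal(e$itype, "HBOND")
  expect_equal(e$distance, 2.9, tolerance = 1e-9)

  # stretched beyond the cutoff
  st2 <- make_structure(
    res_atoms("GLY", 1, N = c(-3.45, 1.05, 0), CA = c(-2.03, 1.19, 0),
              C = c(-1.23, 0, 0), O = c(0, 0, 0)),
    res_atoms("GLY", 5, N = c(3.6, 0, 0), CA = c(5.06, 0, 0),
              C = c(5.83, -1.26, 0), O = c(5.25, -2.36, 0))
  )
  expect_equal(nrow(detect_hbonds(st2)), 0L)

  # covalent neighbours (|i-j| < 2) are never counted
  st3 <- make_structure(
    res_atoms("GLY", 1, O = c(0, 0, 0), C = c(-1.23, 0, 0)),
    res_atoms("GLY", 2, N = c(2.9, 0, 0), CA = c(4.36, 0, 0))
  )
  expect_equal(nrow(detect_hbonds(st3)), 0L)
})

test_that("planted i,i+4 helix-like contacts are all found and no others", {
  # 20 residues on a wide circle; k = 4 planted N...O contacts at 2.9 A
  k <- 4
  rows <- list()
  for (i in 1:20) {
    base <- c(50 * cos(2 * pi * i / 20) * 3, 50 * sin(2 * pi * i / 20) * 3, 0)
    rows[[i]] <- res_atoms("GLY", i, N = base, CA = base + c(1.46, 0, 0),
                           C = base + c(2.2, 1.2, 0), O = base + c(2, 2.4, 0))
  }
  st <- make_structure(do.call(rbind, rows))
  # overwrite: place O of residue i at fixed offset 2.9 from N of residue i+4
  at <- st$atoms
  for (i in seq_len(k)) {
    n_next <- which(at$resno == i + 4 & at$elety == "N")
    o_this <- which(at$resno == i & at$elety == "O")
    at[o_this, c("x", "y", "z")] <- at[n_next, c("x", "y", "z")] +
      c(0, 0, 2.9)
  }
  at$resi <- NULL
  st <- new_structure(at)
  e <- detect_hbonds(st)
  expect_equal(nrow(e), k)
  expect_equal(sort(e$resno_a), 1:k)
  # matches the brute-force oracle
  or <- oracle_rin(st)
  expect_identical(edge_key(e), oracle_key(or[or$itype == "HBOND", ]))
})

test_that("Van der Waals uses radius sum plus slack on side-chain atoms", {
  mk <- function(d) make_structure(
    res_atoms("ALA", 1, CB = c(0, 0, 0), CA = c(-1.53, 0, 0)),
    res_atoms("ALA", 4, CB = c(d, 0, 0), CA = c(d + 1.53, 0, 0))
  )
  expect_equal(nrow(detect_vdw(mk(3.8))), 1L)  # 3.8 <= 1.7+1.7+0.5
  expect_equal(nrow(detect_vdw(mk(3.95))), 0L)
  # backbone-only contact is not a VdW edge
  st <- make_structure(
    res_atoms("GLY", 1, CA = c(0, 0, 0), N = c(-1.46, 0, 0)),
    res_atoms("GLY", 4, CA = c(3.0, 0, 0), N = c(4.46, 0, 0))
  )
  expect_equal(nrow(detect_vdw(st)), 0L)
  # unknown element is an error naming the atom
  bad <- make_structure(res_atoms("ALA", 1, CB = c(0, 0, 0)),
                        res_atoms("ALA", 4, CB = c(3, 0, 0)))
  bad$atoms$element[1] <- "ZZ"
  expect_error(detect_vdw(bad), "ZZ")
})

test_that("disulfides pair SG atoms within 2.5 A", {
  mk_cys <- function(resno, sg) res_atoms("CYS", resno, SG = sg,
                                          CB = sg - c(1.81, 0, 0))
  st <- make_structure(mk_cys(1, c(0, 0, 0)), mk_cys(10, c(2.05, 0, 0)))
  e <- detect_ssbonds(st)
  expect_equal(nrow(e), 1L)
  expect_equal(e$distance, 2.05, tolerance = 1e-9)
  st2 <- make_structure(mk_cys(1, c(0, 0, 0)), mk_cys(10, c(2.6, 0, 0)))
  expect_equal(nrow(detect_ssbonds(st2)), 0L)
  # three cysteines, one qualifying pair
  st3 <- make_structure(mk_cys(1, c(0, 0, 0)), mk_cys(10, c(2.05, 0, 0)),
                        mk_cys(20, c(20, 0, 0)))
  e3 <- detect_ssbonds(st3)
  expect_equal(nrow(e3), 1L)
  expect_identical(edge_key(e3),
                   oracle_key(oracle_rin(st3) |>
                                (\(o) o[o$itype == "SSBOND", ])()))
})

test_that("ionic bonds require opposite charges within 4.0 A", {
  asp <- function(resno, od2) res_atoms("ASP", resno, OD2 = od2,
                                        CG = od2 - c(1.25, 0, 0),
                                        OD1 = od2 + c(-1.87, 1.08, 0))
  lys <- function(resno, nz) res_atoms("LYS", resno, NZ = nz,
                                       CE = nz + c(1.49, 0, 0))
  glu <- function(resno, oe1) res_atoms("GLU", resno, OE1 = oe1,
                                        CD = oe1 - c(1.25, 0, 0))
  st <- make_structure(asp(1, c(0, 0, 0)), lys(5, c(3.5, 0, 0)))
  e <- detect_ionic(st)
  expect_equal(nrow(e), 1L)
  expect_equal(e$itype, "IONIC")
  # like charges: no edge
  st2 <- make_structure(asp(1, c(0, 0, 0)), glu(5, c(3.5, 0, 0)))
  expect_equal(nrow(detect_ionic(st2)), 0L)
})

test_that("planted salt bridges are found and decoys rejected", {
  set.seed(1)
  rows <- list()
  d_in <- c(2.8, 3.1, 3.4, 3.7, 3.9)
  d_out <- c(4.2, 4.6, 5.0, 5.5, 6.0)
  for (i in 1:5) {
    base <- c(40 * i, 0, 0)
    rows[[2 * i - 1]] <- res_atoms("ASP", 10 * i, OD2 = base,
                                   CG = base - c(1.25, 0, 0))
    rows[[2 * i]] <- res_atoms("LYS", 10 * i + 3, NZ = base + c(d_in[i], 0, 0),
                               CE = base + c(d_in[i] + 1.49, 0, 0))
  }
  for (i in 1:5) {
    base <- c(40 * i, 100, 0)
    rows[[10 + 2 * i - 1]] <- res_atoms("ASP", 200 + 10 * i, OD2 = base,
                                        CG = base - c(1.25, 0, 0))
    rows[[10 + 2 * i]] <- res_atoms("LYS", 200 + 10 * i + 3,
                                    NZ = base + c(d_out[i], 0, 0),
                                    CE = base + c(d_out[i] + 1.49, 0, 0))
  }
  st <- make_structure(do.call(rbind, rows))
  e <- detect_ionic(st)
  expect_equal(nrow(e), 5L)
  expect_true(all(e$resno_a < 200))
})

test_that("aromatic centroids follow the ring definitions", {
  ring <- phe_ring_atoms(1)
  cents <- aromatic_centroids(ring)
  expect_length(cents, 1L)
  expect_equal(unname(cents[[1]]$centroid), c(0, 0, 0), tolerance = 1e-6)

  # TRP yields two centroids
  trp <- data.frame(chain = "A", resno = 1, insert = "", resid = "TRP",
                    elety = c("CG", "CD1", "CD2", "NE1", "CE2",
                              "CE3", "CZ2", "CZ3", "CH2"),
                    element = c("C", "C", "C", "N", "C", "C", "C", "C", "C"),
                    x = rnorm(9), y = rnorm(9), z = rnorm(9),
                    o = 1, alt = "", stringsAsFactors = FALSE)
  expect_length(aromatic_centroids(trp), 2L)

  # missing ring atom: skipped with a warning
  incomplete <- ring[ring$elety != "CZ", ]
  expect_warning(out <- aromatic_centroids(incomplete), "CZ")
  expect_length(out, 0L)
})

test_that("pi-pi stacking uses centroid distance and labels pairs", {
  st <- make_structure(phe_ring_atoms(1), phe_ring_atoms(5, c(5, 0, 0)))
  e <- detect_pipi(st)
  expect_equal(nrow(e), 1L)
  expect_equal(e$pair_label, "F-F")
  expect_equal(e$distance, 5.0, tolerance = 1e-9)

  st2 <- make_structure(phe_ring_atoms(1), phe_ring_atoms(5, c(6.6, 0, 0)))
  expect_equal(nrow(detect_pipi(st2)), 0L)

  # pair-type tally: 3 F-F and 1 F-Y inside the cutoff
  tyr <- phe_ring_atoms(42, c(200, 5, 0))
  tyr$resid <- "TYR"
  st3 <- make_structure(
    phe_ring_atoms(1), phe_ring_atoms(5, c(5, 0, 0)),
    phe_ring_atoms(11, c(0, 100, 0)), phe_ring_atoms(15, c(5, 100, 0)),
    phe_ring_atoms(21, c(0, 200, 0)), phe_ring_atoms(25, c(5, 200, 0)),
    phe_ring_atoms(40, c(200, 0, 0)), tyr
  )
  s <- build_rin(st3)$summary
  expect_equal(s$pipi_pairs[["F-F"]], 3L)
  expect_equal(s$pipi_pairs[["F-Y"]], 1L)
})

test_that("pi-cation pairs cation points with ring centroids", {
  lys <- function(resno, nz) res_atoms("LYS", resno, NZ = nz,
                                       CE = nz + c(0, 3, 1.49))
  st <- make_structure(phe_ring_atoms(1), lys(5, c(4.2, 0, 0)))
  e <- detect_pication(st)
  expect_equal(nrow(e), 1L)
  expect_equal(e$distance, 4.2, tolerance = 1e-9)
  st2 <- make_structure(phe_ring_atoms(1), lys(5, c(5.2, 0, 0)))
  expect_equal(nrow(detect_pication(st2)), 0L)

  # 2 Lys-Phe + 1 Arg-Tyr geometries inside the cutoff -> 3 edges
  arg <- function(resno, ctr) res_atoms("ARG", resno,
    CZ = ctr, NE = ctr + c(0, 1.2, 0), NH1 = ctr + c(0, -0.6, 1.04),
    NH2 = ctr + c(0, -0.6, -1.04))
  tyr <- phe_ring_atoms(31, c(200, 0, 0)); tyr$resid <- "TYR"
  st3 <- make_structure(
    phe_ring_atoms(1), lys(5, c(4.2, 0, 0)),
    phe_ring_atoms(11, c(0, 100, 0)), lys(15, c(4.2, 100, 0)),
    tyr, arg(35, c(204.5, 0, 0))
  )
  expect_equal(nrow(detect_pication(st3)), 3L)
})

test_that("build_rin deduplicates, orders deterministically, and is additive", {
  fx <- make_structure_fixture(seed = 2)
  net1 <- build_rin(fx$structure)
  net2 <- build_rin(fx$structure)
  expect_identical(net1$edges, net2$edges)
  s <- net1$summary
  expect_equal(s$n_edges, sum(s$per_type))
  expect_equal(sum(s$pipi_pairs), unname(s$per_type["PIPI"]))
  expect_true(s$n_nodes <= 2 * s$n_edges)

  # empty-interaction structure: all residues far apart
  far <- make_structure(
    res_atoms("ALA", 1, CB = c(0, 0, 0), CA = c(-1.53, 0, 0)),
    res_atoms("ALA", 5, CB = c(50, 0, 0), CA = c(51.53, 0, 0))
  )
  s0 <- build_rin(far)$summary
  expect_equal(s0$n_edges, 0L)
  expect_true(is.na(s0$edge_node_ratio))
})
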