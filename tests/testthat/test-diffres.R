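# Group A/B column classification, mutant design, terminus splitting, and
# spatial region enrichment.

toy_alignment <- function() {
  # ref vs 5-member cluster (query = M1); columns:
  # 1: identical; 2: all differ (A); 3: only the query differs (B);
  # 4: identical; 5: query gapped, all differ (A, no query position);
  # 6: ref gapped, all differ (A); 7: identical
  c(REF = "QWKAQ-G",
    M1 = "QERA-SG", M2 = "QEKARSG", M3 = "QEKARSG", M4 = "QEKARSG",
    M5 = "QEKARSG")
}

test_that("columns where every cluster member differs are group A", {
  aln <- c(REF = "Q", M1 = "E", M2 = "E", M3 = "E", M4 = "E", M5 = "E")
  cls <- classify_columns(aln, "REF", "M1", paste0("M", 1:5))
  expect_equal(nrow(cls), 1L)
  expect_equal(cls$group, "A")
  expect_equal(cls$n_cluster_diff, 5L)
})

test_that("columns where a proper subset differs are group B", {
  aln <- c(REF = "Q", M1 = "E", M2 = "Q", M3 = "Q", M4 = "E", M5 = "E")
  cls <- classify_columns(aln, "REF", "M1", paste0("M", 1:5))
  expect_equal(cls$group, "B")
  expect_equal(cls$n_cluster_diff, 3L)
})

test_that("columns matching the reference yield no record", {
  aln <- c(REF = "Q", M1 = "Q", M2 = "E", M3 = "Q", M4 = "Q", M5 = "Q")
  cls <- classify_columns(aln, "REF", "M1", paste0("M", 1:5))
  expect_equal(nrow(cls), 0L)
})

test_that("gap handling: gaps differ from residues; query gaps unmutable", {
  cls <- classify_columns(toy_alignment(), "REF", "M1", paste0("M", 1:5))
  expect_equal(cls$column, c(2L, 3L, 5L, 6L))
  expect_equal(cls$group, c("A", "B", "A", "A"))
  expect_true(is.na(cls$query_position[cls$column == 5])) # query gapped
  expect_equal(cls$query_position[cls$column == 2], 2L)
  # ungapped query position accounts for the query gap at column 5
  expect_equal(cls$query_position[cls$column == 6], 5L)
})

test_that("classification errors on missing ids and non-member queries", {
  aln <- toy_alignment()
  expect_error(classify_columns(aln, "NOPE", "M1", paste0("M", 1:5)), "NOPE")
  expect_error(classify_columns(aln, "REF", "REF", paste0("M", 1:5)),
               "member")
})

test_that("group A and B partition the differing columns", {
  for (seed in 1:8) {
    fx <- make_msa_fixture(n_cluster = 5, length = 50,
                           n_groupA = sample(0:8, 1),
                           n_groupB = sample(0:8, 1), seed = seed)
    cls <- classify_columns(fx$alignment, fx$truth$ref_id, fx$truth$query_id,
                            fx$truth$cluster_ids)
    expect_setequal(cls$column[cls$group == "A"],
                    which(fx$truth$groups == "A"))
    expect_setequal(cls$column[cls$group == "B"],
                    which(fx$truth$groups == "B"))
    expect_length(intersect(cls$column[cls$group == "A"],
                            cls$column[cls$group == "B"]), 0)
  }
})

test_that("mutant design writes reference residues at selected positions", {
  fx <- make_msa_fixture(n_cluster = 5, length = 40, n_groupA = 4,
                         n_groupB = 3, seed = 13)
  aln <- fx$alignment
  cls <- classify_columns(aln, "REF", "M1", fx$truth$cluster_ids)
  query <- gsub("-", "", aln[["M1"]])
  ref <- gsub("-", "", aln[["REF"]])

  all_set <- substitution_set("all", positions_by_group(cls, "all"))
  m <- design_mutants(query, cls, list(all_set))
  # all differing positions replaced: mutant equals the reference sequence
  # at every classified column and the query elsewhere (no gaps here)
  expect_identical(unname(m), ref)

  # empty selection is the identity
  m0 <- design_mutants(query, cls, list(substitution_set("id", integer())))
  expect_identical(unname(m0), query)

  # groupA-only: exactly the A positions change
  a_pos <- positions_by_group(cls, "A")
  b_pos <- positions_by_group(cls, "B")
  mA <- design_mutants(query, cls, list(substitution_set("A", a_pos)))[[1]]
  ch <- which(strsplit(mA, "")[[1]] != strsplit(query, "")[[1]])
  expect_setequal(ch, a_pos)

  # idempotence and composition: A then B equals all
  mA_then_B <- design_mutants(mA, cls, list(substitution_set("B", b_pos)))[[1]]
  expect_identical(mA_then_B, unname(m))
  mAA <- design_mutants(mA, cls, list(substitution_set("A", a_pos)))[[1]]
  expect_identical(mAA, mA)

  # unknown position errors with the offending position
  expect_error(design_mutants(query, cls,
                              list(substitution_set("bad", c(a_pos[1], 9999)))),
               "9999")
})

test_that("terminus splitting follows the ceil and midpoint policies", {
  sp <- split_termini(c(3, 10, 40, 200))
  expect_equal(sp$N, c(3L, 10L))
  expect_equal(sp$C, c(40L, 200L))

  sp_odd <- split_termini(c(5, 6, 7))
  expect_equal(sp_odd$N, c(5L, 6L))
  expect_equal(sp_odd$C, 7L)

  sp_mid <- split_termini(c(10, 290), boundary_policy = "midpoint",
                          seq_length = 300)
  expect_equal(sp_mid$N, 10L)
  expect_equal(sp_mid$C, 290L)

  expect_error(split_termini(integer()), "non-empty")
})

test_that("spatial regions are single-linkage components at the cutoff", {
  # two planted clusters of 4 residues, intra < 8 A, inter > 25 A
  mk <- function(resno, p) res_atoms("ALA", resno, CB = p,
                                     CA = p + c(1.5, 0, 0))
  st <- make_structure(
    mk(1, c(0, 0, 0)), mk(3, c(5, 0, 0)), mk(5, c(0, 5, 0)),
    mk(7, c(5, 5, 0)),
    mk(20, c(100, 0, 0)), mk(22, c(105, 0, 0)), mk(24, c(100, 5, 0)),
    mk(26, c(105, 5, 0))
  )
  regions <- find_enriched_regions(st, 1:8, linkage_cutoff = 10, min_size = 3)
  expect_length(regions, 2L)
  expect_equal(vapply(regions, function(r) nrow(r$members), integer(1)),
               c(4L, 4L))
  expect_equal(regions[[1]]$region_id, 1L)

  # all far apart: no regions even at min_size 2
  st2 <- make_structure(mk(1, c(0, 0, 0)), mk(3, c(20, 0, 0)),
                        mk(5, c(40, 0, 0)))
  expect_length(find_enriched_regions(st2, 1:3, linkage_cutoff = 10,
                                      min_size = 2), 0L)

  # glycine uses CA
  gly <- res_atoms("GLY", 9, CA = c(2.5, 2.5, 0))
  st3 <- make_structure(mk(1, c(0, 0, 0)), mk(3, c(5, 0, 0)), gly)
  r3 <- find_enriched_regions(st3, 1:3, linkage_cutoff = 10, min_size = 3)
  expect_length(r3, 1L)
  expect_equal(nrow(r3[[1]]$members), 3L)

  expect_error(find_enriched_regions(st2, c(1, 99)), "99")
})

test_that("region detection matches the adjacency-components oracle and is invariant", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 12
    coords <- matrix(runif(3 * n, 0, 30), ncol = 3)
    rows <- lapply(seq_len(n), function(i) {
      res_atoms("ALA", 2 * i, CB = coords[i, ])
    })
    st <- make_structure(do.call(rbind, rows))
    regions <- find_enriched_regions(st, seq_len(n), linkage_cutoff = 9,
                                     min_size = 1)
    comp <- oracle_components(coords, 9)
    got_sizes <- sort(vapply(regions, function(r) nrow(r$members),
                             integer(1)))
    expect_equal(got_sizes, sort(as.integer(table(comp))))
    # member sets agree
    got_sets <- lapply(regions, function(r) sort(r$members$position))
    want_sets <- lapply(split(seq_len(n), comp), sort)
    expect_setequal(lapply(got_sets, paste, collapse = ","),
                    lapply(want_sets, paste, collapse = ","))

    # rigid motion and permutation invariance
    tf <- random_rigid_transform()
    moved <- apply_rigid(st, tf)
    r2 <- find_enriched_regions(moved, sample(seq_len(n)),
                                linkage_cutoff = 9, min_size = 1)
    got2 <- lapply(r2, function(r) sort(r$members$position))
    expect_setequal(lapply(got2, paste, collapse = ","),
                    lapply(got_sets, paste, collapse = ","))
  }
})
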