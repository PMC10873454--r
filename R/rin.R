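# Residue interaction network: six geometric contact detectors and the
# per-protein network census.

#' Interaction detection configuration
#'
#' Distance cutoffs and options for the six contact detectors. Defaults are
#' the conventional per-type cutoffs: hydrogen bonds 3.5 A (donor to acceptor
#' heavy atom), Van der Waals slack 0.5 A over the atomic radius sum,
#' disulfide 2.5 A (SG-SG), ionic 4.0 A (charged-group atoms), pi-pi 6.5 A
#' (ring centroids), pi-cation 5.0 A (cation point to ring centroid).
#'
#' @param hbond_cutoff,disulfide_cutoff,ionic_cutoff,pipi_cutoff,pication_cutoff
#'   distance cutoffs in Angstrom.
#' @param vdw_slack slack added to the sum of Van der Waals radii (A).
#' @param sequence_separation_min minimum |resno| separation within a chain
#'   (default 2 excludes covalent neighbours i, i+1).
#' @param include_his_aromatic treat the histidine imidazole as an aromatic
#'   ring for pi-pi and pi-cation detection.
#' @param his_as_cation treat histidine ring nitrogens as a cation point for
#'   pi-cation detection (off by default: protonation is ambiguous).
#' @param vdw_radii named numeric vector, element -> radius (A).
#' @return An `interaction_config` list.
#' @export
interaction_config <- function(hbond_cutoff = 3.5,
                               vdw_slack = 0.5,
                               disulfide_cutoff = 2.5,
                               ionic_cutoff = 4.0,
                               pipi_cutoff = 6.5,
                               pication_cutoff = 5.0,
                               sequence_separation_min = 2L,
                               include_his_aromatic = TRUE,
                               his_as_cation = FALSE,
                               vdw_radii = .default_vdw_radii) {
  cfg <- list(hbond_cutoff = hbond_cutoff, vdw_slack = vdw_slack,
              disulfide_cutoff = disulfide_cutoff, ionic_cutoff = ionic_cutoff,
              pipi_cutoff = pipi_cutoff, pication_cutoff = pication_cutoff,
              sequence_separation_min = as.integer(sequence_separation_min),
              include_his_aromatic = include_his_aromatic,
              his_as_cation = his_as_cation,
              vdw_radii = vdw_radii)
  cuts <- unlist(cfg[c("hbond_cutoff", "vdw_slack", "disulfide_cutoff",
                       "ionic_cutoff", "pipi_cutoff", "pication_cutoff")])
  if (any(cuts <= 0)) stop("all cutoffs must be > 0")
  if (cfg$sequence_separation_min < 0L) {
    stop("sequence_separation_min must be >= 0")
  }
  structure(cfg, class = "interaction_config")
}

.itypes <- c("HBOND", "VDW", "SSBOND", "IONIC", "PIPI", "PICATION")

.empty_edges <- function() {
  data.frame(resi_a = integer(), chain_a = character(), resno_a = integer(),
             insert_a = character(), resname_a = character(),
             atom_a = character(),
             resi_b = integer(), chain_b = character(), resno_b = integer(),
             insert_b = character(), resname_b = character(),
             atom_b = character(),
             itype = character(), distance = numeric(),
             pair_label = character(), stringsAsFactors = FALSE)
}

# candidate atom pairs (rows of `at`) within `cutoff`; A_idx/B_idx are row
# indices into `at`
.cross_pairs <- function(at, A_idx, B_idx, cutoff) {
  if (!length(A_idx) || !length(B_idx)) {
    return(data.frame(i = integer(), j = integer(), d = numeric()))
  }
  A <- as.matrix(at[A_idx, c("x", "y", "z")])
  B <- as.matrix(at[B_idx, c("x", "y", "z")])
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  data.frame(i = A_idx[hit[, 1]], j = B_idx[hit[, 2]],
             d = sqrt(d2[hit]))
}

# turn qualifying atom pairs into one edge per unordered residue pair,
# keeping the pair realizing the smallest `rank_by` (default: distance)
.reduce_edges <- function(at, pairs, itype, config, rank_by = NULL) {
  if (!nrow(pairs)) return(.empty_edges())
  ra <- at$resi[pairs$i]
  rb <- at$resi[pairs$j]
  keep <- ra != rb
  same_chain <- at$chain[pairs$i] == at$chain[pairs$j]
  sep_ok <- !same_chain |
    abs(at$resno[pairs$i] - at$resno[pairs$j]) >= config$sequence_separation_min
  keep <- keep & sep_ok
  pairs <- pairs[keep, , drop = FALSE]
  if (!nrow(pairs)) return(.empty_edges())
  ra <- at$resi[pairs$i]; rb <- at$resi[pairs$j]
  # canonical orientation: residue with the smaller file index first
  swap <- ra > rb
  tmp <- pairs$i[swap]; pairs$i[swap] <- pairs$j[swap]; pairs$j[swap] <- tmp
  ra <- at$resi[pairs$i]; rb <- at$resi[pairs$j]
  key <- paste(ra, rb)
  rank <- if (is.null(rank_by)) pairs$d else rank_by[keep]
  ord <- order(key, rank)
  pairs <- pairs[ord, , drop = FALSE]
  first <- !duplicated(key[ord])
  pairs <- pairs[first, , drop = FALSE]
  i <- pairs$i; j <- pairs$j
  data.frame(
    resi_a = at$resi[i], chain_a = at$chain[i], resno_a = at$resno[i],
    insert_a = at$insert[i], resname_a = at$resid[i], atom_a = at$elety[i],
    resi_b = at$resi[j], chain_b = at$chain[j], resno_b = at$resno[j],
    insert_b = at$insert[j], resname_b = at$resid[j], atom_b = at$elety[j],
    itype = itype, distance = pairs$d, pair_label = NA_character_,
    stringsAsFactors = FALSE
  )
}

.sort_edges <- function(edges) {
  if (!nrow(edges)) return(edges)
  edges <- edges[order(edges$resi_a, edges$resi_b,
                       match(edges$itype, .itypes)), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Detect hydrogen bonds
#'
#' An edge is recorded between two residues when a donor-capable N/O heavy
#' atom of one lies within the cutoff of an acceptor-capable N/O heavy atom
#' of the other. Capabilities come from a fixed per-residue table (backbone N
#' donor except proline, backbone O/OXT acceptor, side-chain N/O per standard
#' chemistry); geometry is heavy-atom, distance-only.
#'
#' @param structure a `protein_structure`.
#' @param config an [interaction_config()].
#' @return Edge data frame (one row per residue pair, minimal distance kept).
#' @export
detect_hbonds <- function(structure, config = interaction_config()) {
  at <- structure$atoms
  don <- which((at$elety == "N" & at$resid != "PRO") |
                 .atom_in_table(at, .hbond_donors))
  acc <- which(at$elety %in% .hbond_acceptors$backbone |
                 .atom_in_table(at, .hbond_acceptors))
  pairs <- .cross_pairs(at, don, acc, config$hbond_cutoff)
  .sort_edges(.reduce_edges(at, pairs, "HBOND", config))
}

.atom_in_table <- function(at, table) {
  hit <- rep(FALSE, nrow(at))
  for (res in setdiff(names(table), "backbone")) {
    hit <- hit | (at$resid == res & at$elety %in% table[[res]])
  }
  hit
}

#' Detect Van der Waals contacts
#'
#' An edge is recorded when two side-chain heavy atoms (side chain plus
#' C-beta; backbone excluded so the detector does not mirror the covalent
#' backbone) from distinct residues satisfy d <= r_i + r_j + slack. Atom
#' pairs covalently connected through a disulfide bridge (SG-SG and CB-SG
#' across an SG-SG pair within the disulfide cutoff) are excluded, mirroring
#' force-field nonbonded exclusions.
#'
#' @inheritParams detect_hbonds
#' @return Edge data frame (minimal surface-gap pair kept per residue pair).
#' @export
detect_vdw <- function(structure, config = interaction_config()) {
  at <- structure$atoms
  sel <- which(at$element != "H" & !(at$elety %in% .backbone_atoms))
  if (!length(sel)) return(.empty_edges())
  rad <- config$vdw_radii[at$element[sel]]
  if (anyNA(rad)) {
    k <- sel[which(is.na(rad))[1]]
    stop("no Van der Waals radius for element '", at$element[k],
         "' (atom ", at$elety[k], " of ", at$resid[k], " ",
         at$chain[k], at$resno[k], ")")
  }
  max_cut <- 2 * max(config$vdw_radii) + config$vdw_slack
  pairs <- .cross_pairs(at, sel, sel, max_cut)
  if (!nrow(pairs)) return(.empty_edges())
  ri <- config$vdw_radii[at$element[pairs$i]]
  rj <- config$vdw_radii[at$element[pairs$j]]
  gap <- pairs$d - ri - rj
  ok <- gap <= config$vdw_slack
  pairs <- pairs[ok, , drop = FALSE]
  gap <- gap[ok]
  if (!nrow(pairs)) return(.empty_edges())
  # exclude covalent pairs across detected disulfide bridges
  ss <- detect_ssbonds(structure, config)
  if (nrow(ss)) {
    excl <- rep(FALSE, nrow(pairs))
    for (k in seq_len(nrow(ss))) {
      a <- ss$resi_a[k]; b <- ss$resi_b[k]
      cross <- (at$resi[pairs$i] == a & at$resi[pairs$j] == b) |
               (at$resi[pairs$i] == b & at$resi[pairs$j] == a)
      bonded <- (at$elety[pairs$i] == "SG" & at$elety[pairs$j] == "SG") |
                (at$elety[pairs$i] == "SG" & at$elety[pairs$j] == "CB") |
                (at$elety[pairs$i] == "CB" & at$elety[pairs$j] == "SG")
      excl <- excl | (cross & bonded)
    }
    pairs <- pairs[!excl, , drop = FALSE]
    gap <- gap[!excl]
  }
  .sort_edges(.reduce_edges(at, pairs, "VDW", config, rank_by = gap))
}

#' Detect disulfide bonds
#'
#' Edge when the SG atoms of two cysteines lie within the disulfide cutoff.
#'
#' @inheritParams detect_hbonds
#' @return Edge data frame.
#' @export
detect_ssbonds <- function(structure, config = interaction_config()) {
  at <- structure$atoms
  sg <- which(at$resid == "CYS" & at$elety == "SG")
  pairs <- .cross_pairs(at, sg, sg, config$disulfide_cutoff)
  .sort_edges(.reduce_edges(at, pairs, "SSBOND", config))
}

#' Detect ionic bonds (salt bridges)
#'
#' Edge when a negative-group atom (ASP OD1/OD2, GLU OE1/OE2, C-terminal OXT)
#' and a positive-group atom (LYS NZ; ARG NE/NH1/NH2; HIS ND1/NE2; the
#' N-terminal backbone N of each chain) of distinct residues lie within the
#' ionic cutoff. Opposite charges only.
#'
#' @inheritParams detect_hbonds
#' @return Edge data frame.
#' @export
detect_ionic <- function(structure, config = interaction_config()) {
  at <- structure$atoms
  neg <- which(.atom_in_table(at, .ionic_negative) | at$elety == "OXT")
  pos <- which(.atom_in_table(at, .ionic_positive))
  # N-terminal backbone N per chain (first residue in file order)
  for (ch in unique(at$chain)) {
    rows <- which(at$chain == ch)
    first_resi <- min(at$resi[rows])
    nt <- rows[at$resi[rows] == first_resi & at$elety[rows] == "N"]
    pos <- c(pos, nt)
  }
  pairs <- .cross_pairs(at, neg, unique(pos), config$ionic_cutoff)
  .sort_edges(.reduce_edges(at, pairs, "IONIC", config))
}

#' Aromatic ring centroids of a residue
#'
#' PHE/TYR yield the six-membered ring centroid, HIS the imidazole centroid
#' (when histidine counts as aromatic), TRP both its five- and six-membered
#' ring centroids. A residue with missing ring atoms is skipped with a
#' warning.
#'
#' @param residue_atoms atom table rows of a single residue (as in
#'   `protein_structure$atoms`).
#' @param include_his treat HIS as aromatic.
#' @return List of `list(label, centroid)`; empty if not aromatic or rings
#'   incomplete.
#' @export
aromatic_centroids <- function(residue_atoms, include_his = TRUE) {
  res <- residue_atoms$resid[1]
  if (!(res %in% names(.aromatic_rings))) return(list())
  if (res == "HIS" && !include_his) return(list())
  out <- list()
  for (label in names(.aromatic_rings[[res]])) {
    ring_atoms <- .aromatic_rings[[res]][[label]]
    rows <- match(ring_atoms, residue_atoms$elety)
    if (anyNA(rows)) {
      warning("incomplete aromatic ring (", res, " ",
              residue_atoms$chain[1], residue_atoms$resno[1],
              "): missing ", paste(ring_atoms[is.na(rows)], collapse = ","),
              "; residue skipped")
      next
    }
    out[[length(out) + 1L]] <- list(
      label = label,
      centroid = colMeans(as.matrix(
        residue_atoms[rows, c("x", "y", "z")]))
    )
  }
  out
}

# all ring centroids of a structure: data frame resi, letter, label, x, y, z
.all_centroids <- function(structure, config) {
  at <- structure$atoms
  arom <- unique(at$resi[at$resid %in% names(.aromatic_rings)])
  rows <- lapply(arom, function(ri) {
    sub <- at[at$resi == ri, , drop = FALSE]
    cents <- aromatic_centroids(sub, include_his = config$include_his_aromatic)
    if (!length(cents)) return(NULL)
    do.call(rbind, lapply(cents, function(cc) {
      data.frame(resi = ri, letter = aa321(sub$resid[1], TRUE),
                 label = cc$label,
                 x = cc$centroid[1], y = cc$centroid[2], z = cc$centroid[3],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(resi = integer(), letter = character(),
                      label = character(), x = numeric(), y = numeric(),
                      z = numeric(), stringsAsFactors = FALSE)
  }
  out
}

# pseudo-atom table for centroid/cation points so .reduce_edges can be reused
.pseudo_atoms <- function(structure, points, elety_label) {
  at <- structure$atoms
  first <- at[!duplicated(at$resi), , drop = FALSE]
  m <- match(points$resi, first$resi)
  data.frame(chain = first$chain[m], resno = first$resno[m],
             insert = first$insert[m], resid = first$resid[m],
             elety = elety_label, element = "X",
             x = points$x, y = points$y, z = points$z,
             o = 1, alt = "", resi = points$resi,
             stringsAsFactors = FALSE)
}

#' Detect pi-pi stacking interactions
#'
#' Edge when any ring-centroid pair from two distinct aromatic residues lies
#' within the cutoff; distance-only criterion (no ring-angle term). The
#' `pair_label` tags the unordered 1-letter pair (e.g. `"F-F"`, `"F-Y"`).
#'
#' @inheritParams detect_hbonds
#' @return Edge data frame with `pair_label` filled in.
#' @export
detect_pipi <- function(structure, config = interaction_config()) {
  cents <- .all_centroids(structure, config)
  if (nrow(cents) < 2) return(.empty_edges())
  pat <- .pseudo_atoms(structure, cents, paste0("ring:", cents$label))
  pairs <- .cross_pairs(pat, seq_len(nrow(pat)), seq_len(nrow(pat)),
                        config$pipi_cutoff)
  edges <- .reduce_edges(pat, pairs, "PIPI", config)
  if (nrow(edges)) {
    la <- aa321(edges$resname_a, TRUE)
    lb <- aa321(edges$resname_b, TRUE)
    edges$pair_label <- ifelse(la <= lb, paste(la, lb, sep = "-"),
                               paste(lb, la, sep = "-"))
  }
  .sort_edges(edges)
}

#' Detect pi-cation interactions
#'
#' Edge when an aromatic ring centroid and a cation reference point (LYS NZ;
#' ARG guanidinium centroid of CZ, NE, NH1, NH2; optionally the HIS ring) of
#' distinct residues lie within the cutoff.
#'
#' @inheritParams detect_hbonds
#' @return Edge data frame.
#' @export
detect_pication <- function(structure, config = interaction_config()) {
  cents <- .all_centroids(structure, config)
  at <- structure$atoms
  cat_pts <- list()
  nz <- which(at$resid == "LYS" & at$elety == "NZ")
  if (length(nz)) {
    cat_pts$lys <- data.frame(resi = at$resi[nz], x = at$x[nz],
                              y = at$y[nz], z = at$z[nz], elety = "NZ")
  }
  for (ri in unique(at$resi[at$resid == "ARG"])) {
    sub <- at[at$resi == ri & at$elety %in% c("CZ", "NE", "NH1", "NH2"), ]
    if (nrow(sub) == 4) {
      cat_pts[[paste0("arg", ri)]] <- data.frame(
        resi = ri, x = mean(sub$x), y = mean(sub$y), z = mean(sub$z),
        elety = "guanidinium")
    }
  }
  if (isTRUE(config$his_as_cation)) {
    his <- cents[cents$letter == "H", , drop = FALSE]
    if (nrow(his)) {
      cat_pts$his <- data.frame(resi = his$resi, x = his$x, y = his$y,
                                z = his$z, elety = "imidazolium")
    }
  }
  cat_df <- do.call(rbind, cat_pts)
  if (is.null(cat_df) || !nrow(cat_df) || !nrow(cents)) {
    return(.empty_edges())
  }
  pat <- rbind(
    .pseudo_atoms(structure, cat_df[, c("resi", "x", "y", "z")],
                  cat_df$elety),
    .pseudo_atoms(structure, cents, paste0("ring:", cents$label))
  )
  n_cat <- nrow(cat_df)
  pairs <- .cross_pairs(pat, seq_len(n_cat), n_cat + seq_len(nrow(cents)),
                        config$pication_cutoff)
  .sort_edges(.reduce_edges(pat, pairs, "PICATION", config))
}

#' Build the full residue interaction network
#'
#' Runs all six detectors and assembles the network census: total edges,
#' participating residues (nodes), edge-to-node ratio, per-type counts, and
#' the pi-pi aromatic pair-type tally. A residue pair may carry several
#' interaction types; within a type it is counted once at the minimal
#' qualifying distance.
#'
#' @inheritParams detect_hbonds
#' @return A `rin` object: list with `edges` (data frame), `summary`
#'   (a `rin_summary`), and `config`.
#' @export
build_rin <- function(structure, config = interaction_config()) {
  edges <- rbind(
    detect_hbonds(structure, config),
    detect_vdw(structure, config),
    detect_ssbonds(structure, config),
    detect_ionic(structure, config),
    detect_pipi(structure, config),
    detect_pication(structure, config)
  )
  edges <- .sort_edges(edges)
  structure(list(edges = edges, summary = rin_summary(edges),
                 config = config, id = structure$id),
            class = "rin")
}

#' Network census of an edge list
#'
#' @param edges an edge data frame as returned by the detectors.
#' @return A `rin_summary`: n_edges, n_nodes, edge_node_ratio (NA when no
#'   nodes), per_type counts, pipi_pairs tally.
#' @export
rin_summary <- function(edges) {
  per_type <- stats::setNames(integer(length(.itypes)), .itypes)
  tab <- table(edges$itype)
  per_type[names(tab)] <- as.integer(tab)
  nodes <- unique(c(edges$resi_a, edges$resi_b))
  n_edges <- nrow(edges)
  pipi <- edges$pair_label[edges$itype == "PIPI"]
  pipi_pairs <- if (length(pipi)) {
    tt <- table(pipi)
    stats::setNames(as.integer(tt), names(tt))
  } else integer()
  structure(list(
    n_edges = n_edges,
    n_nodes = length(nodes),
    edge_node_ratio = if (length(nodes)) n_edges / length(nodes) else NA_real_,
    per_type = per_type,
    pipi_pairs = pipi_pairs
  ), class = "rin_summary")
}

#' @export
print.rin_summary <- function(x, ...) {
  cat("Residue interaction network census\n")
  cat("  edges:", x$n_edges, " nodes:", x$n_nodes,
      " edge/node ratio:",
      if (is.na(x$edge_node_ratio)) "NA" else
        formatC(x$edge_node_ratio, digits = 3, format = "f"), "\n")
  cat("  per type:",
      paste(names(x$per_type), x$per_type, sep = "=", collapse = " "), "\n")
  if (length(x$pipi_pairs)) {
    cat("  pi-pi pairs:",
        paste(names(x$pipi_pairs), x$pipi_pairs, sep = "=", collapse = " "),
        "\n")
  }
  invisible(x)
}

#' @export
print.rin <- function(x, ...) {
  cat("RIN for '", x$id, "'\n", sep = "")
  print(x$summary)
  invisible(x)
}
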