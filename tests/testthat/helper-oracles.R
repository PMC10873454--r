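# Independent brute-force oracles: naive all-pairs double loops with their
# own chemistry tables, kept deliberately separate from the package
# implementation.

.o_dist <- function(a, b) sqrt(sum((a - b)^2))

.o_atom_xyz <- function(at, i) c(at$x[i], at$y[i], at$z[i])

# residue list: split atom table by residue index
.o_residues <- function(structure) {
  split(structure$atoms, structure$atoms$resi)
}

.o_pair_allowed <- function(ra, rb, sep_min) {
  if (ra$resi[1] == rb$resi[1]) return(FALSE)
  if (ra$chain[1] == rb$chain[1] &&
      abs(ra$resno[1] - rb$resno[1]) < sep_min) return(FALSE)
  TRUE
}

.o_donors <- function(r) {
  res <- r$resid[1]
  sc <- switch(res,
    ARG = c("NE", "NH1", "NH2"), ASN = "ND2", GLN = "NE2",
    HIS = c("ND1", "NE2"), LYS = "NZ", SER = "OG", THR = "OG1",
    TRP = "NE1", TYR = "OH", character())
  bb <- if (res == "PRO") character() else "N"
  which(r$elety %in% c(bb, sc))
}

.o_acceptors <- function(r) {
  res <- r$resid[1]
  sc <- switch(res,
    ASN = "OD1", ASP = c("OD1", "OD2"), GLN = "OE1",
    GLU = c("OE1", "OE2"), HIS = c("ND1", "NE2"), SER = "OG",
    THR = "OG1", TYR = "OH", character())
  which(r$elety %in% c("O", "OXT", sc))
}

.o_min_cross <- function(ra, rb, ia, ib) {
  best <- Inf
  for (i in ia) for (j in ib) {
    d <- .o_dist(.o_atom_xyz(ra, i), .o_atom_xyz(rb, j))
    if (d < best) best <- d
  }
  best
}

# returns data.frame(resi_a, resi_b, itype) with resi_a < resi_b
oracle_rin <- function(structure, config = interaction_config()) {
  rs <- .o_residues(structure)
  sep <- config$sequence_separation_min
  out <- list()
  add <- function(ra, rb, itype) {
    a <- ra$resi[1]; b <- rb$resi[1]
    out[[length(out) + 1L]] <<- data.frame(
      resi_a = min(a, b), resi_b = max(a, b), itype = itype,
      stringsAsFactors = FALSE)
  }
  # N-terminal residues per chain, C-terminal OXT handled inline
  first_resi <- tapply(structure$atoms$resi, structure$atoms$chain, min)

  n <- length(rs)
  for (p in seq_len(n - 1)) for (q in (p + 1):n) {
    ra <- rs[[p]]; rb <- rs[[q]]
    if (!.o_pair_allowed(ra, rb, sep)) next

    # hydrogen bond: donor N/O of one vs acceptor N/O of the other
    d1 <- .o_min_cross(ra, rb, .o_donors(ra), .o_acceptors(rb))
    d2 <- .o_min_cross(ra, rb, .o_acceptors(ra), .o_donors(rb))
    if (min(d1, d2) <= config$hbond_cutoff) add(ra, rb, "HBOND")

    # disulfide
    if (ra$resid[1] == "CYS" && rb$resid[1] == "CYS") {
      dss <- .o_min_cross(ra, rb, which(ra$elety == "SG"),
                          which(rb$elety == "SG"))
      if (dss <= config$disulfide_cutoff) add(ra, rb, "SSBOND")
    } else dss <- Inf

    # Van der Waals over side-chain heavy atoms (+CB), excluding atom pairs
    # covalently joined through a disulfide bridge
    bb <- c("N", "CA", "C", "O", "OXT")
    sa <- which(!(ra$elety %in% bb) & ra$element != "H")
    sb <- which(!(rb$elety %in% bb) & rb$element != "H")
    ss_bonded <- (ra$resid[1] == "CYS" && rb$resid[1] == "CYS" &&
                    is.finite(dss) && dss <= config$disulfide_cutoff)
    hit <- FALSE
    for (i in sa) for (j in sb) {
      if (ss_bonded &&
          ((ra$elety[i] == "SG" && rb$elety[j] %in% c("SG", "CB")) ||
           (ra$elety[i] == "CB" && rb$elety[j] == "SG"))) next
      ri <- config$vdw_radii[[ra$element[i]]]
      rj <- config$vdw_radii[[rb$element[j]]]
      d <- .o_dist(.o_atom_xyz(ra, i), .o_atom_xyz(rb, j))
      if (d <= ri + rj + config$vdw_slack) { hit <- TRUE; break }
    }
    if (hit) add(ra, rb, "VDW")

    # ionic
    neg <- function(r) {
      sc <- switch(r$resid[1], ASP = c("OD1", "OD2"),
                   GLU = c("OE1", "OE2"), character())
      which(r$elety %in% c(sc, "OXT"))
    }
    pos <- function(r) {
      sc <- switch(r$resid[1], LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
                   HIS = c("ND1", "NE2"), character())
      idx <- which(r$elety %in% sc)
      if (r$resi[1] == first_resi[[r$chain[1]]]) {
        idx <- c(idx, which(r$elety == "N"))
      }
      idx
    }
    dion <- min(.o_min_cross(ra, rb, neg(ra), pos(rb)),
                .o_min_cross(ra, rb, pos(ra), neg(rb)))
    if (dion <= config$ionic_cutoff) add(ra, rb, "IONIC")

    # rings and cations
    rings <- function(r) {
      defs <- switch(r$resid[1],
        PHE = , TYR = list(c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
        HIS = if (config$include_his_aromatic)
          list(c("CG", "ND1", "CD2", "CE1", "NE2")) else list(),
        TRP = list(c("CG", "CD1", "CD2", "NE1", "CE2"),
                   c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")),
        list())
      cents <- list()
      for (def in defs) {
        idx <- match(def, r$elety)
        if (anyNA(idx)) next
        cents[[length(cents) + 1L]] <-
          c(mean(r$x[idx]), mean(r$y[idx]), mean(r$z[idx]))
      }
      cents
    }
    cations <- function(r) {
      pts <- list()
      if (r$resid[1] == "LYS") {
        i <- which(r$elety == "NZ")
        if (length(i)) pts[[1]] <- .o_atom_xyz(r, i)
      }
      if (r$resid[1] == "ARG") {
        idx <- match(c("CZ", "NE", "NH1", "NH2"), r$elety)
        if (!anyNA(idx)) {
          pts[[length(pts) + 1L]] <-
            c(mean(r$x[idx]), mean(r$y[idx]), mean(r$z[idx]))
        }
      }
      pts
    }
    ca <- suppressWarnings(rings(ra)); cb <- suppressWarnings(rings(rb))
    if (length(ca) && length(cb)) {
      dpp <- min(vapply(ca, function(u)
        min(vapply(cb, function(v) .o_dist(u, v), numeric(1))), numeric(1)))
      if (dpp <= config$pipi_cutoff) add(ra, rb, "PIPI")
    }
    dcat <- Inf
    for (u in cations(ra)) for (v in cb) {
      dcat <- min(dcat, .o_dist(u, v))
    }
    for (u in cations(rb)) for (v in ca) {
      dcat <- min(dcat, .o_dist(u, v))
    }
    if (dcat <= config$pication_cutoff) add(ra, rb, "PICATION")
  }
  if (!length(out)) {
    return(data.frame(resi_a = integer(), resi_b = integer(),
                      itype = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$resi_a, res$resi_b, res$itype), , drop = FALSE]
}

# closed-form pooled two-sample t statistic and two-sided p
oracle_pooled_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = t, p = 2 * pt(-abs(t), df = na + nb - 2))
}

# connected components of the <=cutoff adjacency graph, brute force
oracle_components <- function(coords, cutoff) {
  n <- nrow(coords)
  adj <- as.matrix(dist(coords)) <= cutoff
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        lab <- min(comp[i], comp[j])
        comp[comp == comp[i] | comp == comp[j]] <- lab
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

# canonical edge-set string for comparing detector output with the oracle
edge_key <- function(edges) {
  if (!nrow(edges)) return(character())
  sort(paste(edges$resi_a, edges$resi_b, edges$itype))
}
oracle_key <- function(or) {
  if (!nrow(or)) return(character())
  sort(paste(or$resi_a, or$resi_b, or$itype))
}
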