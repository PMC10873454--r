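# Differential-residue analysis: group A/B classification of alignment
# columns against a reference, substitution-set mutant design, and spatial
# region enrichment on the structure.

#' Classify alignment columns into differential groups A and B
#'
#' For every alignment column where the query differs from the reference, the
#' column is labelled group A when all members of the homolog cluster
#' (including the query) also differ from the reference at that column, and
#' group B when only a proper subset does. Positions are 1-based; the
#' ungapped query position is reported where the query carries a residue.
#'
#' A gap counts as differing from any residue (and from the reference's gap
#' state); a column gapped in the query yields a record without a mutable
#' query position.
#'
#' @param alignment named character vector of equal-length gapped sequences
#'   (see [read_alignment()]).
#' @param ref_id reference row id.
#' @param query_id query row id; must be one of `cluster_ids`.
#' @param cluster_ids ids of the homolog cluster members (the "(n/n)" rule is
#'   counted over these, query included).
#' @return Data frame with one row per differing column: `column`, `ref`,
#'   `query`, `n_cluster_diff`, `n_cluster`, `group` (`"A"`/`"B"`), and
#'   `query_position` (NA when the query is gapped).
#' @export
classify_columns <- function(alignment, ref_id, query_id, cluster_ids) {
  ids <- names(alignment)
  missing_ids <- setdiff(c(ref_id, query_id, cluster_ids), ids)
  if (length(missing_ids)) {
    stop("ids not found in alignment: ", paste(missing_ids, collapse = ", "))
  }
  if (!(query_id %in% cluster_ids)) {
    stop("query_id must be a member of cluster_ids")
  }
  if (length(unique(nchar(alignment))) != 1L) {
    stop("alignment rows have unequal lengths")
  }
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(mat) <- ids
  ref <- mat[ref_id, ]
  qry <- mat[query_id, ]
  clu <- mat[cluster_ids, , drop = FALSE]

  q_diff <- qry != ref
  n_diff <- colSums(sweep(clu, 2, ref, "!="))
  q_pos <- cumsum(qry != "-")
  cols <- which(q_diff)
  if (!length(cols)) {
    return(data.frame(column = integer(), ref = character(),
                      query = character(), n_cluster_diff = integer(),
                      n_cluster = integer(), group = character(),
                      query_position = integer(), stringsAsFactors = FALSE))
  }
  n_cluster <- length(cluster_ids)
  data.frame(
    column = cols,
    ref = ref[cols],
    query = qry[cols],
    n_cluster_diff = as.integer(n_diff[cols]),
    n_cluster = n_cluster,
    group = ifelse(n_diff[cols] == n_cluster, "A", "B"),
    query_position = ifelse(qry[cols] == "-", NA_integer_,
                            as.integer(q_pos[cols])),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Query positions carrying a given differential group
#'
#' @param classifications data frame from [classify_columns()].
#' @param group `"A"`, `"B"`, or `"all"`.
#' @return Sorted integer vector of mutable (non-gap) query positions.
#' @export
positions_by_group <- function(classifications, group = c("all", "A", "B")) {
  group <- match.arg(group)
  keep <- !is.na(classifications$query_position) &
    classifications$ref != "-"
  if (group != "all") keep <- keep & classifications$group == group
  sort(unique(classifications$query_position[keep]))
}

#' Define a substitution set
#'
#' @param name mutant label (e.g. `"RE_2"`).
#' @param positions query sequence positions (1-based) to replace.
#' @param description free-text selection rule recorded in the FASTA header.
#' @return A `substitution_set` list.
#' @export
substitution_set <- function(name, positions, description = "") {
  structure(list(name = name, positions = sort(unique(as.integer(positions))),
                 description = description),
            class = "substitution_set")
}

#' Generate mutant sequences from substitution sets
#'
#' Each mutant is the query with the reference residue written at every
#' selected position; all other positions are untouched, so the length is
#' preserved and applying a set twice equals applying it once.
#'
#' @param query_sequence ungapped query sequence (character scalar).
#' @param classifications data frame from [classify_columns()].
#' @param substitution_sets list of [substitution_set()] objects.
#' @return Named character vector of mutant sequences, one per set.
#' @export
design_mutants <- function(query_sequence, classifications,
                           substitution_sets) {
  q <- strsplit(toupper(query_sequence), "")[[1]]
  mutable <- classifications[!is.na(classifications$query_position) &
                               classifications$ref != "-", , drop = FALSE]
  repl <- stats::setNames(mutable$ref, mutable$query_position)
  out <- character(0)
  for (set in substitution_sets) {
    pos <- set$positions
    unknown <- pos[!(as.character(pos) %in% names(repl))]
    if (length(unknown)) {
      stop("substitution set '", set$name,
           "': position(s) not among classified differential positions: ",
           paste(unknown, collapse = ", "))
    }
    m <- q
    m[pos] <- repl[as.character(pos)]
    out[set$name] <- paste(m, collapse = "")
  }
  out
}

#' Split positions into N-terminal and C-terminal halves
#'
#' With `boundary_policy = "count"` the sorted positions are split so the
#' first ceiling(k/2) go to the N half; with `"midpoint"` the split is at
#' `seq_length / 2` in sequence coordinates.
#'
#' @param positions integer positions.
#' @param boundary_policy `"count"` or `"midpoint"`.
#' @param seq_length sequence length, required for the midpoint policy.
#' @return List with sorted integer vectors `N` and `C`.
#' @export
split_termini <- function(positions, boundary_policy = c("count", "midpoint"),
                          seq_length = NULL) {
  boundary_policy <- match.arg(boundary_policy)
  if (!length(positions)) stop("positions must be non-empty")
  pos <- sort(unique(as.integer(positions)))
  if (boundary_policy == "count") {
    k <- ceiling(length(pos) / 2)
    list(N = pos[seq_len(k)], C = pos[setdiff(seq_along(pos), seq_len(k))])
  } else {
    if (is.null(seq_length)) stop("midpoint policy requires seq_length")
    list(N = pos[pos <= seq_length / 2], C = pos[pos > seq_length / 2])
  }
}

#' Find spatially enriched regions of a residue set
#'
#' Single-linkage connected components of the selected residues under
#' pairwise C-beta distance (C-alpha for glycine) at the linkage cutoff;
#' components below the minimum size are discarded. Regions are ordered by
#' decreasing size, ties broken by first residue number.
#'
#' @param structure a `protein_structure`.
#' @param residue_positions 1-based positions into the structure's residue
#'   sequence.
#' @param linkage_cutoff single-linkage distance cutoff (A).
#' @param min_size minimum component size retained.
#' @return List of regions: each a list with `region_id`, `members` (data
#'   frame chain, resno, resid, position), `centroid`, `diameter`.
#' @export
find_enriched_regions <- function(structure, residue_positions,
                                  linkage_cutoff = 10.0, min_size = 3L) {
  rt <- residue_table(structure)
  pos <- sort(unique(as.integer(residue_positions)))
  if (any(pos < 1L | pos > nrow(rt))) {
    stop("position(s) outside structure: ",
         paste(pos[pos < 1L | pos > nrow(rt)], collapse = ", "))
  }
  at <- structure$atoms
  coords <- t(vapply(pos, function(p) {
    ri <- rt$resi[p]
    sub <- at[at$resi == ri, , drop = FALSE]
    want <- if (sub$resid[1] == "GLY") "CA" else "CB"
    row <- which(sub$elety == want)
    if (!length(row)) row <- which(sub$elety == "CA")
    if (!length(row)) {
      stop("residue at position ", p, " (", sub$resid[1], " ",
           sub$chain[1], sub$resno[1], ") has no CB or CA atom")
    }
    as.numeric(sub[row[1], c("x", "y", "z")])
  }, numeric(3)))

  n <- length(pos)
  comp <- if (n == 1L) {
    1L
  } else {
    hc <- stats::hclust(stats::dist(coords), method = "single")
    stats::cutree(hc, h = linkage_cutoff)
  }
  regions <- list()
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    if (length(idx) < min_size) next
    p <- pos[idx]
    xyz <- coords[idx, , drop = FALSE]
    d <- as.matrix(stats::dist(xyz))
    regions[[length(regions) + 1L]] <- list(
      members = data.frame(chain = rt$chain[p], resno = rt$resno[p],
                           resid = rt$resid[p], position = p,
                           stringsAsFactors = FALSE),
      centroid = colMeans(xyz),
      diameter = if (length(idx) > 1) max(d) else 0,
      first_resno = min(rt$resno[p])
    )
  }
  if (!length(regions)) return(list())
  sizes <- vapply(regions, function(r) nrow(r$members), integer(1))
  firsts <- vapply(regions, function(r) r$first_resno, numeric(1))
  ord <- order(-sizes, firsts)
  regions <- regions[ord]
  for (k in seq_along(regions)) {
    regions[[k]]$region_id <- k
    regions[[k]]$first_resno <- NULL
  }
  regions
}
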