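# Readers/writers for the standard formats the pipeline touches (PDB, FASTA,
# Newick) into the package's domain model.

#' Read a protein structure from a PDB file
#'
#' Parses ATOM/HETATM records into a `protein_structure`: a flat atom table
#' grouped by author residue numbering. One residue per (chain, resno,
#' insertion code); HETATM records and waters are excluded by default;
#' hydrogens are retained if present (no downstream detector requires them).
#'
#' @param path PDB file, plain or gzipped.
#' @param model_policy for multi-MODEL files, `"first"` keeps the first model,
#'   `"index"` keeps the model selected by `model_index`.
#' @param model_index 1-based model index used when `model_policy = "index"`.
#' @param altloc_policy `"highest-occupancy"` keeps, per atom name within a
#'   residue, the alternate location with the largest occupancy;
#'   `"blank-only"` keeps only records with a blank altloc.
#' @param keep_hetatm retain non-water HETATM records.
#' @param mse_as_met treat selenomethionine (MSE) as methionine.
#' @param id optional structure label; defaults to the file base name.
#' @return A `protein_structure`: list with `id`, `atoms` (data frame with
#'   columns chain, resno, insert, resid, elety, element, x, y, z, o, alt),
#'   and `source_path`. Residue order follows the file.
#' @export
read_pdb <- function(path,
                     model_policy = c("first", "index"),
                     model_index = 1L,
                     altloc_policy = c("highest-occupancy", "blank-only"),
                     keep_hetatm = FALSE,
                     mse_as_met = FALSE,
                     id = NULL) {
  model_policy <- match.arg(model_policy)
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) stop("PDB file not found: ", path)

  con <- gzfile(path, open = "rt")
  on.exit(close(con), add = TRUE)
  lines <- readLines(con, warn = FALSE)

  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  # validate coordinate fields before handing off to the parser
  bad <- which(is_atom & (nchar(lines) < 54 |
    is.na(suppressWarnings(as.numeric(substr(lines, 31, 38)))) |
    is.na(suppressWarnings(as.numeric(substr(lines, 39, 46)))) |
    is.na(suppressWarnings(as.numeric(substr(lines, 47, 54))))))
  if (length(bad)) {
    stop("unparseable ATOM/HETATM record at line ", bad[1], " of ", path)
  }

  # model selection on raw lines: keep the ATOM/HETATM records of one block
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts)) {
    k <- if (model_policy == "first") 1L else as.integer(model_index)
    if (k < 1L || k > length(model_starts)) {
      stop("model_index ", k, " out of range: file has ",
           length(model_starts), " MODEL blocks")
    }
    ends <- which(rec == "ENDMDL")
    end_k <- ends[ends > model_starts[k]][1]
    if (is.na(end_k)) end_k <- length(lines) + 1L
    keep <- seq_along(lines) > model_starts[k] & seq_along(lines) < end_k
    lines <- lines[keep]
    rec <- rec[keep]
    is_atom <- rec %in% c("ATOM  ", "HETATM")
  }
  if (!any(rec == "ATOM  ")) {
    stop("no ATOM records in ", path)
  }

  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(c(lines[is_atom], "END"), tmp)
  pdb <- suppressWarnings(suppressMessages(
    bio3d::read.pdb(tmp, rm.alt = FALSE, verbose = FALSE)
  ))
  at <- pdb$atom

  atoms <- data.frame(
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", at$insert),
    resid = at$resid,
    elety = at$elety,
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     .element_from_name(at$elety), toupper(at$elesy)),
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1.0, at$o),
    alt = ifelse(is.na(at$alt), "", at$alt),
    het = at$type == "HETATM",
    stringsAsFactors = FALSE
  )

  if (mse_as_met) {
    is_mse <- atoms$resid == "MSE"
    atoms$resid[is_mse] <- "MET"
    atoms$elety[is_mse & atoms$elety == "SE"] <- "SD"
    atoms$element[is_mse & atoms$element == "SE"] <- "S"
    atoms$het[is_mse] <- FALSE
  }

  atoms <- atoms[!(atoms$resid %in% .water_resnames), , drop = FALSE]
  if (!keep_hetatm) atoms <- atoms[!atoms$het, , drop = FALSE]

  nonstd <- !(atoms$resid %in% .standard_aa3)
  if (any(nonstd)) {
    n_res <- length(unique(paste(atoms$chain, atoms$resno, atoms$insert,
                                 atoms$resid)[nonstd]))
    message("read_pdb: excluded ", n_res,
            " non-standard residue(s) from ", basename(path))
    atoms <- atoms[!nonstd, , drop = FALSE]
  }
  if (!nrow(atoms)) stop("no standard-residue ATOM records in ", path)

  if (altloc_policy == "blank-only") {
    atoms <- atoms[atoms$alt == "", , drop = FALSE]
  } else {
    key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety,
                 sep = "\r")
    ord <- order(key, -atoms$o, atoms$alt)
    atoms <- atoms[ord, , drop = FALSE]
    atoms <- atoms[!duplicated(key[ord]), , drop = FALSE]
    # restore file order
    atoms <- atoms[order(as.integer(rownames(atoms))), , drop = FALSE]
    atoms$alt <- ""
  }
  rownames(atoms) <- NULL

  new_structure(atoms,
                id = if (is.null(id)) sub("\\.(pdb|ent)(\\.gz)?$", "",
                                          basename(path)) else id,
                source_path = path)
}

#' Construct a protein_structure from an atom table
#'
#' @param atoms data frame with columns chain, resno, insert, resid, elety,
#'   element, x, y, z and optionally o, alt.
#' @param id structure label.
#' @param source_path provenance string.
#' @return A `protein_structure` object.
#' @export
new_structure <- function(atoms, id = "structure", source_path = NA_character_) {
  need <- c("chain", "resno", "insert", "resid", "elety", "element",
            "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table missing columns: ",
                         paste(miss, collapse = ", "))
  if (!nrow(atoms)) stop("structure must contain at least one residue")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite atom coordinates")
  }
  if (is.null(atoms$o)) atoms$o <- 1.0
  if (is.null(atoms$alt)) atoms$alt <- ""
  rkey <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  atoms$resi <- match(rkey, unique(rkey)) # residue index in file order
  structure(list(id = id, atoms = atoms, source_path = source_path),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  rt <- residue_table(x)
  cat("protein_structure '", x$id, "': ", nrow(rt), " residues, ",
      nrow(x$atoms), " atoms, ", length(unique(rt$chain)), " chain(s)\n",
      sep = "")
  invisible(x)
}

#' Residue-level view of a structure
#'
#' @param structure a `protein_structure`.
#' @return Data frame with one row per residue (resi, chain, resno, insert,
#'   resid), in file order.
#' @export
residue_table <- function(structure) {
  at <- structure$atoms
  first <- !duplicated(at$resi)
  out <- at[first, c("resi", "chain", "resno", "insert", "resid")]
  rownames(out) <- NULL
  out
}

#' One-letter sequence of a structure
#'
#' @param structure a `protein_structure`.
#' @return Character scalar; non-standard residues appear as `"X"`.
#' @export
structure_sequence <- function(structure) {
  paste(aa321(residue_table(structure)$resid, x_for_unknown = TRUE),
        collapse = "")
}

#' Write a structure to a PDB file
#'
#' @param structure a `protein_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  at <- structure$atoms
  n <- nrow(at)
  het <- if (is.null(at$het)) rep(FALSE, n) else at$het
  bio3d::write.pdb(
    pdb = NULL, file = path,
    xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
    type = ifelse(het, "HETATM", "ATOM"),
    resno = at$resno, resid = at$resid,
    eleno = seq_len(n), elety = at$elety,
    chain = ifelse(at$chain == "", " ", at$chain),
    insert = ifelse(at$insert == "", "", at$insert),
    alt = ifelse(at$alt == "", "", at$alt),
    o = at$o, b = rep(0, n), elesy = at$element
  )
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file, plain or gzipped.
#' @return Named character vector of upper-cased sequences. Stop codons
#'   (`"*"`) are stripped with a warning; duplicate ids are an error.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (!length(set)) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (any(grepl("\\*", seqs))) {
    warning("stripping '*' stop symbols from ",
            sum(grepl("\\*", seqs)), " sequence(s)")
    seqs <- gsub("\\*", "", seqs)
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param records named character vector of sequences.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.null(names(records)) || any(names(records) == "")) {
    stop("all records must be named")
  }
  Biostrings::writeXStringSet(Biostrings::AAStringSet(records), path,
                              width = 70L)
  invisible(path)
}

#' Read a multiple sequence alignment from aligned FASTA
#'
#' @param path aligned FASTA file.
#' @return Named character vector of equal-length gapped sequences.
#' @export
read_alignment <- function(path) {
  aln <- read_fasta(path)
  if (length(unique(nchar(aln))) != 1L) {
    stop("ragged alignment: row lengths ",
         paste(sort(unique(nchar(aln))), collapse = ", "))
  }
  aln
}

#' Read a phylogenetic tree from a Newick file
#'
#' Requires a single tree in which every edge carries a branch length
#' (branch-length statistics are undefined otherwise).
#'
#' @param path Newick file, plain or gzipped.
#' @return An [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("Newick file not found: ", path)
  con <- gzfile(path, open = "rt")
  on.exit(close(con), add = TRUE)
  txt <- paste(readLines(con, warn = FALSE), collapse = "")
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("Newick parse error in ", path,
                                            ": ", conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error in ", path)
  if (inherits(tree, "multiPhylo")) {
    stop("expected a single tree in ", path, ", found ", length(tree))
  }
  if (is.null(tree$edge.length) ||
      any(!is.finite(tree$edge.length))) {
    stop("missing branch length on one or more edges in ", path)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch length in ", path)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf labels in ", path)
  }
  tree
}

#' Write a tree to a Newick file
#'
#' @param tree a `phylo` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
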