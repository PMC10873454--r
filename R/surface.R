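# Solvent-accessible surface area, surface classification, and the
# acidic/basic charge profiles.

# deterministic golden-spiral unit sphere lattice (no RNG)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

# orientation-canonical frame: principal axes of the heavy-atom cloud with
# eigenvector signs fixed by third moments, so that rigidly moved copies of
# a (generic) structure sample the same lattice directions
.canonical_coords <- function(xyz) {
  if (nrow(xyz) < 3) return(sweep(xyz, 2, colMeans(xyz)))
  ctr <- colMeans(xyz)
  xc <- sweep(xyz, 2, ctr)
  ev <- eigen(crossprod(xc) / nrow(xc), symmetric = TRUE)
  v <- ev$vectors
  proj <- xc %*% v
  for (k in 1:3) {
    s <- sum(proj[, k]^3)
    if (s < 0) {
      v[, k] <- -v[, k]
      proj[, k] <- -proj[, k]
    }
  }
  proj
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA by uniform sphere sampling: each heavy atom's sphere of
#' radius r_atom + probe is covered by a deterministic golden-spiral point
#' lattice and a point counts as accessible if it lies outside every
#' neighbour's expanded sphere. Coordinates are first rotated into a
#' principal-axes frame so that results are invariant under rigid motion of
#' the input (exact for generic structures; highly symmetric atom clouds
#' fall back to the file frame). Hydrogens are ignored.
#'
#' @param structure a `protein_structure`.
#' @param probe_radius solvent probe radius in Angstrom.
#' @param n_sphere_points number of lattice points per atom.
#' @param radii named per-element radii (A).
#' @return A `sasa_result`: list with `per_atom_sasa` (A^2, parallel to the
#'   heavy-atom rows, named by atom), `per_residue_sasa` (named by residue
#'   index), `atoms` (the heavy-atom table), `probe_radius`,
#'   `n_sphere_points`.
#' @export
compute_sasa <- function(structure, probe_radius = 1.4,
                         n_sphere_points = 960L,
                         radii = .default_vdw_radii) {
  at <- structure$atoms
  at <- at[at$element != "H", , drop = FALSE]
  r <- radii[at$element]
  if (anyNA(r)) {
    k <- which(is.na(r))[1]
    stop("no radius for element '", at$element[k], "' (atom ",
         at$elety[k], " of ", at$resid[k], " ", at$chain[k], at$resno[k], ")")
  }
  r <- unname(r)
  n <- nrow(at)
  xyz <- .canonical_coords(as.matrix(at[, c("x", "y", "z")]))
  dirs <- .sphere_points(n_sphere_points)
  rs <- r + probe_radius
  sasa <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (rs[i] + rs)^2 & d2 > 0)
    if (!length(nb)) {
      acc <- n_sphere_points
    } else {
      pts <- dirs * rs[i]
      pts <- sweep(pts, 2, xyz[i, ], "+")
      free <- rep(TRUE, n_sphere_points)
      for (j in nb) {
        dd <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
          (pts[, 3] - xyz[j, 3])^2
        free <- free & dd >= rs[j]^2
        if (!any(free)) break
      }
      acc <- sum(free)
    }
    sasa[i] <- 4 * pi * rs[i]^2 * acc / n_sphere_points
  }
  per_res <- tapply(sasa, at$resi, sum)
  structure(list(
    per_atom_sasa = stats::setNames(sasa, paste(at$chain, at$resno,
                                                at$elety)),
    per_residue_sasa = stats::setNames(as.numeric(per_res),
                                       names(per_res)),
    atoms = at,
    probe_radius = probe_radius,
    n_sphere_points = as.integer(n_sphere_points)
  ), class = "sasa_result")
}

#' Classify residues as surface or buried by relative SASA
#'
#' A residue is on the surface when its SASA divided by the residue-type
#' theoretical maximum (Tien et al. 2013 table) reaches the threshold.
#'
#' @param sasa a `sasa_result` from [compute_sasa()].
#' @param rsasa_threshold relative-SASA threshold (fraction).
#' @param max_sasa named per-residue-type maximum SASA table (A^2).
#' @return Data frame with resi, chain, resno, resid, sasa, rsasa and logical
#'   `surface`.
#' @export
classify_surface <- function(sasa, rsasa_threshold = 0.25,
                             max_sasa = .max_sasa_tien2013) {
  at <- sasa$atoms
  first <- at[!duplicated(at$resi), c("resi", "chain", "resno", "resid")]
  s <- sasa$per_residue_sasa[as.character(first$resi)]
  mx <- max_sasa[first$resid]
  if (anyNA(mx)) {
    stop("no reference max SASA for residue type(s): ",
         paste(unique(first$resid[is.na(mx)]), collapse = ", "))
  }
  out <- data.frame(first, sasa = as.numeric(s),
                    rsasa = as.numeric(s / mx),
                    surface = as.numeric(s / mx) >= rsasa_threshold,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Acidic/basic charge profile of a sequence or structure
#'
#' Counts acidic (D, E) and basic (R, K, H) residues, their total, and the
#' acidic-to-basic ratio, over the whole protein and optionally restricted to
#' surface residues.
#'
#' @param x a `protein_structure`, or a character scalar / vector of 1-letter
#'   residue codes.
#' @param surface_flags optional logical vector (or the data frame from
#'   [classify_surface()]) marking surface residues; when given, a second
#'   profile restricted to the surface is returned.
#' @return A `charge_profile` (scope `"whole"`), or when `surface_flags` is
#'   supplied a list with elements `whole` and `surface`.
#' @export
charge_profile <- function(x, surface_flags = NULL) {
  seq1 <- if (inherits(x, "protein_structure")) {
    strsplit(structure_sequence(x), "")[[1]]
  } else if (is.character(x) && length(x) == 1L && nchar(x) > 1L) {
    strsplit(toupper(x), "")[[1]]
  } else {
    toupper(as.character(x))
  }
  if (is.data.frame(surface_flags)) surface_flags <- surface_flags$surface
  whole <- .charge_counts(seq1, scope = "whole")
  if (is.null(surface_flags)) return(whole)
  if (length(surface_flags) != length(seq1)) {
    stop("surface_flags length (", length(surface_flags),
         ") != number of residues (", length(seq1), ")")
  }
  list(whole = whole,
       surface = .charge_counts(seq1[surface_flags], scope = "surface"))
}

.charge_counts <- function(seq1, scope) {
  n_acidic <- sum(seq1 %in% c("D", "E"))
  n_basic <- sum(seq1 %in% c("R", "K", "H"))
  structure(list(
    scope = scope,
    n_residues = length(seq1),
    n_acidic = n_acidic,
    n_basic = n_basic,
    n_charged = n_acidic + n_basic,
    acidic_basic_ratio = if (n_basic > 0) n_acidic / n_basic else NA_real_
  ), class = "charge_profile")
}

#' @export
print.charge_profile <- function(x, ...) {
  cat("charge profile (", x$scope, "): acidic ", x$n_acidic,
      ", basic ", x$n_basic, ", charged ", x$n_charged,
      ", acidic/basic ",
      if (is.na(x$acidic_basic_ratio)) "NA" else
        formatC(x$acidic_basic_ratio, digits = 3, format = "f"),
      "\n", sep = "")
  invisible(x)
}
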