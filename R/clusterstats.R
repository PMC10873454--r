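# Cross-cluster statistics: F-test-then-t-test contrasts, compact letter
# displays, and per-clade branch-length summaries.

#' Two-sample comparison: F test for equal variances, then t test
#'
#' The variance-ratio F statistic (larger variance over smaller, two-sided p)
#' decides the t-test flavour: pooled-variance two-sample t when equal
#' variances are not rejected at `alpha`, Welch otherwise. Both tests are
#' two-sided.
#'
#' @param a,b numeric samples (each of length >= 2, finite).
#' @param alpha significance level for the variance pre-test.
#' @param labels length-2 character vector naming the groups.
#' @return A `group_comparison`: group_labels, n_a, n_b, mean_a, mean_b,
#'   f_stat, f_pvalue, pooled (logical), t_stat, t_pvalue, alpha.
#' @export
compare_groups <- function(a, b, alpha = 0.05, labels = c("a", "b")) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 values")
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("non-finite values")
  va <- stats::var(a); vb <- stats::var(b)

  if (va == 0 && vb == 0) {
    f_stat <- NA_real_; f_p <- NA_real_; pooled <- TRUE
    if (mean(a) == mean(b)) {
      t_stat <- 0; t_p <- 1
    } else {
      t_stat <- sign(mean(a) - mean(b)) * Inf; t_p <- 0
    }
  } else {
    if (va >= vb) {
      f_stat <- if (vb > 0) va / vb else Inf
      df1 <- length(a) - 1L; df2 <- length(b) - 1L
    } else {
      f_stat <- vb / va
      df1 <- length(b) - 1L; df2 <- length(a) - 1L
    }
    f_p <- if (is.finite(f_stat)) {
      min(1, 2 * stats::pf(f_stat, df1, df2, lower.tail = FALSE))
    } else 0
    pooled <- f_p >= alpha
    tt <- stats::t.test(a, b, var.equal = pooled)
    t_stat <- unname(tt$statistic); t_p <- tt$p.value
  }
  structure(list(group_labels = labels,
                 n_a = length(a), n_b = length(b),
                 mean_a = mean(a), mean_b = mean(b),
                 f_stat = f_stat, f_pvalue = f_p,
                 pooled = pooled,
                 t_stat = t_stat, t_pvalue = t_p,
                 alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s (n=%d, mean=%.4g) vs %s (n=%d, mean=%.4g)\n",
              x$group_labels[1], x$n_a, x$mean_a,
              x$group_labels[2], x$n_b, x$mean_b))
  cat(sprintf("  F=%.4g (p=%.4g) -> %s t=%.4g, p=%.4g\n",
              x$f_stat, x$f_pvalue,
              if (x$pooled) "pooled" else "Welch", x$t_stat, x$t_pvalue))
  invisible(x)
}

#' Compact letter display across several clusters
#'
#' All pairwise [compare_groups()] contrasts; clusters that are not
#' significantly different share a letter. Letters correspond to the maximal
#' cliques of the non-significance graph, ordered by the highest-mean member,
#' so two clusters share a letter iff their pairwise test is not significant.
#'
#' @param samples named list of numeric vectors, one per cluster.
#' @param alpha significance level.
#' @param adjust p-value adjustment across the pairwise tests
#'   (`"none"` matches plain per-pair testing; `"holm"` available).
#' @return List with `letters` (named character vector), `pairwise` (data
#'   frame of the pairwise tests), `means`.
#' @export
letter_groups <- function(samples, alpha = 0.05,
                          adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  k <- length(samples)
  if (k < 2) stop("need at least 2 clusters")
  if (is.null(names(samples)) || any(names(samples) == "")) {
    stop("samples must be a named list")
  }
  nm <- names(samples)
  pairs <- utils::combn(k, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(c2) {
    i <- pairs[1, c2]; j <- pairs[2, c2]
    cmp <- compare_groups(samples[[i]], samples[[j]], alpha = alpha,
                          labels = nm[c(i, j)])
    data.frame(group_a = nm[i], group_b = nm[j],
               t_stat = cmp$t_stat, p_value = cmp$t_pvalue,
               pooled = cmp$pooled, stringsAsFactors = FALSE)
  }))
  pw$p_adjusted <- stats::p.adjust(pw$p_value, method = adjust)
  sig <- pw$p_adjusted < alpha

  means <- vapply(samples, mean, numeric(1))
  ord <- order(-means)
  # non-significance graph on rank-ordered clusters
  adj <- matrix(FALSE, k, k, dimnames = list(nm, nm))
  for (c2 in seq_len(nrow(pw))) {
    if (!sig[c2]) {
      adj[pw$group_a[c2], pw$group_b[c2]] <- TRUE
      adj[pw$group_b[c2], pw$group_a[c2]] <- TRUE
    }
  }
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  cliques <- igraph::max_cliques(g)
  members <- lapply(cliques, function(cl) nm[as.integer(cl)])
  # order letters by the best (highest-mean) member of each clique
  best <- vapply(members, function(m) min(match(m, nm[ord])), numeric(1))
  members <- members[order(best)]
  letters_out <- stats::setNames(rep("", k), nm)
  for (li in seq_along(members)) {
    for (m in members[[li]]) {
      letters_out[m] <- paste0(letters_out[m], letters[li])
    }
  }
  list(letters = letters_out, pairwise = pw, means = means)
}

#' Per-clade branch-length statistics
#'
#' For each clade (given as its leaf set, which must be monophyletic) the
#' most recent common ancestor is located and two summaries are reported:
#' the mean over all edge lengths strictly within the MRCA subtree (the
#' MRCA's own parent edge excluded), and the mean tip-to-MRCA path length,
#' an alternative reading of "average branch length".
#'
#' @param tree a `phylo` object with branch lengths on every edge.
#' @param clade_leaf_sets named list of character vectors of leaf labels.
#' @return Data frame with clade, n_leaves, n_edges, mean_branch_length,
#'   alt_mean_tip_depth.
#' @export
clade_branch_stats <- function(tree, clade_leaf_sets) {
  if (is.null(tree$edge.length) || any(!is.finite(tree$edge.length))) {
    stop("tree has missing branch lengths")
  }
  if (is.null(names(clade_leaf_sets))) {
    names(clade_leaf_sets) <- paste0("clade", seq_along(clade_leaf_sets))
  }
  out <- lapply(names(clade_leaf_sets), function(cn) {
    leaves <- clade_leaf_sets[[cn]]
    missing_l <- setdiff(leaves, tree$tip.label)
    if (length(missing_l)) {
      stop("clade '", cn, "': leaves not in tree: ",
           paste(missing_l, collapse = ", "))
    }
    if (length(leaves) < 2) {
      stop("clade '", cn, "' needs at least 2 leaves")
    }
    if (length(leaves) == length(tree$tip.label)) {
      sub <- tree
    } else {
      mrca <- ape::getMRCA(tree, leaves)
      sub <- ape::extract.clade(tree, mrca)
      extra <- setdiff(sub$tip.label, leaves)
      if (length(extra)) {
        stop("clade '", cn, "' is not monophyletic; subtree also contains: ",
             paste(extra, collapse = ", "))
      }
    }
    depths <- ape::node.depth.edgelength(sub)
    data.frame(clade = cn,
               n_leaves = length(leaves),
               n_edges = length(sub$edge.length),
               mean_branch_length = mean(sub$edge.length),
               alt_mean_tip_depth = mean(depths[seq_along(sub$tip.label)]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
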