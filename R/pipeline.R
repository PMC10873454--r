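# Orchestration: run the full comparative analysis from structures, an
# alignment and a tree to a plain TSV/JSON report directory.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis stages. `structures` assigns each
#' input PDB to a cluster; comparisons contrast the first two clusters that
#' have at least two structures each.
#'
#' @param structures named character vector of PDB paths; `clusters` a
#'   parallel character vector of cluster labels.
#' @param clusters cluster label per structure.
#' @param alignment_path optional aligned FASTA for the differential-residue
#'   stage.
#' @param ref_id,query_id,cluster_ids alignment row ids for
#'   [classify_columns()] (required with `alignment_path`).
#' @param region_structure name (in `structures`) of the structure used for
#'   region detection; defaults to none.
#' @param tree_path optional Newick file for clade statistics.
#' @param clades optional named list of leaf sets for [clade_branch_stats()].
#' @param interaction an [interaction_config()].
#' @param rsasa_threshold relative-SASA surface threshold.
#' @param sasa_points sphere-lattice size for [compute_sasa()].
#' @param region_linkage_cutoff,region_min_size parameters of
#'   [find_enriched_regions()].
#' @param alpha significance level of all tests.
#' @param out_dir report directory (created if absent).
#' @param seed seed recorded in the report (the pipeline itself is
#'   deterministic).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(structures, clusters,
                            alignment_path = NULL,
                            ref_id = NULL, query_id = NULL,
                            cluster_ids = NULL,
                            region_structure = NULL,
                            tree_path = NULL, clades = NULL,
                            interaction = interaction_config(),
                            rsasa_threshold = 0.25,
                            sasa_points = 960L,
                            region_linkage_cutoff = 10.0,
                            region_min_size = 3L,
                            alpha = 0.05,
                            out_dir = tempfile("protrin_report_"),
                            seed = 1L) {
  if (!length(structures)) stop("no structures given")
  if (is.null(names(structures)) || any(names(structures) == "")) {
    stop("structures must be a named vector of paths")
  }
  if (length(clusters) != length(structures)) {
    stop("clusters must parallel structures")
  }
  missing_f <- structures[!file.exists(structures)]
  if (length(missing_f)) {
    stop("input structure file(s) not found: ",
         paste(missing_f, collapse = ", "))
  }
  if (!is.null(alignment_path)) {
    if (!file.exists(alignment_path)) {
      stop("alignment file not found: ", alignment_path)
    }
    if (is.null(ref_id) || is.null(query_id) || is.null(cluster_ids)) {
      stop("alignment_path requires ref_id, query_id and cluster_ids")
    }
  }
  if (!is.null(tree_path) && !file.exists(tree_path)) {
    stop("tree file not found: ", tree_path)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Per structure: residue interaction network census, SASA, and whole/surface
#' charge profiles. Across clusters: F-test-then-t-test contrasts (with a
#' compact letter display when more than two clusters) of edges, edge/node
#' ratio, per-type counts, the F-F stacking count, and charge counts. With an
#' alignment: group A/B classification (plus spatial regions when a structure
#' is named, and the all/groupA/groupB substitution-set mutants). With a
#' tree: per-clade branch-length statistics. Everything is written as TSV and
#' JSON under `config$out_dir` and returned invisibly.
#'
#' @param config a [pipeline_config()].
#' @return A `pipeline_report` list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  stage <- function(name, expr) {
    s <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - s, 3)
    res
  }

  structs <- stage("read_structures", lapply(config$structures, read_pdb))

  per_protein <- stage("rin_and_charge", lapply(names(structs), function(nm) {
    st <- structs[[nm]]
    net <- build_rin(st, config$interaction)
    sasa <- compute_sasa(st, n_sphere_points = config$sasa_points)
    flags <- classify_surface(sasa, config$rsasa_threshold)
    prof <- charge_profile(st, surface_flags = flags)
    ff <- net$summary$pipi_pairs["F-F"]
    list(name = nm, cluster = config$clusters[[match(nm, names(structs))]],
         rin = net, sasa = sasa, flags = flags, profile = prof,
         metrics = c(
           n_edges = net$summary$n_edges,
           edge_node_ratio = net$summary$edge_node_ratio,
           net$summary$per_type,
           ff_count = if (is.na(ff)) 0 else unname(ff),
           acidic_whole = prof$whole$n_acidic,
           basic_whole = prof$whole$n_basic,
           charged_whole = prof$whole$n_charged,
           ratio_whole = prof$whole$acidic_basic_ratio,
           acidic_surface = prof$surface$n_acidic,
           basic_surface = prof$surface$n_basic,
           charged_surface = prof$surface$n_charged,
           ratio_surface = prof$surface$acidic_basic_ratio
         ))
  }))
  names(per_protein) <- names(structs)

  metric_tab <- do.call(rbind, lapply(per_protein, function(p) {
    data.frame(structure = p$name, cluster = p$cluster,
               t(p$metrics), stringsAsFactors = FALSE)
  }))
  rownames(metric_tab) <- NULL
  utils::write.table(metric_tab,
                     file.path(config$out_dir, "per_protein_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  comparisons <- stage("cluster_comparisons", {
    cl <- unique(config$clusters)
    ok <- cl[vapply(cl, function(c2) sum(config$clusters == c2) >= 2,
                    logical(1))]
    if (length(ok) >= 2) {
      metrics <- setdiff(names(metric_tab), c("structure", "cluster"))
      out <- lapply(metrics, function(mm) {
        vals <- lapply(ok, function(c2) {
          v <- metric_tab[[mm]][metric_tab$cluster == c2]
          v[is.finite(v)]
        })
        names(vals) <- ok
        usable <- vapply(vals, function(v) length(v) >= 2, logical(1))
        if (sum(usable) < 2) return(NULL)
        vals <- vals[usable]
        if (length(vals) == 2) {
          cmp <- compare_groups(vals[[1]], vals[[2]], alpha = config$alpha,
                                labels = names(vals))
          list(metric = mm, type = "pair", comparison = unclass(cmp))
        } else {
          lg <- letter_groups(vals, alpha = config$alpha)
          list(metric = mm, type = "letters", letters = lg$letters,
               pairwise = lg$pairwise, means = lg$means)
        }
      })
      out[!vapply(out, is.null, logical(1))]
    } else list()
  })

  diffres <- NULL
  if (!is.null(config$alignment_path)) {
    diffres <- stage("differential_residues", {
      aln <- read_alignment(config$alignment_path)
      cls <- classify_columns(aln, config$ref_id, config$query_id,
                              config$cluster_ids)
      query_seq <- gsub("-", "", aln[[config$query_id]])
      sets <- list(
        substitution_set(paste0(config$query_id, "_all"),
                         positions_by_group(cls, "all"), "all"),
        substitution_set(paste0(config$query_id, "_groupA"),
                         positions_by_group(cls, "A"), "groupA"),
        substitution_set(paste0(config$query_id, "_groupB"),
                         positions_by_group(cls, "B"), "groupB")
      )
      sets <- Filter(function(s) length(s$positions) > 0, sets)
      mutants <- if (length(sets)) {
        design_mutants(query_seq, cls, sets)
      } else character()
      regions <- NULL
      if (!is.null(config$region_structure)) {
        st <- structs[[config$region_structure]]
        posA <- positions_by_group(cls, "A")
        posA <- posA[posA <= nrow(residue_table(st))]
        regions <- find_enriched_regions(
          st, posA, linkage_cutoff = config$region_linkage_cutoff,
          min_size = config$region_min_size)
      }
      utils::write.table(cls,
                         file.path(config$out_dir, "classification.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (length(mutants)) {
        write_fasta(mutants, file.path(config$out_dir, "mutants.fasta"))
      }
      list(classification = cls, mutants = mutants, regions = regions)
    })
  }

  clades <- NULL
  if (!is.null(config$tree_path) && !is.null(config$clades)) {
    clades <- stage("clade_stats", {
      tree <- read_newick(config$tree_path)
      clade_branch_stats(tree, config$clades)
    })
    utils::write.table(clades, file.path(config$out_dir, "clades.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  report <- list(
    config = list(
      structures = as.list(config$structures),
      clusters = as.list(config$clusters),
      interaction = unclass(config$interaction),
      rsasa_threshold = config$rsasa_threshold,
      sasa_points = config$sasa_points,
      region_linkage_cutoff = config$region_linkage_cutoff,
      region_min_size = config$region_min_size,
      alpha = config$alpha,
      seed = config$seed
    ),
    per_protein = lapply(per_protein, function(p) as.list(p$metrics)),
    comparisons = comparisons,
    differential = if (!is.null(diffres)) {
      list(n_differential = nrow(diffres$classification),
           n_groupA = sum(diffres$classification$group == "A"),
           n_groupB = sum(diffres$classification$group == "B"),
           mutants = names(diffres$mutants),
           n_regions = length(diffres$regions))
    },
    clades = clades,
    timings = as.list(timings),
    elapsed = round(proc.time()[["elapsed"]] - t0, 3)
  )
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", force = TRUE)
  invisible(structure(list(report = report, per_protein = per_protein,
                           comparisons = comparisons, diffres = diffres,
                           clades = clades, out_dir = config$out_dir),
                      class = "pipeline_report"))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline report:", length(x$per_protein), "structure(s),",
      length(x$comparisons), "cluster comparison(s)\n")
  cat("  written to", x$out_dir, "\n")
  invisible(x)
}
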