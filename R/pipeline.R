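#' Run the full phylogeography pipeline
#'
#' Orchestrates the analysis stages on a cohort: TMA filtering and
#' relatedness deduplication, haplogroup classification, the regional
#' frequency table with its chi-square test of geographic structure,
#' diversity summaries, extraction of the focal clade (default A2af-like:
#' the samples calling into `focal_clade` or below), the median-joining
#' network of its control-region haplotypes, and rho-based dating of the
#' network from its modal founder node. All artifacts are written under
#' `out_dir` and the per-stage counts are logged.
#'
#' @param haps an `mt_cohort` (e.g. from [read_haplotypes()] or
#'   [simulate_cohort()]).
#' @param metadata metadata `data.frame` (see [read_metadata()]).
#' @param tree a [haplogroup_tree()] for classification.
#' @param region_type named vector region -> `"province"`/`"comarca"`;
#'   defaults to the bundled Panamanian region table.
#' @param focal_clade haplogroup whose haplotypes get the network/dating
#'   treatment; `NULL` skips those stages.
#' @param clock a [clock_config()].
#' @param epsilon median-joining tolerance.
#' @param keep_origin TMA origin retained (default `"Panama"`).
#' @param out_dir output directory (created); `NULL` writes nothing.
#' @param verbose log stage counts to the console.
#' @return list of class `pipeline_result`: `calls`, `freq_table`,
#'   `chisq`, `diversity`, `network`, `ages`, `log`.
#' @export
run_pipeline <- function(haps, metadata, tree,
                         region_type = NULL, focal_clade = "A2",
                         clock = clock_config(), epsilon = 0,
                         keep_origin = "Panama", out_dir = NULL,
                         verbose = TRUE) {
  stopifnot(inherits(haps, "mt_cohort"))
  log <- list(n_input = length(haps))
  say <- function(...) if (verbose) message(sprintf(...))
  say("input: %d samples", log$n_input)

  tma <- filter_by_tma(metadata, keep_origin)
  log$n_foreign_tma <- tma$n_excluded
  meta_kept <- metadata[metadata$sample_id %in% tma$kept, , drop = FALSE]
  dd <- dedup_related(meta_kept)
  log$n_clustered <- dd$n_clustered
  log$n_removed_related <- dd$n_removed
  keep_ids <- dd$retained
  core <- haps[names(haps) %in% keep_ids]
  log$n_final <- length(core)
  say("TMA filter: -%d foreign; dedup: -%d related; final: %d",
      tma$n_excluded, dd$n_removed, log$n_final)

  calls <- classify_cohort(core, tree)
  if (is.null(region_type)) {
    rc <- utils::read.delim(
      system.file("extdata", "panama_region_counts.tsv", package = "panmito"),
      stringsAsFactors = FALSE, check.names = FALSE
    )
    region_type <- setNames(rc$type, rc$region)[!duplicated(rc$region)]
  }
  ft <- frequency_table(calls, region_type)
  origin <- matrix(
    vapply(BIN_GROUPS, function(b) {
      rowSums(ft$counts[ft$regions, b, drop = FALSE])
    }, numeric(length(ft$regions))),
    nrow = length(ft$regions),
    dimnames = list(ft$regions, names(BIN_GROUPS))
  )
  chisq <- if (nrow(origin) >= 2L && sum(colSums(origin) > 0) >= 2L) {
    chisq_independence(origin[, colSums(origin) > 0, drop = FALSE])
  } else NULL

  div <- if (length(core) >= 2L) diversity_stats(core) else {
    warning("fewer than 2 samples; diversity stage skipped")
    NULL
  }

  network <- NULL
  ages <- NULL
  if (!is.null(focal_clade)) {
    in_focal <- startsWith(calls$haplogroup, focal_clade)
    focal <- core[names(core) %in% calls$sample_id[in_focal]]
    if (length(focal) >= 2L) {
      cm <- build_character_matrix(focal, site_filter("network"))
      network <- median_joining(cm, epsilon = epsilon)
      root <- network$nodes$id[which.max(network$nodes$multiplicity)]
      ages <- network_node_ages(network, root, clock, "control_region")
      log$n_focal <- length(focal)
      say("focal clade %s: %d samples, %d network nodes",
          focal_clade, length(focal), nrow(network$nodes))
    }
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(calls, file.path(out_dir, "classification.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_frequency_table(ft, file.path(out_dir, "frequency_table.tsv"))
    if (!is.null(div)) {
      diversity_report(core, path = file.path(out_dir, "diversity.tsv"))
    }
    if (!is.null(network)) {
      write_network(network, file.path(out_dir, "network.gml"),
                    node_table = file.path(out_dir, "network_nodes.csv"))
      age_report(list(focal = ages), file.path(out_dir, "ages.tsv"))
    }
    jsonlite::write_json(log, file.path(out_dir, "log.json"),
                         auto_unbox = TRUE)
  }
  structure(
    list(calls = calls, freq_table = ft, chisq = chisq, diversity = div,
         network = network, ages = ages, log = log),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ", x$log$n_input, " -> ", x$log$n_final,
      " samples after TMA filter and dedup\n", sep = "")
  if (!is.null(x$chisq)) {
    cat("  region x origin chi-square p = ",
        format.pval(x$chisq$p.value, digits = 3), "\n", sep = "")
  }
  invisible(x)
}
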