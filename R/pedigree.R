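#' Deduplicate maternally related samples
#'
#' Given relatedness clusters (maternally related extended families, each
#' a set of sample ids), retains exactly one member per cluster -- the
#' lexicographically smallest sample id, a deterministic stand-in for the
#' study's unstated choice -- and logs the removals.
#'
#' @param metadata metadata `data.frame` with at least `sample_id`;
#'   clusters default to its `cluster_id` column when `clusters` is `NULL`.
#' @param clusters optional list of character vectors of sample ids; must
#'   be disjoint.
#' @return list with `retained` (character vector of all surviving
#'   sample ids, in input order), `removed` (`data.frame`: `sample_id`,
#'   `cluster_id`, `retained_as`), and counts `n_clustered`, `n_removed`.
#' @export
dedup_related <- function(metadata, clusters = NULL) {
  stopifnot("sample_id" %in% names(metadata))
  ids <- metadata$sample_id
  if (is.null(clusters)) {
    if (!"cluster_id" %in% names(metadata)) stop("no clusters supplied")
    cl <- metadata$cluster_id
    clusters <- split(ids[!is.na(cl)], cl[!is.na(cl)])
  } else if (is.null(names(clusters))) {
    names(clusters) <- sprintf("fam%03d", seq_along(clusters))
  }
  all_members <- unlist(clusters)
  if (anyDuplicated(all_members)) {
    stop("overlapping clusters: ",
         paste(unique(all_members[duplicated(all_members)]), collapse = ", "))
  }
  missing <- setdiff(all_members, ids)
  if (length(missing)) stop("cluster member(s) not in metadata: ",
                            paste(missing, collapse = ", "))
  removed <- NULL
  for (nm in names(clusters)) {
    mem <- sort(clusters[[nm]])
    if (length(mem) > 1L) {
      removed <- rbind(removed, data.frame(
        sample_id = mem[-1L], cluster_id = nm, retained_as = mem[1L],
        stringsAsFactors = FALSE
      ))
    }
  }
  if (is.null(removed)) {
    removed <- data.frame(sample_id = character(), cluster_id = character(),
                          retained_as = character(), stringsAsFactors = FALSE)
  }
  list(
    retained = ids[!ids %in% removed$sample_id],
    removed = removed,
    n_clustered = length(all_members),
    n_removed = nrow(removed)
  )
}

#' Filter samples by terminal-maternal-ancestor origin
#'
#' Splits a cohort on the origin of the last known forebear on the
#' strictly maternal line (TMA), keeping the autochthonous samples and
#' tallying the excluded by origin.
#'
#' @param metadata metadata `data.frame` with `sample_id` and `tma_origin`.
#' @param keep_origin TMA origin label to retain (e.g. `"Panama"`).
#' @return list with `kept` (sample ids), `excluded_by_origin` (table),
#'   `n_kept`, `n_excluded`.
#' @export
filter_by_tma <- function(metadata, keep_origin = "Panama") {
  stopifnot(all(c("sample_id", "tma_origin") %in% names(metadata)))
  keep <- metadata$tma_origin == keep_origin
  list(
    kept = metadata$sample_id[keep],
    excluded_by_origin = table(metadata$tma_origin[!keep]),
    n_kept = sum(keep),
    n_excluded = sum(!keep)
  )
}
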