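#' Build a cohort from haplotypes
#'
#' A cohort is an ordered collection of [haplotype()] objects sharing the
#' analysis conventions (covered range, notation).
#'
#' @param haps list of `mt_haplotype` objects.
#' @return an object of class `mt_cohort`.
#' @export
cohort <- function(haps) {
  stopifnot(all(vapply(haps, inherits, TRUE, "mt_haplotype")))
  ids <- vapply(haps, function(h) h$sample_id, "")
  if (anyDuplicated(ids)) stop("duplicate sample ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(setNames(haps, ids), class = "mt_cohort")
}

#' @export
print.mt_cohort <- function(x, ...) {
  cat("<mt_cohort> ", length(x), " samples\n", sep = "")
  invisible(x)
}

#' @export
`[.mt_cohort` <- function(x, i) {
  structure(unclass(x)[i], class = "mt_cohort")
}

#' Read / write per-sample variant tables
#'
#' The haplotype TSV dialect has columns `sample_id`, `region`,
#' `tma_origin`, `haplogroup` (may be empty) and `variants`
#' (space-separated rCRS-relative tokens), one sample per row -- the
#' structure of a control-region haplotype supplementary table.
#'
#' @param path file path.
#' @param covered_range circular rCRS interval the samples were sequenced
#'   over.
#' @return `read_haplotypes()` returns an `mt_cohort`.
#' @export
read_haplotypes <- function(path, covered_range = c(16000L, 580L)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = character())
  need <- c("sample_id", "region", "tma_origin", "variants")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("haplotype TSV missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"haplogroup" %in% names(df)) df$haplogroup <- NA_character_
  haps <- lapply(seq_len(nrow(df)), function(i) {
    toks <- strsplit(trimws(df$variants[i]), "[ ]+")[[1]]
    toks <- toks[nzchar(toks)]
    haplotype(df$sample_id[i], toks, covered_range = covered_range,
              region = df$region[i], tma_origin = df$tma_origin[i],
              haplogroup = if (nzchar(df$haplogroup[i])) df$haplogroup[i]
                           else NA_character_)
  })
  cohort(haps)
}

#' @rdname read_haplotypes
#' @param x an `mt_cohort`.
#' @export
write_haplotypes <- function(x, path) {
  stopifnot(inherits(x, "mt_cohort"))
  df <- data.frame(
    sample_id = vapply(x, function(h) h$sample_id, ""),
    region = vapply(x, function(h) h$region, ""),
    tma_origin = vapply(x, function(h) h$tma_origin, ""),
    haplogroup = vapply(x, function(h) ifelse(is.na(h$haplogroup), "",
                                              h$haplogroup), ""),
    variants = vapply(x, function(h) paste(h$variants$token, collapse = " "), ""),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write sample metadata tables
#'
#' Metadata TSV columns: `sample_id`, `region`, `tma_origin`,
#' `generations` (recorded maternal generations), `cluster_id`
#' (relatedness cluster; empty when unrelated).
#'
#' @param path file path.
#' @return a `data.frame`.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = character())
  need <- c("sample_id", "region", "tma_origin", "generations", "cluster_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata TSV missing column(s): ",
                         paste(miss, collapse = ", "))
  df$generations <- as.integer(df$generations)
  df$cluster_id[!nzchar(df$cluster_id)] <- NA_character_
  df
}

#' @rdname read_metadata
#' @param x metadata `data.frame`.
#' @export
write_metadata <- function(x, path) {
  x$cluster_id[is.na(x$cluster_id)] <- ""
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
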