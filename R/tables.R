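MAJOR_BINS <- c("A2", "B2", "C1", "D1", "L0", "L1", "L2", "L3",
                "HV", "JT", "N1'2", "U", "G")

BIN_GROUPS <- list(
  Native = c("A2", "B2", "C1", "D1"),
  Africa = c("L0", "L1", "L2", "L3"),
  `West Eurasia` = c("HV", "JT", "N1'2", "U"),
  `East Asia` = c("G")
)

#' Default collapse of haplogroup labels into major-clade bins
#'
#' Maps a (sub-)haplogroup label to one of the major clade columns used in
#' regional frequency tables (A2, B2, C1, D1, L0--L3, HV, JT, N1'2, U, G)
#' by longest-prefix matching, so e.g. `"A2af1a"` collapses to `"A2"` and
#' `"L3e2b"` to `"L3"`.
#'
#' @param labels character vector of haplogroup labels.
#' @return character vector of bin labels; unmapped labels raise an error
#'   listing the offenders.
#' @export
default_collapse <- function(labels) {
  bins <- character(length(labels))
  for (i in seq_along(labels)) {
    hit <- MAJOR_BINS[startsWith(labels[i], MAJOR_BINS)]
    bins[i] <- if (length(hit)) hit[which.max(nchar(hit))] else NA_character_
  }
  if (anyNA(bins)) {
    stop("haplogroup label(s) not covered by the collapse map: ",
         paste(unique(labels[is.na(bins)]), collapse = ", "))
  }
  bins
}

#' Regional haplogroup frequency table
#'
#' Tabulates collapsed haplogroup calls by collection region, with row
#' percentages, continent-level group columns (Native American = A2 + B2 +
#' C1 + D1; Africa = L0--L3; West Eurasia = HV + JT + N1'2 + U; East Asia
#' = G), and marginal rows for all provinces, all comarcas, and the grand
#' total.
#'
#' @param calls `data.frame` with columns `sample_id`, `haplogroup`,
#'   `region` (as from [classify_cohort()]).
#' @param region_type named character vector mapping each region to
#'   `"province"` or `"comarca"`.
#' @param collapse function mapping haplogroup labels to bin labels
#'   (default [default_collapse()]); must error on unmapped labels.
#' @param bins column order of the table.
#' @return an object of class `haplogroup_freq_table`: a list with
#'   `counts` and `percent` data frames (regions plus marginal rows by
#'   bins plus group columns) and the sample sizes `n`.
#' @export
frequency_table <- function(calls, region_type,
                            collapse = default_collapse, bins = MAJOR_BINS) {
  stopifnot(all(c("haplogroup", "region") %in% names(calls)))
  if (any(!calls$region %in% names(region_type))) {
    stop("region(s) missing from region_type: ",
         paste(setdiff(unique(calls$region), names(region_type)), collapse = ", "))
  }
  bin <- collapse(calls$haplogroup)
  bad <- setdiff(unique(bin), bins)
  if (length(bad)) stop("collapsed bin(s) outside table columns: ",
                        paste(bad, collapse = ", "))
  regions <- sort(unique(calls$region))
  counts <- table(factor(calls$region, regions), factor(bin, bins))
  counts <- matrix(as.integer(counts), nrow = length(regions),
                   dimnames = list(regions, bins))

  prov <- regions[region_type[regions] == "province"]
  com <- regions[region_type[regions] == "comarca"]
  marg <- rbind(
    `Total Provinces` = colSums(counts[prov, , drop = FALSE]),
    `Total Comarcas` = colSums(counts[com, , drop = FALSE]),
    `Grand Total` = colSums(counts)
  )
  full <- rbind(counts, marg)
  grp <- vapply(BIN_GROUPS, function(b) {
    rowSums(full[, intersect(b, bins), drop = FALSE])
  }, numeric(nrow(full)))
  n <- rowSums(full)
  pct <- round(100 * cbind(full, grp) / n, 2)
  structure(
    list(counts = cbind(as.data.frame(full), as.data.frame(grp, check.names = FALSE)),
         percent = as.data.frame(pct, check.names = FALSE),
         n = n, regions = regions,
         province_rows = prov, comarca_rows = com),
    class = "haplogroup_freq_table"
  )
}

#' @export
print.haplogroup_freq_table <- function(x, ...) {
  cat("<haplogroup_freq_table> ", length(x$regions), " regions, n = ",
      x$n[["Grand Total"]], "\n", sep = "")
  out <- cbind(n = x$n, x$percent)
  print(out, ...)
  invisible(x)
}

#' @rdname frequency_table
#' @param x a `haplogroup_freq_table`.
#' @param path output TSV path.
#' @export
write_frequency_table <- function(x, path) {
  out <- cbind(`Province/Comarca` = rownames(x$percent), n = x$n, x$percent)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pearson chi-square test of independence
#'
#' Tests independence of rows and columns of a contingency table of
#' haplogroup counts (e.g. geographic structure of haplogroup origin
#' classes), without continuity correction.
#'
#' @param tab matrix of non-negative integer counts, at least 2x2.
#' @return list with `statistic`, `df`, `p.value`.
#' @export
chisq_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2L || ncol(tab) < 2L) stop("need at least a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab))) stop("counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero-margin row/column; collapse categories first")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = unname(ct$p.value))
}
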