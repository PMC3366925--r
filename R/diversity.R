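#' Sequence diversity summary of a cohort
#'
#' Computes the standard control-region diversity summaries over a cohort
#' of haplotypes: mean pairwise differences k (over substitution variants
#' under the `"stats"` filter), nucleotide diversity pi = k / L where L is
#' the number of compared sites (the covered range minus columns affected
#' by gaps/indels or heteroplasmic ambiguity anywhere in the cohort),
#' segregating-site count S, the invariable-site count L - S, haplotype
#' diversity Hd = n (1 - sum p_i^2) / (n - 1) over distinct haplotype
#' frequencies, and the distinct-haplotype count.
#'
#' @param haps an `mt_cohort` (or list of [haplotype()]).
#' @param filter a [site_filter()]; the default `"stats"` profile keeps
#'   substitutions only.
#' @return an object of class `diversity_stats`: list with `n`, `L`, `S`,
#'   `invariable`, `pi`, `k`, `Hd`, `n_haplotypes`.
#' @export
diversity_stats <- function(haps, filter = site_filter("stats")) {
  if (inherits(haps, "mt_cohort")) haps <- unclass(haps)
  n <- length(haps)
  if (n < 2L) stop("diversity statistics need at least 2 samples")
  rng <- haps[[1]]$covered_range
  range_len <- circular_range_intersection_length(rng, rng)

  filt <- lapply(haps, function(h) filter_variants(h$variants, filter))
  tok_sets <- lapply(filt, function(v) sort(v$token[!v$reversion]))

  # columns excluded from comparison: any indel or heteroplasmic position
  excluded_cols <- integer()
  for (h in haps) {
    v <- h$variants
    bad <- v$kind %in% c("insertion", "deletion", "heteroplasmy")
    if (any(bad)) {
      for (i in which(bad)) {
        if (v$kind[i] == "insertion") next  # insertions add no rCRS column
        excluded_cols <- c(excluded_cols, v$position[i]:v$span_end[i])
      }
    }
  }
  L <- range_len - length(unique(excluded_cols))

  # mean pairwise differences: a variant carried by c of n samples
  # separates exactly c (n - c) of the n (n - 1) / 2 pairs
  tok_count <- table(unlist(tok_sets))
  cc <- as.numeric(tok_count)
  k <- sum(cc * (n - cc)) / (n * (n - 1) / 2)

  # segregating sites: positions whose variant pattern differs across samples
  seg_tokens <- names(tok_count)[tok_count < n]
  S <- length(unique(parse_variants(seg_tokens)$position))

  key <- vapply(tok_sets, paste, "", collapse = " ")
  freq <- table(key)
  p <- as.numeric(freq) / n
  Hd <- n * (1 - sum(p^2)) / (n - 1L)

  structure(
    list(n = n, L = L, S = S, invariable = L - S, pi = k / L, k = k,
         Hd = Hd, n_haplotypes = length(freq)),
    class = "diversity_stats"
  )
}

#' @export
print.diversity_stats <- function(x, ...) {
  cat("<diversity_stats> n = ", x$n, ", compared sites L = ", x$L, "\n",
      "  S = ", x$S, " polymorphic / ", x$invariable, " invariable\n",
      "  pi = ", signif(x$pi, 4), "  k = ", signif(x$k, 5),
      "  Hd = ", signif(x$Hd, 4), "  (", x$n_haplotypes,
      " distinct haplotypes)\n", sep = "")
  invisible(x)
}

#' Haplotype census
#'
#' Counts distinct (filtered) haplotypes and their multiplicity spectrum.
#'
#' @inheritParams diversity_stats
#' @return list with `n_haplotypes` and `spectrum` (table:
#'   multiplicity -> number of haplotypes with that multiplicity).
#' @export
haplotype_census <- function(haps, filter = site_filter("stats")) {
  if (inherits(haps, "mt_cohort")) haps <- unclass(haps)
  if (length(haps) == 0L) return(list(n_haplotypes = 0L, spectrum = table(integer())))
  key <- vapply(haps, function(h) {
    v <- filter_variants(h$variants, filter)
    paste(sort(v$token[!v$reversion]), collapse = " ")
  }, "")
  freq <- table(key)
  list(n_haplotypes = length(freq), spectrum = table(as.integer(freq)))
}

#' Per-stratum diversity report
#'
#' @param haps an `mt_cohort`.
#' @param strata named character vector sample_id -> stratum (e.g.
#'   region); `NULL` computes the whole-cohort row only.
#' @param filter a [site_filter()].
#' @param path optional TSV output path.
#' @return `data.frame` with one row per stratum plus `"all"`.
#' @export
diversity_report <- function(haps, strata = NULL,
                             filter = site_filter("stats"), path = NULL) {
  stopifnot(inherits(haps, "mt_cohort"))
  row_of <- function(label, subset) {
    if (length(subset) < 2L) {
      return(data.frame(stratum = label, n = length(subset), L = NA, S = NA,
                        pi = NA, k = NA, Hd = NA, n_haplotypes = NA))
    }
    d <- diversity_stats(subset, filter)
    data.frame(stratum = label, n = d$n, L = d$L, S = d$S, pi = d$pi,
               k = d$k, Hd = d$Hd, n_haplotypes = d$n_haplotypes)
  }
  out <- row_of("all", haps)
  if (!is.null(strata)) {
    ids <- names(haps)
    for (s in sort(unique(strata[ids]))) {
      out <- rbind(out, row_of(s, haps[ids[strata[ids] == s]]))
    }
  }
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
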