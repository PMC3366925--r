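MT_LEN <- 16569L

IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

#' Parse rCRS-relative variant tokens
#'
#' Parses mitochondrial control-region variant notation relative to the
#' revised Cambridge Reference Sequence (rCRS) into a structured table.
#' Recognised forms: transitions (`"16360"`), transversions with an explicit
#' derived base (`"16182C"`), heteroplasmies with an IUPAC ambiguity code
#' (`"152Y"`), insertions (`"309.1C"`, `"309.2C"`), single- and multi-base
#' deletions (`"247d"`, `"106-111d"`; en-dash accepted on input), and a
#' trailing `"@"` marking a reversion (back mutation) on any of these.
#'
#' @param tokens character vector of variant tokens.
#' @return A `data.frame` with one row per token and columns `position`
#'   (1-based rCRS coordinate), `kind` (one of `"transition"`,
#'   `"transversion"`, `"insertion"`, `"deletion"`, `"heteroplasmy"`),
#'   `span_end` (last deleted position; equals `position` otherwise),
#'   `derived_base` (`""` for transitions and deletions), `insert_index`
#'   (the `.1` in `309.1C`; `NA` unless an insertion), `reversion`
#'   (logical), and `token` (the canonical serialised form).
#' @examples
#' parse_variants(c("16360", "106-111d", "309.1C", "64@", "16182C"))
#' @seealso [serialize_variants()]
#' @export
parse_variants <- function(tokens) {
  tokens <- as.character(tokens)
  if (length(tokens) == 0L) return(empty_variants())
  pat <- "^([0-9]+)(?:[-–]([0-9]+))?(?:\\.([0-9]+))?([A-Za-z]+)?(@)?$"
  m <- regmatches(tokens, regexec(pat, tokens))
  bad <- vapply(m, length, 0L) == 0L
  if (any(bad)) {
    stop("malformed variant token(s): ", paste(tokens[bad], collapse = ", "))
  }
  parse1 <- function(g, tok) {
    pos <- as.integer(g[2])
    span <- if (nzchar(g[3])) as.integer(g[3]) else NA_integer_
    idx <- if (nzchar(g[4])) as.integer(g[4]) else NA_integer_
    suff <- toupper(g[5])
    rev <- nzchar(g[6])
    if (pos < 1L || pos > MT_LEN) {
      stop("position outside 1..", MT_LEN, " in token: ", tok)
    }
    if (identical(suff, "D")) {
      if (!is.na(idx)) stop("malformed variant token(s): ", tok)
      span_end <- if (is.na(span)) pos else span
      if (span_end < pos || span_end > MT_LEN) {
        stop("invalid deletion span in token: ", tok)
      }
      return(list(pos, "deletion", span_end, "", NA_integer_, rev))
    }
    if (!is.na(span)) stop("span only valid for deletions: ", tok)
    if (!is.na(idx)) {
      if (!nzchar(suff) || !all(strsplit(suff, "")[[1]] %in% c("A", "C", "G", "T"))) {
        stop("insertion requires inserted base(s): ", tok)
      }
      if (idx < 1L) stop("insertion index must be >= 1: ", tok)
      return(list(pos, "insertion", pos, suff, idx, rev))
    }
    if (nzchar(suff)) {
      if (nchar(suff) != 1L) stop("malformed variant token(s): ", tok)
      if (suff %in% c("A", "C", "G", "T")) {
        return(list(pos, "transversion", pos, suff, NA_integer_, rev))
      }
      if (suff %in% IUPAC_AMBIG) {
        return(list(pos, "heteroplasmy", pos, suff, NA_integer_, rev))
      }
      stop("unrecognised base suffix in token: ", tok)
    }
    list(pos, "transition", pos, "", NA_integer_, rev)
  }
  rows <- mapply(parse1, m, tokens, SIMPLIFY = FALSE)
  out <- data.frame(
    position = vapply(rows, function(r) r[[1]], 0L),
    kind = vapply(rows, function(r) r[[2]], ""),
    span_end = vapply(rows, function(r) r[[3]], 0L),
    derived_base = vapply(rows, function(r) r[[4]], ""),
    insert_index = vapply(rows, function(r) r[[5]], 0L),
    reversion = vapply(rows, function(r) r[[6]], TRUE),
    stringsAsFactors = FALSE
  )
  out$token <- serialize_variants(out)
  out
}

empty_variants <- function() {
  data.frame(
    position = integer(), kind = character(), span_end = integer(),
    derived_base = character(), insert_index = integer(),
    reversion = logical(), token = character(), stringsAsFactors = FALSE
  )
}

#' Serialise variants back to canonical tokens
#'
#' Inverse of [parse_variants()]: emits the canonical token for each row
#' (hyphen for deletion spans, uppercase bases, trailing `@` for
#' reversions), so that `parse_variants(serialize_variants(v))` reproduces
#' `v`.
#'
#' @param v a variant `data.frame` as produced by [parse_variants()].
#' @return character vector of canonical tokens.
#' @export
serialize_variants <- function(v) {
  if (nrow(v) == 0L) return(character())
  core <- character(nrow(v))
  for (i in seq_len(nrow(v))) {
    core[i] <- switch(v$kind[i],
      transition = as.character(v$position[i]),
      transversion = ,
      heteroplasmy = paste0(v$position[i], v$derived_base[i]),
      insertion = paste0(v$position[i], ".", v$insert_index[i], v$derived_base[i]),
      deletion = if (v$span_end[i] > v$position[i]) {
        paste0(v$position[i], "-", v$span_end[i], "d")
      } else {
        paste0(v$position[i], "d")
      },
      stop("unknown variant kind: ", v$kind[i])
    )
  }
  paste0(core, ifelse(v$reversion, "@", ""))
}

#' Site filter profiles for variant sets
#'
#' A filter bundles the positional exclusions and C-stretch rules applied
#' before distance, network and diversity computations. Three profiles are
#' provided. `"network"` mirrors the conventions used for control-region
#' median-joining networks: the mutations 16182C, 16183C, 16194C and 16519
#' are excluded; length variants (insertions/deletions) in the C-stretches
#' 303--315 and 16184--16193 are disregarded; insertions, heteroplasmies
#' and deletions are dropped -- with the exception of the 6-bp deletion at
#' 106--111 which is retained and scored as a single character. `"stats"`
#' keeps substitutions only (transitions and transversions), the
#' convention for nucleotide-diversity summaries where gaps and ambiguous
#' sites are excluded. `"none"` keeps everything.
#'
#' @param profile one of `"network"`, `"stats"`, `"none"`.
#' @param excluded character vector of excluded variant descriptors; a bare
#'   position (e.g. `"16519"`) excludes every variant at that position, a
#'   full token (e.g. `"16182C"`) excludes only that variant.
#' @param cstretch list of length-2 integer vectors: ranges whose length
#'   variants are ignored.
#' @param keep_deletions canonical tokens of deletions retained even when
#'   the profile drops indels.
#' @return an object of class `site_filter`.
#' @export
site_filter <- function(profile = c("network", "stats", "none"),
                        excluded = c("16182C", "16183C", "16194C", "16519"),
                        cstretch = list(c(303L, 315L), c(16184L, 16193L)),
                        keep_deletions = "106-111d") {
  profile <- match.arg(profile)
  structure(
    list(profile = profile, excluded = excluded, cstretch = cstretch,
         keep_deletions = keep_deletions),
    class = "site_filter"
  )
}

#' Apply a site filter to a variant table
#'
#' @param v variant `data.frame` from [parse_variants()].
#' @param filter a [site_filter()].
#' @return the filtered variant `data.frame`.
#' @export
filter_variants <- function(v, filter = site_filter()) {
  stopifnot(inherits(filter, "site_filter"))
  if (nrow(v) == 0L || filter$profile == "none") return(v)
  token_nor <- sub("@$", "", v$token)
  bare <- grepl("^[0-9]+$", filter$excluded)
  drop <- token_nor %in% filter$excluded[!bare] |
    v$position %in% as.integer(filter$excluded[bare])
  # length variants inside C-stretch ranges
  is_indel <- v$kind %in% c("insertion", "deletion")
  for (rng in filter$cstretch) {
    drop <- drop | (is_indel & v$position >= rng[1] & v$span_end <= rng[2])
  }
  if (filter$profile == "network") {
    drop <- drop | v$kind == "insertion" | v$kind == "heteroplasmy"
    drop <- drop | (v$kind == "deletion" & !(token_nor %in% filter$keep_deletions))
  } else if (filter$profile == "stats") {
    drop <- drop | !(v$kind %in% c("transition", "transversion"))
  }
  v[!drop, , drop = FALSE]
}

#' Circular rCRS intervals
#'
#' mtDNA is circular; the control region wraps the origin, so the default
#' sequenced range runs from np 16000 through np 16569/1 to np 580.
#' `in_circular_range()` tests membership of 1-based positions in a closed
#' circular interval.
#'
#' @param pos integer vector of rCRS positions.
#' @param range length-2 integer vector `c(start, end)`; `start > end`
#'   denotes a wrap through the origin.
#' @return logical vector.
#' @export
in_circular_range <- function(pos, range = c(16000L, 580L)) {
  s <- range[1]; e <- range[2]
  if (s <= e) pos >= s & pos <= e else pos >= s | pos <= e
}

circular_ranges_overlap <- function(r1, r2) {
  probe <- function(r) {
    if (r[1] <= r[2]) seq.int(r[1], r[2]) else c(seq.int(r[1], MT_LEN), seq.int(1L, r[2]))
  }
  any(probe(r1) %in% probe(r2))
}

circular_range_intersection_length <- function(r1, r2) {
  probe <- function(r) {
    if (r[1] <= r[2]) seq.int(r[1], r[2]) else c(seq.int(r[1], MT_LEN), seq.int(1L, r[2]))
  }
  length(intersect(probe(r1), probe(r2)))
}

#' Construct a haplotype
#'
#' A haplotype is a sample's set of rCRS-relative variants over a declared
#' sequenced range, plus collection metadata.
#'
#' @param sample_id sample identifier.
#' @param variants character vector of variant tokens, or a parsed variant
#'   `data.frame`.
#' @param covered_range circular rCRS interval actually sequenced; the
#'   default 16000--580 covers the whole control region.
#' @param region collection province or comarca label.
#' @param tma_origin country/region of the terminal maternal ancestor.
#' @param haplogroup optional haplogroup call.
#' @return an object of class `mt_haplotype`.
#' @export
haplotype <- function(sample_id, variants = character(),
                      covered_range = c(16000L, 580L),
                      region = NA_character_, tma_origin = NA_character_,
                      haplogroup = NA_character_) {
  v <- if (is.data.frame(variants)) variants else parse_variants(variants)
  key <- paste(v$position, v$kind, v$insert_index, sep = "/")
  if (anyDuplicated(key)) {
    stop("duplicate variant entries in sample ", sample_id, ": ",
         paste(v$token[duplicated(key)], collapse = ", "))
  }
  out_of_range <- !in_circular_range(v$position, covered_range)
  if (any(out_of_range)) {
    stop("variant(s) outside covered_range in sample ", sample_id, ": ",
         paste(v$token[out_of_range], collapse = ", "))
  }
  structure(
    list(sample_id = sample_id, variants = v, covered_range = covered_range,
         region = region, tma_origin = tma_origin, haplogroup = haplogroup),
    class = "mt_haplotype"
  )
}

#' @export
print.mt_haplotype <- function(x, ...) {
  cat("<mt_haplotype> ", x$sample_id,
      if (!is.na(x$region)) paste0(" [", x$region, "]"), "\n", sep = "")
  cat("  range ", x$covered_range[1], "-", x$covered_range[2],
      ", ", nrow(x$variants), " variants: ",
      paste(x$variants$token, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Mutational distance between two haplotypes
#'
#' Counts the symmetric difference of the two filtered variant sets,
#' restricted to the shared covered range. Under the `"network"` profile
#' insertions, heteroplasmies and deletions are excluded -- except the 6-bp
#' deletion at 106--111, which counts as exactly one character. Reversion
#' tokens (`"@"`) denote the reference state and contribute no difference.
#'
#' @param a,b `mt_haplotype` objects with overlapping covered ranges.
#' @param filter a [site_filter()].
#' @return non-negative integer count.
#' @export
haplotype_distance <- function(a, b, filter = site_filter("network")) {
  stopifnot(inherits(a, "mt_haplotype"), inherits(b, "mt_haplotype"))
  if (!circular_ranges_overlap(a$covered_range, b$covered_range)) {
    stop("haplotypes have disjoint covered ranges")
  }
  ta <- distance_tokens(a, filter, b$covered_range)
  tb <- distance_tokens(b, filter, a$covered_range)
  length(setdiff(ta, tb)) + length(setdiff(tb, ta))
}

distance_tokens <- function(h, filter, other_range) {
  v <- filter_variants(h$variants, filter)
  v <- v[!v$reversion, , drop = FALSE]  # reversion = reference state
  v <- v[in_circular_range(v$position, h$covered_range) &
           in_circular_range(v$position, other_range), , drop = FALSE]
  v$token
}
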