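#' Reference mtDNA sequence
#'
#' Container for a 16,569-bp reference mitochondrial sequence with 1-based
#' circular numbering, against which variants are named (the rCRS
#' convention). Users supply the actual rCRS via [read_reference()];
#' [synthetic_reference()] generates a random stand-in of the correct
#' length for simulations and tests.
#'
#' @param id sequence identifier.
#' @param bases single character string of A/C/G/T/N.
#' @param partial allow lengths other than 16,569 (toy sequences).
#' @return an object of class `mt_reference`.
#' @export
mt_reference <- function(id, bases, partial = FALSE) {
  bases <- toupper(bases)
  if (!partial && nchar(bases) != MT_LEN) {
    stop("reference must be exactly ", MT_LEN, " bp (got ", nchar(bases), ")")
  }
  if (grepl("[^ACGTN]", bases)) stop("reference alphabet must be A/C/G/T/N")
  structure(list(id = id, bases = bases), class = "mt_reference")
}

#' @export
print.mt_reference <- function(x, ...) {
  cat("<mt_reference> ", x$id, " (", nchar(x$bases), " bp)\n", sep = "")
  invisible(x)
}

#' @rdname mt_reference
#' @param path FASTA file containing one sequence.
#' @export
read_reference <- function(path, partial = FALSE) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) != 1L) stop("reference FASTA must contain exactly one sequence")
  mt_reference(names(ss)[1], as.character(ss[[1]]), partial = partial)
}

#' @rdname mt_reference
#' @param seed integer seed for the random stand-in.
#' @export
synthetic_reference <- function(seed = 1L) {
  set.seed(seed)
  b <- sample(c("A", "C", "G", "T"), MT_LEN, replace = TRUE,
              prob = c(0.31, 0.31, 0.13, 0.25))
  mt_reference("synthetic-mt-reference", paste(b, collapse = ""))
}

ref_base <- function(ref, pos) substring(ref$bases, pos, pos)

is_transition <- function(a, b) {
  (a %in% c("A", "G") & b %in% c("A", "G")) |
    (a %in% c("C", "T") & b %in% c("C", "T"))
}

#' Call rCRS-relative variants from a sequence
#'
#' Compares a query sequence with the reference and emits variants in
#' control-region notation: bare positions for transitions, position+base
#' for transversions, IUPAC codes for mixed (heteroplasmic) positions,
#' `.k`-indexed insertions and `d`-suffixed deletions. Indels inside
#' repeats are placed 3'-most, the usual mtDNA nomenclature convention.
#'
#' @param query query DNA as a character string; if `aligned = TRUE` it
#'   must be the same length as the (gapped) reference string, with gaps
#'   as `"-"`.
#' @param ref an [mt_reference()]; when `aligned = TRUE`, `ref_aligned`
#'   supplies the gapped reference row of the alignment (defaults to the
#'   ungapped reference, i.e. no insertions).
#' @param aligned is the query already aligned to the reference?
#' @param ref_aligned gapped reference string (only with `aligned = TRUE`).
#' @param max_divergence abort if the aligned difference fraction exceeds
#'   this (guards against aligning non-homologous input).
#' @return variant `data.frame` as from [parse_variants()].
#' @export
call_variants <- function(query, ref, aligned = FALSE, ref_aligned = NULL,
                          max_divergence = 0.1) {
  query <- toupper(query)
  if (!aligned) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(query), Biostrings::DNAString(ref$bases),
      type = "global", gapOpening = 10, gapExtension = 0.5
    )
    qa <- as.character(Biostrings::alignedPattern(pa))
    ra <- as.character(Biostrings::alignedSubject(pa))
  } else {
    qa <- query
    ra <- if (is.null(ref_aligned)) ref$bases else toupper(ref_aligned)
    if (nchar(qa) != nchar(ra)) stop("aligned query/reference lengths differ")
  }
  qv <- strsplit(qa, "")[[1]]
  rv <- strsplit(ra, "")[[1]]
  ndiff <- sum(qv != rv)
  if (ndiff / length(rv) > max_divergence) {
    stop("alignment divergence ", round(ndiff / length(rv), 3),
         " exceeds ", max_divergence, "; pre-align the input and use aligned = TRUE")
  }
  refpos <- cumsum(rv != "-")  # rCRS coordinate of each alignment column
  tokens <- character()

  # substitutions
  sub_cols <- which(rv != "-" & qv != "-" & rv != qv & qv != "N")
  for (i in sub_cols) {
    p <- refpos[i]
    if (qv[i] %in% c("A", "C", "G", "T")) {
      tokens <- c(tokens, if (is_transition(rv[i], qv[i])) as.character(p)
                  else paste0(p, qv[i]))
    } else if (qv[i] %in% IUPAC_AMBIG) {
      tokens <- c(tokens, paste0(p, qv[i]))
    }
  }

  # deletions (runs of query gaps), shifted 3'-most within repeats
  rfull <- strsplit(ref$bases, "")[[1]]
  del_runs <- run_ranges(which(qv == "-" & rv != "-"))
  for (r in del_runs) {
    s <- refpos[r[1]]; e <- refpos[r[2]]
    while (e < length(rfull) && rfull[e + 1L] == rfull[s]) { s <- s + 1L; e <- e + 1L }
    tokens <- c(tokens, if (e > s) paste0(s, "-", e, "d") else paste0(s, "d"))
  }

  # insertions (runs of reference gaps), anchored after preceding ref base
  ins_runs <- run_ranges(which(rv == "-" & qv != "-"))
  for (r in ins_runs) {
    anchor <- if (r[1] == 1L) 0L else refpos[r[1] - 1L]
    bases <- qv[r[1]:r[2]]
    while (anchor < length(rfull) && rfull[anchor + 1L] == bases[1]) {
      anchor <- anchor + 1L
      bases <- c(bases[-1], bases[1])
    }
    tokens <- c(tokens, paste0(anchor, ".", seq_along(bases), bases))
  }

  parse_variants(tokens)
}

run_ranges <- function(idx) {
  if (length(idx) == 0L) return(list())
  brk <- c(0L, which(diff(idx) != 1L), length(idx))
  lapply(seq_len(length(brk) - 1L), function(k) {
    c(idx[brk[k] + 1L], idx[brk[k + 1L]])
  })
}

#' Reconstruct a sequence from a reference and variant set
#'
#' Applies substitutions, deletions and insertions to the reference; the
#' inverse of [call_variants()] for round-trip checks and simulation.
#' Reversion tokens are skipped (they denote the reference state).
#'
#' @param ref an [mt_reference()].
#' @param v variant `data.frame`.
#' @return character string.
#' @export
apply_variants <- function(ref, v) {
  bases <- strsplit(ref$bases, "")[[1]]
  v <- v[!v$reversion, , drop = FALSE]
  ins <- list()
  for (i in seq_len(nrow(v))) {
    p <- v$position[i]
    switch(v$kind[i],
      transition = {
        bases[p] <- c(A = "G", G = "A", C = "T", T = "C")[[bases[p]]]
      },
      transversion = ,
      heteroplasmy = { bases[p] <- v$derived_base[i] },
      deletion = { bases[v$position[i]:v$span_end[i]] <- "" },
      insertion = {
        key <- as.character(p)
        cur <- if (is.null(ins[[key]])) character() else ins[[key]]
        cur[v$insert_index[i]] <- v$derived_base[i]
        ins[[key]] <- cur
      }
    )
  }
  for (key in names(ins)) {
    p <- as.integer(key)
    bases[p] <- paste0(bases[p], paste(ins[[key]], collapse = ""))
  }
  paste(bases, collapse = "")
}
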