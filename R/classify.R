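#' Haplogroup tree with defining motifs
#'
#' A rooted, labelled tree whose edges carry the mutation motif defining
#' each child haplogroup. The root is a reference node (the rCRS itself, or
#' an internal haplogroup such as A2 when only its sub-clades are of
#' interest) and carries no motif. Reversion entries (`"64@"`) on an edge
#' mean the sample must *lack* the corresponding rCRS-relative variant.
#'
#' @param labels character vector of node labels (unique).
#' @param parents parent label per node; `NA` for the root.
#' @param motifs list of character vectors of variant tokens per node;
#'   must be non-empty except at the root.
#' @return an object of class `haplogroup_tree`.
#' @export
haplogroup_tree <- function(labels, parents, motifs) {
  stopifnot(length(labels) == length(parents), length(labels) == length(motifs))
  if (anyDuplicated(labels)) stop("duplicate haplogroup labels")
  root <- labels[is.na(parents)]
  if (length(root) != 1L) stop("tree must have exactly one root")
  unknown <- setdiff(parents[!is.na(parents)], labels)
  if (length(unknown)) stop("unknown parent label(s): ",
                            paste(unknown, collapse = ", "))
  for (i in seq_along(labels)) {
    if (!is.na(parents[i]) && length(motifs[[i]]) == 0L) {
      stop("empty edge motif for ", labels[i])
    }
    parse_variants(motifs[[i]])  # validates tokens
  }
  structure(
    list(labels = labels, parents = setNames(parents, labels),
         motifs = setNames(motifs, labels), root = root),
    class = "haplogroup_tree"
  )
}

#' @export
print.haplogroup_tree <- function(x, ...) {
  cat("<haplogroup_tree> ", length(x$labels), " nodes, root ", x$root, "\n",
      sep = "")
  invisible(x)
}

tree_depth <- function(tree, label) {
  d <- 0L
  while (!is.na(tree$parents[[label]])) {
    label <- tree$parents[[label]]
    d <- d + 1L
  }
  d
}

tree_path <- function(tree, label) {
  path <- character()
  while (!is.na(label)) {
    path <- c(label, path)
    label <- tree$parents[[label]]
  }
  path
}

#' Read / write haplogroup tree files
#'
#' Plain-text format: one node per line, nesting by two-space indentation,
#' `label: token token ...` (the root line may omit tokens). Tokens are
#' validated with [parse_variants()].
#'
#' @param path file path.
#' @return a [haplogroup_tree()].
#' @export
read_haplogroup_tree <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  indent <- nchar(sub("\\S.*$", "", lines))
  if (any(indent %% 2L != 0L)) stop("indentation must be multiples of two spaces")
  depth <- indent %/% 2L
  labels <- character(); parents <- character(); motifs <- list()
  stack <- character()
  for (i in seq_along(lines)) {
    body <- trimws(lines[i])
    parts <- strsplit(body, ":", fixed = TRUE)[[1]]
    lab <- trimws(parts[1])
    toks <- if (length(parts) > 1L) {
      t <- strsplit(trimws(parts[2]), "[ ,]+")[[1]]
      t[nzchar(t)]
    } else character()
    if (depth[i] > length(stack)) stop("indentation jump at line: ", body)
    stack <- c(stack[seq_len(depth[i])], lab)
    labels <- c(labels, lab)
    parents <- c(parents, if (depth[i] == 0L) NA_character_ else stack[depth[i]])
    motifs <- c(motifs, list(toks))
  }
  haplogroup_tree(labels, parents, motifs)
}

#' @rdname read_haplogroup_tree
#' @param tree a `haplogroup_tree`.
#' @export
write_haplogroup_tree <- function(tree, path) {
  order <- tree_preorder(tree)
  lines <- vapply(order, function(lab) {
    ind <- strrep("  ", tree_depth(tree, lab))
    toks <- paste(tree$motifs[[lab]], collapse = " ")
    paste0(ind, lab, if (nzchar(toks)) paste0(": ", toks) else "")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

tree_preorder <- function(tree) {
  out <- character()
  visit <- function(lab) {
    out <<- c(out, lab)
    kids <- sort(tree$labels[!is.na(tree$parents) & tree$parents == lab])
    for (k in kids) visit(k)
  }
  visit(tree$root)
  out
}

#' Bundled A2 sub-clade fixture tree
#'
#' The A2-rooted tree of the Panamanian/Chibchan A2 sub-clades: A2af
#' (basal motif 73@, the 6-bp "Huetar" deletion 106-111d, 5460, 16360),
#' its major branch A2af1 (64@, 6794, 7960) with sub-branches A2af1a
#' (89) and A2af1b (11482), and A2ad (control-region motif 16175, 16300).
#'
#' @return a [haplogroup_tree()].
#' @export
a2_fixture_tree <- function() {
  read_haplogroup_tree(
    system.file("extdata", "a2_haplogroup_tree.txt", package = "panmito")
  )
}

#' Classify a haplotype on a haplogroup tree
#'
#' Best-path motif matching: for each node, the expected state of every
#' motif entry on the root-to-node path is computed (a reversion entry
#' flips the expectation back to the reference state), entries lying
#' outside the haplotype's covered range are unobservable and excluded
#' from both the matched and expected counts, and the score is
#' matched/expected (1 when nothing is expected). The call is the deepest
#' node maximising the score, tie-broken by greater depth, fewer private
#' mutations, then lexicographic label; nodes scoring below
#' `demote_below` are demoted to their parent.
#'
#' @param h an [haplotype()].
#' @param tree a [haplogroup_tree()].
#' @param filter a [site_filter()] applied to the sample's variants before
#'   counting private mutations (motif matching always sees the full set).
#' @param demote_below score threshold below which a call falls back to
#'   its parent (default 1: all observable expected mutations must match).
#' @return a one-row `data.frame`: `sample_id`, `haplogroup`, `matched`,
#'   `expected`, `private`, `score`.
#' @export
classify <- function(h, tree, filter = site_filter("none"), demote_below = 1) {
  stopifnot(inherits(h, "mt_haplotype"), inherits(tree, "haplogroup_tree"))
  if (length(tree$labels) == 0L) stop("empty haplogroup tree")
  idx <- tree_index(tree)
  classify_one(h, tree, idx, filter, demote_below)
}

# Precompute, per node: the root-to-node path, the net expected state per
# motif key (a reversion flips the expectation back to the reference
# state), and per-edge positive (non-reversion) entries used for the
# descent-eligibility check.
tree_index <- function(tree) {
  parsed <- lapply(tree$motifs, parse_variants)
  edge_positive <- lapply(parsed, function(ev) {
    ev <- ev[!ev$reversion, , drop = FALSE]
    list(tokens = ev$token, pos = ev$position)
  })
  nodes <- lapply(tree$labels, function(lab) {
    path <- tree_path(tree, lab)
    ev <- do.call(rbind, parsed[path])
    if (is.null(ev) || nrow(ev) == 0L) {
      return(list(path = path, depth = length(path) - 1L,
                  keys = character(), key_pos = integer(), expect = logical()))
    }
    key <- sub("@$", "", ev$token)
    net <- tapply(ifelse(ev$reversion, -1L, 1L), key, sum)
    keys <- names(net)
    list(path = path, depth = length(path) - 1L,
         keys = keys,
         key_pos = ev$position[match(keys, key)],
         expect = as.vector(net > 0))  # TRUE = variant expected present
  })
  names(nodes) <- tree$labels
  list(nodes = nodes, edge_positive = edge_positive)
}

classify_one <- function(h, tree, idx, filter, demote_below) {
  sample_tokens <- sub("@$", "", h$variants$token[!h$variants$reversion])
  # literal reversion tokens in the data denote the reference state
  revoked <- sub("@$", "", h$variants$token[h$variants$reversion])
  sample_tokens <- setdiff(sample_tokens, revoked)
  filt <- filter_variants(h$variants, filter)
  filt_tokens <- setdiff(sub("@$", "", filt$token[!filt$reversion]), revoked)

  n <- length(tree$labels)
  score <- numeric(n); depth <- integer(n); priv <- integer(n)
  matched_v <- integer(n); expected_v <- integer(n); elig <- logical(n)
  for (i in seq_len(n)) {
    nd <- idx$nodes[[tree$labels[i]]]
    # a call may only descend through edges carrying positive evidence:
    # at least one observable, non-reversion motif entry present in the
    # sample (reversion-only or fully unobservable edges are vacuous)
    ok <- TRUE
    for (edge_lab in setdiff(nd$path, tree$root)) {
      ep <- idx$edge_positive[[edge_lab]]
      vis <- in_circular_range(ep$pos, h$covered_range)
      if (!any(vis & ep$tokens %in% sample_tokens)) { ok <- FALSE; break }
    }
    elig[i] <- ok
    observable <- in_circular_range(nd$key_pos, h$covered_range)
    keys <- nd$keys[observable]
    expect <- nd$expect[observable]
    hit <- keys %in% sample_tokens
    matched_v[i] <- sum(hit == expect)
    expected_v[i] <- length(keys)
    score[i] <- if (length(keys) == 0L) 1 else matched_v[i] / expected_v[i]
    depth[i] <- nd$depth
    priv[i] <- length(setdiff(filt_tokens, keys[expect]))
  }
  cand <- which(elig)
  ord <- cand[order(-score[cand], -depth[cand], priv[cand], tree$labels[cand])]
  lab <- tree$labels[ord[1]]
  # demotion: walk up while below threshold
  while (score[match(lab, tree$labels)] < demote_below &&
         !is.na(tree$parents[[lab]])) {
    lab <- tree$parents[[lab]]
  }
  i <- match(lab, tree$labels)
  data.frame(
    sample_id = h$sample_id, haplogroup = lab,
    matched = matched_v[i], expected = expected_v[i],
    private = priv[i], score = score[i],
    stringsAsFactors = FALSE
  )
}

#' @rdname classify
#' @param x an `mt_cohort`.
#' @export
classify_cohort <- function(x, tree, filter = site_filter("none"),
                            demote_below = 1) {
  stopifnot(inherits(x, "mt_cohort"))
  idx <- tree_index(tree)
  out <- do.call(rbind, lapply(x, classify_one, tree = tree, idx = idx,
                               filter = filter, demote_below = demote_below))
  rownames(out) <- NULL
  out$region <- vapply(x, function(h) h$region, "")
  out
}
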