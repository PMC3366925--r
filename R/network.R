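#' Binary character matrix from haplotypes
#'
#' Reduces a set of haplotypes to the binary presence/absence matrix of
#' their filtered variants, merging identical rows with multiplicities
#' (the circle sizes of a haplotype network) and keeping per-character
#' integer weights. Under the default `"network"` filter insertions,
#' heteroplasmies and deletions are excluded, with the exception of the
#' 6-bp deletion at 106--111 which is encoded as a single character.
#'
#' @param haps an `mt_cohort` or list of [haplotype()] objects.
#' @param filter a [site_filter()].
#' @param weights optional named integer vector of per-character weights
#'   (names = variant tokens); default 1 for every character.
#' @param drop_invariant drop characters present in all or none of the
#'   haplotypes.
#' @return an object of class `char_matrix`: list with binary `matrix`
#'   (taxa x characters), `taxa` ids, `multiplicity`, `members` (sample
#'   ids per taxon), `regions` (region count vector per taxon) and
#'   `weights`.
#' @export
build_character_matrix <- function(haps, filter = site_filter("network"),
                                   weights = NULL, drop_invariant = TRUE) {
  if (inherits(haps, "mt_cohort")) haps <- unclass(haps)
  if (length(haps) == 0L) stop("no haplotypes supplied")
  tok_sets <- lapply(haps, function(h) {
    v <- filter_variants(h$variants, filter)
    sort(v$token[!v$reversion])
  })
  ids <- vapply(haps, function(h) h$sample_id, "")
  regs <- vapply(haps, function(h) h$region, "")
  chars <- sort(unique(unlist(tok_sets)))
  M <- t(vapply(tok_sets, function(s) as.integer(chars %in% s),
                integer(length(chars))))
  colnames(M) <- chars
  if (drop_invariant && ncol(M) > 0L) {
    keep <- colSums(M) > 0L & colSums(M) < nrow(M)
    M <- M[, keep, drop = FALSE]
  }
  key <- apply(M, 1L, paste, collapse = "")
  grp <- split(seq_along(key), key)
  # deterministic taxon order: by first occurrence
  grp <- grp[order(vapply(grp, min, 0L))]
  Mu <- M[vapply(grp, `[`, 0L, 1L), , drop = FALSE]
  taxa <- vapply(grp, function(g) ids[g[1]], "")
  rownames(Mu) <- taxa
  w <- setNames(rep(1L, ncol(Mu)), colnames(Mu))
  if (!is.null(weights)) {
    hit <- intersect(names(weights), names(w))
    w[hit] <- as.integer(weights[hit])
    if (any(w < 1L)) stop("character weights must be positive integers")
  }
  structure(
    list(matrix = Mu, taxa = taxa,
         multiplicity = setNames(vapply(grp, length, 0L), taxa),
         members = setNames(lapply(grp, function(g) ids[g]), taxa),
         regions = setNames(lapply(grp, function(g) table(regs[g])), taxa),
         weights = w),
    class = "char_matrix"
  )
}

#' @export
print.char_matrix <- function(x, ...) {
  cat("<char_matrix> ", nrow(x$matrix), " taxa (",
      sum(x$multiplicity), " samples), ", ncol(x$matrix),
      " characters\n", sep = "")
  invisible(x)
}

weighted_hamming <- function(M, w) {
  n <- nrow(M)
  D <- matrix(0, n, n)
  if (ncol(M) > 0L) {
    for (j in seq_len(ncol(M))) {
      d <- outer(M[, j], M[, j], `!=`)
      D <- D + w[j] * d
    }
  }
  D
}

# Minimum spanning network: edge (u,v) is included iff
# d(u,v) <= bottleneck(u,v) + epsilon, where bottleneck is the minimax
# path distance (largest edge on the MST path between u and v).
msn_edges <- function(D, epsilon = 0) {
  n <- nrow(D)
  if (n == 1L) return(cbind(i = integer(), j = integer()))
  g <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  mst <- igraph::mst(g, algorithm = "prim")
  # bottleneck (minimax-path) distances by single-linkage merging of the
  # MST edges in ascending weight order
  B <- matrix(0, n, n)
  comp <- as.list(seq_len(n))
  comp_of <- seq_len(n)
  me <- igraph::as_edgelist(mst, names = FALSE)
  mw <- igraph::E(mst)$weight
  for (k in order(mw)) {
    a <- comp_of[me[k, 1]]; b <- comp_of[me[k, 2]]
    if (a == b) next
    B[comp[[a]], comp[[b]]] <- mw[k]
    B[comp[[b]], comp[[a]]] <- mw[k]
    comp[[a]] <- c(comp[[a]], comp[[b]])
    comp_of[comp[[b]]] <- a
    comp[[b]] <- integer()
  }
  idx <- which(upper.tri(D) & D <= B + epsilon, arr.ind = TRUE)
  cbind(i = idx[, 1], j = idx[, 2])
}

#' Median-joining network
#'
#' Builds the median-joining network of a binary character matrix:
#' iteratively computes the minimum spanning network within the `epsilon`
#' tolerance, adds the quasi-median (majority state per character) of
#' every mutually linked triplet, prunes sequenceless median vectors with
#' fewer than three links, and repeats to a fixpoint. The resulting
#' network contains a minimum spanning tree of the observed taxa.
#'
#' @param cm a [build_character_matrix()] result.
#' @param epsilon non-negative weighted tolerance above the minimum
#'   spanning connection cost (default 0).
#' @param max_iter safety cap on the median-addition rounds.
#' @return an object of class `hap_network`: list with `graph` (an
#'   `igraph` whose edges carry `weight` and mutation-token `label`
#'   attributes), `nodes` data frame (`id`, `type`, `multiplicity`),
#'   `matrix` (node x character states), and the input `cm`.
#' @export
median_joining <- function(cm, epsilon = 0, max_iter = 50L) {
  stopifnot(inherits(cm, "char_matrix"), epsilon >= 0)
  M <- cm$matrix
  if (!all(M %in% c(0L, 1L))) stop("characters must be binary")
  w <- cm$weights
  type <- rep("observed", nrow(M))
  D <- weighted_hamming(M, w)
  # distances of new rows against the current node set, and among themselves
  extend_D <- function(D, M, New) {
    Nw <- sweep(New, 2L, w, `*`)
    cross <- Nw %*% t(1 - M) + sweep(1 - New, 2L, w, `*`) %*% t(M)
    self <- weighted_hamming(New, w)
    rbind(cbind(D, t(cross)), cbind(cross, self))
  }
  median_counter <- 0L
  repeat_count <- 0L
  repeat {
    repeat_count <- repeat_count + 1L
    E <- msn_edges(D, epsilon)
    # quasi-medians of mutually linked triplets (triangles of the MSN);
    # among the candidates only those within epsilon of the minimal
    # connection cost (the summed distance of the median to its
    # generating triplet) are added in this round
    new_rows <- NULL
    if (nrow(M) >= 3L && nrow(E) >= 3L) {
      gm <- igraph::make_empty_graph(n = nrow(M), directed = FALSE)
      gm <- igraph::add_edges(gm, t(E))
      tri <- matrix(as.integer(igraph::triangles(gm)), nrow = 3L)
      have <- apply(M, 1L, paste, collapse = "")
      cand <- list()
      cost <- numeric()
      for (k in seq_len(ncol(tri))) {
        sub <- M[tri[, k], , drop = FALSE]
        med <- as.integer(colSums(sub) >= 2L)
        key <- paste(med, collapse = "")
        if (key %in% have) next
        cc <- sum(w * (sub[1, ] != med)) + sum(w * (sub[2, ] != med)) +
          sum(w * (sub[3, ] != med))
        if (is.na(cost[key]) || cc < cost[key]) cost[key] <- cc
        cand[[key]] <- med
      }
      if (length(cand)) {
        keep <- names(cand)[cost[names(cand)] <= min(cost) + epsilon]
        new_rows <- do.call(rbind, cand[keep])
      }
    }
    changed <- FALSE
    if (!is.null(new_rows) && nrow(new_rows) > 0L) {
      rownames(new_rows) <- paste0("mv", median_counter + seq_len(nrow(new_rows)))
      median_counter <- median_counter + nrow(new_rows)
      D <- extend_D(D, M, new_rows)
      M <- rbind(M, new_rows)
      type <- c(type, rep("median", nrow(new_rows)))
      changed <- TRUE
    }
    # prune sequenceless nodes with < 3 links (cascade until stable)
    repeat {
      E <- msn_edges(D, epsilon)
      deg <- tabulate(c(E[, 1], E[, 2]), nbins = nrow(M))
      obsolete <- which(type == "median" & deg < 3L)
      if (length(obsolete) == 0L) break
      M <- M[-obsolete, , drop = FALSE]
      D <- D[-obsolete, -obsolete, drop = FALSE]
      type <- type[-obsolete]
      changed <- TRUE
    }
    if (!changed || repeat_count >= max_iter) break
  }
  # final cleanup: a median vector is superfluous unless it lies exactly
  # between some pair of observed haplotypes (it can then be threaded
  # into a minimum spanning tree at no extra cost); betweenness only
  # involves observed nodes, so one pass suffices, followed by the
  # degree-rule cascade
  obs_idx <- which(type == "observed")
  med_idx <- which(type == "median")
  if (length(med_idx) > 0L) {
    D_obs <- D[obs_idx, obs_idx, drop = FALSE]
    ut <- upper.tri(D_obs)
    between <- vapply(med_idx, function(m) {
      a <- D[obs_idx, m]
      any((outer(a, a, `+`) - D_obs)[ut] == 0)
    }, TRUE)
    drop_idx <- med_idx[!between]
    if (length(drop_idx) > 0L) {
      M <- M[-drop_idx, , drop = FALSE]
      D <- D[-drop_idx, -drop_idx, drop = FALSE]
      type <- type[-drop_idx]
    }
    repeat {
      E <- msn_edges(D, epsilon)
      deg <- tabulate(c(E[, 1], E[, 2]), nbins = nrow(M))
      obsolete <- which(type == "median" & deg < 3L)
      if (length(obsolete) == 0L) break
      M <- M[-obsolete, , drop = FALSE]
      D <- D[-obsolete, -obsolete, drop = FALSE]
      type <- type[-obsolete]
    }
  }
  E <- msn_edges(D, epsilon)
  ids <- rownames(M)
  g <- igraph::make_empty_graph(n = nrow(M), directed = FALSE)
  igraph::V(g)$name <- ids
  igraph::V(g)$type <- type
  igraph::V(g)$multiplicity <- ifelse(type == "observed",
                                      cm$multiplicity[ids], 0L)
  if (nrow(E) > 0L) {
    g <- igraph::add_edges(g, t(E))
    igraph::E(g)$weight <- D[E]
    igraph::E(g)$label <- vapply(seq_len(nrow(E)), function(k) {
      diffc <- colnames(M)[M[E[k, 1], ] != M[E[k, 2], ]]
      paste(diffc, collapse = " ")
    }, "")
  }
  structure(
    list(graph = g,
         nodes = data.frame(id = ids, type = type,
                            multiplicity = igraph::V(g)$multiplicity,
                            stringsAsFactors = FALSE),
         matrix = M, cm = cm, epsilon = epsilon),
    class = "hap_network"
  )
}

#' @export
print.hap_network <- function(x, ...) {
  cat("<hap_network> ", sum(x$nodes$type == "observed"), " observed + ",
      sum(x$nodes$type == "median"), " median nodes, ",
      igraph::ecount(x$graph), " links (epsilon = ", x$epsilon, ")\n", sep = "")
  invisible(x)
}

#' Date network nodes with a mutation clock
#'
#' Computes the rho statistic over the network: the multiplicity-weighted
#' mean weighted-mutation distance (shortest path) from the chosen root
#' node to every observed haplotype, converted to years with the supplied
#' clock.
#'
#' @param net a [median_joining()] network.
#' @param root node id to treat as the ancestral haplotype.
#' @param clock a [clock_config()].
#' @param scale which calibration to use, `"control_region"` (the usual
#'   choice for control-region networks) or `"whole_molecule"`.
#' @return an `age_estimate` (see [rho_sigma()]) with `sigma = NA`
#'   (the network carries no genealogy; use [rho_sigma()] on a resolved
#'   tree for the heuristic standard error).
#' @export
network_node_ages <- function(net, root, clock = clock_config(),
                              scale = c("control_region", "whole_molecule")) {
  stopifnot(inherits(net, "hap_network"))
  scale <- match.arg(scale)
  if (!root %in% net$nodes$id) stop("root '", root, "' is not a network node")
  obs <- net$nodes$id[net$nodes$type == "observed"]
  d <- igraph::distances(net$graph, v = root, to = obs)
  mult <- net$nodes$multiplicity[match(obs, net$nodes$id)]
  rho <- sum(d * mult) / sum(mult)
  est <- age_estimate(rho = rho, sigma = NA_real_, method = "rho")
  to_years(est, clock, scale)
}

#' Export a haplotype network
#'
#' Writes the network in GML or DOT format (edge labels = mutation
#' tokens) and optionally a CSV node table (id, type, multiplicity,
#' region counts).
#'
#' @param net a [median_joining()] network.
#' @param path output file; format chosen by extension `.gml` or `.dot`.
#' @param node_table optional CSV path for the node table.
#' @export
write_network <- function(net, path, node_table = NULL) {
  stopifnot(inherits(net, "hap_network"))
  fmt <- if (grepl("\\.gml$", path)) "gml" else if (grepl("\\.dot$", path))
    "dot" else stop("path must end in .gml or .dot")
  igraph::write_graph(net$graph, path, format = fmt)
  if (fmt == "gml") {
    # drop the timestamped Creator header so outputs are reproducible
    lines <- readLines(path)
    writeLines(lines[!startsWith(lines, "Creator")], path)
  }
  if (!is.null(node_table)) {
    reg <- net$cm$regions
    tab <- net$nodes
    tab$regions <- vapply(tab$id, function(id) {
      r <- reg[[id]]
      if (is.null(r)) "" else paste(sprintf("%s:%d", names(r), r), collapse = ";")
    }, "")
    utils::write.csv(tab, node_table, row.names = FALSE)
  }
  invisible(path)
}
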