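# shared builders and independent oracles

mk_hap <- function(id, tokens, range = c(16000L, 580L), region = "R1") {
  haplotype(id, tokens, covered_range = range, region = region)
}

# a char_matrix built directly from a binary matrix (taxa x characters)
mk_cm <- function(M, multiplicity = NULL, weights = NULL) {
  if (is.null(rownames(M))) rownames(M) <- paste0("t", seq_len(nrow(M)))
  if (is.null(colnames(M)) && ncol(M) > 0L) {
    colnames(M) <- paste0("16", 100 + seq_len(ncol(M)))
  }
  taxa <- rownames(M)
  if (is.null(multiplicity)) multiplicity <- stats::setNames(rep(1L, nrow(M)), taxa)
  if (is.null(weights)) weights <- stats::setNames(rep(1L, ncol(M)), colnames(M))
  structure(
    list(matrix = M, taxa = taxa, multiplicity = multiplicity,
         members = stats::setNames(as.list(taxa), taxa),
         regions = stats::setNames(rep(list(table(character())), nrow(M)), taxa),
         weights = weights),
    class = "char_matrix"
  )
}

# all rooted binary topologies on n labelled leaves, as newick strings
# without branch lengths (recursive leaf insertion; (2n-3)!! trees)
enumerate_rooted_topologies <- function(n) {
  stopifnot(n >= 2L)
  trees <- list(list("t1", "t2"))
  if (n == 2L) return(vapply(trees, nested_to_newick, ""))
  for (k in 3L:n) {
    leaf <- paste0("t", k)
    nxt <- list()
    for (tr in trees) {
      # position 1 grafts above the whole tree (a new root); the rest
      # subdivide each of the remaining edges
      for (i in seq_len(n_insertion_points(tr))) {
        nxt[[length(nxt) + 1L]] <- insert_at(tr, leaf, i)
      }
    }
    trees <- nxt
  }
  vapply(trees, nested_to_newick, "")
}

n_insertion_points <- function(tr) {
  if (is.character(tr)) return(1L)  # the edge above this leaf
  1L + n_insertion_points(tr[[1]]) + n_insertion_points(tr[[2]])
}

# insertion point i (preorder over edges): replace subtree s by (s, leaf)
insert_at <- function(tr, leaf, i) {
  res <- insert_rec(tr, leaf, i)
  res$tree
}
insert_rec <- function(tr, leaf, i) {
  if (i == 1L) return(list(tree = list(tr, leaf), used = TRUE))
  i <- i - 1L
  if (is.character(tr)) return(list(tree = tr, used = FALSE, left = i))
  n1 <- n_insertion_points(tr[[1]])
  if (i <= n1) {
    r <- insert_rec(tr[[1]], leaf, i)
    return(list(tree = list(r$tree, tr[[2]]), used = TRUE))
  }
  r <- insert_rec(tr[[2]], leaf, i - n1)
  list(tree = list(tr[[1]], r$tree), used = TRUE)
}

nested_to_newick <- function(tr) {
  str <- function(x) {
    if (is.character(x)) x else paste0("(", str(x[[1]]), ",", str(x[[2]]), ")")
  }
  paste0(str(tr), ";")
}

# independent rho/sigma oracle: explicit path walks on the phylo edge table
rho_sigma_oracle <- function(tree) {
  ntip <- ape::Ntip(tree)
  parent_of <- integer(max(tree$edge))
  len_of <- numeric(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  len_of[tree$edge[, 2]] <- tree$edge.length
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  path_edges <- function(tip) {
    e <- integer()
    v <- tip
    while (v != root) {
      e <- c(e, v)  # identify each edge by its child node
      v <- parent_of[v]
    }
    e
  }
  paths <- lapply(seq_len(ntip), path_edges)
  rho <- mean(vapply(paths, function(e) sum(len_of[e]), 0))
  sigma2 <- 0
  for (child in tree$edge[, 2]) {
    n_e <- sum(vapply(paths, function(e) child %in% e, TRUE))
    sigma2 <- sigma2 + len_of[child] * (n_e / ntip)^2
  }
  list(rho = rho, sigma = sqrt(sigma2))
}

# exhaustive HKY likelihood: sum over all internal-state assignments
exhaustive_loglik <- function(tree, aln, kappa, pi, rates = 1) {
  code <- matrix(match(toupper(as.matrix(aln)), c("A", "C", "G", "T")),
                 nrow(aln), ncol(aln), dimnames = dimnames(aln))
  code <- code[tree$tip.label, , drop = FALSE]
  Q <- panmito:::hky_Q(kappa, pi)
  ntip <- ape::Ntip(tree)
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  total <- 0
  for (s in seq_len(ncol(code))) {
    lik_site <- 0
    for (r in rates) {
      Plist <- lapply(tree$edge.length, function(l)
        as.matrix(Matrix::expm(Q * l * r)))
      grid <- do.call(expand.grid, rep(list(1:4), length(internal)))
      lik_r <- 0
      for (g in seq_len(nrow(grid))) {
        st <- integer(ntip + tree$Nnode)
        st[seq_len(ntip)] <- code[, s]
        st[internal] <- as.integer(grid[g, ])
        p <- pi[st[root]]
        for (e in seq_len(nrow(tree$edge))) {
          p <- p * Plist[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
        }
        lik_r <- lik_r + p
      }
      lik_site <- lik_site + lik_r / length(rates)
    }
    total <- total + log(lik_site)
  }
  total
}

# brute-force Pearson chi-square
pearson_oracle <- function(tab) {
  n <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / n
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  stat
}

random_tokens <- function(n) {
  kinds <- sample(c("ts", "tv", "ins", "del", "het"), n, replace = TRUE,
                  prob = c(0.5, 0.2, 0.1, 0.1, 0.1))
  pos <- sample.int(16569L, n)
  vapply(seq_len(n), function(i) {
    p <- pos[i]
    tok <- switch(kinds[i],
      ts = as.character(p),
      tv = paste0(p, sample(c("A", "C", "G", "T"), 1)),
      ins = paste0(p, ".", sample(1:3, 1), sample(c("A", "C", "G", "T"), 1)),
      del = if (p < 16560 && stats::runif(1) < 0.5)
        paste0(p, "-", p + sample(1:5, 1), "d") else paste0(p, "d"),
      het = paste0(p, sample(c("R", "Y", "W", "K"), 1))
    )
    if (stats::runif(1) < 0.15) tok <- paste0(tok, "@")
    tok
  }, "")
}

# does the network realise at least one MST of the observed taxa?  An
# observed pair (u, v) is "realised" when the network geodesic equals the
# weighted character distance; the realised-pair graph must then admit a
# spanning tree whose total weight matches the MST of the full distance
# matrix.
network_contains_mst <- function(net, M, w) {
  D <- panmito:::weighted_hamming(M, w)
  rownames(D) <- colnames(D) <- rownames(M)
  W_mst <- sum(igraph::E(igraph::mst(igraph::graph_from_adjacency_matrix(
    D, mode = "undirected", weighted = TRUE)))$weight)
  geo <- igraph::distances(net$graph, rownames(M), rownames(M))
  realized <- abs(geo - D) < 1e-9
  Dr <- D
  Dr[!realized] <- 0
  gr <- igraph::graph_from_adjacency_matrix(Dr, mode = "undirected",
                                            weighted = TRUE)
  if (!igraph::is_connected(gr)) return(FALSE)
  abs(sum(igraph::E(igraph::mst(gr))$weight) - W_mst) < 1e-9
}
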