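test_that("character matrix merges identical haplotypes and drops indels", {
  haps <- list(
    mk_hap("s1", c("16360", "89")),
    mk_hap("s2", c("16360", "89")),
    mk_hap("s3", c("16360", "309.1C"))
  )
  cm <- build_character_matrix(haps)
  expect_equal(nrow(cm$matrix), 2L)
  expect_equal(unname(sort(cm$multiplicity, decreasing = TRUE)), c(2L, 1L))
  # the insertion contributes no character
  expect_false(any(grepl("309", colnames(cm$matrix))))
  # invariant 16360 removed, 89 the only character left
  expect_equal(colnames(cm$matrix), "89")
  expect_error(build_character_matrix(list()), "no haplotypes")
})

test_that("median joining resolves chains, stars and singletons", {
  # chain: A - B - C, no medians
  chain <- mk_cm(rbind(A = c(0, 0), B = c(1, 0), C = c(1, 1)))
  net <- median_joining(chain)
  expect_equal(sum(net$nodes$type == "median"), 0L)
  expect_equal(igraph::ecount(net$graph), 2L)
  d <- igraph::distances(net$graph, "A", "C")
  expect_equal(unname(d[1, 1]), 2)

  # triplet A={}, B={m1,m2}, C={m1,m3}: exactly one median {m1}
  tri <- mk_cm(rbind(A = c(0, 0, 0), B = c(1, 1, 0), C = c(1, 0, 1)),
               )
  colnames(tri$matrix) <- c("m1", "m2", "m3")
  tri$weights <- stats::setNames(rep(1L, 3), c("m1", "m2", "m3"))
  net <- median_joining(tri)
  med <- net$matrix[net$nodes$type == "median", , drop = FALSE]
  expect_equal(nrow(med), 1L)
  expect_equal(unname(med[1, ]), c(1, 0, 0))  # the majority vector {m1}
  expect_equal(igraph::ecount(net$graph), 3L)
  expect_equal(unname(igraph::degree(net$graph)[net$nodes$type == "median"]), 3)

  # singleton
  one <- mk_cm(matrix(integer(), 1, 0, dimnames = list("A", NULL)))
  net1 <- median_joining(one)
  expect_equal(nrow(net1$nodes), 1L)
  expect_equal(igraph::ecount(net1$graph), 0L)
})

test_that("non-binary characters are rejected", {
  bad <- mk_cm(rbind(A = c(0, 2), B = c(1, 0)))
  expect_error(median_joining(bad), "binary")
})

random_cm <- function(ntaxa, nchar) {
  M <- matrix(rbinom(ntaxa * nchar, 1, 0.5), ntaxa, nchar)
  rownames(M) <- paste0("t", seq_len(ntaxa))
  colnames(M) <- paste0("c", seq_len(nchar))
  keep <- colSums(M) > 0 & colSums(M) < ntaxa
  M <- M[, keep, drop = FALSE]
  M <- M[!duplicated(apply(M, 1, paste, collapse = "")), , drop = FALSE]
  if (nrow(M) < 2) return(NULL)
  mk_cm(M)
}

test_that("the network realises a minimum spanning tree of the observed taxa", {
  set.seed(51)
  done <- 0
  while (done < 60) {
    cm <- random_cm(sample(3:8, 1), sample(3:8, 1))
    if (is.null(cm)) next
    done <- done + 1
    net <- median_joining(cm)
    expect_true(igraph::is_connected(net$graph))
    expect_true(network_contains_mst(net, cm$matrix, cm$weights))
  }
})

test_that("medians act as Steiner points: spanning the taxa never costs more", {
  # spanning the observed haplotypes through the network (medians allowed
  # as intermediate nodes) never exceeds their own minimum spanning tree
  set.seed(52)
  done <- 0
  while (done < 40) {
    cm <- random_cm(sample(4:7, 1), sample(4:7, 1))
    if (is.null(cm)) next
    done <- done + 1
    net <- median_joining(cm)
    D_obs <- panmito:::weighted_hamming(cm$matrix, cm$weights)
    g_obs <- igraph::graph_from_adjacency_matrix(D_obs, mode = "undirected",
                                                 weighted = TRUE)
    w_obs <- sum(igraph::E(igraph::mst(g_obs))$weight)
    geo <- igraph::distances(net$graph, rownames(cm$matrix),
                             rownames(cm$matrix))
    g_geo <- igraph::graph_from_adjacency_matrix(geo, mode = "undirected",
                                                 weighted = TRUE)
    w_geo <- sum(igraph::E(igraph::mst(g_geo))$weight)
    expect_lte(w_geo, w_obs)
  }
  # the canonical triplet shows a strict reduction: MST 4 -> network 3
  tri <- mk_cm(rbind(A = c(0, 0, 0), B = c(1, 1, 0), C = c(1, 0, 1)))
  net <- median_joining(tri)
  expect_equal(sum(igraph::E(net$graph)$weight), 3)
})

test_that("epsilon-0 node patterns persist in wider-tolerance networks", {
  set.seed(53)
  done <- 0
  while (done < 25) {
    cm <- random_cm(sample(3:6, 1), sample(3:6, 1))
    if (is.null(cm)) next
    done <- done + 1
    pat <- function(net) apply(net$matrix, 1, paste, collapse = "")
    n0 <- pat(median_joining(cm, epsilon = 0))
    n1 <- pat(median_joining(cm, epsilon = 1))
    expect_true(all(n0 %in% n1))
  }
})

test_that("network dating weights haplotype multiplicities", {
  # star: root plus 4 taxa at weighted distances 1, 2, 3, 2
  M <- rbind(root = c(0, 0, 0, 0, 0),
             a = c(1, 0, 0, 0, 0),
             b = c(0, 1, 1, 0, 0),
             c = c(0, 0, 0, 1, 1))
  M <- cbind(M, extra = c(0, 0, 0, 1))  # c at distance 3
  cm <- mk_cm(M)
  net <- median_joining(cm)
  est <- network_node_ages(net, "root", clock_config(), "whole_molecule")
  expect_equal(est$rho, (0 + 1 + 2 + 3) / 4)
  # multiplicity reweighting moves rho toward the heavy taxon
  cm2 <- mk_cm(M, multiplicity = c(root = 1L, a = 5L, b = 1L, c = 1L))
  net2 <- median_joining(cm2)
  est2 <- network_node_ages(net2, "root", clock_config(), "whole_molecule")
  expect_equal(est2$rho, (0 + 5 * 1 + 2 + 3) / 8)
  expect_error(network_node_ages(net, "nope", clock_config()), "not a network node")
})

test_that("rho is invariant to relabeling and scales with character weights", {
  set.seed(54)
  M <- rbind(r = c(0, 0, 0), x = c(1, 0, 0), y = c(1, 1, 0), z = c(0, 0, 1))
  cm <- mk_cm(M)
  est <- network_node_ages(median_joining(cm), "r", clock_config(),
                           "whole_molecule")
  perm <- M[c(3, 1, 4, 2), ]
  cmp <- mk_cm(perm)
  estp <- network_node_ages(median_joining(cmp), "r", clock_config(),
                            "whole_molecule")
  expect_equal(est$rho, estp$rho)
  cm2 <- mk_cm(M, weights = stats::setNames(c(2L, 2L, 2L), colnames(cm$matrix)))
  est2 <- network_node_ages(median_joining(cm2), "r", clock_config(),
                            "whole_molecule")
  expect_equal(est2$rho, 2 * est$rho)
})

test_that("networks export to GML/DOT with a node table", {
  cm <- mk_cm(rbind(A = c(0, 0), B = c(1, 0), C = c(1, 1)))
  net <- median_joining(cm)
  gml <- withr::local_tempfile(fileext = ".gml")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_network(net, gml, node_table = csv)
  expect_true(file.size(gml) > 0)
  tab <- read.csv(csv)
  expect_setequal(tab$id, c("A", "B", "C"))
  dot <- withr::local_tempfile(fileext = ".dot")
  write_network(net, dot)
  expect_true(any(grepl("graph", readLines(dot))))
})
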