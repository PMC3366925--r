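FAST_SITES <- c(16093L, 16129L, 16189L, 16311L, 16362L, 146L, 150L, 152L,
                195L, 16519L)

#' Configuration for the synthetic cohort generator
#'
#' The generator emulates the structure of a region-stratified
#' control-region survey: samples are drawn per region with the bundled
#' Panamanian haplogroup composition (counts recovered from the published
#' regional frequency table), each sample's haplotype starts from its
#' haplogroup's founding motif on the supplied haplogroup tree and gains
#' `Poisson(age / years_per_mutation)` private transitions at distinct,
#' hotspot-weighted control-region positions (an infinite-sites-style
#' draw: a sample never hits the same site twice, so mutation counts are
#' exactly Poisson). Foreign-TMA samples and maternally related clusters
#' (members share the haplotype of a cluster seed) are then injected.
#'
#' @param seed integer seed; all randomness flows from it.
#' @param region_counts `data.frame` region/type/haplogroup/count; default
#'   is the bundled Panamanian table.
#' @param tree a [haplogroup_tree()] providing founding motifs; default
#'   the bundled synthetic tree.
#' @param clade_ages named numeric vector, years per haplogroup; defaults
#'   are field-plausible founder ages (Native clades 15--18 ka, African
#'   L clades older, West Eurasian intermediate).
#' @param clock a [clock_config()]; private mutation counts use its
#'   control-region rate.
#' @param hotspot_multiplier rate multiplier at the classic fast sites.
#' @param mode `"exact"` (quota per region x haplogroup = count; the
#'   deterministic composition used for table reconstruction) or
#'   `"sampled"` (multinomial).
#' @param n_foreign number of extra foreign-TMA samples.
#' @param n_pairs,n_triplets relatedness clusters to inject (each adds 1
#'   resp. 2 copies of a cluster seed).
#' @param covered_range sequenced circular range.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       region_counts = NULL,
                       tree = NULL,
                       clade_ages = NULL,
                       clock = clock_config(),
                       hotspot_multiplier = 5,
                       mode = c("exact", "sampled"),
                       n_foreign = 149L, n_pairs = 42L, n_triplets = 13L,
                       covered_range = c(16000L, 580L)) {
  mode <- match.arg(mode)
  if (is.null(region_counts)) {
    region_counts <- utils::read.delim(
      system.file("extdata", "panama_region_counts.tsv", package = "panmito"),
      stringsAsFactors = FALSE, check.names = FALSE
    )
  }
  if (is.null(tree)) {
    tree <- read_haplogroup_tree(
      system.file("extdata", "synthetic_haplogroup_tree.txt", package = "panmito")
    )
  }
  if (is.null(clade_ages)) {
    clade_ages <- c(
      A2 = 17000, B2 = 17000, C1 = 16500, D1 = 15500,
      L0 = 70000, L1 = 60000, L2 = 55000, L3 = 50000,
      HV = 22000, JT = 28000, `N1'2` = 32000, U = 45000, G = 35000
    )
  }
  missing_age <- setdiff(unique(region_counts$haplogroup), names(clade_ages))
  if (length(missing_age)) stop("no clade age for: ",
                                paste(missing_age, collapse = ", "))
  if (any(clade_ages <= 0)) stop("clade ages must be positive")
  structure(
    list(seed = as.integer(seed), region_counts = region_counts, tree = tree,
         clade_ages = clade_ages, clock = clock,
         hotspot_multiplier = hotspot_multiplier, mode = mode,
         n_foreign = as.integer(n_foreign), n_pairs = as.integer(n_pairs),
         n_triplets = as.integer(n_triplets), covered_range = covered_range),
    class = "sim_config"
  )
}

# positions available for private mutations: inside the covered range but
# away from every tree motif position and from the default exclusions
private_site_pool <- function(config) {
  rng <- config$covered_range
  pool <- if (rng[1] <= rng[2]) seq.int(rng[1], rng[2]) else
    c(seq.int(rng[1], MT_LEN), seq.int(1L, rng[2]))
  motif_pos <- unique(unlist(lapply(config$tree$motifs, function(m) {
    if (length(m) == 0L) return(integer())
    v <- parse_variants(m)
    unlist(mapply(seq.int, v$position, v$span_end, SIMPLIFY = FALSE))
  })))
  excl <- c(16182L, 16183L, 16194L, 16519L, 303:315, 16184:16193)
  pool <- setdiff(pool, c(motif_pos, excl))
  w <- rep(1, length(pool))
  w[pool %in% FAST_SITES] <- config$hotspot_multiplier
  list(pool = pool, weights = w)
}

founding_motif <- function(tree, label) {
  path <- tree_path(tree, label)
  toks <- unlist(tree$motifs[path], use.names = FALSE)
  if (length(toks) == 0L) return(character())
  v <- parse_variants(toks)
  key <- sub("@$", "", v$token)
  net <- tapply(ifelse(v$reversion, -1L, 1L), key, sum)
  names(net)[net > 0]
}

#' Simulate a region-stratified cohort
#'
#' @param config a [sim_config()].
#' @return list of class `sim_cohort`: `cohort` (an `mt_cohort` including
#'   foreign-TMA and related extra samples), `metadata` (`data.frame`:
#'   `sample_id`, `region`, `tma_origin`, `generations`, `cluster_id`),
#'   and `truth` (`data.frame` with the true haplogroup and private-
#'   mutation count per sample, plus a `config` attribute echo).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rc <- config$region_counts
  sites <- private_site_pool(config)
  rate <- config$clock$control_region_rate

  if (config$mode == "exact") {
    draws <- rc[rep(seq_len(nrow(rc)), rc$count), c("region", "haplogroup")]
  } else {
    draws <- NULL
    for (reg in unique(rc$region)) {
      sub <- rc[rc$region == reg, ]
      hg <- sample(sub$haplogroup, sum(sub$count), replace = TRUE,
                   prob = sub$count / sum(sub$count))
      draws <- rbind(draws, data.frame(region = reg, haplogroup = hg))
    }
  }
  n_core <- nrow(draws)
  ids <- sprintf("PA%05d", seq_len(n_core))

  make_sample <- function(id, region, hg, tma) {
    motif <- founding_motif(config$tree, hg)
    m <- stats::rpois(1L, config$clade_ages[[hg]] / rate)
    m <- min(m, length(sites$pool))
    priv <- sample(sites$pool, m, prob = sites$weights)
    haplotype(id, c(motif, as.character(priv)),
              covered_range = config$covered_range,
              region = region, tma_origin = tma, haplogroup = hg)
  }
  haps <- vector("list", n_core)
  for (i in seq_len(n_core)) {
    haps[[i]] <- make_sample(ids[i], draws$region[i], draws$haplogroup[i],
                             "Panama")
  }
  truth <- data.frame(
    sample_id = ids, region = draws$region, haplogroup = draws$haplogroup,
    n_private = vapply(haps, function(h) {
      nrow(h$variants) - length(founding_motif(config$tree, h$haplogroup))
    }, 0L),
    tma_origin = "Panama", cluster_id = NA_character_,
    stringsAsFactors = FALSE
  )

  # foreign-TMA extras, with haplogroups typical of the origin area
  foreign_areas <- c("South America" = 0.483, "Central America" = 0.215,
                     "Europe" = 0.128, "North America" = 0.074,
                     "Caribbean" = 0.060, "Asia" = 0.040)
  area_bins <- list(
    "South America" = c("A2", "B2", "C1", "D1"),
    "Central America" = c("A2", "B2"),
    "Europe" = c("HV", "JT", "U"),
    "North America" = c("A2", "HV"),
    "Caribbean" = c("L2", "L3"),
    "Asia" = c("G")
  )
  if (config$n_foreign > 0L) {
    areas <- sample(names(foreign_areas), config$n_foreign, replace = TRUE,
                    prob = foreign_areas)
    regs <- sample(unique(rc$region), config$n_foreign, replace = TRUE)
    for (j in seq_len(config$n_foreign)) {
      id <- sprintf("PF%05d", j)
      hg <- sample(area_bins[[areas[j]]], 1L)
      haps[[length(haps) + 1L]] <- make_sample(id, regs[j], hg, areas[j])
      truth <- rbind(truth, data.frame(
        sample_id = id, region = regs[j], haplogroup = hg,
        n_private = nrow(haps[[length(haps)]]$variants) -
          length(founding_motif(config$tree, hg)),
        tma_origin = areas[j], cluster_id = NA_character_
      ))
    }
  }

  # relatedness clusters: seeds among the core samples; members share the
  # seed's haplotype. Copies sort after the seed so deterministic dedup
  # (lexicographically smallest) recovers the core cohort exactly.
  n_clusters <- config$n_pairs + config$n_triplets
  if (n_clusters > 0L) {
    if (n_clusters > n_core) stop("more clusters than core samples")
    seeds <- sample(ids, n_clusters)
    sizes <- c(rep(2L, config$n_pairs), rep(3L, config$n_triplets))
    for (ci in seq_len(n_clusters)) {
      cl_id <- sprintf("fam%03d", ci)
      seed_hap <- haps[[match(seeds[ci], vapply(haps, `[[`, "", "sample_id"))]]
      truth$cluster_id[truth$sample_id == seeds[ci]] <- cl_id
      for (copy in seq_len(sizes[ci] - 1L)) {
        id <- sprintf("%sr%d", seeds[ci], copy)
        h <- seed_hap; h$sample_id <- id
        haps[[length(haps) + 1L]] <- h
        truth <- rbind(truth, data.frame(
          sample_id = id, region = seed_hap$region,
          haplogroup = seed_hap$haplogroup,
          n_private = truth$n_private[truth$sample_id == seeds[ci]],
          tma_origin = "Panama", cluster_id = cl_id
        ))
      }
    }
  }

  metadata <- data.frame(
    sample_id = truth$sample_id, region = truth$region,
    tma_origin = truth$tma_origin,
    generations = pmax(0L, round(stats::rnorm(nrow(truth), 3.13, 0.87))),
    cluster_id = truth$cluster_id,
    stringsAsFactors = FALSE
  )
  attr(truth, "config") <- list(
    seed = config$seed, mode = config$mode,
    clade_ages = as.list(config$clade_ages),
    control_region_rate = rate,
    n_foreign = config$n_foreign, n_pairs = config$n_pairs,
    n_triplets = config$n_triplets
  )
  structure(list(cohort = cohort(haps), metadata = metadata, truth = truth),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("<sim_cohort> ", length(x$cohort), " samples (",
      sum(x$truth$tma_origin == "Panama"), " Panama TMA, ",
      sum(!is.na(x$truth$cluster_id)), " in relatedness clusters)\n", sep = "")
  invisible(x)
}

#' Write a simulated cohort's truth record as JSON
#'
#' @param sim a [simulate_cohort()] result.
#' @param path output path.
#' @export
write_truth <- function(sim, path) {
  jsonlite::write_json(
    list(config = attr(sim$truth, "config"), samples = sim$truth),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' Simulate a star genealogy of known age
#'
#' Each of `n` lineages independently accumulates
#' `Poisson(age_years / years_per_mutation)` mutations since the founder.
#' Returns the star tree (edge lengths in mutations) and the per-lineage
#' counts; used to calibrate the rho estimator.
#'
#' @param n number of sampled lineages.
#' @param age_years true clade age.
#' @param years_per_mutation clock rate.
#' @return list with `tree` (a star `phylo`) and `counts`.
#' @export
simulate_star_clade <- function(n, age_years, years_per_mutation = 3624) {
  counts <- stats::rpois(n, age_years / years_per_mutation)
  tree <- ape::read.tree(text = paste0(
    "(", paste(sprintf("t%d:%d", seq_len(n), counts), collapse = ","), ");"
  ))
  tree$root.edge <- 0  # the founder node is the declared root
  list(tree = tree, counts = counts)
}

#' Simulate an alignment under HKY85 + discrete gamma on a fixed tree
#'
#' Sites evolve independently down the tree from root states drawn from
#' the base frequencies; each site's rate is its partition multiplier
#' times a gamma category rate.
#'
#' @param tree rooted `phylo`, branch lengths in substitutions/site.
#' @param nsites number of alignment columns.
#' @param kappa transition/transversion parameter.
#' @param base_freq A,C,G,T frequencies.
#' @param alpha gamma shape (`NA` = no rate variation).
#' @param n_rate_categories discrete categories.
#' @param positions rCRS coordinates of the columns (default `1:nsites`).
#' @param partitions named list of position vectors; remainder implicit.
#' @param multipliers named per-partition rate multipliers.
#' @return character matrix (tips x sites) with `positions` attribute.
#' @export
simulate_alignment <- function(tree, nsites, kappa = 10,
                               base_freq = rep(0.25, 4), alpha = NA,
                               n_rate_categories = 32L, positions = NULL,
                               partitions = NULL, multipliers = NULL) {
  stopifnot(inherits(tree, "phylo"), all(tree$edge.length >= 0))
  if (is.null(positions)) positions <- seq_len(nsites)
  part_id <- rep("remainder", nsites)
  if (!is.null(partitions)) {
    for (nm in names(partitions)) part_id[positions %in% partitions[[nm]]] <- nm
  }
  m <- setNames(rep(1, length(unique(part_id))), unique(part_id))
  if (!is.null(multipliers)) m[names(multipliers)] <- multipliers
  rates <- if (is.na(alpha)) rep(1, nsites) else {
    cat_rates <- discrete_gamma_rates(alpha, n_rate_categories)
    cat_rates[sample.int(n_rate_categories, nsites, replace = TRUE)]
  }
  rates <- rates * m[part_id]
  eig <- hky_eigen(kappa, base_freq)
  ntip <- ape::Ntip(tree)
  nnode <- ntip + tree$Nnode
  states <- matrix(0L, nnode, nsites)
  ord <- rev(ape::postorder(tree))  # preorder: parents before children
  root <- tree$edge[ord[1], 1]
  states[root, ] <- sample.int(4L, nsites, replace = TRUE, prob = base_freq)
  rate_grp <- split(seq_len(nsites), rates)
  for (k in ord) {
    par <- tree$edge[k, 1]; child <- tree$edge[k, 2]; len <- tree$edge.length[k]
    for (g in seq_along(rate_grp)) {
      idx <- rate_grp[[g]]
      P <- hky_P(eig, len * as.numeric(names(rate_grp)[g]))
      cum <- t(apply(P, 1L, cumsum))
      u <- stats::runif(length(idx))
      cp <- cum[states[par, idx], , drop = FALSE]
      states[child, idx] <- 1L + (u > cp[, 1]) + (u > cp[, 2]) + (u > cp[, 3])
    }
  }
  out <- matrix(c("A", "C", "G", "T")[states[seq_len(ntip), , drop = FALSE]],
                ntip, nsites, dimnames = list(tree$tip.label, NULL))
  attr(out, "positions") <- positions
  out
}
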