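#' Mutation-rate calibrations
#'
#' Bundles the per-mutation clock rates used to convert mutational
#' distances into years. The whole-molecule calibration -- one mutation
#' per 3,624 years over the complete mitochondrial genome -- is the only
#' hard-coded value. The control-region rate differs between published
#' calibrations, so it ships as a named entry the user must confirm
#' (`confirmed = TRUE`) before relying on control-region ages; the default
#' placeholder of 9,058 years per control-region mutation is merely of the
#' order of published control-region clocks.
#'
#' @param years_per_mutation whole-molecule years per mutation.
#' @param control_region_rate years per control-region mutation.
#' @param label calibration name.
#' @param confirmed has the user confirmed the control-region rate?
#' @return an object of class `clock_config`.
#' @export
clock_config <- function(years_per_mutation = 3624,
                         control_region_rate = 9058,
                         label = "whole-molecule 3624 yr/mutation",
                         confirmed = FALSE) {
  stopifnot(years_per_mutation > 0, control_region_rate > 0)
  structure(
    list(years_per_mutation = years_per_mutation,
         control_region_rate = control_region_rate,
         label = label, confirmed = confirmed),
    class = "clock_config"
  )
}

age_estimate <- function(rho, sigma, method, age_years = NA_real_,
                         age_se_years = NA_real_, clock_label = NA_character_) {
  stopifnot(rho >= 0, is.na(sigma) || sigma >= 0)
  structure(
    list(rho = rho, sigma = sigma, age_years = age_years,
         age_se_years = age_se_years, method = method,
         clock_label = clock_label),
    class = "age_estimate"
  )
}

#' @export
print.age_estimate <- function(x, ...) {
  cat("<age_estimate> [", x$method, "] rho = ", signif(x$rho, 4), sep = "")
  if (!is.na(x$sigma)) cat(" +/- ", signif(x$sigma, 4), sep = "")
  if (!is.na(x$age_years)) {
    cat("  age = ", round(x$age_years), " y", sep = "")
    if (!is.na(x$age_se_years)) cat(" +/- ", round(x$age_se_years), " y", sep = "")
    if (!is.na(x$clock_label)) cat("  (", x$clock_label, ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Rho statistic and its heuristic standard error
#'
#' On a rooted genealogy with edge lengths in mutations, computes rho --
#' the mean mutational distance from the root to the sampled haplotypes
#' (each tip counted once; represent multiplicities by duplicated tips) --
#' and the heuristic standard error sigma with
#' sigma^2 = sum over edges of l_e (n_e / N)^2, where l_e is the edge
#' length, n_e the number of sampled tips below the edge and N the total
#' number of tips.
#'
#' @param tree a `phylo` object with non-negative edge lengths in
#'   mutations; its basal node is taken as the clade root (a star
#'   genealogy is a basal polytomy).
#' @return an `age_estimate` with the mutational `rho` and `sigma` set
#'   (convert to years with [to_years()]).
#' @export
rho_sigma <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  # the basal node is taken as the root; star genealogies (basal
  # polytomies) are legitimate rooted genealogies here
  if (is.null(tree$edge.length)) stop("tree must have edge lengths")
  if (any(tree$edge.length < 0)) stop("edge lengths must be non-negative")
  n <- ape::Ntip(tree)
  depths <- ape::node.depth.edgelength(tree)
  rho <- mean(depths[seq_len(n)])
  ntips_below <- tips_below(tree)
  n_e <- ntips_below[tree$edge[, 2]]
  sigma2 <- sum(tree$edge.length * (n_e / n)^2)
  age_estimate(rho = rho, sigma = sqrt(sigma2), method = "rho")
}

# number of sampled tips below each node (tips themselves count 1)
tips_below <- function(tree) {
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  cnt <- c(rep(1L, n), rep(0L, m))
  ord <- ape::postorder(tree)  # children counted before parents
  for (i in ord) {
    cnt[tree$edge[i, 1]] <- cnt[tree$edge[i, 1]] + cnt[tree$edge[i, 2]]
  }
  cnt
}

#' Convert a mutational age estimate into years
#'
#' Multiplies rho and sigma by the per-mutation rate of the requested
#' calibration scale.
#'
#' @param est an `age_estimate` from [rho_sigma()] or [ml_age()].
#' @param clock a [clock_config()].
#' @param scale `"whole_molecule"` or `"control_region"`.
#' @return the `age_estimate` with `age_years`/`age_se_years` filled in.
#' @export
to_years <- function(est, clock = clock_config(),
                     scale = c("whole_molecule", "control_region")) {
  stopifnot(inherits(est, "age_estimate"), inherits(clock, "clock_config"))
  scale <- match.arg(scale)
  rate <- switch(scale,
    whole_molecule = clock$years_per_mutation,
    control_region = {
      if (is.null(clock$control_region_rate)) {
        stop("no control-region rate configured")
      }
      clock$control_region_rate
    }
  )
  est$age_years <- est$rho * rate
  est$age_se_years <- if (is.na(est$sigma)) NA_real_ else est$sigma * rate
  est$clock_label <- paste0(clock$label, " [", scale, "]")
  est
}

#' Maximum-likelihood age from a substitutions-per-site tree
#'
#' Converts the mean root-to-tip branch-length distance of a tree in
#' expected substitutions per site into an age: mean distance x genome
#' length = expected mutations, times the whole-molecule years-per-
#' mutation rate.
#'
#' @param tree a rooted `phylo` with branch lengths in substitutions/site
#'   (e.g. from [ml_branch_lengths()]).
#' @param clock a [clock_config()].
#' @param genome_length number of sites the per-site lengths refer to
#'   (16,569 for the complete molecule).
#' @return an `age_estimate` with `method = "ML"` (no heuristic sigma).
#' @export
ml_age <- function(tree, clock = clock_config(), genome_length = 16569L) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have edge lengths")
  n <- ape::Ntip(tree)
  depths <- ape::node.depth.edgelength(tree)
  rho_mut <- mean(depths[seq_len(n)]) * genome_length
  est <- age_estimate(rho = rho_mut, sigma = NA_real_, method = "ML")
  to_years(est, clock, "whole_molecule")
}

#' Age-estimate report table
#'
#' @param estimates named list of `age_estimate` objects (names = clades).
#' @param path optional TSV path.
#' @return a `data.frame` (written to `path` when given).
#' @export
age_report <- function(estimates, path = NULL) {
  df <- data.frame(
    clade = names(estimates),
    rho = vapply(estimates, function(e) e$rho, 0),
    sigma = vapply(estimates, function(e) e$sigma, 0),
    age_years = vapply(estimates, function(e) e$age_years, 0),
    age_se_years = vapply(estimates, function(e) e$age_se_years, 0),
    method = vapply(estimates, function(e) e$method, ""),
    clock = vapply(estimates, function(e) e$clock_label, ""),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}
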