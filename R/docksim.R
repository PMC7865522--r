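#' Intersect the top-n molecules of two docking runs
#'
#' Takes the molecules ranked within the top n of both runs, keeps the
#' common set, and renumbers the ranks 1..k within the intersection while
#' preserving each run's original order.
#'
#' @param run_a,run_b ranked \code{docking_run} objects.
#' @param n top-list cutoff (>= 1).
#' @return a list of class \code{rank_intersection} with elements
#'   \code{molecule_ids}, \code{ranks_a}, \code{ranks_b} (each a
#'   permutation of 1..k) and \code{k}.
#' @export
top_n_intersection <- function(run_a, run_b, n) {
  stopifnot(inherits(run_a, "docking_run"), inherits(run_b, "docking_run"),
            n >= 1)
  top_a <- run_a$table[run_a$table$rank <= n, ]
  top_b <- run_b$table[run_b$table$rank <= n, ]
  common <- intersect(top_a$molecule_id, top_b$molecule_id)
  ra <- top_a$rank[match(common, top_a$molecule_id)]
  rb <- top_b$rank[match(common, top_b$molecule_id)]
  structure(list(molecule_ids = common,
                 ranks_a = rank(ra, ties.method = "first"),
                 ranks_b = rank(rb, ties.method = "first"),
                 k = length(common)),
            class = "rank_intersection")
}

#' Docking-rank similarity of two docking runs
#'
#' Spearman rank correlation of the renumbered ranks of the molecules
#' common to the top-n lists of both runs. Because upstream ranks are
#' ordinal (no ties), the renumbered ranks are exact permutations and no
#' tie correction is needed. When fewer than two molecules are shared the
#' correlation is undefined and \code{NaN} is returned.
#'
#' @param run_a,run_b ranked \code{docking_run} objects.
#' @param n top-list cutoff; the conventional default is 25,000.
#' @return Spearman correlation in [-1, 1], or \code{NaN} if k < 2.
#' @export
dockrank_sim <- function(run_a, run_b, n = 25000L) {
  xs <- top_n_intersection(run_a, run_b, n)
  if (xs$k < 2L) return(NaN)
  stopifnot(identical(sort(xs$ranks_a), seq_len(xs$k)),
            identical(sort(xs$ranks_b), seq_len(xs$k)))
  stats::cor(xs$ranks_a, xs$ranks_b, method = "spearman")
}

#' Kinase-level docking-rank similarity matrix
#'
#' Reduces structure-pair docking-rank similarities to the kinase level by
#' taking, for each kinase pair, the maximum over all structure pairs (one
#' structure from each kinase). The diagonal takes the maximum over
#' distinct structure pairs within the kinase and is \code{NaN} for
#' kinases with a single structure.
#'
#' @param runs_by_kinase named list: kinase_id -> list of ranked
#'   \code{docking_run} objects.
#' @param n top-list cutoff passed to \code{\link{dockrank_sim}}.
#' @return a \code{\link{similarity_matrix}} with range [-1, 1]. The
#'   attribute \code{"pairs"} holds the per-structure-pair overlap report
#'   (kinase_a, structure_a, kinase_b, structure_b, k, rho).
#' @export
kinase_dockrank_matrix <- function(runs_by_kinase, n = 25000L) {
  kinases <- names(runs_by_kinase)
  stopifnot(length(kinases) >= 1L, all(lengths(runs_by_kinase) >= 1L))
  mat <- matrix(NaN, length(kinases), length(kinases),
                dimnames = list(kinases, kinases))
  pairs <- list()
  for (i in seq_along(kinases)) {
    for (j in i:length(kinases)) {
      ra <- runs_by_kinase[[i]]
      rb <- runs_by_kinase[[j]]
      best <- NaN
      for (a in seq_along(ra)) {
        for (b in seq_along(rb)) {
          if (i == j && b <= a) next  # distinct pairs only on the diagonal
          xs <- top_n_intersection(ra[[a]], rb[[b]], n)
          rho <- if (xs$k < 2L) NaN
                 else stats::cor(xs$ranks_a, xs$ranks_b, method = "spearman")
          pairs[[length(pairs) + 1L]] <- data.frame(
            kinase_a = kinases[[i]], structure_a = ra[[a]]$structure_id,
            kinase_b = kinases[[j]], structure_b = rb[[b]]$structure_id,
            k = xs$k, rho = rho, stringsAsFactors = FALSE)
          if (!is.nan(rho) && (is.nan(best) || rho > best)) best <- rho
        }
      }
      mat[i, j] <- mat[j, i] <- best
    }
  }
  out <- similarity_matrix(mat, measure_name = "DockRankSim",
                           range = c(-1, 1))
  attr(out, "pairs") <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(kinase_a = character(0), structure_a = character(0),
               kinase_b = character(0), structure_b = character(0),
               k = integer(0), rho = numeric(0))
  out
}
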