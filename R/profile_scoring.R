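#' Define a kinase selectivity profile
#'
#' A profile is an ordered set of kinases, each a target (binding is
#' desired) or an anti-target (binding is to be designed out), together
#' with the docking structures available per kinase.
#'
#' @param members data.frame with columns \code{kinase_id} and \code{role}
#'   (\code{"target"} or \code{"anti_target"}), or a named character vector
#'   of roles.
#' @param structures named list: kinase_id -> character vector of structure
#'   identifiers (each member kinase needs at least one).
#' @param profile_id single string naming the profile.
#' @param log_base base of the logarithm applied to scaled ranks; any base
#'   greater than 1 yields the same molecule ordering, so the default 10
#'   only fixes the reported magnitudes.
#' @return an object of class \code{profile_spec}.
#' @examples
#' profile_spec(c(EGFR = "target", ErbB2 = "target", BRAF = "anti_target"),
#'              structures = list(EGFR = c("1XKK", "3POZ"),
#'                                ErbB2 = c("3PP0", "3RCD"),
#'                                BRAF = c("1UWH", "3PPK")),
#'              profile_id = "profile1")
#' @export
profile_spec <- function(members, structures, profile_id = "profile",
                         log_base = 10) {
  if (is.character(members) && !is.null(names(members))) {
    members <- data.frame(kinase_id = names(members),
                          role = unname(members),
                          stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(members),
            all(c("kinase_id", "role") %in% names(members)))
  if (nrow(members) < 1L) stop("profile needs at least one member kinase")
  if (!all(members$role %in% c("target", "anti_target")))
    stop("role must be 'target' or 'anti_target'")
  if (anyDuplicated(members$kinase_id))
    stop("duplicate member kinase")
  if (!is.numeric(log_base) || log_base <= 0 || log_base == 1)
    stop("log_base must be positive and != 1")
  missing_struct <- setdiff(members$kinase_id, names(structures))
  if (length(missing_struct))
    stop("no structures listed for: ", paste(missing_struct, collapse = ", "))
  if (any(lengths(structures[members$kinase_id]) == 0L))
    stop("every member kinase needs >= 1 structure")
  structure(list(profile_id = profile_id,
                 members = members[, c("kinase_id", "role")],
                 structures = structures[members$kinase_id],
                 log_base = log_base),
            class = "profile_spec")
}

#' @export
print.profile_spec <- function(x, ...) {
  sign_of <- ifelse(x$members$role == "target", "+", "-")
  cat("Profile", x$profile_id, ":",
      paste0(sign_of, x$members$kinase_id, collapse = " "), "\n")
  cat("  structures:",
      paste(sprintf("%s(%d)", x$members$kinase_id,
                    lengths(x$structures)), collapse = " "), "\n")
  cat("  log base:", x$log_base, "\n")
  invisible(x)
}

# scaled rank used for anti-targets: inverted with a -1 offset so the
# worst-ranked molecule maps to 1/m rather than 0 (where the log would be
# undefined), exactly mirroring the target-side range [1/m, 1]
inverted_scaled_rank <- function(r, m) 1 - (r - 1) / m

#' Aggregate a molecule's rank over the structures of one kinase
#'
#' For a target kinase the per-structure scaled ranks r/m are reduced with
#' min (only the best structure counts); for an anti-target each rank is
#' first inverted to 1 - (r-1)/m, then reduced with max, so good docking
#' into an anti-target is penalised. The log (default base 10) of the
#' reduced scaled rank is returned; it is always <= 0.
#'
#' @param runs list of \code{docking_run} objects for one kinase.
#' @param molecule_id single molecule identifier.
#' @param role \code{"target"} or \code{"anti_target"}.
#' @param log_base log base (> 0, != 1).
#' @return the aggregated log scaled rank P (numeric scalar <= 0).
#' @export
aggregate_kinase_rank <- function(runs, molecule_id, role = "target",
                                  log_base = 10) {
  role <- match.arg(role, c("target", "anti_target"))
  stopifnot(length(molecule_id) == 1L)
  vals <- numeric(0)
  for (run in runs) {
    idx <- match(molecule_id, run$table$molecule_id)
    if (is.na(idx)) next
    r <- run$table$rank[idx]
    m <- run$m
    vals <- c(vals, if (role == "target") r / m
              else inverted_scaled_rank(r, m))
  }
  if (length(vals) == 0L)
    stop("no rank for kinase: molecule ", molecule_id,
         " absent from all runs")
  R <- if (role == "target") min(vals) else max(vals)
  log(R, base = log_base)
}

#' Combine per-kinase log ranks into the profile score S
#'
#' S is the mean of the per-kinase aggregated log scaled ranks plus half
#' the spread between the best and the worst component:
#' S = mean(P) + (max(P) - min(P)) / 2. Lower S means a better match to
#' the profile; the spread term penalises molecules that do well on some
#' profile members but poorly on others.
#'
#' @param P numeric vector of per-kinase log scaled ranks (finite).
#' @return the profile score S (numeric scalar).
#' @examples
#' profile_score(c(-1, -0.699, -1))  # mean -0.8997 + spread/2 0.1505
#' @export
profile_score <- function(P) {
  if (length(P) == 0L) stop("P must be non-empty")
  if (!all(is.finite(P))) stop("P must be finite")
  mean(P) + (max(P) - min(P)) / 2
}

#' Re-rank molecules by profile score
#'
#' Computes, for every molecule that has a docking rank in at least one
#' structure of every member kinase, the per-kinase aggregated log ranks
#' and the combined profile score S, and returns the table sorted
#' ascending by S (ties broken by molecule identifier). Molecules missing
#' from some member kinase are dropped (strict coverage) unless
#' \code{missing_as_worst = TRUE}, which scores an absent molecule as if
#' it held rank m + 1 in every structure it misses.
#'
#' @param runs_by_kinase named list: kinase_id -> list of ranked
#'   \code{docking_run} objects.
#' @param spec a \code{\link{profile_spec}}.
#' @param missing_as_worst impute rank m + 1 for molecules absent from a
#'   structure instead of dropping them (default \code{FALSE}).
#' @return an object of class \code{profile_ranking}: a data.frame with
#'   \code{molecule_id}, one \code{P_<kinase>} column per member, \code{S}
#'   and \code{profile_rank}; attribute \code{n_dropped} counts molecules
#'   excluded by the coverage rule.
#' @export
rank_by_profile <- function(runs_by_kinase, spec, missing_as_worst = FALSE) {
  stopifnot(inherits(spec, "profile_spec"))
  kinases <- spec$members$kinase_id
  roles <- spec$members$role
  absent <- setdiff(kinases, names(runs_by_kinase))
  if (length(absent))
    stop("no docking runs for kinase: ", paste(absent, collapse = ", "))

  all_ids <- sort(unique(unlist(lapply(kinases, function(k) {
    unlist(lapply(runs_by_kinase[[k]], function(run) run$table$molecule_id))
  }))), method = "radix")

  # per kinase: reduced scaled rank per molecule (vectorised over molecules)
  P <- matrix(NA_real_, nrow = length(all_ids), ncol = length(kinases),
              dimnames = list(all_ids, kinases))
  for (j in seq_along(kinases)) {
    k <- kinases[[j]]
    target <- roles[[j]] == "target"
    red <- rep(NA_real_, length(all_ids))
    for (run in runs_by_kinase[[k]]) {
      idx <- match(all_ids, run$table$molecule_id)
      r <- run$table$rank[idx]
      m <- run$m
      if (missing_as_worst) r[is.na(r)] <- m + 1
      R <- if (target) r / m else inverted_scaled_rank(r, m)
      red <- if (target) pmin(red, R, na.rm = TRUE)
             else pmax(red, R, na.rm = TRUE)
    }
    P[, j] <- red
  }

  covered <- rowSums(is.na(P)) == 0L
  n_dropped <- sum(!covered)
  if (n_dropped > 0L)
    message(n_dropped, " molecule(s) dropped: not docked in every member kinase")
  P <- P[covered, , drop = FALSE]
  if (nrow(P) == 0L) stop("no molecule is rankable in all member kinases")
  logP <- log(P, base = spec$log_base)

  S <- rowMeans(logP) +
    (apply(logP, 1L, max) - apply(logP, 1L, min)) / 2
  out <- data.frame(molecule_id = rownames(P), stringsAsFactors = FALSE)
  for (j in seq_along(kinases)) out[[paste0("P_", kinases[[j]])]] <- logP[, j]
  out$S <- S
  ord <- order(S, ordered_id(out$molecule_id))
  out <- out[ord, ]
  out$profile_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("profile_ranking", "data.frame"),
            profile_id = spec$profile_id, n_dropped = n_dropped)
}

#' @export
print.profile_ranking <- function(x, n = 10L, ...) {
  cat("Profile ranking '", attr(x, "profile_id"), "': ",
      nrow(x), " molecule(s) scored, ",
      attr(x, "n_dropped"), " dropped by coverage rule\n", sep = "")
  print.data.frame(utils::head(x, n), digits = 4)
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more\n")
  invisible(x)
}

#' @export
summary.profile_ranking <- function(object, ...) {
  cat("Profile ranking '", attr(object, "profile_id"), "'\n", sep = "")
  cat("  molecules scored:", nrow(object), "\n")
  cat("  dropped (coverage):", attr(object, "n_dropped"), "\n")
  cat("  S range: [", sprintf("%.4f", min(object$S)), ", ",
      sprintf("%.4f", max(object$S)), "]\n", sep = "")
  invisible(object)
}

#' Expected hit rate of a multi-target profile
#'
#' Under independence, the chance that one molecule satisfies the whole
#' profile is the product of the per-kinase probabilities (for targets the
#' per-target hit rate, for anti-targets the avoidance probability). With
#' single-target docking hit rates around 10-25% and a ~90% chance of
#' sparing a given anti-target, a two-target/one-anti-target profile gives
#' 0.25 x 0.25 x 0.90 = 0.056.
#'
#' @param per_kinase_rates numeric vector of probabilities in [0, 1].
#' @return the product (a probability).
#' @examples
#' expected_profile_hit_rate(c(0.25, 0.25, 0.90))
#' @export
expected_profile_hit_rate <- function(per_kinase_rates) {
  if (length(per_kinase_rates) == 0L) stop("need at least one rate")
  if (!is.numeric(per_kinase_rates) || anyNA(per_kinase_rates) ||
      any(per_kinase_rates < 0 | per_kinase_rates > 1))
    stop("rates must lie in [0, 1]")
  prod(per_kinase_rates)
}
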