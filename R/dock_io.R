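#' Construct a docking run from molecule identifiers and scores
#'
#' A docking run is one structure's scored molecule list. Scores follow the
#' DOCK convention of lower-is-better energies by default; set
#' \code{lower_is_better = FALSE} for scoring functions where larger values
#' indicate better poses. Duplicate molecule rows are collapsed to the best
#' score, mirroring keeping a molecule's best pose. Ordinal 1-based ranks
#' are assigned immediately (see \code{\link{compute_ranks}}).
#'
#' @param molecule_id character vector of non-empty molecule identifiers
#'   (opaque strings; ZINC identifiers fit but are not required).
#' @param score numeric docking scores, same length as \code{molecule_id}.
#' @param kinase_id single string naming the kinase.
#' @param structure_id single string naming the structure (PDB-style code).
#' @param lower_is_better logical; if \code{TRUE} (default) the smallest
#'   score gets rank 1.
#' @return An object of class \code{docking_run}: a list with elements
#'   \code{kinase_id}, \code{structure_id}, \code{table} (data.frame with
#'   columns \code{molecule_id}, \code{score}, \code{rank}) and \code{m},
#'   the number of distinct docked molecules.
#' @examples
#' run <- docking_run(c("a", "b", "c"), c(-42.1, -38.0, -51.3),
#'                    "EGFR", "1XKK")
#' run$m
#' run$table
#' @export
docking_run <- function(molecule_id, score, kinase_id, structure_id,
                        lower_is_better = TRUE) {
  molecule_id <- as.character(molecule_id)
  score <- as.numeric(score)
  if (length(molecule_id) == 0L) stop("no molecules")
  if (length(molecule_id) != length(score))
    stop("molecule_id and score must have equal length")
  if (anyNA(molecule_id) || any(!nzchar(molecule_id)))
    stop("molecule_id must be non-empty strings")
  if (anyNA(score)) stop("scores must be numeric and non-missing")
  stopifnot(is.character(kinase_id), length(kinase_id) == 1L,
            is.character(structure_id), length(structure_id) == 1L)

  # collapse duplicates to the best score for that molecule
  if (anyDuplicated(molecule_id)) {
    best <- if (lower_is_better) {
      tapply(score, molecule_id, min)
    } else {
      tapply(score, molecule_id, max)
    }
    molecule_id <- names(best)
    score <- as.numeric(best)
  }

  run <- structure(
    list(kinase_id = kinase_id,
         structure_id = structure_id,
         table = data.frame(molecule_id = molecule_id, score = score,
                            stringsAsFactors = FALSE),
         m = length(molecule_id),
         lower_is_better = isTRUE(lower_is_better)),
    class = "docking_run")
  compute_ranks(run)
}

#' Assign deterministic ordinal docking ranks
#'
#' Ranks 1..m are assigned by ascending score (descending when the run was
#' built with \code{lower_is_better = FALSE}). Ties in score are broken by
#' lexicographic molecule identifier, so ranks are a reproducible
#' permutation of 1..m on any platform.
#'
#' @param run a \code{docking_run}.
#' @return The run with its \code{table$rank} column (re)computed and rows
#'   ordered by rank.
#' @export
compute_ranks <- function(run) {
  stopifnot(inherits(run, "docking_run"))
  tab <- run$table
  if (nrow(tab) == 0L) stop("no molecules")
  s <- if (run$lower_is_better) tab$score else -tab$score
  # C locale ordering for reproducibility across platforms
  ord <- order(s, ordered_id(tab$molecule_id))
  tab <- tab[ord, c("molecule_id", "score")]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  run$table <- tab
  run$m <- nrow(tab)
  run
}

# locale-independent string ordering key
ordered_id <- function(x) {
  factor(x, levels = sort(unique(x), method = "radix"))
}

#' Scaled docking rank r/m
#'
#' The scaled rank of a molecule is its ordinal rank divided by the number
#' of molecules docked into that structure, a fraction in (0, 1].
#'
#' @param run a \code{docking_run} with ranks computed.
#' @param molecule_id character vector of molecules to look up.
#' @return numeric vector of r/m values.
#' @examples
#' run <- docking_run(c("a", "b"), c(-5, -9), "EGFR", "1XKK")
#' scaled_rank(run, "b")  # rank 1 of 2 -> 0.5
#' @export
scaled_rank <- function(run, molecule_id) {
  stopifnot(inherits(run, "docking_run"))
  idx <- match(molecule_id, run$table$molecule_id)
  if (anyNA(idx)) {
    stop("not docked in this structure: ",
         paste(molecule_id[is.na(idx)], collapse = ", "))
  }
  run$table$rank[idx] / run$m
}

#' Read a two-column docking score table
#'
#' Reads a molecule/score table in CSV or TSV form (delimiter auto-detected
#' from the first line unless given). A header line is detected by a
#' non-numeric second field. Duplicate molecules keep their best score and
#' deterministic ordinal ranks are assigned.
#'
#' @param path path to a delimited text file with columns
#'   (molecule_id, score).
#' @param kinase_id,structure_id identifiers attached to the run.
#' @param sep field delimiter; \code{NULL} (default) auto-detects
#'   comma vs tab.
#' @param lower_is_better logical, see \code{\link{docking_run}}.
#' @return a \code{docking_run}.
#' @export
read_score_table <- function(path, kinase_id, structure_id, sep = NULL,
                             lower_is_better = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no molecules in ", path)
  if (is.null(sep)) {
    sep <- if (grepl("\t", lines[[1L]], fixed = TRUE)) "\t" else ","
  }
  fields <- strsplit(lines, sep, fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad))
    stop("row ", bad[[1L]], " of ", path, " has fewer than 2 fields")
  first_score <- suppressWarnings(as.numeric(trimws(fields[[1L]][[2L]])))
  if (is.na(first_score)) fields <- fields[-1L]  # header line
  if (length(fields) == 0L) stop("no molecules in ", path)
  ids <- vapply(fields, function(f) trimws(f[[1L]]), character(1))
  raw <- vapply(fields, function(f) trimws(f[[2L]]), character(1))
  scores <- suppressWarnings(as.numeric(raw))
  if (anyNA(scores)) {
    bad <- which(is.na(scores))[[1L]]
    stop("non-numeric score '", raw[[bad]], "' in row ", bad, " of ", path)
  }
  docking_run(ids, scores, kinase_id, structure_id,
              lower_is_better = lower_is_better)
}

#' Write a ranked score table
#'
#' Emits columns molecule_id, score, rank as CSV; re-reading with
#' \code{\link{read_score_table}} reproduces identical ranks.
#'
#' @param run a \code{docking_run}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_ranked_table <- function(run, path) {
  stopifnot(inherits(run, "docking_run"))
  utils::write.csv(run$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a docking-run manifest
#'
#' A manifest maps kinases to structures to score-file paths, as YAML or
#' JSON:
#' \preformatted{
#' EGFR:
#'   1XKK: scores/egfr_1xkk.csv
#'   3POZ: scores/egfr_3poz.csv
#' }
#' Relative paths are resolved against the manifest's directory.
#'
#' @param path manifest file (.yaml/.yml or .json).
#' @param lower_is_better passed to \code{\link{read_score_table}}.
#' @return named list: kinase_id -> list of \code{docking_run}.
#' @export
read_manifest <- function(path, lower_is_better = TRUE) {
  ext <- tolower(tools::file_ext(path))
  spec <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("manifest must be YAML or JSON: ", path)
  }
  base <- dirname(normalizePath(path))
  runs <- lapply(names(spec), function(kin) {
    structs <- spec[[kin]]
    lapply(names(structs), function(st) {
      f <- as.character(structs[[st]])
      if (!file.exists(f)) f <- file.path(base, f)
      if (!file.exists(f)) stop("score file not found: ", structs[[st]])
      read_score_table(f, kin, st, lower_is_better = lower_is_better)
    })
  })
  names(runs) <- names(spec)
  runs
}

#' @export
print.docking_run <- function(x, ...) {
  cat("Docking run:", x$kinase_id, "/", x$structure_id,
      "-", x$m, "molecules\n")
  cat("  best:", x$table$molecule_id[1L],
      sprintf("(score %.4g)", x$table$score[1L]), "\n")
  invisible(x)
}
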