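#' Ingest bioactivity records into a compound-by-kinase activity matrix
#'
#' Applies the filtering and deduplication rules used for ligand-profile
#' comparison of kinases:
#' \itemize{
#'   \item only binding assays reporting an IC50 are kept (both matched
#'     case-insensitively);
#'   \item records carrying a ">" relation qualifier are dropped (the
#'     potency cannot be confirmed); "<" and "=" are taken at face value;
#'   \item malformed records (missing fields, non-positive or missing
#'     values) are rejected and counted;
#'   \item repeated measurements of the same compound against the same
#'     kinase in the same assay keep the lowest IC50 (most active), and
#'     the minimum is likewise taken across assays of the same
#'     compound/kinase pair.
#' }
#'
#' @param records data.frame with columns \code{compound_id},
#'   \code{kinase_id}, \code{assay_id}, \code{assay_class},
#'   \code{activity_type}, \code{value_nM}, and optionally
#'   \code{relation} (one of "=", "<", ">") and \code{units}
#'   ("nM", "uM"/"µM", or "M"; values are converted to nM).
#' @param threshold_nM activity threshold passed to
#'   \code{\link{classify_active}}.
#' @return an object of class \code{activity_matrix}: a list with
#'   \code{values} (data.frame compound_id, kinase_id, value_nM, active),
#'   \code{threshold_nM} and \code{dropped} (named counts of rejected
#'   records).
#' @export
ingest_activities <- function(records, threshold_nM = 500) {
  req <- c("compound_id", "kinase_id", "assay_id", "assay_class",
           "activity_type", "value_nM")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols))
    stop("records missing column(s): ", paste(missing_cols, collapse = ", "))
  rec <- records
  n0 <- nrow(rec)

  dropped <- c(malformed = 0L, wrong_assay_class = 0L,
               wrong_activity_type = 0L, qualifier_gt = 0L,
               unknown_units = 0L)

  # unit conversion first, so value checks run in nM
  if ("units" %in% names(rec)) {
    u <- tolower(trimws(as.character(rec$units)))
    u[u %in% c("µm", "um")] <- "um"
    known <- u %in% c("nm", "um", "m")
    dropped[["unknown_units"]] <- sum(!known)
    rec <- rec[known, , drop = FALSE]
    u <- u[known]
    fac <- c(nm = 1, um = 1e3, m = 1e9)[u]
    rec$value_nM <- rec$value_nM * fac
  }

  val <- suppressWarnings(as.numeric(rec$value_nM))
  ok <- !is.na(val) & val > 0 &
    !is.na(rec$compound_id) & nzchar(as.character(rec$compound_id)) &
    !is.na(rec$kinase_id) & nzchar(as.character(rec$kinase_id)) &
    !is.na(rec$assay_id)
  dropped[["malformed"]] <- sum(!ok)
  rec <- rec[ok, , drop = FALSE]
  rec$value_nM <- val[ok]

  is_binding <- tolower(trimws(rec$assay_class)) == "binding"
  dropped[["wrong_assay_class"]] <- sum(!is_binding)
  rec <- rec[is_binding, , drop = FALSE]

  is_ic50 <- tolower(trimws(rec$activity_type)) == "ic50"
  dropped[["wrong_activity_type"]] <- sum(!is_ic50)
  rec <- rec[is_ic50, , drop = FALSE]

  if ("relation" %in% names(rec)) {
    gt <- trimws(as.character(rec$relation)) == ">"
    dropped[["qualifier_gt"]] <- sum(gt, na.rm = TRUE)
    rec <- rec[!gt | is.na(gt), , drop = FALSE]
  }

  total_dropped <- sum(dropped)
  if (total_dropped > 0L)
    message("ingest_activities: dropped ", total_dropped, " of ", n0,
            " record(s) (",
            paste(names(dropped)[dropped > 0],
                  dropped[dropped > 0], sep = "=", collapse = ", "), ")")

  if (nrow(rec) == 0L) {
    values <- data.frame(compound_id = character(0),
                         kinase_id = character(0),
                         value_nM = numeric(0))
  } else {
    # min within assay, then min across assays == min per compound/kinase
    agg <- stats::aggregate(
      value_nM ~ compound_id + kinase_id,
      data = rec[, c("compound_id", "kinase_id", "value_nM")], FUN = min)
    values <- agg[order(agg$compound_id, agg$kinase_id), ]
    rownames(values) <- NULL
  }
  m <- structure(list(values = values, threshold_nM = NA_real_,
                      dropped = dropped),
                 class = "activity_matrix")
  classify_active(m, threshold_nM)
}

#' Flag tested compound/kinase pairs as active below an IC50 threshold
#'
#' A tested pair is active when its minimum IC50 is strictly below the
#' threshold ("below 500 nM"); the boundary value itself is inactive.
#'
#' @param matrix an \code{activity_matrix}.
#' @param threshold_nM positive threshold in nM (default 500).
#' @return the matrix with its \code{active} column and threshold updated.
#' @export
classify_active <- function(matrix, threshold_nM = 500) {
  stopifnot(inherits(matrix, "activity_matrix"), threshold_nM > 0)
  matrix$values$active <- matrix$values$value_nM < threshold_nM
  matrix$threshold_nM <- threshold_nM
  matrix
}

#' @export
print.activity_matrix <- function(x, ...) {
  v <- x$values
  cat("Activity matrix:", nrow(v), "tested compound-kinase pair(s),",
      length(unique(v$compound_id)), "compound(s),",
      length(unique(v$kinase_id)), "kinase(s)\n")
  cat("  active (<", x$threshold_nM, "nM):", sum(v$active), "\n")
  if (sum(x$dropped) > 0)
    cat("  records dropped at ingest:", sum(x$dropped), "\n")
  invisible(x)
}

#' Promiscuity of a kinase
#'
#' The fraction of compounds tested against a kinase that are active on
#' it — the kinase's ligand-profile self-similarity.
#'
#' @param matrix an \code{activity_matrix}.
#' @param kinase_id kinase to summarise.
#' @return ratio in [0, 1]; \code{NaN} with a warning when nothing was
#'   tested on the kinase.
#' @export
promiscuity <- function(matrix, kinase_id) {
  stopifnot(inherits(matrix, "activity_matrix"))
  v <- matrix$values[matrix$values$kinase_id == kinase_id, ]
  if (nrow(v) == 0L) {
    warning("no compounds tested on ", kinase_id)
    return(NaN)
  }
  sum(v$active) / nrow(v)
}

#' Ligand-profile similarity between two kinases
#'
#' The number of compounds active on both kinases divided by the number of
#' compounds tested on both. For a kinase against itself this reduces to
#' \code{\link{promiscuity}}. Undefined (NaN) when no compound was tested
#' on both kinases.
#'
#' @param matrix an \code{activity_matrix}.
#' @param kinase_a,kinase_b kinase identifiers.
#' @return ratio in [0, 1] or \code{NaN}.
#' @export
ligprof_sim <- function(matrix, kinase_a, kinase_b) {
  stopifnot(inherits(matrix, "activity_matrix"))
  if (kinase_a == kinase_b) return(promiscuity(matrix, kinase_a))
  cnt <- ligprof_pair_counts(matrix, kinase_a, kinase_b)
  if (cnt[["tested_both"]] == 0L) return(NaN)
  cnt[["active_both"]] / cnt[["tested_both"]]
}

ligprof_pair_counts <- function(matrix, kinase_a, kinase_b) {
  v <- matrix$values
  va <- v[v$kinase_id == kinase_a, ]
  vb <- v[v$kinase_id == kinase_b, ]
  tested_both <- intersect(va$compound_id, vb$compound_id)
  active_both <- intersect(va$compound_id[va$active],
                           vb$compound_id[vb$active])
  c(tested_both = length(tested_both), active_both = length(active_both))
}

#' Ligand-profile similarity matrix with companion counts
#'
#' @param matrix an \code{activity_matrix}.
#' @param kinases kinase identifiers to compare (default: all kinases in
#'   the matrix, sorted).
#' @return a \code{\link{similarity_matrix}} (measure "LigProfSim") whose
#'   attributes \code{"kinase_counts"} (kinase, actives, tested) and
#'   \code{"pair_counts"} (kinase_a, kinase_b, tested_both, active_both)
#'   carry the underlying counts.
#' @export
ligprof_matrix <- function(matrix, kinases = NULL) {
  stopifnot(inherits(matrix, "activity_matrix"))
  if (is.null(kinases))
    kinases <- sort(unique(matrix$values$kinase_id), method = "radix")
  stopifnot(length(kinases) >= 1L)
  n <- length(kinases)
  mat <- matrix(NaN, n, n, dimnames = list(kinases, kinases))
  pair_counts <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      mat[i, j] <- mat[j, i] <- ligprof_sim(matrix, kinases[[i]], kinases[[j]])
      if (i < j) {
        cnt <- ligprof_pair_counts(matrix, kinases[[i]], kinases[[j]])
        pair_counts[[length(pair_counts) + 1L]] <- data.frame(
          kinase_a = kinases[[i]], kinase_b = kinases[[j]],
          tested_both = cnt[["tested_both"]],
          active_both = cnt[["active_both"]],
          stringsAsFactors = FALSE)
      }
    }
  }
  v <- matrix$values
  kin_counts <- do.call(rbind, lapply(kinases, function(k) {
    vk <- v[v$kinase_id == k, ]
    data.frame(kinase = k, actives = sum(vk$active), tested = nrow(vk),
               stringsAsFactors = FALSE)
  }))
  out <- similarity_matrix(mat, measure_name = "LigProfSim",
                           range = c(0, 1))
  attr(out, "kinase_counts") <- kin_counts
  attr(out, "pair_counts") <- if (length(pair_counts))
    do.call(rbind, pair_counts) else
    data.frame(kinase_a = character(0), kinase_b = character(0),
               tested_both = integer(0), active_both = integer(0))
  out
}

#' Render an activity matrix back into bioactivity records
#'
#' Inverse of \code{\link{ingest_activities}} up to the information the
#' matrix retains (one minimum-IC50 binding record per tested pair), so
#' ingestion is idempotent.
#'
#' @param matrix an \code{activity_matrix}.
#' @return data.frame of records acceptable to
#'   \code{\link{ingest_activities}}.
#' @export
activity_records <- function(matrix) {
  stopifnot(inherits(matrix, "activity_matrix"))
  v <- matrix$values
  data.frame(compound_id = v$compound_id, kinase_id = v$kinase_id,
             assay_id = paste0("assay_", v$kinase_id),
             assay_class = "binding", activity_type = "IC50",
             value_nM = v$value_nM, stringsAsFactors = FALSE)
}
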