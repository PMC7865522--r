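POCKET_LENGTH <- 85L
IFP_TYPES <- 7L
IFP_LENGTH <- POCKET_LENGTH * IFP_TYPES  # 595 bits, residue-major
POCKET_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "-")

#' Validate an 85-residue pocket sequence
#'
#' The ATP-binding pocket of protein kinases is described by a fixed
#' 85-position alignment; sequences must be exactly 85 characters over the
#' 20 standard one-letter amino-acid codes, 'X', and the gap symbol '-'.
#'
#' @param residues single string of length 85.
#' @param kinase_id kinase label.
#' @return an object of class \code{pocket_sequence}.
#' @export
pocket_sequence <- function(residues, kinase_id) {
  residues <- toupper(as.character(residues))
  stopifnot(length(residues) == 1L)
  if (nchar(residues) != POCKET_LENGTH)
    stop("pocket sequence must have length ", POCKET_LENGTH,
         " (got ", nchar(residues), ")")
  chars <- strsplit(residues, "")[[1]]
  bad <- setdiff(chars, POCKET_ALPHABET)
  if (length(bad))
    stop("invalid residue symbol(s): ", paste(unique(bad), collapse = ", "))
  structure(list(kinase_id = kinase_id, residues = residues),
            class = "pocket_sequence")
}

#' @export
print.pocket_sequence <- function(x, ...) {
  cat("Pocket sequence", x$kinase_id, "(85 aa):\n ", x$residues, "\n")
  invisible(x)
}

#' Pocket-sequence identity between two kinases
#'
#' The fraction of the 85 alignment positions at which both sequences
#' carry the same residue. A gap matches nothing — not even another gap —
#' since no residue is present to be identical.
#'
#' @param a,b \code{pocket_sequence} objects (or bare 85-character
#'   strings).
#' @return identity fraction in [0, 1].
#' @export
poc_seq_sim <- function(a, b) {
  if (!inherits(a, "pocket_sequence")) a <- pocket_sequence(a, "a")
  if (!inherits(b, "pocket_sequence")) b <- pocket_sequence(b, "b")
  ca <- strsplit(a$residues, "")[[1]]
  cb <- strsplit(b$residues, "")[[1]]
  sum(ca == cb & ca != "-") / POCKET_LENGTH
}

#' Pairwise pocket-sequence identity matrix
#'
#' @param sequences list of \code{pocket_sequence} objects with unique
#'   kinase ids.
#' @return a \code{\link{similarity_matrix}} (measure "PocSeqSim").
#' @export
poc_seq_matrix <- function(sequences) {
  ids <- vapply(sequences, function(s) s$kinase_id, character(1))
  stopifnot(!anyDuplicated(ids))
  n <- length(ids)
  mat <- matrix(1, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        mat[i, j] <- mat[j, i] <- poc_seq_sim(sequences[[i]], sequences[[j]])
      }
    }
  }
  for (i in seq_len(n)) mat[i, i] <- poc_seq_sim(sequences[[i]], sequences[[i]])
  similarity_matrix(mat, measure_name = "PocSeqSim", range = c(0, 1))
}

#' Read pocket sequences from FASTA
#'
#' Record identifiers become kinase ids; each sequence must be exactly 85
#' residues long.
#'
#' @param path FASTA file.
#' @return list of \code{pocket_sequence} objects.
#' @export
read_pocket_fasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1L)
  lapply(seq_along(seqs), function(i) {
    pocket_sequence(as.character(seqs[[i]]), ids[[i]])
  })
}

#' Interaction-fingerprint records
#'
#' One row per KLIFS-style structure entry: a 595-bit interaction
#' fingerprint (85 pocket residues x 7 interaction types, residue-major
#' bit order), a 0-10 structure/alignment quality score, whether the bound
#' ligand is orthosteric, and the DFG / alphaC conformation annotations.
#'
#' @param structure_key entry identifier: PDB id plus a chain or
#'   alternate-model discriminator, e.g. \code{"3POZ_A"}. The PDB id is
#'   the part before the first \code{"_"} or \code{"/"} unless a
#'   \code{pdb_id} is given.
#' @param kinase_id kinase label per entry.
#' @param bits character vector of 595-character 0/1 strings, or a logical
#'   matrix with 595 columns.
#' @param quality numeric in [0, 10].
#' @param orthosteric logical.
#' @param dfg,alpha_c conformation annotations ("in", "out", "out-like").
#' @param pdb_id optional explicit PDB id per entry.
#' @return data.frame of class \code{ifp_records}.
#' @export
ifp_records <- function(structure_key, kinase_id, bits, quality,
                        orthosteric = TRUE, dfg = "in", alpha_c = "in",
                        pdb_id = NULL) {
  if (is.matrix(bits)) {
    stopifnot(ncol(bits) == IFP_LENGTH)
    bits <- apply(bits, 1L, function(b) paste(as.integer(b), collapse = ""))
  }
  bits <- as.character(bits)
  if (any(nchar(bits) != IFP_LENGTH))
    stop("IFP bit strings must have length ", IFP_LENGTH)
  if (any(grepl("[^01]", bits))) stop("IFP bit strings must be 0/1")
  if (any(quality < 0 | quality > 10)) stop("quality must lie in [0, 10]")
  if (is.null(pdb_id)) pdb_id <- sub("[_/].*$", "", structure_key)
  df <- data.frame(structure_key = as.character(structure_key),
                   kinase_id = as.character(kinase_id),
                   pdb_id = as.character(pdb_id),
                   quality = as.numeric(quality),
                   orthosteric = as.logical(orthosteric),
                   dfg = as.character(dfg),
                   alpha_c = as.character(alpha_c),
                   ifp = bits,
                   stringsAsFactors = FALSE)
  class(df) <- c("ifp_records", "data.frame")
  df
}

#' Read interaction-fingerprint records from TSV
#'
#' Expected columns: structure_key, kinase_id, quality, orthosteric
#' (0/1 or TRUE/FALSE), dfg, alpha_c, ifp (595-character 0/1 string);
#' optional pdb_id.
#'
#' @param path TSV file.
#' @return \code{\link{ifp_records}}.
#' @export
read_ifp_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(ifp = "character"))
  req <- c("structure_key", "kinase_id", "quality", "orthosteric",
           "dfg", "alpha_c", "ifp")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("IFP table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  ifp_records(df$structure_key, df$kinase_id, df$ifp, df$quality,
              orthosteric = as.logical(as.integer(as.logical(df$orthosteric))),
              dfg = df$dfg, alpha_c = df$alpha_c,
              pdb_id = if ("pdb_id" %in% names(df)) df$pdb_id else NULL)
}

#' Write interaction-fingerprint records to TSV
#' @param records \code{\link{ifp_records}}.
#' @param path output path.
#' @return \code{path} invisibly.
#' @export
write_ifp_table <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter structure entries for fingerprint comparison
#'
#' Drops entries whose ligand is not orthosteric; where one PDB structure
#' is represented by several chain/alternate-model entries, keeps only the
#' entry with the highest quality score, breaking quality ties by the
#' lexicographically smallest structure key so the result does not depend
#' on input order. Optional DFG / alphaC conformation filters.
#'
#' @param records \code{\link{ifp_records}}.
#' @param dfg,alpha_c optional conformation values to keep (e.g.
#'   \code{"in"}); \code{NULL} (default) keeps all.
#' @return filtered \code{ifp_records}, ordered by structure key, with at
#'   most one entry per PDB structure.
#' @export
filter_structures <- function(records, dfg = NULL, alpha_c = NULL) {
  stopifnot(inherits(records, "ifp_records"))
  df <- as.data.frame(records)
  df <- df[df$orthosteric, , drop = FALSE]
  if (!is.null(dfg)) df <- df[df$dfg %in% dfg, , drop = FALSE]
  if (!is.null(alpha_c)) df <- df[df$alpha_c %in% alpha_c, , drop = FALSE]
  if (nrow(df) > 0L) {
    # highest quality per PDB structure; ties -> smallest structure_key
    ord <- order(df$pdb_id, -df$quality,
                 ordered_id(df$structure_key), method = "radix")
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(df$pdb_id), , drop = FALSE]
    df <- df[order(ordered_id(df$structure_key)), , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("ifp_records", "data.frame")
  df
}

ifp_bits <- function(s) as.integer(strsplit(s, "")[[1]]) == 1L

#' Tanimoto similarity of two binary fingerprints
#'
#' |a AND b| / |a OR b|. When both fingerprints are all-zero the
#' similarity is defined as 0 (an empty interaction pattern shares
#' nothing) and a warning is raised, since filtered data should not
#' contain interaction-free structures.
#'
#' @param a,b logical vectors of equal length, or 0/1 bit strings.
#' @return similarity in [0, 1].
#' @export
tanimoto <- function(a, b) {
  if (is.character(a)) a <- ifp_bits(a)
  if (is.character(b)) b <- ifp_bits(b)
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b))
    stop("fingerprint length mismatch: ", length(a), " vs ", length(b))
  u <- sum(a | b)
  if (u == 0L) {
    warning("both fingerprints are all-zero; Tanimoto defined as 0")
    return(0)
  }
  sum(a & b) / u
}

#' Kinase-level interaction-fingerprint similarity matrix
#'
#' For each kinase pair, the maximum Tanimoto similarity over all
#' cross-kinase structure pairs. The diagonal is the best match among
#' distinct structures of the same kinase, and \code{NaN} for kinases
#' with fewer than two structures.
#'
#' @param records \code{\link{ifp_records}}; filtered with
#'   \code{\link{filter_structures}} first unless
#'   \code{apply_filter = FALSE}.
#' @param kinases kinases to compare (default: all in \code{records},
#'   sorted); kinases without structures get \code{NaN} rows with a
#'   warning.
#' @param apply_filter run \code{\link{filter_structures}} internally
#'   (default \code{TRUE}).
#' @return a \code{\link{similarity_matrix}} (measure "IFPSim").
#' @export
ifp_sim_matrix <- function(records, kinases = NULL, apply_filter = TRUE) {
  stopifnot(inherits(records, "ifp_records"))
  if (apply_filter) records <- filter_structures(records)
  df <- as.data.frame(records)
  if (is.null(kinases))
    kinases <- sort(unique(df$kinase_id), method = "radix")
  empty <- setdiff(kinases, df$kinase_id)
  if (length(empty))
    warning("no structures for kinase(s): ", paste(empty, collapse = ", "))
  bits <- lapply(df$ifp, ifp_bits)
  by_kin <- split(seq_len(nrow(df)), df$kinase_id)
  n <- length(kinases)
  mat <- matrix(NaN, n, n, dimnames = list(kinases, kinases))
  for (i in seq_len(n)) {
    for (j in i:n) {
      ia <- by_kin[[kinases[[i]]]]
      ib <- by_kin[[kinases[[j]]]]
      if (is.null(ia) || is.null(ib)) next
      best <- NaN
      for (a in ia) {
        for (b in ib) {
          if (i == j && b <= a) next
          t <- tanimoto(bits[[a]], bits[[b]])
          if (is.nan(best) || t > best) best <- t
        }
      }
      mat[i, j] <- mat[j, i] <- best
    }
  }
  similarity_matrix(mat, measure_name = "IFPSim", range = c(0, 1))
}
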