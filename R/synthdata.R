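# deterministic per-stream sub-seeds: every generator draws from its own
# stream keyed by (base seed, label), so adding a kinase or structure does
# not perturb the values generated for the others
stream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(as.character(label)) *
             (seq_len(nchar(as.character(label))) %% 31L + 1L))
  as.integer((as.numeric(seed) * 10007 + h * 97) %% 2147483399)
}

#' Simulate docking runs with controlled rank correlation
#'
#' Emulates score lists from structure-based virtual screening with a
#' latent-affinity model: each molecule has a standard-normal reference
#' affinity; each kinase's latent affinity mixes the reference with an
#' independent normal at correlation \code{rho_lat}; each structure's
#' docking score adds independent noise on top of the kinase latent.
#' Lower scores are better. Two structures generated at
#' \code{rho_lat = 1, noise_sd = 0} produce identical orderings; at
#' \code{rho_lat = 0} their top-list rank correlation is centred on 0.
#'
#' @param n_molecules number of molecules docked (>= 2).
#' @param kinase_plan named list, one entry per kinase:
#'   \code{list(n_structures =, rho_lat =, noise_sd =)}; \code{rho_lat}
#'   in [-1, 1], \code{noise_sd >= 0} (default 0.3).
#' @param seed integer seed; fixed seed gives identical output.
#' @return named list: kinase_id -> list of \code{\link{docking_run}}.
#' @examples
#' runs <- simulate_docking_runs(100,
#'   list(EGFR = list(n_structures = 2, rho_lat = 0.9)), seed = 1)
#' dockrank_sim(runs$EGFR[[1]], runs$EGFR[[2]], n = 50)
#' @export
simulate_docking_runs <- function(n_molecules, kinase_plan, seed = 1L) {
  stopifnot(n_molecules >= 2, length(kinase_plan) >= 1L,
            !is.null(names(kinase_plan)))
  ids <- sprintf("mol%06d", seq_len(n_molecules))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(stream_seed(seed, "reference"))
  ref <- stats::rnorm(n_molecules)
  out <- lapply(names(kinase_plan), function(kin) {
    plan <- kinase_plan[[kin]]
    rho <- if (is.null(plan$rho_lat)) 1 else plan$rho_lat
    if (rho < -1 || rho > 1) stop("rho_lat must lie in [-1, 1]")
    noise_sd <- if (is.null(plan$noise_sd)) 0.3 else plan$noise_sd
    n_struct <- if (is.null(plan$n_structures)) 1L else plan$n_structures
    set.seed(stream_seed(seed, paste0("kinase:", kin)))
    latent <- rho * ref + sqrt(1 - rho^2) * stats::rnorm(n_molecules)
    lapply(seq_len(n_struct), function(s) {
      set.seed(stream_seed(seed, paste0("structure:", kin, ":", s)))
      score <- latent + noise_sd * stats::rnorm(n_molecules)
      docking_run(ids, score, kin, sprintf("%s_s%d", kin, s))
    })
  })
  names(out) <- names(kinase_plan)
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a bioactivity table with planned counts or rates
#'
#' Exact-count mode builds a record table whose per-kinase
#' (actives, tested) counts and per-pair (active on both, tested on both)
#' counts equal the plan exactly, so promiscuity and ligand-profile
#' similarity reproduce the planned ratios by construction. Compounds used
#' to satisfy pair counts are tested on both kinases of the pair (active
#' ones at 100 nM on both, the rest at 1000 nM on both); the remaining
#' marginal counts are filled with kinase-private compounds. Stochastic
#' mode draws per-compound Bernoulli tested/active indicators.
#'
#' @param plan for \code{mode = "exact"}: list with \code{kinases}, a
#'   data.frame (kinase_id, tested, active), and optionally \code{pairs},
#'   a data.frame (kinase_a, kinase_b, tested_both, active_both). For
#'   \code{mode = "stochastic"}: list with \code{n_compounds} and
#'   \code{kinases}, a data.frame (kinase_id, p_tested, p_active).
#' @param mode \code{"exact"} (default) or \code{"stochastic"}.
#' @param seed integer seed (used by the stochastic mode and for IC50
#'   jitter-free reproducibility).
#' @return data.frame of bioactivity records suitable for
#'   \code{\link{ingest_activities}}.
#' @export
simulate_activity_table <- function(plan, mode = c("exact", "stochastic"),
                                    seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(plan$kinases), nrow(plan$kinases) >= 1L)
  if (mode == "stochastic") return(simulate_activity_stochastic(plan, seed))

  kin <- plan$kinases
  stopifnot(all(c("kinase_id", "tested", "active") %in% names(kin)))
  if (any(kin$active > kin$tested))
    stop("infeasible plan: actives exceed tested for ",
         paste(kin$kinase_id[kin$active > kin$tested], collapse = ", "))
  pairs <- plan$pairs
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    stopifnot(all(c("kinase_a", "kinase_b", "tested_both",
                    "active_both") %in% names(pairs)))
    if (any(pairs$active_both > pairs$tested_both))
      stop("infeasible plan: pair actives exceed pair tested")
  } else {
    pairs <- data.frame(kinase_a = character(0), kinase_b = character(0),
                        tested_both = integer(0), active_both = integer(0))
  }
  pair_tested_of <- function(k)
    sum(pairs$tested_both[pairs$kinase_a == k | pairs$kinase_b == k])
  pair_active_of <- function(k)
    sum(pairs$active_both[pairs$kinase_a == k | pairs$kinase_b == k])
  for (k in kin$kinase_id) {
    t_k <- kin$tested[kin$kinase_id == k]
    a_k <- kin$active[kin$kinase_id == k]
    if (pair_tested_of(k) > t_k || pair_active_of(k) > a_k ||
        (a_k - pair_active_of(k)) > (t_k - pair_tested_of(k)))
      stop("infeasible plan: pair counts exceed marginals for ", k)
  }

  active_value <- 100    # nM, well below the 500 nM threshold
  inactive_value <- 1000
  recs <- list()
  cid <- 0L
  next_ids <- function(n) {
    ids <- sprintf("cpd%07d", cid + seq_len(n))
    cid <<- cid + n
    ids
  }
  add <- function(compound_id, kinase_id, value) {
    if (length(compound_id) == 0L) return()
    recs[[length(recs) + 1L]] <<- data.frame(
      compound_id = compound_id, kinase_id = kinase_id,
      assay_id = paste0("assay_", kinase_id), assay_class = "binding",
      activity_type = "IC50", value_nM = value, stringsAsFactors = FALSE)
  }

  if (nrow(pairs) > 0L) {
    for (p in seq_len(nrow(pairs))) {
      ids <- next_ids(pairs$tested_both[p])
      n_act <- pairs$active_both[p]
      vals <- c(rep(active_value, n_act),
                rep(inactive_value, pairs$tested_both[p] - n_act))
      add(ids, pairs$kinase_a[p], vals)
      add(ids, pairs$kinase_b[p], vals)
    }
  }
  for (k in kin$kinase_id) {
    t_priv <- kin$tested[kin$kinase_id == k] - pair_tested_of(k)
    a_priv <- kin$active[kin$kinase_id == k] - pair_active_of(k)
    ids <- next_ids(t_priv)
    add(ids, k, c(rep(active_value, a_priv),
                  rep(inactive_value, t_priv - a_priv)))
  }
  if (length(recs) == 0L)
    return(data.frame(compound_id = character(0), kinase_id = character(0),
                      assay_id = character(0), assay_class = character(0),
                      activity_type = character(0), value_nM = numeric(0)))
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

simulate_activity_stochastic <- function(plan, seed) {
  kin <- plan$kinases
  stopifnot(all(c("kinase_id", "p_tested", "p_active") %in% names(kin)),
            all(kin$p_tested >= 0 & kin$p_tested <= 1),
            all(kin$p_active >= 0 & kin$p_active <= 1),
            plan$n_compounds >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  ids <- sprintf("cpd%07d", seq_len(plan$n_compounds))
  recs <- lapply(kin$kinase_id, function(k) {
    set.seed(stream_seed(seed, paste0("activity:", k)))
    tested <- stats::runif(plan$n_compounds) <
      kin$p_tested[kin$kinase_id == k]
    n_t <- sum(tested)
    if (n_t == 0L) return(NULL)
    active <- stats::runif(n_t) < kin$p_active[kin$kinase_id == k]
    data.frame(compound_id = ids[tested], kinase_id = k,
               assay_id = paste0("assay_", k), assay_class = "binding",
               activity_type = "IC50",
               value_nM = ifelse(active, 100, 1000),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  if (is.null(out))
    out <- data.frame(compound_id = character(0), kinase_id = character(0),
                      assay_id = character(0), assay_class = character(0),
                      activity_type = character(0), value_nM = numeric(0))
  rownames(out) <- NULL
  out
}

#' Simulate pocket sequences with exact mutation counts
#'
#' Derives one 85-residue pocket sequence per kinase from a common base
#' sequence by mutating exactly the planned number of positions, each to a
#' residue different from the base at that position. The identity between
#' the base and a derived sequence is therefore exactly (85 - k)/85.
#'
#' @param mutations named integer vector: kinase_id -> number of mutated
#'   positions (0..85).
#' @param base optional 85-character base sequence; random (gap-free) when
#'   \code{NULL}.
#' @param seed integer seed.
#' @return named list of \code{\link{pocket_sequence}} objects; the base
#'   is attached as attribute \code{"base"}.
#' @export
simulate_pocket_sequences <- function(mutations, base = NULL, seed = 1L) {
  stopifnot(!is.null(names(mutations)), all(mutations >= 0))
  if (any(mutations > POCKET_LENGTH))
    stop("mutation count exceeds ", POCKET_LENGTH)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  aa <- setdiff(POCKET_ALPHABET, c("X", "-"))
  if (is.null(base)) {
    set.seed(stream_seed(seed, "base_sequence"))
    base <- paste(sample(aa, POCKET_LENGTH, replace = TRUE), collapse = "")
  }
  base_seq <- pocket_sequence(base, "base")
  out <- lapply(names(mutations), function(kin) {
    chars <- strsplit(base_seq$residues, "")[[1]]
    k <- mutations[[kin]]
    if (k > 0) {
      set.seed(stream_seed(seed, paste0("sequence:", kin)))
      pos <- sample.int(POCKET_LENGTH, k)
      for (p in pos) chars[p] <- sample(setdiff(aa, chars[p]), 1L)
    }
    pocket_sequence(paste(chars, collapse = ""), kin)
  })
  names(out) <- names(mutations)
  attr(out, "base") <- base_seq
  out
}

#' Simulate interaction fingerprints with bit-flip noise
#'
#' Each kinase gets a reference 595-bit fingerprint drawn at the base bit
#' density from a common template; each structure's fingerprint flips
#' every bit independently at the planned rate. A flip rate of 0 makes all
#' of a kinase's structures identical (pairwise Tanimoto 1); higher rates
#' decrease the expected pairwise Tanimoto monotonically.
#'
#' @param kinase_plan named list, one entry per kinase:
#'   \code{list(n_structures =, flip_rate =)} with flip_rate in [0, 1].
#' @param base_density probability that a template bit is set, in (0, 1).
#' @param seed integer seed.
#' @return \code{\link{ifp_records}} with one entry per structure
#'   (quality drawn in [5, 10], orthosteric, DFG-in).
#' @export
simulate_ifps <- function(kinase_plan, base_density = 0.15, seed = 1L) {
  stopifnot(length(kinase_plan) >= 1L, !is.null(names(kinase_plan)),
            base_density > 0, base_density < 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(stream_seed(seed, "ifp_template"))
  template <- stats::runif(IFP_LENGTH) < base_density
  recs <- lapply(names(kinase_plan), function(kin) {
    plan <- kinase_plan[[kin]]
    flip <- if (is.null(plan$flip_rate)) 0.05 else plan$flip_rate
    if (flip < 0 || flip > 1) stop("flip_rate must lie in [0, 1]")
    n_struct <- if (is.null(plan$n_structures)) 1L else plan$n_structures
    set.seed(stream_seed(seed, paste0("ifp_kinase:", kin)))
    kin_base <- xor(template, stats::runif(IFP_LENGTH) < 0.02)
    do.call(rbind, lapply(seq_len(n_struct), function(s) {
      set.seed(stream_seed(seed, paste0("ifp:", kin, ":", s)))
      bits <- xor(kin_base, stats::runif(IFP_LENGTH) < flip)
      ifp_records(structure_key = sprintf("%s%02d_A", kin, s),
                  kinase_id = kin,
                  bits = paste(as.integer(bits), collapse = ""),
                  quality = round(stats::runif(1, 5, 10), 1))
    }))
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  class(out) <- c("ifp_records", "data.frame")
  out
}

#' Write a full synthetic input bundle to disk
#'
#' Materialises every synthetic input in its on-disk exchange format:
#' per-structure score CSVs plus a YAML manifest, a bioactivity CSV, a
#' pocket-sequence FASTA and an IFP TSV. Re-reading the files with the
#' package's readers reproduces the in-memory objects.
#'
#' @param config list with elements \code{seed}, \code{n_molecules},
#'   \code{kinase_plan} (docking), \code{activity_plan},
#'   \code{sequence_plan} (named mutation counts) and \code{ifp_plan};
#'   any of the plans may be omitted to skip that output.
#' @param out_dir output directory (created if needed).
#' @return named list of written paths, invisibly.
#' @export
write_simulation_bundle <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else config$seed
  paths <- list()
  if (!is.null(config$kinase_plan)) {
    runs <- simulate_docking_runs(config$n_molecules, config$kinase_plan,
                                  seed = seed)
    manifest <- list()
    for (kin in names(runs)) {
      manifest[[kin]] <- list()
      for (run in runs[[kin]]) {
        f <- file.path(out_dir,
                       sprintf("scores_%s.csv", run$structure_id))
        write_ranked_table(run, f)
        manifest[[kin]][[run$structure_id]] <- basename(f)
      }
    }
    paths$manifest <- file.path(out_dir, "runs.yaml")
    yaml::write_yaml(manifest, paths$manifest)
  }
  if (!is.null(config$activity_plan)) {
    recs <- simulate_activity_table(config$activity_plan,
                                    mode = if (is.null(config$activity_plan$mode))
                                      "exact" else config$activity_plan$mode,
                                    seed = seed)
    paths$activities <- file.path(out_dir, "activities.csv")
    utils::write.csv(recs, paths$activities, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(config$sequence_plan)) {
    seqs <- simulate_pocket_sequences(unlist(config$sequence_plan),
                                      seed = seed)
    paths$sequences <- file.path(out_dir, "pockets.fasta")
    writeLines(unlist(lapply(seqs, function(s)
      c(paste0(">", s$kinase_id), s$residues))), paths$sequences)
  }
  if (!is.null(config$ifp_plan)) {
    ifps <- simulate_ifps(config$ifp_plan,
                          base_density = if (is.null(config$ifp_density))
                            0.15 else config$ifp_density,
                          seed = seed)
    paths$ifps <- file.path(out_dir, "ifps.tsv")
    write_ifp_table(ifps, paths$ifps)
  }
  invisible(paths)
}
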