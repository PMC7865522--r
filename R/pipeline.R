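#' Run the full profiling pipeline from a config file
#'
#' Orchestrates the stages requested in a single YAML (or JSON) config:
#' optional synthetic-bundle generation, profile scoring, and the four
#' similarity matrices, followed by per-kinase summaries and pairwise
#' cross-measure correlations. All outputs are CSV; a JSON run report
#' records the seed, the stages run and the dropped/undefined counts.
#'
#' Config layout (stages are independent; omit a block to skip it):
#' \preformatted{
#' seed: 1
#' simulate:            # write_simulation_bundle() config
#'   n_molecules: 2000
#'   kinase_plan: {EGFR: {n_structures: 2, rho_lat: 0.9}}
#' score_profile:
#'   manifest: runs.yaml
#'   profile:
#'     profile_id: profile1
#'     members: [{kinase: EGFR, role: target}]
#'     log_base: 10
#'   top_k: 500
#' docksim:   {manifest: runs.yaml, top_n: 25000}
#' ligprofsim: {activities: activities.csv}
#' pocseqsim: {fasta: pockets.fasta}
#' ifpsim:    {ifps: ifps.tsv}
#' summaries: true
#' compare: true
#' }
#' Relative input paths are resolved against \code{out_dir} first, then
#' against the config file's directory.
#'
#' @param config path to a YAML/JSON config file, or an equivalent list.
#' @param out_dir output directory (default \code{"."}; overrides an
#'   \code{out_dir} entry in the config).
#' @return named list of the objects produced per stage, invisibly; side
#'   effect: CSV/JSON files under \code{out_dir}.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg_dir <- "."
  if (is.character(config)) {
    cfg_dir <- dirname(normalizePath(config))
    ext <- tolower(tools::file_ext(config))
    config <- if (ext == "json") jsonlite::read_json(config,
                                                     simplifyVector = TRUE)
              else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(out_dir)) out_dir <- if (!is.null(config$out_dir))
    config$out_dir else "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  resolve <- function(path) {
    for (p in c(path, file.path(out_dir, path), file.path(cfg_dir, path))) {
      if (file.exists(p)) return(p)
    }
    stop("input file not found: ", path)
  }

  report <- list(seed = seed, stages = character(0),
                 package_version = as.character(utils::packageVersion("profiledock")))
  results <- list()
  matrices <- list()

  if (!is.null(config$simulate)) {
    sim_cfg <- config$simulate
    sim_cfg$seed <- seed
    results$simulate <- write_simulation_bundle(sim_cfg, out_dir)
    report$stages <- c(report$stages, "simulate")
  }

  if (!is.null(config$score_profile)) {
    sp <- config$score_profile
    runs <- read_manifest(resolve(sp$manifest))
    members <- do.call(rbind, lapply(sp$profile$members, function(m)
      data.frame(kinase_id = m$kinase, role = m$role,
                 stringsAsFactors = FALSE)))
    structures <- lapply(runs, function(rr)
      vapply(rr, function(r) r$structure_id, character(1)))
    spec <- profile_spec(members, structures[members$kinase_id],
                         profile_id = if (is.null(sp$profile$profile_id))
                           "profile" else sp$profile$profile_id,
                         log_base = if (is.null(sp$profile$log_base)) 10
                                    else sp$profile$log_base)
    ranking <- rank_by_profile(runs, spec)
    top_k <- if (is.null(sp$top_k)) 500L else as.integer(sp$top_k)
    utils::write.csv(utils::head(as.data.frame(ranking), top_k),
                     file.path(out_dir, paste0(spec$profile_id,
                                               "_ranking.csv")),
                     row.names = FALSE)
    results$score_profile <- ranking
    report$profile_molecules_scored <- nrow(ranking)
    report$profile_molecules_dropped <- attr(ranking, "n_dropped")
    report$stages <- c(report$stages, "score_profile")
  }

  if (!is.null(config$docksim)) {
    runs <- read_manifest(resolve(config$docksim$manifest))
    top_n <- if (is.null(config$docksim$top_n)) 25000L
             else as.integer(config$docksim$top_n)
    mat <- kinase_dockrank_matrix(runs, n = top_n)
    write_similarity_matrix(mat, file.path(out_dir, "dockranksim.csv"))
    utils::write.csv(attr(mat, "pairs"),
                     file.path(out_dir, "dockrank_overlaps.csv"),
                     row.names = FALSE)
    matrices$DockRankSim <- mat
    report$stages <- c(report$stages, "docksim")
  }

  if (!is.null(config$ligprofsim)) {
    recs <- utils::read.csv(resolve(config$ligprofsim$activities),
                            stringsAsFactors = FALSE)
    am <- ingest_activities(recs)
    mat <- ligprof_matrix(am)
    write_similarity_matrix(mat, file.path(out_dir, "ligprofsim.csv"))
    utils::write.csv(attr(mat, "kinase_counts"),
                     file.path(out_dir, "ligprof_counts.csv"),
                     row.names = FALSE)
    utils::write.csv(attr(mat, "pair_counts"),
                     file.path(out_dir, "ligprof_pair_counts.csv"),
                     row.names = FALSE)
    matrices$LigProfSim <- mat
    report$activity_records_dropped <- sum(am$dropped)
    report$stages <- c(report$stages, "ligprofsim")
  }

  if (!is.null(config$pocseqsim)) {
    seqs <- read_pocket_fasta(resolve(config$pocseqsim$fasta))
    mat <- poc_seq_matrix(seqs)
    write_similarity_matrix(mat, file.path(out_dir, "pocseqsim.csv"))
    matrices$PocSeqSim <- mat
    report$stages <- c(report$stages, "pocseqsim")
  }

  if (!is.null(config$ifpsim)) {
    recs <- read_ifp_table(resolve(config$ifpsim$ifps))
    recs <- filter_structures(recs, dfg = config$ifpsim$dfg,
                              alpha_c = config$ifpsim$alpha_c)
    mat <- ifp_sim_matrix(recs, apply_filter = FALSE)
    write_similarity_matrix(mat, file.path(out_dir, "ifpsim.csv"))
    matrices$IFPSim <- mat
    report$stages <- c(report$stages, "ifpsim")
  }

  results$matrices <- matrices

  if (isTRUE(config$summaries) && length(matrices)) {
    summaries <- lapply(matrices, summarize_similarity)
    for (nm in names(summaries)) {
      utils::write.csv(summaries[[nm]],
                       file.path(out_dir,
                                 paste0("summary_", tolower(nm), ".csv")),
                       row.names = FALSE)
    }
    results$summaries <- summaries
    report$stages <- c(report$stages, "summaries")
  }

  if (isTRUE(config$compare) && length(matrices) >= 2L) {
    nms <- names(matrices)
    cmp <- list()
    for (i in seq_len(length(nms) - 1L)) {
      for (j in (i + 1L):length(nms)) {
        res <- tryCatch(compare_measures(matrices[[i]], matrices[[j]]),
                        error = function(e) list(r = NaN, p_value = NaN,
                                                 n_pairs = 0L,
                                                 n_dropped = NA_integer_))
        cmp[[length(cmp) + 1L]] <- data.frame(
          measure_a = nms[[i]], measure_b = nms[[j]],
          r = res$r, p_value = res$p_value, n_pairs = res$n_pairs,
          stringsAsFactors = FALSE)
      }
    }
    cmp <- do.call(rbind, cmp)
    utils::write.csv(cmp, file.path(out_dir, "measure_correlations.csv"),
                     row.names = FALSE)
    results$compare <- cmp
    report$stages <- c(report$stages, "compare")
  }

  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
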