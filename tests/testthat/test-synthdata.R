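test_that("docking-run generation is deterministic and stream-split", {
  plan <- list(A = list(n_structures = 2, rho_lat = 0.8),
               B = list(n_structures = 1, rho_lat = 0.3))
  r1 <- simulate_docking_runs(100, plan, seed = 5)
  r2 <- simulate_docking_runs(100, plan, seed = 5)
  expect_identical(r1$A[[1]]$table, r2$A[[1]]$table)
  expect_identical(r1$B[[1]]$table, r2$B[[1]]$table)

  # adding a kinase leaves existing kinases' runs untouched
  r3 <- simulate_docking_runs(100, c(plan, list(
    C = list(n_structures = 1, rho_lat = 0.5))), seed = 5)
  expect_identical(r3$A[[1]]$table, r1$A[[1]]$table)
  expect_identical(r3$B[[1]]$table, r1$B[[1]]$table)

  expect_error(simulate_docking_runs(
    10, list(A = list(n_structures = 1, rho_lat = 1.5)), seed = 1),
    "rho_lat")
})

test_that("perfectly correlated noise-free structures rank identically", {
  runs <- simulate_docking_runs(
    500, list(K = list(n_structures = 2, rho_lat = 1, noise_sd = 0)),
    seed = 2)
  expect_equal(dockrank_sim(runs$K[[1]], runs$K[[2]], n = 100), 1.0)
  expect_equal(dockrank_sim(runs$K[[1]], runs$K[[2]], n = 500), 1.0)
})

test_that("uncorrelated runs give rank correlations centred near zero", {
  vals <- vapply(1:50, function(s) {
    runs <- simulate_docking_runs(
      400, list(R = list(n_structures = 1, rho_lat = 1, noise_sd = 0),
                K = list(n_structures = 1, rho_lat = 0, noise_sd = 0)),
      seed = s)
    dockrank_sim(runs$R[[1]], runs$K[[1]], n = 400)
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.05)
})

test_that("exact-count activity tables hit planned ratios exactly", {
  plan <- list(
    kinases = data.frame(kinase_id = c("EGFR", "BRAF"),
                         tested = c(5702, 3625),
                         active = c(3382, 2968)),
    pairs = data.frame(kinase_a = "EGFR", kinase_b = "BRAF",
                       tested_both = 180, active_both = 13))
  am <- ingest_activities(simulate_activity_table(plan))
  expect_equal(round(promiscuity(am, "EGFR"), 2), 0.59)
  expect_equal(round(promiscuity(am, "BRAF"), 2), 0.82)
  expect_equal(ligprof_sim(am, "EGFR", "BRAF"), 13 / 180)

  # infeasible plans error out before emitting records
  bad <- plan
  bad$pairs$active_both <- 200
  expect_error(simulate_activity_table(bad), "infeasible")
  bad2 <- list(kinases = data.frame(kinase_id = "K", tested = 5,
                                    active = 9))
  expect_error(simulate_activity_table(bad2), "infeasible")

  empty <- simulate_activity_table(
    list(kinases = data.frame(kinase_id = "K", tested = 0L, active = 0L)))
  expect_equal(nrow(empty), 0L)
})

test_that("stochastic activity tables track their Bernoulli rates", {
  plan <- list(n_compounds = 4000,
               kinases = data.frame(kinase_id = c("A", "B"),
                                    p_tested = c(0.5, 0.3),
                                    p_active = c(0.6, 0.8)))
  recs <- simulate_activity_table(plan, mode = "stochastic", seed = 9)
  expect_identical(recs,
                   simulate_activity_table(plan, mode = "stochastic",
                                           seed = 9))
  am <- ingest_activities(recs)
  expect_equal(promiscuity(am, "A"), 0.6, tolerance = 0.05)
  expect_equal(promiscuity(am, "B"), 0.8, tolerance = 0.05)
})

test_that("pocket sequences carry exact mutation counts", {
  seqs <- simulate_pocket_sequences(c(A = 0L, B = 9L, C = 85L), seed = 6)
  base <- attr(seqs, "base")
  expect_equal(poc_seq_sim(base, seqs$A), 1.0)
  expect_equal(poc_seq_sim(base, seqs$B), 76 / 85)
  expect_equal(poc_seq_sim(base, seqs$C), 0.0)
  expect_error(simulate_pocket_sequences(c(A = 86L)), "exceeds")

  again <- simulate_pocket_sequences(c(A = 0L, B = 9L, C = 85L), seed = 6)
  expect_identical(seqs$B$residues, again$B$residues)
})

test_that("IFP generation is deterministic with monotone flip-rate decay", {
  recs <- simulate_ifps(list(K = list(n_structures = 2, flip_rate = 0)),
                        seed = 3)
  expect_equal(tanimoto(recs$ifp[1], recs$ifp[2]), 1.0)
  expect_identical(
    recs$ifp,
    simulate_ifps(list(K = list(n_structures = 2, flip_rate = 0)),
                  seed = 3)$ifp)
  expect_error(simulate_ifps(list(K = list(n_structures = 1,
                                           flip_rate = 1.2))),
               "flip_rate")

  mean_tani <- vapply(c(0.01, 0.1, 0.3), function(fr) {
    vals <- vapply(1:30, function(s) {
      r <- simulate_ifps(list(K = list(n_structures = 2, flip_rate = fr)),
                         seed = s)
      tanimoto(r$ifp[1], r$ifp[2])
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(mean_tani) < 0))
})

test_that("simulation bundles round-trip through the package readers", {
  dir <- withr::local_tempdir()
  config <- list(
    seed = 17, n_molecules = 200,
    kinase_plan = list(A = list(n_structures = 2, rho_lat = 0.9),
                       B = list(n_structures = 1, rho_lat = 0.4)),
    activity_plan = list(
      kinases = data.frame(kinase_id = c("A", "B"),
                           tested = c(50, 40), active = c(20, 10)),
      pairs = data.frame(kinase_a = "A", kinase_b = "B",
                         tested_both = 10, active_both = 4)),
    sequence_plan = c(A = 5L, B = 20L),
    ifp_plan = list(A = list(n_structures = 2, flip_rate = 0.05),
                    B = list(n_structures = 1, flip_rate = 0.1)))
  paths <- write_simulation_bundle(config, dir)

  runs <- read_manifest(paths$manifest)
  expect_named(runs, c("A", "B"))
  mem <- simulate_docking_runs(200, config$kinase_plan, seed = 17)
  expect_equal(runs$A[[1]]$table$rank, mem$A[[1]]$table$rank)
  expect_identical(runs$A[[1]]$table$molecule_id,
                   mem$A[[1]]$table$molecule_id)

  am <- ingest_activities(utils::read.csv(paths$activities))
  expect_equal(ligprof_sim(am, "A", "B"), 0.4)

  seqs <- read_pocket_fasta(paths$sequences)
  expect_length(seqs, 2L)
  ifps <- read_ifp_table(paths$ifps)
  expect_equal(nrow(ifps), 3L)

  # byte-identical re-run under the same seed
  dir2 <- withr::local_tempdir()
  paths2 <- write_simulation_bundle(config, dir2)
  for (nm in names(paths)) {
    expect_identical(readLines(paths[[nm]]), readLines(paths2[[nm]]))
  }
})
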