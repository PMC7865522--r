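test_that("per-kinase aggregation takes best structure and inverts anti-targets", {
  ids <- sprintf("m%02d", 1:10)
  run <- make_run(ids, 1:10)  # rank == index
  expect_equal(aggregate_kinase_rank(list(run), "m01", "target"), -1)

  runs2 <- list(make_run(sprintf("m%03d", 1:100), 1:100),
                make_run(sprintf("m%03d", c(5, 1:4, 6:100)), 1:100,
                         structure = "S2"))
  # m005 ranks 5/100 in S1 but 1/100 in S2: min rule keeps 0.01
  p <- aggregate_kinase_rank(runs2, "m005", "target")
  expect_equal(p, log10(0.01))

  # two structures, ranks 50 and 5 of 100: min-then-log
  ids2 <- sprintf("m%03d", append(setdiff(1:100, 50), 50, after = 4))
  runsA <- list(make_run(sprintf("m%03d", 1:100), 1:100),
                make_run(ids2, 1:100, structure = "S2"))
  expect_equal(aggregate_kinase_rank(runsA, "m050", "target"),
               log10(0.05), tolerance = 1e-12)

  # anti-target: worst rank r = m = 10 maps to 1 - (r-1)/m = 1/10
  expect_equal(aggregate_kinase_rank(list(run), "m10", "anti_target"), -1)
  # anti-target: best rank r = 1 maps to 1 -> P = 0
  expect_equal(aggregate_kinase_rank(list(run), "m01", "anti_target"), 0)

  expect_error(aggregate_kinase_rank(list(run), "absent", "target"),
               "no rank")
})

test_that("profile score is mean plus half the spread", {
  expect_equal(profile_score(-1), -1)
  expect_equal(profile_score(c(-1, -1, -1)), -1)
  P <- c(-1, -0.6990, -1)
  expect_equal(profile_score(P), mean(P) + (max(P) - min(P)) / 2)
  expect_equal(profile_score(P), -0.7492, tolerance = 1e-4)
  expect_error(profile_score(numeric(0)))
  expect_error(profile_score(c(-1, Inf)))
})

test_that("profile score is translation-equivariant, permutation-invariant, and penalises spread", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(2:8, 1)
    P <- -abs(rnorm(n))
    cst <- rnorm(1)
    expect_equal(profile_score(P + cst), profile_score(P) + cst,
                 tolerance = 1e-12)
    expect_equal(profile_score(sample(P)), profile_score(P),
                 tolerance = 1e-12)
  }
  # improving the already-best component by delta raises S by
  # |delta| * (1/2 - 1/N) when N >= 3
  for (i in 1:100) {
    n <- sample(3:8, 1)
    P <- -abs(rnorm(n)) - 0.01
    delta <- abs(rnorm(1)) + 0.01
    P2 <- P
    P2[which.min(P)] <- min(P) - delta
    expect_equal(profile_score(P2) - profile_score(P),
                 delta * (1 / 2 - 1 / n), tolerance = 1e-10)
    expect_gt(profile_score(P2), profile_score(P))
  }
})

test_that("single-target profiles rank exactly like the docking run", {
  set.seed(3)
  run <- make_run(sprintf("m%03d", 1:50), rnorm(50))
  spec <- profile_spec(c(EGFR = "target"), list(EGFR = "S1"))
  ranking <- rank_by_profile(list(EGFR = list(run)), spec)
  expect_identical(ranking$molecule_id, run$table$molecule_id)
  expect_identical(ranking$profile_rank, run$table$rank)
})

test_that("molecule ordering by S is invariant to the log base", {
  set.seed(19)
  for (i in 1:10) {
    runs <- simulate_docking_runs(80, list(
      A = list(n_structures = 2, rho_lat = 0.8),
      B = list(n_structures = 1, rho_lat = 0.5),
      C = list(n_structures = 1, rho_lat = 0.2)), seed = i)
    members <- data.frame(kinase_id = c("A", "B", "C"),
                          role = c("target", "target", "anti_target"))
    structs <- lapply(runs, function(rr)
      vapply(rr, function(r) r$structure_id, character(1)))
    orderings <- lapply(c(2, 10, exp(1)), function(base) {
      spec <- profile_spec(members, structs, log_base = base)
      rank_by_profile(runs, spec)$molecule_id
    })
    expect_identical(orderings[[1]], orderings[[2]])
    expect_identical(orderings[[2]], orderings[[3]])
  }
})

test_that("anti-target component strictly improves as docking rank worsens", {
  m <- 50
  run <- make_run(sprintf("m%03d", 1:m), 1:m)
  P <- vapply(sprintf("m%03d", 1:m), function(id)
    aggregate_kinase_rank(list(run), id, "anti_target"), numeric(1))
  expect_true(all(diff(P) < 0))
  expect_true(all(P <= 0))
})

test_that("adding a worse structure never changes the aggregated rank", {
  set.seed(23)
  for (i in 1:20) {
    ids <- sprintf("m%03d", 1:30)
    r1 <- make_run(ids, rnorm(30))
    r2 <- make_run(ids, rnorm(30), structure = "S2")
    for (role in c("target", "anti_target")) {
      id <- sample(ids, 1)
      best <- aggregate_kinase_rank(list(r1, r2), id, role)
      # a run where the molecule is ranked last is never better
      worst <- make_run(c(setdiff(ids, id), id),
                        c(rnorm(29), 100), structure = "S3")
      expect_equal(aggregate_kinase_rank(list(r1, r2, worst), id, role),
                   best, tolerance = 1e-12)
    }
  }
})

test_that("full profile table matches a brute-force evaluation", {
  set.seed(5)
  runs <- simulate_docking_runs(10, list(
    EGFR = list(n_structures = 2, rho_lat = 0.9, noise_sd = 0.5),
    ErbB2 = list(n_structures = 1, rho_lat = 0.7, noise_sd = 0.5),
    BRAF = list(n_structures = 2, rho_lat = 0.1, noise_sd = 0.5)),
    seed = 99)
  members <- data.frame(kinase_id = c("EGFR", "ErbB2", "BRAF"),
                        role = c("target", "target", "anti_target"))
  structs <- lapply(runs, function(rr)
    vapply(rr, function(r) r$structure_id, character(1)))
  spec <- profile_spec(members, structs)
  ranking <- rank_by_profile(runs, spec)
  oracle <- brute_force_profile_scores(runs, members)
  expect_equal(unname(oracle[ranking$molecule_id]), ranking$S,
               tolerance = 1e-12)
  expect_false(is.unsorted(ranking$S))
})

test_that("coverage rule drops molecules missing from a member kinase", {
  runs <- list(
    T1 = list(make_run(c("a", "b", "c"), c(-3, -2, -1))),
    T2 = list(make_run(c("a", "b"), c(-2, -1), kinase = "T2")))
  spec <- profile_spec(c(T1 = "target", T2 = "anti_target"),
                       list(T1 = "S1", T2 = "S1"))
  expect_message(ranking <- rank_by_profile(runs, spec), "dropped")
  expect_setequal(ranking$molecule_id, c("a", "b"))
  expect_equal(attr(ranking, "n_dropped"), 1L)

  # missing-as-worst imputation keeps the molecule with rank m + 1
  imputed <- rank_by_profile(runs, spec, missing_as_worst = TRUE)
  expect_setequal(imputed$molecule_id, c("a", "b", "c"))
})

test_that("expected profile hit rate multiplies independent per-kinase rates", {
  expect_equal(round(expected_profile_hit_rate(c(0.25, 0.25, 0.90)), 3),
               0.056)
  expect_equal(expected_profile_hit_rate(1), 1)
  expect_equal(expected_profile_hit_rate(c(0.4, 0, 0.9)), 0)
  expect_error(expected_profile_hit_rate(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(expected_profile_hit_rate(numeric(0)))
})
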