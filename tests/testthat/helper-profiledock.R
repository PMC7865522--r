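# shared fixtures and independent oracles

# docking run from parallel vectors with defaults
make_run <- function(ids, scores, kinase = "KIN", structure = "S1") {
  docking_run(ids, scores, kinase, structure)
}

# independent Spearman oracle for tie-free permutations:
# rho = 1 - 6 * sum(d^2) / (k (k^2 - 1))
spearman_d2 <- function(ra, rb) {
  k <- length(ra)
  1 - 6 * sum((ra - rb)^2) / (k * (k^2 - 1))
}

# enumerate all permutations of 1..n (n small)
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  idx <- 0L
  for (p in sub) {
    for (pos in seq_len(n)) {
      idx <- idx + 1L
      out[[idx]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# brute-force profile score: direct transcription of the combined-score
# definition, evaluated per molecule with plain loops
brute_force_profile_scores <- function(runs_by_kinase, members, log_base = 10) {
  ids <- Reduce(intersect, lapply(members$kinase_id, function(k) {
    Reduce(union, lapply(runs_by_kinase[[k]],
                         function(r) r$table$molecule_id))
  }))
  sapply(ids, function(id) {
    P <- numeric(0)
    for (i in seq_len(nrow(members))) {
      k <- members$kinase_id[i]
      vals <- c()
      for (run in runs_by_kinase[[k]]) {
        hit <- run$table[run$table$molecule_id == id, ]
        if (nrow(hit) == 0) next
        vals <- c(vals, if (members$role[i] == "target")
          hit$rank / run$m else 1 - (hit$rank - 1) / run$m)
      }
      if (length(vals) == 0) return(NA_real_)
      R <- if (members$role[i] == "target") min(vals) else max(vals)
      P <- c(P, log(R, base = log_base))
    }
    mean(P) + (max(P) - min(P)) / 2
  })
}

# random 85-mer over the 20 standard residues
random_pocket <- function() {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 85,
               replace = TRUE), collapse = "")
}
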