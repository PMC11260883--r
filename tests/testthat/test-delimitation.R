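test_that("all-zero distances yield only the singleton and one-cluster partitions", {
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  parts <- candidate_partitions(fake_k2p_matrix(d))
  expect_length(parts, 2)
  expect_equal(parts[[1]]$n_clusters, 4)
  expect_equal(parts[[2]]$n_clusters, 1)
})

test_that("single linkage recovers two tight groups at the separating height", {
  ids <- paste0("s", 1:6)
  d <- matrix(0.10, 6, 6, dimnames = list(ids, ids))
  within <- matrix(runif(36, 0, 0.01), 6)
  within <- (within + t(within)) / 2
  d[1:3, 1:3] <- within[1:3, 1:3]
  d[4:6, 4:6] <- within[4:6, 4:6]
  diag(d) <- 0
  parts <- candidate_partitions(fake_k2p_matrix(d))
  two <- Filter(function(p) p$n_clusters == 2, parts)
  expect_length(two, 1)
  expect_equal(two[[1]]$cut_height, 0.10)
  asg <- two[[1]]$assignment
  expect_equal(length(unique(asg[1:3])), 1)
  expect_equal(length(unique(asg[4:6])), 1)
  expect_false(asg[["s1"]] == asg[["s4"]])
  # one partition per distinct merge height, plus the singleton partition
  hc <- hclust(as.dist(d), method = "single")
  expect_length(parts, length(unique(hc$height)) + 1)
})

test_that("relative gap width W follows the stated formula and is scale-invariant", {
  m <- two_cluster_matrix()  # within 0.01, between 0.10, overall mean 0.055
  p <- new_partition_for_test(c(a = 1, b = 1, c = 1, d = 2))
  s <- score_partition(p, m, n_perm = 49, seed = 1)
  expect_equal(s$w, (0.10 - 0.01) / 0.055)
  m2 <- fake_k2p_matrix(m$d * 3)
  s2 <- score_partition(p, m2, n_perm = 49, seed = 1)
  expect_equal(s2$w, s$w)
})

test_that("panmixia probability hits the floor for perfect separation and stays high for noise", {
  set.seed(71)
  sim <- simulate_genus(sim_config(n_species = 2, haplotypes_per_species = 5,
                                   intra_depth = 0.005, inter_depth = 0.2,
                                   sampling_counts = 1), seed = 3)
  ds <- sim$dataset
  m <- pairwise_matrix(ds)
  truth_part <- new_partition_for_test(
    stats::setNames(as.integer(factor(ds$species)), ds$ids))
  s <- score_partition(truth_part, m, n_perm = 99, seed = 2)
  # at the floor up to chance re-draws of the observed grouping itself
  # (probability 2/choose(10,5) per permutation)
  expect_lte(s$p_panmixia, 4 / 100)

  # structureless data: random labels should rarely look structured
  lows <- 0L
  for (i in 1:20) {
    root <- sample(NT, 300, replace = TRUE)
    seqs <- t(vapply(1:10, function(k) {
      s <- root; pos <- sample(300, 30)
      s[pos] <- sample(NT, 30, replace = TRUE)
      s
    }, character(300)))
    rownames(seqs) <- sprintf("s%02d", 1:10)
    mm <- pairwise_matrix(seqs)
    lab <- stats::setNames(rep(1:2, 5), rownames(seqs))
    sc <- score_partition(new_partition_for_test(lab), mm,
                          n_perm = 99, seed = i)
    if (sc$p_panmixia < 0.05) lows <- lows + 1L
  }
  expect_lte(lows, 2)  # >= 90% of seeds stay above 0.05
})

test_that("ranking averages the two metric ranks and breaks ties toward fewer species", {
  mk_score <- function(k, w, p) {
    asg <- stats::setNames(rep(seq_len(k), length.out = 10),
                           sprintf("s%02d", 1:10))
    structure(list(partition = new_partition_for_test(asg),
                   n_clusters = as.integer(k), w = w, p_panmixia = p,
                   cut_height = NA_real_),
              class = "partition_score")
  }
  scores <- list(mk_score(4, 0.8, 0.01), mk_score(7, 0.8, 0.01),
                 mk_score(2, 0.1, 0.50))
  out <- rank_partitions(scores)
  expect_equal(out$ranking$score[1], out$ranking$score[2])  # tied pair first
  expect_equal(out$selected$n_clusters, 4)                  # fewer clusters

  # near-singleton partitions are excluded from selection
  scores2 <- list(mk_score(10, 2.0, 0.001), mk_score(3, 0.5, 0.2))
  out2 <- rank_partitions(scores2, plausibility_cap = 0.9)
  expect_equal(out2$selected$n_clusters, 3)
  expect_error(rank_partitions(list(mk_score(10, 1, 0.1))), "plausibility")
})

test_that("partitions round-trip through TSV and import is validated", {
  asg <- stats::setNames(c(1L, 1L, 2L, 2L, 3L), paste0("q", 1:5))
  p <- new_partition_for_test(asg)
  f <- tempfile(fileext = ".tsv")
  write_partition(p, f)
  back <- import_partition(f, ids = paste0("q", 1:5))
  expect_equal(back$assignment, p$assignment)
  expect_equal(back$n_clusters, 3)
  expect_error(import_partition(f, ids = paste0("q", 1:6)), "missing")
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("id\tcluster", "q1\t1", "q1\t2"), bad)
  expect_error(import_partition(bad), "duplicate")
})

test_that("masked pairs block delimitation with advice", {
  d <- matrix(0.1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(d) <- 0
  app <- matrix(TRUE, 3, 3); app[1, 2] <- app[2, 1] <- FALSE
  expect_error(candidate_partitions(fake_k2p_matrix(d, app)),
               "inapplicable")
})

test_that("well-separated simulated species are recovered by the selected partition", {
  hits <- 0L
  n_rep <- 100L
  for (i in seq_len(n_rep)) {
    sim <- simulate_genus(sim_config(n_species = 5, haplotypes_per_species = 4,
                                     intra_depth = 0.01, inter_depth = 0.05,
                                     sampling_counts = 1), seed = 5000 + i)
    ds <- sim$dataset
    m <- pairwise_matrix(ds)
    if (m$n_masked > 0) next
    res <- delimit_species(m, n_perm = 49, seed = i)
    sel <- res$selected$assignment[ds$ids]
    truth <- as.integer(factor(unname(ds$species)))
    # compare as partitions (label-invariant)
    same <- outer(sel, sel, "==") == outer(truth, truth, "==")
    if (all(same)) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})
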