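test_that("k2p_distance matches the closed form on hand-built cases", {
  a <- rep("A", 100)
  expect_equal(k2p_distance(a, a),
               list(d = 0, P = 0, Q = 0, sites = 100L, applicable = TRUE))

  # 10 transitions out of 100 sites, no transversions
  b <- a; b[1:10] <- "G"
  r <- k2p_distance(a, b)
  expect_equal(r$P, 0.1)
  expect_equal(r$Q, 0)
  expect_equal(r$d, -0.5 * log(0.8))

  # saturation: P = 0.25, Q = 0.5 makes 1 - 2Q = 0
  cc <- rep(c("A", "A", "A", "A"), 25)
  dd <- cc; dd[1:25] <- "G"; dd[26:75] <- "C"
  r2 <- k2p_distance(cc, dd)
  expect_equal(r2$P, 0.25)
  expect_equal(r2$Q, 0.5)
  expect_false(r2$applicable)
  expect_true(is.na(r2$d))

  expect_error(k2p_distance(rep("A", 5), rep("A", 6)), "equal length")
})

test_that("k2p_distance is symmetric and only counts unambiguous sites", {
  set.seed(31)
  for (i in 1:20) {
    a <- sample(c(NT, "N", "-", "R"), 60, replace = TRUE,
                prob = c(rep(0.22, 4), 0.05, 0.05, 0.02))
    b <- sample(c(NT, "N", "-", "R"), 60, replace = TRUE,
                prob = c(rep(0.22, 4), 0.05, 0.05, 0.02))
    r1 <- k2p_distance(a, b); r2 <- k2p_distance(b, a)
    expect_identical(r1, r2)
    expect_equal(r1$sites, sum(a %in% NT & b %in% NT))
    if (r1$applicable) {
      # substitution correction can only stretch the observed p-distance
      expect_gte(r1$d, r1$P + r1$Q - 1e-12)
    }
  }
})

test_that("pairwise_matrix equals per-pair recomputation and the ape oracle", {
  set.seed(32)
  root <- sample(NT, 200, replace = TRUE)
  seqs <- t(vapply(1:10, function(i) {
    s <- root
    pos <- sample(200, 25)
    s[pos] <- sample(NT, 25, replace = TRUE)
    s
  }, character(200)))
  rownames(seqs) <- sprintf("s%02d", 1:10)
  seqs[1, 1:40] <- "N"          # missing block
  seqs[2, 50:60] <- "-"
  seqs[3, 100] <- "R"           # partial ambiguity: not a comparable site
  m <- pairwise_matrix(seqs)
  for (i in 1:9) for (j in (i + 1):10) {
    expect_equal(m$d[i, j], oracle_k2p(seqs[i, ], seqs[j, ]))
  }
  # independent implementation: ape's K80 with pairwise deletion
  d_ape <- as.matrix(ape::dist.dna(ape::as.DNAbin(seqs), model = "K80",
                                   pairwise.deletion = TRUE))
  expect_equal(m$d[upper.tri(m$d)], d_ape[upper.tri(d_ape)],
               tolerance = 1e-12)
})

test_that("masked pairs are excluded from species summaries", {
  d <- matrix(c(0, 0.02, NA,
                0.02, 0, 0.05,
                NA, 0.05, 0), 3, 3,
              dimnames = list(c("x1", "x2", "y1"), c("x1", "x2", "y1")))
  app <- !is.na(d)
  m <- fake_k2p_matrix(d, app)
  s <- summarize_by_species(m, c(x1 = "x", x2 = "x", y1 = "y"))
  expect_equal(s$n_masked_skipped, 1)
  expect_equal(s$inter$n_pairs, 1)       # only the applicable inter pair
  expect_equal(s$inter$mean_inter, 0.05)
  expect_equal(s$intra$max_intra[s$intra$species == "x"], 0.02)
})

test_that("species summaries match brute-force enumeration", {
  set.seed(33)
  species <- rep(paste0("sp", 1:4), each = 3)
  sim <- simulate_genus(sim_config(n_species = 4, haplotypes_per_species = 3,
                                   seq_length = 120, intra_depth = 0.02,
                                   inter_depth = 0.08, sampling_counts = 1),
                        seed = 33)
  seqs <- sim$dataset$seqs
  rownames(seqs) <- sprintf("s%02d", 1:12)
  names(species) <- rownames(seqs)
  m <- pairwise_matrix(seqs)
  s <- summarize_by_species(m, species)
  # brute force over all pairs
  for (sp in unique(species)) {
    ids <- names(species)[species == sp]
    prs <- t(combn(ids, 2))
    dv <- mapply(function(i, j) oracle_k2p(seqs[i, ], seqs[j, ]),
                 prs[, 1], prs[, 2])
    expect_equal(s$intra$mean_intra[s$intra$species == sp], mean(dv))
    expect_equal(s$intra$max_intra[s$intra$species == sp], max(dv))
  }
  pr <- s$inter[s$inter$species_a == "sp1" & s$inter$species_b == "sp2", ]
  dv <- as.vector(outer(1:3, 4:6, Vectorize(function(i, j)
    oracle_k2p(seqs[i, ], seqs[j, ]))))
  expect_equal(pr$mean_inter, mean(dv))
  expect_equal(pr$min_inter, min(dv))
})

test_that("single-sequence species are flagged with zero intra statistics", {
  set.seed(34)
  seqs <- random_seq_matrix(4, 50)
  s <- summarize_by_species(pairwise_matrix(seqs),
                            c(s01 = "a", s02 = "a", s03 = "a", s04 = "b"))
  b <- s$intra[s$intra$species == "b", ]
  expect_true(b$singleton)
  expect_equal(b$n_intra_pairs, 0)
  expect_equal(b$max_intra, 0)
})

test_that("haplotype multiplicities reproduce the all-sequence statistics", {
  set.seed(35)
  # build an NS dataset by duplicating haplotypes, and an NH view + weights
  haps <- random_seq_matrix(6, 80, ids = paste0("h", 1:6))
  w <- c(h1 = 3L, h2 = 1L, h3 = 2L, h4 = 4L, h5 = 1L, h6 = 2L)
  species_h <- c(h1 = "a", h2 = "a", h3 = "a", h4 = "b", h5 = "b", h6 = "b")
  idx <- rep(1:6, w)
  ns <- haps[idx, , drop = FALSE]
  rownames(ns) <- sprintf("r%02d", seq_len(nrow(ns)))
  species_s <- stats::setNames(species_h[idx], rownames(ns))
  s_ns <- summarize_by_species(pairwise_matrix(ns), species_s)
  s_w <- summarize_by_species(pairwise_matrix(haps), species_h, weights = w)
  expect_equal(s_w$intra$mean_intra, s_ns$intra$mean_intra)
  expect_equal(s_w$intra$max_intra, s_ns$intra$max_intra)
  expect_equal(s_w$intra$n_intra_pairs, s_ns$intra$n_intra_pairs)
  expect_equal(s_w$inter$mean_inter, s_ns$inter$mean_inter)
  expect_equal(s_w$inter$min_inter, s_ns$inter$min_inter)
})

test_that("a shared haplotype forces a zero minimum interspecific distance", {
  set.seed(36)
  seqs <- random_seq_matrix(6, 60)
  seqs[4, ] <- seqs[1, ]  # species b carries a copy of species a's haplotype
  species <- stats::setNames(rep(c("a", "b"), each = 3), rownames(seqs))
  s <- summarize_by_species(pairwise_matrix(seqs), species)
  expect_equal(s$inter$min_inter, 0)
})
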