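# Shared fixture builders; everything is generated in code.

NT <- c("A", "C", "G", "T")

random_seq_matrix <- function(n, L, ids = sprintf("s%02d", seq_len(n))) {
  m <- matrix(sample(NT, n * L, replace = TRUE), n, L)
  rownames(m) <- ids
  m
}

# A matrix whose rows are copies of `base` with the given substitutions
# applied; subs is a list of (row, site, char).
seq_with_subs <- function(base, n, subs = list(),
                          ids = sprintf("s%02d", seq_len(n))) {
  m <- matrix(rep(base, each = n), n, length(base))
  for (s in subs) m[s[[1]], s[[2]]] <- s[[3]]
  rownames(m) <- ids
  m
}

# Write a dataset to temp FASTA + metadata files; returns the two paths.
write_fixture_files <- function(seqs, genus, species) {
  fa <- tempfile(fileext = ".fasta")
  tsv <- tempfile(fileext = ".tsv")
  lines <- as.vector(rbind(paste0(">", rownames(seqs)),
                           apply(seqs, 1L, paste, collapse = "")))
  writeLines(lines, fa)
  writeLines(c("id\tgenus\tspecies",
               paste(rownames(seqs), genus, species, sep = "\t")), tsv)
  list(fasta = fa, metadata = tsv)
}

# Small two-species dataset with known distances for summary oracles.
two_cluster_matrix <- function() {
  # 3 + 1 points: within pairs at 0.01, between pairs at 0.10
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["a", "c"] <- d["b", "c"] <- 0.01
  d["a", "d"] <- d["b", "d"] <- d["c", "d"] <- 0.10
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  fake_k2p_matrix(d)
}

# Wrap a plain symmetric matrix as a k2p_matrix (for stages that only read
# d/applicable/ids).
fake_k2p_matrix <- function(d, applicable = NULL) {
  ids <- rownames(d)
  if (is.null(applicable)) {
    applicable <- matrix(TRUE, nrow(d), ncol(d), dimnames = dimnames(d))
  }
  structure(list(ids = ids, d = d, applicable = applicable,
                 sites = matrix(1L, nrow(d), ncol(d)),
                 n_masked = sum(!applicable[upper.tri(applicable)])),
            class = "k2p_matrix")
}

# Build a species_distance_summary directly from stated per-species /
# per-pair values (for gap-rule tests that do not need sequences).
fake_summary <- function(intra_means, inter_means, max_intra = intra_means,
                         min_inter = inter_means) {
  sp <- names(intra_means) %||% paste0("sp", seq_along(intra_means))
  pairs <- t(utils::combn(sp, 2))[seq_along(inter_means), , drop = FALSE]
  structure(list(
    intra = data.frame(species = sp, n_units = 2L, n_intra_pairs = 1L,
                       mean_intra = unname(intra_means),
                       max_intra = unname(max_intra), singleton = FALSE,
                       stringsAsFactors = FALSE),
    inter = data.frame(species_a = pairs[, 1], species_b = pairs[, 2],
                       n_pairs = 1L, mean_inter = unname(inter_means),
                       min_inter = unname(min_inter),
                       stringsAsFactors = FALSE),
    pooled_intra = data.frame(species = sp, d = unname(intra_means),
                              weight = 1),
    pooled_inter = data.frame(species_a = pairs[, 1],
                              species_b = pairs[, 2],
                              d = unname(inter_means), weight = 1),
    n_masked_skipped = 0L), class = "species_distance_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force K2P for oracle comparisons (character level,
# written without reference to the package internals).
oracle_k2p <- function(a, b) {
  ok <- a %in% NT & b %in% NT
  A <- a[ok]; B <- b[ok]
  if (!length(A)) return(NA_real_)
  pur <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  ts <- sum(A != B & pur[A] == pur[B])
  tv <- sum(A != B & pur[A] != pur[B])
  P <- ts / length(A); Q <- tv / length(A)
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) return(NA_real_)
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

# Build a partition object from a named assignment vector (via the package's
# internal constructor, so cluster ids are canonicalized the same way).
new_partition_for_test <- function(asg) barcodegap:::new_partition(asg)
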