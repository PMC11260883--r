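#' Configuration for simulating a genus of COI-like sequences
#'
#' Describes a star phylogeny: a genus root sequence, species ancestors at
#' expected depth `inter_depth` (substitutions/site) from the root, and
#' haplotypes at expected depth `intra_depth` from their species ancestor,
#' all evolved under a two-rate (transition/transversion) Markov substitution
#' process with rate ratio `kappa` — the generating process of the K2P
#' distance, so the estimator is model-consistent with the simulator.
#' Redundant sampling (`sampling_counts`) makes the total sequence count
#' exceed the haplotype count; `shared_haplotype_pairs` copies a haplotype
#' verbatim between two species (forcing a minimum interspecific distance of
#' zero, as seen when congeners share barcodes); `missing_end_fraction`
#' blanks leading/trailing blocks of some sequences, emulating untrimmed
#' alignment ends.
#'
#' @param genus Genus label (default `"Simulus"`).
#' @param n_species Number of species (default 5).
#' @param seq_length Alignment length in bp (default 600).
#' @param kappa Transition/transversion rate ratio (default 2.0).
#' @param intra_depth Expected substitutions/site from species ancestor to
#'   each haplotype (default 0.01).
#' @param inter_depth Expected substitutions/site from genus root to each
#'   species ancestor (default 0.05).
#' @param haplotypes_per_species Integer, recycled across species
#'   (default 8).
#' @param sampling_counts Per-haplotype multiplicities: `NULL` (default)
#'   draws `1 + rpois(lambda = 1)` per haplotype, an integer vector is
#'   recycled across haplotypes, and a `function(n)` is called to produce
#'   `n` counts.
#' @param shared_haplotype_pairs List of length-2 integer vectors
#'   `c(donor_species, recipient_species)`; the recipient's first haplotype
#'   becomes a verbatim copy of the donor's first haplotype.
#' @param missing_end_fraction Fraction of sequences given missing (`N`)
#'   leading and trailing blocks (default 0; each block is up to 10% of the
#'   alignment).
#' @param seed Optional integer default seed for [simulate_genus()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(genus = "Simulus", n_species = 5, seq_length = 600,
                       kappa = 2.0, intra_depth = 0.01, inter_depth = 0.05,
                       haplotypes_per_species = 8, sampling_counts = NULL,
                       shared_haplotype_pairs = NULL,
                       missing_end_fraction = 0, seed = NULL) {
  stopifnot(n_species >= 1, seq_length >= 1, kappa > 0,
            intra_depth >= 0, inter_depth >= 0,
            all(haplotypes_per_species >= 1),
            missing_end_fraction >= 0, missing_end_fraction <= 1)
  hps <- rep_len(as.integer(haplotypes_per_species), n_species)
  if (!is.null(shared_haplotype_pairs)) {
    for (pr in shared_haplotype_pairs) {
      if (length(pr) != 2L || any(pr < 1) || any(pr > n_species) ||
          pr[1] == pr[2]) {
        stop("each shared haplotype pair must name two distinct species ",
             "indices in 1..n_species", call. = FALSE)
      }
    }
  }
  if (!is.null(sampling_counts) && !is.function(sampling_counts)) {
    sampling_counts <- as.integer(sampling_counts)
    stopifnot(all(sampling_counts >= 1L))
  }
  structure(list(genus = genus, n_species = as.integer(n_species),
                 seq_length = as.integer(seq_length), kappa = kappa,
                 intra_depth = intra_depth, inter_depth = inter_depth,
                 haplotypes_per_species = hps,
                 sampling_counts = sampling_counts,
                 shared_haplotype_pairs = shared_haplotype_pairs,
                 missing_end_fraction = missing_end_fraction,
                 seed = seed),
            class = "sim_config")
}

# Two-rate (K80) substitution: evolve one sequence over branch length t
# expected substitutions/site. Transition rate kappa*beta, each transversion
# rate beta, scaled so the total substitution rate is 1 per unit t.
evolve_sequence <- function(parent, t, kappa) {
  L <- length(parent)
  if (t == 0) return(parent)
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e_tv <- exp(-4 * beta * t)
  e_ts <- exp(-2 * (alpha + beta) * t)
  p_ts <- 0.25 + 0.25 * e_tv - 0.5 * e_ts
  p_tv <- 0.25 - 0.25 * e_tv      # each of the two transversion targets
  u <- stats::runif(L)
  nt <- c("A", "C", "G", "T")
  ts_partner <- c(A = "G", C = "T", G = "A", T = "C")
  tv1 <- c(A = "C", C = "A", G = "C", T = "A")
  tv2 <- c(A = "T", C = "G", G = "T", T = "G")
  child <- parent
  i <- u < p_ts
  child[i] <- ts_partner[parent[i]]
  i <- u >= p_ts & u < p_ts + p_tv
  child[i] <- tv1[parent[i]]
  i <- u >= p_ts + p_tv & u < p_ts + 2 * p_tv
  child[i] <- tv2[parent[i]]
  child
}

#' Simulate a genus of aligned COI-like sequences with known truth
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed (defaults to `cfg$seed`); the same seed gives a
#'   byte-identical dataset.
#' @return A list with `dataset` (a [genus_dataset()]) and `truth` (named
#'   vectors `species` and `haplotype` per sequence id, the `ancestors`
#'   matrix, and the `root` sequence).
#' @export
simulate_genus <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(seed, {
    L <- cfg$seq_length
    nt <- c("A", "C", "G", "T")
    root <- sample(nt, L, replace = TRUE)
    sp_names <- sprintf("%s_sp%02d", tolower(cfg$genus), seq_len(cfg$n_species))
    ancestors <- t(vapply(seq_len(cfg$n_species), function(i) {
      evolve_sequence(root, cfg$inter_depth, cfg$kappa)
    }, character(L)))
    rownames(ancestors) <- sp_names

    haps <- list()
    for (i in seq_len(cfg$n_species)) {
      k <- cfg$haplotypes_per_species[i]
      haps[[i]] <- t(vapply(seq_len(k), function(j) {
        evolve_sequence(ancestors[i, ], cfg$intra_depth, cfg$kappa)
      }, character(L)))
    }
    for (pr in cfg$shared_haplotype_pairs %||% list()) {
      haps[[pr[2]]][1L, ] <- haps[[pr[1]]][1L, ]
    }

    seqs <- list(); species <- character(0); hap_id <- character(0)
    for (i in seq_len(cfg$n_species)) {
      k <- nrow(haps[[i]])
      counts <- if (is.null(cfg$sampling_counts)) {
        1L + stats::rpois(k, 1)
      } else if (is.function(cfg$sampling_counts)) {
        as.integer(cfg$sampling_counts(k))
      } else {
        rep_len(cfg$sampling_counts, k)
      }
      stopifnot(all(counts >= 1L))
      for (j in seq_len(k)) {
        hname <- sprintf("%s_h%02d", sp_names[i], j)
        for (r in seq_len(counts[j])) {
          id <- sprintf("%s_r%02d", hname, r)
          seqs[[id]] <- haps[[i]][j, ]
          species <- c(species, sp_names[i])
          hap_id <- c(hap_id, hname)
        }
      }
    }
    mat <- do.call(rbind, seqs)
    rownames(mat) <- names(seqs)

    if (cfg$missing_end_fraction > 0) {
      n_aff <- ceiling(cfg$missing_end_fraction * nrow(mat))
      affected <- sample.int(nrow(mat), n_aff)
      max_run <- max(1L, floor(0.1 * L))
      for (ix in affected) {
        lead <- sample.int(max_run, 1L)
        trail <- sample.int(max_run, 1L)
        mat[ix, seq_len(lead)] <- "N"
        mat[ix, seq.int(L - trail + 1L, L)] <- "N"
      }
    }

    ds <- genus_dataset(cfg$genus, mat, species)
    truth <- list(species = stats::setNames(species, rownames(mat)),
                  haplotype = stats::setNames(hap_id, rownames(mat)),
                  ancestors = ancestors, root = root)
    list(dataset = ds, truth = truth)
  })
}

#' Closed-form expected mean distances for a simulation configuration
#'
#' Under the star phylogeny, two conspecific haplotypes are separated by two
#' independent branches of expected length `intra_depth`, and two haplotypes
#' from different species by two `inter_depth` branches plus two
#' `intra_depth` branches, so the expected mean intraspecific distance is
#' `2 * intra_depth` and the expected mean interspecific distance is
#' `2 * (inter_depth + intra_depth)` — a calibration oracle for Monte-Carlo
#' checks of the whole pipeline (stated tolerance band: 15%).
#'
#' @param cfg A [sim_config()].
#' @return A list with `mean_intra`, `mean_inter`, `tolerance` (0.15). A
#'   warning is issued when the expected interspecific distance exceeds 0.75
#'   substitutions/site, where saturation makes the linear expectation
#'   unreliable.
#' @export
expected_summaries <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  mi <- 2 * cfg$intra_depth
  mx <- 2 * (cfg$inter_depth + cfg$intra_depth)
  if (mx >= 0.75) {
    warning("expected interspecific distance >= 0.75 substitutions/site; ",
            "saturation will bias the closed-form expectation", call. = FALSE)
  }
  list(mean_intra = mi, mean_inter = mx, tolerance = 0.15)
}
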