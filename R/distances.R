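#' Kimura two-parameter distance between two aligned sequences
#'
#' Comparable sites are the alignment columns where both sequences carry an
#' unambiguous nucleotide (`A`, `C`, `G` or `T`); all other columns —
#' gaps, `N`, `?` and IUPAC partial ambiguities — are excluded for this pair
#' only (pairwise deletion). With transition proportion `P` and transversion
#' proportion `Q` over those sites, the distance is
#' `d = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))` substitutions/site,
#' assuming uniform rates among sites. When no site is comparable or a log
#' argument is non-positive (saturation) the pair is inapplicable and `d` is
#' `NA` with `applicable = FALSE`.
#'
#' @param a,b Character vectors of aligned residues (or single strings) of
#'   equal length.
#' @return A list with `d`, `P`, `Q`, `sites` (comparable-site count) and
#'   `applicable`.
#' @export
k2p_distance <- function(a, b) {
  if (length(a) == 1L && nchar(a) > 1L) a <- strsplit(a, "")[[1L]]
  if (length(b) == 1L && nchar(b) > 1L) b <- strsplit(b, "")[[1L]]
  if (length(a) != length(b)) {
    stop("sequences must be aligned to equal length", call. = FALSE)
  }
  k2p_core(encode_nt(toupper(a)), encode_nt(toupper(b)))
}

# A=1, C=2, G=3, T=4, everything else 0 (not a comparable site).
encode_nt <- function(x) {
  m <- match(x, c("A", "C", "G", "T"))
  m[is.na(m)] <- 0L
  m
}

# purine flag indexed by the 1..4 encoding (A, C, G, T)
.purine <- c(TRUE, FALSE, TRUE, FALSE)

k2p_core <- function(ea, eb) {
  ok <- ea > 0L & eb > 0L
  sites <- sum(ok)
  if (sites == 0L) {
    return(list(d = NA_real_, P = NA_real_, Q = NA_real_, sites = 0L,
                applicable = FALSE))
  }
  idx <- which(ok & ea != eb)
  ts <- sum(.purine[ea[idx]] == .purine[eb[idx]])
  tv <- length(idx) - ts
  P <- ts / sites
  Q <- tv / sites
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    return(list(d = NA_real_, P = P, Q = Q, sites = sites,
                applicable = FALSE))
  }
  list(d = -0.5 * log(w1 * sqrt(w2)), P = P, Q = Q, sites = sites,
       applicable = TRUE)
}

# Pull the residue matrix out of whatever the caller passed.
seq_matrix <- function(x) {
  if (inherits(x, "genus_dataset") || inherits(x, "genus_view")) return(x$seqs)
  if (is.matrix(x) && is.character(x)) {
    if (is.null(rownames(x))) rownames(x) <- paste0("seq", seq_len(nrow(x)))
    return(toupper(x))
  }
  stop("expected a genus_dataset, genus_view or character matrix",
       call. = FALSE)
}

#' Pairwise K2P distance matrix
#'
#' Computes [k2p_distance()] for every unordered pair of sequences.
#' Inapplicable pairs (no comparable sites, or saturated) are masked rather
#' than assigned an arbitrary large value; downstream summaries skip masked
#' pairs and report how many were skipped.
#'
#' @param x A `genus_dataset`, `genus_view`, or character matrix of aligned
#'   residues with row names.
#' @return An object of class `k2p_matrix`: `ids`, `d` (symmetric numeric
#'   matrix, `NA` where masked), `applicable` (symmetric logical),
#'   `sites` (comparable-site counts) and `n_masked`.
#' @export
pairwise_matrix <- function(x) {
  seqs <- seq_matrix(x)
  n <- nrow(seqs)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  ids <- rownames(seqs)
  enc <- matrix(encode_nt(seqs), nrow = n, dimnames = list(ids, NULL))
  d <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  app <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  sites <- matrix(0L, n, n, dimnames = list(ids, ids))
  diag(d) <- 0
  diag(app) <- TRUE
  nonmiss <- rowSums(enc > 0L)
  diag(sites) <- as.integer(nonmiss)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      r <- k2p_core(enc[i, ], enc[j, ])
      d[i, j] <- d[j, i] <- r$d
      app[i, j] <- app[j, i] <- r$applicable
      sites[i, j] <- sites[j, i] <- r$sites
    }
  }
  structure(list(ids = ids, d = d, applicable = app, sites = sites,
                 n_masked = sum(!app[upper.tri(app)])),
            class = "k2p_matrix")
}

#' @export
print.k2p_matrix <- function(x, ...) {
  cat("<k2p_matrix> ", length(x$ids), " sequences, ", x$n_masked,
      " masked pair(s)\n", sep = "")
  invisible(x)
}

#' Write a square distance-matrix TSV
#'
#' @param m A [pairwise_matrix()] result.
#' @param path Output path; masked pairs are written as `NA`.
#' @return `m`, invisibly.
#' @export
write_distance_matrix <- function(m, path) {
  stopifnot(inherits(m, "k2p_matrix"))
  utils::write.table(cbind(id = m$ids, as.data.frame(m$d)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(m)
}

#' Intra- and interspecific distance summaries per species
#'
#' Summarizes a K2P matrix by species: within-species maximum and mean
#' distance over applicable pairs, and per species-pair minimum and mean
#' between-species distances. Masked (inapplicable) pairs are skipped and
#' counted. A species represented by a single sequence gets
#' `max_intra = mean_intra = 0` with `n_intra_pairs = 0` and is flagged.
#'
#' Optional per-id `weights` (haplotype multiplicities) reproduce the
#' all-sequence (N_S) statistics from a unique-haplotype matrix: a pair of
#' distinct haplotypes contributes with weight `w_i * w_j`, and each
#' haplotype carried by `w_i > 1` sequences additionally contributes
#' `choose(w_i, 2)` zero-distance intraspecific pairs.
#'
#' @param m A [pairwise_matrix()] result.
#' @param species Named character vector mapping every id in `m` to a
#'   species label. For a `genus_view` input to [pairwise_matrix()], pass
#'   `view$species`.
#' @param weights Optional named integer vector of per-id multiplicities.
#' @return An object of class `species_distance_summary` with data.frames
#'   `intra` (`species`, `n_units`, `n_intra_pairs`, `mean_intra`,
#'   `max_intra`, `singleton`) and `inter` (`species_a`, `species_b`,
#'   `n_pairs`, `mean_inter`, `min_inter`), plus pooled per-pair records for
#'   histogram-style analyses and `n_masked_skipped`.
#' @export
summarize_by_species <- function(m, species, weights = NULL) {
  stopifnot(inherits(m, "k2p_matrix"))
  unlabeled <- setdiff(m$ids, names(species))
  if (length(unlabeled)) {
    stop("id(s) without species label: ", paste(unlabeled, collapse = ", "),
         call. = FALSE)
  }
  sp <- as.character(species[m$ids])
  if (is.null(weights)) {
    w <- rep(1L, length(m$ids))
  } else {
    if (!all(m$ids %in% names(weights))) {
      stop("`weights` must cover every id", call. = FALSE)
    }
    w <- as.integer(weights[m$ids])
    stopifnot(all(w >= 1L))
  }
  n <- length(m$ids)
  ui <- which(upper.tri(m$d), arr.ind = TRUE)
  di <- m$d[ui]
  appi <- m$applicable[ui]
  wi <- w[ui[, 1L]] * w[ui[, 2L]]
  sp1 <- sp[ui[, 1L]]; sp2 <- sp[ui[, 2L]]
  same <- sp1 == sp2
  skipped <- sum(!appi)

  species_levels <- sort(unique(sp))
  intra <- do.call(rbind, lapply(species_levels, function(s) {
    sel <- same & sp1 == s & appi
    dv <- di[sel]; wv <- wi[sel]
    extra0 <- sum(choose(w[sp == s], 2))  # duplicate copies of one haplotype
    npairs <- sum(wv) + extra0
    if (npairs == 0L) {
      return(data.frame(species = s, n_units = sum(sp == s),
                        n_intra_pairs = 0L, mean_intra = 0, max_intra = 0,
                        singleton = TRUE, stringsAsFactors = FALSE))
    }
    data.frame(species = s, n_units = sum(sp == s),
               n_intra_pairs = as.integer(npairs),
               mean_intra = sum(dv * wv) / npairs,
               max_intra = if (length(dv)) max(dv) else 0,
               singleton = FALSE, stringsAsFactors = FALSE)
  }))
  rownames(intra) <- NULL

  pa <- pmin(sp1, sp2); pb <- pmax(sp1, sp2)
  inter_sel <- !same & appi
  inter <- NULL
  if (any(inter_sel)) {
    key <- paste(pa[inter_sel], pb[inter_sel], sep = "\r")
    dv <- di[inter_sel]; wv <- wi[inter_sel]
    inter <- do.call(rbind, lapply(split(seq_along(key), key), function(ix) {
      parts <- strsplit(key[ix[1L]], "\r", fixed = TRUE)[[1L]]
      data.frame(species_a = parts[1L], species_b = parts[2L],
                 n_pairs = as.integer(sum(wv[ix])),
                 mean_inter = sum(dv[ix] * wv[ix]) / sum(wv[ix]),
                 min_inter = min(dv[ix]), stringsAsFactors = FALSE)
    }))
    rownames(inter) <- NULL
  } else {
    inter <- data.frame(species_a = character(0), species_b = character(0),
                        n_pairs = integer(0), mean_inter = numeric(0),
                        min_inter = numeric(0), stringsAsFactors = FALSE)
  }

  pooled_intra <- data.frame(species = sp1[same & appi],
                             d = di[same & appi],
                             weight = wi[same & appi],
                             stringsAsFactors = FALSE)
  # weighted duplicate pairs sit at distance zero
  dup <- w > 1L
  if (any(dup)) {
    pooled_intra <- rbind(pooled_intra, data.frame(
      species = sp[dup], d = 0, weight = choose(w[dup], 2)))
  }
  pooled_inter <- data.frame(species_a = pa[inter_sel],
                             species_b = pb[inter_sel],
                             d = di[inter_sel], weight = wi[inter_sel],
                             stringsAsFactors = FALSE)

  structure(list(intra = intra, inter = inter,
                 pooled_intra = pooled_intra, pooled_inter = pooled_inter,
                 n_masked_skipped = skipped),
            class = "species_distance_summary")
}

#' @export
print.species_distance_summary <- function(x, ...) {
  cat("<species_distance_summary> ", nrow(x$intra), " species, ",
      nrow(x$inter), " species pair(s), ", x$n_masked_skipped,
      " masked pair(s) skipped\n", sep = "")
  invisible(x)
}
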