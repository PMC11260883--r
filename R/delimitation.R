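# Partition constructor: assignment is a named integer vector; cluster ids
# are relabelled to be contiguous from 1 in order of first appearance.
new_partition <- function(assignment, cut_height = NA_real_) {
  ids <- names(assignment)
  stopifnot(!is.null(ids), !anyDuplicated(ids))
  lev <- unique(as.vector(assignment))
  relab <- stats::setNames(seq_along(lev), lev)
  out <- stats::setNames(as.integer(relab[as.character(assignment)]), ids)
  structure(list(assignment = out, n_clusters = length(lev),
                 cut_height = cut_height),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat("<partition> ", length(x$assignment), " ids in ", x$n_clusters,
      " cluster(s)", sep = "")
  if (!is.na(x$cut_height)) cat(" (cut height ", format(x$cut_height), ")",
                                sep = "")
  cat("\n")
  invisible(x)
}

#' Candidate species partitions by single-linkage threshold sweep
#'
#' Ascending hierarchical (single-linkage) clustering of the distance matrix
#' yields one candidate partition per distinct merge height, from all
#' singletons down to one cluster — the sweep of distance thresholds a
#' distance-based delimitation method scores. Ties are resolved
#' deterministically by ordering sequences lexicographically by id before
#' clustering.
#'
#' @param m A fully applicable [pairwise_matrix()] result (masked pairs are
#'   an error; drop the offending sequences first).
#' @return A list of `partition` objects ordered from most to fewest
#'   clusters; length is the number of distinct merge heights plus one.
#' @export
candidate_partitions <- function(m) {
  stopifnot(inherits(m, "k2p_matrix"))
  n <- length(m$ids)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  if (m$n_masked > 0L) {
    stop("distance matrix has ", m$n_masked, " inapplicable pair(s); ",
         "drop the sequences involved before delimitation", call. = FALSE)
  }
  ord <- order(m$ids)
  d <- m$d[ord, ord]
  ids <- m$ids[ord]
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  hts <- sort(hc$height)
  distinct <- hts[c(TRUE, diff(hts) > 1e-12)]
  # partition i is the state of the sweep just below merge height h_i (its
  # cut height); the final partition has everything merged
  parts <- list(new_partition(stats::setNames(seq_len(n), ids),
                              cut_height = distinct[1L]))
  if (length(distinct) > 1L) {
    for (i in seq.int(2L, length(distinct))) {
      cl <- stats::cutree(hc, h = distinct[i - 1L] + 1e-13)
      parts[[length(parts) + 1L]] <- new_partition(cl,
                                                   cut_height = distinct[i])
    }
  }
  cl <- stats::cutree(hc, h = distinct[length(distinct)] + 1e-13)
  parts[[length(parts) + 1L]] <- new_partition(cl, cut_height = NA_real_)
  parts
}

#' Score a candidate partition (panmixia probability and relative gap width)
#'
#' Two complementary metrics in the style of average-rank partition scoring:
#' the relative barcode gap width
#' `W = max(0, (min between-cluster d - max within-cluster d) / mean d)`
#' and a panmixia probability `p`, the add-one permutation probability that
#' randomly reassigning sequences to clusters of the same sizes yields a
#' mean-within / mean-between ratio at most the observed one. Good partitions
#' have large `W` and small `p`.
#'
#' @param p A `partition` covering the matrix ids.
#' @param m The [pairwise_matrix()] the partition was built from.
#' @param n_perm Permutations for the panmixia probability (default 999).
#' @param seed Optional integer for reproducibility.
#' @return An object of class `partition_score`: `partition`, `n_clusters`,
#'   `w`, `p_panmixia`, `cut_height`.
#' @export
score_partition <- function(p, m, n_perm = 999, seed = NULL) {
  stopifnot(inherits(p, "partition"), inherits(m, "k2p_matrix"))
  if (!setequal(names(p$assignment), m$ids)) {
    stop("partition must cover exactly the matrix ids", call. = FALSE)
  }
  if (m$n_masked > 0L) {
    stop("distance matrix has inapplicable pair(s); scoring needs a fully ",
         "applicable matrix", call. = FALSE)
  }
  n <- length(m$ids)
  if (p$n_clusters < 2L || p$n_clusters >= n) {
    stop("scoring requires 2 <= n_clusters < n", call. = FALSE)
  }
  lab <- p$assignment[m$ids]
  up <- upper.tri(m$d)
  dvals <- m$d[up]
  same <- outer(lab, lab, "==")[up]
  mean_all <- mean(dvals)
  max_within <- if (any(same)) max(dvals[same]) else 0
  min_between <- min(dvals[!same])
  w <- if (mean_all > 0) max(0, (min_between - max_within) / mean_all) else 0

  stat <- function(sm) {
    mw <- if (any(sm)) mean(dvals[sm]) else 0
    mb <- mean(dvals[!sm])
    if (mb == 0) return(NA_real_)
    mw / mb
  }
  obs <- stat(same)
  if (is.na(obs)) {
    warning("all distances zero; panmixia probability set to 1",
            call. = FALSE)
    pval <- 1
  } else {
    count <- with_seed(seed, {
      sum(vapply(seq_len(n_perm), function(i) {
        perm <- sample(lab)
        s <- stat(outer(perm, perm, "==")[up])
        !is.na(s) && s <= obs + 1e-12
      }, logical(1)))
    })
    pval <- (1 + count) / (1 + n_perm)
  }
  structure(list(partition = p, n_clusters = p$n_clusters, w = w,
                 p_panmixia = pval, cut_height = p$cut_height),
            class = "partition_score")
}

#' Rank scored partitions and select the best plausible one
#'
#' Ranks partitions by the average of two ranks — descending `W` and
#' ascending panmixia `p` (ties get average ranks) — so a lower score is a
#' better partition. Partitions delimiting nearly every sequence as its own
#' species (`n_clusters > plausibility_cap * n`) are excluded from
#' selection. Among eligible partitions the lowest score wins; score ties go
#' to the partition delimiting fewer species.
#'
#' @param scores A list of [score_partition()] results for one matrix.
#' @param plausibility_cap Fraction of `n` above which a partition is
#'   considered implausibly fine (default 0.9).
#' @return A list with `ranking` (data.frame: `n_clusters`, `cut_height`,
#'   `w`, `p_panmixia`, `rank_w`, `rank_p`, `score`, `eligible`, ordered by
#'   score) and `selected` (the chosen `partition`).
#' @export
rank_partitions <- function(scores, plausibility_cap = 0.9) {
  stopifnot(length(scores) >= 1L,
            all(vapply(scores, inherits, logical(1), "partition_score")))
  n <- length(scores[[1L]]$partition$assignment)
  df <- data.frame(
    n_clusters = vapply(scores, `[[`, integer(1), "n_clusters"),
    cut_height = vapply(scores, `[[`, numeric(1), "cut_height"),
    w = vapply(scores, `[[`, numeric(1), "w"),
    p_panmixia = vapply(scores, `[[`, numeric(1), "p_panmixia"))
  df$rank_w <- rank(-df$w, ties.method = "average")
  df$rank_p <- rank(df$p_panmixia, ties.method = "average")
  df$score <- (df$rank_w + df$rank_p) / 2
  df$eligible <- df$n_clusters <= plausibility_cap * n
  ord <- order(df$score, df$n_clusters)
  df <- df[ord, , drop = FALSE]
  scores <- scores[ord]
  rownames(df) <- NULL
  if (!any(df$eligible)) {
    stop("every partition exceeds the plausibility cap; nothing to select",
         call. = FALSE)
  }
  sel <- which(df$eligible)[1L]
  list(ranking = df, selected = scores[[sel]]$partition)
}

#' Import an externally produced partition
#'
#' Reads a two-column TSV (`id`, `cluster`) — e.g. output of an external
#' delimitation tool — and validates it against a known id set.
#'
#' @param tsv_path Path to the TSV (header required).
#' @param ids Optional character vector the partition must cover exactly.
#' @return A `partition` (with `cut_height = NA`).
#' @export
import_partition <- function(tsv_path, ids = NULL) {
  tab <- utils::read.delim(tsv_path, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (!all(c("id", "cluster") %in% names(tab))) {
    stop("partition TSV must have columns `id` and `cluster`", call. = FALSE)
  }
  if (anyDuplicated(tab$id)) {
    stop("duplicate id(s) in partition file: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(ids)) {
    miss <- setdiff(ids, tab$id)
    extra <- setdiff(tab$id, ids)
    if (length(miss) || length(extra)) {
      stop("partition does not match the dataset ids",
           if (length(miss)) paste0("; missing: ",
                                    paste(miss, collapse = ", ")),
           if (length(extra)) paste0("; unknown: ",
                                     paste(extra, collapse = ", ")),
           call. = FALSE)
    }
  }
  new_partition(stats::setNames(tab$cluster, tab$id))
}

#' Export a partition as TSV
#'
#' @param p A `partition`.
#' @param path Output path.
#' @return `p`, invisibly.
#' @export
write_partition <- function(p, path) {
  stopifnot(inherits(p, "partition"))
  utils::write.table(
    data.frame(id = names(p$assignment), cluster = unname(p$assignment)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(p)
}

#' Distance-based species delimitation for one dataset view
#'
#' Convenience wrapper: builds the candidate partitions, scores every
#' partition with 2 to n-1 clusters, and ranks/selects the best plausible
#' one.
#'
#' @param m A fully applicable [pairwise_matrix()].
#' @inheritParams score_partition
#' @inheritParams rank_partitions
#' @return As [rank_partitions()], plus `scores`.
#' @export
delimit_species <- function(m, n_perm = 999, seed = NULL,
                            plausibility_cap = 0.9) {
  parts <- candidate_partitions(m)
  n <- length(m$ids)
  parts <- Filter(function(p) p$n_clusters >= 2L && p$n_clusters < n, parts)
  if (!length(parts)) {
    stop("no candidate partition with 2 <= n_clusters < n; ",
         "the data may be all-identical", call. = FALSE)
  }
  scores <- lapply(seq_along(parts), function(i) {
    score_partition(parts[[i]], m, n_perm = n_perm,
                    seed = stage_seed(seed, i))
  })
  out <- rank_partitions(scores, plausibility_cap = plausibility_cap)
  out$scores <- scores
  out
}
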