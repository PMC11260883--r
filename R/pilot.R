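#' Benchmark mean intraspecific distance from a full dataset
#'
#' The mean over all applicable pairwise K2P distances in a single-species
#' dataset, treated as the "true" value a subsampling pilot tries to recover.
#'
#' @param x A `genus_dataset`, `genus_view` or character matrix of aligned
#'   sequences from one species.
#' @return Mean pairwise distance (substitutions/site).
#' @export
benchmark_mean <- function(x) {
  m <- pairwise_matrix(x)
  up <- upper.tri(m$d)
  vals <- m$d[up][m$applicable[up]]
  if (!length(vals)) stop("no applicable sequence pair", call. = FALSE)
  mean(vals)
}

#' Subsampling convergence curve for minimum sample-size selection
#'
#' Draws, for each subset size, `replicates` random subsamples without
#' replacement and records each subsample's mean applicable pairwise K2P
#' distance. Comparing the replicate means against the full-data benchmark
#' shows how small a sample can get before distance estimates become
#' unacceptably biased or variable.
#'
#' @param x Single-species dataset (as for [benchmark_mean()]).
#' @param sizes Integer subset sizes (each at least 2, at most the dataset
#'   size); e.g. `3:12` for a haplotype-level pilot or `seq(5, 32, 3)` for a
#'   sequence-level one.
#' @param replicates Subsamples per size (default 10).
#' @param seed Optional integer for reproducibility.
#' @return An object of class `pilot_result`: `truth` (benchmark mean),
#'   `rows` (per size: `size`, `mean_of_means`, `sd_of_means`,
#'   `mean_abs_rel_dev`), `means` (replicates x sizes matrix), `replicates`,
#'   `seed`.
#' @export
subsample_curve <- function(x, sizes, replicates = 10, seed = NULL) {
  seqs <- seq_matrix(x)
  n <- nrow(seqs)
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes < 2L)) stop("subset sizes must be at least 2", call. = FALSE)
  if (max(sizes) > n) {
    stop("largest subset size exceeds the dataset size (", n, ")",
         call. = FALSE)
  }
  truth <- benchmark_mean(seqs)
  means <- with_seed(seed, {
    vapply(sizes, function(s) {
      vapply(seq_len(replicates), function(r) {
        sub <- seqs[sample.int(n, s), , drop = FALSE]
        m <- pairwise_matrix(sub)
        up <- upper.tri(m$d)
        vals <- m$d[up][m$applicable[up]]
        if (!length(vals)) NA_real_ else mean(vals)
      }, numeric(1))
    }, numeric(replicates))
  })
  means <- matrix(means, nrow = replicates,
                  dimnames = list(NULL, paste0("n", sizes)))
  if (anyNA(means)) {
    warning("some subsamples had no applicable pair; their means are NA",
            call. = FALSE)
  }
  rows <- data.frame(
    size = sizes,
    mean_of_means = colMeans(means, na.rm = TRUE),
    sd_of_means = apply(means, 2L, stats::sd, na.rm = TRUE),
    mean_abs_rel_dev = if (truth > 0) {
      colMeans(abs(means - truth) / truth, na.rm = TRUE)
    } else NA_real_,
    row.names = NULL)
  structure(list(truth = truth, rows = rows, means = means,
                 replicates = as.integer(replicates), seed = seed,
                 sizes = sizes),
            class = "pilot_result")
}

#' @export
print.pilot_result <- function(x, ...) {
  cat("<pilot_result> truth = ", format(x$truth), ", ",
      length(x$sizes), " sizes x ", x$replicates, " replicates\n", sep = "")
  print(x$rows)
  invisible(x)
}

#' Select the minimum acceptable sample size from a pilot curve
#'
#' Returns the smallest subset size balancing departure from and variance
#' around the benchmark: mean absolute relative deviation at most
#' `max_rel_dev` and relative standard deviation of replicate means at most
#' `max_rel_sd`. If no size qualifies, the largest size is returned with a
#' warning.
#'
#' @param res A [subsample_curve()] result.
#' @param max_rel_dev Maximum mean |relative deviation| from truth
#'   (default 0.10).
#' @param max_rel_sd Maximum sd-of-means / truth (default 0.10).
#' @return The selected size (integer).
#' @export
select_minimum <- function(res, max_rel_dev = 0.10, max_rel_sd = 0.10) {
  stopifnot(inherits(res, "pilot_result"), nrow(res$rows) > 0L)
  if (res$truth <= 0) {
    stop("benchmark mean is 0: relative criteria undefined; ",
         "use an absolute tolerance on the curve instead", call. = FALSE)
  }
  ok <- res$rows$mean_abs_rel_dev <= max_rel_dev &
    res$rows$sd_of_means / res$truth <= max_rel_sd
  ok[is.na(ok)] <- FALSE
  if (any(ok)) return(res$rows$size[which(ok)[1L]])
  warning("no subset size met both tolerances; returning the largest size",
          call. = FALSE)
  res$rows$size[nrow(res$rows)]
}

#' Write the pilot replicate means and summary as TSV
#'
#' @param res A [subsample_curve()] result.
#' @param path Output path for the long-format replicate table; a summary
#'   file is written alongside with suffix `_summary`.
#' @return `res`, invisibly.
#' @export
write_pilot <- function(res, path) {
  stopifnot(inherits(res, "pilot_result"))
  long <- data.frame(
    size = rep(res$sizes, each = res$replicates),
    replicate = rep(seq_len(res$replicates), length(res$sizes)),
    mean_distance = as.vector(res$means))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(res$rows, sub("(\\.[^.]*)?$", "_summary\\1", path),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(res)
}
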