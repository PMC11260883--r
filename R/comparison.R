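# Two-group one-way F statistic (between-group MS / within-group MS).
f_statistic <- function(values, in_a) {
  na <- sum(in_a); nb <- sum(!in_a); n <- na + nb
  ma <- mean(values[in_a]); mb <- mean(values[!in_a]); gm <- mean(values)
  ssb <- na * (ma - gm)^2 + nb * (mb - gm)^2
  ssw <- sum((values[in_a] - ma)^2) + sum((values[!in_a] - mb)^2)
  (ssb / 1) / (ssw / (n - 2))
}

#' Permutation test comparing two groups of summary distances
#'
#' Randomization analogue of a one-way two-group ANOVA, used to compare
#' per-species mean intraspecific distances (or per species-pair mean
#' interspecific distances) between the unique-haplotype and all-sequence
#' versions of a genus dataset. The observed F statistic is compared against
#' the distribution obtained by permuting group labels uniformly; the add-one
#' p-value is `(1 + #{permuted >= observed}) / (1 + iterations)`. When the
#' number of distinct label assignments is small (at most `exhaustive_limit`)
#' all assignments are enumerated instead of sampled.
#'
#' @param a,b Numeric vectors (each of length at least 2).
#' @param iterations Monte-Carlo permutations (default 10000).
#' @param seed Optional integer for reproducibility.
#' @param exhaustive_limit Enumerate all assignments when
#'   `choose(length(a)+length(b), length(a))` does not exceed this
#'   (default 50000).
#' @return An object of class `permutation_result`: `statistic`, `p_value`,
#'   `iterations` (assignments actually evaluated), `exhaustive`, `seed`,
#'   `group_sizes`.
#' @export
permutation_test <- function(a, b, iterations = 10000, seed = NULL,
                             exhaustive_limit = 50000) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  values <- c(a, b)
  na <- length(a); n <- length(values)
  if (stats::var(values) == 0) {
    warning("zero total variance; p = 1 by convention", call. = FALSE)
    return(structure(list(statistic = NA_real_, p_value = 1,
                          iterations = 0L, exhaustive = TRUE, seed = seed,
                          group_sizes = c(na, length(b))),
                     class = "permutation_result"))
  }
  obs <- f_statistic(values, c(rep(TRUE, na), rep(FALSE, n - na)))
  eps <- 1e-12 * max(1, abs(obs[is.finite(obs)]), na.rm = TRUE)
  ge_obs <- function(x) x >= obs - eps | (is.infinite(obs) & is.infinite(x))
  if (choose(n, na) <= exhaustive_limit) {
    combos <- utils::combn(n, na)
    stats_all <- apply(combos, 2L, function(ix) {
      in_a <- logical(n); in_a[ix] <- TRUE
      f_statistic(values, in_a)
    })
    k <- ncol(combos)
    p <- (1 + sum(ge_obs(stats_all))) / (1 + k)
    exhaustive <- TRUE
  } else {
    k <- as.integer(iterations)
    count <- with_seed(seed, {
      sum(vapply(seq_len(k), function(i) {
        in_a <- logical(n); in_a[sample.int(n, na)] <- TRUE
        ge_obs(f_statistic(values, in_a))
      }, logical(1)))
    })
    p <- (1 + count) / (1 + k)
    exhaustive <- FALSE
  }
  structure(list(statistic = obs, p_value = p, iterations = k,
                 exhaustive = exhaustive, seed = seed,
                 group_sizes = c(na, length(b))),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("<permutation_result> F = ", format(x$statistic), ", p = ",
      format(x$p_value), " (", if (x$exhaustive) "exhaustive, " else "",
      x$iterations, " assignments)\n", sep = "")
  invisible(x)
}
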