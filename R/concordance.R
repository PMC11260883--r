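CONCORDANCE_CATEGORIES <- c("perfect_taxonomy", "pure_undersplit",
                            "impure_undersplit", "pure_oversplit",
                            "impure_oversplit")

#' Classify recognized species against a delimited partition
#'
#' Compares each recognized species (the labels that went into delimitation)
#' with the delimited clusters and assigns exactly one of five categories:
#'
#' * `perfect_taxonomy` — the species occupies exactly one cluster and that
#'   cluster contains nothing else (100% concordance).
#' * `pure_undersplit` — the species is split across two or more clusters,
#'   each containing only members of this species (its diversity exceeds one
#'   delimited species, but naming new species would reconcile it).
#' * `impure_undersplit` — split across two or more clusters, at least one
#'   of which also contains members of another species.
#' * `pure_oversplit` — the species shares its single cluster with one or
#'   more other species that are each wholly contained in that cluster
#'   (synonymy would reconcile it).
#' * `impure_oversplit` — shares its single cluster with another species
#'   that also has members elsewhere.
#'
#' A species that is both split across clusters and cohabiting with another
#' species is an impure undersplit (the split takes precedence over the
#' sharing).
#'
#' @param recognized Named list mapping each recognized species to its member
#'   ids (a partition of the id set), or a named character vector of species
#'   labels keyed by id (e.g. a `genus_view$species`).
#' @param part A `partition` covering the same ids.
#' @return A data.frame with one row per recognized species: `species`,
#'   `category` (factor over the five categories), `clusters_spanned`,
#'   `cohabitants` (comma-separated species sharing a cluster, or `""`).
#' @export
classify_species <- function(recognized, part) {
  stopifnot(inherits(part, "partition"))
  if (!is.list(recognized)) {
    recognized <- split(names(recognized), as.character(recognized))
  }
  all_ids <- unlist(recognized, use.names = FALSE)
  if (anyDuplicated(all_ids)) {
    stop("recognized species must partition the id set (duplicated ids)",
         call. = FALSE)
  }
  part_ids <- names(part$assignment)
  if (!setequal(all_ids, part_ids)) {
    stop("partition and recognized species cover different id sets",
         call. = FALSE)
  }
  cl <- part$assignment
  sp_of <- stats::setNames(rep(names(recognized), lengths(recognized)),
                           all_ids)
  rows <- lapply(names(recognized), function(r) {
    members <- recognized[[r]]
    clusters <- unique(unname(cl[members]))
    cohab <- unique(sp_of[names(cl)[cl %in% clusters]])
    cohab <- sort(setdiff(cohab, r))
    if (length(clusters) >= 2L) {
      cat_ <- if (length(cohab) == 0L) "pure_undersplit" else
        "impure_undersplit"
    } else {
      cluster_members <- names(cl)[cl == clusters]
      if (setequal(cluster_members, members)) {
        cat_ <- "perfect_taxonomy"
      } else {
        others_whole <- vapply(cohab, function(s) {
          all(recognized[[s]] %in% cluster_members)
        }, logical(1))
        cat_ <- if (all(others_whole)) "pure_oversplit" else
          "impure_oversplit"
      }
    }
    data.frame(species = r, category = cat_,
               clusters_spanned = length(clusters),
               cohabitants = paste(cohab, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$category <- factor(out$category, levels = CONCORDANCE_CATEGORIES)
  rownames(out) <- NULL
  out
}

#' Summarize concordance records as counts and percentages
#'
#' @param records A [classify_species()] result.
#' @param part The `partition` the records were classified against (supplies
#'   the delimited-species count).
#' @return An object of class `concordance_summary`: `counts` and
#'   `percentages` (integer, rounded half-up) per category, `n_recognized`,
#'   `n_delimited`, and `delimited_ratio` (delimited / recognized, one
#'   decimal).
#' @export
summarize_concordance <- function(records, part) {
  stopifnot(is.data.frame(records), nrow(records) > 0L,
            inherits(part, "partition"))
  counts <- table(factor(records$category, levels = CONCORDANCE_CATEGORIES))
  counts <- stats::setNames(as.integer(counts), names(counts))
  n <- nrow(records)
  structure(list(
    counts = counts,
    percentages = round_half_up(100 * counts / n),
    n_recognized = n,
    n_delimited = part$n_clusters,
    delimited_ratio = round_half_up(part$n_clusters / n, 1)
  ), class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat("<concordance_summary> ", x$n_recognized, " recognized -> ",
      x$n_delimited, " delimited species (", format(x$delimited_ratio),
      "x)\n", sep = "")
  df <- data.frame(category = names(x$counts), count = x$counts,
                   percent = x$percentages, row.names = NULL)
  print(df)
  invisible(x)
}

#' Write concordance records and summary as TSVs
#'
#' @param records A [classify_species()] result.
#' @param summary A [summarize_concordance()] result.
#' @param records_path,summary_path Output paths.
#' @return `records`, invisibly.
#' @export
write_concordance <- function(records, summary, records_path, summary_path) {
  utils::write.table(records, records_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  df <- data.frame(category = names(summary$counts),
                   count = summary$counts,
                   percent = summary$percentages, row.names = NULL)
  utils::write.table(df, summary_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(records)
}
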