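#' Inclusion thresholds for the parallel haplotype/sequence datasets
#'
#' Minimum sample sizes a species must reach to enter the unique-haplotype
#' (N_H) or all-sequence (N_S) dataset, and the minimum number of qualifying
#' species a genus needs to be analysed at all. Defaults follow the pilot
#' outcome used throughout: N_H >= 6, N_S >= 12, and at least 4 species per
#' genus.
#'
#' @param min_n_h Minimum unique haplotypes per species (default 6).
#' @param min_n_s Minimum sequences per species (default 12).
#' @param min_species_per_genus Minimum qualifying species per genus
#'   (default 4).
#' @return An object of class `inclusion_config`.
#' @export
inclusion_config <- function(min_n_h = 6, min_n_s = 12,
                             min_species_per_genus = 4) {
  stopifnot(min_n_h >= 1, min_n_s >= 1, min_species_per_genus >= 1)
  structure(list(min_n_h = as.integer(min_n_h),
                 min_n_s = as.integer(min_n_s),
                 min_species_per_genus = as.integer(min_species_per_genus)),
            class = "inclusion_config")
}

# TRUE when two aligned sequences show no countable difference: no site where
# both characters are unambiguous nucleotides and differ.
zero_countable_diff <- function(a, b) {
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  !any(a[ok] != b[ok])
}

#' Collapse redundant haplotypes within each species
#'
#' Groups each species' sequences by the relation "zero countable
#' differences" (no alignment column at which both sequences carry
#' unambiguous, different nucleotides), closed transitively with union-find:
#' missing data can chain together sequences that differ at mutually masked
#' sites, in which case a warning is issued. Each group becomes one haplotype
#' whose representative is the member with the most non-missing characters
#' (ties broken by lexicographically smallest id), and the group size is kept
#' as the haplotype multiplicity, so N_S is conserved.
#'
#' @param ds A [genus_dataset()] (already trimmed and quality-checked).
#' @return An object of class `haplotype_table`: `genus`; `entries`, a
#'   data.frame with one row per haplotype (`species`, `haplotype_id`,
#'   `rep_id`, `multiplicity`, `member_ids`); `per_species`, a data.frame of
#'   `species`, `n_h`, `n_s`; and `dataset`, the input dataset (for sequence
#'   lookup when building views).
#' @export
collapse_haplotypes <- function(ds) {
  stopifnot(inherits(ds, "genus_dataset"))
  entries <- list()
  chained <- character(0)
  for (sp in unique(ds$species)) {
    ids <- ds$ids[ds$species == sp]
    n <- length(ids)
    parent <- seq_len(n)
    find <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    if (n > 1L) {
      for (i in seq_len(n - 1L)) {
        for (j in seq.int(i + 1L, n)) {
          if (zero_countable_diff(ds$seqs[ids[i], ], ds$seqs[ids[j], ])) {
            ri <- find(i); rj <- find(j)
            if (ri != rj) parent[rj] <- ri
          }
        }
      }
    }
    roots <- vapply(seq_len(n), find, integer(1))
    for (r in unique(roots)) {
      members <- ids[roots == r]
      # flag transitive chains: some pair inside the group still differs
      if (length(members) > 2L) {
        pairs_differ <- FALSE
        for (i in seq_len(length(members) - 1L)) {
          for (j in seq.int(i + 1L, length(members))) {
            if (!zero_countable_diff(ds$seqs[members[i], ],
                                     ds$seqs[members[j], ])) {
              pairs_differ <- TRUE
            }
          }
        }
        if (pairs_differ) chained <- c(chained, members[1L])
      }
      nonmiss <- rowSums(matrix(!is_missing_char(
        ds$seqs[members, , drop = FALSE]), nrow = length(members)))
      best <- members[order(-nonmiss, members)][1L]
      entries[[length(entries) + 1L]] <- data.frame(
        species = sp, rep_id = best, multiplicity = length(members),
        member_ids = paste(sort(members), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(chained)) {
    warning("transitive merging through missing data chained non-identical ",
            "sequences in group(s) containing: ",
            paste(chained, collapse = ", "), call. = FALSE)
  }
  entries <- do.call(rbind, entries)
  entries <- entries[order(entries$species, entries$rep_id), , drop = FALSE]
  hap_num <- stats::ave(seq_len(nrow(entries)), entries$species,
                        FUN = seq_along)
  entries$haplotype_id <- sprintf("%s_h%02d", entries$species, hap_num)
  entries <- entries[, c("species", "haplotype_id", "rep_id",
                         "multiplicity", "member_ids")]
  rownames(entries) <- NULL
  per_species <- do.call(rbind, lapply(split(entries, entries$species),
    function(e) data.frame(species = e$species[1L], n_h = nrow(e),
                           n_s = sum(e$multiplicity),
                           stringsAsFactors = FALSE)))
  rownames(per_species) <- NULL
  structure(list(genus = ds$genus, entries = entries,
                 per_species = per_species, dataset = ds),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("<haplotype_table> ", x$genus, ": ", nrow(x$per_species), " species, ",
      sum(x$per_species$n_h), " haplotypes from ", sum(x$per_species$n_s),
      " sequences\n", sep = "")
  invisible(x)
}

#' Write the haplotype membership map as TSV
#'
#' @param tab A [collapse_haplotypes()] result.
#' @param path Output path.
#' @return `tab`, invisibly.
#' @export
write_haplotype_map <- function(tab, path) {
  stopifnot(inherits(tab, "haplotype_table"))
  utils::write.table(
    tab$entries[, c("species", "haplotype_id", "member_ids", "multiplicity")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

# A dataset view: the subset of sequences a given unit of analysis uses.
new_genus_view <- function(genus, view, seqs, species, multiplicity = NULL) {
  structure(list(genus = genus, view = view, ids = rownames(seqs),
                 species = stats::setNames(species, rownames(seqs)),
                 seqs = seqs, multiplicity = multiplicity),
            class = "genus_view")
}

#' @export
print.genus_view <- function(x, ...) {
  cat("<genus_view> ", x$genus, " [", x$view, "]: ", nrow(x$seqs),
      " sequences, ", length(unique(x$species)), " species\n", sep = "")
  invisible(x)
}

#' Build the parallel N_H and N_S datasets from haplotype tables
#'
#' Applies the inclusion thresholds to each genus' haplotype table and
#' returns two parallel collections of dataset views: the `NH` view keeps,
#' for species with at least `min_n_h` unique haplotypes, one representative
#' sequence per haplotype; the `NS` view keeps, for species with at least
#' `min_n_s` sequences, every sequence (redundant haplotypes retained). In
#' either view a genus is dropped when fewer than `min_species_per_genus`
#' species qualify. A species may appear in one view and not the other.
#'
#' @param tables A single `haplotype_table` or a list of them (one per
#'   genus).
#' @param cfg An [inclusion_config()].
#' @return A list with elements `nh` and `ns`, each a named list of
#'   `genus_view` objects (possibly empty, with a warning, when no genus
#'   qualifies).
#' @export
build_datasets <- function(tables, cfg = inclusion_config()) {
  if (inherits(tables, "haplotype_table")) tables <- list(tables)
  stopifnot(all(vapply(tables, inherits, logical(1), "haplotype_table")),
            inherits(cfg, "inclusion_config"))
  nh <- list(); ns <- list()
  for (tab in tables) {
    ds <- tab$dataset
    sp_h <- tab$per_species$species[tab$per_species$n_h >= cfg$min_n_h]
    if (length(sp_h) >= cfg$min_species_per_genus) {
      keep <- tab$entries[tab$entries$species %in% sp_h, , drop = FALSE]
      seqs <- ds$seqs[keep$rep_id, , drop = FALSE]
      nh[[tab$genus]] <- new_genus_view(tab$genus, "NH", seqs, keep$species,
                                        multiplicity = stats::setNames(
                                          keep$multiplicity, keep$rep_id))
    }
    sp_s <- tab$per_species$species[tab$per_species$n_s >= cfg$min_n_s]
    if (length(sp_s) >= cfg$min_species_per_genus) {
      ids <- ds$ids[ds$species %in% sp_s]
      ns[[tab$genus]] <- new_genus_view(tab$genus, "NS",
                                        ds$seqs[ids, , drop = FALSE],
                                        ds$species[ids])
    }
  }
  if (!length(nh) && !length(ns)) {
    warning("no genus met the inclusion thresholds in either dataset",
            call. = FALSE)
  }
  list(nh = nh, ns = ns)
}
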