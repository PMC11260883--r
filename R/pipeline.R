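#' Run the full barcoding-gap audit on one or more genus datasets
#'
#' End-to-end orchestration of the audit for each genus: collapse haplotypes,
#' build the parallel unique-haplotype (N_H) and all-sequence (N_S) views
#' under the inclusion thresholds, compute K2P distance matrices and species
#' summaries per view, detect local (per species) and global (per genus)
#' barcoding gaps, compare the two views with permutation tests, delimit
#' species from the N_H view (unique haplotypes only) and classify
#' recognized species into the five concordance categories. Produces three
#' report tables: local-gap counts/percentages per genus and view plus their
#' union ("total examined" counts a species once, with a gap if it has one
#' in either view); genus means, gap threshold ratios and view-comparison
#' p-values; and delimitation concordance counts.
#'
#' @param datasets A `genus_dataset` or list of them (one per genus), e.g.
#'   from [read_alignment()] or [simulate_genus()].
#' @param inclusion An [inclusion_config()].
#' @param multipliers Global-gap rule multipliers (default `c(10, 5)`).
#' @param pooling Distribution pooling for the global gap (see
#'   [global_gap()]).
#' @param iterations Permutation-test iterations (default 10000; small
#'   groups are enumerated exhaustively regardless).
#' @param n_perm Permutations per partition score in delimitation
#'   (default 199).
#' @param plausibility_cap See [rank_partitions()].
#' @param seed Optional integer; every stochastic stage derives its own
#'   recorded sub-seed from it.
#' @param out_dir Optional directory; when given, all stage TSVs and report
#'   tables are written there.
#' @return An object of class `barcodegap_run` with `local_table`,
#'   `gap_table`, `concordance_table`, per-genus `detail` (matrices,
#'   summaries, gap records, rankings, records) and a `log` of seeds,
#'   thresholds and dropped records.
#' @export
run_full_analysis <- function(datasets, inclusion = inclusion_config(),
                              multipliers = c(10, 5),
                              pooling = "species_means",
                              iterations = 10000, n_perm = 199,
                              plausibility_cap = 0.9, seed = NULL,
                              out_dir = NULL) {
  if (inherits(datasets, "genus_dataset")) datasets <- list(datasets)
  stopifnot(all(vapply(datasets, inherits, logical(1), "genus_dataset")))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  tables <- lapply(datasets, collapse_haplotypes)
  names(tables) <- vapply(tables, `[[`, character(1), "genus")
  views <- build_datasets(tables, inclusion)
  genera <- union(names(views$nh), names(views$ns))

  detail <- list()
  local_rows <- list(); gap_rows <- list(); conc_rows <- list()
  for (g in genera) {
    d <- list(genus = g)
    for (v in c("nh", "ns")) {
      view <- views[[v]][[g]]
      if (is.null(view)) next
      if (length(unique(view$species)) < 2L) next
      m <- pairwise_matrix(view)
      summ <- summarize_by_species(m, view$species)
      d[[v]] <- list(view = view, matrix = m, summary = summ,
                     local = local_gaps(summ),
                     global = global_gap(summ, genus = g,
                                         multipliers = multipliers,
                                         pooling = pooling))
    }
    # view comparison: per-species mean intra and per-pair mean inter
    if (!is.null(d$nh) && !is.null(d$ns)) {
      d$compare <- list(
        intra = permutation_test(d$nh$summary$intra$mean_intra,
                                 d$ns$summary$intra$mean_intra,
                                 iterations = iterations,
                                 seed = stage_seed(seed, 1000L)),
        inter = permutation_test(d$nh$summary$inter$mean_inter,
                                 d$ns$summary$inter$mean_inter,
                                 iterations = iterations,
                                 seed = stage_seed(seed, 2000L)))
    }
    # delimitation on the unique-haplotype view only
    if (!is.null(d$nh) && d$nh$matrix$n_masked == 0L) {
      delim <- tryCatch(
        delimit_species(d$nh$matrix, n_perm = n_perm,
                        seed = stage_seed(seed, 3000L),
                        plausibility_cap = plausibility_cap),
        error = function(e) NULL)
      if (!is.null(delim)) {
        records <- classify_species(d$nh$view$species, delim$selected)
        d$delimitation <- delim
        d$concordance <- list(
          records = records,
          summary = summarize_concordance(records, delim$selected))
      }
    }
    detail[[g]] <- d
    local_rows[[g]] <- local_table_row(d)
    gap_rows[[g]] <- gap_table_row(d)
    if (!is.null(d$concordance)) conc_rows[[g]] <- conc_table_row(d)
  }

  local_table <- do.call(rbind, local_rows)
  gap_table <- do.call(rbind, gap_rows)
  concordance_table <- if (length(conc_rows)) do.call(rbind, conc_rows)
  rownames(local_table) <- rownames(gap_table) <- NULL
  if (!is.null(concordance_table)) rownames(concordance_table) <- NULL

  log <- list(
    inclusion = unclass(inclusion), multipliers = multipliers,
    pooling = pooling, iterations = iterations, n_perm = n_perm,
    plausibility_cap = plausibility_cap, seed = seed,
    genera_in = names(tables), genera_analysed = genera,
    genera_dropped = setdiff(names(tables), genera))

  run <- structure(list(local_table = local_table, gap_table = gap_table,
                        concordance_table = concordance_table,
                        detail = detail, views = views, log = log),
                   class = "barcodegap_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# Per-genus row of the local-gap report. "Total examined" is the union of
# species across both views; a species counts as gap-present when it has a
# gap in either view, and view-discrepant species are listed.
local_table_row <- function(d) {
  stats_for <- function(x) {
    if (is.null(x)) return(list(n = NA_integer_, pct = NA_real_,
                                gap_sp = character(0), sp = character(0)))
    lg <- x$local
    list(n = nrow(lg), pct = round_half_up(100 * mean(lg$gap_present)),
         gap_sp = lg$species[lg$gap_present], sp = lg$species)
  }
  nh <- stats_for(d$nh); ns <- stats_for(d$ns)
  all_sp <- union(nh$sp, ns$sp)
  gap_any <- union(nh$gap_sp, ns$gap_sp)
  both <- intersect(nh$sp, ns$sp)
  discrepant <- both[both %in% gap_any &
                       !(both %in% nh$gap_sp & both %in% ns$gap_sp)]
  data.frame(
    genus = d$genus,
    n_species_nh = nh$n, pct_gap_nh = nh$pct,
    n_species_ns = ns$n, pct_gap_ns = ns$pct,
    n_species_total = length(all_sp),
    n_gap_total = length(gap_any),
    pct_gap_total = round_half_up(100 * length(gap_any) / length(all_sp)),
    discrepant_species = paste(discrepant, collapse = ","),
    stringsAsFactors = FALSE)
}

gap_table_row <- function(d) {
  fmt <- function(x) {
    if (is.null(x)) {
      return(list(intra = NA_real_, inter = NA_real_, gap = NA,
                  thr = NA_character_))
    }
    gg <- x$global
    list(intra = round_half_up(100 * gg$mean_intra, 1),
         inter = round_half_up(100 * gg$mean_inter, 1),
         gap = gg$gap_present,
         thr = if (!is.na(gg$threshold_ratio)) {
           sprintf("%.1fx", gg$threshold_ratio)
         } else "-")
  }
  nh <- fmt(d$nh); ns <- fmt(d$ns)
  data.frame(
    genus = d$genus,
    intra_pct_nh = nh$intra, inter_pct_nh = nh$inter,
    gap_nh = nh$gap, threshold_nh = nh$thr,
    intra_pct_ns = ns$intra, inter_pct_ns = ns$inter,
    gap_ns = ns$gap, threshold_ns = ns$thr,
    p_intra = if (!is.null(d$compare)) d$compare$intra$p_value else NA_real_,
    p_inter = if (!is.null(d$compare)) d$compare$inter$p_value else NA_real_,
    stringsAsFactors = FALSE)
}

conc_table_row <- function(d) {
  cs <- d$concordance$summary
  lg <- d$nh$local
  data.frame(
    genus = d$genus,
    n_local_gap = sum(lg$gap_present),
    n_species = cs$n_recognized,
    n_delimited = cs$n_delimited,
    PT = cs$counts[["perfect_taxonomy"]],
    PU = cs$counts[["pure_undersplit"]],
    IU = cs$counts[["impure_undersplit"]],
    PO = cs$counts[["pure_oversplit"]],
    IO = cs$counts[["impure_oversplit"]],
    stringsAsFactors = FALSE)
}

write_run <- function(run, out_dir) {
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(run$local_table, "table1_local_gaps.tsv")
  wt(run$gap_table, "table2_global_gaps.tsv")
  if (!is.null(run$concordance_table)) {
    wt(run$concordance_table, "table3_concordance.tsv")
  }
  for (g in names(run$detail)) {
    d <- run$detail[[g]]
    for (v in c("nh", "ns")) {
      if (is.null(d[[v]])) next
      wt(d[[v]]$local, sprintf("%s_%s_local_gaps.tsv", g, v))
      write_distance_matrix(d[[v]]$matrix,
                            file.path(out_dir,
                                      sprintf("%s_%s_k2p.tsv", g, v)))
      gg <- d[[v]]$global
      wt(rbind(data.frame(type = "intra",
                          unit = names(gg$intra_means) %||%
                            seq_along(gg$intra_means),
                          distance = unname(gg$intra_means)),
               data.frame(type = "inter",
                          unit = names(gg$inter_means) %||%
                            seq_along(gg$inter_means),
                          distance = unname(gg$inter_means))),
         sprintf("%s_%s_gap_distributions.tsv", g, v))
    }
    if (!is.null(d$delimitation)) {
      write_partition(d$delimitation$selected,
                      file.path(out_dir, sprintf("%s_partition.tsv", g)))
      wt(d$delimitation$ranking, sprintf("%s_partition_ranking.tsv", g))
    }
    if (!is.null(d$concordance)) {
      write_concordance(d$concordance$records, d$concordance$summary,
                        file.path(out_dir, sprintf("%s_concordance.tsv", g)),
                        file.path(out_dir,
                                  sprintf("%s_concordance_summary.tsv", g)))
    }
  }
  invisible(run)
}

#' @export
print.barcodegap_run <- function(x, ...) {
  cat("<barcodegap_run> ", length(x$detail), " genus/genera analysed\n\n",
      sep = "")
  cat("Local barcoding gaps:\n")
  print(x$local_table)
  cat("\nGlobal barcoding gaps:\n")
  print(x$gap_table)
  if (!is.null(x$concordance_table)) {
    cat("\nDelimitation concordance:\n")
    print(x$concordance_table)
  }
  invisible(x)
}
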