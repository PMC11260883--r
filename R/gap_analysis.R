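#' Local barcoding gaps per species
#'
#' A species has a local barcoding gap when its minimum interspecific K2P
#' distance to any congener in the dataset is strictly greater than its
#' maximum intraspecific distance; such species can be reliably identified
#' from the barcode alone. Species sharing a haplotype with a congener have
#' `min_inter = 0` and therefore never show a gap. Ties
#' (`min_inter == max_intra`) count as no gap.
#'
#' @param summ A [summarize_by_species()] result.
#' @return A data.frame with one row per species: `species`, `max_intra`,
#'   `min_inter`, `gap_present`, `nearest_congener`. Species with no
#'   applicable interspecific pair are excluded and listed in the
#'   `excluded` attribute. Plot the result with `max_intra` on x and
#'   `min_inter` on y: points above the 1:1 line have a gap.
#' @export
local_gaps <- function(summ) {
  stopifnot(inherits(summ, "species_distance_summary"))
  species <- summ$intra$species
  rows <- lapply(species, function(s) {
    rel <- summ$inter[summ$inter$species_a == s | summ$inter$species_b == s, ,
                      drop = FALSE]
    if (!nrow(rel)) return(NULL)
    k <- which.min(rel$min_inter)
    congener <- ifelse(rel$species_a[k] == s, rel$species_b[k],
                       rel$species_a[k])
    mi <- summ$intra$max_intra[summ$intra$species == s]
    data.frame(species = s, max_intra = mi, min_inter = rel$min_inter[k],
               gap_present = rel$min_inter[k] > mi,
               nearest_congener = congener, stringsAsFactors = FALSE)
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) {
    stop("no species has an applicable interspecific distance", call. = FALSE)
  }
  out <- do.call(rbind, rows[keep])
  rownames(out) <- NULL
  attr(out, "excluded") <- species[!keep]
  out
}

#' Global barcoding gap for a genus
#'
#' Builds the genus' distributions of intraspecific and interspecific
#' distances and tests for a global barcoding gap: no overlap between the two
#' distributions (strictly, `max(intra) < min(inter)`). When a gap is
#' present, the threshold ratio `mean_inter / mean_intra` is compared against
#' the configured multipliers (defaults 10, the classical rule, and 5, the
#' relaxed working threshold for taxa with shallow interspecific divergence).
#'
#' Two poolings are available: `"species_means"` (default) uses one mean
#' intraspecific distance per species and one mean interspecific distance per
#' species pair, so the genus means are unweighted averages of those;
#' `"raw_pairs"` pools every applicable pairwise distance directly.
#'
#' @param summ A [summarize_by_species()] result.
#' @param genus Genus label to record.
#' @param multipliers Numeric rule multipliers to evaluate (default
#'   `c(10, 5)`).
#' @param pooling `"species_means"` or `"raw_pairs"`.
#' @return An object of class `genus_gap`: the two distributions, their
#'   means, `gap_present`, `threshold_ratio` (reported only when a gap is
#'   present and `mean_intra > 0`, otherwise `NA`), and `meets_rule`, a named
#'   logical per multiplier.
#' @export
global_gap <- function(summ, genus = NA_character_, multipliers = c(10, 5),
                       pooling = c("species_means", "raw_pairs")) {
  stopifnot(inherits(summ, "species_distance_summary"))
  pooling <- match.arg(pooling)
  if (nrow(summ$intra) < 2L) stop("need at least 2 species", call. = FALSE)
  if (pooling == "species_means") {
    intra_vals <- stats::setNames(summ$intra$mean_intra, summ$intra$species)
    inter_vals <- stats::setNames(
      summ$inter$mean_inter,
      paste(summ$inter$species_a, summ$inter$species_b, sep = " vs "))
    mean_intra <- mean(intra_vals)
    mean_inter <- mean(inter_vals)
  } else {
    intra_vals <- rep(summ$pooled_intra$d, summ$pooled_intra$weight)
    inter_vals <- rep(summ$pooled_inter$d, summ$pooled_inter$weight)
    mean_intra <- mean(intra_vals)
    mean_inter <- mean(inter_vals)
  }
  if (!length(inter_vals)) {
    stop("no applicable interspecific distances", call. = FALSE)
  }
  gap <- max(intra_vals) < min(inter_vals)
  ratio_defined <- mean_intra > 0
  if (!ratio_defined) {
    warning("all species monomorphic: mean intraspecific distance is 0, ",
            "threshold ratio undefined", call. = FALSE)
  }
  ratio <- if (gap && ratio_defined) mean_inter / mean_intra else NA_real_
  meets <- stats::setNames(!is.na(ratio) & ratio >= multipliers,
                           paste0(format(multipliers), "x"))
  structure(list(genus = genus, pooling = pooling,
                 intra_means = intra_vals, inter_means = inter_vals,
                 mean_intra = mean_intra, mean_inter = mean_inter,
                 gap_present = gap, threshold_ratio = ratio,
                 ratio_defined = ratio_defined, meets_rule = meets),
            class = "genus_gap")
}

#' @export
print.genus_gap <- function(x, ...) {
  cat("<genus_gap> ", if (is.na(x$genus)) "(genus)" else x$genus,
      ": mean intra ", sprintf("%.1f%%", 100 * x$mean_intra),
      ", mean inter ", sprintf("%.1f%%", 100 * x$mean_inter),
      ", gap ", if (x$gap_present) "present" else "absent", sep = "")
  if (!is.na(x$threshold_ratio)) {
    cat(sprintf(" (%.1fx)", x$threshold_ratio))
  }
  cat("\n")
  invisible(x)
}
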