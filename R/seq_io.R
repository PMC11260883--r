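#' Construct a genus dataset
#'
#' A genus dataset holds one genus' aligned sequences as an uppercase
#' character matrix (rows = sequences, columns = alignment positions) together
#' with per-sequence species labels. It is the unit every downstream stage
#' (haplotype collapsing, distances, gap analysis, delimitation) operates on.
#'
#' @param genus Single genus label.
#' @param seqs Character matrix of aligned residues with unique row names
#'   (sequence ids). Residues are uppercased; `-`, `N` and `?` are treated as
#'   missing downstream.
#' @param species Character vector of species labels, one per row of `seqs`
#'   (recycled names are not allowed; order must match).
#' @return An object of class `genus_dataset` with elements `genus`, `ids`,
#'   `species` (named by id) and `seqs`.
#' @export
genus_dataset <- function(genus, seqs, species) {
  stopifnot(is.character(genus), length(genus) == 1L, nzchar(genus))
  if (!is.matrix(seqs) || !is.character(seqs)) {
    stop("`seqs` must be a character matrix of aligned residues", call. = FALSE)
  }
  if (nrow(seqs) < 1L) stop("a genus dataset needs at least one sequence", call. = FALSE)
  ids <- rownames(seqs)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("every sequence needs a non-empty id (row name)", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  if (length(species) != nrow(seqs)) {
    stop("`species` must have one label per sequence", call. = FALSE)
  }
  seqs[] <- toupper(seqs)
  species <- as.character(species)
  names(species) <- ids
  structure(
    list(genus = genus, ids = ids, species = species, seqs = seqs),
    class = "genus_dataset"
  )
}

#' @export
print.genus_dataset <- function(x, ...) {
  cat("<genus_dataset> ", x$genus, ": ", nrow(x$seqs), " sequences, ",
      length(unique(x$species)), " species, ", ncol(x$seqs), " bp\n", sep = "")
  invisible(x)
}

#' Read an aligned FASTA plus metadata table into a genus dataset
#'
#' Reads an aligned FASTA (wrapped or single-line; case-insensitive residues)
#' and a tab-separated metadata table with columns `id`, `genus`, `species`,
#' then validates that the alignment is rectangular, every sequence id occurs
#' exactly once in the metadata, and all sequences belong to one genus.
#'
#' @param fasta_path Path to the aligned FASTA file.
#' @param metadata_path Path to the metadata TSV (`id`, `genus`, `species`
#'   header).
#' @return A [genus_dataset()].
#' @export
read_alignment <- function(fasta_path, metadata_path) {
  dna <- ape::read.FASTA(fasta_path)
  if (length(dna) == 0L) stop("no sequences found in ", fasta_path, call. = FALSE)
  lens <- lengths(dna)
  if (length(unique(lens)) != 1L) {
    stop("ragged alignment: sequence lengths ",
         paste(sort(unique(lens)), collapse = ", "),
         " differ (inputs must be pre-aligned)", call. = FALSE)
  }
  ids <- names(dna)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("FASTA sequences must all be named", call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(do.call(rbind, as.character(dna)))
  rownames(seqs) <- ids

  meta <- utils::read.delim(metadata_path, colClasses = "character",
                            stringsAsFactors = FALSE)
  need <- c("id", "genus", "species")
  if (!all(need %in% names(meta))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(meta$id)) {
    stop("duplicate id(s) in metadata: ",
         paste(unique(meta$id[duplicated(meta$id)]), collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(ids, meta$id)
  if (length(missing)) {
    stop("sequence id(s) missing from metadata: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  meta <- meta[match(ids, meta$id), , drop = FALSE]
  genera <- unique(meta$genus)
  if (length(genera) != 1L) {
    stop("mixed genera in one dataset: ", paste(genera, collapse = ", "),
         "; analyse each genus separately", call. = FALSE)
  }
  genus_dataset(genera, seqs, meta$species)
}

#' Write a genus dataset back to FASTA + metadata TSV
#'
#' Emits exactly the two files [read_alignment()] consumes, so simulated data
#' can round-trip through the ingestion path.
#'
#' @param ds A [genus_dataset()].
#' @param fasta_path,metadata_path Output paths.
#' @return `ds`, invisibly.
#' @export
write_genus_dataset <- function(ds, fasta_path, metadata_path) {
  stopifnot(inherits(ds, "genus_dataset"))
  dna <- ape::as.DNAbin(ds$seqs)
  ape::write.FASTA(dna, fasta_path)
  meta <- data.frame(id = ds$ids, genus = ds$genus,
                     species = unname(ds$species[ds$ids]),
                     stringsAsFactors = FALSE)
  utils::write.table(meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(ds)
}

#' Trim poorly covered alignment ends and drop short sequences
#'
#' Removes leading and trailing alignment columns whose fraction of
#' non-missing characters (`-`, `N`, `?` count as missing) falls below
#' `min_col_coverage`; internal columns are never touched. Sequences left with
#' fewer than `min_seq_bp` non-missing characters are then dropped. Retained
#' characters are never altered, so the operation is idempotent.
#'
#' @param ds A [genus_dataset()].
#' @param min_col_coverage Minimum fraction of non-missing characters a
#'   terminal column must have to be kept (default 0.9).
#' @param min_seq_bp Minimum number of non-missing characters a sequence must
#'   retain (default 200 bp, so short fragments above that are kept).
#' @return A trimmed [genus_dataset()] with attributes `cols_removed` and
#'   `seqs_removed` recording what was cut.
#' @export
trim_alignment <- function(ds, min_col_coverage = 0.9, min_seq_bp = 200) {
  stopifnot(inherits(ds, "genus_dataset"))
  if (!(min_col_coverage > 0 && min_col_coverage <= 1)) {
    stop("`min_col_coverage` must be in (0, 1]", call. = FALSE)
  }
  if (min_seq_bp < 1) stop("`min_seq_bp` must be >= 1", call. = FALSE)

  present <- matrix(!is_missing_char(ds$seqs), nrow = nrow(ds$seqs))
  cov <- colMeans(present)
  ok <- cov >= min_col_coverage
  first <- if (any(ok)) which(ok)[1L] else ncol(ds$seqs) + 1L
  last <- if (any(ok)) which(ok)[length(which(ok))] else 0L
  if (first > last) {
    stop("no alignment column meets the coverage threshold; nothing left after trimming",
         call. = FALSE)
  }
  keep_cols <- seq.int(first, last)
  seqs <- ds$seqs[, keep_cols, drop = FALSE]

  nonmiss <- rowSums(matrix(!is_missing_char(seqs), nrow = nrow(seqs)))
  keep_rows <- nonmiss >= min_seq_bp
  if (!any(keep_rows)) {
    stop("all sequences fall below `min_seq_bp` after trimming", call. = FALSE)
  }
  out <- genus_dataset(ds$genus, seqs[keep_rows, , drop = FALSE],
                       ds$species[keep_rows])
  attr(out, "cols_removed") <- ncol(ds$seqs) - length(keep_cols)
  attr(out, "seqs_removed") <- ds$ids[!keep_rows]
  out
}

# NCBI genetic-code ids seqinr knows about (some ids are retired).
valid_genetic_codes <- function() {
  tab <- seqinr::SEQINR.UTIL$CODES.NCBI
  which(!grepl("deleted", as.character(tab$CODES)))
}

#' Check a sequence for an open reading frame
#'
#' Translates the sequence in the given frame under an NCBI genetic code
#' (default 5, invertebrate mitochondrial, appropriate for COI in
#' crustaceans) and reports whether any internal stop codon occurs. Codons
#' containing missing or ambiguous characters are skipped rather than counted
#' as stops; a trailing incomplete codon is ignored.
#'
#' @param seq Character vector of residues (or a single string), e.g. one row
#'   of a [genus_dataset()] `seqs` matrix.
#' @param code NCBI genetic-code id (default 5).
#' @param frame Reading-frame offset: 0, 1 or 2.
#' @return A list with `pass` (logical), `first_stop` (codon index within the
#'   frame, or `NA`), `n_codons` (codons examined) and `n_skipped`
#'   (ambiguous/missing codons skipped).
#' @export
check_orf <- function(seq, code = 5, frame = 0) {
  if (length(seq) == 1L && nchar(seq) > 1L) seq <- strsplit(seq, "")[[1L]]
  seq <- toupper(seq)
  if (!frame %in% 0:2) stop("`frame` must be 0, 1 or 2", call. = FALSE)
  if (!code %in% valid_genetic_codes()) {
    stop("unknown genetic code id: ", code, call. = FALSE)
  }
  inframe <- seq[seq_along(seq) > frame]
  clean <- inframe %in% c("A", "C", "G", "T")
  if (sum(clean) < 3L) {
    stop("fewer than 3 unambiguous in-frame characters; cannot assess ORF",
         call. = FALSE)
  }
  n_codons <- length(inframe) %/% 3L
  if (n_codons == 0L) stop("no complete codon in frame", call. = FALSE)
  codons <- matrix(inframe[seq_len(n_codons * 3L)], nrow = 3L)
  usable <- colSums(matrix(clean[seq_len(n_codons * 3L)], nrow = 3L)) == 3L
  aa <- rep(NA_character_, n_codons)
  if (any(usable)) {
    flat <- tolower(as.vector(codons[, usable, drop = FALSE]))
    aa[usable] <- seqinr::translate(flat, numcode = code)
  }
  stops <- which(!is.na(aa) & aa == "*")
  list(
    pass = length(stops) == 0L,
    first_stop = if (length(stops)) stops[1L] else NA_integer_,
    n_codons = n_codons,
    n_skipped = sum(!usable)
  )
}
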