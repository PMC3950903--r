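# Reading aligned sequence data, collapsing to distinct lineages, and
# deriving the segregating-site and 0/1 mutation-label matrices.

DNA_BASES <- c("A", "C", "G", "T")

# transition partner of each base (purine<->purine, pyrimidine<->pyrimidine)
TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

#' Construct a segregating-site alignment of distinct lineages
#'
#' A `seg_alignment` holds the distinct sequence lineages of a sample
#' together with their multiplicities (observed copy numbers).  The sample
#' size is `n = sum(multiplicities)`.
#'
#' @param lineage_ids Character vector of unique lineage labels.
#' @param sequences Character vector of equal-length base strings over
#'   `A`, `C`, `G`, `T`; pairwise distinct.
#' @param multiplicities Positive integer copy number per lineage.
#' @param site_positions Optional 1-based original coordinates of the
#'   alignment columns; defaults to `1:L`.
#' @return An object of class `seg_alignment` with fields `lineage_ids`,
#'   `sequences`, `multiplicities`, `site_positions`, `n` (sample size) and
#'   `n_sites`.
#' @export
seg_alignment <- function(lineage_ids, sequences, multiplicities,
                          site_positions = NULL) {
  lineage_ids <- as.character(lineage_ids)
  sequences <- toupper(as.character(sequences))
  multiplicities <- as.integer(multiplicities)
  if (length(lineage_ids) == 0L)
    stop("alignment must contain at least one lineage")
  if (length(sequences) != length(lineage_ids) ||
      length(multiplicities) != length(lineage_ids))
    stop("lineage_ids, sequences and multiplicities must have equal length")
  if (anyDuplicated(lineage_ids))
    stop("lineage ids must be unique")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop("all sequences must have equal length (aligned input required)")
  if (any(is.na(multiplicities)) || any(multiplicities < 1L))
    stop("multiplicities (frequencies) must be positive integers")
  if (anyDuplicated(sequences))
    stop("lineage sequences must be pairwise distinct; collapse duplicates ",
         "into a single lineage with a larger multiplicity")
  chars <- strsplit(sequences, "", fixed = TRUE)
  bad <- !vapply(chars, function(s) all(s %in% DNA_BASES), logical(1))
  if (any(bad))
    stop("sequences contain characters outside {A,C,G,T} (ambiguity codes ",
         "are rejected, not imputed): lineage(s) ",
         paste(lineage_ids[bad], collapse = ", "))
  L <- lens[1]
  if (is.null(site_positions)) site_positions <- seq_len(L)
  site_positions <- as.integer(site_positions)
  if (length(site_positions) != L)
    stop("site_positions must have one entry per alignment column")
  structure(
    list(lineage_ids = lineage_ids,
         sequences = sequences,
         multiplicities = multiplicities,
         site_positions = site_positions,
         n = sum(multiplicities),
         n_sites = L),
    class = "seg_alignment")
}

#' @export
print.seg_alignment <- function(x, ...) {
  cat(sprintf(
    "seg_alignment: %d distinct lineages, n = %d sequences, %d sites\n",
    length(x$lineage_ids), x$n, x$n_sites))
  invisible(x)
}

#' Read a lineage-frequency table
#'
#' Reads a delimited table with one row per distinct lineage: a `lineage`
#' label column, one single-base column per site (header gives the 1-based
#' site position), and a final `freq` column with the lineage multiplicity.
#' Both tab- and comma-separated files are accepted.  This is the layout of
#' the packaged Nuu-Chah-Nulth table (see [nuu_chah_nulth_path()]).
#'
#' @param path Path to the TSV/CSV file.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return A [seg_alignment()].
#' @export
read_lineage_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  header <- readLines(path, n = 1L)
  if (is.null(sep))
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  cols <- names(tab)
  if (length(cols) < 3L)
    stop("lineage table needs a lineage column, >=1 site column and a ",
         "freq column")
  freq_col <- which(tolower(cols) %in% c("freq", "freqs", "frequency"))
  if (length(freq_col) != 1L)
    stop("lineage table must have exactly one 'freq' column")
  id_col <- 1L
  site_cols <- setdiff(seq_along(cols), c(id_col, freq_col))
  freq_num <- suppressWarnings(as.numeric(tab[[freq_col]]))
  if (any(is.na(freq_num)) || any(freq_num != round(freq_num)) ||
      any(freq_num < 1))
    stop("frequencies must be positive integers")
  pos <- suppressWarnings(as.integer(gsub("^[^0-9]*", "", cols[site_cols])))
  if (any(is.na(pos))) pos <- seq_along(site_cols)
  seqs <- apply(as.matrix(tab[site_cols]), 1L, paste, collapse = "")
  seg_alignment(lineage_ids = tab[[id_col]],
                sequences = seqs,
                multiplicities = as.integer(freq_num),
                site_positions = pos)
}

#' Write a lineage-frequency table
#'
#' Inverse of [read_lineage_table()]; used by the simulator and the CLI.
#'
#' @param aln A [seg_alignment()].
#' @param path Output file path.
#' @param sep Field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_lineage_table <- function(aln, path, sep = "\t") {
  stopifnot(inherits(aln, "seg_alignment"))
  mat <- do.call(rbind, strsplit(aln$sequences, "", fixed = TRUE))
  df <- data.frame(lineage = aln$lineage_ids, mat,
                   freq = aln$multiplicities,
                   stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- c("lineage", aln$site_positions, "freq")
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read aligned FASTA sequences and collapse to distinct lineages
#'
#' Identical sequences are collapsed into one lineage whose multiplicity is
#' the number of copies; the lineage keeps the id of its first
#' representative.  Sequences must be pre-aligned (equal length).
#'
#' @param path Path to a FASTA file with at least one record.
#' @return A [seg_alignment()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  recs <- suppressWarnings(ape::read.FASTA(path))
  if (is.null(recs) || length(recs) == 0L)
    stop("FASTA file contains no records: ", path)
  seqs <- toupper(vapply(as.character(recs), paste, character(1),
                         collapse = ""))
  if (length(unique(nchar(seqs))) != 1L)
    stop("FASTA sequences have unequal lengths; aligned input required")
  first <- !duplicated(seqs)
  mult <- as.integer(table(factor(seqs, levels = seqs[first])))
  seg_alignment(lineage_ids = names(recs)[first],
                sequences = seqs[first],
                multiplicities = mult)
}

#' Extract the segregating sites of an alignment
#'
#' A segregating site is a column at which not all observed sequences carry
#' the same base.  Monomorphic columns are dropped; under the infinite-sites
#' assumption every retained column must show exactly two base types, and a
#' column with three or more observed bases raises a condition of class
#' `coaltree_infinite_sites_violation` (such data needs the upstream
#' preprocessing that removes sequences with repeat mutations at a site).
#'
#' @param aln A [seg_alignment()].
#' @return An object of class `seg_matrix`: fields `lineage_ids`,
#'   `multiplicities`, `bases` (character matrix, lineages x segregating
#'   sites), `site_positions` (original 1-based coordinates), `s` (number of
#'   segregating sites) and `base_counts` (per column, the two observed
#'   bases with their multiplicity-weighted counts).
#' @export
find_segregating_sites <- function(aln) {
  stopifnot(inherits(aln, "seg_alignment"))
  mat <- do.call(rbind, strsplit(aln$sequences, "", fixed = TRUE))
  rownames(mat) <- aln$lineage_ids
  n_types <- apply(mat, 2L, function(col) length(unique(col)))
  bad <- which(n_types > 2L)
  if (length(bad)) {
    pos <- aln$site_positions[bad]
    stop(errorCondition(
      paste0("infinite-sites violation: ", length(bad), " column(s) with ",
             ">2 observed bases at site position(s) ",
             paste(pos, collapse = ", ")),
      sites = pos,
      class = c("coaltree_infinite_sites_violation", "error")))
  }
  keep <- which(n_types == 2L)
  bases <- mat[, keep, drop = FALSE]
  colnames(bases) <- aln$site_positions[keep]
  counts <- lapply(seq_along(keep), function(j) {
    tab <- tapply(aln$multiplicities, bases[, j], sum)
    sort(tab, decreasing = TRUE)
  })
  structure(
    list(lineage_ids = aln$lineage_ids,
         multiplicities = aln$multiplicities,
         bases = bases,
         site_positions = aln$site_positions[keep],
         s = length(keep),
         base_counts = counts),
    class = "seg_matrix")
}

#' @export
print.seg_matrix <- function(x, ...) {
  cat(sprintf("seg_matrix: %d lineages (n = %d), s = %d segregating sites\n",
              length(x$lineage_ids), sum(x$multiplicities), x$s))
  invisible(x)
}

#' Construct a 0/1 mutation-label matrix
#'
#' Low-level constructor used by [label_least_shared()] and
#' [enumerate_rooted_trees()]; exposed for building matrices directly in
#' tests and examples.
#'
#' @param x Integer 0/1 matrix, lineages in rows, segregating sites in
#'   columns.
#' @param lineage_ids,multiplicities Lineage labels and copy numbers
#'   (defaults: rownames of `x` / all 1).
#' @param site_positions 1-based site coordinates (default: column index).
#' @param mutant_base,ancestral_base Optional per-column record of which
#'   base was labeled mutant/ancestral.
#' @param labeling Provenance tag, e.g. `"least-shared"` or
#'   `"enumerated-root-3"`.
#' @return An object of class `binary_matrix`.
#' @export
binary_matrix <- function(x, lineage_ids = rownames(x),
                          multiplicities = rep(1L, nrow(x)),
                          site_positions = seq_len(ncol(x)),
                          mutant_base = rep(NA_character_, ncol(x)),
                          ancestral_base = rep(NA_character_, ncol(x)),
                          labeling = "manual") {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (nrow(x) == 0L) stop("binary matrix needs at least one lineage row")
  if (any(!x %in% c(0L, 1L))) stop("matrix entries must be 0 or 1")
  if (is.null(lineage_ids))
    lineage_ids <- paste0("L", seq_len(nrow(x)))
  if (length(lineage_ids) != nrow(x))
    stop("one lineage id per row required")
  multiplicities <- as.integer(multiplicities)
  if (length(multiplicities) != nrow(x) || any(multiplicities < 1L))
    stop("one positive multiplicity per row required")
  dimnames(x) <- list(lineage_ids, site_positions)
  structure(
    list(x = x,
         lineage_ids = as.character(lineage_ids),
         multiplicities = multiplicities,
         site_positions = as.integer(site_positions),
         mutant_base = mutant_base,
         ancestral_base = ancestral_base,
         labeling = labeling),
    class = "binary_matrix")
}

#' @export
print.binary_matrix <- function(x, ...) {
  cat(sprintf("binary_matrix (%s): %d lineages x %d sites\n",
              x$labeling, nrow(x$x), ncol(x$x)))
  invisible(x)
}

#' Least-shared-mutations labeling of segregating sites
#'
#' At each segregating site the less common base type is labeled mutant
#' (`x = 1`) and the other ancestral (`x = 0`).  "Less common" is weighted
#' by lineage multiplicity, i.e. counts sequences, not distinct lineages.
#' Ties are broken by labeling the lexicographically smaller base mutant.
#'
#' @param m A `seg_matrix` from [find_segregating_sites()].
#' @return A [binary_matrix()] with labeling tag `"least-shared"`.
#' @export
label_least_shared <- function(m) {
  stopifnot(inherits(m, "seg_matrix"))
  s <- m$s
  x <- matrix(0L, nrow = length(m$lineage_ids), ncol = s)
  mutant <- character(s)
  ancestral <- character(s)
  if (s > 0L) {
    for (j in seq_len(s)) {
      counts <- m$base_counts[[j]]
      bs <- names(counts)
      mut <- if (counts[1] == counts[2]) min(bs) else bs[2]
      mutant[j] <- mut
      ancestral[j] <- setdiff(bs, mut)
      x[, j] <- as.integer(m$bases[, j] == mut)
    }
  }
  binary_matrix(x,
                lineage_ids = m$lineage_ids,
                multiplicities = m$multiplicities,
                site_positions = m$site_positions,
                mutant_base = mutant,
                ancestral_base = ancestral,
                labeling = "least-shared")
}

# expand a seg_alignment into one sequence per sampled copy (used for the
# FASTA round-trip property and by the simulator's FASTA output)
expand_alignment <- function(aln) {
  idx <- rep(seq_along(aln$lineage_ids), aln$multiplicities)
  copy <- sequence(aln$multiplicities)
  list(ids = paste0(aln$lineage_ids[idx], "_", copy),
       sequences = aln$sequences[idx])
}

#' Write an alignment as FASTA, expanded by multiplicity
#'
#' Each lineage is written `multiplicity` times with suffixed record ids, so
#' `read_fasta(write_fasta(aln, f))` recovers `aln` up to lineage order.
#'
#' @param aln A [seg_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  stopifnot(inherits(aln, "seg_alignment"))
  ex <- expand_alignment(aln)
  writeLines(paste0(">", ex$ids, "\n", ex$sequences), path)
  invisible(path)
}
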