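#' Construct a locus alignment
#'
#' The basic container for one locus: a character matrix of aligned
#' residues, one row per sample, with unique row names.  Residues are
#' uppercased and `U` is rewritten to `T`; the permitted alphabet is
#' A/C/G/T, the IUPAC ambiguity codes, `-` (gap) and `N`/`?`/`X` (missing).
#'
#' @param locus Locus name (single string).
#' @param matrix Character matrix of single residues with row names giving
#'   the sample ids.
#' @return An object of class `"locus_alignment"`: a list with elements
#'   `locus`, `sample_ids`, `matrix` and `length` (alignment columns).
#' @export
locus_alignment <- function(locus, matrix) {
  stopifnot(is.character(locus), length(locus) == 1, nzchar(locus))
  if (!is.matrix(matrix) || !is.character(matrix)) {
    stop("'matrix' must be a character matrix", call. = FALSE)
  }
  ids <- rownames(matrix)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("alignment matrix must have non-empty row names (sample ids)",
         call. = FALSE)
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate sample id(s) in locus '%s': %s", locus,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  if (ncol(matrix) < 1) {
    stop("alignment must have at least one column", call. = FALSE)
  }
  mat <- chartr("U", "T", toupper(matrix))
  encode_residues(mat, context = sprintf("locus '%s'", locus))  # validates
  rownames(mat) <- ids
  structure(
    list(locus = locus, sample_ids = ids, matrix = mat,
         length = ncol(mat)),
    class = "locus_alignment"
  )
}

#' @export
print.locus_alignment <- function(x, ...) {
  cat(sprintf("Locus alignment '%s': %d sequences x %d bp\n",
              x$locus, length(x$sample_ids), x$length))
  invisible(x)
}

#' Read an aligned multi-FASTA file as a locus alignment
#'
#' All records must have identical lengths (the file is an alignment, not a
#' sequence collection); violations are reported with the offending record.
#' Record order is preserved; residues are uppercased, `U` mapped to `T`.
#'
#' @param path Path to the FASTA file.
#' @param locus_name Locus name; defaults to the file name without
#'   extension.
#' @return A [locus_alignment()].
#' @export
read_fasta_alignment <- function(path,
                                 locus_name = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) {
    stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
  }
  recs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "DNA", forceDNAtolower = FALSE,
                       set.attributes = FALSE),
    error = function(e) stop(sprintf("cannot parse FASTA '%s': %s",
                                     path, conditionMessage(e)),
                             call. = FALSE)
  )
  if (length(recs) == 0) {
    stop(sprintf("no FASTA records in '%s'", path), call. = FALSE)
  }
  ids <- names(recs)
  lens <- lengths(recs)
  if (length(unique(lens)) > 1) {
    bad <- which(lens != lens[1])[1]
    stop(sprintf(
      "unequal sequence lengths in '%s': record %d ('%s') has %d bp, expected %d",
      path, bad, ids[bad], lens[bad], lens[1]), call. = FALSE)
  }
  mat <- do.call(rbind, recs)
  rownames(mat) <- ids
  locus_alignment(locus_name, mat)
}

#' Write a locus alignment as multi-FASTA
#'
#' @param alignment A [locus_alignment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(alignment, path) {
  stopifnot(inherits(alignment, "locus_alignment"))
  seqs <- lapply(seq_along(alignment$sample_ids),
                 function(i) alignment$matrix[i, ])
  seqinr::write.fasta(seqs, names = alignment$sample_ids,
                      file.out = path, nbchar = 60)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Expects a delimited text file with header columns `sample_id`,
#' `species`, `group` and `individual`.  The delimiter is sniffed between
#' tab and comma from the header line.  Extra columns are dropped with a
#' warning; duplicate sample ids and missing required columns are errors.
#'
#' @param path Path to the TSV/CSV file.
#' @return A data frame with the four required character columns.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("metadata file not found: %s", path), call. = FALSE)
  }
  header <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(header, gregexpr("\t", header))) >=
             lengths(regmatches(header, gregexpr(",", header)))) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", quote = "\"",
                          comment.char = "", check.names = FALSE,
                          stringsAsFactors = FALSE)
  required <- c("sample_id", "species", "group", "individual")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("metadata is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    warning(sprintf("ignoring extra metadata column(s): %s",
                    paste(extra, collapse = ", ")))
  }
  df <- df[required]
  if (anyDuplicated(df$sample_id)) {
    stop(sprintf("duplicate sample_id(s) in metadata: %s",
                 paste(unique(df$sample_id[duplicated(df$sample_id)]),
                       collapse = ", ")), call. = FALSE)
  }
  if (any(!nzchar(df$species))) {
    stop("metadata contains empty species names", call. = FALSE)
  }
  df
}

#' Cross-check alignments against sample metadata
#'
#' Report-only validation of a multi-locus dataset: flags alignment sample
#' ids absent from the metadata, metadata rows absent from every alignment,
#' and singleton species (informational).  Also attaches a `loci_present`
#' list column to the metadata recording, per sample, the loci whose
#' alignment contains it.  Never mutates its inputs.
#'
#' @param alignments Named list of [locus_alignment()] objects (names are
#'   locus names; unnamed lists are named from each alignment's `locus`).
#' @param metadata Data frame from [read_metadata()].
#' @return A list of class `"dataset_validation"` with elements `metadata`
#'   (input plus `loci_present`), `issues` (data frame with columns `type`,
#'   `item`, `message`; types `sample_not_in_metadata` and
#'   `sample_no_sequence` are fatal under a strict pipeline run,
#'   `singleton_species` is informational) and `species_counts` (species
#'   and sample tallies per group).
#' @export
validate_dataset <- function(alignments, metadata) {
  alignments <- name_alignments(alignments)
  issues <- list()
  add_issue <- function(type, item, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      type = type, item = item, message = message, stringsAsFactors = FALSE)
  }
  loci_present <- rep(list(character()), nrow(metadata))
  names(loci_present) <- metadata$sample_id
  for (locus in names(alignments)) {
    aln <- alignments[[locus]]
    for (id in aln$sample_ids) {
      if (id %in% metadata$sample_id) {
        loci_present[[id]] <- c(loci_present[[id]], locus)
      } else {
        add_issue("sample_not_in_metadata", id,
                  sprintf("sample '%s' in locus '%s' has no metadata row",
                          id, locus))
      }
    }
  }
  orphan <- metadata$sample_id[lengths(loci_present) == 0]
  for (id in orphan) {
    add_issue("sample_no_sequence", id,
              sprintf("metadata sample '%s' is absent from all alignments", id))
  }
  md <- metadata
  md$loci_present <- unname(loci_present)
  tally <- stats::aggregate(
    cbind(n_samples = metadata$sample_id) ~ species + group,
    data = transform(metadata, n_samples = 1), FUN = length)
  for (i in seq_len(nrow(tally))) {
    if (tally$n_samples[i] == 1) {
      add_issue("singleton_species", tally$species[i],
                sprintf("species '%s' is represented by a single individual",
                        tally$species[i]))
    }
  }
  counts <- stats::aggregate(species ~ group, data = tally, FUN = length)
  names(counts)[2] <- "n_species"
  counts$n_samples <- stats::aggregate(n_samples ~ group, data = tally,
                                       FUN = sum)$n_samples
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(type = character(), item = character(),
               message = character(), stringsAsFactors = FALSE)
  structure(
    list(metadata = md, issues = issues, species_counts = counts),
    class = "dataset_validation"
  )
}

#' @export
print.dataset_validation <- function(x, ...) {
  fatal <- x$issues$type %in% c("sample_not_in_metadata", "sample_no_sequence")
  cat(sprintf("Dataset validation: %d samples, %d issue(s) (%d consistency, %d informational)\n",
              nrow(x$metadata), nrow(x$issues), sum(fatal), sum(!fatal)))
  if (nrow(x$issues)) {
    for (m in x$issues$message) cat("  - ", m, "\n", sep = "")
  }
  invisible(x)
}

#' Write a distance table to disk
#'
#' @param table A `"distance_table"` from [distance_matrix()].
#' @param path Output path.
#' @param dialect `"long"` (TSV with columns `sample_a`, `sample_b`,
#'   `locus`, `distance`, `comparable_sites`) or `"phylip"` (square
#'   PHYLIP-style distance matrix; undefined entries are written as `NA`).
#' @return `path`, invisibly.
#' @export
write_distance_table <- function(table, path, dialect = c("long", "phylip")) {
  stopifnot(inherits(table, "distance_table"))
  dialect <- match.arg(dialect)
  if (dialect == "long") {
    df <- as.data.frame(table)
    if (nrow(df) == 0) {
      warning("empty distance table; writing header-only file")
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    n <- length(table$sample_ids)
    lines <- sprintf("%5d", n)
    for (i in seq_len(n)) {
      name <- formatC(substr(table$sample_ids[i], 1, 10), width = -10)
      vals <- ifelse(is.na(table$d[i, ]), "NA",
                     sprintf("%.6f", table$d[i, ]))
      lines <- c(lines, paste(name, paste(vals, collapse = " ")))
    }
    writeLines(lines, path)
  }
  invisible(path)
}

# Ensure a list of alignments is named by locus.
name_alignments <- function(alignments) {
  stopifnot(is.list(alignments), length(alignments) >= 1)
  ok <- vapply(alignments, inherits, logical(1), "locus_alignment")
  if (!all(ok)) stop("all elements must be locus_alignment objects",
                     call. = FALSE)
  if (is.null(names(alignments)) || any(!nzchar(names(alignments)))) {
    names(alignments) <- vapply(alignments, `[[`, character(1), "locus")
  }
  if (anyDuplicated(names(alignments))) {
    stop("duplicate locus names in alignment list", call. = FALSE)
  }
  alignments
}
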