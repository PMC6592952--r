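#' Read a protein FASTA file
#'
#' Reads a (possibly line-wrapped) multi-record protein FASTA file into an
#' [Biostrings::AAStringSet]. Record ids are the first whitespace-delimited
#' token of each header; the remainder of the header is kept as a
#' `description` metadata column. Sequences are upper-cased and whitespace
#' is stripped.
#'
#' @param path path to a FASTA file.
#' @return an `AAStringSet` named by record id, with a `description`
#'   metadata column. An empty file yields an empty set with a warning.
#'   Duplicate ids and non-FASTA content are errors (the latter reported
#'   with a line number).
#' @examples
#' tf <- tempfile(fileext = ".faa")
#' writeLines(c(">p1 a kinase", "MKT", ">p2", "MKV"), tf)
#' readProteinFasta(tf)
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) {
    warning("empty FASTA file: ", path)
    return(Biostrings::AAStringSet())
  }
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">"))
    stop(sprintf("not FASTA: line %d does not start with '>'", first))
  hdr_idx <- which(startsWith(lines, ">"))
  # every non-header, non-blank line must be plausible sequence
  seq_idx <- setdiff(nonblank, hdr_idx)
  seqs <- gsub("[[:space:]]", "", lines[seq_idx])
  bad <- which(grepl("[^A-Za-z*.-]", seqs))
  if (length(bad))
    stop(sprintf("not FASTA: unexpected characters on line %d", seq_idx[bad[1L]]))

  headers <- sub("^>", "", lines[hdr_idx])
  ids <- sub("[[:space:]].*$", "", headers)
  desc <- ifelse(grepl("[[:space:]]", headers),
                 sub("^[^[:space:]]+[[:space:]]+", "", headers), "")
  if (any(!nzchar(ids))) stop("FASTA header with empty id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate FASTA id: ", paste(unique(dup), collapse = ", "))

  rec_of_line <- findInterval(seq_idx, hdr_idx)
  seq <- vapply(seq_along(hdr_idx), function(i)
    paste(seqs[rec_of_line == i], collapse = ""), character(1L))
  out <- Biostrings::AAStringSet(toupper(seq))
  names(out) <- ids
  S4Vectors::mcols(out)$description <- desc
  out
}

#' Write a protein FASTA file
#'
#' @param x an `AAStringSet` (named).
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
writeProteinFasta <- function(x, path, width = 60L) {
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

.CYPOME_TABLE_COLS <- c("gene_no", "cyp_name", "length_aa", "heme_start",
                        "heme_motif", "perf_start", "perf_motif",
                        "khelix_start", "khelix_motif", "ortholog_name",
                        "ortholog_identity_pct", "ortholog_organism")

#' Path to the packaged Cunninghamella elegans CYPome annotation table
#'
#' @return path to the TSV shipped in `inst/extdata`.
#' @export
cypomeTablePath <- function() {
  system.file("extdata", "cunninghamella_cypome.tsv", package = "cypome",
              mustWork = TRUE)
}

#' Read a CYPome annotation table
#'
#' Loads a tab-delimited annotation table with one row per CYP gene model:
#' gene number, CYP name, protein length, the three signature motifs
#' (haem-binding decapeptide, PERF domain, K-helix) with their 1-based
#' start positions, and the closest known CYP ortholog with its percent
#' identity. The default is the packaged 32-gene *C. elegans* CYPome.
#' Thousands separators in numeric fields (e.g. `"1,211"`) are stripped at
#' parse time.
#'
#' @param path path to the TSV; defaults to the packaged table.
#' @return a data frame with columns `gene_no`, `cyp_name`, `length_aa`,
#'   `heme_start`, `heme_motif`, `perf_start`, `perf_motif`, `khelix_start`,
#'   `khelix_motif`, `ortholog_name`, `ortholog_identity_pct`,
#'   `ortholog_organism`.
#' @examples
#' tab <- readCypomeTable()
#' nrow(tab)  # 32
#' @export
readCypomeTable <- function(path = cypomeTablePath()) {
  raw <- read.delim(path, colClasses = "character", check.names = FALSE)
  miss <- setdiff(.CYPOME_TABLE_COLS, names(raw))
  extra <- setdiff(names(raw), .CYPOME_TABLE_COLS)
  if (length(miss) || length(extra))
    stop("annotation table schema mismatch; missing: [",
         paste(miss, collapse = ", "), "], unexpected: [",
         paste(extra, collapse = ", "), "]")
  tab <- raw[, .CYPOME_TABLE_COLS]
  for (col in c("length_aa", "heme_start", "perf_start", "khelix_start",
                "ortholog_identity_pct")) {
    v <- gsub(",", "", tab[[col]], fixed = TRUE)
    num <- suppressWarnings(as.numeric(v))
    if (anyNA(num))
      stop(sprintf("non-numeric value '%s' in column '%s', row %d",
                   tab[[col]][which(is.na(num))[1L]], col, which(is.na(num))[1L]))
    tab[[col]] <- num
  }
  # field-level invariants
  stopifnot(nchar(tab$heme_motif) == 10L, nchar(tab$perf_motif) == 4L,
            nchar(tab$khelix_motif) == 4L)
  if (any(tab$ortholog_identity_pct <= 0 | tab$ortholog_identity_pct > 100))
    stop("ortholog identity out of (0, 100]")
  if (any(tab$length_aa < 1 | tab$heme_start < 1 | tab$perf_start < 1 |
          tab$khelix_start < 1))
    stop("lengths and motif starts must be >= 1")
  if (anyDuplicated(tab$cyp_name)) stop("duplicate CYP names in table")
  tab
}

.REPORT_COLS <- c("query_id", "length_aa", "partial_flag", "khelix_motif",
                  "khelix_start", "perf_motif", "perf_start", "heme_motif",
                  "heme_start", "best_reference", "identity_pct", "tier",
                  "consistency_flags")

#' Write / read a candidate report
#'
#' Serialises a candidate table (the `candidates` slot of a
#' [CypomeResult-class]) to a TSV mirroring the layout of published CYPome
#' tables, one row per screened protein. Missing signatures are emitted as
#' `NA`. `readCandidateReport()` restores an equal data frame, so the pair
#' round-trips losslessly.
#'
#' @param candidates a data frame with the report columns (see
#'   [CypomeResult-class]).
#' @param path output (input) TSV path.
#' @return `writeCandidateReport()`: `path` invisibly;
#'   `readCandidateReport()`: the candidate data frame.
#' @export
writeCandidateReport <- function(candidates, path) {
  miss <- setdiff(.REPORT_COLS, names(candidates))
  if (length(miss))
    stop("candidate table is missing columns: ", paste(miss, collapse = ", "))
  out <- candidates[, .REPORT_COLS, drop = FALSE]
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA")
    TRUE
  }, error = function(e) stop("cannot write report to '", path, "': ",
                              conditionMessage(e)))
  invisible(path)
}

#' @rdname writeCandidateReport
#' @export
readCandidateReport <- function(path) {
  tab <- read.delim(path, colClasses = "character", na.strings = "NA",
                    check.names = FALSE)
  miss <- setdiff(.REPORT_COLS, names(tab))
  if (length(miss))
    stop("report schema mismatch; missing: ", paste(miss, collapse = ", "))
  tab <- tab[, .REPORT_COLS]
  for (col in c("length_aa", "khelix_start", "perf_start", "heme_start"))
    tab[[col]] <- as.integer(tab[[col]])
  tab$identity_pct <- as.numeric(tab$identity_pct)
  tab$partial_flag <- as.logical(tab$partial_flag)
  # empty flag strings come back as NA from read.delim
  tab$consistency_flags[is.na(tab$consistency_flags)] <- ""
  tab
}
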