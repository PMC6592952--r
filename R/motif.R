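# Degenerate motif scanning: the three conserved P450 signatures
# (K-helix EXXR < PERF PXRX < haem-binding FXXGXRXCXG along the sequence).

#' Compile a degenerate motif pattern
#'
#' @param id pattern name; the signature patterns use `"heme"`, `"perf"`
#'   and `"khelix"`.
#' @param spec motif string over the 20 standard residues plus `X`
#'   (wildcard for exactly one standard residue).
#' @return a [DegeneratePattern-class].
#' @examples
#' degeneratePattern("heme", "FXXGXRXCXG")
#' @export
degeneratePattern <- function(id, spec) {
  new("DegeneratePattern", id = as.character(id),
      spec = toupper(as.character(spec)))
}

#' The three P450 signature patterns
#'
#' Default degenerate patterns for the haem-binding decapeptide, the PERF
#' domain and the K-helix, in the orientation they occur along a P450
#' (K-helix, then PERF, then haem towards the C-terminus).
#'
#' @param heme,perf,khelix motif specs; override to scan variants.
#' @return named list of three [DegeneratePattern-class] objects.
#' @export
signaturePatterns <- function(heme = "FXXGXRXCXG", perf = "PXRX",
                              khelix = "EXXR") {
  list(heme = degeneratePattern("heme", heme),
       perf = degeneratePattern("perf", perf),
       khelix = degeneratePattern("khelix", khelix))
}

.asSequence <- function(sequence) {
  if (is(sequence, "XString") || is(sequence, "XStringSet"))
    sequence <- as.character(sequence)
  if (length(sequence) != 1L)
    stop("expected a single sequence")
  toupper(unname(sequence))
}

#' Test a degenerate pattern at one position
#'
#' `TRUE` iff, anchored at `start` (1-based), every literal pattern position
#' equals the target residue and every `X` position holds one of the 20
#' standard residues. Ambiguity codes (B, Z, J), U, `*` and `X` in the
#' target fail an `X` position: motif presence is not claimed on ambiguous
#' residues. Matching is case-insensitive on the target.
#'
#' @param pattern a [DegeneratePattern-class].
#' @param sequence a character string, `AAString` or length-1 `AAStringSet`.
#' @param start 1-based anchor position; must satisfy
#'   `1 <= start <= nchar(sequence) - length(pattern) + 1`.
#' @return logical.
#' @examples
#' p <- degeneratePattern("heme", "FXXGXRXCXG")
#' matchAt(p, "FSTGRRVCVG", 1)  # TRUE
#' @export
matchAt <- function(pattern, sequence, start) {
  stopifnot(is(pattern, "DegeneratePattern"))
  seq <- .asSequence(sequence)
  plen <- length(pattern)
  if (start < 1L || start > nchar(seq) - plen + 1L)
    stop(sprintf("start %d out of range for a %d-mer pattern on a %d-residue sequence",
                 start, plen, nchar(seq)))
  window <- strsplit(substr(seq, start, start + plen - 1L), "", fixed = TRUE)[[1L]]
  pat <- strsplit(pattern@spec, "", fixed = TRUE)[[1L]]
  all(ifelse(pat == "X", window %in% AA_STANDARD, window == pat))
}

.patternRegex <- function(pattern) {
  chars <- strsplit(pattern@spec, "", fixed = TRUE)[[1L]]
  cls <- paste0("[", paste(AA_STANDARD, collapse = ""), "]")
  paste(ifelse(chars == "X", cls, chars), collapse = "")
}

#' Scan a sequence for all (overlapping) motif hits
#'
#' Reports every position where [matchAt()] is true, ascending by start;
#' overlapping occurrences are all reported. A sequence shorter than the
#' pattern yields an empty result.
#'
#' @inheritParams matchAt
#' @return data frame with columns `pattern_id`, `start` (1-based) and
#'   `matched` (the matching substring).
#' @examples
#' scanMotif(degeneratePattern("khelix", "EXXR"), "ETLRETLR")  # hits at 1, 5
#' @export
scanMotif <- function(pattern, sequence) {
  stopifnot(is(pattern, "DegeneratePattern"))
  seq <- .asSequence(sequence)
  empty <- data.frame(pattern_id = character(), start = integer(),
                      matched = character(), stringsAsFactors = FALSE)
  if (nchar(seq) < length(pattern)) return(empty)
  # lookahead regex finds overlapping occurrences
  rx <- sprintf("(?=%s)", .patternRegex(pattern))
  m <- gregexpr(rx, seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(empty)
  starts <- as.integer(m)
  data.frame(pattern_id = pattern@id, start = starts,
             matched = substring(seq, starts, starts + length(pattern) - 1L),
             stringsAsFactors = FALSE)
}

#' Anchor the three-motif P450 signature in a sequence
#'
#' Applies the deterministic anchor rule: the haem anchor is the rightmost
#' haem-pattern hit; the PERF anchor is the rightmost PERF hit strictly
#' upstream of the haem anchor; the K-helix anchor is the rightmost K-helix
#' hit strictly upstream of the PERF anchor. Returns `NULL` when any anchor
#' is absent. The haem motif sits C-terminally in every coordinate-consistent
#' annotated CYP, which makes rightmost selection both deterministic and
#' biologically ordered.
#'
#' @param sequence a character string, `AAString` or length-1 `AAStringSet`.
#' @param patterns list with elements `heme`, `perf`, `khelix`
#'   (see [signaturePatterns()]).
#' @return `NULL`, or a list with elements `khelix`, `perf`, `heme`, each a
#'   list with `start` and `matched`; starts satisfy
#'   `khelix$start < perf$start < heme$start`.
#' @export
findSignature <- function(sequence, patterns = signaturePatterns()) {
  stopifnot(all(c("heme", "perf", "khelix") %in% names(patterns)))
  seq <- .asSequence(sequence)
  heme_hits <- scanMotif(patterns$heme, seq)
  if (!nrow(heme_hits)) return(NULL)
  h <- heme_hits[nrow(heme_hits), ]
  perf_hits <- scanMotif(patterns$perf, seq)
  perf_hits <- perf_hits[perf_hits$start < h$start, , drop = FALSE]
  if (!nrow(perf_hits)) return(NULL)
  p <- perf_hits[nrow(perf_hits), ]
  k_hits <- scanMotif(patterns$khelix, seq)
  k_hits <- k_hits[k_hits$start < p$start, , drop = FALSE]
  if (!nrow(k_hits)) return(NULL)
  k <- k_hits[nrow(k_hits), ]
  list(khelix = list(start = k$start, matched = k$matched),
       perf   = list(start = p$start, matched = p$matched),
       heme   = list(start = h$start, matched = h$matched))
}

.conforms <- function(pattern, motif) {
  nchar(motif) == length(pattern) && matchAt(pattern, motif, 1L)
}

#' Validate one CYPome annotation row
#'
#' Runs six independent checks on a row of a CYPome annotation table (see
#' [readCypomeTable()]): conformance of the three motif strings to their
#' degenerate patterns, the K-helix < PERF < haem ordering of start
#' positions, coordinate consistency of the haem motif with the protein
#' length (`heme_start + heme_length - 1 <= length_aa`), and full-length
#' status (`length_aa >= partial_threshold`). Failures are reported, never
#' raised: a published row may legitimately fail a check (one *C. elegans*
#' row places its haem motif beyond the stated protein length).
#'
#' @param row a one-row data frame or list with the annotation fields.
#' @param patterns signature patterns, see [signaturePatterns()].
#' @param partial_threshold minimum full-length protein size in residues.
#' @return named logical vector with elements `heme_conforms`,
#'   `perf_conforms`, `khelix_conforms`, `motif_order`, `coords_consistent`,
#'   `full_length`.
#' @export
validateCypRow <- function(row, patterns = signaturePatterns(),
                           partial_threshold = 300L) {
  c(heme_conforms   = .conforms(patterns$heme, row$heme_motif),
    perf_conforms   = .conforms(patterns$perf, row$perf_motif),
    khelix_conforms = .conforms(patterns$khelix, row$khelix_motif),
    motif_order     = row$khelix_start < row$perf_start &&
                      row$perf_start < row$heme_start,
    coords_consistent = row$heme_start + length(patterns$heme) - 1L <=
                        row$length_aa,
    full_length     = row$length_aa >= partial_threshold)
}

#' @rdname validateCypRow
#' @param rows an annotation data frame (all rows are validated).
#' @return `validateCypTable()`: a logical data frame, one row per
#'   annotation row (rownames = CYP names), one column per check.
#' @export
validateCypTable <- function(rows, patterns = signaturePatterns(),
                             partial_threshold = 300L) {
  check_names <- c("heme_conforms", "perf_conforms", "khelix_conforms",
                   "motif_order", "coords_consistent", "full_length")
  checks <- t(vapply(seq_len(nrow(rows)), function(i)
    validateCypRow(rows[i, ], patterns, partial_threshold), logical(6L)))
  if (!nrow(rows))
    checks <- matrix(logical(0), 0L, 6L)
  colnames(checks) <- check_names
  out <- as.data.frame(checks)
  rownames(out) <- rows$cyp_name
  out
}
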