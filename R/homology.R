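# Global pairwise alignment, percent identity and identity-tier
# classification. Stands in for a BLASTP screen at desk scale: every
# query-reference pair is aligned exactly (Needleman-Wunsch, affine gaps),
# optionally after a shared k-mer prefilter.

roundHalfUp <- function(x, digits = 0L) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' Alignment scoring parameters
#'
#' Default scoring follows the EMBOSS Needle defaults the field uses for
#' protein global alignment: BLOSUM62, gap opening 10, gap extension 0.5.
#' A gap run of length L costs `gapOpening + L * gapExtension`.
#'
#' @param matrix a substitution matrix, or the name of one shipped with
#'   Biostrings (e.g. `"BLOSUM62"`, `"BLOSUM50"`, `"PAM250"`).
#' @param gapOpening,gapExtension non-negative gap penalties.
#' @return list with elements `matrix`, `gapOpening`, `gapExtension`.
#' @export
needleScoring <- function(matrix = "BLOSUM62", gapOpening = 10,
                          gapExtension = 0.5) {
  if (is.character(matrix)) {
    e <- new.env()
    data(list = matrix, package = "Biostrings", envir = e)
    matrix <- get(matrix, envir = e)
  }
  stopifnot(is.matrix(matrix), gapOpening >= 0, gapExtension >= 0)
  list(matrix = matrix, gapOpening = gapOpening, gapExtension = gapExtension)
}

#' Read an NCBI-format substitution matrix file
#'
#' Parses the plain-text matrix format used by BLAST (`#` comments, a
#' header row of residue letters, one labelled row per residue).
#'
#' @param path path to the matrix file.
#' @return numeric substitution matrix with residue dimnames.
#' @export
readSubstitutionMatrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a substitution matrix file: ", path)
  cols <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  rows <- lapply(lines[-1L], function(l) strsplit(trimws(l), "\\s+")[[1L]])
  rn <- vapply(rows, `[`, character(1L), 1L)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1L]), numeric(length(cols))))
  dimnames(vals) <- list(rn, cols)
  vals
}

.checkResidues <- function(seq, mat, what) {
  chars <- unique(strsplit(seq, "", fixed = TRUE)[[1L]])
  bad <- setdiff(chars, rownames(mat))
  if (length(bad))
    stop(sprintf("residue '%s' in %s sequence is absent from the substitution matrix",
                 bad[1L], what))
}

#' Global pairwise protein alignment
#'
#' Optimal Needleman-Wunsch global alignment under affine gap penalties.
#' Percent identity is counted over all alignment columns, terminal gaps
#' included (the EMBOSS Needle convention), so a short query aligned into a
#' long reference is penalised in identity.
#'
#' @param query,ref sequences (character, `AAString`, or length-1
#'   `AAStringSet`); must be non-empty.
#' @param scoring a [needleScoring()] list.
#' @return an [AlignmentResult-class].
#' @examples
#' globalAlign("MKT", "MKV")
#' @export
globalAlign <- function(query, ref, scoring = needleScoring()) {
  q <- .asSequence(query)
  r <- .asSequence(ref)
  if (!nzchar(q) || !nzchar(r)) stop("cannot align an empty sequence")
  .checkResidues(q, scoring$matrix, "query")
  .checkResidues(r, scoring$matrix, "reference")
  aln <- Biostrings::pairwiseAlignment(
    q, r, type = "global", substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gapOpening, gapExtension = scoring$gapExtension)
  aq <- as.character(Biostrings::alignedPattern(aln))
  ar <- as.character(Biostrings::alignedSubject(aln))
  qc <- strsplit(aq, "", fixed = TRUE)[[1L]]
  rc <- strsplit(ar, "", fixed = TRUE)[[1L]]
  cols <- length(qc)
  matches <- sum(qc == rc & qc != "-")
  new("AlignmentResult", alignedQuery = aq, alignedRef = ar,
      score = Biostrings::score(aln), columns = cols,
      matches = as.integer(matches), identityPct = 100 * matches / cols)
}

.alignmentCoverage <- function(aln) {
  qc <- strsplit(aln@alignedQuery, "", fixed = TRUE)[[1L]]
  rc <- strsplit(aln@alignedRef, "", fixed = TRUE)[[1L]]
  100 * sum(qc != "-" & rc != "-") / sum(rc != "-")
}

#' Classify percent identity into CYP nomenclature tiers
#'
#' The nomenclature convention places two sequences in the same family at
#' >= 40% amino-acid identity and the same subfamily at >= 55%; boundary
#' values classify upward. Committee judgement occasionally keeps a
#' borderline sequence (e.g. 39%) in a family, which is why the thresholds
#' are exposed.
#'
#' @param identity_pct percent identity in `[0, 100]`.
#' @param family_threshold,subfamily_threshold tier cutoffs.
#' @return one of `"same_subfamily"`, `"same_family"`, `"new_family"`.
#' @examples
#' classifyTier(94)  # same_subfamily
#' classifyTier(47)  # same_family
#' classifyTier(32)  # new_family
#' @export
classifyTier <- function(identity_pct, family_threshold = 40,
                         subfamily_threshold = 55) {
  if (any(identity_pct < 0 | identity_pct > 100))
    stop("identity must be in [0, 100]")
  ifelse(identity_pct >= subfamily_threshold, "same_subfamily",
         ifelse(identity_pct >= family_threshold, "same_family", "new_family"))
}

#' Parse a CYP name into family / subfamily / member
#'
#' Accepts names with or without the `CYP` prefix: family is the leading
#' digit run, subfamily the optional letter(s), member the optional
#' trailing digits (e.g. `"5313D1"` is family 5313, subfamily D, member 1;
#' plain `"51"` is a family-level name).
#'
#' @param name CYP name(s).
#' @return data frame with columns `family`, `subfamily`, `member`.
#' @export
parseCypName <- function(name) {
  core <- sub("^CYP", "", toupper(name))
  m <- regmatches(core, regexec("^([0-9]+)([A-Z]*)([0-9]*)$", core))
  bad <- vapply(m, length, integer(1L)) == 0L
  if (any(bad)) stop("not a CYP name: ", name[bad][1L])
  data.frame(family = vapply(m, `[`, character(1L), 2L),
             subfamily = vapply(m, `[`, character(1L), 3L),
             member = vapply(m, `[`, character(1L), 4L),
             stringsAsFactors = FALSE)
}

.sharedKmerCount <- function(a, b, k = 4L) {
  if (nchar(a) < k || nchar(b) < k) return(0L)
  ka <- unique(substring(a, 1:(nchar(a) - k + 1L), k:nchar(a)))
  kb <- unique(substring(b, 1:(nchar(b) - k + 1L), k:nchar(b)))
  length(intersect(ka, kb))
}

#' Best reference CYP for a query protein
#'
#' Aligns the query to every reference, picks the maximal percent identity
#' (ties broken by byte-order lexicographic reference name) and attaches a
#' [classifyTier()] assignment.
#'
#' @param query a sequence (character / `AAString` / length-1 `AAStringSet`).
#' @param refs a named `AAStringSet` (or named character vector) of
#'   reference CYP protein sequences; must be non-empty.
#' @param scoring a [needleScoring()] list.
#' @param family_threshold,subfamily_threshold tier cutoffs.
#' @return list with `best_reference`, `identity_pct`, `coverage_pct`
#'   (fraction of reference residues aligned to query residues), `tier`.
#' @export
bestReference <- function(query, refs, scoring = needleScoring(),
                          family_threshold = 40, subfamily_threshold = 55) {
  if (length(refs) == 0L) stop("reference set is empty")
  if (is.null(names(refs)) || any(!nzchar(names(refs))))
    stop("references must be named")
  ids <- numeric(length(refs))
  cov <- numeric(length(refs))
  for (i in seq_along(refs)) {
    aln <- globalAlign(query, refs[[i]], scoring)
    ids[i] <- aln@identityPct
    cov[i] <- .alignmentCoverage(aln)
  }
  ord <- order(-ids, names(refs), method = "radix")
  best <- ord[1L]
  list(best_reference = names(refs)[best], identity_pct = ids[best],
       coverage_pct = cov[best],
       tier = classifyTier(ids[best], family_threshold, subfamily_threshold))
}
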