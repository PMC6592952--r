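# Discovery pipeline: homology screen -> signature validation -> partial
# filter -> identity-tier classification, plus the redox-partner screen and
# a table-validation entry point for curated annotation tables.

#' Discovery pipeline configuration
#'
#' @param partial_threshold proteins shorter than this many residues are
#'   flagged partial and excluded from classification (default 300 aa).
#' @param screen_identity,screen_coverage first-pass homology screen: keep a
#'   protein when some reference aligns with at least `screen_identity`
#'   percent identity over at least `screen_coverage` percent of the
#'   reference. Permissive by design; the signature filter does the real
#'   work.
#' @param family_threshold,subfamily_threshold tier cutoffs, see
#'   [classifyTier()].
#' @param patterns signature patterns, see [signaturePatterns()].
#' @param scoring alignment scoring, see [needleScoring()].
#' @param kmer_prefilter,kmer_k,kmer_min_shared skip full alignment of a
#'   query-reference pair sharing fewer than `kmer_min_shared` distinct
#'   k-mers (cheap pruning of obviously unrelated pairs).
#' @return a named list.
#' @export
discoveryConfig <- function(partial_threshold = 300L, screen_identity = 20,
                            screen_coverage = 40, family_threshold = 40,
                            subfamily_threshold = 55,
                            patterns = signaturePatterns(),
                            scoring = needleScoring(),
                            kmer_prefilter = TRUE, kmer_k = 4L,
                            kmer_min_shared = 2L) {
  stopifnot(partial_threshold >= 1L)
  list(partial_threshold = as.integer(partial_threshold),
       screen_identity = screen_identity, screen_coverage = screen_coverage,
       family_threshold = family_threshold,
       subfamily_threshold = subfamily_threshold,
       patterns = patterns, scoring = scoring,
       kmer_prefilter = isTRUE(kmer_prefilter), kmer_k = as.integer(kmer_k),
       kmer_min_shared = as.integer(kmer_min_shared))
}

# identity/coverage of one query against every reference, honouring the
# k-mer prefilter; rows for pruned references carry identity -Inf
.alignAll <- function(query, refs, config) {
  out <- data.frame(name = names(refs), identity = -Inf, coverage = 0,
                    stringsAsFactors = FALSE)
  for (i in seq_along(refs)) {
    rseq <- as.character(refs[[i]])
    if (config$kmer_prefilter &&
        .sharedKmerCount(query, rseq, config$kmer_k) < config$kmer_min_shared)
      next
    aln <- globalAlign(query, rseq, config$scoring)
    out$identity[i] <- aln@identityPct
    out$coverage[i] <- .alignmentCoverage(aln)
  }
  out
}

#' Homology screen of a proteome against reference CYPs
#'
#' Retains, in input order, every protein whose alignment to some reference
#' passes the screen thresholds; each retained record is annotated (metadata
#' columns) with the best passing reference and its identity and coverage.
#'
#' @param proteome an `AAStringSet` (named), e.g. from [readProteinFasta()].
#' @param refs a named `AAStringSet` of reference CYPs; must be non-empty.
#' @param config a [discoveryConfig()] list.
#' @return the retained `AAStringSet` subset with metadata columns
#'   `screen_reference`, `screen_identity`, `screen_coverage`.
#' @export
screenProteome <- function(proteome, refs, config = discoveryConfig()) {
  if (length(refs) == 0L) stop("reference set is empty")
  if (length(proteome) == 0L) {
    out <- proteome
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      screen_reference = character(), screen_identity = numeric(),
      screen_coverage = numeric())
    return(out)
  }
  keep <- logical(length(proteome))
  ref_name <- character(length(proteome))
  ref_id <- numeric(length(proteome))
  ref_cov <- numeric(length(proteome))
  for (i in seq_along(proteome)) {
    hits <- .alignAll(as.character(proteome[[i]]), refs, config)
    pass <- hits$identity >= config$screen_identity &
            hits$coverage >= config$screen_coverage
    if (any(pass)) {
      hits <- hits[pass, , drop = FALSE]
      best <- order(-hits$identity, hits$name, method = "radix")[1L]
      keep[i] <- TRUE
      ref_name[i] <- hits$name[best]
      ref_id[i] <- hits$identity[best]
      ref_cov[i] <- hits$coverage[best]
    }
  }
  out <- proteome[keep]
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    screen_reference = ref_name[keep], screen_identity = ref_id[keep],
    screen_coverage = ref_cov[keep])
  out
}

.emptyCandidates <- function() {
  data.frame(query_id = character(), length_aa = integer(),
             partial_flag = logical(), khelix_motif = character(),
             khelix_start = integer(), perf_motif = character(),
             perf_start = integer(), heme_motif = character(),
             heme_start = integer(), best_reference = character(),
             identity_pct = numeric(), tier = character(),
             consistency_flags = character(), stringsAsFactors = FALSE)
}

.familyCounts <- function(names) {
  if (!length(names)) return(integer(0))
  fam <- parseCypName(names)$family
  tally <- sort(table(fam), decreasing = TRUE)
  setNames(as.integer(tally), names(tally))
}

#' Discover the CYPome of a proteome
#'
#' Full pipeline: [screenProteome()] against the references, then
#' [findSignature()] on every retained protein, partial-length flagging,
#' and [classifyTier()] on full-length signatured candidates. Every
#' screened protein is kept in the report (partials and signature-less
#' records are flagged, not dropped) so the screen is auditable.
#'
#' @inheritParams screenProteome
#' @return a [CypomeResult-class]. The summary counts satisfy
#'   `screened == classified + partial + signature_absent` (a partial with
#'   a signature counts in `partial`).
#' @export
discoverCypome <- function(proteome, refs, config = discoveryConfig()) {
  screened <- screenProteome(proteome, refs, config)
  mc <- S4Vectors::mcols(screened)
  cand <- .emptyCandidates()
  for (i in seq_along(screened)) {
    seq <- as.character(screened[[i]])
    sig <- findSignature(seq, config$patterns)
    partial <- nchar(seq) < config$partial_threshold
    tier <- NA_character_
    flags <- character(0)
    if (partial) flags <- c(flags, "partial")
    if (is.null(sig)) flags <- c(flags, "no_signature")
    if (!is.null(sig) && !partial)
      tier <- classifyTier(mc$screen_identity[i], config$family_threshold,
                           config$subfamily_threshold)
    cand <- rbind(cand, data.frame(
      query_id = names(screened)[i], length_aa = nchar(seq),
      partial_flag = partial,
      khelix_motif = if (is.null(sig)) NA_character_ else sig$khelix$matched,
      khelix_start = if (is.null(sig)) NA_integer_ else sig$khelix$start,
      perf_motif = if (is.null(sig)) NA_character_ else sig$perf$matched,
      perf_start = if (is.null(sig)) NA_integer_ else sig$perf$start,
      heme_motif = if (is.null(sig)) NA_character_ else sig$heme$matched,
      heme_start = if (is.null(sig)) NA_integer_ else sig$heme$start,
      best_reference = mc$screen_reference[i],
      identity_pct = mc$screen_identity[i], tier = tier,
      consistency_flags = paste(flags, collapse = ";"),
      stringsAsFactors = FALSE))
  }
  n_sig <- sum(!is.na(cand$heme_start))
  n_partial <- sum(cand$partial_flag)
  n_classified <- sum(!is.na(cand$tier))
  fams <- character(0)
  if (n_classified) {
    cls <- cand[!is.na(cand$tier), ]
    fams <- ifelse(cls$tier == "new_family", "new",
                   parseCypName(cls$best_reference)$family)
  }
  tally <- if (length(fams)) sort(table(fams), decreasing = TRUE) else table(character(0))
  summary <- list(
    input = length(proteome), screened = length(screened),
    signatured = n_sig, partial = n_partial, classified = n_classified,
    signature_absent = sum(!cand$partial_flag & is.na(cand$heme_start)),
    tiers = table(factor(cand$tier[!is.na(cand$tier)],
                         levels = c("same_subfamily", "same_family", "new_family"))),
    family_counts = setNames(as.integer(tally), names(tally)),
    n_flagged = sum(nzchar(cand$consistency_flags)))
  new("CypomeResult", candidates = cand, summary = summary, config = config)
}

#' Validate a curated CYPome annotation table
#'
#' Table-validation mode of the pipeline: the input is an annotation table
#' (motif strings, coordinates and ortholog identities, no sequences), as
#' produced by [readCypomeTable()]. Every row is checked with
#' [validateCypRow()]; rows whose three motifs conform and that are not
#' partial are counted as classified, with tiers assigned from the recorded
#' ortholog identity.
#'
#' @param rows annotation data frame, see [readCypomeTable()].
#' @param config a [discoveryConfig()] list.
#' @return a [CypomeResult-class]; `candidates$consistency_flags` names the
#'   failed checks per row, and the summary carries the family tally keyed
#'   by the rows' own CYP names.
#' @examples
#' res <- validateCypomeTable(readCypomeTable())
#' res
#' @export
validateCypomeTable <- function(rows, config = discoveryConfig()) {
  checks <- validateCypTable(rows, config$patterns, config$partial_threshold)
  conform <- checks$heme_conforms & checks$perf_conforms & checks$khelix_conforms
  partial <- !checks$full_length
  flags <- vapply(seq_len(nrow(checks)), function(i) {
    ok <- unlist(checks[i, ])
    paste(names(ok)[!ok], collapse = ";")
  }, character(1L))
  tier <- rep(NA_character_, nrow(rows))
  if (nrow(rows))
    tier <- ifelse(conform & !partial,
                   classifyTier(rows$ortholog_identity_pct,
                                config$family_threshold,
                                config$subfamily_threshold),
                   NA_character_)
  cand <- data.frame(
    query_id = rows$cyp_name, length_aa = as.integer(rows$length_aa),
    partial_flag = partial,
    khelix_motif = rows$khelix_motif, khelix_start = as.integer(rows$khelix_start),
    perf_motif = rows$perf_motif, perf_start = as.integer(rows$perf_start),
    heme_motif = rows$heme_motif, heme_start = as.integer(rows$heme_start),
    best_reference = rows$ortholog_name,
    identity_pct = rows$ortholog_identity_pct, tier = tier,
    consistency_flags = unname(flags), stringsAsFactors = FALSE)
  summary <- list(
    input = nrow(rows), screened = nrow(rows),
    signatured = sum(conform), partial = sum(partial),
    classified = sum(!is.na(tier)),
    signature_absent = sum(!partial & !conform),
    tiers = table(factor(tier[!is.na(tier)],
                         levels = c("same_subfamily", "same_family", "new_family"))),
    family_counts = .familyCounts(rows$cyp_name),
    n_flagged = sum(!checks$coords_consistent))
  new("CypomeResult", candidates = cand, summary = summary, config = config)
}

#' @describeIn summarizeCypome family tallies of a discovery / validation run
#' @export
setMethod("summarizeCypome", "CypomeResult", function(object, ...) {
  s <- object@summary
  list(family_counts = s$family_counts,
       n_families = length(s$family_counts),
       n_total = s$screened, n_classified = s$classified,
       n_partial = s$partial, n_flagged = s$n_flagged)
})

#' @describeIn summarizeCypome validate an annotation data frame, then summarise
#' @export
setMethod("summarizeCypome", "data.frame", function(object, ...) {
  summarizeCypome(validateCypomeTable(object, ...))
})

#' Default flavin-domain fingerprints for the redox-partner screen
#'
#' Simplified degenerate fingerprints for dinucleotide (FAD) and flavin
#' mononucleotide (FMN) binding regions, used by the synthetic benchmarks;
#' replace with curated patterns for real proteomes.
#'
#' @param fad,fmn motif specs.
#' @return named list of two [DegeneratePattern-class] objects.
#' @export
redoxSignaturePatterns <- function(fad = "GXGXXG", fmn = "TXTGXT") {
  list(fad = degeneratePattern("fad", fad),
       fmn = degeneratePattern("fmn", fmn))
}

.REDOX_BUCKETS <- c("CPR", "diflavin_oxidoreductase", "cyt_b5", "cyt_b5_reductase")

#' Screen a proteome for CYP redox-partner proteins
#'
#' Assigns each protein the bucket of its best redox reference passing the
#' homology screen thresholds. A CPR (NADPH-cytochrome P450 reductase)
#' call additionally requires both the FAD- and the FMN-binding fingerprint
#' in the query: CPRs are diflavin enzymes, and homology alone is not
#' accepted as evidence. A CPR-homologous protein missing either flavin
#' fingerprint is downgraded to `none` with the partial evidence recorded.
#'
#' @param proteome an `AAStringSet` (named).
#' @param redox_refs a named `AAStringSet` of labelled reference sequences;
#'   `S4Vectors::mcols(redox_refs)$bucket` must give each reference's class
#'   (one of `"CPR"`, `"diflavin_oxidoreductase"`, `"cyt_b5"`,
#'   `"cyt_b5_reductase"`).
#' @param redox_signatures FAD/FMN patterns, see [redoxSignaturePatterns()];
#'   required whenever CPR references are supplied.
#' @param config a [discoveryConfig()] list.
#' @return data frame with columns `id`, `bucket` (`"none"` when no call)
#'   and `evidence` (semicolon-joined).
#' @export
screenRedoxPartners <- function(proteome, redox_refs,
                                redox_signatures = redoxSignaturePatterns(),
                                config = discoveryConfig()) {
  buckets <- S4Vectors::mcols(redox_refs)$bucket
  if (is.null(buckets) || length(buckets) != length(redox_refs))
    stop("redox_refs must carry a 'bucket' metadata column")
  if (!all(buckets %in% .REDOX_BUCKETS))
    stop("unknown bucket label: ",
         paste(setdiff(buckets, .REDOX_BUCKETS), collapse = ", "))
  if (any(buckets == "CPR") &&
      (is.null(redox_signatures$fad) || is.null(redox_signatures$fmn)))
    stop("CPR references supplied but FAD/FMN signature patterns are missing")
  out <- data.frame(id = character(), bucket = character(),
                    evidence = character(), stringsAsFactors = FALSE)
  for (i in seq_along(proteome)) {
    seq <- as.character(proteome[[i]])
    hits <- .alignAll(seq, redox_refs, config)
    pass <- hits$identity >= config$screen_identity &
            hits$coverage >= config$screen_coverage
    bucket <- "none"
    evidence <- character(0)
    if (any(pass)) {
      h <- hits[pass, , drop = FALSE]
      best <- order(-h$identity, h$name, method = "radix")[1L]
      bucket <- buckets[match(h$name[best], names(redox_refs))]
      evidence <- sprintf("homology:%s(%.0f%%)", h$name[best], h$identity[best])
      if (bucket == "CPR") {
        has_fad <- nrow(scanMotif(redox_signatures$fad, seq)) > 0L
        has_fmn <- nrow(scanMotif(redox_signatures$fmn, seq)) > 0L
        if (has_fad) evidence <- c(evidence, "FAD")
        if (has_fmn) evidence <- c(evidence, "FMN")
        if (!(has_fad && has_fmn)) {
          evidence <- c(evidence, "CPR_evidence_incomplete")
          bucket <- "none"
        }
      }
    }
    out <- rbind(out, data.frame(id = names(proteome)[i], bucket = bucket,
                                 evidence = paste(evidence, collapse = ";"),
                                 stringsAsFactors = FALSE))
  }
  out
}
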