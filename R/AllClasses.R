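#' @import methods
#' @importFrom stats lm coef quantile sd setNames t.test p.adjust rnorm
#' @importFrom utils read.delim write.table data
NULL

#' The twenty standard amino-acid one-letter codes
#'
#' Residues an `X` wildcard position is allowed to match. Ambiguity codes
#' (B, Z, J), selenocysteine (U), stops (`*`) and `X` itself are excluded on
#' purpose: a signature motif should not be called on an ambiguous residue.
#'
#' @format A character vector of length 20.
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# ---- DegeneratePattern -----------------------------------------------------

#' Degenerate protein motif pattern
#'
#' A motif over the 20 standard amino-acid letters plus the wildcard `X`,
#' e.g. the P450 haem-binding decapeptide `FXXGXRXCXG`. Literal letters
#' match only themselves; `X` matches exactly one standard residue.
#'
#' @slot id single string naming the pattern (e.g. `"heme"`).
#' @slot spec the motif string over `{A..Y standard 20} + X`.
#'
#' @seealso [degeneratePattern()], [matchAt()], [scanMotif()]
#' @export
setClass("DegeneratePattern",
         representation(id = "character", spec = "character"))

setValidity("DegeneratePattern", function(object) {
  if (length(object@id) != 1L || !nzchar(object@id))
    return("'id' must be a single non-empty string")
  if (length(object@spec) != 1L || !nzchar(object@spec))
    return("'spec' must be a single non-empty string")
  chars <- strsplit(object@spec, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% c(AA_STANDARD, "X")))
  if (length(bad))
    return(sprintf("illegal character '%s' at position %d of pattern spec",
                   chars[bad[1L]], bad[1L]))
  TRUE
})

# ---- AlignmentResult -------------------------------------------------------

#' Global pairwise alignment result
#'
#' Holds the two gapped alignment strings of a Needleman-Wunsch global
#' alignment under affine gap penalties, the alignment score, and percent
#' identity counted over all alignment columns (terminal gaps included,
#' EMBOSS Needle convention).
#'
#' @slot alignedQuery,alignedRef gapped alignment strings of equal length.
#' @slot score alignment score.
#' @slot columns number of alignment columns.
#' @slot matches number of identical columns.
#' @slot identityPct `100 * matches / columns`.
#'
#' @seealso [globalAlign()], [percentIdentity()]
#' @export
setClass("AlignmentResult",
         representation(alignedQuery = "character", alignedRef = "character",
                        score = "numeric", columns = "integer",
                        matches = "integer", identityPct = "numeric"))

setValidity("AlignmentResult", function(object) {
  q <- object@alignedQuery; r <- object@alignedRef
  if (nchar(q) != nchar(r)) return("aligned strings differ in length")
  if (nchar(q) != object@columns) return("'columns' does not match strings")
  qc <- strsplit(q, "", fixed = TRUE)[[1L]]
  rc <- strsplit(r, "", fixed = TRUE)[[1L]]
  if (any(qc == "-" & rc == "-")) return("gap-vs-gap column present")
  if (sum(qc == rc & qc != "-") != object@matches)
    return("'matches' does not match the aligned strings")
  if (abs(object@identityPct - 100 * object@matches / object@columns) > 1e-9)
    return("identityPct != 100 * matches / columns")
  TRUE
})

# ---- EfficiencyFit ---------------------------------------------------------

#' qPCR amplification-efficiency fit
#'
#' Result of an ordinary least-squares fit of quantification cycle (Cq) on
#' log10 relative template concentration over a serial-dilution standard
#' curve. The per-cycle amplification factor is `E = 10^(-1/slope)`; a
#' perfect doubling assay has slope -3.3219 and E = 2.
#'
#' @slot gene gene/assay name.
#' @slot slope OLS slope of Cq on log10(concentration).
#' @slot efficiency amplification factor `10^(-1/slope)`.
#' @slot r2 coefficient of determination of the fit.
#' @slot nPoints number of dilution points used.
#' @slot valid `FALSE` when the slope is non-negative (unusable curve).
#'
#' @seealso [fitEfficiency()]
#' @export
setClass("EfficiencyFit",
         representation(gene = "character", slope = "numeric",
                        efficiency = "numeric", r2 = "numeric",
                        nPoints = "integer", valid = "logical"))

setValidity("EfficiencyFit", function(object) {
  if (object@nPoints < 3L) return("a fit needs at least 3 dilution points")
  if (is.finite(object@slope) && is.finite(object@efficiency) &&
      abs(object@efficiency - 10^(-1 / object@slope)) > 1e-9)
    return("efficiency != 10^(-1/slope)")
  TRUE
})

# ---- GeNormResult ----------------------------------------------------------

#' geNorm reference-gene stability result
#'
#' @slot mValues gene stability measures M (average pairwise SD of log2
#'   expression ratios against all other genes); lower is more stable.
#' @slot ranking exclusion order, least stable gene first.
#' @slot stabilityOrder genes from most to least stable.
#' @slot vSeries pairwise variations V(n/n+1) between normalisation factors
#'   built from the n and n+1 most stable genes, named `"2/3"`, `"3/4"`, ...
#' @slot optimalN recommended number of reference genes (>= 2).
#' @slot cutoff the V cutoff used to pick `optimalN`.
#'
#' @seealso [genormM()], [genormRank()]
#' @export
setClass("GeNormResult",
         representation(mValues = "numeric", ranking = "character",
                        stabilityOrder = "character", vSeries = "numeric",
                        optimalN = "integer", cutoff = "numeric"))

setValidity("GeNormResult", function(object) {
  if (any(object@mValues < 0)) return("M values must be >= 0")
  if (object@optimalN < 2L) return("optimalN must be >= 2")
  TRUE
})

# ---- RelQuantResult --------------------------------------------------------

#' Calibrated normalised relative quantities
#'
#' Per-sample and per-group results of efficiency-corrected, multi-reference
#' relative quantification: RQ (relative quantity), NF (normalisation
#' factor, geometric mean of reference RQs), NRQ = RQ/NF, CNRQ (NRQ scaled
#' so the calibrator group's geometric mean is 1) and delta-method
#' propagated standard errors.
#'
#' @slot samples per (sample, gene) data frame: `sample_id`, `group`,
#'   `gene`, `cq`, `rq`, `nf`, `nrq`, `cnrq`, `se_cnrq` and relative-SE
#'   components.
#' @slot groups per (group, gene) data frame: geometric-mean CNRQ,
#'   propagated SE, fold change and log10 fold change versus the calibrator
#'   group, and a Welch p-value where at least two biological replicates
#'   exist on both sides.
#' @slot references reference (normaliser) gene names.
#' @slot calibratorGroup the group whose geometric-mean CNRQ is fixed at 1.
#' @slot efficiencies per-gene amplification factors used.
#'
#' @seealso [computeCNRQ()], [groupFoldChange()], [testDifferential()]
#' @export
setClass("RelQuantResult",
         representation(samples = "data.frame", groups = "data.frame",
                        references = "character", calibratorGroup = "character",
                        efficiencies = "numeric"))

setValidity("RelQuantResult", function(object) {
  s <- object@samples
  need <- c("sample_id", "group", "gene", "rq", "nf", "nrq", "cnrq", "se_cnrq")
  if (!all(need %in% names(s)))
    return(paste("samples is missing columns:",
                 paste(setdiff(need, names(s)), collapse = ", ")))
  if (any(s$se_cnrq < 0, na.rm = TRUE)) return("negative standard error")
  cal <- s[s$group == object@calibratorGroup, , drop = FALSE]
  if (nrow(cal)) {
    gm <- tapply(cal$cnrq, cal$gene, function(x) exp(mean(log(x))))
    if (any(abs(gm - 1) > 1e-9))
      return("calibrator-group geometric mean CNRQ is not 1")
  }
  TRUE
})

# ---- CypomeResult ----------------------------------------------------------

#' Result of a CYPome discovery run or annotation-table validation
#'
#' @slot candidates one row per screened protein (or per annotation row in
#'   table-validation mode): signature motifs and 1-based start positions,
#'   partial flag, best reference, percent identity, classification tier
#'   and consistency flags.
#' @slot summary list of pipeline counts (screened, signatured, partial,
#'   classified, per-tier and per-family tallies, flagged rows).
#' @slot config the [discoveryConfig()] list the run used.
#'
#' @seealso [discoverCypome()], [validateCypomeTable()], [summarizeCypome()]
#' @export
setClass("CypomeResult",
         representation(candidates = "data.frame", summary = "list",
                        config = "list"))

setValidity("CypomeResult", function(object) {
  need <- c("query_id", "length_aa", "partial_flag", "khelix_motif",
            "khelix_start", "perf_motif", "perf_start", "heme_motif",
            "heme_start", "best_reference", "identity_pct", "tier",
            "consistency_flags")
  miss <- setdiff(need, names(object@candidates))
  if (length(miss))
    return(paste("candidates is missing columns:", paste(miss, collapse = ", ")))
  TRUE
})
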