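# Accessor generics. Slots are never reached into directly by user code.

#' @describeIn DegeneratePattern-class pattern identifier
#' @param object,x an object of the documented class
#' @export
setGeneric("patternId", function(object) standardGeneric("patternId"))

#' @describeIn DegeneratePattern-class motif string
#' @export
setGeneric("patternSpec", function(object) standardGeneric("patternSpec"))

#' @describeIn AlignmentResult-class alignment score
#' @export
setGeneric("alignmentScore", function(object) standardGeneric("alignmentScore"))

#' @describeIn GeNormResult-class named vector of gene stability values M
#' @export
setGeneric("mValues", function(object) standardGeneric("mValues"))

#' @describeIn GeNormResult-class named vector of pairwise variations V(n/n+1)
#' @export
setGeneric("vSeries", function(object) standardGeneric("vSeries"))

#' @describeIn GeNormResult-class recommended number of reference genes
#' @export
setGeneric("optimalN", function(object) standardGeneric("optimalN"))

#' @describeIn GeNormResult-class genes ordered most to least stable
#' @export
setGeneric("stabilityOrder", function(object) standardGeneric("stabilityOrder"))

#' @describeIn RelQuantResult-class per (sample, gene) quantity table
#' @export
setGeneric("sampleQuantities", function(object) standardGeneric("sampleQuantities"))

#' @describeIn RelQuantResult-class per (group, gene) statistics table
#' @export
setGeneric("groupStats", function(object) standardGeneric("groupStats"))

#' @describeIn CypomeResult-class per-candidate table
#' @export
setGeneric("candidates", function(object) standardGeneric("candidates"))

#' Percent identity of an alignment
#'
#' `100 * matches / columns`, counted over all alignment columns including
#' gapped ones (EMBOSS Needle convention). With `digits` given, values are
#' rounded half-up to that many decimals (`digits = 0` gives the integer
#' convention used in printed CYP ortholog tables).
#'
#' @param object an [AlignmentResult-class] object.
#' @param digits optional number of decimals (half-up rounding).
#' @return numeric percent identity in `[0, 100]`.
#' @examples
#' a <- globalAlign("MKT", "MKV")
#' percentIdentity(a)            # 66.666...
#' percentIdentity(a, digits = 0)  # 67
#' @export
setGeneric("percentIdentity",
           function(object, digits = NULL) standardGeneric("percentIdentity"))

#' Summarise a CYPome (family tallies and pipeline counts)
#'
#' Tallies classified candidates by CYP family (the leading digits of the
#' CYP name, e.g. family 5313 for CYP5313D1), and reports totals of
#' classified, partial and consistency-flagged entries.
#'
#' @param object a [CypomeResult-class], or an annotation data frame as
#'   returned by [readCypomeTable()].
#' @param ... passed on to methods.
#' @return a list with elements `family_counts` (named integer vector,
#'   decreasing), `n_families`, `n_total`, `n_classified`, `n_partial`,
#'   `n_flagged`.
#' @examples
#' tab <- readCypomeTable()
#' summarizeCypome(tab)$family_counts
#' @export
setGeneric("summarizeCypome", function(object, ...) standardGeneric("summarizeCypome"))

# ---- methods ---------------------------------------------------------------

#' @export
setMethod("patternId", "DegeneratePattern", function(object) object@id)

#' @export
setMethod("patternSpec", "DegeneratePattern", function(object) object@spec)

#' @describeIn DegeneratePattern-class number of motif positions
#' @export
setMethod("length", "DegeneratePattern", function(x) nchar(x@spec))

setMethod("show", "DegeneratePattern", function(object) {
  cat(sprintf("DegeneratePattern '%s': %s (%d positions)\n",
              object@id, object@spec, length(object)))
})

#' @export
setMethod("alignmentScore", "AlignmentResult", function(object) object@score)

#' @export
setMethod("percentIdentity", "AlignmentResult", function(object, digits = NULL) {
  p <- object@identityPct
  if (is.null(digits)) p else roundHalfUp(p, digits)
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf("Global alignment: %d columns, %d identical (%.2f%%), score %.1f\n",
              object@columns, object@matches, object@identityPct, object@score))
  cat(" query: ", object@alignedQuery, "\n", sep = "")
  cat(" ref:   ", object@alignedRef, "\n", sep = "")
})

setMethod("show", "EfficiencyFit", function(object) {
  cat(sprintf("EfficiencyFit '%s': slope %.4f, E = %.4f, R2 = %.4f (%d points)%s\n",
              object@gene, object@slope, object@efficiency, object@r2,
              object@nPoints, if (object@valid) "" else " [INVALID: slope >= 0]"))
})

#' @export
setMethod("mValues", "GeNormResult", function(object) object@mValues)

#' @export
setMethod("vSeries", "GeNormResult", function(object) object@vSeries)

#' @export
setMethod("optimalN", "GeNormResult", function(object) object@optimalN)

#' @export
setMethod("stabilityOrder", "GeNormResult", function(object) object@stabilityOrder)

setMethod("show", "GeNormResult", function(object) {
  cat("geNorm stability analysis\n")
  m <- sort(object@mValues)
  cat(" M values:", paste(sprintf("%s=%.3f", names(m), m), collapse = ", "), "\n")
  if (length(object@vSeries))
    cat(" V series:", paste(sprintf("V(%s)=%.3f", names(object@vSeries),
                                    object@vSeries), collapse = ", "), "\n")
  cat(sprintf(" optimal number of reference genes: %d (cutoff %.2f)\n",
              object@optimalN, object@cutoff))
})

#' @export
setMethod("sampleQuantities", "RelQuantResult", function(object) object@samples)

#' @export
setMethod("groupStats", "RelQuantResult", function(object) object@groups)

setMethod("show", "RelQuantResult", function(object) {
  cat(sprintf("Relative quantification: %d samples x %d genes\n",
              length(unique(object@samples$sample_id)),
              length(unique(object@samples$gene))))
  cat(sprintf(" references: %s; calibrator group: %s\n",
              paste(object@references, collapse = ", "), object@calibratorGroup))
  print(object@groups, digits = 4)
})

#' @export
setMethod("candidates", "CypomeResult", function(object) object@candidates)

setMethod("show", "CypomeResult", function(object) {
  s <- object@summary
  cat("CYPome discovery result\n")
  cat(sprintf(" screened: %d, signatured: %d, partial: %d, classified: %d\n",
              s$screened, s$signatured, s$partial, s$classified))
  if (!is.null(s$family_counts) && length(s$family_counts))
    cat(" families:",
        paste(sprintf("%s(%d)", names(s$family_counts), s$family_counts),
              collapse = " "), "\n")
})
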