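# RT-qPCR relative quantification: replicate concordance, standard-curve
# efficiencies, geNorm reference stability, efficiency-corrected
# multi-reference normalisation with delta-method error propagation,
# calibrated fold changes and Welch tests. The math follows the published
# multi-reference efficiency-corrected model (RQ = E^dCq, NF = geometric
# mean of reference RQs, CNRQ calibrated so one group averages 1).

geomMean <- function(x) exp(mean(log(x)))

.CQ_COLS <- c("sample_id", "group", "gene", "bio_rep", "tech_rep", "cq")

.checkCqTable <- function(table) {
  miss <- setdiff(.CQ_COLS, names(table))
  if (length(miss))
    stop("Cq table is missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(table$cq)) {
    warning(sum(is.na(table$cq)), " missing Cq value(s) dropped")
    table <- table[!is.na(table$cq), , drop = FALSE]
  }
  if (any(!is.finite(table$cq) | table$cq <= 0))
    stop("Cq values must be finite and > 0")
  key <- paste(table$sample_id, table$gene, table$tech_rep, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (sample_id, gene, tech_rep) measurement")
  g <- unique(table[, c("sample_id", "group")])
  if (anyDuplicated(g$sample_id))
    stop("a sample_id maps to more than one group")
  table
}

#' Read a long-format Cq table
#'
#' Tab-delimited with header columns `sample_id`, `group`, `gene`,
#' `bio_rep`, `tech_rep`, `cq`. Missing Cq values are dropped with a
#' warning; non-positive or duplicate measurements are errors.
#'
#' @param path path to the TSV.
#' @return a validated data frame of quantification-cycle records.
#' @export
readCqTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  for (col in c("sample_id", "group", "gene", "bio_rep", "tech_rep"))
    if (col %in% names(tab)) tab[[col]] <- as.character(tab[[col]])
  .checkCqTable(tab)
}

# arithmetic mean of Cq over technical replicates, one row per
# (sample_id, group, gene), with the SE of the mean
.techAverage <- function(table) {
  key <- interaction(table$sample_id, table$gene, drop = TRUE)
  agg <- do.call(rbind, lapply(split(table, key), function(d) {
    n <- nrow(d)
    data.frame(sample_id = d$sample_id[1L], group = d$group[1L],
               gene = d$gene[1L], n_tech = n, cq = mean(d$cq),
               cq_se = if (n > 1L) sd(d$cq) / sqrt(n) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  agg[order(agg$sample_id, agg$gene, method = "radix"), , drop = FALSE]
}

#' Replicate concordance of Cq measurements
#'
#' For every replicate set (technical: the technical replicates of one
#' sample and gene; biological: the technically averaged Cq of the
#' biological replicates of one group and gene) the range `max Cq - min Cq`
#' is computed. Reported are the fraction of sets within each threshold and
#' quantiles of the ranges.
#'
#' @param table a Cq record data frame (see [readCqTable()]).
#' @param level `"technical"` or `"biological"`.
#' @param thresholds Cq deltas to report fractions for.
#' @param probs quantile probabilities of the replicate ranges (the default
#'   reports the median and a 95.8th-style upper percentile).
#' @return list with `level`, `n_sets`, `ranges`, `fraction_within` (named
#'   by threshold) and `quantiles`.
#' @examples
#' cq <- simulateCq(cqSpec(seed = 7))$table
#' replicateConcordance(cq, "technical")$fraction_within
#' @export
replicateConcordance <- function(table, level = c("technical", "biological"),
                                 thresholds = c(0.5, 0.8),
                                 probs = c(0.5, 0.958)) {
  level <- match.arg(level)
  table <- .checkCqTable(table)
  if (level == "technical") {
    values <- table$cq
    key <- interaction(table$sample_id, table$gene, drop = TRUE)
  } else {
    avg <- .techAverage(table)
    values <- avg$cq
    key <- interaction(avg$group, avg$gene, drop = TRUE)
  }
  sets <- split(values, key)
  sets <- sets[lengths(sets) >= 2L]
  if (!length(sets))
    stop("no replicate set with at least 2 members at the ", level, " level")
  ranges <- vapply(sets, function(x) max(x) - min(x), numeric(1L))
  list(level = level, n_sets = length(ranges), ranges = unname(ranges),
       fraction_within = setNames(
         vapply(thresholds, function(t) mean(ranges <= t), numeric(1L)),
         as.character(thresholds)),
       quantiles = quantile(ranges, probs = probs, names = TRUE))
}

#' Amplification efficiency from a serial-dilution standard curve
#'
#' Ordinary least squares of Cq on log10 relative concentration;
#' the per-cycle amplification factor is `E = 10^(-1/slope)`. A perfect
#' doubling assay on 4-fold dilutions shows a Cq step of 2 per dilution
#' (slope -3.3219, E = 2).
#'
#' @param conc relative template concentrations (e.g. `c(1, 1/4, 1/16, 1/64)`).
#' @param cq measured Cq at each concentration.
#' @param gene assay name carried into the result.
#' @return an [EfficiencyFit-class]; a non-negative slope flags the fit
#'   invalid rather than raising.
#' @examples
#' fitEfficiency(c(1, 1/4, 1/16, 1/64), c(20, 22, 24, 26))  # E = 2
#' @export
fitEfficiency <- function(conc, cq, gene = "gene") {
  if (length(conc) != length(cq)) stop("conc and cq differ in length")
  if (length(unique(conc)) < 3L)
    stop("need at least 3 distinct concentrations")
  if (any(conc <= 0)) stop("concentrations must be > 0")
  x <- log10(conc)
  fit <- lm(cq ~ x)
  slope <- unname(coef(fit)[2L])
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits are expected
  valid <- is.finite(slope) && slope < 0
  if (!valid) warning("non-negative slope for '", gene, "': invalid standard curve")
  new("EfficiencyFit", gene = gene, slope = slope,
      efficiency = 10^(-1 / slope), r2 = r2,
      nPoints = length(conc), valid = valid)
}

#' geNorm gene-stability measure M
#'
#' For genes j and k let `V_jk` be the standard deviation over samples of
#' `log2(q_j / q_k)` (n-1 denominator); `M_j` is the mean of `V_jk` over
#' all `k != j`. Lower M means more stable expression; two genes with
#' proportional profiles both attain M = 0.
#'
#' @param quantities numeric matrix of relative quantities, samples in
#'   rows, genes in columns (named); all values must be positive. See
#'   [quantityMatrix()].
#' @return named numeric vector of M values.
#' @export
genormM <- function(quantities) {
  q <- as.matrix(quantities)
  if (ncol(q) < 2L || nrow(q) < 2L)
    stop("need at least 2 genes and 2 samples")
  if (any(q <= 0)) stop("relative quantities must be positive")
  lq <- log2(q)
  genes <- colnames(q)
  m <- vapply(seq_along(genes), function(j) {
    v <- vapply(setdiff(seq_along(genes), j),
                function(k) sd(lq[, j] - lq[, k]), numeric(1L))
    mean(v)
  }, numeric(1L))
  setNames(m, genes)
}

#' geNorm ranking and pairwise variation
#'
#' Iteratively removes the least stable gene (highest M; ties broken by
#' gene name, the alphabetically later gene leaving first) until two genes
#' remain, then computes the pairwise variations
#' `V(n/n+1) = sd over samples of log2(NF_n / NF_{n+1})`, where `NF_n` is
#' the geometric mean of the n most stable genes' quantities. The
#' recommended number of references is the smallest n with
#' `V(n/n+1) < cutoff`, or failing that the n minimising V. At least two
#' references are always recommended.
#'
#' @inheritParams genormM
#' @param cutoff pairwise-variation cutoff (field convention 0.15).
#' @return a [GeNormResult-class].
#' @examples
#' cqs <- simulateCq(cqSpec(seed = 11))
#' rq <- relativeQuantities(cqs$table, cqs$truth$efficiencies)
#' genormRank(quantityMatrix(rq, c("ref1", "ref2", "ref3")))
#' @export
genormRank <- function(quantities, cutoff = 0.15) {
  q <- as.matrix(quantities)
  if (ncol(q) < 3L) stop("geNorm ranking needs at least 3 genes")
  current <- sort(colnames(q), method = "radix")
  exclusion <- character(0)
  last_m <- NULL
  while (length(current) > 2L) {
    m <- genormM(q[, current, drop = FALSE])
    last_m <- m
    worst <- max(m)
    # among ties, the alphabetically later name leaves first
    cand <- sort(names(m)[m == worst], method = "radix")
    out <- cand[length(cand)]
    exclusion <- c(exclusion, out)
    current <- setdiff(current, out)
  }
  # the final pair is unrankable by M alone; order by M in the last
  # 3-gene round, ties by name
  final_m <- last_m[current]
  pair <- current[order(final_m, current, method = "radix")]
  stability <- c(pair, rev(exclusion))
  G <- ncol(q)
  lognf <- function(n) {
    sel <- stability[seq_len(n)]
    rowMeans(log2(q[, sel, drop = FALSE]))
  }
  v <- vapply(2:(G - 1L), function(n) sd(lognf(n) - lognf(n + 1L)), numeric(1L))
  names(v) <- paste0(2:(G - 1L), "/", 3:G)
  below <- which(v < cutoff)
  optimal <- if (length(below)) (2:(G - 1L))[below[1L]]
             else (2:(G - 1L))[which.min(v)]
  new("GeNormResult", mValues = genormM(q), ranking = exclusion,
      stabilityOrder = stability, vSeries = v,
      optimalN = as.integer(optimal), cutoff = cutoff)
}

#' Reshape per-sample relative quantities to a samples-by-genes matrix
#'
#' @param rq a data frame from [relativeQuantities()].
#' @param genes genes to keep (default all).
#' @return numeric matrix, samples in rows, genes in columns.
#' @export
quantityMatrix <- function(rq, genes = NULL) {
  if (is.null(genes)) genes <- sort(unique(rq$gene), method = "radix")
  samples <- sort(unique(rq$sample_id), method = "radix")
  m <- matrix(NA_real_, length(samples), length(genes),
              dimnames = list(samples, genes))
  sel <- rq$gene %in% genes
  m[cbind(match(rq$sample_id[sel], samples), match(rq$gene[sel], genes))] <-
    rq$rq[sel]
  if (anyNA(m)) stop("missing (sample, gene) combinations in rq table")
  m
}

#' Efficiency-corrected relative quantities
#'
#' Technical replicates are arithmetic-mean-averaged on the Cq scale, then
#' `RQ = E^(Cq_ref - Cq_sample)` with `Cq_ref` the gene's mean Cq across
#' samples. Any per-gene constant reference point cancels downstream in
#' CNRQ; the mean keeps intermediate RQs near 1. The relative SE of RQ is
#' `ln(E) * SE(Cq)` (delta method on the log), with `SE(Cq)` the standard
#' error of the technical-replicate mean.
#'
#' @param table a Cq record data frame (see [readCqTable()]).
#' @param efficiencies named per-gene amplification factors in `(1, 2]`.
#'   `NULL` uses E = 2 for every gene with a warning; a gene missing from a
#'   non-NULL vector is an error.
#' @return data frame with one row per (sample, gene): `sample_id`,
#'   `group`, `gene`, `n_tech`, `cq`, `cq_se`, `rq`, `rq_rel_se`.
#' @export
relativeQuantities <- function(table, efficiencies = NULL) {
  table <- .checkCqTable(table)
  genes <- unique(table$gene)
  if (is.null(efficiencies)) {
    warning("no efficiencies supplied; assuming E = 2 for all genes")
    efficiencies <- setNames(rep(2, length(genes)), genes)
  }
  miss <- setdiff(genes, names(efficiencies))
  if (length(miss))
    stop("no amplification efficiency for gene: ", paste(miss, collapse = ", "))
  if (any(efficiencies[genes] <= 1 | efficiencies[genes] > 2))
    stop("amplification factors must lie in (1, 2]")
  avg <- .techAverage(table)
  cq_ref <- tapply(avg$cq, avg$gene, mean)
  E <- unname(efficiencies[avg$gene])
  avg$rq <- as.vector(E^(cq_ref[avg$gene] - avg$cq))
  avg$rq_rel_se <- as.vector(log(E) * avg$cq_se)
  avg
}

#' Delta-method error propagation for CNRQ
#'
#' Relative SE of a product/quotient of independent components is the
#' square root of the sum of squared relative SEs. A geometric mean over
#' `f` reference genes enters with each reference's squared relative SE
#' divided by `f^2`.
#'
#' @param rq_rel_se relative SE of the target RQ.
#' @param ref_rel_ses relative SEs of the reference RQs entering the
#'   normalisation factor (length f).
#' @param calibrator_rel_se relative SE of the calibrator term.
#' @return the relative SE of the calibrated normalised relative quantity.
#' @examples
#' propagateSE(0.03, 0.04)          # 0.05
#' propagateSE(0, c(0.04, 0.04))    # sqrt(2) * 0.02
#' @export
propagateSE <- function(rq_rel_se, ref_rel_ses = numeric(0),
                        calibrator_rel_se = 0) {
  if (any(c(rq_rel_se, ref_rel_ses, calibrator_rel_se) < 0))
    stop("standard errors must be >= 0")
  f <- length(ref_rel_ses)
  nf2 <- if (f) sum((ref_rel_ses / f)^2) else 0
  sqrt(rq_rel_se^2 + nf2 + calibrator_rel_se^2)
}

#' Calibrated normalised relative quantities (CNRQ)
#'
#' Per sample, `NF` is the geometric mean of the reference genes' RQs and
#' `NRQ = RQ / NF`; per gene, CNRQ rescales NRQ so that the geometric mean
#' over the calibrator group's samples is exactly 1. Standard errors are
#' propagated with [propagateSE()]; group-level SEs come from the spread of
#' log CNRQ across biological replicates. Group-versus-calibrator Welch
#' tests on log2 CNRQ are attached where both sides have at least two
#' biological replicates.
#'
#' @param rq per-sample relative quantities from [relativeQuantities()].
#' @param references reference (normaliser) gene names; each must be
#'   measured in every sample.
#' @param calibrator_group the group whose geometric-mean CNRQ defines 1.
#' @param p_adjust_method multiplicity correction for the group tests
#'   (`"none"` by default; e.g. `"BH"`).
#' @return a [RelQuantResult-class].
#' @export
computeCNRQ <- function(rq, references, calibrator_group,
                        p_adjust_method = "none") {
  stopifnot(length(references) >= 1L)
  samples <- unique(rq$sample_id)
  for (ref in references) {
    have <- rq$sample_id[rq$gene == ref]
    miss <- setdiff(samples, have)
    if (length(miss))
      stop("reference gene '", ref, "' missing in sample: ",
           paste(miss, collapse = ", "))
  }
  if (!any(rq$group == calibrator_group))
    stop("calibrator group '", calibrator_group, "' has no samples")

  refdat <- rq[rq$gene %in% references, , drop = FALSE]
  nf <- tapply(refdat$rq, refdat$sample_id, geomMean)
  f <- length(references)
  nf_rel <- tapply(refdat$rq_rel_se, refdat$sample_id,
                   function(s) sqrt(sum((s / f)^2)))
  s <- rq
  s$nf <- as.vector(nf[s$sample_id])
  s$nf_rel_se <- as.vector(nf_rel[s$sample_id])
  s$nrq <- s$rq / s$nf
  s$nrq_rel_se <- sqrt(s$rq_rel_se^2 + s$nf_rel_se^2)

  cal <- s[s$group == calibrator_group, , drop = FALSE]
  cal_factor <- tapply(cal$nrq, cal$gene, geomMean)
  cal_rel <- tapply(cal$nrq_rel_se, cal$gene,
                    function(x) sqrt(sum(x^2)) / length(x))
  miss <- setdiff(unique(s$gene), names(cal_factor))
  if (length(miss))
    stop("gene not measured in the calibrator group: ",
         paste(miss, collapse = ", "))
  s$cnrq <- s$nrq / as.vector(cal_factor[s$gene])
  s$cal_rel_se <- as.vector(cal_rel[s$gene])
  # propagate per-sample: target RQ, NF (reference SEs already aggregated
  # into nf_rel_se with the 1/f^2 weights) and the calibrator term
  s$se_cnrq <- s$cnrq * sqrt(s$rq_rel_se^2 + s$nf_rel_se^2 + s$cal_rel_se^2)

  groups <- unique(s[, c("group", "gene")])
  stats <- do.call(rbind, lapply(seq_len(nrow(groups)), function(i) {
    g <- groups$group[i]; gene <- groups$gene[i]
    d <- s[s$group == g & s$gene == gene, , drop = FALSE]
    n <- nrow(d)
    gm <- geomMean(d$cnrq)
    se <- if (n >= 2L) gm * sd(log(d$cnrq)) / sqrt(n) else d$se_cnrq[1L]
    data.frame(group = g, gene = gene, n_bio = n, cnrq_geomean = gm,
               cnrq_se = se, fold = gm, log10_fold = log10(gm),
               stringsAsFactors = FALSE)
  }))
  stats$p_value <- NA_real_
  for (i in seq_len(nrow(stats))) {
    if (stats$group[i] == calibrator_group) next
    a <- s[s$group == stats$group[i] & s$gene == stats$gene[i], "cnrq"]
    b <- s[s$group == calibrator_group & s$gene == stats$gene[i], "cnrq"]
    if (length(a) >= 2L && length(b) >= 2L)
      stats$p_value[i] <- .welchLog2(a, b)
  }
  if (p_adjust_method != "none") {
    idx <- !is.na(stats$p_value)
    stats$p_adj <- NA_real_
    stats$p_adj[idx] <- p.adjust(stats$p_value[idx], method = p_adjust_method)
  }
  rownames(stats) <- NULL
  new("RelQuantResult", samples = s, groups = stats,
      references = references, calibratorGroup = calibrator_group,
      efficiencies = numeric(0))
}

# two-sided Welch t-test on log2-transformed quantities; degenerate
# zero-variance identical groups count as no evidence (p = 1)
.welchLog2 <- function(a, b) {
  la <- log2(a); lb <- log2(b)
  if (sd(la) == 0 && sd(lb) == 0)
    return(if (isTRUE(all.equal(mean(la), mean(lb)))) 1 else 0)
  t.test(la, lb, var.equal = FALSE)$p.value
}

#' Fold change of one group versus the calibrator
#'
#' `fold = geomean CNRQ(group) / geomean CNRQ(calibrator)`. A gene reported
#' as "k times down-regulated" has fold `1/k`; the sign of `log10_fold`
#' encodes direction.
#'
#' @param result a [RelQuantResult-class].
#' @param gene,group gene and group of interest.
#' @param calibrator_group defaults to the result's calibrator.
#' @return list with `fold`, `log10_fold`, `direction`
#'   (`"up"`, `"down"` or `"none"`).
#' @export
groupFoldChange <- function(result, gene, group,
                            calibrator_group = NULL) {
  stopifnot(is(result, "RelQuantResult"))
  if (is.null(calibrator_group)) calibrator_group <- result@calibratorGroup
  g <- result@groups
  pick <- function(grp) {
    row <- g[g$group == grp & g$gene == gene, , drop = FALSE]
    if (!nrow(row)) stop("no results for gene '", gene, "' in group '", grp, "'")
    row$cnrq_geomean
  }
  fold <- pick(group) / pick(calibrator_group)
  lf <- log10(fold)
  list(fold = fold, log10_fold = lf,
       direction = if (abs(lf) < .Machine$double.eps^0.5) "none"
                   else if (lf > 0) "up" else "down")
}

#' Welch test between two groups on log2 CNRQ
#'
#' Two-sided unequal-variance t-test on the log2 calibrated normalised
#' relative quantities of the biological replicates.
#'
#' @param result a [RelQuantResult-class].
#' @param gene gene of interest.
#' @param groupA,groupB the two groups; each needs at least 2 biological
#'   replicates.
#' @return the p-value.
#' @export
testDifferential <- function(result, gene, groupA, groupB) {
  stopifnot(is(result, "RelQuantResult"))
  s <- result@samples
  a <- s$cnrq[s$group == groupA & s$gene == gene]
  b <- s$cnrq[s$group == groupB & s$gene == gene]
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least 2 biological replicates per group")
  .welchLog2(a, b)
}
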