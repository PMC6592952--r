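# Seeded generators: proteomes with implanted CYP signature triplets at
# controlled identity to synthetic references, and Cq tables with known
# fold changes, efficiencies and reference-gene stability. Everything the
# pipeline consumes can be produced here with full ground truth.

# run expr under set.seed(seed) without disturbing the caller's RNG stream
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

.randomAA <- function(n) paste(sample(AA_STANDARD, n, replace = TRUE),
                               collapse = "")

# one concrete instance of a degenerate pattern (X positions drawn uniform)
.patternInstance <- function(pattern) {
  chars <- strsplit(patternSpec(pattern), "", fixed = TRUE)[[1L]]
  chars[chars == "X"] <- sample(AA_STANDARD, sum(chars == "X"), replace = TRUE)
  paste(chars, collapse = "")
}

.replaceAt <- function(seq, start, insert) {
  paste0(substr(seq, 1L, start - 1L), insert,
         substr(seq, start + nchar(insert), nchar(seq)))
}

# TRUE iff each pattern occurs exactly once, at its implanted start
.scansExactly <- function(seq, patterns, starts) {
  all(vapply(names(starts), function(nm) {
    hits <- scanMotif(patterns[[nm]], seq)
    nrow(hits) == 1L && hits$start == starts[[nm]]
  }, logical(1L)))
}

#' Synthetic proteome specification
#'
#' Parameters of [simulateProteome()]. The defaults describe the package's
#' standard benchmark: 50 background proteins, 8 full-length CYPs and 3
#' partial (250 aa) CYPs derived from 3 synthetic reference CYPs at 60%
#' identity, signature motifs placed at C-terminal offsets mirroring
#' annotated fungal CYPs.
#'
#' @param n_background number of motif-free background proteins.
#' @param background_length length range (residues) of background proteins.
#' @param n_cyps number of full-length implanted CYPs.
#' @param cyp_length length range (or single length) of reference CYPs.
#' @param n_partials number of partial CYPs (C-terminal fragments of
#'   references, `partial_length` residues).
#' @param partial_length fragment length; must be below the pipeline's
#'   partial threshold to exercise the filter.
#' @param identity target ungapped percent identity of each derived CYP to
#'   its reference, motif positions protected.
#' @param n_refs number of synthetic reference CYPs.
#' @param motif_starts optional named vector `c(khelix=, perf=, heme=)` of
#'   1-based implant starts (requires a single `cyp_length`); by default
#'   starts are placed at fixed C-terminal offsets (K-helix at L-141, PERF
#'   at L-85, haem at L-66).
#' @param patterns signature patterns, see [signaturePatterns()].
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return a validated spec list.
#' @export
proteomeSpec <- function(n_background = 50L, background_length = c(150L, 600L),
                         n_cyps = 8L, cyp_length = c(450L, 550L),
                         n_partials = 3L, partial_length = 250L,
                         identity = 60, n_refs = 3L, motif_starts = NULL,
                         patterns = signaturePatterns(), seed = 1L) {
  stopifnot(n_background >= 0L, n_cyps >= 0L, n_partials >= 0L, n_refs >= 1L,
            identity > 0, identity <= 100, seed == as.integer(seed))
  if (length(cyp_length) == 1L) cyp_length <- rep(cyp_length, 2L)
  if (length(background_length) == 1L)
    background_length <- rep(background_length, 2L)
  plen <- vapply(patterns, length, integer(1L))
  minlen <- cyp_length[1L]
  if (!is.null(motif_starts)) {
    stopifnot(all(c("khelix", "perf", "heme") %in% names(motif_starts)))
    if (cyp_length[1L] != cyp_length[2L])
      stop("explicit motif_starts require a single cyp_length")
    k <- motif_starts[["khelix"]]; p <- motif_starts[["perf"]]
    h <- motif_starts[["heme"]]
    if (!(k >= 1 && k + plen[["khelix"]] - 1L < p &&
          p + plen[["perf"]] - 1L < h &&
          h + plen[["heme"]] - 1L <= minlen))
      stop("motif starts must be ordered khelix < perf < heme, non-overlapping, and fit the length")
  } else if (minlen < 142L + plen[["khelix"]]) {
    stop("cyp_length too short for the default motif layout")
  }
  protected_frac <- sum(plen) / minlen
  if (identity < 100 * protected_frac)
    stop("target identity infeasible: protected motif positions alone exceed it")
  list(n_background = as.integer(n_background),
       background_length = as.integer(background_length),
       n_cyps = as.integer(n_cyps), cyp_length = as.integer(cyp_length),
       n_partials = as.integer(n_partials),
       partial_length = as.integer(partial_length),
       identity = identity, n_refs = as.integer(n_refs),
       motif_starts = motif_starts, patterns = patterns,
       seed = as.integer(seed))
}

.defaultStarts <- function(L) c(khelix = L - 141L, perf = L - 85L, heme = L - 66L)

# random sequence carrying exactly one instance of each pattern at the
# given starts (rejection-sampled so no decoy occurrences exist)
.cleanImplanted <- function(L, patterns, starts, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    seq <- .randomAA(L)
    for (nm in names(starts))
      seq <- .replaceAt(seq, starts[[nm]], .patternInstance(patterns[[nm]]))
    if (.scansExactly(seq, patterns, starts)) return(seq)
  }
  stop("could not place signature motifs without decoy occurrences")
}

# background sequence with no full ordered signature triplet
.cleanBackground <- function(L, patterns, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    seq <- .randomAA(L)
    if (is.null(findSignature(seq, patterns))) return(seq)
  }
  stop("could not draw a signature-free background sequence")
}

#' Mutate a sequence to a target ungapped identity
#'
#' Substitutes exactly `round(L * (1 - target/100))` positions, drawn
#' outside the protected set, each replaced by a different residue, so the
#' realised ungapped identity matches the target count exactly.
#'
#' @param seq amino-acid string.
#' @param target_identity_pct target percent identity in `(0, 100]`.
#' @param protected 1-based positions that must not be touched (e.g.
#'   implanted motifs).
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return the mutated sequence string.
#' @examples
#' mutateToIdentity("MKTAYIAKQR", 100)       # unchanged
#' mutateToIdentity(strrep("A", 100), 60, seed = 1)  # 40 substitutions
#' @export
mutateToIdentity <- function(seq, target_identity_pct, protected = integer(0),
                             seed = NULL) {
  .withSeed(seed, {
    L <- nchar(seq)
    n_sub <- L - as.integer(roundHalfUp(L * target_identity_pct / 100))
    free <- setdiff(seq_len(L), protected)
    if (n_sub > length(free))
      stop("target identity infeasible: would require mutating protected positions")
    if (n_sub == 0L) {
      seq
    } else {
      pos <- if (length(free) == 1L) free else sample(free, n_sub)
      chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
      for (i in pos) {
        alt <- setdiff(AA_STANDARD, chars[i])
        chars[i] <- alt[sample.int(length(alt), 1L)]
      }
      paste(chars, collapse = "")
    }
  })
}

.motifPositions <- function(starts, patterns) {
  unlist(lapply(names(starts), function(nm)
    seq(starts[[nm]], length.out = length(patterns[[nm]]))))
}

# mutate a reference, rejecting draws whose mutations create decoy motif
# occurrences or destroy the exact-scan property
.mutateClean <- function(ref, identity, patterns, starts, max_tries = 200L) {
  protected <- .motifPositions(starts, patterns)
  for (i in seq_len(max_tries)) {
    mut <- mutateToIdentity(ref, identity, protected)
    if (.scansExactly(mut, patterns, starts)) return(mut)
  }
  stop("could not mutate to target identity without decoy motif occurrences")
}

#' Simulate a proteome with implanted CYP signatures
#'
#' Generates synthetic reference CYPs (random background with one concrete
#' instance of each signature motif), derives full-length and partial CYPs
#' from them at a controlled ungapped identity (motif positions protected),
#' and adds background proteins rejection-sampled to contain no full
#' ordered signature triplet. Identical seeds give identical output.
#'
#' @param spec a [proteomeSpec()] list.
#' @return list with elements `proteome` (named `AAStringSet`: CYPs,
#'   partials, then background), `refs` (named `AAStringSet` of the
#'   synthetic references) and `truth` (data frame: `id`, `role` one of
#'   `cyp`/`cyp_partial`/`background`, `ref`, `identity`, implant starts,
#'   `length`).
#' @examples
#' sim <- simulateProteome(proteomeSpec(n_background = 5, n_cyps = 2,
#'                                      n_partials = 1, seed = 42))
#' sim$truth
#' @export
simulateProteome <- function(spec) {
  .withSeed(spec$seed, {
    patterns <- spec$patterns
    # references
    ref_len <- if (spec$cyp_length[1L] == spec$cyp_length[2L])
      rep(spec$cyp_length[1L], spec$n_refs)
    else sample(spec$cyp_length[1L]:spec$cyp_length[2L], spec$n_refs,
                replace = TRUE)
    ref_starts <- lapply(ref_len, function(L)
      if (!is.null(spec$motif_starts)) spec$motif_starts else .defaultStarts(L))
    refs <- vapply(seq_len(spec$n_refs), function(i)
      .cleanImplanted(ref_len[i], patterns, ref_starts[[i]]), character(1L))
    ref_names <- sprintf("CYP%dA1", 9000L + seq_len(spec$n_refs))

    ids <- character(0); seqs <- character(0)
    truth <- data.frame(id = character(), role = character(),
                        ref = character(), identity = numeric(),
                        khelix_start = integer(), perf_start = integer(),
                        heme_start = integer(), length = integer(),
                        stringsAsFactors = FALSE)
    addTruth <- function(id, role, ref, identity, starts, L) {
      truth <<- rbind(truth, data.frame(
        id = id, role = role, ref = ref, identity = identity,
        khelix_start = if (is.null(starts)) NA_integer_ else starts[["khelix"]],
        perf_start = if (is.null(starts)) NA_integer_ else starts[["perf"]],
        heme_start = if (is.null(starts)) NA_integer_ else starts[["heme"]],
        length = L, stringsAsFactors = FALSE))
    }

    for (i in seq_len(spec$n_cyps)) {
      r <- ((i - 1L) %% spec$n_refs) + 1L
      seq <- if (spec$identity == 100) refs[r]
             else .mutateClean(refs[r], spec$identity, patterns, ref_starts[[r]])
      id <- sprintf("cyp%02d", i)
      ids <- c(ids, id); seqs <- c(seqs, seq)
      addTruth(id, "cyp", ref_names[r], spec$identity, ref_starts[[r]],
               nchar(seq))
    }
    for (i in seq_len(spec$n_partials)) {
      r <- ((i - 1L) %% spec$n_refs) + 1L
      L <- ref_len[r]; w <- spec$partial_length
      if (w >= L) stop("partial_length must be below the reference length")
      offset <- L - w
      starts <- ref_starts[[r]]
      if (any(unlist(starts) <= offset))
        stop("partial_length too short to contain the signature motifs")
      frag <- substr(refs[r], offset + 1L, L)
      shifted <- vapply(starts, function(s) as.integer(s - offset), integer(1L))
      seq <- .mutateClean(frag, spec$identity, patterns, as.list(shifted))
      id <- sprintf("partial%02d", i)
      ids <- c(ids, id); seqs <- c(seqs, seq)
      addTruth(id, "cyp_partial", ref_names[r], spec$identity,
               as.list(shifted), nchar(seq))
    }
    for (i in seq_len(spec$n_background)) {
      L <- sample(spec$background_length[1L]:spec$background_length[2L], 1L)
      seq <- .cleanBackground(L, patterns)
      id <- sprintf("bg%03d", i)
      ids <- c(ids, id); seqs <- c(seqs, seq)
      addTruth(id, "background", NA_character_, NA_real_, NULL, L)
    }
    proteome <- Biostrings::AAStringSet(setNames(seqs, ids))
    ref_set <- Biostrings::AAStringSet(setNames(refs, ref_names))
    list(proteome = proteome, refs = ref_set, truth = truth)
  })
}

#' Synthetic Cq-table specification
#'
#' Parameters of [simulateCq()]. The defaults emulate a four-condition
#' expression study (two media, two timepoints) with one induced target
#' gene (20-fold up in group `B72`), two stable reference genes and one
#' unstable reference, duplicate technical and triplicate biological
#' replicates.
#'
#' @param target_genes target gene names.
#' @param stable_refs,unstable_refs reference gene names; stable references
#'   have true fold 1 in every group, unstable ones receive an extra
#'   per-sample log-normal wobble of `unstable_sd` Cq units.
#' @param groups experimental groups.
#' @param calibrator_group group with true fold 1 that downstream analysis
#'   calibrates against.
#' @param folds named list: per target gene, a named vector of true fold
#'   changes per group (missing groups default to 1).
#' @param efficiency per-gene amplification factors in (1, 2]; a single
#'   value recycles.
#' @param baseline_cq per-gene baseline Cq in the calibrator condition; a
#'   single value recycles.
#' @param bio_sd biological noise SD (Cq units), one shared draw per
#'   sample; cancels through reference normalisation like a loading effect.
#' @param tech_sd technical replicate noise SD (Cq units).
#' @param unstable_sd extra per-(sample, gene) SD of unstable references.
#' @param n_bio,n_tech biological / technical replicates per group.
#' @param dilutions relative concentrations of the standard curve.
#' @param dilution_sd Cq noise on the standard curve (0 = noise-free).
#' @param seed integer seed.
#' @return a validated spec list.
#' @export
cqSpec <- function(target_genes = "tgt1",
                   stable_refs = c("ref1", "ref2"),
                   unstable_refs = "ref3",
                   groups = c("A72", "B72", "A96", "B96"),
                   calibrator_group = "A72",
                   folds = list(tgt1 = c(B72 = 20)),
                   efficiency = 2, baseline_cq = 22,
                   bio_sd = 0.3, tech_sd = 0.2, unstable_sd = 0.8,
                   n_bio = 3L, n_tech = 2L,
                   dilutions = c(1, 1/4, 1/16, 1/64), dilution_sd = 0,
                   seed = 1L) {
  genes <- c(target_genes, stable_refs, unstable_refs)
  if (anyDuplicated(genes)) stop("duplicate gene names across roles")
  if (!calibrator_group %in% groups) stop("calibrator group not in groups")
  stopifnot(bio_sd >= 0, tech_sd >= 0, unstable_sd >= 0, dilution_sd >= 0,
            n_bio >= 2L, n_tech >= 1L)
  eff <- if (length(efficiency) == 1L && is.null(names(efficiency)))
    setNames(rep(efficiency, length(genes)), genes) else efficiency
  if (!all(genes %in% names(eff))) stop("efficiency missing for some gene")
  if (any(eff[genes] <= 1 | eff[genes] > 2))
    stop("amplification factors must lie in (1, 2]")
  base <- if (length(baseline_cq) == 1L && is.null(names(baseline_cq)))
    setNames(rep(baseline_cq, length(genes)), genes) else baseline_cq
  if (!all(genes %in% names(base))) stop("baseline_cq missing for some gene")
  fold_mat <- matrix(1, length(genes), length(groups),
                     dimnames = list(genes, groups))
  for (g in names(folds)) {
    if (!g %in% target_genes) stop("folds given for non-target gene: ", g)
    f <- folds[[g]]
    if (any(f <= 0)) stop("fold changes must be > 0")
    bad <- setdiff(names(f), groups)
    if (length(bad)) stop("fold group not in groups: ", paste(bad, collapse = ", "))
    fold_mat[g, names(f)] <- f
  }
  if (any(fold_mat[, calibrator_group] != 1))
    stop("the calibrator group must have true fold 1")
  list(target_genes = target_genes, stable_refs = stable_refs,
       unstable_refs = unstable_refs, groups = groups,
       calibrator_group = calibrator_group, folds = fold_mat,
       efficiency = eff, baseline_cq = base, bio_sd = bio_sd,
       tech_sd = tech_sd, unstable_sd = unstable_sd,
       n_bio = as.integer(n_bio), n_tech = as.integer(n_tech),
       dilutions = dilutions, dilution_sd = dilution_sd,
       seed = as.integer(seed))
}

#' Simulate a long-format Cq table with known ground truth
#'
#' Per sample and gene,
#' `Cq = baseline - log_E(fold) + bio_effect + unstable_effect + tech noise`
#' with one biological effect drawn per sample (shared across genes), an
#' extra per-(sample, gene) term for unstable references, and independent
#' technical noise per replicate. Standard-curve dilution series are
#' generated per gene (noise-free by default). Identical seeds give
#' identical tables.
#'
#' @param spec a [cqSpec()] list.
#' @return list with `table` (long-format Cq records), `dilutions` (per
#'   gene: `gene`, `conc`, `cq`) and `truth` (true fold matrix,
#'   efficiencies, gene roles, calibrator group).
#' @examples
#' sim <- simulateCq(cqSpec(bio_sd = 0, tech_sd = 0, unstable_sd = 0))
#' head(sim$table)
#' @export
simulateCq <- function(spec) {
  .withSeed(spec$seed, {
    genes <- rownames(spec$folds)
    rows <- vector("list", 0L)
    for (g in spec$groups) {
      for (b in seq_len(spec$n_bio)) {
        sample_id <- sprintf("%s_b%d", g, b)
        bio_eff <- rnorm(1L, 0, spec$bio_sd)
        for (gene in genes) {
          E <- spec$efficiency[[gene]]
          mu <- spec$baseline_cq[[gene]] -
            log(spec$folds[gene, g]) / log(E) + bio_eff
          if (gene %in% spec$unstable_refs)
            mu <- mu + rnorm(1L, 0, spec$unstable_sd)
          for (r in seq_len(spec$n_tech)) {
            cq <- mu + rnorm(1L, 0, spec$tech_sd)
            rows[[length(rows) + 1L]] <- data.frame(
              sample_id = sample_id, group = g, gene = gene,
              bio_rep = as.character(b), tech_rep = as.character(r),
              cq = cq, stringsAsFactors = FALSE)
          }
        }
      }
    }
    table <- do.call(rbind, rows)
    dil <- do.call(rbind, lapply(genes, function(gene) {
      E <- spec$efficiency[[gene]]
      cq <- spec$baseline_cq[[gene]] - log(spec$dilutions) / log(E)
      if (spec$dilution_sd > 0)
        cq <- cq + rnorm(length(cq), 0, spec$dilution_sd)
      data.frame(gene = gene, conc = spec$dilutions, cq = cq,
                 stringsAsFactors = FALSE)
    }))
    roles <- setNames(c(rep("target", length(spec$target_genes)),
                        rep("reference_stable", length(spec$stable_refs)),
                        rep("reference_unstable", length(spec$unstable_refs))),
                      c(spec$target_genes, spec$stable_refs,
                        spec$unstable_refs))
    list(table = table, dilutions = dil,
         truth = list(folds = spec$folds,
                      efficiencies = spec$efficiency[genes],
                      roles = roles,
                      calibrator_group = spec$calibrator_group))
  })
}
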