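## Identification of probable auto-inducing peptide (AIP) genes among
## neighborhood short CDSs: SHP feature flags, mature-form prediction by
## the acidic-residue cleavage rule, similarity transfer from published
## AIP seeds, and gene-orientation classification relative to the
## regulator.

.AIP_CLASSES <- c("SHP", "ComS", "PapR", "LCP", "MutS", "unknown")

#' SHP likeness features of a peptide
#'
#' The five diagnostic features of SHP precursors: length 20-26 aa, an
#' N-terminal Lys (within the first three residues), a C-terminal
#' stretch of at least five hydrophobic residues (Kyte-Doolittle value
#' > 0, Gly permitted), a C-terminal Gly, and a central acidic residue
#' (Asp/Glu in the C-terminal half, not the last residue). The score is
#' the number of features present (0-5).
#'
#' @param peptide amino-acid string (length >= 7).
#' @return list with `flags` (named logical vector of the five
#'   features) and `score`.
#' @export
scoreShpLikeness <- function(peptide) {
  stopifnot(nchar(peptide) >= 7L)
  res <- strsplit(peptide, "")[[1]]
  n <- length(res)
  kd <- kyteDoolittle[res]
  kd[is.na(kd)] <- -5           # non-standard residues count hydrophilic
  hydro <- kd > 0 | res == "G"
  runLen <- 0L
  for (i in n:1) { if (hydro[i]) runLen <- runLen + 1L else break }
  cHalf <- seq.int(floor(n / 2) + 1L, n)
  flags <- c(
    length_in_range = n >= 20L && n <= 26L,
    n_term_lys = any(res[seq_len(min(3L, n))] == "K"),
    c_term_hydrophobic_stretch = runLen >= 5L,
    c_term_gly = res[n] == "G",
    central_acidic = any(res[setdiff(cHalf, n)] %in% c("D", "E"))
  )
  list(flags = flags, score = sum(flags))
}

#' Predict the mature SHP form of a precursor
#'
#' SHP precursors are cleaved in front of a glutamate or aspartate
#' residue; the rule returns the suffix starting at the LAST acidic
#' residue (D/E) found in the C-terminal half of the precursor
#' (excluding the final residue), or `NA` when no such residue exists
#' (flagging the precursor for a manual override). The returned mature
#' form is always a suffix of the precursor and starts with D or E.
#'
#' @param precursor amino-acid string (length >= 8).
#' @return mature-form string or `NA_character_`.
#' @export
predictMatureForm <- function(precursor) {
  stopifnot(nchar(precursor) >= 8L)
  res <- strsplit(precursor, "")[[1]]
  n <- length(res)
  cand <- seq.int(floor(n / 2) + 1L, n - 1L)
  acidic <- cand[res[cand] %in% c("D", "E")]
  if (!length(acidic)) return(NA_character_)
  substr(precursor, max(acidic), n)
}

#' Read / write an AIP seed set
#'
#' FASTA with the class encoded in the description line:
#' `>seed_id class` with class one of SHP, ComS, PapR, LCP, MutS.
#'
#' @param path FASTA file.
#' @return data.frame with `seed_id`, `class`, `sequence`.
#' @export
readAipSeeds <- function(path) {
  recs <- readFasta(path, type = "AA")
  parts <- strsplit(names(recs), "\\s+")
  out <- data.frame(
    seed_id = vapply(parts, `[`, character(1), 1),
    class = vapply(parts, function(p) if (length(p) >= 2) p[2]
                   else "unknown", character(1)),
    sequence = unname(recs), stringsAsFactors = FALSE)
  bad <- !(out$class %in% .AIP_CLASSES)
  if (any(bad))
    stop("unknown AIP class: ", paste(unique(out$class[bad]), collapse = ", "),
         call. = FALSE)
  out
}

#' @rdname readAipSeeds
#' @param seeds data.frame as returned by `readAipSeeds`.
#' @export
writeAipSeeds <- function(seeds, path) {
  writeFasta(stats::setNames(seeds$sequence,
                             paste(seeds$seed_id, seeds$class)), path, "AA")
}

#' Match a peptide against known AIP seeds
#'
#' Best global-alignment identity (BLOSUM62, gap 11/1) against every
#' seed; the seed's class is transferred when the identity reaches
#' `minIdentity` percent.
#'
#' @param peptide amino-acid string.
#' @param seeds data.frame from [readAipSeeds()].
#' @param minIdentity percent identity threshold (default 40).
#' @return list with `seed_id`, `class`, `identity_pct`, or `NULL` when
#'   no seed reaches the threshold.
#' @export
matchKnownAips <- function(peptide, seeds, minIdentity = 40) {
  stopifnot(nrow(seeds) >= 1L)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(seeds$sequence), Biostrings::AAString(peptide),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  idn <- Biostrings::pid(aln, type = "PID1")
  i <- which.max(idn)
  if (idn[i] >= minIdentity)
    list(seed_id = seeds$seed_id[i], class = seeds$class[i],
         identity_pct = idn[i])
  else NULL
}

#' Orientation of an AIP gene relative to its regulator
#'
#' Geometry on the forward axis: `divergent` when the genes are on
#' opposite strands pointing away from each other (5' ends adjacent),
#' `convergent` when pointing toward each other (3' ends adjacent),
#' `co_upstream` / `co_downstream` when co-oriented with the AIP gene
#' 5' respectively 3' of the regulator. Invariant under
#' reverse-complementing the whole contig.
#'
#' @param aipCds one-row data.frame (or list) with `start`, `end`,
#'   `strand` of the AIP gene.
#' @param regulatorFeature same for the regulator gene.
#' @return one of `"divergent"`, `"convergent"`, `"co_upstream"`,
#'   `"co_downstream"`.
#' @export
assignOrientation <- function(aipCds, regulatorFeature) {
  aMid <- (aipCds$start + aipCds$end) / 2
  rMid <- (regulatorFeature$start + regulatorFeature$end) / 2
  aipLeft <- aMid < rMid
  sameStrand <- aipCds$strand == regulatorFeature$strand
  if (sameStrand) {
    upstream <- if (regulatorFeature$strand == "+") aipLeft else !aipLeft
    return(if (upstream) "co_upstream" else "co_downstream")
  }
  ## opposite strands: divergent iff each gene points away from the other
  regPointsAway <- (regulatorFeature$strand == "+") == aipLeft
  if (regPointsAway) "divergent" else "convergent"
}

#' Annotate the AIP candidates of one regulator
#'
#' For every short CDS in the regulator's neighborhood: SHP feature
#' flags, class (transferred from the best seed match when one reaches
#' the identity threshold, otherwise SHP when the feature score is at
#' least `shpScoreMin`, otherwise unknown), predicted mature form and
#' gene orientation. Candidates are returned sorted by decreasing
#' feature score.
#'
#' @param regulatorFeature one-row data.frame with `start`, `end`,
#'   `strand` (and optionally `feature_id`) of the regulator CDS.
#' @param neighborhoodCds data.frame from [neighborhoodScan()].
#' @param seeds optional data.frame from [readAipSeeds()].
#' @param minSeedIdentity percent identity for class transfer (40).
#' @param shpScoreMin feature-score threshold for a de novo SHP call
#'   (default 3 of 5).
#' @param matureOverrides optional named character vector mapping a
#'   candidate's `aa_sequence` to a curated mature form, for precursors
#'   whose cleavage does not follow the acidic-residue rule.
#' @return data.frame with columns `aa_sequence`, `start`, `end`,
#'   `strand`, `aip_class`, `score`, `flags` (semicolon list),
#'   `mature_form`, `orientation`, `best_seed`, `seed_identity_pct`.
#' @export
annotateRegulator <- function(regulatorFeature, neighborhoodCds,
                              seeds = NULL, minSeedIdentity = 40,
                              shpScoreMin = 3L, matureOverrides = NULL) {
  if (is.null(neighborhoodCds) || nrow(neighborhoodCds) == 0L)
    return(data.frame(aa_sequence = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      aip_class = character(0), score = integer(0),
                      flags = character(0), mature_form = character(0),
                      orientation = character(0), best_seed = character(0),
                      seed_identity_pct = numeric(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(neighborhoodCds)), function(i) {
    cds <- neighborhoodCds[i, ]
    pep <- cds$aa_sequence
    sl <- scoreShpLikeness(pep)
    seedHit <- if (!is.null(seeds) && nrow(seeds))
      matchKnownAips(pep, seeds, minSeedIdentity) else NULL
    cls <- if (!is.null(seedHit)) seedHit$class
           else if (sl$score >= shpScoreMin) "SHP" else "unknown"
    mature <- if (!is.null(matureOverrides) && pep %in% names(matureOverrides))
      unname(matureOverrides[pep])
      else if (nchar(pep) >= 8L) predictMatureForm(pep) else NA_character_
    data.frame(aa_sequence = pep, start = cds$start, end = cds$end,
               strand = cds$strand, aip_class = cls,
               score = sl$score,
               flags = paste(names(sl$flags)[sl$flags], collapse = ";"),
               mature_form = mature,
               orientation = assignOrientation(cds, regulatorFeature),
               best_seed = if (is.null(seedHit)) NA_character_
                           else seedHit$seed_id,
               seed_identity_pct = if (is.null(seedHit)) NA_real_
                                   else seedHit$identity_pct,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
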