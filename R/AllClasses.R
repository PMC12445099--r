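#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<-
#' @importFrom Biostrings DNAStringSet AAStringSet
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
NULL

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

#' A bacterial genome with CDS annotation
#'
#' Container for one annotated genome: contigs as a
#' [Biostrings::DNAStringSet] and CDS features as a
#' [GenomicRanges::GRanges] on the forward axis (0-based half-open
#' coordinates are used at the file interface; internally the GRanges is
#' 1-based as usual for Bioconductor, see [readGenBank()]).
#' Feature metadata columns: `feature_id`, `protein`, `product`.
#'
#' @slot genomeId single genome identifier, unique within a corpus.
#' @slot speciesLabel free-text species label.
#' @slot contigs `DNAStringSet` over A/C/G/T/N.
#' @slot features `GRanges` of CDS spans with strand and metadata.
#'
#' @aliases GenomeRecord-class
#' @exportClass GenomeRecord
setClass("GenomeRecord",
  representation(
    genomeId = "character",
    speciesLabel = "character",
    contigs = "DNAStringSet",
    features = "GRanges"
  )
)

setValidity("GenomeRecord", function(object) {
  msg <- character(0)
  if (length(object@genomeId) != 1L || !nzchar(object@genomeId))
    msg <- c(msg, "genomeId must be a single non-empty string")
  if (length(object@contigs) < 1L)
    msg <- c(msg, "a GenomeRecord needs at least one contig")
  if (is.null(names(object@contigs)) || anyDuplicated(names(object@contigs)))
    msg <- c(msg, "contigs must carry unique names")
  if (length(object@features)) {
    cl <- as.character(GenomicRanges::seqnames(object@features))
    bad <- !(cl %in% names(object@contigs))
    if (any(bad))
      msg <- c(msg, "features reference unknown contigs")
    else {
      lens <- Biostrings::width(object@contigs)[match(cl, names(object@contigs))]
      if (any(GenomicRanges::end(object@features) > lens) ||
          any(GenomicRanges::start(object@features) < 1L))
        msg <- c(msg, "features fall outside their contig")
    }
    needed <- c("feature_id", "protein", "product")
    if (!all(needed %in% colnames(S4Vectors::mcols(object@features))))
      msg <- c(msg, "features need mcols feature_id, protein, product")
  }
  if (length(msg)) msg else TRUE
})

#' Profile hidden Markov model of a protein family
#'
#' A plan7-like profile HMM estimated from a bait multiple alignment:
#' match states are alignment columns with gap fraction <= 0.5, with
#' Laplace-smoothed transitions estimated from the observed gap structure
#' and match emissions blended with background frequencies by a
#' pseudocount weight.
#'
#' @slot matchEmissions M x 20 matrix of match-state emission
#'   probabilities, columns ordered as the 20 standard residues.
#' @slot insertEmissions length-20 background emission row shared by all
#'   insert states.
#' @slot transitions list of length-M (or M-1) numeric vectors with
#'   components `MM`, `MI`, `MD`, `IM`, `II`, `DM`, `DD`.
#' @slot matchColumnMap integer vector: source alignment column of each
#'   match state.
#' @slot background length-20 background residue distribution.
#' @slot calibration a [CalibrationParams] or `NULL` before calibration.
#'
#' @aliases ProfileHMM-class
#' @exportClass ProfileHMM
setClass("ProfileHMM",
  representation(
    matchEmissions = "matrix",
    insertEmissions = "numeric",
    transitions = "list",
    matchColumnMap = "integer",
    background = "numeric",
    calibration = "ANY"
  )
)

setValidity("ProfileHMM", function(object) {
  msg <- character(0)
  M <- nrow(object@matchEmissions)
  if (M < 1L) msg <- c(msg, "profile needs at least one match state")
  if (ncol(object@matchEmissions) != 20L)
    msg <- c(msg, "matchEmissions must have 20 columns")
  if (any(abs(rowSums(object@matchEmissions) - 1) > 1e-9))
    msg <- c(msg, "match emission rows must sum to 1")
  if (abs(sum(object@insertEmissions) - 1) > 1e-9)
    msg <- c(msg, "insert emissions must sum to 1")
  if (abs(sum(object@background) - 1) > 1e-9)
    msg <- c(msg, "background must sum to 1")
  if (length(object@matchColumnMap) != M)
    msg <- c(msg, "matchColumnMap length must equal number of match states")
  if (length(msg)) msg else TRUE
})

#' E-value calibration of a profile HMM
#'
#' Gumbel (type-I extreme value) parameters fitted by maximum likelihood
#' to Viterbi bit scores of random background-composition sequences.
#' E-value of a bit score s against a database of D sequences is
#' `D * exp(-lambda * (s - mu))`.
#'
#' @slot mu Gumbel location (bits).
#' @slot lambda inverse Gumbel scale (1/bits), > 0.
#' @slot nRandom number of random sequences used for the fit (>= 100).
#' @slot randomSeed RNG seed recorded for reproducibility.
#' @slot dbSize default database size D for E-values.
#'
#' @aliases CalibrationParams-class
#' @exportClass CalibrationParams
setClass("CalibrationParams",
  representation(
    mu = "numeric", lambda = "numeric",
    nRandom = "integer", randomSeed = "integer", dbSize = "integer"
  )
)

setValidity("CalibrationParams", function(object) {
  msg <- character(0)
  if (object@lambda <= 0) msg <- c(msg, "lambda must be > 0")
  if (object@nRandom < 100L) msg <- c(msg, "nRandom must be >= 100")
  if (length(msg)) msg else TRUE
})

#' Sequence-composition model for short-CDS detection
#'
#' Two-class model behind the short-ORF confidence score: a coding model
#' (61-codon usage table, or 3 x 4 nucleotide-by-codon-position
#' distributions) against an order-k Markov background chain over
#' nucleotides, combined with a coding prior into a posterior
#' probability of coding.
#'
#' @slot mode `"codon"` or `"positional"`.
#' @slot codonUsage named numeric over the 61 sense codons (sums to 1).
#' @slot positionalEmissions 3 x 4 matrix, rows = codon positions,
#'   columns = A,C,G,T.
#' @slot backgroundOrder Markov order k of the background chain.
#' @slot backgroundTransitions matrix 4^k x 4 of transition
#'   probabilities; rownames are the k-mers.
#' @slot backgroundInit length-4^k initial k-mer distribution.
#' @slot priorCoding prior probability that an enumerated ORF is coding.
#' @slot trainingGenomeIds genomes the model was estimated from.
#'
#' @aliases CdsCompositionModel-class
#' @exportClass CdsCompositionModel
setClass("CdsCompositionModel",
  representation(
    mode = "character",
    codonUsage = "numeric",
    positionalEmissions = "matrix",
    backgroundOrder = "integer",
    backgroundTransitions = "matrix",
    backgroundInit = "numeric",
    priorCoding = "numeric",
    trainingGenomeIds = "character"
  )
)

setValidity("CdsCompositionModel", function(object) {
  msg <- character(0)
  if (!object@mode %in% c("codon", "positional"))
    msg <- c(msg, "mode must be 'codon' or 'positional'")
  if (abs(sum(object@codonUsage) - 1) > 1e-9)
    msg <- c(msg, "codonUsage must sum to 1")
  if (any(abs(rowSums(object@positionalEmissions) - 1) > 1e-9))
    msg <- c(msg, "positional emission rows must sum to 1")
  if (any(abs(rowSums(object@backgroundTransitions) - 1) > 1e-9))
    msg <- c(msg, "background transition rows must sum to 1")
  if (object@priorCoding <= 0 || object@priorCoding >= 1)
    msg <- c(msg, "priorCoding must lie in (0,1)")
  if (length(object@trainingGenomeIds) < 1L)
    msg <- c(msg, "model must record at least one training genome")
  if (length(msg)) msg else TRUE
})

#' Strains x clusters presence/absence matrix
#'
#' Binary repertoire matrix: one row per strain, one column per
#' regulator cluster, cell 1 iff the strain carries at least one hit of
#' that cluster. Species labels run parallel to the rows.
#'
#' @slot presence binary matrix with strain rownames and cluster colnames.
#' @slot speciesLabels character vector parallel to rows.
#'
#' @aliases RepertoireMatrix-class
#' @exportClass RepertoireMatrix
setClass("RepertoireMatrix",
  representation(presence = "matrix", speciesLabels = "character")
)

setValidity("RepertoireMatrix", function(object) {
  msg <- character(0)
  if (!all(object@presence %in% c(0, 1)))
    msg <- c(msg, "cells must be 0/1")
  if (length(object@speciesLabels) != nrow(object@presence))
    msg <- c(msg, "speciesLabels must parallel the rows")
  if (is.null(rownames(object@presence)) || is.null(colnames(object@presence)))
    msg <- c(msg, "presence needs strain rownames and cluster colnames")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GenomeRecord", function(object) {
  cat("GenomeRecord", object@genomeId,
      sprintf("(%s)\n", object@speciesLabel))
  cat(" ", length(object@contigs), "contig(s),",
      sum(Biostrings::width(object@contigs)), "bp,",
      length(object@features), "CDS feature(s)\n")
})

setMethod("show", "ProfileHMM", function(object) {
  cat("ProfileHMM with", nrow(object@matchEmissions), "match states\n")
  if (!is.null(object@calibration))
    cat("  calibrated: mu =", signif(object@calibration@mu, 4),
        " lambda =", signif(object@calibration@lambda, 4), "\n")
  else cat("  not calibrated\n")
})

setMethod("show", "CdsCompositionModel", function(object) {
  cat("CdsCompositionModel (mode:", object@mode,
      ", background order", object@backgroundOrder, ")\n")
  cat("  trained on:", paste(object@trainingGenomeIds, collapse = ", "), "\n")
})

setMethod("show", "RepertoireMatrix", function(object) {
  cat("RepertoireMatrix:", nrow(object@presence), "strains x",
      ncol(object@presence), "clusters;",
      length(unique(object@speciesLabels)), "species\n")
})
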