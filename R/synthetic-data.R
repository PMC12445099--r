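## Synthetic corpus generator: genomes whose coding regions are drawn
## from a codon-usage model, intergenic background from a distinct
## order-k Markov chain, planted RRNPP regulator homologs at controlled
## pairwise identities, planted AIP genes within 300 bp of them, shared
## context genes, decoy short ORFs, and a ground-truth manifest. All
## stages of the pipeline are testable against the manifest without any
## download.

.SPECIES3 <- c("S. thermophilus", "S. salivarius", "S. vestibularis")

## published S. thermophilus SHP precursors and their experimentally
## supported mature forms: the default AIP templates of the generator
.DEFAULT_AIP_TEMPLATES <- data.frame(
  template_id = c("shpT1", "shpT2", "shpT3", "shpT4", "shpT5"),
  class = "SHP",
  precursor = c("MKKVIAIFLFIQTVVVIDIIIFPPFG",
                "MEKVSKILPILILVMDIIIIVGG",
                "MNKKALFSLLFVILEGIIVIGVG",
                "MNKESFLAILLLIFESIIVIAVG",
                "MKKQILLTLLLVVFEGIIVIVVG"),
  mature = c("DIIIFPPFG", "DIIIIVGG", "EGIIVIGVG", "ESIIVIAVG",
             "EGIIVIVVG"),
  stringsAsFactors = FALSE)

.DEFAULT_AIP_SEEDS <- data.frame(
  seed_id = c(paste0("seed_", .DEFAULT_AIP_TEMPLATES$template_id),
              "seed_comS", "seed_papR", "seed_lcp", "seed_mutS"),
  class = c(rep("SHP", 5), "ComS", "PapR", "LCP", "MutS"),
  sequence = c(.DEFAULT_AIP_TEMPLATES$precursor,
               "MKTLKIFVLFSLLIAILPYFAGCL",
               "MRKFLKKLIVISLLGGLILAIGKGGTNKVKPMNGIDPGPANIMVK",
               "MWLLLLFL",
               "MLKTILKRIISLALVLPFFLLPIL"),
  stringsAsFactors = FALSE)

#' Default order-2 background chain (AT-rich, ~39% GC)
#' @keywords internal
.defaultBackground <- function(order = 2L) {
  base <- c(A = 0.31, C = 0.19, G = 0.20, T = 0.30)
  kmers <- .allKmers(order)
  trans <- matrix(0, length(kmers), 4, dimnames = list(kmers, .NT))
  for (i in seq_along(kmers)) {
    lastNt <- substr(kmers[i], order, order)
    w <- base * (1 + 0.35 * (names(base) == lastNt))   # mild autocorrelation
    trans[i, ] <- w / sum(w)
  }
  first <- substr(kmers, 1, 1); second <- substr(kmers, order, order)
  init <- base[first] * base[second]
  list(order = order, trans = trans, init = init / sum(init))
}

#' Default codon-usage table
#'
#' Amino-acid marginals follow Robinson-Robinson frequencies; the
#' synonymous choice prefers A/T in the wobble position, mimicking a
#' low-GC streptococcal genome.
#' @keywords internal
.defaultCodonUsage <- function() {
  w3 <- c(A = 0.40, C = 0.12, G = 0.13, T = 0.35)
  aa <- .BACTERIAL_CODE[.SENSE_CODONS]
  u <- stats::setNames(numeric(length(.SENSE_CODONS)), .SENSE_CODONS)
  for (a in unique(aa)) {
    syn <- .SENSE_CODONS[aa == a]
    wob <- w3[substr(syn, 3, 3)]
    u[syn] <- robinsonRobinson[[a]] * wob / sum(wob)
  }
  u / sum(u)
}

#' Synthetic corpus configuration
#'
#' The default is the stated world of the acceptance tests: 20 genomes
#' (7 + 7 + 6 across the three salivarius-group species) of 200 kbp
#' each, 33 baits over the four RRNPP families, 5 planted regulator
#' clusters with pairwise within-cluster identity 0.95 and
#' between-cluster identity at most 0.70, AIP genes from SHP templates
#' planted within 300 bp of 80% of the regulator loci, shared context
#' genes, and decoy short ORFs at 0.1 per kbp.
#'
#' @param rngSeed integer seed; the whole corpus is a pure function of
#'   it.
#' @param nGenomesPerSpecies named integer vector over the 3 species.
#' @param genomeLength contig length in bp.
#' @param nGenes ordinary protein-coding genes per genome.
#' @param geneLenRangeAa length range of ordinary gene products (aa).
#' @param background list with `order`, `trans`, `init` (see
#'   `.defaultBackground`).
#' @param codonUsage named 61-codon distribution.
#' @param nBaits number of baits (33).
#' @param baitIdentityRange identity range of baits to their family
#'   prototype.
#' @param nClusters planted regulator clusters (5).
#' @param clusterBaitIdentity identity of each cluster centre to its
#'   source bait (0.80, keeping every planted homolog >= 60% identical
#'   to a bait).
#' @param withinClusterIdentity target pairwise identity among cluster
#'   members (0.95); members are drawn at identity (1 + w)/2 to the
#'   centre.
#' @param betweenClusterIdentityMax maximum tolerated identity between
#'   cluster centres (0.70).
#' @param presenceProbs per-cluster probability that a genome carries
#'   the cluster.
#' @param aipTemplates data.frame of SHP precursor templates with
#'   mature suffixes.
#' @param aipPlantingRate fraction of regulator loci receiving an AIP
#'   gene within 300 bp (0.8).
#' @param aipOrientations orientation per cluster, recycled.
#' @param decoyShortOrfRate decoy short ORFs per kbp (0.1).
#' @param contextPlantingRate probability of each flanking context gene
#'   at a regulator locus (0.6).
#' @return a `SyntheticConfig` list.
#' @export
syntheticConfig <- function(
    rngSeed = 1L,
    nGenomesPerSpecies = c("S. thermophilus" = 7L, "S. salivarius" = 7L,
                           "S. vestibularis" = 6L),
    genomeLength = 200000L,
    nGenes = 110L,
    geneLenRangeAa = c(120L, 400L),
    background = .defaultBackground(2L),
    codonUsage = .defaultCodonUsage(),
    nBaits = 33L,
    baitIdentityRange = c(0.75, 0.95),
    nClusters = 5L,
    clusterBaitIdentity = 0.85,
    withinClusterIdentity = 0.95,
    betweenClusterIdentityMax = 0.70,
    presenceProbs = c(0.95, 0.80, 0.60, 0.45, 0.25),
    aipTemplates = .DEFAULT_AIP_TEMPLATES,
    aipPlantingRate = 0.8,
    aipOrientations = c("divergent", "co_upstream", "divergent",
                        "co_downstream", "convergent"),
    decoyShortOrfRate = 0.1,
    contextPlantingRate = 0.6) {
  stopifnot(withinClusterIdentity > 0, withinClusterIdentity <= 1,
            betweenClusterIdentityMax > 0, betweenClusterIdentityMax < 1,
            aipPlantingRate >= 0, decoyShortOrfRate >= 0)
  cfg <- list(rngSeed = as.integer(rngSeed),
              nGenomesPerSpecies = nGenomesPerSpecies,
              genomeLength = as.integer(genomeLength),
              nGenes = as.integer(nGenes),
              geneLenRangeAa = as.integer(geneLenRangeAa),
              background = background, codonUsage = codonUsage,
              nBaits = as.integer(nBaits),
              baitIdentityRange = baitIdentityRange,
              nClusters = as.integer(nClusters),
              clusterBaitIdentity = clusterBaitIdentity,
              withinClusterIdentity = withinClusterIdentity,
              betweenClusterIdentityMax = betweenClusterIdentityMax,
              presenceProbs = rep_len(presenceProbs, nClusters),
              aipTemplates = aipTemplates,
              aipPlantingRate = aipPlantingRate,
              aipOrientations = rep_len(aipOrientations, nClusters),
              decoyShortOrfRate = decoyShortOrfRate,
              contextPlantingRate = contextPlantingRate)
  class(cfg) <- c("SyntheticConfig", "list")
  cfg
}

#' Mutate a protein to a target identity
#'
#' Substitutions at uniformly chosen distinct positions (position 1 is
#' preserved so the start Met survives); the replacement residue is
#' drawn from background frequencies excluding the original residue.
#' The realized identity is exact: `1 - nSubstitutions / length`.
#'
#' @param seq amino-acid string.
#' @param targetIdentity in (0, 1].
#' @param keepFirst preserve position 1 (default TRUE).
#' @return list with `sequence` and `realizedIdentity`.
#' @export
mutateProtein <- function(seq, targetIdentity, keepFirst = TRUE) {
  stopifnot(targetIdentity > 0, targetIdentity <= 1)
  res <- strsplit(seq, "")[[1]]
  L <- length(res)
  nMut <- round((1 - targetIdentity) * L)
  pool <- if (keepFirst) 2:L else seq_len(L)
  nMut <- min(nMut, length(pool))
  if (nMut > 0) {
    pos <- sample(pool, nMut)
    for (p in pos) {
      alt <- setdiff(names(robinsonRobinson), res[p])
      res[p] <- sample(alt, 1, prob = robinsonRobinson[alt])
    }
  }
  list(sequence = paste(res, collapse = ""),
       realizedIdentity = 1 - nMut / L)
}

.randomProtein <- function(lenAa) {
  paste(c("M", sample(names(robinsonRobinson), lenAa - 1L, replace = TRUE,
                      prob = robinsonRobinson)), collapse = "")
}

.SYN_BY_AA <- split(.SENSE_CODONS, .BACTERIAL_CODE[.SENSE_CODONS])

## back-translate a protein with the configured codon usage; first
## residue M becomes ATG; a stop codon is appended
.backTranslate <- function(protein, codonUsage,
                           stopProbs = c(TAA = 0.6, TAG = 0.15, TGA = 0.25)) {
  res <- strsplit(protein, "")[[1]]
  codons <- vapply(res, function(a) {
    syn <- .SYN_BY_AA[[a]]
    if (is.null(syn)) return("NNN")
    if (length(syn) == 1L) return(syn)
    sample(syn, 1, prob = codonUsage[syn])
  }, character(1))
  codons[1] <- "ATG"
  stopCodon <- sample(names(stopProbs), 1, prob = stopProbs)
  paste(c(codons, stopCodon), collapse = "")
}

.sampleBackground <- function(n, bg) {
  if (n <= 0L) return("")
  enc <- .sample_markov(n, bg$order, 4L, bg$trans, bg$init)
  paste(.NT[enc + 1L], collapse = "")
}

## a gene segment on the forward axis: list(seq, start, end, strand)
## relative offsets are 0-based half-open within the segment
.geneSegment <- function(dna, strand, guard = "") {
  own <- paste0(guard, dna)
  if (strand == "+")
    list(seq = own, start = nchar(guard), end = nchar(own), strand = "+")
  else
    list(seq = revcomp(own), start = 0L, end = nchar(dna), strand = "-")
}

#' Generate a synthetic corpus with ground truth
#'
#' Produces annotated genomes, the bait alignment (indel-free mutants
#' of family prototypes, so the trivial columnwise alignment is valid),
#' the AIP seed set, and a manifest of every planted feature. The
#' output is a pure function of `cfg$rngSeed` (bit-identical reruns).
#'
#' @param cfg a [syntheticConfig()].
#' @return list with elements `genomes` (list of [GenomeRecord]),
#'   `baits` (bait alignment data.frame), `seeds` (AIP seed set),
#'   `manifest` (list of data.frames: `regulators`, `aips`, `context`,
#'   `decoys`) and `config`.
#' @export
generateCorpus <- function(cfg = syntheticConfig()) {
  old <- .saveSeed(); on.exit(.restoreSeed(old))
  set.seed(cfg$rngSeed)

  ## ---- baits: indel-free mutants of four family prototypes ----
  famPlan <- c(rep("Rgg", 20), rep("ComR", 6), rep("PlcR", 4), rep("PrgX", 3))
  famPlan <- rep_len(famPlan, cfg$nBaits)
  subPlan <- c(rep("SHP/Rgg", 12), rep("LCP/RopB", 3), rep("MutS/MutR", 2),
               rep("Rgg", 3), rep("ComS/ComR", 6), rep("PapR/TprA", 4),
               rep("PrgX", 3))
  subPlan <- rep_len(subPlan, cfg$nBaits)
  ## family prototypes descend from one ancestor (the shared TPR/HTH
  ## architecture of the superfamily), ~60% identity to it, so the
  ## generic profile has a coherent consensus across families and true
  ## homologs align end to end, as the real superfamily profile does
  ancestor <- .randomProtein(300L)
  protos <- stats::setNames(
    lapply(c("Rgg", "ComR", "PlcR", "PrgX"), function(f)
      mutateProtein(ancestor, 0.6)$sequence),
    c("Rgg", "ComR", "PlcR", "PrgX"))
  baitIdent <- stats::runif(cfg$nBaits, cfg$baitIdentityRange[1],
                            cfg$baitIdentityRange[2])
  baitSeqs <- vapply(seq_len(cfg$nBaits), function(i)
    mutateProtein(protos[[famPlan[i]]], baitIdent[i])$sequence, character(1))
  baits <- data.frame(
    bait_id = sprintf("bait%d_%s", seq_len(cfg$nBaits),
                      gsub("/", "", subPlan)),
    family = famPlan, subfamily = subPlan, aligned = baitSeqs,
    stringsAsFactors = FALSE)

  ## ---- cluster centres at controlled separation ----
  srcIdx <- round(seq(1, cfg$nBaits - 3, length.out = cfg$nClusters))
  centres <- character(cfg$nClusters)
  for (k in seq_len(cfg$nClusters)) {
    repeat {
      cand <- mutateProtein(baitSeqs[srcIdx[k]],
                            cfg$clusterBaitIdentity)$sequence
      ok <- TRUE
      if (k > 1) {
        for (j in seq_len(k - 1)) {
          idn <- pairwiseIdentity(strsplit(cand, "")[[1]],
                                  strsplit(centres[j], "")[[1]])
          if (idn > cfg$betweenClusterIdentityMax) { ok <- FALSE; break }
        }
      }
      if (ok) { centres[k] <- cand; break }
    }
  }

  ## ---- shared context gene pool ----
  ctxPool <- data.frame(
    ctx_id = c("ctxA", "ctxB", "ctxC"),
    product = c("radical SAM enzyme", "ABC transporter permease",
                "transposase fragment"),
    sequence = c(.randomProtein(260L), .randomProtein(300L),
                 .randomProtein(180L)),
    stringsAsFactors = FALSE)

  speciesVec <- rep(names(cfg$nGenomesPerSpecies), cfg$nGenomesPerSpecies)
  nG <- length(speciesVec)
  genomes <- vector("list", nG)
  manReg <- list(); manAip <- list(); manCtx <- list()
  manDecoy <- list(); manRoles <- list()

  templates <- cfg$aipTemplates[rep_len(seq_len(nrow(cfg$aipTemplates)),
                                        cfg$nClusters), , drop = FALSE]

  for (gi in seq_len(nG)) {
    gid <- sprintf("synth_%03d", gi)
    segs <- list()      # each: list(seq, feats = data.frame, kind)
    featCounter <- 0L
    newId <- function() {
      featCounter <<- featCounter + 1L
      sprintf("%s_cds_%04d", gid, featCounter)
    }

    ## ordinary genes: codons i.i.d. from the usage table
    for (j in seq_len(cfg$nGenes)) {
      lenAa <- sample(cfg$geneLenRangeAa[1]:cfg$geneLenRangeAa[2], 1)
      codons <- sample(.SENSE_CODONS, lenAa, replace = TRUE,
                       prob = cfg$codonUsage)
      codons[1] <- "ATG"
      dna <- paste(c(codons, "TAA"), collapse = "")
      strand <- sample(c("+", "-"), 1)
      seg <- .geneSegment(dna, strand)
      prot <- translateCds(if (strand == "+") seg$seq
                           else revcomp(seg$seq))
      segs[[length(segs) + 1L]] <- list(
        seq = seg$seq, kind = "gene",
        feats = data.frame(feature_id = newId(), start = seg$start,
                           end = seg$end, strand = strand, protein = prot,
                           product = "hypothetical protein", role = "gene",
                           stringsAsFactors = FALSE))
    }

    ## decoy short ORFs: background-composition codons
    nDecoy <- stats::rpois(1, cfg$decoyShortOrfRate * cfg$genomeLength / 1000)
    for (j in seq_len(nDecoy)) {
      lenAa <- sample(7:60, 1)
      aa <- c("M", sample(names(robinsonRobinson), lenAa - 1L, replace = TRUE))
      dna <- .backTranslate(paste(aa, collapse = ""), cfg$codonUsage * 0 + 1 / 61)
      strand <- sample(c("+", "-"), 1)
      seg <- .geneSegment(dna, strand, guard = "TAA")
      segs[[length(segs) + 1L]] <- list(seq = seg$seq, kind = "decoy",
        feats = NULL,
        decoy = data.frame(genome_id = gid, start = seg$start,
                           end = seg$end, strand = strand,
                           stringsAsFactors = FALSE))
    }

    ## regulator loci
    present <- stats::runif(cfg$nClusters) < cfg$presenceProbs
    for (k in which(present)) {
      mem <- mutateProtein(centres[k], (1 + cfg$withinClusterIdentity) / 2)
      regDna <- .backTranslate(mem$sequence, cfg$codonUsage)
      regStrand <- sample(c("+", "-"), 1)
      orient <- cfg$aipOrientations[k]
      plantAip <- stats::runif(1) < cfg$aipPlantingRate
      aipDna <- if (plantAip)
        .backTranslate(templates$precursor[k], cfg$codonUsage) else NULL

      ## build the block with the regulator on "+", mirror afterwards
      parts <- list(); feats <- list(); aipRec <- NULL
      addPart <- function(seq) {
        off <- sum(vapply(parts, nchar, numeric(1)))
        parts[[length(parts) + 1L]] <<- seq
        off
      }
      ctxLeft <- stats::runif(1) < cfg$contextPlantingRate
      ctxRight <- stats::runif(1) < cfg$contextPlantingRate
      ctxRows <- list()
      if (ctxLeft) {
        ci <- sample(nrow(ctxPool), 1)
        cStrand <- sample(c("+", "-"), 1)
        cSeg <- .geneSegment(.backTranslate(ctxPool$sequence[ci],
                                            cfg$codonUsage), cStrand)
        off <- addPart(cSeg$seq)
        ctxRows[[length(ctxRows) + 1L]] <- list(
          off = off, seg = cSeg, ci = ci)
        addPart(.sampleBackground(sample(150:600, 1), cfg$background))
      }
      aipLeft <- orient %in% c("divergent", "co_upstream")
      aipStrandInBlock <- if (orient %in% c("divergent", "convergent"))
        "-" else "+"
      if (plantAip && aipLeft) {
        aSeg <- .geneSegment(aipDna, aipStrandInBlock, guard = "TAA")
        off <- addPart(aSeg$seq)
        aipRec <- list(off = off, seg = aSeg)
        addPart(.sampleBackground(sample(30:220, 1), cfg$background))
      }
      regOff <- addPart(regDna)
      regLen <- nchar(regDna)
      if (plantAip && !aipLeft) {
        addPart(.sampleBackground(sample(30:220, 1), cfg$background))
        aSeg <- .geneSegment(aipDna, aipStrandInBlock, guard = "TAA")
        off <- addPart(aSeg$seq)
        aipRec <- list(off = off, seg = aSeg)
      }
      if (ctxRight) {
        addPart(.sampleBackground(sample(150:600, 1), cfg$background))
        ci <- sample(nrow(ctxPool), 1)
        cStrand <- sample(c("+", "-"), 1)
        cSeg <- .geneSegment(.backTranslate(ctxPool$sequence[ci],
                                            cfg$codonUsage), cStrand)
        off <- addPart(cSeg$seq)
        ctxRows[[length(ctxRows) + 1L]] <- list(off = off, seg = cSeg, ci = ci)
      }
      blockSeq <- paste(parts, collapse = "")
      blockLen <- nchar(blockSeq)

      mirror <- regStrand == "-"
      if (mirror) blockSeq <- revcomp(blockSeq)
      flip <- function(start, end, strand) {
        if (!mirror) return(list(start = start, end = end, strand = strand))
        list(start = blockLen - end, end = blockLen - start,
             strand = if (strand == "+") "-" else "+")
      }
      regId <- newId()
      regPos <- flip(regOff, regOff + regLen, "+")
      blockFeats <- list(data.frame(feature_id = regId, start = regPos$start,
        end = regPos$end, strand = regPos$strand, protein = mem$sequence,
        product = "transcriptional regulator", role = "regulator",
        stringsAsFactors = FALSE))
      manReg[[length(manReg) + 1L]] <- data.frame(
        genome_id = gid, feature_id = regId, cluster = k,
        source_bait = baits$bait_id[srcIdx[k]],
        realized_identity = round(mem$realizedIdentity, 3),
        strand = regPos$strand, stringsAsFactors = FALSE)
      aipRow <- NULL
      if (!is.null(aipRec)) {
        aPos <- flip(aipRec$off + aipRec$seg$start,
                     aipRec$off + aipRec$seg$end, aipRec$seg$strand)
        aipRow <- data.frame(
          genome_id = gid, regulator_id = regId, cluster = k,
          start = aPos$start, end = aPos$end, strand = aPos$strand,
          precursor = templates$precursor[k], mature = templates$mature[k],
          class = templates$class[k], orientation = orient,
          stringsAsFactors = FALSE)
      }
      for (cr in ctxRows) {
        cPos <- flip(cr$off + cr$seg$start, cr$off + cr$seg$end,
                     cr$seg$strand)
        cid <- newId()
        blockFeats[[length(blockFeats) + 1L]] <- data.frame(
          feature_id = cid, start = cPos$start, end = cPos$end,
          strand = cPos$strand, protein = ctxPool$sequence[cr$ci],
          product = ctxPool$product[cr$ci], role = "context",
          stringsAsFactors = FALSE)
        manCtx[[length(manCtx) + 1L]] <- data.frame(
          genome_id = gid, feature_id = cid, ctx_id = ctxPool$ctx_id[cr$ci],
          regulator_id = regId, stringsAsFactors = FALSE)
      }
      segs[[length(segs) + 1L]] <- list(seq = blockSeq, kind = "locus",
        feats = do.call(rbind, blockFeats), aip = aipRow)
    }

    ## assemble: shuffle segments, fill with background to genomeLength;
    ## rejection guard: background must not accidentally spell a planted
    ## AIP template in any frame (retry the assembly if it ever does)
    contigId <- paste0(gid, "_c1")
    nPlantedPerTemplate <- table(factor(
      unlist(lapply(segs, function(s) if (!is.null(s$aip)) s$aip$precursor)),
      levels = unique(templates$precursor)))
    for (attempt in 1:5) {
      segs <- segs[sample(length(segs))]
      segLen <- sum(vapply(segs, function(s) nchar(s$seq), numeric(1)))
      slack <- cfg$genomeLength - segLen
      if (slack < length(segs) + 1L)
        stop("genomeLength too small for the configured gene content",
             call. = FALSE)
      cuts <- sort(sample.int(slack, length(segs)))
      gaps <- diff(c(0L, cuts, slack))
      pieces <- character(2L * length(segs) + 1L)
      featRows <- list(); decoyRows <- list(); aipRows <- list()
      pos <- 0L
      pieces[1] <- .sampleBackground(gaps[1], cfg$background)
      pos <- gaps[1]
      for (si in seq_along(segs)) {
        s <- segs[[si]]
        if (!is.null(s$feats)) {
          f <- s$feats
          f$start <- f$start + pos; f$end <- f$end + pos
          featRows[[length(featRows) + 1L]] <- f
        }
        if (!is.null(s$decoy)) {
          d <- s$decoy
          d$start <- d$start + pos; d$end <- d$end + pos
          decoyRows[[length(decoyRows) + 1L]] <- d
        }
        if (!is.null(s$aip)) {
          a <- s$aip
          a$start <- a$start + pos; a$end <- a$end + pos
          a$contig_id <- contigId
          aipRows[[length(aipRows) + 1L]] <- a
        }
        pieces[2L * si] <- s$seq
        pos <- pos + nchar(s$seq)
        pieces[2L * si + 1L] <- .sampleBackground(gaps[si + 1L],
                                                  cfg$background)
        pos <- pos + gaps[si + 1L]
      }
      contigSeq <- paste(pieces, collapse = "")
      if (all(.countTemplateOrfs(contigSeq, names(nPlantedPerTemplate)) <=
              as.integer(nPlantedPerTemplate)) || attempt == 5L) break
    }
    ft <- do.call(rbind, featRows)
    ft <- ft[order(ft$start), , drop = FALSE]
    ft$contig_id <- contigId
    genomes[[gi]] <- makeGenomeRecord(gid, speciesVec[gi],
      stats::setNames(contigSeq, contigId),
      ft[, c("feature_id", "contig_id", "start", "end", "strand",
             "protein", "product")])
    if (length(aipRows))
      manAip <- c(manAip, aipRows)
    rolesRows <- ft[, c("feature_id", "role")]
    rolesRows$genome_id <- gid
    manRoles[[length(manRoles) + 1L]] <- rolesRows
    if (length(decoyRows)) {
      dd <- do.call(rbind, decoyRows)
      dd$contig_id <- contigId
      manDecoy[[length(manDecoy) + 1L]] <- dd
    }
  }

  manifest <- list(
    regulators = do.call(rbind, manReg),
    aips = if (length(manAip)) do.call(rbind, manAip) else data.frame(),
    context = if (length(manCtx)) do.call(rbind, manCtx) else data.frame(),
    roles = do.call(rbind, manRoles),
    decoys = if (length(manDecoy)) do.call(rbind, manDecoy)
             else data.frame())
  seeds <- .DEFAULT_AIP_SEEDS
  list(genomes = genomes, baits = baits, seeds = seeds,
       manifest = manifest, config = cfg)
}

## occurrences of each template peptide across the 6 reading frames
.countTemplateOrfs <- function(contigSeq, precursors) {
  if (!length(precursors)) return(integer(0))
  counts <- integer(length(precursors))
  for (s in c(contigSeq, revcomp(contigSeq))) {
    n <- nchar(s)
    for (f in 0:2) {
      len <- ((n - f) %/% 3L) * 3L
      if (len < 3L) next
      aa <- suppressWarnings(as.character(Biostrings::translate(
        Biostrings::DNAString(substr(s, f + 1L, f + len)),
        genetic.code = .BACTERIAL_CODE, if.fuzzy.codon = "X",
        no.init.codon = TRUE)))
      for (p in seq_along(precursors)) {
        m <- gregexpr(precursors[p], aa, fixed = TRUE)[[1]]
        counts[p] <- counts[p] + sum(m > 0)
      }
    }
  }
  counts
}
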