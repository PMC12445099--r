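## End-to-end workflow glue: profile building + search + filtering +
## clustering + naming, short-CDS/AIP discovery around the hits, and
## repertoire statistics, in one call. Also disk output of a synthetic
## corpus in the formats the pipeline reads.

#' Run the full genome-mining workflow on a corpus
#'
#' Builds the generic profile HMM from the bait alignment, calibrates
#' E-values, searches every proteome, filters hits (E-value <= 1e-5,
#' profile start <= 10, coverage >= 90% by default), projects hits onto
#' consensus-filtered columns, clusters them by connected components at
#' the identity cutoff, transfers family/subfamily from the closest
#' bait, names clusters with the species-scoped scheme, builds the
#' repertoire matrix, and (optionally) trains the short-CDS model on
#' the training genomes and annotates AIP candidates within 300 bp of
#' every regulator hit.
#'
#' @param genomes list of [GenomeRecord] objects.
#' @param baits bait alignment data.frame (see [readBaitAlignment()]).
#' @param seeds optional AIP seed set (see [readAipSeeds()]).
#' @param calibSeed seed for E-value calibration randomness.
#' @param nCalib number of calibration sequences (default 1000).
#' @param identityCutoff clustering cutoff (default 0.90, strict ">").
#' @param doShortCds run short-CDS discovery and AIP annotation.
#' @param trainingGenomes indices of genomes used to train the
#'   composition model (default the first five).
#' @param filterConfig list with `evalueMax`, `profileStartMax`,
#'   `coverageMin` overriding the hit-filter defaults.
#' @return list with `profile`, `proteome`, `hits`, `filteredHits`,
#'   `retained`, `hitMatrix`, `clusters`, `clusterTable`,
#'   `memberships`, `repertoire`, `cdsModel`, `shortCds`,
#'   `aipAnnotations`.
#' @export
mineCorpus <- function(genomes, baits, seeds = NULL, calibSeed = 42L,
                       nCalib = 1000L, identityCutoff = 0.90,
                       doShortCds = TRUE,
                       trainingGenomes = seq_len(min(5L, length(genomes))),
                       filterConfig = list()) {
  proteome <- do.call(rbind, lapply(genomes, extractProteome))
  profile <- buildProfile(baits)
  profile <- calibrateEvalues(profile, nRandom = nCalib, seed = calibSeed,
                              lengths = 300L, dbSize = nrow(proteome))
  hits <- searchProfile(profile, proteome)
  fc <- utils::modifyList(list(evalueMax = 1e-5, profileStartMax = 10L,
                               coverageMin = 0.90), filterConfig)
  fhits <- filterHits(hits, fc$evalueMax, fc$profileStartMax, fc$coverageMin)
  out <- list(profile = profile, proteome = proteome, hits = hits,
              filteredHits = fhits)
  if (nrow(fhits) == 0L) return(out)
  retained <- retainedColumns(fhits)
  hitMatrix <- alignedHitMatrix(fhits, retained$mask)
  clusters <- clusterHits(hitMatrix, cutoff = identityCutoff)
  genomeSpecies <- stats::setNames(
    vapply(genomes, speciesLabel, character(1)),
    vapply(genomes, genomeId, character(1)))
  clusterTable <- regulatorClusterTable(clusters, fhits, baits,
                                        genomeSpecies)
  memberships <- do.call(rbind, lapply(seq_along(clusters), function(k)
    data.frame(hit_id = clusters[[k]],
               genome_id = fhits$genome_id[match(clusters[[k]],
                                                 fhits$protein_id)],
               cluster_id = clusterTable$cluster_id[k],
               stringsAsFactors = FALSE)))
  strains <- data.frame(genome_id = names(genomeSpecies),
                        species = unname(genomeSpecies),
                        stringsAsFactors = FALSE)
  repertoire <- buildRepertoireMatrix(memberships, strains)
  out <- c(out, list(retained = retained, hitMatrix = hitMatrix,
                     clusters = clusters, clusterTable = clusterTable,
                     memberships = memberships, repertoire = repertoire))
  if (!doShortCds) return(out)
  cdsModel <- trainCdsModel(genomes[trainingGenomes])
  genomeById <- stats::setNames(genomes, names(genomeSpecies))
  shortCds <- list(); aipAnn <- list()
  for (g in genomes) {
    gid <- genomeId(g)
    regHere <- fhits[fhits$genome_id == gid, , drop = FALSE]
    if (nrow(regHere) == 0L) next
    cand <- predictShortCds(g, cdsModel)
    shortCds[[gid]] <- cand
    ft <- featureTable(g)
    for (r in seq_len(nrow(regHere))) {
      feat <- ft[ft$feature_id == regHere$protein_id[r], , drop = FALSE]
      if (nrow(feat) != 1L) next
      nb <- neighborhoodScan(cand, feat)
      ann <- annotateRegulator(feat, nb, seeds = seeds)
      if (nrow(ann)) {
        ann$genome_id <- gid
        ann$regulator_id <- feat$feature_id
        aipAnn[[length(aipAnn) + 1L]] <- ann
      }
    }
  }
  out$cdsModel <- cdsModel
  out$shortCds <- shortCds
  out$aipAnnotations <- if (length(aipAnn)) do.call(rbind, aipAnn)
                        else data.frame()
  out
}

#' Write a synthetic corpus to disk
#'
#' Emits the corpus in the formats the pipeline reads: one GenBank flat
#' file per genome plus a combined proteome FASTA, the bait alignment
#' as aligned FASTA, the AIP seed set as FASTA, and the ground-truth
#' manifest as JSON.
#'
#' @param corpus output of [generateCorpus()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCorpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in corpus$genomes)
    writeGenBank(g, file.path(dir, paste0(genomeId(g), ".gbff")))
  proteome <- do.call(rbind, lapply(corpus$genomes, extractProteome))
  writeFasta(stats::setNames(proteome$sequence, proteome$protein_id),
             file.path(dir, "proteome.faa"), type = "AA")
  writeBaitAlignment(corpus$baits, file.path(dir, "baits.afa"))
  writeAipSeeds(corpus$seeds, file.path(dir, "aip_seeds.faa"))
  jsonlite::write_json(corpus$manifest,
                       file.path(dir, "manifest.json"),
                       dataframe = "rows", digits = NA)
  invisible(dir)
}
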