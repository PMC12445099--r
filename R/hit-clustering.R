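## Clustering of filtered hits into RRNPP similarity clusters at an
## identity cutoff, family/subfamily transfer from the closest bait,
## species-scoped cluster naming and 2-kbp neighborhood gene clustering.

#' @importFrom igraph graph_from_adjacency_matrix components
NULL

## Karlin-Altschul parameters for gapped BLOSUM62 (open 11 / extend 1)
.KA_LAMBDA <- 0.267
.KA_K <- 0.041

#' Pairwise identity between two aligned rows
#'
#' Identity = identical-residue columns / columns where both rows are
#' non-gap; 0 when no such column exists. Symmetric, and 1 for a row
#' against itself.
#'
#' @param rowA,rowB character vectors of single residues/gaps, or
#'   strings of equal length (gap = "-").
#' @return fraction in `[0, 1]`.
#' @export
pairwiseIdentity <- function(rowA, rowB) {
  if (is.character(rowA) && length(rowA) == 1L) rowA <- strsplit(rowA, "")[[1]]
  if (is.character(rowB) && length(rowB) == 1L) rowB <- strsplit(rowB, "")[[1]]
  if (length(rowA) != length(rowB))
    stop("rows differ in length", call. = FALSE)
  both <- rowA != "-" & rowB != "-"
  if (!any(both)) return(0)
  sum(rowA[both] == rowB[both]) / sum(both)
}

#' All-pairs identity matrix of an aligned hit matrix
#'
#' @param mat character matrix from [alignedHitMatrix()].
#' @return symmetric numeric matrix of pairwise identities.
#' @export
identityMatrix <- function(mat) {
  n <- nrow(mat)
  out <- matrix(1, n, n, dimnames = list(rownames(mat), rownames(mat)))
  if (n < 2L) return(out)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    out[i, j] <- out[j, i] <- pairwiseIdentity(mat[i, ], mat[j, ])
  }
  out
}

#' Cluster hits by connected components at an identity cutoff
#'
#' Builds a graph with an edge between two hits iff their pairwise
#' identity exceeds `cutoff` (strictly by default, matching "more than
#' 90% pairwise identity"; set `strict = FALSE` for ">="), and returns
#' the connected components, ordered by size (descending) and then by
#' lexicographically smallest member.
#'
#' @param mat character matrix from [alignedHitMatrix()] (rows named by
#'   hit id), or a precomputed identity matrix via `idMat`.
#' @param cutoff identity cutoff (default 0.90).
#' @param strict logical; edge rule ">" (default) or ">=".
#' @param idMat optional precomputed identity matrix.
#' @return list of character vectors of member hit ids.
#' @export
clusterHits <- function(mat, cutoff = 0.90, strict = TRUE, idMat = NULL) {
  if (is.null(idMat)) idMat <- identityMatrix(mat)
  ids <- rownames(idMat)
  n <- length(ids)
  if (n == 0L) return(list())
  adj <- if (strict) idMat > cutoff else idMat >= cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  cl <- split(ids, comp)
  minMember <- vapply(cl, function(x) sort(x)[1], character(1))
  cl <- cl[order(-lengths(cl), minMember)]
  unname(lapply(cl, sort))
}

.degap <- function(x) gsub("-", "", x)

.localAlign <- function(a, b) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
}

## one vectorized call: each of `patterns` against the single `query`
.localAlignSet <- function(patterns, query, type = "local") {
  Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(patterns), Biostrings::AAString(query),
    type = type, substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
}

#' Assign family/subfamily from the closest bait
#'
#' Local alignment (BLOSUM62, gap open 11 / extend 1) of a cluster
#' representative against every bait; the closest bait (highest
#' alignment score, as for a blastp best hit; ties broken by identity,
#' then coverage, then bait order) transfers its family and subfamily.
#' Identity < 40% raises the "like" flag, turning e.g. subfamily
#' "SHP/Rgg" into the reported "SHP/Rgg-like".
#'
#' @param representativeSeq ungapped amino-acid string.
#' @param baits data.frame with `bait_id`, `family`, `subfamily` and
#'   `aligned` (or `sequence`) columns.
#' @return list with `best_bait`, `family`, `subfamily`,
#'   `identity_pct`, `coverage_pct`, `like_flag`, `unclassified`.
#' @export
assignFamily <- function(representativeSeq, baits) {
  seqs <- if ("sequence" %in% names(baits)) baits$sequence
          else .degap(baits$aligned)
  aln <- .localAlignSet(seqs, representativeSeq)
  sc <- Biostrings::score(aln)
  if (all(sc <= 0))
    return(list(best_bait = NA_character_, family = NA_character_,
                subfamily = NA_character_, identity_pct = NA_real_,
                coverage_pct = NA_real_, like_flag = NA, unclassified = TRUE))
  idn <- Biostrings::pid(aln, type = "PID1")
  cov <- 100 * Biostrings::width(Biostrings::subject(aln)) /
    nchar(representativeSeq)
  ok <- sc > 0
  ord <- order(-sc, -idn, -cov, seq_along(sc))
  i <- ord[ok[ord]][1]
  list(best_bait = baits$bait_id[i], family = baits$family[i],
       subfamily = baits$subfamily[i], identity_pct = idn[i],
       coverage_pct = cov[i], like_flag = idn[i] < 40,
       unclassified = FALSE)
}

.defaultSpeciesTokens <- c(
  "S. thermophilus" = "Sthermo",
  "S. salivarius" = "Ssali",
  "S. vestibularis" = "Svesti")

#' Species-scoped cluster identifiers
#'
#' Builds identifiers of the form `subfamily_scope_n_` (e.g.
#' `SHP/Rgg_Sthermo_6_`): the scope token is the species token when the
#' cluster is confined to one species and `gp_sali` when it spans at
#' least two; the running integer is a per-(family, scope) counter in
#' input order, so naming is deterministic given identical input
#' ordering. A "-like" suffix is appended to the subfamily when
#' `like_flag` is set.
#'
#' @param subfamilies character vector per cluster.
#' @param families character vector per cluster (counter scope).
#' @param speciesSets list of character vectors of species labels.
#' @param likeFlags logical vector per cluster.
#' @param speciesTokens named map species label -> token.
#' @param groupToken token for multi-species clusters.
#' @return character vector of cluster ids.
#' @export
nameClusters <- function(subfamilies, families, speciesSets,
                         likeFlags = rep(FALSE, length(subfamilies)),
                         speciesTokens = .defaultSpeciesTokens,
                         groupToken = "gp_sali") {
  counters <- new.env(parent = emptyenv())
  vapply(seq_along(subfamilies), function(i) {
    sp <- unique(speciesSets[[i]])
    scope <- if (length(sp) >= 2L) groupToken
             else if (sp %in% names(speciesTokens)) speciesTokens[[sp]]
             else gsub("[^A-Za-z0-9]", "", sp)
    sub <- subfamilies[i]
    if (isTRUE(likeFlags[i]) && !grepl("-like$", sub))
      sub <- paste0(sub, "-like")
    key <- paste(families[i], scope, sep = "\r")
    n <- (if (is.null(counters[[key]])) 0L else counters[[key]]) + 1L
    counters[[key]] <- n
    paste0(sub, "_", scope, "_", n, "_")
  }, character(1))
}

#' Cluster neighborhood genes by mutual-coverage alignment
#'
#' All-against-all local alignment of proteins drawn from the 2-kbp
#' neighborhoods of regulator genes; an edge requires a Karlin-Altschul
#' E-value <= `evalueMax` and an aligned span covering >= `coverageMin`
#' of BOTH sequences. Clusters are the connected components.
#'
#' @param proteins data.frame with `protein_id`, `sequence` and
#'   optionally `product`.
#' @param evalueMax E-value threshold (default 1e-3).
#' @param coverageMin mutual coverage threshold (default 0.70).
#' @return list of clusters, each a list with `members` (protein ids)
#'   and `annotation_consensus` (most frequent product, or "").
#' @export
clusterContextGenes <- function(proteins, evalueMax = 1e-3,
                                coverageMin = 0.70) {
  n <- nrow(proteins)
  if (n == 0L) return(list())
  adj <- matrix(FALSE, n, n)
  dbLen <- sum(nchar(proteins$sequence))
  for (i in seq_len(max(0L, n - 1L))) for (j in (i + 1L):n) {
    a <- proteins$sequence[i]; b <- proteins$sequence[j]
    aln <- .localAlign(a, b)
    s <- Biostrings::score(aln)
    if (s <= 0) next
    ev <- .KA_K * nchar(a) * nchar(b) * exp(-.KA_LAMBDA * s)
    wa <- Biostrings::width(Biostrings::pattern(aln))
    wb <- Biostrings::width(Biostrings::subject(aln))
    if (ev <= evalueMax && wa >= coverageMin * nchar(a) &&
        wb >= coverageMin * nchar(b))
      adj[i, j] <- adj[j, i] <- TRUE
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  lapply(unname(split(seq_len(n), comp)), function(idx) {
    prod <- if ("product" %in% names(proteins))
      proteins$product[idx] else character(0)
    prod <- prod[!is.na(prod) & nzchar(prod)]
    cons <- if (length(prod)) names(sort(table(prod), decreasing = TRUE))[1]
            else ""
    list(members = proteins$protein_id[idx], annotation_consensus = cons)
  })
}

#' Proteins in the 2-kbp neighborhood of a regulator gene
#'
#' Any CDS overlapping the window extending `window` bp on both sides
#' of the regulator feature (0-based half-open arithmetic, clamped at
#' the contig start).
#'
#' @param genome a [GenomeRecord].
#' @param regulatorFeatureId `feature_id` of the regulator CDS.
#' @param window neighborhood size in bp (default 2000).
#' @return proteome-style data.frame of the neighborhood CDSs
#'   (regulator excluded).
#' @export
neighborhoodProteins <- function(genome, regulatorFeatureId, window = 2000L) {
  prot <- extractProteome(genome)
  reg <- prot[prot$protein_id == regulatorFeatureId, , drop = FALSE]
  if (nrow(reg) != 1L)
    stop("regulator feature not found: ", regulatorFeatureId, call. = FALSE)
  lo <- max(0L, reg$start - window)
  hi <- reg$end + window
  keep <- prot$contig_id == reg$contig_id &
    prot$start < hi & prot$end > lo &
    prot$protein_id != regulatorFeatureId
  prot[keep, , drop = FALSE]
}

#' Full regulator-cluster table
#'
#' Composes clustering, family transfer and naming into the cluster
#' table: one row per cluster with id, family, subfamily, best bait,
#' identity/coverage to it, member count and species set.
#'
#' @param clusters list of member-id vectors from [clusterHits()].
#' @param hits filtered hits data.frame (for representative sequences;
#'   the lexicographically smallest member is the representative).
#' @param baits bait data.frame (see [readBaitAlignment()]).
#' @param genomeSpecies named character vector mapping `genome_id` to
#'   species label.
#' @param aipNames optional named character vector mapping cluster index
#'   to an AIP precursor name to splice into the identifier.
#' @return data.frame with one row per cluster plus a `members` list
#'   column.
#' @export
regulatorClusterTable <- function(clusters, hits, baits, genomeSpecies,
                                  aipNames = NULL) {
  reps <- vapply(clusters, function(m) sort(m)[1], character(1))
  fam <- lapply(reps, function(r) {
    seq <- .degap(hits$aligned_row[hits$protein_id == r][1])
    assignFamily(seq, baits)
  })
  speciesSets <- lapply(clusters, function(m) {
    gid <- hits$genome_id[match(m, hits$protein_id)]
    unique(unname(genomeSpecies[gid]))
  })
  subf <- vapply(fam, function(f)
    ifelse(is.na(f$subfamily), "unclassified", f$subfamily), character(1))
  if (!is.null(aipNames)) {
    idx <- as.integer(names(aipNames))
    subf[idx] <- paste0(aipNames, "/", sub("^[^/]*/", "", subf[idx]))
  }
  ids <- nameClusters(subf, vapply(fam, function(f)
    ifelse(is.na(f$family), "unclassified", f$family), character(1)),
    speciesSets, vapply(fam, function(f) isTRUE(f$like_flag), logical(1)))
  data.frame(
    cluster_id = ids,
    family = vapply(fam, function(f) f$family, character(1)),
    subfamily = subf,
    best_bait = vapply(fam, function(f) f$best_bait, character(1)),
    bait_identity_pct = vapply(fam, function(f) f$identity_pct, numeric(1)),
    bait_coverage_pct = vapply(fam, function(f) f$coverage_pct, numeric(1)),
    like_flag = vapply(fam, function(f) isTRUE(f$like_flag), logical(1)),
    n_members = lengths(clusters),
    species_set = vapply(speciesSets, paste, character(1), collapse = ";"),
    members = I(clusters),
    stringsAsFactors = FALSE)
}
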