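## Strain x cluster presence/absence repertoires: prevalence, profile
## diversity (Hamming-distance statistics), hierarchical ordering for
## heatmap display, and neighbor-joining trees with midpoint rooting.

#' @importFrom ape nj as.phylo write.tree read.tree cophenetic.phylo
#' @importFrom phangorn midpoint
NULL

#' Build the strains x clusters presence/absence matrix
#'
#' Cell (strain, cluster) is 1 iff the strain has at least one hit
#' assigned to the cluster; paralogous hits do not count twice.
#'
#' @param memberships data.frame with columns `hit_id`, `genome_id`,
#'   `cluster_id` (one row per hit).
#' @param strains data.frame with columns `genome_id`, `species`
#'   (strains without hits give all-zero rows).
#' @return a [RepertoireMatrix].
#' @export
buildRepertoireMatrix <- function(memberships, strains) {
  clusterIds <- unique(memberships$cluster_id)
  m <- matrix(0L, nrow(strains), length(clusterIds),
              dimnames = list(strains$genome_id, clusterIds))
  if (nrow(memberships)) {
    idx <- cbind(match(memberships$genome_id, strains$genome_id),
                 match(memberships$cluster_id, clusterIds))
    idx <- idx[!is.na(idx[, 1]), , drop = FALSE]
    m[idx] <- 1L
  }
  methods::new("RepertoireMatrix", presence = m,
               speciesLabels = strains$species)
}

#' Per-cluster prevalence within a species
#'
#' Fraction of the species' strains carrying each cluster; invariant to
#' strain ordering.
#'
#' @param mat a [RepertoireMatrix].
#' @param species species label (must be present).
#' @return named numeric vector, cluster id -> fraction in `[0, 1]`.
#' @export
clusterPrevalence <- function(mat, species) {
  rows <- mat@speciesLabels == species
  if (!any(rows)) stop("no strains with species '", species, "'",
                       call. = FALSE)
  colMeans(mat@presence[rows, , drop = FALSE])
}

#' Profile-diversity statistics of a species
#'
#' The profile of a strain is its binary presence/absence vector over
#' the clusters; the distance between two profiles is the Hamming count
#' of differing clusters. Reports the number of distinct profiles, the
#' fraction of strains in the `topK` most abundant profiles, the mean
#' pairwise distance over all unordered distinct strain pairs, and the
#' per-cluster prevalence.
#'
#' @param mat a [RepertoireMatrix].
#' @param species species label with >= 2 strains.
#' @param topK number of top profiles for the abundance fraction (4).
#' @param withReplacement if `TRUE`, the mean is over ordered pairs with
#'   replacement, differing by a factor (n-1)/n.
#' @return list with `n_strains`, `n_distinct_profiles`,
#'   `top_k_profile_fraction`, `mean_pairwise_difference`,
#'   `per_cluster_prevalence`.
#' @export
profileStats <- function(mat, species, topK = 4L, withReplacement = FALSE) {
  rows <- mat@presence[mat@speciesLabels == species, , drop = FALSE]
  n <- nrow(rows)
  if (n < 2L) stop("need >= 2 strains of species '", species, "'",
                   call. = FALSE)
  keys <- apply(rows, 1, paste, collapse = "")
  tab <- sort(table(keys), decreasing = TRUE)
  d <- as.matrix(stats::dist(rows, method = "manhattan"))
  meanPair <- sum(d[upper.tri(d)]) / (n * (n - 1) / 2)
  if (withReplacement) meanPair <- meanPair * (n - 1) / n
  list(n_strains = n,
       n_distinct_profiles = length(tab),
       top_k_profile_fraction = sum(tab[seq_len(min(topK, length(tab)))]) / n,
       mean_pairwise_difference = meanPair,
       per_cluster_prevalence = colMeans(rows))
}

#' Hierarchical ordering of strains by profile distance
#'
#' Average-linkage agglomeration on Hamming distances between profiles,
#' with deterministic tie-breaking via the strain ordering of the
#' matrix. Returns the leaf ordering used to arrange heatmap rows and
#' the dendrogram as a tree.
#'
#' @param mat a [RepertoireMatrix].
#' @return list with `order` (strain ids in display order), `hclust`
#'   (the hclust object) and `newick` (dendrogram serialized as a
#'   Newick string).
#' @export
hierarchicalOrder <- function(mat) {
  p <- mat@presence[order(rownames(mat@presence)), , drop = FALSE]
  if (nrow(p) < 2L) stop("need >= 2 strains", call. = FALSE)
  d <- stats::dist(p, method = "manhattan")
  hc <- stats::hclust(d, method = "average")
  phy <- ape::as.phylo(hc)
  list(order = hc$labels[hc$order], hclust = hc,
       newick = ape::write.tree(phy))
}

#' Neighbor-joining tree from a distance matrix
#'
#' @param distanceMatrix symmetric non-negative matrix with zero
#'   diagonal and labelled rows.
#' @return an `ape` `phylo` object (unrooted), negative NJ branch
#'   lengths clamped at 0.
#' @export
njTree <- function(distanceMatrix) {
  stopifnot(isSymmetric(unname(as.matrix(distanceMatrix))),
            all(diag(as.matrix(distanceMatrix)) == 0))
  tr <- ape::nj(stats::as.dist(distanceMatrix))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Midpoint rooting
#'
#' Places the root halfway along the longest leaf-to-leaf path, so the
#' two farthest leaves are equidistant from the root.
#'
#' @param tree a `phylo` object.
#' @return the midpoint-rooted `phylo` object.
#' @export
midpointRoot <- function(tree) {
  phangorn::midpoint(tree)
}

#' Serialize / parse trees as Newick
#'
#' @param tree a `phylo` object.
#' @return `treeToNewick`: Newick string; `newickToTree`: `phylo`.
#' @export
treeToNewick <- function(tree) ape::write.tree(tree)

#' @rdname treeToNewick
#' @param newick Newick string.
#' @export
newickToTree <- function(newick) ape::read.tree(text = newick)
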