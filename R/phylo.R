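# Phylogenetics stage: maximum-likelihood distances, neighbor joining,
# NeighborNet split networks, Dayhoff + gamma ML tree search with NNI,
# nonparametric bootstrap and monophyly queries. The numerical engines are
# phangorn/ape; this file defines the pipeline's surface, input checking and
# degenerate-case policy on top of them.

.alignToPhyDat <- function(aln) {
  m <- siteMatrix(aln)
  m[m == "?"] <- "X"       # ambiguous/all-ones state for the likelihood
  phangorn::phyDat(m, type = "AA")
}

.checkSharedSites <- function(aln) {
  obs <- siteMatrix(aln) %in% .AA_ORDER
  dim(obs) <- dim(siteMatrix(aln))
  shared <- obs %*% t(obs)
  taxa <- alignmentTaxa(aln)
  bad <- which(shared == 0 & upper.tri(shared), arr.ind = TRUE)
  if (nrow(bad))
    stop("no shared observed sites between ", taxa[bad[1, 1]], " and ",
         taxa[bad[1, 2]])
  invisible(TRUE)
}

#' Maximum-likelihood pairwise distances under the Dayhoff model
#'
#' Two-sequence ML distances (expected substitutions/site) for every taxon
#' pair, with unobserved sites contributing flat partial likelihoods
#' (equivalent to pairwise deletion). Saturated estimates are capped at
#' \code{maxDist} with a warning.
#'
#' @param aln A \linkS4class{ConcatAlignment}.
#' @param maxDist Saturation cap in substitutions/site (default 5).
#' @return A \code{dist} object.
#' @export
mlDistances <- function(aln, maxDist = 5) {
  .checkSharedSites(aln)
  d <- phangorn::dist.ml(.alignToPhyDat(aln), model = "Dayhoff")
  if (any(d > maxDist)) {
    warning("capping ", sum(d > maxDist), " saturated distance(s) at ",
            maxDist)
    d[d > maxDist] <- maxDist
  }
  d
}

#' Maximum-likelihood distance between two sequences
#'
#' @param a,b Sequences (strings; '?' marks unobserved sites).
#' @param maxDist Saturation cap (default 5).
#' @return Distance in expected substitutions/site.
#' @export
pairwiseDistance <- function(a, b, maxDist = 5) {
  stopifnot(nchar(a) == nchar(b))
  m <- rbind(A = strsplit(a, "")[[1]], B = strsplit(b, "")[[1]])
  aln <- new("ConcatAlignment", seqs = m, boundary = ncol(m))
  as.numeric(mlDistances(aln, maxDist))
}

#' Neighbor-joining tree
#'
#' Standard Saitou-Nei agglomeration (exact on additive matrices). Negative
#' branch-length estimates are clamped to zero with the deficit transferred
#' to the adjacent branch, preserving path lengths through the node.
#'
#' @param d A \code{dist} object or symmetric matrix with zero diagonal.
#' @return Unrooted \code{phylo} tree.
#' @export
njTree <- function(d) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-8))
    stop("distance matrix must be symmetric")
  tree <- ape::nj(stats::as.dist(m))
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    child <- tree$edge[e, 2L]
    adj <- which(tree$edge[, 1L] == child)
    if (length(adj)) tree$edge.length[adj] <-
        tree$edge.length[adj] + tree$edge.length[e]
    tree$edge.length[e] <- 0
  }
  tree
}

#' NeighborNet split network
#'
#' Agglomerates the distance matrix into a circular taxon ordering and
#' estimates non-negative split weights over the circular split space;
#' splits below the weight threshold are dropped. Pairs of incompatible
#' retained splits display as boxes, visualising conflicting signal.
#'
#' @param d A \code{dist} object or symmetric matrix (>= 4 taxa).
#' @param threshold Minimum retained split weight (default 1e-6).
#' @return A \linkS4class{SplitSystem}.
#' @export
splitNetwork <- function(d, threshold = 1e-6) {
  m <- as.matrix(d)
  if (nrow(m) < 4L) stop("NeighborNet requires >= 4 taxa")
  nn <- phangorn::neighborNet(stats::as.dist(m))
  sp <- phangorn::as.splits(nn)
  w <- attr(sp, "weights")
  labels <- attr(sp, "labels")
  cycle <- attr(sp, "cycle")
  if (is.null(cycle)) cycle <- seq_along(labels)
  keep <- which(w >= threshold)
  new("SplitSystem",
      splits = lapply(unclass(sp)[keep], as.integer),
      weights = as.numeric(w[keep]),
      cycle = as.integer(cycle), taxa = labels)
}

#' Log-likelihood of an alignment on a tree
#'
#' Felsenstein pruning under the Dayhoff model with discrete-gamma rate
#' heterogeneity (equal-probability category means) and an optional fixed
#' proportion of invariable sites. '?' and '-' contribute flat partial
#' likelihoods.
#'
#' @param aln A \linkS4class{ConcatAlignment}.
#' @param tree \code{phylo} whose tip labels equal the alignment taxa;
#'   branch lengths >= 0.
#' @param k Number of gamma categories (default 4).
#' @param shape Gamma shape; ignored when \code{k = 1}.
#' @param pInv Fixed proportion of invariable sites (default 0).
#' @return Log-likelihood (numeric scalar).
#' @export
treeLogLik <- function(aln, tree, k = 4, shape = 1, pInv = 0) {
  if (!setequal(tree$tip.label, alignmentTaxa(aln)))
    stop("tree leaves must equal alignment taxa")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  fit <- phangorn::pml(tree, .alignToPhyDat(aln), model = "Dayhoff",
                       k = k, shape = shape, inv = pInv)
  as.numeric(fit$logLik)
}

#' Maximum-likelihood tree search
#'
#' Neighbor-joining start from ML distances, then alternating branch-length
#' optimisation and NNI hill-climbing under Dayhoff + gamma(k) until no
#' improving move remains. Deterministic given the data and tie rules.
#'
#' @param aln A \linkS4class{ConcatAlignment} (>= 3 taxa).
#' @param k Gamma categories (default 4).
#' @param shape Initial gamma shape (default 1).
#' @param optGamma Optimise the gamma shape (default TRUE).
#' @param pInv Fixed invariable-site proportion (default 0, never
#'   optimised).
#' @param rearrange Perform NNI topology search (default TRUE).
#' @return List with \code{tree} (unrooted \code{phylo}), \code{logLik},
#'   \code{shape} and \code{fit} (the underlying \code{pml} object).
#' @export
mlTree <- function(aln, k = 4, shape = 1, optGamma = TRUE, pInv = 0,
                   rearrange = TRUE) {
  start <- njTree(mlDistances(aln))
  start$edge.length[start$edge.length < 1e-8] <- 1e-8
  fit <- phangorn::pml(start, .alignToPhyDat(aln), model = "Dayhoff",
                       k = k, shape = shape, inv = pInv)
  fit <- phangorn::optim.pml(fit, optNni = rearrange, optEdge = TRUE,
                             optGamma = optGamma, optInv = FALSE,
                             model = "Dayhoff",
                             control = phangorn::pml.control(trace = 0))
  list(tree = fit$tree, logLik = as.numeric(fit$logLik),
       shape = fit$shape, fit = fit)
}

#' Nonparametric bootstrap supports
#'
#' Resamples alignment columns with replacement, reruns the ML search per
#' replicate, and writes the percentage of replicates containing each
#' original-tree bipartition onto the tree's node labels.
#'
#' @param mlFit Result of \code{\link{mlTree}}.
#' @param nReplicates Bootstrap replicates (default 100; the published
#'   analysis used 10,000 — desk-scale runs use fewer).
#' @param seed Integer seed (same seed, same supports).
#' @param rearrange NNI search within replicates (default TRUE).
#' @return The ML tree with node labels set to supports in [0, 100], and the
#'   replicate trees attached as attribute \code{"replicates"}. When the
#'   alignment has no parsimony-informative site the supports are
#'   meaningless; they are still reported, with a warning and attribute
#'   \code{"degenerate"} set to TRUE.
#' @export
bootstrapSupport <- function(mlFit, nReplicates = 100, seed = 1,
                             rearrange = TRUE) {
  stopifnot(nReplicates >= 1)
  dat <- as.character(mlFit$fit$data)
  informative <- any(apply(dat, 2L, function(col) {
    tab <- table(col[col %in% .AA_ORDER])
    sum(tab >= 2L) >= 2L
  }))
  if (!informative)
    warning("alignment has no parsimony-informative site; ",
            "bootstrap supports are degenerate")
  # bootstrap.pml inspects optNni before evaluation, so pass a literal
  bs <- .withSeed(seed, if (rearrange)
    phangorn::bootstrap.pml(mlFit$fit, bs = nReplicates, optNni = TRUE,
                            control = phangorn::pml.control(trace = 0))
  else
    phangorn::bootstrap.pml(mlFit$fit, bs = nReplicates, optNni = FALSE,
                            control = phangorn::pml.control(trace = 0)))
  tr <- phangorn::plotBS(mlFit$tree, bs, type = "none")
  sup <- as.numeric(tr$node.label)
  if (all(is.na(sup) | sup <= 1)) sup <- sup * 100   # proportions -> %
  tr$node.label <- sup
  attr(tr, "replicates") <- bs
  attr(tr, "degenerate") <- !informative
  tr
}

#' Monophyly query on a rooted view of a tree
#'
#' Roots the tree at the outgroup and reports whether the taxon subset forms
#' exactly a clade, together with the smallest clade containing it.
#'
#' @param tree \code{phylo} (node labels, if any, are treated as edge
#'   supports and preserved under rerooting).
#' @param taxa Character vector of tip labels.
#' @param outgroup Tip label used to root.
#' @return List with \code{monophyletic} (logical) and \code{clade}
#'   (tip labels of the smallest containing clade).
#' @export
checkMonophyly <- function(tree, taxa, outgroup) {
  unknown <- setdiff(c(taxa, outgroup), tree$tip.label)
  if (length(unknown))
    stop("unknown taxa: ", paste(unknown, collapse = ", "))
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
                      edgelabel = TRUE)
  mono <- ape::is.monophyletic(rooted, taxa)
  clade <- if (length(taxa) == 1L) taxa else {
    node <- ape::getMRCA(rooted, taxa)
    ape::extract.clade(rooted, node)$tip.label
  }
  list(monophyletic = mono, clade = clade)
}

#' Bootstrap support of a clade
#'
#' Reads the support value attached to the edge that separates the given
#' taxa from the rest, on a tree with supports as node labels.
#'
#' @inheritParams checkMonophyly
#' @return Support in [0, 100], or \code{NA} if the taxa are not
#'   monophyletic on this tree.
#' @export
cladeSupport <- function(tree, taxa, outgroup) {
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
                      edgelabel = TRUE)
  if (!ape::is.monophyletic(rooted, taxa)) return(NA_real_)
  node <- ape::getMRCA(rooted, taxa)
  as.numeric(rooted$node.label[node - length(rooted$tip.label)])
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param d \code{dist} object or symmetric matrix.
#' @param file Output path.
#' @export
writeDistPhylip <- function(d, file) {
  m <- as.matrix(d)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(formatC(rownames(m)[i], width = -10),
                     paste(sprintf("%.6f", m[i, ]), collapse = " ")), con)
  invisible(file)
}

#' Write a split system as a SplitsTree-compatible NEXUS SPLITS block
#'
#' @param ss A \linkS4class{SplitSystem}.
#' @param file Output path.
#' @export
writeSplitsNexus <- function(ss, file) {
  sp <- structure(ss@splits, labels = ss@taxa, weights = ss@weights,
                  cycle = ss@cycle, class = "splits")
  phangorn::write.nexus.splits(sp, file = file)
  invisible(file)
}
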