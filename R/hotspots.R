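## Euclidean geometry on the bead model: pairwise distances, hierarchical
## hot-spot detection, shuffle/Wilcoxon significance, radial positioning,
## cross-model projection, replicate stability, expression-radius correlation.

#' Pairwise Euclidean distances among beads
#'
#' Straight-line 3D distances in model units. With
#' \code{interChromOnly = TRUE}, same-chromosome pairs are masked (set to
#' \code{NA}) so that runs of contiguous domains on one chromosome do not
#' deflate the distance distribution.
#'
#' @param model a \code{\link{BeadModel}}.
#' @param ids bead ids to include (default: all).
#' @param interChromOnly mask same-chromosome pairs?
#' @return list of class \code{DistanceMatrix}: \code{ids}, \code{chrom}
#'   (per bead), \code{d} (symmetric matrix, masked entries \code{NA}),
#'   \code{masked} (logical: any pair masked).
#' @export
pairwiseDistances <- function(model, ids = NULL, interChromOnly = FALSE) {
  stopifnot(is(model, "BeadModel"))
  all_ids <- beadIds(model)
  if (is.null(ids)) ids <- all_ids
  unknown <- setdiff(ids, all_ids)
  if (length(unknown))
    stop("unknown bead id(s): ", paste(head(unknown, 5), collapse = ", "))
  ids <- as.character(ids)
  coords <- beadCoords(model)[ids, , drop = FALSE]
  d <- as.matrix(dist(coords))
  dimnames(d) <- list(ids, ids)
  chrom <- as.character(seqnames(beads(model)))[match(ids, all_ids)]
  masked <- FALSE
  if (interChromOnly) {
    same <- outer(chrom, chrom, "==")
    diag(same) <- FALSE
    d[same] <- NA_real_
    masked <- any(same)
  }
  structure(list(ids = ids, chrom = chrom, d = d, masked = masked),
            class = "DistanceMatrix")
}

#' @export
print.DistanceMatrix <- function(x, ...) {
  cat("DistanceMatrix over", length(x$ids), "beads",
      if (x$masked) "(same-chromosome pairs masked)" else "", "\n")
  invisible(x)
}

#' Extract the unmasked pair distances from a DistanceMatrix
#' @param x a \code{DistanceMatrix}.
#' @return numeric vector of unique unordered pair distances (NA masked
#'   pairs dropped).
#' @export
pairDistances <- function(x) {
  d <- x$d[upper.tri(x$d)]
  d[!is.na(d)]
}

#' Distance of each bead to the nuclear centroid
#'
#' The model centroid is the origin, so this is the Euclidean norm of each
#' bead coordinate (its radial position).
#'
#' @param model a \code{\link{BeadModel}}.
#' @param ids bead ids (default: all).
#' @return named numeric vector, model units.
#' @export
centroidDistances <- function(model, ids = NULL) {
  stopifnot(is(model, "BeadModel"))
  if (is.null(ids)) ids <- beadIds(model)
  unknown <- setdiff(ids, beadIds(model))
  if (length(unknown))
    stop("unknown bead id(s): ", paste(head(unknown, 5), collapse = ", "))
  coords <- beadCoords(model)[as.character(ids), , drop = FALSE]
  sqrt(rowSums(coords^2))
}

## Mean silhouette width computed directly from a distance matrix.
meanSilhouette <- function(d, labels) {
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(d[i, own]) else 0
    bs <- vapply(setdiff(unique(labels), labels[i]),
                 function(cl) mean(d[i, labels == cl]), numeric(1))
    if (!length(bs)) { s[i] <- 0; next }
    b <- min(bs)
    denom <- max(a, b)
    s[i] <- if (denom > 0) (b - a) / denom else 0
  }
  mean(s)
}

#' Detect Euclidean hot spots by hierarchical clustering
#'
#' Agglomerative clustering of the bead distance matrix; the tree is cut at
#' \code{k} clusters and clusters smaller than \code{minSize} are discarded.
#' With \code{k = "auto"}, k maximizes the mean silhouette width over
#' k in [2, min(15, floor(n/3))]. If all pairwise distances are zero
#' (degenerate coincident beads) a single cluster is returned.
#'
#' @param dmat \code{DistanceMatrix} from \code{\link{pairwiseDistances}}
#'   (must be unmasked: clustering needs a complete matrix).
#' @param linkage "complete" (default) or "average".
#' @param k number of clusters, or "auto".
#' @param minSize smallest reported cluster (default 3).
#' @return list of class \code{HotSpotSet}: \code{labels} (named integer),
#'   \code{hotspots} (list of \code{id}, \code{members},
#'   \code{mean_delta}, \code{distances}), \code{k}, \code{silhouette}.
#' @export
detectHotspots <- function(dmat, linkage = c("complete", "average"),
                           k = "auto", minSize = 3) {
  linkage <- match.arg(linkage)
  if (dmat$masked)
    stop("clustering requires a complete (unmasked) distance matrix")
  n <- length(dmat$ids)
  if (n < 2 * minSize)
    stop("need at least 2*minSize = ", 2 * minSize, " beads, got ", n)
  d <- dmat$d
  if (all(d[upper.tri(d)] == 0)) {
    labels <- setNames(rep(1L, n), dmat$ids)
    hs <- list(list(id = "EH1", members = dmat$ids, mean_delta = 0,
                    distances = rep(0, n * (n - 1) / 2)))
    return(structure(list(labels = labels, hotspots = hs, k = 1L,
                          silhouette = NA_real_), class = "HotSpotSet"))
  }
  tree <- hclust(as.dist(d), method = linkage)
  if (identical(k, "auto")) {
    kmax <- min(15L, n %/% 3L)
    ks <- seq(2L, max(2L, kmax))
    sil <- vapply(ks, function(kk) meanSilhouette(d, cutree(tree, kk)),
                  numeric(1))
    k <- ks[which.max(sil)]
    silBest <- max(sil)
  } else {
    k <- as.integer(k)
    silBest <- meanSilhouette(d, cutree(tree, k))
  }
  labels <- cutree(tree, k)
  names(labels) <- dmat$ids
  keep <- names(table(labels))[table(labels) >= minSize]
  hs <- lapply(seq_along(keep), function(ii) {
    cl <- as.integer(keep[ii])
    members <- dmat$ids[labels == cl]
    sub <- d[members, members, drop = FALSE]
    dd <- sub[upper.tri(sub)]
    list(id = paste0("EH", ii), members = members,
         mean_delta = mean(dd), distances = dd)
  })
  structure(list(labels = labels, hotspots = hs, k = k,
                 silhouette = silBest), class = "HotSpotSet")
}

#' @export
print.HotSpotSet <- function(x, ...) {
  cat("HotSpotSet:", length(x$hotspots), "hot spot(s) at k =", x$k, "\n")
  for (h in x$hotspots)
    cat(sprintf("  %s: %d beads, mean delta %.3f\n", h$id,
                length(h$members), h$mean_delta))
  invisible(x)
}

#' Empirical significance of a hot spot against random same-size draws
#'
#' Draws \code{nSamples} random bead sets of the hot spot's size (without
#' replacement) from the shared-domain pool and compares intra-set pairwise
#' distances. The headline empirical p is the add-one rank of the observed
#' mean distance among the null means (smaller = tighter). A one-sided
#' Wilcoxon rank-sum p (hot-spot distances vs pooled null distances) is also
#' reported, with a Shapiro normality check of the observed distances
#' recorded as the rationale for the nonparametric test.
#'
#' @param model a \code{\link{BeadModel}}.
#' @param members bead ids of the hot spot.
#' @param pool bead ids of the shared-domain space (must contain
#'   \code{members}).
#' @param nSamples number of random draws (>= 100).
#' @param seed RNG seed.
#' @return list: \code{p} (empirical, add-one), \code{p_wilcoxon},
#'   \code{shapiro_p}, \code{obs_mean}, \code{null_means}.
#' @export
hotspotSignificance <- function(model, members, pool, nSamples = 1000,
                                seed = 1) {
  if (nSamples < 100) stop("nSamples must be >= 100")
  if (!all(members %in% pool))
    stop("pool must contain all hot-spot members")
  m <- length(members)
  if (m < 2) stop("hot spot must have >= 2 members")
  if (setequal(members, pool)) {
    warning("hot spot equals the pool; p = 1 by construction")
    obs <- pairDistances(pairwiseDistances(model, members))
    return(list(p = 1, p_wilcoxon = 1, shapiro_p = NA_real_,
                obs_mean = mean(obs), null_means = numeric()))
  }
  coords <- beadCoords(model)
  obsD <- dist(coords[members, , drop = FALSE])
  obsMean <- mean(obsD)
  set.seed(seed)
  nullMeans <- numeric(nSamples)
  nullPool <- vector("list", min(nSamples, 200L))
  for (s in seq_len(nSamples)) {
    draw <- sample(pool, m)
    dd <- dist(coords[draw, , drop = FALSE])
    nullMeans[s] <- mean(dd)
    if (s <= length(nullPool)) nullPool[[s]] <- as.numeric(dd)
  }
  pEmp <- addOneP(sum(nullMeans <= obsMean), nSamples)
  nullD <- unlist(nullPool)
  pW <- suppressWarnings(
    wilcox.test(as.numeric(obsD), nullD, alternative = "less")$p.value)
  shp <- if (length(obsD) >= 3 && length(obsD) <= 5000 &&
             stats::var(as.numeric(obsD)) > 0)
    shapiro.test(as.numeric(obsD))$p.value else NA_real_
  list(p = pEmp, p_wilcoxon = pW, shapiro_p = shp, obs_mean = obsMean,
       null_means = nullMeans)
}

#' Project a hot spot onto another cell type's bead model
#'
#' Maps each hot-spot domain to every target-model bead overlapping it by at
#' least 1 bp, per haplotype (alleles handled separately), then computes
#' inter-chromosomal pairwise distances and centroid distances in the target
#' model. Domains with no overlapping target bead are recorded as unmapped.
#'
#' @param members source bead ids of the hot spot.
#' @param sourceDomains source segmentation \code{GRanges}.
#' @param targetModel target \code{\link{BeadModel}}.
#' @return list: \code{dist} (\code{DistanceMatrix}, inter-chromosomal),
#'   \code{centroid} (named numeric), \code{mapping} (data.frame
#'   source_bead -> target_bead), \code{unmapped} (character).
#' @export
crossModelProjection <- function(members, sourceDomains, targetModel) {
  src <- sourceDomains[match(members, sourceDomains$bead_id)]
  if (anyNA(match(members, sourceDomains$bead_id)))
    stop("hot-spot member(s) absent from source segmentation")
  tgt <- beads(targetModel)
  maps <- list()
  unmapped <- character()
  for (i in seq_along(src)) {
    sameHap <- tgt$haplotype == src$haplotype[i]
    hits <- which(sameHap & overlapsAny(tgt, src[i]))
    if (!length(hits)) {
      unmapped <- c(unmapped, members[i])
    } else {
      maps[[length(maps) + 1]] <-
        data.frame(source_bead = members[i],
                   target_bead = as.character(tgt$bead_id[hits]),
                   stringsAsFactors = FALSE)
    }
  }
  mapping <- if (length(maps)) do.call(rbind, maps)
             else data.frame(source_bead = character(),
                             target_bead = character())
  tgtIds <- unique(mapping$target_bead)
  if (!length(tgtIds)) {
    return(list(dist = NULL, centroid = numeric(), mapping = mapping,
                unmapped = unmapped))
  }
  list(dist = pairwiseDistances(targetModel, tgtIds, interChromOnly = TRUE),
       centroid = centroidDistances(targetModel, tgtIds),
       mapping = mapping, unmapped = unmapped)
}

#' Cluster-label stability across replicate models
#'
#' Clusters the same bead set in each replicate model (same segmentation,
#' independent embedding runs) and reports the mean pairwise adjusted Rand
#' index of the labelings plus, per cluster, the best-match Jaccard overlap
#' across replicate pairs.
#'
#' @param models list of \code{\link{BeadModel}} over the same bead set.
#' @param ids bead ids to cluster.
#' @param k number of clusters (fixed across replicates).
#' @param linkage linkage method.
#' @return list: \code{mean_ari}, \code{ari} (matrix), \code{jaccard}
#'   (mean best-match Jaccard per replicate pair).
#' @export
replicateStability <- function(models, ids, k, linkage = "complete") {
  if (length(models) < 2) stop("need >= 2 replicate models")
  for (m in models) {
    if (!all(ids %in% beadIds(m)))
      stop("mismatched bead sets across replicate models")
  }
  labelings <- lapply(models, function(m) {
    dm <- pairwiseDistances(m, ids)
    cutree(hclust(as.dist(dm$d), method = linkage), k)
  })
  np <- length(models)
  ari <- matrix(1, np, np)
  jac <- c()
  for (a in seq_len(np - 1)) {
    for (b in seq(a + 1, np)) {
      ari[a, b] <- ari[b, a] <-
        mclust::adjustedRandIndex(labelings[[a]], labelings[[b]])
      ja <- vapply(unique(labelings[[a]]), function(cl) {
        sa <- ids[labelings[[a]] == cl]
        max(vapply(unique(labelings[[b]]), function(cl2) {
          sb <- ids[labelings[[b]] == cl2]
          length(intersect(sa, sb)) / length(union(sa, sb))
        }, numeric(1)))
      }, numeric(1))
      jac <- c(jac, mean(ja))
    }
  }
  list(mean_ari = mean(ari[upper.tri(ari)]), ari = ari,
       jaccard = mean(jac))
}

#' Correlation of a per-domain value with radial position
#'
#' Pearson (default) or Spearman correlation of a per-bead quantity (e.g.
#' expression) against distance to the nuclear centroid; central positioning
#' of active domains shows up as a negative r.
#'
#' @param values numeric vector (per bead).
#' @param radii matching centroid distances (model units).
#' @param method "pearson" or "spearman".
#' @return list: \code{r}, \code{p}, \code{n}, \code{method}; \code{r} is
#'   \code{NA} with a note when either input has zero variance.
#' @export
expressionRadialCorrelation <- function(values, radii,
                                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  keep <- is.finite(values) & is.finite(radii)
  values <- values[keep]
  radii <- radii[keep]
  if (length(values) < 3) stop("need >= 3 paired values")
  if (sd(values) == 0 || sd(radii) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(values),
                method = method, note = "zero variance: correlation undefined"))
  ct <- cor.test(values, radii, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(values),
       method = method)
}
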