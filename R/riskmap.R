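## Intersection of two trait risk architectures with the domain segmentation:
## shared domains, linear-genome separation statistics, shuffle nulls and a
## cross-GWAS specificity scan.

haploidView <- function(domains) {
  if (!is.null(domains$haplotype) && any(domains$haplotype != "unphased"))
    domains[domains$haplotype == "A"]
  else domains
}

assertSameAssembly <- function(domains, features) {
  if (length(features) == 0) return(invisible(TRUE))
  extra <- setdiff(unique(as.character(seqnames(features))),
                   unique(as.character(seqnames(domains))))
  if (length(extra))
    stop("assembly mismatch: feature chromosome(s) absent from segmentation: ",
         paste(extra, collapse = ", "))
  invisible(TRUE)
}

#' Annotate domains with per-trait risk content
#'
#' Counts, per haploid genomic domain, the trait-A index SNPs it contains
#' (half-open containment: a SNP at position p counts for [s, e) iff
#' s <= p < e) and the trait-B risk loci it overlaps by at least 1 bp. A
#' locus spanning several domains counts for every overlapped domain
#' (bedtools-intersect semantics). Flags each domain A_only / B_only /
#' shared / none; shared means >= 1 SNP and >= 1 locus.
#'
#' @param domains segmentation \code{GRanges} (diploid or haploid).
#' @param snps trait-A index SNPs, width-1 \code{GRanges}.
#' @param loci trait-B risk loci, \code{GRanges}.
#' @return data.frame with columns \code{domain_id}, \code{n_snps},
#'   \code{n_loci}, \code{flag}.
#' @export
annotateDomains <- function(domains, snps, loci) {
  assertSameAssembly(domains, snps)
  assertSameAssembly(domains, loci)
  hap <- haploidView(domains)
  ns <- countOverlaps(hap, snps)
  nl <- countOverlaps(hap, loci)
  flag <- ifelse(ns >= 1 & nl >= 1, "shared",
                 ifelse(ns >= 1, "A_only", ifelse(nl >= 1, "B_only", "none")))
  data.frame(domain_id = hap$domain_id, n_snps = ns, n_loci = nl,
             flag = flag, stringsAsFactors = FALSE)
}

#' Shared-risk domains, haploid or diploid
#'
#' Haploid mode returns the genomic domain ids carrying both traits; diploid
#' mode expands them to bead-level ids (one per haplotype), dropping beads
#' absent from the model when one is supplied (mirroring domains discarded
#' from an embedding run).
#'
#' @param annotation result of \code{\link{annotateDomains}}.
#' @param mode "haploid" or "diploid".
#' @param domains diploid segmentation (needed for diploid mode).
#' @param model optional \code{\link{BeadModel}}: beads missing from it are
#'   dropped in diploid mode.
#' @return character vector of domain ids (haploid) or bead ids (diploid).
#' @export
sharedDomains <- function(annotation, mode = c("haploid", "diploid"),
                          domains = NULL, model = NULL) {
  mode <- match.arg(mode)
  sharedIds <- annotation$domain_id[annotation$flag == "shared"]
  if (mode == "haploid") return(sharedIds)
  if (is.null(domains))
    stop("diploid mode needs the diploid segmentation")
  beadIds <- domains$bead_id[domains$domain_id %in% sharedIds]
  if (!is.null(model)) beadIds <- intersect(beadIds, beadIds(model))
  as.character(beadIds)
}

#' Count risk loci harboring at least one index SNP
#'
#' @param loci risk-locus \code{GRanges}.
#' @param snps index-SNP \code{GRanges} (width 1).
#' @return integer: number of loci containing >= 1 SNP.
#' @export
snpInLocusCount <- function(loci, snps) {
  if (length(loci) == 0 || length(snps) == 0) return(0L)
  sum(countOverlaps(loci, snps) >= 1)
}

separationStats <- function(d, threshold = NULL) {
  finite <- d[is.finite(d)]
  out <- list(distances = d, n = length(d),
              mean = if (length(finite)) mean(finite) else NA_real_,
              sd = if (length(finite) > 1) sd(finite) else NA_real_,
              min = if (length(finite)) min(finite) else NA_real_,
              max = if (length(finite)) max(finite) else NA_real_)
  if (!is.null(threshold)) {
    out$threshold <- threshold
    out$fraction_beyond <- if (length(d)) mean(d > threshold) else NA_real_
  }
  class(out) <- "SeparationStats"
  out
}

#' @export
print.SeparationStats <- function(x, ...) {
  cat(sprintf("SeparationStats: n=%d, mean=%.4g, sd=%.4g, min=%.4g, max=%.4g\n",
              x$n, x$mean, x$sd, x$min, x$max))
  if (!is.null(x$threshold))
    cat(sprintf("  fraction beyond %g bp: %.3f\n", x$threshold,
                x$fraction_beyond))
  invisible(x)
}

#' Distance from each risk locus to the nearest index SNP
#'
#' Per locus: 0 if a SNP lies inside it, otherwise the gap (bp) between the
#' nearest same-chromosome SNP and the closest locus boundary. Loci on
#' chromosomes with no SNP at all get an infinite distance and count toward
#' the beyond-threshold fraction.
#'
#' @param loci risk-locus \code{GRanges}.
#' @param snps index-SNP \code{GRanges}.
#' @param threshold bp threshold for the "separated by more than" fraction
#'   (default 1 Mb).
#' @return A \code{SeparationStats} list (distances, mean, sd, min, max,
#'   fraction_beyond).
#' @export
nearestFeatureSeparation <- function(loci, snps, threshold = 1e6) {
  if (length(loci) == 0) return(separationStats(numeric(), threshold))
  d <- rep(Inf, length(loci))
  if (length(snps)) {
    hits <- distanceToNearest(loci, snps)
    d[queryHits(hits)] <- as.numeric(mcols(hits)$distance)
  }
  separationStats(d, threshold)
}

#' Consecutive-neighbor separation within one risk set
#'
#' Elements are sorted per chromosome and distances taken between consecutive
#' elements: midpoint-to-midpoint for interval loci, position-to-position for
#' SNPs. Statistics are pooled over chromosomes; chromosomes with a single
#' element contribute no distance.
#'
#' @param elements \code{GRanges} (SNPs or loci).
#' @return A \code{SeparationStats} list; empty (n = 0) when no chromosome
#'   has two elements.
#' @export
intraSetSeparation <- function(elements) {
  if (length(elements) < 2) return(separationStats(numeric()))
  mid <- (start(elements) + end(elements)) / 2
  ch <- as.character(seqnames(elements))
  d <- unlist(lapply(split(mid, ch), function(m) {
    if (length(m) < 2) return(numeric())
    diff(sort(m))
  }), use.names = FALSE)
  separationStats(d)
}

addOneP <- function(k, nPerm) (1 + k) / (1 + nPerm)

#' Shuffle test for the number of shared-risk domains
#'
#' Each permutation reassigns every SNP and every locus to a uniformly random
#' haploid domain (per-trait counts preserved) and recounts domains holding
#' both. The empirical two-sided p doubles the smaller add-one tail, capped
#' at 1.
#'
#' @param domains segmentation \code{GRanges}.
#' @param snps,loci risk sets.
#' @param nPerm number of permutations (>= 1).
#' @param seed RNG seed.
#' @return list with \code{observed}, \code{null} (integer vector),
#'   \code{p_two_sided}, \code{p_lower}, \code{p_upper}, \code{null_mean}.
#' @export
sharedCountShuffleTest <- function(domains, snps, loci, nPerm = 1000,
                                   seed = 1) {
  if (nPerm < 1) stop("nPerm must be >= 1")
  ann <- annotateDomains(domains, snps, loci)
  observed <- sum(ann$flag == "shared")
  nd <- nrow(ann)
  nA <- length(snps)
  nB <- length(loci)
  set.seed(seed)
  null <- vapply(seq_len(nPerm), function(i) {
    a <- unique.default(sample.int(nd, nA, replace = TRUE))
    b <- unique.default(sample.int(nd, nB, replace = TRUE))
    length(intersect(a, b))
  }, integer(1))
  pLow <- addOneP(sum(null <= observed), nPerm)
  pUp <- addOneP(sum(null >= observed), nPerm)
  list(observed = observed, null = null, null_mean = mean(null),
       p_lower = pLow, p_upper = pUp,
       p_two_sided = min(1, 2 * min(pLow, pUp)))
}

#' Cross-GWAS specificity scan over hot-spot domains
#'
#' For each feature set (a trait's SNPs), counts SNPs falling in the given
#' hot-spot domains and compares against a null in which SNPs are reassigned
#' to uniformly random domains. Output is ranked by enrichment
#' (observed / null mean).
#'
#' @param hotspotDomainIds character vector of (haploid) domain ids defining
#'   the hot-spot space.
#' @param featureSets named list of SNP \code{GRanges}, one per trait.
#' @param domains segmentation \code{GRanges}.
#' @param nPerm permutations per trait.
#' @param seed RNG seed.
#' @return data.frame (one row per trait, ranked): trait, observed,
#'   null_mean, enrichment, p.
#' @export
gwasSpecificityScan <- function(hotspotDomainIds, featureSets, domains,
                                nPerm = 1000, seed = 1) {
  if (!length(featureSets)) stop("need at least one feature set")
  hap <- haploidView(domains)
  inHot <- hap$domain_id %in% hotspotDomainIds
  k <- sum(inHot)
  nd <- length(hap)
  hot <- hap[inHot]
  set.seed(seed)
  rows <- lapply(seq_along(featureSets), function(fi) {
    snps <- featureSets[[fi]]
    nSnp <- length(snps)
    obs <- if (nSnp) sum(overlapsAny(snps, hot)) else 0L
    null <- vapply(seq_len(nPerm), function(i) {
      sum(sample.int(nd, nSnp, replace = TRUE) <= k)
    }, integer(1))
    nm <- mean(null)
    data.frame(trait = names(featureSets)[fi] %||% paste0("set", fi),
               observed = obs, null_mean = nm,
               enrichment = if (nm > 0) obs / nm else NA_real_,
               p = addOneP(sum(null >= obs), nPerm),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$enrichment, out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
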