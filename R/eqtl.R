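## Permutation test for enrichment of significant cis-eQTLs in cross-disorder
## contact bins, with a multi-catalog (tissue) scan and a clump-filter helper.

eqtlGRanges <- function(eqtls) {
  if (!nrow(eqtls)) return(GRanges())
  GRanges(eqtls$chrom, IRanges(eqtls$pos + 1L, width = 1L))
}

#' Count significant eQTLs overlapping target bins
#'
#' Unique eQTL coordinates (deduplicated on chrom + position) with
#' \code{fdr < fdrCut} falling inside the target bins; positions are
#' 0-based, bins half-open, so a position equal to a bin's end coordinate
#' does not count.
#'
#' @param eqtls eQTL data.frame (chrom, pos, gene, fdr).
#' @param targetBins \code{GRanges} of target intervals.
#' @param fdrCut significance cut, strict (default 1e-8).
#' @return integer overlap count.
#' @export
overlapCount <- function(eqtls, targetBins, fdrCut = 1e-8) {
  if (!nrow(eqtls) || !length(targetBins)) return(0L)
  sig <- eqtls[eqtls$fdr < fdrCut, , drop = FALSE]
  sig <- sig[!duplicated(paste(sig$chrom, sig$pos)), , drop = FALSE]
  if (!nrow(sig)) return(0L)
  sum(overlapsAny(eqtlGRanges(sig), targetBins))
}

#' Permutation enrichment of eQTLs in target bins
#'
#' The randomization unit is the bin: each permutation draws
#' \code{length(targetBins)} bins uniformly without replacement from the
#' background set and recomputes the overlap count. The empirical p uses the
#' add-one convention, p = (1 + #\{null >= observed\}) / (1 + nPerm), so its
#' floor is 1/(nPerm + 1). A chromosome-matched resampling mode preserves
#' the per-chromosome composition of the target set.
#'
#' @param eqtls eQTL data.frame.
#' @param targetBins \code{GRanges}: the tested bins (must be a subset of
#'   the background).
#' @param backgroundBins \code{GRanges}: the background bin universe.
#' @param nPerm number of permutations (default 10000).
#' @param seed RNG seed.
#' @param fdrCut eQTL significance cut (default 1e-8).
#' @param chromMatched preserve per-chromosome bin counts when resampling?
#' @return list of class \code{EnrichmentResult}: observed, null_mean,
#'   null_sd, quantiles, p, n_perm, background description.
#' @export
permutationEnrichment <- function(eqtls, targetBins, backgroundBins,
                                  nPerm = 10000, seed = 1, fdrCut = 1e-8,
                                  chromMatched = FALSE) {
  if (nPerm < 1) stop("nPerm must be >= 1")
  nT <- length(targetBins)
  nB <- length(backgroundBins)
  if (nB < nT) stop("background smaller than target set")
  ov <- findOverlaps(targetBins, backgroundBins, type = "equal")
  if (length(unique(queryHits(ov))) < nT)
    stop("target bins must be a subset of the background bins")
  # precompute per-background-bin overlap counts once; a permutation is then
  # a subset sum, which keeps 10^4 permutations cheap
  sig <- eqtls[eqtls$fdr < fdrCut, , drop = FALSE]
  sig <- sig[!duplicated(paste(sig$chrom, sig$pos)), , drop = FALSE]
  perBin <- countOverlaps(backgroundBins, eqtlGRanges(sig))
  observed <- overlapCount(eqtls, targetBins, fdrCut)
  set.seed(seed)
  if (chromMatched) {
    chT <- as.character(seqnames(targetBins))
    chB <- as.character(seqnames(backgroundBins))
    byChrom <- split(seq_len(nB), chB)
    need <- table(chT)
    if (any(!names(need) %in% names(byChrom)))
      stop("target chromosome absent from background")
    null <- vapply(seq_len(nPerm), function(s) {
      idx <- unlist(lapply(names(need), function(ch)
        sample(byChrom[[ch]], need[[ch]])), use.names = FALSE)
      sum(perBin[idx])
    }, numeric(1))
  } else {
    null <- vapply(seq_len(nPerm), function(s)
      sum(perBin[sample.int(nB, nT)]), numeric(1))
  }
  out <- list(observed = observed, null_mean = mean(null),
              null_sd = sd(null),
              quantiles = quantile(null, c(0.025, 0.5, 0.975)),
              p = addOneP(sum(null >= observed), nPerm),
              n_perm = nPerm,
              background = sprintf("%d bins (%s resampling)", nB,
                                   if (chromMatched) "chromosome-matched"
                                   else "unconstrained"))
  class(out) <- "EnrichmentResult"
  out
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf("EnrichmentResult: observed %d vs null %.2f +/- %.2f; p = %.4g (%d permutations)\n",
              x$observed, x$null_mean, x$null_sd, x$p, x$n_perm))
  cat("  background:", x$background, "\n")
  invisible(x)
}

#' Multi-catalog (tissue) eQTL enrichment scan
#'
#' Runs \code{\link{permutationEnrichment}} for each tissue catalog against
#' the same target/background bins and flags tissues with p below
#' \code{alpha}. Optionally deduplicates coordinates across catalogs first
#' (unique-eQTL mode).
#'
#' @param catalogs named list of eQTL data.frames.
#' @param targetBins,backgroundBins as in
#'   \code{\link{permutationEnrichment}}.
#' @param nPerm permutations per tissue.
#' @param seed RNG seed (per-tissue seeds derived from it).
#' @param alpha significance level for the flag (default 0.05).
#' @param fdrCut eQTL significance cut.
#' @param dedupAcross drop coordinates seen in an earlier catalog?
#' @return data.frame (one row per tissue): tissue, observed, null_mean, p,
#'   significant.
#' @export
multiCatalogScan <- function(catalogs, targetBins, backgroundBins,
                             nPerm = 1000, seed = 1, alpha = 0.05,
                             fdrCut = 1e-8, dedupAcross = FALSE) {
  if (!length(catalogs)) stop("need at least one catalog")
  if (dedupAcross) {
    seen <- character()
    catalogs <- lapply(catalogs, function(cat) {
      key <- paste(cat$chrom, cat$pos)
      keep <- !key %in% seen
      seen <<- c(seen, key[keep])
      cat[keep, , drop = FALSE]
    })
  }
  rows <- lapply(seq_along(catalogs), function(k) {
    res <- permutationEnrichment(catalogs[[k]], targetBins, backgroundBins,
                                 nPerm = nPerm, seed = seed + k,
                                 fdrCut = fdrCut)
    data.frame(tissue = names(catalogs)[k] %||% paste0("catalog", k),
               observed = res$observed, null_mean = res$null_mean,
               p = res$p, significant = res$p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter an eQTL catalog to clump leads
#'
#' Keeps one representative (the lead) per gene-by-clump group, using an
#' externally produced clump assignment table; the clumping computation
#' itself (LD-based) is not performed here. eQTLs missing from the
#' assignment are retained with a warning.
#'
#' @param eqtls eQTL data.frame.
#' @param clumpAssignments data.frame with columns chrom, pos, gene,
#'   clump_id, is_lead.
#' @return filtered eQTL data.frame.
#' @export
clumpedInputFilter <- function(eqtls, clumpAssignments) {
  need <- c("chrom", "pos", "gene", "clump_id", "is_lead")
  if (!nrow(clumpAssignments)) {
    if (nrow(eqtls))
      warning(nrow(eqtls), " eQTL(s) missing from clump assignment; retained")
    return(eqtls)
  }
  if (!all(need %in% names(clumpAssignments)))
    stop("clump assignment needs columns ", paste(need, collapse = ", "))
  keyE <- paste(eqtls$chrom, eqtls$pos, eqtls$gene)
  keyC <- paste(clumpAssignments$chrom, clumpAssignments$pos,
                clumpAssignments$gene)
  m <- match(keyE, keyC)
  unassigned <- is.na(m)
  if (any(unassigned))
    warning(sum(unassigned), " eQTL(s) missing from clump assignment; retained")
  keep <- unassigned | clumpAssignments$is_lead[m]
  out <- eqtls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
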