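## Distance-stratified binomial model for calling significant intra-
## chromosomal contacts from raw matrices, plus matrix reproducibility.

#' Expected contact counts by bin separation
#'
#' For each chromosome, E(d) is the mean raw count over *all* bin pairs at
#' separation d (in bins), counting absent pairs as zero — the complete pair
#' census, not just observed pixels. The diagonal (d = 0) is excluded.
#'
#' @param x a raw \code{\link{ContactMap}}.
#' @return list of class \code{ExpectedProfile}: per chromosome a list with
#'   \code{E} (length n_bins - 1), \code{n_pairs}, \code{bin_ids} (global
#'   ids, in order).
#' @export
expectedByDistance <- function(x) {
  stopifnot(is(x, "ContactMap"))
  if (contactKind(x) != "raw")
    stop("expected-count profile requires a raw contact map")
  bins <- contactBins(x)
  px <- contactPixels(x)
  chroms <- as.character(seqnames(bins))
  binChrom <- chroms[match(px$i, bins$bin_id)]
  sameChrom <- binChrom == chroms[match(px$j, bins$bin_id)]
  out <- list()
  for (ch in unique(chroms)) {
    ids <- bins$bin_id[chroms == ch]
    n <- length(ids)
    if (n < 2) {
      out[[ch]] <- list(E = numeric(), n_pairs = integer(), bin_ids = ids)
      next
    }
    sel <- sameChrom & binChrom == ch & px$i != px$j
    sep <- px$j[sel] - px$i[sel]
    sums <- numeric(n - 1)
    if (any(sel)) {
      agg <- rowsum(px$value[sel], sep)
      sums[as.integer(rownames(agg))] <- agg[, 1]
    }
    nPairs <- n - seq_len(n - 1)
    out[[ch]] <- list(E = sums / nPairs, n_pairs = nPairs, bin_ids = ids)
  }
  structure(out, class = "ExpectedProfile")
}

#' Contact probability vector for a bin of interest
#'
#' The probability of a contact between bin i and partner j is
#' E(d_ij) / sum_k E(d_ik) over all intra-chromosomal partners k; the vector
#' sums to one.
#'
#' @param profile an \code{ExpectedProfile}.
#' @param binId global bin id of the bin of interest.
#' @return named numeric vector of probabilities over all same-chromosome
#'   partner bin ids.
#' @export
contactProbability <- function(profile, binId) {
  ch <- NULL
  for (nm in names(profile)) {
    if (binId %in% profile[[nm]]$bin_ids) { ch <- nm; break }
  }
  if (is.null(ch)) stop("bin ", binId, " not found in profile")
  p <- profile[[ch]]
  ids <- p$bin_ids
  i <- match(binId, ids)
  partners <- ids[-i]
  sep <- abs(seq_along(ids)[-i] - i)
  e <- p$E[sep]
  tot <- sum(e)
  if (tot == 0)
    stop("no signal: all expected counts are zero for bin ", binId)
  setNames(e / tot, partners)
}

#' Upper-tail binomial p-value
#'
#' P(X >= o) for X ~ Binomial(n, p), computed with the stable distribution
#' tail (log-space internally for large n). P(X >= 0) = 1 by convention.
#'
#' @param o observed count (successes).
#' @param n number of tries.
#' @param p success probability.
#' @return numeric p-value(s); vectorized over \code{o}, \code{n}, \code{p}.
#' @export
binomialPvalue <- function(o, n, p) {
  if (any(o > n)) stop("observed count exceeds the number of tries")
  if (any(p < 0 | p > 1)) stop("probability outside [0, 1]")
  ifelse(o <= 0, 1, pbinom(o - 1, n, p, lower.tail = FALSE))
}

#' Call significant contacts for bins of interest
#'
#' For each bin of interest the number of tries n_i is the total observed
#' count between that bin and all intra-chromosomal partners (chromosome-wide
#' by default; \code{tries = "window"} restricts it to the tested window as a
#' sensitivity option), the per-partner success probability comes from
#' \code{\link{contactProbability}}, and upper-tail binomial p-values are
#' computed for all partners within \code{windowBp} up/downstream. BH
#' adjustment is applied within each bin-of-interest's test family
#' (\code{family = "global"} pools all families instead).
#'
#' @param x a raw \code{\link{ContactMap}}.
#' @param binsOfInterest global bin ids to test.
#' @param windowBp tested window half-width in bp (default 1 Mb).
#' @param fdrThreshold q-value threshold for the significant flag
#'   (default 0.05).
#' @param tries "chromosome" (default) or "window".
#' @param family "bin" (BH per bin of interest, default) or "global".
#' @return data.frame: chrom, bin_i, bin_j, distance_bins, observed,
#'   expected, prob, n_tries, pvalue, qvalue, significant.
#' @export
callSignificant <- function(x, binsOfInterest, windowBp = 1e6,
                            fdrThreshold = 0.05,
                            tries = c("chromosome", "window"),
                            family = c("bin", "global")) {
  tries <- match.arg(tries)
  family <- match.arg(family)
  stopifnot(is(x, "ContactMap"))
  if (windowBp < contactResolution(x))
    stop("window smaller than one bin")
  bins <- contactBins(x)
  if (!all(binsOfInterest %in% bins$bin_id))
    stop("bin(s) of interest outside the matrix")
  profile <- expectedByDistance(x)
  chroms <- as.character(seqnames(bins))
  starts <- start(bins)
  px <- contactPixels(x)
  res <- list()
  for (b in binsOfInterest) {
    ch <- chroms[match(b, bins$bin_id)]
    ids <- profile[[ch]]$bin_ids
    if (length(ids) < 2) next
    prob <- tryCatch(contactProbability(profile, b), error = function(e) NULL)
    if (is.null(prob)) next
    partners <- as.integer(names(prob))
    obs <- numeric(length(partners))
    ri <- px$i == b
    rj <- px$j == b
    m1 <- match(px$j[ri], partners)
    obs[m1[!is.na(m1)]] <- px$value[ri][!is.na(m1)]
    m2 <- match(px$i[rj], partners)
    obs[m2[!is.na(m2)]] <- px$value[rj][!is.na(m2)]
    inWin <- abs(starts[match(partners, bins$bin_id)] -
                 starts[match(b, bins$bin_id)]) <= windowBp
    nI <- if (tries == "chromosome") sum(obs) else sum(obs[inWin])
    if (!any(inWin)) next
    pj <- prob[inWin]
    oj <- obs[inWin]
    pv <- binomialPvalue(oj, nI, pj)
    sep <- abs(partners[inWin] - b)
    eTab <- profile[[ch]]$E
    res[[length(res) + 1]] <- data.frame(
      chrom = ch, bin_i = b, bin_j = partners[inWin],
      distance_bins = sep, observed = oj, expected = eTab[sep],
      prob = unname(pj), n_tries = nI, pvalue = unname(pv),
      stringsAsFactors = FALSE)
  }
  if (!length(res))
    return(data.frame(chrom = character(), bin_i = integer(),
                      bin_j = integer(), distance_bins = integer(),
                      observed = numeric(), expected = numeric(),
                      prob = numeric(), n_tries = numeric(),
                      pvalue = numeric(), qvalue = numeric(),
                      significant = logical()))
  out <- do.call(rbind, res)
  if (family == "bin") {
    out$qvalue <- stats::ave(out$pvalue, out$bin_i,
                             FUN = function(p) p.adjust(p, "BH"))
  } else {
    out$qvalue <- p.adjust(out$pvalue, "BH")
  }
  out$significant <- out$qvalue < fdrThreshold
  rownames(out) <- NULL
  out
}

#' Pearson correlation between two contact maps
#'
#' Computed over the union of non-zero pixels of the two maps (absent pairs
#' count as zero), genome-wide or intra-chromosomal only.
#'
#' @param m1,m2 \code{\link{ContactMap}}s over the same bin table.
#' @param scope "genomewide" or "cis".
#' @return Pearson r.
#' @export
matrixCorrelation <- function(m1, m2, scope = c("genomewide", "cis")) {
  scope <- match.arg(scope)
  b1 <- contactBins(m1)
  b2 <- contactBins(m2)
  if (length(b1) != length(b2) ||
      !all(start(b1) == start(b2)) ||
      !all(as.character(seqnames(b1)) == as.character(seqnames(b2))))
    stop("bin tables differ between the two maps")
  p1 <- contactPixels(m1)
  p2 <- contactPixels(m2)
  keys <- union(paste(p1$i, p1$j), paste(p2$i, p2$j))
  v1 <- p1$value[match(keys, paste(p1$i, p1$j))]
  v2 <- p2$value[match(keys, paste(p2$i, p2$j))]
  v1[is.na(v1)] <- 0
  v2[is.na(v2)] <- 0
  if (scope == "cis") {
    ij <- do.call(rbind, strsplit(keys, " "))
    chroms <- as.character(seqnames(b1))
    keep <- chroms[as.integer(ij[, 1])] == chroms[as.integer(ij[, 2])]
    v1 <- v1[keep]
    v2 <- v2[keep]
  }
  cor(v1, v2)
}
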