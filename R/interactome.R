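## Cross-disorder contact extraction at bin resolution: bins harboring
## trait-A SNPs connected to bins harboring trait-B loci, classified
## intra/trans-chromosomal and within/across domain, with hot-spot
## assignment, feature annotation and track export.

binsOverlapping <- function(bins, features) {
  if (length(features) == 0) return(integer())
  bins$bin_id[overlapsAny(bins, features)]
}

## haploid domain id of each bin (by largest overlap; NA when none)
binDomainIds <- function(bins, domains) {
  hap <- haploidView(domains)
  hits <- findOverlaps(bins, hap)
  if (!length(hits)) return(rep(NA_character_, length(bins)))
  ov <- width(IRanges::pintersect(granges(bins)[queryHits(hits)],
                                  granges(hap)[subjectHits(hits)]))
  best <- tapply(seq_along(ov), queryHits(hits),
                 function(idx) idx[which.max(ov[idx])])
  out <- rep(NA_character_, length(bins))
  out[as.integer(names(best))] <- hap$domain_id[subjectHits(hits)[unlist(best)]]
  out
}

#' Extract cross-disorder contacts from a normalized matrix
#'
#' A contact is retained iff one anchor bin overlaps at least one trait-A
#' SNP and the other overlaps at least one trait-B locus (the reciprocal
#' orientation is the same unordered pair and is counted once). Contacts are
#' classified intra/trans-chromosomal and, for intra contacts, within/across
#' domain; when hot-spot memberships are supplied each contact whose two
#' anchor domains fall in the same hot spot is tagged with its id. Bins
#' carrying both traits may anchor either side and contacts between two such
#' dual bins are flagged role "both". Zero-frequency pairs are never
#' emitted.
#'
#' @param x a normalized \code{\link{ContactMap}}.
#' @param snps trait-A SNP \code{GRanges}.
#' @param loci trait-B locus \code{GRanges}.
#' @param domains segmentation \code{GRanges}.
#' @param hotspots optional named list: hot-spot id -> character vector of
#'   haploid domain ids.
#' @param restrictTo optional character vector of haploid domain ids; only
#'   contacts with both anchors in these domains are kept.
#' @return data.frame of class \code{CrossDisorderContacts}: bin1, bin2,
#'   chrom1, start1, end1, chrom2, start2, end2 (anchors, 0-based half-open),
#'   freq, class ("intra"/"trans"), domain_relation
#'   ("within_domain"/"across_domain"), hotspot, role
#'   ("A_B"/"B_A"/"both").
#' @export
extractCrossContacts <- function(x, snps, loci, domains, hotspots = NULL,
                                 restrictTo = NULL) {
  stopifnot(is(x, "ContactMap"))
  if (contactKind(x) != "normalized")
    stop("interactome extraction requires a normalized contact map")
  bins <- contactBins(x)
  px <- contactPixels(x)
  px <- px[px$value > 0 & px$i != px$j, , drop = FALSE]
  aBins <- binsOverlapping(bins, snps)
  bBins <- binsOverlapping(bins, loci)
  iA <- px$i %in% aBins; iB <- px$i %in% bBins
  jA <- px$j %in% aBins; jB <- px$j %in% bBins
  keep <- (iA & jB) | (iB & jA)
  px <- px[keep, , drop = FALSE]
  iA <- iA[keep]; iB <- iB[keep]; jA <- jA[keep]; jB <- jB[keep]
  domIds <- binDomainIds(bins, domains)
  d1 <- domIds[px$i]
  d2 <- domIds[px$j]
  if (!is.null(restrictTo)) {
    keep2 <- d1 %in% restrictTo & d2 %in% restrictTo
    px <- px[keep2, , drop = FALSE]
    iA <- iA[keep2]; iB <- iB[keep2]; jA <- jA[keep2]; jB <- jB[keep2]
    d1 <- d1[keep2]; d2 <- d2[keep2]
  }
  if (!nrow(px)) {
    out <- data.frame(bin1 = integer(), bin2 = integer(),
                      chrom1 = character(), start1 = integer(),
                      end1 = integer(), chrom2 = character(),
                      start2 = integer(), end2 = integer(),
                      freq = numeric(), class = character(),
                      domain_relation = character(), hotspot = character(),
                      role = character(), stringsAsFactors = FALSE)
    class(out) <- c("CrossDisorderContacts", class(out))
    return(out)
  }
  chroms <- as.character(seqnames(bins))
  cls <- ifelse(chroms[px$i] == chroms[px$j], "intra", "trans")
  rel <- ifelse(cls == "intra" & !is.na(d1) & !is.na(d2) & d1 == d2,
                "within_domain", "across_domain")
  role <- ifelse(iA & iB & jA & jB, "both",
                 ifelse(iA & jB, "A_B", "B_A"))
  hot <- rep(NA_character_, nrow(px))
  if (!is.null(hotspots)) {
    for (nm in names(hotspots)) {
      inHs <- d1 %in% hotspots[[nm]] & d2 %in% hotspots[[nm]]
      hot[inHs & is.na(hot)] <- nm
    }
  }
  out <- data.frame(bin1 = px$i, bin2 = px$j,
                    chrom1 = chroms[px$i], start1 = start(bins)[px$i] - 1L,
                    end1 = end(bins)[px$i],
                    chrom2 = chroms[px$j], start2 = start(bins)[px$j] - 1L,
                    end2 = end(bins)[px$j],
                    freq = px$value, class = cls, domain_relation = rel,
                    hotspot = hot, role = role, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("CrossDisorderContacts", class(out))
  out
}

#' Background contacts: trait anchors to the rest of a hot spot
#'
#' Contacts connecting each bin that carries the given trait's feature (and
#' lies in the hot-spot bin set) to every other bin of the same hot spot
#' with non-zero frequency.
#'
#' @param x a \code{\link{ContactMap}}.
#' @param features one trait's \code{GRanges} (SNPs or loci).
#' @param hotspotBins integer vector of global bin ids forming the hot spot.
#' @param trait label recorded in the output.
#' @return data.frame: bin1 (anchor), bin2 (rest-of-hot-spot), anchor
#'   coordinates, freq, trait.
#' @export
backgroundContacts <- function(x, features, hotspotBins, trait = "trait") {
  stopifnot(is(x, "ContactMap"))
  bins <- contactBins(x)
  anchors <- intersect(binsOverlapping(bins, features), hotspotBins)
  px <- contactPixels(x)
  px <- px[px$value > 0, , drop = FALSE]
  keep <- (px$i %in% anchors & px$j %in% hotspotBins & !(px$j %in% anchors) ) |
          (px$j %in% anchors & px$i %in% hotspotBins & !(px$i %in% anchors)) |
          (px$i %in% anchors & px$j %in% anchors & px$i != px$j)
  px <- px[keep, , drop = FALSE]
  if (!nrow(px))
    return(data.frame(bin1 = integer(), bin2 = integer(),
                      chrom1 = character(), start1 = integer(),
                      end1 = integer(), chrom2 = character(),
                      start2 = integer(), end2 = integer(),
                      freq = numeric(), trait = character()))
  # orient so bin1 is an anchor
  a1 <- px$i %in% anchors
  b1 <- ifelse(a1, px$i, px$j)
  b2 <- ifelse(a1, px$j, px$i)
  chroms <- as.character(seqnames(bins))
  data.frame(bin1 = b1, bin2 = b2,
             chrom1 = chroms[b1], start1 = start(bins)[b1] - 1L,
             end1 = end(bins)[b1],
             chrom2 = chroms[b2], start2 = start(bins)[b2] - 1L,
             end2 = end(bins)[b2],
             freq = px$value, trait = trait, stringsAsFactors = FALSE)
}

#' Annotate contacts with feature counts
#'
#' A feature counts for a contact iff it overlaps either anchor bin by at
#' least 1 bp, deduplicated within the contact (a feature spanning both
#' anchors counts once). Per-hot-spot totals deduplicate features across all
#' contacts of the hot spot (clamped accumulation).
#'
#' @param contacts result of \code{\link{extractCrossContacts}}.
#' @param features feature \code{GRanges} (e.g. transcribed non-coding
#'   elements).
#' @return list: \code{perContact} (contacts with an added
#'   \code{n_features} column), \code{perHotspot} (data.frame hotspot /
#'   n_features).
#' @export
annotateContacts <- function(contacts, features) {
  n <- nrow(contacts)
  featIdx <- vector("list", n)
  if (length(features) && n) {
    anchor1 <- GRanges(contacts$chrom1,
                       IRanges(contacts$start1 + 1L, contacts$end1))
    anchor2 <- GRanges(contacts$chrom2,
                       IRanges(contacts$start2 + 1L, contacts$end2))
    h1 <- findOverlaps(anchor1, features)
    h2 <- findOverlaps(anchor2, features)
    for (k in seq_len(n)) {
      featIdx[[k]] <- union(subjectHits(h1)[queryHits(h1) == k],
                            subjectHits(h2)[queryHits(h2) == k])
    }
  }
  contacts$n_features <- lengths(featIdx)
  hsIds <- unique(contacts$hotspot[!is.na(contacts$hotspot)])
  perHot <- data.frame(hotspot = hsIds,
                       n_features = vapply(hsIds, function(h) {
                         length(unique(unlist(featIdx[which(contacts$hotspot == h)])))
                       }, integer(1)), stringsAsFactors = FALSE)
  list(perContact = contacts, perHotspot = perHot)
}

#' Export contacts as BEDPE, WashU long-range, or circos anchor table
#'
#' @param contacts a contacts data.frame with anchor columns and
#'   \code{freq}.
#' @param path output file.
#' @param format "bedpe", "washu" or "circos".
#' @return invisibly, \code{path}.
#' @export
exportInteractome <- function(contacts, path,
                              format = c("bedpe", "washu", "circos")) {
  format <- match.arg(format)
  switch(format,
         bedpe = writeBedpe(contacts, path),
         washu = writeWashuLongrange(contacts, path),
         circos = {
           df <- data.frame(chrom1 = contacts$chrom1,
                            start1 = contacts$start1, end1 = contacts$end1,
                            chrom2 = contacts$chrom2,
                            start2 = contacts$start2, end2 = contacts$end2,
                            score = fmtScore(contacts$freq))
           write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
           invisible(path)
         })
}
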