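## two-chromosome toy world shared by the blocks below: 10 bins of 40 kb per
## chromosome, domains of 5 bins
interactomeFixture <- function() {
  lens <- c(chr1 = 400000, chr2 = 400000)
  bins <- binTable(lens, 40000)
  dom <- GRanges(rep(c("chr1", "chr2"), each = 2),
                 IRanges(start = rep(c(1, 200001), 2),
                         end = rep(c(200000, 400000), 2)))
  dom <- rep(dom, each = 2)
  dom$haplotype <- rep(c("A", "B"), 4)
  dom$domain_id <- paste0("d", rep(1:4, each = 2))
  dom$bead_id <- paste0(dom$domain_id, "_", dom$haplotype)
  # SNP in bin 3 (chr1), locus spanning bin 7 (chr1) and bin 13 (chr2)
  snps <- GRanges("chr1", IRanges(100001, width = 1))        # bin 3
  loci <- GRanges(c("chr1", "chr2"),
                  IRanges(c(250001, 90001), c(260000, 100000))) # bins 7, 13
  list(bins = bins, domains = dom, snps = snps, loci = loci)
}

test_that("cross-disorder contacts classify intra/trans and domain relation", {
  fx <- interactomeFixture()
  px <- data.frame(i = c(3, 3, 3, 7, 1), j = c(7, 13, 4, 13, 2),
                   value = c(2.5, 1.5, 9, 4, 3))
  cm <- ContactMap(fx$bins, px, kind = "normalized")
  got <- extractCrossContacts(cm, fx$snps, fx$loci, fx$domains)
  # kept: (3,7) SNP-locus intra, (3,13) SNP-locus trans; (3,4), (7,13), (1,2)
  # have no SNP-locus pairing
  expect_equal(nrow(got), 2)
  intra <- got[got$class == "intra", ]
  expect_equal(intra$bin1, 3)
  expect_equal(intra$bin2, 7)
  expect_equal(intra$freq, 2.5)
  expect_equal(intra$domain_relation, "across_domain") # bins 3 vs 7: d1 vs d2
  trans <- got[got$class == "trans", ]
  expect_equal(trans$bin2, 13)
  # a raw map is rejected; the reciprocal orientation collapses to one record
  expect_error(extractCrossContacts(
    ContactMap(fx$bins, data.frame(i = 3, j = 7, value = 2), kind = "raw"),
    fx$snps, fx$loci, fx$domains), "normalized")
  cmSwap <- ContactMap(fx$bins, data.frame(i = 7, j = 3, value = 2.5),
                       kind = "normalized")
  expect_equal(nrow(extractCrossContacts(cmSwap, fx$snps, fx$loci,
                                         fx$domains)), 1)
})

test_that("within-domain contacts, hotspot tags and trait symmetry hold", {
  fx <- interactomeFixture()
  # SNP in bin 1 and locus in bin 4: same domain d1 -> within_domain
  snps <- GRanges("chr1", IRanges(10001, width = 1))          # bin 1
  loci <- GRanges("chr1", IRanges(130001, 140000))            # bin 4
  cm <- ContactMap(fx$bins, data.frame(i = 1, j = 4, value = 1.2),
                   kind = "normalized")
  got <- extractCrossContacts(cm, snps, loci, fx$domains,
                              hotspots = list(EH1 = c("d1", "d2")))
  expect_equal(got$domain_relation, "within_domain")
  expect_equal(got$hotspot, "EH1")
  # swapping trait labels yields the same unordered contact set
  swapped <- extractCrossContacts(cm, GRanges("chr1", IRanges(135001, width = 1)),
                                  GRanges("chr1", IRanges(1, 20000)),
                                  fx$domains)
  expect_equal(got[, c("bin1", "bin2", "freq")],
               swapped[, c("bin1", "bin2", "freq")])
  # restrictTo drops contacts outside the named domains
  gotR <- extractCrossContacts(cm, snps, loci, fx$domains,
                               restrictTo = "d3")
  expect_equal(nrow(gotR), 0)
  # dual-anchor bins are flagged "both"
  dual <- extractCrossContacts(
    ContactMap(fx$bins, data.frame(i = 1, j = 4, value = 2),
               kind = "normalized"),
    GRanges("chr1", IRanges(c(10001, 130005), width = 1)),   # SNPs bins 1+4
    GRanges("chr1", IRanges(c(15001, 131001), width = 500)), # loci bins 1+4
    fx$domains)
  expect_equal(dual$role, "both")
})

test_that("planted cross-disorder pairs are recovered exactly", {
  cfg <- tinyConfig(resolution = 500000)
  study <- simulateStudy(cfg)
  norm <- normalizeContacts(study$contacts)
  got <- extractCrossContacts(norm, study$snps, study$loci, study$domains)
  # brute-force enumeration over all pixels
  bins <- contactBins(norm)
  aB <- bins$bin_id[countOverlaps(bins, study$snps) > 0]
  bB <- bins$bin_id[countOverlaps(bins, study$loci) > 0]
  px <- contactPixels(norm)
  want <- px[((px$i %in% aB & px$j %in% bB) |
                (px$i %in% bB & px$j %in% aB)) & px$i != px$j & px$value > 0, ]
  expect_equal(nrow(got), nrow(want))
  expect_setequal(paste(got$bin1, got$bin2), paste(want$i, want$j))
  # partition invariants
  expect_equal(sum(got$class == "intra") + sum(got$class == "trans"),
               nrow(got))
  intra <- got[got$class == "intra", ]
  expect_equal(sum(intra$domain_relation == "within_domain") +
                 sum(intra$domain_relation == "across_domain"), nrow(intra))
})

test_that("background contacts enumerate trait-anchor-to-hotspot pairs", {
  fx <- interactomeFixture()
  hotBins <- c(1, 2, 3, 4)
  px <- data.frame(i = c(3, 3, 3, 2), j = c(1, 2, 4, 4),
                   value = c(1, 2, 3, 4))
  cm <- ContactMap(fx$bins, px, kind = "normalized")
  got <- backgroundContacts(cm, fx$snps, hotBins, trait = "A")
  # SNP bin 3 connects to hotspot bins 1, 2, 4
  expect_equal(nrow(got), 3)
  expect_true(all(got$bin1 == 3))
  expect_setequal(got$bin2, c(1, 2, 4))
  expect_equal(got$trait, rep("A", 3))
  # no contacts in the matrix -> empty list
  empty <- ContactMap(fx$bins, data.frame(i = integer(), j = integer(),
                                          value = numeric()),
                      kind = "normalized")
  expect_equal(nrow(backgroundContacts(empty, fx$snps, hotBins)), 0)
})

test_that("contact annotation deduplicates features per contact and hotspot", {
  fx <- interactomeFixture()
  cm <- ContactMap(fx$bins, data.frame(i = c(1, 2), j = c(4, 4),
                                       value = c(1, 1)),
                   kind = "normalized")
  snps <- GRanges("chr1", IRanges(c(10001, 50001), width = 1))  # bins 1, 2
  loci <- GRanges("chr1", IRanges(130001, 140000))              # bin 4
  contacts <- extractCrossContacts(cm, snps, loci, fx$domains,
                                   hotspots = list(EH1 = c("d1")))
  expect_equal(nrow(contacts), 2)
  # one feature spanning both anchors of contact (1,4); one feature in bin 4
  feats <- GRanges("chr1", IRanges(c(30001, 125001), c(125000, 126000)))
  ann <- annotateContacts(contacts, feats)
  # contact (1,4): feature 1 overlaps both anchors -> counted once; feature 2
  # overlaps anchor 2 only -> 2 features total
  c14 <- ann$perContact[ann$perContact$bin1 == 1, ]
  expect_equal(c14$n_features, 2)
  # hotspot total deduplicates across the two contacts
  expect_equal(ann$perHotspot$n_features[ann$perHotspot$hotspot == "EH1"], 2)
  # disjoint feature contributes nothing (different chromosome)
  ann0 <- suppressWarnings(
    annotateContacts(contacts, GRanges("chr2", IRanges(1, 100))))
  expect_true(all(ann0$perContact$n_features == 0))
})

test_that("interactome export formats are consistent", {
  fx <- interactomeFixture()
  cm <- ContactMap(fx$bins, data.frame(i = 3, j = 7, value = 2.5),
                   kind = "normalized")
  contacts <- extractCrossContacts(cm, fx$snps, fx$loci, fx$domains)
  bp <- tempfile(); wu <- tempfile(); ct <- tempfile()
  exportInteractome(contacts, bp, "bedpe")
  expect_length(strsplit(readLines(bp), "\t")[[1]], 10)
  exportInteractome(contacts, wu, "washu")
  expect_identical(readLines(wu), "chr1:80000-120000\tchr1:240000-280000\t2.5")
  exportInteractome(contacts, ct, "circos")
  expect_equal(nrow(read.table(ct, header = TRUE)), 1)
  expect_error(exportInteractome(contacts, ct, "hic"), "arg")
  unlink(c(bp, wu, ct))
})
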