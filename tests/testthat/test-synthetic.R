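test_that("domain tiling is contiguous, conservative and diploid", {
  cfg <- syntheticConfig(chromosome_lengths = c(chr1 = 10e6),
                         n_domains_per_chrom = 10L, seed = 1)
  gen <- simulateGenome(cfg)
  dom <- gen$domains
  expect_equal(length(dom), 20)                     # 10 domains x 2 haplotypes
  hap <- dom[dom$haplotype == "A"]
  expect_equal(width(hap), rep(1e6, 10))
  # spans tile the chromosome exactly, half-open and non-overlapping
  expect_equal(start(hap), seq(1, 9e6 + 1, by = 1e6))
  expect_equal(sum(width(hap)), 10e6)
  expect_setequal(unique(dom$haplotype), c("A", "B"))
  # conservation holds for non-divisible lengths too
  cfg2 <- syntheticConfig(chromosome_lengths = c(chr1 = 10e6 + 777),
                          n_domains_per_chrom = 7L, seed = 1)
  hap2 <- simulateGenome(cfg2)$domains
  hap2 <- hap2[hap2$haplotype == "A"]
  expect_equal(sum(width(hap2)), 10e6 + 777)
  expect_true(all(start(hap2)[-1] == head(end(hap2), -1) + 1))
  expect_error(syntheticConfig(chromosome_lengths = c(chr1 = 0)),
               "invalid config")
})

test_that("bead coordinates are confined and planted clusters are tight", {
  cfg <- tinyConfig()
  gen <- simulateGenome(cfg)
  model <- simulateCoordinates(gen$domains, cfg)
  expect_true(all(sqrt(rowSums(beadCoords(model)^2)) <= 3.0 + 1e-9))
  # planted cluster beads sit within `spread` of the center; spread 0 is
  # fully degenerate
  ids <- head(beadIds(model), 5)
  cfg0 <- tinyConfig(planted_hotspots = list(
    list(bead_ids = ids, center = c(1, 0, 0), spread = 0)))
  m0 <- simulateCoordinates(simulateGenome(cfg0)$domains, cfg0)
  sub <- beadCoords(m0)[ids, ]
  expect_true(all(dist(sub) == 0))
  expect_equal(unname(sub[1, ]), c(1, 0, 0))
  # Monte-Carlo: planted spread-0.1 clusters are tighter than uniform draws
  planted <- numeric(100); uniform <- numeric(100)
  for (s in seq_len(100)) {
    cfgS <- tinyConfig(seed = s, planted_hotspots = list(
      list(bead_ids = ids, center = c(1, 0, 0), spread = 0.1)))
    mS <- simulateCoordinates(simulateGenome(cfgS)$domains, cfgS)
    planted[s] <- mean(dist(beadCoords(mS)[ids, ]))
    uniform[s] <- mean(dist(beadCoords(mS)[tail(beadIds(mS), 5), ]))
  }
  expect_lt(mean(planted), mean(uniform))
  expect_error(tinyConfig(planted_hotspots = list(
    list(bead_ids = ids, center = c(9, 0, 0), spread = 0.1))),
    "outside the nucleus")
})

test_that("risk sets respect the planted shared-domain ground truth", {
  cfg <- tinyConfig()                               # 20 haploid domains, 20% shared
  gen <- simulateGenome(cfg)
  risk <- simulateRiskSets(gen$domains, cfg)
  expect_length(risk$shared_domains, ceiling(0.2 * 20))
  ann <- annotateDomains(gen$domains, risk$snps, risk$loci)
  expect_setequal(sharedDomains(ann, "haploid"), risk$shared_domains)
  # shared_fraction = 0: SNP-bearing and locus-bearing domains are disjoint
  cfg0 <- tinyConfig(shared_fraction = 0)
  r0 <- simulateRiskSets(simulateGenome(cfg0)$domains, cfg0)
  a0 <- annotateDomains(simulateGenome(cfg0)$domains, r0$snps, r0$loci)
  expect_equal(sum(a0$flag == "shared"), 0)
  expect_length(r0$shared_domains, 0)
  # n_snps = 0: empty variant set, no shared domains
  cfgE <- tinyConfig(n_snps = 0L)
  rE <- simulateRiskSets(simulateGenome(cfgE)$domains, cfgE)
  expect_length(rE$snps, 0)
  expect_length(rE$shared_domains, 0)
})

test_that("contact counts follow the configured distance decay", {
  # flat decay: mean count independent of separation (within 3 SE)
  cfg <- syntheticConfig(chromosome_lengths = c(chr1 = 8e6),
                         n_domains_per_chrom = 4L, resolution = 40000,
                         decay_exponent = 0, sequencing_depth = 5,
                         trans_depth_fraction = 0, seed = 3)
  bins <- binTable(c(chr1 = 8e6), 40000)            # 200 bins, ~2e4 pairs
  cm <- simulateContacts(bins, cfg)
  px <- contactPixels(cm)
  sep <- px$j - px$i
  nPairs <- 200 - seq_len(199)
  sums <- vapply(seq_len(199), function(d) sum(px$value[sep == d]),
                 numeric(1))
  meanNear <- sum(sums[1:40]) / sum(nPairs[1:40])
  meanFar <- sum(sums[150:199]) / sum(nPairs[150:199])
  se <- sqrt(5 / sum(nPairs[150:199]))
  expect_lt(abs(meanNear - meanFar), 3 * se * sqrt(2))
  # depth 0: empty matrix
  cfg0 <- syntheticConfig(chromosome_lengths = c(chr1 = 8e6),
                          n_domains_per_chrom = 4L, sequencing_depth = 0,
                          seed = 3)
  expect_equal(nrow(contactPixels(simulateContacts(bins, cfg0))), 0)
  expect_error(syntheticConfig(planted_loop_pairs = list(
    list(bin_i = 1, bin_j = 5, fold = -2))), "negative fold")
})

test_that("planted loop pairs are enriched by about their fold", {
  bins <- binTable(c(chr1 = 2e6), 40000)            # 50 bins
  ratios <- vapply(seq_len(100), function(s) {
    cfg <- syntheticConfig(chromosome_lengths = c(chr1 = 2e6),
                           n_domains_per_chrom = 2L, resolution = 40000,
                           sequencing_depth = 20, decay_exponent = 1,
                           trans_depth_fraction = 0, seed = s,
                           planted_loop_pairs = list(
                             list(bin_i = 10, bin_j = 20, fold = 10)))
    cm <- simulateContacts(bins, cfg)
    contactValue(cm, 10, 20) / (20 / 10)            # expected base mean: lam0/sep
  }, numeric(1))
  expect_gt(mean(ratios), 5)
  expect_lt(mean(ratios), 15)
})

test_that("eQTL placement matches the configured enrichment fold", {
  bins <- binTable(c(chr1 = 4e6), 40000)            # 100 bins
  target <- 1:10
  # fold 1: overlap proportion ~ genomic fraction of the target bins
  cfg1 <- syntheticConfig(chromosome_lengths = c(chr1 = 4e6),
                          n_domains_per_chrom = 4L, n_eqtls = 2000L,
                          eqtl_enrichment_fold = 1, seed = 11)
  e1 <- simulateEqtls(bins, target, cfg1)
  inT <- sum(overlapsAny(GRanges(e1$chrom, IRanges(e1$pos + 1, width = 1)),
                         bins[target]))
  ci <- qbinom(c(0.005, 0.995), 2000, 0.1)
  expect_gte(inT, ci[1])
  expect_lte(inT, ci[2])
  # fold 0: targets excluded entirely
  cfg0 <- syntheticConfig(chromosome_lengths = c(chr1 = 4e6),
                          n_domains_per_chrom = 4L, n_eqtls = 500L,
                          eqtl_enrichment_fold = 0, seed = 11)
  e0 <- simulateEqtls(bins, target, cfg0)
  expect_equal(sum(overlapsAny(GRanges(e0$chrom,
                                       IRanges(e0$pos + 1, width = 1)),
                               bins[target])), 0)
  # n = 0: empty catalog, and the permutation contract still returns p = 1
  cfgE <- syntheticConfig(n_eqtls = 0L, seed = 1)
  eE <- simulateEqtls(bins, target, cfgE)
  expect_equal(nrow(eE), 0)
  res <- permutationEnrichment(eE, bins[target], bins, nPerm = 99, seed = 1)
  expect_equal(res$p, 1)
})

test_that("identical configs give byte-identical outputs", {
  cfg <- tinyConfig()
  s1 <- simulateStudy(cfg)
  s2 <- simulateStudy(cfg)
  expect_identical(beadCoords(s1$model), beadCoords(s2$model))
  expect_identical(contactPixels(s1$contacts), contactPixels(s2$contacts))
  expect_identical(s1$eqtls, s2$eqtls)
  expect_identical(s1$manifest, s2$manifest)
  d1 <- file.path(tempdir(), "studyA"); d2 <- file.path(tempdir(), "studyB")
  writeStudy(s1, d1); writeStudy(s2, d2)
  for (f in list.files(d1)) {
    if (f == "manifest.json") next
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})
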