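test_that("pairwise and centroid distances are exact", {
  m <- manualModel(rbind(c(0, 0, 0), c(3, 4, 0), c(3, 4, 12)),
                   nucleusRadius = 15)
  dm <- pairwiseDistances(m)
  expect_equal(unname(dm$d["d1_A", "d2_A"]), 5)
  expect_equal(unname(dm$d["d2_A", "d3_A"]), 12)
  expect_equal(unname(dm$d["d1_A", "d3_A"]), 13)
  expect_true(all(diag(dm$d) == 0))
  expect_equal(dm$d, t(dm$d))
  expect_error(pairwiseDistances(m, ids = "nope"), "unknown bead")
  cd <- centroidDistances(m)
  expect_equal(unname(cd), c(0, 5, 13))
  # brute-force double loop on a random model, exact equality
  set.seed(4)
  coords <- matrix(rnorm(150), ncol = 3)
  mr <- manualModel(coords, nucleusRadius = 50)
  dmr <- pairwiseDistances(mr)$d
  for (i in c(1, 17, 50)) for (j in c(3, 25, 49))
    expect_equal(unname(dmr[i, j]),
                 sqrt(sum((coords[i, ] - coords[j, ])^2)))
  expect_equal(unname(centroidDistances(mr)), sqrt(rowSums(coords^2)))
  # same-chromosome masking
  m2 <- manualModel(coords[1:4, ], chrom = c("chr1", "chr1", "chr2", "chr2"),
                    nucleusRadius = 50)
  dm2 <- pairwiseDistances(m2, interChromOnly = TRUE)
  expect_true(is.na(dm2$d[1, 2]))
  expect_false(is.na(dm2$d[1, 3]))
  # distances are invariant to rotation/translation of the coordinates
  # (clustering depends only on the matrix): rotate about z by 90 degrees
  rot <- coords %*% matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3)
  expect_equal(pairwiseDistances(manualModel(rot, nucleusRadius = 50))$d,
               dmr, tolerance = 1e-12)
})

test_that("hot-spot detection recovers planted clusters", {
  # two tight clusters far apart: exact membership at k = 2
  set.seed(7)
  c1 <- matrix(rnorm(15, sd = 0.05), ncol = 3) + rep(c(2, 0, 0), each = 5)
  c2 <- matrix(rnorm(15, sd = 0.05), ncol = 3) + rep(c(-2, 0, 0), each = 5)
  m <- manualModel(rbind(c1, c2), nucleusRadius = 4)
  hs <- detectHotspots(pairwiseDistances(m), k = 2)
  expect_length(hs$hotspots, 2)
  got <- sort(vapply(hs$hotspots, function(h) paste(sort(h$members),
                                                    collapse = ","),
                     character(1)))
  want <- sort(c(paste(sort(beadIds(m)[1:5]), collapse = ","),
                 paste(sort(beadIds(m)[6:10]), collapse = ",")))
  expect_equal(got, want)
  # auto-k silhouette finds the same two clusters
  hsAuto <- detectHotspots(pairwiseDistances(m), k = "auto")
  expect_equal(hsAuto$k, 2)
  # order invariance: permuting bead input order does not change clusters
  perm <- sample(10)
  hsPerm <- detectHotspots(pairwiseDistances(m, ids = beadIds(m)[perm]),
                           k = 2)
  gotPerm <- sort(vapply(hsPerm$hotspots,
                         function(h) paste(sort(h$members), collapse = ","),
                         character(1)))
  expect_equal(gotPerm, want)
  # degenerate: all beads coincident -> single cluster
  m0 <- manualModel(matrix(0, 10, 3), nucleusRadius = 1)
  hs0 <- detectHotspots(pairwiseDistances(m0), k = "auto")
  expect_length(hs0$hotspots, 1)
  expect_length(hs0$hotspots[[1]]$members, 10)
  expect_error(detectHotspots(pairwiseDistances(m, ids = beadIds(m)[1:4])),
               "at least")
  mShared <- manualModel(rbind(c1, c2), chrom = rep(c("chr1", "chr2"), 5),
                         nucleusRadius = 4)
  expect_error(detectHotspots(pairwiseDistances(mShared,
                                                interChromOnly = TRUE)),
               "unmasked")
})

test_that("planted 4-cluster models are recovered with high ARI", {
  aris <- vapply(seq_len(20), function(s) {
    cfg <- syntheticConfig(chromosome_lengths = setNames(rep(4e6, 6),
                                                         paste0("chr", 1:6)),
                           n_domains_per_chrom = 4L, seed = s)
    gen <- simulateGenome(cfg)
    ids <- as.character(gen$domains$bead_id)
    centers <- list(c(2, 0, 0), c(-2, 0, 0), c(0, 2, 0), c(0, -2, 0))
    groups <- split(ids[1:24], rep(1:4, each = 6))
    cfg <- syntheticConfig(chromosome_lengths = setNames(rep(4e6, 6),
                                                         paste0("chr", 1:6)),
                           n_domains_per_chrom = 4L, seed = s,
                           planted_hotspots = lapply(1:4, function(g)
                             list(bead_ids = groups[[g]],
                                  center = centers[[g]], spread = 0.1)))
    model <- simulateCoordinates(gen$domains, cfg)
    dm <- pairwiseDistances(model, ids[1:24])
    hs <- detectHotspots(dm, k = 4)
    truth <- rep(1:4, each = 6)
    mclust::adjustedRandIndex(hs$labels[ids[1:24]], truth)
  }, numeric(1))
  expect_gte(mean(aris), 0.9)
})

test_that("hot-spot significance: exact rank-sum, planted power, pool edge", {
  # exact one-sided rank-sum enumeration: {1,2} vs {3,4} -> p = 1/6
  expect_equal(wilcox.test(c(1, 2), c(3, 4),
                           alternative = "less")$p.value, 1 / 6)
  set.seed(21)
  pool <- matrix(runif(90, -1.5, 1.5), ncol = 3)
  tight <- matrix(rnorm(15, sd = 0.05), ncol = 3)
  m <- manualModel(rbind(tight, pool), nucleusRadius = 3)
  ids <- beadIds(m)
  res <- hotspotSignificance(m, ids[1:5], ids, nSamples = 1000, seed = 2)
  expect_lt(res$p, 0.01)
  expect_lt(res$p_wilcoxon, 0.01)
  expect_gte(res$p, 1 / 1001)                       # add-one floor
  # hotspot == pool: p = 1 with a warning
  expect_warning(r2 <- hotspotSignificance(m, ids, ids, nSamples = 100),
                 "pool")
  expect_equal(r2$p, 1)
  expect_error(hotspotSignificance(m, ids[1:3], ids, nSamples = 10), ">= 100")
})

test_that("cross-model projection maps per haplotype and handles splits", {
  cfg <- tinyConfig()
  gen <- simulateGenome(cfg)
  model <- simulateCoordinates(gen$domains, cfg)
  members <- beadIds(model)[c(1, 5, 21)]           # beads on both chroms
  # identical segmentations: distances equal direct computation
  pr <- crossModelProjection(members, gen$domains, model)
  expect_setequal(pr$mapping$target_bead, members)
  direct <- pairwiseDistances(model, members, interChromOnly = TRUE)
  expect_equal(pr$dist$d[members, members], direct$d)
  # target with split domains: every source domain maps to 2 target beads
  cfgSplit <- syntheticConfig(chromosome_lengths = c(chr1 = 10e6,
                                                     chr2 = 10e6),
                              n_domains_per_chrom = 20L, seed = 9)
  genS <- simulateGenome(cfgSplit)
  modelS <- simulateCoordinates(genS$domains, cfgSplit)
  prS <- crossModelProjection(members, gen$domains, modelS)
  expect_equal(nrow(prS$mapping), 2 * length(members))
  expect_length(prS$unmapped, 0)
  # disjoint assemblies: everything unmapped, empty result
  cfgX <- syntheticConfig(chromosome_lengths = c(chrX = 10e6),
                          n_domains_per_chrom = 10L, seed = 9)
  genX <- simulateGenome(cfgX)
  modelX <- simulateCoordinates(genX$domains, cfgX)
  prX <- suppressWarnings(crossModelProjection(members, gen$domains, modelX))
  expect_length(prX$unmapped, length(members))
  expect_null(prX$dist)
})

test_that("replicate stability separates signal from noise", {
  cfg <- tinyConfig()
  gen <- simulateGenome(cfg)
  ids <- as.character(gen$domains$bead_id)[1:20]
  mk <- function(seed, planted = TRUE) {
    hs <- if (planted) lapply(1:2, function(g)
      list(bead_ids = ids[(g - 1) * 6 + 1:6],
           center = list(c(2, 0, 0), c(-2, 0, 0))[[g]], spread = 0.15))
      else list()
    cfgS <- tinyConfig(seed = seed, planted_hotspots = hs)
    simulateCoordinates(gen$domains, cfgS)
  }
  # identical models: ARI exactly 1
  m1 <- mk(1)
  same <- replicateStability(list(m1, m1), ids, k = 3)
  expect_equal(same$mean_ari, 1)
  expect_equal(same$jaccard, 1)
  # planted structure survives replicate noise; pure noise does not
  planted <- replicateStability(lapply(1:4, mk), ids, k = 3)
  noise <- replicateStability(lapply(11:14, function(s) mk(s, FALSE)),
                              ids, k = 3)
  expect_gt(planted$mean_ari, noise$mean_ari)
  expect_lt(abs(noise$mean_ari), 0.35)
  expect_error(replicateStability(list(m1), ids, k = 3), ">= 2")
})

test_that("expression-radius correlation recovers planted gradients", {
  set.seed(13)
  r <- runif(300, 0, 3)
  exact <- expressionRadialCorrelation(-r, r)
  expect_equal(exact$r, -1)
  # planted linear gradient with slope -0.3 SD is recovered within 0.1
  val <- -0.3 * scale(r)[, 1] + rnorm(300) * sqrt(1 - 0.09)
  rec <- expressionRadialCorrelation(val, r)
  expect_lt(abs(rec$r - (-0.3)), 0.1)
  # independent values: small |r|
  indep <- expressionRadialCorrelation(rnorm(300), r)
  expect_lt(abs(indep$r), 0.2)
  flat <- expressionRadialCorrelation(rep(1, 10), runif(10))
  expect_true(is.na(flat$r))
  expect_match(flat$note, "zero variance")
  expect_error(expressionRadialCorrelation(1:2, 1:2), ">= 3")
})
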