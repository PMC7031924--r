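## Synthetic-data generator: every input the pipeline consumes, with the
## statistical structure the downstream analysis assumes and with planted
## ground truth recorded in a manifest so each stage has an oracle.

#' Configuration for the synthetic study generator
#'
#' Defaults emulate the study conditions of the analysis this package
#' implements: ~Mb chromatin domains (the reference segmentation averages
#' 1.3 Mb), a spherical nucleus of radius 3.0 model units, power-law contact
#' distance decay with exponent 1, and risk sets sized like typical GWAS
#' summaries (hundreds of index SNPs / LD loci).
#'
#' @param chromosome_lengths named numeric vector, chromosome lengths in bp.
#' @param n_domains_per_chrom integer (scalar or per-chromosome), number of
#'   contiguous domains each chromosome is tiled into.
#' @param nucleus_radius nucleus radius in model units (default 3.0).
#' @param decay_exponent power-law exponent of contact distance decay
#'   (default 1).
#' @param sequencing_depth expected count at one-bin separation (the Poisson
#'   base mean lambda0).
#' @param trans_depth_fraction trans-chromosomal Poisson mean as a fraction
#'   of \code{sequencing_depth} (default 0.01); 0 disables trans background.
#' @param resolution contact-matrix bin size in bp (default 40000).
#' @param planted_hotspots list of \code{list(bead_ids, center, spread)}:
#'   beads drawn uniformly within \code{spread} of \code{center}.
#' @param planted_loop_pairs list of \code{list(bin_i, bin_j, fold)}: bin
#'   pairs whose Poisson mean is multiplied by \code{fold}.
#' @param shared_fraction fraction of (haploid) domains seeded with both risk
#'   types, in [0, 1].
#' @param n_snps,n_loci number of trait-A index SNPs and trait-B risk loci.
#' @param locus_width_fraction locus width as a fraction of its domain width
#'   (default 0.1).
#' @param n_eqtls number of eQTL records.
#' @param eqtl_enrichment_fold eQTL placement density in target bins relative
#'   to background (1 = no enrichment, 0 = excluded from targets).
#' @param seed master seed; per-stage substreams are derived from it.
#' @return A validated list of class \code{SyntheticConfig}.
#' @export
syntheticConfig <- function(chromosome_lengths = c(chr1 = 60e6, chr2 = 50e6,
                                                   chr3 = 40e6),
                            n_domains_per_chrom = 40L,
                            nucleus_radius = 3.0,
                            decay_exponent = 1.0,
                            sequencing_depth = 20,
                            trans_depth_fraction = 0.001,
                            resolution = 40000,
                            planted_hotspots = list(),
                            planted_loop_pairs = list(),
                            shared_fraction = 0.05,
                            n_snps = 289L,
                            n_loci = 139L,
                            locus_width_fraction = 0.1,
                            n_eqtls = 1000L,
                            eqtl_enrichment_fold = 1.0,
                            seed = 1L) {
  cfg <- list(chromosome_lengths = chromosome_lengths,
              n_domains_per_chrom = n_domains_per_chrom,
              nucleus_radius = nucleus_radius,
              decay_exponent = decay_exponent,
              sequencing_depth = sequencing_depth,
              trans_depth_fraction = trans_depth_fraction,
              resolution = resolution,
              planted_hotspots = planted_hotspots,
              planted_loop_pairs = planted_loop_pairs,
              shared_fraction = shared_fraction,
              n_snps = as.integer(n_snps),
              n_loci = as.integer(n_loci),
              locus_width_fraction = locus_width_fraction,
              n_eqtls = as.integer(n_eqtls),
              eqtl_enrichment_fold = eqtl_enrichment_fold,
              seed = as.integer(seed))
  validateSyntheticConfig(cfg)
  class(cfg) <- "SyntheticConfig"
  cfg
}

validateSyntheticConfig <- function(cfg) {
  if (is.null(names(cfg$chromosome_lengths)) ||
      anyDuplicated(names(cfg$chromosome_lengths)))
    stop("invalid config: chromosome lengths must be uniquely named")
  if (any(cfg$chromosome_lengths <= 0))
    stop("invalid config: zero-length chromosome")
  if (any(cfg$n_domains_per_chrom < 1))
    stop("invalid config: n_domains_per_chrom must be >= 1")
  if (cfg$nucleus_radius <= 0)
    stop("invalid config: nucleus_radius must be positive")
  if (cfg$decay_exponent < 0)
    stop("invalid config: decay_exponent must be >= 0")
  if (cfg$shared_fraction < 0 || cfg$shared_fraction > 1)
    stop("invalid config: shared_fraction must lie in [0, 1]")
  if (cfg$n_snps < 0 || cfg$n_loci < 0)
    stop("invalid config: n_snps and n_loci must be >= 0")
  for (hs in cfg$planted_hotspots) {
    if (sqrt(sum(hs$center^2)) > cfg$nucleus_radius)
      stop("invalid config: planted cluster_center outside the nucleus")
  }
  for (lp in cfg$planted_loop_pairs) {
    if (lp$fold < 0) stop("invalid config: negative fold_enrichment")
  }
  invisible(TRUE)
}

## Deterministic per-stage substreams from the master seed: keeps every stage
## reproducible in isolation and all seeds below 2^31.
stageSeed <- function(cfg, stage) {
  offsets <- c(genome = 11L, coords = 23L, risk = 37L, contacts = 53L,
               eqtl = 71L)
  (cfg$seed %% 100000000L) * 19L + offsets[[stage]]
}

#' Generate a genome assembly and diploid domain segmentation
#'
#' Each chromosome is tiled into contiguous, non-overlapping domains (uniform
#' tiling; the last domain absorbs rounding). Every domain is emitted twice,
#' once per haplotype ("A" and "B"), as in a diploid bead model.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @return list with \code{assembly} (\code{Seqinfo}) and \code{domains}
#'   (\code{GRanges} with \code{domain_id}, \code{bead_id},
#'   \code{haplotype}).
#' @export
simulateGenome <- function(config) {
  validateSyntheticConfig(config)
  lens <- config$chromosome_lengths
  ndom <- rep_len(as.integer(config$n_domains_per_chrom), length(lens))
  assembly <- Seqinfo(seqnames = names(lens), seqlengths = as.integer(lens))
  parts <- lapply(seq_along(lens), function(k) {
    bounds <- round(seq(0, lens[[k]], length.out = ndom[k] + 1))
    GRanges(names(lens)[k],
            IRanges(start = bounds[-length(bounds)] + 1, end = bounds[-1]),
            seqinfo = assembly)
  })
  hap <- do.call(c, parts)
  hap$domain_id <- sprintf("%s:%d-%d", as.character(seqnames(hap)),
                           start(hap) - 1L, end(hap))
  domains <- rep(hap, each = 2)
  domains$haplotype <- rep(c("A", "B"), length(hap))
  domains$bead_id <- paste0(domains$domain_id, "_", domains$haplotype)
  list(assembly = assembly, domains = domains)
}

## Uniform draws in the 3D ball of given radius.
runifBall <- function(n, radius) {
  v <- matrix(rnorm(3 * n), ncol = 3)
  v <- v / sqrt(rowSums(v^2))
  r <- radius * runif(n)^(1 / 3)
  v * r
}

#' Generate bead coordinates for a diploid segmentation
#'
#' Non-planted beads are uniform in the nuclear ball; beads listed in a
#' planted hot spot are drawn uniformly within \code{spread} of the cluster
#' center (and kept inside the nucleus).
#'
#' @param domains diploid segmentation from \code{\link{simulateGenome}}.
#' @param config a \code{\link{syntheticConfig}}.
#' @return A \code{\link{BeadModel}}.
#' @export
simulateCoordinates <- function(domains, config) {
  validateSyntheticConfig(config)
  set.seed(stageSeed(config, "coords"))
  R <- config$nucleus_radius
  ids <- as.character(domains$bead_id)
  coords <- runifBall(length(ids), R)
  rownames(coords) <- ids
  for (hs in config$planted_hotspots) {
    bad <- setdiff(hs$bead_ids, ids)
    if (length(bad))
      stop("invalid config: planted bead id(s) not in segmentation: ",
           paste(bad, collapse = ", "))
    m <- length(hs$bead_ids)
    pts <- matrix(rep(hs$center, each = m), ncol = 3) +
      if (hs$spread > 0) runifBall(m, hs$spread) else 0
    # confine to the nucleus (relevant only when center + spread graze the wall)
    norms <- sqrt(rowSums(pts^2))
    over <- norms > R
    if (any(over)) pts[over, ] <- pts[over, , drop = FALSE] * (R / norms[over])
    coords[hs$bead_ids, ] <- pts
  }
  BeadModel(domains, coords, beadRadius = 0, nucleusRadius = R)
}

#' Generate trait-A SNP and trait-B locus risk sets with planted sharing
#'
#' Exactly \code{ceiling(shared_fraction * n_haploid_domains)} domains (capped
#' at \code{min(n_snps, n_loci)}) receive both one SNP and one locus; the
#' remaining SNPs and loci are placed in disjoint domain pools so no sharing
#' arises by accident. The planted shared domain ids are recorded in the
#' returned manifest.
#'
#' @param domains diploid segmentation from \code{\link{simulateGenome}}.
#' @param config a \code{\link{syntheticConfig}}.
#' @return list with \code{snps} (\code{GRanges}, width 1), \code{loci}
#'   (\code{GRanges}) and \code{shared_domains} (character vector of haploid
#'   domain ids).
#' @export
simulateRiskSets <- function(domains, config) {
  validateSyntheticConfig(config)
  set.seed(stageSeed(config, "risk"))
  hap <- domains[domains$haplotype == "A"]
  nH <- length(hap)
  nShared <- min(ceiling(config$shared_fraction * nH),
                 config$n_snps, config$n_loci)
  if (nShared > nH)
    stop("invalid config: requested shared count exceeds domain count")
  sharedIdx <- sort(sample(nH, nShared))
  rest <- setdiff(seq_len(nH), sharedIdx)
  half <- length(rest) %/% 2
  snpPool <- rest[seq_len(half)]
  locPool <- rest[setdiff(seq_along(rest), seq_len(half))]

  placeSnp <- function(idx) {
    d <- hap[idx]
    pos <- start(d) + floor(runif(length(d)) * (width(d) - 1))
    GRanges(seqnames(d), IRanges(pos, width = 1), seqinfo = seqinfo(hap))
  }
  placeLocus <- function(idx) {
    d <- hap[idx]
    w <- pmax(1L, as.integer(round(width(d) * config$locus_width_fraction)))
    s <- start(d) + floor(runif(length(d)) * (width(d) - w))
    GRanges(seqnames(d), IRanges(s, width = w), seqinfo = seqinfo(hap))
  }

  nSnpExtra <- config$n_snps - nShared
  nLocExtra <- config$n_loci - nShared
  snpExtraPool <- if (length(snpPool)) snpPool else sharedIdx
  locExtraPool <- if (length(locPool)) locPool else sharedIdx
  if (nSnpExtra > 0 && !length(snpExtraPool))
    stop("invalid config: no domains available for SNP placement")
  if (nLocExtra > 0 && !length(locExtraPool))
    stop("invalid config: no domains available for locus placement")

  snpIdx <- c(sharedIdx,
              if (nSnpExtra > 0)
                sample(snpExtraPool, nSnpExtra, replace = TRUE))
  locIdx <- c(sharedIdx,
              if (nLocExtra > 0)
                sample(locExtraPool, nLocExtra, replace = TRUE))
  snps <- if (length(snpIdx)) placeSnp(snpIdx) else
    GRanges(seqinfo = seqinfo(hap))
  loci <- if (length(locIdx)) placeLocus(locIdx) else
    GRanges(seqinfo = seqinfo(hap))
  if (length(snps)) snps$snp_id <- sprintf("snpA_%04d", seq_along(snps))
  if (length(loci)) loci$locus_id <- sprintf("locB_%04d", seq_along(loci))
  list(snps = snps, loci = loci,
       shared_domains = hap$domain_id[sharedIdx])
}

#' Generate a raw contact matrix with power-law distance decay
#'
#' Intra-chromosomal counts at bin separation s are Poisson with mean
#' \code{sequencing_depth * s^-decay_exponent}; planted pairs have their mean
#' multiplied by \code{fold}. Trans-chromosomal background (if enabled) is
#' Poisson with mean \code{sequencing_depth * trans_depth_fraction}. Only
#' non-zero upper-triangle triplets are stored.
#'
#' @param bins bin table \code{GRanges} from \code{\link{binTable}}.
#' @param config a \code{\link{syntheticConfig}}.
#' @return A raw \code{\link{ContactMap}}.
#' @export
simulateContacts <- function(bins, config) {
  validateSyntheticConfig(config)
  set.seed(stageSeed(config, "contacts"))
  lam0 <- config$sequencing_depth
  alpha <- config$decay_exponent
  chroms <- as.character(seqnames(bins))
  pieces <- list()
  for (ch in unique(chroms)) {
    idx <- bins$bin_id[chroms == ch]
    n <- length(idx)
    if (n < 2 || lam0 <= 0) next
    # all upper-triangle pairs, vectorized: for each i, partners i+1..n
    i0 <- rep.int(seq_len(n - 1), (n - 1):1)
    j0 <- sequence((n - 1):1) + i0
    mu <- lam0 * (j0 - i0)^(-alpha)
    val <- rpois(length(mu), mu)
    nz <- val > 0
    pieces[[ch]] <- data.frame(i = idx[i0[nz]], j = idx[j0[nz]],
                               value = val[nz])
  }
  tf <- config$trans_depth_fraction
  if (tf > 0 && lam0 > 0 && length(unique(chroms)) > 1) {
    # trans pairs share one Poisson mean, so draw the number of non-zero
    # pairs Binomial(N, 1 - exp(-mu)), place them uniformly among distinct
    # trans pairs, and give each a zero-truncated Poisson value -- exactly
    # the law of independent Poisson draws over all trans pairs, without
    # enumerating them
    mu <- lam0 * tf
    nChromBins <- table(chroms)[unique(chroms)]
    nTotal <- length(bins)
    nTrans <- (nTotal * (nTotal - 1) - sum(nChromBins * (nChromBins - 1))) / 2
    k <- stats::rbinom(1, nTrans, 1 - exp(-mu))
    if (k > 0) {
      picked <- matrix(integer(), 0, 2)
      while (nrow(picked) < k) {
        cand <- matrix(sample.int(nTotal, 2 * (k - nrow(picked)) * 2,
                                  replace = TRUE), ncol = 2)
        cand <- cbind(pmin(cand[, 1], cand[, 2]), pmax(cand[, 1], cand[, 2]))
        cand <- cand[chroms[cand[, 1]] != chroms[cand[, 2]], , drop = FALSE]
        picked <- unique(rbind(picked, cand))
      }
      picked <- picked[seq_len(k), , drop = FALSE]
      # zero-truncated Poisson via inverse-cdf on the conditional tail
      u <- runif(k)
      val <- stats::qpois(stats::ppois(0, mu) + u * (1 - stats::ppois(0, mu)),
                          mu)
      pieces[["__trans__"]] <- data.frame(i = bins$bin_id[picked[, 1]],
                                          j = bins$bin_id[picked[, 2]],
                                          value = val)
    }
  }
  px <- if (length(pieces)) do.call(rbind, pieces)
        else data.frame(i = integer(), j = integer(), value = numeric())
  rownames(px) <- NULL
  for (lp in config$planted_loop_pairs) {
    lo <- min(lp$bin_i, lp$bin_j)
    hi <- max(lp$bin_i, lp$bin_j)
    sameChrom <- chroms[lo] == chroms[hi]
    mu <- if (sameChrom) {
      sep <- abs(match(hi, bins$bin_id[chroms == chroms[hi]]) -
                 match(lo, bins$bin_id[chroms == chroms[lo]]))
      lam0 * sep^(-alpha) * lp$fold
    } else lam0 * tf * lp$fold
    px <- px[!(px$i == lo & px$j == hi), , drop = FALSE]
    v <- rpois(1, mu)
    if (v > 0) px <- rbind(px, data.frame(i = lo, j = hi, value = v))
  }
  ContactMap(bins, px, kind = "raw")
}

#' Generate an eQTL catalog with controllable bin enrichment
#'
#' eQTL positions are placed bin by bin with sampling weight proportional to
#' bin width, multiplied by \code{eqtl_enrichment_fold} for bins in
#' \code{target_bins}. Each record carries a pseudo FDR drawn log-uniformly,
#' so roughly half pass the conventional significance cut of 1e-8.
#'
#' @param bins bin table \code{GRanges}.
#' @param target_bins integer vector of bin ids to enrich (subset of the bin
#'   table).
#' @param config a \code{\link{syntheticConfig}}.
#' @return data.frame with columns \code{chrom}, \code{pos} (0-based bp),
#'   \code{gene}, \code{fdr}.
#' @export
simulateEqtls <- function(bins, target_bins, config) {
  validateSyntheticConfig(config)
  if (length(target_bins) && !all(target_bins %in% bins$bin_id))
    stop("invalid config: target_bins must be a subset of the bin table")
  set.seed(stageSeed(config, "eqtl"))
  n <- config$n_eqtls
  if (n == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      gene = character(), fdr = numeric()))
  w <- as.numeric(width(bins))
  w[bins$bin_id %in% target_bins] <- w[bins$bin_id %in% target_bins] *
    config$eqtl_enrichment_fold
  if (all(w == 0)) stop("invalid config: all placement weights are zero")
  pick <- sample(length(bins), n, replace = TRUE, prob = w)
  pos0 <- (start(bins)[pick] - 1L) + floor(runif(n) * width(bins)[pick])
  data.frame(chrom = as.character(seqnames(bins))[pick],
             pos = as.integer(pos0),
             gene = sprintf("G%04d", pick),
             fdr = 10^(-runif(n, 0, 16)))
}

#' Generate a complete synthetic study with planted ground truth
#'
#' Runs every generator stage from one config and returns all inputs the
#' pipeline consumes plus a manifest of planted truth (shared domain ids,
#' planted hot-spot memberships, planted loop pairs, eQTL target bins).
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @param eqtl_target_bins optional integer bin ids for eQTL enrichment; by
#'   default the anchor bins of planted loop pairs (or none).
#' @return list with \code{assembly}, \code{domains}, \code{model},
#'   \code{snps}, \code{loci}, \code{bins}, \code{contacts} (raw
#'   \code{ContactMap}), \code{eqtls}, and \code{manifest}.
#' @export
simulateStudy <- function(config, eqtl_target_bins = NULL) {
  gen <- simulateGenome(config)
  model <- simulateCoordinates(gen$domains, config)
  risk <- simulateRiskSets(gen$domains, config)
  bins <- binTable(gen$assembly, config$resolution)
  contacts <- simulateContacts(bins, config)
  if (is.null(eqtl_target_bins)) {
    eqtl_target_bins <- unique(unlist(lapply(config$planted_loop_pairs,
                                             function(lp) c(lp$bin_i, lp$bin_j))))
    if (is.null(eqtl_target_bins)) eqtl_target_bins <- integer()
  }
  eqtls <- simulateEqtls(bins, eqtl_target_bins, config)
  manifest <- list(seed = config$seed,
                   shared_domains = risk$shared_domains,
                   planted_hotspots = lapply(config$planted_hotspots,
                                             function(h) h$bead_ids),
                   planted_loop_pairs = config$planted_loop_pairs,
                   eqtl_target_bins = eqtl_target_bins,
                   eqtl_enrichment_fold = config$eqtl_enrichment_fold)
  list(assembly = gen$assembly, domains = gen$domains, model = model,
       snps = risk$snps, loci = risk$loci, bins = bins, contacts = contacts,
       eqtls = eqtls, manifest = manifest)
}

#' Coverage-normalize a raw contact map
#'
#' Square-root vanilla-coverage balancing: each value is divided by the
#' square root of the product of its two bins' marginal totals, then scaled
#' so the overall sum is preserved. Stands in for iterative (ICE) balancing
#' at the scale of the synthetic maps.
#'
#' @param x a raw \code{ContactMap}.
#' @return A normalized \code{ContactMap}.
#' @export
normalizeContacts <- function(x) {
  stopifnot(is(x, "ContactMap"))
  if (contactKind(x) == "normalized") return(x)
  px <- x@pixels
  if (nrow(px) == 0) return(ContactMap(x@bins, px, kind = "normalized",
                                       resolution = x@resolution))
  marg <- numeric(length(x@bins))
  agg <- rowsum(c(px$value, px$value), c(px$i, px$j))
  marg[as.integer(rownames(agg))] <- agg[, 1]
  val <- px$value / sqrt(marg[px$i] * marg[px$j])
  val <- val * sum(px$value) / sum(val)
  ContactMap(x@bins, data.frame(i = px$i, j = px$j, value = val),
             kind = "normalized", resolution = x@resolution)
}

#' Write all synthetic study inputs to a directory
#'
#' Emits the external-format files a real study would provide: domain BED and
#' gtrack, bead-coordinate TSV, HiC-Pro matrix + abs.bed, risk-set BED files,
#' eQTL TSV, and a JSON manifest of planted truth.
#'
#' @param study result of \code{\link{simulateStudy}}.
#' @param outdir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
writeStudy <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(domains_bed = file.path(outdir, "domains.bed"),
             gtrack = file.path(outdir, "model.gtrack"),
             coords = file.path(outdir, "bead_coordinates.tsv"),
             matrix = file.path(outdir, "contacts.matrix"),
             abs_bed = file.path(outdir, "contacts_abs.bed"),
             snps = file.path(outdir, "snps_traitA.bed"),
             loci = file.path(outdir, "loci_traitB.bed"),
             eqtls = file.path(outdir, "eqtls.tsv"),
             manifest = file.path(outdir, "manifest.json"))
  writeBed(study$domains[study$domains$haplotype == "A"],
           paths["domains_bed"], names = study$domains$domain_id[
             study$domains$haplotype == "A"])
  writeGtrack(study$domains, paths["gtrack"])
  writeBeadCoordinates(study$model, paths["coords"])
  writeHicproMatrix(study$contacts, paths["matrix"], paths["abs_bed"])
  writeBed(study$snps, paths["snps"], names = study$snps$snp_id)
  writeBed(study$loci, paths["loci"], names = study$loci$locus_id)
  writeEqtls(study$eqtls, paths["eqtls"])
  jsonlite::write_json(study$manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
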