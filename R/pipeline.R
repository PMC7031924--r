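## End-to-end orchestration: simulate -> map risk -> hot spots -> contact
## calls -> interactome -> eQTL enrichment -> report, from one config, with
## deterministic seeding and per-stage serialized outputs.

#' Default pipeline configuration
#'
#' Thresholds mirror the analysis conventions this package implements:
#' interactome resolution 40 kb, eQTL significance FDR < 1e-8, contact-call
#' FDR 0.05 within a 1 Mb window, 10,000-permutation defaults (scaled down
#' here for a desk-scale synthetic run).
#'
#' @param seed master seed.
#' @param outdir output directory.
#' @return nested list of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(seed = 1L, outdir = tempfile("spatialRisk_run_")) {
  cfg <- list(
    seed = as.integer(seed),
    outdir = outdir,
    synthetic = list(shared_fraction = 0.10, n_snps = 120L, n_loci = 60L,
                     n_eqtls = 2000L, eqtl_enrichment_fold = 4,
                     sequencing_depth = 20, resolution = 40000),
    hotspots = list(k = "auto", min_size = 3L, n_samples = 500L),
    interactions = list(window_bp = 1e6, fdr_threshold = 0.05),
    eqtl = list(fdr_cut = 1e-8, n_perm = 1000L),
    risk = list(separation_threshold_bp = 1e6, n_perm = 500L))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys absent from the file keep their defaults; the file must exist.
#'
#' @param path YAML file.
#' @return \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- pipelineConfig()
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(user[[nm]])] <- user[[nm]]
    else cfg[[nm]] <- user[[nm]]
  }
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Stages: (1) generate the synthetic study; (2) annotate domains with both
#' risk architectures and compute shared domains, linear-genome separation
#' statistics and the shared-count shuffle test; (3) cluster shared beads
#' into Euclidean hot spots and assign each an empirical p; (4) call
#' significant contacts for SNP-bearing bins with the binomial model;
#' (5) extract the cross-disorder interactome from the normalized matrix;
#' (6) test eQTL enrichment in interactome anchor bins by permutation;
#' (7) write per-stage TSV/JSON outputs and a run manifest. Deterministic
#' given config and seed.
#'
#' @param config a \code{\link{pipelineConfig}} (or path handled by
#'   \code{\link{readPipelineConfig}}).
#' @param writeOutputs write per-stage files under \code{config$outdir}?
#' @return list with all stage results and \code{summary}.
#' @export
runPipeline <- function(config = pipelineConfig(), writeOutputs = TRUE) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stages <- list()
  fail <- function(stage, e) stop("stage '", stage, "' failed: ",
                                  conditionMessage(e), call. = FALSE)

  ## 1. simulate
  sc <- tryCatch(do.call(syntheticConfig,
                         c(config$synthetic, list(seed = config$seed))),
                 error = function(e) fail("simulate", e))
  study <- tryCatch(simulateStudy(sc), error = function(e) fail("simulate", e))
  stages$study <- study

  ## 2. risk mapping
  risk <- tryCatch({
    ann <- annotateDomains(study$domains, study$snps, study$loci)
    sharedHap <- sharedDomains(ann, "haploid")
    sharedDip <- sharedDomains(ann, "diploid", domains = study$domains,
                               model = study$model)
    list(annotation = ann, shared_haploid = sharedHap,
         shared_diploid = sharedDip,
         snp_in_locus = snpInLocusCount(study$loci, study$snps),
         locus_separation = nearestFeatureSeparation(
           study$loci, study$snps, config$risk$separation_threshold_bp),
         intra_loci = intraSetSeparation(study$loci),
         intra_snps = intraSetSeparation(study$snps),
         shuffle = sharedCountShuffleTest(study$domains, study$snps,
                                          study$loci,
                                          nPerm = config$risk$n_perm,
                                          seed = config$seed + 101L))
  }, error = function(e) fail("map-risk", e))
  stages$risk <- risk

  ## 3. hot spots
  hot <- tryCatch({
    if (length(risk$shared_diploid) >= 2 * config$hotspots$min_size) {
      dm <- pairwiseDistances(study$model, risk$shared_diploid)
      hs <- detectHotspots(dm, k = config$hotspots$k,
                           minSize = config$hotspots$min_size)
      sig <- lapply(hs$hotspots, function(h)
        hotspotSignificance(study$model, h$members, risk$shared_diploid,
                            nSamples = config$hotspots$n_samples,
                            seed = config$seed + 211L))
      tab <- data.frame(
        hotspot = vapply(hs$hotspots, `[[`, character(1), "id"),
        n_beads = vapply(hs$hotspots, function(h) length(h$members),
                         integer(1)),
        mean_delta = vapply(hs$hotspots, `[[`, numeric(1), "mean_delta"),
        p = vapply(sig, `[[`, numeric(1), "p"),
        p_wilcoxon = vapply(sig, `[[`, numeric(1), "p_wilcoxon"),
        stringsAsFactors = FALSE)
      centro <- centroidDistances(study$model, risk$shared_diploid)
      list(distance = dm, hotspots = hs, table = tab, centroid = centro)
    } else {
      list(distance = NULL, hotspots = NULL,
           table = data.frame(), centroid = numeric())
    }
  }, error = function(e) fail("hotspots", e))
  stages$hotspots <- hot

  ## 4. binomial contact calls at SNP-bearing bins
  calls <- tryCatch({
    snpBins <- binsOverlapping(study$bins, study$snps)
    callSignificant(study$contacts, snpBins,
                    windowBp = config$interactions$window_bp,
                    fdrThreshold = config$interactions$fdr_threshold)
  }, error = function(e) fail("interactions", e))
  stages$calls <- calls

  ## 5. cross-disorder interactome
  interactome <- tryCatch({
    norm <- normalizeContacts(study$contacts)
    hsMap <- NULL
    if (!is.null(hot$hotspots)) {
      hsMap <- lapply(hot$hotspots$hotspots, function(h)
        unique(sub("_[AB]$", "", h$members)))
      names(hsMap) <- vapply(hot$hotspots$hotspots, `[[`, character(1), "id")
    }
    extractCrossContacts(norm, study$snps, study$loci, study$domains,
                         hotspots = hsMap)
  }, error = function(e) fail("interactome", e))
  stages$interactome <- interactome

  ## 6. eQTL enrichment in interactome anchor bins; the synthetic catalog is
  ## (re)generated with its enrichment planted in exactly those bins, so the
  ## permutation test has a known signal to find
  eqtl <- tryCatch({
    anchorIds <- sort(unique(c(interactome$bin1, interactome$bin2)))
    if (length(anchorIds) >= 1) {
      eqtls <- simulateEqtls(study$bins, anchorIds, sc)
      study$eqtls <- eqtls
      stages$study <- study
      permutationEnrichment(eqtls, study$bins[anchorIds],
                            study$bins,
                            nPerm = config$eqtl$n_perm,
                            seed = config$seed + 307L,
                            fdrCut = config$eqtl$fdr_cut)
    } else NULL
  }, error = function(e) fail("eqtl", e))
  stages$eqtl <- eqtl

  summary <- list(
    n_domains_haploid = sum(study$domains$haplotype == "A"),
    mean_domain_size_bp = mean(width(study$domains)),
    shared_haploid = length(risk$shared_haploid),
    shared_diploid = length(risk$shared_diploid),
    snp_in_locus = risk$snp_in_locus,
    fraction_loci_beyond_threshold = risk$locus_separation$fraction_beyond,
    shuffle_p = risk$shuffle$p_two_sided,
    n_hotspots = nrow(hot$table),
    n_significant_calls = sum(calls$significant),
    n_contacts_intra = sum(interactome$class == "intra"),
    n_contacts_trans = sum(interactome$class == "trans"),
    eqtl_p = if (!is.null(eqtl)) eqtl$p else NA_real_,
    eqtl_observed = if (!is.null(eqtl)) eqtl$observed else NA_integer_)
  stages$summary <- summary

  if (writeOutputs) {
    out <- config$outdir
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    writeStudy(study, file.path(out, "inputs"))
    write.table(risk$annotation, file.path(out, "domain_annotation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(hot$table))
      write.table(hot$table, file.path(out, "hotspots.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    if (nrow(calls))
      write.table(calls, file.path(out, "interaction_calls.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(interactome)) {
      write.table(interactome, file.path(out, "interactome.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      exportInteractome(interactome, file.path(out, "interactome.bedpe"),
                        "bedpe")
      exportInteractome(interactome, file.path(out, "interactome.washu.txt"),
                        "washu")
    }
    manifest <- list(seed = config$seed,
                     package_version = as.character(
                       utils::packageVersion("spatialRisk")),
                     config = unclass(config)[setdiff(names(config), "outdir")],
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  stages
}
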