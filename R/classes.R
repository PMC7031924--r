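## Core S4 containers: diploid bead model and sparse binned contact map.
##
## Conventions used throughout the package:
##  * GRanges are 1-based closed (the Bioconductor standard); all text formats
##    (BED, gtrack, HiC-Pro abs.bed) are 0-based half-open and converted at
##    the I/O boundary.
##  * Bead ids are "<domain id>_<haplotype>", e.g. "chr1:0-1000000_A"; the
##    domain id uses the 0-based half-open span so it matches the BED/gtrack
##    representation byte for byte.

#' BeadModel: a diploid 3D chromatin-domain model
#'
#' One bead per chromatin domain copy (haplotypes "A" and "B"), each with an
#' (x, y, z) coordinate in model units, confined to a spherical nucleus of
#' radius \code{nucleusRadius} centred at the origin.
#'
#' @slot beads \code{GRanges} with metadata columns \code{bead_id},
#'   \code{domain_id} and \code{haplotype}.
#' @slot coords numeric matrix, one row per bead (rownames = bead ids),
#'   columns x, y, z, in model units.
#' @slot beadRadius single numeric, bead radius in model units.
#' @slot nucleusRadius single numeric, nucleus radius in model units.
#' @export
setClass("BeadModel",
         representation(beads = "GRanges", coords = "matrix",
                        beadRadius = "numeric", nucleusRadius = "numeric"))

setValidity("BeadModel", function(object) {
  msg <- character()
  ids <- object@beads$bead_id
  if (is.null(ids)) return("beads must carry a 'bead_id' metadata column")
  if (anyDuplicated(ids)) msg <- c(msg, "bead ids must be unique")
  if (nrow(object@coords) != length(object@beads))
    msg <- c(msg, "coords must have one row per bead")
  if (ncol(object@coords) != 3) msg <- c(msg, "coords must have 3 columns")
  if (!identical(rownames(object@coords), as.character(ids)))
    msg <- c(msg, "coords rownames must equal bead ids, in order")
  if (length(object@nucleusRadius) != 1 || object@nucleusRadius <= 0)
    msg <- c(msg, "nucleusRadius must be a single positive number")
  if (nrow(object@coords) > 0) {
    norms <- sqrt(rowSums(object@coords^2))
    lim <- object@nucleusRadius + object@beadRadius + 1e-8
    if (any(norms > lim))
      msg <- c(msg, sprintf("%d bead(s) lie outside the nucleus (max norm %.4f > %.4f)",
                            sum(norms > lim), max(norms), lim))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a BeadModel
#'
#' @param beads \code{GRanges} of diploid domain beads with \code{bead_id},
#'   \code{domain_id}, \code{haplotype} metadata columns (see
#'   \code{\link{simulateGenome}}).
#' @param coords numeric matrix of bead coordinates (n x 3), rows in bead
#'   order or named by bead id.
#' @param beadRadius bead radius, model units.
#' @param nucleusRadius nucleus radius, model units (default 3.0).
#' @return A \code{BeadModel}.
#' @export
BeadModel <- function(beads, coords, beadRadius = 0, nucleusRadius = 3.0) {
  coords <- as.matrix(coords)
  colnames(coords) <- c("x", "y", "z")
  ids <- as.character(beads$bead_id)
  if (!is.null(rownames(coords))) {
    missing <- setdiff(ids, rownames(coords))
    if (length(missing))
      stop("missing coordinate for bead(s): ", paste(missing, collapse = ", "))
    coords <- coords[ids, , drop = FALSE]
  } else {
    rownames(coords) <- ids
  }
  new("BeadModel", beads = beads, coords = coords,
      beadRadius = beadRadius, nucleusRadius = nucleusRadius)
}

#' @describeIn BeadModel-class bead annotation as \code{GRanges}
#' @param x,object a \code{BeadModel}
#' @export
setGeneric("beads", function(x) standardGeneric("beads"))
#' @export
setMethod("beads", "BeadModel", function(x) x@beads)

#' @describeIn BeadModel-class coordinate matrix (model units)
#' @export
setGeneric("beadCoords", function(x) standardGeneric("beadCoords"))
#' @export
setMethod("beadCoords", "BeadModel", function(x) x@coords)

#' @describeIn BeadModel-class bead ids
#' @export
setGeneric("beadIds", function(x) standardGeneric("beadIds"))
#' @export
setMethod("beadIds", "BeadModel", function(x) as.character(x@beads$bead_id))

#' @describeIn BeadModel-class nucleus radius (model units)
#' @export
setGeneric("nucleusRadius", function(x) standardGeneric("nucleusRadius"))
#' @export
setMethod("nucleusRadius", "BeadModel", function(x) x@nucleusRadius)

setMethod("show", "BeadModel", function(object) {
  cat("BeadModel with", length(object@beads), "beads on",
      length(unique(as.character(seqnames(object@beads)))), "chromosome(s)\n")
  cat("  nucleus radius:", object@nucleusRadius, "model units;",
      "bead radius:", object@beadRadius, "\n")
  if (length(object@beads) > 0) {
    norms <- sqrt(rowSums(object@coords^2))
    cat(sprintf("  radial position: median %.3f, max %.3f\n",
                stats::median(norms), max(norms)))
  }
})

#' ContactMap: a sparse binned Hi-C contact matrix
#'
#' Upper-triangle triplet storage over a genome-wide bin table. Raw maps hold
#' integral counts; normalized maps (e.g. ICE-balanced) hold non-negative
#' reals. The binomial interaction caller requires \code{kind == "raw"};
#' interactome extraction requires \code{kind == "normalized"}.
#'
#' @slot bins \code{GRanges} bin table with integer \code{bin_id} metadata
#'   column (1-based, strictly increasing).
#' @slot pixels data.frame with columns \code{i}, \code{j} (bin ids,
#'   \code{i <= j}) and \code{value}.
#' @slot kind "raw" or "normalized".
#' @slot resolution bin size in bp.
#' @export
setClass("ContactMap",
         representation(bins = "GRanges", pixels = "data.frame",
                        kind = "character", resolution = "numeric"))

setValidity("ContactMap", function(object) {
  msg <- character()
  if (!object@kind %in% c("raw", "normalized"))
    msg <- c(msg, "kind must be 'raw' or 'normalized'")
  if (is.null(object@bins$bin_id) ||
      !identical(as.integer(object@bins$bin_id), seq_along(object@bins)))
    msg <- c(msg, "bins must carry bin_id == 1..n in order")
  px <- object@pixels
  if (!all(c("i", "j", "value") %in% names(px)))
    msg <- c(msg, "pixels must have columns i, j, value")
  else if (nrow(px) > 0) {
    if (any(px$i > px$j)) msg <- c(msg, "pixels must be upper-triangle (i <= j)")
    if (any(px$value < 0)) msg <- c(msg, "contact values must be non-negative")
    if (any(px$j > length(object@bins))) msg <- c(msg, "pixel bin id outside bin table")
    if (anyDuplicated(px$i * (length(object@bins) + 1) + px$j))
      msg <- c(msg, "duplicate (i, j) pixel")
    if (object@kind == "raw" && any(abs(px$value - round(px$value)) > 1e-9))
      msg <- c(msg, "raw contact values must be integral")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ContactMap
#'
#' Triplets are canonicalized to the upper triangle (i <= j); duplicate
#' entries after canonicalization are summed.
#'
#' @param bins bin table \code{GRanges} (see \code{\link{binTable}}).
#' @param pixels data.frame with columns \code{i}, \code{j}, \code{value}.
#' @param kind "raw" (integral counts) or "normalized".
#' @param resolution bin size in bp; inferred from the bin table if missing.
#' @return A \code{ContactMap}.
#' @export
ContactMap <- function(bins, pixels, kind = c("raw", "normalized"),
                       resolution = NULL) {
  kind <- match.arg(kind)
  if (is.null(bins$bin_id)) bins$bin_id <- seq_along(bins)
  if (is.null(resolution)) resolution <- max(width(bins))
  pixels <- as.data.frame(pixels)[, c("i", "j", "value")]
  if (nrow(pixels) > 0) {
    swap <- pixels$i > pixels$j
    if (any(swap)) {
      tmp <- pixels$i[swap]
      pixels$i[swap] <- pixels$j[swap]
      pixels$j[swap] <- tmp
    }
    key <- pixels$i * (length(bins) + 1) + pixels$j
    if (anyDuplicated(key)) {
      v <- rowsum(pixels$value, key)
      k <- as.numeric(rownames(v))
      pixels <- data.frame(i = k %/% (length(bins) + 1),
                           j = k %% (length(bins) + 1), value = v[, 1])
    }
    pixels <- pixels[order(pixels$i, pixels$j), , drop = FALSE]
    rownames(pixels) <- NULL
  }
  new("ContactMap", bins = bins, pixels = pixels, kind = kind,
      resolution = as.numeric(resolution))
}

#' @describeIn ContactMap-class bin table
#' @param x,object a \code{ContactMap}
#' @export
setGeneric("contactBins", function(x) standardGeneric("contactBins"))
#' @export
setMethod("contactBins", "ContactMap", function(x) x@bins)

#' @describeIn ContactMap-class triplet data.frame (i, j, value)
#' @export
setGeneric("contactPixels", function(x) standardGeneric("contactPixels"))
#' @export
setMethod("contactPixels", "ContactMap", function(x) x@pixels)

#' @describeIn ContactMap-class "raw" or "normalized"
#' @export
setGeneric("contactKind", function(x) standardGeneric("contactKind"))
#' @export
setMethod("contactKind", "ContactMap", function(x) x@kind)

#' @describeIn ContactMap-class bin size in bp
#' @export
setGeneric("contactResolution", function(x) standardGeneric("contactResolution"))
#' @export
setMethod("contactResolution", "ContactMap", function(x) x@resolution)

setMethod("show", "ContactMap", function(object) {
  cat("ContactMap (", object@kind, ") with ", nrow(object@pixels),
      " non-zero pixels over ", length(object@bins), " bins at ",
      object@resolution, " bp\n", sep = "")
})

#' Query contact values symmetrically
#'
#' Returns the stored value for unordered bin pairs; absent pairs are 0.
#'
#' @param x a \code{ContactMap}
#' @param i,j integer vectors of bin ids (recycled to common length).
#' @return numeric vector of contact values.
#' @export
contactValue <- function(x, i, j) {
  stopifnot(is(x, "ContactMap"))
  n <- max(length(i), length(j))
  i <- rep_len(as.integer(i), n)
  j <- rep_len(as.integer(j), n)
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  px <- x@pixels
  nb <- length(x@bins) + 1
  out <- px$value[match(lo * nb + hi, px$i * nb + px$j)]
  out[is.na(out)] <- 0
  out
}

#' Build a genome-wide bin table
#'
#' Tiles each chromosome at \code{resolution}; the last bin of a chromosome
#' may be short. Bins carry a 1-based integer \code{bin_id}, matching the
#' HiC-Pro abs.bed convention.
#'
#' @param assembly a \code{Seqinfo} or named vector of chromosome lengths (bp).
#' @param resolution bin size in bp.
#' @return \code{GRanges} bin table.
#' @export
binTable <- function(assembly, resolution) {
  if (!is(assembly, "Seqinfo")) {
    lens <- assembly
    assembly <- Seqinfo(seqnames = names(lens), seqlengths = as.integer(lens))
  }
  stopifnot(resolution >= 1)
  bins <- tileGenome(assembly, tilewidth = resolution, cut.last.tile.in.chrom = TRUE)
  bins$bin_id <- seq_along(bins)
  bins
}
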