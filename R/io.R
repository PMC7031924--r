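## Readers/writers for the text formats the pipeline touches. All external
## coordinates are 0-based half-open (BED convention); GRanges in memory are
## 1-based closed. Scores are written with 6 significant digits.

fmtScore <- function(x) formatC(signif(x, 6), format = "g", digits = 6,
                                width = 1)

checkAssembly <- function(gr, assembly) {
  if (is.null(assembly)) return(invisible(TRUE))
  lens <- if (is(assembly, "Seqinfo")) seqlengths(assembly) else assembly
  ch <- as.character(seqnames(gr))
  bad <- !ch %in% names(lens)
  if (any(bad))
    stop("coordinate(s) on chromosome(s) absent from assembly: ",
         paste(unique(ch[bad]), collapse = ", "))
  over <- end(gr) > lens[ch] | start(gr) < 1
  if (any(over))
    stop(sum(over), " coordinate(s) outside assembly bounds")
  invisible(TRUE)
}

#' Read a gtrack domain segmentation
#'
#' Parses the GTrack dialect used by chrom3D-style bead models: "##" lines
#' are metadata, a "###"-prefixed line names the columns (seqid, start, end,
#' id required; extra columns are kept verbatim and not interpreted), data
#' lines are tab-separated with 0-based half-open coordinates. Haplotype is
#' parsed from an "_A"/"_B" id suffix; ids without a suffix are unphased.
#'
#' @param path gtrack file.
#' @param assembly optional \code{Seqinfo} or named length vector; when
#'   given, out-of-assembly coordinates are rejected.
#' @return \code{GRanges} with \code{bead_id}, \code{domain_id},
#'   \code{haplotype} metadata columns (plus any extra gtrack columns).
#' @export
readGtrack <- function(path, assembly = NULL) {
  lines <- readLines(path)
  if (!length(lines)) stop("format error: empty gtrack file")
  headIdx <- grep("^###", lines)
  if (!length(headIdx))
    stop("format error: gtrack column header line ('###...') missing")
  cols <- strsplit(sub("^###", "", lines[headIdx[1]]), "\t")[[1]]
  need <- c("seqid", "start", "end", "id")
  if (!all(need %in% cols))
    stop("format error: gtrack header missing mandatory column(s): ",
         paste(setdiff(need, cols), collapse = ", "))
  dataIdx <- which(!startsWith(lines, "#") & nzchar(lines))
  if (!length(dataIdx)) {
    gr <- GRanges()
    gr$bead_id <- character()
    return(gr)
  }
  fields <- strsplit(lines[dataIdx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(cols)))
    stop("format error: line ", dataIdx[which(nf != length(cols))[1]],
         ": expected ", length(cols), " columns, found ",
         nf[which(nf != length(cols))[1]])
  m <- do.call(rbind, fields)
  colnames(m) <- cols
  startv <- suppressWarnings(as.numeric(m[, "start"]))
  endv <- suppressWarnings(as.numeric(m[, "end"]))
  bad <- which(is.na(startv) | is.na(endv) | startv < 0 | endv <= startv)
  if (length(bad))
    stop("format error: line ", dataIdx[bad[1]], ": invalid coordinates")
  ids <- m[, "id"]
  if (anyDuplicated(ids))
    stop("format error: duplicate bead id in gtrack")
  gr <- GRanges(m[, "seqid"], IRanges(startv + 1, endv))
  gr$bead_id <- ids
  gr$haplotype <- ifelse(endsWith(ids, "_A"), "A",
                         ifelse(endsWith(ids, "_B"), "B", "unphased"))
  gr$domain_id <- ifelse(gr$haplotype == "unphased", ids,
                         sub("_[AB]$", "", ids))
  extra <- setdiff(cols, need)
  for (cn in extra) mcols(gr)[[cn]] <- m[, cn]
  checkAssembly(gr, assembly)
  gr
}

#' Write a domain segmentation as gtrack
#'
#' @param domains \code{GRanges} with \code{bead_id} metadata column.
#' @param path output file.
#' @param radius optional bead radius column value.
#' @return invisibly, \code{path}.
#' @export
writeGtrack <- function(domains, path, radius = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##gtrack version: 1.0",
               "##track type: linear segments"), con)
  cols <- c("seqid", "start", "end", "id")
  if (!is.null(radius)) cols <- c(cols, "radius")
  writeLines(paste0("###", paste(cols, collapse = "\t")), con)
  df <- data.frame(seqid = as.character(seqnames(domains)),
                   start = start(domains) - 1L,
                   end = end(domains),
                   id = as.character(domains$bead_id))
  if (!is.null(radius)) df$radius <- radius
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read bead coordinates and join them to a segmentation
#'
#' @param path TSV with header columns \code{id, x, y, z} (optional
#'   \code{radius}).
#' @param domains segmentation \code{GRanges} (with \code{bead_id}); every
#'   bead must have a coordinate.
#' @param nucleusRadius nucleus radius in model units (default 3.0).
#' @return A \code{\link{BeadModel}}.
#' @export
readBeadCoordinates <- function(path, domains, nucleusRadius = 3.0) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("id", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("format error: coordinate table must have columns id, x, y, z")
  if (anyDuplicated(df$id))
    stop("format error: duplicate bead id in coordinate table: ",
         df$id[duplicated(df$id)][1])
  ids <- as.character(domains$bead_id)
  missing <- setdiff(ids, df$id)
  if (length(missing))
    stop("missing coordinate for bead(s): ", paste(missing, collapse = ", "))
  unmatched <- setdiff(df$id, ids)
  if (length(unmatched))
    warning(length(unmatched), " coordinate id(s) not in segmentation: ",
            paste(head(unmatched, 5), collapse = ", "))
  coords <- as.matrix(df[match(ids, df$id), c("x", "y", "z")])
  rownames(coords) <- ids
  beadRadius <- if ("radius" %in% names(df)) max(df$radius) else 0
  BeadModel(domains, coords, beadRadius = beadRadius,
            nucleusRadius = nucleusRadius)
}

#' Write bead coordinates as TSV
#'
#' @param model a \code{\link{BeadModel}}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeBeadCoordinates <- function(model, path) {
  df <- data.frame(id = beadIds(model), beadCoords(model),
                   radius = model@beadRadius)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a HiC-Pro triplet matrix and its abs.bed bin table
#'
#' The abs.bed file gives 0-based half-open bins with 1-based integer ids;
#' the matrix file holds tab-separated (i, j, value) triplets. Triplets with
#' i > j are canonicalized to the upper triangle.
#'
#' @param matrix_path HiC-Pro \code{.matrix} file.
#' @param bed_path matching \code{_abs.bed} file.
#' @param kind "raw" or "normalized".
#' @return A \code{\link{ContactMap}}.
#' @export
readHicproMatrix <- function(matrix_path, bed_path,
                             kind = c("raw", "normalized")) {
  kind <- match.arg(kind)
  bed <- read.table(bed_path, header = FALSE, sep = "\t",
                    col.names = c("chrom", "start", "end", "id"),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(bed$id)) stop("format error: duplicate bin id in abs.bed")
  bed <- bed[order(bed$id), , drop = FALSE]
  if (!identical(as.integer(bed$id), seq_len(nrow(bed))))
    stop("format error: abs.bed bin ids must be 1..n")
  bins <- GRanges(bed$chrom, IRanges(bed$start + 1, bed$end))
  bins$bin_id <- bed$id
  info <- file.info(matrix_path)
  if (is.na(info$size)) stop("matrix file not found: ", matrix_path)
  if (info$size == 0) {
    px <- data.frame(i = integer(), j = integer(), value = numeric())
  } else {
    px <- read.table(matrix_path, header = FALSE, sep = "\t",
                     col.names = c("i", "j", "value"))
    if (any(!px$i %in% bed$id) || any(!px$j %in% bed$id))
      stop("format error: matrix bin id absent from abs.bed")
  }
  ContactMap(bins, px, kind = kind)
}

#' Write a ContactMap in HiC-Pro triplet format
#'
#' @param x a \code{\link{ContactMap}}.
#' @param matrix_path output \code{.matrix} file.
#' @param bed_path output \code{_abs.bed} file.
#' @return invisibly, c(matrix_path, bed_path).
#' @export
writeHicproMatrix <- function(x, matrix_path, bed_path) {
  stopifnot(is(x, "ContactMap"))
  bins <- contactBins(x)
  bed <- data.frame(chrom = as.character(seqnames(bins)),
                    start = start(bins) - 1L, end = end(bins),
                    id = bins$bin_id)
  write.table(bed, bed_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  px <- contactPixels(x)
  val <- if (contactKind(x) == "raw") format(px$value, trim = TRUE,
                                             scientific = FALSE)
         else fmtScore(px$value)
  write.table(data.frame(px$i, px$j, val), matrix_path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(matrix_path, bed_path))
}

#' Read BED features
#'
#' Standard BED (0-based half-open, >= 3 columns); column 4, when present,
#' becomes the \code{name} metadata column.
#'
#' @param path BED file.
#' @param assembly optional assembly for coordinate validation.
#' @return \code{GRanges}.
#' @export
readBedFeatures <- function(path, assembly = NULL) {
  info <- file.info(path)
  if (is.na(info$size)) stop("file not found: ", path)
  if (info$size == 0) return(GRanges())
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("format error: BED needs >= 3 columns")
  s <- suppressWarnings(as.numeric(df[[2]]))
  e <- suppressWarnings(as.numeric(df[[3]]))
  bad <- which(is.na(s) | is.na(e) | s < 0 | e <= s)
  if (length(bad)) stop("format error: line ", bad[1], ": malformed coordinate")
  gr <- GRanges(df[[1]], IRanges(s + 1, e))
  if (ncol(df) >= 4) gr$name <- as.character(df[[4]])
  checkAssembly(gr, assembly)
  gr
}

#' Write features as BED
#'
#' @param gr \code{GRanges}.
#' @param path output file.
#' @param names optional name column (4th BED field).
#' @param scores optional score column (5th BED field).
#' @return invisibly, \code{path}.
#' @export
writeBed <- function(gr, path, names = NULL, scores = NULL) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1L, end = end(gr))
  if (!is.null(names)) df$name <- names
  if (!is.null(scores)) {
    if (is.null(names)) df$name <- "."
    df$score <- fmtScore(scores)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read an eQTL catalog
#'
#' TSV with header columns \code{chrom}, \code{pos} (0-based bp),
#' \code{gene}, \code{fdr}.
#'
#' @param path eQTL TSV.
#' @param fdrCut optional: keep only records with \code{fdr < fdrCut}
#'   (strict, matching a "called at FDR < cut" convention).
#' @return data.frame with columns chrom, pos, gene, fdr.
#' @export
readEqtls <- function(path, fdrCut = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "gene", "fdr")
  if (!all(need %in% names(df)))
    stop("format error: eQTL table must have columns chrom, pos, gene, fdr")
  if (any(df$fdr <= 0 | df$fdr > 1))
    stop("format error: fdr values must lie in (0, 1]")
  if (!is.null(fdrCut)) df <- df[df$fdr < fdrCut, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write an eQTL catalog
#' @param eqtls data.frame with chrom, pos, gene, fdr.
#' @param path output TSV.
#' @return invisibly, \code{path}.
#' @export
writeEqtls <- function(eqtls, path) {
  write.table(eqtls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- paired-anchor interaction formats ----

contactFrame <- function(contacts) {
  need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2", "freq")
  if (!all(need %in% names(contacts)))
    stop("contacts must have columns ", paste(need, collapse = ", "))
  # bp coordinates as plain integers (never scientific notation)
  for (cn in c("start1", "end1", "start2", "end2"))
    contacts[[cn]] <- as.integer(round(contacts[[cn]]))
  contacts
}

#' Write contacts as 10-field BEDPE
#'
#' Fields: chrom1 start1 end1 chrom2 start2 end2 name score strand1 strand2,
#' 0-based half-open anchors, score = normalized frequency at 6 significant
#' digits.
#'
#' @param contacts data.frame with anchor columns \code{chrom1, start1,
#'   end1, chrom2, start2, end2} (0-based half-open) and \code{freq}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeBedpe <- function(contacts, path) {
  contacts <- contactFrame(contacts)
  nm <- if ("name" %in% names(contacts)) contacts$name
        else sprintf("contact_%d", seq_len(nrow(contacts)))
  df <- data.frame(contacts$chrom1, contacts$start1, contacts$end1,
                   contacts$chrom2, contacts$start2, contacts$end2,
                   nm, fmtScore(contacts$freq), ".", ".")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a 10-field BEDPE file
#'
#' @param path BEDPE file.
#' @return data.frame with chrom1, start1, end1, chrom2, start2, end2, name,
#'   freq (anchors 0-based half-open).
#' @export
readBedpe <- function(path) {
  info <- file.info(path)
  if (is.na(info$size)) stop("file not found: ", path)
  if (info$size == 0)
    return(data.frame(chrom1 = character(), start1 = integer(),
                      end1 = integer(), chrom2 = character(),
                      start2 = integer(), end2 = integer(),
                      name = character(), freq = numeric()))
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 8) stop("format error: BEDPE needs >= 8 columns")
  out <- data.frame(chrom1 = df[[1]], start1 = as.integer(df[[2]]),
                    end1 = as.integer(df[[3]]), chrom2 = df[[4]],
                    start2 = as.integer(df[[5]]), end2 = as.integer(df[[6]]),
                    name = as.character(df[[7]]),
                    freq = suppressWarnings(as.numeric(df[[8]])))
  bad <- which(is.na(out$start1) | is.na(out$start2))
  if (length(bad)) stop("format error: line ", bad[1], ": malformed coordinate")
  out
}

#' Write contacts as WashU long-range text
#'
#' One line per contact: "chrom:start-end<TAB>chrom:start-end<TAB>score",
#' anchors 0-based half-open, score at 6 significant digits.
#'
#' @inheritParams writeBedpe
#' @return invisibly, \code{path}.
#' @export
writeWashuLongrange <- function(contacts, path) {
  contacts <- contactFrame(contacts)
  lines <- sprintf("%s:%d-%d\t%s:%d-%d\t%s",
                   contacts$chrom1, contacts$start1, contacts$end1,
                   contacts$chrom2, contacts$start2, contacts$end2,
                   fmtScore(contacts$freq))
  writeLines(lines, path)
  invisible(path)
}
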