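#' @include AllClasses.R AllGenerics.R
NULL

#' Read a gene-position table (BED or GFF3) into a GenomeTable
#'
#' Ranks are always recomputed from sorted start coordinates within each
#' chromosome, so row order in the file is irrelevant. BED coordinates are
#' used as-is (0-based half-open); GFF3 coordinates (1-based closed) are
#' converted on read. For GFF3 only rows of type \code{gene} (falling back to
#' \code{mRNA} when no gene rows exist) are used and their \code{ID}
#' attribute becomes the gene id.
#'
#' @param path file to read.
#' @param format "BED", "GFF3" or "TSV" (the package's own dialect written by
#'   \code{\link{writeGeneTable}}, which preserves family ids).
#' @param genomeId genome identifier; defaults to the file base name.
#' @return a \linkS4class{GenomeTable}.
#' @export
readGeneTable <- function(path, format = c("BED", "GFF3", "TSV"),
                          genomeId = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(genomeId))
    genomeId <- sub("\\.[^.]+$", "", basename(path))
  if (format == "BED") {
    .validateBedLines(path)
    gr <- rtracklayer::import(path, format = "BED")
    genes <- data.frame(
      gene_id = as.character(gr$name),
      chromosome = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,   # back to 0-based half-open
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE)
  } else if (format == "GFF3") {
    gr <- rtracklayer::import(path, format = "GFF3")
    keep <- gr$type == "gene"
    if (!any(keep)) keep <- gr$type == "mRNA"
    gr <- gr[keep]
    if (!length(gr)) stop("no gene/mRNA rows in ", path)
    if (any(is.na(gr$ID))) stop("gene/mRNA rows without ID attribute in ", path)
    genes <- data.frame(
      gene_id = as.character(gr$ID),
      chromosome = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE)
  } else {
    genes <- utils::read.table(path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  }
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in ", path, ": ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)])[1:3],
               collapse = ", "))
  GenomeTable(genomeId, genes)
}

## cheap structural check so malformed rows are reported with a line number
.validateBedLines <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                 !startsWith(lines, "#")]
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) < 4)
      stop("malformed BED line ", i, ": fewer than 4 fields")
    s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e))
      stop("malformed BED line ", i, ": non-numeric coordinates")
    if (s >= e)
      stop("malformed BED line ", i, ": start >= end (", f[2], " >= ", f[3], ")")
  }
  invisible(TRUE)
}

#' Write a GenomeTable
#'
#' BED6 output keeps coordinates and strand (family ids are not representable
#' in BED); the TSV dialect keeps every column including family_id and is the
#' lossless round-trip format.
#'
#' @param x a \linkS4class{GenomeTable}.
#' @param path output file.
#' @param format "BED", "GFF3" or "TSV".
#' @export
writeGeneTable <- function(x, path, format = c("BED", "GFF3", "TSV")) {
  format <- match.arg(format)
  g <- genes(x)
  if (format == "BED") {
    gr <- GenomicRanges::GRanges(
      seqnames = g$chromosome,
      ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
      strand = g$strand, name = g$gene_id,
      score = 0L)
    rtracklayer::export(gr, path, format = "BED")
  } else if (format == "GFF3") {
    gr <- GenomicRanges::GRanges(
      seqnames = g$chromosome,
      ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
      strand = g$strand, type = "gene", ID = g$gene_id)
    rtracklayer::export(gr, path, format = "GFF3")
  } else {
    utils::write.table(g, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read/write homolog pair tables
#'
#' Tab-separated with columns gene_a, gene_b, score and optional ks.
#'
#' @param path file path.
#' @return data.frame with columns gene_a, gene_b, score, ks.
#' @export
readHomologs <- function(path) {
  h <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "score")
  if (!all(need %in% names(h)))
    stop("homolog table must have columns gene_a, gene_b, score")
  if (any(h$score < 0)) stop("negative homolog score")
  if (is.null(h$ks)) h$ks <- NA_real_
  h[, c("gene_a", "gene_b", "score", "ks")]
}

#' @rdname readHomologs
#' @param x homolog data.frame.
#' @export
writeHomologs <- function(x, path) {
  utils::write.table(x[, c("gene_a", "gene_b", "score", "ks")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write karyotype maps
#'
#' TSV columns: genome_id, chromosome, rank_start, rank_end (half-open rank
#' interval), proto.
#'
#' @param path file path.
#' @param karyotypeId identifier stored on read (defaults to file base name).
#' @return a \linkS4class{KaryotypeMap}.
#' @export
readKaryotypeMap <- function(path, karyotypeId = NULL) {
  s <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (is.null(karyotypeId))
    karyotypeId <- sub("\\.[^.]+$", "", basename(path))
  new("KaryotypeMap", karyotypeId = karyotypeId,
      protoChromosomes = unique(s$proto),
      segments = s[, c("genome_id", "chromosome", "rank_start",
                       "rank_end", "proto")])
}

#' @rdname readKaryotypeMap
#' @param x a KaryotypeMap.
#' @export
writeKaryotypeMap <- function(x, path) {
  utils::write.table(karyoSegments(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write orthogroup tables (OrthoFinder Orthogroups.tsv dialect)
#'
#' Tab-separated: an Orthogroup column then one column per unit (genome or
#' subgenome), each cell a comma+space separated gene-id list. Reading
#' returns both the membership lists and the copy-count matrix.
#'
#' @param path file path.
#' @return list with elements \code{counts} (integer matrix orthogroup x
#'   unit) and \code{membership} (nested list orthogroup -> unit -> ids).
#' @export
readOrthogroups <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "", comment.char = "")
  if (names(tab)[1] != "Orthogroup")
    stop("first column must be 'Orthogroup'")
  units <- names(tab)[-1]
  splitcell <- function(x) {
    x <- trimws(x)
    if (is.na(x) || !nzchar(x)) character() else
      trimws(strsplit(x, ",")[[1]])
  }
  membership <- lapply(seq_len(nrow(tab)), function(i) {
    cells <- lapply(units, function(u) splitcell(tab[[u]][i]))
    names(cells) <- units
    cells
  })
  names(membership) <- tab$Orthogroup
  counts <- t(vapply(membership, function(m)
    vapply(m, length, integer(1)), integer(length(units))))
  colnames(counts) <- units
  list(counts = counts, membership = membership)
}

#' @rdname readOrthogroups
#' @param x either an integer count matrix (rows = orthogroups, cols =
#'   units; placeholder gene ids are generated) or a membership list as
#'   returned by \code{readOrthogroups}.
#' @export
writeOrthogroups <- function(x, path) {
  if (is.matrix(x)) {
    og <- rownames(x); if (is.null(og)) og <- sprintf("OG%06d", seq_len(nrow(x)))
    units <- colnames(x)
    cells <- sapply(units, function(u) {
      vapply(seq_len(nrow(x)), function(i) {
        n <- x[i, u]
        if (n == 0) "" else
          paste(sprintf("%s_%s_%d", og[i], u, seq_len(n)), collapse = ", ")
      }, character(1))
    })
    tab <- data.frame(Orthogroup = og, cells, check.names = FALSE,
                      stringsAsFactors = FALSE)
  } else {
    units <- names(x[[1]])
    tab <- data.frame(
      Orthogroup = names(x),
      sapply(units, function(u) vapply(x, function(m)
        paste(m[[u]], collapse = ", "), character(1))),
      check.names = FALSE, stringsAsFactors = FALSE)
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write any supported result object to file
#'
#' Dispatch wrapper: GenomeTable to BED/TSV, KaryotypeMap to TSV, homolog
#' data.frames to TSV, orthogroup matrices to OrthoFinder-dialect TSV. Every
#' writer round-trips with its reader.
#'
#' @param object object to write.
#' @param path output file.
#' @param format format hint where the type supports several.
#' @export
writeResults <- function(object, path, format = "TSV") {
  if (is(object, "GenomeTable")) writeGeneTable(object, path, format)
  else if (is(object, "KaryotypeMap")) writeKaryotypeMap(object, path)
  else if (is.matrix(object)) writeOrthogroups(object, path)
  else if (is.data.frame(object) &&
           all(c("gene_a", "gene_b") %in% names(object)))
    writeHomologs(object, path)
  else stop("no writer for class ", paste(class(object), collapse = "/"))
}
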