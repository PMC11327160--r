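#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

.GENE_COLS <- c("gene_id", "chromosome", "start", "end", "strand",
                "rank", "family_id")

#' GenomeTable: ordered genes on chromosomes
#'
#' The universal substrate of the package: every gene carries a chromosome,
#' base-pair coordinates (0-based, half-open), a strand, a rank (its 0-based
#' position index along the chromosome in gene order) and an optional gene
#' family label. Synteny, painting and depth all operate on ranks; base-pair
#' coordinates are retained for reporting only.
#'
#' @slot genomeId single genome identifier.
#' @slot genes data.frame with columns gene_id, chromosome, start, end,
#'   strand, rank, family_id, ordered by (chromosome, rank).
#' @slot chromosomeLengths named numeric vector of chromosome sizes in bp.
#' @export
setClass("GenomeTable",
  representation(genomeId = "character",
                 genes = "data.frame",
                 chromosomeLengths = "numeric"))

setValidity("GenomeTable", function(object) {
  g <- object@genes
  msg <- character()
  if (length(object@genomeId) != 1L || is.na(object@genomeId))
    msg <- c(msg, "genomeId must be a single string")
  if (!all(.GENE_COLS %in% names(g)))
    msg <- c(msg, paste("genes must have columns:",
                        paste(.GENE_COLS, collapse = ", ")))
  else {
    if (anyDuplicated(g$gene_id))
      msg <- c(msg, "duplicate gene_id")
    if (any(g$start >= g$end))
      msg <- c(msg, "start must be < end for every gene")
    if (any(g$start < 0))
      msg <- c(msg, "negative start coordinate")
    if (!all(g$strand %in% c("+", "-")))
      msg <- c(msg, "strand must be '+' or '-'")
    bad <- vapply(split(g$rank, g$chromosome), function(r) {
      !identical(sort(r), seq(0L, length(r) - 1L))
    }, logical(1))
    if (any(bad))
      msg <- c(msg, paste("ranks not consecutive from 0 on:",
                          paste(names(bad)[bad], collapse = ", ")))
    if (!all(unique(g$chromosome) %in% names(object@chromosomeLengths)))
      msg <- c(msg, "every gene chromosome must appear in chromosomeLengths")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeTable
#'
#' Ranks are recomputed from start coordinates within each chromosome unless
#' already present and consistent; chromosome lengths default to just past the
#' last gene.
#'
#' @param genomeId genome identifier.
#' @param genes data.frame with at least gene_id, chromosome, start, end;
#'   strand defaults to "+", family_id to the gene id.
#' @param chromosomeLengths optional named vector of chromosome sizes (bp).
#' @return a validated \linkS4class{GenomeTable}.
#' @export
GenomeTable <- function(genomeId, genes, chromosomeLengths = NULL) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (is.null(genes$strand)) genes$strand <- "+"
  if (is.null(genes$family_id)) genes$family_id <- genes$gene_id
  genes$chromosome <- as.character(genes$chromosome)
  genes$gene_id <- as.character(genes$gene_id)
  genes <- genes[order(genes$chromosome, genes$start), , drop = FALSE]
  genes$rank <- stats::ave(genes$start, genes$chromosome,
                           FUN = function(x) rank(x, ties.method = "first") - 1L)
  genes$rank <- as.integer(genes$rank)
  genes <- genes[order(genes$chromosome, genes$rank), , drop = FALSE]
  rownames(genes) <- NULL
  if (is.null(chromosomeLengths)) {
    chromosomeLengths <- vapply(split(genes$end, genes$chromosome), max,
                                numeric(1)) + 1
  }
  new("GenomeTable", genomeId = as.character(genomeId),
      genes = genes[, .GENE_COLS], chromosomeLengths = chromosomeLengths)
}

#' SyntenyBlockSet: chained collinear blocks between two genomes
#'
#' @slot genomeA,genomeB identifiers of the compared genomes (equal for a
#'   self-comparison).
#' @slot blocks data.frame: block_id, chrom_a, chrom_b, orientation
#'   ("parallel"/"antiparallel"), anchor_count, median_ks (NA until annotated),
#'   saturated flag.
#' @slot anchors data.frame: block_id, gene_a, chrom_a, rank_a, gene_b,
#'   chrom_b, rank_b, score, ks.
#' @export
setClass("SyntenyBlockSet",
  representation(genomeA = "character", genomeB = "character",
                 blocks = "data.frame", anchors = "data.frame"))

setValidity("SyntenyBlockSet", function(object) {
  b <- object@blocks; a <- object@anchors
  msg <- character()
  need_b <- c("block_id", "chrom_a", "chrom_b", "orientation", "anchor_count")
  need_a <- c("block_id", "gene_a", "chrom_a", "rank_a", "gene_b",
              "chrom_b", "rank_b")
  if (!all(need_b %in% names(b))) msg <- c(msg, "blocks missing columns")
  if (!all(need_a %in% names(a))) msg <- c(msg, "anchors missing columns")
  if (!length(msg) && nrow(b)) {
    if (!all(b$orientation %in% c("parallel", "antiparallel")))
      msg <- c(msg, "orientation must be parallel/antiparallel")
    for (id in b$block_id) {
      aa <- a[a$block_id == id, ]
      if (is.unsorted(aa$rank_a, strictly = TRUE))
        msg <- c(msg, paste("block", id, "not strictly monotone in A"))
      d <- diff(aa$rank_b)
      ori <- b$orientation[b$block_id == id]
      if (ori == "parallel" && any(d <= 0))
        msg <- c(msg, paste("block", id, "not increasing in B"))
      if (ori == "antiparallel" && any(d >= 0))
        msg <- c(msg, paste("block", id, "not decreasing in B"))
    }
  }
  if (length(msg)) msg else TRUE
})

#' KsMixtureModel: fitted Gaussian mixture over a Ks sample
#'
#' @slot components data.frame (weight, mean, sd) sorted by ascending mean.
#' @slot nPoints number of Ks values fitted.
#' @slot bic BIC of the selected model.
#' @slot bicTable data.frame (k, bic, loglik) over all candidate k.
#' @slot seed integer seed the fit was run under.
#' @slot converged logical.
#' @export
setClass("KsMixtureModel",
  representation(components = "data.frame", nPoints = "integer",
                 bic = "numeric", bicTable = "data.frame",
                 seed = "integer", converged = "logical"))

setValidity("KsMixtureModel", function(object) {
  cp <- object@components
  msg <- character()
  if (!all(c("weight", "mean", "sd") %in% names(cp)))
    msg <- c(msg, "components need weight/mean/sd")
  else {
    if (any(cp$weight <= 0) || abs(sum(cp$weight) - 1) > 1e-6)
      msg <- c(msg, "weights must be positive and sum to 1")
    if (is.unsorted(cp$mean)) msg <- c(msg, "means must be sorted ascending")
    if (any(cp$sd <= 0)) msg <- c(msg, "sds must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' KaryotypeMap: proto-chromosome segments of one or more genomes
#'
#' Maps half-open rank intervals of extant (or proxy) chromosomes onto
#' proto-chromosomes of a named ancestral karyotype.
#'
#' @slot karyotypeId e.g. "LAK", "post-LAK".
#' @slot protoChromosomes ordered proto-chromosome ids.
#' @slot segments data.frame: genome_id, chromosome, rank_start, rank_end
#'   (half-open), proto.
#' @export
setClass("KaryotypeMap",
  representation(karyotypeId = "character", protoChromosomes = "character",
                 segments = "data.frame"))

setValidity("KaryotypeMap", function(object) {
  s <- object@segments
  msg <- character()
  need <- c("genome_id", "chromosome", "rank_start", "rank_end", "proto")
  if (!all(need %in% names(s))) return("segments missing columns")
  if (nrow(s)) {
    if (any(s$rank_start >= s$rank_end))
      msg <- c(msg, "rank intervals must be non-empty half-open")
    if (!all(s$proto %in% object@protoChromosomes))
      msg <- c(msg, "segment proto not in protoChromosomes")
    ov <- vapply(split(s, paste(s$genome_id, s$chromosome)), function(x) {
      x <- x[order(x$rank_start), ]
      nrow(x) > 1 && any(x$rank_start[-1] < x$rank_end[-nrow(x)])
    }, logical(1))
    if (any(ov)) msg <- c(msg, "overlapping rank intervals within a chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' KaryotypePainting: per-chromosome proto-chromosome segments
#'
#' @slot genomeId painted genome.
#' @slot ancestorId karyotype id of the ancestor used.
#' @slot segments data.frame: chromosome, rank_start, rank_end (half-open
#'   over extant ranks), proto, orientation, support (anchor count),
#'   proto_min, proto_max (rank span covered on the proto side).
#' @export
setClass("KaryotypePainting",
  representation(genomeId = "character", ancestorId = "character",
                 segments = "data.frame"))

#' CSOMatrix: core set of orthogroups by unit copy-number table
#'
#' @slot counts integer matrix, rows = CSO ids, cols = units (subgenomes +
#'   outgroups).
#' @slot categories character matrix same shape: Absent/Single/Two/Multiple.
#' @slot unitClass named character vector over columns: "A", "B" or
#'   "outgroup".
#' @slot unitSpecies named character vector over columns (species each
#'   subgenome belongs to; outgroups map to themselves).
#' @slot cluster integer vector over rows (1/2/3, keyed to the first
#'   outgroup's copy number).
#' @export
setClass("CSOMatrix",
  representation(counts = "matrix", categories = "matrix",
                 unitClass = "character", unitSpecies = "character",
                 cluster = "integer"))

setValidity("CSOMatrix", function(object) {
  msg <- character()
  if (!is.integer(object@counts) || any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative integers")
  if (!identical(dim(object@counts), dim(object@categories)))
    msg <- c(msg, "counts/categories shape mismatch")
  if (length(object@unitClass) != ncol(object@counts))
    msg <- c(msg, "unitClass length must match columns")
  if (!all(object@unitClass %in% c("A", "B", "outgroup")))
    msg <- c(msg, "unitClass values must be A/B/outgroup")
  want <- .ksCategory(object@counts)
  if (!identical(unname(want), unname(object@categories)))
    msg <- c(msg, "categories inconsistent with counts")
  if (length(msg)) msg else TRUE
})

## copy-number category, a pure function of the count
.ksCategory <- function(x) {
  out <- x
  out[] <- ifelse(x == 0L, "Absent",
           ifelse(x == 1L, "Single", ifelse(x == 2L, "Two", "Multiple")))
  mode(out) <- "character"
  out
}

#' GenomeSimulation: a simulated genome plus its ground truth
#'
#' Carries the evolving \linkS4class{GenomeTable} alongside the event log and
#' the truth table linking every extant gene to its ancestral gene,
#' proto-chromosome, per-event subgenome labels (the copy path) and, for
#' genes born by small-scale duplication, the duplication mode.
#'
#' @slot genome the current \linkS4class{GenomeTable}.
#' @slot truth data.frame: gene_id, ancestral_gene, proto, copy_path, mode.
#' @slot events data.frame: event_id, kind, age_ks, detail.
#' @export
setClass("GenomeSimulation",
  representation(genome = "GenomeTable", truth = "data.frame",
                 events = "data.frame"))

setValidity("GenomeSimulation", function(object) {
  msg <- character()
  tr <- object@truth
  if (!all(c("gene_id", "ancestral_gene", "proto", "copy_path", "mode")
           %in% names(tr)))
    msg <- c(msg, "truth missing columns")
  else if (!setequal(tr$gene_id, object@genome@genes$gene_id))
    msg <- c(msg, "truth and genome gene sets differ")
  ev <- object@events
  if (nrow(ev) && is.unsorted(rev(ev$age_ks)))
    msg <- c(msg, "event ages must be non-increasing (oldest first)")
  if (length(msg)) msg else TRUE
})
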