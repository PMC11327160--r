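#' @include AllClasses.R AllGenerics.R
NULL

#' Build anchors from a homolog table with c-score filtering
#'
#' A pair (a, b) is kept iff score(a, b) >= threshold * max(best score of a
#' against genome B, best score of b against genome A). For a
#' self-comparison the identity diagonal is excluded. Tandem arrays
#' (rank-adjacent genes of the same family) are collapsed to their
#' highest-scoring member before chaining to avoid spurious depth inflation.
#'
#' @param genomeA,genomeB \linkS4class{GenomeTable}s (the same object for a
#'   self-comparison).
#' @param homologs data.frame with gene_a, gene_b, score and optional ks.
#' @param cscoreThreshold c-score threshold in (0, 1]; 0 disables filtering.
#' @param collapseTandem collapse tandem arrays (default TRUE).
#' @param maskDiagonal for self-comparisons: drop same-chromosome anchors
#'   with |rank_a - rank_b| at or below this band width, the standard
#'   masking that keeps local (tandem/proximal) duplicates from chaining
#'   into fake collinear blocks (default 0 = off).
#' @return anchor data.frame: gene_a, chrom_a, rank_a, gene_b, chrom_b,
#'   rank_b, score, ks.
#' @export
buildAnchors <- function(genomeA, genomeB, homologs, cscoreThreshold = 0.99,
                         collapseTandem = TRUE, maskDiagonal = 0L) {
  if (cscoreThreshold > 1) stop("cscoreThreshold must be in [0, 1]")
  ga <- genes(genomeA); gb <- genes(genomeB)
  h <- homologs
  if (is.null(h$ks)) h$ks <- NA_real_
  bad <- setdiff(c(h$gene_a, h$gene_b), c(ga$gene_id, gb$gene_id))
  if (length(bad))
    stop("homolog references unknown gene(s): ",
         paste(utils::head(bad, 3), collapse = ", "))
  self <- identical(genomeId(genomeA), genomeId(genomeB))
  if (self) h <- h[h$gene_a != h$gene_b, , drop = FALSE]
  if (cscoreThreshold > 0 && nrow(h)) {
    if (self) {
      ## symmetric comparison: each gene's best hit over both columns
      best <- tapply(c(h$score, h$score), c(h$gene_a, h$gene_b), max)
      cut <- cscoreThreshold * pmax(best[h$gene_a], best[h$gene_b])
    } else {
      bestA <- tapply(h$score, h$gene_a, max)
      bestB <- tapply(h$score, h$gene_b, max)
      cut <- cscoreThreshold * pmax(bestA[h$gene_a], bestB[h$gene_b])
    }
    h <- h[h$score >= cut - 1e-12, , drop = FALSE]
  }
  ia <- match(h$gene_a, ga$gene_id); ib <- match(h$gene_b, gb$gene_id)
  if (anyNA(ia) || anyNA(ib))
    stop("homolog gene absent from its genome table")
  a <- data.frame(gene_a = h$gene_a, chrom_a = ga$chromosome[ia],
                  rank_a = ga$rank[ia], gene_b = h$gene_b,
                  chrom_b = gb$chromosome[ib], rank_b = gb$rank[ib],
                  score = h$score, ks = h$ks, stringsAsFactors = FALSE)
  if (collapseTandem) {
    if (self) a <- .dropTandemSelfPairs(a, ga)
    a <- .collapseTandem(a, ga, side = "a")
    a <- .collapseTandem(a, gb, side = "b")
  }
  if (maskDiagonal > 0 && self)
    a <- a[!(a$chrom_a == a$chrom_b &
             abs(a$rank_a - a$rank_b) <= maskDiagonal), , drop = FALSE]
  a <- a[order(a$chrom_a, a$rank_a, a$chrom_b, a$rank_b), ]
  rownames(a) <- NULL
  a
}

## anchors linking two members of the same tandem array are self-pairs of
## the array, never collinearity evidence
.dropTandemSelfPairs <- function(a, g) {
  if (!nrow(a)) return(a)
  g <- g[order(g$chromosome, g$rank), ]
  newRun <- c(TRUE, g$family_id[-1] != g$family_id[-nrow(g)] |
                    g$chromosome[-1] != g$chromosome[-nrow(g)])
  runOf <- stats::setNames(cumsum(newRun), g$gene_id)
  drop <- !is.na(runOf[a$gene_a]) & !is.na(runOf[a$gene_b]) &
          runOf[a$gene_a] == runOf[a$gene_b]
  a[!drop, , drop = FALSE]
}

## identify runs of rank-adjacent same-family genes; keep only anchors of
## the member with the best anchor score in each run
.collapseTandem <- function(a, g, side = c("a", "b")) {
  side <- match.arg(side)
  if (!nrow(a)) return(a)
  g <- g[order(g$chromosome, g$rank), ]
  newRun <- c(TRUE, g$family_id[-1] != g$family_id[-nrow(g)] |
                    g$chromosome[-1] != g$chromosome[-nrow(g)])
  run <- cumsum(newRun)
  runSize <- table(run)
  multi <- run %in% as.integer(names(runSize)[runSize > 1])
  if (!any(multi)) return(a)
  runOf <- stats::setNames(run, g$gene_id)
  gcol <- paste0("gene_", side)
  r <- runOf[a[[gcol]]]
  inMulti <- !is.na(r) & r %in% unique(run[multi])
  if (!any(inMulti)) return(a)
  ## best-scoring member per multi-gene run
  bestScore <- tapply(a$score[inMulti], a[[gcol]][inMulti], max)
  geneRun <- runOf[names(bestScore)]
  keepGene <- tapply(seq_along(bestScore), geneRun, function(i)
    names(bestScore)[i][which.max(bestScore[i])])
  drop <- inMulti & !(a[[gcol]] %in% unlist(keepGene))
  a[!drop, , drop = FALSE]
}

## best monotone chain (strictly increasing in both axes, gaps <= maxGap)
## over anchors given as rank vectors; returns indices of chain members
.bestChain <- function(ra, rb, maxGap) {
  n <- length(ra)
  o <- order(ra, rb)
  ra <- ra[o]; rb <- rb[o]
  L <- rep(1L, n); P <- rep(0L, n)
  lo <- 1L
  for (i in seq_len(n)) {
    while (ra[i] - ra[lo] > maxGap) lo <- lo + 1L
    js <- lo:i
    js <- js[ra[js] < ra[i] & rb[js] < rb[i] & rb[i] - rb[js] <= maxGap]
    if (length(js)) {
      bj <- js[which.max(L[js])]
      L[i] <- L[bj] + 1L
      P[i] <- bj
    }
  }
  end <- which.max(L)
  chain <- integer(L[end])
  k <- L[end]; i <- end
  while (i > 0L) { chain[k] <- i; k <- k - 1L; i <- P[i] }
  o[chain]
}

#' Chain anchors into collinear synteny blocks
#'
#' Within each chromosome pair, maximal anchor chains monotone in both rank
#' axes (separately for parallel and antiparallel orientation) are extracted
#' greedily best-chain-first by dynamic programming with chain score = anchor
#' count; extension requires both rank gaps <= \code{maxGap}; each anchor
#' joins at most one block and chains shorter than \code{minBlockSize} are
#' discarded. Ties between chains are broken toward parallel orientation,
#' then the smaller chromosome pair id, then the lower start rank, so output
#' is deterministic.
#'
#' @param anchorDf anchors from \code{\link{buildAnchors}}.
#' @param minBlockSize minimum anchors per block (>= 2, default 5).
#' @param maxGap maximum rank gap on either axis (>= 1, default 25).
#' @param genomeA,genomeB ids recorded on the result (optional).
#' @return a \linkS4class{SyntenyBlockSet}.
#' @export
chainBlocks <- function(anchorDf, minBlockSize = 5L, maxGap = 25L,
                        genomeA = "A", genomeB = "B") {
  if (minBlockSize < 2) stop("minBlockSize must be >= 2")
  if (maxGap < 1) stop("maxGap must be >= 1")
  blockRows <- list(); anchorRows <- list()
  bid <- 0L
  pairs <- unique(anchorDf[, c("chrom_a", "chrom_b")])
  pairs <- pairs[order(pairs$chrom_a, pairs$chrom_b), , drop = FALSE]
  for (pi in seq_len(nrow(pairs))) {
    sel <- anchorDf$chrom_a == pairs$chrom_a[pi] &
           anchorDf$chrom_b == pairs$chrom_b[pi]
    av <- anchorDf[sel, , drop = FALSE]
    repeat {
      if (nrow(av) < minBlockSize) break
      cp <- .bestChain(av$rank_a, av$rank_b, maxGap)
      ca <- .bestChain(av$rank_a, -av$rank_b, maxGap)
      if (length(cp) >= length(ca)) { chain <- cp; ori <- "parallel" }
      else { chain <- ca; ori <- "antiparallel" }
      if (length(chain) < minBlockSize) break
      bid <- bid + 1L
      ch <- av[chain, , drop = FALSE]
      ch <- ch[order(ch$rank_a), ]
      id <- sprintf("B%04d", bid)
      ch$block_id <- id
      blockRows[[bid]] <- data.frame(
        block_id = id, chrom_a = pairs$chrom_a[pi],
        chrom_b = pairs$chrom_b[pi], orientation = ori,
        anchor_count = nrow(ch), median_ks = NA_real_,
        saturated = FALSE, stringsAsFactors = FALSE)
      anchorRows[[bid]] <- ch
      av <- av[-chain, , drop = FALSE]
    }
  }
  bl <- if (length(blockRows)) do.call(rbind, blockRows) else
    data.frame(block_id = character(), chrom_a = character(),
               chrom_b = character(), orientation = character(),
               anchor_count = integer(), median_ks = numeric(),
               saturated = logical(), stringsAsFactors = FALSE)
  an <- if (length(anchorRows)) do.call(rbind, anchorRows) else
    cbind(anchorDf[0, ], block_id = character())
  rownames(bl) <- rownames(an) <- NULL
  new("SyntenyBlockSet", genomeA = genomeA, genomeB = genomeB,
      blocks = bl,
      anchors = an[, c("block_id", "gene_a", "chrom_a", "rank_a",
                       "gene_b", "chrom_b", "rank_b", "score", "ks")])
}

#' Export blocks as a dot-plot table (and optional PNG)
#'
#' The TSV carries one row per anchor: chrom_a, rank_a, chrom_b, rank_b,
#' block_id, orientation, median_ks, gene ids, score and ks —
#' \code{\link{readBlockSet}} reconstructs the full block set from it.
#'
#' @param blockSet a \linkS4class{SyntenyBlockSet}.
#' @param path TSV output path.
#' @param pngPath optional dot-plot image path.
#' @export
dotplotExport <- function(blockSet, path, pngPath = NULL) {
  an <- anchors(blockSet); bl <- blocks(blockSet)
  m <- match(an$block_id, bl$block_id)
  out <- data.frame(chrom_a = an$chrom_a, rank_a = an$rank_a,
                    chrom_b = an$chrom_b, rank_b = an$rank_b,
                    block_id = an$block_id,
                    orientation = bl$orientation[m],
                    median_ks = bl$median_ks[m],
                    gene_a = an$gene_a, gene_b = an$gene_b,
                    score = an$score, ks = an$ks,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(pngPath)) {
    grDevices::png(pngPath, width = 900, height = 900)
    on.exit(grDevices::dev.off())
    if (nrow(an)) {
      graphics::plot(an$rank_a, an$rank_b,
                     col = as.integer(factor(an$block_id)) %% 8 + 1,
                     pch = 20, cex = 0.4, xlab = "rank (A)", ylab = "rank (B)",
                     main = "synteny dot plot (ranks)")
    } else graphics::plot.new()
  }
  invisible(path)
}

#' @rdname dotplotExport
#' @param genomeA,genomeB ids recorded on the reconstructed set.
#' @export
readBlockSet <- function(path, genomeA = "A", genomeB = "B") {
  t <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  bl <- unique(t[, c("block_id", "chrom_a", "chrom_b", "orientation",
                     "median_ks")])
  cnt <- table(t$block_id)
  bl$anchor_count <- as.integer(cnt[bl$block_id])
  bl$saturated <- FALSE
  bl <- bl[, c("block_id", "chrom_a", "chrom_b", "orientation",
               "anchor_count", "median_ks", "saturated")]
  rownames(bl) <- NULL
  an <- t[, c("block_id", "gene_a", "chrom_a", "rank_a", "gene_b",
              "chrom_b", "rank_b", "score", "ks")]
  new("SyntenyBlockSet", genomeA = genomeA, genomeB = genomeB,
      blocks = bl, anchors = an)
}
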