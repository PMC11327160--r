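#' @include AllClasses.R AllGenerics.R synteny.R
NULL

#' DepthProfile: per-gene syntenic coverage depth in both directions
#'
#' @slot refDepth data.frame (chromosome, rank, depth) over reference genes:
#'   the number of retained blocks whose reference-side span contains the
#'   gene — i.e. how many query copies cover each reference locus.
#' @slot queryDepth same over query genes.
#' @slot modalRef,modalQuery modal depth over covered (depth >= 1) genes.
#' @slot coveredRef,coveredQuery covered fraction of genes.
#' @export
setClass("DepthProfile",
  representation(refDepth = "data.frame", queryDepth = "data.frame",
                 modalRef = "integer", modalQuery = "integer",
                 coveredRef = "numeric", coveredQuery = "numeric"))

setMethod("show", "DepthProfile", function(object) {
  cat("DepthProfile: modal depth on reference genes =", object@modalRef,
      sprintf("(%.0f%% covered);", 100 * object@coveredRef),
      "on query genes =", object@modalQuery,
      sprintf("(%.0f%% covered)\n", 100 * object@coveredQuery))
})

.depthOneSide <- function(genome, spans, chromCol, loCol, hiCol) {
  g <- genes(genome)
  out <- g[, c("chromosome", "rank")]
  out$depth <- 0L
  for (ch in unique(spans[[chromCol]])) {
    n <- sum(g$chromosome == ch)
    if (!n) next
    diffv <- integer(n + 1L)
    s <- spans[spans[[chromCol]] == ch, , drop = FALSE]
    lo <- pmax(0L, s[[loCol]]); hi <- pmin(n - 1L, s[[hiCol]])
    for (i in seq_len(nrow(s))) {
      diffv[lo[i] + 1L] <- diffv[lo[i] + 1L] + 1L
      diffv[hi[i] + 2L] <- diffv[hi[i] + 2L] - 1L
    }
    d <- cumsum(diffv[seq_len(n)])
    idx <- which(out$chromosome == ch)
    out$depth[idx[order(out$rank[idx])]] <- d
  }
  out
}

.modalDepth <- function(d) {
  d <- d[d >= 1]
  if (!length(d)) return(0L)
  tab <- table(d)
  as.integer(names(tab)[which.max(tab)])
}

#' Syntenic depth of collinear blocks in both directions
#'
#' For each reference gene, depth is the number of retained blocks whose
#' reference-side rank span contains the gene (how many query copies map
#' there); symmetrically for query genes. The modal depth is taken over
#' covered genes only, since fractionation-induced zeros would otherwise
#' dominate.
#'
#' @param blockSet blocks with the query as genome A and the reference as
#'   genome B.
#' @param query,reference the two \linkS4class{GenomeTable}s.
#' @param minBlockSize blocks with fewer anchors are ignored (default 5).
#' @return a \linkS4class{DepthProfile}.
#' @export
syntenicDepth <- function(blockSet, query, reference, minBlockSize = 5L) {
  if (!identical(blockSet@genomeA, genomeId(query)) ||
      !identical(blockSet@genomeB, genomeId(reference)))
    stop("block set was built for ", blockSet@genomeA, " vs ",
         blockSet@genomeB, ", not ", genomeId(query), " vs ",
         genomeId(reference))
  bl <- blocks(blockSet)
  keep <- bl$block_id[bl$anchor_count >= minBlockSize]
  an <- anchors(blockSet)
  an <- an[an$block_id %in% keep, , drop = FALSE]
  if (nrow(an)) {
    spans <- do.call(rbind, lapply(split(an, an$block_id), function(x)
      data.frame(chrom_a = x$chrom_a[1], lo_a = min(x$rank_a),
                 hi_a = max(x$rank_a), chrom_b = x$chrom_b[1],
                 lo_b = min(x$rank_b), hi_b = max(x$rank_b),
                 stringsAsFactors = FALSE)))
  } else {
    spans <- data.frame(chrom_a = character(), lo_a = integer(),
                        hi_a = integer(), chrom_b = character(),
                        lo_b = integer(), hi_b = integer())
  }
  refD <- .depthOneSide(reference, spans, "chrom_b", "lo_b", "hi_b")
  qryD <- .depthOneSide(query, spans, "chrom_a", "lo_a", "hi_a")
  new("DepthProfile", refDepth = refD, queryDepth = qryD,
      modalRef = .modalDepth(refD$depth),
      modalQuery = .modalDepth(qryD$depth),
      coveredRef = mean(refD$depth >= 1),
      coveredQuery = mean(qryD$depth >= 1))
}

#' Modal depth ratio (query : reference)
#'
#' The ratio the ploidy inference is based on: modal depth over reference
#' genes (number of query copies per reference locus) to modal depth over
#' query genes.
#'
#' @param profile a \linkS4class{DepthProfile}.
#' @param minCoveredFraction required covered fraction in both directions
#'   (default 0.3).
#' @return named integer vector c(query = ..., reference = ...).
#' @export
depthRatio <- function(profile, minCoveredFraction = 0.3) {
  if (profile@coveredRef < minCoveredFraction ||
      profile@coveredQuery < minCoveredFraction)
    stop("covered fraction below ", minCoveredFraction,
         " (reference ", round(profile@coveredRef, 2), ", query ",
         round(profile@coveredQuery, 2),
         "); review block parameters before interpreting a ratio")
  c(query = profile@modalRef, reference = profile@modalQuery)
}

#' PloidyCall: decomposition of a depth ratio into polyploidy events
#'
#' @slot ratio integer (query, reference) modal depths.
#' @slot factorizations list of candidate multiplicity sequences (oldest
#'   event first).
#' @slot multiplicities the selected sequence when unambiguous.
#' @slot ambiguous logical.
#' @slot peakAges supporting Ks peak ages (oldest first), if given.
#' @export
setClass("PloidyCall",
  representation(ratio = "integer", factorizations = "list",
                 multiplicities = "numeric", ambiguous = "logical",
                 peakAges = "numeric"))

setMethod("show", "PloidyCall", function(object) {
  cat("PloidyCall ", object@ratio[1], ":", object@ratio[2], " -> ", sep = "")
  if (object@ambiguous) {
    cat("ambiguous: ",
        paste(vapply(object@factorizations, paste, character(1),
                     collapse = "x"), collapse = " | "), "\n")
  } else if (length(object@multiplicities)) {
    cat(paste(object@multiplicities, collapse = "x"), "\n")
  } else cat("no post-reference event\n")
})

#' Decompose a depth ratio into an event sequence
#'
#' Enumerates ordered factorizations of query/reference into factors from
#' \{2, 3\} with exactly one factor per post-reference Ks peak. A unique
#' factorization yields an unambiguous call with factors mapped
#' oldest-peak-first; multiple factorizations are surfaced as an ambiguity
#' (cross-species comparisons are the sanctioned resolver); zero
#' factorizations is an inconsistency error.
#'
#' @param ratio integer pair (query, reference) from \code{\link{depthRatio}}.
#' @param nPeaks number of post-reference Ks peaks.
#' @param peakAges optional ages (any order; sorted oldest first).
#' @return a \linkS4class{PloidyCall}.
#' @export
decomposePloidy <- function(ratio, nPeaks, peakAges = numeric()) {
  q <- as.integer(ratio[1]); r <- as.integer(ratio[2])
  if (q < 1 || r < 1) stop("ratio components must be >= 1")
  if (nPeaks < 0) stop("nPeaks must be >= 0")
  if (q %% r != 0)
    stop("query depth ", q, " is not divisible by reference depth ", r,
         "; reciprocal lineage-specific events are likely - compare the ",
         "lineages directly (sharedEventTest)")
  target <- q %/% r
  if (nPeaks == 0) {
    facs <- if (target == 1) list(numeric()) else list()
  } else {
    grid <- expand.grid(rep(list(c(2, 3)), nPeaks))
    prods <- apply(grid, 1, prod)
    facs <- lapply(which(prods == target), function(i) as.numeric(grid[i, ]))
  }
  if (!length(facs))
    stop("no sequence of ", nPeaks, " events from {2,3} explains a ",
         q, ":", r, " ratio; Ks peak count and depth are inconsistent")
  ages <- sort(as.numeric(peakAges), decreasing = TRUE)
  new("PloidyCall", ratio = c(q, r), factorizations = facs,
      multiplicities = if (length(facs) == 1) facs[[1]] else numeric(),
      ambiguous = length(facs) > 1, peakAges = ages)
}

#' Shared versus independent polyploidy events between two lineages
#'
#' Matches each lineage's post-reference events by Ks age: events whose
#' ages agree within \code{ageTol} are called shared, others independent.
#' The observed between-lineage depth ratio is checked against the
#' classification: lineage-specific multiplicities must multiply to each
#' side of the ratio (shared events contribute to both sides equally and
#' cancel); a contradiction yields an inconsistency report with no call.
#'
#' @param ratioBetween integer pair: modal depth ratio lineage A : lineage B.
#' @param callA,callB unambiguous \linkS4class{PloidyCall}s with peak ages.
#' @param ageTol age tolerance in Ks units (default 0.15).
#' @return list with \code{events} (data.frame: lineage, age, multiplicity,
#'   call, matched_age), \code{consistent}, \code{expected_ratio} and
#'   \code{rule}.
#' @export
sharedEventTest <- function(ratioBetween, callA, callB, ageTol = 0.15) {
  if (callA@ambiguous || callB@ambiguous)
    stop("resolve ambiguous calls before testing for shared events")
  if (length(callA@peakAges) != length(callA@multiplicities) ||
      length(callB@peakAges) != length(callB@multiplicities))
    stop("each event needs a supporting Ks peak age")
  evA <- data.frame(lineage = "A", age = callA@peakAges,
                    multiplicity = callA@multiplicities)
  evB <- data.frame(lineage = "B", age = callB@peakAges,
                    multiplicity = callB@multiplicities)
  if (!nrow(evA) && !nrow(evB))
    stop("both lineages lack post-reference events")
  usedB <- rep(FALSE, nrow(evB))
  callAv <- rep("independent", nrow(evA))
  matchA <- rep(NA_real_, nrow(evA))
  for (i in seq_len(nrow(evA))) {
    cand <- which(!usedB & evB$multiplicity == evA$multiplicity[i] &
                  abs(evB$age - evA$age[i]) <= ageTol)
    if (length(cand)) {
      j <- cand[which.min(abs(evB$age[cand] - evA$age[i]))]
      usedB[j] <- TRUE
      callAv[i] <- "shared"
      matchA[i] <- evB$age[j]
    }
  }
  callBv <- ifelse(usedB, "shared", "independent")
  matchB <- rep(NA_real_, nrow(evB))
  events <- rbind(
    if (nrow(evA)) cbind(evA, call = callAv, matched_age = matchA),
    if (nrow(evB)) cbind(evB, call = callBv, matched_age = matchB))
  ## lineage-specific events must account for the observed cross ratio;
  ## shared events cover both lineages and cancel out of the ratio
  expA <- prod(c(1, evA$multiplicity[callAv == "independent"]))
  expB <- prod(c(1, evB$multiplicity[callBv == "independent"]))
  sharedMult <- prod(c(1, evA$multiplicity[callAv == "shared"]))
  expected <- c(expA * sharedMult, expB * sharedMult)
  consistent <- all(expected == as.numeric(ratioBetween))
  list(events = events, consistent = consistent,
       expected_ratio = expected,
       rule = paste0("events matched by multiplicity and |delta age| <= ",
                     ageTol, " Ks"))
}
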