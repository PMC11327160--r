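#' @include AllClasses.R AllGenerics.R synteny.R ploidy.R
NULL

#' Identity karyotype map for an ancestor proxy genome
#'
#' Each chromosome of the proxy becomes its own proto-chromosome spanning
#' all of its ranks — the usual way a conserved genome (or a simulated
#' ancestor) stands in for an ancestral karyotype.
#'
#' @param genome a \linkS4class{GenomeTable}.
#' @param karyotypeId identifier for the map.
#' @export
protoIdentityMap <- function(genome, karyotypeId = "ancestor") {
  g <- genes(genome)
  n <- vapply(split(g$rank, g$chromosome), function(r) max(r) + 1L,
              integer(1))
  seg <- data.frame(genome_id = genomeId(genome), chromosome = names(n),
                    rank_start = 0L, rank_end = unname(n),
                    proto = names(n), stringsAsFactors = FALSE)
  new("KaryotypeMap", karyotypeId = karyotypeId,
      protoChromosomes = names(n), segments = seg)
}

## proto id for (chromosome, rank) positions under a map
.protoAt <- function(map, chrom, rank) {
  s <- map@segments
  out <- rep(NA_character_, length(chrom))
  for (i in seq_len(nrow(s))) {
    hit <- chrom == s$chromosome[i] & rank >= s$rank_start[i] &
           rank < s$rank_end[i]
    out[hit] <- s$proto[i]
  }
  out
}

## rank span of every proto (for terminal-completeness tests)
.protoLengths <- function(map) {
  s <- map@segments
  tapply(s$rank_end - s$rank_start, s$proto, sum)
}

## merge a run-length segmentation until every run has >= minLen genes;
## short runs join the flank with more support, ties toward the preceding
.mergeShortRuns <- function(proto, support, minLen) {
  repeat {
    r <- rle(proto)
    if (length(r$lengths) <= 1) break
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    segSup <- vapply(seq_along(ends), function(i)
      sum(support[starts[i]:ends[i]]), numeric(1))
    short <- which(r$lengths < minLen)
    if (!length(short)) break
    i <- short[which.min(r$lengths[short])]
    left <- if (i > 1) segSup[i - 1] else -Inf
    right <- if (i < length(ends)) segSup[i + 1] else -Inf
    tgt <- if (left >= right) i - 1 else i + 1
    proto[starts[i]:ends[i]] <- r$values[tgt]
  }
  proto
}

#' Paint extant chromosomes by ancestral proto-chromosomes
#'
#' Every extant gene receives score-weighted votes from its anchors, each
#' anchor voting for the proto-chromosome its partner position belongs to
#' under the ancestor map; chromosomes are then partitioned into maximal
#' same-proto runs, runs below \code{minSegmentGenes} are merged into the
#' flanking segment with more anchor support (ties toward the preceding
#' segment), and segments supported by fewer than \code{minPaint} anchors
#' are merged likewise.
#'
#' @param blockSet blocks with the extant genome as A and the ancestor
#'   proxy as B.
#' @param extant the extant \linkS4class{GenomeTable}.
#' @param ancestorMap \linkS4class{KaryotypeMap} resolving the proxy.
#' @param minPaint minimum anchors per emitted segment (default 3).
#' @param minSegmentGenes minimum genes per segment (default 10).
#' @return a \linkS4class{KaryotypePainting}.
#' @export
paintChromosomes <- function(blockSet, extant, ancestorMap, minPaint = 3L,
                             minSegmentGenes = 10L) {
  if (!nrow(ancestorMap@segments))
    stop("ancestor map carries no proto assignments")
  an <- anchors(blockSet)
  an$proto <- .protoAt(ancestorMap, an$chrom_b, an$rank_b)
  an <- an[!is.na(an$proto), , drop = FALSE]
  g <- genes(extant)
  segs <- list()
  for (ch in unique(g$chromosome)) {
    n <- sum(g$chromosome == ch)
    aCh <- an[an$chrom_a == ch, , drop = FALSE]
    ## score-weighted proto vote per rank
    protos <- unique(aCh$proto)
    votes <- matrix(0, nrow = n, ncol = length(protos),
                    dimnames = list(NULL, protos))
    if (nrow(aCh))
      for (i in seq_len(nrow(aCh)))
        votes[aCh$rank_a[i] + 1L, aCh$proto[i]] <-
          votes[aCh$rank_a[i] + 1L, aCh$proto[i]] + aCh$score[i]
    assn <- rep(NA_character_, n)
    sup <- rowSums(votes) > 0
    if (any(sup))
      assn[sup] <- protos[max.col(votes[sup, , drop = FALSE],
                                  ties.method = "first")]
    if (all(is.na(assn))) next
    ## fill unanchored genes from the nearest assigned neighbour
    idx <- which(!is.na(assn))
    near <- idx[pmax(1L, findInterval(seq_len(n), idx))]
    ## findInterval gives the preceding assigned gene; genes before the
    ## first assigned one inherit from it
    assn <- assn[near]
    anchCount <- tabulate(aCh$rank_a + 1L, n)
    assn <- .mergeShortRuns(assn, anchCount, minSegmentGenes)
    ## per-segment support, then merge under-supported segments
    repeat {
      r <- rle(assn)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
      segSup <- vapply(seq_along(ends), function(i) {
        sum(aCh$proto == r$values[i] &
            aCh$rank_a >= starts[i] - 1L & aCh$rank_a <= ends[i] - 1L)
      }, numeric(1))
      weak <- which(segSup < minPaint)
      if (!length(weak) || length(ends) == 1) break
      i <- weak[which.min(segSup[weak])]
      left <- if (i > 1) segSup[i - 1] else -Inf
      right <- if (i < length(ends)) segSup[i + 1] else -Inf
      tgt <- if (left >= right) i - 1 else i + 1
      if (!is.finite(left) && !is.finite(right)) break
      assn[starts[i]:ends[i]] <- r$values[tgt]
    }
    r <- rle(assn)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (i in seq_along(ends)) {
      inSeg <- aCh$proto == r$values[i] &
               aCh$rank_a >= starts[i] - 1L & aCh$rank_a <= ends[i] - 1L
      pm <- if (any(inSeg)) min(aCh$rank_b[inSeg]) else NA_integer_
      px <- if (any(inSeg)) max(aCh$rank_b[inSeg]) else NA_integer_
      ori <- if (sum(inSeg) >= 2) {
        ct <- stats::cor(aCh$rank_a[inSeg], aCh$rank_b[inSeg])
        if (!is.na(ct) && ct < 0) "antiparallel" else "parallel"
      } else "parallel"
      segs[[length(segs) + 1L]] <- data.frame(
        chromosome = ch, rank_start = starts[i] - 1L, rank_end = ends[i],
        proto = r$values[i], orientation = ori, support = sum(inSeg),
        proto_min = pm, proto_max = px, stringsAsFactors = FALSE)
    }
  }
  segdf <- if (length(segs)) do.call(rbind, segs) else
    data.frame(chromosome = character(), rank_start = integer(),
               rank_end = integer(), proto = character(),
               orientation = character(), support = integer(),
               proto_min = integer(), proto_max = integer())
  new("KaryotypePainting", genomeId = genomeId(extant),
      ancestorId = ancestorMap@karyotypeId, segments = segdf)
}

#' Classify rearrangement events from a painting
#'
#' Signature matching per chromosome: an X-Y-X pattern is a nested
#' chromosome fusion (Y into X); adjacent distinct protos whose segments
#' both reach their proto-chromosome termini are end-to-end joins; a proto
#' split across two chromosomes that reciprocally exchange with a second
#' proto is one reciprocal arm translocation; a split without reciprocity
#' is a fission; anything else is surfaced UNRESOLVED with its signature.
#' The chromosome-count identity n_extant = n_proto - #EEJ - #NCF +
#' #FISSION is reported as an arithmetic check.
#'
#' @param painting a \linkS4class{KaryotypePainting}.
#' @param ancestorMap the map the painting was made against.
#' @param telomereWindow ranks from a proto end that count as terminal
#'   (default 5).
#' @return list: \code{events} data.frame (kind, protos, chromosome,
#'   evidence), \code{check} list with the count arithmetic, and
#'   \code{n_extant}.
#' @export
classifyEvents <- function(painting, ancestorMap, telomereWindow = 5L) {
  segs <- painting@segments
  if (!nrow(segs)) stop("empty painting")
  plen <- .protoLengths(ancestorMap)
  complete <- function(proto, pmin, pmax) {
    !is.na(pmin) && pmin <= telomereWindow - 1L &&
      pmax >= plen[[proto]] - telomereWindow
  }
  headOnly <- function(proto, pmin, pmax)
    !is.na(pmin) && xor(pmin <= telomereWindow - 1L,
                        pmax >= plen[[proto]] - telomereWindow)
  events <- list()
  partial <- list()  # candidate RTA/FISSION pieces
  emit <- function(kind, protos, chrom, evidence)
    events[[length(events) + 1L]] <<- data.frame(
      kind = kind, protos = paste(sort(protos), collapse = "+"),
      chromosome = chrom, evidence = evidence, stringsAsFactors = FALSE)
  for (ch in unique(segs$chromosome)) {
    s <- segs[segs$chromosome == ch, , drop = FALSE]
    s <- s[order(s$rank_start), , drop = FALSE]
    sig <- paste(s$proto, collapse = "-")
    ## collapse nested donors: X-Y-X -> NCF(Y into X)
    repeat {
      if (nrow(s) < 3) break
      hit <- 0L
      for (i in 2:(nrow(s) - 1L))
        if (s$proto[i - 1] == s$proto[i + 1] &&
            s$proto[i] != s$proto[i - 1]) { hit <- i; break }
      if (!hit) break
      emit("NCF", c(s$proto[hit], s$proto[hit - 1]), ch,
           paste0(s$proto[hit - 1], "-", s$proto[hit], "-",
                  s$proto[hit - 1]))
      merged <- s[hit - 1, ]
      merged$rank_end <- s$rank_end[hit + 1]
      merged$support <- s$support[hit - 1] + s$support[hit + 1]
      merged$proto_min <- min(s$proto_min[c(hit - 1, hit + 1)], na.rm = TRUE)
      merged$proto_max <- max(s$proto_max[c(hit - 1, hit + 1)], na.rm = TRUE)
      s <- rbind(if (hit > 2) s[1:(hit - 2), ], merged,
                 if (hit + 2 <= nrow(s)) s[(hit + 2):nrow(s), ])
    }
    if (nrow(s) == 1) {
      if (!complete(s$proto[1], s$proto_min[1], s$proto_max[1]))
        partial[[length(partial) + 1L]] <-
          cbind(s, chrom = ch, stringsAsFactors = FALSE)
      next
    }
    ## linear multi-proto chromosome: EEJ at junctions of complete segments
    comp <- vapply(seq_len(nrow(s)), function(i)
      complete(s$proto[i], s$proto_min[i], s$proto_max[i]), logical(1))
    for (i in seq_len(nrow(s) - 1L)) {
      if (comp[i] && comp[i + 1]) {
        emit("EEJ", c(s$proto[i], s$proto[i + 1]), ch,
             paste0(s$proto[i], "|", s$proto[i + 1]))
      }
    }
    ## incomplete segments await cross-chromosome (RTA/fission) resolution
    for (i in which(!comp))
      partial[[length(partial) + 1L]] <-
        cbind(s[i, ], chrom = ch, stringsAsFactors = FALSE)
  }
  evdf <- if (length(events)) do.call(rbind, events) else
    data.frame(kind = character(), protos = character(),
               chromosome = character(), evidence = character(),
               stringsAsFactors = FALSE)
  ## cross-chromosome resolution of partial pieces
  if (length(partial)) {
    pd <- do.call(rbind, partial)
    byProto <- split(pd, pd$proto)
    handled <- character()
    for (p in names(byProto)) {
      if (p %in% handled) next
      pieces <- byProto[[p]]
      chs <- unique(pieces$chrom)
      if (length(chs) == 2) {
        ## reciprocity: another split proto on the same two chromosomes?
        mates <- setdiff(names(byProto), p)
        rec <- mates[vapply(mates, function(m)
          setequal(unique(byProto[[m]]$chrom), chs), logical(1))]
        if (length(rec)) {
          m <- rec[1]
          evdf <- rbind(evdf, data.frame(
            kind = "RTA", protos = paste(sort(c(p, m)), collapse = "+"),
            chromosome = paste(sort(chs), collapse = ","),
            evidence = "reciprocal arm exchange", stringsAsFactors = FALSE))
          handled <- c(handled, p, m)
          next
        }
        evdf <- rbind(evdf, data.frame(
          kind = "FISSION", protos = p,
          chromosome = paste(sort(chs), collapse = ","),
          evidence = "proto split without reciprocity",
          stringsAsFactors = FALSE))
        handled <- c(handled, p)
      } else if (length(chs) > 2) {
        evdf <- rbind(evdf, data.frame(
          kind = "UNRESOLVED", protos = p,
          chromosome = paste(sort(chs), collapse = ","),
          evidence = paste0("proto on ", length(chs), " chromosomes"),
          stringsAsFactors = FALSE))
        handled <- c(handled, p)
      }
      ## single truncated piece on one chromosome: fractionation noise,
      ## not an event
    }
  }
  nExtant <- length(unique(segs$chromosome))
  nProto <- length(unique(segs$proto))
  nEej <- sum(evdf$kind == "EEJ"); nNcf <- sum(evdf$kind == "NCF")
  nFis <- sum(evdf$kind == "FISSION")
  predicted <- nProto - nEej - nNcf + nFis
  list(events = evdf,
       check = list(n_extant = nExtant, n_proto = nProto, eej = nEej,
                    ncf = nNcf, fission = nFis,
                    predicted_n = predicted,
                    balanced = predicted == nExtant),
       n_extant = nExtant)
}

## union-find
.ufFind <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

#' Reconstruct an ancestral karyotype from a conserved post-WGD genome
#'
#' Step 1 verifies the claimed multiplicity against the modal intra-genomic
#' syntenic depth. Step 2 groups self-syntenic blocks at the WGD's Ks age
#' into ancestral linkage groups by single-linkage clustering (two regions
#' join a proto-chromosome when connected by a block or by a sufficient
#' rank overlap on the same chromosome), assigns every gene to the group
#' covering it best, and orders each proto by the gene order of its
#' largest extant copy. Step 3 validates that each proto-chromosome occurs
#' exactly \code{multiplicity} times and, when outgroup blocks are given,
#' that one-to-one collinearity with the outgroup covers at least
#' \code{minCollinearFraction} of its genes.
#'
#' @param genome the conserved \linkS4class{GenomeTable}.
#' @param selfBlocks Ks-annotated self-comparison
#'   \linkS4class{SyntenyBlockSet}.
#' @param multiplicity claimed WGD multiplicity (2 or 3).
#' @param wgdKs Ks age of the WGD peak; default median of block medians.
#' @param ksWindow age gate half-width (default 0.2).
#' @param minSegGenes minimum genes per emitted map segment (default 10).
#' @param minOverlap rank overlap required to merge same-chromosome
#'   regions (default 5).
#' @param maxJoinGap rank gap across which abutting same-chromosome
#'   regions linked to the same partner chromosome still merge (default
#'   25, matching the chaining gap).
#' @param minProtoGenes components smaller than this are dissolved
#'   (default 30).
#' @param outgroupBlocks optional blocks genome-vs-outgroup for Step 3.
#' @param minCollinearFraction outgroup validation threshold (default 0.6).
#' @return list: \code{map} (\linkS4class{KaryotypeMap}), \code{assignment}
#'   (per-gene proto), \code{validation} (per-proto copies and outgroup
#'   fraction), \code{ok}.
#' @export
reconstructAncestor <- function(genome, selfBlocks, multiplicity,
                                wgdKs = NULL, ksWindow = 0.2,
                                minSegGenes = 10L, minOverlap = 5L,
                                maxJoinGap = 25L, minProtoGenes = 30L,
                                outgroupBlocks = NULL,
                                minCollinearFraction = 0.6) {
  bl <- blocks(selfBlocks); an <- anchors(selfBlocks)
  if (is.null(wgdKs)) {
    wgdKs <- stats::median(bl$median_ks, na.rm = TRUE)
    if (is.na(wgdKs)) stop("blocks carry no Ks; annotate or pass wgdKs")
  }
  keep <- !is.na(bl$median_ks) & abs(bl$median_ks - wgdKs) <= ksWindow
  bl <- bl[keep, , drop = FALSE]
  if (!nrow(bl)) stop("no self-synteny blocks at the WGD age; no clustering solution")
  an <- an[an$block_id %in% bl$block_id, , drop = FALSE]
  ## Step 1: modal self-depth equals multiplicity - 1 partner copies
  spans <- do.call(rbind, lapply(split(an, an$block_id), function(x)
    data.frame(block_id = x$block_id[1],
               chrom_a = x$chrom_a[1], lo_a = min(x$rank_a),
               hi_a = max(x$rank_a), chrom_b = x$chrom_b[1],
               lo_b = min(x$rank_b), hi_b = max(x$rank_b),
               stringsAsFactors = FALSE)))
  dA <- .depthOneSide(genome, spans, "chrom_a", "lo_a", "hi_a")
  dB <- .depthOneSide(genome, spans, "chrom_b", "lo_b", "hi_b")
  selfDepth <- dA$depth + dB$depth
  modal <- .modalDepth(selfDepth)
  if (modal != multiplicity - 1L)
    warning("modal self-depth ", modal, " does not match multiplicity ",
            multiplicity, " - 1; reconstruction may be unreliable")
  ## Step 2: single-linkage clustering of block-linked regions
  nb <- nrow(spans)
  nodes <- rbind(
    data.frame(id = seq_len(nb), chrom = spans$chrom_a, lo = spans$lo_a,
               hi = spans$hi_a, partner = spans$chrom_b,
               stringsAsFactors = FALSE),
    data.frame(id = nb + seq_len(nb), chrom = spans$chrom_b,
               lo = spans$lo_b, hi = spans$hi_b, partner = spans$chrom_a,
               stringsAsFactors = FALSE))
  parent <- seq_len(2L * nb)
  union <- function(i, j) {
    ri <- .ufFind(parent, i); rj <- .ufFind(parent, j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (i in seq_len(nb)) union(i, nb + i)  # the two copies of one segment
  for (ch in unique(nodes$chrom)) {
    ids <- which(nodes$chrom == ch)
    ids <- ids[order(nodes$lo[ids])]
    for (k in seq_along(ids)) {
      for (m in seq_len(k - 1L)) {
        ov <- min(nodes$hi[ids[k]], nodes$hi[ids[m]]) -
              max(nodes$lo[ids[k]], nodes$lo[ids[m]]) + 1L
        ## overlapping regions always merge; abutting regions merge only
        ## when they collinearise against the same partner chromosome
        ## (a nested insertion splits both copies at the same spot, so
        ## the two flanks of the intact copy never overlap)
        if (ov >= minOverlap ||
            (ov > -maxJoinGap &&
             nodes$partner[ids[k]] == nodes$partner[ids[m]]))
          union(ids[k], ids[m])
      }
    }
  }
  comp <- vapply(seq_len(2L * nb), function(i) .ufFind(parent, i),
                 integer(1))
  nodes$comp <- comp
  ## per-gene component votes (number of covering intervals per component)
  g <- genes(genome)
  assn <- rep(NA_integer_, nrow(g))
  votes <- new.env(parent = emptyenv())
  gidx <- split(seq_len(nrow(g)), g$chromosome)
  compOf <- rep(NA_integer_, nrow(g))
  for (ch in unique(nodes$chrom)) {
    rows <- gidx[[ch]]
    if (is.null(rows)) next
    rr <- g$rank[rows]
    sub <- nodes[nodes$chrom == ch, , drop = FALSE]
    cps <- unique(sub$comp)
    vm <- matrix(0L, nrow = length(rows), ncol = length(cps),
                 dimnames = list(NULL, as.character(cps)))
    for (i in seq_len(nrow(sub))) {
      hit <- rr >= sub$lo[i] & rr <= sub$hi[i]
      vm[hit, as.character(sub$comp[i])] <-
        vm[hit, as.character(sub$comp[i])] + 1L
    }
    got <- rowSums(vm) > 0
    compOf[rows[got]] <- cps[max.col(vm[got, , drop = FALSE],
                                     ties.method = "first")]
  }
  ## dissolve tiny components, then fill gaps from neighbours
  sizes <- table(compOf)
  small <- as.integer(names(sizes)[sizes < minProtoGenes])
  compOf[compOf %in% small] <- NA_integer_
  if (all(is.na(compOf))) stop("no clustering solution")
  ord <- order(g$chromosome, g$rank)
  for (ch in unique(g$chromosome)) {
    rows <- gidx[[ch]][order(g$rank[gidx[[ch]]])]
    v <- compOf[rows]
    idx <- which(!is.na(v))
    if (!length(idx)) next
    near <- idx[pmax(1L, findInterval(seq_along(v), idx))]
    compOf[rows] <- v[near]
  }
  ## name protos by decreasing size
  sizes <- sort(table(compOf), decreasing = TRUE)
  protoName <- stats::setNames(sprintf("R%02d", seq_along(sizes)),
                               names(sizes))
  protoOf <- protoName[as.character(compOf)]
  ## map segments: merged runs per chromosome
  segs <- list()
  for (ch in unique(g$chromosome)) {
    rows <- gidx[[ch]][order(g$rank[gidx[[ch]]])]
    v <- protoOf[rows]
    if (all(is.na(v))) next
    v <- .mergeShortRuns(v, rep(1, length(v)), minSegGenes)
    protoOf[rows] <- v
    r <- rle(v)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (i in seq_along(ends))
      segs[[length(segs) + 1L]] <- data.frame(
        genome_id = genomeId(genome), chromosome = ch,
        rank_start = starts[i] - 1L, rank_end = ends[i],
        proto = r$values[i], stringsAsFactors = FALSE)
  }
  segdf <- do.call(rbind, segs)
  map <- new("KaryotypeMap",
             karyotypeId = paste0(genomeId(genome), "-ancestor"),
             protoChromosomes = unname(protoName),
             segments = segdf)
  ## Step 3: validation
  copies <- vapply(unname(protoName), function(p) {
    s <- segdf[segdf$proto == p, , drop = FALSE]
    cnt <- tapply(s$rank_end - s$rank_start, s$chromosome, sum)
    sum(cnt >= minSegGenes)
  }, integer(1))
  outFrac <- rep(NA_real_, length(copies))
  if (!is.null(outgroupBlocks)) {
    oan <- anchors(outgroupBlocks)
    inBlock <- g$gene_id %in% oan$gene_a
    outFrac <- vapply(unname(protoName), function(p)
      mean(inBlock[which(protoOf == p)]), numeric(1))
  }
  val <- data.frame(proto = unname(protoName), copies = copies,
                    genes = as.integer(table(protoOf)[unname(protoName)]),
                    outgroup_fraction = outFrac,
                    stringsAsFactors = FALSE)
  ok <- all(copies == multiplicity) &&
        (is.null(outgroupBlocks) ||
         all(outFrac >= minCollinearFraction, na.rm = TRUE))
  assignment <- data.frame(gene_id = g$gene_id, chromosome = g$chromosome,
                           rank = g$rank, proto = unname(protoOf),
                           stringsAsFactors = FALSE)
  list(map = map, assignment = assignment, validation = val, ok = ok)
}

#' Per-lineage trajectory table and shared-event intersection
#'
#' Events are keyed by kind and the involved proto-chromosome pair;
#' identical keys across lineages are candidate shared events.
#'
#' @param eventsByLineage named list: lineage -> result of
#'   \code{\link{classifyEvents}}.
#' @return list: \code{perLineage} (lineage, eej, ncf, rta, fission,
#'   unresolved, n_extant), \code{shared} (key, kind, protos, n_lineages,
#'   lineages).
#' @export
trajectoryReport <- function(eventsByLineage) {
  per <- do.call(rbind, lapply(names(eventsByLineage), function(ln) {
    e <- eventsByLineage[[ln]]$events
    data.frame(lineage = ln,
               eej = sum(e$kind == "EEJ"), ncf = sum(e$kind == "NCF"),
               rta = sum(e$kind == "RTA"),
               fission = sum(e$kind == "FISSION"),
               unresolved = sum(e$kind == "UNRESOLVED"),
               n_extant = eventsByLineage[[ln]]$n_extant,
               stringsAsFactors = FALSE)
  }))
  keys <- lapply(names(eventsByLineage), function(ln) {
    e <- eventsByLineage[[ln]]$events
    e <- e[e$kind %in% c("EEJ", "NCF"), , drop = FALSE]
    unique(paste(e$kind, e$protos))
  })
  names(keys) <- names(eventsByLineage)
  allk <- unique(unlist(keys))
  shared <- do.call(rbind, lapply(allk, function(k) {
    lns <- names(keys)[vapply(keys, function(x) k %in% x, logical(1))]
    if (length(lns) < 2) return(NULL)
    data.frame(key = k, kind = sub(" .*", "", k),
               protos = sub("^[A-Z]+ ", "", k),
               n_lineages = length(lns),
               lineages = paste(lns, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  if (is.null(shared))
    shared <- data.frame(key = character(), kind = character(),
                         protos = character(), n_lineages = integer(),
                         lineages = character(), stringsAsFactors = FALSE)
  list(perLineage = per, shared = shared)
}
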