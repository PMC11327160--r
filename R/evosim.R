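#' @include AllClasses.R AllGenerics.R
NULL

## gene coordinates are regenerated from ranks after every operation: base
## pairs carry no information in simulated genomes, only gene order does
.GENE_SPACING <- 1000L
.GENE_LEN <- 900L

.rebuildGenome <- function(genomeIdStr, genesdf) {
  genesdf <- genesdf[order(genesdf$chromosome, genesdf$rank), , drop = FALSE]
  genesdf$rank <- as.integer(stats::ave(seq_len(nrow(genesdf)),
                                        genesdf$chromosome,
                                        FUN = function(i) seq_along(i) - 1L))
  genesdf$start <- genesdf$rank * .GENE_SPACING
  genesdf$end <- genesdf$start + .GENE_LEN
  rownames(genesdf) <- NULL
  lens <- vapply(split(genesdf$end, genesdf$chromosome), max, numeric(1)) + 1
  new("GenomeTable", genomeId = genomeIdStr,
      genes = genesdf[, .GENE_COLS], chromosomeLengths = lens)
}

.newEventId <- function(sim) sprintf("E%03d", nrow(sim@events) + 1L)

## kinds that create divergent gene pairs; only their ages must be applied
## oldest-first (neutral rearrangements carry an age for the record only)
.PAIR_KINDS <- c("WGD", "WGT", "SPLIT", "TD", "PD", "TRD", "DSD")

.lastAge <- function(sim) {
  a <- sim@events$age_ks[sim@events$kind %in% .PAIR_KINDS]
  if (length(a)) min(a) else Inf
}

.addEvent <- function(sim, kind, age, detail = "") {
  id <- .newEventId(sim)
  if (kind %in% .PAIR_KINDS && age > .lastAge(sim) + 1e-9)
    stop("event age ", age, " is older than an already-applied event; ",
         "events must be applied oldest first")
  sim@events <- rbind(sim@events,
                      data.frame(event_id = id, kind = kind, age_ks = age,
                                 detail = detail, stringsAsFactors = FALSE))
  list(sim = sim, id = id)
}

#' Simulate an ancestral genome
#'
#' Creates a diploid-like ancestor of single-copy genes: every gene founds
#' its own family and its chromosome is its proto-chromosome.
#'
#' @param nChromosomes number of chromosomes (>= 1).
#' @param genesPerChromosome genes on each chromosome (>= 1).
#' @param seed integer seed (strand draw).
#' @param genomeId identifier, default "ancestor".
#' @return a \linkS4class{GenomeSimulation}.
#' @export
simulateAncestor <- function(nChromosomes, genesPerChromosome, seed = 1L,
                             genomeId = "ancestor") {
  if (nChromosomes < 1 || genesPerChromosome < 1)
    stop("nChromosomes and genesPerChromosome must be >= 1")
  set.seed(seed)
  n <- nChromosomes * genesPerChromosome
  chrom <- rep(sprintf("chr%02d", seq_len(nChromosomes)),
               each = genesPerChromosome)
  gid <- sprintf("g%05d", seq_len(n))
  genesdf <- data.frame(
    gene_id = gid, chromosome = chrom, start = 0L, end = 1L,
    strand = sample(c("+", "-"), n, replace = TRUE),
    rank = rep(seq_len(genesPerChromosome) - 1L, nChromosomes),
    family_id = gid, stringsAsFactors = FALSE)
  truth <- data.frame(gene_id = gid, ancestral_gene = gid, proto = chrom,
                      copy_path = "", mode = NA_character_,
                      stringsAsFactors = FALSE)
  events <- data.frame(event_id = character(), kind = character(),
                       age_ks = numeric(), detail = character(),
                       stringsAsFactors = FALSE)
  new("GenomeSimulation", genome = .rebuildGenome(genomeId, genesdf),
      truth = truth, events = events)
}

#' Apply a whole-genome duplication or triplication
#'
#' Every chromosome and gene is copied \code{multiplicity} times; the copies
#' are labelled (default A/B/C) and the label is appended to each gene's
#' copy path, from which per-event subgenome membership and pairwise
#' divergence ages derive.
#'
#' @param sim a \linkS4class{GenomeSimulation}.
#' @param multiplicity 2 (WGD) or 3 (WGT).
#' @param ageKs mean synonymous divergence of paralog pairs created here.
#' @param labels copy labels, default LETTERS.
#' @return the updated simulation.
#' @export
applyPolyploidy <- function(sim, multiplicity, ageKs,
                            labels = LETTERS[seq_len(multiplicity)]) {
  if (!multiplicity %in% c(2L, 3L)) stop("multiplicity must be 2 or 3")
  if (ageKs <= 0) stop("ageKs must be > 0")
  kind <- if (multiplicity == 2) "WGD" else "WGT"
  ae <- .addEvent(sim, kind, ageKs, paste(labels, collapse = ","))
  sim <- ae$sim; id <- ae$id
  g <- genes(sim@genome); tr <- sim@truth
  glist <- list(); tlist <- list()
  for (k in seq_len(multiplicity)) {
    gk <- g; tk <- tr
    gk$gene_id <- paste0(g$gene_id, "_", labels[k])
    gk$chromosome <- paste0(g$chromosome, labels[k])
    tk$gene_id <- gk$gene_id
    tk$copy_path <- ifelse(nzchar(tr$copy_path),
                           paste0(tr$copy_path, ";", id, "=", labels[k]),
                           paste0(id, "=", labels[k]))
    glist[[k]] <- gk; tlist[[k]] <- tk
  }
  sim@genome <- .rebuildGenome(genomeId(sim@genome), do.call(rbind, glist))
  sim@truth <- do.call(rbind, tlist)
  rownames(sim@truth) <- NULL
  validObject(sim)
  sim
}

#' Apply a chromosome fusion (EEJ or NCF)
#'
#' EEJ concatenates the donor after the host terminus; NCF inserts the whole
#' donor at a strictly internal host rank so the host painting pattern reads
#' host-donor-host. Chromosome count drops by one.
#'
#' @param sim a \linkS4class{GenomeSimulation}.
#' @param kind "EEJ" or "NCF".
#' @param donor,host chromosome names; the fused chromosome keeps the host
#'   name and the donor name disappears.
#' @param insertionRank NCF only: host rank the donor is inserted at
#'   (0 < rank < host gene count).
#' @param reverseDonor logical or NA (NA = seeded random choice for EEJ).
#' @param ageKs event age for the log (ordering only), default the age of
#'   the last event.
#' @export
applyFusion <- function(sim, kind = c("EEJ", "NCF"), donor, host,
                        insertionRank = NULL, reverseDonor = NA,
                        ageKs = NULL) {
  kind <- match.arg(kind)
  g <- genes(sim@genome)
  if (donor == host) stop("donor and host must differ")
  if (!donor %in% g$chromosome) stop("unknown donor chromosome: ", donor)
  if (!host %in% g$chromosome) stop("unknown host chromosome: ", host)
  if (is.null(ageKs)) ageKs <- if (is.finite(.lastAge(sim))) .lastAge(sim) else 0
  hostN <- sum(g$chromosome == host)
  if (kind == "NCF") {
    if (is.null(insertionRank))
      stop("NCF requires insertionRank")
    if (insertionRank <= 0 || insertionRank >= hostN)
      stop("NCF insertion at a terminal rank: that is EEJ")
  }
  if (is.na(reverseDonor)) reverseDonor <- stats::runif(1) < 0.5
  dg <- g[g$chromosome == donor, ]
  dg <- dg[order(dg$rank), ]
  if (reverseDonor) {
    dg <- dg[rev(seq_len(nrow(dg))), ]
    dg$strand <- ifelse(dg$strand == "+", "-", "+")
  }
  hg <- g[g$chromosome == host, ]
  hg <- hg[order(hg$rank), ]
  rest <- g[!g$chromosome %in% c(donor, host), ]
  if (kind == "EEJ") {
    fused <- rbind(hg, dg)
  } else {
    fused <- rbind(hg[seq_len(insertionRank), ], dg,
                   hg[(insertionRank + 1):hostN, ])
  }
  fused$chromosome <- host
  fused$rank <- seq_len(nrow(fused)) - 1L
  ae <- .addEvent(sim, kind, ageKs,
                  paste0(donor, ">", host,
                         if (kind == "NCF") paste0("@", insertionRank) else ""))
  sim <- ae$sim
  sim@genome <- .rebuildGenome(genomeId(sim@genome), rbind(rest, fused))
  validObject(sim)
  sim
}

#' Apply a reciprocal translocation of chromosome arms
#'
#' The tails beyond the two (strictly internal) break ranks are exchanged;
#' chromosome count is unchanged.
#'
#' @param sim a \linkS4class{GenomeSimulation}.
#' @param chromA,chromB chromosome names.
#' @param breakA,breakB break ranks; the tail from the break rank onward
#'   moves (0 < break < gene count).
#' @param ageKs event age for the log.
#' @export
applyRta <- function(sim, chromA, chromB, breakA, breakB, ageKs = NULL) {
  g <- genes(sim@genome)
  for (ch in c(chromA, chromB))
    if (!ch %in% g$chromosome) stop("unknown chromosome: ", ch)
  if (chromA == chromB) stop("chromosomes must differ")
  nA <- sum(g$chromosome == chromA); nB <- sum(g$chromosome == chromB)
  if (breakA <= 0 || breakA >= nA || breakB <= 0 || breakB >= nB)
    stop("terminal break rank; breaks must be strictly internal")
  if (is.null(ageKs)) ageKs <- if (is.finite(.lastAge(sim))) .lastAge(sim) else 0
  ga <- g[g$chromosome == chromA, ]; ga <- ga[order(ga$rank), ]
  gb <- g[g$chromosome == chromB, ]; gb <- gb[order(gb$rank), ]
  rest <- g[!g$chromosome %in% c(chromA, chromB), ]
  newA <- rbind(ga[seq_len(breakA), ], gb[(breakB + 1):nB, ])
  newB <- rbind(gb[seq_len(breakB), ], ga[(breakA + 1):nA, ])
  newA$chromosome <- chromA; newB$chromosome <- chromB
  newA$rank <- seq_len(nrow(newA)) - 1L
  newB$rank <- seq_len(nrow(newB)) - 1L
  ae <- .addEvent(sim, "RTA", ageKs,
                  paste0(chromA, "@", breakA, "<->", chromB, "@", breakB))
  sim <- ae$sim
  sim@genome <- .rebuildGenome(genomeId(sim@genome), rbind(rest, newA, newB))
  validObject(sim)
  sim
}

#' Apply an inversion
#'
#' Gene order within the half-open rank interval is reversed and strands
#' flipped.
#'
#' @param sim a \linkS4class{GenomeSimulation}.
#' @param chromosome chromosome name.
#' @param rankStart,rankEnd half-open rank interval, non-empty.
#' @param ageKs event age for the log.
#' @export
applyInversion <- function(sim, chromosome, rankStart, rankEnd,
                           ageKs = NULL) {
  g <- genes(sim@genome)
  if (!chromosome %in% g$chromosome) stop("unknown chromosome: ", chromosome)
  n <- sum(g$chromosome == chromosome)
  if (rankStart < 0 || rankEnd > n || rankStart >= rankEnd)
    stop("empty or out-of-range inversion interval")
  if (is.null(ageKs)) ageKs <- if (is.finite(.lastAge(sim))) .lastAge(sim) else 0
  gc <- g[g$chromosome == chromosome, ]; gc <- gc[order(gc$rank), ]
  idx <- (rankStart + 1):rankEnd
  seg <- gc[rev(idx), ]
  seg$strand <- ifelse(seg$strand == "+", "-", "+")
  gc[idx, ] <- seg
  gc$rank <- seq_len(nrow(gc)) - 1L
  rest <- g[g$chromosome != chromosome, ]
  ae <- .addEvent(sim, "INV", ageKs,
                  paste0(chromosome, "[", rankStart, ",", rankEnd, ")"))
  sim <- ae$sim
  sim@genome <- .rebuildGenome(genomeId(sim@genome), rbind(rest, gc))
  validObject(sim)
  sim
}

#' Fractionate duplicated genes with per-subgenome retention
#'
#' Each gene carrying a subgenome label for \code{eventId} is independently
#' retained with its subgenome's probability; every ancestral family keeps
#' at least one copy (a uniformly chosen copy is rescued when all copies
#' would be lost).
#'
#' @param sim a \linkS4class{GenomeSimulation}.
#' @param retention named probabilities, one per subgenome label of the
#'   event (e.g. \code{c(A = 0.8, B = 0.5)}).
#' @param eventId polyploidy event the labels refer to; default the most
#'   recent WGD/WGT.
#' @param seed integer seed.
#' @export
fractionate <- function(sim, retention, eventId = NULL, seed = 1L) {
  if (any(retention < 0 | retention > 1))
    stop("retention probabilities must be in [0, 1]")
  ev <- sim@events
  if (is.null(eventId)) {
    poly <- ev$event_id[ev$kind %in% c("WGD", "WGT")]
    if (!length(poly)) stop("no polyploidy event to fractionate")
    eventId <- poly[length(poly)]
  }
  set.seed(seed)
  lab <- .eventLabel(sim@truth$copy_path, eventId)
  p <- retention[lab]
  p[is.na(p)] <- 1  # genes without the label (or unlisted subgenome) kept
  keep <- stats::runif(length(p)) < p
  ## every ancestral family keeps at least one copy: families drawn as
  ## all-lost are redrawn, i.e. retention is conditioned on survival
  fam <- sim@truth$ancestral_gene
  repeat {
    lost <- setdiff(unique(fam), unique(fam[keep]))
    if (!length(lost)) break
    idx <- which(fam %in% lost)
    keep[idx] <- stats::runif(length(idx)) < p[idx]
  }
  keptIds <- sim@truth$gene_id[keep]
  g <- genes(sim@genome)
  g <- g[g$gene_id %in% keptIds, ]
  ae <- .addEvent(sim, "LOSS",
                  if (is.finite(.lastAge(sim))) .lastAge(sim) else 0,
                  paste0(eventId, ":",
                         paste(names(retention), retention, sep = "=",
                               collapse = ",")))
  sim <- ae$sim
  sim@genome <- .rebuildGenome(genomeId(sim@genome), g)
  sim@truth <- sim@truth[keep, ]
  rownames(sim@truth) <- NULL
  validObject(sim)
  sim
}

## subgenome label of each copy path for one event id ("" when absent)
.eventLabel <- function(paths, eventId) {
  pat <- paste0("(?:^|;)", eventId, "=([^;]+)")
  m <- regmatches(paths, regexpr(pat, paths, perl = TRUE))
  out <- rep(NA_character_, length(paths))
  has <- grepl(pat, paths, perl = TRUE)
  out[has] <- sub(pat, "\\1", regmatches(paths, regexpr(pat, paths,
                                                        perl = TRUE)),
                  perl = TRUE)
  out
}

#' Plant small-scale duplications
#'
#' TD inserts the copy rank-adjacent to its parent; PD within
#' \code{proximalWindow} ranks on the same chromosome; TRD moves the copy to
#' a random position on another chromosome while the parent keeps its
#' ancestral locus; DSD inserts the copy at a random non-adjacent,
#' non-proximal position and marks the family untraceable (its outgroup
#' ortholog is dropped by the scenario runner, emulating dispersed
#' duplicates whose ancestral locus is no longer recoverable).
#'
#' @param sim a \linkS4class{GenomeSimulation}.
#' @param kind one of "TD", "PD", "TRD", "DSD".
#' @param n number of events to plant.
#' @param ageKs divergence age of the created pairs.
#' @param proximalWindow PD window in ranks (> 1, default 10).
#' @param seed integer seed.
#' @export
applySmallScaleDuplication <- function(sim, kind = c("TD", "PD", "TRD", "DSD"),
                                       n = 1L, ageKs = 0.05,
                                       proximalWindow = 10L, seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  for (k in seq_len(n)) {
    g <- genes(sim@genome)
    ## one small-scale event per ancestral family keeps truth unambiguous
    touched <- unique(sim@truth$ancestral_gene[!is.na(sim@truth$mode)])
    fam <- stats::setNames(sim@truth$ancestral_gene, sim@truth$gene_id)
    eligible <- which(!(fam[g$gene_id] %in% touched))
    if (!length(eligible)) stop("no untouched family left to duplicate")
    parent <- g[eligible[sample.int(length(eligible), 1)], ]
    chromN <- table(g$chromosome)
    newId <- paste0(parent$gene_id, "_", tolower(kind),
                    sum(sim@events$kind == kind) + 1L)
    ## rank distance between parent and copy after the copy is inserted at
    ## position `at` (insertion at <= parent rank shifts the parent by one)
    distAfter <- function(at, prank)
      ifelse(at > prank, at - prank, prank + 1L - at)
    if (kind == "TD") {
      chrom <- parent$chromosome; at <- parent$rank + 1L
    } else if (kind == "PD") {
      chrom <- parent$chromosome
      cand <- 0:chromN[[chrom]]
      d <- distAfter(cand, parent$rank)
      cand <- cand[d >= 2 & d <= proximalWindow]
      if (!length(cand)) stop("chromosome too short for a proximal insert")
      at <- cand[sample.int(length(cand), 1)]
    } else if (kind == "TRD") {
      others <- setdiff(names(chromN), parent$chromosome)
      if (!length(others)) stop("TRD requires a second chromosome")
      chrom <- sample(others, 1)
      at <- sample.int(chromN[[chrom]] + 1L, 1) - 1L
    } else {
      repeat {
        chrom <- sample(names(chromN), 1)
        at <- sample.int(chromN[[chrom]] + 1L, 1) - 1L
        if (chrom != parent$chromosome ||
            distAfter(at, parent$rank) > proximalWindow) break
      }
    }
    ae <- .addEvent(sim, kind, ageKs, paste0(parent$gene_id, ">", newId))
    sim <- ae$sim; id <- ae$id
    copy <- parent
    copy$gene_id <- newId; copy$chromosome <- chrom
    ## shift ranks at/after the insertion point
    g$rank[g$chromosome == chrom & g$rank >= at] <-
      g$rank[g$chromosome == chrom & g$rank >= at] + 1L
    copy$rank <- at
    ptruth <- sim@truth[sim@truth$gene_id == parent$gene_id, ]
    ctruth <- ptruth
    ctruth$gene_id <- newId
    ctruth$mode <- kind
    ctruth$copy_path <- ifelse(nzchar(ptruth$copy_path),
                               paste0(ptruth$copy_path, ";", id, "=D"),
                               paste0(id, "=D"))
    sim@genome <- .rebuildGenome(genomeId(sim@genome), rbind(g, copy))
    sim@truth <- rbind(sim@truth, ctruth)
    rownames(sim@truth) <- NULL
  }
  validObject(sim)
  sim
}

## ---- homolog pair synthesis from ground truth ----

.parsePath <- function(path) {
  if (!nzchar(path)) return(character())
  parts <- strsplit(path, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  stats::setNames(vapply(kv, `[`, character(1), 2),
                  vapply(kv, `[`, character(1), 1))
}

## event at which two copy paths diverge: the oldest (lowest-numbered)
## event where the ordered label sequences first disagree
.divergenceEvent <- function(pa, pb) {
  na_ <- names(pa); nb_ <- names(pb)
  m <- max(length(pa), length(pb))
  for (i in seq_len(m)) {
    ea <- if (i <= length(pa)) na_[i] else NA
    eb <- if (i <= length(pb)) nb_[i] else NA
    if (is.na(ea) && is.na(eb)) next
    if (is.na(ea)) return(eb)
    if (is.na(eb)) return(ea)
    if (ea != eb) return(if (ea < eb) ea else eb)
    if (pa[[i]] != pb[[i]]) return(ea)
  }
  NA_character_
}

.truncNorm <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x <= 0)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- which(x <= 0)
  }
  x
}

#' Synthesize homolog pair tables from simulation ground truth
#'
#' All gene pairs sharing an ancestral family are emitted; each pair's Ks is
#' drawn from Normal(age, relSigma * age) truncated at zero, where age is
#' the age of the event at which the two copies diverged. Similarity scores
#' are synthesized as 100 * (1 - ks / ksMax) so that recent pairs score
#' highest and the c-score filter can be exercised without alignment.
#'
#' @param simA,simB simulations sharing a history (same object for a
#'   self-comparison, in which case unordered non-identical pairs are
#'   emitted).
#' @param relSigma relative Ks spread per event (default 0.1).
#' @param seed integer seed.
#' @param ksMax score normalisation ceiling; default just above the largest
#'   drawn Ks.
#' @return data.frame: gene_a, gene_b, score, ks, event_id, age.
#' @export
makeHomologPairs <- function(simA, simB = simA, relSigma = 0.1, seed = 1L,
                             ksMax = NULL) {
  set.seed(seed)
  self <- identical(simA, simB)
  ta <- simA@truth; tb <- simB@truth
  evs <- unique(rbind(simA@events, simB@events))
  ages <- stats::setNames(evs$age_ks, evs$event_id)
  pa <- lapply(ta$copy_path, .parsePath)
  pb <- if (self) pa else lapply(tb$copy_path, .parsePath)
  ia <- split(seq_len(nrow(ta)), ta$ancestral_gene)
  ib <- if (self) ia else split(seq_len(nrow(tb)), tb$ancestral_gene)
  fams <- intersect(names(ia), names(ib))
  out <- vector("list", length(fams))
  for (fi in seq_along(fams)) {
    f <- fams[[fi]]
    A <- ia[[f]]; B <- ib[[f]]
    if (self) {
      if (length(A) < 2) next
      cmb <- utils::combn(A, 2)
      aa <- cmb[1, ]; bb <- cmb[2, ]
    } else {
      grid <- expand.grid(a = A, b = B)
      aa <- grid$a; bb <- grid$b
    }
    ev <- vapply(seq_along(aa), function(j)
      .divergenceEvent(pa[[aa[j]]], pb[[bb[j]]]), character(1))
    out[[fi]] <- data.frame(gene_a = ta$gene_id[aa], gene_b = tb$gene_id[bb],
                            event_id = ev, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  if (is.null(out) || !nrow(out))
    return(data.frame(gene_a = character(), gene_b = character(),
                      score = numeric(), ks = numeric(),
                      event_id = character(), age = numeric()))
  ## identical copy paths arise when one side is an ancestral snapshot of
  ## the other: the pair is the same lineage sampled at two times, age ~ 0
  ident <- is.na(out$event_id)
  out$event_id[ident] <- "IDENT"
  out$age <- unname(ages[out$event_id])
  out$age[ident] <- 0
  if (anyNA(out$age))
    stop("pair with unknown divergence event; simulations do not share ",
         "a common history")
  out$ks <- .truncNorm(nrow(out), out$age, pmax(relSigma * out$age, 1e-6))
  if (is.null(ksMax)) ksMax <- max(out$ks) * 1.001
  out$score <- pmax(0, 100 * (1 - out$ks / ksMax))
  rownames(out) <- NULL
  out[, c("gene_a", "gene_b", "score", "ks", "event_id", "age")]
}
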