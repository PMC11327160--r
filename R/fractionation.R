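#' @include AllClasses.R AllGenerics.R synteny.R karyotype.R
NULL

#' Assign genes to subgenomes after a shared WGD
#'
#' Each extant gene is assigned to the doubled-ancestor copy whose blocks
#' cover it with the most (score-weighted) anchor support; equal support
#' leaves the gene unassigned. The least-fractionated (LF) and
#' most-fractionated (MF) subgenomes are decided by total assigned gene
#' counts; a binomial test reports whether the asymmetry is significant.
#'
#' @param blockSet blocks with the extant genome as A and a doubled
#'   ancestor proxy as B.
#' @param extant the extant \linkS4class{GenomeTable}.
#' @param ancestorMap \linkS4class{KaryotypeMap} of the doubled ancestor.
#' @param copyMap named character vector proto -> subgenome label
#'   (e.g. c(chr01A = "A", chr01B = "B", ...)).
#' @return list: \code{assignment} (gene_id, subgenome), \code{counts},
#'   \code{lf}, \code{mf}, \code{p_value} (binomial, two-sided),
#'   \code{tie} logical.
#' @export
assignSubgenomes <- function(blockSet, extant, ancestorMap, copyMap) {
  an <- anchors(blockSet)
  an$proto <- .protoAt(ancestorMap, an$chrom_b, an$rank_b)
  an <- an[!is.na(an$proto), , drop = FALSE]
  an$copy <- copyMap[an$proto]
  if (anyNA(an$copy)) stop("copyMap does not cover every proto")
  labs <- sort(unique(unname(copyMap)))
  if (length(labs) != 2) stop("expected exactly two subgenome labels")
  g <- genes(extant)
  w <- matrix(0, nrow = nrow(g), ncol = 2, dimnames = list(NULL, labs))
  idx <- match(paste(an$chrom_a, an$rank_a),
               paste(g$chromosome, g$rank))
  for (j in seq_len(nrow(an)))
    w[idx[j], an$copy[j]] <- w[idx[j], an$copy[j]] + an$score[j]
  sub <- rep("unassigned", nrow(g))
  hasA <- w[, 1] > w[, 2]; hasB <- w[, 2] > w[, 1]
  sub[hasA] <- labs[1]; sub[hasB] <- labs[2]
  counts <- c(sum(sub == labs[1]), sum(sub == labs[2]))
  names(counts) <- labs
  tie <- counts[1] == counts[2]
  lf <- if (counts[2] > counts[1]) labs[2] else labs[1]
  if (tie)
    warning("equal subgenome gene counts; labelling copy '", labs[1],
            "' as LF")
  pv <- stats::binom.test(counts[1], sum(counts))$p.value
  list(assignment = data.frame(gene_id = g$gene_id, subgenome = sub,
                               stringsAsFactors = FALSE),
       counts = counts, lf = lf, mf = setdiff(labs, lf),
       p_value = pv, tie = unname(tie))
}

#' Build the core set of orthogroups (CSO)
#'
#' Admits orthogroups present (count >= 1) in at least \code{minUnits}
#' subgenome units and in every required unit (the outgroups). Each cell is
#' categorised Absent / Single / Two / Multiple by its copy number, and
#' every CSO is clustered 1/2/3 by the first required unit's copy number
#' (1, 2, >= 3).
#'
#' @param counts integer matrix orthogroups x units.
#' @param unitClass named character ("A"/"B"/"outgroup") per column.
#' @param requiredUnits unit names that must all contain the orthogroup;
#'   default all outgroup-class columns.
#' @param minUnits minimum subgenome units with a copy (default 8).
#' @param unitSpecies named character per column giving the species each
#'   subgenome unit belongs to; default the unit name stripped of a
#'   trailing _A/_B.
#' @return a \linkS4class{CSOMatrix}.
#' @export
buildCSO <- function(counts, unitClass, requiredUnits = NULL, minUnits = 8L,
                     unitSpecies = NULL) {
  if (is.null(colnames(counts))) stop("counts needs unit column names")
  unitClass <- unitClass[colnames(counts)]
  if (anyNA(unitClass)) stop("unitClass must cover every unit")
  if (is.null(requiredUnits))
    requiredUnits <- colnames(counts)[unitClass == "outgroup"]
  miss <- setdiff(requiredUnits, colnames(counts))
  if (length(miss))
    stop("required unit column(s) missing: ", paste(miss, collapse = ", "))
  if (is.null(unitSpecies))
    unitSpecies <- stats::setNames(sub("_[AB]$", "", colnames(counts)),
                                   colnames(counts))
  subCols <- colnames(counts)[unitClass != "outgroup"]
  storage.mode(counts) <- "integer"
  keep <- rowSums(counts[, subCols, drop = FALSE] >= 1L) >= minUnits &
          apply(counts[, requiredUnits, drop = FALSE] >= 1L, 1, all)
  cs <- counts[keep, , drop = FALSE]
  ref <- cs[, requiredUnits[1]]
  cluster <- ifelse(ref <= 1L, 1L, ifelse(ref == 2L, 2L, 3L))
  new("CSOMatrix", counts = cs, categories = .ksCategory(cs),
      unitClass = unitClass, unitSpecies = unitSpecies[colnames(counts)],
      cluster = as.integer(cluster))
}

#' Copy-number category of a count
#'
#' Absent (0), Single (1), Two (2), Multiple (> 2) — a pure function of
#' the count.
#'
#' @param x integer vector or matrix.
#' @export
copyCategory <- function(x) {
  storage.mode(x) <- "integer"
  .ksCategory(x)
}

#' Retained/lost CSO partition across the two subgenome classes
#'
#' A CSO is retained in a class when present (count >= 1) in strictly more
#' than \code{presenceThreshold} of that class's units. The partition
#' (both / A-only / B-only / neither) and the complementary count
#' (A-only + B-only) are reported.
#'
#' @param cso a \linkS4class{CSOMatrix}.
#' @param presenceThreshold fraction of units (default 0.5, strict).
#' @return list: \code{partition} (per-CSO factor), \code{sizes},
#'   \code{complementary}, \code{total}.
#' @export
retentionSets <- function(cso, presenceThreshold = 0.5) {
  aCols <- names(cso@unitClass)[cso@unitClass == "A"]
  bCols <- names(cso@unitClass)[cso@unitClass == "B"]
  if (!length(aCols) || !length(bCols))
    stop("need at least one unit in each subgenome class")
  inA <- rowMeans(cso@counts[, aCols, drop = FALSE] >= 1L) >
         presenceThreshold
  inB <- rowMeans(cso@counts[, bCols, drop = FALSE] >= 1L) >
         presenceThreshold
  part <- ifelse(inA & inB, "both",
          ifelse(inA, "A-only", ifelse(inB, "B-only", "neither")))
  part <- factor(part, levels = c("both", "A-only", "B-only", "neither"))
  sizes <- table(part)
  list(partition = part, sizes = sizes,
       complementary = unname(sizes["A-only"] + sizes["B-only"]),
       total = nrow(cso@counts))
}

#' Fractionation statistics across species pairs
#'
#' For every cluster and copy-number category, counts per unit are paired
#' by species (each species contributing one A and one B subgenome) and
#' compared with a two-sided Wilcoxon signed-rank test. Fewer than 5 pairs
#' skips the test with a notice. The complementary fraction from
#' \code{\link{retentionSets}} is included.
#'
#' @param cso a \linkS4class{CSOMatrix}.
#' @param presenceThreshold passed to \code{\link{retentionSets}}.
#' @return list: \code{tests} data.frame (cluster, category, mean_A,
#'   mean_B, p_value), \code{pairs} (species used), \code{venn} the
#'   retention partition.
#' @export
fractionationStats <- function(cso, presenceThreshold = 0.5) {
  aCols <- names(cso@unitClass)[cso@unitClass == "A"]
  bCols <- names(cso@unitClass)[cso@unitClass == "B"]
  spA <- cso@unitSpecies[aCols]; spB <- cso@unitSpecies[bCols]
  species <- intersect(spA, spB)
  aBySp <- stats::setNames(aCols[match(species, spA)], species)
  bBySp <- stats::setNames(bCols[match(species, spB)], species)
  cats <- c("Absent", "Single", "Two", "Multiple")
  rows <- list()
  for (cl in sort(unique(cso@cluster))) {
    sel <- cso@cluster == cl
    for (cat in cats) {
      ca <- vapply(species, function(s)
        sum(cso@categories[sel, aBySp[[s]]] == cat), numeric(1))
      cb <- vapply(species, function(s)
        sum(cso@categories[sel, bBySp[[s]]] == cat), numeric(1))
      pv <- if (length(species) < 5) NA_real_ else
        suppressWarnings(
          stats::wilcox.test(ca, cb, paired = TRUE, exact = FALSE)$p.value)
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, category = cat, mean_A = mean(ca), mean_B = mean(cb),
        p_value = pv, stringsAsFactors = FALSE)
    }
  }
  tests <- do.call(rbind, rows)
  if (length(species) < 5)
    message("fewer than 5 species pairs; Wilcoxon tests skipped")
  venn <- retentionSets(cso, presenceThreshold)
  list(tests = tests, pairs = species, venn = venn)
}

#' Classify gene duplication modes
#'
#' DupGen-style precedence WGD > TD > PD > TRD > DSD: a gene in any
#' intra-genome collinear block anchor pair is WGD-derived; otherwise a
#' rank-adjacent homolog makes it tandem (TD), a homolog within
#' \code{proximalWindow} ranks proximal (PD); otherwise a gene that is not
#' outgroup-syntenic but has an outgroup-syntenic homolog is a transposed
#' duplicate (TRD, the partner marking the ancestral locus); remaining
#' homologous genes are dispersed (DSD); genes without any within-genome
#' homolog are UD (unduplicated).
#'
#' @param genome the \linkS4class{GenomeTable}.
#' @param homologs within-genome homolog pairs (gene_a, gene_b, score).
#' @param intraBlocks self-comparison \linkS4class{SyntenyBlockSet}.
#' @param outgroupBlocks genome-vs-outgroup blocks marking ancestral loci;
#'   required (TRD cannot be called without an outgroup).
#' @param proximalWindow PD window in ranks (default 10).
#' @return data.frame: gene_id, mode, partner, evidence.
#' @export
classifyDuplicates <- function(genome, homologs, intraBlocks,
                               outgroupBlocks, proximalWindow = 10L) {
  if (missing(outgroupBlocks) || is.null(outgroupBlocks))
    stop("outgroup blocks are required to classify transposed duplicates")
  g <- genes(genome)
  h <- homologs[homologs$gene_a != homologs$gene_b, , drop = FALSE]
  ban <- anchors(intraBlocks)
  wgdGenes <- unique(c(ban$gene_a, ban$gene_b))
  outSyn <- unique(anchors(outgroupBlocks)$gene_a)
  chrom <- stats::setNames(g$chromosome, g$gene_id)
  rnk <- stats::setNames(g$rank, g$gene_id)
  ## partner lists per gene, both directions
  pl <- rbind(data.frame(g1 = h$gene_a, g2 = h$gene_b, score = h$score,
                         stringsAsFactors = FALSE),
              data.frame(g1 = h$gene_b, g2 = h$gene_a, score = h$score,
                         stringsAsFactors = FALSE))
  partners <- split(pl[, c("g2", "score")], pl$g1)
  out <- data.frame(gene_id = g$gene_id, mode = "UD",
                    partner = NA_character_, evidence = "",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    gid <- out$gene_id[i]
    ps <- partners[[gid]]
    if (is.null(ps) || !nrow(ps)) next
    if (gid %in% wgdGenes) {
      hit <- ban[ban$gene_a == gid | ban$gene_b == gid, ][1, ]
      out$mode[i] <- "WGD"
      out$partner[i] <- if (hit$gene_a == gid) hit$gene_b else hit$gene_a
      out$evidence[i] <- paste0("collinear block ", hit$block_id)
      next
    }
    sameCh <- chrom[ps$g2] == chrom[gid]
    dist <- abs(rnk[ps$g2] - rnk[gid])
    if (any(sameCh & dist == 1, na.rm = TRUE)) {
      j <- which(sameCh & dist == 1)[1]
      out$mode[i] <- "TD"; out$partner[i] <- ps$g2[j]
      out$evidence[i] <- "rank-adjacent homolog"
      next
    }
    if (any(sameCh & dist > 1 & dist <= proximalWindow, na.rm = TRUE)) {
      j <- which(sameCh & dist > 1 & dist <= proximalWindow)[1]
      out$mode[i] <- "PD"; out$partner[i] <- ps$g2[j]
      out$evidence[i] <- paste0("homolog within ", proximalWindow, " ranks")
      next
    }
    partnerSyn <- ps$g2 %in% outSyn
    if (!(gid %in% outSyn) && any(partnerSyn)) {
      j <- which(partnerSyn)[1]
      out$mode[i] <- "TRD"; out$partner[i] <- ps$g2[j]
      out$evidence[i] <- "ancestral-locus partner, novel locus"
      next
    }
    j <- which.max(ps$score)
    out$mode[i] <- "DSD"; out$partner[i] <- ps$g2[j]
    out$evidence[i] <- "dispersed homolog"
  }
  out
}

#' Tally duplication modes per gene family (and subgenome)
#'
#' @param modes data.frame from \code{\link{classifyDuplicates}}.
#' @param families data.frame (gene_id, family_id).
#' @param subgenomes optional data.frame (gene_id, subgenome).
#' @return contingency data.frame of counts; totals equal gene counts.
#' @export
modeTallyByFamily <- function(modes, families, subgenomes = NULL) {
  m <- merge(modes, families, by = "gene_id", all.x = TRUE)
  if (!is.null(subgenomes)) {
    m <- merge(m, subgenomes, by = "gene_id", all.x = TRUE)
    tab <- as.data.frame(table(family = m$family_id, mode = m$mode,
                               subgenome = m$subgenome))
  } else {
    tab <- as.data.frame(table(family = m$family_id, mode = m$mode))
  }
  names(tab)[names(tab) == "Freq"] <- "count"
  tab
}
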