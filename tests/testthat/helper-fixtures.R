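# shared fixture builders; everything is generated in code at test time

tinyGenome <- function(id = "G", chroms = 2, genesPer = 5) {
  n <- chroms * genesPer
  GenomeTable(id, data.frame(
    gene_id = sprintf("%s_g%03d", id, seq_len(n)),
    chromosome = rep(sprintf("c%d", seq_len(chroms)), each = genesPer),
    start = rep(seq_len(genesPer) * 100L - 100L, chroms),
    end = rep(seq_len(genesPer) * 100L - 10L, chroms),
    strand = "+", stringsAsFactors = FALSE))
}

# post-WGD extant genome (optionally fractionated / fused) plus the
# unfractionated post-WGD proxy and its identity karyotype map
wgdFixture <- function(seed, nChrom = 11, genesPer = 120,
                       retention = NULL, wgdAge = 0.6) {
  sim <- simulateAncestor(nChrom, genesPer, seed = seed, genomeId = "anc")
  sim <- applyPolyploidy(sim, 2L, wgdAge)
  proxy <- sim
  proxy@genome@genomeId <- "proxy"
  ext <- sim
  if (!is.null(retention))
    ext <- fractionate(ext, retention, seed = seed + 1000L)
  ext@genome@genomeId <- "ext"
  list(ext = ext, proxy = proxy,
       map = protoIdentityMap(simGenome(proxy), "proxy"))
}

paintFixture <- function(ext, proxy, map, seed, cscore = 0.9,
                         telomereWindow = 5L) {
  h <- makeHomologPairs(ext, proxy, seed = seed)
  bs <- chainBlocks(buildAnchors(simGenome(ext), simGenome(proxy), h,
                                 cscore),
                    5L, 25L, genomeId(simGenome(ext)),
                    genomeId(simGenome(proxy)))
  pt <- paintChromosomes(bs, simGenome(ext), map)
  classifyEvents(pt, map, telomereWindow = telomereWindow)
}

# independent brute-force oracle for the c-score filter
cscoreOracle <- function(h, thr, self = FALSE) {
  if (self) h <- h[h$gene_a != h$gene_b, ]
  keep <- logical(nrow(h))
  for (i in seq_len(nrow(h))) {
    if (self) {
      bestA <- max(h$score[h$gene_a == h$gene_a[i] |
                           h$gene_b == h$gene_a[i]])
      bestB <- max(h$score[h$gene_a == h$gene_b[i] |
                           h$gene_b == h$gene_b[i]])
    } else {
      bestA <- max(h$score[h$gene_a == h$gene_a[i]])
      bestB <- max(h$score[h$gene_b == h$gene_b[i]])
    }
    keep[i] <- h$score[i] >= thr * max(bestA, bestB) - 1e-12
  }
  h[keep, ]
}

# independent oracle: repeatedly extract the longest strictly-monotone
# double-gap-bounded chain (naive O(n^2) DP written separately from the
# package implementation); returns the multiset of chain sizes
chainOracleSizes <- function(ra, rb, minSize, maxGap) {
  longest <- function(ra, rb, sgn) {
    n <- length(ra)
    if (!n) return(integer())
    o <- order(ra, sgn * rb)
    ra <- ra[o]; rb2 <- sgn * rb[o]
    L <- rep(1L, n); P <- rep(0L, n)
    for (i in seq_len(n)) for (j in seq_len(i - 1)) {
      if (ra[j] < ra[i] && ra[i] - ra[j] <= maxGap &&
          rb2[j] < rb2[i] && rb2[i] - rb2[j] <= maxGap && L[j] + 1 > L[i]) {
        L[i] <- L[j] + 1L; P[i] <- j
      }
    }
    i <- which.max(L); chain <- integer(0)
    while (i > 0) { chain <- c(i, chain); i <- P[i] }
    o[chain]
  }
  sizes <- integer()
  repeat {
    cp <- longest(ra, rb, 1); ca <- longest(ra, rb, -1)
    ch <- if (length(cp) >= length(ca)) cp else ca
    if (length(ch) < minSize) break
    sizes <- c(sizes, length(ch))
    keep <- setdiff(seq_along(ra), ch)
    ra <- ra[keep]; rb <- rb[keep]
  }
  sort(sizes, decreasing = TRUE)
}

# exhaustive oracle for ploidy decomposition
factorOracle <- function(target, nPeaks) {
  if (nPeaks == 0) return(if (target == 1) list(numeric()) else list())
  out <- list()
  rec <- function(prefix, remaining) {
    if (length(prefix) == nPeaks) {
      if (remaining == 1) out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (f in c(2, 3)) if (remaining %% f == 0)
      rec(c(prefix, f), remaining / f)
  }
  rec(numeric(), target)
  out
}
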