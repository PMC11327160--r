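test_that("c-score filtering keeps only near-best reciprocal hits", {
  ga <- tinyGenome("A", 1, 3)
  gb <- tinyGenome("B", 1, 3)
  h <- data.frame(gene_a = c("A_g001", "A_g001"),
                  gene_b = c("B_g001", "B_g002"),
                  score = c(100, 90), stringsAsFactors = FALSE)
  kept <- buildAnchors(ga, gb, h, cscoreThreshold = 0.99)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$gene_b, "B_g001")
  ## threshold 0 keeps everything
  expect_equal(nrow(buildAnchors(ga, gb, h, cscoreThreshold = 0)), 2)
  expect_error(buildAnchors(ga, gb,
                            data.frame(gene_a = "zz", gene_b = "B_g001",
                                       score = 1), 0.5), "unknown")
})

test_that("c-score filter matches a brute-force oracle on random tables", {
  set.seed(77)
  ga <- tinyGenome("A", 2, 10)
  gb <- tinyGenome("B", 2, 10)
  for (rep in 1:5) {
    h <- data.frame(
      gene_a = sample(genes(ga)$gene_id, 50, replace = TRUE),
      gene_b = sample(genes(gb)$gene_id, 50, replace = TRUE),
      score = round(runif(50, 10, 100), 1), stringsAsFactors = FALSE)
    h <- unique(h)
    for (thr in c(0.5, 0.9, 0.99)) {
      mine <- buildAnchors(ga, gb, h, thr, collapseTandem = FALSE)
      oracle <- cscoreOracle(h, thr)
      expect_setequal(paste(mine$gene_a, mine$gene_b),
                      paste(oracle$gene_a, oracle$gene_b))
    }
  }
})

test_that("a perfect diagonal chains into a single parallel block", {
  a <- data.frame(gene_a = sprintf("a%03d", 1:100), chrom_a = "c1",
                  rank_a = 0:99, gene_b = sprintf("b%03d", 1:100),
                  chrom_b = "d1", rank_b = 0:99, score = 50, ks = NA_real_,
                  stringsAsFactors = FALSE)
  bs <- chainBlocks(a, minBlockSize = 5, maxGap = 25)
  expect_equal(nrow(blocks(bs)), 1)
  expect_equal(blocks(bs)$anchor_count, 100)
  expect_equal(blocks(bs)$orientation, "parallel")
  expect_true(validObject(bs))
})

test_that("a gap wider than maxGap splits the chain in two", {
  rb <- c(0:49, 80:129)   # 30-rank jump on the B axis after anchor 50
  a <- data.frame(gene_a = sprintf("a%03d", 1:100), chrom_a = "c1",
                  rank_a = c(0:49, 80:129), gene_b = sprintf("b%03d", 1:100),
                  chrom_b = "d1", rank_b = rb, score = 50, ks = NA_real_,
                  stringsAsFactors = FALSE)
  bs <- chainBlocks(a, minBlockSize = 5, maxGap = 25)
  expect_equal(sort(blocks(bs)$anchor_count), c(50, 50))
})

test_that("reversed runs come out antiparallel and inversions are seen", {
  a <- data.frame(gene_a = sprintf("a%02d", 1:20), chrom_a = "c1",
                  rank_a = 0:19, gene_b = sprintf("b%02d", 1:20),
                  chrom_b = "d1", rank_b = 19:0, score = 50, ks = NA_real_,
                  stringsAsFactors = FALSE)
  bs <- chainBlocks(a, 5, 25)
  expect_equal(blocks(bs)$orientation, "antiparallel")

  ## an evosim inversion shows up as an antiparallel block
  sim <- simulateAncestor(1, 80, seed = 12, genomeId = "anc")
  proxy <- sim; proxy@genome@genomeId <- "proxy"
  inv <- applyInversion(sim, "chr01", 20, 60)
  inv@genome@genomeId <- "inv"
  h <- makeHomologPairs(inv, proxy, seed = 13)
  bs2 <- chainBlocks(buildAnchors(simGenome(inv), simGenome(proxy), h, 0.5),
                     5, 10, "inv", "proxy")
  ori <- blocks(bs2)$orientation
  expect_true("antiparallel" %in% ori)
  anti <- blocks(bs2)[ori == "antiparallel", ]
  expect_equal(sum(anti$anchor_count), 40)
})

test_that("greedy chaining matches an independent oracle on random sets", {
  set.seed(99)
  for (rep in 1:6) {
    n <- sample(30:60, 1)
    a <- data.frame(gene_a = sprintf("a%03d", 1:n), chrom_a = "c1",
                    rank_a = sample(0:150, n), gene_b = sprintf("b%03d", 1:n),
                    chrom_b = "d1", rank_b = sample(0:150, n),
                    score = 50, ks = NA_real_, stringsAsFactors = FALSE)
    bs <- chainBlocks(a, minBlockSize = 3, maxGap = 20)
    oracle <- chainOracleSizes(a$rank_a, a$rank_b, 3, 20)
    expect_identical(sort(blocks(bs)$anchor_count, decreasing = TRUE),
                     as.integer(oracle))
    expect_true(validObject(bs))
  }
})

test_that("noiseless WGD output tiles each chromosome pair once per copy", {
  fx <- wgdFixture(seed = 20, nChrom = 4, genesPer = 60)
  h <- makeHomologPairs(fx$ext, seed = 21)
  bs <- chainBlocks(buildAnchors(simGenome(fx$ext), simGenome(fx$ext), h, 0),
                    5, 25, "ext", "ext")
  bl <- blocks(bs)
  ## one block per proto pairing copy A with copy B
  expect_equal(nrow(bl), 4)
  expect_true(all(sub("A$|B$", "", bl$chrom_a) ==
                  sub("A$|B$", "", bl$chrom_b)))
})

test_that("dot-plot export round-trips and is deterministic", {
  fx <- wgdFixture(seed = 22, nChrom = 3, genesPer = 40)
  h <- makeHomologPairs(fx$ext, fx$proxy, seed = 23)
  bs <- chainBlocks(buildAnchors(simGenome(fx$ext), simGenome(fx$proxy),
                                 h, 0.9), 5, 25, "ext", "proxy")
  f <- tempfile(fileext = ".tsv")
  dotplotExport(bs, f)
  back <- readBlockSet(f, "ext", "proxy")
  expect_equal(anchors(back)[, c("block_id", "gene_a", "gene_b")],
               anchors(bs)[, c("block_id", "gene_a", "gene_b")])
  expect_equal(blocks(back)$anchor_count, blocks(bs)$anchor_count)
  ## rerun on the same inputs gives identical ids
  bs2 <- chainBlocks(buildAnchors(simGenome(fx$ext), simGenome(fx$proxy),
                                  h, 0.9), 5, 25, "ext", "proxy")
  expect_identical(blocks(bs2), blocks(bs))
  ## empty block list writes a header-only table
  f2 <- tempfile(fileext = ".tsv")
  dotplotExport(chainBlocks(bs@anchors[0, -1], 5, 25), f2)
  expect_equal(nrow(utils::read.table(f2, header = TRUE, sep = "\t")), 0)
})
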