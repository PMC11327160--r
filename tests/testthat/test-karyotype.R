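test_that("an unrearranged genome paints one proto per chromosome", {
  fx <- wgdFixture(seed = 40, nChrom = 4, genesPer = 80)
  h <- makeHomologPairs(fx$ext, fx$proxy, seed = 41)
  bs <- chainBlocks(buildAnchors(simGenome(fx$ext), simGenome(fx$proxy),
                                 h, 0.9), 5, 25, "ext", "proxy")
  pt <- paintChromosomes(bs, simGenome(fx$ext), fx$map)
  segs <- karyoSegments(pt)
  expect_equal(nrow(segs), 8)                     # one segment per chromosome
  expect_identical(segs$proto, segs$chromosome)   # painted by itself
  ev <- classifyEvents(pt, fx$map)
  expect_equal(nrow(ev$events), 0)
  expect_true(ev$check$balanced)
})

test_that("EEJ and NCF leave their painting signatures", {
  fx <- wgdFixture(seed = 42, nChrom = 4, genesPer = 80)
  ext <- applyFusion(fx$ext, "EEJ", "chr01A", "chr02A", reverseDonor = FALSE)
  ext <- applyFusion(ext, "NCF", "chr03B", "chr04B", insertionRank = 40)
  h <- makeHomologPairs(ext, fx$proxy, seed = 43)
  bs <- chainBlocks(buildAnchors(simGenome(ext), simGenome(fx$proxy),
                                 h, 0.9), 5, 25, "ext", "proxy")
  pt <- paintChromosomes(bs, simGenome(ext), fx$map)
  segs <- karyoSegments(pt)
  eejSig <- segs$proto[segs$chromosome == "chr02A"]
  expect_identical(eejSig, c("chr02A", "chr01A"))
  ncfSig <- segs$proto[segs$chromosome == "chr04B"]
  expect_identical(ncfSig, c("chr04B", "chr03B", "chr04B"))
  ev <- classifyEvents(pt, fx$map)
  expect_equal(sort(ev$events$kind), c("EEJ", "NCF"))
  expect_true(ev$check$balanced)
  expect_equal(ev$check$predicted_n, 6)
})

test_that("an RTA is recognised from reciprocal partial arms", {
  fx <- wgdFixture(seed = 44, nChrom = 4, genesPer = 80)
  ext <- applyRta(fx$ext, "chr01A", "chr02B", 40, 35)
  ev <- paintFixture(ext, fx$proxy, fx$map, seed = 45)
  expect_equal(ev$events$kind, "RTA")
  expect_true(ev$check$balanced)
  expect_equal(ev$check$n_extant, 8)
})

test_that("fusion inventories reproduce printed chromosome numbers", {
  ## 2 EEJ + 4 NCF on the 22-chromosome doubled karyotype gives n = 16
  fx <- wgdFixture(seed = 46, nChrom = 11, genesPer = 100)
  ext <- fx$ext
  ext <- applyFusion(ext, "EEJ", "chr01A", "chr02A", reverseDonor = FALSE)
  ext <- applyFusion(ext, "EEJ", "chr03A", "chr04A", reverseDonor = FALSE)
  hosts <- c("chr06A", "chr08A", "chr10B", "chr01B")
  donors <- c("chr05A", "chr07A", "chr09B", "chr11B")
  for (i in 1:4)
    ext <- applyFusion(ext, "NCF", donors[i], hosts[i], insertionRank = 50)
  expect_equal(chromosomeCount(simGenome(ext)), 16)
  ev <- paintFixture(ext, fx$proxy, fx$map, seed = 47)
  expect_equal(ev$check$eej, 2)
  expect_equal(ev$check$ncf, 4)
  expect_equal(ev$check$predicted_n, 16)
  expect_true(ev$check$balanced)
})

test_that("ancestor reconstruction recovers the proto-chromosomes", {
  sim <- simulateAncestor(11, 120, seed = 50, genomeId = "cons")
  sim <- applyPolyploidy(sim, 2, 0.6)
  truthProto <- simTruth(sim)$proto
  names(truthProto) <- simTruth(sim)$gene_id
  sim <- fractionate(sim, c(A = 0.8, B = 0.6), seed = 51)
  g <- simGenome(sim)
  h <- makeHomologPairs(sim, seed = 52)
  bs <- annotateBlockKs(
    chainBlocks(buildAnchors(g, g, h, 0), 5, 25, "cons", "cons"))
  rec <- reconstructAncestor(g, bs, 2, wgdKs = 0.6)
  expect_length(protoChromosomes(rec$map), 11)
  expect_true(rec$ok)
  expect_true(all(rec$validation$copies == 2))
  acc <- local({
    m <- rec$assignment
    tab <- table(m$proto, truthProto[m$gene_id])
    sum(apply(tab, 1, max)) / nrow(m)
  })
  expect_gte(acc, 0.95)
  ## deterministic
  rec2 <- reconstructAncestor(g, bs, 2, wgdKs = 0.6)
  expect_identical(rec2$assignment, rec$assignment)
})

test_that("fusions do not create extra proto-chromosomes on reconstruction", {
  sim <- simulateAncestor(11, 120, seed = 53, genomeId = "cons")
  sim <- applyPolyploidy(sim, 2, 0.6)
  sim <- fractionate(sim, c(A = 0.8, B = 0.6), seed = 54)
  donors <- c("chr01A", "chr03A", "chr05B")
  hosts <- c("chr02A", "chr04A", "chr06B")
  sim <- applyFusion(sim, "EEJ", donors[1], hosts[1], reverseDonor = FALSE)
  sim <- applyFusion(sim, "EEJ", donors[2], hosts[2], reverseDonor = FALSE)
  hn <- sum(genes(simGenome(sim))$chromosome == hosts[3])
  sim <- applyFusion(sim, "NCF", donors[3], hosts[3],
                     insertionRank = hn %/% 2)
  g <- simGenome(sim)
  h <- makeHomologPairs(sim, seed = 55)
  bs <- annotateBlockKs(
    chainBlocks(buildAnchors(g, g, h, 0), 5, 25, "cons", "cons"))
  rec <- reconstructAncestor(g, bs, 2, wgdKs = 0.6)
  expect_length(protoChromosomes(rec$map), 11)
})

test_that("trajectories intersect shared fusions across lineages", {
  base <- wgdFixture(seed = 56, nChrom = 6, genesPer = 80)
  shared <- applyFusion(base$ext, "EEJ", "chr01A", "chr02A",
                        reverseDonor = FALSE)
  l1 <- applyFusion(shared, "EEJ", "chr03A", "chr04A", reverseDonor = FALSE)
  l1@genome@genomeId <- "L1"
  l2 <- applyFusion(shared, "NCF", "chr05B", "chr06B", insertionRank = 40)
  l2@genome@genomeId <- "L2"
  l3 <- shared; l3@genome@genomeId <- "L3"
  evs <- list(L1 = paintFixture(l1, base$proxy, base$map, 57),
              L2 = paintFixture(l2, base$proxy, base$map, 58),
              L3 = paintFixture(l3, base$proxy, base$map, 59))
  tr <- trajectoryReport(evs)
  expect_equal(nrow(tr$perLineage), 3)
  expect_equal(tr$shared$protos, "chr01A+chr02A")
  expect_equal(tr$shared$n_lineages, 3)
  ## lineage-specific events are not in the intersection
  expect_false("chr03A+chr04A" %in% tr$shared$protos)
  ## a single lineage has an empty intersection
  expect_equal(nrow(trajectoryReport(evs["L1"])$shared), 0)
})
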