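test_that("ancestor simulation meets its contract and is deterministic", {
  sim <- simulateAncestor(11, 200, seed = 1)
  expect_equal(chromosomeCount(simGenome(sim)), 11)
  expect_equal(geneCount(simGenome(sim)), 2200)
  expect_true(all(table(genes(simGenome(sim))$family_id) == 1))
  one <- simulateAncestor(1, 1, seed = 0)
  expect_equal(geneCount(simGenome(one)), 1)
  expect_identical(simulateAncestor(4, 30, seed = 9),
                   simulateAncestor(4, 30, seed = 9))
  expect_error(simulateAncestor(0, 10), ">= 1")
})

test_that("polyploidy multiplies chromosomes and genes with labelled copies", {
  s11 <- applyPolyploidy(simulateAncestor(11, 20, seed = 2), 2, 0.6)
  expect_equal(chromosomeCount(simGenome(s11)), 22)
  s7 <- applyPolyploidy(simulateAncestor(7, 20, seed = 2), 3, 1.8)
  expect_equal(chromosomeCount(simGenome(s7)), 21)
  expect_equal(geneCount(simGenome(s7)), 7 * 20 * 3)
  expect_error(applyPolyploidy(s7, 4, 1), "2 or 3")
})

test_that("paralog pair Ks centres on the event age", {
  sim <- applyPolyploidy(simulateAncestor(5, 200, seed = 3), 2, 0.8)
  h <- makeHomologPairs(sim, seed = 4)
  ks <- h$ks[h$event_id == "E001"]
  expect_gte(length(ks), 1000)
  se <- sd(ks) / sqrt(length(ks))
  expect_lt(abs(mean(ks) - 0.8), 2 * se + 1e-9)
})

test_that("EEJ concatenates and NCF nests the donor", {
  sim <- simulateAncestor(2, 6, seed = 5)
  a <- genes(simGenome(sim))
  idsA <- a$gene_id[a$chromosome == "chr01"]
  idsB <- a$gene_id[a$chromosome == "chr02"]
  eej <- applyFusion(sim, "EEJ", donor = "chr02", host = "chr01",
                     reverseDonor = FALSE)
  expect_equal(chromosomeCount(simGenome(eej)), 1)
  g <- genes(simGenome(eej))
  expect_identical(g$gene_id[order(g$rank)], c(idsA, idsB))

  ncf <- applyFusion(sim, "NCF", donor = "chr02", host = "chr01",
                     insertionRank = 3, reverseDonor = FALSE)
  g <- genes(simGenome(ncf))
  expect_identical(g$gene_id[order(g$rank)],
                   c(idsA[1:3], idsB, idsA[4:6]))
  expect_error(applyFusion(sim, "NCF", "chr02", "chr01",
                           insertionRank = 0), "EEJ")
  expect_error(applyFusion(sim, "NCF", "chr02", "chr01",
                           insertionRank = 6), "EEJ")
})

test_that("RTA conserves genes, keeps the count and is an involution", {
  sim <- simulateAncestor(3, 20, seed = 6)
  before <- genes(simGenome(sim))
  r1 <- applyRta(sim, "chr01", "chr02", 8, 12)
  expect_equal(chromosomeCount(simGenome(r1)), 3)
  expect_setequal(genes(simGenome(r1))$gene_id, before$gene_id)
  r2 <- applyRta(r1, "chr01", "chr02", 8, 12)
  after <- genes(simGenome(r2))
  expect_identical(after[order(after$gene_id), c("chromosome", "rank")],
                   before[order(before$gene_id), c("chromosome", "rank")])
  expect_error(applyRta(sim, "chr01", "chr02", 0, 5), "internal")
})

test_that("inversion reverses order, flips strand, and squares to identity", {
  sim <- simulateAncestor(1, 12, seed = 7)
  before <- genes(simGenome(sim))
  i1 <- applyInversion(sim, "chr01", 3, 9)
  g1 <- genes(simGenome(i1))
  expect_setequal(g1$gene_id, before$gene_id)
  i2 <- applyInversion(i1, "chr01", 3, 9)
  g2 <- genes(simGenome(i2))
  expect_identical(g2[order(g2$gene_id), c("rank", "strand")],
                   before[order(before$gene_id), c("rank", "strand")])
  ## single-gene inversion flips strand only
  s1 <- applyInversion(sim, "chr01", 4, 5)
  gs <- genes(simGenome(s1))
  expect_identical(gs$rank[order(gs$gene_id)],
                   before$rank[order(before$gene_id)])
  flip <- gs$strand[order(gs$gene_id)] != before$strand[order(before$gene_id)]
  expect_equal(sum(flip), 1)
  expect_error(applyInversion(sim, "chr01", 5, 5), "empty")
})

test_that("fractionation follows per-subgenome binomial retention", {
  sim <- applyPolyploidy(simulateAncestor(10, 200, seed = 8), 2, 0.6)
  ## identity retention changes nothing
  same <- fractionate(sim, c(A = 1, B = 1), seed = 1)
  expect_equal(geneCount(simGenome(same)), geneCount(simGenome(sim)))
  fr <- fractionate(sim, c(A = 0.8, B = 0.5), seed = 2)
  tr <- simTruth(fr)
  lab <- karyevol:::.eventLabel(tr$copy_path, "E001")
  nA <- sum(lab == "A"); nB <- sum(lab == "B")
  n <- 2000
  ## survival conditioning (families are redrawn until one copy remains)
  ## lifts each marginal retention to r / (1 - (1-rA)(1-rB))
  z <- 1 - 0.2 * 0.5
  pA <- 0.8 / z; pB <- 0.5 / z
  expect_lt(abs(nA - n * pA), 3 * sqrt(n * pA * (1 - pA)) + 3)
  expect_lt(abs(nB - n * pB), 3 * sqrt(n * pB * (1 - pB)) + 3)
  expect_gt(nA, nB)  # the LF/MF asymmetry
  ## every ancestral family keeps at least one copy
  expect_setequal(unique(tr$ancestral_gene),
                  unique(simTruth(sim)$ancestral_gene))
})

test_that("small-scale duplications land where their mode dictates", {
  sim <- simulateAncestor(3, 40, seed = 9)
  n0 <- geneCount(simGenome(sim))
  td <- applySmallScaleDuplication(sim, "TD", n = 5, seed = 1)
  expect_equal(geneCount(simGenome(td)), n0 + 5)
  tr <- simTruth(td)
  g <- genes(simGenome(td))
  for (cid in tr$gene_id[!is.na(tr$mode)]) {
    pid <- sub("_td[0-9]+$", "", cid)
    gc_ <- g[g$gene_id == cid, ]; gp <- g[g$gene_id == pid, ]
    expect_equal(gc_$chromosome, gp$chromosome)
    expect_equal(abs(gc_$rank - gp$rank), 1)
  }
  trd <- applySmallScaleDuplication(sim, "TRD", n = 5, seed = 2)
  tr <- simTruth(trd); g <- genes(simGenome(trd))
  for (cid in tr$gene_id[!is.na(tr$mode)]) {
    pid <- sub("_trd[0-9]+$", "", cid)
    expect_false(g$chromosome[g$gene_id == cid] ==
                 g$chromosome[g$gene_id == pid])
  }
})

test_that("chromosome bookkeeping holds across random scenarios", {
  for (s in 1:5) {
    set.seed(s)
    nE <- sample(0:2, 1); nN <- sample(0:2, 1)
    sc <- list(ancestor = list(chromosomes = 8, genes = 60),
               shared_events = c(
                 list(list(kind = "WGD", age = 0.6,
                           retention = list(A = 0.9, B = 0.7))),
                 rep(list(list(kind = "EEJ")), nE),
                 rep(list(list(kind = "NCF")), nN),
                 list(list(kind = "RTA"), list(kind = "INV"))),
               lineages = list(L = list(events = list())))
    r <- runScenario(sc, seed = s)
    expect_equal(chromosomeCount(simGenome(r$sims$L)),
                 8 * 2 - nE - nN)
    expect_equal(expectedChromosomeCount(r$sims$L, 8),
                 chromosomeCount(simGenome(r$sims$L)))
  }
})

test_that("older events yield stochastically larger Ks than younger ones", {
  sim <- simulateAncestor(5, 250, seed = 10)
  sim <- applyPolyploidy(sim, 2, 1.0)
  sim <- applyPolyploidy(sim, 2, 0.4)
  h <- makeHomologPairs(sim, seed = 11)
  old <- h$ks[h$event_id == "E001"][1:500]
  young <- h$ks[h$event_id == "E002"][1:500]
  expect_lt(wilcox.test(old, young, alternative = "greater")$p.value, 0.01)
})

test_that("scenarios are reproducible from their seed", {
  sc <- list(ancestor = list(chromosomes = 5, genes = 40),
             split_age = 1.0,
             lineages = list(
               Q = list(events = list(list(kind = "WGD", age = 0.5,
                                           retention = list(A = .8, B = .6)),
                                      list(kind = "EEJ"))),
               R = list(events = list())))
  r1 <- runScenario(sc, seed = 42)
  r2 <- runScenario(sc, seed = 42)
  expect_identical(r1$sims, r2$sims)
  expect_identical(r1$homologs, r2$homologs)
  r3 <- runScenario(sc, seed = 43)
  expect_false(identical(genes(simGenome(r1$sims$Q)),
                         genes(simGenome(r3$sims$Q))))
})

test_that("inconsistent scenarios fail naming the offending event", {
  sc <- list(ancestor = list(chromosomes = 3, genes = 30),
             lineages = list(L = list(events = list(
               list(kind = "EEJ", donor = "chrXX", host = "chr01")))))
  expect_error(runScenario(sc, seed = 1), "event 1.*EEJ")
})
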