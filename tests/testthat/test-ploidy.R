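test_that("depth counts blocks covering each gene, in both directions", {
  q <- tinyGenome("Q", 1, 20)
  r <- tinyGenome("R", 1, 20)
  a <- data.frame(gene_a = genes(q)$gene_id[1:10], chrom_a = "c1",
                  rank_a = 0:9, gene_b = genes(r)$gene_id[1:10],
                  chrom_b = "c1", rank_b = 0:9, score = 50, ks = NA_real_,
                  stringsAsFactors = FALSE)
  bs <- chainBlocks(a, 5, 25, "Q", "R")
  prof <- syntenicDepth(bs, q, r)
  expect_equal(sum(prof@refDepth$depth), 10)
  expect_equal(prof@modalRef, 1L)
  expect_equal(prof@coveredRef, 0.5)
  ## empty block set: all depths zero, nothing covered
  empty <- chainBlocks(a[0, ], 5, 25, "Q", "R")
  p0 <- syntenicDepth(empty, q, r)
  expect_equal(sum(p0@refDepth$depth), 0)
  expect_equal(p0@coveredRef, 0)
  expect_error(depthRatio(p0), "covered fraction")
  expect_error(syntenicDepth(bs, r, q), "built for")
})

test_that("a lineage-specific WGD at full retention reads exactly 2:1", {
  sc <- list(ancestor = list(chromosomes = 5, genes = 100),
             split_age = 1.0,
             lineages = list(
               Q = list(events = list(list(kind = "WGD", age = 0.5))),
               R = list(events = list())))
  r <- runScenario(sc, seed = 31)
  ## no score filtering: at full retention every anchor is real, so the
  ## by-construction depth claim holds for every reference gene
  bs <- chainBlocks(buildAnchors(simGenome(r$sims$Q), simGenome(r$sims$R),
                                 r$homologs[["Q|R"]], 0), 5, 25, "Q", "R")
  prof <- syntenicDepth(bs, simGenome(r$sims$Q), simGenome(r$sims$R))
  ## by construction every reference gene lies in two query blocks
  expect_equal(mean(prof@refDepth$depth == 2), 1)
  expect_equal(unname(depthRatio(prof)), c(2L, 1L))
})

test_that("ploidy decomposition enumerates ordered {2,3} factorizations", {
  call <- decomposePloidy(c(8, 1), 3, peakAges = c(0.21, 0.87, 1.12))
  expect_false(call@ambiguous)
  expect_equal(call@multiplicities, c(2, 2, 2))
  expect_equal(call@peakAges, c(1.12, 0.87, 0.21))  # oldest first

  none <- decomposePloidy(c(1, 1), 0)
  expect_false(none@ambiguous)
  expect_length(none@multiplicities, 0)

  amb <- decomposePloidy(c(6, 1), 2)
  expect_true(amb@ambiguous)
  expect_setequal(vapply(amb@factorizations, paste, character(1),
                         collapse = "x"), c("3x2", "2x3"))

  expect_error(decomposePloidy(c(5, 1), 2), "no sequence")
  expect_error(decomposePloidy(c(3, 2), 1), "not divisible")
})

test_that("decomposition equals the exhaustive oracle up to ratio 12", {
  for (target in 1:12) for (k in 0:3) {
    oracle <- factorOracle(target, k)
    got <- tryCatch(decomposePloidy(c(target, 1), k)@factorizations,
                    error = function(e) list())
    expect_setequal(vapply(got, paste, character(1), collapse = "x"),
                    vapply(oracle, paste, character(1), collapse = "x"))
  }
})

test_that("shared and independent events separate by age matching", {
  mk <- function(ratio, mult, ages)
    new("PloidyCall", ratio = as.integer(ratio),
        factorizations = list(mult), multiplicities = mult,
        ambiguous = FALSE, peakAges = ages)
  ## same WGD before the split: ages agree, cross ratio 2:2
  sh <- sharedEventTest(c(2, 2), mk(c(2, 1), 2, 0.77), mk(c(2, 1), 2, 0.80))
  expect_true(all(sh$events$call == "shared"))
  expect_true(sh$consistent)
  ## independent WGDs after the split: ages differ beyond tolerance
  ind <- sharedEventTest(c(2, 2), mk(c(2, 1), 2, 0.27), mk(c(2, 1), 2, 0.77))
  expect_true(all(ind$events$call == "independent"))
  expect_true(ind$consistent)
  ## one lineage with an extra WGD stacked on a shared triploidization
  mix <- sharedEventTest(c(6, 3),
                         mk(c(6, 1), c(3, 2), c(0.77, 0.27)),
                         mk(c(3, 1), 3, 0.77))
  ev <- mix$events
  expect_equal(ev$call[ev$lineage == "A" & ev$multiplicity == 3], "shared")
  expect_equal(ev$call[ev$lineage == "A" & ev$multiplicity == 2],
               "independent")
  expect_true(mix$consistent)
  ## a ratio contradicting the classification is reported, not called
  bad <- sharedEventTest(c(4, 2), mk(c(2, 1), 2, 0.3), mk(c(2, 1), 2, 0.8))
  expect_false(bad$consistent)
})

test_that("simulated shared vs independent WGDs are told apart end-to-end", {
  ## two lineages that duplicated before splitting
  scSh <- list(ancestor = list(chromosomes = 5, genes = 80),
               shared_events = list(list(kind = "WGD", age = 0.9,
                                         retention = list(A = .8, B = .7))),
               split_age = 0.5,
               lineages = list(Q = list(events = list()),
                               R = list(events = list())))
  r <- runScenario(scSh, seed = 33)
  bs <- chainBlocks(buildAnchors(simGenome(r$sims$Q), simGenome(r$sims$R),
                                 r$homologs[["Q|R"]], 0.5), 5, 25, "Q", "R")
  rat <- depthRatio(syntenicDepth(bs, simGenome(r$sims$Q),
                                  simGenome(r$sims$R)))
  expect_equal(unname(rat), c(2L, 2L))
  ## paralog ages on both sides sit at the same (shared) peak
  ksQ <- r$homologs[["Q|Q"]]$ks[r$homologs[["Q|Q"]]$event_id == "E001"]
  ksR <- r$homologs[["R|R"]]$ks[r$homologs[["R|R"]]$event_id == "E001"]
  expect_lt(abs(median(ksQ) - median(ksR)), 0.15)
  call <- function(age) new("PloidyCall", ratio = c(2L, 1L),
                            factorizations = list(2), multiplicities = 2,
                            ambiguous = FALSE, peakAges = age)
  verdict <- sharedEventTest(rat, call(median(ksQ)), call(median(ksR)))
  expect_true(all(verdict$events$call == "shared"))
})
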