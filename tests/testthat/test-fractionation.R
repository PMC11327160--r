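test_that("subgenome assignment recovers truth with the right polarity", {
  sim <- simulateAncestor(8, 100, seed = 60, genomeId = "anc")
  sim <- applyPolyploidy(sim, 2, 0.6)
  proxy <- sim; proxy@genome@genomeId <- "proxy"
  ext <- fractionate(sim, c(A = 0.8, B = 0.5), seed = 61)
  ext@genome@genomeId <- "ext"
  h <- makeHomologPairs(ext, proxy, seed = 62)
  bs <- chainBlocks(buildAnchors(simGenome(ext), simGenome(proxy), h, 0.5),
                    5, 25, "ext", "proxy")
  amap <- protoIdentityMap(simGenome(proxy), "proxy")
  cm <- setNames(ifelse(grepl("A$", protoChromosomes(amap)), "A", "B"),
                 protoChromosomes(amap))
  asn <- assignSubgenomes(bs, simGenome(ext), amap, cm)
  tr <- simTruth(ext)
  lab <- karyevol:::.eventLabel(tr$copy_path, "E001")
  m <- merge(asn$assignment,
             data.frame(gene_id = tr$gene_id, truthsub = lab),
             by = "gene_id")
  assigned <- m$subgenome != "unassigned"
  expect_gte(mean(m$subgenome[assigned] == m$truthsub[assigned]), 0.95)
  expect_equal(asn$lf, "A")   # 0.8-retention side dominates
  expect_lt(asn$p_value, 0.05)
})

test_that("symmetric retention leaves the LF/MF call non-significant", {
  nonsig <- 0
  for (s in 1:3) {
    sim <- simulateAncestor(6, 80, seed = 70 + s, genomeId = "anc")
    sim <- applyPolyploidy(sim, 2, 0.6)
    proxy <- sim; proxy@genome@genomeId <- "proxy"
    ext <- fractionate(sim, c(A = 0.7, B = 0.7), seed = 80 + s)
    ext@genome@genomeId <- "ext"
    h <- makeHomologPairs(ext, proxy, seed = 90 + s)
    bs <- chainBlocks(buildAnchors(simGenome(ext), simGenome(proxy), h, 0.5),
                      5, 25, "ext", "proxy")
    amap <- protoIdentityMap(simGenome(proxy), "proxy")
    cm <- setNames(ifelse(grepl("A$", protoChromosomes(amap)), "A", "B"),
                   protoChromosomes(amap))
    asn <- assignSubgenomes(bs, simGenome(ext), amap, cm)
    if (asn$p_value >= 0.05) nonsig <- nonsig + 1
  }
  expect_gte(nonsig, 2)
})

test_that("CSO admission matches a brute-force filter", {
  set.seed(100)
  units <- c(paste0("sp", 1:4, "_A"), paste0("sp", 1:4, "_B"),
             "vvin", "opum")
  cls <- setNames(c(rep("A", 4), rep("B", 4), "outgroup", "outgroup"),
                  units)
  counts <- matrix(rpois(10 * 50, 0.9), nrow = 50,
                   dimnames = list(sprintf("OG%03d", 1:50), units))
  storage.mode(counts) <- "integer"
  cso <- buildCSO(counts, cls, minUnits = 5)
  oracle <- apply(counts, 1, function(x)
    sum(x[1:8] >= 1) >= 5 && all(x[9:10] >= 1))
  expect_setequal(rownames(cso@counts), rownames(counts)[oracle])
  ## an orthogroup short of the unit minimum is excluded even with both
  ## outgroups present
  row <- matrix(c(1, 1, 1, 1, 0, 0, 0, 0, 1, 1), 1,
                dimnames = list("OGx", units))
  storage.mode(row) <- "integer"
  expect_equal(nrow(buildCSO(row, cls, minUnits = 5)@counts), 0)
  expect_error(buildCSO(counts[, 1:8], cls[1:8],
                        requiredUnits = "vvin"), "missing")
})

test_that("copy-number categories are a pure function of the count", {
  expect_identical(unname(copyCategory(c(0, 1, 2, 3, 7))),
                   c("Absent", "Single", "Two", "Multiple", "Multiple"))
  set.seed(101)
  x <- matrix(rpois(200, 1.5), 20)
  cats <- copyCategory(x)
  expect_identical(cats == "Absent", unname(x == 0))
  expect_identical(cats == "Two", unname(x == 2))
})

test_that("retention partition applies the strict majority rule", {
  units <- c(paste0("s", 1:8, "A"), paste0("s", 1:8, "B"), "og1", "og2")
  cls <- setNames(c(rep("A", 8), rep("B", 8), "outgroup", "outgroup"),
                  units)
  mk <- function(nA, nB) c(rep(1L, nA), rep(0L, 8 - nA),
                           rep(1L, nB), rep(0L, 8 - nB), 1L, 1L)
  counts <- rbind(aOnly = mk(5, 3), bOnly = mk(4, 5), both = mk(8, 8),
                  neither = mk(4, 4))
  colnames(counts) <- units
  cso <- buildCSO(counts, cls, minUnits = 4)
  part <- retentionSets(cso)
  expect_identical(as.character(part$partition),
                   c("A-only", "B-only", "both", "neither"))
  expect_equal(part$complementary, 2)
})

test_that("biased fractionation drives significant absent-count asymmetry", {
  ## eight species pairs with 22A-style retention 0.8 vs 22B-style 0.5,
  ## orthogroup counts derived from simulation ground truth
  set.seed(110)
  species <- sprintf("sp%d", 1:8)
  nFam <- 400
  cols <- list()
  for (s in seq_along(species)) {
    sim <- applyPolyploidy(simulateAncestor(4, nFam / 4, seed = 200 + s),
                           2, 0.6)
    sim <- fractionate(sim, c(A = 0.8, B = 0.5), seed = 300 + s)
    tr <- simTruth(sim)
    lab <- karyevol:::.eventLabel(tr$copy_path, "E001")
    fam <- sort(unique(tr$ancestral_gene))
    cols[[paste0(species[s], "_A")]] <-
      as.integer(table(factor(tr$ancestral_gene[lab == "A"], fam)))
    cols[[paste0(species[s], "_B")]] <-
      as.integer(table(factor(tr$ancestral_gene[lab == "B"], fam)))
  }
  counts <- do.call(cbind, cols)
  counts <- cbind(counts, vvin = 1L, opum = 1L)
  rownames(counts) <- sprintf("OG%04d", seq_len(nFam))
  cls <- setNames(c(rep(c("A", "B"), 8), "outgroup", "outgroup"),
                  colnames(counts))
  cso <- buildCSO(counts, cls, minUnits = 8)
  st <- fractionationStats(cso)
  abs1 <- st$tests[st$tests$cluster == 1 & st$tests$category == "Absent", ]
  expect_gt(abs1$mean_B, abs1$mean_A)
  expect_lt(abs1$p_value, 0.05)
  expect_equal(length(st$pairs), 8)
  ## Venn partition sizes always add up
  expect_equal(sum(st$venn$sizes), st$venn$total)
  expect_equal(unname(st$venn$sizes["A-only"] + st$venn$sizes["B-only"]),
               st$venn$complementary)
})

test_that("single-species input produces tables but skips the test", {
  units <- c("s1A", "s1B", "og")
  cls <- setNames(c("A", "B", "outgroup"), units)
  counts <- matrix(rep(1L, 30), 10, dimnames = list(NULL, units))
  cso <- buildCSO(counts, cls, minUnits = 2)
  expect_message(st <- fractionationStats(cso), "skipped")
  expect_true(all(is.na(st$tests$p_value)))
})

test_that("duplication modes follow precedence and recover planted truth", {
  sc <- list(ancestor = list(chromosomes = 8, genes = 150),
             split_age = 0.8,
             lineages = list(
               G = list(events = list(list(kind = "TD", n = 10, age = 0.05),
                                      list(kind = "PD", n = 10, age = 0.05),
                                      list(kind = "TRD", n = 10, age = 0.05),
                                      list(kind = "DSD", n = 10, age = 0.05))),
               O = list(events = list())))
  r <- runScenario(sc, seed = 120)
  G <- simGenome(r$sims$G); O <- simGenome(r$sims$O)
  intra <- chainBlocks(buildAnchors(G, G, r$homologs[["G|G"]], 0,
                                    maskDiagonal = 25), 5, 25, "G", "G")
  outb <- chainBlocks(buildAnchors(G, O, r$homologs[["G|O"]], 0),
                      5, 25, "G", "O")
  modes <- classifyDuplicates(G, r$homologs[["G|G"]], intra, outb)
  tr <- simTruth(r$sims$G)
  m <- merge(tr[!is.na(tr$mode), c("gene_id", "mode")], modes,
             by = "gene_id")
  expect_gte(mean(m$mode.x == m$mode.y), 0.9)
  ## genes with no within-genome homolog are unduplicated
  expect_true(all(modes$mode[!modes$gene_id %in%
    c(r$homologs[["G|G"]]$gene_a, r$homologs[["G|G"]]$gene_b)] == "UD"))
  expect_error(classifyDuplicates(G, r$homologs[["G|G"]], intra, NULL),
               "outgroup")
})

test_that("collinear pairs outrank adjacency in mode precedence", {
  ## a WGD genome: every duplicate pair is in a block, even close ones
  fx <- wgdFixture(seed = 130, nChrom = 3, genesPer = 60)
  g <- simGenome(fx$ext)
  h <- makeHomologPairs(fx$ext, seed = 131)
  intra <- chainBlocks(buildAnchors(g, g, h, 0), 5, 25, "ext", "ext")
  outProxy <- fx$proxy
  ho <- makeHomologPairs(fx$ext, outProxy, seed = 132)
  outb <- chainBlocks(buildAnchors(g, simGenome(outProxy), ho, 0),
                      5, 25, "ext", "proxy")
  modes <- classifyDuplicates(g, h, intra, outb)
  expect_true(all(modes$mode %in% c("WGD", "UD")))
  expect_gt(mean(modes$mode == "WGD"), 0.9)
})

test_that("mode tallies preserve totals by family and subgenome", {
  modes <- data.frame(gene_id = sprintf("g%d", 1:6),
                      mode = c("TD", "TD", "WGD", "DSD", "UD", "UD"),
                      partner = NA, evidence = "",
                      stringsAsFactors = FALSE)
  fams <- data.frame(gene_id = modes$gene_id,
                     family_id = c("F1", "F1", "F1", "F2", "F2", "F3"))
  tab <- modeTallyByFamily(modes, fams)
  expect_equal(sum(tab$count), 6)
  expect_equal(sum(tab$count[tab$family == "F1"]), 3)
  subg <- data.frame(gene_id = modes$gene_id,
                     subgenome = rep(c("A", "B"), 3))
  tab2 <- modeTallyByFamily(modes, fams, subg)
  expect_equal(sum(tab2$count), 6)
})
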