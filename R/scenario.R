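#' @include evosim.R
NULL

#' Split a simulation into diverging lineages
#'
#' Appends a shared SPLIT event and a lineage label to every gene's copy
#' path, so that cross-lineage gene pairs date to the split age.
#'
#' @param sim a \linkS4class{GenomeSimulation}.
#' @param lineages character vector of lineage names (>= 2).
#' @param age split age in Ks units.
#' @return named list of \linkS4class{GenomeSimulation}, one per lineage.
#' @export
splitLineages <- function(sim, lineages, age) {
  if (length(lineages) < 2) stop("need at least two lineages")
  ae <- .addEvent(sim, "SPLIT", age, paste(lineages, collapse = ","))
  sim <- ae$sim; id <- ae$id
  out <- lapply(lineages, function(ln) {
    s <- sim
    s@genome@genomeId <- ln
    s@truth$copy_path <- ifelse(nzchar(s@truth$copy_path),
                                paste0(s@truth$copy_path, ";", id, "=", ln),
                                paste0(id, "=", ln))
    s
  })
  stats::setNames(out, lineages)
}

#' Expected chromosome count from the event log
#'
#' Bookkeeping identity: n = n0 x (product of polyploidy multiplicities)
#' - (#EEJ + #NCF); RTA and inversions are count-neutral.
#'
#' @param sim a \linkS4class{GenomeSimulation}.
#' @param n0 ancestral chromosome count.
#' @export
expectedChromosomeCount <- function(sim, n0) {
  ev <- simEvents(sim)
  mult <- prod(c(1, ifelse(ev$kind == "WGD", 2,
                           ifelse(ev$kind == "WGT", 3, 1))))
  n0 * mult - sum(ev$kind %in% c("EEJ", "NCF"))
}

## seeded choice of fusion partners: prefer chromosomes untouched by earlier
## fusions so painting signatures stay clean
.pickFusionPair <- function(sim, usedChroms) {
  ch <- chromosomeNames(simGenome(sim))
  fresh <- setdiff(ch, usedChroms)
  pool <- if (length(fresh) >= 2) fresh else ch
  sample(pool, 2)
}

.applyScenarioEvent <- function(sim, evt, usedChroms, seedK) {
  kind <- evt$kind
  g <- genes(simGenome(sim))
  set.seed(seedK)
  if (kind %in% c("WGD", "WGT")) {
    mult <- if (kind == "WGD") 2L else 3L
    sim <- applyPolyploidy(sim, mult, evt$age)
    if (!is.null(evt$retention)) {
      ret <- unlist(evt$retention)
      sim <- fractionate(sim, ret, seed = seedK + 1L)
    }
  } else if (kind %in% c("EEJ", "NCF")) {
    if (is.null(evt$donor) || is.null(evt$host)) {
      pr <- .pickFusionPair(sim, usedChroms)
      evt$donor <- pr[1]; evt$host <- pr[2]
    }
    usedChroms <- c(usedChroms, evt$donor, evt$host)
    ir <- evt$insertion_rank
    if (kind == "NCF" && is.null(ir)) {
      hn <- sum(g$chromosome == evt$host)
      lo <- min(20L, max(1L, hn %/% 4)); hi <- hn - lo
      ir <- sample(lo:hi, 1)
    }
    sim <- applyFusion(sim, kind, evt$donor, evt$host, insertionRank = ir,
                       ageKs = evt$age)
  } else if (kind == "RTA") {
    if (is.null(evt$chrom_a) || is.null(evt$chrom_b)) {
      pr <- .pickFusionPair(sim, usedChroms)
      evt$chrom_a <- pr[1]; evt$chrom_b <- pr[2]
    }
    usedChroms <- c(usedChroms, evt$chrom_a, evt$chrom_b)
    nA <- sum(g$chromosome == evt$chrom_a)
    nB <- sum(g$chromosome == evt$chrom_b)
    bA <- if (is.null(evt$break_a)) sample(seq(max(1, nA %/% 4),
                                               nA - max(1, nA %/% 4)), 1)
          else evt$break_a
    bB <- if (is.null(evt$break_b)) sample(seq(max(1, nB %/% 4),
                                               nB - max(1, nB %/% 4)), 1)
          else evt$break_b
    sim <- applyRta(sim, evt$chrom_a, evt$chrom_b, bA, bB, ageKs = evt$age)
  } else if (kind == "INV") {
    ch <- if (is.null(evt$chromosome))
      sample(chromosomeNames(simGenome(sim)), 1) else evt$chromosome
    n <- sum(g$chromosome == ch)
    len <- if (is.null(evt$length)) max(2L, n %/% 5) else evt$length
    st <- sample(0:(n - len), 1)
    sim <- applyInversion(sim, ch, st, st + len, ageKs = evt$age)
  } else if (kind %in% c("TD", "PD", "TRD", "DSD")) {
    n <- if (is.null(evt$n)) 1L else evt$n
    age <- if (is.null(evt$age)) 0.05 else evt$age
    sim <- applySmallScaleDuplication(sim, kind, n = n, ageKs = age,
                                     seed = seedK)
  } else stop("unknown scenario event kind: ", kind)
  list(sim = sim, usedChroms = usedChroms)
}

#' Run a declarative evolution scenario
#'
#' A scenario describes an ancestor, events shared by all lineages (applied
#' oldest-first before the split), a split age, and per-lineage event lists.
#' Chromosome partners, insertion ranks and breakpoints may be given
#' explicitly or left to seeded random choice. Emits one extant
#' \linkS4class{GenomeSimulation} per lineage plus synthesized homolog pair
#' tables for every lineage pair and every self-comparison.
#'
#' @param scenario a nested list (see Details) or path to a YAML file with
#'   the same structure.
#' @param seed global integer seed; all per-stage seeds derive from it.
#' @details Structure:
#' \preformatted{
#' list(
#'   ancestor = list(chromosomes = 11, genes = 200),
#'   shared_events = list(list(kind = "WGT", age = 1.85,
#'                             retention = list(A=.9, B=.6, C=.6))),
#'   split_age = 1.0,
#'   lineages = list(
#'     Q = list(events = list(list(kind = "WGD", age = 0.5,
#'                                 retention = list(A=.8, B=.6)),
#'                            list(kind = "EEJ"))),
#'     R = list(events = list())))
#' }
#' @param dropDsdOrthologs when TRUE (default), families that received a DSD
#'   copy in one lineage are removed from the other lineages, emulating
#'   dispersed duplicates whose ancestral locus is untraceable.
#' @return list with elements \code{sims} (named list of simulations),
#'   \code{homologs} (named list of pair tables, names "A|B"), and
#'   \code{scenario} (the expanded configuration).
#' @export
runScenario <- function(scenario, seed = 1L, dropDsdOrthologs = TRUE) {
  if (is.character(scenario)) scenario <- yaml::read_yaml(scenario)
  if (is.null(scenario$ancestor)) stop("scenario needs an 'ancestor' block")
  if (is.null(scenario$lineages) || length(scenario$lineages) < 1)
    stop("scenario needs at least one lineage")
  anc <- scenario$ancestor
  sim <- simulateAncestor(anc$chromosomes, anc$genes, seed = seed)
  used <- character()
  k <- 0L
  for (evt in scenario$shared_events) {
    k <- k + 1L
    r <- tryCatch(.applyScenarioEvent(sim, evt, used, seed * 1000L + k),
                  error = function(e)
                    stop("shared event ", k, " (", evt$kind, "): ",
                         conditionMessage(e)))
    sim <- r$sim; used <- r$usedChroms
  }
  lnames <- names(scenario$lineages)
  if (length(lnames) >= 2) {
    splitAge <- scenario$split_age
    if (is.null(splitAge)) stop("scenario needs split_age")
    sims <- splitLineages(sim, lnames, splitAge)
  } else {
    sims <- stats::setNames(list(sim), lnames)
  }
  for (ln in lnames) {
    usedL <- used
    evts <- scenario$lineages[[ln]]$events
    for (j in seq_along(evts)) {
      k <- k + 1L
      r <- tryCatch(
        .applyScenarioEvent(sims[[ln]], evts[[j]], usedL, seed * 1000L + k),
        error = function(e)
          stop("lineage ", ln, " event ", j, " (", evts[[j]]$kind, "): ",
               conditionMessage(e)))
      sims[[ln]] <- r$sim; usedL <- r$usedChroms
    }
  }
  if (dropDsdOrthologs) {
    dsdFams <- unique(unlist(lapply(sims, function(s) {
      tr <- simTruth(s)
      tr$ancestral_gene[!is.na(tr$mode) & tr$mode == "DSD"]
    })))
    if (length(dsdFams)) {
      for (ln in lnames) {
        tr <- simTruth(sims[[ln]])
        famWithDsdHere <- unique(
          tr$ancestral_gene[!is.na(tr$mode) & tr$mode == "DSD"])
        ## lineages that did not receive the dispersed copy lose the family
        drop <- tr$ancestral_gene %in% setdiff(dsdFams, famWithDsdHere)
        if (any(drop)) {
          keep <- tr$gene_id[!drop]
          g <- genes(simGenome(sims[[ln]]))
          sims[[ln]]@genome <- .rebuildGenome(ln, g[g$gene_id %in% keep, ])
          sims[[ln]]@truth <- tr[!drop, ]
        }
      }
    }
  }
  homologs <- list()
  hk <- 0L
  for (i in seq_along(lnames)) {
    for (j in i:length(lnames)) {
      hk <- hk + 1L
      homologs[[paste(lnames[i], lnames[j], sep = "|")]] <-
        makeHomologPairs(sims[[lnames[i]]], sims[[lnames[j]]],
                         seed = seed * 100L + hk)
    }
  }
  list(sims = sims, homologs = homologs, scenario = scenario)
}
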