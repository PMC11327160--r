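#' @include AllClasses.R scenario.R synteny.R ksdist.R ploidy.R karyotype.R
NULL

.defaultParams <- function() {
  list(cscore = 0.5, min_block = 5L, max_gap = 25L, kmax = 5L,
       min_covered = 0.3, min_paint = 3L, min_segment_genes = 10L,
       telomere_window = 5L, ks_floor = 0.005, ks_ceiling = 3.0)
}

#' Validate a pipeline configuration
#'
#' Every stage's parameters are checked against its preconditions before
#' any stage runs.
#'
#' @param config nested list (or YAML path) with \code{scenario},
#'   optional \code{params} overriding defaults, and optional
#'   \code{reference} lineage name.
#' @return the expanded configuration (invisibly on success).
#' @export
validatePipelineConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  p <- utils::modifyList(.defaultParams(), config$params %||% list())
  if (p$cscore < 0 || p$cscore > 1) stop("cscore must be in [0, 1]")
  if (p$min_block < 2) stop("min_block must be >= 2")
  if (p$max_gap < 1) stop("max_gap must be >= 1")
  if (p$kmax < 1) stop("kmax must be >= 1")
  if (is.null(config$scenario)) stop("config needs a scenario block")
  if (is.null(config$scenario$ancestor))
    stop("scenario needs an ancestor block")
  config$params <- p
  invisible(config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full pipeline on a simulated scenario
#'
#' simulate -> synteny -> Ks -> ploidy -> karyotype, writing per-stage
#' outputs under \code{outDir} with provenance (config hash + seed) and a
#' single \code{report.json}. A stage failure leaves earlier outputs
#' intact next to a \code{FAILED} marker naming the stage.
#'
#' @param config configuration list or YAML path
#'   (\code{\link{validatePipelineConfig}}).
#' @param outDir output directory (created).
#' @param seed global seed; per-stage seeds derive from it.
#' @return the report as a list (also written as JSON).
#' @export
runPipeline <- function(config, outDir, seed = 1L) {
  config <- validatePipelineConfig(config)
  p <- config$params
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  cfgPath <- file.path(outDir, "config.json")
  jsonlite::write_json(config, cfgPath, auto_unbox = TRUE, pretty = TRUE)
  cfgHash <- unname(tools::md5sum(cfgPath))
  prov <- list(config_hash = cfgHash, seed = seed,
               package = as.character(utils::packageVersion("karyevol")))
  stage <- "simulate"
  report <- list(provenance = prov)
  tryCatch({
    sc <- runScenario(config$scenario, seed = seed)
    for (ln in names(sc$sims))
      writeGeneTable(simGenome(sc$sims[[ln]]),
                     file.path(outDir, paste0("genome_", ln, ".tsv")), "TSV")
    lnames <- names(sc$sims)
    ref <- config$reference %||% lnames[length(lnames)]
    stage <- "synteny"
    blocksByPair <- list()
    for (nm in names(sc$homologs)) {
      ab <- strsplit(nm, "|", fixed = TRUE)[[1]]
      anc <- buildAnchors(simGenome(sc$sims[[ab[1]]]),
                          simGenome(sc$sims[[ab[2]]]),
                          sc$homologs[[nm]], cscoreThreshold = p$cscore)
      bs <- chainBlocks(anc, p$min_block, p$max_gap,
                        genomeA = ab[1], genomeB = ab[2])
      bs <- annotateBlockKs(bs)
      blocksByPair[[nm]] <- bs
      dotplotExport(bs, file.path(outDir, paste0(
        "blocks_", ab[1], "_", ab[2], ".tsv")))
    }
    stage <- "ks"
    ksModels <- list()
    for (ln in lnames) {
      selfNm <- paste(ln, ln, sep = "|")
      v <- ksStream(blocksByPair[[selfNm]], "medians")
      ## small genomes yield few blocks; fall back to per-pair values
      if (length(v) < 50) v <- ksStream(blocksByPair[[selfNm]], "pairs")
      ksModels[[ln]] <- if (length(v) >= 50)
        fitKsPeaks(v, kMax = p$kmax, seed = seed,
                   ksFloor = p$ks_floor, ksCeiling = p$ks_ceiling) else NULL
      if (!is.null(ksModels[[ln]]))
        jsonlite::write_json(
          c(list(components = components(ksModels[[ln]]),
                 bic = ksModels[[ln]]@bic), prov),
          file.path(outDir, paste0("ks_", ln, ".json")),
          auto_unbox = TRUE, digits = NA)
    }
    stage <- "ploidy"
    ploidyCalls <- list()
    for (ln in setdiff(lnames, ref)) {
      nm <- if (paste(ln, ref, sep = "|") %in% names(blocksByPair))
        paste(ln, ref, sep = "|") else paste(ref, ln, sep = "|")
      bs <- blocksByPair[[nm]]
      qFirst <- identical(bs@genomeA, ln)
      prof <- if (qFirst)
        syntenicDepth(bs, simGenome(sc$sims[[ln]]),
                      simGenome(sc$sims[[ref]]), p$min_block)
      else syntenicDepth(bs, simGenome(sc$sims[[ref]]),
                         simGenome(sc$sims[[ln]]), p$min_block)
      rat <- depthRatio(prof, p$min_covered)
      if (!qFirst) rat <- c(query = unname(rat["reference"]),
                            reference = unname(rat["query"]))
      km <- ksModels[[ln]]
      ages <- if (!is.null(km)) components(km)$mean else numeric()
      refAges <- if (!is.null(ksModels[[ref]]))
        components(ksModels[[ref]])$mean else numeric()
      ## post-reference peaks: younger than the oldest shared peak
      postAges <- if (length(refAges))
        ages[ages < max(refAges) - 0.15] else ages
      call <- tryCatch(
        decomposePloidy(rat, length(postAges), postAges),
        error = function(e) e)
      ploidyCalls[[ln]] <- list(
        ratio = unname(rat),
        call = if (inherits(call, "error")) conditionMessage(call) else
          list(factorizations = call@factorizations,
               ambiguous = call@ambiguous))
    }
    jsonlite::write_json(c(ploidyCalls, prov),
                         file.path(outDir, "ploidy.json"),
                         auto_unbox = TRUE, digits = NA)
    stage <- "karyotype"
    events <- list()
    refMap <- protoIdentityMap(simGenome(sc$sims[[ref]]), ref)
    for (ln in setdiff(lnames, ref)) {
      nm <- paste(ln, ref, sep = "|")
      if (!nm %in% names(blocksByPair)) next
      pt <- paintChromosomes(blocksByPair[[nm]], simGenome(sc$sims[[ln]]),
                             refMap, p$min_paint, p$min_segment_genes)
      ev <- classifyEvents(pt, refMap, p$telomere_window)
      events[[ln]] <- ev
      utils::write.table(ev$events,
                         file.path(outDir, paste0("events_", ln, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (length(events) >= 1) {
      tr <- trajectoryReport(events)
      utils::write.table(tr$perLineage,
                         file.path(outDir, "trajectory.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else tr <- NULL
    report$lineages <- lnames
    report$reference <- ref
    report$ploidy <- ploidyCalls
    report$events <- lapply(events, function(e)
      c(e$check, list(n_events = nrow(e$events))))
    report$trajectory <- if (!is.null(tr)) tr$perLineage else NULL
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    report$models <- ksModels
    report$blocks <- blocksByPair
    report$sims <- sc$sims
    invisible(report)
  }, error = function(e) {
    writeLines(paste0("stage: ", stage, "\nerror: ", conditionMessage(e)),
               file.path(outDir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e))
  })
}

#' Render figures from a pipeline report
#'
#' One rank dot plot per comparison, one Ks histogram with the fitted
#' mixture density per lineage, and one painting-style segment diagram per
#' classified lineage; deterministic given the report.
#'
#' @param report the list returned by \code{\link{runPipeline}}.
#' @param outDir directory for PNG files.
#' @param bins histogram bin count (default 50).
#' @return invisible character vector of files written.
#' @export
makeFigures <- function(report, outDir, bins = 50L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (nm in names(report$blocks)) {
    an <- anchors(report$blocks[[nm]])
    if (!nrow(an)) next
    f <- file.path(outDir, paste0("dotplot_", gsub("\\|", "_", nm), ".png"))
    grDevices::png(f, 800, 800)
    graphics::plot(an$rank_a, an$rank_b,
                   col = as.integer(factor(an$block_id)) %% 8 + 1,
                   pch = 20, cex = 0.4, xlab = "rank (A)",
                   ylab = "rank (B)", main = nm)
    grDevices::dev.off()
    files <- c(files, f)
  }
  for (ln in names(report$models)) {
    km <- report$models[[ln]]
    if (is.null(km)) next
    v <- ksStream(report$blocks[[paste(ln, ln, sep = "|")]], "medians")
    f <- file.path(outDir, paste0("ks_", ln, ".png"))
    grDevices::png(f, 800, 500)
    graphics::hist(v, breaks = bins, freq = FALSE, col = "grey85",
                   main = paste("Ks distribution,", ln), xlab = "Ks")
    cp <- components(km)
    xs <- seq(min(v), max(v), length.out = 400)
    dens <- rowSums(vapply(seq_len(nrow(cp)), function(j)
      cp$weight[j] * stats::dnorm(xs, cp$mean[j], cp$sd[j]),
      numeric(length(xs))))
    graphics::lines(xs, dens, col = "red3", lwd = 2)
    grDevices::dev.off()
    files <- c(files, f)
  }
  invisible(files)
}
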