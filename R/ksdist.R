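#' @include AllClasses.R AllGenerics.R synteny.R codon.R
NULL

#' Compute per-anchor Ks from coding sequences
#'
#' Runs the NG86 estimator (\code{\link{ngKs}}) on every anchor pair of a
#' block set and stores the ds estimate in the anchor table (NA when
#' saturated).
#'
#' @param blockSet a \linkS4class{SyntenyBlockSet}.
#' @param cdsA,cdsB named character vectors or \code{Biostrings::DNAStringSet}
#'   of in-frame CDS, names matching gene ids.
#' @return the block set with anchor ks filled in.
#' @export
annotatePairKs <- function(blockSet, cdsA, cdsB) {
  cdsA <- vapply(as.character(cdsA), identity, character(1))
  cdsB <- vapply(as.character(cdsB), identity, character(1))
  an <- anchors(blockSet)
  an$ks <- vapply(seq_len(nrow(an)), function(i) {
    a <- cdsA[[an$gene_a[i]]]; b <- cdsB[[an$gene_b[i]]]
    if (is.null(a) || is.null(b)) return(NA_real_)
    ngKs(a, b)$ds
  }, numeric(1))
  blockSet@anchors <- an
  blockSet
}

#' Annotate blocks with their median Ks
#'
#' The median over the block's defined (non-saturated) pair Ks values
#' represents the block; the even-count median is the mean of the central
#' two. Blocks whose pairs are all saturated/undefined keep an NA median
#' and are flagged.
#'
#' @param blockSet a \linkS4class{SyntenyBlockSet}.
#' @param pairKs optional data.frame (gene_a, gene_b, ks) overriding the
#'   anchor table's ks column.
#' @return the block set with blocks$median_ks and blocks$saturated set.
#' @export
annotateBlockKs <- function(blockSet, pairKs = NULL) {
  an <- anchors(blockSet)
  if (!is.null(pairKs)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    m <- match(key(an$gene_a, an$gene_b), key(pairKs$gene_a, pairKs$gene_b))
    an$ks <- pairKs$ks[m]
    blockSet@anchors <- an
  }
  bl <- blocks(blockSet)
  med <- vapply(bl$block_id, function(id) {
    v <- an$ks[an$block_id == id]
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else stats::median(v)
  }, numeric(1))
  bl$median_ks <- unname(med)
  bl$saturated <- is.na(bl$median_ks)
  blockSet@blocks <- bl
  blockSet
}

## one EM run for a k-component 1-D Gaussian mixture
.emGmm1 <- function(x, k, tol = 1e-6, maxIter = 500L, sdFloor = 1e-4) {
  n <- length(x)
  init <- tryCatch({
    km <- stats::kmeans(x, centers = k, nstart = 1)
    mu <- as.numeric(km$centers)
    sdv <- vapply(seq_len(k), function(j) {
      v <- stats::sd(x[km$cluster == j])
      if (is.na(v) || v < sdFloor) sdFloor else v
    }, numeric(1))
    w <- as.numeric(table(factor(km$cluster, levels = seq_len(k)))) / n
    list(mu = mu, sd = sdv, w = pmax(w, 1e-6) / sum(pmax(w, 1e-6)))
  }, error = function(e) {
    q <- stats::quantile(x, probs = (seq_len(k) - 0.5) / k, names = FALSE)
    list(mu = q, sd = rep(max(stats::sd(x), sdFloor), k), w = rep(1 / k, k))
  })
  mu <- init$mu; sdv <- init$sd; w <- init$w
  ll <- -Inf; converged <- FALSE
  for (it in seq_len(maxIter)) {
    dens <- vapply(seq_len(k), function(j)
      w[j] * stats::dnorm(x, mu[j], sdv[j]), numeric(n))
    if (k == 1) dens <- matrix(dens, ncol = 1)
    tot <- rowSums(dens)
    tot[tot < 1e-300] <- 1e-300
    newll <- sum(log(tot))
    if (is.finite(ll) && abs(newll - ll) < tol) {
      ll <- newll; converged <- TRUE; break
    }
    ll <- newll
    r <- dens / tot
    nk <- colSums(r)
    nk[nk < 1e-10] <- 1e-10
    w <- nk / n
    mu <- colSums(r * x) / nk
    sdv <- sqrt(colSums(r * (x - rep(mu, each = n))^2) / nk)
    sdv[sdv < sdFloor] <- sdFloor
  }
  o <- order(mu)
  list(w = w[o], mu = mu[o], sd = sdv[o], loglik = ll,
       converged = converged)
}

#' Fit Gaussian mixtures to a Ks sample and select peaks by BIC
#'
#' EM fits for k = 1..kMax with seeded k-means initialisations and
#' restarts; the model with the lowest BIC is returned. Values are first
#' filtered to (ksFloor, ksCeiling] to trim allele-level noise and
#' saturated estimates. Deterministic given the seed.
#'
#' @param values numeric Ks values.
#' @param kMax maximum number of components (>= 1).
#' @param nRestarts restarts per k (default 10).
#' @param seed integer seed.
#' @param ksFloor,ksCeiling filtering bounds (defaults 0.005 and 3.0).
#' @param tol,maxIter EM convergence controls.
#' @return a \linkS4class{KsMixtureModel}.
#' @export
fitKsPeaks <- function(values, kMax = 5L, nRestarts = 10L, seed = 42L,
                       ksFloor = 0.005, ksCeiling = 3.0, tol = 1e-6,
                       maxIter = 500L) {
  if (kMax < 1) stop("kMax must be >= 1")
  x <- values[!is.na(values) & values > ksFloor & values <= ksCeiling]
  if (length(x) < 50)
    stop("need at least 50 Ks values in (", ksFloor, ", ", ksCeiling,
         "]; got ", length(x))
  if (stats::sd(x) < 1e-12) {
    ## degenerate sample: a single spike component at the sd floor
    comp <- data.frame(weight = 1, mean = mean(x), sd = 1e-4)
    return(new("KsMixtureModel", components = comp,
               nPoints = length(x), bic = NA_real_,
               bicTable = data.frame(k = 1L, bic = NA_real_,
                                     loglik = NA_real_),
               seed = as.integer(seed), converged = TRUE))
  }
  bicTab <- data.frame(k = integer(), bic = numeric(), loglik = numeric())
  best <- NULL; bestBic <- Inf; anyConv <- FALSE
  for (k in seq_len(kMax)) {
    bestK <- NULL
    for (r in seq_len(nRestarts)) {
      set.seed(seed + 1000L * k + r)
      fit <- .emGmm1(x, k, tol = tol, maxIter = maxIter)
      if (is.null(bestK) || fit$loglik > bestK$loglik) bestK <- fit
    }
    p <- 3L * k - 1L
    bic <- -2 * bestK$loglik + p * log(length(x))
    bicTab <- rbind(bicTab, data.frame(k = k, bic = bic,
                                       loglik = bestK$loglik))
    if (bic < bestBic) {
      bestBic <- bic; best <- bestK; anyConv <- bestK$converged
    }
  }
  if (!anyConv)
    warning("EM did not converge within ", maxIter,
            " iterations; returning best model found")
  comp <- data.frame(weight = best$w, mean = best$mu, sd = best$sd)
  new("KsMixtureModel", components = comp, nPoints = length(x),
      bic = bestBic, bicTable = bicTab, seed = as.integer(seed),
      converged = anyConv)
}

#' Filter blocks by median Ks
#'
#' Keeps blocks whose median Ks lies in (minKs, maxKs]. Gating blocks below
#' the age of an old shared polyploidy is how orthologous depth ratios are
#' read between genomes that both carry it: homoeologous (older) blocks are
#' excluded so the shared event never inflates the ratio.
#'
#' @param blockSet an annotated \linkS4class{SyntenyBlockSet}.
#' @param maxKs upper bound (inclusive).
#' @param minKs lower bound (exclusive, default 0).
#' @return the filtered block set.
#' @export
filterBlocksByKs <- function(blockSet, maxKs, minKs = 0) {
  bl <- blocks(blockSet)
  keep <- !is.na(bl$median_ks) & bl$median_ks > minKs & bl$median_ks <= maxKs
  blockSet@blocks <- bl[keep, , drop = FALSE]
  blockSet@anchors <- blockSet@anchors[
    blockSet@anchors$block_id %in% bl$block_id[keep], , drop = FALSE]
  blockSet
}

#' Ks stream for peak fitting
#'
#' Returns either the per-block median Ks values (the default
#' representation of a block) or the raw per-pair values.
#'
#' @param blockSet an annotated \linkS4class{SyntenyBlockSet}.
#' @param stream "medians" or "pairs".
#' @export
ksStream <- function(blockSet, stream = c("medians", "pairs")) {
  stream <- match.arg(stream)
  if (stream == "medians") {
    v <- blocks(blockSet)$median_ks
  } else {
    v <- anchors(blockSet)$ks
  }
  v[!is.na(v)]
}
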