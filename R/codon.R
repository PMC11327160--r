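#' @include AllClasses.R
NULL

## ---- genetic-code helpers (cached at first use) ----

.codonEnv <- new.env(parent = emptyenv())

.geneticCode <- function() {
  if (is.null(.codonEnv$code)) {
    code <- Biostrings::GENETIC_CODE
    .codonEnv$code <- code
    .codonEnv$codons <- names(code)
    .codonEnv$stops <- names(code)[code == "*"]
    ## per-codon synonymous site count, NG86 convention: at each position
    ## (# synonymous one-nucleotide changes)/(# possible changes not
    ## creating a stop codon); stop codons themselves carry no sites
    nt <- c("A", "C", "G", "T")
    syn <- vapply(names(code), function(cd) {
      if (code[[cd]] == "*") return(NA_real_)
      s <- 0
      cv <- strsplit(cd, "")[[1]]
      for (p in 1:3) {
        nsyn <- 0; npos <- 0
        for (b in setdiff(nt, cv[p])) {
          alt <- cv; alt[p] <- b
          altc <- paste(alt, collapse = "")
          if (code[[altc]] == "*") next
          npos <- npos + 1
          if (code[[altc]] == code[[cd]]) nsyn <- nsyn + 1
        }
        if (npos > 0) s <- s + nsyn / npos
      }
      s
    }, numeric(1))
    .codonEnv$synSites <- syn
    .codonEnv$pathCache <- new.env(parent = emptyenv())
  }
  invisible(NULL)
}

.isStop <- function(codon) {
  .geneticCode()
  codon %in% .codonEnv$stops
}

## synonymous/nonsynonymous differences between two codons, averaged over
## all orderings of single-nucleotide steps; paths through stop codons are
## excluded (all-stop-path pairs fall back to using every path)
.codonPairDiffs <- function(c1, c2) {
  .geneticCode()
  if (c1 == c2) return(c(sd = 0, nd = 0))
  key <- paste(sort(c(c1, c2)), collapse = "|")
  hit <- .codonEnv$pathCache[[key]]
  if (!is.null(hit)) return(hit)
  code <- .codonEnv$code
  v1 <- strsplit(c1, "")[[1]]; v2 <- strsplit(c2, "")[[1]]
  pos <- which(v1 != v2)
  perms <- switch(as.character(length(pos)),
    "1" = list(pos),
    "2" = list(pos, rev(pos)),
    "3" = {
      p <- pos
      list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
           p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
    })
  tally <- function(order, allowStops) {
    cur <- v1; s <- 0; n <- 0
    for (p in order) {
      prev <- paste(cur, collapse = "")
      cur[p] <- v2[p]
      now <- paste(cur, collapse = "")
      if (!allowStops && code[[now]] == "*") return(NULL)
      if (code[[prev]] == code[[now]]) s <- s + 1 else n <- n + 1
    }
    c(s, n)
  }
  res <- Filter(Negate(is.null), lapply(perms, tally, allowStops = FALSE))
  if (!length(res))
    res <- Filter(Negate(is.null), lapply(perms, tally, allowStops = TRUE))
  m <- do.call(rbind, res)
  out <- c(sd = mean(m[, 1]), nd = mean(m[, 2]))
  assign(key, out, envir = .codonEnv$pathCache)
  out
}

.splitCodons <- function(x) {
  x <- toupper(as.character(x))
  if (nchar(x) %% 3 != 0) stop("sequence length is not a multiple of 3")
  substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
}

#' Nei-Gojobori (NG86) synonymous and nonsynonymous divergence
#'
#' Counts synonymous (S) and nonsynonymous (N) sites per codon with the
#' NG86 fractional convention (single-nucleotide changes creating stop
#' codons are excluded from the possible-change denominator), averages site
#' counts over the two sequences, resolves multi-nucleotide codon
#' differences by averaging over all orderings of single steps (paths
#' through stop codons excluded), and applies the Jukes-Cantor correction
#' d = -3/4 log(1 - 4p/3). Codons containing '-' or 'N' in either sequence
#' are skipped pairwise.
#'
#' @param seqA,seqB in-frame coding sequences (character or DNAString),
#'   equal length, multiple of 3, no internal stop codons.
#' @return list with ds, dn (NA with \code{saturated = TRUE} when the
#'   proportion reaches the Jukes-Cantor bound 3/4), S, N, sd, nd, pS, pN,
#'   codons (number compared), saturated_s, saturated_n.
#' @examples
#' ngKs("AAAGGGCCC", "AAGGGGCCC")$ds  # 0.6354 by hand enumeration
#' @export
ngKs <- function(seqA, seqB) {
  .geneticCode()
  ca <- .splitCodons(seqA); cb <- .splitCodons(seqB)
  if (length(ca) != length(cb)) stop("sequences differ in length")
  gap <- grepl("[-N]", ca) | grepl("[-N]", cb)
  ca <- ca[!gap]; cb <- cb[!gap]
  if (!length(ca)) stop("no comparable codons")
  if (any(.isStop(ca)) || any(.isStop(cb)))
    stop("internal stop codon")
  sa <- sum(.codonEnv$synSites[ca])
  sb <- sum(.codonEnv$synSites[cb])
  S <- (sa + sb) / 2
  N <- 3 * length(ca) - S
  d <- vapply(which(ca != cb), function(i) .codonPairDiffs(ca[i], cb[i]),
              numeric(2))
  sd_ <- if (length(d)) sum(d[1, ]) else 0
  nd_ <- if (length(d)) sum(d[2, ]) else 0
  pS <- sd_ / S; pN <- nd_ / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(ds = jc(pS), dn = jc(pN), S = S, N = N, sd = sd_, nd = nd_,
       pS = pS, pN = pN, codons = length(ca),
       saturated_s = pS >= 0.75, saturated_n = pN >= 0.75)
}

#' Generate a codon-sequence pair with a target synonymous divergence
#'
#' Builds a random stop-free coding sequence and derives a partner differing
#' only by synonymous substitutions, placed greedily on fourfold-degenerate
#' third positions first (then remaining synonymous single-nucleotide
#' options) until the NG86 estimate of the pair first reaches the target.
#' The two sequences always translate to the same protein.
#'
#' @param nCodons number of codons (>= 10).
#' @param targetDs target synonymous divergence (>= 0).
#' @param seed integer seed.
#' @return list with seqA, seqB (character strings) and ks (the realised
#'   NG86 estimate, >= targetDs).
#' @export
generateCodonPair <- function(nCodons, targetDs, seed = 1L) {
  .geneticCode()
  if (nCodons < 10) stop("nCodons must be >= 10")
  if (targetDs < 0) stop("targetDs must be >= 0")
  set.seed(seed)
  pool <- setdiff(.codonEnv$codons, .codonEnv$stops)
  ca <- sample(pool, nCodons, replace = TRUE)
  cb <- ca
  if (targetDs == 0)
    return(list(seqA = paste(ca, collapse = ""),
                seqB = paste(cb, collapse = ""), ks = 0))
  code <- .codonEnv$code
  nt <- c("A", "C", "G", "T")
  ## candidate synonymous edits: (codon index, position, new base); a site is
  ## edited at most once. fourfold third positions first, then the rest.
  cands <- list()
  for (i in seq_len(nCodons)) {
    cv <- strsplit(ca[i], "")[[1]]
    for (p in 1:3) {
      alts <- character()
      for (b in setdiff(nt, cv[p])) {
        alt <- cv; alt[p] <- b
        altc <- paste(alt, collapse = "")
        if (code[[altc]] == code[[ca[i]]]) alts <- c(alts, b)
      }
      if (length(alts))
        cands[[length(cands) + 1L]] <-
          list(i = i, p = p, alts = alts, fourfold = length(alts) == 3)
    }
  }
  ff <- vapply(cands, `[[`, logical(1), "fourfold")
  ord <- c(sample(which(ff)), sample(which(!ff)))
  est <- ngKs(paste(ca, collapse = ""), paste(cb, collapse = ""))
  used <- rep(FALSE, nCodons * 3)
  for (j in ord) {
    cd <- cands[[j]]
    slot <- (cd$i - 1L) * 3L + cd$p
    if (used[slot]) next
    cv <- strsplit(cb[cd$i], "")[[1]]
    b <- sample(cd$alts, 1)
    cv[cd$p] <- b
    newc <- paste(cv, collapse = "")
    if (code[[newc]] != code[[cb[cd$i]]]) next  # no longer synonymous in b
    cb[cd$i] <- newc
    used[slot] <- TRUE
    est <- ngKs(paste(ca, collapse = ""), paste(cb, collapse = ""))
    if (!is.na(est$ds) && est$ds >= targetDs) break
  }
  if (is.na(est$ds) || est$ds < targetDs) {
    maxds <- if (is.na(est$ds)) Inf else est$ds
    if (is.na(est$ds))
      stop("target Ks unreachable: estimate saturated before reaching ",
           targetDs)
    stop("target Ks unreachable: maximum achievable is ",
         format(maxds, digits = 4))
  }
  list(seqA = paste(ca, collapse = ""), seqB = paste(cb, collapse = ""),
       ks = est$ds)
}
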