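#' @include AllClasses.R
NULL

#' @rdname GenomeTable-class
#' @param object,x a package object.
#' @export
setGeneric("genomeId", function(object) standardGeneric("genomeId"))
#' @rdname GenomeTable-class
#' @export
setGeneric("genes", function(object) standardGeneric("genes"))
#' @rdname GenomeTable-class
#' @export
setGeneric("chromosomeLengths",
           function(object) standardGeneric("chromosomeLengths"))
#' @rdname GenomeTable-class
#' @export
setGeneric("chromosomeNames",
           function(object) standardGeneric("chromosomeNames"))
#' @rdname GenomeTable-class
#' @export
setGeneric("geneCount", function(object) standardGeneric("geneCount"))
#' @rdname GenomeTable-class
#' @export
setGeneric("chromosomeCount",
           function(object) standardGeneric("chromosomeCount"))

#' @rdname SyntenyBlockSet-class
#' @export
setGeneric("blocks", function(object) standardGeneric("blocks"))
#' @rdname SyntenyBlockSet-class
#' @export
setGeneric("anchors", function(object) standardGeneric("anchors"))

#' @rdname KsMixtureModel-class
#' @export
setGeneric("components", function(object) standardGeneric("components"))

#' @rdname KaryotypeMap-class
#' @export
setGeneric("protoChromosomes",
           function(object) standardGeneric("protoChromosomes"))
#' @rdname KaryotypeMap-class
#' @export
setGeneric("karyoSegments", function(object) standardGeneric("karyoSegments"))

#' @rdname GenomeSimulation-class
#' @export
setGeneric("simGenome", function(object) standardGeneric("simGenome"))
#' @rdname GenomeSimulation-class
#' @export
setGeneric("simTruth", function(object) standardGeneric("simTruth"))
#' @rdname GenomeSimulation-class
#' @export
setGeneric("simEvents", function(object) standardGeneric("simEvents"))

#' @export
setMethod("genomeId", "GenomeTable", function(object) object@genomeId)
#' @export
setMethod("genes", "GenomeTable", function(object) object@genes)
#' @export
setMethod("chromosomeLengths", "GenomeTable",
          function(object) object@chromosomeLengths)
#' @export
setMethod("chromosomeNames", "GenomeTable",
          function(object) unique(object@genes$chromosome))
#' @export
setMethod("geneCount", "GenomeTable", function(object) nrow(object@genes))
#' @export
setMethod("chromosomeCount", "GenomeTable",
          function(object) length(unique(object@genes$chromosome)))

#' @export
setMethod("blocks", "SyntenyBlockSet", function(object) object@blocks)
#' @export
setMethod("anchors", "SyntenyBlockSet", function(object) object@anchors)

#' @export
setMethod("components", "KsMixtureModel", function(object) object@components)

#' @export
setMethod("protoChromosomes", "KaryotypeMap",
          function(object) object@protoChromosomes)
#' @export
setMethod("karyoSegments", "KaryotypeMap", function(object) object@segments)
#' @export
setMethod("karyoSegments", "KaryotypePainting", function(object) object@segments)

#' @export
setMethod("simGenome", "GenomeSimulation", function(object) object@genome)
#' @export
setMethod("simTruth", "GenomeSimulation", function(object) object@truth)
#' @export
setMethod("simEvents", "GenomeSimulation", function(object) object@events)

setMethod("show", "GenomeTable", function(object) {
  cat("GenomeTable '", object@genomeId, "': ", nrow(object@genes),
      " genes on ", length(unique(object@genes$chromosome)),
      " chromosomes\n", sep = "")
})

setMethod("show", "SyntenyBlockSet", function(object) {
  cat("SyntenyBlockSet ", object@genomeA, " vs ", object@genomeB, ": ",
      nrow(object@blocks), " blocks, ", nrow(object@anchors),
      " anchors\n", sep = "")
})

setMethod("show", "KsMixtureModel", function(object) {
  cat("KsMixtureModel: k =", nrow(object@components),
      "on", object@nPoints, "values, BIC =",
      format(object@bic, digits = 6), "\n")
  print(object@components, digits = 4)
})

setMethod("show", "KaryotypeMap", function(object) {
  cat("KaryotypeMap '", object@karyotypeId, "': ",
      length(object@protoChromosomes), " proto-chromosomes, ",
      nrow(object@segments), " segments\n", sep = "")
})

setMethod("show", "KaryotypePainting", function(object) {
  cat("KaryotypePainting of '", object@genomeId, "' on '",
      object@ancestorId, "': ", nrow(object@segments), " segments on ",
      length(unique(object@segments$chromosome)), " chromosomes\n", sep = "")
})

setMethod("show", "CSOMatrix", function(object) {
  cat("CSOMatrix: ", nrow(object@counts), " CSOs x ", ncol(object@counts),
      " units (", sum(object@unitClass == "A"), " A, ",
      sum(object@unitClass == "B"), " B, ",
      sum(object@unitClass == "outgroup"), " outgroup)\n", sep = "")
})

setMethod("show", "GenomeSimulation", function(object) {
  cat("GenomeSimulation: ")
  show(object@genome)
  if (nrow(object@events))
    cat("  events:", paste(object@events$kind, collapse = ", "), "\n")
})
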