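#' @rdname BlockStructure-class
#' @param x a gcadapt object.
#' @export
setGeneric("blocks", function(x) standardGeneric("blocks"))

#' @rdname BlockStructure-class
#' @export
setGeneric("stopCodons", function(x) standardGeneric("stopCodons"))

#' @rdname GeneticCode-class
#' @param x a gcadapt object.
#' @export
setGeneric("assignment", function(x) standardGeneric("assignment"))

#' @rdname ParetoFront-class
#' @param x a gcadapt object.
#' @export
setGeneric("objectives", function(x) standardGeneric("objectives"))

#' @rdname ParetoFront-class
#' @export
setGeneric("specs", function(x) standardGeneric("specs"))

#' @rdname ParetoFront-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname ObjectiveSpec-class
#' @param x a gcadapt object.
#' @export
setGeneric("specLabel", function(x) standardGeneric("specLabel"))

#' @describeIn BlockStructure-class the named list of codon blocks.
#' @export
setMethod("blocks", "BlockStructure", function(x) x@blocks)

#' @describeIn BlockStructure-class the three stop codons.
#' @export
setMethod("stopCodons", "BlockStructure", function(x) x@stops)

#' @describeIn GeneticCode-class the block-to-amino-acid assignment.
#' @export
setMethod("assignment", "GeneticCode", function(x) x@assignment)

#' @describeIn ParetoFront-class numeric matrix of objective values
#'   (members x objectives).
#' @export
setMethod("objectives", "ParetoFront", function(x) x@objectives)

#' @describeIn ParetoFront-class the list of objective specifications.
#' @export
setMethod("specs", "ParetoFront", function(x) x@specs)

#' @describeIn ParetoFront-class per-member run id and generation.
#' @export
setMethod("provenance", "ParetoFront", function(x) x@provenance)

#' @describeIn ParetoFront-class the objective specifications of the sample.
#' @export
setMethod("specs", "SampleSummary", function(x) x@specs)

#' @describeIn ObjectiveSpec-class short label, e.g. `"ms:pr"`.
#' @export
setMethod("specLabel", "ObjectiveSpec",
          function(x) paste(x@measure, x@propertyName, sep = ":"))

#' @describeIn ParetoFront-class number of front members.
#' @param object a gcadapt object.
#' @export
setMethod("length", "ParetoFront", function(x) nrow(x@assignments))

setMethod("show", "BlockStructure", function(object) {
  sizes <- lengths(object@blocks)
  cat("BlockStructure: 20 synonymous-codon blocks (61 sense codons)\n")
  cat("  block sizes:", paste(sizes, collapse = " "), "\n")
  cat("  stop codons:", paste(object@stops, collapse = " "), "(fixed)\n")
})

setMethod("show", "GeneticCode", function(object) {
  a <- object@assignment
  moved <- sum(a != names(a))
  cat("GeneticCode (restrictive encoding): 20 blocks -> 20 amino acids\n")
  cat("  blocks differing from canonical:", moved, "\n")
  if (moved > 0L && moved <= 8L) {
    d <- which(a != names(a))
    cat("  ", paste0(names(a)[d], "->", a[d], collapse = ", "), "\n")
  }
})

setMethod("show", "ObjectiveSpec", function(object) {
  cat("ObjectiveSpec:", specLabel(object), "\n")
  if (object@measure == "mst")
    cat("  weights (ti/tv by base):",
        paste(apply(object@weights, 1L, paste, collapse = "/"),
              collapse = " ; "), "\n")
})

setMethod("show", "ParetoFront", function(object) {
  labs <- vapply(object@specs, specLabel, "")
  cat("ParetoFront:", nrow(object@assignments), "nondominated codes,",
      "objectives:", paste(labs, collapse = ", "), "\n")
  if (nrow(object@objectives)) {
    rng <- apply(object@objectives, 2L, range)
    for (k in seq_along(labs))
      cat(sprintf("  %s in [%.4g, %.4g]\n", labs[k], rng[1L, k], rng[2L, k]))
  }
})

setMethod("show", "SampleSummary", function(object) {
  labs <- vapply(object@specs, specLabel, "")
  cat("SampleSummary:", format(object@n, big.mark = ","),
      "uniform random restrictive codes (seed", object@seed, ")\n")
  for (k in seq_along(labs))
    cat(sprintf("  %-7s mean %.4g sd %.4g canonical %.4g better %d\n",
                labs[k], object@mean[k], object@sd[k], object@canonical[k],
                as.integer(object@countBetter[k])))
})
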