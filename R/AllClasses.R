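#' gcadapt: multiobjective analysis of genetic code adaptability
#'
#' Scores hypothetical genetic codes by robustness to single-nucleotide
#' substitutions under amino-acid property scales, searches the space of
#' codes preserving the canonical synonymous-codon blocks with NSGA-II, and
#' compares optimized codes with the canonical code against random-code null
#' distributions.
#'
#' @import methods
#' @importFrom stats runif setNames sd
#' @importFrom utils read.delim write.table read.csv head
#' @name gcadapt-package
#' @keywords internal
"_PACKAGE"

AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
         "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
         "Tyr", "Val")

RNA_BASES <- c("U", "C", "A", "G")

#' Partition of the sense codons into synonymous blocks
#'
#' A `BlockStructure` holds the fixed partition of the 61 sense codons into
#' 20 synonymous-codon groups ("blocks"), plus the 3 stop codons. In the
#' restrictive encoding a hypothetical genetic code is a permutation of the
#' 20 amino acids over these blocks; the blocks themselves and the stop
#' codons never move.
#'
#' Blocks are ordered lexicographically by their smallest codon and labelled
#' by the amino acid the canonical code assigns to them, so block labels are
#' stable identifiers in every serialized output.
#'
#' @slot blocks named list of character vectors; each element the RNA codons
#'   of one block, names are block labels (the canonical amino acid).
#' @slot stops character vector of the 3 stop codons.
#' @seealso [canonicalBlocks()]
#' @export
setClass("BlockStructure",
         representation(blocks = "list", stops = "character"))

setValidity("BlockStructure", function(object) {
  msg <- character(0)
  all_codons <- unlist(object@blocks, use.names = FALSE)
  if (length(object@blocks) != 20L)
    msg <- c(msg, "must have exactly 20 blocks")
  if (anyDuplicated(all_codons))
    msg <- c(msg, "blocks must be pairwise disjoint")
  if (length(all_codons) != 61L)
    msg <- c(msg, "blocks must cover exactly 61 sense codons")
  if (!setequal(object@stops, c("UAA", "UAG", "UGA")))
    msg <- c(msg, "stop codons must be UAA, UAG, UGA")
  if (length(intersect(all_codons, object@stops)) > 0L)
    msg <- c(msg, "stop codons cannot belong to a block")
  bad <- all_codons[!grepl("^[UCAG]{3}$", all_codons)]
  if (length(bad))
    msg <- c(msg, paste("invalid codons:", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' A hypothetical genetic code in restrictive encoding
#'
#' A `GeneticCode` assigns one amino acid to each of the 20 synonymous-codon
#' blocks of [canonicalBlocks()]. The assignment is a permutation of the 20
#' standard amino acids: every amino acid is used exactly once. Together
#' with the block structure it induces a total map from sense codons to
#' amino acids.
#'
#' @slot assignment named character vector of length 20; names are block
#'   labels (canonical amino acid of the block), values the assigned amino
#'   acids (three-letter codes).
#' @seealso [canonicalCode()], [randomCode()], [swapMutate()]
#' @export
setClass("GeneticCode", representation(assignment = "character"))

setValidity("GeneticCode", function(object) {
  a <- object@assignment
  if (length(a) != 20L)
    return("assignment must have length 20")
  if (!setequal(names(a), AA3))
    return("assignment names must be the 20 block labels")
  if (!setequal(unname(a), AA3) || anyDuplicated(a))
    return("assignment must be a permutation of the 20 amino acids")
  TRUE
})

#' One objective of a multiobjective code evaluation
#'
#' An `ObjectiveSpec` pairs an amino-acid property scale with an error
#' measure: `"ms"` (plain mean squared property change over all
#' single-nucleotide sense-codon substitutions) or `"mst"` (the same mean
#' weighted by base position and transition/transversion status, modelling
#' unequal mistranslation frequencies). Lower values mean a more robust
#' code.
#'
#' @slot measure `"ms"` or `"mst"`.
#' @slot property named numeric vector of length 20, one value per amino
#'   acid.
#' @slot propertyName short name of the scale (e.g. `"pr"`).
#' @slot weights 2 x 3 numeric matrix of mistranslation weights (rows
#'   transition/transversion, columns base positions); ignored for `"ms"`.
#' @seealso [objectiveSpec()], [evaluateCode()]
#' @export
setClass("ObjectiveSpec",
         representation(measure = "character", property = "numeric",
                        propertyName = "character", weights = "matrix"))

setValidity("ObjectiveSpec", function(object) {
  msg <- character(0)
  if (!object@measure %in% c("ms", "mst"))
    msg <- c(msg, "measure must be 'ms' or 'mst'")
  if (length(object@property) != 20L || !setequal(names(object@property), AA3))
    msg <- c(msg, "property must be named by the 20 amino acids")
  if (anyNA(object@property))
    msg <- c(msg, "property values must not be NA")
  if (object@measure == "mst") {
    w <- object@weights
    if (!is.numeric(w) || !all(dim(w) == c(2L, 3L)))
      msg <- c(msg, "weights must be a 2 x 3 numeric matrix")
    else if (any(w < 0))
      msg <- c(msg, "weights must be nonnegative")
  }
  if (length(msg)) msg else TRUE
})

#' A set of mutually nondominated evaluated codes
#'
#' Rows of `assignments` are restrictive-encoding codes (one amino acid per
#' block, columns named by block label); `objectives` holds the evaluation
#' of each code under `specs` (one column per objective, lower is better).
#' No member dominates any other member and no two members share an
#' assignment.
#'
#' @slot assignments character matrix (members x 20 blocks).
#' @slot objectives numeric matrix (members x objectives).
#' @slot specs list of [ObjectiveSpec-class] objects.
#' @slot provenance data.frame with columns `run` and `generation`.
#' @seealso [nsga2()], [mergeFronts()], [compareToCanonical()]
#' @export
setClass("ParetoFront",
         representation(assignments = "matrix", objectives = "matrix",
                        specs = "list", provenance = "data.frame"))

setValidity("ParetoFront", function(object) {
  msg <- character(0)
  n <- nrow(object@assignments)
  if (nrow(object@objectives) != n)
    msg <- c(msg, "assignments and objectives must have the same rows")
  if (ncol(object@assignments) != 20L)
    msg <- c(msg, "assignments must have 20 columns")
  if (ncol(object@objectives) != length(object@specs))
    msg <- c(msg, "one objective column per spec required")
  if (nrow(object@provenance) != n)
    msg <- c(msg, "provenance must have one row per member")
  if (n > 1L && anyDuplicated(apply(object@assignments, 1L, paste,
                                    collapse = " ")))
    msg <- c(msg, "duplicate assignments are not allowed")
  if (n > 1L && n <= 500L) {
    ranks <- .peelRanks(object@objectives)
    if (any(ranks != 1L))
      msg <- c(msg, "members must be mutually nondominated")
  }
  if (length(msg)) msg else TRUE
})

#' Streaming summary of a random-code sample
#'
#' Accumulated in one pass over `n` uniform random restrictive codes:
#' per-objective mean, sample standard deviation, the number of sampled
#' codes strictly better (lower) than the canonical code, and a fixed-bin
#' histogram. Memory use is independent of `n`.
#'
#' @slot n number of codes sampled.
#' @slot seed the seed that produced the sample.
#' @slot specs list of [ObjectiveSpec-class] objects.
#' @slot mean,sd,countBetter,canonical numeric vectors, one entry per
#'   objective; `canonical` is the canonical code's evaluation.
#' @slot breaks,counts lists (one element per objective) of histogram bin
#'   edges and bin counts.
#' @seealso [sampleSummary()], [pmd()], [empiricalDistribution()]
#' @export
setClass("SampleSummary",
         representation(n = "numeric", seed = "numeric", specs = "list",
                        mean = "numeric", sd = "numeric",
                        countBetter = "numeric", canonical = "numeric",
                        breaks = "list", counts = "list"))

setValidity("SampleSummary", function(object) {
  k <- length(object@specs)
  lens <- c(length(object@mean), length(object@sd),
            length(object@countBetter), length(object@canonical),
            length(object@breaks), length(object@counts))
  if (any(lens != k))
    return("per-objective slots must have one entry per spec")
  if (any(object@countBetter < 0) || any(object@countBetter > object@n))
    return("countBetter must lie in [0, n]")
  if (!all(vapply(object@counts, sum, 0) == object@n))
    return("histogram counts must sum to n")
  TRUE
})
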