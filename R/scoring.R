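# Error measures. The unweighted measure is the mean squared difference of
# an amino-acid property over all 263 single-nucleotide substitution pairs
# between sense codons; the weighted variant multiplies each pair by a
# mistranslation weight depending on base position and transition vs
# transversion, and divides by the total weight. Evaluation is done at
# block level: pairs are aggregated once per weight scheme into per-block-
# pair totals, after which scoring any permutation code costs O(20^2)
# instead of O(263).

#' Specify one objective (error measure x property scale)
#'
#' @param measure `"ms"` (unweighted) or `"mst"` (mistranslation-weighted).
#' @param property a built-in scale name accepted by [aaProperty()] or a
#'   named numeric vector of 20 property values.
#' @param weights 2 x 3 weight matrix for `"mst"`; defaults to
#'   [mistranslationWeights()]. Ignored for `"ms"`.
#' @param name label used for the property in outputs; derived
#'   automatically for built-in scales.
#' @return an [ObjectiveSpec-class] object.
#' @examples
#' objectiveSpec("ms", "pr")
#' objectiveSpec("mst", "hi")
#' @export
objectiveSpec <- function(measure = c("ms", "mst"), property,
                          weights = mistranslationWeights(), name = NULL) {
  measure <- match.arg(measure)
  if (is.character(property) && length(property) == 1L) {
    if (is.null(name)) {
      name <- tolower(property)
      name <- c(polar_requirement = "pr", hydropathy = "hi",
                hydropathy_index = "hi",
                molecular_volume = "mv")[name] %||% name
    }
    property <- aaProperty(property)
  } else {
    if (is.null(name)) name <- "custom"
    if (!is.numeric(property) || length(property) != 20L ||
        !setequal(names(property), AA3))
      stop("property must be a scale name or a named numeric vector ",
           "covering the 20 standard amino acids")
    property <- property[AA3]
  }
  if (measure == "ms") weights <- uniformWeights()
  if (any(weights < 0)) stop("weights must be nonnegative")
  new("ObjectiveSpec", measure = measure, property = property,
      propertyName = name, weights = weights)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Aggregate substitution pairs by block pair
#'
#' Regroups the 263 codon substitution pairs by the (unordered) pair of
#' blocks they connect, summing their weights. Intra-block pairs connect
#' synonymous codons, contribute zero squared property difference, and
#' enter only the normalizer. The result makes code evaluation independent
#' of the codon level: only inter-block totals and the fixed normalizer
#' are needed.
#'
#' @param weights 2 x 3 weight matrix, or `NULL` for unit weights (plain
#'   pair counts).
#' @param blockStructure a [BlockStructure-class]; defaults to
#'   [canonicalBlocks()].
#' @return list with `blockLabels`, integer index vectors `ia`, `ib` and
#'   weight vector `w` for the inter-block pairs with nonzero total,
#'   `intra` (total intra-block weight) and `normalizer` (total weight over
#'   all 263 pairs).
#' @examples
#' bw <- blockPairWeights()
#' bw$normalizer  # 263 pairs
#' @export
blockPairWeights <- function(weights = NULL,
                             blockStructure = canonicalBlocks()) {
  key <- if (is.null(weights)) "unit" else
    paste0("w:", paste(signif(weights, 12), collapse = ","))
  cached <- .pkgCache$bpw[[key]]
  if (!is.null(cached) && identical(cached$blockKey,
                                    names(blocks(blockStructure))))
    return(cached)
  sp <- substitutionPairs(blockStructure)
  labs <- names(blocks(blockStructure))
  w <- if (is.null(weights)) rep(1, nrow(sp)) else {
    if (any(weights < 0)) stop("weights must be nonnegative")
    weights[cbind(match(sp$kind, c("transition", "transversion")),
                  sp$position)]
  }
  bi <- match(sp$block_i, labs)
  bj <- match(sp$block_j, labs)
  lo <- pmin(bi, bj)
  hi <- pmax(bi, bj)
  inter <- lo != hi
  agg <- rowsum(w[inter], paste(lo[inter], hi[inter]))
  idx <- do.call(rbind, lapply(strsplit(rownames(agg), " "), as.integer))
  out <- list(blockLabels = labs, blockKey = labs,
              ia = idx[, 1L], ib = idx[, 2L], w = as.numeric(agg),
              intra = sum(w[!inter]), normalizer = sum(w))
  if (is.null(.pkgCache$bpw)) .pkgCache$bpw <- list()
  .pkgCache$bpw[[key]] <- out
  out
}

.checkProperty <- function(property, code) {
  miss <- setdiff(unname(assignment(code)), names(property))
  if (length(miss))
    stop("property table missing amino acid(s): ",
         paste(miss, collapse = ", "))
}

# property values per block position for a matrix of codes; `perm` is an
# n x 20 character matrix of assignments in block order.
.scoreAssignments <- function(values, bw) {
  d2 <- (values[, bw$ia, drop = FALSE] - values[, bw$ib, drop = FALSE])^2
  as.numeric(d2 %*% bw$w) / bw$normalizer
}

#' Unweighted mean squared property change of a code
#'
#' The mean, over all 263 single-nucleotide substitution pairs between
#' sense codons, of the squared difference of the amino-acid property
#' between the two codons' amino acids under `code`. Lower values mean the
#' code is more robust to point mutations with respect to that property.
#'
#' @param code a [GeneticCode-class] object.
#' @param property a scale name accepted by [aaProperty()] or a named
#'   numeric vector of 20 values.
#' @return a single nonnegative number (squared property units).
#' @examples
#' msError(canonicalCode(), "pr")  # 5.19 to printed precision
#' @export
msError <- function(code, property) {
  spec <- if (is(property, "ObjectiveSpec")) property else
    objectiveSpec("ms", property)
  evaluateCode(code, list(spec))[[1L]]
}

#' Mistranslation-weighted mean squared property change
#'
#' As [msError()], but each substitution pair is weighted by the
#' mistranslation weight for its base position and transition/transversion
#' kind, and the sum is divided by the total weight. With
#' [uniformWeights()] it equals [msError()] exactly.
#'
#' @inheritParams msError
#' @param weights 2 x 3 weight matrix; defaults to
#'   [mistranslationWeights()].
#' @return a single nonnegative number (squared property units).
#' @examples
#' mstError(canonicalCode(), "pr")  # 2.63 to printed precision
#' @export
mstError <- function(code, property, weights = mistranslationWeights()) {
  evaluateCode(code, list(objectiveSpec("mst", property, weights)))[[1L]]
}

#' Evaluate a code under a list of objectives
#'
#' @param code a [GeneticCode-class] object.
#' @param specList list of [ObjectiveSpec-class] objects (see
#'   [objectiveSpec()]); order is preserved in the result.
#' @return named numeric vector, one value per objective, labelled by
#'   [specLabel()].
#' @examples
#' evaluateCode(canonicalCode(),
#'              list(objectiveSpec("ms", "pr"), objectiveSpec("ms", "hi")))
#' @export
evaluateCode <- function(code, specList) {
  stopifnot(is(code, "GeneticCode"))
  if (!length(specList)) stop("at least one objective spec is required")
  if (is(specList, "ObjectiveSpec")) specList <- list(specList)
  for (spec in specList) .checkProperty(spec@property, code)
  vals <- vapply(specList, function(spec) {
    bw <- blockPairWeights(if (spec@measure == "ms") NULL else spec@weights)
    x <- spec@property[assignment(code)[bw$blockLabels]]
    .scoreAssignments(matrix(x, nrow = 1L), bw)
  }, 0)
  names(vals) <- vapply(specList, specLabel, "")
  vals
}

# Vectorized evaluation of many codes. `perms` is an n x 20 integer matrix;
# row r assigns amino acid AA3[perms[r, b]] to block b (blocks in
# canonical order). Returns an n x length(specList) matrix.
.evaluatePermMatrix <- function(perms, specList) {
  labs <- names(blocks(canonicalBlocks()))
  out <- matrix(0, nrow(perms), length(specList))
  for (k in seq_along(specList)) {
    spec <- specList[[k]]
    bw <- blockPairWeights(if (spec@measure == "ms") NULL else spec@weights)
    x <- unname(spec@property[AA3])
    vals <- matrix(x[perms], nrow(perms), 20L)
    out[, k] <- .scoreAssignments(vals, bw)
  }
  colnames(out) <- vapply(specList, specLabel, "")
  out
}

# n uniform random permutations of 1:20 as an n x 20 integer matrix, via
# row-wise ranks of iid uniforms (rank of column j = 1 + #smaller entries).
.randomPermMatrix <- function(n) {
  r <- matrix(runif(n * 20L), n, 20L)
  p <- matrix(1L, n, 20L)
  for (j in 1:20) p[, j] <- p[, j] + as.integer(rowSums(r < r[, j]))
  p
}

.permOfCode <- function(code) {
  labs <- names(blocks(canonicalBlocks()))
  match(assignment(code)[labs], AA3)
}

.codeOfPerm <- function(perm) {
  labs <- names(blocks(canonicalBlocks()))
  new("GeneticCode", assignment = setNames(AA3[perm], labs))
}
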