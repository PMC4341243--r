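# Canonical codon table in RNA alphabet. Stop codons are never part of a
# block; substitutions into or out of a stop are excluded from scoring.

.canonicalMap <- c(
  UUU = "Phe", UUC = "Phe", UUA = "Leu", UUG = "Leu",
  CUU = "Leu", CUC = "Leu", CUA = "Leu", CUG = "Leu",
  AUU = "Ile", AUC = "Ile", AUA = "Ile", AUG = "Met",
  GUU = "Val", GUC = "Val", GUA = "Val", GUG = "Val",
  UCU = "Ser", UCC = "Ser", UCA = "Ser", UCG = "Ser",
  CCU = "Pro", CCC = "Pro", CCA = "Pro", CCG = "Pro",
  ACU = "Thr", ACC = "Thr", ACA = "Thr", ACG = "Thr",
  GCU = "Ala", GCC = "Ala", GCA = "Ala", GCG = "Ala",
  UAU = "Tyr", UAC = "Tyr",
  CAU = "His", CAC = "His", CAA = "Gln", CAG = "Gln",
  AAU = "Asn", AAC = "Asn", AAA = "Lys", AAG = "Lys",
  GAU = "Asp", GAC = "Asp", GAA = "Glu", GAG = "Glu",
  UGU = "Cys", UGC = "Cys", UGG = "Trp",
  CGU = "Arg", CGC = "Arg", CGA = "Arg", CGG = "Arg",
  AGU = "Ser", AGC = "Ser", AGA = "Arg", AGG = "Arg",
  GGU = "Gly", GGC = "Gly", GGA = "Gly", GGG = "Gly")

.stopCodons <- c("UAA", "UAG", "UGA")

.pkgCache <- new.env(parent = emptyenv())

.normalizeCodons <- function(x) {
  x <- toupper(trimws(x))
  chartr("T", "U", x)
}

#' Canonical synonymous-codon block structure
#'
#' Returns the fixed partition of the 61 sense codons into the 20
#' synonymous-codon groups of the canonical genetic code, with the three
#' stop codons (UAA, UAG, UGA) held apart. This partition defines the
#' restrictive encoding: hypothetical codes permute amino acids over these
#' blocks and never touch the blocks or the stops themselves.
#'
#' Blocks are ordered lexicographically by their smallest codon and
#' labelled by their canonical amino acid.
#'
#' @return a [BlockStructure-class] object.
#' @examples
#' bs <- canonicalBlocks()
#' lengths(blocks(bs))
#' stopCodons(bs)
#' @export
canonicalBlocks <- function() {
  if (!is.null(.pkgCache$blocks)) return(.pkgCache$blocks)
  grp <- split(names(.canonicalMap), .canonicalMap)
  grp <- lapply(grp, function(cs) sort(cs, method = "radix"))
  first <- vapply(grp, `[`, "", 1L)
  grp <- grp[order(first, method = "radix")]
  bs <- new("BlockStructure", blocks = grp, stops = .stopCodons)
  .pkgCache$blocks <- bs
  bs
}

#' The canonical genetic code
#'
#' The identity assignment: every block keeps its canonical amino acid.
#' This is the reference solution against which hypothetical codes are
#' compared throughout.
#'
#' @return a [GeneticCode-class] object.
#' @examples
#' translateCodons(canonicalCode(), c("AUG", "UGG"))
#' @export
canonicalCode <- function() {
  labs <- names(blocks(canonicalBlocks()))
  new("GeneticCode", assignment = setNames(labs, labs))
}

#' Construct a genetic code from a block assignment
#'
#' @param assignment character vector of 20 three-letter amino-acid codes,
#'   either named by block labels or given in block order.
#' @return a [GeneticCode-class] object.
#' @export
geneticCode <- function(assignment) {
  labs <- names(blocks(canonicalBlocks()))
  if (is.null(names(assignment))) {
    if (length(assignment) != 20L)
      stop("assignment must have length 20")
    names(assignment) <- labs
  }
  new("GeneticCode", assignment = assignment[labs])
}

#' Draw a uniformly random restrictive code
#'
#' Permutes the 20 amino acids uniformly at random over the 20 canonical
#' blocks, using R's current random number generator state; call
#' `set.seed()` first for reproducibility.
#'
#' @return a [GeneticCode-class] object.
#' @examples
#' set.seed(1)
#' randomCode()
#' @export
randomCode <- function() {
  labs <- names(blocks(canonicalBlocks()))
  new("GeneticCode", assignment = setNames(sample(labs), labs))
}

#' Translate codons under a genetic code
#'
#' @param code a [GeneticCode-class] object.
#' @param codons character vector of codons (RNA or DNA alphabet).
#' @return character vector of three-letter amino-acid codes, `"Stop"` for
#'   the three stop codons.
#' @export
translateCodons <- function(code, codons) {
  stopifnot(is(code, "GeneticCode"))
  codons <- .normalizeCodons(codons)
  bad <- codons[!codons %in% c(names(.canonicalMap), .stopCodons)]
  if (length(bad))
    stop("not codons: ", paste(unique(bad), collapse = ", "))
  out <- rep("Stop", length(codons))
  sense <- codons %in% names(.canonicalMap)
  out[sense] <- unname(assignment(code)[.canonicalMap[codons[sense]]])
  out
}

#' Enumerate single-nucleotide substitution pairs between sense codons
#'
#' Lists every unordered pair of sense codons that differ at exactly one
#' base position, annotated with the position (1-3), the substitution kind
#' (transition for A<->G and C<->U, transversion otherwise), and the block
#' labels of both codons. Pairs involving a stop codon are excluded, since
#' stops are fixed and carry no amino-acid property. There are exactly 263
#' such pairs; the order is deterministic (lexicographic by codon pair).
#'
#' @param blockStructure a [BlockStructure-class] object; defaults to
#'   [canonicalBlocks()].
#' @return a data.frame with columns `codon_i`, `codon_j`, `position`,
#'   `kind`, `block_i`, `block_j`.
#' @examples
#' sp <- substitutionPairs()
#' nrow(sp)           # 263
#' table(sp$kind)
#' @export
substitutionPairs <- function(blockStructure = canonicalBlocks()) {
  stopifnot(is(blockStructure, "BlockStructure"))
  bl <- blocks(blockStructure)
  codon2block <- setNames(rep(names(bl), lengths(bl)),
                          unlist(bl, use.names = FALSE))
  sense <- sort(names(codon2block), method = "radix")
  stops <- stopCodons(blockStructure)
  transitions <- c("AG", "CU")
  res <- vector("list", 600L)
  nres <- 0L
  for (codon in sense) {
    b <- strsplit(codon, "")[[1L]]
    for (pos in 1:3) {
      for (nb in setdiff(RNA_BASES, b[pos])) {
        other <- b
        other[pos] <- nb
        other <- paste(other, collapse = "")
        if (other <= codon || other %in% stops) next
        pair_kind <- paste(sort(c(b[pos], nb)), collapse = "")
        nres <- nres + 1L
        res[[nres]] <- data.frame(
          codon_i = codon, codon_j = other, position = pos,
          kind = if (pair_kind %in% transitions) "transition"
                 else "transversion",
          block_i = unname(codon2block[codon]),
          block_j = unname(codon2block[other]),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, res[seq_len(nres)])
  out[order(out$codon_i, out$codon_j, method = "radix"), , drop = FALSE]
}

#' Read a genetic code from a codon table file
#'
#' Parses a 64-row tab-separated table with header columns `codon` and
#' `amino_acid` (three-letter code, or `Stop`). DNA input (`T`) is
#' normalized to RNA (`U`). The table is validated against the restrictive
#' encoding: the three canonical stop codons must be the only stops, and
#' every synonymous block of the canonical code must map to a single amino
#' acid, each amino acid used by exactly one block.
#'
#' @param file path to the TSV file, or a connection.
#' @return a [GeneticCode-class] object.
#' @seealso [writeCodeTable()]
#' @export
readCodeTable <- function(file) {
  tab <- read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("codon", "amino_acid") %in% names(tab)))
    stop("code table must have columns 'codon' and 'amino_acid'")
  tab$codon <- .normalizeCodons(tab$codon)
  if (anyDuplicated(tab$codon))
    stop("duplicate codons in code table: ",
         paste(unique(tab$codon[duplicated(tab$codon)]), collapse = ", "))
  if (!setequal(tab$codon, c(names(.canonicalMap), .stopCodons)) ||
      nrow(tab) != 64L)
    stop("code table must list all 64 codons exactly once")
  aa <- setNames(trimws(tab$amino_acid), tab$codon)
  if (!all(aa[.stopCodons] == "Stop") || sum(aa == "Stop") != 3L)
    stop("encoding violation: stop codons are fixed to UAA, UAG, UGA")
  bl <- blocks(canonicalBlocks())
  assign <- character(length(bl))
  names(assign) <- names(bl)
  for (lab in names(bl)) {
    vals <- unique(unname(aa[bl[[lab]]]))
    if (length(vals) != 1L)
      stop("encoding violation: block ", lab,
           " maps to several amino acids (", paste(vals, collapse = ", "),
           "); the restrictive encoding requires block-constant assignment")
    assign[lab] <- vals
  }
  unknown <- setdiff(assign, AA3)
  if (length(unknown))
    stop("unknown amino acid(s): ", paste(unknown, collapse = ", "))
  new("GeneticCode", assignment = assign)
}

#' Write a genetic code as a 64-row codon table
#'
#' Inverse of [readCodeTable()]: writes one row per codon with its assigned
#' amino acid (`Stop` for the three stop codons), tab-separated with a
#' header. Round-trips exactly.
#'
#' @param code a [GeneticCode-class] object.
#' @param file path or connection; `""` writes to stdout.
#' @return invisibly, the data.frame that was written.
#' @export
writeCodeTable <- function(code, file = "") {
  stopifnot(is(code, "GeneticCode"))
  codons <- sort(c(names(.canonicalMap), .stopCodons), method = "radix")
  df <- data.frame(codon = codons,
                   amino_acid = translateCodons(code, codons),
                   stringsAsFactors = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
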