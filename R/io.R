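# Serialization: fronts (TSV + JSON summary), sample summaries (JSON),
# comparison tables (TSV), gray-scale code-organization tables (TSV).
# Every file written here can be re-read by the package's own readers.

#' Write a Pareto front as TSV (plus a JSON run summary)
#'
#' One row per member: the 20 block-wise amino-acid assignments (columns
#' `block_<label>`), the objective values, run id and generation. When
#' `jsonFile` is given, a JSON summary (objective labels, seed if
#' recorded, per-run front sizes) is written alongside.
#'
#' @param front a [ParetoFront-class] object.
#' @param file TSV output path.
#' @param jsonFile optional JSON summary path.
#' @return invisibly, the data.frame written.
#' @export
writeFront <- function(front, file, jsonFile = NULL) {
  stopifnot(is(front, "ParetoFront"))
  labs <- vapply(front@specs, specLabel, "")
  df <- data.frame(front@assignments, check.names = FALSE)
  names(df) <- paste0("block_", colnames(front@assignments))
  obj <- data.frame(front@objectives, check.names = FALSE)
  names(obj) <- labs
  df <- cbind(df, obj, front@provenance)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(jsonFile)) {
    runFronts <- attr(front, "runFronts")
    info <- list(objectives = labs,
                 members = nrow(front@assignments),
                 runs = sort(unique(front@provenance$run)))
    if (!is.null(runFronts))
      info$run_front_sizes <- vapply(runFronts, length, 0L)
    seeds <- if (!is.null(runFronts))
      vapply(runFronts, function(f) attr(f, "seed") %||% NA_integer_, 0L)
    if (!is.null(seeds)) info$run_seeds <- seeds
    jsonlite::write_json(info, jsonFile, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(df)
}

#' Read a Pareto front written by [writeFront()]
#'
#' @param file TSV path.
#' @param specList the objectives the front was evaluated under; when
#'   omitted, objective columns are matched by their `measure:property`
#'   labels against built-in scales.
#' @return a [ParetoFront-class] object.
#' @export
readFront <- function(file, specList = NULL) {
  df <- read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  bcols <- grep("^block_", names(df), value = TRUE)
  if (length(bcols) != 20L) stop("front file must have 20 block_ columns")
  ocols <- setdiff(names(df), c(bcols, "run", "generation"))
  if (is.null(specList))
    specList <- lapply(ocols, function(lab) {
      parts <- strsplit(lab, ":", fixed = TRUE)[[1L]]
      if (length(parts) != 2L)
        stop("cannot reconstruct objective '", lab,
             "'; pass specList explicitly")
      objectiveSpec(parts[1L], parts[2L])
    })
  assignments <- as.matrix(df[bcols])
  colnames(assignments) <- sub("^block_", "", bcols)
  rownames(assignments) <- NULL
  obj <- as.matrix(df[ocols])
  rownames(obj) <- NULL
  prov <- data.frame(
    run = if ("run" %in% names(df)) df$run else rep(NA_integer_, nrow(df)),
    generation = if ("generation" %in% names(df)) df$generation
                 else rep(NA_integer_, nrow(df)))
  new("ParetoFront", assignments = assignments, objectives = obj,
      specs = specList, provenance = prov)
}

#' Write a sample summary as JSON
#'
#' @param summary a [SampleSummary-class] object.
#' @param file JSON output path.
#' @return invisibly, the list serialized.
#' @export
writeSampleSummary <- function(summary, file) {
  stopifnot(is(summary, "SampleSummary"))
  labs <- vapply(summary@specs, specLabel, "")
  out <- list(n = summary@n, seed = summary@seed, objectives = labs,
              mean = summary@mean, sd = summary@sd,
              count_better = summary@countBetter,
              canonical = summary@canonical,
              histogram = lapply(seq_along(labs), function(j)
                list(breaks = summary@breaks[[j]],
                     counts = summary@counts[[j]])))
  jsonlite::write_json(out, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(out)
}

#' Read a sample summary written by [writeSampleSummary()]
#'
#' @param file JSON path.
#' @param specList optional list of objective specs; reconstructed from
#'   the stored labels when omitted.
#' @return a [SampleSummary-class] object.
#' @export
readSampleSummary <- function(file, specList = NULL) {
  x <- jsonlite::read_json(file, simplifyVector = FALSE)
  num <- function(v) vapply(v, as.numeric, 0)
  if (is.null(specList))
    specList <- lapply(x$objectives, function(lab) {
      parts <- strsplit(lab, ":", fixed = TRUE)[[1L]]
      objectiveSpec(parts[[1L]], parts[[2L]])
    })
  new("SampleSummary", n = as.numeric(x$n), seed = as.numeric(x$seed),
      specs = specList, mean = num(x$mean), sd = num(x$sd),
      countBetter = num(x$count_better), canonical = num(x$canonical),
      breaks = lapply(x$histogram, function(h) num(h$breaks)),
      counts = lapply(x$histogram, function(h) num(h$counts)))
}

#' Gray-scale code-organization table
#'
#' Rows are the 20 amino acids sorted ascending by a property (ties broken
#' alphabetically); columns give the property value, the canonical codon
#' group of the row's amino acid, and, for each supplied code, the codon
#' group that code assigns to the amino acid. Rendering the property
#' gradient as actual gray shades is a downstream concern; the table holds
#' the full content of such a figure.
#'
#' @param codes a list of [GeneticCode-class] objects, a
#'   [ParetoFront-class], or a single code.
#' @param property scale name or named numeric vector (see
#'   [objectiveSpec()]).
#' @param codeNames column names for the codes.
#' @return data.frame with 20 rows.
#' @export
grayscaleTable <- function(codes, property, codeNames = NULL) {
  if (is(codes, "ParetoFront"))
    codes <- lapply(seq_len(length(codes)), frontCode, front = codes)
  if (is(codes, "GeneticCode")) codes <- list(codes)
  stopifnot(length(codes) >= 1L,
            all(vapply(codes, is, TRUE, "GeneticCode")))
  if (is.character(property) && length(property) == 1L)
    property <- aaProperty(property)
  if (is.null(codeNames)) codeNames <- paste0("HC", seq_along(codes))
  bl <- blocks(canonicalBlocks())
  groups <- vapply(bl, paste, "", collapse = ",")
  aas <- sort(AA3)
  ord <- order(property[aas], aas)
  aas <- aas[ord]
  out <- data.frame(amino_acid = aas, property = unname(property[aas]),
                    canonical_codons = unname(groups[aas]),
                    stringsAsFactors = FALSE)
  for (i in seq_along(codes)) {
    a <- assignment(codes[[i]])
    blockOf <- setNames(names(a), a)      # amino acid -> block label
    out[[codeNames[i]]] <- unname(groups[blockOf[aas]])
  }
  out
}

#' Write a gray-scale table as TSV
#'
#' @param table data.frame from [grayscaleTable()].
#' @param file output path.
#' @export
writeGrayscale <- function(table, file) {
  write.table(table, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(table)
}

#' Write a comparison table as TSV
#'
#' @param comparison data.frame from [compareToCanonical()].
#' @param file output path.
#' @export
writeComparison <- function(comparison, file) {
  write.table(comparison, file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(comparison)
}
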