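# Amino-acid property scales. Polar requirement (Woese), hydropathy index
# (Kyte-Doolittle) and molecular volume (Grantham; Gly = 3 on that scale).

.aaProperties <- data.frame(
  amino_acid = c("Ala", "Arg", "Asp", "Asn", "Cys", "Glu", "Gln", "Gly",
                 "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser",
                 "Thr", "Trp", "Tyr", "Val"),
  polar_requirement = c(7, 9.1, 13, 10, 4.8, 12.5, 8.6, 7.9, 8.4, 4.9,
                        4.9, 10.1, 5.3, 5, 6.6, 7.5, 6.6, 5.2, 5.4, 5.6),
  hydropathy = c(1.8, -4.5, -3.5, -3.5, 2.5, -3.5, -3.5, -0.4, -3.2, 4.5,
                 3.8, -3.9, 1.9, 2.8, -1.6, -0.8, -0.7, -0.9, -1.3, 4.2),
  molecular_volume = c(31, 124, 54, 56, 55, 83, 85, 3, 96, 111, 111, 119,
                       105, 132, 32.5, 32, 61, 170, 136, 84),
  stringsAsFactors = FALSE)

.propertyAliases <- c(pr = "polar_requirement",
                      polar_requirement = "polar_requirement",
                      hi = "hydropathy", hydropathy = "hydropathy",
                      hydropathy_index = "hydropathy",
                      mv = "molecular_volume",
                      molecular_volume = "molecular_volume")

#' Built-in amino-acid property scales
#'
#' The three scales classically used in genetic-code optimality studies:
#' polar requirement, hydropathy index, and molecular volume.
#'
#' @return data.frame with columns `amino_acid`, `polar_requirement`,
#'   `hydropathy`, `molecular_volume`.
#' @export
aaProperties <- function() .aaProperties

#' One built-in property scale as a named vector
#'
#' @param name `"polar_requirement"` (alias `"pr"`), `"hydropathy"`
#'   (`"hi"`), or `"molecular_volume"` (`"mv"`).
#' @return named numeric vector of length 20.
#' @examples
#' aaProperty("pr")[["Cys"]]  # the least polar-requiring amino acid
#' @export
aaProperty <- function(name) {
  name <- tolower(name)
  if (!name %in% names(.propertyAliases))
    stop("unknown property '", name, "'; use pr, hi or mv, ",
         "or supply a custom table via readPropertyTable()")
  col <- .propertyAliases[[name]]
  setNames(.aaProperties[[col]], .aaProperties$amino_acid)
}

#' Read a custom amino-acid property scale
#'
#' Expects a CSV with columns `amino_acid` (three-letter codes) and
#' `value`, exactly one row per standard amino acid.
#'
#' @param file path to the CSV file.
#' @return named numeric vector of length 20.
#' @export
readPropertyTable <- function(file) {
  tab <- read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("amino_acid", "value") %in% names(tab)))
    stop("property table must have columns 'amino_acid' and 'value'")
  tab$amino_acid <- trimws(tab$amino_acid)
  if (!setequal(tab$amino_acid, AA3) || nrow(tab) != 20L)
    stop("property table must have exactly one row per standard amino acid")
  v <- setNames(as.numeric(tab$value), tab$amino_acid)
  if (anyNA(v)) stop("property values must be numeric and non-missing")
  v
}

#' Mistranslation weight matrix
#'
#' The default weights model how mistranslation frequency depends on the
#' base position within the codon and on whether the change is a transition
#' or a transversion: second-base changes are rare (and mostly
#' transitional), first-base changes less frequent than third-base ones.
#' Rows are `transition`/`transversion`, columns base positions 1-3.
#'
#' @return 2 x 3 numeric matrix.
#' @seealso [uniformWeights()], [objectiveSpec()]
#' @export
mistranslationWeights <- function() {
  matrix(c(1, 0.5, 1,
           0.5, 0.1, 1),
         nrow = 2L, byrow = TRUE,
         dimnames = list(c("transition", "transversion"),
                         c("base1", "base2", "base3")))
}

#' Uniform substitution weights
#'
#' All-ones weight matrix; with it the weighted error measure degenerates
#' to the unweighted one.
#'
#' @return 2 x 3 numeric matrix of ones.
#' @export
uniformWeights <- function() {
  w <- mistranslationWeights()
  w[] <- 1
  w
}
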