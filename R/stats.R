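# Statistical comparison of the canonical code with the code space:
# streaming Monte-Carlo sampling of uniform random restrictive codes,
# empirical null distributions, counts of codes better than canonical,
# and the percentage-of-minimization-distance (pmd) statistic.

#' Streaming summary of uniform random restrictive codes
#'
#' Draws `n` codes uniformly from the 20! permutations of amino acids over
#' the canonical blocks, evaluates every objective in `specList`, and
#' accumulates per-objective mean, sample standard deviation, the count of
#' codes strictly better (lower) than the canonical code, and a fixed-bin
#' histogram — all in one pass over chunks, so memory use is independent
#' of `n`.
#'
#' Histogram bin edges are fixed from the first chunk (its range widened
#' by 25%); later values outside that range are counted in the extreme
#' bins, so counts always sum to `n`.
#'
#' @param n number of random codes (>= 1).
#' @param specList list of [ObjectiveSpec-class] objects.
#' @param seed integer seed; the sample is fully reproducible from it.
#' @param chunkSize codes evaluated per chunk.
#' @param bins number of histogram bins.
#' @return a [SampleSummary-class] object.
#' @examples
#' s <- sampleSummary(2000, list(objectiveSpec("ms", "pr")), seed = 1)
#' s
#' @export
sampleSummary <- function(n, specList, seed, chunkSize = 50000L,
                          bins = 50L) {
  stopifnot(n >= 1L, length(specList) >= 1L, bins >= 1L)
  set.seed(seed)
  k <- length(specList)
  canon <- unname(evaluateCode(canonicalCode(), specList))
  tot <- numeric(k)
  totSq <- numeric(k)
  cntBetter <- numeric(k)
  breaks <- vector("list", k)
  counts <- vector("list", k)
  left <- n
  while (left > 0L) {
    m <- min(left, chunkSize)
    obj <- .evaluatePermMatrix(.randomPermMatrix(m), specList)
    for (j in seq_len(k)) {
      v <- obj[, j]
      tot[j] <- tot[j] + sum(v)
      totSq[j] <- totSq[j] + sum(v * v)
      cntBetter[j] <- cntBetter[j] + sum(v < canon[j])
      if (is.null(breaks[[j]])) {
        r <- range(v)
        pad <- 0.25 * (r[2L] - r[1L])
        if (pad == 0) pad <- max(abs(r[1L]), 1) * 0.01
        breaks[[j]] <- seq(r[1L] - pad, r[2L] + pad, length.out = bins + 1L)
        counts[[j]] <- numeric(bins)
      }
      b <- breaks[[j]]
      bin <- pmin(pmax(findInterval(v, b, all.inside = TRUE), 1L),
                  length(b) - 1L)
      counts[[j]] <- counts[[j]] + tabulate(bin, nbins = length(b) - 1L)
    }
    left <- left - m
  }
  mu <- tot / n
  s2 <- if (n > 1L) pmax(totSq - n * mu^2, 0) / (n - 1L) else rep(NA_real_, k)
  new("SampleSummary", n = as.numeric(n), seed = as.numeric(seed),
      specs = specList, mean = mu, sd = sqrt(s2),
      countBetter = cntBetter, canonical = canon,
      breaks = breaks, counts = counts)
}

#' Percentage of minimization distance (pmd)
#'
#' `100 * |(fMean - fCanonical) / (fMean - fCode)|`: how close a code's
#' objective value is to the canonical code's, relative to the estimated
#' mean over random codes. 100 means exactly as good as the canonical
#' code; values approach 100 from below as the code improves towards the
#' canonical value (for codes better than canonical the ratio exceeds
#' 100, which is why it is conventionally reported only for dominating
#' codes).
#'
#' @param fCode objective value of the hypothetical code.
#' @param fCanonical objective value of the canonical code.
#' @param fMean estimated mean objective value over random codes.
#' @return percentage; `NA` with a warning when `fMean == fCode` (the
#'   ratio is undefined).
#' @examples
#' pmd(5.19, 5.19, 9.41)   # 100
#' @export
pmd <- function(fCode, fCanonical, fMean) {
  if (isTRUE(all.equal(fMean, fCode, tolerance = 0))) {
    warning("pmd undefined: mean evaluation equals the code's evaluation")
    return(NA_real_)
  }
  100 * abs((fMean - fCanonical) / (fMean - fCode))
}

#' Codes better than canonical, per objective
#'
#' Tabulates, for every objective of a random-code sample, how many
#' sampled codes evaluated strictly below the canonical code.
#'
#' @param summary a [SampleSummary-class] object.
#' @return data.frame with columns `objective`, `n`, `count_better`,
#'   `frequency`.
#' @export
countBetterReport <- function(summary) {
  stopifnot(is(summary, "SampleSummary"))
  labs <- vapply(summary@specs, specLabel, "")
  data.frame(objective = labs, n = summary@n,
             count_better = summary@countBetter,
             frequency = summary@countBetter / summary@n,
             stringsAsFactors = FALSE)
}

#' Compare front members with the canonical code
#'
#' For every member of a Pareto front: whether it dominates the canonical
#' code, its pmd per objective (reported only for dominating members, the
#' usual convention since pmd exceeds 100 on objectives where the code
#' beats canonical), and its Euclidean distance to the canonical code in
#' normalized objective space.
#'
#' @param front a [ParetoFront-class] object.
#' @param summary a [SampleSummary-class] computed under the same
#'   objectives (supplies the random-code means for pmd and the default
#'   normalization).
#' @param normalization `"mean"` (divide each objective by its
#'   random-sample mean), `"zscore"`, or `"minmax"` (range of the front
#'   plus the canonical point).
#' @return data.frame with the objective values, `distance`,
#'   `dominates_canonical`, and one `pmd_*` column per objective.
#' @export
compareToCanonical <- function(front, summary,
                               normalization = c("mean", "zscore",
                                                 "minmax")) {
  stopifnot(is(front, "ParetoFront"), is(summary, "SampleSummary"))
  normalization <- match.arg(normalization)
  labsF <- vapply(front@specs, specLabel, "")
  labsS <- vapply(summary@specs, specLabel, "")
  if (!identical(labsF, labsS))
    stop("front and summary were evaluated under different objectives")
  obj <- front@objectives
  canon <- summary@canonical
  scale <- switch(normalization,
                  mean = summary@mean,
                  zscore = summary@sd,
                  minmax = apply(rbind(obj, canon), 2L, function(x)
                    max(diff(range(x)), .Machine$double.eps)))
  center <- if (normalization == "zscore") summary@mean else 0
  zObj <- sweep(sweep(obj, 2L, center), 2L, scale, "/")
  zCan <- (canon - center) / scale
  dist <- sqrt(rowSums(sweep(zObj, 2L, zCan)^2))
  dom <- apply(obj, 1L, dominates, b = canon)
  pmds <- sapply(seq_along(canon), function(j)
    ifelse(dom, 100 * abs((summary@mean[j] - canon[j]) /
                            (summary@mean[j] - obj[, j])), NA_real_))
  pmds <- matrix(pmds, nrow = nrow(obj))
  colnames(pmds) <- paste0("pmd_", sub(":", "_", labsF))
  out <- data.frame(code = seq_len(nrow(obj)), obj,
                    distance = dist, dominates_canonical = dom,
                    check.names = FALSE)
  cbind(out, pmds)
}

#' Empirical distribution of one objective over random codes
#'
#' The histogram accumulated by [sampleSummary()] for one objective, with
#' the canonical value and optional extra code values attached as marker
#' attributes. Suitable for export as CSV.
#'
#' @param summary a [SampleSummary-class] object.
#' @param specIndex which objective.
#' @param codeValues optional named numeric vector of additional marker
#'   values (e.g. best GA codes).
#' @return data.frame with columns `lower`, `upper`, `count`; attributes
#'   `canonical` and `markers`.
#' @export
empiricalDistribution <- function(summary, specIndex = 1L,
                                  codeValues = NULL) {
  stopifnot(is(summary, "SampleSummary"),
            specIndex >= 1L, specIndex <= length(summary@specs))
  b <- summary@breaks[[specIndex]]
  out <- data.frame(lower = b[-length(b)], upper = b[-1L],
                    count = summary@counts[[specIndex]])
  attr(out, "canonical") <- summary@canonical[specIndex]
  attr(out, "markers") <- codeValues
  attr(out, "objective") <- specLabel(summary@specs[[specIndex]])
  out
}
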