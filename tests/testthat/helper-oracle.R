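# Independent brute-force oracle. The canonical codon table comes from
# Biostrings::GENETIC_CODE, pair enumeration is done from scratch at codon
# level, and scoring loops directly over codon pairs -- none of the
# package's block-level machinery is reused here.

ONE2THREE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
               Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
               L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
               S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")

# codon (RNA) -> canonical three-letter amino acid, "Stop" for stops
oracleCanonicalMap <- local({
  map <- NULL
  function() {
    if (!is.null(map)) return(map)
    gc1 <- Biostrings::GENETIC_CODE
    codons <- chartr("T", "U", names(gc1))
    aa <- ifelse(gc1 == "*", "Stop", ONE2THREE[gc1])
    map <<- stats::setNames(aa, codons)
    map
  }
})

# codon -> amino acid under a GeneticCode (permutation of canonical labels)
oracleCodeMap <- function(code) {
  can <- oracleCanonicalMap()
  a <- gcadapt::assignment(code)
  ifelse(can == "Stop", "Stop", unname(a[can]))
}

# all unordered single-base substitution pairs between sense codons
oraclePairs <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    can <- oracleCanonicalMap()
    sense <- names(can)[can != "Stop"]
    res <- list()
    for (i in seq_along(sense)) {
      a <- strsplit(sense[i], "")[[1L]]
      for (j in seq_along(sense)) {
        if (j <= i) next
        b <- strsplit(sense[j], "")[[1L]]
        d <- which(a != b)
        if (length(d) != 1L) next
        ts <- paste(sort(c(a[d], b[d])), collapse = "")
        res[[length(res) + 1L]] <- list(
          i = sense[i], j = sense[j], pos = d,
          kind = if (ts %in% c("AG", "CU")) "transition" else "transversion")
      }
    }
    cache <<- res
    res
  }
})

# direct codon-level mean squared property change
oracleScore <- function(code, property, weights = NULL) {
  cmap <- oracleCodeMap(code)
  num <- 0
  den <- 0
  for (p in oraclePairs()) {
    w <- if (is.null(weights)) 1 else
      weights[p$kind, paste0("base", p$pos)]
    num <- num + w * (property[[cmap[[p$i]]]] - property[[cmap[[p$j]]]])^2
    den <- den + w
  }
  num / den
}

# naive layer peeling: repeatedly remove the nondominated set
oraclePeel <- function(obj) {
  n <- nrow(obj)
  rank <- integer(n)
  alive <- rep(TRUE, n)
  layer <- 0L
  nondom <- function(i, idx) {
    for (j in idx)
      if (j != i && all(obj[j, ] <= obj[i, ]) && any(obj[j, ] < obj[i, ]))
        return(FALSE)
    TRUE
  }
  while (any(alive)) {
    layer <- layer + 1L
    idx <- which(alive)
    front <- idx[vapply(idx, nondom, TRUE, idx = idx)]
    rank[front] <- layer
    alive[front] <- FALSE
  }
  rank
}

# direct two-objective crowding distance (independent of the package's
# generic k-objective implementation)
oracleCrowding2 <- function(obj) {
  stopifnot(ncol(obj) == 2L)
  n <- nrow(obj)
  if (n <= 2L) return(rep(Inf, n))
  d <- numeric(n)
  for (k in 1:2) {
    ord <- order(obj[, k])
    d[ord[1L]] <- Inf
    d[ord[n]] <- Inf
    rng <- obj[ord[n], k] - obj[ord[1L], k]
    for (m in 2:(n - 1L)) {
      if (rng > 0)
        d[ord[m]] <- d[ord[m]] +
          (obj[ord[m + 1L], k] - obj[ord[m - 1L], k]) / rng
    }
  }
  d
}

canonicalSixSpecs <- function() {
  list(objectiveSpec("ms", "pr"), objectiveSpec("ms", "hi"),
       objectiveSpec("ms", "mv"), objectiveSpec("mst", "pr"),
       objectiveSpec("mst", "hi"), objectiveSpec("mst", "mv"))
}
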