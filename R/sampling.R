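# Occurrence-sample generation: idealised detection-filtered sampling of
# the niche, plus error/bias contamination with replacement semantics.

# Constructor; keeps the m x n matrix together with per-row provenance.
.occurrenceSample <- function(X, provenance, seed = NULL) {
  X <- .asEnvMatrix(X)
  m <- nrow(X)
  provenance <- as.character(provenance)
  if (length(provenance) != m ||
      !all(provenance %in% c("idealised", "error", "bias"))) {
    .nicheStop("shapeError",
               "provenance must be one of idealised/error/bias per row")
  }
  structure(list(X = X, provenance = provenance, m = m, seed = seed),
            class = "occurrenceSample")
}

#' @export
print.occurrenceSample <- function(x, ...) {
  tab <- table(factor(x$provenance, levels = c("idealised", "error", "bias")))
  cat("Occurrence sample: m =", x$m, "points\n")
  cat("  provenance:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Idealised occurrence sampling of the fundamental niche
#'
#' Generates an idealised sample of `m` occurrences by rejection: candidate
#' environments are drawn from the multivariate normal `N(mu, sigma)` that
#' defines the niche, and each candidate is kept with its
#' presence-and-detection probability `P_d(lambda_F(x))`. The detection
#' filter up-weights high-growth-rate environments, so accepted points
#' concentrate towards the centre of the niche.
#'
#' @param params a [nicheParams()].
#' @param m number of occurrences required (>= 1).
#' @param seed integer seed, or `NULL` for the ambient RNG stream.
#' @param max_attempts iteration cap on candidate draws.
#' @return an `occurrenceSample` with all rows labelled `"idealised"`.
#' @export
sampleIdealised <- function(params, m, seed = NULL, max_attempts = 1e6) {
  stopifnot(inherits(params, "nicheParams"), m >= 1)
  m <- as.integer(m)
  .withSeed(seed, {
    acc <- matrix(numeric(0), 0, params$n)
    attempts <- 0
    while (nrow(acc) < m) {
      if (attempts >= max_attempts) {
        .nicheStop("samplingInfeasibleError",
                   "detection filter rejected essentially all candidates")
      }
      batch <- min(max(2L * (m - nrow(acc)), 50L), max_attempts - attempts)
      cand <- .rmvnorm(batch, as.numeric(params$mu), params$sigma)
      if (is.null(dim(cand))) cand <- matrix(cand, nrow = 1L)
      pd <- detectionProbability(nicheGrowthRate(params, cand))
      acc <- rbind(acc, cand[stats::runif(batch) < pd, , drop = FALSE])
      attempts <- attempts + batch
    }
    X <- acc[seq_len(m), , drop = FALSE]
    colnames(X) <- names(params$mu)
    .occurrenceSample(X, rep("idealised", m), seed = seed)
  })
}

#' Contaminate an occurrence sample with errors and/or bias
#'
#' Replaces a fraction of the sample's rows with contaminated records while
#' keeping the total size `m` fixed: `round(error_frac * m)` rows become
#' uniform draws from the sampling space (errors — random locations within
#' the region), and `round(bias_frac * m)` further rows become
#' detection-weighted draws (bias — records concentrated where the region's
#' climate overlaps the niche). Replaced row positions are chosen uniformly
#' without replacement; remaining rows are untouched. Counts round halves
#' up, so the canonical `m = 100` contamination grids are exact.
#'
#' @param sample an `occurrenceSample` (typically from [sampleIdealised()]).
#' @param space a [samplingSpace()].
#' @param params a [nicheParams()] (needed for the detection weighting).
#' @param error_frac,bias_frac fractions in `[0, 1]` with
#'   `error_frac + bias_frac <= 1`.
#' @param seed integer seed, or `NULL` for the ambient RNG stream.
#' @return an `occurrenceSample` of the same size with updated rows and
#'   provenance labels.
#' @export
contaminate <- function(sample, space, params, error_frac = 0, bias_frac = 0,
                        seed = NULL) {
  stopifnot(inherits(sample, "occurrenceSample"))
  if (!is.numeric(error_frac) || !is.numeric(bias_frac) ||
      error_frac < 0 || error_frac > 1 || bias_frac < 0 || bias_frac > 1 ||
      error_frac + bias_frac > 1 + 1e-12) {
    .nicheStop("domainError",
               "error_frac and bias_frac must lie in [0, 1] and sum to at most 1")
  }
  m <- sample$m
  ne <- .roundHalfUp(error_frac * m)
  nb <- min(.roundHalfUp(bias_frac * m), m - ne)
  if (ne + nb == 0) return(sample)
  stopifnot(inherits(space, "samplingSpace"), inherits(params, "nicheParams"))
  .withSeed(seed, {
    sel <- sample.int(m, ne + nb)
    X <- sample$X
    prov <- sample$provenance
    if (ne > 0) {
      pos <- sel[seq_len(ne)]
      X[pos, ] <- drawUniform(space, ne)
      prov[pos] <- "error"
    }
    if (nb > 0) {
      pos <- sel[ne + seq_len(nb)]
      X[pos, ] <- drawBiased(space, params, nb)
      prov[pos] <- "bias"
    }
    .occurrenceSample(X, prov, seed = seed)
  })
}

#' Read/write occurrence samples as CSV
#'
#' CSV columns are the environment coordinates (temperature, rainfall)
#' followed by `provenance`.
#'
#' @param sample an `occurrenceSample`.
#' @param path CSV file path.
#' @return `readOccurrenceSample` returns an `occurrenceSample`;
#'   `writeOccurrenceSample` returns `path` invisibly.
#' @export
writeOccurrenceSample <- function(sample, path) {
  stopifnot(inherits(sample, "occurrenceSample"))
  df <- as.data.frame(sample$X)
  df$provenance <- sample$provenance
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeOccurrenceSample
#' @export
readOccurrenceSample <- function(path) {
  df <- utils::read.csv(path, header = TRUE)
  if (!"provenance" %in% names(df)) {
    .nicheStop("shapeError", "occurrence CSV must carry a provenance column")
  }
  prov <- df$provenance
  X <- as.matrix(df[setdiff(names(df), "provenance")])
  .occurrenceSample(X, prov)
}
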