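#' Configuration for the virtual-ecology experiments
#'
#' Describes one of the three replicated experiments: `"size"` varies the
#' occurrence sample size `m`, `"error"` varies the fraction of the sample
#' replaced by uniform climate-space draws at fixed `m_fixed`, and `"bias"`
#' varies the fraction replaced by detection-weighted draws. Every
#' condition x replicate is fitted with the sample estimator and with MCD
#' and MVE at each subset proportion in `k_values`; the defaults are the
#' canonical grids (m from 10 to 160 in steps of 15; error 0–50% in steps
#' of 5%; bias 0–100% in steps of 10%; k in {0.55, 0.75, 0.95}; 500
#' replicates).
#'
#' @param mode one of `"size"`, `"error"`, `"bias"`.
#' @param m_values sample sizes for size mode.
#' @param e_values error fractions for error mode.
#' @param b_values bias fractions for bias mode.
#' @param k_values subset proportions for the robust estimators.
#' @param m_fixed sample size used in error/bias modes.
#' @param reps replicates per condition.
#' @param seed master seed; every replicate derives its own child seed from
#'   it, so single cells can be reproduced in isolation.
#' @param estimator an [estimatorConfig()] supplying `n_trials`,
#'   `max_csteps` and `rescale` (its `k` and `seed` are set per cell).
#' @param cor_method correlation flavour for the performance metric;
#'   Pearson by default, Spearman available for sensitivity analysis.
#' @return a list of class `experimentConfig`.
#' @export
experimentConfig <- function(mode = c("size", "error", "bias"),
                             m_values = seq(10L, 160L, by = 15L),
                             e_values = seq(0, 0.5, by = 0.05),
                             b_values = seq(0, 1, by = 0.1),
                             k_values = c(0.55, 0.75, 0.95),
                             m_fixed = 100L,
                             reps = 500L,
                             seed = 1L,
                             estimator = estimatorConfig(),
                             cor_method = c("pearson", "spearman")) {
  mode <- match.arg(mode)
  cor_method <- match.arg(cor_method)
  if (reps < 1) .nicheStop("domainError", "reps must be >= 1")
  if (any(k_values <= 0.5) || any(k_values > 1)) {
    .nicheStop("domainError", "all k_values must lie in (0.5, 1]")
  }
  vals <- switch(mode, size = m_values, error = e_values, bias = b_values)
  if (length(vals) < 1L) {
    .nicheStop("domainError", "the condition grid for this mode is empty")
  }
  structure(
    list(mode = mode, m_values = as.integer(m_values), e_values = e_values,
         b_values = b_values, k_values = k_values,
         m_fixed = as.integer(m_fixed), reps = as.integer(reps),
         seed = as.integer(seed), estimator = estimator,
         cor_method = cor_method),
    class = "experimentConfig"
  )
}

#' Performance of a fitted niche model against the known niche
#'
#' The experiments' scoring metric: the correlation, over the rows of the
#' occurrence sample, between the true finite rate of increase
#' `lambda_F(x_i)` and the modelled within-niche probability
#' `P(chi^2_n > D^2(x_i))`. Both are monotone decreasing transforms of a
#' quadratic form, so a model fitted with the true parameters scores
#' (numerically) 1.
#'
#' @param params the true [nicheParams()].
#' @param sample the `occurrenceSample` the model is scored on.
#' @param ls the fitted `locationScatter`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return a single correlation in `[-1, 1]`.
#' @export
performanceCorrelation <- function(params, sample, ls,
                                   method = c("pearson", "spearman")) {
  method <- match.arg(method)
  X <- if (inherits(sample, "occurrenceSample")) sample$X else .asEnvMatrix(sample)
  lam <- nicheGrowthRate(params, X)
  p <- nicheProbability(mahalanobisD2(ls, X), dof = ncol(X), invert = TRUE)
  if (stats::sd(lam) == 0 || stats::sd(p) == 0) {
    .nicheStop("undefinedCorrelationError",
               "correlation undefined: a score vector is constant")
  }
  stats::cor(lam, p, method = method)
}

# Method/k cells fitted per replicate: the sample estimator once, MCD and
# MVE at each k.
.methodCells <- function(k_values) {
  cells <- list(list(method = "sample", k = NA_real_))
  for (k in k_values) {
    cells <- c(cells, list(list(method = "mcd", k = k),
                           list(method = "mve", k = k)))
  }
  cells
}

.modeId <- function(mode) match(mode, c("size", "error", "bias"))

#' Run a replicated virtual-ecology experiment
#'
#' For every condition value and replicate: generate an idealised
#' occurrence sample ([sampleIdealised()]); in error/bias modes contaminate
#' it ([contaminate()]) at the condition's fraction; fit all method/k cells
#' on the same sample (a paired design); and score each fit with
#' [performanceCorrelation()]. Degenerate fits or undefined correlations
#' are recorded as failed replicates for their cell, not crashes, and are
#' excluded from the summaries with a logged count.
#'
#' The run is fully deterministic given `config$seed`: replicate `r` of
#' condition `c` draws its sample under a child seed derived by a
#' documented integer hash of `(seed, mode, c, r)`, and each estimator cell
#' hashes in its own cell index.
#'
#' @param config an [experimentConfig()].
#' @param params the true [nicheParams()] (defaults to the standard virtual
#'   species).
#' @param space a [samplingSpace()] for error/bias modes; when `NULL`, the
#'   default synthetic space is generated from the master seed.
#' @return an object of class `experimentResult`: a list with `records`
#'   (one row per condition x replicate x cell: `mode`, `condition`,
#'   `method`, `k`, `replicate`, `correlation`, `failed`), `summary` (from
#'   [summariseExperiment()]) and the `config`.
#' @export
runExperiment <- function(config, params = nicheParams(), space = NULL) {
  stopifnot(inherits(config, "experimentConfig"))
  mode <- config$mode
  mid <- .modeId(mode)
  conds <- switch(mode, size = config$m_values, error = config$e_values,
                  bias = config$b_values)
  n <- params$n
  if (mode == "size" && any(conds < 5L * n)) {
    .nicheStop("sampleSizeError", sprintf(
      "size mode requires every m >= 5 n = %d (MCD feasibility floor)", 5L * n))
  }
  if (mode %in% c("error", "bias") && is.null(space)) {
    space <- generateSpace(spaceConfig(),
                           seed = .childSeed(config$seed, 99L, 0L, 0L))
  }

  cells <- .methodCells(config$k_values)
  nrow_out <- length(conds) * config$reps * length(cells)
  rec_cond <- numeric(nrow_out)
  rec_meth <- character(nrow_out)
  rec_k <- numeric(nrow_out)
  rec_rep <- integer(nrow_out)
  rec_cor <- numeric(nrow_out)
  row <- 0L

  for (ci in seq_along(conds)) {
    cond <- conds[ci]
    m <- if (mode == "size") cond else config$m_fixed
    for (r in seq_len(config$reps)) {
      samp <- sampleIdealised(params, m,
                              seed = .childSeed(config$seed, mid, ci, r, 1L))
      if (mode == "error" && cond > 0) {
        samp <- contaminate(samp, space, params, error_frac = cond,
                            seed = .childSeed(config$seed, mid, ci, r, 2L))
      } else if (mode == "bias" && cond > 0) {
        samp <- contaminate(samp, space, params, bias_frac = cond,
                            seed = .childSeed(config$seed, mid, ci, r, 2L))
      }
      for (j in seq_along(cells)) {
        cell <- cells[[j]]
        cfg <- estimatorConfig(
          k = if (is.na(cell$k)) NULL else cell$k,
          n_trials = config$estimator$n_trials,
          max_csteps = config$estimator$max_csteps,
          exhaustive = config$estimator$exhaustive,
          rescale = config$estimator$rescale,
          reweight = config$estimator$reweight,
          seed = .childSeed(config$seed, mid, ci, r, 10L + j)
        )
        ls <- tryCatch(
          switch(cell$method,
                 sample = estimateSample(samp),
                 mcd = estimateMCD(samp, cfg),
                 mve = estimateMVE(samp, cfg)),
          nicheD2Error = function(e) NULL
        )
        rv <- if (is.null(ls)) NA_real_ else {
          tryCatch(performanceCorrelation(params, samp, ls,
                                          method = config$cor_method),
                   nicheD2Error = function(e) NA_real_)
        }
        row <- row + 1L
        rec_cond[row] <- cond
        rec_meth[row] <- cell$method
        rec_k[row] <- cell$k
        rec_rep[row] <- r
        rec_cor[row] <- rv
      }
    }
  }

  records <- data.frame(
    mode = mode, condition = rec_cond, method = rec_meth, k = rec_k,
    replicate = rec_rep, correlation = rec_cor,
    failed = is.na(rec_cor), stringsAsFactors = FALSE
  )
  structure(list(records = records, summary = summariseExperiment(records),
                 config = config),
            class = "experimentResult")
}

#' Summarise experiment records
#'
#' Median and inter-quartile range of the performance correlation per
#' (condition, method, k) cell, using the linear-interpolation (type 7)
#' quantile convention. Failed replicates are excluded from the quantiles
#' and counted in `n_failed`; a cell with no successful replicate carries
#' `NA` quantiles as its missing-cell marker.
#'
#' @param records the `records` data frame of an [runExperiment()] result
#'   (or a compatible data frame with columns `mode`, `condition`,
#'   `method`, `k`, `correlation`).
#' @return data frame with one row per cell: `mode`, `condition`, `method`,
#'   `k`, `n`, `n_failed`, `median_r`, `q1_r`, `q3_r`.
#' @export
summariseExperiment <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("mode", "condition", "method", "k", "correlation") %in%
                  names(records)))
  key <- paste(records$mode, records$condition, records$method,
               ifelse(is.na(records$k), "-", records$k), sep = "\r")
  parts <- split(seq_len(nrow(records)), key)
  out <- do.call(rbind, lapply(parts, function(ix) {
    r <- records$correlation[ix]
    ok <- r[!is.na(r)]
    q <- if (length(ok)) stats::quantile(ok, c(0.25, 0.5, 0.75), type = 7,
                                         names = FALSE)
         else rep(NA_real_, 3)
    data.frame(mode = records$mode[ix[1]],
               condition = records$condition[ix[1]],
               method = records$method[ix[1]],
               k = records$k[ix[1]],
               n = length(ok), n_failed = sum(is.na(r)),
               median_r = q[2], q1_r = q[1], q3_r = q[3],
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$condition, out$method, out$k, na.last = FALSE), ]
  rownames(out) <- NULL
  out
}

#' @export
print.experimentResult <- function(x, ...) {
  cat("Virtual-ecology experiment (", x$config$mode, " mode): ",
      length(unique(x$records$condition)), " conditions x ",
      x$config$reps, " replicates\n", sep = "")
  print(x$summary, digits = 3)
  invisible(x)
}
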