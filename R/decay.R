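# Decay-factor normalization and the linearized exponential decay fit.
#
# The model is Ct = C0 * exp(-lambda * t), fit on y = ln(Ct) by ordinary
# least squares so that the slope is the signed decay rate (negative for
# decaying transcripts) and t1/2 = ln(0.5)/slope.

#' Mean-normalize abundance to the GV (time-zero) mean
#'
#' Divides every transcript's values by its mean across the GV samples of
#' the same age group, so that the GV mean of each transcript equals 1
#' exactly. Transcripts whose GV mean is 0 in any present age group are
#' dropped with a warning.
#'
#' @param x A [DecayExperiment-class] with assay `"tpm"` (or any abundance
#'   assay in first position).
#' @return A [DecayExperiment-class] with assay `"normalized"`;
#'   `metadata(x)$meanNormalized` is set.
#' @export
meanNormalize <- function(x) {
  stopifnot(is(x, "DecayExperiment"))
  cd <- SummarizedExperiment::colData(x)
  a <- SummarizedExperiment::assay(x)
  out <- a
  drop <- rep(FALSE, nrow(a))
  for (ag in unique(cd$age_group)) {
    gv <- which(cd$age_group == ag & cd$stage == "GV")
    if (length(gv) < 2L)
      stop("mean normalization needs >= 2 GV samples in age group ", ag)
    grp <- which(cd$age_group == ag)
    m <- rowMeans(a[, gv, drop = FALSE])
    drop <- drop | m == 0
    out[, grp] <- a[, grp, drop = FALSE] / m
  }
  if (any(drop)) {
    warning(sum(drop), " transcript(s) dropped: GV mean of 0")
    out <- out[!drop, , drop = FALSE]
    x <- x[!drop, ]
  }
  res <- DecayExperiment(out, as.data.frame(cd), assayName = "normalized")
  S4Vectors::metadata(res)$meanNormalized <- TRUE
  res
}

#' Estimate the decay factor from apparently stable transcripts
#'
#' Because GV oocytes are transcriptionally quiescent and most mRNA mass is
#' degraded by MII, per-library TPM renormalization inflates the apparent
#' abundance of stable transcripts at MII. The decay factor is that
#' apparent fold increase: transcripts whose mean-normalized MII fold
#' change exceeds `threshold` and whose variance across MII samples is
#' below their mean fold change form the stable set, and the factor is the
#' arithmetic mean of their fold changes.
#'
#' @param x mean-normalized [DecayExperiment-class] for a single age group.
#' @param threshold fold-change threshold (>= 1).
#' @param minStable smallest stable set considered evaluable; below it the
#'   result is flagged with `factor = NA`.
#' @return list with `threshold`, `stable_ids`, `n_stable`, `factor` and
#'   `variance` (variance of the stable-set MII values after dividing by
#'   the factor).
#' @export
estimateDecayFactor <- function(x, threshold, minStable = 20L) {
  stopifnot(is(x, "DecayExperiment"), threshold >= 1)
  if (!isTRUE(S4Vectors::metadata(x)$meanNormalized))
    stop("estimateDecayFactor expects a mean-normalized experiment")
  .assert_one_age_group(x, "estimateDecayFactor")
  cd <- SummarizedExperiment::colData(x)
  mii <- SummarizedExperiment::assay(x)[, cd$stage == "MII", drop = FALSE]
  fold <- rowMeans(mii)
  v <- apply(mii, 1L, stats::var)
  stable <- fold > threshold & v < fold
  if (sum(stable) < minStable)
    return(list(threshold = threshold, stable_ids = character(),
                n_stable = sum(stable), factor = NA_real_,
                variance = NA_real_))
  factor <- mean(fold[stable])
  list(threshold = threshold,
       stable_ids = rownames(mii)[stable],
       n_stable = sum(stable),
       factor = factor,
       variance = stats::var(as.vector(mii[stable, , drop = FALSE] / factor)))
}

# Inflection detector over a variance-vs-threshold trace. The curvature is
# the discrete second difference; an inflection is the first interior point
# where it crosses zero: either an outright sign change, or a collapse of
# its magnitude to (near) zero, taken as <= `tol` of the largest curvature
# seen so far. Without the collapse rule a noisy convex trace that keeps
# creeping downward would never trigger and the fallback would select a
# nearly empty stable set at the extreme threshold. NA when no inflection.
.inflection_index <- function(v, tol = 0.1) {
  if (length(v) < 4L) return(NA_integer_)
  d2 <- diff(v, differences = 2L)      # d2[j] is curvature at trace point j+1
  if (length(d2) < 2L) return(NA_integer_)
  for (j in 2:length(d2)) {
    # a sign change only counts when both curvatures are non-negligible;
    # near-zero values are sampling noise around zero, not curvature
    floor_j <- tol * max(abs(d2[seq_len(j)]))
    if (abs(d2[j]) > floor_j && abs(d2[j - 1L]) > floor_j &&
        sign(d2[j]) != sign(d2[j - 1L]))
      return(j + 1L)
    if (abs(d2[j]) <= tol * max(abs(d2[seq_len(j - 1L)])))
      return(j + 1L)
  }
  NA_integer_
}

#' Select the decay-factor threshold iteratively
#'
#' Evaluates fold-change thresholds `start, start + step, ...` up to
#' `maxThreshold`, recording the post-normalization variance of each
#' threshold's stable set, and returns the threshold at the inflection
#' point of the variance-vs-threshold curve (first sign change of the
#' discrete second difference). When no inflection exists, or fewer than 3
#' thresholds are evaluable, the minimum-variance threshold is returned
#' with a warning.
#'
#' @inheritParams estimateDecayFactor
#' @param start,step,maxThreshold threshold grid (defaults 1.0, 0.5, 10).
#' @return list with `threshold`, `result` (the [estimateDecayFactor()]
#'   output at the selected threshold) and `trace` (data.frame of
#'   threshold, variance, n_stable, factor).
#' @export
selectDecayThreshold <- function(x, start = 1.0, step = 0.5,
                                 maxThreshold = 10.0, minStable = 20L) {
  grid <- seq(start, maxThreshold, by = step)
  res <- lapply(grid, function(th) estimateDecayFactor(x, th, minStable))
  trace <- data.frame(
    threshold = grid,
    variance = vapply(res, `[[`, numeric(1), "variance"),
    n_stable = vapply(res, `[[`, integer(1), "n_stable"),
    factor = vapply(res, `[[`, numeric(1), "factor"))
  ok <- which(!is.na(trace$variance))
  if (length(ok) == 0L)
    stop("no threshold yields an evaluable stable set")
  pick <- NA_integer_
  if (length(ok) >= 3L) {
    infl <- .inflection_index(trace$variance[ok])
    if (!is.na(infl)) pick <- ok[infl]
  }
  if (is.na(pick)) {
    if (length(ok) < 3L)
      warning("fewer than 3 evaluable thresholds; ",
              "falling back to the minimum-variance threshold")
    else
      warning("no inflection point in the variance trace; ",
              "falling back to the minimum-variance threshold")
    # Raising the threshold into the stable fold distribution always lowers
    # the recorded variance spuriously: truncating a normal at its mean
    # cuts the between-transcript variance component to ~36%, a ~25%
    # drop of the total at typical replicate structures, on top of
    # sampling error. The smallest threshold within a 40% band of the
    # minimum (the largest statistically equivalent stable set) is
    # therefore preferred over the literal argmin.
    vv <- trace$variance[ok]
    pick <- ok[which(vv <= 1.4 * min(vv))[1L]]
  }
  list(threshold = grid[pick], result = res[[pick]], trace = trace)
}

#' Apply a decay factor to the MII samples
#'
#' Divides MII values by the factor, leaving GV values unchanged, so that
#' truly stable transcripts return to a fold change of ~1 and decay slopes
#' are measured against a compositional baseline.
#'
#' @param x mean-normalized [DecayExperiment-class].
#' @param factor positive decay factor, typically from
#'   [selectDecayThreshold()].
#' @return The corrected [DecayExperiment-class];
#'   `metadata(x)$decayFactor` records the factor.
#' @export
applyDecayFactor <- function(x, factor) {
  stopifnot(is(x, "DecayExperiment"), is.numeric(factor), factor > 0)
  a <- SummarizedExperiment::assay(x)
  mii <- SummarizedExperiment::colData(x)$stage == "MII"
  a[, mii] <- a[, mii, drop = FALSE] / factor
  SummarizedExperiment::assay(x) <- a
  S4Vectors::metadata(x)$decayFactor <- factor
  x
}

# Core least-squares machinery on y = ln(value). `Y` is an n_transcripts x
# n_samples matrix of logged values, `x_t` the per-sample times. Returns the
# per-transcript slope, residual variance (df = n - 2), slope SE, t and p.
.ls_decay <- function(Y, x_t) {
  n <- length(x_t)
  cx <- x_t - mean(x_t)
  sxx <- sum(cx^2)
  lambda <- as.vector(Y %*% cx) / sxx
  resid <- Y - rowMeans(Y) - outer(lambda, cx)
  sigma2 <- rowSums(resid^2) / (n - 2L)
  se <- sqrt(sigma2 / sxx)
  t_stat <- ifelse(se > 0, lambda / se,
                   ifelse(lambda == 0, NaN, sign(lambda) * Inf))
  p <- ifelse(is.nan(t_stat), 1,
              pmax(2 * stats::pt(-abs(t_stat), df = n - 2L),
                   .Machine$double.xmin))
  list(lambda = lambda, sigma2 = sigma2, se = se, t = t_stat, p = p)
}

#' Fit the exponential decay model to one transcript
#'
#' Fits `Ct = C0 * exp(-lambda * t)` on the log scale by least squares:
#' the slope is the signed decay rate, the residual variance uses
#' `n - 2` degrees of freedom, `SE = sqrt(sigma2 / sum((x - mean(x))^2))`,
#' the t statistic is `lambda / SE` with a two-sided p from the
#' t-distribution, and the half-life is `ln(0.5)/lambda` when the slope is
#' negative (undefined otherwise).
#'
#' @param times numeric vector of sample times in hours (>= 3 observations
#'   spanning >= 2 distinct times).
#' @param values normalized abundance values, same length; nonpositive
#'   values are floored at `floorValue` and counted.
#' @param floorValue floor applied before taking logs.
#' @return One-row data.frame with `lambda`, `se_lambda`, `sigma2`,
#'   `t_stat`, `p_value`, `half_life_h`, `n_obs`, `n_floored`.
#' @examples
#' fitDecay(c(0, 0, 0, 24, 24, 24), c(1, 1, 1, 0.25, 0.25, 0.25))
#' @export
fitDecay <- function(times, values, floorValue = 1e-6) {
  stopifnot(length(times) == length(values))
  if (length(times) < 3L) stop("at least 3 observations are required")
  if (length(unique(times)) < 2L)
    stop("observations must span at least 2 distinct times")
  n_floored <- sum(values < floorValue)
  y <- log(pmax(values, floorValue))
  fit <- .ls_decay(matrix(y, nrow = 1L), times)
  data.frame(
    lambda = fit$lambda, se_lambda = fit$se, sigma2 = fit$sigma2,
    t_stat = fit$t, p_value = fit$p,
    half_life_h = ifelse(fit$lambda < 0, log(0.5) / fit$lambda, NA_real_),
    n_obs = length(times), n_floored = n_floored)
}

#' Fit the decay model to every transcript of an experiment
#'
#' Vectorized [fitDecay()] across all transcripts of a mean-normalized,
#' decay-factor-corrected experiment for one age group. The decay-fit set
#' is the subset with a negative slope and `p_value < alpha`.
#'
#' @param x normalized [DecayExperiment-class], single age group.
#' @param alpha significance level for the decay-fit call (default 0.05).
#' @param floorValue floor applied to normalized values before logs.
#' @return data.frame with one row per transcript: `transcript_id`,
#'   `age_group`, all [fitDecay()] columns and the logical `decay_fit`.
#' @export
fitAllDecay <- function(x, alpha = 0.05, floorValue = 1e-6) {
  stopifnot(is(x, "DecayExperiment"))
  ag <- .assert_one_age_group(x, "fitAllDecay")
  times <- SummarizedExperiment::colData(x)$time_h
  a <- SummarizedExperiment::assay(x)
  n_floored <- rowSums(a < floorValue)
  fit <- .ls_decay(log(pmax(a, floorValue)), times)
  data.frame(
    transcript_id = rownames(a), age_group = ag,
    lambda = fit$lambda, se_lambda = fit$se, sigma2 = fit$sigma2,
    t_stat = fit$t, p_value = fit$p,
    half_life_h = ifelse(fit$lambda < 0, log(0.5) / fit$lambda, NA_real_),
    n_obs = length(times), n_floored = n_floored,
    decay_fit = fit$lambda < 0 & fit$p < alpha,
    row.names = NULL)
}

#' Compare decay rates between young and aged fits
#'
#' For every transcript fit in both age groups, computes the standard score
#' `Z = (lambdaY - lambdaA) / (SE_Y + SE_A)` (the denominator is the sum of
#' the two standard errors; `zDenominator = "quadrature"` uses
#' `sqrt(SE_Y^2 + SE_A^2)` instead), a two-sided normal p-value and its
#' Bonferroni correction over the number of shared transcripts tested.
#'
#' @param fitsYoung,fitsAged data.frames from [fitAllDecay()].
#' @param mTests number of tests for the Bonferroni correction; defaults to
#'   the number of shared transcripts.
#' @param zDenominator `"sum"` (as defined above, the default) or
#'   `"quadrature"`.
#' @param decayFitOnly restrict each side to its decay-fit set first?
#' @return data.frame with one row per shared transcript: the two slopes,
#'   SEs and half-lives, `z`, `p_value`, `p_bonf` and `significant`
#'   (`p_bonf < 0.05`).
#' @export
compareAges <- function(fitsYoung, fitsAged, mTests = NULL,
                        zDenominator = c("sum", "quadrature"),
                        decayFitOnly = TRUE) {
  zDenominator <- match.arg(zDenominator)
  if (decayFitOnly) {
    if ("decay_fit" %in% colnames(fitsYoung))
      fitsYoung <- fitsYoung[fitsYoung$decay_fit, ]
    if ("decay_fit" %in% colnames(fitsAged))
      fitsAged <- fitsAged[fitsAged$decay_fit, ]
  }
  shared <- merge(
    fitsYoung[, c("transcript_id", "lambda", "se_lambda", "half_life_h")],
    fitsAged[, c("transcript_id", "lambda", "se_lambda", "half_life_h")],
    by = "transcript_id", suffixes = c("_young", "_aged"))
  if (is.null(mTests)) mTests <- nrow(shared)
  denom <- if (zDenominator == "sum") {
    shared$se_lambda_young + shared$se_lambda_aged
  } else {
    sqrt(shared$se_lambda_young^2 + shared$se_lambda_aged^2)
  }
  z <- (shared$lambda_young - shared$lambda_aged) / denom
  p <- 2 * stats::pnorm(-abs(z))
  shared$z <- z
  shared$p_value <- p
  shared$p_bonf <- pmin(1, p * mTests)
  shared$significant <- shared$p_bonf < 0.05
  shared
}

#' Classify half-life changes with aging
#'
#' Partitions compared transcripts into `unchanged` (absolute half-life
#' difference below `deltaH` hours), `shorter_in_aged` and
#' `longer_in_aged`. When `requireSignificance` is set (the default), the
#' two changed categories additionally require a Bonferroni-corrected
#' p below 0.05; transcripts failing it fall back to `unchanged`.
#'
#' @param comparisons data.frame from [compareAges()].
#' @param deltaH half-life difference threshold in hours (default 1).
#' @param requireSignificance require `p_bonf < 0.05` for a changed call?
#' @return The input with an added `category` factor; rows lacking a finite
#'   half-life on either side get `NA`.
#' @export
classifyChange <- function(comparisons, deltaH = 1.0,
                           requireSignificance = TRUE) {
  hy <- comparisons$half_life_h_young
  ha <- comparisons$half_life_h_aged
  cat <- rep(NA_character_, nrow(comparisons))
  fin <- is.finite(hy) & is.finite(ha)
  d <- ha - hy
  cat[fin & abs(d) < deltaH] <- "unchanged"
  cat[fin & d <= -deltaH] <- "shorter_in_aged"
  cat[fin & d >= deltaH] <- "longer_in_aged"
  if (requireSignificance) {
    demote <- fin & cat != "unchanged" & !comparisons$significant
    cat[demote] <- "unchanged"
  }
  comparisons$category <- factor(
    cat, levels = c("unchanged", "shorter_in_aged", "longer_in_aged"))
  comparisons
}
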