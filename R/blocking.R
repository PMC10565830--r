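#' Flyvbjerg-Petersen pairwise reblocking of a correlated series
#'
#' Estimates the standard error of the mean (SEM) of an autocorrelated
#' series. Level 0 is the raw series; each subsequent level averages
#' adjacent non-overlapping pairs of the previous level (a trailing odd
#' element is discarded). At each level with `m` blocks the SEM estimate is
#' `sqrt(s^2 / m)` with `s^2` the unbiased sample variance of the block
#' values, and its own uncertainty is `sem / sqrt(2 (m - 1))`. Once the
#' block size exceeds the correlation length of the data the SEM estimates
#' plateau at the true value; before that they are biased low.
#'
#' @param series numeric vector, length >= 4.
#' @param strategy how to pick the final SEM from the curve, see
#'   [select_sem]. `"max"` (the conservative default) takes the largest SEM
#'   over all levels; `"heuristic"` applies an optimal-block-size rule.
#' @return an object of class `blocking_curve`: a list with `n`, `levels`
#'   (data frame with `block_size`, `n_blocks`, `block_mean`,
#'   `sem_estimate`, `sem_of_sem`), `n_corr` (estimated correlation length
#'   in snapshots, from the ratio of selected to level-0 SEM),
#'   `selected_level` (1-based row index), `selected_sem`, `strategy`.
#' @seealso [select_sem], [ensemble_sem]
#' @export
reblock <- function(series, strategy = c("max", "heuristic")) {
  strategy <- match.arg(strategy)
  x <- as.numeric(series)
  n <- length(x)
  if (n < 4L) stop("reblocking needs at least 4 points, got ", n)
  if (!all(is.finite(x))) stop("non-finite values in series")
  levels <- list()
  B <- 1L
  while (length(x) >= 2L) {
    m <- length(x)
    s2 <- stats::var(x)
    sem <- sqrt(s2 / m)
    levels[[length(levels) + 1L]] <- data.frame(
      block_size = B, n_blocks = m, block_mean = mean(x),
      sem_estimate = sem, sem_of_sem = sem / sqrt(2 * (m - 1)))
    if (m < 4L) break
    half <- m %/% 2L
    x <- (x[seq(1L, 2L * half, by = 2L)] + x[seq(2L, 2L * half, by = 2L)]) / 2
    B <- B * 2L
  }
  curve <- structure(
    list(n = n, levels = do.call(rbind, levels), n_corr = NA_real_,
         selected_level = NA_integer_, selected_sem = NA_real_,
         strategy = strategy),
    class = "blocking_curve")
  sel <- select_sem(curve, strategy)
  curve$selected_level <- attr(sel, "level")
  curve$selected_sem <- as.numeric(sel)
  sem0 <- curve$levels$sem_estimate[1]
  curve$n_corr <- if (sem0 > 0) (curve$selected_sem / sem0)^2 else 1
  curve
}

#' Select the reported SEM from a blocking curve
#'
#' Strategy `"max"` takes the maximum SEM estimate over all levels with at
#' least two blocks — a deliberately conservative choice that can only
#' overestimate the uncertainty. Strategy `"heuristic"` estimates the
#' correlation length at each level as `n_corr = (sem_B / sem_0)^2` (the
#' statistical inefficiency; equal to `B` times the ratio of block-value
#' variances, and constant once the block size exceeds the true correlation
#' length) and selects the smallest block size `B` satisfying
#' `B^3 >= 2 * n * n_corr^2`; when no level qualifies it falls back to
#' `"max"` with a warning.
#'
#' @param curve a [reblock] result.
#' @param strategy `"max"` or `"heuristic"`.
#' @return the selected SEM (kcal/mol) with attribute `"level"` giving the
#'   1-based index of the chosen level.
#' @export
select_sem <- function(curve, strategy = c("max", "heuristic")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(curve, "blocking_curve"))
  lv <- curve$levels
  ok <- lv$n_blocks >= 2L
  if (strategy == "heuristic") {
    sem0 <- lv$sem_estimate[1]
    if (sem0 > 0) {
      n_corr <- (lv$sem_estimate / sem0)^2
      qual <- ok & (lv$block_size^3 >= 2 * curve$n * n_corr^2)
      if (any(qual)) {
        i <- which(qual)[1]
        return(structure(lv$sem_estimate[i], level = i))
      }
    }
    warning("no block size satisfies the optimality criterion; falling back to the max rule")
  }
  i <- which(ok)[which.max(lv$sem_estimate[ok])]
  structure(lv$sem_estimate[i], level = i)
}

#' @export
print.blocking_curve <- function(x, ...) {
  cat(sprintf("blocking_curve: n = %d, %d levels, selected SEM = %.6g (level %d, strategy '%s')\n",
              x$n, nrow(x$levels), x$selected_sem, x$selected_level, x$strategy))
  print(x$levels, row.names = FALSE, digits = 6)
  invisible(x)
}

#' SEM of an ensemble mean by reblocking
#'
#' Two modes are offered for an ensemble of K independent trajectories.
#' `"pooled"` (default) concatenates the trajectories in trajectory-id
#' order and reblocks the concatenation: block boundaries that span
#' independent trajectories can only reduce the apparent correlation, so
#' under the max rule the estimate stays conservative. `"per-trajectory"`
#' reblocks each trajectory separately and combines the per-trajectory SEMs
#' as `sqrt(sum(sem_t^2)) / K`, the SEM of the unweighted mean of the K
#' trajectory means.
#'
#' @param ensemble a [trajectory_ensemble].
#' @param strategy passed to [select_sem].
#' @param mode `"pooled"` or `"per-trajectory"`.
#' @return the SEM (kcal/mol); attribute `"curve"` carries the pooled
#'   [reblock] curve in pooled mode.
#' @export
ensemble_sem <- function(ensemble, strategy = c("max", "heuristic"),
                         mode = c("pooled", "per-trajectory")) {
  strategy <- match.arg(strategy)
  mode <- match.arg(mode)
  stopifnot(inherits(ensemble, "trajectory_ensemble"))
  tr <- ensemble$traces[order(names(ensemble$traces))]
  if (mode == "pooled") {
    curve <- reblock(unlist(lapply(tr, `[[`, "values"), use.names = FALSE),
                     strategy)
    structure(curve$selected_sem, curve = curve)
  } else {
    sems <- vapply(tr, function(t) reblock(t$values, strategy)$selected_sem,
                   numeric(1))
    sqrt(sum(sems^2)) / length(sems)
  }
}
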