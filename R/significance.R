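#' Summarize a null ensemble against the empirical statistics
#'
#' Reduces a [null_ensemble()] to the quantities used to decide whether a
#' network's modular structure differs from chance: null means and variances
#' of Q and Q'_R, a percentile confidence interval at `level` (default 90%,
#' i.e. the 5th-95th percentiles of the replicate distribution, with linear
#' interpolation), the deltas
#' \deqn{\Delta Q = Q_{emp} - \bar Q_{null}, \quad
#'       \Delta Q'_R = Q'_{R,emp} - \bar Q'_{R,null},}
#' and outside-CI flags. A percentile interval is used rather than a normal
#' approximation because modularity distributions are bounded and often
#' skewed.
#'
#' Field names follow the conventional flat-record layout: `q`/`qr` empirical
#' Q and Q'_R, `qe`/`qre` their null expectations, `eqe`/`eqre` the null
#' variances, `dq`/`dqr` the deltas.
#'
#' @param ensemble a `realmod_ensemble` with at least 2 retained replicates.
#' @param empirical_q empirical Newman-Girvan Q.
#' @param empirical_qprime empirical Q'_R.
#' @param level confidence level, strictly between 0 and 1 (default 0.90).
#' @return An object of class `realmod_nulltest`: list with `q`, `qr`, `qe`,
#'   `eqe`, `qre`, `eqre`, `q_ci`, `qr_ci` (length-2 vectors), `dq`, `dqr`,
#'   `q_outside`, `qr_outside`, `level`, `retained`, `discarded`, `quadrant`
#'   (see [classify()]).
#' @export
summarize_null <- function(ensemble, empirical_q, empirical_qprime,
                           level = 0.90) {
  stopifnot(inherits(ensemble, "realmod_ensemble"))
  if (ensemble$retained < 2L)
    stop("need at least 2 retained replicates to summarize an ensemble")
  if (!(level > 0 && level < 1)) stop("'level' must be in (0, 1)")
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  q_ci <- unname(stats::quantile(ensemble$q, probs, type = 7))
  qr_ci <- unname(stats::quantile(ensemble$qprime, probs, type = 7))
  rep <- structure(list(
    q = empirical_q,
    qr = empirical_qprime,
    qe = mean(ensemble$q),
    eqe = stats::var(ensemble$q),
    qre = mean(ensemble$qprime),
    eqre = stats::var(ensemble$qprime),
    q_ci = q_ci,
    qr_ci = qr_ci,
    dq = empirical_q - mean(ensemble$q),
    dqr = empirical_qprime - mean(ensemble$qprime),
    q_outside = empirical_q < q_ci[1] || empirical_q > q_ci[2],
    qr_outside = empirical_qprime < qr_ci[1] || empirical_qprime > qr_ci[2],
    level = level,
    retained = ensemble$retained,
    discarded = ensemble$discarded
  ), class = "realmod_nulltest")
  rep$quadrant <- classify(rep)
  rep
}

#' Classify a null-test report into a significance quadrant
#'
#' Combines the signs of the deltas with the outside-CI flags. When both
#' statistics fall outside their null confidence intervals, the network is
#' `"more-modular-both"` (both deltas positive), `"less-modular-both"` (both
#' negative), or conflicted: `"conflicted-Q-low-QR-high"` flags the common
#' case of a network whose modularity Q is lower than expected by chance
#' while its realized modularity is higher (the identified modules are
#' nonetheless more densely connected internally than with the rest of the
#' network); `"conflicted-Q-high-QR-low"` is the reverse. If either flag
#' fails to fire the verdict is `"indistinct"`.
#'
#' @param report a `realmod_nulltest`.
#' @return one of `"more-modular-both"`, `"less-modular-both"`,
#'   `"conflicted-Q-low-QR-high"`, `"conflicted-Q-high-QR-low"`,
#'   `"indistinct"`.
#' @export
classify <- function(report) {
  stopifnot(inherits(report, "realmod_nulltest"))
  if (!isTRUE(report$q_outside) || !isTRUE(report$qr_outside))
    return("indistinct")
  if (report$dq > 0 && report$dqr > 0) return("more-modular-both")
  if (report$dq < 0 && report$dqr < 0) return("less-modular-both")
  if (report$dq < 0 && report$dqr > 0) return("conflicted-Q-low-QR-high")
  if (report$dq > 0 && report$dqr < 0) return("conflicted-Q-high-QR-low")
  "indistinct"   # a delta of exactly 0 cannot sit outside its CI
}

#' @export
print.realmod_nulltest <- function(x, ...) {
  cat(sprintf("Null-model test (%d%% percentile CI, %d replicates retained, %d discarded)\n",
              round(100 * x$level), x$retained, x$discarded))
  cat(sprintf("  Q    = %.3g  null %.3g [%.3g, %.3g]  dQ   = %+.3g%s\n",
              x$q, x$qe, x$q_ci[1], x$q_ci[2], x$dq,
              if (x$q_outside) " *" else ""))
  cat(sprintf("  Q'_R = %.2f  null %.3g [%.3g, %.3g]  dQ'R = %+.3g%s\n",
              x$qr, x$qre, x$qr_ci[1], x$qr_ci[2], x$dqr,
              if (x$qr_outside) " *" else ""))
  cat("  verdict:", x$quadrant, "\n")
  invisible(x)
}

#' Flatten a null-test report to a one-row data frame
#'
#' One row per network, with the conventional column names (`q`, `qr`, `qe`,
#' `eqe`, `qre`, `eqre`, `dq`, `dqr`) plus CI bounds, flags and the quadrant
#' label; suitable for stacking across a batch of networks.
#'
#' @param report a `realmod_nulltest`.
#' @return a one-row data.frame.
#' @export
as_record <- function(report) {
  stopifnot(inherits(report, "realmod_nulltest"))
  data.frame(q = report$q, qr = report$qr,
             qe = report$qe, eqe = report$eqe,
             qre = report$qre, eqre = report$eqre,
             q_lo = report$q_ci[1], q_hi = report$q_ci[2],
             qr_lo = report$qr_ci[1], qr_hi = report$qr_ci[2],
             dq = report$dq, dqr = report$dqr,
             q_outside = report$q_outside, qr_outside = report$qr_outside,
             quadrant = report$quadrant,
             retained = report$retained, discarded = report$discarded,
             stringsAsFactors = FALSE)
}

#' Run the full null-model significance pipeline on one network
#'
#' Detects communities on the empirical network ([louvain()]), scores the
#' partition with both measures, draws a [null_ensemble()], and summarizes
#' it with [summarize_null()].
#'
#' @inheritParams null_ensemble
#' @param level confidence level for the percentile interval.
#' @return a `realmod_nulltest` (see [summarize_null()]).
#' @export
null_test <- function(network, replicates = 1000L, seed = 1L, level = 0.90,
                      detector = louvain,
                      normalization = c("degree", "size")) {
  det <- detector(network, seed = seed)
  emp_q <- newman_girvan_q(network, det$partition)$q
  emp_qp <- realized_modularity(network, det$partition)$qprime
  ens <- null_ensemble(network, replicates = replicates, seed = seed,
                       detector = detector, normalization = normalization)
  summarize_null(ens, emp_q, emp_qp, level = level)
}
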