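## Clade-level comparison: the time-weighted null expectation of the
## SA-fusion proportion versus the proportion actually realized on
## stochastic maps.

## Map a Markov state to the karyotype used for the closed-form null:
## diploid number i means Da = i - 2 autosomes plus one X and one Y; a
## neoXY system is treated as the (larger) sex chromosome pair, so the
## same karyotype applies at equal i.
state_karyotype <- function(i) karyotype(as.integer(i) - 2L, x = 1L, y = 1L)

#' Time-weighted expected SA-fusion proportion for a mapped history
#'
#' The closed-form null probability of an SA-fusion, evaluated for the
#' karyotype of each state and averaged with weights equal to the
#' proportion of tree length the history spends in each state:
#' \eqn{\sum_s \tau_s \, P(SA \mid s)}.
#'
#' @param summary a [summarize_map()] result (or a `"karyo_map"`, which is
#'   summarized first).
#' @param mu sex-bias parameter passed to [p_sa()].
#' @return a probability.
#' @export
expected_sa_proportion <- function(summary, mu = 0.5) {
  if (inherits(summary, "karyo_map")) summary <- summarize_map(summary)
  tau <- summary$time_in_state
  i <- as.integer(sub("_.*$", "", names(tau)))
  psa <- vapply(unique(i), function(ii) p_sa(state_karyotype(ii), mu), numeric(1))
  sum(tau * psa[match(i, unique(i))])
}

#' Observed SA-fusion proportion on a mapped history
#'
#' The number of SA-fusion events divided by the total number of fusions
#' (SA plus AA) on the map. Histories with no fusion events have no
#' defined proportion and return `NA`.
#'
#' @inheritParams expected_sa_proportion
#' @return a probability, or `NA_real_` for a fusion-free history.
#' @export
observed_sa_proportion <- function(summary) {
  if (inherits(summary, "karyo_map")) summary <- summarize_map(summary)
  sa <- summary$counts[["SA_fusion"]]; aa <- summary$counts[["AA_fusion"]]
  if (sa + aa == 0L) return(NA_real_)
  sa / (sa + aa)
}

#' Compare observed and expected SA-fusion proportions across maps
#'
#' For each stochastic map, computes the time-weighted expected SA-fusion
#' proportion under the closed-form null and the observed proportion of
#' SA among fusion events, then summarizes both distributions by their
#' mean and equal-tail credible interval and reports whether the two
#' intervals overlap. Maps with no fusion events contribute to the
#' expected distribution but are excluded from the observed one (their
#' number is reported).
#'
#' @param maps a `"karyo_maps"` list (or plain list of `"karyo_map"`).
#' @param mu sex-bias parameter for the null.
#' @param level credible level for the equal-tail intervals.
#' @return an object of class `"clade_report"`: a list with `expected`
#'   and `observed` (each `mean`, `lower`, `upper`), `mean_sa_count`,
#'   `overlap`, `n_maps`, `n_observed_used`, `n_excluded`, `level`, `mu`,
#'   and the per-map vectors in `draws`.
#' @examples
#' \donttest{
#' sim <- synthesize(n_tips = 60, rates = karyo_rates(0.5, 0.5, 0.4, 1),
#'                   seed = 1)
#' fit <- karyo_fit(sim$tree, sim$tip_states, seed = 1)
#' rep <- clade_report(simulate(fit, nsim = 50, seed = 2))
#' rep
#' }
#' @export
clade_report <- function(maps, mu = 0.5, level = 0.95) {
  if (length(maps) < 2L) stop("at least two maps are required")
  sums <- lapply(maps, function(m)
    if (inherits(m, "karyo_map_summary")) m else summarize_map(m))
  exp_draws <- vapply(sums, expected_sa_proportion, numeric(1), mu = mu)
  obs_draws <- vapply(sums, observed_sa_proportion, numeric(1))
  sa_counts <- vapply(sums, function(s) as.numeric(s$counts[["SA_fusion"]]),
                      numeric(1))
  a <- (1 - level) / 2
  ci <- function(x) stats::quantile(x, c(a, 1 - a), names = FALSE, type = 7)
  used <- obs_draws[!is.na(obs_draws)]
  expected <- list(mean = mean(exp_draws), lower = ci(exp_draws)[1],
                   upper = ci(exp_draws)[2])
  observed <- if (length(used)) {
    list(mean = mean(used), lower = ci(used)[1], upper = ci(used)[2])
  } else {
    list(mean = NA_real_, lower = NA_real_, upper = NA_real_)
  }
  overlap <- if (length(used)) {
    observed$lower <= expected$upper && expected$lower <= observed$upper
  } else NA
  structure(list(expected = expected, observed = observed,
                 mean_sa_count = mean(sa_counts), overlap = overlap,
                 n_maps = length(maps), n_observed_used = length(used),
                 n_excluded = sum(is.na(obs_draws)), level = level, mu = mu,
                 draws = list(expected = exp_draws, observed = obs_draws)),
            class = "clade_report")
}

#' @export
print.clade_report <- function(x, digits = 3, ...) {
  f <- function(v) formatC(v, digits = digits, format = "f")
  cat(sprintf("Clade-level SA-fusion comparison (%d maps, mu = %g)\n",
              x$n_maps, x$mu))
  cat(sprintf("  expected proportion: %s (%g%% CI %s-%s)\n",
              f(x$expected$mean), 100 * x$level, f(x$expected$lower),
              f(x$expected$upper)))
  if (x$n_observed_used) {
    cat(sprintf("  observed proportion: %s (%g%% CI %s-%s) from %d maps (%d fusion-free maps excluded)\n",
                f(x$observed$mean), 100 * x$level, f(x$observed$lower),
                f(x$observed$upper), x$n_observed_used, x$n_excluded))
    cat(sprintf("  mean SA-fusion count per map: %s\n", f(x$mean_sa_count)))
    cat(sprintf("  credible intervals %s\n",
                if (x$overlap) "overlap" else "do NOT overlap"))
  } else {
    cat("  observed proportion unavailable: every map was fusion-free\n")
  }
  invisible(x)
}
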