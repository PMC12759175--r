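#' Multiplicatively perturb a passability policy
#'
#' Scales the default up- and downstream passabilities of both barrier
#' kinds (anthropogenic and waterfall) by the given factors, clipping the
#' results to \[0, 1\]. The restrictive `blocked_upstream` scenario
#' additionally forces upstream passage over anthropogenic barriers to 0.
#' Habitat suitability is untouched — only passability varies.
#'
#' @param policy a [PassabilityPolicy][PassabilityPolicy-class]
#' @param up_factor,down_factor multiplicative factors (1 = unchanged)
#' @param blocked_upstream logical, fully block upstream passage at dams
#' @return the perturbed policy
#' @examples
#' p <- perturbPolicy(passabilityPolicy(), up_factor = 1.25)
#' p@defaults["anthropogenic", "up"]  # 0.125
#' @export
perturbPolicy <- function(policy, up_factor = 1, down_factor = 1,
                          blocked_upstream = FALSE) {
  stopifnot(is.finite(up_factor), is.finite(down_factor))
  d <- policy@defaults
  d[, "up"] <- pmin(pmax(d[, "up"] * up_factor, 0), 1)
  d[, "down"] <- pmin(pmax(d[, "down"] * down_factor, 0), 1)
  policy@defaults <- d
  if (blocked_upstream) policy@blockUpstream <- TRUE
  validObject(policy)
  policy
}

#' Standard grid of passability perturbation scenarios
#'
#' Realizes "perturbation by 10%–25% around the baseline" as the grid of
#' multiplicative factors `1 +/- magnitude` applied to the upstream, the
#' downstream, or both passabilities, plus the restrictive scenario with
#' fully blocked upstream passage at anthropogenic barriers.
#'
#' @param magnitudes relative perturbation magnitudes, default `c(0.10, 0.25)`
#' @param blocked include the blocked-upstream scenario (default TRUE)
#' @return data.frame `scenario`, `up_factor`, `down_factor`,
#'   `blocked_upstream`
#' @export
perturbationGrid <- function(magnitudes = c(0.10, 0.25), blocked = TRUE) {
  rows <- list()
  for (m in magnitudes) for (sgn in c(-1, 1)) {
    f <- 1 + sgn * m
    tag <- sprintf("%+d%%", as.integer(round(sgn * m * 100)))
    rows[[length(rows) + 1]] <-
      data.frame(scenario = paste0("up", tag), up_factor = f,
                 down_factor = 1, blocked_upstream = FALSE)
    rows[[length(rows) + 1]] <-
      data.frame(scenario = paste0("down", tag), up_factor = 1,
                 down_factor = f, blocked_upstream = FALSE)
    rows[[length(rows) + 1]] <-
      data.frame(scenario = paste0("both", tag), up_factor = f,
                 down_factor = f, blocked_upstream = FALSE)
  }
  out <- do.call(rbind, rows)
  if (blocked)
    out <- rbind(out, data.frame(scenario = "blocked_upstream",
                                 up_factor = 1, down_factor = 1,
                                 blocked_upstream = TRUE))
  rownames(out) <- NULL
  out
}

#' Robustness of RCI to passability uncertainty
#'
#' Computes the baseline per-reach RCI once, then recomputes it under each
#' perturbation scenario and compares the two vectors with a Pearson
#' correlation and a two-sided paired Wilcoxon signed-rank test (normal
#' approximation; zero differences dropped). Scenarios whose perturbation
#' leaves every RCI unchanged are flagged degenerate and reported with
#' `r = 1`, `p = 1`.
#'
#' @inheritParams rci
#' @param scenarios data.frame from [perturbationGrid()]
#' @return data.frame `scenario`, `up_factor`, `down_factor`,
#'   `blocked_upstream`, `pearson_r`, `wilcoxon_stat`, `p_value`,
#'   `degenerate`
#' @export
sensitivityGrid <- function(network, policy = passabilityPolicy(),
                            scenarios = perturbationGrid(),
                            barrierSet = "current") {
  if (nReaches(network) < 3)
    stop("need at least 3 reaches for a meaningful correlation",
         call. = FALSE)
  base <- rci(network, policy, barrierSet)
  out <- scenarios
  out$pearson_r <- NA_real_
  out$wilcoxon_stat <- NA_real_
  out$p_value <- NA_real_
  out$degenerate <- FALSE
  for (k in seq_len(nrow(scenarios))) {
    p2 <- perturbPolicy(policy, scenarios$up_factor[k],
                        scenarios$down_factor[k],
                        scenarios$blocked_upstream[k])
    pert <- rci(network, p2, barrierSet)
    dif <- pert - base
    if (all(dif == 0)) {
      out$pearson_r[k] <- 1
      out$p_value[k] <- 1
      out$degenerate[k] <- TRUE
      next
    }
    if (stats::sd(base) == 0 || stats::sd(pert) == 0) {
      out$degenerate[k] <- TRUE  # correlation undefined on a constant vector
      next
    }
    out$pearson_r[k] <- stats::cor(base, pert)
    wt <- suppressWarnings(stats::wilcox.test(pert, base, paired = TRUE,
                                              exact = FALSE, correct = TRUE))
    out$wilcoxon_stat[k] <- unname(wt$statistic)
    out$p_value[k] <- wt$p.value
  }
  out
}
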