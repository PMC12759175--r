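#' Connectivity gain from removing one barrier (dCCI)
#'
#' Leave-one-out barrier impact: the Catchment Connectivity Index of the
#' barrier's catchment is computed with the full active barrier set
#' (`CCI_start`), then with barrier `m` made fully passable (removal for
#' existing barriers, prevention of construction for planned ones — all
#' other planned barriers stay active in the `"future"` set), and the gain
#' is expressed in percent:
#' `dCCI_m = (CCI_start,m - CCI_start) / CCI_start * 100`.
#' It is 0 when the barrier has no effect on fragmentation and grows
#' without bound as the catchment approaches total fragmentation. The
#' network is not modified: removal sets both passabilities to 1, keeping
#' the topology intact.
#'
#' @inheritParams cci
#' @param barrier_id id of an active barrier link
#' @return nonnegative percent gain (scalar)
#' @examples
#' fx <- toyFixture("two")
#' dcci(fx$network, fx$policy, c(U = 1, D = 1), "DAM1")  # 60
#' @export
dcci <- function(network, policy = passabilityPolicy(), suitability,
                 barrier_id, barrierSet = "current",
                 weighting = c("suitability", "suitability_length")) {
  weighting <- match.arg(weighting)
  prep <- .prepareNetwork(network, policy, barrierSet)
  .dcciFromPrep(network, prep, suitability, barrier_id, barrierSet, weighting)
}

.dcciFromPrep <- function(network, prep, suitability, barrier_id,
                          barrierSet, weighting) {
  l <- prep$links
  k <- match(barrier_id, l$link_id)
  if (is.na(k) || l$kind[k] == "confluence")
    stop("unknown barrier '", barrier_id, "'", call. = FALSE)
  if (l$status[k] == "planned" && barrierSet != "future")
    stop("barrier '", barrier_id, "' is not active in the '", barrierSet,
         "' barrier set", call. = FALSE)
  catch <- network@reaches$catchment_id[match(l$down_reach[k],
                                              network@reaches$reach_id)]
  rci0 <- .rciFromPrep(prep)
  cci0 <- .cciFromRci(network, rci0, suitability, weighting)[[catch]]
  if (cci0 == 0) stop("CCI of catchment '", catch, "' is 0", call. = FALSE)
  rci1 <- .rciFromPrep(.prepRemove(prep, barrier_id))
  cci1 <- .cciFromRci(network, rci1, suitability, weighting)[[catch]]
  max((cci1 - cci0) / cci0 * 100, 0)
}

#' Active barrier ids of a network
#'
#' @inheritParams rci
#' @param kinds barrier kinds to include
#' @return character vector of link ids active under `barrierSet`
#' @export
activeBarriers <- function(network, barrierSet = "current",
                           kinds = c("waterfall", "anthropogenic")) {
  l <- network@links
  keep <- l$kind %in% setdiff(kinds, "confluence")
  if (barrierSet != "future") keep <- keep & l$status == "existing"
  if (barrierSet == "baseline") keep <- keep & l$kind == "waterfall"
  l$link_id[keep]
}

#' Rank barriers by leave-one-out connectivity gain
#'
#' Evaluates [dcci()] for every candidate (with all other active barriers
#' in place) and ranks them by decreasing gain; rank 1 is the most
#' impactful barrier, ties receive the average of the tied positions. By
#' default only anthropogenic barriers are candidates — waterfalls remain
#' in the network as natural fragmentation but are not ranked.
#'
#' @inheritParams cci
#' @param candidates barrier ids to rank; default: all anthropogenic
#'   barriers active under `barrierSet`
#' @param includeWaterfalls add waterfalls to the default candidate set
#' @param cell optional scenario-cell label carried into the result
#' @return a [BarrierImpact][BarrierImpact-class]
#' @export
rankBarriers <- function(network, policy = passabilityPolicy(), suitability,
                         candidates = NULL, barrierSet = "current",
                         weighting = c("suitability", "suitability_length"),
                         includeWaterfalls = FALSE, cell = NA_character_) {
  weighting <- match.arg(weighting)
  if (is.null(candidates)) {
    kinds <- if (includeWaterfalls) c("waterfall", "anthropogenic")
             else "anthropogenic"
    candidates <- activeBarriers(network, barrierSet, kinds)
  }
  if (length(candidates) == 0) stop("empty candidate set", call. = FALSE)
  prep <- .prepareNetwork(network, policy, barrierSet)
  d <- vapply(candidates, function(b)
    .dcciFromPrep(network, prep, suitability, b, barrierSet, weighting),
    numeric(1))
  rk <- rank(-d, ties.method = "average")
  l <- network@links
  li <- match(candidates, l$link_id)
  tb <- data.frame(barrier_id = candidates, kind = l$kind[li],
                   status = l$status[li], dCCI = unname(d),
                   rank = unname(rk), stringsAsFactors = FALSE)
  tb <- tb[order(tb$rank, tb$barrier_id), , drop = FALSE]
  rownames(tb) <- NULL
  new("BarrierImpact", table = tb, cell = as.character(cell))
}

#' Mean barrier rank across scenario cells
#'
#' Averages the per-cell priority ranks of each barrier over a set of
#' rankings (scenario cells: barrier set x climate x epoch x fish group).
#' All rankings must cover the same candidate set.
#'
#' @param rankings list of [BarrierImpact][BarrierImpact-class] objects
#' @return data.frame `barrier_id`, `mean_rank` (2 decimals), sorted
#'   ascending (1 = most impactful overall)
#' @export
meanRank <- function(rankings) {
  if (is(rankings, "BarrierImpact")) rankings <- list(rankings)
  if (length(rankings) == 0) stop("no rankings supplied", call. = FALSE)
  ids <- sort(impactTable(rankings[[1]])$barrier_id)
  rk <- vapply(rankings, function(bi) {
    tb <- impactTable(bi)
    if (!identical(sort(tb$barrier_id), ids))
      stop("rankings cover different candidate sets", call. = FALSE)
    tb$rank[match(ids, tb$barrier_id)]
  }, numeric(length(ids)))
  rk <- matrix(rk, nrow = length(ids))
  out <- data.frame(barrier_id = ids,
                    mean_rank = round(rowMeans(rk), 2),
                    stringsAsFactors = FALSE)
  out <- out[order(out$mean_rank, out$barrier_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate valid scenario cells
#'
#' Crosses barrier sets, climate scenarios, epochs and fish groups,
#' keeping only valid combinations: the `current` climate exists only at
#' the `current` epoch, and future climates only at future epochs.
#'
#' @param barrier_sets,climates,epochs,groups character vectors of levels
#' @return data.frame `cell`, `barrier_set`, `climate`, `epoch`, `group`
#' @examples
#' nrow(scenarioCells("future", c("moderate", "pessimistic"),
#'                    c("2030", "2050", "2070", "2090"),
#'                    c("combined", "migratory", "sedentary")))  # 24
#' @export
scenarioCells <- function(barrier_sets = "current", climates = CLIMATES,
                          epochs = EPOCHS, groups = GROUPS) {
  stopifnot(all(barrier_sets %in% BARRIER_SETS), all(climates %in% CLIMATES),
            all(epochs %in% EPOCHS), all(groups %in% GROUPS))
  g <- expand.grid(group = groups, epoch = epochs, climate = climates,
                   barrier_set = barrier_sets, stringsAsFactors = FALSE,
                   KEEP.OUT.ATTRS = FALSE)
  ok <- (g$climate == "current") == (g$epoch == "current")
  g <- g[ok, c("barrier_set", "climate", "epoch", "group"), drop = FALSE]
  g$cell <- cellKey(g$group, g$climate, g$epoch, g$barrier_set)
  rownames(g) <- NULL
  g[, c("cell", "barrier_set", "climate", "epoch", "group")]
}

#' Run the connectivity and prioritization analysis over a scenario grid
#'
#' For each requested cell the matching barrier set is activated, the
#' suitability layer for (group, climate, epoch) selected, and RCI,
#' RCIsuit, CCI and the RCIsuit summary computed; optionally barriers are
#' ranked by dCCI in every cell. RCI is cached per barrier set (it does
#' not depend on climate or group). Deterministic given its inputs.
#'
#' @inheritParams rci
#' @param suitability a [SuitabilityLayer][SuitabilityLayer-class]
#'   covering every requested (group, climate, epoch)
#' @param cells data.frame from [scenarioCells()]
#' @param ranking also rank candidate barriers in each cell
#' @param candidates,includeWaterfalls,weighting passed to [rankBarriers()]
#'   and [cci()]
#' @return list with `result` (a
#'   [ConnectivityResult][ConnectivityResult-class]), and when
#'   `ranking = TRUE`, `impacts` (list of `BarrierImpact` per cell) and
#'   `mean_rank` (data.frame from [meanRank()])
#' @export
scenarioGrid <- function(network, policy = passabilityPolicy(), suitability,
                         cells = scenarioCells(), ranking = FALSE,
                         candidates = NULL,
                         weighting = c("suitability", "suitability_length"),
                         includeWaterfalls = FALSE) {
  stopifnot(is(suitability, "SuitabilityLayer"))
  weighting <- match.arg(weighting)
  r <- network@reaches
  nC <- nrow(cells)
  rciM <- matrix(NA_real_, nrow(r), nC,
                 dimnames = list(r$reach_id, cells$cell))
  suitM <- rciM; ccm <- matrix(NA_real_, length(catchments(network)), nC,
                               dimnames = list(catchments(network),
                                               cells$cell))
  summ <- cells
  summ$mean <- summ$median <- summ$max <- NA_real_
  rciCache <- list()
  impacts <- if (ranking) vector("list", nC) else NULL
  for (k in seq_len(nC)) {
    bs <- cells$barrier_set[k]
    if (is.null(rciCache[[bs]]))
      rciCache[[bs]] <- rci(network, policy, barrierSet = bs)
    rciV <- rciCache[[bs]]
    sv <- suitabilityFor(suitability, cells$group[k], cells$climate[k],
                         cells$epoch[k])
    rciM[, k] <- rciV[r$reach_id]
    rs <- rciSuit(rciV, sv, network)
    suitM[, k] <- rs[r$reach_id]
    ccm[, k] <- .cciFromRci(network, rciV,
                            .alignSuitability(r$reach_id, sv, network),
                            weighting)[rownames(ccm)]
    st <- summarizeConnectivity(rs)
    summ$mean[k] <- st["mean"]; summ$median[k] <- st["median"]
    summ$max[k] <- st["max"]
    if (ranking)
      impacts[[k]] <- rankBarriers(network, policy, sv,
                                   candidates = candidates, barrierSet = bs,
                                   weighting = weighting,
                                   includeWaterfalls = includeWaterfalls,
                                   cell = cells$cell[k])
  }
  result <- new("ConnectivityResult",
                reaches = r[, c("reach_id", "catchment_id", "length_km")],
                cells = cells, rci = rciM, rcisuit = suitM, cci = ccm,
                summary = summ[, c("cell", "mean", "median", "max")])
  validObject(result)
  if (!ranking) return(list(result = result))
  names(impacts) <- cells$cell
  # candidate sets differ between barrier sets (planned dams only exist in
  # "future"), so mean ranks are taken within each barrier set
  mr <- do.call(rbind, lapply(unique(cells$barrier_set), function(bs) {
    m <- meanRank(impacts[cells$barrier_set == bs])
    cbind(barrier_set = bs, m, stringsAsFactors = FALSE)
  }))
  rownames(mr) <- NULL
  list(result = result, impacts = impacts, mean_rank = mr)
}
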