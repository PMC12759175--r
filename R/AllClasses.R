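#' @import methods
NULL

LINK_KINDS <- c("confluence", "waterfall", "anthropogenic")
LINK_STATUS <- c("existing", "planned")
BARRIER_SETS <- c("baseline", "current", "future")
CLIMATES <- c("current", "moderate", "pessimistic")
EPOCHS <- c("current", "2030", "2050", "2070", "2090")
GROUPS <- c("combined", "migratory", "sedentary")

#' RiverNetwork: a dendritic river network as a forest of reaches
#'
#' Nodes are river reaches (segments between neighboring confluences or
#' barriers); edges joining a reach to its downstream neighbor carry one or
#' more links, each a confluence, a waterfall, or an anthropogenic barrier
#' (dam). Flow direction is encoded solely by the `next_down` pointer; the
#' outlet of each catchment is the one reach with no downstream neighbor.
#'
#' @slot reaches data.frame with columns `reach_id`, `length_km` (> 0),
#'   `catchment_id`, `next_down` (`NA` for the outlet), `origin` (the
#'   pre-splitting reach a sub-reach descends from) and `geometry`
#'   (optional WKT LINESTRING, decorative).
#' @slot links data.frame with columns `link_id`, `kind`
#'   (confluence/waterfall/anthropogenic), `status` (existing/planned),
#'   `up_reach`, `down_reach`, `pass_up`, `pass_down` (`NA` means "use the
#'   policy default"). Every link joins a reach to its `next_down`
#'   neighbor; several barriers may sit between the same pair.
#'
#' @seealso [buildNetwork()], [splitReachAtBarrier()], [pathLinks()]
#' @exportClass RiverNetwork
setClass("RiverNetwork",
         representation(reaches = "data.frame", links = "data.frame"))

.reachColumns <- c("reach_id", "length_km", "catchment_id", "next_down",
                   "origin", "geometry")
.linkColumns <- c("link_id", "kind", "status", "up_reach", "down_reach",
                  "pass_up", "pass_down")

# Distance-to-outlet walk with cycle detection; returns NULL on success or
# a message describing the cycle.
.checkAcyclic <- function(reach_id, next_down) {
  parent <- match(next_down, reach_id)
  n <- length(parent)
  depth <- rep(NA_integer_, n)
  for (s in seq_len(n)) {
    if (!is.na(depth[s])) next
    path <- integer(0)
    v <- s
    while (!is.na(v) && is.na(depth[v])) {
      if (v %in% path)
        return(sprintf("cycle detected through reach '%s'", reach_id[v]))
      path <- c(path, v)
      v <- parent[v]
    }
    base <- if (is.na(v)) 0L else depth[v]
    depth[rev(path)] <- base + seq_along(path)
  }
  NULL
}

.validateNetwork <- function(object) {
  r <- object@reaches
  l <- object@links
  msgs <- character(0)
  if (!all(.reachColumns %in% names(r)))
    return(paste("reaches must have columns:",
                 paste(.reachColumns, collapse = ", ")))
  if (!all(.linkColumns %in% names(l)))
    return(paste("links must have columns:",
                 paste(.linkColumns, collapse = ", ")))
  if (anyDuplicated(r$reach_id))
    msgs <- c(msgs, "duplicate reach ids")
  if (any(!is.finite(r$length_km)) || any(r$length_km <= 0))
    msgs <- c(msgs, "all reach lengths must be positive and finite")
  known <- is.na(r$next_down) | r$next_down %in% r$reach_id
  if (!all(known))
    msgs <- c(msgs, sprintf("next_down references unknown reach (rows %s)",
                            paste(which(!known), collapse = ", ")))
  if (length(msgs) > 0) return(msgs)
  cyc <- .checkAcyclic(r$reach_id, r$next_down)
  if (!is.null(cyc)) return(cyc)
  # one outlet per catchment; catchment consistent along the flow path
  parent <- match(r$next_down, r$reach_id)
  inner <- !is.na(parent)
  if (any(r$catchment_id[inner] != r$catchment_id[parent[inner]]))
    msgs <- c(msgs, "catchment_id differs between a reach and its next_down")
  outlets <- tapply(is.na(r$next_down), r$catchment_id, sum)
  if (any(outlets != 1L))
    msgs <- c(msgs, sprintf("catchments with != 1 outlet: %s",
                            paste(names(outlets)[outlets != 1L], collapse = ", ")))
  if (nrow(l) > 0) {
    if (anyDuplicated(l$link_id))
      msgs <- c(msgs, "duplicate link ids")
    if (!all(l$kind %in% LINK_KINDS))
      msgs <- c(msgs, "link kind must be confluence, waterfall or anthropogenic")
    if (!all(l$status %in% LINK_STATUS))
      msgs <- c(msgs, "link status must be existing or planned")
    ui <- match(l$up_reach, r$reach_id)
    if (anyNA(ui))
      msgs <- c(msgs, "link up_reach references unknown reach")
    else if (any(is.na(r$next_down[ui]) | r$next_down[ui] != l$down_reach))
      msgs <- c(msgs, "every link must join a reach to its next_down neighbor")
    pv <- c(l$pass_up, l$pass_down)
    if (any(!is.na(pv) & (pv < 0 | pv > 1)))
      msgs <- c(msgs, "explicit link passabilities must lie in [0, 1]")
    conf <- l$kind == "confluence"
    bad <- conf & ((!is.na(l$pass_up) & l$pass_up != 1) |
                   (!is.na(l$pass_down) & l$pass_down != 1))
    if (any(bad))
      msgs <- c(msgs, "confluence links must have passability 1 both ways")
    # forest: each adjacent pair is one tree edge; links only annotate edges
    edge <- paste(l$up_reach, l$down_reach)
    nEdges <- length(unique(edge))
    if (nEdges != sum(!is.na(r$next_down)))
      msgs <- c(msgs, "every non-outlet reach needs links to its next_down")
  }
  if (length(msgs) == 0) TRUE else msgs
}

setValidity("RiverNetwork", .validateNetwork)

#' PassabilityPolicy: default and overridden barrier passabilities
#'
#' Holds the per-kind, per-direction default passabilities applied to
#' barriers without explicit values, optional per-barrier overrides, and the
#' directionality mode. Defaults follow expert-elicited values for large
#' tropical river fish: anthropogenic barriers pass 0.1 upstream and 0.4
#' downstream; natural waterfalls 0.1 upstream and 0.7 downstream;
#' confluences are fully passable.
#'
#' @slot defaults numeric matrix, rows `anthropogenic`/`waterfall`,
#'   columns `up`/`down`, values in \[0, 1\].
#' @slot overrides data.frame `barrier_id`, `pass_up`, `pass_down`.
#' @slot mode `"outgoing"` (direction of travel away from the focal reach
#'   selects `pass_up`/`pass_down`) or `"symmetric"` (geometric mean used
#'   both ways).
#' @slot blockUpstream logical; if TRUE, upstream passage over
#'   anthropogenic barriers is forced to 0 (restrictive sensitivity
#'   scenario).
#' @seealso [passabilityPolicy()], [perturbPolicy()]
#' @exportClass PassabilityPolicy
setClass("PassabilityPolicy",
         representation(defaults = "matrix", overrides = "data.frame",
                        mode = "character", blockUpstream = "logical"))

setValidity("PassabilityPolicy", function(object) {
  d <- object@defaults
  msgs <- character(0)
  if (!identical(rownames(d), c("anthropogenic", "waterfall")) ||
      !identical(colnames(d), c("up", "down")))
    msgs <- c(msgs, "defaults must be a 2x2 matrix [anthropogenic, waterfall] x [up, down]")
  if (any(!is.finite(d)) || any(d < 0 | d > 1))
    msgs <- c(msgs, "default passabilities must lie in [0, 1]")
  ov <- object@overrides
  if (!all(c("barrier_id", "pass_up", "pass_down") %in% names(ov)))
    msgs <- c(msgs, "overrides needs columns barrier_id, pass_up, pass_down")
  else {
    pv <- c(ov$pass_up, ov$pass_down)
    if (any(!is.na(pv) & (pv < 0 | pv > 1)))
      msgs <- c(msgs, "override passabilities must lie in [0, 1]")
  }
  if (!object@mode %in% c("outgoing", "symmetric"))
    msgs <- c(msgs, "mode must be 'outgoing' or 'symmetric'")
  if (length(msgs) == 0) TRUE else msgs
})

#' SuitabilityLayer: per-reach habitat suitability keyed by scenario cell
#'
#' A reach-by-cell matrix of climatic-environmental suitabilities in
#' \[0, 1\], where each cell is a (fish group, climate scenario, epoch)
#' combination. `NA` means "suitability unknown"; downstream weighting
#' treats it as 0 (unsuitable by omission).
#'
#' @slot values numeric matrix, rownames = reach ids, colnames = cell keys.
#' @slot cells data.frame `cell`, `group`, `climate`, `epoch` describing
#'   each column of `values`.
#' @seealso [suitabilityLayer()], [suitabilityFor()], [generateSuitability()]
#' @exportClass SuitabilityLayer
setClass("SuitabilityLayer",
         representation(values = "matrix", cells = "data.frame"))

setValidity("SuitabilityLayer", function(object) {
  v <- object@values
  msgs <- character(0)
  if (is.null(rownames(v))) msgs <- c(msgs, "values must have reach ids as rownames")
  if (any(!is.na(v) & (v < 0 | v > 1)))
    msgs <- c(msgs, "suitabilities must lie in [0, 1]")
  cl <- object@cells
  if (!all(c("cell", "group", "climate", "epoch") %in% names(cl)))
    msgs <- c(msgs, "cells needs columns cell, group, climate, epoch")
  else if (!identical(as.character(cl$cell), colnames(v)))
    msgs <- c(msgs, "cells$cell must match colnames(values)")
  if (length(msgs) == 0) TRUE else msgs
})

#' ConnectivityResult: reach, catchment and summary connectivity indices
#'
#' @slot reaches data.frame `reach_id`, `catchment_id`, `length_km`.
#' @slot cells data.frame, one row per scenario cell (`cell`,
#'   `barrier_set`, `climate`, `epoch`, `group`).
#' @slot rci reach-by-cell matrix of Reach Connectivity Index values.
#' @slot rcisuit reach-by-cell matrix of suitability-weighted RCI.
#' @slot cci catchment-by-cell matrix of Catchment Connectivity Index.
#' @slot summary data.frame per cell: mean, median, max of RCIsuit.
#' @seealso [scenarioGrid()], [summarizeConnectivity()]
#' @exportClass ConnectivityResult
setClass("ConnectivityResult",
         representation(reaches = "data.frame", cells = "data.frame",
                        rci = "matrix", rcisuit = "matrix", cci = "matrix",
                        summary = "data.frame"))

setValidity("ConnectivityResult", function(object) {
  msgs <- character(0)
  for (nm in c("rci", "rcisuit")) {
    m <- slot(object, nm)
    if (any(!is.na(m) & (m < 0 | m > 1)))
      msgs <- c(msgs, sprintf("%s values must lie in [0, 1]", nm))
  }
  ok <- is.na(object@rcisuit) | is.na(object@rci) |
    object@rcisuit <= object@rci + 1e-12
  if (!all(ok)) msgs <- c(msgs, "RCIsuit must not exceed RCI")
  if (length(msgs) == 0) TRUE else msgs
})

#' BarrierImpact: leave-one-out barrier prioritization result
#'
#' Per-barrier connectivity gain on removal (dCCI, in percent) and the
#' resulting priority rank (1 = most impactful; ties get the average of the
#' tied positions). A set of per-cell rankings can be averaged with
#' [meanRank()].
#'
#' @slot table data.frame `barrier_id`, `kind`, `status`, `dCCI`, `rank`,
#'   sorted by decreasing dCCI.
#' @slot cell character scalar identifying the scenario cell (may be `NA`).
#' @seealso [rankBarriers()], [dcci()], [meanRank()]
#' @exportClass BarrierImpact
setClass("BarrierImpact",
         representation(table = "data.frame", cell = "character"))

setValidity("BarrierImpact", function(object) {
  tb <- object@table
  msgs <- character(0)
  if (!all(c("barrier_id", "dCCI", "rank") %in% names(tb)))
    msgs <- c(msgs, "table needs columns barrier_id, dCCI, rank")
  else {
    if (any(tb$dCCI < -1e-9)) msgs <- c(msgs, "dCCI must be nonnegative")
    if (nrow(tb) > 0 && abs(sum(tb$rank) - sum(seq_len(nrow(tb)))) > 1e-9)
      msgs <- c(msgs, "ranks must be a (tie-averaged) permutation")
  }
  if (length(msgs) == 0) TRUE else msgs
})

#' RiverscapeConfig: parameters of the synthetic riverscape generator
#'
#' See [riverscapeConfig()] for the meaning and defaults of every field.
#'
#' @seealso [riverscapeConfig()], [generateRiverscape()]
#' @exportClass RiverscapeConfig
setClass("RiverscapeConfig",
         representation(nReaches = "integer", branchingProb = "numeric",
                        lengthMeanLog = "numeric", lengthSdLog = "numeric",
                        nWaterfalls = "integer", nDamsExisting = "integer",
                        nDamsPlanned = "integer", placement = "character",
                        superBarrier = "logical", suitAutocorr = "numeric",
                        trendModerate = "numeric", trendPessimistic = "numeric",
                        nMigratory = "integer", nSedentary = "integer",
                        seed = "integer"))

setValidity("RiverscapeConfig", function(object) {
  msgs <- character(0)
  if (object@nReaches < 1L) msgs <- c(msgs, "nReaches must be >= 1")
  if (object@branchingProb <= 0 || object@branchingProb >= 1)
    msgs <- c(msgs, "branchingProb must lie in (0, 1)")
  if (object@suitAutocorr < 0 || object@suitAutocorr >= 1)
    msgs <- c(msgs, "suitAutocorr must lie in [0, 1)")
  if (!object@placement %in% c("uniform", "mainstem_biased"))
    msgs <- c(msgs, "placement must be 'uniform' or 'mainstem_biased'")
  # feasibility of barrier counts is checked at placement time
  if (min(object@nWaterfalls, object@nDamsExisting, object@nDamsPlanned) < 0L)
    msgs <- c(msgs, "barrier counts must be nonnegative")
  if (length(msgs) == 0) TRUE else msgs
})
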