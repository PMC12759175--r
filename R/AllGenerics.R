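#' @rdname RiverNetwork-class
#' @param x a `RiverNetwork`
#' @export
setGeneric("reaches", function(x) standardGeneric("reaches"))

#' @rdname RiverNetwork-class
#' @export
setGeneric("links", function(x) standardGeneric("links"))

#' @rdname RiverNetwork-class
#' @export
setGeneric("nReaches", function(x) standardGeneric("nReaches"))

#' @rdname RiverNetwork-class
#' @export
setGeneric("nLinks", function(x) standardGeneric("nLinks"))

#' @rdname RiverNetwork-class
#' @export
setGeneric("outlets", function(x) standardGeneric("outlets"))

#' @rdname RiverNetwork-class
#' @export
setGeneric("catchments", function(x) standardGeneric("catchments"))

#' @rdname RiverNetwork-class
#' @export
setGeneric("totalLength", function(x) standardGeneric("totalLength"))

#' @rdname BarrierImpact-class
#' @param x a `BarrierImpact`
#' @export
setGeneric("impactTable", function(x) standardGeneric("impactTable"))

#' Extract one per-reach suitability vector from a layer
#'
#' @param x a [SuitabilityLayer][SuitabilityLayer-class]
#' @param group,climate,epoch the scenario cell key
#' @return named numeric vector over reaches
#' @export
setGeneric("suitabilityFor",
           function(x, group = "combined", climate = "current",
                    epoch = "current") standardGeneric("suitabilityFor"))

#' @rdname RiverNetwork-class
setMethod("reaches", "RiverNetwork", function(x) x@reaches)
#' @rdname RiverNetwork-class
setMethod("links", "RiverNetwork", function(x) x@links)
#' @rdname RiverNetwork-class
setMethod("nReaches", "RiverNetwork", function(x) nrow(x@reaches))
#' @rdname RiverNetwork-class
setMethod("nLinks", "RiverNetwork", function(x) nrow(x@links))
#' @rdname RiverNetwork-class
setMethod("outlets", "RiverNetwork",
          function(x) x@reaches$reach_id[is.na(x@reaches$next_down)])
#' @rdname RiverNetwork-class
setMethod("catchments", "RiverNetwork",
          function(x) sort(unique(x@reaches$catchment_id)))
#' @rdname RiverNetwork-class
setMethod("totalLength", "RiverNetwork", function(x) sum(x@reaches$length_km))

#' @rdname BarrierImpact-class
setMethod("impactTable", "BarrierImpact", function(x) x@table)

setMethod("suitabilityFor", "SuitabilityLayer",
          function(x, group = "combined", climate = "current",
                   epoch = "current") {
  key <- cellKey(group, climate, epoch)
  j <- match(key, colnames(x@values))
  if (is.na(j))
    stop("no suitability layer for cell '", key, "'", call. = FALSE)
  x@values[, j]
})

#' Build the canonical key of a scenario cell
#'
#' @param group,climate,epoch cell coordinates
#' @param barrier_set optional barrier set prefix
#' @return character key, e.g. `"combined|pessimistic|2090"`
#' @export
cellKey <- function(group, climate, epoch, barrier_set = NULL) {
  base <- paste(group, climate, epoch, sep = "|")
  if (is.null(barrier_set)) base else paste(barrier_set, base, sep = "|")
}

setMethod("show", "RiverNetwork", function(object) {
  l <- object@links
  nb <- sum(l$kind != "confluence")
  cat(sprintf("RiverNetwork: %d reaches (%.1f km) in %d catchment(s)\n",
              nrow(object@reaches), sum(object@reaches$length_km),
              length(unique(object@reaches$catchment_id))))
  cat(sprintf("  links: %d (%d confluences, %d waterfalls, %d dams; %d planned)\n",
              nrow(l), sum(l$kind == "confluence"),
              sum(l$kind == "waterfall"), sum(l$kind == "anthropogenic"),
              sum(l$status == "planned")))
})

setMethod("show", "PassabilityPolicy", function(object) {
  d <- object@defaults
  cat(sprintf("PassabilityPolicy (%s mode%s)\n", object@mode,
              if (object@blockUpstream) ", upstream blocked" else ""))
  cat(sprintf("  anthropogenic: up %.3g / down %.3g\n",
              d["anthropogenic", "up"], d["anthropogenic", "down"]))
  cat(sprintf("  waterfall:     up %.3g / down %.3g\n",
              d["waterfall", "up"], d["waterfall", "down"]))
  if (nrow(object@overrides) > 0)
    cat(sprintf("  overrides: %d barrier(s)\n", nrow(object@overrides)))
})

setMethod("show", "SuitabilityLayer", function(object) {
  cat(sprintf("SuitabilityLayer: %d reaches x %d cells\n",
              nrow(object@values), ncol(object@values)))
  cl <- object@cells
  cat(sprintf("  groups: %s | climates: %s | epochs: %s\n",
              paste(unique(cl$group), collapse = ", "),
              paste(unique(cl$climate), collapse = ", "),
              paste(unique(cl$epoch), collapse = ", ")))
})

setMethod("show", "ConnectivityResult", function(object) {
  cat(sprintf("ConnectivityResult: %d reaches, %d catchments, %d scenario cells\n",
              nrow(object@reaches), nrow(object@cci), nrow(object@cells)))
  if (nrow(object@summary) > 0) {
    cat("  RCIsuit summary (first cells):\n")
    print(utils::head(object@summary, 4), row.names = FALSE)
  }
})

setMethod("show", "BarrierImpact", function(object) {
  cat(sprintf("BarrierImpact%s: %d candidate barrier(s)\n",
              if (!is.na(object@cell)) paste0(" [", object@cell, "]") else "",
              nrow(object@table)))
  print(utils::head(object@table, 5), row.names = FALSE)
})

setMethod("show", "RiverscapeConfig", function(object) {
  cat(sprintf(paste0("RiverscapeConfig: %d reaches, branching %.2f, ",
                     "%d falls + %d dams + %d planned%s, seed %d\n"),
              object@nReaches, object@branchingProb, object@nWaterfalls,
              object@nDamsExisting, object@nDamsPlanned,
              if (object@superBarrier) " + super-barrier" else "",
              object@seed))
})
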