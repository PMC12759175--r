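#' Read reach and barrier tables and assemble the network
#'
#' Reads `reaches.csv` (`reach_id`, `length_km`, `next_down`, optional
#' `catchment_id`, `geometry`) and optionally `barriers.csv`
#' (`barrier_id`, `kind`, `status`, `reach_id` + `fraction` or
#' `up_reach` + `down_reach`, optional `pass_up`, `pass_down`), validates
#' them (errors name the offending rows), and builds the network. Unknown
#' columns are preserved in the input but ignored.
#'
#' @param reaches_path path to reaches.csv
#' @param barriers_path optional path to barriers.csv
#' @return a [RiverNetwork][RiverNetwork-class]
#' @export
readNetwork <- function(reaches_path, barriers_path = NULL) {
  rt <- utils::read.csv(reaches_path, stringsAsFactors = FALSE)
  miss <- setdiff(c("reach_id", "length_km", "next_down"), names(rt))
  if (length(miss) > 0)
    stop(basename(reaches_path), ": missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  suppressWarnings(len <- as.numeric(rt$length_km))
  if (anyNA(len))
    stop(basename(reaches_path), ": non-numeric length_km (rows ",
         paste(which(is.na(len)), collapse = ", "), ")", call. = FALSE)
  bt <- NULL
  if (!is.null(barriers_path)) {
    bt <- utils::read.csv(barriers_path, stringsAsFactors = FALSE)
    miss <- setdiff(c("barrier_id", "kind"), names(bt))
    if (length(miss) > 0)
      stop(basename(barriers_path), ": missing required column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  tryCatch(buildNetwork(rt, bt),
           error = function(e) stop(basename(reaches_path), "/",
                                    if (is.null(barriers_path)) "" else
                                      basename(barriers_path), ": ",
                                    conditionMessage(e), call. = FALSE))
}

#' Read a long-format suitability table into a layer
#'
#' Expects columns `reach_id`, `group`, `climate`, `epoch`, `suitability`.
#'
#' @param path path to suitability.csv
#' @return a [SuitabilityLayer][SuitabilityLayer-class]
#' @export
readSuitability <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("reach_id", "group", "climate", "epoch", "suitability")
  if ("epoch" %in% names(x)) x$epoch <- as.character(x$epoch)
  miss <- setdiff(req, names(x))
  if (length(miss) > 0)
    stop(basename(path), ": missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!is.na(x$suitability) &
                 (x$suitability < 0 | x$suitability > 1))
  if (length(bad) > 0)
    stop(basename(path), ": suitability outside [0, 1] (rows ",
         paste(bad, collapse = ", "), ")", call. = FALSE)
  key <- cellKey(x$group, x$climate, x$epoch)
  cells <- unique(data.frame(cell = key, group = x$group,
                             climate = x$climate, epoch = x$epoch,
                             stringsAsFactors = FALSE))
  ids <- unique(x$reach_id)
  vals <- matrix(NA_real_, length(ids), nrow(cells),
                 dimnames = list(ids, cells$cell))
  vals[cbind(match(x$reach_id, ids), match(key, cells$cell))] <- x$suitability
  suitabilityLayer(vals, cells)
}

#' Read a complete input set from a directory
#'
#' @param dir directory holding `reaches.csv`, optional `barriers.csv`
#'   and optional `suitability.csv`
#' @return list `network`, `policy` (defaults), `suitability` (or `NULL`)
#' @export
readInputs <- function(dir) {
  rp <- file.path(dir, "reaches.csv")
  if (!file.exists(rp)) stop("no reaches.csv in ", dir, call. = FALSE)
  bp <- file.path(dir, "barriers.csv")
  sp <- file.path(dir, "suitability.csv")
  list(network = readNetwork(rp, if (file.exists(bp)) bp else NULL),
       policy = passabilityPolicy(),
       suitability = if (file.exists(sp)) readSuitability(sp) else NULL)
}

#' Write a riverscape (network + suitability) as CSV inputs
#'
#' Emits `reaches.csv`, `barriers.csv` and `suitability.csv` in the
#' schemas accepted by [readInputs()]. Barrier links are exported in
#' `up_reach`/`down_reach` form (splitting already applied).
#'
#' @param network a [RiverNetwork][RiverNetwork-class]
#' @param suitability optional [SuitabilityLayer][SuitabilityLayer-class]
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
writeRiverscape <- function(network, suitability = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  r <- network@reaches
  paths <- file.path(dir, "reaches.csv")
  utils::write.csv(r[, c("reach_id", "length_km", "catchment_id",
                         "next_down", "geometry")],
                   paths, row.names = FALSE, na = "")
  l <- network@links
  b <- l[l$kind != "confluence", , drop = FALSE]
  if (nrow(b) > 0) {
    bp <- file.path(dir, "barriers.csv")
    utils::write.csv(data.frame(barrier_id = b$link_id, kind = b$kind,
                                status = b$status, up_reach = b$up_reach,
                                down_reach = b$down_reach,
                                pass_up = b$pass_up, pass_down = b$pass_down),
                     bp, row.names = FALSE, na = "")
    paths <- c(paths, bp)
  }
  if (!is.null(suitability)) {
    cl <- suitability@cells
    v <- suitability@values
    long <- data.frame(reach_id = rep(rownames(v), ncol(v)),
                       group = rep(cl$group, each = nrow(v)),
                       climate = rep(cl$climate, each = nrow(v)),
                       epoch = rep(cl$epoch, each = nrow(v)),
                       suitability = signif(as.vector(v), 6),
                       stringsAsFactors = FALSE)
    sp <- file.path(dir, "suitability.csv")
    utils::write.csv(long, sp, row.names = FALSE, na = "")
    paths <- c(paths, sp)
  }
  invisible(paths)
}

.fmtNum <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  df
}

#' Write analysis outputs and a run manifest
#'
#' Emits `rci.csv` (long per-reach table), `cci.csv`, `summary.csv`, and
#' when supplied `ranking.csv` and `sensitivity.csv`, all with a
#' deterministic column order and 6 significant digits, plus
#' `manifest.json` recording the seed, config and package version. Two
#' identical runs produce byte-identical outputs.
#'
#' @param result a [ConnectivityResult][ConnectivityResult-class]
#' @param ranking optional list of
#'   [BarrierImpact][BarrierImpact-class] (per cell) or a single object
#' @param sensitivity optional data.frame from [sensitivityGrid()]
#' @param dir output directory (created if needed)
#' @param seed,config recorded in the manifest
#' @return invisibly, the paths written
#' @export
writeResults <- function(result, ranking = NULL, sensitivity = NULL, dir,
                         seed = NA_integer_, config = list()) {
  stopifnot(is(result, "ConnectivityResult"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cl <- result@cells
  n <- nrow(result@reaches)
  long <- data.frame(reach_id = rep(result@reaches$reach_id, nrow(cl)),
                     barrier_set = rep(cl$barrier_set, each = n),
                     climate = rep(cl$climate, each = n),
                     epoch = rep(cl$epoch, each = n),
                     group = rep(cl$group, each = n),
                     RCI = as.vector(result@rci),
                     RCIsuit = as.vector(result@rcisuit),
                     stringsAsFactors = FALSE)
  paths <- file.path(dir, "rci.csv")
  utils::write.csv(.fmtNum(long), paths, row.names = FALSE, na = "")
  ccl <- data.frame(catchment_id = rep(rownames(result@cci), nrow(cl)),
                    cell = rep(cl$cell, each = nrow(result@cci)),
                    CCI = as.vector(result@cci), stringsAsFactors = FALSE)
  p <- file.path(dir, "cci.csv")
  utils::write.csv(.fmtNum(ccl), p, row.names = FALSE, na = "")
  paths <- c(paths, p)
  p <- file.path(dir, "summary.csv")
  utils::write.csv(.fmtNum(result@summary), p, row.names = FALSE, na = "")
  paths <- c(paths, p)
  if (!is.null(ranking)) {
    if (is(ranking, "BarrierImpact")) ranking <- list(ranking)
    rows <- lapply(ranking, function(bi)
      cbind(cell = bi@cell, impactTable(bi), stringsAsFactors = FALSE))
    rk <- do.call(rbind, rows)
    if (length(ranking) > 1) {
      # cells may rank different candidate sets; average within each set
      sig <- vapply(ranking, function(bi)
        paste(sort(impactTable(bi)$barrier_id), collapse = ";"),
        character(1))
      mr <- do.call(rbind, lapply(unique(sig), function(s)
        meanRank(ranking[sig == s])))
      rk$mean_rank <- mr$mean_rank[match(rk$barrier_id, mr$barrier_id)]
    }
    p <- file.path(dir, "ranking.csv")
    utils::write.csv(.fmtNum(rk), p, row.names = FALSE, na = "")
    paths <- c(paths, p)
  }
  if (!is.null(sensitivity)) {
    p <- file.path(dir, "sensitivity.csv")
    utils::write.csv(.fmtNum(sensitivity), p, row.names = FALSE, na = "")
    paths <- c(paths, p)
  }
  manifest <- list(package = "riverfrag",
                   version = as.character(utils::packageVersion("riverfrag")),
                   seed = seed, config = config,
                   files = basename(paths))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(paths, file.path(dir, "manifest.json")))
}
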