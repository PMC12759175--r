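#' Assemble a validated river network from reach and barrier tables
#'
#' Turns a next-down reach table (HydroRIVERS-style topology) and a barrier
#' inventory into a [RiverNetwork][RiverNetwork-class]. Adjacent reaches
#' without a barrier record are joined by an implicit, fully passable
#' confluence link. Barriers located by `(reach_id, fraction)` split the
#' host reach at that position (see [splitReachAtBarrier()]); barriers
#' located by `(up_reach, down_reach)` attach to the existing edge.
#'
#' @param reach_table data.frame with columns `reach_id`, `length_km`,
#'   `next_down` (empty/`NA` for the outlet) and optionally `catchment_id`
#'   (derived from the outlet id when absent) and `geometry` (WKT).
#' @param barrier_table optional data.frame with columns `barrier_id`,
#'   `kind` (`waterfall`/`anthropogenic`), `status` (`existing`/`planned`),
#'   and either `reach_id` + `fraction` or `up_reach` + `down_reach`;
#'   optional `pass_up`, `pass_down` in \[0, 1\] override policy defaults.
#' @return a validated `RiverNetwork`
#' @examples
#' rt <- data.frame(reach_id = c("A", "B"), length_km = c(1, 1),
#'                  next_down = c("B", NA))
#' net <- buildNetwork(rt)
#' nLinks(net)  # one implicit confluence
#' @export
buildNetwork <- function(reach_table, barrier_table = NULL) {
  r <- as.data.frame(reach_table, stringsAsFactors = FALSE)
  req <- c("reach_id", "length_km", "next_down")
  miss <- setdiff(req, names(r))
  if (length(miss) > 0)
    stop("reach table misses column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  r$reach_id <- as.character(r$reach_id)
  nd <- as.character(r$next_down)
  nd[!is.na(nd) & !nzchar(trimws(nd))] <- NA_character_
  r$next_down <- nd
  if (anyDuplicated(r$reach_id))
    stop("duplicate reach ids: ",
         paste(unique(r$reach_id[duplicated(r$reach_id)]), collapse = ", "),
         call. = FALSE)
  r$length_km <- as.numeric(r$length_km)
  if (any(!is.finite(r$length_km) | r$length_km <= 0))
    stop("non-positive or non-numeric length_km (rows ",
         paste(which(!is.finite(r$length_km) | r$length_km <= 0),
               collapse = ", "), ")", call. = FALSE)
  bad <- !is.na(r$next_down) & !(r$next_down %in% r$reach_id)
  if (any(bad))
    stop("next_down references unknown reach (rows ",
         paste(which(bad), collapse = ", "), ")", call. = FALSE)
  cyc <- .checkAcyclic(r$reach_id, r$next_down)
  if (!is.null(cyc)) stop(cyc, call. = FALSE)
  if (is.null(r$catchment_id)) r$catchment_id <- .deriveCatchments(r)
  r$catchment_id <- as.character(r$catchment_id)
  if (is.null(r$origin)) r$origin <- r$reach_id
  if (is.null(r$geometry)) r$geometry <- NA_character_
  r <- r[, .reachColumns]

  net <- new("RiverNetwork", reaches = r, links = .emptyLinks())
  if (!is.null(barrier_table) && nrow(barrier_table) > 0)
    net <- .attachBarriers(net, as.data.frame(barrier_table,
                                              stringsAsFactors = FALSE))
  net@links <- .addConfluences(net@reaches, net@links)
  validObject(net)
  net
}

.emptyLinks <- function() {
  data.frame(link_id = character(0), kind = character(0),
             status = character(0), up_reach = character(0),
             down_reach = character(0), pass_up = numeric(0),
             pass_down = numeric(0), stringsAsFactors = FALSE)
}

# catchment id = outlet reach id, found by following next_down
.deriveCatchments <- function(r) {
  parent <- match(r$next_down, r$reach_id)
  out <- character(nrow(r))
  for (s in seq_len(nrow(r))) {
    v <- s
    while (!is.na(parent[v])) v <- parent[v]
    out[s] <- r$reach_id[v]
  }
  out
}

.linkRow <- function(link_id, kind, status, up, down,
                     pass_up = NA_real_, pass_down = NA_real_) {
  data.frame(link_id = link_id, kind = kind, status = status,
             up_reach = up, down_reach = down,
             pass_up = as.numeric(pass_up), pass_down = as.numeric(pass_down),
             stringsAsFactors = FALSE)
}

.attachBarriers <- function(net, b) {
  req <- c("barrier_id", "kind")
  miss <- setdiff(req, names(b))
  if (length(miss) > 0)
    stop("barrier table misses column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  b$barrier_id <- as.character(b$barrier_id)
  if (anyDuplicated(b$barrier_id))
    stop("duplicate barrier ids", call. = FALSE)
  if (!all(b$kind %in% c("waterfall", "anthropogenic")))
    stop("barrier kind must be 'waterfall' or 'anthropogenic'", call. = FALSE)
  if (is.null(b$status)) b$status <- "existing"
  b$status[is.na(b$status)] <- "existing"
  if (!all(b$status %in% LINK_STATUS))
    stop("barrier status must be 'existing' or 'planned'", call. = FALSE)
  for (col in c("pass_up", "pass_down"))
    if (is.null(b[[col]])) b[[col]] <- NA_real_ else
      b[[col]] <- as.numeric(b[[col]])
  pv <- c(b$pass_up, b$pass_down)
  if (any(!is.na(pv) & (pv < 0 | pv > 1))) {
    i <- which(!is.na(b$pass_up) & (b$pass_up < 0 | b$pass_up > 1) |
               !is.na(b$pass_down) & (b$pass_down < 0 | b$pass_down > 1))
    stop("barrier passability outside [0, 1] (rows ",
         paste(i, collapse = ", "), ")", call. = FALSE)
  }
  hasPair <- !is.null(b$up_reach) && !is.null(b$down_reach)
  hasFrac <- !is.null(b$reach_id) && !is.null(b$fraction)
  byPair <- if (hasPair) !is.na(b$up_reach) & nzchar(as.character(b$up_reach))
            else rep(FALSE, nrow(b))
  byFrac <- if (hasFrac) !is.na(b$fraction) & !byPair else rep(FALSE, nrow(b))
  if (any(!byPair & !byFrac))
    stop("barrier rows need either up_reach/down_reach or reach_id/fraction (rows ",
         paste(which(!byPair & !byFrac), collapse = ", "), ")", call. = FALSE)

  # pair-located barriers attach to the existing edge
  for (i in which(byPair)) {
    up <- as.character(b$up_reach[i]); down <- as.character(b$down_reach[i])
    k <- match(up, net@reaches$reach_id)
    if (is.na(k) || !(down %in% net@reaches$reach_id))
      stop("barrier '", b$barrier_id[i], "' references unknown reach",
           call. = FALSE)
    if (is.na(net@reaches$next_down[k]) || net@reaches$next_down[k] != down)
      stop("barrier '", b$barrier_id[i],
           "': reaches are not upstream/downstream neighbors", call. = FALSE)
    net@links <- rbind(net@links,
                       .linkRow(b$barrier_id[i], b$kind[i], b$status[i],
                                up, down, b$pass_up[i], b$pass_down[i]))
  }

  # fraction-located barriers split their host reach, upstream-most first
  fb <- b[byFrac, , drop = FALSE]
  if (nrow(fb) > 0) {
    fb$reach_id <- as.character(fb$reach_id)
    fb$fraction <- as.numeric(fb$fraction)
    if (any(fb$fraction <= 0 | fb$fraction >= 1))
      stop("barrier fraction must lie in (0, 1)", call. = FALSE)
    for (rid in unique(fb$reach_id)) {
      if (!rid %in% net@reaches$reach_id)
        stop("barrier references unknown reach '", rid, "'", call. = FALSE)
      rows <- fb[fb$reach_id == rid, , drop = FALSE]
      rows <- rows[order(rows$fraction), , drop = FALSE]
      L <- net@reaches$length_km[net@reaches$reach_id == rid]
      offset <- 0; lastUp <- NA_character_
      for (i in seq_len(nrow(rows))) {
        pos <- rows$fraction[i] * L
        spec <- list(link_id = rows$barrier_id[i], kind = rows$kind[i],
                     status = rows$status[i], pass_up = rows$pass_up[i],
                     pass_down = rows$pass_down[i])
        if (pos - offset < 1e-12 && !is.na(lastUp)) {
          # coincident barriers: parallel links on the same edge
          net@links <- rbind(net@links,
                             .linkRow(spec$link_id, spec$kind, spec$status,
                                      lastUp, rid, spec$pass_up,
                                      spec$pass_down))
          next
        }
        local <- (pos - offset) /
          net@reaches$length_km[net@reaches$reach_id == rid]
        net <- splitReachAtBarrier(net, rid, local, spec, validate = FALSE)
        lastUp <- attr(net, "lastSplitUpstream")
        offset <- pos
      }
    }
  }
  net
}

.addConfluences <- function(r, l) {
  linked <- unique(l$up_reach)
  need <- which(!is.na(r$next_down) & !(r$reach_id %in% linked))
  if (length(need) > 0) {
    conf <- .linkRow(paste0("CONF_", r$reach_id[need]), "confluence",
                     "existing", r$reach_id[need], r$next_down[need], 1, 1)
    l <- rbind(l, conf)
  }
  rownames(l) <- NULL
  l
}

#' Split a reach in two at a barrier position
#'
#' Replaces one reach by an upstream part of length `fraction * L` and a
#' downstream part of length `(1 - fraction) * L`, joined by the supplied
#' barrier link. The downstream part keeps the original reach id (and its
#' downstream pointer); the upstream part gets a derived id and inherits
#' upstream neighbors. Both record the original id in `origin`, so
#' suitability keyed on pre-split reaches still applies. Total network
#' length is conserved.
#'
#' @param network a [RiverNetwork][RiverNetwork-class]
#' @param reach_id reach to split
#' @param fraction barrier position as distance from the upstream end,
#'   as a fraction of reach length, in (0, 1)
#' @param barrier list with `link_id`, `kind`, `status` and optional
#'   `pass_up`, `pass_down`
#' @param validate run class validity after the edit (default TRUE)
#' @return the edited `RiverNetwork`
#' @export
splitReachAtBarrier <- function(network, reach_id, fraction, barrier,
                                validate = TRUE) {
  stopifnot(is(network, "RiverNetwork"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stop("fraction must lie strictly between 0 and 1", call. = FALSE)
  r <- network@reaches
  k <- match(reach_id, r$reach_id)
  if (is.na(k)) stop("unknown reach '", reach_id, "'", call. = FALSE)
  newId <- reach_id
  repeat {
    newId <- paste0(newId, "u")
    if (!newId %in% r$reach_id) break
  }
  L <- r$length_km[k]
  upRow <- r[k, , drop = FALSE]
  upRow$reach_id <- newId
  upRow$length_km <- fraction * L
  upRow$next_down <- reach_id
  upRow$geometry <- NA_character_
  r$length_km[k] <- (1 - fraction) * L
  r$geometry[k] <- NA_character_
  r$next_down[!is.na(r$next_down) & r$next_down == reach_id &
                r$reach_id != newId] <- newId
  r <- rbind(r[seq_len(k - 1), , drop = FALSE], upRow,
             r[seq(k, nrow(r)), , drop = FALSE])
  rownames(r) <- NULL
  l <- network@links
  l$down_reach[l$down_reach == reach_id] <- newId
  bl <- .linkRow(barrier$link_id, barrier$kind,
                 if (is.null(barrier$status)) "existing" else barrier$status,
                 newId, reach_id,
                 if (is.null(barrier$pass_up)) NA_real_ else barrier$pass_up,
                 if (is.null(barrier$pass_down)) NA_real_ else barrier$pass_down)
  network@reaches <- r
  network@links <- rbind(l, bl)
  if (validate) validObject(network)
  attr(network, "lastSplitUpstream") <- newId
  network
}

#' Links along the unique tree path between two reaches
#'
#' Returns the links encountered travelling from reach `i` toward reach
#' `j`: a (possibly empty) downstream leg to the common ancestor followed
#' by an upstream leg, with the traversal direction recorded per link.
#' Reaches in different catchments are not connected and raise an error.
#'
#' @param network a [RiverNetwork][RiverNetwork-class]
#' @param i,j reach ids
#' @return data.frame of link rows plus a `direction` column
#'   (`"downstream"`/`"upstream"`); zero rows when `i == j`
#' @export
pathLinks <- function(network, i, j) {
  r <- network@reaches
  ki <- match(i, r$reach_id); kj <- match(j, r$reach_id)
  if (is.na(ki) || is.na(kj))
    stop("unknown reach id", call. = FALSE)
  if (r$catchment_id[ki] != r$catchment_id[kj])
    stop("reaches '", i, "' and '", j, "' lie in different catchments",
         call. = FALSE)
  parent <- match(r$next_down, r$reach_id)
  anc <- function(k) {
    out <- k
    while (!is.na(parent[k])) { k <- parent[k]; out <- c(out, k) }
    out
  }
  ai <- anc(ki); aj <- anc(kj)
  common <- intersect(ai, aj)
  lca <- common[1]  # first common ancestor walking up from i
  downLeg <- ai[seq_len(which(ai == lca) - 1)]            # i ... below lca
  upLeg <- rev(aj[seq_len(which(aj == lca) - 1)])         # below lca ... j
  l <- network@links
  edgeLinks <- function(upIdx) which(l$up_reach == r$reach_id[upIdx])
  rows <- list()
  for (k in downLeg)
    rows[[length(rows) + 1]] <- cbind(l[edgeLinks(k), , drop = FALSE],
                                      direction = "downstream")
  for (k in upLeg)
    rows[[length(rows) + 1]] <- cbind(l[edgeLinks(k), , drop = FALSE],
                                      direction = "upstream")
  if (length(rows) == 0) {
    out <- cbind(l[integer(0), , drop = FALSE], direction = character(0))
  } else out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
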