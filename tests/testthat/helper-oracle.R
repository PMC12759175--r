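# Independent brute-force oracle for the connectivity indices: explicit
# path enumeration with igraph, and a naive re-statement of the
# passability-resolution rules. Shares no code with the production
# two-pass traversal.

oraclePass <- function(link, policy, barrier_set, removed = character(0),
                       direction) {
  if (link$kind == "confluence") return(1)
  if (link$status == "planned" && barrier_set != "future") return(1)
  if (link$kind == "anthropogenic" && barrier_set == "baseline") return(1)
  if (link$link_id %in% removed) return(1)
  ov <- policy@overrides
  k <- match(link$link_id, ov$barrier_id)
  up <- if (!is.na(k) && !is.na(ov$pass_up[k])) ov$pass_up[k] else
    if (!is.na(link$pass_up)) link$pass_up else
      policy@defaults[link$kind, "up"]
  dn <- if (!is.na(k) && !is.na(ov$pass_down[k])) ov$pass_down[k] else
    if (!is.na(link$pass_down)) link$pass_down else
      policy@defaults[link$kind, "down"]
  if (policy@blockUpstream && link$kind == "anthropogenic") up <- 0
  if (policy@mode == "symmetric") return(sqrt(up * dn))
  if (direction == "up") up else dn
}

# cumulative passability between two reaches by explicit graph search
oracleCij <- function(net, policy, from, to, barrier_set = "current",
                      removed = character(0), g = NULL) {
  r <- reaches(net)
  l <- links(net)
  if (is.null(g)) g <- oracleGraph(net)
  vp <- suppressWarnings(
    igraph::shortest_paths(g, from = from, to = to, mode = "all")$vpath[[1]])
  ids <- names(vp)
  if (length(ids) == 0) return(NA_real_)  # disconnected
  c_ij <- 1
  nd <- setNames(r$next_down, r$reach_id)
  for (s in seq_len(length(ids) - 1)) {
    a <- ids[s]; b <- ids[s + 1]
    if (!is.na(nd[a]) && nd[a] == b) {        # moving downstream over edge a->b
      rows <- which(l$up_reach == a)
      dirn <- "down"
    } else {                                  # moving upstream over edge b->a
      rows <- which(l$up_reach == b)
      dirn <- "up"
    }
    for (i in rows)
      c_ij <- c_ij * oraclePass(l[i, ], policy, barrier_set, removed, dirn)
  }
  c_ij
}

oracleGraph <- function(net) {
  r <- reaches(net)
  e <- r[!is.na(r$next_down), c("reach_id", "next_down")]
  igraph::graph_from_data_frame(e, directed = FALSE,
                                vertices = data.frame(name = r$reach_id))
}

# RCI by enumerating all ordered pairs within each catchment
oracleRci <- function(net, policy = passabilityPolicy(),
                      barrier_set = "current", removed = character(0)) {
  r <- reaches(net)
  g <- oracleGraph(net)
  out <- setNames(numeric(nrow(r)), r$reach_id)
  for (i in r$reach_id) {
    same <- r$catchment_id == r$catchment_id[match(i, r$reach_id)]
    W <- sum(r$length_km[same])
    acc <- 0
    for (k in which(same)) {
      j <- r$reach_id[k]
      cij <- if (i == j) 1 else oracleCij(net, policy, i, j, barrier_set,
                                          removed, g)
      acc <- acc + cij * r$length_km[k]
    }
    out[i] <- acc / W
  }
  out
}

oracleCci <- function(net, policy, suitability, barrier_set = "current",
                      removed = character(0)) {
  r <- reaches(net)
  rciV <- oracleRci(net, policy, barrier_set, removed)
  u <- suitability[r$reach_id]
  u[is.na(u)] <- 0
  tapply(u * rciV[r$reach_id], r$catchment_id, sum) /
    tapply(u, r$catchment_id, sum)
}
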