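#' Construct a passability policy
#'
#' @param anthropogenic,waterfall length-2 numeric `(up, down)` default
#'   passabilities for each barrier kind. Defaults are the conservative
#'   expert-elicited values for large tropical river fish (dams: 0.1 up /
#'   0.4 down; waterfalls: 0.1 up / 0.7 down).
#' @param overrides optional data.frame `barrier_id`, `pass_up`,
#'   `pass_down`; takes precedence over both defaults and per-link values.
#' @param mode `"outgoing"` (default) or `"symmetric"`.
#' @param blockUpstream force upstream passability of anthropogenic
#'   barriers to 0 (restrictive sensitivity scenario).
#' @return a [PassabilityPolicy][PassabilityPolicy-class]
#' @export
passabilityPolicy <- function(anthropogenic = c(0.1, 0.4),
                              waterfall = c(0.1, 0.7),
                              overrides = NULL, mode = "outgoing",
                              blockUpstream = FALSE) {
  d <- rbind(anthropogenic = anthropogenic, waterfall = waterfall)
  colnames(d) <- c("up", "down")
  if (is.null(overrides))
    overrides <- data.frame(barrier_id = character(0), pass_up = numeric(0),
                            pass_down = numeric(0), stringsAsFactors = FALSE)
  obj <- new("PassabilityPolicy", defaults = d,
             overrides = as.data.frame(overrides, stringsAsFactors = FALSE),
             mode = mode, blockUpstream = blockUpstream)
  validObject(obj)
  obj
}

# Resolve per-link (pass_up, pass_down) given policy, active barrier set and
# a "removed" set (leave-one-out: treated as fully passable, topology kept).
# Precedence: removed/inactive > policy overrides > explicit link values >
# kind defaults. Returns a 2-column matrix aligned with the links table.
.resolveLinkPass <- function(links, policy, barrier_set = "current",
                             removed = character(0)) {
  barrier_set <- match.arg(barrier_set, BARRIER_SETS)
  d <- policy@defaults
  ov <- policy@overrides
  kind <- links$kind
  pu <- ov$pass_up[match(links$link_id, ov$barrier_id)]
  pd <- ov$pass_down[match(links$link_id, ov$barrier_id)]
  pu[is.na(pu)] <- links$pass_up[is.na(pu)]
  pd[is.na(pd)] <- links$pass_down[is.na(pd)]
  isBar <- kind != "confluence"
  pu[is.na(pu) & isBar] <- d[kind[is.na(pu) & isBar], "up"]
  pd[is.na(pd) & isBar] <- d[kind[is.na(pd) & isBar], "down"]
  if (policy@blockUpstream) pu[kind == "anthropogenic"] <- 0
  inactive <- !isBar |
    (links$status == "planned" & barrier_set != "future") |
    (kind == "anthropogenic" & barrier_set == "baseline") |
    links$link_id %in% removed
  pu[inactive] <- 1
  pd[inactive] <- 1
  if (policy@mode == "symmetric") {
    g <- sqrt(pu * pd)
    pu <- g; pd <- g
  }
  cbind(up = pu, down = pd)
}

# product of parallel-link passabilities per tree edge (edge e(v) joins
# reach v to its next_down parent)
.edgeProducts <- function(n, upIdx, pass) {
  pu <- rep(1, n); pd <- rep(1, n)
  if (length(upIdx) > 0) {
    gu <- tapply(pass[, "up"], upIdx, prod)
    gd <- tapply(pass[, "down"], upIdx, prod)
    at <- as.integer(names(gu))
    pu[at] <- as.numeric(gu)
    pd[at] <- as.numeric(gd)
  }
  list(pu = pu, pd = pd)
}

# Precompute the rooted-forest structure and per-edge passability products.
.prepareNetwork <- function(network, policy, barrier_set = "current",
                            removed = character(0)) {
  r <- network@reaches
  l <- network@links
  parent <- match(r$next_down, r$reach_id)
  pass <- .resolveLinkPass(l, policy, barrier_set, removed)
  upIdx <- match(l$up_reach, r$reach_id)
  ep <- .edgeProducts(nrow(r), upIdx, pass)
  pu <- ep$pu; pd <- ep$pd
  comp <- match(r$catchment_id, unique(r$catchment_id))
  W <- as.numeric(tapply(r$length_km, comp, sum))[comp]
  # children-first (reverse BFS) order
  roots <- which(is.na(parent))
  order <- integer(nrow(r))
  order[seq_along(roots)] <- roots
  head <- 1L; tail <- length(roots)
  childList <- split(seq_len(nrow(r))[!is.na(parent)],
                     factor(parent[!is.na(parent)], levels = seq_len(nrow(r))))
  while (head <= tail) {
    v <- order[head]; head <- head + 1L
    ch <- childList[[v]]
    if (length(ch) > 0) {
      order[tail + seq_along(ch)] <- ch
      tail <- tail + length(ch)
    }
  }
  list(reach_id = r$reach_id, w = r$length_km, parent = parent, pu = pu,
       pd = pd, comp = comp, W = W, topo = order, links = l, upIdx = upIdx,
       pass = pass)
}

# leave-one-out on a prepared network: recompute only the affected edges
.prepRemove <- function(prep, removedIds) {
  hit <- which(prep$links$link_id %in% removedIds)
  for (i in hit) {
    v <- prep$upIdx[i]
    sib <- which(prep$upIdx == v)
    keep <- setdiff(sib, which(prep$links$link_id %in% removedIds))
    prep$pu[v] <- prod(prep$pass[keep, "up"], 1)
    prep$pd[v] <- prod(prep$pass[keep, "down"], 1)
  }
  prep
}

# Two-pass message passing over the rooted forest.
# S[v] = sum over j in subtree(v) of c_vj * w_j  (outgoing, upstream legs)
# T[v] = same sum over j outside subtree(v)      (downstream leg first)
.rciFromPrep <- function(prep) {
  w <- prep$w; parent <- prep$parent
  pu <- prep$pu; pd <- prep$pd; topo <- prep$topo
  S <- w
  for (v in rev(topo)) {
    p <- parent[v]
    if (!is.na(p)) S[p] <- S[p] + pu[v] * S[v]
  }
  T <- numeric(length(w))
  for (v in topo) {
    p <- parent[v]
    if (!is.na(p)) T[v] <- pd[v] * (T[p] + S[p] - pu[v] * S[v])
  }
  out <- (S + T) / prep$W
  names(out) <- prep$reach_id
  out
}

#' Cumulative passability between two reaches
#'
#' Product of the direction-specific passabilities of every barrier on the
#' unique path from reach `i` to reach `j` ("outgoing" directionality: the
#' traversal direction of each barrier is judged travelling away from `i`).
#' Equals 1 for a barrier-free path and for `i == j` (empty product).
#'
#' @inheritParams rci
#' @param i,j reach ids (must share a catchment)
#' @return numeric in \[0, 1\]
#' @export
cumulativePassability <- function(network, policy = passabilityPolicy(),
                                  i, j, barrierSet = "current",
                                  removed = character(0)) {
  pl <- pathLinks(network, i, j)
  if (nrow(pl) == 0) return(1)
  pass <- .resolveLinkPass(pl[, .linkColumns], policy, barrierSet, removed)
  prod(ifelse(pl$direction == "upstream", pass[, "up"], pass[, "down"]))
}

#' Reach Connectivity Index
#'
#' For each focal reach `i`, the length-weighted mean over all reaches `j`
#' of its catchment of the cumulative passability of the `i -> j` path
#' (the self term contributes 1). Computed by memoized two-pass tree
#' traversal, exactly equivalent to explicit path enumeration.
#'
#' @param network a [RiverNetwork][RiverNetwork-class]
#' @param policy a [PassabilityPolicy][PassabilityPolicy-class]
#' @param barrierSet which barriers are active: `"baseline"` (waterfalls
#'   only), `"current"` (existing barriers, default) or `"future"`
#'   (existing + planned)
#' @param removed barrier ids treated as fully passable (leave-one-out)
#' @return named numeric vector of RCI values in (0, 1\]
#' @examples
#' fx <- toyFixture("two")
#' rci(fx$network, fx$policy)  # c(U = 0.70, D = 0.55)
#' @export
rci <- function(network, policy = passabilityPolicy(),
                barrierSet = "current", removed = character(0)) {
  stopifnot(is(network, "RiverNetwork"))
  if (nReaches(network) == 0) stop("empty network", call. = FALSE)
  prep <- .prepareNetwork(network, policy, barrierSet, removed)
  .rciFromPrep(prep)
}

#' Suitability-weighted Reach Connectivity Index (RCIsuit)
#'
#' Elementwise product of RCI and group-mean climatic-environmental
#' suitability, joining habitat accessibility and quality in one index in
#' \[0, 1\]. Suitability may be keyed by the reach id or by its pre-split
#' `origin` id.
#'
#' @param rciValues named numeric vector from [rci()]
#' @param suitability named numeric vector of suitabilities in \[0, 1\]
#' @param network optional [RiverNetwork][RiverNetwork-class]; if given,
#'   suitability names are matched through `origin` for split reaches
#' @return named numeric vector, `NA` suitability propagates as `NA`
#' @export
rciSuit <- function(rciValues, suitability, network = NULL) {
  s <- .alignSuitability(names(rciValues), suitability, network)
  if (any(!is.na(s) & (s < 0 | s > 1)))
    stop("suitability outside [0, 1]", call. = FALSE)
  rciValues * s
}

.alignSuitability <- function(reachIds, suitability, network = NULL) {
  s <- unname(suitability[reachIds])
  if (!is.null(network) && anyNA(s)) {
    ori <- network@reaches$origin[match(reachIds, network@reaches$reach_id)]
    fill <- is.na(s) & !is.na(ori)
    s[fill] <- unname(suitability[ori[fill]])
  }
  names(s) <- reachIds
  s
}

#' Catchment Connectivity Index
#'
#' Suitability-weighted aggregate of RCI per catchment:
#' `CCI = sum(u_i * RCI_i) / sum(u_i)` with `u_i` the mean group
#' suitability of reach `i` (default), or suitability times reach length
#' (`weighting = "suitability_length"`). Reaches with missing suitability
#' get weight 0.
#'
#' @inheritParams rci
#' @param suitability named per-reach suitability vector (weights)
#' @param weighting `"suitability"` (default) or `"suitability_length"`
#' @return named numeric vector, one CCI in \[0, 1\] per catchment
#' @examples
#' fx <- toyFixture("two")
#' cci(fx$network, fx$policy, c(U = 1, D = 1))  # 0.625
#' @export
cci <- function(network, policy = passabilityPolicy(), suitability,
                barrierSet = "current",
                weighting = c("suitability", "suitability_length"),
                removed = character(0)) {
  weighting <- match.arg(weighting)
  rciV <- rci(network, policy, barrierSet, removed)
  .cciFromRci(network, rciV, suitability, weighting)
}

.cciFromRci <- function(network, rciV, suitability, weighting = "suitability") {
  r <- network@reaches
  u <- .alignSuitability(r$reach_id, suitability, network)
  if (any(!is.na(u) & u < 0))
    stop("suitability weights must be nonnegative", call. = FALSE)
  u[is.na(u)] <- 0
  if (weighting == "suitability_length") u <- u * r$length_km
  num <- tapply(u * rciV[r$reach_id], r$catchment_id, sum)
  den <- tapply(u, r$catchment_id, sum)
  if (any(den == 0))
    stop("all-zero suitability weights in catchment(s): ",
         paste(names(den)[den == 0], collapse = ", "), call. = FALSE)
  out <- as.numeric(num / den)
  names(out) <- names(num)
  out
}

#' Summary statistics of a connectivity index vector
#'
#' @param values numeric vector (e.g. RCIsuit over reaches); `NA` dropped
#' @return named numeric: `mean`, `median`, `max`
#' @export
summarizeConnectivity <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) == 0) stop("no non-missing values to summarize", call. = FALSE)
  c(mean = mean(v), median = stats::median(v), max = max(v))
}

#' Construct a suitability layer from a reach-by-cell matrix
#'
#' @param values numeric matrix, rownames = reach ids; colnames are
#'   rebuilt from `cells`
#' @param cells data.frame `group`, `climate`, `epoch` (and optionally
#'   `cell`), one row per column of `values`
#' @return a [SuitabilityLayer][SuitabilityLayer-class]
#' @export
suitabilityLayer <- function(values, cells) {
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  if (is.null(cells$cell))
    cells$cell <- cellKey(cells$group, cells$climate, cells$epoch)
  colnames(values) <- cells$cell
  obj <- new("SuitabilityLayer", values = values,
             cells = cells[, c("cell", "group", "climate", "epoch")])
  validObject(obj)
  obj
}
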