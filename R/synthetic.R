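#' Configuration of the synthetic riverscape generator
#'
#' Bundles every knob of the generator with defaults chosen to emulate a
#' fragmented tropical basin at desk scale: a dendritic tree of a few
#' hundred reaches with log-normal lengths (median ~5 km), a mixed barrier
#' portfolio of natural waterfalls plus existing and planned dams, strong
#' along-network suitability autocorrelation, and a monotone temporal
#' suitability decline that is steeper under the pessimistic climate
#' scenario. Species counts default to 27 migratory + 25 sedentary.
#'
#' @param nReaches number of reaches in the generated tree
#' @param branchingProb probability in (0, 1) that a growth step branches
#'   (adds two children) instead of extending a single tip
#' @param lengthMeanLog,lengthSdLog log-normal reach-length parameters (km)
#' @param nWaterfalls,nDamsExisting,nDamsPlanned barrier counts
#' @param placement `"uniform"` or `"mainstem_biased"` barrier placement
#' @param superBarrier also plant one mainstem "super-barrier" dam on the
#'   most fragmenting edge (the one splitting suitable length most evenly)
#' @param suitAutocorr along-network suitability autocorrelation in \[0, 1)
#' @param trendModerate,trendPessimistic per-epoch-step suitability drift
#'   (on the latent probit scale) for the two future climates;
#'   pessimistic > moderate
#' @param nMigratory,nSedentary species numbers per group
#' @param seed master seed; all generator stages derive their streams
#'   from it
#' @return a validated [RiverscapeConfig][RiverscapeConfig-class]
#' @export
riverscapeConfig <- function(nReaches = 500L, branchingProb = 0.3,
                             lengthMeanLog = log(5), lengthSdLog = 0.5,
                             nWaterfalls = 5L, nDamsExisting = 30L,
                             nDamsPlanned = 15L, placement = "uniform",
                             superBarrier = FALSE, suitAutocorr = 0.8,
                             trendModerate = 0.15, trendPessimistic = 0.30,
                             nMigratory = 27L, nSedentary = 25L, seed = 1L) {
  obj <- new("RiverscapeConfig", nReaches = as.integer(nReaches),
             branchingProb = branchingProb, lengthMeanLog = lengthMeanLog,
             lengthSdLog = lengthSdLog, nWaterfalls = as.integer(nWaterfalls),
             nDamsExisting = as.integer(nDamsExisting),
             nDamsPlanned = as.integer(nDamsPlanned), placement = placement,
             superBarrier = superBarrier, suitAutocorr = suitAutocorr,
             trendModerate = trendModerate,
             trendPessimistic = trendPessimistic,
             nMigratory = as.integer(nMigratory),
             nSedentary = as.integer(nSedentary), seed = as.integer(seed))
  validObject(obj)
  obj
}

# stage-specific substream of the master seed (kept below 2^31)
.stageSeed <- function(config, stage) {
  (config@seed %% 1000003L) * 1009L + stage
}

#' Generate a random dendritic river network
#'
#' Grows a tree from the outlet by seeded extension: each step picks a
#' random tip and either extends it with one upstream reach or, with
#' probability `branchingProb`, branches into two. Reach lengths are drawn
#' log-normally. The result has exactly `nReaches` reaches, a single
#' outlet, and `nReaches - 1` confluence links; it always passes network
#' validation. Bit-reproducible given the config.
#'
#' @param config a [riverscapeConfig()]
#' @return a [RiverNetwork][RiverNetwork-class] without barriers
#' @export
generateNetwork <- function(config) {
  stopifnot(is(config, "RiverscapeConfig"))
  set.seed(.stageSeed(config, 0L))
  n <- config@nReaches
  parent <- rep(NA_integer_, n)
  tips <- 1L
  cnt <- 1L
  while (cnt < n) {
    t <- if (length(tips) == 1L) tips else sample(tips, 1L)
    nk <- if (stats::runif(1) < config@branchingProb && cnt + 2L <= n) 2L else 1L
    kids <- cnt + seq_len(nk)
    parent[kids] <- t
    cnt <- cnt + nk
    tips <- c(setdiff(tips, t), kids)
  }
  ids <- sprintf("R%04d", seq_len(n))
  rt <- data.frame(reach_id = ids,
                   length_km = stats::rlnorm(n, config@lengthMeanLog,
                                             config@lengthSdLog),
                   next_down = ifelse(is.na(parent), NA_character_,
                                      ids[parent]),
                   catchment_id = "C1", stringsAsFactors = FALSE)
  buildNetwork(rt)
}

# total upstream-subtree weight per reach (the reach itself included)
.subtreeWeights <- function(network, w = NULL) {
  r <- network@reaches
  if (is.null(w)) w <- r$length_km
  parent <- match(r$next_down, r$reach_id)
  S <- w
  depth <- .depths(parent)
  for (v in order(depth, decreasing = TRUE))
    if (!is.na(parent[v])) S[parent[v]] <- S[parent[v]] + S[v]
  stats::setNames(S, r$reach_id)
}

.depths <- function(parent) {
  n <- length(parent)
  depth <- rep(NA_integer_, n)
  for (s in seq_len(n)) {
    v <- s; chain <- integer(0)
    while (!is.na(v) && is.na(depth[v])) { chain <- c(chain, v); v <- parent[v] }
    base <- if (is.na(v)) 0L else depth[v]
    depth[rev(chain)] <- base + seq_along(chain)
  }
  depth
}

#' Reaches on the mainstem of a network
#'
#' The mainstem is the outlet-to-headwater path that follows, at every
#' confluence, the branch with the greatest total upstream length.
#'
#' @param network a [RiverNetwork][RiverNetwork-class]
#' @return character vector of reach ids, outlet first
#' @export
mainstem <- function(network) {
  r <- network@reaches
  S <- .subtreeWeights(network)
  parent <- match(r$next_down, r$reach_id)
  children <- split(seq_len(nrow(r)), factor(parent, levels = seq_len(nrow(r))))
  v <- which(is.na(parent))[1]
  path <- character(0)
  repeat {
    path <- c(path, r$reach_id[v])
    ch <- children[[v]]
    if (length(ch) == 0) break
    v <- ch[which.max(S[ch])]
  }
  path
}

#' Place a barrier portfolio on a synthetic network
#'
#' Assigns the configured numbers of waterfalls, existing dams and planned
#' dams to reach interiors by seeded draw (each barrier splits its host
#' reach at a random position). `placement = "mainstem_biased"` makes
#' mainstem reaches ten times more likely hosts. With
#' `superBarrier = TRUE` one additional existing dam (`DAM_SUPER`) is
#' planted on the most fragmenting tree edge: the edge whose removal
#' splits the network's (suitability-weighted, if supplied) length most
#' evenly, i.e. maximizing `f * (1 - f)` over upstream weight fractions
#' `f` — on a dendritic tree this edge lies on the mainstem.
#'
#' @param network a barrier-free [RiverNetwork][RiverNetwork-class]
#' @param config a [riverscapeConfig()]
#' @param suitability optional per-reach weights used to pick the
#'   super-barrier edge (default: reach lengths)
#' @return a `RiverNetwork` with barrier links (planned dams carry
#'   `status = "planned"` and are inactive outside the `"future"` set)
#' @export
placeBarriers <- function(network, config, suitability = NULL) {
  stopifnot(is(network, "RiverNetwork"), is(config, "RiverscapeConfig"))
  set.seed(.stageSeed(config, 1L))
  r <- network@reaches
  nb <- config@nWaterfalls + config@nDamsExisting + config@nDamsPlanned
  if (nb + as.integer(config@superBarrier) > nrow(r))
    stop("barrier counts exceed network capacity", call. = FALSE)
  superUp <- NA_character_
  if (config@superBarrier) {
    w <- if (is.null(suitability)) r$length_km
         else .alignSuitability(r$reach_id, suitability, network) * r$length_km
    S <- .subtreeWeights(network, w)
    f <- S / sum(w)
    cand <- r$reach_id[!is.na(r$next_down)]
    superUp <- cand[which.max((f * (1 - f))[cand])]
  }
  pool <- setdiff(r$reach_id, superUp)
  if (config@superBarrier)
    # planted mode: competitors are tributary-scale dams; the planted
    # mega-dam is the unique mainstem-scale fragmentation
    pool <- setdiff(pool, mainstem(network))
  prob <- rep(1, length(pool))
  if (config@placement == "mainstem_biased")
    prob[pool %in% mainstem(network)] <- 10
  hosts <- sample(pool, nb, prob = prob)
  kinds <- rep(c("waterfall", "anthropogenic", "anthropogenic"),
               c(config@nWaterfalls, config@nDamsExisting,
                 config@nDamsPlanned))
  status <- rep(c("existing", "existing", "planned"),
                c(config@nWaterfalls, config@nDamsExisting,
                  config@nDamsPlanned))
  prefix <- rep(c("WF", "DAM", "PLAN"),
                c(config@nWaterfalls, config@nDamsExisting,
                  config@nDamsPlanned))
  bt <- data.frame(barrier_id = sprintf("%s%03d", prefix,
                                        unlist(lapply(table(prefix)[unique(prefix)],
                                                      seq_len))),
                   kind = kinds, status = status, reach_id = hosts,
                   fraction = stats::runif(nb, 0.1, 0.9),
                   stringsAsFactors = FALSE)
  if (config@superBarrier) {
    bt$up_reach <- NA_character_; bt$down_reach <- NA_character_
    bt$pass_up <- NA_real_; bt$pass_down <- NA_real_
    # mega-dam passabilities: a mainstem hydropower plant an order of
    # magnitude less passable than the default dam
    super <- data.frame(barrier_id = "DAM_SUPER", kind = "anthropogenic",
                        status = "existing", reach_id = NA_character_,
                        fraction = NA_real_, up_reach = superUp,
                        down_reach = r$next_down[match(superUp, r$reach_id)],
                        pass_up = 0.01, pass_down = 0.05,
                        stringsAsFactors = FALSE)
    bt <- rbind(bt, super)
  }
  rt <- r[, c("reach_id", "length_km", "next_down", "catchment_id")]
  buildNetwork(rt, bt)
}

#' Generate autocorrelated per-species suitability layers
#'
#' For each species, a latent Gaussian field is propagated down the tree
#' (child = `rho * parent + sqrt(1 - rho^2) * noise`, plus a species-level
#' prevalence shift) and squashed through the normal CDF into \[0, 1\].
#' Future epochs subtract a climate-specific linear drift on the latent
#' scale before squashing, so mean suitability declines monotonically
#' over the century and faster under the pessimistic scenario. Group
#' layers (combined / migratory / sedentary) are the per-reach means over
#' the group's species, via [groupMeanSuitability()].
#'
#' @param network the (possibly barrier-split) network the layer must cover
#' @param config a [riverscapeConfig()]
#' @return a [SuitabilityLayer][SuitabilityLayer-class] with cells
#'   `group x {(current, current), (moderate|pessimistic) x 2030..2090}`
#' @export
generateSuitability <- function(network, config) {
  set.seed(.stageSeed(config, 2L))
  r <- network@reaches
  n <- nrow(r)
  rho <- config@suitAutocorr
  parent <- match(r$next_down, r$reach_id)
  ord <- order(.depths(parent))  # parents before children
  nsp <- config@nMigratory + config@nSedentary
  latent <- matrix(NA_real_, n, nsp)
  for (sp in seq_len(nsp)) {
    shift <- stats::rnorm(1, 0, 0.5)
    eps <- stats::rnorm(n)
    z <- numeric(n)
    for (v in ord) {
      p <- parent[v]
      z[v] <- if (is.na(p)) eps[v] else rho * z[p] + sqrt(1 - rho^2) * eps[v]
    }
    latent[, sp] <- z + shift
  }
  groups <- list(combined = seq_len(nsp),
                 migratory = seq_len(config@nMigratory),
                 sedentary = config@nMigratory + seq_len(config@nSedentary))
  slopes <- c(moderate = config@trendModerate,
              pessimistic = config@trendPessimistic)
  cells <- scenarioCells("current")[, c("group", "climate", "epoch")]
  vals <- matrix(NA_real_, n, nrow(cells), dimnames = list(r$reach_id, NULL))
  for (k in seq_len(nrow(cells))) {
    drift <- if (cells$climate[k] == "current") 0 else
      slopes[[cells$climate[k]]] * (match(cells$epoch[k], EPOCHS) - 1L)
    spSuit <- stats::pnorm(latent - drift)
    vals[, k] <- groupMeanSuitability(spSuit, groups[[cells$group[k]]])
  }
  suitabilityLayer(vals, cells)
}

#' Generate a complete synthetic riverscape
#'
#' Convenience wrapper running [generateNetwork()], [placeBarriers()] and
#' [generateSuitability()] from one config (all stages draw independent
#' substreams of the master seed).
#'
#' @param config a [riverscapeConfig()]
#' @return list `network`, `policy` (default
#'   [passabilityPolicy()]), `suitability`
#' @export
generateRiverscape <- function(config = riverscapeConfig()) {
  net <- generateNetwork(config)
  net <- placeBarriers(net, config)
  list(network = net, policy = passabilityPolicy(),
       suitability = generateSuitability(net, config))
}

#' Deterministic worked-example fixtures
#'
#' `"two"`: two equal reaches separated by one dam with default
#' passabilities (up 0.1, down 0.4). Hand computation gives RCI 0.70 for
#' the upstream and 0.55 for the downstream reach, CCI 0.625 under
#' uniform suitability, and dCCI 60% for the dam.
#' `"six"`: a six-reach, two-catchment-free dendritic tree with one dam
#' and one waterfall, for path and oracle tests.
#'
#' @param which `"two"` or `"six"`
#' @return list `network`, `policy`, `suitability` (named vector),
#'   `expected` (hand-computed constants, `"two"` only)
#' @export
toyFixture <- function(which = c("two", "six")) {
  which <- match.arg(which)
  pol <- passabilityPolicy()
  if (which == "two") {
    rt <- data.frame(reach_id = c("U", "D"), length_km = c(1, 1),
                     next_down = c("D", NA), stringsAsFactors = FALSE)
    bt <- data.frame(barrier_id = "DAM1", kind = "anthropogenic",
                     status = "existing", up_reach = "U", down_reach = "D",
                     stringsAsFactors = FALSE)
    net <- buildNetwork(rt, bt)
    return(list(network = net, policy = pol,
                suitability = c(U = 1, D = 1),
                expected = list(rci = c(U = 0.70, D = 0.55), cci = 0.625,
                                dcci = 60.0)))
  }
  rt <- data.frame(reach_id = c("O", "A", "B", "C", "D", "E"),
                   length_km = c(2, 1, 3, 1, 2, 1),
                   next_down = c(NA, "O", "O", "A", "A", "B"),
                   stringsAsFactors = FALSE)
  bt <- data.frame(barrier_id = c("DAM_A", "WF_E"),
                   kind = c("anthropogenic", "waterfall"),
                   status = "existing",
                   up_reach = c("A", "E"), down_reach = c("O", "B"),
                   stringsAsFactors = FALSE)
  net <- buildNetwork(rt, bt)
  suit <- c(O = 0.9, A = 0.7, B = 0.8, C = 0.5, D = 0.6, E = 0.4)
  list(network = net, policy = pol, suitability = suit, expected = NULL)
}
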