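pol <- passabilityPolicy()

test_that("dCCI reproduces the hand-computed leave-one-out example", {
  fx <- toyFixture("two")
  expect_equal(dcci(fx$network, fx$policy, fx$suitability, "DAM1"), 60.0)
  expect_error(dcci(fx$network, fx$policy, fx$suitability, "NOPE"),
               "unknown barrier")
})

test_that("a fully passable barrier has dCCI exactly zero", {
  ov <- passabilityPolicy(overrides = data.frame(barrier_id = "DAM1",
                                                 pass_up = 1, pass_down = 1))
  fx <- toyFixture("two")
  expect_identical(dcci(fx$network, ov, fx$suitability, "DAM1"), 0)
  rt <- data.frame(reach_id = c("U", "D"), length_km = 1,
                   next_down = c("D", NA))
  bt <- data.frame(barrier_id = "FREE", kind = "anthropogenic",
                   up_reach = "U", down_reach = "D", pass_up = 1,
                   pass_down = 1)
  net <- buildNetwork(rt, bt)
  expect_identical(dcci(net, pol, c(U = 1, D = 1), "FREE"), 0)
})

test_that("mirror-image dams on symmetric tributaries tie at rank 1.5", {
  rt <- data.frame(reach_id = c("O", "L", "R"), length_km = c(2, 3, 3),
                   next_down = c(NA, "O", "O"))
  bt <- data.frame(barrier_id = c("DL", "DR"), kind = "anthropogenic",
                   up_reach = c("L", "R"), down_reach = "O")
  net <- buildNetwork(rt, bt)
  suit <- c(O = 1, L = 1, R = 1)
  expect_equal(dcci(net, pol, suit, "DL"), dcci(net, pol, suit, "DR"))
  bi <- rankBarriers(net, pol, suit)
  expect_equal(impactTable(bi)$rank, c(1.5, 1.5))
  one <- rankBarriers(net, pol, suit, candidates = "DL")
  expect_equal(impactTable(one)$rank, 1)
})

test_that("a mainstem dam blocking most habitat outranks a tributary dam", {
  # long mainstem M1..M4 with a short tributary T1; BIG cuts the whole
  # upstream network off the outlet, SMALL only isolates T1
  rt <- data.frame(reach_id = c("M1", "M2", "M3", "M4", "T1"),
                   length_km = c(5, 5, 5, 5, 1),
                   next_down = c(NA, "M1", "M2", "M3", "M3"))
  bt <- data.frame(barrier_id = c("BIG", "SMALL"), kind = "anthropogenic",
                   up_reach = c("M2", "T1"), down_reach = c("M1", "M3"))
  net <- buildNetwork(rt, bt)
  suit <- setNames(rep(1, 5), rt$reach_id)
  bi <- impactTable(rankBarriers(net, pol, suit))
  expect_equal(bi$barrier_id[bi$rank == 1], "BIG")
  # and both dCCI values agree with the brute-force oracle
  skip_if_not_installed("igraph")
  for (b in c("BIG", "SMALL")) {
    cci0 <- oracleCci(net, pol, suit)[["M1"]]
    cci1 <- oracleCci(net, pol, suit, removed = b)[["M1"]]
    expect_equal(bi$dCCI[bi$barrier_id == b], (cci1 - cci0) / cci0 * 100,
                 tolerance = 1e-12)
  }
})

test_that("rankings are invariant to candidate enumeration order", {
  fx <- randomScape(5, nReaches = 25, dams = 5, falls = 1)
  suit <- randomSuit(fx$network, 5)
  cand <- activeBarriers(fx$network, kinds = "anthropogenic")
  a <- impactTable(rankBarriers(fx$network, pol, suit, candidates = cand))
  b <- impactTable(rankBarriers(fx$network, pol, suit,
                                candidates = rev(cand)))
  expect_equal(a, b)
})

test_that("waterfalls stay in the network but out of the candidate set", {
  fx <- randomScape(9, nReaches = 20, dams = 3, falls = 2)
  bi <- impactTable(rankBarriers(fx$network, pol, uniformSuit(fx$network)))
  expect_true(all(bi$kind == "anthropogenic"))
  wf <- impactTable(rankBarriers(fx$network, pol, uniformSuit(fx$network),
                                 includeWaterfalls = TRUE))
  expect_true(any(wf$kind == "waterfall"))
})

test_that("planned barriers are only rankable in the future set", {
  fx <- randomScape(3, nReaches = 20, dams = 2, falls = 0, planned = 2)
  suit <- uniformSuit(fx$network)
  planned <- links(fx$network)$link_id[links(fx$network)$status == "planned"]
  expect_error(dcci(fx$network, pol, suit, planned[1], barrierSet = "current"),
               "not active")
  expect_gte(dcci(fx$network, pol, suit, planned[1], barrierSet = "future"), 0)
  expect_setequal(impactTable(rankBarriers(fx$network, pol, suit,
                                           barrierSet = "future"))$barrier_id,
                  activeBarriers(fx$network, "future", "anthropogenic"))
})

test_that("mean rank averages per-cell ranks and preserves order", {
  mk <- function(ids, ranks, d) {
    new("BarrierImpact",
        table = data.frame(barrier_id = ids, kind = "anthropogenic",
                           status = "existing", dCCI = d, rank = ranks),
        cell = NA_character_)
  }
  one <- mk(c("a", "b"), c(1, 2), c(5, 3))
  expect_equal(meanRank(list(one))$mean_rank, c(1, 2))
  two <- mk(c("a", "b"), c(2, 1), c(1, 9))
  mr <- meanRank(list(one, two))
  expect_equal(mr$mean_rank[mr$barrier_id == "a"], 1.5)
  expect_equal(mr$mean_rank[mr$barrier_id == "b"], 1.5)
  three <- list(mk(c("a", "b"), c(1, 2), c(2, 1)),
                mk(c("a", "b"), c(1, 2), c(2, 1)),
                mk(c("a", "b"), c(2, 1), c(1, 2)))
  mr3 <- meanRank(three)
  expect_equal(mr3$mean_rank, c(1.33, 1.67))
  expect_equal(mr3$barrier_id, c("a", "b"))
  expect_error(meanRank(list(one, mk(c("a", "z"), c(1, 2), c(1, 1)))),
               "different candidate sets")
})

test_that("the scenario grid enumerates valid cells and runs end to end", {
  cells <- scenarioCells("future", c("moderate", "pessimistic"),
                         c("2030", "2050", "2070", "2090"),
                         c("combined", "migratory", "sedentary"))
  expect_equal(nrow(cells), 24)
  expect_true(all(cells$epoch != "current"))
  # current climate implies current epoch
  all9 <- scenarioCells("current", groups = "combined")
  expect_equal(nrow(all9), 9)
  expect_equal(sum(all9$climate == "current"), 1)

  fx <- randomScape(21, nReaches = 30, dams = 4, falls = 1, planned = 2)
  suit <- generateSuitability(fx$network, fx$config)
  out <- scenarioGrid(fx$network, pol, suit,
                      scenarioCells(c("current", "future"),
                                    "pessimistic", "2090"),
                      ranking = TRUE)
  expect_s4_class(out$result, "ConnectivityResult")
  expect_equal(ncol(out$result@rci), 6)
  expect_false(anyNA(out$result@rcisuit))
  # baseline on a dam-free network gives RCI = 1 everywhere
  cfg0 <- riverscapeConfig(nReaches = 15, nDamsExisting = 0, nWaterfalls = 0,
                           nDamsPlanned = 0, seed = 4)
  net0 <- generateNetwork(cfg0)
  suit0 <- generateSuitability(net0, cfg0)
  out0 <- scenarioGrid(net0, pol, suit0,
                       scenarioCells("baseline", "current", "current",
                                     "combined"))
  expect_equal(unname(out0$result@rci[, 1]), rep(1, 15))
})

test_that("a planned dam only degrades CCI in the future barrier set", {
  fx <- randomScape(31, nReaches = 25, dams = 3, falls = 1, planned = 2)
  suit <- uniformSuit(fx$network)
  cur <- cci(fx$network, pol, suit, barrierSet = "current")
  fut <- cci(fx$network, pol, suit, barrierSet = "future")
  expect_true(all(fut <= cur + 1e-12))
})
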