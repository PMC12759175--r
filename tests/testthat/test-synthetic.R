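test_that("network generation is reproducible and always a valid tree", {
  cfg <- riverscapeConfig(nReaches = 50, seed = 7)
  a <- generateNetwork(cfg)
  b <- generateNetwork(cfg)
  expect_identical(reaches(a), reaches(b))
  expect_equal(nReaches(a), 50)
  expect_equal(nLinks(a), 49)
  expect_length(outlets(a), 1)
  expect_true(validObject(a))
  one <- generateNetwork(riverscapeConfig(nReaches = 1, seed = 1))
  expect_equal(nReaches(one), 1)
  expect_equal(nLinks(one), 0)
})

test_that("expected mainstem length grows with network size", {
  msLen <- function(n, seed) {
    net <- generateNetwork(riverscapeConfig(nReaches = n, seed = seed))
    r <- reaches(net)
    sum(r$length_km[r$reach_id %in% mainstem(net)])
  }
  small <- mean(vapply(1:20, function(s) msLen(20, s), numeric(1)))
  large <- mean(vapply(1:20, function(s) msLen(150, s), numeric(1)))
  expect_gt(large, small)
})

test_that("barrier placement honours counts, status and splitting", {
  fx <- randomScape(4, nReaches = 40, dams = 6, falls = 2, planned = 3)
  l <- links(fx$network)
  expect_equal(sum(l$kind == "waterfall"), 2)
  expect_equal(sum(l$kind == "anthropogenic" & l$status == "existing"), 6)
  expect_equal(sum(l$status == "planned"), 3)
  expect_equal(nLinks(fx$network), nReaches(fx$network) - 1)
  # zero barriers leave the confluence-only network
  none <- randomScape(4, nReaches = 40, dams = 0, falls = 0)
  expect_true(all(links(none$network)$kind == "confluence"))
  expect_error(placeBarriers(generateNetwork(riverscapeConfig(nReaches = 5,
                                                              seed = 1)),
                             riverscapeConfig(nReaches = 5, nDamsExisting = 30,
                                              seed = 1)),
               "exceed|capacity|feasible")
})

test_that("mainstem-biased placement favours the outlet path", {
  hits <- vapply(1:300, function(s) {
    cfg <- riverscapeConfig(nReaches = 30, nDamsExisting = 1,
                            nWaterfalls = 0, nDamsPlanned = 0,
                            placement = "mainstem_biased", seed = s)
    net <- placeBarriers(generateNetwork(cfg), cfg)
    dam <- links(net)[links(net)$kind == "anthropogenic", ]
    ms <- mainstem(generateNetwork(cfg))
    reaches(net)$origin[match(dam$up_reach, reaches(net)$reach_id)] %in% ms
  }, logical(1))
  unif <- vapply(1:300, function(s) {
    cfg <- riverscapeConfig(nReaches = 30, nDamsExisting = 1,
                            nWaterfalls = 0, nDamsPlanned = 0, seed = s)
    net <- placeBarriers(generateNetwork(cfg), cfg)
    dam <- links(net)[links(net)$kind == "anthropogenic", ]
    ms <- mainstem(generateNetwork(cfg))
    reaches(net)$origin[match(dam$up_reach, reaches(net)$reach_id)] %in% ms
  }, logical(1))
  expect_gt(mean(hits), mean(unif))
})

test_that("the planted super-barrier sits on the most balanced edge", {
  cfg <- riverscapeConfig(nReaches = 60, nDamsExisting = 3, nWaterfalls = 1,
                          superBarrier = TRUE, seed = 17)
  net0 <- generateNetwork(cfg)
  net <- placeBarriers(net0, cfg)
  sup <- links(net)[links(net)$link_id == "DAM_SUPER", ]
  expect_equal(nrow(sup), 1)
  # exhaustive subtree search: the chosen edge maximizes f(1-f)
  r <- reaches(net0)
  W <- sum(r$length_km)
  up <- function(id) {  # total length upstream of (and including) id
    ids <- id
    repeat {
      more <- r$reach_id[r$next_down %in% ids & !r$reach_id %in% ids]
      if (length(more) == 0) break
      ids <- c(ids, more)
    }
    sum(r$length_km[r$reach_id %in% ids])
  }
  f <- vapply(r$reach_id[!is.na(r$next_down)], up, numeric(1)) / W
  best <- names(which.max(f * (1 - f)))
  expect_equal(sup$up_reach, best)
})

test_that("suitability layers are bounded, reproducible and declining", {
  fx <- randomScape(10, nReaches = 60, dams = 4, falls = 1)
  suit <- generateSuitability(fx$network, fx$config)
  suit2 <- generateSuitability(fx$network, fx$config)
  expect_identical(suit@values, suit2@values)
  expect_true(all(suit@values >= 0 & suit@values <= 1))
  expect_equal(ncol(suit@values), 27)  # 3 groups x 9 climate-epoch cells
  cur <- suitabilityFor(suit, "combined", "current", "current")
  for (g in c("combined", "migratory", "sedentary")) {
    path <- vapply(c("2030", "2050", "2070", "2090"), function(e)
      mean(suitabilityFor(suit, g, "pessimistic", e)), numeric(1))
    expect_true(all(diff(path) < 0))  # monotone decline over the century
  }
  p90 <- mean(suitabilityFor(suit, "combined", "pessimistic", "2090"))
  m90 <- mean(suitabilityFor(suit, "combined", "moderate", "2090"))
  expect_lt(p90, m90)       # pessimistic declines faster
  expect_lt(p90, mean(cur)) # and below today
})

test_that("suitability is spatially autocorrelated along the network", {
  adjCor <- function(rho, seed) {
    cfg <- riverscapeConfig(nReaches = 200, nDamsExisting = 0,
                            nWaterfalls = 0, nDamsPlanned = 0,
                            suitAutocorr = rho, seed = seed)
    net <- generateNetwork(cfg)
    s <- suitabilityFor(generateSuitability(net, cfg), "combined",
                        "current", "current")
    r <- reaches(net)
    adj <- !is.na(r$next_down)
    near <- cor(s[r$reach_id[adj]], s[r$next_down[adj]])
    set.seed(seed)
    far <- cor(s, sample(s))
    c(near = near, far = far)
  }
  cc <- rowMeans(vapply(1:10, function(s) adjCor(0.8, s), numeric(2)))
  expect_gt(cc["near"], cc["far"] + 0.2)
  # with autocorrelation 0 the neighbour correlation collapses
  c0 <- rowMeans(vapply(1:10, function(s) adjCor(0, s), numeric(2)))
  expect_lt(abs(c0["near"]), 0.2)
})

test_that("toy fixtures survive a write/read round trip", {
  fx <- randomScape(30, nReaches = 20, dams = 3, falls = 1, planned = 1)
  suit <- generateSuitability(fx$network, fx$config)
  dir <- withr::local_tempdir()
  writeRiverscape(fx$network, suit, dir)
  back <- readInputs(dir)
  expect_equal(reaches(back$network)$reach_id, reaches(fx$network)$reach_id)
  expect_equal(reaches(back$network)$length_km, reaches(fx$network)$length_km)
  bl <- links(back$network); ol <- links(fx$network)
  expect_setequal(bl$link_id[bl$kind != "confluence"],
                  ol$link_id[ol$kind != "confluence"])
  expect_equal(back$suitability@values[rownames(suit@values),
                                       colnames(suit@values)],
               suit@values, tolerance = 1e-5)
  expect_equal(rci(back$network), rci(fx$network))
})
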