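test_that("maxSSS picks the smallest threshold maximizing sens + spec", {
  r <- maxSssThreshold(c(0.9, 0.7, 0.6, 0.2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r$threshold, 0.7)
  expect_equal(r$sensitivity + r$specificity, 2)
  # separable case returns the smallest observed presence suitability
  r2 <- maxSssThreshold(c(0.8, 0.95, 0.1, 0.3), c(1, 1, 0, 0))
  expect_equal(r2$threshold, 0.8)
  expect_error(maxSssThreshold(c(0.1, 0.9), c(1, 1)), "presence and one absence")
})

test_that("maxSSS is optimal over all candidate thresholds", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 40
    lab <- c(rep(TRUE, 15), rep(FALSE, 25))
    suit <- ifelse(lab, rbeta(n, 4, 2), rbeta(n, 2, 4))
    r <- maxSssThreshold(suit, lab)
    best <- r$sensitivity + r$specificity
    for (t in sort(unique(suit))) {
      ss <- mean(suit[lab] >= t) + mean(suit[!lab] < t)
      expect_lte(ss, best + 1e-12)
      if (abs(ss - best) < 1e-12) expect_gte(t, r$threshold)
    }
  }
})

test_that("maxSSS on interleaved random labels gives sens + spec near 1", {
  set.seed(99)
  reps <- replicate(50, {
    suit <- runif(60)
    lab <- sample(c(TRUE, FALSE), 60, TRUE)
    r <- maxSssThreshold(suit, lab)
    r$sensitivity + r$specificity
  })
  # optimum is >= 1 by construction (threshold at extremes); under no signal
  # the excess is sampling noise only
  expect_true(all(reps >= 1))
  expect_lt(mean(reps), 1.5)
})

test_that("consensus presence requires a strict majority", {
  maps5 <- matrix(c(1, 1, 1, 0, 0,
                    1, 1, 0, 0, 0), nrow = 2, byrow = TRUE)
  expect_equal(consensusPresence(maps5), c(TRUE, FALSE))
  maps4 <- matrix(c(1, 1, 0, 0), nrow = 1)
  expect_false(consensusPresence(maps4))  # 2 of 4 is not > half
  expect_true(consensusPresence(matrix(c(1, 1, 1, 0), nrow = 1)))
  expect_error(consensusPresence(list(a = c(1, 0), b = c(1, 0, 1))),
               "mismatched")
})

test_that("adding a presence vote never flips present to absent", {
  set.seed(12)
  for (rep in 1:20) {
    m <- sample(3:7, 1)
    votes <- matrix(rbinom(10 * m, 1, 0.5), nrow = 10)
    before <- consensusPresence(votes)
    j <- sample(m, 1)
    votes2 <- votes
    votes2[, j] <- 1
    after <- consensusPresence(votes2)
    expect_true(all(after >= before))
  }
})

test_that("AUC filter keeps models strictly above the cutoff", {
  auc <- c(glm = 0.85, gam = 0.8, rf = 0.95, brt = 0.62, maxent = 0.81)
  expect_equal(aucFilter(auc), c("glm", "rf", "maxent"))
  pred <- matrix(runif(20 * 5), 20, 5)
  expect_warning(out <- consensusSuitability(pred, rep(0.5, 5)),
                 "excluded")
  expect_null(out)
  cs <- consensusSuitability(pred, auc)
  expect_equal(cs$retained, c(1, 3, 5))
  expect_equal(cs$continuous, rowMeans(pred[, c(1, 3, 5)]))
})

test_that("group means average species layers and respect permutations", {
  sp <- cbind(a = c(r1 = 0.2, r2 = 0.4), b = c(r1 = 0.8, r2 = 0.6))
  expect_equal(groupMeanSuitability(sp, "a"), c(r1 = 0.2, r2 = 0.4))
  expect_equal(groupMeanSuitability(sp), c(r1 = 0.5, r2 = 0.5))
  expect_error(groupMeanSuitability(sp, character(0)), "empty")
  set.seed(5)
  big <- matrix(runif(30 * 10), 30, 10)
  perm <- sample(10)
  expect_equal(groupMeanSuitability(big), groupMeanSuitability(big[, perm]))
  expect_true(all(groupMeanSuitability(big) >= 0 &
                    groupMeanSuitability(big) <= 1))
  # combined mean equals the species-weighted mean of the group means
  nm <- 6; ns <- 4
  mig <- groupMeanSuitability(big, 1:nm)
  sed <- groupMeanSuitability(big, nm + 1:ns)
  expect_equal(groupMeanSuitability(big, 1:(nm + ns)),
               (nm * mig + ns * sed) / (nm + ns))
})

test_that("grid suitability maps onto reaches by length-weighted mean", {
  grid <- list(origin = c(0, 0), cellsize = 1,
               values = matrix(c(0.2, 0.6), nrow = 1))  # two cells along x
  rt <- data.frame(reach_id = c("in1", "split"), length_km = c(0.4, 1),
                   next_down = c("split", NA),
                   geometry = c("LINESTRING (0.1 0.5, 0.5 0.5)",
                                "LINESTRING (0.5 0.5, 1.5 0.5)"))
  net <- buildNetwork(rt)
  v <- cellsToReaches(grid, net)
  expect_equal(v[["in1"]], 0.2)        # entirely inside one cell
  expect_equal(v[["split"]], 0.4)      # 50/50 across 0.2 and 0.6
})

test_that("grid projection matches a dense point-sampling oracle", {
  set.seed(8)
  grid <- list(origin = c(0, 0), cellsize = 0.5,
               values = matrix(runif(16), 4, 4))
  for (rep in 1:5) {
    pts <- cbind(runif(4, 0.05, 1.95), runif(4, 0.05, 1.95))
    wkt <- paste0("LINESTRING (",
                  paste(apply(pts, 1, paste, collapse = " "),
                        collapse = ", "), ")")
    rt <- data.frame(reach_id = "r", length_km = 1, next_down = NA,
                     geometry = wkt)
    net <- buildNetwork(rt)
    got <- cellsToReaches(grid, net)[["r"]]
    # oracle: sample many points along the polyline, average cell values
    segs <- cbind(pts[-nrow(pts), , drop = FALSE], pts[-1, , drop = FALSE])
    lens <- sqrt((segs[, 3] - segs[, 1])^2 + (segs[, 4] - segs[, 2])^2)
    tt <- seq(0, 1, length.out = 200001)
    cum <- c(0, cumsum(lens)) / sum(lens)
    seg <- findInterval(tt, cum, rightmost.closed = TRUE)
    seg[seg > nrow(segs)] <- nrow(segs)
    loc <- (tt - cum[seg]) / (cum[seg + 1] - cum[seg])
    x <- segs[seg, 1] + loc * (segs[seg, 3] - segs[seg, 1])
    y <- segs[seg, 2] + loc * (segs[seg, 4] - segs[seg, 2])
    i <- pmin(pmax(floor(y / 0.5) + 1, 1), 4)
    j <- pmin(pmax(floor(x / 0.5) + 1, 1), 4)
    want <- mean(grid$values[cbind(i, j)])
    expect_equal(got, want, tolerance = 1e-3)
  }
})

test_that("reaches without geometry or off-grid raise errors", {
  rt <- data.frame(reach_id = "r", length_km = 1, next_down = NA)
  net <- buildNetwork(rt)
  grid <- list(origin = c(0, 0), cellsize = 1, values = matrix(0.5))
  expect_error(cellsToReaches(grid, net), "no geometry")
  rt2 <- data.frame(reach_id = "r", length_km = 1, next_down = NA,
                    geometry = "LINESTRING (5 5, 6 6)")
  expect_error(cellsToReaches(grid, buildNetwork(rt2)), "no grid cell")
})
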