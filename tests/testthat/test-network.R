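# Placement, wiring statistics and serialization.

test_that("placement honors counts, spacing and the box", {
  rec <- reduced_recipe(600, fx_params())
  cells <- place_cells(rec, seed = 3)
  expect_equal(sum(cells$type == "PN_A"), rec$n_pn_a)
  expect_equal(sum(cells$type == "PN_C"), rec$n_pn_c)
  expect_equal(sum(cells$type == "FSI"), rec$n_fsi)
  expect_true(all(cells$x >= 0 & cells$x <= rec$box_um))
  d <- stats::dist(as.matrix(cells[, c("x", "y", "z")]))
  expect_gt(min(d), rec$min_dist)
  # orientation vectors are unit length
  expect_equal(cells$ox^2 + cells$oy^2 + cells$oz^2, rep(1, nrow(cells)),
               tolerance = 1e-9)
  # deterministic under the seed
  cells2 <- place_cells(rec, seed = 3)
  expect_identical(cells, cells2)
  # infeasible packing errors out
  rec$min_dist <- 300
  expect_error(place_cells(rec, seed = 1), "infeasible")
})

test_that("conduction delays follow the printed composition", {
  p <- fx_params()
  set.seed(1)
  d0 <- replicate(200, conduction_delay(0, p))
  expect_true(all(d0 >= 0.75 & d0 <= 0.95))
  d1 <- replicate(200, conduction_delay(1000, p))
  expect_true(all(d1 >= 1.75 & d1 <= 1.95))
  expect_equal(mean(d1), 1.85, tolerance = 0.01)
  expect_error(conduction_delay(-5, p), "negative")
})

test_that("realized in-degrees match the brute-force pair-enumeration expectation", {
  rec <- reduced_recipe(900, fx_params())
  cells <- place_cells(rec, seed = 7)
  wi <- wire_intrinsic(cells, rec$box_um, seed = 8, fx_params())
  ed <- wi$edges
  # no autapses
  expect_true(all(ed$src != ed$dst))
  # brute-force expectation for PN->PN from the actual pairwise distances
  pn <- which(cells$type != "FSI")
  D <- as.matrix(stats::dist(as.matrix(cells[pn, c("x", "y", "z")])))
  nw <- fx_params()$network
  pmat <- matrix(0, length(pn), length(pn))
  br <- nw$pn_pn$breaks_um; pr <- nw$pn_pn$prob
  for (b in seq_along(pr))
    pmat[D > br[b] & D <= br[b + 1]] <- pr[b]
  diag(pmat) <- 0
  expected_mean <- mean(colSums(pmat))
  realized <- tabulate(match(ed$dst[ed$class == "pn_pn"], pn), length(pn))
  se <- stats::sd(realized) / sqrt(length(pn))
  expect_lt(abs(mean(realized) - expected_mean), 3 * se + 0.05 * expected_mean)
  # PN-FSI outcomes: expectation from the categorical rule within range
  fsi <- which(cells$type == "FSI")
  Dpf <- sqrt(outer(cells$x[pn], cells$x[fsi], "-")^2 +
              outer(cells$y[pn], cells$y[fsi], "-")^2 +
              outer(cells$z[pn], cells$z[fsi], "-")^2)
  n_in_range <- sum(Dpf <= nw$fsi_range_um)
  exp_fsi2pn <- n_in_range * (nw$pn_fsi$fsi_to_pn + nw$pn_fsi$reciprocal)
  exp_pn2fsi <- n_in_range * (nw$pn_fsi$pn_to_fsi + nw$pn_fsi$reciprocal)
  expect_equal(sum(ed$class == "fsi_pn"), exp_fsi2pn, tolerance = 0.1)
  expect_equal(sum(ed$class == "pn_fsi"), exp_pn2fsi, tolerance = 0.1)
  # all FSI-involved edges respect the range cutoff
  expect_true(all(ed$dist[ed$class != "pn_pn"] <= nw$fsi_range_um + 1e-9))
  expect_true(all(ed$dist[ed$class == "pn_pn"] <= 600 + 1e-9))
})

test_that("FSI-FSI chemical probabilities are conditioned on electrical coupling", {
  # dense FSI-only box so every pair is in range; aggregate over seeds
  p <- fx_params()
  n <- 40
  uni_c <- bi_c <- n_c <- uni_u <- bi_u <- n_u <- 0
  for (sd in 1:10) {
    cells <- data.frame(type = "FSI",
                        x = runif(n, 0, 180), y = runif(n, 0, 180), z = runif(n, 0, 180),
                        ox = 0, oy = 0, oz = 1)
    wi <- wire_intrinsic(cells, 180, seed = 100 + sd, p)
    gp <- wi$gaps
    coupled <- paste(pmin(gp$a, gp$b), pmax(gp$a, gp$b))
    ed <- wi$edges
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (sqrt(sum((cells[i, 2:4] - cells[j, 2:4])^2)) > p$network$fsi_range_um) next
      key <- paste(i, j)
      fwd <- any(ed$src == i & ed$dst == j)
      bwd <- any(ed$src == j & ed$dst == i)
      if (key %in% coupled) {
        n_c <- n_c + 1
        if (fwd && bwd) bi_c <- bi_c + 1 else if (fwd || bwd) uni_c <- uni_c + 1
      } else {
        n_u <- n_u + 1
        if (fwd && bwd) bi_u <- bi_u + 1 else if (fwd || bwd) uni_u <- uni_u + 1
      }
    }
  }
  ci <- function(k, n, p0) abs(k / n - p0) < 3 * sqrt(p0 * (1 - p0) / n)
  expect_true(ci(uni_c, n_c, 0.50))
  expect_true(ci(bi_c, n_c, 0.25))
  expect_true(ci(uni_u, n_u, 0.19))
  expect_true(ci(bi_u, n_u, 0.03))
  # electrical coupling rate itself
  expect_true(ci(n_c, n_c + n_u, 0.08))
})

test_that("afferent fan-out reproduces the published extrinsic statistics", {
  net <- fx_reduced_net()
  af <- net$afferents
  npn <- sum(net$cells$type != "FSI")
  deg <- tabulate(af$dst[af$class == "aff_pn"], nbins = nrow(net$cells))
  deg_pn <- deg[net$cells$type != "FSI"]
  expected <- net$n_afferents * 40 / npn
  expect_equal(mean(deg_pn), expected, tolerance = 0.1)
  # binomial spread and coverage
  pcov <- 1 - (1 - 40 / npn)^net$n_afferents
  expect_equal(mean(deg_pn >= 1), pcov, tolerance = 0.05)
  # every afferent contacts exactly 40 distinct PNs
  tgt <- split(af$dst[af$class == "aff_pn"], af$aff[af$class == "aff_pn"])
  expect_true(all(vapply(tgt, function(x) length(unique(x)) == 40, TRUE)))
})

test_that("networks round-trip through the plain-text serialization", {
  net <- make_fixtures("fifty_cell_net", seed = 2, params = fx_params())
  dir <- withr::local_tempdir()
  write_network(net, dir)
  net2 <- read_network(dir, fx_params())
  expect_equal(net2$cells$x, net$cells$x)
  expect_equal(net2$edges$w1, net$edges$w1)
  expect_equal(net2$edges$delay_ms, net$edges$delay_ms)
  expect_equal(net2$gaps$g_nS, net$gaps$g_nS)
  expect_equal(net2$n_afferents, net$n_afferents)
  # identical dynamics from the restored network
  tr1 <- simulate_network(net, 300, seed = 9, record_v = 1)
  tr2 <- simulate_network(net2, 300, seed = 9, record_v = 1)
  expect_identical(tr1$spikes, tr2$spikes)
})
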