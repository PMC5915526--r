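test_that("distance transform is exact and validates input", {
  expect_error(distance_map(matrix(TRUE, 4, 4)), "background")
  expect_true(all(distance_map(matrix(FALSE, 6, 6)) == 0))
  one <- matrix(FALSE, 7, 7); one[4, 4] <- TRUE
  expect_equal(distance_map(one)[4, 4], 1)
})

test_that("seeding thresholds the sharpened transform and suppresses by balls", {
  m <- matrix(FALSE, 20, 70); m[9:13, 6:65] <- TRUE
  s <- compute_seeds(m, repair = FALSE)
  # away from the bar tips every seed lies on the centerline row
  interior <- s[s$x >= 12 & s$x <= 59, ]
  expect_gt(nrow(interior), 5)
  expect_true(all(interior$y == 11))
  # suppression postcondition: no seed inside another's clearance ball
  for (i in seq_len(nrow(s))) {
    d <- sqrt((s$y - s$y[i])^2 + (s$x - s$x[i])^2)
    d[i] <- Inf
    expect_true(all(d >= pmax(s$df[i], s$df) - 1e-9))
  }
  expect_equal(nrow(compute_seeds(matrix(FALSE, 10, 10))), 0)
})

test_that("fan search honours orientation, range and the angular limit", {
  mk_seeds <- function(pts, df = 2) {
    data.frame(y = pts[, 1], x = pts[, 2], df = df)
  }
  cur <- c(50, 50)
  # dead-ahead seed at 5 px: found in round 0
  s1 <- mk_seeds(rbind(c(50, 55)))
  r <- next_seed_search(cur, 0, s1, trace_config())
  expect_equal(r$round, 0)
  expect_equal(r$idx, 1)
  # seeds beyond the 2*pi/5 angular limit are never selected
  far_dev <- rbind(c(50 + 6 * sin(1.4), 50 + 6 * cos(1.4)),   # dev 80 deg
                   c(50 - 10 * sin(1.5), 50 + 10 * cos(1.5)))
  expect_null(next_seed_search(cur, 0, mk_seeds(far_dev), trace_config()))
  # crossing fixture: near-axis seed beats a closer transversal seed
  a <- c(50 + 5 * sin(5 * pi / 180), 50 + 5 * cos(5 * pi / 180))
  b <- c(50 + 3 * sin(85 * pi / 180), 50 + 3 * cos(85 * pi / 180))
  r2 <- next_seed_search(cur, 0, mk_seeds(rbind(a, b)), trace_config())
  expect_equal(r2$idx, 1)
})

test_that("neurite initialization recovers radial directions", {
  shape <- c(120, 120)
  soma <- disk_mask(shape, 60, 60, 20)
  f <- soma
  angs <- c(0, 2 * pi / 3, 4 * pi / 3) + 0.2
  for (a in angs) {
    from <- c(60 + 20 * sin(a), 60 + 20 * cos(a))
    to <- c(60 + 45 * sin(a), 60 + 45 * cos(a))
    f <- tube_mask(f, from, to, hw = 2)
  }
  reg <- neurotracer:::new_soma_region(1L, soma)
  starts <- initialize_neurites(reg, f, trace_config())
  expect_length(starts, 3)
  th0 <- sort(vapply(starts, function(s) s$theta0 %% (2 * pi), numeric(1)))
  expect_equal(th0, sort(angs %% (2 * pi)), tolerance = 5 * pi / 180)
  # soma with no neurites
  expect_length(initialize_neurites(reg, soma, trace_config()), 0)
  # soma outside the foreground is rejected
  expect_error(initialize_neurites(reg, f & !soma, trace_config()),
               "foreground")
  # rotating the input rotates every initial orientation
  f90 <- rot90_mat(f)
  reg90 <- neurotracer:::new_soma_region(1L, rot90_mat(soma))
  st90 <- initialize_neurites(reg90, f90, trace_config())
  th90 <- sort(vapply(st90, function(s) s$theta0 %% (2 * pi), numeric(1)))
  expect_equal(sort((th0 - pi / 2) %% (2 * pi)), th90,
               tolerance = 6 * pi / 180)
})

test_that("tracing a straight neurite visits its seeds in arclength order", {
  m <- matrix(FALSE, 30, 120)
  m <- tube_mask(m, c(15, 8), c(15, 112), hw = 2)
  seeds <- compute_seeds(m)
  start <- list(point = c(15, 8), theta0 = 0)
  tr <- trace_neurite(start, seeds, trace_config(), f = m)
  expect_gt(nrow(tr$nodes), 10)
  expect_true(all(diff(tr$nodes[, "arclength"]) > 0))
  expect_true(all(diff(tr$nodes[, "x"]) > 0))
  expect_lt(max(abs(tr$nodes[, "y"] - 15)), 1.5)
  # start with no reachable seeds terminates immediately
  lone <- list(point = c(5, 5), theta0 = pi)
  tr0 <- trace_neurite(lone, compute_seeds(m), trace_config(), f = m)
  expect_equal(nrow(tr0$nodes), 1)
})

test_that("a bifurcating neurite yields one child branch covering both arms", {
  yfix <- matrix(FALSE, 120, 160)
  stem <- cbind(60, 10:70)
  armA <- cbind(60 - round((1:50) * sin(pi / 6)), 70 + round((1:50) * cos(pi / 6)))
  armB <- cbind(60 + round((1:50) * sin(pi / 6)), 70 + round((1:50) * cos(pi / 6)))
  yfix <- neurotracer:::draw_tube(yfix, stem, 2)
  yfix <- neurotracer:::draw_tube(yfix, armA, 2)
  yfix <- neurotracer:::draw_tube(yfix, armB, 2)
  soma <- disk_mask(c(120, 160), 60, 12, 9)
  yfix <- yfix | soma
  reg <- neurotracer:::new_soma_region(1L, soma)
  trees <- suppressMessages(extract_trees(list(reg), yfix))
  expect_length(trees, 1)
  parents <- vapply(trees[[1]]$neurites,
                    function(n) !is.null(n$parent), logical(1))
  expect_true(any(parents))
  all_nodes <- do.call(rbind, lapply(trees[[1]]$neurites,
                                     function(n) n$nodes[, 1:2, drop = FALSE]))
  tipA <- c(60 - 25, 113); tipB <- c(60 + 25, 113)
  expect_lt(min(sqrt((all_nodes[, 1] - tipA[1])^2 +
                       (all_nodes[, 2] - tipA[2])^2)), 5)
  expect_lt(min(sqrt((all_nodes[, 1] - tipB[1])^2 +
                       (all_nodes[, 2] - tipB[2])^2)), 5)
})

test_that("trees are acyclic, monotone in arclength and respect turning bounds", {
  runs <- standard_suite_runs()[c(1, 4, 7)]
  cfg <- trace_config()
  for (r in runs) {
    seen_seeds <- integer(0)
    for (tr in r$trees) {
      expect_silent(neurotracer:::validate_tree(tr))
      for (nn in tr$neurites) {
        expect_true(all(diff(nn$nodes[, "arclength"]) > 0))
        if (nrow(nn$nodes) >= 3) {
          d <- diff(nn$nodes[, 1:2, drop = FALSE])
          ang <- atan2(d[, 1], d[, 2])
          turns <- abs(neurotracer:::wrap_angle(diff(ang)))
          expect_lte(max(turns), cfg$fan_max + 1e-9)
        }
        sd <- nn$nodes[, "seed"]
        seen <- sd[!is.na(sd)]
        # no seed is claimed by two different trees
        expect_length(intersect(seen, seen_seeds), 0)
        seen_seeds <- c(seen_seeds, seen)
      }
    }
  }
})

test_that("tiling partitions somas by proximity", {
  mk_soma <- function(cy, cx, id) {
    neurotracer:::new_soma_region(id, disk_mask(c(700, 700), cy, cx, 10))
  }
  close_pair <- list(mk_soma(100, 100, 1L), mk_soma(150, 130, 2L))
  far <- mk_soma(620, 620, 3L)
  tiles <- tile_large_image(c(close_pair, list(far)), c(700, 700),
                            max_tile = 1024, margin = 100, cutoff = 100)
  expect_length(tiles, 2)
  ids <- sort(unlist(lapply(tiles, `[[`, "soma_ids")))
  expect_equal(ids, 1:3)
  # single-group case
  t1 <- tile_large_image(close_pair, c(700, 700), cutoff = 100)
  expect_length(t1, 1)
  expect_equal(sort(t1[[1]]$soma_ids), 1:2)
  # somas fully inside their rectangle
  for (tl in tiles) {
    for (id in tl$soma_ids) {
      s <- c(close_pair, list(far))[[id]]
      w <- which(s$mask, arr.ind = TRUE)
      expect_true(min(w[, 1]) >= tl$rect[1] && max(w[, 1]) <= tl$rect[2])
      expect_true(min(w[, 2]) >= tl$rect[3] && max(w[, 2]) <= tl$rect[4])
    }
  }
  big <- neurotracer:::new_soma_region(9L, disk_mask(c(700, 700), 350, 350, 200))
  expect_error(tile_large_image(list(big), c(700, 700), max_tile = 100),
               "max_tile")
})
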