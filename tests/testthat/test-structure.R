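test_that("raw coverage score equals an enumeration over spanning cells", {
  g <- bin_grid(2e6, 5e5)
  v <- matrix(0, 4, 4)
  v[upper.tri(v)] <- c(2, 4, 8, 16, 32, 64)
  v <- v + t(v)
  m <- contact_matrix(v, g, stage = "iced")
  cs <- coverage_score(m, rescale = "none")
  raw <- cs$params$raw
  # bin 1 is spanned by (0,1), (0,2), (0,3), (1,2), (1,3)
  cells <- c(v[1, 2], v[1, 3], v[1, 4], v[2, 3], v[2, 4])
  expect_equal(raw[2], mean(cells))
  # full enumeration oracle for every bin
  for (i in 0:3) {
    acc <- c()
    for (a in 0:2) for (b in (a + 1):3) {
      if (a <= i && i <= b) acc <- c(acc, v[a + 1, b + 1])
    }
    expect_equal(raw[i + 1], mean(acc))
  }
})

test_that("uniform matrices give a flat coverage log2 ratio", {
  cs <- coverage_score(uniform_cm(40), rescale = "none")
  interior <- cs$values[5:36]
  expect_lt(max(abs(interior)), 1e-6)
})

test_that("coverage score is invariant to global scaling", {
  m <- iced_bipartite(seed = 5)
  m2 <- contact_matrix(m$values * 11, m$grid, mask = m$mask, stage = "iced")
  c1 <- coverage_score(m, rescale = "none")
  c2 <- coverage_score(m2, rescale = "none")
  expect_equal(c1$values, c2$values, tolerance = 1e-9)
})

test_that("coverage minimum marks the superdomain boundary on bipartite sims", {
  hits <- vapply(1:6, function(sd) {
    m <- iced_bipartite(seed = sd)
    cz <- coverage_score(m, rescale = "unit")
    abs((which.min(cz$values) - 1) - m$meta$truth$superdomain_boundary) <= 1
  }, TRUE)
  expect_true(all(hits))
})

test_that("edge exclusion drops the outermost bins and validates length", {
  m <- iced_bipartite(seed = 1)
  cz <- coverage_score(m, edge_exclude_bp = 1e7, rescale = "zscore")
  expect_true(all(is.na(cz$values[c(1:20, 181:200)])))
  short <- uniform_cm(10)
  expect_error(coverage_score(short, edge_exclude_bp = 3e6), "shorter")
})

test_that("boundary region extraction handles trivial and empty cases", {
  g <- bin_grid(5e6, 5e5)
  t_hi <- score_track(rep(0.5, 10), g, "coverage_01")
  expect_length(boundary_region(t_hi), 0)
  v <- rep(0.5, 10); v[4] <- 0.01
  t_one <- score_track(v, g, "coverage_01")
  expect_identical(boundary_region(t_one), 3L)
  v2 <- c(0.5, 0.01, 0.012, 0.005, 0.5, 0.01, rep(0.5, 4))
  reg <- boundary_region(score_track(v2, g, "coverage_01"))
  expect_identical(reg, 1:3)   # run containing the global minimum only
})

test_that("the boundary region flips sides after hinge inversion", {
  flips <- vapply(1:6, function(sd) {
    wt <- iced_bipartite(seed = sd)
    inv <- iced_bipartite(seed = sd, preset = "inv")
    h <- wt$meta$truth$hinge_bin
    br_wt <- boundary_region(coverage_score(wt, rescale = "unit"))
    br_inv <- boundary_region(coverage_score(inv, rescale = "unit"))
    length(br_wt) > 0 && length(br_inv) > 0 &&
      sign(mean(br_wt) - h) != sign(mean(br_inv) - h)
  }, TRUE)
  expect_true(all(flips))
})

test_that("insulation is flat on uniform matrices and dips at block junctions", {
  u <- uniform_cm(40)
  ip <- insulation_profile(u)
  ok <- !is.na(ip$insulation$values)
  expect_lt(max(abs(ip$insulation$values[ok])), 1e-6)
  okd <- !is.na(ip$delta$values)
  expect_lt(max(abs(ip$delta$values[okd])), 1e-6)

  b <- block_cm(20, split = 10, hi = 10, lo = 1)
  ipb <- insulation_profile(b, is_bp = 2.5e6, ids_bp = 1e6, ss_bp = 5e5)
  iv <- ipb$insulation$values
  # symmetric toy: the two junction-flanking bins tie at the minimum
  expect_true((which.min(iv) - 1) %in% c(9, 10))
  dv <- ipb$delta$values
  # +/- zero crossing at the junction
  expect_true(dv[10] > 0 && dv[11] <= 0)
})

test_that("insulation profiles are deterministic and scale invariant", {
  m <- iced_bipartite(seed = 4)
  i1 <- insulation_profile(m)
  i2 <- insulation_profile(m)
  expect_identical(i1$insulation$values, i2$insulation$values)
  m2 <- contact_matrix(m$values * 4, m$grid, mask = m$mask, stage = "iced")
  i3 <- insulation_profile(m2)
  expect_equal(i1$insulation$values, i3$insulation$values, tolerance = 1e-9)
  expect_error(insulation_profile(uniform_cm(30), is_bp = 5e5,
                                  ids_bp = 1e6, ss_bp = 5e5), "at least 2")
})

test_that("boundary calling on a block toy gives one junction boundary", {
  b <- block_cm(20, split = 10, hi = 10, lo = 1)
  ip <- insulation_profile(b, is_bp = 2.5e6, ids_bp = 1e6, ss_bp = 5e5)
  ts <- call_boundaries_tads(ip$insulation, ip$delta)
  expect_equal(ts$boundaries, 10L)
  dv <- ip$delta$values
  want <- max(dv[7:10], na.rm = TRUE) - min(dv[11:14], na.rm = TRUE)
  expect_equal(ts$strength, want)
  expect_equal(nrow(ts$tads), 2)

  mono <- score_track(seq(1, 0.1, length.out = 20), b$grid, "delta")
  ins <- score_track(rep(0, 20), b$grid, "insulation")
  expect_length(call_boundaries_tads(ins, mono)$boundaries, 0)
})

test_that("TAD boundaries and partitions are recovered on 5-block sims", {
  m <- iced_tads(seed = 2)
  ip <- insulation_profile(m)
  ts <- call_boundaries_tads(ip$insulation, ip$delta)
  truth <- m$meta$truth$tad_boundaries
  expect_length(truth, 4)
  for (b in truth) expect_true(any(abs(ts$boundaries - b) <= 1))
  ari <- tad_similarity(partition_from_tads(ts),
                        findInterval(0:199, truth) + 1L)
  expect_gt(ari, 0.8)
})

test_that("PC1 switches sign exactly once at the superdomain boundary", {
  hits <- vapply(1:6, function(sd) {
    m <- iced_bipartite(seed = sd)
    pc1 <- compartment_pcs(m)[[1]]
    sw <- sign_switch_bins(pc1)
    length(sw) == 1 && abs(sw - m$meta$truth$superdomain_boundary) <= 1
  }, TRUE)
  expect_true(all(hits))
})

test_that("PC1 sign pattern matches planted compartments", {
  m <- iced_compartments(seed = 3)
  v <- compartment_pcs(m)[[1]]$values
  lab <- m$meta$truth$compartment_labels
  ok <- !is.na(v)
  agree <- max(mean(sign(v[ok]) == ifelse(lab[ok] == "A", 1, -1)),
               mean(sign(v[ok]) == ifelse(lab[ok] == "A", -1, 1)))
  expect_gt(agree, 0.9)
})

test_that("PC tracks are deterministic with a fixed sign convention", {
  m <- iced_bipartite(seed = 9)
  p1 <- compartment_pcs(m)
  p2 <- compartment_pcs(m)
  for (k in 1:4) expect_identical(p1[[k]]$values, p2[[k]]$values)
  v <- p1[[1]]$values
  expect_gt(v[which.max(abs(v))], 0)
  expect_gt(p1[[1]]$params$explained_var, p1[[2]]$params$explained_var)
})

test_that("PC1 sign switch co-locates with the coverage minimum", {
  for (sd in c(2, 5, 8)) {
    m <- iced_bipartite(seed = sd)
    sw <- sign_switch_bins(compartment_pcs(m)[[1]])
    mn <- which.min(coverage_score(m, rescale = "unit")$values) - 1
    expect_lte(abs(sw[1] - mn), 1)
  }
})

test_that("Spearman track correlation matches a rank-then-Pearson oracle", {
  g <- bin_grid(6 * 5e5, 5e5)
  a <- score_track(c(1, 2, 2, 4, 5, 6) + 0, g, "pc1")
  b <- score_track(c(2, 1, 5, 4, 4, 9) + 0, g, "pc1")
  g10 <- bin_grid(10 * 5e5, 5e5)
  a10 <- score_track(c(1, 2, 2, 4, 5, 6, 7, 8, 9, 10), g10, "pc1")
  b10 <- score_track(c(2, 1, 5, 4, 4, 9, 6, 8, 10, 7), g10, "pc1")
  expect_equal(pc_correlation(a10, a10), 1)
  neg <- score_track(-a10$values, g10, "pc1")
  expect_equal(pc_correlation(a10, neg), -1)
  expect_equal(pc_correlation(a10, b10),
               cor(rank(a10$values), rank(b10$values)))
  expect_error(pc_correlation(a, b), "10 shared")
})

test_that("adjusted Rand index matches a pair-counting enumeration", {
  expect_equal(tad_similarity(rep(1:4, each = 5), rep(1:4, each = 5)), 1)
  # brute force over all bin pairs
  ari_brute <- function(x, y) {
    n <- length(x)
    a <- b <- c <- d <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      sx <- x[i] == x[j]; sy <- y[i] == y[j]
      if (sx && sy) a <- a + 1
      else if (sx && !sy) b <- b + 1
      else if (!sx && sy) c <- c + 1
      else d <- d + 1
    }
    n2 <- a + b + c + d
    exp_a <- (a + b) * (a + c) / n2
    (a - exp_a) / ((a + b + a + c) / 2 - exp_a)
  }
  x <- rep(1, 20)
  y <- rep(1:4, each = 5)
  expect_equal(tad_similarity(x, y), ari_brute(x, y))
  set.seed(3)
  x2 <- sample(1:3, 20, replace = TRUE)
  y2 <- sample(1:4, 20, replace = TRUE)
  expect_equal(tad_similarity(x2, y2), ari_brute(x2, y2))
  expect_equal(tad_similarity(x2, y2), tad_similarity(y2, x2))
  expect_error(tad_similarity(integer(0), integer(0)), "non-empty")
})

test_that("ARI agrees with an established implementation and is null-centred", {
  skip_if_not_installed("mclust")
  set.seed(11)
  for (i in 1:5) {
    x <- sample(1:4, 30, replace = TRUE)
    y <- sample(1:3, 30, replace = TRUE)
    expect_equal(tad_similarity(x, y), mclust::adjustedRandIndex(x, y),
                 tolerance = 1e-12)
  }
  set.seed(12)
  null_ari <- replicate(100, {
    tad_similarity(sample(1:3, 40, replace = TRUE),
                   sample(1:3, 40, replace = TRUE))
  })
  expect_lt(abs(mean(null_ari)), 0.05)
})

test_that("track clustering orders duplicates and opposites correctly", {
  g <- bin_grid(20 * 5e5, 5e5)
  set.seed(2)
  base <- rnorm(20)
  tracks <- list(a = score_track(base, g, "insulation"),
                 b = score_track(base, g, "insulation"),
                 c = score_track(-base, g, "insulation"))
  eu <- compare_tracks(tracks, "euclidean")
  dm <- as.matrix(eu$dist)
  expect_equal(dm["a", "b"], 0)
  om <- as.matrix(compare_tracks(tracks, "one_minus_r")$dist)
  expect_equal(om["a", "c"], 2, tolerance = 1e-12)
  # same-truth pair merges first
  merged_first <- eu$hclust$merge[1, ]
  expect_setequal(abs(merged_first), c(1, 2))
  expect_error(compare_tracks(tracks[1]), "at least 2")
})

test_that("same-truth insulation tracks cluster together", {
  t1 <- insulation_profile(iced_tads(seed = 1))$insulation
  t2 <- insulation_profile(iced_tads(seed = 2))$insulation
  u <- insulation_profile(iced_bipartite(seed = 1,
                                         chrom_length = 8e6,
                                         bin_size = 4e4))$insulation
  cl <- compare_tracks(list(tad_a = t1, tad_b = t2, bip = u), "euclidean")
  expect_setequal(abs(cl$hclust$merge[1, ]), c(1, 2))
})
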