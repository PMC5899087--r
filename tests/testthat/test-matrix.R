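test_that("pairs are binned by floor((pos - 1) / bin_size)", {
  g <- bin_grid(2e6, 5e5)
  p <- data.frame(chrom1 = "chrX", pos1 = c(1, 499999, 1),
                  chrom2 = "chrX", pos2 = c(1, 500001, 2e6),
                  strand1 = "+", strand2 = "-")
  m <- bin_pairs(p, g)
  expect_equal(m$values[1, 1], 1)       # (1, 1) -> cell (0, 0)
  expect_equal(m$values[1, 2], 1)       # 499999 -> bin 0, 500001 -> bin 1
  expect_equal(m$values[2, 1], 1)
  expect_equal(m$values[1, 4], 1)
  expect_equal(sum(m$values), 2 * 2 + 1) # diagonal cell counted once
  bad <- data.frame(chrom1 = "chrX", pos1 = 3e6, chrom2 = "chrX",
                    pos2 = 1, strand1 = "+", strand2 = "-")
  expect_error(bin_pairs(bad, g), "outside")
  expect_equal(sum(bin_pairs(p[0, ], g)$values), 0)
})

test_that("filtering zeroes the diagonal band and the lowest-coverage bins", {
  set.seed(1)
  n <- 100
  v <- matrix(rpois(n * n, 20), n, n)
  v <- v + t(v)
  # plant two near-empty bins
  v[5, ] <- v[, 5] <- rpois(n, 0.1)
  v[60, ] <- v[, 60] <- rpois(n, 0.1)
  m <- contact_matrix(v, bin_grid(n * 5e5, 5e5))
  f <- filter_matrix(m)
  d <- abs(row(f$values) - col(f$values))
  expect_true(all(f$values[d <= 1] == 0))
  # oracle: sort post-zeroing marginals, lowest 2% -> exactly bins 4, 59
  expect_equal(f$mask, c(4L, 59L))
  expect_true(all(f$values[f$mask + 1L, ] == 0))
})

test_that("tied marginals at the cutoff are all masked", {
  v <- matrix(5, 50, 50)
  m <- contact_matrix(v, bin_grid(50 * 5e5, 5e5))
  f <- filter_matrix(m)
  # after diagonal-band zeroing the 48 interior bins tie at the lowest
  # marginal; the tie at the percentile masks them all, corners survive
  expect_equal(f$mask, 1:48)
})

test_that("ICE balances row sums and is invertible through its bias vector", {
  m2 <- contact_matrix(matrix(c(0, 2, 2, 0), 2), bin_grid(1e6, 5e5),
                       stage = "filtered")
  b2 <- ice_normalize(m2)
  expect_equal(b2$values / sum(b2$values), m2$values / sum(m2$values),
               tolerance = 1e-10)

  m <- random_cm(50, seed = 3)
  out <- ice_normalize(m, tol = 1e-6)
  rs <- rowSums(out$values)
  expect_lt(sd(rs) / mean(rs), 1e-4)
  b <- out$meta$ice_bias
  recon <- out$values * outer(b, b)
  expect_lt(max(abs(recon - m$values) / max(m$values)), 1e-8)
  expect_equal(sum(out$values), sum(m$values), tolerance = 1e-8)

  zero <- contact_matrix(matrix(0, 5, 5), bin_grid(25e5, 5e5),
                         stage = "filtered")
  expect_error(ice_normalize(zero), "all-zero")
})

test_that("masked bins stay zero with undefined bias through ICE", {
  m <- random_cm(20, seed = 4)
  mm <- contact_matrix(m$values * outer(0:19 != 3, 0:19 != 3),
                       m$grid, mask = 3L, stage = "filtered")
  out <- ice_normalize(mm)
  expect_true(all(out$values[4, ] == 0))
  expect_true(is.na(out$meta$ice_bias[4]))
})

test_that("quantile normalization equals a rank-mean oracle on toys", {
  g <- bin_grid(2e6, 5e5)
  va <- matrix(0, 4, 4); vb <- matrix(0, 4, 4)
  va[upper.tri(va)] <- c(1, 2, 3, 4, 5, 6)
  vb[upper.tri(vb)] <- c(10, 40, 20, 60, 30, 50)
  va <- va + t(va); vb <- vb + t(vb)
  a <- contact_matrix(va, g, stage = "iced")
  b <- contact_matrix(vb, g, stage = "iced")
  qn <- quantile_normalize(list(a, b))
  # brute-force oracle: sort each vector, average rank-wise, put back
  xa <- va[upper.tri(va)]; xb <- vb[upper.tri(vb)]
  pooled <- (sort(xa) + sort(xb)) / 2
  want_a <- pooled[rank(xa)]
  want_b <- pooled[rank(xb)]
  expect_equal(qn[[1]]$values[upper.tri(va)], want_a)
  expect_equal(qn[[2]]$values[upper.tri(vb)], want_b)
  expect_identical(qn[[1]]$values, t(qn[[1]]$values))
})

test_that("quantile normalization is an identity on a matrix against itself", {
  m <- random_cm(30, seed = 5, stage = "iced")
  qn <- quantile_normalize(list(m, m))
  ut <- upper.tri(m$values)
  expect_equal(qn[[1]]$values[ut], m$values[ut], tolerance = 1e-12)
  expect_equal(qn[[2]]$values[ut], m$values[ut], tolerance = 1e-12)
  g2 <- random_cm(20, seed = 6, stage = "iced")
  expect_error(quantile_normalize(list(m, g2)), "grid")
})

test_that("identical rank orders give identical matrices after quantile", {
  m <- random_cm(15, seed = 7, stage = "iced")
  m2 <- contact_matrix(m$values * 3 + 1, m$grid, stage = "iced")
  qn <- quantile_normalize(list(m, m2))
  expect_equal(qn[[1]]$values, qn[[2]]$values, tolerance = 1e-12)
})

test_that("Pearson transform gives +-1 blocks on a two-block toy", {
  m <- block_cm(8, split = 4)
  p <- pearson_transform(m)
  expect_equal(p$stage, "pearson")
  within <- p$values[1, 2]; across <- p$values[1, 5]
  expect_gt(within, 0.9)
  expect_lt(across, -0.9)
  expect_equal(diag(p$values), rep(1, 8))
})

test_that("Pearson transform is scale invariant and mask aware", {
  m <- random_cm(20, seed = 8, stage = "iced")
  p1 <- pearson_transform(m)
  p2 <- pearson_transform(cm_scaled <- contact_matrix(m$values * 7.3,
                                                      m$grid, stage = "iced"))
  expect_equal(p1$values, p2$values, tolerance = 1e-10)
  masked <- contact_matrix(m$values * outer(0:19 != 2, 0:19 != 2), m$grid,
                           mask = 2L, stage = "iced")
  pm <- pearson_transform(masked)
  expect_true(all(is.na(pm$values[3, ])))
  expect_error(pearson_transform(random_cm(5, stage = "raw")), "iced")
})

test_that("differential maps subtract elementwise with missing propagation", {
  m <- random_cm(10, seed = 9, stage = "iced")
  expect_true(all(differential_map(m, m) == 0))
  v2 <- m$values; v2[2, 3] <- v2[3, 2] <- NA
  m2 <- contact_matrix(v2, m$grid, stage = "iced")
  d <- differential_map(m2, m)
  expect_true(is.na(d[2, 3]))
  expect_error(differential_map(m, pearson_transform(m)), "stage")
})

test_that("decay curve is uniform for uniform matrices and sums to one", {
  u <- uniform_cm(4)
  dc <- decay_curve(u)
  # k masses proportional to cell counts (3, 2, 1): per-cell mean uniform
  expect_equal(dc$mean, rep(1, 3))
  expect_equal(sum(dc$prob), 1)
  expect_error(decay_curve(u, region = c(1, 1)), "2 bins")
})

test_that("fitted decay exponent recovers the generator alpha", {
  m <- iced_decay(seed = 6)
  dc <- decay_curve(m)
  expect_equal(sum(dc$prob), 1, tolerance = 1e-12)
  alpha <- fit_decay_exponent(dc)
  expect_lt(abs(alpha - 1) / 1, 0.1)
})

test_that("regional decay curves respect their support and insulation loss
           shifts mass to very long range", {
  m <- iced_bipartite(seed = 2)
  h <- m$meta$truth$hinge_bin
  sd1 <- decay_curve(m, region = c(0, h - 1))
  expect_equal(sum(sd1$prob[h:199], na.rm = TRUE), 0)
  expect_equal(sum(sd1$prob, na.rm = TRUE), 1, tolerance = 1e-12)
  # losing the superdomain seam increases the very-long-range proportion,
  # the hallmark of the hinge-deleted contact profile
  del <- iced_bipartite(seed = 2, preset = "del")
  wt_curve <- decay_curve(m)
  del_curve <- decay_curve(del)
  expect_gt(sum(del_curve$prob[40:198], na.rm = TRUE),
            sum(wt_curve$prob[40:198], na.rm = TRUE))
})

test_that("autosomal scaling factors follow the least-squares closed form", {
  u <- uniform_cm(30)
  base <- decay_curve(u)
  twice <- base; twice$mean <- base$mean * 2; twice$sum <- base$sum * 2
  sc <- autosomal_scale(list(a = base, b = base),
                        list(a = base, b = twice))
  expect_equal(unname(sc$factors), c(1, 0.5))
  # noisy 2x case stays within 5%
  set.seed(10)
  noisy <- base
  noisy$mean <- base$mean * 2 * exp(rnorm(length(base$mean), 0, 0.05))
  sc2 <- autosomal_scale(list(a = base, b = base), list(a = base, b = noisy))
  expect_lt(abs(sc2$factors[["b"]] - 0.5) / 0.5, 0.05)
  zero <- base; zero$mean[] <- 0
  expect_error(autosomal_scale(list(a = base), list(a = zero)), "zero mass")
})

test_that("virtual 4C tracks are row sums with missing viewpoints", {
  m <- random_cm(20, seed = 11, stage = "iced")
  t1 <- virtual_4c(m, 5)
  expect_equal(t1$values[-6], m$values[6, -6])
  expect_true(is.na(t1$values[6]))
  t2 <- virtual_4c(m, c(5, 6))
  expect_equal(t2$values[-(6:7)], colSums(m$values[6:7, ])[-(6:7)])
  expect_error(virtual_4c(m, 25), "viewpoint")
})

test_that("virtual 4C side mass at the hinge inverts after inversion", {
  wt <- iced_bipartite(seed = 3)
  inv <- iced_bipartite(seed = 3, preset = "inv")
  h <- wt$meta$truth$hinge_bin
  side_ratio <- function(m) {
    t0 <- virtual_4c(m, h)
    sum(t0$values[(h + 2):200], na.rm = TRUE) /
      sum(t0$values[1:h], na.rm = TRUE)
  }
  expect_gt(side_ratio(wt), 1)
  expect_lt(side_ratio(inv), 1)
})

test_that("transforms preserve symmetry and mask", {
  m <- simulate_preset("wt", seed = 12)
  f <- filter_matrix(m)
  i <- ice_normalize(f)
  p <- pearson_transform(i)
  for (x in list(f, i)) {
    expect_lt(max(abs(x$values - t(x$values))), 1e-9)
    expect_identical(x$mask, f$mask)
    expect_true(all(x$values[x$mask + 1L, ] == 0))
  }
  expect_identical(p$mask, f$mask)
  expect_true(all(is.na(p$values[p$mask + 1L, ])))
})
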