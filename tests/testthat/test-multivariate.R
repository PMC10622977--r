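test_that("Manhattan distances follow the city-block definition", {
  x <- rbind(c(0, 0), c(1, 2), c(0, 0))
  d <- as.matrix(manhattan_distances(x, standardize = FALSE))
  expect_equal(d[1, 2], 3)
  expect_equal(d[1, 3], 0)
  expect_equal(d, t(d))
  # column permutation invariance
  d2 <- as.matrix(manhattan_distances(x[, 2:1], standardize = FALSE))
  expect_equal(d, d2)
  xna <- x; xna[2, 1] <- NA
  expect_error(manhattan_distances(xna), "missing values")
})

test_that("PCoA reproduces known configurations", {
  # three collinear points: first axis separation equals the distance
  d <- as.dist(matrix(c(0, 2, 1, 2, 0, 1, 1, 1, 0), 3))
  ord <- pcoa(d)
  expect_equal(abs(ord$points[1, 1] - ord$points[2, 1]), 2, tolerance = 1e-8)

  # Euclidean distances from a known 2D configuration are reproduced:
  # inter-point distances of the embedding equal the originals
  set.seed(3)
  conf <- matrix(rnorm(20), 10, 2)
  ord2 <- pcoa(dist(conf))
  expect_equal(as.vector(dist(ord2$points[, 1:2])),
               as.vector(dist(conf)), tolerance = 1e-8)
  expect_lte(ord2$n_negative, 0)
  # coordinates are centered and axes ordered by decreasing eigenvalue
  expect_lt(max(abs(colMeans(ord2$points[, 1:2]))), 1e-9)
  expect_true(all(diff(ord2$eig) <= 1e-8))
  # positive eigenvalues conserve the Gower-centered trace
  dm <- as.matrix(dist(conf))
  g <- -0.5 * dm^2
  g <- sweep(sweep(g, 1, rowMeans(g)), 2, colMeans(g)) + mean(g)
  expect_equal(sum(ord2$eig[ord2$eig > 1e-8]), sum(diag(g)),
               tolerance = 1e-8)

  expect_error(pcoa(dist(matrix(0, 4, 2))), "all distances are zero")
})

test_that("PCoA matches the standard implementation on Manhattan input", {
  skip_if_not_installed("ape")
  set.seed(8)
  x <- matrix(rnorm(60), 12, 5)
  d <- manhattan_distances(x)
  ours <- pcoa(d)
  ref <- ape::pcoa(d)
  k <- min(ncol(ours$points), ncol(ref$vectors))
  for (j in seq_len(min(3, k))) {
    expect_equal(abs(ours$points[, j]), abs(ref$vectors[, j]),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("PERMANOVA matches complete enumeration on a toy design", {
  x <- c(0, 0, 0, 10, 10, 10)
  g <- factor(rep(c("a", "b"), each = 3))
  d <- dist(x)
  res <- permanova(d, g)  # auto-enumerates: choose(6,3) = 20
  oracle <- oracle_permanova_enum(d, g)
  expect_equal(res$F, oracle$F, tolerance = 1e-12)
  expect_equal(res$p, oracle$p)
  expect_equal(res$p, 2 / 20)  # only the two block labelings reach F_obs
  expect_match(res$method, "enumeration")

  # Monte-Carlo agrees with enumeration up to sampling resolution
  mc <- permanova(d, g, n_permutations = 9999, seed = 1, complete = FALSE)
  expect_lt(abs(mc$p - oracle$p), 0.01 + 1 / (9999 + 1))

  # pseudo-F invariant under distance rescaling
  expect_equal(permanova(d * 17, g, complete = TRUE)$F, res$F,
               tolerance = 1e-10)

  expect_error(permanova(d, factor(c("a", "a", "a", "a", "a", "b"))),
               "singleton")
})

test_that("PERMANOVA agrees with vegan and is calibrated under the null", {
  skip_if_not_installed("vegan")
  set.seed(12)
  x <- matrix(rnorm(24 * 4), 24)
  g <- factor(rep(c("a", "b"), each = 12))
  d <- dist(x, method = "manhattan")
  ours <- permanova(d, g, n_permutations = 999, seed = 2, complete = FALSE)
  ref <- vegan::adonis2(d ~ g, permutations = 999)
  expect_equal(ours$F, ref$F[1], tolerance = 1e-10)
  expect_equal(ours$df_between, ref$Df[1])

  # null calibration: p roughly uniform -> rejection rate near 0.05
  rej <- vapply(1:60, function(s) {
    xs <- matrix(rnorm(12 * 3), 12)
    permanova(dist(xs), factor(rep(c("a", "b"), each = 6)),
              n_permutations = 199, seed = s, complete = FALSE)$p <= 0.05
  }, logical(1))
  expect_lt(mean(rej), 0.18)
})

test_that("animal integration joins and validates ids", {
  beh <- data.frame(animal_id = c("a1", "a2", "a3", "a4"),
                    group = rep(c("x", "y"), 2), m1 = 1:4)
  phys <- data.frame(animal_id = c("a4", "a3", "a2", "a1"), bmr = 5:8,
                     mb_g = 9:12)
  mf <- data.frame(animal_id = paste0("a", 1:4), H = runif(4))
  out <- integrate_animals(beh, phys, mf)
  expect_equal(out$animal_id, beh$animal_id)
  expect_equal(out$bmr, c(8, 7, 6, 5))  # re-ordered to match behavior ids
  expect_equal(names(out), c("animal_id", "group", "m1", "bmr", "mb_g", "H"))

  expect_error(integrate_animals(beh, phys[1:3, ]), "id mismatch")
  expect_error(integrate_animals(beh, rbind(phys, phys[1, ])), "duplicate")
  phys2 <- phys; phys2$animal_id[1] <- "zz"
  expect_error(integrate_animals(beh, phys2), "zz")
  expect_error(integrate_animals(beh, phys, variables = "nope"),
               "unknown variables")
})
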