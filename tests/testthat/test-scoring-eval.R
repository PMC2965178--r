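shared_potentials <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      native <- small_fixture()
      train <- suppressMessages(lapply(1:40, function(i)
        perturb_structure(native, 0.35, seed = 500 + i)))
      cache <<- list(
        native = native,
        dp = suppressMessages(train_rw(train)),
        op = suppressMessages(train_orientation(train)))
    }
    cache
  }
})

test_that("the hybrid score composes the two terms with the orientation weight", {
  ctx <- shared_potentials()
  s <- ctx$native
  sc0 <- score_rwplus(s, ctx$dp, ctx$op, w_orient = 0)
  expect_equal(sc0$e_rwplus, sc0$e_rw)
  sc <- score_rwplus(s, ctx$dp, ctx$op, w_orient = 0.1)
  expect_equal(sc$e_rwplus, sc$e_rw + 0.1 * sc$e_orient, tolerance = 1e-9)
  # w_orient = 0.1 with E_orient = -50 shifts the total by -5
  expect_equal(sc$e_rw + 0.1 * (-50), sc$e_rw - 5)
  # components match their stand-alone scoring paths
  expect_equal(sc$e_rw, score_rw(s, ctx$dp))
  expect_equal(sc$e_orient, score_orientation(s, ctx$op))
  # without an orientation potential the term is zero
  expect_equal(score_rwplus(s, ctx$dp)$e_orient, 0)
})

test_that("Kabsch RMSD is zero on rigid copies, symmetric, and matches a grid oracle", {
  set.seed(15)
  P <- matrix(rnorm(30, sd = 5), ncol = 3L)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  Q <- P %*% t(R) + matrix(rnorm(3, sd = 10), nrow(P), 3L, byrow = TRUE)
  expect_equal(kabsch_rmsd(P, Q), 0, tolerance = 1e-9)
  Q2 <- Q + matrix(rnorm(30, sd = 1), ncol = 3L)
  expect_equal(kabsch_rmsd(P, Q2), kabsch_rmsd(Q2, P), tolerance = 1e-12)
  expect_error(kabsch_rmsd(P, Q2[1:9, ]), "size")
  # 4-point toy set against an exhaustive rotation-grid oracle
  P4 <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  Q4 <- rbind(c(0.1, 0, 0), c(2, 0.2, 0), c(-0.1, 1.9, 0.1), c(0, 0.1, 2.1))
  rmsd_at <- function(a, b, c) {
    Rz <- rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
    Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
    Rx <- rbind(c(1, 0, 0), c(0, cos(c), -sin(c)), c(0, sin(c), cos(c)))
    Pc <- sweep(P4, 2, colMeans(P4))
    Qc <- sweep(Q4, 2, colMeans(Q4))
    sqrt(mean(rowSums((Qc - Pc %*% t(Rz %*% Ry %*% Rx))^2)))
  }
  g <- seq(-0.2, 0.2, length.out = 21L)
  oracle <- min(vapply(seq_len(21L^3) - 1L, function(i) {
    rmsd_at(g[i %% 21L + 1L], g[(i %/% 21L) %% 21L + 1L], g[i %/% 441L + 1L])
  }, numeric(1)))
  expect_lte(kabsch_rmsd(P4, Q4), oracle + 1e-9)
  # the grid has 0.02 rad spacing, so agreement is to ~2%
  expect_equal(kabsch_rmsd(P4, Q4), oracle, tolerance = 0.02)
})

test_that("Kabsch uses proper rotations only (no reflection onto mirror images)", {
  set.seed(16)
  P <- matrix(rnorm(30, sd = 5), ncol = 3L)
  Pm <- P
  Pm[, 1] <- -Pm[, 1]      # mirror image
  expect_gt(kabsch_rmsd(P, Pm), 0.5)
})

test_that("the built-in TM-score is 1 on identity and decreases with noise", {
  s <- small_fixture()
  expect_equal(tm_score(s, s), 1, tolerance = 1e-9)
  t1 <- tm_score(perturb_structure(s, 1, seed = 2), s)
  t4 <- tm_score(perturb_structure(s, 4, seed = 2), s)
  expect_true(t1 > t4)
  # at L = 30, d0 is only ~1.26 A, so 1 A noise already costs much of the
  # score; the point is ordering and range, not a particular value
  expect_true(t1 > 0.25 && t1 <= 1)
  expect_true(t4 > 0)
})

test_that("decoy evaluation recognises the native and reports a funnel", {
  ctx <- shared_potentials()
  ds <- make_decoy_set(ctx$native, c(0.5, 1, 2), 12L, seed = 31)
  rep <- evaluate_decoy_set(ctx$native, ds$decoys, ctx$dp, ctx$op)
  g <- glance(rep)
  expect_equal(g$native_rank, 1L)
  expect_lt(g$z_native, 0)
  expect_gt(g$corr_energy_rmsd, 0.3)
  td <- tidy(rep)
  expect_equal(nrow(td), 37L)
  expect_equal(td$e_rwplus, td$e_rw + 0.1 * td$e_orient, tolerance = 1e-9)
  # best quality within top-k can only improve as k grows
  expect_lte(g$top10_rmsd, g$top5_rmsd)
  expect_lte(g$top5_rmsd, g$top1_rmsd)
})

test_that("rankings ignore constant energy offsets and z is scale-free", {
  ctx <- shared_potentials()
  ds <- make_decoy_set(ctx$native, c(1, 2), 5L, seed = 8)
  rep1 <- evaluate_decoy_set(ctx$native, ds$decoys, ctx$dp, ctx$op)
  z1 <- rep1$summary$z_native
  # affine rescaling of all scores leaves ranks and z unchanged
  sc <- rep1$scores
  expect_equal(order(sc$e_rwplus * 3.7 + 120, sc$name), order(sc$rank))
  e <- sc$e_rwplus * 3.7 + 120
  z2 <- (e[sc$is_native] - mean(e)) / sd(e)
  expect_equal(z2, z1, tolerance = 1e-12)
})

test_that("degenerate decoy sets yield undefined z and missing correlations", {
  ctx <- shared_potentials()
  same <- list(a = ctx$native, b = ctx$native, c = ctx$native)
  rep <- evaluate_decoy_set(ctx$native, same, ctx$dp)
  expect_true(is.na(rep$summary$z_native))
  expect_true(is.na(rep$summary$corr_energy_rmsd))  # zero quality spread
  expect_error(evaluate_decoy_set(ctx$native, same[1], ctx$dp), "at least 2")
})

test_that("a monotone linear energy-quality relation gives correlation 1", {
  ctx <- shared_potentials()
  ds <- make_decoy_set(ctx$native, c(0.5, 1, 2), 4L, seed = 12)
  quality <- data.frame(name = names(ds$decoys), rmsd = NA_real_, tm = NA_real_)
  rep0 <- evaluate_decoy_set(ctx$native, ds$decoys, ctx$dp, ctx$op)
  dec <- rep0$scores[!rep0$scores$is_native, ]
  quality$rmsd <- 2 * dec$e_rwplus[match(quality$name, dec$name)] + 7
  quality$tm <- -0.001 * quality$rmsd + 0.9
  rep <- evaluate_decoy_set(ctx$native, ds$decoys, ctx$dp, ctx$op,
                            quality = quality)
  expect_equal(rep$summary$corr_energy_rmsd, 1, tolerance = 1e-12)
  expect_equal(rep$summary$corr_energy_tm, -1, tolerance = 1e-12)
})

test_that("external quality tables override internal RMSD and feed TM columns", {
  ctx <- shared_potentials()
  ds <- make_decoy_set(ctx$native, c(1), 3L, seed = 4)
  quality <- data.frame(name = names(ds$decoys),
                        rmsd = c(9, 8, 7), tm = c(0.2, 0.3, 0.4))
  rep <- evaluate_decoy_set(ctx$native, ds$decoys, ctx$dp, quality = quality)
  sc <- rep$scores[!rep$scores$is_native, ]
  expect_equal(sort(sc$rmsd), c(7, 8, 9), ignore_attr = TRUE)
  expect_equal(sort(sc$tm), c(0.2, 0.3, 0.4), ignore_attr = TRUE)
})
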