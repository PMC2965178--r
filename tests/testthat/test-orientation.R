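test_that("frames are orthonormal, equivariant, and reject collinear triples", {
  m <- build_frame(c(0, 0, 0), c(0, 0, 1), c(1, 0, 0))
  expect_equal(m, diag(3), ignore_attr = TRUE)
  # orthonormality and right-handedness for a generic triple
  f <- build_frame(c(1, 2, 3), c(2, 4, 3.5), c(0, 1, 1))
  expect_equal(crossprod(f), diag(3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(det(f), 1, tolerance = 1e-12)
  # equivariance under rigid rotation
  set.seed(1)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  f2 <- build_frame(R %*% c(1, 2, 3), R %*% c(2, 4, 3.5), R %*% c(0, 1, 1))
  expect_equal(f2, R %*% f, tolerance = 1e-12)
  expect_error(build_frame(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2)), "collinear")
})

test_that("the direction partition tiles the sphere with exactly 26 bins", {
  th <- seq(0, pi, length.out = 181L)
  ph <- seq(0, 2 * pi - 1e-9, length.out = 360L)
  grid <- expand.grid(theta = th, phi = ph)
  bins <- direction_bin(grid$theta, grid$phi)
  expect_false(anyNA(bins))
  expect_equal(sort(unique(bins)), 1:26)
  # polar caps catch every azimuth
  expect_true(all(direction_bin(rep(0.1, 8L), seq(0, 2 * pi - 0.1, length.out = 8L)) == 1L))
  expect_true(all(direction_bin(rep(pi - 0.1, 8L), seq(0, 2 * pi - 0.1, length.out = 8L)) == 2L))
  # the phi = pi/8 boundary opens its sector (half-open convention)
  b_open <- direction_bin(pi / 2, pi / 8)
  b_before <- direction_bin(pi / 2, pi / 8 - 1e-9)
  expect_false(b_open == b_before)
  # wrap-around sector: phi just below 2*pi shares the sector of phi = 0
  expect_equal(direction_bin(pi / 2, 2 * pi - 1e-9), direction_bin(pi / 2, 0))
  expect_error(direction_bin(-0.1, 0), "theta")
  expect_error(direction_bin(pi / 2, 2 * pi), "phi")
})

test_that("direction reference probabilities are exact sphere-area fractions", {
  p <- direction_ref_prob()
  expect_length(p, 26L)
  expect_equal(sum(p), 1, tolerance = 1e-14)
  expect_equal(p[1], (1 - sqrt(3) / 2) / 2, tolerance = 1e-14)  # polar cap
  expect_equal(p[1], p[2])
  expect_equal(unique(p[11:18]), 1 / 16)                        # equatorial sectors
  expect_equal(p[3:10], p[19:26])                               # mirror bands
})

test_that("the flat orientation index is a bijection over 2704 bins", {
  u <- unpack_orientation_index(seq_len(N_ORIENTATION_BINS))
  expect_equal(flat_orientation_index(u$dir_ab, u$dir_ba, u$torsion),
               seq_len(N_ORIENTATION_BINS))
  expect_equal(N_ORIENTATION_BINS, 26L * 26L * 4L)
  pref <- orientation_ref_prob()
  expect_length(pref, 2704L)
  expect_equal(sum(pref), 1, tolerance = 1e-12)
})

test_that("relative orientation swaps directions and preserves the torsion", {
  # the A1-A0-B0-B1 dihedral read in reverse atom order is the same signed
  # angle, so the torsion bin is symmetric under the swap
  set.seed(3)
  for (i in 1:20) {
    A <- matrix(rnorm(9, sd = 2), 3L)
    B <- matrix(rnorm(9, sd = 2), 3L) + 8
    oab <- relative_orientation(A, B)
    oba <- relative_orientation(B, A)
    expect_equal(oab$dir_ab, oba$dir_ba)
    expect_equal(oab$dir_ba, oba$dir_ab)
    expect_equal(oba$torsion, oab$torsion)
  }
  expect_error(relative_orientation(diag(3), diag(3)), "coincident")
})

test_that("relative orientation is invariant under rigid-body transforms", {
  set.seed(4)
  A <- matrix(rnorm(9, sd = 2), 3L)
  B <- matrix(rnorm(9, sd = 2), 3L) + 6
  o1 <- relative_orientation(A, B)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t0 <- rnorm(3, sd = 30)
  tf <- function(M) t(R %*% t(M) + t0)
  o2 <- relative_orientation(tf(A), tf(B))
  expect_identical(o1, o2)
})

test_that("rotations about the inter-origin axis populate torsion bins uniformly", {
  # B spun about the A0-B0 axis: torsion sweeps, directions fixed
  set.seed(5)
  A <- rbind(c(0, 0, 0), c(0, 0, 1.5), c(1.2, 0, 0))
  B0 <- c(6, 0, 0)
  n <- 1e4L
  angs <- runif(n, 0, 2 * pi)
  tor <- integer(n)
  dirs <- integer(n)
  axis_rot <- function(ang) {
    # rotation about the x axis (the A0->B0 direction)
    rbind(c(1, 0, 0), c(0, cos(ang), -sin(ang)), c(0, sin(ang), cos(ang)))
  }
  base_B <- rbind(c(0, 0, 0), c(0, 1.4, 0.6), c(0.9, -0.5, 0.4))
  for (i in seq_len(n)) {
    Bi <- t(axis_rot(angs[i]) %*% t(base_B))
    Bi <- sweep(Bi, 2L, -B0)
    o <- relative_orientation(A, Bi)
    tor[i] <- o$torsion
    dirs[i] <- o$dir_ab
  }
  expect_equal(length(unique(dirs)), 1L)   # direction A->B unchanged
  expect_gt(chisq.test(tabulate(tor, 4L))$p.value, 0.001)
})

test_that("contact detection uses a strict heavy-atom cutoff and matches brute force", {
  a <- rbind(c(0, 0, 0), c(1.5, 0, 0))
  expect_true(in_contact(a, rbind(c(9.99 + 1.5, 0, 0)), 10))
  expect_false(in_contact(a, rbind(c(10 + 1.5, 0, 0)), 10))
  s <- small_fixture()
  xyz <- cbind(s$x, s$y, s$z)
  by_res <- split(seq_len(nrow(s)), s$residue_index)
  for (pair in list(c(1L, 4L), c(2L, 9L), c(5L, 25L), c(10L, 30L))) {
    ai <- xyz[by_res[[pair[1]]], , drop = FALSE]
    bi <- xyz[by_res[[pair[2]]], , drop = FALSE]
    brute <- min(as.matrix(dist(rbind(ai, bi)))[seq_len(nrow(ai)),
                                                nrow(ai) + seq_len(nrow(bi))]) < 10
    expect_equal(in_contact(ai, bi, 10), brute)
  }
})

test_that("vector-pair definitions cover 18 side chains plus 2 backbone types", {
  defs <- vector_pair_defs()
  expect_equal(nrow(defs), 20L)
  expect_equal(n_vector_pair_types(defs), 20L)
  expect_equal(sum(defs$residue_scope == "backbone"), 2L)
  sc <- defs$residue_scope[defs$residue_scope != "backbone"]
  expect_setequal(sc, setdiff(aa20, c("GLY", "ALA")))
  # definitions round-trip through their TSV form
  f <- withr::local_tempfile(fileext = ".tsv")
  write_vector_pair_defs(defs, f)
  defs2 <- read_vector_pair_defs(f)
  expect_equal(as.data.frame(defs2), as.data.frame(defs))
  writeLines("vp_type\tresidue_scope", f)
  expect_error(read_vector_pair_defs(f), "columns")
})

test_that("uniform random orientations train to near-zero energies", {
  cnt <- sample_orientation_counts(2e5, seed = 12)
  expect_equal(sum(cnt), 2e5)
  nv <- 20L
  arr <- array(0, dim = c(nv, nv, N_ORIENTATION_BINS))
  arr[3L, 5L, ] <- cnt
  arr[5L, 3L, ] <- cnt
  op <- orientation_potential_from_counts(arr)
  e <- op$energy[3L, 5L, ]
  band <- 3 / sqrt(pmax(cnt, 1))
  expect_gt(mean(abs(e) <= band), 0.99)
  expect_true(all(abs(e) <= 5 / sqrt(pmax(cnt, 1))))
  # untouched pairs stay flat at zero
  expect_true(all(op$energy[1L, 2L, ] == 0))
})

test_that("a single occupied orientation bin trains to a deep minimum", {
  nv <- 20L
  arr <- array(0, dim = c(nv, nv, N_ORIENTATION_BINS))
  arr[2L, 7L, 100L] <- 500
  op <- orientation_potential_from_counts(arr)
  expect_lt(op$energy[2L, 7L, 100L], -3)
  expect_true(all(op$energy[2L, 7L, -100L] == op$cap))
})

test_that("observed and expected orientation counts share their per-pair totals", {
  tr <- suppressMessages(lapply(1:3, function(i)
    generate_fixture(fixture_sequence(20, seed = i), seed = i)))
  nv <- 20L
  obs <- array(0, dim = c(nv, nv, N_ORIENTATION_BINS))
  for (s in tr) {
    ev <- rwpot:::.orientation_events(s, vector_pair_defs(), 10, 2L)
    for (r in seq_len(nrow(ev))) {
      obs[ev$vpa[r], ev$vpb[r], ev$flat_ab[r]] <-
        obs[ev$vpa[r], ev$vpb[r], ev$flat_ab[r]] + 1
      obs[ev$vpb[r], ev$vpa[r], ev$flat_ba[r]] <-
        obs[ev$vpb[r], ev$vpa[r], ev$flat_ba[r]] + 1
    }
  }
  tot <- apply(obs, c(1, 2), sum)
  expd <- array(as.numeric(tot) %o% orientation_ref_prob(), dim = dim(obs))
  expect_equal(apply(expd, c(1, 2), sum), tot, tolerance = 1e-9)
})

test_that("orientation scoring is zero without contacts, rigid-invariant, and matches brute force", {
  tr <- suppressMessages(lapply(1:4, function(i)
    generate_fixture(fixture_sequence(20, seed = 10 + i), seed = 20 + i)))
  op <- suppressMessages(train_orientation(tr))
  s <- suppressMessages(generate_fixture(fixture_sequence(20, seed = 31), seed = 31))
  e <- score_orientation(s, op)
  expect_true(is.finite(e))
  # brute-force re-summation over residue pairs
  defs <- vector_pair_defs()
  xyz <- cbind(s$x, s$y, s$z)
  by_res <- split(seq_len(nrow(s)), s$residue_index)
  inst_of <- function(i) {
    res <- s$residue_name[by_res[[i]][1]]
    rows <- defs[defs$residue_scope %in% c(res, "backbone"), , drop = FALSE]
    out <- list()
    for (r in seq_len(nrow(rows))) {
      at <- s[by_res[[i]], ]
      m <- rbind(
        as.numeric(at[match(rows$x0[r], at$atom_name), c("x", "y", "z")]),
        as.numeric(at[match(rows$x1[r], at$atom_name), c("x", "y", "z")]),
        as.numeric(at[match(rows$x2[r], at$atom_name), c("x", "y", "z")]))
      if (anyNA(m)) next
      out[[length(out) + 1L]] <- list(vp = rows$vp_type[r], m = m)
    }
    out
  }
  e_brute <- 0
  nres <- n_residues(s)
  for (i in seq_len(nres - 2L)) {
    for (j in (i + 2L):nres) {
      ai <- xyz[by_res[[i]], , drop = FALSE]
      bj <- xyz[by_res[[j]], , drop = FALSE]
      if (!in_contact(ai, bj, op$contact_cutoff)) next
      for (va in inst_of(i)) for (vb in inst_of(j)) {
        o <- relative_orientation(va$m, vb$m)
        e_brute <- e_brute + op$energy[va$vp, vb$vp, o$flat]
      }
    }
  }
  expect_equal(e, e_brute, tolerance = 1e-9)
  # rigid-body invariance
  expect_equal(score_orientation(rigid_transform(s, 77), op), e, tolerance = 1e-6)
  # far-apart residues: no contacts, zero energy
  far <- s
  far$x <- far$x + 200 * far$residue_index
  expect_equal(score_orientation(far, op), 0)
})
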