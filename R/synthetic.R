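#' Seeded synthetic structures, training sets and decoy sets
#'
#' Desk-scale stand-ins for experimental training libraries and decoy
#' downloads: a toy-polypeptide fixture generator with idealised backbone
#' geometry, Gaussian perturbation decoys with a known RMSD ladder,
#' random-walk chain ensembles whose pair-distance statistics follow the
#' reference state by construction (with optional injected pair-distance
#' biases of known location), and a uniform-orientation sampler for the
#' orientation term.  Every generator is fully determined by its seed.
#'
#' @name synthetic-data
NULL

.residue_heavy_atoms <- function(res) c(.BACKBONE, .SIDECHAIN[[res]])

.check_sequence <- function(sequence) {
  sequence <- toupper(sequence)
  bad <- setdiff(unique(sequence), .AA3)
  if (length(bad))
    abort(sprintf("non-standard residue(s) in sequence: %s",
                  paste(bad, collapse = ", ")))
  if (length(sequence) < 3L) abort("sequence must have at least 3 residues")
  sequence
}

# backbone ideal geometry (A, radians)
.BB <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
            a_n_ca_c = 111.0 * pi / 180, a_ca_c_n = 116.6 * pi / 180,
            a_c_n_ca = 121.9 * pi / 180, a_ca_c_o = 120.8 * pi / 180)

# side-chain atoms beyond CB: outward zig-zag in the local frame; the
# golden-angle lateral offsets keep any three atoms non-collinear
.place_sidechain <- function(res, n, ca, c) {
  atoms <- .SIDECHAIN[[res]]
  if (!length(atoms)) return(NULL)
  u1 <- .unit(n - ca)
  u2 <- .unit(c - ca)
  e1 <- .unit(-(u1 + u2))
  e3 <- .unit(.cross(u1, u2))
  e2 <- .cross(e3, e1)
  cb <- ca + 1.53 * .unit(e1 + 0.9 * e3)
  out <- matrix(0, length(atoms), 3L)
  out[1L, ] <- cb
  if (length(atoms) > 1L) {
    d1 <- .unit(cb - ca)
    g <- 2.399963
    for (j in 2L:length(atoms)) {
      out[j, ] <- cb + 0.8 * sqrt(j - 1) * d1 +
        0.8 * sin(g * (j - 1)) * e2 + 0.8 * cos(g * (j - 1)) * e3 +
        rnorm(3L, sd = 0.03)
    }
  }
  rownames(out) <- atoms
  out
}

.as_structure_rows <- function(res_idx, res_name, atom_names, xyz) {
  tibble::tibble(
    residue_index = res_idx, residue_name = res_name,
    atom_name = atom_names,
    type_id = atom_type(res_name, atom_names),
    x = .round3(xyz[, 1L]), y = .round3(xyz[, 2L]), z = .round3(xyz[, 3L]))
}

#' Generate a deterministic toy polypeptide structure
#'
#' Builds an idealised backbone (standard bond lengths and angles, trans
#' peptide bonds) with seeded random backbone torsions drawn from a broad
#' coil region, rejecting placements that bring a residue within
#' `min_clearance` of residues more than one position away (up to
#' `max_retries` redraws, then the best candidate is kept).  Side-chain
#' heavy atoms are placed as compact stubs in a local frame — chemically
#' idealised only in scale, but with every vector-pair triple
#' well-conditioned.  Coordinates are rounded to 0.001 A so the structure
#' round-trips exactly through [write_pdb()]/[read_pdb()].
#'
#' @param sequence Character vector of 3-letter residue codes, length >= 3.
#' @param seed Integer seed; the same spec and seed give a byte-identical
#'   structure.
#' @param min_clearance Minimum allowed distance (A) between atoms of
#'   residues at separation >= 2 (default 2.5).
#' @param max_retries Torsion redraws per residue (default 30).
#' @return A [typed_structure].
#' @export
generate_fixture <- function(sequence, seed = 1L, min_clearance = 2.5,
                             max_retries = 30L) {
  sequence <- .check_sequence(sequence)
  nres <- length(sequence)
  rows <- vector("list", nres)
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(old(), add = TRUE)
  # first residue backbone in the xy-plane
  n1 <- c(0, 0, 0)
  ca1 <- c(.BB$b_n_ca, 0, 0)
  c1 <- ca1 + .BB$b_ca_c * c(-cos(.BB$a_n_ca_c), sin(.BB$a_n_ca_c), 0)
  prev <- list(n = n1, ca = ca1, c = c1)
  placed <- list()
  res_done <- function(res, i, bb, psi) {
    o <- .place_atom(bb$n, bb$ca, bb$c, .BB$b_c_o, .BB$a_ca_c_o, psi + pi)
    sc <- .place_sidechain(res, bb$n, bb$ca, bb$c)
    xyz <- rbind(N = bb$n, CA = bb$ca, C = bb$c, O = o, sc)
    .as_structure_rows(i, res, rownames(xyz), xyz)
  }
  psi1 <- runif(1L, -pi / 3, 5 * pi / 6)
  rows[[1L]] <- res_done(sequence[1L], 1L, prev, psi1)
  psi_prev <- psi1
  n_clash <- 0L
  for (i in 2L:nres) {
    prior <- if (i > 2L) do.call(rbind, lapply(rows[seq_len(i - 2L)],
                                               function(r) cbind(r$x, r$y, r$z)))
             else NULL
    best <- NULL
    best_clear <- -Inf
    for (try in seq_len(max_retries)) {
      phi <- runif(1L, -5 * pi / 6, -pi / 3)
      psi <- runif(1L, -pi / 3, 5 * pi / 6)
      n_i <- .place_atom(prev$n, prev$ca, prev$c, .BB$b_c_n, .BB$a_ca_c_n,
                         psi_prev)
      ca_i <- .place_atom(prev$ca, prev$c, n_i, .BB$b_n_ca, .BB$a_c_n_ca, pi)
      c_i <- .place_atom(prev$c, n_i, ca_i, .BB$b_ca_c, .BB$a_n_ca_c, phi)
      cand <- res_done(sequence[i], i, list(n = n_i, ca = ca_i, c = c_i), psi)
      clear <- if (is.null(prior)) Inf else {
        cxyz <- cbind(cand$x, cand$y, cand$z)
        min(sqrt(pmax(0, outer(rowSums(cxyz^2), rowSums(prior^2), `+`) -
                        2 * cxyz %*% t(prior))))
      }
      if (clear > best_clear) {
        best_clear <- clear
        best <- list(rows = cand, bb = list(n = n_i, ca = ca_i, c = c_i),
                     psi = psi)
      }
      if (clear >= min_clearance) break
    }
    if (best_clear < min_clearance) n_clash <- n_clash + 1L
    rows[[i]] <- best$rows
    prev <- best$bb
    psi_prev <- best$psi
  }
  if (n_clash > 0L)
    inform(sprintf("fixture kept %d residue(s) below the clearance target",
                   n_clash))
  .new_typed_structure(dplyr::bind_rows(rows))
}

# save/restore the global RNG state around seeded generators
.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    saved <- get(".Random.seed", envir = globalenv())
    function() assign(".Random.seed", saved, envir = globalenv())
  } else {
    function() if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }
}

#' Perturb a structure with isotropic Gaussian coordinate noise
#'
#' Adds iid N(0, sigma^2) displacements to every coordinate (sigma in A)
#' and re-rounds to 0.001 A.  With `sigma = 0` the structure is returned
#' unchanged.
#'
#' @param structure A [typed_structure].
#' @param sigma Noise standard deviation per coordinate (A).
#' @param seed Integer seed.
#' @return A perturbed [typed_structure].
#' @export
perturb_structure <- function(structure, sigma, seed = 1L) {
  stopifnot(inherits(structure, "typed_structure"))
  if (sigma < 0) abort("`sigma` must be >= 0")
  if (sigma == 0) return(structure)
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(old(), add = TRUE)
  out <- structure
  n <- nrow(out)
  out$x <- .round3(out$x + rnorm(n, sd = sigma))
  out$y <- .round3(out$y + rnorm(n, sd = sigma))
  out$z <- .round3(out$z + rnorm(n, sd = sigma))
  out
}

#' Generate a random-walk chain training set
#'
#' Each structure is an ideal chain at residue resolution in the Gaussian
#' (random-walk) limit: successive nodes differ by iid isotropic Gaussian
#' steps of mean-square length `lam`, so the displacement over `n` links is
#' exactly N(0, n lam / 3) per axis and the inter-node distance follows the
#' Gaussian-chain radial density [fjc_density()] at every separation.  All
#' heavy atoms of residue i sit at node i plus small iid offsets
#' (`sigma_atom`, kept well below the bin width so the pair-distance law is
#' not smeared).  Training an unbiased set against the
#' multiplicity-weighted reference therefore yields energies that vanish
#' within counting noise.  An optional `pair_bias` injects a known signal:
#' in each structure up to `n_per_structure` qualifying atom pairs are
#' repositioned to a preferred distance.
#'
#' @param n_structures Number of chains.
#' @param length Residues per chain.
#' @param seed Integer seed.
#' @param params An [rw_params()] object; `lam` sets the mean-square step.
#' @param sigma_atom Within-residue atom scatter (A, default 0.05).
#' @param pair_bias Optional list with `res_a`, `atom_a`, `res_b`,
#'   `atom_b`, `distance` (A, must be < `R0`), and optionally `sd`
#'   (default 0.1) and `n_per_structure` (default 2).
#' @return List of [typed_structure] objects.
#' @export
make_training_set <- function(n_structures, length, seed = 1L,
                              params = rw_params(), sigma_atom = 0.05,
                              pair_bias = NULL) {
  .check_params(params)
  stopifnot(.is_count(n_structures), n_structures >= 1,
            .is_count(length), length >= 3)
  if (!is.null(pair_bias)) {
    req <- c("res_a", "atom_a", "res_b", "atom_b", "distance")
    if (!all(req %in% names(pair_bias)))
      abort("`pair_bias` needs res_a, atom_a, res_b, atom_b, distance")
    if (pair_bias$distance >= params$R0)
      abort("`pair_bias$distance` must be below the cutoff R0")
    pair_bias$sd <- pair_bias$sd %||% 0.1
    pair_bias$n_per_structure <- pair_bias$n_per_structure %||% 2L
  }
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(old(), add = TRUE)
  lapply(seq_len(n_structures), function(s) {
    sequence <- sample(.AA3, length, replace = TRUE)
    steps <- matrix(rnorm(3L * (length - 1L), sd = sqrt(params$lam / 3)),
                    ncol = 3L)
    nodes <- rbind(0, apply(steps, 2L, cumsum))
    rows <- dplyr::bind_rows(lapply(seq_len(length), function(i) {
      atoms <- .residue_heavy_atoms(sequence[i])
      xyz <- matrix(rep(nodes[i, ], each = base::length(atoms)), ncol = 3L) +
        matrix(rnorm(3L * base::length(atoms), sd = sigma_atom), ncol = 3L)
      .as_structure_rows(i, sequence[i], atoms, xyz)
    }))
    if (!is.null(pair_bias)) {
      ia <- which(rows$residue_name == toupper(pair_bias$res_a) &
                    rows$atom_name == toupper(pair_bias$atom_a))
      ib <- which(rows$residue_name == toupper(pair_bias$res_b) &
                    rows$atom_name == toupper(pair_bias$atom_b))
      cand <- expand.grid(a = ia, b = ib)
      cand <- cand[abs(rows$residue_index[cand$a] -
                         rows$residue_index[cand$b]) >= 2L, , drop = FALSE]
      if (nrow(cand)) {
        pick <- cand[sample.int(nrow(cand),
                                min(pair_bias$n_per_structure, nrow(cand))), ,
                     drop = FALSE]
        for (r in seq_len(nrow(pick))) {
          a <- pick$a[r]; b <- pick$b[r]
          dir <- .unit(rnorm(3L))
          d <- pair_bias$distance + rnorm(1L, sd = pair_bias$sd)
          new <- c(rows$x[a], rows$y[a], rows$z[a]) + d * dir
          rows$x[b] <- .round3(new[1L])
          rows$y[b] <- .round3(new[2L])
          rows$z[b] <- .round3(new[3L])
        }
      }
    }
    .new_typed_structure(rows)
  })
}

#' Generate a perturbation decoy set with its true quality table
#'
#' Decoys are Gaussian coordinate perturbations of the native at each
#' requested noise level, giving a controlled RMSD ladder; the true
#' Calpha RMSD of every decoy is returned alongside.
#'
#' @param native A [typed_structure].
#' @param sigmas Noise levels (A), one rung per value.
#' @param n_per_sigma Decoys per rung (0 gives an empty set).
#' @param seed Integer seed.
#' @return List with `decoys` (named list of [typed_structure]) and
#'   `truth` (tibble `name`, `sigma`, `rmsd`).
#' @export
make_decoy_set <- function(native, sigmas = c(0.5, 1, 2, 4),
                           n_per_sigma = 10L, seed = 1L) {
  stopifnot(inherits(native, "typed_structure"), .is_count(n_per_sigma))
  grid <- expand.grid(rep = seq_len(n_per_sigma), sigma = sigmas)
  if (!nrow(grid))
    return(list(decoys = list(),
                truth = tibble::tibble(name = character(), sigma = numeric(),
                                       rmsd = numeric())))
  nat_ca <- .ca_coords(native)
  decoys <- vector("list", nrow(grid))
  names(decoys) <- sprintf("decoy_s%04.1f_%02d", grid$sigma, grid$rep)
  for (i in seq_len(nrow(grid)))
    decoys[[i]] <- perturb_structure(native, grid$sigma[i], seed + i)
  truth <- tibble::tibble(
    name = names(decoys), sigma = grid$sigma,
    rmsd = vapply(decoys, function(d) kabsch_rmsd(nat_ca, .ca_coords(d)),
                  numeric(1L)))
  list(decoys = decoys, truth = truth)
}

#' Write a native-plus-decoys fixture set to a directory
#'
#' Emits `native.pdb`, `decoy_*.pdb` and a `truth.tsv` quality table —
#' the directory layout the command-line interface consumes.
#'
#' @param native A [typed_structure].
#' @param decoy_set A list from [make_decoy_set()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture_set <- function(native, decoy_set, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pdb(native, file.path(dir, "native.pdb"))
  for (nm in names(decoy_set$decoys))
    write_pdb(decoy_set$decoys[[nm]], file.path(dir, paste0(nm, ".pdb")))
  write.table(decoy_set$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Sample orientation-bin counts under the uniform reference
#'
#' Draws `n` independent vector-pair encounters with uniformly random
#' relative geometry — both frames uniformly rotated, the inter-origin
#' direction uniform on the sphere — and tallies their orientation bins.
#' Under this null the counts match the analytic reference probabilities,
#' so a potential built from them trains to zero within counting noise.
#'
#' @param n Number of samples.
#' @param seed Integer seed.
#' @return Integer vector of length 2704 (counts per flat orientation
#'   bin).
#' @export
sample_orientation_counts <- function(n, seed = 1L) {
  stopifnot(.is_count(n), n >= 1)
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(old(), add = TRUE)
  rand_axes <- function() {
    q <- matrix(rnorm(4L * n), ncol = 4L)
    q <- q / .row_norm(q)
    w <- q[, 1L]; x <- q[, 2L]; y <- q[, 3L]; z <- q[, 4L]
    list(
      x = cbind(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y)),
      y = cbind(2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x)),
      z = cbind(2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)))
  }
  fa <- rand_axes()
  fb <- rand_axes()
  d <- matrix(rnorm(3L * n), ncol = 3L)
  d <- d / .row_norm(d)
  r <- 1
  bin_of <- function(fr, dd) {
    lx <- rowSums(dd * fr$x)
    ly <- rowSums(dd * fr$y)
    lz <- rowSums(dd * fr$z)
    direction_bin(acos(pmax(-1, pmin(1, lz / r))), atan2(ly, lx) %% (2 * pi))
  }
  dir_ab <- bin_of(fa, d)
  dir_ba <- bin_of(fb, -d)
  # torsion A1-A0-B0-B1 with A0 at origin, B0 at 5 A along d:
  # A1 = A0 + fa$z, B1 = B0 + fb$z
  p1 <- fa$z
  p2 <- matrix(0, n, 3L)
  p3 <- 5 * d
  p4 <- p3 + fb$z
  om <- .dihedral(p1, p2, p3, p4) %% (2 * pi)
  torsion <- pmin(as.integer(floor(om / (pi / 2))) + 1L, 4L)
  tabulate(flat_orientation_index(dir_ab, dir_ba, torsion),
           nbins = N_ORIENTATION_BINS)
}
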