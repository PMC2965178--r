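#' Side-chain orientation-dependent packing potential
#'
#' Each residue contributes up to three "vector pairs": one side-chain
#' triple (every standard residue except GLY and ALA; 18 types) and two
#' backbone triples defined for all residues (2 types), 20 vector-pair
#' types in total.  A triple (X0, X1, X2) defines the two vectors X0->X1
#' and X0->X2 and an orthonormal frame.  The relative orientation of two
#' triples A and B is described by three variables — the direction of B0
#' seen from A's frame, the direction of A0 seen from B's frame, and the
#' torsion angle A1-A0-B0-B1 — discretised into 26 x 26 x 4 = 2704 bins.
#' The energy is the inverse-Boltzmann log-ratio of observed to expected
#' bin counts, where the expectation assumes independent uniformly random
#' orientations (analytic sphere-area fractions per direction bin, 1/4 per
#' torsion bin).
#'
#' @name orientation-potential
NULL

#' Number of orientation bins (26 x 26 x 4)
#' @export
N_ORIENTATION_BINS <- 26L * 26L * 4L

#' Vector-pair definitions
#'
#' The default table: one side-chain triple per residue type (except GLY
#' and ALA) using a distal branched triple, plus two backbone triples
#' defined for every residue.  The triple is ordered (X0, X1, X2); the
#' frame's z axis runs X0->X1 and its x axis is the component of X0->X2
#' orthogonal to z.
#'
#' @return A tibble with columns `vp_type` (1..20), `residue_scope`
#'   (residue name or `"backbone"`), `x0`, `x1`, `x2`.
#' @export
vector_pair_defs <- function() {
  tibble::tribble(
    ~residue_scope, ~x0, ~x1, ~x2,
    "ARG", "NE",  "NH1", "NH2",
    "ASN", "CG",  "OD1", "ND2",
    "ASP", "CG",  "OD1", "OD2",
    "CYS", "CB",  "SG",  "CA",
    "GLN", "CD",  "OE1", "NE2",
    "GLU", "CD",  "OE1", "OE2",
    "HIS", "CG",  "ND1", "CD2",
    "ILE", "CB",  "CG1", "CG2",
    "LEU", "CB",  "CD1", "CD2",
    "LYS", "CE",  "NZ",  "CD",
    "MET", "SD",  "CG",  "CE",
    "PHE", "CG",  "CD1", "CD2",
    "PRO", "CG",  "CB",  "CD",
    "SER", "CB",  "OG",  "CA",
    "THR", "CB",  "OG1", "CG2",
    "TRP", "CD2", "CZ2", "CE3",
    "TYR", "CG",  "CD1", "CD2",
    "VAL", "CB",  "CG1", "CG2",
    "backbone", "CA", "N", "C",
    "backbone", "CA", "C", "O"
  ) |>
    dplyr::mutate(vp_type = dplyr::row_number(), .before = 1L)
}

#' Number of vector-pair types
#' @param defs A definitions table from [vector_pair_defs()].
#' @return Integer scalar (20 for the default table).
#' @export
n_vector_pair_types <- function(defs = vector_pair_defs()) {
  max(defs$vp_type)
}

#' Read or write a vector-pair definitions table
#'
#' The definitions are an editable convention, so they can be persisted as
#' tab-separated text (`vp_type`, `residue_scope`, `x0`, `x1`, `x2`) and
#' swapped for a custom set in [train_orientation()] and
#' [score_orientation()] — as long as training and scoring share one table.
#'
#' @param defs A definitions table (as from [vector_pair_defs()]).
#' @param path File path.
#' @return `write_vector_pair_defs()` returns `path` invisibly;
#'   `read_vector_pair_defs()` returns the definitions tibble.
#' @export
write_vector_pair_defs <- function(defs, path) {
  write.table(defs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vector_pair_defs
#' @export
read_vector_pair_defs <- function(path) {
  defs <- tibble::as_tibble(read.table(path, header = TRUE, sep = "\t",
                                       stringsAsFactors = FALSE))
  need <- c("vp_type", "residue_scope", "x0", "x1", "x2")
  if (!all(need %in% names(defs)))
    abort("definitions table needs columns vp_type, residue_scope, x0, x1, x2")
  defs
}

#' Orthonormal frame of an atom triple
#'
#' Right-handed frame of the triple (X0, X1, X2): z along X0->X1, x the
#' Gram-Schmidt component of X0->X2 orthogonal to z, y = z cross x.
#'
#' @param p0,p1,p2 Numeric length-3 positions (A).
#' @return A 3x3 matrix whose columns are the x, y, z axes.
#' @export
build_frame <- function(p0, p1, p2) {
  z <- .unit(p1 - p0)
  v <- (p2 - p0) - sum((p2 - p0) * z) * z
  if (sqrt(sum(v^2)) < 1e-8) abort("collinear atom triple: frame undefined")
  x <- v / sqrt(sum(v^2))
  m <- cbind(x, .cross(z, x), z)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Direction bin on the unit sphere
#'
#' Partitions the sphere into 26 bins: two polar caps (theta below pi/6 and
#' above 5 pi/6, all phi) and three latitude bands (pi/6..pi/3,
#' pi/3..2 pi/3, 2 pi/3..5 pi/6), each cut into 8 azimuth sectors of width
#' pi/4 whose first sector opens at phi = pi/8 (the eighth sector wraps
#' through 2 pi).  Sectors are half-open at their opening edge.
#'
#' @param theta Polar angle(s) in radians, in `[0, pi]`.
#' @param phi Azimuth angle(s) in radians, in `[0, 2*pi)`.
#' @return Integer bin ids in 1..26 (1 = north cap, 2 = south cap,
#'   3..10 / 11..18 / 19..26 the three bands).
#' @export
direction_bin <- function(theta, phi) {
  if (any(theta < 0 | theta > pi + 1e-12)) abort("`theta` must be in [0, pi]")
  if (any(phi < 0 | phi >= 2 * pi)) abort("`phi` must be in [0, 2*pi)")
  band <- findInterval(theta, c(pi / 6, pi / 3, 2 * pi / 3, 5 * pi / 6))
  sector <- (floor(((phi - pi / 8) %% (2 * pi)) / (pi / 4)) %% 8L) + 1L
  out <- integer(length(theta))
  out[band == 0L] <- 1L
  out[band == 4L] <- 2L
  mid <- band >= 1L & band <= 3L
  out[mid] <- 2L + (band[mid] - 1L) * 8L + sector[mid]
  out
}

#' Reference probability of each direction bin
#'
#' The sphere-area fraction of each of the 26 direction bins under a
#' uniform direction distribution: caps get `(1 - cos(pi/6)) / 2`, each
#' sector of the two mid-latitude bands `(cos(pi/6) - cos(pi/3)) / 16`, and
#' each equatorial sector `1/16`.  The 26 values sum to 1.
#'
#' @param bin Optional integer bin ids; default returns all 26.
#' @return Numeric probabilities.
#' @export
direction_ref_prob <- function(bin = seq_len(26L)) {
  cap <- (1 - cos(pi / 6)) / 2
  band1 <- (cos(pi / 6) - cos(pi / 3)) / 16
  band2 <- (cos(pi / 3) - cos(2 * pi / 3)) / 16
  p <- c(cap, cap, rep(band1, 8L), rep(band2, 8L), rep(band1, 8L))
  p[bin]
}

#' Flat index of an orientation bin
#'
#' Packs (direction A->B, direction B->A, torsion) into one index in
#' 1..2704 as `(dir_ab - 1) * 104 + (dir_ba - 1) * 4 + torsion`.
#'
#' @param dir_ab,dir_ba Direction bins in 1..26.
#' @param torsion Torsion bin in 1..4.
#' @return Integer flat index in 1..2704.
#' @export
flat_orientation_index <- function(dir_ab, dir_ba, torsion) {
  (dir_ab - 1L) * 104L + (dir_ba - 1L) * 4L + torsion
}

#' @rdname flat_orientation_index
#' @param flat Flat index in 1..2704.
#' @return For `unpack_orientation_index`: a list with `dir_ab`, `dir_ba`,
#'   `torsion`.
#' @export
unpack_orientation_index <- function(flat) {
  f0 <- flat - 1L
  list(dir_ab = f0 %/% 104L + 1L,
       dir_ba = (f0 %% 104L) %/% 4L + 1L,
       torsion = f0 %% 4L + 1L)
}

#' Reference probability over the full orientation space
#'
#' Product of the two direction-bin sphere fractions and the uniform 1/4
#' torsion probability; sums to 1 over the 2704 bins.
#'
#' @return Numeric vector of length 2704 indexed by
#'   [flat_orientation_index()].
#' @export
orientation_ref_prob <- function() {
  u <- unpack_orientation_index(seq_len(N_ORIENTATION_BINS))
  direction_ref_prob(u$dir_ab) * direction_ref_prob(u$dir_ba) * 0.25
}

# signed dihedral p1-p2-p3-p4 (IUPAC), vectorised over n x 3 matrices
.dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- .cross_m(b1, b2)
  n2 <- .cross_m(b2, b3)
  b2u <- b2 / .row_norm(b2)
  m1 <- .cross_m(n1, b2u)
  atan2(rowSums(m1 * n2), rowSums(n1 * n2))
}

#' Relative orientation of two vector-pair instances
#'
#' @param A,B 3x3 matrices whose rows are the positions of X0, X1, X2 of
#'   each triple.
#' @return A list with `dir_ab`, `dir_ba`, `torsion` (bins) and `flat`
#'   (1..2704).
#' @export
relative_orientation <- function(A, B) {
  d <- B[1L, ] - A[1L, ]
  r <- sqrt(sum(d^2))
  if (r < 1e-6) abort("coincident vector-pair origins")
  fa <- build_frame(A[1L, ], A[2L, ], A[3L, ])
  fb <- build_frame(B[1L, ], B[2L, ], B[3L, ])
  la <- as.numeric(crossprod(fa, d))
  lb <- as.numeric(crossprod(fb, -d))
  dir_ab <- direction_bin(acos(max(-1, min(1, la[3L] / r))),
                          atan2(la[2L], la[1L]) %% (2 * pi))
  dir_ba <- direction_bin(acos(max(-1, min(1, lb[3L] / r))),
                          atan2(lb[2L], lb[1L]) %% (2 * pi))
  om <- .dihedral(matrix(A[2L, ], 1L), matrix(A[1L, ], 1L),
                  matrix(B[1L, ], 1L), matrix(B[2L, ], 1L)) %% (2 * pi)
  torsion <- pmin(as.integer(floor(om / (pi / 2))) + 1L, 4L)
  list(dir_ab = dir_ab, dir_ba = dir_ba, torsion = torsion,
       flat = flat_orientation_index(dir_ab, dir_ba, torsion))
}

#' Are two residues in contact?
#'
#' Contact means at least one heavy-atom pair across the two residues is
#' strictly closer than the cutoff (default 10 A).
#'
#' @param xyz_a,xyz_b Coordinate matrices (n x 3) of the two residues'
#'   heavy atoms.
#' @param cutoff Contact cutoff in A.
#' @return Logical scalar.
#' @export
in_contact <- function(xyz_a, xyz_b, cutoff = 10) {
  dx <- outer(xyz_a[, 1L], xyz_b[, 1L], `-`)
  dy <- outer(xyz_a[, 2L], xyz_b[, 2L], `-`)
  dz <- outer(xyz_a[, 3L], xyz_b[, 3L], `-`)
  min(dx^2 + dy^2 + dz^2) < cutoff^2
}

# all vector-pair instances of a structure with precomputed frames;
# instances with missing atoms or degenerate geometry are skipped
.vp_instances <- function(structure, defs = vector_pair_defs()) {
  key <- paste(structure$residue_index, structure$atom_name, sep = "|")
  pos <- function(res, atom) {
    i <- match(paste(res, atom, sep = "|"), key)
    cbind(structure$x[i], structure$y[i], structure$z[i])
  }
  res_names <- structure$residue_name[!duplicated(structure$residue_index)]
  res_ids <- structure$residue_index[!duplicated(structure$residue_index)]
  rows <- purrr::map_dfr(seq_len(nrow(defs)), function(d) {
    scope <- defs$residue_scope[d]
    res <- if (scope == "backbone") res_ids else res_ids[res_names == scope]
    if (!length(res)) return(NULL)
    tibble::tibble(res = res, vp = defs$vp_type[d],
                   x0 = defs$x0[d], x1 = defs$x1[d], x2 = defs$x2[d])
  })
  if (!nrow(rows)) return(NULL)
  p0 <- pos(rows$res, rows$x0)
  p1 <- pos(rows$res, rows$x1)
  p2 <- pos(rows$res, rows$x2)
  ok <- !is.na(p0[, 1L]) & !is.na(p1[, 1L]) & !is.na(p2[, 1L])
  z <- p1 - p0
  zn <- .row_norm(z)
  ok <- ok & !is.na(zn) & zn > 1e-8
  z <- z / ifelse(zn > 0, zn, 1)
  v <- p2 - p0
  v <- v - z * rowSums(v * z)
  vn <- .row_norm(v)
  ok <- ok & !is.na(vn) & vn > 1e-8
  n_skip <- sum(!ok)
  if (n_skip)
    inform(sprintf("skipped %d vector-pair instance(s) with missing or degenerate atoms",
                   n_skip))
  if (!any(ok)) return(NULL)
  x <- (v / ifelse(vn > 0, vn, 1))[ok, , drop = FALSE]
  z <- z[ok, , drop = FALSE]
  list(res = rows$res[ok], vp = rows$vp[ok],
       p0 = p0[ok, , drop = FALSE], p1 = p1[ok, , drop = FALSE],
       fx = x, fy = .cross_m(z, x), fz = z)
}

# residue-level contact matrix (strictly < cutoff), n_res x n_res
.residue_contacts <- function(structure, cutoff) {
  xyz <- .coords(structure)
  dm <- as.matrix(stats::dist(xyz)) < cutoff
  grp <- factor(structure$residue_index,
                levels = seq_len(n_residues(structure)))
  m1 <- rowsum(dm + 0, grp)
  m2 <- t(rowsum(t(m1), grp))
  m2 > 0
}

# observed orientation events: tibble(vpa, vpb, flat_ab, flat_ba) over
# unordered instance pairs of contacting residues i < j with j - i >= min_sep
.orientation_events <- function(structure, defs, cutoff, min_separation) {
  inst <- .vp_instances(structure, defs)
  if (is.null(inst)) return(NULL)
  contacts <- .residue_contacts(structure, cutoff)
  nres <- n_residues(structure)
  cand <- which(upper.tri(contacts) & contacts &
                  abs(row(contacts) - col(contacts)) >= min_separation,
                arr.ind = TRUE)
  if (!nrow(cand)) return(NULL)
  by_res <- split(seq_along(inst$res), inst$res)
  ri <- as.character(cand[, 1L])
  rj <- as.character(cand[, 2L])
  ia <- by_res[ri]
  ib <- by_res[rj]
  na <- lengths(ia)
  nb <- lengths(ib)
  keep <- na > 0L & nb > 0L
  if (!any(keep)) return(NULL)
  a_idx <- unlist(purrr::map2(ia[keep], nb[keep], function(a, k) rep(a, times = k)),
                  use.names = FALSE)
  b_idx <- unlist(purrr::map2(ib[keep], na[keep], function(b, k) rep(b, each = k)),
                  use.names = FALSE)
  d <- inst$p0[b_idx, , drop = FALSE] - inst$p0[a_idx, , drop = FALSE]
  r <- .row_norm(d)
  good <- r > 1e-6
  a_idx <- a_idx[good]; b_idx <- b_idx[good]
  d <- d[good, , drop = FALSE]; r <- r[good]
  if (!length(r)) return(NULL)
  loc <- function(ii, dd) {
    lx <- rowSums(dd * inst$fx[ii, , drop = FALSE])
    ly <- rowSums(dd * inst$fy[ii, , drop = FALSE])
    lz <- rowSums(dd * inst$fz[ii, , drop = FALSE])
    direction_bin(acos(pmax(-1, pmin(1, lz / r))),
                  atan2(ly, lx) %% (2 * pi))
  }
  dir_ab <- loc(a_idx, d)
  dir_ba <- loc(b_idx, -d)
  om <- .dihedral(inst$p1[a_idx, , drop = FALSE], inst$p0[a_idx, , drop = FALSE],
                  inst$p0[b_idx, , drop = FALSE], inst$p1[b_idx, , drop = FALSE]) %% (2 * pi)
  torsion <- pmin(as.integer(floor(om / (pi / 2))) + 1L, 4L)
  # under A<->B swap the direction bins exchange while the torsion is
  # unchanged (a signed dihedral is invariant under atom-order reversal)
  tibble::tibble(vpa = inst$vp[a_idx], vpb = inst$vp[b_idx],
                 flat_ab = flat_orientation_index(dir_ab, dir_ba, torsion),
                 flat_ba = flat_orientation_index(dir_ba, dir_ab, torsion))
}

# energy array from an observed-count array (nv x nv x 2704)
.orientation_energy <- function(obs, cap) {
  nv <- dim(obs)[1L]
  flat <- obs
  dim(flat) <- c(nv * nv, N_ORIENTATION_BINS)
  tot <- rowSums(flat)
  expd <- tot %o% orientation_ref_prob()
  en <- -log(flat / expd)
  en[flat == 0] <- cap
  en <- pmin(en, cap)
  en[tot == 0, ] <- 0
  dim(en) <- dim(obs)
  en
}

#' Train the orientation-dependent potential
#'
#' Counts the relative-orientation bins of all vector-pair instances on
#' contacting, non-consecutive residue pairs across the training set, and
#' converts them to energies against the analytic uniform-orientation
#' reference: `N_exp(A, B, O) = N_total(A, B) * p_ref(O)`.
#'
#' @param structures List of [typed_structure] objects (or one).
#' @param defs Vector-pair definitions ([vector_pair_defs()]).
#' @param contact_cutoff Heavy-atom contact cutoff in A (default 10).
#' @param min_separation Minimum residue separation (default 2).
#' @param cap Energy cap in kT for unobserved bins (default 10).
#' @return An `orientation_potential`: list with `energy`
#'   (`20 x 20 x 2704`, kT), `ref_prob`, `contact_cutoff`,
#'   `min_separation`, `cap`, `n_structures`, `typing_hash`.
#' @export
train_orientation <- function(structures, defs = vector_pair_defs(),
                              contact_cutoff = 10, min_separation = 2L,
                              cap = 10) {
  if (inherits(structures, "typed_structure")) structures <- list(structures)
  if (!length(structures)) abort("empty training set")
  nv <- n_vector_pair_types(defs)
  obs <- array(0, dim = c(nv, nv, N_ORIENTATION_BINS))
  for (s in structures) {
    ev <- .orientation_events(s, defs, contact_cutoff, min_separation)
    if (is.null(ev)) next
    i1 <- ev$vpa + (ev$vpb - 1L) * nv + (ev$flat_ab - 1L) * nv * nv
    i2 <- ev$vpb + (ev$vpa - 1L) * nv + (ev$flat_ba - 1L) * nv * nv
    add <- tabulate(c(i1, i2), nbins = nv * nv * N_ORIENTATION_BINS)
    obs <- obs + array(add, dim = dim(obs))
  }
  orientation_potential_from_counts(obs, contact_cutoff = contact_cutoff,
                                    min_separation = min_separation,
                                    cap = cap, n_structures = length(structures))
}

#' Build an orientation potential from a pre-accumulated count array
#'
#' @param counts Array `n_vp x n_vp x 2704` of observed orientation counts.
#' @inheritParams train_orientation
#' @param n_structures Number of structures the counts came from (metadata).
#' @return An `orientation_potential`.
#' @export
orientation_potential_from_counts <- function(counts, contact_cutoff = 10,
                                              min_separation = 2L, cap = 10,
                                              n_structures = NA_integer_) {
  structure(list(energy = .orientation_energy(counts, cap),
                 ref_prob = orientation_ref_prob(),
                 contact_cutoff = contact_cutoff,
                 min_separation = as.integer(min_separation), cap = cap,
                 n_structures = n_structures, typing_hash = typing_hash()),
            class = "orientation_potential")
}

#' Score a structure with a trained orientation potential
#'
#' Sums the orientation energies over all unordered vector-pair instance
#' pairs of contacting residues at separation >= `min_separation`.
#' Residues lacking the atoms of a vector-pair definition are skipped.
#'
#' @param structure A [typed_structure].
#' @param potential An `orientation_potential`.
#' @param defs Vector-pair definitions (must match training).
#' @return Energy in kT (numeric scalar).
#' @export
score_orientation <- function(structure, potential,
                              defs = vector_pair_defs()) {
  stopifnot(inherits(potential, "orientation_potential"))
  if (!identical(potential$typing_hash, typing_hash()))
    abort("potential was trained under a different atom-typing scheme")
  ev <- .orientation_events(structure, defs, potential$contact_cutoff,
                            potential$min_separation)
  if (is.null(ev)) return(0)
  sum(potential$energy[cbind(ev$vpa, ev$vpb, ev$flat_ab)])
}

#' @export
print.orientation_potential <- function(x, ...) {
  cat(sprintf(
    "<orientation_potential> %d vector-pair types, %d orientation bins, %d training structure(s)\n",
    dim(x$energy)[1L], dim(x$energy)[3L], x$n_structures))
  invisible(x)
}

#' @rdname tidy.distance_potential
#' @export
glance.orientation_potential <- function(x, ...) {
  nv <- dim(x$energy)[1L]
  flat <- x$energy
  dim(flat) <- c(nv * nv, N_ORIENTATION_BINS)
  tibble::tibble(n_vp_types = nv, n_bins = N_ORIENTATION_BINS,
                 contact_cutoff = x$contact_cutoff,
                 min_separation = x$min_separation, cap = x$cap,
                 n_structures = x$n_structures,
                 frac_pairs_observed = mean(rowSums(flat != 0) > 0))
}
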