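#' Distance-dependent statistical potential with a random-walk reference
#'
#' The potential is the inverse-Boltzmann log-ratio of observed to expected
#' atom-pair counts per distance bin,
#' \deqn{E(\alpha, \beta, R) = -kT \,\ln
#'   \frac{N_{obs}(\alpha, \beta, R)\, /\, N_{obs}(\alpha, \beta, R_0)}
#'        {P_{RW}(R)\, /\, P_{RW}(R_0)},}
#' with the expected shape taken from the freely-jointed-chain reference
#' ([rw_probability()]), anchored so that the energy vanishes in the bin
#' containing the cutoff `R0`.  Energies are in kT units (kT = 1).
#'
#' @name distance-potential
NULL

# atom pairs of a structure inside the cutoff: list(ti, tj, bin, n = n atoms)
.atom_pairs <- function(structure, params, min_separation) {
  xyz <- .coords(structure)
  n <- nrow(xyz)
  if (n < 2L) return(list(ti = integer(), tj = integer(), bin = integer()))
  dm <- as.matrix(stats::dist(xyz))
  sep <- abs(outer(structure$residue_index, structure$residue_index, `-`))
  sel <- upper.tri(dm) & dm < params$R0 & sep >= min_separation
  idx <- which(sel, arr.ind = TRUE)
  list(ti = structure$type_id[idx[, 1L]],
       tj = structure$type_id[idx[, 2L]],
       bin = pmin(as.integer(floor(dm[sel] / params$dR)) + 1L, params$n_bins))
}

# symmetric count array [T, T, n_bins] from pair lists
.count_array <- function(ti, tj, bin, n_types, n_bins) {
  i1 <- ti + (tj - 1L) * n_types + (bin - 1L) * n_types * n_types
  i2 <- tj + (ti - 1L) * n_types + (bin - 1L) * n_types * n_types
  flat <- tabulate(c(i1, i2[ti != tj]), nbins = n_types * n_types * n_bins)
  array(as.numeric(flat), dim = c(n_types, n_types, n_bins))
}

#' Count typed atom pairs of one structure per distance bin
#'
#' Every unordered heavy-atom pair whose residues are at least
#' `min_separation` apart along the chain and whose distance is below the
#' cutoff `R0` contributes one count to its (type, type, bin) cell; the
#' mirrored cell is kept in step so the table is symmetric.  Intra-residue
#' pairs are never counted.
#'
#' @param structure A [typed_structure].
#' @param params An [rw_params()] object.
#' @param min_separation Minimum residue separation |i - j| (default 2:
#'   intra-residue and consecutive-residue pairs excluded).
#' @return A `pair_count_table`: list with `counts` (symmetric
#'   `158 x 158 x n_bins` array), `n_structures`, `n_res`, `params`,
#'   `min_separation`.
#' @export
count_pairs <- function(structure, params = rw_params(), min_separation = 2L) {
  .check_params(params)
  stopifnot(inherits(structure, "typed_structure"))
  if (!nrow(structure)) abort("empty structure")
  nt <- n_atom_types()
  p <- .atom_pairs(structure, params, min_separation)
  structure(list(counts = .count_array(p$ti, p$tj, p$bin, nt, params$n_bins),
                 n_structures = 1L, n_res = n_residues(structure),
                 params = params, min_separation = as.integer(min_separation)),
            class = "pair_count_table")
}

#' Total number of unordered pair observations in a count table
#' @param x A `pair_count_table`.
#' @return Numeric scalar.
#' @export
total_pair_count <- function(x) {
  stopifnot(inherits(x, "pair_count_table"))
  nt <- dim(x$counts)[1L]
  nb <- dim(x$counts)[3L]
  dg <- sum(x$counts[cbind(rep(seq_len(nt), nb), rep(seq_len(nt), nb),
                           rep(seq_len(nb), each = nt))])
  (sum(x$counts) + dg) / 2
}

#' @export
print.pair_count_table <- function(x, ...) {
  cat(sprintf("<pair_count_table> %d structure(s), %g pair observations, %d bins\n",
              x$n_structures, total_pair_count(x), x$params$n_bins))
  invisible(x)
}

# number of trailing bins pooled when the top bin is empty (outer 2 A)
.anchor_bins <- function(params) max(1L, min(params$n_bins,
                                             as.integer(ceiling(2 / params$dR))))

#' Train the random-walk distance potential
#'
#' Aggregates observed pair counts over a training set and converts them to
#' energies against the random-walk reference.  Expected counts are built
#' per structure — each structure's total observed count for a type pair is
#' redistributed over bins by that structure's own reference shape
#' ([shell_weights()] at its chain length) — and then aggregated, so chains
#' of different lengths are handled exactly.
#'
#' Per type pair, energies are anchored at the bin containing `R0` (energy
#' zero there whenever that bin has counts); if the top bin is empty the
#' anchor falls back to the outer 2 A, then to the whole range.  Bins with
#' zero observed counts for an otherwise-observed pair get the cap energy;
#' pairs never observed anywhere are uninformative and get a flat zero row.
#'
#' @param structures List of [typed_structure] objects (or a single one).
#' @param params An [rw_params()] object.
#' @param min_separation Minimum residue separation (default 2).
#' @param cap Energy (kT) assigned to unobserved bins and used as an upper
#'   bound everywhere (default 10).
#' @param weighting,n_min Aggregation shape of the reference over sequence
#'   separations, passed to [shell_weights()].  Defaults: uniform over
#'   `n = 1..N-1`.
#' @return A `distance_potential`: list with `energy`
#'   (`158 x 158 x n_bins`, kT), `params`, `cap`, `min_separation`,
#'   `weighting`, `n_min`, `n_structures`, `typing_hash`.
#' @export
train_rw <- function(structures, params = rw_params(), min_separation = 2L,
                     cap = 10, weighting = c("uniform", "multiplicity"),
                     n_min = 1L) {
  .check_params(params)
  weighting <- match.arg(weighting)
  if (inherits(structures, "typed_structure")) structures <- list(structures)
  if (!length(structures)) abort("empty training set")
  nt <- n_atom_types()
  nb <- params$n_bins
  obs <- matrix(0, nt * nt, nb)
  expd <- matrix(0, nt * nt, nb)
  weight_cache <- list()
  for (s in structures) {
    p <- .atom_pairs(s, params, min_separation)
    if (!length(p$ti)) next
    cnt <- .count_array(p$ti, p$tj, p$bin, nt, nb)
    dim(cnt) <- c(nt * nt, nb)
    obs <- obs + cnt
    key <- as.character(n_residues(s))
    if (is.null(weight_cache[[key]]))
      weight_cache[[key]] <- shell_weights(n_residues(s), params, n_min, weighting)
    expd <- expd + rowSums(cnt) %o% weight_cache[[key]]
  }
  en <- .energy_from_counts(obs, expd, nb, cap, .anchor_bins(params))
  dim(en$energy) <- c(nt, nt, nb)
  if (en$n_fallback > 0L)
    inform(sprintf("anchor fallback to outer %g A used for %d type pair(s)",
                   .anchor_bins(params) * params$dR, en$n_fallback))
  structure(list(energy = en$energy, params = params, cap = cap,
                 min_separation = as.integer(min_separation),
                 weighting = weighting, n_min = as.integer(n_min),
                 n_structures = length(structures),
                 typing_hash = typing_hash()),
            class = "distance_potential")
}

# energies from flattened observed/expected count matrices (rows = pairs)
.energy_from_counts <- function(obs, expd, nb, cap, n_anchor) {
  tot <- rowSums(obs)
  oK <- obs[, nb]
  eK <- expd[, nb]
  oA <- rowSums(obs[, (nb - n_anchor + 1L):nb, drop = FALSE])
  eA <- rowSums(expd[, (nb - n_anchor + 1L):nb, drop = FALSE])
  anum <- ifelse(oK > 0, oK, ifelse(oA > 0, oA, tot))
  aden <- ifelse(oK > 0, eK, ifelse(oA > 0, eA, rowSums(expd)))
  r_anchor <- ifelse(tot > 0, anum / aden, 1)
  ratio <- obs / expd
  en <- -log(ratio / r_anchor)
  en[obs == 0] <- cap
  en <- pmin(en, cap)
  en[tot == 0, ] <- 0
  list(energy = en, n_fallback = sum(tot > 0 & oK == 0))
}

#' Score a structure with a trained distance potential
#'
#' Sums the per-bin energies over all unordered heavy-atom pairs at residue
#' separation >= `min_separation` and distance < `R0`.  Invariant under
#' rigid-body motion of the structure.
#'
#' @param structure A [typed_structure].
#' @param potential A `distance_potential` from [train_rw()] or
#'   [load_potential_table()].
#' @param min_separation Residue-separation filter; defaults to the value
#'   the potential was trained with.
#' @return Energy in kT (numeric scalar).
#' @export
score_rw <- function(structure, potential,
                     min_separation = potential$min_separation) {
  stopifnot(inherits(potential, "distance_potential"))
  if (!identical(potential$typing_hash, typing_hash()))
    abort("potential was trained under a different atom-typing scheme")
  p <- .atom_pairs(structure, potential$params, min_separation)
  if (!length(p$ti)) return(0)
  sum(potential$energy[cbind(p$ti, p$tj, p$bin)])
}

#' @export
print.distance_potential <- function(x, ...) {
  cat(sprintf(
    "<distance_potential> %d x %d types, %d bins (R0 = %g A), %d training structure(s)\n",
    dim(x$energy)[1L], dim(x$energy)[2L], x$params$n_bins, x$params$R0,
    x$n_structures))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a distance potential into a long tibble
#'
#' @param x A `distance_potential`.
#' @param informative_only Keep only type pairs with a non-flat energy row
#'   (default `TRUE`).
#' @param ... Unused.
#' @return Tibble with `type_a`, `type_b`, `bin`, `r_mid` (A), `energy`
#'   (kT).
#' @export
tidy.distance_potential <- function(x, informative_only = TRUE, ...) {
  nt <- dim(x$energy)[1L]
  nb <- dim(x$energy)[3L]
  flat <- x$energy
  dim(flat) <- c(nt * nt, nb)
  keep <- if (informative_only) rowSums(flat != 0) > 0 else rep(TRUE, nt * nt)
  ab <- which(keep)
  a <- ((ab - 1L) %% nt) + 1L
  b <- ((ab - 1L) %/% nt) + 1L
  tibble::tibble(
    type_a = rep(a, each = nb),
    type_b = rep(b, each = nb),
    bin = rep(seq_len(nb), length(ab)),
    r_mid = (rep(seq_len(nb), length(ab)) - 0.5) * x$params$dR,
    energy = as.numeric(t(flat[ab, , drop = FALSE])))
}

#' @rdname tidy.distance_potential
#' @export
glance.distance_potential <- function(x, ...) {
  nt <- dim(x$energy)[1L]
  flat <- x$energy
  dim(flat) <- c(nt * nt, dim(x$energy)[3L])
  tibble::tibble(
    n_types = nt, n_bins = x$params$n_bins,
    lam = x$params$lam, R0 = x$params$R0, dR = x$params$dR,
    cap = x$cap, min_separation = x$min_separation,
    n_structures = x$n_structures,
    frac_pairs_observed = mean(rowSums(flat != 0) > 0))
}

#' Plot energy profiles of selected type pairs
#'
#' @param object A `distance_potential`.
#' @param pairs Data frame with columns `res_a`, `atom_a`, `res_b`,
#'   `atom_b` naming the type pairs to draw.
#' @param ... Unused.
#' @return A ggplot object: energy (kT) versus distance (A), one line per
#'   pair.
#' @export
autoplot.distance_potential <- function(object, pairs, ...) {
  ta <- atom_type(pairs$res_a, pairs$atom_a)
  tb <- atom_type(pairs$res_b, pairs$atom_b)
  lab <- sprintf("%s %s - %s %s", pairs$res_a, pairs$atom_a,
                 pairs$res_b, pairs$atom_b)
  nb <- object$params$n_bins
  df <- purrr::map_dfr(seq_along(ta), function(i) tibble::tibble(
    pair = lab[i], r_mid = (seq_len(nb) - 0.5) * object$params$dR,
    energy = object$energy[ta[i], tb[i], ]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r_mid, y = .data$energy,
                                   colour = .data$pair)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance (Å)", y = "energy (kT)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
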