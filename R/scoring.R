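#' Hybrid RWplus scoring and decoy-set evaluation
#'
#' The hybrid score adds the orientation term to the distance term with a
#' fixed weight,
#' \deqn{E_{RWplus} = E_{RW} + w_{orient} \, E_{orient},}
#' with `w_orient = 0.1` by default.  Decoy-set evaluation ranks a native
#' structure against computer-generated decoys, reports the native Z-score
#' `(E_native - mean E) / sd E` over the pooled conformations, the best
#' model quality among the top-1/5/10 lowest-energy decoys, and the Pearson
#' correlations of energy with RMSD and TM-score over the decoys.
#'
#' @name scoring-eval
NULL

#' Score a structure with the hybrid RWplus potential
#'
#' @param structure A [typed_structure].
#' @param dist_pot A `distance_potential` from [train_rw()].
#' @param orient_pot An `orientation_potential` from [train_orientation()],
#'   or `NULL` to score with the distance term only.
#' @param w_orient Weight of the orientation term (default 0.1).
#' @param defs Vector-pair definitions used for the orientation term.
#' @return A one-row tibble with `e_rw`, `e_orient`, `e_rwplus` (kT).
#' @export
score_rwplus <- function(structure, dist_pot, orient_pot = NULL,
                         w_orient = 0.1, defs = vector_pair_defs()) {
  e_rw <- score_rw(structure, dist_pot)
  e_or <- if (is.null(orient_pot)) 0
          else score_orientation(structure, orient_pot, defs)
  tibble::tibble(e_rw = e_rw, e_orient = e_or,
                 e_rwplus = e_rw + w_orient * e_or)
}

#' Optimal-superposition RMSD (Kabsch algorithm)
#'
#' Root-mean-square deviation of two equal-length coordinate sets after
#' optimal rigid-body superposition.  The rotation is restricted to proper
#' rotations (determinant +1), so mirror images are not superposed onto
#' each other.
#'
#' @param P,Q Numeric `n x 3` coordinate matrices, `n >= 3`, with matching
#'   row order.
#' @return RMSD in A (numeric scalar).
#' @export
kabsch_rmsd <- function(P, Q) {
  P <- as.matrix(P)
  Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q))) abort("coordinate sets differ in size")
  if (nrow(P) < 3L) abort("need at least 3 points")
  Pc <- sweep(P, 2L, colMeans(P))
  Qc <- sweep(Q, 2L, colMeans(Q))
  s <- svd(crossprod(Pc, Qc))
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((Qc - Pc %*% t(rot))^2)))
}

# Calpha coordinates of a typed structure, ordered by residue
.ca_coords <- function(x) {
  ca <- x[x$atom_name == "CA", , drop = FALSE]
  ca <- ca[order(ca$residue_index), , drop = FALSE]
  .coords(ca)
}

#' TM-score of a model against a reference (fixed correspondence)
#'
#' Length-normalised structural similarity over Calpha pairs,
#' `mean(1 / (1 + (d_i/d0)^2))` with `d0 = 1.24 (L - 15)^{1/3} - 1.8`,
#' maximised over superpositions seeded from contiguous fragments and
#' refined by iterating the superposition on the well-fitting subset.
#' This is a simplified re-implementation kept for convenience; for
#' published comparisons use the canonical external program and pass its
#' values through the `quality` table of [evaluate_decoy_set()].
#'
#' @param model,reference [typed_structure] objects (or `n x 3` Calpha
#'   coordinate matrices) of equal residue count.
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(model, reference) {
  P <- if (inherits(model, "typed_structure")) .ca_coords(model) else as.matrix(model)
  Q <- if (inherits(reference, "typed_structure")) .ca_coords(reference) else as.matrix(reference)
  if (!all(dim(P) == dim(Q))) abort("coordinate sets differ in size")
  L <- nrow(Q)
  if (L < 3L) abort("need at least 3 residues")
  d0 <- max(0.5, 1.24 * (max(L, 17) - 15)^(1 / 3) - 1.8)
  score_for <- function(idx) {
    for (iter in 1:6) {
      Pc <- sweep(P, 2L, colMeans(P[idx, , drop = FALSE]))
      Qc <- sweep(Q, 2L, colMeans(Q[idx, , drop = FALSE]))
      s <- svd(crossprod(Pc[idx, , drop = FALSE], Qc[idx, , drop = FALSE]))
      d <- sign(det(s$v %*% t(s$u)))
      rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
      dist <- sqrt(rowSums((Qc - Pc %*% t(rot))^2))
      new_idx <- which(dist < max(d0, 3))
      if (length(new_idx) < 3L) break
      if (identical(new_idx, idx)) break
      idx <- new_idx
    }
    mean(1 / (1 + (dist / d0)^2))
  }
  frags <- unique(c(list(seq_len(L)), lapply(
    seq(1L, max(1L, L - max(4L, L %/% 2) + 1L), by = max(1L, L %/% 4)),
    function(s) seq(s, min(L, s + max(4L, L %/% 2) - 1L)))))
  max(vapply(frags, score_for, numeric(1L)))
}

#' Evaluate a potential on a native-plus-decoys set
#'
#' Scores the native and every decoy with the distance (and optionally
#' orientation) potential, ranks all conformations by hybrid energy with
#' deterministic name tie-breaks, and summarises native recognition
#' (native rank and Z-score over the pooled conformations), best-model
#' selection (lowest-RMSD / highest-TM model among the top-1/5/10
#' lowest-energy decoys), and energy-quality Pearson correlations over the
#' decoys (native excluded).
#'
#' Calpha RMSD to the native is computed internally by [kabsch_rmsd()]
#' when decoys match the native residue count; TM-scores are taken from
#' the optional `quality` table (columns `name`, `tm`, and optionally
#' `rmsd` to override the internal values).
#'
#' @param native A [typed_structure].
#' @param decoys Named list of [typed_structure] decoys (>= 2).
#' @param dist_pot A `distance_potential`.
#' @param orient_pot Optional `orientation_potential`.
#' @param w_orient Hybrid weight (default 0.1).
#' @param quality Optional data frame with per-decoy quality values.
#' @param defs Vector-pair definitions for the orientation term.
#' @return A `decoy_report`: list with `scores` (per-conformation tibble)
#'   and `summary` (one-row tibble).
#' @export
evaluate_decoy_set <- function(native, decoys, dist_pot, orient_pot = NULL,
                               w_orient = 0.1, quality = NULL,
                               defs = vector_pair_defs()) {
  if (length(decoys) < 2L) abort("need at least 2 decoys")
  if (is.null(names(decoys)) || any(!nzchar(names(decoys))))
    names(decoys) <- sprintf("decoy_%03d", seq_along(decoys))
  all_str <- c(list(native = native), decoys)
  scores <- purrr::map_dfr(all_str, function(s)
    score_rwplus(s, dist_pot, orient_pot, w_orient, defs))
  scores <- dplyr::mutate(scores,
                          name = names(all_str),
                          is_native = names(all_str) == "native",
                          .before = 1L)
  nat_ca <- .ca_coords(native)
  scores$rmsd <- vapply(all_str, function(s) {
    ca <- .ca_coords(s)
    if (!all(dim(ca) == dim(nat_ca))) return(NA_real_)
    kabsch_rmsd(nat_ca, ca)
  }, numeric(1L))
  scores$tm <- NA_real_
  if (!is.null(quality)) {
    i <- match(scores$name, quality$name)
    if ("tm" %in% names(quality)) scores$tm <- quality$tm[i]
    if ("rmsd" %in% names(quality)) {
      have <- !is.na(quality$rmsd[i])
      scores$rmsd[have] <- quality$rmsd[i][have]
    }
  }
  scores <- scores[order(scores$e_rwplus, scores$name), , drop = FALSE]
  scores$rank <- seq_len(nrow(scores))
  e_all <- scores$e_rwplus
  sd_all <- sd(e_all)
  z_native <- if (sd_all > 0) (e_all[scores$is_native] - mean(e_all)) / sd_all
              else NA_real_
  dec <- scores[!scores$is_native, , drop = FALSE]
  topk <- function(k, col, best) {
    v <- dec[[col]][seq_len(min(k, nrow(dec)))]
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else best(v)
  }
  corr <- function(col) {
    v <- dec[[col]]
    ok <- !is.na(v)
    if (sum(ok) < 3L || sd(v[ok]) == 0 || sd(dec$e_rwplus[ok]) == 0)
      return(NA_real_)
    cor(dec$e_rwplus[ok], v[ok])
  }
  summary <- tibble::tibble(
    n_decoys = nrow(dec),
    native_rank = scores$rank[scores$is_native],
    native_is_top1 = scores$rank[scores$is_native] == 1L,
    z_native = z_native,
    top1_rmsd = topk(1L, "rmsd", min),
    top5_rmsd = topk(5L, "rmsd", min),
    top10_rmsd = topk(10L, "rmsd", min),
    top1_tm = topk(1L, "tm", max),
    top5_tm = topk(5L, "tm", max),
    top10_tm = topk(10L, "tm", max),
    corr_energy_rmsd = corr("rmsd"),
    corr_energy_tm = corr("tm"),
    w_orient = w_orient)
  structure(list(scores = tibble::as_tibble(scores), summary = summary),
            class = "decoy_report")
}

#' @export
print.decoy_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<decoy_report> %d decoys | native rank %d (z = %s) | top5 best RMSD %s A | corr(E, RMSD) = %s\n",
    s$n_decoys, s$native_rank,
    formatC(s$z_native, digits = 3, format = "f"),
    formatC(s$top5_rmsd, digits = 2, format = "f"),
    formatC(s$corr_energy_rmsd, digits = 3, format = "f")))
  invisible(x)
}

#' Tidy / summarise a decoy report
#'
#' `tidy()` returns the per-conformation score table; `glance()` the
#' one-row summary.
#'
#' @param x A `decoy_report`.
#' @param ... Unused.
#' @export
tidy.decoy_report <- function(x, ...) x$scores

#' @rdname tidy.decoy_report
#' @export
glance.decoy_report <- function(x, ...) x$summary

#' Energy-versus-quality funnel plot of a decoy report
#'
#' @param object A `decoy_report`.
#' @param ... Unused.
#' @return A ggplot object: hybrid energy against Calpha RMSD, decoys as
#'   points and the native highlighted.
#' @export
autoplot.decoy_report <- function(object, ...) {
  df <- object$scores
  ggplot2::ggplot(df[!df$is_native, ],
                  ggplot2::aes(x = .data$rmsd, y = .data$e_rwplus)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_point(data = df[df$is_native, ], colour = "red", size = 3L) +
    ggplot2::labs(x = "Cα RMSD to native (Å)",
                  y = expression(E[RWplus] ~ "(kT)")) +
    ggplot2::theme_minimal()
}
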