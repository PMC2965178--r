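# Shared fixtures and brute-force oracles. Everything is generated in code
# under fixed seeds; no binary data.

aa20 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

fixture_sequence <- function(n, seed = 42) {
  set.seed(seed)
  sample(aa20, n, replace = TRUE)
}

# small compact fixture shared across tests (30 residues, all types present
# often enough for scoring paths)
small_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressMessages(generate_fixture(fixture_sequence(30), seed = 7))
    cache
  }
})

# O(n^2) double-loop oracle for pair counting inside the cutoff
brute_pair_list <- function(s, R0 = 15.5, dR = 0.5, min_sep = 2) {
  n <- nrow(s)
  out <- list(ti = integer(), tj = integer(), bin = integer())
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (abs(s$residue_index[i] - s$residue_index[j]) < min_sep) next
      d <- sqrt((s$x[i] - s$x[j])^2 + (s$y[i] - s$y[j])^2 + (s$z[i] - s$z[j])^2)
      if (d >= R0) next
      out$ti <- c(out$ti, s$type_id[i])
      out$tj <- c(out$tj, s$type_id[j])
      out$bin <- c(out$bin, min(floor(d / dR) + 1L, as.integer(R0 / dR)))
    }
  }
  out
}

brute_score_rw <- function(s, pot) {
  p <- brute_pair_list(s, pot$params$R0, pot$params$dR, pot$min_separation)
  if (!length(p$ti)) return(0)
  sum(pot$energy[cbind(p$ti, p$tj, p$bin)])
}

# rigid-body transform of a typed structure (exact, no re-rounding)
rigid_transform <- function(s, seed = 1) {
  set.seed(seed)
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  t0 <- rnorm(3, sd = 20)
  xyz <- cbind(s$x, s$y, s$z) %*% t(R)
  out <- s
  out$x <- xyz[, 1] + t0[1]
  out$y <- xyz[, 2] + t0[2]
  out$z <- xyz[, 3] + t0[3]
  out
}

# minimal hand-written PDB text for parser tests
gag_pdb_text <- c(
  "REMARK synthetic three-residue test peptide",
  "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C",
  "ATOM      3  C   GLY A   1       2.009   1.420   0.000  1.00  0.00           C",
  "ATOM      4  O   GLY A   1       1.251   2.390   0.000  1.00  0.00           O",
  "ATOM      5  N   ALA A   2       3.332   1.536   0.000  1.00  0.00           N",
  "ATOM      6  CA  ALA A   2       4.000   2.800   0.100  1.00  0.00           C",
  "ATOM      7  C   ALA A   2       5.400   2.600   0.700  1.00  0.00           C",
  "ATOM      8  O   ALA A   2       5.600   1.700   1.500  1.00  0.00           O",
  "ATOM      9  CB  ALA A   2       4.100   3.500  -1.260  1.00  0.00           C",
  "ATOM     10  H   ALA A   2       3.400   1.000  -0.800  1.00  0.00           H",
  "ATOM     11  N   GLY A   3       6.400   3.400   0.300  1.00  0.00           N",
  "ATOM     12  CA  GLY A   3       7.800   3.300   0.800  1.00  0.00           C",
  "ATOM     13  C   GLY A   3       8.600   4.600   0.600  1.00  0.00           C",
  "ATOM     14  O   GLY A   3       8.100   5.600   0.100  1.00  0.00           O",
  "ATOM     15  OXT GLY A   3       9.800   4.600   1.000  1.00  0.00           O",
  "TER",
  "END")
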