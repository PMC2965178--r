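#' Plain-text persistence of count and potential tables
#'
#' Tables are written as tab-separated text: header comment lines
#' (`# key value`) carrying the kind, the reference parameters and the
#' typing-scheme hash, followed by sparse `a b k value` rows for non-zero
#' (counts) or non-default (energies) entries at full double precision.
#' Loading validates the typing hash against the running session and
#' refuses tables built under a different scheme or bin layout.
#'
#' @name tables-io
NULL

.header_kv <- function(...) {
  kv <- list(...)
  sprintf("# %s %s", names(kv), vapply(kv, function(v)
    format(v, digits = 17, scientific = FALSE), character(1L)))
}

.sparse_rows <- function(arr, default) {
  idx <- which(arr != default, arr.ind = TRUE)
  data.frame(a = idx[, 1L], b = idx[, 2L], k = idx[, 3L],
             value = arr[idx])
}

#' Save a potential or count table as text
#'
#' @param x A `distance_potential`, `pair_count_table` or
#'   `orientation_potential`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_potential_table <- function(x, path) {
  p <- x$params
  if (inherits(x, "distance_potential")) {
    head <- .header_kv(kind = "distance_potential", lam = p$lam, R0 = p$R0,
                       dR = p$dR, cap = x$cap,
                       min_separation = x$min_separation,
                       weighting = x$weighting, n_min = x$n_min,
                       n_structures = x$n_structures,
                       typing_hash = x$typing_hash)
    rows <- .sparse_rows(x$energy, 0)
  } else if (inherits(x, "pair_count_table")) {
    head <- .header_kv(kind = "pair_count_table", lam = p$lam, R0 = p$R0,
                       dR = p$dR, min_separation = x$min_separation,
                       n_structures = x$n_structures, n_res = x$n_res,
                       typing_hash = typing_hash())
    rows <- .sparse_rows(x$counts, 0)
  } else if (inherits(x, "orientation_potential")) {
    head <- .header_kv(kind = "orientation_potential", cap = x$cap,
                       contact_cutoff = x$contact_cutoff,
                       min_separation = x$min_separation,
                       n_structures = x$n_structures,
                       typing_hash = x$typing_hash)
    rows <- .sparse_rows(x$energy, 0)
  } else abort("unsupported table type")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(head, con)
  writeLines("a\tb\tk\tvalue", con)
  if (nrow(rows))
    writeLines(sprintf("%d\t%d\t%d\t%s", rows$a, rows$b, rows$k,
                       formatC(rows$value, digits = 17, format = "g")), con)
  invisible(path)
}

.parse_header <- function(lines) {
  hl <- lines[startsWith(lines, "# ")]
  parts <- strsplit(sub("^# ", "", hl), " ", fixed = TRUE)
  stats::setNames(vapply(parts, function(p) paste(p[-1L], collapse = " "),
                         character(1L)),
                  vapply(parts, `[[`, character(1L), 1L))
}

#' Load a table written by [save_potential_table()]
#'
#' @param path Path to the table file.
#' @return The reconstructed object (values bit-identical to what was
#'   saved).
#' @export
load_potential_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("table file not found: %s", path))
  lines <- readLines(path)
  h <- .parse_header(lines)
  if (is.null(h[["kind"]]) || is.na(h["kind"]))
    abort(sprintf("%s is not a rwpot table (missing header)", path))
  if (!is.na(h["typing_hash"]) && !identical(unname(h[["typing_hash"]]), typing_hash()))
    abort("table was built under a different atom-typing scheme")
  body <- lines[!startsWith(lines, "#")]
  if (!length(body) || body[1L] != "a\tb\tk\tvalue")
    abort(sprintf("%s: malformed or truncated table", path))
  rows <- if (length(body) > 1L)
    read.table(text = body[-1L], sep = "\t",
               col.names = c("a", "b", "k", "value"),
               colClasses = c("integer", "integer", "integer", "numeric"))
  else data.frame(a = integer(), b = integer(), k = integer(),
                  value = numeric())
  num <- function(key) as.numeric(h[[key]])
  kind <- h[["kind"]]
  if (kind %in% c("distance_potential", "pair_count_table")) {
    params <- rw_params(num("lam"), num("R0"), num("dR"))
    nt <- n_atom_types()
    arr <- array(0, dim = c(nt, nt, params$n_bins))
    if (nrow(rows)) {
      if (any(rows$k > params$n_bins | rows$a > nt | rows$b > nt))
        abort(sprintf("%s: indices exceed the declared bin layout", path))
      arr[cbind(rows$a, rows$b, rows$k)] <- rows$value
    }
    if (kind == "distance_potential")
      return(structure(list(energy = arr, params = params, cap = num("cap"),
                            min_separation = as.integer(num("min_separation")),
                            weighting = h[["weighting"]],
                            n_min = as.integer(num("n_min")),
                            n_structures = as.integer(num("n_structures")),
                            typing_hash = unname(h[["typing_hash"]])),
                       class = "distance_potential"))
    return(structure(list(counts = arr,
                          n_structures = as.integer(num("n_structures")),
                          n_res = as.integer(num("n_res")), params = params,
                          min_separation = as.integer(num("min_separation"))),
                     class = "pair_count_table"))
  }
  if (kind == "orientation_potential") {
    nv <- n_vector_pair_types()
    arr <- array(0, dim = c(nv, nv, N_ORIENTATION_BINS))
    if (nrow(rows)) arr[cbind(rows$a, rows$b, rows$k)] <- rows$value
    return(structure(list(energy = arr, ref_prob = orientation_ref_prob(),
                          contact_cutoff = num("contact_cutoff"),
                          min_separation = as.integer(num("min_separation")),
                          cap = num("cap"),
                          n_structures = as.integer(num("n_structures")),
                          typing_hash = unname(h[["typing_hash"]])),
                     class = "orientation_potential"))
  }
  abort(sprintf("unknown table kind '%s'", kind))
}
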