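#' Read a restraint table from TSV
#'
#' Expects a UTF-8, tab-delimited file with header
#' `pair_i  pair_j  d  sigma  averaging  k` ('.' decimal separator). Indices
#' are 0-based; an optional `offset` column (1-based residue numbering start)
#' is subtracted from the pair indices when present. All rows must share one
#' averaging type and exponent. Malformed rows are rejected with their line
#' number.
#'
#' @param path file path.
#' @return a [restraint_set()].
#' @export
read_restraints <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("restraint file has no data rows: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  required <- c("pair_i", "pair_j", "d", "sigma", "averaging", "k")
  missing <- setdiff(required, header)
  if (length(missing))
    stop("restraint file is missing column(s): ",
         paste(missing, collapse = ", "))
  idx <- match(c(required, "offset"), header)
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  parse_row <- function(fields, line_no) {
    if (length(fields) < length(header))
      stop("line ", line_no, ": expected ", length(header),
           " tab-separated fields, found ", length(fields))
    num <- function(j, what) {
      v <- suppressWarnings(as.numeric(fields[idx[j]]))
      if (is.na(v)) stop("line ", line_no, ": malformed numeric in '",
                         what, "': ", fields[idx[j]])
      v
    }
    avg <- fields[idx[5L]]
    if (!avg %in% c("linear", "power"))
      stop("line ", line_no, ": unknown averaging tag '", avg, "'")
    off <- if (!is.na(idx[7L])) num(7L, "offset") else 0
    c(i = num(1L, "pair_i") - off, j = num(2L, "pair_j") - off,
      d = num(3L, "d"), sigma = num(4L, "sigma"), k = num(6L, "k"),
      avg = match(avg, c("linear", "power")))
  }
  parsed <- mapply(parse_row, rows, seq_along(rows) + 1L)
  avg <- c("linear", "power")[parsed["avg", 1L]]
  if (length(unique(parsed["avg", ])) != 1L ||
      length(unique(parsed["k", ])) != 1L)
    stop("all restraints in one file must share averaging type and k")
  key <- paste(pmin(parsed["i", ], parsed["j", ]),
               pmax(parsed["i", ], parsed["j", ]))
  if (anyDuplicated(key))
    stop("line ", which(duplicated(key))[1L] + 1L, ": duplicate pair")
  restraint_set(cbind(parsed["i", ], parsed["j", ]), parsed["d", ],
                parsed["sigma", ], averaging = avg,
                k = as.integer(parsed["k", 1L]))
}

#' Write a restraint table to TSV
#'
#' Numbers are written with 17 significant digits so that
#' `read_restraints(write_restraints(x))` is a lossless round-trip.
#'
#' @param set a [restraint_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_restraints <- function(set, path) {
  if (!inherits(set, "restraint_set")) stop("'set' must be a restraint_set")
  fmt <- function(x) formatC(x, digits = 17L, format = "g")
  lines <- c(paste(c("pair_i", "pair_j", "d", "sigma", "averaging", "k"),
                   collapse = "\t"),
             sprintf("%d\t%d\t%s\t%s\t%s\t%d",
                     set$pairs[, 1L], set$pairs[, 2L], fmt(set$d),
                     fmt(set$sigma), set$averaging, set$k))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write an ensemble of conformations
#'
#' XYZ: one block per conformation (`n`, a comment line, then `CA x y z`
#' rows, six decimals). PDB: C-alpha-only ATOM records in fixed columns
#' (three decimals) framed by MODEL/ENDMDL.
#'
#' @param samples non-empty list of conformations.
#' @param path output file path.
#' @param format `"xyz"` or `"pdb"`.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(samples, path, format = c("xyz", "pdb")) {
  format <- match.arg(format)
  if (length(samples) == 0L) stop("cannot write an empty ensemble")
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "xyz") {
    for (s in seq_along(samples)) {
      coords <- unclass(samples[[s]])
      writeLines(c(as.character(nrow(coords)), sprintf("model %d", s),
                   sprintf("CA %.6f %.6f %.6f",
                           coords[, 1L], coords[, 2L], coords[, 3L])), con)
    }
  } else {
    for (s in seq_along(samples)) {
      coords <- unclass(samples[[s]])
      writeLines(sprintf("MODEL     %4d", s), con)
      writeLines(sprintf(
        "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
        seq_len(nrow(coords)), seq_len(nrow(coords)),
        coords[, 1L], coords[, 2L], coords[, 3L]), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  }
  invisible(path)
}

#' Read an ensemble of conformations
#'
#' @param path file path.
#' @param format `"xyz"` or `"pdb"`; inferred from the file extension when
#'   missing.
#' @return list of [conformation()] objects.
#' @export
read_ensemble <- function(path, format = NULL) {
  if (is.null(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xyz", "pdb")) ext else
      stop("cannot infer ensemble format from extension '", ext, "'")
  }
  format <- match.arg(format, c("xyz", "pdb"))
  lines <- readLines(path)
  out <- list()
  if (format == "xyz") {
    i <- 1L
    while (i <= length(lines)) {
      if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
      n <- suppressWarnings(as.integer(trimws(lines[i])))
      if (is.na(n)) stop("line ", i, ": expected an atom count")
      block <- lines[(i + 2L):(i + 1L + n)]
      fields <- do.call(rbind, strsplit(trimws(block), "\\s+"))
      coords <- matrix(as.numeric(fields[, 2:4, drop = FALSE]), ncol = 3L)
      out[[length(out) + 1L]] <- conformation(coords)
      i <- i + 2L + n
    }
  } else {
    atom <- startsWith(lines, "ATOM")
    model_id <- cumsum(startsWith(lines, "MODEL"))
    if (max(model_id) == 0L) model_id <- rep(1L, length(lines))
    for (mid in unique(model_id[atom])) {
      rows <- lines[atom & model_id == mid]
      coords <- cbind(as.numeric(substr(rows, 31L, 38L)),
                      as.numeric(substr(rows, 39L, 46L)),
                      as.numeric(substr(rows, 47L, 54L)))
      out[[length(out) + 1L]] <- conformation(coords)
    }
  }
  if (length(out) == 0L) stop("no conformations found in ", path)
  out
}
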