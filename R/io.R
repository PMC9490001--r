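#' @importFrom stats coef dnorm lm median nlminb quantile residuals
#'   rnorm runif sd setNames splinefun uniroot var vcov
#' @importFrom utils read.table write.table head tail
NULL

.aa1 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V","X")

#' Residue identifier
#'
#' @param index 1-based sequence position
#' @param aa one-letter amino-acid code ('X' allowed for unknown)
#' @return list of class \code{residue_id}
#' @export
residue_id <- function(index, aa = "X") {
  index <- as.integer(index)
  if (is.na(index) || index < 1L)
    stop("residue index must be a positive integer")
  if (!is.character(aa) || nchar(aa) != 1L || !(aa %in% .aa1))
    stop("unknown one-letter amino-acid code: ", aa)
  structure(list(index = index, aa = aa), class = "residue_id")
}

#' Peak-intensity decay curve for one residue
#'
#' Holds a relaxation or hydrogen-exchange intensity decay I(t). Delays in
#' seconds, strictly increasing; at least three points and at least one
#' positive intensity are required.
#'
#' @param residue a \code{residue_id}
#' @param times delay values (s), strictly increasing
#' @param intensities non-negative signal values (arbitrary units)
#' @param errors optional per-point uncertainties
#' @return list of class \code{decay_curve}
#' @export
decay_curve <- function(residue, times, intensities, errors = NULL) {
  if (!inherits(residue, "residue_id")) residue <- residue_id(residue)
  times <- as.numeric(times); intensities <- as.numeric(intensities)
  if (length(times) != length(intensities) || length(times) < 3L)
    stop("need equal-length times/intensities with >= 3 points")
  if (any(diff(times) <= 0))
    stop("validation error: delay times must be strictly increasing")
  if (any(!is.finite(times)) || any(!is.finite(intensities)))
    stop("non-finite values in decay curve")
  if (any(intensities < 0))
    stop("intensities must be non-negative")
  if (!any(intensities > 0))
    stop("decay curve needs at least one positive intensity")
  if (!is.null(errors)) {
    errors <- as.numeric(errors)
    if (length(errors) != length(times)) stop("errors length mismatch")
  }
  structure(list(residue = residue, times = times,
                 intensities = intensities, errors = errors),
            class = "decay_curve")
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf("<decay_curve> residue %d%s, %d points, t = [%g, %g] s\n",
              x$residue$index, x$residue$aa, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Single protein conformation
#'
#' A flat atom table (one row per atom) with 1-based residue numbering,
#' one-letter codes, atom names, element symbols and coordinates in
#' Angstrom. Atom names must be unique within a residue and every residue
#' must carry at least one atom.
#'
#' @param atoms data.frame with columns resno, aa, atom, element, x, y, z
#' @param model_id integer model identifier
#' @return data.frame of class \code{conformation}
#' @export
conformation <- function(atoms, model_id = 1L) {
  need <- c("resno", "aa", "atom", "element", "x", "y", "z")
  if (!all(need %in% names(atoms)))
    stop("atoms must have columns: ", paste(need, collapse = ", "))
  atoms <- as.data.frame(atoms)[, need]
  atoms$resno <- as.integer(atoms$resno)
  if (any(atoms$resno < 1L)) stop("residue numbers must be >= 1")
  if (!all(atoms$aa %in% .aa1)) stop("unknown amino-acid code in atoms")
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates")
  key <- paste(atoms$resno, atoms$atom)
  if (anyDuplicated(key))
    stop("duplicate atom name within a residue: ",
         key[duplicated(key)][1])
  attr(atoms, "model_id") <- as.integer(model_id)
  class(atoms) <- c("conformation", "data.frame")
  atoms
}

#' @export
print.conformation <- function(x, ...) {
  cat(sprintf("<conformation> model %d: %d atoms, %d residues\n",
              attr(x, "model_id"), nrow(x), length(unique(x$resno))))
  invisible(x)
}

#' Coordinate matrix of a conformation
#' @param conf a \code{conformation}
#' @return n x 3 numeric matrix
#' @export
coords <- function(conf) {
  as.matrix(conf[, c("x", "y", "z")])
}

.read_tsv_commented <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(list(header = character(0), data = NULL))
  h <- lines[1]
  if (!startsWith(h, "#"))
    stop("format error: expected a commented header line starting with '#'")
  header <- strsplit(trimws(sub("^#\\s*", "", h)), "[\t ]+")[[1]]
  if (length(lines) == 1L)
    return(list(header = header, data = NULL))
  data <- read.table(text = lines[-1], sep = "\t", header = FALSE,
                     stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (ncol(data) != length(header))
    stop("format error: header declares ", length(header),
         " columns but rows have ", ncol(data))
  names(data) <- header
  list(header = header, data = data)
}

#' Read a wide-format intensity decay table
#'
#' Expects the package's tab-separated dialect: a commented header
#' \code{# residue aa <t1> <t2> ...} whose delay column names are the delay
#' values in seconds, then one row per residue. Missing cells are dropped
#' from that residue's curve with a warning.
#'
#' @param path file path
#' @param dialect table dialect id; only \code{"wide"} is defined
#' @return list of \code{decay_curve}
#' @export
read_decay_table <- function(path, dialect = "wide") {
  dialect <- match.arg(dialect, "wide")
  tab <- .read_tsv_commented(path)
  if (is.null(tab$data)) return(list())
  header <- tab$header
  if (length(header) < 5L || header[1] != "residue" || header[2] != "aa")
    stop("format error: decay header must be '# residue aa <delays...>'")
  delays <- suppressWarnings(as.numeric(header[-(1:2)]))
  if (any(is.na(delays)))
    stop("format error: delay columns must be numeric seconds")
  if (any(diff(delays) <= 0))
    stop("validation error: delay columns not strictly increasing")
  df <- tab$data
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    ii <- as.numeric(df[i, -(1:2)])
    keep <- is.finite(ii)
    if (!all(keep))
      warning(sprintf("residue %s: dropped %d missing cell(s)",
                      df$residue[i], sum(!keep)))
    out[[i]] <- decay_curve(residue_id(df$residue[i], df$aa[i]),
                            delays[keep], ii[keep])
  }
  out
}

#' Read a multi-model structure file into conformations
#'
#' Reads PDB-style files (MODEL/ENDMDL records) via bio3d and returns one
#' \code{conformation} per model. All models must share the same atom
#' count; offenders are named in the error.
#'
#' @param path PDB file path
#' @return list of \code{conformation}
#' @export
read_ensemble <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1L) {
    ends <- grep("^ENDMDL", lines)
    if (length(ends) == length(model_starts)) {
      counts <- mapply(function(a, b) sum(grepl("^ATOM  |^HETATM",
                                                lines[a:b])),
                       model_starts, ends)
      ids <- as.integer(sub("^MODEL\\s+", "",
                            substr(lines[model_starts], 1, 14)))
      if (length(unique(counts)) > 1L) {
        bad <- ids[counts != as.numeric(names(sort(table(counts),
                                                   decreasing = TRUE))[1])]
        stop("validation error: models with differing atom counts: ",
             paste(bad, collapse = ", "))
      }
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  n_models <- nrow(xyz)
  at <- pdb$atom
  aa <- suppressWarnings(bio3d::aa321(at$resid))
  aa[is.na(aa) | !(aa %in% .aa1)] <- "X"
  lapply(seq_len(n_models), function(m) {
    v <- xyz[m, ]
    conformation(data.frame(
      resno = at$resno, aa = aa, atom = at$elety,
      element = ifelse(is.na(at$elesy) | !nzchar(at$elesy),
                       substr(gsub("[0-9]", "", at$elety), 1, 1), at$elesy),
      x = v[seq(1, length(v), 3)],
      y = v[seq(2, length(v), 3)],
      z = v[seq(3, length(v), 3)],
      stringsAsFactors = FALSE), model_id = m)
  })
}

#' Write conformations as a multi-model PDB file
#'
#' @param ensemble list of \code{conformation} sharing one topology
#' @param path output file path
#' @return invisibly, the path
#' @export
write_ensemble <- function(ensemble, path) {
  if (inherits(ensemble, "conformation")) ensemble <- list(ensemble)
  stopifnot(length(ensemble) >= 1L)
  ref <- ensemble[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(ensemble)) {
    conf <- ensemble[[m]]
    if (nrow(conf) != nrow(ref))
      stop("validation error: model ", m, " atom count differs")
    writeLines(sprintf("MODEL %8d", m), con)
    aa3 <- bio3d::aa123(conf$aa)
    aa3[is.na(aa3)] <- "UNK"
    writeLines(sprintf(
      "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(nrow(conf)),
      ifelse(nchar(conf$atom) < 4, paste0(" ", conf$atom), conf$atom),
      aa3, conf$resno, conf$x, conf$y, conf$z, conf$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a per-residue result table
#'
#' Writes any per-residue data.frame in the package's tab-separated dialect
#' (commented header), sorted by residue index, with full double precision
#' so that write-then-read round-trips bit-identically for finite values.
#'
#' @param records data.frame with a \code{residue} column of unique indices
#' @param path output file path
#' @return invisibly, the path
#' @export
write_per_residue_table <- function(records, path) {
  records <- as.data.frame(records)
  if (!"residue" %in% names(records))
    stop("records must have a 'residue' column")
  if (anyDuplicated(records$residue))
    stop("validation error: duplicate residue ids: ",
         paste(unique(records$residue[duplicated(records$residue)]),
               collapse = ", "))
  records <- records[order(records$residue), , drop = FALSE]
  fmt <- vapply(records, function(col) {
    if (is.numeric(col) && !is.integer(col))
      sprintf("%.17g", col)
    else as.character(col)
  }, character(nrow(records)))
  if (nrow(records) == 1L) fmt <- matrix(fmt, nrow = 1L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", paste(names(records), collapse = "\t")), con)
  writeLines(apply(fmt, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a per-residue table written by \code{write_per_residue_table}
#'
#' @param path file path
#' @return data.frame sorted by residue index
#' @export
read_per_residue_table <- function(path) {
  tab <- .read_tsv_commented(path)
  if (is.null(tab$data)) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(tab$header)),
                                 tab$header))
    return(df)
  }
  df <- tab$data
  if ("residue" %in% names(df)) df <- df[order(df$residue), , drop = FALSE]
  rownames(df) <- NULL
  df
}
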