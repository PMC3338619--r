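# Reading, validation and assembly of assigned HSQC peak lists.

AA1 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
         E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
         M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
         Y = "TYR", V = "VAL")
AA3 <- structure(names(AA1), names = AA1)

#' Construct a validated peak list
#'
#' A peak list holds the assigned backbone amide cross-peaks of one
#' \eqn{^1H}-\eqn{^{15}N} HSQC spectrum recorded at a single point of a
#' titration, together with the total ligand and protein concentrations of
#' that point.
#'
#' @param peaks data frame with columns \code{residue_id} (positive integer
#'   sequence number), \code{residue_name} (amino-acid code),
#'   \code{delta_H} and \code{delta_N} (chemical shifts, ppm),
#'   \code{intensity} (peak height, arbitrary units, \code{NA} if the
#'   source format carried no intensities) and optionally \code{state}
#'   (\code{"free"} or \code{"bound"}; slow-exchange bound-state peaks are
#'   tracked separately from the free-state peak of the same residue).
#' @param ligand_conc total ligand concentration of the titration point (uM).
#' @param protein_conc total protein concentration (uM).
#'
#' @return An object of class \code{peaklist}.
#' @details Amide shifts far outside the usual envelope
#'   (\eqn{\delta_H} in 4--13 ppm, \eqn{\delta_N} in 95--140 ppm) raise a
#'   warning, not an error: folded peaks and unusual chemistry occur in
#'   practice. A duplicated (residue, state) assignment is a hard error.
#' @export
peaklist <- function(peaks, ligand_conc, protein_conc) {
  stopifnot(is.data.frame(peaks))
  required <- c("residue_id", "residue_name", "delta_H", "delta_N", "intensity")
  missing_cols <- setdiff(required, names(peaks))
  if (length(missing_cols) > 0L)
    stop("peak table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (is.null(peaks$state)) peaks$state <- rep("free", nrow(peaks))
  peaks$residue_id <- as.integer(peaks$residue_id)
  peaks$state <- as.character(peaks$state)
  if (nrow(peaks) > 0L) {
    if (any(!peaks$state %in% c("free", "bound")))
      stop("peak state must be 'free' or 'bound'")
    if (any(peaks$residue_id < 1L))
      stop("residue_id must be >= 1")
    if (any(!is.na(peaks$intensity) & peaks$intensity < 0))
      stop("peak intensity must be >= 0")
    key <- paste(peaks$residue_id, peaks$state)
    if (anyDuplicated(key)) {
      dup <- peaks$residue_id[duplicated(key)]
      stop("duplicate assignment for residue(s): ",
           paste(unique(dup), collapse = ", "))
    }
    odd_H <- !is.na(peaks$delta_H) & (peaks$delta_H < 4 | peaks$delta_H > 13)
    odd_N <- !is.na(peaks$delta_N) & (peaks$delta_N < 95 | peaks$delta_N > 140)
    if (any(odd_H | odd_N))
      warning("chemical shift(s) outside the typical amide envelope for residue(s): ",
              paste(peaks$residue_id[odd_H | odd_N], collapse = ", "))
  }
  if (length(ligand_conc) != 1L || is.na(ligand_conc) || ligand_conc < 0)
    stop("ligand_conc must be a single non-negative number (uM)")
  if (length(protein_conc) != 1L || is.na(protein_conc) || protein_conc < 0)
    stop("protein_conc must be a single non-negative number (uM)")
  structure(list(peaks = peaks[order(peaks$residue_id, peaks$state), ,
                               drop = FALSE],
                 ligand_conc = as.numeric(ligand_conc),
                 protein_conc = as.numeric(protein_conc)),
            class = "peaklist")
}

#' @export
print.peaklist <- function(x, ...) {
  cat(sprintf("HSQC peak list: %d peaks, [L] = %g uM, [P]0 = %g uM\n",
              nrow(x$peaks), x$ligand_conc, x$protein_conc))
  invisible(x)
}

#' Read an assigned peak list from disk
#'
#' Two dialects are supported: a plain CSV with header
#' \code{residue_id,residue_name,delta_H,delta_N,intensity} (optional
#' \code{state} column), and a Sparky-style \code{.list} export whose
#' assignment tokens look like \code{G110N-H} (w1 = \eqn{^{15}N}, w2 =
#' \eqn{^1H}, optional Data Height column). A lowercase \code{b} after the
#' residue number (\code{G110bN-H}) marks a slow-exchange bound-state peak.
#'
#' Peak-list formats carry no concentration metadata, so \code{ligand_conc}
#' and \code{protein_conc} are passed by the caller (normally from a series
#' manifest, see \code{\link{read_series_manifest}}).
#'
#' @param path file to read.
#' @param dialect \code{"csv"} or \code{"sparky"}.
#' @param ligand_conc,protein_conc concentrations of this titration point (uM).
#' @return A \code{\link{peaklist}}.
#' @export
read_peaklist <- function(path, dialect = c("csv", "sparky"),
                          ligand_conc = 0, protein_conc = 0) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  peaks <- switch(dialect,
                  csv = read_peaks_csv(path),
                  sparky = read_peaks_sparky(path))
  if (nrow(peaks) == 0L)
    warning("no data rows in ", path, "; empty peak list")
  peaklist(peaks, ligand_conc = ligand_conc, protein_conc = protein_conc)
}

read_peaks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        blank.lines.skip = TRUE)
  required <- c("residue_id", "residue_name", "delta_H", "delta_N")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L)
    stop("CSV peak list ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  if (is.null(df$intensity)) df$intensity <- rep(NA_real_, nrow(df))
  bad <- which(is.na(suppressWarnings(as.numeric(df$residue_id))) |
                 is.na(suppressWarnings(as.numeric(df$delta_H))) |
                 is.na(suppressWarnings(as.numeric(df$delta_N))))
  if (length(bad) > 0L)
    stop("unparseable row at line ", bad[1] + 1L, " of ", path)
  df$residue_id <- as.integer(df$residue_id)
  df$delta_H <- as.numeric(df$delta_H)
  df$delta_N <- as.numeric(df$delta_N)
  df$intensity <- as.numeric(df$intensity)
  df
}

read_peaks_sparky <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !grepl("Assignment", lines, fixed = TRUE)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(data.frame(residue_id = integer(0), residue_name = character(0),
                      delta_H = numeric(0), delta_N = numeric(0),
                      intensity = numeric(0), state = character(0)))
  parse_one <- function(i) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(tok) < 3L)
      stop("unparseable row at line ", i, " of ", path)
    m <- regmatches(tok[1],
                    regexec("^([A-Za-z])([0-9]+)(b?)N-H$", tok[1]))[[1]]
    if (length(m) == 0L)
      stop("unparseable assignment '", tok[1], "' at line ", i, " of ", path)
    w1 <- suppressWarnings(as.numeric(tok[2]))  # 15N
    w2 <- suppressWarnings(as.numeric(tok[3]))  # 1H
    if (is.na(w1) || is.na(w2))
      stop("unparseable row at line ", i, " of ", path)
    ht <- if (length(tok) >= 4L) suppressWarnings(as.numeric(tok[4])) else NA_real_
    data.frame(residue_id = as.integer(m[3]),
               residue_name = toupper(m[2]),
               delta_H = w2, delta_N = w1, intensity = ht,
               state = if (m[4] == "b") "bound" else "free",
               stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(seq_along(lines), parse_one))
}

#' Write a peak list
#'
#' Canonical writer for both dialects; \code{read_peaklist} followed by
#' \code{write_peaklist} is the identity on the peak table.
#'
#' @param x a \code{\link{peaklist}}.
#' @param path output file.
#' @param dialect \code{"csv"} or \code{"sparky"}.
#' @export
write_peaklist <- function(x, path, dialect = c("csv", "sparky")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "peaklist"))
  pk <- x$peaks
  if (dialect == "csv") {
    utils::write.csv(pk[, c("residue_id", "residue_name", "delta_H",
                            "delta_N", "intensity", "state")],
                     path, row.names = FALSE, quote = FALSE)
  } else {
    one <- ifelse(nchar(pk$residue_name) == 3L,
                  AA3[toupper(pk$residue_name)],
                  toupper(pk$residue_name))
    one[is.na(one)] <- "X"
    tag <- sprintf("%s%d%sN-H", one, pk$residue_id,
                   ifelse(pk$state == "bound", "b", ""))
    lines <- c(sprintf("%17s %10s %10s %12s",
                       "Assignment", "w1", "w2", "Data Height"),
               "",
               sprintf("%17s %10.3f %10.3f %12.1f",
                       tag, pk$delta_N, pk$delta_H, pk$intensity))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Assemble peak lists into a titration series
#'
#' Orders peak lists by ligand concentration, checks the design (exactly
#' one reference point at \eqn{[L]=0}, strictly increasing ligand
#' concentrations, constant protein concentration), and flags residues
#' present in the reference spectrum but absent at one or more later
#' points. Disappearance is evidence of slow or intermediate exchange and
#' such residues are retained, never dropped.
#'
#' @param lists a list of \code{\link{peaklist}} objects.
#' @param P0 protein concentration (uM); defaults to the concentration
#'   recorded in the peak lists, which must agree across points.
#' @return An object of class \code{titration_series} with elements
#'   \code{points} (ordered peak lists), \code{ligand_conc},
#'   \code{protein_conc}, \code{reference_index} (always 1 after sorting)
#'   and \code{disappeared} (data frame of residue, state and the first
#'   point index at which the peak is missing).
#' @export
assemble_series <- function(lists, P0 = NULL) {
  if (!is.list(lists) || length(lists) < 2L)
    stop("need at least 2 peak lists to assemble a titration series")
  if (!all(vapply(lists, inherits, logical(1), "peaklist")))
    stop("all elements must be peaklist objects")
  L <- vapply(lists, function(p) p$ligand_conc, numeric(1))
  if (anyDuplicated(L))
    stop("duplicate ligand concentration(s): ",
         paste(unique(L[duplicated(L)]), collapse = ", "))
  if (sum(L == 0) != 1L)
    stop("a titration series requires exactly one reference point at [L] = 0")
  ord <- order(L)
  lists <- lists[ord]
  L <- L[ord]
  P <- vapply(lists, function(p) p$protein_conc, numeric(1))
  if (is.null(P0)) {
    if (length(unique(P)) != 1L)
      stop("protein concentration differs across points (",
           paste(unique(P), collapse = ", "),
           "); dilution correction is not performed")
    P0 <- P[1]
  }
  ref <- lists[[1]]$peaks
  key <- function(pk) paste(pk$residue_id, pk$state)
  first_absent <- integer(0); gone_id <- integer(0); gone_state <- character(0)
  for (i in seq_len(nrow(ref))) {
    k <- key(ref)[i]
    present <- vapply(lists, function(p) k %in% key(p$peaks), logical(1))
    if (!all(present)) {
      first_absent <- c(first_absent, which(!present)[1])
      gone_id <- c(gone_id, ref$residue_id[i])
      gone_state <- c(gone_state, ref$state[i])
    }
  }
  structure(list(points = lists,
                 ligand_conc = L,
                 protein_conc = as.numeric(P0),
                 reference_index = 1L,
                 disappeared = data.frame(residue_id = gone_id,
                                          state = gone_state,
                                          first_absent = first_absent,
                                          stringsAsFactors = FALSE)),
            class = "titration_series")
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf(
    "Titration series: %d points, [L] = %s uM, [P]0 = %g uM\n",
    length(x$points), paste(x$ligand_conc, collapse = "/"), x$protein_conc))
  if (nrow(x$disappeared) > 0L)
    cat(sprintf("  %d reference peak(s) disappear during the titration\n",
                nrow(x$disappeared)))
  invisible(x)
}

#' Read a titration series from a manifest
#'
#' The manifest is a YAML key--value file naming the peak-list files of a
#' titration together with their ligand concentrations, because peak-list
#' formats themselves carry no concentration metadata:
#'
#' \preformatted{
#' protein_conc: 270
#' dialect: csv
#' points:
#'   - {file: t0.csv, ligand_conc: 0}
#'   - {file: t1.csv, ligand_conc: 270}
#' }
#'
#' File paths are resolved relative to the manifest's directory.
#'
#' @param path manifest file.
#' @return A \code{titration_series}.
#' @export
read_series_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- yaml::read_yaml(path)
  for (k in c("protein_conc", "points"))
    if (is.null(man[[k]])) stop("manifest lacks key '", k, "'")
  dialect <- if (is.null(man$dialect)) "csv" else man$dialect
  base <- dirname(path)
  lists <- lapply(man$points, function(pt) {
    if (is.null(pt$file) || is.null(pt$ligand_conc))
      stop("each manifest point needs 'file' and 'ligand_conc'")
    read_peaklist(file.path(base, pt$file), dialect = dialect,
                  ligand_conc = pt$ligand_conc,
                  protein_conc = man$protein_conc)
  })
  assemble_series(lists, P0 = man$protein_conc)
}
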