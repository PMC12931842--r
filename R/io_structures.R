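## Readers for biomolecular structure files.  PDB parsing is deliberately
## minimal and deterministic: fixed columns, ATOM records of the first model,
## first alternate location kept — enough to extract C-alpha or phosphate
## backbone traces.

#' Read a point cloud from a PDB file
#'
#' Selects ATOM records of the first model whose atom name matches
#' `atom_name` (e.g. `"CA"` for protein alpha-carbons, `"P"` for nucleic-acid
#' phosphates), optionally restricted to one chain.  For alternate locations
#' only the first occurrence per residue is kept.  Labels are
#' `chain + residue number (+ insertion code)`.
#'
#' @param path PDB file in the standard fixed-column format.
#' @param atom_name atom name to select (default `"CA"`).
#' @param chain optional single chain identifier.
#' @return A [point_cloud()].
#' @export
read_pdb <- function(path, atom_name = "CA", chain = NULL) {
  lines <- readLines(path, warn = FALSE)
  labels <- character(0)
  coords <- matrix(numeric(0), ncol = 3)
  seen <- character(0)
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    rec <- substr(line, 1, 6)
    if (rec == "ENDMDL") break     # first model only
    if (rec != "ATOM  ") next
    name <- trimws(substr(line, 13, 16))
    if (name != atom_name) next
    ch <- substr(line, 22, 22)
    if (!is.null(chain) && ch != chain) next
    resseq <- trimws(substr(line, 23, 26))
    icode <- trimws(substr(line, 27, 27))
    resid <- paste0(ch, resseq, icode)
    if (resid %in% seen) next      # keep first altLoc occurrence
    xyz <- suppressWarnings(as.numeric(c(substr(line, 31, 38),
                                         substr(line, 39, 46),
                                         substr(line, 47, 54))))
    if (anyNA(xyz))
      stop(sprintf("unparsable coordinates in '%s' line %d", path, ln))
    seen <- c(seen, resid)
    labels <- c(labels, resid)
    coords <- rbind(coords, xyz)
  }
  if (length(labels) == 0L)
    stop(sprintf("no '%s' atoms selected from '%s'%s", atom_name, path,
                 if (is.null(chain)) "" else sprintf(" (chain %s)", chain)))
  point_cloud(coords, labels)
}

#' Read a point cloud from an XYZ file
#'
#' Standard XYZ format: an atom-count line, a comment line, then
#' `element x y z` rows (whitespace-separated).  Labels are
#' `element + running index`.
#'
#' @param path XYZ file path.
#' @return A [point_cloud()].
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop(sprintf("'%s' is not a valid XYZ file", path))
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L)
    stop(sprintf("invalid atom count line in '%s'", path))
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n)
    stop(sprintf("'%s' declares %d atoms but has %d rows", path, n,
                 length(body)))
  body <- body[seq_len(n)]
  labels <- character(n)
  coords <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    tok <- strsplit(trimws(body[i]), "\\s+")[[1L]]
    if (length(tok) < 4L)
      stop(sprintf("malformed XYZ row %d in '%s'", i + 2L, path))
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz))
      stop(sprintf("non-numeric coordinates in row %d of '%s'", i + 2L, path))
    labels[i] <- paste0(tok[1L], i)
    coords[i, ] <- xyz
  }
  point_cloud(coords, labels)
}
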