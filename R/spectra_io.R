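#' Read a Sparky-format peak list
#'
#' Parses a whitespace-separated Sparky `.list` file: an optional header line
#' (first token `Assignment` or starting with `#`), then one peak per line
#' with the assignment label first, the chemical shifts in the declared axis
#' order, and optionally a final intensity column (missing intensities
#' default to 1.0).
#'
#' @param path Path to the peak list.
#' @param axis_order Character vector naming each shift column in file order;
#'   any permutation of `c("h", "c", "n15", "hn")` for a 4D list, or of
#'   `c("n15", "hn")` for a 2D root (HSQC) list.
#' @return For 4D lists a data frame with columns `label`, `h`, `c`, `n15`,
#'   `hn`, `intensity`; for 2D root lists `label`, `n15`, `hn`.  Peaks are
#'   identified elsewhere in the package by their row number in this frame.
#' @export
read_sparky_peaks <- function(path, axis_order = c("h", "c", "n15", "hn")) {
  if (!file.exists(path)) stop("no such file: ", path)
  valid4 <- c("h", "c", "n15", "hn")
  if (length(axis_order) == 4L) {
    if (!setequal(axis_order, valid4))
      stop("4D axis_order must be a permutation of h, c, n15, hn")
  } else if (length(axis_order) == 2L) {
    if (!setequal(axis_order, c("n15", "hn")))
      stop("2D axis_order must be a permutation of n15, hn")
  } else stop("axis_order must have length 2 or 4")
  k <- length(axis_order)
  lines <- readLines(path)
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    tok <- strsplit(ln, "[ \t]+")[[1L]]
    if (tok[1L] == "Assignment") next
    if (!(length(tok) %in% c(k + 1L, k + 2L)))
      stop(sprintf("parse error in %s line %d: expected %d or %d columns, got %d",
                   path, i, k + 1L, k + 2L, length(tok)))
    vals <- suppressWarnings(as.numeric(tok[-1L]))
    if (anyNA(vals))
      stop(sprintf("parse error in %s line %d: non-numeric chemical shift",
                   path, i))
    shifts <- vals[seq_len(k)]
    names(shifts) <- axis_order
    inten <- if (length(tok) == k + 2L) vals[k + 1L] else 1.0
    rows[[length(rows) + 1L]] <-
      if (k == 4L)
        data.frame(label = tok[1L], h = shifts[["h"]], c = shifts[["c"]],
                   n15 = shifts[["n15"]], hn = shifts[["hn"]],
                   intensity = inten, stringsAsFactors = FALSE)
      else
        data.frame(label = tok[1L], n15 = shifts[["n15"]],
                   hn = shifts[["hn"]], stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(if (k == 4L)
      data.frame(label = character(), h = numeric(), c = numeric(),
                 n15 = numeric(), hn = numeric(), intensity = numeric(),
                 stringsAsFactors = FALSE)
      else
      data.frame(label = character(), n15 = numeric(), hn = numeric(),
                 stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a Sparky-format peak list
#'
#' Inverse of [read_sparky_peaks()]; shifts are printed with three decimals
#' so that a write/read/write cycle is byte-stable.
#'
#' @param peaks Data frame as produced by [read_sparky_peaks()].
#' @param path Output path.
#' @param axis_order Column order to write (see [read_sparky_peaks()]).
#' @param header Write a Sparky header line (default `TRUE`).
#' @export
write_sparky_peaks <- function(peaks, path,
                               axis_order = c("h", "c", "n15", "hn"),
                               header = TRUE) {
  k <- length(axis_order)
  con <- file(path, "w")
  on.exit(close(con))
  if (header) {
    wcols <- paste(sprintf("%9s", paste0("w", seq_len(k))), collapse = "")
    hdr <- paste0(sprintf("%-18s", "Assignment"), wcols,
                  if (k == 4L) sprintf("%15s", "Height") else "")
    writeLines(hdr, con)
  }
  for (i in seq_len(nrow(peaks))) {
    shifts <- vapply(axis_order, function(a) peaks[[a]][i], numeric(1))
    line <- paste0(sprintf("%-18s", peaks$label[i]),
                   paste(sprintf("%9.3f", shifts), collapse = ""),
                   if (k == 4L) sprintf("%15.6g", peaks$intensity[i]) else "")
    writeLines(line, con)
  }
  invisible(path)
}

#' Read a single-record FASTA protein sequence
#'
#' @param path Path to a FASTA file holding exactly one record.
#' @return Character vector of one-letter residue codes (uppercased), with
#'   the record id as attribute `"id"`.
#' @export
read_fasta_sequence <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  if (length(set) > 1L) stop("expected a single FASTA record, found ",
                             length(set))
  res <- strsplit(toupper(as.character(set[[1L]])), "")[[1L]]
  bad <- setdiff(unique(res), standard_aa())
  if (length(bad))
    stop("illegal residue letter(s) in FASTA: ", paste(bad, collapse = ", "))
  if (length(res) < 2L) stop("sequence must have at least 2 residues")
  structure(res, id = names(set)[1L])
}

#' Write a protein sequence as FASTA
#' @param residues Character vector of one-letter codes.
#' @param path Output path.
#' @param id Record identifier.
#' @export
write_fasta_sequence <- function(residues, path, id = "protein") {
  set <- Biostrings::AAStringSet(paste(residues, collapse = ""))
  names(set) <- id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# canonical ordering of atom names inside one residue for output tables
.ATOM_ORDER <- c("N", "H", "CA", "HA", "HA2", "HA3", "CB", "HB", "HB2", "HB3",
                 "CG", "CG1", "CG2", "HG", "HG1", "HG2", "HG3", "HG12", "HG13",
                 "CD", "CD1", "CD2", "HD", "HD1", "HD2", "HD3",
                 "CE", "HE", "HE2", "HE3")

atom_rank <- function(atom) {
  r <- match(atom, .ATOM_ORDER)
  r[is.na(r)] <- length(.ATOM_ORDER) + 1L
  r
}

#' Write an assignment table as an XEASY .prot shift list
#'
#' One line per assigned nucleus: index, shift value, error column, atom
#' name, residue number; ordered deterministically by residue and canonical
#' atom name.
#'
#' @param table Assignment table: data frame with columns `residue`, `atom`,
#'   `shift` (and optionally `nucleus`, `provenance`, `score`).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_xeasy_shifts <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (is.null(table) || nrow(table) == 0L) return(invisible(path))
  key <- paste(table$residue, table$atom)
  if (anyDuplicated(key))
    stop("duplicate (residue, atom) in assignment table: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  ord <- order(table$residue, atom_rank(table$atom), table$atom)
  table <- table[ord, ]
  for (i in seq_len(nrow(table))) {
    writeLines(sprintf("%4d %8.3f %6.3f %-5s %4d",
                       i, table$shift[i], 0, table$atom[i],
                       as.integer(table$residue[i])), con)
  }
  invisible(path)
}

#' Read an XEASY .prot shift list
#' @param path Path to the file.
#' @return Data frame with columns `residue`, `atom`, `shift`.
#' @export
read_xeasy_shifts <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(residue = integer(), atom = character(),
                      shift = numeric(), stringsAsFactors = FALSE))
  rows <- lapply(seq_along(lines), function(i) {
    tok <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (length(tok) != 5L)
      stop(sprintf("parse error in %s line %d: expected 5 columns", path, i))
    data.frame(residue = as.integer(tok[5L]), atom = tok[4L],
               shift = as.numeric(tok[2L]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Format / parse assignment labels on annotated peak lists
#'
#' The annotated Sparky lists written by [write_assigned_peaklists()] use the
#' label grammar `<aa><residue>:<carbon>-<proton>`, e.g. `A15:CB-HB2`;
#' unassigned peaks keep the label `?`.
#'
#' @param aa,residue,atom_c,atom_h Assignment components (vectorized).
#' @return `format_assignment_label`: character vector of labels.
#' @export
format_assignment_label <- function(aa, residue, atom_c, atom_h) {
  sprintf("%s%d:%s-%s", aa, as.integer(residue), atom_c, atom_h)
}

#' @rdname format_assignment_label
#' @param label Label string to parse.
#' @return `parse_assignment_label`: list with `aa`, `residue`, `atom_c`,
#'   `atom_h` (or `NULL` for `?`).
#' @export
parse_assignment_label <- function(label) {
  if (label == "?") return(NULL)
  m <- regmatches(label,
                  regexec("^([A-Z])([0-9]+):([A-Z0-9]+)-([A-Z0-9]+)$", label))[[1L]]
  if (length(m) != 5L) stop("unparseable assignment label: ", label)
  list(aa = m[2L], residue = as.integer(m[3L]), atom_c = m[4L],
       atom_h = m[5L])
}

#' Write annotated (assigned) Sparky peak lists
#'
#' Rewrites the label column of a peak list with the assignments found by the
#' pipeline, for visual verification; unassigned peaks keep `?`.
#'
#' @param peaks 4D peak data frame.
#' @param annotations Data frame with columns `peak_row`, `residue`, `aa`,
#'   `atom_c`, `atom_h` (as produced by [transfer_to_noesy()]).
#' @param path Output path.
#' @param axis_order Column order to write.
#' @export
write_assigned_peaklists <- function(peaks, annotations, path,
                                     axis_order = c("h", "c", "n15", "hn")) {
  labels <- rep("?", nrow(peaks))
  if (!is.null(annotations) && nrow(annotations)) {
    labels[annotations$peak_row] <-
      format_assignment_label(annotations$aa, annotations$residue,
                              annotations$atom_c, annotations$atom_h)
  }
  out <- peaks
  out$label <- labels
  write_sparky_peaks(out, path, axis_order = axis_order)
}
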