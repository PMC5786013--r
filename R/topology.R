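#' @name topology
#' @title Aliphatic CH topology of the 20 standard amino acids
#'
#' @description
#' Every operation in the package that reasons about atom types consults a
#' single topology table listing, per amino acid, its aliphatic carbons
#' carrying at least one proton, the pair label used to key the chemical-shift
#' statistics (`"CA-HA"`, `"CG2-HG2"`, ...), the moiety class (`CH` methine,
#' `CH2` methylene, `CH3` methyl) and the individual proton names.  Aromatic
#' ring CH, sidechain amide and exchangeable protons lie outside the
#' aliphatic 13C-edited spectral region and are not modelled.
#'
#' A methylene contributes up to two cross-peaks (one per proton) that share
#' one carbon frequency; a methyl contributes a single (three-fold degenerate)
#' cross-peak.
NULL

.aa_row <- function(carbon, atom_type, group, protons) {
  data.frame(carbon = carbon, atom_type = atom_type, group = group,
             protons = protons, stringsAsFactors = FALSE)
}

.build_topology <- function() {
  ch  <- function(cb, at, h) .aa_row(cb, at, "CH", h)
  ch2 <- function(cb, at, h) .aa_row(cb, at, "CH2", h)
  ch3 <- function(cb, at, h) .aa_row(cb, at, "CH3", h)
  list(
    A = rbind(ch("CA", "CA-HA", "HA"), ch3("CB", "CB-HB", "HB")),
    R = rbind(ch("CA", "CA-HA", "HA"), ch2("CB", "CB-HB", "HB2,HB3"),
              ch2("CG", "CG-HG", "HG2,HG3"), ch2("CD", "CD-HD", "HD2,HD3")),
    N = rbind(ch("CA", "CA-HA", "HA"), ch2("CB", "CB-HB", "HB2,HB3")),
    D = rbind(ch("CA", "CA-HA", "HA"), ch2("CB", "CB-HB", "HB2,HB3")),
    C = rbind(ch("CA", "CA-HA", "HA"), ch2("CB", "CB-HB", "HB2,HB3")),
    Q = rbind(ch("CA", "CA-HA", "HA"), ch2("CB", "CB-HB", "HB2,HB3"),
              ch2("CG", "CG-HG", "HG2,HG3")),
    E = rbind(ch("CA", "CA-HA", "HA"), ch2("CB", "CB-HB", "HB2,HB3"),
              ch2("CG", "CG-HG", "HG2,HG3")),
    G = ch2("CA", "CA-HA", "HA2,HA3"),
    H = rbind(ch("CA", "CA-HA", "HA"), ch2("CB", "CB-HB", "HB2,HB3")),
    I = rbind(ch("CA", "CA-HA", "HA"), ch("CB", "CB-HB", "HB"),
              ch2("CG1", "CG1-HG1", "HG12,HG13"),
              ch3("CG2", "CG2-HG2", "HG2"), ch3("CD1", "CD1-HD1", "HD1")),
    L = rbind(ch("CA", "CA-HA", "HA"), ch2("CB", "CB-HB", "HB2,HB3"),
              ch("CG", "CG-HG", "HG"),
              ch3("CD1", "CD1-HD1", "HD1"), ch3("CD2", "CD2-HD2", "HD2")),
    K = rbind(ch("CA", "CA-HA", "HA"), ch2("CB", "CB-HB", "HB2,HB3"),
              ch2("CG", "CG-HG", "HG2,HG3"), ch2("CD", "CD-HD", "HD2,HD3"),
              ch2("CE", "CE-HE", "HE2,HE3")),
    M = rbind(ch("CA", "CA-HA", "HA"), ch2("CB", "CB-HB", "HB2,HB3"),
              ch2("CG", "CG-HG", "HG2,HG3"), ch3("CE", "CE-HE", "HE")),
    F = rbind(ch("CA", "CA-HA", "HA"), ch2("CB", "CB-HB", "HB2,HB3")),
    P = rbind(ch("CA", "CA-HA", "HA"), ch2("CB", "CB-HB", "HB2,HB3"),
              ch2("CG", "CG-HG", "HG2,HG3"), ch2("CD", "CD-HD", "HD2,HD3")),
    S = rbind(ch("CA", "CA-HA", "HA"), ch2("CB", "CB-HB", "HB2,HB3")),
    T = rbind(ch("CA", "CA-HA", "HA"), ch("CB", "CB-HB", "HB"),
              ch3("CG2", "CG2-HG2", "HG2")),
    W = rbind(ch("CA", "CA-HA", "HA"), ch2("CB", "CB-HB", "HB2,HB3")),
    Y = rbind(ch("CA", "CA-HA", "HA"), ch2("CB", "CB-HB", "HB2,HB3")),
    V = rbind(ch("CA", "CA-HA", "HA"), ch("CB", "CB-HB", "HB"),
              ch3("CG1", "CG1-HG1", "HG1"), ch3("CG2", "CG2-HG2", "HG2"))
  )
}

.AA_TOPOLOGY <- .build_topology()

#' One-letter codes of the 20 standard amino acids
#' @return Character vector of length 20.
#' @export
standard_aa <- function() names(.AA_TOPOLOGY)

#' Aliphatic CH topology for one amino acid
#'
#' @param aa One-letter amino-acid code.
#' @return A data frame with columns `carbon`, `atom_type` (the pair label
#'   keying the statistics library), `group` (`CH`/`CH2`/`CH3`) and `protons`
#'   (comma-separated proton names).
#' @export
aa_topology <- function(aa) {
  top <- .AA_TOPOLOGY[[aa]]
  if (is.null(top)) stop("unknown amino acid code: ", aa)
  top
}

#' Proton names attached to one carbon of an amino acid
#' @param aa One-letter code.
#' @param carbon Carbon name, e.g. `"CB"`.
#' @return Character vector of proton names (length 1 or 2).
#' @export
proton_names <- function(aa, carbon) {
  top <- aa_topology(aa)
  row <- top[top$carbon == carbon, ]
  if (nrow(row) != 1L) stop("carbon ", carbon, " not in topology of ", aa)
  strsplit(row$protons, ",", fixed = TRUE)[[1L]]
}

#' Cross-peak capacity of an amino acid
#'
#' The maximum number of distinct aliphatic 13C-1H cross-peaks an amino acid
#' can give rise to: one per methine or methyl, two per methylene.  A spin
#' system holding more CH pairs than an amino acid's capacity cannot belong to
#' that type.
#' @param aa One-letter code.
#' @return Integer capacity.
#' @export
atom_capacity <- function(aa) {
  top <- aa_topology(aa)
  sum(ifelse(top$group == "CH2", 2L, 1L))
}

# internal: key used throughout for (amino acid, atom type) map lookup
stats_key <- function(aa, atom_type) paste(aa, atom_type, sep = "|")

# internal: carbon name for a proton name (e.g. "HB2" of Lys -> "CB")
carbon_of_proton <- function(aa, proton) {
  top <- aa_topology(aa)
  for (i in seq_len(nrow(top))) {
    if (proton %in% strsplit(top$protons[i], ",", fixed = TRUE)[[1L]])
      return(top$carbon[i])
  }
  NA_character_
}

# internal: stereo/enantiotopic equivalence classes used by the evaluator
# (assignments are not stereo-specific, so swapped prochiral methyls count
#  as correct)
equivalent_carbons <- function(aa, carbon) {
  eq <- switch(aa,
    V = list(CG1 = c("CG1", "CG2"), CG2 = c("CG1", "CG2")),
    L = list(CD1 = c("CD1", "CD2"), CD2 = c("CD1", "CD2")),
    NULL)
  if (!is.null(eq) && carbon %in% names(eq)) eq[[carbon]] else carbon
}
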