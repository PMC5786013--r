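# Brute-force oracles shared by the unit and acceptance suites.

# brute-force path enumeration oracle over a connectivity data frame
path_oracle <- function(conn, L_min, L_max) {
  verts <- unique(c(conn$noesy_aaig, conn$tocsy_aaig))
  succ <- lapply(verts, function(v) conn$tocsy_aaig[conn$noesy_aaig == v])
  names(succ) <- verts
  paths <- character(0)
  rec <- function(path) {
    if (length(path) >= L_min && length(path) <= L_max)
      paths <<- c(paths, paste(path, collapse = ">"))
    if (length(path) == L_max) return()
    for (nxt in succ[[path[length(path)]]])
      if (!nxt %in% path) rec(c(path, nxt))
  }
  for (v in verts) rec(v)
  sort(paths)
}

# brute-force contig oracle: grow every chain forwards until no extension,
# starting only from chains that extend nothing
contig_oracle <- function(chains, L) {
  key <- vapply(chains, function(ch)
    paste(ch$pos1, paste(ch$aaigs, collapse = ","), sep = "|"), character(1))
  chains <- chains[!duplicated(key)]
  extends <- function(a, b)   # b follows a
    b$pos1 == a$pos1 + 1L &&
      identical(a$aaigs[-1L], b$aaigs[-length(b$aaigs)])
  out <- character(0)
  grow <- function(aaigs, pos1, last_chain) {
    ext <- Filter(function(b) extends(last_chain, b) &&
                    !(b$aaigs[L] %in% aaigs), chains)
    if (!length(ext)) {
      if (length(aaigs) > L)
        out <<- c(out, paste(pos1, paste(aaigs, collapse = ","), sep = "|"))
      return()
    }
    for (b in ext)
      grow(c(aaigs, b$aaigs[L]), pos1, b)
  }
  for (ch in chains) {
    has_pred <- any(vapply(chains, function(a) extends(a, ch), logical(1)))
    if (!has_pred) grow(ch$aaigs, ch$pos1, ch)
  }
  sort(unique(out))
}

conn_df <- function(from, to, occ = 1) {
  data.frame(tocsy_aaig = to, noesy_aaig = from, matched = 1L, total = 1L,
             occupancy = occ, stringsAsFactors = FALSE)
}

# enumeration oracle: best ungapped placement score
placement_oracle <- function(pep, seqv, sub) {
  L <- length(pep); n <- length(seqv)
  best <- -Inf
  for (s in seq_len(n - L + 1L))
    best <- max(best, sum(sub[cbind(pep, seqv[s:(s + L - 1L)])]))
  best
}
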