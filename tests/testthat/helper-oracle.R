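# Independent brute-force oracle for restriction-site scanning: expand the
# degenerate pattern to concrete strings by hand and substring-scan both
# strands. Deliberately shares no code with the package's matching engine.

oracle_expand <- function(site) {
  sets <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T")
  )
  out <- ""
  for (ch in strsplit(site, "", fixed = TRUE)[[1]]) {
    out <- as.vector(vapply(out, function(pre) paste0(pre, sets[[ch]]),
                            character(length(sets[[ch]]))))
  }
  out
}

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x),
                     "", fixed = TRUE)[[1]]), collapse = "")
}

# all hits of one enzyme on a concrete sequence, mirroring the scanner's
# output contract (0-based coords, palindrome dedup, cut bounds check)
oracle_scan <- function(sequence, site, cut_top, cut_bottom) {
  slen <- nchar(sequence)
  L <- nchar(site)
  starts_of <- function(pats) {
    if (L > slen) return(integer(0))
    subs <- substring(sequence, 1:(slen - L + 1L), L:slen)
    which(subs %in% pats) - 1L
  }
  s_starts <- starts_of(oracle_expand(site))
  rc_site <- oracle_revcomp(site)
  rc_ct <- L - cut_bottom
  rc_cb <- L - cut_top
  a_starts <- starts_of(oracle_expand(rc_site))
  sense <- data.frame(strand = rep("sense", length(s_starts)),
                      match_start = s_starts,
                      cut_top = s_starts + cut_top,
                      cut_bottom = s_starts + cut_bottom)
  anti <- data.frame(strand = rep("antisense", length(a_starts)),
                     match_start = a_starts,
                     cut_top = a_starts + rc_ct,
                     cut_bottom = a_starts + rc_cb)
  key <- function(d) paste(d$match_start, d$cut_top, d$cut_bottom)
  anti <- anti[!(key(anti) %in% key(sense)), ]
  h <- rbind(sense, anti)
  h <- h[h$cut_top >= 0 & h$cut_top <= slen &
           h$cut_bottom >= 0 & h$cut_bottom <= slen, ]
  h <- h[order(h$match_start, h$strand), ]
  rownames(h) <- NULL
  h
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

ecoRI <- function() read_enzyme_table("EcoRI\tG^AATTC\tN\t62")
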