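# Independent quadratic brute-force oracle for the longest shared
# substring: enumerate substrings of `a` from longest to shortest and look
# each up in `b` with fixed-string matching. Only used to verify the
# package's DP engine on small inputs.
bruteLCS <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  for (len in seq.int(min(nchar(a), nchar(b)), 1L)) {
    for (i in seq_len(nchar(a) - len + 1L)) {
      sub <- substr(a, i, i + len - 1L)
      j <- regexpr(sub, b, fixed = TRUE)
      if (j > 0L)
        return(list(length = len, startA = i, startB = as.integer(j)))
    }
  }
  list(length = 0L, startA = 0L, startB = 0L)
}

randomSeq <- function(len)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")

# plain-string reverse complement, independent of Biostrings
rcChar <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}
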