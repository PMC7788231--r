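# Independent brute-force exhaustive-history parser: a phrase starting at p
# is extended while s[p..q] occurs as a substring of s[1..q-1] (any such
# occurrence necessarily starts before p); the first non-reproducible
# extension closes the word. A trailing reproducible phrase counts as one
# word. O(L^2) via plain substring search.
lzOracle <- function(s) {
  str <- paste(s, collapse = "")
  n <- nchar(str)
  stopifnot(n >= 1)
  cnt <- 0L
  p <- 1L
  while (p <= n) {
    len <- 1L
    repeat {
      q <- p + len - 1L
      if (q > n) {                       # ran off the end while reproducible
        cnt <- cnt + 1L
        return(cnt)
      }
      word <- substr(str, p, q)
      hist <- substr(str, 1L, q - 1L)
      if (q == 1L || !grepl(word, hist, fixed = TRUE)) {
        cnt <- cnt + 1L                  # word = reproducible part + 1 symbol
        p <- q + 1L
        break
      }
      len <- len + 1L
    }
  }
  cnt
}
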