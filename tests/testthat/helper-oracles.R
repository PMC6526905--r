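## Independent oracles used by the tests. These deliberately share no code
## with the package implementation.

## Brute-force affine-gap glocal DP: pattern global, subject local (free
## subject prefix/suffix), gap of length L costs open + L * extend, only
## identical A/C/G/T letters match. Returns the optimal score.
dp_glocal_score <- function(pattern, subject, match = 2, mismatch = -3,
                            open = 5, extend = 2) {
  p <- strsplit(toupper(pattern), "")[[1]]
  s <- strsplit(toupper(subject), "")[[1]]
  n <- length(p); m <- length(s)
  NEG <- -1e9
  ## state matrices over subject positions 0..m for the current pattern row
  Mrow <- c(rep(0, m + 1))          # i = 0: empty pattern, free prefix
  Drow <- rep(NEG, m + 1)
  Irow <- rep(NEG, m + 1)
  for (i in seq_len(n)) {
    Mnew <- rep(NEG, m + 1)
    Dnew <- rep(NEG, m + 1)
    Inew <- rep(NEG, m + 1)
    Dnew[1] <- max(Mrow[1] - open - extend, Drow[1] - extend,
                   Irow[1] - open - extend)
    for (j in seq_len(m)) {
      sc <- if (p[i] == s[j] && p[i] %in% c("A", "C", "G", "T"))
        match else mismatch
      Mnew[j + 1] <- sc + max(Mrow[j], Drow[j], Irow[j])
      Dnew[j + 1] <- max(Mrow[j + 1] - open - extend,
                         Drow[j + 1] - extend,
                         Irow[j + 1] - open - extend)
      Inew[j + 1] <- max(Mnew[j] - open - extend,
                         Inew[j] - extend,
                         Dnew[j] - open - extend)
    }
    Mrow <- Mnew; Drow <- Dnew; Irow <- Inew
  }
  max(Mrow, Drow)  # free subject suffix; trailing pattern-gaps via Drow
}

## Exhaustive left-alignment oracle: enumerate every placement of an indel
## that reproduces the same mutant sequence and return the smallest 0-based
## position (with its allele).
enumerate_leftmost <- function(ref, type, pos, allele) {
  apply_indel <- function(p, a) {
    if (type == "deletion") {
      if (substr(ref, p + 1, p + nchar(a)) != a) return(NULL)
      paste0(substr(ref, 1, p), substr(ref, p + nchar(a) + 1, nchar(ref)))
    } else {
      paste0(substr(ref, 1, p), a, substr(ref, p + 1, nchar(ref)))
    }
  }
  target <- apply_indel(pos, allele)
  len <- nchar(allele)
  best <- NULL
  for (p in 0:(nchar(ref) - if (type == "deletion") len else 0)) {
    if (type == "deletion") {
      a <- substr(ref, p + 1, p + len)
      cand <- apply_indel(p, a)
      if (!is.null(cand) && cand == target) { best <- list(pos = p, allele = a); break }
    } else {
      ## try all alleles that could be inserted at p to give the target
      a <- substr(target, p + 1, p + len)
      cand <- apply_indel(p, a)
      if (cand == target) { best <- list(pos = p, allele = a); break }
    }
  }
  best
}

## Direct codon-scan translation oracle: 0-based CDS coordinate of the first
## stop codon in frame 0, or NA.
first_stop_coord <- function(cds) {
  stops <- c("TAA", "TAG", "TGA")
  for (j in seq_len(nchar(cds) %/% 3)) {
    if (substr(cds, 3 * j - 2, 3 * j) %in% stops) return(3L * (j - 1L))
  }
  NA_integer_
}

random_seq <- function(n) paste0(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")
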