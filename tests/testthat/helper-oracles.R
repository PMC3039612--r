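# Independent oracles shared across test files.

# Brute-force affine-gap alignment score by exhaustive enumeration of all
# alignments (a gap of length L costs open + (L-1)*extend, as in the DP).
brute_force_score <- function(a, b, S, go, ge) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, state) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb))
      rec(i + 1, j + 1, score + S[ca[i], cb[j]], 0)
    if (j <= length(cb)) rec(i, j + 1, score - (if (state == 1) ge else go), 1)
    if (i <= length(ca)) rec(i + 1, j, score - (if (state == 2) ge else go), 2)
  }
  rec(1, 1, 0, 0)
  best
}

# Small 3-letter substitution matrix extended to the accepted alphabet.
toy_matrix <- function() {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y", "X")
  S <- matrix(-2, 21, 21, dimnames = list(aa, aa))
  S["A", "A"] <- 4; S["R", "R"] <- 5; S["N", "N"] <- 6
  S["A", "R"] <- S["R", "A"] <- -1
  S["A", "N"] <- S["N", "A"] <- -2
  S["R", "N"] <- S["N", "R"] <- 0
  S
}

rand_arn <- function(len) paste(sample(c("A", "R", "N"), len, replace = TRUE),
                                collapse = "")
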