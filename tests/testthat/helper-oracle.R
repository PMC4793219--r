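# Independent alignment oracle, written directly from the alignment model:
# plain R dynamic programs (forward "ending at", backward "starting at")
# composed explicitly for the one-intron spliced mode.  Used to verify the
# compiled aligner; shares no code with it.

# Best local alignment score ending exactly at (i, j), Gotoh affine gaps.
# Returns list(H, E, F) matrices (n+1) x (m+1); H clamped at 0.
oracle_end_matrices <- function(q, r, match = 1, mismatch = -1,
                                open = -2, ext = -1) {
  qc <- strsplit(q, "")[[1]]; rc <- strsplit(r, "")[[1]]
  n <- length(qc); m <- length(rc)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    E[i + 1, j + 1] <- max(H[i + 1, j] + open, E[i + 1, j] + ext)
    F[i + 1, j + 1] <- max(H[i, j + 1] + open, F[i, j + 1] + ext)
    s <- if (qc[i] == rc[j]) match else mismatch
    H[i + 1, j + 1] <- max(0, H[i, j] + s, E[i + 1, j + 1], F[i + 1, j + 1])
  }
  list(H = H, E = E, F = F)
}

# Best local alignment score starting exactly at (i, j): backward DP.
oracle_start_matrix <- function(q, r, match = 1, mismatch = -1,
                                open = -2, ext = -1) {
  qc <- strsplit(q, "")[[1]]; rc <- strsplit(r, "")[[1]]
  n <- length(qc); m <- length(rc)
  H <- matrix(0, n + 2, m + 2)   # H[i, j]: best starting at (i, j)
  E <- matrix(-Inf, n + 2, m + 2)
  F <- matrix(-Inf, n + 2, m + 2)
  for (i in n:1) for (j in m:1) {
    E[i, j] <- max(H[i, j + 1] + open, E[i, j + 1] + ext)
    F[i, j] <- max(H[i + 1, j] + open, F[i + 1, j] + ext)
    s <- if (qc[i] == rc[j]) match else mismatch
    H[i, j] <- max(0, H[i + 1, j + 1] + s, E[i, j], F[i, j])
  }
  H
}

# Best scores under the three modes (ungapped / gapped / one-intron
# spliced); spliced requires both pieces positive and an intron length in
# [min_intron, max_intron].
oracle_align <- function(q, r, match = 1, mismatch = -1, open = -2,
                         ext = -1, intron = -3, min_intron = 20,
                         max_intron = 50000) {
  qc <- strsplit(q, "")[[1]]; rc <- strsplit(r, "")[[1]]
  n <- length(qc); m <- length(rc)
  # ungapped: best diagonal run
  U <- matrix(0, n + 1, m + 1)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (qc[i] == rc[j]) match else mismatch
    U[i + 1, j + 1] <- max(0, U[i, j] + s)
  }
  fwd <- oracle_end_matrices(q, r, match, mismatch, open, ext)
  bwd <- oracle_start_matrix(q, r, match, mismatch, open, ext)
  spliced <- 0
  if (n >= 2 && m >= min_intron + 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq_len(m)) {
        a <- fwd$H[i + 1, j + 1]
        if (a <= 0) next
        ks <- seq_len(m)
        ks <- ks[ks - j - 1 >= min_intron & ks - j - 1 <= max_intron]
        if (length(ks) == 0) next
        b <- max(bwd[i + 1, ks])
        if (b > 0) spliced <- max(spliced, a + b + intron)
      }
    }
  }
  list(ungapped = max(U), gapped = max(fwd$H), spliced = spliced,
       best = max(max(U), max(fwd$H), spliced))
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
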