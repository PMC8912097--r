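# Independent oracles, written as plain double loops against the defining
# formulas so they share no code path with the package implementation.

`%||%` <- function(a, b) if (is.null(a)) b else a

oracle_alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                     "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

oracle_scales <- function() {
  raw <- list(
    c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
      I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
      R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3),
    c(A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5, G = 0.0, H = -0.5,
      I = -1.8, K = 3.0, L = -1.8, M = -1.3, N = 0.2, P = 0.0, Q = 0.2,
      R = 3.0, S = 0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3),
    c(A = 15, C = 47, D = 59, E = 73, F = 91, G = 1, H = 82, I = 57,
      K = 73, L = 57, M = 75, N = 58, P = 42, Q = 72, R = 101, S = 31,
      T = 45, V = 43, W = 130, Y = 107))
  lapply(raw, function(s) {
    s <- s[oracle_alphabet]
    (s - mean(s)) / sqrt(mean((s - mean(s))^2))
  })
}

# Naive double-loop pseudo amino acid composition.
oracle_paac <- function(seq, lam = 10, w = 0.05) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  scales <- oracle_scales()
  f <- numeric(20)
  for (ch in chars) f[match(ch, oracle_alphabet)] <-
    f[match(ch, oracle_alphabet)] + 1
  f <- f / L
  tau <- numeric(lam)
  if (lam > 0) {
    for (k in 1:lam) {
      acc <- 0
      for (i in 1:(L - k)) {
        j <- 0
        for (q in 1:3)
          j <- j + (scales[[q]][[chars[i + k]]] - scales[[q]][[chars[i]]])^2
        acc <- acc + j / 3
      }
      tau[k] <- acc / (L - k)
    }
  }
  denom <- sum(f) + w * sum(tau)
  c(f / denom, w * tau / denom)
}

# AUC as the pairwise comparison probability (Mann-Whitney), ties at 0.5.
oracle_auc <- function(scores, truth) {
  sp <- scores[truth == 1]; sn <- scores[truth == 0]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Average precision by an explicit threshold sweep over unique scores.
oracle_ap <- function(scores, truth) {
  ths <- sort(unique(scores), decreasing = TRUE)
  ap <- 0; prev_rec <- 0
  npos <- sum(truth == 1)
  for (th in ths) {
    pred <- as.integer(scores >= th)
    tp <- sum(pred == 1 & truth == 1)
    rec <- tp / npos
    prec <- tp / sum(pred == 1)
    ap <- ap + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  ap
}

# Random valid peptide, length in [lmin, lmax].
random_peptide <- function(lmin = 11, lmax = 40) {
  paste(sample(oracle_alphabet, sample(lmin:lmax, 1), replace = TRUE),
        collapse = "")
}

tmp_fasta <- function(ids, seqs) {
  path <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", ids, "\n", seqs), path)
  path
}

# Small, fast training configuration used across network tests.
fast_config <- function(mode = "MS", seed = 7, ...) {
  acpnet_config(mode = mode, max_epochs = 15, patience = 5, seed = seed, ...)
}
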