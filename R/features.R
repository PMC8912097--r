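#' Pseudo amino acid composition parameters
#'
#' Bundles the PAAC tuning parameters: the number of sequence-order
#' correlation tiers `lam` (lambda), the weight `w` given to the correlation
#' part relative to plain composition, and the three per-residue property
#' scales (hydrophobicity, hydrophilicity, side-chain mass) used to measure
#' how different two residues are. Scales are standardized to mean 0 /
#' population SD 1 across the 20 residues unless `normalize = FALSE`.
#'
#' @param lam integer >= 0, number of correlation tiers; default 10. Every
#'   sequence fed to [paac()] must be longer than `lam`.
#' @param w correlation weight factor; default 0.05.
#' @param scales list of three named 20-value numeric vectors.
#' @param normalize standardize each scale (default TRUE).
#' @return object of class `paac_params`.
#' @export
paac_params <- function(lam = 10L, w = 0.05,
                        scales = list(hydrophobicity = KYTE_DOOLITTLE,
                                      hydrophilicity = HOPP_WOODS,
                                      side_chain_mass = SIDE_CHAIN_MASS),
                        normalize = TRUE) {
  stopifnot(lam >= 0L, w >= 0, length(scales) >= 1L)
  scales <- if (normalize) lapply(scales, normalize_scale)
            else lapply(scales, function(s) s[AA_ALPHABET])
  structure(list(lam = as.integer(lam), w = w, scales = scales,
                 normalized = normalize),
            class = "paac_params")
}

seq_chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1L]]

#' Amino-acid frequencies
#'
#' @param seq canonical sequence.
#' @return numeric vector of 20 frequencies in alphabet order (A..Y), summing
#'   to 1.
#' @export
aa_frequencies <- function(seq) {
  chars <- seq_chars(validate_sequence(seq))
  tab <- table(factor(chars, levels = AA_ALPHABET))
  f <- as.numeric(tab) / length(chars)
  names(f) <- AA_ALPHABET
  f
}

#' Sequence-order coupling between two residues
#'
#' Mean squared difference of the standardized property values of the two
#' residues over the property scales: symmetric, non-negative, zero for
#' identical residues.
#'
#' @param ri,rj single residue letters.
#' @param scales list of standardized property vectors (as stored in
#'   [paac_params()]).
#' @return non-negative real.
#' @export
coupling <- function(ri, rj, scales) {
  if (!ri %in% AA_ALPHABET) stop("unknown residue: ", ri)
  if (!rj %in% AA_ALPHABET) stop("unknown residue: ", rj)
  mean(vapply(scales, function(s) (s[[rj]] - s[[ri]])^2, numeric(1)))
}

## Vectorized pairwise coupling matrix J[ri, rj] for all residue pairs.
coupling_matrix <- function(scales) {
  J <- matrix(0, 20L, 20L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  for (s in scales) J <- J + outer(s, s, function(a, b) (b - a)^2)
  J / length(scales)
}

#' k-th tier sequence-order correlation factor
#'
#' Average coupling between residues k positions apart.
#'
#' @param seq canonical sequence.
#' @param k tier, 1 <= k < length(seq).
#' @param scales standardized property scales.
#' @return non-negative real.
#' @export
tier_correlation <- function(seq, k, scales) {
  chars <- seq_chars(validate_sequence(seq))
  L <- length(chars)
  if (k < 1L || k >= L) stop("tier k must satisfy 1 <= k < L (k=", k,
                             ", L=", L, ")")
  J <- coupling_matrix(scales)
  i <- seq_len(L - k)
  mean(J[cbind(chars[i], chars[i + k])])
}

#' Pseudo amino acid composition
#'
#' The 20 + lambda descriptor: the first 20 components are the amino-acid
#' frequencies and the last lambda components the tier correlation factors,
#' jointly normalized so the whole vector sums to 1:
#' `p_u = f_u / (1 + w * sum(tau))` for u <= 20 and
#' `p_u = w * tau_(u-20) / (1 + w * sum(tau))` above. With `lam = 0` the
#' result is exactly the plain composition.
#'
#' @param seq canonical sequence, longer than `params$lam`.
#' @param params a [paac_params()] object.
#' @return numeric vector of length `20 + lam`, named `paac1..paac(20+lam)`,
#'   non-negative, summing to 1.
#' @export
paac <- function(seq, params = paac_params()) {
  stopifnot(inherits(params, "paac_params"))
  seq <- validate_sequence(seq)
  L <- nchar(seq)
  lam <- params$lam
  if (L <= lam)
    stop(sprintf(
      "sequence length %d does not exceed lambda = %d; PAAC requires lambda < L",
      L, lam))
  f <- aa_frequencies(seq)
  tau <- if (lam > 0L)
    vapply(seq_len(lam), function(k) tier_correlation(seq, k, params$scales),
           numeric(1))
  else numeric(0)
  denom <- sum(f) + params$w * sum(tau)
  p <- c(f, params$w * tau) / denom
  names(p) <- paste0("paac", seq_along(p))
  p
}

#' Shannon entropy of the residue composition
#'
#' Natural-log entropy of the 20 amino-acid frequencies, with 0*log(0) = 0:
#' 0 for a homopolymer, log(20) for a sequence using all residues equally.
#'
#' @param seq canonical sequence.
#' @return real in [0, log(20)].
#' @export
shannon_entropy <- function(seq) {
  f <- aa_frequencies(seq)
  f <- f[f > 0]
  -sum(f * log(f))
}

#' GRAVY (grand average of hydropathy)
#'
#' Mean Kyte-Doolittle hydropathy over residues; positive values indicate
#' hydrophobic peptides.
#'
#' @param seq canonical sequence.
#' @return real.
#' @export
gravy <- function(seq) {
  mean(KYTE_DOOLITTLE[seq_chars(validate_sequence(seq))])
}

#' Peptide molecular weight
#'
#' Sum of average residue masses plus one water for the free termini.
#'
#' @param seq canonical sequence.
#' @return mass in Daltons.
#' @export
molecular_weight <- function(seq) {
  sum(RESIDUE_MASS_AVG[seq_chars(validate_sequence(seq))]) + WATER_MASS_AVG
}

#' Charge model parameters
#'
#' @param ph pH at which net charge is evaluated; default 10, the descriptor
#'   used by the classifier (cationic ACPs retain positive charge even at
#'   alkaline pH).
#' @param pka named vector of pKa values for the ionizable side chains
#'   (C, D, E, H, K, R, Y) and the `Nterm`/`Cterm` groups; defaults to
#'   EMBOSS-style values.
#' @return object of class `charge_params`.
#' @export
charge_params <- function(ph = 10, pka = PKA_EMBOSS) {
  needed <- c("Nterm", "Cterm", "C", "D", "E", "H", "K", "R", "Y")
  if (!all(needed %in% names(pka))) stop("pKa table incomplete")
  if (any(pka <= 0)) stop("pKa values must be positive")
  structure(list(ph = ph, pka = pka), class = "charge_params")
}

#' Net peptide charge at a given pH
#'
#' Henderson-Hasselbalch net charge: each basic group (N-terminus, K, R, H)
#' contributes `+1/(1+10^(pH-pKa))` and each acidic group (C-terminus, D, E,
#' C, Y) contributes `-1/(1+10^(pKa-pH))`. Strictly decreasing in pH.
#'
#' @param seq canonical sequence.
#' @param params a [charge_params()] object (default: pH 10, EMBOSS pKa).
#' @return net charge in elementary charge units.
#' @export
charge_at_ph <- function(seq, params = charge_params()) {
  stopifnot(inherits(params, "charge_params"))
  chars <- seq_chars(validate_sequence(seq))
  ph <- params$ph; pka <- params$pka
  basic_frac <- function(pk) 1 / (1 + 10^(ph - pk))
  acid_frac <- function(pk) 1 / (1 + 10^(pk - ph))
  counts <- table(factor(chars, levels = AA_ALPHABET))
  pos <- basic_frac(pka[["Nterm"]]) +
    counts[["K"]] * basic_frac(pka[["K"]]) +
    counts[["R"]] * basic_frac(pka[["R"]]) +
    counts[["H"]] * basic_frac(pka[["H"]])
  neg <- acid_frac(pka[["Cterm"]]) +
    counts[["D"]] * acid_frac(pka[["D"]]) +
    counts[["E"]] * acid_frac(pka[["E"]]) +
    counts[["C"]] * acid_frac(pka[["C"]]) +
    counts[["Y"]] * acid_frac(pka[["Y"]])
  pos - neg
}

#' The 35-dimensional manual feature vector
#'
#' Fixed, documented order: PAAC components 1..(20+lam) (30 with the default
#' lambda 10), then length, Shannon entropy, GRAVY, molecular weight, and net
#' charge at the configured pH (10 by default).
#'
#' @param seq canonical sequence longer than `paac_pars$lam`.
#' @param paac_pars [paac_params()] object.
#' @param charge_pars [charge_params()] object.
#' @return named numeric vector of length `20 + lam + 5`.
#' @export
manual_features <- function(seq, paac_pars = paac_params(),
                            charge_pars = charge_params()) {
  seq <- validate_sequence(seq)
  c(paac(seq, paac_pars),
    length = nchar(seq),
    shannon = shannon_entropy(seq),
    gravy = gravy(seq),
    mol_weight = molecular_weight(seq),
    charge = charge_at_ph(seq, charge_pars))
}

#' Integer index encoding of a sequence
#'
#' Maps residues to integers by alphabet position (A=1, C=2, ..., Y=20) and
#' post-pads with 0 (a reserved index that is masked from the recurrent
#' branch) to a fixed length. Sequences longer than `max_len` are truncated
#' with a warning.
#'
#' @param seq canonical sequence.
#' @param max_len fixed encoded length, >= 1.
#' @return list with `indices` (integer vector of length `max_len`) and
#'   `true_length` (encoded residue count).
#' @export
index_encode <- function(seq, max_len) {
  stopifnot(max_len >= 1L)
  chars <- seq_chars(validate_sequence(seq))
  idx <- match(chars, AA_ALPHABET)
  if (length(idx) > max_len) {
    warning(sprintf("sequence of length %d truncated to max_len = %d",
                    length(idx), max_len))
    idx <- idx[seq_len(max_len)]
  }
  list(indices = as.integer(c(idx, rep(0L, max_len - length(idx)))),
       true_length = length(idx))
}

#' Decode an index encoding back to a sequence
#'
#' @param indices integer vector with values in 0..20; trailing zeros are
#'   padding.
#' @return character sequence.
#' @export
decode_indices <- function(indices) {
  indices <- indices[indices != 0L]
  paste(AA_ALPHABET[indices], collapse = "")
}

#' Featurize a whole dataset
#'
#' Computes the manual feature matrix and the padded index-encoding matrix
#' for every peptide, preserving dataset order.
#'
#' @param dataset a `peptide_set`.
#' @param paac_pars,charge_pars feature parameters.
#' @param max_len encoded length; default the longest sequence in `dataset`.
#' @return list with `manual` (N x (25+lam) matrix, named columns), `encoded`
#'   (N x max_len integer matrix), `lengths`, `labels`, `ids`, `max_len`.
#' @export
featurize_dataset <- function(dataset, paac_pars = paac_params(),
                              charge_pars = charge_params(),
                              max_len = NULL) {
  stopifnot(inherits(dataset, "peptide_set"))
  if (nrow(dataset) == 0L) stop("empty dataset")
  if (is.null(max_len)) max_len <- max(nchar(dataset$seq))
  manual <- t(vapply(
    seq_len(nrow(dataset)),
    function(i) tryCatch(
      manual_features(dataset$seq[i], paac_pars, charge_pars),
      error = function(e) stop(sprintf("peptide '%s': %s", dataset$id[i],
                                       conditionMessage(e)), call. = FALSE)),
    numeric(20L + paac_pars$lam + 5L)))
  rownames(manual) <- dataset$id
  enc <- t(vapply(dataset$seq,
                  function(s) index_encode(s, max_len)$indices,
                  integer(max_len), USE.NAMES = FALSE))
  rownames(enc) <- dataset$id
  list(manual = manual, encoded = enc, lengths = nchar(dataset$seq),
       labels = dataset$label, ids = dataset$id, max_len = as.integer(max_len))
}
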