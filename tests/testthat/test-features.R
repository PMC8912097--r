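test_that("amino-acid frequencies are ordered, non-negative, sum to 1", {
  f <- aa_frequencies("ADGF")
  expect_equal(sum(f), 1)
  expect_equal(unname(f[c("A", "D", "F", "G")]), rep(0.25, 4))
  expect_equal(sum(f > 0), 4)
  expect_equal(unname(aa_frequencies("AAAA")[["A"]]), 1)
  expect_equal(unname(aa_frequencies(paste(acpnet:::AA_ALPHABET,
                                           collapse = ""))),
               rep(0.05, 20))
})

test_that("coupling is symmetric, zero on identical residues, matches hand math", {
  sc <- paac_params()$scales
  expect_equal(coupling("A", "A", sc), 0)
  expect_equal(coupling("A", "K", sc), coupling("K", "A", sc))
  expect_gt(coupling("A", "K", sc), 0)
  # hand evaluation from the standardized tables
  hand <- mean(sapply(oracle_scales(), function(s) (s[["W"]] - s[["G"]])^2))
  expect_equal(coupling("G", "W", sc), hand, tolerance = 1e-12)
  expect_error(coupling("X", "A", sc), "unknown residue")
})

test_that("tier correlation averages couplings at lag k", {
  sc <- paac_params()$scales
  expect_equal(tier_correlation("AAAAAA", 1, sc), 0)
  expect_equal(tier_correlation("AAAAAA", 3, sc), 0)
  expect_equal(tier_correlation("ADAD", 2, sc), 0)
  expect_equal(tier_correlation("ADGF", 1, sc),
               mean(c(coupling("A", "D", sc), coupling("D", "G", sc),
                      coupling("G", "F", sc))))
  expect_error(tier_correlation("ADGF", 4, sc), "k < L")
})

test_that("PAAC limits: lambda 0 is plain composition, homopolymer is one-hot", {
  s <- "KLWKKIEKLIKKLLTSIR"
  expect_equal(unname(paac(s, paac_params(lam = 0))),
               unname(aa_frequencies(s)))
  p <- paac("AAAAAAAAAAAA", paac_params(lam = 10))
  expect_equal(unname(p[1]), 1)  # A component
  expect_equal(unname(p[-1]), rep(0, 29))
  expect_error(paac("ADGF", paac_params(lam = 10)), "lambda < L")
})

test_that("PAAC components sum to 1 across random peptides and parameters", {
  set.seed(101)
  for (i in 1:100) {
    lam <- sample(0:10, 1)
    w <- runif(1, 0.01, 0.2)
    p <- paac(random_peptide(), paac_params(lam = lam, w = w))
    expect_length(p, 20 + lam)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("PAAC agrees with the naive double-loop oracle to 1e-10", {
  set.seed(202)
  for (i in 1:50) {
    s <- random_peptide()
    expect_equal(unname(paac(s, paac_params(lam = 10, w = 0.05))),
                 oracle_paac(s, lam = 10, w = 0.05), tolerance = 1e-10)
  }
  # fixture sequence, explicitly
  s <- "KLWKKIEKLIKKLLTSIR"
  expect_equal(unname(paac(s)), oracle_paac(s), tolerance = 1e-10)
})

test_that("Shannon entropy respects its bounds and known values", {
  expect_equal(shannon_entropy("AAAA"), 0)
  expect_equal(shannon_entropy("ADGF"), log(4))
  expect_equal(shannon_entropy(paste(acpnet:::AA_ALPHABET, collapse = "")),
               log(20))
  set.seed(5)
  for (i in 1:25) {
    h <- shannon_entropy(random_peptide())
    expect_gte(h, 0); expect_lte(h, log(20) + 1e-12)
  }
})

test_that("GRAVY is the mean Kyte-Doolittle hydropathy", {
  expect_equal(gravy("AA"), 1.8)
  expect_equal(gravy("KK"), -3.9)
  expect_equal(gravy("AILV"), (1.8 + 4.5 + 3.8 + 4.2) / 4)
  s <- "KLWKKIEKLIKKLLTSIR"
  perm <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(gravy(s), gravy(perm))
})

test_that("molecular weight sums residue masses plus one water", {
  expect_equal(molecular_weight("G"), 75.07, tolerance = 1e-2)
  expect_equal(molecular_weight("GG"), 132.12, tolerance = 1e-2)
  s1 <- "ADGF"; s2 <- "KLWK"
  expect_equal(molecular_weight(paste0(s1, s2)),
               molecular_weight(s1) + molecular_weight(s2) - 18.0153,
               tolerance = 1e-9)
  expect_equal(molecular_weight(s1),
               molecular_weight("FGDA"))  # permutation invariance
})

test_that("net charge follows Henderson-Hasselbalch and decreases with pH", {
  # polylysine nearly +5 at pH 1 (4 side chains + N-terminus)
  expect_equal(charge_at_ph("KKKK", charge_params(ph = 1)), 5,
               tolerance = 0.01)
  # glycylglycine at pH = N-terminal pKa: hand two-term computation
  ph <- 8.6
  hand <- 0.5 - 1 / (1 + 10^(3.6 - ph))
  expect_equal(charge_at_ph("GG", charge_params(ph = ph)), hand,
               tolerance = 1e-12)
  set.seed(9)
  for (i in 1:10) {
    s <- random_peptide()
    ch <- sapply(seq(2, 12, by = 0.5),
                 function(ph) charge_at_ph(s, charge_params(ph = ph)))
    expect_true(all(diff(ch) < 0))
  }
})

test_that("order sensitivity: tier correlation is not permutation invariant", {
  sc <- paac_params()$scales
  expect_false(isTRUE(all.equal(tier_correlation("AKAKWDWD", 1, sc),
                                tier_correlation("AAKKWWDD", 1, sc))))
})

test_that("manual feature vector is the documented 35-number concatenation", {
  s <- "KLWKKIEKLIKKLLTSIR"
  mf <- manual_features(s)
  expect_length(mf, 35)
  expect_equal(unname(mf[1:30]), unname(paac(s)))
  expect_equal(unname(mf[31]), nchar(s))
  expect_equal(unname(mf[32]), shannon_entropy(s))
  expect_equal(unname(mf[33]), gravy(s))
  expect_equal(unname(mf[34]), molecular_weight(s))
  expect_equal(unname(mf[35]), charge_at_ph(s))

  hp <- manual_features("AAAAAAAAAAAA")
  expect_equal(unname(hp[1]), 1)
  expect_equal(unname(hp["shannon"]), 0)
  expect_equal(unname(hp["gravy"]), 1.8)
  expect_equal(unname(hp["length"]), 12)
})

test_that("index encoding maps A=1..Y=20, pads with 0, round-trips", {
  enc <- index_encode("ADGF", 6)
  expect_identical(enc$indices, c(1L, 3L, 6L, 5L, 0L, 0L))
  expect_equal(enc$true_length, 4)
  expect_identical(index_encode("A", 1)$indices, 1L)
  set.seed(77)
  for (i in 1:20) {
    s <- random_peptide(5, 30)
    expect_identical(decode_indices(index_encode(s, 30)$indices), s)
  }
  expect_warning(tr <- index_encode("ADGFKL", 3), "truncated")
  expect_identical(decode_indices(tr$indices), "ADG")
})

test_that("featurize_dataset produces aligned matrices deterministically", {
  ds <- table6_dataset()
  ft <- featurize_dataset(ds, max_len = 50)
  expect_equal(dim(ft$manual), c(20, 35))
  expect_equal(dim(ft$encoded), c(20, 50))
  expect_identical(ft$labels, ds$label)
  expect_identical(rownames(ft$manual), ds$id)
  ft2 <- featurize_dataset(ds, max_len = 50)
  expect_identical(ft, ft2)
  short <- acpnet:::new_peptide_set("s", "ADGF", 1L)
  expect_error(featurize_dataset(short), "'s'")
})
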