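test_that("phase decomposition returns the three suffixes", {
  expect_equal(phase_subsequences("ACGTA"), c("ACGTA", "CGTA", "GTA"))
  expect_equal(phase_subsequences("AAA"), c("AAA", "AA", "A"))
  expect_error(phase_subsequences("AC"), "length >= 3")
})

test_that("k-mer vectors have the documented dimensions and frequencies", {
  lnc_seq <- random_dna(500, seed = 7)
  v <- kmer_vector(lnc_seq, kmer_ks("lncRNA"))
  expect_length(v, 340L)
  expect_length(kmer_vector(random_dna(22, seed = 8), kmer_ks("miRNA")), 84L)

  # homopolymer: all 1-mer mass on A
  expect_equal(unname(kmer_vector("AAAA", 1L)), c(1, 0, 0, 0))

  # "ACGT", k = 2: three windows AC, CG, GT, each 1/3 (enumerated by hand)
  v2 <- kmer_vector("ACGT", 2L)
  expect_equal(unname(v2[c("k2_AC", "k2_CG", "k2_GT")]), rep(1 / 3, 3))
  expect_equal(sum(v2), 1)
  expect_equal(sum(v2 > 0), 3L)

  expect_error(kmer_vector("ACG", 4L), "shorter than k")
})

test_that("each k-block sums to one for arbitrary sequences", {
  for (s in 1:5) {
    seq <- random_dna(sample(50:400, 1), seed = 100 + s)
    v <- kmer_vector(seq, 1:4)
    offsets <- c(0, cumsum(4^(1:3)))
    for (i in 1:4)
      expect_equal(sum(v[(offsets[i] + 1):(offsets[i] + 4^i)]), 1,
                   tolerance = 1e-9)
  }
})

test_that("CTD reproduces the worked toy example", {
  v <- ctd_vector(toy_ctd_seq)
  expect_length(v, 30L)
  expect_equal(unname(v[paste0("comp_", c("A", "T", "G", "C"))]),
               rep(0.25, 4))
  # transitions counted exhaustively from the sequence; note the A/T pair:
  # the adjacent {A,T} pairs are at positions 1-2, 2-3, 6-7, 17-18, so 4/19
  expect_equal(unname(v[paste0("trans_", c("AT", "AC", "AG", "TG", "TC", "GC"))]),
               c(4, 3, 2, 4, 2, 4) / 19)
  expect_equal(unname(v[grep("^dist_A", names(v))]),
               c(1, 3, 7, 14, 18) / 20)
  expect_equal(unname(v[grep("^dist_T", names(v))]),
               c(2, 6, 9, 12, 17) / 20)
})

test_that("CTD handles homopolymers and absent nucleotides", {
  v <- ctd_vector("AAAAA")
  expect_equal(unname(v[1:4]), c(1, 0, 0, 0))
  expect_equal(unname(v[5:10]), rep(0, 6))
  expect_equal(unname(v[grep("^dist_A", names(v))]), c(0.2, 0.4, 0.6, 0.8, 1.0))
  expect_equal(unname(v[grep("^dist_G", names(v))]), rep(0, 5))
  expect_error(ctd_vector("A"), "length >= 2")
})

test_that("CTD structural invariants hold on random sequences", {
  for (s in 1:10) {
    seq <- random_dna(sample(10:200, 1), seed = 200 + s)
    v <- ctd_vector(seq)
    L <- nchar(seq)
    expect_true(all(v >= 0 & v <= 1))
    expect_equal(sum(v[1:4]), 1)                      # composition simplex
    expect_equal(sum(v[5:10]) * (L - 1), L - 1 -
                   sum(sapply(c("A", "T", "G", "C"), function(x)
                     sum(substring(seq, 1:(L - 1), 1:(L - 1)) == x &
                           substring(seq, 2:L, 2:L) == x))))
    for (x in c("A", "T", "G", "C")) {               # quantiles non-decreasing
      d <- v[grep(paste0("^dist_", x), names(v))]
      expect_true(all(diff(d) >= 0))
    }
  }
})

test_that("3-mer tokenization slides a width-3 window with step 1", {
  expect_equal(tokenize_kmers("ACGTA"), c("ACG", "CGT", "GTA"))
  expect_equal(tokenize_kmers("AAA"), "AAA")
  expect_error(tokenize_kmers("AC"), "shorter")
})
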