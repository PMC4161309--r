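test_that("back-translation maps residues to codons and gaps to triple gaps", {
  cds <- c(x = "ATGAAATTTGGG", y = "ATGAAAGGG")
  paln <- c(x = "MKFG", y = "MK-G")
  caln <- backtranslate(paln, cds)
  expect_equal(nchar(caln[[1]]), 3 * nchar(paln[[1]]))
  expect_equal(caln[["x"]], "ATGAAATTTGGG")
  expect_equal(caln[["y"]], "ATGAAA---GGG")
  # protein gap at column 3 becomes nucleotide gaps at columns 7-9
  expect_equal(substr(caln[["y"]], 7, 9), "---")
  # mismatched CDS is an error naming the sequence
  expect_error(backtranslate(paln, c(x = "ATGAAATTTGGG", y = "ATGTTTGGG")), "y")
})

test_that("NG86 reproduces the hand-computed example and limiting cases", {
  # 10 x TTT vs 9 x TTT + TTC: S = 10/3, pS = 0.3, dS = 0.3831
  a <- strrep("TTT", 10)
  b <- paste0(strrep("TTT", 9), "TTC")
  r <- ng86_divergence(c(a = a, b = b))
  expect_equal(round(r$dS, 4), 0.3831)
  expect_equal(r$dN, 0)
  # identical sequences
  r0 <- ng86_divergence(c(a = a, b = a))
  expect_equal(r0$dS, 0)
  expect_equal(r0$dN, 0)
  # site counts always sum to 3 x codons
  set.seed(41)
  pr <- simulate_codon_pair(50, 0.1, 0.2)
  cc <- sagevo:::comparable_codons(pr[[1]], pr[[2]])
  ss <- sagevo:::codon_syn_sites()
  S <- (sum(ss[cc$a]) + sum(ss[cc$b])) / 2
  expect_equal(S + (3 * length(cc$a) - S), 3 * length(cc$a))
  # fewer than 10 codons refused
  expect_error(ng86_divergence(c(a = "ATGAAA", b = "ATGAAA")), "codons")
  # saturation: wildly divergent codons flag and cap dS
  set.seed(42)
  ps <- simulate_codon_pair(200, 8, 1)
  rs <- ng86_divergence(ps)
  expect_true(rs$saturated)
  expect_equal(rs$dS, 3)
})

test_that("the ML codon estimator agrees with NG86 and handles degenerate input", {
  set.seed(43)
  pr <- simulate_codon_pair(800, 0.15, 0.1)
  ng <- ng86_divergence(pr)
  ml <- ml_pairwise_divergence(pr)
  expect_lt(abs(ng$dS - ml$dS), 0.05)
  expect_lt(abs(ng$dN - ml$dN), 0.02)
  # identical sequences return exact zeros
  same <- c(a = strrep("ATGAAATTTCCC", 20), b = strrep("ATGAAATTTCCC", 20))
  r0 <- ml_pairwise_divergence(same)
  expect_identical(r0$dS, 0)
  expect_identical(r0$dN, 0)
})

test_that("concatenated estimates are order-invariant and match the single-gene case", {
  set.seed(44)
  g1 <- simulate_codon_pair(300, 0.1, 0.1)
  g2 <- simulate_codon_pair(300, 0.3, 0.1)
  names(g1) <- names(g2) <- c("a", "b")
  single <- ml_pairwise_divergence(g1)
  one <- concat_divergence(list(gene1 = g1))
  expect_equal(one$dS, single$dS, tolerance = 1e-8)
  fwd <- concat_divergence(list(gene1 = g1, gene2 = g2))
  rev <- concat_divergence(list(gene2 = g2, gene1 = g1))
  expect_identical(fwd$dS, rev$dS)
  expect_error(concat_divergence(list()), "empty")
})

test_that("nucleotide diversity averages pairwise p-distances", {
  a <- strrep("A", 100)
  b <- paste0(strrep("A", 99), "C")
  expect_equal(nucleotide_diversity(c(a = a, b = b)), 0.01)
  expect_equal(nucleotide_diversity(c(a = a, b = a)), 0)
  # three sequences with pairwise p of 0.01, 0.02, 0.03 -> pi = 0.02
  s1 <- strrep("A", 100)
  s2 <- paste0(strrep("A", 99), "C")                      # 1 diff to s1
  s3 <- paste0(strrep("A", 97), "GGT")                    # 3 diffs to s1, 2 or 4 to s2
  # construct exactly: s3 differs from s1 at 3 sites, from s2 at those 3 + site 100
  s3 <- paste0(strrep("A", 96), "GGG", "A")
  p12 <- mean(sagevo:::seq_chars(s1) != sagevo:::seq_chars(s2))
  p13 <- mean(sagevo:::seq_chars(s1) != sagevo:::seq_chars(s3))
  p23 <- mean(sagevo:::seq_chars(s2) != sagevo:::seq_chars(s3))
  expect_equal(nucleotide_diversity(c(s1 = s1, s2 = s2, s3 = s3)),
               mean(c(p12, p13, p23)))
})

test_that("pairwise identity excludes end gaps and rounds to 2 decimals", {
  a <- strrep("ACGT", 250)
  expect_equal(pairwise_identity(a, a), 100)
  b <- a
  substr(b, 500, 500) <- "A"  # one mismatch in 1000 columns
  expect_equal(pairwise_identity(a, b), 99.9)
  # a fragment still aligns at full identity (overhangs unpenalised)
  expect_equal(pairwise_identity(a, substr(a, 101, 900)), 100)
})

test_that("sliding windows tile the gap-stripped alignment and flag saturation", {
  set.seed(45)
  # uniform 2% divergence -> flat track at JC(0.02) = 0.0203
  n <- 400
  s1 <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  s2 <- sagevo:::seq_chars(s1)
  flip <- seq(1, n, by = 50)  # exactly 2% of sites, evenly spread
  for (i in flip) s2[i] <- setdiff(c("A", "C", "G", "T"), s2[i])[1]
  tr <- sliding_window_divergence(c(a = s1, b = paste(s2, collapse = "")),
                                  window = 200, step = 50)
  expect_equal(nrow(tr), 5)  # floor((400-200)/50)+1
  expect_true(all(abs(tr$divergence - 0.0203) < 1e-4))
  # implanted identical tract dips to zero
  t1 <- paste(sample(c("A", "C", "G", "T"), 1200, replace = TRUE), collapse = "")
  t2 <- sagevo:::seq_chars(t1)
  mut <- sample(1200, 120)
  for (i in mut) t2[i] <- setdiff(c("A", "C", "G", "T"), t2[i])[1]
  t2[500:799] <- sagevo:::seq_chars(t1)[500:799]
  tr2 <- sliding_window_divergence(c(a = t1, b = paste(t2, collapse = "")), 200, 50)
  inside <- tr2$start >= 500 & tr2$end <= 799
  expect_true(any(tr2$divergence[inside] == 0))
  expect_gt(max(tr2$divergence[!inside]), 0.05)
  # shorter than one window errors; saturated windows are NA
  expect_error(sliding_window_divergence(c(a = "ACGT", b = "ACGT"), 200, 50),
               "window")
})

test_that("ternary normalisation, categories and spread behave as specified", {
  tp <- ternary_analysis(tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    p1 = c(0.1, 0.05, 0.02), p2 = c(0.1, 0.05, 0.03), p3 = c(0.1, 2.0, 0.04)))
  pts <- tp$points
  expect_true(all(abs(pts$x + pts$y + pts$z - 1) < 1e-9))
  expect_equal(unname(unlist(pts[pts$gene_id == "g1", c("x", "y", "z")])),
               rep(1 / 3, 3))
  expect_equal(pts$category, c("orange", "red", "yellow"))
  expect_equal(round(unlist(pts[pts$gene_id == "g2", c("x", "y", "z")]), 4),
               c(x = 0.0238, y = 0.0238, z = 0.9524))
  # degenerate input: identical triplets give zero spread under both modes
  tp0 <- ternary_analysis(tibble::tibble(gene_id = c("a", "b", "c"),
                                         p1 = 0.2, p2 = 0.2, p3 = 0.2))
  expect_equal(tp0$spread_mean, 0)
  expect_equal(tp0$spread_median, 0)
  # capping only decreases values; zero-sum genes are dropped and reported
  tpz <- ternary_analysis(tibble::tibble(gene_id = c("a", "z"),
                                         p1 = c(4, 0), p2 = c(1, 0), p3 = c(1, 0)))
  expect_equal(tpz$dropped, "z")
  expect_true(tpz$points$capped[1])
  expect_equal(tpz$points$x[1], 3 / 5)
  expect_error(ternary_analysis(tibble::tibble(gene_id = "g", p1 = -1, p2 = 1, p3 = 1)),
               "negative")
  # tidiers expose points and spreads
  expect_equal(nrow(tidy(tp)), 3)
  expect_equal(glance(tp)$spread_mean, tp$spread_mean)
})

test_that("plot methods return ggplot objects", {
  tp <- ternary_analysis(tibble::tibble(gene_id = c("g1", "g2"),
                                        a = c(0.05, 0.3), b = c(0.06, 0.2),
                                        c = c(0.04, 1.4)))
  expect_s3_class(autoplot(tp), "ggplot")
  tr <- tibble::tibble(start = c(1, 51), end = c(200, 250),
                       midpoint = c(100, 150), p = c(0.02, 0.03),
                       divergence = c(0.0203, 0.0306))
  expect_s3_class(plot_window_track(tr, highlight = c(60, 120)), "ggplot")
})
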