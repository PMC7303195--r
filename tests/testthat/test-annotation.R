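test_that("histone overlap uses half-open intervals and the class grouping", {
  marks <- data.table::data.table(
    chrom = "c", start = c(100L, 100L, 100L, 100L),
    end = c(200L, 200L, 200L, 200L),
    tissue = "adipose",
    mark = c("H3K4me1", "H3K27ac", "H3K4me3", "H3K9ac"))
  v_in <- data.frame(rsid = "rsIn", chrom = "c", pos = 150L)
  got <- histone_overlap(v_in, marks)
  expect_equal(nrow(got), 1L)
  expect_true(got$enhancer)           # H3K4me1 + H3K27ac
  expect_true(got$promoter)           # H3K4me3 + H3K9ac
  expect_setequal(unlist(got$marks),
                  c("H3K27ac", "H3K4me1", "H3K4me3", "H3K9ac"))

  ## boundaries: pos0 = start is inside; pos0 = end is 1 bp past the end
  v_edge <- data.frame(rsid = c("rsL", "rsR"), chrom = "c",
                       pos = c(101L, 201L))
  got_edge <- histone_overlap(v_edge, marks)
  expect_equal(got_edge$rsid, "rsL")

  ## tissue filter
  expect_equal(nrow(histone_overlap(v_in, marks, tissues = "liver")), 0L)
})

test_that("unknown marks are classed other, not enhancer/promoter", {
  marks <- data.table::data.table(chrom = "c", start = 0L, end = 100L,
                                  tissue = "t", mark = "H3K36me3")
  v <- data.frame(rsid = "r", chrom = "c", pos = 50L)
  expect_message(got <- histone_overlap(v, marks), "other")
  expect_false(got$enhancer)
  expect_false(got$promoter)
})

test_that("PWM scoring reproduces the worked log2-odds examples", {
  uni <- pwm("uniform", matrix(0.25, nrow = 3, ncol = 4))
  expect_equal(score_allele_against_pwm("ACGTACGT", 4, "T", uni), 0)
  expect_equal(score_allele_against_pwm("ACGTACGT", 4, "A", uni), 0)

  single <- pwm("single", matrix(c(0.97, 0.01, 0.01, 0.01), nrow = 1))
  expect_equal(score_allele_against_pwm("GGAGG", 3, "A", single),
               log2(0.97 / 0.25), tolerance = 1e-12)
  expect_equal(log2(0.97 / 0.25), 1.956, tolerance = 1e-3)
  expect_equal(score_allele_against_pwm("GGAGG", 3, "C", single),
               max(log2(0.01 / 0.25), log2(0.01 / 0.25)), tolerance = 1e-12)
  expect_equal(log2(0.01 / 0.25), -4.644, tolerance = 1e-3)
})

test_that("single-column delta equals the difference of allele scores", {
  single <- pwm("single", matrix(c(0.97, 0.01, 0.01, 0.01), nrow = 1))
  ctx <- data.table::data.table(rsid = "r", context = "GGAGG", offset = 3L,
                                ref = "A", alt = "C")
  hit <- motif_delta(ctx, list(single))
  expect_equal(hit$delta, log2(0.01 / 0.25) - log2(0.97 / 0.25),
               tolerance = 1e-12)
  expect_equal(hit$delta, -6.60, tolerance = 1e-2)
})

test_that("scoring is strand-consistent", {
  set.seed(5)
  probs <- matrix(runif(5 * 4), ncol = 4)
  probs <- probs / rowSums(probs)
  p <- pwm("m", probs)
  p_rc <- pwm("m_rc", probs[rev(seq_len(nrow(probs))), c(4, 3, 2, 1)])
  ctx <- "ACGGTTACAG"
  rc <- function(s) paste(rev(c(A = "T", C = "G", G = "C", T = "A")[
    strsplit(s, "")[[1]]]), collapse = "")
  for (allele in c("A", "C")) {
    s1 <- score_allele_against_pwm(ctx, 5, allele, p)
    s2 <- score_allele_against_pwm(rc(ctx), nchar(ctx) - 5 + 1,
                                   c(A = "T", C = "G", G = "C", T = "A")[[allele]],
                                   p_rc)
    expect_equal(s1, s2)
  }

  ## palindromic PWM: identical delta whether context is given + or -
  pal <- pwm("pal", rbind(c(0.7, 0.1, 0.1, 0.1),
                          c(0.1, 0.1, 0.1, 0.7)))   # "AT" favoured, palindromic
  ctx2 <- "GGATCC"
  d_fwd <- motif_delta(data.table::data.table(
    rsid = "x", context = ctx2, offset = 3L, ref = "A", alt = "C"),
    list(pal))$delta
  d_rev <- motif_delta(data.table::data.table(
    rsid = "x", context = rc(ctx2), offset = nchar(ctx2) - 3L + 1L,
    ref = "T", alt = "G"), list(pal))$delta
  expect_equal(d_fwd, d_rev)
})

test_that("non-ACGT context is rejected", {
  uni <- pwm("u", matrix(0.25, 1, 4))
  ## the N sits away from the substituted position
  expect_error(score_allele_against_pwm("ANCGT", 3, "A", uni), "non-ACGT")
})

test_that("pwm constructor validates rows", {
  expect_error(pwm("bad", matrix(c(0.5, 0.2, 0.2, 0.2), 1)), "sum to 1")
})

test_that("LD matches the worked 2x2 table and its invariances", {
  ## 20 haplotypes: AB = 6, Ab = 4, aB = 4, ab = 6
  a <- c(rep(1, 6), rep(1, 4), rep(0, 4), rep(0, 6))
  b <- c(rep(1, 6), rep(0, 4), rep(1, 4), rep(0, 6))
  h <- cbind(A = a, B = b)
  ld <- ld_matrix(h)
  row <- ld[rsid_a == "A" & rsid_b == "B"]
  expect_equal(row$d, 0.05)
  expect_equal(row$r2, 0.04)
  expect_equal(row$d_prime, 0.2)
  ## diagonal
  expect_equal(ld[rsid_a == "A" & rsid_b == "A"]$r2, 1)

  ## allele relabelling at either locus leaves r2 and D' unchanged
  for (flip in list(c(1, 0), c(0, 1), c(1, 1))) {
    h2 <- cbind(A = if (flip[1]) 1 - a else a,
                B = if (flip[2]) 1 - b else b)
    ld2 <- ld_matrix(h2)[rsid_a == "A" & rsid_b == "B"]
    expect_equal(ld2$r2, row$r2)
    expect_equal(ld2$d_prime, row$d_prime)
  }
})

test_that("LD handles perfect LD, equilibrium and monomorphic input", {
  x <- c(rep(1, 7), rep(0, 13))
  expect_equal(ld_matrix(cbind(a = x, b = x))[rsid_a == "a" & rsid_b == "b"]$r2, 1)
  expect_equal(ld_matrix(cbind(a = x, b = x))[rsid_a == "a" & rsid_b == "b"]$d_prime, 1)

  ## pAB = pA pB exactly: 2x2 counts 1,1,1,1
  h_eq <- cbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0))
  eq <- ld_matrix(h_eq)[rsid_a == "a" & rsid_b == "b"]
  expect_equal(eq$r2, 0)
  expect_equal(eq$d_prime, 0)

  expect_error(ld_matrix(cbind(a = x, mono = rep(1, 20))), "mono")
})

test_that("PWM text round-trips", {
  p1 <- pwm("m1", rbind(c(0.7, 0.1, 0.1, 0.1), c(0.25, 0.25, 0.25, 0.25)))
  p2 <- pwm("m2", matrix(c(0.97, 0.01, 0.01, 0.01), 1))
  path <- withr::local_tempfile(fileext = ".pwm")
  write_pwms(list(m1 = p1, m2 = p2), path)
  back <- read_pwms(path)
  expect_equal(names(back), c("m1", "m2"))
  expect_equal(back$m1$probs, p1$probs, tolerance = 1e-5, ignore_attr = TRUE)
})
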