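# Pileup parsing, depth-chart round trips, matrix assembly, VCF output.

write_tmp <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}

test_that("pileup read bases are parsed per the grammar", {
  f <- write_tmp("chr1\t100\tA\t5\t..,.C\tIIIII")
  rec <- read_pileup(f)
  expect_equal(rec$A, 4L)
  expect_equal(rec$C, 1L)
  expect_equal(rec$G + rec$T, 0L)
  expect_equal(rec$pos, 100L)

  # start/end markers: ^~ consumed (mapping quality), $ skipped; the
  # stated depth (3) disagrees with the 2 parsed bases, which warns
  f <- write_tmp("chr1\t101\tG\t3\t^~.,$\tII")
  expect_warning(rec <- read_pileup(f), class = "vbsnv_warning")
  expect_equal(rec$G, 2L)  # "." and "," toward ref
  expect_equal(rec$A + rec$C + rec$T, 0L)

  # insertion skipped entirely
  f <- write_tmp("chr1\t102\tT\t2\t.+2AG,\tII")
  rec <- read_pileup(f)
  expect_equal(rec$T, 2L)
  expect_equal(rec$A + rec$C + rec$G, 0L)

  # multi-digit indel length: all 12 deleted bases are skipped
  f <- write_tmp("chr1\t103\tA\t2\t.-12ACGTACGTACGT,\tII")
  rec <- read_pileup(f)
  expect_equal(rec$A, 2L)
  expect_equal(rec$A + rec$C + rec$G + rec$T, 2L)

  # depth-column disagreement is a warning, parsed counts win
  f <- write_tmp("chr1\t104\tA\t7\t..,\tIII")
  expect_warning(rec <- read_pileup(f), class = "vbsnv_warning")
  expect_equal(rec$A, 3L)
})

test_that("malformed pileup lines are reported with their line number", {
  f <- write_tmp(c("chr1\t1\tA\t1\t.\tI", "chr1\tX\tA\t1\t.\tI"))
  expect_error(read_pileup(f), "line 2", class = "vbsnv_input_error")
  f <- write_tmp("chr1\t5\tA\t1\t.%\tI")
  expect_error(read_pileup(f), "line 1", class = "vbsnv_input_error")
  f <- write_tmp("chr1\t5\tA\t1")
  expect_error(read_pileup(f), class = "vbsnv_input_error")
})

test_that("pileup counts round-trip under random grammar encodings", {
  set.seed(71)
  for (k in 1:20) {
    ref <- sample(c("A", "C", "G", "T"), 1)
    counts <- setNames(rpois(4, 3), c("A", "C", "G", "T"))
    # encode: ref as ./,; others as letters; sprinkle markers
    toks <- c(rep(c(".", ","), length.out = counts[ref]),
              unlist(mapply(function(b, k) rep(b, k),
                            setdiff(names(counts), ref),
                            counts[setdiff(names(counts), ref)])))
    toks <- sample(toks)
    if (length(toks) > 0 && runif(1) < 0.5) {
      toks[1] <- paste0("^!", toks[1])
    }
    if (length(toks) > 1 && runif(1) < 0.5) {
      toks[2] <- paste0(toks[2], "+3TTT")
    }
    counts[ref] <- counts[ref]  # reference pooled with ./,
    f <- write_tmp(sprintf("c\t%d\t%s\t%d\t%s\t%s", k, ref, sum(counts),
                           paste(toks, collapse = ""),
                           paste(rep("I", sum(counts)), collapse = "")))
    rec <- read_pileup(f)
    expect_equal(unlist(rec[, c("A", "C", "G", "T")]),
                 counts[c("A", "C", "G", "T")],
                 ignore_attr = TRUE)
  }
})

test_that("depth charts round-trip and enforce their dialect", {
  rec <- data.frame(chrom = "c4", pos = c(7L, 9L, 12L),
                    ref = c("A", "C", "T"),
                    A = c(90L, 2L, 0L), C = c(1L, 60L, 3L),
                    G = c(0L, 1L, 0L), T = c(2L, 0L, 70L))
  f <- tempfile(fileext = ".tsv")
  write_depth_chart(rec, f)
  back <- read_depth_chart(f)
  expect_equal(back, rec)

  # header-only file
  f2 <- write_tmp("chrom\tpos\tref\tA\tC\tG\tT")
  expect_equal(nrow(read_depth_chart(f2)), 0L)

  # negative count
  f3 <- write_tmp(c("chrom\tpos\tref\tA\tC\tG\tT", "c\t1\tA\t-1\t0\t0\t0"))
  expect_error(read_depth_chart(f3), class = "vbsnv_input_error")
  # missing column
  f4 <- write_tmp(c("chrom\tpos\tref\tA\tC\tG", "c\t1\tA\t1\t0\t0"))
  expect_error(read_depth_chart(f4), class = "vbsnv_input_error")
})

test_that("assemble_count_matrix unions positions and checks consistency", {
  r1 <- data.frame(chrom = "c", pos = c(1L, 2L), ref = c("A", "A"),
                   A = c(90L, 80L), C = c(10L, 0L), G = c(0L, 0L),
                   T = c(0L, 0L))
  r2 <- data.frame(chrom = "c", pos = 2L, ref = "A",
                   A = 70L, C = 0L, G = 5L, T = 0L)
  cm <- assemble_count_matrix(list(r1, r2))
  expect_equal(cm$positions, c(1L, 2L))
  expect_equal(cm$r[1, ], c(10, 0))   # replicate 2 missing position 1
  expect_equal(cm$n[1, ], c(100, 0))
  expect_equal(cm$r[2, ], c(0, 5))

  r_bad <- data.frame(chrom = "c", pos = 2L, ref = "C",
                      A = 1L, C = 1L, G = 1L, T = 1L)
  expect_error(assemble_count_matrix(list(r1, r_bad)),
               class = "vbsnv_input_error")
  r_other <- data.frame(chrom = "c2", pos = 5L, ref = "A",
                        A = 1L, C = 0L, G = 0L, T = 0L)
  expect_error(assemble_count_matrix(list(r1, r_other)),
               class = "vbsnv_input_error")
})

test_that("coordinates stay 1-based through pileup, chart and matrix", {
  f <- write_tmp("chrX\t85\tG\t4\t.AA,\tIIII")
  rec <- read_pileup(f)
  f2 <- tempfile(fileext = ".tsv")
  write_depth_chart(rec, f2)
  cm <- assemble_count_matrix(list(read_depth_chart(f2)))
  expect_equal(cm$positions, 85L)
  expect_equal(cm$r[1, 1], 2)
  expect_equal(cm$n[1, 1], 4)
})

test_that("write_vcf emits valid records with the declared INFO keys", {
  calls <- data.frame(position = c(85L, 90L), ref = c("A", "C"),
                      nraf_case = c(0.1, 0.2), nraf_control = c(0.001, 0.002),
                      diff_prob = c(0.999, 0.99),
                      chi2_p = c(0.001, 0.5),
                      provisional = c(TRUE, TRUE),
                      called = c(TRUE, FALSE))
  bc <- array(0L, dim = c(2, 1, 4))
  bc[1, 1, ] <- c(80L, 3L, 3L, 14L)   # ref A, T most frequent alt
  bc[2, 1, ] <- c(5L, 90L, 5L, 0L)    # ref C, tie A/G -> A
  cm <- read_count_matrix(bc, c(85L, 90L), c("A", "C"), chrom = "c4")

  f <- tempfile(fileext = ".vcf")
  write_vcf(calls, cm, f)
  lines <- readLines(f)
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 1L)
  fields <- strsplit(body, "\t")[[1]]
  expect_equal(fields[1:5], c("c4", "85", ".", "A", "T"))
  expect_match(fields[8], "NRAF_CASE=0.1;")
  expect_match(fields[8], "DIFFPROB=0.999")

  # filtered provisional record on request, ALT tie broken A < G
  write_vcf(calls, cm, f, emit_filtered = TRUE)
  body <- readLines(f)
  body <- body[!startsWith(body, "#")]
  expect_length(body, 2L)
  f2 <- strsplit(body[2], "\t")[[1]]
  expect_equal(f2[5], "A")
  expect_equal(f2[7], "chi2_uniform")

  # zero calls: header-only VCF, readable by an independent parser
  none <- calls; none$called <- FALSE
  write_vcf(none, cm, f)
  expect_length(readLines(f)[!startsWith(readLines(f), "#")], 0L)
  skip_if_not_installed("vcfR")
  write_vcf(calls, cm, f)
  v <- suppressWarnings(vcfR::read.vcfR(f, verbose = FALSE))
  expect_equal(unname(v@fix[1, "POS"]), "85")
  expect_equal(unname(v@fix[1, "ALT"]), "T")
})

test_that("estimates serialize and restore losslessly", {
  set.seed(72)
  cm <- make_counts(matrix(rbinom(6, 80, 0.1), 3, 2), matrix(80L, 3, 2))
  est <- suppressWarnings(vb_fit(cm))
  f <- tempfile(fileext = ".json")
  write_estimate(est, f)
  back <- read_estimate(f)
  expect_equal(back$params, est$params)
  expect_equal(back$vparams$gamma, est$vparams$gamma, ignore_attr = TRUE)
  expect_equal(back$vparams$delta, est$vparams$delta, ignore_attr = TRUE)
  expect_equal(back$nraf, est$nraf)
  expect_equal(back$positions, est$positions)
  expect_error(read_estimate(write_tmp("{}")), class = "vbsnv_input_error")
})
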