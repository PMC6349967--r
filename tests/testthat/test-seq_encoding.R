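test_that("read_fasta preserves order, ids and normalizes case", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a desc here", "AC", ">b", "MK", ">c", "acd"), f)
  recs <- read_fasta(f)
  expect_length(recs, 3)
  expect_equal(vapply(recs, `[[`, "", "id"), c("a", "b", "c"))
  expect_equal(recs[[1]]$sequence, "AC")
  expect_equal(recs[[3]]$sequence, "ACD")
})

test_that("read_fasta rejects empty files and bad alphabets with context", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(), f)
  expect_error(read_fasta(f), "empty")
  writeLines(c(">a", "AX?"), f)
  expect_error(read_fasta(f), "record 'a'")
  writeLines(c(">a", "AC?"), f)
  expect_error(read_fasta(f), "record 'a'.*'\\?'")
})

test_that("non-standard letters are rejected by default, mappable on request", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">z", "ABZ"), f)
  expect_error(read_fasta(f), "'B'")
  recs <- read_fasta(f, map_nonstandard = TRUE)
  expect_equal(recs[[1]]$sequence, "ADE")  # B->D, Z->E
  expect_error(protein_record("x", "AXA", map_nonstandard = TRUE), "'X'")
})

test_that("one-hot encoding matches the published unit-vector layout", {
  a <- one_hot_encode(protein_record("p", "A"))
  expect_equal(unname(a[1, ]), c(1, rep(0, 19)))
  cc <- one_hot_encode(protein_record("p", "C"))
  expect_equal(unname(cc[1, ]), c(0, 1, rep(0, 18)))
  ac <- one_hot_encode(protein_record("p", "AC"))
  expect_equal(dim(ac), c(2, 20))
  expect_equal(unname(colSums(ac))[1:2], c(1, 1))
})

test_that("every one-hot row has exactly one 1 on random sequences", {
  set.seed(1)
  for (i in 1:20) {
    L <- sample(1:80, 1)
    seq <- paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
    m <- one_hot_encode(protein_record("r", seq))
    expect_equal(unname(rowSums(m)), rep(1, L))
    expect_true(all(m %in% c(0, 1)))
  }
})

test_that("fallback profile equals the one-hot encoding numerically", {
  set.seed(2)
  for (i in 1:10) {
    seq <- paste(sample(AA_ALPHABET, sample(1:50, 1), replace = TRUE),
                 collapse = "")
    r <- protein_record("r", seq)
    fb <- fallback_pssm(r)
    expect_equal(attr(fb, "source"), "fallback")
    expect_equal(unclass(fb)[, ], one_hot_encode(r)[, ])
  }
})

test_that("ASCII PSSM parsing scales percentages and round-trips", {
  r <- protein_record("q", "MKA")
  pct <- matrix(0, 3, 20, dimnames = list(NULL, AA_ALPHABET))
  pct[cbind(1:3, match(c("M", "K", "A"), AA_ALPHABET))] <- 1
  f <- withr::local_tempfile(fileext = ".pssm")
  mlenz:::write_ascii_pssm(r, pct, f)
  parsed <- parse_pssm(f, r)
  expect_equal(attr(parsed, "source"), "parsed")
  expect_equal(unclass(parsed)[, ], pct[, ])
  # round-trip on an arbitrary frequency profile (2-decimal precision)
  set.seed(3)
  p2 <- matrix(round(runif(60), 2), 3, 20)
  mlenz:::write_ascii_pssm(r, p2, f)
  expect_equal(unname(unclass(parse_pssm(f, r))[, ]), p2, tolerance = 1e-12)
})

test_that("PSSM parsing enforces the residue and length contracts", {
  r3 <- protein_record("q", "MKA")
  pct <- diag(1, 3, 20)
  f <- withr::local_tempfile(fileext = ".pssm")
  # residue mismatch reported with its position
  mlenz:::write_ascii_pssm(protein_record("q", "MMA"), pct, f)
  expect_error(parse_pssm(f, r3), "position 2")
  # row-count mismatch
  mlenz:::write_ascii_pssm(protein_record("q", "MK"), pct[1:2, ], f)
  expect_error(parse_pssm(f, r3), "2 data rows")
  # malformed row reported with its line number
  mlenz:::write_ascii_pssm(r3, pct, f)
  lines <- readLines(f)
  data_line <- grep("^\\s*2\\s+K", lines)[1]
  lines[data_line] <- "    2 K   1 2 3"
  writeLines(lines, f)
  expect_error(parse_pssm(f, r3), paste("line", data_line))
})

test_that("log-odds columns parse through the logistic squashing", {
  r <- protein_record("q", "AC")
  pct <- matrix(0.5, 2, 20)
  f <- withr::local_tempfile(fileext = ".pssm")
  mlenz:::write_ascii_pssm(r, pct, f)
  lo <- parse_pssm(f, r, columns = "logodds")
  expect_true(all(lo >= 0 & lo <= 1))
})

test_that("domain encoding follows the hit/no-hit contract", {
  expect_equal(unname(domain_encode(character(), paste0("PF", 1:4))),
               rep(0, 4))
  v <- domain_encode("PF_B", c("PF_A", "PF_B", "PF_C"))
  expect_equal(unname(v), c(0, 1, 0))
  expect_warning(out <- domain_encode("PF_X", "PF_A"), "1 domain hit")
  expect_equal(unname(out), 0)
  expect_error(domain_encode("a", c("PF_A", "PF_A")), "duplicate")
})

test_that("domain encoding ignores hit order and multiplicity", {
  vocab <- c("PF1", "PF2", "PF3", "PF4")
  a <- domain_encode(c("PF3", "PF1"), vocab)
  b <- domain_encode(c("PF1", "PF3", "PF3", "PF1"), vocab)
  expect_identical(a, b)
})

test_that("domain hits parse from plain lists and tblout tables", {
  f <- withr::local_tempfile()
  writeLines(c("PF00001", "PF00002", "PF00001"), f)
  expect_equal(parse_domain_hits(f), c("PF00001", "PF00002"))

  writeLines(c("# comment", "#", "# more",
               paste("dom1 PF00010.3 query -", paste(rep("0", 14), collapse = " ")),
               paste("dom2 PF00020.1 query -", paste(rep("0", 14), collapse = " "))),
             f)
  expect_equal(parse_domain_hits(f), c("PF00010.3", "PF00020.1"))

  writeLines(character(), f)
  expect_equal(parse_domain_hits(f), character())
})

test_that("domain vocabulary round-trips through its text format", {
  v <- c("PF00002", "PF00010", "PF99999")
  f <- withr::local_tempfile()
  write_domain_vocabulary(v, f)
  expect_identical(read_domain_vocabulary(f), v)
})

test_that("encoded_protein enforces matching row counts", {
  r <- protein_record("r", "ACDE")
  expect_error(encoded_protein(one_hot_encode(r), matrix(0, 3, 20), 0),
               "identical row counts")
  x <- encode_record(r, vocabulary = paste0("PF", 1:5), hits = "PF2")
  expect_equal(nrow(x$one_hot), nrow(x$pssm))
  expect_equal(unname(x$domains), c(0, 1, 0, 0, 0))
})
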