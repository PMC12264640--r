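make_cds_seq <- function(n_codons_body, body = "GCT", start = "ATG",
                         stop = "TAA") {
  paste0(start, strrep(body, n_codons_body), stop)
}

test_that("FASTA reading validates records, order, and alphabet", {
  p <- tempfile(fileext = ".fa")
  writeLines(c(">rec1", strrep("ACGT", 15)), p)
  recs <- read_fasta(p)
  expect_length(recs, 1)
  expect_equal(nchar(recs[[1]]$seq), 60)

  writeLines(c(">a", "ACGT", ">b", "GGCC"), p)
  recs <- read_fasta(p)
  expect_equal(vapply(recs, `[[`, "", "id"), c("a", "b"))

  writeLines(c(">bad", "ACGXA"), p)
  expect_error(read_fasta(p), "position 4")

  writeLines(c(">dup", "ACGT", ">dup", "GGCC"), p)
  expect_error(read_fasta(p), "dup")

  writeLines(character(0), p)
  expect_error(read_fasta(p), "format")
})

test_that("GenBank parsing handles multi-exon minus-strand CDS and topology", {
  set.seed(42)
  seqv <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
  gb <- tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       toyrec 120 bp    DNA     circular PLN 01-JAN-2026",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    "     CDS             complement(join(10..30,50..70))",
    "                     /gene=\"toyg\"",
    "ORIGIN",
    paste("        1", tolower(substr(seqv, 1, 60))),
    paste("       61", tolower(substr(seqv, 61, 120))),
    "//"), gb)
  rec <- read_genbank(gb)
  expect_true(rec$circular)
  expect_equal(rec$seq, seqv)
  f <- rec$features[[1]]
  expect_equal(f$gene, "toyg")
  expect_equal(f$strand, "-")
  expect_equal(nrow(f$intervals), 2)
  spliced <- cpcub:::splice_feature(rec, f)
  expected <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
    paste0(substr(seqv, 10, 30), substr(seqv, 50, 70)))))
  expect_equal(spliced, expected)
})

test_that("GenBank parsing rejects out-of-range locations and missing ORIGIN", {
  gb <- tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       bad 20 bp DNA linear PLN 01-JAN-2026",
    "FEATURES             Location/Qualifiers",
    "     CDS             10..300",
    "ORIGIN",
    "        1 acgtacgtac gtacgtacgt",
    "//"), gb)
  expect_error(read_genbank(gb), "exceeds")
  writeLines(c("LOCUS       bad 20 bp DNA linear", "//"), gb)
  expect_error(read_genbank(gb), "ORIGIN")
})

test_that("a CDS annotated across the origin splices contiguously", {
  body <- make_cds_seq(99)  # 303 nt
  pad <- strrep("C", 200)
  # genome: last 100 nt of the CDS at the start, pad, first 203 nt at the end
  genome <- paste0(substr(body, 204, 303), pad, substr(body, 1, 203))
  rec <- seq_record("wrap", genome, circular = TRUE, features = list(
    feature("wrapg", "CDS",
            matrix(c(300, 503, 0, 100), ncol = 2, byrow = TRUE))))
  expect_equal(cpcub:::splice_feature(rec, rec$features[[1]]), body)
  cds <- extract_cds(rec)
  expect_equal(cds$genes$sequence, body)
})

test_that("CDS filters: length boundary, start codon, stops, N codons, dedup", {
  s299 <- paste0("ATG", strrep("C", 293), "TAA")
  s300 <- make_cds_seq(98)
  s303 <- make_cds_seq(99)
  genome <- paste0(s299, s300, s303)
  rec <- seq_record("flt", genome, features = list(
    feature("g299", "CDS", matrix(c(0, 299), ncol = 2)),
    feature("g300", "CDS", matrix(c(299, 599), ncol = 2)),
    feature("g303", "CDS", matrix(c(599, 902), ncol = 2))))
  cds <- extract_cds(rec)
  expect_setequal(cds$genes$gene, c("g300", "g303"))

  # GTG start excluded; internal stop excluded
  gtg <- make_cds_seq(98, start = "GTG")
  istop <- paste0("ATG", "TAA", strrep("GCT", 97), "TAA")
  genome2 <- paste0(gtg, istop, s300)
  rec2 <- seq_record("flt2", genome2, features = list(
    feature("gtg", "CDS", matrix(c(0, 300), ncol = 2)),
    feature("istop", "CDS", matrix(c(300, 600), ncol = 2)),
    feature("ok", "CDS", matrix(c(600, 900), ncol = 2))))
  expect_equal(extract_cds(rec2)$genes$gene, "ok")

  # one N codon in a 303-nt CDS: codon dropped, 300 nt retained
  withN <- paste0("ATG", "ANA", strrep("GCT", 98), "TAA")
  recN <- seq_record("fltN", paste0(withN, s300), features = list(
    feature("gN", "CDS", matrix(c(0, 303), ncol = 2)),
    feature("ok", "CDS", matrix(c(303, 603), ncol = 2))))
  cdsN <- extract_cds(recN)
  gN <- cdsN$genes$sequence[cdsN$genes$gene == "gN"]
  expect_equal(nchar(gN), 300)
  expect_false(grepl("N", gN))

  # IR-duplicated gene: identical (name, sequence) keeps one copy
  recD <- seq_record("dup", paste0(s300, s300), features = list(
    feature("rps19", "CDS", matrix(c(0, 300), ncol = 2)),
    feature("rps19", "CDS", matrix(c(300, 600), ncol = 2))))
  expect_equal(nrow(extract_cds(recD)$genes), 1)
})

test_that("quadripartite detection recovers planted architecture exactly", {
  rec <- simulate_quadripartite_genome(lsc_len = 10000, ssc_len = 1000,
                                       ir_len = 2000, seed = 7)
  st <- detect_quadripartite(rec)
  expect_equal(unname(st$lsc[["length"]]), 10000)
  expect_equal(unname(st$ssc[["length"]]), 1000)
  expect_equal(unname(st$ira[["length"]]), 2000)
  expect_equal(unname(st$irb[["length"]]), 2000)
  # the four regions tile the genome
  expect_equal(st$lsc[["length"]] + st$ssc[["length"]] +
                 2 * st$ira[["length"]], st$genome_length)
  # the two IR copies are exact reverse complements
  ira_seq <- cpcub:::region_seq(rec, st$ira[["start"]], st$ira[["length"]])
  irb_seq <- cpcub:::region_seq(rec, st$irb[["start"]], st$irb[["length"]])
  expect_equal(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(ira_seq))), irb_seq)
})

test_that("detection is invariant to rotating the origin, including into the IR", {
  rec <- simulate_quadripartite_genome(seed = 7)
  for (off in c(4321, 11000, 12500)) {
    st <- detect_quadripartite(rotate_record(rec, off))
    expect_equal(unname(st$ira[["length"]]), 2000)
    expect_equal(unname(st$lsc[["length"]]), 10000)
    expect_equal(unname(st$ssc[["length"]]), 1000)
  }
})

test_that("random sequence without a planted repeat yields the no-structure signal", {
  set.seed(3)
  s <- paste(sample(c("A", "C", "G", "T"), 20000, TRUE), collapse = "")
  rec <- seq_record("rand", s, circular = TRUE)
  expect_message(st <- detect_quadripartite(rec), "no quadripartite")
  expect_null(st)
  # independent substring-multiset oracle on a smaller random sequence
  set.seed(5)
  s2 <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
  expect_false(oracle_has_inverted_repeat(s2, 100))
  expect_null(suppressMessages(
    detect_quadripartite(seq_record("r2", s2, circular = TRUE),
                         min_ir_len = 100)))
})

test_that("equally-maximal repeat pairs break ties toward the smallest start", {
  set.seed(9)
  rseg <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  qseg <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  pad <- function(n) strrep("A", n)
  # junction base "A" on both sides blocks chance extension (A != comp(A))
  genome <- paste0(pad(500), rseg, pad(500), rc(rseg),
                   pad(500), qseg, pad(500), rc(qseg), pad(500))
  rec <- seq_record("tie", genome, circular = FALSE)
  st <- detect_quadripartite(rec, min_ir_len = 500)
  expect_equal(unname(st$ira[["start"]]), 500)
  expect_equal(unname(st$ira[["length"]]), 1000)
})

test_that("region GC is exact on constructed regions and excludes N", {
  # genome laid out as LSC (all AT) + IRa (all GC) + SSC (AT with N) + IRb
  genome <- paste0(strrep("AT", 100), strrep("GGCC", 50),
                   paste0(strrep("AT", 20), "N"), strrep("GGCC", 50))
  rec <- seq_record("gc", genome, circular = TRUE)
  st <- structure(list(
    lsc = c(start = 0, length = 200), ira = c(start = 200, length = 200),
    ssc = c(start = 400, length = 41), irb = c(start = 441, length = 200),
    genome_length = nchar(genome)), class = "quadripartite")
  gcv <- region_gc(rec, st)
  expect_equal(unname(gcv[["lsc"]]), 0)
  expect_equal(unname(gcv[["ir"]]), 100)
  expect_equal(unname(gcv[["ssc"]]), 0)  # N excluded from the denominator
  # length mismatch is an error
  st$genome_length <- 10
  expect_error(region_gc(rec, st), "match")
})

test_that("extract_cds is invariant to origin rotation of a circular record", {
  rec <- simulate_quadripartite_genome(seed = 21)
  base <- extract_cds(rec)
  for (off in c(150, 7777)) {
    rot <- extract_cds(rotate_record(rec, off))
    expect_setequal(rot$genes$sequence, base$genes$sequence)
    expect_setequal(rot$genes$gene, base$genes$gene)
  }
})
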