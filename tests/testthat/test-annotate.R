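test_that("E-value normalization scales linearly with genome size", {
  expect_equal(normalize_evalue(5, 2e6), 10)
  expect_equal(normalize_evalue(7.3, 4e6), 7.3)
  expect_equal(normalize_evalue(0, 1e6), 0)
  expect_error(normalize_evalue(1, 0), "positive")
})

test_that("presence calls use inclusive thresholds and default to absent", {
  hits <- data.frame(
    genome = c("g1", "g2", "g3", "g3"),
    evalue = c(10, 9, 11, 20),
    identity = c(0.30, 0.29, 0.80, 0.95)
  )
  prof <- call_presence_from_hits(hits, genomes = c("g1", "g2", "g3", "g4"))
  # boundary hit (E = 10, id = 0.30) is present; E or id below threshold absent
  expect_equal(prof, c(g1 = 1L, g2 = 0L, g3 = 0L, g4 = 0L))

  # monotone in both thresholds: relaxing never removes presence
  set.seed(3)
  big <- data.frame(
    genome = sample(paste0("g", 1:40), 200, replace = TRUE),
    evalue = rexp(200, 1 / 8),
    identity = runif(200)
  )
  genomes <- paste0("g", 1:40)
  last <- NULL
  for (id_min in c(0.70, 0.50, 0.30)) {
    cur <- call_presence_from_hits(big, genomes, id_min = id_min)
    if (!is.null(last)) expect_true(all(cur >= last))
    last <- cur
  }
})

test_that("start-codon windows follow the strand conventions", {
  contig <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                  collapse = "")
  w <- extract_window(contig, 200, "+")
  expect_equal(w, substr(contig, 51, 250))
  expect_equal(nchar(w), 200)

  expect_message(w2 <- extract_window(contig, 100, "+"), "truncated")
  expect_equal(w2, substr(contig, 1, 150))

  # reverse strand: reverse complement of the mirrored window
  w3 <- extract_window(contig, 200, "-")
  expect_equal(w3, revcomp(substr(contig, 200 - 49 + 1, 200 + 151)))
  expect_error(extract_window(contig, 400, "+"), "outside")
})

test_that("reverse complement handles DNA, RNA and case", {
  expect_equal(revcomp("ACGT"), "ACGT")
  expect_equal(revcomp("AACG"), "CGTT")
  expect_equal(revcomp("ACGU"), "ACGU")
  expect_equal(revcomp("GGAU"), "AUCC")
})

test_that("site columns map through gaps and flag core-gap rows", {
  msa <- c(
    ref = "AACCGGTTAACCGGTT",
    o1  = "AACCGGTTAACCGGTT",
    o2  = "AACC--TTAACCGGTT",
    o3  = "AACCGGTTAA--GGTT"
  )
  # site [4, 8) on the ungapped ref = "GGTT"; pad 2 -> [2, 10)
  ext <- map_site_columns(msa, "ref", 4, 8, pad = 2)
  expect_equal(ext$seq[ext$genome == "ref"], "CCGGTTAA")
  expect_true(ext$gap_flag[ext$genome == "o2"])   # gap inside core
  expect_false(ext$gap_flag[ext$genome == "o3"])  # gap only in the pad
  expect_equal(ext$seq[ext$genome == "o2"], "CCTTAA")

  # degapping the reference extraction reproduces the site plus pads
  expect_equal(substr(ext$seq[ext$genome == "ref"], 3, 6), "GGTT")

  # pads clip at the sequence start
  ext2 <- map_site_columns(msa, "ref", 1, 4, pad = 5)
  expect_equal(ext2$seq[ext2$genome == "ref"],
               unname(substr(msa["ref"], 1, 9)))
})

test_that("reference-row gap columns are retained for other rows", {
  msa <- c(ref = "AC--GT", oo = "ACTTGT")
  ext <- map_site_columns(msa, "ref", 0, 4, pad = 0)
  expect_equal(ext$seq[ext$genome == "ref"], "ACGT")
  expect_equal(ext$seq[ext$genome == "oo"], "ACTTGT")
  expect_false(ext$gap_flag[ext$genome == "oo"])
})

test_that("consensus follows majority with documented tie-breaks", {
  expect_equal(consensus_site(c("ACGU", "ACGU", "ACGU")), "ACGU")
  expect_equal(consensus_site(c("AAG", "AAG", "GAG")), "AAG")
  expect_message(cs <- consensus_site(c("AC", "GC")), "tie")
  expect_equal(cs, "AC")
  # gaps do not vote; all-gap columns are dropped
  expect_equal(consensus_site(c("A-C", "A-C", "AGC")), "AGC")
  expect_error(consensus_site(character(0)), "empty")
})

test_that("interaction merging uses the <10 nt edge rule transitively", {
  rec <- function(ss, se, ms, me) {
    data.frame(srna = "s", target = "t", sbs_start = ss, sbs_end = se,
               mbs_start = ms, mbs_end = me)
  }
  # overlap on the sRNA, 2 nt apart on the mRNA: one interaction
  r2 <- rbind(rec(0, 12, 100, 110), rec(5, 15, 112, 120))
  m2 <- distinct_interactions(r2)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$mbs_start, 100)
  expect_equal(m2$mbs_end, 120)

  # exactly 10 nt apart on the mRNA: stays two entries
  r10 <- rbind(rec(0, 12, 100, 110), rec(0, 12, 120, 130))
  expect_equal(nrow(distinct_interactions(r10)), 2L)

  # identical records collapse; merging is idempotent and order-free
  rid <- rbind(rec(0, 12, 100, 110), rec(0, 12, 100, 110))
  expect_equal(nrow(distinct_interactions(rid)), 1L)
  r3 <- rbind(rec(0, 12, 100, 110), rec(0, 12, 105, 115), rec(0, 12, 112, 122))
  m3 <- distinct_interactions(r3)
  expect_equal(nrow(m3), 1L)  # transitive closure chains the three
  m3b <- distinct_interactions(r3[c(3, 1, 2), ])
  expect_equal(m3b$mbs_start, m3$mbs_start)
  expect_equal(nrow(distinct_interactions(m3)), nrow(m3))

  # different sRNA-target pairs never merge
  r4 <- rbind(rec(0, 12, 100, 110),
              transform(rec(0, 12, 100, 110), target = "t2"))
  expect_equal(nrow(distinct_interactions(r4)), 2L)
})

test_that("alignments round-trip through FASTA", {
  msa <- c(row1 = "ACGU-ACGU", row2 = "ACGUUACGU")
  f <- tempfile(fileext = ".fasta")
  write_alignment(msa, f)
  expect_equal(read_alignment(f), msa)
})
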