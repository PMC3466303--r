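mkseq <- function(res, id = res) protein_seq(res, id = id)

test_that("filter_hits applies the E-value threshold and deduplicates", {
  a <- homolog_hit(mkseq("MKTAYIAKQR", "a"), 0.05)
  b <- homolog_hit(mkseq("MKTAYIAKQW", "b"), 0.5)
  expect_equal(filter_hits(list(a, b)), list(a))
  expect_equal(filter_hits(list()), list())

  dup1 <- homolog_hit(mkseq("MKTAYIAKQR", "x1"), 0.05)
  dup2 <- homolog_hit(mkseq("MKTAYIAKQR", "x2"), 0.01)
  kept <- filter_hits(list(dup1, dup2))
  expect_length(kept, 1)
  expect_equal(kept[[1]]$evalue, 0.01)

  expect_message(res <- filter_hits(list(homolog_hit(mkseq("MWWA", "n")))),
                 "lack an E-value")
  expect_length(res, 1)
})

test_that("pairwise_identity matches definition and enumeration oracle", {
  expect_equal(pairwise_identity("AAAA", "AAAA"), 1.0)
  expect_equal(pairwise_identity("AAAA", "TTTT"), 0.0)
  # denominator is the shorter sequence
  expect_equal(pairwise_identity("AAAA", "AAAAWWWW"), 1.0)

  set.seed(31)
  for (rep in 1:40) {
    a <- random_protein(sample(2:6, 1), c("A", "C", "G", "W"))
    b <- random_protein(sample(2:6, 1), c("A", "C", "G", "W"))
    o <- oracle_semiglobal(a$residues, b$residues)
    expect_equal(pairwise_identity(a, b),
                 o$identities / min(seq_length(a), seq_length(b)))
  }
})

test_that("greedy clustering partitions the input and honors the threshold", {
  base <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEV"
  seqs <- c(
    lapply(1:4, function(i) mkseq(base, sprintf("copy%d", i))),
    list(mkseq(sub("^M", "W", base), "near"),
         mkseq(paste(rep("PW", 16), collapse = ""), "far"))
  )
  cl <- cluster_sequences(seqs, 0.80)
  total <- sum(vapply(cl, function(x) length(x$members), 0L))
  expect_equal(total, length(seqs))
  for (x in cl)
    for (mem in x$members)
      expect_gte(pairwise_identity(mem, x$representative), 0.80)
  # n identical copies form one cluster
  cl1 <- cluster_sequences(lapply(1:5, function(i) mkseq(base, paste0("c", i))))
  expect_length(cl1, 1)
  expect_length(cl1[[1]]$members, 5)
  # zero-identity sequences form singletons
  cl2 <- cluster_sequences(list(mkseq("AAAA"), mkseq("TTTT")))
  expect_length(cl2, 2)
})

test_that("clustering equals an independent greedy re-implementation", {
  set.seed(53)
  for (rep in 1:5) {
    fam <- generate_family(family_model(length = 30, n_homologs = 10,
                                        n_subfamilies = 3,
                                        indel_rate = 0.05,
                                        seed = 100 + rep))
    cl <- cluster_sequences(fam$homologs, 0.80)
    part <- oracle_greedy_partition(fam$homologs, 0.80)
    got <- vapply(cl, function(x)
      paste(sort(vapply(x$members, function(s) s$id, "")), collapse = ","),
      "")
    want <- vapply(part, function(idx)
      paste(sort(vapply(fam$homologs[idx], function(s) s$id, "")),
            collapse = ","), "")
    expect_setequal(got, want)
  }
})

test_that("build_supporting_set ranks, caps, and always contains the query", {
  q <- mkseq("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEV", "query")
  # no homologs: the query-only fallback still supports scoring
  ss0 <- build_supporting_set(q, list())
  expect_s3_class(ss0, "supporting_set")
  expect_equal(n_clusters(ss0), 1L)
  expect_equal(n_supporting_sequences(ss0), 1L)
  expect_equal(provean_score(q, null_variant(q, 1), ss0)$score, 0)

  # a duplicate of the query joins the query's cluster
  ss1 <- build_supporting_set(q, list(mkseq(q$residues, "dup")))
  expect_equal(n_clusters(ss1), 1L)
  expect_equal(length(ss1$clusters[[1]]$members), 2L)

  # 50 mutually dissimilar homologs + query: capped at 45 clusters
  set.seed(61)
  far <- lapply(1:50, function(i) random_protein(32, id = sprintf("h%02d", i)))
  ss2 <- build_supporting_set(q, far, max_clusters = 45)
  expect_equal(n_clusters(ss2), 45L)
  # the query's cluster is first and clusters are sorted by similarity
  expect_true(any(vapply(ss2$clusters[[1]]$members,
                         function(s) identical(s$residues, q$residues), TRUE)))
  sims <- vapply(ss2$clusters[-1], function(cl) cl$query_similarity, 0)
  expect_true(all(diff(sims) <= 0))
  # adding an exact duplicate of a member never changes the cluster count
  ss3 <- build_supporting_set(q, c(far, list(mkseq(far[[3]]$residues, "dup"))),
                              max_clusters = 60)
  ss4 <- build_supporting_set(q, far, max_clusters = 60)
  expect_equal(n_clusters(ss3), n_clusters(ss4))
})

test_that("BLAST tabular hits are parsed and cross-referenced", {
  seqs <- list(h1 = mkseq("MKTAYIAKQR", "h1"), h2 = mkseq("MKWAYIAKQR", "h2"),
               h3 = mkseq("MKCAYIAKQR", "h3"))
  path <- withr::local_tempfile(fileext = ".tsv")
  row <- function(id, ev, bs)
    paste(c("q", id, "95.0", "10", "1", "0", "1", "10", "1", "10", ev, bs),
          collapse = "\t")
  writeLines(c(row("h1", "1e-30", "120"), row("h2", "0.05", "40"),
               row("h3", "0.2", "25")), path)
  hits <- read_hit_table(path, seqs)
  expect_length(hits, 3)
  expect_equal(vapply(hits, function(h) h$evalue, 0), c(1e-30, 0.05, 0.2))
  expect_length(filter_hits(hits), 2)

  writeLines(row("missing", "0.01", "50"), path)
  expect_error(read_hit_table(path, seqs), "not present")
  writeLines("q\th1\tshort", path)
  expect_error(read_hit_table(path, seqs), "12 tab-separated")
})

test_that("CD-HIT .clstr files are parsed", {
  seqs <- list(a = mkseq("MKTAYIAKQR", "a"), b = mkseq("MKTAYIAKQW", "b"),
               c = mkseq("WWPPWWPPWW", "c"))
  path <- withr::local_tempfile(fileext = ".clstr")
  writeLines(c(
    ">Cluster 0",
    "0\t10aa, >a... *",
    "1\t10aa, >b... at 90.00%",
    ">Cluster 1",
    "0\t10aa, >c... *"), path)
  cl <- read_cdhit_clusters(path, seqs)
  expect_length(cl, 2)
  expect_equal(cl[[1]]$representative$id, "a")
  expect_length(cl[[1]]$members, 2)
  expect_equal(cl[[2]]$representative$id, "c")

  writeLines(c(">Cluster 0", "0\t10aa, >zz... *"), path)
  expect_error(read_cdhit_clusters(path, seqs), "not present")
})
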