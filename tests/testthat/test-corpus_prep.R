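test_that("count_terms counts, filters stopwords, handles empty docs", {
  docs <- make_documents(data.frame(id = "d", date = "2020-01-01",
                                    text = "a b a"))
  tc <- count_terms(docs)
  expect_equal(tc$counts[[1]], c(a = 2, b = 1))
  tc2 <- count_terms(docs, stopwords = "a")
  expect_equal(tc2$counts[[1]], c(b = 1))
  # hand-enumerated 3-doc fixture
  tc3 <- count_terms(make_documents(fixture_records()))
  expect_equal(tc3$counts[[1]], c(apple = 2, banana = 1, cherry = 1))
  expect_equal(tc3$counts[[2]], c(banana = 2, date = 1))
  expect_equal(tc3$counts[[3]], c(apple = 1, cherry = 3))
  expect_equal(unname(tc3$totals), c(4, 3, 4))
  # all tokens removed -> retained with zero counts and a warning
  expect_warning(tcz <- count_terms(docs, stopwords = c("a", "b")),
                 "zero surviving tokens")
  expect_length(tcz$counts[[1]], 0)
  expect_error(count_terms(list()), "empty corpus")
})

test_that("punctuation-only tokens are dropped at document assembly", {
  docs <- make_documents(data.frame(id = "d", date = "2020-01-01",
                                    text = "a -- b ?! ..."))
  expect_equal(docs[[1]]$tokens, c("a", "b"))
})

test_that("tfidf_rank matches the formula and a brute-force oracle", {
  # term present in every document scores 0 (idf = ln(N/N))
  recs <- data.frame(id = c("a", "b"), date = c("2020-01-01", "2020-01-02"),
                     text = c("common rare rare rare", "common other"))
  tc <- count_terms(make_documents(recs))
  rk <- tfidf_rank(tc, 3)
  expect_equal(rk$score[rk$term == "common"], 0)
  # N = 2 docs, term in 1 doc with f = 3 -> 3 * ln 2
  expect_equal(rk$score[rk$term == "rare"], 3 * log(2), tolerance = 1e-12)
  # 5-doc fixture against exhaustive scoring
  set.seed(42)
  vocab <- letters[1:8]
  texts <- replicate(5, paste(sample(vocab, 12, replace = TRUE),
                              collapse = " "))
  recs5 <- data.frame(id = paste0("d", 1:5),
                      date = sprintf("2020-01-%02d", 1:5), text = texts,
                      stringsAsFactors = FALSE)
  tc5 <- count_terms(make_documents(recs5))
  got <- tfidf_rank(tc5, 3)
  want <- tfidf_bruteforce(tc5$counts)
  expect_equal(got$term, want$term[1:3])
  expect_equal(got$score, want$score[1:3], tolerance = 1e-12,
               ignore_attr = TRUE)
  # K larger than the vocabulary returns everything with a warning
  expect_warning(all_terms <- tfidf_rank(tc5, 100), "vocabulary")
  expect_equal(sort(all_terms$term), sort(want$term))
})

test_that("tfidf_rank is invariant to duplicating the whole corpus", {
  tc <- count_terms(make_documents(fixture_records()))
  recs2 <- rbind(fixture_records(),
                 transform(fixture_records(), id = paste0(id, "x")))
  tc2 <- count_terms(make_documents(recs2))
  r1 <- tfidf_rank(tc, 4)
  r2 <- tfidf_rank(tc2, 4)
  expect_equal(r1$term, r2$term)
  expect_equal(r1$score, r2$score, tolerance = 1e-12)
})

test_that("merge_synonyms sums counts and rejects chained maps", {
  docs <- make_documents(data.frame(
    id = "d", date = "2020-01-01",
    text = "doctor doctor physician nurse"))
  tc <- count_terms(docs)
  merged <- merge_synonyms(tc, c(physician = "doctor"))
  expect_equal(merged$counts[[1]][["doctor"]], 3)
  expect_equal(merged$counts[[1]][["nurse"]], 1)
  # empty map is the identity
  expect_equal(merge_synonyms(tc, character())$counts, tc$counts)
  # 3-way merge summed by hand: 2 + 1 + 1 = 4
  docs3 <- make_documents(data.frame(
    id = "d", date = "2020-01-01",
    text = "md md physician doc nurse"))
  m3 <- merge_synonyms(count_terms(docs3),
                       c(md = "doctor", physician = "doctor",
                         doc = "doctor"))
  expect_equal(m3$counts[[1]][["doctor"]], 4)
  expect_error(merge_synonyms(tc, c(a = "b", b = "c")), "one-hop")
})

test_that("build_panel computes adjusted term frequencies", {
  recs <- data.frame(
    id = c("r1", "r2"),
    date = c("2020-01-05", "2020-02-05"),
    text = c(paste(c(rep("kw", 2), rep("x", 8)), collapse = " "),
             paste(rep("y", 5), collapse = " ")),
    stringsAsFactors = FALSE)
  ks <- keyword_set(c("kw", "y"))
  pan <- build_panel(make_documents(recs), ks, scale = 1000)
  # 10-token report with the keyword twice at scale 1000 -> 200
  expect_equal(pan$matrices[[1]][1, "kw"], 200, ignore_attr = TRUE)
  # keyword absent from a report -> 0
  expect_equal(pan$matrices[[1]][1, "y"], 0, ignore_attr = TRUE)
  expect_equal(pan$periods, "2020 Q1")
})

test_that("build_panel errors on an empty quarter in range", {
  recs <- data.frame(id = c("a", "b"),
                     date = c("2020-01-05", "2020-07-05"),
                     text = c("kw x", "kw y"), stringsAsFactors = FALSE)
  expect_error(build_panel(make_documents(recs), keyword_set("kw")),
               "2020 Q2")
})

test_that("panel entries are invariant to document order and count scaling", {
  recs <- data.frame(
    id = c("r1", "r2", "r3"),
    date = c("2020-01-05", "2020-01-15", "2020-02-05"),
    text = c("kw x x x", "x kw kw y", "y kw x x"),
    stringsAsFactors = FALSE)
  ks <- keyword_set(c("kw", "y"))
  p1 <- build_panel(make_documents(recs), ks)
  p2 <- build_panel(make_documents(recs[c(3, 1, 2), ]), ks)
  expect_equal(p1$matrices[[1]][order(rownames(p1$matrices[[1]])), ],
               p2$matrices[[1]][order(rownames(p2$matrices[[1]])), ])
  # doubling every count in a report leaves its row unchanged
  recs_dbl <- recs
  recs_dbl$text[1] <- paste(rep(c("kw", "x", "x", "x"), 2), collapse = " ")
  p3 <- build_panel(make_documents(recs_dbl), ks)
  expect_equal(p3$matrices[[1]]["r1", ], p1$matrices[[1]]["r1", ])
})

test_that("panel round-trips through CSV + manifest", {
  sc <- make_scenario(p = 3, M = 2, n_phases = 1, edges_per_phase = 1,
                      n_per_period = 5, seed = 2)
  pan <- sample_scenario_panel(sc)
  dir <- withr::local_tempdir()
  write_panel(pan, dir, scale = 1000)
  back <- read_panel(dir)
  expect_equal(back$periods, pan$periods)
  expect_equal(back$keywords$keywords, pan$keywords$keywords)
  expect_equal(back$matrices, pan$matrices, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("corpus JSONL reading matches in-memory documents", {
  recs <- fixture_records()
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(vapply(seq_len(nrow(recs)), function(i)
    jsonlite::toJSON(as.list(recs[i, ]), auto_unbox = TRUE), ""), path)
  d1 <- read_corpus_jsonl(path)
  d2 <- make_documents(recs)
  expect_equal(d1, d2)
})
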