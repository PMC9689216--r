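#' Default tokenizer: lowercase, split on whitespace
#'
#' Splits raw text on whitespace and lowercases the tokens. Tokenization is
#' pluggable throughout the package: corpora in languages that need real
#' word segmentation should be tokenized upstream (or a segmenting callable
#' passed wherever a `tokenizer` argument is accepted).
#'
#' @param text character vector of raw document texts.
#' @return List of character vectors, one per input text.
#' @export
tokenize_whitespace <- function(text) {
  strsplit(tolower(trimws(text)), "\\s+")
}

.is_punct_only <- function(tokens) grepl("^[[:punct:]]+$", tokens)

#' Assemble a document set from id/date/text records
#'
#' @param records data.frame with columns `id`, `date` (ISO-8601 or Date),
#'   and `text`.
#' @param tokenizer callable mapping a character vector of texts to a list
#'   of token vectors; default [tokenize_whitespace()].
#' @return List of documents, each `list(id, date, tokens)` with `date` a
#'   `Date` and punctuation-only tokens removed.
#' @export
make_documents <- function(records, tokenizer = tokenize_whitespace) {
  stopifnot(is.data.frame(records),
            all(c("id", "date", "text") %in% names(records)))
  dates <- as.Date(records$date)
  if (anyNA(dates)) stop("unparseable date(s) in corpus records")
  toks <- tokenizer(as.character(records$text))
  Map(function(id, date, tk) {
    tk <- tk[nzchar(tk) & !.is_punct_only(tk)]
    list(id = id, date = date, tokens = tk)
  }, records$id, dates, toks)
}

#' Read a JSON-lines corpus
#'
#' One JSON object per line with fields `id`, `date` (ISO-8601), `text`.
#'
#' @param path file path.
#' @inheritParams make_documents
#' @return A document list as from [make_documents()].
#' @export
read_corpus_jsonl <- function(path, tokenizer = tokenize_whitespace) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty corpus file: ", path)
  recs <- lapply(lines, jsonlite::fromJSON)
  df <- data.frame(id = vapply(recs, function(r) as.character(r$id), ""),
                   date = vapply(recs, function(r) as.character(r$date), ""),
                   text = vapply(recs, function(r) as.character(r$text), ""),
                   stringsAsFactors = FALSE)
  make_documents(df, tokenizer)
}

#' Per-document term counts with stopword removal
#'
#' @param documents list of documents from [make_documents()].
#' @param stopwords character vector of terms to drop (may be empty).
#' @return Object of class `term_counts`: list with `counts` (one named
#'   numeric vector per document), `ids`, and `totals` (surviving tokens per
#'   document). A document whose tokens are all removed is retained with an
#'   all-zero (empty) count vector and a warning.
#' @export
count_terms <- function(documents, stopwords = character()) {
  if (length(documents) == 0) stop("empty corpus")
  stopwords <- as.character(stopwords)
  counts <- lapply(documents, function(d) {
    tk <- d$tokens[!(d$tokens %in% stopwords)]
    if (length(tk) == 0) return(numeric(0))
    tab <- table(tk)
    stats::setNames(as.numeric(tab), names(tab))
  })
  empty <- vapply(counts, length, 0L) == 0
  if (any(empty))
    warning(sum(empty), " document(s) with zero surviving tokens retained ",
            "with all-zero counts")
  structure(list(counts = counts,
                 ids = vapply(documents, function(d) as.character(d$id), ""),
                 totals = vapply(counts, sum, 0)),
            class = "term_counts")
}

#' Rank terms by TF-IDF and keep the top K
#'
#' The per-document score is \eqn{f_{t,d} \cdot \ln(N / df_t)} with raw term
#' frequency \eqn{f_{t,d}}, corpus size N, and document frequency
#' \eqn{df_t}; a term's corpus-level score aggregates per-document scores
#' (default: maximum over documents, favoring terms highly salient
#' somewhere). Ties are broken lexicographically.
#'
#' @param term_counts a [count_terms()] result.
#' @param K number of top terms to return.
#' @param agg aggregation of per-document scores: "max", "mean" or "sum".
#' @param smooth_idf if TRUE use \eqn{\ln(1 + N/df_t)} instead of
#'   \eqn{\ln(N/df_t)}.
#' @return data.frame with columns `term` and `score`, K rows (or all terms
#'   with a warning when K exceeds the vocabulary).
#' @export
tfidf_rank <- function(term_counts, K, agg = c("max", "mean", "sum"),
                       smooth_idf = FALSE) {
  stopifnot(inherits(term_counts, "term_counts"))
  agg <- match.arg(agg)
  N <- length(term_counts$counts)
  vocab <- sort(unique(unlist(lapply(term_counts$counts, names))))
  if (length(vocab) == 0) stop("no terms left after filtering")
  df_t <- stats::setNames(numeric(length(vocab)), vocab)
  for (ct in term_counts$counts)
    df_t[names(ct)] <- df_t[names(ct)] + 1
  idf <- if (smooth_idf) log(1 + N / df_t) else log(N / df_t)
  aggfun <- switch(agg, max = max, mean = mean, sum = sum)
  # per-term aggregate over the documents that contain it (absent docs
  # contribute score 0, which only matters for "mean": we use mean over all
  # N documents to keep the statistic a true corpus average)
  sc <- stats::setNames(numeric(length(vocab)), vocab)
  acc <- lapply(vocab, function(t) numeric(0))
  names(acc) <- vocab
  for (ct in term_counts$counts) {
    s <- ct * idf[names(ct)]
    for (t in names(s)) acc[[t]] <- c(acc[[t]], s[[t]])
  }
  sc <- vapply(vocab, function(t) {
    v <- acc[[t]]
    if (agg == "mean") sum(v) / N else aggfun(v)
  }, 0)
  ord <- order(-sc, vocab)
  out <- data.frame(term = vocab[ord], score = sc[ord], row.names = NULL,
                    stringsAsFactors = FALSE)
  if (K > nrow(out)) {
    warning("K = ", K, " exceeds the ", nrow(out), "-term vocabulary; ",
            "returning all terms")
    return(out)
  }
  out[seq_len(K), ]
}

.check_merge_map <- function(merge_map) {
  if (length(merge_map) == 0) return(invisible(merge_map))
  if (is.null(names(merge_map)) || any(!nzchar(names(merge_map))))
    stop("merge_map must be a named character vector (raw -> canonical)")
  chained <- intersect(unname(merge_map), names(merge_map))
  chained <- chained[merge_map[chained] != chained]
  if (length(chained))
    stop("merge_map must be one-hop raw -> canonical; chained/cyclic ",
         "mapping via: ", paste(chained, collapse = ", "))
  invisible(merge_map)
}

#' Merge synonym counts into canonical terms
#'
#' @param term_counts a [count_terms()] result.
#' @param merge_map named character vector mapping raw term -> canonical
#'   term (one hop; chained mappings are an error). Unmapped terms pass
#'   through unchanged.
#' @return A `term_counts` object with merged per-document counts.
#' @export
merge_synonyms <- function(term_counts, merge_map = character()) {
  stopifnot(inherits(term_counts, "term_counts"))
  .check_merge_map(merge_map)
  out <- term_counts
  out$counts <- lapply(term_counts$counts, function(ct) {
    if (length(ct) == 0) return(ct)
    canon <- names(ct)
    hit <- canon %in% names(merge_map)
    canon[hit] <- unname(merge_map[canon[hit]])
    agg <- tapply(ct, canon, sum)[sort(unique(canon))]
    stats::setNames(as.numeric(agg), names(agg))
  })
  out
}

#' Keyword vocabulary with synonym map
#'
#' @param keywords ordered character vector of distinct canonical terms.
#' @param merge_map named character vector raw -> canonical; every target
#'   must be one of `keywords`.
#' @return Object of class `keyword_set`.
#' @export
keyword_set <- function(keywords, merge_map = character()) {
  keywords <- as.character(keywords)
  if (anyDuplicated(keywords)) stop("duplicate keywords")
  .check_merge_map(merge_map)
  if (length(merge_map) && !all(merge_map %in% keywords))
    stop("every merge_map target must be a keyword")
  structure(list(keywords = keywords, merge_map = merge_map),
            class = "keyword_set")
}

#' Period rule: calendar quarters
#'
#' Maps dates to labels like `"2015 Q1"`. Quarter labels sort correctly in
#' chronological order within this format.
#'
#' @param dates Date vector.
#' @return Character vector of quarter labels.
#' @export
quarter_of <- function(dates) {
  dates <- as.Date(dates)
  sprintf("%s Q%d", format(dates, "%Y"),
          (as.integer(format(dates, "%m")) - 1L) %/% 3L + 1L)
}

.quarter_seq <- function(from, to) {
  f <- as.Date(from); t <- as.Date(to)
  y <- as.integer(format(f, "%Y")); q <- (as.integer(format(f, "%m")) - 1L) %/% 3L
  y2 <- as.integer(format(t, "%Y")); q2 <- (as.integer(format(t, "%m")) - 1L) %/% 3L
  idx <- seq.int(y * 4L + q, y2 * 4L + q2)
  sprintf("%d Q%d", idx %/% 4L, idx %% 4L + 1L)
}

#' Per-period panel of non-negative observation matrices
#'
#' The container consumed by [fit_joint()]: an ordered collection of M
#' per-period matrices (rows = reports, columns = keywords) sharing one
#' keyword vocabulary.
#'
#' @param matrices list of M non-negative numeric matrices with identical
#'   column count p (column order = keyword order).
#' @param periods ordered character vector of M period labels.
#' @param keywords a [keyword_set()] or character vector of p keywords.
#' @return Object of class `panel_data` with elements `matrices`, `periods`,
#'   `keywords`, `p`, `M`, `n` (per-period row counts).
#' @export
panel_data <- function(matrices, periods, keywords) {
  if (is.character(keywords)) keywords <- keyword_set(keywords)
  stopifnot(inherits(keywords, "keyword_set"))
  M <- length(matrices)
  if (M == 0) stop("panel must have at least one period")
  if (length(periods) != M) stop("periods and matrices lengths differ")
  p <- length(keywords$keywords)
  matrices <- lapply(matrices, function(m) {
    m <- as.matrix(m)
    if (ncol(m) != p) stop("all matrices must have p = ", p, " columns")
    if (anyNA(m) || any(!is.finite(m)) || any(m < 0))
      stop("panel entries must be finite and non-negative")
    colnames(m) <- keywords$keywords
    m
  })
  structure(list(matrices = matrices, periods = as.character(periods),
                 keywords = keywords, p = p, M = M,
                 n = vapply(matrices, nrow, 0L)),
            class = "panel_data")
}

#' @export
print.panel_data <- function(x, ...) {
  cat(sprintf("panel_data: M = %d periods, p = %d keywords, n = %s reports\n",
              x$M, x$p, paste(range(x$n), collapse = "-")))
  invisible(x)
}

#' Build the per-period keyword panel from documents
#'
#' For report i and keyword j the panel entry is the adjusted term
#' frequency \eqn{\mathrm{scale} \cdot c_{ij} / T_i}, where \eqn{c_{ij}} is
#' the (synonym-merged) count of keyword j in report i and \eqn{T_i} is the
#' report's surviving token total: a per-report relative frequency times a
#' scale constant, making rows comparable across periods with different
#' report counts and lengths.
#'
#' @param documents document list from [make_documents()].
#' @param keywords a [keyword_set()].
#' @param stopwords character vector of stopwords.
#' @param period_rule callable mapping Date vector -> period labels; default
#'   calendar quarters ([quarter_of()]). With the default rule, quarters in
#'   the corpus date range with zero reports are an error.
#' @param scale positive scale constant (default 1000).
#' @return A [panel_data()] object with periods in chronological order.
#' @export
build_panel <- function(documents, keywords, stopwords = character(),
                        period_rule = quarter_of, scale = 1000) {
  stopifnot(inherits(keywords, "keyword_set"), scale > 0)
  tc <- merge_synonyms(count_terms(documents, stopwords), keywords$merge_map)
  dates <- do.call(c, lapply(documents, function(d) d$date))
  labels <- period_rule(dates)
  expected <- if (identical(period_rule, quarter_of))
    .quarter_seq(min(dates), max(dates)) else unique(labels[order(dates)])
  missing <- setdiff(expected, labels)
  if (length(missing))
    stop("period(s) with zero reports: ", paste(missing, collapse = ", "))
  kw <- keywords$keywords
  rows <- t(vapply(seq_along(tc$counts), function(i) {
    ct <- tc$counts[[i]]
    tot <- tc$totals[[i]]
    v <- numeric(length(kw))
    if (tot > 0) {
      hit <- intersect(names(ct), kw)
      v[match(hit, kw)] <- scale * ct[hit] / tot
    }
    v
  }, numeric(length(kw))))
  mats <- lapply(expected, function(pd) {
    m <- rows[labels == pd, , drop = FALSE]
    rownames(m) <- tc$ids[labels == pd]
    m
  })
  panel_data(mats, expected, keywords)
}

#' Write / read a panel as per-period CSV files plus a JSON manifest
#'
#' @param panel a [panel_data()] object.
#' @param dir output directory (created if needed).
#' @param scale scale constant recorded in the manifest (metadata only).
#' @return `write_panel` returns `dir` invisibly; `read_panel` returns a
#'   [panel_data()] object.
#' @export
write_panel <- function(panel, dir, scale = NA_real_) {
  stopifnot(inherits(panel, "panel_data"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("period_%03d.csv", seq_len(panel$M))
  for (m in seq_len(panel$M))
    utils::write.csv(panel$matrices[[m]], file.path(dir, files[m]),
                     row.names = FALSE)
  manifest <- list(periods = panel$periods, files = files,
                   keywords = panel$keywords$keywords,
                   merge_map = as.list(panel$keywords$merge_map),
                   scale = scale)
  jsonlite::write_json(manifest, file.path(dir, "panel_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_panel
#' @export
read_panel <- function(dir) {
  manifest <- jsonlite::fromJSON(file.path(dir, "panel_manifest.json"))
  mm <- unlist(manifest$merge_map)
  if (is.null(mm)) mm <- character()
  ks <- keyword_set(manifest$keywords, mm)
  mats <- lapply(manifest$files, function(f)
    as.matrix(utils::read.csv(file.path(dir, f), check.names = FALSE)))
  panel_data(mats, manifest$periods, ks)
}
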