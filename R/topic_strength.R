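#' Topic lexicon
#'
#' Named topics defined by keyword sets, used to label detected modules
#' and to count topic-related reports.
#'
#' @param topics named list: topic id -> non-empty character vector of
#'   keywords.
#' @param labels optional named character vector of display names; default
#'   the topic ids.
#' @return Object of class `topic_lexicon`.
#' @export
topic_lexicon <- function(topics, labels = NULL) {
  if (length(topics) == 0) stop("empty lexicon")
  if (is.null(names(topics)) || any(!nzchar(names(topics))))
    stop("topics must be named")
  if (any(vapply(topics, length, 0L) == 0))
    stop("topic keyword sets must be non-empty")
  if (is.null(labels)) labels <- stats::setNames(names(topics), names(topics))
  structure(list(topics = lapply(topics, as.character),
                 labels = labels),
            class = "topic_lexicon")
}

#' Read a topic lexicon from YAML
#'
#' The YAML maps each topic id either to a keyword list or to a mapping
#' with `label` and `keywords` fields.
#'
#' @param path YAML file path.
#' @return A [topic_lexicon()].
#' @export
read_lexicon_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  topics <- lapply(raw, function(x)
    if (is.list(x) && !is.null(x$keywords)) unlist(x$keywords) else unlist(x))
  labels <- vapply(names(raw), function(nm) {
    x <- raw[[nm]]
    if (is.list(x) && !is.null(x$label)) as.character(x$label) else nm
  }, "")
  topic_lexicon(topics, labels)
}

#' Map detected modules to lexicon topics
#'
#' Each non-omitted module is assigned the topic whose keyword set has the
#' largest Jaccard overlap with the module's keywords; ties go to the
#' earliest topic in the lexicon, and modules with zero overlap stay
#' unassigned (`NA`).
#'
#' @param partition a [louvain()] result (possibly after
#'   [filter_small_modules()]).
#' @param lexicon a [topic_lexicon()].
#' @return data.frame with `module`, `topic` (id or `NA`), `jaccard`,
#'   `omitted`.
#' @export
assign_topics <- function(partition, lexicon) {
  stopifnot(inherits(partition, "module_partition"),
            inherits(lexicon, "topic_lexicon"))
  mods <- split(names(partition$assignment), partition$assignment)
  out <- lapply(seq_along(mods), function(i) {
    if (partition$omitted[i])
      return(data.frame(module = i, topic = NA_character_,
                        jaccard = NA_real_, omitted = TRUE))
    jac <- vapply(lexicon$topics, function(kw) {
      length(intersect(mods[[i]], kw)) / length(union(mods[[i]], kw))
    }, 0)
    if (max(jac) == 0)
      return(data.frame(module = i, topic = NA_character_, jaccard = 0,
                        omitted = FALSE))
    best <- which.max(jac)   # first maximum = lowest topic id on ties
    data.frame(module = i, topic = names(lexicon$topics)[best],
               jaccard = jac[[best]], omitted = FALSE)
  })
  do.call(rbind, out)
}

#' Absolute and relative topic strengths per period
#'
#' For topic u and period m, the absolute strength is
#' \eqn{n_{u,m}/M_m} — the share of the period's reports related to the
#' topic — and the relative strength renormalizes the absolute strengths
#' across topics to sum to one within the period. A report is related to
#' a topic when it contains at least one of the topic's keywords
#' (default), or, in `"plurality"` mode, only to the topic(s) with the
#' most keyword hits; under the default a report may count toward several
#' topics, which the relative normalization is designed to absorb.
#'
#' @param documents document list from [make_documents()].
#' @param lexicon a [topic_lexicon()].
#' @param period_rule callable mapping dates to period labels (default
#'   [quarter_of()]).
#' @param mode `"any"` (default) or `"plurality"`.
#' @return data.frame in long format: `period`, `topic`, `n_related`,
#'   `n_total`, `a_strength`, `r_strength`.
#' @export
topic_strengths <- function(documents, lexicon, period_rule = quarter_of,
                            mode = c("any", "plurality")) {
  stopifnot(inherits(lexicon, "topic_lexicon"))
  mode <- match.arg(mode)
  if (length(documents) == 0) stop("empty corpus")
  dates <- do.call(c, lapply(documents, function(d) d$date))
  labels <- period_rule(dates)
  periods <- unique(labels[order(dates)])
  tnames <- names(lexicon$topics)
  hits <- vapply(documents, function(d) {
    vapply(lexicon$topics, function(kw) sum(d$tokens %in% kw), 0)
  }, numeric(length(tnames)))
  hits <- matrix(hits, nrow = length(tnames))   # topics x docs
  related <- if (mode == "any") hits > 0
             else hits > 0 & sweep(hits, 2, apply(hits, 2, max), "==")
  out <- lapply(periods, function(pd) {
    sel <- labels == pd
    Mm <- sum(sel)
    if (Mm == 0) stop("period with no reports: ", pd)
    n_u <- rowSums(related[, sel, drop = FALSE])
    a <- n_u / Mm
    tot <- sum(a)
    r <- if (tot > 0) a / tot else a * 0
    data.frame(period = pd, topic = tnames, n_related = n_u, n_total = Mm,
               a_strength = a, r_strength = r, row.names = NULL,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
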