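# Evaluation utilities: BLEU-4 with add-one smoothing on higher orders,
# ROUGE-L F1, expert-rating aggregation, and the LLM-call accounting model
# behind topology-discovery cost reduction.

tokenize_text <- function(x) {
  x <- tolower(trimws(x))
  if (!nzchar(x)) character() else strsplit(x, "\\s+")[[1L]]
}

ngrams <- function(tokens, n) {
  if (length(tokens) < n) return(character())
  vapply(seq_len(length(tokens) - n + 1L), function(i)
    paste(tokens[i:(i + n - 1L)], collapse = ""), "")
}

#' BLEU score of a candidate against reference texts
#'
#' BLEU-4: modified (clipped) n-gram precisions for n = 1..4 — orders
#' above the candidate length are skipped — combined as the geometric mean
#' of log precisions, multiplied by the brevity penalty
#' `exp(1 - r/c)` when the candidate (length `c`) is shorter than the
#' closest reference (length `r`, ties to the shorter). Higher orders
#' (n >= 2) use add-one smoothing `(m + 1)/(t + 1)`; a zero unigram
#' precision yields 0. Tokenization is lower-cased whitespace splitting.
#'
#' @param candidate Candidate text.
#' @param references Character vector of one or more reference texts.
#' @return Score in `[0, 1]`.
#' @export
bleu_score <- function(candidate, references) {
  if (!nzchar(trimws(candidate)) || !length(references) ||
      any(!nzchar(trimws(references)))) {
    stop("candidate and references must be non-empty", call. = FALSE)
  }
  cand <- tokenize_text(candidate)
  refs <- lapply(references, tokenize_text)
  c_len <- length(cand)
  orders <- seq_len(min(4L, c_len))
  logp <- numeric(0)
  for (n in orders) {
    cg <- ngrams(cand, n)
    total <- length(cg)
    counts <- table(cg)
    clipped <- 0
    for (g in names(counts)) {
      max_ref <- max(vapply(refs, function(r) sum(ngrams(r, n) == g),
                            numeric(1L)))
      clipped <- clipped + min(counts[[g]], max_ref)
    }
    p <- if (n == 1L) {
      if (total == 0) 0 else clipped / total
    } else {
      (clipped + 1) / (total + 1)
    }
    if (n == 1L && p == 0) return(0)
    logp <- c(logp, log(p))
  }
  ref_lens <- vapply(refs, length, integer(1L))
  r <- ref_lens[order(abs(ref_lens - c_len), ref_lens)][1L]
  bp <- if (c_len > r) 1 else exp(1 - r / c_len)
  bp * exp(mean(logp))
}

lcs_length <- function(a, b) {
  la <- length(a); lb <- length(b)
  if (!la || !lb) return(0L)
  prev <- integer(lb + 1L)
  for (i in seq_len(la)) {
    cur <- integer(lb + 1L)
    for (j in seq_len(lb)) {
      cur[j + 1L] <- if (a[i] == b[j]) prev[j] + 1L else
        max(prev[j + 1L], cur[j])
    }
    prev <- cur
  }
  prev[lb + 1L]
}

#' ROUGE-L F1 of a candidate against a reference
#'
#' Longest-common-subsequence based F1:
#' `P = LCS/|candidate|`, `R = LCS/|reference|`, `F1 = 2PR/(P + R)`
#' (0 when the LCS is empty). Deterministic; tokenization as in
#' [bleu_score()].
#'
#' @param candidate Candidate text.
#' @param reference Reference text.
#' @return Score in `[0, 1]`.
#' @export
rouge_l <- function(candidate, reference) {
  if (!nzchar(trimws(candidate)) || !nzchar(trimws(reference))) {
    stop("candidate and reference must be non-empty", call. = FALSE)
  }
  a <- tokenize_text(candidate)
  b <- tokenize_text(reference)
  l <- lcs_length(a, b)
  if (l == 0L) return(0)
  p <- l / length(a)
  r <- l / length(b)
  2 * p * r / (p + r)
}

#' Aggregate expert clinical ratings
#'
#' Ratings are integers on a structured 5-point scale from poor to
#' excellent. A response is clinically acceptable at rating >= 3 and very
#' good or excellent at rating >= 4; percentages are on the 0-100 scale.
#'
#' @param ratings Integer vector (or data frame with a `rating` column) of
#'   ratings in `1..5`.
#' @return List with `acceptable_pct`, `very_good_or_excellent_pct`,
#'   `mean`.
#' @export
aggregate_ratings <- function(ratings) {
  if (is.data.frame(ratings)) ratings <- ratings$rating
  ratings <- as.numeric(ratings)
  if (!length(ratings)) stop("at least one rating required", call. = FALSE)
  if (any(is.na(ratings)) || any(ratings != round(ratings)) ||
      any(ratings < 1 | ratings > 5)) {
    stop("ratings must be integers in 1..5", call. = FALSE)
  }
  list(
    acceptable_pct = 100 * mean(ratings >= 3),
    very_good_or_excellent_pct = 100 * mean(ratings >= 4),
    mean = mean(ratings)
  )
}

#' LLM-call accounting for topology discovery
#'
#' Upfront topology discovery replaces repeated on-the-fly extraction; the
#' cost model reports `reduction = 100 * (1 - init_calls/dynamic_calls)`,
#' the percentage of LLM invocations saved relative to fully dynamic
#' construction.
#'
#' @param init_calls Calls used for initial topology discovery.
#' @param dynamic_calls Estimated calls under fully dynamic construction
#'   (> 0).
#' @return List of class `kg_call_account` with `init_calls`,
#'   `dynamic_calls`, `reduction`.
#' @export
call_accounting <- function(init_calls, dynamic_calls) {
  if (!is.numeric(dynamic_calls) || dynamic_calls <= 0) {
    stop("dynamic_calls must be > 0", call. = FALSE)
  }
  if (!is.numeric(init_calls) || init_calls < 0) {
    stop("init_calls must be >= 0", call. = FALSE)
  }
  structure(
    list(init_calls = init_calls, dynamic_calls = dynamic_calls,
         reduction = 100 * (1 - init_calls / dynamic_calls)),
    class = "kg_call_account"
  )
}

#' @export
print.kg_call_account <- function(x, ...) {
  cat(sprintf("call accounting: %g init vs %g dynamic -> %.1f%% reduction\n",
              x$init_calls, x$dynamic_calls, x$reduction))
  invisible(x)
}
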