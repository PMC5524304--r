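#' Parameters for the pairwise (fish-specific) CNE search
#'
#' Local alignment scoring mirrors a nucleotide BLAST run with match reward
#' +1, mismatch penalty -1, gap opening 2 and gap extension 2 (a gap of
#' length k costs `gap_open + k * gap_extend`, so the first gap column costs
#' 4). Retained hits must span more than `min_hit_length` aligned columns
#' and be at least `min_identity` identical.
#'
#' @param match_reward,mismatch_penalty substitution scores (penalty given
#'   as a positive number).
#' @param gap_open_cost,gap_extend_cost gap costs (positive numbers).
#' @param min_hit_length retained hits must be strictly longer than this
#'   many aligned (match/mismatch) columns; default 50.
#' @param min_identity minimum identity fraction, default 0.60.
#' @param window region size in bp centred on the focal gene within which
#'   the search is meant to run (default 800 kb); metadata only.
#' @param identity_denominator `"columns"` (matches / match+mismatch
#'   columns, the default) or `"with-gaps"` (matches / all alignment
#'   columns).
#' @param min_score stop the iterative search when the best remaining local
#'   alignment scores below this; default derived as the lowest score an
#'   ungapped retainable hit can achieve,
#'   `ceil((min_hit_length + 1) * (2 * min_identity - 1))`.
#' @param max_nonretained_streak also stop after this many consecutive
#'   best hits that fail the length/identity filters (default 5). Because
#'   hits emerge in non-increasing score order, once the search has dropped
#'   to background-level alignments it rarely climbs back to a qualifying
#'   one; the streak bound keeps the greedy search from grinding through
#'   arbitrarily many low-score background hits.
#' @return A list of class `pairwise_params`.
#' @export
pairwise_params <- function(match_reward = 1, mismatch_penalty = 1,
                            gap_open_cost = 2, gap_extend_cost = 2,
                            min_hit_length = 50L, min_identity = 0.60,
                            window = 8e5,
                            identity_denominator = c("columns", "with-gaps"),
                            min_score = NULL,
                            max_nonretained_streak = 5L) {
  identity_denominator <- match.arg(identity_denominator)
  stopifnot(mismatch_penalty >= 0, gap_open_cost >= 0, gap_extend_cost >= 0,
            min_identity > 0, min_identity <= 1, min_hit_length >= 0)
  if (is.null(min_score)) {
    min_score <- max(1, ceiling((min_hit_length + 1) *
                                  (2 * min_identity - 1)))
  }
  structure(list(match_reward = match_reward,
                 mismatch_penalty = mismatch_penalty,
                 gap_open_cost = gap_open_cost,
                 gap_extend_cost = gap_extend_cost,
                 min_hit_length = as.integer(min_hit_length),
                 min_identity = min_identity, window = window,
                 identity_denominator = identity_denominator,
                 min_score = min_score,
                 max_nonretained_streak = as.integer(max_nonretained_streak)),
            class = "pairwise_params")
}

#' Reverse complement of a nucleotide string
#' @param seq character scalar over `A,C,G,T,N` (case-insensitive).
#' @export
reverse_complement <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Optimal local alignment of two sequences
#'
#' Smith-Waterman dynamic programming under the scoring of
#' [pairwise_params()]. `N` never matches anything (it scores as a
#' mismatch, including against another `N`), so hard-masked stretches
#' cannot anchor hits. Ties on score are broken deterministically: smaller
#' query start, then smaller subject start, then shorter alignment.
#'
#' @param query,subject nucleotide strings over `A,C,G,T,N`.
#' @param params a [pairwise_params] list.
#' @return `NULL` when no alignment scores above zero; otherwise a one-row
#'   data frame with `q_start`, `q_end`, `s_start`, `s_end` (0-based
#'   half-open), `strand`, `score`, `identity`, `aligned_columns`,
#'   `gapped_columns` and the alignment `path` (`M`/`I`/`D` string).
#' @export
local_align <- function(query, subject, params = pairwise_params()) {
  if (!nzchar(query) || !nzchar(subject)) {
    stop("empty sequence", call. = FALSE)
  }
  res <- .cpp_local_align(toupper(query), toupper(subject),
                          params$match_reward, -params$mismatch_penalty,
                          params$gap_open_cost, params$gap_extend_cost)
  if (!isTRUE(res$found)) return(NULL)
  aligned <- res$n_match + res$n_mismatch
  denom <- if (params$identity_denominator == "columns") aligned else
    aligned + res$n_gap
  data.frame(q_start = res$q_start, q_end = res$q_end,
             s_start = res$s_start, s_end = res$s_end,
             strand = "+", score = res$score,
             identity = res$n_match / denom,
             aligned_columns = aligned, gapped_columns = res$n_gap,
             path = res$path, stringsAsFactors = FALSE)
}

#' Iterative local-alignment hit search between two regions
#'
#' Emulates a BLAST-style search at desk scale: both strands of the subject
#' are aligned against the (pre-masked) query; the best local hit is
#' reported, its query footprint hard-masked with `N`, and the search
#' repeated until the best remaining score falls below `params$min_score`.
#' Hits are then filtered to those with more than `min_hit_length` aligned
#' columns and identity of at least `min_identity`.
#'
#' @param query_region,subject_region nucleotide strings; exon/UTR masking
#'   of the query should already have been applied (see [mask_sequence()]).
#' @param params a [pairwise_params] list.
#' @param query_id,subject_id identifiers carried into the output.
#' @param keep_all also return hits failing the length/identity filters,
#'   flagged by the `retained` column (default `FALSE`).
#' @return Data frame of hits (BLAST tabular-like column order): `query_id`,
#'   `q_start`, `q_end`, `subject_id`, `s_start`, `s_end`, `strand`,
#'   `score`, `identity`, `aligned_columns`, `gapped_columns`, `retained`.
#'   Subject coordinates always refer to the forward strand.
#' @export
find_hits <- function(query_region, subject_region,
                      params = pairwise_params(),
                      query_id = "query", subject_id = "subject",
                      keep_all = FALSE) {
  q <- toupper(query_region)
  s_fwd <- toupper(subject_region)
  s_rev <- reverse_complement(s_fwd)
  m <- nchar(s_fwd)
  hits <- list()
  streak <- 0L
  retain_ok <- function(h) {
    h$aligned_columns > params$min_hit_length &&
      h$identity >= params$min_identity
  }
  repeat {
    h_fwd <- local_align(q, s_fwd, params)
    h_rev <- local_align(q, s_rev, params)
    h <- NULL
    if (!is.null(h_fwd) && (is.null(h_rev) || h_fwd$score >= h_rev$score)) {
      h <- h_fwd
    } else if (!is.null(h_rev)) {
      h <- h_rev
      h$strand <- "-"
      se <- m - h$s_start
      ss <- m - h$s_end
      h$s_start <- ss
      h$s_end <- se
    }
    if (is.null(h) || h$score < params$min_score) break
    hits[[length(hits) + 1L]] <- h
    streak <- if (retain_ok(h)) 0L else streak + 1L
    if (streak >= params$max_nonretained_streak) break
    # hard-mask the query footprint so the region cannot be re-reported
    substr(q, h$q_start + 1L, h$q_end) <-
      strrep("N", h$q_end - h$q_start)
    if (length(hits) > nchar(q)) break  # safety net
  }
  if (!length(hits)) return(empty_hits())
  out <- do.call(rbind, hits)
  out$retained <- out$aligned_columns > params$min_hit_length &
    out$identity >= params$min_identity
  out <- cbind(query_id = query_id, subject_id = subject_id, out,
               stringsAsFactors = FALSE)
  out <- out[, c("query_id", "q_start", "q_end", "subject_id", "s_start",
                 "s_end", "strand", "score", "identity", "aligned_columns",
                 "gapped_columns", "retained")]
  if (!keep_all) out <- out[out$retained, , drop = FALSE]
  out <- out[order(out$q_start, out$s_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_hits <- function() {
  data.frame(query_id = character(), q_start = integer(), q_end = integer(),
             subject_id = character(), s_start = integer(), s_end = integer(),
             strand = character(), score = numeric(), identity = numeric(),
             aligned_columns = integer(), gapped_columns = integer(),
             retained = logical(), stringsAsFactors = FALSE)
}

#' Hard-mask intervals of a sequence with N
#'
#' Used to remove exonic/UTR stretches from a query region before the
#' pairwise search; `N` runs cannot match anything.
#'
#' @param seq nucleotide string.
#' @param intervals `genomic_intervals` data frame in coordinates local to
#'   `seq` (0-based half-open); the `seqid` column is ignored.
#' @export
mask_sequence <- function(seq, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) return(seq)
  n <- nchar(seq)
  for (i in seq_len(nrow(intervals))) {
    a <- max(0L, intervals$start[i])
    b <- min(n, intervals$end[i])
    if (a < b) substr(seq, a + 1L, b) <- strrep("N", b - a)
  }
  seq
}
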