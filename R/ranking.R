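#' Rank contrasts by absolute effect size within each posterior draw
#'
#' Per draw, rank 1 goes to the contrast with the largest absolute ATE
#' (the direction of an effect relative to its reference level is
#' arbitrary, so magnitude is what is ranked).  Ties are broken by item
#' declaration order.
#'
#' @param ate_matrix draws x items matrix of ATE values.
#' @return draws x items integer matrix; each row is a permutation of
#'   `1..n_items`.
#' @export
rank_draws <- function(ate_matrix) {
  if (anyNA(ate_matrix))
    hl_abort("ATE draws contain NA/NaN", "hlmrp_data_error")
  if (ncol(ate_matrix) < 2)
    hl_abort("need at least 2 items to rank", "hlmrp_config_error")
  r <- t(apply(-abs(ate_matrix), 1, rank, ties.method = "first"))
  storage.mode(r) <- "integer"
  colnames(r) <- colnames(ate_matrix)
  r
}

#' Cumulative rank probabilities
#'
#' For item i and rank r, `P[i, r]` is the probability (fraction of
#' draws) that item i achieves rank r or better.
#'
#' @param ranks integer matrix from [rank_draws()].
#' @return An object of class `rank_profile`: list with `items`, `n`,
#'   `prob` (items x ranks matrix of exact rank probabilities) and
#'   `cumulative` (items x ranks cumulative probabilities).
#' @export
cumulative_rank_probs <- function(ranks) {
  n <- ncol(ranks)
  bad <- which(apply(ranks, 1, function(r)
    !all(sort.int(unname(r)) == seq_len(n))))
  if (length(bad))
    hl_abort(sprintf("draw %d is not a rank permutation", bad[1]),
             "hlmrp_data_error")
  items <- colnames(ranks)
  if (is.null(items)) items <- paste0("item", seq_len(n))
  prob <- t(vapply(seq_len(n), function(i)
    tabulate(ranks[, i], nbins = n) / nrow(ranks), numeric(n)))
  cumulative <- t(apply(prob, 1, cumsum))
  dimnames(prob) <- dimnames(cumulative) <- list(items, seq_len(n))
  structure(list(items = items, n = n, prob = prob,
                 cumulative = cumulative),
            class = "rank_profile")
}

#' @export
print.rank_profile <- function(x, ...) {
  cat("Rank profile over", x$n, "items\n")
  invisible(x)
}

#' SUCRA and expected rank
#'
#' The surface under the cumulative ranking curve,
#' `SUCRA_i = sum_{r=1}^{n-1} P[i, r] / (n - 1)`, and the mean rank,
#' `E[rank_i] = n - sum_{r=1}^{n-1} P[i, r]`; the two are linearly
#' related by `E[rank] = n - (n - 1) * SUCRA`.  SUCRA 1 means certainly
#' ranked first, 0 certainly last.
#'
#' @param profile a `rank_profile`.
#' @return Data frame with columns `item`, `sucra`, `expected_rank`
#'   (unrounded), `sucra_pct` (rounded integer percent) and
#'   `expected_rank_r` (rounded integer), following the conventional
#'   report format.
#' @export
sucra <- function(profile) {
  n <- profile$n
  if (n < 2)
    hl_abort("SUCRA needs at least 2 items", "hlmrp_degenerate_error")
  csum <- rowSums(profile$cumulative[, seq_len(n - 1), drop = FALSE])
  s <- csum / (n - 1)
  data.frame(item = profile$items, sucra = s, expected_rank = n - csum,
             sucra_pct = round(100 * s), expected_rank_r = round(n - csum),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Filtered rankogram table
#'
#' Long-format cumulative rank probabilities for the first `top_ranks`
#' positions, keeping only items whose cumulative probability at
#' `top_ranks` reaches `min_prob` (use `min_prob = 0` for the unfiltered
#' table).
#'
#' @param profile a `rank_profile`.
#' @param top_ranks number of leading rank positions (default 4).
#' @param min_prob retention threshold in `[0, 1]` (default 0.25).
#' @return Data frame with columns `item`, `rank`,
#'   `cumulative_probability`.
#' @export
rankogram_table <- function(profile, top_ranks = 4, min_prob = 0.25) {
  if (min_prob < 0 || min_prob > 1)
    hl_abort("min_prob must be in [0, 1]", "hlmrp_config_error")
  if (top_ranks > profile$n)
    hl_abort("top_ranks exceeds item count", "hlmrp_config_error")
  keep <- profile$cumulative[, top_ranks] >= min_prob
  items <- profile$items[keep]
  if (length(items) == 0)
    return(data.frame(item = character(0), rank = integer(0),
                      cumulative_probability = numeric(0)))
  out <- do.call(rbind, lapply(seq_len(top_ranks), function(r)
    data.frame(item = items, rank = r,
               cumulative_probability = profile$cumulative[keep, r],
               stringsAsFactors = FALSE)))
  out <- out[order(match(out$item, profile$items), out$rank), ]
  rownames(out) <- NULL
  out
}
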