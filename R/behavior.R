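#' Subjective embarrassment composite
#'
#' Mean of the two post-playback ratings ("how ashamed", "how stressful"),
#' each on the 0-4 (none-highly) scale.
#'
#' @param item1,item2 ratings in [0, 4]; vectorized.
#' @return composite in [0, 4].
#' @export
embarrassment_composite <- function(item1, item2) {
  if (any(item1 < 0 | item1 > 4 | item2 < 0 | item2 > 4, na.rm = TRUE))
    stop("ratings must lie in [0, 4]")
  (item1 + item2) / 2
}

#' Score a cued-recall response
#'
#' Deterministic scoring of manually categorized responses: an exact target
#' word scores 1 point, a synonym or a higher/lower abstraction scores 0.5,
#' anything else 0. The linguistic judgment itself (is "bug" a synonym of
#' "insect"?) is an input category, mirroring manual scoring.
#'
#' @param category `"exact"`, `"synonym_or_abstraction"` or `"other"`;
#'   vectorized.
#' @return score in \{0, 0.5, 1\}.
#' @export
score_response <- function(category) {
  scores <- c(exact = 1, synonym_or_abstraction = 0.5, other = 0)
  bad <- setdiff(unique(category), names(scores))
  if (length(bad) > 0)
    stop("unknown response category: ", paste(bad, collapse = ", "))
  unname(scores[category])
}

#' Session recall percentage
#'
#' @param scores item scores in \{0, 0.5, 1\} for the tested items.
#' @return 100 times the mean score.
#' @export
recall_percentage <- function(scores) {
  stopifnot(length(scores) > 0, all(scores %in% c(0, 0.5, 1)))
  100 * mean(scores)
}

#' Split 60 items into two ease-matched 30-item subsets
#'
#' Partitions the items into pre- and postsleep recall subsets matched on
#' the normative ease dimension: items are sorted by ease and consecutive
#' pairs are assigned to alternating subsets (the top pair splits A/B, the
#' next B/A, and so on), which nearly cancels the mean difference. The
#' balance report carries the subset means, ranges and a Welch two-sample
#' t-test; the partition is accepted when the t-test p-value exceeds
#' `p_accept`.
#'
#' @param ease numeric vector of exactly 60 normative ease values.
#' @param p_accept minimal t-test p-value for acceptance.
#' @return list with `subset_a`, `subset_b` (item indices), `means`,
#'   `ranges`, `p_value`, `accepted`.
#' @export
match_subsets <- function(ease, p_accept = 0.05) {
  if (length(ease) != 60) stop("exactly 60 ease values are required")
  ord <- order(ease, decreasing = TRUE)
  a <- integer(0); b <- integer(0)
  for (k in seq_len(30)) {
    pair <- ord[c(2 * k - 1, 2 * k)]
    if (k %% 2 == 1) { a <- c(a, pair[1]); b <- c(b, pair[2]) }
    else             { a <- c(a, pair[2]); b <- c(b, pair[1]) }
  }
  means <- c(a = mean(ease[a]), b = mean(ease[b]))
  p <- if (stats::sd(ease) == 0) 1 else
    stats::t.test(ease[a], ease[b])$p.value
  list(subset_a = sort(a), subset_b = sort(b), means = means,
       ranges = rbind(a = range(ease[a]), b = range(ease[b])),
       p_value = p, accepted = p > p_accept)
}

#' Counterbalanced subset-order assignment
#'
#' Alternates which matched subset is tested pre-sleep across participants,
#' keeping the order assignment balanced within one participant.
#'
#' @param n_participants number of participants.
#' @return character vector of `"AB"`/`"BA"` order labels.
#' @export
counterbalance_orders <- function(n_participants) {
  rep(c("AB", "BA"), length.out = n_participants)
}
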