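# Quantitative scoring: ipsative defense/level/category percentages and the
# Overall Defensive Functioning (ODF) index.
#
# Each defense owns 5 items. With rank capacities (60,30,20,16,10,8,6) the
# total rank mass of a valid sort is fixed at
#   60*1 + 30*2 + 20*3 + 16*4 + 10*5 + 8*6 + 6*7 = 384,
# so subtracting the minimum contribution (5 items * rank 1) per defense and
# summing over the 30 defenses leaves 384 - 150 = 234: the normalizer that
# makes the 30 defense percentages sum to exactly 100 on every valid sort.

#' Scoring normalizer implied by a forced distribution
#'
#' Total rank mass minus the number of items (234 for the default
#' distribution). Asserted against the packaged constant on every scoring
#' call; non-default distributions recompute it.
#'
#' @param dist A \code{dmrsq_distribution}.
#' @return A single number.
#' @export
score_normalizer <- function(dist = forced_distribution()) {
  sum(dist$capacities * dist$ranks) - dist$n_items
}

#' Individual defense scores
#'
#' For defense d with item set I_d, the ipsative percentage is
#' \deqn{score_d = (\sum_{i \in I_d} rank_i - 5) \times 100 / 234.}
#' A defense whose five items all sit in rank 1 scores 0; the attainable
#' per-defense maximum (all five items in rank 7) is 30 x 100 / 234 = 12.82.
#' Scores over the 30 defenses always sum to 100.
#'
#' @param sort A complete \code{dmrsq_sort}; scoring is refused (with the
#'   validation report attached to the error) if the sort does not satisfy
#'   the forced distribution.
#' @param bank A \code{dmrsq_bank}.
#' @param dist A \code{dmrsq_distribution}; a warning is issued for
#'   non-default distributions, whose scores have no published semantics.
#' @return Named numeric vector of percentages over \code{D1..D30}.
#' @examples
#' bank <- load_item_bank()
#' s <- random_sort(seed = 1)
#' sum(score_defenses(s, bank))  # 100
#' @export
score_defenses <- function(sort, bank, dist = forced_distribution()) {
  v <- validate_sort(sort, dist)
  if (!v$ok) {
    stop(invalid_sort_condition(v, "scoring refused, sort is invalid"))
  }
  if (!is_default_distribution(dist)) {
    warning("scoring a non-default forced distribution: ",
            "percentages have no published interpretation", call. = FALSE)
  }
  norm <- score_normalizer(dist)
  ranks <- rank_vector(sort, dist)
  ids <- bank$defenses$defense_id
  scores <- vapply(ids, function(d) {
    items <- items_for_defense(bank, d)
    (sum(ranks[items]) - length(items)) * 100 / norm
  }, numeric(1))
  stats::setNames(scores, ids)
}

#' Defense level scores
#'
#' Sums defense percentages into the seven adaptiveness levels, plus the
#' neurotic sublevels L5a (hysterical: dissociation + repression) and L5b
#' (other neurotic: displacement + reaction formation).
#'
#' @param defense_scores Named numeric vector over \code{D1..D30}, as
#'   returned by [score_defenses()].
#' @return Named numeric vector over \code{L1..L7, L5a, L5b}.
#' @export
score_levels <- function(defense_scores) {
  hier <- defense_hierarchy()
  d <- defense_scores[hier$defense_id]
  by_level <- vapply(paste0("L", 1:7), function(l) {
    sum(d[hier$defense_id[hier$level_id == l]])
  }, numeric(1))
  l5a <- sum(d[hier$defense_id[hier$sublevel == "L5a"]])
  l5b <- sum(d[hier$defense_id[hier$sublevel == "L5b"]])
  c(by_level, L5a = l5a, L5b = l5b)
}

#' Defensive category scores
#'
#' The tripartite maturity summary: C1 immature (levels 1-4), C2 neurotic
#' (levels 5-6), C3 mature (level 7); C1 splits into C1a depressive and C1b
#' other-immature defenses.
#'
#' @param defense_scores Named numeric vector over \code{D1..D30}.
#' @return Named numeric vector over \code{C1, C2, C3, C1a, C1b}.
#' @export
score_categories <- function(defense_scores) {
  hier <- defense_hierarchy()
  d <- defense_scores[hier$defense_id]
  cat_sum <- function(ids) sum(d[ids])
  c(C1 = cat_sum(hier$defense_id[hier$category_id == "C1"]),
    C2 = cat_sum(hier$defense_id[hier$category_id == "C2"]),
    C3 = cat_sum(hier$defense_id[hier$category_id == "C3"]),
    C1a = cat_sum(hier$defense_id[hier$subcategory == "C1a"]),
    C1b = cat_sum(hier$defense_id[hier$subcategory == "C1b"]))
}

#' Overall Defensive Functioning
#'
#' The level-weighted mean of defensive mass on the 1-7 adaptiveness scale:
#' \deqn{ODF = \sum_{l=1}^{7} (L_l / 100) \cdot l.}
#' Values below 4 are typical of severe depression or personality
#' pathology; the attainable extremes under the default forced distribution
#' are 553/234 (2.36) and 1513/234 (6.47).
#'
#' @param level_scores Named numeric vector including \code{L1..L7}, as
#'   returned by [score_levels()].
#' @return A single number on the 1-7 scale.
#' @export
compute_odf <- function(level_scores) {
  sum(level_scores[paste0("L", 1:7)] / 100 * (1:7))
}

#' Full quantitative defensive profile
#'
#' Composes defense, level and category scoring with the ODF into one
#' internally consistent profile object.
#'
#' @inheritParams score_defenses
#' @return An object of class \code{dmrsq_profile}: list with elements
#'   \code{defense_scores}, \code{level_scores}, \code{category_scores},
#'   \code{odf}, \code{odf_below_4} (advisory flag) and \code{meta}.
#' @examples
#' bank <- load_item_bank()
#' p <- full_profile(random_sort(seed = 7), bank)
#' p$odf
#' @export
full_profile <- function(sort, bank, dist = forced_distribution()) {
  d <- score_defenses(sort, bank, dist)
  l <- score_levels(d)
  cc <- score_categories(d)
  odf <- compute_odf(l)
  structure(
    list(defense_scores = d, level_scores = l, category_scores = cc,
         odf = odf, odf_below_4 = odf < 4, meta = sort$meta),
    class = "dmrsq_profile")
}

#' @export
print.dmrsq_profile <- function(x, digits = 2, ...) {
  cat("DMRS-Q defensive profile\n")
  cat(sprintf("  ODF: %.*f (1-7 adaptiveness scale)%s\n", digits, x$odf,
              if (x$odf_below_4) "  [below 4: range typical of severe depression/personality pathology]" else ""))
  cat(sprintf("  Categories: mature %.*f%%, neurotic %.*f%%, immature %.*f%% (depressive %.*f%%)\n",
              digits, x$category_scores[["C3"]], digits, x$category_scores[["C2"]],
              digits, x$category_scores[["C1"]], digits, x$category_scores[["C1a"]]))
  lv <- x$level_scores[paste0("L", 1:7)]
  cat("  Levels (%):", paste(sprintf("%s=%.*f", names(lv), digits, lv),
                             collapse = " "), "\n")
  top <- sort(x$defense_scores, decreasing = TRUE)[1:3]
  cat("  Top defenses:", paste(sprintf("%s (%.*f%%)", names(top), digits, top),
                               collapse = ", "), "\n")
  invisible(x)
}
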