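# Shared fixtures for the dmrsq test suite.

the_bank <- load_item_bank()
the_dist <- forced_distribution()

# Case-fold and strip everything but letters/digits: compares statement
# content while ignoring typographic quote/punctuation variants.
normalize_statement <- function(x) {
  gsub("[^a-z0-9]", "", tolower(x))
}

# A valid sort that places `top_items` in the two highest ranks (the last
# length-6 block at rank 7, the first length-8 block at rank 6) and fills
# the remaining items downward in ascending id order.
sort_with_top_items <- function(top_items, dist = the_dist) {
  stopifnot(length(top_items) == sum(utils::tail(dist$capacities, 2)))
  rest <- setdiff(seq_len(dist$n_items), top_items)
  ordered <- c(top_items, rest)  # filled rank 7 down to rank 1
  ranks <- integer(dist$n_items)
  pos <- 1L
  for (r in rev(dist$ranks)) {
    cap <- dist$capacities[[as.character(r)]]
    ranks[ordered[pos:(pos + cap - 1L)]] <- r
    pos <- pos + cap
  }
  from_rank_vector(ranks, dist = dist)
}

# Independent item-level ODF oracle: each item contributes its defense's
# adaptiveness level weighted by its rank; 675 = 5 * sum of the 30 levels.
item_level_odf <- function(sort, bank = the_bank) {
  lev <- as.integer(sub("^L", "", bank$items$level_id))
  ranks <- rank_vector(sort)
  (sum(lev * ranks) - 5 * sum(tapply(lev, bank$items$defense_id, unique))) /
    score_normalizer()
}
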