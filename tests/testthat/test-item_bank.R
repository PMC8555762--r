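test_that("the default bank has 150 items partitioned 5-per-defense over 30 defenses", {
  expect_s3_class(the_bank, "dmrsq_bank")
  expect_equal(nrow(the_bank$items), 150)
  expect_equal(nrow(the_bank$defenses), 30)
  counts <- table(the_bank$items$defense_id)
  expect_true(all(counts == 5))
  # bijection: concatenating the per-defense item lists recovers 1..150
  all_items <- unlist(lapply(the_bank$defenses$defense_id,
                             function(d) items_for_defense(the_bank, d)))
  expect_setequal(all_items, 1:150)
  expect_equal(anyDuplicated(all_items), 0)
})

test_that("levels and categories partition the 30 defenses as the hierarchy requires", {
  hier <- the_bank$defenses
  level_counts <- table(hier$level_id)
  expect_equal(as.integer(level_counts[paste0("L", 1:7)]),
               c(3, 3, 4, 5, 4, 3, 8))
  expect_equal(sum(level_counts), 30)
  cat_counts <- table(hier$category_id)
  expect_equal(as.integer(cat_counts[c("C1", "C2", "C3")]), c(15, 7, 8))
  # C1a and C1b partition C1
  c1 <- hier$defense_id[hier$category_id == "C1"]
  c1a <- hier$defense_id[hier$subcategory == "C1a"]
  c1b <- hier$defense_id[hier$subcategory == "C1b"]
  expect_setequal(c(c1a, c1b), c1)
  expect_length(intersect(c1a, c1b), 0)
  expect_setequal(c1a, c("D1", "D2", "D3", "D4", "D5", "D6", "D8", "D14", "D15"))
  # sublevels cover exactly the neurotic level
  expect_setequal(hier$defense_id[hier$sublevel %in% c("L5a", "L5b")],
                  hier$defense_id[hier$level_id == "L5"])
  expect_setequal(hier$defense_id[hier$sublevel == "L5a"], c("D18", "D19"))
})

test_that("item -> defense lookup matches the published scoring grid", {
  cases <- list(
    list(item = 49, defense = "D30", name = "Suppression"),
    list(item = 5, defense = "D1", name = "Acting out"),
    list(item = 114, defense = "D4", name = "Splitting of other's image"),
    list(item = 145, defense = "D5", name = "Splitting of self-image"),
    list(item = 84, defense = "D2", name = "Help-rejecting complaining")
  )
  for (cs in cases) {
    d <- defense_for_item(the_bank, cs$item)
    expect_equal(d$defense_id, cs$defense)
    expect_equal(d$defense_name, cs$name)
  }
  expect_error(defense_for_item(the_bank, 0), "item_id")
  expect_error(defense_for_item(the_bank, 151), "item_id")
})

test_that("per-defense item lists are the published five-item sets, ascending", {
  expect_equal(items_for_defense(the_bank, "D1"), c(5, 76, 80, 118, 144))
  expect_equal(items_for_defense(the_bank, "D30"), c(49, 117, 128, 131, 150))
  expect_equal(items_for_defense(the_bank, "D5"), c(3, 6, 98, 142, 145))
  expect_equal(items_for_defense(the_bank, "D4"), c(35, 61, 92, 94, 114))
  expect_error(items_for_defense(the_bank, "D31"), "unknown defense")
})

test_that("corrupted bank files raise integrity errors naming the culprit", {
  base <- the_bank$items
  write_tmp <- function(items) {
    path <- tempfile(fileext = ".csv")
    items$placeholder <- ifelse(items$placeholder, "TRUE", "FALSE")
    utils::write.csv(items, path, row.names = FALSE, fileEncoding = "UTF-8")
    path
  }
  # item 5 listed under two defenses
  dup <- base
  dup$item_id[dup$item_id == 6] <- 5L
  expect_error(load_item_bank(write_tmp(dup)), "item.*5")
  # only 4 items for D24
  short <- base[base$item_id != 79, ]
  expect_error(load_item_bank(write_tmp(short)), "missing: 79")
  # hierarchy code inconsistent with the defense
  bad <- base
  bad$level_id[bad$item_id == 49] <- "L1"
  expect_error(load_item_bank(write_tmp(bad)), "item 49.*level_id")
  # missing column
  nocol <- base[, setdiff(names(base), "text")]
  expect_error(load_item_bank(write_tmp(nocol)), "missing column")
})

test_that("the bank round-trips through csv and json", {
  for (fmt in c("csv", "json")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_item_bank(the_bank, path, format = fmt)
    again <- load_item_bank(path)
    expect_equal(again$items, the_bank$items)
  }
})

test_that("the one placeholder statement is flagged and still scored", {
  ph <- the_bank$items[the_bank$items$placeholder, ]
  expect_equal(ph$item_id, 79)
  expect_equal(ph$defense_id, "D24")
  expect_true(nzchar(ph$text))
  # item 79 contributes to D24 like any other item
  s <- sort_with_top_items(c(items_for_defense(the_bank, "D24"),
                             setdiff(1:14, items_for_defense(the_bank, "D24"))[1:9]))
  d <- score_defenses(s, the_bank)
  expect_gt(d[["D24"]], 10)
})
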