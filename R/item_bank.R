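# Item bank: the 150-item instrument and the defense hierarchy it maps onto.
#
# The packaged bank file (inst/extdata/dmrsq_item_bank.csv) is the single
# source of truth for item -> defense membership; the hierarchy scaffolding
# below (defense -> level -> category) is fixed by the instrument and is used
# to integrity-check every loaded bank, never inferred from item ordering.

#' Canonical defense hierarchy
#'
#' The 30 defense mechanisms with their level, sublevel, category and
#' subcategory assignments. Defenses are numbered D1 (Acting out, least
#' adaptive) through D30 (Suppression, most adaptive). Levels run L1 (Action)
#' to L7 (High adaptive); the neurotic level L5 splits into L5a (hysterical:
#' dissociation, repression) and L5b (other neurotic: displacement, reaction
#' formation). Categories are C1 immature (levels 1-4), C2 neurotic
#' (levels 5-6) and C3 mature (level 7); C1 splits into C1a depressive and
#' C1b other-immature defenses.
#'
#' @return A data.frame with one row per defense and columns
#'   \code{defense_id}, \code{defense_name}, \code{level_id},
#'   \code{level_name}, \code{sublevel}, \code{category_id},
#'   \code{subcategory}.
#' @export
defense_hierarchy <- function() {
  def <- function(id, name, level) list(id = id, name = name, level = level)
  rows <- list(
    def("D1",  "Acting out",                    "L1"),
    def("D2",  "Help-rejecting complaining",    "L1"),
    def("D3",  "Passive aggression",            "L1"),
    def("D4",  "Splitting of other's image",    "L2"),
    def("D5",  "Splitting of self-image",       "L2"),
    def("D6",  "Projective identification",     "L2"),
    def("D7",  "Autistic fantasy",              "L3"),
    def("D8",  "Projection",                    "L3"),
    def("D9",  "Rationalization",               "L3"),
    def("D10", "Denial",                        "L3"),
    def("D11", "Omnipotence",                   "L4"),
    def("D12", "Idealization of self-image",    "L4"),
    def("D13", "Idealization of other's image", "L4"),
    def("D14", "Devaluation of self-image",     "L4"),
    def("D15", "Devaluation of other's image",  "L4"),
    def("D16", "Displacement",                  "L5"),
    def("D17", "Reaction formation",            "L5"),
    def("D18", "Dissociation",                  "L5"),
    def("D19", "Repression",                    "L5"),
    def("D20", "Undoing",                       "L6"),
    def("D21", "Intellectualization",           "L6"),
    def("D22", "Isolation of affects",          "L6"),
    def("D23", "Affiliation",                   "L7"),
    def("D24", "Altruism",                      "L7"),
    def("D25", "Anticipation",                  "L7"),
    def("D26", "Humor",                         "L7"),
    def("D27", "Self-assertion",                "L7"),
    def("D28", "Self-observation",              "L7"),
    def("D29", "Sublimation",                   "L7"),
    def("D30", "Suppression",                   "L7")
  )
  level_names <- c(
    L1 = "Action", L2 = "Major image-distorting", L3 = "Disavowal",
    L4 = "Minor image-distorting", L5 = "Neurotic", L6 = "Obsessional",
    L7 = "High adaptive"
  )
  sublevels <- c(D18 = "L5a", D19 = "L5a", D16 = "L5b", D17 = "L5b")
  depressive <- c("D1", "D2", "D3", "D4", "D5", "D6", "D8", "D14", "D15")
  categories <- c(L1 = "C1", L2 = "C1", L3 = "C1", L4 = "C1",
                  L5 = "C2", L6 = "C2", L7 = "C3")

  out <- data.frame(
    defense_id   = vapply(rows, `[[`, "", "id"),
    defense_name = vapply(rows, `[[`, "", "name"),
    level_id     = vapply(rows, `[[`, "", "level"),
    stringsAsFactors = FALSE
  )
  out$level_name  <- unname(level_names[out$level_id])
  out$sublevel    <- ifelse(out$defense_id %in% names(sublevels),
                            unname(sublevels[out$defense_id]), "")
  out$category_id <- unname(categories[out$level_id])
  out$subcategory <- ifelse(out$category_id == "C1",
                            ifelse(out$defense_id %in% depressive, "C1a", "C1b"),
                            "")
  out
}

# Numeric adaptiveness level (1..7) per defense id, used by the ODF weighting.
defense_level_number <- function(defense_id) {
  hier <- defense_hierarchy()
  as.integer(sub("^L", "", hier$level_id[match(defense_id, hier$defense_id)]))
}

bank_columns <- c("item_id", "defense_id", "defense_name", "level_id",
                  "level_name", "sublevel", "category_id", "subcategory",
                  "placeholder", "text")

#' Load and integrity-check an item bank
#'
#' Reads the packaged 150-item bank (the default) or a user-supplied bank
#' file in the same delimited or JSON format, and checks every structural
#' invariant eagerly: 150 items, 30 defenses owning exactly 5 items each,
#' item ids forming 1..150 with no duplicates, and per-item hierarchy codes
#' consistent with [defense_hierarchy()].
#'
#' @param source Path to a bank file (\code{.csv} or \code{.json}). When
#'   \code{NULL}, the bank shipped with the package is used.
#' @return An object of class \code{dmrsq_bank}: a list with elements
#'   \code{items} (data.frame, one row per item), \code{defenses}
#'   (the hierarchy table), \code{version} and \code{language}.
#' @examples
#' bank <- load_item_bank()
#' nrow(bank$items)
#' @export
load_item_bank <- function(source = NULL) {
  if (is.null(source)) {
    source <- system.file("extdata", "dmrsq_item_bank.csv", package = "dmrsq",
                          mustWork = TRUE)
  }
  if (!file.exists(source)) {
    stop(sprintf("item bank file not found: %s", source), call. = FALSE)
  }
  items <- if (grepl("\\.json$", source, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(source)$items, stringsAsFactors = FALSE)
  } else {
    tryCatch(
      utils::read.csv(source, stringsAsFactors = FALSE, encoding = "UTF-8",
                      colClasses = "character"),
      error = function(e) stop(sprintf("malformed bank file %s: %s",
                                       source, conditionMessage(e)),
                               call. = FALSE)
    )
  }
  missing_cols <- setdiff(bank_columns, names(items))
  if (length(missing_cols) > 0) {
    stop(sprintf("malformed bank file: missing column(s) %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  items <- items[, bank_columns]
  items$item_id <- suppressWarnings(as.integer(items$item_id))
  if (anyNA(items$item_id)) {
    stop(sprintf("malformed bank file: non-integer item_id at row(s) %s",
                 paste(which(is.na(items$item_id)), collapse = ", ")),
         call. = FALSE)
  }
  items$placeholder <- toupper(items$placeholder) == "TRUE"
  items <- items[order(items$item_id), ]
  rownames(items) <- NULL

  bank <- structure(
    list(items = items, defenses = defense_hierarchy(),
         version = "1.0", language = "en"),
    class = "dmrsq_bank"
  )
  validate_item_bank(bank)
  bank
}

#' Check item-bank integrity
#'
#' @param bank A \code{dmrsq_bank} object.
#' @return The bank, invisibly; an integrity error naming the offending
#'   defense or item is raised on any violation.
#' @export
validate_item_bank <- function(bank) {
  items <- bank$items
  hier <- bank$defenses
  n_expected <- 150L

  dup <- unique(items$item_id[duplicated(items$item_id)])
  if (length(dup) > 0) {
    stop(sprintf("bank integrity error: item(s) %s listed under more than one defense",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  if (nrow(items) != n_expected ||
      !setequal(items$item_id, seq_len(n_expected))) {
    missing <- setdiff(seq_len(n_expected), items$item_id)
    extra <- setdiff(items$item_id, seq_len(n_expected))
    stop(sprintf(
      "bank integrity error: expected items 1..%d exactly once (missing: %s; unexpected: %s)",
      n_expected,
      if (length(missing)) paste(missing, collapse = ", ") else "none",
      if (length(extra)) paste(extra, collapse = ", ") else "none"),
      call. = FALSE)
  }
  unknown <- setdiff(items$defense_id, hier$defense_id)
  if (length(unknown) > 0) {
    stop(sprintf("bank integrity error: unknown defense code(s) %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  counts <- table(factor(items$defense_id, levels = hier$defense_id))
  bad <- names(counts)[counts != 5L]
  if (length(bad) > 0) {
    stop(sprintf("bank integrity error: defense %s owns %s items (5 required)",
                 bad[1], counts[bad[1]]), call. = FALSE)
  }
  # per-item hierarchy codes must agree with the canonical defense table
  ref <- hier[match(items$defense_id, hier$defense_id), ]
  for (col in c("defense_name", "level_id", "level_name", "sublevel",
                "category_id", "subcategory")) {
    mism <- which(items[[col]] != ref[[col]])
    if (length(mism) > 0) {
      stop(sprintf("bank integrity error: item %d has %s = '%s', expected '%s'",
                   items$item_id[mism[1]], col, items[[col]][mism[1]],
                   ref[[col]][mism[1]]), call. = FALSE)
    }
  }
  if (any(!nzchar(items$text))) {
    stop(sprintf("bank integrity error: empty statement text for item %d",
                 items$item_id[which(!nzchar(items$text))[1]]), call. = FALSE)
  }
  invisible(bank)
}

#' Write an item bank to disk
#'
#' @param bank A \code{dmrsq_bank}.
#' @param path Output file path.
#' @param format \code{"csv"} (delimited, one row per item) or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
write_item_bank <- function(bank, path, format = c("csv", "json")) {
  format <- match.arg(format)
  items <- bank$items
  if (format == "csv") {
    items$placeholder <- ifelse(items$placeholder, "TRUE", "FALSE")
    utils::write.csv(items, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(
      list(version = bank$version, language = bank$language, items = items),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Look up the defense owning an item
#'
#' @param bank A \code{dmrsq_bank}.
#' @param item_id Integer item id in 1..150.
#' @return A one-row data.frame describing the owning defense (id, name,
#'   level, sublevel, category, subcategory).
#' @examples
#' bank <- load_item_bank()
#' defense_for_item(bank, 49)$defense_id  # "D30"
#' @export
defense_for_item <- function(bank, item_id) {
  item_id <- as.integer(item_id)
  if (length(item_id) != 1L || is.na(item_id) ||
      !item_id %in% bank$items$item_id) {
    stop(sprintf("item_id must be a single integer in 1..%d",
                 nrow(bank$items)), call. = FALSE)
  }
  did <- bank$items$defense_id[bank$items$item_id == item_id]
  bank$defenses[bank$defenses$defense_id == did, ]
}

#' List the five items belonging to a defense
#'
#' @param bank A \code{dmrsq_bank}.
#' @param defense_id A code in \code{D1..D30}.
#' @return An ascending integer vector of the 5 item ids.
#' @examples
#' bank <- load_item_bank()
#' items_for_defense(bank, "D1")  # 5 76 80 118 144
#' @export
items_for_defense <- function(bank, defense_id) {
  if (length(defense_id) != 1L || !defense_id %in% bank$defenses$defense_id) {
    stop(sprintf("unknown defense code: %s",
                 paste(defense_id, collapse = ", ")), call. = FALSE)
  }
  sort(bank$items$item_id[bank$items$defense_id == defense_id])
}

#' @export
print.dmrsq_bank <- function(x, ...) {
  cat(sprintf("DMRS-Q item bank (version %s, language %s)\n",
              x$version, x$language))
  cat(sprintf("  %d items across %d defenses, %d levels, %d categories\n",
              nrow(x$items), nrow(x$defenses),
              length(unique(x$defenses$level_id)),
              length(unique(x$defenses$category_id))))
  n_ph <- sum(x$items$placeholder)
  if (n_ph > 0) {
    cat(sprintf("  %d item(s) carry placeholder statement text: %s\n", n_ph,
                paste(x$items$item_id[x$items$placeholder], collapse = ", ")))
  }
  invisible(x)
}
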