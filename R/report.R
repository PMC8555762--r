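# Qualitative Defensive Profile Narrative (DPN) and combined report rendering.

#' Build the Defensive Profile Narrative
#'
#' The DPN comprises every item placed in the two highest ranks (ranks 6 and
#' 7 under the default distribution: 8 + 6 = 14 items), each labeled with
#' its defense and level. Entries are ordered rank 7 ("almost always used")
#' first, then rank 6, ascending item id within rank, so the narrative is a
#' deterministic function of the sort.
#'
#' @param sort A complete, valid \code{dmrsq_sort}.
#' @param bank A \code{dmrsq_bank}.
#' @param dist A \code{dmrsq_distribution}.
#' @return An object of class \code{dmrsq_dpn}: list with \code{entries}
#'   (data.frame: item_id, rank, defense_id, defense_name, level_id,
#'   level_name, statement) and \code{narrative} (the statements joined
#'   into one paragraph).
#' @export
build_dpn <- function(sort, bank, dist = forced_distribution()) {
  v <- validate_sort(sort, dist)
  if (!v$ok) {
    stop(invalid_sort_condition(v, "DPN refused, sort is invalid"))
  }
  top_ranks <- sort(utils::tail(dist$ranks, 2))  # 6 and 7 by default
  ranks <- rank_vector(sort, dist)
  keep <- which(ranks %in% top_ranks)
  items <- bank$items[match(keep, bank$items$item_id), ]
  entries <- data.frame(
    item_id = items$item_id,
    rank = ranks[keep],
    defense_id = items$defense_id,
    defense_name = items$defense_name,
    level_id = items$level_id,
    level_name = items$level_name,
    statement = items$text,
    stringsAsFactors = FALSE
  )
  entries <- entries[order(-entries$rank, entries$item_id), ]
  rownames(entries) <- NULL
  structure(list(entries = entries,
                 narrative = paste(entries$statement, collapse = " ")),
            class = "dmrsq_dpn")
}

#' @export
print.dmrsq_dpn <- function(x, ...) {
  cat(sprintf("Defensive Profile Narrative (%d statements)\n",
              nrow(x$entries)))
  for (i in seq_len(nrow(x$entries))) {
    e <- x$entries[i, ]
    cat(sprintf("  [rank %d, %s / %s] item %d\n", e$rank, e$level_name,
                e$defense_name, e$item_id))
  }
  invisible(x)
}

#' Assemble the combined qualitative + quantitative assessment report
#'
#' @param sort A complete, valid \code{dmrsq_sort}.
#' @param bank A \code{dmrsq_bank}.
#' @param dist A \code{dmrsq_distribution}.
#' @param meta Optional named list of report metadata; defaults to the
#'   sort's own metadata.
#' @return An object of class \code{dmrsq_report}: list with \code{meta},
#'   \code{dpn} and \code{profile}, all derived from the same sort.
#' @export
assessment_report <- function(sort, bank, dist = forced_distribution(),
                              meta = NULL) {
  structure(
    list(meta = if (is.null(meta)) sort$meta else meta,
         dpn = build_dpn(sort, bank, dist),
         profile = full_profile(sort, bank, dist)),
    class = "dmrsq_report")
}

# flat one-row-per-scale table: 30 defenses + 9 levels + 5 categories + ODF
score_table <- function(profile) {
  rbind(
    data.frame(scale = "defense", label = names(profile$defense_scores),
               score = unname(profile$defense_scores)),
    data.frame(scale = "level", label = names(profile$level_scores),
               score = unname(profile$level_scores)),
    data.frame(scale = "category", label = names(profile$category_scores),
               score = unname(profile$category_scores)),
    data.frame(scale = "odf", label = "ODF", score = profile$odf)
  )
}

#' Render an assessment report
#'
#' Three deterministic serializations: \code{"json"} (structured, lossless,
#' round-trips through [parse_report()]), \code{"markdown"} (DPN paragraph
#' followed by score tables; percentages and ODF to 2 decimals) and
#' \code{"csv"} (the flat score table: 30 defense + 9 level + 5 category +
#' 1 ODF rows).
#'
#' @param report A \code{dmrsq_report}.
#' @param format One of \code{"json"}, \code{"markdown"}, \code{"csv"}.
#' @return A single character string (the document).
#' @export
render_report <- function(report, format = c("json", "markdown", "csv")) {
  format <- match.arg(format)
  p <- report$profile
  if (format == "json") {
    doc <- list(
      meta = report$meta,
      dpn = list(entries = report$dpn$entries,
                 narrative = report$dpn$narrative),
      profile = list(defense_scores = as.list(p$defense_scores),
                     level_scores = as.list(p$level_scores),
                     category_scores = as.list(p$category_scores),
                     odf = p$odf, odf_below_4 = p$odf_below_4)
    )
    return(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                         pretty = TRUE)))
  }
  if (format == "csv") {
    con <- textConnection("out", "w", local = TRUE)
    utils::write.csv(score_table(p), con, row.names = FALSE)
    close(con)
    return(paste0(paste(out, collapse = "\n"), "\n"))
  }
  # markdown
  lines <- c("# DMRS-Q assessment report", "")
  if (length(report$meta) > 0) {
    lines <- c(lines,
               paste0("- ", names(report$meta), ": ", unlist(report$meta)), "")
  }
  lines <- c(lines, "## Defensive Profile Narrative", "",
             report$dpn$entries$statement, "",
             "## Overall Defensive Functioning", "",
             sprintf("ODF = %.2f on the 1-7 adaptiveness scale%s", p$odf,
                     if (p$odf_below_4)
                       " (below 4: range typical of severe depression or personality pathology)"
                     else ""),
             "", "## Category scores (%)", "",
             "| category | score |", "|---|---|",
             sprintf("| %s | %.2f |", names(p$category_scores),
                     p$category_scores),
             "", "## Level scores (%)", "",
             "| level | score |", "|---|---|",
             sprintf("| %s | %.2f |", names(p$level_scores), p$level_scores),
             "", "## Individual defense scores (%)", "",
             "| defense | score |", "|---|---|",
             sprintf("| %s | %.2f |", names(p$defense_scores),
                     p$defense_scores))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Parse a JSON report back into a report object
#'
#' Inverse of \code{render_report(report, "json")}.
#'
#' @param text JSON document string (or path to one).
#' @return A \code{dmrsq_report}.
#' @export
parse_report <- function(text) {
  doc <- jsonlite::fromJSON(text)
  entries <- as.data.frame(doc$dpn$entries, stringsAsFactors = FALSE)
  profile <- structure(
    list(defense_scores = unlist(doc$profile$defense_scores),
         level_scores = unlist(doc$profile$level_scores),
         category_scores = unlist(doc$profile$category_scores),
         odf = doc$profile$odf,
         odf_below_4 = doc$profile$odf_below_4,
         meta = as.list(doc$meta)),
    class = "dmrsq_profile")
  structure(
    list(meta = as.list(doc$meta),
         dpn = structure(list(entries = entries,
                              narrative = doc$dpn$narrative),
                         class = "dmrsq_dpn"),
         profile = profile),
    class = "dmrsq_report")
}

#' @export
print.dmrsq_report <- function(x, ...) {
  cat("DMRS-Q assessment report\n")
  print(x$dpn)
  print(x$profile)
  invisible(x)
}
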