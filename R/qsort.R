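# Forced-distribution Q-sorts: representation, validation, file I/O.

#' Forced distribution of rank capacities
#'
#' The instrument's fixed pile sizes. Rank 1 ("not used at all") holds 60
#' items and successive ranks shrink through rank 7 ("almost always used",
#' 6 items). Custom distributions are accepted for research variants, but
#' only the default carries published scoring semantics; scoring warns on
#' any other distribution.
#'
#' @param capacities Named integer vector mapping rank to required item
#'   count. Ranks must be consecutive integers starting at 1 and capacities
#'   must strictly decrease above rank 1.
#' @return An object of class \code{dmrsq_distribution}.
#' @examples
#' forced_distribution()  # 60 30 20 16 10 8 6
#' @export
forced_distribution <- function(capacities = c(`1` = 60L, `2` = 30L, `3` = 20L,
                                               `4` = 16L, `5` = 10L, `6` = 8L,
                                               `7` = 6L)) {
  caps <- as.integer(capacities)
  ranks <- as.integer(names(capacities))
  if (anyNA(ranks) || !identical(ranks, seq_along(ranks))) {
    stop("capacities must be named by consecutive ranks starting at 1",
         call. = FALSE)
  }
  if (anyNA(caps) || any(caps <= 0L)) {
    stop("all rank capacities must be positive integers", call. = FALSE)
  }
  if (length(caps) > 2 && any(diff(caps[-1]) >= 0L)) {
    stop("capacities must strictly decrease above rank 1", call. = FALSE)
  }
  structure(list(capacities = stats::setNames(caps, ranks),
                 ranks = ranks, n_items = sum(caps)),
            class = "dmrsq_distribution")
}

is_default_distribution <- function(dist) {
  identical(unname(dist$capacities), c(60L, 30L, 20L, 16L, 10L, 8L, 6L))
}

#' Construct a Q-sort from an item -> rank assignment
#'
#' @param assignment Named integer vector: names are item ids, values ranks.
#'   May be partial (scoring requires a complete, valid sort; validation
#'   reports what is missing).
#' @param meta Optional named list of free-text metadata (rater id, subject
#'   id, session label, ...).
#' @return An object of class \code{dmrsq_sort}.
#' @export
qsort <- function(assignment, meta = list()) {
  ids <- suppressWarnings(as.integer(names(assignment)))
  ranks <- suppressWarnings(as.integer(assignment))
  if (anyNA(ids)) stop("assignment names must be integer item ids", call. = FALSE)
  if (anyNA(ranks)) stop("assignment values must be integer ranks", call. = FALSE)
  ord <- order(ids)
  structure(list(assignment = stats::setNames(ranks[ord], ids[ord]),
                 meta = meta),
            class = "dmrsq_sort")
}

#' Construct a Q-sort from a full rank vector
#'
#' Position i of \code{ranks} is the rank given to item i. Validity against
#' the forced distribution is \emph{not} asserted here; use
#' [validate_sort()].
#'
#' @param ranks Integer vector of length 150 (generally
#'   \code{dist$n_items}) with entries within the distribution's rank range.
#' @param meta Optional metadata list.
#' @param dist Forced distribution defining the expected length and rank
#'   range.
#' @return A \code{dmrsq_sort}.
#' @export
from_rank_vector <- function(ranks, meta = list(),
                             dist = forced_distribution()) {
  if (length(ranks) != dist$n_items) {
    stop(sprintf("rank vector must have length %d (got %d)",
                 dist$n_items, length(ranks)), call. = FALSE)
  }
  r <- suppressWarnings(as.integer(ranks))
  bad <- which(is.na(r) | r < min(dist$ranks) | r > max(dist$ranks))
  if (length(bad) > 0) {
    stop(sprintf("rank entries out of range %d..%d at position(s) %s",
                 min(dist$ranks), max(dist$ranks),
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  qsort(stats::setNames(r, seq_along(r)), meta = meta)
}

#' Extract the full rank vector of a sort
#'
#' @param sort A \code{dmrsq_sort} assigning every item exactly once.
#' @param dist Forced distribution (defines the item universe).
#' @return Integer vector of length \code{dist$n_items}; entry i is the rank
#'   of item i.
#' @export
rank_vector <- function(sort, dist = forced_distribution()) {
  v <- validate_sort(sort, dist)
  if (!v$ok) {
    stop(invalid_sort_condition(v, "cannot extract a total rank vector"))
  }
  unname(sort$assignment[as.character(seq_len(dist$n_items))])
}

#' Validate a sort against the forced distribution
#'
#' Validation is total: violations are returned as data, never raised.
#'
#' @param sort A \code{dmrsq_sort}.
#' @param dist A \code{dmrsq_distribution}.
#' @return An object of class \code{dmrsq_validation}: list with \code{ok}
#'   (logical), \code{violations} (character vector, one message per
#'   problem) and \code{counts} (observed per-rank counts).
#' @examples
#' s <- from_rank_vector(rep(1, 150))
#' validate_sort(s)$ok  # FALSE: rank 1 over capacity
#' @export
validate_sort <- function(sort, dist = forced_distribution()) {
  ids <- as.integer(names(sort$assignment))
  ranks <- as.integer(sort$assignment)
  universe <- seq_len(dist$n_items)
  violations <- character(0)

  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    violations <- c(violations,
                    sprintf("duplicate: {%s}", paste(sort(dup), collapse = ", ")))
  }
  unknown <- setdiff(ids, universe)
  if (length(unknown) > 0) {
    violations <- c(violations,
                    sprintf("unknown item ids: {%s}",
                            paste(sort(unknown), collapse = ", ")))
  }
  missing <- setdiff(universe, ids)
  if (length(missing) > 0) {
    violations <- c(violations,
                    sprintf("unassigned: {%s}",
                            paste(abbreviate_run(missing), collapse = ", ")))
  }
  out_of_range <- ids[!is.na(ranks) &
                        (ranks < min(dist$ranks) | ranks > max(dist$ranks))]
  if (length(out_of_range) > 0) {
    violations <- c(violations,
                    sprintf("rank out of range for item(s): {%s}",
                            paste(sort(out_of_range), collapse = ", ")))
  }
  counts <- stats::setNames(
    as.integer(table(factor(ranks, levels = dist$ranks))), dist$ranks)
  for (r in dist$ranks) {
    if (counts[[as.character(r)]] != dist$capacities[[as.character(r)]]) {
      violations <- c(violations,
                      sprintf("rank %d: %d/%d", r, counts[[as.character(r)]],
                              dist$capacities[[as.character(r)]]))
    }
  }
  structure(list(ok = length(violations) == 0L, violations = violations,
                 counts = counts),
            class = "dmrsq_validation")
}

# "1, 2, 3, 7" -> "1-3, 7" for readable violation messages
abbreviate_run <- function(x) {
  x <- sort(unique(x))
  if (length(x) == 0) return(character(0))
  breaks <- c(0, which(diff(x) != 1), length(x))
  vapply(seq_len(length(breaks) - 1), function(i) {
    seg <- x[(breaks[i] + 1):breaks[i + 1]]
    if (length(seg) == 1) as.character(seg)
    else paste0(seg[1], "-", seg[length(seg)])
  }, "")
}

invalid_sort_condition <- function(report, prefix = "invalid sort") {
  errorCondition(
    paste0(prefix, ": ", paste(report$violations, collapse = "; ")),
    class = c("dmrsq_invalid_sort", "dmrsqError"),
    report = report
  )
}

#' Per-rank item counts of a sort
#'
#' @param sort A \code{dmrsq_sort} (may be partial or empty).
#' @param dist Forced distribution defining the rank range.
#' @return Named integer vector over all ranks (zero counts included).
#' @export
rank_histogram <- function(sort, dist = forced_distribution()) {
  ranks <- as.integer(sort$assignment)
  stats::setNames(as.integer(table(factor(ranks, levels = dist$ranks))),
                  dist$ranks)
}

#' Read a sort file
#'
#' Accepts the two round-trippable formats: delimited text with columns
#' \code{item_id, rank} (one row per item) or a JSON document
#' \code{\{meta, ranks\}} with a full rank vector.
#'
#' @param path File path (\code{.csv} or \code{.json}).
#' @return A \code{dmrsq_sort}. Parse failures raise an error of class
#'   \code{dmrsq_parse_error}.
#' @export
read_qsort <- function(path) {
  if (!file.exists(path)) {
    stop(errorCondition(sprintf("sort file not found: %s", path),
                        class = c("dmrsq_parse_error", "dmrsqError")))
  }
  parse_fail <- function(msg) {
    stop(errorCondition(sprintf("cannot parse sort file %s: %s", path, msg),
                        class = c("dmrsq_parse_error", "dmrsqError")))
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- tryCatch(jsonlite::fromJSON(path),
                    error = function(e) parse_fail(conditionMessage(e)))
    if (is.null(doc$ranks)) parse_fail("missing 'ranks' field")
    meta <- if (is.null(doc$meta)) list() else as.list(doc$meta)
    return(qsort(stats::setNames(as.integer(doc$ranks),
                                 seq_along(doc$ranks)), meta = meta))
  }
  tab <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) parse_fail(conditionMessage(e)))
  if (!all(c("item_id", "rank") %in% names(tab))) {
    parse_fail("expected columns item_id, rank")
  }
  ids <- suppressWarnings(as.integer(tab$item_id))
  ranks <- suppressWarnings(as.integer(tab$rank))
  if (anyNA(ids) || anyNA(ranks)) parse_fail("non-integer item_id or rank")
  qsort(stats::setNames(ranks, ids))
}

#' Write a sort file
#'
#' @param sort A \code{dmrsq_sort}.
#' @param path Output path.
#' @param format \code{"csv"} (item_id, rank rows) or \code{"json"}
#'   (\code{\{meta, ranks\}}; requires a total assignment).
#' @param dist Forced distribution (JSON format only).
#' @return \code{path}, invisibly.
#' @export
write_qsort <- function(sort, path, format = c("csv", "json"),
                        dist = forced_distribution()) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(
      data.frame(item_id = as.integer(names(sort$assignment)),
                 rank = as.integer(sort$assignment)),
      path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(meta = sort$meta, ranks = rank_vector(sort, dist)),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @export
print.dmrsq_sort <- function(x, ...) {
  v <- validate_sort(x)
  cat(sprintf("DMRS-Q sort: %d item(s) assigned; %s\n",
              length(x$assignment),
              if (v$ok) "valid against the default forced distribution"
              else sprintf("%d validation issue(s)", length(v$violations))))
  if (length(x$meta) > 0) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.dmrsq_validation <- function(x, ...) {
  if (x$ok) {
    cat(sprintf("OK (%d items, %d ranks)\n", sum(x$counts), length(x$counts)))
  } else {
    cat("INVALID sort:\n")
    for (v in x$violations) cat("  -", v, "\n")
  }
  invisible(x)
}
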