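# Agreement statistics: two-way random-effects intraclass correlations
# (absolute agreement) over subjects x raters score matrices, and the
# Q-correlation between two complete sorts.

#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' From the two-way mean squares of an n subjects x k raters matrix --
#' MSR (rows/subjects), MSC (columns/raters), MSE (residual) -- the
#' single-rater and average-rater forms are
#' \deqn{ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)}
#' \deqn{ICC(2,k) = (MSR - MSE) / (MSR + (MSC - MSE) / n)}
#' A matrix with zero total variance is a defined degenerate case: the
#' estimate is 1 with \code{degenerate = TRUE}. Negative estimates are
#' reported as computed (flagged), never truncated at 0.
#'
#' @param x Numeric matrix, subjects in rows, raters in columns; at least
#'   2 x 2, no missing cells.
#' @param form \code{"ICC2_1"} (single rater) or \code{"ICC2_k"} (mean of
#'   the k raters).
#' @return An object of class \code{dmrsq_agreement}: list with
#'   \code{statistic}, \code{estimate}, \code{n_subjects}, \code{n_raters},
#'   \code{mean_squares} (MSR, MSC, MSE), \code{degenerate},
#'   \code{negative}.
#' @examples
#' m <- cbind(1:4, 1:4, 1:4)  # raters agree perfectly
#' icc(m)$estimate  # 1
#' @export
icc <- function(x, form = c("ICC2_1", "ICC2_k")) {
  form <- match.arg(form)
  x <- as.matrix(x)
  if (anyNA(x)) stop("score matrix must have no missing cells", call. = FALSE)
  n <- nrow(x)
  k <- ncol(x)
  if (n < 2 || k < 2) {
    stop("ICC requires at least 2 subjects and 2 raters", call. = FALSE)
  }
  grand <- mean(x)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((x - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  degenerate <- sst <= .Machine$double.eps * max(1, abs(grand))^2 * n * k
  if (degenerate) {
    est <- 1
  } else if (form == "ICC2_1") {
    est <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  } else {
    est <- (msr - mse) / (msr + (msc - mse) / n)
  }
  structure(
    list(statistic = form, estimate = est, n_subjects = n, n_raters = k,
         mean_squares = c(MSR = msr, MSC = msc, MSE = mse),
         degenerate = degenerate, negative = !degenerate && est < 0),
    class = "dmrsq_agreement")
}

#' Q-correlation between two complete sorts
#'
#' Agreement between two raters (or the similarity of two profiles)
#' computed as the correlation across the paired item ranks of the 150
#' items.
#'
#' @param a,b Complete, valid \code{dmrsq_sort} objects over the same
#'   distribution.
#' @param method \code{"rank"} (Spearman) or \code{"linear"} (Pearson).
#' @param dist A \code{dmrsq_distribution}.
#' @return A \code{dmrsq_agreement} with the estimate in [-1, 1].
#' @export
q_correlation <- function(a, b, method = c("rank", "linear"),
                          dist = forced_distribution()) {
  method <- match.arg(method)
  if (!setequal(names(a$assignment), names(b$assignment))) {
    stop("sorts cover different item sets", call. = FALSE)
  }
  ra <- rank_vector(a, dist)
  rb <- rank_vector(b, dist)
  est <- stats::cor(ra, rb,
                    method = if (method == "rank") "spearman" else "pearson")
  structure(
    list(statistic = paste0("q_correlation_", method), estimate = est,
         n_subjects = 1L, n_raters = 2L, n_items = length(ra),
         degenerate = FALSE, negative = est < 0),
    class = "dmrsq_agreement")
}

#' Scale score matrix of a rater panel
#'
#' Scores every sort in a panel and extracts one scale, arranged subjects
#' in rows by raters in columns.
#'
#' @param panel A \code{dmrsq_panel}.
#' @param bank A \code{dmrsq_bank}.
#' @param scale One of \code{"ODF"}, a defense code \code{D1..D30}, a level
#'   code \code{L1..L7}/\code{L5a}/\code{L5b}, or a category code
#'   \code{C1..C3}/\code{C1a}/\code{C1b}.
#' @param dist A \code{dmrsq_distribution}.
#' @return Numeric matrix with subject rows and rater columns.
#' @export
score_matrix <- function(panel, bank = load_item_bank(), scale = "ODF",
                         dist = forced_distribution()) {
  extract <- function(profile) {
    if (scale == "ODF") return(profile$odf)
    for (slot in c("defense_scores", "level_scores", "category_scores")) {
      if (scale %in% names(profile[[slot]])) return(profile[[slot]][[scale]])
    }
    stop(sprintf("unknown scale: %s", scale), call. = FALSE)
  }
  vals <- vapply(panel$sorts, function(subject_sorts) {
    vapply(subject_sorts, function(s) extract(full_profile(s, bank, dist)),
           numeric(1))
  }, numeric(panel$n_raters))
  m <- t(matrix(vals, nrow = panel$n_raters, ncol = panel$n_subjects))
  dimnames(m) <- list(paste0("subject", seq_len(panel$n_subjects)),
                      paste0("rater", seq_len(panel$n_raters)))
  m
}

#' Read / write a score matrix as delimited text
#'
#' Subjects as rows, raters as columns, header row of rater labels, first
#' column of subject labels.
#'
#' @param path File path.
#' @return \code{read_score_matrix}: a numeric matrix.
#' @export
read_score_matrix <- function(path) {
  tab <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(tab)
}

#' @rdname read_score_matrix
#' @param x Numeric matrix.
#' @export
write_score_matrix <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = TRUE)
  invisible(path)
}

#' Simulated inter-rater reliability experiment
#'
#' Mirrors the instrument's reliability study design with synthetic data:
#' draw heterogeneous subject profiles, simulate a panel of noisy raters
#' sorting each subject, score every sort, and compute the ICC of each
#' requested scale. Fully seeded and reproducible.
#'
#' @param n_subjects,n_raters Panel dimensions (both >= 2).
#' @param noise_sd Rater noise on the attractiveness scale.
#' @param seed Master seed; subject profiles and rater seeds derive from it.
#' @param scales Character vector of scale codes (see [score_matrix()]).
#' @param form ICC form, \code{"ICC2_1"} or \code{"ICC2_k"}.
#' @param alpha Dirichlet concentration of the subject profiles.
#' @param bank A \code{dmrsq_bank}.
#' @param dist A \code{dmrsq_distribution}.
#' @return A data.frame with one row per scale: \code{scale},
#'   \code{statistic}, \code{estimate}, \code{n_subjects}, \code{n_raters},
#'   \code{degenerate}.
#' @export
reliability_experiment <- function(n_subjects = 10, n_raters = 3,
                                   noise_sd = 0.02, seed = 1L,
                                   scales = c("ODF", "C1", "C2", "C3"),
                                   form = c("ICC2_1", "ICC2_k"),
                                   alpha = 1, bank = load_item_bank(),
                                   dist = forced_distribution()) {
  form <- match.arg(form)
  if (n_subjects < 2 || n_raters < 2) {
    stop("reliability experiment needs >= 2 subjects and >= 2 raters",
         call. = FALSE)
  }
  profiles <- lapply(seq_len(n_subjects),
                     function(s) random_profile(seed + 131L * s, alpha = alpha))
  raters <- lapply(seq_len(n_raters),
                   function(r) rater_model(noise_sd, seed + 977L * r))
  panel <- rater_panel(profiles, raters, bank = bank, dist = dist)
  rows <- lapply(scales, function(sc) {
    res <- icc(score_matrix(panel, bank = bank, scale = sc, dist = dist),
               form = form)
    data.frame(scale = sc, statistic = res$statistic,
               estimate = res$estimate, n_subjects = res$n_subjects,
               n_raters = res$n_raters, degenerate = res$degenerate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.dmrsq_agreement <- function(x, ...) {
  cat(sprintf("%s = %.4f  (n_subjects = %d, n_raters = %d)%s%s\n",
              x$statistic, x$estimate, x$n_subjects, x$n_raters,
              if (isTRUE(x$degenerate)) "  [degenerate: zero total variance]" else "",
              if (isTRUE(x$negative)) "  [negative estimate reported as computed]" else ""))
  invisible(x)
}
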