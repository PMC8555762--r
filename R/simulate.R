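# Synthetic sorts: uniform random, profile-conditioned with rater noise,
# rater panels, and the ODF-extremal greedy constructions.
#
# Every stochastic operation takes an explicit seed and restores the
# caller's RNG state; there is no hidden global state.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Fill items into rank piles from the top down: the first cap(7) entries of
# `ordered_items` get rank 7, the next cap(6) get rank 6, and so on.
fill_ranks <- function(ordered_items, dist) {
  ranks_desc <- rev(dist$ranks)
  assignment <- integer(dist$n_items)
  pos <- 1L
  for (r in ranks_desc) {
    cap <- dist$capacities[[as.character(r)]]
    assignment[ordered_items[pos:(pos + cap - 1L)]] <- r
    pos <- pos + cap
  }
  assignment
}

#' Uniformly random valid sort
#'
#' A seeded random permutation of the items filled into the rank piles from
#' rank 7 down to rank 1; always satisfies the forced distribution.
#'
#' @param seed Integer seed.
#' @param dist A \code{dmrsq_distribution}.
#' @return A valid \code{dmrsq_sort}.
#' @examples
#' validate_sort(random_sort(seed = 42))$ok  # TRUE
#' @export
random_sort <- function(seed, dist = forced_distribution()) {
  perm <- with_seed(seed, sample.int(dist$n_items))
  from_rank_vector(fill_ranks(perm, dist),
                   meta = list(generator = "random_sort", seed = seed),
                   dist = dist)
}

#' Latent defensive profile
#'
#' The target share of defensive mass per defense: 30 nonnegative weights
#' normalized to sum 1.
#'
#' @param weights Numeric vector of length 30 (optionally named by
#'   \code{D1..D30}); nonnegative, not all zero. Normalized internally.
#' @return An object of class \code{dmrsq_latent_profile}.
#' @export
latent_profile <- function(weights) {
  ids <- paste0("D", 1:30)
  if (is.null(names(weights))) {
    if (length(weights) != 30) {
      stop("weights must have length 30 (or be named by D1..D30)",
           call. = FALSE)
    }
    names(weights) <- ids
  }
  if (!setequal(names(weights), ids)) {
    stop("weights must be named by exactly D1..D30", call. = FALSE)
  }
  w <- as.numeric(weights[ids])
  if (anyNA(w) || any(w < 0)) stop("weights must be nonnegative", call. = FALSE)
  if (sum(w) <= 0) stop("weights must not all be zero", call. = FALSE)
  structure(list(weights = stats::setNames(w / sum(w), ids)),
            class = "dmrsq_latent_profile")
}

#' Rater model
#'
#' A synthetic rater is a Gaussian perturbation of item attractiveness:
#' each item's appeal is its defense's latent weight plus independent
#' N(0, noise_sd) noise from the rater's seeded generator. noise_sd = 0 is
#' a perfectly profile-faithful rater; large noise_sd converges to a
#' uniformly random sorter.
#'
#' @param noise_sd Nonnegative perturbation scale (on the attractiveness
#'   scale; latent weights sum to 1 across the 30 defenses, so typical
#'   weight differences are of order 1/30).
#' @param seed Integer seed for the rater's generator.
#' @return An object of class \code{dmrsq_rater}.
#' @export
rater_model <- function(noise_sd = 0, seed = 1L) {
  if (length(noise_sd) != 1 || is.na(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be a single nonnegative number", call. = FALSE)
  }
  structure(list(noise_sd = noise_sd, seed = as.integer(seed)),
            class = "dmrsq_rater")
}

#' Profile-conditioned synthetic sort
#'
#' Each item i receives attractiveness a_i = w[defense(i)] + eps_i with
#' eps_i ~ N(0, noise_sd) from the rater's seeded generator. Items are
#' sorted by attractiveness (descending; ties broken by ascending item id)
#' and filled into the rank piles from rank 7 down. The output is always a
#' valid sort; with noise_sd = 0 the ranking of defense scores reproduces
#' the ranking of profile weights up to capacity-induced ties.
#'
#' @param profile A \code{dmrsq_latent_profile}.
#' @param rater A \code{dmrsq_rater}.
#' @param bank A \code{dmrsq_bank} (supplies item -> defense membership).
#' @param dist A \code{dmrsq_distribution}.
#' @return A valid \code{dmrsq_sort}.
#' @export
profile_sort <- function(profile, rater = rater_model(), bank = load_item_bank(),
                         dist = forced_distribution()) {
  stopifnot(inherits(profile, "dmrsq_latent_profile"),
            inherits(rater, "dmrsq_rater"))
  w <- profile$weights[bank$items$defense_id]  # per item, in item_id order
  eps <- if (rater$noise_sd > 0) {
    with_seed(rater$seed, stats::rnorm(dist$n_items, 0, rater$noise_sd))
  } else {
    numeric(dist$n_items)
  }
  a <- as.numeric(w) + eps
  ordered <- order(-a, bank$items$item_id)
  from_rank_vector(fill_ranks(bank$items$item_id[ordered], dist),
                   meta = list(generator = "profile_sort",
                               noise_sd = rater$noise_sd, seed = rater$seed),
                   dist = dist)
}

#' Simulate a subjects x raters panel of sorts
#'
#' One sort per (subject, rater) pair. Each pair draws its noise from a
#' seed derived deterministically from the rater's seed and the subject
#' index, so the whole panel is reproducible while raters remain
#' independent across subjects.
#'
#' @param profiles List of \code{dmrsq_latent_profile}, one per subject.
#' @param raters List of \code{dmrsq_rater}, one per rater.
#' @param bank A \code{dmrsq_bank}.
#' @param dist A \code{dmrsq_distribution}.
#' @return An object of class \code{dmrsq_panel}: list with \code{sorts}
#'   (list of lists indexed [[subject]][[rater]]), \code{n_subjects},
#'   \code{n_raters}.
#' @export
rater_panel <- function(profiles, raters, bank = load_item_bank(),
                        dist = forced_distribution()) {
  if (length(profiles) == 0 || length(raters) == 0) {
    stop("profiles and raters must be non-empty lists", call. = FALSE)
  }
  sorts <- lapply(seq_along(profiles), function(s) {
    lapply(seq_along(raters), function(r) {
      rt <- raters[[r]]
      pair_seed <- (rt$seed * 7919L + s * 104729L) %% 2147483587L
      profile_sort(profiles[[s]],
                   rater_model(rt$noise_sd, pair_seed),
                   bank = bank, dist = dist)
    })
  })
  structure(list(sorts = sorts, n_subjects = length(profiles),
                 n_raters = length(raters)),
            class = "dmrsq_panel")
}

#' Greedy ODF-extremal sort
#'
#' Orders items by the adaptiveness level of their defense (descending for
#' the maximum, ascending for the minimum; ties broken by ascending item
#' id) and fills the rank piles from rank 7 down. By the rearrangement
#' inequality this attains the extreme of the level-by-rank assignment, so
#' the resulting ODF values, 1513/234 (6.47) and 553/234 (2.36) under the
#' default distribution, bound ODF over all valid sorts.
#'
#' @param bank A \code{dmrsq_bank}.
#' @param dist A \code{dmrsq_distribution}.
#' @param maximize If \code{TRUE} (default) construct the ODF-maximal sort,
#'   else the minimal one.
#' @return A valid \code{dmrsq_sort}.
#' @examples
#' bank <- load_item_bank()
#' full_profile(extremal_odf_sort(bank), bank)$odf * 234  # 1513
#' @export
extremal_odf_sort <- function(bank = load_item_bank(),
                              dist = forced_distribution(),
                              maximize = TRUE) {
  lev <- defense_level_number(bank$items$defense_id)
  key <- if (maximize) -lev else lev
  ordered <- bank$items$item_id[order(key, bank$items$item_id)]
  from_rank_vector(fill_ranks(ordered, dist),
                   meta = list(generator = "extremal_odf_sort",
                               maximize = maximize),
                   dist = dist)
}

#' Draw a random latent profile
#'
#' Subject heterogeneity for simulation studies: weights drawn from a
#' symmetric Dirichlet distribution (gamma draws normalized to sum 1).
#'
#' @param seed Integer seed.
#' @param alpha Dirichlet concentration (default 1: uniform over the
#'   simplex).
#' @return A \code{dmrsq_latent_profile}.
#' @export
random_profile <- function(seed, alpha = 1) {
  g <- with_seed(seed, stats::rgamma(30, shape = alpha, rate = 1))
  if (sum(g) <= 0) g <- rep(1, 30)  # degenerate draw guard for tiny alpha
  latent_profile(g)
}
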