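#' Greedy selection of a phenotypically extreme set under a distance constraint
#'
#' Walks candidates in trait order starting from the most extreme value
#' (largest for `tail = "high"`, smallest for `"low"`) and admits each
#' candidate unless its Euclidean genetic distance to any already admitted
#' line is below `min_distance`, stopping once `set_size` lines are
#' admitted. Forced members are admitted first, regardless of rank or
#' distance. Ties in trait value are broken by input order, so selection is
#' deterministic given the panel.
#'
#' @param panel A `variety_panel`, or a data frame with columns
#'   `variety_id` and `trait` (then supply `genotypes`).
#' @param tail `"high"` or `"low"`.
#' @param set_size Number of lines to admit (default 12).
#' @param min_distance Minimum within-set Euclidean distance (default 20,
#'   about 400 allele differences on 0/1 coding).
#' @param forced Variety ids admitted unconditionally.
#' @param genotypes Genotype matrix when `panel` is a plain data frame.
#' @param dist_matrix Optional precomputed distance matrix (as returned by
#'   [euclidean_distance_matrix()]); computed from the genotypes otherwise.
#' @return A tibble of admitted lines (`variety_id`, `trait`, `forced`) in
#'   admission order, with attribute `skip_log`: a tibble of
#'   `(variety_id, trait, reason)` for candidates passed over.
#' @export
select_contrasting_sets <- function(panel, tail = c("high", "low"),
                                    set_size = 12, min_distance = 20,
                                    forced = character(),
                                    genotypes = NULL, dist_matrix = NULL) {
  tail <- match.arg(tail)
  if (inherits(panel, "variety_panel")) {
    pheno <- panel$phenotypes
    genotypes <- panel$genotypes
  } else {
    pheno <- tibble::as_tibble(panel)
    stopifnot(!is.null(genotypes) || !is.null(dist_matrix))
  }
  stopifnot(all(c("variety_id", "trait") %in% names(pheno)))
  pheno <- pheno[is.finite(pheno$trait), ]
  if (is.null(dist_matrix)) dist_matrix <- euclidean_distance_matrix(genotypes)
  missing_forced <- setdiff(forced, pheno$variety_id)
  if (length(missing_forced) > 0) {
    abort(paste("forced members not in panel:", paste(missing_forced, collapse = ", ")))
  }

  ord <- order(pheno$trait, decreasing = (tail == "high"))
  queue <- pheno$variety_id[ord]
  queue <- c(forced, setdiff(queue, forced))

  admitted <- character()
  skipped <- list()
  for (v in queue) {
    if (length(admitted) >= set_size) break
    if (v %in% forced) {
      admitted <- c(admitted, v)
      next
    }
    d <- dist_matrix[v, admitted]
    if (length(d) > 0 && any(d < min_distance)) {
      nearest <- admitted[which.min(d)]
      skipped[[length(skipped) + 1]] <- tibble::tibble(
        variety_id = v,
        trait = pheno$trait[match(v, pheno$variety_id)],
        reason = sprintf("distance %.2f to %s below %g", min(d), nearest,
                         min_distance)
      )
      next
    }
    admitted <- c(admitted, v)
  }
  if (length(admitted) < set_size) {
    abort(sprintf(
      "candidates exhausted: admitted %d of %d requested for the %s set",
      length(admitted), set_size, tail))
  }
  # selection contract: every non-forced within-set pair at least min_distance apart
  free <- setdiff(admitted, forced)
  if (length(free) > 1) {
    dd <- dist_matrix[free, free]
    stopifnot(all(dd[upper.tri(dd)] >= min_distance))
  }
  out <- tibble::tibble(
    variety_id = admitted,
    trait = pheno$trait[match(admitted, pheno$variety_id)],
    forced = admitted %in% forced
  )
  empty_log <- tibble::tibble(variety_id = character(), trait = numeric(),
                              reason = character())
  attr(out, "skip_log") <- dplyr::bind_rows(empty_log, !!!skipped)
  out
}

#' Select both contrasting sets of a high/low pool-seq design
#'
#' Convenience wrapper around [select_contrasting_sets()] producing the
#' paired high-trait and low-trait sets used for pooled sequencing.
#'
#' @inheritParams select_contrasting_sets
#' @param forced_high,forced_low Variety ids forced into each set.
#' @return A `contrast_sets` object: list with `high_members`,
#'   `low_members`, `set_size`, `min_distance`, `forced_members` and a
#'   combined `skip_log` tibble.
#' @export
select_contrast_sets <- function(panel, set_size = 12, min_distance = 20,
                                 forced_high = character(),
                                 forced_low = character(),
                                 dist_matrix = NULL) {
  if (is.null(dist_matrix) && inherits(panel, "variety_panel")) {
    dist_matrix <- euclidean_distance_matrix(panel$genotypes)
  }
  high <- select_contrasting_sets(panel, "high", set_size, min_distance,
                                  forced_high, dist_matrix = dist_matrix)
  # high-set members are unavailable to the low set (disjoint pools)
  low_pool <- panel
  if (inherits(panel, "variety_panel")) {
    keep <- !(panel$phenotypes$variety_id %in% high$variety_id)
    low_pool$phenotypes <- panel$phenotypes[keep, ]
  } else {
    low_pool <- panel[!(panel$variety_id %in% high$variety_id), ]
  }
  low <- select_contrasting_sets(low_pool, "low", set_size, min_distance,
                                 forced_low, dist_matrix = dist_matrix)
  skip <- dplyr::bind_rows(
    dplyr::mutate(attr(high, "skip_log"), tail = "high"),
    dplyr::mutate(attr(low, "skip_log"), tail = "low")
  )
  structure(
    list(
      high_members = high$variety_id,
      low_members = low$variety_id,
      set_size = set_size,
      min_distance = min_distance,
      forced_members = c(forced_high, forced_low),
      skip_log = skip
    ),
    class = "contrast_sets"
  )
}

#' @export
print.contrast_sets <- function(x, ...) {
  cat("<contrast_sets> high:", length(x$high_members),
      "| low:", length(x$low_members),
      "| min distance:", x$min_distance, "\n")
  cat("  high:", paste(head(x$high_members, 6), collapse = ", "),
      if (length(x$high_members) > 6) "...", "\n")
  cat("  low: ", paste(head(x$low_members, 6), collapse = ", "),
      if (length(x$low_members) > 6) "...", "\n")
  invisible(x)
}
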