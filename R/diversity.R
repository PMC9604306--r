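#' Species abundance table
#'
#' Tallies observation counts per species — the abundance proxy used
#' throughout: true individual counts are unavailable in opportunistic
#' community-science data, so the number of (de-duplicated) observations of
#' a species stands in for its abundance. Species with no records are absent
#' from the table.
#'
#' @param occ An occurrence tibble. A warning is raised if the set has not
#'   been through [deduplicate()], since platform double-reports inflate
#'   abundances.
#' @return A tibble with columns `species` and `n` (count >= 1), one row per
#'   observed species, in first-appearance order.
#' @examples
#' occ <- as_occurrences(data.frame(
#'   species = c("A", "A", "B"), lat = 0, lon = 0,
#'   event_date = as.Date("2020-06-01")
#' ), deduplicated = TRUE)
#' abundance_table(occ)
#' @export
abundance_table <- function(occ) {
  if (!is_deduplicated(occ)) {
    warn("abundance_table: occurrence set is not flagged as deduplicated; counts may include cross-platform duplicates.")
  }
  tab <- count(tibble(species = occ$species), .data$species, sort = FALSE)
  # count() sorts by species; restore first-appearance order
  tab[order(match(tab$species, unique(occ$species))), , drop = FALSE]
}

#' Species richness
#'
#' The total number of distinct species observed.
#'
#' @param tab An abundance table from [abundance_table()].
#' @return A non-negative integer count of species.
#' @export
species_richness <- function(tab) {
  nrow(tab)
}

#' Shannon diversity index
#'
#' \eqn{H = -\sum_i p_i \log p_i} over species relative abundances
#' \eqn{p_i = n_i / \sum n_i}, in natural-log units (nats) by default.
#' An empty table returns 0 (rather than NaN) so that null-distribution
#' replicates from empty sampling rectangles stay well defined.
#'
#' @param tab An abundance table from [abundance_table()].
#' @param base Logarithm base; `exp(1)` (default), 2 and 10 are the usual
#'   choices.
#' @return A non-negative number, at most `log(richness, base)`.
#' @examples
#' tab <- data.frame(species = letters[1:4], n = 5)
#' shannon_index(tab) # log(4)
#' @export
shannon_index <- function(tab, base = exp(1)) {
  shannon_from_counts(tab$n, base = base)
}

shannon_from_counts <- function(n, base = exp(1)) {
  n <- n[n > 0]
  if (length(n) == 0) return(0)
  p <- n / sum(n)
  -sum(p * log(p, base = base))
}

#' Richness and Shannon diversity of an occurrence set
#'
#' Convenience wrapper: abundance table, then both metrics.
#'
#' @inheritParams abundance_table
#' @param base Logarithm base for the Shannon index.
#' @return A one-row tibble with columns `richness` and `shannon`.
#' @export
diversity_metrics <- function(occ, base = exp(1)) {
  tab <- abundance_table(occ)
  tibble(richness = species_richness(tab),
         shannon = shannon_index(tab, base = base))
}
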