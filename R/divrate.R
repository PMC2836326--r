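# Per-clade net diversification rates by the method-of-moments stem-age
# estimator, and taxon-coverage summaries.

#' Method-of-moments net diversification rate (stem age)
#'
#' The stem-group estimator of the net diversification rate
#' r = b - d (events/lineage/Myr) under a relative extinction rate
#' epsilon = d/b:
#' \deqn{\hat r = \log(n (1 - \epsilon) + \epsilon) / t}
#' where n is the present-day species diversity of the clade and t its stem
#' age in Myr.
#'
#' @param n extant species count(s), >= 1.
#' @param t stem age(s) in Myr, > 0.
#' @param epsilon relative extinction rate(s) in [0, 1).
#' @return net diversification rate(s), unrounded; tables round half-up to
#'   4 decimals.
#' @examples
#' stemMomRate(161, 117.2, 0)      # 0.0434 once rounded
#' stemMomRate(25, 134.7, 0.95)    # 0.0059
#' @export
stemMomRate <- function(n, t, epsilon = 0) {
  if (any(n < 1)) stop("n must be >= 1 (no surviving lineage otherwise)")
  if (any(t <= 0)) stop("stem age t must be > 0")
  if (any(epsilon < 0 | epsilon >= 1)) stop("epsilon must be in [0, 1)")
  log(n * (1 - epsilon) + epsilon) / t
}

#' Per-clade diversification-rate table
#'
#' One row per clade and epsilon value, with rates rounded half-up to four
#' decimals as in printed tables.  Clades without a stem age are skipped
#' with a warning.
#'
#' @param diversity data.frame with columns \code{clade} and \code{n}
#'   (extant species).
#' @param stemAges named numeric vector of stem ages (Myr) per clade.
#' @param epsilons relative extinction rates (default \code{c(0, 0.95)}).
#' @return data.frame: \code{clade, n, t, epsilon, r}.
#' @export
diversificationTable <- function(diversity, stemAges, epsilons = c(0, 0.95)) {
  rows <- list()
  for (i in seq_len(nrow(diversity))) {
    cl <- diversity$clade[i]
    t <- if (cl %in% names(stemAges)) stemAges[[cl]] else NA_real_
    if (is.na(t)) {
      warning("no stem age for clade ", cl, "; row skipped")
      next
    }
    for (eps in epsilons) {
      rows[[length(rows) + 1L]] <-
        data.frame(clade = cl, n = diversity$n[i], t = t, epsilon = eps,
                   r = roundHalfUp(stemMomRate(diversity$n[i], t, eps), 4))
    }
  }
  do.call(rbind, rows)
}

#' Taxon-coverage summary
#'
#' Sampled percentages per clade and in total, rounded half-up to one
#' decimal.  A zero denominator yields NA (undefined), never 0.
#'
#' @param diversity data.frame with columns \code{clade},
#'   \code{genera_sampled}, \code{genera_total}, \code{species_sampled},
#'   \code{species_total}.
#' @return data.frame with per-clade rows plus a \code{Total} row, columns
#'   \code{clade, genera_sampled, genera_total, genus_pct, species_sampled,
#'   species_total, species_pct}.
#' @export
coverageSummary <- function(diversity) {
  pct <- function(s, tot) ifelse(tot == 0, NA_real_,
                                 roundHalfUp(100 * s / tot, 1))
  if (any(diversity$genera_sampled > diversity$genera_total, na.rm = TRUE) ||
      any(diversity$species_sampled > diversity$species_total, na.rm = TRUE))
    stop("sampled counts exceed totals")
  out <- data.frame(clade = diversity$clade,
                    genera_sampled = diversity$genera_sampled,
                    genera_total = diversity$genera_total,
                    genus_pct = pct(diversity$genera_sampled, diversity$genera_total),
                    species_sampled = diversity$species_sampled,
                    species_total = diversity$species_total,
                    species_pct = pct(diversity$species_sampled, diversity$species_total))
  total <- data.frame(clade = "Total",
                      genera_sampled = sum(diversity$genera_sampled),
                      genera_total = sum(diversity$genera_total),
                      genus_pct = pct(sum(diversity$genera_sampled),
                                      sum(diversity$genera_total)),
                      species_sampled = sum(diversity$species_sampled),
                      species_total = sum(diversity$species_total),
                      species_pct = pct(sum(diversity$species_sampled),
                                        sum(diversity$species_total)))
  rbind(out, total)
}
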