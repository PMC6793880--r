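#' Index of relative importance (IRI) table
#'
#' Summarizes stomach contents of a predator group per prey taxon. With
#' counts \eqn{N_i}, masses \eqn{M_i} and occurrences across the group's
#' (non-empty) stomachs:
#' \deqn{\%N_i = N_i/\sum N \times 100,\quad \%M_i = M_i/\sum M \times 100,
#'   \quad \%FO_i = stomachs_i/stomachs \times 100}
#' \deqn{IRI_i = (\%N_i + \%M_i) \times \%FO_i,\qquad
#'   \%IRI_i = IRI_i/\sum IRI \times 100}
#' Empty stomachs never appear in the records, so %FO denominators count
#' full stomachs only. If a group's total prey mass is zero while counts are
#' positive, the mass term is dropped (`IRI = %N x %FO`) and the group is
#' flagged in the `mass_used` column.
#'
#' @param diet Diet record data frame (see [read_diet_csv()]): columns
#'   `predator_id`, `prey_taxon`, `prey_count`, `prey_mass`, plus any
#'   grouping columns.
#' @param by Character vector of grouping columns (default
#'   `c("predator_species", "area")`); use `NULL` to pool everything.
#' @return Data frame with one row per group x taxon: `n_stomachs`,
#'   `pct_n`, `pct_m`, `pct_fo`, `iri`, `pct_iri`, `mass_used`. Within each
#'   group, `pct_n`, `pct_m` and `pct_iri` sum to 100.
#' @examples
#' d <- data.frame(predator_id = c("f1", "f1", "f2"),
#'                 predator_species = "black", area = "MPA",
#'                 prey_taxon = c("crab", "amphipod", "crab"),
#'                 prey_count = c(2, 5, 1), prey_mass = c(1.2, 0.3, 0.8))
#' iri_table(d)
#' @export
iri_table <- function(diet, by = c("predator_species", "area")) {
  if (!nrow(diet)) stop("no diet records")
  need <- c("predator_id", "prey_taxon", "prey_count", "prey_mass")
  if (!all(need %in% names(diet)))
    stop("diet records need columns: ", paste(need, collapse = ", "))
  grp <- if (is.null(by)) rep("all", nrow(diet)) else
    interaction(diet[by], sep = " | ", drop = TRUE)
  out <- lapply(split(diet, grp), function(d) {
    # aggregate duplicate (predator, taxon) rows before anything else
    d <- stats::aggregate(d[c("prey_count", "prey_mass")],
                          d[c("predator_id", "prey_taxon")], sum)
    stomachs <- length(unique(d$predator_id))
    cnt <- tapply(d$prey_count, d$prey_taxon, sum)
    mas <- tapply(d$prey_mass, d$prey_taxon, sum)
    fo <- tapply(d$predator_id, d$prey_taxon,
                 function(x) length(unique(x))) / stomachs * 100
    pct_n <- cnt / sum(cnt) * 100
    mass_used <- sum(mas) > 0
    pct_m <- if (mass_used) mas / sum(mas) * 100 else rep(0, length(mas))
    iri <- if (mass_used) (pct_n + pct_m) * fo else pct_n * fo
    res <- data.frame(prey_taxon = names(cnt), n_stomachs = stomachs,
                      pct_n = as.numeric(pct_n),
                      pct_m = as.numeric(pct_m),
                      pct_fo = as.numeric(fo),
                      iri = as.numeric(iri),
                      pct_iri = as.numeric(iri / sum(iri) * 100),
                      mass_used = mass_used)
    res[order(-res$pct_iri), ]
  })
  if (!is.null(by)) {
    keys <- do.call(rbind, strsplit(names(out), " | ", fixed = TRUE))
    for (i in seq_along(out))
      for (j in seq_along(by)) out[[i]][[by[j]]] <- keys[i, j]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  cols <- c(by, "prey_taxon", "n_stomachs", "pct_n", "pct_m", "pct_fo",
            "iri", "pct_iri", "mass_used")
  res[, cols]
}

#' Prey richness per predator group, with rarefaction
#'
#' Counts distinct prey taxa per group and, optionally, rarefies richness to
#' a common number of stomachs by resampling stomachs without replacement,
#' so groups with unequal stomach counts are comparable. The rarefied mean
#' over resamples converges to the closed-form hypergeometric expectation
#' \eqn{E[S_k] = \sum_t (1 - \binom{H - H_t}{k} / \binom{H}{k})} where
#' \eqn{H} is the number of stomachs and \eqn{H_t} the number containing
#' taxon t.
#'
#' @param diet Diet record data frame.
#' @param by Grouping columns (default `c("predator_species", "area")`).
#' @param rarefy_to Common stomach count to rarefy to, or `NULL` (observed
#'   richness only). Groups with fewer stomachs report `NA` rarefied values.
#' @param n_resample Number of resamples (default 1000).
#' @param seed Optional seed for the resampler.
#' @return Data frame per group: `n_stomachs`, `richness`, and when
#'   requested `rarefied_mean` at `rarefy_to` stomachs.
#' @export
prey_richness <- function(diet, by = c("predator_species", "area"),
                          rarefy_to = NULL, n_resample = 1000, seed = NULL) {
  if (!nrow(diet)) stop("no diet records")
  if (!is.null(seed)) set.seed(seed)
  grp <- if (is.null(by)) rep("all", nrow(diet)) else
    interaction(diet[by], sep = " | ", drop = TRUE)
  out <- lapply(split(diet, grp), function(d) {
    ids <- unique(d$predator_id)
    res <- data.frame(n_stomachs = length(ids),
                      richness = length(unique(d$prey_taxon)))
    if (!is.null(rarefy_to)) {
      res$rarefied_mean <- if (rarefy_to > length(ids)) NA_real_ else
        mean(vapply(seq_len(n_resample), function(i) {
          keep <- sample(ids, rarefy_to)
          length(unique(d$prey_taxon[d$predator_id %in% keep]))
        }, numeric(1)))
    }
    res
  })
  keys <- names(out)
  res <- do.call(rbind, out)
  if (!is.null(by)) {
    km <- do.call(rbind, strsplit(keys, " | ", fixed = TRUE))
    for (j in seq_along(by)) res[[by[j]]] <- km[, j]
    res <- res[, c(by, setdiff(names(res), by))]
  }
  rownames(res) <- NULL
  res
}
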