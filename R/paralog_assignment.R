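#' All-against-all protein hit tables
#'
#' A `hit_table` holds precomputed all-against-all protein alignment hits
#' (e.g. BLASTP output already thresholded upstream on E-value): one row per
#' directed hit with the query and subject gene ids, the genome label of
#' each, and the alignment bitscore.  Self-hits within a genome are
#' rejected; bitscores must be finite and non-negative.
#'
#' @param x Data frame with columns `query_gene`, `subject_gene`,
#'   `query_genome`, `subject_genome`, `bitscore`.
#' @return A validated `hit_table` (a data frame).
#' @export
hit_table <- function(x) {
  req <- c("query_gene", "subject_gene", "query_genome", "subject_genome",
           "bitscore")
  if (!is.data.frame(x) || !all(req %in% names(x))) {
    stop("need a data frame with columns ", paste(req, collapse = ", "))
  }
  out <- data.frame(
    query_gene = as.character(x$query_gene),
    subject_gene = as.character(x$subject_gene),
    query_genome = as.character(x$query_genome),
    subject_genome = as.character(x$subject_genome),
    bitscore = as.numeric(x$bitscore),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(out$bitscore) | out$bitscore < 0)) {
    stop("bitscore must be finite and non-negative")
  }
  self <- out$query_gene == out$subject_gene &
    out$query_genome == out$subject_genome
  if (any(self)) {
    stop("self-hit not allowed: ", out$query_gene[self][1L])
  }
  rownames(out) <- NULL
  class(out) <- c("hit_table", "data.frame")
  out
}

#' Read a hit table from TSV
#'
#' @param path TSV with header `query_gene`, `subject_gene`, `query_genome`,
#'   `subject_genome`, `bitscore`.
#' @return A [hit_table()].
#' @export
read_hit_table <- function(path) {
  hit_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Best-reciprocal-hit paralog pairs
#'
#' Within a genome's self-comparison, the closest paralog pairs — the ones
#' attributable to the most recent WGD when several rounds of duplication
#' have stacked up, as in the teleosts — are taken to be the best reciprocal
#' hits (BRH): `a` and `b` are paired when `b` is `a`'s highest-bitscore hit
#' and `a` is `b`'s.  A tie for a gene's best hit is broken toward the
#' lexicographically smallest partner id, with a warning.
#'
#' @param hits A [hit_table()] restricted to a single genome's
#'   self-comparison (all rows must have `query_genome == subject_genome`).
#' @param genome Optionally, the [genome_table()] the genes belong to; when
#'   supplied the result is returned as a [paralog_map()].
#' @return A two-column data frame of pairs (`gene_a`, `gene_b`), or a
#'   [paralog_map()] when `genome` is given.  The result is always a
#'   matching: each gene occurs in at most one pair.
#' @export
best_reciprocal_hits <- function(hits, genome = NULL) {
  hits <- hit_table(hits)
  if (nrow(hits) > 0L &&
      (length(unique(c(hits$query_genome, hits$subject_genome))) != 1L)) {
    stop("best_reciprocal_hits expects a single genome's self-comparison")
  }
  best <- best_hit_per_gene(hits)
  # mutual argmax: partner's best points back
  cand <- names(best)
  mutual <- !is.na(best[best[cand]]) & best[best[cand]] == cand
  cand <- cand[mutual]
  a <- pmin(cand, best[cand])
  b <- pmax(cand, best[cand])
  pairs <- unique(data.frame(gene_a = a, gene_b = b,
                             stringsAsFactors = FALSE))
  pairs <- pairs[order(pairs$gene_a, method = "radix"), , drop = FALSE]
  rownames(pairs) <- NULL
  if (is.null(genome)) pairs else paralog_map(pairs, genome)
}

# Highest-bitscore subject per query gene; lexicographic tie-break (warned).
best_hit_per_gene <- function(hits) {
  if (nrow(hits) == 0L) return(stats::setNames(character(), character()))
  ord <- order(hits$query_gene, -hits$bitscore, hits$subject_gene,
               method = "radix")
  h <- hits[ord, , drop = FALSE]
  first <- !duplicated(h$query_gene)
  best <- stats::setNames(h$subject_gene[first], h$query_gene[first])
  # detect ties at the top score
  key <- paste(h$query_gene, h$bitscore)
  tied <- first & duplicated(key, fromLast = TRUE)
  if (any(tied)) {
    warning("best-hit tie for gene(s) ",
            paste(h$query_gene[tied], collapse = ", "),
            "; broken toward lexicographically smallest partner")
  }
  best
}

#' Outgroup score bracket for WGD paralog hits
#'
#' Filters candidate paralog hits so that only pairs plausibly dating from
#' the focal WGD survive: a hit `(a, b, S)` is kept only when, for both
#' genes, `S` is strictly stronger than the best alignment to the lower
#' (pre-WGD divergence) outgroups and strictly weaker than every upper
#' (post-WGD divergence) outgroup's best alignment.  The upper condition
#' uses, per gene, the minimum over upper-outgroup genomes of that genome's
#' best score — "weaker than any" means weaker than all of them.
#'
#' Genes absent from the lower-outgroup tables pass the lower condition
#' vacuously by default; genes absent from the upper tables fail the upper
#' condition by default (there is then no evidence the pair predates the
#' upper split).  Both behaviours are configurable.
#'
#' @param paralog_hits [hit_table()] of within-genome candidate paralog hits.
#' @param lower_outgroup_hits,upper_outgroup_hits [hit_table()]s of hits from
#'   the focal genome to the lower/upper outgroup genomes (one table may
#'   contain several outgroup genomes, distinguished by `subject_genome`).
#' @param missing_lower_passes,missing_upper_passes How to treat genes with
#'   no hits in an outgroup table.
#' @return The retained rows of `paralog_hits`, a [hit_table()].
#' @export
bracket_filter <- function(paralog_hits, lower_outgroup_hits,
                           upper_outgroup_hits,
                           missing_lower_passes = TRUE,
                           missing_upper_passes = FALSE) {
  paralog_hits <- hit_table(paralog_hits)
  if (nrow(paralog_hits) == 0L) return(paralog_hits)
  lower_best <- overall_best(lower_outgroup_hits)
  upper_best <- per_genome_min_best(upper_outgroup_hits)

  bound <- function(tab, gene, missing_passes, lower) {
    v <- tab[gene]
    if (missing_passes) {
      v[is.na(v)] <- if (lower) -Inf else Inf
    } else {
      v[is.na(v)] <- if (lower) Inf else -Inf
    }
    unname(v)
  }
  S <- paralog_hits$bitscore
  ok <- S > bound(lower_best, paralog_hits$query_gene, missing_lower_passes, TRUE) &
    S > bound(lower_best, paralog_hits$subject_gene, missing_lower_passes, TRUE) &
    S < bound(upper_best, paralog_hits$query_gene, missing_upper_passes, FALSE) &
    S < bound(upper_best, paralog_hits$subject_gene, missing_upper_passes, FALSE)
  out <- paralog_hits[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# best score per query gene over all rows
overall_best <- function(hits) {
  hits <- hit_table(hits)
  if (nrow(hits) == 0L) return(stats::setNames(numeric(), character()))
  v <- tapply(hits$bitscore, hits$query_gene, max)
  stats::setNames(as.numeric(v), names(v))
}

# min over subject genomes of the per-genome best score, per query gene
per_genome_min_best <- function(hits) {
  hits <- hit_table(hits)
  if (nrow(hits) == 0L) return(stats::setNames(numeric(), character()))
  per <- tapply(hits$bitscore,
                list(hits$query_gene, hits$subject_genome), max)
  v <- apply(per, 1L, min, na.rm = TRUE)
  stats::setNames(as.numeric(v), rownames(per))
}

#' Minimum-bitscore filter
#'
#' Retains hits with `bitscore >= threshold`.  The default of 140 bits is
#' the cutoff used to keep only duplicates produced by the most recent
#' vertebrate WGD; hits scoring strictly below the threshold are discarded.
#'
#' @param hits A [hit_table()].
#' @param threshold Minimum bitscore to retain (default 140).
#' @return The retained rows, a [hit_table()].
#' @export
bitscore_filter <- function(hits, threshold = 140) {
  stopifnot(threshold >= 0)
  hits <- hit_table(hits)
  out <- hits[hits$bitscore >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Verify single-copy genes against two outgroups
#'
#' A gene counted as single-copy should be a genuine gene with orthologous
#' support, not an annotation artifact: it is verified when it has at least
#' one hit in each of two outgroup hit tables.
#'
#' @param genes Character vector of gene ids (typically the unpaired genes
#'   of a genome).
#' @param outgroup_hits_1,outgroup_hits_2 [hit_table()]s of hits from the
#'   focal genome to each outgroup.
#' @return The subset of `genes` with support in both tables.
#' @export
verify_singletons <- function(genes, outgroup_hits_1, outgroup_hits_2) {
  h1 <- hit_table(outgroup_hits_1)
  h2 <- hit_table(outgroup_hits_2)
  genes[genes %in% h1$query_gene & genes %in% h2$query_gene]
}
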