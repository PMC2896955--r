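#' Gene-order tables
#'
#' A `genome_table` is the gene-order substrate of every analysis in this
#' package: one row per gene, with the chromosome (or contig) it sits on, its
#' 0-based rank along that chromosome, a unique gene identifier, and its
#' reading direction coded as `+1`/`-1`.  Positions are pure gene-order
#' ranks; there are no base-pair coordinates anywhere in the package.
#'
#' Invariants enforced by the constructor:
#' \itemize{
#'   \item `gene_id` values are unique across the whole table;
#'   \item within each chromosome the ranks are exactly `0..(length-1)`,
#'         dense, with no duplicates;
#'   \item `strand` is `+1L` or `-1L`.
#' }
#' Rows are stored in canonical order: chromosome (C-locale lexicographic),
#' then rank.
#'
#' @param x A data frame with columns `chromosome`, `rank`, `gene_id`,
#'   `strand`.  Strand may be given as `"+"`/`"-"`, `"+1"`/`"-1"` or numeric
#'   `1`/`-1`; it is stored as integer `+1`/`-1`.
#' @return A validated `genome_table` (a data frame).
#' @seealso [read_gene_order()], [write_gene_order()], [paralog_map()]
#' @export
genome_table <- function(x) {
  req <- c("chromosome", "rank", "gene_id", "strand")
  if (!is.data.frame(x) || !all(req %in% names(x))) {
    stop("need a data frame with columns ", paste(req, collapse = ", "))
  }
  chromosome <- as.character(x$chromosome)
  gene_id <- as.character(x$gene_id)
  rank <- as.integer(x$rank)
  strand <- parse_strand(x$strand)

  dup <- gene_id[duplicated(gene_id)]
  if (length(dup) > 0L) {
    stop("duplicate gene_id: ", paste(unique(dup), collapse = ", "))
  }
  ord <- order(chromosome, rank, method = "radix")
  out <- data.frame(
    chromosome = chromosome[ord], rank = rank[ord],
    gene_id = gene_id[ord], strand = strand[ord],
    stringsAsFactors = FALSE
  )
  for (chr in unique(out$chromosome)) {
    r <- out$rank[out$chromosome == chr]
    if (!identical(r, seq_along(r) - 1L)) {
      stop("non-dense ranks on chromosome '", chr,
           "': expected 0..", length(r) - 1L)
    }
  }
  rownames(out) <- NULL
  class(out) <- c("genome_table", "data.frame")
  out
}

parse_strand <- function(s) {
  if (is.numeric(s)) {
    v <- as.integer(s)
  } else {
    s <- as.character(s)
    v <- rep(NA_integer_, length(s))
    v[s %in% c("+", "+1", "1")] <- 1L
    v[s %in% c("-", "-1")] <- -1L
  }
  bad <- is.na(v) | !(v %in% c(1L, -1L))
  if (any(bad)) {
    stop("strand must be one of +, -, +1, -1 (got '",
         as.character(s[bad][1L]), "')")
  }
  v
}

#' @export
print.genome_table <- function(x, ...) {
  cat("Gene-order table: ", nrow(x), " genes on ",
      length(unique(x$chromosome)), " chromosomes/contigs\n", sep = "")
  NextMethod()
}

#' Read and write gene-order tables
#'
#' Gene orders travel as UTF-8 tab-separated files with a header row and
#' columns `chromosome`, `rank`, `gene_id`, `strand`.  The writer emits
#' deterministic canonical order (chromosome lexicographic, then rank) and
#' `+1`/`-1` strand spellings, so `write_gene_order(read_gene_order(f))`
#' is byte-identical to a canonicalized `f`.
#'
#' @param path Path to a TSV file.
#' @return `read_gene_order()` returns a validated [genome_table()];
#'   `write_gene_order()` returns `path` invisibly.
#' @export
read_gene_order <- function(path) {
  x <- utils::read.delim(path, colClasses = "character")
  genome_table(x)
}

#' @param genome A [genome_table()].
#' @rdname read_gene_order
#' @export
write_gene_order <- function(genome, path) {
  genome <- genome_table(genome)
  out <- genome
  out$strand <- ifelse(out$strand > 0L, "+1", "-1")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' WGD paralog maps
#'
#' A `paralog_map` records which genes of a genome still have their
#' whole-genome-duplication (WGD) partner: a perfect matching on its support.
#' Every gene occurs in at most one pair, and both members of every pair must
#' exist in the associated genome.  Genes in no pair are single-copy; the
#' derived counts are `n` (total genes) and `m` (single-copy genes), so
#' `n = 2 * npairs + m`.
#'
#' @param pairs A data frame (or 2-column matrix) whose first two columns
#'   hold the gene ids of each duplicate pair.  Order within a pair is
#'   immaterial; pairs are canonicalized so the lexicographically smaller id
#'   comes first.
#' @param genome The [genome_table()] the pairs refer to.
#' @return An object of class `paralog_map`: a list with elements `pairs`
#'   (canonical two-column data frame), `partner` (named character vector
#'   mapping each paired gene to its partner), `n` and `m`.
#' @export
paralog_map <- function(pairs, genome) {
  genome <- genome_table(genome)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) < 2L && nrow(pairs) > 0L) {
    stop("pairs must have two gene id columns")
  }
  if (nrow(pairs) == 0L) {
    pairs <- data.frame(gene_a = character(), gene_b = character(),
                        stringsAsFactors = FALSE)
  } else {
    a <- as.character(pairs[[1L]])
    b <- as.character(pairs[[2L]])
    if (any(a == b)) stop("a gene cannot be paired with itself: ", a[a == b][1L])
    swap <- b < a
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    ord <- order(a, b, method = "radix")
    pairs <- data.frame(gene_a = a[ord], gene_b = b[ord],
                        stringsAsFactors = FALSE)
  }
  support <- c(pairs$gene_a, pairs$gene_b)
  dup <- support[duplicated(support)]
  if (length(dup) > 0L) {
    stop("gene in more than one pair: ", paste(unique(dup), collapse = ", "))
  }
  missing <- setdiff(support, genome$gene_id)
  if (length(missing) > 0L) {
    stop("paired gene absent from genome: ", paste(missing, collapse = ", "))
  }
  partner <- stats::setNames(c(pairs$gene_b, pairs$gene_a),
                             c(pairs$gene_a, pairs$gene_b))
  n <- nrow(genome)
  structure(
    list(pairs = pairs, partner = partner, n = n, m = n - 2L * nrow(pairs)),
    class = "paralog_map"
  )
}

#' @export
print.paralog_map <- function(x, ...) {
  cat("WGD paralog map: ", nrow(x$pairs), " duplicate pairs; n = ", x$n,
      ", m = ", x$m, " single-copy genes\n", sep = "")
  invisible(x)
}

#' Read and write WGD paralog-pair lists
#'
#' Paralog pairs travel as a TSV with header columns `gene_a`, `gene_b`.
#' Reading validates the pairs against a genome (every gene must exist, and
#' occur in at most one pair) and computes the derived counts `n` and `m`.
#'
#' @param path Path to a TSV file.
#' @param genome The [genome_table()] the pairs refer to.
#' @return `read_paralog_pairs()` returns a [paralog_map()];
#'   `write_paralog_pairs()` returns `path` invisibly.
#' @export
read_paralog_pairs <- function(path, genome) {
  x <- utils::read.delim(path, colClasses = "character")
  paralog_map(x, genome)
}

#' @param pmap A [paralog_map()].
#' @rdname read_paralog_pairs
#' @export
write_paralog_pairs <- function(pmap, path) {
  stopifnot(inherits(pmap, "paralog_map"))
  utils::write.table(pmap$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Discard under-assembled contigs
#'
#' Incompletely assembled genomes contribute many short contigs that would
#' distort simulated null genomes.  A contig is kept when it carries at least
#' `min_duplicated` duplicated genes or at least `min_single` single-copy
#' genes (defaults 2 and 10); all other contigs are dropped and the ranks of
#' the survivors re-densified, preserving gene order.  Pair membership is
#' counted once, on the map as given; the filter is not re-iterated after
#' partners are lost with their contigs, and it is idempotent.
#'
#' @param genome A [genome_table()].
#' @param pmap The [paralog_map()] for `genome`.
#' @param min_duplicated,min_single Retention thresholds (non-negative).
#' @return A [genome_table()] with only the retained contigs.  The paralog
#'   map is not modified; rebuild it against the filtered genome with
#'   [prune_pairs()].
#' @export
filter_contigs <- function(genome, pmap, min_duplicated = 2, min_single = 10) {
  stopifnot(min_duplicated >= 0, min_single >= 0)
  genome <- genome_table(genome)
  paired <- genome$gene_id %in% names(pmap$partner)
  chroms <- unique(genome$chromosome)
  ndup <- table(factor(genome$chromosome[paired], levels = chroms))
  nsing <- table(factor(genome$chromosome[!paired], levels = chroms))
  keep <- chroms[ndup >= min_duplicated | nsing >= min_single]
  out <- genome[genome$chromosome %in% keep, , drop = FALSE]
  out$rank <- stats::ave(out$rank, out$chromosome,
                         FUN = function(r) seq_along(r) - 1L)
  rownames(out) <- NULL
  class(out) <- c("genome_table", "data.frame")
  out
}

#' Restrict a paralog map to the genes of a (filtered) genome
#'
#' Drops every pair with at least one member absent from `genome` and
#' recomputes `n` and `m`.  Used after [filter_contigs()], whose removal of a
#' contig can strand the partners of its duplicated genes.
#'
#' @param pmap A [paralog_map()].
#' @param genome The [genome_table()] to restrict to.
#' @return A [paralog_map()] valid for `genome`.
#' @export
prune_pairs <- function(pmap, genome) {
  stopifnot(inherits(pmap, "paralog_map"))
  keep <- pmap$pairs$gene_a %in% genome$gene_id &
    pmap$pairs$gene_b %in% genome$gene_id
  paralog_map(pmap$pairs[keep, , drop = FALSE], genome)
}
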