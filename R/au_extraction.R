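#' Pillar positions per chromosome
#'
#' A *pillar* is a gene that still has its WGD partner.  Pillars delimit the
#' runs of single-copy genes from which analytical units are built.
#'
#' @param genome A [genome_table()].
#' @param pmap The [paralog_map()] for `genome`.
#' @return A named list, one element per chromosome, of the ascending ranks
#'   of the paired genes on that chromosome (possibly empty).
#' @export
find_pillars <- function(genome, pmap) {
  genome <- genome_table(genome)
  paired <- genome$gene_id %in% names(pmap$partner)
  chroms <- unique(genome$chromosome)
  out <- lapply(chroms, function(chr) {
    genome$rank[paired & genome$chromosome == chr]
  })
  stats::setNames(out, chroms)
}

#' Extract analytical units (AUs)
#'
#' An analytical unit is a pair of homeologous single-copy segments: a run
#' of unpaired genes `p1, s, ..., s, q1` between two consecutive pillars on
#' one chromosome, together with the run `p2, t, ..., t, q2` between the
#' partners `p2 = partner(p1)` and `q2 = partner(q1)`, which must themselves
#' be consecutive pillars on their chromosome (another chromosome, or
#' elsewhere on the same one).  Orientation must be consistent: either the
#' *parallel* form, with `strand(p1) == strand(p2)` and
#' `strand(q1) == strand(q2)` and the second segment read `p2 .. q2`, or the
#' *inverted* form, with the second segment read `q2 .. p2` and both
#' bounding pairs on opposite strands.  These requirements make it very
#' unlikely that rearrangement has swapped material in or out of the unit,
#' so the interior genes can be attributed to fractionation of originally
#' duplicated positions.
#'
#' The bounding pairs determine everything: an adjacency `(p1, q1)` can
#' belong to at most one AU because its partner adjacency is forced.  Two
#' AUs may share a bounding pillar but never interior genes; the degenerate
#' case where an adjacency would pair with itself (both sides the same
#' segment) is rejected.  Strands of interior single-copy genes are ignored.
#'
#' @param genome A [genome_table()].
#' @param pmap The [paralog_map()] for `genome`.
#' @return An `au_set`: a data frame with one row per AU and columns
#'   `chrom_a`, `p1`, `q1`, `chrom_b`, `p2`, `q2`, `form`
#'   (`"parallel"`/`"inverted"`), `side_a_count`, `side_b_count`,
#'   `s` (total single-copy genes, both sides), `q_min`
#'   (the smaller side count), and list columns `side_a_genes`,
#'   `side_b_genes` with the interior gene ids in chromosome order.
#' @export
extract_aus <- function(genome, pmap) {
  genome <- genome_table(genome)
  adj <- pillar_adjacencies(genome, pmap)
  empty <- empty_au_set()
  if (nrow(adj) == 0L) return(empty)

  partner <- pmap$partner
  strand <- stats::setNames(genome$strand, genome$gene_id)
  left_idx <- stats::setNames(seq_len(nrow(adj)), adj$left)

  p1 <- adj$left
  q1 <- adj$right
  p2 <- unname(partner[p1])
  q2 <- unname(partner[q1])

  # parallel: partner segment runs p2 .. q2, strands equal at both ends
  b_par <- unname(left_idx[p2])
  ok_par <- !is.na(b_par) & adj$right[b_par] == q2 &
    strand[p1] == strand[p2] & strand[q1] == strand[q2]
  # inverted: partner segment runs q2 .. p2, strands opposite at both ends
  b_inv <- unname(left_idx[q2])
  ok_inv <- !is.na(b_inv) & adj$right[b_inv] == p2 &
    strand[p1] == -strand[p2] & strand[q1] == -strand[q2]

  b <- ifelse(ok_par, b_par, ifelse(ok_inv, b_inv, NA_integer_))
  form <- ifelse(ok_par, "parallel", "inverted")
  a <- seq_len(nrow(adj))
  # each AU is seen from both of its sides; keep the a < b representative
  # (a == b would be a segment paired with itself: overlapping, rejected)
  sel <- which(!is.na(b) & a < b)
  if (length(sel) == 0L) return(empty)
  bb <- b[sel]

  interior <- function(i) {
    lo <- adj$li[i] + 1L
    hi <- adj$ri[i] - 1L
    if (lo > hi) character() else genome$gene_id[lo:hi]
  }
  side_a <- lapply(sel, interior)
  side_b <- lapply(bb, interior)
  na <- lengths(side_a)
  nb <- lengths(side_b)
  out <- data.frame(
    chrom_a = adj$chrom[sel], p1 = p1[sel], q1 = q1[sel],
    chrom_b = adj$chrom[bb], p2 = p2[sel], q2 = q2[sel],
    form = form[sel],
    side_a_count = na, side_b_count = nb,
    s = na + nb, q_min = pmin(na, nb),
    stringsAsFactors = FALSE
  )
  out$side_a_genes <- side_a
  out$side_b_genes <- side_b
  rownames(out) <- NULL
  class(out) <- c("au_set", "data.frame")
  out
}

empty_au_set <- function() {
  out <- data.frame(
    chrom_a = character(), p1 = character(), q1 = character(),
    chrom_b = character(), p2 = character(), q2 = character(),
    form = character(), side_a_count = integer(), side_b_count = integer(),
    s = integer(), q_min = integer(), stringsAsFactors = FALSE
  )
  out$side_a_genes <- list()
  out$side_b_genes <- list()
  class(out) <- c("au_set", "data.frame")
  out
}

# One row per pair of consecutive pillars on a chromosome: the bounding
# genes, their row indices in the canonical table, and the chromosome.
# Interior genes are unpaired by construction (no pillar lies between).
pillar_adjacencies <- function(genome, pmap) {
  paired <- genome$gene_id %in% names(pmap$partner)
  idx <- which(paired)
  if (length(idx) == 0L) {
    return(data.frame(chrom = character(), left = character(),
                      right = character(), li = integer(), ri = integer(),
                      stringsAsFactors = FALSE))
  }
  chrom <- genome$chromosome[idx]
  keep <- which(chrom[-length(chrom)] == chrom[-1L])  # consecutive, same chrom
  li <- idx[keep]
  ri <- idx[keep + 1L]
  data.frame(
    chrom = genome$chromosome[li],
    left = genome$gene_id[li], right = genome$gene_id[ri],
    li = li, ri = ri, stringsAsFactors = FALSE
  )
}

#' AU size histogram
#'
#' Counts `N(s)` of analytical units by total single-copy content `s`,
#' including `s = 0` (two duplicate pairs immediately adjacent on both
#' chromosomes).
#'
#' @param aus An `au_set` from [extract_aus()].
#' @return An `au_histogram`: a named integer vector of counts for
#'   `s = 0..max(s)` (a single zero count when there are no AUs).
#' @export
au_histogram <- function(aus) {
  if (nrow(aus) == 0L) {
    counts <- c(`0` = 0L)
  } else {
    smax <- max(aus$s)
    counts <- tabulate(aus$s + 1L, nbins = smax + 1L)
    names(counts) <- 0:smax
  }
  structure(counts, class = "au_histogram")
}

#' @export
print.au_histogram <- function(x, ...) {
  cat("AU size histogram (", sum(x), " AUs, s = 0..",
      length(x) - 1L, ")\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Write an AU table to TSV
#'
#' Emits the scalar columns of an `au_set` (bounding genes, form, side
#' counts, `s`, `q_min`); interior gene lists go to a companion file with
#' one row per AU side, genes comma-separated.
#'
#' @param aus An `au_set` from [extract_aus()].
#' @param path Output TSV path.
#' @param genes_path Optional companion file for the interior gene lists.
#' @return `path`, invisibly.
#' @export
write_aus <- function(aus, path, genes_path = NULL) {
  flat <- as.data.frame(aus)[, c("chrom_a", "p1", "q1", "chrom_b", "p2",
                                 "q2", "form", "side_a_count",
                                 "side_b_count", "s", "q_min")]
  utils::write.table(flat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(genes_path)) {
    sides <- data.frame(
      au = rep(seq_len(nrow(aus)), 2L),
      side = rep(c("a", "b"), each = nrow(aus)),
      genes = c(vapply(aus$side_a_genes, paste, "", collapse = ","),
                vapply(aus$side_b_genes, paste, "", collapse = ",")),
      stringsAsFactors = FALSE
    )
    sides <- sides[order(sides$au, sides$side), , drop = FALSE]
    utils::write.table(sides, genes_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  invisible(path)
}
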