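#' Toy three-chromosome AU demonstration genome
#'
#' A deterministic fixture with two homeologous chromosomes carrying four
#' duplicate pairs (`a`, `b`, `c`, `d`) and a third chromosome holding the
#' partner of a gene `x1` that sits between the last two pairs on
#' chromosome 1.  The adjacencies bounded by `a`/`b` and `b`/`c` form two
#' valid analytical units (sizes 3 and 3); the candidate bounded by `c`/`d`
#' is disqualified because `x1` is itself a pillar — its paralog lies on
#' the third chromosome, breaking the pillar adjacency.
#'
#' @return List with `genome` (a [genome_table()]) and `pmap`
#'   (a [paralog_map()]); `extract_aus()` on it yields exactly 2 AUs.
#' @export
make_figure2_fixture <- function() {
  rows <- function(chr, genes, strands) {
    data.frame(chromosome = chr, rank = seq_along(genes) - 1L,
               gene_id = genes, strand = strands, stringsAsFactors = FALSE)
  }
  genome <- genome_table(rbind(
    rows("chr1", c("a1", "u1", "u2", "b1", "u3", "c1", "u4", "x1", "u5", "d1"),
         rep(1L, 10L)),
    rows("chr2", c("a2", "v1", "b2", "v2", "v3", "c2", "v4", "d2"),
         rep(1L, 8L)),
    rows("chr3", c("x2", "w1"), rep(1L, 2L))
  ))
  pairs <- data.frame(
    gene_a = c("a1", "b1", "c1", "d1", "x1"),
    gene_b = c("a2", "b2", "c2", "d2", "x2"),
    stringsAsFactors = FALSE
  )
  list(genome = genome, pmap = paralog_map(pairs, genome))
}

#' Synthetic all-against-all hit tables with planted WGD pairs
#'
#' Emulates the score structure of BLASTP hit tables used to assign
#' vertebrate WGD paralogs: planted WGD pairs score inside the outgroup
#' bracket (stronger than their best lower-outgroup hit, weaker than every
#' upper-outgroup genome's best hit) and above the 140-bit floor; decoys
#' fall outside — one "young" duplicate pair scoring above the upper
#' bracket (post-split duplication) and one "ancient" pair scoring below
#' 140 bits.  Noise hits between non-partner genes are weaker than the
#' planted pair scores, so best-reciprocal-hit filtering removes them.
#' Remaining genes are singletons, half of them with a correspondence in
#' both outgroup clades (verifiable), half missing one.
#'
#' @param num_genes Total genes in the focal genome (`>= 4`).
#' @param seed RNG seed.
#' @return List of [hit_table()]s `self`, `lower1`, `lower2` (two lower
#'   outgroup genomes), `upper1`, `upper2` (two upper outgroup genomes),
#'   and `truth`: the planted `pairs` (data frame), `verified_singletons`,
#'   and `decoy_pairs`.
#' @export
make_hit_table_fixture <- function(num_genes, seed = NULL) {
  stopifnot(num_genes >= 4)
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("g%03d", seq_len(num_genes))
  P <- max(1L, (num_genes - 4L) %/% 4L)
  if (num_genes < 8L) P <- 1L
  pair_a <- genes[2L * seq_len(P) - 1L]
  pair_b <- genes[2L * seq_len(P)]
  rest <- genes[-seq_len(2L * P)]
  has_decoys <- length(rest) >= 4L
  if (has_decoys) {
    young <- rest[1:2]   # duplicated after the upper-outgroup split
    old <- rest[3:4]     # duplicated long before the WGD
    singles <- rest[-(1:4)]
  } else {
    young <- old <- character()
    singles <- rest
  }

  S <- stats::runif(P, 200, 300)             # planted paralog scores
  lower_gap <- stats::runif(P, 20, 60)
  upper_gap <- stats::runif(P, 20, 60)

  hit <- function(q, s, qg, sg, score) {
    data.frame(query_gene = q, subject_gene = s, query_genome = qg,
               subject_genome = sg, bitscore = score,
               stringsAsFactors = FALSE)
  }
  og <- function(genes, genome, scores) {
    hit(genes, paste0(genome, "_", genes), "target", genome, scores)
  }

  self <- rbind(
    hit(pair_a, pair_b, "target", "target", S),
    hit(pair_b, pair_a, "target", "target", S)
  )
  # noise: each planted gene also weakly hits the next pair's genes
  if (P > 1L) {
    noise_s <- stats::runif(P - 1L, 80, 190)
    self <- rbind(
      self,
      hit(pair_a[-P], pair_a[-1L], "target", "target", noise_s),
      hit(pair_a[-1L], pair_a[-P], "target", "target", noise_s)
    )
  }
  lower1 <- og(c(pair_a, pair_b), "lowerA", rep(S - lower_gap, 2L))
  lower2 <- og(c(pair_a, pair_b), "lowerB", rep(S - lower_gap - 5, 2L))
  upper1 <- og(c(pair_a, pair_b), "upperA", rep(S + upper_gap, 2L))
  upper2 <- og(c(pair_a, pair_b), "upperB", rep(S + upper_gap + 5, 2L))

  if (has_decoys) {
    self <- rbind(
      self,
      hit(young, rev(young), "target", "target", c(400, 400)),
      hit(old, rev(old), "target", "target", c(120, 120))
    )
    # young pair: upper-outgroup best (320) below the paralog score
    lower1 <- rbind(lower1, og(young, "lowerA", c(200, 200)))
    upper1 <- rbind(upper1, og(young, "upperA", c(320, 320)))
    upper2 <- rbind(upper2, og(young, "upperB", c(330, 330)))
    # old pair: inside the bracket but under the 140-bit floor
    lower1 <- rbind(lower1, og(old, "lowerA", c(100, 100)))
    upper1 <- rbind(upper1, og(old, "upperA", c(300, 300)))
    upper2 <- rbind(upper2, og(old, "upperB", c(310, 310)))
  }

  verified <- character()
  if (length(singles) > 0L) {
    idx <- seq_along(singles)
    verified <- singles[idx %% 2L == 1L]     # hits in both clades
    unver <- singles[idx %% 2L == 0L]        # lower-clade hit only
    if (length(verified) > 0L) {
      lower1 <- rbind(lower1, og(verified, "lowerA",
                                 stats::runif(length(verified), 100, 200)))
      lower2 <- rbind(lower2, og(verified, "lowerB",
                                 stats::runif(length(verified), 100, 200)))
      upper1 <- rbind(upper1, og(verified, "upperA",
                                 stats::runif(length(verified), 150, 250)))
      upper2 <- rbind(upper2, og(verified, "upperB",
                                 stats::runif(length(verified), 150, 250)))
    }
    if (length(unver) > 0L) {
      lower1 <- rbind(lower1, og(unver, "lowerA",
                                 stats::runif(length(unver), 100, 200)))
      lower2 <- rbind(lower2, og(unver, "lowerB",
                                 stats::runif(length(unver), 100, 200)))
    }
  }

  list(
    self = hit_table(self),
    lower1 = hit_table(lower1), lower2 = hit_table(lower2),
    upper1 = hit_table(upper1), upper2 = hit_table(upper2),
    truth = list(
      pairs = data.frame(gene_a = pair_a, gene_b = pair_b,
                         stringsAsFactors = FALSE),
      verified_singletons = verified,
      decoy_pairs = data.frame(
        gene_a = c(young[1L][has_decoys], old[1L][has_decoys]),
        gene_b = c(young[2L][has_decoys], old[2L][has_decoys]),
        stringsAsFactors = FALSE
      )
    )
  )
}
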