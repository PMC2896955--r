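#' Simulation configuration for post-WGD genome collapse
#'
#' Bundles the parameters of one simulated descendant of a whole-genome
#' duplication.  The ancestral tetraploid holds `num_pairs` duplicate pairs
#' (`(n + m) / 2` when matching a real genome with `n` genes and `m`
#' single-copy genes) spread over `num_chromosomes` pre-WGD chromosomes,
#' each then doubled.  Collapse reduces exactly `m` pairs in deletion runs
#' whose drawn length is Geometric with mean `mu` (support `1, 2, ...`),
#' applies `d` rearrangements (inversions and reciprocal translocations),
#' and conserves each run's survivors on chromosome copy "A" with
#' probability `retention_bias` (0.5 = the unbiased null).
#'
#' @param num_pairs Ancestral duplicate-pair count.
#' @param m Number of pairs to reduce (`m <= num_pairs`).
#' @param d Number of rearrangement events.
#' @param num_chromosomes Pre-WGD chromosome count (default 8).
#' @param mu Mean deletion-run length, `>= 1`; `mu = 1` deletes one gene at
#'   a time.
#' @param retention_bias Probability a run's survivors sit on copy A.
#' @param inversion_fraction Share of rearrangements that are inversions
#'   (the rest are reciprocal translocations).
#' @param interleave When rearrangements happen relative to deletions:
#'   `"shuffled"` scatters the `d` events uniformly along the deletion
#'   timeline; `"deletions_first"` and `"rearrangements_first"` do what they
#'   say.
#' @param seed RNG seed; identical config and seed give identical outputs.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(num_pairs, m, d, num_chromosomes = 8,
                              mu = 1, retention_bias = 0.5,
                              inversion_fraction = 0.5,
                              interleave = c("shuffled", "deletions_first",
                                             "rearrangements_first"),
                              seed = NULL) {
  interleave <- match.arg(interleave)
  stopifnot(num_pairs >= 1, num_chromosomes >= 1,
            num_pairs >= num_chromosomes,
            m >= 0, m <= num_pairs, d >= 0, mu >= 1,
            retention_bias >= 0, retention_bias <= 1,
            inversion_fraction >= 0, inversion_fraction <= 1)
  structure(
    list(num_pairs = as.integer(num_pairs), m = as.integer(m),
         d = as.integer(d), num_chromosomes = as.integer(num_chromosomes),
         mu = mu, retention_bias = retention_bias,
         inversion_fraction = inversion_fraction, interleave = interleave,
         seed = seed),
    class = "simulation_config"
  )
}

# ---- internal genome representation ---------------------------------------
# ids:        character, gene id per integer code
# strand:     integer +-1 per code
# chrom_genes: named list (chromosome -> integer codes in gene order)
# gene_chrom: integer chromosome index per code
# pair_of:    integer pair id per code (NA for never-duplicated genes)
# pair_genes: K x 2 matrix of codes, column 1 = copy "A" (lower gene id)
# reduced:    logical per pair

state_from_tables <- function(genome, pmap = NULL) {
  genome <- genome_table(genome)
  n <- nrow(genome)
  chroms <- unique(genome$chromosome)
  f <- factor(genome$chromosome, levels = chroms)
  chrom_genes <- split(seq_len(n), f)
  if (is.null(pmap)) {
    pair_genes <- matrix(integer(), 0L, 2L)
  } else {
    a <- match(pmap$pairs$gene_a, genome$gene_id)
    b <- match(pmap$pairs$gene_b, genome$gene_id)
    pair_genes <- cbind(a, b)
  }
  pair_of <- rep(NA_integer_, n)
  if (nrow(pair_genes) > 0L) {
    pair_of[pair_genes[, 1L]] <- seq_len(nrow(pair_genes))
    pair_of[pair_genes[, 2L]] <- seq_len(nrow(pair_genes))
  }
  list(ids = genome$gene_id, strand = genome$strand,
       chrom_genes = chrom_genes, gene_chrom = match(genome$chromosome, chroms),
       pair_of = pair_of, pair_genes = pair_genes,
       reduced = rep(FALSE, nrow(pair_genes)))
}

state_to_tables <- function(state) {
  lens <- lengths(state$chrom_genes)
  keep <- which(lens > 0L)
  codes <- unlist(state$chrom_genes[keep], use.names = FALSE)
  genome <- data.frame(
    chromosome = rep(names(state$chrom_genes)[keep], lens[keep]),
    rank = unlist(lapply(lens[keep], function(k) seq_len(k) - 1L),
                  use.names = FALSE),
    gene_id = state$ids[codes],
    strand = state$strand[codes],
    stringsAsFactors = FALSE
  )
  genome <- genome_table(genome)
  alive <- !state$reduced
  pairs <- data.frame(
    gene_a = state$ids[state$pair_genes[alive, 1L]],
    gene_b = state$ids[state$pair_genes[alive, 2L]],
    stringsAsFactors = FALSE
  )
  list(genome = genome, pmap = paralog_map(pairs, genome))
}

# Doubled ancestor, directly in internal representation.  Genes are
# distributed near-evenly (1 + multinomial remainder) over the pre-WGD
# chromosomes, every chromosome is duplicated into copies A and B, pairs sit
# at positionally homologous ranks, and strands are random but identical
# within a pair.
ancestor_state <- function(num_pairs, num_chromosomes) {
  P <- as.integer(num_pairs)
  k <- as.integer(num_chromosomes)
  counts <- rep(1L, k)
  if (P > k) {
    counts <- counts + as.integer(stats::rmultinom(1L, P - k, rep(1 / k, k)))
  }
  pair_strand <- sample(c(1L, -1L), P, replace = TRUE)
  ids <- c(sprintf("g%05dA", seq_len(P)), sprintf("g%05dB", seq_len(P)))
  chrom_of_pair <- rep(seq_len(k), counts)
  chrom_genes <- vector("list", 2L * k)
  cn <- character(2L * k)
  for (i in seq_len(k)) {
    codes_a <- which(chrom_of_pair == i)
    chrom_genes[[2L * i - 1L]] <- codes_a
    chrom_genes[[2L * i]] <- codes_a + P
    cn[2L * i - 1L] <- sprintf("chr%02dA", i)
    cn[2L * i] <- sprintf("chr%02dB", i)
  }
  names(chrom_genes) <- cn
  gene_chrom <- integer(2L * P)
  for (c in seq_along(chrom_genes)) gene_chrom[chrom_genes[[c]]] <- c
  list(ids = ids, strand = c(pair_strand, pair_strand),
       chrom_genes = chrom_genes, gene_chrom = gene_chrom,
       pair_of = c(seq_len(P), seq_len(P)),
       pair_genes = cbind(seq_len(P), seq_len(P) + P),
       reduced = rep(FALSE, P))
}

# Core collapse engine: exactly m pair reductions via geometric deletion
# runs, d rearrangements, interleaved per policy.  Consumes the current RNG
# stream.  Returns list(state, events).
run_collapse <- function(state, m, d, mu = 1, retention_bias = 0.5,
                         inversion_fraction = 0.5, interleave = "shuffled") {
  ids <- state$ids
  strand <- state$strand
  chrom_genes <- state$chrom_genes
  cnames <- names(chrom_genes)
  gene_chrom <- state$gene_chrom
  pair_of <- state$pair_of
  pair_genes <- state$pair_genes
  reduced <- state$reduced

  avail <- which(!reduced)
  if (m > length(avail)) {
    stop("m (", m, ") exceeds the ", length(avail), " unreduced pairs")
  }
  avail_pos <- integer(length(reduced))
  avail_pos[avail] <- seq_along(avail)
  nav <- length(avail)

  events <- vector("list", m + d + 8L)
  nev <- 0L
  add_event <- function(e) {
    nev <<- nev + 1L
    if (nev > length(events)) length(events) <<- 2L * nev  # grow
    events[[nev]] <<- e
  }

  do_rearrangement <- function() {
    lens <- lengths(chrom_genes)
    ne <- which(lens > 0L)
    want_inv <- stats::runif(1) < inversion_fraction
    fallback <- !want_inv && length(ne) < 2L
    if (want_inv || fallback) {
      c1 <- ne[sample.int(length(ne), 1L)]
      v <- chrom_genes[[c1]]
      ij <- sort(sample.int(length(v), 2L, replace = TRUE))
      seg <- ij[1L]:ij[2L]
      v[seg] <- rev(v[seg])
      strand[v[seg]] <<- -strand[v[seg]]
      chrom_genes[[c1]] <<- v
      add_event(list(type = "inversion", chrom = cnames[c1],
                     start = ij[1L], end = ij[2L], fallback = fallback))
    } else {
      cc <- ne[sample.int(length(ne), 2L)]
      v1 <- chrom_genes[[cc[1L]]]
      v2 <- chrom_genes[[cc[2L]]]
      b1 <- sample.int(length(v1) + 1L, 1L) - 1L
      b2 <- sample.int(length(v2) + 1L, 1L) - 1L
      new1 <- c(v1[seq_len(b1)],
                if (b2 < length(v2)) v2[(b2 + 1L):length(v2)])
      new2 <- c(v2[seq_len(b2)],
                if (b1 < length(v1)) v1[(b1 + 1L):length(v1)])
      chrom_genes[[cc[1L]]] <<- new1
      chrom_genes[[cc[2L]]] <<- new2
      gene_chrom[new1] <<- cc[1L]
      gene_chrom[new2] <<- cc[2L]
      add_event(list(type = "translocation", chrom1 = cnames[cc[1L]],
                     chrom2 = cnames[cc[2L]], break1 = b1, break2 = b2))
    }
  }

  thr <- switch(interleave,
    shuffled = sort(sample.int(m + 1L, d, replace = TRUE) - 1L),
    deletions_first = rep(m, d),
    rearrangements_first = rep(0L, d)
  )
  ri <- 1L
  done <- 0L
  while (done < m) {
    while (ri <= d && thr[ri] <= done) {
      do_rearrangement()
      ri <- ri + 1L
    }
    L <- if (mu <= 1) 1L else stats::rgeom(1L, 1 / mu) + 1L
    j <- avail[sample.int(nav, 1L)]
    del_side <- if (stats::runif(1) < retention_bias) 2L else 1L
    start <- pair_genes[j, del_side]
    ci <- gene_chrom[start]
    vec <- chrom_genes[[ci]]
    pos <- match(start, vec)
    kmax <- min(L, length(vec) - pos + 1L, m - done)
    k <- 0L
    while (k < kmax) {
      cd <- vec[pos + k]
      pid <- pair_of[cd]
      if (is.na(pid) || reduced[pid]) break
      reduced[pid] <- TRUE
      pp <- avail_pos[pid]
      last <- avail[nav]
      avail[pp] <- last
      avail_pos[last] <- pp
      nav <- nav - 1L
      k <- k + 1L
    }
    del <- vec[pos:(pos + k - 1L)]
    chrom_genes[[ci]] <- vec[-(pos:(pos + k - 1L))]
    done <- done + k
    surv <- pair_genes[pair_of[del], , drop = FALSE]  # survivor = other copy
    surv <- ifelse(surv[, 1L] == del, surv[, 2L], surv[, 1L])
    add_event(list(type = "deletion", chrom = cnames[ci], start = pos,
                   length_drawn = as.integer(L), length = k,
                   genes = ids[del], survivors = ids[surv],
                   retained_side = if (del_side == 2L) "A" else "B"))
  }
  while (ri <= d) {
    do_rearrangement()
    ri <- ri + 1L
  }

  state$strand <- strand
  state$chrom_genes <- chrom_genes
  state$gene_chrom <- gene_chrom
  state$reduced <- reduced
  list(state = state, events = events[seq_len(nev)])
}

#' Build a doubled (post-WGD) ancestor genome
#'
#' Distributes `num_pairs` genes near-evenly over `num_chromosomes`
#' pre-WGD chromosomes, then duplicates every chromosome into copies A and
#' B.  Pairs sit at positionally homologous ranks; strands are random but
#' identical within a pair.  On the untouched ancestor every interior
#' pillar adjacency bounds an AU of size 0.
#'
#' @inheritParams simulation_config
#' @return A list with elements `genome` (a [genome_table()]) and `pmap`
#'   (the [paralog_map()] pairing the A and B copies).
#' @export
make_doubled_ancestor <- function(num_pairs, num_chromosomes = 8,
                                  seed = NULL) {
  stopifnot(num_pairs >= num_chromosomes, num_chromosomes >= 1)
  if (!is.null(seed)) set.seed(seed)
  state_to_tables(ancestor_state(num_pairs, num_chromosomes))
}

#' Reduce paralog pairs by geometric deletion runs
#'
#' Repeats until exactly `m` pairs are reduced: draw a run length `L` from
#' a Geometric distribution with mean `mu` (`P(L = k) = (1 - 1/mu)^(k-1) /
#' mu`, support `k >= 1`); pick a uniform random gene among copies of
#' unreduced pairs (choosing the copy on side B with probability
#' `retention_bias`, so the survivors sit on side A); delete up to `L`
#' consecutive deletable genes rightward from that position.  A run
#' truncates at the chromosome end, at an already-single gene (deleting it
#' would kill a pair's last copy), or when the `m` quota is reached; the
#' event log records both the drawn and the realized length.  Survivors are
#' the partners on the homeologous chromosome.
#'
#' @param genome A [genome_table()].
#' @param pmap The [paralog_map()] for `genome`.
#' @param m Number of pairs to reduce.
#' @inheritParams simulation_config
#' @return List with the reduced `genome`, the pruned `pmap` (surviving
#'   pairs only), and `events` (the deletion log).
#' @export
simulate_reduction <- function(genome, pmap, m, mu = 1,
                               retention_bias = 0.5, seed = NULL) {
  stopifnot(mu >= 1, m >= 0)
  if (!is.null(seed)) set.seed(seed)
  state <- state_from_tables(genome, pmap)
  res <- run_collapse(state, m = m, d = 0L, mu = mu,
                      retention_bias = retention_bias)
  out <- state_to_tables(res$state)
  list(genome = out$genome, pmap = out$pmap, events = res$events)
}

#' Apply random genome rearrangements
#'
#' Applies `d` events.  Each is, with probability `inversion_fraction`, an
#' inversion of a uniform random rank interval on a uniform random
#' (non-empty) chromosome — reversing gene order and flipping strands — and
#' otherwise a reciprocal translocation exchanging the tails of two
#' distinct chromosomes at uniform random breakpoints.  A translocation
#' requested when fewer than two non-empty chromosomes exist falls back to
#' an inversion (flagged in the log).  Gene content is unchanged.
#'
#' @param genome A [genome_table()].
#' @param d Number of events.
#' @inheritParams simulation_config
#' @return List with the rearranged `genome` and `events`.
#' @export
apply_rearrangements <- function(genome, d, inversion_fraction = 0.5,
                                 seed = NULL) {
  stopifnot(d >= 0)
  if (!is.null(seed)) set.seed(seed)
  state <- state_from_tables(genome, pmap = NULL)
  res <- run_collapse(state, m = 0L, d = as.integer(d),
                      inversion_fraction = inversion_fraction,
                      interleave = "rearrangements_first")
  lens <- lengths(res$state$chrom_genes)
  keep <- which(lens > 0L)
  codes <- unlist(res$state$chrom_genes[keep], use.names = FALSE)
  out <- data.frame(
    chromosome = rep(names(res$state$chrom_genes)[keep], lens[keep]),
    rank = unlist(lapply(lens[keep], function(k) seq_len(k) - 1L),
                  use.names = FALSE),
    gene_id = res$state$ids[codes],
    strand = res$state$strand[codes],
    stringsAsFactors = FALSE
  )
  list(genome = genome_table(out), events = res$events)
}

#' Simulate one post-WGD descendant genome
#'
#' Composes the full collapse: doubled ancestor, `m` pair reductions in
#' geometric deletion runs, and `d` rearrangements interleaved according to
#' the configured policy.  Deterministic given the config and seed.
#'
#' @param config A [simulation_config()].
#' @return List with `genome`, `pmap` (surviving pairs), `events`,
#'   `ancestor` (the pre-collapse `genome`/`pmap` pair, for event-log
#'   replay) and `config`.
#' @export
simulate_descendant <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  state <- ancestor_state(config$num_pairs, config$num_chromosomes)
  ancestor <- state_to_tables(state)
  res <- run_collapse(state, m = config$m, d = config$d, mu = config$mu,
                      retention_bias = config$retention_bias,
                      inversion_fraction = config$inversion_fraction,
                      interleave = config$interleave)
  out <- state_to_tables(res$state)
  list(genome = out$genome, pmap = out$pmap, events = res$events,
       ancestor = ancestor, config = config)
}

#' Replay an event log
#'
#' Applies a logged sequence of deletion, inversion and translocation
#' events to a genome, mechanically.  Replaying the log returned by
#' [simulate_descendant()] on its `ancestor$genome` reproduces the
#' simulated genome exactly — the determinism contract of the event log.
#'
#' @param genome The starting [genome_table()].
#' @param events An event list as produced by the simulator.
#' @return The resulting [genome_table()].
#' @export
replay_events <- function(genome, events) {
  genome <- genome_table(genome)
  chroms <- unique(genome$chromosome)
  f <- factor(genome$chromosome, levels = chroms)
  gl <- split(genome$gene_id, f)
  st <- split(genome$strand, f)
  for (e in events) {
    if (e$type == "deletion") {
      keep <- !(gl[[e$chrom]] %in% e$genes)
      gl[[e$chrom]] <- gl[[e$chrom]][keep]
      st[[e$chrom]] <- st[[e$chrom]][keep]
    } else if (e$type == "inversion") {
      seg <- e$start:e$end
      gl[[e$chrom]][seg] <- rev(gl[[e$chrom]][seg])
      st[[e$chrom]][seg] <- -rev(st[[e$chrom]][seg])
    } else if (e$type == "translocation") {
      v1 <- gl[[e$chrom1]]; s1 <- st[[e$chrom1]]
      v2 <- gl[[e$chrom2]]; s2 <- st[[e$chrom2]]
      tail1 <- if (e$break1 < length(v1)) (e$break1 + 1L):length(v1) else integer()
      tail2 <- if (e$break2 < length(v2)) (e$break2 + 1L):length(v2) else integer()
      gl[[e$chrom1]] <- c(v1[seq_len(e$break1)], v2[tail2])
      st[[e$chrom1]] <- c(s1[seq_len(e$break1)], s2[tail2])
      gl[[e$chrom2]] <- c(v2[seq_len(e$break2)], v1[tail1])
      st[[e$chrom2]] <- c(s2[seq_len(e$break2)], s1[tail1])
    } else {
      stop("unknown event type: ", e$type)
    }
  }
  lens <- lengths(gl)
  keep <- which(lens > 0L)
  genome_table(data.frame(
    chromosome = rep(chroms[keep], lens[keep]),
    rank = unlist(lapply(lens[keep], function(k) seq_len(k) - 1L),
                  use.names = FALSE),
    gene_id = unlist(gl[keep], use.names = FALSE),
    strand = unlist(st[keep], use.names = FALSE),
    stringsAsFactors = FALSE
  ))
}

#' Deletion-run length experiment
#'
#' Generates one "pseudo-real" genome collapsed with deletion runs of mean
#' `mu`, plus a matched ensemble of single-gene-deletion (`mu = 1`) null
#' simulations with the same `(num_pairs, m, d)`, runs the full AU +
#' concentration pipeline and returns the per-size above-diagonal
#' proportion curves.  Defaults reproduce the published experiment: a
#' present-day genome of `n = 12000` genes with `m = 10000` single-copy
#' genes (ancestor of `(n + m)/2 = 11000` pairs) and `d = 500`
#' rearrangements.
#'
#' @param mu Mean deletion-run length of the pseudo-real genome.
#' @param reps Number of null replicates.
#' @inheritParams simulation_config
#' @return List with `mu`, the [diagonal_comparison()], and the per-size
#'   proportions `prop_all` (all points) and `prop_offdiag` (points on the
#'   diagonal ignored).
#' @export
run_deletion_length_experiment <- function(mu, reps = 200,
                                           num_pairs = 11000, m = 10000,
                                           d = 500, num_chromosomes = 8,
                                           seed = NULL) {
  stopifnot(mu >= 1, reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  subseeds <- sample.int(.Machine$integer.max, reps + 1L)
  conc_of <- function(cfg) {
    sim <- simulate_descendant(cfg)
    empirical_concentration(extract_aus(sim$genome, sim$pmap))
  }
  real <- conc_of(simulation_config(num_pairs, m, d,
                                    num_chromosomes = num_chromosomes,
                                    mu = mu, seed = subseeds[1L]))
  sims <- lapply(seq_len(reps), function(i) {
    conc_of(simulation_config(num_pairs, m, d,
                              num_chromosomes = num_chromosomes,
                              mu = 1, seed = subseeds[i + 1L]))
  })
  comp <- diagonal_comparison(real, sims)
  list(mu = mu, comparison = comp,
       prop_all = proportion_above_by_size(comp, exclude_on_diagonal = FALSE),
       prop_offdiag = proportion_above_by_size(comp, exclude_on_diagonal = TRUE))
}
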