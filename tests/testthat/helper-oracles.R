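# Independent oracles and random-case generators shared across tests.
# Everything here is deliberately naive: plain loops and per-element checks,
# no reuse of the package's vectorized internals.

# All pairs of consecutive pillars per chromosome, by direct scanning.
bf_adjacencies <- function(genome, pmap) {
  paired_ids <- names(pmap$partner)
  out <- list()
  for (chr in unique(genome$chromosome)) {
    g <- genome[genome$chromosome == chr, , drop = FALSE]
    g <- g[order(g$rank), , drop = FALSE]
    pi <- which(g$gene_id %in% paired_ids)
    if (length(pi) < 2L) next
    for (i in seq_len(length(pi) - 1L)) {
      interior <- if (pi[i + 1L] - pi[i] > 1L) {
        g$gene_id[(pi[i] + 1L):(pi[i + 1L] - 1L)]
      } else {
        character()
      }
      out[[length(out) + 1L]] <- list(
        chrom = chr, left = g$gene_id[pi[i]], right = g$gene_id[pi[i + 1L]],
        interior = interior
      )
    }
  }
  out
}

# Exhaustive AU enumeration: test every unordered pair of adjacencies
# against the definition (partner identity + strand consistency).
brute_force_aus <- function(genome, pmap) {
  adj <- bf_adjacencies(genome, pmap)
  strand <- stats::setNames(genome$strand, genome$gene_id)
  partner <- pmap$partner
  keys <- character()
  forms <- character()
  s <- integer()
  q_min <- integer()
  if (length(adj) >= 2L) {
    for (i in seq_along(adj)) {
      for (j in seq_along(adj)) {
        if (i >= j) next
        a <- adj[[i]]
        b <- adj[[j]]
        par <- identical(unname(partner[a$left]), b$left) &&
          identical(unname(partner[a$right]), b$right) &&
          strand[[a$left]] == strand[[b$left]] &&
          strand[[a$right]] == strand[[b$right]]
        inv <- identical(unname(partner[a$left]), b$right) &&
          identical(unname(partner[a$right]), b$left) &&
          strand[[a$left]] == -strand[[b$right]] &&
          strand[[a$right]] == -strand[[b$left]]
        if (par || inv) {
          keys <- c(keys, au_key(a$left, a$right, b$left, b$right))
          forms <- c(forms, if (par) "parallel" else "inverted")
          s <- c(s, length(a$interior) + length(b$interior))
          q_min <- c(q_min, min(length(a$interior), length(b$interior)))
        }
      }
    }
  }
  df <- data.frame(key = keys, form = forms, s = s, q_min = q_min,
                   stringsAsFactors = FALSE)
  df[order(df$key), , drop = FALSE]
}

# Orientation-free identity of an AU: the sorted pair of its bounding
# adjacencies, each written left>right in chromosome order.
au_key <- function(l1, r1, l2, r2) {
  paste(sort(c(paste(l1, r1, sep = ">"), paste(l2, r2, sep = ">"))),
        collapse = "|")
}

# extract_aus() result in the same comparable form.  The stored side-b
# adjacency runs p2>q2 for parallel and q2>p2 for inverted AUs.
au_set_keys <- function(aus) {
  if (nrow(aus) == 0L) {
    return(data.frame(key = character(), form = character(), s = integer(),
                      q_min = integer(), stringsAsFactors = FALSE))
  }
  bl <- ifelse(aus$form == "parallel", aus$p2, aus$q2)
  br <- ifelse(aus$form == "parallel", aus$q2, aus$p2)
  keys <- mapply(au_key, aus$p1, aus$q1, bl, br, USE.NAMES = FALSE)
  df <- data.frame(key = keys, form = aus$form, s = aus$s, q_min = aus$q_min,
                   stringsAsFactors = FALSE)
  df <- df[order(df$key), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Random gene order + random matching.  Half the cases come from the
# collapse simulator (rich in genuine parallel and inverted AUs), half are
# fully random matchings (rich in near-miss configurations).
random_genome_case <- function(seed) {
  set.seed(seed)
  if (stats::runif(1) < 0.5) {
    num_pairs <- sample(10:140, 1L)
    k <- sample(1:4, 1L)
    m <- sample.int(num_pairs, 1L)
    d <- sample(0:20, 1L)
    sim <- simulate_descendant(simulation_config(
      num_pairs = num_pairs, m = m, d = d,
      num_chromosomes = min(k, num_pairs),
      mu = sample(c(1, 1.5, 2), 1L),
      seed = sample.int(.Machine$integer.max, 1L)
    ))
    list(genome = sim$genome, pmap = sim$pmap)
  } else {
    n <- sample(20:300, 1L)
    k <- sample(1:6, 1L)
    df <- data.frame(
      chromosome = sort(sample(sprintf("c%d", seq_len(k)), n, replace = TRUE)),
      gene_id = sprintf("g%03d", sample.int(n)),
      strand = sample(c(1L, -1L), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    df$rank <- stats::ave(seq_len(n), df$chromosome,
                          FUN = seq_along) - 1L
    genome <- genome_table(df)
    npair <- sample(0:(n %/% 2L), 1L)
    sel <- sample(genome$gene_id, 2L * npair)
    pairs <- data.frame(gene_a = sel[seq_len(npair)],
                        gene_b = sel[npair + seq_len(npair)],
                        stringsAsFactors = FALSE)
    list(genome = genome, pmap = paralog_map(pairs, genome))
  }
}

# Fake AU sets for concentration tests: only s and q_min matter.
fake_aus <- function(s, q_min) {
  data.frame(s = as.integer(s), q_min = as.integer(q_min))
}

# Concentration tables for one simulated descendant.
sim_concentration <- function(cfg) {
  sim <- simulate_descendant(cfg)
  empirical_concentration(extract_aus(sim$genome, sim$pmap))
}
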