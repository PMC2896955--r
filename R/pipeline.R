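#' Run the full fractionation analysis pipeline
#'
#' Composes the whole analysis for one genome: contig filtering, AU
#' extraction, the AU size histogram and its geometric fit, empirical
#' concentration, a matched ensemble of simulated null genomes (same
#' `(n, m, d)`, unbiased single-gene reduction unless configured
#' otherwise), the real-vs-simulated diagonal comparison and its per-size
#' decomposition.  All intermediate artifacts are written to `outdir` as
#' TSV/CSV/JSON together with a manifest; the summary JSON is
#' byte-reproducible for a fixed config and seed.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{genome}{path to a gene-order TSV, or a [genome_table()]}
#'     \item{pairs}{path to a paralog-pair TSV, or a [paralog_map()]}
#'     \item{d}{halving distance to simulate (rearrangement count)}
#'     \item{outdir}{output directory (created if needed)}
#'     \item{reps}{number of null replicates (default 200)}
#'     \item{seed}{RNG seed}
#'     \item{min_duplicated, min_single}{contig-filter thresholds (2, 10)}
#'     \item{mu, retention_bias, inversion_fraction, interleave,
#'       num_chromosomes}{optional simulator overrides; `num_chromosomes`
#'       defaults to half the real chromosome count}
#'     \item{min_expected}{tail pooling floor for the geometric fit (1)}
#'   }
#' @return Invisibly, a list with the filtered `genome` and `pmap`, `aus`,
#'   `histogram`, `fit` (or `NULL` if the histogram cannot support one),
#'   `concentration`, `comparison`, `prop_all`, `prop_offdiag`, `summary`.
#' @export
run_full_pipeline <- function(config) {
  cfg <- config
  if (is.null(cfg$reps)) cfg$reps <- 200L
  if (is.null(cfg$min_duplicated)) cfg$min_duplicated <- 2
  if (is.null(cfg$min_single)) cfg$min_single <- 10
  if (is.null(cfg$mu)) cfg$mu <- 1
  if (is.null(cfg$retention_bias)) cfg$retention_bias <- 0.5
  if (is.null(cfg$inversion_fraction)) cfg$inversion_fraction <- 0.5
  if (is.null(cfg$interleave)) cfg$interleave <- "shuffled"
  if (is.null(cfg$min_expected)) cfg$min_expected <- 1
  if (is.null(cfg$d)) stop("config$d (halving distance) is required")
  stopifnot(cfg$reps >= 1)
  if (!is.null(cfg$outdir) && !dir.exists(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE)
  }
  emit <- function(name, writer) {
    if (!is.null(cfg$outdir)) writer(file.path(cfg$outdir, name))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  genome <- stage("read_genome", {
    if (inherits(cfg$genome, "genome_table")) cfg$genome
    else read_gene_order(cfg$genome)
  })
  pmap <- stage("read_pairs", {
    if (inherits(cfg$pairs, "paralog_map")) cfg$pairs
    else read_paralog_pairs(cfg$pairs, genome)
  })
  genome_f <- stage("filter_contigs",
                    filter_contigs(genome, pmap, cfg$min_duplicated,
                                   cfg$min_single))
  pmap_f <- stage("prune_pairs", prune_pairs(pmap, genome_f))
  emit("genome_filtered.tsv", function(p) write_gene_order(genome_f, p))
  emit("pairs_filtered.tsv", function(p) write_paralog_pairs(pmap_f, p))

  aus <- stage("extract_aus", extract_aus(genome_f, pmap_f))
  emit("aus.tsv", function(p) {
    write_aus(aus, p, sub("\\.tsv$", "_genes.tsv", p))
  })
  hist <- stage("au_histogram", au_histogram(aus))
  emit("au_histogram.csv", function(p) {
    utils::write.csv(data.frame(s = as.integer(names(hist)),
                                N = as.integer(hist)),
                     p, row.names = FALSE)
  })
  fit <- stage("fit_geometric", {
    tryCatch(fit_geometric(hist, min_expected = cfg$min_expected),
             error = function(e) NULL)
  })
  conc <- stage("empirical_concentration", empirical_concentration(aus))
  emit("concentration.csv", function(p) {
    utils::write.csv(as.data.frame(conc), p, row.names = FALSE)
  })

  n <- pmap_f$n
  m <- pmap_f$m
  num_pairs <- (n + m) %/% 2L
  num_chr <- cfg$num_chromosomes
  if (is.null(num_chr)) {
    num_chr <- max(1L, length(unique(genome_f$chromosome)) %/% 2L)
  }
  num_chr <- min(num_chr, num_pairs)
  sims <- stage("simulate_null", {
    subseeds <- sample.int(.Machine$integer.max, cfg$reps)
    lapply(seq_len(cfg$reps), function(i) {
      sim <- simulate_descendant(simulation_config(
        num_pairs = num_pairs, m = m, d = cfg$d,
        num_chromosomes = num_chr, mu = cfg$mu,
        retention_bias = cfg$retention_bias,
        inversion_fraction = cfg$inversion_fraction,
        interleave = cfg$interleave, seed = subseeds[i]
      ))
      empirical_concentration(extract_aus(sim$genome, sim$pmap))
    })
  })
  comp <- stage("diagonal_comparison", diagonal_comparison(conc, sims))
  emit("diagonal_points.csv", function(p) {
    utils::write.csv(comp$points, p, row.names = FALSE)
  })
  prop_all <- proportion_above_by_size(comp, exclude_on_diagonal = FALSE)
  prop_off <- proportion_above_by_size(comp, exclude_on_diagonal = TRUE)

  summary <- list(
    n = n, m = m, d = cfg$d,
    c = reduction_proportion(n, m),
    D = if (n > m) normalized_halving_distance(cfg$d, n, m) else NA_real_,
    au_count = nrow(aus),
    geometric = if (is.null(fit)) NULL else
      list(p = fit$p, N1 = fit$N1, chi2 = fit$chi2, N0_hat = fit$N0_hat),
    above = comp$above, on = comp$on, below = comp$below,
    prop_above_by_s = as.list(prop_all),
    prop_above_offdiag_by_s = as.list(prop_off)
  )
  emit("summary.json", function(p) {
    jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })
  emit("manifest.json", function(p) {
    manifest <- list(
      inputs = list(
        genome = if (is.character(cfg$genome)) cfg$genome else "<in-memory>",
        pairs = if (is.character(cfg$pairs)) cfg$pairs else "<in-memory>"
      ),
      config = cfg[setdiff(names(cfg), c("genome", "pairs"))],
      package = as.character(utils::packageVersion("wgdfrac")),
      r_version = paste(R.version$major, R.version$minor, sep = ".")
    )
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  })

  invisible(list(genome = genome_f, pmap = pmap_f, aus = aus,
                 histogram = hist, fit = fit, concentration = conc,
                 comparison = comp, prop_all = prop_all,
                 prop_offdiag = prop_off, summary = summary))
}

#' Per-genome summary table
#'
#' Assembles the standard summary of post-WGD collapse for a set of
#' genomes: WGD age `t` (My), gene counts `n` and `m`, halving distance
#' `d`, AU count, the derived reduction proportion `c = 2m/(n+m)` and
#' normalized distance `D = 2d/(n-m)`, the above/on/below diagonal triple,
#' and the fitted geometric parameter `p`.  `c` and `D` are recomputed from
#' `n`, `m`, `d` at full precision; round only for presentation.
#'
#' @param genomes A data frame with columns `genome`, `t`, `n`, `m`, `d`
#'   and optionally `au_count`, `above`, `on`, `below`, `p`.
#' @return A data frame in the column order
#'   `genome, t, n, m, d, au_count, c, D, above, on, below, p`.
#' @export
summary_table <- function(genomes) {
  g <- as.data.frame(genomes, stringsAsFactors = FALSE)
  req <- c("genome", "t", "n", "m", "d")
  if (!all(req %in% names(g))) {
    stop("need columns ", paste(req, collapse = ", "))
  }
  for (col in c("au_count", "above", "on", "below", "p")) {
    if (is.null(g[[col]])) g[[col]] <- NA
  }
  g$c <- reduction_proportion(g$n, g$m)
  g$D <- normalized_halving_distance(g$d, g$n, g$m)
  g[, c("genome", "t", "n", "m", "d", "au_count", "c", "D",
        "above", "on", "below", "p")]
}
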