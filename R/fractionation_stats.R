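#' Gross collapse statistics
#'
#' Two per-genome summaries of post-WGD collapse.  The reduction proportion
#' `c = 2m / (n + m)` is the fraction of ancestral duplicate pairs that have
#' been reduced to a single copy, where `n` is the present-day gene total
#' and `m` the single-copy count; the ancestral tetraploid held `(n + m) / 2`
#' pairs.  The normalized halving distance `D = 2d / (n - m)` scales the
#' genome-halving rearrangement distance `d` (an input to this package,
#' never computed here) by the number of surviving duplicate pairs.
#'
#' @param n Total gene count (positive).
#' @param m Single-copy gene count, `0 <= m <= n` (and `m < n` for `D`).
#' @param d Halving distance, `>= 0`.
#' @return A numeric scalar: `c` in `[0, 1]`, or `D >= 0`.
#' @examples
#' reduction_proportion(n = 5616, m = 4498)         # ~0.89
#' normalized_halving_distance(135, 5616, 4498)     # ~0.24
#' @export
reduction_proportion <- function(n, m) {
  if (any(n <= 0)) stop("n must be positive")
  if (any(m < 0 | m > n)) stop("need 0 <= m <= n")
  2 * m / (n + m)
}

#' @rdname reduction_proportion
#' @export
normalized_halving_distance <- function(d, n, m) {
  if (any(d < 0)) stop("d must be non-negative")
  if (any(m < 0 | n <= m)) {
    stop("need n > m >= 0 (no surviving pairs when n == m)")
  }
  2 * d / (n - m)
}

#' Fit a geometric model to the AU size histogram
#'
#' Under random, independent choice of which paralog pair to reduce, the
#' number `s` of single-copy genes in an AU is approximately geometric.  The
#' model fitted here is `M(s) = N1 * (1 - p)^(s - 1)` for `s >= 1`, with two
#' free parameters `N1` (the expected count at `s = 1`) and `p` in (0, 1);
#' successive sizes decay by the factor `1 - p`.  The observed `N(0)` is
#' deliberately excluded from the fit: the model's continuation to `s = 0`,
#' `N1 / (1 - p)` (see [predict_N0()]), is compared with the observed count
#' to reveal the excess of fully retained adjacent pairs.
#'
#' Estimation minimizes Pearson's chi-square
#' `sum_s (N(s) - M(s))^2 / M(s)` over `s = 1..s_max`.  Sparse tail bins are
#' pooled (from the largest `s` downward) until every pooled expected count
#' reaches `min_expected`.  The minimization scans `p` over a grid of step
#' 0.001 with `N1` profiled out in closed form at each `p`
#' (`N1 = sqrt(sum(O^2/g) / sum(g))` with `g_s = (1-p)^(s-1)`), then refines
#' the best grid point locally.
#'
#' @param hist An [au_histogram()] (or named integer vector of counts with
#'   names `0, 1, 2, ...`).  At least three distinct sizes `s >= 1` must
#'   have positive counts.
#' @param min_expected Minimum pooled expected count in the tail (default 1;
#'   5 gives the textbook-conservative pooling).
#' @return A `geometric_fit`: list with elements `p`, `N1`, `chi2`,
#'   `N0_hat`, `df` (pooled bins minus the two fitted parameters) and
#'   `pooling` (the `min_expected` used).
#' @export
fit_geometric <- function(hist, min_expected = 1) {
  counts <- as.vector(unclass(hist))
  s_all <- as.integer(names(hist))
  if (is.null(s_all) || anyNA(s_all)) s_all <- seq_along(counts) - 1L
  keep <- s_all >= 1L
  s <- s_all[keep]
  O <- as.numeric(counts[keep])
  pos <- s[O > 0]
  if (length(pos) < 3L) {
    stop("need counts at >= 3 distinct sizes s >= 1 to fit")
  }
  # drop trailing zero bins beyond the largest observed size
  smax <- max(pos)
  O <- O[s <= smax]
  s <- s[s <= smax]

  obj <- function(p) geom_chi2(p, s, O, min_expected)
  grid <- seq(0.001, 0.999, by = 0.001)
  chi <- vapply(grid, function(p) obj(p)$chi2, numeric(1))
  i <- which.min(chi)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(function(p) obj(p)$chi2, lower = lo, upper = hi,
                         tol = 1e-8)
  p_hat <- opt$minimum
  fit <- obj(p_hat)
  structure(
    list(p = p_hat, N1 = fit$N1, chi2 = fit$chi2,
         N0_hat = fit$N1 / (1 - p_hat), df = fit$nbins - 2L,
         pooling = min_expected),
    class = "geometric_fit"
  )
}

# Profiled chi-square at a given p, with greedy tail pooling.
geom_chi2 <- function(p, s, O, min_expected) {
  g <- (1 - p)^(s - 1)
  N1 <- sqrt(sum(O^2 / g) / sum(g))
  # pool from the tail until every pooled expected count >= min_expected
  k <- length(g)
  Gp <- numeric(k); Op <- numeric(k)
  nb <- 0L
  accG <- 0; accO <- 0
  for (i in k:1) {
    accG <- accG + g[i]
    accO <- accO + O[i]
    if (N1 * accG >= min_expected || i == 1L) {
      nb <- nb + 1L
      Gp[nb] <- accG; Op[nb] <- accO
      accG <- 0; accO <- 0
    }
  }
  Gp <- Gp[seq_len(nb)]; Op <- Op[seq_len(nb)]
  N1 <- sqrt(sum(Op^2 / Gp) / sum(Gp))
  E <- N1 * Gp
  list(chi2 = sum((Op - E)^2 / E), N1 = N1, nbins = nb)
}

#' @export
print.geometric_fit <- function(x, ...) {
  cat(sprintf(
    "Geometric fit: p = %.4f, N1 = %.2f, chi2 = %.3f on %d bins-2 df\n",
    x$p, x$N1, x$chi2, x$df + 2L))
  cat(sprintf("Extrapolated N0_hat = N1/(1-p) = %.2f\n", x$N0_hat))
  invisible(x)
}

#' Extrapolated AU count at s = 0
#'
#' Continues the fitted geometric model `M(s) = N1 (1-p)^(s-1)` one step
#' below the fitted range, to `s = 0`: `N0_hat = N1 / (1 - p)`.  Comparing
#' this with the *observed* `N(0)` measures the excess of adjacent duplicate
#' pairs retained together — reduction-resistant regions leave
#' `N(0) > N0_hat`.
#'
#' @param fit A `geometric_fit` from [fit_geometric()].
#' @return The extrapolated expected count at `s = 0`.
#' @export
predict_N0 <- function(fit) {
  stopifnot(inherits(fit, "geometric_fit"))
  if (fit$p >= 1) stop("p must be < 1")
  fit$N1 / (1 - fit$p)
}

#' Null concentration model for an AU of size s
#'
#' If, each time a pair is reduced, the surviving copy lands on either
#' chromosome independently with probability 1/2, then the number of an
#' AU's `s` single-copy genes that end up together on one chromosome is a
#' folded Binomial(s, 1/2): the probability that the split is `(q, s - q)`
#' is `b(s, q) + b(s, s - q)` for `q < s/2`, and `b(s, s/2)` once at the
#' midpoint for even `s` (the two homeologous sides are treated
#' symmetrically, so `q` only runs to `floor(s/2)`).  The cumulative
#' `B(s, q)` sums the masses up to `q` and reaches exactly 1 at
#' `q = floor(s/2)`.
#'
#' @param s AU size, an integer `>= 2` (an AU of size 0 or 1 carries no
#'   concentration information).
#' @return A data frame with columns `s`, `q` (`0..floor(s/2)`), `P` (the
#'   folded-binomial mass) and `B` (its cumulative sum).
#' @examples
#' concentration_cdf(4)  # B = 0.125, 0.625, 1
#' @export
concentration_cdf <- function(s) {
  s <- as.integer(s)
  if (length(s) != 1L || s < 2L) stop("s must be a single integer >= 2")
  q <- 0:(s %/% 2L)
  P <- stats::dbinom(q, s, 0.5) + stats::dbinom(s - q, s, 0.5)
  if (s %% 2L == 0L) P[length(P)] <- stats::dbinom(s %/% 2L, s, 0.5)
  data.frame(s = s, q = q, P = P, B = cumsum(P))
}

#' Empirical concentration of single-copy genes in AUs
#'
#' The empirical counterpart of [concentration_cdf()]: `F(s, q)` is the
#' proportion of AUs of size `s` whose minority side holds `q` of the `s`
#' single-copy genes, and `Fhat(s, q)` its cumulative in `q`.  AUs with
#' `s < 2` are excluded (an AU with `s = 1` can only be fractionated one
#' way); sizes with no AU are simply absent.
#'
#' @param aus An `au_set` from [extract_aus()].
#' @return A `concentration_empirical`: data frame with columns `s`, `q`
#'   (the full grid `0..floor(s/2)` for each present `s`), `count`, `F`,
#'   `Fhat`, with the per-size AU totals in `attr(, "n_au")`.
#' @export
empirical_concentration <- function(aus) {
  use <- aus[aus$s >= 2L, , drop = FALSE]
  if (nrow(use) == 0L) {
    out <- data.frame(s = integer(), q = integer(), count = integer(),
                      F = numeric(), Fhat = numeric())
    attr(out, "n_au") <- stats::setNames(integer(), character())
    class(out) <- c("concentration_empirical", "data.frame")
    return(out)
  }
  sizes <- sort(unique(use$s))
  rows <- lapply(sizes, function(sz) {
    qm <- use$q_min[use$s == sz]
    q <- 0:(sz %/% 2L)
    count <- tabulate(qm + 1L, nbins = length(q))
    F <- count / length(qm)
    data.frame(s = sz, q = q, count = count, F = F, Fhat = cumsum(F))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_au <- vapply(sizes, function(sz) sum(use$s == sz), integer(1))
  attr(out, "n_au") <- stats::setNames(n_au, sizes)
  class(out) <- c("concentration_empirical", "data.frame")
  out
}

#' Compare real and simulated concentration, cell by cell
#'
#' For every AU size `s` with at least one real AU, every minority count
#' `q` in `0..floor(s/2)`, and every simulated replicate containing at
#' least one AU of size `s`, emits the point `(x, y)` with `x` the
#' replicate's cumulative concentration `Fhat(s, q)` and `y` the real
#' genome's.  Points above the diagonal (`y > x`) indicate more
#' concentration of single-copy genes on one chromosome in the real genome
#' than under the simulated null.  The full `q` grid is compared — not just
#' the cells the real genome happens to occupy — so that under a true null
#' the above and below counts are exchangeable.  The above/on/below
#' classification compares the two count fractions exactly
#' (cross-multiplied integer counts), never by floating-point equality.
#'
#' @param real A `concentration_empirical` for the genome under study.
#' @param sims List of `concentration_empirical` objects, one per simulated
#'   replicate generated under matched `(n, m, d)`.
#' @return A `diagonal_comparison`: list with `points` (data frame `s`, `q`,
#'   `rep`, `x`, `y`, `class`), the boxed counts `above`, `on`, `below`,
#'   and `per_s` (data frame of per-size counts).
#' @export
diagonal_comparison <- function(real, sims) {
  stopifnot(inherits(real, "concentration_empirical"))
  if (length(sims) == 0L) stop("need at least one simulated replicate")
  cells <- as.data.frame(real)
  if (nrow(cells) == 0L) stop("real genome has no AUs of size >= 2")
  n_real <- attr(real, "n_au")
  # real cumulative counts (integers, for exact comparison)
  A <- unname(n_real[as.character(cells$s)])
  a <- round(cells$Fhat * A)

  pts <- vector("list", length(sims))
  for (r in seq_along(sims)) {
    sim <- sims[[r]]
    n_sim <- attr(sim, "n_au")
    B <- unname(n_sim[as.character(cells$s)])          # NA when s absent
    key <- paste(sim$s, sim$q)
    j <- match(paste(cells$s, cells$q), key)
    b <- round(sim$Fhat[j] * B)
    ok <- !is.na(B)
    if (!any(ok)) next
    yB <- a[ok] * B[ok]
    xA <- b[ok] * A[ok]
    cls <- ifelse(yB > xA, "above", ifelse(yB < xA, "below", "on"))
    pts[[r]] <- data.frame(
      s = cells$s[ok], q = cells$q[ok], rep = r,
      x = b[ok] / B[ok], y = a[ok] / A[ok], class = cls,
      stringsAsFactors = FALSE
    )
  }
  points <- do.call(rbind, pts)
  if (is.null(points) || nrow(points) == 0L) {
    stop("no AU size occurs in both the real genome and any replicate")
  }
  rownames(points) <- NULL
  sizes <- sort(unique(points$s))
  tab <- function(cl) {
    as.integer(tapply(points$class == cl, factor(points$s, levels = sizes),
                      sum))
  }
  per_s <- data.frame(
    s = sizes, above = tab("above"), on = tab("on"), below = tab("below")
  )
  structure(
    list(points = points,
         above = sum(points$class == "above"),
         on = sum(points$class == "on"),
         below = sum(points$class == "below"),
         per_s = per_s),
    class = "diagonal_comparison"
  )
}

#' @export
print.diagonal_comparison <- function(x, ...) {
  cat("Real-vs-simulated concentration: ",
      x$above, " above / ", x$on, " on / ", x$below,
      " below the diagonal (", nrow(x$points), " points)\n", sep = "")
  invisible(x)
}

#' Above-diagonal proportion by AU size
#'
#' Decomposes a [diagonal_comparison()] by AU size `s`: the proportion of
#' points above the diagonal, either among all points
#' (`above / (above + on + below)`) or among off-diagonal points only
#' (`above / (above + below)`, with `exclude_on_diagonal = TRUE`).  Sizes
#' with a zero denominator are omitted.
#'
#' @param comp A `diagonal_comparison`.
#' @param exclude_on_diagonal Ignore points lying exactly on the diagonal.
#' @return A named numeric vector mapping `s` to a proportion.
#' @export
proportion_above_by_size <- function(comp, exclude_on_diagonal = FALSE) {
  stopifnot(inherits(comp, "diagonal_comparison"))
  p <- comp$per_s
  den <- if (exclude_on_diagonal) p$above + p$below
         else p$above + p$on + p$below
  keep <- den > 0L
  stats::setNames(p$above[keep] / den[keep], p$s[keep])
}

#' Average per-size proportions over the descendants of one WGD
#'
#' Descendant genomes of the same WGD event behave as replicates; their
#' per-size above-diagonal proportions are combined by an unweighted mean at
#' each size present in *all* of them (a size missing from any genome is
#' omitted).
#'
#' @param per_genome A list of named numeric vectors as returned by
#'   [proportion_above_by_size()].
#' @return A named numeric vector over the common sizes.
#' @export
average_over_descendants <- function(per_genome) {
  if (length(per_genome) == 0L) stop("need at least one genome")
  common <- Reduce(intersect, lapply(per_genome, names))
  common <- common[order(as.integer(common))]
  if (length(common) == 0L) return(stats::setNames(numeric(), character()))
  vals <- vapply(common, function(s) {
    mean(vapply(per_genome, function(g) g[[s]], numeric(1)))
  }, numeric(1))
  stats::setNames(vals, common)
}
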