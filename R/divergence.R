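#' Complete rank pairs over the union of two ranked systems
#'
#' Aligns two ranked distributions on the union of their types. A type
#' observed only in system 1 is assigned, in system 2, the tied rank that
#' all of system 2's unobserved types share: `N2 + (Nx1 + 1) / 2`, where
#' `N2` is the number of types observed in system 2 and `Nx1` the number of
#' types exclusive to system 1 (and symmetrically for system 1).
#'
#' @param ranks1,ranks2 ranked distributions from [rank_distribution()]
#'   (columns `ngram`/`type` and `rank`).
#' @return `data.table` with columns `type`, `r1`, `r2`, `exclusivity`
#'   (`"both"`, `"only_1"`, `"only_2"`).
#' @export
impute_absent_ranks <- function(ranks1, ranks2) {
  r1 <- as_ranked(ranks1)
  r2 <- as_ranked(ranks2)
  if (nrow(r1) == 0L || nrow(r2) == 0L) {
    stop("both systems must be non-empty", call. = FALSE)
  }
  m <- merge(r1[, .(type, r1 = rank)], r2[, .(type, r2 = rank)],
             by = "type", all = TRUE)
  n1 <- nrow(r1); n2 <- nrow(r2)
  nx1 <- sum(is.na(m$r2))  # exclusive to system 1
  nx2 <- sum(is.na(m$r1))
  m[, exclusivity := fifelse(is.na(r2), "only_1",
                      fifelse(is.na(r1), "only_2", "both"))]
  m[is.na(r2), r2 := n2 + (nx1 + 1) / 2]
  m[is.na(r1), r1 := n1 + (nx2 + 1) / 2]
  m[]
}

as_ranked <- function(x) {
  d <- as.data.table(x)
  nm <- if ("type" %in% names(d)) "type" else if ("ngram" %in% names(d)) "ngram"
        else stop("ranked distribution needs a `type` or `ngram` column",
                  call. = FALSE)
  if (!"rank" %in% names(d)) {
    if (!"count" %in% names(d)) stop("need `rank` or `count` column", call. = FALSE)
    d[, rank := frank(-count, ties.method = "average")]
  }
  out <- d[, .(type = get(nm), rank)]
  if (anyDuplicated(out$type)) stop("duplicated types in ranked system", call. = FALSE)
  out
}

rtd_term <- function(r1, r2, alpha) {
  (alpha + 1) / alpha * abs(r1^(-alpha) - r2^(-alpha))^(1 / (alpha + 1))
}

#' Rank-turbulence divergence between two ranked systems
#'
#' Computes the rank-turbulence divergence with exponent `alpha`: for each
#' type in the union (absent types receiving imputed tied ranks, see
#' [impute_absent_ranks()]) the unnormalized contribution is
#' `(alpha+1)/alpha * | r1^-alpha - r2^-alpha |^(1/(alpha+1))`.
#' The normalization is the same sum evaluated in the all-disjoint
#' hypothetical: each system keeps its observed ranks while every one of
#' its types is treated as absent from the other system, so that two
#' systems sharing no types have divergence exactly 1. The result is
#' symmetric, lies in \[0, 1\], and is 0 iff the two systems have identical
#' tied ranks over identical support.
#'
#' @param ranks1,ranks2 ranked distributions (see [impute_absent_ranks()]).
#' @param alpha positive exponent tuning sensitivity to high vs low ranks;
#'   default 1/3, the conventional choice for allotaxonometric comparison
#'   of heavy-tailed vocabularies. The limit cases `alpha -> 0` and
#'   `alpha -> Inf` are not implemented.
#' @return object of class `rtd_result`: list with `alpha`, `divergence`,
#'   `normalization`, `contributions` (a `data.table` `type`, `r1`, `r2`,
#'   `contribution` — normalized, summing to `divergence` — and
#'   `exclusivity`, sorted by contribution descending), and `balance`, a
#'   summary of each system's share of total counts, of all types, and of
#'   exclusive types (count shares are `NA` when counts were not supplied).
#' @export
rank_turbulence_divergence <- function(ranks1, ranks2, alpha = 1 / 3) {
  if (!(length(alpha) == 1L && is.finite(alpha) && alpha > 0)) {
    stop("`alpha` must be a positive finite number", call. = FALSE)
  }
  pairs <- impute_absent_ranks(ranks1, ranks2)
  contrib <- rtd_term(pairs$r1, pairs$r2, alpha)

  r1 <- as_ranked(ranks1)
  r2 <- as_ranked(ranks2)
  n1 <- nrow(r1); n2 <- nrow(r2)
  # all-disjoint hypothetical: every type exclusive to its own system
  disj1 <- rtd_term(r1$rank, n2 + (n1 + 1) / 2, alpha)
  disj2 <- rtd_term(n1 + (n2 + 1) / 2, r2$rank, alpha)
  norm <- sum(disj1) + sum(disj2)

  out <- copy(pairs)
  out[, contribution := contrib / norm]
  setorder(out, -contribution, type)
  d <- sum(out$contribution)

  cnt1 <- count_lookup(ranks1)
  cnt2 <- count_lookup(ranks2)
  tot1 <- if (is.null(cnt1)) NA_real_ else sum(cnt1)
  tot2 <- if (is.null(cnt2)) NA_real_ else sum(cnt2)
  balance <- data.table(
    system = c("system_1", "system_2"),
    pct_total_counts = c(tot1, tot2) / sum(c(tot1, tot2)) * 100,
    pct_all_types = c(n1, n2) / (n1 + n2) * 100,
    pct_exclusive_types = {
      ex1 <- sum(out$exclusivity == "only_1")
      ex2 <- sum(out$exclusivity == "only_2")
      if (ex1 + ex2 == 0) c(NA_real_, NA_real_)
      else c(ex1, ex2) / (ex1 + ex2) * 100
    })
  res <- list(alpha = alpha, divergence = d, normalization = norm,
              contributions = out[], balance = balance)
  class(res) <- "rtd_result"
  res
}

count_lookup <- function(x) {
  d <- as.data.table(x)
  if ("count" %in% names(d)) d$count else NULL
}

#' @export
print.rtd_result <- function(x, ...) {
  cat(sprintf("Rank-turbulence divergence (alpha = %.4g): D = %.6f\n",
              x$alpha, x$divergence))
  print(utils::head(x$contributions, 10))
  invisible(x)
}

#' Drop 3-grams built directly on the anchor phrase
#'
#' Removes from an order-3 ranked distribution every 3-gram whose first two
#' or last two tokens equal the 2-token anchor (e.g. `"my mental health"`,
#' `"mental health is"` for anchor `"mental health"`), then re-ranks the
#' survivors. Used to declutter divergence tables for an anchored corpus,
#' where such phrases are present by construction.
#'
#' @param ranked a ranked distribution of 3-grams (with a `count` column).
#' @param anchor the 2-token anchor phrase.
#' @return the filtered, re-ranked distribution.
#' @export
filter_anchor_phrases <- function(ranked, anchor) {
  d <- as.data.table(ranked)
  nm <- if ("type" %in% names(d)) "type" else "ngram"
  atoks <- strsplit(anchor, " ", fixed = TRUE)[[1]]
  if (length(atoks) != 2L) stop("anchor must be a 2-token phrase", call. = FALSE)
  a <- paste(atoks, collapse = " ")
  g <- d[[nm]]
  drop <- startsWith(g, paste0(a, " ")) | endsWith(g, paste0(" ", a))
  keep <- d[!drop]
  if (nrow(keep) && "count" %in% names(keep)) {
    keep[, rank := frank(-count, ties.method = "average")]
    if ("frequency" %in% names(keep)) keep[, frequency := count / sum(count)]
    setorder(keep, rank)
  }
  keep[]
}

#' Log-rank histogram of a two-system comparison
#'
#' Bins the completed rank pairs on a square grid in
#' `(log10 r1, log10 r2)`; types exclusive to one system are binned along
#' their observed coordinate into a separate exclusive band, mirroring the
#' bottom-edge bands of an allotaxonograph. Cell indices are
#' `floor(log10 r / cell_size)`.
#'
#' @param pairs completed rank pairs from [impute_absent_ranks()].
#' @param cell_size side of a histogram cell in log10-rank units.
#' @return `data.table` with `cell_x`, `cell_y`, `band` (`"shared"`,
#'   `"only_1"`, `"only_2"`; exclusive bands carry `NA` in the unobserved
#'   coordinate), and `count`. Cell counts always sum to the number of
#'   union types.
#' @export
rank_rank_histogram <- function(pairs, cell_size = 0.25) {
  if (!(length(cell_size) == 1L && cell_size > 0)) {
    stop("`cell_size` must be positive", call. = FALSE)
  }
  p <- as.data.table(pairs)
  cell <- function(r) as.integer(floor(log10(r) / cell_size))
  shared <- p[exclusivity == "both",
              .(count = .N, band = "shared"),
              by = .(cell_x = cell(r1), cell_y = cell(r2))]
  ex1 <- p[exclusivity == "only_1",
           .(count = .N, band = "only_1", cell_y = NA_integer_),
           by = .(cell_x = cell(r1))]
  ex2 <- p[exclusivity == "only_2",
           .(count = .N, band = "only_2", cell_x = NA_integer_),
           by = .(cell_y = cell(r2))]
  out <- rbindlist(list(shared, ex1, ex2), use.names = TRUE, fill = TRUE)
  setcolorder(out, c("cell_x", "cell_y", "band", "count"))
  setorder(out, band, cell_x, cell_y, na.last = TRUE)
  out[]
}
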