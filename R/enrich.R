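#' Upper-tail hypergeometric over-representation test
#'
#' For a top list of size `n` drawn from a universe of size `N` containing
#' `K` category members, with `k` members observed in the top list, computes
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` by stable log-space
#' summation of the tail.
#'
#' @param top_set,category_set,universe character id sets; both sets must be
#'   subsets of the universe.
#' @return object of class `enrichment_result` with fields `k`, `n`, `K`,
#'   `N`, `p_value`.
#' @export
hypergeom_test <- function(top_set, category_set, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  top_set <- unique(top_set); category_set <- unique(category_set)
  if (!all(top_set %in% universe)) stop("top_set is not a subset of the universe")
  if (!all(category_set %in% universe)) {
    stop("category_set is not a subset of the universe")
  }
  N <- length(universe); K <- length(category_set); n <- length(top_set)
  k <- length(intersect(top_set, category_set))
  structure(list(k = k, n = n, K = K, N = N,
                 p_value = hypergeom_tail(k, N, K, n)),
            class = "enrichment_result")
}

# P(X >= k), X ~ Hypergeom(N, K, n), via log-space summation
hypergeom_tail <- function(k, N, K, n) {
  if (k <= 0) return(1)
  hi <- min(n, K)
  if (k > hi) return(0)
  lt <- lchoose(K, k:hi) + lchoose(N - K, n - (k:hi)) - lchoose(N, n)
  m <- max(lt)
  min(1, exp(m + log(sum(exp(lt - m)))))
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment: k=%d of n=%d (category K=%d of N=%d), P = %.3g\n",
              x$k, x$n, x$K, x$N, x$p_value))
  invisible(x)
}

#' Category over-representation among top-ranked pathways
#'
#' Applies [hypergeom_test()] with the first `top_k` ranked pathways as the
#' top list and all ranked pathways as the universe (the universe is always
#' explicit in the returned counts).
#'
#' @param ranking a `pathway_ranking`.
#' @param category character vector of category pathway ids (e.g. lipid
#'   pathways); ids outside the ranked universe are dropped.
#' @param top_k size of the top list (default 30).
#' @return an `enrichment_result`.
#' @export
category_overrepresentation <- function(ranking, category, top_k = 30L) {
  ids <- ranking$pathway_id
  if (top_k > length(ids)) stop("top_k exceeds the ranking length")
  hypergeom_test(head(ids, top_k), intersect(category, ids), ids)
}

#' Over-representation of several category sets
#'
#' Convenience wrapper over [category_overrepresentation()] for a GMT-style
#' list of sets, with an optional Bonferroni adjustment across the sets
#' (raw values are reported by default).
#'
#' @param ranking a `pathway_ranking`.
#' @param sets named list of id sets (e.g. from [read_gmt()]).
#' @param top_k top-list size.
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return data.table with one row per set: `set_id`, `k`, `n`, `K`, `N`,
#'   `p_value` (and `p_adjusted` when requested).
#' @export
enrich_sets <- function(ranking, sets, top_k = 30L,
                        adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  rows <- lapply(names(sets), function(nm) {
    r <- category_overrepresentation(ranking, sets[[nm]], top_k)
    data.table::data.table(set_id = nm, k = r$k, n = r$n, K = r$K, N = r$N,
                           p_value = r$p_value)
  })
  dt <- data.table::rbindlist(rows)
  if (adjust == "bonferroni") {
    dt$p_adjusted <- pmin(1, dt$p_value * nrow(dt))
  }
  dt
}
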