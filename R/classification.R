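#' Distance between a multi-dimensional pattern and the current signal
#'
#' The arithmetic mean of the one-dimensional matching distances
#' [h_distance()] over the shared signal indices:
#' `dist = (1/N) * sum_i h(P_i, S_i)`.
#'
#' @param P_u a [pattern_md()].
#' @param S_cur a [multi_signal()]; its index set must contain the
#'   pattern's indices.
#' @param grid a [match_grid()] shared by all members (default per member:
#'   `default_grid(w)`).
#' @param n matched length, default `min(m, w)` per member.
#' @param indices optional subset of pattern indices to use.
#' @return Non-negative scalar distance.
#' @export
dist_md <- function(P_u, S_cur, grid = NULL, n = NULL, indices = NULL) {
  if (!inherits(P_u, "pattern_md")) mt_invalid_input("P_u must be a pattern_md")
  if (!inherits(S_cur, "multi_signal")) mt_invalid_input("S_cur must be a multi_signal")
  idx <- if (is.null(indices)) P_u$indices else intersect(P_u$indices, indices)
  if (!length(idx)) mt_config_error("no usable pattern indices")
  if (!all(idx %in% S_cur$indices))
    mt_config_error("pattern indices missing from the current signal")
  hs <- vapply(idx, function(i) {
    h_distance(P_u$members[[as.character(i)]],
               S_cur$signals[[as.character(i)]], grid = grid, n = n)$h
  }, numeric(1))
  mean(hs)
}

#' kNNModel class decision for the current motion signal
#'
#' Computes [dist_md()] from the current signal to every bank entry, takes
#' the `k` nearest, partitions them by label, and returns the label of the
#' largest subset. Ties are broken by the smaller mean distance inside the
#' tied subsets, then by bank order. Only member patterns carrying the
#' `class` role enter the distance (all members, if no entry declares
#' roles).
#'
#' @param bank a [pattern_bank()].
#' @param S_cur a [multi_signal()].
#' @param k neighbourhood size, `1 <= k <= n_pairs` (default 3).
#' @param grid,n passed to [dist_md()].
#' @return An object of class `class_decision` with fields `label`,
#'   `neighbors` (data.frame: entry, label, dist), `subset_cards`,
#'   `mean_dists`, `dists` (all bank distances).
#' @export
classify_knn <- function(bank, S_cur, k = 3, grid = NULL, n = NULL) {
  if (!inherits(bank, "pattern_bank")) mt_config_error("bank must be a pattern_bank")
  if (k < 1) mt_invalid_input("k must be >= 1")
  if (k > bank$n_pairs) mt_invalid_input("k exceeds the number of bank entries")
  class_idx <- function(e) {
    has_role <- vapply(e$members, function(p) "class" %in% p$roles, logical(1))
    if (any(has_role)) e$indices[has_role] else e$indices
  }
  dists <- vapply(seq_len(bank$n_pairs), function(u) {
    e <- bank$entries[[u]]
    dist_md(e, S_cur, grid = grid, n = n, indices = class_idx(e))
  }, numeric(1))
  ord <- order(dists)                      # stable: ties keep bank order
  nn <- ord[seq_len(k)]
  nbr <- data.frame(entry = nn, label = bank$labels[nn], dist = dists[nn],
                    stringsAsFactors = FALSE)
  cards <- table(factor(nbr$label, levels = unique(bank$labels[nn])))
  means <- tapply(nbr$dist, nbr$label, mean)
  top <- names(cards)[cards == max(cards)]
  if (length(top) > 1L) {
    mtop <- means[top]
    top <- top[mtop == min(mtop)]
    if (length(top) > 1L)                  # final tie-break: bank order
      top <- top[which.min(match(top, bank$labels[nn]))]
  }
  structure(list(label = top[1], neighbors = nbr,
                 subset_cards = as.list(cards), mean_dists = as.list(means),
                 dists = dists, k = k),
            class = "class_decision")
}

#' @export
print.class_decision <- function(x, ...) {
  cat(sprintf("<class_decision: '%s' (k = %d; cards: %s)>\n", x$label, x$k,
              paste(sprintf("%s=%d", names(x$subset_cards),
                            unlist(x$subset_cards)), collapse = ", ")))
  invisible(x)
}
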