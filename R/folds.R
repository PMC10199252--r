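# Group-aware stratified k-fold assignment. Folds are stratified by class
# and never split one participant's episodes across train and test: the unit
# of assignment is the group (participant), placed greedily so every fold's
# class counts track the global class proportions.

#' Assign group-aware stratified folds
#'
#' @param y binary labels, one per episode.
#' @param groups grouping vector (participant ids) of the same length, or
#'   `NULL` to treat every episode as its own group.
#' @param n_folds number of folds.
#' @param seed integer seed for the assignment shuffle.
#' @return an integer vector of fold ids in `1:n_folds`.
#' @export
make_folds <- function(y, groups = NULL, n_folds = 10L, seed = 1L) {
  y <- as_binary_y(y)
  n <- length(y)
  if (is.null(groups)) groups <- seq_len(n)
  if (length(groups) != n) {
    stop_modulearn("groups must have one entry per episode",
                   "modulearn_contract_error")
  }
  g <- factor(groups)
  minority <- names(which.min(table(y)))
  n_min_groups <- dplyr::n_distinct(g[y == minority])
  if (n_folds > n_min_groups) {
    stop_modulearn(
      sprintf("n_folds (%d) exceeds the minority-class group count (%d)",
              n_folds, n_min_groups),
      "modulearn_parameter_error")
  }

  # per-group class counts
  counts <- table(g, y)
  k <- nlevels(g)
  with_seed(as.integer(seed), {
    ord <- sample(k)
    ord <- ord[order(-rowSums(counts)[ord])] # big groups first, random ties
    fold_counts <- matrix(0, n_folds, 2)
    fold_of_group <- integer(k)
    for (gi in ord) {
      add <- counts[gi, ]
      # least-loaded fold for the classes this group brings, then overall
      cost <- fold_counts %*% add + 1e-3 * rowSums(fold_counts)
      f <- which.min(cost)
      fold_of_group[gi] <- f
      fold_counts[f, ] <- fold_counts[f, ] + add
    }
    fold_of_group[as.integer(g)]
  })
}

# hard guarantee used by every CV loop: no group on both sides of a split
assert_group_integrity <- function(folds, groups) {
  if (is.null(groups)) return(invisible(TRUE))
  tab <- table(groups, folds)
  if (any(rowSums(tab > 0) > 1)) {
    stop_modulearn("internal error: a participant's episodes span folds",
                   "modulearn_contract_error")
  }
  invisible(TRUE)
}
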