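# Trap-scale urbanization index ---------------------------------------------

#' Trap-scale urbanization index
#'
#' The index is the Euclidean distance of a trap's 250-m-buffer covariates
#' (tree cover %, barrier-free angle %) from the hypothetical full-natural
#' state (100, 100), rescaled to \[0, 100\] by dividing the raw distance by
#' sqrt(2). The scaling is global and data-independent, so the index is
#' comparable across studies and stable on subsets: 0 means full tree cover
#' and no artificial barriers, 100 means neither.
#'
#' @param tree_cover_250m tree cover percentage in the 250-m buffer, in
#'   \[0, 100\].
#' @param barrier_free_angle angular percentage of the buffer free of
#'   artificial barriers (roads, buildings), in \[0, 100\].
#' @return numeric vector of index values in \[0, 100\].
#' @examples
#' urbanization_index(100, 100)  # full-natural state -> 0
#' urbanization_index(0, 0)      # fully urban -> 100
#' urbanization_index(60, 80)
#' @export
urbanization_index <- function(tree_cover_250m, barrier_free_angle) {
  .check_percent(tree_cover_250m, "tree_cover_250m")
  .check_percent(barrier_free_angle, "barrier_free_angle")
  sqrt((100 - tree_cover_250m)^2 + (100 - barrier_free_angle)^2) / sqrt(2)
}

#' Add the urbanization index to a trap table
#'
#' @param traps a trap table (see [read_trap_table()]).
#' @return the table with an `urbanization_index` column.
#' @export
add_urbanization_index <- function(traps) {
  traps <- validate_trap_table(traps)
  traps$urbanization_index <-
    urbanization_index(traps$tree_cover_250m, traps$barrier_free_angle)
  traps
}

#' Covariate correlations across spatial scales
#'
#' Reports (a) the Pearson correlation between trap-scale tree cover and
#' barrier-free angle over all traps, and (b) the Pearson correlation between
#' the per-landscape mean trap-scale tree cover and the landscape-scale tree
#' cover. The second checks that traps sample forest and urban area
#' proportionally across scales (a balanced design).
#'
#' @param traps trap table.
#' @param landscapes landscape table (`landscape_id`, `tree_cover_2km`).
#' @return a list with `trap_tree_barrier_r` and `landscape_tree_cover_r`,
#'   plus the sample sizes used for each.
#' @export
covariate_correlations <- function(traps, landscapes) {
  traps <- validate_trap_table(traps)
  if (nrow(traps) < 3L) stop("need at least 3 traps", call. = FALSE)
  if (stats::sd(traps$tree_cover_250m) == 0 ||
      stats::sd(traps$barrier_free_angle) == 0) {
    stop("zero variance in a trap covariate: correlation undefined",
         call. = FALSE)
  }
  r_tb <- stats::cor(traps$tree_cover_250m, traps$barrier_free_angle)

  mean_cover <- tapply(traps$tree_cover_250m, traps$landscape_id, mean)
  ls_cover <- landscapes$tree_cover_2km[
    match(names(mean_cover), landscapes$landscape_id)]
  if (anyNA(ls_cover)) {
    stop("trap table references landscapes absent from landscape table",
         call. = FALSE)
  }
  if (length(mean_cover) < 3L) {
    stop("need at least 3 landscapes for the cross-scale correlation",
         call. = FALSE)
  }
  if (stats::sd(mean_cover) == 0 || stats::sd(ls_cover) == 0) {
    stop("zero variance in landscape cover: correlation undefined",
         call. = FALSE)
  }
  list(trap_tree_barrier_r = r_tb,
       n_traps = nrow(traps),
       landscape_tree_cover_r = stats::cor(as.numeric(mean_cover), ls_cover),
       n_landscapes = length(mean_cover))
}
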