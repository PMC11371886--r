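#' Random survival forest parameters
#'
#' @param n_trees number of bootstrap trees (default 500).
#' @param mtry variables sampled at each node; default `ceiling(sqrt(p))`.
#' @param min_node_deaths smallest number of events a node must contain to
#'   be split further (default 3).
#' @param min_node_size smallest node size eligible for splitting
#'   (default 15).
#' @param n_split_candidates candidate cut points per variable, taken as its
#'   node-level quantiles at evenly spaced probabilities (default 10).
#' @param seed RNG seed for reproducible forests (`NULL` = current RNG
#'   state).
#' @return object of class `forest_params`.
#' @export
forest_params <- function(n_trees = 500L, mtry = NULL, min_node_deaths = 3L,
                          min_node_size = 15L, n_split_candidates = 10L,
                          seed = NULL) {
  stopifnot(n_trees >= 1, min_node_deaths >= 1, min_node_size >= 2,
            n_split_candidates >= 1)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 min_node_deaths = as.integer(min_node_deaths),
                 min_node_size = as.integer(min_node_size),
                 n_split_candidates = as.integer(n_split_candidates),
                 seed = seed),
            class = "forest_params")
}

#' Fit a random survival forest with log-rank splitting
#'
#' Each tree is grown on a bootstrap sample (with replacement, size n). At
#' every node, `mtry` variables are drawn from the non-forced columns and
#' the `forced` columns (e.g. age and sex, to adjust the ranking for them)
#' are always added to the candidate set. Candidate cut points per variable
#' are its node-level quantiles at `n_split_candidates` evenly spaced
#' probabilities; the chosen split maximizes the absolute two-sample
#' log-rank statistic. Splitting stops below `min_node_size` samples or
#' `min_node_deaths` events, or when no candidate strictly partitions the
#' node. Given a seed the forest is fully deterministic.
#'
#' @param X numeric matrix (subjects x variables) with column names; no
#'   missing values.
#' @param time follow-up times.
#' @param event event indicators (0/1); at least one event required.
#' @param params a [forest_params].
#' @param forced column names always included in the candidate set.
#' @return object of class `survival_forest`: list with `trees` (each a
#'   data.frame of nodes), `in_bag` (list of index vectors), `params`,
#'   `forced`, `var_names`.
#' @export
fit_survival_forest <- function(X, time, event, params = forest_params(),
                                forced = character()) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X must have column names", call. = FALSE)
  if (anyNA(X)) stop("X contains missing values; impute or drop upstream",
                     call. = FALSE)
  stopifnot(length(time) == nrow(X), length(event) == nrow(X))
  event <- as.integer(event != 0)
  if (sum(event) == 0L) stop("no events in the data", call. = FALSE)
  if (!all(forced %in% colnames(X)))
    stop("forced covariates absent from X", call. = FALSE)
  if (!is.null(params$seed)) set.seed(params$seed)
  free_vars <- setdiff(colnames(X), forced)
  mtry <- if (is.null(params$mtry)) ceiling(sqrt(ncol(X)))
          else as.integer(params$mtry)
  mtry <- min(mtry, length(free_vars))
  n <- nrow(X)
  trees <- vector("list", params$n_trees)
  in_bag <- vector("list", params$n_trees)
  for (b in seq_len(params$n_trees)) {
    bag <- sample.int(n, n, replace = TRUE)
    in_bag[[b]] <- bag
    trees[[b]] <- grow_tree(X, time, event, bag, params, free_vars, forced,
                            mtry)
  }
  structure(list(trees = trees, in_bag = in_bag, params = params,
                 forced = forced, var_names = colnames(X)),
            class = "survival_forest")
}

grow_tree <- function(X, time, event, bag, params, free_vars, forced, mtry) {
  nodes <- list()
  # stack of (index vector, node id, depth); preallocated ids
  queue <- list(list(idx = bag, id = 1L, depth = 0L))
  next_id <- 2L
  while (length(queue)) {
    nd <- queue[[length(queue)]]
    queue[[length(queue)]] <- NULL
    idx <- nd$idx
    deaths <- sum(event[idx])
    rec <- list(id = nd$id, depth = nd$depth, split_var = NA_character_,
                split_val = NA_real_, left = NA_integer_,
                right = NA_integer_, n = length(idx), deaths = deaths)
    if (length(idx) >= params$min_node_size &&
        deaths >= params$min_node_deaths) {
      cand <- c(if (mtry > 0) sample(free_vars, mtry) else character(),
                forced)
      ord <- idx[order(time[idx])]
      ts <- time[ord]; ev <- event[ord]
      best_stat <- 0; best_var <- NA_character_; best_cut <- NA_real_
      for (v in cand) {
        xv <- X[ord, v]
        cuts <- unique(stats::quantile(
          xv, seq_len(params$n_split_candidates) /
              (params$n_split_candidates + 1), names = FALSE, type = 7))
        cuts <- cuts[cuts >= min(xv) & cuts < max(xv)]
        if (length(cuts) == 0L) next
        stats_v <- abs(cpp_logrank_stats(ts, ev, xv, cuts))
        j <- which.max(stats_v)
        if (stats_v[j] > best_stat) {
          best_stat <- stats_v[j]; best_var <- v; best_cut <- cuts[j]
        }
      }
      if (!is.na(best_var) && best_stat > 0) {
        left_idx <- idx[X[idx, best_var] <= best_cut]
        right_idx <- idx[X[idx, best_var] > best_cut]
        rec$split_var <- best_var
        rec$split_val <- best_cut
        rec$left <- next_id
        rec$right <- next_id + 1L
        queue[[length(queue) + 1L]] <-
          list(idx = left_idx, id = next_id, depth = nd$depth + 1L)
        queue[[length(queue) + 1L]] <-
          list(idx = right_idx, id = next_id + 1L, depth = nd$depth + 1L)
        next_id <- next_id + 2L
      }
    }
    nodes[[length(nodes) + 1L]] <- rec
  }
  df <- do.call(rbind, lapply(nodes, as.data.frame))
  df[order(df$id), , drop = FALSE]
}

#' Minimal-depth variable importance
#'
#' Per tree, the minimal depth of a variable is the depth of the shallowest
#' node splitting on it (root = 0); a variable never split in a tree is
#' assigned that tree's maximal terminal depth. The importance is the mean
#' over trees; lower values mean greater importance.
#'
#' @param forest a [fit_survival_forest] result.
#' @return named numeric vector of mean minimal depths, sorted ascending
#'   (rank 1 = most important).
#' @export
minimal_depth_importance <- function(forest) {
  stopifnot(inherits(forest, "survival_forest"))
  vars <- forest$var_names
  depths <- matrix(NA_real_, length(forest$trees), length(vars),
                   dimnames = list(NULL, vars))
  for (b in seq_along(forest$trees)) {
    tr <- forest$trees[[b]]
    worst <- max(tr$depth[is.na(tr$split_var)])
    md <- rep(worst, length(vars))
    names(md) <- vars
    splits <- tr[!is.na(tr$split_var), c("split_var", "depth")]
    if (nrow(splits)) {
      agg <- tapply(splits$depth, splits$split_var, min)
      md[names(agg)] <- pmin(md[names(agg)], agg)
    }
    depths[b, ] <- md
  }
  sort(colMeans(depths))
}

#' @export
print.survival_forest <- function(x, ...) {
  nn <- vapply(x$trees, nrow, 1L)
  cat(sprintf(
    "<survival_forest: %d trees, %d variables (%s forced), %.1f nodes/tree>\n",
    length(x$trees), length(x$var_names),
    if (length(x$forced)) paste(x$forced, collapse = "+") else "none",
    mean(nn)))
  invisible(x)
}
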