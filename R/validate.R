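# Validation harness: match traced filaments to ground truth and compute
# count error and length RMSE over a synthetic image bank.

#' Match traced filaments to ground-truth filaments
#'
#' Computes the symmetric mean closest-point distance between every traced
#' centerline and every ground-truth centerline, then finds the one-to-one
#' assignment that maximizes the number of matches within
#' `max_match_dist_px` and, among those, minimizes the total distance
#' (weighted bipartite matching).
#'
#' @param pred a [disambiguate()] result or list of paths.
#' @param truth a ground-truth network (`$filaments` with `centerline`), as
#'   in [render_network()]'s `truth`.
#' @param max_match_dist_px distance gate; candidate pairs farther apart are
#'   rejected.
#' @return data.frame with `pred_index`, `truth_index`, `dist_px`.
#' @export
match_filaments <- function(pred, truth, max_match_dist_px = 5) {
  stopifnot(max_match_dist_px > 0)
  np <- length(pred)
  nt <- length(truth$filaments)
  empty <- data.frame(pred_index = integer(0), truth_index = integer(0),
                      dist_px = numeric(0))
  if (np == 0 || nt == 0) return(empty)
  D <- matrix(Inf, np, nt)
  for (i in seq_len(np)) {
    P <- pred[[i]]$pixels
    for (j in seq_len(nt)) {
      Tm <- truth$filaments[[j]]$centerline
      if (nrow(Tm) == 0) next
      D[i, j] <- symmetric_mean_dist(P, Tm)
    }
  }
  el <- which(D <= max_match_dist_px, arr.ind = TRUE)
  if (nrow(el) == 0) return(empty)
  # bipartite max-weight matching; the constant K makes cardinality dominate,
  # then weights prefer the smallest total distance
  K <- max_match_dist_px * (min(np, nt) + 1)
  g <- igraph::make_bipartite_graph(
    c(rep(TRUE, np), rep(FALSE, nt)),
    edges = as.vector(t(cbind(el[, 1], np + el[, 2]))))
  igraph::E(g)$weight <- K - D[el]
  mm <- igraph::max_bipartite_match(g)$matching
  pi <- seq_len(np)
  ti <- mm[seq_len(np)] - np
  ok <- !is.na(ti)
  data.frame(pred_index = pi[ok], truth_index = as.integer(ti[ok]),
             dist_px = D[cbind(pi[ok], ti[ok])])
}

# Symmetric mean closest-point distance between two point chains.
symmetric_mean_dist <- function(A, B) {
  d2 <- outer(A[, 1], B[, 1], "-")^2 + outer(A[, 2], B[, 2], "-")^2
  (mean(sqrt(apply(d2, 1, min))) + mean(sqrt(apply(d2, 2, min)))) / 2
}

#' Relative error in filament count
#'
#' `|n_pred - n_true| / n_true`.
#'
#' @param n_pred,n_true predicted and true filament counts; `n_true >= 1`.
#' @return nonnegative real.
#' @export
count_relative_error <- function(n_pred, n_true) {
  if (n_true < 1) stop("n_true must be >= 1", call. = FALSE)
  abs(n_pred - n_true) / n_true
}

#' Root-mean-square error of matched filament lengths
#'
#' @param matches a [match_filaments()] result (needs >= 1 row).
#' @param pred traced paths (lengths taken from `length_px`).
#' @param truth ground-truth network (lengths from `length_px`).
#' @return RMSE in pixels; `NA` with a warning when there are no matches.
#' @export
length_rmse <- function(matches, pred, truth) {
  if (nrow(matches) == 0) {
    warning("no matched pairs; length RMSE undefined")
    return(NA_real_)
  }
  pl <- vapply(pred[matches$pred_index], function(p) p$length_px, 1)
  tl <- vapply(truth$filaments[matches$truth_index],
               function(f) f$length_px, 1)
  sqrt(mean((pl - tl)^2))
}

#' Run the full pipeline over a validation bank and score it
#'
#' Applies enhancement, foreground clustering, thinning and junction
#' disambiguation to every synthetic image, matches the traced filaments to
#' the ground truth, and reports the per-image relative count error and
#' matched length RMSE together with their maxima over the bank.
#'
#' @param bank a [validation_bank()] result (nonempty list of
#'   `synthetic_network` objects).
#' @param template a [template_bank()]; defaults to the package default.
#' @param min_object_px,max_turn_deg,min_length_px pipeline parameters (see
#'   [estimate_foreground()], [disambiguate()], [length_distribution()]).
#' @param max_match_dist_px matching gate, see [match_filaments()].
#' @return object of class `validation_report`: list with `per_image`
#'   (data.frame: `density_level`, `image_index`, `n_true`, `n_pred`,
#'   `count_rel_error`, `n_matched`, `length_rmse_px`),
#'   `max_count_rel_error`, `max_length_rmse_px`.
#' @export
run_validation <- function(bank, template = template_bank(),
                           min_object_px = 20L, max_turn_deg = 30,
                           min_length_px = 3, max_match_dist_px = 5) {
  stopifnot(length(bank) >= 1)
  rows <- vector("list", length(bank))
  for (i in seq_along(bank)) {
    net <- bank[[i]]
    pred <- trace_paths(net$image, template,
                        min_object_px = min_object_px,
                        max_turn_deg = max_turn_deg,
                        min_length_px = min_length_px)
    n_true <- length(net$truth$filaments)
    n_pred <- length(pred)
    matches <- match_filaments(pred, net$truth, max_match_dist_px)
    rmse <- if (nrow(matches) > 0)
      length_rmse(matches, pred, net$truth) else NA_real_
    rows[[i]] <- data.frame(
      density_level = if (is.null(net$density_level)) n_true else net$density_level,
      image_index = if (is.null(net$image_index)) i else net$image_index,
      n_true = n_true, n_pred = n_pred,
      count_rel_error = count_relative_error(n_pred, n_true),
      n_matched = nrow(matches), length_rmse_px = rmse)
  }
  per_image <- do.call(rbind, rows)
  structure(list(per_image = per_image,
                 max_count_rel_error = max(per_image$count_rel_error),
                 max_length_rmse_px = max(per_image$length_rmse_px, na.rm = TRUE)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation_report: %d images\n", nrow(x$per_image)))
  cat(sprintf("max relative count error: %.4f (%.1f%%)\n",
              x$max_count_rel_error, 100 * x$max_count_rel_error))
  cat(sprintf("max length RMSE: %.2f px\n", x$max_length_rmse_px))
  invisible(x)
}
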