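#' Classify a fish's movement history
#'
#' Reduces an ordered pool sequence (pool index increases moving upstream)
#' to one of four movement classes: `"none"` when the fish never changed
#' pool, `"downstream"` when every change decreased the pool index,
#' `"upstream"` when every change increased it, and `"both"` otherwise. An
#' empty sequence classifies as `"none"`.
#'
#' @param pools Integer vector of pool indices in chronological order
#'   (gaps already removed); consecutive repeats are collapsed.
#' @return One of `"none"`, `"downstream"`, `"upstream"`, `"both"`.
#' @export
classify_movement <- function(pools) {
  pools <- pools[!is.na(pools)]
  if (length(pools) <= 1) return("none")
  ch <- diff(pools)
  ch <- ch[ch != 0]
  if (length(ch) == 0) return("none")
  if (all(ch < 0)) return("downstream")
  if (all(ch > 0)) return("upstream")
  "both"
}

#' Tabulate movement classes over a cohort
#'
#' @param seqs Named list of pool-index sequences, one per fish (see
#'   [pool_sequences_monthly] and [pool_sequences_detections]).
#' @return Data frame with one row per class (`none`, `downstream`,
#'   `upstream`, `both`): count `n` and percentage `pct` of the cohort.
#' @export
tabulate_movement_classes <- function(seqs) {
  cls <- factor(vapply(seqs, classify_movement, character(1)),
                levels = c("none", "downstream", "upstream", "both"))
  tab <- table(cls)
  data.frame(class = names(tab), n = as.integer(tab),
             pct = 100 * as.integer(tab) / max(length(seqs), 1),
             row.names = NULL)
}

#' Per-fish pool sequences on the monthly basis
#'
#' Pool occupancy sequence from monthly histories (release pool and all
#' detected-in-pool months, in month order; not-detected and expired months
#' are gaps and are dropped).
#'
#' @param histories Data frame `fish_id`, `month`, `obs`.
#' @return Named list of integer pool sequences.
#' @export
pool_sequences_monthly <- function(histories) {
  h <- histories[order(histories$month), ]
  pool <- suppressWarnings(as.integer(sub("pool_", "", as.character(h$obs))))
  keep <- !is.na(pool)
  split(pool[keep], factor(h$fish_id[keep], unique(histories$fish_id)))
}

#' Per-fish pool sequences over all detections
#'
#' Pool sequence of every retained detection in timestamp order, prefixed
#' by the release pool. Lock receivers are excluded, as are detections
#' after the projected tag-expiration date.
#'
#' @param detections Data frame `tag_code`, `receiver_id`, `timestamp`.
#' @param tags Tag deployments (`fish_id`, `tag_code`, `release_pool`,
#'   `release_date`, `expire_date`).
#' @param receivers Receiver table (`receiver_id`, `pool`, `at_lock`).
#' @return Named list of integer pool sequences (one per tagged fish).
#' @export
pool_sequences_detections <- function(detections, tags, receivers) {
  det <- join_detections(detections, tags, receivers)
  det <- det[!det$at_lock & as.Date(det$timestamp) < det$expire_date, ]
  det <- det[order(det$timestamp), ]
  out <- lapply(seq_len(nrow(tags)), function(k) {
    p <- det$pool[det$fish_id == tags$fish_id[k]]
    c(tags$release_pool[k], p)
  })
  stats::setNames(out, tags$fish_id)
}

#' Detection frequency: distinct days with at least one detection
#'
#' @param detections Detections for one fish (`timestamp`, POSIXct or Date).
#' @return Integer count of distinct calendar days.
#' @export
detection_frequency <- function(detections) {
  length(unique(as.Date(detections$timestamp)))
}

#' Detection period: days spanned by the detection record
#'
#' Days between the first detection and the last detection or the projected
#' tag expiration, whichever comes first.
#'
#' @param detections Detections for one fish (`timestamp`).
#' @param expiration Optional projected expiration `Date` capping the last
#'   detection.
#' @return Numeric day count (0 for a single detection; `NA` if none).
#' @export
detection_period <- function(detections, expiration = NULL) {
  if (nrow(detections) == 0) return(NA_real_)
  d <- as.Date(detections$timestamp)
  last <- max(d)
  if (!is.null(expiration)) last <- min(last, as.Date(expiration))
  max(as.numeric(last - min(d)), 0)
}

#' Reduce a movement matrix to stay/upstream/downstream totals
#'
#' For a six-pool movement matrix oriented destination-by-origin
#' (`m[i, j]` = monthly probability of moving to pool `i` from pool `j`;
#' pool index increases upstream), computes per-origin staying
#' probabilities (the diagonal), total downstream probability (sum above
#' the diagonal in each column; defined for origins above the most
#' downstream pool) and total upstream probability (sum below the
#' diagonal; defined for origins below the most upstream pool), together
#' with cross-pool means and ranges and the column sums (which equal
#' `phi * delta` when the matrix is built from model parameters).
#'
#' @param m A 6 x 6 numeric matrix, destination rows by origin columns.
#' @return List with `stay`, `total_down`, `total_up` (per-origin; `NA`
#'   where undefined), `mean_stay`, `mean_down`, `mean_up`, `range_stay`,
#'   `range_down`, `range_up`, and `column_sums`.
#' @export
summarize_movement_matrix <- function(m) {
  if (!is.matrix(m) || !all(dim(m) == c(6, 6)))
    stop("movement matrix must be 6 x 6 (destination rows, origin columns)")
  P <- 6
  stay <- diag(m)
  total_down <- vapply(seq_len(P), function(j)
    if (j == 1) NA_real_ else sum(m[seq_len(j - 1), j]), numeric(1))
  total_up <- vapply(seq_len(P), function(j)
    if (j == P) NA_real_ else sum(m[(j + 1):P, j]), numeric(1))
  list(stay = stay,
       total_down = total_down,
       total_up = total_up,
       mean_stay = mean(stay),
       mean_down = mean(total_down[-1]),
       mean_up = mean(total_up[-P]),
       range_stay = range(stay),
       range_down = range(total_down[-1]),
       range_up = range(total_up[-P]),
       column_sums = colSums(m))
}

#' Published reference movement matrices
#'
#' Posterior-mean monthly movement-probability matrices (the product of
#' survival, battery retention and pool-transition probability) for silver
#' and bighead carp among the six navigation pools of the lower Illinois
#' Waterway (Alton up through Dresden Island), as published from a Bayesian
#' multistate telemetry analysis of that system. Shipped as plain-text
#' fixtures; used for summary-operation checks, never as model input.
#'
#' @param species `"silver"` or `"bighead"`.
#' @return A 6 x 6 matrix, destination rows by origin columns, ordered from
#'   the most downstream pool (Alton) upstream.
#' @export
example_movement_matrix <- function(species = c("silver", "bighead")) {
  species <- match.arg(species)
  path <- system.file("extdata", paste0("movement_matrix_", species, ".csv"),
                      package = "poolstate", mustWork = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  dimnames(m) <- list(to = rownames(m), from = colnames(m))
  m
}
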